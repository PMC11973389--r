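#' SNP genotype container
#'
#' A `genotype_set` holds an animals x markers dosage matrix coded 0/1/2
#' (count of the alternate = A1 allele, `NA` for missing calls) together with
#' marker metadata (chromosome, position, alleles, id).
#'
#' @param dosage integer/numeric matrix, animals in rows, markers in columns;
#'   rownames are animal ids, colnames marker ids.
#' @param map data.frame with columns `id`, `chrom`, `pos`, `a1`, `a2`
#'   matching the marker columns in order.
#' @return an object of class `genotype_set`.
#' @export
genotype_set <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) data_error("genotype dosages must be 0/1/2 or missing")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "a1", "a2")
  if (!all(need %in% names(map)))
    config_error(paste("marker map needs columns:", paste(need, collapse = ", ")))
  if (nrow(map) != ncol(dosage))
    config_error("marker map must cover every marker column")
  colnames(dosage) <- map$id
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("animal_", seq_len(nrow(dosage)))
  structure(list(dosage = dosage, map = map), class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("<genotype_set> %d animals x %d markers on %d chromosome(s), %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

## ---- PLINK bed/bim/fam codec ------------------------------------------------
## The 2-bit SNP-major layout: per marker, ceiling(n/4) bytes, two bits per
## animal starting at the least significant pair. Bit pairs: 00 = hom A1
## (dosage 2), 01 = missing, 10 = het, 11 = hom A2 (dosage 0).

#' Write genotypes as a PLINK bed/bim/fam fileset
#'
#' @param geno a `genotype_set`.
#' @param stem path prefix; `<stem>.bed/.bim/.fam` are created.
#' @return `stem`, invisibly.
#' @export
write_plink <- function(geno, stem) {
  stopifnot(inherits(geno, "genotype_set"))
  n <- nrow(geno$dosage); m <- ncol(geno$dosage)
  fam <- data.frame(fid = rownames(geno$dosage), iid = rownames(geno$dosage),
                    pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(stem, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = geno$map$chrom, id = geno$map$id, cm = 0L,
                    pos = geno$map$pos, a1 = geno$map$a1, a2 = geno$map$a2)
  utils::write.table(bim, paste0(stem, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  nb <- ceiling(n / 4)
  pair_code <- matrix(0L, nrow = 4 * nb, ncol = m)
  d <- geno$dosage
  code <- matrix(1L, n, m)                    # 01 = missing
  code[!is.na(d) & d == 2] <- 0L              # 00 = hom A1
  code[!is.na(d) & d == 1] <- 2L              # 10 = het
  code[!is.na(d) & d == 0] <- 3L              # 11 = hom A2
  pair_code[seq_len(n), ] <- code
  i1 <- seq(1, 4 * nb, by = 4)
  bytes <- pair_code[i1, , drop = FALSE] +
    4L * pair_code[i1 + 1, , drop = FALSE] +
    16L * pair_code[i1 + 2, , drop = FALSE] +
    64L * pair_code[i1 + 3, , drop = FALSE]
  con <- file(paste0(stem, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(stem)
}

#' Read a PLINK bed/bim/fam fileset
#'
#' @param stem path prefix of the `.bed/.bim/.fam` files.
#' @return a `genotype_set` (dosage = count of the bim A1 allele).
#' @export
read_plink <- function(stem) {
  fam <- utils::read.table(paste0(stem, ".fam"), stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(stem, ".bim"), stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "integer",
                                          "integer", "character", "character"))
  n <- nrow(fam); m <- nrow(bim); nb <- ceiling(n / 4)
  con <- file(paste0(stem, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    data_error("not a SNP-major PLINK bed file")
  bytes <- as.integer(readBin(con, "raw", nb * m))
  if (length(bytes) != nb * m) data_error("truncated bed file")
  bytes <- matrix(bytes, nrow = nb, ncol = m)
  dosage_of <- c(2L, NA_integer_, 1L, 0L)  # indexed by pair code 00,01,10,11 (+1)
  pairs <- array(0L, dim = c(4, nb, m))
  b <- bytes
  for (k in 1:4) { pairs[k, , ] <- b %% 4L; b <- b %/% 4L }
  code <- matrix(pairs, nrow = 4 * nb, ncol = m)
  d <- matrix(dosage_of[code[seq_len(n), , drop = FALSE] + 1L], n, m)
  rownames(d) <- fam$V2
  map <- data.frame(id = bim$V2, chrom = bim$V1, pos = bim$V4,
                    a1 = bim$V5, a2 = bim$V6, stringsAsFactors = FALSE)
  genotype_set(d, map)
}

## ---- minimal VCF 4.2 (GT-only) ---------------------------------------------

#' Write genotypes as a minimal VCF 4.2 file
#'
#' GT-only biallelic records; A1 is written as ALT so that the 0/1/2 dosage
#' (ALT-allele count) matches the PLINK A1 dosage.
#'
#' @param geno a `genotype_set`.
#' @param path output path (plain text, uncompressed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_set"))
  ids <- rownames(geno$dosage)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ubtnet",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  gt_of <- c("0/0", "0/1", "1/1")
  d <- t(geno$dosage)                       # markers x animals
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_of[d[ok] + 1L]
  body <- paste(geno$map$chrom, geno$map$pos, geno$map$id, geno$map$a2,
                geno$map$a1, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal GT-only VCF into a genotype set
#'
#' @param path VCF path (plain text).
#' @return a `genotype_set` with dosage = ALT allele count.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) data_error("no #CHROM header line in VCF")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t")
  m <- length(fields)
  d <- matrix(NA_real_, length(ids), m)
  map <- data.frame(id = character(m), chrom = character(m), pos = integer(m),
                    a1 = character(m), a2 = character(m), stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    f <- fields[[j]]
    map$chrom[j] <- f[1]; map$pos[j] <- as.integer(f[2]); map$id[j] <- f[3]
    map$a2[j] <- f[4]; map$a1[j] <- f[5]
    gt <- sub(":.*", "", f[-(1:9)])
    alt <- vapply(strsplit(gt, "[/|]"), function(a) {
      if (any(a == ".")) NA_real_ else sum(a == "1")
    }, numeric(1))
    d[, j] <- alt
  }
  rownames(d) <- ids
  genotype_set(d, map)
}
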