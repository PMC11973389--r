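#' Trait panel container
#'
#' A `trait_panel` bundles an animals x traits numeric matrix with per-trait
#' metadata and per-animal covariates. Missing phenotypes are `NA` (never
#' silent zeros). Trait metadata records, for every column, the trait block
#' (`body`, `reproductive` or `carcass`), whether it was measured directly on
#' the animal or calculated from other measures, and a priority rank used by
#' the correlation-pruning stage (lower rank = higher priority; direct
#' measures outrank calculated ones).
#'
#' @param values numeric matrix, one row per animal; rownames are animal ids.
#' @param meta data.frame with columns `name`, `block`, `kind`, `priority`
#'   covering every column of `values` in order.
#' @param covariates data.frame of per-animal categorical covariates
#'   (`year`, `dam_age`, `breed_group`, `generation`), one row per animal.
#' @return an object of class `trait_panel`.
#' @export
trait_panel <- function(values, meta, covariates = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("animal_", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values)))
    data_error("duplicate animal ids in trait panel")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("name", "block", "kind", "priority")
  if (!all(need %in% names(meta)))
    config_error(paste("trait meta must have columns:", paste(need, collapse = ", ")))
  if (nrow(meta) != ncol(values))
    config_error("trait meta must cover every trait column")
  if (!all(meta$kind %in% c("direct", "calculated")))
    config_error("trait kind must be 'direct' or 'calculated'")
  colnames(values) <- meta$name
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = rownames(values))
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(values))
      config_error("covariates must have one row per animal")
    rownames(covariates) <- rownames(values)
  }
  structure(list(values = values, meta = meta, covariates = covariates),
            class = "trait_panel")
}

#' @export
print.trait_panel <- function(x, ...) {
  cat(sprintf("<trait_panel> %d animals x %d traits (%d calculated), %d covariates\n",
              nrow(x$values), ncol(x$values),
              sum(x$meta$kind == "calculated"), ncol(x$covariates)))
  cat("  blocks:", paste(sprintf("%s=%d", names(table(x$meta$block)),
                                 table(x$meta$block)), collapse = " "), "\n")
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.trait_panel <- function(x) dim(x$values)

#' Subset a trait panel by animals and/or traits
#'
#' @param panel a `trait_panel`.
#' @param animals animal ids or row indices to keep (default all).
#' @param traits trait names or column indices to keep (default all).
#' @return a `trait_panel`.
#' @export
panel_subset <- function(panel, animals = NULL, traits = NULL) {
  stopifnot(inherits(panel, "trait_panel"))
  ai <- if (is.null(animals)) seq_len(nrow(panel$values)) else animals
  ti <- if (is.null(traits)) seq_len(ncol(panel$values)) else traits
  if (is.character(ti)) ti <- match(ti, panel$meta$name)
  if (anyNA(ti)) config_error("unknown trait name in panel_subset")
  trait_panel(panel$values[ai, ti, drop = FALSE],
              panel$meta[ti, , drop = FALSE],
              panel$covariates[ai, , drop = FALSE])
}

#' Write / read a trait panel as CSV
#'
#' The CSV layout has the animal id first, then covariates, then trait
#' columns; missing cells are empty fields. Trait metadata travels in a
#' sibling `<stem>_meta.csv` so the panel round-trips.
#'
#' @param panel a `trait_panel`.
#' @param path CSV path for the phenotype table.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  df <- data.frame(animal_id = rownames(panel$values),
                   panel$covariates,
                   as.data.frame(panel$values, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  meta_path <- sub("\\.csv$", "_meta.csv", path)
  utils::write.csv(panel$meta, meta_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @param covariate_cols names of covariate columns in the CSV.
#' @export
read_panel_csv <- function(path, covariate_cols = c("year", "dam_age",
                                                    "breed_group", "generation")) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_path <- sub("\\.csv$", "_meta.csv", path)
  covariate_cols <- intersect(covariate_cols, names(df))
  trait_cols <- setdiff(names(df), c("animal_id", covariate_cols))
  values <- as.matrix(df[, trait_cols, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- df$animal_id
  if (file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    meta <- meta[match(trait_cols, meta$name), , drop = FALSE]
  } else {
    meta <- data.frame(name = trait_cols, block = "body", kind = "direct",
                       priority = seq_along(trait_cols))
  }
  cov <- if (length(covariate_cols)) {
    cv <- df[, covariate_cols, drop = FALSE]
    cv[] <- lapply(cv, as.character)   # covariates are categorical levels
    cv
  } else NULL
  trait_panel(values, meta, cov)
}
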