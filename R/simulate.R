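#' Simulation configuration for the synthetic heifer fixture
#'
#' Describes the world the generator emulates: a few hundred admixed heifers
#' measured for correlated body-size, reproductive/ovarian and carcass traits
#' driven by a small set of heritable latent factors, genotyped on a
#' desk-scale SNP panel. Observed traits follow the common-factor measurement
#' model `y = mu + sd * (lambda * eta + covariate shifts + eps)` with
#' `var(eps) = 1 - lambda^2` on the standardized scale, and the latent
#' factors carry a genetic component (heritability `h2`) propagated through a
#' directed acyclic graph of genetic path coefficients.
#'
#' @param n_animals number of animals.
#' @param n_snps number of biallelic markers.
#' @param n_chromosomes autosomes the markers are spread across.
#' @param maf_range allele-frequency range `(lo, hi]` in `(0, 0.5]` from which
#'   per-marker frequencies are drawn uniformly.
#' @param latent_spec data.frame with columns `factor`, `h2` (heritability of
#'   each latent factor, in `[0, 1]`).
#' @param dag_spec data.frame with columns `from`, `to`, `beta`: directed
#'   genetic paths among latent factors; must be acyclic.
#' @param loading_spec data.frame with columns `name`, `block`, `kind`,
#'   `priority`, `factor` (`NA` = pure-noise trait), `loading`, `mean`, `sd`.
#'   Uniqueness is `1 - loading^2` on the standardized scale.
#' @param covariate_spec named list (`year`, `dam_age`, `breed_group`,
#'   `generation`), each `list(levels = ..., effect = ...)` with effects in
#'   within-trait standard-deviation units applied on the observed scale.
#' @param missing_rate,outlier_rate cell-level corruption proportions in
#'   `[0, 1)`.
#' @param seed integer seed; every generator consumes it reproducibly.
#' @param traits `"panel16"` (the default 16-variable analysis panel) or
#'   `"measurement"` (raw girth/follicle/ovary measures from which composite
#'   traits can be derived with [derive_calculated_traits()]).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_animals = 300,
                       n_snps = 2000,
                       n_chromosomes = 10,
                       maf_range = c(0.05, 0.5),
                       latent_spec = NULL,
                       dag_spec = NULL,
                       loading_spec = NULL,
                       covariate_spec = NULL,
                       missing_rate = 0.02,
                       outlier_rate = 0.01,
                       seed = 1L,
                       traits = c("panel16", "measurement")) {
  traits <- match.arg(traits)
  if (n_animals < 1 || n_snps < 1) config_error("n_animals and n_snps must be >= 1")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    config_error("maf_range must lie within (0, 0.5] with lo <= hi")
  if (missing_rate < 0 || missing_rate >= 1 || outlier_rate < 0 || outlier_rate >= 1)
    config_error("missing_rate and outlier_rate must be in [0, 1)")
  latent_spec <- latent_spec %||% data.frame(
    factor = c("body_size", "ovary_size", "yield_grade"),
    h2 = c(0.5, 0.5, 0.5), stringsAsFactors = FALSE)
  if (any(latent_spec$h2 < 0 | latent_spec$h2 > 1))
    config_error("heritabilities must be in [0, 1]")
  dag_spec <- dag_spec %||% data.frame(
    from = "body_size", to = "ovary_size", beta = 0.6, stringsAsFactors = FALSE)
  if (nrow(dag_spec) &&
      !all(c(dag_spec$from, dag_spec$to) %in% latent_spec$factor))
    config_error("dag_spec references unknown factors")
  topo_order(latent_spec$factor, dag_spec)  # errors if cyclic
  loading_spec <- loading_spec %||%
    switch(traits, panel16 = panel16_spec(), measurement = measurement_spec())
  if (!all(stats::na.omit(loading_spec$factor) %in% latent_spec$factor))
    config_error("loading_spec references unknown factors")
  if (any(abs(loading_spec$loading) > 1))
    config_error("standardized loadings must be in [-1, 1]")
  covariate_spec <- covariate_spec %||% list(
    year        = list(levels = c("2015", "2016", "2017", "2018"),
                       effect = c(-0.15, -0.05, 0.05, 0.15)),
    dam_age     = list(levels = c("2", "3", "4plus"),
                       effect = c(-0.1, 0, 0.1)),
    breed_group = list(levels = c("ARI", "ANI", "ADI", "F1"),
                       effect = c(0.1, 0.05, -0.1, 0)),
    generation  = list(levels = c("base", "daughter"),
                       effect = c(0, 0.05)))
  structure(list(n_animals = n_animals, n_snps = n_snps,
                 n_chromosomes = n_chromosomes, maf_range = maf_range,
                 latent_spec = latent_spec, dag_spec = dag_spec,
                 loading_spec = loading_spec, covariate_spec = covariate_spec,
                 missing_rate = missing_rate, outlier_rate = outlier_rate,
                 seed = seed, traits = traits),
            class = "sim_config")
}

# 16-variable analysis panel mirroring a joint body/reproductive/carcass run:
# 7 body-size indicators, 4 ovarian, 3 carcass, plus 2 pure-noise traits
# (body density, intramuscular fat) that no latent factor explains.
panel16_spec <- function() {
  data.frame(
    name = c("mid_girth", "heart_girth", "flank_girth", "body_length",
             "hip_height", "body_weight", "hip_width",
             "uterine_horn_diameter", "left_ovary_diameter",
             "right_ovary_diameter", "antral_follicle_count",
             "ribeye_area", "rump_fat", "yield_grade",
             "body_density", "intramuscular_fat"),
    block = c(rep("body", 7), rep("reproductive", 4), rep("carcass", 5)),
    kind = c(rep("direct", 14), "calculated", "direct"),
    priority = c(rep(1L, 14), 2L, 1L),
    factor = c(rep("body_size", 7), rep("ovary_size", 4),
               rep("yield_grade", 3), NA, NA),
    loading = c(0.90, 0.80, 0.82, 0.70, 0.72, 0.88, 0.73,
                0.60, 0.75, 0.72, 0.65,
                0.75, 0.60, 0.80, 0, 0),
    mean = c(170, 155, 160, 120, 115, 350, 40,
             12, 25, 25, 22, 75, 0.5, 2.5, 1.05, 3.5),
    sd = c(9, 8, 8, 6, 5, 30, 3, 2, 4, 4, 6, 8, 0.15, 0.5, 0.08, 0.8),
    stringsAsFactors = FALSE)
}

# raw measurement panel carrying the source columns for calculated traits
measurement_spec <- function() {
  data.frame(
    name = c("end_girth", "mid_girth", "body_length", "body_weight",
             "heart_girth", "hip_height",
             "foll_small", "foll_medium", "foll_large", "foll_xl",
             "left_ovary_length", "left_ovary_height",
             "right_ovary_length", "right_ovary_height",
             "rib_fat", "rump_fat", "yield_grade"),
    block = c(rep("body", 6), rep("reproductive", 8), rep("carcass", 3)),
    kind = "direct",
    priority = 1L,
    factor = c(rep("body_size", 6), rep("ovary_size", 8),
               rep("yield_grade", 3)),
    loading = c(0.85, 0.90, 0.70, 0.88, 0.80, 0.72,
                0.70, 0.65, 0.55, 0.45, 0.75, 0.70, 0.72, 0.68,
                0.80, 0.60, 0.85),
    mean = c(165, 170, 120, 350, 155, 115,
             15, 6, 2, 1, 30, 20, 30, 20, 0.6, 0.5, 2.5),
    sd = c(8, 9, 6, 30, 8, 5, 5, 2.5, 1, 0.5, 4, 3, 4, 3, 0.15, 0.15, 0.5),
    stringsAsFactors = FALSE)
}

# Kahn topological sort; configuration error on cycles
topo_order <- function(nodes, edges) {
  if (!nrow(edges)) return(nodes)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  out <- character(0)
  queue <- nodes[indeg == 0]
  edges_left <- edges
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    ch <- edges_left$to[edges_left$from == v]
    edges_left <- edges_left[edges_left$from != v, , drop = FALSE]
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(nodes)) config_error("dag_spec contains a cycle")
  out
}

#' Simulate a 0/1/2 genotype panel
#'
#' Unlinked biallelic markers: per-marker allele frequency drawn uniformly
#' from `cfg$maf_range`, dosages binomial(2, p), markers spread evenly over
#' `cfg$n_chromosomes` with increasing positions.
#'
#' @param cfg a [sim_config()].
#' @return a `genotype_set` with attribute `freq` (the drawn frequencies).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_animals; m <- cfg$n_snps
    p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    d <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
    rownames(d) <- sprintf("animal_%03d", seq_len(n))
    chrom <- rep(seq_len(cfg$n_chromosomes), length.out = m)
    chrom <- sort(chrom)
    pos <- unlist(lapply(split(seq_len(m), chrom), function(i)
      seq(1e4, by = 5e4, length.out = length(i))), use.names = FALSE)
    map <- data.frame(id = sprintf("snp_%05d", seq_len(m)),
                      chrom = chrom, pos = pos,
                      a1 = "A", a2 = "G", stringsAsFactors = FALSE)
    g <- genotype_set(d, map)
    attr(g, "freq") <- p
    g
  })
}

#' Simulate latent factors and observed traits
#'
#' Latent genetic values are built from independent marker effects, scaled so
#' each factor's genetic variance equals its heritability, propagated through
#' the genetic DAG, and completed with an orthogonalized residual so the total
#' latent variance is exactly 1 in-sample. Observed traits follow the
#' measurement model in [sim_config()]; fixed-effect shifts act on the
#' observed-trait scale.
#'
#' @param cfg a [sim_config()].
#' @param geno a `genotype_set` from [simulate_genotypes()].
#' @return list with elements `panel` (a `trait_panel`) and `truth` (true
#'   loadings, uniquenesses, latent values `eta`, breeding values `g`,
#'   heritabilities, the genetic DAG and covariate effects).
#' @export
simulate_latent_and_traits <- function(cfg, geno) {
  stopifnot(inherits(cfg, "sim_config"), inherits(geno, "genotype_set"))
  with_seed(cfg$seed + 1L, {
    n <- cfg$n_animals
    lf <- cfg$latent_spec
    ord <- topo_order(lf$factor, cfg$dag_spec)
    Z <- scale(geno$dosage)                 # markers with zero variance -> NaN
    Z[, !is.finite(colSums(Z))] <- 0
    g <- eta <- matrix(0, n, nrow(lf), dimnames = list(rownames(geno$dosage), lf$factor))
    for (f in ord) {
      h2 <- lf$h2[lf$factor == f]
      alpha <- stats::rnorm(ncol(Z))
      r <- as.numeric(Z %*% alpha)
      r <- (r - mean(r)) / stats::sd(r)
      par_edges <- cfg$dag_spec[cfg$dag_spec$to == f, , drop = FALSE]
      inherited <- if (nrow(par_edges))
        as.numeric(g[, par_edges$from, drop = FALSE] %*% par_edges$beta)
      else rep(0, n)
      v_inh <- stats::var(inherited)
      if (v_inh > h2 + 1e-12)
        config_error(sprintf("inherited genetic variance for '%s' exceeds its heritability", f))
      if (v_inh > 0) {                       # orthogonalize own term to inherited part
        r <- r - inherited * (stats::cov(r, inherited) / v_inh)
        r <- r / stats::sd(r)
      }
      gf <- inherited + r * sqrt(max(h2 - v_inh, 0))
      e <- stats::rnorm(n)
      if (h2 > 0 && stats::var(gf) > 0) {
        e <- e - gf * (stats::cov(e, gf) / stats::var(gf))
      }
      e <- if (h2 < 1) (e - mean(e)) / stats::sd(e) * sqrt(1 - h2) else e * 0
      g[, f] <- gf
      eta[, f] <- gf + e
    }
    ls <- cfg$loading_spec
    uniq <- 1 - ls$loading^2
    cov_df <- draw_covariates(cfg, n)
    shift <- covariate_shift(cfg, cov_df)    # n-vector of SD-unit shifts
    y <- matrix(NA_real_, n, nrow(ls), dimnames = list(rownames(eta), ls$name))
    for (j in seq_len(nrow(ls))) {
      common <- if (is.na(ls$factor[j])) rep(0, n) else ls$loading[j] * eta[, ls$factor[j]]
      eps <- stats::rnorm(n, 0, sqrt(uniq[j]))
      y[, j] <- ls$mean[j] + ls$sd[j] * (common + eps + shift)
    }
    meta <- ls[, c("name", "block", "kind", "priority")]
    panel <- trait_panel(y, meta, cov_df)
    truth <- list(loadings = stats::setNames(ls$loading, ls$name),
                  factor_of = stats::setNames(ls$factor, ls$name),
                  uniqueness = stats::setNames(uniq, ls$name),
                  eta = eta, g = g,
                  h2 = stats::setNames(lf$h2, lf$factor),
                  dag = cfg$dag_spec,
                  covariates = cov_df)
    list(panel = panel, truth = truth)
  })
}

draw_covariates <- function(cfg, n) {
  out <- lapply(cfg$covariate_spec, function(cv)
    sample(cv$levels, n, replace = TRUE))
  as.data.frame(out, stringsAsFactors = FALSE)
}

covariate_shift <- function(cfg, cov_df) {
  shift <- rep(0, nrow(cov_df))
  for (nm in names(cfg$covariate_spec)) {
    cv <- cfg$covariate_spec[[nm]]
    shift <- shift + cv$effect[match(cov_df[[nm]], cv$levels)]
  }
  shift
}

#' Append calculated composite traits to a measurement panel
#'
#' Implements the composite-trait arithmetic used for the heifer panel:
#' girth-derived radii, the conical-frustum body volume in litres, body
#' density, the antral follicle count (AFC) as the sum of the four
#' follicle-size classes, and left/right ovary diameters (LOD/ROD) as the
#' mean of each ovary's length and height. Units: girths and lengths in cm,
#' weight in kg, hence volume in L after the /1000 conversion and density in
#' kg/L. Calculated traits are flagged `kind = "calculated"` with a priority
#' rank one below the lowest-priority direct trait, so correlation pruning
#' prefers the direct measures.
#'
#' Records with non-positive girths, body length or body weight are flagged
#' invalid: their volume/density are `NA` and their ids are returned in the
#' `invalid` attribute rather than silently propagated.
#'
#' @param panel a `trait_panel` containing the needed source columns (only
#'   the composites whose sources are present are computed).
#' @return the panel with calculated columns appended; attribute `invalid`
#'   lists flagged animal ids.
#' @export
derive_calculated_traits <- function(panel) {
  stopifnot(inherits(panel, "trait_panel"))
  v <- panel$values
  have <- function(...) all(c(...) %in% colnames(v))
  new <- list()
  invalid <- character(0)
  max_prio <- max(panel$meta$priority)
  if (have("end_girth")) new$radius_end <- v[, "end_girth"] / (2 * pi)
  if (have("mid_girth")) new$radius_mid <- v[, "mid_girth"] / (2 * pi)
  if (have("end_girth", "mid_girth", "body_length")) {
    bad <- !is.na(v[, "end_girth"]) & (v[, "end_girth"] <= 0 |
             v[, "mid_girth"] <= 0 | v[, "body_length"] <= 0)
    bad[is.na(bad)] <- FALSE
    r1 <- v[, "end_girth"] / (2 * pi)
    r2 <- v[, "mid_girth"] / (2 * pi)
    vol <- (pi * v[, "body_length"] * (r1^2 + 2 * r2^2)) / 3 / 1000
    vol[bad] <- NA_real_
    new$volume_l <- vol
    if (have("body_weight")) {
      wbad <- bad | (!is.na(v[, "body_weight"]) & v[, "body_weight"] <= 0)
      dens <- v[, "body_weight"] / vol
      dens[wbad] <- NA_real_
      new$body_density <- dens
    }
    invalid <- rownames(v)[bad]
  }
  if (have("foll_small", "foll_medium", "foll_large", "foll_xl"))
    new$antral_follicle_count <- v[, "foll_small"] + v[, "foll_medium"] +
      v[, "foll_large"] + v[, "foll_xl"]
  if (have("left_ovary_length", "left_ovary_height"))
    new$left_ovary_diameter <- (v[, "left_ovary_length"] + v[, "left_ovary_height"]) / 2
  if (have("right_ovary_length", "right_ovary_height"))
    new$right_ovary_diameter <- (v[, "right_ovary_length"] + v[, "right_ovary_height"]) / 2
  if (!length(new)) return(panel)
  block_of <- c(radius_end = "body", radius_mid = "body", volume_l = "body",
                body_density = "body", antral_follicle_count = "reproductive",
                left_ovary_diameter = "reproductive",
                right_ovary_diameter = "reproductive")
  add <- do.call(cbind, new)
  meta_add <- data.frame(name = names(new),
                         block = unname(block_of[names(new)]),
                         kind = "calculated",
                         priority = max_prio + 1L,
                         stringsAsFactors = FALSE)
  out <- trait_panel(cbind(panel$values, add),
                     rbind(panel$meta, meta_add), panel$covariates)
  attr(out, "invalid") <- invalid
  out
}

#' Inject missing values and Tukey-fence outliers into a panel
#'
#' Masks `missing_rate` of trait cells and displaces `outlier_rate` of the
#' remaining cells far beyond (6 IQR) the Tukey fences of their column, so
#' every injected outlier is detectable by [tukey_flags()]. Injection
#' positions are recorded for recovery tests.
#'
#' @param panel a `trait_panel`.
#' @param cfg a [sim_config()] (uses `missing_rate`, `outlier_rate`, `seed`).
#' @return the corrupted panel with attribute `injection` (a list of
#'   `missing` and `outlier` index matrices).
#' @export
inject_missing_and_outliers <- function(panel, cfg) {
  stopifnot(inherits(panel, "trait_panel"), inherits(cfg, "sim_config"))
  if (cfg$missing_rate == 0 && cfg$outlier_rate == 0) {
    attr(panel, "injection") <- list(missing = cbind(row = integer(0), col = integer(0)),
                                     outlier = cbind(row = integer(0), col = integer(0)))
    return(panel)
  }
  with_seed(cfg$seed + 2L, {
    v <- panel$values
    ncell <- length(v)
    idx <- seq_len(ncell)
    n_miss <- stats::rbinom(1, ncell, cfg$missing_rate)
    miss <- sample(idx, n_miss)
    pool <- setdiff(idx, miss)
    n_out <- stats::rbinom(1, length(pool), cfg$outlier_rate)
    outl <- sample(pool, n_out)
    oc <- arrayInd(outl, dim(v))
    for (k in seq_len(nrow(oc))) {
      col <- v[, oc[k, 2]]
      q <- stats::quantile(col, c(0.25, 0.75), na.rm = TRUE, type = 7)
      iqr <- q[2] - q[1]
      if (iqr <= 0) iqr <- max(stats::sd(col, na.rm = TRUE), 1)
      up <- stats::runif(1) < 0.5
      v[oc[k, 1], oc[k, 2]] <- if (up) q[2] + 6 * iqr else q[1] - 6 * iqr
    }
    v[miss] <- NA_real_
    out <- trait_panel(v, panel$meta, panel$covariates)
    attr(out, "injection") <- list(missing = arrayInd(miss, dim(v)),
                                   outlier = oc)
    out
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Phenotypes as CSV (+ metadata CSV), genotypes as PLINK bed/bim/fam and
#' optionally VCF 4.2, the truth record as JSON, and a manifest listing every
#' file with its md5 checksum.
#'
#' @param panel a `trait_panel`.
#' @param geno a `genotype_set`.
#' @param dir output directory (created if absent).
#' @param truth optional truth record from [simulate_latent_and_traits()].
#' @param vcf also write a VCF export (default `TRUE`).
#' @return the manifest as a data.frame, invisibly.
#' @export
write_fixture <- function(panel, geno, dir, truth = NULL, vcf = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) ubt_stop(paste("directory not writable:", dir),
                                         class = "ubtnet_io_error")
  write_panel_csv(panel, file.path(dir, "phenotypes.csv"))
  write_plink(geno, file.path(dir, "genotypes"))
  files <- c("phenotypes.csv", "phenotypes_meta.csv",
             "genotypes.bed", "genotypes.bim", "genotypes.fam")
  if (vcf) {
    write_vcf(geno, file.path(dir, "genotypes.vcf"))
    files <- c(files, "genotypes.vcf")
  }
  if (!is.null(truth)) {
    jsonlite::write_json(lapply(truth, function(x) {
      if (is.matrix(x)) list(rownames = rownames(x), colnames = colnames(x),
                             values = unname(x)) else x
    }), file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE,
    na = "null")
    files <- c(files, "truth.json")
  }
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
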