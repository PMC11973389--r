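#' Pipeline run configuration
#'
#' Collects every stage parameter for an end-to-end run. Defaults follow the
#' reference procedure: r2 pruning threshold 0.85, MSA threshold 0.5, 1000
#' parallel-analysis simulations, 10000 MCMC iterations with 5000 burn-in,
#' SNP QC at MAF 0.05 / call rate 0.95 / HWE 1e-4, bootstrap direction
#' threshold 0.5.
#'
#' @param panel a `trait_panel`, or path to a phenotype CSV.
#' @param geno a `genotype_set`, a PLINK stem, or a VCF path (`NULL` to skip
#'   the genomic stages).
#' @param design `"joint"` (all traits in one analysis) or `"split"` (per
#'   `split_panels`, with latent scores pooled afterwards).
#' @param split_panels named list of trait-name vectors partitioning the
#'   panel (required for `design = "split"`).
#' @param exclude_traits traits dropped up-front (composite measures whose
#'   information is carried by their sources).
#' @param r2_threshold,msa_threshold,tukey_k preprocessing thresholds.
#' @param n_factors `"auto"` (parallel analysis) or an integer per panel.
#' @param pa_sims parallel-analysis simulation count.
#' @param rotation EFA rotation.
#' @param cutoff loading salience cutoff for assignment.
#' @param iterations,burnin,chains CFA MCMC settings.
#' @param maf,call_rate,hwe_p SNP QC thresholds.
#' @param gblup_mode `"multivariate"` or `"univariate"`.
#' @param algorithm `"tabu"`, `"mmhc"` or `"both"`.
#' @param n_boot bootstrap replicate count.
#' @param strength_threshold consensus strength threshold.
#' @param seed master seed fanned out per stage.
#' @param out_dir output directory for [render_report()] (`NULL`: no files).
#' @return an object of class `run_config`.
#' @export
run_config <- function(panel, geno = NULL, design = c("joint", "split"),
                       split_panels = NULL, exclude_traits = character(0),
                       r2_threshold = 0.85, msa_threshold = 0.5, tukey_k = 1.5,
                       n_factors = "auto", pa_sims = 1000,
                       rotation = "oblimin", cutoff = 0.3,
                       iterations = 10000, burnin = 5000, chains = 2,
                       maf = 0.05, call_rate = 0.95, hwe_p = 1e-4,
                       gblup_mode = "univariate",
                       algorithm = c("both", "tabu", "mmhc"),
                       n_boot = 500, strength_threshold = 0.5,
                       seed = 1L, out_dir = NULL) {
  design <- match.arg(design)
  algorithm <- match.arg(algorithm)
  structure(as.list(environment()), class = "run_config")
}

#' Validate a run configuration
#'
#' Schema and cross-reference checks; returns issues rather than throwing,
#' so callers can collect and report them. An empty result means runnable.
#'
#' @param config a [run_config()].
#' @return character vector of issues (empty if valid).
#' @export
validate_config <- function(config) {
  issues <- character(0)
  panel <- config$panel
  if (is.character(panel) && !file.exists(panel))
    issues <- c(issues, sprintf("phenotype file not found: %s", panel))
  if (inherits(panel, "trait_panel")) {
    tn <- panel$meta$name
    if (config$design == "split") {
      if (is.null(config$split_panels))
        issues <- c(issues, "split design requires split_panels")
      else {
        all_t <- unlist(config$split_panels)
        if (anyDuplicated(all_t))
          issues <- c(issues, "split panels overlap")
        unknown <- setdiff(all_t, tn)
        if (length(unknown))
          issues <- c(issues, paste("split panels reference unknown traits:",
                                    paste(unknown, collapse = ", ")))
      }
    }
    unknown_ex <- setdiff(config$exclude_traits, tn)
    if (length(unknown_ex))
      issues <- c(issues, paste("exclude list references unknown traits:",
                                paste(unknown_ex, collapse = ", ")))
  }
  if (is.null(config$geno))
    issues <- c(issues, "no genotypes: gEBV-adjusted network will be skipped")
  if (is.character(config$geno)) {
    ok <- file.exists(config$geno) || file.exists(paste0(config$geno, ".bed"))
    if (!ok) issues <- c(issues, sprintf("genotype input not found: %s", config$geno))
  }
  if (config$r2_threshold <= 0 || config$r2_threshold > 1)
    issues <- c(issues, "r2_threshold must be in (0, 1]")
  if (config$burnin >= config$iterations)
    issues <- c(issues, "burnin must be < iterations")
  issues
}

#' Run the full latent-trait pipeline
#'
#' Preprocessing (outlier/missing filtering, correlation pruning, MSA
#' screening) then, per analysis panel, exploratory factor analysis with
#' parallel-analysis retention and highest-loading assignment, Bayesian
#' confirmatory factor analysis yielding latent-trait scores, then (if
#' genotypes are supplied) SNP QC, GRM, GBLUP and gEBV decorrelation, and
#' finally bootstrap-averaged network learning on both raw latent scores and
#' adjusted gEBV, with an edge-level diff. For the split design, each panel
#' is processed independently and latent scores are pooled over the
#' intersection of retained animals before the genomic and network stages;
#' no within-panel network is attempted for a panel with a single latent
#' factor.
#'
#' @param config a [run_config()].
#' @return an object of class `run_report` (a structured list; see
#'   [render_report()]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hard <- grep("not found|must be|overlap|unknown traits|requires",
               validate_config(config), value = TRUE)
  if (length(hard)) config_error(paste(hard, collapse = "; "))
  seeds <- fan_seeds(config$seed, c("pa", "cfa", "boot_raw", "boot_adj", "misc"))
  panel <- if (is.character(config$panel)) read_panel_csv(config$panel) else config$panel
  geno <- load_geno(config$geno)
  panels <- if (config$design == "joint") list(joint = panel$meta$name)
            else config$split_panels
  report <- list(config = config, design = config$design,
                 panels = list(), univariate = character(0))
  scores_list <- list()
  for (pn in names(panels)) {
    sub <- panel_subset(panel, traits = intersect(panels[[pn]], panel$meta$name))
    st <- process_panel(sub, config, seeds, pn)
    report$panels[[pn]] <- st
    report$univariate <- union(report$univariate, st$univariate)
    if (!is.null(st$scores)) scores_list[[pn]] <- st$scores
  }
  if (!length(scores_list)) data_error("no latent factors identified in any panel")
  pooled <- pool_scores(scores_list)
  report$scores <- pooled
  ## genomic stages
  if (!is.null(geno)) {
    qc <- snp_qc(geno, maf = config$maf, call_rate = config$call_rate,
                 hwe_p = config$hwe_p)
    report$qc <- qc$report
    grm <- build_grm(qc$geno)
    ids <- intersect(rownames(pooled), rownames(grm$g))
    sc <- pooled[ids, , drop = FALSE]
    covs <- panel$covariates[ids, , drop = FALSE]
    gebv <- fit_gblup(sc, covs, grm, mode = config$gblup_mode)
    gebv <- decorrelate_gebv(gebv, grm)
    report$gebv <- gebv
    report$grm_summary <- c(mean_diag = mean(diag(grm$g)),
                            mean_offdiag = mean(grm$g[upper.tri(grm$g)]))
  }
  ## network stages
  learners <- make_learners(config)
  if (ncol(pooled) >= 2) {
    report$network_raw <- lapply(learners, function(L)
      bootstrap_average(pooled, L, n_boot = config$n_boot,
                        seed = seeds[["boot_raw"]],
                        strength_threshold = config$strength_threshold))
    if (!is.null(report$gebv)) {
      report$network_adj <- lapply(learners, function(L)
        bootstrap_average(report$gebv$adjusted, L, n_boot = config$n_boot,
                          seed = seeds[["boot_adj"]],
                          strength_threshold = config$strength_threshold))
      report$network_diff <- lapply(names(learners), function(nm)
        compare_networks(report$network_raw[[nm]], report$network_adj[[nm]]))
      names(report$network_diff) <- names(learners)
    }
  } else {
    report$notes <- c(report$notes %||% character(0),
                      "single pooled latent factor: no network learned")
  }
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) render_report(report, config$out_dir)
  report
}

load_geno <- function(geno) {
  if (is.null(geno) || inherits(geno, "genotype_set")) return(geno)
  if (file.exists(paste0(geno, ".bed"))) return(read_plink(geno))
  if (grepl("\\.vcf$", geno) && file.exists(geno)) return(read_vcf(geno))
  config_error(sprintf("cannot load genotypes from '%s'", geno))
}

# preprocessing + EFA + CFA for one analysis panel
process_panel <- function(sub, config, seeds, panel_name) {
  f1 <- filter_panel(sub, tukey_k = config$tukey_k,
                     exclude_traits = config$exclude_traits)
  f2 <- correlation_prune(f1$panel, r2_threshold = config$r2_threshold)
  f3 <- msa_screen(f2$panel, threshold = config$msa_threshold)
  rep <- merge_reports(merge_reports(f1$report, f2$report), f3$report)
  clean <- f3$panel
  k <- if (identical(config$n_factors, "auto")) {
    pa <- parallel_analysis(clean, n_sims = config$pa_sims,
                            seed = seeds[["pa"]])
    as.integer(pa)
  } else as.integer(config$n_factors)
  k <- max(k, 1L)
  efa <- fit_efa(clean, k = k, rotation = config$rotation)
  efa <- assign_highest_loading(efa, cutoff = config$cutoff)
  unassigned <- names(efa$assignment)[is.na(efa$assignment)]
  measurement <- split(names(efa$assignment)[!is.na(efa$assignment)],
                       efa$assignment[!is.na(efa$assignment)])
  measurement <- measurement[lengths(measurement) >= 2]
  dropped_small <- setdiff(unique(stats::na.omit(efa$assignment)),
                           names(measurement))
  if (length(dropped_small))
    unassigned <- union(unassigned, names(efa$assignment)[
      efa$assignment %in% dropped_small])
  if (!length(measurement)) {
    return(list(filter_report = rep, k = k, efa = efa, cfa = NULL,
                scores = NULL, univariate = names(efa$assignment)))
  }
  names(measurement) <- label_factors(measurement, clean$meta, panel_name)
  spec <- cfa_spec(measurement, iterations = config$iterations,
                   burnin = config$burnin, chains = config$chains,
                   seed = seeds[["cfa"]])
  post <- fit_cfa(clean, spec)
  unexpl <- drop_unexplained(post, threshold = config$cutoff)
  msa_dropped <- rep$dropped_traits$trait[rep$dropped_traits$reason == "msa"]
  univariate <- Reduce(union, list(unassigned, unexpl$indicator[unexpl$unexplained],
                                   msa_dropped))
  list(filter_report = rep, k = k, efa = efa, cfa = post,
       unexplained = unexpl, scores = factor_scores(post),
       univariate = univariate)
}

# name each latent factor after the dominant block of its indicators
label_factors <- function(measurement, meta, panel_name) {
  base <- vapply(measurement, function(ind) {
    bl <- meta$block[match(ind, meta$name)]
    top <- names(sort(table(bl), decreasing = TRUE))[1]
    c(body = "BS", reproductive = "OS", carcass = "YG")[top]
  }, character(1))
  out <- base
  dup <- duplicated(base) | duplicated(base, fromLast = TRUE)
  out[dup] <- paste0(base[dup], seq_along(base)[dup])
  unname(out)
}

pool_scores <- function(scores_list) {
  ids <- Reduce(intersect, lapply(scores_list, rownames))
  if (!length(ids)) data_error("no common animals across split panels")
  out <- do.call(cbind, lapply(scores_list, function(s) s[ids, , drop = FALSE]))
  nm <- unlist(lapply(scores_list, colnames), use.names = FALSE)
  if (anyDuplicated(nm)) nm <- make.unique(nm, sep = "_")
  colnames(out) <- nm
  out
}

make_learners <- function(config) {
  L <- list(
    tabu = function(d) tabu_search(d),
    mmhc = function(d) mmhc(d))
  switch(config$algorithm, both = L, tabu = L["tabu"], mmhc = L["mmhc"])
}

#' Render a run report to files
#'
#' Writes machine-readable tables (filter report, loading/PSD/R-squared CFA
#' tables, latent scores, gEBV, QC report, network edge lists and diffs) and
#' a human-readable markdown summary. Non-convergence is flagged at the top
#' of the summary.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of files written.
#' @export
render_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  w <- function(obj, name) {
    path <- file.path(dir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    files <<- c(files, path)
  }
  md <- c("# Latent-trait pipeline report", "")
  for (pn in names(report$panels)) {
    st <- report$panels[[pn]]
    if (!is.null(st$cfa) && !st$cfa$converged)
      md <- c(md, sprintf("**WARNING: CFA for panel '%s' did NOT converge (PSRF > 1.1).**", pn), "")
  }
  for (pn in names(report$panels)) {
    st <- report$panels[[pn]]
    w(st$filter_report$stages, sprintf("filter_stages_%s.csv", pn))
    if (nrow(st$filter_report$dropped_traits))
      w(st$filter_report$dropped_traits, sprintf("dropped_traits_%s.csv", pn))
    w(export_loading_table(st$efa), sprintf("efa_loadings_%s.csv", pn))
    md <- c(md, sprintf("## Panel %s", pn),
            sprintf("- retained factors (parallel analysis): %d", st$k),
            sprintf("- overall KMO: %.3f", st$filter_report$kmo))
    if (!is.null(st$cfa)) {
      tab <- st$cfa$summary
      names(tab) <- c("latent_trait", "phenotypic_parameter", "loading",
                      "psd", "r2", "psrf")
      w(tab, sprintf("cfa_table_%s.csv", pn))
      md <- c(md, sprintf("- CFA: %d indicators across %d latent trait(s); %s",
                          nrow(tab), length(unique(tab$latent_trait)),
                          if (st$cfa$converged) "converged (all PSRF <= 1.1)"
                          else "NOT converged"))
    }
    md <- c(md, "")
  }
  if (length(report$univariate))
    md <- c(md, "## Recommended for univariate modeling",
            paste("-", report$univariate), "")
  if (!is.null(report$scores))
    w(data.frame(animal_id = rownames(report$scores), report$scores),
      "latent_scores.csv")
  if (!is.null(report$qc)) w(report$qc, "snp_qc.csv")
  if (!is.null(report$gebv)) {
    w(data.frame(animal_id = rownames(report$gebv$gebv), report$gebv$gebv),
      "gebv.csv")
    w(data.frame(animal_id = rownames(report$gebv$adjusted),
                 report$gebv$adjusted), "gebv_adjusted.csv")
  }
  for (kind in c("network_raw", "network_adj")) {
    for (nm in names(report[[kind]])) {
      net <- report[[kind]][[nm]]
      stem <- file.path(dir, paste0(kind, "_", nm))
      export_network(net, stem)
      files <- c(files, paste0(stem, ".csv"), paste0(stem, ".dot"))
      e <- dag_edges(net$consensus)
      md <- c(md, sprintf("## %s (%s)", kind, nm),
              if (nrow(e)) sprintf("- %s -> %s", e$from, e$to)
              else "- (no consensus edges)", "")
    }
  }
  for (nm in names(report$network_diff)) {
    d <- report$network_diff[[nm]]
    if (nrow(d)) w(d, sprintf("network_diff_%s.csv", nm))
  }
  summary_path <- file.path(dir, "summary.md")
  writeLines(md, summary_path)
  invisible(c(files, summary_path))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> design=%s, %d panel(s), %d pooled latent trait(s)\n",
              x$design, length(x$panels),
              if (is.null(x$scores)) 0L else ncol(x$scores)))
  for (pn in names(x$panels))
    cat(sprintf("  %s: k=%d, %d traits after filtering\n", pn, x$panels[[pn]]$k,
                nrow(x$panels[[pn]]$efa$loadings)))
  if (!is.null(x$network_adj))
    for (nm in names(x$network_adj)) {
      e <- dag_edges(x$network_adj[[nm]]$consensus)
      cat(sprintf("  adjusted network (%s): %s\n", nm,
                  if (nrow(e)) paste(e$from, "->", e$to, collapse = "; ")
                  else "empty"))
    }
  invisible(x)
}
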