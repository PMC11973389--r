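#' Flag outliers by Tukey's rule
#'
#' Flags values outside `[Q1 - k*IQR, Q3 + k*IQR]` with quartiles computed by
#' linear interpolation of order statistics (quantile type 7, the convention
#' mainstream statistical environments default to). Missing entries are
#' ignored when computing fences and are never flagged.
#'
#' @param values numeric vector (may contain `NA`).
#' @param k fence multiplier (default 1.5).
#' @return logical vector, `TRUE` where flagged.
#' @export
tukey_flags <- function(values, k = 1.5) {
  flags <- rep(FALSE, length(values))
  ok <- !is.na(values)
  if (sum(ok) < 4) {
    warning("fewer than 4 non-missing values; no outlier flags computed")
    return(flags)
  }
  q <- stats::quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  flags[ok] <- values[ok] < lo | values[ok] > hi
  flags
}

new_filter_report <- function() {
  list(stages = data.frame(stage = character(0), animals_in = integer(0),
                           animals_out = integer(0), traits_in = integer(0),
                           traits_out = integer(0), stringsAsFactors = FALSE),
       dropped_traits = data.frame(trait = character(0), reason = character(0),
                                   detail = character(0), stringsAsFactors = FALSE),
       dropped_pairs = data.frame(kept = character(0), dropped = character(0),
                                  r = numeric(0), r2 = numeric(0),
                                  stringsAsFactors = FALSE),
       msa = NULL, kmo = NA_real_,
       notes = character(0))
}

report_stage <- function(rep, stage, a_in, a_out, t_in, t_out) {
  rep$stages <- rbind(rep$stages, data.frame(
    stage = stage, animals_in = a_in, animals_out = a_out,
    traits_in = t_in, traits_out = t_out, stringsAsFactors = FALSE))
  rep
}

#' Outlier-to-missing and complete-case filtering
#'
#' Applies [tukey_flags()] per trait, sets flagged cells to missing, then
#' removes every animal with any missing value among the retained traits
#' (complete-case). Setting outliers missing before row deletion minimizes
#' animal loss compared with dropping an animal at first offence. The
#' flag/drop round is repeated until no new cell is flagged, so the whole
#' filter is idempotent: re-running it on its own output is a no-op.
#'
#' @param panel a `trait_panel`.
#' @param tukey_k fence multiplier.
#' @param exclude_traits traits to drop up-front (the case-specific composite
#'   exclusions — e.g. when their information is already carried by source
#'   measures — are expressed here rather than hard-coded).
#' @return list `panel` (filtered) and `report` (a filter report).
#' @export
filter_panel <- function(panel, tukey_k = 1.5, exclude_traits = character(0)) {
  stopifnot(inherits(panel, "trait_panel"))
  rep <- new_filter_report()
  rep$notes <- c(rep$notes,
                 "tukey quantile convention: linear interpolation (type 7)")
  a0 <- nrow(panel$values); t0 <- ncol(panel$values)
  if (length(exclude_traits)) {
    keep <- setdiff(panel$meta$name, exclude_traits)
    dropped <- intersect(panel$meta$name, exclude_traits)
    if (length(dropped))
      rep$dropped_traits <- rbind(rep$dropped_traits, data.frame(
        trait = dropped, reason = "excluded",
        detail = "config exclude-list", stringsAsFactors = FALSE))
    panel <- panel_subset(panel, traits = keep)
  }
  rep <- report_stage(rep, "exclude", a0, nrow(panel$values), t0, ncol(panel$values))
  # iterate outlier-to-missing + complete-case to a fixed point, so that
  # re-applying the cascade changes nothing (fences move once rows drop)
  v <- panel$values
  cov <- panel$covariates
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    n_out <- 0L
    for (j in seq_len(ncol(v))) {
      fl <- suppressWarnings(tukey_flags(v[, j], k = tukey_k))
      n_out <- n_out + sum(fl)
      v[fl, j] <- NA_real_
    }
    rep$notes <- c(rep$notes,
                   sprintf("round %d: outlier cells set missing: %d", round_i, n_out))
    complete <- stats::complete.cases(v)
    if (!any(complete))
      ubt_stop("no complete-case animals survive filtering",
               class = "ubtnet_data_error")
    v <- v[complete, , drop = FALSE]
    cov <- cov[complete, , drop = FALSE]
    if (n_out == 0L && all(complete)) break
  }
  out <- trait_panel(v, panel$meta, cov)
  rep <- report_stage(rep, "outlier_and_complete_case", a0, nrow(out$values),
                      t0, ncol(out$values))
  list(panel = out, report = rep)
}

#' Prune highly correlated trait pairs with direct-measure priority
#'
#' Repeatedly finds the trait pair with the largest squared Pearson
#' correlation at or above `r2_threshold` and drops the lower-priority member:
#' calculated traits lose to direct ones, ties break by the configured
#' priority rank, then by column order. Iterates until no pair is at or above
#' threshold. The threshold applies to r-squared (so r2 = 0.85 means
#' |r| >= 0.922), matching a squared-correlation reading of the rule.
#'
#' @param panel a `trait_panel`.
#' @param r2_threshold squared-correlation threshold in (0, 1].
#' @param report optional existing filter report to append to.
#' @return list `panel`, `report`.
#' @export
correlation_prune <- function(panel, r2_threshold = 0.85, report = NULL) {
  stopifnot(inherits(panel, "trait_panel"))
  if (r2_threshold <= 0 || r2_threshold > 1)
    config_error("r2_threshold must be in (0, 1]")
  rep <- report %||% new_filter_report()
  a0 <- nrow(panel$values); t0 <- ncol(panel$values)
  repeat {
    v <- panel$values
    if (ncol(v) < 2) break
    r <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
    r2 <- r^2
    diag(r2) <- 0
    r2[is.na(r2)] <- 0
    if (max(r2) < r2_threshold) break
    ij <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    drop <- pick_lower_priority(panel$meta, i, j)
    keep <- if (drop == i) j else i
    rep$dropped_pairs <- rbind(rep$dropped_pairs, data.frame(
      kept = panel$meta$name[keep], dropped = panel$meta$name[drop],
      r = r[i, j], r2 = r2[i, j], stringsAsFactors = FALSE))
    rep$dropped_traits <- rbind(rep$dropped_traits, data.frame(
      trait = panel$meta$name[drop], reason = "correlation",
      detail = sprintf("r2=%.4f with %s", r2[i, j], panel$meta$name[keep]),
      stringsAsFactors = FALSE))
    panel <- panel_subset(panel, traits = setdiff(seq_len(ncol(v)), drop))
  }
  rep <- report_stage(rep, "correlation_prune", a0, nrow(panel$values),
                      t0, ncol(panel$values))
  list(panel = panel, report = rep)
}

# lower priority loses: calculated < direct, then larger priority rank,
# then later column
pick_lower_priority <- function(meta, i, j) {
  ki <- meta$kind[i]; kj <- meta$kind[j]
  if (ki != kj) return(if (ki == "calculated") i else j)
  if (meta$priority[i] != meta$priority[j])
    return(if (meta$priority[i] > meta$priority[j]) i else j)
  max(i, j)
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Computes the overall KMO statistic and per-variable MSA from the
#' anti-image partial correlations `q[j,k] = -S[j,k]/sqrt(S[j,j]S[k,k])`
#' (with `S` the inverse correlation matrix):
#' `KMO = sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal pairs, and
#' `MSA[j]` analogously restricted to row `j`. A near-singular correlation
#' matrix gets a 1e-8 diagonal ridge (with a warning) before inversion.
#'
#' @param panel a `trait_panel` or a numeric matrix/correlation matrix.
#' @param is_cor set `TRUE` if `panel` is already a correlation matrix.
#' @return list `kmo` (overall) and `msa` (named per-variable vector). If all
#'   off-diagonal correlations are zero the statistic is undefined: `NA` is
#'   returned with a warning.
#' @export
kmo <- function(panel, is_cor = FALSE) {
  r <- if (inherits(panel, "trait_panel")) {
    stats::cor(panel$values, use = "pairwise.complete.obs")
  } else if (is_cor) as.matrix(panel)
  else stats::cor(as.matrix(panel), use = "pairwise.complete.obs")
  p <- ncol(r)
  off <- row(r) != col(r)
  if (all(abs(r[off]) < 1e-12)) {
    warning("all correlations are zero; KMO undefined")
    return(list(kmo = NA_real_, msa = stats::setNames(rep(NA_real_, p), colnames(r))))
  }
  s <- tryCatch(solve(r), error = function(e) NULL)
  if (is.null(s)) {
    warning("correlation matrix near-singular; applying 1e-8 ridge")
    s <- tryCatch(solve(r + diag(1e-8, p)), error = function(e) NULL)
    if (is.null(s)) {
      cn <- colnames(r)[colSums(abs(r) > 0.999) > 1]
      data_error(paste("singular correlation matrix; collinear set:",
                       paste(cn, collapse = ", ")))
    }
  }
  d <- 1 / sqrt(diag(s))
  q <- -s * outer(d, d)      # anti-image partial correlations
  diag(q) <- 0
  r0 <- r; diag(r0) <- 0
  overall <- sum(r0^2) / (sum(r0^2) + sum(q^2))
  msa <- rowSums(r0^2) / (rowSums(r0^2) + rowSums(q^2))
  names(msa) <- colnames(r)
  list(kmo = overall, msa = msa)
}

#' Iterative MSA screening
#'
#' While any per-variable MSA is below `threshold`, removes the variable with
#' the lowest MSA (ties broken by column order) and recomputes, stopping when
#' all survive or fewer than 3 variables remain (which halts the pipeline).
#'
#' @param panel a `trait_panel`.
#' @param threshold minimum acceptable MSA (default 0.5).
#' @param report optional filter report to append to.
#' @return list `panel`, `report` (with final `kmo` and `msa` recorded).
#' @export
msa_screen <- function(panel, threshold = 0.5, report = NULL) {
  stopifnot(inherits(panel, "trait_panel"))
  rep <- report %||% new_filter_report()
  a0 <- nrow(panel$values); t0 <- ncol(panel$values)
  repeat {
    k <- kmo(panel)
    if (all(is.na(k$msa))) break
    if (all(k$msa >= threshold, na.rm = TRUE)) break
    worst <- which.min(replace(k$msa, is.na(k$msa), Inf))
    rep$dropped_traits <- rbind(rep$dropped_traits, data.frame(
      trait = panel$meta$name[worst], reason = "msa",
      detail = sprintf("MSA=%.4f", k$msa[worst]), stringsAsFactors = FALSE))
    panel <- panel_subset(panel, traits = setdiff(seq_len(ncol(panel$values)), worst))
    if (ncol(panel$values) < 3)
      ubt_stop("fewer than 3 variables survive MSA screening",
               class = "ubtnet_data_error")
  }
  k <- kmo(panel)
  rep$kmo <- k$kmo
  rep$msa <- k$msa
  rep <- report_stage(rep, "msa_screen", a0, nrow(panel$values),
                      t0, ncol(panel$values))
  list(panel = panel, report = rep)
}

#' Combine two filter reports sequentially
#' @keywords internal
merge_reports <- function(a, b) {
  list(stages = rbind(a$stages, b$stages),
       dropped_traits = rbind(a$dropped_traits, b$dropped_traits),
       dropped_pairs = rbind(a$dropped_pairs, b$dropped_pairs),
       msa = b$msa %||% a$msa, kmo = if (!is.na(b$kmo)) b$kmo else a$kmo,
       notes = c(a$notes, b$notes))
}
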