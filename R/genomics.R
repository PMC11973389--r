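#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test: conditional on the observed allele counts, sums the
#' probabilities of all heterozygote counts no more probable than the one
#' observed (the enumeration underlying the standard fast recurrence).
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom ref, het, hom alt).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) config_error("need at least one genotyped individual")
  n1 <- 2 * n_aa + n_ab                     # allele A count
  n2 <- 2 * n_bb + n_ab
  rare <- min(n1, n2)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(h) up to a constant: fixed allele counts, multinomial x 2^h
  logp <- hets * log(2) - lfactorial(hets) -
    lfactorial((rare - hets) / 2) - lfactorial((2 * n - rare - hets) / 2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- n_ab
  p_obs <- pr[match(obs, hets)]
  if (is.na(p_obs)) data_error("heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

#' SNP quality control
#'
#' Removes non-autosomal markers, then applies, in fixed order: call-rate
#' (retain > `call_rate`), minor allele frequency (retain >= `maf`), and the
#' exact Hardy-Weinberg test (remove `p < hwe_p`). Criteria are evaluated on
#' the marker set surviving the previous step; per-criterion removal counts
#' are reported.
#'
#' @param geno a `genotype_set`.
#' @param maf minimum minor allele frequency (default 0.05).
#' @param call_rate minimum call rate, exclusive (default 0.95).
#' @param hwe_p HWE exact-test removal threshold (default 1e-4).
#' @return list `geno` (filtered) and `report` (data.frame of per-stage
#'   marker counts).
#' @export
snp_qc <- function(geno, maf = 0.05, call_rate = 0.95, hwe_p = 1e-4) {
  stopifnot(inherits(geno, "genotype_set"))
  d <- geno$dosage
  m0 <- ncol(d)
  autosomal <- grepl("^[0-9]+$", as.character(geno$map$chrom))
  d <- d[, autosomal, drop = FALSE]
  map <- geno$map[autosomal, , drop = FALSE]
  n_auto <- m0 - ncol(d)
  cr <- colMeans(!is.na(d))
  keep <- cr > call_rate
  n_cr <- sum(!keep)
  d <- d[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  p <- colMeans(d, na.rm = TRUE) / 2
  mafs <- pmin(p, 1 - p)
  keep <- mafs >= maf
  n_maf <- sum(!keep)
  d <- d[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  hwe <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    hwe_exact_test(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                   sum(x == 0, na.rm = TRUE))
  }, numeric(1))
  keep <- hwe >= hwe_p
  n_hwe <- sum(!keep)
  d <- d[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  if (!ncol(d)) ubt_stop("all markers removed by QC", class = "ubtnet_data_error")
  report <- data.frame(
    stage = c("input", "non_autosomal", "call_rate", "maf", "hwe", "retained"),
    removed = c(NA, n_auto, n_cr, n_maf, n_hwe, NA),
    markers = c(m0, m0 - n_auto, m0 - n_auto - n_cr,
                m0 - n_auto - n_cr - n_maf, ncol(d), ncol(d)),
    stringsAsFactors = FALSE)
  list(geno = genotype_set(d, map), report = report)
}

#' VanRaden method-1 genomic relationship matrix
#'
#' `G = Z Z' / (2 sum p_j (1 - p_j))` where `Z` centers the dosage matrix at
#' twice the observed allele frequencies; missing calls are mean-imputed per
#' marker beforehand. A diagonal ridge (1e-6, escalating tenfold to at most
#' 1e-3) is added if the Cholesky factorization fails; the lower-triangular
#' factor `L` with `G = L L'` is stored for gEBV decorrelation.
#'
#' @param geno a QC'd `genotype_set`.
#' @return an object of class `grm`: `g` (the matrix), `L` (lower Cholesky
#'   factor), `freq` (allele frequencies used), `ridge`.
#' @export
build_grm <- function(geno) {
  stopifnot(inherits(geno, "genotype_set"))
  d <- geno$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- 2 * p[j]
  z <- sweep(d, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) data_error("all markers monomorphic; GRM undefined")
  g <- tcrossprod(z) / denom
  ridge <- 0
  l <- NULL
  for (r in c(0, 1e-6, 1e-5, 1e-4, 1e-3)) {
    l <- tryCatch(t(chol(g + diag(r, nrow(g)))), error = function(e) NULL)
    if (!is.null(l)) { ridge <- r; break }
  }
  if (is.null(l))
    ubt_stop("GRM not positive definite even with 1e-3 ridge",
             class = "ubtnet_data_error")
  if (ridge > 0) g <- g + diag(ridge, nrow(g))
  dimnames(g) <- list(rownames(d), rownames(d))
  structure(list(g = g, L = l, freq = p, ridge = ridge), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d animals, mean diag %.3f, ridge %g\n",
              nrow(x$g), mean(diag(x$g)), x$ridge))
  invisible(x)
}

#' GBLUP for latent-trait scores
#'
#' Mixed model `y = X b + u + e` per latent trait with `u ~ N(0, G x Su)`
#' (Kronecker structure in the multivariate mode, per-trait `G s2u` in the
#' univariate mode) and independent residuals. Variance components are
#' estimated by EM-REML after rotating the model by the eigenvectors of `G`,
#' which diagonalizes the random-effect covariance; fixed effects are GLS
#' (BLUE) and breeding values BLUP at the converged components.
#'
#' @param scores numeric matrix of latent-trait phenotypes (animals x
#'   factors, rownames = animal ids).
#' @param covariates data.frame of fixed-effect factors for the same animals
#'   (may be `NULL` for an intercept-only model).
#' @param grm a [build_grm()] result covering the scored animals.
#' @param mode `"multivariate"` (joint fit, default) or `"univariate"`.
#' @param tol relative EM convergence tolerance (default 1e-8).
#' @param max_iter EM iteration cap (default 500).
#' @param fix_vc optional list `Su`, `Se` (k x k matrices) to skip variance
#'   estimation and solve at the given components.
#' @return an object of class `gebv_set`: `gebv` (animals x traits), `fixed`
#'   (BLUE estimates), `Su`, `Se`, `h2` (per-trait ratio), `converged`,
#'   `loglik` trace, `mode`.
#' @export
fit_gblup <- function(scores, covariates = NULL, grm,
                      mode = c("multivariate", "univariate"),
                      tol = 1e-8, max_iter = 500, fix_vc = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(grm, "grm"))
  scores <- as.matrix(scores)
  ids <- rownames(scores)
  if (is.null(ids) || !all(ids %in% rownames(grm$g)))
    config_error("animals in scores must be present in the GRM")
  g <- grm$g[ids, ids]
  x <- build_design(covariates, nrow(scores))
  if (mode == "univariate" && ncol(scores) > 1) {
    fits <- lapply(seq_len(ncol(scores)), function(j)
      fit_gblup(scores[, j, drop = FALSE], covariates, grm,
                mode = "multivariate", tol = tol, max_iter = max_iter,
                fix_vc = if (is.null(fix_vc)) NULL else
                  list(Su = fix_vc$Su[j, j, drop = FALSE],
                       Se = fix_vc$Se[j, j, drop = FALSE])))
    gebv <- do.call(cbind, lapply(fits, function(f) f$gebv))
    colnames(gebv) <- colnames(scores)
    return(structure(list(gebv = gebv,
                          fixed = lapply(fits, `[[`, "fixed"),
                          Su = diag(vapply(fits, function(f) f$Su[1, 1], 0), ncol(scores)),
                          Se = diag(vapply(fits, function(f) f$Se[1, 1], 0), ncol(scores)),
                          h2 = vapply(fits, function(f) f$h2, 0),
                          converged = all(vapply(fits, `[[`, TRUE, "converged")),
                          loglik = NULL, mode = "univariate", ids = ids),
                     class = "gebv_set"))
  }
  k <- ncol(scores); pX <- ncol(x)
  eg <- eigen(g, symmetric = TRUE)
  d <- pmax(eg$values, 1e-10)
  u <- eg$vectors
  yr <- crossprod(u, scores)                 # rotated records
  xr <- crossprod(u, x)
  n <- nrow(yr)
  if (qr(x)$rank < pX) {
    bad <- colnames(x)[qr(x)$pivot[-seq_len(qr(x)$rank)]]
    config_error(paste("singular fixed-effect design; confounded columns:",
                       paste(bad, collapse = ", ")))
  }
  if (is.null(fix_vc)) {
    vc <- em_reml(yr, xr, d, tol = tol, max_iter = max_iter)
  } else {
    vc <- list(Su = as.matrix(fix_vc$Su), Se = as.matrix(fix_vc$Se),
               converged = TRUE, loglik = numeric(0))
  }
  sol <- gls_blup(yr, xr, d, vc$Su, vc$Se)
  gebv <- u %*% sol$ustar
  rownames(gebv) <- ids
  colnames(gebv) <- colnames(scores) %||% paste0("trait", seq_len(k))
  h2 <- diag(as.matrix(vc$Su)) / (diag(as.matrix(vc$Su)) + diag(as.matrix(vc$Se)))
  structure(list(gebv = gebv, fixed = sol$b, Su = vc$Su, Se = vc$Se, h2 = h2,
                 converged = vc$converged, loglik = vc$loglik, mode = mode,
                 ids = ids),
            class = "gebv_set")
}

#' @export
print.gebv_set <- function(x, ...) {
  cat(sprintf("<gebv_set> %d animals x %d traits (%s), h2 = %s, %s\n",
              nrow(x$gebv), ncol(x$gebv), x$mode,
              paste(sprintf("%.2f", x$h2), collapse = "/"),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

build_design <- function(covariates, n) {
  if (is.null(covariates) || !ncol(as.data.frame(covariates)))
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  cv <- as.data.frame(covariates)
  cv[] <- lapply(cv, function(col) {
    if (is.character(col) || is.logical(col)) factor(col) else col
  })
  # drop single-level factors (no contrast possible)
  keep <- vapply(cv, function(col) !is.factor(col) || nlevels(col) > 1, TRUE)
  cv <- cv[, keep, drop = FALSE]
  if (!ncol(cv)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  stats::model.matrix(~ ., data = cv)
}

# EM-REML on the eigen-rotated model: record i has covariance
# V_i = d_i Su + Se. The E-step includes the fixed-effect uncertainty term,
# making the updates REML rather than ML. Plain EM converges geometrically
# but slowly, so the loop applies Aitken extrapolation along the EM path
# every few iterations (jumps are accepted only when both extrapolated
# matrices stay positive semi-definite); the convergence test remains the
# relative size of the raw EM step.
em_reml <- function(yr, xr, d, tol = 1e-8, max_iter = 500) {
  n <- nrow(yr); k <- ncol(yr)
  vy <- stats::var(as.matrix(yr))
  su <- vy / 2 + diag(1e-6, k)
  se <- vy / 2 + diag(1e-6, k)
  pack <- function(a, b) c(a[lower.tri(a, diag = TRUE)],
                           b[lower.tri(b, diag = TRUE)])
  unpack <- function(v) {
    m <- length(v) / 2
    mk <- function(w) {
      out <- matrix(0, k, k)
      out[lower.tri(out, diag = TRUE)] <- w
      out + t(out) - diag(diag(out), k)
    }
    list(mk(v[seq_len(m)]), mk(v[m + seq_len(m)]))
  }
  psd_ok <- function(m, strict = FALSE) {
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (strict) min(ev) > 1e-10 else min(ev) > -1e-10
  }
  ll <- numeric(0)
  converged <- FALSE
  prev_step <- NULL
  delta <- Inf
  for (it in seq_len(max_iter)) {
    step <- tryCatch(em_reml_step(yr, xr, d, su, se), error = function(e) e)
    if (inherits(step, "error") || !is.finite(step$loglik)) {
      stop(structure(class = c("ubtnet_convergence_error", "ubtnet_error",
                               "error", "condition"),
                     list(message = sprintf(
                       "EM-REML failed at iteration %d: %s", it,
                       if (inherits(step, "error")) conditionMessage(step)
                       else "non-finite restricted log-likelihood"),
                       call = sys.call(-1), loglik = ll)))
    }
    ll <- c(ll, step$loglik)
    th0 <- pack(su, se)
    th1 <- pack(step$su, step$se)
    delta <- max(abs(th1 - th0)) / (1 + max(abs(th1)))
    su <- step$su; se <- step$se
    # EM increases the restricted likelihood monotonically; near-flat
    # variance ridges make the parameter step a poor convergence gauge, so
    # either a small parameter step or a stationary likelihood terminates
    ll_rel <- if (it > 1) abs(ll[it] - ll[it - 1]) / (1 + abs(ll[it])) else Inf
    if (delta < tol || ll_rel < tol) { converged <- TRUE; break }
    cur_step <- th1 - th0
    if (!is.null(prev_step) && it %% 5 == 0) {
      denom <- sqrt(sum(prev_step^2))
      r <- if (denom > 0) sqrt(sum(cur_step^2)) / denom else 1
      if (r > 0 && r < 1) {
        thj <- th1 + r / (1 - r) * cur_step
        cand <- unpack(thj)
        if (psd_ok(cand[[1]]) && psd_ok(cand[[2]], strict = TRUE)) {
          su <- cand[[1]]; se <- cand[[2]]
          cur_step <- NULL                   # rate estimate invalid after jump
        }
      }
    }
    prev_step <- cur_step
  }
  if (!converged)
    warning(sprintf(
      "EM-REML stopped at the %d-iteration cap (last relative change %.2e); estimates flagged non-converged",
      max_iter, delta))
  list(Su = su, Se = se, converged = converged, loglik = ll)
}

# one EM-REML update of (Su, Se)
em_reml_step <- function(yr, xr, d, su, se) {
  n <- nrow(yr); k <- ncol(yr)
  sol <- gls_blup(yr, xr, d, su, se, want_cov = TRUE)
  su_new <- matrix(0, k, k); se_new <- matrix(0, k, k)
  llik <- 0
  for (i in seq_len(n)) {
    vi <- d[i] * su + se
    vinv <- chol2inv(chol(vi))
    ri <- yr[i, ] - drop(crossprod(sol$b, xr[i, ]))
    mi <- xr[i, ]
    fvar <- sol_cb_block(sol$cb, mi, k)      # REML fixed-effect term
    cu <- d[i] * su
    m_u <- cu %*% vinv %*% ri
    s_u <- cu - cu %*% vinv %*% cu + cu %*% vinv %*% fvar %*% vinv %*% cu
    su_new <- su_new + (s_u + tcrossprod(m_u)) / d[i]
    m_e <- se %*% vinv %*% ri
    s_e <- se - se %*% vinv %*% se + se %*% vinv %*% fvar %*% vinv %*% se
    se_new <- se_new + s_e + tcrossprod(m_e)
    llik <- llik - 0.5 * (determinant(vi)$modulus + drop(crossprod(ri, vinv %*% ri)))
  }
  list(su = su_new / n, se = se_new / n, loglik = as.numeric(llik))
}

# E[b] covariance contribution for record i: x_i' C x_i with C the kp x kp
# covariance of vec(b); returns the k x k block
sol_cb_block <- function(cb, mi, k) {
  pX <- length(mi)
  out <- matrix(0, k, k)
  for (a in seq_len(pX)) for (b in seq_len(pX)) {
    out <- out + mi[a] * mi[b] *
      cb[((a - 1) * k + 1):(a * k), ((b - 1) * k + 1):(b * k)]
  }
  out
}

# GLS fixed effects and BLUP of rotated breeding values at given components
gls_blup <- function(yr, xr, d, su, se, want_cov = FALSE) {
  n <- nrow(yr); k <- ncol(yr); pX <- ncol(xr)
  lhs <- matrix(0, pX * k, pX * k)
  rhs <- numeric(pX * k)
  vinv_list <- vector("list", n)
  for (i in seq_len(n)) {
    vi <- d[i] * su + se
    vinv <- chol2inv(chol(vi))
    vinv_list[[i]] <- vinv
    mi <- xr[i, ]
    lhs <- lhs + kronecker(tcrossprod(mi), vinv)
    vy <- drop(vinv %*% yr[i, ])
    rhs <- rhs + rep(vy, times = pX) * rep(mi, each = k)   # kron(mi, vinv y_i)
  }
  cb <- chol2inv(chol(lhs))
  bvec <- cb %*% rhs
  b <- matrix(bvec, nrow = k)               # k x p, trait-fastest layout
  b <- t(b)                                 # p x k
  ustar <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ri <- yr[i, ] - drop(crossprod(b, xr[i, ]))
    ustar[i, ] <- d[i] * su %*% vinv_list[[i]] %*% ri
  }
  list(b = b, ustar = ustar, cb = if (want_cov) cb else NULL)
}

#' Decorrelate gEBV through the GRM Cholesky factor
#'
#' Left-multiplies each trait's gEBV vector by `L^-1` (with `G = L L'`),
#' removing the relatedness-induced covariance among individuals so that the
#' network-learning stage's independence assumptions hold.
#'
#' @param gebv a `gebv_set` (or plain matrix of gEBV).
#' @param grm the [build_grm()] result used in fitting.
#' @return the input with an `adjusted` matrix added (or, for matrix input,
#'   the adjusted matrix itself).
#' @export
decorrelate_gebv <- function(gebv, grm) {
  stopifnot(inherits(grm, "grm"))
  m <- if (inherits(gebv, "gebv_set")) gebv$gebv else as.matrix(gebv)
  ids <- rownames(m)
  if (is.null(ids) || !all(ids %in% rownames(grm$g)))
    config_error("gEBV animal ids must match the GRM")
  li <- match(ids, rownames(grm$g))
  if (length(li) != nrow(grm$g) || any(li != seq_along(li))) {
    # sub-matrix case: refactor G over the scored animals
    l <- t(chol(grm$g[ids, ids]))
  } else l <- grm$L
  adj <- forwardsolve(l, m)
  dimnames(adj) <- dimnames(m)
  if (inherits(gebv, "gebv_set")) {
    gebv$adjusted <- adj
    gebv
  } else adj
}
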