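#' Exploratory factor analysis (minimum residual or maximum likelihood)
#'
#' Fits the common-factor model `R ~ Lambda Phi Lambda' + Psi` to the
#' correlation matrix of a standardized trait panel. The default extraction
#' minimizes the sum of squared off-diagonal residuals over the uniquenesses
#' (minres); maximum likelihood delegates to [stats::factanal()]. Rotation is
#' oblique oblimin (quartimin criterion, gradient projection) by default,
#' with orthogonal varimax as an option. Each factor is reflected so its
#' largest-magnitude loading is positive, removing sign indeterminacy.
#'
#' @param panel a `trait_panel` or numeric matrix (columns standardized
#'   internally).
#' @param k number of factors (>= 1 and below the Lederman bound).
#' @param method `"minres"` or `"ml"`.
#' @param rotation `"oblimin"`, `"varimax"` or `"none"`.
#' @return an object of class `factor_model`: `loadings` (pattern matrix),
#'   `uniquenesses`, `factor_corr` (identity for orthogonal solutions),
#'   `assignment` (filled by [assign_highest_loading()]), `k`, `n_obs`,
#'   `method`, `rotation`.
#' @export
fit_efa <- function(panel, k, method = c("minres", "ml"),
                    rotation = c("oblimin", "varimax", "none")) {
  method <- match.arg(method)
  rotation <- match.arg(rotation)
  x <- if (inherits(panel, "trait_panel")) panel$values else as.matrix(panel)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  p <- ncol(x)
  if (k < 1) config_error("k must be >= 1")
  lederman <- floor((2 * p + 1 - sqrt(8 * p + 1)) / 2)
  if (k > lederman)
    config_error(sprintf("k = %d exceeds the Lederman bound %d for %d traits",
                         k, lederman, p))
  r <- stats::cor(x)
  fit <- if (method == "minres") minres_extract(r, k, n_obs = nrow(x))
         else ml_extract(x, k)
  lam <- fit$loadings
  phi <- diag(k)
  if (rotation == "varimax" && k > 1) {
    vr <- stats::varimax(lam, normalize = TRUE)
    lam <- lam %*% vr$rotmat
  } else if (rotation == "oblimin" && k > 1) {
    ob <- oblimin_rotate(lam)
    lam <- ob$loadings
    phi <- ob$phi
  }
  refl <- reflect_factors(lam, phi)
  lam <- refl$loadings; phi <- refl$phi
  colnames(lam) <- colnames(phi) <- rownames(phi) <- paste0("F", seq_len(k))
  rownames(lam) <- colnames(x)
  # communality + uniqueness = 1 on the standardized scale by construction
  communality <- diag(lam %*% phi %*% t(lam))
  uniq <- pmax(1 - communality, 1e-3)
  structure(list(loadings = lam, uniquenesses = stats::setNames(uniq, colnames(x)),
                 factor_corr = phi,
                 assignment = stats::setNames(rep(NA_character_, p), colnames(x)),
                 k = k, n_obs = nrow(x), method = method, rotation = rotation,
                 converged = fit$converged,
                 retention_evidence = NULL),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d traits, %d factors (%s, %s rotation)\n",
              nrow(x$loadings), x$k, x$method, x$rotation))
  print(round(x$loadings, 3))
  invisible(x)
}

# minres: optimize uniquenesses; loadings from the top-k eigenpairs of the
# reduced correlation matrix. Heywood cases are bounded at psi >= 1e-3.
minres_extract <- function(r, k, n_obs) {
  p <- ncol(r)
  smc <- 1 - 1 / diag(solve(r + diag(1e-8, p)))
  start <- pmin(pmax(1 - smc, 0.05), 0.95)
  lam_of <- function(psi) {
    rr <- r
    diag(rr) <- 1 - psi
    e <- eigen(rr, symmetric = TRUE)
    v <- pmax(e$values[seq_len(k)], 0)
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(v), k)
  }
  obj <- function(psi) {
    res <- r - tcrossprod(lam_of(psi))
    sum(res[upper.tri(res)]^2)
  }
  opt <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = rep(1e-3, p), upper = rep(1, p),
                      control = list(maxit = 500, factr = 1e4))
  if (any(opt$par <= 1e-3 + 1e-9))
    warning("Heywood case: uniqueness bounded at 1e-3")
  lam <- lam_of(opt$par)
  list(loadings = lam, uniquenesses = stats::setNames(opt$par, colnames(r)),
       converged = opt$convergence == 0)
}

ml_extract <- function(x, k) {
  fa <- stats::factanal(x, factors = k, rotation = "none")
  lam <- unclass(fa$loadings)
  list(loadings = lam,
       uniquenesses = pmax(fa$uniquenesses, 1e-3),
       converged = TRUE)
}

# Oblique quartimin rotation by gradient projection (Jennrich's GPFoblq
# scheme). Returns the pattern matrix and factor correlation matrix.
oblimin_rotate <- function(a, maxit = 500, tol = 1e-6) {
  k <- ncol(a)
  tm <- diag(k)
  n1 <- matrix(1, k, k) - diag(k)
  crit <- function(l) {
    l2 <- l^2
    g <- l * (l2 %*% n1)
    list(f = sum(l2 * (l2 %*% n1)) / 4, grad = g)
  }
  ti <- solve(tm)
  l <- a %*% t(ti)
  q <- crit(l)
  g <- -t(t(l) %*% q$grad %*% ti)
  al <- 1
  for (it in seq_len(maxit)) {
    gp <- g - tm %*% diag(colSums(tm * g))
    s <- sqrt(sum(gp^2))
    if (s < tol) break
    al <- 2 * al
    improved <- FALSE
    for (half in 0:15) {
      tt <- tm - al * gp
      tt <- tt %*% diag(1 / sqrt(colSums(tt^2)))
      ti2 <- solve(tt)
      l2 <- a %*% t(ti2)
      q2 <- crit(l2)
      if (q2$f < q$f - 0.5 * s^2 * al * 1e-4) { improved <- TRUE; break }
      al <- al / 2
    }
    if (!improved) break
    tm <- tt; l <- l2; q <- q2
    g <- -t(t(l) %*% q$grad %*% solve(tm))
  }
  list(loadings = l, phi = t(tm) %*% tm)
}

# reflect each factor so its largest-|loading| trait loads positively
reflect_factors <- function(lam, phi) {
  sgn <- vapply(seq_len(ncol(lam)), function(j) {
    i <- which.max(abs(lam[, j]))
    if (lam[i, j] < 0) -1 else 1
  }, numeric(1))
  lam <- sweep(lam, 2, sgn, "*")
  k <- ncol(lam)
  phi <- diag(sgn, k) %*% phi %*% diag(sgn, k)
  list(loadings = lam, phi = phi)
}

#' Horn's parallel analysis for factor retention
#'
#' Compares observed eigenvalues against the 95th percentile (or mean)
#' eigenvalues of `n_sims` simulated uncorrelated standard-normal datasets of
#' identical dimension. Retains eigenvalues, counting from the first, while
#' the observed value exceeds its simulated reference. The default reference
#' is the 95th percentile: with the classical simulated-mean rule a
#' pure-noise panel exceeds the reference for one or more eigenvalues in
#' roughly a third of replicates (the observed eigenvalues are a draw from
#' the very distribution being averaged), while the percentile reference
#' keeps that false-retention rate at the nominal few percent. The
#' simulated-mean rule remains available via `quantile = "mean"`.
#'
#' @param panel a `trait_panel` or numeric matrix.
#' @param n_sims number of simulated datasets (>= 100; default 1000).
#' @param seed RNG seed.
#' @param quantile `"q95"` (default) or `"mean"` (the classical rule).
#' @return integer retained factor count, with attribute `evidence` (a
#'   data.frame of observed vs simulated eigenvalues).
#' @export
parallel_analysis <- function(panel, n_sims = 1000, seed = 1L,
                              quantile = c("q95", "mean")) {
  quantile <- match.arg(quantile)
  if (n_sims < 100) config_error("n_sims must be >= 100")
  x <- if (inherits(panel, "trait_panel")) panel$values else as.matrix(panel)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); p <- ncol(x)
  obs <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  sims <- with_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      z <- matrix(stats::rnorm(n * p), n, p)
      eigen(stats::cor(z), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p))
  })
  ref <- if (quantile == "mean") rowMeans(sims)
         else apply(sims, 1, stats::quantile, probs = 0.95, type = 7)
  keep <- obs > ref
  n_keep <- if (!keep[1]) 0L else which(c(!keep, TRUE))[1] - 1L
  structure(as.integer(n_keep),
            evidence = data.frame(component = seq_len(p), observed = obs,
                                  simulated = ref))
}

#' Assign each trait to its highest-loading factor
#'
#' Each trait is assigned to the factor carrying its largest absolute
#' loading, provided that loading reaches `cutoff`; traits below cutoff on
#' every factor stay unassigned (they will be recommended for univariate
#' modeling downstream). Ties break by factor index and are reported via a
#' message.
#'
#' @param model a `factor_model`.
#' @param cutoff salience threshold on |loading| (default 0.3).
#' @return the model with `assignment` filled (`NA` = unassigned).
#' @export
assign_highest_loading <- function(model, cutoff = 0.3) {
  stopifnot(inherits(model, "factor_model"))
  lam <- abs(model$loadings)
  assign <- rep(NA_character_, nrow(lam))
  for (i in seq_len(nrow(lam))) {
    best <- max(lam[i, ])
    if (best >= cutoff) {
      js <- which(lam[i, ] == best)
      if (length(js) > 1)
        message(sprintf("tie for trait '%s'; assigned to %s by factor order",
                        rownames(lam)[i], colnames(lam)[js[1]]))
      assign[i] <- colnames(lam)[js[1]]
    }
  }
  names(assign) <- rownames(lam)
  model$assignment <- assign
  model$cutoff <- cutoff
  model
}

#' Export loadings as a long-format table
#'
#' @param model a `factor_model`.
#' @return data.frame with columns `trait`, `factor`, `loading`, `assigned`.
#' @export
export_loading_table <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  lam <- model$loadings
  out <- data.frame(trait = rep(rownames(lam), times = ncol(lam)),
                    factor = rep(colnames(lam), each = nrow(lam)),
                    loading = as.vector(lam), stringsAsFactors = FALSE)
  out$assigned <- !is.na(model$assignment[out$trait]) &
    model$assignment[out$trait] == out$factor
  out
}
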