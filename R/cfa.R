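#' Confirmatory factor analysis specification
#'
#' Fixes the measurement structure (factor -> indicator lists, no
#' cross-loadings), the priors and the MCMC settings for [fit_cfa()].
#' Identification is by unit factor variances with free loadings,
#' sign-anchored on each factor's first indicator, so the solution is
#' directly comparable to standardized loading tables.
#'
#' @param measurement named list: factor name -> character vector of
#'   indicator names. Each indicator may appear under exactly one factor;
#'   factors need >= 2 indicators (2 triggers a warning, 3+ recommended).
#' @param iterations total MCMC iterations per chain (default 10000).
#' @param burnin discarded iterations (default 5000).
#' @param chains number of chains (>= 2 for convergence checks).
#' @param seed RNG seed; chain c uses `seed + c`.
#' @param prior list: `loading_mean`, `loading_var` (normal prior on
#'   loadings), `resid_shape`, `resid_rate` (gamma prior on residual
#'   precisions), `phi_df` (inverse-Wishart working prior df used in the
#'   parameter-expanded factor-correlation update; default k + 2).
#' @return an object of class `cfa_spec`.
#' @export
cfa_spec <- function(measurement, iterations = 10000, burnin = 5000,
                     chains = 2, seed = 1L, prior = list()) {
  inds <- unlist(measurement, use.names = FALSE)
  if (anyDuplicated(inds))
    config_error("each indicator may appear under exactly one factor")
  sizes <- lengths(measurement)
  if (any(sizes < 2))
    config_error("every factor needs at least 2 indicators")
  if (any(sizes == 2))
    warning("factor(s) with only 2 indicators: identification is weak")
  if (burnin >= iterations) config_error("burnin must be < iterations")
  defaults <- list(loading_mean = 0, loading_var = 10,
                   resid_shape = 1, resid_rate = 0.5,
                   phi_df = length(measurement) + 2)
  prior <- utils::modifyList(defaults, prior)
  structure(list(measurement = measurement, iterations = iterations,
                 burnin = burnin, chains = chains, seed = seed, prior = prior),
            class = "cfa_spec")
}

#' Fit a Bayesian CFA by Gibbs sampling
#'
#' Linear measurement model for z-scored indicators:
#' `y_i = Lambda eta_i + eps_i`, `eta_i ~ N(0, Phi)` with unit factor
#' variances, `eps_i` diagonal normal. Conjugate updates for loadings
#' (normal), residual precisions (gamma) and factor values (multivariate
#' normal); the factor correlation matrix is updated by a parameter-expanded
#' inverse-Wishart step rescaled to a correlation matrix (loadings and factor
#' draws are rescaled compensatingly, leaving the likelihood invariant).
#' Each factor is reflected every sweep so its first indicator loads
#' positively.
#'
#' @param panel a `trait_panel` or numeric matrix holding the indicators.
#' @param spec a [cfa_spec()].
#' @return an object of class `cfa_posterior`: draw matrices for standardized
#'   loadings, raw loadings, residual variances and factor correlations (per
#'   chain), posterior summaries (`summary` data.frame with posterior mean,
#'   PSD, R2 and PSRF per indicator), per-animal posterior-mean factor scores,
#'   and a `converged` flag (all PSRF <= 1.1).
#' @export
fit_cfa <- function(panel, spec) {
  stopifnot(inherits(spec, "cfa_spec"))
  x <- if (inherits(panel, "trait_panel")) panel$values else as.matrix(panel)
  inds <- unlist(spec$measurement, use.names = FALSE)
  missing_ind <- setdiff(inds, colnames(x))
  if (length(missing_ind))
    config_error(paste("indicators absent from panel:",
                       paste(missing_ind, collapse = ", ")))
  x <- x[stats::complete.cases(x[, inds, drop = FALSE]), inds, drop = FALSE]
  n <- nrow(x)
  if (n < length(inds) + 1) data_error("too few complete cases for CFA")
  sc <- scale(x)
  if (any(!is.finite(sc))) data_error("constant indicator column")
  ev <- eigen(stats::cov(sc), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) data_error("sample covariance of indicators is not positive definite")
  y <- sc
  p <- ncol(y); k <- length(spec$measurement)
  fmap <- rep(seq_len(k), lengths(spec$measurement))  # factor index per indicator
  anchors <- match(vapply(spec$measurement, `[`, "", 1), inds)
  keep <- spec$iterations - spec$burnin
  chains <- lapply(seq_len(spec$chains), function(ch) {
    with_seed(spec$seed + ch, {
      gibbs_cfa_chain(y, fmap, anchors, k, spec$iterations, spec$burnin,
                      spec$prior)
    })
  })
  lam_star <- lapply(chains, `[[`, "lam_star")
  param_names <- c(paste0("lambda_std.", inds),
                   paste0("resid_var.", inds),
                   if (k > 1) paste0("phi.", phi_pair_names(names(spec$measurement))))
  draw_mats <- lapply(chains, function(ch)
    cbind(ch$lam_star, ch$psi, if (k > 1) ch$phi))
  psrf_all <- psrf(lapply(draw_mats, function(m) {
    colnames(m) <- param_names; m
  }))
  lam_mean <- colMeans(do.call(rbind, lam_star))
  lam_psd <- apply(do.call(rbind, lam_star), 2, stats::sd)
  scores <- Reduce(`+`, lapply(chains, `[[`, "eta_mean")) / length(chains)
  rownames(scores) <- rownames(y)
  colnames(scores) <- names(spec$measurement)
  phi_mean <- if (k > 1) {
    pm <- colMeans(do.call(rbind, lapply(chains, `[[`, "phi")))
    m <- diag(k); m[upper.tri(m)] <- pm; m[lower.tri(m)] <- t(m)[lower.tri(m)]
    dimnames(m) <- list(names(spec$measurement), names(spec$measurement))
    m
  } else matrix(1, 1, 1, dimnames = list(names(spec$measurement), names(spec$measurement)))
  summ <- data.frame(factor = names(spec$measurement)[fmap],
                     indicator = inds,
                     loading = lam_mean,
                     psd = lam_psd,
                     r2 = lam_mean^2,
                     psrf = psrf_all[seq_len(p)],
                     stringsAsFactors = FALSE, row.names = NULL)
  converged <- all(psrf_all <= 1.1)
  if (!converged)
    warning("PSRF > 1.1 for at least one parameter; result flagged non-converged")
  structure(list(summary = summ, psrf = psrf_all, scores = scores,
                 factor_corr = phi_mean,
                 draws = list(lam_star = lam_star,
                              psi = lapply(chains, `[[`, "psi"),
                              phi = if (k > 1) lapply(chains, `[[`, "phi")),
                 spec = spec, n_obs = n,
                 retained = as.integer(keep * spec$chains),
                 converged = converged),
            class = "cfa_posterior")
}

phi_pair_names <- function(fnames) {
  idx <- which(upper.tri(diag(length(fnames))), arr.ind = TRUE)
  paste(fnames[idx[, 1]], fnames[idx[, 2]], sep = ":")
}

# one Gibbs chain; returns retained draws of standardized loadings, residual
# variances, factor correlations, plus the running mean of factor scores
gibbs_cfa_chain <- function(y, fmap, anchors, k, iterations, burnin, prior) {
  n <- nrow(y); p <- ncol(y)
  keep <- iterations - burnin
  lam <- stats::rnorm(p, 0.5, 0.5)          # dispersed start
  psi <- stats::runif(p, 0.5, 1.5)
  phi <- diag(k)
  eta <- matrix(0, n, k)
  out_lam <- matrix(NA_real_, keep, p)
  out_psi <- matrix(NA_real_, keep, p)
  out_phi <- if (k > 1) matrix(NA_real_, keep, k * (k - 1) / 2) else NULL
  eta_sum <- matrix(0, n, k)
  Lmat <- matrix(0, p, k)
  jidx <- cbind(seq_len(p), fmap)
  for (it in seq_len(iterations)) {
    ## eta | rest
    Lmat[jidx] <- lam
    lw <- Lmat / psi                         # p x k, Psi^-1 Lambda
    prec <- chol2inv(chol(phi)) + crossprod(Lmat, lw)
    a <- chol2inv(chol(prec))                # k x k posterior covariance
    mu <- y %*% lw %*% a
    eta <- mu + matrix(stats::rnorm(n * k), n, k) %*% chol(a)
    ## lambda | rest (independent across indicators)
    eta_f <- eta[, fmap, drop = FALSE]       # n x p, each indicator's factor
    ss_eta <- colSums(eta_f^2)
    v_post <- 1 / (1 / prior$loading_var + ss_eta / psi)
    m_post <- v_post * (prior$loading_mean / prior$loading_var +
                          colSums(eta_f * y) / psi)
    lam <- stats::rnorm(p, m_post, sqrt(v_post))
    ## psi | rest
    resid <- y - eta_f * rep(lam, each = n)
    ssr <- colSums(resid^2)
    prec_draw <- stats::rgamma(p, prior$resid_shape + n / 2,
                               prior$resid_rate + ssr / 2)
    psi <- 1 / prec_draw
    ## phi via parameter expansion (k > 1)
    if (k > 1) {
      s <- diag(1, k) + crossprod(eta)
      w <- chol2inv(chol(stats::rWishart(1, prior$phi_df + n,
                                         chol2inv(chol(s)))[, , 1]))
      d <- sqrt(diag(w))
      phi <- w / tcrossprod(d)
      eta <- eta %*% diag(1 / d, k)
      lam <- lam * d[fmap]
    }
    ## sign anchoring
    for (f in seq_len(k)) {
      if (lam[anchors[f]] < 0) {
        sel <- fmap == f
        lam[sel] <- -lam[sel]
        eta[, f] <- -eta[, f]
        if (k > 1) {
          phi[f, ] <- -phi[f, ]; phi[, f] <- -phi[, f]; phi[f, f] <- 1
        }
      }
    }
    if (it > burnin) {
      r <- it - burnin
      out_lam[r, ] <- lam
      out_psi[r, ] <- psi
      if (k > 1) out_phi[r, ] <- phi[upper.tri(phi)]
      eta_sum <- eta_sum + eta
    }
  }
  lam_star <- out_lam / sqrt(out_lam^2 + out_psi)   # implied standardization
  list(lam_star = lam_star, lam = out_lam, psi = out_psi, phi = out_phi,
       eta_mean = eta_sum / keep)
}

#' Standardized loadings and per-indicator R-squared
#'
#' Under the congeneric (single-loading) model the variance a factor explains
#' in a standardized indicator is the squared standardized loading, so
#' `R2 = loading^2` exactly. Reported values are the posterior-mean
#' standardized loading and its square, preserving the identity in the
#' output table.
#'
#' @param post a `cfa_posterior`, or a numeric vector of standardized
#'   loadings (e.g. a printed table column) for the bare identity.
#' @return data.frame `indicator`, `loading`, `r2` (for a vector input, the
#'   names are taken from the vector).
#' @export
standardize_and_r2 <- function(post) {
  if (inherits(post, "cfa_posterior")) {
    return(data.frame(indicator = post$summary$indicator,
                      loading = post$summary$loading,
                      r2 = post$summary$loading^2,
                      stringsAsFactors = FALSE))
  }
  lam <- as.numeric(post)
  data.frame(indicator = names(post) %||% paste0("v", seq_along(lam)),
             loading = lam, r2 = lam^2, stringsAsFactors = FALSE)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' `PSRF = sqrt(1 + B/(n*W))` from the between-chain (`B`) and within-chain
#' (`W`) variances of equal-length retained draws; equals 1 exactly when the
#' chains are identical and is >= 1 by construction.
#'
#' @param chains list (length >= 2) of draw matrices with common columns
#'   (parameters) and equal row counts, or list of numeric vectors for a
#'   single parameter.
#' @return named numeric vector of PSRF values per parameter.
#' @export
psrf <- function(chains) {
  if (!is.list(chains) || length(chains) < 2)
    config_error("psrf needs >= 2 chains; rerun with chains >= 2")
  if (is.null(dim(chains[[1]])))
    chains <- lapply(chains, function(v) matrix(v, ncol = 1))
  lens <- vapply(chains, nrow, integer(1))
  if (length(unique(lens)) != 1) config_error("chains must have equal retained lengths")
  n <- lens[1]
  means <- do.call(rbind, lapply(chains, colMeans))
  vars <- do.call(rbind, lapply(chains, function(m) apply(m, 2, stats::var)))
  w <- colMeans(vars)
  b <- n * apply(means, 2, stats::var)
  out <- sqrt(1 + b / (n * pmax(w, .Machine$double.eps)))
  names(out) <- colnames(chains[[1]]) %||% paste0("param", seq_along(out))
  out
}

#' Posterior-mean factor scores (the latent-trait phenotypes)
#'
#' @param post a `cfa_posterior`.
#' @return numeric matrix, one row per retained animal, one column per
#'   latent factor.
#' @export
factor_scores <- function(post) {
  stopifnot(inherits(post, "cfa_posterior"))
  post$scores
}

#' Flag indicators a factor fails to explain
#'
#' An indicator is reported unexplained when the lower bound of the 95%
#' credible interval of its standardized loading falls below the salience
#' threshold — the situation where a trait should be modeled univariately
#' rather than through the latent factor.
#'
#' @param post a `cfa_posterior`.
#' @param threshold salience threshold (default 0.3).
#' @return data.frame `factor`, `indicator`, `loading`, `lo95`, `hi95`,
#'   `unexplained`.
#' @export
drop_unexplained <- function(post, threshold = 0.3) {
  stopifnot(inherits(post, "cfa_posterior"))
  all_draws <- do.call(rbind, post$draws$lam_star)
  lo <- apply(all_draws, 2, stats::quantile, probs = 0.025, type = 7)
  hi <- apply(all_draws, 2, stats::quantile, probs = 0.975, type = 7)
  data.frame(factor = post$summary$factor,
             indicator = post$summary$indicator,
             loading = post$summary$loading,
             lo95 = lo, hi95 = hi,
             unexplained = lo < threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}
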