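# shared fixtures, built once per test run and cached in this environment
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# small genotype + trait fixture used across genomics/pipeline tests
small_sim <- function() {
  cached("small_sim", function() {
    cfg <- sim_config(n_animals = 120, n_snps = 400, seed = 42,
                      missing_rate = 0, outlier_rate = 0)
    geno <- simulate_genotypes(cfg)
    sim <- simulate_latent_and_traits(cfg, geno)
    list(cfg = cfg, geno = geno, panel = sim$panel, truth = sim$truth)
  })
}

# clean one-factor panel with known loadings, for EFA/KMO oracles
one_factor_panel <- function(n = 2000, lambda = c(0.9, 0.8, 0.7, 0.6, 0.8),
                             seed = 99) {
  withr_seed(seed, {
    eta <- stats::rnorm(n)
    y <- vapply(lambda, function(l)
      l * eta + stats::rnorm(n, 0, sqrt(1 - l^2)), numeric(n))
    colnames(y) <- paste0("v", seq_along(lambda))
    y
  })
}

# local seed sandbox (tests must not disturb the global stream)
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# independent KMO oracle: explicit inversion + elementwise sums
kmo_oracle <- function(x) {
  r <- stats::cor(x)
  s <- solve(r)
  p <- ncol(r)
  q <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    q[i, j] <- -s[i, j] / sqrt(s[i, i] * s[j, j])
  num <- 0; den_q <- 0
  msa_num <- numeric(p); msa_q <- numeric(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    num <- num + r[i, j]^2
    den_q <- den_q + q[i, j]^2
    msa_num[i] <- msa_num[i] + r[i, j]^2
    msa_q[i] <- msa_q[i] + q[i, j]^2
  }
  list(kmo = num / (num + den_q), msa = msa_num / (msa_num + msa_q))
}

# brute-force HWE exact p by direct enumeration of genotype tables with the
# same allele counts, using plain factorial arithmetic
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nA <- 2 * n_aa + n_ab
  configs <- list()
  for (h in 0:min(nA, 2 * n - nA)) {
    if ((nA - h) %% 2 != 0) next
    aa <- (nA - h) / 2
    bb <- n - aa - h
    if (aa < 0 || bb < 0) next
    configs[[length(configs) + 1]] <- c(aa, h, bb)
  }
  logw <- vapply(configs, function(cf)
    lgamma(n + 1) - lgamma(cf[1] + 1) - lgamma(cf[2] + 1) - lgamma(cf[3] + 1) +
      cf[2] * log(2), numeric(1))
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  hs <- vapply(configs, `[`, numeric(1), 2)
  p_obs <- w[match(n_ab, hs)]
  sum(w[w <= p_obs * (1 + 1e-9)])
}

# exhaustive DAG enumeration for <= 3 nodes: all 25 DAGs on 3 labelled nodes
enumerate_dags <- function(nodes) {
  p <- length(nodes)
  out <- list()
  # assign each unordered pair one of: none, i->j, j->i; drop cyclic results
  pairs <- utils::combn(p, 2)
  n_pairs <- ncol(pairs)
  for (code in 0:(3^n_pairs - 1)) {
    a <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
    c0 <- code
    for (q in seq_len(n_pairs)) {
      v <- c0 %% 3; c0 <- c0 %/% 3
      i <- pairs[1, q]; j <- pairs[2, q]
      if (v == 1) a[i, j] <- TRUE
      if (v == 2) a[j, i] <- TRUE
    }
    d <- tryCatch(dag(nodes, dag_edges(structure(list(nodes = nodes, amat = a),
                                                 class = "ubt_dag"))),
                  error = function(e) NULL)
    if (!is.null(d)) out[[length(out) + 1]] <- d
  }
  out
}

# X -> Y -> Z linear-Gaussian chain
chain_data <- function(n = 2000, seed = 12) {
  cached(paste0("chain_", n, "_", seed), function() {
    withr_seed(seed, {
      x <- rnorm(n)
      y <- 0.8 * x + rnorm(n, 0, 0.6)
      z <- 0.8 * y + rnorm(n, 0, 0.6)
      cbind(X = x, Y = y, Z = z)
    })
  })
}

skeleton_of <- function(g) {
  e <- dag_edges(g)
  if (!nrow(e)) return(character(0))
  sort(paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "--"))
}
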