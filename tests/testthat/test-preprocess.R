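make_panel <- function(values, kind = "direct", priority = NULL) {
  p <- ncol(values)
  meta <- data.frame(name = colnames(values) %||% paste0("t", seq_len(p)),
                     block = "body",
                     kind = rep(kind, length.out = p),
                     priority = priority %||% rep(1L, p))
  colnames(values) <- meta$name
  ubtnet::trait_panel(values, meta)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("tukey_flags handles degenerate and planted cases", {
  # collapsed fences: only the displaced value is outside [0, 0]
  expect_identical(tukey_flags(c(0, 0, 0, 0, 100)),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(tukey_flags(rep(7, 10))))
  expect_warning(fl <- tukey_flags(c(1, 2, NA)), "fewer than 4")
  expect_false(any(fl))
  # missing entries never flagged, fences computed without them
  x <- c(rnorm(50), NA, 1000)
  fl <- tukey_flags(x)
  expect_false(fl[51])
  expect_true(fl[52])
  # planted outlier in normal draws: flagged, and the total rate is near the
  # normal-theory Tukey rate, checked against a brute-force fence computation
  set.seed(8)
  x <- c(rnorm(200), 10)
  fl <- tukey_flags(x)
  expect_true(fl[201])
  q <- quantile(x, c(.25, .75), type = 7)
  manual <- x < q[1] - 1.5 * diff(q) | x > q[2] + 1.5 * diff(q)
  expect_identical(fl, unname(manual))
  rates <- replicate(200, mean(tukey_flags(rnorm(200))))
  expect_lt(abs(mean(rates) - 0.007), 0.01)
})

test_that("filter_panel applies outlier-to-missing then complete-case", {
  set.seed(11)
  # evenly spaced values sit well inside the Tukey fences: nothing is flagged
  v <- replicate(10, sample(seq(0, 1, length.out = 10)))
  clean <- make_panel(v)
  out <- filter_panel(clean)
  expect_equal(out$panel$values, clean$values)
  # one missing cell drops exactly that animal
  v2 <- v; v2[3, 5] <- NA
  out2 <- filter_panel(make_panel(v2))
  expect_equal(nrow(out2$panel$values), 9)
  expect_false("animal_3" %in% rownames(out2$panel$values))
  # report stage counts are chained consistently
  st <- out2$report$stages
  expect_identical(st$animals_out[1], st$animals_in[2])
  expect_identical(st$traits_out[1], st$traits_in[2])
})

test_that("injected corruption is fully removed by filtering", {
  cfg <- sim_config(n_animals = 400, n_snps = 10, seed = 61,
                    missing_rate = 0.03, outlier_rate = 0.05)
  g <- simulate_genotypes(cfg)
  sim <- simulate_latent_and_traits(cfg, g)
  dirty <- inject_missing_and_outliers(sim$panel, cfg)
  inj <- attr(dirty, "injection")
  out <- filter_panel(dirty)
  # independent recount: iterate flag-then-drop by brute force to the same
  # fixed point the filter promises
  v <- dirty$values
  repeat {
    n_fl <- 0
    for (j in seq_len(ncol(v))) {
      fl <- tukey_flags(v[, j])
      n_fl <- n_fl + sum(fl)
      v[fl, j] <- NA
    }
    cc <- complete.cases(v)
    v <- v[cc, , drop = FALSE]
    if (n_fl == 0 && all(cc)) break
  }
  expect_equal(nrow(out$panel$values), nrow(v))
  # no injected outlier cell survives into the filtered panel
  kept <- rownames(out$panel$values)
  for (k in seq_len(nrow(inj$outlier))) {
    an <- rownames(dirty$values)[inj$outlier[k, 1]]
    expect_false(an %in% kept)
  }
})

test_that("correlation pruning drops the lower-priority member until clean", {
  set.seed(4)
  n <- 200
  base <- matrix(rnorm(n * 4), n, 4)
  dup <- base[, 1]
  v <- cbind(base, dup)
  colnames(v) <- c("a", "b", "c", "d", "a_copy")
  out <- correlation_prune(make_panel(v))
  expect_false("a_copy" %in% out$panel$meta$name)  # later column loses the tie
  expect_true("a" %in% out$panel$meta$name)
  expect_equal(nrow(out$report$dropped_pairs), 1)
  expect_gte(out$report$dropped_pairs$r2, 0.85)
  # calculated trait loses to its direct source regardless of order
  v2 <- cbind(calc = base[, 1] + rnorm(n, 0, 0.1), direct = base[, 1])
  p2 <- make_panel(v2, kind = c("calculated", "direct"))
  out2 <- correlation_prune(p2)
  expect_identical(out2$panel$meta$name, "direct")
  # threshold validation
  expect_error(correlation_prune(make_panel(v), r2_threshold = 0),
               class = "ubtnet_config_error")
})

test_that("iterative pruning matches an exhaustive greedy oracle", {
  set.seed(9)
  n <- 300
  x <- matrix(rnorm(n * 6), n, 6)
  x[, 2] <- 0.97 * x[, 1] + sqrt(1 - 0.97^2) * x[, 2]  # planted r ~ 0.97
  colnames(x) <- paste0("v", 1:6)
  pan <- make_panel(x)
  out <- correlation_prune(pan, r2_threshold = 0.85)
  # oracle: greedy scan dropping the later column of the worst pair
  keep <- seq_len(6)
  repeat {
    r2 <- cor(x[, keep])^2; diag(r2) <- 0
    if (max(r2) < 0.85) break
    ij <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
    keep <- keep[-max(ij)]
  }
  expect_identical(out$panel$meta$name, paste0("v", keep))
  # never drops both members of a flagged pair
  expect_true(all(out$report$dropped_pairs$kept %in% out$panel$meta$name))
})

test_that("kmo matches the anti-image oracle and its closed forms", {
  y <- one_factor_panel(n = 2000)
  k <- kmo(y)
  oracle <- kmo_oracle(y)
  expect_equal(k$kmo, oracle$kmo, tolerance = 1e-10)
  expect_equal(unname(k$msa), oracle$msa, tolerance = 1e-10)
  expect_true(all(k$msa >= 0 & k$msa <= 1))
  expect_true(k$kmo >= 0 && k$kmo <= 1)
  # any 2-variable panel: KMO = 0.5 exactly
  k2 <- kmo(y[, 1:2])
  expect_equal(k2$kmo, 0.5, tolerance = 1e-12)
  # exact identity correlation: undefined, sentinel + warning
  expect_warning(k0 <- kmo(diag(4), is_cor = TRUE), "undefined")
  expect_true(is.na(k0$kmo))
})

test_that("msa screening removes noise variables first and is idempotent", {
  set.seed(14)
  y <- one_factor_panel(n = 600, lambda = c(.85, .8, .75, .8, .7))
  noise <- matrix(rnorm(600 * 2), 600, 2)
  v <- cbind(y, noise)
  colnames(v) <- c(paste0("f", 1:5), "junk1", "junk2")
  pan <- make_panel(v)
  out <- msa_screen(pan, threshold = 0.5)
  expect_true(all(out$report$dropped_traits$trait %in% c("junk1", "junk2")))
  expect_true(all(out$report$msa >= 0.5))
  # dropped order is deterministic and recomputed each round (oracle check)
  msa1 <- kmo(v)$msa
  first_dropped <- out$report$dropped_traits$trait[1]
  expect_identical(first_dropped, names(which.min(msa1)))
  # clean panel is untouched, and the full cascade is idempotent
  clean <- msa_screen(out$panel)$panel
  expect_identical(clean$values, out$panel$values)
  f1 <- filter_panel(out$panel)
  c1 <- correlation_prune(f1$panel)
  m1 <- msa_screen(c1$panel)
  f2 <- filter_panel(m1$panel)
  c2 <- correlation_prune(f2$panel)
  m2 <- msa_screen(c2$panel)
  expect_identical(m1$panel$values, m2$panel$values)
})

test_that("every dropped trait carries exactly one recorded reason", {
  cfg <- sim_config(seed = 3)
  g <- simulate_genotypes(cfg)
  sim <- simulate_latent_and_traits(cfg, g)
  dirty <- inject_missing_and_outliers(sim$panel, cfg)
  f <- filter_panel(dirty)
  cpr <- correlation_prune(f$panel, report = f$report)
  ms <- msa_screen(cpr$panel, report = cpr$report)
  dropped <- ms$report$dropped_traits
  expect_false(anyDuplicated(dropped$trait) > 0)
  expect_true(all(dropped$reason %in% c("excluded", "correlation", "msa")))
  survivors <- ms$panel$meta$name
  expect_length(intersect(survivors, dropped$trait), 0)
})
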