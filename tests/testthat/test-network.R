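# closed-form BIC of a DAG computed independently (naive regressions)
bic_oracle <- function(x, g) {
  n <- nrow(x)
  total <- 0
  for (j in seq_along(g$nodes)) {
    pa <- g$nodes[g$amat[, j]]
    f <- if (length(pa))
      lm(x[, g$nodes[j]] ~ x[, pa, drop = FALSE])
    else lm(x[, g$nodes[j]] ~ 1)
    s2 <- sum(resid(f)^2) / n
    ll <- -n / 2 * (log(2 * pi * s2) + 1)
    total <- total + ll - log(n) / 2 * (length(pa) + 2)
  }
  total
}

test_that("gaussian BIC matches a hand-computed oracle", {
  withr_seed(3, {
    x <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("A", "B", "C")))
  })
  g_empty <- dag(c("A", "B", "C"))
  expect_equal(as.numeric(bic_g_score(x, g_empty)), bic_oracle(x, g_empty),
               tolerance = 1e-10)
  g_edge <- dag(c("A", "B", "C"), data.frame(from = "A", to = "B"))
  expect_equal(as.numeric(bic_g_score(x, g_edge)), bic_oracle(x, g_edge),
               tolerance = 1e-10)
  # adding an uncorrelated parent lowers the score (penalty dominates)
  expect_lt(as.numeric(bic_g_score(x, g_edge)),
            as.numeric(bic_g_score(x, g_empty)))
  # node order in the data is irrelevant
  expect_equal(as.numeric(bic_g_score(x[, c(3, 1, 2)], g_edge)),
               as.numeric(bic_g_score(x, g_edge)), tolerance = 1e-12)
  # singular parent sets score -Inf
  xx <- cbind(x, D = x[, "A"])
  g_sing <- dag(colnames(xx), data.frame(from = c("A", "D"), to = c("B", "B")))
  expect_identical(as.numeric(bic_g_score(xx, g_sing)), -Inf)
})

test_that("dag constructor enforces acyclicity", {
  expect_error(dag(c("a", "b"), data.frame(from = c("a", "b"), to = c("b", "a"))),
               class = "ubtnet_config_error")
  g <- dag(c("a", "b", "c"), data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_true(dag_is_acyclic(g))
  expect_identical(dag_edges(g)$from, c("a", "b"))
})

test_that("tabu search attains the exhaustive optimum on 3-node problems", {
  data_sets <- list(
    chain_data(n = 400, seed = 1)[1:400, ],
    withr_seed(2, matrix(rnorm(1200), 400, 3,
                         dimnames = list(NULL, c("X", "Y", "Z")))),
    withr_seed(3, {
      a <- rnorm(400); b <- 0.7 * a + rnorm(400, 0, .7)
      c <- 0.5 * a - 0.5 * b + rnorm(400, 0, .7)
      cbind(X = a, Y = b, Z = c)
    }))
  all_dags <- enumerate_dags(c("X", "Y", "Z"))
  expect_length(all_dags, 25)
  for (x in data_sets) {
    best_enum <- max(vapply(all_dags, function(g)
      as.numeric(bic_g_score(x, g)), numeric(1)))
    got <- tabu_search(x)
    expect_equal(attr(got, "score"), best_enum, tolerance = 1e-9)
  }
})

test_that("tabu recovers the chain equivalence class and empty truths", {
  x <- chain_data()
  g <- tabu_search(x)
  expect_setequal(skeleton_of(g), c("X--Y", "Y--Z"))
  noise <- withr_seed(8, matrix(rnorm(3000), 1000, 3,
                                dimnames = list(NULL, c("A", "B", "C"))))
  expect_identical(nrow(dag_edges(tabu_search(noise))), 0L)
  # 2-node case: agrees with direct enumeration of the 3 candidate structures
  for (seed in 1:3) {
    xy <- withr_seed(seed, {
      a <- rnorm(300); cbind(A = a, B = 0.4 * a + rnorm(300, 0, 0.9))
    })
    cands <- list(dag(c("A", "B")),
                  dag(c("A", "B"), data.frame(from = "A", to = "B")),
                  dag(c("A", "B"), data.frame(from = "B", to = "A")))
    best <- max(vapply(cands, function(g) as.numeric(bic_g_score(xy, g)),
                       numeric(1)))
    expect_equal(attr(tabu_search(xy), "score"), best, tolerance = 1e-9)
  }
})

test_that("mmhc learns the chain skeleton and respects independences", {
  x <- chain_data()
  g <- mmhc(x, alpha = 0.05)
  expect_setequal(skeleton_of(g), c("X--Y", "Y--Z"))
  skel <- attr(g, "skeleton")
  expect_false(skel["X", "Z"])               # X _||_ Z | Y accepted
  noise <- withr_seed(19, matrix(rnorm(3000), 1000, 3,
                                 dimnames = list(NULL, c("A", "B", "C"))))
  g0 <- mmhc(noise)
  expect_identical(nrow(dag_edges(g0)), 0L)
  expect_true(all(!attr(g0, "skeleton")))
})

test_that("mmhc and tabu agree up to the equivalence class on the fixture", {
  fx <- small_sim()
  grm <- build_grm(fx$geno)
  fit <- suppressWarnings(
    fit_gblup(fx$truth$eta, fx$truth$covariates, grm, mode = "univariate"))
  adj <- decorrelate_gebv(fit, grm)$adjusted
  expect_identical(skeleton_of(tabu_search(adj)), skeleton_of(mmhc(adj)))
})

test_that("bootstrap averaging tallies strengths and is reproducible", {
  x <- chain_data(n = 500, seed = 44)
  learner <- function(d) tabu_search(d)
  net <- bootstrap_average(x, learner, n_boot = 120, seed = 5)
  e <- net$edges
  key <- paste(e$from, e$to)
  expect_equal(e$strength[key == "X Y"], 1, tolerance = 1e-12)
  expect_equal(e$strength[key == "Y Z"], 1, tolerance = 1e-12)
  expect_lt(e$strength[key == "X Z"], 0.5)
  # direction probabilities complement each other
  nz <- !is.na(e$dir_fwd)
  expect_equal(e$dir_fwd[nz] + e$dir_rev[nz], rep(1, sum(nz)), tolerance = 1e-12)
  expect_true(all(e$strength >= 0 & e$strength <= 1))
  net2 <- bootstrap_average(x, learner, n_boot = 120, seed = 5)
  expect_identical(net$edges, net2$edges)
  expect_error(bootstrap_average(x, learner, n_boot = 50),
               class = "ubtnet_config_error")
})

test_that("consensus orientation handles exact 0.5 ties lexicographically", {
  nodes <- c("P", "Q")
  counts_net <- structure(list(
    edges = data.frame(from = "P", to = "Q", strength = 1,
                       dir_fwd = 0.5, dir_rev = 0.5),
    n_boot = 100), class = "averaged_network")
  # exercise via the internal path: rebuild consensus from the edge table
  cons <- ubtnet:::consensus_dag(nodes,
                                 data.frame(from = "P", to = "Q", strength = 1,
                                            direction = 0.5), character(0))
  expect_identical(dag_edges(cons$dag)$from, "P")  # lexicographic origin
})

test_that("network comparison reports gains, losses and antisymmetry", {
  x_ind <- withr_seed(3, matrix(rnorm(1000), 500, 2,
                                dimnames = list(NULL, c("BS", "BC"))))
  x_dep <- withr_seed(4, {
    a <- rnorm(500)
    cbind(BS = a, BC = 0.6 * a + rnorm(500, 0, 0.8))
  })
  learner <- function(d) tabu_search(d)
  net_raw <- bootstrap_average(x_ind, learner, n_boot = 100, seed = 1)
  net_adj <- bootstrap_average(x_dep, learner, n_boot = 100, seed = 1)
  expect_identical(nrow(compare_networks(net_raw, net_raw)), 0L)
  d1 <- compare_networks(net_raw, net_adj)
  expect_identical(d1$status, "gained")
  d2 <- compare_networks(net_adj, net_raw)
  expect_identical(d2$status, "lost")
  bad <- bootstrap_average(cbind(x_ind, Z = rnorm(500)), learner,
                           n_boot = 100, seed = 1)
  expect_error(compare_networks(net_raw, bad), class = "ubtnet_config_error")
})

test_that("all learner outputs are acyclic across random problems", {
  for (i in 1:5) {
    x <- withr_seed(100 + i, {
      p <- 4
      m <- matrix(rnorm(200 * p), 200, p)
      m[, 2] <- m[, 1] * 0.5 + m[, 2]
      m[, 4] <- m[, 3] * 0.4 + m[, 4]
      colnames(m) <- paste0("n", 1:p)
      m
    })
    expect_true(dag_is_acyclic(tabu_search(x)))
    expect_true(dag_is_acyclic(mmhc(x)))
  }
})

test_that("consensus is invariant to row permutation given identical resamples", {
  x <- chain_data(n = 300, seed = 77)
  learner <- function(d) tabu_search(d)
  net1 <- bootstrap_average(x, learner, n_boot = 100, seed = 9)
  perm <- withr_seed(1, sample(nrow(x)))
  # permuted rows, re-seeded identical resample index stream: same tallies up
  # to which rows the indices pick, so compare consensus structures instead
  net2 <- bootstrap_average(x[perm, ], learner, n_boot = 100, seed = 9)
  expect_identical(dag_edges(net1$consensus), dag_edges(net2$consensus))
})

test_that("networks export to edge-list CSV and DOT", {
  x <- chain_data(n = 300, seed = 77)
  net <- bootstrap_average(x, function(d) tabu_search(d), n_boot = 100, seed = 2)
  stem <- file.path(withr::local_tempdir(), "net")
  export_network(net, stem)
  back <- read.csv(paste0(stem, ".csv"))
  expect_equal(back$strength, net$edges$strength, tolerance = 1e-6)
  dot <- readLines(paste0(stem, ".dot"))
  expect_identical(dot[1], "digraph consensus {")
  e <- dag_edges(net$consensus)
  expect_length(grep("->", dot), nrow(e))
})
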