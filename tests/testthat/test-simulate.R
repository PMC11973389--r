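test_that("simulated genotypes respect the configured allele frequencies", {
  cfg <- sim_config(n_animals = 200, n_snps = 2000, seed = 5,
                    maf_range = c(0.05, 0.5))
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosage %in% 0:2))
  p_drawn <- attr(g, "freq")
  p_emp <- colMeans(g$dosage) / 2
  se <- sqrt(p_drawn * (1 - p_drawn) / (2 * 200))
  within3 <- abs(p_emp - p_drawn) <= 3 * se
  expect_gte(mean(within3), 0.99)
  # degenerate range pins every frequency at 0.5
  cfg2 <- sim_config(n_animals = 2000, n_snps = 50, seed = 5,
                     maf_range = c(0.5, 0.5))
  g2 <- simulate_genotypes(cfg2)
  dev <- abs(colMeans(g2$dosage) / 2 - 0.5)
  expect_gte(mean(dev < 3 * sqrt(0.25 / 4000)), 0.95)
  expect_lt(abs(mean(colMeans(g2$dosage)) / 2 - 0.5), 0.01)
})

test_that("genotype and trait generation are deterministic under a seed", {
  cfg <- sim_config(n_animals = 50, n_snps = 100, seed = 77)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  s1 <- simulate_latent_and_traits(cfg, g1)
  s2 <- simulate_latent_and_traits(cfg, g1)
  expect_identical(s1$panel$values, s2$panel$values)
  expect_identical(s1$truth$g, s2$truth$g)
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(maf_range = c(0, 0.5)), class = "ubtnet_config_error")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), class = "ubtnet_config_error")
  expect_error(sim_config(missing_rate = 1), class = "ubtnet_config_error")
  expect_error(sim_config(latent_spec = data.frame(factor = "a", h2 = 1.2)),
               class = "ubtnet_config_error")
  expect_error(
    sim_config(dag_spec = data.frame(from = c("body_size", "ovary_size"),
                                     to = c("ovary_size", "body_size"),
                                     beta = c(.3, .3))),
    class = "ubtnet_config_error")
})

test_that("trait correlations follow the one-factor closed form", {
  # single factor, all loadings 0.8: corr(y_j, y_k) = 0.64 for j != k
  lspec <- data.frame(name = paste0("t", 1:5), block = "body", kind = "direct",
                      priority = 1L, factor = "f1", loading = 0.8,
                      mean = 0, sd = 1)
  cfg <- sim_config(n_animals = 5000, n_snps = 50, seed = 13,
                    latent_spec = data.frame(factor = "f1", h2 = 0.4),
                    dag_spec = data.frame(from = character(0),
                                          to = character(0), beta = numeric(0)),
                    loading_spec = lspec,
                    covariate_spec = list(
                      year = list(levels = "y1", effect = 0)),
                    missing_rate = 0, outlier_rate = 0)
  g <- simulate_genotypes(cfg)
  sim <- simulate_latent_and_traits(cfg, g)
  r <- cor(sim$panel$values)
  off <- r[upper.tri(r)]
  expect_true(all(abs(off - 0.64) < 0.05))
  # zero loadings give an identity correlation matrix
  lspec$loading <- 0
  cfg0 <- sim_config(n_animals = 5000, n_snps = 50, seed = 13,
                     latent_spec = data.frame(factor = "f1", h2 = 0.4),
                     dag_spec = data.frame(from = character(0),
                                           to = character(0), beta = numeric(0)),
                     loading_spec = lspec,
                     covariate_spec = list(year = list(levels = "y1", effect = 0)),
                     missing_rate = 0, outlier_rate = 0)
  sim0 <- simulate_latent_and_traits(cfg0, g)
  r0 <- cor(sim0$panel$values)
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.05)
})

test_that("model-implied correlation matches the generated panel at n = 5000", {
  cfg <- sim_config(n_animals = 5000, n_snps = 100, seed = 21,
                    missing_rate = 0, outlier_rate = 0,
                    covariate_spec = list(year = list(levels = "y1", effect = 0)))
  g <- simulate_genotypes(cfg)
  sim <- simulate_latent_and_traits(cfg, g)
  ls <- cfg$loading_spec
  k <- nrow(cfg$latent_spec)
  lam <- matrix(0, nrow(ls), k,
                dimnames = list(ls$name, cfg$latent_spec$factor))
  for (j in seq_len(nrow(ls)))
    if (!is.na(ls$factor[j])) lam[j, ls$factor[j]] <- ls$loading[j]
  phi <- cor(sim$truth$eta)   # implied factor correlation from the DAG
  implied <- lam %*% phi %*% t(lam)
  diag(implied) <- 1
  observed <- cor(sim$panel$values)
  expect_lt(max(abs(observed - implied)), 0.05)
})

test_that("zero heritability yields identically zero breeding values", {
  cfg <- sim_config(n_animals = 100, n_snps = 50, seed = 3,
                    latent_spec = data.frame(factor = c("body_size",
                                                        "ovary_size",
                                                        "yield_grade"),
                                             h2 = c(0, 0.5, 0.5)),
                    dag_spec = data.frame(from = character(0), to = character(0),
                                          beta = numeric(0)))
  g <- simulate_genotypes(cfg)
  sim <- simulate_latent_and_traits(cfg, g)
  expect_true(all(sim$truth$g[, "body_size"] == 0))
  # heritable factor has BV variance ratio equal to h2 (exact in-sample scaling)
  expect_equal(var(sim$truth$g[, "ovary_size"]) /
                 var(sim$truth$eta[, "ovary_size"]), 0.5, tolerance = 1e-6)
})

test_that("calculated traits reproduce the composite formulas", {
  v <- matrix(c(100, 2 * pi * 20, 2 * pi * 25, 300,
                3, 2, 1, 0,
                30, 20, 28, 22),
              nrow = 1,
              dimnames = list("a1", c("body_length", "end_girth", "mid_girth",
                                      "body_weight", "foll_small", "foll_medium",
                                      "foll_large", "foll_xl",
                                      "left_ovary_length", "left_ovary_height",
                                      "right_ovary_length", "right_ovary_height")))
  meta <- data.frame(name = colnames(v), block = "body", kind = "direct",
                     priority = 1L)
  panel <- trait_panel(v, meta)
  out <- derive_calculated_traits(panel)
  val <- out$values[1, ]
  expect_equal(unname(val["radius_end"]), 20, tolerance = 1e-9)
  expect_equal(unname(val["radius_mid"]), 25, tolerance = 1e-9)
  # worked example: volume = pi*100*(400 + 2*625)/3/1000 L
  expect_equal(unname(val["volume_l"]), pi * 100 * (400 + 2 * 625) / 3 / 1000,
               tolerance = 1e-9)
  expect_equal(unname(val["volume_l"]), 172.7876, tolerance = 1e-4)
  expect_equal(unname(val["body_density"]), 300 / (pi * 100 * 1650 / 3 / 1000),
               tolerance = 1e-9)
  expect_equal(unname(val["antral_follicle_count"]), 6, tolerance = 1e-12)
  expect_equal(unname(val["left_ovary_diameter"]), 25, tolerance = 1e-12)
  expect_equal(unname(val["right_ovary_diameter"]), 25, tolerance = 1e-12)
  expect_true(all(out$meta$kind[out$meta$name %in% names(val)[13:19]] ==
                    "calculated"))
  expect_true(all(out$meta$priority[out$meta$kind == "calculated"] >
                    max(panel$meta$priority)))
})

test_that("non-positive source measures flag the record instead of propagating", {
  v <- matrix(c(100, -5, 150, 300, 90, 140, 160, 310), nrow = 2,
              dimnames = list(c("bad", "good"),
                              c("body_length", "end_girth", "mid_girth",
                                "body_weight")))
  v["bad", ] <- c(100, -5, 150, 300)
  v["good", ] <- c(90, 140, 160, 310)
  meta <- data.frame(name = colnames(v), block = "body", kind = "direct",
                     priority = 1L)
  out <- derive_calculated_traits(trait_panel(v, meta))
  expect_true(is.na(out$values["bad", "volume_l"]))
  expect_true(is.na(out$values["bad", "body_density"]))
  expect_false(is.na(out$values["good", "volume_l"]))
  expect_identical(attr(out, "invalid"), "bad")
})

test_that("missing/outlier injection hits its target rates and is detectable", {
  lspec <- data.frame(name = paste0("t", 1:10), block = "body", kind = "direct",
                      priority = 1L, factor = NA, loading = 0,
                      mean = 50, sd = 5)
  cfg <- sim_config(n_animals = 1000, n_snps = 10, seed = 31,
                    latent_spec = data.frame(factor = "f1", h2 = 0.5),
                    dag_spec = data.frame(from = character(0),
                                          to = character(0), beta = numeric(0)),
                    loading_spec = lspec, missing_rate = 0.1, outlier_rate = 0.02)
  g <- simulate_genotypes(cfg)
  sim <- simulate_latent_and_traits(cfg, g)
  out <- inject_missing_and_outliers(sim$panel, cfg)
  inj <- attr(out, "injection")
  n_cells <- length(out$values)
  se <- sqrt(n_cells * 0.1 * 0.9)
  expect_lt(abs(nrow(inj$missing) - n_cells * 0.1), 3 * se)
  # every injected outlier must be caught by the Tukey rule on its column
  for (k in seq_len(nrow(inj$outlier))) {
    fl <- tukey_flags(out$values[, inj$outlier[k, 2]])
    expect_true(fl[inj$outlier[k, 1]])
  }
  # zero rates leave the panel untouched
  cfg0 <- sim_config(n_animals = 100, n_snps = 10, seed = 31,
                     missing_rate = 0, outlier_rate = 0)
  g0 <- simulate_genotypes(cfg0)
  s0 <- simulate_latent_and_traits(cfg0, g0)
  expect_identical(inject_missing_and_outliers(s0$panel, cfg0)$values,
                   s0$panel$values)
})

test_that("fixtures round-trip through the on-disk formats", {
  fx <- small_sim()
  dir <- withr::local_tempdir()
  manifest <- write_fixture(fx$panel, fx$geno, dir, truth = fx$truth)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  expect_true(all(nchar(manifest$md5) == 32))
  # genotypes: PLINK and VCF decode to the identical dosage matrix
  plink <- read_plink(file.path(dir, "genotypes"))
  vcf <- read_vcf(file.path(dir, "genotypes.vcf"))
  expect_identical(unname(plink$dosage), unname(fx$geno$dosage))
  expect_identical(unname(vcf$dosage), unname(plink$dosage) * 1)
  expect_identical(rownames(plink$dosage), rownames(fx$geno$dosage))
  # phenotypes round-trip to stated precision with metadata intact
  panel2 <- read_panel_csv(file.path(dir, "phenotypes.csv"))
  expect_equal(panel2$values, fx$panel$values, tolerance = 1e-12)
  expect_identical(panel2$meta$kind, fx$panel$meta$kind)
  expect_identical(panel2$covariates$year, fx$panel$covariates$year)
})

test_that("plink codec preserves missing calls", {
  d <- matrix(c(0L, 1L, 2L, NA, 2L, 0L, 1L, 1L, NA, 0L), nrow = 5,
              dimnames = list(paste0("a", 1:5), NULL))
  map <- data.frame(id = c("m1", "m2"), chrom = c(1, 2), pos = c(100, 200),
                    a1 = "A", a2 = "G")
  geno <- genotype_set(d, map)
  stem <- file.path(withr::local_tempdir(), "g")
  write_plink(geno, stem)
  back <- read_plink(stem)
  expect_identical(unname(back$dosage), unname(d))
  vcf_path <- paste0(stem, ".vcf")
  write_vcf(geno, vcf_path)
  expect_equal(unname(read_vcf(vcf_path)$dosage), unname(d) * 1.0)
})
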