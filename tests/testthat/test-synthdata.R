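test_that("population generation is a pure function of spec and seed", {
  spec <- population_spec(M = 40, seed = 99)
  pop1 <- generate_population(spec)
  pop2 <- generate_population(spec)
  expect_identical(lapply(pop1$patterns, function(x) x$positions),
                   lapply(pop2$patterns, function(x) x$positions))
  expect_identical(pop1$geometry, pop2$geometry)
  expect_equal(length(pop1$patterns), 40L)
  ## geometries respect the declarative distributions
  expect_true(all(pop1$geometry$R >= 0.8 & pop1$geometry$R <= 1.2))
  expect_true(all(abs(pop1$geometry$z) <= 0.8 * pop1$geometry$R))
  ## manifest records the generative model
  expect_equal(unlist(pop1$manifest$theta_true),
               c(lam = 20, gamma = 1, alpha = 1, beta = 2, kappa = 5))
  expect_equal(pop1$manifest$seed, 99L)
  f <- tempfile(fileext = ".json")
  write_manifest_json(pop1, f)
  m <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(m$M, 40L)
  unlink(f)
})

test_that("per-cell empirical counts regress onto the analytic means with slope 1", {
  spec <- population_spec(M = 400, seed = 123)
  pop <- generate_population(spec)
  counts <- sapply(pop$patterns, function(x) x$n)
  pred <- mapply(function(R, z) {
    mean_count(model_params(lam = 20, alpha = 1, beta = 2, gamma = 1, D = 1,
                            z = z, kappa = 5), domain_1d(R))
  }, pop$geometry$R, pop$geometry$z)
  fitlm <- lm(counts ~ pred)
  ci <- confint(fitlm, "pred", level = 0.99)
  expect_gt(1, ci[1])
  expect_lt(1, ci[2])
  ## pooled mean agrees within Monte-Carlo error
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mean(pred)), 3 * se)
})

test_that("random 2D domains honour their contracts", {
  ## zero roughness gives a circle of radius R0
  circ <- generate_domain2d(seed = 2, R0 = 1.3, roughness = 0)
  rads <- sqrt(rowSums(circ$polygon^2))
  expect_equal(rads, rep(1.3, nrow(circ$polygon)), tolerance = 1e-9)
  ## rough domains: simple polygon, D within range, centroid interior
  dom2 <- generate_domain2d(seed = 8, R0 = 1, roughness = 0.15,
                            D_range = c(0.4, 1.6))
  expect_true(all(dom2$D_grid >= 0.4 - 1e-12 & dom2$D_grid <= 1.6 + 1e-12))
  p <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1, z = c(0, 0))
  expect_s3_class(validate_params(p, dom2), "sb_params")
  ## reproducible
  dom2b <- generate_domain2d(seed = 8, R0 = 1, roughness = 0.15,
                             D_range = c(0.4, 1.6))
  expect_identical(dom2$polygon, dom2b$polygon)
  expect_identical(dom2$D_grid, dom2b$D_grid)
})

test_that("sweep tables expose the qualitative trends of the model", {
  base <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1, z = 0.3)
  tab <- sweep_figures(base, domain_1d(1),
                       sweeps = list(z = c(0, 0.3, 0.6, 0.9),
                                     kappa = c(0.25, 1, 4, 16, 64)))
  expect_true(all(tab$S >= 0 & tab$S <= 1))
  ## mean -> 0 as the gene site approaches the wall
  zrows <- tab[tab$parameter == "z", ]
  expect_true(all(diff(zrows$mean) < 0))
  ## Fano factor decreases monotonically with the export rate
  krows <- tab[tab$parameter == "kappa", ]
  expect_true(all(diff(krows$fano_spat) < 0))
  ## variance columns agree to a few percent away from the near-wall
  ## regime (the heuristic scaling degrades mildly as S -> 0)
  ok <- !is.na(tab$var_series) & tab$S > 0.15
  expect_true(all(abs(tab$var_pb[ok] - tab$var_series[ok]) / tab$var_series[ok] < 0.05))
  expect_true(all(abs(tab$var_pb[!is.na(tab$var_series)] -
                        tab$var_series[!is.na(tab$var_series)]) /
                    tab$var_series[!is.na(tab$var_series)] < 0.10))
  ## simulated columns carry standard errors
  tab_sim <- sweep_figures(base, domain_1d(1), sweeps = list(z = c(0, 0.5)),
                           simulate = TRUE, n_samples = 300, seed = 4)
  expect_true(all(is.finite(tab_sim$sim_mean_se)))
  expect_true(all(abs(tab_sim$sim_mean - tab_sim$mean) < 4 * tab_sim$sim_mean_se))
})

test_that("patterns round-trip through the CSV interchange format", {
  spec <- population_spec(M = 15, seed = 55)
  pop <- generate_population(spec)
  f <- tempfile(fileext = ".csv")
  write_patterns_csv(pop$patterns, f)
  back <- read_patterns_csv(f)
  expect_equal(length(back), 15L)
  for (i in seq_len(15)) {
    expect_equal(back[[i]]$positions, pop$patterns[[i]]$positions,
                 tolerance = 1e-12)
    expect_equal(back[[i]]$domain$R, pop$patterns[[i]]$domain$R)
  }
  unlink(f); unlink(sub("\\.csv$", "_geometry.csv", f))
})
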