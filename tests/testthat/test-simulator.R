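dom <- domain_1d(1)

test_that("telegraph promoter has the stationary on-fraction and holding times", {
  path <- simulate_telegraph(alpha = 1, beta = 2, t_end = 4000, seed = 11)
  durs <- diff(c(path$time, 4000))
  on_frac <- sum(durs[path$state == 1]) / 4000
  expect_equal(on_frac, 1 / 3, tolerance = 0.05)
  ## mean holding time in the on state ~ 1/beta
  on_holds <- durs[path$state == 1]
  on_holds <- on_holds[-length(on_holds)]  # last interval is censored
  expect_equal(mean(on_holds), 1 / 2,
               tolerance = 4 / sqrt(length(on_holds)) * 0.5)
  ## symmetric rates: half the time on
  path2 <- simulate_telegraph(alpha = 2, beta = 2, t_end = 4000, seed = 12)
  durs2 <- diff(c(path2$time, 4000))
  expect_equal(sum(durs2[path2$state == 1]) / 4000, 0.5, tolerance = 0.05)
})

test_that("boundary update rule: reflection never exports, absorption removes crossers", {
  p_ref <- model_params(lam = 1, alpha = 1, beta = 1, gamma = 1, D = 1,
                        z = 0, kappa = 0)
  p_abs <- model_params(lam = 1, alpha = 1, beta = 1, gamma = 1, D = 1, z = 0)
  set.seed(3)
  for (i in 1:200) {
    xo <- runif(1, -0.99, 0.99)
    xn <- xo + rnorm(1, 0, 0.3)
    r <- apply_boundary_1d(xo, xn, dom, p_ref, dt = 0.01)
    expect_false(is.na(r))
    expect_lte(abs(r), 1)
    if (abs(xn) >= 1) {
      expect_true(is.na(apply_boundary_1d(xo, xn, dom, p_abs, dt = 0.01)))
    }
  }
  ## the kappa = Inf flag behaves as absorbing: certain removal on crossing
  expect_true(is.na(apply_boundary_1d(0.5, 1.2, dom, p_abs, dt = 0.01)))
  ## Robin clamp guards against an over-coarse step
  p_rob <- model_params(lam = 1, alpha = 1, beta = 1, gamma = 1, D = 1e-4,
                        z = 0, kappa = 50)
  expect_error(apply_boundary_1d(0.5, 1.2, dom, p_rob, dt = 0.1), "smaller dt")
})

test_that("constitutive production yields Poisson counts (Fano -> 1)", {
  ## lam = lam_off removes promoter noise entirely
  p <- model_params(lam = 8, lam_off = 8, alpha = 1, beta = 1, gamma = 1,
                    D = 1, z = 0.2)
  set.seed(21)
  cts <- simulate_counts(p, dom, sim_config(n_samples = 1500))
  fano <- var(cts) / mean(cts)
  se <- sqrt(2 / length(cts))  # approximate SE of the Fano under Poisson
  expect_lt(abs(fano - 1), 4 * se)
})

test_that("simulated means track the closed forms across a gene-site sweep", {
  for (z in c(0, 0.45, 0.85)) {
    p <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1, z = z)
    set.seed(100 + round(100 * z))
    cts <- simulate_counts(p, dom, sim_config(n_samples = 1200))
    se <- sd(cts) / sqrt(length(cts))
    expect_lt(abs(mean(cts) - mean_count(p, dom)), 3 * se)
  }
})

test_that("pooled positions follow the normalized mean intensity (chi-square GOF)", {
  p <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1, z = 0.3)
  set.seed(31)
  pats <- simulate_cell(p, dom, sim_config(n_samples = 1200))
  xs <- unlist(lapply(pats, function(pp) pp$positions))
  expect_gt(length(xs), 1500)
  breaks <- seq(-1, 1, length.out = 13)
  obs <- table(cut(xs, breaks))
  tot <- mean_count(p, dom)
  probs <- sapply(seq_len(length(breaks) - 1), function(i) {
    stats::integrate(function(x) mean_intensity(p, dom, x),
                     breaks[i], breaks[i + 1], rel.tol = 1e-9)$value / tot
  })
  gof <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = probs / sum(probs)))
  ## positions within a snapshot are correlated through the shared
  ## intensity, which inflates the statistic mildly; 0.1% is the guard
  expect_gt(gof$p.value, 0.001)
})

test_that("Robin-boundary simulation reproduces the S_kappa mean curve", {
  for (kap in c(0.5, 4)) {
    p <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1,
                      z = 0.5, kappa = kap)
    set.seed(200 + round(kap))
    cts <- simulate_counts(p, dom, sim_config(n_samples = 700))
    se <- sd(cts) / sqrt(length(cts))
    expect_lt(abs(mean(cts) - mean_count(p, dom)), 3 * se)
  }
})

test_that("halving dt moves the mean by less than the Monte-Carlo error", {
  p <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1, z = 0.3)
  set.seed(41)
  c1 <- simulate_counts(p, dom, sim_config(n_samples = 800))
  set.seed(41)
  c2 <- simulate_counts(p, dom, sim_config(dt = 5e-4, n_samples = 800))
  se <- sqrt(var(c1) / length(c1) + var(c2) / length(c2))
  expect_lt(abs(mean(c1) - mean(c2)), 3 * se)
})

test_that("population simulation is reproducible and matches per-cell means", {
  p <- model_params(lam = 20, alpha = 1, beta = 2, gamma = 1, D = 1, z = 0,
                    kappa = 5)
  sampler <- function(m) {
    data.frame(R = runif(m, 0.8, 1.2), z = runif(m, -0.6, 0.6))
  }
  pop1 <- simulate_population(p, sampler, M = 120, cfg = sim_config(seed = 7))
  pop2 <- simulate_population(p, sampler, M = 120, cfg = sim_config(seed = 7))
  expect_identical(lapply(pop1, function(x) x$positions),
                   lapply(pop2, function(x) x$positions))
  expect_identical(simulate_population(p, sampler, M = 0), list())
  ## pooled mean vs mean of per-cell analytic predictions
  counts <- sapply(pop1, function(x) x$n)
  pred <- sapply(pop1, function(x) {
    mean_count(model_params(lam = p$lam, alpha = p$alpha, beta = p$beta,
                            gamma = p$gamma, D = p$D, z = x$z, kappa = p$kappa),
               x$domain)
  })
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mean(pred)), 3 * se)
})

test_that("particle safety cap triggers with an informative error", {
  p <- model_params(lam = 5000, alpha = 1, beta = 0.01, gamma = 0.01, D = 1,
                    z = 0, kappa = 0)
  expect_error(simulate_counts(p, dom, sim_config(n_samples = 2,
                                                  max_particles = 50L)),
               "safety cap")
})
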