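dom <- domain_1d(1)
p0 <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1, z = 0.3)

test_that("absorbing mean intensity vanishes at the walls and is symmetric for z = 0", {
  expect_equal(mean_intensity(p0, dom, c(-1, 1)), c(0, 0))
  pz0 <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1, z = 0)
  xs <- seq(0.05, 0.95, by = 0.1)
  expect_equal(mean_intensity(pz0, dom, xs), mean_intensity(pz0, dom, -xs))
  expect_true(all(mean_intensity(p0, dom, seq(-1, 1, by = 0.01)) >= 0))
  expect_error(mean_intensity(p0, dom, 1.2), "outside")
})

test_that("closed-form mean intensity matches the finite-difference oracle", {
  p <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1, z = 0.3)
  fd <- fd_mean_1d(p, R = 1, n = 10001L)
  x0 <- 0.1
  u_fd <- fd$u[which.min(abs(fd$x - x0))]
  expect_equal(mean_intensity(p, dom, x0), u_fd, tolerance = 1e-4)
  ## 10-point stratified sweep over the parameter box
  lh <- latin_hypercube(10, list(lam = c(2, 30), alpha = c(0.2, 4),
                                 beta = c(0.2, 4), gamma = c(0.2, 4),
                                 D = c(0.2, 4), z = c(-0.8, 0.8)), seed = 42)
  for (i in seq_len(nrow(lh))) {
    pi_ <- model_params(lam = lh$lam[i], alpha = lh$alpha[i], beta = lh$beta[i],
                        gamma = lh$gamma[i], D = lh$D[i], z = lh$z[i])
    fd <- fd_mean_1d(pi_, R = 1, n = 10001L)
    tot <- mean_count(pi_, dom)
    expect_equal(tot, fd$total, tolerance = 5e-4, info = paste("row", i))
  }
})

test_that("Robin mean intensity satisfies the flux-jump and limit conditions", {
  pk <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1,
                     z = 0.3, kappa = 2)
  ## continuity at z
  eps <- 1e-7
  uL <- mean_intensity_robin(pk, dom, pk$z - eps)
  uR <- mean_intensity_robin(pk, dom, pk$z + eps)
  expect_equal(uL, uR, tolerance = 1e-4)
  ## flux jump -D (u'(z+) - u'(z-)) = lam * rho
  h <- 1e-6
  dL <- (mean_intensity_robin(pk, dom, pk$z - eps) -
           mean_intensity_robin(pk, dom, pk$z - eps - h)) / h
  dR <- (mean_intensity_robin(pk, dom, pk$z + eps + h) -
           mean_intensity_robin(pk, dom, pk$z + eps)) / h
  expect_equal(-pk$D * (dR - dL), pk$lam * pk$rho, tolerance = 1e-3)
  ## large-kappa limit agrees with the absorbing closed form at x = 0
  pbig <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1,
                       z = 0.3, kappa = 1e6)
  expect_equal(mean_intensity_robin(pbig, dom, 0),
               mean_intensity(p0, dom, 0), tolerance = 1e-4)
  ## kappa = 0: no export, integral equals lam * rho / gamma
  pref <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1,
                       z = 0.3, kappa = 0)
  tot <- stats::integrate(function(x) mean_intensity_robin(pref, dom, x),
                          -1, 1, rel.tol = 1e-10)$value
  expect_equal(tot, pref$lam * pref$rho / pref$gamma, tolerance = 1e-8)
  ## Robin FD oracle agreement
  fd <- fd_mean_1d(pk, R = 1, n = 10001L)
  expect_equal(mean_count(pk, dom), fd$total, tolerance = 5e-4)
})

test_that("scale factor S has the printed value and limiting behaviour", {
  pz0 <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1, z = 0)
  expect_equal(scale_factor_S(pz0, dom), 1 - 1 / cosh(1))
  ## z -> +-R pushes S to zero
  pz <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1, z = 0.999)
  expect_lt(scale_factor_S(pz, dom), 0.01)
  ## gamma/D -> Inf recovers the non-spatial limit S -> 1 (no overflow)
  pfast <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1e6, D = 1e-6, z = 0.3)
  expect_equal(scale_factor_S(pfast, dom), 1)
  ## monotone: decreasing in D and |z|, increasing in gamma and R
  Sv <- function(D = 1, z = 0.3, gamma = 1, R = 1) {
    scale_factor_S(model_params(lam = 10, alpha = 1, beta = 1, gamma = gamma,
                                D = D, z = z), domain_1d(R))
  }
  expect_true(all(diff(sapply(c(0.25, 0.5, 1, 2, 4), function(d) Sv(D = d))) < 0))
  expect_true(all(diff(sapply(c(0, 0.2, 0.4, 0.6, 0.8), function(z) Sv(z = z))) < 0))
  expect_true(all(diff(sapply(c(0.25, 0.5, 1, 2, 4), function(g) Sv(gamma = g))) > 0))
  expect_true(all(diff(sapply(c(0.5, 1, 2, 4), function(r) Sv(R = r))) > 0))
})

test_that("Robin scale factor interpolates between reflecting and absorbing", {
  mk <- function(kap) model_params(lam = 10, alpha = 1, beta = 1, gamma = 1,
                                   D = 1, z = 0.3, kappa = kap)
  S_abs <- scale_factor_S(p0, dom)
  expect_equal(scale_factor_Skappa(mk(0), dom), 1)
  expect_equal(scale_factor_Skappa(mk(1e8), dom), S_abs, tolerance = 1e-6)
  ## monotone decreasing in kappa (export lowers retention)
  ks <- c(0.1, 0.5, 1, 2, 5, 10, 50, 200)
  Sk <- sapply(ks, function(k) scale_factor_Skappa(mk(k), dom))
  expect_true(all(diff(Sk) < 0))
  expect_true(all(Sk > S_abs & Sk < 1))
  ## quadrature consistency: S_kappa = gamma * integral(u) / (lam * rho)
  for (kap in c(0.5, 3, 20)) {
    pk <- mk(kap)
    tot <- stats::integrate(function(x) mean_intensity_robin(pk, dom, x),
                            -1, 1, rel.tol = 1e-10)$value
    expect_equal(scale_factor_Skappa(pk, dom),
                 pk$gamma * tot / (pk$lam * pk$rho), tolerance = 1e-8)
  }
})

test_that("mean count equals the integrated mean intensity", {
  for (kap in c(Inf, 0, 2)) {
    pk <- model_params(lam = 10, alpha = 1, beta = 2, gamma = 1.5, D = 0.7,
                       z = -0.4, kappa = kap)
    tot <- stats::integrate(function(x) mean_intensity_robin(pk, dom, x),
                            -1, 1, rel.tol = 1e-11)$value
    expect_equal(mean_count(pk, dom), tot, tolerance = 1e-8)
  }
  ## mean count decreasing as the gene site approaches the wall
  ms <- sapply(c(0, 0.3, 0.6, 0.9, 0.99), function(z) {
    mean_count(model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1,
                            z = z), dom)
  })
  expect_true(all(diff(ms) < 0))
  expect_lt(ms[length(ms)], 0.1)
})

test_that("variance series vanishes for a never-off promoter and is stable", {
  p_on <- model_params(lam = 10, alpha = 1, beta = 0, gamma = 1, D = 1, z = 0.3)
  vs <- integrated_intensity_variance(p_on, dom)
  expect_equal(vs$value, 0)
  vs2 <- integrated_intensity_variance(p0, dom)
  expect_gt(vs2$value, 0)
  ## tightening the tolerance (more modes) changes nothing material
  partial_at <- function(tolv) integrated_intensity_variance(p0, dom, tol = tolv)$value
  expect_equal(partial_at(1e-6), partial_at(1e-10), tolerance = 1e-6)
  expect_lt(vs2$est_truncation_error, 1e-10 * vs2$value + 1e-15)
})

test_that("variance series matches the independent Lyapunov-moment oracle", {
  cases <- list(
    model_params(lam = 10, alpha = 1, beta = 2, gamma = 1, D = 0.8, z = 0.3),
    model_params(lam = 15, alpha = 0.5, beta = 0.5, gamma = 2, D = 1, z = -0.2),
    model_params(lam = 8, alpha = 2, beta = 1, gamma = 0.5, D = 0.5, z = 0.5)
  )
  for (p in cases) {
    oracle <- lyapunov_var_int(p, R = 1, n = 72L)
    series <- integrated_intensity_variance(p, dom)$value
    expect_equal(series, oracle, tolerance = 0.02)
  }
})

test_that("series-based count variance decreases in D, gamma, alpha and z", {
  vfun <- function(D = 1, gamma = 1, alpha = 1, z = 0.3) {
    p <- model_params(lam = 10, alpha = alpha, beta = 1, gamma = gamma,
                      D = D, z = z)
    var_count(p, dom)
  }
  expect_true(all(diff(sapply(c(0.5, 1, 2, 4), function(v) vfun(D = v))) < 0))
  expect_true(all(diff(sapply(c(0.5, 1, 2, 4), function(v) vfun(gamma = v))) < 0))
  expect_true(all(diff(sapply(c(0, 0.3, 0.6, 0.9), function(v) vfun(z = v))) < 0))
  ## the alpha trend holds in the burst-noise-dominated regime (alpha >=
  ## beta with switching slow relative to transport and degradation);
  ## in fast-degradation regimes the variance is non-monotone in alpha
  vslow <- sapply(c(1, 2, 4, 8), function(a) {
    var_count(model_params(lam = 10, alpha = a, beta = 1, gamma = 0.25,
                           D = 0.25, z = 0.3), dom)
  })
  expect_true(all(diff(vslow) < 0))
})

test_that("Fano factors obey the spatial-reduction identities", {
  ## S = 1 (no export) recovers the non-spatial Fano factor
  pref <- model_params(lam = 10, alpha = 1, beta = 2, gamma = 1, D = 1,
                       z = 0.3, kappa = 0)
  expect_equal(fano_spatial(pref, dom), fano_nonspatial(pref))
  ## beta = 0: Poisson limit, both equal 1
  pon <- model_params(lam = 10, alpha = 1, beta = 0, gamma = 1, D = 1, z = 0)
  expect_equal(fano_spatial(pon, dom), 1)
  expect_equal(fano_nonspatial(pon), 1)
  ## S = 0 substitution gives exactly 1
  expect_equal(fano_spatial(p0, S = 1e-300), 1)
  ## F_spat <= F_nonspat over a parameter sweep, both >= 1
  lh <- latin_hypercube(25, list(lam = c(1, 40), alpha = c(0.1, 5),
                                 beta = c(0.1, 5), gamma = c(0.1, 5),
                                 D = c(0.1, 5), z = c(-0.9, 0.9)), seed = 7)
  for (i in seq_len(nrow(lh))) {
    p <- model_params(lam = lh$lam[i], alpha = lh$alpha[i], beta = lh$beta[i],
                      gamma = lh$gamma[i], D = lh$D[i], z = lh$z[i])
    fs <- fano_spatial(p, dom); fn <- fano_nonspatial(p)
    expect_gte(fn, fs)
    expect_gte(fs, 1)
  }
})

test_that("variance layer refuses a nonzero basal rate explicitly", {
  pb <- model_params(lam = 10, lam_off = 1, alpha = 1, beta = 1, gamma = 1,
                     D = 1, z = 0)
  expect_error(integrated_intensity_variance(pb, dom), "lam_off")
  expect_error(mean_count(pb, dom), "lam_off")
  expect_error(fano_spatial(pb, dom), "lam_off")
})
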