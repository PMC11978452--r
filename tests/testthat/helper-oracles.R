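## Independent numerical oracles used to validate the closed forms.
## These are deliberately separate implementations: plain finite-difference
## boundary-value solves and a stationary second-moment (Lyapunov) solve
## for the switching system, sharing no code with the package internals.

## FD solve of 0 = D u'' - gamma u + lam*rho*delta(x-z) on [-R, R].
## kappa = Inf -> Dirichlet ends; finite kappa -> Robin via ghost nodes.
## Returns list(x, u, total).
fd_mean_1d <- function(p, R, n = 4001L, kappa = p$kappa) {
  h <- 2 * R / (n - 1)
  x <- seq(-R, R, length.out = n)
  D <- p$D; gam <- p$gamma
  src <- p$lam * p$rho
  iz <- which.min(abs(x - p$z))
  if (is.infinite(kappa)) {
    m <- n - 2L
    xi <- x[2:(n - 1)]
    iiz <- which.min(abs(xi - p$z))
    A <- Matrix::bandSparse(m, k = c(-1, 0, 1),
                            diagonals = list(rep(D / h^2, m - 1),
                                             rep(-2 * D / h^2 - gam, m),
                                             rep(D / h^2, m - 1)))
    b <- numeric(m); b[iiz] <- -src / h
    u <- c(0, as.numeric(Matrix::solve(A, b)), 0)
  } else {
    ii <- c(); jj <- c(); vv <- c()
    b <- numeric(n)
    for (k in 2:(n - 1)) {
      ii <- c(ii, k, k, k); jj <- c(jj, k - 1, k, k + 1)
      vv <- c(vv, D / h^2, -2 * D / h^2 - gam, D / h^2)
    }
    b[iz] <- -src / h
    ## ghost-node elimination for D u'(-R) = kappa u(-R), -D u'(R) = kappa u(R)
    ii <- c(ii, 1, 1); jj <- c(jj, 1, 2)
    vv <- c(vv, -2 * D / h^2 - 2 * kappa / h - gam, 2 * D / h^2)
    ii <- c(ii, n, n); jj <- c(jj, n - 1, n)
    vv <- c(vv, 2 * D / h^2, -2 * D / h^2 - 2 * kappa / h - gam)
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
    u <- as.numeric(Matrix::solve(A, b))
  }
  list(x = x, u = u, total = sum((u[-1] + u[-n]) / 2) * h)
}

## Stationary variance of the integrated intensity for the absorbing 1D
## model, from the coupled second-moment (Lyapunov-type) equations of the
## finite-difference switching system. Independent of the series code.
lyapunov_var_int <- function(p, R, n = 64L) {
  h <- 2 * R / (n + 1)
  x <- seq(-R + h, R - h, length.out = n)
  L <- Matrix::bandSparse(n, k = c(-1, 0, 1),
                          diagonals = list(rep(1, n - 1), rep(-2, n), rep(1, n - 1))) / h^2
  A <- p$D * L - p$gamma * Matrix::Diagonal(n)
  iz <- which.min(abs(x - p$z))
  e <- numeric(n); e[iz] <- 1 / h
  I <- Matrix::Diagonal(n)
  ## first moments by promoter state (1 = on, 0 = off)
  big <- rbind(cbind(A - p$beta * I, p$alpha * I),
               cbind(p$beta * I, A - p$alpha * I))
  mm <- Matrix::solve(big, c(-p$lam * p$rho * e, numeric(n)))
  m1 <- as.numeric(mm[1:n]); m0 <- as.numeric(mm[(n + 1):(2 * n)])
  ## second moments via vec(kron) solve
  In2 <- Matrix::Diagonal(n^2)
  K <- Matrix::kronecker(I, A) + Matrix::kronecker(A, I)
  v_src <- as.numeric(e %o% m1 + m1 %o% e)
  BIG <- rbind(cbind(K - p$beta * In2, p$alpha * In2),
               cbind(p$beta * In2, K - p$alpha * In2))
  VV <- Matrix::solve(BIG, c(-p$lam * v_src, numeric(n^2)))
  M1 <- matrix(as.numeric(VV[1:n^2]), n, n)
  M0 <- matrix(as.numeric(VV[n^2 + (1:n^2)]), n, n)
  mu <- m1 + m0
  Cov <- (M1 + M0) - mu %o% mu
  w <- rep(h, n)
  as.numeric(t(w) %*% Cov %*% w)
}

## Tiny stratified ("Latin hypercube") sampler over named parameter ranges.
latin_hypercube <- function(n, ranges, seed = 1) {
  set.seed(seed)
  out <- lapply(ranges, function(r) {
    u <- (sample(n) - stats::runif(n)) / n
    r[1] + u * (r[2] - r[1])
  })
  as.data.frame(out)
}

## Quadrature oracle for the Poisson-beta pmf (adaptive Beta-mixture
## integral, independent of the hypergeometric path). The substitutions
## u = t^alpha (near 0) and v = (1-t)^beta (near 1) absorb the Beta
## endpoint singularities so the integrands are smooth for any shapes.
pb_pmf_quad_oracle <- function(n, alpha_t, beta_t, lam_t) {
  lB <- lbeta(alpha_t, beta_t)
  vapply(n, function(nn) {
    left <- stats::integrate(function(u) {
      t <- u^(1 / alpha_t)
      stats::dpois(nn, lam_t * t) * (1 - t)^(beta_t - 1) / alpha_t / exp(lB)
    }, 0, 0.5^alpha_t, rel.tol = 1e-13, abs.tol = 1e-15, subdivisions = 500L)$value
    right <- stats::integrate(function(v) {
      t <- 1 - v^(1 / beta_t)
      stats::dpois(nn, lam_t * t) * t^(alpha_t - 1) / beta_t / exp(lB)
    }, 0, 0.5^beta_t, rel.tol = 1e-13, abs.tol = 1e-15, subdivisions = 500L)$value
    left + right
  }, numeric(1))
}
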