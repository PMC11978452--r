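## Closed-form steady-state results for the 1D model on [-R, R].
##
## All hyperbolic expressions are evaluated through scaled exponentials
## (every exponent <= 0) so that large gamma/D causes no overflow; the
## closed forms are valid to machine precision for q*R up to ~700 with
## q = sqrt(gamma/D).

## Scaled building blocks of the Robin two-point boundary-value solution.
## With q = sqrt(gamma/D) and h = kappa/sqrt(gamma*D), the solution on
## [-R, z] is proportional to cosh(q(x+R)) + h sinh(q(x+R)) (and mirrored
## on [z, R]); factoring the growing exponentials out leaves
##   gL(s) = (A + B exp(-2q(s+R)))/2,  gR(s) = (A + B exp(-2q(R-s)))/2,
##   gW    = (A^2 - B^2 exp(-4qR))/2,
## with A = 1+h, B = 1-h.  The fully absorbing boundary is the h -> Inf
## limit, equivalently A = 1, B = -1 after cancelling h.
robin_parts <- function(p, R) {
  q <- sqrt(p$gamma / p$D)
  if (p$absorbing) {
    list(q = q, A = 1, B = -1, h = Inf)
  } else {
    h <- p$kappa / sqrt(p$gamma * p$D)
    list(q = q, A = 1 + h, B = 1 - h, h = h)
  }
}

## log of gL/gR/gW style terms; arguments e <= 0 guaranteed.
g_of <- function(A, B, e) (A + B * exp(e)) / 2

#' Steady-state mean transcript intensity in 1D
#'
#' The mean of the Cox-process intensity, i.e. the expected transcript
#' density, for the interval nucleus `[-R, R]` with a point source of
#' strength `lam * rho` at the gene site `z`, degradation `gamma` and
#' diffusivity `D`. `mean_intensity()` requires the fully absorbing
#' boundary (`kappa = Inf`); `mean_intensity_robin()` solves the same
#' two-point boundary-value problem under Robin (semi-absorbing) conditions
#' `-D u'(R) = kappa u(R)`, `D u'(-R) = kappa u(-R)` and covers the whole
#' range `kappa` in `[0, Inf]` (it dispatches to the absorbing expression
#' when `kappa = Inf`, and to the reflecting solution when `kappa = 0`).
#'
#' Both require `lam_off = 0` (the basal-rate generalization is supported
#' only through [effective_production()] in the mean source strength; call
#' with `lam` set to the effective rate divided by `rho` if needed).
#'
#' @param p An [model_params()] object with `lam_off = 0`.
#' @param dom A [domain_1d()].
#' @param x Position(s) in `[-R, R]` (vectorized).
#' @param log If `TRUE`, return the log intensity.
#' @return Intensity values (molecules per unit length), non-negative, zero
#'   at `x = +-R` for the absorbing boundary.
#' @examples
#' p <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1, z = 0.3)
#' mean_intensity(p, domain_1d(1), x = c(-1, 0, 0.3, 1))
#' @export
mean_intensity <- function(p, dom, x, log = FALSE) {
  if (!p$absorbing) {
    stop("mean_intensity requires the absorbing boundary (kappa = Inf); ",
         "use mean_intensity_robin for finite kappa", call. = FALSE)
  }
  mean_intensity_robin(p, dom, x, log = log)
}

#' @rdname mean_intensity
#' @export
mean_intensity_robin <- function(p, dom, x, log = FALSE) {
  p <- validate_params(p, dom)
  require_lam_off_zero(p, "mean_intensity")
  R <- dom$R
  if (any(abs(x) > R + 1e-12)) stop("x outside domain", call. = FALSE)
  x <- pmin(pmax(x, -R), R)
  rp <- robin_parts(p, R)
  q <- rp$q; z <- p$z
  m1 <- pmin(x, z); m2 <- pmax(x, z)
  lg <- base::log(p$lam * p$rho / (p$D * q)) - q * (m2 - m1) +
    base::log(g_of(rp$A, rp$B, -2 * q * (m1 + R))) +
    base::log(g_of(rp$A, rp$B, -2 * q * (R - m2))) -
    base::log((rp$A^2 - rp$B^2 * exp(-4 * q * R)) / 2)
  if (log) lg else exp(lg)
}

#' Dimensionless nuclear retention scale factors
#'
#' `scale_factor_S` is the factor `S = 1 - cosh(z*sqrt(gamma/D)) *
#' sech(R*sqrt(gamma/D))` multiplying the non-spatial mean count for the
#' fully absorbing boundary; `scale_factor_Skappa` is its Robin-boundary
#' generalization, obtained in closed form from the Robin mean-intensity
#' solution. Both lie in `[0, 1]` and equal the probability that a
#' transcript is degraded inside the nucleus before being exported, so that
#' the mean count is `lam * rho * S / gamma`. `S` decreases with
#' diffusivity `D`, with proximity of the gene site to the boundary, and
#' with the export rate `kappa`, and increases with `gamma` and `R`.
#' Limits: `Skappa -> 1` as `kappa -> 0` (reflecting boundary: nothing is
#' exported and the non-spatial mean is recovered) and `Skappa -> S` as
#' `kappa -> Inf`.
#'
#' @param p An [model_params()] object; `scale_factor_S` ignores `kappa`,
#'   `scale_factor_Skappa` uses it (finite or infinite).
#' @param dom A [domain_1d()].
#' @return A dimensionless value in `[0, 1]`.
#' @examples
#' p <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1, z = 0)
#' scale_factor_S(p, domain_1d(1))  # 1 - sech(1)
#' @export
scale_factor_S <- function(p, dom) {
  stopifnot(inherits(dom, "sb_domain_1d"))
  q <- sqrt(p$gamma / p$D)
  R <- dom$R; z <- p$z
  if (abs(z) >= R) return(0)
  ## cosh(zq)/cosh(Rq) via non-overflowing exponentials
  a <- abs(z) * q; b <- R * q
  ratio <- exp(a - b) * (1 + exp(-2 * a)) / (1 + exp(-2 * b))
  max(0, 1 - ratio)
}

#' @rdname scale_factor_S
#' @export
scale_factor_Skappa <- function(p, dom) {
  stopifnot(inherits(dom, "sb_domain_1d"))
  if (p$absorbing) return(scale_factor_S(p, dom))
  if (p$kappa == 0) return(1)
  R <- dom$R; z <- p$z
  rp <- robin_parts(p, R); q <- rp$q; h <- rp$h
  gL <- g_of(rp$A, rp$B, -2 * q * (z + R))
  gR <- g_of(rp$A, rp$B, -2 * q * (R - z))
  gW <- (rp$A^2 - rp$B^2 * exp(-4 * q * R)) / 2
  sk <- 1 - h * (exp(-q * (R - z)) * gL + exp(-q * (R + z)) * gR) / gW
  min(1, max(0, sk))
}

#' Mean molecular count
#'
#' The steady-state mean number of nuclear transcripts,
#' `lam * rho * S_kappa / gamma`, with the scale factor chosen by the
#' boundary type encoded in `kappa` (absorbing: `S`; Robin: `S_kappa`;
#' reflecting: 1, the non-spatial telegraph mean `lam * rho / gamma`).
#'
#' @param p An [model_params()] object with `lam_off = 0`.
#' @param dom A [domain_1d()].
#' @return The mean count (dimensionless).
#' @export
mean_count <- function(p, dom) {
  p <- validate_params(p, dom)
  require_lam_off_zero(p, "mean_count")
  p$lam * p$rho / p$gamma * scale_factor_Skappa(p, dom)
}

#' Variance of the integrated intensity (doubly infinite series)
#'
#' Evaluates the series for the variance of the spatially integrated
#' Cox-process intensity for the absorbing-boundary 1D model. Expanding the
#' intensity in the sine eigenmodes of the interval with Dirichlet ends,
#' only odd modes couple to the integral; the modal covariance of an
#' exponentially correlated dichotomous drive with switching timescale
#' `omega = alpha + beta` gives
#' \deqn{\psi \sum_{j,k \,\mathrm{odd}} w_j w_k
#'   \frac{a_j + a_k + 2\omega}{(a_j+\omega)(a_k+\omega)(a_j+a_k)},}
#' with `psi = lam^2 alpha beta / (alpha+beta)^2`, decay rates
#' `a_m = gamma + pi^2 D m^2 / (4 R^2)` and weights
#' `w_m = 4 sin(pi m (R+z) / (2R)) / (pi m)`. The variance of the total
#' count is this value plus the mean count (Poisson plus intensity
#' fluctuations); see [var_count()].
#'
#' The sum is truncated adaptively: the number of odd modes per axis is
#' doubled until the last doubling changes the value by less than `tol`
#' relative, with a hard cap. Terms decay like `1/(j^3 k^3)` so shell
#' doubling converges quickly and monotonically.
#'
#' @param p An [model_params()] object with `lam_off = 0` and absorbing
#'   boundary.
#' @param dom A [domain_1d()].
#' @param tol Relative truncation tolerance (default `1e-10`).
#' @param max_modes Hard cap on odd modes per axis.
#' @return An object of class `sb_variance_series`: list with `value`
#'   (>= 0), `terms_used` (odd modes per axis) and `est_truncation_error`.
#' @examples
#' p <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1, z = 0.3)
#' integrated_intensity_variance(p, domain_1d(1))$value
#' @export
integrated_intensity_variance <- function(p, dom, tol = 1e-10,
                                          max_modes = 8192L) {
  p <- validate_params(p, dom)
  require_lam_off_zero(p, "integrated_intensity_variance")
  if (!p$absorbing) {
    stop("the variance series is available for the absorbing boundary only; ",
         "finite-kappa variance comes from the Poisson-beta approximation ",
         "or simulation", call. = FALSE)
  }
  R <- dom$R; z <- p$z
  psi <- p$lam^2 * p$alpha * p$beta / (p$alpha + p$beta)^2
  if (psi == 0) {
    return(structure(list(value = 0, terms_used = 0L, est_truncation_error = 0),
                     class = "sb_variance_series"))
  }
  om <- p$omega
  partial <- function(J) {
    j <- seq(1, 2 * J - 1, by = 2)
    a <- p$gamma + p$D * pi^2 * j^2 / (4 * R^2)
    w <- 4 * sin(pi * j * (R + z) / (2 * R)) / (pi * j)
    acc <- 0
    for (i in seq_along(j)) {  # O(J) memory
      kern <- (a[i] + a + 2 * om) / ((a[i] + om) * (a + om) * (a[i] + a))
      acc <- acc + w[i] * sum(w * kern)
    }
    psi * acc
  }
  J <- 32L
  v_old <- partial(J)
  repeat {
    J <- J * 2L
    v <- partial(J)
    err <- abs(v - v_old)
    if (err <= tol * max(abs(v), .Machine$double.eps)) break
    if (J >= max_modes) {
      stop(sprintf(
        "variance series did not converge within %d modes (partial sum %.6g, last change %.3g)",
        J, v, err), call. = FALSE)
    }
    v_old <- v
  }
  if (v < 0) stop("variance series evaluated negative; parameters out of the supported regime",
                  call. = FALSE)
  structure(list(value = v, terms_used = J, est_truncation_error = err),
            class = "sb_variance_series")
}

#' @export
print.sb_variance_series <- function(x, ...) {
  cat(sprintf("Integrated-intensity variance: %.6g (%d odd modes/axis, est. trunc. err. %.2g)\n",
              x$value, x$terms_used, x$est_truncation_error))
  invisible(x)
}

#' Variance of the molecular count
#'
#' `method = "series"` (absorbing boundary only) combines the mean count
#' with the exact mode-expansion series for the intensity variance;
#' `method = "poisson_beta"` uses the Poisson-beta approximation with the
#' spatially rescaled parameters, which is available for any boundary via
#' the appropriate scale factor.
#'
#' @param p An [model_params()] object with `lam_off = 0`.
#' @param dom A [domain_1d()].
#' @param method `"series"` or `"poisson_beta"`.
#' @param ... Passed to [integrated_intensity_variance()].
#' @return The count variance.
#' @export
var_count <- function(p, dom, method = c("series", "poisson_beta"), ...) {
  method <- match.arg(method)
  if (method == "series") {
    mean_count(p, dom) + integrated_intensity_variance(p, dom, ...)$value
  } else {
    S <- scale_factor_Skappa(p, dom)
    poisson_beta_variance(spatial_rescale(p, S))
  }
}

#' Fano factors of the spatial and non-spatial telegraph models
#'
#' Closed-form variance-to-mean ratios of the molecular counts under the
#' Poisson-beta approximation. For the spatial model,
#' `F_spat = 1 + lam * beta * S / ((alpha+beta) (gamma + S (alpha+beta)))`
#' with the retention factor `S` from [scale_factor_S()] (or
#' [scale_factor_Skappa()] for Robin boundaries); the non-spatial model has
#' the same form with `S = 1`. Both are >= 1, `F_spat <= F_nonspat`
#' everywhere, with equality iff `S = 1`: export removes molecules before
#' they are counted and thereby suppresses fluctuations.
#'
#' @param p An [model_params()] object with `lam_off = 0`.
#' @param dom A [domain_1d()] (`fano_spatial` only).
#' @param S Optionally override the scale factor (e.g. from
#'   [scale_factor_general()] for a 2D solve).
#' @return A dimensionless Fano factor >= 1.
#' @export
fano_spatial <- function(p, dom = NULL, S = NULL) {
  require_lam_off_zero(p, "fano_spatial")
  if (is.null(S)) {
    if (is.null(dom)) stop("supply a domain or an explicit S", call. = FALSE)
    S <- scale_factor_Skappa(p, dom)
  }
  1 + p$lam * p$beta * S / ((p$alpha + p$beta) * (p$gamma + S * (p$alpha + p$beta)))
}

#' @rdname fano_spatial
#' @export
fano_nonspatial <- function(p) {
  require_lam_off_zero(p, "fano_nonspatial")
  1 + p$lam * p$beta / ((p$alpha + p$beta) * (p$gamma + p$alpha + p$beta))
}
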