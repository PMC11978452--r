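#' Steady-state mean-intensity solver for 2D nuclei
#'
#' Solves the steady-state mean-intensity equation for a two-dimensional
#' nucleus with spatially varying diffusivity in the Ito convention,
#' \deqn{0 = \nabla^2 [D(x) u(x)] - \gamma u + \lambda_p \delta(x - z),
#'       \quad u|_{\partial\Omega} = 0,}
#' where `lambda_p` is the promoter-averaged production rate
#' ([effective_production()]). Substituting `w = D(x) u` turns the Ito
#' form's inner-derivative placement into a standard symmetric problem
#' `Laplacian(w) - (gamma/D) w = -lambda_p delta`, which is discretized
#' with second-order centred finite differences on a regular grid over the
#' domain's bounding box; nodes outside the polygon carry the Dirichlet
#' value 0. The point source is mollified onto the four grid nodes
#' surrounding `z` with bilinear (mass-conserving) weights; since the
#' scale factor is an integral, it is insensitive to the mollification
#' width. The recovered `u = w / D` is non-negative up to discretization
#' tolerance.
#'
#' For a [domain_strip()] the long sides are reflecting (homogeneous
#' Neumann via mirrored ghost nodes) and only the ends `x = +-R` are
#' absorbing; transversally uniform solutions on the strip reproduce the
#' 1D closed forms, which is the solver's convergence benchmark.
#'
#' @param p An [model_params()] object (2D gene site for polygon domains,
#'   scalar for strips). `lam_off > 0` is supported here since only the
#'   effective production rate enters the mean.
#' @param dom A [domain_2d()] or [domain_strip()].
#' @param resolution Grid nodes along x (y scales with the aspect ratio).
#' @return An object of class `sb_mesh_solution`: list with grid vectors
#'   `gx`, `gy`, matrix `u_mean` (NA outside the domain), `inside` mask,
#'   `total` (the quadrature of `u` over the domain), `h` (grid steps),
#'   `lambda_p`, and `source` metadata describing the delta mollification.
#' @seealso [scale_factor_general()]
#' @export
solve_mean_pde <- function(p, dom, resolution = 121L) {
  if (inherits(dom, "sb_domain_strip")) {
    return(solve_mean_pde_strip(p, dom, resolution))
  }
  stopifnot(inherits(dom, "sb_domain_2d"))
  p <- validate_params(p, dom)
  lam_p <- effective_production(p)
  nx <- as.integer(resolution)
  xr <- range(dom$polygon[, 1]); yr <- range(dom$polygon[, 2])
  ny <- max(11L, as.integer(round(nx * diff(yr) / diff(xr))))
  gx <- seq(xr[1], xr[2], length.out = nx)
  gy <- seq(yr[1], yr[2], length.out = ny)
  hx <- gx[2] - gx[1]; hy <- gy[2] - gy[1]
  pts <- expand.grid(x = gx, y = gy)
  inside <- matrix(in_polygon(pts$x, pts$y, dom$polygon), nx, ny)
  Dm <- outer(gx, gy, function(x, y) interp_D(dom, x, y))
  if (any(Dm[inside] <= 0)) stop("non-positive diffusivity sample", call. = FALSE)
  idx <- matrix(0L, nx, ny)
  idx[inside] <- seq_len(sum(inside))
  nun <- sum(inside)
  if (nun == 0) stop("no grid nodes inside the polygon; raise resolution", call. = FALSE)

  ## assemble Laplacian(w) - (gamma/D) w on interior nodes
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  b <- numeric(nun)
  add <- function(r, c, v) { ii <<- c(ii, r); jj <<- c(jj, c); vv <<- c(vv, v) }
  ijs <- which(inside, arr.ind = TRUE)
  ## vectorized assembly: center terms
  ctr <- idx[inside]
  add(ctr, ctr, -2 / hx^2 - 2 / hy^2 - p$gamma / Dm[inside])
  offs <- list(c(1L, 0L, 1 / hx^2), c(-1L, 0L, 1 / hx^2),
               c(0L, 1L, 1 / hy^2), c(0L, -1L, 1 / hy^2))
  for (o in offs) {
    ni <- ijs[, 1] + o[1]; nj <- ijs[, 2] + o[2]
    ok <- ni >= 1 & ni <= nx & nj >= 1 & nj <= ny
    ok[ok] <- inside[cbind(ni[ok], nj[ok])]
    add(ctr[ok], idx[cbind(ni[ok], nj[ok])], rep(o[3], sum(ok)))
    ## neighbours outside the polygon carry w = 0 (Dirichlet): no entry
  }
  ## bilinear hat source at z, conserving unit mass (density 1/(hx*hy))
  fx <- (p$z[1] - gx[1]) / hx; fy <- (p$z[2] - gy[1]) / hy
  i0 <- pmin(pmax(floor(fx), 0), nx - 2) + 1; j0 <- pmin(pmax(floor(fy), 0), ny - 2) + 1
  tx <- fx - (i0 - 1); ty <- fy - (j0 - 1)
  wts <- c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  srcs <- rbind(c(i0, j0), c(i0 + 1, j0), c(i0, j0 + 1), c(i0 + 1, j0 + 1))
  for (k in 1:4) {
    if (!inside[srcs[k, 1], srcs[k, 2]]) {
      stop("gene site too close to the boundary for this resolution", call. = FALSE)
    }
    b[idx[srcs[k, 1], srcs[k, 2]]] <- b[idx[srcs[k, 1], srcs[k, 2]]] -
      lam_p * wts[k] / (hx * hy)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nun, nun))
  w <- as.numeric(Matrix::solve(A, b))
  um <- matrix(NA_real_, nx, ny)
  um[inside] <- w / Dm[inside]
  total <- sum(um[inside]) * hx * hy
  structure(list(gx = gx, gy = gy, u_mean = um, inside = inside,
                 total = total, h = c(hx, hy), lambda_p = lam_p,
                 source = list(type = "bilinear_hat", nodes = srcs, weights = wts)),
            class = "sb_mesh_solution")
}

solve_mean_pde_strip <- function(p, dom, resolution = 121L) {
  p <- validate_params(p, dom)
  lam_p <- effective_production(p)
  R <- dom$R; H <- dom$H
  nx <- as.integer(resolution)
  ny <- max(5L, as.integer(round(nx * H / (2 * R))))
  gx <- seq(-R, R, length.out = nx)  # includes Dirichlet end nodes
  gy <- seq(0, H, length.out = ny)
  hx <- gx[2] - gx[1]; hy <- gy[2] - gy[1]
  Dconst <- p$D
  nin <- (nx - 2) * ny  # unknowns: interior in x, all rows in y (Neumann sides)
  id <- function(i, j) (j - 1L) * (nx - 2L) + (i - 1L)  # i in 2..nx-1
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  b <- numeric(nin)
  for (j in seq_len(ny)) {
    for (i in 2:(nx - 1)) {
      r <- id(i, j)
      cxy <- -2 / hx^2 - 2 / hy^2 - p$gamma / Dconst
      ii <- c(ii, r); jj <- c(jj, r); vv <- c(vv, cxy)
      if (i > 2) { ii <- c(ii, r); jj <- c(jj, id(i - 1, j)); vv <- c(vv, 1 / hx^2) }
      if (i < nx - 1) { ii <- c(ii, r); jj <- c(jj, id(i + 1, j)); vv <- c(vv, 1 / hx^2) }
      ## Neumann in y: mirrored ghost doubles the inner neighbour
      if (j > 1) { ii <- c(ii, r); jj <- c(jj, id(i, j - 1)); vv <- c(vv, 1 / hy^2) }
      else { ii <- c(ii, r); jj <- c(jj, id(i, 2)); vv <- c(vv, 1 / hy^2) }
      if (j < ny) { ii <- c(ii, r); jj <- c(jj, id(i, j + 1)); vv <- c(vv, 1 / hy^2) }
      else { ii <- c(ii, r); jj <- c(jj, id(i, ny - 1)); vv <- c(vv, 1 / hy^2) }
    }
  }
  ## line source at x = z spread over all y with 1D hat weights, total
  ## strength lam_p (per unit length in y: lam_p / H)
  fx <- (p$z - gx[1]) / hx
  i0 <- pmin(pmax(floor(fx), 1), nx - 3) + 1
  tx <- fx - (i0 - 1)
  for (j in seq_len(ny)) {
    b[id(i0, j)] <- b[id(i0, j)] - lam_p / H * (1 - tx) / hx
    b[id(i0 + 1, j)] <- b[id(i0 + 1, j)] - lam_p / H * tx / hx
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nin, nin))
  w <- as.numeric(Matrix::solve(A, b))
  um <- matrix(NA_real_, nx, ny)
  for (j in seq_len(ny)) um[2:(nx - 1), j] <- w[id(2:(nx - 1), j)] / Dconst
  um[c(1, nx), ] <- 0
  inside <- matrix(TRUE, nx, ny)
  ## trapezoid quadrature in both directions
  wtx <- rep(1, nx); wtx[c(1, nx)] <- 0.5
  wty <- rep(1, ny); wty[c(1, ny)] <- 0.5
  total <- as.numeric(t(wtx) %*% um %*% wty) * hx * hy
  structure(list(gx = gx, gy = gy, u_mean = um, inside = inside,
                 total = total, h = c(hx, hy), lambda_p = lam_p,
                 source = list(type = "line_hat", i0 = i0, tx = tx)),
            class = "sb_mesh_solution")
}

#' @export
print.sb_mesh_solution <- function(x, ...) {
  cat(sprintf("Mean-intensity mesh solution: %dx%d grid, integral %.5g\n",
              length(x$gx), length(x$gy), x$total))
  invisible(x)
}

#' Generalized retention scale factor from a PDE solution
#'
#' The analogue of the 1D scale factor for arbitrary geometries:
#' `S = gamma * integral(u) / lambda_p`, the probability that a transcript
#' is degraded rather than exported, computed from the numerical mean
#' intensity. For a domain with no export (all-reflecting) `S = 1` by
#' steady-state balance; values outside `[0, 1]` beyond a small tolerance
#' indicate a failed discretization and raise an error.
#'
#' @param sol A [solve_mean_pde()] result.
#' @param p The [model_params()] used in the solve.
#' @param tol Tolerated overshoot beyond `[0, 1]`.
#' @return `S` in `[0, 1]`.
#' @export
scale_factor_general <- function(sol, p, tol = 1e-3) {
  S <- p$gamma * sol$total / sol$lambda_p
  if (S < -tol || S > 1 + tol) {
    stop(sprintf("scale factor %.4g outside [0, 1]; discretization failure", S),
         call. = FALSE)
  }
  min(1, max(0, S))
}

#' Export a mesh solution as tidy CSV
#'
#' Writes one row per interior grid node with columns `x`, `y`, `D`, `u`.
#'
#' @param sol A [solve_mean_pde()] result.
#' @param dom The [domain_2d()] used (for the diffusivity field); may be
#'   `NULL` for strips (constant D).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_mesh_csv <- function(sol, dom, path) {
  ij <- which(sol$inside & !is.na(sol$u_mean), arr.ind = TRUE)
  df <- data.frame(x = sol$gx[ij[, 1]], y = sol$gy[ij[, 2]],
                   D = if (is.null(dom)) NA_real_ else
                     interp_D(dom, sol$gx[ij[, 1]], sol$gy[ij[, 2]]),
                   u = sol$u_mean[ij])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
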