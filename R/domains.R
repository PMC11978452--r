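#' Nuclear domain geometries
#'
#' `domain_1d(R)` is the interval nucleus `[-R, R]` used throughout the 1D
#' theory; its boundary behaviour (absorbing, Robin with export rate
#' `kappa`, or reflecting) is taken from the `kappa` field of the parameter
#' set used with it, with `kappa = 0` equivalent to reflecting and
#' `kappa = Inf` to absorbing.
#'
#' `domain_strip(R, H)` is a rectangle `[-R, R] x [0, H]` with absorbing
#' ends at `x = -R, R` and reflecting long sides; transversally uniform
#' solutions on it reproduce the 1D model exactly, which is the benchmark
#' used to validate the 2D solver.
#'
#' `domain_2d(polygon, D_field, ...)` is an irregular planar nucleus with a
#' simple closed polygon boundary (fully absorbing) and a spatially varying
#' diffusivity `D(x, y)` sampled on a regular grid over the polygon's
#' bounding box. `D_field` may be a function `(x, y) -> D` (vectorized) or
#' a matrix of values on the grid (rows indexing `x`, columns `y`).
#'
#' @param R Half-width of the interval (or strip length / 2), > 0.
#' @param H Strip height, > 0.
#' @param polygon Two-column matrix of vertices of a simple closed polygon
#'   (last vertex need not repeat the first).
#' @param D_field Function of `(x, y)` or matrix on the grid; values must be
#'   bounded between positive constants.
#' @param grid_n Number of grid points per axis for the stored diffusivity
#'   field (when `D_field` is a function).
#' @return A domain object of class `sb_domain_1d`, `sb_domain_strip` or
#'   `sb_domain_2d`.
#' @examples
#' domain_1d(1)
#' sq <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
#' domain_2d(sq, D_field = function(x, y) 1 + 0 * x)
#' @export
domain_1d <- function(R) {
  if (!is.numeric(R) || length(R) != 1L || is.na(R) || R <= 0) {
    stop("R must be a single positive number", call. = FALSE)
  }
  structure(list(R = R), class = "sb_domain_1d")
}

#' @rdname domain_1d
#' @export
domain_strip <- function(R, H) {
  if (R <= 0 || H <= 0) stop("R and H must be positive", call. = FALSE)
  structure(list(R = R, H = H), class = "sb_domain_strip")
}

#' @rdname domain_1d
#' @export
domain_2d <- function(polygon, D_field, grid_n = 64L) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
    stop("polygon must be a matrix with >= 3 rows and 2 columns", call. = FALSE)
  }
  if (polygon_self_intersects(polygon)) {
    stop("polygon must be simple (non self-intersecting)", call. = FALSE)
  }
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  gx <- seq(xr[1], xr[2], length.out = grid_n)
  gy <- seq(yr[1], yr[2], length.out = grid_n)
  if (is.function(D_field)) {
    Dm <- outer(gx, gy, D_field)
  } else {
    Dm <- as.matrix(D_field)
    if (nrow(Dm) != grid_n || ncol(Dm) != grid_n) {
      gx <- seq(xr[1], xr[2], length.out = nrow(Dm))
      gy <- seq(yr[1], yr[2], length.out = ncol(Dm))
    }
  }
  if (anyNA(Dm) || any(Dm <= 0)) {
    stop("diffusivity field must be positive everywhere on the grid", call. = FALSE)
  }
  structure(list(polygon = polygon, gx = gx, gy = gy, D_grid = Dm),
            class = "sb_domain_2d")
}

#' @export
print.sb_domain_1d <- function(x, ...) {
  cat(sprintf("1D nuclear domain [-R, R], R = %g\n", x$R)); invisible(x)
}

#' @export
print.sb_domain_2d <- function(x, ...) {
  cat(sprintf("2D nuclear domain: %d-vertex polygon, D in [%.3g, %.3g] on a %dx%d grid\n",
              nrow(x$polygon), min(x$D_grid), max(x$D_grid),
              length(x$gx), length(x$gy)))
  invisible(x)
}

## Even-odd rule point-in-polygon test, vectorized over query points.
in_polygon <- function(px, py, polygon) {
  vx <- polygon[, 1]; vy <- polygon[, 2]
  n <- length(vx)
  jx <- c(vx[n], vx[-n]); jy <- c(vy[n], vy[-n])
  inside <- logical(length(px))
  for (k in seq_len(n)) {
    crosses <- ((vy[k] > py) != (jy[k] > py)) &
      (px < (jx[k] - vx[k]) * (py - vy[k]) / (jy[k] - vy[k]) + vx[k])
    inside <- xor(inside, crosses)
  }
  inside
}

polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), ])
  segs_cross <- function(a, b) {
    d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    p1 <- a[1:2]; p2 <- a[3:4]; p3 <- b[1:2]; p4 <- b[3:4]
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent via wrap-around
      if (segs_cross(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}

## Bilinear interpolation of the stored diffusivity grid (clamped at edges).
interp_D <- function(dom, px, py) {
  gx <- dom$gx; gy <- dom$gy; Dm <- dom$D_grid
  hx <- gx[2] - gx[1]; hy <- gy[2] - gy[1]
  fx <- pmin(pmax((px - gx[1]) / hx, 0), length(gx) - 1 - 1e-9)
  fy <- pmin(pmax((py - gy[1]) / hy, 0), length(gy) - 1 - 1e-9)
  i <- floor(fx); j <- floor(fy); tx <- fx - i; ty <- fy - j
  i <- i + 1; j <- j + 1
  Dm[cbind(i, j)] * (1 - tx) * (1 - ty) + Dm[cbind(i + 1, j)] * tx * (1 - ty) +
    Dm[cbind(i, j + 1)] * (1 - tx) * ty + Dm[cbind(i + 1, j + 1)] * tx * ty
}

#' One cell's observed transcript positions
#'
#' A point pattern couples the observed transcript coordinates of a single
#' cell with that cell's geometry (its domain and gene site). Empty
#' patterns (`n = 0`) are allowed; every position must lie inside the
#' domain.
#'
#' @param positions Numeric vector (1D) or two-column matrix (2D) of
#'   transcript coordinates; may be length/row 0.
#' @param domain A [domain_1d()] or [domain_2d()] object.
#' @param z The cell's gene site.
#' @return An object of class `sb_point_pattern` with fields `positions`,
#'   `domain`, `z` and `n`.
#' @export
point_pattern <- function(positions, domain, z) {
  if (inherits(domain, "sb_domain_1d")) {
    positions <- as.numeric(positions)
    if (length(positions) && any(abs(positions) > domain$R)) {
      stop("positions outside domain", call. = FALSE)
    }
  } else if (inherits(domain, "sb_domain_2d")) {
    positions <- matrix(as.numeric(positions), ncol = 2)
    if (nrow(positions) && !all(in_polygon(positions[, 1], positions[, 2],
                                           domain$polygon))) {
      stop("positions outside domain", call. = FALSE)
    }
  } else {
    stop("domain must be a spatburst domain object", call. = FALSE)
  }
  n <- if (is.matrix(positions)) nrow(positions) else length(positions)
  structure(list(positions = positions, domain = domain, z = z, n = n),
            class = "sb_point_pattern")
}

#' @export
print.sb_point_pattern <- function(x, ...) {
  cat(sprintf("Point pattern: %d transcripts, gene site z = %s\n", x$n,
              paste(format(x$z), collapse = ", ")))
  invisible(x)
}

#' Truncated distribution of molecular counts
#'
#' A probability mass function over counts `n = 0, 1, ..., n_max` together
#' with the mass beyond the truncation bound. Entries are non-negative and
#' `sum(pmf) + tail_mass = 1` to within 1e-12.
#'
#' @param pmf Numeric vector of probabilities for `n = 0 .. n_max`.
#' @param tail_mass Probability mass beyond `n_max` (default: `1 - sum(pmf)`
#'   floored at 0).
#' @param tail_tol Maximum tolerated tail mass before a warning is raised.
#' @return An object of class `sb_count_distribution` with fields `pmf`,
#'   `n_max` and `tail_mass`.
#' @seealso [poisson_beta_pmf()], [jensen_shannon()]
#' @export
count_distribution <- function(pmf, tail_mass = NULL, tail_tol = 1e-6) {
  pmf <- as.numeric(pmf)
  if (any(pmf < -1e-14)) stop("pmf entries must be non-negative", call. = FALSE)
  pmf <- pmax(pmf, 0)
  if (is.null(tail_mass)) tail_mass <- max(0, 1 - sum(pmf))
  if (abs(sum(pmf) + tail_mass - 1) > 1e-12) {
    stop("pmf + tail_mass must sum to 1 within 1e-12", call. = FALSE)
  }
  if (tail_mass > tail_tol) {
    warning(sprintf("tail mass %.3g exceeds tolerance %.3g; increase n_max",
                    tail_mass, tail_tol))
  }
  structure(list(pmf = pmf, n_max = length(pmf) - 1L, tail_mass = tail_mass),
            class = "sb_count_distribution")
}

#' @export
print.sb_count_distribution <- function(x, ...) {
  m <- sum((seq_along(x$pmf) - 1) * x$pmf)
  cat(sprintf("Count distribution on 0..%d (tail mass %.3g), truncated mean %.4g\n",
              x$n_max, x$tail_mass, m))
  invisible(x)
}

#' Empirical count distribution from simulated samples
#'
#' @param counts Integer vector of count samples.
#' @param n_max Support bound (default: observed maximum).
#' @return An `sb_count_distribution` of the empirical frequencies.
#' @export
empirical_counts <- function(counts, n_max = max(counts)) {
  tab <- tabulate(pmin(counts, n_max) + 1L, nbins = n_max + 1L)
  count_distribution(tab / length(counts), tail_mass = 0)
}

#' Write / read a count distribution as two-column CSV
#'
#' @param cd An `sb_count_distribution`.
#' @param path CSV path; columns are `n` and `probability`.
#' @return `write_count_distribution` returns `path` invisibly;
#'   `read_count_distribution` returns the `sb_count_distribution`.
#' @export
write_count_distribution <- function(cd, path) {
  utils::write.csv(data.frame(n = 0:cd$n_max, probability = cd$pmf),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_distribution
#' @export
read_count_distribution <- function(path) {
  df <- utils::read.csv(path)
  count_distribution(df$probability, tail_mass = max(0, 1 - sum(df$probability)))
}
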