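#' Simulation configuration
#'
#' Controls the particle-based stochastic simulator. Defaults follow the
#' timescales of the model: the time step resolves both degradation and
#' diffusion across the domain (`dt = min(1/(100 gamma), R^2/(1000 D))`,
#' further reduced for Robin boundaries so that the per-contact absorption
#' probability `kappa * sqrt(pi dt / D)` stays near 0.1); burn-in covers
#' ten multiples of the slowest relaxation time `max(1/gamma, R^2/D,
#' 1/(alpha+beta))`; retained snapshots are spaced three multiples of
#' `max(1/gamma, 1/(alpha+beta))` apart so successive samples are close to
#' decorrelated.
#'
#' @param dt Diffusion time step (`NULL` = automatic per cell).
#' @param t_burnin Relaxation time before sampling (`NULL` = automatic).
#' @param n_samples Number of steady-state snapshots per cell.
#' @param sample_spacing Time between retained snapshots (`NULL` = automatic).
#' @param seed Optional RNG seed applied before simulating.
#' @param max_particles Safety cap on the live particle count.
#' @return An object of class `sb_sim_config`.
#' @export
sim_config <- function(dt = NULL, t_burnin = NULL, n_samples = 1L,
                       sample_spacing = NULL, seed = NULL,
                       max_particles = 100000L) {
  if (!is.null(dt) && dt <= 0) stop("dt must be > 0", call. = FALSE)
  structure(list(dt = dt, t_burnin = t_burnin, n_samples = as.integer(n_samples),
                 sample_spacing = sample_spacing, seed = seed,
                 max_particles = as.integer(max_particles)),
            class = "sb_sim_config")
}

resolve_cfg_1d <- function(cfg, p, R) {
  dt <- cfg$dt
  if (is.null(dt)) {
    dt <- min(1 / (100 * p$gamma), R^2 / (1000 * p$D))
    if (is.finite(p$kappa) && p$kappa > 0) {
      dt <- min(dt, p$D * (0.1 / p$kappa)^2 / pi)
    }
  }
  if (is.finite(p$kappa) && p$kappa > 0) {
    pab <- p$kappa * sqrt(pi * dt / p$D)
    if (pab > 1) {
      stop(sprintf("Robin absorption probability %.3g > 1 at dt = %g; use a smaller dt",
                   pab, dt), call. = FALSE)
    }
  }
  burnin <- cfg$t_burnin
  if (is.null(burnin)) burnin <- 10 * max(1 / p$gamma, R^2 / p$D, 1 / p$omega)
  spacing <- cfg$sample_spacing
  if (is.null(spacing)) spacing <- 3 * max(1 / p$gamma, 1 / p$omega)
  list(dt = dt, burnin = burnin, spacing = spacing)
}

#' Exact simulation of the telegraph promoter
#'
#' Event-driven simulation of the two-state promoter: exponential holding
#' times with rate `beta` in the on state and `alpha` in the off state,
#' initial state drawn from the stationary law (on with probability
#' `rho = alpha/(alpha+beta)`).
#'
#' @param alpha,beta Switching rates, both > 0.
#' @param t_end Path length (time units).
#' @param seed Optional RNG seed.
#' @return A data frame with columns `time` (switch epochs, starting at 0)
#'   and `state` (1 = on, 0 = off), giving the piecewise-constant path: the
#'   state holds from each `time` to the next row's `time`, the final row
#'   holding through `t_end`.
#' @export
simulate_telegraph <- function(alpha, beta, t_end, seed = NULL) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rho <- alpha / (alpha + beta)
  state0 <- as.integer(stats::runif(1) < rho)
  times <- 0; states <- state0
  t <- 0; s <- state0
  ## batch-draw holding times, extending until t_end is passed
  repeat {
    n_guess <- max(16L, ceiling(1.5 * (t_end - t) * (alpha + beta)))
    ## exit rates alternate starting from the current state's exit rate
    rates <- ifelse(((seq_len(n_guess) - 1) + (1 - s)) %% 2 == 0, beta, alpha)
    hold <- stats::rexp(n_guess) / rates
    ct <- t + cumsum(hold)
    keep <- which(ct < t_end)
    if (length(keep)) {
      times <- c(times, ct[keep])
      states <- c(states, (s + seq_along(keep)) %% 2)
      t <- ct[keep[length(keep)]]
      s <- states[length(states)]
    }
    if (length(keep) < n_guess) break
  }
  data.frame(time = times, state = as.integer(states))
}

#' Reference 1D boundary update (single step)
#'
#' The boundary rule applied by the simulator to one Euler-Maruyama step,
#' exposed at the R level for inspection and testing: absorbing boundaries
#' remove crossing particles and apply the Brownian-bridge first-passage
#' correction `exp(-(R - x_old)(R - x_new)/(D dt))` for unobserved
#' crossings; Robin boundaries reflect at the walls but export with
#' probability `kappa * sqrt(pi dt / D)` per boundary contact (the
#' partially reflected Brownian motion rule); reflecting boundaries mirror.
#'
#' @param x_old,x_new Pre- and post-step positions (`x_old` inside the domain).
#' @param dom A [domain_1d()].
#' @param p An [model_params()] object (supplies `D` and `kappa`).
#' @param dt Step length used for the proposal.
#' @return The updated position, or `NA_real_` if the particle was exported.
#' @export
apply_boundary_1d <- function(x_old, x_new, dom, p, dt) {
  R <- dom$R; D <- p$D
  b <- boundary_type(p$kappa)
  if (b == "absorbing") {
    if (abs(x_new) >= R) return(NA_real_)
    if (stats::runif(1) < exp(-(R - x_old) * (R - x_new) / (D * dt))) return(NA_real_)
    if (stats::runif(1) < exp(-(x_old + R) * (x_new + R) / (D * dt))) return(NA_real_)
    return(x_new)
  }
  p_abs <- if (b == "robin") p$kappa * sqrt(pi * dt / D) else 0
  if (p_abs > 1) stop("absorption probability > 1; use a smaller dt", call. = FALSE)
  guard <- 0
  while (abs(x_new) > R && guard < 64) {
    if (b == "robin" && stats::runif(1) < p_abs) return(NA_real_)
    x_new <- if (x_new > R) 2 * R - x_new else -2 * R - x_new
    guard <- guard + 1
  }
  x_new
}

#' Simulate steady-state snapshots of a single cell
#'
#' Hybrid particle simulation of the full spatial model: the promoter
#' evolves by exact event-driven switching; births form an inhomogeneous
#' Poisson process along the promoter path, each newborn placed at the
#' gene site; particles diffuse by Euler-Maruyama steps, are thinned at
#' the degradation rate, and are exported at the boundary according to the
#' boundary type encoded in `kappa`. Snapshots are retained after burn-in
#' at the configured spacing and are approximately stationary draws.
#'
#' @param p An [model_params()] object.
#' @param dom A [domain_1d()] or [domain_2d()].
#' @param cfg A [sim_config()].
#' @return A list of [point_pattern()] objects, one per snapshot.
#' @seealso [simulate_counts()] for count samples without positions,
#'   [simulate_population()] for heterogeneous populations.
#' @export
simulate_cell <- function(p, dom, cfg = sim_config()) {
  p <- validate_params(p, dom)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (inherits(dom, "sb_domain_1d")) {
    rc <- resolve_cfg_1d(cfg, p, dom$R)
    raw <- .sim_cells_1d(p$lam, p$lam_off, p$alpha, p$beta, p$gamma, p$D,
                         if (is.finite(p$kappa)) p$kappa else 0,
                         boundary_code(p$kappa), dom$R, p$z,
                         rc$dt, rc$burnin, cfg$n_samples, rc$spacing,
                         TRUE, cfg$max_particles)[[1]]
    lapply(raw$positions, point_pattern, domain = dom, z = p$z)
  } else if (inherits(dom, "sb_domain_2d")) {
    raw <- sim_cell_2d_raw(p, dom, cfg, keep_positions = TRUE)
    lapply(raw$positions, point_pattern, domain = dom, z = p$z)
  } else {
    stop("unsupported domain for simulation", call. = FALSE)
  }
}

boundary_code <- function(kappa) {
  if (is.infinite(kappa)) 0L else if (kappa == 0) 2L else 1L
}

sim_cell_2d_raw <- function(p, dom, cfg, keep_positions = FALSE) {
  Dmax <- max(dom$D_grid)
  rmin <- min(sqrt(rowSums(dom$polygon^2)))
  dt <- cfg$dt
  if (is.null(dt)) dt <- min(1 / (100 * p$gamma), rmin^2 / (1000 * Dmax))
  burnin <- cfg$t_burnin
  if (is.null(burnin)) burnin <- 10 * max(1 / p$gamma, rmin^2 / min(dom$D_grid), 1 / p$omega)
  spacing <- cfg$sample_spacing
  if (is.null(spacing)) spacing <- 3 * max(1 / p$gamma, 1 / p$omega)
  .sim_cell_2d(p$lam, p$lam_off, p$alpha, p$beta, p$gamma,
               dom$polygon, dom$D_grid,
               dom$gx[1], dom$gy[1], dom$gx[2] - dom$gx[1], dom$gy[2] - dom$gy[1],
               p$z[1], p$z[2], 0.95 * rmin,
               dt, burnin, cfg$n_samples, spacing,
               keep_positions, cfg$max_particles)
}

#' Simulate steady-state count samples
#'
#' Convenience wrapper returning only the molecular counts of each
#' retained snapshot (positions discarded), used for count-distribution
#' studies where many samples are needed.
#'
#' @inheritParams simulate_cell
#' @return Integer vector of `cfg$n_samples` counts.
#' @export
simulate_counts <- function(p, dom, cfg = sim_config(n_samples = 1000L)) {
  p <- validate_params(p, dom)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (inherits(dom, "sb_domain_1d")) {
    rc <- resolve_cfg_1d(cfg, p, dom$R)
    raw <- .sim_cells_1d(p$lam, p$lam_off, p$alpha, p$beta, p$gamma, p$D,
                         if (is.finite(p$kappa)) p$kappa else 0,
                         boundary_code(p$kappa), dom$R, p$z,
                         rc$dt, rc$burnin, cfg$n_samples, rc$spacing,
                         FALSE, cfg$max_particles)[[1]]
    as.integer(raw$counts)
  } else {
    as.integer(sim_cell_2d_raw(p, dom, cfg, keep_positions = FALSE)$counts)
  }
}

#' Simulate a heterogeneous population of cells
#'
#' Simulates `M` independent cells sharing kinetic parameters but each with
#' its own geometry `(R_i, z_i)` supplied by `domain_sampler`; one
#' stationary snapshot is taken per cell, matching the design of a
#' snapshot-imaging experiment. Fully reproducible given a seed.
#'
#' @param p An [model_params()] object (its `z` field is overridden per cell).
#' @param domain_sampler Function `(m) -> data.frame(R, z)` drawing `m`
#'   per-cell geometries.
#' @param M Number of cells.
#' @param cfg A [sim_config()]; `n_samples` is forced to 1 per cell.
#' @return A list of `M` [point_pattern()] objects (each carries its own
#'   `domain_1d(R_i)` and `z_i`).
#' @export
simulate_population <- function(p, domain_sampler, M, cfg = sim_config()) {
  if (M == 0) return(list())
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  geo <- domain_sampler(M)
  stopifnot(is.data.frame(geo), all(c("R", "z") %in% names(geo)), nrow(geo) == M)
  if (any(abs(geo$z) >= geo$R)) stop("sampled gene site outside its domain", call. = FALSE)
  rc <- resolve_cfg_1d(cfg, p, max(geo$R))
  ## one shared dt (smallest over cells) keeps the Robin clamp safe
  rc$dt <- min(rc$dt, min(1 / (100 * p$gamma), min(geo$R)^2 / (1000 * p$D)))
  raw <- .sim_cells_1d(p$lam, p$lam_off, p$alpha, p$beta, p$gamma, p$D,
                       if (is.finite(p$kappa)) p$kappa else 0,
                       boundary_code(p$kappa), geo$R, geo$z,
                       rc$dt, rc$burnin, 1L, rc$spacing,
                       TRUE, cfg$max_particles)
  lapply(seq_len(M), function(i) {
    point_pattern(raw[[i]]$positions[[1]], domain_1d(geo$R[i]), geo$z[i])
  })
}

#' Write / read point patterns as CSV
#'
#' Patterns are written as a long table (columns `cell_id`, `x`, and `y`
#' in 2D) with a side-car geometry table (`cell_id`, `R`, `z`). Cells with
#' zero transcripts appear only in the geometry table.
#'
#' @param patterns List of 1D [point_pattern()] objects.
#' @param path CSV path for positions; the geometry table is written to
#'   `sub("\\.csv$", "_geometry.csv", path)`.
#' @return `write_patterns_csv` returns `path` invisibly;
#'   `read_patterns_csv` returns the list of patterns.
#' @export
write_patterns_csv <- function(patterns, path) {
  pos <- do.call(rbind, lapply(seq_along(patterns), function(i) {
    pp <- patterns[[i]]
    if (pp$n == 0) return(NULL)
    data.frame(cell_id = i, x = pp$positions)
  }))
  if (is.null(pos)) pos <- data.frame(cell_id = integer(), x = numeric())
  geo <- data.frame(cell_id = seq_along(patterns),
                    R = vapply(patterns, function(pp) pp$domain$R, numeric(1)),
                    z = vapply(patterns, function(pp) pp$z, numeric(1)))
  utils::write.csv(pos, path, row.names = FALSE)
  utils::write.csv(geo, sub("\\.csv$", "_geometry.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_patterns_csv
#' @export
read_patterns_csv <- function(path) {
  pos <- utils::read.csv(path)
  geo <- utils::read.csv(sub("\\.csv$", "_geometry.csv", path))
  lapply(seq_len(nrow(geo)), function(i) {
    xs <- pos$x[pos$cell_id == geo$cell_id[i]]
    point_pattern(xs, domain_1d(geo$R[i]), geo$z[i])
  })
}
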