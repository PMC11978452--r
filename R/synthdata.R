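#' Specification of a heterogeneous synthetic cell population
#'
#' Declares the generative model for a population of cells sharing kinetic
#' parameters but with per-cell geometry: nuclear half-widths `R_i` drawn
#' from `R_dist` and gene sites `z_i` drawn, relative to the cell's own
#' `R_i`, from `z_dist`. Distribution specs are declarative
#' (`list(family, par1, par2)` with family `"uniform"` or `"fixed"`), so
#' alternative heterogeneity models are testable without code changes.
#'
#' Defaults emulate a snapshot-imaging experiment on a heterogeneous
#' population: `R_i ~ Uniform(0.8, 1.2)` (micrometre-scale nuclei),
#' `z_i | R_i ~ Uniform(-0.8 R_i, 0.8 R_i)` (gene sites anywhere but the
#' immediate nuclear periphery), shared kinetics
#' `theta = (lam = 20, gamma = 1, alpha = 1, beta = 2, kappa = 5)` and
#' known diffusivity `D = 1`.
#'
#' @param M Number of cells, >= 1.
#' @param theta_true Named vector of shared kinetics
#'   (`lam`, `gamma`, `alpha`, `beta`, `kappa`).
#' @param D Known diffusivity.
#' @param R_dist Distribution spec for `R_i`.
#' @param z_dist Distribution spec for `z_i / R_i` (must stay inside
#'   `(-1, 1)`).
#' @param seed RNG seed; the whole dataset is a pure function of the spec.
#' @return An object of class `sb_population_spec`.
#' @export
population_spec <- function(M = 500L,
                            theta_true = c(lam = 20, gamma = 1, alpha = 1,
                                           beta = 2, kappa = 5),
                            D = 1,
                            R_dist = list("uniform", 0.8, 1.2),
                            z_dist = list("uniform", -0.8, 0.8),
                            seed = 1L) {
  if (M < 1) stop("M must be >= 1", call. = FALSE)
  theta_true <- theta_true[theta_names]
  if (anyNA(theta_true)) stop("theta_true must name lam, gamma, alpha, beta, kappa",
                              call. = FALSE)
  if (z_dist[[1]] == "uniform" && (z_dist[[2]] <= -1 || z_dist[[3]] >= 1)) {
    stop("relative gene-site distribution must stay strictly inside (-1, 1)",
         call. = FALSE)
  }
  structure(list(M = as.integer(M), theta_true = theta_true, D = D,
                 R_dist = R_dist, z_dist = z_dist, seed = as.integer(seed)),
            class = "sb_population_spec")
}

draw_dist <- function(spec, n) {
  switch(spec[[1]],
         uniform = stats::runif(n, spec[[2]], spec[[3]]),
         fixed = rep(spec[[2]], n),
         stop("unknown distribution family '", spec[[1]], "'", call. = FALSE))
}

#' Generate a heterogeneous synthetic population
#'
#' Draws per-cell geometries from the spec and simulates one stationary
#' snapshot per cell with the particle simulator. The returned manifest
#' records everything needed to regenerate the dataset bitwise: the true
#' kinetics, the diffusivity, the per-cell geometry, the distribution
#' specs, the seed and the package version.
#'
#' @param spec A [population_spec()].
#' @param cfg Optional [sim_config()] overriding simulator resolution.
#' @return A list with `patterns` (list of [point_pattern()]),
#'   `geometry` (data frame `cell_id`, `R`, `z`) and `manifest` (list).
#' @seealso [write_manifest_json()]
#' @export
generate_population <- function(spec, cfg = sim_config()) {
  stopifnot(inherits(spec, "sb_population_spec"))
  set.seed(spec$seed)
  geo <- data.frame(R = draw_dist(spec$R_dist, spec$M))
  geo$z <- draw_dist(spec$z_dist, spec$M) * geo$R
  p <- theta_to_params(spec$theta_true, spec$D, z = 0)
  cfg$seed <- NULL  # RNG already seeded above; keep one stream
  patterns <- simulate_population(p, function(m) geo, spec$M, cfg)
  manifest <- list(theta_true = as.list(spec$theta_true), D = spec$D,
                   M = spec$M,
                   R_dist = spec$R_dist, z_dist = spec$z_dist,
                   seed = spec$seed,
                   package_version = as.character(utils::packageVersion("spatburst")))
  list(patterns = patterns,
       geometry = cbind(cell_id = seq_len(spec$M), geo),
       manifest = manifest)
}

#' @rdname generate_population
#' @param pop A [generate_population()] result.
#' @param path JSON path for the manifest.
#' @export
write_manifest_json <- function(pop, path) {
  jsonlite::write_json(pop$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Random star-convex 2D nucleus with heterogeneous diffusivity
#'
#' Generates an irregular nuclear outline
#' `r(theta) = R0 (1 + sum_k a_k cos(k theta + phi_k))` with small random
#' harmonic amplitudes, plus a smooth random diffusivity field (a constant
#' background plus Gaussian bumps) clamped to `D_range`. Self-intersecting
#' outlines (possible at large roughness) are regenerated up to a retry
#' cap. The polygon is centred so the centroid sits at the origin, which
#' is therefore always strictly interior for these star-convex shapes.
#'
#' @param seed RNG seed.
#' @param R0 Mean radius.
#' @param roughness Scale of the harmonic amplitudes (`0` gives a circle).
#' @param D_range Length-2 positive range for the diffusivity field.
#' @param n_vertices Polygon resolution.
#' @param n_bumps Number of Gaussian bumps in the diffusivity field.
#' @param grid_n Grid resolution of the stored diffusivity field.
#' @return A [domain_2d()] object.
#' @export
generate_domain2d <- function(seed = 1L, R0 = 1, roughness = 0.12,
                              D_range = c(0.4, 1.6), n_vertices = 96L,
                              n_bumps = 4L, grid_n = 64L) {
  set.seed(seed)
  for (try in 1:20) {
    th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    r <- rep(R0, n_vertices)
    if (roughness > 0) {
      for (k in 2:5) {
        ak <- stats::rnorm(1, 0, roughness / k)
        ph <- stats::runif(1, 0, 2 * pi)
        r <- r + R0 * ak * cos(k * th + ph)
      }
    }
    if (min(r) < 0.2 * R0) next
    poly <- cbind(r * cos(th), r * sin(th))
    poly <- sweep(poly, 2, colMeans(poly))  # centroid (vertex mean) at origin
    if (!polygon_self_intersects(poly)) {
      ## smooth random diffusivity: background + Gaussian bumps, clamped
      ctr <- matrix(stats::runif(2 * n_bumps, -0.6 * R0, 0.6 * R0), ncol = 2)
      amp <- stats::runif(n_bumps, -1, 1) * diff(D_range) / 2
      wid <- stats::runif(n_bumps, 0.25, 0.5) * R0
      base <- mean(D_range)
      D_field <- function(x, y) {
        v <- base + 0 * x
        for (b in seq_len(n_bumps)) {
          v <- v + amp[b] * exp(-((x - ctr[b, 1])^2 + (y - ctr[b, 2])^2) /
                                  (2 * wid[b]^2))
        }
        pmin(pmax(v, D_range[1]), D_range[2])
      }
      return(domain_2d(poly, D_field, grid_n = grid_n))
    }
  }
  stop("failed to generate a simple polygon within the retry cap; lower roughness",
       call. = FALSE)
}

#' Parameter-sweep summary table
#'
#' Reproduces the standard one-at-a-time parameter sweeps (gene site `z`,
#' diffusivity `D`, degradation `gamma`, switching rate `alpha`, export
#' rate `kappa`) around a base parameter set, emitting for each row the
#' retention factor, analytic mean, series and Poisson-beta variances and
#' both Fano factors, optionally alongside stochastic-simulation estimates
#' with standard errors.
#'
#' @param base An [model_params()] object (absorbing boundary for the
#'   series-variance column; the `kappa` sweep switches to Robin).
#' @param dom A [domain_1d()].
#' @param sweeps Named list of parameter value vectors, any of `z`, `D`,
#'   `gamma`, `alpha`, `kappa`.
#' @param simulate If `TRUE`, append Monte-Carlo estimates.
#' @param n_samples Snapshots per simulated row.
#' @param seed RNG seed for the simulated columns.
#' @return A tidy data frame, one row per (parameter, value).
#' @export
sweep_figures <- function(base, dom,
                          sweeps = list(z = seq(0, 0.9 * dom$R, length.out = 5),
                                        D = c(0.25, 0.5, 1, 2, 4),
                                        gamma = c(0.25, 0.5, 1, 2, 4),
                                        alpha = c(0.25, 0.5, 1, 2, 4),
                                        kappa = c(0.25, 1, 4, 16, 64)),
                          simulate = FALSE, n_samples = 2000L, seed = 1L) {
  rows <- list()
  if (!is.null(seed)) set.seed(seed)
  for (pname in names(sweeps)) {
    for (v in sweeps[[pname]]) {
      p <- base
      if (pname == "z") p$z <- v else p[[pname]] <- v
      p <- model_params(lam = p$lam, alpha = p$alpha, beta = p$beta,
                        gamma = p$gamma, D = p$D, z = p$z, kappa = p$kappa,
                        lam_off = p$lam_off)
      S <- scale_factor_Skappa(p, dom)
      mn <- mean_count(p, dom)
      var_pb <- poisson_beta_variance(spatial_rescale(p, S))
      var_series <- if (p$absorbing)
        mn + integrated_intensity_variance(p, dom)$value else NA_real_
      row <- data.frame(parameter = pname, value = v, S = S, mean = mn,
                        var_series = var_series, var_pb = var_pb,
                        fano_spat = fano_spatial(p, dom),
                        fano_nonspat = fano_nonspatial(p))
      if (simulate) {
        cts <- simulate_counts(p, dom, sim_config(n_samples = n_samples))
        row$sim_mean <- mean(cts)
        row$sim_mean_se <- stats::sd(cts) / sqrt(length(cts))
        row$sim_var <- stats::var(cts)
        m2 <- stats::var(cts); m4 <- mean((cts - mean(cts))^4)
        row$sim_var_se <- sqrt(max(m4 - m2^2, 0) / length(cts))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
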