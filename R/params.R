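#' Kinetic and transport parameters of the spatial telegraph model
#'
#' Bundles the kinetic and transport parameters of the nuclear mRNA model:
#' a promoter switching between an "on" transcription rate `lam` and an
#' "off" rate `lam_off` (off-to-on rate `alpha`, on-to-off rate `beta`),
#' transcripts appearing at the gene site `z`, diffusing with diffusivity
#' `D`, degrading at rate `gamma`, and being exported at the nuclear
#' boundary at a rate controlled by `kappa`.
#'
#' Units are unconstrained but must be mutually consistent; throughout the
#' documentation lengths are quoted in micrometres and times in seconds,
#' the scales reported for nuclear mRNA diffusion.
#'
#' `kappa = Inf` is stored as a symbolic "absorbing" flag rather than a
#' floating-point infinity: downstream formulas then dispatch to the
#' dedicated absorbing-boundary expressions instead of evaluating the
#' Robin-boundary expressions at a huge `kappa`, which is numerically
#' unstable. `kappa = 0` is a purely reflecting (no-export) boundary.
#'
#' @param lam On-state transcription rate (molecules per unit time), > 0.
#' @param alpha Off-to-on promoter switching rate, >= 0.
#' @param beta On-to-off promoter switching rate, >= 0.
#' @param gamma Degradation rate, > 0.
#' @param D Diffusivity (length^2 per unit time), > 0.
#' @param z Gene site location: a scalar in 1D, an `(x, y)` pair in 2D.
#' @param kappa Export rate parameter in `[0, Inf]`; `Inf` means a fully
#'   absorbing boundary, `0` a reflecting one.
#' @param lam_off Off-state transcription rate, >= 0 (default 0).
#'
#' @return An object of class `sb_params`: a list with the supplied fields
#'   plus the derived on-fraction `rho = alpha/(alpha+beta)`, the switching
#'   timescale `omega = alpha+beta`, and the logical `absorbing` flag.
#'   The field-level naming follows the field's convention; the fraction of
#'   time the promoter is on is called `rho` throughout (some authors write
#'   `p` for the same quantity).
#' @seealso [validate_params()], [effective_production()], [domain_1d()]
#' @examples
#' p <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1, z = 0)
#' p$rho  # 0.5
#' @export
model_params <- function(lam, alpha, beta, gamma, D, z,
                         kappa = Inf, lam_off = 0) {
  for (nm in c("lam", "alpha", "beta", "gamma", "D", "kappa", "lam_off")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop("parameter '", nm, "' must be a single non-missing number", call. = FALSE)
    }
    if (v < 0) stop("parameter '", nm, "' must be non-negative", call. = FALSE)
  }
  if (D <= 0) stop("parameter 'D' must be > 0", call. = FALSE)
  if (gamma <= 0) stop("parameter 'gamma' must be > 0", call. = FALSE)
  if (alpha + beta <= 0) {
    stop("promoter never switches; rho undefined (alpha + beta must be > 0)",
         call. = FALSE)
  }
  if (!is.numeric(z) || !length(z) %in% c(1L, 2L) || anyNA(z)) {
    stop("parameter 'z' must be a numeric scalar (1D) or length-2 vector (2D)",
         call. = FALSE)
  }
  structure(list(
    lam = lam, lam_off = lam_off, alpha = alpha, beta = beta,
    gamma = gamma, D = D, kappa = kappa, z = z,
    absorbing = is.infinite(kappa),
    rho = alpha / (alpha + beta),
    omega = alpha + beta
  ), class = "sb_params")
}

#' @export
print.sb_params <- function(x, ...) {
  cat("Spatial telegraph model parameters\n")
  cat(sprintf("  lam = %g, lam_off = %g, alpha = %g, beta = %g\n",
              x$lam, x$lam_off, x$alpha, x$beta))
  cat(sprintf("  gamma = %g, D = %g, kappa = %s, z = %s\n",
              x$gamma, x$D,
              if (x$absorbing) "Inf (absorbing)" else format(x$kappa),
              paste(format(x$z), collapse = ", ")))
  cat(sprintf("  derived: rho = %.4g, omega = %g\n", x$rho, x$omega))
  invisible(x)
}

#' Validate a parameter set against a domain
#'
#' Checks that the parameter set is internally consistent and that the gene
#' site lies strictly inside the domain. Returns the normalized parameter
#' set (absorbing flag resolved, derived `rho` and `omega` cached) with the
#' resolved boundary type attached.
#'
#' @param p An [model_params()] object (or a plain list with the same fields).
#' @param dom A [domain_1d()], [domain_strip()] or [domain_2d()] object.
#' @return The validated `sb_params` object, with attribute `boundary` set
#'   to one of `"absorbing"`, `"robin"`, `"reflecting"`.
#' @examples
#' p <- model_params(lam = 10, alpha = 1, beta = 1, gamma = 1, D = 1, z = 0)
#' validate_params(p, domain_1d(R = 1))
#' @export
validate_params <- function(p, dom) {
  if (!inherits(p, "sb_params")) {
    p <- do.call(model_params, p[c("lam", "alpha", "beta", "gamma", "D", "z",
                                   "kappa", "lam_off")[
      c("lam", "alpha", "beta", "gamma", "D", "z", "kappa", "lam_off") %in% names(p)]])
  }
  if (inherits(dom, "sb_domain_1d")) {
    if (length(p$z) != 1L) stop("1D domain requires scalar gene site z", call. = FALSE)
    if (abs(p$z) >= dom$R) stop("gene site outside domain", call. = FALSE)
  } else if (inherits(dom, "sb_domain_strip")) {
    if (length(p$z) != 1L) stop("strip domain requires scalar gene site z", call. = FALSE)
    if (abs(p$z) >= dom$R) stop("gene site outside domain", call. = FALSE)
  } else if (inherits(dom, "sb_domain_2d")) {
    if (length(p$z) != 2L) stop("2D domain requires length-2 gene site z", call. = FALSE)
    if (!in_polygon(p$z[1], p$z[2], dom$polygon)) {
      stop("gene site outside domain", call. = FALSE)
    }
  } else {
    stop("'dom' must be a spatburst domain object", call. = FALSE)
  }
  attr(p, "boundary") <- boundary_type(p$kappa)
  p
}

boundary_type <- function(kappa) {
  if (is.infinite(kappa)) "absorbing" else if (kappa == 0) "reflecting" else "robin"
}

#' Effective (promoter-averaged) production rate
#'
#' The mean transcription rate once promoter switching is averaged out:
#' `(alpha*lam + beta*lam_off) / (alpha + beta)`. With `lam_off = 0` this
#' reduces to `lam * rho`. It is the lumped rate at which the mean
#' intensity equation is sourced, and is invariant under simultaneous
#' scaling of `alpha` and `beta`.
#'
#' @param p An [model_params()] object.
#' @return The effective production rate (same units as `lam`).
#' @examples
#' effective_production(model_params(lam = 10, alpha = 1, beta = 1,
#'                                   gamma = 1, D = 1, z = 0))  # 5
#' @export
effective_production <- function(p) {
  (p$alpha * p$lam + p$beta * p$lam_off) / (p$alpha + p$beta)
}

require_lam_off_zero <- function(p, what) {
  if (p$lam_off != 0) {
    stop(what, " is implemented for lam_off = 0 only; a nonzero basal rate ",
         "is supported in the mean layer but not in the variance/",
         "count-distribution layer", call. = FALSE)
  }
  invisible(p)
}

#' Read and write parameter configuration files
#'
#' Parameter sets (plus the 1D domain half-width `R`) serialize to a flat
#' key-value file with keys exactly `lam`, `lam_off`, `alpha`, `beta`,
#' `gamma`, `D`, `kappa`, `z`, `R`. YAML and JSON dialects are supported
#' (chosen from the file extension). `kappa = Inf` round-trips as the YAML
#' `.inf` / JSON string `"Inf"`.
#'
#' @param p An [model_params()] object.
#' @param R Domain half-width to record alongside the kinetics.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_params_config` returns `path` invisibly;
#'   `read_params_config` returns a list with elements `params`
#'   (an `sb_params`) and `domain` (a [domain_1d()] when `R` is present,
#'   otherwise `NULL`).
#' @export
write_params_config <- function(p, path, R = NULL) {
  kv <- list(lam = p$lam, lam_off = p$lam_off, alpha = p$alpha, beta = p$beta,
             gamma = p$gamma, D = p$D,
             kappa = if (is.infinite(p$kappa)) "Inf" else p$kappa,
             z = p$z)
  if (!is.null(R)) kv$R <- R
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(kv, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(kv, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("config path must end in .yaml, .yml or .json", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  kv <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config path must end in .yaml, .yml or .json", call. = FALSE)
  }
  kap <- kv$kappa
  if (is.character(kap)) kap <- if (toupper(kap) %in% c("INF", ".INF", "ABSORBING")) Inf else as.numeric(kap)
  if (is.null(kap)) kap <- Inf
  p <- model_params(lam = kv$lam, alpha = kv$alpha, beta = kv$beta,
                    gamma = kv$gamma, D = kv$D, z = unlist(kv$z),
                    kappa = kap,
                    lam_off = if (is.null(kv$lam_off)) 0 else kv$lam_off)
  dom <- if (!is.null(kv$R)) domain_1d(R = kv$R) else NULL
  list(params = p, domain = dom)
}
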