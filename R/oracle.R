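# Synthetic density oracle
#
# Stands in for the condensed-phase MD estimate of the bulk density.  The
# reference closed form is documented here, versioned with the package, and
# treated as ground truth by every downstream component:
#
#   v(p)      = 8 sigma_C^3 + 18 sigma_H^3                (molecular-volume proxy, nm^3)
#   smooth(p) = b + A / (1 + exp(s * (v(p) - v0) / v0))   (monotone sigmoid in v)
#   rugged(p) = a_r * (eps_C / eps_ref) *
#               sin(2 pi sigma_H / lambda_sigma) * sin(2 pi eps_C / lambda_eps)
#   rho(p)    = clamp(smooth + rugged + noise, 0, cap),   noise ~ N(0, noise_sd^2)
#
# With the defaults b = 100, A = 1200 the smooth component ranges over
# roughly (100, 1300) kg/m^3 and equals the 700 kg/m^3 target exactly on
# the level set v(p) = v0, which crosses the interior of the default
# feasible box.  The rugged term creates alternating
# above/below-target bands in the (sigma_H, eps_C) plane whose amplitude
# grows with eps_C, mimicking the observed ruggedness of the simulated
# landscape; the sigma_C-sigma_H coupling stays smooth.  With the
# configured failure probability a pseudo-simulation "fails" and the record
# is marked invalid with an implausible density (0 or 1.25 * cap).

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic per-point stream seed below 2^31
derive_seed <- function(master, index) {
  as.integer((as.double(master) %% 2147483563 * 69069 +
                as.double(index) * 1234567) %% 2147483563) + 1L
}

#' Configure the synthetic density oracle
#'
#' @param target_density nominal experimental density target, kg/m^3.
#' @param smooth_offset baseline density of the smooth response, kg/m^3.
#' @param smooth_amplitude amplitude of the smooth response above the
#'   baseline, kg/m^3.
#' @param smooth_v0 centre of the sigmoid on the molecular-volume proxy
#'   scale, nm^3; the smooth response equals `smooth_amplitude / 2` there.
#' @param smooth_steepness dimensionless steepness of the sigmoid.
#' @param rugged_amplitude amplitude scale of the rugged term, kg/m^3
#'   (0 switches ruggedness off).
#' @param rugged_wavelength_sigma,rugged_wavelength_eps wavelengths of the
#'   sinusoids in `sigma_H` (nm) and `eps_C` (kJ/mol).
#' @param noise_sd standard deviation of the zero-mean Gaussian noise,
#'   kg/m^3.
#' @param failure_prob probability in \[0, 1\] that a pseudo-simulation
#'   fails and yields an invalid record.
#' @param cap upper clamp for plausible densities, kg/m^3.
#' @param seed master seed from which per-point streams are derived.
#' @return An object of class `oracle_config`.
#' @export
oracle_config <- function(target_density = 700,
                          smooth_offset = 100,
                          smooth_amplitude = 1200,
                          smooth_v0 = 0.6025,
                          smooth_steepness = 6,
                          rugged_amplitude = 60,
                          rugged_wavelength_sigma = 0.037,
                          rugged_wavelength_eps = 0.25,
                          noise_sd = 5,
                          failure_prob = 0.05,
                          cap = 2000,
                          seed = 1L) {
  cfg <- list(target_density = target_density,
              smooth_offset = smooth_offset,
              smooth_amplitude = smooth_amplitude,
              smooth_v0 = smooth_v0,
              smooth_steepness = smooth_steepness,
              rugged_amplitude = rugged_amplitude,
              rugged_wavelength_sigma = rugged_wavelength_sigma,
              rugged_wavelength_eps = rugged_wavelength_eps,
              noise_sd = noise_sd,
              failure_prob = failure_prob,
              cap = cap,
              seed = as.integer(seed),
              eps_ref = 1.15)
  stopifnot(cfg$smooth_amplitude >= 0, cfg$rugged_amplitude >= 0,
            cfg$rugged_wavelength_sigma > 0, cfg$rugged_wavelength_eps > 0,
            cfg$noise_sd >= 0, cfg$failure_prob >= 0, cfg$failure_prob <= 1,
            cfg$cap > 0)
  class(cfg) <- "oracle_config"
  cfg
}

#' Deterministic components of the oracle response
#'
#' Exposes the molecular-volume proxy and the smooth and rugged parts of
#' the reference closed form, without noise, clamping or failures.
#'
#' @param p a parameter point (see [lj_params()]).
#' @param cfg an [oracle_config()].
#' @return A list with elements `volume`, `smooth`, `rugged` and their sum
#'   `mean_density`.
#' @export
oracle_components <- function(p, cfg = oracle_config()) {
  v <- as_param_vector(p, c("sigma_C", "sigma_H", "eps_C", "eps_H"))
  vol <- 8 * v[1]^3 + 18 * v[2]^3
  smooth <- cfg$smooth_offset + cfg$smooth_amplitude /
    (1 + exp(cfg$smooth_steepness * (vol - cfg$smooth_v0) / cfg$smooth_v0))
  rugged <- cfg$rugged_amplitude * (v[3] / cfg$eps_ref) *
    sin(2 * pi * v[2] / cfg$rugged_wavelength_sigma) *
    sin(2 * pi * v[3] / cfg$rugged_wavelength_eps)
  list(volume = unname(vol), smooth = unname(smooth),
       rugged = unname(rugged), mean_density = unname(smooth + rugged))
}

#' Evaluate the density oracle at one parameter point
#'
#' @inheritParams oracle_components
#' @param draw_seed integer seed for this single draw (noise and failure).
#' @return A one-row data frame with columns `sigma_C`, `sigma_H`, `eps_C`,
#'   `eps_H`, `density` (kg/m^3) and `valid` (logical); invalid records
#'   carry an implausible density.
#' @export
oracle_density <- function(p, cfg = oracle_config(), draw_seed = cfg$seed) {
  v <- as_param_vector(p, c("sigma_C", "sigma_H", "eps_C", "eps_H"))
  if (!all(is.finite(v)) || any(v <= 0))
    stop("parameter point must be finite and strictly positive", call. = FALSE)
  comp <- oracle_components(v, cfg)
  draws <- with_seed(draw_seed, {
    u_fail <- stats::runif(1)
    noise <- stats::rnorm(1, 0, cfg$noise_sd)
    u_kind <- stats::runif(1)
    list(u_fail = u_fail, noise = noise, u_kind = u_kind)
  })
  if (draws$u_fail < cfg$failure_prob) {
    density <- if (draws$u_kind < 0.5) 0 else 1.25 * cfg$cap
    valid <- FALSE
  } else {
    density <- min(max(comp$mean_density + draws$noise, 0), cfg$cap)
    valid <- TRUE
  }
  data.frame(sigma_C = v[1], sigma_H = v[2], eps_C = v[3], eps_H = v[4],
             density = density, valid = valid)
}

#' Evaluate the oracle over a sample set
#'
#' One record per point; the per-point random stream is derived
#' deterministically from the master seed of `cfg` and the point index, so
#' the dataset does not depend on evaluation order.
#'
#' @param points data frame of parameter points (from [make_grid()] or
#'   [make_sobol()], or any data frame with the four parameter columns).
#' @param cfg an [oracle_config()].
#' @param name dataset label (e.g. `"Sobol1"`).
#' @return A `density_dataset`: a data frame with the parameter columns
#'   plus `density` and `valid`, labelled with attribute `"name"`.
#' @export
evaluate_samples <- function(points, cfg = oracle_config(), name = "dataset") {
  if (!is.data.frame(points) || nrow(points) == 0L)
    stop("'points' must be a nonempty data frame of parameter sets",
         call. = FALSE)
  recs <- lapply(seq_len(nrow(points)), function(i)
    oracle_density(points[i, , drop = FALSE], cfg,
                   draw_seed = derive_seed(cfg$seed, i)))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  density_dataset(out, name = name)
}

#' Construct a density dataset
#'
#' @param df data frame with columns `sigma_C`, `sigma_H`, `eps_C`,
#'   `eps_H`, `density` and `valid`.
#' @param name dataset label.
#' @return The data frame with class `density_dataset` and attribute
#'   `"name"`.
#' @export
density_dataset <- function(df, name = "dataset") {
  needed <- c("sigma_C", "sigma_H", "eps_C", "eps_H", "density", "valid")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("density dataset is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[, needed]
  df$valid <- as.logical(df$valid)
  if (any(!is.finite(df$density)))
    stop("densities must be finite", call. = FALSE)
  attr(df, "name") <- name
  class(df) <- c("density_dataset", "data.frame")
  df
}

#' @export
print.density_dataset <- function(x, n = 6L, ...) {
  cat(sprintf("<density_dataset> '%s': %d records (%d valid)\n",
              dataset_name(x), nrow(x), sum(x$valid)))
  print.data.frame(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more record(s)\n", sep = "")
  invisible(x)
}

#' Dataset label accessor
#' @param ds a `density_dataset`.
#' @return The label attached by [density_dataset()].
#' @export
dataset_name <- function(ds) {
  nm <- attr(ds, "name", exact = TRUE)
  if (is.null(nm)) "dataset" else nm
}

#' Remove invalid and implausible records
#'
#' Keeps exactly the records flagged valid whose density lies in
#' `(plaus_low, plaus_high]`; order is preserved.  The default window of
#' (0, 1500\] kg/m^3 brackets the range over which the pseudo-simulated
#' densities plausibly vary.
#'
#' @param ds a `density_dataset`.
#' @param plaus_low,plaus_high plausibility window bounds, kg/m^3
#'   (`plaus_low < plaus_high`).
#' @return The filtered `density_dataset`; the number of dropped records is
#'   attached as attribute `"n_removed"`.
#' @export
preprocess_dataset <- function(ds, plaus_low = 0, plaus_high = 1500) {
  stopifnot(inherits(ds, "density_dataset"), plaus_low < plaus_high)
  keep <- ds$valid & ds$density > plaus_low & ds$density <= plaus_high
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "name") <- dataset_name(ds)
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- class(ds)
  out
}
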