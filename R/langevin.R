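# Overdamped Langevin engine (R interface to the compiled integrator).
# Update rule: z <- z + (D/kBT) F_total(z) dt + sqrt(2 D dt) xi,
# with xi standard normal drawn from R's RNG stream, so set.seed()
# controls the trajectory bit-for-bit.

#' Langevin engine parameters
#'
#' @param temperature Temperature, Kelvin.
#' @param diffusion Diffusion coefficient D, A^2/ns.
#' @param timestep Integration timestep, ns.
#' @param seed Integer seed, or `NULL` to continue the current RNG stream
#'   (used for sequential seeding chains).
#' @param sample_interval Interval between retained samples, ns; must be a
#'   multiple of `timestep`.
#' @return A `langevin_params` object.
#' @export
langevin_params <- function(temperature = 310, diffusion = 0.5,
                            timestep = 1e-4, seed = NULL,
                            sample_interval = 1e-4) {
  stopifnot(temperature > 0, diffusion > 0, timestep > 0,
            sample_interval >= timestep)
  m <- sample_interval / timestep
  if (abs(m - round(m)) > 1e-8) {
    stop("`sample_interval` must be an integer multiple of `timestep`")
  }
  structure(list(temperature = temperature, diffusion = diffusion,
                 timestep = timestep, seed = seed,
                 sample_interval = sample_interval),
            class = "langevin_params")
}

# crude bound on the total stiffness (bias + maximum potential curvature)
max_curvature <- function(potential, n_grid = 1000, h = 1e-4) {
  zg <- seq(potential$domain[1], potential$domain[2], length.out = n_grid)
  u0 <- potential_energy(potential, zg)
  up <- potential_energy(potential, zg + h)
  um <- potential_energy(potential, zg - h)
  max((up - 2 * u0 + um) / h^2)
}

#' Check the Euler-Maruyama stability criterion
#'
#' Requires `timestep * (k_total / kBT) * D < 0.1`, where `k_total` is the
#' bias stiffness plus the maximum curvature of the system potential over
#' its domain. Raises a configuration error otherwise (rather than letting
#' the trajectory diverge silently).
#'
#' @param potential A `potential1d`.
#' @param bias_k Bias stiffness, kcal/mol/A^2.
#' @param params A `langevin_params`.
#' @return Invisibly, the stability number.
#' @export
check_stability <- function(potential, bias_k, params) {
  k_tot <- bias_k + max(0, max_curvature(potential))
  s <- params$timestep * (k_tot / kbt(params$temperature)) * params$diffusion
  if (s >= 0.1) {
    stop(sprintf(
      "unstable configuration: dt * (k_total/kBT) * D = %.3g >= 0.1; reduce the timestep",
      s))
  }
  invisible(s)
}

#' Simulate relaxation under a fixed potential and harmonic bias
#'
#' Runs the overdamped Euler-Maruyama integrator for `duration` ns and
#' returns the sampled positions. If `params$seed` is non-`NULL` the RNG is
#' seeded first; otherwise the current stream continues, which is how the
#' sequential-seeding chain of a pulling run is realised.
#'
#' @param potential A `potential1d`.
#' @param bias A `bias_potential` (use `bias_potential(0, 0)` for none).
#' @param z0 Initial position, Angstrom.
#' @param params A `langevin_params`.
#' @param duration Run length, ns; must be at least `sample_interval`.
#' @return A `sample_stream`: list with `samples` (data.frame `time`, `z`),
#'   `z_final`, and metadata (`bias`, `params`, `potential_label`).
#' @export
simulate_relaxation <- function(potential, bias, z0, params, duration) {
  stopifnot(inherits(potential, "potential1d"),
            inherits(bias, "bias_potential"),
            inherits(params, "langevin_params"))
  if (duration < params$sample_interval) {
    stop("`duration` must be at least one sample interval")
  }
  check_stability(potential, bias$k, params)
  if (!is.null(params$seed)) set.seed(params$seed)
  every <- as.integer(round(params$sample_interval / params$timestep))
  res <- simulate_cpp(potential$type_code, potential$par,
                      bias$k, bias$lambda_center, z0,
                      params$diffusion, kbt(params$temperature),
                      params$timestep, duration, every)
  structure(
    list(samples = data.frame(time = res$time, z = res$z),
         z_final = res$z_final,
         bias = bias, params = params,
         potential_label = potential$label),
    class = "sample_stream"
  )
}

#' @export
print.sample_stream <- function(x, ...) {
  cat("<sample_stream>", nrow(x$samples), "samples, potential:",
      x$potential_label, " bias: k =", x$bias$k,
      "lambda =", x$bias$lambda_center, "\n")
  invisible(x)
}
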