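# Step-wise pulling protocol: the lambda ladder, sequential seeding,
# relaxation at each step, and per-step bookkeeping of positions and work
# increments. Produces the archive all estimators consume.

#' Pulling schedule
#'
#' Defaults follow the canonical step-wise protocol: increments of 1.0 A,
#' 25 lambda values from 0 to 24 A, a sequential relaxation of
#' tau1 = 0.5 ns at each step followed by tau2 = 10 ns of further
#' relaxation, and a soft harmonic bias of k = 0.6 kcal/mol/A^2.
#'
#' @param lambda_start First bias center, Angstrom.
#' @param delta_lambda Increment magnitude, Angstrom (> 0).
#' @param n_steps Number of lambda values (>= 2).
#' @param tau1 Sequential (burn-in) relaxation per step, ns (> 0).
#' @param tau2 Further relaxation per step, ns (>= 0); samples retained for
#'   analysis come from this phase.
#' @param k Bias stiffness, kcal/mol/A^2.
#' @param direction `"forward"` (lambda increasing) or `"backward"`.
#' @return A `pulling_schedule` object.
#' @export
pulling_schedule <- function(lambda_start = 0, delta_lambda = 1.0,
                             n_steps = 25, tau1 = 0.5, tau2 = 10,
                             k = 0.6,
                             direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  # delta_lambda = 0 is allowed as the degenerate (all-zero-work) schedule
  stopifnot(n_steps >= 2, delta_lambda >= 0, tau1 > 0, tau2 >= 0, k >= 0)
  structure(list(lambda_start = lambda_start, delta_lambda = delta_lambda,
                 n_steps = as.integer(n_steps), tau1 = tau1, tau2 = tau2,
                 k = k, direction = direction),
            class = "pulling_schedule")
}

#' Signed lambda increment of a schedule
#' @param schedule A `pulling_schedule`.
#' @return `delta_lambda` with sign: positive for forward, negative for
#'   backward pulling.
#' @export
signed_delta_lambda <- function(schedule) {
  if (schedule$direction == "forward") schedule$delta_lambda
  else -schedule$delta_lambda
}

#' Lambda ladder of a schedule
#' @param schedule A `pulling_schedule`.
#' @return Numeric vector of the `n_steps` bias centers, Angstrom.
#' @export
lambda_grid <- function(schedule) {
  schedule$lambda_start +
    (seq_len(schedule$n_steps) - 1) * signed_delta_lambda(schedule)
}

#' Mirror a schedule (forward <-> backward)
#'
#' The backward schedule starts where the forward ladder ends and descends
#' it; `backward_schedule(backward_schedule(s))` is `s`.
#'
#' @param schedule A `pulling_schedule`.
#' @return The mirrored `pulling_schedule`.
#' @export
backward_schedule <- function(schedule) {
  lam <- lambda_grid(schedule)
  pulling_schedule(
    lambda_start = lam[length(lam)],
    delta_lambda = schedule$delta_lambda,
    n_steps = schedule$n_steps,
    tau1 = schedule$tau1, tau2 = schedule$tau2, k = schedule$k,
    direction = if (schedule$direction == "forward") "backward" else "forward"
  )
}

#' Work increment of one bias switch at frozen position
#'
#' The instantaneous-switch work for advancing the bias center from
#' `lambda_i` to `lambda_i + delta_lambda` with the particle frozen at z:
#' `w = (k/2) * ((z - lambda_i - delta_lambda)^2 - (z - lambda_i)^2)`,
#' algebraically `(k/2) * (delta_lambda^2 - 2 delta_lambda (z - lambda_i))`.
#'
#' @param z Position(s), Angstrom.
#' @param lambda_i Current bias center, Angstrom.
#' @param delta_lambda Signed increment, Angstrom.
#' @param k Bias stiffness, kcal/mol/A^2.
#' @return Work in kcal/mol (vectorised over `z`).
#' @export
step_work_increment <- function(z, lambda_i, delta_lambda, k) {
  (k / 2) * ((z - lambda_i - delta_lambda)^2 - (z - lambda_i)^2)
}

#' Normalised position histogram g_i(z)
#'
#' @param z Position samples, Angstrom.
#' @param bin_width Bin width, Angstrom (default 0.01).
#' @return A `step_density` object: `breaks`, `mids`, `density` (integrates
#'   to 1), `counts`, `bin_width`, `n`.
#' @export
step_density <- function(z, bin_width = 0.01) {
  stopifnot(length(z) >= 1, all(is.finite(z)), bin_width > 0)
  lo <- floor(min(z) / bin_width) * bin_width - bin_width / 2
  nb <- ceiling((max(z) - lo) / bin_width) + 1L
  breaks <- lo + (0:nb) * bin_width
  counts <- tabulate(findInterval(z, breaks, rightmost.closed = TRUE),
                     nbins = nb)
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-(nb + 1)]) / 2,
                 density = counts / (length(z) * bin_width),
                 counts = counts, bin_width = bin_width, n = length(z)),
            class = "step_density")
}

# deterministic per-step seed derivation (doubles stay exact below 2^53)
derive_seed <- function(master, step, phase) {
  as.integer((master * 67 + step * 104729 + phase * 7919) %% 2147483629)
}

#' Run a step-wise pulling protocol
#'
#' For each lambda on the ladder: relax tau1 ns starting from the previous
#' step's tau1 endpoint (the sequential-seeding chain), then extend by
#' tau2 ns; tau2 samples are retained for all statistics (tau1 is treated
#' as burn-in). Per-step seeds are derived from the master seed and the
#' step index, so results do not depend on execution order.
#'
#' @param potential A `potential1d`.
#' @param schedule A `pulling_schedule`.
#' @param params A `langevin_params`; its `seed` is the master seed
#'   (required here for reproducibility).
#' @param z0 Initial position, Angstrom (default: the first bias center).
#' @param bin_width Histogram bin width for g_i(z), Angstrom.
#' @return A `pulling_run` archive: schedule, params, potential label, and
#'   per-step records with fields `index`, `lambda`, `samples` (data.frame
#'   `time`, `z`; times within the tau2 phase), `z_init`, `z_after_tau1`,
#'   `mean_z`, `g` (a `step_density`), `work_increments`.
#' @export
run_stepwise_pulling <- function(potential, schedule, params, z0 = NULL,
                                 bin_width = 0.01) {
  stopifnot(inherits(potential, "potential1d"),
            inherits(schedule, "pulling_schedule"),
            inherits(params, "langevin_params"))
  if (is.null(params$seed)) {
    stop("`params$seed` (master seed) is required for a pulling run")
  }
  master <- params$seed
  lam <- lambda_grid(schedule)
  dl <- signed_delta_lambda(schedule)
  if (is.null(z0)) z0 <- lam[1]
  use_tau2 <- schedule$tau2 >= params$sample_interval
  steps <- vector("list", schedule$n_steps)
  z_chain <- z0
  for (i in seq_len(schedule$n_steps)) {
    bias <- bias_potential(schedule$k, lam[i])
    p1 <- params; p1$seed <- derive_seed(master, i, 1L)
    s1 <- simulate_relaxation(potential, bias, z_chain, p1, schedule$tau1)
    if (use_tau2) {
      p2 <- params; p2$seed <- derive_seed(master, i, 2L)
      s2 <- simulate_relaxation(potential, bias, s1$z_final, p2,
                                schedule$tau2)
      retained <- s2$samples
    } else {
      retained <- s1$samples
    }
    if (nrow(retained) == 0) {
      stop(sprintf("step %d produced an empty sample set", i - 1L))
    }
    w <- step_work_increment(retained$z, lam[i], dl, schedule$k)
    steps[[i]] <- list(
      index = i - 1L, lambda = lam[i], samples = retained,
      z_init = z_chain, z_after_tau1 = s1$z_final,
      mean_z = mean(retained$z),
      g = step_density(retained$z, bin_width),
      work_increments = w
    )
    z_chain <- s1$z_final
  }
  structure(list(schedule = schedule, params = params,
                 master_seed = master, potential = potential,
                 potential_label = potential$label, steps = steps,
                 bin_width = bin_width),
            class = "pulling_run")
}

#' Validate a pulling-run archive
#'
#' Checks the sequential-seeding chain (each step's initial position equals
#' the previous step's tau1 endpoint), histogram normalisation, and the
#' sample-wise work-increment identity. Stops on the first violation.
#'
#' @param run A `pulling_run`.
#' @return Invisibly `TRUE` if valid.
#' @export
validate_pulling_run <- function(run) {
  stopifnot(inherits(run, "pulling_run"))
  dl <- signed_delta_lambda(run$schedule)
  for (i in seq_along(run$steps)) {
    st <- run$steps[[i]]
    if (i > 1 &&
        !isTRUE(all.equal(st$z_init, run$steps[[i - 1]]$z_after_tau1,
                          tolerance = 0))) {
      stop(sprintf("seeding chain broken at step %d", st$index))
    }
    mass <- sum(st$g$density) * st$g$bin_width
    if (abs(mass - 1) > 1e-9) {
      stop(sprintf("g_%d does not integrate to 1 (mass = %.12f)",
                   st$index, mass))
    }
    w_ref <- (run$schedule$k / 2) *
      (dl^2 - 2 * dl * (st$samples$z - st$lambda))
    if (max(abs(w_ref - st$work_increments)) > 1e-12) {
      stop(sprintf("work-increment identity violated at step %d", st$index))
    }
  }
  invisible(TRUE)
}

#' @export
print.pulling_run <- function(x, ...) {
  lam <- lambda_grid(x$schedule)
  cat("<pulling_run>", x$potential_label, "|", length(x$steps),
      "steps, lambda", lam[1], "->", lam[length(lam)], "A | k =",
      x$schedule$k, "kcal/mol/A^2 | seed", x$master_seed, "\n")
  invisible(x)
}
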