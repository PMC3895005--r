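# Free-energy profiles from step-wise work distributions: the Jarzynski
# exponential average over assembled cumulative works, the stepwise
# quasi-equilibrium (free-energy-perturbation) estimator, a mean-force
# (thermodynamic-integration) cross-check, species differences, and
# convergence traces.

log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

log_wmean_exp <- function(x, w) {
  m <- max(x)
  m + log(sum(w * exp(x - m)) / sum(w))
}

#' Assemble cumulative work distributions from a pulling run
#'
#' Builds the distribution rho(W) of cumulative work up to each lambda by
#' drawing one retained position per step independently and summing the
#' per-step work increments (cross-step independence is the construction
#' implied by building rho(W) from the per-step g_i). Monte-Carlo mode
#' draws `n_draws` trajectories; exhaustive mode enumerates the full
#' product space of discretised per-step values and is only permitted when
#' the product size is at most 1e7.
#'
#' @param run A validated `pulling_run`.
#' @param upto_step Last step index (0-based) whose increment is included;
#'   default: all steps.
#' @param mode `"monte_carlo"` or `"exhaustive"`.
#' @param n_draws Number of Monte-Carlo trajectories.
#' @param seed RNG seed for Monte-Carlo assembly.
#' @param discretize_width Bin width (Angstrom) used to discretise each
#'   step's positions in exhaustive mode.
#' @return A `work_set`: `lambda` (grid of length `upto_step + 2`,
#'   starting at the ladder origin where W = 0), and either a `works`
#'   matrix (`n_draws` rows, one column per grid point) or, in exhaustive
#'   mode, `works_list` of `(values, weights)` per grid point.
#' @export
assemble_work_distribution <- function(run,
                                       upto_step = run$schedule$n_steps - 1L,
                                       mode = c("monte_carlo", "exhaustive"),
                                       n_draws = 1e5, seed = 1,
                                       discretize_width = 0.01) {
  mode <- match.arg(mode)
  stopifnot(inherits(run, "pulling_run"), upto_step >= 0,
            upto_step <= run$schedule$n_steps - 1L)
  m <- upto_step + 1L          # number of increments used
  lam <- lambda_grid(run$schedule)
  dl <- signed_delta_lambda(run$schedule)
  grid <- c(lam[seq_len(m)], lam[m] + dl)
  if (mode == "monte_carlo") {
    set.seed(seed)
    works <- matrix(0, nrow = n_draws, ncol = m + 1L)
    for (i in seq_len(m)) {
      w_i <- run$steps[[i]]$work_increments
      works[, i + 1L] <- works[, i] +
        w_i[sample.int(length(w_i), n_draws, replace = TRUE)]
    }
    structure(list(lambda = grid, mode = mode, works = works,
                   n = n_draws), class = "work_set")
  } else {
    vals <- vector("list", m)
    for (i in seq_len(m)) {
      zdisc <- round(run$steps[[i]]$samples$z / discretize_width) *
        discretize_width
      tab <- table(zdisc)
      zu <- as.numeric(names(tab))
      vals[[i]] <- list(
        w = step_work_increment(zu, lam[i], dl, run$schedule$k),
        wt = as.numeric(tab)
      )
    }
    if (prod(vapply(vals, function(v) length(v$w), 1)) > 1e7) {
      stop("exhaustive product space exceeds 1e7; use mode = \"monte_carlo\"")
    }
    works_list <- vector("list", m + 1L)
    works_list[[1]] <- list(values = 0, weights = 1)
    for (i in seq_len(m)) {
      prev <- works_list[[i]]
      works_list[[i + 1L]] <- list(
        values = as.vector(outer(prev$values, vals[[i]]$w, `+`)),
        weights = as.vector(outer(prev$weights, vals[[i]]$wt, `*`))
      )
    }
    structure(list(lambda = grid, mode = mode, works_list = works_list,
                   n = length(works_list[[m + 1L]]$values)),
              class = "work_set")
  }
}

#' Mean cumulative work per lambda
#' @param works A `work_set`.
#' @return Numeric vector of mean cumulative work (kcal/mol) per grid point.
#' @export
mean_work <- function(works) {
  if (works$mode == "monte_carlo") colMeans(works$works)
  else vapply(works$works_list,
              function(v) sum(v$values * v$weights) / sum(v$weights), 1)
}

new_fe_profile <- function(lambda, delta_F, se, estimator, temperature) {
  structure(data.frame(lambda = lambda, delta_F = delta_F, se = se),
            estimator = estimator, temperature = temperature,
            class = c("free_energy_profile", "data.frame"))
}

#' Jarzynski free-energy profile from assembled work distributions
#'
#' `DeltaF(lambda) = -kBT log < exp(-W / kBT) >` over the assembled
#' trajectories, computed with an overflow-safe log-sum-exp. The profile is
#' zero at the ladder origin and satisfies `DeltaF <= <W>` (Jensen).
#'
#' @param works A `work_set`.
#' @param temperature Temperature, Kelvin.
#' @param n_boot Bootstrap resamples for the standard error (Monte-Carlo
#'   mode only; 0 disables).
#' @param seed Bootstrap seed.
#' @return A `free_energy_profile` data.frame: `lambda`, `delta_F`, `se`.
#' @export
jarzynski_delta_f <- function(works, temperature, n_boot = 200, seed = 1) {
  stopifnot(inherits(works, "work_set"))
  kT <- kbt(temperature)
  if (works$mode == "exhaustive") {
    dF <- vapply(works$works_list,
                 function(v) -kT * log_wmean_exp(-v$values / kT, v$weights),
                 1)
    return(new_fe_profile(works$lambda, dF, NA_real_,
                          "jarzynski", temperature))
  }
  W <- works$works
  if (nrow(W) == 0) stop("empty work set")
  # column-shifted exponentials so bootstrap means stay in range
  Mn <- apply(W, 2, min)
  E <- exp(-sweep(W, 2, Mn) / kT)
  dF <- -kT * log(colMeans(E)) + Mn
  se <- rep(NA_real_, length(dF))
  if (n_boot > 0) {
    set.seed(seed)
    boots <- matrix(0, n_boot, ncol(W))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(W), nrow(W), replace = TRUE)
      boots[b, ] <- -kT * log(colMeans(E[idx, , drop = FALSE])) + Mn
    }
    se <- apply(boots, 2, sd)
  }
  new_fe_profile(works$lambda, dF, se, "jarzynski", temperature)
}

#' Quasi-equilibrium (stepwise exponential-averaging) free-energy profile
#'
#' The infinite-relaxation estimator applied stepwise:
#' `DeltaF(lambda_m) = sum_{i<m} -kBT log < exp(-beta w_i(z)) >_{z ~ g_i}`,
#' with each average over the step's retained samples. Under cross-step
#' independence this is the large-sample limit of [jarzynski_delta_f()] on
#' assembled works.
#'
#' @param run A `pulling_run`.
#' @param temperature Temperature, Kelvin.
#' @param n_boot Bootstrap resamples per step for the standard error.
#' @param seed Bootstrap seed.
#' @return A `free_energy_profile` over the ladder grid (origin plus one
#'   point per completed increment).
#' @export
quasi_equilibrium_delta_f <- function(run, temperature, n_boot = 200,
                                      seed = 1) {
  stopifnot(inherits(run, "pulling_run"))
  kT <- kbt(temperature)
  lam <- lambda_grid(run$schedule)
  dl <- signed_delta_lambda(run$schedule)
  n <- run$schedule$n_steps
  a <- numeric(n)
  v <- numeric(n)
  set.seed(seed)
  for (i in seq_len(n)) {
    w <- run$steps[[i]]$work_increments
    a[i] <- -kT * log_mean_exp(-w / kT)
    if (n_boot > 0) {
      bo <- vapply(seq_len(n_boot), function(b) {
        wb <- w[sample.int(length(w), length(w), replace = TRUE)]
        -kT * log_mean_exp(-wb / kT)
      }, 1)
      v[i] <- var(bo)
    } else v[i] <- NA_real_
  }
  grid <- c(lam, lam[n] + dl)
  new_fe_profile(grid, c(0, cumsum(a)), c(0, sqrt(cumsum(v))),
                 "quasi_equilibrium", temperature)
}

#' Mean-force (thermodynamic-integration) free-energy cross-check
#'
#' `DeltaF(lambda_m) = sum_{i<m} k (lambda_i - <z>_i) delta_lambda`, the
#' Riemann sum of the mean bias force along the ladder. Agrees with the
#' exponential-averaging estimators up to O(delta_lambda) discretisation
#' error in the equilibrium limit.
#'
#' @param run A `pulling_run`.
#' @return A `free_energy_profile` (estimator `"mean_force"`, no SE).
#' @export
mean_force_delta_f <- function(run) {
  stopifnot(inherits(run, "pulling_run"))
  lam <- lambda_grid(run$schedule)
  dl <- signed_delta_lambda(run$schedule)
  n <- run$schedule$n_steps
  zbar <- vapply(run$steps, function(s) s$mean_z, 1)
  incr <- run$schedule$k * (lam - zbar) * dl
  new_fe_profile(c(lam, lam[n] + dl), c(0, cumsum(incr)), NA_real_,
                 "mean_force", NA_real_)
}

#' Per-lambda difference between two free-energy profiles
#'
#' @param profile_A,profile_B `free_energy_profile`s on identical lambda
#'   grids.
#' @param signed If `FALSE` (default) the magnitude |DeltaF_A - DeltaF_B|
#'   is reported.
#' @return A `ddf_profile` list: `lambda`, `delta_delta_F`, `peak_lambda`
#'   (arg-max), `peak_value`, `signed`.
#' @export
delta_delta_f <- function(profile_A, profile_B, signed = FALSE) {
  if (length(profile_A$lambda) != length(profile_B$lambda) ||
      max(abs(profile_A$lambda - profile_B$lambda)) > 1e-9) {
    stop("lambda grids of the two profiles do not match")
  }
  d <- profile_A$delta_F - profile_B$delta_F
  if (!signed) d <- abs(d)
  i <- which.max(d)
  structure(list(lambda = profile_A$lambda, delta_delta_F = d,
                 peak_lambda = profile_A$lambda[i], peak_value = d[i],
                 signed = signed),
            class = "ddf_profile")
}

#' Boltzmann selectivity ratio from a free-energy barrier difference
#'
#' @param delta_delta_f Barrier difference, kcal/mol.
#' @param temperature Temperature, Kelvin.
#' @return `exp(delta_delta_f / kBT)`, dimensionless.
#' @examples
#' selectivity_ratio(3.7, 310)  # ~406
#' @export
selectivity_ratio <- function(delta_delta_f, temperature) {
  exp(delta_delta_f / kbt(temperature))
}

# quasi-equilibrium estimate at one grid lambda using samples up to time tau
qe_delta_f_at <- function(run, lambda_focus, tau, kT) {
  lam <- lambda_grid(run$schedule)
  dl <- signed_delta_lambda(run$schedule)
  grid <- c(lam, lam[length(lam)] + dl)
  j <- which(abs(grid - lambda_focus) < 1e-9)
  if (length(j) != 1) stop("`lambda_focus` is not on the profile grid")
  if (j == 1) return(0)
  total <- 0
  for (i in seq_len(j - 1L)) {
    st <- run$steps[[i]]
    keep <- st$samples$time <= tau + 1e-12
    if (!any(keep)) stop(sprintf("no samples within tau = %g at step %d",
                                 tau, st$index))
    total <- total - kT * log_mean_exp(-st$work_increments[keep] / kT)
  }
  total
}

#' Convergence of the free-energy estimate with relaxation time
#'
#' Recomputes the quasi-equilibrium estimate at one lambda using only
#' samples collected up to each time in `tau_grid`. With a second archive,
#' the trace is of |DeltaF_A - DeltaF_B| instead.
#'
#' @param run A `pulling_run`.
#' @param lambda_focus Grid lambda at which to evaluate, Angstrom.
#' @param tau_grid Increasing relaxation times, ns; each must not exceed
#'   the recorded tau2.
#' @param temperature Temperature, Kelvin.
#' @param run2 Optional second `pulling_run` for a difference trace.
#' @param tol Convergence tolerance on the last two points, kcal/mol.
#' @return A data.frame `tau`, `value` with attribute `converged` (`NA` if
#'   the grid has fewer than two points).
#' @export
convergence_trace <- function(run, lambda_focus, tau_grid, temperature,
                              run2 = NULL, tol = 0.1) {
  stopifnot(inherits(run, "pulling_run"), length(tau_grid) >= 1)
  tmax <- max(run$steps[[1]]$samples$time)
  if (any(tau_grid > tmax + 1e-9)) {
    stop("`tau_grid` contains times beyond the recorded relaxation")
  }
  kT <- kbt(temperature)
  vals <- vapply(tau_grid, function(tau) {
    v <- qe_delta_f_at(run, lambda_focus, tau, kT)
    if (!is.null(run2)) v <- abs(v - qe_delta_f_at(run2, lambda_focus,
                                                   tau, kT))
    v
  }, 1)
  out <- data.frame(tau = tau_grid, value = vals)
  n <- length(vals)
  attr(out, "converged") <-
    if (n >= 2) abs(vals[n] - vals[n - 1]) < tol else NA
  out
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat("<free_energy_profile>", attr(x, "estimator"), "| lambda",
      min(x$lambda), "->", max(x$lambda), "A |", nrow(x), "points\n")
  print.data.frame(x, ...)
  invisible(x)
}
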