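gauss_work_set <- function(n, mu, sigma, seed = 1) {
  set.seed(seed)
  structure(list(lambda = c(0, 1), mode = "monte_carlo",
                 works = cbind(0, rnorm(n, mu, sigma)), n = n),
            class = "work_set")
}

# three-step archive with a handful of discrete positions per step
discrete_run <- function(n_levels = 10, reps = 5) {
  sch <- pulling_schedule(0, 1, n_steps = 3, tau1 = 0.1, tau2 = 0, k = 0.6)
  z_by_step <- lapply(1:3, function(i) {
    rep(seq(i - 1 - 0.5, i - 1 + 0.5, length.out = n_levels), reps)
  })
  manual_run(z_by_step, sch)
}

test_that("delta-distributed works give delta_F equal to the work", {
  sch <- pulling_schedule(0, 1, n_steps = 2, tau1 = 0.1, tau2 = 0, k = 0.6)
  run <- manual_run(list(rep(0.25, 50), rep(1.25, 50)), sch)
  ws <- assemble_work_distribution(run, mode = "monte_carlo",
                                   n_draws = 1000, seed = 1)
  W_exp <- step_work_increment(0.25, 0, 1, 0.6) +
    step_work_increment(1.25, 1, 1, 0.6)
  expect_equal(unique(ws$works[, 3]), W_exp)
  jz <- jarzynski_delta_f(ws, 310, n_boot = 0)
  expect_equal(jz$delta_F[3], W_exp, tolerance = 1e-12)
  expect_identical(jz$delta_F[1], 0)
})

test_that("Gaussian works reproduce the mu - sigma^2/(2 kBT) closed form", {
  ws <- gauss_work_set(1e5, mu = 1.0, sigma = 0.5, seed = 11)
  jz <- jarzynski_delta_f(ws, 310, n_boot = 0)
  expect_lt(abs(jz$delta_F[2] - (1.0 - 0.5^2 / (2 * kbt(310)))), 0.05)
})

test_that("exhaustive enumeration agrees with Monte-Carlo assembly", {
  run <- discrete_run()
  ex <- assemble_work_distribution(run, mode = "exhaustive")
  expect_identical(ex$n, 1000L)  # 10^3 distinct combinations
  mc <- assemble_work_distribution(run, mode = "monte_carlo",
                                   n_draws = 1e5, seed = 2)
  mw_ex <- mean_work(ex)
  mw_mc <- mean_work(mc)
  se <- apply(mc$works, 2, sd) / sqrt(nrow(mc$works))
  expect_true(all(abs(mw_ex - mw_mc) <= 3 * pmax(se, 1e-12)))
  jz_ex <- jarzynski_delta_f(ex, 310)
  jz_mc <- jarzynski_delta_f(mc, 310, n_boot = 50, seed = 3)
  expect_true(all(abs(jz_ex$delta_F - jz_mc$delta_F) <=
                    3 * pmax(jz_mc$se, 1e-3)))
})

test_that("exhaustive mode refuses oversized product spaces", {
  sch <- pulling_schedule(0, 1, n_steps = 3, tau1 = 0.1, tau2 = 0, k = 0.6)
  z_by_step <- lapply(1:3, function(i) seq(0, 5, length.out = 500) + i)
  run <- manual_run(z_by_step, sch)
  expect_error(assemble_work_distribution(run, mode = "exhaustive"),
               "monte_carlo")
})

test_that("Jensen: Jarzynski estimate never exceeds the mean work", {
  run <- discrete_run()
  ws <- assemble_work_distribution(run, mode = "monte_carlo",
                                   n_draws = 2e4, seed = 5)
  jz <- jarzynski_delta_f(ws, 310, n_boot = 0)
  expect_true(all(jz$delta_F <= mean_work(ws) + 1e-9))
  gs <- gauss_work_set(1e4, 0.5, 1, seed = 6)
  expect_lte(jarzynski_delta_f(gs, 310, n_boot = 0)$delta_F[2],
             mean_work(gs)[2] + 1e-9)
})

test_that("assembled works from Gaussian g_i are close to Gaussian", {
  run <- harmonic_toy_run(n_steps = 3, tau2 = 10, diffusion = 50, seed = 7)
  ws <- assemble_work_distribution(run, n_draws = 1e5, seed = 4)
  W <- ws$works[, 4]
  skew <- mean((W - mean(W))^3) / sd(W)^3
  expect_lt(abs(skew), 0.2)
})

test_that("mean-force variant reproduces the Riemann sum of the mean force", {
  run <- harmonic_toy_run(n_steps = 3, tau2 = 10, diffusion = 50, seed = 7)
  mf <- mean_force_delta_f(run)
  # analytic mean force at lambda is k (lambda - lambda/2) = 0.3 lambda;
  # left Riemann sum over lambda = 0, 1, 2
  expect_lt(abs(mf$delta_F[3] - 0.3 * (0 + 1)), 0.1)
  expect_lt(abs(mf$delta_F[4] - 0.3 * (0 + 1 + 2)), 0.15)
})

test_that("delta_delta_f handles identity, shifts, and grid mismatch", {
  p <- structure(data.frame(lambda = 0:3, delta_F = c(0, 1, 3, 2),
                            se = NA_real_),
                 estimator = "quasi_equilibrium", temperature = 310,
                 class = c("free_energy_profile", "data.frame"))
  expect_identical(unique(delta_delta_f(p, p)$delta_delta_F), 0)
  q <- p; q$delta_F <- p$delta_F + 2.5
  dd <- delta_delta_f(q, p)
  expect_identical(unique(dd$delta_delta_F), 2.5)
  signed <- delta_delta_f(p, q, signed = TRUE)
  expect_identical(unique(signed$delta_delta_F), -2.5)
  r <- p; r$lambda <- p$lambda + 0.5
  expect_error(delta_delta_f(p, r), "grids")
  # peak reporting
  s <- p; s$delta_F <- c(0, 5, 1, 0)
  dd2 <- delta_delta_f(s, p)
  expect_equal(dd2$peak_lambda, 1)
  expect_equal(dd2$peak_value, 4)
})

test_that("selectivity ratio is the Boltzmann factor of the barrier", {
  expect_lt(abs(selectivity_ratio(3.7, 310) - 405.9), 0.1)
  expect_identical(selectivity_ratio(0, 310), 1)
  expect_equal(selectivity_ratio(kbt(310), 310), exp(1), tolerance = 1e-12)
})

test_that("convergence trace approaches the analytic value", {
  # slow-relaxing toy (D = 2): the short-tau estimate is strongly biased,
  # the full-tau one is close to the analytic 0.6 kcal/mol
  sch <- pulling_schedule(0, 1, n_steps = 3, tau1 = 0.5, tau2 = 10, k = 0.6)
  run <- run_stepwise_pulling(potential_harmonic(0.6), sch,
                              langevin_params(diffusion = 2, seed = 7))
  tr <- convergence_trace(run, 2, c(0.5, 2, 10), 310)
  analytic <- harmonic_toy_analytic(2)
  expect_lt(abs(tr$value[3] - analytic), abs(tr$value[1] - analytic))
  expect_true(isTRUE(attr(tr, "converged")))
  # single-point grid: no convergence flag
  tr1 <- convergence_trace(run, 2, 5, 310)
  expect_identical(nrow(tr1), 1L)
  expect_true(is.na(attr(tr1, "converged")))
  # identical archives: difference trace is exactly zero
  tr0 <- convergence_trace(run, 2, c(1, 5), 310, run2 = run)
  expect_identical(unique(tr0$value), 0)
  expect_error(convergence_trace(run, 2.5, c(1, 5), 310), "grid")
  expect_error(convergence_trace(run, 2, c(1, 50), 310), "beyond")
})
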