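test_that("work increment matches its algebraic identity sample-wise", {
  set.seed(1)
  z <- runif(200, -5, 30); lam <- runif(200, 0, 24); k <- runif(200, 0, 2)
  dl <- sample(c(-1, 0.5, 1, 2), 200, replace = TRUE)
  direct <- (k / 2) * ((z - lam - dl)^2 - (z - lam)^2)
  expanded <- (k / 2) * (dl^2 - 2 * dl * (z - lam))
  expect_equal(step_work_increment(z, lam, dl, k), direct, tolerance = 0)
  expect_equal(direct, expanded, tolerance = 1e-12)
})

test_that("work increment spot values", {
  expect_identical(step_work_increment(5, 5, 1, 0.6), 0.3)
  expect_identical(step_work_increment(5.5, 5, 1, 0.6), 0)
  expect_equal(step_work_increment(7, 5, 1, 0.6), -0.9, tolerance = 1e-12)
})

test_that("schedules validate and expose their lambda ladder", {
  s <- pulling_schedule()
  expect_identical(s$n_steps, 25L)
  expect_equal(lambda_grid(s), 0:24)
  expect_error(pulling_schedule(n_steps = 1))
  expect_error(pulling_schedule(tau1 = 0))
  expect_error(pulling_schedule(delta_lambda = -1))
})

test_that("backward schedule mirrors the ladder and is an involution", {
  s <- pulling_schedule()
  b <- backward_schedule(s)
  expect_equal(lambda_grid(b), 24:0)
  expect_identical(signed_delta_lambda(b), -1)
  expect_equal(backward_schedule(b), s)
})

test_that("degenerate delta_lambda = 0 gives exactly zero work", {
  sch <- pulling_schedule(0, 0, n_steps = 2, tau1 = 0.05, tau2 = 0.05,
                          k = 0.6)
  run <- run_stepwise_pulling(potential_harmonic(0.6), sch,
                              langevin_params(diffusion = 2, seed = 2))
  for (st in run$steps) expect_identical(unique(st$work_increments), 0)
  qe <- quasi_equilibrium_delta_f(run, 310, n_boot = 0)
  expect_identical(unique(qe$delta_F), 0)
})

test_that("harmonic toy: per-step means approach lambda/2 within 3 SE", {
  run <- harmonic_toy_run(tau2 = 20, diffusion = 50, seed = 7)
  lam <- lambda_grid(run$schedule)
  # SE of the mean ~ sd * sqrt(2 tau_c / tau2); tau_c = kBT/((a+k) D)
  se <- sqrt(kbt(310) / 1.2) * sqrt(2 * (kbt(310) / (1.2 * 50)) / 20)
  for (i in seq_along(run$steps)) {
    expect_lt(abs(run$steps[[i]]$mean_z - lam[i] / 2), 3 * se)
  }
})

test_that("archive validates; a broken seeding chain is caught", {
  run <- harmonic_toy_run(n_steps = 3, tau2 = 0.2, diffusion = 2, seed = 4)
  expect_true(validate_pulling_run(run))
  broken <- run
  broken$steps[[2]]$z_init <- broken$steps[[2]]$z_init + 0.1
  expect_error(validate_pulling_run(broken), "seeding chain")
  tampered <- run
  tampered$steps[[3]]$work_increments[5] <-
    tampered$steps[[3]]$work_increments[5] + 1e-6
  expect_error(validate_pulling_run(tampered), "work-increment")
})

test_that("g_i integrates to one and pools correctly", {
  run <- harmonic_toy_run(n_steps = 3, tau2 = 0.2, diffusion = 2, seed = 4)
  for (st in run$steps) {
    expect_lt(abs(sum(st$g$density) * st$g$bin_width - 1), 1e-9)
  }
})

test_that("relaxation samples converge to the Boltzmann marginal in tau2", {
  # KS distance to the analytic Gaussian falls as more of tau2 is used
  run <- harmonic_toy_run(n_steps = 3, tau2 = 20, diffusion = 50, seed = 7)
  st <- run$steps[[2]]  # lambda = 1: z ~ N(0.5, kBT/(a+k))
  ks_at <- function(tau) {
    z <- st$samples$z[st$samples$time <= tau]
    suppressWarnings(ks.test(z, "pnorm", 0.5, sqrt(kbt(310) / 1.2))$statistic)
  }
  ks <- vapply(c(1, 4, 16), ks_at, 1)
  expect_true(all(diff(ks) < 0))
})

test_that("forward and backward ladders agree on the free-energy change", {
  # state-function property on the coupled-harmonic toy; desk-scale
  # estimator error is ~0.05 kcal/mol per profile (see methods vignette)
  fwd <- harmonic_toy_run(n_steps = 3, tau2 = 10, diffusion = 50, seed = 7)
  sch_b <- backward_schedule(fwd$schedule)  # ladder 2, 1, 0
  bwd <- run_stepwise_pulling(potential_harmonic(0.6), sch_b,
                              langevin_params(diffusion = 50, seed = 8),
                              z0 = 1)  # equilibrium mean at lambda = 2
  dF_f <- quasi_equilibrium_delta_f(fwd, 310, n_boot = 0)
  dF_b <- quasi_equilibrium_delta_f(bwd, 310, n_boot = 0)
  # F(2) - F(0) traversed forward plus F(0) - F(2) traversed backward
  expect_equal(dF_f$lambda[3], 2)
  expect_equal(dF_b$lambda[3], 0)
  expect_lt(abs(dF_f$delta_F[3] + dF_b$delta_F[3]), 0.15)
})
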