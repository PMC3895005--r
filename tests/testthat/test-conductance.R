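mk_pair <- function(G, W = 1, i = 0L) {
  structure(list(i = i, j = i + 1L, G_pS = G, mean_work = W,
                 dispersion = abs(G), n_retained = 100L),
            class = "pair_conductance")
}

test_that("steady-flow worked example: 150 pS <-> ~0.6 kcal/mol", {
  W <- steady_flow_work(150, 1, 0.5, 10)
  expect_lt(abs(W - 0.6157), 5e-4)
  expect_identical(round(W, 1), 0.6)
  # mutual inversion on the degenerate flow
  G <- conductance_from_flow(0.5^2 / 10, 1, W)
  expect_lt(abs(G - 150), 1e-9)
})

test_that("steady-flow work scales quadratically in the displacement", {
  w_half <- steady_flow_work(150, 1, 0.5, 10)
  w_full <- steady_flow_work(150, 1, 1.0, 10)
  expect_equal(w_full / w_half, 4, tolerance = 1e-12)
  expect_error(steady_flow_work(0, 1, 0.5, 10))
  expect_error(steady_flow_work(150, 1, 0.5, 0))
})

test_that("conductance scales as q^2 and inherits the sign of the work", {
  G1 <- conductance_from_flow(0.1, 2, 0.5)
  G2 <- conductance_from_flow(0.1, 2, 0.5, q = 2 * unit_system()$e_charge)
  expect_equal(G2 / G1, 4, tolerance = 1e-12)
  expect_lt(conductance_from_flow(0.1, 2, -0.5), 0)
  expect_identical(conductance_from_flow(0, 2, 0.5), 0)
})

test_that("pair sampling rejects non-positive effective times", {
  sch <- pulling_schedule(0, 1, n_steps = 2, tau1 = 0.1, tau2 = 0, k = 0.6)
  run <- manual_run(list(seq(0, 0.5, length.out = 50),
                         seq(1, 1.5, length.out = 50)), sch)
  pairs <- sample_flow_pairs(run, 0, 1, tau = 5, n_pairs = 500, seed = 2)
  expect_true(all(pairs$dt_eff > 0))
  # with tau = 0 and j = i, only t_j > t_i pairs survive
  same <- sample_flow_pairs(run, 0, 0, tau = 0, n_pairs = 500, seed = 3)
  expect_true(all(same$dt_eff > 0))
})

test_that("zero displacement gives zero conductance", {
  sch <- pulling_schedule(0, 1, n_steps = 2, tau1 = 0.1, tau2 = 0, k = 0.6)
  run <- manual_run(list(rep(0.2, 50), rep(0.2, 50)), sch)
  pc <- pair_conductance(run, 0, 1, tau = 1, n_pairs = 500, seed = 4)
  expect_identical(pc$G_pS, 0)
  expect_gt(abs(pc$mean_work), 0)
})

test_that("pair conductance q^2 scaling holds on sampled archives", {
  run <- harmonic_toy_run(n_steps = 3, tau2 = 0.5, diffusion = 2, seed = 9)
  p1 <- pair_conductance(run, 0, 1, tau = 0.5, n_pairs = 1000, seed = 5)
  p2 <- pair_conductance(run, 0, 1, tau = 0.5, n_pairs = 1000, seed = 5,
                         q = 2 * unit_system()$e_charge)
  expect_equal(p2$G_pS / p1$G_pS, 4, tolerance = 1e-12)
})

test_that("dispersion term: degenerate and ballistic limits", {
  expect_identical(dispersion_term(data.frame(dz = rep(0, 10),
                                              dt_eff = 1:10))$dispersion, 0)
  # deterministic drift z = v t: dz^2/dt = v^2 dt
  v <- 0.3; dt <- runif(100, 1, 5)
  pairs <- data.frame(dz = v * dt, dt_eff = dt)
  expect_equal(dispersion_term(pairs)$dispersion, v^2 * mean(dt),
               tolerance = 1e-12)
})

test_that("series law composes pair conductances", {
  expect_equal(total_conductance(list(mk_pair(20), mk_pair(20)))$G_total_pS,
               10, tolerance = 1e-12)
  one <- total_conductance(list(mk_pair(7.5)))
  expect_identical(one$G_total_pS, 7.5)
  expect_error(total_conductance(list(mk_pair(0), mk_pair(5))), "zero")
})

test_that("negative series total with positive work raises, never clips", {
  pairs <- list(mk_pair(10), mk_pair(-2), mk_pair(10))
  # harmonic series value would be -10/3 pS while total work is +3
  expect_error(total_conductance(pairs), "internal inconsistency")
  # with negative total work the same series value is reported as-is
  pairs_nw <- list(mk_pair(10, W = -2), mk_pair(-2, W = -2),
                   mk_pair(10, W = -2))
  tot <- total_conductance(pairs_nw)
  expect_equal(tot$G_total_pS, -10 / 3, tolerance = 1e-12)
})

test_that("independent-ion scaling", {
  expect_identical(independent_ion_scaling(29, 3), 87)
  expect_identical(independent_ion_scaling(12.5, 1), 12.5)
  expect_identical(independent_ion_scaling(0, 5), 0)
  expect_error(independent_ion_scaling(29, 0))
})
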