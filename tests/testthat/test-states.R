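dens_from_grid <- function(mids, density, bin_width) {
  nb <- length(mids)
  breaks <- c(mids - bin_width / 2, mids[nb] + bin_width / 2)
  structure(list(breaks = breaks, mids = mids, density = density,
                 counts = round(density * bin_width * 1e6),
                 bin_width = bin_width, n = 1e6),
            class = "step_density")
}

test_that("pooled histogram counts all samples and is additive", {
  sch <- pulling_schedule(0, 1, n_steps = 2, tau1 = 0.1, tau2 = 0, k = 0.6)
  run <- manual_run(list(c(0.1, 0.1, 0.2), c(1.1, 1.2, 1.2)), sch)
  h <- pool_positions(run)
  expect_identical(h$total, 6L)
  expect_identical(sum(h$counts), 6L)
  # additivity against the per-step histograms
  per_step <- sum(run$steps[[1]]$g$n) + sum(run$steps[[2]]$g$n)
  expect_identical(h$total, as.integer(per_step))
})

test_that("K_like pooled histogram has modes at fixture wells", {
  h <- pool_positions(species_run("K_like"), bin_width = 0.1)
  modes <- histogram_modes(h, min_frac = 0.05, min_separation = 1)
  wells <- c(7.1, 10.4, 13.6, 17.0, 23.1)
  hits <- vapply(wells, function(w) any(abs(modes - w) < 0.5), TRUE)
  expect_gte(sum(hits), 3)
})

test_that("mixture EM recovers a two-Gaussian blend and its count", {
  set.seed(31)
  x <- c(rnorm(2500, 7.1, 0.3), rnorm(2500, 10.4, 0.3))
  fit <- fit_position_mixture(x, max_components = 4)
  expect_identical(nrow(fit), 2L)
  expect_lt(abs(fit$mean[1] - 7.1), 0.1)
  expect_lt(abs(fit$mean[2] - 10.4), 0.1)
  expect_lt(abs(sum(fit$weight) - 1), 1e-9)
  # log-likelihood is non-decreasing across EM iterations
  tr <- attr(fit, "loglik_trace")
  expect_true(all(diff(tr) > -1e-8))
})

test_that("a single Gaussian selects one component by BIC", {
  set.seed(32)
  fit <- fit_position_mixture(rnorm(5000, 5, 0.4), max_components = 4)
  expect_identical(nrow(fit), 1L)
  expect_lt(abs(fit$mean - 5), 0.05)
})

test_that("mixture output is invariant to sample order", {
  set.seed(33)
  x <- c(rnorm(1000, 0, 0.2), rnorm(1000, 2, 0.2))
  f1 <- fit_position_mixture(x, max_components = 3)
  f2 <- fit_position_mixture(sample(x), max_components = 3)
  expect_equal(f1$mean, f2$mean, tolerance = 1e-9)
})

test_that("degenerate zero-variance data yields one floored component", {
  fit <- fit_position_mixture(rep(3, 100), max_components = 3)
  expect_identical(nrow(fit), 1L)
  expect_gt(fit$sd, 0)
})

test_that("partition_forces recomputes f = k (lambda - z) exactly", {
  sch <- pulling_schedule(0, 1, n_steps = 2, tau1 = 0.1, tau2 = 0, k = 0.6)
  # all samples at z = lambda: zero force
  run0 <- manual_run(list(rep(0, 30), rep(1, 30)), sch)
  comp <- data.frame(id = 1, mean = 0.5, sd = 2, weight = 1)
  segs <- partition_forces(run0, comp)
  expect_identical(unique(segs[[1]]$f), 0)
  # uniform displacement -1 A: constant force 0.6
  run1 <- manual_run(list(rep(-1, 30), rep(0, 30)), sch)
  segs1 <- partition_forces(run1, data.frame(id = 1, mean = -0.5, sd = 2,
                                             weight = 1))
  expect_identical(unique(segs1[[1]]$f), 0.6)
  expect_identical(segs1[[1]]$dispersion_class, "small")
  # component whose CI contains no samples is dropped with a warning
  expect_warning(
    empty <- partition_forces(run1, data.frame(id = 1, mean = 20, sd = 0.1,
                                               weight = 1)),
    "dropped")
  expect_length(empty, 0)
})

test_that("fixture forces are broad at the entry trap, narrow beyond it", {
  runN <- species_run("Na_like")
  trap <- window_force_segment(runN, 4.5, 6.5)
  beyond <- window_force_segment(runN, 15, 25)
  expect_gt(trap$sd_f, beyond$sd_f)
  expect_identical(trap$dispersion_class, "large")
})

test_that("three-case transition rule: small/small is deterministic", {
  a <- force_segment(rnorm(100, 1.0, 0.01), sd_threshold = 0.3)
  b <- force_segment(rnorm(100, 0.5, 0.01), sd_threshold = 0.3)
  expect_identical(transition_probability(a, b), 1)
  expect_identical(transition_probability(b, a), 0)
})

test_that("case (b): fraction within the large-SD segment (386/1300)", {
  set.seed(35)
  f_large <- c(runif(386, -2, -0.01), runif(914, 0.01, 4))
  to_seg <- force_segment(sample(f_large), sd_threshold = 0.3)   # large SD
  from_seg <- force_segment(rnorm(200, 0, 0.01), sd_threshold = 0.3)
  expect_identical(from_seg$dispersion_class, "small")
  expect_identical(to_seg$dispersion_class, "large")
  # P(f_to <= mean f_from = 0): the 386 negatives of 1300
  expect_equal(transition_probability(from_seg, to_seg), 386 / 1300,
               tolerance = 1e-9)
})

test_that("case (c) equals the brute-force double count over the product", {
  set.seed(36)
  fi <- rnorm(150, 0.5, 1); fj <- rnorm(130, 0.8, 1.2)
  si <- force_segment(fi, sd_threshold = 0.1)
  sj <- force_segment(fj, sd_threshold = 0.1)
  expect_identical(si$dispersion_class, "large")
  p_pair <- mean(outer(fi, fj, `>=`))
  expect_equal(transition_probability(si, sj), p_pair^2, tolerance = 1e-12)
  # identical symmetric segments: ~0.25 (ties on the diagonal only)
  f <- seq(-1, 1, length.out = 200)
  s <- force_segment(f, sd_threshold = 0.1)
  expect_lt(abs(transition_probability(s, s) - 0.25), 0.01)
})

test_that("negative-force fraction gives the spontaneous-jump probability", {
  seg <- force_segment(c(rep(-0.5, 386), rep(0.7, 914)))
  expect_equal(negative_force_fraction(seg), 386 / 1300, tolerance = 1e-12)
  expect_lt(abs(negative_force_fraction(seg) - 0.3), 0.01)
  expect_identical(negative_force_fraction(force_segment(c(1, 2))), 0)
  expect_identical(negative_force_fraction(force_segment(c(-1, -2))), 1)
})

test_that("probability ratio reproduces the 15x entry-rate comparison", {
  expect_identical(probability_ratio(0.3, 0.02), 15)
  expect_identical(probability_ratio(0.4, 0.4), 1)
  expect_identical(probability_ratio(0, 0.3), 0)
  expect_error(probability_ratio(0.3, 0), "positive")
})

test_that("overlap coefficient: identity, disjoint, Gaussian closed form", {
  bw <- 0.01
  mids <- seq(-8, 9, by = bw)
  g1 <- dens_from_grid(mids, dnorm(mids, 0, 1), bw)
  g2 <- dens_from_grid(mids, dnorm(mids, 1, 1), bw)
  ov_self <- detailed_balance_overlap(g1, g1)
  expect_lt(abs(ov_self$overlap - 1), 1e-6)
  expect_equal(ov_self$forward_weight, ov_self$backward_weight)
  # two unit Gaussians one SD apart: overlap = 2 Phi(-1/2)
  ov <- detailed_balance_overlap(g1, g2)
  expect_lt(abs(ov$overlap - 2 * pnorm(-0.5)), 1e-3)
  # symmetry
  ov_rev <- detailed_balance_overlap(g2, g1)
  expect_lt(abs(ov$overlap - ov_rev$overlap), 1e-12)
  # disjoint supports
  g3 <- step_density(rnorm(500, 100, 0.1), bw)
  g4 <- step_density(rnorm(500, -100, 0.1), bw)
  ov0 <- detailed_balance_overlap(g3, g4)
  expect_identical(ov0$overlap, 0)
  expect_true(ov0$flagged)
})

test_that("overlap is stable under common rebinning", {
  set.seed(37)
  z <- rnorm(2e4, 0, 1); w <- rnorm(2e4, 1, 1)
  fine <- detailed_balance_overlap(step_density(z, 0.01),
                                   step_density(w, 0.01))
  coarse <- detailed_balance_overlap(step_density(z, 0.05),
                                     step_density(w, 0.05))
  expect_lt(abs(fine$overlap - coarse$overlap), 0.02)
})
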