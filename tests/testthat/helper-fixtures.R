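# Shared toy systems for the test suite. Kept small; analytic references
# are computed in the tests themselves.

# coupled-harmonic toy: system a z^2/2 plus bias k (z - lambda)^2 / 2.
# Analytic free energy relative to lambda = 0: (a k / (a + k)) lambda^2 / 2.
harmonic_toy_run <- function(a = 0.6, k = 0.6, n_steps = 3, tau2 = 10,
                             diffusion = 50, seed = 7, dt = 1e-4) {
  sch <- pulling_schedule(0, 1, n_steps = n_steps, tau1 = 0.5, tau2 = tau2,
                          k = k)
  run_stepwise_pulling(potential_harmonic(a), sch,
                       langevin_params(diffusion = diffusion, seed = seed,
                                       timestep = dt, sample_interval = dt))
}

harmonic_toy_analytic <- function(lambda, a = 0.6, k = 0.6) {
  (a * k / (a + k)) * lambda^2 / 2
}

# tiny archive with hand-set samples, bypassing the engine: used where a
# deterministic archive is clearer than a simulated one
manual_run <- function(z_by_step, schedule, bin_width = 0.01) {
  lam <- lambda_grid(schedule)
  dl <- signed_delta_lambda(schedule)
  steps <- lapply(seq_along(z_by_step), function(i) {
    z <- z_by_step[[i]]
    list(index = i - 1L, lambda = lam[i],
         samples = data.frame(time = seq_along(z) * 1e-4, z = z),
         z_init = if (i == 1) z[1] else tail(z_by_step[[i - 1]], 1),
         z_after_tau1 = tail(z, 1),
         mean_z = mean(z),
         g = step_density(z, bin_width),
         work_increments = step_work_increment(z, lam[i], dl, schedule$k))
  })
  structure(list(schedule = schedule,
                 params = langevin_params(seed = 1),
                 master_seed = 1L,
                 potential = potential_harmonic(0),
                 potential_label = "manual", steps = steps,
                 bin_width = bin_width),
            class = "pulling_run")
}

# species fixture pulling runs at desk scale (tau2 = 1 ns, D = 2 A^2/ns);
# cached per session because several test files reuse them
species_run <- local({
  cache <- list()
  function(species, seed = if (species == "K_like") 11 else 12) {
    key <- paste(species, seed)
    if (is.null(cache[[key]])) {
      sch <- pulling_schedule(0, 1, n_steps = 25, tau1 = 0.5, tau2 = 1,
                              k = 0.6)
      cache[[key]] <<- run_stepwise_pulling(
        make_species_fixture(species), sch,
        langevin_params(diffusion = 2, seed = seed))
    }
    cache[[key]]
  }
})
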