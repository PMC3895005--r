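# Conductance estimation from work and displacement statistics. Work on a
# charge q moving between two "electrodes" (bias centers lambda_i < lambda_j)
# is equated with the heat dissipated in a resistance R = 1/G:
#   G = (q / L)^2 <dz^2 / dt_eff> / <W>,
# with L = lambda_j - lambda_i, dz = z(t_j) - z(t_i),
# dt_eff = t_j - t_i + (j - i) tau > 0, W the mean work between the steps.
# The form is fixed by the steady-flow limit I = q v / L, under which it
# inverts exactly to W = (q dz / L)^2 / (G t).

#' Conductance from flow statistics
#'
#' Core conversion `G = (q / L)^2 * dispersion / W`, taking the
#' displacement dispersion `<dz^2 / dt_eff>` in A^2/ns, the electrode
#' separation in Angstrom and the mean work in kcal/mol (converted to
#' joule per particle internally), and returning picosiemens. On a
#' degenerate steady flow (single-valued `dz`, `dt_eff`) this is the exact
#' inverse of [steady_flow_work()].
#'
#' @param dispersion `<dz^2 / dt_eff>`, A^2/ns.
#' @param L Electrode separation, Angstrom.
#' @param mean_work_kcalmol Mean work, kcal/mol (sign carries through).
#' @param q Charge, coulomb.
#' @return Conductance in pS.
#' @examples
#' conductance_from_flow(0.5^2 / 10, 1, 0.6157)  # ~150 pS
#' @export
conductance_from_flow <- function(dispersion, L, mean_work_kcalmol,
                                  q = unit_system()$e_charge) {
  us <- unit_system()
  disp_SI <- dispersion * us$angstrom_to_m^2 / us$ns_to_s
  L_SI <- L * us$angstrom_to_m
  W_J <- kcalmol_to_J(mean_work_kcalmol)
  G_S <- (q / L_SI)^2 * disp_SI / W_J
  G_S / 1e-12
}

#' Sample steady-flow pairs from two pulling steps
#'
#' Draws `(t_i, z(t_i))` and `(t_j, z(t_j))` independently from the two
#' steps' retained streams and keeps pairs with positive effective time
#' `dt_eff = t_j - t_i + (j - i) tau`.
#'
#' @param run A `pulling_run`.
#' @param i,j Step indices (0-based, `j > i`, or `j = i` for same-step
#'   diffusion sampling).
#' @param tau Per-step relaxation time entering `dt_eff`, ns (default: the
#'   schedule's tau2).
#' @param n_pairs Number of pairs drawn before rejection.
#' @param seed RNG seed.
#' @return A data.frame `dz` (Angstrom), `dt_eff` (ns) of retained pairs.
#' @export
sample_flow_pairs <- function(run, i, j, tau = run$schedule$tau2,
                              n_pairs = 1e4, seed = 1) {
  stopifnot(inherits(run, "pulling_run"), j >= i,
            i >= 0, j <= run$schedule$n_steps - 1L)
  si <- run$steps[[i + 1L]]$samples
  sj <- run$steps[[j + 1L]]$samples
  set.seed(seed)
  ii <- sample.int(nrow(si), n_pairs, replace = TRUE)
  jj <- sample.int(nrow(sj), n_pairs, replace = TRUE)
  dt_eff <- sj$time[jj] - si$time[ii] + (j - i) * tau
  keep <- dt_eff > 0
  if (!any(keep)) stop("all sampled pairs were rejected (dt_eff <= 0)")
  data.frame(dz = sj$z[jj][keep] - si$z[ii][keep], dt_eff = dt_eff[keep])
}

#' Displacement dispersion term and its diffusion interpretation
#'
#' @param pairs Data.frame of flow pairs (`dz`, `dt_eff`), e.g. from
#'   [sample_flow_pairs()].
#' @return A list: `dispersion` = `<dz^2 / dt_eff>` (A^2/ns, non-negative)
#'   and `D_implied` = `dispersion / 2` under the free-diffusion reading
#'   `<dz^2> = 2 D dt`.
#' @export
dispersion_term <- function(pairs) {
  stopifnot(nrow(pairs) >= 1)
  disp <- mean(pairs$dz^2 / pairs$dt_eff)
  list(dispersion = disp, D_implied = disp / 2)
}

#' Conductance for a pair of pulling steps
#'
#' @param run A `pulling_run`.
#' @param i,j Step indices (0-based, `j > i`).
#' @param q Charge, coulomb (default one elementary charge).
#' @param tau Per-step relaxation time entering `dt_eff`, ns.
#' @param n_pairs Pairs drawn (at least 100).
#' @param seed RNG seed.
#' @return A `pair_conductance` list: `i`, `j`, `G_pS` (may be negative:
#'   negative work means attraction, not resistance), `mean_work`
#'   (kcal/mol; for `j = i + 1` the mean per-step increment at step i, in
#'   general the sum of mean increments over steps i..j-1), `dispersion`
#'   (A^2/ns), `n_retained`.
#' @export
pair_conductance <- function(run, i, j, q = unit_system()$e_charge,
                             tau = run$schedule$tau2, n_pairs = 1e4,
                             seed = 1) {
  stopifnot(j > i, n_pairs >= 100)
  pairs <- sample_flow_pairs(run, i, j, tau, n_pairs, seed)
  disp <- dispersion_term(pairs)$dispersion
  mw <- sum(vapply(run$steps[(i + 1L):j],
                   function(st) mean(st$work_increments), 1))
  if (abs(mw) < 1e-12) {
    stop("mean work is zero within tolerance; conductance undefined")
  }
  L <- abs(run$steps[[j + 1L]]$lambda - run$steps[[i + 1L]]$lambda)
  structure(list(i = i, j = j,
                 G_pS = conductance_from_flow(disp, L, mw, q),
                 mean_work = mw, dispersion = disp,
                 n_retained = nrow(pairs)),
            class = "pair_conductance")
}

#' Invert the steady-flow conductance relation for the mean work
#'
#' For a steady single-ion flow, `W = (q dz / L)^2 / (G t_eff)`.
#'
#' @param G Conductance, pS (> 0).
#' @param L Electrode separation, Angstrom (> 0).
#' @param delta_z Displacement, Angstrom (> 0).
#' @param t_eff Effective time, ns (> 0).
#' @param q Charge, coulomb.
#' @return Work in kcal/mol.
#' @examples
#' steady_flow_work(150, 1, 0.5, 10)  # ~0.6 kcal/mol
#' @export
steady_flow_work <- function(G, L, delta_z, t_eff,
                             q = unit_system()$e_charge) {
  stopifnot(G > 0, L > 0, delta_z > 0, t_eff > 0, q > 0)
  us <- unit_system()
  W_J <- (q * delta_z * us$angstrom_to_m / (L * us$angstrom_to_m))^2 /
    (G * 1e-12 * t_eff * us$ns_to_s)
  J_to_kcalmol(W_J)
}

#' Total conductance of successive-step pairs in series
#'
#' `G_total = 1 / sum(1 / G_i)`, the series-resistor law. If the total
#' work over the pairs is positive but the series value is not, an
#' internal-consistency error is raised rather than the value being
#' clipped.
#'
#' @param pairs List of `pair_conductance` objects.
#' @return A `total_conductance` list: `G_total_pS`, `W_total`
#'   (kcal/mol), `pairs`.
#' @export
total_conductance <- function(pairs) {
  stopifnot(length(pairs) >= 1,
            all(vapply(pairs, inherits, TRUE, "pair_conductance")))
  G <- vapply(pairs, function(p) p$G_pS, 1)
  W <- vapply(pairs, function(p) p$mean_work, 1)
  if (any(G == 0)) stop("a pair conductance of exactly zero cannot enter the series sum")
  G_tot <- 1 / sum(1 / G)
  W_tot <- sum(W)
  if (W_tot > 0 && G_tot <= 0) {
    stop(paste("internal inconsistency: total work is positive but the",
               "series conductance is not; negative pairs dominate the ladder"))
  }
  structure(list(G_total_pS = G_tot, W_total = W_tot, pairs = pairs),
            class = "total_conductance")
}

#' Conductance profile over the full ladder
#'
#' Computes [pair_conductance()] for every successive step pair.
#'
#' @param run A `pulling_run`.
#' @inheritParams pair_conductance
#' @return A list of `pair_conductance` objects (one per successive pair).
#' @export
conductance_profile <- function(run, q = unit_system()$e_charge,
                                tau = run$schedule$tau2, n_pairs = 1e4,
                                seed = 1) {
  n <- run$schedule$n_steps
  lapply(seq_len(n - 1L) - 1L, function(i) {
    pair_conductance(run, i, i + 1L, q = q, tau = tau, n_pairs = n_pairs,
                     seed = derive_seed(seed, i, 3L))
  })
}

#' Independent-ion scaling of a single-ion conductance
#'
#' @param G_single Single-ion conductance, pS.
#' @param n_ions Number of independently moving ions (>= 1).
#' @return `n_ions * G_single`, pS.
#' @examples
#' independent_ion_scaling(29, 3)  # 87 pS
#' @export
independent_ion_scaling <- function(G_single, n_ions) {
  stopifnot(n_ions >= 1)
  n_ions * G_single
}
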