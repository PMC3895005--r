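---
title: "Step-wise pulling: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step-wise pulling: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ionpull)
```

## The model

`ionpull` analyses *step-wise pulling*: a particle (canonically, an ion in
a channel pore) moves along a coordinate $z$ under a system potential
$U_0(z)$ and a harmonic bias $U(z,\lambda) = k(z-\lambda)^2/2$ whose
center advances on a ladder $\lambda_i = \lambda_0 + i\,\Delta\lambda$.
After every increment the system relaxes: a sequential burn-in $\tau_1$
(whose endpoint seeds the next step, mirroring how such protocols chain
initial configurations) followed by a longer relaxation $\tau_2$ whose
samples are retained. The defaults — $\Delta\lambda = 1$ Å, 25 steps over
0–24 Å, $\tau_1 = 0.5$ ns, $\tau_2 = 10$ ns, $k = 0.6$ kcal/mol/Å²
$\approx 1\,k_BT$/Å² at 310 K — are the canonical soft-bias protocol for
ion-channel pulling; the soft bias deliberately lets the particle hop
between metastable sites instead of being dragged rigidly.

Every estimator consumes only per-step $(t, z)$ samples, so a
one-dimensional overdamped Langevin engine is a faithful stand-in for the
all-atom simulations such data usually come from:
$$z \leftarrow z + \frac{D}{k_BT}F(z)\,\mathrm{d}t + \sqrt{2D\,\mathrm{d}t}\;\xi,
\qquad \xi \sim \mathcal N(0,1),$$
an Euler–Maruyama step with all randomness drawn from R's seeded RNG
stream (bit-identical reruns). A configuration-time guard requires
$\mathrm{d}t\,(k_{\mathrm{tot}}/k_BT)\,D < 0.1$ with $k_{\mathrm{tot}}$
the bias stiffness plus the largest potential curvature over the declared
domain — an unstable setup errors instead of silently diverging. This is
why the quartic double-well's default domain is $\pm 3$ half-widths: its
curvature grows without bound, and a needlessly wide domain would make
the guard reject configurations the trajectory can actually integrate.

## Free-energy estimators

With the bias advanced at frozen $z$, the switch work is
$w_i(z) = \tfrac{k}{2}\big[\Delta\lambda^2 -
2\Delta\lambda\,(z-\lambda_i)\big]$ — an exact algebraic identity that the
archive validator re-checks sample-wise.

Two estimator routes are implemented and cross-checked:

* **Assembled-work route** (`assemble_work_distribution()` +
  `jarzynski_delta_f()`): cumulative works are assembled by drawing one
  retained position per step *independently across steps* — the
  construction implied by building the work distribution from the per-step
  marginals $g_i(z)$ — and exponentially averaged,
  $\Delta F = -k_BT\,\ln\langle e^{-W/k_BT}\rangle$, via log-sum-exp.
  Assembly is Monte-Carlo (seeded) or exhaustive over discretised
  positions (capped at $10^7$ combinations; the cap errors with a pointer
  to Monte-Carlo rather than truncating silently).
* **Stepwise route** (`quasi_equilibrium_delta_f()`):
  $\Delta F(\lambda_m) = \sum_{i<m} -k_BT \ln\langle e^{-w_i/k_BT}\rangle_{g_i}$.
  Under cross-step independence this is exactly the
  $n\to\infty$ limit of the assembled-work estimator, so the two agreeing
  is a check of the assembly and averaging code paths, not a tautology.

A third reading of the infinite-relaxation limit — thermodynamic
integration over the mean bias force,
$\sum_i k(\lambda_i - \langle z\rangle_i)\Delta\lambda$
(`mean_force_delta_f()`) — is exposed as a cross-check. Unlike the
exponential forms it carries an $O(\Delta\lambda)$ discretisation error
(it is a left Riemann sum), so tests compare it against the Riemann sum
of the analytic mean force, not against the continuum profile.

Cross-step independence is a modelling choice: real pulling trajectories
are correlated across steps. The package documents this as the
construction the work-distribution formalism implies; it is exact for the
toy engine in the equilibrium limit and a stated approximation otherwise.

**Uncertainty.** No closed-form error formula is assumed; bootstrap SEs
(default 200 resamples, seeded) are attached per profile point. Note that
bootstrap SEs on correlated relaxation samples underestimate the true
error; for desk-scale toy runs the observed seed-to-seed spread of the
$\lambda = 2$ Å harmonic-toy estimate is $\approx 0.05$ kcal/mol, which
is the basis for the 0.15 kcal/mol tolerance on the forward/backward
state-function test.

**Convergence.** `convergence_trace()` recomputes the stepwise estimate
using only samples up to each $\tau$ of a grid and flags convergence when
the last two points differ by less than 0.1 kcal/mol — an order below the
~1 kcal/mol uncertainty typical of such profiles.

## The analytic oracle and equilibration-time choices

For a harmonic system $a z^2/2$ coupled to the bias, every quantity is
closed-form: $\Delta F(\lambda) = \frac{ak}{a+k}\frac{\lambda^2}{2}$,
per-step marginals are Gaussian with variance $k_BT/(a+k)$, and the
stepwise exponential average is *exact* at equilibrium regardless of
$\Delta\lambda$. This is the package's primary parameter-recovery test
(tolerance 0.1 kcal/mol at $\lambda = 2$ Å).

The relaxation time of the toy is $\tau_c = k_BT/(k_{\mathrm{tot}} D)$.
No effective 1D diffusion coefficient is published for an ion in a pore,
so $D$ is a free parameter (package default 0.5 Å²/ns, a plausible
in-pore magnitude). Oracle-recovery tests raise $D$ (2–50 Å²/ns, always
re-checked against the stability guard) so that $\tau_2$ covers hundreds
of $\tau_c$ — these are equilibration choices computed from $\tau_c$
*before* asserting, not tuned thresholds. The same formula explains why
the engine's Boltzmann (KS) and equipartition checks use long runs: the
effective sample count of a correlated stream is
$\tau_2/(2\tau_c)$, not the raw sample count.

## Species fixtures

`make_species_fixture()` returns qualitative emulations of a
selectivity-filter landscape on $z \in [0, 25]$ Å, built from Gaussian
wells (width 0.5 Å) plus confining walls:

| fixture | wells (Å) | depths (kcal/mol) |
|---|---|---|
| `K_like` | 7.1, 10.4, 13.6, 17.0, 23.1 | 3.5, 3.0, 3.0, 2.5, 1.5 |
| `Na_like` | 5.5, 9.1, 22.5 | 7.0, 2.0, 1.0 |

The K-like wells sit at the crystallographic-like stable sites; the
Na-like fixture has its deep trap just below the filter entrance, one
in-filter site, no wells in (12, 21) Å, and a shallow exit-region well
(ions that do traverse re-stabilise near the mouth). Depths are free
parameters chosen once so the Na-like entry barrier exceeds the K-like
one by ≈3.5 kcal/mol; they are *not* fits to any real channel, so tests
and the acceptance suite assert only signs, locations and orderings
(e.g. the ΔΔF peak falls in the 7–20 Å entry-to-filter window), never
magnitudes.

What a green fixture test establishes: the estimator stack reproduces
known orderings on a landscape with the right topology. What it does not:
anything about real ionic selectivity values, multi-ion permeation,
filter flexibility, or hydration — the 1D engine has no water, no
protein degrees of freedom, and a single particle.

## States, forces, transitions

Pooled positions over all steps are decomposed by a univariate Gaussian
mixture fitted by EM with a deterministic quantile initialisation and
selected by BIC (the mixture machinery is self-contained; per-fit
log-likelihood traces are kept and asserted non-decreasing). The bias
force $f(z) = k(\lambda - z)$ pooled over all $(\lambda, z)$ samples is
partitioned by each component's 95% CI in $z$.

A segment is *large*-dispersion when $\mathrm{SD}(f) > \tfrac12 k\,
\Delta\lambda$ — half the force change of one pulling increment, the
scale at which the inequality between neighbouring forces becomes
genuinely uncertain. The transition probability between ordered stable
positions follows the three-case rule: deterministic (0/1) for two sharp
segments; for one sharp and one broad segment, the empirical fraction
within the broad segment satisfying the inequality against the sharp
segment's mean; for two broad segments, the product of the two
pair-fractions over the sample product (ties count as satisfying). The
two factors of that product are the same event counted from each side —
a logical tension inherited from the rule's source — so the returned
value is the square of the pair fraction; the brute-force double count
over the product is the test oracle.

The spontaneous-jump probability is the fraction of negative forces in a
segment: the particle is ahead of the bias center, i.e. it has already
jumped into the site unassisted. For cross-species comparisons this
estimator, evaluated in each species' first in-filter site window
(6–8.5 Å for K-like, 8–10.2 Å for Na-like), proved far more stable at
desk scale than the windowed three-case product, whose cross-species
ordering flips between seeds; the acceptance suite therefore asserts the
ordering on the spontaneous-jump fractions.

Distribution overlaps between successive $g_i$ use the min-overlap
coefficient $\sum \min(g_i, g_j)\,\Delta z$ on a common grid (rebinned to
the coarser width when needed). This is a declared operationalisation of
the detailed-balance/Franck–Condon overlap idea and is used as a
path-dominance diagnostic only, never as a weight inside the Jarzynski
average.

## Conductance

Equating work on a charge with dissipated heat gives, per step pair
$(i, j)$, $G = (q/L)^2\,\langle\Delta z^2/\Delta t_{\mathrm{eff}}\rangle
/ \langle W\rangle$ with $\Delta t_{\mathrm{eff}} = t_j - t_i +
(j-i)\tau > 0$ (pairs drawn independently from the two steps' streams;
non-positive effective times rejected). The form is pinned by two
requirements: it reduces to $I = qv/L$ for a steady flow, and it inverts
the published worked example exactly — 150 pS with $L = 1$ Å,
$\Delta z = 0.5$ Å, $t = 10$ ns gives back 0.6157 ≈ 0.6 kcal/mol
(`steady_flow_work()` / `conductance_from_flow()` are mutual inverses on
degenerate flows, and the test suite enforces this closure).

The dispersion term is read as free diffusion,
$D_{ij} = \langle\Delta z^2/\Delta t_{\mathrm{eff}}\rangle/2$ (the exact
prefactor multiplying $D_{ij}$ in the source formalism is not
recoverable; this reading is declared and tested by parameter recovery).
A single stream gives this estimator very few effective degrees of
freedom — pairs at the largest time separations share one Brownian
excursion — so the recovery test pools pairs across 50 independent
streams, which is also the realistic archive geometry.

Per-pair $G$ may legitimately be negative (negative mean work: the site
attracts the ion). The ladder total composes by the series-resistor law
$G_{\mathrm{tot}} = (\sum_i G_i^{-1})^{-1}$; if the total is non-positive
while the total work is positive the package raises an
internal-inconsistency error rather than clipping, surfacing the
ambiguity in how positivity is guaranteed in the source formalism.
`independent_ion_scaling()` implements the $n$-fold scaling for $n$
independently moving ions.

## Geometry observables

`coordination_count()` (Euclidean distance, default cutoff 3 Å, counting
labelled oxygen positions; no periodic minimum-image — the analysis
region of interest is assumed far from box edges) and
`axial_dispersion_histogram()` (per-label deviation from a reference
plane, with bimodality decided by a 1-vs-2 component BIC comparison)
operate on plain `(frame, label, x, y, z)` tables. The bundled fixture
generators produce a logistic hydration-shell profile (6 → 0.5 waters)
and ±0.75 Å two-cluster dispersions; they are labelled synthetic and test
only the observables, not any physical hydration model.

## Numerical choices (summary)

* Histogram bin width 0.01 Å (configurable); archives store raw samples,
  histograms are always recomputed.
* $\tau_1$ samples are burn-in and excluded from all statistics (flag-free
  default; the retained phase is where convergence is ensured).
* Per-step seeds derive deterministically from the master seed and step
  index, so serial and parallel execution agree; all derived seeds stay
  below $2^{31}$.
* log-sum-exp everywhere an exponential average appears; EM standard
  deviations floored at $10^{-3}$ Å; mixture initialisation by quantiles
  (deterministic), BIC penalty $(3K-1)\ln n$.
* Degenerate inputs: zero-variance mixture data yield one floored
  component; empty force windows return `NULL`/warn rather than
  fabricating segments; $\Delta\lambda = 0$ schedules are legal and give
  exactly zero work.
* Ties in force comparisons count as satisfying ("equal to or larger").

## Known limitations

* One particle, one dimension: no multi-ion correlations (knock-on), no
  filter flexibility, no solvent — fixture conclusions are topological,
  not quantitative.
* Cross-step independence in work assembly ignores trajectory
  correlation; with real MD archives the Jarzynski route inherits that
  approximation.
* Bootstrap SEs understate errors on strongly correlated streams; use
  seed replication for honest spread at desk scale.
* The three-case transition rule is a faithful implementation of an
  operationally specified recipe; its case (c) product double-counts one
  event by construction and should be read as a score, not a calibrated
  probability.
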