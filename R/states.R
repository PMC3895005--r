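# Stable-state analysis: pooled position histograms, univariate Gaussian
# mixture decomposition (EM + BIC), force partitioning by component, the
# three-case transition-probability rule, spontaneous-jump fractions, and
# detailed-balance distribution overlaps.

#' Pooled positions from all steps of a pulling run
#'
#' @param run A `pulling_run`.
#' @return A data.frame with one row per retained sample: `lambda`
#'   (the step's bias center) and `z`.
#' @export
pooled_samples <- function(run) {
  stopifnot(inherits(run, "pulling_run"))
  do.call(rbind, lapply(run$steps, function(st) {
    data.frame(lambda = st$lambda, z = st$samples$z)
  }))
}

#' Pooled position histogram over all lambda steps
#'
#' @param run A `pulling_run`.
#' @param bin_width Bin width, Angstrom (default 0.01).
#' @return A `pooled_histogram`: `breaks`, `mids`, `counts`, `total`,
#'   `bin_width`.
#' @export
pool_positions <- function(run, bin_width = 0.01) {
  z <- pooled_samples(run)$z
  if (length(z) == 0) stop("archive contains no retained samples")
  g <- step_density(z, bin_width)
  structure(list(breaks = g$breaks, mids = g$mids, counts = g$counts,
                 total = g$n, bin_width = bin_width),
            class = "pooled_histogram")
}

#' Histogram modes (local maxima of counts)
#' @param hist A `pooled_histogram`.
#' @param min_frac Minimum count (as a fraction of the maximum bin) for a
#'   reported mode.
#' @param min_separation Minimum distance between reported modes, Angstrom.
#' @return Positions of the modes, Angstrom, in decreasing order of height.
#' @export
histogram_modes <- function(hist, min_frac = 0.05, min_separation = 1) {
  cnt <- hist$counts
  ord <- order(cnt, decreasing = TRUE)
  out <- numeric(0)
  for (i in ord) {
    if (cnt[i] < min_frac * max(cnt)) break
    if (all(abs(hist$mids[i] - out) >= min_separation)) {
      out <- c(out, hist$mids[i])
    }
  }
  out
}

# univariate Gaussian mixture EM with deterministic quantile init
gmm_em <- function(x, K, max_iter = 300, tol = 1e-8, sd_floor = 1e-3) {
  n <- length(x)
  s0 <- sd(x)
  if (!is.finite(s0) || s0 < sd_floor) {
    # degenerate data: single component at the SD floor
    return(list(mean = mean(x), sd = sd_floor, weight = 1,
                loglik = sum(dnorm(x, mean(x), sd_floor, log = TRUE)),
                loglik_trace = NA_real_, K = 1L))
  }
  mu <- quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  sig <- rep(max(s0 / K, sd_floor), K)
  pk <- rep(1 / K, K)
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(K),
                   function(k) log(pk[k]) + dnorm(x, mu[k], sig[k], log = TRUE),
                   numeric(n))
    if (K == 1) logd <- matrix(logd, ncol = 1)
    m <- do.call(pmax, as.data.frame(logd))
    r <- exp(logd - m)
    s <- rowSums(r)
    ll <- sum(m + log(s))
    trace <- c(trace, ll)
    resp <- r / s
    nk <- colSums(resp)
    pk <- nk / n
    mu <- colSums(resp * x) / nk
    sig <- pmax(sqrt(colSums(resp * (outer(x, mu, `-`))^2) / nk), sd_floor)
    if (is.finite(ll_old) && ll - ll_old < tol * abs(ll)) break
    ll_old <- ll
  }
  list(mean = mu, sd = sig, weight = pk, loglik = ll,
       loglik_trace = trace, K = K)
}

#' Fit a univariate Gaussian mixture to position samples
#'
#' EM fits with 1 to `max_components` components are compared by BIC;
#' initialisation is a deterministic quantile spread, so the fit is
#' reproducible. Components are returned sorted by mean.
#'
#' @param samples Position samples, Angstrom (at least
#'   `10 * max_components`).
#' @param max_components Largest number of components tried.
#' @param seed Kept for interface stability; the fit is deterministic.
#' @return A `mixture_fit` data.frame with columns `id`, `mean`, `sd`,
#'   `weight`; attributes `bic` (per K), `loglik` and `loglik_trace` of the
#'   selected fit.
#' @export
fit_position_mixture <- function(samples, max_components = 5, seed = 1) {
  x <- as.numeric(samples)
  stopifnot(all(is.finite(x)))
  if (length(x) < 10 * max_components) {
    stop("need at least 10 samples per candidate component")
  }
  fits <- lapply(seq_len(max_components), function(K) gmm_em(x, K))
  bic <- vapply(seq_along(fits), function(K) {
    -2 * fits[[K]]$loglik + (3 * fits[[K]]$K - 1) * log(length(x))
  }, 1)
  best <- fits[[which.min(bic)]]
  ord <- order(best$mean)
  out <- data.frame(id = seq_along(ord), mean = best$mean[ord],
                    sd = best$sd[ord], weight = best$weight[ord])
  structure(out, bic = bic, loglik = best$loglik,
            loglik_trace = best$loglik_trace,
            class = c("mixture_fit", "data.frame"))
}

#' Partition bias forces by mixture component
#'
#' Pools the per-sample bias force `f(z) = k (lambda - z)` over all steps
#' and assigns each sample whose z lies in a component's 95% confidence
#' interval to that component's force segment. A segment is classed
#' `"large"` dispersion when `SD(f) > sd_threshold` (default: half the
#' bias-force quantum `k * delta_lambda`, the force change of one pulling
#' increment).
#'
#' @param run A `pulling_run`.
#' @param components A `mixture_fit` (or data.frame with `mean`, `sd`).
#' @param ci_level Confidence level for the z-window (default 0.95).
#' @param sd_threshold Dispersion threshold in kcal/mol/A; `NULL` uses the
#'   default rule.
#' @return A list of `force_segment` objects: `id`, `mean_z`, `f` (force
#'   samples, kcal/mol/A), `mean_f`, `sd_f`, `n`, `dispersion_class`.
#'   Components with no samples in their window are dropped with a warning.
#' @export
partition_forces <- function(run, components, ci_level = 0.95,
                             sd_threshold = NULL) {
  stopifnot(inherits(run, "pulling_run"))
  if (is.null(sd_threshold)) {
    sd_threshold <- 0.5 * run$schedule$k * run$schedule$delta_lambda
  }
  pool <- pooled_samples(run)
  f_all <- run$schedule$k * (pool$lambda - pool$z)
  zcrit <- qnorm((1 + ci_level) / 2)
  segs <- list()
  for (r in seq_len(nrow(components))) {
    lo <- components$mean[r] - zcrit * components$sd[r]
    hi <- components$mean[r] + zcrit * components$sd[r]
    sel <- pool$z >= lo & pool$z <= hi
    if (!any(sel)) {
      warning(sprintf("component %d has no samples in its %g%% CI; dropped",
                      r, 100 * ci_level))
      next
    }
    f <- f_all[sel]
    segs[[length(segs) + 1L]] <- structure(
      list(id = r, mean_z = components$mean[r], f = f,
           mean_f = mean(f), sd_f = sd(f), n = length(f),
           dispersion_class = if (sd(f) > sd_threshold) "large" else "small",
           sd_threshold = sd_threshold),
      class = "force_segment")
  }
  segs
}

#' Construct a force segment directly from force samples
#'
#' @param f Force samples, kcal/mol/A.
#' @param mean_z Representative position, Angstrom.
#' @param sd_threshold Dispersion threshold, kcal/mol/A (default 0.3, half
#'   the default bias-force quantum 0.6 * 1.0).
#' @param id Segment id.
#' @return A `force_segment`.
#' @export
force_segment <- function(f, mean_z = NA_real_, sd_threshold = 0.3, id = 1L) {
  stopifnot(length(f) >= 1, all(is.finite(f)))
  s <- if (length(f) > 1) sd(f) else 0
  structure(list(id = id, mean_z = mean_z, f = f, mean_f = mean(f),
                 sd_f = s,
                 dispersion_class = if (s > sd_threshold) "large" else "small",
                 n = length(f), sd_threshold = sd_threshold),
            class = "force_segment")
}

#' Force segment from a fixed z-window of a pulling run
#'
#' Pools the bias forces of all retained samples whose position falls in
#' `[zlo, zhi]`. Useful when a site's window is known a priori (e.g. the
#' first in-filter binding site) rather than fitted by a mixture.
#'
#' @param run A `pulling_run`.
#' @param zlo,zhi Window bounds, Angstrom.
#' @param sd_threshold Dispersion threshold; `NULL` uses half the
#'   bias-force quantum.
#' @return A `force_segment`, or `NULL` if the window is empty.
#' @export
window_force_segment <- function(run, zlo, zhi, sd_threshold = NULL) {
  stopifnot(inherits(run, "pulling_run"), zhi > zlo)
  if (is.null(sd_threshold)) {
    sd_threshold <- 0.5 * run$schedule$k * run$schedule$delta_lambda
  }
  pool <- pooled_samples(run)
  sel <- pool$z >= zlo & pool$z <= zhi
  if (!any(sel)) return(NULL)
  f <- run$schedule$k * (pool$lambda[sel] - pool$z[sel])
  force_segment(f, mean_z = mean(pool$z[sel]), sd_threshold = sd_threshold)
}

# fraction of ordered pairs (a, b) with a >= b; ties count as satisfying
pair_fraction_ge <- function(a, b) {
  sum(findInterval(a, sort(b))) / (length(a) * length(b))
}

#' Transition probability between two stable positions (three-case rule)
#'
#' The probability that the force at the current position is equal to or
#' larger than at the next, `P(f(z_i) >= f(z_j))`:
#' \itemize{
#'   \item both segments small-SD: 1 if `mean f_i >= mean f_j`, else 0
#'     (deterministic rule; the reverse transition is its complement);
#'   \item one small, one large: the empirical fraction, within the
#'     large-SD segment, of observations satisfying the inequality against
#'     the small segment's mean;
#'   \item both large: the product
#'     `P(f_i >= f_j) * P(f_j <= f_i)` with each factor the empirical
#'     fraction over the sample product, treating the two events as
#'     independent (ties satisfy the inequality).
#' }
#'
#' @param segment_i Current position's `force_segment` (smaller mean z).
#' @param segment_j Next position's `force_segment`.
#' @return A probability in `[0, 1]`.
#' @export
transition_probability <- function(segment_i, segment_j) {
  stopifnot(inherits(segment_i, "force_segment"),
            inherits(segment_j, "force_segment"))
  if (segment_i$n == 0 || segment_j$n == 0) stop("empty force segment")
  ci <- segment_i$dispersion_class
  cj <- segment_j$dispersion_class
  if (ci == "small" && cj == "small") {
    return(as.numeric(segment_i$mean_f >= segment_j$mean_f))
  }
  if (ci == "large" && cj == "small") {
    return(mean(segment_i$f >= segment_j$mean_f))
  }
  if (ci == "small" && cj == "large") {
    return(mean(segment_j$f <= segment_i$mean_f))
  }
  p_fwd <- pair_fraction_ge(segment_i$f, segment_j$f)
  p_bwd <- pair_fraction_ge(segment_i$f, segment_j$f) # P(f_j <= f_i), same event
  p_fwd * p_bwd
}

#' Fraction of negative forces in a segment
#'
#' The spontaneous-jump probability: the fraction of force observations
#' below zero, i.e. samples where the bias pulls the particle backwards
#' because it has already jumped ahead of the bias center.
#'
#' @param segment A `force_segment`.
#' @return A probability in `[0, 1]`.
#' @export
negative_force_fraction <- function(segment) {
  stopifnot(inherits(segment, "force_segment"), segment$n >= 1)
  mean(segment$f < 0)
}

#' Ratio of two probabilities
#' @param p_A,p_B Probabilities; `p_B` must be positive.
#' @return `p_A / p_B`.
#' @export
probability_ratio <- function(p_A, p_B) {
  if (p_B <= 0) stop("denominator probability must be positive")
  p_A / p_B
}

# rebin a step_density onto target breaks (aligned, width a multiple)
rebin_density <- function(g, breaks) {
  bw <- breaks[2] - breaks[1]
  idx <- findInterval(g$mids, breaks, rightmost.closed = TRUE)
  dens <- numeric(length(breaks) - 1)
  ok <- idx >= 1 & idx <= length(dens)
  mass <- g$density * g$bin_width
  for (i in which(ok)) dens[idx[i]] <- dens[idx[i]] + mass[i]
  dens / bw
}

#' Overlap between two step position distributions
#'
#' Computes the overlap coefficient `sum min(g_i, g_j) * bin_width` on a
#' common grid, the detailed-balance diagnostic for which step pairs carry
#' appreciable forward/backward transition weight. Forward and backward
#' weights are the overlap mass normalised by each distribution's mass on
#' the shared support.
#'
#' @param g_i,g_j `step_density` objects (rebinned to the coarser bin
#'   width if they differ).
#' @param min_overlap Overlap value below which the pair is flagged.
#' @return An `overlap_report`: `overlap` in `[0, 1]`, `forward_weight`,
#'   `backward_weight`, `flagged`.
#' @export
detailed_balance_overlap <- function(g_i, g_j, min_overlap = 0.01) {
  stopifnot(inherits(g_i, "step_density"), inherits(g_j, "step_density"))
  bw <- max(g_i$bin_width, g_j$bin_width)
  lo <- floor(min(g_i$breaks[1], g_j$breaks[1]) / bw) * bw - bw / 2
  hi <- max(max(g_i$breaks), max(g_j$breaks))
  nb <- ceiling((hi - lo) / bw) + 1L
  breaks <- lo + (0:nb) * bw
  di <- rebin_density(g_i, breaks)
  dj <- rebin_density(g_j, breaks)
  ov <- sum(pmin(di, dj)) * bw
  supp <- di > 0 & dj > 0
  mi <- sum(di[supp]) * bw
  mj <- sum(dj[supp]) * bw
  structure(list(overlap = ov,
                 forward_weight = if (mi > 0) ov / mi else 0,
                 backward_weight = if (mj > 0) ov / mj else 0,
                 flagged = ov < min_overlap),
            class = "overlap_report")
}
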