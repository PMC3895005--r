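# Generic 3D geometry observables on coordinate frames: coordination
# (hydration-shell) counting within a cutoff and per-atom axial dispersion
# histograms, plus the synthetic fixture generators used to test them.
#
# Frames are a long data.frame with columns (frame, label, x, y, z); the
# tracked ion carries the reserved label given by `ion_label`.

check_frames <- function(frames, ion_label) {
  stopifnot(is.data.frame(frames),
            all(c("frame", "label", "x", "y", "z") %in% names(frames)))
  if (nrow(frames) == 0) stop("empty coordinate frames")
  if (!any(frames$label == ion_label)) {
    stop(sprintf("no rows labelled '%s' (the tracked ion)", ion_label))
  }
  invisible(TRUE)
}

#' Coordination count within a cutoff
#'
#' Counts, per frame, the particles with a target label within `cutoff`
#' Angstrom (Euclidean distance) of the ion, and aggregates mean and SD of
#' the count in bins of the ion's z position.
#'
#' @param frames Coordinate data.frame `(frame, label, x, y, z)`.
#' @param target_labels Labels counted (e.g. `"OW"` for water oxygens).
#' @param cutoff Shell radius, Angstrom (> 0).
#' @param ion_label Label of the tracked ion row in each frame.
#' @param bin_width Width of the ion-z bins for the profile, Angstrom.
#' @return A list: `per_frame` data.frame (`frame`, `ion_z`, `count`) and
#'   `profile` data.frame (`z_mid`, `mean`, `sd`, `n_frames`).
#' @export
coordination_count <- function(frames, target_labels, cutoff = 3,
                               ion_label = "ion", bin_width = 1) {
  stopifnot(cutoff > 0)
  check_frames(frames, ion_label)
  ions <- frames[frames$label == ion_label, ]
  part <- frames[frames$label %in% target_labels, ]
  per <- lapply(seq_len(nrow(ions)), function(r) {
    fr <- ions$frame[r]
    p <- part[part$frame == fr, ]
    d2 <- (p$x - ions$x[r])^2 + (p$y - ions$y[r])^2 + (p$z - ions$z[r])^2
    data.frame(frame = fr, ion_z = ions$z[r], count = sum(d2 <= cutoff^2))
  })
  per <- do.call(rbind, per)
  bin <- floor(per$ion_z / bin_width)
  agg <- lapply(split(per, bin), function(df) {
    data.frame(z_mid = (unique(floor(df$ion_z / bin_width)) + 0.5) * bin_width,
               mean = mean(df$count),
               sd = if (nrow(df) > 1) sd(df$count) else 0,
               n_frames = nrow(df))
  })
  profile <- do.call(rbind, agg)
  profile <- profile[order(profile$z_mid), ]
  rownames(profile) <- NULL
  list(per_frame = per, profile = profile)
}

#' Axial dispersion histogram of tagged atoms around reference planes
#'
#' For each requested label, histograms the axial deviation `z - reference`
#' of that label's atoms over all frames and flags bimodality by a
#' one-versus-two-component Gaussian-mixture BIC comparison.
#'
#' @param frames Coordinate data.frame `(frame, label, x, y, z)`.
#' @param labels Labels to analyse.
#' @param reference_plane_z Named numeric vector: reference z per label,
#'   Angstrom.
#' @param bin_width Histogram bin width, Angstrom.
#' @return Named list per label: `histogram` (a `step_density` of
#'   deviations), `bimodal` (logical), `component_means` (of the selected
#'   mixture).
#' @export
axial_dispersion_histogram <- function(frames, labels, reference_plane_z,
                                       bin_width = 0.05) {
  stopifnot(is.data.frame(frames))
  out <- list()
  for (lb in labels) {
    if (!lb %in% frames$label) stop(sprintf("unknown label '%s'", lb))
    if (!lb %in% names(reference_plane_z)) {
      stop(sprintf("no reference plane for label '%s'", lb))
    }
    dz <- frames$z[frames$label == lb] - reference_plane_z[[lb]]
    fit <- fit_position_mixture(dz, max_components = 2)
    out[[lb]] <- list(histogram = step_density(dz, bin_width),
                      bimodal = nrow(fit) == 2,
                      component_means = fit$mean)
  }
  out
}

#' Synthetic hydration fixture
#'
#' Generates frames of an ion walking along z in `z_range` with a first
#' hydration shell whose mean occupancy falls from `n_bulk` (vestibule) to
#' `n_filter` (filter site) along a logistic profile centred at
#' `z_switch`; the realised count per frame is binomial-thinned. Shell
#' waters are placed at `shell_radius`; `n_far` spectator waters are
#' placed far away. Synthetic stand-in for hydration analysis, not a
#' physical water model.
#'
#' @param n_frames Number of frames.
#' @param z_range Ion path endpoints, Angstrom.
#' @param n_bulk,n_filter Shell occupancy at the two ends.
#' @param z_switch,width Logistic midpoint and width, Angstrom.
#' @param shell_radius Shell placement radius, Angstrom (< 3).
#' @param n_far Far (uncounted) waters per frame.
#' @param seed RNG seed.
#' @return A list: `frames` (coordinate data.frame, waters labelled
#'   `"OW"`), `expected` data.frame (`z`, `mean_count`) of the configured
#'   profile.
#' @export
make_hydration_fixture <- function(n_frames = 500, z_range = c(0, 25),
                                   n_bulk = 6, n_filter = 0.5,
                                   z_switch = 6.5, width = 1.2,
                                   shell_radius = 2.5, n_far = 10,
                                   seed = 1) {
  set.seed(seed)
  zi <- seq(z_range[1], z_range[2], length.out = n_frames)
  p_mean <- n_filter + (n_bulk - n_filter) / (1 + exp((zi - z_switch) / width))
  rows <- vector("list", n_frames)
  for (r in seq_len(n_frames)) {
    n_shell <- rbinom(1, n_bulk, p_mean[r] / n_bulk)
    ion <- data.frame(frame = r, label = "ion", x = 0, y = 0, z = zi[r])
    shell <- NULL
    if (n_shell > 0) {
      th <- runif(n_shell, 0, pi); ph <- runif(n_shell, 0, 2 * pi)
      shell <- data.frame(frame = r, label = "OW",
                          x = shell_radius * sin(th) * cos(ph),
                          y = shell_radius * sin(th) * sin(ph),
                          z = zi[r] + shell_radius * cos(th))
    }
    far <- data.frame(frame = r, label = "OW",
                      x = runif(n_far, 20, 30), y = runif(n_far, 20, 30),
                      z = runif(n_far, -30, -20))
    rows[[r]] <- rbind(ion, shell, far)
  }
  list(frames = do.call(rbind, rows),
       expected = data.frame(z = zi, mean_count = p_mean))
}

#' Synthetic axial-dispersion fixture
#'
#' Atoms of one label drawn around `reference + offsets` (one cluster per
#' offset), emulating carbonyl oxygens distributed above/below a reference
#' plane.
#'
#' @param n Atoms per cluster arrangement (total rows = n).
#' @param offsets Cluster offsets from the reference plane, Angstrom; a
#'   single offset gives a unimodal fixture.
#' @param sd Within-cluster SD, Angstrom.
#' @param reference Reference plane z, Angstrom.
#' @param label Atom label.
#' @param seed RNG seed.
#' @return A coordinate data.frame (with one `"ion"` row per frame so the
#'   frame is well-formed).
#' @export
make_dispersion_fixture <- function(n = 2000, offsets = c(-0.75, 0.75),
                                    sd = 0.1, reference = 10,
                                    label = "O_carbonyl", seed = 1) {
  set.seed(seed)
  cl <- sample(offsets, n, replace = TRUE)
  at <- data.frame(frame = seq_len(n), label = label,
                   x = rnorm(n, 0, 0.2), y = rnorm(n, 0, 0.2),
                   z = reference + cl + rnorm(n, 0, sd))
  ion <- data.frame(frame = seq_len(n), label = "ion", x = 0, y = 0, z = 0)
  rbind(at, ion)
}
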