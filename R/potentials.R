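# 1D potentials for the synthetic Langevin engine. Each constructor returns
# a `potential1d` object carrying a type code and parameter list understood
# by the compiled evaluator, so that R-side evaluation and the integrator
# share one implementation of energy(z) and force(z) = -dU/dz.

new_potential1d <- function(form, type_code, par, domain, label = form) {
  structure(
    list(form = form, type_code = type_code, par = par,
         domain = domain, label = label),
    class = "potential1d"
  )
}

#' Harmonic potential U(z) = a (z - center)^2 / 2
#'
#' A flat potential (free diffusion) is obtained with `a = 0`.
#'
#' @param a Curvature in kcal/mol/A^2 (>= 0).
#' @param center Minimum position, Angstrom.
#' @param domain Numeric length-2 working domain, Angstrom.
#' @return A `potential1d` object.
#' @export
potential_harmonic <- function(a, center = 0, domain = c(-50, 50)) {
  stopifnot(is.numeric(a), length(a) == 1, is.finite(a), a >= 0)
  new_potential1d("harmonic", 1L, list(a = a, center = center), domain)
}

#' Symmetric double-well potential
#'
#' U(z) = height * ((z - center)^2 - half_width^2)^2 / half_width^4, with
#' minima at `center +- half_width` (U = 0) and a barrier of `height`
#' kcal/mol at `center`.
#'
#' @param height Barrier height, kcal/mol (> 0).
#' @param center Barrier-top position, Angstrom.
#' @param half_width Distance from barrier top to each minimum, Angstrom.
#' @param domain Working domain, Angstrom; the default covers the region a
#'   trajectory can realistically sample (the quartic's curvature grows
#'   without bound, so an over-wide domain makes the stability guard
#'   needlessly conservative).
#' @return A `potential1d` object.
#' @export
potential_double_well <- function(height, center = 0, half_width = 1,
                                  domain = center + c(-3, 3) * half_width) {
  stopifnot(height > 0, half_width > 0)
  new_potential1d("double_well", 2L,
                  list(height = height, center = center,
                       half_width = half_width), domain)
}

#' Multi-well potential: sum of Gaussian wells with confining walls
#'
#' U(z) = -sum_m depth_m exp(-(z - center_m)^2 / (2 width_m^2)) plus a
#' quadratic wall of stiffness `k_wall` outside `[zlo, zhi]`. Smooth
#' everywhere, so the analytic force matches central differences.
#'
#' @param centers Well centers, Angstrom.
#' @param depths Well depths, kcal/mol (> 0).
#' @param widths Gaussian SD widths, Angstrom (> 0); recycled.
#' @param zlo,zhi Wall positions, Angstrom.
#' @param k_wall Wall stiffness, kcal/mol/A^2.
#' @param label Optional label stored with the potential.
#' @return A `potential1d` object.
#' @export
potential_multiwell <- function(centers, depths, widths = 0.5,
                                zlo = 0, zhi = 25, k_wall = 10,
                                label = "multiwell") {
  stopifnot(length(centers) >= 1, all(depths > 0), all(widths > 0),
            zhi > zlo, k_wall >= 0)
  widths <- rep_len(widths, length(centers))
  depths <- rep_len(depths, length(centers))
  new_potential1d("piecewise_multiwell", 3L,
                  list(centers = as.numeric(centers),
                       depths = as.numeric(depths),
                       widths = as.numeric(widths),
                       zlo = zlo, zhi = zhi, k_wall = k_wall),
                  c(zlo, zhi), label)
}

# natural cubic spline coefficients for the tabulated form
natural_spline_coefs <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  if (n < 3) stop("tabulated potential needs at least 3 knots")
  # solve tridiagonal system for second derivatives M (natural: M1 = Mn = 0)
  M <- numeric(n)
  if (n > 2) {
    a <- h[1:(n - 2)]
    b <- 2 * (h[1:(n - 2)] + h[2:(n - 1)])
    cc <- h[2:(n - 1)]
    d <- 6 * (diff(y)[2:(n - 1)] / h[2:(n - 1)] -
                diff(y)[1:(n - 2)] / h[1:(n - 2)])
    m <- n - 2
    # Thomas algorithm
    for (i in seq_len(m - 1)) {
      w <- a[i + 1] / b[i]
      b[i + 1] <- b[i + 1] - w * cc[i]
      d[i + 1] <- d[i + 1] - w * d[i]
    }
    sol <- numeric(m)
    sol[m] <- d[m] / b[m]
    if (m > 1) for (i in (m - 1):1) sol[i] <- (d[i] - cc[i] * sol[i + 1]) / b[i]
    M[2:(n - 1)] <- sol
  }
  k <- seq_len(n - 1)
  cbind(
    a = y[k],
    b = diff(y) / h - h * (2 * M[k] + M[k + 1]) / 6,
    c = M[k] / 2,
    d = (M[k + 1] - M[k]) / (6 * h)
  )
}

#' Tabulated potential interpolated by a natural cubic spline
#'
#' @param z Knot positions (strictly increasing), Angstrom.
#' @param energy Energies at the knots, kcal/mol.
#' @return A `potential1d` object; outside the knot range the boundary
#'   cubic is extrapolated.
#' @export
potential_tabulated <- function(z, energy) {
  stopifnot(length(z) == length(energy), all(diff(z) > 0),
            all(is.finite(z)), all(is.finite(energy)))
  new_potential1d("tabulated", 4L,
                  list(knots = as.numeric(z),
                       coefs = natural_spline_coefs(z, energy)),
                  range(z))
}

#' Evaluate potential energy
#' @param potential A `potential1d` object.
#' @param z Positions, Angstrom.
#' @return Energies in kcal/mol.
#' @export
potential_energy <- function(potential, z) {
  stopifnot(inherits(potential, "potential1d"))
  pot_eval_cpp(potential$type_code, potential$par, as.numeric(z))$energy
}

#' Evaluate potential force -dU/dz
#' @param potential A `potential1d` object.
#' @param z Positions, Angstrom.
#' @return Forces in kcal/mol/A.
#' @export
potential_force <- function(potential, z) {
  stopifnot(inherits(potential, "potential1d"))
  pot_eval_cpp(potential$type_code, potential$par, as.numeric(z))$force
}

#' @export
print.potential1d <- function(x, ...) {
  cat("<potential1d> form:", x$form, " domain: [",
      x$domain[1], ",", x$domain[2], "] A\n")
  invisible(x)
}

#' Harmonic bias U(z, lambda) = k (z - lambda)^2 / 2
#'
#' @param k Bias stiffness, kcal/mol/A^2.
#' @param lambda_center Bias center lambda, Angstrom.
#' @return A `bias_potential` object with fields `k` and `lambda_center`.
#' @export
bias_potential <- function(k, lambda_center) {
  stopifnot(k >= 0, is.finite(lambda_center))
  structure(list(k = k, lambda_center = lambda_center),
            class = "bias_potential")
}

#' Bias energy and force on the particle
#' @param bias A `bias_potential`.
#' @param z Positions, Angstrom.
#' @return Energy kcal/mol (`bias_energy`) or force kcal/mol/A
#'   (`bias_force`, equal to -k (z - lambda)).
#' @export
bias_energy <- function(bias, z) bias$k * (z - bias$lambda_center)^2 / 2

#' @rdname bias_energy
#' @export
bias_force <- function(bias, z) -bias$k * (z - bias$lambda_center)

#' Locate local minima of a potential by grid scan plus refinement
#'
#' Scans a grid, flags local minima with prominence above `min_depth`
#' (so numerically flat stretches are not reported), then refines each by
#' golden-section minimisation.
#'
#' @param potential A `potential1d`.
#' @param lower,upper Search interval, Angstrom (defaults: the domain).
#' @param n_grid Grid resolution.
#' @param min_depth Minimum prominence (kcal/mol) for a reported minimum.
#' @return Numeric vector of minima positions (Angstrom), ascending.
#' @export
find_minima <- function(potential, lower = potential$domain[1],
                        upper = potential$domain[2], n_grid = 2000,
                        min_depth = 0.05) {
  zg <- seq(lower, upper, length.out = n_grid)
  u <- potential_energy(potential, zg)
  n <- length(u)
  cand <- which(u[2:(n - 1)] <= u[1:(n - 2)] & u[2:(n - 1)] <= u[3:n]) + 1L
  # barrier height crossed walking from u[i] along idx until terrain drops
  # below u[i]; if it never does, the running maximum to the boundary
  side_barrier <- function(i, idx) {
    m <- -Inf
    for (j in idx) {
      if (u[j] > m) m <- u[j]
      if (u[j] < u[i]) break
    }
    m - u[i]
  }
  out <- numeric(0)
  for (i in cand) {
    left <- if (i > 1) side_barrier(i, (i - 1):1) else Inf
    right <- if (i < n) side_barrier(i, (i + 1):n) else Inf
    prom <- min(left, right)
    if (is.finite(prom) && prom > min_depth) {
      lo <- zg[max(1L, i - 2L)]
      hi <- zg[min(n, i + 2L)]
      out <- c(out, optimize(function(z) potential_energy(potential, z),
                             c(lo, hi))$minimum)
    }
  }
  # merge refinements that collapsed onto the same minimum
  out <- sort(out)
  if (length(out) > 1) out <- out[c(TRUE, diff(out) > 1e-3)]
  out
}

#' Species fixture potentials emulating multi-site ion binding
#'
#' Returns a documented multi-well potential on z in 0..25 Angstrom.
#' `"K_like"` has wells at the five crystallographic-like stable sites
#' (7.1, 10.4, 13.6, 17.0, 23.1 A); `"Na_like"` has a deep well just below
#' the filter entrance (5.5 A), a well between the first two sites (9.1 A),
#' a shallow exit-region well (22.5 A), and no wells in (12, 21) A. The
#' default depths make the Na-like entry barrier exceed the K-like one by
#' roughly 3.5 kcal/mol; they are qualitative emulations, not fits.
#'
#' @param species `"K_like"` or `"Na_like"`.
#' @param depths Optional replacement well depths (kcal/mol).
#' @return A `potential1d` object.
#' @export
make_species_fixture <- function(species = c("K_like", "Na_like"),
                                 depths = NULL) {
  species <- match.arg(species)
  if (species == "K_like") {
    centers <- c(7.1, 10.4, 13.6, 17.0, 23.1)
    if (is.null(depths)) depths <- c(3.5, 3.0, 3.0, 2.5, 1.5)
  } else {
    centers <- c(5.5, 9.1, 22.5)
    if (is.null(depths)) depths <- c(7.0, 2.0, 1.0)
  }
  stopifnot(length(depths) == length(centers))
  potential_multiwell(centers, depths, widths = 0.5, zlo = 0, zhi = 25,
                      k_wall = 10, label = species)
}
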