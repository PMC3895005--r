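#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Potential type codes shared with R/potentials.R:
//   1 = harmonic            par: a (kcal/mol/A^2), center (A)
//   2 = double_well         par: height (kcal/mol), center (A), half_width (A)
//   3 = multiwell           par: centers, depths, widths (vectors), zlo, zhi,
//                                k_wall (quadratic confinement outside [zlo, zhi])
//   4 = tabulated (cubic)   par: knots (ascending A), coefs (n-1 x 4: a,b,c,d)
//
// Energies in kcal/mol, positions in Angstrom, force = -dU/dz in kcal/mol/A.

static void pot_ef(int type, const List& par, double z, double& E, double& F) {
  switch (type) {
  case 1: {
    double a = as<double>(par["a"]);
    double c = as<double>(par["center"]);
    E = 0.5 * a * (z - c) * (z - c);
    F = -a * (z - c);
    break;
  }
  case 2: {
    double h = as<double>(par["height"]);
    double c = as<double>(par["center"]);
    double w = as<double>(par["half_width"]);
    double u = (z - c) * (z - c) - w * w;
    double w4 = w * w * w * w;
    E = h * u * u / w4;
    F = -4.0 * h * u * (z - c) / w4;
    break;
  }
  case 3: {
    NumericVector ctr = par["centers"];
    NumericVector dep = par["depths"];
    NumericVector wid = par["widths"];
    double zlo = as<double>(par["zlo"]);
    double zhi = as<double>(par["zhi"]);
    double kw  = as<double>(par["k_wall"]);
    E = 0.0; F = 0.0;
    for (R_xlen_t m = 0; m < ctr.size(); ++m) {
      double u = (z - ctr[m]) / wid[m];
      double g = dep[m] * std::exp(-0.5 * u * u);
      E -= g;
      F -= g * u / wid[m];
    }
    if (z < zlo) { E += 0.5 * kw * (z - zlo) * (z - zlo); F += -kw * (z - zlo); }
    if (z > zhi) { E += 0.5 * kw * (z - zhi) * (z - zhi); F += -kw * (z - zhi); }
    break;
  }
  case 4: {
    NumericVector x = par["knots"];
    NumericMatrix cf = par["coefs"]; // rows: intervals; cols: a,b,c,d
    R_xlen_t n = x.size();
    R_xlen_t k;
    if (z <= x[0]) k = 0;
    else if (z >= x[n - 1]) k = n - 2;
    else {
      // binary search for interval with x[k] <= z < x[k+1]
      R_xlen_t lo = 0, hi = n - 1;
      while (hi - lo > 1) {
        R_xlen_t mid = (lo + hi) / 2;
        if (x[mid] <= z) lo = mid; else hi = mid;
      }
      k = lo;
    }
    double t = z - x[k];
    double a = cf(k, 0), b = cf(k, 1), c = cf(k, 2), d = cf(k, 3);
    E = a + t * (b + t * (c + t * d));
    F = -(b + t * (2.0 * c + 3.0 * d * t));
    break;
  }
  default:
    stop("unknown potential type code: %d", type);
  }
}

//' @noRd
// [[Rcpp::export]]
List pot_eval_cpp(int type, List par, NumericVector z) {
  R_xlen_t n = z.size();
  NumericVector E(n), F(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double e, f;
    pot_ef(type, par, z[i], e, f);
    E[i] = e; F[i] = f;
  }
  return List::create(_["energy"] = E, _["force"] = F);
}

// Overdamped Euler-Maruyama integrator. Uses R's RNG stream so that
// set.seed() on the R side gives bit-identical trajectories.
// Samples are recorded every `sample_every` integration steps, starting
// at step `sample_every` (time = i * dt).
//' @noRd
// [[Rcpp::export]]
List simulate_cpp(int type, List par, double k_bias, double lambda,
                  double z0, double D, double kBT, double dt,
                  double duration, int sample_every) {
  long n_total = (long)std::floor(duration / dt + 0.5);
  if (n_total < 1) stop("duration shorter than one timestep");
  if (sample_every < 1) stop("sample_every must be >= 1");
  long n_keep = n_total / sample_every;
  NumericVector t_out(n_keep), z_out(n_keep);
  double mob = D / kBT;
  double sig = std::sqrt(2.0 * D * dt);
  double z = z0;
  long idx = 0;
  double E, F;
  for (long i = 1; i <= n_total; ++i) {
    pot_ef(type, par, z, E, F);
    double Ftot = F - k_bias * (z - lambda);
    z += mob * Ftot * dt + sig * norm_rand();
    if (!std::isfinite(z))
      stop("trajectory diverged at step %ld (non-finite position); "
           "check the stability criterion", i);
    if (i % sample_every == 0) {
      t_out[idx] = i * dt;
      z_out[idx] = z;
      ++idx;
    }
  }
  return List::create(_["time"] = t_out, _["z"] = z_out, _["z_final"] = z);
}
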