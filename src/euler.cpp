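#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step explicit Euler for the within-culture infection model on the
// flat state c(P[3], I[3x2 col-major], C[2]). Mirrors the reference
// fixed-step integration at step 0.001; trajectory is sampled every
// sample_dt time units (sample_dt <= 0: endpoint only).
//
// Negative-density policy: undershoots smaller in magnitude than
// 1e-12 * (current total density) are clamped to 0; anything larger stops
// with the time and variable index. Non-finite values stop likewise.
// [[Rcpp::export]]
List euler_integrate_cpp(NumericVector y0, NumericMatrix b,
                         NumericMatrix lam, NumericMatrix k,
                         NumericVector r, double duration, double step,
                         double sample_dt) {
  const int nP = 3, nH = 2, n = 11;
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> dy(n);

  long nsteps = (long)std::lround(duration / step);
  if (nsteps < 1) nsteps = 1;
  double h = duration / (double)nsteps;

  long rec_every = 0;
  if (sample_dt > 0) {
    rec_every = (long)std::lround(sample_dt / h);
    if (rec_every < 1) rec_every = 1;
  }
  std::vector<double> times;
  std::vector<double> traj;  // row-major rows of length n
  if (rec_every > 0) {
    times.push_back(0.0);
    traj.insert(traj.end(), y.begin(), y.end());
  }

  for (long s = 1; s <= nsteps; ++s) {
    // adsorption flux ads[i][j] = k_ij * P_i * C_j
    double dP[3], dC[2];
    double dI[3][2];
    for (int i = 0; i < nP; ++i) dP[i] = 0.0;
    for (int j = 0; j < nH; ++j) dC[j] = r[j] * y[9 + j];
    for (int j = 0; j < nH; ++j) {
      double C = y[9 + j];
      for (int i = 0; i < nP; ++i) {
        double I = y[3 + j * nP + i];
        double ads = k(i, j) * y[i] * C;
        double lys = lam(i, j) * I;
        dP[i] += b(i, j) * lys - ads;
        dI[i][j] = ads - lys;
        dC[j] -= ads;
      }
    }
    for (int i = 0; i < nP; ++i) dy[i] = dP[i];
    for (int j = 0; j < nH; ++j)
      for (int i = 0; i < nP; ++i) dy[3 + j * nP + i] = dI[i][j];
    for (int j = 0; j < nH; ++j) dy[9 + j] = dC[j];

    double total = 0.0;
    for (int v = 0; v < n; ++v) total += y[v];

    for (int v = 0; v < n; ++v) {
      y[v] += h * dy[v];
      if (!std::isfinite(y[v])) {
        stop("non-finite state at t=%f in variable %d", s * h, v + 1);
      }
      if (y[v] < 0) {
        if (-y[v] < 1e-12 * total) {
          y[v] = 0.0;
        } else {
          stop("negative density at t=%f in variable %d (%.3e); "
               "use a smaller step", s * h, v + 1, y[v]);
        }
      }
    }
    if (rec_every > 0 && (s % rec_every == 0 || s == nsteps)) {
      times.push_back(s * h);
      traj.insert(traj.end(), y.begin(), y.end());
    }
  }

  if (rec_every == 0) {
    times.push_back(duration);
    traj.insert(traj.end(), y.begin(), y.end());
  }
  int nrow = (int)times.size();
  NumericMatrix states(nrow, n);
  for (int rI = 0; rI < nrow; ++rI)
    for (int cI = 0; cI < n; ++cI) states(rI, cI) = traj[rI * n + cI];
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["states"] = states);
}
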