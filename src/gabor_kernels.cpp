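// Hot kernels for Gabor spike localisation.  The per-candidate refinement
// evaluates the quadrature projection energy hundreds of times per spike;
// these loops dominate the run time of reduce_emg on realistic recordings.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>

using namespace Rcpp;

// Projection energy of x onto {sin, cos} Gabor atoms over t0 +/- 4 sigma.
// Mirrors quad_fit(extra_hf = FALSE): returns 0 for degenerate windows.
static double quad_energy(const NumericVector& x, double fs, double t0,
                          double sigma, double f, double* r2_out = nullptr) {
  const int n = x.size();
  int i0 = (int)std::floor((t0 - 4.0 * sigma) * fs) + 1;  // 1-based
  int i1 = (int)std::ceil((t0 + 4.0 * sigma) * fs) + 1;
  if (i0 < 1) i0 = 1;
  if (i1 > n) i1 = n;
  const int m = i1 - i0 + 1;
  if (m < 4) return 0.0;
  const double w0 = 2.0 * M_PI * f;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double ss_ = 0, cc = 0, sc = 0, sy = 0, cy = 0, yy = 0;
  for (int i = 0; i < m; ++i) {
    const double tg = (i0 - 1 + i) / fs - t0;
    const double g = std::exp(-tg * tg * inv2s2);
    const double s = std::sin(w0 * tg) * g;
    const double c = std::cos(w0 * tg) * g;
    const double y = x[i0 - 1 + i];
    ss_ += s * s; cc += c * c; sc += s * c;
    sy += s * y; cy += c * y; yy += y * y;
  }
  const double det = ss_ * cc - sc * sc;
  if (det <= 1e-12 * (ss_ * cc + 1e-300)) return 0.0;
  const double b1 = (cc * sy - sc * cy) / det;
  const double b2 = (ss_ * cy - sc * sy) / det;
  const double energy = b1 * sy + b2 * cy;
  if (r2_out) *r2_out = yy > 0 ? energy / yy : 0.0;
  return std::isfinite(energy) ? energy : 0.0;
}

// [[Rcpp::export(name = ".gabor_quad_energy")]]
double gabor_quad_energy(NumericVector x, double fs, double t0, double sigma,
                         double f) {
  return quad_energy(x, fs, t0, sigma, f);
}

// Golden-section maximisation of projection energy over sigma (seconds).
static double golden_sigma(const NumericVector& x, double fs, double t0,
                           double f, double lo, double hi, double tol) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = quad_energy(x, fs, t0, c, f), fd = quad_energy(x, fs, t0, d, f);
  while (b - a > tol) {
    if (fc > fd) { b = d; d = c; fd = fc; c = b - gr * (b - a);
                   fc = quad_energy(x, fs, t0, c, f); }
    else         { a = c; c = d; fc = fd; d = a + gr * (b - a);
                   fd = quad_energy(x, fs, t0, d, f); }
  }
  return 0.5 * (a + b);
}

// Alternate sub-sample t0 hill-climbing (step = refine_step_s) with a
// sigma line search, maximising the projection energy.  Returns
// (t0, sigma, corr) where corr = sqrt(captured energy fraction).
// [[Rcpp::export(name = ".polish_spike_cpp")]]
NumericVector polish_spike_cpp(NumericVector x, double fs, double t0,
                               double sigma, double f, double step,
                               int max_steps, double sig_lo, double sig_hi,
                               int cycles) {
  double cur = quad_energy(x, fs, t0, sigma, f);
  for (int cy = 0; cy < cycles; ++cy) {
    const double t0_before = t0, sig_before = sigma;
    // hill climb on t0: try +, then - if + gave nothing
    for (int dirpass = 0; dirpass < 2; ++dirpass) {
      const double dir = dirpass == 0 ? 1.0 : -1.0;
      bool moved = false;
      for (int k = 0; k < max_steps; ++k) {
        const double cand = quad_energy(x, fs, t0 + dir * step, sigma, f);
        if (cand > cur) { t0 += dir * step; cur = cand; moved = true; }
        else break;
      }
      if (moved) break;
    }
    // sigma line search around the current value, widened if at an edge
    double lo = std::max(sig_lo, sigma / 2.5);
    double hi = std::min(sig_hi, sigma * 2.5);
    double s_new = golden_sigma(x, fs, t0, f, lo, hi, 2e-5);
    if (s_new - lo < 3e-5 || hi - s_new < 3e-5)
      s_new = golden_sigma(x, fs, t0, f, sig_lo, sig_hi, 2e-5);
    sigma = s_new;
    cur = quad_energy(x, fs, t0, sigma, f);
    if (std::fabs(t0 - t0_before) < step / 2 &&
        std::fabs(sigma - sig_before) < 2e-8) break;
  }
  double r2 = 0.0;
  quad_energy(x, fs, t0, sigma, f, &r2);
  NumericVector out(3);
  out[0] = t0; out[1] = sigma; out[2] = std::sqrt(std::max(r2, 0.0));
  return out;
}

// Solve the k x k normal equations by Gaussian elimination with partial
// pivoting; returns false on a degenerate pivot.
static bool solve_small(double A[4][4], double b[4], int k) {
  int piv[4] = {0, 1, 2, 3};
  for (int col = 0; col < k; ++col) {
    int best = col;
    for (int r = col + 1; r < k; ++r)
      if (std::fabs(A[piv[r]][col]) > std::fabs(A[piv[best]][col])) best = r;
    std::swap(piv[col], piv[best]);
    const double p = A[piv[col]][col];
    if (std::fabs(p) < 1e-12) return false;
    for (int r = col + 1; r < k; ++r) {
      const double m = A[piv[r]][col] / p;
      for (int c = col; c < k; ++c) A[piv[r]][c] -= m * A[piv[col]][c];
      b[piv[r]] -= m * b[piv[col]];
    }
  }
  double xout[4];
  for (int col = k - 1; col >= 0; --col) {
    double s = b[piv[col]];
    for (int c = col + 1; c < k; ++c) s -= A[piv[col]][c] * xout[c];
    xout[col] = s / A[piv[col]][col];
  }
  for (int c = 0; c < k; ++c) b[c] = xout[c];
  return true;
}

// Quadrature amplitude fit and canonical-atom subtraction over the support
// window t0 +/- 4 sigma.  The subtracted waveform is evaluated with the
// same expression (and operation order) as the R-level atom reconstruction
// so that corrected = input - sum(inventory atoms) holds exactly.
// Returns list(ok, i0, values, A, phi, A2, phi2, corr) with 1-based i0.
// [[Rcpp::export(name = ".fit_subtract_cpp")]]
List fit_subtract_cpp(NumericVector x, double fs, double t0, double sigma,
                      double f, bool extra_hf) {
  const int n = x.size();
  int i0 = (int)std::floor((t0 - 4.0 * sigma) * fs) + 1;
  int i1 = (int)std::ceil((t0 + 4.0 * sigma) * fs) + 1;
  if (i0 < 1 || i1 > n) return List::create(Named("ok") = false);
  const int m = i1 - i0 + 1;
  if (m < 4) return List::create(Named("ok") = false);
  const int k = extra_hf ? 4 : 2;
  std::vector<double> bs(m), bc(m), bs2(m), bc2(m), tgv(m), gv(m), wv(m);
  double XtX[4][4] = {{0}}, Xty[4] = {0};
  double yy = 0;
  for (int i = 0; i < m; ++i) {
    const double tg = (double)(i0 - 1 + i) / fs - t0;
    const double g = std::exp(-(tg * tg) / (2 * sigma * sigma));
    const double w = 2 * M_PI * f * tg;
    tgv[i] = tg; gv[i] = g; wv[i] = w;
    bs[i] = std::sin(w) * g;
    bc[i] = std::cos(w) * g;
    if (extra_hf) {
      bs2[i] = std::sin(2 * w) * g;
      bc2[i] = std::cos(2 * w) * g;
    }
    const double y = x[i0 - 1 + i];
    const double col[4] = {bs[i], bc[i], extra_hf ? bs2[i] : 0.0,
                           extra_hf ? bc2[i] : 0.0};
    for (int a = 0; a < k; ++a) {
      for (int b = a; b < k; ++b) XtX[a][b] += col[a] * col[b];
      Xty[a] += col[a] * y;
    }
    yy += y * y;
  }
  for (int a = 1; a < 4; ++a)
    for (int b = 0; b < a; ++b) XtX[a][b] = XtX[b][a];
  const double scale = XtX[0][0] + XtX[1][1] + 1e-300;
  double beta[4] = {Xty[0], Xty[1], Xty[2], Xty[3]};
  double M[4][4];
  std::memcpy(M, XtX, sizeof(M));
  if (!solve_small(M, beta, k) ||
      XtX[0][0] < 1e-10 * scale || XtX[1][1] < 1e-10 * scale)
    return List::create(Named("ok") = false);
  const double A = std::sqrt(beta[0] * beta[0] + beta[1] * beta[1]);
  const double phi = std::atan2(beta[1], beta[0]);
  double A2 = 0, phi2 = 0;
  if (extra_hf) {
    A2 = std::sqrt(beta[2] * beta[2] + beta[3] * beta[3]);
    phi2 = std::atan2(beta[3], beta[2]);
  }
  // canonical atom, same expression as the R-level reconstruction
  NumericVector vals(m);
  double vy = 0, vv = 0;
  for (int i = 0; i < m; ++i) {
    double v = A * std::sin(2 * M_PI * f * tgv[i] + phi) * gv[i];
    if (A2 != 0.0) v = v + A2 * std::sin(2 * M_PI * (2 * f) * tgv[i] + phi2) * gv[i];
    vals[i] = v;
    const double y = x[i0 - 1 + i];
    vy += v * y; vv += v * v;
  }
  const double corr = (yy > 0 && vv > 0) ? vy / std::sqrt(yy * vv) : 0.0;
  return List::create(Named("ok") = true, Named("i0") = i0,
                      Named("values") = vals, Named("A") = A,
                      Named("phi") = phi, Named("A2") = A2,
                      Named("phi2") = phi2, Named("corr") = corr);
}

// Full per-candidate chain for one channel: locate -> sigma estimate ->
// polish -> fit & subtract, sequentially over the supplied candidates
// (temporal order), each subtraction applied to the working copy before
// later candidates are evaluated.  Compiled because realistic recordings
// carry thousands of candidates.  Mirrors the R-level operations
// locate_center / estimate_sigma / polish_spike / fit_amplitude_and_subtract.
// [[Rcpp::export(name = ".reduce_channel_cpp")]]
List reduce_channel_cpp(NumericVector x_in, double fs, IntegerVector cands,
                        double corr_thresh, int search_n, int w_corr,
                        double f, NumericVector grid_ms,
                        NumericVector ratio_tab, int i_min_1based,
                        double refine_step, int max_steps, bool extra_hf) {
  NumericVector x = clone(x_in);
  const int n = x.size();
  const int h = std::max(2, w_corr / 2);
  const int n1 = std::max(1, (int)std::lround(0.001 * fs));
  const int ng = grid_ms.size();
  const int i_min = i_min_1based - 1;
  const double sig_lo = grid_ms[0] / 1000.0, sig_hi = grid_ms[ng - 1] / 1000.0;
  std::vector<double> out_rows;
  int n_acc = 0;

  for (int ci_idx = 0; ci_idx < cands.size(); ++ci_idx) {
    const int cand = cands[ci_idx];           // 1-based
    // ---- locate: most negative sliding-window corr of paired d1/d3 ----
    int j_lo = std::max(cand - search_n, h + 1);
    int j_hi = std::min(cand + search_n, n - 3 - h);
    if (j_lo > j_hi) continue;
    double best_r = 1.0; int best_j = -1;
    for (int j = j_lo; j <= j_hi; ++j) {
      // pairs k = (j-h) .. (j+h-1), 1-based k; a[k]=x[k+1]-x[k] (d1),
      // b[k]=x[k+3]-3x[k+2]+3x[k+1]-x[k] (d3)
      double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
      const int k0 = j - h, k1 = j + h - 1;
      if (k0 < 1 || k1 + 3 > n) continue;
      for (int k = k0; k <= k1; ++k) {
        const double a = x[k] - x[k - 1];
        const double b = x[k + 2] - 3 * x[k + 1] + 3 * x[k] - x[k - 1];
        sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
      }
      const int nw = k1 - k0 + 1;
      const double va = saa - sa * sa / nw, vb = sbb - sb * sb / nw;
      const double den = std::sqrt(std::max(va * vb, 0.0));
      const double r = den > 0 ? (sab - sa * sb / nw) / den : 0.0;
      if (r < best_r) { best_r = r; best_j = j; }
    }
    if (best_j < 0 || best_r > corr_thresh) continue;
    const int center = best_j;

    // ---- sigma: gradient-ratio table inversion (invertible branch) ----
    double sig_ms = -1.0;
    bool ambiguous = false;
    if (center - n1 - 1 >= 1 && center + 1 <= n) {
      const double g0 = (x[center] - x[center - 2]) / 2.0;
      const double g1 = (x[center - n1] - x[center - n1 - 2]) / 2.0;
      if (std::isfinite(g0) && std::isfinite(g1) &&
          std::fabs(g1) > 1e-9 * std::max(std::fabs(g0), 1e-12)) {
        const double r = g0 / g1;
        const int bs = i_min;                 // branch start (0-based)
        const double r_hi = ratio_tab[bs];    // largest (near the pole)
        const double r_lo = ratio_tab[ng - 1];
        if (!std::isfinite(r)) {
          // grid search below
        } else if (r <= 0.0) {
          sig_ms = grid_ms[0];
          ambiguous = true;
        } else if (r >= r_hi) {
          sig_ms = grid_ms[bs];
          ambiguous = true;
        } else if (r <= r_lo) {
          sig_ms = grid_ms[ng - 1];
          ambiguous = r < r_lo - 0.05;
        } else {
          for (int i = bs; i < ng - 1; ++i)   // decreasing in i
            if (r <= ratio_tab[i] && r >= ratio_tab[i + 1]) {
              const double w = (ratio_tab[i] - r) / (ratio_tab[i] - ratio_tab[i + 1]);
              sig_ms = grid_ms[i] + w * (grid_ms[i + 1] - grid_ms[i]);
              break;
            }
          if (sig_ms < 0) sig_ms = grid_ms[bs];
        }
      }
    }
    const double t0_init = (center - 1) / fs;
    if (sig_ms < 0 || ambiguous) {
      double best_e = -1.0;
      for (int i = 0; i < ng; i += 5) {
        const double e = quad_energy(x, fs, t0_init, grid_ms[i] / 1000.0, f);
        if (e > best_e) { best_e = e; sig_ms = grid_ms[i]; }
      }
    }

    // ---- polish (t0 hill climb alternated with sigma line search) ----
    double t0 = t0_init, sigma = sig_ms / 1000.0;
    {
      double cur = quad_energy(x, fs, t0, sigma, f);
      for (int cy = 0; cy < 3; ++cy) {
        const double t0b = t0, sgb = sigma;
        for (int dirpass = 0; dirpass < 2; ++dirpass) {
          const double dir = dirpass == 0 ? 1.0 : -1.0;
          bool moved = false;
          for (int k = 0; k < max_steps; ++k) {
            const double c2 = quad_energy(x, fs, t0 + dir * refine_step, sigma, f);
            if (c2 > cur) { t0 += dir * refine_step; cur = c2; moved = true; }
            else break;
          }
          if (moved) break;
        }
        double lo = std::max(sig_lo, sigma / 2.5), hi = std::min(sig_hi, sigma * 2.5);
        double s_new = golden_sigma(x, fs, t0, f, lo, hi, 2e-5);
        if (s_new - lo < 3e-5 || hi - s_new < 3e-5)
          s_new = golden_sigma(x, fs, t0, f, sig_lo, sig_hi, 2e-5);
        sigma = s_new;
        cur = quad_energy(x, fs, t0, sigma, f);
        if (std::fabs(t0 - t0b) < refine_step / 2 && std::fabs(sigma - sgb) < 2e-8)
          break;
      }
    }

    // ---- amplitude fit + canonical subtraction ----
    List ft = fit_subtract_cpp(x, fs, t0, sigma, f, extra_hf);
    if (!as<bool>(ft["ok"])) continue;
    NumericVector vals = ft["values"];
    const int i0 = as<int>(ft["i0"]);
    for (int i = 0; i < vals.size(); ++i) x[i0 - 1 + i] -= vals[i];
    ++n_acc;
    out_rows.push_back(t0);
    out_rows.push_back(sigma * 1000.0);
    out_rows.push_back(f);
    out_rows.push_back(as<double>(ft["phi"]));
    out_rows.push_back(as<double>(ft["A"]));
    out_rows.push_back(as<double>(ft["A2"]));
    out_rows.push_back(as<double>(ft["phi2"]));
    out_rows.push_back(as<double>(ft["corr"]));
  }
  NumericMatrix inv(n_acc, 8);
  for (int r = 0; r < n_acc; ++r)
    for (int c = 0; c < 8; ++c) inv(r, c) = out_rows[r * 8 + c];
  return List::create(Named("x") = x, Named("inventory") = inv);
}
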