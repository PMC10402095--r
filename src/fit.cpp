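#include <Rcpp.h>
using namespace Rcpp;

// Asymmetric Gaussian similarity model:
//   yhat(d) = b + A * exp(-d^2 / (2 * sigma^2)),  sigma = sigma_b if d < 0 else sigma_f
// Penalized objective: sum_j (y_j - yhat(d_j))^2 + lambda * (A^2 + b^2).
// For fixed widths the objective is quadratic in (A, b), so A and b are
// profiled out in closed form (2x2 ridge solve) and the numerical search runs
// over the two widths only, bounded to [smin, smax].

static const int MAX_PTS = 16;

static inline double gaussw(double d, double sf, double sb) {
  double s = (d < 0.0) ? sb : sf;
  return std::exp(-(d * d) / (2.0 * s * s));
}

static double eval_obj(const double* d, const double* y, int m,
                       double sf, double sb, double lam,
                       double smin, double smax,
                       double* A_out, double* b_out, double* sse_out) {
  if (sf < smin) sf = smin;
  if (sf > smax) sf = smax;
  if (sb < smin) sb = smin;
  if (sb > smax) sb = smax;
  double g[MAX_PTS];
  double Sgg = 0.0, Sg = 0.0, Sgy = 0.0, Sy = 0.0;
  for (int j = 0; j < m; ++j) {
    g[j] = gaussw(d[j], sf, sb);
    Sgg += g[j] * g[j];
    Sg  += g[j];
    Sgy += g[j] * y[j];
    Sy  += y[j];
  }
  double a11 = Sgg + lam, a12 = Sg, a22 = (double)m + lam;
  double det = a11 * a22 - a12 * a12;
  double A = ( a22 * Sgy - a12 * Sy) / det;
  double b = (-a12 * Sgy + a11 * Sy) / det;
  double sse = 0.0;
  for (int j = 0; j < m; ++j) {
    double r = y[j] - b - A * g[j];
    sse += r * r;
  }
  if (A_out)   *A_out = A;
  if (b_out)   *b_out = b;
  if (sse_out) *sse_out = sse;
  return sse + lam * (A * A + b * b);
}

// Nelder-Mead over (sigma_f, sigma_b); objective clamps into bounds.
static double nelder_mead(const double* d, const double* y, int m, double lam,
                          double smin, double smax, double s0f, double s0b,
                          double* xf, double* xb,
                          double ftol = 1e-13, double dtol = 5e-9,
                          int max_iter = 300) {
  double vx[3][2];
  double fv[3];
  vx[0][0] = s0f;        vx[0][1] = s0b;
  vx[1][0] = s0f * 1.25; vx[1][1] = s0b;
  vx[2][0] = s0f;        vx[2][1] = s0b * 1.25;
  for (int i = 0; i < 3; ++i)
    fv[i] = eval_obj(d, y, m, vx[i][0], vx[i][1], lam, smin, smax, 0, 0, 0);

  for (int iter = 0; iter < max_iter; ++iter) {
    // order vertices: lo best, hi worst, mid the other (stable in index)
    int lo = 0, hi = 0;
    for (int i = 1; i < 3; ++i) {
      if (fv[i] < fv[lo]) lo = i;
      if (fv[i] > fv[hi]) hi = i;
    }
    if (hi == lo) hi = (lo + 1) % 3;
    int mid = 3 - lo - hi;

    double diam = 0.0;
    for (int i = 0; i < 3; ++i) {
      double dx = vx[i][0] - vx[lo][0], dy = vx[i][1] - vx[lo][1];
      double dd = std::sqrt(dx * dx + dy * dy);
      if (dd > diam) diam = dd;
    }
    if (fv[hi] - fv[lo] < ftol * (1.0 + std::fabs(fv[lo])) && diam < dtol) break;

    double cx = 0.5 * (vx[lo][0] + vx[mid][0]);
    double cy = 0.5 * (vx[lo][1] + vx[mid][1]);
    double rx = cx + (cx - vx[hi][0]);
    double ry = cy + (cy - vx[hi][1]);
    double fr = eval_obj(d, y, m, rx, ry, lam, smin, smax, 0, 0, 0);
    if (fr < fv[lo]) {
      double ex = cx + 2.0 * (cx - vx[hi][0]);
      double ey = cy + 2.0 * (cy - vx[hi][1]);
      double fe = eval_obj(d, y, m, ex, ey, lam, smin, smax, 0, 0, 0);
      if (fe < fr) { vx[hi][0] = ex; vx[hi][1] = ey; fv[hi] = fe; }
      else         { vx[hi][0] = rx; vx[hi][1] = ry; fv[hi] = fr; }
    } else if (fr < fv[mid]) {
      vx[hi][0] = rx; vx[hi][1] = ry; fv[hi] = fr;
    } else {
      double ccx, ccy, fc;
      if (fr < fv[hi]) {  // outside contraction
        ccx = cx + 0.5 * (rx - cx);
        ccy = cy + 0.5 * (ry - cy);
      } else {            // inside contraction
        ccx = cx + 0.5 * (vx[hi][0] - cx);
        ccy = cy + 0.5 * (vx[hi][1] - cy);
      }
      fc = eval_obj(d, y, m, ccx, ccy, lam, smin, smax, 0, 0, 0);
      if (fc < std::min(fr, fv[hi])) {
        vx[hi][0] = ccx; vx[hi][1] = ccy; fv[hi] = fc;
      } else {            // shrink toward best
        for (int i = 0; i < 3; ++i) {
          if (i == lo) continue;
          vx[i][0] = vx[lo][0] + 0.5 * (vx[i][0] - vx[lo][0]);
          vx[i][1] = vx[lo][1] + 0.5 * (vx[i][1] - vx[lo][1]);
          fv[i] = eval_obj(d, y, m, vx[i][0], vx[i][1], lam, smin, smax, 0, 0, 0);
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < 3; ++i) if (fv[i] < fv[lo]) lo = i;
  *xf = std::min(std::max(vx[lo][0], smin), smax);
  *xb = std::min(std::max(vx[lo][1], smin), smax);
  return fv[lo];
}

// core fit used everywhere: a width start grid covering narrow-spike through
// near-flat basins is screened by direct evaluation, the best starts are
// refined by Nelder-Mead, and the winner is polished with tight tolerances
// (this also makes mirrored profiles converge to mirrored solutions to high
// precision). Ties broken toward the narrower (sf+sb) solution.
static void fit_core(const double* d, const double* y, int m,
                     double lam, double smin, double smax,
                     double* A, double* b, double* sf, double* sb,
                     double* sse, double* obj) {
  // canonical orientation: fit whichever of the profile and its mirror is
  // lexicographically smaller (values read along ascending offset), then
  // swap the widths back. Reflected inputs thus follow bit-identical
  // arithmetic and the fit is exactly mirror-equivariant.
  {
    int ord[MAX_PTS], mord[MAX_PTS];
    for (int j = 0; j < m; ++j) ord[j] = mord[j] = j;
    for (int a = 1; a < m; ++a) {        // insertion sort by d / by -d
      int ka = ord[a], kb = mord[a];
      int i = a - 1;
      while (i >= 0 && d[ord[i]] > d[ka]) { ord[i + 1] = ord[i]; --i; }
      ord[i + 1] = ka;
      i = a - 1;
      while (i >= 0 && -d[mord[i]] > -d[kb]) { mord[i + 1] = mord[i]; --i; }
      mord[i + 1] = kb;
    }
    bool mirror = false;
    for (int j = 0; j < m; ++j) {
      if (y[mord[j]] < y[ord[j]]) { mirror = true; break; }
      if (y[ord[j]] < y[mord[j]]) break;
    }
    // re-emit the points sorted by (possibly negated) offset so both
    // orientations of the same profile produce bit-identical arrays
    bool sorted = !mirror;
    if (sorted) for (int j = 0; j < m; ++j) if (ord[j] != j) sorted = false;
    if (mirror || !sorted) {
      double dc[MAX_PTS], yc[MAX_PTS];
      const int* use = mirror ? mord : ord;
      for (int j = 0; j < m; ++j) {
        dc[j] = mirror ? -d[use[j]] : d[use[j]];
        yc[j] = y[use[j]];
      }
      if (mirror) fit_core(dc, yc, m, lam, smin, smax, A, b, sb, sf, sse, obj);
      else        fit_core(dc, yc, m, lam, smin, smax, A, b, sf, sb, sse, obj);
      return;
    }
  }
  static const double starts[7] = {0.1, 0.25, 0.5, 1.0, 2.0, 4.0, 8.0};
  const int NS = 7, NG = NS * NS, NPICK = 4;
  double gf[NG];
  int k = 0;
  for (int i = 0; i < NS; ++i) {
    for (int j = 0; j < NS; ++j) {
      gf[k] = eval_obj(d, y, m, starts[i], starts[j], lam, smin, smax, 0, 0, 0);
      ++k;
    }
  }
  // indices of the best grid points (stable selection)
  int pick[NPICK];
  for (int t = 0; t < NPICK; ++t) {
    int besti = -1;
    for (int i = 0; i < NG; ++i) {
      bool used = false;
      for (int u = 0; u < t; ++u) if (pick[u] == i) used = true;
      if (used) continue;
      if (besti < 0 || gf[i] < gf[besti]) besti = i;
    }
    pick[t] = besti;
  }
  double best_f = R_PosInf, best_sf = 1.0, best_sb = 1.0;
  for (int t = 0; t < NPICK; ++t) {
    double s0f = starts[pick[t] / NS], s0b = starts[pick[t] % NS];
    double xf, xb;
    double f = nelder_mead(d, y, m, lam, smin, smax, s0f, s0b, &xf, &xb);
    bool better = f < best_f - 1e-12;
    bool tie = std::fabs(f - best_f) <= 1e-12 && (xf + xb < best_sf + best_sb);
    if (better || tie) { best_f = f; best_sf = xf; best_sb = xb; }
  }
  // final polish: restarted Nelder-Mead from the winning basin (restarts
  // re-inflate the simplex and break collapse-induced stagnation)
  for (int r = 0; r < 3; ++r) {
    double xf, xb;
    double f = nelder_mead(d, y, m, lam, smin, smax, best_sf, best_sb,
                           &xf, &xb, 1e-15, 1e-11, 500);
    if (f <= best_f) { best_f = f; best_sf = xf; best_sb = xb; }
  }
  // below sigma ~ 0.1 the basis underflows to an indicator at d = 0, so the
  // objective is numerically flat in that width; collapse such plateaus to
  // the narrow bound (the narrower-solution tie-break, made canonical)
  {
    double tolf = 1e-13 * (1.0 + std::fabs(best_f));
    double cand[3][2] = {{smin, best_sb}, {best_sf, smin}, {smin, smin}};
    double bsum = best_sf + best_sb;
    for (int c = 2; c >= 0; --c) {
      double f = eval_obj(d, y, m, cand[c][0], cand[c][1], lam, smin, smax,
                          0, 0, 0);
      if (f <= best_f + tolf && cand[c][0] + cand[c][1] < bsum) {
        best_sf = cand[c][0];
        best_sb = cand[c][1];
        bsum = best_sf + best_sb;
        if (f < best_f) best_f = f;
        break;
      }
    }
  }
  *sf = best_sf;
  *sb = best_sb;
  *obj = eval_obj(d, y, m, best_sf, best_sb, lam, smin, smax, A, b, sse);
}

// [[Rcpp::export]]
NumericVector cpp_fit_profile(NumericVector y, NumericVector d,
                              double penalty, double width_max) {
  int m = y.size();
  if (m > MAX_PTS) stop("too many profile points");
  double A, b, sf, sb, sse, obj;
  fit_core(REAL(d), REAL(y), m, penalty, 1e-3, width_max,
           &A, &b, &sf, &sb, &sse, &obj);
  NumericVector out = NumericVector::create(
    _["A"] = A, _["b"] = b, _["sigma_f"] = sf, _["sigma_b"] = sb,
    _["sse"] = sse, _["objective"] = obj);
  return out;
}

// mean leave-one-out SSE: for each row i, fit on the column means of the other
// rows and score unpenalized SSE on row i
static double loo_error_core(const double* P, int n, int m, const double* d,
                             double lam, double smax) {
  std::vector<double> colsum(m, 0.0);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) colsum[j] += P[i + (size_t)j * n];
  double total = 0.0;
  std::vector<double> mu(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j)
      mu[j] = (colsum[j] - P[i + (size_t)j * n]) / (double)(n - 1);
    double A, b, sf, sb, sse, obj;
    fit_core(d, mu.data(), m, lam, 1e-3, smax, &A, &b, &sf, &sb, &sse, &obj);
    double err = 0.0;
    for (int j = 0; j < m; ++j) {
      double r = P[i + (size_t)j * n] - (b + A * gaussw(d[j], sf, sb));
      err += r * r;
    }
    total += err;
  }
  return total / (double)n;
}

// [[Rcpp::export]]
double cpp_loo_error(NumericMatrix P, NumericVector d,
                     double penalty, double width_max) {
  int n = P.nrow(), m = P.ncol();
  if (n < 2) stop("need at least 2 rows");
  if (m != d.size()) stop("offset/point mismatch");
  return loo_error_core(REAL(P), n, m, REAL(d), penalty, width_max);
}

// SSE of fits to shuffled versions of a single profile (searchlight
// goodness-of-fit denominator). v holds the distinct values ordered by
// dist_d ascending (+4 last); each shuffle permutes them, rebuilds the full
// point vector (duplicating +4 at -4 when dup), fits, and records the
// unpenalized SSE. Uses R's RNG stream.
// [[Rcpp::export]]
NumericVector cpp_shuffled_fit_sse(NumericVector v, NumericVector dist_d,
                                   bool dup, double penalty, double width_max,
                                   int n_shuffles) {
  int k = v.size();
  if (k != dist_d.size()) stop("offset/value mismatch");
  int m = dup ? k + 1 : k;
  if (m > MAX_PTS) stop("too many profile points");
  std::vector<double> d(m), y(m), row(k);
  if (dup) {
    d[0] = -4.0;
    for (int j = 0; j < k; ++j) d[j + 1] = dist_d[j];
  } else {
    for (int j = 0; j < k; ++j) d[j] = dist_d[j];
  }
  NumericVector out(n_shuffles);
  for (int s = 0; s < n_shuffles; ++s) {
    for (int j = 0; j < k; ++j) row[j] = v[j];
    for (int j = k - 1; j > 0; --j) {
      int u = (int)std::floor(unif_rand() * (j + 1));
      if (u > j) u = j;
      std::swap(row[j], row[u]);
    }
    if (dup) {
      y[0] = row[k - 1];
      for (int j = 0; j < k; ++j) y[j + 1] = row[j];
    } else {
      for (int j = 0; j < k; ++j) y[j] = row[j];
    }
    double A, b, sf, sb, sse, obj;
    fit_core(d.data(), y.data(), m, penalty, 1e-3, width_max,
             &A, &b, &sf, &sb, &sse, &obj);
    out[s] = sse;
  }
  return out;
}

// Null distribution of the leave-one-out group error. V holds each
// participant's distinct similarity values (one per distinct circular
// position, ordered by dist_d ascending; the +4 value is last). Each shuffle
// permutes every row independently across the distinct positions, rebuilds the
// full point vector (duplicating the +4 value at -4 when dup is true), and
// recomputes the mean leave-one-out error. Uses R's RNG stream.
// [[Rcpp::export]]
NumericVector cpp_shuffled_null(NumericMatrix V, NumericVector dist_d,
                                bool dup, double penalty, double width_max,
                                int n_shuffles) {
  int n = V.nrow(), k = V.ncol();
  if (k != dist_d.size()) stop("offset/value mismatch");
  if (n_shuffles < 1) stop("n_shuffles must be >= 1");
  int m = dup ? k + 1 : k;
  if (m > MAX_PTS) stop("too many profile points");
  std::vector<double> d(m);
  if (dup) {
    d[0] = -4.0;
    for (int j = 0; j < k; ++j) d[j + 1] = dist_d[j];
  } else {
    for (int j = 0; j < k; ++j) d[j] = dist_d[j];
  }
  NumericVector out(n_shuffles);
  std::vector<double> P((size_t)n * m);
  std::vector<double> row(k);
  for (int s = 0; s < n_shuffles; ++s) {
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < k; ++j) row[j] = V(i, j);
      for (int j = k - 1; j > 0; --j) {   // Fisher-Yates
        int u = (int)std::floor(unif_rand() * (j + 1));
        if (u > j) u = j;
        std::swap(row[j], row[u]);
      }
      if (dup) {
        P[i] = row[k - 1];                // value landing at +4 duplicated at -4
        for (int j = 0; j < k; ++j) P[i + (size_t)(j + 1) * n] = row[j];
      } else {
        for (int j = 0; j < k; ++j) P[i + (size_t)j * n] = row[j];
      }
    }
    out[s] = loo_error_core(P.data(), n, m, d.data(), penalty, width_max);
  }
  return out;
}
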