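// Core numerics for the multi-gradient cellular automaton: spectral-angle
// gradient extraction at window sizes 3/5/7, rotation/reflection-invariant
// rule matching, the directed weighted-average state update, and the
// synchronous iteration loop.  Kept in C++ because rule evolution runs the
// automaton thousands of times per training session.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double EPS_NORM = 1e-12;

// symmetric reflect padding: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

struct Cube {
  const double *x;
  int H, W, B;
  inline double at(int r, int c, int b) const {
    return x[r + (size_t)H * c + (size_t)H * W * b];
  }
};

// unit-normalized spectra stored pixel-major (each spectrum contiguous);
// zero-norm pixels are flagged and contribute angle 0 by convention
struct NormCube {
  std::vector<double> v;
  std::vector<char> zero;
  int H, W, B;
  inline const double *at(int r, int c) const {
    return &v[(size_t)B * (r + (size_t)H * c)];
  }
  inline bool is_zero(int r, int c) const { return zero[r + (size_t)H * c] != 0; }
};

static void normalize_pixels(const Cube &img, NormCube &nc) {
  nc.H = img.H; nc.W = img.W; nc.B = img.B;
  nc.v.assign((size_t)img.H * img.W * img.B, 0.0);
  nc.zero.assign((size_t)img.H * img.W, 0);
  for (int c = 0; c < img.W; ++c)
    for (int r = 0; r < img.H; ++r) {
      double s = 0.0;
      for (int b = 0; b < img.B; ++b) { double x = img.at(r, c, b); s += x * x; }
      s = std::sqrt(s);
      double *out = &nc.v[(size_t)img.B * (r + (size_t)img.H * c)];
      if (s < EPS_NORM) { nc.zero[r + (size_t)img.H * c] = 1; continue; }
      for (int b = 0; b < img.B; ++b) out[b] = img.at(r, c, b) / s;
    }
}

// normalized spectral angle between two unit spectra via the numerically
// stable form 2 * atan2(||u - v||, ||u + v||); exactly 0 for identical
// spectra and well-conditioned at both ends, unlike acos of the cosine
static inline double sangle_unit(const double *u, const double *v, int B) {
  double dm = 0.0, dp = 0.0;
  for (int b = 0; b < B; ++b) {
    double d = u[b] - v[b], s = u[b] + v[b];
    dm += d * d; dp += s * s;
  }
  return (2.0 / M_PI) * 2.0 * std::atan2(std::sqrt(dm), std::sqrt(dp));
}

// gradient feature of one cell: fills g[6] = gx3, gy3, gx5, gy5, gx7, gy7
// masks are 3x3 / 5x5 / 7x7 column gradients; the row gradient uses the
// transpose.  x = column index, y = row index (increasing downward).
static void cell_gradients(const NormCube &img, int r, int c,
                           const NumericMatrix &mx3, const NumericMatrix &mx5,
                           const NumericMatrix &mx7, double g[6]) {
  for (int k = 0; k < 6; ++k) g[k] = 0.0;
  bool z0 = img.is_zero(r, c);
  const double *u0 = img.at(r, c);
  for (int dy = -3; dy <= 3; ++dy) {
    int rr = reflect_idx(r + dy, img.H);
    for (int dx = -3; dx <= 3; ++dx) {
      int cc = reflect_idx(c + dx, img.W);
      double a = (z0 || img.is_zero(rr, cc)) ? 0.0
                 : sangle_unit(u0, img.at(rr, cc), img.B);
      if (a == 0.0) continue;
      // 7x7 window always applies
      g[4] += a * mx7(dy + 3, dx + 3);
      g[5] += a * mx7(dx + 3, dy + 3);
      if (dy >= -2 && dy <= 2 && dx >= -2 && dx <= 2) {
        g[2] += a * mx5(dy + 2, dx + 2);
        g[3] += a * mx5(dx + 2, dy + 2);
      }
      if (dy >= -1 && dy <= 1 && dx >= -1 && dx <= 1) {
        g[0] += a * mx3(dy + 1, dx + 1);
        g[1] += a * mx3(dx + 1, dy + 1);
      }
    }
  }
}

// ---- rotation/reflection-invariant rule matching ------------------------

struct RuleCache {
  // rule condition vectors (ux, uy) at scales 3/5/7, and their moduli
  std::vector<double> ux, uy, mod;  // 3*M each
  std::vector<double> theta;        // M
  int M;
};

static RuleCache build_rule_cache(const NumericMatrix &rules) {
  RuleCache rc;
  rc.M = rules.nrow();
  rc.ux.resize(3 * rc.M); rc.uy.resize(3 * rc.M); rc.mod.resize(3 * rc.M);
  rc.theta.resize(rc.M);
  for (int k = 0; k < rc.M; ++k) {
    double m3 = rules(k, 0), m5 = rules(k, 1), m7 = rules(k, 2);
    double p5 = rules(k, 3), p7 = rules(k, 4);
    rc.ux[3 * k + 0] = m3;                 rc.uy[3 * k + 0] = 0.0;
    rc.ux[3 * k + 1] = m5 * std::cos(p5);  rc.uy[3 * k + 1] = m5 * std::sin(p5);
    rc.ux[3 * k + 2] = m7 * std::cos(p7);  rc.uy[3 * k + 2] = m7 * std::sin(p7);
    rc.mod[3 * k + 0] = std::fabs(m3);
    rc.mod[3 * k + 1] = std::fabs(m5);
    rc.mod[3 * k + 2] = std::fabs(m7);
    rc.theta[k] = rules(k, 5);
  }
  return rc;
}

// sum of unsquared norms ||g_m - R(phi) u_m|| from per-pair invariants
static inline double match_dist(double phi, const double cm[3],
                                const double dot[3], const double cr[3]) {
  double cp = std::cos(phi), sp = std::sin(phi), d = 0.0;
  for (int m = 0; m < 3; ++m) {
    double v = cm[m] - 2.0 * (cp * dot[m] + sp * cr[m]);
    d += std::sqrt(v > 0.0 ? v : 0.0);
  }
  return d;
}

// minimize the unsquared alignment distance over rotations for one
// reflection state.  Candidates: closed-form optimum of the squared
// objective, the three per-pair alignment angles and a coarse angular scan;
// the best candidate is polished by golden-section search.
static void min_over_rotation(const double gx[3], const double gy[3],
                              const double ux[3], const double uy[3],
                              int coarse, int golden,
                              double &best_d, double &best_phi) {
  double cm[3], dot[3], cr[3], sdot = 0.0, scr = 0.0;
  for (int m = 0; m < 3; ++m) {
    cm[m] = gx[m] * gx[m] + gy[m] * gy[m] + ux[m] * ux[m] + uy[m] * uy[m];
    dot[m] = gx[m] * ux[m] + gy[m] * uy[m];
    cr[m] = ux[m] * gy[m] - uy[m] * gx[m];
    sdot += dot[m]; scr += cr[m];
  }
  best_d = R_PosInf; best_phi = 0.0;
  double cand;
  cand = std::atan2(scr, sdot);
  { double d = match_dist(cand, cm, dot, cr); if (d < best_d) { best_d = d; best_phi = cand; } }
  for (int m = 0; m < 3; ++m) {
    cand = std::atan2(cr[m], dot[m]);
    double d = match_dist(cand, cm, dot, cr);
    if (d < best_d) { best_d = d; best_phi = cand; }
  }
  double step = 2.0 * M_PI / coarse;
  for (int i = 0; i < coarse; ++i) {
    double d = match_dist(i * step, cm, dot, cr);
    if (d < best_d) { best_d = d; best_phi = i * step; }
  }
  // golden-section polish on the bracket around the best candidate
  const double gr = 0.6180339887498949;
  double a = best_phi - step, b = best_phi + step;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = match_dist(x1, cm, dot, cr), f2 = match_dist(x2, cm, dot, cr);
  for (int i = 0; i < golden; ++i) {
    if (f1 < f2) { b = x2; x2 = x1; f2 = f1; x1 = b - gr * (b - a); f1 = match_dist(x1, cm, dot, cr); }
    else { a = x1; x1 = x2; f1 = f2; x2 = a + gr * (b - a); f2 = match_dist(x2, cm, dot, cr); }
  }
  if (f1 < best_d) { best_d = f1; best_phi = x1; }
  if (f2 < best_d) { best_d = f2; best_phi = x2; }
}

// candidate-only evaluation (no coarse scan / polish): cheap upper bound
static double quick_min(const double gx[3], const double gy[3],
                        const double ux[3], const double uy[3]) {
  double cm[3], dot[3], cr[3], sdot = 0.0, scr = 0.0;
  for (int m = 0; m < 3; ++m) {
    cm[m] = gx[m] * gx[m] + gy[m] * gy[m] + ux[m] * ux[m] + uy[m] * uy[m];
    dot[m] = gx[m] * ux[m] + gy[m] * uy[m];
    cr[m] = ux[m] * gy[m] - uy[m] * gx[m];
    sdot += dot[m]; scr += cr[m];
  }
  double best = match_dist(std::atan2(scr, sdot), cm, dot, cr);
  for (int m = 0; m < 3; ++m) {
    double d = match_dist(std::atan2(cr[m], dot[m]), cm, dot, cr);
    if (d < best) best = d;
  }
  return best;
}

// match one gradient feature against all rules; returns (k, phi, reflect, d).
// Two phases: candidate-only upper bounds for every rule, then the full
// coarse + golden search only for rules whose modulus-difference lower
// bound (moduli are rotation/reflection invariant) can still win.
// Smallest rule index wins on exact distance ties.
static void match_feature(const double g[6], const RuleCache &rc,
                          int coarse, int golden,
                          int &k_out, double &phi_out, int &refl_out, double &d_out) {
  double gx[3] = { g[0], g[2], g[4] }, gy[3] = { g[1], g[3], g[5] };
  double gm[3];
  for (int m = 0; m < 3; ++m) gm[m] = std::sqrt(gx[m] * gx[m] + gy[m] * gy[m]);
  const int M = rc.M;
  std::vector<double> lb(M), dc(M);
  std::vector<int> ord(M);
  double best_ub = R_PosInf;
  for (int k = 0; k < M; ++k) {
    lb[k] = std::fabs(gm[0] - rc.mod[3 * k]) +
            std::fabs(gm[1] - rc.mod[3 * k + 1]) +
            std::fabs(gm[2] - rc.mod[3 * k + 2]);
    const double *ux = &rc.ux[3 * k], *uy = &rc.uy[3 * k];
    double uyr[3] = { -uy[0], -uy[1], -uy[2] };
    double q = quick_min(gx, gy, ux, uy);
    double qr = quick_min(gx, gy, ux, uyr);
    dc[k] = q < qr ? q : qr;
    if (dc[k] < best_ub) best_ub = dc[k];
    ord[k] = k;
  }
  // full search in order of increasing upper bound (index breaks sort ties)
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return dc[a] < dc[b] || (dc[a] == dc[b] && a < b);
  });
  k_out = 0; phi_out = 0.0; refl_out = 0; d_out = R_PosInf;
  for (int i = 0; i < M; ++i) {
    int k = ord[i];
    if (lb[k] >= d_out) continue;
    const double *ux = &rc.ux[3 * k], *uy = &rc.uy[3 * k];
    double d0, p0, d1, p1;
    min_over_rotation(gx, gy, ux, uy, coarse, golden, d0, p0);
    double uyr[3] = { -uy[0], -uy[1], -uy[2] };  // reflect about the x-axis
    min_over_rotation(gx, gy, ux, uyr, coarse, golden, d1, p1);
    double d = d0, p = p0; int refl = 0;
    if (d1 < d0) { d = d1; p = p1; refl = 1; }
    if (d < d_out || (d == d_out && k < k_out)) {
      d_out = d; phi_out = p; refl_out = refl; k_out = k;
    }
  }
}

// ---- state update --------------------------------------------------------

// weighted spectral average toward the point one pixel away along `dir`
// from cell (r, c); contributors are in-image lattice points within
// Euclidean distance 1 of that point, the cell itself excluded (it enters
// through the separate self weight f_th / (sum f + f_th)).
static void update_state(const Cube &img, int r, int c, double dir, double fth,
                         double *out, int H /* out leading dim */) {
  double px = c + std::cos(dir), py = r + std::sin(dir);
  int cmin = (int)std::floor(px - 1.0), cmax = (int)std::ceil(px + 1.0);
  int rmin = (int)std::floor(py - 1.0), rmax = (int)std::ceil(py + 1.0);
  int nc = 0;
  int crr[16], ccc[16];
  double fr[16], sumfr = 0.0;
  for (int rr = rmin; rr <= rmax; ++rr)
    for (int cc = cmin; cc <= cmax; ++cc) {
      if (rr < 0 || rr >= img.H || cc < 0 || cc >= img.W) continue;
      if (rr == r && cc == c) continue;
      double dx = cc - px, dy = rr - py;
      double rj = std::sqrt(dx * dx + dy * dy);
      if (rj > 1.0 + 1e-9) continue;
      double f = (rj < 1.0 / fth) ? fth : 1.0 / rj;
      crr[nc] = rr; ccc[nc] = cc; fr[nc] = f; sumfr += f;
      ++nc;
    }
  double denom = sumfr + fth;
  for (int b = 0; b < img.B; ++b) {
    double acc = (fth / denom) * img.at(r, c, b);
    for (int j = 0; j < nc; ++j)
      acc += (fr[j] / denom) * img.at(crr[j], ccc[j], b);
    out[r + (size_t)H * c + (size_t)H * img.W * b] = acc;
  }
}

// ---- exported entry points ----------------------------------------------

// [[Rcpp::export(name = ".gradient_features_cpp")]]
NumericVector gradient_features_cpp(NumericVector cube,
                                    NumericMatrix mx3, NumericMatrix mx5,
                                    NumericMatrix mx7) {
  IntegerVector dm = cube.attr("dim");
  Cube img = { REAL(cube), dm[0], dm[1], dm[2] };
  NormCube nrm;
  normalize_pixels(img, nrm);
  NumericVector out((size_t)img.H * img.W * 6);
  out.attr("dim") = IntegerVector::create(img.H, img.W, 6);
  double g[6];
  for (int c = 0; c < img.W; ++c)
    for (int r = 0; r < img.H; ++r) {
      cell_gradients(nrm, r, c, mx3, mx5, mx7, g);
      for (int m = 0; m < 3; ++m) {
        double mod = std::sqrt(g[2 * m] * g[2 * m] + g[2 * m + 1] * g[2 * m + 1]);
        double phi = mod < EPS_NORM ? 0.0 : std::atan2(g[2 * m + 1], g[2 * m]);
        if (phi < 0) phi += 2.0 * M_PI;
        out[r + (size_t)img.H * c + (size_t)img.H * img.W * m] = mod;
        out[r + (size_t)img.H * c + (size_t)img.H * img.W * (m + 3)] = phi;
      }
    }
  return out;
}

// feat = (gx3, gy3, gx5, gy5, gx7, gy7)
// [[Rcpp::export(name = ".match_rule_cpp")]]
NumericVector match_rule_cpp(NumericVector feat, NumericMatrix rules,
                             int coarse, int golden) {
  RuleCache rc = build_rule_cache(rules);
  double g[6];
  for (int i = 0; i < 6; ++i) g[i] = feat[i];
  int k, refl; double phi, d;
  match_feature(g, rc, coarse, golden, k, phi, refl, d);
  phi -= 2.0 * M_PI * std::floor(phi / (2.0 * M_PI));
  return NumericVector::create(k + 1, phi, refl, d);
}

// [[Rcpp::export(name = ".update_cell_cpp")]]
NumericVector update_cell_cpp(NumericVector cube, int row, int col,
                              double dir, double fth) {
  IntegerVector dm = cube.attr("dim");
  Cube img = { REAL(cube), dm[0], dm[1], dm[2] };
  std::vector<double> buf((size_t)img.H * img.W * img.B);
  update_state(img, row - 1, col - 1, dir, fth, buf.data(), img.H);
  NumericVector out(img.B);
  for (int b = 0; b < img.B; ++b)
    out[b] = buf[(row - 1) + (size_t)img.H * (col - 1) + (size_t)img.H * img.W * b];
  return out;
}

// K synchronous sweeps of the automaton
// [[Rcpp::export(name = ".run_mgca_cpp")]]
NumericVector run_mgca_cpp(NumericVector cube, NumericMatrix rules,
                           NumericMatrix mx3, NumericMatrix mx5,
                           NumericMatrix mx7, int K, double fth,
                           int coarse, int golden) {
  IntegerVector dm = cube.attr("dim");
  int H = dm[0], W = dm[1], B = dm[2];
  RuleCache rc = build_rule_cache(rules);
  std::vector<double> cur(REAL(cube), REAL(cube) + (size_t)H * W * B);
  std::vector<double> nxt((size_t)H * W * B);
  NormCube nrm;
  double g[6];
  for (int it = 0; it < K; ++it) {
    Cube img = { cur.data(), H, W, B };
    normalize_pixels(img, nrm);
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        cell_gradients(nrm, r, c, mx3, mx5, mx7, g);
        int k, refl; double phi, d;
        match_feature(g, rc, coarse, golden, k, phi, refl, d);
        // matched in the reflected frame => mirror the action angle too,
        // so the update direction is equivariant under reflection
        double theta = refl ? -rc.theta[k] : rc.theta[k];
        update_state(img, r, c, phi + theta, fth, nxt.data(), H);
      }
    }
    cur.swap(nxt);
    Rcpp::checkUserInterrupt();
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = IntegerVector::create(H, W, B);
  return out;
}

// mean normalized spectral angle of each pixel to its in-image 8-neighbors
// (frame pixels average over the neighbors that exist)
// [[Rcpp::export(name = ".mean_neighbor_angle_cpp")]]
NumericMatrix mean_neighbor_angle_cpp(NumericVector cube) {
  IntegerVector dm = cube.attr("dim");
  Cube img = { REAL(cube), dm[0], dm[1], dm[2] };
  NormCube nrm;
  normalize_pixels(img, nrm);
  NumericMatrix out(img.H, img.W);
  for (int c = 0; c < img.W; ++c)
    for (int r = 0; r < img.H; ++r) {
      double acc = 0.0; int n = 0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= img.H || cc < 0 || cc >= img.W) continue;
          if (!nrm.is_zero(r, c) && !nrm.is_zero(rr, cc))
            acc += sangle_unit(nrm.at(r, c), nrm.at(rr, cc), img.B);
          ++n;
        }
      out(r, c) = n ? acc / n : 0.0;
    }
  return out;
}
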