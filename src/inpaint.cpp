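#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exemplar-based (patch-copy) inpainting engine.
//
// Conventions: rasters are R matrices (column-major, h x w); pixel (r, c)
// is 0-based here; the row-major linear index r * w + c is used for all
// tie-breaks. x runs along columns, y along rows. The multiband image is a
// NumericVector with dim (h, w, nb).

static inline double patch_confidence(const NumericMatrix &conf,
                                      int r, int c, int half) {
  int h = conf.nrow(), w = conf.ncol();
  double s = 0.0; int n = 0;
  for (int dc = -half; dc <= half; ++dc) {
    int cc = c + dc; if (cc < 0 || cc >= w) continue;
    for (int dr = -half; dr <= half; ++dr) {
      int rr = r + dr; if (rr < 0 || rr >= h) continue;
      s += conf(rr, cc); ++n;
    }
  }
  return n ? s / n : 0.0;
}

// one-sided finite-difference gradient of gray at a *filled* pixel, using
// filled neighbours only (forward preferred); returns false if no
// difference is computable in that direction (component left 0)
static inline void grad_at(const NumericMatrix &gray,
                           const LogicalMatrix &filled,
                           int r, int c, double &gx, double &gy) {
  int h = gray.nrow(), w = gray.ncol();
  gx = 0.0; gy = 0.0;
  if (c + 1 < w && filled(r, c + 1)) gx = gray(r, c + 1) - gray(r, c);
  else if (c - 1 >= 0 && filled(r, c - 1)) gx = gray(r, c) - gray(r, c - 1);
  if (r + 1 < h && filled(r + 1, c)) gy = gray(r + 1, c) - gray(r, c);
  else if (r - 1 >= 0 && filled(r - 1, c)) gy = gray(r, c) - gray(r - 1, c);
}

// unit normal of the fill front at (r, c): central differences of the
// filled indicator; returns false if degenerate
static inline bool front_normal(const LogicalMatrix &filled,
                                int r, int c, double &nx, double &ny) {
  int h = filled.nrow(), w = filled.ncol();
  double fxp = (c + 1 < w) ? (filled(r, c + 1) ? 1.0 : 0.0) : (filled(r, c) ? 1.0 : 0.0);
  double fxm = (c - 1 >= 0) ? (filled(r, c - 1) ? 1.0 : 0.0) : (filled(r, c) ? 1.0 : 0.0);
  double fyp = (r + 1 < h) ? (filled(r + 1, c) ? 1.0 : 0.0) : (filled(r, c) ? 1.0 : 0.0);
  double fym = (r - 1 >= 0) ? (filled(r - 1, c) ? 1.0 : 0.0) : (filled(r, c) ? 1.0 : 0.0);
  nx = (fxp - fxm) / 2.0;
  ny = (fyp - fym) / 2.0;
  double nn = std::sqrt(nx * nx + ny * ny);
  if (nn < 1e-12) return false;
  nx /= nn; ny /= nn;
  return true;
}

// data term D(p): gradient variant takes the max-magnitude isophote over
// filled patch pixels; tensor variant uses the patch-averaged structure
// tensor (isophote direction = minor eigenvector, strength = sqrt of the
// dominant eigenvalue)
static double data_term_at(const NumericMatrix &gray,
                           const LogicalMatrix &filled,
                           int r, int c, int half, double alpha,
                           int data_term) {
  int h = gray.nrow(), w = gray.ncol();
  double nx, ny;
  if (!front_normal(filled, r, c, nx, ny)) return 0.0;
  if (data_term == 0) { // gradient / isophote
    double best = 0.0, bgx = 0.0, bgy = 0.0;
    for (int dc = -half; dc <= half; ++dc) {
      int cc = c + dc; if (cc < 0 || cc >= w) continue;
      for (int dr = -half; dr <= half; ++dr) {
        int rr = r + dr; if (rr < 0 || rr >= h) continue;
        if (!filled(rr, cc)) continue;
        double gx, gy; grad_at(gray, filled, rr, cc, gx, gy);
        double m = gx * gx + gy * gy;
        if (m > best) { best = m; bgx = gx; bgy = gy; }
      }
    }
    // isophote = gradient rotated 90 degrees: (-gy, gx)
    return std::fabs(-bgy * nx + bgx * ny) / alpha;
  } else { // structure tensor
    double jxx = 0.0, jxy = 0.0, jyy = 0.0; int n = 0;
    for (int dc = -half; dc <= half; ++dc) {
      int cc = c + dc; if (cc < 0 || cc >= w) continue;
      for (int dr = -half; dr <= half; ++dr) {
        int rr = r + dr; if (rr < 0 || rr >= h) continue;
        if (!filled(rr, cc)) continue;
        double gx, gy; grad_at(gray, filled, rr, cc, gx, gy);
        jxx += gx * gx; jxy += gx * gy; jyy += gy * gy; ++n;
      }
    }
    if (!n) return 0.0;
    jxx /= n; jxy /= n; jyy /= n;
    double tr = jxx + jyy;
    double det = jxx * jyy - jxy * jxy;
    double disc = std::sqrt(std::max(tr * tr / 4.0 - det, 0.0));
    double l1 = tr / 2.0 + disc;
    if (l1 < 1e-15) return 0.0;
    // dominant eigenvector (along the mean gradient)
    double vx, vy;
    if (std::fabs(jxy) > 1e-15) { vx = l1 - jyy; vy = jxy; }
    else if (jxx >= jyy) { vx = 1.0; vy = 0.0; }
    else { vx = 0.0; vy = 1.0; }
    double vn = std::sqrt(vx * vx + vy * vy);
    vx /= vn; vy /= vn;
    // isophote direction is perpendicular to the dominant eigenvector
    return std::sqrt(l1) * std::fabs(-vy * nx + vx * ny) / alpha;
  }
}

// [[Rcpp::export]]
double cpp_priority(NumericMatrix gray, LogicalMatrix filled,
                    NumericMatrix conf, int r, int c, int half,
                    double alpha, int data_term) {
  double C = patch_confidence(conf, r, c, half);
  double D = data_term_at(gray, filled, r, c, half, alpha, data_term);
  return C * D;
}

// SSD search over candidate source-patch centers; comparison is over the
// currently-filled pixels of the target patch, summed across bands;
// ties broken by smallest row-major linear index
// [[Rcpp::export]]
List cpp_best_source(NumericVector img, LogicalMatrix filled,
                     int tr, int tc,
                     IntegerVector cand_r, IntegerVector cand_c,
                     int half) {
  IntegerVector dims = img.attr("dim");
  int h = dims[0], w = dims[1], nb = dims[2];
  const double *px = REAL(img);
  std::vector<int> odr, odc;
  for (int dc = -half; dc <= half; ++dc) {
    int cc = tc + dc; if (cc < 0 || cc >= w) continue;
    for (int dr = -half; dr <= half; ++dr) {
      int rr = tr + dr; if (rr < 0 || rr >= h) continue;
      if (filled(rr, cc)) { odr.push_back(dr); odc.push_back(dc); }
    }
  }
  int nOff = (int)odr.size();
  int nC = cand_r.size();
  if (nC == 0) return List::create(_["r"] = -1, _["c"] = -1, _["ssd"] = NA_REAL);
  double best = R_PosInf;
  long bestIdx = -1;
  int br = -1, bc = -1;
  long plane = (long)h * w;
  for (int k = 0; k < nC; ++k) {
    int sr = cand_r[k], sc = cand_c[k];
    double ssd = 0.0;
    for (int o = 0; o < nOff && ssd <= best; ++o) {
      int trr = tr + odr[o], tcc = tc + odc[o];
      int srr = sr + odr[o], scc = sc + odc[o];
      long ti = (long)tcc * h + trr;
      long si = (long)scc * h + srr;
      for (int b = 0; b < nb; ++b) {
        double d = px[ti + b * plane] - px[si + b * plane];
        ssd += d * d;
      }
    }
    long idx = (long)sr * w + sc;
    if (ssd < best || (ssd == best && idx < bestIdx)) {
      best = ssd; bestIdx = idx; br = sr; bc = sc;
    }
  }
  return List::create(_["r"] = br, _["c"] = bc, _["ssd"] = best);
}

// full priority-ordered fill loop; modifies a copy of img and returns it
// together with per-iteration diagnostics
// [[Rcpp::export]]
List cpp_inpaint(NumericVector img_in, LogicalMatrix target,
                 IntegerVector cand_r, IntegerVector cand_c,
                 int half, double alpha, int data_term, int max_iter) {
  NumericVector img = clone(img_in);
  IntegerVector dims = img.attr("dim");
  int h = dims[0], w = dims[1], nb = dims[2];
  double *px = REAL(img);
  long plane = (long)h * w;
  LogicalMatrix filled(h, w);
  NumericMatrix conf(h, w);
  NumericMatrix gray(h, w);
  int remaining = 0;
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      bool f = !target(r, c);
      filled(r, c) = f;
      conf(r, c) = f ? 1.0 : 0.0;
      if (!f) ++remaining;
      double s = 0.0;
      long i = (long)c * h + r;
      for (int b = 0; b < nb; ++b) s += px[i + b * plane];
      gray(r, c) = s / nb;
    }
  if (cand_r.size() == 0 && remaining > 0)
    stop("no admissible source patch: mask too dense for patch size");
  std::vector<int> rem_hist;
  rem_hist.reserve(256);
  int iter = 0;
  while (remaining > 0) {
    if (++iter > max_iter)
      stop("inpainting failed to terminate: fill front not shrinking");
    // locate the fill front: unfilled pixels with a filled 8-neighbour
    double bestP = -1.0;
    long bestIdx = -1;
    int pr = -1, pc = -1;
    for (int c = 0; c < w; ++c)
      for (int r = 0; r < h; ++r) {
        if (filled(r, c)) continue;
        bool onFront = false;
        for (int dc = -1; dc <= 1 && !onFront; ++dc)
          for (int dr = -1; dr <= 1 && !onFront; ++dr) {
            if (!dr && !dc) continue;
            int rr = r + dr, cc = c + dc;
            if (rr >= 0 && rr < h && cc >= 0 && cc < w && filled(rr, cc))
              onFront = true;
          }
        if (!onFront) continue;
        double P = patch_confidence(conf, r, c, half) *
          data_term_at(gray, filled, r, c, half, alpha, data_term);
        long idx = (long)r * w + c;
        if (P > bestP || (P == bestP && idx < bestIdx)) {
          bestP = P; bestIdx = idx; pr = r; pc = c;
        }
      }
    if (pr < 0)
      stop("inpainting failed: no fill front although pixels remain");
    // best source patch for the chosen target
    List bs = cpp_best_source(img, filled, pr, pc, cand_r, cand_c, half);
    int sr = bs["r"], sc = bs["c"];
    if (sr < 0)
      stop("no admissible source patch: mask too dense for patch size");
    double Cp = patch_confidence(conf, pr, pc, half);
    for (int dc = -half; dc <= half; ++dc) {
      int tcc = pc + dc; if (tcc < 0 || tcc >= w) continue;
      for (int dr = -half; dr <= half; ++dr) {
        int trr = pr + dr; if (trr < 0 || trr >= h) continue;
        if (filled(trr, tcc)) continue;
        int srr = sr + dr, scc = sc + dc;
        long ti = (long)tcc * h + trr;
        long si = (long)scc * h + srr;
        double s = 0.0;
        for (int b = 0; b < nb; ++b) {
          px[ti + b * plane] = px[si + b * plane];
          s += px[ti + b * plane];
        }
        gray(trr, tcc) = s / nb;
        filled(trr, tcc) = true;
        conf(trr, tcc) = Cp;
        --remaining;
      }
    }
    rem_hist.push_back(remaining);
  }
  return List::create(_["image"] = img, _["iterations"] = iter,
                      _["remaining_history"] = wrap(rem_hist));
}
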