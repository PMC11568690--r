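#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 8-connected component labelling by iterative flood fill (explicit stack,
// no recursion). Input: logical/numeric matrix, nonzero = foreground.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      stack.push_back(r0 + c0 * nr);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        const int idx = stack.back(); stack.pop_back();
        const int r = idx % nr, c = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc) continue;
            const int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(rr + cc * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher) with
// nearest-site tracking. Sites are pixels with label > 0. Returns the
// distance to, and the label of, the nearest site for every pixel.
// [[Rcpp::export(name = ".edt_nearest")]]
List edt_nearest(const IntegerMatrix& lab) {
  const int nr = lab.nrow(), nc = lab.ncol();
  // BIG exceeds any achievable squared distance, so columns without a site
  // never win the envelope unless the whole image is empty.
  const double BIG = 4.0 * ((double)nr * nr + (double)nc * nc) + 16.0;
  const double INF = 1e30;
  NumericMatrix d1(nr, nc);     // squared vertical distance (clamped)
  IntegerMatrix srow(nr, nc);   // row of nearest site within the column
  bool any_site = false;
  for (int c = 0; c < nc; ++c) {
    double d = BIG; int s = -1;
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) > 0) { d = 0; s = r; any_site = true; }
      else if (s >= 0) { d = (double)(r - s) * (r - s); if (d > BIG) d = BIG; }
      d1(r, c) = d;
      srow(r, c) = s < 0 ? 0 : s;
    }
    s = -1;
    for (int r = nr - 1; r >= 0; --r) {
      if (lab(r, c) > 0) s = r;
      else if (s >= 0) {
        double dd = (double)(s - r) * (s - r);
        if (dd < d1(r, c)) { d1(r, c) = dd; srow(r, c) = s; }
      }
    }
  }
  NumericMatrix dist(nr, nc);
  IntegerMatrix nearest(nr, nc);
  if (!any_site) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    return List::create(_["dist"] = dist, _["label"] = nearest);
  }
  std::vector<int> v(nc);        // columns of parabolas in lower envelope
  std::vector<double> z(nc + 1); // boundaries between parabolas
  for (int r = 0; r < nr; ++r) {
    int k = 0;
    v[0] = 0; z[0] = -INF; z[1] = INF;
    for (int q = 1; q < nc; ++q) {
      const double fq = d1(r, q);
      double s_ = 0;
      while (true) {
        const int p = v[k];
        const double fp = d1(r, p);
        s_ = ((fq + (double)q * q) - (fp + (double)p * p)) / (2.0 * (q - p));
        if (s_ <= z[k] && k > 0) { --k; }
        else break;
      }
      if (s_ <= z[k] && k == 0) { v[0] = q; }
      else { ++k; v[k] = q; }
      z[k] = (k == 0) ? -INF : s_;
      z[k + 1] = INF;
    }
    int k2 = 0;
    for (int c = 0; c < nc; ++c) {
      while (z[k2 + 1] < c) ++k2;
      const int q = v[k2];
      const double f = d1(r, q);
      const double dd = (double)(c - q) * (c - q) + f;
      if (dd >= BIG) { dist(r, c) = R_PosInf; nearest(r, c) = 0; continue; }
      dist(r, c) = std::sqrt(dd);
      nearest(r, c) = lab(srow(r, q), q);
    }
  }
  return List::create(_["dist"] = dist, _["label"] = nearest);
}

// Seeded watershed: grow seed labels over `mask` in order of decreasing
// intensity (priority-queue flooding, 4-connectivity). Used to declump
// touching nuclei from intensity-peak seeds.
// [[Rcpp::export(name = ".watershed_seeded")]]
IntegerMatrix watershed_seeded(const NumericMatrix& img,
                               const IntegerMatrix& seeds,
                               const LogicalMatrix& mask) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  typedef std::pair<double, int> QE; // (intensity, linear index); max-heap
  std::priority_queue<QE> pq;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c)) {
        lab(r, c) = seeds(r, c);
        pq.push(QE(img(r, c), r + c * nr));
      }
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    const int idx = pq.top().second; pq.pop();
    const int r = idx % nr, c = idx / nr;
    const int l = lab(r, c);
    for (int k = 0; k < 4; ++k) {
      const int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (mask(rr, cc) && lab(rr, cc) == 0) {
        lab(rr, cc) = l;
        pq.push(QE(img(rr, cc), rr + cc * nr));
      }
    }
  }
  return lab;
}

// Rigid warp by inverse mapping with bilinear interpolation. The forward
// transform moves content by (+dx cols, +dy rows) and rotates by theta
// degrees (counter-clockwise in row/col coordinates) about the image
// center. `valid` is FALSE where sampling fell outside the source.
// [[Rcpp::export(name = ".warp_rigid")]]
List warp_rigid(const NumericMatrix& img, double dx, double dy,
                double theta_deg) {
  const int nr = img.nrow(), nc = img.ncol();
  const double th = theta_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cr = (nr - 1) / 2.0, cc = (nc - 1) / 2.0;
  NumericMatrix out(nr, nc);
  LogicalMatrix valid(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      // inverse transform: undo translation, rotate by -theta about center
      const double yr = (r - dy) - cr, xc = (c - dx) - cc;
      const double sr = ct * yr + st * xc + cr;
      const double sc = -st * yr + ct * xc + cc;
      const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      if (r0 < 0 || c0 < 0 || r0 + 1 > nr - 1 || c0 + 1 > nc - 1) {
        // allow exact top/left edge
        if (sr >= 0 && sc >= 0 && sr <= nr - 1 && sc <= nc - 1) {
          const int ri = (int)std::round(sr), ci = (int)std::round(sc);
          out(r, c) = img(ri, ci);
          valid(r, c) = true;
        }
        continue;
      }
      const double fr = sr - r0, fc = sc - c0;
      out(r, c) =
        img(r0, c0) * (1 - fr) * (1 - fc) + img(r0 + 1, c0) * fr * (1 - fc) +
        img(r0, c0 + 1) * (1 - fr) * fc + img(r0 + 1, c0 + 1) * fr * fc;
      valid(r, c) = true;
    }
  }
  return List::create(_["image"] = out, _["valid"] = valid);
}

// Separable convolution with a symmetric 1-D kernel, replicate padding.
// [[Rcpp::export(name = ".sep_conv")]]
NumericMatrix sep_conv(const NumericMatrix& img, const NumericVector& kern) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kl = kern.size(), half = kl / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0;
      for (int k = 0; k < kl; ++k) {
        int rr = r + k - half;
        if (rr < 0) rr = 0; else if (rr >= nr) rr = nr - 1;
        s += img(rr, c) * kern[k];
      }
      tmp(r, c) = s;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0;
      for (int k = 0; k < kl; ++k) {
        int cc2 = c + k - half;
        if (cc2 < 0) cc2 = 0; else if (cc2 >= nc) cc2 = nc - 1;
        s += tmp(r, cc2) * kern[k];
      }
      out(r, c) = s;
    }
  return out;
}
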