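#include <Rcpp.h>
#include <vector>
#include <cmath>

// Welzl-type minimum enclosing circle with move-to-front structure.
// Deterministic: the working order is produced by an internal xorshift
// generator with a fixed seed, so repeated calls on the same input give
// byte-identical results regardless of R's RNG state.

namespace {

struct Pt { double x, y; };
struct Circle { double x, y, r; };

const double REL_EPS = 1e-12;

inline double dist(const Pt &a, const Pt &b) {
  return std::hypot(a.x - b.x, a.y - b.y);
}

inline bool inside(const Circle &c, const Pt &p) {
  double d = std::hypot(p.x - c.x, p.y - c.y);
  return d <= c.r + REL_EPS * (c.r + 1.0e-300) + 1e-305 || d <= c.r * (1.0 + REL_EPS);
}

inline Circle circle2(const Pt &a, const Pt &b) {
  Circle c;
  c.x = 0.5 * (a.x + b.x);
  c.y = 0.5 * (a.y + b.y);
  c.r = 0.5 * dist(a, b);
  return c;
}

// Circumcircle of three points; collinear input falls back to the widest
// two-point circle, which is the correct minimal enclosing circle then.
Circle circle3(const Pt &a, const Pt &b, const Pt &c) {
  double bx = b.x - a.x, by = b.y - a.y;
  double cx = c.x - a.x, cy = c.y - a.y;
  double d = 2.0 * (bx * cy - by * cx);
  double scale = std::max({std::fabs(bx), std::fabs(by), std::fabs(cx), std::fabs(cy)});
  if (std::fabs(d) <= 1e-14 * scale * scale || scale == 0.0) {
    Circle c1 = circle2(a, b), c2 = circle2(a, c), c3 = circle2(b, c);
    Circle best = c1;
    if (c2.r > best.r) best = c2;
    if (c3.r > best.r) best = c3;
    return best;
  }
  double b2 = bx * bx + by * by, c2n = cx * cx + cy * cy;
  double ux = (cy * b2 - by * c2n) / d;
  double uy = (bx * c2n - cx * b2) / d;
  Circle out;
  out.x = a.x + ux;
  out.y = a.y + uy;
  out.r = std::hypot(ux, uy);
  // guard against rounding: radius must cover all three generators
  out.r = std::max({out.r,
                    std::hypot(out.x - a.x, out.y - a.y),
                    std::hypot(out.x - b.x, out.y - b.y),
                    std::hypot(out.x - c.x, out.y - c.y)});
  return out;
}

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // unbiased enough for shuffling small index sets
  size_t bounded(size_t n) { return (size_t)(next() % n); }
};

Circle welzl(std::vector<Pt> &p) {
  size_t n = p.size();
  XorShift rng(0x9E3779B97F4A7C15ULL);
  for (size_t i = n - 1; i > 0; --i) {
    size_t j = rng.bounded(i + 1);
    std::swap(p[i], p[j]);
  }
  Circle c{p[0].x, p[0].y, 0.0};
  for (size_t i = 1; i < n; ++i) {
    if (inside(c, p[i])) continue;
    c = Circle{p[i].x, p[i].y, 0.0};
    for (size_t j = 0; j < i; ++j) {
      if (inside(c, p[j])) continue;
      c = circle2(p[i], p[j]);
      for (size_t k = 0; k < j; ++k) {
        if (inside(c, p[k])) continue;
        c = circle3(p[i], p[j], p[k]);
      }
    }
  }
  return c;
}

} // namespace

// [[Rcpp::export(name = ".mec_cpp")]]
Rcpp::NumericVector mec_cpp(Rcpp::NumericMatrix pts) {
  size_t n = pts.nrow();
  if (n == 0) Rcpp::stop("minimum enclosing circle needs at least one point");
  std::vector<Pt> p(n);
  for (size_t i = 0; i < n; ++i) p[i] = Pt{pts(i, 0), pts(i, 1)};
  Circle c = welzl(p);
  return Rcpp::NumericVector::create(c.x, c.y, c.r);
}

// Radii for `n_rep` stacked replicates of `m` points each; x and y hold the
// replicates consecutively. Used by the Monte-Carlo containment estimator.
// [[Rcpp::export(name = ".mec_radius_batch")]]
Rcpp::NumericVector mec_radius_batch(Rcpp::NumericVector x, Rcpp::NumericVector y, int m) {
  if (m < 1) Rcpp::stop("m must be >= 1");
  if (x.size() != y.size() || x.size() % m != 0)
    Rcpp::stop("coordinate length must be a multiple of m");
  size_t n_rep = x.size() / m;
  Rcpp::NumericVector out(n_rep);
  std::vector<Pt> p(m);
  for (size_t r = 0; r < n_rep; ++r) {
    size_t off = r * m;
    for (int i = 0; i < m; ++i) p[i] = Pt{x[off + i], y[off + i]};
    Circle c = welzl(p);
    out[r] = c.r;
  }
  return out;
}
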