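#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Shapes are analytic primitives: type 1 = sphere (params: radius),
// type 2 = axis-aligned box in body frame (params: half-extents hx, hy, hz).
// Rays go through pixel (row i, col j) with direction
//   d = ((j - cx)/fx, (i - cy)/fy, 1)
// so the ray parameter t *is* the z-depth (distance along the optical axis).

static inline void quat_to_rot(const double *q, double R[9]) {
  const double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z);     R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y);     R[7] = 2 * (y * z + w * x);     R[8] = 1 - 2 * (x * x + y * y);
}

// z-depth of the nearest intersection of the pixel ray with the shape,
// or -1 when the ray misses (or the hit is behind the camera).
static double ray_shape_depth(int type, const double *par,
                              const double *c, const double R[9],
                              double dx, double dy) {
  if (type == 1) { // sphere: ignore orientation
    const double r = par[0];
    const double A = dx * dx + dy * dy + 1.0;
    const double B = dx * c[0] + dy * c[1] + c[2];
    const double C = c[0] * c[0] + c[1] * c[1] + c[2] * c[2] - r * r;
    const double disc = B * B - A * C;
    if (disc < 0) return -1.0;
    const double t = (B - std::sqrt(disc)) / A;
    return t > 0 ? t : -1.0;
  }
  // box: transform the ray into the body frame and slab-test
  double o[3], db[3];
  const double d[3] = {dx, dy, 1.0};
  for (int k = 0; k < 3; ++k) {
    o[k]  = -(R[k] * c[0] + R[3 + k] * c[1] + R[6 + k] * c[2]); // R^T * (-c)
    db[k] =   R[k] * d[0] + R[3 + k] * d[1] + R[6 + k] * d[2];  // R^T * d
  }
  double tmin = -1e300, tmax = 1e300;
  for (int k = 0; k < 3; ++k) {
    const double h = par[k];
    if (std::fabs(db[k]) < 1e-12) {
      if (o[k] < -h || o[k] > h) return -1.0;
    } else {
      double t1 = (-h - o[k]) / db[k], t2 = (h - o[k]) / db[k];
      if (t1 > t2) std::swap(t1, t2);
      tmin = std::max(tmin, t1);
      tmax = std::min(tmax, t2);
      if (tmin > tmax) return -1.0;
    }
  }
  if (tmax <= 0) return -1.0;
  const double t = tmin > 0 ? tmin : tmax; // camera inside the box: exit face
  return t;
}

struct Cam {
  double fx, fy, cx, cy, d_min, d_max;
  int width, height;
};

static Cam cam_from_list(const List &intr) {
  Cam c;
  c.fx = as<double>(intr["fx"]); c.fy = as<double>(intr["fy"]);
  c.cx = as<double>(intr["cx"]); c.cy = as<double>(intr["cy"]);
  c.width = as<int>(intr["width"]); c.height = as<int>(intr["height"]);
  c.d_min = as<double>(intr["d_min"]); c.d_max = as<double>(intr["d_max"]);
  return c;
}

// [[Rcpp::export(name = ".render_depth_cpp")]]
NumericMatrix render_depth_cpp(int type, NumericVector params,
                               NumericVector p, NumericVector q,
                               List intr,
                               Nullable<List> occluder = R_NilValue) {
  const Cam cam = cam_from_list(intr);
  NumericMatrix out(cam.height, cam.width);
  std::fill(out.begin(), out.end(), NA_REAL);

  double R[9];
  quat_to_rot(REAL(q), R);
  const double *c = REAL(p);

  int otype = 0;
  double oR[9];
  NumericVector opar, op;
  if (occluder.isNotNull()) {
    List occ(occluder);
    otype = as<int>(occ["type"]);
    opar = as<NumericVector>(occ["params"]);
    op = as<NumericVector>(occ["p"]);
    NumericVector oq = as<NumericVector>(occ["q"]);
    quat_to_rot(REAL(oq), oR);
  }

  for (int i = 0; i < cam.height; ++i) {
    const double dy = (i - cam.cy) / cam.fy;
    for (int j = 0; j < cam.width; ++j) {
      const double dx = (j - cam.cx) / cam.fx;
      double t = ray_shape_depth(type, REAL(params), c, R, dx, dy);
      if (otype) {
        const double to = ray_shape_depth(otype, REAL(opar), REAL(op), oR, dx, dy);
        if (to > 0 && (t < 0 || to < t)) t = to; // nearer surface wins
      }
      if (t >= cam.d_min && t <= cam.d_max) out(i, j) = t;
    }
  }
  return out;
}

// Per-pixel mixture log-likelihood of an observed depth given an expected
// depth: uniform (random return) + Gaussian (sensor noise, variance
// df*xe^2 + bn) + truncated-exponential (occlusion, only when the
// observation is at or nearer than the expectation). Invalid pixels are NA.
static inline double pixel_ll_one(double xo, double xe,
                                  double w_uni, double w_gaus, double w_exp,
                                  double lam, double df, double bn,
                                  double d_min, double d_max) {
  if (ISNAN(xe)) return 0.0;                 // expected background: anything fits
  const double uni = w_uni / (d_max - d_min);
  if (ISNAN(xo)) return std::log(uni);       // dropped observation: random return
  const double var = df * xe * xe + bn;
  const double gaus = w_gaus * std::exp(-(xo - xe) * (xo - xe) / (2.0 * var)) /
                      std::sqrt(2.0 * M_PI * var);
  double v = uni + gaus;
  if (xe >= xo) {                            // possible occlusion: observed nearer
    v += w_exp * lam * std::exp(-lam * xo) / (1.0 - std::exp(-lam * xe));
  }
  return std::log(v);
}

// [[Rcpp::export(name = ".pixel_ll_cpp")]]
NumericVector pixel_ll_cpp(NumericVector xo, NumericVector xe,
                           double w_uni, double w_gaus, double w_exp,
                           double lam, double df, double bn,
                           double d_min, double d_max) {
  const R_xlen_t n = xo.size();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k)
    out[k] = pixel_ll_one(xo[k], xe[k], w_uni, w_gaus, w_exp,
                          lam, df, bn, d_min, d_max);
  return out;
}

// [[Rcpp::export(name = ".image_weight_cpp")]]
double image_weight_cpp(NumericMatrix obs, NumericMatrix expd,
                        double w_uni, double w_gaus, double w_exp,
                        double lam, double df, double bn,
                        double d_min, double d_max) {
  double s = 0.0;
  const R_xlen_t n = obs.size();
  for (R_xlen_t k = 0; k < n; ++k)
    s += pixel_ll_one(obs[k], expd[k], w_uni, w_gaus, w_exp,
                      lam, df, bn, d_min, d_max);
  return s;
}

// Image weight of K particle hypotheses against one observation. Pixels
// outside a particle's projected footprint have an invalid expected depth
// and contribute exactly 0, so only the bounding box of the projected
// shape is visited; the result equals the full-image sum.
// [[Rcpp::export(name = ".weight_particles_cpp")]]
NumericVector weight_particles_cpp(NumericMatrix obs,
                                   NumericMatrix P, NumericMatrix Q,
                                   int type, NumericVector params,
                                   List intr,
                                   double w_uni, double w_gaus, double w_exp,
                                   double lam, double df, double bn) {
  const Cam cam = cam_from_list(intr);
  const int K = P.nrow();
  NumericVector out(K);

  // conservative bounding-sphere radius of the shape
  double rb;
  if (type == 1) rb = params[0];
  else rb = std::sqrt(params[0] * params[0] + params[1] * params[1] +
                      params[2] * params[2]);

  for (int k = 0; k < K; ++k) {
    const double c[3] = {P(k, 0), P(k, 1), P(k, 2)};
    double w = 0.0;
    const double zn = c[2] - rb; // nearest possible shape point along z
    if (zn <= 0) { out[k] = 0.0; continue; } // straddles the camera plane: no valid render
    double R[9];
    const double qk[4] = {Q(k, 0), Q(k, 1), Q(k, 2), Q(k, 3)};
    quat_to_rot(qk, R);

    // conservative projected extent, valid also for off-axis targets:
    // |du| <= fx * rb * (1 + |cx|/cz) / (cz - rb)
    const double ru = cam.fx * rb * (1.0 + std::fabs(c[0]) / c[2]) / zn;
    const double rv = cam.fy * rb * (1.0 + std::fabs(c[1]) / c[2]) / zn;
    const double u = cam.cx + cam.fx * c[0] / c[2];
    const double v = cam.cy + cam.fy * c[1] / c[2];
    const int j0 = std::max(0, (int)std::floor(u - ru) - 1);
    const int j1 = std::min(cam.width - 1, (int)std::ceil(u + ru) + 1);
    const int i0 = std::max(0, (int)std::floor(v - rv) - 1);
    const int i1 = std::min(cam.height - 1, (int)std::ceil(v + rv) + 1);

    for (int i = i0; i <= i1; ++i) {
      const double dy = (i - cam.cy) / cam.fy;
      for (int j = j0; j <= j1; ++j) {
        const double dx = (j - cam.cx) / cam.fx;
        const double t = ray_shape_depth(type, REAL(params), c, R, dx, dy);
        if (t >= cam.d_min && t <= cam.d_max) {
          w += pixel_ll_one(obs(i, j), t, w_uni, w_gaus, w_exp,
                            lam, df, bn, cam.d_min, cam.d_max);
        }
      }
    }
    out[k] = w;
  }
  return out;
}
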