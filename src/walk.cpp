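#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>

using namespace Rcpp;

// Geometry conventions (validated on the R side before calling in here):
//   * cubic voxel [0, edge)^3 with periodic boundaries; positions held
//     unwrapped, wrapped only for membership tests
//   * cylinders run along +z over the full voxel edge, sinusoidal
//     undulation displaces the centerline along +x with period P dividing
//     the edge, so the wrapped geometry is seamless in z
//   * cyl matrix columns: bx, by, bz, A, P, r
//   * sph matrix columns: cx, cy, cz, r

static inline double wrap1(double x, double e) {
  double y = x - e * std::floor(x / e);
  if (y >= e) y -= e;  // guard against floating rounding at the face
  return y;
}

struct Geom {
  std::vector<std::array<double, 6> > cyl;
  std::vector<std::array<double, 4> > sph;
  double edge;
};

static Geom make_geom(const NumericMatrix& cyl, const NumericMatrix& sph,
                      double edge) {
  Geom g;
  g.edge = edge;
  g.cyl.resize(cyl.nrow());
  for (int i = 0; i < cyl.nrow(); ++i)
    for (int j = 0; j < 6; ++j) g.cyl[i][j] = cyl(i, j);
  g.sph.resize(sph.nrow());
  for (int i = 0; i < sph.nrow(); ++i)
    for (int j = 0; j < 4; ++j) g.sph[i][j] = sph(i, j);
  return g;
}

// signed implicit surface value: negative inside the obstacle
static inline double cyl_f(const std::array<double, 6>& c, double x,
                           double y, double z) {
  double ph = 2.0 * M_PI * (z - c[2]) / c[4];
  double dx = x - c[0] - c[3] * std::sin(ph);
  double dy = y - c[1];
  return std::sqrt(dx * dx + dy * dy) - c[5];
}

static inline double sph_f(const std::array<double, 4>& s, double x,
                           double y, double z) {
  double dx = x - s[0], dy = y - s[1], dz = z - s[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz) - s[3];
}

static inline bool cyl_grad(const std::array<double, 6>& c, double x,
                            double y, double z, double* g) {
  double ph = 2.0 * M_PI * (z - c[2]) / c[4];
  double dx = x - c[0] - c[3] * std::sin(ph);
  double dy = y - c[1];
  double rho = std::sqrt(dx * dx + dy * dy);
  if (rho < 1e-12) return false;
  g[0] = dx / rho;
  g[1] = dy / rho;
  g[2] = -(dx / rho) * c[3] * (2.0 * M_PI / c[4]) * std::cos(ph);
  double n = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
  g[0] /= n; g[1] /= n; g[2] /= n;
  return true;
}

static inline bool sph_grad(const std::array<double, 4>& s, double x,
                            double y, double z, double* g) {
  double dx = x - s[0], dy = y - s[1], dz = z - s[2];
  double n = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (n < 1e-12) return false;
  g[0] = dx / n; g[1] = dy / n; g[2] = dz / n;
  return true;
}

// implicit value for obstacle with 1-based index: 1..ncyl cylinders,
// ncyl+1..ncyl+nsph spheres; point given unwrapped
static inline double obstacle_f(const Geom& g, int idx, const double* p) {
  double x = wrap1(p[0], g.edge), y = wrap1(p[1], g.edge),
         z = wrap1(p[2], g.edge);
  int nc = (int)g.cyl.size();
  if (idx <= nc) return cyl_f(g.cyl[idx - 1], x, y, z);
  return sph_f(g.sph[idx - 1 - nc], x, y, z);
}

static inline bool obstacle_grad(const Geom& g, int idx, const double* p,
                                 double* grad) {
  double x = wrap1(p[0], g.edge), y = wrap1(p[1], g.edge),
         z = wrap1(p[2], g.edge);
  int nc = (int)g.cyl.size();
  if (idx <= nc) return cyl_grad(g.cyl[idx - 1], x, y, z, grad);
  return sph_grad(g.sph[idx - 1 - nc], x, y, z, grad);
}

// 0 = extra-cellular, 1..ncyl = inside cylinder i, ncyl+j = inside sphere j
static inline int classify(const Geom& g, const double* p) {
  double x = wrap1(p[0], g.edge), y = wrap1(p[1], g.edge),
         z = wrap1(p[2], g.edge);
  for (size_t i = 0; i < g.cyl.size(); ++i)
    if (cyl_f(g.cyl[i], x, y, z) < 0.0) return (int)(i + 1);
  for (size_t j = 0; j < g.sph.size(); ++j)
    if (sph_f(g.sph[j], x, y, z) < 0.0) return (int)(g.cyl.size() + j + 1);
  return 0;
}

// is p inside the compartment identified by label (0 = extra)?
static inline bool inside_compartment(const Geom& g, int label,
                                      const double* p) {
  if (label == 0) return classify(g, p) == 0;
  return obstacle_f(g, label, p) < 0.0;
}

// [[Rcpp::export]]
IntegerVector classify_cpp(NumericMatrix pts, NumericMatrix cyl,
                           NumericMatrix sph, double edge) {
  Geom g = make_geom(cyl, sph, edge);
  int n = pts.nrow();
  IntegerVector out(n);
  double p[3];
  for (int i = 0; i < n; ++i) {
    p[0] = pts(i, 0); p[1] = pts(i, 1); p[2] = pts(i, 2);
    out[i] = classify(g, p);
  }
  return out;
}

// Take one fixed-length step with elastic specular reflection off
// impermeable membranes.  Returns true if the move was accepted (pos
// updated in place); false leaves pos untouched (step rejected after
// exhausting the reflection budget).
static bool do_step(const Geom& g, int label, double* pos, const double* dir,
                    double step_len, int max_reflect) {
  double p[3] = {pos[0], pos[1], pos[2]};
  double q[3] = {pos[0] + step_len * dir[0], pos[1] + step_len * dir[1],
                 pos[2] + step_len * dir[2]};
  const double eps = 1e-7;  // um, nudge off the surface after reflection
  for (int it = 0; it <= max_reflect; ++it) {
    if (inside_compartment(g, label, q)) {
      pos[0] = q[0]; pos[1] = q[1]; pos[2] = q[2];
      return true;
    }
    if (it == max_reflect) break;
    // which surface was crossed?
    int surf;
    if (label > 0) {
      surf = label;  // leaving the host obstacle through its own wall
    } else {
      surf = -1;
      double fmin = 0.0;
      int nobs = (int)(g.cyl.size() + g.sph.size());
      for (int k = 1; k <= nobs; ++k) {
        double f = obstacle_f(g, k, q);
        if (f < fmin) { fmin = f; surf = k; }
      }
      if (surf < 0) break;  // inconsistent state; reject
    }
    // bisect p -> q for the crossing of surf's implicit surface
    double lo = 0.0, hi = 1.0;
    double f_lo = obstacle_f(g, surf, p);
    // inside-sign at the start of the sub-segment (negative for intra)
    double sgn = (label > 0) ? -1.0 : 1.0;
    if (f_lo * sgn < 0.0) break;  // start already on the wrong side; reject
    double m[3];
    for (int b = 0; b < 60; ++b) {
      double t = 0.5 * (lo + hi);
      m[0] = p[0] + t * (q[0] - p[0]);
      m[1] = p[1] + t * (q[1] - p[1]);
      m[2] = p[2] + t * (q[2] - p[2]);
      double fm = obstacle_f(g, surf, m);
      if (fm * sgn >= 0.0) lo = t; else hi = t;
    }
    double tstar = lo;
    double xs[3] = {p[0] + tstar * (q[0] - p[0]),
                    p[1] + tstar * (q[1] - p[1]),
                    p[2] + tstar * (q[2] - p[2])};
    double nrm[3];
    if (!obstacle_grad(g, surf, xs, nrm)) break;
    // reflect the remaining displacement about the tangent plane
    double rem[3] = {q[0] - xs[0], q[1] - xs[1], q[2] - xs[2]};
    double dp = rem[0] * nrm[0] + rem[1] * nrm[1] + rem[2] * nrm[2];
    rem[0] -= 2.0 * dp * nrm[0];
    rem[1] -= 2.0 * dp * nrm[1];
    rem[2] -= 2.0 * dp * nrm[2];
    // nudge the pivot to the safe side of the surface
    double side = (label > 0) ? -1.0 : 1.0;
    xs[0] += side * eps * nrm[0];
    xs[1] += side * eps * nrm[1];
    xs[2] += side * eps * nrm[2];
    p[0] = xs[0]; p[1] = xs[1]; p[2] = xs[2];
    q[0] = xs[0] + rem[0]; q[1] = xs[1] + rem[1]; q[2] = xs[2] + rem[2];
  }
  return false;
}

// Core walker.  Draws from R's RNG so set.seed() on the R side gives
// bit-reproducible runs.  wsign (length n_steps+1, entries -1/0/+1) is the
// effective PGSE gradient polarity at each recorded time point; when
// `accumulate` is true the walker keeps, per spin, the running weighted
// position sum T_i = sum_k wsign[k] * x_i(t_k) from which every
// measurement's phase follows as gamma * G * dt * (dir . T_i).
// [[Rcpp::export]]
List walk_cpp(NumericMatrix cyl, NumericMatrix sph, double edge,
              NumericMatrix start, IntegerVector label0, int n_steps,
              double step_len, int max_reflect, bool record,
              NumericVector wsign, bool accumulate) {
  Geom g = make_geom(cyl, sph, edge);
  int n = start.nrow();
  NumericMatrix final_pos(n, 3);
  NumericMatrix Tsum(accumulate ? n : 0, 3);
  NumericVector traj;
  if (record) {
    traj = NumericVector(Dimension(n, n_steps + 1, 3));
  }
  int n_rejected = 0;
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double pos[3] = {start(i, 0), start(i, 1), start(i, 2)};
    int lab = label0[i];
    double T[3] = {0.0, 0.0, 0.0};
    if (record) {
      traj[i] = pos[0];
      traj[i + (size_t)n * (n_steps + 1)] = pos[1];
      traj[i + 2 * (size_t)n * (n_steps + 1)] = pos[2];
    }
    if (accumulate && wsign[0] != 0.0) {
      T[0] += wsign[0] * pos[0];
      T[1] += wsign[0] * pos[1];
      T[2] += wsign[0] * pos[2];
    }
    for (int k = 1; k <= n_steps; ++k) {
      double z = 2.0 * unif_rand() - 1.0;
      double phi = 2.0 * M_PI * unif_rand();
      double s = std::sqrt(std::max(0.0, 1.0 - z * z));
      double dir[3] = {s * std::cos(phi), s * std::sin(phi), z};
      if (step_len > 0.0) {
        if (!do_step(g, lab, pos, dir, step_len, max_reflect)) ++n_rejected;
      }
      if (record) {
        size_t off = (size_t)i + (size_t)n * k;
        traj[off] = pos[0];
        traj[off + (size_t)n * (n_steps + 1)] = pos[1];
        traj[off + 2 * (size_t)n * (n_steps + 1)] = pos[2];
      }
      if (accumulate && wsign[k] != 0.0) {
        T[0] += wsign[k] * pos[0];
        T[1] += wsign[k] * pos[1];
        T[2] += wsign[k] * pos[2];
      }
    }
    final_pos(i, 0) = pos[0];
    final_pos(i, 1) = pos[1];
    final_pos(i, 2) = pos[2];
    if (accumulate) {
      Tsum(i, 0) = T[0]; Tsum(i, 1) = T[1]; Tsum(i, 2) = T[2];
    }
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(_["final"] = final_pos,
                          _["n_rejected"] = n_rejected);
  if (accumulate) out["T"] = Tsum;
  if (record) out["traj"] = traj;
  return out;
}

// Connected-component labelling of a binary mask (iterative flood fill).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, bool eight) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = eight ? dr8 : dr4;
  const int* dc = eight ? dc8 : dc4;
  int nnb = eight ? 8 : 4;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = cr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}
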