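// Monte Carlo kernels: rejection-free weighted joint draws under one linear
// constraint, batched cavity-field estimation on a grid, and the Hit-and-Run
// chain in null-space coordinates. All randomness comes from R's RNG so that
// set.seed() at the R level makes every run reproducible.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// Local xoshiro256++ generator, seeded once per exported call from R's RNG
// stream, so results remain a deterministic function of set.seed() while
// avoiding the per-call overhead of unif_rand() in the innermost loop.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro() {
    uint64_t seed = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
                    (uint64_t)(unif_rand() * 4294967296.0);
    for (int i = 0; i < 4; ++i) s[i] = splitmix(seed);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double runif() { return (next() >> 11) * 0x1.0p-53; }
};

struct Pop {
  std::vector<double> vals;    // sorted ascending
  std::vector<double> prefix;  // prefix[j] = sum of weights[0..j-1]
  double total;
  double lo, hi;               // declared support
  std::vector<double> hist;    // piecewise-constant density, bins over [lo,hi]
  double binw;
  bool degenerate;             // lo == hi (single admissible value)
  bool equispaced;             // O(1) window indexing applies
  bool equal_w;                // all weights equal: O(1) atom selection
  double v0, step;
};

inline double rel_tol(double a, double b) {
  return 1e-12 * std::max(1.0, std::max(std::fabs(a), std::fabs(b)));
}

Pop build_pop(const List& p, int bins) {
  Pop out;
  NumericVector v = p["values"], w = p["weights"];
  out.lo = as<double>(p["lo"]);
  out.hi = as<double>(p["hi"]);
  int Q = v.size();
  out.vals.assign(v.begin(), v.end());
  out.prefix.resize(Q + 1);
  out.prefix[0] = 0.0;
  for (int j = 0; j < Q; ++j) out.prefix[j + 1] = out.prefix[j] + w[j];
  out.total = out.prefix[Q];
  double wmin = w[0], wmax = w[0];
  for (int j = 1; j < Q; ++j) {
    if (w[j] < wmin) wmin = w[j];
    if (w[j] > wmax) wmax = w[j];
  }
  out.equal_w = (wmax - wmin) <= 1e-14 * std::max(1e-300, wmax);
  out.degenerate = (out.hi - out.lo) <= rel_tol(out.lo, out.hi);
  out.equispaced = false;
  out.v0 = out.vals.empty() ? 0.0 : out.vals[0];
  out.step = 0.0;
  if (Q >= 2) {
    double st = (out.vals[Q - 1] - out.vals[0]) / (Q - 1);
    if (st > 0) {
      bool ok = true;
      double tol = 1e-9 * (out.vals[Q - 1] - out.vals[0]);
      for (int j = 1; j < Q; ++j)
        if (std::fabs(out.vals[j] - (out.vals[0] + j * st)) > tol) {
          ok = false; break;
        }
      out.equispaced = ok;
      out.v0 = out.vals[0];
      out.step = st;
    }
  }
  if (out.degenerate) {
    out.binw = 0.0;
  } else {
    out.binw = (out.hi - out.lo) / bins;
    out.hist.assign(bins, 0.0);
    for (int j = 0; j < Q; ++j) {
      int b = (int)((out.vals[j] - out.lo) / out.binw);
      if (b < 0) b = 0;
      if (b >= bins) b = bins - 1;
      out.hist[b] += w[j];
    }
    for (int b = 0; b < bins; ++b) out.hist[b] /= out.total * out.binw;
  }
  return out;
}

// density of the population at x (histogram estimate); degenerate pops act as
// an indicator of the single admissible value (constant scale, consistent
// across evaluation points, which is all message normalization requires)
inline double rho_hat(const Pop& p, double x) {
  double tol = rel_tol(p.lo, p.hi);
  if (x < p.lo - tol || x > p.hi + tol) return 0.0;
  if (p.degenerate) return 1.0;
  int b = (int)((x - p.lo) / p.binw);
  if (b < 0) b = 0;
  if (b >= (int)p.hist.size()) b = (int)p.hist.size() - 1;
  return p.hist[b];
}

// window of values v in [lo,hi] such that coeff*v lies in [alo, ahi];
// returns false if empty
inline bool coeff_window(double coeff, double lo, double hi,
                         double alo, double ahi, double& wlo, double& whi) {
  if (coeff > 0) { wlo = alo / coeff; whi = ahi / coeff; }
  else           { wlo = ahi / coeff; whi = alo / coeff; }
  if (wlo < lo) wlo = lo;
  if (whi > hi) whi = hi;
  return whi - wlo >= -rel_tol(wlo, whi);
}

struct DrawCtx {
  std::vector<Pop> pops;
  std::vector<double> coeffs;
  std::vector<double> cmin, cmax;  // range of coeff*v over each support
  double Tlo, Thi;                 // total achievable range
  int V;
};

DrawCtx make_ctx(const List& pops, const NumericVector& coeffs, int bins) {
  DrawCtx c;
  c.V = pops.size();
  c.coeffs.assign(coeffs.begin(), coeffs.end());
  c.Tlo = c.Thi = 0.0;
  for (int l = 0; l < c.V; ++l) {
    c.pops.push_back(build_pop(pops[l], bins));
    double a = c.coeffs[l] * c.pops[l].lo, b = c.coeffs[l] * c.pops[l].hi;
    c.cmin.push_back(std::min(a, b));
    c.cmax.push_back(std::max(a, b));
    c.Tlo += c.cmin.back();
    c.Thi += c.cmax.back();
  }
  return c;
}

// pick the solved variable for an equality target c: widest feasible window,
// ties broken by largest |coefficient|, then declaration order
int pick_solved(const DrawCtx& ctx, double c) {
  int best = -1;
  double bestw = -1.0, bestc = -1.0;
  for (int l = 0; l < ctx.V; ++l) {
    double rlo = ctx.Tlo - ctx.cmin[l], rhi = ctx.Thi - ctx.cmax[l];
    double wlo, whi;
    double width = -1.0;
    if (coeff_window(ctx.coeffs[l], ctx.pops[l].lo, ctx.pops[l].hi,
                     c - rhi, c - rlo, wlo, whi))
      width = std::max(0.0, whi - wlo);
    double tol = 1e-12 * std::max(1.0, bestw);
    if (width > bestw + tol ||
        (width >= bestw - tol && std::fabs(ctx.coeffs[l]) > bestc)) {
      best = l; bestw = std::max(width, bestw); bestc = std::fabs(ctx.coeffs[l]);
    }
  }
  return best;
}

// one rejection-free draw; fills x (length V) and returns the importance
// weight (0 iff some feasible window was empty or contained no atom);
// solved < 0 means interval target (no solved variable)
double draw_one(const DrawCtx& ctx, double clo, double chi, int solved,
                std::vector<double>& x, std::vector<int>& order,
                double* n_var_draws, Xoshiro& rng) {
  const int V = ctx.V;
  for (int l = 0; l < V; ++l) x[l] = NA_REAL;
  // permutation of the sampled (non-solved) variables
  int m = 0;
  for (int l = 0; l < V; ++l) if (l != solved) order[m++] = l;
  for (int j = m - 1; j > 0; --j) {
    int k = (int)(rng.runif() * (j + 1));
    if (k > j) k = j;
    std::swap(order[j], order[k]);
  }
  double remLo = ctx.Tlo, remHi = ctx.Thi;  // range of all unset contributions
  double consumed = 0.0, w = 1.0;
  for (int jj = 0; jj < m; ++jj) {
    int l = order[jj];
    const Pop& p = ctx.pops[l];
    double rlo = remLo - ctx.cmin[l], rhi = remHi - ctx.cmax[l];
    // need coeff*v in [clo - consumed - rhi, chi - consumed - rlo]
    double wlo, whi;
    if (!coeff_window(ctx.coeffs[l], p.lo, p.hi,
                      clo - consumed - rhi, chi - consumed - rlo, wlo, whi))
      return 0.0;
    double tol = rel_tol(wlo, whi);
    size_t a, b;  // atom index range [a, b), b one past last
    if (p.equispaced) {
      double af = std::ceil((wlo - tol - p.v0) / p.step);
      double bf = std::floor((whi + tol - p.v0) / p.step);
      a = af < 0 ? 0 : (size_t)af;
      b = bf < 0 ? 0 : (size_t)bf + 1;
      if (b > p.vals.size()) b = p.vals.size();
    } else {
      a = std::lower_bound(p.vals.begin(), p.vals.end(), wlo - tol) -
          p.vals.begin();
      b = std::upper_bound(p.vals.begin(), p.vals.end(), whi + tol) -
          p.vals.begin();
    }
    if (b <= a) return 0.0;     // window holds no population atom
    double mass = p.prefix[b] - p.prefix[a];
    if (mass <= 0.0) return 0.0;
    w *= mass / p.total;
    size_t j;
    if (p.equal_w) {
      j = a + (size_t)(rng.runif() * (b - a));
      if (j >= b) j = b - 1;
    } else {
      double u = p.prefix[a] + rng.runif() * mass;
      j = std::upper_bound(p.prefix.begin() + a + 1,
                           p.prefix.begin() + b, u) -
          p.prefix.begin() - 1;
      if (j < a) j = a;
      if (j >= b) j = b - 1;
    }
    x[l] = p.vals[j];
    consumed += ctx.coeffs[l] * x[l];
    remLo = rlo; remHi = rhi;
    if (n_var_draws) *n_var_draws += 1.0;
  }
  if (solved >= 0) {
    const Pop& p = ctx.pops[solved];
    double v = (clo - consumed) / ctx.coeffs[solved];  // clo == chi here
    double tol = 1e-9 * std::max(1.0, std::max(std::fabs(p.lo),
                                               std::fabs(p.hi)));
    if (v < p.lo - tol || v > p.hi + tol) return 0.0;
    if (v < p.lo) v = p.lo;
    if (v > p.hi) v = p.hi;
    x[solved] = v;
    w *= rho_hat(p, v) / std::fabs(ctx.coeffs[solved]);
  }
  return w;
}

}  // namespace

// [[Rcpp::export]]
List cpp_joint_draws(List pops, NumericVector coeffs, NumericVector target,
                     int ndraws, int solved, int bins) {
  DrawCtx ctx = make_ctx(pops, coeffs, bins);
  double clo = target[0], chi = target[target.size() - 1];
  bool equality = (chi - clo) <= rel_tol(clo, chi);
  int k = -1;
  if (equality) {
    if (solved > 0) k = solved - 1;
    else k = pick_solved(ctx, clo);
    chi = clo;
  }
  NumericMatrix xs(ndraws, ctx.V);
  NumericVector ws(ndraws);
  std::vector<double> x(ctx.V);
  std::vector<int> order(ctx.V);
  double nvd = 0.0;
  int nzero = 0;
  Xoshiro rng;
  for (int d = 0; d < ndraws; ++d) {
    double w = draw_one(ctx, clo, chi, k, x, order, &nvd, rng);
    ws[d] = w;
    if (w == 0.0) ++nzero;
    for (int l = 0; l < ctx.V; ++l) xs(d, l) = x[l];
  }
  return List::create(_["values"] = xs, _["weights"] = ws,
                      _["solved"] = k + 1, _["n_zero_weight"] = nzero,
                      _["n_var_draws"] = nvd);
}

// Cavity-field estimation: for every grid value x of the pivot variable
// (coefficient xi), estimate by ndraws rejection-free draws the average
// weight of the constraint  xi * x + sum_l coeff_l v_l  in [target].
// With no remaining variables the field degenerates to an indicator of the
// shifted constraint being (approximately) satisfied.
// Returns the vector of means and the count of elementary variable draws.
// [[Rcpp::export]]
List cpp_estimate_L_grid(NumericVector xgrid, double xi, NumericVector target,
                         NumericVector coeffs, List pops, int ndraws,
                         int bins) {
  DrawCtx ctx = make_ctx(pops, coeffs, bins);
  int Q = xgrid.size();
  double tlo = target[0], thi = target[target.size() - 1];
  bool equality = (thi - tlo) <= rel_tol(tlo, thi);
  NumericVector means(Q);
  std::vector<double> x(std::max(ctx.V, 1));
  std::vector<int> order(std::max(ctx.V, 1));
  double nvd = 0.0;
  Xoshiro rng;
  double scale = std::max(1.0, std::max(std::fabs(tlo), std::fabs(thi)));
  for (int q = 0; q < Q; ++q) {
    double clo = tlo - xi * xgrid[q], chi = thi - xi * xgrid[q];
    if (ctx.V == 0) {
      double tol = 1e-9 * std::max(scale, std::fabs(xi * xgrid[q]));
      means[q] = (clo <= tol && chi >= -tol) ? 1.0 : 0.0;
      continue;
    }
    int k = equality ? pick_solved(ctx, clo) : -1;
    if (equality) chi = clo;
    // a forced single-variable assignment is deterministic: one draw suffices
    int nd = (equality && ctx.V == 1) ? 1 : ndraws;
    double acc = 0.0;
    for (int d = 0; d < nd; ++d)
      acc += draw_one(ctx, clo, chi, k, x, order, &nvd, rng);
    means[q] = acc / nd;
  }
  return List::create(_["means"] = means, _["n_var_draws"] = nvd);
}

// Hit-and-Run on the polytope {y : lo <= Psi y <= hi} from a strictly
// feasible y0: isotropic direction, uniform point on the feasible chord.
// Records every `thin`-th state after `burn_in` steps.
// [[Rcpp::export]]
List cpp_hit_and_run(NumericMatrix Psi, NumericVector lo, NumericVector hi,
                     NumericVector y0, int n_record, int burn_in, int thin) {
  int R = Psi.nrow(), K = Psi.ncol();
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> a(R, 0.0), b(R), d(K);
  for (int j = 0; j < R; ++j)
    for (int k = 0; k < K; ++k) a[j] += Psi(j, k) * y[k];
  NumericMatrix out(n_record, K);
  long long total = (long long)burn_in + (long long)n_record * thin;
  int rec = 0, since = 0;
  double scale = 1.0;
  for (int j = 0; j < R; ++j)
    scale = std::max(scale, std::max(std::fabs(lo[j]), std::fabs(hi[j])));
  for (long long s = 0; s < total; ++s) {
    double nrm = 0.0;
    for (int k = 0; k < K; ++k) { d[k] = norm_rand(); nrm += d[k] * d[k]; }
    nrm = std::sqrt(nrm);
    for (int k = 0; k < K; ++k) d[k] /= nrm;
    double tlo = -HUGE_VAL, thi = HUGE_VAL;
    for (int j = 0; j < R; ++j) {
      double bj = 0.0;
      for (int k = 0; k < K; ++k) bj += Psi(j, k) * d[k];
      b[j] = bj;
      if (std::fabs(bj) < 1e-13) continue;
      double t1 = (lo[j] - a[j]) / bj, t2 = (hi[j] - a[j]) / bj;
      if (bj < 0) std::swap(t1, t2);
      if (t1 > tlo) tlo = t1;
      if (t2 < thi) thi = t2;
    }
    if (!std::isfinite(tlo) || !std::isfinite(thi))
      stop("unbounded chord in hit-and-run: polytope is not bounded");
    if (thi < tlo) { tlo = 0.0; thi = 0.0; }  // float-degenerate chord: stay
    double t = tlo + unif_rand() * (thi - tlo);
    for (int k = 0; k < K; ++k) y[k] += t * d[k];
    for (int j = 0; j < R; ++j) a[j] += t * b[j];
    if (s >= burn_in) {
      if (++since >= thin) {
        since = 0;
        for (int k = 0; k < K; ++k) out(rec, k) = y[k];
        if (++rec >= n_record) break;
      }
    }
  }
  return List::create(_["samples"] = out, _["steps"] = (double)total);
}
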