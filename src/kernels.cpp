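#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_map>
using namespace Rcpp;

// ---- union-find -----------------------------------------------------------

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[ra] = rb;
}

// Cluster 2D points: any chain of points pairwise closer than `radius`
// collapses into one cluster (transitive closure, matching the physical
// picture of unresolvable diffraction-limited spots). Grid hashing keeps it
// near-linear for millions of points. Returns 1-based cluster ids.
// [[Rcpp::export(name = ".oc_merge_points")]]
IntegerVector oc_merge_points(NumericVector x, NumericVector y, double radius) {
  const int n = x.size();
  IntegerVector out(n);
  if (n == 0) return out;
  const double cell = radius;
  const double r2 = radius * radius;

  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(n * 2);
  std::vector<long long> key(n);
  for (int i = 0; i < n; ++i) {
    long long cx = (long long) std::floor(x[i] / cell);
    long long cy = (long long) std::floor(y[i] / cell);
    key[i] = (cx << 32) ^ (cy & 0xffffffffLL);
    grid[key[i]].push_back(i);
  }

  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;

  for (int i = 0; i < n; ++i) {
    long long cx = (long long) std::floor(x[i] / cell);
    long long cy = (long long) std::floor(y[i] / cell);
    for (long long dx = -1; dx <= 1; ++dx) {
      for (long long dy = -1; dy <= 1; ++dy) {
        long long k = ((cx + dx) << 32) ^ ((cy + dy) & 0xffffffffLL);
        std::unordered_map<long long, std::vector<int> >::iterator it = grid.find(k);
        if (it == grid.end()) continue;
        const std::vector<int>& cellpts = it->second;
        for (size_t j = 0; j < cellpts.size(); ++j) {
          int p = cellpts[j];
          if (p <= i) continue;
          double ddx = x[i] - x[p], ddy = y[i] - y[p];
          if (ddx * ddx + ddy * ddy < r2) uf_union(parent, i, p);
        }
      }
    }
  }

  std::unordered_map<int, int> relabel;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf_find(parent, i);
    std::unordered_map<int, int>::iterator it = relabel.find(r);
    if (it == relabel.end()) { relabel[r] = ++next; out[i] = next; }
    else out[i] = it->second;
  }
  return out;
}

// ---- penalized least-squares changepoint segmentation ---------------------

// Optimal partitioning for a piecewise-constant mean model with squared-error
// cost and a fixed per-changepoint penalty (PELT pruning). Returns the sorted
// segment end indices (1-based, excluding n).
// [[Rcpp::export(name = ".oc_segment_trace")]]
IntegerVector oc_segment_trace(NumericVector yv, double penalty) {
  const int n = yv.size();
  if (n < 2) return IntegerVector(0);
  std::vector<double> cs(n + 1, 0.0), css(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + yv[i];
    css[i + 1] = css[i] + yv[i] * yv[i];
  }
  // segment cost for y[a..b] 1-based inclusive
  #define SEGCOST(a, b) (css[(b)] - css[(a) - 1] - \
    (cs[(b)] - cs[(a) - 1]) * (cs[(b)] - cs[(a) - 1]) / ((b) - (a) + 1))

  std::vector<double> F(n + 1);
  std::vector<int> last(n + 1, 0);
  F[0] = -penalty;
  std::vector<int> cand;
  cand.push_back(0);
  for (int t = 1; t <= n; ++t) {
    double best = R_PosInf;
    int arg = 0;
    for (size_t k = 0; k < cand.size(); ++k) {
      int s = cand[k];
      double v = F[s] + SEGCOST(s + 1, t) + penalty;
      if (v < best) { best = v; arg = s; }
    }
    F[t] = best;
    last[t] = arg;
    // PELT prune
    std::vector<int> keep;
    for (size_t k = 0; k < cand.size(); ++k) {
      int s = cand[k];
      if (F[s] + SEGCOST(s + 1, t) <= F[t]) keep.push_back(s);
    }
    keep.push_back(t);
    cand.swap(keep);
  }
  #undef SEGCOST

  std::vector<int> cps;
  int t = n;
  while (t > 0) {
    int s = last[t];
    if (s > 0) cps.push_back(s);
    t = s;
  }
  std::sort(cps.begin(), cps.end());
  return wrap(cps);
}

// ---- dual-color membrane photon-count simulation --------------------------

// Brownian particles in a periodic square box, 2D Gaussian detection profile
// centred in the box. Returns per-bin Poisson counts for five photon classes:
// green signal, green background, red signal, green->red crosstalk, red
// background. Positions advance every `pos_stride` bins (diffusive motion over
// one stride is small relative to the beam waist at the resolutions used).
// Dual-labelled particles emit in both channels from the same trajectory;
// single-labelled particles emit in one.
// [[Rcpp::export(name = ".oc_fccs_counts")]]
IntegerMatrix oc_fccs_counts(int n_bins, double dt, int pos_stride,
                             int n_dual, int n_gonly, int n_ronly,
                             NumericVector D_dual, NumericVector D_gonly,
                             NumericVector D_ronly,
                             double box, double waist_g, double waist_r,
                             double bright_g, double bright_r,
                             double bg_g, double bg_r, double crosstalk) {
  const int ng = n_dual + n_gonly;       // green-labelled particles
  const int nr = n_dual + n_ronly;       // red-labelled particles
  const int ntot = n_dual + n_gonly + n_ronly;
  std::vector<double> px(ntot), py(ntot), sig(ntot);
  // index order: duals, green-only, red-only
  for (int i = 0; i < ntot; ++i) {
    px[i] = unif_rand() * box;
    py[i] = unif_rand() * box;
  }
  const double pos_dt = dt * pos_stride;
  for (int i = 0; i < n_dual; ++i) sig[i] = std::sqrt(2.0 * D_dual[i % D_dual.size()] * pos_dt);
  for (int i = 0; i < n_gonly; ++i) sig[n_dual + i] = std::sqrt(2.0 * D_gonly[i % D_gonly.size()] * pos_dt);
  for (int i = 0; i < n_ronly; ++i) sig[n_dual + n_gonly + i] = std::sqrt(2.0 * D_ronly[i % D_ronly.size()] * pos_dt);

  const double cx = box / 2.0, cy = box / 2.0;
  const double ag = 2.0 / (waist_g * waist_g), ar = 2.0 / (waist_r * waist_r);
  const double mu_bg_g = bg_g * dt, mu_bg_r = bg_r * dt;

  IntegerMatrix out(n_bins, 5);
  double lam_g = 0.0, lam_r = 0.0;
  for (int b = 0; b < n_bins; ++b) {
    if (b % pos_stride == 0) {
      if (b > 0) {
        for (int i = 0; i < ntot; ++i) {
          px[i] += norm_rand() * sig[i];
          py[i] += norm_rand() * sig[i];
          px[i] -= box * std::floor(px[i] / box);
          py[i] -= box * std::floor(py[i] / box);
        }
      }
      lam_g = 0.0; lam_r = 0.0;
      for (int i = 0; i < ntot; ++i) {
        double dx = px[i] - cx, dy = py[i] - cy;
        double r2 = dx * dx + dy * dy;
        if (i < ng) lam_g += bright_g * std::exp(-ag * r2);
        if (i < n_dual || i >= ng) lam_r += bright_r * std::exp(-ar * r2);
      }
    }
    out(b, 0) = (int) R::rpois(lam_g * dt);
    out(b, 1) = (int) R::rpois(mu_bg_g);
    out(b, 2) = (int) R::rpois(lam_r * dt);
    out(b, 3) = (int) R::rpois(crosstalk * lam_g * dt);
    out(b, 4) = (int) R::rpois(mu_bg_r);
  }
  return out;
}
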