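// Core numerical kernels for rigid-body domain assembly:
// pose -> coordinate transform, hybrid energy terms, central-difference
// gradients, Needleman-Wunsch alignment, and density-map simulation.
// Every term here is mirrored by a plain-R double-loop oracle in the tests.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Intrinsic Z-Y-X Euler rotation matrix (a about z, then b about y', then g about x'').
static arma::mat33 euler_zyx(double a, double b, double g) {
  const double ca = std::cos(a), sa = std::sin(a);
  const double cb = std::cos(b), sb = std::sin(b);
  const double cg = std::cos(g), sg = std::sin(g);
  arma::mat33 R;
  R(0, 0) = ca * cb; R(0, 1) = ca * sb * sg - sa * cg; R(0, 2) = ca * sb * cg + sa * sg;
  R(1, 0) = sa * cb; R(1, 1) = sa * sb * sg + ca * cg; R(1, 2) = sa * sb * cg - ca * sg;
  R(2, 0) = -sb;     R(2, 1) = cb * sg;                R(2, 2) = cb * cg;
  return R;
}

// params: 6 per domain (3 Euler angles, 3 translations); rotation about the
// centroid of the INPUT coordinates so rotation and translation decouple.
static arma::mat pose_coords(const arma::vec& params, const arma::mat& X0,
                             const arma::ivec& dom_idx, const arma::mat& centroids) {
  const int ndom = centroids.n_rows;
  std::vector<arma::mat33> Rs(ndom);
  arma::mat shift(ndom, 3);
  for (int d = 0; d < ndom; ++d) {
    Rs[d] = euler_zyx(params[6 * d], params[6 * d + 1], params[6 * d + 2]);
    shift.row(d) = centroids.row(d) +
      arma::rowvec({params[6 * d + 3], params[6 * d + 4], params[6 * d + 5]});
  }
  arma::mat X(X0.n_rows, 3);
  for (arma::uword i = 0; i < X0.n_rows; ++i) {
    const int d = dom_idx[i];
    arma::rowvec v = X0.row(i) - centroids.row(d);
    X.row(i) = v * Rs[d].t() + shift.row(d);
  }
  return X;
}

// [[Rcpp::export]]
arma::mat cpp_pose_coords(const arma::vec& params, const arma::mat& X0,
                          const arma::ivec& dom_idx, const arma::mat& centroids) {
  return pose_coords(params, X0, dom_idx, centroids);
}

static inline double pdist(const arma::mat& X, int i, int j) {
  const double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1), dz = X(i, 2) - X(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Natural cubic spline evaluation from precomputed second derivatives,
// flat (clamped to end values) outside the knot range.
static double spline_eval(double x, const arma::vec& knots, const arma::vec& y,
                          const arma::vec& m) {
  const int n = knots.n_elem;
  if (x <= knots[0]) return y[0];
  if (x >= knots[n - 1]) return y[n - 1];
  int k = 0;
  while (k < n - 2 && x > knots[k + 1]) ++k;
  const double h = knots[k + 1] - knots[k];
  const double A = (knots[k + 1] - x) / h, B = (x - knots[k]) / h;
  return A * y[k] + B * y[k + 1] +
    ((A * A * A - A) * m[k] + (B * B * B - B) * m[k + 1]) * h * h / 6.0;
}

// Raw (unweighted) energy terms. pdata holds 0-based row indices into X.
static arma::vec energy_terms(const arma::mat& X, const List& pdata) {
  arma::vec terms(7, arma::fill::zeros); // dist, contact, clash, generic, conn, template, (dgram folded into dist)

  // Gaussian distance restraints: sum w * min(((d-mean)/sd)^2, 16)
  const arma::ivec gi = pdata["gi"], gj = pdata["gj"];
  const arma::vec gmean = pdata["gmean"], gsd = pdata["gsd"], gw = pdata["gw"];
  for (arma::uword r = 0; r < gi.n_elem; ++r) {
    const double z = (pdist(X, gi[r], gj[r]) - gmean[r]) / gsd[r];
    terms[0] += gw[r] * std::min(z * z, 16.0);
  }
  // Distogram restraints: spline-interpolated -log probability profile.
  const arma::ivec dgi = pdata["dgi"], dgj = pdata["dgj"];
  if (dgi.n_elem > 0) {
    const arma::vec centers = pdata["dg_centers"];
    const arma::mat dy = pdata["dg_y"], dm = pdata["dg_m"];
    for (arma::uword r = 0; r < dgi.n_elem; ++r) {
      terms[0] += spline_eval(pdist(X, dgi[r], dgj[r]), centers,
                              dy.row(r).t(), dm.row(r).t());
    }
  }
  // Interface contacts: prob * ((d-18)/2)^2 capped at 16 beyond 18 A.
  const arma::ivec ci = pdata["ci"], cj = pdata["cj"];
  const arma::vec cprob = pdata["cprob"];
  for (arma::uword r = 0; r < ci.n_elem; ++r) {
    const double d = pdist(X, ci[r], cj[r]);
    if (d > 18.0) {
      const double z = (d - 18.0) / 2.0;
      terms[1] += cprob[r] * std::min(z * z, 16.0);
    }
  }
  // Inter-domain pairs: steric clash everywhere, generic contact on
  // consecutive-domain blocks (gen_block >= 0).
  const arma::ivec pi = pdata["pi"], pj = pdata["pj"], gblock = pdata["gen_block"];
  const arma::vec ncap = pdata["gen_cap"];
  arma::vec nint(ncap.n_elem, arma::fill::zeros);
  for (arma::uword r = 0; r < pi.n_elem; ++r) {
    const double d = pdist(X, pi[r], pj[r]);
    if (d < 3.8) { const double z = 3.8 - d; terms[2] += z * z; }
    const int b = gblock[r];
    if (b >= 0 && d >= 4.5 && d <= 8.0) nint[b] += 1.0;
  }
  for (arma::uword b = 0; b < ncap.n_elem; ++b)
    terms[3] -= std::min(nint[b], ncap[b]) / ncap[b];
  // Domain-boundary connectivity: max(0, d_term - 3.8*(g+1))^2.
  const arma::ivec bi = pdata["bi"], bj = pdata["bj"];
  const arma::vec bspan = pdata["bspan"];
  for (arma::uword r = 0; r < bi.n_elem; ++r) {
    const double over = pdist(X, bi[r], bj[r]) - bspan[r];
    if (over > 0) terms[4] += over * over;
  }
  // Template distance profile: tm_h-weighted mean over hits of the
  // per-hit mean capped harmonic well.
  const arma::ivec ti = pdata["ti"], tj = pdata["tj"], thit = pdata["t_hit"];
  const arma::vec td = pdata["t_d"], hw = pdata["hit_w"];
  if (hw.n_elem > 0 && ti.n_elem > 0) {
    arma::vec hsum(hw.n_elem, arma::fill::zeros);
    arma::vec hcnt(hw.n_elem, arma::fill::zeros);
    for (arma::uword r = 0; r < ti.n_elem; ++r) {
      const double z = (pdist(X, ti[r], tj[r]) - td[r]) / 2.0;
      hsum[thit[r]] += std::min(z * z, 16.0);
      hcnt[thit[r]] += 1.0;
    }
    double num = 0.0, den = 0.0;
    for (arma::uword h = 0; h < hw.n_elem; ++h) {
      if (hcnt[h] > 0) { num += hw[h] * hsum[h] / hcnt[h]; den += hw[h]; }
    }
    if (den > 0) terms[5] = num / den;
  }
  return terms;
}

// [[Rcpp::export]]
arma::vec cpp_energy_terms(const arma::mat& X, const List& pdata) {
  return energy_terms(X, pdata);
}

static double weighted_total(const arma::vec& t, const arma::vec& w) {
  // w: w_dist, w_contact, w_clash, w_generic, w_conn, w_template
  return w[0] * t[0] + w[1] * t[1] + w[2] * t[2] + w[3] * t[3] + w[4] * t[4] + w[5] * t[5];
}

// [[Rcpp::export]]
double cpp_total_energy(const arma::vec& params, const arma::mat& X0,
                        const arma::ivec& dom_idx, const arma::mat& centroids,
                        const List& pdata, const arma::vec& w) {
  const arma::mat X = pose_coords(params, X0, dom_idx, centroids);
  return weighted_total(energy_terms(X, pdata), w);
}

// Central finite differences, step 1e-4 (radians / Angstrom).
// [[Rcpp::export]]
arma::vec cpp_energy_grad(const arma::vec& params, const arma::mat& X0,
                          const arma::ivec& dom_idx, const arma::mat& centroids,
                          const List& pdata, const arma::vec& w, double step = 1e-4) {
  arma::vec g(params.n_elem);
  arma::vec p = params;
  for (arma::uword k = 0; k < params.n_elem; ++k) {
    p[k] = params[k] + step;
    const double fp = cpp_total_energy(p, X0, dom_idx, centroids, pdata, w);
    p[k] = params[k] - step;
    const double fm = cpp_total_energy(p, X0, dom_idx, centroids, pdata, w);
    p[k] = params[k];
    g[k] = (fp - fm) / (2.0 * step);
  }
  return g;
}

// Simulated density: sum of spherical Gaussians (sigma in A) at atom
// positions, truncated at 4 sigma, accumulated on a regular grid.
// [[Rcpp::export]]
arma::vec cpp_simulate_map(const arma::mat& X, const arma::vec& origin,
                           double voxel, const arma::ivec& dims, double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  arma::vec vals((arma::uword)nx * ny * nz, arma::fill::zeros);
  const double cut = 4.0 * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (arma::uword a = 0; a < X.n_rows; ++a) {
    const double ax = X(a, 0), ay = X(a, 1), az = X(a, 2);
    int i0 = std::max(0, (int)std::ceil((ax - cut - origin[0]) / voxel));
    int i1 = std::min(nx - 1, (int)std::floor((ax + cut - origin[0]) / voxel));
    int j0 = std::max(0, (int)std::ceil((ay - cut - origin[1]) / voxel));
    int j1 = std::min(ny - 1, (int)std::floor((ay + cut - origin[1]) / voxel));
    int k0 = std::max(0, (int)std::ceil((az - cut - origin[2]) / voxel));
    int k1 = std::min(nz - 1, (int)std::floor((az + cut - origin[2]) / voxel));
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * voxel - az;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * voxel - ay;
        const double dyz2 = dy * dy + dz * dz;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * voxel - ax;
          const double r2 = dx * dx + dyz2;
          if (r2 <= cut * cut)
            vals[(arma::uword)i + (arma::uword)nx * (j + (arma::uword)ny * k)] +=
              std::exp(-r2 * inv2s2);
        }
      }
    }
  }
  return vals;
}

// Masked Pearson correlation between an experimental map and the map
// simulated from X on the same grid; mask = voxels where either map
// exceeds 1e-6 of its own maximum.
// [[Rcpp::export]]
double cpp_map_correlation(const arma::mat& X, const arma::vec& mapvals,
                           const arma::vec& origin, double voxel,
                           const arma::ivec& dims, double sigma) {
  const arma::vec sim = cpp_simulate_map(X, origin, voxel, dims, sigma);
  const double t1 = 1e-6 * mapvals.max();
  const double t2 = 1e-6 * (sim.n_elem ? sim.max() : 0.0);
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0; long n = 0;
  for (arma::uword v = 0; v < sim.n_elem; ++v) {
    if (mapvals[v] > t1 || sim[v] > t2) {
      const double x = mapvals[v], y = sim[v];
      sx += x; sy += y; sxx += x * x; syy += y * y; sxy += x * y; ++n;
    }
  }
  if (n < 2) return 0.0;
  const double vx = sxx - sx * sx / n, vy = syy - sy * sy / n;
  if (vx <= 0 || vy <= 0) return 0.0;
  return (sxy - sx * sy / n) / std::sqrt(vx * vy);
}

// Gradient of (1 - correlation) w.r.t. pose parameters (central differences).
// [[Rcpp::export]]
arma::vec cpp_density_grad(const arma::vec& params, const arma::mat& X0,
                           const arma::ivec& dom_idx, const arma::mat& centroids,
                           const arma::vec& mapvals, const arma::vec& origin,
                           double voxel, const arma::ivec& dims, double sigma,
                           double step = 1e-4) {
  arma::vec g(params.n_elem);
  arma::vec p = params;
  for (arma::uword k = 0; k < params.n_elem; ++k) {
    p[k] = params[k] + step;
    const double fp = -cpp_map_correlation(pose_coords(p, X0, dom_idx, centroids),
                                           mapvals, origin, voxel, dims, sigma);
    p[k] = params[k] - step;
    const double fm = -cpp_map_correlation(pose_coords(p, X0, dom_idx, centroids),
                                           mapvals, origin, voxel, dims, sigma);
    p[k] = params[k];
    g[k] = (fp - fm) / (2.0 * step);
  }
  return g;
}

// Least-squares (Kabsch) superposition of paired coordinate blocks.
struct Sup { arma::mat33 R; arma::vec3 t; bool ok; };

static Sup kabsch3(const arma::mat& q, const arma::mat& r) {
  Sup out; out.ok = false;
  if (q.n_rows < 3) return out;
  arma::rowvec cq = arma::mean(q, 0), cr = arma::mean(r, 0);
  arma::mat qc = q.each_row() - cq, rc = r.each_row() - cr;
  arma::mat33 H = qc.t() * rc;
  arma::mat U, V; arma::vec s;
  if (!arma::svd(U, s, V, H)) return out;
  double d = arma::det(V * U.t());
  arma::mat33 D = arma::eye(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;
  out.R = V * D * U.t();
  out.t = cr.t() - out.R * cq.t();
  out.ok = true;
  return out;
}

static arma::mat apply_sup(const arma::mat& x, const Sup& s) {
  arma::mat y = x * s.R.t();
  y.each_row() += s.t.t();
  return y;
}

// TM-score maximized over fragment-seeded superpositions with iterative
// distance-cutoff refinement (seeds: all gapless alignment windows of
// lengths L_ali, L_ali/2, 4).
// [[Rcpp::export]]
double cpp_tm_search(const arma::mat& q, const arma::mat& r, double d0,
                     double L_norm) {
  const int La = q.n_rows;
  const double base_cut = std::max(d0, 4.5);
  std::vector<int> lens;
  if (La <= 24) {
    // small problems: exhaustive over all fragment lengths
    for (int wl = 3; wl <= La; ++wl) lens.push_back(wl);
  } else {
    for (int cand : {La, La / 2, 4}) {
      int wl = std::max(3, std::min(La, cand));
      if (std::find(lens.begin(), lens.end(), wl) == lens.end()) lens.push_back(wl);
    }
  }
  double best = 0.0;
  arma::vec d(La);
  for (int wl : lens) {
    for (int off = 0; off + wl <= La; ++off) {
      Sup sup = kabsch3(q.rows(off, off + wl - 1), r.rows(off, off + wl - 1));
      if (!sup.ok) continue;
      std::vector<int> prev_sel;
      for (int it = 0; it < 20; ++it) {
        arma::mat qt = apply_sup(q, sup);
        double sc = 0.0;
        for (int i = 0; i < La; ++i) {
          d[i] = arma::norm(qt.row(i) - r.row(i), 2);
          sc += 1.0 / (1.0 + (d[i] / d0) * (d[i] / d0));
        }
        best = std::max(best, sc / L_norm);
        double cut = base_cut;
        std::vector<int> sel;
        for (;;) {
          sel.clear();
          for (int i = 0; i < La; ++i) if (d[i] < cut) sel.push_back(i);
          if ((int)sel.size() >= 3) break;
          cut += 0.5;
        }
        if (sel == prev_sel) break;
        prev_sel = sel;
        arma::uvec usel(sel.size());
        for (size_t k = 0; k < sel.size(); ++k) usel[k] = sel[k];
        Sup s2 = kabsch3(q.rows(usel), r.rows(usel));
        if (!s2.ok) break;
        sup = s2;
      }
    }
  }
  return best;
}

static IntegerMatrix nw_core(const arma::mat& S, double gap);

// Fragment-seeded iterative DP alignment (simplified TM-align). seeds:
// rows of (qo, ro, wl), 1-based window starts. mask: reference residues
// that may not be aligned. Returns best alignment, its query-normalized
// TM-score and the superposition.
// [[Rcpp::export]]
List cpp_struct_align(const arma::mat& q, const arma::mat& r,
                      const LogicalVector& mask, double d0, double gap,
                      const IntegerMatrix& seeds, int max_iter = 30) {
  const int Lq = q.n_rows, Lr = r.n_rows;
  double best_tm = 0.0;
  arma::imat best_pairs;
  Sup best_sup; best_sup.ok = false;
  const double d02 = d0 * d0;
  for (int s = 0; s < seeds.nrow(); ++s) {
    const int qo = seeds(s, 0) - 1, ro = seeds(s, 1) - 1, wl = seeds(s, 2);
    Sup sup = kabsch3(q.rows(qo, qo + wl - 1), r.rows(ro, ro + wl - 1));
    if (!sup.ok) continue;
    arma::imat prev;
    for (int it = 0; it < max_iter; ++it) {
      arma::mat qt = apply_sup(q, sup);
      arma::mat S(Lq, Lr);
      for (int i = 0; i < Lq; ++i) {
        for (int j = 0; j < Lr; ++j) {
          if (mask[j]) { S(i, j) = -1e6; continue; }
          double dx = qt(i, 0) - r(j, 0), dy = qt(i, 1) - r(j, 1),
                 dz = qt(i, 2) - r(j, 2);
          S(i, j) = 1.0 / (1.0 + (dx * dx + dy * dy + dz * dz) / d02);
        }
      }
      IntegerMatrix pr = nw_core(S, gap);
      const int np = pr.nrow();
      if (np < 4) break;
      arma::mat qp(np, 3), rp(np, 3);
      for (int k = 0; k < np; ++k) {
        qp.row(k) = q.row(pr(k, 0) - 1);
        rp.row(k) = r.row(pr(k, 1) - 1);
      }
      Sup s2 = kabsch3(qp, rp);
      if (!s2.ok) break;
      sup = s2;
      arma::mat qpt = apply_sup(qp, sup);
      double tm = 0.0;
      for (int k = 0; k < np; ++k) {
        double dd = arma::norm(qpt.row(k) - rp.row(k), 2);
        tm += 1.0 / (1.0 + (dd / d0) * (dd / d0));
      }
      tm /= Lq;
      arma::imat cur(np, 2);
      for (int k = 0; k < np; ++k) { cur(k, 0) = pr(k, 0); cur(k, 1) = pr(k, 1); }
      if (tm > best_tm) { best_tm = tm; best_pairs = cur; best_sup = sup; }
      if (cur.n_rows == prev.n_rows && arma::all(arma::vectorise(cur == prev)))
        break;
      prev = cur;
    }
  }
  if (!best_sup.ok || best_pairs.n_rows == 0) {
    return List::create(Named("pairs") = IntegerMatrix(0, 2),
                        Named("tm") = 0.0);
  }
  IntegerMatrix pout(best_pairs.n_rows, 2);
  for (arma::uword k = 0; k < best_pairs.n_rows; ++k) {
    pout(k, 0) = best_pairs(k, 0); pout(k, 1) = best_pairs(k, 1);
  }
  NumericMatrix Rm(3, 3);
  for (int a = 0; a < 3; ++a) for (int b = 0; b < 3; ++b) Rm(a, b) = best_sup.R(a, b);
  return List::create(Named("pairs") = pout, Named("tm") = best_tm,
                      Named("rotation") = Rm,
                      Named("translation") = NumericVector::create(
                        best_sup.t[0], best_sup.t[1], best_sup.t[2]));
}

// Needleman-Wunsch global alignment over a similarity matrix with a
// linear gap penalty (TM-align style, gap typically -0.6). Returns the
// 1-based (query, reference) pairs on the optimal path, strictly
// increasing in both indices.
static IntegerMatrix nw_core(const arma::mat& S, double gap) {
  const int n = S.n_rows, m = S.n_cols;
  arma::mat F(n + 1, m + 1, arma::fill::zeros);
  arma::imat P(n + 1, m + 1, arma::fill::zeros); // 1 diag, 2 up, 3 left
  for (int i = 1; i <= n; ++i) { F(i, 0) = F(i - 1, 0) + gap; P(i, 0) = 2; }
  for (int j = 1; j <= m; ++j) { F(0, j) = F(0, j - 1) + gap; P(0, j) = 3; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double d = F(i - 1, j - 1) + S(i - 1, j - 1);
      const double u = F(i - 1, j) + gap;
      const double l = F(i, j - 1) + gap;
      if (d >= u && d >= l) { F(i, j) = d; P(i, j) = 1; }
      else if (u >= l)      { F(i, j) = u; P(i, j) = 2; }
      else                  { F(i, j) = l; P(i, j) = 3; }
    }
  }
  std::vector<int> qi, ri;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int p = P(i, j);
    if (p == 1) { qi.push_back(i), ri.push_back(j); --i; --j; }
    else if (p == 2) --i;
    else --j;
  }
  const int np = qi.size();
  IntegerMatrix out(np, 2);
  for (int r = 0; r < np; ++r) {
    out(r, 0) = qi[np - 1 - r];
    out(r, 1) = ri[np - 1 - r];
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_nw_align(const arma::mat& S, double gap) {
  return nw_core(S, gap);
}
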