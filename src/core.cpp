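// Compiled cores: G2 radial symmetry functions, bias-free feed-forward
// site-energy network, Metropolis Monte Carlo with fluctuation-formula
// accumulators, and PMF-matching pretraining.
//
// Conventions fixed here and relied on by the R level:
//  - energies are in Kelvin (E/kB), beta = 1/T;
//  - minimum-image distances in an orthorhombic box;
//  - weight layout: layer l maps sizes[l] -> sizes[l+1], element (out j, in i)
//    at offset_l + j*sizes[l] + i (output-major), no biases;
//  - ReLU'(0) = 0; site energies summed in ascending site order;
//  - RDF bin alpha covers [alpha*dr, (alpha+1)*dr), normalization uses the
//    shell volume 4*pi*r_center^2*dr (exact_shell switches to the exact one);
//  - all randomness comes from R's RNG (unif_rand), so set.seed() governs
//    every stochastic path.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

inline double wrap01(double x, double L) {
  double y = x - L * std::floor(x / L);
  if (y >= L) y -= L;   // guard against floor round-off
  return y;
}

inline double dist_pbc(const double* p, int i, int j, const double* box) {
  double dx = min_image(p[3 * i]     - p[3 * j],     box[0]);
  double dy = min_image(p[3 * i + 1] - p[3 * j + 1], box[1]);
  double dz = min_image(p[3 * i + 2] - p[3 * j + 2], box[2]);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

inline double fc_cos(double r, double rc) {
  if (r >= rc) return 0.0;
  return 0.5 * (std::cos(PI_ * r / rc) + 1.0);
}

// ---------------------------------------------------------------------------
// Descriptor machinery
// ---------------------------------------------------------------------------

struct DescSpec {
  std::vector<double> eta, rs;
  double rc = 0.0;
  int K = 0;
  int type = 0;  // 0 = Gaussian * cosine cutoff, 1 = indicator bins (test-only)
  double dr = 1.0;  // indicator bin width = rc / K
};

// Per-pair descriptor contributions for distance r; adds into out[K].
inline void desc_terms_add(const DescSpec& ds, double r, double* out, double sign) {
  if (r >= ds.rc) return;
  if (ds.type == 1) {
    int b = (int)(r / ds.dr);
    if (b >= 0 && b < ds.K) out[b] += sign;
    return;
  }
  double fc = fc_cos(r, ds.rc);
  for (int i = 0; i < ds.K; ++i) {
    double d = r - ds.rs[i];
    double a = ds.eta[i] * d * d;
    if (a < 40.0) out[i] += sign * std::exp(-a) * fc;
  }
}

static void g2_full(const double* p, int N, const double* box,
                    const DescSpec& ds, double* G /* N*K */) {
  std::memset(G, 0, sizeof(double) * (size_t)N * ds.K);
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double r = dist_pbc(p, i, j, box);
      if (r < ds.rc) {
        desc_terms_add(ds, r, G + (size_t)i * ds.K, 1.0);
        desc_terms_add(ds, r, G + (size_t)j * ds.K, 1.0);
      }
    }
}

// [[Rcpp::export]]
NumericMatrix cpp_g2_matrix(NumericMatrix pos, NumericVector box,
                            NumericVector eta, NumericVector rs, double rc,
                            int desc_type) {
  int N = pos.nrow(), K = eta.size();
  DescSpec ds;
  ds.eta.assign(eta.begin(), eta.end());
  ds.rs.assign(rs.begin(), rs.end());
  ds.rc = rc; ds.K = K; ds.type = desc_type; ds.dr = rc / K;
  std::vector<double> p((size_t)3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) p[3 * i + d] = pos(i, d);
  std::vector<double> G((size_t)N * K);
  g2_full(p.data(), N, REAL(box), ds, G.data());
  NumericMatrix out(N, K);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) out(i, k) = G[(size_t)i * K + k];
  return out;
}

// ---------------------------------------------------------------------------
// Network forward / backward (no biases)
// ---------------------------------------------------------------------------

struct Net {
  std::vector<int> sizes;          // [K, h1, ..., 1]
  std::vector<size_t> offs;        // weight offset per layer
  size_t nw;
  int L;                           // number of weight layers
  int maxw;                        // max layer width
  const double* w;
  void init(const std::vector<int>& sz, const double* wptr) {
    sizes = sz;
    L = (int)sz.size() - 1;
    offs.assign(L, 0);
    nw = 0; maxw = 0;
    for (int l = 0; l < L; ++l) {
      offs[l] = nw;
      nw += (size_t)sz[l] * sz[l + 1];
    }
    for (int l = 0; l <= L; ++l) if (sz[l] > maxw) maxw = sz[l];
    w = wptr;
  }
};

// Forward pass for one site; act must have room for (L+1)*maxw doubles and
// receives all layer activations (post-nonlinearity). Returns site energy.
static double net_forward(const Net& net, const double* x, double* act) {
  std::memcpy(act, x, sizeof(double) * net.sizes[0]);
  for (int l = 0; l < net.L; ++l) {
    const double* a = act + (size_t)l * net.maxw;
    double* z = act + (size_t)(l + 1) * net.maxw;
    int nin = net.sizes[l], nout = net.sizes[l + 1];
    const double* W = net.w + net.offs[l];
    for (int j = 0; j < nout; ++j) {
      double s = 0.0;
      const double* wj = W + (size_t)j * nin;
      for (int i = 0; i < nin; ++i) s += wj[i] * a[i];
      z[j] = (l < net.L - 1) ? (s > 0.0 ? s : 0.0) : s;   // ReLU hidden, identity out
    }
  }
  return act[(size_t)net.L * net.maxw];
}

// Backward: accumulates dE_site/dw into grad (sign * contribution).
// act holds activations from net_forward for the same input.
static void net_backward(const Net& net, const double* act, double* grad,
                         double sign, double* delta_buf /* 2*maxw */) {
  double* dcur = delta_buf;
  double* dprev = delta_buf + net.maxw;
  dcur[0] = 1.0;
  for (int l = net.L - 1; l >= 0; --l) {
    int nin = net.sizes[l], nout = net.sizes[l + 1];
    const double* a = act + (size_t)l * net.maxw;
    const double* z = act + (size_t)(l + 1) * net.maxw;
    const double* W = net.w + net.offs[l];
    double* g = grad + net.offs[l];
    // mask deltas by ReLU derivative at this layer's output (hidden only)
    for (int j = 0; j < nout; ++j) {
      double dj = dcur[j];
      if (l < net.L - 1 && z[j] <= 0.0) dj = 0.0;
      dcur[j] = dj;
      if (dj != 0.0) {
        double* gj = g + (size_t)j * nin;
        double sd = sign * dj;
        for (int i = 0; i < nin; ++i) gj[i] += sd * a[i];
      }
    }
    if (l > 0) {
      for (int i = 0; i < nin; ++i) dprev[i] = 0.0;
      for (int j = 0; j < nout; ++j) {
        double dj = dcur[j];
        if (dj == 0.0) continue;
        const double* wj = W + (size_t)j * nin;
        for (int i = 0; i < nin; ++i) dprev[i] += wj[i] * dj;
      }
      std::swap(dcur, dprev);
    }
  }
  if (dcur != delta_buf)
    std::memcpy(delta_buf, dcur, sizeof(double) * net.sizes[0]);
}

static std::vector<int> as_sizes(const IntegerVector& sz) {
  return std::vector<int>(sz.begin(), sz.end());
}

// [[Rcpp::export]]
NumericVector cpp_site_energies(NumericMatrix G, IntegerVector sizes,
                                NumericVector w) {
  int N = G.nrow(), K = G.ncol();
  Net net; std::vector<int> sz = as_sizes(sizes);
  net.init(sz, REAL(w));
  if (net.sizes[0] != K) stop("descriptor width does not match network input");
  std::vector<double> act((size_t)(net.L + 1) * net.maxw);
  std::vector<double> x(K);
  NumericVector out(N);
  for (int n = 0; n < N; ++n) {
    for (int k = 0; k < K; ++k) x[k] = G(n, k);
    out[n] = net_forward(net, x.data(), act.data());
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_energy_grad(NumericMatrix G, IntegerVector sizes,
                              NumericVector w) {
  int N = G.nrow(), K = G.ncol();
  Net net; std::vector<int> sz = as_sizes(sizes);
  net.init(sz, REAL(w));
  if (net.sizes[0] != K) stop("descriptor width does not match network input");
  std::vector<double> act((size_t)(net.L + 1) * net.maxw);
  std::vector<double> delta(2 * (size_t)net.maxw);
  std::vector<double> x(K);
  NumericVector grad(net.nw);
  std::fill(grad.begin(), grad.end(), 0.0);
  for (int n = 0; n < N; ++n) {
    for (int k = 0; k < K; ++k) x[k] = G(n, k);
    net_forward(net, x.data(), act.data());
    net_backward(net, act.data(), REAL(grad), 1.0, delta.data());
  }
  return grad;
}

// ---------------------------------------------------------------------------
// Pair histogram / angular histogram
// ---------------------------------------------------------------------------

static void pair_hist(const double* p, int N, const double* box,
                      double rmax, int nbins, double* counts) {
  double dr = rmax / nbins;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double r = dist_pbc(p, i, j, box);
      if (r < rmax) counts[(int)(r / dr)] += 1.0;
    }
}

// [[Rcpp::export]]
NumericVector cpp_pair_hist(NumericMatrix pos, NumericVector box,
                            double rmax, int nbins) {
  int N = pos.nrow();
  std::vector<double> p((size_t)3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) p[3 * i + d] = pos(i, d);
  NumericVector counts(nbins);
  pair_hist(p.data(), N, REAL(box), rmax, nbins, REAL(counts));
  return counts;
}

// Histogram of central angles (degrees in [0,180]) over all unordered
// neighbour pairs within r_shell of each central site.
// [[Rcpp::export]]
NumericVector cpp_angular_hist(NumericMatrix pos, NumericVector box,
                               double r_shell, int nbins) {
  int N = pos.nrow();
  std::vector<double> p((size_t)3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) p[3 * i + d] = pos(i, d);
  const double* b = REAL(box);
  NumericVector counts(nbins);
  double w = 180.0 / nbins;
  std::vector<int> nb; nb.reserve(64);
  std::vector<double> dv; dv.reserve(192);
  for (int c = 0; c < N; ++c) {
    nb.clear(); dv.clear();
    for (int j = 0; j < N; ++j) {
      if (j == c) continue;
      double dx = min_image(p[3 * j]     - p[3 * c],     b[0]);
      double dy = min_image(p[3 * j + 1] - p[3 * c + 1], b[1]);
      double dz = min_image(p[3 * j + 2] - p[3 * c + 2], b[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 <= r_shell * r_shell && r2 > 0) {
        nb.push_back(j);
        dv.push_back(dx); dv.push_back(dy); dv.push_back(dz);
      }
    }
    int m = (int)nb.size();
    for (int a = 0; a < m; ++a)
      for (int bb = a + 1; bb < m; ++bb) {
        double ux = dv[3 * a], uy = dv[3 * a + 1], uz = dv[3 * a + 2];
        double vx = dv[3 * bb], vy = dv[3 * bb + 1], vz = dv[3 * bb + 2];
        double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
        double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
        double ct = (ux * vx + uy * vy + uz * vz) / (nu * nv);
        if (ct > 1.0) ct = 1.0;
        if (ct < -1.0) ct = -1.0;
        double ang = std::acos(ct) * 180.0 / PI_;
        int k = (int)(ang / w);
        if (k >= nbins) k = nbins - 1;
        counts[k] += 1.0;
      }
  }
  return counts;
}

// ---------------------------------------------------------------------------
// Energy models for MC
// ---------------------------------------------------------------------------

struct EnergyModel {
  int type;                  // 0 LJ, 1 tabulated pair, 2 network on G2
  // LJ
  double eps, sigma, rcut;
  // table
  std::vector<double> tab;   // V per bin, bin width tab_dr, 0 beyond
  double tab_dr;
  // network
  DescSpec ds;
  Net net;
  std::vector<double> wstore;
  // mutable NN state bound to a configuration
  std::vector<double> G;     // N*K
  std::vector<double> Es;    // per-site energies
  // scratch
  std::vector<double> act, delta, rowbuf, dGbuf;
  std::vector<int> affected;

  double pair_energy(double r) const {
    if (type == 0) {
      if (r >= rcut) return 0.0;
      double s6 = std::pow(sigma / r, 6);
      return 4.0 * eps * (s6 * s6 - s6);
    }
    int bdx = (int)(r / tab_dr);
    if (bdx < 0 || bdx >= (int)tab.size()) return 0.0;
    return tab[bdx];
  }

  void bind(const double* p, int N, const double* box) {
    if (type != 2) return;
    G.assign((size_t)N * ds.K, 0.0);
    g2_full(p, N, box, ds, G.data());
    Es.assign(N, 0.0);
    for (int n = 0; n < N; ++n)
      Es[n] = net_forward(net, G.data() + (size_t)n * ds.K, act.data());
  }

  double total_energy(const double* p, int N, const double* box) {
    if (type == 2) {
      double e = 0.0;
      for (int n = 0; n < N; ++n) e += Es[n];
      return e;
    }
    double e = 0.0;
    double rmaxm = (type == 0) ? rcut : tab_dr * tab.size();
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double r = dist_pbc(p, i, j, box);
        if (r < rmaxm) e += pair_energy(r);
      }
    return e;
  }
};

// Proposed-move bookkeeping for the NN model (so accepts can commit lazily).
struct NNMove {
  int n;
  std::vector<double> row_new;        // new row of the moved site
  std::vector<int> aff;               // affected other sites
  std::vector<double> dG;             // per affected site: K deltas
  std::vector<double> Enew;           // new site energies: [moved, affected...]
};

// dE for moving site n from pold to pnew (positions array p still holds pold).
static double nn_delta_e(EnergyModel& em, const double* p, int N,
                         const double* box, int n, const double* pold,
                         const double* pnew, NNMove& mv) {
  int K = em.ds.K;
  mv.n = n;
  mv.row_new.assign(K, 0.0);
  mv.aff.clear();
  mv.dG.clear();
  std::vector<double>& tmp = em.rowbuf;  // K scratch
  for (int j = 0; j < N; ++j) {
    if (j == n) continue;
    double dxo = min_image(pold[0] - p[3 * j],     box[0]);
    double dyo = min_image(pold[1] - p[3 * j + 1], box[1]);
    double dzo = min_image(pold[2] - p[3 * j + 2], box[2]);
    double ro = std::sqrt(dxo * dxo + dyo * dyo + dzo * dzo);
    double dxn = min_image(pnew[0] - p[3 * j],     box[0]);
    double dyn = min_image(pnew[1] - p[3 * j + 1], box[1]);
    double dzn = min_image(pnew[2] - p[3 * j + 2], box[2]);
    double rn = std::sqrt(dxn * dxn + dyn * dyn + dzn * dzn);
    if (rn < em.ds.rc) desc_terms_add(em.ds, rn, mv.row_new.data(), 1.0);
    if (ro < em.ds.rc || rn < em.ds.rc) {
      std::fill(tmp.begin(), tmp.end(), 0.0);
      desc_terms_add(em.ds, rn, tmp.data(), 1.0);
      desc_terms_add(em.ds, ro, tmp.data(), -1.0);
      bool nonzero = false;
      for (int k = 0; k < K; ++k) if (tmp[k] != 0.0) { nonzero = true; break; }
      if (nonzero) {
        mv.aff.push_back(j);
        for (int k = 0; k < K; ++k) mv.dG.push_back(tmp[k]);
      }
    }
  }
  mv.Enew.clear();
  double en = net_forward(em.net, mv.row_new.data(), em.act.data());
  mv.Enew.push_back(en);
  double dE = en - em.Es[n];
  for (size_t a = 0; a < mv.aff.size(); ++a) {
    int j = mv.aff[a];
    const double* gj = em.G.data() + (size_t)j * K;
    for (int k = 0; k < K; ++k) em.rowbuf[k] = gj[k] + mv.dG[a * K + k];
    double ej = net_forward(em.net, em.rowbuf.data(), em.act.data());
    mv.Enew.push_back(ej);
    dE += ej - em.Es[j];
  }
  return dE;
}

static void nn_commit(EnergyModel& em, const NNMove& mv) {
  int K = em.ds.K;
  double* rown = em.G.data() + (size_t)mv.n * K;
  std::memcpy(rown, mv.row_new.data(), sizeof(double) * K);
  em.Es[mv.n] = mv.Enew[0];
  for (size_t a = 0; a < mv.aff.size(); ++a) {
    int j = mv.aff[a];
    double* gj = em.G.data() + (size_t)j * K;
    for (int k = 0; k < K; ++k) gj[k] += mv.dG[a * K + k];
    em.Es[j] = mv.Enew[a + 1];
  }
}

static double pair_delta_e(const EnergyModel& em, const double* p, int N,
                           const double* box, int n, const double* pold,
                           const double* pnew) {
  double rmaxm = (em.type == 0) ? em.rcut : em.tab_dr * em.tab.size();
  double dE = 0.0;
  for (int j = 0; j < N; ++j) {
    if (j == n) continue;
    double dxo = min_image(pold[0] - p[3 * j],     box[0]);
    double dyo = min_image(pold[1] - p[3 * j + 1], box[1]);
    double dzo = min_image(pold[2] - p[3 * j + 2], box[2]);
    double ro = std::sqrt(dxo * dxo + dyo * dyo + dzo * dzo);
    double dxn = min_image(pnew[0] - p[3 * j],     box[0]);
    double dyn = min_image(pnew[1] - p[3 * j + 1], box[1]);
    double dzn = min_image(pnew[2] - p[3 * j + 2], box[2]);
    double rn = std::sqrt(dxn * dxn + dyn * dyn + dzn * dzn);
    if (rn < rmaxm) dE += em.pair_energy(rn);
    if (ro < rmaxm) dE -= em.pair_energy(ro);
  }
  return dE;
}

static void model_from_list(EnergyModel& em, int model_type, List model) {
  em.type = model_type;
  if (model_type == 0) {
    em.eps = as<double>(model["eps"]);
    em.sigma = as<double>(model["sigma"]);
    em.rcut = as<double>(model["rcut"]);
  } else if (model_type == 1) {
    NumericVector tv = model["values"];
    em.tab.assign(tv.begin(), tv.end());
    em.tab_dr = as<double>(model["dr"]);
  } else {
    NumericVector eta = model["eta"], rs = model["rs"], w = model["w"];
    IntegerVector sizes = model["sizes"];
    em.ds.eta.assign(eta.begin(), eta.end());
    em.ds.rs.assign(rs.begin(), rs.end());
    em.ds.rc = as<double>(model["rc"]);
    em.ds.K = eta.size();
    em.ds.type = as<int>(model["desc_type"]);
    em.ds.dr = em.ds.rc / em.ds.K;
    em.wstore.assign(w.begin(), w.end());
    em.net.init(as_sizes(sizes), em.wstore.data());
    if (em.net.sizes[0] != em.ds.K)
      stop("network input width does not match descriptor count");
    if ((size_t)w.size() != em.net.nw) stop("weight vector length mismatch");
    em.act.assign((size_t)(em.net.L + 1) * em.net.maxw, 0.0);
    em.delta.assign(2 * (size_t)em.net.maxw, 0.0);
    em.rowbuf.assign(em.ds.K, 0.0);
  }
}

// ---------------------------------------------------------------------------
// Metropolis MC driver
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix pos0, NumericVector box_in, double beta,
                int model_type, List model,
                double rdf_rmax, int rdf_nbins,
                double steps_d, double equil_d, int out_freq,
                double maxd0, double target_acc, bool adapt, int adapt_interval,
                bool collect_grad, bool collect_scov, bool keep_samples,
                int n_save_frames, bool exact_shell) {
  RNGScope scope;
  int N = pos0.nrow();
  if (N < 2) stop("need at least 2 sites");
  long long steps = (long long)steps_d, equil = (long long)equil_d;
  if (equil >= steps) stop("equilibration must be shorter than total steps");
  if (out_freq < 1) stop("output frequency must be >= 1");
  std::vector<double> p((size_t)3 * N);
  double box[3] = { box_in[0], box_in[1], box_in[2] };
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) p[3 * i + d] = wrap01(pos0(i, d), box[d]);

  EnergyModel em;
  model_from_list(em, model_type, model);
  em.bind(p.data(), N, box);
  NNMove mv;

  double V = box[0] * box[1] * box[2];
  double dr = rdf_rmax / rdf_nbins;
  double npairs = 0.5 * N * (N - 1.0);
  std::vector<double> norm(rdf_nbins);
  for (int a = 0; a < rdf_nbins; ++a) {
    double shell;
    if (exact_shell) {
      double r0 = a * dr, r1 = (a + 1) * dr;
      shell = 4.0 * PI_ / 3.0 * (r1 * r1 * r1 - r0 * r0 * r0);
    } else {
      double rcen = (a + 0.5) * dr;
      shell = 4.0 * PI_ * rcen * rcen * dr;
    }
    norm[a] = npairs * shell / V;
  }

  size_t nw = (model_type == 2) ? em.net.nw : 0;
  std::vector<double> g_sum(rdf_nbins, 0.0);
  std::vector<double> dEdw_sum(collect_grad ? nw : 0, 0.0);
  std::vector<double> cross_sum(collect_grad ? (size_t)rdf_nbins * nw : 0, 0.0);
  std::vector<double> S_sum(collect_scov ? rdf_nbins : 0, 0.0);
  std::vector<double> SS_sum(collect_scov ? (size_t)rdf_nbins * rdf_nbins : 0, 0.0);
  long long n_samples_exp = (steps - equil) / out_freq;
  NumericMatrix g_samples(keep_samples ? (int)n_samples_exp : 0,
                          keep_samples ? rdf_nbins : 0);
  std::vector<double> counts(rdf_nbins), g_inst(rdf_nbins), dEdw(nw);

  List frames(n_save_frames > 0 ? n_save_frames : 0);
  long long frame_every = n_save_frames > 0
    ? std::max((long long)1, (steps - equil) / n_save_frames) : 0;
  int frames_saved = 0;

  double maxd = maxd0;
  long long acc_prod = 0, att_prod = 0, acc_win = 0, att_win = 0;
  long long n_samples = 0, samp_row = 0;
  double pold[3], pnew[3];

  for (long long step = 1; step <= steps; ++step) {
    int n = (int)(N * unif_rand());
    if (n >= N) n = N - 1;
    for (int d = 0; d < 3; ++d) {
      pold[d] = p[3 * n + d];
      pnew[d] = wrap01(pold[d] + maxd * (2.0 * unif_rand() - 1.0), box[d]);
    }
    double dE = (em.type == 2)
      ? nn_delta_e(em, p.data(), N, box, n, pold, pnew, mv)
      : pair_delta_e(em, p.data(), N, box, n, pold, pnew);
    bool ok = R_finite(dE);
    bool accepted = false;
    if (ok) {
      if (dE <= 0.0) accepted = true;
      else accepted = (unif_rand() < std::exp(-beta * dE));
    }
    if (accepted) {
      if (em.type == 2) nn_commit(em, mv);
      for (int d = 0; d < 3; ++d) p[3 * n + d] = pnew[d];
    }
    bool in_equil = step <= equil;
    if (in_equil) {
      ++att_win; if (accepted) ++acc_win;
      if (adapt && att_win >= adapt_interval) {
        double ratio = (double)acc_win / att_win;
        maxd *= std::exp(0.6 * (ratio - target_acc));
        double cap = 0.25 * std::min(box[0], std::min(box[1], box[2]));
        if (maxd > cap) maxd = cap;
        if (maxd < 1e-4) maxd = 1e-4;
        acc_win = att_win = 0;
      }
    } else {
      ++att_prod; if (accepted) ++acc_prod;
      long long post = step - equil;
      if (post % out_freq == 0) {
        std::fill(counts.begin(), counts.end(), 0.0);
        pair_hist(p.data(), N, box, rdf_rmax, rdf_nbins, counts.data());
        for (int a = 0; a < rdf_nbins; ++a) {
          g_inst[a] = counts[a] / norm[a];
          g_sum[a] += g_inst[a];
        }
        if (collect_grad) {
          std::fill(dEdw.begin(), dEdw.end(), 0.0);
          for (int s = 0; s < N; ++s) {
            net_forward(em.net, em.G.data() + (size_t)s * em.ds.K, em.act.data());
            net_backward(em.net, em.act.data(), dEdw.data(), 1.0, em.delta.data());
          }
          for (size_t i = 0; i < nw; ++i) dEdw_sum[i] += dEdw[i];
          for (int a = 0; a < rdf_nbins; ++a) {
            double ga = g_inst[a];
            if (ga != 0.0) {
              double* row = cross_sum.data() + (size_t)a * nw;
              for (size_t i = 0; i < nw; ++i) row[i] += ga * dEdw[i];
            }
          }
        }
        if (collect_scov) {
          for (int a = 0; a < rdf_nbins; ++a) S_sum[a] += counts[a];
          for (int a = 0; a < rdf_nbins; ++a) {
            double ca = counts[a];
            if (ca != 0.0) {
              double* row = SS_sum.data() + (size_t)a * rdf_nbins;
              for (int c2 = 0; c2 < rdf_nbins; ++c2) row[c2] += ca * counts[c2];
            }
          }
        }
        if (keep_samples && samp_row < n_samples_exp) {
          for (int a = 0; a < rdf_nbins; ++a)
            g_samples((int)samp_row, a) = g_inst[a];
          ++samp_row;
        }
        ++n_samples;
      }
      if (n_save_frames > 0 && frames_saved < n_save_frames &&
          post % frame_every == 0) {
        NumericMatrix fr(N, 3);
        for (int i = 0; i < N; ++i)
          for (int d = 0; d < 3; ++d) fr(i, d) = p[3 * i + d];
        frames[frames_saved++] = fr;
      }
    }
  }
  if (n_samples == 0) stop("no post-equilibration samples were collected");

  NumericVector g_mean(rdf_nbins);
  for (int a = 0; a < rdf_nbins; ++a) g_mean[a] = g_sum[a] / n_samples;
  NumericMatrix pos_final(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) pos_final(i, d) = p[3 * i + d];

  List out = List::create(
    _["g"] = g_mean,
    _["n_samples"] = (double)n_samples,
    _["acceptance"] = att_prod > 0 ? (double)acc_prod / att_prod : NA_REAL,
    _["max_disp"] = maxd,
    _["pos"] = pos_final,
    _["energy"] = em.total_energy(p.data(), N, box),
    _["frames"] = frames);
  if (collect_grad) {
    NumericVector dm(nw);
    for (size_t i = 0; i < nw; ++i) dm[i] = dEdw_sum[i] / n_samples;
    NumericMatrix cm(rdf_nbins, (int)nw);
    for (int a = 0; a < rdf_nbins; ++a)
      for (size_t i = 0; i < nw; ++i)
        cm(a, (int)i) = cross_sum[(size_t)a * nw + i] / n_samples;
    out["dEdw"] = dm;
    out["cross"] = cm;
  }
  if (collect_scov) {
    NumericVector sm(rdf_nbins);
    for (int a = 0; a < rdf_nbins; ++a) sm[a] = S_sum[a] / n_samples;
    NumericMatrix ssm(rdf_nbins, rdf_nbins);
    for (int a = 0; a < rdf_nbins; ++a)
      for (int c2 = 0; c2 < rdf_nbins; ++c2)
        ssm(a, c2) = SS_sum[(size_t)a * rdf_nbins + c2] / n_samples;
    out["S"] = sm;
    out["SS"] = ssm;
  }
  if (keep_samples) out["g_samples"] = g_samples;
  return out;
}

// Single Metropolis step (exposed for unit-level checks of the acceptance
// rule); returns new positions, dE and the acceptance flag.
// [[Rcpp::export]]
List cpp_metropolis_step(NumericMatrix pos, NumericVector box_in, double beta,
                         int model_type, List model, double maxd) {
  RNGScope scope;
  int N = pos.nrow();
  std::vector<double> p((size_t)3 * N);
  double box[3] = { box_in[0], box_in[1], box_in[2] };
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) p[3 * i + d] = wrap01(pos(i, d), box[d]);
  EnergyModel em;
  model_from_list(em, model_type, model);
  em.bind(p.data(), N, box);
  NNMove mv;
  int n = (int)(N * unif_rand());
  if (n >= N) n = N - 1;
  double pold[3], pnew[3];
  for (int d = 0; d < 3; ++d) {
    pold[d] = p[3 * n + d];
    pnew[d] = wrap01(pold[d] + maxd * (2.0 * unif_rand() - 1.0), box[d]);
  }
  double dE = (em.type == 2)
    ? nn_delta_e(em, p.data(), N, box, n, pold, pnew, mv)
    : pair_delta_e(em, p.data(), N, box, n, pold, pnew);
  bool accepted = false;
  if (R_finite(dE)) {
    if (dE <= 0.0) accepted = true;
    else accepted = (unif_rand() < std::exp(-beta * dE));
  } else {
    Rf_warning("non-finite energy change; move rejected");
  }
  if (accepted)
    for (int d = 0; d < 3; ++d) p[3 * n + d] = pnew[d];
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = p[3 * i + d];
  return List::create(_["pos"] = out, _["dE"] = dE,
                      _["accepted"] = accepted, _["site"] = n + 1);
}

// ---------------------------------------------------------------------------
// AMSGrad
// ---------------------------------------------------------------------------

static void amsgrad_update(std::vector<double>& w, const std::vector<double>& g,
                           std::vector<double>& m, std::vector<double>& v,
                           std::vector<double>& vhat, long long& t,
                           double lr, double b1, double b2, double eps) {
  ++t;
  double c1 = 1.0 - std::pow(b1, (double)t);
  double c2 = 1.0 - std::pow(b2, (double)t);
  for (size_t i = 0; i < w.size(); ++i) {
    m[i] = b1 * m[i] + (1.0 - b1) * g[i];
    v[i] = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
    if (v[i] > vhat[i]) vhat[i] = v[i];
    w[i] -= lr * (m[i] / c1) / (std::sqrt(vhat[i] / c2) + eps);
  }
}

// [[Rcpp::export]]
List cpp_amsgrad_step(NumericVector w_in, NumericVector g_in,
                      NumericVector m_in, NumericVector v_in,
                      NumericVector vhat_in, double t_in,
                      double lr, double b1, double b2, double eps) {
  std::vector<double> w(w_in.begin(), w_in.end());
  std::vector<double> g(g_in.begin(), g_in.end());
  std::vector<double> m(m_in.begin(), m_in.end());
  std::vector<double> v(v_in.begin(), v_in.end());
  std::vector<double> vh(vhat_in.begin(), vhat_in.end());
  long long t = (long long)t_in;
  amsgrad_update(w, g, m, v, vh, t, lr, b1, b2, eps);
  return List::create(_["w"] = wrap(w), _["m"] = wrap(m), _["v"] = wrap(v),
                      _["vhat"] = wrap(vh), _["t"] = (double)t);
}

// ---------------------------------------------------------------------------
// PMF-matching pretraining
// ---------------------------------------------------------------------------

// systems: list of list(frames = list of N x 3 matrices, box = len-3,
//                       pmf = values per bin, pmf_dr = bin width)
// The gradient of the per-step loss only involves sites whose G2 rows change,
// so the cached descriptor matrices make each step O(N * K).
// [[Rcpp::export]]
List cpp_pretrain(List systems, NumericVector eta, NumericVector rs, double rc,
                  int desc_type, IntegerVector sizes, NumericVector w0,
                  double maxd, int n_steps, double lr, double b1, double b2,
                  double adam_eps, List opt_in) {
  RNGScope scope;
  int S = systems.size();
  DescSpec ds;
  ds.eta.assign(eta.begin(), eta.end());
  ds.rs.assign(rs.begin(), rs.end());
  ds.rc = rc; ds.K = eta.size(); ds.type = desc_type; ds.dr = rc / ds.K;
  std::vector<double> w(w0.begin(), w0.end());
  Net net; net.init(as_sizes(sizes), w.data());
  if (net.sizes[0] != ds.K) stop("descriptor/network width mismatch");
  if (w.size() != net.nw) stop("weight vector length mismatch");

  struct Sys {
    std::vector<std::vector<double>> pos;   // frames, 3N each
    std::vector<std::vector<double>> G;     // cached descriptor matrices
    double box[3];
    std::vector<double> pmf;
    double pmf_dr;
    int N;
  };
  std::vector<Sys> sys(S);
  for (int s = 0; s < S; ++s) {
    List ls = systems[s];
    List fr = ls["frames"];
    if (fr.size() == 0) stop("system %d has an empty frame pool", s + 1);
    NumericVector bx = ls["box"];
    NumericVector pm = ls["pmf"];
    sys[s].box[0] = bx[0]; sys[s].box[1] = bx[1]; sys[s].box[2] = bx[2];
    sys[s].pmf.assign(pm.begin(), pm.end());
    sys[s].pmf_dr = as<double>(ls["pmf_dr"]);
    int nf = fr.size();
    sys[s].pos.resize(nf);
    sys[s].G.resize(nf);
    for (int f = 0; f < nf; ++f) {
      NumericMatrix fm = fr[f];
      int N = fm.nrow();
      sys[s].N = N;
      sys[s].pos[f].resize((size_t)3 * N);
      for (int i = 0; i < N; ++i)
        for (int d = 0; d < 3; ++d)
          sys[s].pos[f][3 * i + d] = wrap01(fm(i, d), sys[s].box[d]);
      sys[s].G[f].assign((size_t)N * ds.K, 0.0);
      g2_full(sys[s].pos[f].data(), N, sys[s].box, ds, sys[s].G[f].data());
    }
  }

  std::vector<double> m(net.nw, 0.0), v(net.nw, 0.0), vh(net.nw, 0.0);
  long long t = 0;
  if (opt_in.size() > 0) {
    NumericVector mi = opt_in["m"], vi = opt_in["v"], vhi = opt_in["vhat"];
    m.assign(mi.begin(), mi.end());
    v.assign(vi.begin(), vi.end());
    vh.assign(vhi.begin(), vhi.end());
    t = (long long)as<double>(opt_in["t"]);
  }

  std::vector<double> act((size_t)(net.L + 1) * net.maxw);
  std::vector<double> delta(2 * (size_t)net.maxw);
  std::vector<double> grad(net.nw), gstep(net.nw);
  std::vector<double> row_old(ds.K), row_new(ds.K), tmp(ds.K), rowk(ds.K);
  NumericVector loss_hist(n_steps);

  for (int step = 0; step < n_steps; ++step) {
    std::fill(grad.begin(), grad.end(), 0.0);
    double loss_acc = 0.0;
    for (int s = 0; s < S; ++s) {
      Sys& sy = sys[s];
      int nf = (int)sy.pos.size();
      int f = (int)(nf * unif_rand()); if (f >= nf) f = nf - 1;
      const double* p = sy.pos[f].data();
      const double* G = sy.G[f].data();
      int N = sy.N;
      int n = (int)(N * unif_rand()); if (n >= N) n = N - 1;
      double pold[3], pnew[3];
      for (int d = 0; d < 3; ++d) {
        pold[d] = p[3 * n + d];
        pnew[d] = wrap01(pold[d] + maxd * (2.0 * unif_rand() - 1.0), sy.box[d]);
      }
      // Energy changes and gradient difference from affected rows only.
      std::memcpy(row_old.data(), G + (size_t)n * ds.K, sizeof(double) * ds.K);
      std::fill(row_new.begin(), row_new.end(), 0.0);
      double dE_nn = 0.0, dE_pmf = 0.0;
      std::fill(gstep.begin(), gstep.end(), 0.0);
      int npmf = (int)sy.pmf.size();
      for (int j = 0; j < N; ++j) {
        if (j == n) continue;
        double dxo = min_image(pold[0] - p[3 * j],     sy.box[0]);
        double dyo = min_image(pold[1] - p[3 * j + 1], sy.box[1]);
        double dzo = min_image(pold[2] - p[3 * j + 2], sy.box[2]);
        double ro = std::sqrt(dxo * dxo + dyo * dyo + dzo * dzo);
        double dxn = min_image(pnew[0] - p[3 * j],     sy.box[0]);
        double dyn = min_image(pnew[1] - p[3 * j + 1], sy.box[1]);
        double dzn = min_image(pnew[2] - p[3 * j + 2], sy.box[2]);
        double rn = std::sqrt(dxn * dxn + dyn * dyn + dzn * dzn);
        if (rn < ds.rc) desc_terms_add(ds, rn, row_new.data(), 1.0);
        int bo = (int)(ro / sy.pmf_dr), bn = (int)(rn / sy.pmf_dr);
        if (bn < npmf) dE_pmf += sy.pmf[bn];
        if (bo < npmf) dE_pmf -= sy.pmf[bo];
        if (ro < ds.rc || rn < ds.rc) {
          std::fill(tmp.begin(), tmp.end(), 0.0);
          desc_terms_add(ds, rn, tmp.data(), 1.0);
          desc_terms_add(ds, ro, tmp.data(), -1.0);
          bool nz = false;
          for (int k = 0; k < ds.K; ++k) if (tmp[k] != 0.0) { nz = true; break; }
          if (!nz) continue;
          const double* gj = G + (size_t)j * ds.K;
          for (int k = 0; k < ds.K; ++k) rowk[k] = gj[k] + tmp[k];
          double e_new = net_forward(net, rowk.data(), act.data());
          net_backward(net, act.data(), gstep.data(), 1.0, delta.data());
          double e_old = net_forward(net, gj, act.data());
          net_backward(net, act.data(), gstep.data(), -1.0, delta.data());
          dE_nn += e_new - e_old;
        }
      }
      double en_new = net_forward(net, row_new.data(), act.data());
      net_backward(net, act.data(), gstep.data(), 1.0, delta.data());
      double en_old = net_forward(net, row_old.data(), act.data());
      net_backward(net, act.data(), gstep.data(), -1.0, delta.data());
      dE_nn += en_new - en_old;

      double resid = dE_nn - dE_pmf;
      loss_acc += resid * resid;
      for (size_t i = 0; i < net.nw; ++i) grad[i] += 2.0 * resid * gstep[i];
    }
    loss_acc /= S;
    for (size_t i = 0; i < net.nw; ++i) grad[i] /= S;
    loss_hist[step] = loss_acc;
    amsgrad_update(w, grad, m, v, vh, t, lr, b1, b2, adam_eps);
    net.w = w.data();   // vector storage may be reused; keep pointer fresh
  }
  return List::create(
    _["w"] = wrap(w), _["loss"] = loss_hist,
    _["opt"] = List::create(_["m"] = wrap(m), _["v"] = wrap(v),
                            _["vhat"] = wrap(vh), _["t"] = (double)t));
}
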