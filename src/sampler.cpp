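// Carlin-Chib sampler for the two-model phenotype similarity regression.
//
// The model indicator gamma is drawn from its full conditional; within-model
// parameters move by Metropolis-Hastings random walks while the inactive
// model's parameters are refreshed from tuned pseudopriors. The
// characteristic phenotype is parameterized as an unrestricted ordered
// k-vector of usable-term indices ("phi tilde"); its minimal-set reduction
// drives the similarity computation and carries a preimage-counting prior so
// that the induced prior over minimal sets is the intended one.
//
// All randomness comes from R's RNG (RNGScope), so results are reproducible
// under set.seed().

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline double softplus(double x) {
  return x > 30.0 ? x : std::log1p(std::exp(x));
}

static inline bool in_sorted(const std::vector<int>& v, int x) {
  return std::binary_search(v.begin(), v.end(), x);
}

// tiny linear-scan memo: per-call distinct arguments are few, so a linear
// search beats hashing
struct SmallMemo {
  std::vector<double> zs, vs;
  double get(double z, double a, double b) {
    for (size_t i = 0; i < zs.size(); ++i)
      if (zs[i] == z) return vs[i];
    double v = R::pbeta(z, a, b, 1, 0);
    zs.push_back(z); vs.push_back(v);
    return v;
  }
};

namespace {

struct Problem {
  int N, U, D, k;
  std::vector<int> y;
  std::vector<double> h;
  bool h_zero;
  const double* P;              // U x D column-major
  std::vector<int> xflat;       // 0-based column indices into P
  std::vector<int> xptr;        // N + 1 offsets
  double sum_y;
  std::vector< std::vector<int> > anc;  // per usable term, sorted, incl self
  std::vector< std::vector<int> > nb;   // usable neighbours
  std::vector<double> term_w;   // frequency proposal probs (sum 1)
  std::vector<double> term_w_cum;
  double pw_unif, pw_nb, pw_freq;       // phi proposal mixture
  // priors
  double pi, a_mean, a_sd, lb_mean, lb_sd;
  double t_lmean[4], t_lsd[4];
  bool lit;
  double log_unif_phi;          // -log |Phi(k)|
  std::vector<double> lit_score; // lit_rate * best-match Lin, per usable term
  double log_lit_Z;
  // modes
  bool fixed_trans;
  std::vector<double> alpha_grid, beta_grid; // empty => continuous
  bool grid() const { return !alpha_grid.empty(); }
};

struct Pseudo {
  bool have;
  double a0_m, a0_s, a1_m, a1_s, lb_m, lb_s;
  double lt_m[4], lt_s[4];
  // empirical phi-tilde table
  double mix_w;
  std::vector<double> phi_probs, phi_cum;
  std::vector<int> phi_vecs;    // k * M, column-major
  std::unordered_map<double, double> phi_map; // key -> prob
  // grid-mode categorical pseudopriors
  std::vector<double> a0_p, a1_p, b_p;
  std::vector<double> a0_cum, a1_cum, b_cum;
};

struct State {
  int gamma;
  double alpha0, alpha1, logbeta;
  double ltr[4];
  int ia0, ia1, ib;             // grid indices (grid mode)
  std::vector<int> phiv;        // k raw coordinates
  std::vector<int> red;         // reduced minimal set
  std::vector<double> sphi, sx, S;
  std::vector<int> nz;          // subjects with nonzero similarity
  double ll0, ll1, lp_phi;      // cached
};

double phi_key(const std::vector<int>& phiv, int U) {
  double key = 0, mult = 1;
  for (size_t j = 0; j < phiv.size(); ++j) {
    key += phiv[j] * mult;
    mult *= U;
  }
  return key;
}

std::vector<int> reduce_phi(const std::vector<int>& phiv, const Problem& pb) {
  std::vector<int> red;
  int k = (int)phiv.size();
  for (int j = 0; j < k; ++j) {
    int t = phiv[j];
    bool drop = false;
    for (int l = 0; l < k && !drop; ++l) {
      if (l == j) continue;
      int u = phiv[l];
      if (u == t) { if (l < j) drop = true; }
      else if (in_sorted(pb.anc[u], t)) drop = true;  // t strict anc of u
    }
    if (!drop) red.push_back(t);
  }
  return red;
}

double log_count_preimage(const std::vector<int>& red, const Problem& pb) {
  int p = (int)red.size();
  double a;
  if (p == 1) {
    a = (double)pb.anc[red[0]].size();
  } else {
    std::vector<int> uni(pb.anc[red[0]]);
    for (int l = 1; l < p; ++l) {
      std::vector<int> merged;
      std::set_union(uni.begin(), uni.end(),
                     pb.anc[red[l]].begin(), pb.anc[red[l]].end(),
                     std::back_inserter(merged));
      uni.swap(merged);
    }
    a = (double)uni.size();
  }
  static const double ch[4][4] = {{1,0,0,0},{1,1,0,0},{1,2,1,0},{1,3,3,1}};
  double cnt = 0, sign = 1;
  for (int i = 0; i <= p; ++i) {
    cnt += sign * ch[p][i] * std::pow(a - i, (double)pb.k);
    sign = -sign;
  }
  return std::log(cnt);
}

double log_prior_phi_tilde(const std::vector<int>& red, const Problem& pb) {
  double lp;
  if (pb.lit) {
    lp = 0;
    for (size_t l = 0; l < red.size(); ++l) lp += pb.lit_score[red[l]];
    lp -= pb.log_lit_Z;
  } else {
    lp = pb.log_unif_phi;
  }
  return lp - log_count_preimage(red, pb);
}

// similarity profile for a reduced phi under transforms (af, bf, ag, bg)
void compute_sim(const std::vector<int>& red, const double* tr,
                 const Problem& pb,
                 std::vector<double>& sphi, std::vector<double>& sx,
                 std::vector<double>& S, std::vector<int>& nz) {
  int p = (int)red.size();
  SmallMemo fm, gm;
  nz.clear();
  std::vector<double> pm(p);
  // gather the p rows of P used by this phi into a contiguous buffer so the
  // per-annotation inner loop stays in L1 cache
  std::vector<double> rows((size_t)p * pb.D);
  for (int l = 0; l < p; ++l)
    for (int d = 0; d < pb.D; ++d)
      rows[(size_t)l * pb.D + d] = pb.P[(size_t)pb.U * d + red[l]];
  for (int i = 0; i < pb.N; ++i) {
    int st = pb.xptr[i], len = pb.xptr[i + 1] - st;
    if (len == 0) { sphi[i] = 0; sx[i] = 0; S[i] = 0; continue; }
    for (int l = 0; l < p; ++l) pm[l] = 0;
    double sxsum = 0;
    for (int j = 0; j < len; ++j) {
      int d = pb.xflat[st + j];
      double dm = 0;
      for (int l = 0; l < p; ++l) {
        double v = rows[(size_t)l * pb.D + d];
        if (v > pm[l]) pm[l] = v;
        if (v > dm) dm = v;
      }
      sxsum += dm;
    }
    double ssum = 0;
    for (int l = 0; l < p; ++l) ssum += pm[l];
    double a_ = ssum / p, b_ = sxsum / len;
    sphi[i] = a_; sx[i] = b_;
    if (a_ <= 0 || b_ <= 0) { S[i] = 0; continue; }
    S[i] = fm.get(a_, tr[0], tr[1]) * gm.get(b_, tr[2], tr[3]);
    nz.push_back(i);
  }
}

// cache of raw similarity profiles keyed by the reduced phi (the raw
// asymmetric similarities do not depend on the transforms); pseudoprior
// draws revisit few distinct phi vectors, so hit rates are high
struct SimCache {
  struct Entry { std::vector<double> sphi, sx; std::vector<int> nz; };
  std::unordered_map<double, Entry> map;
  double key(const std::vector<int>& red, int U) const {
    std::vector<int> s(red); std::sort(s.begin(), s.end());
    double k = 0, mult = 1;
    for (size_t j = 0; j < s.size(); ++j) {
      k += (s[j] + 1) * mult;
      mult *= (U + 1);
    }
    return k;
  }
};

// reapply transforms to cached raw similarities (S is zero off the
// nonzero list, which only depends on phi, not the transforms)
void apply_transform(const std::vector<double>& sphi,
                     const std::vector<double>& sx,
                     const std::vector<int>& nz, const double* tr,
                     std::vector<double>& S) {
  SmallMemo fm, gm;
  std::fill(S.begin(), S.end(), 0.0);
  for (size_t j = 0; j < nz.size(); ++j) {
    int i = nz[j];
    S[i] = fm.get(sphi[i], tr[0], tr[1]) * gm.get(sx[i], tr[2], tr[3]);
  }
}

void compute_sim_cached(SimCache& cache, const std::vector<int>& red,
                        const double* tr, const Problem& pb,
                        std::vector<double>& sphi, std::vector<double>& sx,
                        std::vector<double>& S, std::vector<int>& nz) {
  double key = cache.key(red, pb.U);
  std::unordered_map<double, SimCache::Entry>::iterator it =
    cache.map.find(key);
  if (it == cache.map.end()) {
    compute_sim(red, tr, pb, sphi, sx, S, nz);
    if (cache.map.size() > 1024) cache.map.clear();
    SimCache::Entry& e = cache.map[key];
    e.sphi = sphi; e.sx = sx; e.nz = nz;
    return;
  }
  sphi = it->second.sphi;
  sx = it->second.sx;
  nz = it->second.nz;
  apply_transform(sphi, sx, nz, tr, S);
}

double loglik0(double alpha, const Problem& pb) {
  if (pb.h_zero)
    return pb.sum_y * alpha - pb.N * softplus(alpha);
  double ll = 0;
  for (int i = 0; i < pb.N; ++i) {
    double eta = alpha + pb.h[i];
    ll += pb.y[i] * eta - softplus(eta);
  }
  return ll;
}

double loglik1(double alpha, double beta, const std::vector<double>& S,
               const std::vector<int>& nz, const Problem& pb) {
  double ll = 0;
  if (pb.h_zero) {
    // subjects off the nonzero list share eta = alpha
    double ynz = 0;
    for (size_t j = 0; j < nz.size(); ++j) {
      int i = nz[j];
      double eta = alpha + beta * S[i];
      ll += pb.y[i] * eta - softplus(eta);
      ynz += pb.y[i];
    }
    ll += (pb.sum_y - ynz) * alpha -
      (pb.N - (double)nz.size()) * softplus(alpha);
    return ll;
  }
  for (int i = 0; i < pb.N; ++i) {
    double eta = alpha + pb.h[i] + beta * S[i];
    ll += pb.y[i] * eta - softplus(eta);
  }
  return ll;
}

// phi-tilde coordinate proposal density q(to | from)
double phi_prop_dens(int from, int to, const Problem& pb) {
  double dens = pb.pw_unif / pb.U;
  const std::vector<int>& nbf = pb.nb[from];
  if (nbf.empty()) dens += pb.pw_nb / pb.U;
  else if (in_sorted(nbf, to)) dens += pb.pw_nb / nbf.size();
  dens += pb.pw_freq * pb.term_w[to];
  return dens;
}

int draw_categorical(const std::vector<double>& cum) {
  double u = R::unif_rand() * cum.back();
  int i = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
  return i < (int)cum.size() ? i : (int)cum.size() - 1;
}

int propose_phi_coord(int from, const Problem& pb) {
  double u = R::unif_rand();
  if (u < pb.pw_unif) {
    return (int)(R::unif_rand() * pb.U) % pb.U;
  } else if (u < pb.pw_unif + pb.pw_nb) {
    const std::vector<int>& nbf = pb.nb[from];
    if (nbf.empty()) return (int)(R::unif_rand() * pb.U) % pb.U;
    return nbf[(int)(R::unif_rand() * nbf.size()) % nbf.size()];
  }
  return draw_categorical(pb.term_w_cum);
}

double pseudo_phi_logdens(const std::vector<int>& phiv, const Problem& pb,
                          const Pseudo& ps) {
  double unif = std::exp(-pb.k * std::log((double)pb.U));
  double emp = 0;
  if (!ps.phi_map.empty()) {
    std::unordered_map<double, double>::const_iterator it =
      ps.phi_map.find(phi_key(phiv, pb.U));
    if (it != ps.phi_map.end()) emp = it->second;
  }
  return std::log(ps.mix_w * emp + (1 - ps.mix_w) * unif);
}

void pseudo_phi_draw(std::vector<int>& phiv, const Problem& pb,
                     const Pseudo& ps) {
  if (!ps.phi_cum.empty() && R::unif_rand() < ps.mix_w) {
    int m = draw_categorical(ps.phi_cum);
    for (int j = 0; j < pb.k; ++j) phiv[j] = ps.phi_vecs[m * pb.k + j];
  } else {
    for (int j = 0; j < pb.k; ++j)
      phiv[j] = (int)(R::unif_rand() * pb.U) % pb.U;
  }
}

double dnorm_log(double x, double m, double s) {
  return R::dnorm(x, m, s, 1);
}

} // namespace

// [[Rcpp::export(name = ".cc_sampler")]]
List cc_sampler(IntegerVector y, NumericVector h, NumericMatrix P,
                IntegerVector x_flat, IntegerVector x_ptr,
                List anc, List nb, NumericVector term_w,
                NumericVector phi_prop_w, int k,
                double pi, double alpha_mean, double alpha_sd,
                double log_beta_mean, double log_beta_sd,
                NumericVector trans_log_mean, NumericVector trans_log_sd,
                bool lit, double log_unif_phi, NumericVector lit_score,
                double log_lit_Z,
                bool fixed_trans, NumericVector trans_init,
                NumericVector alpha_grid, NumericVector beta_grid,
                int n_iter, int n_burnin, int thin, int fix_gamma,
                NumericVector scales, int phi_moves, bool adapt,
                List pseudo, List init) {

  RNGScope rngscope;

  if (k < 1 || k > 3)
    stop("the sampler supports characteristic phenotypes of size k in 1..3");

  Problem pb;
  pb.N = y.size(); pb.U = P.nrow(); pb.D = P.ncol(); pb.k = k;
  pb.y.assign(y.begin(), y.end());
  pb.h.assign(h.begin(), h.end());
  pb.h_zero = true;
  for (int i = 0; i < pb.N; ++i) if (pb.h[i] != 0) { pb.h_zero = false; break; }
  pb.P = P.begin();
  pb.xflat.assign(x_flat.begin(), x_flat.end());
  pb.xptr.assign(x_ptr.begin(), x_ptr.end());
  pb.sum_y = 0;
  for (int i = 0; i < pb.N; ++i) pb.sum_y += pb.y[i];
  pb.anc.resize(pb.U); pb.nb.resize(pb.U);
  for (int t = 0; t < pb.U; ++t) {
    IntegerVector a = anc[t];
    pb.anc[t].assign(a.begin(), a.end());
    std::sort(pb.anc[t].begin(), pb.anc[t].end());
    IntegerVector b = nb[t];
    pb.nb[t].assign(b.begin(), b.end());
    std::sort(pb.nb[t].begin(), pb.nb[t].end());
  }
  pb.term_w.assign(term_w.begin(), term_w.end());
  pb.term_w_cum.resize(pb.U);
  double acc = 0;
  for (int t = 0; t < pb.U; ++t) { acc += pb.term_w[t]; pb.term_w_cum[t] = acc; }
  pb.pw_unif = phi_prop_w[0]; pb.pw_nb = phi_prop_w[1]; pb.pw_freq = phi_prop_w[2];
  pb.pi = pi; pb.a_mean = alpha_mean; pb.a_sd = alpha_sd;
  pb.lb_mean = log_beta_mean; pb.lb_sd = log_beta_sd;
  for (int j = 0; j < 4; ++j) {
    pb.t_lmean[j] = trans_log_mean[j]; pb.t_lsd[j] = trans_log_sd[j];
  }
  pb.lit = lit; pb.log_unif_phi = log_unif_phi;
  pb.lit_score.assign(lit_score.begin(), lit_score.end());
  pb.log_lit_Z = log_lit_Z;
  pb.fixed_trans = fixed_trans;
  pb.alpha_grid.assign(alpha_grid.begin(), alpha_grid.end());
  pb.beta_grid.assign(beta_grid.begin(), beta_grid.end());
  const bool grid = pb.grid();

  Pseudo ps;
  ps.have = pseudo.size() > 0;
  ps.mix_w = 0;
  if (ps.have) {
    NumericVector a0 = pseudo["alpha0"]; ps.a0_m = a0[0]; ps.a0_s = a0[1];
    NumericVector a1 = pseudo["alpha1"]; ps.a1_m = a1[0]; ps.a1_s = a1[1];
    NumericVector lb = pseudo["log_beta"]; ps.lb_m = lb[0]; ps.lb_s = lb[1];
    NumericMatrix lt = pseudo["log_transform"];
    for (int j = 0; j < 4; ++j) { ps.lt_m[j] = lt(j, 0); ps.lt_s[j] = lt(j, 1); }
    ps.mix_w = as<double>(pseudo["phi_mix_w"]);
    NumericVector pp = pseudo["phi_probs"];
    IntegerMatrix pv = pseudo["phi_vecs"];
    ps.phi_probs.assign(pp.begin(), pp.end());
    ps.phi_cum.resize(pp.size());
    double c = 0;
    for (int m = 0; m < pp.size(); ++m) { c += pp[m]; ps.phi_cum[m] = c; }
    ps.phi_vecs.resize((size_t)pv.nrow() * pv.ncol());
    for (int m = 0; m < pv.ncol(); ++m) {
      std::vector<int> v(k);
      for (int j = 0; j < k; ++j) {
        v[j] = pv(j, m);
        ps.phi_vecs[(size_t)m * k + j] = pv(j, m);
      }
      ps.phi_map[phi_key(v, pb.U)] = pp[m];
    }
    if (grid) {
      NumericVector g0 = pseudo["alpha0_grid_p"], g1 = pseudo["alpha1_grid_p"],
        gb = pseudo["beta_grid_p"];
      ps.a0_p.assign(g0.begin(), g0.end());
      ps.a1_p.assign(g1.begin(), g1.end());
      ps.b_p.assign(gb.begin(), gb.end());
      ps.a0_cum.resize(g0.size()); ps.a1_cum.resize(g1.size());
      ps.b_cum.resize(gb.size());
      double c0 = 0, c1 = 0, cb = 0;
      for (int m = 0; m < g0.size(); ++m) { c0 += g0[m]; ps.a0_cum[m] = c0; }
      for (int m = 0; m < g1.size(); ++m) { c1 += g1[m]; ps.a1_cum[m] = c1; }
      for (int m = 0; m < gb.size(); ++m) { cb += gb[m]; ps.b_cum[m] = cb; }
    }
  }
  if (fix_gamma < 0 && !ps.have)
    stop("pseudopriors are required when gamma is sampled");

  // ---- state -------------------------------------------------------------
  SimCache simcache;
  State st;
  st.phiv.resize(k);
  st.sphi.resize(pb.N); st.sx.resize(pb.N); st.S.resize(pb.N);
  st.nz.reserve(pb.N);
  IntegerVector phi0 = init["phi"];
  for (int j = 0; j < k; ++j) st.phiv[j] = phi0[j];
  st.alpha0 = as<double>(init["alpha0"]);
  st.alpha1 = as<double>(init["alpha1"]);
  st.logbeta = as<double>(init["log_beta"]);
  NumericVector lt0 = init["log_transform"];
  for (int j = 0; j < 4; ++j) st.ltr[j] = lt0[j];
  if (grid) {
    st.ia0 = as<int>(init["ia0"]); st.ia1 = as<int>(init["ia1"]);
    st.ib = as<int>(init["ib"]);
    st.alpha0 = pb.alpha_grid[st.ia0];
    st.alpha1 = pb.alpha_grid[st.ia1];
    st.logbeta = std::log(pb.beta_grid[st.ib]);
  }
  st.gamma = fix_gamma >= 0 ? fix_gamma : 0;

  double tr[4];
  for (int j = 0; j < 4; ++j)
    tr[j] = fixed_trans ? trans_init[j] : std::exp(st.ltr[j]);
  st.red = reduce_phi(st.phiv, pb);
  compute_sim_cached(simcache, st.red, tr, pb, st.sphi, st.sx, st.S, st.nz);
  st.ll0 = loglik0(st.alpha0, pb);
  st.ll1 = loglik1(st.alpha1, std::exp(st.logbeta), st.S, st.nz, pb);
  st.lp_phi = log_prior_phi_tilde(st.red, pb);

  double s_a0 = scales[0], s_a1 = scales[0], s_lb = scales[1], s_lt = scales[2];

  // chain storage
  int n_keep = (n_iter - n_burnin + thin - 1) / thin;
  IntegerVector out_gamma(n_keep);
  NumericVector out_a0(n_keep), out_a1(n_keep), out_beta(n_keep);
  NumericMatrix out_trans(n_keep, 4);
  IntegerMatrix out_phi(k, n_keep), out_red(k, n_keep);
  long acc_a0 = 0, try_a0 = 0, acc_a1 = 0, try_a1 = 0;
  long acc_lb = 0, try_lb = 0, acc_lt = 0, try_lt = 0;
  long acc_ph = 0, try_ph = 0;
  long w_acc[5] = {0, 0, 0, 0, 0}, w_try[5] = {0, 0, 0, 0, 0};

  std::vector<double> sphi_p(pb.N), sx_p(pb.N), S_p(pb.N);
  std::vector<int> phiv_p(k), nz_p;
  nz_p.reserve(pb.N);

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
    double beta = std::exp(st.logbeta);

    if (st.gamma == 1) {
      // ---- alpha1
      ++try_a1; ++w_try[1];
      if (grid) {
        int ip = (int)(R::unif_rand() * pb.alpha_grid.size()) %
          (int)pb.alpha_grid.size();
        double ap = pb.alpha_grid[ip];
        double llp = loglik1(ap, beta, st.S, st.nz, pb);
        if (std::log(R::unif_rand()) < llp - st.ll1) {
          st.ia1 = ip; st.alpha1 = ap; st.ll1 = llp; ++acc_a1; ++w_acc[1];
        }
      } else {
        double ap = st.alpha1 + R::norm_rand() * s_a1;
        double llp = loglik1(ap, beta, st.S, st.nz, pb);
        double lr = llp - st.ll1 +
          dnorm_log(ap, pb.a_mean, pb.a_sd) -
          dnorm_log(st.alpha1, pb.a_mean, pb.a_sd);
        if (std::log(R::unif_rand()) < lr) {
          st.alpha1 = ap; st.ll1 = llp; ++acc_a1; ++w_acc[1];
        }
      }
      // ---- beta
      ++try_lb; ++w_try[2];
      if (grid) {
        int ip = (int)(R::unif_rand() * pb.beta_grid.size()) %
          (int)pb.beta_grid.size();
        double bp = pb.beta_grid[ip];
        double llp = loglik1(st.alpha1, bp, st.S, st.nz, pb);
        if (std::log(R::unif_rand()) < llp - st.ll1) {
          st.ib = ip; st.logbeta = std::log(bp); st.ll1 = llp;
          ++acc_lb; ++w_acc[2];
        }
      } else {
        double lbp = st.logbeta + R::norm_rand() * s_lb;
        double llp = loglik1(st.alpha1, std::exp(lbp), st.S, st.nz, pb);
        double lr = llp - st.ll1 +
          dnorm_log(lbp, pb.lb_mean, pb.lb_sd) -
          dnorm_log(st.logbeta, pb.lb_mean, pb.lb_sd);
        if (std::log(R::unif_rand()) < lr) {
          st.logbeta = lbp; st.ll1 = llp; ++acc_lb; ++w_acc[2];
        }
      }
      beta = std::exp(st.logbeta);
      // ---- transforms (joint random walk on log scale)
      if (!pb.fixed_trans) {
        ++try_lt; ++w_try[3];
        double ltp[4], trp[4], lr = 0;
        for (int j = 0; j < 4; ++j) {
          ltp[j] = st.ltr[j] + R::norm_rand() * s_lt;
          trp[j] = std::exp(ltp[j]);
          lr += dnorm_log(ltp[j], pb.t_lmean[j], pb.t_lsd[j]) -
            dnorm_log(st.ltr[j], pb.t_lmean[j], pb.t_lsd[j]);
        }
        apply_transform(st.sphi, st.sx, st.nz, trp, S_p);
        double llp = loglik1(st.alpha1, beta, S_p, st.nz, pb);
        lr += llp - st.ll1;
        if (std::log(R::unif_rand()) < lr) {
          for (int j = 0; j < 4; ++j) { st.ltr[j] = ltp[j]; tr[j] = trp[j]; }
          st.S.swap(S_p); st.ll1 = llp; ++acc_lt; ++w_acc[3];
        }
      }
      // ---- phi tilde coordinate moves
      for (int mv = 0; mv < phi_moves; ++mv) {
        ++try_ph; ++w_try[4];
        int j = (int)(R::unif_rand() * k) % k;
        int from = st.phiv[j];
        int to = propose_phi_coord(from, pb);
        phiv_p = st.phiv; phiv_p[j] = to;
        std::vector<int> red_p = reduce_phi(phiv_p, pb);
        compute_sim_cached(simcache, red_p, tr, pb, sphi_p, sx_p, S_p, nz_p);
        double llp = loglik1(st.alpha1, beta, S_p, nz_p, pb);
        double lpp = log_prior_phi_tilde(red_p, pb);
        double lr = llp - st.ll1 + lpp - st.lp_phi +
          std::log(phi_prop_dens(to, from, pb)) -
          std::log(phi_prop_dens(from, to, pb));
        if (std::log(R::unif_rand()) < lr) {
          st.phiv.swap(phiv_p); st.red.swap(red_p);
          st.sphi.swap(sphi_p); st.sx.swap(sx_p); st.S.swap(S_p);
          st.nz.swap(nz_p);
          st.ll1 = llp; st.lp_phi = lpp; ++acc_ph; ++w_acc[4];
        }
      }
      // ---- inactive model: alpha0 from pseudoprior
      if (fix_gamma < 0) {
        if (grid) {
          st.ia0 = draw_categorical(ps.a0_cum);
          st.alpha0 = pb.alpha_grid[st.ia0];
        } else {
          st.alpha0 = ps.a0_m + R::norm_rand() * ps.a0_s;
        }
        st.ll0 = loglik0(st.alpha0, pb);
      }
    } else {
      // ---- gamma = 0: alpha0 by MH
      ++try_a0; ++w_try[0];
      if (grid) {
        int ip = (int)(R::unif_rand() * pb.alpha_grid.size()) %
          (int)pb.alpha_grid.size();
        double ap = pb.alpha_grid[ip];
        double llp = loglik0(ap, pb);
        if (std::log(R::unif_rand()) < llp - st.ll0) {
          st.ia0 = ip; st.alpha0 = ap; st.ll0 = llp; ++acc_a0; ++w_acc[0];
        }
      } else {
        double ap = st.alpha0 + R::norm_rand() * s_a0;
        double llp = loglik0(ap, pb);
        double lr = llp - st.ll0 +
          dnorm_log(ap, pb.a_mean, pb.a_sd) -
          dnorm_log(st.alpha0, pb.a_mean, pb.a_sd);
        if (std::log(R::unif_rand()) < lr) {
          st.alpha0 = ap; st.ll0 = llp; ++acc_a0; ++w_acc[0];
        }
      }
      // ---- inactive model: draw theta1 from pseudopriors
      if (fix_gamma < 0) {
        if (grid) {
          st.ia1 = draw_categorical(ps.a1_cum);
          st.alpha1 = pb.alpha_grid[st.ia1];
          st.ib = draw_categorical(ps.b_cum);
          st.logbeta = std::log(pb.beta_grid[st.ib]);
        } else {
          st.alpha1 = ps.a1_m + R::norm_rand() * ps.a1_s;
          st.logbeta = ps.lb_m + R::norm_rand() * ps.lb_s;
          if (!pb.fixed_trans)
            for (int j = 0; j < 4; ++j) {
              st.ltr[j] = ps.lt_m[j] + R::norm_rand() * ps.lt_s[j];
              tr[j] = std::exp(st.ltr[j]);
            }
        }
        pseudo_phi_draw(st.phiv, pb, ps);
        st.red = reduce_phi(st.phiv, pb);
        compute_sim_cached(simcache, st.red, tr, pb, st.sphi, st.sx, st.S,
                           st.nz);
        st.ll1 = loglik1(st.alpha1, std::exp(st.logbeta), st.S, st.nz, pb);
        st.lp_phi = log_prior_phi_tilde(st.red, pb);
      }
    }

    if (std::fabs(st.alpha0) > 50 || std::fabs(st.alpha1) > 50)
      stop("sampler diverged: |alpha| exceeded 50 at iteration %d", it + 1);

    // ---- gamma full conditional
    if (fix_gamma < 0) {
      double pr_a1, pr_lb, pr_a0, psd_a0, psd_a1, psd_lb;
      double pr_lt = 0, psd_lt = 0;
      if (grid) {
        pr_a1 = -std::log((double)pb.alpha_grid.size());
        pr_a0 = pr_a1;
        pr_lb = -std::log((double)pb.beta_grid.size());
        psd_a0 = std::log(ps.a0_p[st.ia0]);
        psd_a1 = std::log(ps.a1_p[st.ia1]);
        psd_lb = std::log(ps.b_p[st.ib]);
      } else {
        pr_a1 = dnorm_log(st.alpha1, pb.a_mean, pb.a_sd);
        pr_a0 = dnorm_log(st.alpha0, pb.a_mean, pb.a_sd);
        pr_lb = dnorm_log(st.logbeta, pb.lb_mean, pb.lb_sd);
        psd_a0 = dnorm_log(st.alpha0, ps.a0_m, ps.a0_s);
        psd_a1 = dnorm_log(st.alpha1, ps.a1_m, ps.a1_s);
        psd_lb = dnorm_log(st.logbeta, ps.lb_m, ps.lb_s);
        if (!pb.fixed_trans)
          for (int j = 0; j < 4; ++j) {
            pr_lt += dnorm_log(st.ltr[j], pb.t_lmean[j], pb.t_lsd[j]);
            psd_lt += dnorm_log(st.ltr[j], ps.lt_m[j], ps.lt_s[j]);
          }
      }
      double log_a1 = st.ll1 + pr_a1 + pr_lb + pr_lt + st.lp_phi + psd_a0;
      double log_a0 = st.ll0 + pr_a0 + psd_a1 + psd_lb + psd_lt +
        pseudo_phi_logdens(st.phiv, pb, ps);
      double d = log_a1 - log_a0;
      double p1 = 1.0 / (1.0 + std::exp(std::log((1 - pb.pi) / pb.pi) - d));
      st.gamma = (R::unif_rand() < p1) ? 1 : 0;
    }

    // ---- adaptation during burn-in
    if (adapt && it < n_burnin && ((it + 1) % 50 == 0)) {
      double* sc[5] = {&s_a0, &s_a1, &s_lb, &s_lt, 0};
      for (int m = 0; m < 4; ++m) {
        if (w_try[m] >= 10) {
          double r = (double)w_acc[m] / w_try[m];
          if (r > 0.44) *sc[m] *= 1.3;
          else if (r < 0.23) *sc[m] /= 1.3;
        }
        w_acc[m] = w_try[m] = 0;
      }
      w_acc[4] = w_try[4] = 0;
    }

    // ---- record
    if (it >= n_burnin && (it - n_burnin) % thin == 0) {
      out_gamma[kept] = st.gamma;
      out_a0[kept] = st.alpha0;
      out_a1[kept] = st.alpha1;
      out_beta[kept] = std::exp(st.logbeta);
      for (int j = 0; j < 4; ++j)
        out_trans(kept, j) = pb.fixed_trans ? trans_init[j] : std::exp(st.ltr[j]);
      for (int j = 0; j < k; ++j) {
        out_phi(j, kept) = st.phiv[j];
        out_red(j, kept) = j < (int)st.red.size() ? st.red[j] : NA_INTEGER;
      }
      ++kept;
    }
  }

  return List::create(
    _["gamma"] = out_gamma, _["alpha0"] = out_a0, _["alpha1"] = out_a1,
    _["beta"] = out_beta, _["transform"] = out_trans,
    _["phi_tilde"] = out_phi, _["phi"] = out_red,
    _["acceptance"] = NumericVector::create(
      _["alpha0"] = try_a0 ? (double)acc_a0 / try_a0 : NA_REAL,
      _["alpha1"] = try_a1 ? (double)acc_a1 / try_a1 : NA_REAL,
      _["log_beta"] = try_lb ? (double)acc_lb / try_lb : NA_REAL,
      _["log_transform"] = try_lt ? (double)acc_lt / try_lt : NA_REAL,
      _["phi"] = try_ph ? (double)acc_ph / try_ph : NA_REAL),
    _["scales"] = NumericVector::create(s_a0, s_a1, s_lb, s_lt));
}

// Per-subject similarity profile for a fixed phi and transform, exposed so
// the R side (predict, scoring) shares one implementation with the sampler.
// [[Rcpp::export(name = ".sim_profile")]]
List sim_profile(NumericMatrix P, IntegerVector x_flat, IntegerVector x_ptr,
                 IntegerVector phi_red, NumericVector trans) {
  Problem pb;
  pb.N = x_ptr.size() - 1; pb.U = P.nrow(); pb.D = P.ncol();
  pb.P = P.begin();
  pb.xflat.assign(x_flat.begin(), x_flat.end());
  pb.xptr.assign(x_ptr.begin(), x_ptr.end());
  std::vector<int> red(phi_red.begin(), phi_red.end());
  double tr[4] = {trans[0], trans[1], trans[2], trans[3]};
  std::vector<double> sphi(pb.N), sx(pb.N), S(pb.N);
  std::vector<int> nz;
  pb.sum_y = 0; pb.h_zero = true;
  compute_sim(red, tr, pb, sphi, sx, S, nz);
  return List::create(_["s_phi"] = wrap(sphi), _["s_x"] = wrap(sx),
                      _["s"] = wrap(S));
}
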