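// Phylogenetic likelihood core for branch-site codon mixture models.
//
// The branch-site omega random effect is iid across branches, so the model
// factorizes into per-branch mixture transition matrices
//   M_b = sum_k p_k exp(alpha * Q(omega_k) * s * t_b),
// with s the generator scaling that expresses branch lengths in expected
// substitutions per nucleotide site.  Site-level synonymous rate categories
// (alpha) multiply the generator by a scalar, so one symmetric
// eigendecomposition per omega category serves every (branch, alpha) cell.
//
// Because the optimizer evaluates the likelihood along finite-difference
// perturbations that mostly leave the generators untouched (weight sticks,
// alpha values, branch scale), the eigensystems and the reconstructed
// exp(Qt) matrices are cached between calls and invalidated by content keys.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static vec pair_rate_values(const ivec& nd, const ivec& nonsyn,
                            const imat& theta_idx, const vec& pi_prod,
                            const vec& theta, double omega, double delta,
                            double psi, bool strict_nonsyn_psi) {
  const uword m = nd.n_elem;
  vec r(m);
  for (uword p = 0; p < m; ++p) {
    double v;
    switch (nd[p]) {
      case 1: v = 1.0; break;
      case 2: v = delta; break;
      default:
        v = (strict_nonsyn_psi && !nonsyn[p]) ? 0.0 : psi;
    }
    if (nonsyn[p]) v *= omega;
    for (int q = 0; q < 3; ++q) {
      int ti = theta_idx(p, q);
      if (ti > 0) v *= theta[ti - 1];
    }
    r[p] = v * pi_prod[p];
  }
  return r;
}

struct EigenSystem {
  mat U;           // D^{-1/2} V
  mat W;           // V' D^{1/2}
  vec lam;         // eigenvalues of the reversible generator
  vec key;         // content key: theta, omega, delta, psi, strict, pi sig
  double flux = 0; // sum_{i != j} q_ij pi_j for this omega category
  long version = -1;
};

struct ReconCache {
  mat T;           // exp(alpha * Q_k * s * t)
  long version = -1;
  double s = -1, alpha = -1, t = -1;
};

// cache shared across calls (single-threaded use)
static std::vector<EigenSystem> g_eigen;
static std::vector<ReconCache> g_recon;  // [k * (L*E) + l * E + e]
static uword g_K = 0, g_L = 0, g_E = 0, g_n = 0;
static long g_version_counter = 0;
static double g_data_sig = 0;

static EigenSystem make_eigen(const mat& Q, const vec& pi_codon) {
  vec sq = sqrt(pi_codon);
  mat B = Q;
  B.each_col() %= sq;
  B.each_row() /= sq.t();
  B = 0.5 * (B + B.t());
  EigenSystem es;
  mat V;
  if (!eig_sym(es.lam, V, B)) Rcpp::stop("eigendecomposition failed");
  es.U = V;
  es.U.each_col() /= sq;
  es.W = V.t();
  es.W.each_row() %= sq.t();
  return es;
}

// [[Rcpp::export]]
void cpp_clear_cache() {
  g_eigen.clear();
  g_recon.clear();
  g_K = g_L = g_E = g_n = 0;
  g_data_sig = 0;
}

// [[Rcpp::export]]
Rcpp::List cpp_site_loglik(
    const arma::ivec& pair_i, const arma::ivec& pair_j,
    const arma::ivec& pair_nd, const arma::ivec& pair_nonsyn,
    const arma::imat& pair_theta_idx, const arma::vec& pair_pi_prod,
    const arma::vec& theta, const arma::vec& omegas,
    const arma::vec& p_omega, const arma::mat& branch_p,
    double delta, double psi, bool strict_nonsyn_psi,
    const arma::vec& alphas, const arma::vec& pi_codon,
    const arma::imat& edge, const arma::vec& t_branch,
    int root, int n_tips, int n_nodes,
    const arma::imat& leaf_states, const arma::imat& leaf_amb,
    const arma::mat& amb_partials, double s_fixed) {
  const uword n = pi_codon.n_elem;
  const uword K = omegas.n_elem;
  const uword L = alphas.n_elem;
  const uword E = edge.n_rows;
  const uword P = leaf_states.n_rows;

  // reset caches when dimensions or the dataset signature change
  const double data_sig = accu(pair_pi_prod) + pair_pi_prod[0] +
    accu(pi_codon % regspace(1.0, (double)n)) + (double)P;
  if (K != g_K || L != g_L || E != g_E || n != g_n ||
      data_sig != g_data_sig) {
    g_eigen.assign(K, EigenSystem());
    g_recon.assign(K * L * E, ReconCache());
    g_K = K; g_L = L; g_E = E; g_n = n;
    g_data_sig = data_sig;
  }

  // per-omega-category eigensystems (content-keyed cache)
  for (uword k = 0; k < K; ++k) {
    vec key(11);
    for (int i = 0; i < 6; ++i) key[i] = theta[i];
    key[6] = omegas[k];
    key[7] = delta;
    key[8] = psi;
    key[9] = strict_nonsyn_psi ? 1.0 : 0.0;
    key[10] = data_sig;
    EigenSystem& es = g_eigen[k];
    if (es.version >= 0 && es.key.n_elem == 11 &&
        approx_equal(es.key, key, "absdiff", 0.0)) {
      continue;
    }
    vec r = pair_rate_values(pair_nd, pair_nonsyn, pair_theta_idx,
                             pair_pi_prod, theta, omegas[k], delta, psi,
                             strict_nonsyn_psi);
    mat Q(n, n, fill::zeros);
    double flux = 0;
    for (uword p = 0; p < r.n_elem; ++p) {
      Q(pair_i[p] - 1, pair_j[p] - 1) = r[p];
      flux += r[p] * pi_codon[pair_j[p] - 1];
    }
    Q.diag() = -sum(Q, 1);
    EigenSystem fresh = make_eigen(Q, pi_codon);
    fresh.flux = flux;
    fresh.key = key;
    fresh.version = ++g_version_counter;
    es = std::move(fresh);
  }

  double C = 0.0;
  for (uword k = 0; k < K; ++k) C += p_omega[k] * g_eigen[k].flux;
  if (C <= 0) Rcpp::stop("degenerate rate matrix: zero total flux");
  const double s = s_fixed > 0 ? s_fixed : 3.0 / C;

  // per (k, l, e) transition matrices exp(alpha_l * Q_k * s * t_e)
  for (uword k = 0; k < K; ++k) {
    const EigenSystem& es = g_eigen[k];
    for (uword l = 0; l < L; ++l) {
      for (uword e = 0; e < E; ++e) {
        ReconCache& rc = g_recon[k * (L * E) + l * E + e];
        if (rc.version == es.version && rc.s == s &&
            rc.alpha == alphas[l] && rc.t == t_branch[e]) {
          continue;
        }
        vec ex = exp(es.lam * (s * alphas[l] * t_branch[e]));
        rc.T = es.U * (diagmat(ex) * es.W);
        rc.T.clamp(0.0, datum::inf);
        rc.version = es.version;
        rc.s = s; rc.alpha = alphas[l]; rc.t = t_branch[e];
      }
    }
  }

  mat out(P, L);
  mat Mb(n, n);
  std::vector<mat> partials(n_nodes);
  std::vector<bool> touched(n_nodes);

  for (uword l = 0; l < L; ++l) {
    rowvec logscale(P, fill::zeros);
    std::fill(touched.begin(), touched.end(), false);
    for (uword e = 0; e < E; ++e) {
      const int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      Mb.zeros();
      for (uword k = 0; k < K; ++k) {
        if (branch_p(e, k) <= 0) continue;
        Mb += branch_p(e, k) * g_recon[k * (L * E) + l * E + e].T;
      }
      if (!touched[par]) {
        partials[par].ones(n, P);
        touched[par] = true;
      }
      mat& pp = partials[par];
      if (ch < n_tips) {
        for (uword p = 0; p < P; ++p) {
          const int st = leaf_states(p, ch);
          if (st >= 0) {
            pp.col(p) %= Mb.col(st);
          } else {
            const int a = leaf_amb(p, ch);
            if (a >= 0) pp.col(p) %= Mb * amb_partials.col(a);
            // fully missing leaf: conditional of ones, no-op
          }
        }
      } else {
        mat& cp = partials[ch];
        pp %= Mb * cp;
      }
      // keep partials in range for deep trees
      if ((e + 1) % 12 == 0) {
        rowvec mx = max(pp, 0);
        for (uword p = 0; p < P; ++p) {
          if (mx[p] > 0 && mx[p] < 1e-100) {
            pp.col(p) /= mx[p];
            logscale[p] += std::log(mx[p]);
          }
        }
      }
    }
    const mat& rp = partials[root - 1];
    for (uword p = 0; p < P; ++p) {
      const double lik = dot(pi_codon, rp.col(p));
      out(p, l) = lik > 0 ? std::log(lik) + logscale[p] : -datum::inf;
    }
  }
  return Rcpp::List::create(Rcpp::Named("log_site_lik") = out,
                            Rcpp::Named("flux") = C,
                            Rcpp::Named("scale") = s);
}
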