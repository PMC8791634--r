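// Likelihood engine for binary-trait CTMC models on a fixed rooted tree:
// Felsenstein pruning with per-node scaling, plus a Metropolis-Hastings
// sampler over rate parameters (optionally at a power-posterior temperature
// beta, for stepping-stone marginal likelihoods) with joint sampling of
// internal-node states for ancestral reconstruction.
//
// Trees arrive as ape-style edge matrices in postorder (children before
// parents).  Transition probabilities P(t) = exp(Qt) are applied per edge
// from a decomposition of Q prepared once per likelihood evaluation:
//  - 2 states: the closed-form two-state solution;
//  - otherwise: eigendecomposition (real fast path when the spectrum is
//    real, complex otherwise), verified by reconstruction and falling back
//    to scaling-and-squaring (arma::expmat) when ill-conditioned.
// The sampler performs ~1e6 likelihood evaluations per marginal-likelihood
// estimate, so the per-edge kernels use fixed stack buffers and no heap
// allocation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

const double NEG_INF = -std::numeric_limits<double>::infinity();
const int MAXNS = 8;

struct QExp {
  int ns = 0;
  int mode = 3;  // 0 analytic 2-state, 1 real eig, 2 complex eig, 3 expmat
  arma::mat Q;
  double r01 = 0, r10 = 0;                       // 2-state rates
  double Vr[MAXNS * MAXNS], Vir[MAXNS * MAXNS];  // real eig (column-major)
  double lamr[MAXNS];
  std::complex<double> Vc[MAXNS * MAXNS], Vic[MAXNS * MAXNS], lamc[MAXNS];

  void prepare(const arma::mat& Qin) {
    Q = Qin;
    ns = Q.n_rows;
    if (ns == 2) {
      r01 = Q(0, 1);
      r10 = Q(1, 0);
      mode = 0;
      return;
    }
    mode = 3;
    arma::cx_vec eval;
    arma::cx_mat evec;
    if (!arma::eig_gen(eval, evec, Q)) return;
    arma::cx_mat inv_evec;
    if (!arma::inv(inv_evec, evec)) return;
    const double scale = 1.0 + arma::abs(Q).max();
    // verify V diag(lam) V^-1 reconstructs Q (guards ill-conditioned bases)
    arma::cx_mat R = evec * arma::diagmat(eval) * inv_evec;
    if (arma::abs(R - arma::cx_mat(Q, arma::zeros(ns, ns))).max() >
        1e-9 * scale)
      return;
    const bool realspec =
        arma::abs(arma::imag(eval)).max() < 1e-12 * scale &&
        arma::abs(arma::imag(evec)).max() < 1e-12;
    if (realspec) {
      for (int j = 0; j < ns; ++j) {
        lamr[j] = eval(j).real();
        for (int i = 0; i < ns; ++i) {
          Vr[i + j * ns] = evec(i, j).real();
          Vir[i + j * ns] = inv_evec(i, j).real();
        }
      }
      mode = 1;
    } else {
      for (int j = 0; j < ns; ++j) {
        lamc[j] = eval(j);
        for (int i = 0; i < ns; ++i) {
          Vc[i + j * ns] = evec(i, j);
          Vic[i + j * ns] = inv_evec(i, j);
        }
      }
      mode = 2;
    }
  }

  // y = P(t) * v, entries clamped into [0, inf); y must not alias v
  void Pv(double t, const double* v, double* y) const {
    if (mode == 0) {
      const double s = r01 + r10;
      double e = (s > 0) ? std::exp(-s * t) : 1.0;
      double p01 = (s > 0) ? r01 * (1 - e) / s : 0.0;
      double p10 = (s > 0) ? r10 * (1 - e) / s : 0.0;
      y[0] = (1 - p01) * v[0] + p01 * v[1];
      y[1] = p10 * v[0] + (1 - p10) * v[1];
      return;
    }
    if (mode == 1) {
      double w[MAXNS];
      for (int k = 0; k < ns; ++k) {
        double acc = 0;
        for (int j = 0; j < ns; ++j) acc += Vir[k + j * ns] * v[j];
        w[k] = acc * std::exp(lamr[k] * t);
      }
      for (int i = 0; i < ns; ++i) {
        double acc = 0;
        for (int k = 0; k < ns; ++k) acc += Vr[i + k * ns] * w[k];
        y[i] = acc > 0 ? acc : 0;
      }
      return;
    }
    if (mode == 2) {
      std::complex<double> w[MAXNS];
      for (int k = 0; k < ns; ++k) {
        std::complex<double> acc = 0;
        for (int j = 0; j < ns; ++j) acc += Vic[k + j * ns] * v[j];
        w[k] = acc * std::exp(lamc[k] * t);
      }
      for (int i = 0; i < ns; ++i) {
        std::complex<double> acc = 0;
        for (int k = 0; k < ns; ++k) acc += Vc[i + k * ns] * w[k];
        y[i] = acc.real() > 0 ? acc.real() : 0;
      }
      return;
    }
    arma::mat P = arma::expmat(Q * t);
    for (int i = 0; i < ns; ++i) {
      double acc = 0;
      for (int j = 0; j < ns; ++j) acc += P(i, j) * v[j];
      y[i] = acc > 0 ? acc : 0;
    }
  }

  // y = row s of P(t), clamped into [0, inf)
  void Prow(double t, int s, double* y) const {
    double e[MAXNS];
    for (int i = 0; i < ns; ++i) e[i] = 0;
    e[s] = 1;
    // P(t)^T e_s would need the transpose; compute directly instead
    if (mode == 0) {
      const double sm = r01 + r10;
      double ex = (sm > 0) ? std::exp(-sm * t) : 1.0;
      double p01 = (sm > 0) ? r01 * (1 - ex) / sm : 0.0;
      double p10 = (sm > 0) ? r10 * (1 - ex) / sm : 0.0;
      if (s == 0) { y[0] = 1 - p01; y[1] = p01; }
      else       { y[0] = p10;     y[1] = 1 - p10; }
      return;
    }
    if (mode == 1) {
      for (int j = 0; j < ns; ++j) {
        double acc = 0;
        for (int k = 0; k < ns; ++k)
          acc += Vr[s + k * ns] * std::exp(lamr[k] * t) * Vir[k + j * ns];
        y[j] = acc > 0 ? acc : 0;
      }
      return;
    }
    if (mode == 2) {
      for (int j = 0; j < ns; ++j) {
        std::complex<double> acc = 0;
        for (int k = 0; k < ns; ++k)
          acc += Vc[s + k * ns] * std::exp(lamc[k] * t) * Vic[k + j * ns];
        y[j] = acc.real() > 0 ? acc.real() : 0;
      }
      return;
    }
    arma::mat P = arma::expmat(Q * t);
    for (int j = 0; j < ns; ++j) y[j] = P(s, j) > 0 ? P(s, j) : 0;
  }
};

// partials: n_states x n_nodes; tip columns are observation indicators,
// internal columns are constraint masks (all-ones when unconstrained).
double prune_core(const QExp& qe, const arma::imat& edge, const arma::vec& elen,
                  const arma::mat& partials, const arma::vec& root_prior,
                  int root, arma::mat* Lout) {
  arma::mat Ltmp;
  arma::mat& L = Lout ? *Lout : Ltmp;
  L = partials;
  const int ns = qe.ns;
  double logscale = 0.0;
  const arma::uword ne = edge.n_rows;
  double y[MAXNS];
  for (arma::uword i = 0; i < ne; ++i) {
    const arma::uword par = edge(i, 0) - 1;
    const arma::uword chi = edge(i, 1) - 1;
    qe.Pv(elen(i), L.colptr(chi), y);
    double* Lp = L.colptr(par);
    double m = 0;
    for (int s = 0; s < ns; ++s) {
      Lp[s] *= y[s];
      if (Lp[s] > m) m = Lp[s];
    }
    if (m <= 0.0) return NEG_INF;
    if (m < 1e-100) {
      for (int s = 0; s < ns; ++s) Lp[s] /= m;
      logscale += std::log(m);
    }
  }
  double lik = 0;
  const double* Lr = L.colptr(root - 1);
  for (int s = 0; s < ns; ++s) lik += root_prior(s) * Lr[s];
  if (lik <= 0.0) return NEG_INF;
  return std::log(lik) + logscale;
}

arma::mat build_Q(const arma::imat& index, const arma::vec& p) {
  const arma::uword ns = index.n_rows;
  arma::mat Q(ns, ns, arma::fill::zeros);
  for (arma::uword i = 0; i < ns; ++i)
    for (arma::uword j = 0; j < ns; ++j)
      if (i != j && index(i, j) > 0) Q(i, j) = p(index(i, j) - 1);
  Q.diag() = -arma::sum(Q, 1);
  return Q;
}

// prior types: 0 = uniform(a, b); 1 = exponential(mean a)
double log_prior(const arma::vec& p, const arma::ivec& type,
                 const arma::vec& a, const arma::vec& b) {
  double lp = 0.0;
  for (arma::uword k = 0; k < p.n_elem; ++k) {
    if (type(k) == 0) {
      if (p(k) < a(k) || p(k) > b(k)) return NEG_INF;
      lp -= std::log(b(k) - a(k));
    } else {
      if (p(k) < 0.0) return NEG_INF;
      lp += -std::log(a(k)) - p(k) / a(k);
    }
  }
  return lp;
}

int sample_index(const double* w, int n) {
  double tot = 0;
  for (int i = 0; i < n; ++i) tot += w[i];
  double u = unif_rand() * tot;
  for (int i = 0; i < n; ++i) {
    u -= w[i];
    if (u <= 0.0) return i;
  }
  return n - 1;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_prune_loglik")]]
double cpp_prune_loglik(const arma::imat& edge, const arma::vec& edge_len,
                        const arma::mat& partials, const arma::mat& Q,
                        const arma::vec& root_prior, int root) {
  if (Q.n_rows > MAXNS) stop("state spaces beyond 8 states are not supported");
  QExp qe;
  qe.prepare(Q);
  return prune_core(qe, edge, edge_len, partials, root_prior, root, nullptr);
}

// Metropolis-Hastings over rate parameters with multiplicative lognormal
// proposals (one parameter updated per iteration), targeting
// prior(theta) * likelihood(theta)^beta.  During burn-in, per-parameter step
// sizes may be auto-tuned toward 20-40% acceptance.  When sample_states is
// true, a joint draw of internal-node states is recorded with every retained
// sample (root drawn from its conditional, then children given parents in
// preorder).
// [[Rcpp::export(name = ".cpp_mcmc")]]
List cpp_mcmc(const arma::imat& edge, const arma::vec& edge_len,
              const arma::mat& partials, const arma::imat& index,
              const arma::vec& params0, const arma::ivec& prior_type,
              const arma::vec& prior_a, const arma::vec& prior_b,
              const arma::vec& root_prior, int root, double beta, int n_iter,
              int burnin, int thin, const arma::vec& step0, bool tune,
              bool sample_states, int n_tip) {
  if (partials.n_rows > static_cast<arma::uword>(MAXNS))
    stop("state spaces beyond 8 states are not supported");
  const arma::uword np = params0.n_elem;
  const int ns = partials.n_rows;
  const arma::uword n_node = partials.n_cols;
  const arma::uword n_internal = n_node - n_tip;
  const arma::uword ne = edge.n_rows;

  arma::vec p = params0;
  arma::vec step = step0;
  QExp qe, qe_new;
  arma::mat L, L_new;
  qe.prepare(build_Q(index, p));
  double ll = prune_core(qe, edge, edge_len, partials, root_prior, root, &L);
  double lp = log_prior(p, prior_type, prior_a, prior_b);
  if (!std::isfinite(lp))
    stop("initial parameter values have zero prior density");
  if (!std::isfinite(ll) && beta > 0.0)
    stop("initial parameter values have zero likelihood");

  const int n_keep = (n_iter > burnin) ? (n_iter - burnin) / thin : 0;
  arma::mat out_par(n_keep, np);
  arma::vec out_ll(n_keep);
  arma::imat out_states;
  if (sample_states) out_states.set_size(n_keep, n_internal);

  arma::vec acc_win(np, arma::fill::zeros), try_win(np, arma::fill::zeros);
  long n_acc = 0, n_try = 0;
  int kept = 0;

  // proposal mixture: mostly multiplicative lognormal random walks, plus
  // independence draws from the parameter's prior (keep the chain mobile
  // when the tempered posterior is prior-like) and log-uniform independence
  // draws across all rate scales (let the chain hop between the low-rate
  // and saturated-rate modes that tempered posteriors often separate into)
  const double lu_lo = 1e-8, lu_hi = 100.0;
  const double lu_span = std::log(lu_hi / lu_lo);
  for (int it = 1; it <= n_iter; ++it) {
    arma::uword k = static_cast<arma::uword>(unif_rand() * np);
    if (k >= np) k = np - 1;
    arma::vec pnew = p;
    double lhast;
    const double u = unif_rand();
    if (u < 0.10) {
      // global scale move: multiply every rate by a common lognormal factor
      // (travels along the overall-rate direction linking tempered-posterior
      // modes that share rate ratios)
      const double lc = norm_rand() * 1.5;
      pnew = p * std::exp(lc);
      lhast = np * lc;
    } else if (u < 0.25) {
      if (prior_type(k) == 0)
        pnew(k) = prior_a(k) + unif_rand() * (prior_b(k) - prior_a(k));
      else
        pnew(k) = -prior_a(k) * std::log(unif_rand());
      // Hastings ratio q(old)/q(new) for the prior-density proposal
      lhast = (prior_type(k) == 0)
                  ? 0.0
                  : (pnew(k) - p(k)) / prior_a(k);
    } else if (u < 0.40) {
      pnew(k) = lu_lo * std::exp(unif_rand() * lu_span);
      lhast = (p(k) >= lu_lo && p(k) <= lu_hi)
                  ? std::log(pnew(k) / p(k))
                  : NEG_INF;  // reverse move impossible: reject
    } else {
      pnew(k) = p(k) * std::exp(norm_rand() * step(k));
      lhast = std::log(pnew(k) / p(k));
    }
    const double lpnew = log_prior(pnew, prior_type, prior_a, prior_b);
    double lratio = NEG_INF;
    double llnew = NEG_INF;
    if (std::isfinite(lpnew)) {
      qe_new.prepare(build_Q(index, pnew));
      llnew = prune_core(qe_new, edge, edge_len, partials, root_prior, root,
                         &L_new);
      const double tnew = lpnew + (beta > 0.0 ? beta * llnew : 0.0);
      const double told = lp + (beta > 0.0 ? beta * ll : 0.0);
      if (std::isfinite(tnew))
        lratio = tnew - told + lhast;
    }
    ++n_try;
    try_win(k) += 1.0;
    if (std::isfinite(lratio) && std::log(unif_rand()) < lratio) {
      p = pnew;
      ll = llnew;
      lp = lpnew;
      std::swap(qe, qe_new);
      std::swap(L, L_new);
      ++n_acc;
      acc_win(k) += 1.0;
    }

    if (tune && it <= burnin && it % (50 * static_cast<int>(np)) == 0) {
      for (arma::uword j = 0; j < np; ++j) {
        if (try_win(j) >= 10) {
          const double r = acc_win(j) / try_win(j);
          if (r > 0.4)
            step(j) *= 1.25;
          else if (r < 0.2)
            step(j) /= 1.25;
          step(j) = std::min(std::max(step(j), 1e-3), 25.0);
        }
        acc_win(j) = 0.0;
        try_win(j) = 0.0;
      }
    }

    if (it > burnin && (it - burnin) % thin == 0 && kept < n_keep) {
      out_par.row(kept) = p.t();
      out_ll(kept) = ll;
      if (sample_states) {
        // draw root state from its conditional, then walk edges in reverse
        // postorder so every parent is assigned before its children
        arma::ivec st(n_node, arma::fill::zeros);
        double w[MAXNS], pr[MAXNS];
        const double* Lr = L.colptr(root - 1);
        for (int s = 0; s < ns; ++s) w[s] = root_prior(s) * Lr[s];
        st(root - 1) = sample_index(w, ns);
        for (arma::uword i = ne; i-- > 0;) {
          const arma::uword par = edge(i, 0) - 1;
          const arma::uword chi = edge(i, 1) - 1;
          if (chi < static_cast<arma::uword>(n_tip)) continue;
          qe.Prow(edge_len(i), st(par), pr);
          const double* Lc = L.colptr(chi);
          for (int s = 0; s < ns; ++s) w[s] = pr[s] * Lc[s];
          st(chi) = sample_index(w, ns);
        }
        for (arma::uword j = 0; j < n_internal; ++j)
          out_states(kept, j) = st(n_tip + j) + 1;  // 1-based state index
      }
      ++kept;
    }
  }

  return List::create(
      _["samples"] = out_par, _["loglik"] = out_ll, _["states"] = out_states,
      _["acceptance"] = static_cast<double>(n_acc) / n_try,
      _["params_final"] = p, _["step_final"] = step);
}
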