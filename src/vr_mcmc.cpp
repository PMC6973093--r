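// Reversible-jump MCMC kernel for the variable-rates regression model.
//
// Model: y ~ N(X beta, sigma2_b * V(tree scaled by per-branch effective
// scalars)). Two kinds of rate scalars can be placed on a branch:
//   - a branch-local scalar, multiplying that branch alone (a one-off burst);
//   - a clade scalar, multiplying the branch AND every descendant branch
//     (a heritable, inherited rate shift costing a single parameter).
// The effective scalar of a branch is its local scalar times the product of
// all clade scalars anchored on its root-ward path (itself included). Each
// potential scalar site is "active" with prior probability p_active and
// carries log r ~ Normal(0, logr_sd^2) when active; inactive sites have
// r = 1 exactly. sigma2_b has a half-Cauchy prior, coefficients a wide
// normal (proper, as stepping-stone sampling requires).
//
// The Brownian likelihood is evaluated in O(n) by Felsenstein's pruning
// algorithm on the residuals, factorised into (n - 1) contrast terms plus a
// root term. The likelihood enters the target raised to `power`
// (stepping-stone tempering; power = 0 samples the prior).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pruner {
  int n_tips, n_nodes, root;
  const int *par, *chi;   // postorder edge arrays, 0-based node ids
  int n_edge;
  double root_extra;      // root edge length (shared ancestry from pruning)
  std::vector<double> xval, vval;
  std::vector<char> has;

  Pruner(int n_tips_, int n_nodes_, const IntegerVector &parent,
         const IntegerVector &child, double root_extra_ = 0.0)
      : n_tips(n_tips_), n_nodes(n_nodes_), root(n_tips_),
        par(&parent[0]), chi(&child[0]), n_edge(parent.size()),
        root_extra(root_extra_), xval(n_nodes_), vval(n_nodes_),
        has(n_nodes_) {}

  // Brownian log-likelihood factor of residuals at unit rate: fills sumlogw
  // and Q so that
  //   ll(sigma2) = -0.5 (n log(2 pi) + n log(sigma2) + sumlogw + Q / sigma2)
  bool factor(const std::vector<double> &resid, const std::vector<double> &slen,
              double &sumlogw, double &Q) {
    std::fill(has.begin(), has.end(), 0);
    for (int i = 0; i < n_tips; ++i) { xval[i] = resid[i]; vval[i] = 0.0; }
    sumlogw = 0.0; Q = 0.0;
    for (int k = 0; k < n_edge; ++k) {
      int p = par[k], c = chi[k];
      double vtot = vval[c] + slen[k];
      if (!has[p]) { xval[p] = xval[c]; vval[p] = vtot; has[p] = 1; }
      else {
        double w = vval[p] + vtot;
        if (w <= 0.0) return false;  // sibling paths of zero length
        double d = xval[p] - xval[c];
        sumlogw += std::log(w);
        Q += d * d / w;
        xval[p] = (xval[p] * vtot + xval[c] * vval[p]) / w;
        vval[p] = vval[p] * vtot / w;
      }
    }
    double w = vval[root] + root_extra;
    if (w <= 0.0) return false;  // every scalar on some path is zero
    sumlogw += std::log(w);
    Q += xval[root] * xval[root] / w;
    return true;
  }
};

inline double ll_from_factor(int n, double sumlogw, double Q, double sigma2) {
  return -0.5 * (n * std::log(2.0 * M_PI) + n * std::log(sigma2) + sumlogw +
                 Q / sigma2);
}

inline double log_prior_sigma2(double s, double scale) {
  // half-Cauchy(scale) density on sigma2 itself
  return std::log(2.0 / M_PI) - std::log(scale) -
         std::log1p((s / scale) * (s / scale));
}

inline double dnorm_log(double x, double sd) {
  return -0.5 * std::log(2.0 * M_PI) - std::log(sd) - 0.5 * x * x / (sd * sd);
}

}  // namespace

// [[Rcpp::export(name = ".vr_chain_cpp")]]
List vr_chain_cpp(NumericMatrix X, NumericVector y,
                  IntegerVector edge_parent, IntegerVector edge_child,
                  NumericVector edge_length, int n_nodes, double root_edge,
                  IntegerVector clade_ptr, IntegerVector clade_idx,
                  NumericVector beta0, double sigma2_0,
                  NumericVector rb0, IntegerVector ab0,
                  NumericVector rc0, IntegerVector ac0,
                  double beta_sd, double sigma_scale, double p_active,
                  double logr_sd,
                  NumericVector beta_step, double sigma_step, double r_step,
                  int n_rj, int n_scalar,
                  double power, bool use_rj,
                  int n_iter, int burnin, int thin, bool record_r) {
  const int n = y.size(), p = X.ncol(), E = edge_parent.size();
  if ((int)beta0.size() != p || (int)beta_step.size() != p ||
      (int)rb0.size() != E || (int)rc0.size() != E ||
      (int)ab0.size() != E || (int)ac0.size() != E ||
      X.nrow() != n || (int)edge_length.size() != E)
    stop("state dimensions do not match the design matrix / tree");
  Pruner pr(n, n_nodes, edge_parent, edge_child, root_edge);

  std::vector<double> beta(beta0.begin(), beta0.end());
  double sigma2 = sigma2_0;
  std::vector<double> rb(rb0.begin(), rb0.end()), rc(rc0.begin(), rc0.end());
  std::vector<char> ab(E), ac(E);
  for (int e = 0; e < E; ++e) { ab[e] = (char)ab0[e]; ac[e] = (char)ac0[e]; }

  // incoming edge of each node (-1 for root), for the effective-rate pass
  std::vector<int> in_edge(n_nodes, -1);
  for (int k = 0; k < E; ++k) in_edge[edge_child[k]] = k;

  std::vector<double> resid(n), slen(E), reff(E), cpath(n_nodes, 1.0);
  std::vector<double> saved;  // per-move rollback buffer

  // canonical recomputation of effective scalars and scaled lengths from the
  // state (also re-run each sweep to kill multiplicative drift)
  auto recompute_slen = [&]() {
    // reverse postorder: parents before children
    cpath.assign(n_nodes, 1.0);
    for (int k = E - 1; k >= 0; --k) {
      cpath[edge_child[k]] = cpath[edge_parent[k]] * rc[k];
      reff[k] = rb[k] * cpath[edge_child[k]];
      slen[k] = edge_length[k] * reff[k];
    }
  };
  recompute_slen();

  for (int i = 0; i < n; ++i) {
    double m = 0.0;
    for (int j = 0; j < p; ++j) m += X(i, j) * beta[j];
    resid[i] = y[i] - m;
  }

  double sumlogw, Q;
  if (!pr.factor(resid, slen, sumlogw, Q))
    stop("singular covariance at the initial state");
  double ll = ll_from_factor(n, sumlogw, Q, sigma2);
  if (!std::isfinite(ll)) stop("non-finite likelihood at the initial state");

  const int n_keep = (n_iter > burnin) ? (n_iter - burnin) / thin : 0;
  NumericMatrix beta_tr(n_keep, p);
  NumericVector sigma2_tr(n_keep), ll_tr(n_keep);
  IntegerVector nact_tr(n_keep), nact_branch_tr(n_keep), nact_clade_tr(n_keep);
  NumericMatrix r_tr(record_r ? n_keep : 0, record_r ? E : 0);

  long acc_beta = 0, try_beta = 0, acc_sig = 0, try_sig = 0;
  long acc_rj = 0, try_rj = 0, acc_sc = 0, try_sc = 0;
  long acc_tr = 0, try_tr = 0;
  int kept = 0;
  const double log_odds_on = std::log(p_active / (1.0 - p_active));

  // parent node of each node (-1 for root), for ancestry tests
  std::vector<int> parent_of(n_nodes, -1);
  for (int k = 0; k < E; ++k) parent_of[edge_child[k]] = edge_parent[k];
  // is the child node of edge a an ancestor of (the child node of) edge d?
  auto edge_is_ancestor = [&](int a, int d) {
    int na = edge_child[a];
    for (int nd = parent_of[edge_child[d]]; nd >= 0; nd = parent_of[nd])
      if (nd == na) return true;
    return false;
  };

  // multiply the scaled lengths across a clade, saving originals for rollback
  auto scale_clade = [&](int e, double ratio) {
    int lo = clade_ptr[e], hi = clade_ptr[e + 1];
    saved.resize(hi - lo);
    for (int t = lo; t < hi; ++t) {
      saved[t - lo] = slen[clade_idx[t]];
      slen[clade_idx[t]] *= ratio;
    }
  };
  auto unscale_clade = [&](int e) {
    int lo = clade_ptr[e], hi = clade_ptr[e + 1];
    for (int t = lo; t < hi; ++t) slen[clade_idx[t]] = saved[t - lo];
  };

  for (int it = 0; it < n_iter; ++it) {
    recompute_slen();

    // (i) Gaussian random walk on each regression coefficient
    for (int j = 0; j < p; ++j) {
      ++try_beta;
      double bnew = beta[j] + beta_step[j] * norm_rand();
      double delta = bnew - beta[j];
      for (int i = 0; i < n; ++i) resid[i] -= X(i, j) * delta;
      double slw, q;
      bool ok = pr.factor(resid, slen, slw, q);
      double ll_new = ok ? ll_from_factor(n, slw, q, sigma2) : R_NegInf;
      double la = power * (ll_new - ll) +
                  dnorm_log(bnew, beta_sd) - dnorm_log(beta[j], beta_sd);
      if (std::log(unif_rand()) < la) {
        beta[j] = bnew; sumlogw = slw; Q = q; ll = ll_new; ++acc_beta;
      } else {
        for (int i = 0; i < n; ++i) resid[i] += X(i, j) * delta;
      }
    }

    // (ii) multiplicative random walk on sigma2 (O(1) given the factor)
    {
      ++try_sig;
      double snew = sigma2 * std::exp(sigma_step * norm_rand());
      double ll_new = ll_from_factor(n, sumlogw, Q, snew);
      double la = power * (ll_new - ll) +
                  log_prior_sigma2(snew, sigma_scale) -
                  log_prior_sigma2(sigma2, sigma_scale) +
                  std::log(snew / sigma2);  // Jacobian of the log-scale walk
      if (std::log(unif_rand()) < la) { sigma2 = snew; ll = ll_new; ++acc_sig; }
    }

    if (use_rj) {
      // (iii) reversible-jump birth/death over the 2E scalar sites; births
      // draw r from its prior, so prior and proposal densities cancel and
      // the acceptance ratio is the likelihood ratio times the prior odds
      for (int m = 0; m < n_rj; ++m) {
        ++try_rj;
        int site = (int)(unif_rand() * 2 * E); if (site >= 2 * E) site = 2 * E - 1;
        bool clade = site >= E;
        int e = clade ? site - E : site;
        bool birth = clade ? !ac[e] : !ab[e];
        double rnew = birth ? std::exp(logr_sd * norm_rand()) : 1.0;
        double ratio;
        if (clade) ratio = birth ? rnew : 1.0 / rc[e];
        else       ratio = birth ? rnew : 1.0 / rb[e];
        if (clade) scale_clade(e, ratio);
        else { saved.assign(1, slen[e]); slen[e] *= ratio; }
        double slw, q;
        bool ok = pr.factor(resid, slen, slw, q);
        double ll_new = ok ? ll_from_factor(n, slw, q, sigma2) : R_NegInf;
        double la = power * (ll_new - ll) + (birth ? log_odds_on : -log_odds_on);
        if (std::log(unif_rand()) < la) {
          if (clade) { ac[e] = birth; rc[e] = birth ? rnew : 1.0; }
          else       { ab[e] = birth; rb[e] = birth ? rnew : 1.0; }
          sumlogw = slw; Q = q; ll = ll_new; ++acc_rj;
        } else {
          if (clade) unscale_clade(e); else slen[e] = saved[0];
        }
      }

      // (iv) multiplicative random walk on one active scalar per attempt
      for (int m = 0; m < n_scalar; ++m) {
        int n_act = 0;
        for (int e = 0; e < E; ++e) n_act += ab[e] + ac[e];
        if (n_act == 0) break;
        ++try_sc;
        int pick = (int)(unif_rand() * n_act); if (pick >= n_act) pick = n_act - 1;
        int e = -1; bool clade = false;
        for (int k = 0; k < E && pick >= 0; ++k) {
          if (ab[k] && pick-- == 0) { e = k; clade = false; break; }
          if (ac[k] && pick-- == 0) { e = k; clade = true; break; }
        }
        double r_old = clade ? rc[e] : rb[e];
        double lr_new = std::log(r_old) + r_step * norm_rand();
        double r_new = std::exp(lr_new);
        if (clade) scale_clade(e, r_new / r_old);
        else { saved.assign(1, slen[e]); slen[e] *= r_new / r_old; }
        double slw, q;
        bool ok = pr.factor(resid, slen, slw, q);
        double ll_new = ok ? ll_from_factor(n, slw, q, sigma2) : R_NegInf;
        double la = power * (ll_new - ll) +
                    dnorm_log(lr_new, logr_sd) -
                    dnorm_log(std::log(r_old), logr_sd);
        if (std::log(unif_rand()) < la) {
          if (clade) rc[e] = r_new; else rb[e] = r_new;
          sumlogw = slw; Q = q; ll = ll_new; ++acc_sc;
        } else {
          if (clade) unscale_clade(e); else slen[e] = saved[0];
        }
      }
    }

    if (use_rj) {
      // (v) mass transfer between nested active clade scalars: rate-shift
      // anchoring is only weakly identified (a shift "at the stem" vs "split
      // across stem and a subclade" fit almost equally well), which leaves
      // plain birth/death walks stuck on the ridge rc_a * rc_d ~ const.
      // This move slides mass along that ridge: symmetric in log space,
      // unit Jacobian, so only the likelihood (edges between the two
      // anchors) and the scalar-value priors enter the acceptance.
      for (int m = 0; m < n_scalar; ++m) {
        std::vector<int> act;
        for (int e = 0; e < E; ++e) if (ac[e]) act.push_back(e);
        if (act.size() < 2) break;
        std::vector<std::pair<int, int>> pairs;
        for (size_t i = 0; i < act.size(); ++i)
          for (size_t j = 0; j < act.size(); ++j)
            if (i != j && edge_is_ancestor(act[i], act[j]))
              pairs.push_back(std::make_pair(act[i], act[j]));
        if (pairs.empty()) break;
        ++try_tr;
        int pk = (int)(unif_rand() * pairs.size());
        if (pk >= (int)pairs.size()) pk = pairs.size() - 1;
        int a = pairs[pk].first, d = pairs[pk].second;
        double delta = r_step * norm_rand();
        double la_prior =
            dnorm_log(std::log(rc[a]) + delta, logr_sd) +
            dnorm_log(std::log(rc[d]) - delta, logr_sd) -
            dnorm_log(std::log(rc[a]), logr_sd) -
            dnorm_log(std::log(rc[d]), logr_sd);
        std::vector<double> slen_keep(slen);
        double up = std::exp(delta);
        for (int t = clade_ptr[a]; t < clade_ptr[a + 1]; ++t)
          slen[clade_idx[t]] *= up;
        for (int t = clade_ptr[d]; t < clade_ptr[d + 1]; ++t)
          slen[clade_idx[t]] /= up;
        double slw, q;
        bool ok = pr.factor(resid, slen, slw, q);
        double ll_new = ok ? ll_from_factor(n, slw, q, sigma2) : R_NegInf;
        double la = power * (ll_new - ll) + la_prior;
        if (std::log(unif_rand()) < la) {
          rc[a] *= up; rc[d] /= up;
          sumlogw = slw; Q = q; ll = ll_new; ++acc_tr;
        } else slen.swap(slen_keep);
      }
    }

    if (it >= burnin && (it - burnin) % thin == 0 && kept < n_keep) {
      recompute_slen();  // exact effective scalars for the record
      for (int j = 0; j < p; ++j) beta_tr(kept, j) = beta[j];
      sigma2_tr[kept] = sigma2;
      ll_tr[kept] = ll;
      int na_b = 0, na_c = 0;
      for (int e = 0; e < E; ++e) { na_b += ab[e]; na_c += ac[e]; }
      nact_branch_tr[kept] = na_b; nact_clade_tr[kept] = na_c;
      nact_tr[kept] = na_b + na_c;
      if (record_r) for (int e = 0; e < E; ++e) r_tr(kept, e) = reff[e];
      ++kept;
    }
  }

  return List::create(
      _["beta"] = beta_tr, _["sigma2"] = sigma2_tr, _["loglik"] = ll_tr,
      _["n_active"] = nact_tr, _["n_active_branch"] = nact_branch_tr,
      _["n_active_clade"] = nact_clade_tr, _["r"] = r_tr,
      _["final_beta"] = NumericVector(beta.begin(), beta.end()),
      _["final_sigma2"] = sigma2,
      _["final_rb"] = NumericVector(rb.begin(), rb.end()),
      _["final_ab"] = IntegerVector(ab.begin(), ab.end()),
      _["final_rc"] = NumericVector(rc.begin(), rc.end()),
      _["final_ac"] = IntegerVector(ac.begin(), ac.end()),
      _["accept"] = NumericVector::create(
          _["beta"] = try_beta ? (double)acc_beta / try_beta : NA_REAL,
          _["sigma2"] = try_sig ? (double)acc_sig / try_sig : NA_REAL,
          _["rj"] = try_rj ? (double)acc_rj / try_rj : NA_REAL,
          _["scalar"] = try_sc ? (double)acc_sc / try_sc : NA_REAL,
          _["transfer"] = try_tr ? (double)acc_tr / try_tr : NA_REAL));
}

// [[Rcpp::export(name = ".vr_loglik_cpp")]]
double vr_loglik_cpp(NumericMatrix X, NumericVector y,
                     IntegerVector edge_parent, IntegerVector edge_child,
                     NumericVector edge_length, int n_nodes, double root_edge,
                     NumericVector beta, double sigma2, NumericVector r) {
  const int n = y.size(), p = X.ncol(), E = edge_parent.size();
  Pruner pr(n, n_nodes, edge_parent, edge_child, root_edge);
  std::vector<double> resid(n), slen(E);
  for (int e = 0; e < E; ++e) slen[e] = edge_length[e] * r[e];
  for (int i = 0; i < n; ++i) {
    double m = 0.0;
    for (int j = 0; j < p; ++j) m += X(i, j) * beta[j];
    resid[i] = y[i] - m;
  }
  double sumlogw, Q;
  if (!pr.factor(resid, slen, sumlogw, Q))
    stop("singular covariance: some tip's root-to-tip path has zero scaled length");
  return ll_from_factor(n, sumlogw, Q, sigma2);
}
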