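// Cox partial-likelihood kernels (Efron tie handling) and the
// leave-one-out cross-validated risk-group engine.
//
// The permutation test re-runs the entire LOOCV pipeline (per-feature
// screening + supervised PCs + Cox on the PC scores) for every shuffle
// of the survival labels, so the inner loops are compiled. The
// per-feature screen is vectorized across features (columns) with an
// active set and warm starts; the univariate partial likelihood is
// strictly concave, so Newton with a clamped step converges to the
// unique maximizer regardless of the start.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct UniFit {
  double beta;
  double se;
  double loglik;
  int iters;
  int flag; // 0 ok, 1 not converged / monotone likelihood
};

// One backward pass over samples sorted by increasing time.
// Returns loglik; fills grad and hess for a single covariate.
double uni_pass(const vec& x, const vec& time, const ivec& status,
                double beta, double& grad, double& hess) {
  const int n = x.n_elem;
  double S0 = 0.0, S1 = 0.0, S2 = 0.0, ll = 0.0;
  grad = 0.0;
  hess = 0.0;
  int i = n - 1;
  while (i >= 0) {
    const double t = time[i];
    int k = i;
    while (k > 0 && time[k - 1] == t) --k;
    double D0 = 0.0, D1 = 0.0, D2 = 0.0, sx = 0.0, sxb = 0.0;
    int d = 0;
    for (int m = k; m <= i; ++m) {
      const double e = std::exp(x[m] * beta);
      S0 += e; S1 += x[m] * e; S2 += x[m] * x[m] * e;
      if (status[m] == 1) {
        ++d; D0 += e; D1 += x[m] * e; D2 += x[m] * x[m] * e;
        sx += x[m]; sxb += x[m] * beta;
      }
    }
    if (d > 0) {
      grad += sx;
      ll += sxb;
      for (int l = 0; l < d; ++l) {
        const double f = static_cast<double>(l) / d;
        const double s0 = S0 - f * D0;
        const double s1 = S1 - f * D1;
        const double s2 = S2 - f * D2;
        const double r1 = s1 / s0;
        grad -= r1;
        hess += s2 / s0 - r1 * r1;
        ll -= std::log(s0);
      }
    }
    i = k - 1;
  }
  return ll;
}

// Scalar Newton with step halving (used by the user-facing single fit).
UniFit cox_uni(const vec& x, const vec& time, const ivec& status,
               int maxit, double tol) {
  UniFit out{0.0, NA_REAL, NA_REAL, 0, 0};
  double beta = 0.0, grad = 0.0, hess = 0.0;
  double ll = uni_pass(x, time, status, beta, grad, hess);
  int it = 0;
  bool converged = std::fabs(grad) < tol;
  while (!converged && it < maxit) {
    ++it;
    if (hess <= 0.0 || !std::isfinite(hess)) { out.flag = 1; break; }
    double step = grad / hess;
    double beta_new = beta + step;
    double g2, h2;
    double ll_new = uni_pass(x, time, status, beta_new, g2, h2);
    int halves = 0;
    while ((!std::isfinite(ll_new) || ll_new < ll - 1e-12) && halves < 20) {
      step *= 0.5;
      beta_new = beta + step;
      ll_new = uni_pass(x, time, status, beta_new, g2, h2);
      ++halves;
    }
    beta = beta_new; ll = ll_new; grad = g2; hess = h2;
    if (std::fabs(grad) < tol) converged = true;
    if (std::fabs(beta) > 15.0) { out.flag = 1; break; } // monotone likelihood
  }
  if (!converged && out.flag == 0) out.flag = 1;
  out.beta = beta;
  out.loglik = ll;
  out.iters = it;
  out.se = (hess > 0.0) ? 1.0 / std::sqrt(hess) : NA_REAL;
  return out;
}

// Tied-time block structure of a time-sorted cohort.
struct TieBlocks {
  std::vector<int> start, stop;          // inclusive sample ranges
  std::vector<std::vector<int>> deaths;  // event rows per block
};

TieBlocks make_blocks(const vec& time, const ivec& status) {
  TieBlocks tb;
  const int n = time.n_elem;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && time[j + 1] == time[i]) ++j;
    tb.start.push_back(i);
    tb.stop.push_back(j);
    std::vector<int> d;
    for (int m = i; m <= j; ++m)
      if (status[m] == 1) d.push_back(m);
    tb.deaths.push_back(std::move(d));
    i = j + 1;
  }
  return tb;
}

// Per-feature screen, vectorized across the columns of Xs (sorted by
// time). flag: 0 ok, 1 not converged / monotone, 2 no variation.
void screen_block(const mat& Xs, const ivec& status, const TieBlocks& tb,
                  const rowvec& beta_init, int maxit, double tol,
                  rowvec& beta, rowvec& se, rowvec& pval, irowvec& flag) {
  const int n = Xs.n_rows, p = Xs.n_cols;
  const int nb = static_cast<int>(tb.start.size());
  beta.zeros(p);
  se.set_size(p); se.fill(NA_REAL);
  pval.set_size(p); pval.fill(NA_REAL);
  flag.zeros(p);

  std::vector<uword> active;
  active.reserve(p);
  for (int j = 0; j < p; ++j) {
    const vec xj = Xs.col(j);
    if (xj.max() == xj.min()) { flag[j] = 2; continue; }
    double b0 = beta_init.n_elem == static_cast<uword>(p) ? beta_init[j] : 0.0;
    if (!std::isfinite(b0) || std::fabs(b0) > 10.0) b0 = 0.0;
    beta[j] = b0;
    active.push_back(j);
  }

  for (int it = 0; it <= maxit && !active.empty(); ++it) {
    const uvec act(active);
    const int pa = act.n_elem;
    mat Xa = Xs.cols(act);
    rowvec ba = beta.cols(act);
    mat W = exp(Xa.each_row() % ba);
    mat XW = Xa % W;
    mat X2W = Xa % XW;

    rowvec S0(pa, fill::zeros), S1(pa, fill::zeros), S2(pa, fill::zeros);
    rowvec grad(pa, fill::zeros), hess(pa, fill::zeros);
    for (int b = nb - 1; b >= 0; --b) {
      const int lo = tb.start[b], hi = tb.stop[b];
      S0 += sum(W.rows(lo, hi), 0);
      S1 += sum(XW.rows(lo, hi), 0);
      S2 += sum(X2W.rows(lo, hi), 0);
      const int d = static_cast<int>(tb.deaths[b].size());
      if (d == 0) continue;
      rowvec D0(pa, fill::zeros), D1(pa, fill::zeros), D2(pa, fill::zeros);
      for (int m : tb.deaths[b]) {
        D0 += W.row(m);
        D1 += XW.row(m);
        D2 += X2W.row(m);
        grad += Xa.row(m);
      }
      for (int l = 0; l < d; ++l) {
        const double f = static_cast<double>(l) / d;
        const rowvec s0 = S0 - f * D0;
        const rowvec r1 = (S1 - f * D1) / s0;
        grad -= r1;
        hess += (S2 - f * D2) / s0 - r1 % r1;
      }
    }

    std::vector<uword> still;
    still.reserve(pa);
    for (int a = 0; a < pa; ++a) {
      const uword j = act[a];
      if (std::fabs(grad[a]) < tol && hess[a] > 0.0) {
        se[j] = 1.0 / std::sqrt(hess[a]);
        const double z = std::fabs(beta[j] / se[j]);
        pval[j] = 2.0 * R::pnorm(-z, 0.0, 1.0, 1, 0);
        continue; // converged, deactivate
      }
      if (it == maxit || hess[a] <= 0.0 || !std::isfinite(hess[a])) {
        flag[j] = 1;
        continue;
      }
      double step = grad[a] / hess[a];
      if (step > 5.0) step = 5.0;
      if (step < -5.0) step = -5.0;
      beta[j] += step;
      if (std::fabs(beta[j]) > 15.0) { flag[j] = 1; continue; }
      still.push_back(j);
    }
    active.swap(still);
  }
  (void)n;
}

// Multivariate (m <= 2 in practice) Efron Newton; expects sorted data.
double multi_pass(const mat& Z, const vec& time, const ivec& status,
                  const vec& beta, vec& grad, mat& hess) {
  const int n = Z.n_rows, m = Z.n_cols;
  double S0 = 0.0, ll = 0.0;
  vec S1(m, fill::zeros);
  mat S2(m, m, fill::zeros);
  grad.zeros(m);
  hess.zeros(m, m);
  int i = n - 1;
  while (i >= 0) {
    const double t = time[i];
    int k = i;
    while (k > 0 && time[k - 1] == t) --k;
    double D0 = 0.0;
    vec D1(m, fill::zeros), sx(m, fill::zeros);
    mat D2(m, m, fill::zeros);
    int d = 0;
    double sxb = 0.0;
    for (int r = k; r <= i; ++r) {
      const rowvec zr = Z.row(r);
      const double e = std::exp(dot(zr, beta));
      S0 += e; S1 += e * zr.t(); S2 += e * (zr.t() * zr);
      if (status[r] == 1) {
        ++d; D0 += e; D1 += e * zr.t(); D2 += e * (zr.t() * zr);
        sx += zr.t(); sxb += dot(zr, beta);
      }
    }
    if (d > 0) {
      grad += sx;
      ll += sxb;
      for (int l = 0; l < d; ++l) {
        const double f = static_cast<double>(l) / d;
        const double s0 = S0 - f * D0;
        const vec s1 = S1 - f * D1;
        const mat s2 = S2 - f * D2;
        const vec r1 = s1 / s0;
        grad -= r1;
        hess += s2 / s0 - r1 * r1.t();
        ll -= std::log(s0);
      }
    }
    i = k - 1;
  }
  return ll;
}

struct MultiFit {
  vec beta;
  mat imat;
  int flag;
};

MultiFit cox_multi(const mat& Z, const vec& time, const ivec& status,
                   int maxit, double tol) {
  const int m = Z.n_cols;
  MultiFit out{vec(m, fill::zeros), mat(m, m, fill::zeros), 0};
  vec beta(m, fill::zeros), grad(m);
  mat hess(m, m);
  double ll = multi_pass(Z, time, status, beta, grad, hess);
  bool converged = norm(grad, "inf") < tol;
  int it = 0;
  while (!converged && it < maxit) {
    ++it;
    vec step;
    const bool ok = solve(step, hess, grad, solve_opts::no_approx);
    if (!ok) { out.flag = 1; break; }
    vec beta_new = beta + step;
    vec g2(m); mat h2(m, m);
    double ll_new = multi_pass(Z, time, status, beta_new, g2, h2);
    int halves = 0;
    while ((!std::isfinite(ll_new) || ll_new < ll - 1e-12) && halves < 20) {
      step *= 0.5;
      beta_new = beta + step;
      ll_new = multi_pass(Z, time, status, beta_new, g2, h2);
      ++halves;
    }
    beta = beta_new; ll = ll_new; grad = g2; hess = h2;
    if (norm(grad, "inf") < tol) converged = true;
    if (norm(beta, "inf") > 15.0) { out.flag = 1; break; }
  }
  if (!converged && out.flag == 0) out.flag = 1;
  out.beta = beta;
  out.imat = hess;
  return out;
}

// Two-group log-rank chi-square (1 df), hypergeometric variance.
// Returns 0 when one group is empty or the variance vanishes.
double logrank_chisq(const ivec& grp, const vec& time, const ivec& status) {
  const int n = grp.n_elem;
  uvec ord = stable_sort_index(time);
  double O = 0.0, E = 0.0, V = 0.0;
  double nrisk = 0.0, n1risk = 0.0;
  int i = n - 1;
  while (i >= 0) {
    const double t = time[ord[i]];
    int k = i;
    while (k > 0 && time[ord[k - 1]] == t) --k;
    int d = 0, d1 = 0;
    for (int m = k; m <= i; ++m) {
      nrisk += 1.0;
      if (grp[ord[m]] == 1) n1risk += 1.0;
      if (status[ord[m]] == 1) {
        ++d;
        if (grp[ord[m]] == 1) ++d1;
      }
    }
    if (d > 0 && nrisk > 1.0) {
      const double p1 = n1risk / nrisk;
      O += d1;
      E += d * p1;
      V += d * p1 * (1.0 - p1) * (nrisk - d) / (nrisk - 1.0);
    }
    i = k - 1;
  }
  if (V <= 0.0) return 0.0;
  const double diff = O - E;
  return diff * diff / V;
}

struct FoldResult {
  double pi;
  double pct;
  int grp;   // 0 low, 1 high
  int weak;  // 1 if the fold could not support a model (assigned low)
  int nsel;
};

double midrank_pct(const vec& ref, double value) {
  double less = 0.0, eq = 0.0;
  for (uword i = 0; i < ref.n_elem; ++i) {
    if (ref[i] < value) less += 1.0;
    else if (ref[i] == value) eq += 1.0;
  }
  return 100.0 * (less + 0.5 * eq) / ref.n_elem;
}

// Fit the supervised-PC risk model on sorted training data and score
// one held-out sample.
FoldResult fold_fit_score(const mat& Xtr, const vec& time,
                          const ivec& status, const rowvec& beta_init,
                          const rowvec& xtest, double alpha,
                          double cutoff) {
  FoldResult res{NA_REAL, NA_REAL, 0, 1, 0};
  const int n = Xtr.n_rows;
  int nev = 0;
  for (int i = 0; i < n; ++i) nev += status[i];
  if (nev < 2) return res;

  TieBlocks tb = make_blocks(time, status);
  rowvec beta, se, pv;
  irowvec flag;
  screen_block(Xtr, status, tb, beta_init, 50, 1e-8, beta, se, pv, flag);

  std::vector<uword> sel;
  for (uword j = 0; j < pv.n_elem; ++j)
    if (flag[j] == 0 && std::isfinite(pv[j]) && pv[j] < alpha)
      sel.push_back(j);
  res.nsel = static_cast<int>(sel.size());
  if (sel.size() < 2) return res;

  const uvec selidx(sel);
  mat Xsel = Xtr.cols(selidx);
  rowvec mu = mean(Xsel, 0);
  Xsel.each_row() -= mu;

  mat U, Vm;
  vec sv;
  if (!svd_econ(U, sv, Vm, Xsel, "both", "std")) return res;
  if (sv[0] <= 0.0) return res;
  const int ncomp = (sv.n_elem >= 2 && sv[1] > 1e-8 * sv[0]) ? 2 : 1;
  mat scores = U.cols(0, ncomp - 1) * diagmat(sv.subvec(0, ncomp - 1));

  MultiFit cf = cox_multi(scores, time, status, 50, 1e-9);
  if (cf.flag != 0) return res;

  vec pi_train = scores * cf.beta;
  rowvec xc = xtest.cols(selidx) - mu;
  double pi_test = 0.0;
  for (int c = 0; c < ncomp; ++c)
    pi_test += cf.beta[c] * dot(xc, Vm.col(c));

  res.pi = pi_test;
  res.pct = midrank_pct(pi_train, pi_test);
  res.grp = (res.pct > cutoff) ? 1 : 0;
  res.weak = 0;
  return res;
}

// Full LOOCV; outputs indexed by the original sample order.
void loocv_core(const mat& X, const vec& time, const ivec& status,
                double alpha, double cutoff,
                vec& pi, vec& pct, ivec& grp, ivec& weak, ivec& nsel) {
  const int n = X.n_rows, p = X.n_cols;
  pi.set_size(n); pct.set_size(n);
  grp.set_size(n); weak.set_size(n); nsel.set_size(n);

  const uvec ord = stable_sort_index(time);
  const mat Xs = X.rows(ord);
  vec ts(n); ivec ss(n);
  for (int i = 0; i < n; ++i) { ts[i] = time[ord[i]]; ss[i] = status[ord[i]]; }

  // full-data screen: warm starts for the folds
  TieBlocks tb_full = make_blocks(ts, ss);
  rowvec beta_full, se_f, pv_f;
  irowvec flag_f;
  screen_block(Xs, ss, tb_full, rowvec(), 50, 1e-8,
               beta_full, se_f, pv_f, flag_f);

  mat Xtr(n - 1, p);
  vec t_tr(n - 1);
  ivec s_tr(n - 1);
  for (int f = 0; f < n; ++f) {
    if (f > 0) {
      Xtr.rows(0, f - 1) = Xs.rows(0, f - 1);
      t_tr.subvec(0, f - 1) = ts.subvec(0, f - 1);
      s_tr.subvec(0, f - 1) = ss.subvec(0, f - 1);
    }
    if (f < n - 1) {
      Xtr.rows(f, n - 2) = Xs.rows(f + 1, n - 1);
      t_tr.subvec(f, n - 2) = ts.subvec(f + 1, n - 1);
      s_tr.subvec(f, n - 2) = ss.subvec(f + 1, n - 1);
    }
    FoldResult fr = fold_fit_score(Xtr, t_tr, s_tr, beta_full,
                                   Xs.row(f), alpha, cutoff);
    const int orig = ord[f];
    pi[orig] = fr.pi; pct[orig] = fr.pct; grp[orig] = fr.grp;
    weak[orig] = fr.weak; nsel[orig] = fr.nsel;
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_cox_uni")]]
Rcpp::List cpp_cox_uni(const arma::vec& x, const arma::vec& time,
                       const arma::ivec& status,
                       int maxit = 50, double tol = 1e-8) {
  uvec ord = stable_sort_index(time);
  const int n = x.n_elem;
  vec xs(n), ts(n); ivec ss(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = x[ord[i]]; ts[i] = time[ord[i]]; ss[i] = status[ord[i]];
  }
  UniFit f = cox_uni(xs, ts, ss, maxit, tol);
  double p = NA_REAL;
  if (f.flag == 0 && std::isfinite(f.se) && f.se > 0.0) {
    const double z = std::fabs(f.beta / f.se);
    p = 2.0 * R::pnorm(-z, 0.0, 1.0, 1, 0);
  }
  return Rcpp::List::create(
      Rcpp::Named("beta") = f.beta, Rcpp::Named("se") = f.se,
      Rcpp::Named("p") = p, Rcpp::Named("loglik") = f.loglik,
      Rcpp::Named("iters") = f.iters, Rcpp::Named("flag") = f.flag);
}

// [[Rcpp::export(name = ".cpp_cox_screen")]]
Rcpp::NumericMatrix cpp_cox_screen(const arma::mat& X,
                                   const arma::vec& time,
                                   const arma::ivec& status,
                                   int maxit = 50, double tol = 1e-8) {
  const int n = X.n_rows, p = X.n_cols;
  uvec ord = stable_sort_index(time);
  mat Xs = X.rows(ord);
  vec ts(n); ivec ss(n);
  for (int i = 0; i < n; ++i) { ts[i] = time[ord[i]]; ss[i] = status[ord[i]]; }
  TieBlocks tb = make_blocks(ts, ss);
  rowvec beta, se, pv;
  irowvec flag;
  screen_block(Xs, ss, tb, rowvec(), maxit, tol, beta, se, pv, flag);
  Rcpp::NumericMatrix out(p, 4);
  colnames(out) = Rcpp::CharacterVector::create("beta", "se", "p", "flag");
  for (int j = 0; j < p; ++j) {
    out(j, 0) = (flag[j] == 2) ? NA_REAL : beta[j];
    out(j, 1) = se[j];
    out(j, 2) = pv[j];
    out(j, 3) = flag[j];
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_cox_loglik")]]
double cpp_cox_loglik(const arma::vec& x, const arma::vec& time,
                      const arma::ivec& status, double beta) {
  uvec ord = stable_sort_index(time);
  const int n = x.n_elem;
  vec xs(n), ts(n); ivec ss(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = x[ord[i]]; ts[i] = time[ord[i]]; ss[i] = status[ord[i]];
  }
  double g, h;
  return uni_pass(xs, ts, ss, beta, g, h);
}

// [[Rcpp::export(name = ".cpp_cox_multi")]]
Rcpp::List cpp_cox_multi(const arma::mat& Z, const arma::vec& time,
                         const arma::ivec& status,
                         int maxit = 50, double tol = 1e-9) {
  uvec ord = stable_sort_index(time);
  const int n = Z.n_rows;
  mat Zs = Z.rows(ord);
  vec ts(n); ivec ss(n);
  for (int i = 0; i < n; ++i) { ts[i] = time[ord[i]]; ss[i] = status[ord[i]]; }
  MultiFit f = cox_multi(Zs, ts, ss, maxit, tol);
  return Rcpp::List::create(
      Rcpp::Named("beta") = f.beta,
      Rcpp::Named("imat") = f.imat,
      Rcpp::Named("flag") = f.flag);
}

// [[Rcpp::export(name = ".cpp_logrank")]]
double cpp_logrank(const arma::ivec& grp, const arma::vec& time,
                   const arma::ivec& status) {
  return logrank_chisq(grp, time, status);
}

// [[Rcpp::export(name = ".cpp_loocv")]]
Rcpp::List cpp_loocv(const arma::mat& X, const arma::vec& time,
                     const arma::ivec& status, double alpha, double cutoff) {
  vec pi, pct; ivec grp, weak, nsel;
  loocv_core(X, time, status, alpha, cutoff, pi, pct, grp, weak, nsel);
  return Rcpp::List::create(
      Rcpp::Named("pi") = pi,
      Rcpp::Named("percentile") = pct,
      Rcpp::Named("group") = grp,
      Rcpp::Named("weak_fold") = weak,
      Rcpp::Named("n_selected") = nsel);
}

// [[Rcpp::export(name = ".cpp_perm_test")]]
Rcpp::List cpp_perm_test(const arma::mat& X, const arma::vec& time,
                         const arma::ivec& status, double alpha,
                         double cutoff, const arma::imat& perm) {
  vec pi, pct; ivec grp, weak, nsel;
  loocv_core(X, time, status, alpha, cutoff, pi, pct, grp, weak, nsel);
  const double lr_obs = logrank_chisq(grp, time, status);
  const int B = perm.n_cols, n = X.n_rows;
  vec lr_perm(B);
  for (int b = 0; b < B; ++b) {
    Rcpp::checkUserInterrupt();
    vec tp(n); ivec sp(n);
    for (int i = 0; i < n; ++i) {
      const int src = perm(i, b); // 0-based
      tp[i] = time[src]; sp[i] = status[src];
    }
    vec pi2, pct2; ivec grp2, weak2, nsel2;
    loocv_core(X, tp, sp, alpha, cutoff, pi2, pct2, grp2, weak2, nsel2);
    lr_perm[b] = logrank_chisq(grp2, tp, sp);
  }
  int count = 0;
  for (int b = 0; b < B; ++b)
    if (lr_perm[b] >= lr_obs) ++count;
  const double pval = (1.0 + count) / (1.0 + B);
  return Rcpp::List::create(
      Rcpp::Named("lr_obs") = lr_obs,
      Rcpp::Named("lr_perm") = lr_perm,
      Rcpp::Named("p") = pval,
      Rcpp::Named("group") = grp,
      Rcpp::Named("weak_fold") = weak);
}
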