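// Exhaustive QDA subset evaluation under shared cross-validation splits.
// For each split, class means and covariances are computed once over the full
// candidate pool; each subset then only extracts submatrices and runs a
// small in-place Cholesky, which keeps the ~C(15,7) x (iterations x folds)
// sweep tractable. The inner loop is allocation-free.

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// In-place Cholesky of the d x d buffer L (row-major lower triangle).
// Returns false if not positive definite.
static bool chol_small(std::vector<double>& L, int d) {
  for (int j = 0; j < d; ++j) {
    double s = L[j * d + j];
    for (int k = 0; k < j; ++k) s -= L[j * d + k] * L[j * d + k];
    if (s <= 0) return false;
    double diag = std::sqrt(s);
    L[j * d + j] = diag;
    for (int i = j + 1; i < d; ++i) {
      double t = L[i * d + j];
      for (int k = 0; k < j; ++k) t -= L[i * d + k] * L[j * d + k];
      L[i * d + j] = t / diag;
    }
  }
  return true;
}

// Quadratic form (x - mu)' S^{-1} (x - mu) given the Cholesky factor of S.
static double quad_chol(const std::vector<double>& L, int d,
                        const double* x, const double* mu,
                        std::vector<double>& w) {
  double q = 0;
  for (int i = 0; i < d; ++i) {
    double t = x[i] - mu[i];
    for (int k = 0; k < i; ++k) t -= L[i * d + k] * w[k];
    w[i] = t / L[i * d + i];
    q += w[i] * w[i];
  }
  return q;
}

static double midrank_auc(const std::vector<double>& scores,
                          const std::vector<int>& y1,
                          std::vector<int>& ord) {
  const int n = (int)scores.size();
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.begin() + n,
            [&](int a, int b) { return scores[a] < scores[b]; });
  double n1 = 0, sum_r1 = 0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && scores[ord[j + 1]] == scores[ord[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) {
      if (y1[ord[k]]) { n1 += 1; sum_r1 += r; }
    }
    i = j + 1;
  }
  double n0 = n - n1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  return (sum_r1 - n1 * (n1 + 1) / 2.0) / (n1 * n0);
}

// [[Rcpp::export]]
Rcpp::List qda_subset_cv_cpp(const arma::mat& X, const arma::ivec& y,
                             const arma::imat& subsets,
                             const arma::imat& folds,
                             const double ridge_frac) {
  const int S = subsets.n_rows;
  const int d = subsets.n_cols;
  const int Q = folds.n_cols;
  const int p = X.n_cols;

  vec acc_sum(S, fill::zeros), auc_sum(S, fill::zeros);
  vec acc_cnt(S, fill::zeros), auc_cnt(S, fill::zeros);

  std::vector<double> L0(d * d), L1(d * d), w(d), mu0(d), mu1(d), xbuf(d);
  std::vector<int> cols(d);

  for (int q = 0; q < Q; ++q) {
    int K = folds.col(q).max();
    for (int k = 1; k <= K; ++k) {
      uvec test_idx = find(folds.col(q) == k);
      uvec train_idx = find(folds.col(q) != k);
      if (test_idx.is_empty() || train_idx.is_empty()) continue;

      uvec tr0 = train_idx(find(y(train_idx) == 0));
      uvec tr1 = train_idx(find(y(train_idx) == 1));
      if (tr0.n_elem < 2 || tr1.n_elem < 2) continue;

      mat C0 = cov(X.rows(tr0)), C1 = cov(X.rows(tr1));
      rowvec m0 = mean(X.rows(tr0), 0), m1 = mean(X.rows(tr1), 0);
      double lp1 = std::log((double)tr1.n_elem / train_idx.n_elem);
      double lp0 = std::log((double)tr0.n_elem / train_idx.n_elem);
      mat Xt = X.rows(test_idx);
      const int nt = (int)test_idx.n_elem;
      std::vector<int> yt(nt);
      for (int t = 0; t < nt; ++t) yt[t] = (y(test_idx(t)) == 1);
      std::vector<double> score(nt);
      std::vector<int> ord(nt);

      for (int s = 0; s < S; ++s) {
        for (int c = 0; c < d; ++c) cols[c] = subsets(s, c);
        // extract submatrices / subvectors
        double tr_s0 = 0, tr_s1 = 0;
        for (int i = 0; i < d; ++i) {
          mu0[i] = m0(cols[i]); mu1[i] = m1(cols[i]);
          for (int j = 0; j <= i; ++j) {
            L0[i * d + j] = C0(cols[i], cols[j]);
            L1[i * d + j] = C1(cols[i], cols[j]);
          }
          tr_s0 += C0(cols[i], cols[i]);
          tr_s1 += C1(cols[i], cols[i]);
        }
        auto prep = [&](std::vector<double>& L, double tr) {
          if (chol_small(L, d)) return true;
          // restore lower triangle and ridge the diagonal
          for (int i = 0; i < d; ++i) {
            for (int j = 0; j <= i; ++j) {
              double v = (&L == &L0) ? C0(cols[i], cols[j]) : C1(cols[i], cols[j]);
              L[i * d + j] = v;
            }
            L[i * d + i] += ridge_frac * tr / d;
          }
          return chol_small(L, d);
        };
        if (!prep(L0, tr_s0) || !prep(L1, tr_s1)) continue;
        double ld0 = 0, ld1 = 0;
        for (int i = 0; i < d; ++i) {
          ld0 += 2 * std::log(L0[i * d + i]);
          ld1 += 2 * std::log(L1[i * d + i]);
        }
        double correct = 0;
        for (int t = 0; t < nt; ++t) {
          for (int c = 0; c < d; ++c) xbuf[c] = Xt(t, cols[c]);
          double q0 = quad_chol(L0, d, xbuf.data(), mu0.data(), w);
          double q1 = quad_chol(L1, d, xbuf.data(), mu1.data(), w);
          double sc = (-0.5 * q1 - 0.5 * ld1 + lp1) - (-0.5 * q0 - 0.5 * ld0 + lp0);
          score[t] = sc;
          if ((sc > 0) == (yt[t] == 1)) correct += 1;
        }
        acc_sum(s) += correct / nt;
        acc_cnt(s) += 1;
        double a = midrank_auc(score, yt, ord);
        if (std::isfinite(a)) { auc_sum(s) += a; auc_cnt(s) += 1; }
      }
    }
  }

  vec acc = acc_sum / acc_cnt;
  vec auc = auc_sum / auc_cnt;
  return Rcpp::List::create(Rcpp::Named("accuracy") = acc,
                            Rcpp::Named("auc") = auc);
  (void)p;
}
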