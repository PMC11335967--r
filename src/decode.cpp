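// Linear C-SVC via SMO (maximal violating pair), with the pseudo-trial
// cross-validation and temporal-generalization loops kept in C++ so the
// sliding-window decoding stays tractable at desk scale.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TAU = 1e-12;

// SMO solver on a precomputed linear kernel. y in {+1,-1}.
// Returns alpha and bias b through output refs.
static void smo_solve(const arma::mat &K, const arma::vec &y, double C,
                      arma::vec &alpha, double &b,
                      double eps = 1e-3, int max_iter = 100000) {
  int n = K.n_rows;
  alpha.zeros(n);
  arma::vec G(n);
  G.fill(-1.0); // gradient of 1/2 a'Qa - e'a at a = 0

  for (int it = 0; it < max_iter; ++it) {
    // working-set selection: maximal violating pair
    int i = -1, j = -1;
    double Gmax = -arma::datum::inf, Gmin = arma::datum::inf;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (lo && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) {
      b = (Gmax + Gmin) / 2.0;
      break;
    }

    double yi = y[i], yj = y[j];
    // curvature along the feasible direction (e_i + e_j or e_i - e_j,
    // depending on label signs) is |x_i - x_j|^2 in both cases
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = TAU;
    double ai_old = alpha[i], aj_old = alpha[j];

    if (yi != yj) {
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (yi * K(t, i) * dai + yj * K(t, j) * daj);
  }

  // refine b from free support vectors when available
  double bsum = 0; int nfree = 0;
  arma::vec u = K * (alpha % y); // w . x_i
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > TAU && alpha[t] < C - TAU) { bsum += y[t] - u[t]; ++nfree; }
  }
  if (nfree > 0) b = bsum / nfree;
}

// Fit linear SVM on raw features; returns list(w, b, alpha) for cross-checks.
// [[Rcpp::export(name = ".cpp_svm_fit")]]
List cpp_svm_fit(const arma::mat &X, const arma::vec &y, double C) {
  arma::mat K = X * X.t();
  arma::vec alpha; double b = 0;
  smo_solve(K, y, C, alpha, b);
  arma::vec w = X.t() * (alpha % y);
  return List::create(_["w"] = w, _["b"] = b, _["alpha"] = alpha);
}

// column mean/sd (denominator n-1) over selected rows
static void col_stats(const arma::mat &X, const arma::uvec &rows,
                      arma::rowvec &mu, arma::rowvec &sd) {
  arma::mat sub = X.rows(rows);
  mu = arma::mean(sub, 0);
  sd = arma::stddev(sub, 0, 0); // norm_type 0 -> n-1
  sd.for_each([](double &v) { if (v < 1e-12) v = 1.0; });
}

// Train a fold and return the equivalent raw-space linear readout (w2, b2)
// so that decision = X_raw * w2 + b2, absorbing optional z-scoring.
static void fit_fold(const arma::mat &F, const arma::uvec &train, const arma::vec &ytr,
                     double C, bool standardize, arma::vec &w2, double &b2) {
  arma::mat Z = F.rows(train);
  arma::rowvec mu, sd;
  if (standardize) {
    col_stats(F, train, mu, sd);
    Z.each_row() -= mu;
    Z.each_row() /= sd;
  }
  arma::mat K = Z * Z.t();
  arma::vec alpha; double b = 0;
  smo_solve(K, ytr, C, alpha, b);
  arma::vec w = Z.t() * (alpha % ytr);
  if (standardize) {
    w2 = w / sd.t();
    b2 = b - arma::dot(w2, mu.t());
  } else {
    w2 = w;
    b2 = b;
  }
}

// Leave-one-pseudo-trial-per-class-out CV accuracy on one feature block.
// P: (2S) x d, rows 1..S are class +1, rows S+1..2S are class -1.
// [[Rcpp::export(name = ".cpp_cv_accuracy")]]
double cpp_cv_accuracy(const arma::mat &P, double C, bool standardize) {
  int S = P.n_rows / 2;
  int correct = 0;
  for (int k = 0; k < S; ++k) {
    arma::uvec train(2 * S - 2);
    arma::vec ytr(2 * S - 2);
    int idx = 0;
    for (int r = 0; r < 2 * S; ++r) {
      if (r == k || r == S + k) continue;
      train[idx] = r;
      ytr[idx] = (r < S) ? 1.0 : -1.0;
      ++idx;
    }
    arma::vec w2; double b2;
    fit_fold(P, train, ytr, C, standardize, w2, b2);
    double f1 = arma::dot(P.row(k), w2) + b2;
    double f2 = arma::dot(P.row(S + k), w2) + b2;
    if (f1 >= 0) ++correct;
    if (f2 < 0) ++correct;
  }
  return (double)correct / (2.0 * S);
}

// Temporal generalization: F is (2S) x (nt*d) with the d features of time
// block t in columns [t*d, (t+1)*d). Returns nt x nt accuracy matrix
// (rows: training time, cols: testing time).
// [[Rcpp::export(name = ".cpp_tgm")]]
arma::mat cpp_tgm(const arma::mat &F, int nt, double C, bool standardize) {
  int S = F.n_rows / 2;
  int d = F.n_cols / nt;
  arma::mat acc(nt, nt, arma::fill::zeros);
  for (int ti = 0; ti < nt; ++ti) {
    arma::mat Fi = F.cols(ti * d, (ti + 1) * d - 1);
    for (int k = 0; k < S; ++k) {
      arma::uvec train(2 * S - 2);
      arma::vec ytr(2 * S - 2);
      int idx = 0;
      for (int r = 0; r < 2 * S; ++r) {
        if (r == k || r == S + k) continue;
        train[idx] = r; ytr[idx] = (r < S) ? 1.0 : -1.0; ++idx;
      }
      arma::vec w2; double b2;
      fit_fold(Fi, train, ytr, C, standardize, w2, b2);
      for (int tj = 0; tj < nt; ++tj) {
        double f1 = arma::dot(F.submat(k, tj * d, k, (tj + 1) * d - 1), w2) + b2;
        double f2 = arma::dot(F.submat(S + k, tj * d, S + k, (tj + 1) * d - 1), w2) + b2;
        if (f1 >= 0) acc(ti, tj) += 1.0;
        if (f2 < 0) acc(ti, tj) += 1.0;
      }
    }
  }
  return acc / (2.0 * S);
}

// 4-connected component labelling of a logical matrix (row-major grid).
// [[Rcpp::export(name = ".cpp_label_2d")]]
IntegerMatrix cpp_label_2d(const LogicalMatrix &mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int cur = 0;
  std::vector<std::pair<int, int> > stack;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++cur;
      stack.push_back(std::make_pair(r0, c0));
      lab(r0, c0) = cur;
      while (!stack.empty()) {
        int r = stack.back().first, c = stack.back().second;
        stack.pop_back();
        const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
        for (int q = 0; q < 4; ++q) {
          int rr = r + dr[q], cc = c + dc[q];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = cur;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Maximum 4-connected cluster size of a logical matrix (permutation nulls).
// [[Rcpp::export(name = ".cpp_max_cluster_2d")]]
int cpp_max_cluster_2d(const LogicalMatrix &mask) {
  IntegerMatrix lab = cpp_label_2d(mask);
  int mx = 0;
  std::map<int, int> cnt;
  for (int i = 0; i < lab.length(); ++i)
    if (lab[i] > 0) ++cnt[lab[i]];
  for (std::map<int, int>::iterator it = cnt.begin(); it != cnt.end(); ++it)
    if (it->second > mx) mx = it->second;
  return mx;
}
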