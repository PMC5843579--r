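#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Euclidean distances from one query row to every training row.
static void query_distances(const NumericMatrix &X, const NumericVector &q,
                            std::vector<double> &d) {
  const int n = X.nrow(), p = X.ncol();
  for (int i = 0; i < n; ++i) d[i] = 0.0;
  for (int j = 0; j < p; ++j) {
    const double qj = q[j];
    for (int i = 0; i < n; ++i) {
      const double diff = X(i, j) - qj;
      d[i] += diff * diff;
    }
  }
  for (int i = 0; i < n; ++i) d[i] = std::sqrt(d[i]);
}

// Indices 0..n-1 stably sorted by distance: ties keep training-set order.
static void stable_order(const std::vector<double> &d, std::vector<int> &ord) {
  const int n = (int)d.size();
  ord.resize(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&d](int a, int b) { return d[a] < d[b]; });
}

static double weight_of(double d, int scheme, double eps) {
  switch (scheme) {
  case 2: return 1.0 / (1.0 + d);          // Shepard
  case 3: return std::exp(-d);             // exponential
  default: return 1.0 / std::max(d, eps);  // inverse distance
  }
}

// Weighted-mean prediction from the first k entries of ord; exact-match rule:
// any zero-distance neighbour short-circuits to the mean of zero-distance responses.
static double predict_one(const NumericVector &y, const std::vector<double> &d,
                          const std::vector<int> &ord, int k, int scheme,
                          double eps) {
  int nzero = 0;
  double zsum = 0.0;
  for (int r = 0; r < k; ++r) {
    if (d[ord[r]] == 0.0) { ++nzero; zsum += y[ord[r]]; }
  }
  if (nzero > 0) return zsum / nzero;
  double sw = 0.0, swy = 0.0;
  for (int r = 0; r < k; ++r) {
    const double w = weight_of(d[ord[r]], scheme, eps);
    sw += w;
    swy += w * y[ord[r]];
  }
  return swy / sw;
}

// Majority by summed weight; ties broken by the smallest class index.
static int classify_one(const IntegerVector &y, int nclass,
                        const std::vector<double> &d,
                        const std::vector<int> &ord, int k, int scheme,
                        double eps) {
  std::vector<double> score(nclass, 0.0);
  int nzero = 0;
  for (int r = 0; r < k; ++r) {
    if (d[ord[r]] == 0.0) { ++nzero; score[y[ord[r]] - 1] += 1.0; }
  }
  if (nzero == 0) {
    for (int r = 0; r < k; ++r) {
      score[y[ord[r]] - 1] += weight_of(d[ord[r]], scheme, eps);
    }
  }
  int best = 0;
  for (int c = 1; c < nclass; ++c) if (score[c] > score[best]) best = c;
  return best + 1;
}

// [[Rcpp::export]]
List cpp_knn_neighbors(NumericMatrix Xtr, NumericMatrix Xq, int k) {
  const int m = Xq.nrow(), n = Xtr.nrow();
  if (k < 1 || k > n) stop("k must be between 1 and the number of training rows");
  IntegerMatrix idx(m, k);
  NumericMatrix dist(m, k);
  std::vector<double> d(n);
  std::vector<int> ord;
  for (int q = 0; q < m; ++q) {
    query_distances(Xtr, Xq(q, _), d);
    stable_order(d, ord);
    for (int r = 0; r < k; ++r) {
      idx(q, r) = ord[r] + 1;
      dist(q, r) = d[ord[r]];
    }
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// [[Rcpp::export]]
NumericVector cpp_wknn_predict(NumericMatrix Xtr, NumericVector y,
                               NumericMatrix Xq, int k, int scheme,
                               double eps) {
  const int m = Xq.nrow(), n = Xtr.nrow();
  if (k < 1 || k > n) stop("k must be between 1 and the number of training rows");
  NumericVector out(m);
  std::vector<double> d(n);
  std::vector<int> ord;
  for (int q = 0; q < m; ++q) {
    query_distances(Xtr, Xq(q, _), d);
    stable_order(d, ord);
    out[q] = predict_one(y, d, ord, k, scheme, eps);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_wknn_classify(NumericMatrix Xtr, IntegerVector y, int nclass,
                                NumericMatrix Xq, int k, int scheme,
                                double eps) {
  const int m = Xq.nrow(), n = Xtr.nrow();
  if (k < 1 || k > n) stop("k must be between 1 and the number of training rows");
  IntegerVector out(m);
  std::vector<double> d(n);
  std::vector<int> ord;
  for (int q = 0; q < m; ++q) {
    query_distances(Xtr, Xq(q, _), d);
    stable_order(d, ord);
    out[q] = classify_one(y, nclass, d, ord, k, scheme, eps);
  }
  return out;
}

// Predictions for several k values from a single neighbour sort per query.
// [[Rcpp::export]]
NumericMatrix cpp_wknn_predict_multi(NumericMatrix Xtr, NumericVector y,
                                     NumericMatrix Xq, IntegerVector ks,
                                     int scheme, double eps) {
  const int m = Xq.nrow(), n = Xtr.nrow(), nk = ks.size();
  NumericMatrix out(m, nk);
  std::vector<double> d(n);
  std::vector<int> ord;
  for (int q = 0; q < m; ++q) {
    query_distances(Xtr, Xq(q, _), d);
    stable_order(d, ord);
    for (int j = 0; j < nk; ++j) {
      const int k = std::min(ks[j], n);
      out(q, j) = predict_one(y, d, ord, k, scheme, eps);
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_wknn_classify_multi(NumericMatrix Xtr, IntegerVector y,
                                      int nclass, NumericMatrix Xq,
                                      IntegerVector ks, int scheme,
                                      double eps) {
  const int m = Xq.nrow(), n = Xtr.nrow(), nk = ks.size();
  IntegerMatrix out(m, nk);
  std::vector<double> d(n);
  std::vector<int> ord;
  for (int q = 0; q < m; ++q) {
    query_distances(Xtr, Xq(q, _), d);
    stable_order(d, ord);
    for (int j = 0; j < nk; ++j) {
      const int k = std::min(ks[j], n);
      out(q, j) = classify_one(y, nclass, d, ord, k, scheme, eps);
    }
  }
  return out;
}

// Leave-one-out predictions on the training set itself.
// [[Rcpp::export]]
NumericVector cpp_loo_predict(NumericMatrix X, NumericVector y, int k,
                              int scheme, double eps) {
  const int n = X.nrow();
  if (k > n - 1) stop("k must be at most n - 1 for leave-one-out");
  NumericVector out(n);
  std::vector<double> d(n);
  std::vector<int> ord, keep;
  for (int i = 0; i < n; ++i) {
    query_distances(X, X(i, _), d);
    stable_order(d, ord);
    keep.clear();
    for (int r = 0; r < (int)ord.size() && (int)keep.size() < k; ++r) {
      if (ord[r] != i) keep.push_back(ord[r]);
    }
    out[i] = predict_one(y, d, keep, k, scheme, eps);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_loo_classify(NumericMatrix X, IntegerVector y, int nclass,
                               int k, int scheme, double eps) {
  const int n = X.nrow();
  if (k > n - 1) stop("k must be at most n - 1 for leave-one-out");
  IntegerVector out(n);
  std::vector<double> d(n);
  std::vector<int> ord, keep;
  for (int i = 0; i < n; ++i) {
    query_distances(X, X(i, _), d);
    stable_order(d, ord);
    keep.clear();
    for (int r = 0; r < (int)ord.size() && (int)keep.size() < k; ++r) {
      if (ord[r] != i) keep.push_back(ord[r]);
    }
    out[i] = classify_one(y, nclass, d, keep, k, scheme, eps);
  }
  return out;
}

// Pooled out-of-fold predictions for every k in ks, one column per k.
// fold is 1-based fold membership; each fold is predicted from the rest.
// [[Rcpp::export]]
NumericMatrix cpp_cv_predict(NumericMatrix X, NumericVector y,
                             IntegerVector fold, IntegerVector ks, int scheme,
                             double eps) {
  const int n = X.nrow(), p = X.ncol(), nk = ks.size();
  int nfold = 0;
  for (int i = 0; i < n; ++i) nfold = std::max(nfold, fold[i]);
  NumericMatrix out(n, nk);
  std::vector<double> d;
  std::vector<int> ord;
  for (int f = 1; f <= nfold; ++f) {
    std::vector<int> tr, te;
    for (int i = 0; i < n; ++i) (fold[i] == f ? te : tr).push_back(i);
    if (te.empty()) continue;
    const int ntr = (int)tr.size();
    NumericMatrix Xtr(ntr, p);
    NumericVector ytr(ntr);
    for (int i = 0; i < ntr; ++i) {
      ytr[i] = y[tr[i]];
      for (int j = 0; j < p; ++j) Xtr(i, j) = X(tr[i], j);
    }
    d.resize(ntr);
    for (size_t qi = 0; qi < te.size(); ++qi) {
      query_distances(Xtr, X(te[qi], _), d);
      stable_order(d, ord);
      for (int j = 0; j < nk; ++j) {
        const int k = std::min(ks[j], ntr);
        out(te[qi], j) = predict_one(ytr, d, ord, k, scheme, eps);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_cv_classify(NumericMatrix X, IntegerVector y, int nclass,
                              IntegerVector fold, IntegerVector ks, int scheme,
                              double eps) {
  const int n = X.nrow(), p = X.ncol(), nk = ks.size();
  int nfold = 0;
  for (int i = 0; i < n; ++i) nfold = std::max(nfold, fold[i]);
  IntegerMatrix out(n, nk);
  std::vector<double> d;
  std::vector<int> ord;
  for (int f = 1; f <= nfold; ++f) {
    std::vector<int> tr, te;
    for (int i = 0; i < n; ++i) (fold[i] == f ? te : tr).push_back(i);
    if (te.empty()) continue;
    const int ntr = (int)tr.size();
    NumericMatrix Xtr(ntr, p);
    IntegerVector ytr(ntr);
    for (int i = 0; i < ntr; ++i) {
      ytr[i] = y[tr[i]];
      for (int j = 0; j < p; ++j) Xtr(i, j) = X(tr[i], j);
    }
    d.resize(ntr);
    for (size_t qi = 0; qi < te.size(); ++qi) {
      query_distances(Xtr, X(te[qi], _), d);
      stable_order(d, ord);
      for (int j = 0; j < nk; ++j) {
        const int k = std::min(ks[j], ntr);
        out(te[qi], j) = classify_one(ytr, nclass, d, ord, k, scheme, eps);
      }
    }
  }
  return out;
}
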