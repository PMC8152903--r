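#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Deterministic SMO solver for the C-SVC dual with a precomputed kernel.
// Maximal-violating-pair working-set selection; Platt-style pair update.
// K is row-major n x n, y in {+1,-1}. Fills alpha and the bias b.
static void smo_solve(const std::vector<double>& K, const std::vector<int>& y,
                      int n, double C, std::vector<double>& alpha, double& b) {
  const double tol = 1e-6, eps = 1e-12;
  std::vector<double> u(n, 0.0); // u_i = sum_j alpha_j y_j K_ij
  std::fill(alpha.begin(), alpha.end(), 0.0);
  double m_val = 0.0, M_val = 0.0;
  for (int iter = 0; iter < 5000; ++iter) {
    int i = -1, j = -1;
    m_val = -HUGE_VAL; M_val = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      double v = y[t] - u[t];
      bool up = (y[t] > 0 && alpha[t] < C - eps) || (y[t] < 0 && alpha[t] > eps);
      bool lo = (y[t] > 0 && alpha[t] > eps) || (y[t] < 0 && alpha[t] < C - eps);
      if (up && v > m_val) { m_val = v; i = t; }
      if (lo && v < M_val) { M_val = v; j = t; }
    }
    if (i < 0 || j < 0 || m_val - M_val < tol) break;
    double s = (double)y[i] * y[j];
    double L, H;
    if (s < 0) { L = std::max(0.0, alpha[j] - alpha[i]); H = std::min(C, C + alpha[j] - alpha[i]); }
    else       { L = std::max(0.0, alpha[i] + alpha[j] - C); H = std::min(C, alpha[i] + alpha[j]); }
    if (H - L < eps) break;
    double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j], Kij = K[(size_t)i * n + j];
    double eta = Kii + Kjj - 2.0 * Kij;
    double Ei = u[i] - y[i], Ej = u[j] - y[j];
    double aj;
    if (eta > eps) aj = alpha[j] + y[j] * (Ei - Ej) / eta;
    else aj = (y[j] * (Ei - Ej) > 0) ? H : L;
    if (aj > H) aj = H; else if (aj < L) aj = L;
    double daj = aj - alpha[j];
    if (std::fabs(daj) < 1e-14) break;
    double dai = -s * daj;
    alpha[i] += dai; alpha[j] = aj;
    for (int t = 0; t < n; ++t)
      u[t] += dai * y[i] * K[(size_t)i * n + t] + daj * y[j] * K[(size_t)j * n + t];
  }
  // bias: average over free support vectors, else midpoint of the KKT interval
  double acc = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > eps && alpha[t] < C - eps) { acc += y[t] - u[t]; ++nfree; }
  if (nfree > 0) b = acc / nfree;
  else b = (m_val == -HUGE_VAL || M_val == HUGE_VAL) ? 0.0 : 0.5 * (m_val + M_val);
}

// Train one-vs-rest linear SVMs on standardized features and return, for each
// class, the primal weight vector and bias. X row-major nTr x nCh (already
// standardized). cls 1-based class per row.
static void ecoc_fit(const std::vector<double>& X, const std::vector<int>& cls,
                     int nTr, int nCh, int nClasses, double C,
                     std::vector<double>& W, std::vector<double>& B) {
  // Gram
  std::vector<double> K((size_t)nTr * nTr);
  for (int a = 0; a < nTr; ++a)
    for (int bb = a; bb < nTr; ++bb) {
      double d = 0.0;
      const double* xa = &X[(size_t)a * nCh];
      const double* xb = &X[(size_t)bb * nCh];
      for (int c = 0; c < nCh; ++c) d += xa[c] * xb[c];
      K[(size_t)a * nTr + bb] = d; K[(size_t)bb * nTr + a] = d;
    }
  std::vector<int> y(nTr);
  std::vector<double> alpha(nTr);
  for (int cl = 1; cl <= nClasses; ++cl) {
    for (int t = 0; t < nTr; ++t) y[t] = (cls[t] == cl) ? 1 : -1;
    double b = 0.0;
    smo_solve(K, y, nTr, C, alpha, b);
    double* w = &W[(size_t)(cl - 1) * nCh];
    for (int c = 0; c < nCh; ++c) w[c] = 0.0;
    for (int t = 0; t < nTr; ++t) {
      double ay = alpha[t] * y[t];
      if (ay == 0.0) continue;
      const double* xt = &X[(size_t)t * nCh];
      for (int c = 0; c < nCh; ++c) w[c] += ay * xt[c];
    }
    B[cl - 1] = b;
  }
}

// Predicted class for one standardized test vector under one-vs-rest coding
// with average binary hinge loss; ties broken by the lowest class code.
static int ecoc_predict_one(const double* x, const std::vector<double>& W,
                            const std::vector<double>& B, int nCh, int nClasses) {
  std::vector<double> f(nClasses);
  for (int cl = 0; cl < nClasses; ++cl) {
    double d = B[cl];
    const double* w = &W[(size_t)cl * nCh];
    for (int c = 0; c < nCh; ++c) d += w[c] * x[c];
    f[cl] = d;
  }
  int best = 0; double bestLoss = HUGE_VAL;
  for (int cl = 0; cl < nClasses; ++cl) {
    double loss = 0.0;
    for (int j = 0; j < nClasses; ++j) {
      double m = (j == cl) ? 1.0 : -1.0;
      double h = 1.0 - m * f[j];
      if (h > 0) loss += 0.5 * h;
    }
    if (loss < bestLoss - 1e-12) { bestLoss = loss; best = cl; }
  }
  return best + 1;
}

// Extract rows (1-based idx) of the time-t slice of M (nRows x nCh x nT,
// column-major R array) into out (row-major nSel x nCh).
static void slice_rows(const NumericVector& M, int nRows, int nCh, int t,
                       const IntegerVector& idx, std::vector<double>& out) {
  int nSel = idx.size();
  for (int r = 0; r < nSel; ++r) {
    int row = idx[r] - 1;
    for (int c = 0; c < nCh; ++c)
      out[(size_t)r * nCh + c] = M[(size_t)row + (size_t)nRows * (c + (size_t)nCh * t)];
  }
}

// Column means/sds (denominator n-1; zero sd replaced by 1) of row-major X.
static void col_stats(const std::vector<double>& X, int nR, int nCh,
                      std::vector<double>& mu, std::vector<double>& sd) {
  for (int c = 0; c < nCh; ++c) { mu[c] = 0.0; sd[c] = 0.0; }
  for (int r = 0; r < nR; ++r)
    for (int c = 0; c < nCh; ++c) mu[c] += X[(size_t)r * nCh + c];
  for (int c = 0; c < nCh; ++c) mu[c] /= nR;
  for (int r = 0; r < nR; ++r)
    for (int c = 0; c < nCh; ++c) {
      double d = X[(size_t)r * nCh + c] - mu[c];
      sd[c] += d * d;
    }
  for (int c = 0; c < nCh; ++c) {
    sd[c] = (nR > 1) ? std::sqrt(sd[c] / (nR - 1)) : 0.0;
    if (sd[c] <= 0.0) sd[c] = 1.0;
  }
}

static void standardize(std::vector<double>& X, int nR, int nCh,
                        const std::vector<double>& mu, const std::vector<double>& sd) {
  for (int r = 0; r < nR; ++r)
    for (int c = 0; c < nCh; ++c) {
      size_t k = (size_t)r * nCh + c;
      X[k] = (X[k] - mu[c]) / sd[c];
    }
}

// [[Rcpp::export(name = ".ecocSeriesCpp")]]
IntegerMatrix ecocSeriesCpp(NumericVector M, IntegerVector dims,
                            IntegerVector trainIdx, IntegerVector trainCls,
                            IntegerVector testIdx, int nClasses,
                            double cost, bool standardizeFeatures) {
  int nRows = dims[0], nCh = dims[1], nT = dims[2];
  int nTr = trainIdx.size(), nTe = testIdx.size();
  IntegerMatrix pred(nTe, nT);
  std::vector<double> Xtr((size_t)nTr * nCh), Xte((size_t)nTe * nCh);
  std::vector<double> mu(nCh), sd(nCh);
  std::vector<double> W((size_t)nClasses * nCh), B(nClasses);
  std::vector<int> cls(trainCls.begin(), trainCls.end());
  for (int t = 0; t < nT; ++t) {
    slice_rows(M, nRows, nCh, t, trainIdx, Xtr);
    slice_rows(M, nRows, nCh, t, testIdx, Xte);
    if (standardizeFeatures) {
      col_stats(Xtr, nTr, nCh, mu, sd);
      standardize(Xtr, nTr, nCh, mu, sd);
      standardize(Xte, nTe, nCh, mu, sd);
    }
    ecoc_fit(Xtr, cls, nTr, nCh, nClasses, cost, W, B);
    for (int r = 0; r < nTe; ++r)
      pred(r, t) = ecoc_predict_one(&Xte[(size_t)r * nCh], W, B, nCh, nClasses);
  }
  return pred;
}

// Cross-time variant: train at every time index, test every (row, time).
// Returns an nTe x nT x nT integer array: [test row, test time, train time].
// [[Rcpp::export(name = ".ecocCrossCpp")]]
IntegerVector ecocCrossCpp(NumericVector M, IntegerVector dims,
                           IntegerVector trainIdx, IntegerVector trainCls,
                           IntegerVector testIdx, int nClasses,
                           double cost, bool standardizeFeatures) {
  int nRows = dims[0], nCh = dims[1], nT = dims[2];
  int nTr = trainIdx.size(), nTe = testIdx.size();
  IntegerVector pred((R_xlen_t)nTe * nT * nT);
  pred.attr("dim") = IntegerVector::create(nTe, nT, nT);
  std::vector<double> Xtr((size_t)nTr * nCh), Xte((size_t)nTe * nCh);
  std::vector<double> mu(nCh), sd(nCh);
  std::vector<double> W((size_t)nClasses * nCh), B(nClasses);
  std::vector<int> cls(trainCls.begin(), trainCls.end());
  for (int tr = 0; tr < nT; ++tr) {
    slice_rows(M, nRows, nCh, tr, trainIdx, Xtr);
    if (standardizeFeatures) {
      col_stats(Xtr, nTr, nCh, mu, sd);
      standardize(Xtr, nTr, nCh, mu, sd);
    }
    ecoc_fit(Xtr, cls, nTr, nCh, nClasses, cost, W, B);
    for (int te = 0; te < nT; ++te) {
      slice_rows(M, nRows, nCh, te, testIdx, Xte);
      if (standardizeFeatures) standardize(Xte, nTe, nCh, mu, sd);
      for (int r = 0; r < nTe; ++r)
        pred[(R_xlen_t)r + (R_xlen_t)nTe * (te + (R_xlen_t)nT * tr)] =
          ecoc_predict_one(&Xte[(size_t)r * nCh], W, B, nCh, nClasses);
    }
  }
  return pred;
}

// Decision values of the one-vs-rest learners for test rows at a single time
// index; used by unit tests to compare against an independent SVM
// implementation. Returns nTe x nClasses.
// [[Rcpp::export(name = ".ecocDecisionCpp")]]
NumericMatrix ecocDecisionCpp(NumericVector M, IntegerVector dims,
                              IntegerVector trainIdx, IntegerVector trainCls,
                              IntegerVector testIdx, int nClasses,
                              double cost, bool standardizeFeatures) {
  int nRows = dims[0], nCh = dims[1];
  int nTr = trainIdx.size(), nTe = testIdx.size();
  std::vector<double> Xtr((size_t)nTr * nCh), Xte((size_t)nTe * nCh);
  std::vector<double> mu(nCh), sd(nCh);
  std::vector<double> W((size_t)nClasses * nCh), B(nClasses);
  std::vector<int> cls(trainCls.begin(), trainCls.end());
  slice_rows(M, nRows, nCh, 0, trainIdx, Xtr);
  slice_rows(M, nRows, nCh, 0, testIdx, Xte);
  if (standardizeFeatures) {
    col_stats(Xtr, nTr, nCh, mu, sd);
    standardize(Xtr, nTr, nCh, mu, sd);
    standardize(Xte, nTe, nCh, mu, sd);
  }
  ecoc_fit(Xtr, cls, nTr, nCh, nClasses, cost, W, B);
  NumericMatrix out(nTe, nClasses);
  for (int r = 0; r < nTe; ++r)
    for (int cl = 0; cl < nClasses; ++cl) {
      double d = B[cl];
      const double* w = &W[(size_t)cl * nCh];
      const double* x = &Xte[(size_t)r * nCh];
      for (int c = 0; c < nCh; ++c) d += w[c] * x[c];
      out(r, cl) = d;
    }
  return out;
}
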