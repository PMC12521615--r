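#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Hot loops use raw pointers and a residue-major copy of the coefficient
// tables (ct[code * w + j]) so window scoring is a tight strided gather.

static inline void transpose_coeffs(const NumericMatrix& C,
                                    std::vector<double>& ct) {
  const int w = C.nrow(), A = C.ncol();
  ct.resize((size_t)w * A);
  for (int a = 0; a < A; ++a)
    for (int j = 0; j < w; ++j) ct[(size_t)a * w + j] = C(j, a);
}

// Offset sums of both binding modes for integer-coded sequences (1-based
// residue codes). ext: N x (L + 2f) flank-extended codes for the specific
// mode; pep: N x L codes for the non-specific mode.
// [[Rcpp::export]]
List kappa_parts_cpp(const IntegerMatrix& ext, const IntegerMatrix& pep,
                     const NumericMatrix& Cs, const NumericMatrix& Cns,
                     const NumericVector& gamma) {
  const int N = ext.nrow(), next = ext.ncol(), npep = pep.ncol();
  const int ws = Cs.nrow(), wns = Cns.nrow();
  const int noffS = next - ws + 1, noffN = npep - wns + 1;
  std::vector<double> cs, cns;
  transpose_coeffs(Cs, cs);
  transpose_coeffs(Cns, cns);
  const int* extp = INTEGER(ext);
  const int* pepp = INTEGER(pep);
  const double* gam = REAL(gamma);
  NumericVector spec(N), nonspec(N);
  std::vector<int> row(next);
  for (int i = 0; i < N; ++i) {
    for (int c = 0; c < next; ++c) row[c] = extp[(size_t)c * N + i] - 1;
    double b = 0.0;
    for (int x = 0; x < noffS; ++x) {
      double sc = 0.0;
      for (int j = 0; j < ws; ++j) sc += cs[(size_t)row[x + j] * ws + j];
      b += std::exp(sc);
    }
    spec[i] = b;
    for (int c = 0; c < npep; ++c) row[c] = pepp[(size_t)c * N + i] - 1;
    double a = 0.0;
    for (int x = 0; x < noffN; ++x) {
      double sc = gam[x];
      for (int j = 0; j < wns; ++j) sc += cns[(size_t)row[x + j] * wns + j];
      a += std::exp(sc);
    }
    nonspec[i] = a;
  }
  return List::create(_["specific"] = spec, _["nonspecific"] = nonspec);
}

// Minimized loss contribution of one count table (negative scaled binomial
// log-likelihood plus, when dirw > 0, the Dirichlet pseudo-count term with
// weight dirw = dirichlet_count / n_unique) and its gradient with respect to
// the mode coefficients, the position bias and the three per-table scalars
// (log activities and depth log-ratio).
// [[Rcpp::export]]
List table_loss_grad_cpp(const IntegerMatrix& ext, const IntegerMatrix& pep,
                         const NumericVector& kI, const NumericVector& kB,
                         const NumericMatrix& Cs, const NumericMatrix& Cns,
                         const NumericVector& gamma,
                         double log_ans, double log_as, double log_rho,
                         double kc, double dirw) {
  const int N = ext.nrow(), next = ext.ncol(), npep = pep.ncol();
  const int ws = Cs.nrow(), A = Cs.ncol();
  const int wns = Cns.nrow();
  const int noffS = next - ws + 1, noffN = npep - wns + 1;
  const double aS = std::exp(log_as), aNS = std::exp(log_ans);
  const double rho = std::exp(log_rho);

  std::vector<double> cs, cns;
  transpose_coeffs(Cs, cs);
  transpose_coeffs(Cns, cns);
  std::vector<double> gcs((size_t)ws * A, 0.0), gcns((size_t)wns * A, 0.0);
  const int* extp = INTEGER(ext);
  const int* pepp = INTEGER(pep);
  const double* gam = REAL(gamma);
  const double* kIp = REAL(kI);
  const double* kBp = REAL(kB);

  NumericVector gGamma(noffN);
  double* gGam = REAL(gGamma);
  double gAs = 0.0, gAns = 0.0, gRho = 0.0, loss = 0.0;
  std::vector<double> eS(noffS), eN(noffN);
  std::vector<int> rowE(next), rowP(npep);

  for (int i = 0; i < N; ++i) {
    for (int c = 0; c < next; ++c) rowE[c] = extp[(size_t)c * N + i] - 1;
    for (int c = 0; c < npep; ++c) rowP[c] = pepp[(size_t)c * N + i] - 1;
    double bsum = 0.0, asum = 0.0;
    for (int x = 0; x < noffS; ++x) {
      double sc = 0.0;
      for (int j = 0; j < ws; ++j) sc += cs[(size_t)rowE[x + j] * ws + j];
      eS[x] = std::exp(sc);
      bsum += eS[x];
    }
    for (int x = 0; x < noffN; ++x) {
      double sc = gam[x];
      for (int j = 0; j < wns; ++j) sc += cns[(size_t)rowP[x + j] * wns + j];
      eN[x] = std::exp(sc);
      asum += eN[x];
    }
    double kap = aNS * asum + aS * bsum;
    if (kap < 1e-300) kap = 1e-300;
    const double t = rho * kap;
    const double sig = t / (1.0 + t);
    const double l1pt = std::log1p(t);
    const double lt = std::log(t);
    const double ki = kIp[i], kb = kBp[i];
    loss += -(kb * (lt - l1pt) - ki * l1pt) / kc;
    double u = -(kb - (ki + kb) * sig) / kc;
    if (dirw > 0.0) {
      loss += dirw * (2.0 * l1pt - lt);
      u += dirw * (2.0 * sig - 1.0);
    }
    gRho += u;
    const double wS = u * aS / kap;
    const double wN = u * aNS / kap;
    gAs += wS * bsum;
    gAns += wN * asum;
    for (int x = 0; x < noffS; ++x) {
      const double wwx = wS * eS[x];
      for (int j = 0; j < ws; ++j) gcs[(size_t)rowE[x + j] * ws + j] += wwx;
    }
    for (int x = 0; x < noffN; ++x) {
      const double wwx = wN * eN[x];
      gGam[x] += wwx;
      for (int j = 0; j < wns; ++j)
        gcns[(size_t)rowP[x + j] * wns + j] += wwx;
    }
  }
  NumericMatrix gCs(ws, A), gCns(wns, A);
  for (int a = 0; a < A; ++a) {
    for (int j = 0; j < ws; ++j) gCs(j, a) = gcs[(size_t)a * ws + j];
    for (int j = 0; j < wns; ++j) gCns(j, a) = gcns[(size_t)a * wns + j];
  }
  return List::create(_["value"] = loss,
                      _["grad_specific"] = gCs,
                      _["grad_nonspecific"] = gCns,
                      _["grad_gamma"] = gGamma,
                      _["grad_log_alpha_ns"] = gAns,
                      _["grad_log_alpha_s"] = gAs,
                      _["grad_depth_log_ratio"] = gRho);
}
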