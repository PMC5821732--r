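#include <Rcpp.h>
using namespace Rcpp;

// Batched valid cross-correlation.
// A: (H, W, C, B) column-major, Wt: (f, f, C, K), b: length K.
// Returns Z: (Ho, Wo, K, B) with Ho = H-f+1, Wo = W-f+1.
// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector A, NumericVector Wt, NumericVector b) {
  IntegerVector dA = A.attr("dim");
  IntegerVector dW = Wt.attr("dim");
  const int H = dA[0], W = dA[1], C = dA[2], B = dA[3];
  const int f = dW[0], K = dW[3];
  const int Ho = H - f + 1, Wo = W - f + 1;
  NumericVector Z(static_cast<R_xlen_t>(Ho) * Wo * K * B);
  const double *a = A.begin(), *w = Wt.begin();
  double *z = Z.begin();

  for (int n = 0; n < B; ++n) {
    for (int k = 0; k < K; ++k) {
      double *zs = z + (static_cast<R_xlen_t>(n) * K + k) * Ho * Wo;
      const double bk = b[k];
      for (int i = 0; i < Ho * Wo; ++i) zs[i] = bk;
      for (int c = 0; c < C; ++c) {
        const double *as = a + (static_cast<R_xlen_t>(n) * C + c) * H * W;
        const double *ws = w + (static_cast<R_xlen_t>(k) * C + c) * f * f;
        for (int v = 0; v < f; ++v) {
          for (int u = 0; u < f; ++u) {
            const double wv = ws[u + f * v];
            if (wv == 0.0) continue;
            for (int x = 0; x < Wo; ++x) {
              const double *acol = as + u + H * (x + v);
              double *zcol = zs + Ho * x;
              for (int y = 0; y < Ho; ++y) zcol[y] += wv * acol[y];
            }
          }
        }
      }
    }
  }
  Z.attr("dim") = IntegerVector::create(Ho, Wo, K, B);
  return Z;
}

// Gradients of the batched valid cross-correlation.
// Returns list(dA, dW, db) for upstream gradient dZ: (Ho, Wo, K, B).
// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector A, NumericVector Wt, NumericVector dZ) {
  IntegerVector dA_ = A.attr("dim");
  IntegerVector dW_ = Wt.attr("dim");
  const int H = dA_[0], W = dA_[1], C = dA_[2], B = dA_[3];
  const int f = dW_[0], K = dW_[3];
  const int Ho = H - f + 1, Wo = W - f + 1;

  NumericVector dA(A.size());
  NumericVector dW(Wt.size());
  NumericVector db(K);
  const double *a = A.begin(), *w = Wt.begin(), *dz = dZ.begin();
  double *da = dA.begin(), *dw = dW.begin();

  for (int n = 0; n < B; ++n) {
    for (int k = 0; k < K; ++k) {
      const double *dzs = dz + (static_cast<R_xlen_t>(n) * K + k) * Ho * Wo;
      double acc = 0.0;
      for (int i = 0; i < Ho * Wo; ++i) acc += dzs[i];
      db[k] += acc;
      for (int c = 0; c < C; ++c) {
        const double *as = a + (static_cast<R_xlen_t>(n) * C + c) * H * W;
        double *das = da + (static_cast<R_xlen_t>(n) * C + c) * H * W;
        const double *ws = w + (static_cast<R_xlen_t>(k) * C + c) * f * f;
        double *dws = dw + (static_cast<R_xlen_t>(k) * C + c) * f * f;
        for (int v = 0; v < f; ++v) {
          for (int u = 0; u < f; ++u) {
            const double wv = ws[u + f * v];
            double gw = 0.0;
            for (int x = 0; x < Wo; ++x) {
              const double *acol = as + u + H * (x + v);
              double *dacol = das + u + H * (x + v);
              const double *dzcol = dzs + Ho * x;
              for (int y = 0; y < Ho; ++y) {
                gw += acol[y] * dzcol[y];
                dacol[y] += wv * dzcol[y];
              }
            }
            dws[u + f * v] += gw;
          }
        }
      }
    }
  }
  dA.attr("dim") = dA_;
  dW.attr("dim") = dW_;
  return List::create(Named("dA") = dA, Named("dW") = dW, Named("db") = db);
}
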