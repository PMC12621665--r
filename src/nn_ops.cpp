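// Hot-path neural-network ops: im2col convolution and 2x2 max pooling on
// (H, W, C, N) column-major arrays. Backward passes recompute im2col /
// argmax from the cached layer input instead of storing large intermediates,
// which keeps the R heap small during training.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat im2col(const double* x, int H, int W, int C, int N,
                               int k, int s, int p, int Ho, int Wo) {
  arma::mat col(static_cast<size_t>(Ho) * Wo * N, static_cast<size_t>(k) * k * C,
                arma::fill::zeros);
  for (int dj = 0; dj < k; ++dj) {
    for (int di = 0; di < k; ++di) {
      for (int c = 0; c < C; ++c) {
        int q = (dj * k + di) * C + c;
        double* cp = col.colptr(q);
        for (int n = 0; n < N; ++n) {
          const double* xn = x + (static_cast<size_t>(n) * C + c) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = dj + s * wo - p;
            if (wi < 0 || wi >= W) continue;
            double* cpo = cp + static_cast<size_t>(Ho) * (wo + static_cast<size_t>(Wo) * n);
            const double* xcol = xn + static_cast<size_t>(wi) * H;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = di + s * ho - p;
              if (hi < 0 || hi >= H) continue;
              cpo[ho] = xcol[hi];
            }
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector cs_conv_forward(NumericVector x, NumericMatrix Wm,
                              NumericVector b, int k, int s, int p) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = (H + 2 * p - k) / s + 1, Wo = (W + 2 * p - k) / s + 1;
  int cout = Wm.ncol();
  arma::mat col = im2col(x.begin(), H, W, C, N, k, s, p, Ho, Wo);
  arma::mat Wa(Wm.begin(), Wm.nrow(), Wm.ncol(), false);
  arma::mat Y = col * Wa;
  Y.each_row() += arma::rowvec(b.begin(), b.size(), false);
  // rows of Y ordered (ho, wo, n); output array is (Ho, Wo, cout, N)
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);
  double* op = out.begin();
  size_t plane = static_cast<size_t>(Ho) * Wo;
  for (int co = 0; co < cout; ++co) {
    const double* yc = Y.colptr(co);
    for (int n = 0; n < N; ++n) {
      std::copy(yc + n * plane, yc + (n + 1) * plane,
                op + plane * (co + static_cast<size_t>(cout) * n));
    }
  }
  return out;
}

// [[Rcpp::export]]
List cs_conv_backward(NumericVector x, NumericMatrix Wm, NumericVector dout,
                      int k, int s, int p) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector dd = dout.attr("dim");
  int Ho = dd[0], Wo = dd[1], cout = dd[2];
  size_t plane = static_cast<size_t>(Ho) * Wo;
  // reorder dout (Ho,Wo,cout,N) -> matrix rows (ho,wo,n) x cout
  arma::mat dmat(plane * N, cout);
  for (int co = 0; co < cout; ++co) {
    double* dc = dmat.colptr(co);
    const double* dp = dout.begin();
    for (int n = 0; n < N; ++n) {
      std::copy(dp + plane * (co + static_cast<size_t>(cout) * n),
                dp + plane * (co + static_cast<size_t>(cout) * n) + plane,
                dc + n * plane);
    }
  }
  arma::mat col = im2col(x.begin(), H, W, C, N, k, s, p, Ho, Wo);
  arma::mat Wa(Wm.begin(), Wm.nrow(), Wm.ncol(), false);
  arma::mat dW = col.t() * dmat;
  arma::rowvec db = arma::sum(dmat, 0);
  arma::mat dcol = dmat * Wa.t();
  // scatter dcol back into dx (reverse of im2col, accumulating)
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  double* dxp = dx.begin();
  for (int dj = 0; dj < k; ++dj) {
    for (int di = 0; di < k; ++di) {
      for (int c = 0; c < C; ++c) {
        int q = (dj * k + di) * C + c;
        const double* cp = dcol.colptr(q);
        for (int n = 0; n < N; ++n) {
          double* xn = dxp + (static_cast<size_t>(n) * C + c) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = dj + s * wo - p;
            if (wi < 0 || wi >= W) continue;
            const double* cpo = cp + static_cast<size_t>(Ho) * (wo + static_cast<size_t>(Wo) * n);
            double* xcol = xn + static_cast<size_t>(wi) * H;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = di + s * ho - p;
              if (hi < 0 || hi >= H) continue;
              xcol[hi] += cpo[ho];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx,
                      _["W"] = NumericMatrix(Wm.nrow(), cout, dW.begin()),
                      _["b"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
NumericVector cs_maxpool2_forward(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* op = out.begin();
  size_t planes = static_cast<size_t>(C) * N;
  for (size_t cn = 0; cn < planes; ++cn) {
    const double* xi = xp + cn * H * W;
    double* oi = op + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const double* c0 = xi + static_cast<size_t>(2 * wo) * H;
      const double* c1 = c0 + H;
      for (int ho = 0; ho < Ho; ++ho) {
        double m = std::max(std::max(c0[2 * ho], c0[2 * ho + 1]),
                            std::max(c1[2 * ho], c1[2 * ho + 1]));
        oi[ho + static_cast<size_t>(Ho) * wo] = m;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cs_maxpool2_backward(NumericVector x, NumericVector dout) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  const double* xp = x.begin();
  const double* dp = dout.begin();
  double* gp = dx.begin();
  size_t planes = static_cast<size_t>(C) * N;
  for (size_t cn = 0; cn < planes; ++cn) {
    const double* xi = xp + cn * H * W;
    const double* di_ = dp + cn * Ho * Wo;
    double* gi = gp + cn * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        size_t i00 = static_cast<size_t>(2 * wo) * H + 2 * ho;      // (h, w)
        size_t i10 = i00 + 1;                                       // (h+1, w)
        size_t i01 = i00 + H;                                       // (h, w+1)
        size_t i11 = i01 + 1;
        // tie order matches the R reference: (h,w), (h+1,w), (h,w+1), (h+1,w+1)
        size_t best = i00;
        if (xi[i10] > xi[best]) best = i10;
        if (xi[i01] > xi[best]) best = i01;
        if (xi[i11] > xi[best]) best = i11;
        gi[best] += di_[ho + static_cast<size_t>(Ho) * wo];
      }
    }
  }
  return dx;
}
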