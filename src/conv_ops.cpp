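// Inner-loop primitives of the small CNN: im2col for 3x3 pad-1 convolution
// and 2x2 max-pooling. Activations are laid out (S, S, B, C) column-major.

#include <Rcpp.h>
using namespace Rcpp;

// im2col with implicit zero padding: x is an (S,S,B,C) array, the result has
// S*S*B rows ordered (row, col, batch) and 9*C columns ordered
// (offset-row, offset-col, channel), matching the R weight layout.
// [[Rcpp::export]]
NumericMatrix im2col3(const NumericVector& x, int S, int B, int C) {
  const int rows = S * S * B;
  NumericMatrix out(rows, 9 * C);
  const double* xp = x.begin();
  const R_xlen_t planeB = (R_xlen_t)S * S;        // one image plane
  const R_xlen_t planeC = planeB * B;             // one channel block
  for (int ch = 0; ch < C; ++ch) {
    for (int oc = -1; oc <= 1; ++oc) {
      for (int orr = -1; orr <= 1; ++orr) {
        const int col_idx = (orr + 1) + 3 * (oc + 1) + 9 * ch;
        double* op = &out(0, col_idx);
        for (int b = 0; b < B; ++b) {
          const double* xb = xp + ch * planeC + b * planeB;
          for (int c = 0; c < S; ++c) {
            const int sc = c + oc;
            const R_xlen_t out_base = (R_xlen_t)b * planeB + (R_xlen_t)c * S;
            if (sc < 0 || sc >= S) {
              for (int r = 0; r < S; ++r) op[out_base + r] = 0.0;
            } else {
              const double* src = xb + (R_xlen_t)sc * S;
              const int r0 = (orr < 0) ? 1 : 0;
              const int r1 = (orr > 0) ? S - 1 : S;
              if (orr < 0) op[out_base] = 0.0;
              if (orr > 0) op[out_base + S - 1] = 0.0;
              for (int r = r0; r < r1; ++r) op[out_base + r] = src[r + orr];
            }
          }
        }
      }
    }
  }
  return out;
}

// 2x2 stride-2 max-pooling over (S,S,B,F); returns the pooled array and the
// 1-based winner index (1..4 for the (r,c) offsets (0,0),(1,0),(0,1),(1,1)),
// first match winning under ties.
// [[Rcpp::export]]
List maxpool2(const NumericVector& x, int S, int B, int F) {
  const int S2 = S / 2;
  const R_xlen_t n_out = (R_xlen_t)S2 * S2 * B * F;
  NumericVector out(n_out);
  IntegerVector which(n_out);
  const double* xp = x.begin();
  double* op = out.begin();
  int* wp = which.begin();
  const R_xlen_t n_img = (R_xlen_t)B * F;
  for (R_xlen_t i = 0; i < n_img; ++i) {
    const double* xi = xp + i * S * S;
    double* oi = op + i * S2 * S2;
    int* wi = wp + i * S2 * S2;
    for (int c = 0; c < S2; ++c) {
      for (int r = 0; r < S2; ++r) {
        const double a1 = xi[(2 * c) * S + 2 * r];          // (0,0)
        const double a2 = xi[(2 * c) * S + 2 * r + 1];      // (1,0)
        const double a3 = xi[(2 * c + 1) * S + 2 * r];      // (0,1)
        const double a4 = xi[(2 * c + 1) * S + 2 * r + 1];  // (1,1)
        double m = a1; int w = 1;
        if (a2 > m) { m = a2; w = 2; }
        if (a3 > m) { m = a3; w = 3; }
        if (a4 > m) { m = a4; w = 4; }
        oi[c * S2 + r] = m;
        wi[c * S2 + r] = w;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(S2, S2, B, F);
  return List::create(_["out"] = out, _["which"] = which);
}

// scatter the pooled gradient back through the recorded winners
// [[Rcpp::export]]
NumericVector maxpool2_backward(const NumericVector& dout,
                                const IntegerVector& which,
                                int S, int B, int F) {
  const int S2 = S / 2;
  NumericVector dx((R_xlen_t)S * S * B * F);
  const double* dp = dout.begin();
  const int* wp = which.begin();
  double* xp = dx.begin();
  const R_xlen_t n_img = (R_xlen_t)B * F;
  for (R_xlen_t i = 0; i < n_img; ++i) {
    const double* di = dp + i * S2 * S2;
    const int* wi = wp + i * S2 * S2;
    double* xi = xp + i * S * S;
    for (int c = 0; c < S2; ++c) {
      for (int r = 0; r < S2; ++r) {
        const int w = wi[c * S2 + r];
        const int rr = 2 * r + ((w == 2 || w == 4) ? 1 : 0);
        const int cc = 2 * c + ((w >= 3) ? 1 : 0);
        xi[cc * S + rr] = di[c * S2 + r];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(S, S, B, F);
  return dx;
}
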