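#include <Rcpp.h>
using namespace Rcpp;

// Scatter-add an im2col gradient matrix back onto the padded input.
// dxcol: (kh*kw*C) x (oh*ow*N), rows ordered (dh fastest, dw, c),
// columns ordered (oi fastest, oj, n). Returns (ph, pw, C, N) array.
// [[Rcpp::export]]
NumericVector cpp_col2im(const NumericMatrix& dxcol,
                         int kh, int kw, int C,
                         int oh, int ow, int N,
                         int ph, int pw, int stride) {
  NumericVector dxp(static_cast<R_xlen_t>(ph) * pw * C * N);
  double* out = REAL(dxp);
  const double* in = &dxcol(0, 0);
  const int R = kh * kw * C;
  const R_xlen_t plane = static_cast<R_xlen_t>(ph) * pw;
  R_xlen_t col = 0;
  for (int n = 0; n < N; ++n) {
    const R_xlen_t n_off = static_cast<R_xlen_t>(n) * plane * C;
    for (int oj = 0; oj < ow; ++oj) {
      const int base_col = oj * stride;
      for (int oi = 0; oi < oh; ++oi, ++col) {
        const int base_row = oi * stride;
        const double* v = in + col * R;
        for (int c = 0; c < C; ++c) {
          double* o = out + n_off + c * plane + base_col * ph + base_row;
          for (int dw = 0; dw < kw; ++dw) {
            double* oc = o + static_cast<R_xlen_t>(dw) * ph;
            for (int dh = 0; dh < kh; ++dh)
              oc[dh] += *v++;
          }
        }
      }
    }
  }
  dxp.attr("dim") = IntegerVector::create(ph, pw, C, N);
  return dxp;
}

// Max pooling over im2col columns: values and 1-based argmax row.
// xcol: R x M. Returns list(max = numeric(M), which = integer(M)).
// [[Rcpp::export]]
List cpp_colmax(const NumericMatrix& xcol) {
  const int R = xcol.nrow();
  const R_xlen_t M = xcol.ncol();
  NumericVector mx(M);
  IntegerVector wh(M);
  const double* in = &xcol(0, 0);
  for (R_xlen_t j = 0; j < M; ++j) {
    const double* colj = in + j * R;
    double best = colj[0];
    int bi = 0;
    for (int r = 1; r < R; ++r)
      if (colj[r] > best) { best = colj[r]; bi = r; }
    mx[j] = best;
    wh[j] = bi + 1;
  }
  return List::create(_["max"] = mx, _["which"] = wh);
}

// Scatter-add dy values onto flat positions (duplicates accumulate).
// [[Rcpp::export]]
NumericVector cpp_scatter_add(R_xlen_t size, const IntegerVector& pos,
                              const NumericVector& val) {
  NumericVector out(size);
  double* o = REAL(out);
  const R_xlen_t n = pos.size();
  for (R_xlen_t i = 0; i < n; ++i)
    o[pos[i] - 1] += val[i];
  return out;
}
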