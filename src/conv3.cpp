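// Vectorized 3x3x3 "same" convolution primitives for small 3D volumes.
// Layout: x is an (n1, n2, n3, C) array stored column-major (axis 1 fastest),
// viewed as a (V x C) matrix with V = n1*n2*n3. A conv is the sum over the 27
// kernel offsets of a zero-padded shift of x times a (Cin x Cout) weight slab.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// copy y(p) = x(p + d) with zero padding outside, all channels at once
static void shifted_copy(const double* x, double* y,
                         int n1, int n2, int n3, int C,
                         int d1, int d2, int d3) {
  const long V = (long)n1 * n2 * n3;
  std::fill(y, y + V * C, 0.0);
  int i1lo = std::max(0, -d1), i1hi = std::min(n1, n1 - d1);
  int i2lo = std::max(0, -d2), i2hi = std::min(n2, n2 - d2);
  int i3lo = std::max(0, -d3), i3hi = std::min(n3, n3 - d3);
  if (i1lo >= i1hi || i2lo >= i2hi || i3lo >= i3hi) return;
  const long run = i1hi - i1lo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (long)c * V;
    double* yc = y + (long)c * V;
    for (int i3 = i3lo; i3 < i3hi; ++i3) {
      for (int i2 = i2lo; i2 < i2hi; ++i2) {
        long dst = i1lo + (long)n1 * (i2 + (long)n2 * i3);
        long src = (i1lo + d1) + (long)n1 * ((i2 + d2) + (long)n2 * (i3 + d3));
        std::copy(xc + src, xc + src + run, yc + dst);
      }
    }
  }
}

static void get_dims(const Rcpp::NumericVector& x, int dims[4]) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 4) Rcpp::stop("expected a 4-d array (n1,n2,n3,C)");
  for (int i = 0; i < 4; ++i) dims[i] = d[i];
}

// [[Rcpp::export]]
Rcpp::NumericVector conv3_fwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                              Rcpp::NumericVector bias) {
  int dx[4]; get_dims(x, dx);
  const int n1 = dx[0], n2 = dx[1], n3 = dx[2], Cin = dx[3];
  const long V = (long)n1 * n2 * n3;
  Rcpp::IntegerVector dw = w.attr("dim");
  if (dw.size() != 5 || dw[0] != 3 || dw[1] != 3 || dw[2] != 3 || dw[3] != Cin)
    Rcpp::stop("weight array must be (3,3,3,Cin,Cout)");
  const int Cout = dw[4];
  if (bias.size() != Cout) Rcpp::stop("bias length must equal Cout");

  mat out(V, Cout);
  for (int c = 0; c < Cout; ++c) out.col(c).fill(bias[c]);
  std::vector<double> buf(V * Cin);
  const mat Xs(&buf[0], V, Cin, false, true);
  for (int o = 0; o < 27; ++o) {
    int d1 = o % 3 - 1, d2 = (o / 3) % 3 - 1, d3 = o / 9 - 1;
    shifted_copy(x.begin(), &buf[0], n1, n2, n3, Cin, d1, d2, d3);
    // weight slab for offset (d1,d2,d3): w[d1+1, d2+1, d3+1, , ]
    mat W(Cin, Cout);
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        W(ci, co) = w[(d1 + 1) + 3 * ((d2 + 1) + 3 * ((d3 + 1) + 3 * (ci + (long)Cin * co)))];
    out += Xs * W;
  }
  Rcpp::NumericVector res(out.begin(), out.end());
  res.attr("dim") = Rcpp::IntegerVector::create(n1, n2, n3, Cout);
  return res;
}

// [[Rcpp::export]]
Rcpp::NumericVector conv3_bwd_input(Rcpp::NumericVector gy, Rcpp::NumericVector w) {
  int dg[4]; get_dims(gy, dg);
  const int n1 = dg[0], n2 = dg[1], n3 = dg[2], Cout = dg[3];
  const long V = (long)n1 * n2 * n3;
  Rcpp::IntegerVector dw = w.attr("dim");
  if (dw.size() != 5 || dw[4] != Cout) Rcpp::stop("weight/grad channel mismatch");
  const int Cin = dw[3];

  mat gx(V, Cin, fill::zeros);
  std::vector<double> buf(V * Cout);
  const mat Gs(&buf[0], V, Cout, false, true);
  for (int o = 0; o < 27; ++o) {
    int d1 = o % 3 - 1, d2 = (o / 3) % 3 - 1, d3 = o / 9 - 1;
    // dx(p) = sum_d gy(p - d) W_d^T
    shifted_copy(gy.begin(), &buf[0], n1, n2, n3, Cout, -d1, -d2, -d3);
    mat W(Cin, Cout);
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        W(ci, co) = w[(d1 + 1) + 3 * ((d2 + 1) + 3 * ((d3 + 1) + 3 * (ci + (long)Cin * co)))];
    gx += Gs * W.t();
  }
  Rcpp::NumericVector res(gx.begin(), gx.end());
  res.attr("dim") = Rcpp::IntegerVector::create(n1, n2, n3, Cin);
  return res;
}

// [[Rcpp::export]]
Rcpp::List conv3_bwd_weights(Rcpp::NumericVector x, Rcpp::NumericVector gy) {
  int dx[4]; get_dims(x, dx);
  int dg[4]; get_dims(gy, dg);
  const int n1 = dx[0], n2 = dx[1], n3 = dx[2], Cin = dx[3], Cout = dg[3];
  const long V = (long)n1 * n2 * n3;
  if (dg[0] != n1 || dg[1] != n2 || dg[2] != n3) Rcpp::stop("shape mismatch");

  const mat Gy(const_cast<double*>(gy.begin()), V, Cout, false, true);
  Rcpp::NumericVector gw(3 * 3 * 3 * (long)Cin * Cout);
  gw.attr("dim") = Rcpp::IntegerVector::create(3, 3, 3, Cin, Cout);
  std::vector<double> buf(V * Cin);
  const mat Xs(&buf[0], V, Cin, false, true);
  for (int o = 0; o < 27; ++o) {
    int d1 = o % 3 - 1, d2 = (o / 3) % 3 - 1, d3 = o / 9 - 1;
    shifted_copy(x.begin(), &buf[0], n1, n2, n3, Cin, d1, d2, d3);
    mat GW = Xs.t() * Gy;  // Cin x Cout
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        gw[(d1 + 1) + 3 * ((d2 + 1) + 3 * ((d3 + 1) + 3 * (ci + (long)Cin * co)))] = GW(ci, co);
  }
  rowvec gb = sum(Gy, 0);
  return Rcpp::List::create(Rcpp::Named("w") = gw,
                            Rcpp::Named("b") = Rcpp::NumericVector(gb.begin(), gb.end()));
}
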