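// Batched valid cross-correlation and max-pooling primitives used by the
// network layers. Layout conventions (column-major, matching R arrays):
//   1-D activations: cube (time, channels, batch)
//   1-D weights:     mat  (out_channels, in_channels * kernel), patch index
//                    (c, j) flattened as c*k + j
//   2-D activations: flat vector with dims (H, W, C, B)
//   2-D weights:     mat  (out_channels, C*kh*kw), patch index (c, kj, ki)
//                    flattened as c*kh*kw + kj*kh + ki
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline void im2col1d(const mat& xs, int k, int stride, mat& col) {
  const int Cin = xs.n_cols, Tout = col.n_cols;
  for (int t = 0; t < Tout; ++t) {
    const int off = t * stride;
    for (int c = 0; c < Cin; ++c)
      col.col(t).subvec(c * k, c * k + k - 1) = xs.col(c).subvec(off, off + k - 1);
  }
}

// [[Rcpp::export]]
arma::cube conv1d_fwd(const arma::cube& x, const arma::mat& w, int stride) {
  const int T = x.n_rows, Cin = x.n_cols, B = x.n_slices;
  const int k = w.n_cols / Cin;
  const int Tout = (T - k) / stride + 1;
  cube y(Tout, w.n_rows, B);
  mat col(w.n_cols, Tout);
  for (int b = 0; b < B; ++b) {
    im2col1d(x.slice(b), k, stride, col);
    y.slice(b) = (w * col).t();
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd(const arma::cube& x, const arma::mat& w,
                      const arma::cube& gy, int stride) {
  const int T = x.n_rows, Cin = x.n_cols, B = x.n_slices;
  const int k = w.n_cols / Cin;
  const int Tout = gy.n_rows;
  cube gx(T, Cin, B, fill::zeros);
  mat gw(w.n_rows, w.n_cols, fill::zeros);
  mat col(w.n_cols, Tout);
  for (int b = 0; b < B; ++b) {
    im2col1d(x.slice(b), k, stride, col);
    mat gym = gy.slice(b).t();          // Cout x Tout
    gw += gym * col.t();
    mat gcol = w.t() * gym;             // (Cin*k) x Tout
    mat& gxs = gx.slice(b);
    for (int t = 0; t < Tout; ++t) {
      const int off = t * stride;
      for (int c = 0; c < Cin; ++c)
        gxs.col(c).subvec(off, off + k - 1) += gcol.col(t).subvec(c * k, c * k + k - 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw);
}

// [[Rcpp::export]]
Rcpp::List maxpool1d_fwd(const arma::cube& x, int pool) {
  const int T = x.n_rows, C = x.n_cols, B = x.n_slices;
  const int Tout = T / pool;
  cube y(Tout, C, B);
  icube idx(Tout, C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < Tout; ++t) {
        uword rel;
        y(t, c, b) = x.slice(b).col(c).subvec(t * pool, t * pool + pool - 1).max(rel);
        idx(t, c, b) = t * pool + (int)rel;
      }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool1d_bwd(const arma::icube& idx, const arma::cube& gy, int T) {
  const int Tout = gy.n_rows, C = gy.n_cols, B = gy.n_slices;
  cube gx(T, C, B, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < Tout; ++t)
        gx(idx(t, c, b), c, b) += gy(t, c, b);
  return gx;
}

static inline void im2col2d(const cube& xs, int kh, int kw, int sh, int sw,
                            int Ho, int Wo, mat& col) {
  const int C = xs.n_slices;
  int t = 0;
  for (int jo = 0; jo < Wo; ++jo)
    for (int io = 0; io < Ho; ++io, ++t)
      for (int c = 0; c < C; ++c)
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i)
            col(c * kh * kw + j * kh + i, t) = xs(io * sh + i, jo * sw + j, c);
}

// [[Rcpp::export]]
Rcpp::NumericVector conv2d_fwd(Rcpp::NumericVector x4, const arma::mat& w,
                               int kh, int kw, int sh, int sw) {
  Rcpp::IntegerVector d = x4.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const int Ho = (H - kh) / sh + 1, Wo = (W - kw) / sw + 1, Cout = w.n_rows;
  Rcpp::NumericVector out(Ho * Wo * Cout * B);
  out.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, Cout, B);
  mat col(w.n_cols, Ho * Wo);
  for (int b = 0; b < B; ++b) {
    const cube xs(const_cast<double*>(x4.begin()) + (size_t)b * H * W * C,
                  H, W, C, false, true);
    im2col2d(xs, kh, kw, sh, sw, Ho, Wo, col);
    mat ym = w * col;                   // Cout x (Ho*Wo)
    cube ys(out.begin() + (size_t)b * Ho * Wo * Cout, Ho, Wo, Cout, false, true);
    for (int o = 0; o < Cout; ++o)
      ys.slice(o) = reshape(ym.row(o), Ho, Wo);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(Rcpp::NumericVector x4, const arma::mat& w,
                      Rcpp::NumericVector gy4, int kh, int kw, int sh, int sw) {
  Rcpp::IntegerVector d = x4.attr("dim"), dg = gy4.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const int Ho = dg[0], Wo = dg[1], Cout = dg[2];
  Rcpp::NumericVector gx(x4.size());
  gx.attr("dim") = d;
  mat gw(w.n_rows, w.n_cols, fill::zeros);
  mat col(w.n_cols, Ho * Wo), gym(Cout, Ho * Wo);
  for (int b = 0; b < B; ++b) {
    const cube xs(const_cast<double*>(x4.begin()) + (size_t)b * H * W * C,
                  H, W, C, false, true);
    im2col2d(xs, kh, kw, sh, sw, Ho, Wo, col);
    const cube gys(const_cast<double*>(gy4.begin()) + (size_t)b * Ho * Wo * Cout,
                   Ho, Wo, Cout, false, true);
    for (int o = 0; o < Cout; ++o)
      gym.row(o) = vectorise(gys.slice(o)).t();
    gw += gym * col.t();
    mat gcol = w.t() * gym;
    cube gxs(gx.begin() + (size_t)b * H * W * C, H, W, C, false, true);
    int t = 0;
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io, ++t)
        for (int c = 0; c < C; ++c)
          for (int j = 0; j < kw; ++j)
            for (int i = 0; i < kh; ++i)
              gxs(io * sh + i, jo * sw + j, c) += gcol(c * kh * kw + j * kh + i, t);
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw);
}

// [[Rcpp::export]]
Rcpp::List maxpool2d_fwd(Rcpp::NumericVector x4, int ph, int pw) {
  Rcpp::IntegerVector d = x4.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const int Ho = H / ph, Wo = W / pw;
  Rcpp::NumericVector out(Ho * Wo * C * B);
  out.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, C, B);
  Rcpp::IntegerVector idx(Ho * Wo * C * B);  // linear index into H*W plane
  for (int b = 0; b < B; ++b) {
    const cube xs(const_cast<double*>(x4.begin()) + (size_t)b * H * W * C,
                  H, W, C, false, true);
    cube ys(out.begin() + (size_t)b * Ho * Wo * C, Ho, Wo, C, false, true);
    for (int c = 0; c < C; ++c)
      for (int jo = 0; jo < Wo; ++jo)
        for (int io = 0; io < Ho; ++io) {
          double best = -datum::inf;
          int besti = 0;
          for (int j = 0; j < pw; ++j)
            for (int i = 0; i < ph; ++i) {
              const double v = xs(io * ph + i, jo * pw + j, c);
              if (v > best) { best = v; besti = (jo * pw + j) * H + io * ph + i; }
            }
          ys(io, jo, c) = best;
          idx[(size_t)b * Ho * Wo * C + (size_t)c * Ho * Wo + jo * Ho + io] = besti;
        }
  }
  return Rcpp::List::create(Rcpp::Named("y") = out, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
Rcpp::NumericVector maxpool2d_bwd(Rcpp::IntegerVector idx, Rcpp::NumericVector gy4,
                                  int H, int W) {
  Rcpp::IntegerVector d = gy4.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], B = d[3];
  Rcpp::NumericVector gx((size_t)H * W * C * B);
  gx.attr("dim") = Rcpp::IntegerVector::create(H, W, C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int jo = 0; jo < Wo; ++jo)
        for (int io = 0; io < Ho; ++io) {
          const size_t oflat = (size_t)b * Ho * Wo * C + (size_t)c * Ho * Wo + jo * Ho + io;
          gx[(size_t)b * H * W * C + (size_t)c * H * W + idx[oflat]] += gy4[oflat];
        }
  return gx;
}
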