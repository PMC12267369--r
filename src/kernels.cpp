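// Dense numeric kernels for the segmentation network.
//
// Feature maps are R arrays of dim c(H, W, C); column-major layout matches
// arma::cube(H, W, C). Convolution weights are arrays of dim c(k, k, Cin,
// Cout), so the flattened weight matrix is (k*k*Cin) x Cout without any
// re-ordering. All convolutions are stride 1 with "same" zero padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::cube as_cube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array (H x W x C)");
  return arma::cube(const_cast<double*>(x.begin()), d[0], d[1], d[2], false);
}

static NumericVector wrap_cube(const arma::cube& c) {
  NumericVector out(c.begin(), c.end());
  out.attr("dim") = IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return out;
}

// im2col: column j = flattened k x k x Cin patch centred on output pixel j
// (pixels in R column-major order), rows ordered dh + k*dw + k*k*c.
static arma::mat im2col(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  arma::mat cols(k * k * C, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int row = dh + k * dw + k * k * c;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw - pad;
          if (sw < 0 || sw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int sh = h + dh - pad;
            if (sh < 0 || sh >= H) continue;
            cols(row, h + H * w) = x(sh, sw, c);
          }
        }
      }
    }
  }
  return cols;
}

// scatter-add of column gradients back onto the input image (adjoint of im2col)
static arma::cube col2im(const arma::mat& cols, int H, int W, int C, int k) {
  const int pad = (k - 1) / 2;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int row = dh + k * dw + k * k * c;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw - pad;
          if (sw < 0 || sw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int sh = h + dh - pad;
            if (sh < 0 || sh >= H) continue;
            dx(sh, sw, c) += cols(row, h + H * w);
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".cpp_conv2d_fw")]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  arma::cube xc = as_cube(x);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must be k x k x Cin x Cout");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("square kernels only");
  if ((int)xc.n_slices != Cin) stop("input channel mismatch");
  const int H = xc.n_rows, W = xc.n_cols;
  arma::mat wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false);
  arma::mat out;
  if (k == 1) {
    arma::mat xm(xc.memptr(), H * W, Cin, false);
    out = xm * wm;                       // (HW x Cout)
  } else {
    out = im2col(xc, k).t() * wm;
  }
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false);
  out.each_row() += bv;
  arma::cube oc(out.memptr(), H, W, Cout);
  return wrap_cube(oc);
}

// [[Rcpp::export(name = ".cpp_conv2d_bw")]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gout) {
  arma::cube xc = as_cube(x);
  arma::cube gc = as_cube(gout);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int H = xc.n_rows, W = xc.n_cols;
  arma::mat wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false);
  arma::mat gm(gc.memptr(), H * W, Cout, false); // HW x Cout
  NumericVector dw_out(k * k * Cin * Cout);
  arma::mat dwm(dw_out.begin(), k * k * Cin, Cout, false);
  arma::cube dx;
  if (k == 1) {
    arma::mat xm(xc.memptr(), H * W, Cin, false);
    dwm = xm.t() * gm;
    arma::mat dxm = gm * wm.t();         // HW x Cin
    dx = arma::cube(dxm.memptr(), H, W, Cin);
  } else {
    arma::mat cols = im2col(xc, k);      // KKC x HW
    dwm = cols * gm;
    arma::mat dcols = wm * gm.t();       // KKC x HW
    dx = col2im(dcols, H, W, Cin, k);
  }
  arma::vec db = arma::sum(gm, 0).t();
  dw_out.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  return List::create(_["dx"] = wrap_cube(dx), _["dw"] = dw_out,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 non-overlapping max pooling; idx stores, per output element, the
// 0-based linear offset of the argmax within the input cube (for backward).
// [[Rcpp::export(name = ".cpp_maxpool2_fw")]]
List cpp_maxpool2_fw(NumericVector x) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  if (H % 2 || W % 2) stop("spatial dims must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  arma::cube out(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        double best = -std::numeric_limits<double>::infinity();
        int bi = 0;
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh) {
            const int sh = 2 * h + dh, sw = 2 * w + dw;
            double v = xc(sh, sw, c);
            if (v > best) { best = v; bi = sh + H * (sw + (long)W * c); }
          }
        out(h, w, c) = best;
        idx[h + Ho * (w + (long)Wo * c)] = bi;
      }
  return List::create(_["out"] = wrap_cube(out), _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bw")]]
NumericVector cpp_maxpool2_bw(IntegerVector idx, NumericVector gout,
                              int H, int W, int C) {
  NumericVector dx(H * W * C);
  for (int i = 0; i < gout.size(); ++i) dx[idx[i]] += gout[i];
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// Bilinear 2x upsampling with half-pixel centre alignment:
// source coordinate = (dest + 0.5)/2 - 0.5, clamped to the image.
static inline void lin_coef(int d, int n, int& i0, int& i1, double& a) {
  double s = (d + 0.5) / 2.0 - 0.5;
  if (s < 0) s = 0;
  if (s > n - 1) s = n - 1;
  i0 = (int)std::floor(s);
  i1 = std::min(i0 + 1, n - 1);
  a = s - i0;
}

// [[Rcpp::export(name = ".cpp_upsample2_fw")]]
NumericVector cpp_upsample2_fw(NumericVector x) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  arma::cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < 2 * W; ++w) {
      int w0, w1; double aw;
      lin_coef(w, W, w0, w1, aw);
      for (int h = 0; h < 2 * H; ++h) {
        int h0, h1; double ah;
        lin_coef(h, H, h0, h1, ah);
        out(h, w, c) = (1 - ah) * (1 - aw) * xc(h0, w0, c)
                     + ah * (1 - aw) * xc(h1, w0, c)
                     + (1 - ah) * aw * xc(h0, w1, c)
                     + ah * aw * xc(h1, w1, c);
      }
    }
  return wrap_cube(out);
}

// [[Rcpp::export(name = ".cpp_upsample2_bw")]]
NumericVector cpp_upsample2_bw(NumericVector gout, int H, int W, int C) {
  arma::cube gc = as_cube(gout);
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < 2 * W; ++w) {
      int w0, w1; double aw;
      lin_coef(w, W, w0, w1, aw);
      for (int h = 0; h < 2 * H; ++h) {
        int h0, h1; double ah;
        lin_coef(h, H, h0, h1, ah);
        const double g = gc(h, w, c);
        dx(h0, w0, c) += (1 - ah) * (1 - aw) * g;
        dx(h1, w0, c) += ah * (1 - aw) * g;
        dx(h0, w1, c) += (1 - ah) * aw * g;
        dx(h1, w1, c) += ah * aw * g;
      }
    }
  return wrap_cube(dx);
}
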