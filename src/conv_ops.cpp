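// 3x3 "same" convolution kernels for the 2D U-Net base learners.
// Arrays are column-major with layout (H, W, N, C); weights are (3, 3, Cin, Cout).
// These two hot loops dominate training time; everything else in the network
// is vectorised R.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector conv3x3_fwd_cpp(NumericVector x, NumericVector W, NumericVector b,
                              int H, int Wd, int N, int Cin, int Cout) {
  NumericVector y(static_cast<R_xlen_t>(H) * Wd * N * Cout);
  const double* xp = x.begin();
  const double* wp = W.begin();
  double* yp = y.begin();
  const R_xlen_t plane = static_cast<R_xlen_t>(H) * Wd * N;
  for (int co = 0; co < Cout; ++co) {
    double bc = b[co];
    double* yc = yp + co * plane;
    for (R_xlen_t t = 0; t < plane; ++t) yc[t] = bc;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + ci * plane;
      for (int dx = 0; dx < 3; ++dx) {
        for (int dy = 0; dy < 3; ++dy) {
          double w = wp[dy + 3 * dx + 9 * ci + 9 * Cin * co];
          if (w == 0.0) continue;
          int oy = dy - 1, ox = dx - 1;
          int i0 = std::max(0, -oy), i1 = std::min(H, H - oy);
          int j0 = std::max(0, -ox), j1 = std::min(Wd, Wd - ox);
          for (int n = 0; n < N; ++n) {
            for (int j = j0; j < j1; ++j) {
              const double* xs = xc + (static_cast<R_xlen_t>(n) * Wd + (j + ox)) * H + oy;
              double* ys = yc + (static_cast<R_xlen_t>(n) * Wd + j) * H;
              for (int i = i0; i < i1; ++i) ys[i] += w * xs[i];
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3x3_bwd_cpp(NumericVector dy_, NumericVector x, NumericVector W,
                     int H, int Wd, int N, int Cin, int Cout) {
  NumericVector dx_(static_cast<R_xlen_t>(H) * Wd * N * Cin);
  NumericVector dW(9 * Cin * Cout);
  NumericVector db(Cout);
  const double* gp = dy_.begin();
  const double* xp = x.begin();
  const double* wp = W.begin();
  double* dxp = dx_.begin();
  double* dWp = dW.begin();
  const R_xlen_t plane = static_cast<R_xlen_t>(H) * Wd * N;
  for (int co = 0; co < Cout; ++co) {
    const double* gc = gp + co * plane;
    double s = 0.0;
    for (R_xlen_t t = 0; t < plane; ++t) s += gc[t];
    db[co] = s;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + ci * plane;
      double* dxc = dxp + ci * plane;
      for (int dx = 0; dx < 3; ++dx) {
        for (int dy = 0; dy < 3; ++dy) {
          double w = wp[dy + 3 * dx + 9 * ci + 9 * Cin * co];
          int oy = dy - 1, ox = dx - 1;
          int i0 = std::max(0, -oy), i1 = std::min(H, H - oy);
          int j0 = std::max(0, -ox), j1 = std::min(Wd, Wd - ox);
          double acc = 0.0;
          for (int n = 0; n < N; ++n) {
            for (int j = j0; j < j1; ++j) {
              const double* xs = xc + (static_cast<R_xlen_t>(n) * Wd + (j + ox)) * H + oy;
              const double* gs = gc + (static_cast<R_xlen_t>(n) * Wd + j) * H;
              double* dxs = dxc + (static_cast<R_xlen_t>(n) * Wd + (j + ox)) * H + oy;
              for (int i = i0; i < i1; ++i) {
                acc += xs[i] * gs[i];
                dxs[i] += w * gs[i];
              }
            }
          }
          dWp[dy + 3 * dx + 9 * ci + 9 * Cin * co] = acc;
        }
      }
    }
  }
  return List::create(_["dx"] = dx_, _["dW"] = dW, _["db"] = db);
}

// y[, j] = a[j] * x[, j] + b[j]  (x treated as an (m x C) matrix)
// [[Rcpp::export]]
NumericVector col_affine_cpp(NumericVector x, NumericVector a, NumericVector b) {
  int C = a.size();
  R_xlen_t m = x.size() / C;
  NumericVector y(x.size());
  const double* xp = x.begin(); double* yp = y.begin();
  for (int j = 0; j < C; ++j) {
    double aj = a[j], bj = b[j];
    const double* xc = xp + j * m; double* yc = yp + j * m;
    for (R_xlen_t i = 0; i < m; ++i) yc[i] = aj * xc[i] + bj;
  }
  return y;
}

// y[, j] = a[j] * A[, j] + b[j] * B[, j] + c[j]
// [[Rcpp::export]]
NumericVector col_lincomb_cpp(NumericVector A, NumericVector B,
                              NumericVector a, NumericVector b, NumericVector c) {
  int C = a.size();
  R_xlen_t m = A.size() / C;
  NumericVector y(A.size());
  const double* Ap = A.begin(); const double* Bp = B.begin(); double* yp = y.begin();
  for (int j = 0; j < C; ++j) {
    double aj = a[j], bj = b[j], cj = c[j];
    const double* Ac = Ap + j * m; const double* Bc = Bp + j * m;
    double* yc = yp + j * m;
    for (R_xlen_t i = 0; i < m; ++i) yc[i] = aj * Ac[i] + bj * Bc[i] + cj;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin(); double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector dy, NumericVector out) {
  NumericVector dx(dy.size());
  const double* gp = dy.begin(); const double* op = out.begin();
  double* dp = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) dp[i] = op[i] > 0 ? gp[i] : 0.0;
  return dx;
}

// 2x2 stride-2 max pool on (H, W, N, C); returns pooled values and the
// winning quadrant (0..3) per output element.
// [[Rcpp::export]]
List maxpool2_cpp(NumericVector x, int H, int Wd, int NC) {
  int Ho = H / 2, Wo = Wd / 2;
  R_xlen_t n_out = static_cast<R_xlen_t>(Ho) * Wo * NC;
  NumericVector y(n_out);
  IntegerVector arg(n_out);
  const double* xp = x.begin(); double* yp = y.begin(); int* ap = arg.begin();
  for (int s = 0; s < NC; ++s) {
    const double* xs = xp + static_cast<R_xlen_t>(s) * H * Wd;
    double* ys = yp + static_cast<R_xlen_t>(s) * Ho * Wo;
    int* as = ap + static_cast<R_xlen_t>(s) * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      const double* c0 = xs + (2 * j) * H;
      const double* c1 = xs + (2 * j + 1) * H;
      double* yc = ys + j * Ho;
      int* ac = as + j * Ho;
      for (int i = 0; i < Ho; ++i) {
        double a = c0[2 * i], b = c0[2 * i + 1];
        double c = c1[2 * i], d = c1[2 * i + 1];
        double best = a; int which = 0;
        if (b > best) { best = b; which = 1; }
        if (c > best) { best = c; which = 2; }
        if (d > best) { best = d; which = 3; }
        yc[i] = best; ac[i] = which;
      }
    }
  }
  return List::create(_["out"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector arg,
                               int H, int Wd, int NC) {
  int Ho = H / 2, Wo = Wd / 2;
  NumericVector dx(static_cast<R_xlen_t>(H) * Wd * NC);
  const double* gp = dy.begin(); const int* ap = arg.begin();
  double* dp = dx.begin();
  for (int s = 0; s < NC; ++s) {
    const double* gs = gp + static_cast<R_xlen_t>(s) * Ho * Wo;
    const int* as = ap + static_cast<R_xlen_t>(s) * Ho * Wo;
    double* ds = dp + static_cast<R_xlen_t>(s) * H * Wd;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int which = as[j * Ho + i];
        int ii = 2 * i + (which & 1);
        int jj = 2 * j + (which >> 1);
        ds[jj * H + ii] = gs[j * Ho + i];
      }
    }
  }
  return dx;
}

// Affine warp of an image/mask slice pair about the slice centre:
// output(r,c) samples input at the inverse-transformed coordinates
// (bilinear for the image, nearest for the mask, zero fill outside).
// [[Rcpp::export]]
List warp_pair_cpp(NumericMatrix img, NumericMatrix msk,
                   double ct, double st, double inv_scale,
                   int flip_v, int flip_h) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix oi(nr, nc), om(nr, nc);
  double cy = (nr + 1) / 2.0, cx = (nc + 1) / 2.0;
  for (int c = 0; c < nc; ++c) {
    double cc0 = (c + 1) - cx;
    if (flip_h) cc0 = -cc0;
    for (int r = 0; r < nr; ++r) {
      double rr0 = (r + 1) - cy;
      if (flip_v) rr0 = -rr0;
      double sr = (rr0 * ct - cc0 * st) * inv_scale + cy;
      double sc = (rr0 * st + cc0 * ct) * inv_scale + cx;
      // bilinear (image)
      double v = 0.0;
      int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      double fr = sr - r0, fc = sc - c0;
      for (int dr = 0; dr <= 1; ++dr) {
        for (int dc = 0; dc <= 1; ++dc) {
          int ri = r0 + dr, ci = c0 + dc;
          if (ri >= 1 && ri <= nr && ci >= 1 && ci <= nc) {
            double w = (dr ? fr : 1 - fr) * (dc ? fc : 1 - fc);
            v += w * img(ri - 1, ci - 1);
          }
        }
      }
      oi(r, c) = v;
      // nearest (mask)
      int rn = (int)std::lround(sr), cn = (int)std::lround(sc);
      om(r, c) = (rn >= 1 && rn <= nr && cn >= 1 && cn <= nc)
        ? msk(rn - 1, cn - 1) : 0.0;
    }
  }
  return List::create(_["image"] = oi, _["mask"] = om);
}
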