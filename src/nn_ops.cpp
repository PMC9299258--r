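// Convolution / pooling kernels for the built-in network engine.
// Layout conventions (fixed across the package):
//   * images / feature maps: arma::cube H x W x C  (an R array dim c(H,W,C))
//   * conv weights: matrix Cout x (kh*kw*Cin); feature index
//     f = c*(kh*kw) + ky*kw + kx  (channel outermost)
//   * flattened output pixel index p = ox*OH + oy, i.e. column-major within
//     a slice, so a row of the GEMM result maps straight onto cube memory.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_size(int n, int k, int stride, int pad, int dil,
                                bool ceil_mode) {
  double eff = dil * (k - 1) + 1;
  double v = (n + 2.0 * pad - eff) / stride + 1.0;
  return ceil_mode ? (int)std::ceil(v) : (int)std::floor(v);
}

// Transposed im2col: colT is (OH*OW) x (kh*kw*C) so that, for stride 1,
// each (c,ky,kx) feature column is filled by contiguous memory copies.
static void im2colT(const arma::cube& x, arma::mat& colT, int kh, int kw,
                    int stride, int pad_h, int pad_w, int dil, int OH,
                    int OW) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  colT.zeros(OH * OW, kh * kw * C);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.slice_memptr(c);
    for (int ky = 0; ky < kh; ++ky) {
      const int oy_shift = ky * dil - pad_h;   // iy = oy*stride + oy_shift
      for (int kx = 0; kx < kw; ++kx) {
        const int f = c * kh * kw + ky * kw + kx;
        double* cf = colT.colptr(f);
        const int ox_shift = kx * dil - pad_w;
        for (int ox = 0; ox < OW; ++ox) {
          const int ix = ox * stride + ox_shift;
          if (ix < 0 || ix >= W) continue;
          if (stride == 1) {
            int oy0 = std::max(0, -oy_shift);
            int oy1 = std::min(OH - 1, H - 1 - oy_shift);
            if (oy1 < oy0) continue;
            std::memcpy(cf + (size_t)ox * OH + oy0,
                        xs + (size_t)ix * H + oy0 + oy_shift,
                        (size_t)(oy1 - oy0 + 1) * sizeof(double));
          } else {
            for (int oy = 0; oy < OH; ++oy) {
              const int iy = oy * stride + oy_shift;
              if (iy < 0 || iy >= H) continue;
              cf[(size_t)ox * OH + oy] = xs[(size_t)ix * H + iy];
            }
          }
        }
      }
    }
  }
}

// scatter-add of gcolT (same layout as colT) back onto the input gradient
static void col2imT(const arma::mat& gcolT, arma::cube& gx, int kh, int kw,
                    int stride, int pad_h, int pad_w, int dil, int OH,
                    int OW) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    double* gs = gx.slice_memptr(c);
    for (int ky = 0; ky < kh; ++ky) {
      const int oy_shift = ky * dil - pad_h;
      for (int kx = 0; kx < kw; ++kx) {
        const int f = c * kh * kw + ky * kw + kx;
        const double* cf = gcolT.colptr(f);
        const int ox_shift = kx * dil - pad_w;
        for (int ox = 0; ox < OW; ++ox) {
          const int ix = ox * stride + ox_shift;
          if (ix < 0 || ix >= W) continue;
          if (stride == 1) {
            int oy0 = std::max(0, -oy_shift);
            int oy1 = std::min(OH - 1, H - 1 - oy_shift);
            double* dst = gs + (size_t)ix * H + oy0 + oy_shift;
            const double* src = cf + (size_t)ox * OH + oy0;
            for (int t = 0; t <= oy1 - oy0; ++t) dst[t] += src[t];
          } else {
            for (int oy = 0; oy < OH; ++oy) {
              const int iy = oy * stride + oy_shift;
              if (iy < 0 || iy >= H) continue;
              gs[(size_t)ix * H + iy] += cf[(size_t)ox * OH + oy];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd")]]
arma::cube conv_fwd(const arma::cube& x, const arma::mat& w,
                    const arma::vec& b, int kh, int kw, int stride,
                    int pad_h, int pad_w, int dil) {
  const int OH = conv_out_size(x.n_rows, kh, stride, pad_h, dil, false);
  const int OW = conv_out_size(x.n_cols, kw, stride, pad_w, dil, false);
  if (OH < 1 || OW < 1) stop("convolution output would be empty");
  if ((int)w.n_cols != kh * kw * (int)x.n_slices)
    stop("weight/input channel mismatch");
  arma::mat colT;
  im2colT(x, colT, kh, kw, stride, pad_h, pad_w, dil, OH, OW);
  arma::mat y = colT * w.t();        // P x Cout, columns are output slices
  y.each_row() += b.t();
  arma::cube out(OH, OW, w.n_rows);
  std::memcpy(out.memptr(), y.memptr(),
              (size_t)OH * OW * w.n_rows * sizeof(double));
  return out;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& gy,
              int kh, int kw, int stride, int pad_h, int pad_w, int dil,
              bool need_gx = true) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int OH = gy.n_rows, OW = gy.n_cols, Cout = gy.n_slices;
  const int P = OH * OW;
  arma::mat colT;
  im2colT(x, colT, kh, kw, stride, pad_h, pad_w, dil, OH, OW);
  const arma::mat gymT((double*)gy.memptr(), P, Cout, false, true);
  arma::mat gw = gymT.t() * colT;    // Cout x K
  arma::vec gb = arma::sum(gymT, 0).t();
  if (!need_gx)
    return List::create(_["gx"] = R_NilValue, _["gw"] = gw, _["gb"] = gb);
  arma::mat gcolT = gymT * w;        // P x K
  arma::cube gx(H, W, C, arma::fill::zeros);
  col2imT(gcolT, gx, kh, kw, stride, pad_h, pad_w, dil, OH, OW);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Max pooling. ceil_mode reproduces the SSD trunk's 75 -> 38 pool; windows
// are clipped to the input so the argmax is always a real pixel.
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(const arma::cube& x, int k, int stride, int pad,
                 bool ceil_mode) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int OH = conv_out_size(H, k, stride, pad, 1, ceil_mode);
  int OW = conv_out_size(W, k, stride, pad, 1, ceil_mode);
  // a ceil-mode window must start inside the (left-padded) input
  if (ceil_mode) {
    if ((OH - 1) * stride >= H + pad) --OH;
    if ((OW - 1) * stride >= W + pad) --OW;
  }
  arma::cube y(OH, OW, C);
  arma::ucube idx(OH, OW, C);       // linear index iy + ix*H into the slice
  for (int c = 0; c < C; ++c) {
    for (int ox = 0; ox < OW; ++ox) {
      for (int oy = 0; oy < OH; ++oy) {
        double best = -std::numeric_limits<double>::infinity();
        int bi = 0;
        for (int ky = 0; ky < k; ++ky) {
          const int iy = oy * stride - pad + ky;
          if (iy < 0 || iy >= H) continue;
          for (int kx = 0; kx < k; ++kx) {
            const int ix = ox * stride - pad + kx;
            if (ix < 0 || ix >= W) continue;
            const double v = x(iy, ix, c);
            if (v > best) { best = v; bi = iy + ix * H; }
          }
        }
        y(oy, ox, c) = best;
        idx(oy, ox, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
arma::cube maxpool_bwd(const arma::cube& gy, const arma::ucube& idx, int H,
                       int W) {
  const int OH = gy.n_rows, OW = gy.n_cols, C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* gs = gx.slice_memptr(c);
    for (int ox = 0; ox < OW; ++ox)
      for (int oy = 0; oy < OH; ++oy)
        gs[idx(oy, ox, c)] += gy(oy, ox, c);
  }
  return gx;
}

// Bilinear resize with align_corners = FALSE (pixel-centre) convention;
// used by the augmentation pipeline and HRGAN mask pyramids.
// [[Rcpp::export(name = ".resize_bilinear")]]
arma::cube resize_bilinear(const arma::cube& x, int out_h, int out_w) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (out_h < 1 || out_w < 1) stop("invalid output size");
  arma::cube out(out_h, out_w, C);
  const double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int ox = 0; ox < out_w; ++ox) {
    double fx = (ox + 0.5) * sx - 0.5;
    if (fx < 0) fx = 0;
    int x0 = (int)std::floor(fx);
    int x1 = std::min(x0 + 1, W - 1);
    if (x0 > W - 1) x0 = W - 1;
    const double wx = fx - x0;
    for (int oy = 0; oy < out_h; ++oy) {
      double fy = (oy + 0.5) * sy - 0.5;
      if (fy < 0) fy = 0;
      int y0 = (int)std::floor(fy);
      int y1 = std::min(y0 + 1, H - 1);
      if (y0 > H - 1) y0 = H - 1;
      const double wy = fy - y0;
      for (int c = 0; c < C; ++c) {
        const double top = x(y0, x0, c) * (1 - wx) + x(y0, x1, c) * wx;
        const double bot = x(y1, x0, c) * (1 - wx) + x(y1, x1, c) * wx;
        out(oy, ox, c) = top * (1 - wy) + bot * wy;
      }
    }
  }
  return out;
}

// CRC32 (PNG chunk checksum) and Adler32 (zlib trailer) for the 16-bit
// grayscale PNG writer; R has no exported incremental CRC.
// [[Rcpp::export(name = ".crc32")]]
double crc32_bytes(const RawVector& data) {
  static uint32_t table[256];
  static bool have = false;
  if (!have) {
    for (uint32_t n = 0; n < 256; ++n) {
      uint32_t c = n;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[n] = c;
    }
    have = true;
  }
  uint32_t c = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    c = table[(c ^ data[i]) & 0xFFu] ^ (c >> 8);
  return (double)(c ^ 0xFFFFFFFFu);
}

// [[Rcpp::export(name = ".adler32")]]
double adler32_bytes(const RawVector& data) {
  uint32_t a = 1, b = 0;
  for (R_xlen_t i = 0; i < data.size(); ++i) {
    a = (a + data[i]) % 65521u;
    b = (b + a) % 65521u;
  }
  return (double)((b << 16) | a);
}
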