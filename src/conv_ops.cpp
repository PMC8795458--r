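#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Direct 3D convolution kernels over channels-last, column-major
// (D, H, W, C) arrays (slice axis fastest). The weight matrix is
// (out_channels, in_channels * K) with column j = o + K*c, where o
// enumerates kernel offsets slice-fastest (then row, then col) and c the
// input channel — i.e. the flattening of a conceptual
// (out, k_slice, k_row, k_col, in) array. Direct loops avoid
// materialising im2col patch matrices, which would dominate runtime
// through allocation traffic at the small channel counts used by
// width-reduced networks. The (w, h) output-position loops are outermost
// so that each output column tile stays cache-resident while all
// in_channels * K kernel contributions accumulate into it; with kernel
// offsets outermost the full output array would be re-streamed through
// cache in_channels * K times per layer, which makes the kernels
// memory-bound.

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector xdim,
                         NumericMatrix wm, IntegerVector kernel,
                         IntegerVector stride, IntegerVector pad,
                         IntegerVector outdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int kd = kernel[0], kh = kernel[1], kw = kernel[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int Do = outdim[0], Ho = outdim[1], Wo = outdim[2];
  const int K = kd * kh * kw;
  const int Cout = wm.nrow();
  const R_xlen_t N = (R_xlen_t)Do * Ho * Wo;
  NumericVector y(N * Cout);  // zero-initialised
  double* ys = y.begin();
  const double* xs = x.begin();
  const double* ws = wm.begin();
  // output channels are processed in chunks of four; each chunk's output
  // column accumulates in a stack-local tile (register/L1 resident) and is
  // written to y exactly once per (w, h) position
  std::vector<double> accbuf(4 * (size_t)Do);
  for (int w = 0; w < Wo; ++w) {
    for (int h = 0; h < Ho; ++h) {
      const R_xlen_t nbase = (R_xlen_t)Do * (h + (R_xlen_t)Ho * w);
      for (int cb = 0; cb < Cout; cb += 4) {
        const int nb = std::min(4, Cout - cb);
        double* __restrict a0 = accbuf.data();
        double* __restrict a1 = a0 + Do;
        double* __restrict a2 = a1 + Do;
        double* __restrict a3 = a2 + Do;
        std::memset(accbuf.data(), 0, sizeof(double) * nb * (size_t)Do);
        for (int c = 0; c < C; ++c) {
          const double* xc = xs + (R_xlen_t)D * H * W * c;
          int o = 0;
          for (int okw = 0; okw < kw; ++okw) {
            const int iw = w * sw + okw - pw;
            if (iw < 0 || iw >= W) { o += kh * kd; continue; }
            for (int okh = 0; okh < kh; ++okh) {
              const int ih = h * sh + okh - ph;
              if (ih < 0 || ih >= H) { o += kd; continue; }
              const double* xr = xc + (R_xlen_t)D * (ih + (R_xlen_t)H * iw);
              for (int okd = 0; okd < kd; ++okd, ++o) {
                // weight column j: entries for all output channels
                const double* wj =
                  ws + ((R_xlen_t)o + (R_xlen_t)K * c) * Cout + cb;
                const int off = okd - pd;
                if (nb == 4) {
                  const double w0 = wj[0], w1 = wj[1];
                  const double w2 = wj[2], w3 = wj[3];
                  if (sd == 1) {
                    const int d0 = std::max(0, -off);
                    const int d1 = std::min(Do, D - off);
                    const double* __restrict xo = xr + off;
                    for (int d = d0; d < d1; ++d) {
                      const double xv = xo[d];
                      a0[d] += w0 * xv; a1[d] += w1 * xv;
                      a2[d] += w2 * xv; a3[d] += w3 * xv;
                    }
                  } else {
                    for (int d = 0; d < Do; ++d) {
                      const int id = d * sd + off;
                      if (id < 0 || id >= D) continue;
                      const double xv = xr[id];
                      a0[d] += w0 * xv; a1[d] += w1 * xv;
                      a2[d] += w2 * xv; a3[d] += w3 * xv;
                    }
                  }
                } else {
                  for (int b = 0; b < nb; ++b) {
                    const double wv = wj[b];
                    if (wv == 0.0) continue;
                    double* ar = accbuf.data() + b * (size_t)Do;
                    if (sd == 1) {
                      const int d0 = std::max(0, -off);
                      const int d1 = std::min(Do, D - off);
                      const double* xo = xr + off;
                      for (int d = d0; d < d1; ++d) ar[d] += wv * xo[d];
                    } else {
                      for (int d = 0; d < Do; ++d) {
                        const int id = d * sd + off;
                        if (id >= 0 && id < D) ar[d] += wv * xr[id];
                      }
                    }
                  }
                }
              }
            }
          }
        }
        for (int b = 0; b < nb; ++b) {
          std::memcpy(ys + nbase + N * (cb + b),
                      accbuf.data() + b * (size_t)Do,
                      sizeof(double) * (size_t)Do);
        }
      }
    }
  }
  IntegerVector yd = IntegerVector::create(Do, Ho, Wo, Cout);
  y.attr("dim") = yd;
  return y;
}

// Gradient wrt the input: transposed convolution of dy with the same weights.

// [[Rcpp::export]]
NumericVector conv3d_bwd_data(NumericVector dy, IntegerVector xdim,
                              NumericMatrix wm, IntegerVector kernel,
                              IntegerVector stride, IntegerVector pad,
                              IntegerVector outdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int kd = kernel[0], kh = kernel[1], kw = kernel[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int Do = outdim[0], Ho = outdim[1], Wo = outdim[2];
  const int K = kd * kh * kw;
  const int Cout = wm.nrow();
  const R_xlen_t N = (R_xlen_t)Do * Ho * Wo;
  NumericVector dx((R_xlen_t)D * H * W * C);
  double* dxs = dx.begin();
  const double* dys = dy.begin();
  const double* ws = wm.begin();
  for (int w = 0; w < Wo; ++w) {
    for (int h = 0; h < Ho; ++h) {
      const R_xlen_t nbase = (R_xlen_t)Do * (h + (R_xlen_t)Ho * w);
      for (int c = 0; c < C; ++c) {
        double* dxc = dxs + (R_xlen_t)D * H * W * c;
        int o = 0;
        for (int okw = 0; okw < kw; ++okw) {
          const int iw = w * sw + okw - pw;
          if (iw < 0 || iw >= W) { o += kh * kd; continue; }
          for (int okh = 0; okh < kh; ++okh) {
            const int ih = h * sh + okh - ph;
            if (ih < 0 || ih >= H) { o += kd; continue; }
            double* dxr = dxc + (R_xlen_t)D * (ih + (R_xlen_t)H * iw);
            for (int okd = 0; okd < kd; ++okd, ++o) {
              const double* wj = ws + ((R_xlen_t)o + (R_xlen_t)K * c) * Cout;
              const int off = okd - pd;
              int d0 = 0, d1 = Do;
              if (sd == 1) {
                d0 = std::max(0, -off);
                d1 = std::min(Do, D - off);
              }
              // fuse four output-channel contributions into one pass over
              // the input-gradient row
              int co = 0;
              for (; co + 3 < Cout; co += 4) {
                const double w0 = wj[co], w1 = wj[co + 1];
                const double w2 = wj[co + 2], w3 = wj[co + 3];
                const double* __restrict g0 = dys + nbase + N * co;
                const double* __restrict g1 = g0 + N;
                const double* __restrict g2 = g1 + N;
                const double* __restrict g3 = g2 + N;
                if (sd == 1) {
                  double* __restrict dxo = dxr + off;
                  for (int d = d0; d < d1; ++d) {
                    dxo[d] += w0 * g0[d] + w1 * g1[d] +
                              w2 * g2[d] + w3 * g3[d];
                  }
                } else {
                  for (int d = 0; d < Do; ++d) {
                    const int id = d * sd + off;
                    if (id < 0 || id >= D) continue;
                    dxr[id] += w0 * g0[d] + w1 * g1[d] +
                               w2 * g2[d] + w3 * g3[d];
                  }
                }
              }
              for (; co < Cout; ++co) {
                const double wv = wj[co];
                if (wv == 0.0) continue;
                const double* dyr = dys + nbase + N * co;
                if (sd == 1) {
                  double* dxo = dxr + off;
                  for (int d = d0; d < d1; ++d) dxo[d] += wv * dyr[d];
                } else {
                  for (int d = 0; d < Do; ++d) {
                    const int id = d * sd + off;
                    if (id >= 0 && id < D) dxr[id] += wv * dyr[d];
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}

// Gradient wrt the weights: correlation of dy with the cached input.

// [[Rcpp::export]]
NumericMatrix conv3d_bwd_weight(NumericVector dy, NumericVector x,
                                IntegerVector xdim, int n_out,
                                IntegerVector kernel, IntegerVector stride,
                                IntegerVector pad, IntegerVector outdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int kd = kernel[0], kh = kernel[1], kw = kernel[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int Do = outdim[0], Ho = outdim[1], Wo = outdim[2];
  const int K = kd * kh * kw;
  const int Cout = n_out;
  const R_xlen_t N = (R_xlen_t)Do * Ho * Wo;
  NumericMatrix dW(Cout, (R_xlen_t)C * K);
  double* dws = dW.begin();
  const double* dys = dy.begin();
  const double* xs = x.begin();
  for (int w = 0; w < Wo; ++w) {
    for (int h = 0; h < Ho; ++h) {
      const R_xlen_t nbase = (R_xlen_t)Do * (h + (R_xlen_t)Ho * w);
      for (int c = 0; c < C; ++c) {
        const double* xc = xs + (R_xlen_t)D * H * W * c;
        int o = 0;
        for (int okw = 0; okw < kw; ++okw) {
          const int iw = w * sw + okw - pw;
          if (iw < 0 || iw >= W) { o += kh * kd; continue; }
          for (int okh = 0; okh < kh; ++okh) {
            const int ih = h * sh + okh - ph;
            if (ih < 0 || ih >= H) { o += kd; continue; }
            const double* xr = xc + (R_xlen_t)D * (ih + (R_xlen_t)H * iw);
            for (int okd = 0; okd < kd; ++okd, ++o) {
              double* dwj = dws + ((R_xlen_t)o + (R_xlen_t)K * c) * Cout;
              const int off = okd - pd;
              int d0 = 0, d1 = Do;
              if (sd == 1) {
                d0 = std::max(0, -off);
                d1 = std::min(Do, D - off);
              }
              // four dot products per pass over the cached input row
              int co = 0;
              for (; co + 3 < Cout; co += 4) {
                const double* __restrict g0 = dys + nbase + N * co;
                const double* __restrict g1 = g0 + N;
                const double* __restrict g2 = g1 + N;
                const double* __restrict g3 = g2 + N;
                double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
                if (sd == 1) {
                  const double* __restrict xo = xr + off;
                  for (int d = d0; d < d1; ++d) {
                    const double xv = xo[d];
                    s0 += g0[d] * xv; s1 += g1[d] * xv;
                    s2 += g2[d] * xv; s3 += g3[d] * xv;
                  }
                } else {
                  for (int d = 0; d < Do; ++d) {
                    const int id = d * sd + off;
                    if (id < 0 || id >= D) continue;
                    const double xv = xr[id];
                    s0 += g0[d] * xv; s1 += g1[d] * xv;
                    s2 += g2[d] * xv; s3 += g3[d] * xv;
                  }
                }
                dwj[co] += s0; dwj[co + 1] += s1;
                dwj[co + 2] += s2; dwj[co + 3] += s3;
              }
              for (; co < Cout; ++co) {
                const double* dyr = dys + nbase + N * co;
                double s = 0.0;
                if (sd == 1) {
                  const double* xo = xr + off;
                  for (int d = d0; d < d1; ++d) s += dyr[d] * xo[d];
                } else {
                  for (int d = 0; d < Do; ++d) {
                    const int id = d * sd + off;
                    if (id >= 0 && id < D) s += dyr[d] * xr[id];
                  }
                }
                dwj[co] += s;
              }
            }
          }
        }
      }
    }
  }
  return dW;
}

// Trilinear sampling of a 3D (D, H, W) volume at fractional 0-based voxel
// coordinates. Coordinates outside the grid return `fill` when clamp = false,
// or are clamped to the boundary when clamp = true.

// [[Rcpp::export]]
NumericVector trilinear3d(NumericVector vol, IntegerVector vdim,
                          NumericVector cd, NumericVector ch,
                          NumericVector cw, bool clamp, double fill) {
  const int D = vdim[0], H = vdim[1], W = vdim[2];
  const R_xlen_t n = cd.size();
  NumericVector out(n);
  const double* v = vol.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = cd[i], y = ch[i], z = cw[i];
    if (clamp) {
      x = std::min(std::max(x, 0.0), (double)(D - 1));
      y = std::min(std::max(y, 0.0), (double)(H - 1));
      z = std::min(std::max(z, 0.0), (double)(W - 1));
    } else if (x < 0 || x > D - 1 || y < 0 || y > H - 1 || z < 0 ||
               z > W - 1) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(z);
    if (x0 > D - 2) x0 = D > 1 ? D - 2 : 0;
    if (y0 > H - 2) y0 = H > 1 ? H - 2 : 0;
    if (z0 > W - 2) z0 = W > 1 ? W - 2 : 0;
    const int x1 = D > 1 ? x0 + 1 : x0, y1 = H > 1 ? y0 + 1 : y0,
              z1 = W > 1 ? z0 + 1 : z0;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    const R_xlen_t DH = (R_xlen_t)D * H;
    #define V(a, b, c) v[(a) + (R_xlen_t)D * (b) + DH * (c)]
    const double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
    const double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
    const double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
    const double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
    #undef V
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Batch-norm over the channel axis of an (n, ch) view of a channels-last
// feature map, training semantics: per-channel batch statistics
// (population variance in the normaliser).

// [[Rcpp::export]]
List bn_fwd_train(NumericVector x, R_xlen_t n, int ch, NumericVector gamma,
                  NumericVector beta, double eps) {
  NumericVector y(n * ch), xhat(n * ch), mu(ch), var(ch), ivar(ch);
  const double* xs = x.begin();
  double* ys = y.begin();
  double* xh = xhat.begin();
  for (int c = 0; c < ch; ++c) {
    const double* xc = xs + n * c;
    double m = 0;
    for (R_xlen_t i = 0; i < n; ++i) m += xc[i];
    m /= n;
    double v = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double d = xc[i] - m;
      v += d * d;
    }
    v /= n;
    const double iv = 1.0 / std::sqrt(v + eps);
    mu[c] = m;
    var[c] = v;
    ivar[c] = iv;
    const double g = gamma[c], b = beta[c];
    double* yc = ys + n * c;
    double* xhc = xh + n * c;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double z = (xc[i] - m) * iv;
      xhc[i] = z;
      yc[i] = g * z + b;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["ivar"] = ivar);
}

// [[Rcpp::export]]
NumericVector bn_fwd_eval(NumericVector x, R_xlen_t n, int ch,
                          NumericVector gamma, NumericVector beta,
                          NumericVector rmean, NumericVector rvar,
                          double eps) {
  NumericVector y(n * ch);
  const double* xs = x.begin();
  double* ys = y.begin();
  for (int c = 0; c < ch; ++c) {
    const double iv = 1.0 / std::sqrt(rvar[c] + eps);
    const double g = gamma[c] * iv, b = beta[c] - gamma[c] * iv * rmean[c];
    const double* xc = xs + n * c;
    double* yc = ys + n * c;
    for (R_xlen_t i = 0; i < n; ++i) yc[i] = g * xc[i] + b;
  }
  return y;
}

// [[Rcpp::export]]
List bn_bwd(NumericVector dy, NumericVector xhat, NumericVector ivar,
            NumericVector gamma, R_xlen_t n, int ch) {
  NumericVector dx(n * ch), dgamma(ch), dbeta(ch);
  const double* dys = dy.begin();
  const double* xh = xhat.begin();
  double* dxs = dx.begin();
  for (int c = 0; c < ch; ++c) {
    const double* dyc = dys + n * c;
    const double* xhc = xh + n * c;
    double sg = 0, sb = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      sg += dyc[i] * xhc[i];
      sb += dyc[i];
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double k = ivar[c] * gamma[c] / n;
    double* dxc = dxs + n * c;
    for (R_xlen_t i = 0; i < n; ++i) {
      dxc[i] = k * (n * dyc[i] - sb - xhc[i] * sg);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double* xs = x.begin();
  double* ys = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) ys[i] = xs[i] > 0 ? xs[i] : 0;
  return y;
}

// ReLU applied to the sum of the residual main path and the shortcut.

// [[Rcpp::export]]
NumericVector add_relu_fwd(NumericVector a, NumericVector b) {
  NumericVector y(a.size());
  const double* as = a.begin();
  const double* bs = b.begin();
  double* ys = y.begin();
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    const double s = as[i] + bs[i];
    ys[i] = s > 0 ? s : 0;
  }
  return y;
}

// Backward through ReLU given its own output (zero where the output is zero).

// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  const double* dys = dy.begin();
  const double* ys = y.begin();
  double* dxs = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) dxs[i] = ys[i] > 0 ? dys[i] : 0;
  return dx;
}
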