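// Compiled numerical kernels: 2D (dilated) convolution forward/backward via
// im2col + GEMM, and connected-component labelling for binary masks.
// Array convention throughout: R arrays of dim (N, C, H, W), column-major,
// so element (n,c,h,w) sits at n + N*(c + C*(h + H*w)) (0-based).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& N, int& C, int& H, int& W) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4D array (N, C, H, W)");
  N = d[0]; C = d[1]; H = d[2]; W = d[3];
}

// Batch-wide transposed im2col: colT is (N*Hout*Wout) x (Cin*k*k); row index
// = o + HW*n with o = ho + Hout*wo, column index r = ci + Cin*(kh + k*kw).
// Column-major storage makes the inner (ho) loop write contiguously.
static void im2col_batch(const double* x, int N, int Cin, int H, int W,
                         int k, int pad, int dil, int Hout, int Wout,
                         arma::mat& colT) {
  const int HWo = Hout * Wout;
  for (int kw = 0; kw < k; ++kw) {
    for (int kh = 0; kh < k; ++kh) {
      for (int ci = 0; ci < Cin; ++ci) {
        int r = ci + Cin * (kh + k * kw);
        double* dst = colT.colptr(r);
        for (int n = 0; n < N; ++n) {
          for (int wo = 0; wo < Wout; ++wo) {
            int wi = wo - pad + dil * kw;
            bool wok = (wi >= 0 && wi < W);
            double* d2 = dst + (size_t)HWo * n + (size_t)Hout * wo;
            for (int ho = 0; ho < Hout; ++ho) {
              int hi = ho - pad + dil * kh;
              d2[ho] = (wok && hi >= 0 && hi < H)
                ? x[n + (size_t)N * (ci + (size_t)Cin * (hi + (size_t)H * wi))]
                : 0.0;
            }
          }
        }
      }
    }
  }
}

static void col2im_batch(const arma::mat& gcolT, double* gx, int N, int Cin,
                         int H, int W, int k, int pad, int dil,
                         int Hout, int Wout) {
  const int HWo = Hout * Wout;
  for (int kw = 0; kw < k; ++kw) {
    for (int kh = 0; kh < k; ++kh) {
      for (int ci = 0; ci < Cin; ++ci) {
        int r = ci + Cin * (kh + k * kw);
        const double* src = gcolT.colptr(r);
        for (int n = 0; n < N; ++n) {
          for (int wo = 0; wo < Wout; ++wo) {
            int wi = wo - pad + dil * kw;
            if (wi < 0 || wi >= W) continue;
            const double* s2 = src + (size_t)HWo * n + (size_t)Hout * wo;
            for (int ho = 0; ho < Hout; ++ho) {
              int hi = ho - pad + dil * kh;
              if (hi < 0 || hi >= H) continue;
              gx[n + (size_t)N * (ci + (size_t)Cin * (hi + (size_t)H * wi))] += s2[ho];
            }
          }
        }
      }
    }
  }
}

// Forward convolution; returns the output and the im2col matrix, which the
// backward pass reuses instead of rebuilding.
// [[Rcpp::export]]
List conv2d_forward_cpp(NumericVector x, NumericVector w, NumericVector b,
                        int pad, int dil) {
  int N, Cin, H, W;
  get_dims4(x, N, Cin, H, W);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must be (Cout, Cin, k, k)");
  int Cout = wd[0], Cin_w = wd[1], k = wd[2];
  if (wd[3] != k) stop("kernel must be square");
  if (Cin_w != Cin) stop("input channels do not match weights");
  int Hout = H + 2 * pad - dil * (k - 1);
  int Wout = W + 2 * pad - dil * (k - 1);
  if (Hout < 1 || Wout < 1) stop("kernel/dilation exceed the padded input extent");
  const int HWo = Hout * Wout, R = Cin * k * k;

  arma::mat Wmat(const_cast<double*>(&w[0]), Cout, R, false, true);

  NumericMatrix colT_r((R_xlen_t)N * HWo, R);
  arma::mat colT(colT_r.begin(), (size_t)N * HWo, R, false, true);
  im2col_batch(&x[0], N, Cin, H, W, k, pad, dil, Hout, Wout, colT);

  arma::mat outT = colT * Wmat.t();  // (N*HWo) x Cout
  NumericVector out((R_xlen_t)N * Cout * HWo);
  out.attr("dim") = IntegerVector::create(N, Cout, Hout, Wout);
  for (int co = 0; co < Cout; ++co) {
    const double* src = outT.colptr(co);
    double bc = b[co];
    for (int n = 0; n < N; ++n) {
      const double* s2 = src + (size_t)HWo * n;
      for (int j = 0; j < HWo; ++j)
        out[n + (size_t)N * (co + (size_t)Cout * j)] = s2[j] + bc;
    }
  }
  return List::create(_["out"] = out, _["col"] = colT_r);
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericMatrix colT_r, NumericVector w, NumericVector gout,
                         IntegerVector xdim, int pad, int dil) {
  int N = xdim[0], Cin = xdim[1], H = xdim[2], W = xdim[3];
  IntegerVector wd = w.attr("dim");
  int Cout = wd[0], k = wd[2];
  int Hout = H + 2 * pad - dil * (k - 1);
  int Wout = W + 2 * pad - dil * (k - 1);
  const int HWo = Hout * Wout, R = Cin * k * k;

  arma::mat Wmat(const_cast<double*>(&w[0]), Cout, R, false, true);
  arma::mat colT(colT_r.begin(), (size_t)N * HWo, R, false, true);

  arma::mat goT((size_t)N * HWo, Cout);
  for (int co = 0; co < Cout; ++co) {
    double* dst = goT.colptr(co);
    for (int n = 0; n < N; ++n) {
      double* d2 = dst + (size_t)HWo * n;
      for (int j = 0; j < HWo; ++j)
        d2[j] = gout[n + (size_t)N * (co + (size_t)Cout * j)];
    }
  }

  arma::mat gW = goT.t() * colT;          // Cout x R
  arma::rowvec gB = arma::sum(goT, 0);
  arma::mat gcolT = goT * Wmat;           // (N*HWo) x R

  NumericVector gx((R_xlen_t)N * Cin * H * W);
  gx.attr("dim") = xdim;
  col2im_batch(gcolT, &gx[0], N, Cin, H, W, k, pad, dil, Hout, Wout);

  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  std::copy(gW.memptr(), gW.memptr() + gW.n_elem, gw.begin());
  NumericVector gb(Cout);
  std::copy(gB.memptr(), gB.memptr() + Cout, gb.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---- batched linear algebra -------------------------------------------------

static inline void slice_to_mat(const double* x, int n, int N, int A, int B,
                                arma::mat& m) {
  for (int j = 0; j < B; ++j)
    for (int i = 0; i < A; ++i)
      m(i, j) = x[n + (size_t)N * (i + (size_t)A * j)];
}

// batched matrix product with optional per-slice transposes:
// out[n,,] = op_a(a[n,,]) %*% op_b(b[n,,])
// [[Rcpp::export]]
NumericVector bmm_cpp(NumericVector a, NumericVector b, bool ta, bool tb) {
  IntegerVector da = a.attr("dim"), db = b.attr("dim");
  if (da.size() != 3 || db.size() != 3 || da[0] != db[0])
    stop("bmm expects two (N, ., .) arrays");
  int N = da[0];
  int ra = ta ? da[2] : da[1], ca = ta ? da[1] : da[2];
  int rb = tb ? db[2] : db[1], cb = tb ? db[1] : db[2];
  if (ca != rb) stop("bmm inner dimensions disagree");
  NumericVector out((R_xlen_t)N * ra * cb);
  out.attr("dim") = IntegerVector::create(N, ra, cb);
  arma::mat ma(da[1], da[2]), mb(db[1], db[2]);
  for (int n = 0; n < N; ++n) {
    slice_to_mat(&a[0], n, N, da[1], da[2], ma);
    slice_to_mat(&b[0], n, N, db[1], db[2], mb);
    arma::mat mo;
    if (!ta && !tb) mo = ma * mb;
    else if (ta && !tb) mo = ma.t() * mb;
    else if (!ta && tb) mo = ma * mb.t();
    else mo = ma.t() * mb.t();
    for (int j = 0; j < cb; ++j)
      for (int i = 0; i < ra; ++i)
        out[n + (size_t)N * (i + (size_t)ra * j)] = mo(i, j);
  }
  return out;
}

// separable spatial map: out[n,c,,] = A %*% x[n,c,,] %*% B^T
// (used by exact x2 up/down interpolation and its adjoint)
// [[Rcpp::export]]
NumericVector sepmm_cpp(NumericVector x, NumericMatrix A_r, NumericMatrix B_r) {
  int N, C, H, W;
  get_dims4(x, N, C, H, W);
  arma::mat A(A_r.begin(), A_r.nrow(), A_r.ncol(), false, true);
  arma::mat B(B_r.begin(), B_r.nrow(), B_r.ncol(), false, true);
  if ((int)A.n_cols != H || (int)B.n_cols != W) stop("sepmm dims disagree");
  int Ho = A.n_rows, Wo = B.n_rows;
  NumericVector out((R_xlen_t)N * C * Ho * Wo);
  out.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  arma::mat xs(H, W);
  size_t NC = (size_t)N * C;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      for (int w2 = 0; w2 < W; ++w2)
        for (int h = 0; h < H; ++h)
          xs(h, w2) = x[n + (size_t)N * (c + (size_t)C * (h + (size_t)H * w2))];
      arma::mat o = A * xs * B.t();
      for (int w2 = 0; w2 < Wo; ++w2)
        for (int h = 0; h < Ho; ++h)
          out[n + (size_t)N * (c + (size_t)C * (h + (size_t)Ho * w2))] = o(h, w2);
      (void)NC;
    }
  return out;
}

// 2x2 max pooling, stride 2; also returns the argmax slab (1..4, ties first)
// [[Rcpp::export]]
List maxpool2_cpp(NumericVector x) {
  int N, C, H, W;
  get_dims4(x, N, C, H, W);
  if (H % 2 || W % 2) stop("maxpool2 needs even H and W");
  int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)N * C * Ho * Wo);
  IntegerVector arg((R_xlen_t)N * C * Ho * Wo);
  out.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          size_t base = n + (size_t)N * c;
          double v[4] = {
            x[base + (size_t)N * C * ((2 * ho)     + (size_t)H * (2 * wo))],
            x[base + (size_t)N * C * ((2 * ho + 1) + (size_t)H * (2 * wo))],
            x[base + (size_t)N * C * ((2 * ho)     + (size_t)H * (2 * wo + 1))],
            x[base + (size_t)N * C * ((2 * ho + 1) + (size_t)H * (2 * wo + 1))]};
          int best = 0;
          for (int q = 1; q < 4; ++q) if (v[q] > v[best]) best = q;
          size_t oi = n + (size_t)N * (c + (size_t)C * (ho + (size_t)Ho * wo));
          out[oi] = v[best];
          arg[oi] = best;
        }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector g, IntegerVector arg,
                               IntegerVector xdim) {
  int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector gx((R_xlen_t)N * C * H * W);
  gx.attr("dim") = xdim;
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          size_t oi = n + (size_t)N * (c + (size_t)C * (ho + (size_t)Ho * wo));
          int q = arg[oi];
          int h = 2 * ho + (q == 1 || q == 3);
          int w2 = 2 * wo + (q >= 2);
          gx[n + (size_t)N * (c + (size_t)C * (h + (size_t)H * w2))] = g[oi];
        }
  return gx;
}

// [[Rcpp::export]]
NumericVector relu_cpp(NumericVector x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = x[i] > 0 ? x[i] : 0.0;
  return out;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector g, NumericVector x) {
  NumericVector out(g.size());
  out.attr("dim") = g.attr("dim");
  for (R_xlen_t i = 0; i < g.size(); ++i) out[i] = x[i] > 0 ? g[i] : 0.0;
  return out;
}

// ---- fused channel-broadcast helpers (hot paths of BN / SE / gating) -------

// out[n,c,h,w] = x[n,c,h,w] * s[c] + t[c]
// [[Rcpp::export]]
NumericVector chan_affine_cpp(NumericVector x, NumericVector s, NumericVector t) {
  int N, C, H, W;
  get_dims4(x, N, C, H, W);
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  size_t HW = (size_t)H * W;
  for (size_t p = 0; p < HW; ++p)
    for (int c = 0; c < C; ++c) {
      double sc = s[c], tc = t[c];
      size_t off = (size_t)N * (c + (size_t)C * p);
      for (int n = 0; n < N; ++n) out[off + n] = x[off + n] * sc + tc;
    }
  return out;
}

// out[n,c,h,w] = x[n,c,h,w] * v[n,c]
// [[Rcpp::export]]
NumericVector chan_scale_nc_cpp(NumericVector x, NumericMatrix v) {
  int N, C, H, W;
  get_dims4(x, N, C, H, W);
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  size_t HW = (size_t)H * W;
  for (size_t p = 0; p < HW; ++p)
    for (int c = 0; c < C; ++c) {
      size_t off = (size_t)N * (c + (size_t)C * p);
      const double* vc = &v(0, c);
      for (int n = 0; n < N; ++n) out[off + n] = x[off + n] * vc[n];
    }
  return out;
}

// (N, C) matrix of sum over (h, w) of a*b
// [[Rcpp::export]]
NumericMatrix chan_dot_nc_cpp(NumericVector a, NumericVector b) {
  int N, C, H, W;
  get_dims4(a, N, C, H, W);
  NumericMatrix out(N, C);
  size_t HW = (size_t)H * W;
  for (size_t p = 0; p < HW; ++p)
    for (int c = 0; c < C; ++c) {
      size_t off = (size_t)N * (c + (size_t)C * p);
      double* oc = &out(0, c);
      for (int n = 0; n < N; ++n) oc[n] += a[off + n] * b[off + n];
    }
  return out;
}

// (N, C) matrix of sum over (h, w) of x
// [[Rcpp::export]]
NumericMatrix chan_ncsum_cpp(NumericVector x) {
  int N, C, H, W;
  get_dims4(x, N, C, H, W);
  NumericMatrix out(N, C);
  size_t HW = (size_t)H * W;
  for (size_t p = 0; p < HW; ++p)
    for (int c = 0; c < C; ++c) {
      size_t off = (size_t)N * (c + (size_t)C * p);
      double* oc = &out(0, c);
      for (int n = 0; n < N; ++n) oc[n] += x[off + n];
    }
  return out;
}

// per-channel sum over (n, h, w) of a*b
// [[Rcpp::export]]
NumericVector chan_dot_c_cpp(NumericVector a, NumericVector b) {
  int N, C, H, W;
  get_dims4(a, N, C, H, W);
  NumericVector out(C);
  size_t HW = (size_t)H * W;
  for (size_t p = 0; p < HW; ++p)
    for (int c = 0; c < C; ++c) {
      size_t off = (size_t)N * (c + (size_t)C * p);
      double acc = 0.0;
      for (int n = 0; n < N; ++n) acc += a[off + n] * b[off + n];
      out[c] += acc;
    }
  return out;
}

// per-channel total sum over (n, h, w)
// [[Rcpp::export]]
NumericVector chan_sum_cpp(NumericVector x) {
  int N, C, H, W;
  get_dims4(x, N, C, H, W);
  NumericVector out(C);
  size_t HW = (size_t)H * W;
  for (size_t p = 0; p < HW; ++p)
    for (int c = 0; c < C; ++c) {
      size_t off = (size_t)N * (c + (size_t)C * p);
      double acc = 0.0;
      for (int n = 0; n < N; ++n) acc += x[off + n];
      out[c] += acc;
    }
  return out;
}

// broadcast an (N, C) matrix over space into (N, C, H, W)
// [[Rcpp::export]]
NumericVector bcast_nc_cpp(NumericMatrix v, IntegerVector dims) {
  int N = dims[0], C = dims[1], H = dims[2], W = dims[3];
  NumericVector out((R_xlen_t)N * C * H * W);
  out.attr("dim") = dims;
  size_t NC = (size_t)N * C, HW = (size_t)H * W;
  for (size_t p = 0; p < HW; ++p)
    std::copy(v.begin(), v.begin() + NC, out.begin() + NC * p);
  return out;
}

// BFS connected-component labelling of a binary H x W matrix.
// connectivity: 4 or 8. Returns an integer matrix of labels (0 = background).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  const int dh4[] = {-1, 1, 0, 0}, dw4[] = {0, 0, -1, 1};
  const int dh8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dw8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dh = (connectivity == 8) ? dh8 : dh4;
  const int* dw = (connectivity == 8) ? dw8 : dw4;
  int nn = (connectivity == 8) ? 8 : 4;

  for (int w0 = 0; w0 < W; ++w0) {
    for (int h0 = 0; h0 < H; ++h0) {
      if (mask(h0, w0) == 0 || lab(h0, w0) != 0) continue;
      ++next;
      lab(h0, w0) = next;
      stack.clear();
      stack.push_back(h0 + H * w0);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int h = p % H, w = p / H;
        for (int q = 0; q < nn; ++q) {
          int h2 = h + dh[q], w2 = w + dw[q];
          if (h2 < 0 || h2 >= H || w2 < 0 || w2 >= W) continue;
          if (mask(h2, w2) != 0 && lab(h2, w2) == 0) {
            lab(h2, w2) = next;
            stack.push_back(h2 + H * w2);
          }
        }
      }
    }
  }
  return lab;
}
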