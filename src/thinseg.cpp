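// Compiled numerical core: exact Euclidean distance transform and the
// U-Net forward/backward pass.  Everything here is deterministic; all
// random number generation happens on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas, applied along columns then rows).  Returns, for
// every pixel, the Euclidean distance to the nearest nonzero pixel of the
// input.  BIG stands in for +infinity; distances in a 2^15-sided image are
// far below its square root.
static const double BIG = 1e12;

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(const NumericMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  NumericMatrix out(H, W);
  bool any_fg = false;
  for (int i = 0; i < H * W; ++i)
    if (mask[i] != 0) { any_fg = true; break; }
  if (!any_fg) {
    std::fill(out.begin(), out.end(), R_PosInf);
    return out;
  }
  arma::mat sq(H, W);
  int n = std::max(H, W);
  std::vector<double> f(n), d(n);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  // pass 1: along columns
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) f[r] = (mask(r, c) != 0) ? 0.0 : BIG;
    dt1d(f, d, H, v, z);
    for (int r = 0; r < H; ++r) sq(r, c) = d[r];
  }
  // pass 2: along rows
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) f[c] = sq(r, c);
    dt1d(f, d, W, v, z);
    for (int c = 0; c < W; ++c) out(r, c) = std::sqrt(d[c]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Convolution primitives (stride 1, explicit asymmetric zero padding).
// Weight layout: w is (Cout x kh*kw*Cin); the column index of a weight is
// ch*kh*kw + dr*kw + dc with 0-based kernel offsets (dr, dc) and input
// channel ch.  im2col produces the matching (kh*kw*Cin x Ho*Wo) matrix with
// output pixels ordered column-major, so conv output = w * col.

static arma::mat im2col(const arma::cube& x, int kh, int kw, int pT, int pB,
                        int pL, int pR, int& Ho, int& Wo) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  Ho = H + pT + pB - kh + 1;
  Wo = W + pL + pR - kw + 1;
  arma::mat col(kh * kw * C, (arma::uword)Ho * Wo, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch)
    for (int dr = 0; dr < kh; ++dr)
      for (int dc = 0; dc < kw; ++dc) {
        int rowIdx = ch * kh * kw + dr * kw + dc;
        for (int oc = 0; oc < Wo; ++oc) {
          int ic = oc - pL + dc;
          if (ic < 0 || ic >= W) continue;
          const double* xc = x.slice(ch).colptr(ic);
          double* cp = col.colptr(0);
          for (int orr = 0; orr < Ho; ++orr) {
            int ir = orr - pT + dr;
            if (ir < 0 || ir >= H) continue;
            col(rowIdx, (arma::uword)oc * Ho + orr) = xc[ir];
          }
          (void)cp;
        }
      }
  return col;
}

static arma::cube conv_fwd(const arma::cube& x, const arma::mat& w,
                           const arma::vec& b, int kh, int kw, int pT, int pB,
                           int pL, int pR) {
  int Ho, Wo;
  arma::mat col = im2col(x, kh, kw, pT, pB, pL, pR, Ho, Wo);
  arma::mat out = w * col;
  out.each_col() += b;
  arma::cube y(Ho, Wo, w.n_rows);
  for (arma::uword f = 0; f < w.n_rows; ++f)
    y.slice(f) = arma::reshape(out.row(f), Ho, Wo);
  return y;
}

// Backward pass; recomputes im2col from the cached layer input (9x less
// memory than caching the col matrix).
static arma::cube conv_bwd(const arma::cube& x, const arma::mat& w,
                           const arma::cube& gy, int kh, int kw, int pT,
                           int pB, int pL, int pR, arma::mat& dw,
                           arma::vec& db) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int Ho, Wo;
  arma::mat col = im2col(x, kh, kw, pT, pB, pL, pR, Ho, Wo);
  int Cout = gy.n_slices;
  arma::mat g(Cout, (arma::uword)Ho * Wo);
  for (int f = 0; f < Cout; ++f)
    g.row(f) = arma::vectorise(gy.slice(f)).t();
  dw = g * col.t();
  db = arma::sum(g, 1);
  arma::mat dcol = w.t() * g;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch)
    for (int dr = 0; dr < kh; ++dr)
      for (int dc = 0; dc < kw; ++dc) {
        int rowIdx = ch * kh * kw + dr * kw + dc;
        for (int oc = 0; oc < Wo; ++oc) {
          int ic = oc - pL + dc;
          if (ic < 0 || ic >= W) continue;
          double* xc = dx.slice(ch).colptr(ic);
          for (int orr = 0; orr < Ho; ++orr) {
            int ir = orr - pT + dr;
            if (ir < 0 || ir >= H) continue;
            xc[ir] += dcol(rowIdx, (arma::uword)oc * Ho + orr);
          }
        }
      }
  return dx;
}

static arma::cube relu(const arma::cube& x) {
  arma::cube y = x;
  for (arma::uword i = 0; i < y.n_elem; ++i)
    if (y[i] < 0) y[i] = 0;
  return y;
}

// gradient through ReLU given the *post-activation* output
static arma::cube relu_bwd(const arma::cube& g, const arma::cube& out) {
  arma::cube r = g;
  for (arma::uword i = 0; i < r.n_elem; ++i)
    if (out[i] <= 0) r[i] = 0;
  return r;
}

static arma::cube maxpool(const arma::cube& x, arma::ucube& amax) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  amax.set_size(Ho, Wo, C);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r) {
        double best = -1e300;
        arma::uword bi = 0;
        for (int dc = 0; dc < 2; ++dc)
          for (int dr = 0; dr < 2; ++dr) {
            int ir = 2 * r + dr, ic = 2 * c + dc;
            double v = x(ir, ic, ch);
            if (v > best) {
              best = v;
              bi = (arma::uword)ic * H + ir;
            }
          }
        y(r, c, ch) = best;
        amax(r, c, ch) = bi;
      }
  return y;
}

static arma::cube maxpool_bwd(const arma::cube& gy, const arma::ucube& amax,
                              int H, int W) {
  int C = gy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch)
    for (arma::uword c = 0; c < gy.n_cols; ++c)
      for (arma::uword r = 0; r < gy.n_rows; ++r)
        dx.slice(ch)(amax(r, c, ch)) += gy(r, c, ch);
  return dx;
}

static arma::cube upsample2(const arma::cube& x) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        double v = x(r, c, ch);
        y(2 * r, 2 * c, ch) = v;
        y(2 * r + 1, 2 * c, ch) = v;
        y(2 * r, 2 * c + 1, ch) = v;
        y(2 * r + 1, 2 * c + 1, ch) = v;
      }
  return y;
}

static arma::cube upsample2_bwd(const arma::cube& gy) {
  int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  arma::cube dx(H, W, C);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        dx(r, c, ch) = gy(2 * r, 2 * c, ch) + gy(2 * r + 1, 2 * c, ch) +
                       gy(2 * r, 2 * c + 1, ch) + gy(2 * r + 1, 2 * c + 1, ch);
  return dx;
}

// ---------------------------------------------------------------------------
// U-Net orchestration.  Parameter list naming convention (1-based level i):
//   enc{i}_c1_w/b, enc{i}_c2_w/b        3x3 encoder convolutions
//   bot_c1_w/b, bot_c2_w/b              3x3 bottleneck convolutions
//   dec{i}_up_w/b                       2x2 conv after nearest upsampling
//   dec{i}_c1_w/b, dec{i}_c2_w/b        3x3 decoder convolutions
//   out_w, out_b                        1x1 conv -> sigmoid

struct Cache {
  arma::cube in;
  arma::cube out;
};

static arma::mat getm(const List& p, const std::string& nm) {
  return as<arma::mat>(p[nm]);
}
static arma::vec getv(const List& p, const std::string& nm) {
  return as<arma::vec>(p[nm]);
}

// forward + (optionally) loss and full gradient for one image
// loss: 0 = none (predict only), 1 = cross-entropy, 2 = focal
// [[Rcpp::export]]
List cpp_unet_run(const List& params, const arma::mat& x, int depth,
                  bool compute_grad, const arma::mat& y, int loss_type,
                  double alpha, double gamma, double eps) {
  std::vector<Cache> ec1(depth), ec2(depth), up(depth), dc1(depth),
      dc2(depth);
  std::vector<arma::ucube> pid(depth);
  Cache b1, b2, oc;

  arma::cube a(x.n_rows, x.n_cols, 1);
  a.slice(0) = x;

  for (int i = 0; i < depth; ++i) {
    char n1[32], n2[32];
    snprintf(n1, 32, "enc%d_c1", i + 1);
    snprintf(n2, 32, "enc%d_c2", i + 1);
    ec1[i].in = a;
    ec1[i].out = relu(conv_fwd(a, getm(params, std::string(n1) + "_w"),
                               getv(params, std::string(n1) + "_b"), 3, 3, 1,
                               1, 1, 1));
    ec2[i].in = ec1[i].out;
    ec2[i].out = relu(conv_fwd(ec1[i].out,
                               getm(params, std::string(n2) + "_w"),
                               getv(params, std::string(n2) + "_b"), 3, 3, 1,
                               1, 1, 1));
    a = maxpool(ec2[i].out, pid[i]);
  }
  b1.in = a;
  b1.out = relu(conv_fwd(a, getm(params, "bot_c1_w"), getv(params, "bot_c1_b"),
                         3, 3, 1, 1, 1, 1));
  b2.in = b1.out;
  b2.out = relu(conv_fwd(b1.out, getm(params, "bot_c2_w"),
                         getv(params, "bot_c2_b"), 3, 3, 1, 1, 1, 1));
  arma::cube cur = b2.out;
  for (int i = depth - 1; i >= 0; --i) {
    char nu[32], n1[32], n2[32];
    snprintf(nu, 32, "dec%d_up", i + 1);
    snprintf(n1, 32, "dec%d_c1", i + 1);
    snprintf(n2, 32, "dec%d_c2", i + 1);
    up[i].in = upsample2(cur);
    up[i].out = relu(conv_fwd(up[i].in, getm(params, std::string(nu) + "_w"),
                              getv(params, std::string(nu) + "_b"), 2, 2, 0,
                              1, 0, 1));
    dc1[i].in = arma::join_slices(up[i].out, ec2[i].out);
    dc1[i].out = relu(conv_fwd(dc1[i].in,
                               getm(params, std::string(n1) + "_w"),
                               getv(params, std::string(n1) + "_b"), 3, 3, 1,
                               1, 1, 1));
    dc2[i].in = dc1[i].out;
    dc2[i].out = relu(conv_fwd(dc1[i].out,
                               getm(params, std::string(n2) + "_w"),
                               getv(params, std::string(n2) + "_b"), 3, 3, 1,
                               1, 1, 1));
    cur = dc2[i].out;
  }
  oc.in = cur;
  arma::cube z = conv_fwd(cur, getm(params, "out_w"), getv(params, "out_b"),
                          1, 1, 0, 0, 0, 0);
  arma::mat p = 1.0 / (1.0 + arma::exp(-z.slice(0)));

  List res;
  res["pred"] = p;

  if (loss_type == 0) return res;

  arma::mat pc = arma::clamp(p, eps, 1.0 - eps);
  double loss;
  arma::mat dLdp;
  if (loss_type == 1) {
    loss = -arma::accu(y % arma::log(pc) +
                       (1.0 - y) % arma::log(1.0 - pc));
    dLdp = (pc - y) / (pc % (1.0 - pc));
  } else {
    arma::mat q = y % pc + (1.0 - y) % (1.0 - pc);
    arma::mat av = alpha * y + (1.0 - alpha) * (1.0 - y);
    arma::mat omq = 1.0 - q;
    loss = -arma::accu(av % arma::pow(omq, gamma) % arma::log(q));
    arma::mat dLdq;
    if (gamma > 0) {
      dLdq = gamma * (av % arma::pow(omq, gamma - 1.0) % arma::log(q)) -
             av % arma::pow(omq, gamma) / q;
    } else {
      dLdq = -av / q;
    }
    dLdp = dLdq % (2.0 * y - 1.0);
  }
  res["loss"] = loss;
  if (!compute_grad) return res;

  List grads;
  arma::mat dw;
  arma::vec db;

  arma::cube gz(p.n_rows, p.n_cols, 1);
  gz.slice(0) = dLdp % p % (1.0 - p);

  arma::cube g = conv_bwd(oc.in, getm(params, "out_w"), gz, 1, 1, 0, 0, 0, 0,
                          dw, db);
  grads["out_w"] = dw;
  grads["out_b"] = db;

  std::vector<arma::cube> skipg(depth);
  for (int i = 0; i < depth; ++i) {
    char nu[32], n1[32], n2[32];
    snprintf(nu, 32, "dec%d_up", i + 1);
    snprintf(n1, 32, "dec%d_c1", i + 1);
    snprintf(n2, 32, "dec%d_c2", i + 1);
    g = relu_bwd(g, dc2[i].out);
    g = conv_bwd(dc2[i].in, getm(params, std::string(n2) + "_w"), g, 3, 3, 1,
                 1, 1, 1, dw, db);
    grads[std::string(n2) + "_w"] = dw;
    grads[std::string(n2) + "_b"] = db;
    g = relu_bwd(g, dc1[i].out);
    g = conv_bwd(dc1[i].in, getm(params, std::string(n1) + "_w"), g, 3, 3, 1,
                 1, 1, 1, dw, db);
    grads[std::string(n1) + "_w"] = dw;
    grads[std::string(n1) + "_b"] = db;
    int cu = up[i].out.n_slices;
    arma::cube gup = g.slices(0, cu - 1);
    skipg[i] = g.slices(cu, g.n_slices - 1);
    gup = relu_bwd(gup, up[i].out);
    gup = conv_bwd(up[i].in, getm(params, std::string(nu) + "_w"), gup, 2, 2,
                   0, 1, 0, 1, dw, db);
    grads[std::string(nu) + "_w"] = dw;
    grads[std::string(nu) + "_b"] = db;
    g = upsample2_bwd(gup);
  }

  g = relu_bwd(g, b2.out);
  g = conv_bwd(b2.in, getm(params, "bot_c2_w"), g, 3, 3, 1, 1, 1, 1, dw, db);
  grads["bot_c2_w"] = dw;
  grads["bot_c2_b"] = db;
  g = relu_bwd(g, b1.out);
  g = conv_bwd(b1.in, getm(params, "bot_c1_w"), g, 3, 3, 1, 1, 1, 1, dw, db);
  grads["bot_c1_w"] = dw;
  grads["bot_c1_b"] = db;

  for (int i = depth - 1; i >= 0; --i) {
    char n1[32], n2[32];
    snprintf(n1, 32, "enc%d_c1", i + 1);
    snprintf(n2, 32, "enc%d_c2", i + 1);
    arma::cube ge =
        maxpool_bwd(g, pid[i], ec2[i].out.n_rows, ec2[i].out.n_cols) +
        skipg[i];
    ge = relu_bwd(ge, ec2[i].out);
    ge = conv_bwd(ec2[i].in, getm(params, std::string(n2) + "_w"), ge, 3, 3,
                  1, 1, 1, 1, dw, db);
    grads[std::string(n2) + "_w"] = dw;
    grads[std::string(n2) + "_b"] = db;
    ge = relu_bwd(ge, ec1[i].out);
    g = conv_bwd(ec1[i].in, getm(params, std::string(n1) + "_w"), ge, 3, 3, 1,
                 1, 1, 1, dw, db);
    grads[std::string(n1) + "_w"] = dw;
    grads[std::string(n1) + "_b"] = db;
  }

  res["grads"] = grads;
  return res;
}
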