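// Peephole convolutional LSTM: forward pass, backpropagation through time,
// and the pooled/batch-norm/dense classification head.
//
// Cell recurrence (gates are 3-D tensors, * = same-padded 2-D convolution,
// . = Hadamard product; note the output-gate peephole uses the UPDATED cell
// state):
//   i_t = sigma(Wxi*X_t + Whi*H_{t-1} + Wci . C_{t-1} + b_i)
//   f_t = sigma(Wxf*X_t + Whf*H_{t-1} + Wcf . C_{t-1} + b_f)
//   C_t = f_t . C_{t-1} + i_t . tanh(Wxc*X_t + Whc*H_{t-1} + b_c)
//   o_t = sigma(Wxo*X_t + Who*H_{t-1} + Wco . C_t + b_o)
//   H_t = o_t . tanh(C_t)
//
// Head: spatial mean pool of H_T per filter -> batch norm -> dropout ->
// dense ReLU -> single sigmoid unit; loss is binary cross-entropy plus an
// L2 penalty on the weight tensors (biases and batch-norm affine excluded).
//
// Parameter vector layout (gate order i, f, c, o; see paramLayout() in R,
// which must stay in lockstep):
//   Wx  : 4 * F * K*K          input -> state kernels (1 input channel)
//   Wh  : 4 * F * F * K*K      state -> state kernels
//   Pe  : 3 * F * H*W          peepholes Wci, Wcf, Wco (state-shaped)
//   b   : 4 * F
//   gamma, beta : F each       batch-norm affine
//   W1  : Dh * F, b1 : Dh      dense ReLU layer
//   W2  : Dh,     b2 : 1       sigmoid output unit
//
// Frames are stored column-major within a frame (R array semantics):
// element (r, c) of frame t of chunk j sits at
//   x[r + c*H + t*H*W + j*H*W*T].

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

namespace {

struct Layout {
  int T, H, W, F, K, Dh;
  int kk, hw;
  int oWx, oWh, oPe, oB, oGamma, oBeta, oW1, oB1, oW2, oB2, n;
};

Layout makeLayout(const IntegerVector& dims) {
  Layout L;
  L.T = dims[0]; L.H = dims[1]; L.W = dims[2];
  L.F = dims[3]; L.K = dims[4]; L.Dh = dims[5];
  L.kk = L.K * L.K; L.hw = L.H * L.W;
  L.oWx = 0;
  L.oWh = L.oWx + 4 * L.F * L.kk;
  L.oPe = L.oWh + 4 * L.F * L.F * L.kk;
  L.oB  = L.oPe + 3 * L.F * L.hw;
  L.oGamma = L.oB + 4 * L.F;
  L.oBeta  = L.oGamma + L.F;
  L.oW1 = L.oBeta + L.F;
  L.oB1 = L.oW1 + L.Dh * L.F;
  L.oW2 = L.oB1 + L.Dh;
  L.oB2 = L.oW2 + L.Dh;
  L.n   = L.oB2 + 1;
  return L;
}

inline double sigm(double v) { return 1.0 / (1.0 + std::exp(-v)); }

// The three convolution primitives iterate over kernel offsets in the
// outer loops and over the contiguous valid pixel range in the inner loops
// (no per-pixel bounds checks), which lets the compiler vectorize them.
// For offset (u, v) with center c0, output pixel (r, c) pairs with input
// pixel (r + u - c0, c + v - c0); the valid output range is
// r in [max(0, c0-u), min(H, H+c0-u)) and likewise for c.

// out += ker (cross-)correlated with in, same-size zero-padded output.
void convAdd(const double* in, const double* ker, double* out,
             int H, int W, int K) {
  const int c0 = K / 2;
  for (int u = 0; u < K; ++u) {
    const int du = u - c0;
    const int r0 = std::max(0, -du), r1 = std::min(H, H - du);
    for (int v = 0; v < K; ++v) {
      const int dv = v - c0;
      const int cA = std::max(0, -dv), cB = std::min(W, W - dv);
      const double kv = ker[u * K + v];
      if (kv == 0.0) continue;
      for (int c = cA; c < cB; ++c) {
        double* o = out + c * H;
        const double* i = in + (c + dv) * H + du;
        for (int r = r0; r < r1; ++r) o[r] += kv * i[r];
      }
    }
  }
}

// dKer accumulation for the correlation above.
void convKerGrad(const double* in, const double* dout, double* dker,
                 int H, int W, int K) {
  const int c0 = K / 2;
  for (int u = 0; u < K; ++u) {
    const int du = u - c0;
    const int r0 = std::max(0, -du), r1 = std::min(H, H - du);
    for (int v = 0; v < K; ++v) {
      const int dv = v - c0;
      const int cA = std::max(0, -dv), cB = std::min(W, W - dv);
      double s = 0.0;
      for (int c = cA; c < cB; ++c) {
        const double* o = dout + c * H;
        const double* i = in + (c + dv) * H + du;
        for (int r = r0; r < r1; ++r) s += o[r] * i[r];
      }
      dker[u * K + v] += s;
    }
  }
}

// dIn accumulation (transposed correlation).
void convInGrad(const double* dout, const double* ker, double* din,
                int H, int W, int K) {
  const int c0 = K / 2;
  for (int u = 0; u < K; ++u) {
    const int du = u - c0;
    const int r0 = std::max(0, -du), r1 = std::min(H, H - du);
    for (int v = 0; v < K; ++v) {
      const int dv = v - c0;
      const int cA = std::max(0, -dv), cB = std::min(W, W - dv);
      const double kv = ker[u * K + v];
      if (kv == 0.0) continue;
      for (int c = cA; c < cB; ++c) {
        const double* o = dout + c * H;
        double* i = din + (c + dv) * H + du;
        for (int r = r0; r < r1; ++r) i[r] += kv * o[r];
      }
    }
  }
}

// Unroll one chunk, storing gate/state activations for BPTT.
// Buffers (if non-null) are each T*F*hw; pool receives the spatial mean of
// the final hidden state per filter (length F).
void forwardChunk(const double* p, const Layout& L, const double* x,
                  double* Si, double* Sf, double* Sg, double* So,
                  double* SC, double* SH, double* pool) {
  const int F = L.F, hw = L.hw, K = L.K, kk = L.kk;
  const int fhw = F * hw;
  std::vector<double> pre(4 * fhw);
  const double* Wci = p + L.oPe;
  const double* Wcf = Wci + fhw;
  const double* Wco = Wcf + fhw;
  for (int t = 0; t < L.T; ++t) {
    const double* xt = x + (size_t)t * hw;
    const double* Hprev = (t > 0) ? SH + (size_t)(t - 1) * fhw : nullptr;
    const double* Cprev = (t > 0) ? SC + (size_t)(t - 1) * fhw : nullptr;
    for (int g = 0; g < 4; ++g) {
      double* P = pre.data() + g * fhw;
      for (int f = 0; f < F; ++f) {
        const double b = p[L.oB + g * F + f];
        double* Pf = P + f * hw;
        for (int j = 0; j < hw; ++j) Pf[j] = b;
        convAdd(xt, p + L.oWx + (g * F + f) * kk, Pf, L.H, L.W, K);
        if (Hprev) {
          for (int fi = 0; fi < F; ++fi)
            convAdd(Hprev + fi * hw,
                    p + L.oWh + ((g * F + f) * F + fi) * kk,
                    Pf, L.H, L.W, K);
        }
      }
    }
    double* It = Si + (size_t)t * fhw;
    double* Ft = Sf + (size_t)t * fhw;
    double* Gt = Sg + (size_t)t * fhw;
    double* Ot = So + (size_t)t * fhw;
    double* Ct = SC + (size_t)t * fhw;
    double* Ht = SH + (size_t)t * fhw;
    for (int j = 0; j < fhw; ++j) {
      const double cp = Cprev ? Cprev[j] : 0.0;
      const double iv = sigm(pre[0 * fhw + j] + Wci[j] * cp);
      const double fv = sigm(pre[1 * fhw + j] + Wcf[j] * cp);
      const double gv = std::tanh(pre[2 * fhw + j]);
      const double cv = fv * cp + iv * gv;
      const double ov = sigm(pre[3 * fhw + j] + Wco[j] * cv);
      It[j] = iv; Ft[j] = fv; Gt[j] = gv; Ct[j] = cv; Ot[j] = ov;
      Ht[j] = ov * std::tanh(cv);
    }
  }
  const double* Hlast = SH + (size_t)(L.T - 1) * fhw;
  for (int f = 0; f < F; ++f) {
    double s = 0.0;
    for (int j = 0; j < hw; ++j) s += Hlast[f * hw + j];
    pool[f] = s / hw;
  }
}

// BPTT for one chunk; dPool is the gradient w.r.t. the pooled features.
void backwardChunk(const double* p, const Layout& L, const double* x,
                   const double* Si, const double* Sf, const double* Sg,
                   const double* So, const double* SC, const double* SH,
                   const double* dPool, double* grad) {
  const int F = L.F, hw = L.hw, K = L.K, kk = L.kk;
  const int fhw = F * hw;
  const double* Wci = p + L.oPe;
  const double* Wcf = Wci + fhw;
  const double* Wco = Wcf + fhw;
  double* dWci = grad + L.oPe;
  double* dWcf = dWci + fhw;
  double* dWco = dWcf + fhw;
  std::vector<double> dH(fhw, 0.0), dC(fhw, 0.0), dHprev(fhw);
  std::vector<double> dA(4 * fhw);
  for (int f = 0; f < F; ++f) {
    const double v = dPool[f] / hw;
    for (int j = 0; j < hw; ++j) dH[f * hw + j] = v;
  }
  for (int t = L.T - 1; t >= 0; --t) {
    const double* xt = x + (size_t)t * hw;
    const double* It = Si + (size_t)t * fhw;
    const double* Ft = Sf + (size_t)t * fhw;
    const double* Gt = Sg + (size_t)t * fhw;
    const double* Ot = So + (size_t)t * fhw;
    const double* Ct = SC + (size_t)t * fhw;
    const double* Hprev = (t > 0) ? SH + (size_t)(t - 1) * fhw : nullptr;
    const double* Cprev = (t > 0) ? SC + (size_t)(t - 1) * fhw : nullptr;
    std::vector<double> dCprev(fhw, 0.0);
    for (int j = 0; j < fhw; ++j) {
      const double tc = std::tanh(Ct[j]);
      const double ov = Ot[j];
      const double dAo = dH[j] * tc * ov * (1.0 - ov);
      double dc = dC[j] + dH[j] * ov * (1.0 - tc * tc) + dAo * Wco[j];
      dA[3 * fhw + j] = dAo;
      dWco[j] += dAo * Ct[j];
      const double cp = Cprev ? Cprev[j] : 0.0;
      const double iv = It[j], fv = Ft[j], gv = Gt[j];
      const double dAi = dc * gv * iv * (1.0 - iv);
      const double dAf = dc * cp * fv * (1.0 - fv);
      const double dAg = dc * iv * (1.0 - gv * gv);
      dA[0 * fhw + j] = dAi;
      dA[1 * fhw + j] = dAf;
      dA[2 * fhw + j] = dAg;
      dCprev[j] = dc * fv + dAi * Wci[j] + dAf * Wcf[j];
      dWci[j] += dAi * cp;
      dWcf[j] += dAf * cp;
    }
    std::fill(dHprev.begin(), dHprev.end(), 0.0);
    for (int g = 0; g < 4; ++g) {
      const double* dAg = dA.data() + g * fhw;
      for (int f = 0; f < F; ++f) {
        const double* dAf = dAg + f * hw;
        double s = 0.0;
        for (int j = 0; j < hw; ++j) s += dAf[j];
        grad[L.oB + g * F + f] += s;
        convKerGrad(xt, dAf, grad + L.oWx + (g * F + f) * kk, L.H, L.W, K);
        if (Hprev) {
          for (int fi = 0; fi < F; ++fi) {
            convKerGrad(Hprev + fi * hw, dAf,
                        grad + L.oWh + ((g * F + f) * F + fi) * kk,
                        L.H, L.W, K);
            convInGrad(dAf, p + L.oWh + ((g * F + f) * F + fi) * kk,
                       dHprev.data() + fi * hw, L.H, L.W, K);
          }
        }
      }
    }
    std::copy(dHprev.begin(), dHprev.end(), dH.begin());
    std::copy(dCprev.begin(), dCprev.end(), dC.begin());
  }
}

// Dense head on (possibly normalized+masked) features z of one sample.
double headForward(const double* p, const Layout& L, const double* z,
                   double* a1) {
  double logit = p[L.oB2];
  for (int d = 0; d < L.Dh; ++d) {
    double a = p[L.oB1 + d];
    for (int f = 0; f < L.F; ++f) a += p[L.oW1 + d * L.F + f] * z[f];
    a1[d] = a;
    logit += p[L.oW2 + d] * (a > 0.0 ? a : 0.0);
  }
  return sigm(logit);
}

}  // namespace

// [[Rcpp::export]]
int clstmNParamsCpp(IntegerVector dims) {
  return makeLayout(dims).n;
}

// Inference-mode forward: batch norm uses supplied running statistics,
// no dropout. x has dim c(H, W, T, n); returns the n class probabilities.
// [[Rcpp::export]]
NumericVector clstmForwardCpp(NumericVector params, NumericVector x,
                              IntegerVector dims, NumericVector bnMean,
                              NumericVector bnVar) {
  const Layout L = makeLayout(dims);
  if ((int)params.size() != L.n) stop("parameter vector length mismatch");
  const size_t chunkLen = (size_t)L.hw * L.T;
  const int n = x.size() / chunkLen;
  if ((size_t)n * chunkLen != (size_t)x.size()) stop("chunk array length mismatch");
  const size_t fhwT = (size_t)L.F * L.hw * L.T;
  std::vector<double> Si(fhwT), Sf(fhwT), Sg(fhwT), So(fhwT), SC(fhwT), SH(fhwT);
  NumericVector out(n);
  std::vector<double> pool(L.F), z(L.F), a1(L.Dh);
  const double eps = 1e-5;
  for (int j = 0; j < n; ++j) {
    forwardChunk(params.begin(), L, x.begin() + (size_t)j * chunkLen,
                 Si.data(), Sf.data(), Sg.data(), So.data(), SC.data(),
                 SH.data(), pool.data());
    for (int f = 0; f < L.F; ++f) {
      const double xh = (pool[f] - bnMean[f]) / std::sqrt(bnVar[f] + eps);
      z[f] = params[L.oGamma + f] * xh + params[L.oBeta + f];
    }
    out[j] = headForward(params.begin(), L, z.data(), a1.data());
  }
  return out;
}

// Hidden/cell state trajectories for one chunk (oracle comparisons).
// [[Rcpp::export]]
List clstmStatesCpp(NumericVector params, NumericVector x, IntegerVector dims) {
  const Layout L = makeLayout(dims);
  if ((int)params.size() != L.n) stop("parameter vector length mismatch");
  const size_t fhwT = (size_t)L.F * L.hw * L.T;
  NumericVector Si(fhwT), Sf(fhwT), Sg(fhwT), So(fhwT), SC(fhwT), SH(fhwT);
  NumericVector pool(L.F);
  forwardChunk(params.begin(), L, x.begin(), Si.begin(), Sf.begin(),
               Sg.begin(), So.begin(), SC.begin(), SH.begin(), pool.begin());
  IntegerVector dm = IntegerVector::create(L.hw, L.F, L.T);
  Si.attr("dim") = dm; Sf.attr("dim") = dm; Sg.attr("dim") = dm;
  So.attr("dim") = dm; SC.attr("dim") = dm; SH.attr("dim") = dm;
  return List::create(_["i"] = Si, _["f"] = Sf, _["g"] = Sg, _["o"] = So,
                      _["C"] = SC, _["H"] = SH, _["pool"] = pool);
}

// Pooled (pre-batch-norm) features for a batch of chunks: F x n matrix.
// Used to recalibrate batch-norm statistics on the full training set.
// [[Rcpp::export]]
NumericMatrix clstmPoolCpp(NumericVector params, NumericVector x,
                           IntegerVector dims) {
  const Layout L = makeLayout(dims);
  if ((int)params.size() != L.n) stop("parameter vector length mismatch");
  const size_t chunkLen = (size_t)L.hw * L.T;
  const int n = x.size() / chunkLen;
  if ((size_t)n * chunkLen != (size_t)x.size()) stop("chunk array length mismatch");
  const size_t fhwT = (size_t)L.F * L.hw * L.T;
  std::vector<double> Si(fhwT), Sf(fhwT), Sg(fhwT), So(fhwT), SC(fhwT), SH(fhwT);
  NumericMatrix out(L.F, n);
  std::vector<double> pool(L.F);
  for (int j = 0; j < n; ++j) {
    forwardChunk(params.begin(), L, x.begin() + (size_t)j * chunkLen,
                 Si.data(), Sf.data(), Sg.data(), So.data(), SC.data(),
                 SH.data(), pool.data());
    for (int f = 0; f < L.F; ++f) out(f, j) = pool[f];
  }
  return out;
}

// Training-mode loss and full analytic gradient for one minibatch.
// x: dim c(H, W, T, n); y: labels in {0,1}; dropMask: F x n multipliers
// (0 for dropped units, 1/(1-rate) otherwise); l2: weight-decay coefficient
// applied to all convolution, peephole and dense weight tensors.
// [[Rcpp::export]]
List clstmLossGradCpp(NumericVector params, NumericVector x, NumericVector y,
                      IntegerVector dims, NumericVector dropMask, double l2) {
  const Layout L = makeLayout(dims);
  if ((int)params.size() != L.n) stop("parameter vector length mismatch");
  const size_t chunkLen = (size_t)L.hw * L.T;
  const int n = y.size();
  if ((size_t)x.size() != chunkLen * n) stop("chunk array length mismatch");
  if ((int)dropMask.size() != L.F * n) stop("dropout mask length mismatch");
  const double* p = params.begin();
  const size_t fhwT = (size_t)L.F * L.hw * L.T;

  // Activations for every chunk in the batch (needed after batch norm).
  std::vector<double> Si(fhwT * n), Sf(fhwT * n), Sg(fhwT * n),
      So(fhwT * n), SC(fhwT * n), SH(fhwT * n);
  std::vector<double> pool((size_t)L.F * n);
  for (int j = 0; j < n; ++j)
    forwardChunk(p, L, x.begin() + (size_t)j * chunkLen,
                 Si.data() + fhwT * j, Sf.data() + fhwT * j,
                 Sg.data() + fhwT * j, So.data() + fhwT * j,
                 SC.data() + fhwT * j, SH.data() + fhwT * j,
                 pool.data() + (size_t)L.F * j);

  // Batch norm over the minibatch (population variance).
  const double eps = 1e-5;
  NumericVector mu(L.F), var(L.F);
  for (int f = 0; f < L.F; ++f) {
    double m = 0.0;
    for (int j = 0; j < n; ++j) m += pool[f + (size_t)L.F * j];
    m /= n;
    double v = 0.0;
    for (int j = 0; j < n; ++j) {
      const double d = pool[f + (size_t)L.F * j] - m;
      v += d * d;
    }
    mu[f] = m; var[f] = v / n;
  }

  std::vector<double> xhat((size_t)L.F * n), zd((size_t)L.F * n);
  std::vector<double> a1((size_t)L.Dh * n), relu1((size_t)L.Dh * n);
  NumericVector probs(n);
  double loss = 0.0;
  for (int j = 0; j < n; ++j) {
    for (int f = 0; f < L.F; ++f) {
      const size_t ix = f + (size_t)L.F * j;
      xhat[ix] = (pool[ix] - mu[f]) / std::sqrt(var[f] + eps);
      zd[ix] = (p[L.oGamma + f] * xhat[ix] + p[L.oBeta + f]) * dropMask[ix];
    }
    const double pr = headForward(p, L, zd.data() + (size_t)L.F * j,
                                  a1.data() + (size_t)L.Dh * j);
    for (int d = 0; d < L.Dh; ++d) {
      const double a = a1[d + (size_t)L.Dh * j];
      relu1[d + (size_t)L.Dh * j] = (a > 0.0 ? a : 0.0);
    }
    probs[j] = pr;
    const double pc = std::min(std::max(pr, 1e-12), 1.0 - 1e-12);
    loss += -(y[j] * std::log(pc) + (1.0 - y[j]) * std::log(1.0 - pc));
  }
  loss /= n;

  NumericVector grad(L.n);
  double* g = grad.begin();

  // Head backward.
  std::vector<double> dpool((size_t)L.F * n, 0.0);
  std::vector<double> dz((size_t)L.F * n, 0.0);
  for (int j = 0; j < n; ++j) {
    const double dlogit = (probs[j] - y[j]) / n;
    g[L.oB2] += dlogit;
    for (int d = 0; d < L.Dh; ++d) {
      const size_t dx = d + (size_t)L.Dh * j;
      g[L.oW2 + d] += dlogit * relu1[dx];
      const double da = dlogit * p[L.oW2 + d] * (a1[dx] > 0.0 ? 1.0 : 0.0);
      g[L.oB1 + d] += da;
      for (int f = 0; f < L.F; ++f) {
        const size_t ix = f + (size_t)L.F * j;
        g[L.oW1 + d * L.F + f] += da * zd[ix];
        dz[ix] += da * p[L.oW1 + d * L.F + f];
      }
    }
  }
  // Through dropout and batch norm.
  for (int f = 0; f < L.F; ++f) {
    const double sg = std::sqrt(var[f] + eps);
    double sum_dxhat = 0.0, sum_dxhat_xc = 0.0;
    for (int j = 0; j < n; ++j) {
      const size_t ix = f + (size_t)L.F * j;
      const double dzb = dz[ix] * dropMask[ix];  // grad w.r.t. BN output
      g[L.oGamma + f] += dzb * xhat[ix];
      g[L.oBeta + f] += dzb;
      const double dxh = dzb * p[L.oGamma + f];
      sum_dxhat += dxh;
      sum_dxhat_xc += dxh * (pool[ix] - mu[f]);
    }
    const double dvar = sum_dxhat_xc * (-0.5) / (sg * sg * sg);
    double sum_xc = 0.0;
    for (int j = 0; j < n; ++j) sum_xc += pool[f + (size_t)L.F * j] - mu[f];
    const double dmu = -sum_dxhat / sg + dvar * (-2.0) * sum_xc / n;
    for (int j = 0; j < n; ++j) {
      const size_t ix = f + (size_t)L.F * j;
      const double dxh = dz[ix] * dropMask[ix] * p[L.oGamma + f];
      dpool[ix] = dxh / sg + dvar * 2.0 * (pool[ix] - mu[f]) / n + dmu / n;
    }
  }

  // BPTT per chunk.
  for (int j = 0; j < n; ++j)
    backwardChunk(p, L, x.begin() + (size_t)j * chunkLen,
                  Si.data() + fhwT * j, Sf.data() + fhwT * j,
                  Sg.data() + fhwT * j, So.data() + fhwT * j,
                  SC.data() + fhwT * j, SH.data() + fhwT * j,
                  dpool.data() + (size_t)L.F * j, g);

  // L2 penalty on weight tensors (not biases / batch-norm affine).
  if (l2 > 0.0) {
    auto pen = [&](int from, int to) {
      for (int k = from; k < to; ++k) {
        loss += l2 * p[k] * p[k];
        g[k] += 2.0 * l2 * p[k];
      }
    };
    pen(L.oWx, L.oB);            // Wx, Wh, peepholes
    pen(L.oW1, L.oB1);           // W1
    pen(L.oW2, L.oB2);           // W2
  }

  return List::create(_["loss"] = loss, _["grad"] = grad, _["probs"] = probs,
                      _["bnMean"] = mu, _["bnVar"] = var);
}
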