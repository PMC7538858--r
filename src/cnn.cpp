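#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Small convolutional classifier for two-channel 64x64 binary patches:
// three 3x3 conv (pad 1) + ReLU + 2x2 maxpool blocks, global average
// pooling, and a linear head with sigmoid output. Weights live in one flat
// vector; training is plain mini-batch RMSProp on binary cross-entropy.
// All stochastic choices (initial weights, epoch shuffles) are made on the
// R side and passed in, so this code is fully deterministic.

namespace {

struct NetDims {
  int c0, c1, c2, c3;          // channel counts: input, block 1..3
  int s1, s2, s3;              // spatial size entering each conv block
  // flat-weight offsets
  int oW1, ob1, oW2, ob2, oW3, ob3, oWf, obf, total;
  explicit NetDims(IntegerVector channels) {
    c0 = 2; c1 = channels[0]; c2 = channels[1]; c3 = channels[2];
    s1 = 64; s2 = 32; s3 = 16;
    oW1 = 0;               ob1 = oW1 + c1 * c0 * 9;
    oW2 = ob1 + c1;        ob2 = oW2 + c2 * c1 * 9;
    oW3 = ob2 + c2;        ob3 = oW3 + c3 * c2 * 9;
    oWf = ob3 + c3;        obf = oWf + c3;
    total = obf + 1;
  }
};

inline int widx(int o, int c, int di, int dj, int cin) {
  return ((o * cin + c) * 3 + di) * 3 + dj;
}

// 3x3 same-padding convolution; `in` and `out` are channel-major,
// column-major planes of size s*s.
void conv_fwd(const double* in, double* out, const double* w, const double* b,
              int cin, int cout, int s) {
  for (int o = 0; o < cout; ++o) {
    double* op = out + o * s * s;
    for (int j = 0; j < s; ++j)
      for (int i = 0; i < s; ++i)
        op[j * s + i] = b[o];
    for (int c = 0; c < cin; ++c) {
      const double* ip = in + c * s * s;
      for (int di = 0; di < 3; ++di) {
        for (int dj = 0; dj < 3; ++dj) {
          const double wv = w[widx(o, c, di, dj, cin)];
          if (wv == 0.0) continue;
          const int ioff = di - 1, joff = dj - 1;
          const int i0 = std::max(0, -ioff), i1 = std::min(s, s - ioff);
          const int j0 = std::max(0, -joff), j1 = std::min(s, s - joff);
          for (int j = j0; j < j1; ++j) {
            const double* icol = ip + (j + joff) * s + ioff;
            double* ocol = op + j * s;
            for (int i = i0; i < i1; ++i) ocol[i] += wv * icol[i];
          }
        }
      }
    }
  }
}

// Gradient of the same convolution: accumulates dW, db and (optionally)
// the gradient w.r.t. the input.
void conv_bwd(const double* in, const double* dout, double* dw, double* db,
              double* din, const double* w, int cin, int cout, int s) {
  for (int o = 0; o < cout; ++o) {
    const double* dop = dout + o * s * s;
    double acc = 0.0;
    for (int p = 0; p < s * s; ++p) acc += dop[p];
    db[o] += acc;
    for (int c = 0; c < cin; ++c) {
      const double* ip = in + c * s * s;
      double* dip = din ? din + c * s * s : nullptr;
      for (int di = 0; di < 3; ++di) {
        for (int dj = 0; dj < 3; ++dj) {
          const int ioff = di - 1, joff = dj - 1;
          const int i0 = std::max(0, -ioff), i1 = std::min(s, s - ioff);
          const int j0 = std::max(0, -joff), j1 = std::min(s, s - joff);
          double g = 0.0;
          const double wv = w[widx(o, c, di, dj, cin)];
          for (int j = j0; j < j1; ++j) {
            const double* icol = ip + (j + joff) * s + ioff;
            double* dicol = dip ? dip + (j + joff) * s + ioff : nullptr;
            const double* docol = dop + j * s;
            for (int i = i0; i < i1; ++i) {
              g += icol[i] * docol[i];
              if (dicol) dicol[i] += wv * docol[i];
            }
          }
          dw[widx(o, c, di, dj, cin)] += g;
        }
      }
    }
  }
}

// ReLU + 2x2 maxpool; records the flat argmax position per output cell.
void relu_pool_fwd(const double* z, double* out, int* arg, int cc, int s) {
  const int h = s / 2;
  for (int c = 0; c < cc; ++c) {
    const double* zp = z + c * s * s;
    for (int j = 0; j < h; ++j) {
      for (int i = 0; i < h; ++i) {
        double best = 0.0;
        int bestp = (2 * j) * s + 2 * i;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int p = (2 * j + dj) * s + (2 * i + di);
            const double a = zp[p] > 0.0 ? zp[p] : 0.0;
            if (a > best) { best = a; bestp = p; }
          }
        out[c * h * h + j * h + i] = best;
        arg[c * h * h + j * h + i] = bestp;
      }
    }
  }
}

void relu_pool_bwd(const double* z, const double* dout, const int* arg,
                   double* dz, int cc, int s) {
  const int h = s / 2;
  std::fill(dz, dz + cc * s * s, 0.0);
  for (int c = 0; c < cc; ++c) {
    for (int p = 0; p < h * h; ++p) {
      const int q = arg[c * h * h + p];
      if (z[c * s * s + q] > 0.0) dz[c * s * s + q] += dout[c * h * h + p];
    }
  }
}

struct Workspace {
  std::vector<double> z1, p1, z2, p2, z3, p3, g;
  std::vector<double> dz1, dp1, dz2, dp2, dz3, dp3;
  std::vector<int> a1, a2, a3;
  explicit Workspace(const NetDims& d)
      : z1(d.c1 * 64 * 64), p1(d.c1 * 32 * 32), z2(d.c2 * 32 * 32),
        p2(d.c2 * 16 * 16), z3(d.c3 * 16 * 16), p3(d.c3 * 8 * 8), g(d.c3),
        dz1(d.c1 * 64 * 64), dp1(d.c1 * 32 * 32), dz2(d.c2 * 32 * 32),
        dp2(d.c2 * 16 * 16), dz3(d.c3 * 16 * 16), dp3(d.c3 * 8 * 8),
        a1(d.c1 * 32 * 32), a2(d.c2 * 16 * 16), a3(d.c3 * 8 * 8) {}
};

// Forward pass for one patch; returns prob_poor.
double forward(const double* x, const double* w, const NetDims& d,
               Workspace& ws) {
  conv_fwd(x, ws.z1.data(), w + d.oW1, w + d.ob1, d.c0, d.c1, 64);
  relu_pool_fwd(ws.z1.data(), ws.p1.data(), ws.a1.data(), d.c1, 64);
  conv_fwd(ws.p1.data(), ws.z2.data(), w + d.oW2, w + d.ob2, d.c1, d.c2, 32);
  relu_pool_fwd(ws.z2.data(), ws.p2.data(), ws.a2.data(), d.c2, 32);
  conv_fwd(ws.p2.data(), ws.z3.data(), w + d.oW3, w + d.ob3, d.c2, d.c3, 16);
  relu_pool_fwd(ws.z3.data(), ws.p3.data(), ws.a3.data(), d.c3, 16);
  double z = w[d.obf];
  for (int c = 0; c < d.c3; ++c) {
    double m = 0.0;
    for (int p = 0; p < 64; ++p) m += ws.p3[c * 64 + p];
    ws.g[c] = m / 64.0;
    z += w[d.oWf + c] * ws.g[c];
  }
  return 1.0 / (1.0 + std::exp(-z));
}

// Backward pass (forward state must be in ws); accumulates into grad.
void backward(const double* x, double dz, const double* w, const NetDims& d,
              Workspace& ws, double* grad) {
  grad[d.obf] += dz;
  for (int c = 0; c < d.c3; ++c) {
    grad[d.oWf + c] += dz * ws.g[c];
    const double dg = dz * w[d.oWf + c] / 64.0;
    for (int p = 0; p < 64; ++p) ws.dp3[c * 64 + p] = dg;
  }
  relu_pool_bwd(ws.z3.data(), ws.dp3.data(), ws.a3.data(), ws.dz3.data(),
                d.c3, 16);
  std::fill(ws.dp2.begin(), ws.dp2.end(), 0.0);
  conv_bwd(ws.p2.data(), ws.dz3.data(), grad + d.oW3, grad + d.ob3,
           ws.dp2.data(), w + d.oW3, d.c2, d.c3, 16);
  relu_pool_bwd(ws.z2.data(), ws.dp2.data(), ws.a2.data(), ws.dz2.data(),
                d.c2, 32);
  std::fill(ws.dp1.begin(), ws.dp1.end(), 0.0);
  conv_bwd(ws.p1.data(), ws.dz2.data(), grad + d.oW2, grad + d.ob2,
           ws.dp1.data(), w + d.oW2, d.c1, d.c2, 32);
  relu_pool_bwd(ws.z1.data(), ws.dp1.data(), ws.a1.data(), ws.dz1.data(),
                d.c1, 64);
  conv_bwd(x, ws.dz1.data(), grad + d.oW1, grad + d.ob1, nullptr, w + d.oW1,
           d.c0, d.c1, 64);
}

}  // namespace

// [[Rcpp::export]]
int cnn_n_weights_cpp(IntegerVector channels) {
  return NetDims(channels).total;
}

// [[Rcpp::export]]
NumericVector cnn_predict_cpp(const NumericMatrix& X, const NumericVector& w,
                              IntegerVector channels) {
  NetDims d(channels);
  if ((int)w.size() != d.total) stop("weight vector has wrong length");
  if (X.ncol() != 2 * 64 * 64) stop("patches must be 2x64x64 (8192 columns)");
  Workspace ws(d);
  const int n = X.nrow();
  NumericVector out(n);
  std::vector<double> x(2 * 64 * 64);
  for (int r = 0; r < n; ++r) {
    for (int k = 0; k < 8192; ++k) x[k] = X(r, k);
    out[r] = forward(x.data(), &w[0], d, ws);
  }
  return out;
}

// Mini-batch RMSProp training.  `order` holds one 1-based permutation of
// the training rows per epoch (epochs x n); learning rate is multiplied by
// lr_factor every factor_epoch epochs.
// [[Rcpp::export]]
List cnn_train_cpp(const NumericMatrix& X, const NumericVector& y,
                   NumericVector w0, IntegerVector channels,
                   const IntegerMatrix& order, double lr, double lr_factor,
                   int factor_epoch, double weight_decay, int batch_size,
                   double rho, double eps) {
  NetDims d(channels);
  if ((int)w0.size() != d.total) stop("weight vector has wrong length");
  const int n = X.nrow();
  if ((int)y.size() != n || order.ncol() != n)
    stop("y/order do not match the number of patches");
  const int epochs = order.nrow();
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> grad(d.total), cache(d.total, 0.0);
  std::vector<double> x(8192);
  Workspace ws(d);
  NumericVector ep_loss(epochs), ep_acc(epochs);

  for (int e = 0; e < epochs; ++e) {
    const double lr_e = lr * std::pow(lr_factor, e / factor_epoch);
    double loss_sum = 0.0;
    int correct = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int bs = std::min(batch_size, n - start);
      std::fill(grad.begin(), grad.end(), 0.0);
      for (int b = 0; b < bs; ++b) {
        const int r = order(e, start + b) - 1;
        for (int k = 0; k < 8192; ++k) x[k] = X(r, k);
        const double p = forward(x.data(), w.data(), d, ws);
        const double yr = y[r];
        const double pc = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
        loss_sum += -(yr * std::log(pc) + (1.0 - yr) * std::log(1.0 - pc));
        if ((p > 0.5 ? 1.0 : 0.0) == yr) ++correct;
        backward(x.data(), (p - yr) / bs, w.data(), d, ws, grad.data());
      }
      for (int k = 0; k < d.total; ++k) {
        const double g = grad[k] + weight_decay * w[k];
        cache[k] = rho * cache[k] + (1.0 - rho) * g * g;
        w[k] -= lr_e * g / (std::sqrt(cache[k]) + eps);
      }
    }
    ep_loss[e] = loss_sum / n;
    ep_acc[e] = (double)correct / n;
    if (!std::isfinite(ep_loss[e]))
      stop("training diverged: non-finite loss at epoch %d (lr = %g)", e + 1,
           lr_e);
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["epoch_loss"] = ep_loss, _["epoch_accuracy"] = ep_acc);
}
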