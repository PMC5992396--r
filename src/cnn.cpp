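// Convolutional network used for braking-intention classification.
//
// Topology (fixed two conv/pool stages + one hidden dense layer):
//   input 1 x H x W -> conv k x k SAME (K1 kernels, ReLU) -> maxpool 2x2
//   (ceiling) -> conv SAME (K2 kernels, ReLU) -> maxpool -> flatten ->
//   dense hidden (sigmoid) -> dense 2 (softmax).
// Training: plain SGD on softmax cross-entropy; per-step batches are a
// fixed fraction of the training set; inverted dropout on both pooled conv
// stages and the dense hidden layer. All randomness comes from a local
// xorshift64* generator seeded from R, so runs are bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Xorshift {
  uint64_t s;
  explicit Xorshift(uint64_t seed) {
    s = seed * 2862933555777941757ULL + 3037000493ULL;
    if (s == 0) s = 88172645463325252ULL;
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  uint32_t below(uint32_t n) { return (uint32_t)(unif() * n) % n; }
};

struct ConvGeom {
  int H, W, C, k, Hp, Wp, npos, patch;
  // idx(p, q): linear index into a (C*H*W) activation row, or -1 for pad
  arma::imat idx;
};

// SAME padding, stride 1: pad_beg = floor((k-1)/2)
ConvGeom make_geom(int H, int W, int C, int k) {
  ConvGeom g;
  g.H = H; g.W = W; g.C = C; g.k = k;
  g.Hp = (H + 1) / 2; g.Wp = (W + 1) / 2;
  g.npos = H * W; g.patch = C * k * k;
  int pad = (k - 1) / 2;
  g.idx.set_size(g.npos, g.patch);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int p = i + j * H;
      for (int c = 0; c < C; ++c) {
        for (int n = 0; n < k; ++n) {
          for (int m = 0; m < k; ++m) {
            int q = c * k * k + n * k + m;
            int ii = i + m - pad, jj = j + n - pad;
            g.idx(p, q) = (ii >= 0 && ii < H && jj >= 0 && jj < W)
              ? c * H * W + jj * H + ii : -1;
          }
        }
      }
    }
  }
  return g;
}

// gather patches for a batch: A is nb x (C*H*W), result (nb*npos) x patch
arma::mat im2col(const arma::mat& A, const ConvGeom& g) {
  const int nb = A.n_rows;
  arma::mat P(nb * g.npos, g.patch);
  for (int q = 0; q < g.patch; ++q) {
    for (int p = 0; p < g.npos; ++p) {
      long src = g.idx(p, q);
      double* dst = P.colptr(q) + (size_t)p * nb;
      if (src < 0) {
        for (int b = 0; b < nb; ++b) dst[b] = 0.0;
      } else {
        const double* a = A.colptr(src);
        for (int b = 0; b < nb; ++b) dst[b] = a[b];
      }
    }
  }
  return P;
}

// scatter-add gradient of patches back onto the activation layout
void col2im(const arma::mat& dP, const ConvGeom& g, arma::mat& dA) {
  const int nb = dA.n_rows;
  for (int q = 0; q < g.patch; ++q) {
    for (int p = 0; p < g.npos; ++p) {
      long src = g.idx(p, q);
      if (src < 0) continue;
      const double* d = dP.colptr(q) + (size_t)p * nb;
      double* a = dA.colptr(src);
      for (int b = 0; b < nb; ++b) a[b] += d[b];
    }
  }
}

// 2x2 ceiling-mode max pooling over Z laid out (nb*npos) x K (position
// p = i + j*H within each instance block). Output nb x (K*Hp*Wp);
// amax records the winning row of Z for backprop.
void maxpool(const arma::mat& Z, const ConvGeom& g, int nb,
             arma::mat& out, arma::umat& amax) {
  const int K = Z.n_cols;
  out.set_size(nb, K * g.Hp * g.Wp);
  amax.set_size(nb, K * g.Hp * g.Wp);
  for (int c = 0; c < K; ++c) {
    const double* z = Z.colptr(c);
    for (int jj = 0; jj < g.Wp; ++jj) {
      for (int ii = 0; ii < g.Hp; ++ii) {
        int oc = c * g.Hp * g.Wp + jj * g.Hp + ii;
        for (int b = 0; b < nb; ++b) {
          double best = -1e300; size_t bestrow = 0;
          for (int dj = 0; dj < 2; ++dj) {
            int j = 2 * jj + dj; if (j >= g.W) continue;
            for (int di = 0; di < 2; ++di) {
              int i = 2 * ii + di; if (i >= g.H) continue;
              size_t row = (size_t)(i + j * g.H) * nb + b;
              if (z[row] > best) { best = z[row]; bestrow = row; }
            }
          }
          out(b, oc) = best;
          amax(b, oc) = bestrow;
        }
      }
    }
  }
}

struct Params {
  arma::mat W1, W2, Wd, Wo;
  arma::rowvec b1, b2, bd, bo;
};

Params params_from_list(const List& pl) {
  Params P;
  P.W1 = as<arma::mat>(pl["W1"]); P.W2 = as<arma::mat>(pl["W2"]);
  P.Wd = as<arma::mat>(pl["Wd"]); P.Wo = as<arma::mat>(pl["Wo"]);
  P.b1 = as<arma::rowvec>(pl["b1"]); P.b2 = as<arma::rowvec>(pl["b2"]);
  P.bd = as<arma::rowvec>(pl["bd"]); P.bo = as<arma::rowvec>(pl["bo"]);
  return P;
}

List params_to_list(const Params& P) {
  return List::create(_["W1"] = P.W1, _["b1"] = P.b1,
                      _["W2"] = P.W2, _["b2"] = P.b2,
                      _["Wd"] = P.Wd, _["bd"] = P.bd,
                      _["Wo"] = P.Wo, _["bo"] = P.bo);
}

// rows of X are channel-major feature vectors x[(ch)*W + j]; the input map
// I(i=ch, j) is stored col-major as j*H + i.
arma::mat input_layout(const arma::mat& X, int H, int W) {
  arma::mat A(X.n_rows, H * W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j)
      A.col(j * H + i) = X.col(i * W + j);
  return A;
}

struct ForwardCache {
  arma::mat P1, S1, A1, P2, S2, A2, Hpre, Hs, A3, Pr;
  arma::umat am1, am2;
  arma::mat M1, M2, M3;  // dropout masks (already scaled)
};

// forward pass; when training, rng supplies dropout masks
void forward(const arma::mat& Xin, const Params& P,
             const ConvGeom& g1, const ConvGeom& g2,
             double r_conv, double r_dense, bool train, Xorshift* rng,
             ForwardCache& fc) {
  const int nb = Xin.n_rows;
  fc.P1 = im2col(Xin, g1);
  fc.S1 = fc.P1 * P.W1;
  fc.S1.each_row() += P.b1;
  fc.S1 = arma::clamp(fc.S1, 0.0, arma::datum::inf);  // ReLU
  arma::mat pooled1;
  maxpool(fc.S1, g1, nb, pooled1, fc.am1);
  if (train && r_conv < 1.0) {
    fc.M1.set_size(arma::size(pooled1));
    for (arma::uword t = 0; t < fc.M1.n_elem; ++t)
      fc.M1(t) = rng->unif() < r_conv ? 1.0 / r_conv : 0.0;
    fc.A1 = pooled1 % fc.M1;
  } else {
    fc.A1 = pooled1;
  }
  fc.P2 = im2col(fc.A1, g2);
  fc.S2 = fc.P2 * P.W2;
  fc.S2.each_row() += P.b2;
  fc.S2 = arma::clamp(fc.S2, 0.0, arma::datum::inf);
  arma::mat pooled2;
  maxpool(fc.S2, g2, nb, pooled2, fc.am2);
  if (train && r_conv < 1.0) {
    fc.M2.set_size(arma::size(pooled2));
    for (arma::uword t = 0; t < fc.M2.n_elem; ++t)
      fc.M2(t) = rng->unif() < r_conv ? 1.0 / r_conv : 0.0;
    fc.A2 = pooled2 % fc.M2;
  } else {
    fc.A2 = pooled2;
  }
  fc.Hpre = fc.A2 * P.Wd;
  fc.Hpre.each_row() += P.bd;
  fc.Hs = 1.0 / (1.0 + arma::exp(-fc.Hpre));
  if (train && r_dense < 1.0) {
    fc.M3.set_size(arma::size(fc.Hs));
    for (arma::uword t = 0; t < fc.M3.n_elem; ++t)
      fc.M3(t) = rng->unif() < r_dense ? 1.0 / r_dense : 0.0;
    fc.A3 = fc.Hs % fc.M3;
  } else {
    fc.A3 = fc.Hs;
  }
  arma::mat O = fc.A3 * P.Wo;
  O.each_row() += P.bo;
  O.each_col() -= arma::max(O, 1);
  fc.Pr = arma::exp(O);
  fc.Pr.each_col() /= arma::sum(fc.Pr, 1);
}

}  // namespace

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
arma::mat cnn_predict_cpp(const arma::mat& X, const List& params,
                          const List& cfg) {
  const int H = cfg["H"], W = cfg["W"], k = cfg["k"];
  const int K1 = cfg["K1"];
  Params P = params_from_list(params);
  ConvGeom g1 = make_geom(H, W, 1, k);
  ConvGeom g2 = make_geom(g1.Hp, g1.Wp, K1, k);
  ForwardCache fc;
  arma::mat Xin = input_layout(X, H, W);
  forward(Xin, P, g1, g2, 1.0, 1.0, false, nullptr, fc);
  return fc.Pr;
}

// [[Rcpp::export(name = ".cnn_activations_cpp")]]
List cnn_activations_cpp(const arma::mat& X, const List& params,
                         const List& cfg) {
  const int H = cfg["H"], W = cfg["W"], k = cfg["k"];
  const int K1 = cfg["K1"], K2 = cfg["K2"];
  Params P = params_from_list(params);
  ConvGeom g1 = make_geom(H, W, 1, k);
  ConvGeom g2 = make_geom(g1.Hp, g1.Wp, K1, k);
  ForwardCache fc;
  arma::mat Xin = input_layout(X, H, W);
  const int nb = X.n_rows;
  // pre-activation (linear) stage-1 maps for oracle comparison
  arma::mat P1 = im2col(Xin, g1);
  arma::mat C1 = P1 * P.W1;
  C1.each_row() += P.b1;
  forward(Xin, P, g1, g2, 1.0, 1.0, false, nullptr, fc);
  return List::create(
    _["conv1_pre"] = C1,             // (nb*H*W) x K1, p = i + j*H
    _["stage1_dims"] = IntegerVector::create(K1, g1.Hp, g1.Wp),
    _["stage2_dims"] = IntegerVector::create(K2, g2.Hp, g2.Wp),
    _["pool1"] = fc.A1,              // nb x (K1*Hp1*Wp1)
    _["pool2"] = fc.A2,              // nb x (K2*Hp2*Wp2)
    _["hidden"] = fc.Hs,
    _["probs"] = fc.Pr,
    _["nb"] = nb);
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(const arma::mat& X, const arma::ivec& y01,
                   const List& params0, const List& cfg,
                   int seed, bool record_history) {
  const int H = cfg["H"], W = cfg["W"], k = cfg["k"];
  const int K1 = cfg["K1"];
  const int steps = cfg["steps"];
  const double lr = cfg["lr"];
  const double batch_frac = cfg["batch_fraction"];
  const double r_conv = cfg["r_conv"], r_dense = cfg["r_dense"];

  Params P = params_from_list(params0);
  ConvGeom g1 = make_geom(H, W, 1, k);
  ConvGeom g2 = make_geom(g1.Hp, g1.Wp, K1, k);

  const int n = X.n_rows;
  int nb = std::max(2, (int)std::round(batch_frac * n));
  if (nb > n) nb = n;
  arma::mat Xin = input_layout(X, H, W);

  Xorshift rng((uint64_t)seed);
  std::vector<int> order(n);
  NumericVector hist_loss(record_history ? steps : 0);
  NumericVector hist_val(record_history ? steps : 0);

  ForwardCache fc;
  for (int step = 0; step < steps; ++step) {
    // sample a batch without replacement
    for (int i = 0; i < n; ++i) order[i] = i;
    for (int i = 0; i < nb; ++i) {
      int j = i + (int)rng.below((uint32_t)(n - i));
      std::swap(order[i], order[j]);
    }
    arma::uvec bidx(nb);
    for (int i = 0; i < nb; ++i) bidx[i] = order[i];
    arma::mat Xb = Xin.rows(bidx);
    forward(Xb, P, g1, g2, r_conv, r_dense, true, &rng, fc);

    // softmax cross-entropy gradient
    arma::mat dO = fc.Pr;
    double loss = 0.0;
    for (int b = 0; b < nb; ++b) {
      int cls = y01[bidx[b]];
      dO(b, cls) -= 1.0;
      loss -= std::log(std::max(fc.Pr(b, cls), 1e-12));
    }
    loss /= nb;
    dO /= nb;

    arma::mat dWo = fc.A3.t() * dO;
    arma::rowvec dbo = arma::sum(dO, 0);
    arma::mat dA3 = dO * P.Wo.t();
    if (r_dense < 1.0) dA3 %= fc.M3;
    arma::mat dHpre = dA3 % fc.Hs % (1.0 - fc.Hs);
    arma::mat dWd = fc.A2.t() * dHpre;
    arma::rowvec dbd = arma::sum(dHpre, 0);
    arma::mat dA2 = dHpre * P.Wd.t();
    if (r_conv < 1.0) dA2 %= fc.M2;

    // back through pool2 -> relu2 -> conv2
    arma::mat dS2((size_t)g2.npos * nb, P.W2.n_cols, arma::fill::zeros);
    for (arma::uword c = 0; c < dA2.n_cols; ++c) {
      int ch = c / (g2.Hp * g2.Wp);
      for (int b = 0; b < nb; ++b) {
        dS2(fc.am2(b, c), ch) += dA2(b, c);
      }
    }
    dS2 %= arma::conv_to<arma::mat>::from(fc.S2 > 0);
    arma::mat dW2 = fc.P2.t() * dS2;
    arma::rowvec db2 = arma::sum(dS2, 0);
    arma::mat dP2 = dS2 * P.W2.t();
    arma::mat dA1(nb, g2.C * g2.H * g2.W, arma::fill::zeros);
    col2im(dP2, g2, dA1);
    if (r_conv < 1.0) dA1 %= fc.M1;

    // back through pool1 -> relu1 -> conv1
    arma::mat dS1((size_t)g1.npos * nb, P.W1.n_cols, arma::fill::zeros);
    for (arma::uword c = 0; c < dA1.n_cols; ++c) {
      int ch = c / (g1.Hp * g1.Wp);
      for (int b = 0; b < nb; ++b) {
        dS1(fc.am1(b, c), ch) += dA1(b, c);
      }
    }
    dS1 %= arma::conv_to<arma::mat>::from(fc.S1 > 0);
    arma::mat dW1 = fc.P1.t() * dS1;
    arma::rowvec db1 = arma::sum(dS1, 0);

    P.Wo -= lr * dWo; P.bo -= lr * dbo;
    P.Wd -= lr * dWd; P.bd -= lr * dbd;
    P.W2 -= lr * dW2; P.b2 -= lr * db2;
    P.W1 -= lr * dW1; P.b1 -= lr * db1;

    if (record_history) {
      hist_loss[step] = loss;
      // validation = the rest of the training set this step
      int nv = n - nb;
      double acc = NA_REAL;
      if (nv > 0) {
        arma::uvec vidx(nv);
        for (int i = 0; i < nv; ++i) vidx[i] = order[nb + i];
        ForwardCache vc;
        arma::mat Xv = Xin.rows(vidx);
        forward(Xv, P, g1, g2, 1.0, 1.0, false, nullptr, vc);
        int ok = 0;
        for (int b = 0; b < nv; ++b) {
          int pred = vc.Pr(b, 1) > vc.Pr(b, 0) ? 1 : 0;
          if (pred == y01[vidx[b]]) ++ok;
        }
        acc = (double)ok / nv;
      }
      hist_val[step] = acc;
    }
  }

  List out = params_to_list(P);
  return List::create(_["params"] = out,
                      _["loss"] = hist_loss,
                      _["val_acc"] = hist_val);
}
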