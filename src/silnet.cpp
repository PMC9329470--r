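// Minimal multi-task convolutional regression engine.
//
// Architecture: a stack of (3x3 conv, pad 1) + ReLU + (2x2 average pool,
// stride 2) blocks, followed by a fully connected ReLU layer and a linear
// head with one output per task. Trained with Adam on a weighted
// mean-squared-error over standardized targets. Single-threaded and
// deterministic given the seed.
//
// Image layout: one column per sample, flattened as (h + H*w + H*W*c),
// i.e. row-fastest within a channel plane, channels outermost.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>
using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::fvec;

namespace {

struct Arch {
  int H, W, C0, dense, tasks;
  std::vector<int> channels;
  fvec loss_w;
};

Arch parse_arch(const List& arch) {
  Arch a;
  a.H = as<int>(arch["H"]);
  a.W = as<int>(arch["W"]);
  a.C0 = as<int>(arch["C0"]);
  a.dense = as<int>(arch["dense"]);
  a.tasks = as<int>(arch["tasks"]);
  IntegerVector ch = arch["channels"];
  a.channels.assign(ch.begin(), ch.end());
  NumericVector lw = arch["loss_weights"];
  a.loss_w = arma::conv_to<fvec>::from(as<arma::vec>(lw));
  return a;
}

struct Weights {
  std::vector<fmat> cw;  // conv weights, C_out x (C_in*9)
  std::vector<fvec> cb;  // conv biases
  fmat dw; fvec db;      // dense
  fmat hw; fvec hb;      // heads
};

Weights parse_weights(const List& w) {
  Weights ww;
  List cw = w["conv_W"], cb = w["conv_b"];
  for (int i = 0; i < cw.size(); ++i) {
    ww.cw.push_back(arma::conv_to<fmat>::from(as<arma::mat>(cw[i])));
    ww.cb.push_back(arma::conv_to<fvec>::from(as<arma::vec>(cb[i])));
  }
  ww.dw = arma::conv_to<fmat>::from(as<arma::mat>(w["dense_W"]));
  ww.db = arma::conv_to<fvec>::from(as<arma::vec>(w["dense_b"]));
  ww.hw = arma::conv_to<fmat>::from(as<arma::mat>(w["head_W"]));
  ww.hb = arma::conv_to<fvec>::from(as<arma::vec>(w["head_b"]));
  return ww;
}

List weights_to_list(const Weights& w) {
  List cw(w.cw.size()), cb(w.cb.size());
  for (size_t i = 0; i < w.cw.size(); ++i) {
    cw[i] = wrap(arma::conv_to<arma::mat>::from(w.cw[i]));
    cb[i] = wrap(arma::conv_to<arma::vec>::from(w.cb[i]));
  }
  return List::create(_["conv_W"] = cw, _["conv_b"] = cb,
                      _["dense_W"] = wrap(arma::conv_to<arma::mat>::from(w.dw)),
                      _["dense_b"] = wrap(arma::conv_to<arma::vec>::from(w.db)),
                      _["head_W"] = wrap(arma::conv_to<arma::mat>::from(w.hw)),
                      _["head_b"] = wrap(arma::conv_to<arma::vec>::from(w.hb)));
}

// im2col for 3x3 kernels with zero padding 1, transposed layout:
// cols is (HW*B) x (C*9), so the inner h-loop writes contiguously.
void im2col(const fmat& A, int C, int H, int W, fmat& cols) {
  const int B = A.n_cols, HW = H * W;
  cols.zeros(static_cast<size_t>(HW) * B, C * 9);
  for (int c = 0; c < C; ++c) {
    for (int kw = -1; kw <= 1; ++kw) {
      for (int kh = -1; kh <= 1; ++kh) {
        const int kcol = c * 9 + (kw + 1) * 3 + (kh + 1);
        float* dcol = cols.colptr(kcol);
        for (int b = 0; b < B; ++b) {
          const float* src = A.colptr(b) + c * HW;
          float* dst = dcol + static_cast<size_t>(b) * HW;
          for (int w = 0; w < W; ++w) {
            const int ws = w + kw;
            if (ws < 0 || ws >= W) continue;
            const float* s = src + ws * H + kh;
            float* d = dst + w * H;
            const int h0 = std::max(0, -kh), h1 = std::min(H, H - kh);
            for (int h = h0; h < h1; ++h) d[h] = s[h];
          }
        }
      }
    }
  }
}

// Transpose of im2col: scatter-add column gradients back to image layout.
void col2im(const fmat& dcols, int C, int H, int W, fmat& dA) {
  const int B = dA.n_cols, HW = H * W;
  dA.zeros();
  for (int c = 0; c < C; ++c) {
    for (int kw = -1; kw <= 1; ++kw) {
      for (int kh = -1; kh <= 1; ++kh) {
        const int kcol = c * 9 + (kw + 1) * 3 + (kh + 1);
        const float* scol = dcols.colptr(kcol);
        for (int b = 0; b < B; ++b) {
          float* dst = dA.colptr(b) + c * HW;
          const float* src = scol + static_cast<size_t>(b) * HW;
          for (int w = 0; w < W; ++w) {
            const int ws = w + kw;
            if (ws < 0 || ws >= W) continue;
            float* d = dst + ws * H + kh;
            const float* s = src + w * H;
            const int h0 = std::max(0, -kh), h1 = std::min(H, H - kh);
            for (int h = h0; h < h1; ++h) d[h] += s[h];
          }
        }
      }
    }
  }
}

// Reshape conv output Z (HW*B x C, row = (b, position)) to image layout
// (C*HW x B).
void conv_to_img(const fmat& Z, int C, int HW, fmat& img) {
  const int B = img.n_cols;
  for (int c = 0; c < C; ++c) {
    const float* src = Z.colptr(c);
    for (int b = 0; b < B; ++b)
      std::copy(src + static_cast<size_t>(b) * HW,
                src + static_cast<size_t>(b) * HW + HW,
                img.colptr(b) + c * HW);
  }
}

void img_to_conv(const fmat& img, int C, int HW, fmat& Z) {
  const int B = img.n_cols;
  for (int c = 0; c < C; ++c) {
    float* dst = Z.colptr(c);
    for (int b = 0; b < B; ++b)
      std::copy(img.colptr(b) + c * HW, img.colptr(b) + (c + 1) * HW,
                dst + static_cast<size_t>(b) * HW);
  }
}

// 2x2 average pooling, stride 2, remainder rows/cols dropped.
void pool_fwd(const fmat& A, int C, int H, int W, fmat& out) {
  const int B = A.n_cols, Ho = H / 2, Wo = W / 2, HW = H * W, HWo = Ho * Wo;
  out.set_size(static_cast<size_t>(C) * HWo, B);
  for (int b = 0; b < B; ++b) {
    const float* src = A.colptr(b);
    float* dst = out.colptr(b);
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const float* s = src + c * HW + (2 * wo) * H + 2 * ho;
          dst[c * HWo + wo * Ho + ho] =
            0.25f * (s[0] + s[1] + s[H] + s[H + 1]);
        }
  }
}

void pool_bwd(const fmat& dout, int C, int H, int W, fmat& dA) {
  const int B = dout.n_cols, Ho = H / 2, Wo = W / 2, HW = H * W, HWo = Ho * Wo;
  dA.zeros(static_cast<size_t>(C) * HW, B);
  for (int b = 0; b < B; ++b) {
    const float* src = dout.colptr(b);
    float* dst = dA.colptr(b);
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const float g = 0.25f * src[c * HWo + wo * Ho + ho];
          float* d = dst + c * HW + (2 * wo) * H + 2 * ho;
          d[0] += g; d[1] += g; d[H] += g; d[H + 1] += g;
        }
  }
}

struct Cache {
  std::vector<fmat> cols, zrelu, pooled;
  std::vector<int> Hs, Ws;  // dims entering each block
  fmat dense_in, dense_act;
};

fmat forward(const Weights& w, const Arch& a, const fmat& X, Cache* cache) {
  const int nb = static_cast<int>(w.cw.size());
  fmat cur = X;
  int H = a.H, W = a.W, C = a.C0;
  Cache local;
  Cache& cc = cache ? *cache : local;
  cc.cols.resize(nb); cc.zrelu.resize(nb); cc.pooled.resize(nb);
  cc.Hs.resize(nb); cc.Ws.resize(nb);
  for (int i = 0; i < nb; ++i) {
    cc.Hs[i] = H; cc.Ws[i] = W;
    const int HW = H * W, Cout = w.cw[i].n_rows;
    im2col(cur, C, H, W, cc.cols[i]);
    fmat Z = cc.cols[i] * w.cw[i].t();  // (HW*B) x Cout
    Z.each_row() += w.cb[i].t();
    Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    cc.zrelu[i] = Z;
    fmat img(static_cast<size_t>(Cout) * HW, cur.n_cols);
    conv_to_img(Z, Cout, HW, img);
    pool_fwd(img, Cout, H, W, cc.pooled[i]);
    cur = cc.pooled[i];
    H /= 2; W /= 2; C = Cout;
  }
  cc.dense_in = cur;
  fmat Zd = w.dw * cur;
  Zd.each_col() += w.db;
  Zd.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  cc.dense_act = Zd;
  fmat Yh = w.hw * Zd;
  Yh.each_col() += w.hb;
  return Yh;
}

struct Grads {
  std::vector<fmat> cw; std::vector<fvec> cb;
  fmat dw; fvec db; fmat hw; fvec hb;
};

float backward(const Weights& w, const Arch& a, const Cache& cc,
               const fmat& Yh, const fmat& Y, Grads& g) {
  const int B = Y.n_cols, T = a.tasks;
  fmat diff = Yh - Y;
  fmat wdiff = diff;
  wdiff.each_col() %= a.loss_w;
  const float loss = arma::accu(wdiff % diff) / (B * T);
  fmat dYh = 2.0f * wdiff / (B * T);

  g.hw = dYh * cc.dense_act.t();
  g.hb = arma::sum(dYh, 1);
  fmat dAd = w.hw.t() * dYh;
  dAd.elem(arma::find(cc.dense_act <= 0.0f)).zeros();
  g.dw = dAd * cc.dense_in.t();
  g.db = arma::sum(dAd, 1);
  fmat dcur = w.dw.t() * dAd;

  const int nb = static_cast<int>(w.cw.size());
  g.cw.resize(nb); g.cb.resize(nb);
  for (int i = nb - 1; i >= 0; --i) {
    const int H = cc.Hs[i], W = cc.Ws[i], HW = H * W;
    const int Cout = w.cw[i].n_rows;
    const int Cin = w.cw[i].n_cols / 9;
    fmat dimg;
    pool_bwd(dcur, Cout, H, W, dimg);
    fmat dZ(static_cast<size_t>(HW) * B, Cout);
    img_to_conv(dimg, Cout, HW, dZ);
    dZ.elem(arma::find(cc.zrelu[i] <= 0.0f)).zeros();
    g.cw[i] = dZ.t() * cc.cols[i];
    g.cb[i] = arma::sum(dZ, 0).t();
    if (i > 0) {
      fmat dcols = dZ * w.cw[i];
      fmat dA(static_cast<size_t>(Cin) * HW, B);
      col2im(dcols, Cin, H, W, dA);
      dcur = dA;
    }
  }
  return loss;
}

struct Adam {
  std::vector<fmat> m, v;
  float lr, b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long t = 0;
  void init(const std::vector<fmat*>& params, float lr_) {
    lr = lr_;
    for (auto* p : params) {
      m.push_back(arma::zeros<fmat>(p->n_rows, p->n_cols));
      v.push_back(arma::zeros<fmat>(p->n_rows, p->n_cols));
    }
  }
  void step(std::vector<fmat*>& params, const std::vector<fmat*>& grads) {
    ++t;
    const float bc1 = 1.0f - std::pow(b1, static_cast<float>(t));
    const float bc2 = 1.0f - std::pow(b2, static_cast<float>(t));
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1.0f - b1) * (*grads[i]);
      v[i] = b2 * v[i] + (1.0f - b2) * arma::square(*grads[i]);
      *params[i] -= lr * (m[i] / bc1) / (arma::sqrt(v[i] / bc2) + eps);
    }
  }
};

float eval_loss(const Weights& w, const Arch& a, const fmat& X, const fmat& Y) {
  const int n = X.n_cols, chunk = 256, T = a.tasks;
  float tot = 0.0f;
  for (int s = 0; s < n; s += chunk) {
    const int e = std::min(n, s + chunk);
    fmat Yh = forward(w, a, X.cols(s, e - 1), nullptr);
    fmat diff = Yh - Y.cols(s, e - 1);
    fmat wd = diff; wd.each_col() %= a.loss_w;
    tot += arma::accu(wd % diff) / T;
  }
  return tot / n;
}

}  // namespace

// [[Rcpp::export(name = ".sn_forward")]]
NumericMatrix sn_forward(List weights, NumericMatrix X, List arch) {
  const Arch a = parse_arch(arch);
  const Weights w = parse_weights(weights);
  const fmat Xf = arma::conv_to<fmat>::from(as<arma::mat>(X));
  const int n = Xf.n_cols, chunk = 256;
  arma::mat out(a.tasks, n);
  for (int s = 0; s < n; s += chunk) {
    const int e = std::min(n, s + chunk);
    fmat Yh = forward(w, a, Xf.cols(s, e - 1), nullptr);
    out.cols(s, e - 1) = arma::conv_to<arma::mat>::from(Yh);
  }
  return wrap(out);
}

// [[Rcpp::export(name = ".sn_train")]]
List sn_train(List weights, NumericMatrix X, NumericMatrix Y,
              Nullable<NumericMatrix> Xval, Nullable<NumericMatrix> Yval,
              List arch, List opts) {
  const Arch a = parse_arch(arch);
  Weights w = parse_weights(weights);
  const fmat Xf = arma::conv_to<fmat>::from(as<arma::mat>(X));
  const fmat Yf = arma::conv_to<fmat>::from(as<arma::mat>(Y));
  fmat Xv, Yv;
  const bool has_val = Xval.isNotNull();
  if (has_val) {
    Xv = arma::conv_to<fmat>::from(as<arma::mat>(NumericMatrix(Xval)));
    Yv = arma::conv_to<fmat>::from(as<arma::mat>(NumericMatrix(Yval)));
  }
  const float lr = as<double>(opts["lr"]);
  const int batch = as<int>(opts["batch"]);
  const int max_epochs = as<int>(opts["max_epochs"]);
  const int patience = as<int>(opts["patience"]);
  const unsigned seed = as<unsigned>(opts["seed"]);
  const int n = Xf.n_cols, nb = static_cast<int>(w.cw.size());

  // Collect parameters as matrices (biases as 1-column matrices).
  std::vector<fmat> cb_m(nb);
  for (int i = 0; i < nb; ++i) cb_m[i] = w.cb[i];
  fmat db_m = w.db, hb_m = w.hb;
  std::vector<fmat*> params;
  for (int i = 0; i < nb; ++i) params.push_back(&w.cw[i]);
  for (int i = 0; i < nb; ++i) params.push_back(&cb_m[i]);
  params.push_back(&w.dw); params.push_back(&db_m);
  params.push_back(&w.hw); params.push_back(&hb_m);
  Adam adam;
  adam.init(params, lr);

  std::mt19937 rng(seed);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  std::vector<double> train_hist, val_hist;
  Weights best = w;
  float best_val = std::numeric_limits<float>::infinity();
  int best_epoch = 0, stall = 0;
  const float loss_floor = 1e-12f;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double epoch_loss = 0.0;
    int nbatch = 0;
    for (int s = 0; s < n; s += batch) {
      const int e = std::min(n, s + batch);
      const int bsz = e - s;
      fmat Xb(Xf.n_rows, bsz), Yb(Yf.n_rows, bsz);
      for (int k = 0; k < bsz; ++k) {
        Xb.col(k) = Xf.col(idx[s + k]);
        Yb.col(k) = Yf.col(idx[s + k]);
      }
      // Sync fvec biases into matrix views before use.
      for (int i = 0; i < nb; ++i) w.cb[i] = cb_m[i].col(0);
      w.db = db_m.col(0); w.hb = hb_m.col(0);
      Cache cc;
      fmat Yh = forward(w, a, Xb, &cc);
      Grads g;
      epoch_loss += backward(w, a, cc, Yh, Yb, g);
      ++nbatch;
      std::vector<fmat> gb(nb);
      for (int i = 0; i < nb; ++i) gb[i] = g.cb[i];
      fmat gdb = g.db, ghb = g.hb;
      std::vector<fmat*> gp;
      for (int i = 0; i < nb; ++i) gp.push_back(&g.cw[i]);
      for (int i = 0; i < nb; ++i) gp.push_back(&gb[i]);
      gp.push_back(&g.dw); gp.push_back(&gdb);
      gp.push_back(&g.hw); gp.push_back(&ghb);
      adam.step(params, gp);
    }
    for (int i = 0; i < nb; ++i) w.cb[i] = cb_m[i].col(0);
    w.db = db_m.col(0); w.hb = hb_m.col(0);
    train_hist.push_back(epoch_loss / std::max(nbatch, 1));

    if (has_val) {
      const float vl = eval_loss(w, a, Xv, Yv);
      val_hist.push_back(vl);
      if (vl < best_val - loss_floor) {
        best_val = vl; best = w; best_epoch = epoch; stall = 0;
      } else if (++stall >= patience && patience > 0) {
        break;
      }
    } else {
      best = w; best_epoch = epoch;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = weights_to_list(best),
                      _["train_loss"] = wrap(train_hist),
                      _["val_loss"] = wrap(val_hist),
                      _["best_epoch"] = best_epoch);
}
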