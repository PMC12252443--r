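// Variable-depth stacked LSTM sequence-to-sequence regressor.
//
// Architecture: l stacked LSTM layers of nc cells (all but the last return
// full sequences), a dense layer mapping the final hidden state nc -> k*nc
// (ReLU), a dense layer k*nc -> pl*k (linear), reshape to (pl, k), and an
// optional batch-normalization over the k output channels.  Trained with
// Adam on an RMSE loss over min-max-normalized labels, full BPTT.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LayerCache {
  std::vector<mat> i, f, g, o, c, tc, h; // per time step, each B x nc
};

class VLSTM {
public:
  int nc, l, nt, pl, k;
  bool use_bn;
  // parameters
  std::vector<mat> Wx, Wh;      // (in x 4nc), (nc x 4nc) per layer
  std::vector<rowvec> b;        // 4nc per layer
  mat W1, W2;                   // nc x k*nc, k*nc x pl*k
  rowvec b1, b2;
  rowvec gamma, beta, run_mean, run_var; // k channels
  // Adam state
  std::vector<mat> mWx, vWx, mWh, vWh;
  std::vector<rowvec> mb, vb;
  mat mW1, vW1, mW2, vW2;
  rowvec mb1, vb1, mb2, vb2, mg, vg, mbe, vbe;
  long adam_t = 0;
  double beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-7;
  double bn_momentum = 0.99, bn_eps = 1e-3;
  std::mt19937_64 rng;

  VLSTM(int nc_, int l_, int nt_, int pl_, int k_, bool bn_, unsigned seed)
      : nc(nc_), l(l_), nt(nt_), pl(pl_), k(k_), use_bn(bn_), rng(seed) {
    for (int j = 0; j < l; ++j) {
      int in = (j == 0) ? k : nc;
      Wx.push_back(glorot(in, 4 * nc));
      Wh.push_back(glorot(nc, 4 * nc));
      rowvec bj(4 * nc, fill::zeros);
      bj.subvec(nc, 2 * nc - 1).fill(1.0); // forget-gate bias 1
      b.push_back(bj);
      mWx.push_back(zeros<mat>(in, 4 * nc)); vWx.push_back(zeros<mat>(in, 4 * nc));
      mWh.push_back(zeros<mat>(nc, 4 * nc)); vWh.push_back(zeros<mat>(nc, 4 * nc));
      mb.push_back(zeros<rowvec>(4 * nc)); vb.push_back(zeros<rowvec>(4 * nc));
    }
    W1 = glorot(nc, k * nc); b1 = zeros<rowvec>(k * nc);
    W2 = glorot(k * nc, pl * k); b2 = zeros<rowvec>(pl * k);
    mW1 = zeros<mat>(nc, k * nc); vW1 = mW1;
    mW2 = zeros<mat>(k * nc, pl * k); vW2 = mW2;
    mb1 = zeros<rowvec>(k * nc); vb1 = mb1;
    mb2 = zeros<rowvec>(pl * k); vb2 = mb2;
    gamma = ones<rowvec>(k); beta = zeros<rowvec>(k);
    run_mean = zeros<rowvec>(k); run_var = ones<rowvec>(k);
    mg = zeros<rowvec>(k); vg = mg; mbe = mg; vbe = mg;
  }

  mat glorot(int fan_in, int fan_out) {
    double lim = std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<double> u(-lim, lim);
    mat w(fan_in, fan_out);
    for (uword r = 0; r < w.n_rows; ++r)
      for (uword c = 0; c < w.n_cols; ++c) w(r, c) = u(rng);
    return w;
  }

  // forward pass; caches filled only when `training`
  mat forward(const std::vector<mat>& Xt, bool training,
              std::vector<LayerCache>& caches, mat& d1_cache,
              mat& pre_bn_cache, rowvec& bmean, rowvec& bvar, mat& xhat_cache) {
    int B = Xt[0].n_rows;
    std::vector<mat> in = Xt;
    caches.assign(l, LayerCache());
    mat h_last;
    for (int j = 0; j < l; ++j) {
      mat H(B, nc, fill::zeros), C(B, nc, fill::zeros);
      LayerCache& cc = caches[j];
      if (training) {
        cc.i.resize(nt); cc.f.resize(nt); cc.g.resize(nt); cc.o.resize(nt);
        cc.c.resize(nt); cc.tc.resize(nt); cc.h.resize(nt);
      }
      std::vector<mat> out_seq;
      bool need_seq = (j < l - 1);
      if (need_seq) out_seq.resize(nt);
      for (int t = 0; t < nt; ++t) {
        mat a = in[t] * Wx[j] + H * Wh[j];
        a.each_row() += b[j];
        mat ig = sigmoid(a.cols(0, nc - 1));
        mat fg = sigmoid(a.cols(nc, 2 * nc - 1));
        mat gg = tanh(a.cols(2 * nc, 3 * nc - 1));
        mat og = sigmoid(a.cols(3 * nc, 4 * nc - 1));
        C = fg % C + ig % gg;
        mat tC = tanh(C);
        H = og % tC;
        if (training) {
          cc.i[t] = ig; cc.f[t] = fg; cc.g[t] = gg; cc.o[t] = og;
          cc.c[t] = C; cc.tc[t] = tC; cc.h[t] = H;
        }
        if (need_seq) out_seq[t] = H;
      }
      if (need_seq) in = out_seq; else h_last = H;
    }
    mat z1 = h_last * W1; z1.each_row() += b1;
    mat d1 = clamp(z1, 0.0, datum::inf); // ReLU
    mat out = d1 * W2; out.each_row() += b2;
    if (training) { d1_cache = d1; }
    if (use_bn) {
      if (training) pre_bn_cache = out;
      bmean.set_size(k); bvar.set_size(k);
      if (training) xhat_cache.set_size(out.n_rows, out.n_cols);
      for (int a = 0; a < k; ++a) {
        uvec cols = regspace<uvec>(a, k, pl * k - 1);
        mat sub = out.cols(cols);
        double mu_c, var_c;
        if (training) {
          mu_c = accu(sub) / sub.n_elem;
          var_c = accu(square(sub - mu_c)) / sub.n_elem;
          bmean(a) = mu_c; bvar(a) = var_c;
        } else {
          mu_c = run_mean(a); var_c = run_var(a);
        }
        mat xh = (sub - mu_c) / std::sqrt(var_c + bn_eps);
        if (training) xhat_cache.cols(cols) = xh;
        out.cols(cols) = xh * gamma(a) + beta(a);
      }
      if (training) {
        run_mean = bn_momentum * run_mean + (1 - bn_momentum) * bmean;
        run_var = bn_momentum * run_var + (1 - bn_momentum) * bvar;
      }
    }
    return out;
  }

  void adam(mat& w, mat& m, mat& v, const mat& g, double lr) {
    m = beta1 * m + (1 - beta1) * g;
    v = beta2 * v + (1 - beta2) * square(g);
    double bc1 = 1 - std::pow(beta1, (double)adam_t);
    double bc2 = 1 - std::pow(beta2, (double)adam_t);
    w -= lr * (m / bc1) / (sqrt(v / bc2) + adam_eps);
  }
  void adam(rowvec& w, rowvec& m, rowvec& v, const rowvec& g, double lr) {
    m = beta1 * m + (1 - beta1) * g;
    v = beta2 * v + (1 - beta2) * square(g);
    double bc1 = 1 - std::pow(beta1, (double)adam_t);
    double bc2 = 1 - std::pow(beta2, (double)adam_t);
    w -= lr * (m / bc1) / (sqrt(v / bc2) + adam_eps);
  }

  // one minibatch step; returns batch RMSE (on normalized scale)
  double train_batch(const std::vector<mat>& Xt, const mat& Y, double lr) {
    int B = Xt[0].n_rows;
    std::vector<LayerCache> caches;
    mat d1, pre_bn, xhat;
    rowvec bmean, bvar;
    mat out = forward(Xt, true, caches, d1, pre_bn, bmean, bvar, xhat);
    mat R = out - Y;
    double M = (double)R.n_elem;
    double loss = std::sqrt(accu(square(R)) / M);
    if (loss <= 0) return 0.0;
    mat dout = R / (M * loss);

    rowvec dgamma(k, fill::zeros), dbeta_(k, fill::zeros);
    if (use_bn) {
      mat dx(dout.n_rows, dout.n_cols);
      double m_ = (double)(dout.n_rows) * pl;
      for (int a = 0; a < k; ++a) {
        uvec cols = regspace<uvec>(a, k, pl * k - 1);
        mat dy = dout.cols(cols);
        mat xh = xhat.cols(cols);
        dgamma(a) = accu(dy % xh);
        dbeta_(a) = accu(dy);
        double inv_sd = 1.0 / std::sqrt(bvar(a) + bn_eps);
        mat dxh = dy * gamma(a);
        // dx = inv_sd/m * (m*dxh - sum(dxh) - xhat*sum(dxh*xhat))
        dx.cols(cols) = (inv_sd / m_) *
          (m_ * dxh - accu(dxh) - xh * accu(dxh % xh));
      }
      dout = dx;
    }

    mat dW2 = d1.t() * dout;
    rowvec db2 = sum(dout, 0);
    mat dd1 = dout * W2.t();
    dd1.elem(find(d1 <= 0)).zeros(); // ReLU'
    // recover h_last from cache of top layer
    const mat& h_last = caches[l - 1].h[nt - 1];
    mat dW1 = h_last.t() * dd1;
    rowvec db1 = sum(dd1, 0);
    mat dh_last = dd1 * W1.t();

    // BPTT top-down; dXext holds the gradient flowing into each layer's
    // output sequence from the layer above
    std::vector<mat> dXext(nt);
    std::vector<mat> gWx(l), gWh(l);
    std::vector<rowvec> gb(l);
    for (int j = l - 1; j >= 0; --j) {
      LayerCache& cc = caches[j];
      int in_dim = (j == 0) ? k : nc;
      gWx[j] = zeros<mat>(in_dim, 4 * nc);
      gWh[j] = zeros<mat>(nc, 4 * nc);
      gb[j] = zeros<rowvec>(4 * nc);
      mat dH(B, nc, fill::zeros), dC(B, nc, fill::zeros);
      std::vector<mat> dX(nt);
      for (int t = nt - 1; t >= 0; --t) {
        mat dHt = dH;
        if (j == l - 1) {
          if (t == nt - 1) dHt += dh_last;
        } else {
          dHt += dXext[t];
        }
        const mat& ig = cc.i[t]; const mat& fg = cc.f[t];
        const mat& gg = cc.g[t]; const mat& og = cc.o[t];
        const mat& tC = cc.tc[t];
        mat dCt = dC + dHt % og % (1 - square(tC));
        mat dog = dHt % tC;
        mat dig = dCt % gg;
        mat dgg = dCt % ig;
        const mat* Cprev = (t > 0) ? &cc.c[t - 1] : nullptr;
        mat dfg = (t > 0) ? mat(dCt % (*Cprev)) : mat(B, nc, fill::zeros);
        mat da(B, 4 * nc);
        da.cols(0, nc - 1) = dig % ig % (1 - ig);
        da.cols(nc, 2 * nc - 1) = dfg % fg % (1 - fg);
        da.cols(2 * nc, 3 * nc - 1) = dgg % (1 - square(gg));
        da.cols(3 * nc, 4 * nc - 1) = dog % og % (1 - og);
        const mat& xin = (j == 0) ? Xt[t]
                         : ((t >= 0) ? caches[j - 1].h[t] : Xt[t]);
        gWx[j] += xin.t() * da;
        if (t > 0) gWh[j] += cc.h[t - 1].t() * da;
        gb[j] += sum(da, 0);
        dX[t] = da * Wx[j].t();
        dH = da * Wh[j].t();
        dC = dCt % fg;
      }
      dXext = dX;
    }

    adam_t++;
    for (int j = 0; j < l; ++j) {
      adam(Wx[j], mWx[j], vWx[j], gWx[j], lr);
      adam(Wh[j], mWh[j], vWh[j], gWh[j], lr);
      adam(b[j], mb[j], vb[j], gb[j], lr);
    }
    adam(W1, mW1, vW1, dW1, lr); adam(b1, mb1, vb1, db1, lr);
    adam(W2, mW2, vW2, dW2, lr); adam(b2, mb2, vb2, db2, lr);
    if (use_bn) {
      adam(gamma, mg, vg, dgamma, lr);
      adam(beta, mbe, vbe, dbeta_, lr);
    }
    return loss;
  }
};

static std::vector<mat> gather_batch(const cube& X, const uvec& idx) {
  // X: nt x k x N -> per-time-step B x k matrices
  int nt = X.n_rows, k = X.n_cols;
  std::vector<mat> Xt(nt);
  for (int t = 0; t < nt; ++t) {
    mat m(idx.n_elem, k);
    for (uword bi = 0; bi < idx.n_elem; ++bi)
      for (int a = 0; a < k; ++a) m(bi, a) = X(t, a, idx(bi));
    Xt[t] = m;
  }
  return Xt;
}

static mat gather_labels(const cube& Y, const uvec& idx) {
  // Y: pl x k x N -> B x (pl*k), element (p,a) at column p*k + a
  int pl = Y.n_rows, k = Y.n_cols;
  mat m(idx.n_elem, pl * k);
  for (uword bi = 0; bi < idx.n_elem; ++bi)
    for (int p = 0; p < pl; ++p)
      for (int a = 0; a < k; ++a) m(bi, p * k + a) = Y(p, a, idx(bi));
  return m;
}

// [[Rcpp::export]]
SEXP vlstm_create(int nc, int l, int nt, int pl, int k, bool use_bn,
                  unsigned int seed) {
  if (nc < 1 || l < 1 || nt < 1 || pl < 1 || k < 1)
    Rcpp::stop("invalid architecture sizes");
  Rcpp::XPtr<VLSTM> ptr(new VLSTM(nc, l, nt, pl, k, use_bn, seed), true);
  return ptr;
}

// [[Rcpp::export]]
double vlstm_train_epoch(SEXP model, const arma::cube& X, const arma::cube& Y,
                         int batch_size, double lr) {
  Rcpp::XPtr<VLSTM> m(model);
  int N = X.n_slices;
  if ((int)Y.n_slices != N) Rcpp::stop("X and Y window counts differ");
  if ((int)X.n_rows != m->nt || (int)X.n_cols != m->k ||
      (int)Y.n_rows != m->pl || (int)Y.n_cols != m->k)
    Rcpp::stop("window shape does not match the model architecture");
  std::vector<uword> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), m->rng);
  double loss_sum = 0; int nb = 0;
  for (int s = 0; s < N; s += batch_size) {
    int e = std::min(N, s + batch_size);
    uvec idx(e - s);
    for (int i = s; i < e; ++i) idx(i - s) = order[i];
    std::vector<mat> Xt = gather_batch(X, idx);
    mat Yb = gather_labels(Y, idx);
    loss_sum += m->train_batch(Xt, Yb, lr);
    nb++;
    Rcpp::checkUserInterrupt();
  }
  return nb > 0 ? loss_sum / nb : NA_REAL;
}

// [[Rcpp::export]]
arma::cube vlstm_predict(SEXP model, const arma::cube& X, int batch_size = 64) {
  Rcpp::XPtr<VLSTM> m(model);
  int N = X.n_slices;
  cube out(m->pl, m->k, N);
  std::vector<LayerCache> caches;
  mat d1, pre_bn, xhat; rowvec bmean, bvar;
  for (int s = 0; s < N; s += batch_size) {
    int e = std::min(N, s + batch_size);
    uvec idx = regspace<uvec>(s, e - 1);
    std::vector<mat> Xt = gather_batch(X, idx);
    mat o = m->forward(Xt, false, caches, d1, pre_bn, bmean, bvar, xhat);
    for (int bi = 0; bi < e - s; ++bi)
      for (int p = 0; p < m->pl; ++p)
        for (int a = 0; a < m->k; ++a) out(p, a, s + bi) = o(bi, p * m->k + a);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List vlstm_get_weights(SEXP model) {
  Rcpp::XPtr<VLSTM> m(model);
  Rcpp::List lw;
  for (int j = 0; j < m->l; ++j) {
    lw.push_back(Rcpp::wrap(m->Wx[j]));
    lw.push_back(Rcpp::wrap(m->Wh[j]));
    lw.push_back(Rcpp::wrap(m->b[j]));
  }
  lw.push_back(Rcpp::wrap(m->W1)); lw.push_back(Rcpp::wrap(m->b1));
  lw.push_back(Rcpp::wrap(m->W2)); lw.push_back(Rcpp::wrap(m->b2));
  lw.push_back(Rcpp::wrap(m->gamma)); lw.push_back(Rcpp::wrap(m->beta));
  lw.push_back(Rcpp::wrap(m->run_mean)); lw.push_back(Rcpp::wrap(m->run_var));
  return lw;
}

// [[Rcpp::export]]
void vlstm_set_weights(SEXP model, Rcpp::List w) {
  Rcpp::XPtr<VLSTM> m(model);
  int pos = 0;
  for (int j = 0; j < m->l; ++j) {
    m->Wx[j] = Rcpp::as<mat>(w[pos++]);
    m->Wh[j] = Rcpp::as<mat>(w[pos++]);
    m->b[j] = Rcpp::as<rowvec>(w[pos++]);
  }
  m->W1 = Rcpp::as<mat>(w[pos++]); m->b1 = Rcpp::as<rowvec>(w[pos++]);
  m->W2 = Rcpp::as<mat>(w[pos++]); m->b2 = Rcpp::as<rowvec>(w[pos++]);
  m->gamma = Rcpp::as<rowvec>(w[pos++]); m->beta = Rcpp::as<rowvec>(w[pos++]);
  m->run_mean = Rcpp::as<rowvec>(w[pos++]);
  m->run_var = Rcpp::as<rowvec>(w[pos++]);
}

// [[Rcpp::export]]
Rcpp::List vlstm_config(SEXP model) {
  Rcpp::XPtr<VLSTM> m(model);
  return Rcpp::List::create(
      Rcpp::Named("nc") = m->nc, Rcpp::Named("l") = m->l,
      Rcpp::Named("nt") = m->nt, Rcpp::Named("pl") = m->pl,
      Rcpp::Named("k") = m->k, Rcpp::Named("use_bn") = m->use_bn);
}
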