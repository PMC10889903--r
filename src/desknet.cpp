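// Reference convolutional network ("desknet") used to classify tilted vs
// near-horizontal grating renders. Four 3x3 conv blocks (ReLU, optional 2x2
// max-pool), global average pooling and a 2-way linear head. Implemented via
// im2col + GEMM so the heavy lifting runs in BLAS; exposes per-block
// activation taps and gradients with respect to tapped activations for
// class-activation mapping and representational analysis.
//
// Layout conventions: images arrive flattened column-major as H x W x C
// (channels last); weights for block b form a (C_out x C_in*9) matrix whose
// column-block order matches im2col rows (input channel major, then kernel
// column, then kernel row). All randomness (weight init, shuffling, dropout
// draws) is generated on the R side so a single R seed governs training.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Arch {
  ivec channels;   // per-block output channels
  ivec strides;    // per-block conv stride
  ivec pools;      // per-block 0/1: 2x2 max-pool after ReLU
  int in_ch;       // image channels (3)
  bool coords;     // append normalized x/y coordinate channels
  int blocks() const { return (int)channels.n_elem; }
  int cin(int b) const {
    return b == 0 ? in_ch + (coords ? 2 : 0) : (int)channels[b - 1];
  }
};

Arch read_arch(const Rcpp::List& arch) {
  Arch a;
  a.channels = Rcpp::as<ivec>(arch["channels"]);
  a.strides = Rcpp::as<ivec>(arch["strides"]);
  a.pools = Rcpp::as<ivec>(arch["pools"]);
  a.in_ch = Rcpp::as<int>(arch["in_ch"]);
  a.coords = Rcpp::as<bool>(arch["coords"]);
  return a;
}

struct Params {
  std::vector<mat> W;  // conv weights per block
  std::vector<vec> b;  // conv biases per block
  mat Wd;              // dense head
  vec bd;
};

Params read_params(const Rcpp::List& p, int blocks) {
  Params out;
  for (int i = 0; i < blocks; ++i) {
    out.W.push_back(Rcpp::as<mat>(p[2 * i]));
    out.b.push_back(Rcpp::as<vec>(p[2 * i + 1]));
  }
  out.Wd = Rcpp::as<mat>(p[2 * blocks]);
  out.bd = Rcpp::as<vec>(p[2 * blocks + 1]);
  return out;
}

Rcpp::List write_params(const Params& p) {
  Rcpp::List out;
  for (size_t i = 0; i < p.W.size(); ++i) {
    std::string idx = std::to_string(i + 1);
    out.push_back(p.W[i], "W" + idx);
    out.push_back(p.b[i], "b" + idx);
  }
  out.push_back(p.Wd, "Wd");
  out.push_back(p.bd, "bd");
  return out;
}

void zero_like(Params& g) {
  for (auto& W : g.W) W.zeros();
  for (auto& b : g.b) b.zeros();
  g.Wd.zeros();
  g.bd.zeros();
}

inline int out_dim(int n, int stride) { return (n - 1) / stride + 1; }

// im2col for 3x3 kernels with pad 1
mat im2col(const cube& in, int stride) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  mat cols(C * 9, (size_t)Ho * Wo, fill::zeros);
  const uword nr = cols.n_rows;
  for (int c = 0; c < C; ++c) {
    const mat& sl = in.slice(c);
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int r = c * 9 + dj * 3 + di;
        for (int jo = 0; jo < Wo; ++jo) {
          const int jj = jo * stride + dj - 1;
          if (jj < 0 || jj >= W) continue;
          double* dst = cols.memptr() + (size_t)(jo * Ho) * nr + r;
          const double* srccol = sl.colptr(jj);
          for (int io = 0; io < Ho; ++io) {
            const int ii = io * stride + di - 1;
            if (ii < 0 || ii >= H) continue;
            dst[(size_t)io * nr] = srccol[ii];
          }
        }
      }
    }
  }
  return cols;
}

// adjoint of im2col
cube col2im(const mat& dcols, int H, int W, int C, int stride) {
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  cube dx(H, W, C, fill::zeros);
  const uword nr = dcols.n_rows;
  for (int c = 0; c < C; ++c) {
    mat& sl = dx.slice(c);
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int r = c * 9 + dj * 3 + di;
        for (int jo = 0; jo < Wo; ++jo) {
          const int jj = jo * stride + dj - 1;
          if (jj < 0 || jj >= W) continue;
          const double* src = dcols.memptr() + (size_t)(jo * Ho) * nr + r;
          double* dstcol = sl.colptr(jj);
          for (int io = 0; io < Ho; ++io) {
            const int ii = io * stride + di - 1;
            if (ii < 0 || ii >= H) continue;
            dstcol[ii] += src[(size_t)io * nr];
          }
        }
      }
    }
  }
  return dx;
}

cube to_cube(const mat& m, int Ho, int Wo, int C) {
  cube out(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    out.slice(c) = reshape(m.row(c), Ho, Wo);
  }
  return out;
}

mat to_mat(const cube& a) {
  const int C = a.n_slices;
  mat out(C, (size_t)a.n_rows * a.n_cols);
  for (int c = 0; c < C; ++c) {
    out.row(c) = vectorise(a.slice(c)).t();
  }
  return out;
}

cube maxpool2(const cube& in, umat& idx) {
  const int Ho = in.n_rows / 2, Wo = in.n_cols / 2, C = in.n_slices;
  cube out(Ho, Wo, C);
  idx.set_size((size_t)Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& sl = in.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        uword arg = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            const double v = sl(ii, jj);
            if (v > best) {
              best = v;
              arg = (uword)jj * in.n_rows + ii;
            }
          }
        }
        out(i, j, c) = best;
        idx((size_t)j * Ho + i, c) = arg;
      }
    }
  }
  return out;
}

cube unpool2(const cube& dout, const umat& idx, int H, int W) {
  const int C = dout.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const vec dv = vectorise(dout.slice(c));
    mat& sl = dx.slice(c);
    for (uword k = 0; k < dv.n_elem; ++k) {
      sl(idx(k, c)) += dv(k);
    }
  }
  return dx;
}

cube make_input(const double* xp, int H, int W, const Arch& a) {
  const int C = a.in_ch + (a.coords ? 2 : 0);
  cube in(H, W, C, fill::zeros);
  std::memcpy(in.memptr(), xp, sizeof(double) * (size_t)H * W * a.in_ch);
  if (a.coords) {
    mat& xs = in.slice(a.in_ch);
    mat& ys = in.slice(a.in_ch + 1);
    for (int j = 0; j < W; ++j) {
      xs.col(j).fill(2.0 * (j + 0.5) / W - 1.0);
    }
    for (int i = 0; i < H; ++i) {
      ys.row(i).fill(2.0 * (i + 0.5) / H - 1.0);
    }
  }
  return in;
}

struct Cache {
  std::vector<cube> inputs;   // input to each block
  std::vector<mat> cols;      // im2col matrices (kept only for training)
  std::vector<cube> act;      // post-ReLU activations (the taps)
  std::vector<cube> pooled;   // block outputs (post-pool where pooled)
  std::vector<umat> poolidx;
  vec gap;
  vec logits;
};

void forward(const Params& p, const Arch& a, const cube& x0, Cache& cc,
             bool keep_cols, const vec& drop_mask = vec()) {
  const int B = a.blocks();
  cc.inputs.clear(); cc.cols.clear(); cc.act.clear();
  cc.pooled.clear(); cc.poolidx.clear();
  cube cur = x0;
  for (int b = 0; b < B; ++b) {
    cc.inputs.push_back(cur);
    const int s = (int)a.strides[b];
    const int Ho = out_dim(cur.n_rows, s), Wo = out_dim(cur.n_cols, s);
    mat cols = im2col(cur, s);
    mat z = p.W[b] * cols;
    z.each_col() += p.b[b];
    if (keep_cols) cc.cols.push_back(std::move(cols));
    z.transform([](double v) { return v > 0 ? v : 0.0; });
    cc.act.push_back(to_cube(z, Ho, Wo, (int)a.channels[b]));
    if (a.pools[b]) {
      umat idx;
      cube P = maxpool2(cc.act.back(), idx);
      cc.poolidx.push_back(std::move(idx));
      cc.pooled.push_back(std::move(P));
    } else {
      cc.poolidx.push_back(umat());
      cc.pooled.push_back(cc.act.back());
    }
    cur = cc.pooled.back();
  }
  const cube& last = cc.pooled.back();
  cc.gap.set_size(last.n_slices);
  for (uword c = 0; c < last.n_slices; ++c) {
    cc.gap(c) = accu(last.slice(c)) / (last.n_rows * last.n_cols);
  }
  if (drop_mask.n_elem > 0) cc.gap %= drop_mask;
  cc.logits = p.Wd * cc.gap + p.bd;
}

// Backward from a gradient on the logits. If stop_tap >= 0, returns the
// gradient with respect to that block's post-ReLU activation (the quantity
// class-activation mapping needs) and touches no parameter gradients;
// otherwise accumulates parameter gradients into *gp.
cube backward(const Params& p, const Arch& a, const Cache& cc,
              const vec& dlogits, Params* gp, int stop_tap,
              const vec& drop_mask = vec()) {
  const int B = a.blocks();
  vec dgap = p.Wd.t() * dlogits;
  if (gp) {
    gp->Wd += dlogits * cc.gap.t();
    gp->bd += dlogits;
  }
  if (drop_mask.n_elem > 0) dgap %= drop_mask;
  const cube& last = cc.pooled.back();
  cube dcur(last.n_rows, last.n_cols, last.n_slices);
  for (uword c = 0; c < last.n_slices; ++c) {
    dcur.slice(c).fill(dgap(c) / (last.n_rows * last.n_cols));
  }
  for (int b = B - 1; b >= 0; --b) {
    cube dA = a.pools[b]
      ? unpool2(dcur, cc.poolidx[b], cc.act[b].n_rows, cc.act[b].n_cols)
      : dcur;
    if (b == stop_tap) return dA;
    for (uword k = 0; k < dA.n_elem; ++k) {
      if (cc.act[b](k) <= 0) dA(k) = 0.0;
    }
    mat dz = to_mat(dA);
    if (gp) {
      gp->W[b] += dz * cc.cols[b].t();
      gp->b[b] += sum(dz, 1);
    }
    if (b == 0) break;
    mat dcols = p.W[b].t() * dz;
    dcur = col2im(dcols, cc.inputs[b].n_rows, cc.inputs[b].n_cols,
                  a.cin(b), (int)a.strides[b]);
  }
  return cube();
}

void softmax2(const vec& logits, vec& prob) {
  prob = exp(logits - logits.max());
  prob /= accu(prob);
}

void adam_update(mat& w, mat& m, mat& v, const mat& g, double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  w -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

void adam_update(vec& w, vec& m, vec& v, const vec& g, double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  w -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

cube row_input(const Rcpp::NumericMatrix& X, int i, int H, int W,
               const Arch& a, std::vector<double>& buf) {
  for (int j = 0; j < X.ncol(); ++j) buf[j] = X(i, j);
  return make_input(buf.data(), H, W, a);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericMatrix dn_forward_batch(Rcpp::List params, Rcpp::List arch,
                                     Rcpp::NumericMatrix X, int H, int W) {
  const Arch a = read_arch(arch);
  const Params p = read_params(params, a.blocks());
  const int n = X.nrow();
  Rcpp::NumericMatrix logits(n, 2);
  Cache cc;
  std::vector<double> buf(X.ncol());
  for (int i = 0; i < n; ++i) {
    cube x0 = row_input(X, i, H, W, a, buf);
    forward(p, a, x0, cc, false);
    logits(i, 0) = cc.logits(0);
    logits(i, 1) = cc.logits(1);
  }
  return logits;
}

// One epoch of minibatch Adam on softmax cross-entropy. `order` is the
// 0-based visiting order (shuffled in R); `dropout_draws`, when dropout is
// active, holds one uniform draw per (image position, GAP unit), generated
// in R so the global seed governs it.
// [[Rcpp::export]]
Rcpp::List dn_train_epoch(Rcpp::List params, Rcpp::List adam, Rcpp::List arch,
                          Rcpp::NumericMatrix X, Rcpp::IntegerVector y,
                          Rcpp::IntegerVector order, int H, int W, double lr,
                          double weight_decay, int batch_size,
                          double dropout_rate,
                          Rcpp::NumericMatrix dropout_draws) {
  const Arch a = read_arch(arch);
  Params p = read_params(params, a.blocks());
  Params m = read_params(adam["m"], a.blocks());
  Params v = read_params(adam["v"], a.blocks());
  double t = Rcpp::as<double>(adam["t"]);

  const int n = order.size();
  double total_loss = 0.0;
  int correct = 0;
  Cache cc;
  std::vector<double> buf(X.ncol());
  Params g = p;

  for (int start = 0; start < n; start += batch_size) {
    const int bs = std::min(batch_size, n - start);
    zero_like(g);
    for (int k = 0; k < bs; ++k) {
      const int i = order[start + k];
      cube x0 = row_input(X, i, H, W, a, buf);
      vec drop;
      if (dropout_rate > 0) {
        drop.set_size(a.channels[a.blocks() - 1]);
        for (uword c = 0; c < drop.n_elem; ++c) {
          drop(c) = dropout_draws(start + k, c) < dropout_rate
            ? 0.0 : 1.0 / (1.0 - dropout_rate);
        }
      }
      forward(p, a, x0, cc, true, drop);
      vec prob;
      softmax2(cc.logits, prob);
      total_loss += -std::log(std::max(prob(y[i]), 1e-12));
      if ((prob(1) > prob(0)) == (y[i] == 1)) ++correct;
      vec dlogits = prob;
      dlogits(y[i]) -= 1.0;
      dlogits /= bs;
      backward(p, a, cc, dlogits, &g, -1, drop);
    }
    // L2 penalty on weight matrices (biases excluded)
    for (int b = 0; b < a.blocks(); ++b) g.W[b] += weight_decay * p.W[b];
    g.Wd += weight_decay * p.Wd;
    t += 1.0;
    for (int b = 0; b < a.blocks(); ++b) {
      adam_update(p.W[b], m.W[b], v.W[b], g.W[b], lr, t);
      adam_update(p.b[b], m.b[b], v.b[b], g.b[b], lr, t);
    }
    adam_update(p.Wd, m.Wd, v.Wd, g.Wd, lr, t);
    adam_update(p.bd, m.bd, v.bd, g.bd, lr, t);
  }

  return Rcpp::List::create(
    Rcpp::Named("params") = write_params(p),
    Rcpp::Named("adam") = Rcpp::List::create(
      Rcpp::Named("m") = write_params(m),
      Rcpp::Named("v") = write_params(v),
      Rcpp::Named("t") = t
    ),
    Rcpp::Named("loss") = total_loss / n,
    Rcpp::Named("accuracy") = (double)correct / n
  );
}

// Post-ReLU activations at every block tap, plus the logits.
// [[Rcpp::export]]
Rcpp::List dn_taps(Rcpp::List params, Rcpp::List arch, Rcpp::NumericVector x,
                   int H, int W) {
  const Arch a = read_arch(arch);
  const Params p = read_params(params, a.blocks());
  cube x0 = make_input(x.begin(), H, W, a);
  Cache cc;
  forward(p, a, x0, cc, false);
  Rcpp::List taps(a.blocks());
  for (int b = 0; b < a.blocks(); ++b) {
    Rcpp::NumericVector out(cc.act[b].begin(), cc.act[b].end());
    out.attr("dim") = Rcpp::IntegerVector::create(
      cc.act[b].n_rows, cc.act[b].n_cols, cc.act[b].n_slices);
    taps[b] = out;
  }
  return Rcpp::List::create(
    Rcpp::Named("taps") = taps,
    Rcpp::Named("logits") = Rcpp::NumericVector(cc.logits.begin(),
                                                cc.logits.end())
  );
}

// Gradient of the class logit with respect to a tapped post-ReLU activation.
// `tap` is 1-based; `cls` is 0 (C1) or 1 (C2).
// [[Rcpp::export]]
Rcpp::NumericVector dn_tap_grad(Rcpp::List params, Rcpp::List arch,
                                Rcpp::NumericVector x, int H, int W,
                                int cls, int tap) {
  const Arch a = read_arch(arch);
  if (tap < 1 || tap > a.blocks()) Rcpp::stop("unknown tap index");
  if (cls < 0 || cls > 1) Rcpp::stop("class index must be 0 or 1");
  const Params p = read_params(params, a.blocks());
  cube x0 = make_input(x.begin(), H, W, a);
  Cache cc;
  forward(p, a, x0, cc, false);
  vec dlogits(2, fill::zeros);
  dlogits(cls) = 1.0;
  cube dA = backward(p, a, cc, dlogits, nullptr, tap - 1);
  Rcpp::NumericVector out(dA.begin(), dA.end());
  out.attr("dim") = Rcpp::IntegerVector::create(
    dA.n_rows, dA.n_cols, dA.n_slices);
  return out;
}
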