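// Minimal convolutional-network engine for the three cascade stages.
//
// Topology: a stack of "conv blocks" (3x3 conv -> batch norm -> LeakyReLU),
// organised in resolution levels; every level after the first is entered
// through a stride-2 block that also carries the channel increase. The head
// is either a linear coordinate-regression readout (flatten or global
// average pooling of the final feature map) or a 2-way softmax classifier.
// Training: Adam on MSE / softmax cross-entropy, Xavier-uniform init.
//
// Activations are stored per sample as (H*W x C) matrices with the spatial
// index p = y + x*H (column-major, matching R). Convolutions run as
// im2col + GEMM; im2col is recomputed in the backward pass to keep memory
// bounded by the cached activations.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::vec;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

struct Adam {
  mat mW, vW;
  void init(const mat& p) { mW.zeros(p.n_rows, p.n_cols); vW.zeros(p.n_rows, p.n_cols); }
  void step(mat& p, const mat& g, double lr, long t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    mW = b1 * mW + (1 - b1) * g;
    vW = b2 * vW + (1 - b2) * (g % g);
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    p -= lr * (mW / c1) / (arma::sqrt(vW / c2) + eps);
  }
};

struct Block {
  int level;        // 1-based resolution level
  int stride;       // 1 or 2
  int cin, cout;
  int in_h, in_w, out_h, out_w;
  mat W;            // (9*cin) x cout
  vec gamma, beta, rmean, rvar;
  Adam aW, agamma, abeta;
};

struct BlockCache {
  arma::cube x;     // input,  (in_h*in_w)  x cin  x N
  arma::cube zhat;  // normalized pre-activation, (out_h*out_w) x cout x N
  arma::cube y;     // output (post-activation)
  vec istd;         // per-channel 1/sqrt(var+eps) used this pass
};

static void im2col(const mat& x, int h, int w, int c, int stride, mat& col) {
  const int ho = (h + stride - 1) / stride, wo = (w + stride - 1) / stride;
  col.zeros(ho * wo, 9 * c);
  for (int ch = 0; ch < c; ++ch) {
    const double* xc = x.colptr(ch);
    for (int kx = -1; kx <= 1; ++kx) {
      for (int ky = -1; ky <= 1; ++ky) {
        const int k = (ky + 1) + (kx + 1) * 3;
        double* cc = col.colptr(k + 9 * ch);
        for (int xo = 0; xo < wo; ++xo) {
          const int xi = xo * stride + kx;
          if (xi < 0 || xi >= w) continue;
          for (int yo = 0; yo < ho; ++yo) {
            const int yi = yo * stride + ky;
            if (yi < 0 || yi >= h) continue;
            cc[yo + xo * ho] = xc[yi + xi * h];
          }
        }
      }
    }
  }
}

static void col2im_add(const mat& dcol, int h, int w, int c, int stride, mat& dx) {
  const int ho = (h + stride - 1) / stride, wo = (w + stride - 1) / stride;
  for (int ch = 0; ch < c; ++ch) {
    double* xc = dx.colptr(ch);
    for (int kx = -1; kx <= 1; ++kx) {
      for (int ky = -1; ky <= 1; ++ky) {
        const int k = (ky + 1) + (kx + 1) * 3;
        const double* cc = dcol.colptr(k + 9 * ch);
        for (int xo = 0; xo < wo; ++xo) {
          const int xi = xo * stride + kx;
          if (xi < 0 || xi >= w) continue;
          for (int yo = 0; yo < ho; ++yo) {
            const int yi = yo * stride + ky;
            if (yi < 0 || yi >= h) continue;
            xc[yi + xi * h] += cc[yo + xo * ho];
          }
        }
      }
    }
  }
}

class ConvNet {
public:
  int input_h, input_w;
  double leaky;
  std::string head_type;   // "regression" | "classification"
  std::string head_style;  // "flatten" | "gap" | "pool"
  int head_dim;
  int feat_h, feat_w, feat_c, head_in;
  int pool_h = 1, pool_w = 1;  // pooled grid for the "pool" head
  std::vector<Block> blocks;
  mat headW; vec headb;
  Adam aheadW, aheadb;
  long t_step = 0;

  std::vector<BlockCache> caches;
  mat feat_cache;  // N x head_in

  ConvNet(Rcpp::List cfg, int seed) {
    input_h = Rcpp::as<int>(cfg["input_h"]);
    input_w = Rcpp::as<int>(cfg["input_w"]);
    leaky = Rcpp::as<double>(cfg["leaky_slope"]);
    head_type = Rcpp::as<std::string>(cfg["head_type"]);
    head_style = Rcpp::as<std::string>(cfg["head_style"]);
    head_dim = Rcpp::as<int>(cfg["head_dim"]);
    Rcpp::IntegerVector nb = cfg["n_blocks"];
    Rcpp::IntegerVector ch = cfg["channels"];

    std::mt19937 rng((unsigned)seed);
    int h = input_h, w = input_w, cin = 1;
    for (int l = 0; l < nb.size(); ++l) {
      for (int b = 0; b < nb[l]; ++b) {
        Block blk;
        blk.level = l + 1;
        blk.stride = (l > 0 && b == 0) ? 2 : 1;
        blk.cin = cin;
        blk.cout = ch[l];
        blk.in_h = h; blk.in_w = w;
        if (blk.stride == 2) { h = (h + 1) / 2; w = (w + 1) / 2; }
        blk.out_h = h; blk.out_w = w;
        xavier(blk.W, 9 * blk.cin, blk.cout, 9 * blk.cin, 9 * blk.cout, rng);
        blk.gamma.ones(blk.cout); blk.beta.zeros(blk.cout);
        blk.rmean.zeros(blk.cout); blk.rvar.ones(blk.cout);
        blk.aW.init(blk.W);
        blk.agamma.init(blk.gamma); blk.abeta.init(blk.beta);
        cin = blk.cout;
        blocks.push_back(std::move(blk));
      }
    }
    feat_h = h; feat_w = w; feat_c = cin;
    if (head_style == "flatten") {
      head_in = feat_h * feat_w * feat_c;
    } else if (head_style == "pool") {
      int grid = cfg.containsElementNamed("pool_grid")
                     ? Rcpp::as<int>(cfg["pool_grid"]) : 4;
      pool_h = std::min(grid, feat_h); pool_w = std::min(grid, feat_w);
      head_in = pool_h * pool_w * feat_c;
    } else {
      head_in = feat_c;
    }
    xavier(headW, head_in, head_dim, head_in, head_dim, rng);
    // the final linear readout starts near zero: a full-scale random head
    // projects feature noise straight into the output and the short fixed
    // training schedule cannot shrink it back down
    headW *= 0.01;
    headb.zeros(head_dim);
    aheadW.init(headW); aheadb.init(headb);
    caches.resize(blocks.size());
  }

  // adaptive average pooling of the (feat_h*feat_w x C) map to a coarse
  // pool_h x pool_w grid, flattened (spatial-major, then channel)
  arma::vec pool_features(const mat& f) {
    arma::vec out(head_in, arma::fill::zeros);
    for (int c = 0; c < feat_c; ++c) {
      for (int ix = 0; ix < pool_w; ++ix) {
        int x0 = ix * feat_w / pool_w, x1 = (ix + 1) * feat_w / pool_w;
        for (int iy = 0; iy < pool_h; ++iy) {
          int y0 = iy * feat_h / pool_h, y1 = (iy + 1) * feat_h / pool_h;
          double s = 0;
          for (int x = x0; x < x1; ++x)
            for (int y = y0; y < y1; ++y) s += f(y + x * feat_h, c);
          out(iy + ix * pool_h + pool_h * pool_w * c) =
              s / ((y1 - y0) * (x1 - x0));
        }
      }
    }
    return out;
  }

  void pool_backward(const arma::rowvec& dfeat, mat& df) {
    df.zeros(feat_h * feat_w, feat_c);
    for (int c = 0; c < feat_c; ++c) {
      for (int ix = 0; ix < pool_w; ++ix) {
        int x0 = ix * feat_w / pool_w, x1 = (ix + 1) * feat_w / pool_w;
        for (int iy = 0; iy < pool_h; ++iy) {
          int y0 = iy * feat_h / pool_h, y1 = (iy + 1) * feat_h / pool_h;
          double g = dfeat(iy + ix * pool_h + pool_h * pool_w * c) /
                     ((y1 - y0) * (x1 - x0));
          for (int x = x0; x < x1; ++x)
            for (int y = y0; y < y1; ++y) df(y + x * feat_h, c) += g;
        }
      }
    }
  }

  static void xavier(mat& W, int r, int c, int fan_in, int fan_out,
                     std::mt19937& rng) {
    double lim = std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<double> U(-lim, lim);
    W.set_size(r, c);
    for (arma::uword j = 0; j < W.n_cols; ++j)
      for (arma::uword i = 0; i < W.n_rows; ++i) W(i, j) = U(rng);
  }

  // Forward pass. train: use batch statistics; cache: keep intermediates
  // for backward; update_running: fold batch stats into running stats.
  mat forward(const arma::cube& x0, bool train, bool cache, bool update_running) {
    const int N = x0.n_slices;
    arma::cube cur = x0;
    mat colbuf;
    for (size_t bi = 0; bi < blocks.size(); ++bi) {
      Block& B = blocks[bi];
      arma::cube z(B.out_h * B.out_w, B.cout, N);
      for (int n = 0; n < N; ++n) {
        im2col(cur.slice(n), B.in_h, B.in_w, B.cin, B.stride, colbuf);
        z.slice(n) = colbuf * B.W;
      }
      // batch norm over N * positions, per channel
      vec mu(B.cout), var(B.cout);
      if (train) {
        const double M = (double)N * B.out_h * B.out_w;
        for (int c = 0; c < B.cout; ++c) {
          double s = 0, s2 = 0;
          for (int n = 0; n < N; ++n) {
            const vec zc = z.slice(n).col(c);
            s += arma::accu(zc); s2 += arma::dot(zc, zc);
          }
          mu(c) = s / M;
          var(c) = s2 / M - mu(c) * mu(c);
          if (var(c) < 0) var(c) = 0;
        }
        if (update_running) {
          B.rmean = (1 - BN_MOMENTUM) * B.rmean + BN_MOMENTUM * mu;
          B.rvar = (1 - BN_MOMENTUM) * B.rvar + BN_MOMENTUM * var;
        }
      } else {
        mu = B.rmean; var = B.rvar;
      }
      vec istd = 1.0 / arma::sqrt(var + BN_EPS);
      if (cache) {
        caches[bi].x = cur;
        caches[bi].istd = istd;
        caches[bi].zhat.set_size(z.n_rows, z.n_cols, N);
      }
      arma::cube out(z.n_rows, z.n_cols, N);
      for (int n = 0; n < N; ++n) {
        mat zh = z.slice(n);
        zh.each_row() -= mu.t();
        zh.each_row() %= istd.t();
        if (cache) caches[bi].zhat.slice(n) = zh;
        mat y = zh;
        y.each_row() %= B.gamma.t();
        y.each_row() += B.beta.t();
        out.slice(n) = y.transform([&](double v) { return v >= 0 ? v : leaky * v; });
      }
      if (cache) caches[bi].y = out;
      cur = std::move(out);
    }
    // head
    mat feat(N, head_in);
    for (int n = 0; n < N; ++n) {
      if (head_style == "flatten") {
        feat.row(n) = arma::vectorise(cur.slice(n)).t();
      } else if (head_style == "pool") {
        feat.row(n) = pool_features(cur.slice(n)).t();
      } else {
        feat.row(n) = arma::mean(cur.slice(n), 0);
      }
    }
    if (cache) feat_cache = feat;
    mat pred = feat * headW;
    pred.each_row() += headb.t();
    return pred;
  }

  double loss_value(const mat& pred, const mat& ytarget, const arma::ivec& ylab) {
    const int N = pred.n_rows;
    if (head_type == "regression") {
      return arma::accu(arma::square(pred - ytarget)) / (N * head_dim);
    }
    double L = 0;
    for (int n = 0; n < N; ++n) {
      arma::rowvec lg = pred.row(n);
      double m = lg.max();
      double lse = m + std::log(arma::accu(arma::exp(lg - m)));
      L += lse - lg(ylab(n));
    }
    return L / N;
  }

  mat loss_grad(const mat& pred, const mat& ytarget, const arma::ivec& ylab) {
    const int N = pred.n_rows;
    if (head_type == "regression") {
      return 2.0 * (pred - ytarget) / (N * head_dim);
    }
    mat g(N, head_dim);
    for (int n = 0; n < N; ++n) {
      arma::rowvec lg = pred.row(n);
      double m = lg.max();
      arma::rowvec s = arma::exp(lg - m);
      s /= arma::accu(s);
      s(ylab(n)) -= 1.0;
      g.row(n) = s / N;
    }
    return g;
  }

  // Backward from dpred; fills grads (same layout as state vector order).
  void backward(const arma::cube& x0, const mat& dpred,
                mat& dheadW, vec& dheadb,
                std::vector<mat>& dW, std::vector<vec>& dgamma,
                std::vector<vec>& dbeta) {
    const int N = dpred.n_rows;
    dheadW = feat_cache.t() * dpred;
    dheadb = arma::sum(dpred, 0).t();
    mat dfeat = dpred * headW.t();  // N x head_in

    // gradient w.r.t. final feature map
    arma::cube dcur(feat_h * feat_w, feat_c, N);
    for (int n = 0; n < N; ++n) {
      if (head_style == "flatten") {
        dcur.slice(n) = arma::reshape(dfeat.row(n).t(), feat_h * feat_w, feat_c);
      } else if (head_style == "pool") {
        pool_backward(dfeat.row(n), dcur.slice(n));
      } else {
        dcur.slice(n) = arma::repmat(dfeat.row(n) / (feat_h * feat_w),
                                     feat_h * feat_w, 1);
      }
    }

    dW.resize(blocks.size());
    dgamma.resize(blocks.size());
    dbeta.resize(blocks.size());
    mat colbuf;
    for (int bi = (int)blocks.size() - 1; bi >= 0; --bi) {
      Block& B = blocks[bi];
      BlockCache& C = caches[bi];
      const double M = (double)N * B.out_h * B.out_w;
      // LeakyReLU backward (sign of cached output = sign of pre-activation)
      arma::cube dz(B.out_h * B.out_w, B.cout, N);
      for (int n = 0; n < N; ++n) {
        mat dy = dcur.slice(n);
        const mat& y = C.y.slice(n);
        for (arma::uword i = 0; i < dy.n_elem; ++i)
          if (y(i) < 0) dy(i) *= leaky;
        dz.slice(n) = dy;
      }
      // batch-norm backward
      vec dg(B.cout), db(B.cout);
      for (int c = 0; c < B.cout; ++c) {
        double sdg = 0, sdb = 0;
        for (int n = 0; n < N; ++n) {
          sdg += arma::dot(dz.slice(n).col(c), C.zhat.slice(n).col(c));
          sdb += arma::accu(dz.slice(n).col(c));
        }
        dg(c) = sdg; db(c) = sdb;
      }
      dgamma[bi] = dg; dbeta[bi] = db;
      for (int n = 0; n < N; ++n) {
        mat& dzs = dz.slice(n);
        const mat& zh = C.zhat.slice(n);
        for (int c = 0; c < B.cout; ++c) {
          double a = B.gamma(c) * C.istd(c);
          dzs.col(c) = a * (dzs.col(c) - db(c) / M - zh.col(c) * (dg(c) / M));
        }
      }
      // conv backward
      dW[bi].zeros(9 * B.cin, B.cout);
      arma::cube dx(B.in_h * B.in_w, B.cin, N, arma::fill::zeros);
      for (int n = 0; n < N; ++n) {
        im2col(C.x.slice(n), B.in_h, B.in_w, B.cin, B.stride, colbuf);
        dW[bi] += colbuf.t() * dz.slice(n);
        mat dcol = dz.slice(n) * B.W.t();
        col2im_add(dcol, B.in_h, B.in_w, B.cin, B.stride, dx.slice(n));
      }
      dcur = std::move(dx);
    }
  }

  double train_batch(const arma::cube& x0, const mat& ytarget,
                     const arma::ivec& ylab, double lr) {
    mat pred = forward(x0, true, true, true);
    double L = loss_value(pred, ytarget, ylab);
    mat dpred = loss_grad(pred, ytarget, ylab);
    mat dheadW; vec dheadb;
    std::vector<mat> dW; std::vector<vec> dg, db;
    backward(x0, dpred, dheadW, dheadb, dW, dg, db);
    ++t_step;
    for (size_t bi = 0; bi < blocks.size(); ++bi) {
      Block& B = blocks[bi];
      B.aW.step(B.W, dW[bi], lr, t_step);
      mat gg(B.gamma.memptr(), B.cout, 1, false);
      // Adam on vectors via 1-column views
      mat g1(dg[bi]); mat b1(db[bi]);
      mat gpar(B.gamma.n_elem, 1), bpar(B.beta.n_elem, 1);
      gpar.col(0) = B.gamma; bpar.col(0) = B.beta;
      B.agamma.step(gpar, g1, lr, t_step);
      B.abeta.step(bpar, b1, lr, t_step);
      B.gamma = gpar.col(0); B.beta = bpar.col(0);
    }
    aheadW.step(headW, dheadW, lr, t_step);
    mat hb(headb.n_elem, 1); hb.col(0) = headb;
    mat dhb(dheadb);
    aheadb.step(hb, dhb, lr, t_step);
    headb = hb.col(0);
    return L;
  }
};

static ConvNet* get_net(SEXP ptr) {
  Rcpp::XPtr<ConvNet> p(ptr);
  return p.get();
}

// [[Rcpp::export]]
SEXP cnet_create(Rcpp::List cfg, int seed) {
  Rcpp::XPtr<ConvNet> p(new ConvNet(cfg, seed), true);
  return p;
}

static arma::cube as_input(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 3) Rcpp::stop("input must be an (H, W, N) array");
  arma::cube c(x.begin(), (arma::uword)d[0] * d[1], 1, d[2]);
  return c;  // (H*W x 1 x N), column-major spatial index
}

// [[Rcpp::export]]
arma::mat cnet_forward(SEXP ptr, Rcpp::NumericVector x, bool train = false) {
  ConvNet* net = get_net(ptr);
  return net->forward(as_input(x), train, false, false);
}

// [[Rcpp::export]]
double cnet_train_batch(SEXP ptr, Rcpp::NumericVector x, SEXP y, double lr) {
  ConvNet* net = get_net(ptr);
  arma::cube in = as_input(x);
  if (net->head_type == "regression") {
    mat yt = Rcpp::as<mat>(y);
    return net->train_batch(in, yt, arma::ivec(), lr);
  }
  arma::ivec yl = Rcpp::as<arma::ivec>(y);
  return net->train_batch(in, mat(), yl, lr);
}

// [[Rcpp::export]]
double cnet_loss(SEXP ptr, Rcpp::NumericVector x, SEXP y, bool train = false) {
  ConvNet* net = get_net(ptr);
  arma::cube in = as_input(x);
  mat pred = net->forward(in, train, false, false);
  if (net->head_type == "regression")
    return net->loss_value(pred, Rcpp::as<mat>(y), arma::ivec());
  return net->loss_value(pred, mat(), Rcpp::as<arma::ivec>(y));
}

// [[Rcpp::export]]
Rcpp::List cnet_grad(SEXP ptr, Rcpp::NumericVector x, SEXP y, bool train = true) {
  ConvNet* net = get_net(ptr);
  arma::cube in = as_input(x);
  mat pred = net->forward(in, train, true, false);
  mat dpred;
  if (net->head_type == "regression")
    dpred = net->loss_grad(pred, Rcpp::as<mat>(y), arma::ivec());
  else
    dpred = net->loss_grad(pred, mat(), Rcpp::as<arma::ivec>(y));
  mat dheadW; vec dheadb;
  std::vector<mat> dW; std::vector<vec> dg, db;
  net->backward(in, dpred, dheadW, dheadb, dW, dg, db);
  Rcpp::List out;
  for (size_t bi = 0; bi < net->blocks.size(); ++bi) {
    out.push_back(dW[bi], "W" + std::to_string(bi));
    out.push_back(Rcpp::wrap(dg[bi]), "gamma" + std::to_string(bi));
    out.push_back(Rcpp::wrap(db[bi]), "beta" + std::to_string(bi));
  }
  out.push_back(dheadW, "headW");
  out.push_back(Rcpp::wrap(dheadb), "headb");
  return out;
}

// [[Rcpp::export]]
Rcpp::List cnet_get_state(SEXP ptr) {
  ConvNet* net = get_net(ptr);
  Rcpp::List out;
  for (size_t bi = 0; bi < net->blocks.size(); ++bi) {
    Block& B = net->blocks[bi];
    std::string s = std::to_string(bi);
    out.push_back(B.W, "W" + s);
    out.push_back(Rcpp::wrap(B.gamma), "gamma" + s);
    out.push_back(Rcpp::wrap(B.beta), "beta" + s);
    out.push_back(Rcpp::wrap(B.rmean), "rmean" + s);
    out.push_back(Rcpp::wrap(B.rvar), "rvar" + s);
  }
  out.push_back(net->headW, "headW");
  out.push_back(Rcpp::wrap(net->headb), "headb");
  out.push_back((double)net->t_step, "t_step");
  return out;
}

// [[Rcpp::export]]
void cnet_set_state(SEXP ptr, Rcpp::List state) {
  ConvNet* net = get_net(ptr);
  int k = 0;
  for (size_t bi = 0; bi < net->blocks.size(); ++bi) {
    Block& B = net->blocks[bi];
    B.W = Rcpp::as<mat>(state[k++]);
    B.gamma = Rcpp::as<vec>(state[k++]);
    B.beta = Rcpp::as<vec>(state[k++]);
    B.rmean = Rcpp::as<vec>(state[k++]);
    B.rvar = Rcpp::as<vec>(state[k++]);
  }
  net->headW = Rcpp::as<mat>(state[k++]);
  net->headb = Rcpp::as<vec>(state[k++]);
  net->t_step = (long)Rcpp::as<double>(state[k++]);
}

// [[Rcpp::export]]
Rcpp::List cnet_info(SEXP ptr) {
  ConvNet* net = get_net(ptr);
  int n_blocks = (int)net->blocks.size();
  int n_stride2 = 0;
  Rcpp::IntegerVector level(n_blocks), stride(n_blocks), cout(n_blocks);
  long n_params = (long)net->headW.n_elem + net->headb.n_elem;
  for (int i = 0; i < n_blocks; ++i) {
    Block& B = net->blocks[i];
    if (B.stride == 2) ++n_stride2;
    level[i] = B.level; stride[i] = B.stride; cout[i] = B.cout;
    n_params += (long)B.W.n_elem + 2 * B.cout;
  }
  return Rcpp::List::create(
      Rcpp::Named("n_blocks") = n_blocks,
      Rcpp::Named("n_stride2") = n_stride2,
      Rcpp::Named("block_level") = level,
      Rcpp::Named("block_stride") = stride,
      Rcpp::Named("block_channels") = cout,
      Rcpp::Named("feat_h") = net->feat_h,
      Rcpp::Named("feat_w") = net->feat_w,
      Rcpp::Named("feat_c") = net->feat_c,
      Rcpp::Named("head_in") = net->head_in,
      Rcpp::Named("head_dim") = net->head_dim,
      Rcpp::Named("n_params") = (double)n_params);
}
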