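// Minimal feedforward-network machinery for the adversarial aligners.
// Everything is dense, double precision, single threaded; batch rows are
// observations (time bins), columns are channels.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::rowvec;

// activation codes: 0 linear, 1 relu, 2 leaky-relu(0.2), 3 elu(1)
static mat act_fwd(const mat& z, int code) {
  switch (code) {
  case 0: return z;
  case 1: return arma::clamp(z, 0.0, arma::datum::inf);
  case 2: return arma::max(z, 0.2 * z);
  case 3: {
    mat out = z;
    out.for_each([](double& v) { if (v < 0.0) v = std::expm1(v); });
    return out;
  }
  default: Rcpp::stop("unknown activation code");
  }
}

// derivative expressed through pre-activation z and post-activation a
static mat act_grad(const mat& z, const mat& a, int code) {
  switch (code) {
  case 0: return arma::ones<mat>(z.n_rows, z.n_cols);
  case 1: return arma::conv_to<mat>::from(z > 0.0);
  case 2: {
    mat g(z.n_rows, z.n_cols);
    g.fill(0.2);
    g.elem(arma::find(z > 0.0)).fill(1.0);
    return g;
  }
  case 3: {
    mat g = a + 1.0;            // elu'(z) = exp(z) = a+1 for z<0
    g.elem(arma::find(z > 0.0)).fill(1.0);
    return g;
  }
  default: Rcpp::stop("unknown activation code");
  }
}

struct Net {
  std::vector<mat> W;
  std::vector<rowvec> b;
  std::vector<int> act;
  bool residual = false;   // y = out_act(x + mlp(x)); needs n_in == n_out
  int out_act = 0;         // activation applied after the residual add
  // ADAM state + gradient accumulators
  std::vector<mat> mW, vW, gW;
  std::vector<rowvec> mb, vb, gb;
  long step_count = 0;

  size_t L() const { return W.size(); }

  void init_state() {
    mW.clear(); vW.clear(); gW.clear(); mb.clear(); vb.clear(); gb.clear();
    for (size_t l = 0; l < L(); ++l) {
      mW.push_back(arma::zeros<mat>(W[l].n_rows, W[l].n_cols));
      vW.push_back(arma::zeros<mat>(W[l].n_rows, W[l].n_cols));
      gW.push_back(arma::zeros<mat>(W[l].n_rows, W[l].n_cols));
      mb.push_back(arma::zeros<rowvec>(b[l].n_elem));
      vb.push_back(arma::zeros<rowvec>(b[l].n_elem));
      gb.push_back(arma::zeros<rowvec>(b[l].n_elem));
    }
    step_count = 0;
  }

  void zero_grad() {
    for (size_t l = 0; l < L(); ++l) { gW[l].zeros(); gb[l].zeros(); }
  }
};

struct Cache {
  std::vector<mat> A;   // A[0] = input, A[l] = post-activation of layer l
  std::vector<mat> Z;   // pre-activations
  mat ypre;             // pre-out_act output (after residual add)
  mat y;
};

static mat net_forward(Net& net, const mat& X, Cache* cache = nullptr) {
  mat a = X;
  if (cache) { cache->A.clear(); cache->Z.clear(); cache->A.push_back(a); }
  for (size_t l = 0; l < net.L(); ++l) {
    mat z = a * net.W[l];
    z.each_row() += net.b[l];
    a = act_fwd(z, net.act[l]);
    if (cache) { cache->Z.push_back(z); cache->A.push_back(a); }
  }
  mat ypre = net.residual ? mat(X + a) : a;
  mat y = act_fwd(ypre, net.out_act);
  if (cache) { cache->ypre = ypre; cache->y = y; }
  return y;
}

// Backprop dL/dY through the net; optionally accumulates parameter
// gradients; always returns dL/dX (needed to chain through frozen nets).
static mat net_backward(Net& net, const Cache& cache, const mat& dY,
                        bool accumulate) {
  mat dypre = dY % act_grad(cache.ypre, cache.y, net.out_act);
  mat da = dypre;
  for (size_t li = net.L(); li-- > 0;) {
    mat dz = da % act_grad(cache.Z[li], cache.A[li + 1], net.act[li]);
    if (accumulate) {
      net.gW[li] += cache.A[li].t() * dz;
      net.gb[li] += arma::sum(dz, 0);
    }
    da = dz * net.W[li].t();
  }
  if (net.residual) da += dypre;
  return da;
}

// ADAM with optional L1 weight-sparsity term and per-matrix gradient-norm
// clipping (keeps the Wasserstein-style ADAN discriminator from blowing up).
static void adam_step(Net& net, double lr, double l1w, double clip) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  net.step_count += 1;
  const double c1 = 1.0 - std::pow(b1, (double)net.step_count);
  const double c2 = 1.0 - std::pow(b2, (double)net.step_count);
  const double ic2r = 1.0 / std::sqrt(c2);
  // single fused pass per parameter block: gradient-norm clip, moment
  // updates, parameter step and the decoupled L1 shrinkage, no
  // temporaries.  The L1 sparsity term is applied outside the ADAM
  // moment normalization (as in decoupled weight decay): fed through
  // ADAM, its tiny but sign-consistent gradient would be renormalized to
  // a full-size step and erode all weights over long runs.
  const double shrink = lr * l1w;
  auto update = [&](double* w, double* m, double* v, double* g,
                    const arma::uword n) {
    double ss = 0.0;
    if (clip > 0.0) {
      for (arma::uword i = 0; i < n; ++i) ss += g[i] * g[i];
      if (ss > clip * clip) {
        const double sc = clip / std::sqrt(ss);
        for (arma::uword i = 0; i < n; ++i) g[i] *= sc;
      }
    }
    for (arma::uword i = 0; i < n; ++i) {
      m[i] = b1 * m[i] + (1.0 - b1) * g[i];
      v[i] = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
      w[i] -= lr * (m[i] / c1) / (std::sqrt(v[i]) * ic2r + eps);
      if (w[i] > shrink) w[i] -= shrink;
      else if (w[i] < -shrink) w[i] += shrink;
      else w[i] = 0.0;
      g[i] = 0.0;
    }
  };
  for (size_t l = 0; l < net.L(); ++l) {
    update(net.W[l].memptr(), net.mW[l].memptr(), net.vW[l].memptr(),
           net.gW[l].memptr(), net.W[l].n_elem);
    update(net.b[l].memptr(), net.mb[l].memptr(), net.vb[l].memptr(),
           net.gb[l].memptr(), net.b[l].n_elem);
  }
}

// ---- construction / (de)serialization --------------------------------

static Net build_net(const arma::ivec& widths, const arma::ivec& acts,
                     bool residual, int out_act, double last_scale,
                     std::mt19937_64& rng) {
  Net net;
  net.residual = residual;
  net.out_act = out_act;
  std::normal_distribution<double> norm(0.0, 1.0);
  for (size_t l = 0; l + 1 < widths.n_elem; ++l) {
    int nin = widths[l], nout = widths[l + 1];
    double sc = std::sqrt(2.0 / (double)nin);
    if (l + 2 == widths.n_elem) sc *= last_scale;
    mat W(nin, nout);
    for (auto& v : W) v = sc * norm(rng);
    net.W.push_back(W);
    net.b.push_back(arma::zeros<rowvec>(nout));
    net.act.push_back((int)acts[l]);
  }
  net.init_state();
  return net;
}

static Rcpp::List net_to_list(const Net& net) {
  Rcpp::List Ws(net.L()), bs(net.L());
  Rcpp::IntegerVector acts(net.L());
  for (size_t l = 0; l < net.L(); ++l) {
    Ws[l] = net.W[l];
    bs[l] = net.b[l];
    acts[l] = net.act[l];
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = Ws, Rcpp::Named("b") = bs, Rcpp::Named("act") = acts,
    Rcpp::Named("residual") = net.residual,
    Rcpp::Named("out_act") = net.out_act);
}

static Net net_from_list(const Rcpp::List& lst) {
  Net net;
  Rcpp::List Ws = lst["W"], bs = lst["b"];
  Rcpp::IntegerVector acts = lst["act"];
  for (int l = 0; l < Ws.size(); ++l) {
    net.W.push_back(Rcpp::as<mat>(Ws[l]));
    net.b.push_back(Rcpp::as<rowvec>(bs[l]));
    net.act.push_back(acts[l]);
  }
  net.residual = Rcpp::as<bool>(lst["residual"]);
  net.out_act = Rcpp::as<int>(lst["out_act"]);
  net.init_state();
  return net;
}

// [[Rcpp::export(name = ".cpp_net_forward")]]
arma::mat cpp_net_forward(Rcpp::List net_list, arma::mat X) {
  Net net = net_from_list(net_list);
  return net_forward(net, X);
}

// [[Rcpp::export(name = ".cpp_build_net")]]
Rcpp::List cpp_build_net(arma::ivec widths, arma::ivec acts, bool residual,
                         int out_act, double last_scale, int seed) {
  std::mt19937_64 rng((uint64_t)seed);
  Net net = build_net(widths, acts, residual, out_act, last_scale, rng);
  return net_to_list(net);
}

// shuffled index stream with wrap-around reshuffling, so unequal session
// lengths can be consumed in balanced mini-batches
struct IndexStream {
  std::vector<arma::uword> idx;
  size_t pos = 0;
  std::mt19937_64* rng;
  IndexStream(size_t n, std::mt19937_64& r) : rng(&r) {
    idx.resize(n);
    for (size_t i = 0; i < n; ++i) idx[i] = i;
    std::shuffle(idx.begin(), idx.end(), *rng);
  }
  arma::uvec next(size_t bsz) {
    arma::uvec out(bsz);
    for (size_t i = 0; i < bsz; ++i) {
      if (pos >= idx.size()) {
        std::shuffle(idx.begin(), idx.end(), *rng);
        pos = 0;
      }
      out[i] = idx[pos++];
    }
    return out;
  }
};

// deviation loss between discriminator output and a constant label;
// returns loss value, writes gradient (d loss / d y) into grad
static double dev_loss(const mat& y, double label, bool l2, mat& grad) {
  mat e = y - label;
  if (l2) {
    grad = 2.0 * e / (double)e.n_elem;
    return arma::accu(e % e) / (double)e.n_elem;
  }
  grad = arma::sign(e) / (double)e.n_elem;
  return arma::accu(arma::abs(e)) / (double)e.n_elem;
}

// mean absolute elementwise deviation (cycle-consistency term)
static double l1_loss(const mat& a, const mat& ref, mat& grad) {
  mat e = a - ref;
  grad = arma::sign(e) / (double)e.n_elem;
  return arma::accu(arma::abs(e)) / (double)e.n_elem;
}

// ---- Cycle-GAN -------------------------------------------------------

// [[Rcpp::export(name = ".cpp_train_cyclegan")]]
Rcpp::List cpp_train_cyclegan(arma::mat X0, arma::mat Xk, int hidden,
                              int epochs, int batch, double lr_g,
                              double lr_d, double lambda_cyc, bool l2_adv,
                              double l1w, int seed, int ckpt_every,
                              double d_noise) {
  const int N = X0.n_cols;
  if ((int)Xk.n_cols != N) Rcpp::stop("channel-count mismatch");
  std::mt19937_64 rng((uint64_t)seed);
  arma::ivec gw = {N, hidden, hidden, N};
  arma::ivec ga = {1, 1, 0};
  arma::ivec dw = {N, hidden, hidden, 1};
  arma::ivec da = {2, 2, 0};
  // generators are residual with a small-scale last layer: near-identity at
  // init, with a final relu keeping rates nonnegative
  Net G1 = build_net(gw, ga, true, 1, 0.1, rng);   // day-k -> day-0
  Net G2 = build_net(gw, ga, true, 1, 0.1, rng);   // day-0 -> day-k
  Net D1 = build_net(dw, da, false, 0, 1.0, rng);  // scores day-0 domain
  Net D2 = build_net(dw, da, false, 0, 1.0, rng);  // scores day-k domain

  size_t n0 = X0.n_rows, nk = Xk.n_rows;
  size_t per_epoch = (std::max(n0, nk) + batch - 1) / batch;
  IndexStream s0(n0, rng), sk(nk, rng);
  const double clip = 5.0;

  arma::mat hist(epochs, 4, arma::fill::zeros); // advD1, advD2, advG, cyc
  Rcpp::List ckpts;
  std::normal_distribution<double> dnoise(0.0, 1.0);
  // small input noise on both discriminator streams keeps the densities
  // overlapping and stops D from memorizing the finite day-0 sample
  auto jitter = [&](const mat& x) {
    if (d_noise <= 0.0) return x;
    mat out = x;
    for (auto& v : out) v += d_noise * dnoise(rng);
    return out;
  };
  mat dY, dtmp;
  for (int ep = 0; ep < epochs; ++ep) {
    double a1 = 0, a2 = 0, ag = 0, cy = 0;
    for (size_t it = 0; it < per_epoch; ++it) {
      mat x0 = X0.rows(s0.next(batch));
      mat xk = Xk.rows(sk.next(batch));

      // discriminator updates (generators detached)
      mat f1 = net_forward(G1, xk);
      Cache cdr, cdf;
      net_forward(D1, jitter(x0), &cdr);
      net_forward(D1, jitter(f1), &cdf);
      double ld = dev_loss(cdr.y, 1.0, l2_adv, dY);
      net_backward(D1, cdr, dY, true);
      ld += dev_loss(cdf.y, 0.0, l2_adv, dY);
      net_backward(D1, cdf, dY, true);
      adam_step(D1, lr_d, l1w, clip);
      a1 += ld;

      mat f2 = net_forward(G2, x0);
      Cache cdr2, cdf2;
      net_forward(D2, jitter(xk), &cdr2);
      net_forward(D2, jitter(f2), &cdf2);
      ld = dev_loss(cdr2.y, 1.0, l2_adv, dY);
      net_backward(D2, cdr2, dY, true);
      ld += dev_loss(cdf2.y, 0.0, l2_adv, dY);
      net_backward(D2, cdf2, dY, true);
      adam_step(D2, lr_d, l1w, clip);
      a2 += ld;

      // generator update: adversarial + both cycle directions
      Cache cg1, cg2, cd1, cd2, cc21, cc12;
      mat g1k = net_forward(G1, xk, &cg1);          // G1(xk)
      mat g20 = net_forward(G2, x0, &cg2);          // G2(x0)
      net_forward(D1, g1k, &cd1);
      net_forward(D2, g20, &cd2);
      mat ckk = net_forward(G2, g1k, &cc21);        // G2(G1(xk))
      mat c00 = net_forward(G1, g20, &cc12);        // G1(G2(x0))

      double lg = dev_loss(cd1.y, 1.0, l2_adv, dY);
      mat d_g1k = net_backward(D1, cd1, dY, false);
      lg += dev_loss(cd2.y, 1.0, l2_adv, dY);
      mat d_g20 = net_backward(D2, cd2, dY, false);

      double lc = l1_loss(ckk, xk, dtmp);
      d_g1k += net_backward(G2, cc21, lambda_cyc * dtmp, true);
      lc += l1_loss(c00, x0, dtmp);
      d_g20 += net_backward(G1, cc12, lambda_cyc * dtmp, true);

      net_backward(G1, cg1, d_g1k, true);
      net_backward(G2, cg2, d_g20, true);
      adam_step(G1, lr_g, l1w, clip);
      adam_step(G2, lr_g, l1w, clip);
      ag += lg;
      cy += lc;
      if (!std::isfinite(lg) || !std::isfinite(lc))
        Rcpp::stop("non-finite loss at epoch %d", ep + 1);
    }
    hist(ep, 0) = a1 / per_epoch;
    hist(ep, 1) = a2 / per_epoch;
    hist(ep, 2) = ag / per_epoch;
    hist(ep, 3) = cy / per_epoch;
    if (ckpt_every > 0 && ((ep + 1) % ckpt_every == 0 || ep + 1 == epochs)) {
      ckpts.push_back(Rcpp::List::create(
        Rcpp::Named("epoch") = ep + 1,
        Rcpp::Named("G1") = net_to_list(G1),
        Rcpp::Named("G2") = net_to_list(G2)));
    }
    if (ep % 25 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("G1") = net_to_list(G1), Rcpp::Named("G2") = net_to_list(G2),
    Rcpp::Named("D1") = net_to_list(D1), Rcpp::Named("D2") = net_to_list(D2),
    Rcpp::Named("history") = hist, Rcpp::Named("checkpoints") = ckpts);
}

// ---- day-0 autoencoder (ADAN latent discovery) -----------------------

// Autoencoder with a jointly trained linear auxiliary readout from the
// bottleneck to the motor outputs; the readout is discarded after training.
// [[Rcpp::export(name = ".cpp_train_autoencoder")]]
Rcpp::List cpp_train_autoencoder(arma::mat X, arma::mat Y, int hidden,
                                 int latent_dim, double aux_weight,
                                 int epochs, int batch, double lr,
                                 double l1w, int seed) {
  const int N = X.n_cols, M = Y.n_cols;
  std::mt19937_64 rng((uint64_t)seed);
  arma::ivec ew = {N, hidden, latent_dim}, dw = {latent_dim, hidden, N};
  arma::ivec aa = {3, 0};
  Net enc = build_net(ew, aa, false, 0, 1.0, rng);
  Net dec = build_net(dw, aa, false, 0, 1.0, rng);
  std::normal_distribution<double> norm(0.0, 1.0);
  mat A(latent_dim, M);
  for (auto& v : A) v = 0.1 * norm(rng);
  rowvec ab = arma::zeros<rowvec>(M);
  mat mA = arma::zeros<mat>(latent_dim, M), vA = mA;
  rowvec mab = ab, vab = ab;

  size_t n = X.n_rows;
  size_t per_epoch = (n + batch - 1) / batch;
  IndexStream sx(n, rng);
  arma::vec hist(epochs, arma::fill::zeros);
  long astep = 0;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8, clip = 5.0;

  for (int ep = 0; ep < epochs; ++ep) {
    double tot = 0;
    for (size_t it = 0; it < per_epoch; ++it) {
      arma::uvec ids = sx.next(batch);
      mat xb = X.rows(ids), yb = Y.rows(ids);
      Cache ce, cd;
      mat z = net_forward(enc, xb, &ce);
      mat r = net_forward(dec, z, &cd);
      mat er = r - xb;
      double loss = arma::accu(er % er) / (double)er.n_elem;
      mat dR = 2.0 * er / (double)er.n_elem;
      mat dZ = net_backward(dec, cd, dR, true);

      mat yh = z * A;
      yh.each_row() += ab;
      mat ey = yh - yb;
      loss += aux_weight * arma::accu(ey % ey) / (double)ey.n_elem;
      mat dYh = aux_weight * 2.0 * ey / (double)ey.n_elem;
      dZ += dYh * A.t();
      mat gA = z.t() * dYh;
      rowvec gab = arma::sum(dYh, 0);

      net_backward(enc, ce, dZ, true);
      adam_step(enc, lr, l1w, clip);
      adam_step(dec, lr, l1w, clip);
      astep += 1;
      double c1 = 1.0 - std::pow(b1, (double)astep);
      double c2 = 1.0 - std::pow(b2, (double)astep);
      mA = b1 * mA + (1 - b1) * gA;  vA = b2 * vA + (1 - b2) * (gA % gA);
      A -= lr * (mA / c1) / (arma::sqrt(vA / c2) + eps);
      mab = b1 * mab + (1 - b1) * gab; vab = b2 * vab + (1 - b2) * (gab % gab);
      ab -= lr * (mab / c1) / (arma::sqrt(vab / c2) + eps);
      tot += loss;
      if (!std::isfinite(loss)) Rcpp::stop("non-finite loss at epoch %d", ep + 1);
    }
    hist(ep) = tot / per_epoch;
    if (ep % 25 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("encoder") = net_to_list(enc),
    Rcpp::Named("decoder") = net_to_list(dec),
    Rcpp::Named("aux_readout") = A, Rcpp::Named("aux_bias") = ab,
    Rcpp::Named("history") = hist);
}

// ---- ADAN ------------------------------------------------------------

// Discriminator is an autoencoder; its per-sample descriptor is the L1
// norm of the reconstruction residual.  D maximizes the separation of the
// mean descriptors of true day-0 samples vs generated samples (difference
// of means of a 1-Lipschitz map of samples: a Wasserstein-1 lower bound);
// G minimizes the generated-sample descriptor mean.
// [[Rcpp::export(name = ".cpp_train_adan")]]
Rcpp::List cpp_train_adan(arma::mat X0, arma::mat Xk, Rcpp::List enc0,
                          Rcpp::List dec0, int g_hidden, int epochs,
                          int batch, double lr_g, double lr_d, double l1w,
                          int seed, int ckpt_every, double d_noise,
                          double hinge) {
  const int N = X0.n_cols;
  if ((int)Xk.n_cols != N) Rcpp::stop("channel-count mismatch");
  std::mt19937_64 rng((uint64_t)seed);
  arma::ivec gw = {N, g_hidden, g_hidden, N};
  arma::ivec ga = {3, 3, 0};
  Net G = build_net(gw, ga, true, 1, 0.1, rng);
  Net Denc = net_from_list(enc0), Ddec = net_from_list(dec0);

  size_t n0 = X0.n_rows, nk = Xk.n_rows;
  size_t per_epoch = (std::max(n0, nk) + batch - 1) / batch;
  IndexStream s0(n0, rng), sk(nk, rng);
  arma::mat hist(epochs, 2, arma::fill::zeros); // mean r(real), mean r(fake)
  Rcpp::List ckpts;
  std::normal_distribution<double> dnoise(0.0, 1.0);
  auto jitter = [&](const mat& x) {
    if (d_noise <= 0.0) return x;
    mat out = x;
    for (auto& v : out) v += d_noise * dnoise(rng);
    return out;
  };
  const double clip = 1.0;

  for (int ep = 0; ep < epochs; ++ep) {
    double rr = 0, rf = 0;
    for (size_t it = 0; it < per_epoch; ++it) {
      mat x0 = X0.rows(s0.next(batch));
      mat xk = Xk.rows(sk.next(batch));
      double B = (double)x0.n_rows;

      // D step: minimize mean r(x0) - mean r(G(xk)), G detached
      mat fk = net_forward(G, xk);
      x0 = jitter(x0);
      fk = jitter(fk);
      Cache ce0, cd0, cek, cdk;
      mat z0 = net_forward(Denc, x0, &ce0);
      mat r0 = net_forward(Ddec, z0, &cd0);
      mat e0 = x0 - r0;
      mat zk = net_forward(Denc, fk, &cek);
      mat rk = net_forward(Ddec, zk, &cdk);
      mat ek = fk - rk;
      double r0_mean = arma::accu(arma::abs(e0)) / B;
      double rf_mean = arma::accu(arma::abs(ek)) / B;
      rr += r0_mean;
      rf += rf_mean;
      // d/dR of sum|x - R| is -sign(e).  The real-reconstruction term is
      // weighted 2x so that, even when the two distributions coincide and
      // the real/fake terms would otherwise cancel, a restoring force
      // keeps D an honest day-0 autoencoder.  The fake term is hinged:
      // once generated-sample residuals exceed `hinge` times the real
      // ones, D stops inflating them (bounds the Wasserstein surrogate).
      mat dz = net_backward(Ddec, cd0, -2.0 * arma::sign(e0) / B, true);
      net_backward(Denc, ce0, dz, true);
      if (rf_mean < hinge * r0_mean) {
        dz = net_backward(Ddec, cdk, arma::sign(ek) / B, true);
        net_backward(Denc, cek, dz, true);
      }
      adam_step(Denc, lr_d, l1w, clip);
      adam_step(Ddec, lr_d, l1w, clip);

      // G step: minimize mean r(G(xk)), D detached
      Cache cg, ce, cd;
      mat fk2 = net_forward(G, xk, &cg);
      mat z2 = net_forward(Denc, fk2, &ce);
      mat r2 = net_forward(Ddec, z2, &cd);
      mat e2 = fk2 - r2;
      // r depends on its input both directly and through the autoencoder
      mat dIn = arma::sign(e2) / B;
      mat dz2 = net_backward(Ddec, cd, -arma::sign(e2) / B, false);
      dIn += net_backward(Denc, ce, dz2, false);
      net_backward(G, cg, dIn, true);
      adam_step(G, lr_g, l1w, clip);
      if (!std::isfinite(rr) || !std::isfinite(rf))
        Rcpp::stop("non-finite loss at epoch %d", ep + 1);
    }
    hist(ep, 0) = rr / per_epoch;
    hist(ep, 1) = rf / per_epoch;
    if (ckpt_every > 0 && ((ep + 1) % ckpt_every == 0 || ep + 1 == epochs)) {
      ckpts.push_back(Rcpp::List::create(
        Rcpp::Named("epoch") = ep + 1,
        Rcpp::Named("G") = net_to_list(G)));
    }
    if (ep % 25 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("G") = net_to_list(G),
    Rcpp::Named("D_encoder") = net_to_list(Denc),
    Rcpp::Named("D_decoder") = net_to_list(Ddec),
    Rcpp::Named("history") = hist, Rcpp::Named("checkpoints") = ckpts);
}
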