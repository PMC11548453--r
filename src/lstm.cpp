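// Windowed many-to-one LSTM binary classifier: forward pass, full
// backpropagation through time, Adam updates, and the training loop with the
// three stopping rules (epoch budget, validation-loss patience, wall-clock
// cap) and best-weights restoration.
//
// Window tensors arrive as arma::cube with dimensions
// (n_windows, n_channels, window_len): slice t is the (batch x channels)
// input at time step t.

#include <RcppArmadillo.h>
#include <chrono>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat sigm(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// activation codes: 0 = tanh, 1 = sigmoid, 2 = relu
static arma::mat act_fun(const arma::mat& x, int a) {
  if (a == 0) return arma::tanh(x);
  if (a == 1) return sigm(x);
  return arma::clamp(x, 0.0, arma::datum::inf);
}

// derivative expressed through the activation output
static arma::mat dact_from_out(const arma::mat& o, int a) {
  if (a == 0) return 1.0 - arma::square(o);
  if (a == 1) return o % (1.0 - o);
  return arma::conv_to<arma::mat>::from(o > 0.0);
}

// Parameter vector layout: per LSTM layer l: [3l] W (d x 4u), [3l+1] U
// (u x 4u), [3l+2] b (1 x 4u); then optionally dense W (u x d_dense), dense
// b (1 x d_dense); then output w (d_out x 1), output b (1 x 1).
struct NetSpec {
  int n_layers, units, act;
  bool has_dense;
  double dropout;
};

static std::vector<arma::mat> unpack_params(const List& weights, NetSpec& spec) {
  List layers = weights["layers"];
  spec.n_layers = layers.size();
  std::vector<arma::mat> P;
  for (int l = 0; l < spec.n_layers; ++l) {
    List lay = layers[l];
    P.push_back(as<arma::mat>(lay["W"]));
    P.push_back(as<arma::mat>(lay["U"]));
    P.push_back(as<arma::mat>(lay["b"]));
  }
  spec.units = P[1].n_rows;
  spec.has_dense = weights.containsElementNamed("dense") &&
    !Rf_isNull(weights["dense"]);
  if (spec.has_dense) {
    List d = weights["dense"];
    P.push_back(as<arma::mat>(d["W"]));
    P.push_back(as<arma::mat>(d["b"]));
  }
  List out = weights["out"];
  P.push_back(as<arma::mat>(out["w"]));
  P.push_back(as<arma::mat>(out["b"]));
  return P;
}

static List pack_params(const std::vector<arma::mat>& P, const NetSpec& spec) {
  List layers(spec.n_layers);
  for (int l = 0; l < spec.n_layers; ++l) {
    layers[l] = List::create(_["W"] = P[3 * l], _["U"] = P[3 * l + 1],
                             _["b"] = P[3 * l + 2]);
  }
  int k = 3 * spec.n_layers;
  RObject dense = R_NilValue;
  if (spec.has_dense) {
    dense = List::create(_["W"] = P[k], _["b"] = P[k + 1]);
    k += 2;
  }
  return List::create(_["layers"] = layers, _["dense"] = dense,
                      _["out"] = List::create(_["w"] = P[k], _["b"] = P[k + 1]));
}

struct Cache {
  // per layer, per time step
  std::vector<std::vector<arma::mat>> I, F, G, O, Ph, C, H;
  arma::mat h_final, z_dense, drop_mask;
};

// Forward pass over the selected rows. When `cache` is non-null all
// intermediate states are kept for BPTT and dropout is applied (inverted
// scaling) using `rng`.
static arma::vec forward(const arma::cube& X, const arma::uvec& rows,
                         const std::vector<arma::mat>& P, const NetSpec& spec,
                         Cache* cache, std::mt19937* rng) {
  const int w = X.n_slices;
  const int b = rows.n_elem;
  const int u = spec.units;
  std::vector<arma::mat> Hseq_prev;  // output sequence of the layer below

  if (cache) {
    cache->I.assign(spec.n_layers, {});
    cache->F.assign(spec.n_layers, {});
    cache->G.assign(spec.n_layers, {});
    cache->O.assign(spec.n_layers, {});
    cache->Ph.assign(spec.n_layers, {});
    cache->C.assign(spec.n_layers, {});
    cache->H.assign(spec.n_layers, {});
  }

  for (int l = 0; l < spec.n_layers; ++l) {
    const arma::mat& W = P[3 * l];
    const arma::mat& U = P[3 * l + 1];
    const arma::mat& bias = P[3 * l + 2];
    arma::mat H(b, u, arma::fill::zeros), C(b, u, arma::fill::zeros);
    std::vector<arma::mat> Hseq;
    Hseq.reserve(w);
    for (int t = 0; t < w; ++t) {
      arma::mat Xt = (l == 0) ? arma::mat(X.slice(t)).rows(rows) : Hseq_prev[t];
      arma::mat A = Xt * W + H * U;
      A.each_row() += bias.row(0);
      arma::mat Ig = sigm(A.cols(0, u - 1));
      arma::mat Fg = sigm(A.cols(u, 2 * u - 1));
      arma::mat Gg = act_fun(A.cols(2 * u, 3 * u - 1), spec.act);
      arma::mat Og = sigm(A.cols(3 * u, 4 * u - 1));
      C = Fg % C + Ig % Gg;
      arma::mat Ph = act_fun(C, spec.act);
      H = Og % Ph;
      Hseq.push_back(H);
      if (cache) {
        cache->I[l].push_back(Ig);
        cache->F[l].push_back(Fg);
        cache->G[l].push_back(Gg);
        cache->O[l].push_back(Og);
        cache->Ph[l].push_back(Ph);
        cache->C[l].push_back(C);
        cache->H[l].push_back(H);
      }
    }
    Hseq_prev = std::move(Hseq);
  }

  arma::mat h = Hseq_prev[w - 1];
  if (cache && spec.dropout > 0.0) {
    std::bernoulli_distribution keep(1.0 - spec.dropout);
    arma::mat mask(h.n_rows, h.n_cols);
    for (arma::uword j = 0; j < mask.n_elem; ++j)
      mask(j) = keep(*rng) ? 1.0 / (1.0 - spec.dropout) : 0.0;
    h %= mask;
    cache->drop_mask = mask;
  } else if (cache) {
    cache->drop_mask = arma::mat(h.n_rows, h.n_cols, arma::fill::ones);
  }

  int k = 3 * spec.n_layers;
  arma::mat z = h;
  if (spec.has_dense) {
    z = h * P[k];
    z.each_row() += P[k + 1].row(0);
    z = arma::clamp(z, 0.0, arma::datum::inf);  // relu dense
    k += 2;
  }
  if (cache) {
    cache->h_final = h;
    cache->z_dense = z;
  }
  arma::vec logits = z * P[k].col(0) + P[k + 1](0, 0);
  return 1.0 / (1.0 + arma::exp(-logits));
}

static double bce(const arma::vec& p, const arma::vec& y) {
  arma::vec pc = arma::clamp(p, 1e-7, 1.0 - 1e-7);
  return -arma::mean(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc));
}

// Backward pass: fills `grad` (same layout as P) from a cached forward.
static void backward(const arma::cube& X, const arma::uvec& rows,
                     const arma::vec& y, const arma::vec& p,
                     const std::vector<arma::mat>& P, const NetSpec& spec,
                     const Cache& cache, std::vector<arma::mat>& grad) {
  const int w = X.n_slices;
  const int b = rows.n_elem;
  const int u = spec.units;
  for (size_t i = 0; i < P.size(); ++i)
    grad[i] = arma::mat(P[i].n_rows, P[i].n_cols, arma::fill::zeros);

  arma::vec dlogit = (p - y) / (double)b;
  int k = 3 * spec.n_layers + (spec.has_dense ? 2 : 0);
  grad[k] = cache.z_dense.t() * dlogit;            // output weights
  grad[k + 1](0, 0) = arma::accu(dlogit);
  arma::mat dz = dlogit * P[k].col(0).t();
  arma::mat dh;
  if (spec.has_dense) {
    int kd = 3 * spec.n_layers;
    arma::mat drelu = dz % dact_from_out(cache.z_dense, 2);
    grad[kd] = cache.h_final.t() * drelu;
    grad[kd + 1] = arma::sum(drelu, 0);
    dh = drelu * P[kd].t();
  } else {
    dh = dz;
  }
  dh %= cache.drop_mask;

  // dH_ext[t]: external gradient flowing into layer l at time t
  std::vector<arma::mat> dHext(w, arma::mat(b, u, arma::fill::zeros));
  dHext[w - 1] = dh;

  for (int l = spec.n_layers - 1; l >= 0; --l) {
    const arma::mat& W = P[3 * l];
    const arma::mat& U = P[3 * l + 1];
    int d_in = W.n_rows;
    std::vector<arma::mat> dXlower;
    if (l > 0) dXlower.assign(w, arma::mat(b, d_in, arma::fill::zeros));
    arma::mat dHrec(b, u, arma::fill::zeros), dCrec(b, u, arma::fill::zeros);
    for (int t = w - 1; t >= 0; --t) {
      arma::mat dH = dHext[t] + dHrec;
      const arma::mat& I = cache.I[l][t];
      const arma::mat& F = cache.F[l][t];
      const arma::mat& G = cache.G[l][t];
      const arma::mat& O = cache.O[l][t];
      const arma::mat& Ph = cache.Ph[l][t];
      arma::mat da_o = (dH % Ph) % O % (1.0 - O);
      arma::mat dC = dCrec + dH % O % dact_from_out(Ph, spec.act);
      arma::mat da_i = (dC % G) % I % (1.0 - I);
      arma::mat Cprev = (t > 0) ? cache.C[l][t - 1]
                                : arma::mat(b, u, arma::fill::zeros);
      arma::mat da_f = (dC % Cprev) % F % (1.0 - F);
      arma::mat da_g = (dC % I) % dact_from_out(G, spec.act);
      arma::mat da = arma::join_rows(da_i, da_f, da_g, da_o);
      arma::mat Xt = (l == 0) ? arma::mat(X.slice(t)).rows(rows)
                              : cache.H[l - 1][t];
      arma::mat Hprev = (t > 0) ? cache.H[l][t - 1]
                                : arma::mat(b, u, arma::fill::zeros);
      grad[3 * l] += Xt.t() * da;
      grad[3 * l + 1] += Hprev.t() * da;
      grad[3 * l + 2] += arma::sum(da, 0);
      if (l > 0) dXlower[t] = da * W.t();
      dHrec = da * U.t();
      dCrec = dC % F;
    }
    if (l > 0) dHext = std::move(dXlower);
  }
}

static double eval_loss(const arma::cube& X, const arma::vec& y,
                        const std::vector<arma::mat>& P, const NetSpec& spec) {
  const arma::uword n = X.n_rows, chunk = 4096;
  double total = 0.0;
  for (arma::uword s = 0; s < n; s += chunk) {
    arma::uword e = std::min(s + chunk, n) - 1;
    arma::uvec rows = arma::regspace<arma::uvec>(s, e);
    arma::vec p = forward(X, rows, P, spec, nullptr, nullptr);
    total += bce(p, y.subvec(s, e)) * rows.n_elem;
  }
  return total / n;
}

// [[Rcpp::export]]
arma::vec cpp_lstm_predict(const arma::cube& X, const List& weights,
                           int activation, bool has_dense_ignored = false) {
  NetSpec spec;
  std::vector<arma::mat> P = unpack_params(weights, spec);
  spec.act = activation;
  spec.dropout = 0.0;
  const arma::uword n = X.n_rows, chunk = 4096;
  arma::vec out(n);
  for (arma::uword s = 0; s < n; s += chunk) {
    arma::uword e = std::min(s + chunk, n) - 1;
    arma::uvec rows = arma::regspace<arma::uvec>(s, e);
    out.subvec(s, e) = forward(X, rows, P, spec, nullptr, nullptr);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_lstm_fit(const arma::cube& X, const arma::vec& y,
                  const arma::cube& Xval, const arma::vec& yval,
                  const List& weights, const List& ctl) {
  NetSpec spec;
  std::vector<arma::mat> P = unpack_params(weights, spec);
  spec.act = as<int>(ctl["activation"]);
  spec.dropout = as<double>(ctl["dropout"]);
  const double lr = as<double>(ctl["learning_rate"]);
  const int batch = as<int>(ctl["batch_size"]);
  const int epochs = as<int>(ctl["epochs"]);
  const int patience = as<int>(ctl["patience"]);
  const double max_seconds = as<double>(ctl["max_seconds"]);
  const double clipnorm = as<double>(ctl["clipnorm"]);
  std::mt19937 rng(as<unsigned int>(ctl["seed"]));

  const arma::uword n = X.n_rows;
  std::vector<arma::mat> grad(P.size()), m(P.size()), v(P.size());
  for (size_t i = 0; i < P.size(); ++i) {
    m[i] = arma::mat(P[i].n_rows, P[i].n_cols, arma::fill::zeros);
    v[i] = m[i];
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  long step = 0;

  std::vector<arma::uword> order(n);
  for (arma::uword i = 0; i < n; ++i) order[i] = i;

  double best_val = arma::datum::inf;
  std::vector<arma::mat> best_P = P;
  int best_epoch = 0, wait = 0;
  std::string stop_reason = "epochs";
  std::vector<double> tr_hist, val_hist, sec_hist;
  auto t_start = std::chrono::steady_clock::now();
  auto elapsed = [&]() {
    return std::chrono::duration<double>(
      std::chrono::steady_clock::now() - t_start).count();
  };

  bool out_of_time = false;
  for (int epoch = 0; epoch < epochs && !out_of_time; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0;
    arma::uword seen = 0;
    Cache cache;
    for (arma::uword s = 0; s < n; s += batch) {
      arma::uword e = std::min<arma::uword>(s + batch, n) - 1;
      arma::uvec rows(e - s + 1);
      for (arma::uword i = s; i <= e; ++i) rows(i - s) = order[i];
      arma::vec yb = y.elem(rows);
      arma::vec p = forward(X, rows, P, spec, &cache, &rng);
      loss_sum += bce(p, yb) * rows.n_elem;
      seen += rows.n_elem;
      backward(X, rows, yb, p, P, spec, cache, grad);

      // global gradient-norm clipping, then Adam
      double gn2 = 0.0;
      for (auto& g : grad) gn2 += arma::accu(arma::square(g));
      double scale = 1.0;
      if (clipnorm > 0.0 && std::sqrt(gn2) > clipnorm)
        scale = clipnorm / std::sqrt(gn2);
      ++step;
      double c1 = 1.0 - std::pow(b1, (double)step);
      double c2 = 1.0 - std::pow(b2, (double)step);
      for (size_t i = 0; i < P.size(); ++i) {
        arma::mat g = grad[i] * scale;
        m[i] = b1 * m[i] + (1.0 - b1) * g;
        v[i] = b2 * v[i] + (1.0 - b2) * arma::square(g);
        P[i] -= lr * (m[i] / c1) / (arma::sqrt(v[i] / c2) + eps);
      }
      if (elapsed() > max_seconds) { out_of_time = true; break; }
    }
    double val_loss = eval_loss(Xval, yval, P, spec);
    tr_hist.push_back(loss_sum / seen);
    val_hist.push_back(val_loss);
    sec_hist.push_back(elapsed());
    if (val_loss < best_val) {
      best_val = val_loss;
      best_P = P;
      best_epoch = epoch + 1;
      wait = 0;
    } else if (++wait >= patience) {
      stop_reason = "patience";
      break;
    }
    if (out_of_time) stop_reason = "time";
  }
  if (out_of_time) stop_reason = "time";

  return List::create(
    _["weights"] = pack_params(best_P, spec),
    _["history"] = DataFrame::create(
      _["epoch"] = seq_len(tr_hist.size()),
      _["train_loss"] = tr_hist, _["val_loss"] = val_hist,
      _["seconds"] = sec_hist),
    _["best_epoch"] = best_epoch,
    _["best_val_loss"] = best_val,
    _["stop_reason"] = stop_reason);
}
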