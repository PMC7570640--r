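// Single-cell LSTM: forward pass, backpropagation-through-time, and the
// mini-batch training loop (ADAM / SGD-with-momentum).  All stochastic
// choices (initial weights, shuffle order) are made in R and passed in, so
// the C++ side is fully deterministic.
//
// Layout conventions:
//   * A sequence is a D x T matrix (D = flattened per-step input, T steps).
//   * A dataset is a cube D x T x N.
//   * Gate pre-activations are stacked rows [forget; input; candidate;
//     output], each H rows, i.e. W is 4H x D, R is 4H x H, b is 4H.
//   * Class labels are 0-based integers 0..K-1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Params {
  arma::mat W;   // 4H x D input weights
  arma::mat R;   // 4H x H recurrent weights
  arma::vec b;   // 4H biases
  arma::mat Wy;  // K x H fully-connected head
  arma::vec by;  // K head biases
  arma::uword H, D, K;
};

Params unpack(const List& p) {
  Params P;
  P.W  = as<arma::mat>(p["W"]);
  P.R  = as<arma::mat>(p["R"]);
  P.b  = as<arma::vec>(p["b"]);
  P.Wy = as<arma::mat>(p["Wy"]);
  P.by = as<arma::vec>(p["by"]);
  P.H  = P.R.n_cols;
  P.D  = P.W.n_cols;
  P.K  = P.Wy.n_rows;
  if (P.W.n_rows != 4 * P.H || P.R.n_rows != 4 * P.H || P.b.n_elem != 4 * P.H)
    stop("inconsistent LSTM parameter shapes");
  if (P.Wy.n_cols != P.H || P.by.n_elem != P.K)
    stop("inconsistent head parameter shapes");
  return P;
}

inline arma::mat sigm(const arma::mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// Gather a batch into one D x (T*B) matrix, columns ordered time-major
// (all batch members of step t are contiguous) so W * Xbig is one GEMM.
// Optional per-row standardisation (center/scale of length D) is applied
// while copying, so callers never materialise standardised copies.
arma::mat gather(const arma::cube& X, const arma::uvec& idx,
                 const arma::vec& center, const arma::vec& scale) {
  const arma::uword D = X.n_rows, T = X.n_cols, B = idx.n_elem;
  const bool std = center.n_elem == D;
  arma::mat Xbig(D, T * B);
  for (arma::uword b = 0; b < B; ++b) {
    const arma::mat& S = X.slice(idx[b]);
    for (arma::uword t = 0; t < T; ++t) {
      double* dst = Xbig.colptr(t * B + b);
      const double* src = S.colptr(t);
      if (std)
        for (arma::uword i = 0; i < D; ++i)
          dst[i] = (src[i] - center[i]) / scale[i];
      else
        std::copy(src, src + D, dst);
    }
  }
  return Xbig;
}

struct Cache {
  arma::cube F, I, G, O, C, Th, Hs;  // each H x B x T
};

// Forward over a gathered batch; fills cache when requested.
void forward_core(const Params& P, const arma::mat& Xbig, arma::uword T,
                  arma::uword B, arma::mat& hT, arma::mat& scores,
                  Cache* cache) {
  const arma::uword H = P.H;
  arma::mat Z = P.W * Xbig;  // 4H x T*B
  Z.each_col() += P.b;
  arma::mat h(H, B, arma::fill::zeros), c(H, B, arma::fill::zeros);
  if (cache) {
    cache->F.set_size(H, B, T);  cache->I.set_size(H, B, T);
    cache->G.set_size(H, B, T);  cache->O.set_size(H, B, T);
    cache->C.set_size(H, B, T);  cache->Th.set_size(H, B, T);
    cache->Hs.set_size(H, B, T);
  }
  for (arma::uword t = 0; t < T; ++t) {
    arma::mat Zt = Z.cols(t * B, t * B + B - 1) + P.R * h;
    arma::mat f = sigm(Zt.rows(0, H - 1));
    arma::mat i = sigm(Zt.rows(H, 2 * H - 1));
    arma::mat g = arma::tanh(Zt.rows(2 * H, 3 * H - 1));
    arma::mat o = sigm(Zt.rows(3 * H, 4 * H - 1));
    c = f % c + i % g;
    arma::mat th = arma::tanh(c);
    h = o % th;
    if (cache) {
      cache->F.slice(t) = f;  cache->I.slice(t) = i;
      cache->G.slice(t) = g;  cache->O.slice(t) = o;
      cache->C.slice(t) = c;  cache->Th.slice(t) = th;
      cache->Hs.slice(t) = h;
    }
  }
  hT = h;
  scores = P.Wy * h;
  scores.each_col() += P.by;
}

double softmax_ce(const arma::mat& scores, const arma::ivec& y,
                  arma::mat& dS) {
  const arma::uword K = scores.n_rows, B = scores.n_cols;
  dS.set_size(K, B);
  double ce = 0.0;
  for (arma::uword b = 0; b < B; ++b) {
    arma::vec s = scores.col(b);
    s -= s.max();
    arma::vec e = arma::exp(s);
    arma::vec p = e / arma::accu(e);
    ce += -std::log(std::max(p[y[b]], 1e-300));
    p[y[b]] -= 1.0;
    dS.col(b) = p;
  }
  dS /= static_cast<double>(B);
  return ce / static_cast<double>(B);
}

struct Grads {
  arma::mat W, R, Wy;
  arma::vec b, by;
};

double l2_penalty(const Params& P, double l2) {
  return 0.5 * l2 * (arma::accu(P.W % P.W) + arma::accu(P.R % P.R) +
                     arma::accu(P.Wy % P.Wy));
}

// Loss and full BPTT gradients for one batch (already gathered). With
// add_l2 the L2 term is folded into loss and gradients here; the training
// loop instead passes add_l2 = false and fuses the L2 handling into its
// update pass (fewer sweeps over the large parameter arrays).
double backward_core(const Params& P, const arma::mat& Xbig, arma::uword T,
                     arma::uword B, const arma::ivec& y, double l2,
                     Grads& g, bool add_l2 = true) {
  const arma::uword H = P.H;
  arma::mat hT, scores;
  Cache cache;
  forward_core(P, Xbig, T, B, hT, scores, &cache);

  arma::mat dS;
  double loss = softmax_ce(scores, y, dS) +
                (add_l2 ? l2_penalty(P, l2) : 0.0);

  g.Wy = dS * hT.t();
  g.by = arma::sum(dS, 1);
  g.R.zeros(4 * H, H);
  g.b.zeros(4 * H);

  arma::mat dh = P.Wy.t() * dS;
  arma::mat dc(H, B, arma::fill::zeros);
  arma::mat dZ(4 * H, T * B);
  arma::mat zero(H, B, arma::fill::zeros);
  for (arma::uword tt = T; tt-- > 0;) {
    const arma::mat& f = cache.F.slice(tt);
    const arma::mat& i = cache.I.slice(tt);
    const arma::mat& gg = cache.G.slice(tt);
    const arma::mat& o = cache.O.slice(tt);
    const arma::mat& th = cache.Th.slice(tt);
    const arma::mat& cprev = (tt == 0) ? zero : cache.C.slice(tt - 1);
    const arma::mat& hprev = (tt == 0) ? zero : cache.Hs.slice(tt - 1);

    dc += dh % o % (1.0 - th % th);
    arma::mat dzo = (dh % th) % o % (1.0 - o);
    arma::mat dzg = (dc % i) % (1.0 - gg % gg);
    arma::mat dzi = (dc % gg) % i % (1.0 - i);
    arma::mat dzf = (dc % cprev) % f % (1.0 - f);
    arma::mat dz = arma::join_cols(dzf, arma::join_cols(dzi, arma::join_cols(dzg, dzo)));
    dZ.cols(tt * B, tt * B + B - 1) = dz;
    g.R += dz * hprev.t();
    g.b += arma::sum(dz, 1);
    dh = P.R.t() * dz;
    dc = dc % f;
  }
  g.W = dZ * Xbig.t();

  if (add_l2 && l2 > 0) {
    g.W += l2 * P.W;
    g.R += l2 * P.R;
    g.Wy += l2 * P.Wy;
  }
  return loss;
}

// One parameter tensor and its optimizer state, viewed as flat arrays.
struct PSlot {
  double *w, *g, *m, *v;
  arma::uword n;
  bool weight;  // L2 applies to weights, not biases
};

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".lstmForwardCpp")]]
List lstm_forward_cpp(List params, arma::cube X, arma::uvec idx,
                      arma::vec center, arma::vec scale,
                      bool keep_states = false) {
  Params P = unpack(params);
  if (X.n_rows != P.D) stop("input dimension %d does not match model (%d)",
                            (int)X.n_rows, (int)P.D);
  const arma::uword T = X.n_cols;
  if (idx.n_elem == 0) idx = arma::regspace<arma::uvec>(0, X.n_slices - 1);
  else idx -= 1;  // 1-based from R
  const arma::uword N = idx.n_elem;
  arma::mat Xbig = gather(X, idx, center, scale);
  arma::mat hT, scores;
  Cache cache;
  forward_core(P, Xbig, T, N, hT, scores, keep_states ? &cache : nullptr);
  List out = List::create(_["h_last"] = hT, _["scores"] = scores);
  if (keep_states) out["states"] = cache.Hs;  // H x N x T
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".lstmLossGradCpp")]]
List lstm_loss_grad_cpp(List params, arma::cube X, arma::ivec y, double l2) {
  Params P = unpack(params);
  if (y.n_elem != X.n_slices) stop("labels do not match batch size");
  const arma::uword T = X.n_cols, B = X.n_slices;
  arma::uvec idx = arma::regspace<arma::uvec>(0, B - 1);
  arma::mat Xbig = gather(X, idx, arma::vec(), arma::vec());
  Grads g;
  double loss = backward_core(P, Xbig, T, B, y, l2, g);
  return List::create(_["loss"] = loss,
                      _["W"] = g.W, _["R"] = g.R, _["b"] = g.b,
                      _["Wy"] = g.Wy, _["by"] = g.by);
}

//' @noRd
// [[Rcpp::export(name = ".lstmTrainCpp")]]
List lstm_train_cpp(List params, arma::cube X, arma::uvec idx, arma::ivec y,
                    List cfg, arma::imat order, arma::vec center,
                    arma::vec scale) {
  Params P = unpack(params);
  const arma::uword T = X.n_cols;
  if (idx.n_elem == 0) idx = arma::regspace<arma::uvec>(0, X.n_slices - 1);
  else idx -= 1;  // 1-based from R
  const arma::uword N = idx.n_elem;
  if (y.n_elem != N) stop("labels do not match dataset size");
  const double lr = as<double>(cfg["learning_rate"]);
  const double l2 = as<double>(cfg["l2"]);
  const double clip = as<double>(cfg["grad_clip"]);  // <= 0 disables
  const double momentum = as<double>(cfg["momentum"]);
  const double beta1 = as<double>(cfg["beta1"]);
  const double beta2 = as<double>(cfg["beta2"]);
  const double eps = as<double>(cfg["epsilon"]);
  const int epochs = as<int>(cfg["epochs"]);
  const int Bsz = as<int>(cfg["mini_batch"]);
  const std::string opt = as<std::string>(cfg["optimizer"]);
  const bool adam = (opt == "adam");
  if ((int)order.n_rows != (int)N || (int)order.n_cols != epochs)
    stop("shuffle order must be n x epochs");

  Grads m, v;  // ADAM moments / momentum buffers
  m.W.zeros(arma::size(P.W));   v.W.zeros(arma::size(P.W));
  m.R.zeros(arma::size(P.R));   v.R.zeros(arma::size(P.R));
  m.b.zeros(arma::size(P.b));   v.b.zeros(arma::size(P.b));
  m.Wy.zeros(arma::size(P.Wy)); v.Wy.zeros(arma::size(P.Wy));
  m.by.zeros(arma::size(P.by)); v.by.zeros(arma::size(P.by));

  arma::vec trace(epochs);
  long step = 0;

  for (int e = 0; e < epochs; ++e) {
    double esum = 0.0;
    int nb = 0;
    for (arma::uword start = 0; start < N; start += Bsz) {
      const arma::uword stop_ = std::min<arma::uword>(start + Bsz, N) - 1;
      const arma::uword B = stop_ - start + 1;
      arma::uvec batch(B);
      arma::ivec yb(B);
      for (arma::uword k = 0; k < B; ++k) {
        arma::uword pos = (arma::uword)(order(start + k, e) - 1);  // 1-based
        batch[k] = idx[pos];
        yb[k] = y[pos];
      }
      arma::mat Xbig = gather(X, batch, center, scale);
      Grads g;
      double ce = backward_core(P, Xbig, T, B, yb, l2, g, false);
      ++nb;

      PSlot slots[5] = {
        {P.W.memptr(), g.W.memptr(), m.W.memptr(), v.W.memptr(),
         P.W.n_elem, true},
        {P.R.memptr(), g.R.memptr(), m.R.memptr(), v.R.memptr(),
         P.R.n_elem, true},
        {P.b.memptr(), g.b.memptr(), m.b.memptr(), v.b.memptr(),
         P.b.n_elem, false},
        {P.Wy.memptr(), g.Wy.memptr(), m.Wy.memptr(), v.Wy.memptr(),
         P.Wy.n_elem, true},
        {P.by.memptr(), g.by.memptr(), m.by.memptr(), v.by.memptr(),
         P.by.n_elem, false}};

      // pass 1: fold L2 into the gradient, accumulate the global gradient
      // norm and the weight sum of squares (for the reported loss)
      double nrm2 = 0.0, sumsq = 0.0;
      for (PSlot& s : slots) {
        if (s.weight && l2 > 0) {
          for (arma::uword i = 0; i < s.n; ++i) {
            double gi = s.g[i] + l2 * s.w[i];
            s.g[i] = gi;
            nrm2 += gi * gi;
            sumsq += s.w[i] * s.w[i];
          }
        } else {
          for (arma::uword i = 0; i < s.n; ++i) {
            nrm2 += s.g[i] * s.g[i];
            if (s.weight) sumsq += s.w[i] * s.w[i];
          }
        }
      }
      esum += ce + 0.5 * l2 * sumsq;
      double sc = 1.0;
      if (clip > 0) {
        double nrm = std::sqrt(nrm2);
        if (nrm > clip) sc = clip / nrm;
      }

      // pass 2: optimizer update
      ++step;
      if (adam) {
        const double bc1 = 1.0 - std::pow(beta1, (double)step);
        const double bc2 = 1.0 - std::pow(beta2, (double)step);
        for (PSlot& s : slots)
          for (arma::uword i = 0; i < s.n; ++i) {
            double gi = s.g[i] * sc;
            double mi = beta1 * s.m[i] + (1.0 - beta1) * gi;
            double vi = beta2 * s.v[i] + (1.0 - beta2) * gi * gi;
            s.m[i] = mi;
            s.v[i] = vi;
            s.w[i] -= lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
          }
      } else {  // SGD with classical momentum
        for (PSlot& s : slots)
          for (arma::uword i = 0; i < s.n; ++i) {
            double vi = momentum * s.v[i] - lr * s.g[i] * sc;
            s.v[i] = vi;
            s.w[i] += vi;
          }
      }
    }
    trace[e] = esum / nb;
    Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["W"] = P.W, _["R"] = P.R, _["b"] = P.b, _["Wy"] = P.Wy,
      _["by"] = P.by, _["trace"] = trace);
}
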