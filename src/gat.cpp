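// Two-layer graph attention classifier: forward pass, analytic backward
// pass and the Adam training loop. Additive attention with a LeakyReLU
// score and softmax normalisation over incoming neighbours; head outputs
// concatenated; global mean pooling; linear classification head.
//
// The code is templated on the element type: training runs in single
// precision, while prediction and the gradient-check entry point run in
// double precision.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Parameter layout (list order fixed between R and C++):
// 0 W1 (F x H1*D1), 1 a1_src (D1 x H1), 2 a1_dst (D1 x H1), 3 b1 (H1*D1 x 1)
// 4 W2 (..), 5 a2_src, 6 a2_dst, 7 b2
// 8 W_out (P2 x C), 9 b_out (C x 1)
static const int N_PARAMS = 10;

template <typename eT>
struct LayerCache {
  arma::Mat<eT> Z;      // N x H*D projected features
  arma::Mat<eT> alpha;  // E x H attention weights
  arma::Mat<eT> epre;   // E x H pre-LeakyReLU scores
};

template <typename eT>
static arma::Mat<eT> gatLayerForward(const arma::Mat<eT>& X,
                                     const arma::uvec& src,
                                     const arma::uvec& dst,
                                     const arma::Mat<eT>& W,
                                     const arma::Mat<eT>& As,
                                     const arma::Mat<eT>& Ad,
                                     const arma::Mat<eT>& b,
                                     int H, int D, eT slope,
                                     LayerCache<eT>& cache) {
  const arma::uword N = X.n_rows, E = src.n_elem;
  cache.Z = X * W;
  arma::Mat<eT> out(N, (arma::uword)(H * D), arma::fill::zeros);
  cache.alpha.set_size(E, H);
  cache.epre.set_size(E, H);
  for (int h = 0; h < H; ++h) {
    const arma::uword c0 = (arma::uword)h * D, c1 = c0 + D - 1;
    arma::Mat<eT> Zh = cache.Z.cols(c0, c1);
    arma::Col<eT> ss = Zh * As.col(h);
    arma::Col<eT> sd = Zh * Ad.col(h);
    arma::Col<eT> e(E);
    for (arma::uword k = 0; k < E; ++k) {
      eT v = ss(src(k)) + sd(dst(k));
      cache.epre(k, h) = v;
      e(k) = v > (eT)0 ? v : slope * v;
    }
    // per-destination softmax (max-shifted for stability)
    arma::Col<eT> mx(N);
    mx.fill(-std::numeric_limits<eT>::infinity());
    for (arma::uword k = 0; k < E; ++k)
      if (e(k) > mx(dst(k))) mx(dst(k)) = e(k);
    arma::Col<eT> denom(N, arma::fill::zeros);
    for (arma::uword k = 0; k < E; ++k) {
      eT ex = std::exp(e(k) - mx(dst(k)));
      cache.alpha(k, h) = ex;
      denom(dst(k)) += ex;
    }
    for (arma::uword k = 0; k < E; ++k) {
      cache.alpha(k, h) /= denom(dst(k));
      out(dst(k), arma::span(c0, c1)) += cache.alpha(k, h) * Zh.row(src(k));
    }
  }
  out.each_row() += b.col(0).t();
  return out;
}

template <typename eT>
static void gatLayerBackward(const arma::Mat<eT>& X,
                             const arma::uvec& src, const arma::uvec& dst,
                             const arma::Mat<eT>& W,
                             const arma::Mat<eT>& As, const arma::Mat<eT>& Ad,
                             int H, int D, eT slope,
                             const LayerCache<eT>& cache,
                             const arma::Mat<eT>& dOut,
                             arma::Mat<eT>& dW, arma::Mat<eT>& dAs,
                             arma::Mat<eT>& dAd, arma::Mat<eT>& db,
                             arma::Mat<eT>* dX) {
  const arma::uword N = X.n_rows, E = src.n_elem;
  db = arma::sum(dOut, 0).t();
  arma::Mat<eT> dZ(N, dOut.n_cols, arma::fill::zeros);
  dAs.set_size(D, H);
  dAd.set_size(D, H);
  for (int h = 0; h < H; ++h) {
    const arma::uword c0 = (arma::uword)h * D, c1 = c0 + D - 1;
    arma::Mat<eT> Zh = cache.Z.cols(c0, c1);
    arma::Mat<eT> Gh = dOut.cols(c0, c1);
    arma::Col<eT> galpha(E);
    arma::Col<eT> S(N, arma::fill::zeros);
    for (arma::uword k = 0; k < E; ++k) {
      galpha(k) = arma::dot(Gh.row(dst(k)), Zh.row(src(k)));
      S(dst(k)) += cache.alpha(k, h) * galpha(k);
    }
    arma::Col<eT> de(E), dss(N, arma::fill::zeros), dsd(N, arma::fill::zeros);
    arma::Mat<eT> dZh(N, (arma::uword)D, arma::fill::zeros);
    for (arma::uword k = 0; k < E; ++k) {
      eT dpre = cache.alpha(k, h) * (galpha(k) - S(dst(k)));
      de(k) = dpre * (cache.epre(k, h) > (eT)0 ? (eT)1 : slope);
      dss(src(k)) += de(k);
      dsd(dst(k)) += de(k);
      dZh.row(src(k)) += cache.alpha(k, h) * Gh.row(dst(k));
    }
    dAs.col(h) = Zh.t() * dss;
    dAd.col(h) = Zh.t() * dsd;
    dZh += dss * As.col(h).t();
    dZh += dsd * Ad.col(h).t();
    dZ.cols(c0, c1) = dZh;
  }
  dW = X.t() * dZ;
  if (dX) *dX = dZ * W.t();
}

// Append self-loop edges (i, i) for every node.
static void addSelfLoopEdges(arma::uvec& src, arma::uvec& dst,
                             arma::uword n) {
  arma::uvec loops = arma::regspace<arma::uvec>(0, n - 1);
  src = arma::join_cols(src, loops);
  dst = arma::join_cols(dst, loops);
}

template <typename eT>
struct ModelCache {
  LayerCache<eT> l1, l2;
  arma::Mat<eT> H1pre, H1, H2pre, H2, pooled, probs;
};

// Forward through both attention layers, pooling and the linear head.
// graphOf(i) gives the batch-graph index of node i; gsize the node counts.
template <typename eT>
static arma::Mat<eT> modelForward(const std::vector<arma::Mat<eT> >& P,
                                  const arma::Mat<eT>& X,
                                  const arma::uvec& src, const arma::uvec& dst,
                                  const arma::uvec& graphOf,
                                  const arma::uvec& gsize,
                                  int H1, int D1, int H2, int D2, eT slope,
                                  ModelCache<eT>& c) {
  c.H1pre = gatLayerForward<eT>(X, src, dst, P[0], P[1], P[2], P[3],
                                H1, D1, slope, c.l1);
  c.H1 = arma::clamp(c.H1pre, (eT)0, std::numeric_limits<eT>::max());
  c.H2pre = gatLayerForward<eT>(c.H1, src, dst, P[4], P[5], P[6], P[7],
                                H2, D2, slope, c.l2);
  c.H2 = arma::clamp(c.H2pre, (eT)0, std::numeric_limits<eT>::max());
  const arma::uword G = gsize.n_elem;
  c.pooled.zeros(G, c.H2.n_cols);
  for (arma::uword i = 0; i < c.H2.n_rows; ++i)
    c.pooled.row(graphOf(i)) += c.H2.row(i);
  for (arma::uword g = 0; g < G; ++g)
    c.pooled.row(g) /= (eT)gsize(g);
  arma::Mat<eT> logits = c.pooled * P[8];
  logits.each_row() += P[9].col(0).t();
  return logits;
}

// Cross-entropy loss (mean over graphs) and gradients for all parameters.
template <typename eT>
static eT modelLossGrad(const std::vector<arma::Mat<eT> >& P,
                        const arma::Mat<eT>& X,
                        const arma::uvec& src, const arma::uvec& dst,
                        const arma::uvec& graphOf, const arma::uvec& gsize,
                        const arma::ivec& y,
                        int H1, int D1, int H2, int D2, eT slope,
                        std::vector<arma::Mat<eT> >& grads) {
  ModelCache<eT> c;
  arma::Mat<eT> logits = modelForward<eT>(P, X, src, dst, graphOf, gsize,
                                          H1, D1, H2, D2, slope, c);
  const arma::uword G = logits.n_rows;
  arma::Mat<eT> probs = logits;
  eT loss = 0;
  for (arma::uword g = 0; g < G; ++g) {
    eT m = probs.row(g).max();
    arma::Row<eT> e = arma::exp(probs.row(g) - m);
    eT s = arma::accu(e);
    probs.row(g) = e / s;
    loss -= std::log(std::max(probs(g, (arma::uword)y(g)), (eT)1e-12));
  }
  loss /= (eT)G;

  arma::Mat<eT> dlogits = probs;
  for (arma::uword g = 0; g < G; ++g)
    dlogits(g, (arma::uword)y(g)) -= (eT)1;
  dlogits /= (eT)G;

  grads.assign(N_PARAMS, arma::Mat<eT>());
  grads[8] = c.pooled.t() * dlogits;
  grads[9] = arma::sum(dlogits, 0).t();
  arma::Mat<eT> dpooled = dlogits * P[8].t();
  arma::Mat<eT> dH2(c.H2.n_rows, c.H2.n_cols);
  for (arma::uword i = 0; i < dH2.n_rows; ++i)
    dH2.row(i) = dpooled.row(graphOf(i)) / (eT)gsize(graphOf(i));
  dH2 %= arma::conv_to<arma::Mat<eT> >::from(c.H2pre > (eT)0);

  arma::Mat<eT> dH1;
  gatLayerBackward<eT>(c.H1, src, dst, P[4], P[5], P[6],
                       H2, D2, slope, c.l2, dH2,
                       grads[4], grads[5], grads[6], grads[7], &dH1);
  dH1 %= arma::conv_to<arma::Mat<eT> >::from(c.H1pre > (eT)0);
  gatLayerBackward<eT>(X, src, dst, P[0], P[1], P[2],
                       H1, D1, slope, c.l1, dH1,
                       grads[0], grads[1], grads[2], grads[3], nullptr);
  return loss;
}

// ---------------------------------------------------------------------------
// R-facing helpers
// ---------------------------------------------------------------------------

template <typename eT>
static std::vector<arma::Mat<eT> > paramsFromList(const List& params) {
  std::vector<arma::Mat<eT> > P(N_PARAMS);
  for (int i = 0; i < N_PARAMS; ++i) {
    NumericMatrix m = params[i];
    arma::mat md(m.begin(), m.nrow(), m.ncol(), false);
    P[i] = arma::conv_to<arma::Mat<eT> >::from(md);
  }
  return P;
}

template <typename eT>
static List paramsToList(const std::vector<arma::Mat<eT> >& P,
                         const List& proto) {
  List out(N_PARAMS);
  for (int i = 0; i < N_PARAMS; ++i)
    out[i] = wrap(arma::conv_to<arma::mat>::from(P[i]));
  out.names() = proto.names();
  return out;
}

// Build batch structures (gathered X, offset edges with optional self-loops,
// node->graph map) for the graphs listed in `ids` (0-based into node_ptr).
template <typename eT>
static void assembleBatch(const arma::Mat<eT>& Xall,
                          const arma::ivec& nodePtr,
                          const arma::imat& edges, const arma::ivec& edgePtr,
                          const std::vector<int>& ids, bool selfLoops,
                          arma::Mat<eT>& Xb, arma::uvec& src, arma::uvec& dst,
                          arma::uvec& graphOf, arma::uvec& gsize) {
  arma::uword nb = 0, eb = 0;
  for (int id : ids) {
    nb += nodePtr(id + 1) - nodePtr(id);
    eb += edgePtr(id + 1) - edgePtr(id);
  }
  Xb.set_size(nb, Xall.n_cols);
  src.set_size(eb);
  dst.set_size(eb);
  graphOf.set_size(nb);
  gsize.set_size(ids.size());
  arma::uword noff = 0, eoff = 0;
  for (size_t g = 0; g < ids.size(); ++g) {
    int id = ids[g];
    arma::uword n0 = nodePtr(id), n1 = nodePtr(id + 1);
    arma::uword n = n1 - n0;
    Xb.rows(noff, noff + n - 1) = Xall.rows(n0, n1 - 1);
    for (arma::uword i = 0; i < n; ++i) graphOf(noff + i) = g;
    gsize(g) = n;
    for (arma::sword k = edgePtr(id); k < edgePtr(id + 1); ++k) {
      src(eoff) = (arma::uword)edges(k, 0) + noff;
      dst(eoff) = (arma::uword)edges(k, 1) + noff;
      ++eoff;
    }
    noff += n;
  }
  if (selfLoops) addSelfLoopEdges(src, dst, nb);
}

static arma::imat edgesFromR(const IntegerMatrix& e) {
  arma::imat out(e.nrow(), 2);
  for (int i = 0; i < e.nrow(); ++i) {
    out(i, 0) = e(i, 0);
    out(i, 1) = e(i, 1);
  }
  return out;
}

// Forward pass over a set of graphs (double precision; prediction path).
// [[Rcpp::export]]
List gat_forward_cpp(List params, NumericMatrix Xall, IntegerVector nodePtr,
                     IntegerMatrix edges, IntegerVector edgePtr,
                     int H1, int D1, int H2, int D2, double slope,
                     bool selfLoops, bool returnIntermediates) {
  std::vector<arma::mat> P = paramsFromList<double>(params);
  arma::mat X(Xall.begin(), Xall.nrow(), Xall.ncol(), false);
  arma::ivec np = as<arma::ivec>(nodePtr);
  arma::ivec ep = as<arma::ivec>(edgePtr);
  arma::imat E = edgesFromR(edges);
  int G = np.n_elem - 1;
  std::vector<int> ids(G);
  for (int i = 0; i < G; ++i) ids[i] = i;
  arma::mat Xb;
  arma::uvec src, dst, graphOf, gsize;
  assembleBatch<double>(X, np, E, ep, ids, selfLoops, Xb, src, dst,
                        graphOf, gsize);
  ModelCache<double> c;
  arma::mat logits = modelForward<double>(P, Xb, src, dst, graphOf, gsize,
                                          H1, D1, H2, D2, slope, c);
  if (!returnIntermediates) return List::create(Named("logits") = logits);
  return List::create(Named("logits") = logits,
                      Named("h1") = c.H1, Named("h2") = c.H2,
                      Named("pooled") = c.pooled);
}

// Loss and analytic gradients for one batch (double precision; used by the
// numerical gradient check).
// [[Rcpp::export]]
List gat_loss_grad_cpp(List params, NumericMatrix Xall, IntegerVector nodePtr,
                       IntegerMatrix edges, IntegerVector edgePtr,
                       IntegerVector y, int H1, int D1, int H2, int D2,
                       double slope, bool selfLoops) {
  std::vector<arma::mat> P = paramsFromList<double>(params);
  arma::mat X(Xall.begin(), Xall.nrow(), Xall.ncol(), false);
  arma::ivec np = as<arma::ivec>(nodePtr);
  arma::ivec ep = as<arma::ivec>(edgePtr);
  arma::imat E = edgesFromR(edges);
  int G = np.n_elem - 1;
  std::vector<int> ids(G);
  for (int i = 0; i < G; ++i) ids[i] = i;
  arma::mat Xb;
  arma::uvec src, dst, graphOf, gsize;
  assembleBatch<double>(X, np, E, ep, ids, selfLoops, Xb, src, dst,
                        graphOf, gsize);
  arma::ivec yy = as<arma::ivec>(y);
  std::vector<arma::mat> grads;
  double loss = modelLossGrad<double>(P, Xb, src, dst, graphOf, gsize, yy,
                                      H1, D1, H2, D2, slope, grads);
  return List::create(Named("loss") = loss,
                      Named("grads") = paramsToList<double>(grads, params));
}

// Mini-batch Adam training loop (single precision). Shuffling uses a
// fully specified Fisher-Yates + mt19937 scheme so runs are reproducible
// bit for bit under a given seed.
// [[Rcpp::export]]
List gat_train_cpp(List params, NumericMatrix Xall, IntegerVector nodePtr,
                   IntegerMatrix edges, IntegerVector edgePtr,
                   IntegerVector y, int H1, int D1, int H2, int D2,
                   double slope, bool selfLoops, double lr, int epochs,
                   int batchSize, int seed) {
  typedef float eT;
  std::vector<arma::Mat<eT> > P = paramsFromList<eT>(params);
  arma::mat Xd(Xall.begin(), Xall.nrow(), Xall.ncol(), false);
  arma::Mat<eT> X = arma::conv_to<arma::Mat<eT> >::from(Xd);
  arma::ivec np = as<arma::ivec>(nodePtr);
  arma::ivec ep = as<arma::ivec>(edgePtr);
  arma::imat E = edgesFromR(edges);
  arma::ivec yy = as<arma::ivec>(y);
  const int G = np.n_elem - 1;

  std::vector<arma::Mat<eT> > m(N_PARAMS), v(N_PARAMS);
  for (int i = 0; i < N_PARAMS; ++i) {
    m[i].zeros(P[i].n_rows, P[i].n_cols);
    v[i].zeros(P[i].n_rows, P[i].n_cols);
  }
  const eT beta1 = (eT)0.9, beta2 = (eT)0.999, eps = (eT)1e-8;
  long step = 0;

  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(G);
  for (int i = 0; i < G; ++i) order[i] = i;

  NumericVector lossHistory(epochs);
  std::vector<arma::Mat<eT> > grads;
  for (int epoch = 0; epoch < epochs; ++epoch) {
    for (int i = G - 1; i > 0; --i) {       // Fisher-Yates
      int j = (int)(rng() % (unsigned)(i + 1));
      std::swap(order[i], order[j]);
    }
    double epLoss = 0;
    for (int s = 0; s < G; s += batchSize) {
      int e = std::min(s + batchSize, G);
      std::vector<int> ids(order.begin() + s, order.begin() + e);
      arma::Mat<eT> Xb;
      arma::uvec src, dst, graphOf, gsize;
      assembleBatch<eT>(X, np, E, ep, ids, selfLoops, Xb, src, dst,
                        graphOf, gsize);
      arma::ivec yb((arma::uword)ids.size());
      for (size_t k = 0; k < ids.size(); ++k) yb(k) = yy(ids[k]);
      eT loss = modelLossGrad<eT>(P, Xb, src, dst, graphOf, gsize, yb,
                                  H1, D1, H2, D2, (eT)slope, grads);
      epLoss += (double)loss * ids.size();
      ++step;
      eT c1 = (eT)1 - std::pow(beta1, (eT)step);
      eT c2 = (eT)1 - std::pow(beta2, (eT)step);
      for (int i = 0; i < N_PARAMS; ++i) {
        m[i] = beta1 * m[i] + ((eT)1 - beta1) * grads[i];
        v[i] = beta2 * v[i] + ((eT)1 - beta2) * (grads[i] % grads[i]);
        P[i] -= (eT)lr * (m[i] / c1) / (arma::sqrt(v[i] / c2) + eps);
      }
    }
    lossHistory[epoch] = epLoss / G;
  }
  return List::create(Named("params") = paramsToList<eT>(P, params),
                      Named("lossHistory") = lossHistory);
}
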