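// Minimal CNN graph engine: forward and backward passes for the layer types
// needed by the modified ResNet-50 / DenseNet-201 feature extractors and the
// shallow concatenation head. Single precision; convolutions are lowered to
// BLAS GEMM via an im2col transform. Graphs arrive from R as an ordered list
// of layer descriptors (topological order is the builder's responsibility).
//
// Tensor layout: one image = arma::fcube (H rows, W cols, C slices).
// A cube's memory is (h fastest, then w, then c); flattening follows that
// order. Conv weights are (cout x k*k*cin) with column index
// c*k*k + ki*k + kj (ki = row offset, kj = col offset).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;
using arma::fcube;
using arma::fmat;
using arma::fvec;

struct LayerDesc {
  std::string type;
  std::vector<int> in;   // 0-based input node ids
  int k = 0, s = 1, p = 0;
  std::string prefix;    // parameter name prefix
};

typedef std::map<std::string, fmat> ParamMap;

static std::vector<LayerDesc> parseLayers(const List& layers) {
  std::vector<LayerDesc> out(layers.size());
  for (int i = 0; i < layers.size(); ++i) {
    List L = layers[i];
    LayerDesc d;
    d.type = as<std::string>(L["type"]);
    if (L.containsElementNamed("in")) {
      IntegerVector iv = L["in"];
      for (int j = 0; j < iv.size(); ++j) d.in.push_back(iv[j] - 1);
    }
    if (L.containsElementNamed("k") && !Rf_isNull(L["k"])) d.k = as<int>(L["k"]);
    if (L.containsElementNamed("s") && !Rf_isNull(L["s"])) d.s = as<int>(L["s"]);
    if (L.containsElementNamed("p") && !Rf_isNull(L["p"])) d.p = as<int>(L["p"]);
    if (L.containsElementNamed("prefix") && !Rf_isNull(L["prefix"]))
      d.prefix = as<std::string>(L["prefix"]);
    out[i] = d;
  }
  return out;
}

static ParamMap parseParams(const List& params) {
  ParamMap pm;
  CharacterVector nm = params.names();
  for (int i = 0; i < params.size(); ++i) {
    RObject o = params[i];
    std::string key = as<std::string>(nm[i]);
    if (Rf_isMatrix(o)) {
      NumericMatrix m(o);
      fmat f(m.nrow(), m.ncol());
      for (int c = 0; c < m.ncol(); ++c)
        for (int r = 0; r < m.nrow(); ++r) f(r, c) = (float)m(r, c);
      pm[key] = f;
    } else {
      NumericVector v(o);
      fmat f(v.size(), 1);
      for (int r = 0; r < v.size(); ++r) f(r, 0) = (float)v[r];
      pm[key] = f;
    }
  }
  return pm;
}

static int outDim(int n, int k, int s, int p) { return (n + 2 * p - k) / s + 1; }

// colT: (Hout*Wout) x (k*k*cin), column index r = c*k*k + ki*k + kj
static void im2colT(const fcube& x, int k, int s, int p, fmat& colT) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = outDim(H, k, s, p), Wo = outDim(W, k, s, p);
  colT.set_size(Ho * Wo, C * k * k);
  for (int c = 0; c < C; ++c) {
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int r = c * k * k + ki * k + kj;
        float* dst = colT.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * s - p + kj;
          const bool wok = (w >= 0 && w < W);
          const float* src = wok ? x.slice_colptr(c, w) : nullptr;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * s - p + ki;
            dst[wo * Ho + ho] =
                (wok && h >= 0 && h < H) ? src[h] : 0.0f;
          }
        }
      }
    }
  }
}

static void col2imT(const fmat& dcolT, int H, int W, int C, int k, int s,
                    int p, fcube& dx) {
  const int Ho = outDim(H, k, s, p), Wo = outDim(W, k, s, p);
  dx.zeros(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int r = c * k * k + ki * k + kj;
        const float* src = dcolT.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * s - p + kj;
          if (w < 0 || w >= W) continue;
          float* dst = dx.slice_colptr(c, w);
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * s - p + ki;
            if (h >= 0 && h < H) dst[h] += src[wo * Ho + ho];
          }
        }
      }
    }
  }
}

struct NodeState {
  fcube out;
  arma::ucube argmax;  // maxpool only: linear index into input cube
  fmat colT;           // conv only (training): cached im2col
};

static const fmat& getParam(const ParamMap& pm, const std::string& key) {
  ParamMap::const_iterator it = pm.find(key);
  if (it == pm.end()) stop("missing parameter '" + key + "'");
  return it->second;
}

// Forward one image through the graph. If `train` is true, conv im2col
// buffers and maxpool argmax are cached for the backward pass.
static void forwardImage(const std::vector<LayerDesc>& L, const ParamMap& pm,
                         const fcube& img, std::vector<NodeState>& st,
                         bool train) {
  const int n = (int)L.size();
  st.assign(n, NodeState());
  for (int i = 0; i < n; ++i) {
    const LayerDesc& d = L[i];
    if (d.type == "input") {
      st[i].out = img;
    } else if (d.type == "conv") {
      const fcube& x = st[d.in[0]].out;
      const fmat& W = getParam(pm, d.prefix + ".W");
      const int Ho = outDim(x.n_rows, d.k, d.s, d.p);
      const int Wo = outDim(x.n_cols, d.k, d.s, d.p);
      const int cout = W.n_rows;
      fmat Yt;  // (Ho*Wo) x cout == output cube memory layout
      if (d.k == 1 && d.s == 1 && d.p == 0) {
        const fmat Xm((float*)x.memptr(), x.n_rows * x.n_cols, x.n_slices,
                      false, true);
        Yt = Xm * W.t();
        if (train) st[i].colT = Xm;  // copy
      } else {
        fmat colT;
        im2colT(x, d.k, d.s, d.p, colT);
        Yt = colT * W.t();
        if (train) st[i].colT = std::move(colT);
      }
      st[i].out = fcube(Yt.memptr(), Ho, Wo, cout);
    } else if (d.type == "bn") {
      const fcube& x = st[d.in[0]].out;
      const fmat& g = getParam(pm, d.prefix + ".gamma");
      const fmat& b = getParam(pm, d.prefix + ".beta");
      fcube y = x;
      for (arma::uword c = 0; c < y.n_slices; ++c)
        y.slice(c) = y.slice(c) * g(c, 0) + b(c, 0);
      st[i].out = std::move(y);
    } else if (d.type == "relu") {
      st[i].out = arma::clamp(st[d.in[0]].out, 0.0f,
                              std::numeric_limits<float>::max());
    } else if (d.type == "maxpool") {
      const fcube& x = st[d.in[0]].out;
      const int Ho = outDim(x.n_rows, d.k, d.s, d.p);
      const int Wo = outDim(x.n_cols, d.k, d.s, d.p);
      fcube y(Ho, Wo, x.n_slices);
      arma::ucube am(Ho, Wo, x.n_slices);
      for (arma::uword c = 0; c < x.n_slices; ++c) {
        for (int wo = 0; wo < Wo; ++wo) {
          for (int ho = 0; ho < Ho; ++ho) {
            float best = -std::numeric_limits<float>::max();
            arma::uword bidx = 0;
            for (int kj = 0; kj < d.k; ++kj) {
              const int w = wo * d.s - d.p + kj;
              if (w < 0 || w >= (int)x.n_cols) continue;
              for (int ki = 0; ki < d.k; ++ki) {
                const int h = ho * d.s - d.p + ki;
                if (h < 0 || h >= (int)x.n_rows) continue;
                const float v = x(h, w, c);
                if (v > best) {
                  best = v;
                  bidx = h + w * x.n_rows + c * x.n_rows * x.n_cols;
                }
              }
            }
            y(ho, wo, c) = best;
            am(ho, wo, c) = bidx;
          }
        }
      }
      st[i].out = std::move(y);
      if (train) st[i].argmax = std::move(am);
    } else if (d.type == "avgpool") {
      const fcube& x = st[d.in[0]].out;
      const int Ho = outDim(x.n_rows, d.k, d.s, d.p);
      const int Wo = outDim(x.n_cols, d.k, d.s, d.p);
      fcube y(Ho, Wo, x.n_slices, arma::fill::zeros);
      const float inv = 1.0f / (d.k * d.k);
      for (arma::uword c = 0; c < x.n_slices; ++c)
        for (int wo = 0; wo < Wo; ++wo)
          for (int ho = 0; ho < Ho; ++ho) {
            float acc = 0.0f;
            for (int kj = 0; kj < d.k; ++kj)
              for (int ki = 0; ki < d.k; ++ki) {
                const int h = ho * d.s + ki, w = wo * d.s + kj;
                if (h < (int)x.n_rows && w < (int)x.n_cols) acc += x(h, w, c);
              }
            y(ho, wo, c) = acc * inv;
          }
      st[i].out = std::move(y);
    } else if (d.type == "add") {
      st[i].out = st[d.in[0]].out + st[d.in[1]].out;
    } else if (d.type == "concat") {
      const fcube& a = st[d.in[0]].out;
      const fcube& b = st[d.in[1]].out;
      fcube y(a.n_rows, a.n_cols, a.n_slices + b.n_slices);
      y.slices(0, a.n_slices - 1) = a;
      y.slices(a.n_slices, y.n_slices - 1) = b;
      st[i].out = std::move(y);
    } else if (d.type == "dense") {
      const fcube& x = st[d.in[0]].out;
      const fmat& W = getParam(pm, d.prefix + ".W");
      const fmat& b = getParam(pm, d.prefix + ".b");
      const fvec a((float*)x.memptr(), x.n_elem);
      fvec z = W * a + b.col(0);
      st[i].out = fcube(z.memptr(), 1, 1, z.n_elem);
    } else {
      stop("unknown layer type '" + d.type + "'");
    }
  }
}

// Backward from a gradient seeded at the final node; accumulates parameter
// gradients into `grads` (same keys/shapes as params).
static void backwardImage(const std::vector<LayerDesc>& L, const ParamMap& pm,
                          std::vector<NodeState>& st, const fvec& dfinal,
                          ParamMap& grads) {
  const int n = (int)L.size();
  std::vector<fcube> dout(n);
  std::vector<bool> seeded(n, false);
  const fcube& fin = st[n - 1].out;
  dout[n - 1] = fcube((float*)dfinal.memptr(), fin.n_rows, fin.n_cols,
                      fin.n_slices);
  seeded[n - 1] = true;
  for (int i = n - 1; i >= 0; --i) {
    const LayerDesc& d = L[i];
    if (!seeded[i] || d.type == "input") continue;
    fcube dy = std::move(dout[i]);
    for (size_t j = 0; j < d.in.size(); ++j) {
      const int src = d.in[j];
      if (!seeded[src]) {
        const fcube& xo = st[src].out;
        dout[src].zeros(xo.n_rows, xo.n_cols, xo.n_slices);
        seeded[src] = true;
      }
    }
    if (d.type == "conv") {
      const fmat& W = getParam(pm, d.prefix + ".W");
      const fcube& x = st[d.in[0]].out;
      const fmat dYt((float*)dy.memptr(), dy.n_rows * dy.n_cols, dy.n_slices,
                     false, true);
      grads[d.prefix + ".W"] += dYt.t() * st[i].colT;
      fmat dcolT = dYt * W;
      if (d.k == 1 && d.s == 1 && d.p == 0) {
        dout[d.in[0]] += fcube(dcolT.memptr(), x.n_rows, x.n_cols, x.n_slices);
      } else {
        fcube dx;
        col2imT(dcolT, x.n_rows, x.n_cols, x.n_slices, d.k, d.s, d.p, dx);
        dout[d.in[0]] += dx;
      }
    } else if (d.type == "bn") {
      const fmat& g = getParam(pm, d.prefix + ".gamma");
      const fcube& x = st[d.in[0]].out;
      fmat& dg = grads[d.prefix + ".gamma"];
      fmat& db = grads[d.prefix + ".beta"];
      for (arma::uword c = 0; c < dy.n_slices; ++c) {
        dg(c, 0) += arma::accu(dy.slice(c) % x.slice(c));
        db(c, 0) += arma::accu(dy.slice(c));
        dout[d.in[0]].slice(c) += dy.slice(c) * g(c, 0);
      }
    } else if (d.type == "relu") {
      dout[d.in[0]] += dy % arma::conv_to<fcube>::from(st[i].out > 0.0f);
    } else if (d.type == "maxpool") {
      fcube& dx = dout[d.in[0]];
      const arma::ucube& am = st[i].argmax;
      for (arma::uword e = 0; e < dy.n_elem; ++e) dx(am(e)) += dy(e);
    } else if (d.type == "avgpool") {
      const fcube& x = st[d.in[0]].out;
      fcube& dx = dout[d.in[0]];
      const float inv = 1.0f / (d.k * d.k);
      for (arma::uword c = 0; c < dy.n_slices; ++c)
        for (arma::uword wo = 0; wo < dy.n_cols; ++wo)
          for (arma::uword ho = 0; ho < dy.n_rows; ++ho) {
            const float v = dy(ho, wo, c) * inv;
            for (int kj = 0; kj < d.k; ++kj)
              for (int ki = 0; ki < d.k; ++ki) {
                const arma::uword h = ho * d.s + ki, w = wo * d.s + kj;
                if (h < x.n_rows && w < x.n_cols) dx(h, w, c) += v;
              }
          }
    } else if (d.type == "add") {
      dout[d.in[0]] += dy;
      dout[d.in[1]] += dy;
    } else if (d.type == "concat") {
      const fcube& a = st[d.in[0]].out;
      dout[d.in[0]] += dy.slices(0, a.n_slices - 1);
      dout[d.in[1]] += dy.slices(a.n_slices, dy.n_slices - 1);
    } else if (d.type == "dense") {
      const fmat& W = getParam(pm, d.prefix + ".W");
      const fcube& x = st[d.in[0]].out;
      const fvec a((float*)x.memptr(), x.n_elem);
      const fvec dz((float*)dy.memptr(), dy.n_elem);
      grads[d.prefix + ".W"] += dz * a.t();
      grads[d.prefix + ".b"] += dz;
      fvec da = W.t() * dz;
      dout[d.in[0]] += fcube(da.memptr(), x.n_rows, x.n_cols, x.n_slices);
    }
    dy.reset();
  }
}

static fcube imageToCube(const NumericVector& a) {
  IntegerVector dim = a.attr("dim");
  if (dim.size() != 3) stop("image must be an H x W x C array");
  fcube x(dim[0], dim[1], dim[2]);
  for (int e = 0; e < a.size(); ++e) x(e) = (float)a[e];
  return x;
}

// Forward a batch of images; returns an N x D matrix of flattened final-node
// outputs. Intermediate buffers are dropped eagerly (inference mode).
// [[Rcpp::export(name = ".nn_forward")]]
NumericMatrix nn_forward(List layers, List params, List images) {
  std::vector<LayerDesc> L = parseLayers(layers);
  ParamMap pm = parseParams(params);
  const int N = images.size();
  NumericMatrix out;
  std::vector<NodeState> st;
  for (int im = 0; im < N; ++im) {
    fcube x = imageToCube(images[im]);
    forwardImage(L, pm, x, st, false);
    const fcube& fin = st[L.size() - 1].out;
    if (im == 0) out = NumericMatrix(N, fin.n_elem);
    for (arma::uword e = 0; e < fin.n_elem; ++e) out(im, e) = fin(e);
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Forward one image, returning the outputs of the requested nodes (1-based).
// [[Rcpp::export(name = ".nn_forward_capture")]]
List nn_forward_capture(List layers, List params, NumericVector image,
                        IntegerVector nodes) {
  std::vector<LayerDesc> L = parseLayers(layers);
  ParamMap pm = parseParams(params);
  fcube x = imageToCube(image);
  std::vector<NodeState> st;
  forwardImage(L, pm, x, st, false);
  List out(nodes.size());
  for (int i = 0; i < nodes.size(); ++i) {
    const fcube& y = st[nodes[i] - 1].out;
    NumericVector a(y.n_elem);
    for (arma::uword e = 0; e < y.n_elem; ++e) a[e] = y(e);
    a.attr("dim") = IntegerVector::create(y.n_rows, y.n_cols, y.n_slices);
    out[i] = a;
  }
  return out;
}

// One training pass over a mini-batch: softmax cross-entropy on the final
// dense node. Returns mean loss, mean parameter gradients, and predictions.
// `labels` are 0-based class indices.
// [[Rcpp::export(name = ".nn_grad_batch")]]
List nn_grad_batch(List layers, List params, List images,
                   IntegerVector labels) {
  std::vector<LayerDesc> L = parseLayers(layers);
  ParamMap pm = parseParams(params);
  const int N = images.size();
  ParamMap grads;
  for (ParamMap::const_iterator it = pm.begin(); it != pm.end(); ++it)
    grads[it->first] = fmat(it->second.n_rows, it->second.n_cols,
                            arma::fill::zeros);
  double lossSum = 0.0;
  IntegerVector pred(N);
  std::vector<NodeState> st;
  for (int im = 0; im < N; ++im) {
    fcube x = imageToCube(images[im]);
    forwardImage(L, pm, x, st, true);
    const fcube& fin = st[L.size() - 1].out;
    fvec z((float*)fin.memptr(), fin.n_elem);
    const float m = z.max();
    fvec e = arma::exp(z - m);
    fvec prob = e / arma::accu(e);
    const int t = labels[im];
    lossSum += -std::log(std::max(prob(t), 1e-30f));
    pred[im] = (int)prob.index_max();
    fvec dz = prob;
    dz(t) -= 1.0f;
    backwardImage(L, pm, st, dz, grads);
    Rcpp::checkUserInterrupt();
  }
  List g(grads.size());
  CharacterVector gn(grads.size());
  int i = 0;
  const double inv = 1.0 / N;
  for (ParamMap::iterator it = grads.begin(); it != grads.end(); ++it, ++i) {
    gn[i] = it->first;
    const fmat& f = it->second;
    if (f.n_cols == 1) {
      NumericVector v(f.n_rows);
      for (arma::uword r = 0; r < f.n_rows; ++r) v[r] = f(r, 0) * inv;
      g[i] = v;
    } else {
      NumericMatrix m(f.n_rows, f.n_cols);
      for (arma::uword c = 0; c < f.n_cols; ++c)
        for (arma::uword r = 0; r < f.n_rows; ++r) m(r, c) = f(r, c) * inv;
      g[i] = m;
    }
  }
  g.names() = gn;
  return List::create(_["loss"] = lossSum * inv, _["grads"] = g,
                      _["pred"] = pred);
}
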