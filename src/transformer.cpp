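// Tiny decoder-only transformer: forward, analytic backward, greedy decoding.
// Sizes are small (word vocab, embedding 64, two layers) so everything is
// recomputed per call; parameters are passed as a named R list of matrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static const double LN_EPS = 1e-5;

struct Layer {
  vec ln1g, ln1b, bq, bk, bv, bo, ln2g, ln2b, b1, b2;
  mat Wq, Wk, Wv, Wo, W1, W2;
};

struct Model {
  mat E, P;
  std::vector<Layer> layers;
  vec lnfg, lnfb, bout;
  mat Wout;
  int H;
};

static Model model_from_list(const List& params, int n_heads) {
  Model m;
  m.E = as<mat>(params["E"]);
  m.P = as<mat>(params["P"]);
  List layers = params["layers"];
  for (int l = 0; l < layers.size(); ++l) {
    List li = layers[l];
    Layer L;
    L.ln1g = as<vec>(li["ln1g"]); L.ln1b = as<vec>(li["ln1b"]);
    L.Wq = as<mat>(li["Wq"]); L.bq = as<vec>(li["bq"]);
    L.Wk = as<mat>(li["Wk"]); L.bk = as<vec>(li["bk"]);
    L.Wv = as<mat>(li["Wv"]); L.bv = as<vec>(li["bv"]);
    L.Wo = as<mat>(li["Wo"]); L.bo = as<vec>(li["bo"]);
    L.ln2g = as<vec>(li["ln2g"]); L.ln2b = as<vec>(li["ln2b"]);
    L.W1 = as<mat>(li["W1"]); L.b1 = as<vec>(li["b1"]);
    L.W2 = as<mat>(li["W2"]); L.b2 = as<vec>(li["b2"]);
    m.layers.push_back(L);
  }
  m.lnfg = as<vec>(params["lnf_g"]); m.lnfb = as<vec>(params["lnf_b"]);
  m.Wout = as<mat>(params["Wout"]); m.bout = as<vec>(params["bout"]);
  m.H = n_heads;
  return m;
}

struct LayerCache {
  mat xin, a_in, xhat1, Q, K, V, O, xmid, m_in, xhat2, H1pre, H1;
  vec inv1, inv2;
  std::vector<mat> Ph;
};

struct Cache {
  mat Emb, X0, xf_in, xhatf, XF, logits;
  vec invf;
  std::vector<LayerCache> lc;
};

struct Grads {
  mat E, P;
  std::vector<Layer> layers;  // reuse Layer as gradient container
  vec lnfg, lnfb, bout;
  mat Wout;
  bool emb;  // whether to accumulate E/P gradients
};

static Grads grads_like(const Model& m, bool emb) {
  Grads g;
  g.emb = emb;
  if (emb) {
    g.E = arma::zeros<mat>(m.E.n_rows, m.E.n_cols);
    g.P = arma::zeros<mat>(m.P.n_rows, m.P.n_cols);
  }
  for (size_t l = 0; l < m.layers.size(); ++l) {
    const Layer& L = m.layers[l];
    Layer z;
    z.ln1g = arma::zeros<vec>(L.ln1g.n_elem); z.ln1b = arma::zeros<vec>(L.ln1b.n_elem);
    z.Wq = arma::zeros<mat>(L.Wq.n_rows, L.Wq.n_cols); z.bq = arma::zeros<vec>(L.bq.n_elem);
    z.Wk = arma::zeros<mat>(L.Wk.n_rows, L.Wk.n_cols); z.bk = arma::zeros<vec>(L.bk.n_elem);
    z.Wv = arma::zeros<mat>(L.Wv.n_rows, L.Wv.n_cols); z.bv = arma::zeros<vec>(L.bv.n_elem);
    z.Wo = arma::zeros<mat>(L.Wo.n_rows, L.Wo.n_cols); z.bo = arma::zeros<vec>(L.bo.n_elem);
    z.ln2g = arma::zeros<vec>(L.ln2g.n_elem); z.ln2b = arma::zeros<vec>(L.ln2b.n_elem);
    z.W1 = arma::zeros<mat>(L.W1.n_rows, L.W1.n_cols); z.b1 = arma::zeros<vec>(L.b1.n_elem);
    z.W2 = arma::zeros<mat>(L.W2.n_rows, L.W2.n_cols); z.b2 = arma::zeros<vec>(L.b2.n_elem);
    g.layers.push_back(z);
  }
  g.lnfg = arma::zeros<vec>(m.lnfg.n_elem);
  g.lnfb = arma::zeros<vec>(m.lnfb.n_elem);
  g.Wout = arma::zeros<mat>(m.Wout.n_rows, m.Wout.n_cols);
  g.bout = arma::zeros<vec>(m.bout.n_elem);
  return g;
}

static List grads_to_list(const Grads& g) {
  List layers(g.layers.size());
  for (size_t l = 0; l < g.layers.size(); ++l) {
    const Layer& z = g.layers[l];
    layers[l] = List::create(
      _["ln1g"] = z.ln1g, _["ln1b"] = z.ln1b,
      _["Wq"] = z.Wq, _["bq"] = z.bq, _["Wk"] = z.Wk, _["bk"] = z.bk,
      _["Wv"] = z.Wv, _["bv"] = z.bv, _["Wo"] = z.Wo, _["bo"] = z.bo,
      _["ln2g"] = z.ln2g, _["ln2b"] = z.ln2b,
      _["W1"] = z.W1, _["b1"] = z.b1, _["W2"] = z.W2, _["b2"] = z.b2);
  }
  List out = List::create(
    _["E"] = g.E, _["P"] = g.P, _["layers"] = layers,
    _["lnf_g"] = g.lnfg, _["lnf_b"] = g.lnfb,
    _["Wout"] = g.Wout, _["bout"] = g.bout);
  return out;
}

static mat ln_fwd(const mat& X, const vec& g, const vec& b, mat& xhat, vec& inv_std) {
  int T = X.n_rows, d = X.n_cols;
  xhat.set_size(T, d);
  inv_std.set_size(T);
  mat Y(T, d);
  for (int t = 0; t < T; ++t) {
    rowvec x = X.row(t);
    double mu = arma::mean(x);
    double var = arma::mean(arma::square(x - mu));
    double is = 1.0 / std::sqrt(var + LN_EPS);
    inv_std(t) = is;
    xhat.row(t) = (x - mu) * is;
    Y.row(t) = xhat.row(t) % g.t() + b.t();
  }
  return Y;
}

// accumulates dg/db, returns dX
static mat ln_bwd(const mat& dY, const mat& xhat, const vec& inv_std,
                  const vec& g, vec& dg, vec& db) {
  int T = dY.n_rows, d = dY.n_cols;
  mat dX(T, d);
  for (int t = 0; t < T; ++t) {
    rowvec dxh = dY.row(t) % g.t();
    double m1 = arma::mean(dxh);
    double m2 = arma::mean(dxh % xhat.row(t));
    dX.row(t) = inv_std(t) * (dxh - m1 - xhat.row(t) * m2);
  }
  dg += arma::sum(dY % xhat, 0).t();
  db += arma::sum(dY, 0).t();
  return dX;
}

static const double GC = 0.044715;
static const double GS = 0.7978845608028654;  // sqrt(2/pi)

static mat gelu(const mat& X) {
  mat U = GS * (X + GC * arma::pow(X, 3));
  return 0.5 * X % (1.0 + arma::tanh(U));
}

static mat gelu_grad(const mat& X) {
  mat U = GS * (X + GC * arma::pow(X, 3));
  mat T = arma::tanh(U);
  return 0.5 * (1.0 + T) + 0.5 * X % (1.0 - arma::square(T)) % (GS * (1.0 + 3.0 * GC * arma::square(X)));
}

// ids are 0-based here
static Cache forward(const Model& m, const std::vector<int>& ids,
                     const mat* emb_override) {
  int T = ids.size();
  int d = m.E.n_cols;
  int H = m.H, dh = d / H;
  double scale = 1.0 / std::sqrt((double)dh);
  Cache c;
  c.Emb.set_size(T, d);
  for (int t = 0; t < T; ++t) {
    c.Emb.row(t) = emb_override ? emb_override->row(t) : m.E.row(ids[t]);
  }
  c.X0 = c.Emb + m.P.rows(0, T - 1);
  mat X = c.X0;
  for (size_t l = 0; l < m.layers.size(); ++l) {
    const Layer& L = m.layers[l];
    LayerCache lc;
    lc.xin = X;
    lc.a_in = ln_fwd(X, L.ln1g, L.ln1b, lc.xhat1, lc.inv1);
    lc.Q = lc.a_in * L.Wq; lc.Q.each_row() += L.bq.t();
    lc.K = lc.a_in * L.Wk; lc.K.each_row() += L.bk.t();
    lc.V = lc.a_in * L.Wv; lc.V.each_row() += L.bv.t();
    lc.O.set_size(T, d);
    for (int h = 0; h < H; ++h) {
      int c0 = h * dh, c1 = (h + 1) * dh - 1;
      mat Qh = lc.Q.cols(c0, c1), Kh = lc.K.cols(c0, c1), Vh = lc.V.cols(c0, c1);
      mat S = scale * (Qh * Kh.t());
      mat Ph(T, T, arma::fill::zeros);
      for (int t = 0; t < T; ++t) {
        rowvec s = S.row(t).cols(0, t);
        s -= s.max();
        rowvec e = arma::exp(s);
        Ph.row(t).cols(0, t) = e / arma::accu(e);
      }
      lc.Ph.push_back(Ph);
      lc.O.cols(c0, c1) = Ph * Vh;
    }
    mat attn = lc.O * L.Wo; attn.each_row() += L.bo.t();
    lc.xmid = X + attn;
    lc.m_in = ln_fwd(lc.xmid, L.ln2g, L.ln2b, lc.xhat2, lc.inv2);
    lc.H1pre = lc.m_in * L.W1; lc.H1pre.each_row() += L.b1.t();
    lc.H1 = gelu(lc.H1pre);
    mat mlp = lc.H1 * L.W2; mlp.each_row() += L.b2.t();
    X = lc.xmid + mlp;
    c.lc.push_back(lc);
  }
  c.xf_in = X;
  c.XF = ln_fwd(X, m.lnfg, m.lnfb, c.xhatf, c.invf);
  c.logits = c.XF * m.Wout;
  c.logits.each_row() += m.bout.t();
  return c;
}

// returns dX0; accumulates parameter grads
static mat backward(const Model& m, const Cache& c, const std::vector<int>& ids,
                    const mat& dlogits, Grads& g) {
  int T = ids.size();
  int d = m.E.n_cols;
  int H = m.H, dh = d / H;
  double scale = 1.0 / std::sqrt((double)dh);
  g.Wout += c.XF.t() * dlogits;
  g.bout += arma::sum(dlogits, 0).t();
  mat dXF = dlogits * m.Wout.t();
  mat dX = ln_bwd(dXF, c.xhatf, c.invf, m.lnfg, g.lnfg, g.lnfb);
  for (int l = (int)m.layers.size() - 1; l >= 0; --l) {
    const Layer& L = m.layers[l];
    const LayerCache& lc = c.lc[l];
    Layer& gl = g.layers[l];
    // MLP branch
    g.layers[l].W2 += lc.H1.t() * dX;
    gl.b2 += arma::sum(dX, 0).t();
    mat dH1 = dX * L.W2.t();
    mat dH1pre = dH1 % gelu_grad(lc.H1pre);
    gl.W1 += lc.m_in.t() * dH1pre;
    gl.b1 += arma::sum(dH1pre, 0).t();
    mat dM_in = dH1pre * L.W1.t();
    mat dXmid = dX + ln_bwd(dM_in, lc.xhat2, lc.inv2, L.ln2g, gl.ln2g, gl.ln2b);
    // attention branch (dXmid feeds both residual and attn output)
    gl.Wo += lc.O.t() * dXmid;
    gl.bo += arma::sum(dXmid, 0).t();
    mat dO = dXmid * L.Wo.t();
    mat dQ(T, d), dK(T, d), dV(T, d);
    for (int h = 0; h < H; ++h) {
      int c0 = h * dh, c1 = (h + 1) * dh - 1;
      mat Qh = lc.Q.cols(c0, c1), Kh = lc.K.cols(c0, c1), Vh = lc.V.cols(c0, c1);
      const mat& Ph = lc.Ph[h];
      mat dOh = dO.cols(c0, c1);
      mat dP = dOh * Vh.t();
      dV.cols(c0, c1) = Ph.t() * dOh;
      dP.each_col() -= arma::sum(dP % Ph, 1);
      mat dS = Ph % dP;
      dQ.cols(c0, c1) = scale * (dS * Kh);
      dK.cols(c0, c1) = scale * (dS.t() * Qh);
    }
    gl.Wq += lc.a_in.t() * dQ; gl.bq += arma::sum(dQ, 0).t();
    gl.Wk += lc.a_in.t() * dK; gl.bk += arma::sum(dK, 0).t();
    gl.Wv += lc.a_in.t() * dV; gl.bv += arma::sum(dV, 0).t();
    mat dA_in = dQ * L.Wq.t() + dK * L.Wk.t() + dV * L.Wv.t();
    dX = dXmid + ln_bwd(dA_in, lc.xhat1, lc.inv1, L.ln1g, gl.ln1g, gl.ln1b);
  }
  if (g.emb) {
    for (int t = 0; t < T; ++t) {
      g.E.row(ids[t]) += dX.row(t);
      g.P.row(t) += dX.row(t);
    }
  }
  return dX;
}

static std::vector<int> to_ids0(const IntegerVector& ids, const Model& m) {
  std::vector<int> v(ids.size());
  if ((int)ids.size() > (int)m.P.n_rows) {
    stop("sequence length %d exceeds model context length %d",
         (int)ids.size(), (int)m.P.n_rows);
  }
  for (int i = 0; i < ids.size(); ++i) {
    if (ids[i] < 1 || ids[i] > (int)m.E.n_rows) stop("token id out of range");
    v[i] = ids[i] - 1;
  }
  return v;
}

static rowvec softmax_row(const rowvec& z) {
  rowvec s = z - z.max();
  rowvec e = arma::exp(s);
  return e / arma::accu(e);
}

// Cross-entropy loss (and optionally gradients) over a minibatch of
// sequences. `cut[i]` is the 1-based index of the first token whose
// prediction contributes to the loss (everything from there to the end of
// the sequence is scored). Loss and grads are summed; divide by n_tok in R.
// [[Rcpp::export]]
List tf_batch(List params, List ids_list, IntegerVector cut, int n_heads,
              bool want_grads) {
  Model m = model_from_list(params, n_heads);
  Grads g;
  if (want_grads) g = grads_like(m, true);
  double loss = 0.0;
  long n_tok = 0;
  for (int b = 0; b < ids_list.size(); ++b) {
    IntegerVector idsR = ids_list[b];
    std::vector<int> ids = to_ids0(idsR, m);
    int T = ids.size();
    if (T < 2) stop("training sequence must have at least 2 tokens");
    int first = std::max((int)cut[b], 2);  // can never predict the first token
    Cache c = forward(m, ids, nullptr);
    mat dlogits;
    if (want_grads) dlogits = arma::zeros<mat>(T, m.E.n_rows);
    for (int k = first - 1; k < T; ++k) {  // k: 0-based index of target token
      rowvec p = softmax_row(c.logits.row(k - 1));
      double pt = std::max(p(ids[k]), 1e-12);
      loss += -std::log(pt);
      n_tok += 1;
      if (want_grads) {
        dlogits.row(k - 1) = p;
        dlogits(k - 1, ids[k]) -= 1.0;
      }
    }
    if (want_grads) backward(m, c, ids, dlogits, g);
  }
  List out = List::create(_["loss"] = loss, _["n_tok"] = (double)n_tok);
  if (want_grads) out["grads"] = grads_to_list(g);
  return out;
}

// Next-token distribution given a prefix.
// [[Rcpp::export]]
NumericVector tf_next_probs(List params, IntegerVector ids, int n_heads) {
  Model m = model_from_list(params, n_heads);
  std::vector<int> v = to_ids0(ids, m);
  Cache c = forward(m, v, nullptr);
  rowvec p = softmax_row(c.logits.row(v.size() - 1));
  return NumericVector(p.begin(), p.end());
}

static rowvec ln_row(const rowvec& x, const vec& g, const vec& b) {
  double mu = arma::mean(x);
  double var = arma::mean(arma::square(x - mu));
  return ((x - mu) / std::sqrt(var + LN_EPS)) % g.t() + b.t();
}

// Greedy decoding: extend `ids` until `eos_id` or `max_new` tokens.
// The prompt is forwarded once; subsequent steps reuse cached per-layer
// keys/values and process a single row. Returns generated ids (excluding
// EOS), their chosen probabilities, and the probability of EOS at the
// stopping step (NA if cut off by max_new).
// [[Rcpp::export]]
List tf_generate(List params, IntegerVector ids, int max_new, int eos_id,
                 int n_heads) {
  Model m = model_from_list(params, n_heads);
  std::vector<int> v = to_ids0(ids, m);
  int nl = m.layers.size();
  int d = m.E.n_cols;
  int H = m.H, dh = d / H;
  double scale = 1.0 / std::sqrt((double)dh);

  Cache c = forward(m, v, nullptr);
  std::vector<mat> Kc(nl), Vc(nl);
  for (int l = 0; l < nl; ++l) { Kc[l] = c.lc[l].K; Vc[l] = c.lc[l].V; }
  rowvec p = softmax_row(c.logits.row(v.size() - 1));

  std::vector<int> out_ids;
  std::vector<double> out_probs;
  double eos_prob = NA_REAL;
  for (int step = 0; step < max_new; ++step) {
    arma::uword best = p.index_max();
    if ((int)best == eos_id - 1) {
      eos_prob = p(best);
      break;
    }
    out_ids.push_back((int)best + 1);
    out_probs.push_back(p(best));
    int pos = v.size();
    if (pos >= (int)m.P.n_rows) break;
    v.push_back((int)best);
    // incremental forward of the single new position
    rowvec x = m.E.row(best) + m.P.row(pos);
    for (int l = 0; l < nl; ++l) {
      const Layer& L = m.layers[l];
      rowvec a = ln_row(x, L.ln1g, L.ln1b);
      rowvec q = a * L.Wq + L.bq.t();
      rowvec k = a * L.Wk + L.bk.t();
      rowvec vv = a * L.Wv + L.bv.t();
      Kc[l] = arma::join_cols(Kc[l], k);
      Vc[l] = arma::join_cols(Vc[l], vv);
      rowvec o(d);
      for (int h = 0; h < H; ++h) {
        int c0 = h * dh, c1 = (h + 1) * dh - 1;
        rowvec s = scale * (q.cols(c0, c1) * Kc[l].cols(c0, c1).t());
        rowvec pw = softmax_row(s);
        o.cols(c0, c1) = pw * Vc[l].cols(c0, c1);
      }
      x += o * L.Wo + L.bo.t();
      rowvec mi = ln_row(x, L.ln2g, L.ln2b);
      rowvec h1 = gelu(arma::conv_to<mat>::from(mi * L.W1 + L.b1.t()));
      x += h1 * L.W2 + L.b2.t();
    }
    rowvec xf = ln_row(x, m.lnfg, m.lnfb);
    rowvec z = xf * m.Wout + m.bout.t();
    p = softmax_row(z);
  }
  return List::create(_["ids"] = wrap(out_ids), _["probs"] = wrap(out_probs),
                      _["eos_prob"] = eos_prob);
}

// Probability scores of the chosen tokens at given 1-based positions, with an
// optional per-position replacement of the token-embedding rows (used by the
// finite-difference saliency oracle).
// [[Rcpp::export]]
NumericVector tf_token_scores(List params, IntegerVector ids,
                              IntegerVector positions, int n_heads,
                              Nullable<NumericMatrix> emb_override) {
  Model m = model_from_list(params, n_heads);
  std::vector<int> v = to_ids0(ids, m);
  mat ov;
  const mat* ovp = nullptr;
  if (emb_override.isNotNull()) {
    ov = as<mat>(emb_override.get());
    ovp = &ov;
  }
  Cache c = forward(m, v, ovp);
  NumericVector scores(positions.size());
  for (int i = 0; i < positions.size(); ++i) {
    int p = positions[i];
    if (p < 2 || p > (int)v.size()) stop("invalid generated-token position");
    rowvec pr = softmax_row(c.logits.row(p - 2));
    scores[i] = pr(v[p - 1]);
  }
  return scores;
}

// Input-times-gradient attributions. For each generated token (1-based
// positions in `ids`), the gradient of its probability score with respect to
// each input-token embedding row is multiplied elementwise by that embedding
// and reduced to an L2 norm. Returns an n_input x n_gen matrix of norms plus
// the scores.
// [[Rcpp::export]]
List tf_input_saliency(List params, IntegerVector ids, IntegerVector positions,
                       int n_input, int n_heads) {
  Model m = model_from_list(params, n_heads);
  std::vector<int> v = to_ids0(ids, m);
  Cache c = forward(m, v, nullptr);
  int T = v.size();
  mat norms(n_input, positions.size());
  NumericVector scores(positions.size());
  for (int i = 0; i < positions.size(); ++i) {
    int p = positions[i];
    if (p < 2 || p > T) stop("invalid generated-token position");
    rowvec pr = softmax_row(c.logits.row(p - 2));
    double pc = pr(v[p - 1]);
    scores[i] = pc;
    mat dlogits = arma::zeros<mat>(T, m.E.n_rows);
    dlogits.row(p - 2) = -pc * pr;
    dlogits(p - 2, v[p - 1]) += pc;
    Grads g = grads_like(m, false);
    mat dX0 = backward(m, c, v, dlogits, g);
    for (int t = 0; t < n_input; ++t) {
      norms(t, i) = arma::norm(dX0.row(t) % c.Emb.row(t), 2);
    }
  }
  return List::create(_["norms"] = norms, _["scores"] = scores);
}
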