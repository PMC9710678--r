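// Message-passing graph network on residue chain graphs.
//
// One graph per sequence: nodes are residues carrying a p-dimensional
// physicochemical profile, adjacent residues are connected by two directed
// edges (one per direction) whose 32-dim features start as ones. Per round:
// edge update from (src node, dst node, edge), node update from (mean of
// incoming updated edges, node), global update from (mean nodes, mean edges,
// previous global). After `rounds` rounds the 128-dim global feature is the
// graph readout; a pair is scored by an MLP on the 256-dim concatenation of
// the two readouts with a sigmoid output.
//
// All update functions are 2-layer leaky-ReLU MLPs shared across rounds.
// Training: binary cross-entropy + AdamW, hand-written backprop, single
// precision (throughput on one CPU), single-threaded and deterministic
// under the given seed (own RNG, R's RNG untouched).
//
// The chain topology is exploited throughout: with edges stored as
// [all forward | all backward] blocks, the source/destination node columns
// of each graph's edges are contiguous column ranges, so every gather,
// aggregation and scatter is a handful of contiguous submatrix copies/adds
// per graph instead of per-edge indexing.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::uword;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  uint32_t unif(uint32_t n) { return (uint32_t)(next() % n); }
};

static const char* kParamNames[] = {
    "enc_W1", "enc_b1", "enc_W2", "enc_b2",
    "edge_W1", "edge_b1", "edge_W2", "edge_b2",
    "node_W1", "node_b1", "node_W2", "node_b2",
    "glob_W1", "glob_b1", "glob_W2", "glob_b2",
    "head_W1", "head_b1", "head_W2", "head_b2"};
constexpr int kNP = 20;

struct Params {
  std::vector<fmat> P;  // biases stored as single-column matrices
  float slope;
  int rounds;
};

Params unpack(const List& params, int rounds, double slope) {
  Params out;
  out.P.resize(kNP);
  for (int i = 0; i < kNP; ++i) {
    NumericMatrix m = params[kParamNames[i]];
    out.P[i] = arma::conv_to<fmat>::from(
        arma::mat(m.begin(), m.nrow(), m.ncol(), false));
  }
  out.slope = (float)slope;
  out.rounds = rounds;
  return out;
}

List pack(const std::vector<fmat>& P) {
  List out(kNP);
  CharacterVector nm(kNP);
  for (int i = 0; i < kNP; ++i) {
    out[i] = wrap(arma::conv_to<arma::mat>::from(P[i]));
    nm[i] = kParamNames[i];
  }
  out.attr("names") = nm;
  return out;
}

inline void leaky_inplace(fmat& A, float slope) {
  float* a = A.memptr();
  const uword n = A.n_elem;
  for (uword i = 0; i < n; ++i) a[i] = a[i] > 0.f ? a[i] : slope * a[i];
}
// dPre = dOut * leaky'(out), derived from the sign of the activation
inline void apply_mask(fmat& dOut, const fmat& act, float slope) {
  float* d = dOut.memptr();
  const float* a = act.memptr();
  const uword n = act.n_elem;
  for (uword i = 0; i < n; ++i) d[i] = a[i] > 0.f ? d[i] : slope * d[i];
}
// fused per-column bias add + leaky rectification (one memory pass)
inline void bias_leaky(fmat& Y, const fmat& b, float slope) {
  const float* bp = b.memptr();
  const uword R = Y.n_rows, C = Y.n_cols;
  float* y = Y.memptr();
  for (uword c = 0; c < C; ++c, y += R)
    for (uword k = 0; k < R; ++k) {
      float t = y[k] + bp[k];
      y[k] = t > 0.f ? t : slope * t;
    }
}
// y = leaky(W x + b)
inline fmat affine_leaky(const fmat& W, const fmat& b, const fmat& X,
                         float slope) {
  fmat Y = W * X;
  bias_leaky(Y, b, slope);
  return Y;
}

// Batch of chain graphs. Nodes of graph g occupy columns
// [off[g], off[g]+len[g]) of node matrices; forward edge i of graph g
// (node i -> i+1, graph-local) occupies column eoff[g]+i of the forward
// block, its mirror the same column of the backward block (offset Ef).
struct Batch {
  std::vector<int> off, len, eoff;
  int N = 0, Ef = 0, G = 0;  // nodes, forward edges, graphs
  int E() const { return 2 * Ef; }
};

Batch make_batch(const std::vector<const std::vector<int>*>& graphs) {
  Batch b;
  b.G = graphs.size();
  b.off.resize(b.G);
  b.len.resize(b.G);
  b.eoff.resize(b.G);
  for (int g = 0; g < b.G; ++g) {
    b.off[g] = b.N;
    b.eoff[g] = b.Ef;
    b.len[g] = graphs[g]->size();
    b.N += b.len[g];
    b.Ef += std::max(0, b.len[g] - 1);
  }
  return b;
}

fmat raw_nodes(const Batch& b,
               const std::vector<const std::vector<int>*>& graphs,
               const fmat& prof) {
  fmat X0(prof.n_rows, b.N);
  for (int g = 0; g < b.G; ++g)
    for (int i = 0; i < b.len[g]; ++i)
      X0.col(b.off[g] + i) = prof.col((*graphs[g])[i]);
  return X0;
}

// The edge MLP's first layer sees [N(src); N(dst); E], i.e. its weight
// matrix splits into three 32x32 blocks A|B|C with
//   pre-activation = A N(src) + B N(dst) + C E + b.
// A N and B N are computed once per node (not per edge) and scattered to
// the edge columns via contiguous submatrix adds; the inverse mappings are
// used in the backward pass. This avoids ever materializing the 96 x E
// gathered input.

// scatter-add per-node products into edge columns: fwd edge i of graph g
// has src = node i, dst = node i+1; the backward block mirrors it
void add_src(const Batch& b, const fmat& Pn, fmat& He) {
  for (int g = 0; g < b.G; ++g) {
    int ne = b.len[g] - 1;
    if (ne <= 0) continue;
    int o = b.off[g], eo = b.eoff[g];
    He.cols(eo, eo + ne - 1) += Pn.cols(o, o + ne - 1);
    He.cols(b.Ef + eo, b.Ef + eo + ne - 1) += Pn.cols(o + 1, o + ne);
  }
}
void add_dst(const Batch& b, const fmat& Pn, fmat& He) {
  for (int g = 0; g < b.G; ++g) {
    int ne = b.len[g] - 1;
    if (ne <= 0) continue;
    int o = b.off[g], eo = b.eoff[g];
    He.cols(eo, eo + ne - 1) += Pn.cols(o + 1, o + ne);
    He.cols(b.Ef + eo, b.Ef + eo + ne - 1) += Pn.cols(o, o + ne - 1);
  }
}
// adjoints of add_src/add_dst: accumulate edge-column gradients on nodes
void add_src_T(const Batch& b, const fmat& dHe, fmat& dN) {
  for (int g = 0; g < b.G; ++g) {
    int ne = b.len[g] - 1;
    if (ne <= 0) continue;
    int o = b.off[g], eo = b.eoff[g];
    dN.cols(o, o + ne - 1) += dHe.cols(eo, eo + ne - 1);
    dN.cols(o + 1, o + ne) += dHe.cols(b.Ef + eo, b.Ef + eo + ne - 1);
  }
}
void add_dst_T(const Batch& b, const fmat& dHe, fmat& dN) {
  for (int g = 0; g < b.G; ++g) {
    int ne = b.len[g] - 1;
    if (ne <= 0) continue;
    int o = b.off[g], eo = b.eoff[g];
    dN.cols(o + 1, o + ne) += dHe.cols(eo, eo + ne - 1);
    dN.cols(o, o + ne - 1) += dHe.cols(b.Ef + eo, b.Ef + eo + ne - 1);
  }
}
// gathered endpoint matrices (backward pass weight gradients only)
void gather_endpoints(const Batch& b, const fmat& N, fmat& Ns, fmat& Nd) {
  Ns.set_size(32, b.E());
  Nd.set_size(32, b.E());
  for (int g = 0; g < b.G; ++g) {
    int ne = b.len[g] - 1;
    if (ne <= 0) continue;
    int o = b.off[g], eo = b.eoff[g];
    Ns.cols(eo, eo + ne - 1) = N.cols(o, o + ne - 1);
    Nd.cols(eo, eo + ne - 1) = N.cols(o + 1, o + ne);
    Ns.cols(b.Ef + eo, b.Ef + eo + ne - 1) = N.cols(o + 1, o + ne);
    Nd.cols(b.Ef + eo, b.Ef + eo + ne - 1) = N.cols(o, o + ne - 1);
  }
}

// per-node mean of incoming edges: interior nodes receive one forward and
// one backward edge, chain ends one
fmat aggregate(const Batch& b, const fmat& E) {
  fmat M(32, b.N, arma::fill::zeros);
  for (int g = 0; g < b.G; ++g) {
    int ne = b.len[g] - 1;
    if (ne <= 0) continue;
    int o = b.off[g], eo = b.eoff[g];
    M.cols(o + 1, o + ne) = E.cols(eo, eo + ne - 1);              // forward
    M.cols(o, o + ne - 1) += E.cols(b.Ef + eo, b.Ef + eo + ne - 1);  // backward
    if (ne > 1) M.cols(o + 1, o + ne - 1) *= 0.5f;  // interior indegree 2
  }
  return M;
}

// adjoint of aggregate(): dE += scaled scatter of dM
void aggregate_backward(const Batch& b, const fmat& dM, fmat& dE) {
  for (int g = 0; g < b.G; ++g) {
    int ne = b.len[g] - 1;
    if (ne <= 0) continue;
    int o = b.off[g], eo = b.eoff[g];
    fmat dMs = dM.cols(o, o + b.len[g] - 1);
    if (ne > 1) dMs.cols(1, ne - 1) *= 0.5f;
    dE.cols(eo, eo + ne - 1) += dMs.cols(1, ne);
    dE.cols(b.Ef + eo, b.Ef + eo + ne - 1) += dMs.cols(0, ne - 1);
  }
}

void graph_means(const Batch& b, const fmat& N, const fmat& E, fmat& meanN,
                 fmat& meanE) {
  meanN.set_size(32, b.G);
  meanE.set_size(32, b.G);
  for (int g = 0; g < b.G; ++g) {
    meanN.col(g) = arma::mean(N.cols(b.off[g], b.off[g] + b.len[g] - 1), 1);
    int ne = b.len[g] - 1;
    if (ne > 0) {
      int eo = b.eoff[g];
      meanE.col(g) = (arma::sum(E.cols(eo, eo + ne - 1), 1) +
                      arma::sum(E.cols(b.Ef + eo, b.Ef + eo + ne - 1), 1)) /
                     (2.f * ne);
    } else {
      meanE.col(g).zeros();
    }
  }
}

struct Cache {
  fmat X0, Henc;
  std::vector<fmat> N, E, U;            // round states (rounds+1 each)
  std::vector<fmat> He, Hn, Hu, M, Xu;  // per-round intermediates
  fmat Z, Hh;
  frowvec s;
};

frowvec forward(const Params& pp, const Batch& b, const fmat& X0raw,
                const arma::uvec& pairA, const arma::uvec& pairB, Cache* C) {
  const std::vector<fmat>& P = pp.P;
  const float sl = pp.slope;
  // round states live in the cache (or a local stand-in) and are never
  // copied; NS[r]/ES[r]/US[r] are the features entering round r
  Cache local;
  Cache& S = C ? *C : local;
  S.N.clear(); S.E.clear(); S.U.clear();
  S.He.clear(); S.Hn.clear(); S.Hu.clear(); S.M.clear(); S.Xu.clear();
  fmat Henc = affine_leaky(P[0], P[1], X0raw, sl);
  S.N.push_back(affine_leaky(P[2], P[3], Henc, sl));
  S.E.emplace_back(32, b.E(), arma::fill::ones);
  S.U.emplace_back(128, b.G, arma::fill::zeros);
  if (C) { C->X0 = X0raw; C->Henc = std::move(Henc); }
  for (int r = 0; r < pp.rounds; ++r) {
    const fmat& Nc = S.N[r];
    const fmat& Ec = S.E[r];
    // edge update: pre-act = A N(src) + B N(dst) + C E + b, blockwise
    fmat He = P[4].cols(64, 95) * Ec;
    add_src(b, P[4].cols(0, 31) * Nc, He);
    add_dst(b, P[4].cols(32, 63) * Nc, He);
    bias_leaky(He, P[5], sl);
    S.E.push_back(affine_leaky(P[6], P[7], He, sl));
    const fmat& Enew = S.E[r + 1];
    fmat M = aggregate(b, Enew);
    // node update: pre-act = A' M + B' N + b
    fmat Hn = P[8].cols(0, 31) * M;
    Hn += P[8].cols(32, 63) * Nc;
    bias_leaky(Hn, P[9], sl);
    S.N.push_back(affine_leaky(P[10], P[11], Hn, sl));
    fmat meanN, meanE;
    graph_means(b, S.N[r + 1], Enew, meanN, meanE);
    fmat Xu = arma::join_cols(meanN, arma::join_cols(meanE, S.U[r]));
    fmat Hu = affine_leaky(P[12], P[13], Xu, sl);
    S.U.push_back(affine_leaky(P[14], P[15], Hu, sl));
    if (C) {
      C->He.push_back(std::move(He)); C->Hn.push_back(std::move(Hn));
      C->Hu.push_back(std::move(Hu)); C->M.push_back(std::move(M));
      C->Xu.push_back(std::move(Xu));
    }
  }
  const fmat& Uc = S.U.back();
  fmat Z(256, pairA.n_elem);
  Z.rows(0, 127) = Uc.cols(pairA);
  Z.rows(128, 255) = Uc.cols(pairB);
  fmat Hh = affine_leaky(P[16], P[17], Z, sl);
  fmat logit = P[18] * Hh;
  logit.each_col() += P[19].col(0);
  frowvec s = 1.f / (1.f + arma::exp(-logit.row(0)));
  if (C) { C->Z = std::move(Z); C->Hh = std::move(Hh); C->s = s; }
  return s;
}

void backward(const Params& pp, const Batch& b, const arma::uvec& pairA,
              const arma::uvec& pairB, const frowvec& y, const Cache& C,
              std::vector<fmat>& G_) {
  const std::vector<fmat>& P = pp.P;
  const float sl = pp.slope;
  const int B = y.n_elem, R = pp.rounds;
  fmat dlogit(1, B);
  dlogit.row(0) = (C.s - y) / (float)B;
  G_[18] += dlogit * C.Hh.t();
  G_[19].col(0) += arma::sum(dlogit, 1);
  fmat dHh = P[18].t() * dlogit;
  apply_mask(dHh, C.Hh, sl);
  G_[16] += dHh * C.Z.t();
  G_[17].col(0) += arma::sum(dHh, 1);
  fmat dZ = P[16].t() * dHh;
  fmat dU(128, b.G, arma::fill::zeros);
  for (int k = 0; k < B; ++k) {
    dU.col(pairA[k]) += dZ.submat(0, k, 127, k);
    dU.col(pairB[k]) += dZ.submat(128, k, 255, k);
  }
  fmat dN(32, b.N, arma::fill::zeros);
  fmat dE(32, b.E(), arma::fill::zeros);
  for (int r = R - 1; r >= 0; --r) {
    // global MLP
    fmat dUo = dU;
    apply_mask(dUo, C.U[r + 1], sl);
    G_[14] += dUo * C.Hu[r].t();
    G_[15].col(0) += arma::sum(dUo, 1);
    fmat dHu = P[14].t() * dUo;
    apply_mask(dHu, C.Hu[r], sl);
    G_[12] += dHu * C.Xu[r].t();
    G_[13].col(0) += arma::sum(dHu, 1);
    fmat dXu = P[12].t() * dHu;
    // mean-gradients broadcast back to nodes/edges; U[r] passes through
    for (int g = 0; g < b.G; ++g) {
      int L = b.len[g], ne = L - 1;
      dN.cols(b.off[g], b.off[g] + L - 1).each_col() +=
          dXu.submat(0, g, 31, g) / (float)L;
      if (ne > 0) {
        int eo = b.eoff[g];
        fmat de = dXu.submat(32, g, 63, g) / (float)(2 * ne);
        dE.cols(eo, eo + ne - 1).each_col() += de;
        dE.cols(b.Ef + eo, b.Ef + eo + ne - 1).each_col() += de;
      }
    }
    dU = dXu.rows(64, 191);
    // node MLP
    apply_mask(dN, C.N[r + 1], sl);
    G_[10] += dN * C.Hn[r].t();
    G_[11].col(0) += arma::sum(dN, 1);
    fmat dHn = P[10].t() * dN;
    apply_mask(dHn, C.Hn[r], sl);
    G_[8].cols(0, 31) += dHn * C.M[r].t();
    G_[8].cols(32, 63) += dHn * C.N[r].t();
    G_[9].col(0) += arma::sum(dHn, 1);
    aggregate_backward(b, P[8].cols(0, 31).t() * dHn, dE);
    dN = P[8].cols(32, 63).t() * dHn;
    // edge MLP
    apply_mask(dE, C.E[r + 1], sl);
    G_[6] += dE * C.He[r].t();
    G_[7].col(0) += arma::sum(dE, 1);
    fmat dHe = P[6].t() * dE;
    apply_mask(dHe, C.He[r], sl);
    fmat Ns, Nd;
    gather_endpoints(b, C.N[r], Ns, Nd);
    G_[4].cols(0, 31) += dHe * Ns.t();
    G_[4].cols(32, 63) += dHe * Nd.t();
    G_[4].cols(64, 95) += dHe * C.E[r].t();
    G_[5].col(0) += arma::sum(dHe, 1);
    add_src_T(b, P[4].cols(0, 31).t() * dHe, dN);
    add_dst_T(b, P[4].cols(32, 63).t() * dHe, dN);
    dE = P[4].cols(64, 95).t() * dHe;
  }
  apply_mask(dN, C.N[0], sl);
  G_[2] += dN * C.Henc.t();
  G_[3].col(0) += arma::sum(dN, 1);
  fmat dHenc = P[2].t() * dN;
  apply_mask(dHenc, C.Henc, sl);
  G_[0] += dHenc * C.X0.t();
  G_[1].col(0) += arma::sum(dHenc, 1);
}

std::vector<std::vector<int>> convert_seqs(const List& seqs) {
  std::vector<std::vector<int>> out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    IntegerVector v = seqs[i];
    out[i].assign(v.begin(), v.end());
  }
  return out;
}

}  // namespace

// Batched forward scores. prof is p x 20 (column = residue profile),
// seqs list of 0-based integer codes, pairA/pairB 0-based indices into seqs.
// [[Rcpp::export]]
NumericVector gnn_forward_scores_cpp(const List& params,
                                     const arma::mat& prof, const List& seqs,
                                     const IntegerVector& pairA,
                                     const IntegerVector& pairB, int rounds,
                                     double slope, int chunk = 128) {
  Params pp = unpack(params, rounds, slope);
  fmat fprof = arma::conv_to<fmat>::from(prof);
  auto sq = convert_seqs(seqs);
  const int n = pairA.size();
  NumericVector out(n);
  for (int start = 0; start < n; start += chunk) {
    int end = std::min(n, start + chunk);
    int B = end - start;
    std::vector<const std::vector<int>*> graphs(2 * B);
    arma::uvec gA(B), gB(B);
    for (int k = 0; k < B; ++k) {
      graphs[2 * k] = &sq[pairA[start + k]];
      graphs[2 * k + 1] = &sq[pairB[start + k]];
      gA[k] = 2 * k;
      gB[k] = 2 * k + 1;
    }
    Batch b = make_batch(graphs);
    fmat X0 = raw_nodes(b, graphs, fprof);
    frowvec s = forward(pp, b, X0, gA, gB, nullptr);
    for (int k = 0; k < B; ++k) out[start + k] = s[k];
  }
  return out;
}

// Analytic gradient of the mean BCE loss for one batch (used for gradient
// checking in the tests). Returns list(loss=, grads=list(...)).
// [[Rcpp::export]]
List gnn_grad_cpp(const List& params, const arma::mat& prof, const List& seqs,
                  const IntegerVector& pairA, const IntegerVector& pairB,
                  const NumericVector& labels, int rounds, double slope) {
  Params pp = unpack(params, rounds, slope);
  fmat fprof = arma::conv_to<fmat>::from(prof);
  auto sq = convert_seqs(seqs);
  const int B = pairA.size();
  std::vector<const std::vector<int>*> graphs(2 * B);
  arma::uvec gA(B), gB(B);
  frowvec y(B);
  for (int k = 0; k < B; ++k) {
    graphs[2 * k] = &sq[pairA[k]];
    graphs[2 * k + 1] = &sq[pairB[k]];
    gA[k] = 2 * k; gB[k] = 2 * k + 1;
    y[k] = (float)labels[k];
  }
  Batch b = make_batch(graphs);
  fmat X0 = raw_nodes(b, graphs, fprof);
  Cache C;
  frowvec s = forward(pp, b, X0, gA, gB, &C);
  std::vector<fmat> G_(kNP);
  for (int i = 0; i < kNP; ++i) G_[i].zeros(arma::size(pp.P[i]));
  backward(pp, b, gA, gB, y, C, G_);
  double loss = 0.0;
  for (int k = 0; k < B; ++k) {
    double p = std::min(1.0 - 1e-7, std::max(1e-7, (double)s[k]));
    loss += -(y[k] * std::log(p) + (1.0 - y[k]) * std::log(1.0 - p));
  }
  loss /= B;
  return List::create(_["loss"] = loss, _["grads"] = pack(G_));
}

// Minibatch AdamW training. Returns list(params=, loss=per-epoch mean BCE).
// [[Rcpp::export]]
List gnn_train_cpp(const List& params, const arma::mat& prof, const List& seqs,
                   const IntegerVector& pairA, const IntegerVector& pairB,
                   const NumericVector& labels, int epochs, int batch_size,
                   double lr, double weight_decay, double seed, int rounds,
                   double slope) {
  Params pp = unpack(params, rounds, slope);
  fmat fprof = arma::conv_to<fmat>::from(prof);
  auto sq = convert_seqs(seqs);
  const int n = pairA.size();
  Rng rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 7ULL);
  std::vector<fmat> m(kNP), v(kNP), G_(kNP);
  for (int i = 0; i < kNP; ++i) {
    m[i].zeros(arma::size(pp.P[i]));
    v[i].zeros(arma::size(pp.P[i]));
    G_[i].zeros(arma::size(pp.P[i]));
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long step = 0;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  NumericVector loss_hist(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = n - 1; i > 0; --i)
      std::swap(order[i], order[rng.unif(i + 1)]);
    double ep_loss = 0.0;
    int nb = 0;
    for (int start = 0; start < n; start += batch_size, ++nb) {
      int end = std::min(n, start + batch_size);
      int B = end - start;
      std::vector<const std::vector<int>*> graphs(2 * B);
      arma::uvec gA(B), gB(B);
      frowvec y(B);
      for (int k = 0; k < B; ++k) {
        int i = order[start + k];
        graphs[2 * k] = &sq[pairA[i]];
        graphs[2 * k + 1] = &sq[pairB[i]];
        gA[k] = 2 * k; gB[k] = 2 * k + 1;
        y[k] = (float)labels[i];
      }
      Batch b = make_batch(graphs);
      fmat X0 = raw_nodes(b, graphs, fprof);
      Cache C;
      frowvec s = forward(pp, b, X0, gA, gB, &C);
      for (int k = 0; k < B; ++k) {
        double p = std::min(1.0 - 1e-7, std::max(1e-7, (double)s[k]));
        ep_loss += -(y[k] * std::log(p) + (1.0 - y[k]) * std::log(1.0 - p)) / B;
      }
      for (int i = 0; i < kNP; ++i) G_[i].zeros();
      backward(pp, b, gA, gB, y, C, G_);
      if (!G_[0].is_finite()) stop("divergent loss: non-finite gradient");
      ++step;
      float bc1 = 1.f - std::pow(b1, (float)step);
      float bc2 = 1.f - std::pow(b2, (float)step);
      for (int i = 0; i < kNP; ++i) {
        pp.P[i] *= (1.f - (float)(lr * weight_decay));
        m[i] = b1 * m[i] + (1.f - b1) * G_[i];
        v[i] = b2 * v[i] + (1.f - b2) * arma::square(G_[i]);
        pp.P[i] -= (float)lr * (m[i] / bc1) / (arma::sqrt(v[i] / bc2) + eps);
      }
    }
    loss_hist[ep] = ep_loss / nb;
    if (!std::isfinite(loss_hist[ep]))
      stop("divergent loss (NaN) at epoch %d", ep + 1);
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = pack(pp.P), _["loss"] = loss_hist);
}
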