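// Felsenstein pruning engine for HKY + discrete-gamma likelihoods on a
// fixed binary topology, with cached per-node partials so that MCMC moves
// touching a few branches only recompute the affected nodes.
//
// Node indexing (0-based internally, 1-based at the R interface):
// tips 0..ntip-1 in the column order of the tip-state matrix, internal
// nodes ntip..nnode-1, root = last element of the postorder vector.
// Branch lengths are indexed by the child node and measured in expected
// substitutions per site (before multiplication by the category rate).
//
// Partial layout is site-major with the rate categories interleaved
// (part[(site*ncat + cat)*4 + state]); one scaling factor per site shared
// across categories, applied only on underflow, keeps the per-site log
// count low and lets the root mix categories in linear space.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

constexpr double RESCALE_BELOW = 1e-120;
constexpr int MAXCAT = 8;

struct Engine {
  int ntip, nnode, nsites, ncat;
  std::vector<int> child1, child2;   // per internal node (index - ntip)
  std::vector<int> post;             // internal nodes in postorder
  std::vector<int> tips;             // col-major nsites per tip, 0..3, >3 missing
  std::vector<double> catRates;
  double kappa;
  double freqs[4];
  std::vector<double> blen;                        // per node
  std::vector<std::vector<double>> part;           // per internal
  std::vector<std::vector<double>> cum;            // per internal: nsites
  std::vector<std::vector<double>> sparePart, spareCum;  // double buffers
  double loglik;
  // proposal bookkeeping
  bool pending;
  std::vector<int> savedNodes, savedBr;
  std::vector<double> savedBlen;
  double savedLoglik;
};

void hkyMatrix(double t, double kappa, const double *f, double *P) {
  const double piR = f[0] + f[2], piY = f[1] + f[3];
  const double beta = 1.0 / (2.0 * piR * piY +
                             2.0 * kappa * (f[0] * f[2] + f[1] * f[3]));
  const double A[4] = {piR, piY, piR, piY};
  const bool pur[4] = {true, false, true, false};
  const double e2 = std::exp(-beta * t);
  double e3[4];
  for (int j = 0; j < 4; ++j)
    e3[j] = std::exp(-beta * t * (A[j] * kappa + (1.0 - A[j])));
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      double v;
      if (i == j)
        v = f[j] + f[j] * (1.0 / A[j] - 1.0) * e2 +
            (A[j] - f[j]) / A[j] * e3[j];
      else if (pur[i] == pur[j])
        v = f[j] + f[j] * (1.0 / A[j] - 1.0) * e2 - f[j] / A[j] * e3[j];
      else
        v = f[j] * (1.0 - e2);
      P[4 * i + j] = v;   // row i = parent state, col j = child state
    }
}

// recompute the partial of internal node v (absolute index)
void computeNode(Engine &e, int v) {
  const int iv = v - e.ntip;
  const int c1 = e.child1[iv], c2 = e.child2[iv];
  const int S = e.nsites, K = e.ncat;
  double P1[MAXCAT][16], P2[MAXCAT][16];
  for (int c = 0; c < K; ++c) {
    hkyMatrix(e.blen[c1] * e.catRates[c], e.kappa, e.freqs, P1[c]);
    hkyMatrix(e.blen[c2] * e.catRates[c], e.kappa, e.freqs, P2[c]);
  }
  const bool t1 = c1 < e.ntip, t2 = c2 < e.ntip;
  const int *ts1 = t1 ? &e.tips[(size_t)c1 * S] : nullptr;
  const int *ts2 = t2 ? &e.tips[(size_t)c2 * S] : nullptr;
  const double *cp1 = t1 ? nullptr : e.part[c1 - e.ntip].data();
  const double *cc1 = t1 ? nullptr : e.cum[c1 - e.ntip].data();
  const double *cp2 = t2 ? nullptr : e.part[c2 - e.ntip].data();
  const double *cc2 = t2 ? nullptr : e.cum[c2 - e.ntip].data();
  double *out = e.part[iv].data();
  double *cumOut = e.cum[iv].data();
  for (int s = 0; s < S; ++s) {
    double *o = out + (size_t)s * K * 4;
    double mx = 0.0;
    for (int c = 0; c < K; ++c) {
      double a[4], b[4];
      if (t1) {
        const int st = ts1[s];
        const double *P = P1[c];
        if (st > 3) { a[0] = a[1] = a[2] = a[3] = 1.0; }
        else { a[0] = P[st]; a[1] = P[4 + st]; a[2] = P[8 + st]; a[3] = P[12 + st]; }
      } else {
        const double *p = cp1 + ((size_t)s * K + c) * 4;
        const double *P = P1[c];
        for (int x = 0; x < 4; ++x)
          a[x] = P[4 * x] * p[0] + P[4 * x + 1] * p[1] +
                 P[4 * x + 2] * p[2] + P[4 * x + 3] * p[3];
      }
      if (t2) {
        const int st = ts2[s];
        const double *P = P2[c];
        if (st > 3) { b[0] = b[1] = b[2] = b[3] = 1.0; }
        else { b[0] = P[st]; b[1] = P[4 + st]; b[2] = P[8 + st]; b[3] = P[12 + st]; }
      } else {
        const double *p = cp2 + ((size_t)s * K + c) * 4;
        const double *P = P2[c];
        for (int x = 0; x < 4; ++x)
          b[x] = P[4 * x] * p[0] + P[4 * x + 1] * p[1] +
                 P[4 * x + 2] * p[2] + P[4 * x + 3] * p[3];
      }
      double *oc = o + 4 * c;
      for (int x = 0; x < 4; ++x) {
        oc[x] = a[x] * b[x];
        if (oc[x] > mx) mx = oc[x];
      }
    }
    double lc = 0.0;
    if (mx > 0.0 && mx < RESCALE_BELOW) {       // rescale only on underflow
      const double inv = 1.0 / mx;
      for (int i = 0; i < 4 * K; ++i) o[i] *= inv;
      lc = std::log(mx);
    }
    if (cc1) lc += cc1[s];
    if (cc2) lc += cc2[s];
    cumOut[s] = lc;
  }
}

double rootLogLik(Engine &e) {
  const int r = e.post.back() - e.ntip;
  const int S = e.nsites, K = e.ncat;
  const double *pr = e.part[r].data();
  const double *cr = e.cum[r].data();
  double total = 0.0;
  for (int s = 0; s < S; ++s) {
    const double *p = pr + (size_t)s * K * 4;
    double site = 0.0;
    for (int c = 0; c < K; ++c)
      site += e.freqs[0] * p[4 * c] + e.freqs[1] * p[4 * c + 1] +
              e.freqs[2] * p[4 * c + 2] + e.freqs[3] * p[4 * c + 3];
    if (site <= 0.0) return -INFINITY;
    total += std::log(site / K) + cr[s];
  }
  return total;
}

} // namespace

typedef Rcpp::XPtr<Engine> EnginePtr;

// [[Rcpp::export(name = ".engine_create")]]
SEXP engine_create(IntegerMatrix tipStates, IntegerVector child1,
                   IntegerVector child2, IntegerVector postorder,
                   NumericVector catRates, double kappa,
                   NumericVector freqs) {
  Engine *e = new Engine();
  e->nsites = tipStates.nrow();
  e->ntip = tipStates.ncol();
  e->ncat = catRates.size();
  if (e->ncat > MAXCAT) stop("at most 8 rate categories supported");
  e->nnode = e->ntip + child1.size();
  e->tips.resize((size_t)e->ntip * e->nsites);
  for (int j = 0; j < e->ntip; ++j)
    for (int s = 0; s < e->nsites; ++s)
      e->tips[(size_t)j * e->nsites + s] = tipStates(s, j) - 1; // 0-based
  e->child1.assign(child1.begin(), child1.end());
  e->child2.assign(child2.begin(), child2.end());
  for (auto &v : e->child1) --v;
  for (auto &v : e->child2) --v;
  e->post.assign(postorder.begin(), postorder.end());
  for (auto &v : e->post) --v;
  e->catRates.assign(catRates.begin(), catRates.end());
  e->kappa = kappa;
  for (int i = 0; i < 4; ++i) e->freqs[i] = freqs[i];
  e->blen.assign(e->nnode, 0.0);
  const int nint = e->nnode - e->ntip;
  e->part.resize(nint);
  e->cum.resize(nint);
  e->sparePart.resize(nint);
  e->spareCum.resize(nint);
  for (int i = 0; i < nint; ++i) {
    e->part[i].assign((size_t)e->ncat * e->nsites * 4, 0.0);
    e->cum[i].assign((size_t)e->nsites, 0.0);
    e->sparePart[i] = e->part[i];
    e->spareCum[i] = e->cum[i];
  }
  e->loglik = NA_REAL;
  e->pending = false;
  return EnginePtr(e, true);
}

// [[Rcpp::export(name = ".engine_set_all")]]
double engine_set_all(SEXP ptr, NumericVector blen) {
  EnginePtr e(ptr);
  if (e->pending) stop("pending proposal: accept or reject first");
  for (int i = 0; i < e->nnode; ++i) e->blen[i] = blen[i];
  for (int v : e->post) computeNode(*e, v);
  e->loglik = rootLogLik(*e);
  return e->loglik;
}

// [[Rcpp::export(name = ".engine_propose")]]
double engine_propose(SEXP ptr, IntegerVector nodes, IntegerVector changedBr,
                      NumericVector newLen) {
  EnginePtr e(ptr);
  if (e->pending) stop("pending proposal: accept or reject first");
  e->savedNodes.assign(nodes.begin(), nodes.end());
  for (auto &v : e->savedNodes) --v;
  for (int v : e->savedNodes) {       // swap current into the spare buffer
    e->part[v - e->ntip].swap(e->sparePart[v - e->ntip]);
    e->cum[v - e->ntip].swap(e->spareCum[v - e->ntip]);
  }
  e->savedBr.resize(changedBr.size());
  e->savedBlen.resize(changedBr.size());
  for (int i = 0; i < changedBr.size(); ++i) {
    const int b = changedBr[i] - 1;
    e->savedBr[i] = b;
    e->savedBlen[i] = e->blen[b];
    e->blen[b] = newLen[i];
  }
  e->savedLoglik = e->loglik;
  for (int v : e->savedNodes) computeNode(*e, v);
  e->loglik = rootLogLik(*e);
  e->pending = true;
  return e->loglik;
}

// [[Rcpp::export(name = ".engine_accept")]]
void engine_accept(SEXP ptr) {
  EnginePtr e(ptr);
  e->pending = false;
  e->savedNodes.clear(); e->savedBr.clear();
}

// [[Rcpp::export(name = ".engine_reject")]]
void engine_reject(SEXP ptr) {
  EnginePtr e(ptr);
  if (!e->pending) return;
  for (int v : e->savedNodes) {       // swap the old buffers back
    e->part[v - e->ntip].swap(e->sparePart[v - e->ntip]);
    e->cum[v - e->ntip].swap(e->spareCum[v - e->ntip]);
  }
  for (size_t i = 0; i < e->savedBr.size(); ++i)
    e->blen[e->savedBr[i]] = e->savedBlen[i];
  e->loglik = e->savedLoglik;
  e->pending = false;
  e->savedNodes.clear(); e->savedBr.clear();
}

// [[Rcpp::export(name = ".engine_loglik")]]
double engine_loglik(SEXP ptr) {
  EnginePtr e(ptr);
  return e->loglik;
}
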