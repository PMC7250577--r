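// Pruning likelihood engine for unrooted binary trees under a reversible
// amino-acid substitution model with discrete-gamma rate mixing.
//
// Transition probabilities come from the spectral decomposition
// P(t) = U diag(exp(lambda t)) Uinv supplied by the R layer. Conditional
// likelihood "messages" are stored per directed edge with per-pattern
// rescaling. Branch lengths are optimized edge by edge via safeguarded
// Newton iterations on the per-pattern exponential-mixture coefficients,
// and the topology search is NNI hill-climbing that reuses the four
// subtree messages around each internal edge. A constraint is a set of
// tip bipartitions that must stay present: NNI moves on edges carrying a
// constrained split are rejected, which is sufficient because an NNI
// replaces exactly the split of the edge it acts on.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <functional>
using namespace Rcpp;

static const double MINBL = 1e-8;
static const double MAXBL = 20.0;
static const double SCALE_THRESH = 1e-120;

struct Engine {
  int ntip, nnode, nedge, nst, ncat, npat;
  // edges: endpoints 0-based node ids; tips 0..ntip-1
  std::vector<int> ea, eb;
  std::vector<double> elen;
  std::vector<std::vector<int>> adj; // incident edge ids per node
  // model
  std::vector<double> U, Uinv, lambda, pi; // nst*nst etc, row-major
  std::vector<double> rates, rw;
  // tip data: codes[tip*npat + pat], -1 = missing
  std::vector<int> tipcode;
  std::vector<double> w; // pattern weights
  // messages: dir id = 2*e + side, side 0 -> into ea[e], 1 -> into eb[e]
  std::vector<std::vector<double>> msg;      // size npat*ncat*nst
  std::vector<std::vector<double>> msgScale; // size npat
  std::vector<char> valid;
  // scratch
  std::vector<double> Pbuf; // ncat * nst * nst

  int other(int e, int node) const { return ea[e] == node ? eb[e] : ea[e]; }
  int dirInto(int e, int node) const { return 2 * e + (node == ea[e] ? 0 : 1); }

  void init(const IntegerMatrix& edge, const NumericVector& len, int ntip_,
            const IntegerMatrix& codes, const NumericVector& wts,
            const NumericMatrix& U_, const NumericMatrix& Uinv_,
            const NumericVector& lambda_, const NumericVector& pi_,
            const NumericVector& rates_, const NumericVector& rw_) {
    ntip = ntip_;
    nedge = edge.nrow();
    nst = U_.nrow();
    ncat = rates_.size();
    npat = codes.nrow();
    nnode = 0;
    ea.resize(nedge); eb.resize(nedge); elen.resize(nedge);
    for (int e = 0; e < nedge; ++e) {
      ea[e] = edge(e, 0) - 1;
      eb[e] = edge(e, 1) - 1;
      elen[e] = std::max(len[e], MINBL);
      nnode = std::max(nnode, std::max(ea[e], eb[e]) + 1);
    }
    adj.assign(nnode, {});
    for (int e = 0; e < nedge; ++e) {
      adj[ea[e]].push_back(e);
      adj[eb[e]].push_back(e);
    }
    U.assign(U_.begin(), U_.end());       // column-major from R
    Uinv.assign(Uinv_.begin(), Uinv_.end());
    lambda.assign(lambda_.begin(), lambda_.end());
    pi.assign(pi_.begin(), pi_.end());
    rates.assign(rates_.begin(), rates_.end());
    rw.assign(rw_.begin(), rw_.end());
    tipcode.resize((size_t)ntip * npat);
    for (int tip = 0; tip < ntip; ++tip)
      for (int p = 0; p < npat; ++p) tipcode[(size_t)tip * npat + p] = codes(p, tip);
    w.assign(wts.begin(), wts.end());
    msg.assign(2 * nedge, {});
    msgScale.assign(2 * nedge, {});
    valid.assign(2 * nedge, 0);
    Pbuf.resize((size_t)ncat * nst * nst);
  }

  inline double Uat(int x, int k) const { return U[(size_t)k * nst + x]; }
  inline double Uinvat(int k, int y) const { return Uinv[(size_t)y * nst + k]; }

  // P row-major: P[x*nst+y]
  void computeP(double t, double* P) const {
    std::vector<double> ex(nst);
    for (int c = 0; c < ncat; ++c) {
      double tr = t * rates[c];
      for (int k = 0; k < nst; ++k) ex[k] = std::exp(lambda[k] * tr);
      double* Pc = P + (size_t)c * nst * nst;
      for (int x = 0; x < nst; ++x) {
        for (int y = 0; y < nst; ++y) {
          double s = 0.0;
          for (int k = 0; k < nst; ++k) s += Uat(x, k) * ex[k] * Uinvat(k, y);
          Pc[(size_t)x * nst + y] = s > 0.0 ? s : 0.0;
        }
      }
    }
  }

  void invalidateAll() { std::fill(valid.begin(), valid.end(), 0); }

  // message into node u along edge e: likelihood of the data behind the
  // far endpoint, as a function of the state at u
  void computeMsg(int e, int u) {
    const int d = dirInto(e, u);
    const int v = other(e, u);
    std::vector<double>& out = msg[d];
    std::vector<double>& osc = msgScale[d];
    out.assign((size_t)npat * ncat * nst, 0.0);
    osc.assign(npat, 0.0);
    if (v >= ntip) {
      // resolve upstream messages BEFORE touching the shared P scratch:
      // the recursion below also writes into Pbuf
      int pre[2], npre = 0;
      for (int e2 : adj[v]) if (e2 != e) pre[npre++] = e2;
      for (int k = 0; k < npre; ++k) ensure(pre[k], v);
    }
    computeP(elen[e], Pbuf.data());
    if (v < ntip) {
      const int* codes = &tipcode[(size_t)v * npat];
      for (int p = 0; p < npat; ++p) {
        const int code = codes[p];
        for (int c = 0; c < ncat; ++c) {
          double* o = &out[((size_t)p * ncat + c) * nst];
          const double* Pc = Pbuf.data() + (size_t)c * nst * nst;
          if (code < 0) {
            for (int x = 0; x < nst; ++x) o[x] = 1.0;
          } else {
            for (int x = 0; x < nst; ++x) o[x] = Pc[(size_t)x * nst + code];
          }
        }
      }
      return;
    }
    // internal far endpoint: product of its other incoming messages
    int ch[2], nch = 0;
    for (int e2 : adj[v]) if (e2 != e) ch[nch++] = e2;
    if (nch != 2) stop("tree must be unrooted binary (all internal nodes degree 3)");
    const std::vector<double>& m1 = msg[dirInto(ch[0], v)];
    const std::vector<double>& s1 = msgScale[dirInto(ch[0], v)];
    const std::vector<double>& m2 = msg[dirInto(ch[1], v)];
    const std::vector<double>& s2 = msgScale[dirInto(ch[1], v)];
    std::vector<double> prod(nst);
    for (int p = 0; p < npat; ++p) {
      osc[p] = s1[p] + s2[p];
      double mx = 0.0;
      for (int c = 0; c < ncat; ++c) {
        const double* a = &m1[((size_t)p * ncat + c) * nst];
        const double* b = &m2[((size_t)p * ncat + c) * nst];
        for (int y = 0; y < nst; ++y) prod[y] = a[y] * b[y];
        const double* Pc = Pbuf.data() + (size_t)c * nst * nst;
        double* o = &out[((size_t)p * ncat + c) * nst];
        for (int x = 0; x < nst; ++x) {
          double s = 0.0;
          const double* Pr = Pc + (size_t)x * nst;
          for (int y = 0; y < nst; ++y) s += Pr[y] * prod[y];
          o[x] = s;
          if (s > mx) mx = s;
        }
      }
      if (mx > 0.0 && mx < SCALE_THRESH) {
        const double inv = 1.0 / mx;
        for (int c = 0; c < ncat; ++c) {
          double* o = &out[((size_t)p * ncat + c) * nst];
          for (int x = 0; x < nst; ++x) o[x] *= inv;
        }
        osc[p] += std::log(mx);
      }
    }
  }

  void ensure(int e, int u) {
    const int d = dirInto(e, u);
    if (!valid[d]) {
      computeMsg(e, u);
      valid[d] = 1;
    }
  }

  // product of messages into `node` over incident edges except `excl`;
  // for a tip node this is the observation indicator
  void partialExcl(int node, int excl, std::vector<double>& out,
                   std::vector<double>& oscale) {
    out.assign((size_t)npat * ncat * nst, 1.0);
    oscale.assign(npat, 0.0);
    if (node < ntip) {
      const int* codes = &tipcode[(size_t)node * npat];
      for (int p = 0; p < npat; ++p) {
        const int code = codes[p];
        if (code < 0) continue;
        for (int c = 0; c < ncat; ++c) {
          double* o = &out[((size_t)p * ncat + c) * nst];
          for (int x = 0; x < nst; ++x) o[x] = (x == code) ? 1.0 : 0.0;
        }
      }
      return;
    }
    for (int e : adj[node]) {
      if (e == excl) continue;
      ensure(e, node);
      const std::vector<double>& m = msg[dirInto(e, node)];
      const std::vector<double>& s = msgScale[dirInto(e, node)];
      for (int p = 0; p < npat; ++p) {
        oscale[p] += s[p];
        double* o = &out[(size_t)p * ncat * nst];
        const double* mm = &m[(size_t)p * ncat * nst];
        for (int i = 0; i < ncat * nst; ++i) o[i] *= mm[i];
      }
    }
  }

  // log-likelihood evaluated at an internal node from its incident messages
  double loglikAt(int node) {
    for (int e : adj[node]) ensure(e, node);
    double lnL = 0.0;
    std::vector<double> prod(nst);
    for (int p = 0; p < npat; ++p) {
      double site = 0.0, sc = 0.0;
      for (int c = 0; c < ncat; ++c) {
        for (int x = 0; x < nst; ++x) prod[x] = pi[x];
        for (int e : adj[node]) {
          const double* m = &msg[dirInto(e, node)][((size_t)p * ncat + c) * nst];
          for (int x = 0; x < nst; ++x) prod[x] *= m[x];
        }
        double s = 0.0;
        for (int x = 0; x < nst; ++x) s += prod[x];
        site += rw[c] * s;
      }
      for (int e : adj[node]) sc += msgScale[dirInto(e, node)][p];
      if (site < 1e-300) site = 1e-300;
      lnL += w[p] * (std::log(site) + sc);
    }
    return lnL;
  }

  // --- branch-length optimization -----------------------------------------
  // coefficients C[p][c][k] with L_p(t) = sum_c rw_c sum_k C e^(lambda_k r_c t)
  void edgeCoefs(const std::vector<double>& A, const std::vector<double>& B,
                 std::vector<double>& C) const {
    C.assign((size_t)npat * ncat * nst, 0.0);
    std::vector<double> va(nst), vb(nst);
    for (int p = 0; p < npat; ++p) {
      for (int c = 0; c < ncat; ++c) {
        const double* a = &A[((size_t)p * ncat + c) * nst];
        const double* b = &B[((size_t)p * ncat + c) * nst];
        for (int k = 0; k < nst; ++k) {
          double sa = 0.0, sb = 0.0;
          for (int x = 0; x < nst; ++x) {
            sa += a[x] * pi[x] * Uat(x, k);
            sb += Uinvat(k, x) * b[x];
          }
          va[k] = sa; vb[k] = sb;
        }
        double* cc = &C[((size_t)p * ncat + c) * nst];
        for (int k = 0; k < nst; ++k) cc[k] = va[k] * vb[k];
      }
    }
  }

  // lnL(t) plus first/second derivatives from the coefficient form; the
  // exponentials depend only on (category, t) and are hoisted out of the
  // pattern loop
  void edgeEval(const std::vector<double>& C, const std::vector<double>& sA,
                const std::vector<double>& sB, double t,
                double& f, double& g, double& h) const {
    f = g = h = 0.0;
    std::vector<double> E0((size_t)ncat * nst), E1((size_t)ncat * nst),
        E2((size_t)ncat * nst);
    for (int c = 0; c < ncat; ++c) {
      const double r = rates[c];
      for (int k = 0; k < nst; ++k) {
        const double lr = lambda[k] * r;
        const double e = rw[c] * std::exp(lr * t);
        E0[(size_t)c * nst + k] = e;
        E1[(size_t)c * nst + k] = lr * e;
        E2[(size_t)c * nst + k] = lr * lr * e;
      }
    }
    for (int p = 0; p < npat; ++p) {
      double L = 0.0, L1 = 0.0, L2 = 0.0;
      const double* cc = &C[(size_t)p * ncat * nst];
      for (int i = 0; i < ncat * nst; ++i) {
        L += cc[i] * E0[i];
        L1 += cc[i] * E1[i];
        L2 += cc[i] * E2[i];
      }
      if (L < 1e-300) L = 1e-300;
      f += w[p] * (std::log(L) + sA[p] + sB[p]);
      const double d1 = L1 / L;
      g += w[p] * d1;
      h += w[p] * (L2 / L - d1 * d1);
    }
  }

  // safeguarded Newton on dlnL/dt within [MINBL, MAXBL]
  double newtonEdge(const std::vector<double>& C, const std::vector<double>& sA,
                    const std::vector<double>& sB, double t0,
                    double& lnLOut) const {
    double lo = MINBL, hi = MAXBL;
    double t = std::min(std::max(t0, lo), hi);
    double f, g, h;
    for (int it = 0; it < 30; ++it) {
      edgeEval(C, sA, sB, t, f, g, h);
      if (std::abs(g) < 1e-8 * (1.0 + std::abs(f))) break;
      if (g > 0) lo = t; else hi = t;
      double tn;
      if (h < 0) {
        tn = t - g / h;
        if (!(tn > lo && tn < hi)) tn = 0.5 * (lo + hi);
      } else {
        tn = 0.5 * (lo + hi);
      }
      if (std::abs(tn - t) < 1e-10 * (1.0 + t)) { t = tn; break; }
      t = tn;
    }
    edgeEval(C, sA, sB, t, f, g, h);
    lnLOut = f;
    return t;
  }

  // one full sweep of branch-length optimization; returns final lnL
  double sweep(int root) {
    invalidateAll();
    for (int e : adj[root]) ensure(e, root);
    std::vector<double> A, B, C, sA, sB;
    double lnL = 0.0;
    // recursive descent via explicit lambda
    std::function<void(int, int)> descend = [&](int u, int fromEdge) {
      for (int e : adj[u]) {
        if (e == fromEdge) continue;
        const int v = other(e, u);
        // optimize edge (u, v): A = partial at u excluding e (valid),
        // B = partial at v excluding e (subtree untouched this sweep)
        partialExcl(u, e, A, sA);
        partialExcl(v, e, B, sB);
        edgeCoefs(A, B, C);
        double l;
        elen[e] = newtonEdge(C, sA, sB, elen[e], l);
        lnL = l;
        if (v >= ntip) {
          // push fresh message into v before working inside its subtree
          computeMsg(e, v);
          valid[dirInto(e, v)] = 1;
          descend(v, e);
        }
        // refresh the rootward message now that the subtree is final
        computeMsg(e, u);
        valid[dirInto(e, u)] = 1;
      }
    };
    descend(root, -1);
    return lnL;
  }

  double optimizeBranchLengths(int root, double tol, int maxSweeps) {
    double prev = -std::numeric_limits<double>::infinity();
    double cur = prev;
    for (int s = 0; s < maxSweeps; ++s) {
      cur = sweep(root);
      if (cur - prev < tol) break;
      prev = cur;
    }
    return cur;
  }

  // --- splits & NNI --------------------------------------------------------
  // canonical split mask of tips behind eb[e] (complemented so bit 0 is 0)
  void splitMasks(std::vector<uint64_t>& out) {
    out.assign(nedge, 0);
    std::vector<uint64_t> behind(2 * nedge, 0);
    std::function<uint64_t(int, int)> tipsBehind = [&](int e, int u) -> uint64_t {
      // tips on the far side of edge e seen from u
      const int d = dirInto(e, u);
      if (behind[d]) return behind[d];
      const int v = other(e, u);
      uint64_t m = 0;
      if (v < ntip) m = (uint64_t)1 << v;
      else for (int e2 : adj[v]) if (e2 != e) m |= tipsBehind(e2, v);
      behind[d] = m;
      return m;
    };
    const uint64_t full = ntip == 64 ? ~(uint64_t)0 : (((uint64_t)1 << ntip) - 1);
    for (int e = 0; e < nedge; ++e) {
      uint64_t m = tipsBehind(e, ea[e]); // tips behind eb side
      if (m & 1) m = full & ~m;
      out[e] = m;
    }
  }

  double nniRound(int root, const std::vector<uint64_t>& constraints,
                  double curLnL, double tol, bool& moved) {
    moved = false;
    // make every directed message valid
    invalidateAll();
    for (int e : adj[root]) ensure(e, root);
    std::function<void(int, int)> down = [&](int u, int fromEdge) {
      for (int e : adj[u]) {
        if (e == fromEdge) continue;
        const int v = other(e, u);
        if (v >= ntip) {
          ensure(e, v);
          down(v, e);
        }
      }
    };
    down(root, -1);
    std::vector<uint64_t> splits;
    if (!constraints.empty()) splitMasks(splits);
    double bestGain = tol;
    int bestEdge = -1, bestCand = -1;
    double bestT = 0.0;
    std::vector<double> A((size_t)npat * ncat * nst), B((size_t)npat * ncat * nst);
    std::vector<double> sA(npat), sB(npat), C;
    for (int e = 0; e < nedge; ++e) {
      const int a = ea[e], b = eb[e];
      if (a < ntip || b < ntip) continue;
      if (!constraints.empty()) {
        bool locked = false;
        for (uint64_t cm : constraints) if (cm == splits[e]) { locked = true; break; }
        if (locked) continue;
      }
      int eas[2], ebs[2], na = 0, nb = 0;
      for (int e2 : adj[a]) if (e2 != e) eas[na++] = e2;
      for (int e2 : adj[b]) if (e2 != e) ebs[nb++] = e2;
      const std::vector<double>* ma[2] = {&msg[dirInto(eas[0], a)], &msg[dirInto(eas[1], a)]};
      const std::vector<double>* sa_[2] = {&msgScale[dirInto(eas[0], a)], &msgScale[dirInto(eas[1], a)]};
      const std::vector<double>* mb[2] = {&msg[dirInto(ebs[0], b)], &msg[dirInto(ebs[1], b)]};
      const std::vector<double>* sb_[2] = {&msgScale[dirInto(ebs[0], b)], &msgScale[dirInto(ebs[1], b)]};
      for (int cand = 0; cand < 2; ++cand) {
        // cand 0: pair (ma0, mb_cand...) -- swap a's second subtree with b's
        const std::vector<double>* A1 = ma[0];
        const std::vector<double>* A2 = mb[cand];
        const std::vector<double>* B1 = ma[1];
        const std::vector<double>* B2 = mb[1 - cand];
        const std::vector<double>* s1 = sa_[0];
        const std::vector<double>* s2 = sb_[cand];
        const std::vector<double>* s3 = sa_[1];
        const std::vector<double>* s4 = sb_[1 - cand];
        const size_t n = (size_t)npat * ncat * nst;
        for (size_t i = 0; i < n; ++i) {
          A[i] = (*A1)[i] * (*A2)[i];
          B[i] = (*B1)[i] * (*B2)[i];
        }
        for (int p = 0; p < npat; ++p) {
          sA[p] = (*s1)[p] + (*s2)[p];
          sB[p] = (*s3)[p] + (*s4)[p];
        }
        edgeCoefs(A, B, C);
        double l;
        const double topt = newtonEdge(C, sA, sB, elen[e], l);
        if (l - curLnL > bestGain) {
          bestGain = l - curLnL;
          bestEdge = e; bestCand = cand; bestT = topt;
        }
      }
    }
    if (bestEdge < 0) return curLnL;
    // apply: swap the subtree behind a's second edge with the one behind
    // b's chosen edge
    const int a = ea[bestEdge], b = eb[bestEdge];
    int eas[2], ebs[2], na = 0, nb = 0;
    for (int e2 : adj[a]) if (e2 != bestEdge) eas[na++] = e2;
    for (int e2 : adj[b]) if (e2 != bestEdge) ebs[nb++] = e2;
    const int eSwapA = eas[1];
    const int eSwapB = ebs[bestCand];
    // reattach eSwapA to b and eSwapB to a
    if (ea[eSwapA] == a) ea[eSwapA] = b; else eb[eSwapA] = b;
    if (ea[eSwapB] == b) ea[eSwapB] = a; else eb[eSwapB] = a;
    adj[a].erase(std::find(adj[a].begin(), adj[a].end(), eSwapA));
    adj[b].erase(std::find(adj[b].begin(), adj[b].end(), eSwapB));
    adj[a].push_back(eSwapB);
    adj[b].push_back(eSwapA);
    elen[bestEdge] = bestT;
    invalidateAll();
    moved = true;
    return curLnL + bestGain;
  }
};

static void buildEngine(Engine& eng, const IntegerMatrix& edge,
                        const NumericVector& len, int ntip,
                        const IntegerMatrix& codes, const NumericVector& wts,
                        const List& model) {
  eng.init(edge, len, ntip, codes, wts,
           as<NumericMatrix>(model["U"]), as<NumericMatrix>(model["Uinv"]),
           as<NumericVector>(model["lambda"]), as<NumericVector>(model["pi"]),
           as<NumericVector>(model["rates"]), as<NumericVector>(model["rweights"]));
}

// [[Rcpp::export]]
double cpp_phylo_loglik(IntegerMatrix edge, NumericVector edge_length, int ntip,
                        IntegerMatrix codes, NumericVector weights, List model) {
  Engine eng;
  buildEngine(eng, edge, edge_length, ntip, codes, weights, model);
  int root = -1;
  for (int v = 0; v < eng.nnode; ++v) if ((int)eng.adj[v].size() > 1) { root = v; break; }
  if (root < 0) stop("no internal node found");
  return eng.loglikAt(root);
}

// [[Rcpp::export]]
List cpp_phylo_optimize(IntegerMatrix edge, NumericVector edge_length, int ntip,
                        IntegerMatrix codes, NumericVector weights, List model,
                        bool do_nni, NumericMatrix constraint_splits,
                        int max_nni_rounds, double tol) {
  Engine eng;
  buildEngine(eng, edge, edge_length, ntip, codes, weights, model);
  if (ntip > 64) stop("at most 64 tips are supported by the NNI engine");
  int root = -1;
  for (int v = 0; v < eng.nnode; ++v) if ((int)eng.adj[v].size() > 1) { root = v; break; }
  if (root < 0) stop("no internal node found");
  std::vector<uint64_t> constraints;
  const uint64_t full = ntip == 64 ? ~(uint64_t)0 : (((uint64_t)1 << ntip) - 1);
  for (int i = 0; i < constraint_splits.nrow(); ++i) {
    uint64_t m = 0;
    for (int tjj = 0; tjj < ntip; ++tjj)
      if (constraint_splits(i, tjj) > 0.5) m |= (uint64_t)1 << tjj;
    if (m & 1) m = full & ~m;
    // trivial splits constrain nothing
    int bits = 0;
    for (uint64_t mm = m; mm; mm &= mm - 1) ++bits;
    if (bits >= 2 && bits <= ntip - 2) constraints.push_back(m);
  }
  double lnL = eng.optimizeBranchLengths(root, tol, 10);
  int moves = 0;
  bool converged = true;
  if (do_nni && ntip >= 4) {
    for (int round = 0; round < max_nni_rounds; ++round) {
      bool moved = false;
      lnL = eng.nniRound(root, constraints, lnL, tol, moved);
      if (!moved) break;
      ++moves;
      lnL = eng.optimizeBranchLengths(root, tol, 10);
      if (round == max_nni_rounds - 1) converged = false;
    }
  }
  IntegerMatrix outEdge(eng.nedge, 2);
  NumericVector outLen(eng.nedge);
  for (int e = 0; e < eng.nedge; ++e) {
    outEdge(e, 0) = eng.ea[e] + 1;
    outEdge(e, 1) = eng.eb[e] + 1;
    outLen[e] = eng.elen[e];
  }
  return List::create(_["edge"] = outEdge, _["edge_length"] = outLen,
                      _["logLik"] = lnL, _["nni_moves"] = moves,
                      _["converged"] = converged);
}
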