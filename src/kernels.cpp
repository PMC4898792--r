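#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <string>
using namespace Rcpp;

// Shared network representation (1-based node indices):
//   nodeTime   time of each node; root at 0, increasing toward the tips
//   nodeParent index of the rootward neighbour; 0 for the root and for
//              reticulation children (routing for those is in the ret table)
//   retChild / retParentA / retParentB / retProbA
//              per-locus routing: child attaches to parentA with prob probA
//   tips       node indices of the leaves, in taxon order (all at equal depth)
// Reticulation children are created after both their parents, so sorting by
// (time desc, index desc) processes every node before its possible parents
// even when a reticulation shares its parents' event time.

static int epoch_of(double tau, const NumericVector& breaks) {
  int e = breaks.size() - 1;
  while (e > 0 && breaks[e] >= tau) --e;
  return e;
}

// [[Rcpp::export]]
List cpp_simulate_profile(NumericVector nodeTime, IntegerVector nodeParent,
                          IntegerVector retChild, NumericVector retProbA,
                          IntegerVector retParentA, IntegerVector retParentB,
                          IntegerVector tips, NumericVector epochBreaks,
                          NumericVector epochRates, int nLoci) {
  const int K = nodeTime.size();
  const int m = tips.size();
  const int R = retChild.size();
  const int G = 2 * m - 1;

  // processing order: time desc, index desc
  std::vector<int> ord(K);
  for (int i = 0; i < K; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (nodeTime[a] != nodeTime[b]) return nodeTime[a] > nodeTime[b];
    return a > b;
  });
  // tip lookup: taxon index per node (-1 if internal)
  std::vector<int> taxonOf(K, -1);
  for (int i = 0; i < m; ++i) taxonOf[tips[i] - 1] = i;

  IntegerMatrix gP(G, nLoci);
  NumericMatrix gT(G, nLoci);
  std::vector<int> effParent(K);
  std::vector< std::vector<int> > pool(K);

  for (int locus = 0; locus < nLoci; ++locus) {
    for (int i = 0; i < K; ++i) effParent[i] = nodeParent[i] - 1; // -1 root
    for (int r = 0; r < R; ++r)
      effParent[retChild[r] - 1] =
        (unif_rand() < retProbA[r] ? retParentA[r] : retParentB[r]) - 1;
    for (int i = 0; i < K; ++i) pool[i].clear();

    int nextGene = m; // 0-based id of next coalescent node
    for (int oi = 0; oi < K; ++oi) {
      int v = ord[oi];
      if (taxonOf[v] >= 0) {
        pool[v].push_back(taxonOf[v]);
        gT(taxonOf[v], locus) = nodeTime[v];
      }
      std::vector<int>& lin = pool[v];
      int k = (int)lin.size();
      if (k == 0) continue;
      int p = effParent[v];
      double tLow = (p < 0) ? R_NegInf : nodeTime[p];
      double tau = nodeTime[v];
      while (k >= 2) {
        int e = epoch_of(tau, epochBreaks);
        double segLow = (e == 0) ? R_NegInf : epochBreaks[e];
        if (segLow < tLow) segLow = tLow;
        double rate = epochRates[e] * k * (k - 1) / 2.0;
        double w = (rate > 0.0) ? exp_rand() / rate : R_PosInf;
        if (tau - w > segLow) {
          tau -= w;
          int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
          int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
          if (j >= i) ++j;
          int g = nextGene++;
          gP(lin[i], locus) = g + 1;
          gP(lin[j], locus) = g + 1;
          gT(g, locus) = tau;
          lin[i] = g;
          lin.erase(lin.begin() + j);
          --k;
        } else if (segLow > tLow) {
          tau = segLow; // step into the previous (older) epoch
        } else {
          break;       // reached the branch's rootward end
        }
      }
      if (p >= 0)
        pool[p].insert(pool[p].end(), lin.begin(), lin.end());
      else
        gP(lin[0], locus) = 0; // gene-tree root
    }
  }
  return List::create(_["parent"] = gP, _["time"] = gT);
}

// ---------------------------------------------------------------------------
// Per-tree topology summaries for a profile of rooted binary gene trees given
// as parent vectors: tips 1..m, internal nodes m+1..2m-1 with every parent
// index larger than its children, root = 2m-1 (parent 0).

static inline int popcount32(unsigned int x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// [[Rcpp::export]]
List cpp_profile_summaries(IntegerMatrix parent, int m, CharacterVector labels,
                           bool quartets) {
  const int G = 2 * m - 1;
  const int nLoci = parent.ncol();
  if (m > 30) stop("profiles with more than 30 taxa are not supported");

  // quartet bookkeeping
  long nQ = 0;
  std::vector< std::vector<long> > chooseTab;
  if (quartets && m >= 4) {
    chooseTab.assign(m + 1, std::vector<long>(5, 0));
    for (int n = 0; n <= m; ++n) {
      chooseTab[n][0] = 1;
      for (int r = 1; r <= 4 && r <= n; ++r)
        chooseTab[n][r] = chooseTab[n - 1][r - 1] +
          (n - 1 >= r ? chooseTab[n - 1][r] : 0);
    }
    nQ = chooseTab[m][4];
  }
  IntegerMatrix wQ((int)nQ, 3);
  std::vector<char> assigned(nQ > 0 ? nQ : 1, 0);

  CharacterVector topo(nLoci);
  List splitsOut(nLoci), cherriesOut(nLoci);
  const unsigned int full = (m == 30) ? 0x3FFFFFFFu : ((1u << m) - 1u);

  std::vector<int> c1(G, -1), c2(G, -1);
  std::vector<unsigned int> ts(G, 0);
  std::vector<std::string> lab(m);
  for (int i = 0; i < m; ++i) lab[i] = as<std::string>(labels[i]);

  for (int locus = 0; locus < nLoci; ++locus) {
    for (int i = 0; i < G; ++i) { c1[i] = -1; c2[i] = -1; }
    int root = -1;
    for (int i = 0; i < G; ++i) {
      int p = parent(i, locus);
      if (p == 0) { root = i; continue; }
      if (c1[p - 1] < 0) c1[p - 1] = i; else c2[p - 1] = i;
    }
    for (int i = 0; i < m; ++i) ts[i] = 1u << i;
    for (int i = m; i < G; ++i) ts[i] = ts[c1[i]] | ts[c2[i]];

    // nontrivial splits, canonicalised to the side not containing taxon 1
    std::vector<unsigned int> sp;
    for (int i = m; i < G; ++i) {
      if (i == root) continue;
      int pc = popcount32(ts[i]);
      if (pc < 2 || pc > m - 2) continue;
      unsigned int msk = ts[i];
      if (msk & 1u) msk = (~msk) & full;
      sp.push_back(msk);
    }
    std::sort(sp.begin(), sp.end());
    sp.erase(std::unique(sp.begin(), sp.end()), sp.end());
    splitsOut[locus] = IntegerVector(sp.begin(), sp.end());

    // cherries on the unrooted view
    std::vector<int> cherryKeys;
    if (m >= 2) {
      std::vector< std::vector<int> > tipN(G);
      for (int i = m; i < G; ++i) {
        if (i == root) continue;
        if (c1[i] < m) tipN[i].push_back(c1[i]);
        if (c2[i] < m) tipN[i].push_back(c2[i]);
      }
      int ra = c1[root], rb = c2[root];
      if (ra < m && rb < m) { // m == 2
        int a = std::min(ra, rb), b = std::max(ra, rb);
        cherryKeys.push_back(a * m + b);
      } else if (ra < m) {
        tipN[rb].push_back(ra);
      } else if (rb < m) {
        tipN[ra].push_back(rb);
      }
      for (int i = m; i < G; ++i) {
        std::vector<int>& tn = tipN[i];
        if ((int)tn.size() >= 2) {
          for (size_t a = 0; a < tn.size(); ++a)
            for (size_t b = a + 1; b < tn.size(); ++b) {
              int x = std::min(tn[a], tn[b]), y = std::max(tn[a], tn[b]);
              cherryKeys.push_back(x * m + y);
            }
        }
      }
    }
    cherriesOut[locus] = IntegerVector(cherryKeys.begin(), cherryKeys.end());

    // canonical rooted topology string (sorted child order, byte comparison)
    std::vector<std::string> nm(G);
    for (int i = 0; i < m; ++i) nm[i] = lab[i];
    for (int i = m; i < G; ++i) {
      const std::string &a = nm[c1[i]], &b = nm[c2[i]];
      nm[i] = (a < b) ? "(" + a + "," + b + ")" : "(" + b + "," + a + ")";
    }
    topo[locus] = nm[root];

    // quartet resolutions (deduped within a tree via 'assigned')
    if (nQ > 0) {
      std::fill(assigned.begin(), assigned.end(), 0);
      std::vector<int> I, O;
      for (size_t s = 0; s < sp.size(); ++s) {
        I.clear(); O.clear();
        for (int t = 0; t < m; ++t)
          ((sp[s] >> t) & 1u) ? I.push_back(t) : O.push_back(t);
        for (size_t a = 0; a < I.size(); ++a)
          for (size_t b = a + 1; b < I.size(); ++b)
            for (size_t c = 0; c < O.size(); ++c)
              for (size_t d = c + 1; d < O.size(); ++d) {
                int q[4] = { I[a], I[b], O[c], O[d] };
                std::sort(q, q + 4);
                long idx = chooseTab[q[3]][4] + chooseTab[q[2]][3] +
                           chooseTab[q[1]][2] + q[0];
                if (assigned[idx]) continue;
                assigned[idx] = 1;
                int i1 = I[a], i2 = I[b];
                int code;
                if ((q[0] == std::min(i1, i2) && q[1] == std::max(i1, i2)) ||
                    (q[2] == std::min(i1, i2) && q[3] == std::max(i1, i2)))
                  code = 0; // q0q1 | q2q3
                else if ((q[0] == std::min(i1, i2) && q[2] == std::max(i1, i2)) ||
                         (q[1] == std::min(i1, i2) && q[3] == std::max(i1, i2)))
                  code = 1; // q0q2 | q1q3
                else
                  code = 2; // q0q3 | q1q2
                wQ((int)idx, code) += 1;
              }
      }
    }
  }
  return List::create(_["topo"] = topo, _["splits"] = splitsOut,
                      _["cherries"] = cherriesOut, _["quartets"] = wQ);
}

static inline bool masks_incompatible(unsigned int a, unsigned int b,
                                      unsigned int full) {
  return (a & b) && (a & ~b & full) && (~a & b & full) && (~a & ~b & full);
}

// Weighted incompatible ordered-pair sums over unique splits, one value per
// threshold k: sum over ordered pairs with w > k of (w_i - k)(w_j - k).
// [[Rcpp::export]]
NumericVector cpp_si_sums(IntegerVector masks, NumericVector w,
                          IntegerVector ks, int m) {
  const unsigned int full = (m == 30) ? 0x3FFFFFFFu : ((1u << m) - 1u);
  const int S = masks.size(), nk = ks.size();
  NumericVector out(nk);
  for (int i = 0; i < S; ++i) {
    unsigned int a = (unsigned int)masks[i];
    for (int j = i + 1; j < S; ++j) {
      if (!masks_incompatible(a, (unsigned int)masks[j], full)) continue;
      for (int t = 0; t < nk; ++t) {
        double k = ks[t];
        if (w[i] > k && w[j] > k) out[t] += 2.0 * (w[i] - k) * (w[j] - k);
      }
    }
  }
  return out;
}

// Greedy consensus over unique splits: candidates in the supplied order must
// already be sorted (weight desc, mask asc, insertion order); accepts a split
// iff compatible with everything accepted so far. Returns accepted indices.
// [[Rcpp::export]]
IntegerVector cpp_greedy_accept(IntegerVector masks, int m) {
  const unsigned int full = (m == 30) ? 0x3FFFFFFFu : ((1u << m) - 1u);
  std::vector<int> acc;
  for (int i = 0; i < masks.size(); ++i) {
    unsigned int a = (unsigned int)masks[i];
    bool ok = true;
    for (size_t j = 0; j < acc.size(); ++j)
      if (masks_incompatible(a, (unsigned int)masks[acc[j]], full)) {
        ok = false; break;
      }
    if (ok) {
      acc.push_back(i);
      if ((int)acc.size() == m - 3) break;
    }
  }
  IntegerVector out(acc.size());
  for (size_t i = 0; i < acc.size(); ++i) out[i] = acc[i] + 1;
  return out;
}

// For each target split, the weights of all observed splits incompatible
// with it (used by the internode-certainty family).
// [[Rcpp::export]]
List cpp_conflict_weights(IntegerVector masks, NumericVector w,
                          IntegerVector targets, int m) {
  const unsigned int full = (m == 30) ? 0x3FFFFFFFu : ((1u << m) - 1u);
  List out(targets.size());
  for (int t = 0; t < targets.size(); ++t) {
    std::vector<double> cw;
    unsigned int a = (unsigned int)targets[t];
    for (int i = 0; i < masks.size(); ++i)
      if (masks_incompatible(a, (unsigned int)masks[i], full))
        cw.push_back(w[i]);
    out[t] = NumericVector(cw.begin(), cw.end());
  }
  return out;
}
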