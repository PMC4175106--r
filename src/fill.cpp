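// Log-space partition-function fill with memory-reduced storage.
//
// Fragments: (i,j) with i <= j is the interior fragment i..j; (i,j) with
// i > j is the exterior ("wrapped") fragment i..N plus 1..j, closed by
// the pair between i and j.  Both passes run the same recursions over
// fragments in ascending length; the wrapped pass replaces the hairpin
// term by the exterior-loop term Q^exterior.  Index arithmetic never
// wraps modulo N: a reference to position 0 or N+1 drops the term, which
// is exactly the rule that forbids loops spanning the molecular ends
// (those belong to Q^exterior alone).
//
// Persistent O(N^2) storage: V, Y, Y^L, Z full (both triangles) plus the
// upper half-triangle of W^Q = 4.5 NxN-equivalents.  W and W^L and W^MBL
// keep two rolling diagonals each, W^MB five; W^coax is transient per
// element.  "Full" storage mode additionally copies the rolling arrays
// into full matrices for inspection; the computation path is identical,
// so results agree bit-for-bit.
//
// Everything is templated on the scalar type: double (default) or float
// (the single-precision mode; loop energies are evaluated in double and
// rounded on entry, all array values and log-sums are 32-bit).

#include <Rcpp.h>
#include <vector>
#include "energy.h"

using namespace Rcpp;

static void parse_tabs(const List& tl, Tabs& tb) {
  NumericVector st = tl["stack"], hi = tl["hp_init"], hm = tl["hp_mm"],
                ii = tl["il_init"], im = tl["il_mm"], d3 = tl["d3"],
                d5 = tl["d5"], tm = tl["tmm"], cf = tl["cf"],
                c1 = tl["cm1"], c2 = tl["cm2"], abc = tl["abc"];
  for (int k = 0; k < 36; ++k) tb.stack[k] = st[k];
  tb.hp_init[0] = INF64;
  for (int k = 1; k <= 30; ++k) tb.hp_init[k] = hi[k - 1];
  for (int k = 0; k < 96; ++k) tb.hp_mm[k] = hm[k];
  tb.il_init[0] = INF64;
  for (int k = 1; k <= 30; ++k) tb.il_init[k] = ii[k - 1];
  for (int k = 0; k < 96; ++k) tb.il_mm[k] = im[k];
  for (int k = 0; k < 24; ++k) tb.d3[k] = d3[k];
  for (int k = 0; k < 24; ++k) tb.d5[k] = d5[k];
  for (int k = 0; k < 96; ++k) tb.tmm[k] = tm[k];
  for (int k = 0; k < 36; ++k) tb.cf[k] = cf[k];
  for (int k = 0; k < 36; ++k) tb.cm1[k] = c1[k];
  for (int k = 0; k < 36; ++k) tb.cm2[k] = c2[k];
  tb.a = abc[0]; tb.b = abc[1]; tb.c = abc[2];
  tb.RT = as<double>(tl["RT"]);
}

static void parse_cfg(const List& cl, Cfg& c) {
  c.cap = as<int>(cl["internal_loop_cap"]);
  c.minhp = as<int>(cl["min_hairpin"]);
  c.dangles = as<bool>(cl["dangles"]);
  c.mism = as<bool>(cl["terminal_mismatches"]);
  c.coax = as<bool>(cl["coaxial_stacking"]);
}

template <typename REAL>
struct Filler {
  int N;
  std::vector<int> seq;  // 1-based codes
  Tabs tb;
  Cfg cfg;
  EnergyModel em;
  REAL INFR;
  REAL ar, br, cr;  // multibranch constants

  std::vector<REAL> V, Y, YL, Zm, WQ, P;
  std::vector<REAL> W5, W3;             // indices 0..N and 1..N+1
  std::vector<REAL> W2[2], WL2[2], MBL2[2], MB5[5];
  bool debug;
  std::vector<REAL> Wd, WLd, MBLd, MBd;
  double tcount;
  REAL dG0;
  // Sparse indices of finite V entries (skipping +Inf operands is exact:
  // +Inf is the identity of the log-sum).  Row lists hold the k with
  // V(x,k) finite, column lists the k with V(k,y) finite; "I" lists hold
  // interior entries, "W" wrapped entries, all ascending in position.
  std::vector<std::vector<int> > VrowI, VrowW, VcolI, VcolW;

  Filler(const IntegerVector& codes, const List& tabs, const List& config,
         bool full_debug)
      : tcount(0) {
    N = codes.size();
    seq.resize(N + 1);
    for (int i = 0; i < N; ++i) seq[i + 1] = codes[i] - 1;  // R codes 1..4
    parse_tabs(tabs, tb);
    parse_cfg(config, cfg);
    em.tb = &tb; em.cfg = &cfg; em.s = seq.data(); em.N = N;
    INFR = std::numeric_limits<REAL>::infinity();
    ar = (REAL)tb.a; br = (REAL)tb.b; cr = (REAL)tb.c;
    size_t nn = (size_t)(N + 1) * (N + 1);
    V.assign(nn, INFR); Y.assign(nn, INFR); YL.assign(nn, INFR);
    Zm.assign(nn, INFR); WQ.assign(nn, INFR); P.assign(nn, (REAL)0);
    W5.assign(N + 2, (REAL)0); W3.assign(N + 3, (REAL)0);
    for (int k = 0; k < 2; ++k) {
      W2[k].assign(N + 2, INFR); WL2[k].assign(N + 2, INFR);
      MBL2[k].assign(N + 2, INFR);
    }
    for (int k = 0; k < 5; ++k) MB5[k].assign(N + 2, INFR);
    VrowI.resize(N + 1); VrowW.resize(N + 1);
    VcolI.resize(N + 1); VcolW.resize(N + 1);
    debug = full_debug;
    if (debug) {
      Wd.assign(nn, INFR); WLd.assign(nn, INFR);
      MBLd.assign(nn, INFR); MBd.assign(nn, INFR);
    }
    dG0 = (REAL)0;
  }

  inline size_t ix(int i, int j) const { return (size_t)i * (N + 1) + j; }

  // Stable two-operand log-sum: at most one exp call, log1p for
  // accuracy when the weights differ by orders of magnitude.
  inline REAL ls(REAL a, REAL b) const {
    if (a == INFR) return b;
    if (b == INFR) return a;
    if (a < b) return a - std::log1p(std::exp(a - b));
    if (b < a) return b - std::log1p(std::exp(b - a));
    return a - (REAL)0.693147180559945309417232121458;
  }

  void reset_rolling() {
    for (int k = 0; k < 2; ++k) {
      std::fill(W2[k].begin(), W2[k].end(), INFR);
      std::fill(WL2[k].begin(), WL2[k].end(), INFR);
      std::fill(MBL2[k].begin(), MBL2[k].end(), INFR);
    }
    for (int k = 0; k < 5; ++k) std::fill(MB5[k].begin(), MB5[k].end(), INFR);
  }

  // position of interior ordinal m (1..L-2) of fragment starting at i
  inline int pos(int i, int m) const {
    int x = i + m;
    return x <= N ? x : x - N;
  }

  // Exterior-loop assembly for wrapped fragment (i,j): the pair's two
  // flanking ends are free (W3'/W5' ensembles), with optional dangles /
  // terminal mismatch on the pair.  The open exterior loop carries no
  // coaxial stacking (see the methods vignette).
  REAL qext(int i, int j) {
    REAL acc = W3[i + 1] + W5[j - 1];
    if (cfg.dangles) {
      if (i + 1 <= N)
        acc = ls(acc, W3[i + 2] + W5[j - 1] + (REAL)em.eD3(i, j, i + 1));
      if (j - 1 >= 1)
        acc = ls(acc, W3[i + 1] + W5[j - 2] + (REAL)em.eD5(i, j, j - 1));
    }
    if (cfg.mism && i + 1 <= N && j - 1 >= 1)
      acc = ls(acc, W3[i + 2] + W5[j - 2] + (REAL)em.eTM(i, j, i + 1, j - 1));
    return acc;
  }

  // rolling W^MB read for sub-fragment of length Ls at 5' position x
  inline REAL mb_get(int Ls, int x) const { return MB5[Ls % 5][x]; }

  template <typename F>
  static inline void for_in(const std::vector<int>& lst, int lo, int hi, F f) {
    if (lo > hi || lst.empty()) return;
    std::vector<int>::const_iterator it =
        std::lower_bound(lst.begin(), lst.end(), lo);
    for (; it != lst.end() && *it <= hi; ++it) f(*it);
  }

  // visit finite V(x,k) / V(k,y) with k in ordinal interval [m1,m2] of the
  // parent fragment starting at i, in ascending ordinal (fold) order
  template <typename F>
  inline void row_query(int i, int m1, int m2, bool interior, int x, F f) const {
    if (m1 > m2) return;
    if (interior) {
      for_in(VrowI[x], i + m1, i + m2, f);
      return;
    }
    int sLo = i + m1, sHi = std::min(N, i + m2);
    int pLo = (i + m1 > N) ? i + m1 - N : 1;
    int pHi = (i + m2 > N) ? i + m2 - N : 0;
    for_in(VrowI[x], sLo, sHi, f);
    for_in(VrowW[x], pLo, pHi, f);
  }
  template <typename F>
  inline void col_query(int i, int m1, int m2, bool interior, int y, F f) const {
    if (m1 > m2) return;
    if (interior) {
      for_in(VcolI[y], i + m1, i + m2, f);
      return;
    }
    int sLo = i + m1, sHi = std::min(N, i + m2);
    int pLo = (i + m1 > N) ? i + m1 - N : 1;
    int pHi = (i + m2 > N) ? i + m2 - N : 0;
    for_in(VcolW[y], sLo, sHi, f);
    for_in(VcolI[y], pLo, pHi, f);
  }

  // Multibranch assembly Q^multibranch for fragment (i,j) of length L.
  // Identical for interior and wrapped fragments; raw position guards
  // (0 / N+1) implement the junction rules for wrapped fragments.
  REAL qmb(int i, int j, int L) {
    REAL acc = INFR;
    bool p3 = (i + 1 <= N), p33 = (i + 2 <= N);
    bool p5 = (j - 1 >= 1), p55 = (j - 2 >= 1);

    if (p3 && p5 && L >= 3) {
      REAL t = mb_get(L - 2, i + 1);
      if (t < INFR) acc = ls(acc, t + ar + cr);
    }
    if (cfg.dangles) {
      if (p33 && p5 && L >= 4) {
        REAL t = mb_get(L - 3, i + 2);
        if (t < INFR) acc = ls(acc, t + (REAL)em.eD3(i, j, i + 1) + ar + br + cr);
      }
      if (p3 && p55 && L >= 4) {
        REAL t = mb_get(L - 3, i + 1);
        if (t < INFR) acc = ls(acc, t + (REAL)em.eD5(i, j, j - 1) + ar + br + cr);
      }
    }
    if (cfg.mism && p33 && p55 && L >= 5) {
      REAL t = mb_get(L - 4, i + 2);
      if (t < INFR)
        acc = ls(acc, t + (REAL)em.eTM(i, j, i + 1, j - 1) + ar + (REAL)2 * br + cr);
    }
    if (!cfg.coax) return acc;
    int pJI = pidx_code(seq[j], seq[i]);     // closing pair as (j,i)
    const double* cfJ = &tb.cf[pJI * 6];
    const double* c1J = &tb.cm1[pJI * 6];
    const double* c2J = &tb.cm2[pJI * 6];
    const REAL cF = ar + (REAL)2 * cr;             // flush constants
    const REAL cM = ar + (REAL)2 * br + (REAL)2 * cr;
    bool interior = (i < j);

    // closing-pair coax with the first branch (3' side of i)
    if (p3 && p5) {
      int x = i + 1, y = j - 1;
      row_query(i, 2, L - 3, interior, x, [&](int k) {  // flush (i+1,k)
        if (k + 1 > N) return;
        REAL y1 = Y[ix(k + 1, y)];
        if (y1 == INFR) return;
        acc = ls(acc, V[ix(x, k)] + y1 +
                       (REAL)cfJ[pidx_code(seq[x], seq[k])] + cF);
      });
    }
    if (p33 && p5) {
      int x = i + 2, y = j - 1;
      row_query(i, 3, L - 4, interior, x, [&](int k) {  // mismatch(2)
        if (k + 2 > N) return;
        REAL y1 = Y[ix(k + 2, y)];
        if (y1 == INFR) return;
        acc = ls(acc, V[ix(x, k)] + y1 +
                       (REAL)c2J[pidx_code(seq[x], seq[k])] + cM);
      });
    }
    if (p33 && p55) {
      int x = i + 2, y = j - 2;
      row_query(i, 3, L - 4, interior, x, [&](int k) {  // mismatch(1)
        if (k + 1 > N) return;
        REAL y1 = Y[ix(k + 1, y)];
        if (y1 == INFR) return;
        acc = ls(acc, V[ix(x, k)] + y1 +
                       (REAL)c1J[pidx_code(seq[x], seq[k])] + cM);
      });
    }
    // closing-pair coax with the last branch (5' side of j)
    if (p3 && p5) {
      int y = j - 1;
      col_query(i, 2, L - 3, interior, y, [&](int k) {  // flush (k,j-1)
        if (k - 1 < 1) return;
        REAL y1 = Y[ix(i + 1, k - 1)];
        if (y1 == INFR) return;
        acc = ls(acc, V[ix(k, y)] + y1 +
                       (REAL)tb.cf[pidx_code(seq[k], seq[y]) * 6 + pJI] + cF);
      });
    }
    if (p3 && p55) {
      int y = j - 2;
      col_query(i, 3, L - 4, interior, y, [&](int k) {  // mismatch(1)
        if (k - 2 < 1) return;
        REAL y1 = Y[ix(i + 1, k - 2)];
        if (y1 == INFR) return;
        acc = ls(acc, V[ix(k, y)] + y1 +
                       (REAL)tb.cm1[pidx_code(seq[k], seq[y]) * 6 + pJI] + cM);
      });
    }
    if (p33 && p55) {
      int y = j - 2;
      col_query(i, 3, L - 4, interior, y, [&](int k) {  // mismatch(2)
        if (k - 1 < 1) return;
        REAL y1 = Y[ix(i + 2, k - 1)];
        if (y1 == INFR) return;
        acc = ls(acc, V[ix(k, y)] + y1 +
                       (REAL)tb.cm2[pidx_code(seq[k], seq[y]) * 6 + pJI] + cM);
      });
    }
    return acc;
  }

  void cellV(int i, int j, int L, bool interior) {
    REAL v = INFR;
    int p = pidx_code(seq[i], seq[j]);
    bool can = (p >= 0) && (!interior || (j - i - 1 >= cfg.minhp));
    if (can) {
      if (interior) {
        v = (REAL)em.eH(i, j);
        if (L >= 4) {
          REAL t = V[ix(i + 1, j - 1)];
          if (t < INFR) v = ls(v, t + (REAL)em.eS(i, j, i + 1, j - 1));
        }
        int smax = std::min(cfg.cap, L - 4);
        for (int n1 = 0; n1 <= smax; ++n1) {
          for (int n2 = (n1 == 0 ? 1 : 0); n1 + n2 <= smax; ++n2) {
            int ip = i + 1 + n1, jp = j - 1 - n2;
            REAL t = V[ix(ip, jp)];
            if (t < INFR) v = ls(v, t + (REAL)em.eIL(i, j, ip, jp, n1, n2));
          }
        }
      } else {
        v = qext(i, j);
        if (i < N && j > 1) {
          REAL t = V[ix(i + 1, j - 1)];
          // interior-orientation lookup of the same physical stack
          if (t < INFR) v = ls(v, t + (REAL)em.eS(j - 1, i + 1, j, i));
        }
        int A = std::min(cfg.cap, N - i - 1), B = j - 2;
        if (A >= 0 && B >= 0) {
          for (int n1 = 0; n1 <= A; ++n1) {
            int n2max = std::min(cfg.cap - n1, B);
            for (int n2 = (n1 == 0 ? 1 : 0); n2 <= n2max; ++n2) {
              int ip = i + 1 + n1, jp = j - 1 - n2;
              REAL t = V[ix(ip, jp)];
              if (t < INFR) v = ls(v, t + (REAL)em.eIL(i, j, ip, jp, n1, n2));
            }
          }
        }
      }
      REAL m = qmb(i, j, L);
      if (m < INFR) v = ls(v, m);
    }
    V[ix(i, j)] = v;
  }

  void cellW(int i, int j, int L, bool interior) {
    REAL vij = V[ix(i, j)];

    // W^coax: a coaxed pair of helices spanning exactly i..j
    REAL wc = INFR;
    if (cfg.coax) {
      bool intr = (i < j);
      const REAL c2 = (REAL)2 * cr;
      const REAL c2b2 = (REAL)2 * br + (REAL)2 * cr;
      row_query(i, 1, L - 3, intr, i, [&](int k) {  // flush split at k | k+1
        if (k + 1 > N) return;
        REAL v2 = V[ix(k + 1, j)];
        if (v2 == INFR) return;
        wc = ls(wc, V[ix(i, k)] + v2 +
                     (REAL)tb.cf[pidx_code(seq[i], seq[k]) * 6 +
                                 pidx_code(seq[k + 1], seq[j])] + c2);
      });
      if (i + 1 <= N) {
        row_query(i, 2, L - 4, intr, i + 1, [&](int k) {  // mm1: consumes k+1, i
          if (k + 2 > N) return;
          REAL v2 = V[ix(k + 2, j)];
          if (v2 == INFR) return;
          wc = ls(wc, V[ix(i + 1, k)] + v2 +
                       (REAL)tb.cm1[pidx_code(seq[i + 1], seq[k]) * 6 +
                                    pidx_code(seq[k + 2], seq[j])] + c2b2);
        });
      }
      if (j - 1 >= 1) {
        row_query(i, 1, L - 5, intr, i, [&](int k) {  // mm2: consumes k+1, j
          if (k + 2 > N) return;
          REAL v2 = V[ix(k + 2, j - 1)];
          if (v2 == INFR) return;
          wc = ls(wc, V[ix(i, k)] + v2 +
                       (REAL)tb.cm2[pidx_code(seq[i], seq[k]) * 6 +
                                    pidx_code(seq[k + 2], seq[j - 1])] + c2b2);
        });
      }
    }

    // W^L: one branch unit, anchored at i (leading unpaired strips pay b)
    REAL wl = INFR;
    if (i + 1 <= N && L >= 2) {
      REAL t = WL2[(L - 1) % 2][i + 1];
      if (t < INFR) wl = t + br;
    }
    if (vij < INFR) wl = ls(wl, vij + cr);
    if (cfg.dangles) {
      if (j - 1 >= 1 && L >= 3) {
        REAL t = V[ix(i, j - 1)];
        if (t < INFR) wl = ls(wl, t + (REAL)em.eD3(j - 1, i, j) + br + cr);
      }
      if (i + 1 <= N && L >= 3) {
        REAL t = V[ix(i + 1, j)];
        if (t < INFR) wl = ls(wl, t + (REAL)em.eD5(j, i + 1, i) + br + cr);
      }
    }
    if (cfg.mism && i + 1 <= N && j - 1 >= 1 && L >= 4) {
      REAL t = V[ix(i + 1, j - 1)];
      if (t < INFR)
        wl = ls(wl, t + (REAL)em.eTM(j - 1, i + 1, j, i) + (REAL)2 * br + cr);
    }

    // W^Q (interior only): the same four alternatives without b/c costs
    if (interior) {
      REAL wq = vij;
      if (cfg.dangles) {
        if (L >= 3) {
          REAL t = V[ix(i, j - 1)];
          if (t < INFR) wq = ls(wq, t + (REAL)em.eD3(j - 1, i, j));
          t = V[ix(i + 1, j)];
          if (t < INFR) wq = ls(wq, t + (REAL)em.eD5(j, i + 1, i));
        }
      }
      if (cfg.mism && L >= 4) {
        REAL t = V[ix(i + 1, j - 1)];
        if (t < INFR) wq = ls(wq, t + (REAL)em.eTM(j - 1, i + 1, j, i));
      }
      WQ[ix(i, j)] = wq;
    }

    // W: trailing unpaired strips
    REAL w = INFR;
    if (j - 1 >= 1 && L >= 2) {
      REAL t = W2[(L - 1) % 2][i];
      if (t < INFR) w = t + br;
    }
    w = ls(w, wl);

    // Z: W^coax plus the anchored (non-strip) W^L alternatives
    REAL z = wc;
    if (vij < INFR) z = ls(z, vij + cr);
    if (cfg.dangles) {
      if (j - 1 >= 1 && L >= 3) {
        REAL t = V[ix(i, j - 1)];
        if (t < INFR) z = ls(z, t + (REAL)em.eD3(j - 1, i, j) + br + cr);
      }
      if (i + 1 <= N && L >= 3) {
        REAL t = V[ix(i + 1, j)];
        if (t < INFR) z = ls(z, t + (REAL)em.eD5(j, i + 1, i) + br + cr);
      }
    }
    if (cfg.mism && i + 1 <= N && j - 1 >= 1 && L >= 4) {
      REAL t = V[ix(i + 1, j - 1)];
      if (t < INFR)
        z = ls(z, t + (REAL)em.eTM(j - 1, i + 1, j, i) + (REAL)2 * br + cr);
    }

    // W^MBL: two or more branch units, anchored at i
    REAL mbl = INFR;
    if (i + 1 <= N && L >= 2) {
      REAL t = MBL2[(L - 1) % 2][i + 1];
      if (t < INFR) mbl = t + br;      // leading unpaired base pays b
    }
    mbl = ls(mbl, wc);
    for (int m = 1; m <= L - 2; ++m) {  // first unit Z(i,k), rest Y^L(k+1,j)
      int k = pos(i, m);
      if (k + 1 > N) continue;
      REAL zz = Zm[ix(i, k)];
      if (zz == INFR) continue;
      REAL yy = YL[ix(k + 1, j)];
      if (yy == INFR) continue;
      mbl = ls(mbl, zz + yy);
    }

    // W^MB: trailing unpaired strips
    REAL mb = INFR;
    if (j - 1 >= 1 && L >= 2) {
      REAL t = MB5[(L - 1) % 5][i];
      if (t < INFR) mb = t + br;
    }
    mb = ls(mb, mbl);

    W2[L % 2][i] = w; WL2[L % 2][i] = wl;
    MBL2[L % 2][i] = mbl; MB5[L % 5][i] = mb;
    Y[ix(i, j)] = ls(w, mb);
    YL[ix(i, j)] = ls(wl, mbl);
    Zm[ix(i, j)] = z;
    if (debug) {
      Wd[ix(i, j)] = w; WLd[ix(i, j)] = wl;
      MBLd[ix(i, j)] = mbl; MBd[ix(i, j)] = mb;
    }
  }

  void pass(bool interior) {
    reset_rolling();
    for (int L = 2; L <= N; ++L) {
      if (interior) {
        for (int i = 1; i + L - 1 <= N; ++i) {
          int j = i + L - 1;
          tcount += cnt_ksums(L, cfg) + cnt_int_interior(L, cfg);
          cellV(i, j, L, true);
          cellW(i, j, L, true);
        }
        for (int i = 1; i + L - 1 <= N; ++i) {   // index the new diagonal
          int j = i + L - 1;
          if (V[ix(i, j)] < INFR) {
            VrowI[i].push_back(j);                       // ascending j
            VcolI[j].insert(VcolI[j].begin(), i);        // ascending i
          }
        }
      } else {
        for (int jj = 1; jj <= L - 1; ++jj) {
          int i = jj + N + 1 - L;
          tcount += cnt_ksums(L, cfg) + cnt_int_wrapped(i, jj, N, cfg);
          cellV(i, jj, L, false);
          cellW(i, jj, L, false);
        }
        for (int jj = 1; jj <= L - 1; ++jj) {
          int i = jj + N + 1 - L;
          if (V[ix(i, jj)] < INFR) {
            VrowW[i].push_back(jj);                      // ascending j
            VcolW[jj].insert(VcolW[jj].begin(), i);      // ascending i
          }
        }
      }
    }
  }

  void prefix_suffix() {
    W5[0] = (REAL)0;
    for (int i = 1; i <= N; ++i) {
      REAL acc = W5[i - 1];
      for (int j = 1; j <= i - 1; ++j) {
        REAL q = WQ[ix(j, i)];
        if (q < INFR) acc = ls(acc, W5[j - 1] + q);
      }
      W5[i] = acc;
    }
    W3[N + 1] = (REAL)0;
    for (int i = N; i >= 1; --i) {
      REAL acc = W3[i + 1];
      for (int j = i + 1; j <= N; ++j) {
        REAL q = WQ[ix(i, j)];
        if (q < INFR) acc = ls(acc, W3[j + 1] + q);
      }
      W3[i] = acc;
    }
    tcount += (double)N * (N - 1);
  }

  // pair probabilities p_ij = w(V_ij + V_ji - dG0), clipped to [0,1]
  void probabilities(bool check) {
    dG0 = W5[N];
    for (int i = 1; i <= N; ++i) {
      for (int j = i + 1; j <= N; ++j) {
        REAL vi = V[ix(i, j)], ve = V[ix(j, i)];
        REAL p = (REAL)0;
        if (vi < INFR && ve < INFR) {
          p = std::exp(-(vi + ve - dG0));
          if (check && p > (REAL)(1 + 1e-6))
            stop("internal consistency error: p(%d,%d) = %g exceeds 1", i, j,
                 (double)p);
          if (p > (REAL)1) p = (REAL)1;
          if (p < (REAL)0) p = (REAL)0;
        }
        P[ix(i, j)] = p;
      }
    }
  }

  List result(int stage) {
    double RT = tb.RT;
    auto mat = [&](const std::vector<REAL>& M) {
      NumericMatrix out(N, N);
      for (int i = 1; i <= N; ++i)
        for (int j = 1; j <= N; ++j)
          out(i - 1, j - 1) = (double)M[ix(i, j)] * RT;
      return out;
    };
    List res = List::create(
        _["N"] = N,
        _["V"] = mat(V), _["WQ"] = mat(WQ), _["Y"] = mat(Y),
        _["YL"] = mat(YL), _["Z"] = mat(Zm),
        _["term_count"] = tcount);
    if (stage >= 2) {
      NumericVector w5(N + 1), w3(N + 1);
      for (int i = 0; i <= N; ++i) w5[i] = (double)W5[i] * RT;       // 0..N
      for (int i = 1; i <= N + 1; ++i) w3[i - 1] = (double)W3[i] * RT;  // 1..N+1
      res["W5"] = w5; res["W3"] = w3;
      res["dG0"] = (double)W5[N] * RT;
    }
    if (stage >= 3) {
      NumericMatrix pm(N, N);
      for (int i = 1; i <= N; ++i)
        for (int j = 1; j <= N; ++j) pm(i - 1, j - 1) = (double)P[ix(i, j)];
      res["prob"] = pm;
    }
    if (debug) {
      res["W"] = mat(Wd); res["WL"] = mat(WLd);
      res["WMBL"] = mat(MBLd); res["WMB"] = mat(MBd);
    }
    return res;
  }

  List run(int stage, bool check_probs) {
    pass(true);
    if (stage >= 2) prefix_suffix();
    if (stage >= 3) {
      pass(false);
      probabilities(check_probs);
    }
    return result(stage);
  }
};

// [[Rcpp::export(name = ".cpp_fold")]]
List cpp_fold(IntegerVector codes, List tabs, List config, int stage,
              bool full_debug, bool single_precision) {
  if (single_precision) {
    Filler<float> f(codes, tabs, config, full_debug);
    return f.run(stage, false);
  }
  Filler<double> f(codes, tabs, config, full_debug);
  return f.run(stage, true);
}
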