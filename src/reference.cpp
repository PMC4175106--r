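// Naive weight-space reference dynamic program.
//
// The same recursions as the log-space fill, evaluated directly on
// Boltzmann weights (no logarithms, no scaling factors) with every array
// (V, W, W^L, W^MB, W^MBL, W^coax, W^Q, Y, Y^L, Z) stored as a full NxN
// matrix: ten full-array equivalents of persistent O(N^2) storage versus
// the production scheme's 4.5.  Usable only while 64-bit weights do not
// overflow (an error otherwise), which is the documented limitation that
// motivates the log-space design.  In weight space an absent/empty
// region is simply weight 0, so unwritten entries need no sentinel.

#include <Rcpp.h>
#include <vector>
#include "energy.h"

using namespace Rcpp;

static void parse_tabs_ref(const List& tl, Tabs& tb) {
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

static void parse_cfg_ref(const List& cl, Cfg& c) {
  c.cap = as<int>(cl["internal_loop_cap"]);
  c.minhp = as<int>(cl["min_hairpin"]);
  c.dangles = as<bool>(cl["dangles"]);
  c.mism = as<bool>(cl["terminal_mismatches"]);
  c.coax = as<bool>(cl["coaxial_stacking"]);
}

struct RefDP {
  int N;
  std::vector<int> seq;
  Tabs tb;
  Cfg cfg;
  EnergyModel em;
  double wa, wb, wc_;  // weights of the multibranch constants

  std::vector<double> V, W, WL, MB, MBL, WC, WQ, Y, YL, Z, P;
  std::vector<double> W5, W3;

  RefDP(const IntegerVector& codes, const List& tabs, const List& config) {
    N = codes.size();
    seq.resize(N + 1);
    for (int i = 0; i < N; ++i) seq[i + 1] = codes[i] - 1;
    parse_tabs_ref(tabs, tb);
    parse_cfg_ref(config, cfg);
    em.tb = &tb; em.cfg = &cfg; em.s = seq.data(); em.N = N;
    wa = std::exp(-tb.a); wb = std::exp(-tb.b); wc_ = std::exp(-tb.c);
    size_t nn = (size_t)(N + 1) * (N + 1);
    V.assign(nn, 0); W.assign(nn, 0); WL.assign(nn, 0); MB.assign(nn, 0);
    MBL.assign(nn, 0); WC.assign(nn, 0); WQ.assign(nn, 0); Y.assign(nn, 0);
    YL.assign(nn, 0); Z.assign(nn, 0); P.assign(nn, 0);
    W5.assign(N + 2, 0); W3.assign(N + 3, 0);
  }

  inline size_t ix(int i, int j) const { return (size_t)i * (N + 1) + j; }
  inline double wg(double e) const { return std::exp(-e); }
  inline int pos(int i, int m) const {
    int x = i + m;
    return x <= N ? x : x - N;
  }

  double qext(int i, int j) {
    double acc = W3[i + 1] * W5[j - 1];
    if (cfg.dangles) {
      if (i + 1 <= N) acc += W3[i + 2] * W5[j - 1] * wg(em.eD3(i, j, i + 1));
      if (j - 1 >= 1) acc += W3[i + 1] * W5[j - 2] * wg(em.eD5(i, j, j - 1));
    }
    if (cfg.mism && i + 1 <= N && j - 1 >= 1)
      acc += W3[i + 2] * W5[j - 2] * wg(em.eTM(i, j, i + 1, j - 1));
    return acc;
  }

  double qmb(int i, int j, int L) {
    double acc = 0;
    bool p3 = (i + 1 <= N), p33 = (i + 2 <= N);
    bool p5 = (j - 1 >= 1), p55 = (j - 2 >= 1);
    if (p3 && p5 && L >= 3) acc += MB[ix(i + 1, j - 1)] * wa * wc_;
    if (cfg.dangles) {
      if (p33 && p5 && L >= 4)
        acc += MB[ix(i + 2, j - 1)] * wg(em.eD3(i, j, i + 1)) * wa * wb * wc_;
      if (p3 && p55 && L >= 4)
        acc += MB[ix(i + 1, j - 2)] * wg(em.eD5(i, j, j - 1)) * wa * wb * wc_;
    }
    if (cfg.mism && p33 && p55 && L >= 5)
      acc += MB[ix(i + 2, j - 2)] * wg(em.eTM(i, j, i + 1, j - 1)) *
             wa * wb * wb * wc_;
    if (!cfg.coax) return acc;
    // index bounds mirror the log-space fill exactly (the ordinal ranges
    // that keep every reference inside the parent fragment)
    if (p3 && p5)
      for (int m = 2; m <= L - 3; ++m) {
        int k = pos(i, m);
        if (k + 1 > N) continue;
        acc += V[ix(i + 1, k)] * Y[ix(k + 1, j - 1)] *
               wg(em.eCF(j, i, i + 1, k)) * wa * wc_ * wc_;
      }
    if (p33 && p5)
      for (int m = 3; m <= L - 4; ++m) {
        int k = pos(i, m);
        if (k + 2 > N) continue;
        acc += V[ix(i + 2, k)] * Y[ix(k + 2, j - 1)] *
               wg(em.eCM2(j, i, i + 2, k)) * wa * wb * wb * wc_ * wc_;
      }
    if (p33 && p55)
      for (int m = 3; m <= L - 4; ++m) {
        int k = pos(i, m);
        if (k + 1 > N) continue;
        acc += V[ix(i + 2, k)] * Y[ix(k + 1, j - 2)] *
               wg(em.eCM1(j, i, i + 2, k)) * wa * wb * wb * wc_ * wc_;
      }
    if (p3 && p5)
      for (int m = 2; m <= L - 3; ++m) {
        int k = pos(i, m);
        if (k - 1 < 1) continue;
        acc += V[ix(k, j - 1)] * Y[ix(i + 1, k - 1)] *
               wg(em.eCF(k, j - 1, j, i)) * wa * wc_ * wc_;
      }
    if (p3 && p55)
      for (int m = 3; m <= L - 4; ++m) {
        int k = pos(i, m);
        if (k - 2 < 1) continue;
        acc += V[ix(k, j - 2)] * Y[ix(i + 1, k - 2)] *
               wg(em.eCM1(k, j - 2, j, i)) * wa * wb * wb * wc_ * wc_;
      }
    if (p33 && p55)
      for (int m = 3; m <= L - 4; ++m) {
        int k = pos(i, m);
        if (k - 1 < 1) continue;
        acc += V[ix(k, j - 2)] * Y[ix(i + 2, k - 1)] *
               wg(em.eCM2(k, j - 2, j, i)) * wa * wb * wb * wc_ * wc_;
      }
    return acc;
  }

  void cell(int i, int j, int L, bool interior) {
    int p = pidx_code(seq[i], seq[j]);
    bool can = (p >= 0) && (!interior || (j - i - 1 >= cfg.minhp));
    double v = 0;
    if (can) {
      if (interior) {
        v = wg(em.eH(i, j));
        if (L >= 4) v += V[ix(i + 1, j - 1)] * wg(em.eS(i, j, i + 1, j - 1));
        int smax = std::min(cfg.cap, L - 4);
        for (int n1 = 0; n1 <= smax; ++n1)
          for (int n2 = (n1 == 0 ? 1 : 0); n1 + n2 <= smax; ++n2) {
            int ip = i + 1 + n1, jp = j - 1 - n2;
            v += V[ix(ip, jp)] * wg(em.eIL(i, j, ip, jp, n1, n2));
          }
      } else {
        v = qext(i, j);
        if (i < N && j > 1)
          v += V[ix(i + 1, j - 1)] * wg(em.eS(j - 1, i + 1, j, i));
        int A = std::min(cfg.cap, N - i - 1), B = j - 2;
        if (A >= 0 && B >= 0)
          for (int n1 = 0; n1 <= A; ++n1) {
            int n2max = std::min(cfg.cap - n1, B);
            for (int n2 = (n1 == 0 ? 1 : 0); n2 <= n2max; ++n2) {
              int ip = i + 1 + n1, jp = j - 1 - n2;
              v += V[ix(ip, jp)] * wg(em.eIL(i, j, ip, jp, n1, n2));
            }
          }
      }
      v += qmb(i, j, L);
    }
    V[ix(i, j)] = v;
    double vij = v;

    double wcx = 0;
    if (cfg.coax) {
      for (int m = 1; m <= L - 3; ++m) {
        int k = pos(i, m);
        if (k + 1 > N) continue;
        wcx += V[ix(i, k)] * V[ix(k + 1, j)] *
               wg(em.eCF(i, k, k + 1, j)) * wc_ * wc_;
      }
      if (i + 1 <= N)
        for (int m = 2; m <= L - 4; ++m) {
          int k = pos(i, m);
          if (k + 2 > N) continue;
          wcx += V[ix(i + 1, k)] * V[ix(k + 2, j)] *
                 wg(em.eCM1(i + 1, k, k + 2, j)) * wb * wb * wc_ * wc_;
        }
      if (j - 1 >= 1)
        for (int m = 1; m <= L - 5; ++m) {
          int k = pos(i, m);
          if (k + 2 > N) continue;
          wcx += V[ix(i, k)] * V[ix(k + 2, j - 1)] *
                 wg(em.eCM2(i, k, k + 2, j - 1)) * wb * wb * wc_ * wc_;
        }
    }
    WC[ix(i, j)] = wcx;

    double wl = 0;
    if (i + 1 <= N) wl += WL[ix(i + 1, j)] * wb;
    wl += vij * wc_;
    if (cfg.dangles) {
      if (j - 1 >= 1 && L >= 3)
        wl += V[ix(i, j - 1)] * wg(em.eD3(j - 1, i, j)) * wb * wc_;
      if (i + 1 <= N && L >= 3)
        wl += V[ix(i + 1, j)] * wg(em.eD5(j, i + 1, i)) * wb * wc_;
    }
    if (cfg.mism && i + 1 <= N && j - 1 >= 1 && L >= 4)
      wl += V[ix(i + 1, j - 1)] * wg(em.eTM(j - 1, i + 1, j, i)) * wb * wb * wc_;
    WL[ix(i, j)] = wl;

    if (interior) {
      double wq = vij;
      if (cfg.dangles && L >= 3) {
        wq += V[ix(i, j - 1)] * wg(em.eD3(j - 1, i, j));
        wq += V[ix(i + 1, j)] * wg(em.eD5(j, i + 1, i));
      }
      if (cfg.mism && L >= 4)
        wq += V[ix(i + 1, j - 1)] * wg(em.eTM(j - 1, i + 1, j, i));
      WQ[ix(i, j)] = wq;
    }

    double w = wl;
    if (j - 1 >= 1) w += W[ix(i, j - 1)] * wb;
    W[ix(i, j)] = w;

    double z = wcx + vij * wc_;
    if (cfg.dangles) {
      if (j - 1 >= 1 && L >= 3)
        z += V[ix(i, j - 1)] * wg(em.eD3(j - 1, i, j)) * wb * wc_;
      if (i + 1 <= N && L >= 3)
        z += V[ix(i + 1, j)] * wg(em.eD5(j, i + 1, i)) * wb * wc_;
    }
    if (cfg.mism && i + 1 <= N && j - 1 >= 1 && L >= 4)
      z += V[ix(i + 1, j - 1)] * wg(em.eTM(j - 1, i + 1, j, i)) * wb * wb * wc_;
    Z[ix(i, j)] = z;

    double mbl = wcx;
    if (i + 1 <= N) mbl += MBL[ix(i + 1, j)] * wb;
    for (int m = 1; m <= L - 2; ++m) {
      int k = pos(i, m);
      if (k + 1 > N) continue;
      mbl += Z[ix(i, k)] * YL[ix(k + 1, j)];
    }
    MBL[ix(i, j)] = mbl;

    double mb = mbl;
    if (j - 1 >= 1) mb += MB[ix(i, j - 1)] * wb;
    MB[ix(i, j)] = mb;

    Y[ix(i, j)] = w + mb;
    YL[ix(i, j)] = wl + mbl;
  }

  void run() {
    for (int L = 2; L <= N; ++L)
      for (int i = 1; i + L - 1 <= N; ++i) cell(i, i + L - 1, L, true);
    W5[0] = 1;
    for (int i = 1; i <= N; ++i) {
      double acc = W5[i - 1];
      for (int j = 1; j <= i - 1; ++j) acc += W5[j - 1] * WQ[ix(j, i)];
      W5[i] = acc;
    }
    W3[N + 1] = 1;
    for (int i = N; i >= 1; --i) {
      double acc = W3[i + 1];
      for (int j = i + 1; j <= N; ++j) acc += W3[j + 1] * WQ[ix(i, j)];
      W3[i] = acc;
    }
    for (int L = 2; L <= N; ++L)
      for (int jj = 1; jj <= L - 1; ++jj) cell(jj + N + 1 - L, jj, L, false);

    double Zt = W5[N];
    if (!std::isfinite(Zt) || Zt <= 0)
      stop("weight-space overflow: the naive reference DP cannot represent this ensemble in 64-bit weights (use the log-space fill)");
    for (size_t k = 0; k < V.size(); ++k)
      if (!std::isfinite(V[k]))
        stop("weight-space overflow in the reference DP arrays");
    for (int i = 1; i <= N; ++i)
      for (int j = i + 1; j <= N; ++j) {
        double pr = V[ix(i, j)] * V[ix(j, i)] / Zt;
        if (pr > 1 + 1e-6)
          stop("internal consistency error in reference DP: p(%d,%d) = %g", i, j, pr);
        P[ix(i, j)] = std::min(1.0, std::max(0.0, pr));
      }
  }

  List result() {
    double RT = tb.RT;
    NumericMatrix pv(N, N), vv(N, N);
    for (int i = 1; i <= N; ++i)
      for (int j = 1; j <= N; ++j) {
        pv(i - 1, j - 1) = P[ix(i, j)];
        vv(i - 1, j - 1) = V[ix(i, j)];  // weights, not energies
      }
    double Zt = W5[N];
    return List::create(
        _["N"] = N, _["Z"] = Zt, _["dG0"] = -RT * std::log(Zt),
        _["prob"] = pv, _["V_weight"] = vv,
        _["storage_equivalents"] = 10.0);
  }
};

// [[Rcpp::export(name = ".cpp_reference_dp")]]
List cpp_reference_dp(IntegerVector codes, List tabs, List config) {
  RefDP r(codes, tabs, config);
  r.run();
  return r.result();
}
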