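#include <Rcpp.h>
#include <vector>
#include <string>
#include "energy.h"

using namespace Rcpp;
using namespace rnt1;

// Minimum-free-energy secondary structure by a Zuker-style dynamic program
// over the simplified nearest-neighbor model in energy.h. Pseudoknot-free;
// pairs are WC, G-U wobble and A-C (surcharged). The recursion is exact for
// the structural energy model: every loop closed by a pair is scored as a
// hairpin, a stack/interior/bulge, or a multiloop.

static const double INF = 1e9;

struct FoldDP {
  int n;
  std::vector<int> s;                 // base codes
  std::vector<std::vector<double> > V, WM;
  std::vector<double> W;

  double pair_extra(int pc) const { return is_ac_pair(pc) ? AC_SURCHARGE : 0.0; }

  void run(const std::string &seq) {
    n = (int)seq.size();
    s.resize(n);
    for (int i = 0; i < n; ++i) s[i] = base_code(seq[i]);
    V.assign(n, std::vector<double>(n, INF));
    WM.assign(n, std::vector<double>(n, INF));
    for (int j = 0; j < n; ++j) {
      for (int i = j; i >= 0; --i) {
        computeV(i, j);
        computeWM(i, j);
      }
    }
    W.assign(n + 1, 0.0);
    for (int j = 1; j <= n; ++j) {
      W[j] = W[j - 1];
      for (int i = 1; i <= j; ++i) {
        double v = V[i - 1][j - 1];
        if (v < INF / 2 && W[i - 1] + v < W[j]) W[j] = W[i - 1] + v;
      }
    }
  }

  void computeV(int i, int j) {
    if (j - i - 1 < MIN_HAIRPIN) return;
    int pc = pair_code(s[i], s[j]);
    if (pc < 0) return;
    double best = hairpin_energy(j - i - 1);
    // stack / interior / bulge to a single inner pair (ip, jp)
    for (int ip = i + 1; ip < j; ++ip) {
      for (int jp = j - 1; jp > ip; --jp) {
        if (V[ip][jp] >= INF / 2) continue;
        int u = (ip - i - 1) + (j - jp - 1);
        double e;
        if (u == 0) {
          int pin = pair_code(s[ip], s[jp]);
          e = stack_energy(pc, pin) + V[ip][jp];
        } else {
          e = interior_energy(u) + V[ip][jp];
        }
        if (e < best) best = e;
      }
    }
    // multiloop: >= 2 branches inside
    for (int k = i + 2; k <= j - 2; ++k) {
      if (WM[i + 1][k - 1] >= INF / 2 || WM[k][j - 1] >= INF / 2) continue;
      double e = ML_CLOSE + WM[i + 1][k - 1] + WM[k][j - 1];
      if (e < best) best = e;
    }
    V[i][j] = best + pair_extra(pc);
  }

  void computeWM(int i, int j) {
    if (i > j) return;
    double best = INF;
    if (V[i][j] < INF / 2) best = V[i][j] + ML_BRANCH;
    if (i + 1 <= j && WM[i + 1][j] < INF / 2)
      best = std::min(best, WM[i + 1][j] + ML_UNPAIRED);
    if (i <= j - 1 && WM[i][j - 1] < INF / 2)
      best = std::min(best, WM[i][j - 1] + ML_UNPAIRED);
    for (int k = i + 1; k <= j; ++k) {
      if (WM[i][k - 1] < INF / 2 && WM[k][j] < INF / 2)
        best = std::min(best, WM[i][k - 1] + WM[k][j]);
    }
    WM[i][j] = best;
  }

  // --- traceback -----------------------------------------------------------
  std::vector<int> pairOf;  // 0-based partner or -1

  void traceV(int i, int j) {
    pairOf[i] = j; pairOf[j] = i;
    int pc = pair_code(s[i], s[j]);
    double target = V[i][j] - pair_extra(pc);
    const double eps = 1e-7;
    if (std::fabs(target - hairpin_energy(j - i - 1)) < eps) return;
    for (int ip = i + 1; ip < j; ++ip) {
      for (int jp = j - 1; jp > ip; --jp) {
        if (V[ip][jp] >= INF / 2) continue;
        int u = (ip - i - 1) + (j - jp - 1);
        double e;
        if (u == 0) {
          int pin = pair_code(s[ip], s[jp]);
          e = stack_energy(pc, pin) + V[ip][jp];
        } else {
          e = interior_energy(u) + V[ip][jp];
        }
        if (std::fabs(target - e) < eps) { traceV(ip, jp); return; }
      }
    }
    for (int k = i + 2; k <= j - 2; ++k) {
      if (WM[i + 1][k - 1] >= INF / 2 || WM[k][j - 1] >= INF / 2) continue;
      double e = ML_CLOSE + WM[i + 1][k - 1] + WM[k][j - 1];
      if (std::fabs(target - e) < eps) {
        traceWM(i + 1, k - 1);
        traceWM(k, j - 1);
        return;
      }
    }
  }

  void traceWM(int i, int j) {
    if (i > j || WM[i][j] >= INF / 2) return;
    const double eps = 1e-7;
    double t = WM[i][j];
    if (V[i][j] < INF / 2 && std::fabs(t - (V[i][j] + ML_BRANCH)) < eps) {
      traceV(i, j); return;
    }
    if (i + 1 <= j && WM[i + 1][j] < INF / 2 &&
        std::fabs(t - (WM[i + 1][j] + ML_UNPAIRED)) < eps) {
      traceWM(i + 1, j); return;
    }
    if (i <= j - 1 && WM[i][j - 1] < INF / 2 &&
        std::fabs(t - (WM[i][j - 1] + ML_UNPAIRED)) < eps) {
      traceWM(i, j - 1); return;
    }
    for (int k = i + 1; k <= j; ++k) {
      if (WM[i][k - 1] < INF / 2 && WM[k][j] < INF / 2 &&
          std::fabs(t - (WM[i][k - 1] + WM[k][j])) < eps) {
        traceWM(i, k - 1); traceWM(k, j); return;
      }
    }
  }

  void traceback() {
    pairOf.assign(n, -1);
    const double eps = 1e-7;
    int j = n;
    while (j >= 1) {
      if (std::fabs(W[j] - W[j - 1]) < eps) { --j; continue; }
      bool found = false;
      // prefer the leftmost i so that the leftmost differing position pairs
      for (int i = 1; i <= j && !found; ++i) {
        double v = V[i - 1][j - 1];
        if (v < INF / 2 && std::fabs(W[j] - (W[i - 1] + v)) < eps) {
          traceV(i - 1, j - 1);
          j = i - 1;
          found = true;
        }
      }
      if (!found) --j;
    }
  }
};

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq) {
  FoldDP dp;
  dp.run(seq);
  double mfe = dp.n > 0 ? dp.W[dp.n] : 0.0;
  dp.traceback();
  std::string db(dp.n, '.');
  IntegerVector partner(dp.n, NA_INTEGER);
  for (int i = 0; i < dp.n; ++i) {
    if (dp.pairOf[i] >= 0) {
      db[i] = (dp.pairOf[i] > i) ? '(' : ')';
      partner[i] = dp.pairOf[i] + 1;  // 1-based
    }
  }
  return List::create(_["dG"] = mfe, _["structure"] = db,
                      _["partner"] = partner);
}

// Energy of one explicitly given structure under the same model; used by the
// scan kernel and exposed for cross-checking DP results from R.
// [[Rcpp::export(name = ".structure_energy_cpp")]]
double structure_energy_cpp(std::string seq, IntegerVector partner) {
  int n = (int)seq.size();
  std::vector<int> s(n), p(n, -1);
  for (int i = 0; i < n; ++i) {
    s[i] = base_code(seq[i]);
    if (partner[i] != NA_INTEGER) p[i] = partner[i] - 1;
  }
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = p[i];
    if (j <= i) continue;  // each pair once, i < j
    int pc = pair_code(s[i], s[j]);
    if (pc < 0) return NA_REAL;
    if (is_ac_pair(pc)) e += AC_SURCHARGE;
    // classify the loop closed by (i,j): collect directly enclosed pairs
    int unpaired = 0, branches = 0;
    int firstIp = -1, firstJp = -1;
    for (int k = i + 1; k < j; ++k) {
      if (p[k] > k && p[k] < j) {
        ++branches;
        if (branches == 1) { firstIp = k; firstJp = p[k]; }
        k = p[k];
      } else if (p[k] == -1) {
        ++unpaired;
      }
    }
    if (branches == 0) {
      e += hairpin_energy(unpaired);
    } else if (branches == 1) {
      if (unpaired == 0) {
        e += stack_energy(pc, pair_code(s[firstIp], s[firstJp]));
      } else {
        e += interior_energy(unpaired);
      }
    } else {
      e += ML_CLOSE + ML_UNPAIRED * unpaired + ML_BRANCH * branches;
    }
  }
  return e;
}
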