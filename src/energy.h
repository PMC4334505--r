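#ifndef RNT1SCAN_ENERGY_H
#define RNT1SCAN_ENERGY_H

#include <cmath>
#include <string>

// Simplified nearest-neighbor free-energy model (kcal/mol, 37 C) used by the
// folding DP, the enumeration kernel and the R-level oracle. Pairs: the four
// Watson-Crick pairs, the G-U wobble, and the non-canonical A-C pair (with a
// destabilizing surcharge).

namespace rnt1 {

// base encoding: A=0, C=1, G=2, U/T=3, other=-1
inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

// pair encoding: CG=0 GC=1 GU=2 UG=3 AU=4 UA=5 AC=6 CA=7, -1 = not a pair
inline int pair_code(int a, int b) {
  if (a == 1 && b == 2) return 0;
  if (a == 2 && b == 1) return 1;
  if (a == 2 && b == 3) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 0 && b == 3) return 4;
  if (a == 3 && b == 0) return 5;
  if (a == 0 && b == 1) return 6;
  if (a == 1 && b == 0) return 7;
  return -1;
}

inline bool is_ac_pair(int pc) { return pc == 6 || pc == 7; }
// canonical = Watson-Crick or wobble (used for stem enumeration)
inline bool is_canonical(int pc) { return pc >= 0 && pc <= 5; }
inline bool is_wc(int pc) { return pc == 0 || pc == 1 || pc == 4 || pc == 5; }

const double AC_SURCHARGE = 1.0;     // per A-C pair
const double AC_STACK = -0.5;        // any stack involving an A-C pair
const double ML_CLOSE = 3.4;         // multiloop closing penalty
const double ML_UNPAIRED = 0.1;      // per unpaired nt in a multiloop
const double ML_BRANCH = 0.4;        // per multiloop branch
const double IL_BASE = 1.6;          // interior/bulge loop opening
const double IL_PER_NT = 0.4;        // per unpaired nt in interior/bulge
const int MIN_HAIRPIN = 3;           // minimal hairpin loop size (nt)

// 6x6 stack table over WC/GU pairs: row = closing pair (i,j),
// col = inner pair (i+1, j-1); 5'->3' convention.
static const double STACK6[6][6] = {
  /* CG */ {-3.3, -3.4, -2.1, -1.4, -2.1, -2.1},
  /* GC */ {-2.4, -3.3, -2.5, -1.5, -2.2, -2.4},
  /* GU */ {-1.4, -1.5, -0.5,  1.3, -0.6, -1.0},
  /* UG */ {-2.1, -2.5, -0.7, -0.5, -1.4, -1.3},
  /* AU */ {-2.1, -2.4, -1.4, -0.6, -0.9, -1.3},
  /* UA */ {-2.4, -2.1, -1.3, -1.0, -1.0, -1.3}
};

inline double stack_energy(int pc_out, int pc_in) {
  if (pc_out < 0 || pc_in < 0) return 0.0;
  if (is_ac_pair(pc_out) || is_ac_pair(pc_in)) return AC_STACK;
  return STACK6[pc_out][pc_in];
}

inline double hairpin_energy(int u) {
  static const double H[7] = {5.4, 5.6, 5.7, 5.4, 6.0, 6.4, 6.8};
  if (u < MIN_HAIRPIN) return 1e9;
  if (u <= 9) return H[u - 3];
  return 6.8 + 1.08 * std::log((double)u / 9.0);
}

inline double interior_energy(int u) {
  return IL_BASE + IL_PER_NT * (double)u;
}

} // namespace rnt1

#endif
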