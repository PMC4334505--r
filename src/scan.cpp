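#include <Rcpp.h>
#include <vector>
#include <string>
#include "energy.h"

using namespace Rcpp;
using namespace rnt1;

// Stem-loop candidate enumeration for the G2-loop scanner. A candidate is an
// NGNN tetraloop (G at loop position 2) whose flanks can pair over a fixed
// stem window, allowing a limited number of bulged (skipped) nucleotides per
// arm. Pairing is greedy from the loop outward; Watson-Crick and G-U wobble
// pairs count. Coordinates returned are 1-based on the given strand sequence.
//
// Model frame: 52 positions, loop at 25-28, upstream stem at 24..9 (24
// adjacent to the loop), downstream stem at 29..44.

struct StepInfo {
  bool paired;
  int upos, dpos;       // 0-based sequence positions consumed at this step
  int ubase, dbase;
};

// [[Rcpp::export(name = ".enumerate_candidates_cpp")]]
DataFrame enumerate_candidates_cpp(std::string seq, int stemSpan, int maxBulge,
                                   int minStem) {
  int n = (int)seq.size();
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);

  std::vector<int> loopStart, candStart, candEnd, downBp, nPaired;
  std::vector<std::string> loopSeq, frame, pairState;
  std::vector<double> dG;
  std::vector<int> wobbleProx;

  for (int i = 0; i + 3 < n; ++i) {
    if (code[i + 1] != 2) continue;                 // loop position 2 must be G
    bool okloop = true;
    for (int k = 0; k < 4; ++k) if (code[i + k] < 0) okloop = false;
    if (!okloop) continue;

    // greedy arm pairing from the loop outward
    std::vector<StepInfo> steps;
    int u = i - 1, d = i + 4;
    int bulgeUp = 0, bulgeDown = 0;
    for (int s = 0; s < stemSpan; ++s) {
      StepInfo st;
      st.paired = false;
      st.upos = u; st.dpos = d;
      st.ubase = (u >= 0) ? code[u] : -1;
      st.dbase = (d < n) ? code[d] : -1;
      if (u < 0 && d >= n) { steps.push_back(st); break; }
      int pc = (st.ubase >= 0 && st.dbase >= 0)
                   ? pair_code(st.ubase, st.dbase) : -1;
      if (is_canonical(pc)) {
        st.paired = true;
        --u; ++d;
      } else {
        // try a single-nucleotide bulge on either arm
        int pcU = (u - 1 >= 0 && st.dbase >= 0)
                      ? pair_code(code[u - 1], st.dbase) : -1;
        int pcD = (d + 1 < n && st.ubase >= 0)
                      ? pair_code(st.ubase, code[d + 1]) : -1;
        if (bulgeUp < maxBulge && is_canonical(pcU)) {
          ++bulgeUp;
          st.upos = u - 1; st.ubase = code[u - 1];
          st.paired = true;
          u -= 2; ++d;
        } else if (bulgeDown < maxBulge && is_canonical(pcD)) {
          ++bulgeDown;
          st.dpos = d + 1; st.dbase = code[d + 1];
          st.paired = true;
          --u; d += 2;
        } else {
          --u; ++d;
        }
      }
      steps.push_back(st);
    }

    int paired = 0, consec = 0, run = 0, bestRun = 0;
    bool counting = true;
    for (size_t s = 0; s < steps.size(); ++s) {
      if (steps[s].paired) {
        ++paired;
        ++run;
        if (run > bestRun) bestRun = run;
        if (counting) ++consec;
      } else {
        counting = false;
        run = 0;
      }
    }
    // candidacy: a stem of >= minStem consecutive pairs must close the loop
    // somewhere in the window
    if (bestRun < minStem) continue;

    // wobble (G-U) in the first two pairs flanking the loop
    int wob = 0;
    for (size_t s = 0; s < steps.size() && s < 2; ++s) {
      if (steps[s].paired) {
        int pc = pair_code(steps[s].ubase, steps[s].dbase);
        if (pc == 2 || pc == 3) wob = 1;
      }
    }

    // candidate span on the sequence
    int lo = i, hi = i + 3;
    for (size_t s = 0; s < steps.size(); ++s) {
      if (steps[s].upos >= 0 && steps[s].upos < lo) lo = steps[s].upos;
      if (steps[s].dpos < n && steps[s].dpos > hi) hi = steps[s].dpos;
    }

    // 52-position model frame
    std::string fr(52, 'N'), ps(52, '.');
    for (int k = 0; k < 4; ++k) fr[24 + k] = seq[i + k];
    for (size_t s = 0; s < steps.size(); ++s) {
      int fu = 24 - 1 - (int)s;   // 0-based frame index of upstream step
      int fd = 28 + (int)s;       // 0-based frame index of downstream step
      if (fu < 0 || fd > 51) break;
      fr[fu] = (steps[s].ubase >= 0) ? seq[steps[s].upos] : 'N';
      fr[fd] = (steps[s].dbase >= 0) ? seq[steps[s].dpos] : 'N';
      ps[fu] = ps[fd] = steps[s].paired ? '1' : '0';
    }

    // hairpin free energy of the enumerated structure
    double e = 0.0;
    int prevU = -1, prevD = -1, prevPc = -1;
    bool first = true;
    for (size_t s = 0; s < steps.size(); ++s) {
      if (!steps[s].paired) continue;
      int pc = pair_code(steps[s].ubase, steps[s].dbase);
      if (first) {
        e += hairpin_energy(steps[s].dpos - steps[s].upos - 1);
        first = false;
      } else {
        int uu = (prevU - steps[s].upos - 1) + (steps[s].dpos - prevD - 1);
        if (uu == 0) e += stack_energy(pc, prevPc);
        else e += interior_energy(uu);
      }
      prevU = steps[s].upos; prevD = steps[s].dpos; prevPc = pc;
    }

    loopStart.push_back(i + 1);
    candStart.push_back(lo + 1);
    candEnd.push_back(hi + 1);
    loopSeq.push_back(seq.substr(i, 4));
    frame.push_back(fr);
    pairState.push_back(ps);
    downBp.push_back(consec);
    nPaired.push_back(paired);
    dG.push_back(e);
    wobbleProx.push_back(wob);
  }

  return DataFrame::create(
      _["loop_start"] = loopStart, _["start"] = candStart,
      _["end"] = candEnd, _["loop_seq"] = loopSeq, _["frame"] = frame,
      _["pairing"] = pairState, _["downstream_bp"] = downBp,
      _["n_paired"] = nPaired, _["dG"] = dG,
      _["wobble_proximal"] = wobbleProx,
      _["stringsAsFactors"] = false);
}

// Global (Needleman-Wunsch) alignment score over integer-coded sequences
// (code 5 = N, which mismatches every base but scores 0 against another N).
// A band half-width limits |i - j|; pass band >= max length for the exact
// unbanded score. With the default scoring (+1/-1/-2) any alignment path
// leaving a generous band is dominated, so banding does not change the
// scores used in practice.
static const int NEG = -1000000;

static std::vector<int> encode_seq(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    v[i] = (c < 0) ? 5 : c;
  }
  return v;
}

static int nw_score_int(const std::vector<int> &a, const std::vector<int> &b,
                        int match, int mismatch, int gap, int band) {
  int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1, NEG), cur(m + 1, NEG);
  for (int j = 0; j <= std::min(m, band); ++j) prev[j] = gap * j;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i - band), jhi = std::min(m, i + band);
    cur.assign(m + 1, NEG);
    if (i <= band) cur[0] = gap * i;
    int ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      int bj = b[j - 1];
      int sub;
      if (ai == 5 && bj == 5) sub = 0;           // N vs N: neutral
      else if (ai == 5 || bj == 5) sub = mismatch;
      else sub = (ai == bj) ? match : mismatch;
      int best = prev[j - 1] + sub;
      if (prev[j] != NEG && prev[j] + gap > best) best = prev[j] + gap;
      if (cur[j - 1] != NEG && cur[j - 1] + gap > best)
        best = cur[j - 1] + gap;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".nw_score_cpp")]]
double nw_score_cpp(std::string a, std::string b, double match,
                    double mismatch, double gap) {
  std::vector<int> ea = encode_seq(a), eb = encode_seq(b);
  int band = (int)std::max(a.size(), b.size()) + 1;
  return (double)nw_score_int(ea, eb, (int)match, (int)mismatch,
                              (int)gap, band);
}

// Best normalized similarity of each query against a reference set.
// Normalization: raw score / (match * number of non-N query positions),
// clipped to [0, 1].
// [[Rcpp::export(name = ".nw_best_cpp")]]
NumericVector nw_best_cpp(CharacterVector queries, CharacterVector refs,
                          double match, double mismatch, double gap,
                          int band = 8) {
  int nq = queries.size(), nr = refs.size();
  std::vector<std::vector<int> > rf(nr);
  for (int r = 0; r < nr; ++r)
    rf[r] = encode_seq(as<std::string>(refs[r]));
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    std::string qraw = as<std::string>(queries[q]);
    std::vector<int> qs = encode_seq(qraw);
    int self = 0;
    for (size_t k = 0; k < qs.size(); ++k)
      if (qs[k] != 5) self += (int)match;
    int best = 0;
    for (int r = 0; r < nr; ++r) {
      int sc = nw_score_int(qs, rf[r], (int)match, (int)mismatch,
                            (int)gap, band);
      if (sc > best) best = sc;
    }
    double v = (self > 0) ? (double)best / self : 0.0;
    if (v < 0) v = 0;
    if (v > 1) v = 1;
    out[q] = v;
  }
  return out;
}
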