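// Core combinatorics for spaced-seed pattern sets.
//
// Patterns are binary masks over {match='1', don't-care='0'} of length <= 64,
// held as uint64_t with bit k = position k (0-based, left to right).  All
// pairwise-shift quantities reduce to popcounts of shifted masks, so a single
// objective evaluation is O(m^2 * l) word operations and the incremental probe
// used by the hill climber is O(m * l).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Pat {
  uint64_t bits;
  int len;
  int w;
};

inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

std::vector<Pat> parsePatterns(const CharacterVector& masks) {
  std::vector<Pat> out;
  out.reserve(masks.size());
  for (R_xlen_t r = 0; r < masks.size(); ++r) {
    std::string s = as<std::string>(masks[r]);
    if (s.empty() || s.size() > 64)
      stop("pattern masks must have length 1..64");
    Pat p{0, (int)s.size(), 0};
    for (size_t k = 0; k < s.size(); ++k) {
      if (s[k] == '1') { p.bits |= (uint64_t)1 << k; ++p.w; }
      else if (s[k] != '0') stop("pattern masks may only contain '0' and '1'");
    }
    out.push_back(p);
  }
  return out;
}

// shared match columns when b is shifted s positions right relative to a
inline int sharedAt(const Pat& a, const Pat& b, int s) {
  if (s >= 0) {
    if (s >= a.len) return 0;
    return popcount64((a.bits >> s) & b.bits);
  }
  if (-s >= b.len) return 0;
  return popcount64(a.bits & (b.bits >> (-s)));
}

// alpha term for pair (r <= r2), objective 0 = OC, 1 = Var (surrogate form).
// powP/powQ are precomputed power tables indexed by the union count n.
double alphaPair(const Pat& a, const Pat& b, bool self, bool selfFull,
                 int objective, const std::vector<double>& powP,
                 const std::vector<double>& powQ, double bgFactor) {
  int lo, hi;
  if (self && !selfFull) { lo = 0; hi = a.len - 1; }
  else { lo = 1 - b.len; hi = a.len - 1; }
  double acc = 0.0;
  for (int s = lo; s <= hi; ++s) {
    int sig = sharedAt(a, b, s);
    if (objective == 0) {
      acc += (double)((uint64_t)1 << sig);  // 2^sigma, exact for sigma <= 52
    } else {
      int n = a.w + b.w - sig;
      acc += powP[n] + bgFactor * powQ[n];
    }
  }
  return acc;
}

struct Objective {
  int kind;           // 0 = OC, 1 = Var
  bool selfFullOC;    // full symmetric self-shift range (OC convention) vs non-negative only
  double p, q, L;
  double scale;       // (L - l + 1) for Var, 1 for OC
  double bgFactor;    // (L - l) for Var, 0 for OC
  std::vector<double> powP, powQ;

  void init(const std::vector<Pat>& pats) {
    int lmax = 0, wmax = 0;
    for (const Pat& pt : pats) { lmax = std::max(lmax, pt.len); wmax = std::max(wmax, pt.w); }
    if (kind == 1) {
      scale = L - lmax + 1.0;
      bgFactor = L - lmax;
      powP.assign(2 * wmax + 1, 1.0);
      powQ.assign(2 * wmax + 1, 1.0);
      for (int k = 1; k <= 2 * wmax; ++k) {
        powP[k] = powP[k - 1] * p;
        powQ[k] = powQ[k - 1] * q;
      }
    } else {
      scale = 1.0; bgFactor = 0.0;
    }
  }

  double alpha(const Pat& a, const Pat& b, bool self) const {
    bool sf = (kind == 0) ? selfFullOC : false;  // Var self-pairs always use the non-negative shift range
    double v = alphaPair(a, b, self, sf, kind, powP, powQ, bgFactor);
    return scale * v;
  }
};

// fixed-order sum over the upper triangle so incremental and from-scratch
// evaluations are bit-identical
double sumAlpha(const std::vector<double>& alpha, int m) {
  double tot = 0.0;
  for (int r = 0; r < m; ++r)
    for (int r2 = r; r2 < m; ++r2)
      tot += alpha[r * m + r2];
  return tot;
}

void fillAlpha(const std::vector<Pat>& pats, const Objective& obj,
               std::vector<double>& alpha) {
  int m = pats.size();
  alpha.assign(m * m, 0.0);
  for (int r = 0; r < m; ++r)
    for (int r2 = r; r2 < m; ++r2)
      alpha[r * m + r2] = obj.alpha(pats[r], pats[r2], r == r2);
}

// C_r = sum over all r' of alpha_{r,r'} (unordered pair, self counted once)
void fillContrib(const std::vector<double>& alpha, int m, std::vector<double>& C) {
  C.assign(m, 0.0);
  for (int r = 0; r < m; ++r)
    for (int r2 = 0; r2 < m; ++r2)
      C[r] += alpha[std::min(r, r2) * m + std::max(r, r2)];
}

}  // namespace

// ---------------------------------------------------------------------------
// pairwise-shift primitives

// [[Rcpp::export]]
IntegerVector cpp_shared_counts(std::string a, std::string b, IntegerVector shifts) {
  CharacterVector cv = CharacterVector::create(a, b);
  std::vector<Pat> pats = parsePatterns(cv);
  IntegerVector out(shifts.size());
  for (R_xlen_t k = 0; k < shifts.size(); ++k)
    out[k] = sharedAt(pats[0], pats[1], shifts[k]);
  return out;
}

// [[Rcpp::export]]
List cpp_oc(CharacterVector masks, bool selfFull) {
  std::vector<Pat> pats = parsePatterns(masks);
  int m = pats.size();
  Objective obj; obj.kind = 0; obj.selfFullOC = selfFull;
  obj.init(pats);
  std::vector<double> alpha, C;
  fillAlpha(pats, obj, alpha);
  fillContrib(alpha, m, C);
  NumericMatrix amat(m, m);
  for (int r = 0; r < m; ++r)
    for (int r2 = r; r2 < m; ++r2)
      amat(r, r2) = alpha[r * m + r2];
  return List::create(_["value"] = sumAlpha(alpha, m),
                      _["alpha"] = amat,
                      _["contributions"] = NumericVector(C.begin(), C.end()));
}

// [[Rcpp::export]]
List cpp_var(CharacterVector masks, double p, double q, double L) {
  std::vector<Pat> pats = parsePatterns(masks);
  int m = pats.size();
  int lmax = 0;
  for (const Pat& pt : pats) lmax = std::max(lmax, pt.len);
  if (L < lmax) stop("sequence length L must be >= the maximum pattern length");
  Objective obj; obj.kind = 1; obj.selfFullOC = false;
  obj.p = p; obj.q = q; obj.L = L;
  obj.init(pats);
  std::vector<double> alpha, C;
  fillAlpha(pats, obj, alpha);
  fillContrib(alpha, m, C);

  // variance value and its homologous / background split, Kahan-accumulated
  int w2 = 2 * pats[0].w;
  double p2w = 1.0, q2w = 1.0;
  for (int k = 0; k < w2; ++k) { p2w *= p; q2w *= q; }
  double hom = 0.0, homc = 0.0, bg = 0.0, bgc = 0.0, surr = 0.0;
  for (int r = 0; r < m; ++r) {
    for (int r2 = r; r2 < m; ++r2) {
      int lo = (r == r2) ? 0 : 1 - pats[r2].len;
      int hi = pats[r].len - 1;
      for (int s = lo; s <= hi; ++s) {
        int n = pats[r].w + pats[r2].w - sharedAt(pats[r], pats[r2], s);
        double th = obj.powP[n] - p2w;
        double y = th - homc, t = hom + y; homc = (t - hom) - y; hom = t;
        double tb = obj.powQ[n] - q2w;
        y = tb - bgc; t = bg + y; bgc = (t - bg) - y; bg = t;
        surr += obj.powP[n] + (L - lmax) * obj.powQ[n];
      }
    }
  }
  double homTerm = (L - lmax + 1.0) * hom;
  double bgTerm = (L - lmax + 1.0) * (L - lmax) * bg;
  NumericMatrix amat(m, m);
  for (int r = 0; r < m; ++r)
    for (int r2 = r; r2 < m; ++r2)
      amat(r, r2) = alpha[r * m + r2];
  return List::create(_["value"] = homTerm + bgTerm,
                      _["homologous"] = homTerm,
                      _["background"] = bgTerm,
                      _["surrogate"] = surr,
                      _["alphaSum"] = sumAlpha(alpha, m),
                      _["alpha"] = amat,
                      _["contributions"] = NumericVector(C.begin(), C.end()));
}

// Incremental re-evaluation after swapping match position i with don't-care
// position j (0-based) in pattern r: only pairs involving r are recomputed,
// then the objective is re-summed from the cached alpha table.
// [[Rcpp::export]]
List cpp_swap_update(CharacterVector masks, int r, int i, int j,
                     int objective, bool selfFull, double p, double q, double L) {
  std::vector<Pat> pats = parsePatterns(masks);
  int m = pats.size();
  if (r < 0 || r >= m) stop("pattern index out of range");
  Pat& pr = pats[r];
  if (i < 0 || i >= pr.len || j < 0 || j >= pr.len) stop("position out of range");
  if (!(pr.bits & ((uint64_t)1 << i))) stop("position i is not a match position");
  if (pr.bits & ((uint64_t)1 << j)) stop("position j is not a don't-care position");
  Objective obj; obj.kind = objective; obj.selfFullOC = selfFull;
  obj.p = p; obj.q = q; obj.L = L;
  obj.init(pats);
  std::vector<double> alpha, C;
  fillAlpha(pats, obj, alpha);
  pr.bits = (pr.bits & ~((uint64_t)1 << i)) | ((uint64_t)1 << j);
  for (int k = 0; k < m; ++k) {
    int lo2 = std::min(r, k), hi2 = std::max(r, k);
    alpha[lo2 * m + hi2] = obj.alpha(pats[lo2], pats[hi2], lo2 == hi2);
  }
  fillContrib(alpha, m, C);
  return List::create(_["value"] = sumAlpha(alpha, m),
                      _["contributions"] = NumericVector(C.begin(), C.end()));
}

// ---------------------------------------------------------------------------
// hill climbers

namespace {

struct ClimbState {
  std::vector<Pat> pats;
  Objective obj;
  std::vector<double> alpha, C;
  std::vector<int> order;
  double value;
  int m;

  void refreshOrder() {
    order.resize(m);
    for (int r = 0; r < m; ++r) order[r] = r;
    std::stable_sort(order.begin(), order.end(),
                     [&](int a, int b) { return C[a] > C[b]; });
  }
  void fullEval() {
    fillAlpha(pats, obj, alpha);
    fillContrib(alpha, m, C);
    value = sumAlpha(alpha, m);
    refreshOrder();
  }
};

// eligible swap positions: interior only when end-anchored
void eligiblePositions(const Pat& p, bool anchored,
                       std::vector<int>& ones, std::vector<int>& zeros) {
  ones.clear(); zeros.clear();
  int lo = anchored ? 1 : 0;
  int hi = anchored ? p.len - 2 : p.len - 1;
  for (int k = lo; k <= hi; ++k) {
    if (p.bits & ((uint64_t)1 << k)) ones.push_back(k);
    else zeros.push_back(k);
  }
}

inline int rUnifInt(int n) {  // uniform on 0..n-1 via R's RNG
  double u;
  do { u = unif_rand(); } while (u >= 1.0);
  return (int)(u * n);
}

}  // namespace

// Contribution-sorted single-swap hill climb.  budgetUnit 0: budget counts
// probes (swap evaluations); 1: budget counts accepted swaps.  stall > 0 adds
// a stagnation cutoff of that many consecutive rejected probes.
// [[Rcpp::export]]
List cpp_hill_climb(CharacterVector masks, bool anchored, int objective,
                    bool selfFull, double p, double q, double L,
                    double budget, int budgetUnit, double stall) {
  ClimbState st;
  st.pats = parsePatterns(masks);
  st.m = st.pats.size();
  st.obj.kind = objective; st.obj.selfFullOC = selfFull;
  st.obj.p = p; st.obj.q = q; st.obj.L = L;
  st.obj.init(st.pats);
  st.fullEval();

  std::vector<int> ones, zeros;
  bool anySwappable = false;
  for (const Pat& pt : st.pats) {
    eligiblePositions(pt, anchored, ones, zeros);
    if (!ones.empty() && !zeros.empty()) { anySwappable = true; break; }
  }

  std::vector<double> traceStep, traceValue;
  traceStep.push_back(0); traceValue.push_back(st.value);
  double probes = 0, swaps = 0, rejectRun = 0;
  std::vector<double> newAlpha(st.m);

  if (anySwappable) {
    GetRNGstate();
    int pos = 0;
    while ((budgetUnit == 0 ? probes : swaps) < budget) {
      if (stall > 0 && rejectRun >= stall) break;
      int r = st.order[pos];
      eligiblePositions(st.pats[r], anchored, ones, zeros);
      if (ones.empty() || zeros.empty()) {
        pos = (pos + 1) % st.m;
        continue;
      }
      int i = ones[rUnifInt((int)ones.size())];
      int j = zeros[rUnifInt((int)zeros.size())];
      uint64_t oldBits = st.pats[r].bits;
      uint64_t newBits = (oldBits & ~((uint64_t)1 << i)) | ((uint64_t)1 << j);
      // a swap may not duplicate another mask in the set
      bool dup = false;
      for (int k = 0; k < st.m && !dup; ++k)
        if (k != r && st.pats[k].len == st.pats[r].len &&
            st.pats[k].bits == newBits) dup = true;
      if (dup) {
        probes += 1;
        rejectRun += 1;
        pos = (pos + 1) % st.m;
        continue;
      }
      st.pats[r].bits = newBits;
      double delta = 0.0;
      for (int k = 0; k < st.m; ++k) {
        int a = std::min(r, k), b = std::max(r, k);
        newAlpha[k] = st.obj.alpha(st.pats[a], st.pats[b], a == b);
        delta += newAlpha[k] - st.alpha[a * st.m + b];
      }
      probes += 1;
      if (delta < 0) {  // strict improvement only
        for (int k = 0; k < st.m; ++k) {
          int a = std::min(r, k), b = std::max(r, k);
          st.alpha[a * st.m + b] = newAlpha[k];
        }
        st.value = sumAlpha(st.alpha, st.m);
        fillContrib(st.alpha, st.m, st.C);
        st.refreshOrder();
        swaps += 1;
        rejectRun = 0;
        pos = 0;
        traceStep.push_back(probes);
        traceValue.push_back(st.value);
      } else {
        st.pats[r].bits = oldBits;
        rejectRun += 1;
        pos = (pos + 1) % st.m;
      }
    }
    PutRNGstate();
  }

  CharacterVector outMasks(st.m);
  for (int r = 0; r < st.m; ++r) {
    std::string s(st.pats[r].len, '0');
    for (int k = 0; k < st.pats[r].len; ++k)
      if (st.pats[r].bits & ((uint64_t)1 << k)) s[k] = '1';
    outMasks[r] = s;
  }
  return List::create(_["masks"] = outMasks,
                      _["value"] = st.value,
                      _["traceStep"] = NumericVector(traceStep.begin(), traceStep.end()),
                      _["traceValue"] = NumericVector(traceValue.begin(), traceValue.end()),
                      _["probes"] = probes,
                      _["swaps"] = swaps);
}

// Reference climber: scan all (r, i, j) triplets, apply the best strictly
// improving swap, repeat until a local minimum.
// [[Rcpp::export]]
List cpp_hill_climb_triplets(CharacterVector masks, bool anchored, int objective,
                             bool selfFull, double p, double q, double L,
                             double maxRounds) {
  ClimbState st;
  st.pats = parsePatterns(masks);
  st.m = st.pats.size();
  st.obj.kind = objective; st.obj.selfFullOC = selfFull;
  st.obj.p = p; st.obj.q = q; st.obj.L = L;
  st.obj.init(st.pats);
  st.fullEval();

  std::vector<int> ones, zeros;
  std::vector<double> newAlpha(st.m);
  double rounds = 0;
  while (rounds < maxRounds) {
    double bestDelta = 0.0;
    int bestR = -1, bestI = -1, bestJ = -1;
    for (int r = 0; r < st.m; ++r) {
      eligiblePositions(st.pats[r], anchored, ones, zeros);
      uint64_t oldBits = st.pats[r].bits;
      for (int i : ones) {
        for (int j : zeros) {
          uint64_t newBits = (oldBits & ~((uint64_t)1 << i)) | ((uint64_t)1 << j);
          bool dup = false;
          for (int k = 0; k < st.m && !dup; ++k)
            if (k != r && st.pats[k].len == st.pats[r].len &&
                st.pats[k].bits == newBits) dup = true;
          if (dup) continue;
          st.pats[r].bits = newBits;
          double delta = 0.0;
          for (int k = 0; k < st.m; ++k) {
            int a = std::min(r, k), b = std::max(r, k);
            delta += st.obj.alpha(st.pats[a], st.pats[b], a == b) -
                     st.alpha[a * st.m + b];
          }
          if (delta < bestDelta) { bestDelta = delta; bestR = r; bestI = i; bestJ = j; }
        }
      }
      st.pats[r].bits = oldBits;
    }
    if (bestR < 0) break;  // local minimum
    uint64_t oldBits = st.pats[bestR].bits;
    st.pats[bestR].bits = (oldBits & ~((uint64_t)1 << bestI)) | ((uint64_t)1 << bestJ);
    for (int k = 0; k < st.m; ++k) {
      int a = std::min(bestR, k), b = std::max(bestR, k);
      st.alpha[a * st.m + b] = st.obj.alpha(st.pats[a], st.pats[b], a == b);
    }
    st.value = sumAlpha(st.alpha, st.m);
    fillContrib(st.alpha, st.m, st.C);
    rounds += 1;
  }

  CharacterVector outMasks(st.m);
  for (int r = 0; r < st.m; ++r) {
    std::string s(st.pats[r].len, '0');
    for (int k = 0; k < st.pats[r].len; ++k)
      if (st.pats[r].bits & ((uint64_t)1 << k)) s[k] = '1';
    outMasks[r] = s;
  }
  return List::create(_["masks"] = outMasks,
                      _["value"] = st.value,
                      _["rounds"] = rounds);
}

// ---------------------------------------------------------------------------
// sensitivity

// Exact hit probability for a Bernoulli(p) 0/1 homology string of length H:
// DFA over the last (lmax - 1) string bits.  A pattern of length l fires when
// the last l bits cover all its match positions and at least l bits exist
// (full-window containment, no partial windows).
// [[Rcpp::export]]
double cpp_sensitivity(CharacterVector masks, int H, double p) {
  std::vector<Pat> pats = parsePatterns(masks);
  int lmax = 0;
  for (const Pat& pt : pats) lmax = std::max(lmax, pt.len);
  if (lmax > 26) stop("sensitivity DP supports maximum pattern length 26");
  bool any = false;
  for (const Pat& pt : pats) if (pt.len <= H) { any = true; break; }
  if (!any) return 0.0;

  // reversed masks: window bit 0 = newest string bit = pattern's last position
  std::vector<uint64_t> rev(pats.size());
  for (size_t r = 0; r < pats.size(); ++r) {
    uint64_t m = 0;
    for (int k = 0; k < pats[r].len; ++k)
      if (pats[r].bits & ((uint64_t)1 << k))
        m |= (uint64_t)1 << (pats[r].len - 1 - k);
    rev[r] = m;
  }

  // min pattern length firing on each lmax-bit window, filled by enumerating
  // the 2^(l - w) supersets of each pattern's match mask
  size_t nWin = (size_t)1 << lmax;
  std::vector<uint8_t> hitLen(nWin, 255);
  for (size_t r = 0; r < pats.size(); ++r) {
    uint64_t need = rev[r];
    uint64_t free_ = (nWin - 1) & ~need;
    uint8_t len = (uint8_t)pats[r].len;
    uint64_t sub = 0;
    while (true) {
      uint64_t wdw = need | sub;
      if (len < hitLen[wdw]) hitLen[wdw] = len;
      if (sub == free_) break;
      sub = (sub - free_) & free_;  // next subset of free_
    }
  }

  size_t nState = (size_t)1 << (lmax - 1);
  uint64_t stateMask = nState - 1;
  std::vector<double> prob(nState, 0.0), nxt(nState, 0.0);
  prob[0] = 1.0;
  double pHit = 0.0;
  const double p1 = p, p0 = 1.0 - p;
  for (int t = 1; t <= H; ++t) {
    // states reachable after t-1 bits use only the low min(t-1, lmax-1) bits
    size_t lim = (t - 1 >= lmax - 1) ? nState : ((size_t)1 << (t - 1));
    std::fill(nxt.begin(), nxt.begin() + std::min(nState, 2 * lim), 0.0);
    double ph = 0.0;
    for (size_t s = 0; s < lim; ++s) {
      double pr = prob[s];
      uint64_t w0 = (uint64_t)s << 1, w1 = w0 | 1;
      double pb0 = pr * p0, pb1 = pr * p1;
      double h0 = (hitLen[w0] <= t) ? 1.0 : 0.0;
      double h1 = (hitLen[w1] <= t) ? 1.0 : 0.0;
      ph += pb0 * h0 + pb1 * h1;
      nxt[w0 & stateMask] += pb0 * (1.0 - h0);
      nxt[w1 & stateMask] += pb1 * (1.0 - h1);
    }
    pHit += ph;
    prob.swap(nxt);
  }
  return pHit;
}

// Enumeration oracle: sum over all 2^H binary strings.
// [[Rcpp::export]]
double cpp_sensitivity_brute(CharacterVector masks, int H, double p) {
  if (H > 22) stop("brute-force sensitivity is limited to H <= 22");
  std::vector<Pat> pats = parsePatterns(masks);
  std::vector<double> powp(H + 1, 1.0), powq(H + 1, 1.0);
  for (int k = 1; k <= H; ++k) {
    powp[k] = powp[k - 1] * p;
    powq[k] = powq[k - 1] * (1.0 - p);
  }
  double tot = 0.0;
  uint64_t nStr = (uint64_t)1 << H;
  for (uint64_t x = 0; x < nStr; ++x) {
    bool hit = false;
    for (size_t r = 0; r < pats.size() && !hit; ++r) {
      for (int o = 0; o + pats[r].len <= H; ++o) {
        if (((x >> o) & pats[r].bits) == pats[r].bits) { hit = true; break; }
      }
    }
    if (hit) {
      int k = popcount64(x);
      tot += powp[k] * powq[H - k];
    }
  }
  return tot;
}

// ---------------------------------------------------------------------------
// spaced-word matching and the sequence-pair simulator

namespace {

inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// spaced words of s under pattern p at every start, packed 2 bits per match
// position; requires ACGT and w <= 31
void spacedWords(const std::string& s, const Pat& p, std::vector<uint64_t>& out) {
  out.clear();
  int L = s.size();
  std::vector<int> mp;
  for (int k = 0; k < p.len; ++k)
    if (p.bits & ((uint64_t)1 << k)) mp.push_back(k);
  for (int i = 0; i + p.len <= L; ++i) {
    uint64_t key = 0;
    for (size_t k = 0; k < mp.size(); ++k) {
      int c = baseCode(s[i + mp[k]]);
      if (c < 0) stop("sequences must be over the DNA alphabet ACGT");
      key = (key << 2) | (uint64_t)c;
    }
    out.push_back(key);
  }
}

double countPairs(std::vector<uint64_t>& a, std::vector<uint64_t>& b) {
  std::sort(a.begin(), a.end());
  std::sort(b.begin(), b.end());
  double tot = 0.0;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (b[j] < a[i]) ++j;
    else {
      uint64_t v = a[i];
      size_t i2 = i, j2 = j;
      while (i2 < a.size() && a[i2] == v) ++i2;
      while (j2 < b.size() && b[j2] == v) ++j2;
      tot += (double)(i2 - i) * (double)(j2 - j);
      i = i2; j = j2;
    }
  }
  return tot;
}

double countMatchesFast(const std::string& s1, const std::string& s2,
                        const std::vector<Pat>& pats) {
  double N = 0.0;
  std::vector<uint64_t> a, b;
  for (const Pat& p : pats) {
    if (p.w > 31) stop("hashed match counting supports weight <= 31");
    spacedWords(s1, p, a);
    spacedWords(s2, p, b);
    N += countPairs(a, b);
  }
  return N;
}

void simulatePairInto(int L, double p, std::string& s1, std::string& s2) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  s1.resize(L); s2.resize(L);
  for (int i = 0; i < L; ++i) {
    int c = rUnifInt(4);
    s1[i] = B[c];
    if (unif_rand() < p) s2[i] = B[c];
    else s2[i] = B[(c + 1 + rUnifInt(3)) & 3];
  }
}

}  // namespace

// [[Rcpp::export]]
bool cpp_spaced_word_match(std::string s1, std::string s2, int i, int j,
                           std::string pattern) {
  // i, j are 1-based window starts
  int l = pattern.size();
  if (i < 1 || j < 1 || i + l - 1 > (int)s1.size() || j + l - 1 > (int)s2.size())
    stop("window out of range");
  for (int k = 0; k < l; ++k) {
    if (pattern[k] == '1' && s1[i - 1 + k] != s2[j - 1 + k]) return false;
    if (pattern[k] != '1' && pattern[k] != '0')
      stop("pattern masks may only contain '0' and '1'");
  }
  return true;
}

// [[Rcpp::export]]
double cpp_count_matches(std::string s1, std::string s2, CharacterVector masks) {
  std::vector<Pat> pats = parsePatterns(masks);
  for (const Pat& p : pats)
    if ((int)s1.size() < p.len || (int)s2.size() < p.len)
      stop("sequences shorter than the pattern length");
  return countMatchesFast(s1, s2, pats);
}

// brute-force reference: all (i, j) window pairs, direct character comparison
// [[Rcpp::export]]
double cpp_count_matches_naive(std::string s1, std::string s2, CharacterVector masks) {
  std::vector<Pat> pats = parsePatterns(masks);
  double N = 0.0;
  for (const Pat& p : pats) {
    std::vector<int> mp;
    for (int k = 0; k < p.len; ++k)
      if (p.bits & ((uint64_t)1 << k)) mp.push_back(k);
    for (int i = 0; i + p.len <= (int)s1.size(); ++i) {
      for (int j = 0; j + p.len <= (int)s2.size(); ++j) {
        bool ok = true;
        for (int k : mp)
          if (s1[i + k] != s2[j + k]) { ok = false; break; }
        if (ok) N += 1.0;
      }
    }
  }
  return N;
}

// [[Rcpp::export]]
List cpp_simulate_pair(int L, double p) {
  std::string s1, s2;
  GetRNGstate();
  simulatePairInto(L, p, s1, s2);
  PutRNGstate();
  return List::create(_["S1"] = s1, _["S2"] = s2);
}

// [[Rcpp::export]]
NumericVector cpp_empirical_counts(CharacterVector masks, int L, double p,
                                   int reps) {
  std::vector<Pat> pats = parsePatterns(masks);
  NumericVector N(reps);
  std::string s1, s2;
  GetRNGstate();
  for (int k = 0; k < reps; ++k) {
    simulatePairInto(L, p, s1, s2);
    N[k] = countMatchesFast(s1, s2, pats);
    if ((k & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();
  return N;
}
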