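// Synchronous Boolean dynamics core: nested canalyzing update, attractor
// detection under (time-limited) knockouts, and the exact-rational
// influence-matrix loop.  Deterministic: all randomness stays on the R side.
#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

namespace {

struct RuleTable {
  int N;
  std::vector<std::vector<int>> regs;  // 0-based; empty => hold rule
  std::vector<std::vector<int>> I, O;
  std::vector<int> odef;
};

RuleTable unpackRules(const List& packed) {
  RuleTable rt;
  List regs = packed["regs"], I = packed["I"], O = packed["O"];
  IntegerVector odef = packed["odef"];
  rt.N = regs.size();
  rt.regs.resize(rt.N);
  rt.I.resize(rt.N);
  rt.O.resize(rt.N);
  rt.odef.assign(odef.begin(), odef.end());
  for (int i = 0; i < rt.N; ++i) {
    IntegerVector r = regs[i], a = I[i], b = O[i];
    rt.regs[i].assign(r.begin(), r.end());
    rt.I[i].assign(a.begin(), a.end());
    rt.O[i].assign(b.begin(), b.end());
  }
  return rt;
}

// First regulator matching its canalyzing value decides; else default.
inline void stepState(const RuleTable& rt, const std::vector<uint8_t>& cur,
                      std::vector<uint8_t>& nxt) {
  for (int i = 0; i < rt.N; ++i) {
    const std::vector<int>& rg = rt.regs[i];
    if (rg.empty()) { nxt[i] = cur[i]; continue; }
    int out = rt.odef[i];
    for (size_t m = 0; m < rg.size(); ++m) {
      if (cur[rg[m]] == (uint8_t)rt.I[i][m]) { out = rt.O[i][m]; break; }
    }
    nxt[i] = (uint8_t)out;
  }
}

struct AttractorResult {
  long long tau = -1;  // -1: not found within maxSteps
  long long period = 0;
  std::vector<std::vector<uint8_t>> cycle;  // period states
};

// koTarget: 0-based node index, -1 for none.  koDuration: steps 1..T are
// produced with the target forced to 0; koDuration < 0 means permanent.
// Cycle detection starts at step max(T, 0) for finite knockouts (states in
// the mutation window are transient by construction) and at step 0
// otherwise, so the returned cycle is an attractor of the rule set that
// actually governs the long-run dynamics.
AttractorResult findAttractorCore(const RuleTable& rt,
                                  const std::vector<uint8_t>& v0,
                                  int koTarget, long long koDuration,
                                  long long maxSteps) {
  const bool ko = koTarget >= 0;
  const bool permanent = ko && koDuration < 0;
  const long long detectStart = (ko && !permanent) ? koDuration : 0;

  std::vector<uint8_t> cur = v0, nxt(rt.N);
  std::unordered_map<std::string, long long> seen;
  std::vector<std::vector<uint8_t>> traj;  // states from detectStart on
  AttractorResult res;

  for (long long t = 0;; ++t) {
    if (t >= detectStart) {
      std::string key(cur.begin(), cur.end());
      auto it = seen.find(key);
      if (it != seen.end()) {
        res.tau = it->second;
        res.period = t - it->second;
        long long off = res.tau - detectStart;
        res.cycle.assign(traj.begin() + off, traj.begin() + off + res.period);
        return res;
      }
      seen.emplace(std::move(key), t);
      traj.push_back(cur);
    }
    if (t >= maxSteps) return res;  // tau = -1: not found
    stepState(rt, cur, nxt);
    long long tNext = t + 1;
    if (ko && (permanent || tNext <= koDuration)) nxt[koTarget] = 0;
    cur.swap(nxt);
  }
}

IntegerMatrix cycleToMatrix(const AttractorResult& a, int N) {
  IntegerMatrix m(a.period, N);
  for (long long r = 0; r < a.period; ++r)
    for (int c = 0; c < N; ++c) m(r, c) = a.cycle[r][c];
  return m;
}

long long llgcd(long long a, long long b) {
  if (a < 0) a = -a;
  if (b < 0) b = -b;
  while (b) { long long t = a % b; a = b; b = t; }
  return a;
}

__int128 gcd128(__int128 a, __int128 b) {
  if (a < 0) a = -a;
  if (b < 0) b = -b;
  while (b) { __int128 t = a % b; a = b; b = t; }
  return a;
}

const long long LL_LIMIT = 4000000000000000000LL;

struct Rat {
  long long n = 0, d = 1;
  void add(long long n2, long long d2) {
    __int128 num = (__int128)n * d2 + (__int128)n2 * d;
    __int128 den = (__int128)d * d2;
    __int128 g = gcd128(num, den);
    if (g > 1) { num /= g; den /= g; }
    if (num > LL_LIMIT || den > LL_LIMIT)
      stop("exact rational accumulation overflow");
    n = (long long)num;
    d = (long long)den;
  }
};

// Minimum-alignment bit difference between two periodic node sequences,
// as a reduced fraction mis/c with c = lcm(p, p').  Offsets range over
// [0, gcd-1] (the printed definition) or [0, c-1] in full-alignment mode.
void seqDistance(const uint8_t* wt, long long p, const uint8_t* mu,
                 long long p2, bool fullAlignment, long long& num,
                 long long& den) {
  long long g = llgcd(p, p2);
  long long c = (p / g) * p2;
  long long nOff = fullAlignment ? c : g;
  long long best = c + 1;
  for (long long m = 0; m < nOff; ++m) {
    long long mis = 0;
    for (long long l = 0; l < c; ++l)
      if (wt[(l + m) % p] != mu[l % p2]) ++mis;
    if (mis < best) best = mis;
    if (best == 0) break;
  }
  long long gg = llgcd(best, c);
  num = best / gg;
  den = c / gg;
}

}  // namespace

// [[Rcpp::export(name = "cpp_find_attractor")]]
List cpp_find_attractor(List packed, IntegerVector v0, int koTarget,
                        double koDuration, double maxSteps) {
  RuleTable rt = unpackRules(packed);
  if ((int)v0.size() != rt.N) stop("state length must equal the node count");
  std::vector<uint8_t> s(v0.begin(), v0.end());
  long long dur =
      (koTarget >= 0 && !R_finite(koDuration)) ? -1 : (long long)koDuration;
  AttractorResult a =
      findAttractorCore(rt, s, koTarget, dur, (long long)maxSteps);
  if (a.tau < 0) return List::create(Named("found") = false);
  return List::create(Named("found") = true, Named("tau") = (double)a.tau,
                      Named("period") = (double)a.period,
                      Named("states") = cycleToMatrix(a, rt.N));
}

// Influence-matrix loop.  For each initial state: one wild-type attractor
// (shared across sources), one mutant attractor per source i (shared
// across targets j), then the per-target alignment distance.  Returns the
// exact reduced mu as parallel numerator/denominator matrices.
// [[Rcpp::export(name = "cpp_influence_matrix")]]
List cpp_influence_matrix(List packed, IntegerMatrix S, double koDuration,
                          double maxSteps, bool fullAlignment) {
  RuleTable rt = unpackRules(packed);
  const int N = rt.N;
  if (S.ncol() != N) stop("initial states must have one column per node");
  const int nS = S.nrow();
  const long long dur = R_finite(koDuration) ? (long long)koDuration : -1;

  std::vector<std::vector<Rat>> acc(N, std::vector<Rat>(N));
  std::vector<uint8_t> v0(N);
  std::vector<uint8_t> wtSeq, muSeq;

  for (int s = 0; s < nS; ++s) {
    for (int c = 0; c < N; ++c) v0[c] = (uint8_t)S(s, c);
    AttractorResult wt =
        findAttractorCore(rt, v0, -1, 0, (long long)maxSteps);
    if (wt.tau < 0)
      stop("attractor not found within max_steps=%.0f for initial state %d",
           maxSteps, s + 1);
    for (int i = 0; i < N; ++i) {
      AttractorResult mu =
          findAttractorCore(rt, v0, i, dur, (long long)maxSteps);
      if (mu.tau < 0)
        stop("attractor not found within max_steps=%.0f for initial state "
             "%d under knockout of node %d", maxSteps, s + 1, i + 1);
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        wtSeq.resize(wt.period);
        muSeq.resize(mu.period);
        for (long long r = 0; r < wt.period; ++r) wtSeq[r] = wt.cycle[r][j];
        for (long long r = 0; r < mu.period; ++r) muSeq[r] = mu.cycle[r][j];
        long long num, den;
        seqDistance(wtSeq.data(), wt.period, muSeq.data(), mu.period,
                    fullAlignment, num, den);
        if (num > 0) acc[i][j].add(num, den);
      }
    }
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix num(N, N), den(N, N);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < N; ++j) {
      if (i == j) { num(i, j) = NA_REAL; den(i, j) = NA_REAL; continue; }
      Rat r = acc[i][j];
      __int128 dd = (__int128)r.d * nS;  // divide the sum by |S|
      __int128 g = gcd128(r.n, dd);
      if (g > 1) { dd /= g; r.n /= (long long)g; }
      if (dd > LL_LIMIT) stop("exact rational accumulation overflow");
      num(i, j) = (double)r.n;
      den(i, j) = (double)(long long)dd;
    }
  }
  return List::create(Named("numerator") = num, Named("denominator") = den);
}
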