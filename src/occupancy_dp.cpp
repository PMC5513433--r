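#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

// Equilibrium fractional occupancy of candidate binding sites under steric
// exclusion and nearest-neighbour pairwise cooperativity, by dynamic
// programming over sites sorted by footprint end.
//
// Configuration weight: prod(q_i over bound i) * omega^(#pairs of
// consecutively bound cooperative sites with edge-to-edge gap <= d).
// A forward pass conditions on the identity of the last bound cooperative
// site within look-back distance d (all farther states collapse into a
// single "far" class, which is exact because future gaps only grow); the
// backward pass is the forward pass on the mirrored locus; marginals come
// from joining the two state sets with a bridge factor for cooperative
// pairs straddling the focal site. All accumulation is log-sum-exp of
// positive terms, so no cancellation occurs and magnitudes up to
// omega^n * prod(q) are safe.

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log1p(std::exp(-std::fabs(a - b)));
}

struct StateSet {
  // k = -1 encodes the "no cooperative partner in range" class
  std::vector<int> k;
  std::vector<double> logv;
};

struct CumList {
  // append-only (j, running LSE) pairs for one cooperative site's states
  std::vector<int> j;
  std::vector<double> cum;
  void push(int jj, double logv) {
    double prev = cum.empty() ? R_NegInf : cum.back();
    j.push_back(jj);
    cum.push_back(lse2(prev, logv));
  }
  // LSE of entries with index <= jmax (jmax exclusive prefix bound: j < jm)
  double prefix(int jm) const {
    // entries have strictly increasing j; find last with j < jm
    int lo = 0, hi = (int)j.size();
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (j[mid] < jm) lo = mid + 1; else hi = mid;
    }
    return lo == 0 ? R_NegInf : cum[lo - 1];
  }
  double total() const { return cum.empty() ? R_NegInf : cum.back(); }
};

struct ForwardResult {
  std::vector<StateSet> states; // per processing index
  double logZ;
};

// sites given in processing order (sorted ascending by end, then start).
// coopRank[i] = rank of site i among cooperative sites (by end order), or -1.
static ForwardResult forward_pass(const std::vector<double>& start,
                                  const std::vector<double>& end,
                                  const std::vector<bool>& coop,
                                  const std::vector<double>& logq,
                                  double logOmega, double d) {
  int n = (int)start.size();
  ForwardResult res;
  res.states.resize(n);

  // cooperative sites in processing (= end) order
  std::vector<int> coopIdx;       // processing indices of cooperative sites
  for (int i = 0; i < n; ++i) if (coop[i]) coopIdx.push_back(i);
  int nc = (int)coopIdx.size();
  std::vector<double> coopEnds(nc); // nondecreasing (coop order = end order)
  for (int r = 0; r < nc; ++r) coopEnds[r] = end[coopIdx[r]];
  std::vector<CumList> cum(nc);   // per cooperative site state accumulators
  std::vector<int> coopRank(n, -1);
  for (int r = 0; r < nc; ++r) coopRank[coopIdx[r]] = r;

  // running LSE cumulative of "far/none" states, indexed by processing order
  std::vector<double> c0cum(n + 1, R_NegInf); // c0cum[j+1] = LSE over <= j
  // frozen cooperative totals in end order, with LSE cumulative
  std::vector<double> frozenEnd;  // end coordinate of frozen coop site
  std::vector<double> frozenCum;  // running LSE of final totals
  int freezePtr = 0;              // next coop rank to consider freezing

  std::vector<double> totalCum(n + 1, R_NegInf);

  for (int m = 0; m < n; ++m) {
    // freeze cooperative sites that can no longer receive contributions
    while (freezePtr < nc && end[coopIdx[freezePtr]] + d < end[m]) {
      double tot = cum[freezePtr].total();
      double prev = frozenCum.empty() ? R_NegInf : frozenCum.back();
      frozenEnd.push_back(end[coopIdx[freezePtr]]);
      frozenCum.push_back(lse2(prev, tot));
      ++freezePtr;
    }

    // prefix of compatible predecessors: j with end[j] <= start[m]
    int jm = (int)(std::upper_bound(end.begin(), end.end(), start[m]) - end.begin());

    // frozen-far sum: frozen coop k with end_k < start_m - d
    double thr = start[m] - d;
    int fi = (int)(std::lower_bound(frozenEnd.begin(), frozenEnd.end(), thr) - frozenEnd.begin());
    double frozenFar = fi == 0 ? R_NegInf : frozenCum[fi - 1];

    // base class: empty config + far/none predecessor states
    double S0 = lse2(0.0, lse2(c0cum[jm], frozenFar));

    // mid-window cooperative sites: end_k in [start_m - d, start_m]
    // (anything with end_k > start_m cannot have states within prefix jm)
    int rLo = (int)(std::lower_bound(coopEnds.begin(), coopEnds.end(),
                      start[m] - d) - coopEnds.begin());
    int rHi = (int)(std::upper_bound(coopEnds.begin(), coopEnds.end(),
                      start[m]) - coopEnds.begin());

    StateSet& st = res.states[m];
    double siteTotal;
    if (coop[m] && logOmega > 0.0) {
      // all in-range partner states gain omega; far ones are in S0
      double nearSum = R_NegInf;
      for (int r = rLo; r < rHi; ++r) nearSum = lse2(nearSum, cum[r].prefix(jm));
      double val = logq[m] + lse2(S0, logOmega + nearSum);
      st.k.push_back(m);
      st.logv.push_back(val);
      cum[coopRank[m]].push(m, val);
      c0cum[m + 1] = c0cum[m];
      siteTotal = val;
    } else {
      // carried states: keep partner k while end_k >= end_m - d, else fold
      double foldSum = R_NegInf;
      siteTotal = R_NegInf;
      for (int r = rLo; r < rHi; ++r) {
        double v = cum[r].prefix(jm);
        if (v == R_NegInf) continue;
        if (end[coopIdx[r]] >= end[m] - d) {
          double val = logq[m] + v;
          st.k.push_back(coopIdx[r]);
          st.logv.push_back(val);
          cum[r].push(m, val);
          siteTotal = lse2(siteTotal, val);
        } else {
          foldSum = lse2(foldSum, v);
        }
      }
      double val0 = logq[m] + lse2(S0, foldSum);
      st.k.push_back(-1);
      st.logv.push_back(val0);
      c0cum[m + 1] = lse2(c0cum[m], val0);
      siteTotal = lse2(siteTotal, val0);
    }
    totalCum[m + 1] = lse2(totalCum[m], siteTotal);
  }

  res.logZ = lse2(0.0, totalCum[n]);
  return res;
}

// [[Rcpp::export(name = ".occupancy_dp_cpp")]]
Rcpp::List occupancy_dp_cpp(Rcpp::NumericVector start,
                            Rcpp::NumericVector end,
                            Rcpp::LogicalVector cooperative,
                            Rcpp::NumericMatrix logq,
                            double omega, double d_omega) {
  int n = start.size();
  int P = logq.ncol();
  Rcpp::NumericMatrix f(n, P);
  Rcpp::NumericVector logZ(P);
  if (n == 0) {
    std::fill(logZ.begin(), logZ.end(), 0.0);
    return Rcpp::List::create(Rcpp::Named("f") = f, Rcpp::Named("logZ") = logZ);
  }

  double logOmega = std::log(omega);
  bool useCoop = omega > 1.0;

  // processing order: ascending end, ties by start
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (end[a] != end[b]) return end[a] < end[b];
    return start[a] < start[b];
  });
  std::vector<double> s(n), e(n);
  std::vector<bool> cp(n);
  for (int i = 0; i < n; ++i) {
    s[i] = start[ord[i]];
    e[i] = end[ord[i]];
    cp[i] = useCoop && cooperative[ord[i]];
  }

  // mirrored instance for the backward pass: x -> -x
  std::vector<int> mord(n);
  for (int i = 0; i < n; ++i) mord[i] = i;
  std::vector<double> ms(n), me(n);
  // mirrored site of original site o: start' = -end[o], end' = -start[o]
  std::sort(mord.begin(), mord.end(), [&](int a, int b) {
    if (start[a] != start[b]) return start[a] > start[b];
    return end[a] > end[b];
  });
  std::vector<bool> mcp(n);
  for (int i = 0; i < n; ++i) {
    ms[i] = -end[mord[i]];
    me[i] = -start[mord[i]];
    mcp[i] = useCoop && cooperative[mord[i]];
  }

  // position of each original site in the two processing orders
  std::vector<int> posF(n), posB(n);
  for (int i = 0; i < n; ++i) { posF[ord[i]] = i; posB[mord[i]] = i; }

  std::vector<double> lq(n), mlq(n);

  for (int x = 0; x < P; ++x) {
    for (int i = 0; i < n; ++i) {
      lq[i] = logq(ord[i], x);
      mlq[i] = logq(mord[i], x);
    }
    ForwardResult fw = forward_pass(s, e, cp, lq, logOmega, d_omega);
    ForwardResult bw = forward_pass(ms, me, mcp, mlq, logOmega, d_omega);

    for (int o = 0; o < n; ++o) {
      double lqo = logq(o, x);
      if (lqo == R_NegInf) { f(o, x) = 0.0; continue; }
      const StateSet& A = fw.states[posF[o]];
      const StateSet& B = bw.states[posB[o]];
      double acc = R_NegInf;
      for (size_t a = 0; a < A.k.size(); ++a) {
        if (A.logv[a] == R_NegInf) continue;
        for (size_t b = 0; b < B.k.size(); ++b) {
          if (B.logv[b] == R_NegInf) continue;
          double term = A.logv[a] + B.logv[b];
          // map processing-local partner indices back to original site ids
          int kL = A.k[a] < 0 ? -1 : ord[A.k[a]];
          int kR = B.k[b] < 0 ? -1 : mord[B.k[b]];
          // bridge: cooperative pair straddling a non-cooperative bound site
          if (!(useCoop && cooperative[o]) && kL >= 0 && kR >= 0 &&
              start[kR] - end[kL] <= d_omega) {
            term += logOmega;
          }
          acc = lse2(acc, term);
        }
      }
      double lf = acc - lqo - fw.logZ;
      f(o, x) = lf == R_NegInf ? 0.0 : std::exp(lf);
      if (f(o, x) > 1.0) f(o, x) = 1.0; // guard against eps overshoot
    }
    logZ[x] = fw.logZ;
  }

  return Rcpp::List::create(Rcpp::Named("f") = f, Rcpp::Named("logZ") = logZ);
}
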