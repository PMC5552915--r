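#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Profile HMM scoring engine.
//
// Architecture (log-odds against an i.i.d. background):
//   local mode:  S -> N (background flank, self-loop eta) -> B -> uniform
//   entry B->M_j (1/L) -> core M/I/D with per-node trained transitions and a
//   geometric exit eps_k = 1/(L-k+1) from every match state -> E -> C
//   (background flank, self-loop eta) -> T.  Deletions are interior only;
//   paths may also leave through the terminal delete chain (D_L -> E).
//   global mode: no flanks, entry fixed at M_1, exit at M_L or D_L; the
//   trained transitions are used unscaled (eps_k = 0 for k < L).
//
// Forward is computed in scaled odds space (per-row rescaling, so no
// underflow at realistic lengths); Viterbi in log2-odds space.  Residue code
// K (one past the alphabet) is the wildcard X and scores odds 1 everywhere.

static inline double log2sumexp(const std::vector<double>& v) {
  double m = R_NegInf;
  for (double x : v) if (x > m) m = x;
  if (!R_FINITE(m)) return m;
  double s = 0.0;
  for (double x : v) s += std::exp2(x - m);
  return m + std::log2(s);
}

static inline double l2(double x) {
  return x > 0.0 ? std::log2(x) : R_NegInf;
}

// [[Rcpp::export]]
NumericMatrix phmm_score_batch_cpp(NumericMatrix match_odds,  // L x (K) match emission / background
                                   NumericMatrix ins_odds,    // L x (K), row k = insert node I_k (row L unused)
                                   NumericVector tMM, NumericVector tMI, NumericVector tMD,
                                   NumericVector tIM, NumericVector tII,
                                   NumericVector tDM, NumericVector tDD,
                                   List seqs, bool local, double eta) {
  const int L = match_odds.nrow();
  const int K = match_odds.ncol();
  const int nseq = seqs.size();
  NumericMatrix out(nseq, 2);  // col 0: viterbi bits, col 1: forward bits

  // per-node exit probability and effective (scaled) transitions
  std::vector<double> eps(L), aMM(L, 0.0), aMI(L, 0.0), aMD(L, 0.0);
  for (int k = 0; k < L; ++k)
    eps[k] = local ? 1.0 / (double)(L - k) : (k == L - 1 ? 1.0 : 0.0);
  for (int k = 0; k < L - 1; ++k) {
    aMM[k] = (1.0 - eps[k]) * tMM[k];
    aMI[k] = (1.0 - eps[k]) * tMI[k];
    aMD[k] = (1.0 - eps[k]) * tMD[k];
  }

  // logs for Viterbi
  std::vector<double> leps(L), laMM(L), laMI(L), laMD(L), ltIM(L), ltII(L), ltDM(L), ltDD(L);
  for (int k = 0; k < L; ++k) {
    leps[k] = l2(eps[k]);
    laMM[k] = l2(aMM[k]); laMI[k] = l2(aMI[k]); laMD[k] = l2(aMD[k]);
    ltIM[k] = (k < L - 1) ? l2(tIM[k]) : R_NegInf;
    ltII[k] = (k < L - 1) ? l2(tII[k]) : R_NegInf;
    ltDM[k] = (k < L - 1) ? l2(tDM[k]) : R_NegInf;
    ltDD[k] = (k < L - 1) ? l2(tDD[k]) : R_NegInf;
  }
  const double leta = l2(eta), lout = l2(1.0 - eta);

  std::vector<double> pM(L), pI(L), pD(L), cM(L), cI(L), cD(L);
  std::vector<double> vpM(L), vpI(L), vpD(L), vcM(L), vcI(L), vcD(L);

  for (int s = 0; s < nseq; ++s) {
    IntegerVector sq = seqs[s];
    const int n = sq.size();
    if (n < 1) stop("empty sequence");

    // ---------- forward (scaled odds space) ----------
    std::fill(pM.begin(), pM.end(), 0.0);
    std::fill(pI.begin(), pI.end(), 0.0);
    std::fill(pD.begin(), pD.end(), 0.0);
    double Nprev = local ? 1.0 : 0.0;  // N(0) flank mass
    double logscale = 0.0;
    std::vector<double> logE;
    logE.reserve(n);

    for (int i = 1; i <= n; ++i) {
      const int a = sq[i - 1];
      const double entry_local = Nprev * (1.0 - eta) / (double)L;
      for (int k = 0; k < L; ++k) {
        const double mo = (a < K) ? match_odds(k, a) : 1.0;
        double x = local ? entry_local : ((i == 1 && k == 0) ? 1.0 : 0.0);
        if (k > 0)
          x += pM[k - 1] * aMM[k - 1] + pI[k - 1] * tIM[k - 1] + pD[k - 1] * tDM[k - 1];
        cM[k] = mo * x;
      }
      for (int k = 0; k < L - 1; ++k) {
        const double io = (a < K) ? ins_odds(k, a) : 1.0;
        cI[k] = io * (pM[k] * aMI[k] + pI[k] * tII[k]);
      }
      if (L > 0) cI[L - 1] = 0.0;
      cD[0] = 0.0;
      for (int k = 1; k < L; ++k)
        cD[k] = cM[k - 1] * aMD[k - 1] + cD[k - 1] * tDD[k - 1];

      if (local) {
        double Ei = cD[L - 1];  // D_L -> E
        for (int k = 0; k < L; ++k) Ei += cM[k] * eps[k];
        if (Ei > 0.0)
          logE.push_back(std::log2(Ei) + logscale + (double)(n - i) * leta);
      }

      double Ncur = Nprev * eta;
      double m = Ncur;
      for (int k = 0; k < L; ++k) {
        if (cM[k] > m) m = cM[k];
        if (cI[k] > m) m = cI[k];
        if (cD[k] > m) m = cD[k];
      }
      if (m > 0.0 && (m > 1e100 || m < 1e-100)) {
        const double inv = 1.0 / m;
        for (int k = 0; k < L; ++k) { cM[k] *= inv; cI[k] *= inv; cD[k] *= inv; }
        Ncur *= inv;
        logscale += std::log2(m);
      }
      std::swap(pM, cM); std::swap(pI, cI); std::swap(pD, cD);
      Nprev = Ncur;
    }

    double fwd;
    if (local) {
      fwd = log2sumexp(logE) + lout;
    } else {
      const double fin = pM[L - 1] + pD[L - 1];
      fwd = fin > 0.0 ? std::log2(fin) + logscale : R_NegInf;
    }

    // ---------- Viterbi (log2-odds space) ----------
    std::fill(vpM.begin(), vpM.end(), R_NegInf);
    std::fill(vpI.begin(), vpI.end(), R_NegInf);
    std::fill(vpD.begin(), vpD.end(), R_NegInf);
    double vbest = R_NegInf;

    for (int i = 1; i <= n; ++i) {
      const int a = sq[i - 1];
      const double lentry = local
        ? (double)(i - 1) * leta + l2((1.0 - eta) / (double)L)
        : ((i == 1) ? 0.0 : R_NegInf);
      for (int k = 0; k < L; ++k) {
        const double lmo = (a < K) ? l2(match_odds(k, a)) : 0.0;
        double x = local ? lentry : ((i == 1 && k == 0) ? 0.0 : R_NegInf);
        if (k > 0) {
          const double c1 = vpM[k - 1] + laMM[k - 1];
          const double c2 = vpI[k - 1] + ltIM[k - 1];
          const double c3 = vpD[k - 1] + ltDM[k - 1];
          if (c1 > x) x = c1;
          if (c2 > x) x = c2;
          if (c3 > x) x = c3;
        }
        vcM[k] = lmo + x;
      }
      for (int k = 0; k < L - 1; ++k) {
        const double lio = (a < K) ? l2(ins_odds(k, a)) : 0.0;
        vcI[k] = lio + std::max(vpM[k] + laMI[k], vpI[k] + ltII[k]);
      }
      if (L > 0) vcI[L - 1] = R_NegInf;
      vcD[0] = R_NegInf;
      for (int k = 1; k < L; ++k)
        vcD[k] = std::max(vcM[k - 1] + laMD[k - 1], vcD[k - 1] + ltDD[k - 1]);

      if (local) {
        const double tail = (double)(n - i) * leta;
        double Ei = vcD[L - 1];
        for (int k = 0; k < L; ++k) Ei = std::max(Ei, vcM[k] + leps[k]);
        vbest = std::max(vbest, Ei + tail);
      } else if (i == n) {
        vbest = std::max(vcM[L - 1], vcD[L - 1]);
      }
      std::swap(vpM, vcM); std::swap(vpI, vcI); std::swap(vpD, vcD);
    }
    if (local) vbest += lout;

    out(s, 0) = vbest;
    out(s, 1) = fwd;
  }
  return out;
}
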