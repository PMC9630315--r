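#include <Rcpp.h>
using namespace Rcpp;

// Enumerate all maximal collinear (gapless) windows between a third-strand
// sequence and a purine-strand sequence under a pairing-rule matrix.
//
// tfo, pur: integer base codes in 1..4 (A, C, G, T); allowed: 4x4 logical
// matrix, rows indexed by the third-strand base, columns by the duplex
// purine-strand base. A window (i, j, len) pairs tfo[i + k] with pur[j + k]
// for k in 0..len-1 (both 0-based). A window is valid when len >= min_len
// and mismatches <= max_err * len (small epsilon absorbs float noise); it
// is maximal when neither single-position extension (left or right,
// staying in bounds) is itself valid.
//
// Validity is evaluated through the slack h[i] = pre[i] - max_err * i
// (pre = prefix mismatch count along the diagonal): window [s, e) is valid
// iff h[e] <= h[s]. Suffix minima of h prune the inner loop exactly: once
// no later endpoint can satisfy h[e] <= h[s], the scan for this start
// stops.
//
// Returns an integer matrix with columns tfo_start, pur_start, len,
// mismatches (starts 0-based).
// [[Rcpp::export]]
IntegerMatrix scan_maximal_windows(IntegerVector tfo, IntegerVector pur,
                                   LogicalMatrix allowed, int min_len,
                                   double max_err) {
  const int nT = tfo.size(), nP = pur.size();
  for (int i = 0; i < nT; ++i)
    if (tfo[i] == NA_INTEGER || tfo[i] < 1 || tfo[i] > 4)
      stop("invalid tfo base code");
  for (int i = 0; i < nP; ++i)
    if (pur[i] == NA_INTEGER || pur[i] < 1 || pur[i] > 4)
      stop("invalid duplex base code");
  std::vector<int> out;
  if (nT < min_len || nP < min_len)
    return IntegerMatrix(0, 4);

  const double eps = 1e-9;
  std::vector<int> pre;
  std::vector<double> h, sufmin;

  // Each diagonal starts at (i0, 0) or (0, j0).
  for (int d = -(nT - 1); d <= nP - 1; ++d) {
    const int i0 = d < 0 ? -d : 0;
    const int j0 = d < 0 ? 0 : d;
    const int M = std::min(nT - i0, nP - j0);
    if (M < min_len) continue;

    pre.assign(M + 1, 0);
    h.assign(M + 1, 0.0);
    for (int k = 0; k < M; ++k) {
      const bool ok = allowed(tfo[i0 + k] - 1, pur[j0 + k] - 1);
      pre[k + 1] = pre[k] + (ok ? 0 : 1);
      h[k + 1] = pre[k + 1] - max_err * (k + 1);
    }
    sufmin.assign(M + 1, 0.0);
    sufmin[M] = h[M];
    for (int k = M - 1; k >= 0; --k)
      sufmin[k] = std::min(h[k], sufmin[k + 1]);

    for (int s = 0; s + min_len <= M; ++s) {
      const double hs = h[s] + eps;
      for (int e = s + min_len; e <= M; ++e) {
        if (sufmin[e] > hs) break;        // no later endpoint can be valid
        if (h[e] > hs) continue;
        // maximality: both one-base extensions must be invalid
        if (s > 0 && h[e] <= h[s - 1] + eps) continue;
        if (e < M && h[e + 1] <= hs) continue;
        out.push_back(i0 + s);
        out.push_back(j0 + s);
        out.push_back(e - s);
        out.push_back(pre[e] - pre[s]);
      }
    }
  }

  const int n = (int) out.size() / 4;
  IntegerMatrix res(n, 4);
  for (int r = 0; r < n; ++r)
    for (int c = 0; c < 4; ++c) res(r, c) = out[4 * r + c];
  colnames(res) = CharacterVector::create("tfo_start", "pur_start", "len",
                                          "mismatches");
  return res;
}

// Internal fast path for the randomization machinery: scans one duplex
// plus strand (integer codes) against a TFO under up to two motifs on both
// strands, collecting the RNA-side intervals (0-based start, length) of
// all maximal valid windows with >= 1 matched position. Semantics are
// identical to repeated scan_maximal_windows calls with the appropriate
// orientation handling; only the packaging differs.
// [[Rcpp::export]]
IntegerMatrix scan_region_hits(IntegerVector tfo, IntegerVector pur,
                               LogicalMatrix codePar, LogicalMatrix codeAnti,
                               bool usePar, bool useAnti, int min_len,
                               double max_err) {
  const int nT = tfo.size(), nP = pur.size();
  for (int i = 0; i < nT; ++i)
    if (tfo[i] == NA_INTEGER || tfo[i] < 1 || tfo[i] > 4)
      stop("invalid tfo base code");
  for (int i = 0; i < nP; ++i)
    if (pur[i] == NA_INTEGER || pur[i] < 1 || pur[i] > 4)
      stop("invalid duplex base code");
  std::vector<int> out;
  if (nT >= min_len && nP >= min_len) {
    const double eps = 1e-9;
    bool par[16], anti[16];
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        par[4 * a + b] = codePar(a, b);
        anti[4 * a + b] = codeAnti(a, b);
      }
    std::vector<int> tfwd(nT), trev(nT), pplus(nP), pminus(nP);
    for (int i = 0; i < nT; ++i) tfwd[i] = tfo[i] - 1;
    for (int i = 0; i < nT; ++i) trev[i] = tfwd[nT - 1 - i];
    for (int i = 0; i < nP; ++i) pplus[i] = pur[i] - 1;
    for (int i = 0; i < nP; ++i) pminus[i] = 3 - pplus[nP - 1 - i];

    std::vector<int> pre(std::min(nT, nP) + 1);
    std::vector<double> h(std::min(nT, nP) + 1),
        sufmin(std::min(nT, nP) + 1);

    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<int>& P = strand == 0 ? pplus : pminus;
      for (int motif = 0; motif < 2; ++motif) {
        if (motif == 0 ? !useAnti : !usePar) continue;
        const bool* code = motif == 0 ? anti : par;
        const std::vector<int>& T = motif == 0 ? trev : tfwd;
        for (int d = -(nT - 1); d <= nP - 1; ++d) {
          const int i0 = d < 0 ? -d : 0;
          const int j0 = d < 0 ? 0 : d;
          const int M = std::min(nT - i0, nP - j0);
          if (M < min_len) continue;
          bool anyValid = false;
          double runmax = 0.0;  // max over h[0 .. k - min_len]
          for (int k = 0; k < M; ++k) {
            const bool ok = code[4 * T[i0 + k] + P[j0 + k]];
            pre[k + 1] = pre[k] + (ok ? 0 : 1);
            h[k + 1] = pre[k + 1] - max_err * (k + 1);
            if (k + 1 >= min_len) {
              if (h[k + 1 - min_len] > runmax) runmax = h[k + 1 - min_len];
              if (h[k + 1] <= runmax + 1e-9) anyValid = true;
            }
          }
          if (!anyValid) continue;
          sufmin[M] = h[M];
          for (int k = M - 1; k >= 0; --k)
            sufmin[k] = std::min(h[k], sufmin[k + 1]);
          for (int s = 0; s + min_len <= M; ++s) {
            const double hs = h[s] + eps;
            for (int e = s + min_len; e <= M; ++e) {
              if (sufmin[e] > hs) break;
              if (h[e] > hs) continue;
              if (s > 0 && h[e] <= h[s - 1] + eps) continue;
              if (e < M && h[e + 1] <= hs) continue;
              const int len = e - s, mm = pre[e] - pre[s];
              if (len - mm < 1) continue;
              // RNA-side 0-based start in the original TFO orientation
              const int t0 = motif == 0 ? nT - (i0 + s + len) : i0 + s;
              out.push_back(t0);
              out.push_back(len);
            }
          }
        }
      }
    }
  }
  const int n = (int) out.size() / 2;
  IntegerMatrix res(n, 2);
  for (int r = 0; r < n; ++r) {
    res(r, 0) = out[2 * r];
    res(r, 1) = out[2 * r + 1];
  }
  return res;
}
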