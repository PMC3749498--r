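#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment identity between two nucleotide
// strings: match +1, mismatch -1, gap -2 (a substitution is always cheaper
// than a gap pair, so point mutations stay aligned as mismatch columns).
// Returns matches / alignment-columns of one optimal alignment, with the
// deterministic tie order diagonal > up > left.
static double nw_identity_one(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  const int MATCH = 1, MISMATCH = -1, GAP = -2;
  // banded DP: an alignment keeping identity near the duplicate-filter
  // threshold can hold at most ~3% gap columns, so the optimal path of
  // any pair that could pass stays within this diagonal band; pairs
  // whose optimum leaves the band score far below the threshold anyway
  const int band = std::max(16, (int)(0.04 * std::max(n, m)) + 2) +
    std::abs(n - m);
  const int NEG = -1000000000;
  std::vector<int> prev(m + 1, NEG), cur(m + 1, NEG);
  std::vector<unsigned char> ptr((n + 1) * (m + 1), 0); // 1=diag 2=up 3=left
  for (int j = 0; j <= std::min(m, band); ++j) {
    prev[j] = GAP * j;
    ptr[j] = 3;
  }
  ptr[0] = 0;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i - band), jhi = std::min(m, i + band);
    if (jlo > 1) cur[jlo - 1] = NEG;
    cur[0] = (i <= band) ? GAP * i : NEG;
    if (i <= band) ptr[i * (m + 1)] = 2;
    for (int j = jlo; j <= jhi; ++j) {
      int sdiag = prev[j - 1] + (a[i - 1] == b[j - 1] ? MATCH : MISMATCH);
      int sup = prev[j] + GAP;
      int sleft = cur[j - 1] + GAP;
      int best = sdiag; unsigned char p = 1;
      if (sup > best) { best = sup; p = 2; }
      if (sleft > best) { best = sleft; p = 3; }
      cur[j] = best;
      ptr[i * (m + 1) + j] = p;
    }
    if (jhi < m) cur[jhi + 1] = NEG;
    std::swap(prev, cur);
  }
  int i = n, j = m, matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    unsigned char p = ptr[i * (m + 1) + j];
    if (p == 1) { if (a[i - 1] == b[j - 1]) ++matches; --i; --j; }
    else if (p == 2) { --i; }
    else { --j; }
    ++cols;
  }
  return (double)matches / (double)cols;
}

// [[Rcpp::export(name = ".nw_identity")]]
NumericVector nw_identity_cpp(CharacterVector query, CharacterVector refs) {
  if (query.size() != 1 && query.size() != refs.size())
    stop("query must be length 1 or match refs");
  int n = refs.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string q = as<std::string>(query[query.size() == 1 ? 0 : k]);
    std::string r = as<std::string>(refs[k]);
    out[k] = nw_identity_one(q, r);
  }
  return out;
}

// Best ungapped alignment score of a position-specific score matrix against
// a peptide over all offsets with >= min_overlap aligned columns. pssm is
// L x 27 (rows = profile columns, cols = 'A'..'Z' plus a final default
// column for residues outside A..Z).
// [[Rcpp::export(name = ".pssm_best_scores")]]
NumericVector pssm_best_scores_cpp(CharacterVector peptides, NumericMatrix pssm,
                                   int min_overlap) {
  const int L = pssm.nrow();
  const int n = peptides.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string p = as<std::string>(peptides[k]);
    const int m = p.size();
    const int ov = std::min(min_overlap, std::min(L, m));
    double best = R_NegInf;
    // offset o: profile column i aligns to peptide position o + i
    for (int o = -(L - ov); o <= m - ov; ++o) {
      int i0 = std::max(0, -o);
      int i1 = std::min(L, m - o);
      if (i1 - i0 < ov) continue;
      double s = 0.0;
      for (int i = i0; i < i1; ++i) {
        char c = p[o + i];
        int col = (c >= 'A' && c <= 'Z') ? (c - 'A') : 26;
        s += pssm(i, col);
      }
      if (s > best) best = s;
    }
    out[k] = (best == R_NegInf) ? NA_REAL : best;
  }
  return out;
}
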