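#include <Rcpp.h>
using namespace Rcpp;

// Semi-global (occurrence) edit-distance search of a short pattern in each
// subject: gaps before/after the occurrence in the subject are free, the
// whole pattern must be consumed. Returns, per subject, the minimal edit
// distance and the 1-based subject position where the best (leftmost-ending
// among ties) occurrence ends.
// [[Rcpp::export(name = ".semiglobal_search")]]
IntegerMatrix semiglobal_search(std::string pattern, CharacterVector subjects) {
  const int m = pattern.size();
  const int ns = subjects.size();
  IntegerMatrix out(ns, 2);
  colnames(out) = CharacterVector::create("edits", "end");
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int s = 0; s < ns; ++s) {
    std::string subj = as<std::string>(subjects[s]);
    const int n = subj.size();
    int best = m, bestEnd = 0; // matching nothing costs m deletions
    for (int i = 0; i <= m; ++i) prev[i] = i;
    for (int j = 1; j <= n; ++j) {
      cur[0] = 0; // free leading gap in subject
      for (int i = 1; i <= m; ++i) {
        int sub = prev[i - 1] + (pattern[i - 1] == subj[j - 1] ? 0 : 1);
        int del = prev[i] + 1;
        int ins = cur[i - 1] + 1;
        cur[i] = std::min(sub, std::min(del, ins));
      }
      if (cur[m] < best) { best = cur[m]; bestEnd = j; }
      std::swap(prev, cur);
    }
    out(s, 0) = best;
    out(s, 1) = bestEnd;
  }
  return out;
}

// Bounded Levenshtein distance between one query and many candidates with
// early exit once the running minimum exceeds maxDist (used for barcode and
// UMI comparisons; all strings are short).
// [[Rcpp::export(name = ".bounded_levenshtein")]]
IntegerVector bounded_levenshtein(std::string query, CharacterVector candidates,
                                  int maxDist) {
  const int m = query.size();
  const int nc = candidates.size();
  IntegerVector out(nc);
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int c = 0; c < nc; ++c) {
    std::string cand = as<std::string>(candidates[c]);
    const int n = cand.size();
    if (std::abs(n - m) > maxDist) { out[c] = maxDist + 1; continue; }
    for (int i = 0; i <= m; ++i) prev[i] = i;
    int dist = m;
    for (int j = 1; j <= n; ++j) {
      cur[0] = j;
      int rowMin = j;
      for (int i = 1; i <= m; ++i) {
        int sub = prev[i - 1] + (query[i - 1] == cand[j - 1] ? 0 : 1);
        cur[i] = std::min(sub, std::min(prev[i] + 1, cur[i - 1] + 1));
        rowMin = std::min(rowMin, cur[i]);
      }
      std::swap(prev, cur);
      if (rowMin > maxDist) { dist = maxDist + 1; break; }
      dist = prev[m];
    }
    out[c] = dist;
  }
  return out;
}
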