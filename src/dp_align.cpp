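#include <Rcpp.h>
using namespace Rcpp;

// Dynamic program over label index i and site index j with transitions
// {match, skip-label, skip-site}.  A match between label i and site j is
// allowed only when |labels[i] - sites[j]| <= width and contributes
// match_score * (1 - |d|/width) (or a flat match_score when flat = true);
// skipping a site costs miss_pen, skipping a label costs extra_pen.  With
// free_ends, terminal skipped sites are free.  Ties are broken by number of
// matches (more is better), then by preferring the lexicographically
// smallest pair list in the traceback (match > skip-site > skip-label).
//
// Returns the optimal score, the matched (label, site) pairs (1-based) and
// the match count.

static const double EPS = 1e-9;

// [[Rcpp::export]]
List dp_align_cpp(NumericVector labels, NumericVector sites,
                  double width, double match_score,
                  double miss_pen, double extra_pen,
                  bool free_ends, bool flat, bool local) {
  int L = labels.size(), S = sites.size();
  // DP tables: score and match count; backpointer 0=none,1=match,2=skip
  // label (i-1,j), 3=skip site (i,j-1), 4=local restart
  NumericMatrix sc(L + 1, S + 1);
  IntegerMatrix mc(L + 1, S + 1), bp(L + 1, S + 1);
  sc(0, 0) = 0; mc(0, 0) = 0; bp(0, 0) = 0;
  for (int i = 1; i <= L; ++i) {
    sc(i, 0) = sc(i - 1, 0) - extra_pen;
    mc(i, 0) = 0; bp(i, 0) = 2;
    if (local && sc(i, 0) < 0) { sc(i, 0) = 0; bp(i, 0) = 4; }
  }
  for (int j = 1; j <= S; ++j) {
    sc(0, j) = free_ends ? 0.0 : sc(0, j - 1) - miss_pen;
    mc(0, j) = 0; bp(0, j) = 3;
    if (local && sc(0, j) < 0) { sc(0, j) = 0; bp(0, j) = 4; }
  }
  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= S; ++j) {
      // preference order encodes the lexicographic tie-break
      double best = sc(i - 1, j - 1) - 1e300; // sentinel low
      int bmc = -1, bbp = 0;
      double d = fabs(labels[i - 1] - sites[j - 1]);
      if (d <= width + EPS) {
        double m = sc(i - 1, j - 1) +
          (flat ? match_score : match_score * std::max(0.0, 1.0 - d / width));
        best = m; bmc = mc(i - 1, j - 1) + 1; bbp = 1;
      }
      double ss = sc(i, j - 1) - miss_pen;   // skip site j
      if (ss > best + EPS || (ss > best - EPS && mc(i, j - 1) > bmc)) {
        best = ss; bmc = mc(i, j - 1); bbp = 3;
      }
      double sl = sc(i - 1, j) - extra_pen;  // skip label i
      if (sl > best + EPS || (sl > best - EPS && mc(i - 1, j) > bmc)) {
        best = sl; bmc = mc(i - 1, j); bbp = 2;
      }
      if (local && best < 0) { best = 0; bmc = 0; bbp = 4; }
      sc(i, j) = best; mc(i, j) = bmc; bp(i, j) = bbp;
    }
  }
  // terminal: with free_ends the remaining sites after the last matched one
  // are free, i.e. take the best over sc(L, j) for any j
  int endj = S;
  double fin = sc(L, S); int finm = mc(L, S);
  if (free_ends) {
    for (int j = S; j >= 0; --j) {
      if (sc(L, j) > fin + EPS ||
          (sc(L, j) > fin - EPS && mc(L, j) > finm)) {
        fin = sc(L, j); finm = mc(L, j); endj = j;
      }
    }
  }
  if (local) {
    for (int i = 0; i <= L; ++i) for (int j = 0; j <= S; ++j) {
      if (sc(i, j) > fin + EPS) { fin = sc(i, j); finm = mc(i, j); }
    }
  }
  // traceback (global / free-end path)
  std::vector<int> pl, ps;
  int i = L, j = endj;
  while (i > 0 || j > 0) {
    int b = bp(i, j);
    if (i == 0) { j--; continue; }
    if (j == 0) { i--; continue; }
    if (b == 1) { pl.push_back(i); ps.push_back(j); i--; j--; }
    else if (b == 2) i--;
    else if (b == 3) j--;
    else break; // local restart
  }
  std::reverse(pl.begin(), pl.end());
  std::reverse(ps.begin(), ps.end());
  IntegerMatrix pairs(pl.size(), 2);
  for (size_t k = 0; k < pl.size(); ++k) {
    pairs(k, 0) = pl[k]; pairs(k, 1) = ps[k];
  }
  return List::create(_["score"] = fin, _["matches"] = finm,
                      _["pairs"] = pairs);
}
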