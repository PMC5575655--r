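#include <Rcpp.h>
#include <string>
#include <algorithm>

// Best windowed base-pairing score between a query sequence and the reverse
// complement of a target. The caller passes the target already
// reverse-complemented, so complementarity reduces to identity matching.
// Every ungapped alignment (diagonal) of the two strings is scanned with a
// rolling window of length w; the score is the maximum fraction of matching
// positions in any window. Overlaps shorter than w are skipped.
// [[Rcpp::export]]
double cpp_complementarity(std::string a, std::string b_rc, int window) {
  const int la = a.size(), lb = b_rc.size();
  if (la == 0 || lb == 0) Rcpp::stop("empty sequence");
  int w = std::min(window, std::min(la, lb));
  if (w < 1) w = 1;
  double best = 0.0;
  // offset s aligns a[i] with b_rc[i + s]
  for (int s = -(la - w); s <= lb - w; ++s) {
    const int i0 = std::max(0, -s);
    const int i1 = std::min(la, lb - s);
    const int len = i1 - i0;
    if (len < w) continue;
    int run = 0;
    for (int i = i0; i < i0 + w; ++i) run += (a[i] == b_rc[i + s]);
    int best_run = run;
    for (int i = i0 + w; i < i1; ++i) {
      run += (a[i] == b_rc[i + s]) - (a[i - w] == b_rc[i - w + s]);
      if (run > best_run) best_run = run;
    }
    const double frac = static_cast<double>(best_run) / w;
    if (frac > best) best = frac;
    if (best == 1.0) return 1.0;
  }
  return best;
}
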