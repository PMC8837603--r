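#include <Rcpp.h>
using namespace Rcpp;

// Needleman-Wunsch on two alignment profiles (columns = frequency vectors
// over A,C,G,T,gap). Expected-score column scoring: residue pairs score
// match/mismatch, residue-vs-existing-gap scores `gap`, gap-gap scores 0;
// inserting a new gap column costs `gap`. Traceback prefers diagonal, then
// up (gap in profile B), then left (gap in profile A), which makes the
// merge deterministic.
//
// prof matrices are 5 x L (rows A,C,G,T,-). Returns a 2 x ncol integer
// matrix of 1-based source column indices (0 = new gap).
// [[Rcpp::export(name = ".nw_profile")]]
IntegerMatrix nw_profile(NumericMatrix pa, NumericMatrix pb,
                         double match, double mismatch, double gap) {
  const int la = pa.ncol(), lb = pb.ncol();
  NumericMatrix M(la + 1, lb + 1);
  IntegerMatrix tb(la + 1, lb + 1); // 1 diag, 2 up, 3 left
  for (int i = 1; i <= la; ++i) { M(i, 0) = i * gap; tb(i, 0) = 2; }
  for (int j = 1; j <= lb; ++j) { M(0, j) = j * gap; tb(0, j) = 3; }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double s = 0.0;
      double resa = 0.0, resb = 0.0;
      for (int x = 0; x < 4; ++x) { resa += pa(x, i - 1); resb += pb(x, j - 1); }
      for (int x = 0; x < 4; ++x) {
        for (int y = 0; y < 4; ++y) {
          s += pa(x, i - 1) * pb(y, j - 1) * (x == y ? match : mismatch);
        }
      }
      s += (pa(4, i - 1) * resb + pb(4, j - 1) * resa) * gap;
      double d = M(i - 1, j - 1) + s;
      double u = M(i - 1, j) + gap;
      double l = M(i, j - 1) + gap;
      if (d >= u && d >= l)      { M(i, j) = d; tb(i, j) = 1; }
      else if (u >= l)           { M(i, j) = u; tb(i, j) = 2; }
      else                       { M(i, j) = l; tb(i, j) = 3; }
    }
  }
  std::vector<int> ia, ib;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    int t = tb(i, j);
    if (t == 1)      { ia.push_back(i); ib.push_back(j); --i; --j; }
    else if (t == 2) { ia.push_back(i); ib.push_back(0); --i; }
    else             { ia.push_back(0); ib.push_back(j); --j; }
  }
  const int n = (int)ia.size();
  IntegerMatrix out(2, n);
  for (int k = 0; k < n; ++k) {
    out(0, k) = ia[n - 1 - k];
    out(1, k) = ib[n - 1 - k];
  }
  return out;
}
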