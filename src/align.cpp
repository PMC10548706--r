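#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gap penalties (Gotoh).
// A gap of length k costs gap_open + (k - 1) * gap_extend.
// Sequences arrive as 0-based row/column indices into the scoring matrix.
// Deterministic tie-breaking: at every cell the traceback prefers the
// diagonal (match) state, then the up state (gap in b, consuming a), then
// the left state (gap in a, consuming b).

static const double NEG_INF = -1e18;

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  // state layers: 0 = M (diag), 1 = X (up, gap in b), 2 = Y (left, gap in a)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // traceback: which state the best path entered this cell's state from
  std::vector<signed char> tbM((n + 1) * (m + 1), -1);
  std::vector<signed char> tbX((n + 1) * (m + 1), -1);
  std::vector<signed char> tbY((n + 1) * (m + 1), -1);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -(gap_open + (i - 1) * gap_extend);
    tbX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -(gap_open + (j - 1) * gap_extend);
    tbY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = S(a[i - 1], b[j - 1]);
      // M: from any state at (i-1, j-1); preference M > X > Y on ties
      {
        double best = M[at(i - 1, j - 1)];
        signed char st = 0;
        if (X[at(i - 1, j - 1)] > best) { best = X[at(i - 1, j - 1)]; st = 1; }
        if (Y[at(i - 1, j - 1)] > best) { best = Y[at(i - 1, j - 1)]; st = 2; }
        if (best > NEG_INF / 2) { M[at(i, j)] = best + s; tbM[at(i, j)] = st; }
      }
      // X: consume a[i-1]; open from M/Y, extend from X
      {
        double best = M[at(i - 1, j)] - gap_open;
        signed char st = 0;
        if (X[at(i - 1, j)] - gap_extend > best) { best = X[at(i - 1, j)] - gap_extend; st = 1; }
        if (Y[at(i - 1, j)] - gap_open > best) { best = Y[at(i - 1, j)] - gap_open; st = 2; }
        if (best > NEG_INF / 2) { X[at(i, j)] = best; tbX[at(i, j)] = st; }
      }
      // Y: consume b[j-1]
      {
        double best = M[at(i, j - 1)] - gap_open;
        signed char st = 0;
        if (X[at(i, j - 1)] - gap_open > best) { best = X[at(i, j - 1)] - gap_open; st = 1; }
        if (Y[at(i, j - 1)] - gap_extend > best) { best = Y[at(i, j - 1)] - gap_extend; st = 2; }
        if (best > NEG_INF / 2) { Y[at(i, j)] = best; tbY[at(i, j)] = st; }
      }
    }
  }

  double score = M[at(n, m)];
  signed char state = 0;
  if (X[at(n, m)] > score) { score = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > score) { score = Y[at(n, m)]; state = 2; }

  // traceback
  std::vector<int> ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    signed char prev;
    if (state == 0) {
      prev = tbM[at(i, j)];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
    } else if (state == 1) {
      prev = tbX[at(i, j)];
      ra.push_back(a[i - 1]); rb.push_back(-1);
      --i;
    } else {
      prev = tbY[at(i, j)];
      ra.push_back(-1); rb.push_back(b[j - 1]);
      --j;
    }
    state = prev;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["score"] = score,
                      _["aln_a"] = IntegerVector(ra.begin(), ra.end()),
                      _["aln_b"] = IntegerVector(rb.begin(), rb.end()));
}

// Count shared k-mers between two index vectors via sorted k-mer codes.
// Used only as a prefilter before full alignment.
// [[Rcpp::export]]
int shared_kmer_count_cpp(IntegerVector codes_a, IntegerVector codes_b) {
  std::vector<int> va(codes_a.begin(), codes_a.end());
  std::vector<int> vb(codes_b.begin(), codes_b.end());
  std::sort(va.begin(), va.end());
  std::sort(vb.begin(), vb.end());
  va.erase(std::unique(va.begin(), va.end()), va.end());
  vb.erase(std::unique(vb.begin(), vb.end()), vb.end());
  std::vector<int> out;
  std::set_intersection(va.begin(), va.end(), vb.begin(), vb.end(),
                        std::back_inserter(out));
  return (int)out.size();
}
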