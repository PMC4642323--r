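#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Needleman-Wunsch global alignment with affine gaps (Gotoh's three-state
// recursion). A gap of length L costs gap_open + L * gap_ext. End gaps are
// penalized. Tie-breaking in the traceback is deterministic: diagonal (match
// state) preferred, then a gap in the second sequence, then in the first.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b, NumericMatrix submat,
                 double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  // residue -> row index of the substitution matrix
  std::vector<int> lut(256, -1);
  CharacterVector rn = rownames(submat);
  for (int i = 0; i < rn.size(); ++i) {
    std::string s = as<std::string>(rn[i]);
    if (s.size() == 1) lut[(unsigned char)s[0]] = i;
  }
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = lut[(unsigned char)a[i]];
    if (ai[i] < 0) stop("residue '%s' not in substitution matrix",
                        std::string(1, a[i]));
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = lut[(unsigned char)b[j]];
    if (bi[j] < 0) stop("residue '%s' not in substitution matrix",
                        std::string(1, b[j]));
  }

  const double open1 = gap_open + gap_ext;  // cost of a length-1 gap
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // traceback: which predecessor state fed each cell (0 = M, 1 = X, 2 = Y)
  std::vector<unsigned char> tbM((n + 1) * W), tbX((n + 1) * W),
      tbY((n + 1) * W);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -(gap_open + i * gap_ext);
    tbX[i * W] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(gap_open + j * gap_ext);
    tbY[j] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
                l = i * W + (j - 1);
      // M: a[i] aligned to b[j]
      double best = M[d]; unsigned char arg = 0;
      if (X[d] > best) { best = X[d]; arg = 1; }
      if (Y[d] > best) { best = Y[d]; arg = 2; }
      M[c] = best + submat(ai[i - 1], bi[j - 1]);
      tbM[c] = arg;
      // X: a[i] aligned to a gap
      best = M[u] - open1; arg = 0;
      if (X[u] - gap_ext > best) { best = X[u] - gap_ext; arg = 1; }
      if (Y[u] - open1 > best) { best = Y[u] - open1; arg = 2; }
      X[c] = best; tbX[c] = arg;
      // Y: b[j] aligned to a gap
      best = M[l] - open1; arg = 0;
      if (X[l] - open1 > best) { best = X[l] - open1; arg = 1; }
      if (Y[l] - gap_ext > best) { best = Y[l] - gap_ext; arg = 2; }
      Y[c] = best; tbY[c] = arg;
    }
  }

  const int end = n * W + m;
  double score = M[end]; int state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tbM[i * W + j];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tbX[i * W + j];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = prev;
    } else {
      int prev = tbY[i * W + j];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["score"] = score, _["aligned_a"] = ra,
                      _["aligned_b"] = rb);
}
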