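#include <Rcpp.h>
using namespace Rcpp;

// Global pairwise alignment with affine gaps (Gotoh three-state DP).
// Gap run of length L costs gap_open + (L - 1) * gap_extend; both are
// negative scores. Traceback prefers match state, then a gap in b, then a
// gap in a, making the reported alignment deterministic among co-optima.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix submat,
                  double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  // residue -> submat index lookup from the matrix dimnames
  std::vector<int> lut(256, -1);
  CharacterVector rn = rownames(submat);
  for (int i = 0; i < rn.size(); ++i) {
    std::string s = as<std::string>(rn[i]);
    if (s.size() == 1) lut[(unsigned char)s[0]] = i;
  }
  CharacterVector cn = colnames(submat);
  for (int i = 0; i < cn.size(); ++i) {
    std::string s = as<std::string>(cn[i]);
    if (s.size() == 1 && lut[(unsigned char)s[0]] < 0)
      lut[(unsigned char)s[0]] = i;
  }
  int xi = lut[(unsigned char)'X'];  // unknown residues score as X when present
  for (int i = 0; i < n; ++i)
    if (lut[(unsigned char)a[i]] < 0 && xi < 0)
      stop("residue '%s' not in substitution matrix", std::string(1, a[i]));
  for (int j = 0; j < m; ++j)
    if (lut[(unsigned char)b[j]] < 0 && xi < 0)
      stop("residue '%s' not in substitution matrix", std::string(1, b[j]));

  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ix((n + 1) * (m + 1), NEG_INF); // gap in b, consumes a
  std::vector<double> Iy((n + 1) * (m + 1), NEG_INF); // gap in a, consumes b
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) Ix[at(i, 0)] = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Iy[at(0, j)] = gap_open + (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    int ra = lut[(unsigned char)a[i - 1]]; if (ra < 0) ra = xi;
    for (int j = 1; j <= m; ++j) {
      int rb = lut[(unsigned char)b[j - 1]]; if (rb < 0) rb = xi;
      double s = submat(ra, rb);
      double dm = std::max(M[at(i - 1, j - 1)],
                           std::max(Ix[at(i - 1, j - 1)], Iy[at(i - 1, j - 1)]));
      M[at(i, j)] = dm + s;
      Ix[at(i, j)] = std::max(std::max(M[at(i - 1, j)] + gap_open,
                                       Ix[at(i - 1, j)] + gap_extend),
                              Iy[at(i - 1, j)] + gap_open);
      Iy[at(i, j)] = std::max(std::max(M[at(i, j - 1)] + gap_open,
                                       Iy[at(i, j - 1)] + gap_extend),
                              Ix[at(i, j - 1)] + gap_open);
    }
  }

  double best = std::max(M[at(n, m)], std::max(Ix[at(n, m)], Iy[at(n, m)]));

  // traceback
  std::string ra_s, rb_s;
  int i = n, j = m;
  int state; // 0 = M, 1 = Ix, 2 = Iy
  if (best == M[at(n, m)]) state = 0;
  else if (best == Ix[at(n, m)]) state = 1;
  else state = 2;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) stop("internal traceback error");
      int rra = lut[(unsigned char)a[i - 1]]; if (rra < 0) rra = xi;
      int rrb = lut[(unsigned char)b[j - 1]]; if (rrb < 0) rrb = xi;
      double s = submat(rra, rrb);
      double prev = M[at(i, j)] - s;
      ra_s.push_back(a[i - 1]); rb_s.push_back(b[j - 1]);
      --i; --j;
      if (std::abs(prev - M[at(i, j)]) < eps) state = 0;
      else if (std::abs(prev - Ix[at(i, j)]) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      if (i == 0) stop("internal traceback error");
      double cur = Ix[at(i, j)];
      ra_s.push_back(a[i - 1]); rb_s.push_back('-');
      --i;
      if (std::abs(cur - (M[at(i, j)] + gap_open)) < eps) state = 0;
      else if (std::abs(cur - (Ix[at(i, j)] + gap_extend)) < eps) state = 1;
      else state = 2;
    } else {
      if (j == 0) stop("internal traceback error");
      double cur = Iy[at(i, j)];
      ra_s.push_back('-'); rb_s.push_back(b[j - 1]);
      --j;
      if (std::abs(cur - (M[at(i, j)] + gap_open)) < eps) state = 0;
      else if (std::abs(cur - (Iy[at(i, j)] + gap_extend)) < eps) state = 2;
      else state = 1;
    }
  }
  std::reverse(ra_s.begin(), ra_s.end());
  std::reverse(rb_s.begin(), rb_s.end());

  int matches = 0, cols = ra_s.size();
  for (int k = 0; k < cols; ++k)
    if (ra_s[k] == rb_s[k] && ra_s[k] != '-') ++matches;

  return List::create(_["score"] = best,
                      _["a"] = ra_s, _["b"] = rb_s,
                      _["identity"] = cols > 0 ? (double)matches / cols : 0.0);
}
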