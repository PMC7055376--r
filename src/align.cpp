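#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap pairwise alignment over integer-encoded residues.
//
// Scoring convention follows protein BLAST: a gap of length k costs
// gap_open + k * gap_extend (the opening charge is in addition to the
// per-residue extension, including the first gapped residue).
//
// States: M (a[i] aligned to b[j]), X (gap in b, i.e. a-residue against
// gap), Y (gap in a). Traceback preference on ties: M > X > Y, and within
// M the diagonal predecessor order M > X > Y. This makes the reported
// alignment deterministic; the optimal score is unique regardless.

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                 double gap_open, double gap_extend, bool local) {
  const int n = a.size(), m = b.size();
  // DP matrices, (n+1) x (m+1), row-major via index i*(m+1)+j
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  const double gopen = -(gap_open + gap_extend);
  const double gext = -gap_extend;
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    if (local) {
      M[idx(i, 0)] = 0.0;
    } else {
      X[idx(i, 0)] = gopen + gext * (i - 1);
    }
  }
  for (int j = 1; j <= m; ++j) {
    if (local) {
      M[idx(0, j)] = 0.0;
    } else {
      Y[idx(0, j)] = gopen + gext * (j - 1);
    }
  }

  double best = 0.0;
  int best_i = 0, best_j = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = sub(a[i - 1], b[j - 1]);
      double dm = M[idx(i - 1, j - 1)], dx = X[idx(i - 1, j - 1)],
             dy = Y[idx(i - 1, j - 1)];
      double d = std::max(dm, std::max(dx, dy));
      double mval = (d <= NEG_INF / 2) ? NEG_INF : d + s;
      if (local && mval < 0) mval = 0.0;
      M[idx(i, j)] = mval;

      double xo = M[idx(i - 1, j)] + gopen;
      double xe = X[idx(i - 1, j)] + gext;
      X[idx(i, j)] = std::max(xo, xe);

      double yo = M[idx(i, j - 1)] + gopen;
      double ye = Y[idx(i, j - 1)] + gext;
      Y[idx(i, j)] = std::max(yo, ye);

      if (local && M[idx(i, j)] > best) {
        best = M[idx(i, j)];
        best_i = i;
        best_j = j;
      }
    }
  }

  int ti, tj;
  char state;
  double score;
  if (local) {
    score = best;
    ti = best_i;
    tj = best_j;
    state = 'M';
  } else {
    ti = n;
    tj = m;
    double em = M[idx(n, m)], ex = X[idx(n, m)], ey = Y[idx(n, m)];
    score = std::max(em, std::max(ex, ey));
    state = (score == em) ? 'M' : (score == ex ? 'X' : 'Y');
  }

  // Traceback
  std::string aln_a, aln_b;
  int i = ti, j = tj;
  while (true) {
    if (local) {
      if (state == 'M' && M[idx(i, j)] == 0.0) break;
    }
    if (i == 0 && j == 0) break;
    if (state == 'M') {
      const double s = sub(a[i - 1], b[j - 1]);
      double cur = M[idx(i, j)];
      double dm = M[idx(i - 1, j - 1)], dx = X[idx(i - 1, j - 1)],
             dy = Y[idx(i - 1, j - 1)];
      aln_a.push_back('A');
      aln_b.push_back('B');
      if (cur == dm + s)
        state = 'M';
      else if (cur == dx + s)
        state = 'X';
      else
        state = 'Y';
      --i;
      --j;
    } else if (state == 'X') {  // gap in b, consume a[i]
      double cur = X[idx(i, j)];
      aln_a.push_back('A');
      aln_b.push_back('-');
      state = (cur == M[idx(i - 1, j)] + gopen) ? 'M' : 'X';
      --i;
    } else {  // gap in a, consume b[j]
      double cur = Y[idx(i, j)];
      aln_a.push_back('-');
      aln_b.push_back('B');
      state = (cur == M[idx(i, j - 1)] + gopen) ? 'M' : 'Y';
      --j;
    }
  }
  const int start_a = i + 1, start_b = j + 1;  // 1-based starts of aligned span

  // Decode placeholder letters into index walks:
  std::reverse(aln_a.begin(), aln_a.end());
  std::reverse(aln_b.begin(), aln_b.end());
  IntegerVector ia(aln_a.size()), ib(aln_b.size());
  int pa = start_a - 1, pb = start_b - 1;  // 0-based cursors
  for (size_t k = 0; k < aln_a.size(); ++k) {
    if (aln_a[k] == '-') {
      ia[k] = NA_INTEGER;
    } else {
      ia[k] = a[pa++];
    }
    if (aln_b[k] == '-') {
      ib[k] = NA_INTEGER;
    } else {
      ib[k] = b[pb++];
    }
  }

  return List::create(
      _["score"] = score, _["a_idx"] = ia, _["b_idx"] = ib,
      _["a_start"] = start_a, _["a_end"] = pa, _["b_start"] = start_b,
      _["b_end"] = pb);
}
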