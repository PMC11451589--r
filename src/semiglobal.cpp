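#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// Affine-gap semi-global alignment of a reference (every base accounted for;
// terminal reference gaps penalized) against a target whose terminal
// overhangs are free.  Three-state DP (match/mismatch M, gap-in-target D
// consuming reference, gap-in-reference I consuming target); a gap of
// length L costs gap_open + L * gap_extend.  'N' never matches.
//
// Determinism: state preference M > D > I everywhere; gap extension is
// preferred over a fresh open on score ties (keeps indels contiguous); the
// smallest end column is chosen among tied terminal maxima.

static const int NEG = std::numeric_limits<int>::min() / 4;

inline int score_pair(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".semiglobal_align_cpp")]]
List semiglobal_align_cpp(std::string ref, std::string target,
                          int match, int mismatch,
                          int gap_open, int gap_extend) {
  const int n = (int) ref.size();
  const int m = (int) target.size();
  const size_t W = (size_t) m + 1;

  std::vector<int> M((n + 1) * W, NEG), D((n + 1) * W, NEG), I((n + 1) * W, NEG);
  // traceback: predecessor state per state matrix. 0=M,1=D,2=I,3=start
  std::vector<unsigned char> tbM((n + 1) * W, 3), tbD((n + 1) * W, 3),
      tbI((n + 1) * W, 3);

#define AT(i, j) ((size_t)(i) * W + (size_t)(j))

  // free target prefix: alignment may start after any target position
  for (int j = 0; j <= m; ++j) M[AT(0, j)] = 0;
  for (int i = 1; i <= n; ++i) {
    D[AT(i, 0)] = -(gap_open + gap_extend * i);
    tbD[AT(i, 0)] = (i == 1) ? 0 : 1;
  }

  for (int i = 1; i <= n; ++i) {
    const char a = ref[i - 1];
    for (int j = 1; j <= m; ++j) {
      // best state at (i-1, j-1), preference M > D > I
      {
        int hm = M[AT(i - 1, j - 1)], hd = D[AT(i - 1, j - 1)],
            hi = I[AT(i - 1, j - 1)];
        int best = hm; unsigned char st = 0;
        if (hd > best) { best = hd; st = 1; }
        if (hi > best) { best = hi; st = 2; }
        if (best <= NEG / 2) {
          M[AT(i, j)] = NEG;
        } else {
          M[AT(i, j)] = best + score_pair(a, target[j - 1], match, mismatch);
          tbM[AT(i, j)] = st;
        }
      }
      // D: consume ref[i-1] against a gap
      {
        int hm = M[AT(i - 1, j)], hi = I[AT(i - 1, j)];
        int open_from = hm; unsigned char ost = 0;
        if (hi > open_from) { open_from = hi; ost = 2; }
        int open_sc = (open_from <= NEG / 2) ? NEG
                        : open_from - gap_open - gap_extend;
        int ext_sc = (D[AT(i - 1, j)] <= NEG / 2) ? NEG
                        : D[AT(i - 1, j)] - gap_extend;
        if (ext_sc >= open_sc) { D[AT(i, j)] = ext_sc; tbD[AT(i, j)] = 1; }
        else { D[AT(i, j)] = open_sc; tbD[AT(i, j)] = ost; }
      }
      // I: consume target[j-1] against a gap
      {
        int hm = M[AT(i, j - 1)], hd = D[AT(i, j - 1)];
        int open_from = hm; unsigned char ost = 0;
        if (hd > open_from) { open_from = hd; ost = 1; }
        int open_sc = (open_from <= NEG / 2) ? NEG
                        : open_from - gap_open - gap_extend;
        int ext_sc = (I[AT(i, j - 1)] <= NEG / 2) ? NEG
                        : I[AT(i, j - 1)] - gap_extend;
        if (ext_sc >= open_sc) { I[AT(i, j)] = ext_sc; tbI[AT(i, j)] = 1; }
        else { I[AT(i, j)] = open_sc; tbI[AT(i, j)] = ost; }
      }
    }
  }

  // free target suffix: end anywhere on the last row; smallest j wins ties
  int best = NEG, bj = 0; unsigned char bst = 0;
  for (int j = 0; j <= m; ++j) {
    int hm = M[AT(n, j)], hd = D[AT(n, j)], hi = I[AT(n, j)];
    int h = hm; unsigned char st = 0;
    if (hd > h) { h = hd; st = 1; }
    if (hi > h) { h = hi; st = 2; }
    if (h > best) { best = h; bj = j; bst = st; }
  }

  // traceback
  std::string ops_rev;
  int i = n, j = bj; unsigned char st = bst;
  while (!(i == 0 && st == 0 && tbM[AT(i, j)] == 3)) {
    if (st == 0) {
      unsigned char prev = tbM[AT(i, j)];
      if (i == 0) break;  // row-0 start state
      char a = ref[i - 1], b = target[j - 1];
      ops_rev.push_back((a != 'N' && b != 'N' && a == b) ? '=' : 'X');
      --i; --j; st = prev;
    } else if (st == 1) {
      unsigned char prev = tbD[AT(i, j)];
      ops_rev.push_back('D');
      --i; st = prev;
    } else {
      unsigned char prev = tbI[AT(i, j)];
      ops_rev.push_back('I');
      --j; st = prev;
    }
  }
  int target_start = j;

  // run-length encode
  std::vector<std::string> op_out;
  std::vector<int> len_out;
  for (int k = (int) ops_rev.size() - 1; k >= 0; --k) {
    char c = ops_rev[k];
    if (!op_out.empty() && op_out.back()[0] == c) {
      len_out.back() += 1;
    } else {
      op_out.push_back(std::string(1, c));
      len_out.push_back(1);
    }
  }

  return List::create(_["score"] = best,
                      _["op"] = op_out,
                      _["len"] = len_out,
                      _["target_start"] = target_start,
                      _["target_end"] = bj);
}
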