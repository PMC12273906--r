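#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Banded pairwise alignment with linear gap cost.
// mode: 0 = global (Needleman-Wunsch), 1 = overlap (terminal gaps free on
// both sequences), 2 = glocal (pattern global, subject terminal gaps free).
// The band is centred on the "stretched" main diagonal for global/glocal and
// on the identity diagonal for overlap, where the two sequences are expected
// to be near-collinear.
// [[Rcpp::export(name = ".cpp_banded_align")]]
List cpp_banded_align(std::string a, std::string b, int band,
                      int match_s, int mismatch_s, int gap_s, int mode) {
  const int na = (int)a.size(), nb = (int)b.size();
  if (na == 0 || nb == 0) stop("empty sequence");
  if (band < 1) stop("band must be >= 1");
  const int NEG = -1000000000;
  const int W = 2 * band + 1;

  auto center = [&](int i) -> int {
    if (mode == 1) return i;
    return (int)(((long long)i * nb) / std::max(1, na));
  };
  std::vector<int> S((long long)(na + 1) * W, NEG);
  std::vector<unsigned char> T((long long)(na + 1) * W, 0);
  auto idx = [&](int i, int j) -> long long {
    int off = j - (center(i) - band);
    if (off < 0 || off >= W) return -1;
    return (long long)i * W + off;
  };

  for (int j = std::max(0, center(0) - band);
       j <= std::min(nb, center(0) + band); ++j) {
    long long q = idx(0, j);
    if (q < 0) continue;
    if (mode == 0) { S[q] = j * gap_s; T[q] = j > 0 ? 3 : 0; }
    else { S[q] = 0; T[q] = 0; }
  }
  for (int i = 1; i <= na; ++i) {
    int c = center(i);
    int jlo = std::max(0, c - band), jhi = std::min(nb, c + band);
    for (int j = jlo; j <= jhi; ++j) {
      long long q = idx(i, j);
      int best = NEG; unsigned char tb = 0;
      if (j == 0) {
        if (mode == 1) { best = 0; tb = 0; }
      }
      if (j > 0) {
        long long qd = idx(i - 1, j - 1);
        if (qd >= 0 && S[qd] > NEG / 2) {
          int sc = S[qd] + (a[i - 1] == b[j - 1] ? match_s : mismatch_s);
          if (sc > best) { best = sc; tb = 1; }
        }
      }
      { long long qu = idx(i - 1, j);
        if (qu >= 0 && S[qu] > NEG / 2) {
          int sc = S[qu] + gap_s;
          if (sc > best) { best = sc; tb = 2; }
        } }
      if (j > 0) {
        long long ql = idx(i, j - 1);
        if (ql >= 0 && S[ql] > NEG / 2) {
          int sc = S[ql] + gap_s;
          if (sc > best) { best = sc; tb = 3; }
        } }
      S[q] = best; T[q] = tb;
    }
  }

  int ei = na, ej = nb, bestScore = NEG;
  if (mode == 0) {
    long long q = idx(na, nb);
    if (q < 0 || S[q] < NEG / 2) stop("band too narrow for global alignment");
    bestScore = S[q];
  } else if (mode == 2) {
    for (int j = 0; j <= nb; ++j) {
      long long q = idx(na, j);
      if (q >= 0 && S[q] > bestScore) { bestScore = S[q]; ej = j; }
    }
    if (bestScore < NEG / 2) stop("band too narrow for glocal alignment");
  } else {
    for (int j = 0; j <= nb; ++j) {
      long long q = idx(na, j);
      if (q >= 0 && S[q] > bestScore) { bestScore = S[q]; ei = na; ej = j; }
    }
    for (int i2 = 0; i2 <= na; ++i2) {
      long long q = idx(i2, nb);
      if (q >= 0 && S[q] > bestScore) { bestScore = S[q]; ei = i2; ej = nb; }
    }
    if (bestScore < NEG / 2) stop("band too narrow for overlap alignment");
  }

  std::string aa, bb;
  int i = ei, j = ej, nmatch = 0, nmis = 0, ngap = 0;
  while (i > 0 || j > 0) {
    long long q = idx(i, j);
    if (q < 0) break;
    unsigned char tb = T[q];
    if (tb == 0) break;
    if (tb == 1) {
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1]) ++nmatch; else ++nmis;
      --i; --j;
    } else if (tb == 2) {
      aa.push_back(a[i - 1]); bb.push_back('-'); ++ngap; --i;
    } else {
      aa.push_back('-'); bb.push_back(b[j - 1]); ++ngap; --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(
    _["score"] = bestScore,
    _["p_start"] = i + 1, _["p_end"] = ei,
    _["s_start"] = j + 1, _["s_end"] = ej,
    _["a_aln"] = aa, _["b_aln"] = bb,
    _["nmatch"] = nmatch, _["nmismatch"] = nmis, _["ngap"] = ngap);
}

// Booth's linear-time least-rotation algorithm; returns the 0-based start
// index of the lexicographically least rotation of s.
// [[Rcpp::export(name = ".cpp_least_rotation")]]
int cpp_least_rotation(std::string s) {
  const int n = (int)s.size();
  if (n == 0) stop("empty sequence");
  std::string t = s + s;
  std::vector<int> f(2 * n, -1);
  int k = 0;
  for (int j = 1; j < 2 * n; ++j) {
    char sj = t[j];
    int i = f[j - k - 1];
    while (i != -1 && sj != t[k + i + 1]) {
      if (sj < t[k + i + 1]) k = j - i - 1;
      i = f[i];
    }
    if (sj != t[k + i + 1]) {
      if (sj < t[k]) k = j;
      f[j - k] = -1;
    } else {
      f[j - k] = i + 1;
    }
  }
  return k;
}
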