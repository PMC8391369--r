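// Unit-cost Levenshtein alignment with substitution/insertion/deletion
// decomposition. The backtrace canonicalizes ties by preferring
// substitution over deletion over insertion; the total S+I+D is
// path-independent.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <map>

using namespace Rcpp;

static void sid_core(const std::vector<int>& ref, const std::vector<int>& hyp,
                     int& S, int& I, int& D) {
  const int m = (int)ref.size(), n = (int)hyp.size();
  std::vector<int> d((m + 1) * (n + 1));
  auto at = [&](int i, int j) -> int& { return d[i * (n + 1) + j]; };
  for (int i = 0; i <= m; ++i) at(i, 0) = i;
  for (int j = 0; j <= n; ++j) at(0, j) = j;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int sub = at(i - 1, j - 1) + (ref[i - 1] == hyp[j - 1] ? 0 : 1);
      int del = at(i - 1, j) + 1;
      int ins = at(i, j - 1) + 1;
      int best = sub < del ? sub : del;
      if (ins < best) best = ins;
      at(i, j) = best;
    }
  }
  S = I = D = 0;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        at(i, j) == at(i - 1, j - 1) + (ref[i - 1] == hyp[j - 1] ? 0 : 1)) {
      if (ref[i - 1] != hyp[j - 1]) ++S;  // substitution preferred on ties
      --i; --j;
    } else if (i > 0 && at(i, j) == at(i - 1, j) + 1) {
      ++D;                                 // then deletion
      --i;
    } else {
      ++I;                                 // then insertion
      --j;
    }
  }
}

static std::vector<int> encode(const CharacterVector& x,
                               std::map<std::string, int>& dict) {
  std::vector<int> out;
  out.reserve(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    auto it = dict.find(s);
    int code;
    if (it == dict.end()) {
      code = (int)dict.size();
      dict[s] = code;
    } else code = it->second;
    out.push_back(code);
  }
  return out;
}

// [[Rcpp::export(name = ".sid_counts")]]
IntegerVector sid_counts(CharacterVector ref, CharacterVector hyp) {
  std::map<std::string, int> dict;
  std::vector<int> r = encode(ref, dict), h = encode(hyp, dict);
  int S, I, D;
  sid_core(r, h, S, I, D);
  return IntegerVector::create(Named("S") = S, Named("I") = I,
                               Named("D") = D);
}

// Total S+I+D for every ordered pair of the supplied integer-coded token
// sequences. Used by the exhaustive alignment validation.
// [[Rcpp::export(name = ".sid_pairwise_total")]]
IntegerMatrix sid_pairwise_total(List seqs) {
  const int n = seqs.size();
  std::vector<std::vector<int>> v(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i];
    v[i] = std::vector<int>(s.begin(), s.end());
  }
  IntegerMatrix out(n, n);
  int S, I, D;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      sid_core(v[i], v[j], S, I, D);
      out(i, j) = S + I + D;
    }
  }
  return out;
}
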