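#include <Rcpp.h>
using namespace Rcpp;

// Hamming mismatches between pattern and text starting at offset `at`
// (0-based). Any character pair that is not an identical A/C/G/T pair
// counts as a mismatch (N never matches). Bails out early past `budget`.
static inline int mismatches(const std::string &text, size_t at,
                             const std::string &pat, int budget) {
  int mm = 0;
  for (size_t j = 0; j < pat.size(); ++j) {
    char a = text[at + j], b = pat[j];
    bool match = (a == b) && (a == 'A' || a == 'C' || a == 'G' || a == 'T');
    if (!match && ++mm > budget) return mm;
  }
  return mm;
}

static inline std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default: break;
    }
  }
  return r;
}

// Scan one oriented sequence for the insertion signature.
// Offsets are visited left to right; at each left-flank hit the mutant
// layout (left + inserted + right) is tested before the wild-type
// layout (left + right contiguous). Returns 0 uninformative, 1 WT,
// 2 MUT.
static int scan_one(const std::string &seq, const std::string &left,
                    const std::string &ins, const std::string &right,
                    int max_mm) {
  size_t L = left.size(), I = ins.size(), R = right.size();
  if (seq.size() < L + R) return 0;
  size_t last = seq.size() - L;
  for (size_t i = 0; i <= last; ++i) {
    if (mismatches(seq, i, left, max_mm) > max_mm) continue;
    // mutant: inserted bases exact, then right flank within budget
    if (i + L + I + R <= seq.size() &&
        seq.compare(i + L, I, ins) == 0 &&
        mismatches(seq, i + L + I, right, max_mm) <= max_mm)
      return 2;
    // wild type: right flank immediately after left flank
    if (i + L + R <= seq.size() &&
        mismatches(seq, i + L, right, max_mm) <= max_mm)
      return 1;
  }
  return 0;
}

// [[Rcpp::export(name = ".scan_reads_cpp")]]
IntegerVector scan_reads_cpp(CharacterVector reads, std::string left,
                             std::string inserted, std::string right,
                             int max_mm, bool scan_revcomp) {
  int n = reads.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    for (auto &c : s) c = std::toupper(c);
    int res = scan_one(s, left, inserted, right, max_mm);
    if (res == 0 && scan_revcomp)
      res = scan_one(revcomp_str(s), left, inserted, right, max_mm);
    out[i] = res;
  }
  return out;
}
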