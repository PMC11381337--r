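#include <Rcpp.h>
#include <cctype>
#include <cstring>
using namespace Rcpp;

// Shared walker over one pileup base/quality string pair. Calls `emit` for
// every decoded base call. Read-start marks ('^' + mapping quality), read-end
// marks ('$') and indel runs ('+n'/'-n' + n bases) consume base-string
// characters but no quality characters; deletion placeholders ('*'), reference
// skips ('<', '>') and N calls consume one quality character but emit nothing.
template <typename Emit>
static void walk_column(const char *b, const char *q, char ref, int line,
                        Emit emit) {
  size_t nb = std::strlen(b), nq = std::strlen(q);
  size_t qi = 0;
  for (size_t j = 0; j < nb; ++j) {
    char c = b[j];
    if (c == '^') {            // next char is mapping quality, never a base
      if (j + 1 >= nb)
        stop("truncated read-start mark at pileup line %d", line);
      ++j;
      continue;
    }
    if (c == '$') continue;
    if (c == '+' || c == '-') { // indel: length digits then inserted bases
      size_t k = j + 1;
      long len = 0;
      if (k >= nb || !std::isdigit((unsigned char)b[k]))
        stop("malformed indel mark at pileup line %d", line);
      while (k < nb && std::isdigit((unsigned char)b[k])) {
        len = len * 10 + (b[k] - '0');
        ++k;
      }
      if (k + len > nb)
        stop("indel run past end of base string at pileup line %d", line);
      j = k + len - 1;
      continue;
    }
    if (c == '*' || c == '<' || c == '>') {
      if (qi >= nq)
        stop("quality string shorter than base calls at pileup line %d", line);
      ++qi;
      continue;
    }
    char up = std::toupper((unsigned char)c);
    char base, strand;
    if (c == '.') {
      base = ref; strand = '+';
    } else if (c == ',') {
      base = ref; strand = '-';
    } else if (up == 'A' || up == 'C' || up == 'G' || up == 'T' || up == 'N') {
      base = up;
      strand = std::isupper((unsigned char)c) ? '+' : '-';
    } else {
      stop("unknown base symbol '%c' at pileup line %d", c, line);
    }
    if (qi >= nq)
      stop("quality string shorter than base calls at pileup line %d", line);
    int qual = (int)(unsigned char)q[qi];
    ++qi;
    if (base == 'N') continue;  // ambiguous call: consumed, never emitted
    emit(base, strand, qual);
  }
  if (qi != nq)
    stop("quality/base length mismatch at pileup line %d (quality has %d unconsumed characters)",
         line, (int)(nq - qi));
}

// Full decode: one row per emitted base call, tagged with its source line.
// [[Rcpp::export]]
List decodePileupCpp(CharacterVector bases, CharacterVector quals,
                     CharacterVector refs, IntegerVector depths,
                     int phredOffset) {
  R_xlen_t n = bases.size();
  std::vector<int> line_idx;
  std::string nuc, strand;
  std::vector<int> qual;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (depths[i] == 0) continue;  // '*'/'*' placeholder column
    const char *b = CHAR(STRING_ELT(bases, i));
    const char *q = CHAR(STRING_ELT(quals, i));
    char ref = std::toupper((unsigned char)*CHAR(STRING_ELT(refs, i)));
    walk_column(b, q, ref, (int)(i + 1),
                [&](char base, char str, char qchar) {
                  line_idx.push_back((int)(i + 1));
                  nuc.push_back(base);
                  strand.push_back(str);
                  qual.push_back((int)qchar - phredOffset);
                });
  }
  R_xlen_t m = (R_xlen_t)line_idx.size();
  CharacterVector nucv(m), strv(m);
  for (R_xlen_t k = 0; k < m; ++k) {
    nucv[k] = std::string(1, nuc[k]);
    strv[k] = std::string(1, strand[k]);
  }
  return List::create(_["line"] = wrap(line_idx), _["nuc"] = nucv,
                      _["strand"] = strv, _["qual"] = wrap(qual));
}

// Counting decode: per line, quality-passing call counts by nucleotide plus
// the decoded (pre-filter) call depth. Columns: A, C, G, T, nCalls, nLowQ.
// [[Rcpp::export]]
IntegerMatrix countPileupCpp(CharacterVector bases, CharacterVector quals,
                             CharacterVector refs, IntegerVector depths,
                             int qMin, int phredOffset) {
  R_xlen_t n = bases.size();
  IntegerMatrix out(n, 6);
  colnames(out) = CharacterVector::create("A", "C", "G", "T", "nCalls", "nLowQ");
  for (R_xlen_t i = 0; i < n; ++i) {
    if (depths[i] == 0) continue;
    const char *b = CHAR(STRING_ELT(bases, i));
    const char *q = CHAR(STRING_ELT(quals, i));
    char ref = std::toupper((unsigned char)*CHAR(STRING_ELT(refs, i)));
    int cnt[4] = {0, 0, 0, 0};
    int ncalls = 0, nlow = 0;
    walk_column(b, q, ref, (int)(i + 1),
                [&](char base, char, char qchar) {
                  ++ncalls;
                  if ((int)qchar - phredOffset < qMin) { ++nlow; return; }
                  switch (base) {
                    case 'A': ++cnt[0]; break;
                    case 'C': ++cnt[1]; break;
                    case 'G': ++cnt[2]; break;
                    case 'T': ++cnt[3]; break;
                  }
                });
    out(i, 0) = cnt[0]; out(i, 1) = cnt[1];
    out(i, 2) = cnt[2]; out(i, 3) = cnt[3];
    out(i, 4) = ncalls; out(i, 5) = nlow;
  }
  return out;
}
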