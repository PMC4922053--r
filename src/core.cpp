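#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// splitmix64 finalizer; scrambles 2-bit packed kmers so that window minima
// are not biased toward poly-A
static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Count canonical kmers (lexicographic min of forward and reverse
// complement in 2-bit encoding) over a set of sequences. Kmers touching a
// non-ACGT base are skipped. Returns the multiplicity histogram and the
// total number of counted kmer instances.
// [[Rcpp::export]]
List kmer_count_cpp(CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_map<uint64_t, uint32_t> counts;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  double total = 0.0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int n = LENGTH(STRING_ELT(reads, r));
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { run = 0; fwd = rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
      if (++run >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++counts[canon];
        total += 1.0;
      }
    }
  }
  // histogram: multiplicity -> number of distinct species
  std::unordered_map<uint32_t, double> hist;
  for (auto &kv : counts) hist[kv.second] += 1.0;
  IntegerVector mult(hist.size());
  NumericVector cnt(hist.size());
  R_xlen_t i = 0;
  for (auto &kv : hist) { mult[i] = (int)kv.first; cnt[i] = kv.second; ++i; }
  return List::create(_["multiplicity"] = mult, _["count"] = cnt,
                      _["total"] = total, _["n_species"] = (double)counts.size());
}

// Canonical kmer set of a sequence (distinct hashed kmers, 52-bit folded).
// Used for exact haplotype kmer-sharing enumeration.
// [[Rcpp::export]]
NumericVector kmer_set_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::unordered_map<uint64_t, uint8_t> seen;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    int n = LENGTH(STRING_ELT(seqs, r));
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { run = 0; fwd = rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
      if (++run >= k) seen[fwd < rev ? fwd : rev] = 1;
    }
  }
  NumericVector out(seen.size());
  R_xlen_t i = 0;
  for (auto &kv : seen) out[i++] = (double)(kv.first & ((1ULL << 52) - 1));
  return out;
}

// Window minimizers over canonical kmer hashes.
// Returns 0-based kmer start positions, 52-bit folded hashes, and the
// strand (+1 when the forward kmer is canonical, -1 otherwise).
// [[Rcpp::export]]
DataFrame minimizers_cpp(std::string seq, int k, int w) {
  int n = (int)seq.size();
  std::vector<double> hashes; std::vector<int> pos; std::vector<int> strand;
  int m = n - k + 1;
  if (m < 1) return DataFrame::create(_["pos"] = IntegerVector(0),
                                      _["hash"] = NumericVector(0),
                                      _["strand"] = IntegerVector(0));
  std::vector<uint64_t> hv(m, ~0ULL);
  std::vector<int8_t> sv(m, 0);
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t fwd = 0, rev = 0; int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { run = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++run >= k) {
      int p = i - k + 1;
      bool f = fwd <= rev;
      hv[p] = mix64(f ? fwd : rev);
      sv[p] = f ? 1 : -1;
    }
  }
  // sliding window minimum (simple scan; w is small)
  int last = -1;
  for (int ws = 0; ws + w <= m; ++ws) {
    int best = -1; uint64_t bh = ~0ULL;
    for (int j = ws; j < ws + w; ++j)
      if (sv[j] != 0 && hv[j] < bh) { bh = hv[j]; best = j; }
    if (best >= 0 && best != last) {
      pos.push_back(best);
      hashes.push_back((double)(hv[best] & ((1ULL << 52) - 1)));
      strand.push_back(sv[best]);
      last = best;
    }
  }
  return DataFrame::create(_["pos"] = wrap(pos), _["hash"] = wrap(hashes),
                           _["strand"] = wrap(strand));
}

// Banded global (Needleman-Wunsch, unit costs) edit distance.
// Band is centred on the rescaled diagonal so sequences of different
// length stay inside it. Returns -1 if the optimum escapes the band.
// [[Rcpp::export]]
int banded_edit_cpp(std::string a, std::string b, int band) {
  int la = (int)a.size(), lb = (int)b.size();
  if (la == 0) return lb;
  if (lb == 0) return la;
  int need = std::abs(la - lb) + 2;
  if (band < need) band = need;
  const int INF = la + lb + 10;
  std::vector<int> prev(2 * band + 1, INF), cur(2 * band + 1, INF);
  // row i covers columns j in [c(i)-band, c(i)+band], c(i) = i*lb/la
  auto center = [&](int i) { return (int)((long long)i * lb / la); };
  int c0 = center(0);
  for (int off = -band; off <= band; ++off) {
    int j = c0 + off;
    if (j >= 0 && j <= lb) prev[off + band] = j;  // row 0: D[0][j] = j
  }
  for (int i = 1; i <= la; ++i) {
    int ci = center(i), cp = center(i - 1);
    std::fill(cur.begin(), cur.end(), INF);
    for (int off = -band; off <= band; ++off) {
      int j = ci + off;
      if (j < 0 || j > lb) continue;
      int best = INF;
      if (j == 0) best = i;
      else {
        int pd = (j - 1) - cp, ps = j - cp, pl = (j - 1) - ci;
        int sub = (pd >= -band && pd <= band) ? prev[pd + band] : INF;
        int del = (ps >= -band && ps <= band) ? prev[ps + band] : INF;  // gap in b
        int ins = (pl >= -band && pl <= band) ? cur[pl + band] : INF;   // gap in a
        int m = (a[i - 1] == b[j - 1] ||
                 a[i - 1] == 'N' || b[j - 1] == 'N') ? 0 : 1;
        best = std::min(sub + m, std::min(del + 1, ins + 1));
      }
      cur[off + band] = best;
    }
    std::swap(prev, cur);
  }
  int offl = lb - center(la);
  if (offl < -band || offl > band) return -1;
  int d = prev[offl + band];
  return d >= INF ? -1 : d;
}
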