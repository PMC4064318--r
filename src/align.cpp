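#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Ungapped, end-to-end placement of short reads on reference sub-transcripts
// with at most v substitutions. N never matches anything (including N).
//
// The production path is pigeonhole seed-and-extend: a read with <= v
// mismatches must contain at least one of v+1 disjoint k-mers matching the
// reference exactly, so exact k-mer index lookups enumerate a candidate
// superset which is then verified by capped Hamming counting. This is
// required to reproduce the brute-force hit set exactly; tests compare
// against an independent full enumeration.

static inline int mm_capped(const std::string &q, const std::string &r,
                            int off, int v) {
  int mm = 0;
  const int L = (int)q.size();
  for (int i = 0; i < L; i++) {
    const char a = q[i], b = r[off + i];
    if (a != b || a == 'N') {
      if (++mm > v) return mm;
    }
  }
  return mm;
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); i++) out[i] = comp_base(out[i]);
  return out;
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

typedef std::unordered_map<uint64_t, std::vector<uint64_t> > KmerIndex;

// index all exact k-mers of the references (k <= 32, 2-bit codes, windows
// containing N are skipped: they can never be an exact seed match)
static void build_index(const std::vector<std::string> &refs, int k,
                        KmerIndex &idx) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (size_t r = 0; r < refs.size(); r++) {
    const std::string &s = refs[r];
    const int n = (int)s.size();
    uint64_t kmer = 0;
    int valid = 0; // length of current run of ACGT ending here
    for (int i = 0; i < n; i++) {
      const int c = base_code(s[i]);
      if (c < 0) {
        valid = 0;
        kmer = 0;
        continue;
      }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        const int pos = i - k + 1;
        idx[kmer].push_back(((uint64_t)r << 32) | (uint64_t)pos);
      }
    }
  }
}

// encode q[from, from+k); returns false if the window contains non-ACGT
static inline bool encode_window(const std::string &q, int from, int k,
                                 uint64_t &out) {
  uint64_t kmer = 0;
  for (int i = 0; i < k; i++) {
    const int c = base_code(q[from + i]);
    if (c < 0) return false;
    kmer = (kmer << 2) | (uint64_t)c;
  }
  out = kmer;
  return true;
}

struct HitSink {
  std::vector<int> read, ref, offset, mism;
  std::vector<int> strand; // 0 = '+', 1 = '-'
  void add(int rd, int rf, int off, int st, int mm) {
    read.push_back(rd);
    ref.push_back(rf);
    offset.push_back(off);
    strand.push_back(st);
    mism.push_back(mm);
  }
};

static void align_one_strand(const std::string &q, int read_i, int strand,
                             const std::vector<std::string> &refs, int v,
                             bool use_index, int k, const KmerIndex &idx,
                             HitSink &sink) {
  const int L = (int)q.size();
  if (L == 0) return;
  std::vector<uint64_t> cand; // (ref << 32) | offset
  if (use_index && (v + 1) * k <= L) {
    for (int j = 0; j <= v; j++) {
      const int qpos = j * k;
      uint64_t kmer;
      if (!encode_window(q, qpos, k, kmer)) continue;
      KmerIndex::const_iterator it = idx.find(kmer);
      if (it == idx.end()) continue;
      const std::vector<uint64_t> &v2 = it->second;
      for (size_t h = 0; h < v2.size(); h++) {
        const int r = (int)(v2[h] >> 32);
        const int pos = (int)(v2[h] & 0xffffffffULL);
        const int off = pos - qpos;
        if (off < 0) continue;
        if (off + L > (int)refs[r].size()) continue;
        cand.push_back(((uint64_t)r << 32) | (uint64_t)off);
      }
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    for (size_t c = 0; c < cand.size(); c++) {
      const int r = (int)(cand[c] >> 32);
      const int off = (int)(cand[c] & 0xffffffffULL);
      const int mm = mm_capped(q, refs[r], off, v);
      if (mm <= v) sink.add(read_i + 1, r + 1, off, strand, mm);
    }
  } else {
    for (size_t r = 0; r < refs.size(); r++) {
      const int n = (int)refs[r].size();
      for (int off = 0; off + L <= n; off++) {
        const int mm = mm_capped(q, refs[r], off, v);
        if (mm <= v) sink.add(read_i + 1, (int)r + 1, off, strand, mm);
      }
    }
  }
}

// [[Rcpp::export(name = ".align_reads_cpp")]]
DataFrame align_reads_cpp(CharacterVector reads, CharacterVector refs,
                          int v) {
  if (v < 0) stop("mismatch budget v must be >= 0");
  std::vector<std::string> R(refs.size());
  for (int i = 0; i < refs.size(); i++) R[i] = as<std::string>(refs[i]);

  int min_len = 0;
  for (int i = 0; i < reads.size(); i++) {
    const int L = LENGTH(STRING_ELT(reads, i));
    if (i == 0 || L < min_len) min_len = L;
  }
  int k = (reads.size() > 0) ? min_len / (v + 1) : 0;
  if (k > 32) k = 32;
  const bool use_index = k >= 8;

  KmerIndex idx;
  if (use_index) build_index(R, k, idx);

  HitSink sink;
  for (int i = 0; i < reads.size(); i++) {
    const std::string q = as<std::string>(reads[i]);
    align_one_strand(q, i, 0, R, v, use_index, k, idx, sink);
    align_one_strand(revcomp(q), i, 1, R, v, use_index, k, idx, sink);
  }

  const size_t n = sink.read.size();
  CharacterVector strand(n);
  for (size_t i = 0; i < n; i++) strand[i] = sink.strand[i] ? "-" : "+";
  return DataFrame::create(_["read"] = sink.read, _["allele"] = sink.ref,
                           _["offset"] = sink.offset, _["strand"] = strand,
                           _["mismatches"] = sink.mism,
                           _["stringsAsFactors"] = false);
}
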