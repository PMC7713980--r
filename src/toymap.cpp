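// Deterministic exact-seed / Hamming-extension toy read mapper.
//
// Stand-in for an external short-read mapper so the evaluation pipeline is
// self-contained: k-mer seeds (k <= 15) at fixed offsets locate candidate
// placements on either strand, candidates are scored by full-length Hamming
// distance, and the unique best placement within the mismatch budget is
// reported with MAPQ 60 (ties -> MAPQ 0, no placement -> unmapped).

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

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

static inline char rc_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  std::string buf;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const char *s = CHAR(STRING_ELT(x, i));
    size_t n = strlen(s);
    buf.resize(n);
    for (size_t j = 0; j < n; ++j) buf[n - 1 - j] = rc_base(s[j]);
    out[i] = buf;
  }
  return out;
}

struct Index {
  std::string ref;                 // concatenated contigs
  std::vector<int64_t> offset;     // contig start offsets, plus total at end
  std::vector<uint64_t> kidx;      // (kmer << 34) | pos, sorted (k > 12)
  std::vector<uint32_t> head;      // bucket starts, 4^k + 1 entries (k <= 12)
  std::vector<uint32_t> posv;      // k-mer start positions by bucket
  bool bucket = false;
  int k;
};

// Direct-addressed bucket index for k <= 12 (O(1) seed lookup); sorted
// packed array with binary search otherwise.
static void build_index(Index &ix, int k) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  size_t ncontig = ix.offset.size() - 1;
  ix.bucket = (k <= 12);
  auto scan = [&](auto emit) {
    for (size_t c = 0; c < ncontig; ++c) {
      int64_t lo = ix.offset[c], hi = ix.offset[c + 1];
      uint64_t kmer = 0;
      int run = 0;
      for (int64_t p = lo; p < hi; ++p) {
        int b = base2bits(ix.ref[p]);
        if (b < 0) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)b) & mask;
        if (++run >= k) emit(kmer, (int64_t)(p - k + 1));
      }
    }
  };
  if (ix.bucket) {
    size_t nb = (size_t)1 << (2 * k);
    ix.head.assign(nb + 1, 0);
    scan([&](uint64_t kmer, int64_t) { ++ix.head[kmer + 1]; });
    for (size_t i = 1; i <= nb; ++i) ix.head[i] += ix.head[i - 1];
    ix.posv.resize(ix.head[nb]);
    std::vector<uint32_t> cur(ix.head.begin(), ix.head.end() - 1);
    scan([&](uint64_t kmer, int64_t pos) {
      ix.posv[cur[kmer]++] = (uint32_t)pos;
    });
  } else {
    ix.kidx.clear();
    ix.kidx.reserve(ix.ref.size());
    scan([&](uint64_t kmer, int64_t pos) {
      ix.kidx.push_back((kmer << 34) | (uint64_t)pos);
    });
    std::sort(ix.kidx.begin(), ix.kidx.end());
  }
}

// contig containing global pos (offset vector is sorted)
static inline int find_contig(const std::vector<int64_t> &off, int64_t pos) {
  return (int)(std::upper_bound(off.begin(), off.end(), pos) - off.begin()) - 1;
}

struct Hit {
  bool mapped = false;
  int64_t pos = -1;       // global
  bool rev = false;
  int mism = 0;
  int mapq = 0;
};

static Hit map_one(const Index &ix, const std::string &fwd,
                   const std::string &rev, int seed_step, int max_mm,
                   size_t max_seed_hits) {
  const int k = ix.k;
  const int len = (int)fwd.size();
  Hit best;
  int best_mm = max_mm + 1, ties = 0;
  int64_t best_pos = -1;
  bool best_rev = false;

  std::vector<std::pair<int64_t, int>> cands;  // (global start, strand)
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  for (int strand = 0; strand < 2; ++strand) {
    const std::string &rd = strand ? rev : fwd;
    if ((int)rd.size() < k) continue;
    for (int o = 0;; o += seed_step) {
      if (o > len - k) {
        if (o - seed_step < len - k) o = len - k; else break;
      }
      uint64_t kmer = 0;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        int b = base2bits(rd[o + j]);
        if (b < 0) { ok = false; break; }
        kmer = (kmer << 2) | (uint64_t)b;
      }
      if (ok) {
        kmer &= mask;
        if (ix.bucket) {
          uint32_t b1 = ix.head[kmer], b2 = ix.head[kmer + 1];
          if ((size_t)(b2 - b1) <= max_seed_hits)
            for (uint32_t j = b1; j < b2; ++j)
              cands.push_back({(int64_t)ix.posv[j] - o, strand});
        } else {
          uint64_t lo = kmer << 34;
          auto it1 = std::lower_bound(ix.kidx.begin(), ix.kidx.end(), lo);
          auto it2 = (kmer == mask)
                         ? ix.kidx.end()
                         : std::lower_bound(it1, ix.kidx.end(), (kmer + 1) << 34);
          if ((size_t)(it2 - it1) <= max_seed_hits) {
            for (auto it = it1; it != it2; ++it) {
              int64_t pos = (int64_t)(*it & ((1ULL << 34) - 1)) - o;
              cands.push_back({pos, strand});
            }
          }
        }
      }
      if (o == len - k) break;
    }
  }
  std::sort(cands.begin(), cands.end());
  cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

  for (auto &cd : cands) {
    int64_t pos = cd.first;
    if (pos < 0) continue;
    int c = find_contig(ix.offset, pos);
    if (c < 0 || pos + len > ix.offset[c + 1]) continue;  // read must fit contig
    const std::string &rd = cd.second ? rev : fwd;
    int mm = 0;
    for (int j = 0; j < len; ++j) {
      if (rd[j] != ix.ref[pos + j] && ++mm > best_mm) break;
    }
    if (mm < best_mm) {
      best_mm = mm; ties = 1; best_pos = pos; best_rev = cd.second;
    } else if (mm == best_mm) {
      ++ties;
    }
  }
  if (best_mm <= max_mm && best_pos >= 0) {
    best.mapped = true;
    best.pos = best_pos;
    best.rev = best_rev;
    best.mism = best_mm;
    best.mapq = (ties > 1) ? 0 : 60;
  }
  return best;
}

// [[Rcpp::export]]
List toy_map_cpp(CharacterVector ref_names, CharacterVector ref_seqs,
                 CharacterVector qnames, CharacterVector reads1,
                 CharacterVector reads2, int seed_len, int seed_step,
                 int max_mismatch, int max_seed_hits = 10000) {
  if (seed_len < 4 || seed_len > 15) stop("seed_len must be in [4, 15]");
  if (seed_step < 1) stop("seed_step must be >= 1");

  Index ix;
  ix.k = seed_len;
  ix.offset.push_back(0);
  for (R_xlen_t i = 0; i < ref_seqs.size(); ++i) {
    ix.ref += std::string(CHAR(STRING_ELT(ref_seqs, i)));
    ix.offset.push_back((int64_t)ix.ref.size());
  }
  if (ix.ref.size() >= (1ULL << 34)) stop("reference too large for toy mapper");
  build_index(ix, seed_len);

  R_xlen_t n = qnames.size();
  IntegerVector flag(2 * n), rname(2 * n), posv(2 * n), mapq(2 * n),
      mism(2 * n);
  CharacterVector cigar(2 * n), seqout(2 * n);

  for (R_xlen_t i = 0; i < n; ++i) {
    for (int mate = 0; mate < 2; ++mate) {
      std::string rd(CHAR(STRING_ELT(mate ? reads2 : reads1, i)));
      std::string rcrd(rd.size(), 'N');
      for (size_t j = 0; j < rd.size(); ++j)
        rcrd[rd.size() - 1 - j] = rc_base(rd[j]);
      Hit h = map_one(ix, rd, rcrd, seed_step, max_mismatch, max_seed_hits);
      R_xlen_t o = 2 * i + mate;
      int f = 0x1 | (mate ? 0x80 : 0x40);
      if (h.mapped) {
        int c = find_contig(ix.offset, h.pos);
        if (h.rev) f |= 0x10;
        rname[o] = c + 1;
        posv[o] = (int)(h.pos - ix.offset[c]) + 1;  // 1-based
        mapq[o] = h.mapq;
        mism[o] = h.mism;
        cigar[o] = std::to_string(rd.size()) + "M";
        seqout[o] = h.rev ? rcrd : rd;
      } else {
        f |= 0x4;
        rname[o] = NA_INTEGER;
        posv[o] = 0;
        mapq[o] = 0;
        mism[o] = NA_INTEGER;
        cigar[o] = "*";
        seqout[o] = rd;
      }
      flag[o] = f;
    }
  }
  // mate-unmapped / mate-reverse cross flags
  for (R_xlen_t i = 0; i < n; ++i) {
    if (flag[2 * i + 1] & 0x4) flag[2 * i] |= 0x8;
    if (flag[2 * i] & 0x4) flag[2 * i + 1] |= 0x8;
    if (flag[2 * i + 1] & 0x10) flag[2 * i] |= 0x20;
    if (flag[2 * i] & 0x10) flag[2 * i + 1] |= 0x20;
  }

  CharacterVector qn(2 * n);
  for (R_xlen_t i = 0; i < n; ++i) {
    qn[2 * i] = qnames[i];
    qn[2 * i + 1] = qnames[i];
  }
  return List::create(_["qname"] = qn, _["flag"] = flag, _["rname"] = rname,
                      _["pos"] = posv, _["mapq"] = mapq, _["cigar"] = cigar,
                      _["seq"] = seqout, _["mismatches"] = mism);
}

// Expand a set of equal-length raw vectors into a longer column space:
// copy `nrun` contiguous runs (1-based old/new starts, lengths) and fill
// everything else with `fill`.  Used by the clade simulator when insertions
// add alignment columns; run-wise memcpy keeps genome-scale simulation fast.
// [[Rcpp::export]]
List expand_rows_cpp(List rows, IntegerVector run_old_start,
                     IntegerVector run_new_start, IntegerVector run_len,
                     int new_len, int fill) {
  int nrun = run_len.size();
  List out(rows.size());
  for (R_xlen_t i = 0; i < rows.size(); ++i) {
    if (Rf_isNull(rows[i])) { out[i] = R_NilValue; continue; }
    RawVector x = rows[i];
    RawVector y(new_len, (Rbyte)fill);
    for (int r = 0; r < nrun; ++r) {
      int L = run_len[r];
      if (L <= 0) continue;
      memcpy(&y[run_new_start[r] - 1], &x[run_old_start[r] - 1], (size_t)L);
    }
    out[i] = y;
  }
  return out;
}
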