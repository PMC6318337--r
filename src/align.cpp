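// Seed-and-extend local aligner: exact k-mer seeding on an indexed target set,
// diagonal clustering, banded affine-gap Smith-Waterman extension.
// Scoring (defaults set from R): match +1, mismatch -2, gap open -4, gap extend -1;
// a gap of length L costs |open| + L*|extend|.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

struct SeedIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // (kmer key, tid<<40 | tpos), sorted by key then packed value
  std::vector<std::pair<uint64_t, uint64_t>> tab;
};

// [[Rcpp::export(name = ".cpp_index_build")]]
SEXP cpp_index_build(CharacterVector seqs, CharacterVector names, int k = 21) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  for (R_xlen_t tid = 0; tid < seqs.size(); ++tid) {
    std::string s = as<std::string>(seqs[tid]);
    for (auto& c : s) c = toupper(c);
    idx->names.push_back(as<std::string>(names[tid]));
    uint64_t key = 0;
    int valid = 0;
    const size_t n = s.size();
    for (size_t i = 0; i < n; ++i) {
      int b = enc(s[i]);
      if (b == 4) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      ++valid;
      if (valid >= k) {
        uint64_t pos = i + 1 - (size_t)k;
        idx->tab.emplace_back(key, ((uint64_t)tid << 40) | pos);
      }
    }
    idx->seqs.push_back(std::move(s));
  }
  std::sort(idx->tab.begin(), idx->tab.end());
  return XPtr<SeedIndex>(idx, true);
}

// [[Rcpp::export(name = ".cpp_index_names")]]
CharacterVector cpp_index_names(SEXP idxptr) {
  XPtr<SeedIndex> idx(idxptr);
  return wrap(idx->names);
}

// [[Rcpp::export(name = ".cpp_index_seqlen")]]
NumericVector cpp_index_seqlen(SEXP idxptr) {
  XPtr<SeedIndex> idx(idxptr);
  NumericVector out(idx->seqs.size());
  for (size_t i = 0; i < idx->seqs.size(); ++i) out[i] = (double)idx->seqs[i].size();
  out.attr("names") = wrap(idx->names);
  return out;
}

struct Aln {
  int tid;
  char strand;
  long qs, qe, ts, te;   // half-open, qs/qe on oriented query (converted later)
  int matches, alnlen, score;
};

static const int NEG = -1000000000;

// Banded local affine SW of oriented query q against target t, band around diag0.
// Traceback byte per cell: bits0-2 H source (0 empty, 1 diag cont, 2 E, 3 F, 4 diag start);
// bit3: E opened here; bit4: F opened here.
static bool banded_sw(const std::string& q, const std::string& t, long diag0, int band,
                      int ma, int mi, int go, int ge, long tlo, long thi, Aln& out) {
  const long m = (long)q.size();
  const int W = 2 * band + 1;
  std::vector<int> Hp(W, NEG), Fp(W, NEG), Hc(W, NEG), Ec(W, NEG), Fc(W, NEG);
  std::vector<uint8_t> tb((size_t)m * W, 0);
  int best = 0; long bi = -1, bd = -1;
  for (long i = 0; i < m; ++i) {
    const long base = i + diag0 - band;  // j = base + d
    const int qb = enc(q[(size_t)i]);
    for (int d = 0; d < W; ++d) {
      const long j = base + d;
      uint8_t byte = 0;
      if (j < tlo || j >= thi) { Hc[d] = NEG; Ec[d] = NEG; Fc[d] = NEG; continue; }
      // E: gap consuming target, from (i, j-1)
      int e = NEG;
      if (d > 0) {
        int eopen = (Hc[d - 1] > NEG) ? Hc[d - 1] + go + ge : NEG;
        int eext  = (Ec[d - 1] > NEG) ? Ec[d - 1] + ge : NEG;
        if (eopen >= eext) { e = eopen; byte |= 8; } else { e = eext; }
      }
      // F: gap consuming query, from (i-1, j)
      int f = NEG;
      if (i > 0 && d + 1 < W) {
        int fopen = (Hp[d + 1] > NEG) ? Hp[d + 1] + go + ge : NEG;
        int fext  = (Fp[d + 1] > NEG) ? Fp[d + 1] + ge : NEG;
        if (fopen >= fext) { f = fopen; byte |= 16; } else { f = fext; }
      }
      // diag from (i-1, j-1); fresh start (predecessor outside band/matrix) scores from 0
      const int tbv = enc(t[(size_t)j]);
      const int s = (qb == 4 || tbv == 4 || qb != tbv) ? mi : ma;
      int prevdiag = 0; bool cont = false;
      if (i > 0 && j - 1 >= tlo && Hp[d] > NEG) { prevdiag = Hp[d]; cont = Hp[d] > 0; }
      const int dg = prevdiag + s;
      int h = 0; int src = 0;
      if (dg >= h && dg >= e && dg >= f) { h = dg; src = cont ? 1 : 4; }
      else if (e >= f && e > h) { h = e; src = 2; }
      else if (f > h) { h = f; src = 3; }
      if (h <= 0) { h = (h < 0) ? 0 : h; if (h == 0) src = 0; }
      Hc[d] = h; Ec[d] = e; Fc[d] = f;
      byte |= (uint8_t)src;
      tb[(size_t)i * W + d] = byte;
      if (h > best) { best = h; bi = i; bd = d; }
    }
    std::swap(Hp, Hc); std::swap(Fp, Fc);
    std::fill(Ec.begin(), Ec.end(), NEG);
  }
  if (best <= 0) return false;
  // traceback
  long i = bi, j = bi + diag0 - band + bd;
  const long qe = i + 1, te = j + 1;
  int matches = 0, alnlen = 0;
  int state = 0;  // 0 = H, 2 = E, 3 = F
  for (;;) {
    const long d = j - (i + diag0 - band);
    const uint8_t byte = tb[(size_t)i * W + d];
    if (state == 0) {
      const int src = byte & 7;
      if (src == 0) break;  // shouldn't hit: best>0
      if (src == 1 || src == 4) {
        const int qb2 = enc(q[(size_t)i]), tb2 = enc(t[(size_t)j]);
        if (qb2 != 4 && qb2 == tb2) ++matches;
        ++alnlen;
        if (src == 4) break;
        --i; --j;
      } else {
        state = src;
      }
    } else if (state == 2) {
      ++alnlen; const bool opened = (byte & 8) != 0; --j; if (opened) state = 0;
    } else {
      ++alnlen; const bool opened = (byte & 16) != 0; --i; if (opened) state = 0;
    }
    if (i < 0 || j < 0) break;
  }
  out.qs = i; out.qe = qe; out.ts = j; out.te = te;
  out.matches = matches; out.alnlen = alnlen; out.score = best;
  return true;
}

struct Seed { int tid; char strand; long diag; long tpos; long qpos; };

// [[Rcpp::export(name = ".cpp_query")]]
DataFrame cpp_query(SEXP idxptr, CharacterVector queries, int min_score = 25,
                    int band = 8, int max_hits = 8, int max_cand = 16, int stride = 1,
                    int max_occ = 64, int ma = 1, int mi = -2, int go = -4, int ge = -1,
                    bool both_strands = true) {
  XPtr<SeedIndex> idx(idxptr);
  const int k = idx->k;
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  std::vector<int> o_query; std::vector<int> o_tid;
  std::vector<std::string> o_strand;
  std::vector<double> o_qs, o_qe, o_ts, o_te;
  std::vector<int> o_matches, o_alnlen, o_score;

  std::vector<Seed> seeds;
  std::vector<Aln> alns, kept;
  for (R_xlen_t qi = 0; qi < queries.size(); ++qi) {
    std::string qf = as<std::string>(queries[qi]);
    for (auto& c : qf) c = toupper(c);
    const long qlen = (long)qf.size();
    if (qlen < k) continue;
    seeds.clear(); alns.clear(); kept.clear();
    for (int si = 0; si < (both_strands ? 2 : 1); ++si) {
      const char strand = si == 0 ? '+' : '-';
      const std::string q = si == 0 ? qf : revcomp(qf);
      uint64_t key = 0; int valid = 0;
      for (long i = 0; i < qlen; ++i) {
        const int b = enc(q[(size_t)i]);
        if (b == 4) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)b) & mask;
        ++valid;
        if (valid < k) continue;
        const long qpos = i + 1 - k;
        if (stride > 1 && (qpos % stride) != 0) continue;
        auto lo = std::lower_bound(idx->tab.begin(), idx->tab.end(),
                                   std::make_pair(key, (uint64_t)0));
        auto hi = std::upper_bound(idx->tab.begin(), idx->tab.end(),
                                   std::make_pair(key, ~(uint64_t)0));
        if (hi - lo > max_occ) continue;
        for (auto it = lo; it != hi; ++it) {
          const int tid = (int)(it->second >> 40);
          const long tpos = (long)(it->second & ((1ULL << 40) - 1));
          seeds.push_back({tid, strand, tpos - qpos, tpos, qpos});
        }
      }
    }
    if (seeds.empty()) continue;
    std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
      if (a.strand != b.strand) return a.strand < b.strand;
      if (a.tid != b.tid) return a.tid < b.tid;
      return a.diag < b.diag;
    });
    // cluster seeds on nearby diagonals
    struct Clust { int tid; char strand; long diag; int count; };
    std::vector<Clust> clusts;
    size_t start = 0;
    for (size_t i = 1; i <= seeds.size(); ++i) {
      const bool brk = i == seeds.size() || seeds[i].tid != seeds[start].tid ||
        seeds[i].strand != seeds[start].strand ||
        seeds[i].diag - seeds[i - 1].diag > band;
      if (brk) {
        const size_t mid = start + (i - start) / 2;
        clusts.push_back({seeds[start].tid, seeds[start].strand, seeds[mid].diag,
                          (int)(i - start)});
        start = i;
      }
    }
    std::sort(clusts.begin(), clusts.end(), [](const Clust& a, const Clust& b) {
      return a.count > b.count;
    });
    if ((int)clusts.size() > max_cand) clusts.resize((size_t)max_cand);
    for (const auto& cl : clusts) {
      const std::string& t = idx->seqs[(size_t)cl.tid];
      const std::string q = cl.strand == '+' ? qf : revcomp(qf);
      Aln a; a.tid = cl.tid; a.strand = cl.strand;
      const long tlo = std::max(0L, cl.diag - band);
      const long thi = std::min((long)t.size(), cl.diag + qlen + band);
      if (thi <= tlo) continue;
      if (!banded_sw(q, t, cl.diag, band, ma, mi, go, ge, tlo, thi, a)) continue;
      if (a.score < min_score) continue;
      if (cl.strand == '-') {  // convert query interval to forward-query coords
        const long qs = qlen - a.qe, qe2 = qlen - a.qs;
        a.qs = qs; a.qe = qe2;
      }
      alns.push_back(a);
    }
    std::sort(alns.begin(), alns.end(), [](const Aln& a, const Aln& b) {
      return a.score > b.score;
    });
    for (const auto& a : alns) {
      bool dup = false;
      for (const auto& b : kept) {
        if (a.tid != b.tid || a.strand != b.strand) continue;
        const long ov = std::min(a.te, b.te) - std::max(a.ts, b.ts);
        const long len = std::min(a.te - a.ts, b.te - b.ts);
        if (ov > 0 && len > 0 && 2 * ov > len) { dup = true; break; }
      }
      if (!dup) kept.push_back(a);
      if ((int)kept.size() >= max_hits) break;
    }
    for (const auto& a : kept) {
      o_query.push_back((int)qi + 1);
      o_tid.push_back(a.tid + 1);
      o_strand.push_back(std::string(1, a.strand));
      o_qs.push_back((double)a.qs); o_qe.push_back((double)a.qe);
      o_ts.push_back((double)a.ts); o_te.push_back((double)a.te);
      o_matches.push_back(a.matches); o_alnlen.push_back(a.alnlen);
      o_score.push_back(a.score);
    }
  }
  return DataFrame::create(
    _["query"] = o_query, _["tid"] = o_tid, _["strand"] = o_strand,
    _["qstart"] = o_qs, _["qend"] = o_qe, _["tstart"] = o_ts, _["tend"] = o_te,
    _["matches"] = o_matches, _["aln_len"] = o_alnlen, _["score"] = o_score,
    _["stringsAsFactors"] = false);
}
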