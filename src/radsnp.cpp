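// Low-level kernels: quality screening, per-locus de Bruijn assembly,
// k-mer read placement, and a seeded banded aligner that accumulates
// per-sample pileup counts. All coordinates are 0-based half-open.

#include <Rcpp.h>
#include <unordered_map>
#include <array>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// local integer parse: avoids strtol (newer-glibc symbol redirection)
static int parse_int(const std::string& s, size_t from, size_t to) {
  int v = 0;
  for (size_t i = from; i < to && i < s.size(); ++i) {
    if (s[i] < '0' || s[i] > '9') break;
    v = v * 10 + (s[i] - '0');
  }
  return v;
}

static inline int base_index(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default: c = 'N';
    }
  }
  return r;
}

// Count characters with code <= max_code in each string (Phred+33 screen).
// [[Rcpp::export]]
IntegerVector cpp_count_lowq(CharacterVector qual, int max_code) {
  const R_xlen_t n = qual.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(qual, i));
    int cnt = 0;
    for (; *s; ++s) if (static_cast<unsigned char>(*s) <= max_code) ++cnt;
    out[i] = cnt;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Per-locus de Bruijn assembly
// ---------------------------------------------------------------------------

struct Walk {
  std::string seq;
  int forks;
};

struct KGraph {
  std::unordered_map<std::string, std::array<int, 4>> nxt, prv;
  std::unordered_map<std::string, int> kcount;
};

// walk forward from `start`, forking once on a clean two-way branch
static std::vector<Walk> walk_forward(const KGraph& g, const std::string& start,
                                      int k, int min_count, double branch_frac,
                                      int max_forks, int max_len) {
  std::vector<Walk> done, active;
  active.push_back(Walk{start, 0});
  while (!active.empty()) {
    Walk w = active.back();
    active.pop_back();
    while (true) {
      if (static_cast<int>(w.seq.size()) >= max_len) break;
      std::string key = w.seq.substr(w.seq.size() - k, k);
      auto it = g.nxt.find(key);
      if (it == g.nxt.end()) break;
      const std::array<int,4>& cnt = it->second;
      int total = cnt[0] + cnt[1] + cnt[2] + cnt[3];
      if (total == 0) break;
      std::vector<int> cand;
      for (int b = 0; b < 4; ++b) if (cnt[b] >= min_count) cand.push_back(b);
      if (cand.empty()) break;
      if (cand.size() == 1) { w.seq.push_back(BASES[cand[0]]); continue; }
      if (cand.size() == 2) {
        int c1 = cnt[cand[0]], c2 = cnt[cand[1]];
        if (std::min(c1, c2) >= branch_frac * total && w.forks < max_forks) {
          // clean two-way branch: haplotype fork
          Walk other = w;
          other.forks = w.forks + 1;
          other.seq.push_back(BASES[cand[1]]);
          active.push_back(other);
          w.forks += 1;
          w.seq.push_back(BASES[cand[0]]);
          continue;
        }
        // noise, or fork budget spent (bubble): follow the majority
        w.seq.push_back(BASES[c1 >= c2 ? cand[0] : cand[1]]);
        continue;
      }
      break; // >= 3 supported continuations: break at the branch point
    }
    done.push_back(w);
  }
  return done;
}

// walk backward (majority only) to the left tip of an island
static std::string walk_back_to_tip(const KGraph& g, const std::string& seed,
                                    int k, int min_count, int max_len) {
  std::string s = seed;
  while (static_cast<int>(s.size()) < max_len) {
    std::string key = s.substr(0, k);
    auto it = g.prv.find(key);
    if (it == g.prv.end()) break;
    const std::array<int,4>& cnt = it->second;
    int best = -1, bestc = 0, nc = 0;
    for (int b = 0; b < 4; ++b) {
      if (cnt[b] >= min_count) {
        ++nc;
        if (cnt[b] > bestc) { bestc = cnt[b]; best = b; }
      }
    }
    if (best < 0 || nc >= 3) break;
    s.insert(s.begin(), BASES[best]);
  }
  return s;
}

// Assemble one RAD locus. `reads` must be in locus-forward orientation (the
// SE representative plus the reverse-complemented mates). For each k a
// k-mer graph is built and walked right from the anchor. When mates do not
// overlap the single-end block (insert minimum >= 2 x read length) the
// sheared-end island that abuts it is assembled separately -- reverse-walk
// from its densest k-mer to the left tip, then forward with haplotype
// forking -- and appended to the anchor.
// [[Rcpp::export]]
List cpp_assemble_locus(CharacterVector reads, std::string anchor,
                        IntegerVector kvals, int min_count,
                        double branch_frac, int max_forks, int max_len) {
  std::vector<std::string> seqs;
  std::vector<double> covs;
  std::vector<int> kused;

  std::vector<std::string> rd(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i)
    rd[i] = std::string(CHAR(STRING_ELT(reads, i)));

  for (int ki = 0; ki < kvals.size(); ++ki) {
    const int k = kvals[ki];
    if (k < 2 || static_cast<size_t>(k) > anchor.size()) continue;

    KGraph g;
    g.nxt.reserve(4096); g.prv.reserve(4096); g.kcount.reserve(4096);
    for (const std::string& r : rd) {
      if (r.size() < static_cast<size_t>(k)) continue;
      const int L = static_cast<int>(r.size());
      for (int i = 0; i + k <= L; ++i) {
        std::string km = r.substr(i, k);
        if (km.find_first_not_of("ACGT") != std::string::npos) continue;
        ++g.kcount[km];
        if (i + k < L) {
          int b = base_index(r[i + k]);
          if (b >= 0) {
            auto it = g.nxt.find(km);
            if (it == g.nxt.end()) it = g.nxt.emplace(km, std::array<int,4>{0,0,0,0}).first;
            it->second[b] += 1;
          }
        }
        if (i > 0) {
          int b = base_index(r[i - 1]);
          if (b >= 0) {
            auto it = g.prv.find(km);
            if (it == g.prv.end()) it = g.prv.emplace(km, std::array<int,4>{0,0,0,0}).first;
            it->second[b] += 1;
          }
        }
      }
    }

    std::vector<Walk> done = walk_forward(g, anchor, k, min_count, branch_frac,
                                          max_forks, max_len);
    size_t best_len = 0;
    for (const Walk& w : done) best_len = std::max(best_len, w.seq.size());
    if (best_len <= anchor.size() + 2) {
      // no junction-spanning reads: assemble the abutting island
      std::unordered_map<std::string, char> in_anchor;
      for (size_t i = 0; i + k <= anchor.size(); ++i)
        in_anchor[anchor.substr(i, k)] = 1;
      std::string seed;
      int seedc = 0;
      for (const auto& kv : g.kcount) {
        if (in_anchor.count(kv.first)) continue;
        if (kv.second > seedc ||
            (kv.second == seedc && (seed.empty() || kv.first < seed))) {
          seedc = kv.second; seed = kv.first;
        }
      }
      if (seedc >= min_count) {
        std::string tip = walk_back_to_tip(g, seed, k, min_count, max_len);
        std::vector<Walk> isl = walk_forward(g, tip, k, min_count, branch_frac,
                                             max_forks, max_len);
        done.clear();
        for (Walk& w : isl) {
          w.seq = anchor + w.seq;
          done.push_back(w);
        }
      }
    }

    for (const Walk& w : done) {
      // mean k-mer coverage over the walked sequence
      double tot = 0; int nk = 0;
      const int L = static_cast<int>(w.seq.size());
      for (int i = 0; i + k <= L; ++i) {
        auto it = g.kcount.find(w.seq.substr(i, k));
        tot += (it == g.kcount.end() ? 0 : it->second);
        ++nk;
      }
      seqs.push_back(w.seq);
      covs.push_back(nk > 0 ? tot / nk : 0.0);
      kused.push_back(k);
    }
  }

  return List::create(_["sequence"] = wrap(seqs),
                      _["kmer_cov"] = wrap(covs),
                      _["k"] = wrap(kused));
}

// Assign reads to contigs by k-mer voting; returns per-contig counts of reads
// whose majority of k-mer windows vote for that contig. Used for paired-end
// coverage estimation (contig count <= 31).
// [[Rcpp::export]]
IntegerVector cpp_map_reads_kmer(CharacterVector contigs, CharacterVector reads, int k) {
  const int nc = contigs.size();
  std::unordered_map<std::string, uint32_t> idx;
  for (int c = 0; c < nc && c < 31; ++c) {
    std::string s(CHAR(STRING_ELT(contigs, c)));
    const int L = static_cast<int>(s.size());
    for (int i = 0; i + k <= L; ++i)
      idx[s.substr(i, k)] |= (1u << c);
  }
  IntegerVector out(nc);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s(CHAR(STRING_ELT(reads, r)));
    const int L = static_cast<int>(s.size());
    if (L < k) continue;
    std::array<int, 31> votes{};
    int windows = 0;
    for (int i = 0; i + k <= L; ++i) {
      ++windows;
      auto it = idx.find(s.substr(i, k));
      if (it == idx.end()) continue;
      uint32_t m = it->second;
      for (int c = 0; c < nc && c < 31; ++c) if (m & (1u << c)) ++votes[c];
    }
    int best = -1, bestv = 0;
    for (int c = 0; c < nc && c < 31; ++c)
      if (votes[c] > bestv) { bestv = votes[c]; best = c; }
    if (best >= 0 && 2 * bestv >= windows) out[best] += 1;
  }
  return out;
}

// All pairs (i, j), i < j, with Hamming distance <= max_mm (equal lengths
// required for a hit). Used to merge allelic single-end clusters.
// [[Rcpp::export]]
DataFrame cpp_hamming_pairs(CharacterVector seqs, int max_mm) {
  std::vector<int> ii, jj, dd;
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = std::string(CHAR(STRING_ELT(seqs, i)));
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (s[i].size() != s[j].size()) continue;
      int d = 0;
      const size_t L = s[i].size();
      for (size_t p = 0; p < L; ++p) {
        if (s[i][p] != s[j][p] && ++d > max_mm) break;
      }
      if (d <= max_mm) { ii.push_back(i + 1); jj.push_back(j + 1); dd.push_back(d); }
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["dist"] = dd);
}

// ---------------------------------------------------------------------------
// Seeded banded alignment + pileup accumulation
// ---------------------------------------------------------------------------

struct AlnEvent { int pos; char type; std::string allele; };

struct AlnResult {
  bool ok = false;
  int contig = -1, offset = -1, mm = 0, gap = 0, cost = 0;
  bool rc = false;
  std::vector<AlnEvent> ev;
};

// Banded global-in-read alignment of `read` against `ref` starting near
// ref offset `diag`. Band half-width = max_gap. Mismatch cost 2, gap cost 3
// per nt (one gap preferred over two mismatches). Events are emitted for
// every consumed read base (type 'M', allele = read base), and for indels as
// left-anchored composite alleles: 'I' => anchor ref base + inserted bases,
// 'D' => anchor position with the deletion length encoded in the allele.
static bool align_banded(const std::string& read, const std::string& ref,
                         int diag, int max_mm, int max_gap,
                         int& mm_out, int& gap_out, int& cost_out,
                         int& off_out, std::vector<AlnEvent>& ev_out) {
  const int band = max_gap;
  const int W = 2 * band + 1;
  const int L = static_cast<int>(read.size());
  const int RL = static_cast<int>(ref.size());
  const int INF = 1 << 28;
  if (L == 0) return false;

  std::vector<int> cost((L + 1) * W, INF), mmc((L + 1) * W, 0), gpc((L + 1) * W, 0);
  std::vector<char> ptr((L + 1) * W, 'x');
  auto id = [W](int i, int j) { return i * W + j; };
  // ref position before cell (i, j): r = diag + i + (j - band)
  cost[id(0, band)] = 0;
  ptr[id(0, band)] = 's';

  for (int i = 0; i <= L; ++i) {
    for (int j = 0; j < W; ++j) {
      const int c = cost[id(i, j)];
      if (c >= INF) continue;
      const int r = diag + i + (j - band);
      // deletion: skip one ref base (move within row)
      if (j + 1 < W && r >= 0 && r < RL) {
        int nc = c + 3;
        if (nc < cost[id(i, j + 1)]) {
          cost[id(i, j + 1)] = nc; mmc[id(i, j + 1)] = mmc[id(i, j)];
          gpc[id(i, j + 1)] = gpc[id(i, j)] + 1; ptr[id(i, j + 1)] = 'd';
        }
      }
      if (i < L) {
        // diagonal: consume read[i] and ref[r]
        if (r >= 0 && r < RL) {
          int mis = (read[i] != ref[r]) ? 1 : 0;
          int nc = c + 2 * mis;
          if (nc < cost[id(i + 1, j)]) {
            cost[id(i + 1, j)] = nc; mmc[id(i + 1, j)] = mmc[id(i, j)] + mis;
            gpc[id(i + 1, j)] = gpc[id(i, j)]; ptr[id(i + 1, j)] = 'm';
          }
        }
        // insertion: consume read[i] only
        if (j - 1 >= 0) {
          int nc = c + 3;
          if (nc < cost[id(i + 1, j - 1)]) {
            cost[id(i + 1, j - 1)] = nc; mmc[id(i + 1, j - 1)] = mmc[id(i, j)];
            gpc[id(i + 1, j - 1)] = gpc[id(i, j)] + 1; ptr[id(i + 1, j - 1)] = 'i';
          }
        }
      }
    }
  }

  int bj = -1, bc = INF;
  for (int j = 0; j < W; ++j) {
    const int c = cost[id(L, j)];
    if (c < bc && mmc[id(L, j)] <= max_mm && gpc[id(L, j)] <= max_gap) { bc = c; bj = j; }
  }
  if (bj < 0) return false;

  // traceback
  std::vector<AlnEvent> ev;
  int i = L, j = bj;
  std::string ins_run;
  int del_len = 0, del_end = -1;
  while (!(i == 0 && j == band)) {
    char p = ptr[id(i, j)];
    const int r_prev_offset = diag + i + (j - band); // ref pos after this cell
    if (p == 'm') {
      const int r = r_prev_offset - 1;
      if (!ins_run.empty()) { // insertion anchored at ref base r
        std::string a(1, ref[r]);
        std::reverse(ins_run.begin(), ins_run.end());
        ev.push_back(AlnEvent{r, 'I', a + ins_run});
        ins_run.clear();
      }
      if (del_len > 0) {
        ev.push_back(AlnEvent{del_end - del_len, 'D', std::to_string(del_len)});
        del_len = 0;
      }
      ev.push_back(AlnEvent{r, 'M', std::string(1, read[i - 1])});
      i -= 1;
    } else if (p == 'i') {
      ins_run.push_back(read[i - 1]);
      i -= 1; j += 1;
    } else if (p == 'd') {
      if (del_len == 0) del_end = r_prev_offset;
      del_len += 1;
      j -= 1;
    } else {
      return false; // should not happen
    }
  }
  if (!ins_run.empty() || del_len > 0) return false; // gap at read start: reject

  mm_out = mmc[id(L, bj)];
  gap_out = gpc[id(L, bj)];
  cost_out = bc;
  off_out = diag; // offset of read[0] on the reference (may differ with lead gaps; none allowed)
  std::reverse(ev.begin(), ev.end());
  ev_out = std::move(ev);
  return true;
}

struct SeedIndex {
  int seed_len;
  std::unordered_map<std::string, std::vector<std::pair<int,int>>> pos; // kmer -> (contig, pos)
};

static void try_orient(const std::string& read, bool rc_flag,
                       const std::vector<std::string>& ctg,
                       const SeedIndex& sidx, int max_mm, int max_gap,
                       int restrict_contig, AlnResult& best) {
  const int L = static_cast<int>(read.size());
  const int sl = sidx.seed_len;
  if (L < sl) return;
  std::vector<std::pair<int,int>> cands; // (contig, diag)
  int seed_starts[4] = {0, L / 3, 2 * L / 3, L - sl};
  for (int s = 0; s < 4; ++s) {
    int sp = seed_starts[s];
    if (sp < 0) continue;
    auto it = sidx.pos.find(read.substr(sp, sl));
    if (it == sidx.pos.end()) continue;
    for (const auto& pr : it->second) {
      if (restrict_contig >= 0 && pr.first != restrict_contig) continue;
      cands.emplace_back(pr.first, pr.second - sp);
    }
  }
  std::sort(cands.begin(), cands.end());
  cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
  if (cands.size() > 24) cands.resize(24);
  for (const auto& cd : cands) {
    if (cd.second < -max_gap) continue;
    int mm, gap, cost, off;
    std::vector<AlnEvent> ev;
    if (!align_banded(read, ctg[cd.first], cd.second, max_mm, max_gap,
                      mm, gap, cost, off, ev)) continue;
    bool better = false;
    if (!best.ok) better = true;
    else if (cost < best.cost) better = true;
    else if (cost == best.cost && mm < best.mm) better = true;
    else if (cost == best.cost && mm == best.mm &&
             (cd.first < best.contig || (cd.first == best.contig && off < best.offset)))
      better = true;
    if (better) {
      best.ok = true; best.contig = cd.first; best.offset = off;
      best.mm = mm; best.gap = gap; best.cost = cost; best.rc = rc_flag;
      best.ev = std::move(ev);
    }
  }
}

// Align read pairs of all samples against a contig set and accumulate pileup
// counts. The single end anchors the pair: the mate is only aligned to the
// single end's contig. Reads failing (mm <= max_mm, gap <= max_gap) are
// dropped and counted.
// [[Rcpp::export]]
List cpp_align_pairs(CharacterVector contigs, CharacterVector se, CharacterVector pe,
                     IntegerVector sample, int n_samples,
                     int seed_len, int max_mm, int max_gap) {
  const int nc = contigs.size();
  std::vector<std::string> ctg(nc);
  std::vector<int> clen(nc), coff(nc);
  int total_len = 0;
  for (int c = 0; c < nc; ++c) {
    ctg[c] = std::string(CHAR(STRING_ELT(contigs, c)));
    clen[c] = static_cast<int>(ctg[c].size());
    coff[c] = total_len;
    total_len += clen[c];
  }

  SeedIndex sidx;
  sidx.seed_len = seed_len;
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i + seed_len <= clen[c]; ++i) {
      auto& v = sidx.pos[ctg[c].substr(i, seed_len)];
      if (v.size() < 16) v.emplace_back(c, i);
    }
  }

  std::vector<std::vector<int>> baseCounts(n_samples, std::vector<int>(4 * total_len, 0));
  std::unordered_map<std::string, int> indelCounts;

  const R_xlen_t n = se.size();
  int n_se_fail = 0, n_pe_fail = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    const int smp = sample[i] - 1;
    std::string s(CHAR(STRING_ELT(se, i)));
    AlnResult bse;
    try_orient(s, false, ctg, sidx, max_mm, max_gap, -1, bse);
    try_orient(revcomp(s), true, ctg, sidx, max_mm, max_gap, -1, bse);
    if (!bse.ok) { ++n_se_fail; continue; }

    AlnResult bpe;
    std::string p(CHAR(STRING_ELT(pe, i)));
    if (p.size() > 0) {
      try_orient(p, false, ctg, sidx, max_mm, max_gap, bse.contig, bpe);
      try_orient(revcomp(p), true, ctg, sidx, max_mm, max_gap, bse.contig, bpe);
      if (!bpe.ok) ++n_pe_fail;
    }

    for (const AlnResult* ar : {&bse, &bpe}) {
      if (!ar->ok) continue;
      const int off0 = coff[ar->contig];
      for (const AlnEvent& e : ar->ev) {
        if (e.pos < 0 || e.pos >= clen[ar->contig]) continue;
        if (e.type == 'M') {
          int b = base_index(e.allele[0]);
          if (b >= 0) baseCounts[smp][4 * (off0 + e.pos) + b] += 1;
        } else {
          std::string key = std::to_string(smp) + "\t" + std::to_string(ar->contig) +
            "\t" + std::to_string(e.pos) + "\t" + e.type + ":" + e.allele;
          indelCounts[key] += 1;
        }
      }
    }
  }

  // long-format pileup
  std::vector<int> o_contig, o_pos, o_sample, o_count;
  std::vector<std::string> o_allele;
  for (int smp = 0; smp < n_samples; ++smp) {
    for (int c = 0; c < nc; ++c) {
      for (int p = 0; p < clen[c]; ++p) {
        for (int b = 0; b < 4; ++b) {
          int cnt = baseCounts[smp][4 * (coff[c] + p) + b];
          if (cnt > 0) {
            o_contig.push_back(c + 1); o_pos.push_back(p); o_sample.push_back(smp + 1);
            o_allele.push_back(std::string(1, BASES[b])); o_count.push_back(cnt);
          }
        }
      }
    }
  }
  for (const auto& kv : indelCounts) {
    const std::string& key = kv.first;
    size_t t1 = key.find('\t'), t2 = key.find('\t', t1 + 1), t3 = key.find('\t', t2 + 1);
    o_sample.push_back(parse_int(key, 0, t1) + 1);
    o_contig.push_back(parse_int(key, t1 + 1, t2) + 1);
    o_pos.push_back(parse_int(key, t2 + 1, t3));
    o_allele.push_back(key.substr(t3 + 1));
    o_count.push_back(kv.second);
  }

  DataFrame counts = DataFrame::create(
    _["contig"] = wrap(o_contig), _["pos"] = wrap(o_pos),
    _["sample"] = wrap(o_sample), _["allele"] = wrap(o_allele),
    _["count"] = wrap(o_count), _["stringsAsFactors"] = false);
  return List::create(_["counts"] = counts,
                      _["n_pairs"] = static_cast<int>(n),
                      _["n_se_unaligned"] = n_se_fail,
                      _["n_pe_unaligned"] = n_pe_fail);
}

// Single-read alignment against one contig; exposes the alignment contract
// (offset, mismatches, gaps) for testing. Returns NULL when rejected.
// [[Rcpp::export]]
List cpp_align_one(std::string read, std::string ref, int seed_len,
                   int max_mm, int max_gap) {
  SeedIndex sidx;
  sidx.seed_len = seed_len;
  const int L = static_cast<int>(ref.size());
  for (int i = 0; i + seed_len <= L; ++i) {
    auto& v = sidx.pos[ref.substr(i, seed_len)];
    if (v.size() < 16) v.emplace_back(0, i);
  }
  std::vector<std::string> ctg{ref};
  AlnResult best;
  try_orient(read, false, ctg, sidx, max_mm, max_gap, -1, best);
  try_orient(revcomp(read), true, ctg, sidx, max_mm, max_gap, -1, best);
  if (!best.ok) return List::create(_["accepted"] = false);
  return List::create(_["accepted"] = true, _["offset"] = best.offset,
                      _["mismatches"] = best.mm, _["gaps"] = best.gap,
                      _["revcomp"] = best.rc);
}
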