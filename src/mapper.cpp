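// Deterministic seed-and-extend short-read mapper.
//
// Candidate loci are found by pigeonhole seeding: a read aligned with at most
// `budget` edits must contain at least one of budget+1 disjoint chunks free of
// edits, so an exact 7-mer at each chunk start locates every alignment within
// the budget. Candidates on the same diagonal run (gap <= budget) are grouped
// into one locus and verified by a semi-global dynamic program (read global,
// reference ends free within the window) that minimises (edits, gap opens)
// lexicographically, with gap opens capped. Reads too short for complete
// seeding fall back to a full window scan.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

const int BIGE = 1 << 20;
const int SEED_K = 7;
const int SPAN_CAP = 64;

inline int b2i(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

inline char cmpl(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = cmpl(c);
  return r;
}

// edits, gap opens; lexicographic order
struct Cell { int e; int o; };
inline bool lt(const Cell& a, const Cell& b) {
  return a.e < b.e || (a.e == b.e && a.o < b.o);
}
const Cell CINF = {BIGE, BIGE};

struct SeedIndex {
  std::unordered_map<uint32_t, std::vector<std::pair<int, int> > > pos;
  void build(const std::vector<std::string>& seqs) {
    const uint32_t mask = (1u << (2 * SEED_K)) - 1;
    for (size_t c = 0; c < seqs.size(); ++c) {
      const std::string& s = seqs[c];
      if ((int)s.size() < SEED_K) continue;
      uint32_t key = 0; int valid = 0;
      for (size_t p = 0; p < s.size(); ++p) {
        int v = b2i(s[p]);
        if (v < 0) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint32_t)v) & mask;
        if (++valid >= SEED_K)
          pos[key].push_back(std::make_pair((int)c, (int)(p + 1 - SEED_K)));
      }
    }
  }
};

struct WinResult {
  Cell c;
  int start, ref_len;
  std::string cigar;
  bool has_indel;
  bool ok;
};

// Align `read` (fully consumed) against ref[ws, we); the alignment may start
// at absolute reference positions [fs_lo_abs, fs_hi_abs].
WinResult align_window(const std::string& ref, int ws, int we,
                       int fs_lo_abs, int fs_hi_abs,
                       const std::string& read, int budget, int max_go,
                       bool traceback) {
  WinResult res; res.c = CINF; res.ok = false;
  res.start = -1; res.ref_len = 0; res.has_indel = false;
  int clen = (int)ref.size();
  ws = std::max(0, ws); we = std::min(clen, we);
  int n = we - ws, m = (int)read.size();
  if (n <= 0 || m == 0) return res;
  int fs_lo = std::max(0, fs_lo_abs - ws);
  int fs_hi = std::min(n, fs_hi_abs - ws);
  if (fs_lo > fs_hi) return res;

  size_t sz = (size_t)(m + 1) * (n + 1);
  std::vector<Cell> M(sz, CINF), I(sz, CINF), D(sz, CINF);
  // parent matrix ids for traceback: 0=M,1=I,2=D,3=origin
  std::vector<uint8_t> pM, pI, pD;
  if (traceback) { pM.assign(sz, 3); pI.assign(sz, 3); pD.assign(sz, 3); }
  #define IX(i, j) ((size_t)(i) * (n + 1) + (j))

  for (int j = fs_lo; j <= fs_hi; ++j) M[IX(0, j)] = {0, 0};

  for (int i = 1; i <= m; ++i) {
    char rb = read[i - 1];
    int rv = b2i(rb);
    for (int j = 0; j <= n; ++j) {
      // I: read base consumed, gap in reference
      Cell op = M[IX(i - 1, j)]; op.e += 1; op.o += 1;
      Cell ex = I[IX(i - 1, j)]; ex.e += 1;
      Cell bi = CINF; uint8_t pbi = 3;
      if (op.o <= max_go && lt(op, bi)) { bi = op; pbi = 0; }
      if (lt(ex, bi)) { bi = ex; pbi = 1; }
      if (bi.e <= budget) { I[IX(i, j)] = bi; if (traceback) pI[IX(i, j)] = pbi; }

      if (j >= 1) {
        // M: diagonal
        int cost = (rv >= 0 && ref[ws + j - 1] == rb) ? 0 : 1;
        Cell bm = CINF; uint8_t pbm = 3;
        Cell a = M[IX(i - 1, j - 1)];
        Cell b = I[IX(i - 1, j - 1)];
        Cell d = D[IX(i - 1, j - 1)];
        if (lt(a, bm)) { bm = a; pbm = 0; }
        if (lt(b, bm)) { bm = b; pbm = 1; }
        if (lt(d, bm)) { bm = d; pbm = 2; }
        bm.e += cost;
        if (bm.e <= budget) { M[IX(i, j)] = bm; if (traceback) pM[IX(i, j)] = pbm; }

        // D: reference base consumed, gap in read
        Cell dop = M[IX(i, j - 1)]; dop.e += 1; dop.o += 1;
        Cell dex = D[IX(i, j - 1)]; dex.e += 1;
        Cell bd = CINF; uint8_t pbd = 3;
        if (dop.o <= max_go && lt(dop, bd)) { bd = dop; pbd = 0; }
        if (lt(dex, bd)) { bd = dex; pbd = 2; }
        if (bd.e <= budget) { D[IX(i, j)] = bd; if (traceback) pD[IX(i, j)] = pbd; }
      }
    }
  }

  // best end state over final row (M or I; ending in D would only add edits)
  int bj = -1, bmat = -1; Cell best = CINF;
  for (int j = 0; j <= n; ++j) {
    if (lt(M[IX(m, j)], best)) { best = M[IX(m, j)]; bj = j; bmat = 0; }
    if (lt(I[IX(m, j)], best)) { best = I[IX(m, j)]; bj = j; bmat = 1; }
  }
  if (best.e > budget) return res;
  res.c = best; res.ok = true;

  if (traceback) {
    std::string ops;
    int i = m, j = bj, mat = bmat;
    while (i > 0 || mat != 0) {
      uint8_t par;
      if (mat == 0) {
        par = pM[IX(i, j)];
        if (i == 0) break;
        ops.push_back('M'); --i; --j;
      } else if (mat == 1) {
        par = pI[IX(i, j)]; ops.push_back('I'); --i;
      } else {
        par = pD[IX(i, j)]; ops.push_back('D'); --j;
      }
      mat = par;
      if (mat == 3) break;
    }
    std::reverse(ops.begin(), ops.end());
    // compress into CIGAR
    std::string cig;
    size_t k = 0;
    while (k < ops.size()) {
      size_t k2 = k;
      while (k2 < ops.size() && ops[k2] == ops[k]) ++k2;
      cig += std::to_string(k2 - k); cig.push_back(ops[k]);
      if (ops[k] != 'M') res.has_indel = true;
      k = k2;
    }
    res.cigar = cig;
    res.start = ws + j;
    int rl = 0;
    for (char c : ops) if (c == 'M' || c == 'D') ++rl;
    res.ref_len = rl;
  }
  return res;
}

struct Locus {
  int chrom; bool minus;
  // windows: list of absolute free-start ranges (lo, hi)
  std::vector<std::pair<int, int> > ranges;
  Cell best; int best_win;
  Locus() : chrom(0), minus(false), best(CINF), best_win(-1) {}
};

void add_ranges(Locus& loc, int lo, int hi) {
  for (int a = lo; a <= hi; a += SPAN_CAP)
    loc.ranges.push_back(std::make_pair(a, std::min(hi, a + SPAN_CAP - 1)));
}

} // namespace

// [[Rcpp::export(name = ".cpp_map_reads")]]
List cpp_map_reads(CharacterVector read_seqs, IntegerVector budgets,
                   CharacterVector ref_seqs, int max_gap_opens) {
  int nref = ref_seqs.size();
  std::vector<std::string> refs(nref);
  for (int i = 0; i < nref; ++i) refs[i] = as<std::string>(ref_seqs[i]);
  SeedIndex idx;
  idx.build(refs);

  int nr = read_seqs.size();
  LogicalVector out_mapped(nr), out_indel(nr);
  IntegerVector out_chrom(nr), out_start(nr), out_mapq(nr), out_ed(nr),
      out_reflen(nr);
  CharacterVector out_strand(nr), out_cigar(nr), out_seq(nr);

  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(read_seqs[r]);
    int L = (int)fwd.size();
    int budget = budgets[r];
    std::vector<Locus> loci;

    for (int st = 0; st < 2; ++st) {
      bool minus = (st == 1);
      std::string rs = minus ? revcomp(fwd) : fwd;
      bool complete_seeding = L >= SEED_K * (budget + 1) && L >= SEED_K;

      if (complete_seeding) {
        // q-gram seeding: look up every overlapping 7-mer of the read and
        // project hits onto diagonals (anchor = genome pos - read offset).
        // An alignment with e <= budget edits keeps at least
        // (L - K + 1) - K*e read 7-mers intact, and diagonal shifts from
        // gaps are at most `budget`, so counting hits per diagonal run and
        // thresholding at (L - K + 1) - K*budget prunes random candidates
        // without losing any locus within the budget.
        std::vector<std::vector<int> > anchors(nref);
        const uint32_t mask = (1u << (2 * SEED_K)) - 1;
        uint32_t key = 0; int valid = 0;
        for (int p = 0; p < L; ++p) {
          int v = b2i(rs[p]);
          if (v < 0) { valid = 0; key = 0; continue; }
          key = ((key << 2) | (uint32_t)v) & mask;
          if (++valid < SEED_K) continue;
          int off = p + 1 - SEED_K;
          auto it = idx.pos.find(key);
          if (it == idx.pos.end()) continue;
          for (auto& pr : it->second)
            anchors[pr.first].push_back(pr.second - off);
        }
        int need = (L - SEED_K + 1) - SEED_K * budget;
        if (need < 1) need = 1;
        for (int c = 0; c < nref; ++c) {
          std::vector<int>& av = anchors[c];
          if (av.empty()) continue;
          std::sort(av.begin(), av.end());
          size_t i0 = 0;
          while (i0 < av.size()) {
            size_t i1 = i0;
            while (i1 + 1 < av.size() && av[i1 + 1] - av[i1] <= budget) ++i1;
            if ((int)(i1 - i0 + 1) >= need) {
              Locus loc; loc.chrom = c; loc.minus = minus;
              add_ranges(loc, av[i0] - budget, av[i1] + budget);
              loci.push_back(loc);
            }
            i0 = i1 + 1;
          }
        }
      } else {
        // complete fallback: tile each chromosome with window-sized loci
        for (int c = 0; c < nref; ++c) {
          int clen = (int)refs[c].size();
          for (int a = 0; a < clen; a += SPAN_CAP) {
            Locus loc; loc.chrom = c; loc.minus = minus;
            loc.ranges.push_back(
                std::make_pair(a, std::min(clen, a + SPAN_CAP - 1)));
            loci.push_back(loc);
          }
        }
      }
    }

    // verify loci
    Cell globalBest = CINF;
    int n_within = 0;
    std::vector<std::string> strands(2);
    for (auto& loc : loci) {
      const std::string& rs0 =
          loc.minus ? (strands[1].empty() ? (strands[1] = revcomp(fwd))
                                          : strands[1])
                    : (strands[0].empty() ? (strands[0] = fwd) : strands[0]);
      for (size_t w = 0; w < loc.ranges.size(); ++w) {
        int lo = loc.ranges[w].first, hi = loc.ranges[w].second;
        WinResult wr = align_window(refs[loc.chrom], lo, hi + L + budget,
                                    lo, hi, rs0, budget, max_gap_opens, false);
        if (wr.ok && lt(wr.c, loc.best)) { loc.best = wr.c; loc.best_win = (int)w; }
      }
      if (loc.best.e <= budget) {
        ++n_within;
        if (lt(loc.best, globalBest)) globalBest = loc.best;
      }
    }

    if (globalBest.e > budget) {
      out_mapped[r] = false;
      out_chrom[r] = NA_INTEGER; out_start[r] = NA_INTEGER;
      out_mapq[r] = NA_INTEGER; out_ed[r] = NA_INTEGER;
      out_reflen[r] = NA_INTEGER;
      out_strand[r] = NA_STRING; out_cigar[r] = NA_STRING;
      out_seq[r] = NA_STRING; out_indel[r] = NA_LOGICAL;
      continue;
    }

    // co-optimal loci (same edit distance as the best)
    int n_best = 0;
    for (auto& loc : loci)
      if (loc.best.e == globalBest.e) ++n_best;
    int mapq = (n_best >= 2) ? 0 : (n_within >= 2 ? 25 : 37);

    // winner: traceback all co-optimal loci, order by
    // (chrom, start, + before -); chromosomes are passed name-sorted
    int bestc = -1; int bestStart = -1; bool bestMinus = false;
    WinResult bestWr; bestWr.ok = false;
    for (auto& loc : loci) {
      if (loc.best.e != globalBest.e || lt(globalBest, loc.best)) continue;
      int lo = loc.ranges[loc.best_win].first,
          hi = loc.ranges[loc.best_win].second;
      const std::string& rs0 = loc.minus ? strands[1] : strands[0];
      WinResult wr = align_window(refs[loc.chrom], lo, hi + L + budget,
                                  lo, hi, rs0, budget, max_gap_opens, true);
      if (!wr.ok) continue;
      bool better = false;
      if (bestc < 0) better = true;
      else if (loc.chrom != bestc) better = loc.chrom < bestc;
      else if (wr.start != bestStart) better = wr.start < bestStart;
      else better = (!loc.minus && bestMinus);
      if (better) {
        bestc = loc.chrom; bestStart = wr.start; bestMinus = loc.minus;
        bestWr = wr;
      }
    }

    out_mapped[r] = true;
    out_chrom[r] = bestc + 1;
    out_start[r] = bestStart;
    out_strand[r] = bestMinus ? "-" : "+";
    out_mapq[r] = mapq;
    out_ed[r] = bestWr.c.e;
    out_indel[r] = bestWr.has_indel;
    out_reflen[r] = bestWr.ref_len;
    out_cigar[r] = bestWr.cigar;
    out_seq[r] = bestMinus ? strands[1] : fwd;
  }

  return List::create(
      _["mapped"] = out_mapped, _["chrom_idx"] = out_chrom,
      _["start"] = out_start, _["strand"] = out_strand,
      _["mapq"] = out_mapq, _["edit_distance"] = out_ed,
      _["has_indel"] = out_indel, _["ref_len"] = out_reflen,
      _["cigar"] = out_cigar, _["seq_fwd"] = out_seq);
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}
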