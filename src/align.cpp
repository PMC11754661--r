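// Seed-and-extend alignment of concatemer read fragments against a small
// genome: exact k-mer seeds, diagonal-band clustering, banded affine-gap
// local extension.  Scores are raw alignment scores (match/mismatch plus
// affine gap costs); a gap of length L costs gap_open + L * gap_extend.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

struct Seg {             // a run of seeds on one diagonal
  int chrom;
  long diag;             // gpos - rpos
  int rmin, rmax;        // seed start positions on the read (0-based)
  long dmin, dmax;       // diag range after merging
  int nseeds;
  long best_diag;        // diagonal of the strongest constituent run
  int best_n;            // its seed count
  bool merged;
};

struct Cand {
  int read;              // 0-based read index
  int qstart, qend;      // 1-based inclusive, original read orientation
  int chrom;             // 0-based chrom index
  long tstart, tend;     // 1-based inclusive genome coords
  char strand;
  int score;
};

static const int NEG = -1000000000;

// Banded affine local alignment over a read window vs genome diagonals.
// Returns best local score plus begin/end coordinates (0-based, inclusive).
static bool banded_local(const std::string &rd, const std::string &gn,
                         int qs0, int qe0, long dmin, long dmax,
                         int match, int mismatch, int gap_open, int gap_extend,
                         int &best_score, int &bqs, int &bqe,
                         long &bts, long &bte) {
  const long Lc = (long)gn.size();
  const int D = (int)(dmax - dmin + 1);
  if (D <= 0 || qe0 <= qs0) return false;
  std::vector<int> Hprev(D, 0), Hcur(D, 0), Fprev(D, NEG), Fcur(D, NEG);
  std::vector<int> BqH_prev(D, -1), BtH_prev(D, -1), BqH_cur(D, -1), BtH_cur(D, -1);
  std::vector<int> BqF_prev(D, -1), BtF_prev(D, -1), BqF_cur(D, -1), BtF_cur(D, -1);
  best_score = 0;
  bqs = bqe = -1; bts = bte = -1;
  const int go = gap_open, ge = gap_extend;
  for (int i = qs0; i < qe0; ++i) {
    char rc = rd[i];
    int E = NEG, BqE = -1, BtE = -1;
    for (int d = 0; d < D; ++d) {
      long j = (long)i + dmin + d;
      if (j < 0 || j >= Lc) {
        Hcur[d] = 0; Fcur[d] = NEG;
        BqH_cur[d] = -1; BtH_cur[d] = -1;
        BqF_cur[d] = -1; BtF_cur[d] = -1;
        E = NEG; BqE = -1; BtE = -1;
        continue;
      }
      char gc = gn[(size_t)j];
      int sub = (rc == gc && rc != 'N') ? match : mismatch;
      // F: gap in read (genome row advance): from (i-1, j) => prev row, d+1
      int f = NEG, bqf = -1, btf = -1;
      if (d + 1 < D) {
        int fo = Hprev[d + 1] - go - ge;
        int fe = Fprev[d + 1] - ge;
        if (fo >= fe) { f = fo; bqf = BqH_prev[d + 1]; btf = BtH_prev[d + 1]; }
        else { f = fe; bqf = BqF_prev[d + 1]; btf = BtF_prev[d + 1]; }
      }
      // E: gap in genome (read stays): from (i, j-1) => same row, d-1
      int e = NEG, bqe_ = -1, bte_ = -1;
      {
        int eo = (d > 0 ? Hcur[d - 1] : NEG) - go - ge;
        int ee = E - ge;
        if (eo >= ee) { e = eo; bqe_ = (d > 0 ? BqH_cur[d - 1] : -1); bte_ = (d > 0 ? BtH_cur[d - 1] : -1); }
        else { e = ee; bqe_ = BqE; bte_ = BtE; }
      }
      // H: diagonal from (i-1, j-1) => prev row, same d
      int hd = Hprev[d] + sub;
      int bqd, btd;
      if (Hprev[d] == 0 || BqH_prev[d] < 0) { bqd = i; btd = (int)j; }
      else { bqd = BqH_prev[d]; btd = BtH_prev[d]; }
      int h = hd, bq = bqd, bt = btd;
      if (e > h) { h = e; bq = bqe_; bt = bte_; }
      if (f > h) { h = f; bq = bqf; bt = btf; }
      if (h < 0) { h = 0; bq = -1; bt = -1; }
      Hcur[d] = h; BqH_cur[d] = bq; BtH_cur[d] = bt;
      Fcur[d] = f; BqF_cur[d] = bqf; BtF_cur[d] = btf;
      E = e; BqE = bqe_; BtE = bte_;
      if (h > best_score) {
        best_score = h; bqs = bq; bqe = i; bts = bt; bte = j;
      }
    }
    std::swap(Hprev, Hcur); std::swap(Fprev, Fcur);
    std::swap(BqH_prev, BqH_cur); std::swap(BtH_prev, BtH_cur);
    std::swap(BqF_prev, BqF_cur); std::swap(BtF_prev, BtF_cur);
  }
  return best_score > 0 && bqs >= 0;
}

// [[Rcpp::export]]
DataFrame cpp_align_candidates(CharacterVector chrom_seqs,
                               CharacterVector read_seqs,
                               int k, int match, int mismatch,
                               int gap_open, int gap_extend,
                               int min_score, int band,
                               int pad, int max_seed_gap,
                               int max_kmer_hits) {
  const int nchrom = chrom_seqs.size();
  std::vector<std::string> gn(nchrom);
  for (int c = 0; c < nchrom; ++c) gn[c] = as<std::string>(chrom_seqs[c]);

  // k-mer index of the plus strand
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > idx;
  idx.reserve(1 << 20);
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int c = 0; c < nchrom; ++c) {
    const std::string &s = gn[c];
    uint64_t code = 0; int valid = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int b = base2bit(s[p]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= k) idx[code].push_back(std::make_pair(c, (int)(p - k + 1)));
    }
  }

  std::vector<Cand> cands;
  const int nreads = read_seqs.size();
  for (int r = 0; r < nreads; ++r) {
    std::string fwd = as<std::string>(read_seqs[r]);
    const int Lr = (int)fwd.size();
    if (Lr < k) continue;
    std::string rev(fwd.rbegin(), fwd.rend());
    for (size_t p = 0; p < rev.size(); ++p) rev[p] = comp(rev[p]);

    for (int ori = 0; ori < 2; ++ori) {
      const std::string &rd = (ori == 0) ? fwd : rev;
      // seed hits
      std::vector<Seg> segs;
      {
        // collect (chrom, diag, rpos) and split into diagonal runs
        std::vector<std::pair<std::pair<int, long>, int> > hits; // ((chrom,diag),rpos)
        uint64_t code = 0; int valid = 0;
        for (int p = 0; p < Lr; ++p) {
          int b = base2bit(rd[(size_t)p]);
          if (b < 0) { valid = 0; code = 0; continue; }
          code = ((code << 2) | (uint64_t)b) & mask;
          if (++valid < k) continue;
          int rpos = p - k + 1;
          std::unordered_map<uint64_t, std::vector<std::pair<int, int> > >::const_iterator it = idx.find(code);
          if (it == idx.end()) continue;
          const std::vector<std::pair<int, int> > &v = it->second;
          if ((int)v.size() > max_kmer_hits) continue;
          for (size_t q = 0; q < v.size(); ++q) {
            hits.push_back(std::make_pair(
              std::make_pair(v[q].first, (long)v[q].second - rpos), rpos));
          }
        }
        std::sort(hits.begin(), hits.end());
        size_t a = 0;
        while (a < hits.size()) {
          size_t b2 = a;
          Seg sg;
          sg.chrom = hits[a].first.first;
          sg.diag = hits[a].first.second;
          sg.rmin = sg.rmax = hits[a].second;
          sg.nseeds = 1; sg.merged = false;
          sg.dmin = sg.dmax = sg.diag;
          sg.best_diag = sg.diag;
          while (b2 + 1 < hits.size() &&
                 hits[b2 + 1].first == hits[a].first &&
                 hits[b2 + 1].second - hits[b2].second <= max_seed_gap) {
            ++b2;
            sg.rmax = hits[b2].second;
            ++sg.nseeds;
          }
          sg.best_n = sg.nseeds;
          segs.push_back(sg);
          a = b2 + 1;
        }
      }
      // merge nearby diagonal runs into clusters
      bool changed = true;
      while (changed) {
        changed = false;
        for (size_t a = 0; a < segs.size(); ++a) {
          if (segs[a].merged) continue;
          for (size_t b2 = a + 1; b2 < segs.size(); ++b2) {
            if (segs[b2].merged) continue;
            if (segs[a].chrom != segs[b2].chrom) continue;
            long ddist = std::max(segs[a].dmin, segs[b2].dmin) -
                         std::min(segs[a].dmax, segs[b2].dmax);
            if (ddist > band) continue;
            int rgap = std::max(segs[a].rmin, segs[b2].rmin) -
                       std::min(segs[a].rmax, segs[b2].rmax);
            if (rgap > max_seed_gap) continue;
            segs[a].rmin = std::min(segs[a].rmin, segs[b2].rmin);
            segs[a].rmax = std::max(segs[a].rmax, segs[b2].rmax);
            segs[a].dmin = std::min(segs[a].dmin, segs[b2].dmin);
            segs[a].dmax = std::max(segs[a].dmax, segs[b2].dmax);
            segs[a].nseeds += segs[b2].nseeds;
            if (segs[b2].best_n > segs[a].best_n) {
              segs[a].best_n = segs[b2].best_n;
              segs[a].best_diag = segs[b2].best_diag;
            }
            segs[b2].merged = true;
            changed = true;
          }
        }
      }
      // extend each cluster
      for (size_t a = 0; a < segs.size(); ++a) {
        if (segs[a].merged) continue;
        const Seg &sg = segs[a];
        int qs0 = std::max(0, sg.rmin - pad);
        int qe0 = std::min(Lr, sg.rmax + k + pad);
        long dmin = sg.dmin - band;
        long dmax = sg.dmax + band;
        if (dmax - dmin + 1 > 81) {
          // keep the band bounded; recentre on the best-supported diagonal
          // (repeat-dense fragments seed many weak off-register diagonals)
          dmin = sg.best_diag - 40; dmax = sg.best_diag + 40;
        }
        int score, bqs, bqe; long bts, bte;
        if (!banded_local(rd, gn[sg.chrom], qs0, qe0, dmin, dmax,
                          match, mismatch, gap_open, gap_extend,
                          score, bqs, bqe, bts, bte)) continue;
        if (score < min_score) continue;
        Cand cd;
        cd.read = r; cd.chrom = sg.chrom; cd.score = score;
        cd.tstart = bts + 1; cd.tend = bte + 1;
        if (ori == 0) {
          cd.qstart = bqs + 1; cd.qend = bqe + 1; cd.strand = '+';
        } else {
          cd.qstart = Lr - (bqe + 1) + 1; cd.qend = Lr - (bqs + 1) + 1;
          cd.strand = '-';
        }
        cands.push_back(cd);
      }
    }
  }

  // dedup identical candidates (same placement found from several clusters)
  std::sort(cands.begin(), cands.end(), [](const Cand &x, const Cand &y) {
    if (x.read != y.read) return x.read < y.read;
    if (x.qstart != y.qstart) return x.qstart < y.qstart;
    if (x.qend != y.qend) return x.qend < y.qend;
    if (x.chrom != y.chrom) return x.chrom < y.chrom;
    if (x.tstart != y.tstart) return x.tstart < y.tstart;
    if (x.strand != y.strand) return x.strand < y.strand;
    return x.score > y.score;
  });
  cands.erase(std::unique(cands.begin(), cands.end(),
                          [](const Cand &x, const Cand &y) {
    return x.read == y.read && x.qstart == y.qstart && x.qend == y.qend &&
           x.chrom == y.chrom && x.tstart == y.tstart && x.tend == y.tend &&
           x.strand == y.strand;
  }), cands.end());

  const size_t n = cands.size();
  IntegerVector read(n), qstart(n), qend(n), chrom(n), score(n);
  NumericVector tstart(n), tend(n);
  CharacterVector strand(n);
  for (size_t i = 0; i < n; ++i) {
    read[i] = cands[i].read + 1;
    qstart[i] = cands[i].qstart; qend[i] = cands[i].qend;
    chrom[i] = cands[i].chrom + 1;
    tstart[i] = (double)cands[i].tstart; tend[i] = (double)cands[i].tend;
    strand[i] = std::string(1, cands[i].strand);
    score[i] = cands[i].score;
  }
  return DataFrame::create(_["read"] = read, _["qstart"] = qstart,
                           _["qend"] = qend, _["chrom"] = chrom,
                           _["tstart"] = tstart, _["tend"] = tend,
                           _["strand"] = strand, _["score"] = score,
                           _["stringsAsFactors"] = false);
}
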