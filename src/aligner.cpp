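// Seed-and-extend local nucleotide matcher.
//
// Scoring is pinned package-wide: match +1, mismatch -1, gap open -2 for the
// first gap column, -1 for each further column (a gap of length L costs
// 2 + (L-1)).  Identity counts every alignment column, gaps included, as the
// denominator.  Two modes:
//   local  - Smith-Waterman local alignment (probe/locus matching);
//   glocal - query-global, target-local ("fitting") alignment used for
//            error-free read mapping, where the whole read must align.
//
// Seeding uses exact k-mers (2-bit packed, k <= 15); seed hits on one contig
// are clustered by diagonal and each cluster is verified with a banded affine
// dynamic program over a target window around the cluster.  Contigs shorter
// than a small-target cutoff skip seeding and are verified by a full dynamic
// program, iterated with target masking so multiple distinct locations can be
// reported.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const int MATCH_SCORE = 1;
static const int MISMATCH_SCORE = -1;
static const int GAP_OPEN = 2;   // cost of the first gap column
static const int GAP_EXT = 1;    // cost of each further gap column
static const int NEG_INF = -100000000;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = comp_base(c);
  return r;
}

static inline int subst(char a, char b) {
  // N never matches anything (including N): ambiguity is penalised.
  if (a == b && a != 'N' && a != '\1') return MATCH_SCORE;
  return MISMATCH_SCORE;
}

struct AlnResult {
  bool ok;
  int score;
  int qstart, qend;   // 0-based half-open on the query
  int tstart, tend;   // 0-based half-open on the (windowed) target
  int matches, columns;
};

// Banded affine alignment of q against t[tlo, thi).  Diagonals d = j - i
// (1-based DP indices) outside [dlo, dhi] are not computed.  glocal forces
// the full query into the alignment with free target ends.
static AlnResult banded_align(const std::string& q, const std::string& t,
                              int tlo, int thi, int dlo, int dhi,
                              bool glocal) {
  const int m = (int)q.size();
  const int n = thi - tlo;
  AlnResult res{false, 0, 0, 0, 0, 0, 0, 0};
  if (n <= 0 || m <= 0) return res;

  const size_t sz = (size_t)(m + 1) * (size_t)(n + 1);
  std::vector<int> M(sz, NEG_INF), X(sz, NEG_INF), Y(sz, NEG_INF);
  std::vector<uint8_t> dM(sz, 0), dX(sz, 0), dY(sz, 0);
  auto idx = [n](int i, int j) { return (size_t)i * (size_t)(n + 1) + (size_t)j; };

  // Row 0: free start in target.  In glocal mode the query may also begin
  // with gap columns (query char vs gap) via X.
  for (int j = 0; j <= n; ++j) M[idx(0, j)] = 0;

  int best = glocal ? NEG_INF : 0;
  int bi = -1, bj = -1; uint8_t bstate = 0;

  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i + dlo);
    int jhi = std::min(n, i + dhi);
    // X (query char against target gap) moves down a column: allow the band
    // edge so glocal tracebacks can consume trailing query in gaps.
    for (int j = std::max(0, jlo - 1); j <= jhi; ++j) {
      const size_t up = idx(i - 1, j);
      int openx = (M[up] > NEG_INF / 2) ? M[up] - GAP_OPEN : NEG_INF;
      int extx = (X[up] > NEG_INF / 2) ? X[up] - GAP_EXT : NEG_INF;
      if (openx >= extx) { X[idx(i, j)] = openx; dX[idx(i, j)] = 1; }
      else { X[idx(i, j)] = extx; dX[idx(i, j)] = 2; }
    }
    for (int j = jlo; j <= jhi; ++j) {
      const size_t dg = idx(i - 1, j - 1);
      const size_t here = idx(i, j);
      int s = subst(q[(size_t)i - 1], t[(size_t)(tlo + j - 1)]);
      int prev = M[dg]; uint8_t st = 1;
      if (X[dg] > prev) { prev = X[dg]; st = 2; }
      if (Y[dg] > prev) { prev = Y[dg]; st = 3; }
      if (!glocal && prev < 0) { prev = 0; st = 0; }  // local restart
      if (prev > NEG_INF / 2) { M[here] = prev + s; dM[here] = st; }

      const size_t left = idx(i, j - 1);
      int openy = (M[left] > NEG_INF / 2) ? M[left] - GAP_OPEN : NEG_INF;
      int exty = (Y[left] > NEG_INF / 2) ? Y[left] - GAP_EXT : NEG_INF;
      if (openy >= exty) { Y[here] = openy; dY[here] = 1; }
      else { Y[here] = exty; dY[here] = 2; }

      if (!glocal && M[here] > best) { best = M[here]; bi = i; bj = j; bstate = 1; }
    }
    if (glocal && i == m) {
      for (int j = std::max(0, jlo - 1); j <= jhi; ++j) {
        if (M[idx(m, j)] > best) { best = M[idx(m, j)]; bi = m; bj = j; bstate = 1; }
        if (X[idx(m, j)] > best) { best = X[idx(m, j)]; bi = m; bj = j; bstate = 2; }
      }
    }
  }
  if (bi < 0 || best <= (glocal ? NEG_INF / 2 : 0)) return res;

  // Traceback.
  int i = bi, j = bj; uint8_t st = bstate;
  int matches = 0, columns = 0;
  int qe = bi, te = bj;
  while (i > 0) {
    if (st == 1) {  // M: query char vs target char
      uint8_t d = dM[idx(i, j)];
      columns++;
      if (subst(q[(size_t)i - 1], t[(size_t)(tlo + j - 1)]) == MATCH_SCORE) matches++;
      i--; j--;
      if (d == 0) break;        // local restart
      st = d;
    } else if (st == 2) {       // X: query char vs gap
      uint8_t d = dX[idx(i, j)];
      columns++;
      i--;
      st = (d == 1) ? 1 : 2;
    } else {                    // Y: gap vs target char
      uint8_t d = dY[idx(i, j)];
      columns++;
      j--;
      st = (d == 1) ? 1 : 3;
    }
  }
  res.ok = true;
  res.score = best;
  res.qstart = i; res.qend = qe;
  res.tstart = tlo + j; res.tend = tlo + te;
  res.matches = matches; res.columns = columns;
  return res;
}

struct SeedIndex {
  int k;
  // packed kmer -> (contig, pos) list
  std::unordered_map<uint32_t, std::vector<std::pair<int, int>>> map;
};

static void index_contig(SeedIndex& ix, const std::string& s, int contig) {
  const int k = ix.k;
  const int n = (int)s.size();
  if (n < k) return;
  uint32_t kmer = 0, mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[(size_t)i]);
    if (c < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint32_t)c) & mask;
    if (++run >= k) ix.map[kmer].push_back({contig, i - k + 1});
  }
}

struct RawHit {
  int contig;
  int tstart, tend;
  char strand;
  int score;
  double identity, qcov;
  int qstart, qend;
};

struct SeedHit { int contig, diag, tpos; };

static void match_one_strand(const std::string& q, char strand,
                             const std::vector<std::string>& targets,
                             const SeedIndex& ix,
                             double min_identity, double min_qcov,
                             bool glocal, int band, int small_cutoff,
                             std::vector<RawHit>& out) {
  const int m = (int)q.size();
  const int k = ix.k;

  auto consider = [&](int contig, const AlnResult& a) {
    if (!a.ok || a.columns == 0) return;
    double identity = (double)a.matches / (double)a.columns;
    double qcov = glocal ? 1.0 : (double)(a.qend - a.qstart) / (double)m;
    if (identity + 1e-12 < min_identity) return;
    if (qcov + 1e-12 < min_qcov) return;
    out.push_back({contig, a.tstart, a.tend, strand, a.score, identity, qcov,
                   a.qstart, a.qend});
  };

  // Small contigs: exhaustive DP, iterated with masking for extra locations.
  for (int c = 0; c < (int)targets.size(); ++c) {
    const std::string& t = targets[(size_t)c];
    if ((int)t.size() > small_cutoff) continue;
    std::string tt = t;
    for (int iter = 0; iter < 8; ++iter) {
      AlnResult a = banded_align(q, tt, 0, (int)tt.size(), -(m + 1),
                                 (int)tt.size() + 1, glocal);
      if (!a.ok || a.score <= 0) break;
      double identity = a.columns ? (double)a.matches / a.columns : 0.0;
      consider(c, a);
      bool qualified = identity + 1e-12 >= min_identity;
      for (int p = a.tstart; p < a.tend; ++p) tt[(size_t)p] = '\1';
      if (!qualified) break;  // weaker secondary hits cannot qualify either
      if (a.tend <= a.tstart) break;
    }
  }

  // Seeded path for large contigs.
  if (m < k) return;
  std::vector<SeedHit> seeds;
  uint32_t kmer = 0, mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
  int run = 0;
  for (int i = 0; i < m; ++i) {
    int cc = base_code(q[(size_t)i]);
    if (cc < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint32_t)cc) & mask;
    if (++run >= k) {
      auto it = ix.map.find(kmer);
      if (it == ix.map.end()) continue;
      int qpos = i - k + 1;
      for (const auto& pr : it->second)
        seeds.push_back({pr.first, pr.second - qpos, pr.second});
    }
  }
  if (seeds.empty()) return;
  std::sort(seeds.begin(), seeds.end(), [](const SeedHit& a, const SeedHit& b) {
    if (a.contig != b.contig) return a.contig < b.contig;
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.tpos < b.tpos;
  });

  size_t i0 = 0;
  while (i0 < seeds.size()) {
    size_t i1 = i0 + 1;
    int dmin = seeds[i0].diag, dmax = seeds[i0].diag;
    int tmin = seeds[i0].tpos, tmax = seeds[i0].tpos;
    while (i1 < seeds.size() && seeds[i1].contig == seeds[i0].contig &&
           seeds[i1].diag - dmax <= band) {
      dmax = seeds[i1].diag;
      tmin = std::min(tmin, seeds[i1].tpos);
      tmax = std::max(tmax, seeds[i1].tpos);
      ++i1;
    }
    int c = seeds[i0].contig;
    const std::string& t = targets[(size_t)c];
    int tlo = std::max(0, std::min(tmin, dmin) - band - 8);
    int thi = std::min((int)t.size(), std::max(tmax + k, dmax + m) + band + 8);
    // Diagonals are absolute (j - i on the window after shifting by tlo).
    int dlo = dmin - tlo - band;
    int dhi = dmax - tlo + band;
    AlnResult a = banded_align(q, t, tlo, thi, dlo, dhi, glocal);
    consider(c, a);
    i0 = i1;
  }
}

static DataFrame hits_to_df(const std::vector<RawHit>& hits,
                            const std::vector<int>& qidx,
                            CharacterVector target_names) {
  const size_t n = hits.size();
  IntegerVector query(n), tstart(n), tend(n), score(n), qstart(n), qend(n);
  CharacterVector contig(n), strand(n);
  NumericVector identity(n), qcov(n);
  for (size_t i = 0; i < n; ++i) {
    query[i] = qidx[i];
    contig[i] = target_names[hits[i].contig];
    tstart[i] = hits[i].tstart;
    tend[i] = hits[i].tend;
    strand[i] = std::string(1, hits[i].strand);
    score[i] = hits[i].score;
    identity[i] = hits[i].identity;
    qcov[i] = hits[i].qcov;
    qstart[i] = hits[i].qstart;
    qend[i] = hits[i].qend;
  }
  return DataFrame::create(
      _["query"] = query, _["contig"] = contig, _["tstart"] = tstart,
      _["tend"] = tend, _["strand"] = strand, _["score"] = score,
      _["identity"] = identity, _["qcov"] = qcov, _["qstart"] = qstart,
      _["qend"] = qend, _["stringsAsFactors"] = false);
}

// Collapse overlapping hits of one query on one contig to the best-scoring
// hit (ties: leftmost), so repeated seeding of the same region is not counted
// as multiple capture locations.
static std::vector<RawHit> collapse_hits(std::vector<RawHit> hits) {
  std::sort(hits.begin(), hits.end(), [](const RawHit& a, const RawHit& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.contig != b.contig) return a.contig < b.contig;
    return a.tstart < b.tstart;
  });
  std::vector<RawHit> kept;
  for (const RawHit& h : hits) {
    bool clash = false;
    for (const RawHit& g : kept) {
      if (g.contig == h.contig && h.tstart < g.tend && g.tstart < h.tend) {
        clash = true;
        break;
      }
    }
    if (!clash) kept.push_back(h);
  }
  return kept;
}

// [[Rcpp::export]]
List cpp_match(CharacterVector queries, CharacterVector targets,
               CharacterVector target_names, double min_identity,
               double min_qcov, int seed_k, bool glocal, int band,
               int small_cutoff) {
  std::vector<std::string> tg(targets.size());
  for (int i = 0; i < targets.size(); ++i) tg[(size_t)i] = as<std::string>(targets[i]);

  SeedIndex ix; ix.k = seed_k;
  for (int c = 0; c < (int)tg.size(); ++c)
    if ((int)tg[(size_t)c].size() > small_cutoff) index_contig(ix, tg[(size_t)c], c);

  std::vector<RawHit> all;
  std::vector<int> qidx;
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    std::vector<RawHit> hits;
    match_one_strand(q, '+', tg, ix, min_identity, min_qcov, glocal, band,
                     small_cutoff, hits);
    std::string qr = revcomp(q);
    std::vector<RawHit> rhits;
    match_one_strand(qr, '-', tg, ix, min_identity, min_qcov, glocal, band,
                     small_cutoff, rhits);
    hits.insert(hits.end(), rhits.begin(), rhits.end());
    hits = collapse_hits(hits);
    std::sort(hits.begin(), hits.end(), [&tg](const RawHit& a, const RawHit& b) {
      if (a.score != b.score) return a.score > b.score;
      if (a.contig != b.contig) return a.contig < b.contig;
      return a.tstart < b.tstart;
    });
    for (const RawHit& h : hits) { all.push_back(h); qidx.push_back(qi + 1); }
  }
  return List::create(_["hits"] = hits_to_df(all, qidx, target_names));
}

// Best local (or glocal) alignment of a single pair by exhaustive DP.
// [[Rcpp::export]]
List cpp_align_pair(std::string q, std::string t, bool glocal) {
  AlnResult a = banded_align(q, t, 0, (int)t.size(), -((int)q.size() + 1),
                             (int)t.size() + 1, glocal);
  if (!a.ok)
    return List::create(_["score"] = 0, _["identity"] = 0.0, _["qcov"] = 0.0,
                        _["tstart"] = NA_INTEGER, _["tend"] = NA_INTEGER,
                        _["qstart"] = NA_INTEGER, _["qend"] = NA_INTEGER,
                        _["matches"] = 0, _["columns"] = 0);
  return List::create(
      _["score"] = a.score,
      _["identity"] = a.columns ? (double)a.matches / a.columns : 0.0,
      _["qcov"] = (double)(a.qend - a.qstart) / (double)q.size(),
      _["tstart"] = a.tstart, _["tend"] = a.tend, _["qstart"] = a.qstart,
      _["qend"] = a.qend, _["matches"] = a.matches, _["columns"] = a.columns);
}

// Candidate-pair similarity scan used by probe deduplication: pairs sharing
// an exact seed (either orientation) are verified by full DP.  An edge means
// the best local alignment scores at least min_score (the HSP significance
// floor), reaches the identity threshold, and covers the required fraction
// of at least one of the two sequences.
// [[Rcpp::export]]
DataFrame cpp_similar_pairs(CharacterVector seqs, double min_identity,
                            double min_cov, int seed_k, int min_score) {
  const int n = seqs.size();
  std::vector<std::string> fw((size_t)n), rc((size_t)n);
  for (int i = 0; i < n; ++i) {
    fw[(size_t)i] = as<std::string>(seqs[i]);
    rc[(size_t)i] = revcomp(fw[(size_t)i]);
  }
  SeedIndex ix; ix.k = seed_k;
  for (int i = 0; i < n; ++i) index_contig(ix, fw[(size_t)i], i);

  // Pairs must share at least two seed k-mers before DP verification: one
  // shared k-mer between unrelated baits is common by chance, while any pair
  // clearing the score floor shares many.  Seed diagonals (query = the
  // lower-index sequence of the pair, per orientation) bound the banded
  // verification window.
  struct PairInfo {
    int cnt = 0;
    int fdmin = 0, fdmax = 0, fcnt = 0;  // fw(a) vs fw(b)
    int rdmin = 0, rdmax = 0, rcnt = 0;  // rc(a) vs fw(b)
  };
  std::unordered_map<uint64_t, PairInfo> cand;
  const int k = ix.k;
  auto note = [&](int a, int b, int diag, bool rcori) {
    PairInfo& pi = cand[((uint64_t)a << 32) | (uint64_t)b];
    pi.cnt++;
    if (rcori) {
      if (pi.rcnt++ == 0) { pi.rdmin = pi.rdmax = diag; }
      else { pi.rdmin = std::min(pi.rdmin, diag); pi.rdmax = std::max(pi.rdmax, diag); }
    } else {
      if (pi.fcnt++ == 0) { pi.fdmin = pi.fdmax = diag; }
      else { pi.fdmin = std::min(pi.fdmin, diag); pi.fdmax = std::max(pi.fdmax, diag); }
    }
  };
  auto scan = [&](const std::string& s, int self, bool is_rc) {
    if ((int)s.size() < k) return;
    uint32_t kmer = 0, mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
    int run = 0;
    const int ls = (int)s.size();
    for (int p = 0; p < ls; ++p) {
      int c = base_code(s[(size_t)p]);
      if (c < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint32_t)c) & mask;
      if (++run < k) continue;
      auto it = ix.map.find(kmer);
      if (it == ix.map.end()) continue;
      int qp = p - k + 1;
      for (const auto& pr : it->second) {
        int j = pr.first, pj = pr.second;
        // every shared k-mer of a pair is seen when scanning its lower-index
        // member, so the self > j hits are duplicates and skipped
        if (j <= self) continue;
        note(self, j, pj - qp, is_rc);
      }
    }
  };
  for (int i = 0; i < n; ++i) { scan(fw[(size_t)i], i, false); scan(rc[(size_t)i], i, true); }

  const int band = 16;
  std::vector<int> ii, jj;
  for (const auto& kv : cand) {
    if (kv.second.cnt < 2) continue;
    uint64_t key = kv.first;
    int a = (int)(key >> 32), b = (int)(key & 0xFFFFFFFFu);
    const std::string& tb = fw[(size_t)b];
    const int nb = (int)tb.size();
    bool edge = false;
    for (int ori = 0; ori < 2 && !edge; ++ori) {
      const PairInfo& pi = kv.second;
      int scnt = ori ? pi.rcnt : pi.fcnt;
      if (scnt == 0) continue;
      int dmin = ori ? pi.rdmin : pi.fdmin;
      int dmax = ori ? pi.rdmax : pi.fdmax;
      const std::string& qa = ori ? rc[(size_t)a] : fw[(size_t)a];
      const int la = (int)qa.size();
      int tlo = std::max(0, dmin - band - 8);
      int thi = std::min(nb, dmax + la + band + 8);
      AlnResult r = banded_align(qa, tb, tlo, thi,
                                 dmin - tlo - band, dmax - tlo + band, false);
      if (!r.ok || r.columns == 0 || r.score < min_score) continue;
      double identity = (double)r.matches / r.columns;
      double cov_a = (double)(r.qend - r.qstart) / (double)la;
      double cov_b = (double)(r.tend - r.tstart) / (double)nb;
      if (identity + 1e-12 >= min_identity &&
          std::max(cov_a, cov_b) + 1e-12 >= min_cov)
        edge = true;
    }
    if (edge) { ii.push_back(a + 1); jj.push_back(b + 1); }
  }
  return DataFrame::create(_["i"] = wrap(ii), _["j"] = wrap(jj));
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  out.names() = x.names();
  return out;
}
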