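#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <climits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// basic sequence utilities
// ---------------------------------------------------------------------------

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char upbase(char c) {
  if (c >= 'a' && c <= 'z') return c - 32;
  return c;
}

static inline char comp(char c) {
  switch (upbase(c)) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'N': return 'N';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
  return r;
}

// case-insensitive exact base match; ambiguity letters match only themselves
static inline bool base_eq(char a, char b) { return upbase(a) == upbase(b); }

// ---------------------------------------------------------------------------
// k-mer index over the forward strand of a reference set
// ---------------------------------------------------------------------------

struct RefIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<uint64_t> > table; // key -> (tid<<32)|pos
};

// [[Rcpp::export]]
SEXP mb_build_index(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 8 || k > 31) stop("k must be in [8, 31]");
  RefIndex* idx = new RefIndex();
  idx->k = k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    idx->names.push_back(as<std::string>(names[s]));
    uint64_t key = 0;
    int run = 0;
    for (size_t i = 0; i < seq.size(); ++i) {
      int b = base2bit(seq[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        uint64_t val = ((uint64_t)s << 32) | (uint64_t)(i + 1 - k);
        idx->table[key].push_back(val);
      }
    }
    idx->seqs.push_back(seq);
  }
  XPtr<RefIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
List mb_index_info(SEXP ptr) {
  XPtr<RefIndex> idx(ptr);
  IntegerVector lens(idx->seqs.size());
  CharacterVector nms(idx->seqs.size());
  for (size_t i = 0; i < idx->seqs.size(); ++i) {
    lens[i] = (int)idx->seqs[i].size();
    nms[i] = idx->names[i];
  }
  return List::create(_["names"] = nms, _["lengths"] = lens, _["k"] = idx->k);
}

// ---------------------------------------------------------------------------
// banded affine-gap alignment with traceback
//   layers: M (diagonal), E (op 'D', consumes target), F (op 'I', consumes query)
//   gap of length L costs gap_open + gap_extend * L
//   mode 0: global (corner to corner); mode 1: extension (anchored at (0,0),
//           ends at the best-scoring cell anywhere)
// ---------------------------------------------------------------------------

struct CigOp { char op; int len; };

struct AlnResult {
  long score;
  int matches, columns, qend, tend;
  bool touched;               // optimal path touched the band edge (global mode)
  std::vector<CigOp> cig;     // query->target order
};

static void cig_push(std::vector<CigOp>& c, char op, int len) {
  if (len <= 0) return;
  if (!c.empty() && c.back().op == op) c.back().len += len;
  else c.push_back({op, len});
}

static const int NEG = INT_MIN / 4;

static AlnResult band_align_core(const std::string& a, const std::string& b,
                                 int match, int mismatch, int gap_open,
                                 int gap_extend, int slack, int mode) {
  int n = (int)a.size(), m = (int)b.size();
  AlnResult res; res.score = 0; res.matches = 0; res.columns = 0;
  res.qend = 0; res.tend = 0; res.touched = false;
  if (n == 0 && m == 0) return res;
  if (n == 0) { cig_push(res.cig, 'D', m); res.columns = m; res.tend = m;
                res.score = -(long)(gap_open + gap_extend * m); return res; }
  if (m == 0) { cig_push(res.cig, 'I', n); res.columns = n; res.qend = n;
                res.score = -(long)(gap_open + gap_extend * n); return res; }
  if (slack < 1) slack = 1;
  int dlo = std::min(0, m - n) - slack;
  int dhi = std::max(0, m - n) + slack;
  int w = dhi - dlo + 1;
  if ((double)(n + 1) * w > 4e8) stop("banded alignment matrix too large");

  // reusable scratch (single-threaded R): avoids per-call allocation in the
  // many small gap-fill alignments along a chain
  static std::vector<int> Mc, Ec, Fc, Mp, Ep, Fp;
  static std::vector<uint8_t> tb;
  Mc.assign(w, NEG); Ec.assign(w, NEG); Fc.assign(w, NEG);
  Mp.assign(w, NEG); Ep.assign(w, NEG); Fp.assign(w, NEG);
  // traceback byte: bits0-1 best layer (0 M,1 E,2 F); bit2 E opened; bit3 F opened
  tb.assign((size_t)(n + 1) * w, 0);

  auto off = [&](int i, int j) { return j - i - dlo; };
  int bi = 0, bj = 0; long bscore = LONG_MIN;

  // row 0
  for (int j = std::max(0, dlo); j <= std::min(m, dhi); ++j) {
    int o = off(0, j);
    if (j == 0) { Mp[o] = 0; Ep[o] = NEG; Fp[o] = NEG; tb[o] = 0; }
    else {
      Ep[o] = -(gap_open + gap_extend * j);
      Mp[o] = NEG; Fp[o] = NEG;
      tb[o] = 1 | (j == 1 ? 4 : 0);
    }
  }
  if (mode == 1) { bscore = 0; bi = 0; bj = 0; }

  const int goe = gap_open + gap_extend;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(0, i + dlo), jhi = std::min(m, i + dhi);
    int olo = jlo - i - dlo, ohi = jhi - i - dlo;
    int* Mc_ = Mc.data(); int* Ec_ = Ec.data(); int* Fc_ = Fc.data();
    const int* Mp_ = Mp.data(); const int* Ep_ = Ep.data();
    const int* Fp_ = Fp.data();
    uint8_t* tb_ = tb.data() + (size_t)i * w;
    if (olo > 0) { Mc_[olo - 1] = Ec_[olo - 1] = Fc_[olo - 1] = NEG; }
    if (ohi < w - 1) { Mc_[ohi + 1] = Ec_[ohi + 1] = Fc_[ohi + 1] = NEG; }
    const char ai = a[i - 1];
    // previous-row offsets: diag (i-1,j-1) -> o; up (i-1,j) -> o+1
    int prev_olo = std::max(0, (i - 1) + dlo) - (i - 1) - dlo;
    int prev_ohi = std::min(m, (i - 1) + dhi) - (i - 1) - dlo;
    for (int j = jlo; j <= jhi; ++j) {
      int o = j - i - dlo;
      uint8_t t = 0;
      // M from diag (i-1, j-1), prev-row offset o
      int diag = NEG;
      if (j >= 1 && o >= prev_olo && o <= prev_ohi) {
        int pv = std::max(Mp_[o], std::max(Ep_[o], Fp_[o]));
        if (pv > NEG / 2)
          diag = pv + (base_eq(ai, b[j - 1]) ? match : mismatch);
      }
      Mc_[o] = diag;
      // E from (i, j-1), same row offset o-1
      int Ev = NEG;
      if (j - 1 >= jlo) {
        int open = std::max(Mc_[o - 1], std::max(Ec_[o - 1], Fc_[o - 1]));
        int cont = Ec_[o - 1];
        int ov = (open > NEG / 2) ? open - goe : NEG;
        int cv = (cont > NEG / 2) ? cont - gap_extend : NEG;
        if (ov >= cv) { Ev = ov; t |= 4; } else Ev = cv;
      }
      Ec_[o] = Ev;
      // F from (i-1, j), prev-row offset o+1
      int Fv = NEG;
      if (o + 1 >= prev_olo && o + 1 <= prev_ohi) {
        int open = std::max(Mp_[o + 1], std::max(Ep_[o + 1], Fp_[o + 1]));
        int cont = Fp_[o + 1];
        int ov = (open > NEG / 2) ? open - goe : NEG;
        int cv = (cont > NEG / 2) ? cont - gap_extend : NEG;
        if (ov >= cv) { Fv = ov; t |= 8; } else Fv = cv;
      }
      Fc_[o] = Fv;
      int best = diag; int bl = 0;
      if (Ev > best) { best = Ev; bl = 1; }
      if (Fv > best) { best = Fv; bl = 2; }
      t |= (uint8_t)bl;
      tb_[o] = t;
      if (mode == 1 && best > NEG / 2 && (long)best > bscore) {
        bscore = best; bi = i; bj = j;
      }
    }
    std::swap(Mc, Mp); std::swap(Ec, Ep); std::swap(Fc, Fp);
    // extension mode: give up when the best score stops improving (X-drop)
    if (mode == 1 && i - bi > 50) { break; }
  }

  int ei, ej;
  if (mode == 0) {
    ei = n; ej = m;
    int o = off(n, m);
    if (o < 0 || o >= w) stop("band does not reach the corner");
    bscore = std::max(Mp[o], std::max(Ep[o], Fp[o]));
  } else {
    ei = bi; ej = bj;
  }
  res.score = bscore; res.qend = ei; res.tend = ej;

  // traceback
  std::vector<CigOp> rev;
  int i = ei, j = ej;
  int layer = tb[(size_t)i * w + off(i, j)] & 3;
  while (i > 0 || j > 0) {
    if (mode == 1 && i == 0 && j == 0) break;
    int jlo = std::max(0, i + dlo), jhi = std::min(m, i + dhi);
    if (i > 0 && i < n && (j == jlo || j == jhi)) res.touched = true;
    uint8_t t = tb[(size_t)i * w + off(i, j)];
    if (layer == 0) {
      if (i == 0 || j == 0) break; // shouldn't happen in global mode
      cig_push(rev, base_eq(a[i - 1], b[j - 1]) ? '=' : 'X', 1);
      --i; --j;
      layer = tb[(size_t)i * w + off(i, j)] & 3;
    } else if (layer == 1) {
      cig_push(rev, 'D', 1);
      bool opened = (t & 4) != 0;
      --j;
      if (j < 0) break;
      layer = opened ? (tb[(size_t)i * w + off(i, j)] & 3) : 1;
      if (j == 0 && i == 0) break;
    } else {
      cig_push(rev, 'I', 1);
      bool opened = (t & 8) != 0;
      --i;
      if (i < 0) break;
      layer = opened ? (tb[(size_t)i * w + off(i, j)] & 3) : 2;
    }
    if (mode == 1 && i == 0 && j == 0) break;
  }
  // reverse op order
  res.cig.assign(rev.rbegin(), rev.rend());
  // merge adjacent same ops after reversal
  std::vector<CigOp> merged;
  for (auto& c : res.cig) cig_push(merged, c.op, c.len);
  res.cig = merged;
  for (auto& c : res.cig) {
    res.columns += c.len;
    if (c.op == '=') res.matches += c.len;
  }
  return res;
}

static AlnResult band_align_auto(const std::string& a, const std::string& b,
                                 int match, int mismatch, int gap_open,
                                 int gap_extend, int slack, int mode,
                                 bool* widened) {
  int s = std::max(1, slack);
  if (widened) *widened = false;
  for (int iter = 0; iter < 5; ++iter) {
    AlnResult r = band_align_core(a, b, match, mismatch, gap_open, gap_extend, s, mode);
    if (!r.touched || mode == 1) return r;
    int lim = (int)std::max(a.size(), b.size());
    if (s >= lim) return r;
    s = std::min(lim, s * 2);
    if (widened) *widened = true;
  }
  return band_align_core(a, b, match, mismatch, gap_open, gap_extend, s, mode);
}

static std::string cig_string(const std::vector<CigOp>& c) {
  std::string out;
  char buf[16];
  for (auto& o : c) { snprintf(buf, sizeof(buf), "%d%c", o.len, o.op); out += buf; }
  return out;
}

// [[Rcpp::export]]
List mb_banded_global(std::string a, std::string b, int match, int mismatch,
                      int gap_open, int gap_extend, int band_slack) {
  bool widened = false;
  AlnResult r = band_align_auto(a, b, match, mismatch, gap_open, gap_extend,
                                band_slack, 0, &widened);
  return List::create(_["score"] = (double)r.score,
                      _["matches"] = r.matches,
                      _["columns"] = r.columns,
                      _["cigar"] = cig_string(r.cig),
                      _["widened"] = widened);
}

// ---------------------------------------------------------------------------
// seed collection, diagonal clustering, chaining, fill-in alignment
// ---------------------------------------------------------------------------

struct Anchor { int tid, tpos, qpos; };

struct Seg { int qs, ts, len; };

struct Hit {
  int tid, tstart, tend, qstart, qend, matches, columns, nseed;
  long score;
  char strand;
  std::vector<CigOp> cig;
};

static long cigar_score(const std::vector<CigOp>& cig, int match, int mismatch,
                        int gap_open, int gap_extend) {
  long s = 0;
  for (auto& c : cig) {
    if (c.op == '=') s += (long)match * c.len;
    else if (c.op == 'X') s += (long)mismatch * c.len;
    else s -= (long)(gap_open + gap_extend * c.len);
  }
  return s;
}

// chain anchors (sorted by qpos) of one diagonal cluster into runs of merged
// exact seed matches; splits on gaps > max_seed_gap
static void chain_cluster(std::vector<Anchor>& anc, int k, int max_seed_gap,
                          std::vector<std::vector<Seg> >& chains,
                          std::vector<int>& chain_nseed) {
  std::sort(anc.begin(), anc.end(), [](const Anchor& x, const Anchor& y) {
    return x.qpos != y.qpos ? x.qpos < y.qpos : x.tpos < y.tpos;
  });
  std::vector<Seg> cur;
  int nseed = 0;
  int qe = -1, te = -1;      // current run end
  int qs0 = 0, ts0 = 0;      // current run start
  auto close_run = [&]() {
    if (qe >= 0) cur.push_back({qs0, ts0, qe - qs0});
  };
  auto close_chain = [&]() {
    close_run();
    if (!cur.empty()) { chains.push_back(cur); chain_nseed.push_back(nseed); }
    cur.clear(); nseed = 0; qe = te = -1;
  };
  for (auto& a : anc) {
    if (qe < 0) { qs0 = a.qpos; ts0 = a.tpos; qe = a.qpos + k; te = a.tpos + k; nseed = 1; continue; }
    int rdiag = ts0 - qs0;
    if (a.tpos - a.qpos == rdiag && a.qpos <= qe) {
      // same diagonal, overlapping/adjacent: extend the exact run
      if (a.qpos + k > qe) { qe = a.qpos + k; te = a.tpos + k; }
      ++nseed;
    } else if (a.qpos >= qe && a.tpos >= te) {
      if (a.qpos - qe > max_seed_gap || a.tpos - te > max_seed_gap) close_chain();
      else close_run();
      qs0 = a.qpos; ts0 = a.tpos; qe = a.qpos + k; te = a.tpos + k; ++nseed;
    } // else: conflicting anchor, skip
  }
  close_chain();
}

static Hit align_chain(const std::string& q, const std::string& t,
                       const std::vector<Seg>& segs, int nseed, int tid,
                       char strand, int match, int mismatch, int gap_open,
                       int gap_extend, int max_ext) {
  Hit h; h.tid = tid; h.strand = strand; h.nseed = nseed;
  std::vector<CigOp> cig;
  cig_push(cig, '=', segs[0].len);
  for (size_t i = 1; i < segs.size(); ++i) {
    int qg = segs[i].qs - (segs[i - 1].qs + segs[i - 1].len);
    int tg = segs[i].ts - (segs[i - 1].ts + segs[i - 1].len);
    if (qg > 0 && qg == tg && qg <= 6) {
      // equal small gap: the diagonal is provably optimal under these scores
      int q0 = segs[i - 1].qs + segs[i - 1].len;
      int t0 = segs[i - 1].ts + segs[i - 1].len;
      for (int x = 0; x < qg; ++x)
        cig_push(cig, base_eq(q[q0 + x], t[t0 + x]) ? '=' : 'X', 1);
    } else if (qg > 0 || tg > 0) {
      std::string qa = q.substr(segs[i - 1].qs + segs[i - 1].len, qg);
      std::string ta = t.substr(segs[i - 1].ts + segs[i - 1].len, tg);
      int slack = std::max(8, std::abs(qg - tg) + 8);
      AlnResult g = band_align_auto(qa, ta, match, mismatch, gap_open,
                                    gap_extend, slack, 0, nullptr);
      for (auto& c : g.cig) cig_push(cig, c.op, c.len);
    }
    cig_push(cig, '=', segs[i].len);
  }
  int qs = segs.front().qs, ts = segs.front().ts;
  int qe = segs.back().qs + segs.back().len, te = segs.back().ts + segs.back().len;
  // right extension (local, X-drop by best-cell)
  {
    int ql = std::min((int)q.size() - qe, max_ext);
    int tl = std::min((int)t.size() - te, ql + 50);
    if (ql > 0 && tl > 0) {
      AlnResult e = band_align_auto(q.substr(qe, ql), t.substr(te, tl), match,
                                    mismatch, gap_open, gap_extend, 50, 1, nullptr);
      if (e.score > 0) {
        for (auto& c : e.cig) cig_push(cig, c.op, c.len);
        qe += e.qend; te += e.tend;
      }
    }
  }
  // left extension on reversed strings
  {
    int ql = std::min(qs, max_ext);
    int tl = std::min(ts, ql + 50);
    if (ql > 0 && tl > 0) {
      std::string qa = q.substr(qs - ql, ql); std::reverse(qa.begin(), qa.end());
      std::string ta = t.substr(ts - tl, tl); std::reverse(ta.begin(), ta.end());
      AlnResult e = band_align_auto(qa, ta, match, mismatch, gap_open,
                                    gap_extend, 50, 1, nullptr);
      if (e.score > 0) {
        std::vector<CigOp> pre(e.cig.rbegin(), e.cig.rend());
        std::vector<CigOp> merged;
        for (auto& c : pre) cig_push(merged, c.op, c.len);
        for (auto& c : cig) cig_push(merged, c.op, c.len);
        cig = merged;
        qs -= e.qend; ts -= e.tend;
      }
    }
  }
  h.qstart = qs; h.qend = qe; h.tstart = ts; h.tend = te;
  h.cig = cig;
  h.matches = 0; h.columns = 0;
  for (auto& c : cig) { h.columns += c.len; if (c.op == '=') h.matches += c.len; }
  h.score = cigar_score(cig, match, mismatch, gap_open, gap_extend);
  return h;
}

// [[Rcpp::export]]
List mb_map(SEXP ptr, std::string read, int max_seed_gap, int band_width,
            int match, int mismatch, int gap_open, int gap_extend,
            int min_chain_seeds, int min_aln_len, int max_occ, int max_ext,
            int max_hits, int max_split_hits) {
  XPtr<RefIndex> idx(ptr);
  int k = idx->k;
  int L = (int)read.size();
  std::vector<Hit> hits;
  const uint64_t mask = (1ULL << (2 * k)) - 1;

  struct Cand {
    std::vector<Seg> segs;
    int nseed, tid;
    char strand;
    long proxy;   // exact-matched bases in the chain
  };
  std::vector<Cand> cands;
  std::string qfwd = read, qrev = revcomp(read);

  for (int strand = 0; strand < 2; ++strand) {
    const std::string& q = strand == 0 ? qfwd : qrev;
    std::vector<Anchor> anchors;
    uint64_t key = 0; int run = 0;
    for (int i = 0; i < (int)q.size(); ++i) {
      int b = base2bit(q[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        auto it = idx->table.find(key);
        if (it != idx->table.end() && (int)it->second.size() <= max_occ) {
          for (uint64_t v : it->second)
            anchors.push_back({(int)(v >> 32), (int)(v & 0xffffffffULL), i + 1 - k});
        }
      }
    }
    if (anchors.empty()) continue;
    std::sort(anchors.begin(), anchors.end(), [](const Anchor& x, const Anchor& y) {
      if (x.tid != y.tid) return x.tid < y.tid;
      long dx = (long)x.tpos - x.qpos, dy = (long)y.tpos - y.qpos;
      if (dx != dy) return dx < dy;
      return x.qpos < y.qpos;
    });
    // diagonal clusters -> chains (alignment deferred)
    size_t start = 0;
    for (size_t i = 1; i <= anchors.size(); ++i) {
      bool brk = i == anchors.size() ||
        anchors[i].tid != anchors[start].tid ||
        ((long)anchors[i].tpos - anchors[i].qpos) -
        ((long)anchors[i - 1].tpos - anchors[i - 1].qpos) > band_width;
      if (brk) {
        if (i - start >= (size_t)min_chain_seeds) {
          std::vector<Anchor> cl(anchors.begin() + start, anchors.begin() + i);
          std::vector<std::vector<Seg> > chains;
          std::vector<int> nseed;
          int tid = cl[0].tid;
          chain_cluster(cl, k, max_seed_gap, chains, nseed);
          for (size_t c = 0; c < chains.size(); ++c) {
            if (nseed[c] < min_chain_seeds) continue;
            long proxy = 0;
            for (auto& s : chains[c]) proxy += s.len;
            Cand cd; cd.segs = chains[c]; cd.nseed = nseed[c]; cd.tid = tid;
            cd.strand = strand == 0 ? '+' : '-'; cd.proxy = proxy;
            cands.push_back(std::move(cd));
          }
        }
        start = i;
      }
    }
  }
  // align only the strongest chains (by exact-matched bases), but always
  // admit chains covering a query region no aligned chain covers yet (e.g.
  // the flank alignment of a read spanning a repeat insertion)
  std::sort(cands.begin(), cands.end(), [](const Cand& x, const Cand& y) {
    return x.proxy > y.proxy;
  });
  long best_proxy = cands.empty() ? 0 : cands[0].proxy;
  int aligned = 0, aligned_new = 0;
  std::vector<std::pair<int, int> > spans;  // original-read coords
  for (auto& cd : cands) {
    if (aligned + aligned_new >= 6 * max_hits) break;
    int cqs = cd.segs.front().qs;
    int cqe = cd.segs.back().qs + cd.segs.back().len;
    int oqs = cd.strand == '+' ? cqs : L - cqe;
    int oqe = cd.strand == '+' ? cqe : L - cqs;
    bool newreg = true;
    for (auto& sp : spans) {
      int ov = std::min(oqe, sp.second) - std::max(oqs, sp.first);
      if (ov > (oqe - oqs) / 2) { newreg = false; break; }
    }
    bool treat_new = newreg && !spans.empty();
    if (treat_new) {
      if (aligned_new >= max_split_hits) continue;
    } else {
      if (aligned >= 2 * max_hits) continue;
      if (cd.proxy < best_proxy / 8 && cd.proxy < 200) continue;
    }
    const std::string& q = cd.strand == '+' ? qfwd : qrev;
    Hit h = align_chain(q, idx->seqs[cd.tid], cd.segs, cd.nseed, cd.tid,
                        cd.strand, match, mismatch, gap_open, gap_extend,
                        max_ext);
    if (h.qend - h.qstart >= min_aln_len) {
      hits.push_back(h);
      if (treat_new) ++aligned_new; else ++aligned;
      spans.push_back(std::make_pair(oqs, oqe));
    }
  }

  // drop duplicates: same tid+strand, both query and target intervals
  // overlapping a better hit by >50% of the smaller interval; the reporting
  // cap keeps records covering new query regions (split-read flanks)
  std::sort(hits.begin(), hits.end(), [](const Hit& x, const Hit& y) {
    return x.score > y.score;
  });
  std::vector<Hit> kept;
  int kept_same = 0, kept_new = 0;
  for (auto& h : hits) {
    bool dup = false, newreg = true;
    int hqs = h.strand == '+' ? h.qstart : L - h.qend;
    int hqe = h.strand == '+' ? h.qend : L - h.qstart;
    for (auto& g : kept) {
      int gqs = g.strand == '+' ? g.qstart : L - g.qend;
      int gqe = g.strand == '+' ? g.qend : L - g.qstart;
      long qo = std::min(gqe, hqe) - (long)std::max(gqs, hqs);
      if (qo > (hqe - hqs) / 2) newreg = false;
      if (g.tid != h.tid || g.strand != h.strand) continue;
      long to = std::min(g.tend, h.tend) - (long)std::max(g.tstart, h.tstart);
      long qo2 = std::min(g.qend, h.qend) - (long)std::max(g.qstart, h.qstart);
      long tmin = std::min(g.tend - g.tstart, h.tend - h.tstart);
      long qmin = std::min(g.qend - g.qstart, h.qend - h.qstart);
      if (to > tmin / 2 && qo2 > qmin / 2) { dup = true; break; }
    }
    if (dup) continue;
    bool treat_new = newreg && !kept.empty();
    if (treat_new ? (kept_new >= max_split_hits) : (kept_same >= max_hits))
      continue;
    kept.push_back(h);
    if (treat_new) ++kept_new; else ++kept_same;
    if ((int)kept.size() >= max_hits + max_split_hits) break;
  }

  int n = (int)kept.size();
  IntegerVector tid(n), tstart(n), tend(n), qstart(n), qend(n), matches(n),
    columns(n), nseed(n);
  NumericVector score(n);
  CharacterVector strand(n), cigar(n), tname(n);
  LogicalVector primary(n);
  // primary: max score, tie-break lowest (target name, target start)
  int best = -1;
  for (int i = 0; i < n; ++i) {
    if (best < 0) best = i;
    else if (kept[i].score > kept[best].score) best = i;
    else if (kept[i].score == kept[best].score) {
      const std::string& ni = idx->names[kept[i].tid];
      const std::string& nb = idx->names[kept[best].tid];
      if (ni < nb || (ni == nb && kept[i].tstart < kept[best].tstart)) best = i;
    }
  }
  for (int i = 0; i < n; ++i) {
    const Hit& h = kept[i];
    tid[i] = h.tid + 1;
    tname[i] = idx->names[h.tid];
    tstart[i] = h.tstart; tend[i] = h.tend;
    // query coordinates on the original read (PAF convention)
    if (h.strand == '+') { qstart[i] = h.qstart; qend[i] = h.qend; }
    else { qstart[i] = L - h.qend; qend[i] = L - h.qstart; }
    matches[i] = h.matches; columns[i] = h.columns;
    score[i] = (double)h.score; nseed[i] = h.nseed;
    strand[i] = std::string(1, h.strand);
    cigar[i] = cig_string(h.cig);
    primary[i] = (i == best);
  }
  return List::create(_["target_id"] = tname, _["target_start"] = tstart,
                      _["target_end"] = tend, _["query_start"] = qstart,
                      _["query_end"] = qend, _["strand"] = strand,
                      _["matches"] = matches, _["aln_columns"] = columns,
                      _["score"] = score, _["n_seeds"] = nseed,
                      _["cigar"] = cigar, _["is_primary"] = primary);
}

// ---------------------------------------------------------------------------
// pileup of alignments onto one target sequence
// rows: A, C, G, T, other, del, ins (insertion opening immediately after pos)
// cigars/query coordinates must be given in target orientation
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix mb_pileup(int tlen, IntegerVector tstart, IntegerVector qstart,
                        CharacterVector cigar, CharacterVector qseq) {
  IntegerMatrix out(7, tlen);
  for (int r = 0; r < tstart.size(); ++r) {
    std::string cig = as<std::string>(cigar[r]);
    std::string q = as<std::string>(qseq[r]);
    int tp = tstart[r], qp = qstart[r];
    size_t i = 0;
    while (i < cig.size()) {
      int len = 0;
      while (i < cig.size() && isdigit(cig[i])) { len = len * 10 + (cig[i] - '0'); ++i; }
      char op = cig[i++];
      if (op == '=' || op == 'X' || op == 'M') {
        for (int x = 0; x < len; ++x) {
          if (tp >= 0 && tp < tlen && qp < (int)q.size()) {
            int b = base2bit(q[qp]);
            out(b < 0 ? 4 : b, tp) += 1;
          }
          ++tp; ++qp;
        }
      } else if (op == 'D') {
        for (int x = 0; x < len; ++x) {
          if (tp >= 0 && tp < tlen) out(5, tp) += 1;
          ++tp;
        }
      } else if (op == 'I') {
        if (tp - 1 >= 0 && tp - 1 < tlen) out(6, tp - 1) += 1;
        qp += len;
      } else stop("unknown cigar op");
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// same-sequence k-mer anchor pairs (for LTR pair detection)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix mb_self_anchors(std::string seq, int k, int min_sep, int max_sep,
                              int max_occ) {
  if (k < 8 || k > 31) stop("k must be in [8, 31]");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::unordered_map<uint64_t, std::vector<int> > pos;
  uint64_t key = 0; int run = 0;
  for (int i = 0; i < (int)seq.size(); ++i) {
    int b = base2bit(seq[i]);
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++run >= k) pos[key].push_back(i + 1 - k);
  }
  std::vector<int> ii, jj;
  for (auto& kv : pos) {
    const std::vector<int>& v = kv.second;
    if (v.size() < 2 || (int)v.size() > max_occ) continue;
    for (size_t x = 0; x < v.size(); ++x)
      for (size_t y = x + 1; y < v.size(); ++y) {
        int sep = v[y] - v[x];
        if (sep >= min_sep && sep <= max_sep) { ii.push_back(v[x]); jj.push_back(v[y]); }
      }
  }
  IntegerMatrix out((int)ii.size(), 2);
  for (size_t x = 0; x < ii.size(); ++x) { out(x, 0) = ii[x]; out(x, 1) = jj[x]; }
  return out;
}

// ---------------------------------------------------------------------------
// per-base read corruption (substitution / insertion / deletion), R RNG
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector mb_corrupt(CharacterVector seqs, double sub, double ins, double del) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(seqs.size());
  for (int s = 0; s < seqs.size(); ++s) {
    std::string x = as<std::string>(seqs[s]);
    std::string y;
    y.reserve(x.size() + 16);
    for (size_t i = 0; i < x.size(); ++i) {
      double u = unif_rand();
      if (u < del) {
        // deleted
      } else if (u < del + sub) {
        int b = base2bit(x[i]);
        int nb = (int)(unif_rand() * 3);
        if (b < 0) b = (int)(unif_rand() * 4);
        y.push_back(B[(b + 1 + nb) % 4]);
      } else {
        y.push_back(upbase(x[i]));
      }
      if (unif_rand() < ins) y.push_back(B[(int)(unif_rand() * 4) % 4]);
    }
    out[s] = y;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector mb_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}
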