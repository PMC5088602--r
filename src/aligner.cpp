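// Self-contained seed-and-extend read mapper and banded pairwise aligner.
//
// Scoring: match +1, mismatch -2, gap -3 (linear).  The mismatch "swap"
// penalty (match -> mismatch) is 3; mapq is 60 when the best alignment
// beats the runner-up by at least that margin, else 3 (co-optimal hits
// are all reported and flagged as ties).
//
// Coordinates are 0-based half-open; for reverse-strand hits the read is
// reverse-complemented before alignment, so rstart/rend and the cigar
// refer to the oriented (target-strand) read.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const int MATCH = 1;
static const int MISMATCH = -2;
static const int GAP = -3;
static const int NEG_INF = -1000000000;

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // N / anything else: never a match
    }
}

static std::vector<int8_t> encode(const char *s, size_t n) {
    std::vector<int8_t> v(n);
    for (size_t i = 0; i < n; ++i) v[i] = (int8_t) base_code(s[i]);
    return v;
}

static std::vector<int8_t> revcomp(const std::vector<int8_t> &v) {
    std::vector<int8_t> r(v.size());
    for (size_t i = 0; i < v.size(); ++i) {
        int8_t c = v[v.size() - 1 - i];
        r[i] = (c < 4) ? (int8_t)(3 - c) : (int8_t)4;
    }
    return r;
}

// ---------------------------------------------------------------------------
// banded alignment of a (rows, length la) vs b (cols, length lb) around
// diagonal d (b_pos ~ a_pos + d), band half-width B.
//
// mode 0 = local (Smith-Waterman),
// mode 1 = glocal (global in a, free end gaps in b),
// mode 2 = overlap (free end gaps in both sequences).
//
// Returns score and, via traceback, matches / columns / coords / cigar ops.

struct AlnResult {
    int score = NEG_INF;
    int matches = 0, cols = 0;
    int astart = 0, aend = 0, bstart = 0, bend = 0;
    std::string cigar;
    bool ok = false;
};

static void push_op(std::string &cig, char op, int &runlen, char &runop) {
    if (op == runop) { ++runlen; return; }
    if (runlen > 0) { cig += std::to_string(runlen); cig += runop; }
    runop = op; runlen = 1;
}

static AlnResult banded_align(const std::vector<int8_t> &a,
                              const std::vector<int8_t> &b,
                              int d, int B, int mode) {
    const int la = (int) a.size(), lb = (int) b.size();
    const int W = 2 * B + 1;
    AlnResult res;
    if (la == 0 || lb == 0) return res;

    // H[i][o] where o = j - (i + d - B), j is #consumed bases of b
    std::vector<int> Hprev(W + 2, NEG_INF), Hcur(W + 2, NEG_INF);
    std::vector<uint8_t> moves((size_t)(la + 1) * (W + 2), 0); // 1=diag 2=up(a) 3=left(b)

    auto jlo_of = [&](int i) { return i + d - B; };

    int best = NEG_INF, bi = -1, bj = -1;

    // row i = 0
    {
        int jlo = jlo_of(0);
        for (int o = 0; o < W; ++o) {
            int j = jlo + o;
            if (j < 0 || j > lb) continue;
            if (mode == 0 || mode == 2) Hprev[o + 1] = 0;      // free start
            else Hprev[o + 1] = 0;                              // glocal: free target prefix
            if (mode == 0 && Hprev[o + 1] > best) { best = 0; bi = 0; bj = j; }
        }
    }

    for (int i = 1; i <= la; ++i) {
        int jlo = jlo_of(i), jlo_prev = jlo_of(i - 1);
        std::fill(Hcur.begin(), Hcur.end(), NEG_INF);
        for (int o = 0; o < W; ++o) {
            int j = jlo + o;
            if (j < 0 || j > lb) continue;
            int h = NEG_INF; uint8_t mv = 0;
            // diagonal: (i-1, j-1) -> offset in prev row = (j-1) - jlo_prev
            if (j >= 1) {
                int op = (j - 1) - jlo_prev;
                if (op >= 0 && op < W && Hprev[op + 1] > NEG_INF) {
                    int s = (a[i - 1] == b[j - 1] && a[i - 1] < 4) ? MATCH : MISMATCH;
                    int v = Hprev[op + 1] + s;
                    if (v > h) { h = v; mv = 1; }
                }
            }
            // up: (i-1, j) consumes a base of a (gap in b)
            {
                int op = j - jlo_prev;
                if (op >= 0 && op < W && Hprev[op + 1] > NEG_INF) {
                    int v = Hprev[op + 1] + GAP;
                    if (v > h) { h = v; mv = 2; }
                }
            }
            // left: (i, j-1) consumes a base of b (gap in a)
            if (o >= 1 && Hcur[o] > NEG_INF) {
                int v = Hcur[o] + GAP;
                if (v > h) { h = v; mv = 3; }
            }
            // fresh starts
            if (mode == 0 && h < 0) { h = 0; mv = 0; }
            if (mode == 2 && j == 0 && h < 0) { h = 0; mv = 0; }         // free b prefix
            if (mode == 1 && j == 0) { /* leading gap in b: pay GAP via 'up' */ }
            Hcur[o + 1] = h;
            moves[(size_t)i * (W + 2) + o + 1] = mv;
            if (h > NEG_INF) {
                bool endpoint =
                    (mode == 0) ||
                    (mode == 1 && i == la) ||
                    (mode == 2 && (i == la || j == lb));
                if (endpoint && h > best) { best = h; bi = i; bj = j; }
            }
        }
        std::swap(Hprev, Hcur);
    }

    if (bi < 0 || best <= NEG_INF / 2) return res;

    // traceback
    int i = bi, j = bj;
    std::string cig_rev;
    int runlen = 0; char runop = 0;
    int matches = 0, cols = 0;
    while (i > 0) {
        int o = j - jlo_of(i);
        if (o < 0 || o >= W) break;
        uint8_t mv = moves[(size_t)i * (W + 2) + o + 1];
        if (mv == 0) break;
        if (mv == 1) {
            if (a[i - 1] == b[j - 1] && a[i - 1] < 4) ++matches;
            push_op(cig_rev, 'M', runlen, runop);
            ++cols; --i; --j;
        } else if (mv == 2) {
            push_op(cig_rev, 'I', runlen, runop);
            ++cols; --i;
        } else {
            push_op(cig_rev, 'D', runlen, runop);
            ++cols; --j;
        }
    }
    if (runlen > 0) { cig_rev += std::to_string(runlen); cig_rev += runop; }

    // cig_rev holds "<count><op>" groups emitted in reverse order; re-reverse groups
    std::string cig;
    {
        std::vector<std::pair<int,char> > groups;
        size_t p = 0;
        while (p < cig_rev.size()) {
            int n = 0;
            while (p < cig_rev.size() && isdigit(cig_rev[p])) { n = n * 10 + (cig_rev[p] - '0'); ++p; }
            groups.push_back(std::make_pair(n, cig_rev[p])); ++p;
        }
        // groups were appended walking backwards, so output reversed; merge equal neighbours
        for (int g = (int)groups.size() - 1; g >= 0; --g) {
            if (!cig.empty() && cig.back() == groups[g].second) {
                // cannot happen after run-length encoding; keep simple
            }
            cig += std::to_string(groups[g].first);
            cig += groups[g].second;
        }
    }

    res.score = best; res.matches = matches; res.cols = cols;
    res.astart = i; res.aend = bi; res.bstart = j; res.bend = bj;
    res.cigar = cig; res.ok = (cols > 0);
    return res;
}

// ---------------------------------------------------------------------------
// k-mer index over the target set

struct KmerIndex {
    int k;
    std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > map; // kmer -> (target, pos)
};

static void index_seq(KmerIndex &idx, const std::vector<int8_t> &s, int tid) {
    const int k = idx.k;
    const int n = (int) s.size();
    if (n < k) return;
    uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
        if (s[i] >= 4) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t) s[i]) & mask;
        if (++valid >= k) idx.map[key].push_back(std::make_pair(tid, i - k + 1));
    }
}

// collect seed candidates (target, representative diagonal, votes)
struct Cand { int target; int diag; int votes; };

static void collect_cands(const KmerIndex &idx, const std::vector<int8_t> &r,
                          int band, int step, std::vector<Cand> &out) {
    const int k = idx.k;
    const int n = (int) r.size();
    if (n < k) return;
    uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int valid = 0, last_used = -1000;
    std::vector<int64_t> hits;   // (target << 32) | (diag + offset)
    for (int i = 0; i < n; ++i) {
        if (r[i] >= 4) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t) r[i]) & mask;
        if (++valid < k) continue;
        if (i - last_used < step) continue;
        std::unordered_map<uint64_t, std::vector<std::pair<int,int> > >::const_iterator it =
            idx.map.find(key);
        if (it == idx.map.end()) continue;
        if (it->second.size() > 200) continue;  // low-complexity guard
        last_used = i;
        int rpos = i - k + 1;
        for (size_t h = 0; h < it->second.size(); ++h)
            hits.push_back(((int64_t) it->second[h].first << 32) |
                           (int64_t)(uint32_t)(it->second[h].second - rpos + 1000000));
    }
    if (hits.empty()) return;
    std::sort(hits.begin(), hits.end());
    // merge diagonals closer than band within a target
    size_t i0 = 0;
    for (size_t i = 1; i <= hits.size(); ++i) {
        bool brk = (i == hits.size());
        if (!brk) {
            int t_prev = (int)(hits[i - 1] >> 32), t_cur = (int)(hits[i] >> 32);
            int d_prev = (int)(uint32_t)(hits[i - 1] & 0xffffffffLL) - 1000000;
            int d_cur  = (int)(uint32_t)(hits[i] & 0xffffffffLL) - 1000000;
            brk = (t_cur != t_prev) || (d_cur - d_prev > band);
        }
        if (brk) {
            // representative diagonal: modal value within the run
            int tgt = (int)(hits[i0] >> 32);
            int bestd = 0, bestv = 0, curv = 0, curd = 0;
            for (size_t j = i0; j < i; ++j) {
                int dd = (int)(uint32_t)(hits[j] & 0xffffffffLL) - 1000000;
                if (j == i0 || dd != curd) { curd = dd; curv = 0; }
                ++curv;
                if (curv > bestv) { bestv = curv; bestd = curd; }
            }
            Cand c; c.target = tgt; c.diag = bestd; c.votes = (int)(i - i0);
            out.push_back(c);
            i0 = i;
        }
    }
}

// ---------------------------------------------------------------------------

struct Hit {
    int target, tstart, tend, rstart, rend, matches, cols, score;
    char strand;
    std::string cigar;
};

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector quals,
                        CharacterVector targets, int mode, int k, int band,
                        int max_ties, int seed_step) {
    const int nt = targets.size();
    std::vector<std::vector<int8_t> > T(nt);
    KmerIndex idx; idx.k = k;
    for (int t = 0; t < nt; ++t) {
        const char *s = CHAR(STRING_ELT(targets, t));
        T[t] = encode(s, strlen(s));
        index_seq(idx, T[t], t);
    }
    const bool have_quals = quals.size() == reads.size();

    std::vector<int> o_read, o_target, o_tstart, o_tend, o_rstart, o_rend,
        o_matches, o_cols, o_score, o_mapq, o_nbest;
    std::vector<double> o_mq;
    std::vector<std::string> o_strand, o_cigar;
    std::vector<int> o_tie;

    const int nr = reads.size();
    for (int r = 0; r < nr; ++r) {
        const char *rs = CHAR(STRING_ELT(reads, r));
        std::vector<int8_t> fwd = encode(rs, strlen(rs));
        if (fwd.empty()) continue;
        std::vector<int8_t> rev = revcomp(fwd);

        double mq = NA_REAL;
        if (have_quals) {
            const char *qs = CHAR(STRING_ELT(quals, r));
            size_t nq = strlen(qs);
            if (nq > 0) {
                long sum = 0;
                for (size_t i = 0; i < nq; ++i) sum += qs[i] - 33;
                mq = (double) sum / (double) nq;
            }
        }

        std::vector<Hit> hits;
        for (int st = 0; st < 2; ++st) {
            const std::vector<int8_t> &rd = (st == 0) ? fwd : rev;
            std::vector<Cand> cands;
            collect_cands(idx, rd, band, seed_step, cands);
            // prune candidates far below the best seed support; a candidate
            // with < 1/4 of the top vote count cannot be co-optimal
            int maxv = 0;
            for (size_t c = 0; c < cands.size(); ++c)
                maxv = std::max(maxv, cands[c].votes);
            for (size_t c = 0; c < cands.size(); ++c) {
                if (cands[c].votes * 4 < maxv) continue;
                const std::vector<int8_t> &tg = T[cands[c].target];
                AlnResult a = banded_align(rd, tg, cands[c].diag, band, mode);
                if (!a.ok || a.score <= 0) continue;
                if (mode == 1 && (a.astart != 0 || a.aend != (int) rd.size()))
                    continue;  // global mode: full read must align
                Hit h;
                h.target = cands[c].target; h.strand = (st == 0) ? '+' : '-';
                h.tstart = a.bstart; h.tend = a.bend;
                h.rstart = a.astart; h.rend = a.aend;
                h.matches = a.matches; h.cols = a.cols;
                h.score = a.score; h.cigar = a.cigar;
                hits.push_back(h);
            }
        }
        if (hits.empty()) continue;

        // dedupe near-identical placements (same target/strand, close start)
        std::sort(hits.begin(), hits.end(), [](const Hit &x, const Hit &y) {
            if (x.target != y.target) return x.target < y.target;
            if (x.strand != y.strand) return x.strand < y.strand;
            if (x.tstart != y.tstart) return x.tstart < y.tstart;
            return x.score > y.score;
        });
        std::vector<Hit> uniq;
        for (size_t i = 0; i < hits.size(); ++i) {
            if (!uniq.empty() && uniq.back().target == hits[i].target &&
                uniq.back().strand == hits[i].strand &&
                std::abs(uniq.back().tstart - hits[i].tstart) <= band) {
                if (hits[i].score > uniq.back().score) uniq.back() = hits[i];
                continue;
            }
            uniq.push_back(hits[i]);
        }
        std::sort(uniq.begin(), uniq.end(), [](const Hit &x, const Hit &y) {
            if (x.score != y.score) return x.score > y.score;
            if (x.target != y.target) return x.target < y.target;
            return x.tstart < y.tstart;
        });

        int best = uniq[0].score;
        int nbest = 0;
        while (nbest < (int) uniq.size() && uniq[nbest].score == best) ++nbest;
        int runner = (nbest < (int) uniq.size()) ? uniq[nbest].score : NEG_INF;
        bool tie = nbest > 1;
        int mapq;
        if (tie) mapq = 3;
        else if (runner == NEG_INF || best - runner >= MATCH - MISMATCH) mapq = 60;
        else mapq = 3;

        int emit = std::min(nbest, max_ties);
        for (int i = 0; i < emit; ++i) {
            const Hit &h = uniq[i];
            o_read.push_back(r + 1); o_target.push_back(h.target + 1);
            o_strand.push_back(std::string(1, h.strand));
            o_tstart.push_back(h.tstart); o_tend.push_back(h.tend);
            o_rstart.push_back(h.rstart); o_rend.push_back(h.rend);
            o_matches.push_back(h.matches); o_cols.push_back(h.cols);
            o_score.push_back(h.score); o_mapq.push_back(mapq);
            o_tie.push_back(tie ? 1 : 0); o_nbest.push_back(nbest);
            o_mq.push_back(mq); o_cigar.push_back(h.cigar);
        }
    }

    return DataFrame::create(
        Named("read") = o_read, Named("target") = o_target,
        Named("strand") = o_strand,
        Named("tstart") = o_tstart, Named("tend") = o_tend,
        Named("rstart") = o_rstart, Named("rend") = o_rend,
        Named("matches") = o_matches, Named("cols") = o_cols,
        Named("score") = o_score, Named("mapq") = o_mapq,
        Named("tie") = o_tie, Named("nbest") = o_nbest,
        Named("mean_qual") = o_mq, Named("cigar") = o_cigar,
        Named("stringsAsFactors") = false);
}

// ---------------------------------------------------------------------------
// pairwise percent identity with mutual-coverage mask (overlap alignment)

// sequence plus its sorted k-mer list ((key << 20) | pos); pos < 2^20
struct SeqK {
    std::vector<int8_t> codes;
    std::vector<uint64_t> kmers;
};

static SeqK make_seqk(const char *s, int k) {
    SeqK q;
    q.codes = encode(s, strlen(s));
    const int n = (int) q.codes.size();
    uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
        if (q.codes[i] >= 4) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t) q.codes[i]) & mask;
        if (++valid >= k) q.kmers.push_back((key << 20) | (uint64_t)(i - k + 1));
    }
    std::sort(q.kmers.begin(), q.kmers.end());
    return q;
}

static double pid_pair(const SeqK &a, const SeqK &b, int band, double min_cov,
                       double *cov_a_out, double *cov_b_out) {
    if (a.codes.empty() || b.codes.empty()) return NA_REAL;
    // best shared-kmer diagonal by merge-join of the sorted k-mer lists
    std::vector<int> diags;
    size_t i = 0, j = 0;
    while (i < a.kmers.size() && j < b.kmers.size()) {
        uint64_t ka = a.kmers[i] >> 20, kb = b.kmers[j] >> 20;
        if (ka < kb) { ++i; continue; }
        if (kb < ka) { ++j; continue; }
        size_t i2 = i, j2 = j;
        while (i2 < a.kmers.size() && (a.kmers[i2] >> 20) == ka) ++i2;
        while (j2 < b.kmers.size() && (b.kmers[j2] >> 20) == ka) ++j2;
        for (size_t x = i; x < i2; ++x)
            for (size_t y = j; y < j2; ++y)
                diags.push_back((int)(a.kmers[x] & 0xfffff) -
                                (int)(b.kmers[y] & 0xfffff));
        i = i2; j = j2;
    }
    if (diags.empty()) return NA_REAL;
    std::sort(diags.begin(), diags.end());
    int bestd = diags[0], bestv = 0, curv = 0, curd = diags[0];
    for (size_t x = 0; x < diags.size(); ++x) {
        if (diags[x] != curd) { curd = diags[x]; curv = 0; }
        if (++curv > bestv) { bestv = curv; bestd = curd; }
    }
    // align a (rows) vs b (cols) around diagonal: b_pos ~ a_pos - bestd
    AlnResult r = banded_align(a.codes, b.codes, -bestd, band, 2);
    if (!r.ok) return NA_REAL;
    double cov_a = (double)(r.aend - r.astart) / (double) a.codes.size();
    double cov_b = (double)(r.bend - r.bstart) / (double) b.codes.size();
    if (cov_a_out) *cov_a_out = cov_a;
    if (cov_b_out) *cov_b_out = cov_b;
    if (cov_a < min_cov || cov_b < min_cov) return NA_REAL;
    return 100.0 * (double) r.matches / (double) r.cols;
}

// [[Rcpp::export]]
NumericMatrix cpp_pid_matrix(CharacterVector seqs, int k, int band, double min_cov) {
    const int n = seqs.size();
    std::vector<SeqK> S(n);
    for (int i = 0; i < n; ++i)
        S[i] = make_seqk(CHAR(STRING_ELT(seqs, i)), k);
    NumericMatrix M(n, n);
    for (int i = 0; i < n; ++i) {
        M(i, i) = 100.0;
        for (int j = i + 1; j < n; ++j) {
            double p = pid_pair(S[i], S[j], band, min_cov, NULL, NULL);
            M(i, j) = p; M(j, i) = p;
        }
    }
    return M;
}

// [[Rcpp::export]]
NumericMatrix cpp_pid_query(CharacterVector queries, CharacterVector targets,
                            int k, int band, double min_cov) {
    const int nq = queries.size(), nt = targets.size();
    std::vector<SeqK> Q(nq), T(nt);
    for (int i = 0; i < nq; ++i)
        Q[i] = make_seqk(CHAR(STRING_ELT(queries, i)), k);
    for (int i = 0; i < nt; ++i)
        T[i] = make_seqk(CHAR(STRING_ELT(targets, i)), k);
    NumericMatrix M(nq, nt);
    for (int i = 0; i < nq; ++i)
        for (int j = 0; j < nt; ++j)
            M(i, j) = pid_pair(Q[i], T[j], band, min_cov, NULL, NULL);
    return M;
}

// ---------------------------------------------------------------------------
// pileup: accumulate quality-filtered base counts per reference position

// [[Rcpp::export]]
List cpp_pileup(IntegerVector target, CharacterVector strand,
                IntegerVector tstart, IntegerVector rstart,
                CharacterVector cigar, CharacterVector reads,
                CharacterVector quals, IntegerVector target_lens,
                int min_qual) {
    const int nt = target_lens.size();
    std::vector<IntegerMatrix> counts;
    for (int t = 0; t < nt; ++t) {
        IntegerMatrix m(4, target_lens[t]);
        counts.push_back(m);
    }
    const int n = target.size();
    for (int a = 0; a < n; ++a) {
        int t = target[a] - 1;
        if (t < 0 || t >= nt) continue;
        const char *rs = CHAR(STRING_ELT(reads, a));
        const char *qs = CHAR(STRING_ELT(quals, a));
        size_t rl = strlen(rs);
        std::vector<int8_t> rd = encode(rs, rl);
        std::vector<int> qv(rl);
        for (size_t i = 0; i < rl; ++i) qv[i] = qs[i] - 33;
        bool minus = (CHAR(STRING_ELT(strand, a))[0] == '-');
        if (minus) {
            rd = revcomp(rd);
            std::reverse(qv.begin(), qv.end());
        }
        int tp = tstart[a], rp = rstart[a];
        const char *cg = CHAR(STRING_ELT(cigar, a));
        size_t p = 0, cl = strlen(cg);
        IntegerMatrix &M = counts[t];
        int L = target_lens[t];
        while (p < cl) {
            int num = 0;
            while (p < cl && isdigit(cg[p])) { num = num * 10 + (cg[p] - '0'); ++p; }
            char op = cg[p]; ++p;
            if (op == 'M') {
                for (int i = 0; i < num; ++i) {
                    if (tp >= 0 && tp < L && rp < (int) rd.size()) {
                        int8_t c = rd[rp];
                        if (c < 4 && qv[rp] >= min_qual) M(c, tp) += 1;
                    }
                    ++tp; ++rp;
                }
            } else if (op == 'I') {
                rp += num;
            } else if (op == 'D') {
                tp += num;
            }
        }
    }
    List out(nt);
    for (int t = 0; t < nt; ++t) {
        rownames(counts[t]) = CharacterVector::create("A", "C", "G", "T");
        out[t] = counts[t];
    }
    return out;
}

// ---------------------------------------------------------------------------
// helpers for the read simulator: integer code matrices -> strings

// [[Rcpp::export]]
CharacterVector cpp_codes_to_strings(IntegerMatrix codes) {
    static const char alpha[] = "ACGTN";
    const int n = codes.nrow(), m = codes.ncol();
    CharacterVector out(n);
    std::string buf(m, 'N');
    for (int i = 0; i < n; ++i) {
        for (int j = 0; j < m; ++j) {
            int c = codes(i, j);
            buf[j] = (c >= 0 && c <= 4) ? alpha[c] : 'N';
        }
        out[i] = buf;
    }
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_quals_to_strings(IntegerMatrix q) {
    const int n = q.nrow(), m = q.ncol();
    CharacterVector out(n);
    std::string buf(m, '!');
    for (int i = 0; i < n; ++i) {
        for (int j = 0; j < m; ++j) buf[j] = (char)(33 + q(i, j));
        out[i] = buf;
    }
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_code_vector_to_string(IntegerVector codes) {
    static const char alpha[] = "ACGTN";
    std::string buf(codes.size(), 'N');
    for (int i = 0; i < (int) codes.size(); ++i) {
        int c = codes[i];
        buf[i] = (c >= 0 && c <= 4) ? alpha[c] : 'N';
    }
    return CharacterVector::create(buf);
}
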