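// Core sequence kernels: canonical k-mer counting, bidirected de Bruijn unitig
// extraction, local affine-gap alignment (full and banded), seed-and-extend
// HSP search, exact-seed read depth mapping, and exact-substring screening.
// K-mers are 2-bit packed into unsigned __int128 (supports odd k up to 63).

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

typedef unsigned __int128 u128;

static const int NEG = -1000000000;

static inline int base2bit(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    }
    return -1;
}

static const char BIT2BASE[4] = {'A', 'C', 'G', 'T'};

struct U128Hash {
    size_t operator()(u128 x) const {
        uint64_t h = (uint64_t)x ^ (uint64_t)(x >> 64);
        h ^= h >> 33; h *= 0xff51afd7ed558ccdULL;
        h ^= h >> 33; h *= 0xc4ceb9fe1a85ec53ULL;
        h ^= h >> 33;
        return (size_t)h;
    }
};

static inline std::string decode_kmer(u128 x, int k) {
    std::string s(k, 'A');
    for (int i = 0; i < k; ++i)
        s[i] = BIT2BASE[(int)((x >> (2 * (k - 1 - i))) & 3)];
    return s;
}

static inline std::string revcomp_str(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) {
        switch (r[i]) {
        case 'A': r[i] = 'T'; break;
        case 'C': r[i] = 'G'; break;
        case 'G': r[i] = 'C'; break;
        case 'T': r[i] = 'A'; break;
        default: break;
        }
    }
    return r;
}

// Enumerate canonical k-mers of one sequence, calling f(canonical) for each
// window free of non-ACGT characters.
template <typename F>
static void for_each_canonical(const char* s, int n, int k, F f) {
    if (n < k) return;
    u128 mask = (((u128)1) << (2 * k)) - 1;
    u128 fwd = 0, rc = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
        int b = base2bit(s[i]);
        if (b < 0) { valid = 0; fwd = 0; rc = 0; continue; }
        fwd = ((fwd << 2) | (u128)b) & mask;
        rc = (rc >> 2) | ((u128)(3 - b) << (2 * (k - 1)));
        if (++valid >= k) f(fwd < rc ? fwd : rc);
    }
}

// ---------------------------------------------------------------------------
// k-mer counting
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
    std::unordered_map<u128, int, U128Hash> cnt;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        const char* s = CHAR(STRING_ELT(seqs, i));
        int n = (int)LENGTH(STRING_ELT(seqs, i));
        for_each_canonical(s, n, k, [&](u128 key) { ++cnt[key]; });
    }
    std::vector<std::pair<u128, int> > v(cnt.begin(), cnt.end());
    std::sort(v.begin(), v.end(),
              [](const std::pair<u128, int>& a, const std::pair<u128, int>& b) {
                  return a.first < b.first;
              });
    CharacterVector kmers(v.size());
    IntegerVector counts(v.size());
    for (size_t i = 0; i < v.size(); ++i) {
        kmers[i] = decode_kmer(v[i].first, k);
        counts[i] = v[i].second;
    }
    return List::create(_["kmer"] = kmers, _["count"] = counts);
}

// ---------------------------------------------------------------------------
// unitig extraction from a canonical k-mer set (bidirected de Bruijn graph)
// ---------------------------------------------------------------------------

struct Oriented { u128 f, r; };

// [[Rcpp::export]]
List cpp_extract_unitigs(CharacterVector kmers, IntegerVector counts,
                         int k, int min_count) {
    u128 mask = (((u128)1) << (2 * k)) - 1;
    std::unordered_map<u128, int, U128Hash> cnt;
    cnt.reserve(kmers.size() * 2);
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        if (counts[i] < min_count) continue;
        const char* s = CHAR(STRING_ELT(kmers, i));
        u128 f = 0;
        bool ok = true;
        for (int j = 0; j < k; ++j) {
            int b = base2bit(s[j]);
            if (b < 0) { ok = false; break; }
            f = (f << 2) | (u128)b;
        }
        if (!ok) continue;
        u128 r = 0;
        for (int j = 0; j < k; ++j) {
            int b = (int)((f >> (2 * j)) & 3);
            r = (r << 2) | (u128)(3 - b);
        }
        cnt[f < r ? f : r] = counts[i];
    }

    std::vector<u128> keys;
    keys.reserve(cnt.size());
    for (auto& kv : cnt) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());

    std::unordered_set<u128, U128Hash> visited;
    visited.reserve(cnt.size() * 2);

    auto in_graph = [&](u128 f, u128 r) {
        return cnt.find(f < r ? f : r) != cnt.end();
    };
    auto fwd_next = [&](const Oriented& o, int b) {
        Oriented n;
        n.f = ((o.f << 2) | (u128)b) & mask;
        n.r = (o.r >> 2) | ((u128)(3 - b) << (2 * (k - 1)));
        return n;
    };
    auto bwd_prev = [&](const Oriented& o, int b) {
        Oriented p;
        p.f = (o.f >> 2) | ((u128)b << (2 * (k - 1)));
        p.r = ((o.r << 2) | (u128)(3 - b)) & mask;
        return p;
    };
    auto outdeg = [&](const Oriented& o, int& only) {
        int d = 0;
        only = -1;
        for (int b = 0; b < 4; ++b) {
            Oriented n = fwd_next(o, b);
            if (in_graph(n.f, n.r)) { ++d; only = b; }
        }
        return d;
    };
    auto indeg = [&](const Oriented& o, int& only) {
        int d = 0;
        only = -1;
        for (int b = 0; b < 4; ++b) {
            Oriented p = bwd_prev(o, b);
            if (in_graph(p.f, p.r)) { ++d; only = b; }
        }
        return d;
    };
    auto canon = [](const Oriented& o) { return o.f < o.r ? o.f : o.r; };

    std::vector<std::string> seqs;
    std::vector<double> covs;

    auto emit_path = [&](const std::vector<Oriented>& path, bool cycle) {
        std::vector<Oriented> p = path;
        if (cycle) {
            // cut at lexicographically smallest canonical k-mer, in its
            // canonical orientation
            size_t L = p.size(), best = 0;
            for (size_t i = 1; i < L; ++i)
                if (canon(p[i]) < canon(p[best])) best = i;
            std::vector<Oriented> q(L);
            if (p[best].f <= p[best].r) {
                for (size_t j = 0; j < L; ++j) q[j] = p[(best + j) % L];
            } else {
                for (size_t j = 0; j < L; ++j) {
                    Oriented o = p[(best + L - j) % L];
                    std::swap(o.f, o.r);
                    q[j] = o;
                }
            }
            p = q;
        }
        std::string s = decode_kmer(p[0].f, k);
        s.reserve(k + p.size() - 1);
        for (size_t i = 1; i < p.size(); ++i)
            s.push_back(BIT2BASE[(int)(p[i].f & 3)]);
        double tot = 0;
        for (size_t i = 0; i < p.size(); ++i) tot += cnt[canon(p[i])];
        if (!cycle) {
            std::string rc = revcomp_str(s);
            if (rc < s) s = rc;
        }
        seqs.push_back(s);
        covs.push_back(tot / (double)p.size());
    };

    for (size_t ki = 0; ki < keys.size(); ++ki) {
        u128 c = keys[ki];
        if (visited.count(c)) continue;
        Oriented start;
        start.f = c;
        {
            u128 r = 0;
            for (int j = 0; j < k; ++j) {
                int b = (int)((c >> (2 * j)) & 3);
                r = (r << 2) | (u128)(3 - b);
            }
            start.r = r;
        }
        // walk backward to the unitig start (or detect a pure cycle)
        Oriented cur = start;
        bool cycle = false;
        size_t guard = 0;
        while (guard++ <= cnt.size()) {
            int ob;
            if (indeg(cur, ob) != 1) break;
            Oriented p = bwd_prev(cur, ob);
            int dummy;
            if (outdeg(p, dummy) != 1) break;
            if (canon(p) == c) { cycle = true; break; }
            cur = p;
        }
        std::vector<Oriented> path;
        if (cycle) {
            // collect the full cycle starting from the seed k-mer
            Oriented o = start;
            do {
                path.push_back(o);
                visited.insert(canon(o));
                int ob, dummy;
                outdeg(o, ob);
                o = fwd_next(o, ob);
                (void)dummy;
            } while (canon(o) != c);
            emit_path(path, true);
        } else {
            path.push_back(cur);
            visited.insert(canon(cur));
            while (true) {
                int ob;
                if (outdeg(path.back(), ob) != 1) break;
                Oriented n = fwd_next(path.back(), ob);
                int ib;
                if (indeg(n, ib) != 1) break;
                if (visited.count(canon(n))) break;
                path.push_back(n);
                visited.insert(canon(n));
            }
            emit_path(path, false);
        }
    }

    return List::create(_["sequence"] = wrap(seqs), _["coverage"] = wrap(covs));
}

// ---------------------------------------------------------------------------
// local alignment: affine-gap Smith-Waterman, full or banded, with traceback
// ---------------------------------------------------------------------------

struct AlnResult {
    int score, qs, qe, ss, se, matches, columns;
};

// Gap of length g costs gap_open + g * gap_extend (both <= 0).
// Banded mode restricts j - i to [dlo, dhi]. Traceback tie-break:
// diagonal > up (gap in subject) > left (gap in query) > stop.
static AlnResult band_sw(const char* a, int n, const char* b, int m,
                         int match, int mismatch, int gap_open, int gap_extend,
                         int dlo, int dhi, bool full) {
    AlnResult res;
    res.score = 0; res.qs = res.qe = res.ss = res.se = 0;
    res.matches = res.columns = 0;
    if (n <= 0 || m <= 0) return res;

    int W = full ? m : (dhi - dlo + 1);
    std::vector<uint8_t> dir((size_t)n * (size_t)W, 0);
    std::vector<int> Hprev(m + 1, 0), Fprev(m + 1, NEG);
    std::vector<int> Hrow(m + 1, 0), Frow(m + 1, NEG);

    int best = 0, bi = -1, bj = -1;

    for (int i = 0; i < n; ++i) {
        int jlo = full ? 0 : std::max(0, i + dlo);
        int jhi = full ? (m - 1) : std::min(m - 1, i + dhi);
        if (!full) {
            // reset stale cells flanking the band in this row
            if (jlo > 0) { Hrow[jlo - 1] = NEG; Frow[jlo - 1] = NEG; }
            if (jhi + 1 <= m) { Hrow[jhi + 1 > m ? m : jhi + 1] = NEG; }
        }
        int E = NEG;
        for (int j = jlo; j <= jhi; ++j) {
            // E: gap in query (left move), within row
            int hl = (j > jlo) ? Hrow[j - 1] : (full && j > 0 ? Hrow[j - 1] : NEG);
            if (full && j > 0) hl = Hrow[j - 1];
            int eo = (hl <= NEG / 2) ? NEG : hl + gap_open + gap_extend;
            int ee = (E <= NEG / 2) ? NEG : E + gap_extend;
            bool e_ext = ee > eo;
            E = e_ext ? ee : eo;
            // F: gap in subject (up move), from previous row same column
            int hu = (i > 0) ? Hprev[j] : NEG;
            int fu = (i > 0) ? Fprev[j] : NEG;
            // previous row band check
            if (!full && i > 0) {
                int pjlo = std::max(0, i - 1 + dlo);
                int pjhi = std::min(m - 1, i - 1 + dhi);
                if (j < pjlo || j > pjhi) { hu = NEG; fu = NEG; }
            }
            int fo = (hu <= NEG / 2) ? NEG : hu + gap_open + gap_extend;
            int fe = (fu <= NEG / 2) ? NEG : fu + gap_extend;
            bool f_ext = fe > fo;
            int F = f_ext ? fe : fo;
            Frow[j] = F;
            // H
            int hd;
            if (i > 0 && j > 0) {
                hd = Hprev[j - 1];
                if (!full) {
                    int pjlo = std::max(0, i - 1 + dlo);
                    int pjhi = std::min(m - 1, i - 1 + dhi);
                    if (j - 1 < pjlo || j - 1 > pjhi) hd = NEG;
                }
            } else {
                hd = (i == 0 || j == 0) ? 0 : NEG;
            }
            int sc = (a[i] == b[j]) ? match : mismatch;
            int dg = (hd <= NEG / 2) ? NEG : hd + sc;

            int v = 0, src = 0;
            if (dg > 0) { v = dg; src = 1; }
            if (F > v) { v = F; src = 2; }
            if (E > v) { v = E; src = 3; }
            Hrow[j] = v;
            uint8_t d = (uint8_t)src;
            if (f_ext) d |= 4;
            if (e_ext) d |= 8;
            size_t idx = (size_t)i * (size_t)W + (size_t)(full ? j : (j - (i + dlo)));
            dir[idx] = d;
            if (v > best) { best = v; bi = i; bj = j; }
        }
        std::swap(Hprev, Hrow);
        std::swap(Fprev, Frow);
        if (!full) {
            // clear next row's potentially stale neighborhood in Hrow/Frow
            int njlo = std::max(0, i + 1 + dlo);
            int njhi = std::min(m - 1, i + 1 + dhi);
            for (int j = std::max(0, njlo - 1); j <= std::min(m - 1, njhi + 1); ++j) {
                Hrow[j] = 0; Frow[j] = NEG;
            }
        } else {
            std::fill(Hrow.begin(), Hrow.end(), 0);
            std::fill(Frow.begin(), Frow.end(), NEG);
        }
    }

    if (best <= 0) return res;

    // traceback
    int i = bi, j = bj, state = 0; // 0 = H, 1 = F(up), 2 = E(left)
    int matches = 0, columns = 0;
    int qe = bi + 1, se = bj + 1;
    while (i >= 0 && j >= 0) {
        size_t idx = (size_t)i * (size_t)W + (size_t)(full ? j : (j - (i + dlo)));
        uint8_t d = dir[idx];
        if (state == 0) {
            int src = d & 3;
            if (src == 0) break;
            if (src == 1) {
                ++columns;
                if (a[i] == b[j]) ++matches;
                --i; --j;
            } else if (src == 2) {
                state = 1;
            } else {
                state = 2;
            }
        } else if (state == 1) {
            ++columns;
            bool ext = (d & 4) != 0;
            --i;
            if (!ext) state = 0;
        } else {
            ++columns;
            bool ext = (d & 8) != 0;
            --j;
            if (!ext) state = 0;
        }
    }
    res.score = best;
    res.qs = i + 1; res.qe = qe;
    res.ss = j + 1; res.se = se;
    res.matches = matches;
    res.columns = columns;
    return res;
}

// [[Rcpp::export]]
List cpp_sw(std::string a, std::string b, int match, int mismatch,
            int gap_open, int gap_extend) {
    double cells = (double)a.size() * (double)b.size();
    if (cells > 4e8)
        stop("sequences too long for full dynamic programming (%d x %d cells)",
             (int)a.size(), (int)b.size());
    AlnResult r = band_sw(a.c_str(), (int)a.size(), b.c_str(), (int)b.size(),
                          match, mismatch, gap_open, gap_extend, 0, 0, true);
    return List::create(
        _["score"] = r.score,
        _["q_start"] = r.qs, _["q_end"] = r.qe,
        _["s_start"] = r.ss, _["s_end"] = r.se,
        _["matches"] = r.matches, _["columns"] = r.columns);
}

// ---------------------------------------------------------------------------
// seed-and-extend HSP search (single orientation; caller handles strands)
// ---------------------------------------------------------------------------

typedef std::unordered_map<u128, std::vector<int>, U128Hash> SeedIndex;

static SeedIndex build_seed_index(const char* q, int nq, int seed_len) {
    SeedIndex idx;
    u128 mask = (((u128)1) << (2 * seed_len)) - 1;
    u128 f = 0;
    int valid = 0;
    for (int i = 0; i < nq; ++i) {
        int b = base2bit(q[i]);
        if (b < 0) { valid = 0; f = 0; continue; }
        f = ((f << 2) | (u128)b) & mask;
        if (++valid >= seed_len) idx[f].push_back(i - seed_len + 1);
    }
    return idx;
}

struct HspRows {
    std::vector<int> subject_idx, q_start, q_end, s_start, s_end,
        score, matches, columns;
};

// seed, extend and refine one query (pre-indexed) against one subject,
// appending HSP rows tagged subj_id
static void seed_extend_into(const char* q, int nq, const SeedIndex& idx,
                             const char* s, int ns, int seed_len,
                             int match, int mismatch, int gap_open,
                             int gap_extend, int x_drop, int subj_id,
                             HspRows& out) {
    if (seed_len > nq || seed_len > ns) return;
    std::vector<int>& q_start = out.q_start;
    std::vector<int>& q_end = out.q_end;
    std::vector<int>& s_start = out.s_start;
    std::vector<int>& s_end = out.s_end;
    std::vector<int>& score = out.score;
    std::vector<int>& matches = out.matches;
    std::vector<int>& columns = out.columns;
    size_t first_row = out.score.size();

    {
        // collect seed hits (diag, spos, qpos)
        struct Seed { int diag, sp, qp; };
        std::vector<Seed> seeds;
        {
            u128 mask = (((u128)1) << (2 * seed_len)) - 1;
            u128 f = 0;
            int valid = 0;
            for (int i = 0; i < ns; ++i) {
                int b = base2bit(s[i]);
                if (b < 0) { valid = 0; f = 0; continue; }
                f = ((f << 2) | (u128)b) & mask;
                if (++valid >= seed_len) {
                    auto it = idx.find(f);
                    if (it != idx.end()) {
                        int sp = i - seed_len + 1;
                        for (int qp : it->second)
                            seeds.push_back({sp - qp, sp, qp});
                    }
                }
            }
        }
        std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
            if (a.diag != b.diag) return a.diag < b.diag;
            if (a.sp != b.sp) return a.sp < b.sp;
            return a.qp < b.qp;
        });

        const int margin = 40;
        struct Box { int qs, qe, ss, se; };
        std::vector<Box> boxes;

        for (const Seed& sd : seeds) {
            bool covered = false;
            for (const Box& bx : boxes) {
                if (sd.qp >= bx.qs && sd.qp + seed_len <= bx.qe &&
                    sd.sp >= bx.ss && sd.sp + seed_len <= bx.se) {
                    covered = true;
                    break;
                }
            }
            if (covered) continue;
            // ungapped x-drop extension
            int sc = seed_len * match, mx = sc;
            int qe0 = sd.qp + seed_len, se0 = sd.sp + seed_len;
            {
                int qi = qe0, si = se0, run_sc = sc, run_best = sc;
                int best_q = qe0, best_s = se0;
                while (qi < nq && si < ns) {
                    run_sc += (q[qi] == s[si]) ? match : mismatch;
                    ++qi; ++si;
                    if (run_sc > run_best) { run_best = run_sc; best_q = qi; best_s = si; }
                    if (run_best - run_sc > x_drop) break;
                }
                qe0 = best_q; se0 = best_s; sc = run_best; mx = run_best;
            }
            int qs0 = sd.qp, ss0 = sd.sp;
            {
                int qi = qs0 - 1, si = ss0 - 1, run_sc = mx, run_best = mx;
                int best_q = qs0, best_s = ss0;
                while (qi >= 0 && si >= 0) {
                    run_sc += (q[qi] == s[si]) ? match : mismatch;
                    if (run_sc > run_best) { run_best = run_sc; best_q = qi; best_s = si; }
                    if (run_best - run_sc > x_drop) break;
                    --qi; --si;
                }
                qs0 = best_q; ss0 = best_s;
            }
            // banded gapped refinement around the ungapped segment
            int wq0 = std::max(0, qs0 - margin), wq1 = std::min(nq, qe0 + margin);
            int ws0 = std::max(0, ss0 - margin), ws1 = std::min(ns, se0 + margin);
            int d0 = (ss0 - ws0) - (qs0 - wq0);
            AlnResult r = band_sw(q + wq0, wq1 - wq0, s + ws0, ws1 - ws0,
                                  match, mismatch, gap_open, gap_extend,
                                  d0 - margin, d0 + margin, false);
            if (r.score <= 0) continue;
            Box bx;
            bx.qs = wq0 + r.qs; bx.qe = wq0 + r.qe;
            bx.ss = ws0 + r.ss; bx.se = ws0 + r.se;
            // drop if contained in an existing HSP with >= score
            bool dup = false;
            for (size_t i = 0; i < boxes.size(); ++i) {
                if (bx.qs >= boxes[i].qs && bx.qe <= boxes[i].qe &&
                    bx.ss >= boxes[i].ss && bx.se <= boxes[i].se &&
                    r.score <= score[first_row + i]) {
                    dup = true;
                    break;
                }
            }
            if (dup) continue;
            boxes.push_back(bx);
            out.subject_idx.push_back(subj_id);
            q_start.push_back(bx.qs); q_end.push_back(bx.qe);
            s_start.push_back(bx.ss); s_end.push_back(bx.se);
            score.push_back(r.score);
            matches.push_back(r.matches);
            columns.push_back(r.columns);
        }
    }
}

static List hsp_rows_to_list(const HspRows& out, bool with_subject) {
    List res = List::create(
        _["q_start"] = wrap(out.q_start), _["q_end"] = wrap(out.q_end),
        _["s_start"] = wrap(out.s_start), _["s_end"] = wrap(out.s_end),
        _["score"] = wrap(out.score), _["matches"] = wrap(out.matches),
        _["columns"] = wrap(out.columns));
    if (with_subject) res["subject_idx"] = wrap(out.subject_idx);
    return res;
}

// [[Rcpp::export]]
List cpp_seed_extend(std::string query, std::string subject, int seed_len,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int x_drop) {
    HspRows out;
    if (seed_len <= (int)query.size()) {
        SeedIndex idx = build_seed_index(query.c_str(), (int)query.size(),
                                         seed_len);
        seed_extend_into(query.c_str(), (int)query.size(), idx,
                         subject.c_str(), (int)subject.size(), seed_len,
                         match, mismatch, gap_open, gap_extend, x_drop, 1,
                         out);
    }
    return hsp_rows_to_list(out, false);
}

// Batched variant: the query is indexed once and aligned against every
// subject; rows carry the 1-based subject index.
// [[Rcpp::export]]
List cpp_seed_extend_many(std::string query, CharacterVector subjects,
                          int seed_len, int match, int mismatch,
                          int gap_open, int gap_extend, int x_drop) {
    HspRows out;
    if (seed_len <= (int)query.size()) {
        SeedIndex idx = build_seed_index(query.c_str(), (int)query.size(),
                                         seed_len);
        for (R_xlen_t i = 0; i < subjects.size(); ++i) {
            const char* s = CHAR(STRING_ELT(subjects, i));
            int ns = (int)LENGTH(STRING_ELT(subjects, i));
            seed_extend_into(query.c_str(), (int)query.size(), idx, s, ns,
                             seed_len, match, mismatch, gap_open, gap_extend,
                             x_drop, (int)(i + 1), out);
        }
    }
    return hsp_rows_to_list(out, true);
}

// ---------------------------------------------------------------------------
// exact-seed read depth mapping
// ---------------------------------------------------------------------------

// Sorted (kmer, position) index over a subject; binary-search lookups.
struct KmerIndex {
    std::vector<std::pair<u128, int> > v;
    void build(const char* s, int n, int k) {
        u128 mask = (((u128)1) << (2 * k)) - 1;
        u128 f = 0;
        int valid = 0;
        for (int i = 0; i < n; ++i) {
            int b = base2bit(s[i]);
            if (b < 0) { valid = 0; f = 0; continue; }
            f = ((f << 2) | (u128)b) & mask;
            if (++valid >= k) v.push_back({f, i - k + 1});
        }
        std::sort(v.begin(), v.end());
    }
    template <typename F>
    void lookup(u128 key, F f) const {
        auto it = std::lower_bound(v.begin(), v.end(),
                                   std::make_pair(key, (int)-2147483648LL));
        for (; it != v.end() && it->first == key; ++it) f(it->second);
    }
};

// [[Rcpp::export]]
IntegerVector cpp_depth_map(CharacterVector mates, std::string ref, int k,
                            int max_mm, bool circular) {
    int G = (int)ref.size();
    std::string subj = circular ? ref + ref : ref;
    const char* rs = subj.c_str();
    int Gs = (int)subj.size();
    KmerIndex idx;
    idx.build(rs, Gs, k);

    IntegerVector depth(G, 0);
    std::vector<int> loci;

    for (R_xlen_t mi = 0; mi < mates.size(); ++mi) {
        std::string m = as<std::string>(mates[mi]);
        int L = (int)m.size();
        if (L < k || L > Gs) continue;
        // candidate anchor windows: non-overlapping k-mers plus the final one
        std::vector<int> offs;
        for (int off = 0; off + k <= L; off += k) offs.push_back(off);
        if (offs.empty() || offs.back() != L - k) offs.push_back(L - k);
        for (int orient = 0; orient < 2; ++orient) {
            const std::string& mm = (orient == 0) ? m : revcomp_str(m);
            const char* mc = mm.c_str();
            // the first anchor window with any index hit anchors the mate
            loci.clear();
            for (int off : offs) {
                u128 f = 0;
                bool valid = true;
                for (int i = off; i < off + k; ++i) {
                    int b = base2bit(mc[i]);
                    if (b < 0) { valid = false; break; }
                    f = (f << 2) | (u128)b;
                }
                if (!valid) continue;
                bool any = false;
                idx.lookup(f, [&](int pos) {
                    any = true;
                    int start = pos - off;
                    if (start < 0 || start + L > Gs) return;
                    if (circular && start >= G) return;
                    loci.push_back(start);
                });
                if (any) break;
            }
            std::sort(loci.begin(), loci.end());
            loci.erase(std::unique(loci.begin(), loci.end()), loci.end());
            for (int start : loci) {
                int nmm = 0;
                for (int i = 0; i < L && nmm <= max_mm; ++i)
                    if (mc[i] != rs[start + i]) ++nmm;
                if (nmm <= max_mm) {
                    for (int i = 0; i < L; ++i) {
                        int p = start + i;
                        if (p >= G) p -= G;
                        ++depth[p];
                    }
                }
            }
        }
    }
    return depth;
}

// ---------------------------------------------------------------------------
// exact full-length substring screening (k-mer index + full verification)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_exact_substring(CharacterVector queries, std::string subject,
                                  int seed_k) {
    const char* ss = subject.c_str();
    int n = (int)subject.size();
    KmerIndex idx;
    if (n >= seed_k) idx.build(ss, n, seed_k);

    LogicalVector out(queries.size());
    for (R_xlen_t qi = 0; qi < queries.size(); ++qi) {
        std::string q = as<std::string>(queries[qi]);
        int L = (int)q.size();
        bool found = false;
        if (L > n) { out[qi] = false; continue; }
        if (L < seed_k) {
            found = subject.find(q) != std::string::npos;
        } else {
            // seed on the first valid k-mer, verify full length; a full
            // match must place that k-mer at one of its indexed positions,
            // so the first probe decides the outcome
            u128 mask = (((u128)1) << (2 * seed_k)) - 1;
            u128 f = 0;
            int valid = 0;
            const char* qc = q.c_str();
            for (int i = 0; i < L && !found; ++i) {
                int b = base2bit(qc[i]);
                if (b < 0) { valid = 0; f = 0; continue; }
                f = ((f << 2) | (u128)b) & mask;
                if (++valid >= seed_k) {
                    int off = i - seed_k + 1;
                    idx.lookup(f, [&](int pos) {
                        if (found) return;
                        int start = pos - off;
                        if (start < 0 || start + L > n) return;
                        if (memcmp(qc, ss + start, (size_t)L) == 0) found = true;
                    });
                    break;
                }
            }
            // a query containing non-ACGT cannot match an ACGT subject only if
            // the subject also lacks them; fall back to direct search when no
            // valid anchor k-mer existed
            if (!found && valid < seed_k && L >= seed_k) {
                bool has_invalid = false;
                for (int i = 0; i < L; ++i)
                    if (base2bit(qc[i]) < 0) { has_invalid = true; break; }
                if (has_invalid) found = subject.find(q) != std::string::npos;
            }
        }
        out[qi] = found;
    }
    return out;
}

// ---------------------------------------------------------------------------
// junction-aware vector trimming
// ---------------------------------------------------------------------------

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    }
    return 'N';
}

// Trim vector sequence off read ends. On a circular cosmid the vector part
// of any junction-spanning mate is anchored at the cloning site, so the
// longest front (back) trim is the longest t for which the mate prefix
// (suffix) equals the vector sequence approaching (leaving) the site, on
// either strand. Mates emptied by trimming are returned as "".
// [[Rcpp::export]]
CharacterVector cpp_junction_trim(CharacterVector mates, std::string vec,
                                  int site) {
    int V = (int)vec.size();
    std::string vecD = vec + vec;
    CharacterVector out(mates.size());
    for (R_xlen_t mi = 0; mi < mates.size(); ++mi) {
        std::string m = as<std::string>(mates[mi]);
        int L = (int)m.size();
        int maxT = std::min(L, V);
        int p1 = 0, p2 = 0;
        // front contexts: vector approaching the site (+), or rc of vector
        // leaving the site (-)
        for (int t = maxT; t >= 1; --t) {
            bool ok = true;
            for (int i = 0; i < t; ++i)
                if (m[i] != vecD[site + V - t + i]) { ok = false; break; }
            if (ok) { p1 = t; break; }
            ok = true;
            for (int i = 0; i < t; ++i)
                if (m[i] != comp_base(vecD[site + t - 1 - i])) { ok = false; break; }
            if (ok) { p1 = t; break; }
        }
        // back contexts: vector leaving the site (+), or rc of vector
        // approaching the site (-)
        for (int t = maxT; t >= 1; --t) {
            bool ok = true;
            for (int i = 0; i < t; ++i)
                if (m[L - t + i] != vecD[site + i]) { ok = false; break; }
            if (ok) { p2 = t; break; }
            ok = true;
            for (int i = 0; i < t; ++i)
                if (m[L - t + i] != comp_base(vecD[site + V - 1 - i])) { ok = false; break; }
            if (ok) { p2 = t; break; }
        }
        if (p1 + p2 >= L) {
            out[mi] = "";
        } else {
            out[mi] = m.substr(p1, L - p1 - p2);
        }
    }
    return out;
}
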