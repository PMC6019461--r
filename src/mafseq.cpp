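#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// ---------------------------------------------------------------------------
// Gapless seed-and-extend alignment of each read against a panel of
// references. For every read the best reference is chosen by score
// (match +1 / mismatch -1 over the overlap of the best diagonal), ties by
// fewer mismatches, then by lower reference index (callers pass references
// sorted by name). Diagonals are nominated by exact seed hits, so a read
// with no seed match to any reference gets no call.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_seed_align(CharacterVector reads, CharacterVector refs,
                    int seed_len = 12, int seed_step = 4, int top_diags = 3) {
  const int nr = reads.size(), nf = refs.size();
  std::vector<std::string> F(nf);
  for (int f = 0; f < nf; ++f) F[f] = as<std::string>(refs[f]);

  IntegerVector best_ref(nr, NA_INTEGER), best_score(nr, NA_INTEGER),
      best_mm(nr, NA_INTEGER), ref_start(nr, NA_INTEGER),
      ref_end(nr, NA_INTEGER), read_start(nr, NA_INTEGER),
      aln_len(nr, NA_INTEGER);
  List mm_ref(nr), mm_read(nr);

  const uint64_t mask = (seed_len >= 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);

  for (int i = 0; i < nr; ++i) {
    std::string R = as<std::string>(reads[i]);
    const int rl = (int)R.size();
    // hash of read k-mers -> positions
    std::unordered_map<uint64_t, std::vector<int> > kmers;
    if (rl >= seed_len) {
      uint64_t key = 0;
      int valid = 0;
      for (int q = 0; q < rl; ++q) {
        int c = base_code(R[q]);
        if (c < 0) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++valid >= seed_len) kmers[key].push_back(q - seed_len + 1);
      }
    }
    int b_ref = -1, b_score = INT_MIN, b_mm = INT_MAX, b_diag = 0;
    for (int f = 0; f < nf; ++f) {
      const std::string &S = F[f];
      const int fl = (int)S.size();
      if (fl < seed_len || rl < seed_len) continue;
      std::unordered_map<int, int> votes;
      for (int p = 0; p + seed_len <= fl; p += seed_step) {
        uint64_t key = 0;
        bool ok = true;
        for (int k = 0; k < seed_len; ++k) {
          int c = base_code(S[p + k]);
          if (c < 0) { ok = false; break; }
          key = (key << 2) | (uint64_t)c;
        }
        if (!ok) continue;
        auto it = kmers.find(key & mask);
        if (it == kmers.end()) continue;
        for (int q : it->second) votes[q - p]++;
      }
      if (votes.empty()) continue;
      // top diagonals by vote count
      std::vector<std::pair<int, int> > dv(votes.begin(), votes.end());
      std::sort(dv.begin(), dv.end(),
                [](const std::pair<int, int> &a, const std::pair<int, int> &b) {
                  return a.second > b.second ||
                         (a.second == b.second && a.first < b.first);
                });
      const int ncand = std::min((int)dv.size(), top_diags);
      for (int d = 0; d < ncand; ++d) {
        const int diag = dv[d].first;
        const int rs = std::max(0, -diag);
        const int re = std::min(fl, rl - diag);
        if (re - rs < seed_len) continue;
        int mm = 0;
        for (int p = rs; p < re; ++p)
          if (S[p] != R[p + diag]) ++mm;
        const int score = (re - rs) - 2 * mm;
        if (score > b_score || (score == b_score && mm < b_mm) ||
            (score == b_score && mm == b_mm && f < b_ref)) {
          b_score = score; b_mm = mm; b_ref = f; b_diag = diag;
        }
      }
    }
    if (b_ref >= 0) {
      const std::string &S = F[b_ref];
      const int fl = (int)S.size();
      const int rs = std::max(0, -b_diag);
      const int re = std::min(fl, rl - b_diag);
      std::vector<int> mr, mq;
      for (int p = rs; p < re; ++p)
        if (S[p] != R[p + b_diag]) { mr.push_back(p); mq.push_back(p + b_diag); }
      best_ref[i] = b_ref + 1;
      best_score[i] = b_score;
      best_mm[i] = b_mm;
      ref_start[i] = rs;
      ref_end[i] = re;
      read_start[i] = rs + b_diag;
      aln_len[i] = re - rs;
      mm_ref[i] = wrap(mr);
      mm_read[i] = wrap(mq);
    } else {
      mm_ref[i] = IntegerVector(0);
      mm_read[i] = IntegerVector(0);
    }
  }
  return List::create(_["ref_index"] = best_ref, _["score"] = best_score,
                      _["mismatches"] = best_mm, _["ref_start"] = ref_start,
                      _["ref_end"] = ref_end, _["read_start"] = read_start,
                      _["aligned_length"] = aln_len,
                      _["mismatch_ref_pos"] = mm_ref,
                      _["mismatch_read_pos"] = mm_read);
}

// ---------------------------------------------------------------------------
// Minimum Hamming distance of each string against a set of references.
// Strings shorter than a reference are compared over the common prefix
// length; callers guarantee equal lengths where that matters.
// Returns best index (1-based), best and second-best distances.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_min_hamming(CharacterVector x, CharacterVector refs) {
  const int n = x.size(), m = refs.size();
  std::vector<std::string> R(m);
  for (int j = 0; j < m; ++j) R[j] = as<std::string>(refs[j]);
  IntegerVector best(n, NA_INTEGER), d1(n, NA_INTEGER), d2(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    int b = -1, bd = INT_MAX, bd2 = INT_MAX;
    for (int j = 0; j < m; ++j) {
      const int L = std::min(s.size(), R[j].size());
      int d = (int)(std::max(s.size(), R[j].size()) - L);  // length gap counts
      for (int k = 0; k < L; ++k)
        if (s[k] != R[j][k]) ++d;
      if (d < bd) { bd2 = bd; bd = d; b = j; }
      else if (d < bd2) bd2 = d;
    }
    if (b >= 0) { best[i] = b + 1; d1[i] = bd; if (m > 1) d2[i] = bd2; }
  }
  return List::create(_["best"] = best, _["d1"] = d1, _["d2"] = d2);
}

// ---------------------------------------------------------------------------
// Majority-vote consensus per UID group.
// Groups with >= min_reads members: restrict to reads of the modal insert
// length (ties -> longer), per-position majority vote, position ties broken
// by the larger summed Phred for the tied base, remaining ties by base
// order A<C<G<T. Smaller groups pass through the member with the highest
// mean Phred (ties -> first member).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_consensus(CharacterVector seqs, CharacterVector quals,
                   IntegerVector group, int ngroups, int min_reads = 3) {
  const int n = seqs.size();
  std::vector<std::vector<int> > members(ngroups);
  for (int i = 0; i < n; ++i) members[group[i] - 1].push_back(i);

  CharacterVector cons(ngroups);
  CharacterVector prov(ngroups);
  IntegerVector nreads(ngroups), used(ngroups), rep(ngroups, NA_INTEGER);

  for (int g = 0; g < ngroups; ++g) {
    const std::vector<int> &mem = members[g];
    const int k = (int)mem.size();
    nreads[g] = k;
    if (k == 0) { cons[g] = NA_STRING; prov[g] = NA_STRING; continue; }
    if (k < min_reads) {
      int bi = mem[0];
      double bq = -1.0;
      for (int i : mem) {
        std::string q = as<std::string>(quals[i]);
        double s = 0;
        for (char c : q) s += (double)(c - 33);
        double mq = q.empty() ? 0.0 : s / q.size();
        if (mq > bq) { bq = mq; bi = i; }
      }
      cons[g] = seqs[bi];
      prov[g] = "passthrough";
      used[g] = 1;
      rep[g] = bi + 1;
      continue;
    }
    // modal length, ties -> longer
    std::unordered_map<int, int> lens;
    for (int i : mem) lens[LENGTH(STRING_ELT(seqs, i))]++;
    int mode_len = -1, mode_n = -1;
    for (auto &kv : lens)
      if (kv.second > mode_n || (kv.second == mode_n && kv.first > mode_len)) {
        mode_n = kv.second; mode_len = kv.first;
      }
    std::vector<int> use;
    for (int i : mem)
      if (LENGTH(STRING_ELT(seqs, i)) == mode_len) use.push_back(i);
    used[g] = (int)use.size();
    std::vector<int> cnt(4 * mode_len, 0);
    std::vector<double> qs(4 * mode_len, 0.0);
    for (int i : use) {
      std::string s = as<std::string>(seqs[i]);
      std::string q = as<std::string>(quals[i]);
      const int ql = (int)q.size();
      for (int p = 0; p < mode_len; ++p) {
        int c = base_code(s[p]);
        if (c < 0) continue;  // ambiguous bases do not vote
        cnt[4 * p + c]++;
        qs[4 * p + c] += (double)((p < ql ? q[p] : (char)33) - 33);
      }
    }
    std::string out(mode_len, 'N');
    for (int p = 0; p < mode_len; ++p) {
      int bc = 0;
      for (int c = 1; c < 4; ++c) {
        if (cnt[4 * p + c] > cnt[4 * p + bc] ||
            (cnt[4 * p + c] == cnt[4 * p + bc] &&
             qs[4 * p + c] > qs[4 * p + bc]))
          bc = c;
      }
      if (cnt[4 * p + bc] > 0) out[p] = BASES[bc];
    }
    cons[g] = out;
    prov[g] = "corrected";
  }
  return List::create(_["sequence"] = cons, _["provenance"] = prov,
                      _["read_count"] = nreads, _["used_reads"] = used,
                      _["representative"] = rep);
}

// ---------------------------------------------------------------------------
// Correlated PCR substitution errors on per-FID amplification lineages.
// Each FID lineage is rooted at one polymerase pass over the original
// molecule (root errors shared by the whole lineage); the remaining
// cycles-1 replications form a binary tree explored lazily along each
// read's random path, so reads sharing a path prefix share those errors.
// Uses R's RNG (deterministic under set.seed()).
// Returns, per read, 0-based mutated positions and base shifts (1-3).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_pcr_errors(IntegerVector fid_id, IntegerVector insert_len,
                    int cycles, double rate) {
  const int n = fid_id.size();
  List pos_out(n), delta_out(n);
  if (rate <= 0.0 || cycles < 1) {
    for (int i = 0; i < n; ++i) {
      pos_out[i] = IntegerVector(0);
      delta_out[i] = IntegerVector(0);
    }
    return List::create(_["pos"] = pos_out, _["delta"] = delta_out);
  }
  if (cycles > 40) stop("cycles too large for lineage encoding");
  typedef std::vector<std::pair<int, int> > MutVec;
  std::unordered_map<uint64_t, MutVec> nodes;  // key: fid lineage x path
  nodes.reserve(n * cycles / 2 + 16);

  for (int i = 0; i < n; ++i) {
    const int L = insert_len[i];
    std::vector<std::pair<int, int> > muts;
    // path key: marker bit then one bit per replication step;
    // step 0 is the lineage root (FID attachment pass).
    uint64_t key = ((uint64_t)(uint32_t)fid_id[i]) << 41 | 1ULL;
    for (int c = 0; c < cycles; ++c) {
      if (c > 0) key = (key << 1) | (unif_rand() < 0.5 ? 1ULL : 0ULL);
      auto it = nodes.find(key);
      if (it == nodes.end()) {
        MutVec mv;
        int nm = (int)R::rbinom((double)L, rate);
        for (int j = 0; j < nm; ++j) {
          int p = (int)(unif_rand() * L);
          if (p >= L) p = L - 1;
          int d = 1 + (int)(unif_rand() * 3);
          if (d > 3) d = 3;
          mv.push_back(std::make_pair(p, d));
        }
        it = nodes.insert(std::make_pair(key, mv)).first;
      }
      for (auto &m : it->second) muts.push_back(m);
    }
    IntegerVector pv(muts.size()), dv(muts.size());
    for (size_t j = 0; j < muts.size(); ++j) {
      pv[j] = muts[j].first;
      dv[j] = muts[j].second;
    }
    pos_out[i] = pv;
    delta_out[i] = dv;
  }
  return List::create(_["pos"] = pos_out, _["delta"] = delta_out);
}

// ---------------------------------------------------------------------------
// Apply substitutions (0-based position, base shift 1-3) to sequences.
// Multiple hits on one position compound in order, mimicking sequential
// replication errors.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
CharacterVector cpp_apply_muts(CharacterVector seqs, List pos, List delta) {
  const int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector p = pos[i], d = delta[i];
    if (p.size() == 0) { out[i] = seqs[i]; continue; }
    std::string s = as<std::string>(seqs[i]);
    for (int j = 0; j < p.size(); ++j) {
      if (p[j] < 0 || p[j] >= (int)s.size()) continue;
      int c = base_code(s[p[j]]);
      if (c < 0) continue;
      s[p[j]] = BASES[(c + d[j]) % 4];
    }
    out[i] = s;
  }
  return out;
}
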