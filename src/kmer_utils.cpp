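#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>
#include <queue>
#include <limits>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// lexicographic min of a k-mer and its reverse complement
static std::string canonical_kmer(const std::string& s) {
  std::string rc(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[s.size() - 1 - i]);
    rc[i] = (c < 0) ? 'N' : BASES[3 - c];
  }
  return (rc < s) ? rc : s;
}

// distinct valid (ACGT-only) k-mers of one sequence
static void collect_kmers(const std::string& seq, int k, bool canonical,
                          std::unordered_set<std::string>& out) {
  const int L = (int)seq.size();
  if (L < k) return;
  int run = 0; // length of current valid suffix
  for (int i = 0; i < L; ++i) {
    run = (base_code(seq[i]) >= 0) ? run + 1 : 0;
    if (run >= k) {
      std::string km = seq.substr(i - k + 1, k);
      out.insert(canonical ? canonical_kmer(km) : km);
    }
  }
}

// [[Rcpp::export]]
CharacterVector kmer_set_cpp(CharacterVector seqs, int k, bool canonical) {
  std::unordered_set<std::string> all;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    collect_kmers(s, k, canonical, all);
  }
  CharacterVector out(all.size());
  R_xlen_t j = 0;
  for (const auto& km : all) out[j++] = km;
  return out;
}

// total k-mer multiplicities across all sequences (every valid window)
// [[Rcpp::export]]
List kmer_count_cpp(CharacterVector seqs, int k, bool canonical) {
  std::unordered_map<std::string, double> counts;
  double total = 0.0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    const int L = (int)s.size();
    int run = 0;
    for (int j = 0; j < L; ++j) {
      run = (base_code(s[j]) >= 0) ? run + 1 : 0;
      if (run >= k) {
        std::string km = s.substr(j - k + 1, k);
        if (canonical) km = canonical_kmer(km);
        counts[km] += 1.0;
        total += 1.0;
      }
    }
  }
  CharacterVector nm(counts.size());
  NumericVector ct(counts.size());
  R_xlen_t j = 0;
  for (const auto& p : counts) { nm[j] = p.first; ct[j] = p.second; ++j; }
  ct.attr("names") = nm;
  return List::create(_["counts"] = ct, _["total"] = total);
}

// DUST-style low-complexity score: for each window, sum c_t(c_t-1)/2 over
// overlapping triplet counts c_t, divided by the fixed normaliser 62
// (= 64 - 2). Windows are every 64-base stretch plus the whole sequence;
// the score is the maximum over windows. Triplets containing non-ACGT
// characters are skipped.
// [[Rcpp::export]]
NumericVector dust_scores_cpp(CharacterVector seqs) {
  const double denom = 62.0;
  NumericVector out(seqs.size());
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    const int L = (int)seq.size();
    if (L < 3) { out[s] = 0.0; continue; }
    const int nt = L - 2;
    std::vector<int> trip(nt, -1);
    for (int i = 0; i < nt; ++i) {
      int a = base_code(seq[i]), b = base_code(seq[i + 1]), c = base_code(seq[i + 2]);
      if (a >= 0 && b >= 0 && c >= 0) trip[i] = (a << 4) | (b << 2) | c;
    }
    // whole-sequence window
    std::vector<int> cnt(64, 0);
    double pairs = 0.0, best = 0.0;
    for (int i = 0; i < nt; ++i)
      if (trip[i] >= 0) { pairs += cnt[trip[i]]; cnt[trip[i]]++; }
    best = pairs;
    // sliding 64-base windows (62 triplets), step 1
    const int wt = 62;
    if (nt > wt) {
      std::fill(cnt.begin(), cnt.end(), 0);
      pairs = 0.0;
      for (int i = 0; i < wt; ++i)
        if (trip[i] >= 0) { pairs += cnt[trip[i]]; cnt[trip[i]]++; }
      if (pairs > best) best = pairs;
      for (int i = wt; i < nt; ++i) {
        if (trip[i] >= 0) { pairs += cnt[trip[i]]; cnt[trip[i]]++; }
        int o = trip[i - wt];
        if (o >= 0) { cnt[o]--; pairs -= cnt[o]; }
        if (pairs > best) best = pairs;
      }
    }
    out[s] = best / denom;
  }
  return out;
}

// number of distinct k-mers of each read found in the host k-mer set
// [[Rcpp::export]]
IntegerVector host_shared_counts_cpp(CharacterVector reads,
                                     CharacterVector host_kmers,
                                     int k, bool canonical) {
  std::unordered_set<std::string> host;
  host.reserve(host_kmers.size() * 2);
  for (R_xlen_t i = 0; i < host_kmers.size(); ++i)
    host.insert(as<std::string>(host_kmers[i]));
  IntegerVector out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    std::unordered_set<std::string> kms;
    collect_kmers(s, k, canonical, kms);
    int shared = 0;
    for (const auto& km : kms) if (host.count(km)) ++shared;
    out[i] = shared;
  }
  return out;
}

// For each read, the 1-based indices of markers sharing >= min_hits
// distinct k-mers with it, together with the hit counts.
// index_kmers/index_marker: flattened (k-mer, marker) pairs.
// [[Rcpp::export]]
List assign_reads_cpp(CharacterVector reads, CharacterVector index_kmers,
                      IntegerVector index_marker, int n_markers, int k,
                      bool canonical, int min_hits) {
  std::unordered_map<std::string, std::vector<int>> idx;
  idx.reserve(index_kmers.size() * 2);
  for (R_xlen_t i = 0; i < index_kmers.size(); ++i)
    idx[as<std::string>(index_kmers[i])].push_back(index_marker[i]);
  List out(reads.size());
  std::vector<int> hits(n_markers + 1, 0);
  std::vector<int> touched;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    std::unordered_set<std::string> kms;
    collect_kmers(s, k, canonical, kms);
    touched.clear();
    for (const auto& km : kms) {
      auto it = idx.find(km);
      if (it == idx.end()) continue;
      for (int m : it->second) {
        if (hits[m] == 0) touched.push_back(m);
        hits[m]++;
      }
    }
    std::vector<int> keep, kc;
    for (int m : touched) {
      if (hits[m] >= min_hits) { keep.push_back(m); kc.push_back(hits[m]); }
      hits[m] = 0;
    }
    IntegerVector mk(keep.begin(), keep.end());
    mk.attr("hits") = IntegerVector(kc.begin(), kc.end());
    out[r] = mk;
  }
  return out;
}

static inline uint64_t encode_kmer(const std::string& s) {
  uint64_t v = 0;
  for (char c : s) v = (v << 2) | (uint64_t)base_code(c);
  return v;
}

// Shortest-path hop counts on the order-k de Bruijn graph over {A,C,G,T}.
// complete = TRUE: undirected graph over all 4^k k-mers, edges between a
// word and its single-shift successors in either direction (diameter <= k).
// complete = FALSE: graph restricted to `observed` nodes; unreachable pairs
// get penalty k + 1.
// [[Rcpp::export]]
NumericMatrix debruijn_dist_cpp(CharacterVector from, CharacterVector to,
                                int k, bool complete,
                                CharacterVector observed) {
  if (k < 2 || k > 13) stop("k must be between 2 and 13");
  const uint64_t n_nodes = ((uint64_t)1) << (2 * k);
  const uint64_t mask = n_nodes - 1;
  const int shift_hi = 2 * (k - 1);
  NumericMatrix out(from.size(), to.size());

  std::vector<uint64_t> to_codes(to.size());
  for (R_xlen_t j = 0; j < to.size(); ++j)
    to_codes[j] = encode_kmer(as<std::string>(to[j]));

  std::unordered_set<uint64_t> allowed;
  if (!complete) {
    for (R_xlen_t i = 0; i < observed.size(); ++i)
      allowed.insert(encode_kmer(as<std::string>(observed[i])));
  }

  std::vector<uint8_t> dist(complete ? n_nodes : 0);
  std::unordered_map<uint64_t, int> sparse_dist;

  for (R_xlen_t i = 0; i < from.size(); ++i) {
    uint64_t src = encode_kmer(as<std::string>(from[i]));
    size_t targets_left = to_codes.size();
    if (complete) {
      std::fill(dist.begin(), dist.end(), 255);
      std::vector<uint64_t> frontier{src}, nxt;
      dist[src] = 0;
      int d = 0;
      while (!frontier.empty() && targets_left > 0 && d <= k) {
        ++d;
        nxt.clear();
        for (uint64_t w : frontier) {
          for (int c = 0; c < 4; ++c) {
            uint64_t r = ((w << 2) & mask) | (uint64_t)c;
            if (dist[r] == 255) { dist[r] = (uint8_t)d; nxt.push_back(r); }
            uint64_t l = (w >> 2) | ((uint64_t)c << shift_hi);
            if (dist[l] == 255) { dist[l] = (uint8_t)d; nxt.push_back(l); }
          }
        }
        frontier.swap(nxt);
      }
      for (R_xlen_t j = 0; j < to.size(); ++j)
        out(i, j) = (double)dist[to_codes[j]];
    } else {
      sparse_dist.clear();
      sparse_dist[src] = 0;
      std::vector<uint64_t> frontier{src}, nxt;
      int d = 0;
      while (!frontier.empty()) {
        ++d;
        nxt.clear();
        for (uint64_t w : frontier) {
          for (int c = 0; c < 4; ++c) {
            uint64_t cand[2] = { ((w << 2) & mask) | (uint64_t)c,
                                 (w >> 2) | ((uint64_t)c << shift_hi) };
            for (uint64_t v : cand) {
              if (allowed.count(v) && !sparse_dist.count(v)) {
                sparse_dist[v] = d;
                nxt.push_back(v);
              }
            }
          }
        }
        frontier.swap(nxt);
      }
      for (R_xlen_t j = 0; j < to.size(); ++j) {
        auto it = sparse_dist.find(to_codes[j]);
        out(i, j) = (it == sparse_dist.end()) ? (double)(k + 1) : (double)it->second;
      }
      (void)targets_left;
    }
  }
  return out;
}

// Optimal transportation cost between supply a and demand b (equal totals)
// with dense cost matrix, by successive shortest paths with node potentials.
// [[Rcpp::export]]
double emd_ssp_cpp(NumericVector a, NumericVector b, NumericMatrix cost) {
  const int m = a.size(), n = b.size();
  if (cost.nrow() != m || cost.ncol() != n) stop("cost dimensions mismatch");
  const double EPS = 1e-12;
  std::vector<double> ra(a.begin(), a.end()), rb(b.begin(), b.end());
  std::vector<std::vector<double>> f(m, std::vector<double>(n, 0.0));
  std::vector<double> pi(m + n, 0.0);
  double total_left = 0.0;
  for (double v : ra) total_left += v;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> d(m + n);
  std::vector<int> parent(m + n);
  std::vector<char> done(m + n);

  long iter = 0, max_iter = 1000L * (m + n) + 1000L;
  while (total_left > 1e-10 && ++iter < max_iter) {
    // Dijkstra from all sources with remaining supply
    std::fill(d.begin(), d.end(), INF);
    std::fill(parent.begin(), parent.end(), -1);
    std::fill(done.begin(), done.end(), 0);
    for (int i = 0; i < m; ++i) if (ra[i] > EPS) d[i] = 0.0;
    int target = -1;
    while (true) {
      int u = -1; double du = INF;
      for (int v = 0; v < m + n; ++v)
        if (!done[v] && d[v] < du) { du = d[v]; u = v; }
      if (u < 0) break;
      done[u] = 1;
      if (u >= m && rb[u - m] > EPS) { target = u; break; }
      if (u < m) {
        for (int j = 0; j < n; ++j) {
          double rc = cost(u, j) + pi[u] - pi[m + j];
          if (rc < 0) rc = 0; // guard rounding
          if (d[u] + rc < d[m + j] - 1e-15) { d[m + j] = d[u] + rc; parent[m + j] = u; }
        }
      } else {
        int j = u - m;
        for (int i = 0; i < m; ++i) {
          if (f[i][j] > EPS) {
            double rc = -cost(i, j) + pi[u] - pi[i];
            if (rc < 0) rc = 0;
            if (d[u] + rc < d[i] - 1e-15) { d[i] = d[u] + rc; parent[i] = u; }
          }
        }
      }
    }
    if (target < 0) stop("transportation solve failed to find augmenting path");
    // bottleneck along path
    double push = rb[target - m];
    for (int v = target; parent[v] >= 0; v = parent[v]) {
      int u = parent[v];
      if (u >= m) push = std::min(push, f[v][u - m]); // backward arc j->i (v is source i)
    }
    {
      int v = target;
      while (parent[v] >= 0) v = parent[v];
      push = std::min(push, ra[v]);
    }
    // apply
    for (int v = target; parent[v] >= 0; v = parent[v]) {
      int u = parent[v];
      if (u < m) f[u][v - m] += push;   // forward arc i->j
      else f[v][u - m] -= push;          // backward arc
    }
    {
      int v = target;
      while (parent[v] >= 0) v = parent[v];
      ra[v] -= push;
    }
    rb[target - m] -= push;
    total_left -= push;
    // potential update
    double dt = d[target];
    for (int v = 0; v < m + n; ++v) pi[v] += std::min(d[v], dt);
  }
  if (total_left > 1e-8) stop("transportation solve did not converge");
  double c = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      if (f[i][j] > 0) c += f[i][j] * cost(i, j);
  return c;
}

// random DNA strings using R's RNG (reproducible under set.seed)
// [[Rcpp::export]]
CharacterVector random_dna_cpp(IntegerVector lens) {
  CharacterVector out(lens.size());
  for (R_xlen_t i = 0; i < lens.size(); ++i) {
    int L = lens[i];
    std::string s(L, 'A');
    for (int j = 0; j < L; ++j)
      s[j] = BASES[(int)(unif_rand() * 4) & 3];
    out[i] = s;
  }
  return out;
}

// per-base substitution errors at rate `rate`, using R's RNG
// [[Rcpp::export]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, double rate) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (rate > 0) {
      for (size_t j = 0; j < s.size(); ++j) {
        if (unif_rand() < rate) {
          int cur = base_code(s[j]);
          int sub = (int)(unif_rand() * 3) & 3; if (sub > 2) sub = 2;
          int nb = (cur + 1 + sub) & 3;
          s[j] = BASES[nb];
        }
      }
    }
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string rc(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) {
      int c = base_code(s[s.size() - 1 - j]);
      rc[j] = (c < 0) ? 'N' : BASES[3 - c];
    }
    out[i] = rc;
  }
  return out;
}
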