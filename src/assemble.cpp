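#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Greedy overlap-layout assembly of short reads into contigs.
//
// Deterministic: reads are deduplicated and sorted (length desc, then
// lexicographic).  Candidate suffix-prefix overlaps are found by seeding
// the prefix SEED-mer of every read against an index of all SEED-mer
// positions in all reads, then verified over the whole overlap at
// minIdentity; contained reads are dropped.  Surviving overlaps of at
// least minOverlap bp are merged greedily by descending overlap length
// (ties by read index), building simple paths.
static const int SEED = 15;

static inline bool pack_kmer(const char *s, uint32_t &key) {
  uint32_t k = 0;
  for (int i = 0; i < SEED; ++i) {
    uint32_t c;
    switch (s[i]) {
      case 'A': c = 0; break; case 'C': c = 1; break;
      case 'G': c = 2; break; case 'T': c = 3; break;
      default: return false;
    }
    k = (k << 2) | c;
  }
  key = k;
  return true;
}

static inline int mismatches(const char *a, const char *b, int n, int allowed) {
  int m = 0;
  for (int i = 0; i < n; ++i)
    if (a[i] != b[i] && ++m > allowed) return m;
  return m;
}

// [[Rcpp::export(name = ".greedyAssembleCpp")]]
CharacterVector greedy_assemble_cpp(CharacterVector reads, int minOverlap,
                                    double minIdentity) {
  if (minOverlap < SEED) minOverlap = SEED;
  std::vector<std::string> seqs;
  seqs.reserve(reads.size());
  for (int i = 0; i < reads.size(); ++i)
    seqs.push_back(as<std::string>(reads[i]));
  std::sort(seqs.begin(), seqs.end(),
            [](const std::string &x, const std::string &y) {
              if (x.size() != y.size()) return x.size() > y.size();
              return x < y;
            });
  seqs.erase(std::unique(seqs.begin(), seqs.end()), seqs.end());
  int n = seqs.size();
  if (n == 0) return CharacterVector(0);

  // index all SEED-mer positions of all reads
  std::unordered_map<uint32_t, std::vector<std::pair<int, int> > > index;
  index.reserve(n * 8);
  for (int i = 0; i < n; ++i) {
    int L = seqs[i].size();
    for (int p = 0; p + SEED <= L; ++p) {
      uint32_t key;
      if (pack_kmer(seqs[i].data() + p, key))
        index[key].push_back(std::make_pair(i, p));
    }
  }

  // candidate edges: seed b's prefix against the index.  Three staggered
  // seeds (offsets 0, 15, 30) make a head discoverable even when a
  // sequencing error corrupts one seed window.
  struct Edge { int ov, a, b; };
  std::vector<Edge> edges;
  std::vector<char> contained(n, 0);
  std::vector<int64_t> seen;                   // (a,b,ov) dedup per b
  for (int b = 0; b < n; ++b) {
    int Lb = seqs[b].size();
    seen.clear();
    for (int s = 0; s <= 2 * SEED; s += SEED) {
      if (s + SEED > Lb) break;
      uint32_t key;
      if (!pack_kmer(seqs[b].data() + s, key)) continue;
      auto it = index.find(key);
      if (it == index.end()) continue;
      for (size_t q = 0; q < it->second.size(); ++q) {
        int a = it->second[q].first, p0 = it->second[q].second - s;
        if (a == b || p0 < 0) continue;
        int La = seqs[a].size();
        int64_t tag = ((int64_t)a << 20) | p0;
        if (std::find(seen.begin(), seen.end(), tag) != seen.end()) continue;
        seen.push_back(tag);
        if (p0 + Lb <= La) {                   // containment candidate
          int allowed = (int)std::floor(Lb * (1.0 - minIdentity));
          if (mismatches(seqs[a].data() + p0, seqs[b].data(), Lb, allowed)
                <= allowed)
            contained[b] = 1;
          continue;
        }
        int ov = La - p0;
        if (ov < minOverlap || ov > Lb) continue;
        int allowed = (int)std::floor(ov * (1.0 - minIdentity));
        if (mismatches(seqs[a].data() + p0, seqs[b].data(), ov, allowed)
              <= allowed)
          edges.push_back({ov, a, b});
      }
    }
  }
  // drop edges touching contained reads
  std::vector<Edge> kept;
  kept.reserve(edges.size());
  for (const Edge &e : edges)
    if (!contained[e.a] && !contained[e.b]) kept.push_back(e);
  std::stable_sort(kept.begin(), kept.end(),
                   [](const Edge &x, const Edge &y) {
                     if (x.ov != y.ov) return x.ov > y.ov;
                     if (x.a != y.a) return x.a < y.a;
                     return x.b < y.b;
                   });

  std::vector<int> succ(n, -1), pred(n, -1), ovOf(n, 0),
      pathEnd(n), pathStart(n);
  for (int i = 0; i < n; ++i) { pathEnd[i] = i; pathStart[i] = i; }
  for (const Edge &e : kept) {
    if (succ[e.a] != -1 || pred[e.b] != -1) continue;  // a must be a tail, b a head
    if (pathEnd[e.b] == e.a) continue;                 // would close a cycle
    succ[e.a] = e.b; pred[e.b] = e.a; ovOf[e.b] = e.ov;
    int s = pathStart[e.a], t = pathEnd[e.b];          // head of a's path, tail of b's
    pathEnd[s] = t; pathStart[t] = s;
  }

  std::vector<std::string> contigs;
  for (int i = 0; i < n; ++i) {
    if (contained[i] || pred[i] != -1) continue;
    std::string contig = seqs[i];
    for (int cur = succ[i]; cur != -1; cur = succ[cur])
      contig += seqs[cur].substr(ovOf[cur]);
    contigs.push_back(contig);
  }
  std::sort(contigs.begin(), contigs.end(),
            [](const std::string &x, const std::string &y) {
              if (x.size() != y.size()) return x.size() > y.size();
              return x < y;
            });
  return wrap(contigs);
}
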