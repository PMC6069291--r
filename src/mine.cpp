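#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <map>
#include <tuple>

using namespace Rcpp;

// Top-k non-redundant rule search over a transaction database whose item
// universe fits in a 62-bit mask.  Mirrors the R reference engine:
// depth-first itemset enumeration with shrinking transaction-id lists,
// rule generation per itemset with a confidence floor, and (when
// `buffer` > 0) a rising support threshold driven by periodic
// redundancy-aware compaction of the candidate buffer.

namespace {

struct Rule {
  uint64_t ant, con;
  int sc, ac;
};

struct Miner {
  int m, n, max_size;
  double minconf;
  int buffer;  // 0 = unlimited (exact enumeration)
  std::vector<std::vector<int>> tids;       // per item
  std::vector<int> single_counts;
  std::unordered_map<uint64_t, int> counts; // itemsets of size >= 2
  std::vector<Rule> rules;
  int threshold = 1;
  size_t next_check;

  static int gcd(int a, int b) {
    while (b) { int t = b; b = a % b; a = t; }
    return a > 0 ? a : 1;
  }

  // true when rule b dominates rule a structurally (ant_b subset of
  // ant_a, con_a subset of con_b) and the two rules differ
  static bool dominates(const Rule &b, const Rule &a) {
    if ((a.ant & b.ant) != b.ant) return false;
    if ((a.con & b.con) != a.con) return false;
    return !(a.ant == b.ant && a.con == b.con);
  }

  void compact() {
    std::vector<Rule> live;
    live.reserve(rules.size());
    for (const Rule &r : rules)
      if (r.sc >= threshold) live.push_back(r);
    // group rules by exact (support, confidence); cohort size is shared
    std::map<std::tuple<int, int, int>, std::vector<size_t>> groups;
    for (size_t i = 0; i < live.size(); ++i) {
      int g = gcd(live[i].sc, live[i].ac);
      groups[std::make_tuple(live[i].sc, live[i].sc / g,
                             live[i].ac / g)].push_back(i);
    }
    std::vector<char> drop(live.size(), 0);
    for (auto &kv : groups) {
      auto &idx = kv.second;
      if (idx.size() < 2) continue;
      for (size_t a = 0; a < idx.size(); ++a) {
        for (size_t b = 0; b < idx.size(); ++b) {
          if (a == b) continue;
          if (dominates(live[idx[b]], live[idx[a]])) {
            drop[idx[a]] = 1;
            break;
          }
        }
      }
    }
    std::vector<Rule> kept;
    kept.reserve(live.size());
    for (size_t i = 0; i < live.size(); ++i)
      if (!drop[i]) kept.push_back(live[i]);
    if (buffer > 0 && (int)kept.size() >= buffer) {
      std::vector<int> sc(kept.size());
      for (size_t i = 0; i < kept.size(); ++i) sc[i] = kept[i].sc;
      std::nth_element(sc.begin(), sc.begin() + (buffer - 1), sc.end(),
                       std::greater<int>());
      threshold = std::max(threshold, sc[buffer - 1]);
      std::vector<Rule> trimmed;
      trimmed.reserve(kept.size());
      for (const Rule &r : kept)
        if (r.sc >= threshold) trimmed.push_back(r);
      kept.swap(trimmed);
    }
    rules.swap(kept);
    next_check = rules.size() + std::max<size_t>(buffer, 4096);
  }

  // subsets of an enumerated itemset may sort lexicographically after
  // it, so antecedent counts are computed on demand and memoised
  int get_count(const std::vector<int> &zi, uint64_t mask) {
    if (zi.size() == 1) return single_counts[zi[0]];
    auto it = counts.find(mask);
    if (it != counts.end()) return it->second;
    std::vector<int> cur = tids[zi[0]], tmp;
    for (size_t k = 1; k < zi.size() && !cur.empty(); ++k) {
      tmp.clear();
      std::set_intersection(cur.begin(), cur.end(), tids[zi[k]].begin(),
                            tids[zi[k]].end(), std::back_inserter(tmp));
      cur.swap(tmp);
    }
    int c = (int)cur.size();
    counts[mask] = c;
    return c;
  }

  void gen_rules(const std::vector<int> &zi, int cz) {
    int len = (int)zi.size();
    int nmask = (1 << len) - 2;
    for (int maskbits = 1; maskbits <= nmask; ++maskbits) {
      uint64_t xmask = 0, ymask = 0;
      std::vector<int> xi;
      for (int p = 0; p < len; ++p) {
        if (maskbits & (1 << p)) {
          xmask |= (uint64_t)1 << zi[p];
          xi.push_back(zi[p]);
        } else {
          ymask |= (uint64_t)1 << zi[p];
        }
      }
      int ac = get_count(xi, xmask);
      if (cz + 1e-9 >= minconf * ac) {
        rules.push_back({xmask, ymask, cz, ac});
        if (buffer > 0 && rules.size() >= next_check) compact();
      }
    }
  }

  void rec(std::vector<int> &prefix, const std::vector<int> &ptid,
           uint64_t pmask, int start) {
    std::vector<int> t2;
    for (int j = start; j < m; ++j) {
      const std::vector<int> &tj = tids[j];
      t2.clear();
      if (prefix.empty()) {
        t2 = tj;
      } else {
        std::set_intersection(ptid.begin(), ptid.end(), tj.begin(),
                              tj.end(), std::back_inserter(t2));
      }
      int cz = (int)t2.size();
      if (cz == 0 || cz < threshold) continue;
      prefix.push_back(j);
      uint64_t zmask = pmask | ((uint64_t)1 << j);
      if (prefix.size() >= 2) {
        counts[zmask] = cz;
        gen_rules(prefix, cz);
      }
      if ((int)prefix.size() < max_size && j + 1 < m)
        rec(prefix, t2, zmask, j + 1);
      prefix.pop_back();
    }
  }
};

}  // namespace

// [[Rcpp::export(rng = false)]]
List mine_rules_cpp(List transactions, int n_items, double minconf,
                    int max_size, int buffer) {
  Miner mn;
  mn.m = n_items;
  mn.n = transactions.size();
  mn.max_size = max_size;
  mn.minconf = minconf;
  mn.buffer = buffer;
  mn.next_check = buffer > 0 ? (size_t)buffer : SIZE_MAX;
  mn.tids.assign(n_items, {});
  for (int t = 0; t < mn.n; ++t) {
    IntegerVector it = transactions[t];
    for (int k = 0; k < it.size(); ++k) mn.tids[it[k] - 1].push_back(t);
  }
  mn.single_counts.assign(n_items, 0);
  for (int j = 0; j < n_items; ++j)
    mn.single_counts[j] = (int)mn.tids[j].size();
  std::vector<int> prefix;
  std::vector<int> root;
  mn.rec(prefix, root, 0, 0);

  std::vector<Rule> out;
  out.reserve(mn.rules.size());
  for (const Rule &r : mn.rules)
    if (buffer == 0 || r.sc >= mn.threshold) out.push_back(r);

  int nr = (int)out.size();
  List ant(nr), con(nr);
  IntegerVector sc(nr), ac(nr);
  for (int i = 0; i < nr; ++i) {
    std::vector<int> xa, xc;
    for (int j = 0; j < n_items; ++j) {
      if (out[i].ant & ((uint64_t)1 << j)) xa.push_back(j + 1);
      if (out[i].con & ((uint64_t)1 << j)) xc.push_back(j + 1);
    }
    ant[i] = wrap(xa);
    con[i] = wrap(xc);
    sc[i] = out[i].sc;
    ac[i] = out[i].ac;
  }
  return List::create(_["ant"] = ant, _["con"] = con, _["sc"] = sc,
                      _["ac"] = ac);
}
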