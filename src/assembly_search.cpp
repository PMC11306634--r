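// Exact string assembly index by iterative-deepening search, plus an
// intentionally simple breadth-first brute-force used as an independent
// reference. A pathway joins two available objects (single symbols are
// free basis objects; every product is necessarily a contiguous
// substring of the target) and the index is the minimal number of joins.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <deque>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

namespace {

struct ExactSolver {
  std::string target;
  std::vector<std::array<std::string, 3>> steps; // (left, right, product)
  std::vector<std::string> builtList;
  std::unordered_set<std::string> builtSet;
  // state -> largest remaining budget that already failed
  std::unordered_map<std::string, int> failMemo;

  // doubling bound: joins needed for goal g given the longest available
  // piece that is a substring of g
  int boundFor(const std::string& g) const {
    size_t L = 1;
    for (const auto& b : builtList) {
      if (b.size() > L && b.size() <= g.size() &&
          g.find(b) != std::string::npos) {
        L = b.size();
      }
    }
    int r = 0;
    size_t cap = L;
    while (cap < g.size()) { cap *= 2; ++r; }
    return r;
  }

  std::string stateKey(const std::vector<std::string>& goals) const {
    std::vector<std::string> gs(goals), bs(builtList);
    std::sort(gs.begin(), gs.end());
    std::sort(bs.begin(), bs.end());
    std::string k;
    for (const auto& x : gs) { k += x; k += '|'; }
    k += '#';
    for (const auto& x : bs) { k += x; k += '|'; }
    return k;
  }

  bool dfs(std::vector<std::string>& goals, int remaining) {
    while (!goals.empty()) {
      const std::string& g = goals.back();
      if (g.size() == 1 || builtSet.count(g)) goals.pop_back();
      else break;
    }
    if (goals.empty()) return true;

    std::unordered_set<std::string> distinctGoals;
    int lbmax = 0;
    for (const auto& g : goals) {
      if (g.size() > 1 && !builtSet.count(g)) {
        distinctGoals.insert(g);
        int b = boundFor(g);
        if (b > lbmax) lbmax = b;
      }
    }
    int need = std::max<int>(lbmax, (int)distinctGoals.size());
    if (need > remaining || remaining <= 0) return false;

    std::string key = stateKey(goals);
    auto it = failMemo.find(key);
    if (it != failMemo.end() && it->second >= remaining) return false;

    std::string g = goals.back();
    goals.pop_back();
    builtSet.insert(g);
    builtList.push_back(g);

    std::unordered_set<std::string> seenSplit;
    bool ok = false;
    for (size_t i = 1; i < g.size() && !ok; ++i) {
      std::string u = g.substr(0, i), v = g.substr(i);
      std::string sk = u;
      sk += '\x01';
      sk += v;
      if (!seenSplit.insert(sk).second) continue;
      steps.push_back({u, v, g});
      size_t gsz = goals.size();
      goals.push_back(v);
      goals.push_back(u); // resolve u first
      if (dfs(goals, remaining - 1)) {
        ok = true;
      } else {
        goals.resize(gsz);
        steps.pop_back();
      }
    }
    if (!ok) {
      builtSet.erase(g);
      builtList.pop_back();
      goals.push_back(g);
      int& slot = failMemo[key];
      if (slot < remaining) slot = remaining;
      return false;
    }
    return true;
  }
};

} // namespace

// [[Rcpp::export(name = ".assembly_exact_cpp")]]
List assembly_exact_cpp(std::string s, int cap) {
  int n = (int)s.size();
  if (n < 1) stop("empty string");
  CharacterMatrix empty(0, 3);
  if (n == 1) return List::create(_["index"] = 0, _["steps"] = empty);

  int lower = (int)std::ceil(std::log2((double)n) - 1e-12);
  for (int b = lower; b <= cap; ++b) {
    ExactSolver S;
    S.target = s;
    std::vector<std::string> goals{s};
    if (S.dfs(goals, b)) {
      // order steps by product length: parts are strictly shorter than
      // their product, so this is a valid topological (build) order
      std::stable_sort(S.steps.begin(), S.steps.end(),
                       [](const std::array<std::string, 3>& a,
                          const std::array<std::string, 3>& c) {
                         return a[2].size() < c[2].size();
                       });
      CharacterMatrix steps((int)S.steps.size(), 3);
      for (int i = 0; i < (int)S.steps.size(); ++i) {
        steps(i, 0) = S.steps[i][0];
        steps(i, 1) = S.steps[i][1];
        steps(i, 2) = S.steps[i][2];
      }
      return List::create(_["index"] = (int)S.steps.size(),
                          _["steps"] = steps);
    }
  }
  stop("exact search failed below the supplied upper bound");
}

// Brute-force reference: plain breadth-first search over states (sets of
// built substrings), no pruning beyond the substring closure that
// defines the state space. Joins are resolved through a precomputed
// object-pair product table so state expansion is array lookups only.
// [[Rcpp::export(name = ".assembly_oracle_cpp")]]
int assembly_oracle_cpp(std::string s) {
  int n = (int)s.size();
  if (n <= 1) return 0;

  std::vector<std::string> cand;
  std::unordered_map<std::string, int> id;
  for (size_t i = 0; i < s.size(); ++i) {
    for (size_t L = 2; i + L <= s.size(); ++L) {
      std::string sub = s.substr(i, L);
      if (!id.count(sub)) {
        id[sub] = (int)cand.size();
        cand.push_back(sub);
      }
    }
  }
  int targetId = id[s];
  int M = (int)cand.size();
  if (M > 255) stop("oracle limited to 255 distinct substrings");

  std::unordered_set<char> chset(s.begin(), s.end());
  std::vector<std::string> alpha;
  for (char c : chset) alpha.push_back(std::string(1, c));
  std::sort(alpha.begin(), alpha.end());
  int A = (int)alpha.size();

  // objects 0..A-1 are symbols, A..A+M-1 are candidate substrings
  int NOBJ = A + M;
  auto objStr = [&](int o) -> const std::string& {
    return o < A ? alpha[o] : cand[o - A];
  };
  std::vector<int> prod((size_t)NOBJ * NOBJ, -1);
  for (int i = 0; i < NOBJ; ++i) {
    for (int j = 0; j < NOBJ; ++j) {
      auto hit = id.find(objStr(i) + objStr(j));
      if (hit != id.end()) prod[(size_t)i * NOBJ + j] = hit->second;
    }
  }

  auto keyOf = [](const std::vector<unsigned char>& st) {
    return std::string(st.begin(), st.end());
  };

  std::deque<std::vector<unsigned char>> frontier;
  frontier.push_back({});
  std::unordered_set<std::string> seen;
  seen.insert(keyOf({}));

  int depth = 0;
  std::vector<int> objs;
  std::vector<char> inState(M, 0);
  while (true) {
    ++depth;
    std::deque<std::vector<unsigned char>> next;
    for (const auto& st : frontier) {
      objs.clear();
      for (int a = 0; a < A; ++a) objs.push_back(a);
      for (unsigned char v : st) {
        objs.push_back(A + v);
        inState[v] = 1;
      }
      for (int x : objs) {
        const int* row = prod.data() + (size_t)x * NOBJ;
        for (int y : objs) {
          int pid = row[y];
          if (pid < 0 || inState[pid]) continue;
          if (pid == targetId) {
            for (unsigned char v : st) inState[v] = 0;
            return depth;
          }
          std::vector<unsigned char> ns(st);
          ns.insert(std::upper_bound(ns.begin(), ns.end(),
                                     (unsigned char)pid),
                    (unsigned char)pid);
          std::string k = keyOf(ns);
          if (seen.insert(k).second) next.push_back(std::move(ns));
        }
      }
      for (unsigned char v : st) inState[v] = 0;
    }
    if (next.empty()) stop("oracle BFS exhausted without reaching target");
    frontier.swap(next);
  }
}
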