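// Asynchronous Boolean-network dynamics on a compiled model.
//
// A compiled model is a list built by g1sbn::compile_model():
//   n      : node count (<= 62)
//   regs   : list of integer vectors, 0-based regulator indices per node,
//            ordered by declared node order (bit j of the truth-table
//            index is regulator j)
//   tables : list of integer truth tables, length 2^k per node
//   clamp  : integer vector, -1 free, 0/1 clamped (inputs are clamped
//            to the root's input value before compilation)
//
// States travel as 0/1 IntegerVectors and are keyed as uint64 bit
// strings (bit i = node i) for hashing.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Model {
  int n;
  std::vector<std::vector<int>> regs;
  std::vector<std::vector<int>> tables;
  std::vector<int> clamp;
};

Model unpack(const List& cm) {
  Model m;
  m.n = as<int>(cm["n"]);
  List regs = cm["regs"], tables = cm["tables"];
  IntegerVector clamp = cm["clamp"];
  m.regs.resize(m.n);
  m.tables.resize(m.n);
  m.clamp.assign(clamp.begin(), clamp.end());
  for (int i = 0; i < m.n; ++i) {
    if (!Rf_isNull(regs[i])) {
      IntegerVector r = regs[i];
      m.regs[i].assign(r.begin(), r.end());
    }
    if (!Rf_isNull(tables[i])) {
      IntegerVector t = tables[i];
      m.tables[i].assign(t.begin(), t.end());
    }
  }
  return m;
}

inline int node_value(const Model& m, const std::vector<int>& s, int i) {
  if (m.clamp[i] >= 0) return m.clamp[i];
  size_t idx = 0;
  const std::vector<int>& r = m.regs[i];
  for (size_t j = 0; j < r.size(); ++j) idx |= ((size_t)s[r[j]]) << j;
  return m.tables[i][idx];
}

// indices of nodes whose rule value differs from the current value
inline void unstable(const Model& m, const std::vector<int>& s,
                     std::vector<int>& out) {
  out.clear();
  for (int i = 0; i < m.n; ++i) {
    if (m.clamp[i] >= 0) continue;
    if (node_value(m, s, i) != s[i]) out.push_back(i);
  }
}

inline uint64_t key_of(const std::vector<int>& s) {
  uint64_t k = 0;
  for (size_t i = 0; i < s.size(); ++i) k |= ((uint64_t)s[i]) << i;
  return k;
}

inline std::vector<int> state_of(uint64_t key, int n) {
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = (key >> i) & 1;
  return s;
}

} // namespace

// [[Rcpp::export(name = ".cpp_async_successors")]]
IntegerMatrix cpp_async_successors(List cm, IntegerVector state) {
  Model m = unpack(cm);
  std::vector<int> s(state.begin(), state.end()), u;
  unstable(m, s, u);
  IntegerMatrix out(u.size(), m.n);
  for (size_t r = 0; r < u.size(); ++r) {
    for (int i = 0; i < m.n; ++i) out(r, i) = s[i];
    out(r, u[r]) = 1 - s[u[r]];
  }
  return out;
}

// Breadth-first closure of the asynchronous dynamics from `root`.
// Returns list(states = <n_states x n matrix>, from, to (1-based
// indices into states), overflow = bool).
// [[Rcpp::export(name = ".cpp_build_stg")]]
List cpp_build_stg(List cm, IntegerVector root, double max_states) {
  Model m = unpack(cm);
  std::vector<int> s(root.begin(), root.end()), u;
  std::unordered_map<uint64_t, int> id;
  std::vector<uint64_t> keys;
  std::vector<int> from, to;
  std::queue<uint64_t> q;
  uint64_t rk = key_of(s);
  id[rk] = 0; keys.push_back(rk); q.push(rk);
  bool overflow = false;
  while (!q.empty()) {
    uint64_t k = q.front(); q.pop();
    std::vector<int> st = state_of(k, m.n);
    unstable(m, st, u);
    int src = id[k];
    for (int i : u) {
      std::vector<int> nx = st;
      nx[i] = 1 - nx[i];
      uint64_t nk = key_of(nx);
      auto it = id.find(nk);
      int dst;
      if (it == id.end()) {
        if ((double)keys.size() >= max_states) { overflow = true; goto done; }
        dst = (int)keys.size();
        id[nk] = dst; keys.push_back(nk); q.push(nk);
      } else dst = it->second;
      from.push_back(src + 1);
      to.push_back(dst + 1);
    }
  }
done:
  IntegerMatrix states(keys.size(), m.n);
  for (size_t r = 0; r < keys.size(); ++r) {
    std::vector<int> st = state_of(keys[r], m.n);
    for (int i = 0; i < m.n; ++i) states(r, i) = st[i];
  }
  return List::create(_["states"] = states,
                      _["from"] = IntegerVector(from.begin(), from.end()),
                      _["to"] = IntegerVector(to.begin(), to.end()),
                      _["overflow"] = overflow);
}

// Random walks with uniform choice among enabled asynchronous
// transitions, absorbed at fixed points.  Uses R's RNG (caller manages
// set.seed).  Walks still unabsorbed after max_steps are returned by
// the key of their final state for cycle resolution in R.
// [[Rcpp::export(name = ".cpp_monte_carlo")]]
List cpp_monte_carlo(List cm, IntegerVector root, int n_runs,
                     int max_steps) {
  Model m = unpack(cm);
  std::vector<int> start(root.begin(), root.end()), s, u;
  std::unordered_map<uint64_t, int> absorbed, unresolved;
  RNGScope scope;
  for (int run = 0; run < n_runs; ++run) {
    s = start;
    bool done = false;
    for (int step = 0; step <= max_steps; ++step) {
      unstable(m, s, u);
      if (u.empty()) {
        ++absorbed[key_of(s)];
        done = true;
        break;
      }
      int pick = (int)(unif_rand() * u.size());
      if (pick == (int)u.size()) pick = u.size() - 1;
      s[u[pick]] = 1 - s[u[pick]];
    }
    if (!done) ++unresolved[key_of(s)];
  }
  int na = absorbed.size(), nu = unresolved.size();
  IntegerMatrix astates(na, m.n);
  IntegerVector acount(na);
  int r = 0;
  for (auto& kv : absorbed) {
    std::vector<int> st = state_of(kv.first, m.n);
    for (int i = 0; i < m.n; ++i) astates(r, i) = st[i];
    acount[r] = kv.second;
    ++r;
  }
  IntegerMatrix ustates(nu, m.n);
  IntegerVector ucount(nu);
  r = 0;
  for (auto& kv : unresolved) {
    std::vector<int> st = state_of(kv.first, m.n);
    for (int i = 0; i < m.n; ++i) ustates(r, i) = st[i];
    ucount[r] = kv.second;
    ++r;
  }
  return List::create(_["absorbed_states"] = astates,
                      _["absorbed_count"] = acount,
                      _["unresolved_states"] = ustates,
                      _["unresolved_count"] = ucount);
}
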