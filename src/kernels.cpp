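// Hot loops: Metropolis-Hastings chain over connected subgraphs, connected
// induced subgraph enumeration (with exact posterior accumulation), and the
// O(n^3) connectivity-preserving peeling heuristic. Graphs arrive as 0-based
// CSR adjacency (offsets, targets); vertex index order equals the package's
// lexicographic tie-breaking order.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <functional>
using namespace Rcpp;

namespace {

// set with O(1) add/remove/contains and O(1) uniform sampling
struct IndexedSet {
  std::vector<int> items;
  std::vector<int> pos;  // pos[v] == -1 if absent
  explicit IndexedSet(int n) : pos(n, -1) {}
  bool contains(int v) const { return pos[v] >= 0; }
  int size() const { return (int)items.size(); }
  void add(int v) {
    pos[v] = (int)items.size();
    items.push_back(v);
  }
  void remove(int v) {
    int p = pos[v], last = items.back();
    items[p] = last;
    pos[last] = p;
    items.pop_back();
    pos[v] = -1;
  }
};

struct Graph {
  std::vector<int> off, tgt;
  int n;
  Graph(IntegerVector offsets, IntegerVector targets)
      : off(offsets.begin(), offsets.end()),
        tgt(targets.begin(), targets.end()),
        n((int)offsets.size() - 1) {}
  inline int deg(int v) const { return off[v + 1] - off[v]; }
};

// Chain state: member set S, frontier nei(S), per-vertex count of neighbours
// in S (for O(deg) frontier maintenance), running sum of log-weights.
struct ChainState {
  const Graph& g;
  std::vector<char> in_s;
  std::vector<int> nbr_in_s;
  IndexedSet members, frontier;
  double sum_logw = 0.0;
  const std::vector<double>& logw;
  // BFS scratch
  std::vector<int> stamp, queue;
  int cur_stamp = 0;

  ChainState(const Graph& g_, const std::vector<double>& logw_)
      : g(g_), in_s(g_.n, 0), nbr_in_s(g_.n, 0),
        members(g_.n), frontier(g_.n), logw(logw_),
        stamp(g_.n, 0), queue(g_.n) {}

  void add_vertex(int v) {
    in_s[v] = 1;
    members.add(v);
    if (frontier.contains(v)) frontier.remove(v);
    for (int i = g.off[v]; i < g.off[v + 1]; ++i) {
      int u = g.tgt[i];
      if (++nbr_in_s[u] == 1 && !in_s[u]) frontier.add(u);
    }
    sum_logw += logw[v];
  }

  void remove_vertex(int v) {
    in_s[v] = 0;
    members.remove(v);
    for (int i = g.off[v]; i < g.off[v + 1]; ++i) {
      int u = g.tgt[i];
      if (--nbr_in_s[u] == 0 && !in_s[u] && frontier.contains(u)) frontier.remove(u);
    }
    if (nbr_in_s[v] > 0) frontier.add(v);
    sum_logw -= logw[v];
  }

  bool connected() {
    int k = members.size();
    if (k <= 1) return true;
    ++cur_stamp;
    int head = 0, tail = 0;
    int start = members.items[0];
    stamp[start] = cur_stamp;
    queue[tail++] = start;
    int reached = 1;
    while (head < tail) {
      int v = queue[head++];
      for (int i = g.off[v]; i < g.off[v + 1]; ++i) {
        int u = g.tgt[i];
        if (in_s[u] && stamp[u] != cur_stamp) {
          stamp[u] = cur_stamp;
          queue[tail++] = u;
          ++reached;
        }
      }
    }
    return reached == k;
  }
};

inline int sample_int(int n) {
  // uniform on 0..n-1 via R's RNG
  int r;
  do { r = (int)(unif_rand() * n); } while (r >= n);
  return r;
}

}  // namespace

// Run the Metropolis-Hastings chain.
//  mode: 0 = fixed order (swap moves), 1 = variable order (add/remove moves)
//  record: 0 = none, 1 = every post-burn-in state, 2 = final state only
// Returns counts needed by the estimators plus an optional retained sample
// list and a log-likelihood trace (loglik = |S| log a + (a-1) sum log w).
// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(IntegerVector offsets, IntegerVector targets,
                   NumericVector logw_in, double a, int mode, double log_tau,
                   IntegerVector init_members, double n_iter, double burn_in,
                   int record, int trace_every, bool retain) {
  Graph g(offsets, targets);
  std::vector<double> logw(logw_in.begin(), logw_in.end());
  ChainState st(g, logw);
  for (int i = 0; i < init_members.size(); ++i) st.add_vertex(init_members[i]);
  if (!st.connected()) stop("initial state is not connected");

  std::vector<double> vertex_counts(g.n, 0.0);
  std::map<int, double> size_counts;
  std::map<int, std::vector<double>> vertex_size_counts;
  double n_samples = 0.0;
  std::vector<int> trace_iter;
  std::vector<double> trace_ll;
  std::vector<std::vector<int>> retained_buf;
  const double am1 = a - 1.0;
  const double log_a = std::log(a);

  auto record_state = [&]() {
    int k = st.members.size();
    n_samples += 1.0;
    size_counts[k] += 1.0;
    auto it = vertex_size_counts.find(k);
    if (it == vertex_size_counts.end())
      it = vertex_size_counts.emplace(k, std::vector<double>(g.n, 0.0)).first;
    for (int j = 0; j < k; ++j) {
      int v = st.members.items[j];
      vertex_counts[v] += 1.0;
      it->second[v] += 1.0;
    }
    if (retain) retained_buf.push_back(st.members.items);
  };

  const long long n_iter_ll = (long long)n_iter;
  const long long burn_in_ll = (long long)burn_in;
  for (long long it = 1; it <= n_iter_ll; ++it) {
    if (mode == 0) {
      // fixed order: v- uniform from S, v+ uniform from nei(S) (before removal)
      int old_nei = st.frontier.size();
      if (old_nei == 0) stop("frontier is empty: k must be < n on a connected graph");
      int v_minus = st.members.items[sample_int(st.members.size())];
      int v_plus = st.frontier.items[sample_int(old_nei)];
      double u = unif_rand();
      st.remove_vertex(v_minus);
      st.add_vertex(v_plus);
      bool ok = st.connected();
      if (ok) {
        double log_rho = am1 * (logw[v_plus] - logw[v_minus]) +
                         std::log((double)old_nei) - std::log((double)st.frontier.size());
        ok = (log_rho >= 0.0) || (std::log(u) < log_rho);
      }
      if (!ok) {
        st.remove_vertex(v_plus);
        st.add_vertex(v_minus);
      }
    } else {
      // variable order: one vertex uniform from V(S) u nei(S)
      int ns = st.members.size(), nf = st.frontier.size();
      int closed_old = ns + nf;
      int j = sample_int(closed_old);
      double u = unif_rand();
      if (j >= ns) {
        // addition of a frontier vertex
        int v_plus = st.frontier.items[j - ns];
        st.add_vertex(v_plus);
        int closed_new = st.members.size() + st.frontier.size();
        double log_rho = am1 * (logw[v_plus] - log_tau) +
                         std::log((double)closed_old) - std::log((double)closed_new);
        if (!(log_rho >= 0.0 || std::log(u) < log_rho)) st.remove_vertex(v_plus);
      } else if (ns >= 2) {
        // removal of a member (a removal from a singleton repeats the state)
        int v_minus = st.members.items[j];
        st.remove_vertex(v_minus);
        bool ok = st.connected();
        if (ok) {
          int closed_new = st.members.size() + st.frontier.size();
          double log_rho = am1 * (log_tau - logw[v_minus]) +
                           std::log((double)closed_old) - std::log((double)closed_new);
          ok = (log_rho >= 0.0) || (std::log(u) < log_rho);
        }
        if (!ok) st.add_vertex(v_minus);
      }
    }
    if (record == 1 && it > burn_in_ll) record_state();
    if (trace_every > 0 && it % trace_every == 0) {
      trace_iter.push_back((int)it);
      trace_ll.push_back(st.members.size() * log_a + am1 * st.sum_logw);
    }
    if (it % 16384 == 0) Rcpp::checkUserInterrupt();
  }
  if (record == 2) record_state();

  IntegerVector sizes(size_counts.size());
  NumericVector size_n(size_counts.size());
  int si = 0;
  for (auto& kv : size_counts) { sizes[si] = kv.first; size_n[si] = kv.second; ++si; }
  NumericMatrix vsc(g.n, (int)vertex_size_counts.size());
  int ci = 0;
  for (auto& kv : vertex_size_counts) {
    for (int v = 0; v < g.n; ++v) vsc(v, ci) = kv.second[v];
    ++ci;
  }
  IntegerVector final_members(st.members.items.begin(), st.members.items.end());
  List retained((int)retained_buf.size());
  for (int i = 0; i < (int)retained_buf.size(); ++i)
    retained[i] = IntegerVector(retained_buf[i].begin(), retained_buf[i].end());
  return List::create(
      _["n_samples"] = n_samples,
      _["vertex_counts"] = NumericVector(vertex_counts.begin(), vertex_counts.end()),
      _["sizes"] = sizes,
      _["size_counts"] = size_n,
      _["vertex_size_counts"] = vsc,
      _["final_members"] = final_members,
      _["trace_iter"] = IntegerVector(trace_iter.begin(), trace_iter.end()),
      _["trace_loglik"] = NumericVector(trace_ll.begin(), trace_ll.end()),
      _["retained"] = retained);
}

namespace {

// Enumerate every connected induced subgraph S with kmin <= |S| <= kmax
// exactly once: recursive prefix extension rooted at each vertex in turn,
// with an exclusion set so that the root is the smallest index in S and each
// branching vertex is excluded from later branches.
struct Enumerator {
  const Graph& g;
  int kmin, kmax;
  double budget;
  double emitted = 0.0;
  std::vector<char> in_s, excluded;
  std::vector<int> sub;
  std::vector<int> cmark;
  int mark_uid = 0;
  // callback(sub)
  std::function<void(const std::vector<int>&)> emit;

  Enumerator(const Graph& g_, int kmin_, int kmax_, double budget_)
      : g(g_), kmin(kmin_), kmax(kmax_), budget(budget_),
        in_s(g_.n, 0), excluded(g_.n, 0), cmark(g_.n, -1) {}

  void run() {
    for (int root = 0; root < g.n; ++root) {
      std::vector<int> cand;
      for (int i = g.off[root]; i < g.off[root + 1]; ++i) {
        int u = g.tgt[i];
        if (u > root) cand.push_back(u);
      }
      in_s[root] = 1;
      sub.push_back(root);
      maybe_emit();
      if (kmax > 1) rec(cand, root);
      sub.pop_back();
      in_s[root] = 0;
      // vertices < root stay permanently available for their own roots:
      // exclusion is scoped inside rec()
      Rcpp::checkUserInterrupt();
    }
  }

  void maybe_emit() {
    if ((int)sub.size() >= kmin) {
      if (++emitted > budget) stop("connected-subgraph enumeration exceeded its budget");
      emit(sub);
    }
  }

  void rec(const std::vector<int>& cand, int root) {
    std::vector<int> branched;
    for (int u : cand) {
      if (excluded[u]) continue;
      // child candidate set: remaining candidates plus new neighbours of u
      ++mark_uid;
      std::vector<int> child;
      child.reserve(cand.size() + g.deg(u));
      for (int w : cand) {
        if (w != u && !excluded[w]) {
          child.push_back(w);
          cmark[w] = mark_uid;
        }
      }
      for (int i = g.off[u]; i < g.off[u + 1]; ++i) {
        int w = g.tgt[i];
        if (w > root && !in_s[w] && !excluded[w] && cmark[w] != mark_uid)
          child.push_back(w);
      }
      in_s[u] = 1;
      sub.push_back(u);
      maybe_emit();
      if ((int)sub.size() < kmax) rec(child, root);
      sub.pop_back();
      in_s[u] = 0;
      excluded[u] = 1;
      branched.push_back(u);
    }
    for (int u : branched) excluded[u] = 0;
  }
};

}  // namespace

// Count connected induced subgraphs of orders kmin..kmax and return the
// maximum of the additive score sum_{v in S} svec[v] over them.
// [[Rcpp::export(name = ".enum_count_cpp")]]
List enum_count_cpp(IntegerVector offsets, IntegerVector targets,
                    NumericVector svec, int kmin, int kmax, double budget) {
  Graph g(offsets, targets);
  Enumerator en(g, kmin, kmax, budget);
  double smax = R_NegInf;
  en.emit = [&](const std::vector<int>& sub) {
    double s = 0.0;
    for (int v : sub) s += svec[v];
    if (s > smax) smax = s;
  };
  en.run();
  return List::create(_["count"] = en.emitted, _["smax"] = smax);
}

// Second pass of the exact posterior: accumulate exp(score - smax) totals,
// per-vertex sums and per-order sums; P(S) is proportional to exp(score(S)).
// [[Rcpp::export(name = ".enum_posterior_cpp")]]
List enum_posterior_cpp(IntegerVector offsets, IntegerVector targets,
                        NumericVector svec, int kmin, int kmax,
                        double budget, double smax) {
  Graph g(offsets, targets);
  Enumerator en(g, kmin, kmax, budget);
  std::vector<double> pv(g.n, 0.0);
  std::vector<double> order_tot(kmax + 1, 0.0);
  double total = 0.0;
  en.emit = [&](const std::vector<int>& sub) {
    double s = 0.0;
    for (int v : sub) s += svec[v];
    double e = std::exp(s - smax);
    total += e;
    order_tot[sub.size()] += e;
    for (int v : sub) pv[v] += e;
  };
  en.run();
  return List::create(
      _["count"] = en.emitted,
      _["total"] = total,
      _["vertex_sums"] = NumericVector(pv.begin(), pv.end()),
      _["order_sums"] = NumericVector(order_tot.begin(), order_tot.end()));
}

// Collect connected induced subgraphs of order exactly k (0-based indices).
// [[Rcpp::export(name = ".enum_collect_cpp")]]
List enum_collect_cpp(IntegerVector offsets, IntegerVector targets,
                      int k, double budget) {
  Graph g(offsets, targets);
  Enumerator en(g, k, k, budget);
  std::vector<std::vector<int>> buf;
  en.emit = [&](const std::vector<int>& sub) {
    std::vector<int> s(sub);
    std::sort(s.begin(), s.end());
    buf.push_back(std::move(s));
  };
  en.run();
  List out((int)buf.size());
  for (int i = 0; i < (int)buf.size(); ++i)
    out[i] = IntegerVector(buf[i].begin(), buf[i].end());
  return out;
}

// Connectivity-preserving peeling heuristic (O(n^3)). p1m = 1 - p per vertex.
// At each step remove the vertex whose removal-block H maximises mean(1 - p)
// (ties: smaller |H|, then smaller index); H takes the lowest remaining rank
// positions, ordered internally so that every global prefix stays connected,
// greedily preferring high-probability vertices. Returns the ranking as
// 0-based vertex indices, best first.
// [[Rcpp::export(name = ".ocpr_peel_cpp")]]
IntegerVector ocpr_peel_cpp(IntegerVector offsets, IntegerVector targets,
                            NumericVector p) {
  Graph g(offsets, targets);
  int n = g.n;
  std::vector<char> active(n, 1);
  int n_active = n;
  std::vector<int> result(n, -1);
  int r = n;  // next block fills positions ending at r (1-based)

  std::vector<int> stamp(n, 0), comp_id(n, -1), queue(n);
  int cur_stamp = 0;

  // largest connected component of active \ {v}; ties -> component containing
  // the smallest index (components are discovered in ascending start order).
  auto largest_cc_without = [&](int v, std::vector<int>& comp_out) {
    ++cur_stamp;
    int best_size = -1;
    std::vector<int> best;
    for (int s0 = 0; s0 < n; ++s0) {
      if (!active[s0] || s0 == v || stamp[s0] == cur_stamp) continue;
      int head = 0, tail = 0;
      std::vector<int> comp;
      stamp[s0] = cur_stamp;
      queue[tail++] = s0;
      while (head < tail) {
        int x = queue[head++];
        comp.push_back(x);
        for (int i = g.off[x]; i < g.off[x + 1]; ++i) {
          int u = g.tgt[i];
          if (active[u] && u != v && stamp[u] != cur_stamp) {
            stamp[u] = cur_stamp;
            queue[tail++] = u;
          }
        }
      }
      if ((int)comp.size() > best_size) {
        best_size = (int)comp.size();
        best = comp;
      }
    }
    comp_out = best;
  };

  std::vector<char> in_next(n, 0);
  while (n_active > 1) {
    int best_v = -1, best_h = -1;
    double best_score = -1.0;
    std::vector<int> comp;
    for (int v = 0; v < n; ++v) {
      if (!active[v]) continue;
      largest_cc_without(v, comp);
      int h_size = n_active - (int)comp.size();
      double s = 1.0;  // contribution of v itself: would double-count via loop below
      // mean of (1 - p) over H = active \ comp
      double sum = 0.0;
      for (int i = 0; i < n; ++i) if (active[i]) sum += 1.0 - p[i];
      for (int u : comp) sum -= 1.0 - p[u];
      s = sum / h_size;
      bool better = s > best_score + 1e-12;
      bool tie = std::fabs(s - best_score) <= 1e-12;
      if (better || (tie && h_size < best_h)) {
        best_v = v;
        best_h = h_size;
        best_score = s;
      }
    }
    largest_cc_without(best_v, comp);
    std::fill(in_next.begin(), in_next.end(), 0);
    for (int u : comp) in_next[u] = 1;
    // H = active \ comp; order it so each global prefix stays connected
    std::vector<int> h;
    for (int v = 0; v < n; ++v) if (active[v] && !in_next[v]) h.push_back(v);
    int h_size = (int)h.size();
    std::vector<char> placed(n, 0);
    for (int slot = 0; slot < h_size; ++slot) {
      int pick = -1;
      double pick_p = -1.0;
      for (int v : h) {
        if (placed[v]) continue;
        bool adjacent = false;
        for (int i = g.off[v]; i < g.off[v + 1] && !adjacent; ++i) {
          int u = g.tgt[i];
          if (in_next[u] || placed[u]) adjacent = true;
        }
        if (!adjacent) continue;
        if (p[v] > pick_p + 1e-15) { pick = v; pick_p = p[v]; }
      }
      if (pick < 0) stop("internal error: no connectable vertex in peeling block");
      placed[pick] = 1;
      result[r - h_size + slot] = pick;  // earliest slot = most confident
    }
    r -= h_size;
    for (int v : h) active[v] = 0;
    n_active -= h_size;
    Rcpp::checkUserInterrupt();
  }
  for (int v = 0; v < n; ++v) if (active[v]) result[0] = v;
  return IntegerVector(result.begin(), result.end());
}
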