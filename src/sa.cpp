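#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Simulated annealing over connected induced subgraphs, maximising the
// size-normalised score s(S) = sum(z_g, g in S) / sqrt(|S|).
//
// Moves: add a node adjacent to the current subgraph, or remove a member
// whose removal keeps the subgraph connected. Geometric cooling. All
// randomness comes from R's RNG (unif_rand), so a set.seed() in R makes the
// search exactly reproducible.

static inline double subscore(double sumz, int n) {
  return sumz / std::sqrt(static_cast<double>(n));
}

// is the current set (minus `rem`, if >= 0) connected?
static bool connected_without(const std::vector<std::vector<int> > &adj,
                              const std::vector<char> &in_set,
                              const std::vector<int> &members, int rem,
                              std::vector<int> &stack, std::vector<char> &seen) {
  int target = 0, start = -1;
  for (size_t i = 0; i < members.size(); ++i) {
    if (members[i] == rem) continue;
    ++target;
    if (start < 0) start = members[i];
  }
  if (target <= 1) return target == 1;
  std::fill(seen.begin(), seen.end(), 0);
  stack.clear();
  stack.push_back(start);
  seen[start] = 1;
  int reached = 1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    const std::vector<int> &nb = adj[v];
    for (size_t k = 0; k < nb.size(); ++k) {
      int u = nb[k];
      if (u == rem || !in_set[u] || seen[u]) continue;
      seen[u] = 1;
      ++reached;
      stack.push_back(u);
    }
  }
  return reached == target;
}

// [[Rcpp::export]]
List sa_search_cpp(List adj_list, NumericVector z, int iterations,
                   double t0, double cooling, int restarts) {
  int n = z.size();
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj_list[i];
    adj[i].assign(nb.begin(), nb.end());
  }
  std::vector<char> in_set(n), seen(n), cand_seen(n);
  std::vector<int> members, stack, addable, removable;
  double best_score = R_NegInf;
  std::vector<int> best_members;

  for (int r = 0; r < restarts; ++r) {
    std::fill(in_set.begin(), in_set.end(), 0);
    members.clear();
    int start = static_cast<int>(unif_rand() * n);
    if (start >= n) start = n - 1;
    in_set[start] = 1;
    members.push_back(start);
    double cur_sum = z[start];
    double cur_score = subscore(cur_sum, 1);
    if (cur_score > best_score) {
      best_score = cur_score;
      best_members = members;
    }
    double temp = t0;
    for (int it = 0; it < iterations; ++it, temp *= cooling) {
      // enumerate candidate moves
      addable.clear();
      std::fill(cand_seen.begin(), cand_seen.end(), 0);
      for (size_t i = 0; i < members.size(); ++i) {
        const std::vector<int> &nb = adj[members[i]];
        for (size_t k = 0; k < nb.size(); ++k) {
          int u = nb[k];
          if (!in_set[u] && !cand_seen[u]) {
            cand_seen[u] = 1;
            addable.push_back(u);
          }
        }
      }
      removable.clear();
      if (members.size() > 1) {
        for (size_t i = 0; i < members.size(); ++i) {
          if (connected_without(adj, in_set, members, members[i], stack, seen)) {
            removable.push_back(members[i]);
          }
        }
      }
      int n_moves = addable.size() + removable.size();
      if (n_moves == 0) break;  // isolated single node: nothing to do
      int pick = static_cast<int>(unif_rand() * n_moves);
      if (pick >= n_moves) pick = n_moves - 1;
      bool adding = pick < static_cast<int>(addable.size());
      int node = adding ? addable[pick] : removable[pick - addable.size()];
      double new_sum = adding ? cur_sum + z[node] : cur_sum - z[node];
      int new_n = adding ? members.size() + 1 : members.size() - 1;
      double new_score = subscore(new_sum, new_n);
      double delta = new_score - cur_score;
      if (delta >= 0 || unif_rand() < std::exp(delta / temp)) {
        if (adding) {
          in_set[node] = 1;
          members.push_back(node);
        } else {
          in_set[node] = 0;
          for (size_t i = 0; i < members.size(); ++i) {
            if (members[i] == node) {
              members[i] = members.back();
              members.pop_back();
              break;
            }
          }
        }
        cur_sum = new_sum;
        cur_score = new_score;
        if (cur_score > best_score) {
          best_score = cur_score;
          best_members = members;
        }
      }
    }
  }
  return List::create(_["members"] = IntegerVector(best_members.begin(), best_members.end()),
                      _["score"] = best_score);
}
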