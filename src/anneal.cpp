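#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// The seriation cost has two parts, both evaluated on the adjacency matrix
// written in ordering coordinates (row i = node at list position i):
//   * distance term: sum over associated pairs of |i - j|^alpha,
//   * smoothness ("bracket") term: beta * L1 difference between adjacent
//     rows and adjacent columns of the 0/1 matrix.
// By symmetry the row-difference and column-difference sums are equal, so the
// bracket term is 2 * beta * sum_i |symdiff(Nbhd_pos(i), Nbhd_pos(i+1))|,
// where Nbhd_pos(i) is the set of list positions of the partners of the node
// sitting at position i.  Everything below works on that sparse form; a swap
// of two positions only perturbs rows {p-1, p, q-1, q}, which is what makes
// the incremental delta O(local degree) instead of O(N^2).

namespace {

struct Net {
  int N;
  std::vector<std::vector<int>> adj;  // 0-based node -> node neighbours
};

Net build_net(int n_nodes, const IntegerVector& eu, const IntegerVector& ev) {
  Net net;
  net.N = n_nodes;
  net.adj.assign(n_nodes, {});
  for (int e = 0; e < eu.size(); ++e) {
    net.adj[eu[e]].push_back(ev[e]);
    net.adj[ev[e]].push_back(eu[e]);
  }
  return net;
}

// |A_{i,.} - A_{i+1,.}|_1 for rows at positions i, i+1 (0-based positions).
double row_symdiff(const Net& net, const std::vector<int>& perm,
                   const std::vector<int>& pos_of, std::vector<char>& mark,
                   int i) {
  const std::vector<int>& a = net.adj[perm[i]];
  const std::vector<int>& b = net.adj[perm[i + 1]];
  for (int x : b) mark[pos_of[x]] = 1;
  int common = 0;
  for (int x : a) common += mark[pos_of[x]];
  for (int x : b) mark[pos_of[x]] = 0;
  return static_cast<double>(a.size()) + static_cast<double>(b.size()) -
         2.0 * common;
}

std::vector<double> pow_table(int N, double alpha) {
  std::vector<double> tbl(N, 0.0);
  for (int d = 1; d < N; ++d) tbl[d] = std::pow(static_cast<double>(d), alpha);
  return tbl;
}

double full_cost(const Net& net, const std::vector<int>& perm, double alpha,
                 double beta, const std::vector<double>& dpow) {
  int N = net.N;
  std::vector<int> pos_of(N);
  for (int i = 0; i < N; ++i) pos_of[perm[i]] = i;
  double fdist = 0.0;
  for (int u = 0; u < N; ++u)
    for (int v : net.adj[u])
      if (u < v) fdist += dpow[std::abs(pos_of[u] - pos_of[v])];
  double d1 = 0.0;
  std::vector<char> mark(N, 0);
  for (int i = 0; i + 1 < N; ++i)
    d1 += row_symdiff(net, perm, pos_of, mark, i);
  return fdist + beta * 2.0 * d1;
}

// Cost contributions touched by swapping list positions p and q, evaluated
// against the *current* perm / pos_of state.
double local_cost(const Net& net, const std::vector<int>& perm,
                  const std::vector<int>& pos_of, std::vector<char>& mark,
                  int p, int q, double beta, const std::vector<double>& dpow) {
  int N = net.N;
  int u = perm[p], v = perm[q];
  double fdist = 0.0;
  for (int x : net.adj[u]) fdist += dpow[std::abs(pos_of[x] - p)];
  for (int x : net.adj[v]) fdist += dpow[std::abs(pos_of[x] - q)];
  // the (u, v) edge, if present, was added from both endpoints
  for (int x : net.adj[u])
    if (x == v) fdist -= dpow[std::abs(p - q)];
  double d1 = 0.0;
  int rows[4] = {p - 1, p, q - 1, q};
  for (int r_i = 0; r_i < 4; ++r_i) {
    int i = rows[r_i];
    if (i < 0 || i + 1 >= N) continue;
    bool dup = false;
    for (int r_j = 0; r_j < r_i; ++r_j)
      if (rows[r_j] == i) dup = true;
    if (dup) continue;
    d1 += row_symdiff(net, perm, pos_of, mark, i);
  }
  return fdist + beta * 2.0 * d1;
}

double delta_swap(const Net& net, std::vector<int>& perm,
                  std::vector<int>& pos_of, std::vector<char>& mark, int p,
                  int q, double beta, const std::vector<double>& dpow) {
  if (p == q) return 0.0;
  double before = local_cost(net, perm, pos_of, mark, p, q, beta, dpow);
  std::swap(perm[p], perm[q]);
  pos_of[perm[p]] = p;
  pos_of[perm[q]] = q;
  double after = local_cost(net, perm, pos_of, mark, p, q, beta, dpow);
  // caller decides whether to keep the swap; undo here
  std::swap(perm[p], perm[q]);
  pos_of[perm[p]] = p;
  pos_of[perm[q]] = q;
  return after - before;
}

std::vector<int> as_perm(const IntegerVector& perm0) {
  return std::vector<int>(perm0.begin(), perm0.end());
}

}  // namespace

// [[Rcpp::export]]
double cpp_cost(int n_nodes, IntegerVector edge_u, IntegerVector edge_v,
                IntegerVector perm0, double alpha, double beta) {
  Net net = build_net(n_nodes, edge_u, edge_v);
  std::vector<int> perm = as_perm(perm0);
  return full_cost(net, perm, alpha, beta, pow_table(net.N, alpha));
}

// [[Rcpp::export]]
double cpp_delta_cost(int n_nodes, IntegerVector edge_u, IntegerVector edge_v,
                      IntegerVector perm0, double alpha, double beta, int p,
                      int q) {
  Net net = build_net(n_nodes, edge_u, edge_v);
  std::vector<int> perm = as_perm(perm0);
  std::vector<int> pos_of(net.N);
  for (int i = 0; i < net.N; ++i) pos_of[perm[i]] = i;
  std::vector<char> mark(net.N, 0);
  std::vector<double> dpow = pow_table(net.N, alpha);
  return delta_swap(net, perm, pos_of, mark, p, q, beta, dpow);
}

// [[Rcpp::export]]
List cpp_anneal(int n_nodes, IntegerVector edge_u, IntegerVector edge_v,
                IntegerVector perm0, double alpha, double beta,
                double t0_frac, int halve_every, int mcs_size,
                int stop_window, double stop_accept_floor, int max_mcs) {
  Net net = build_net(n_nodes, edge_u, edge_v);
  int N = net.N;
  std::vector<int> perm = as_perm(perm0);
  std::vector<int> pos_of(N);
  for (int i = 0; i < N; ++i) pos_of[perm[i]] = i;
  std::vector<char> mark(N, 0);
  std::vector<double> dpow = pow_table(N, alpha);

  double F = full_cost(net, perm, alpha, beta, dpow);
  const double F_init = F;
  double T = t0_frac * F;
  std::vector<int> best_perm = perm;
  double F_best = F;

  std::vector<int> trace_mcs, trace_acc;
  std::vector<double> trace_T, trace_F;
  std::vector<int> window_acc;

  int mcs = 0;
  while (mcs < max_mcs) {
    ++mcs;
    int accepted = 0;
    for (int step = 0; step < mcs_size; ++step) {
      int p = static_cast<int>(unif_rand() * N);
      int q = static_cast<int>(unif_rand() * N);
      if (p >= N) p = N - 1;
      if (q >= N) q = N - 1;
      if (p == q) continue;
      double dF = delta_swap(net, perm, pos_of, mark, p, q, beta, dpow);
      bool take = dF <= 0.0;
      if (!take && T > 0.0) take = unif_rand() < std::exp(-dF / T);
      if (take) {
        std::swap(perm[p], perm[q]);
        pos_of[perm[p]] = p;
        pos_of[perm[q]] = q;
        F += dF;
        ++accepted;
        if (F < F_best) {
          F_best = F;
          best_perm = perm;
        }
      }
    }
    trace_mcs.push_back(mcs);
    trace_T.push_back(T);
    trace_F.push_back(F);
    trace_acc.push_back(accepted);
    window_acc.push_back(accepted);
    if (static_cast<int>(window_acc.size()) > stop_window)
      window_acc.erase(window_acc.begin());

    if (mcs % halve_every == 0) {
      T *= 0.5;
      // guard against incremental drift over very long runs
      F = full_cost(net, perm, alpha, beta, dpow);
    }
    if (static_cast<int>(window_acc.size()) == stop_window) {
      long tot = 0;
      for (int a : window_acc) tot += a;
      double attempts = static_cast<double>(stop_window) * mcs_size;
      if (tot < stop_accept_floor * attempts) break;
    }
    if (T < 1e-300) break;
  }

  return List::create(
      _["perm"] = IntegerVector(best_perm.begin(), best_perm.end()),
      _["f_best"] = F_best, _["f_init"] = F_init,
      _["trace"] = DataFrame::create(_["mcs"] = trace_mcs,
                                     _["temperature"] = trace_T,
                                     _["cost"] = trace_F,
                                     _["accepted"] = trace_acc));
}
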