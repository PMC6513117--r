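#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Greedy modularity optimization for a dense, possibly signed, modularity
// matrix B.  The raw objective is Q_raw = sum_{i,j : sigma_i == sigma_j} B_ij
// over all ordered pairs including the diagonal (the diagonal is constant
// across partitions).  Two move types are alternated until neither improves:
//   * local moves: reassign one node to the community with the largest gain
//     (including a fresh singleton community), random sweep order, ties broken
//     by lowest community index;
//   * merges: join the pair of communities with the largest positive
//     between-block sum.
// Merge-stability at convergence guarantees every between-block sum <= 0,
// which is the sign-contrast property of the returned partition.

namespace {

double q_raw(const NumericMatrix& B, const std::vector<int>& lab) {
  int n = B.nrow();
  double q = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (lab[i] == lab[j]) q += B(i, j);
  return q;
}

// One full pass of local moves; returns true if any node moved.
bool local_sweep(const NumericMatrix& B, std::vector<int>& lab,
                 std::vector<int>& size, std::mt19937& rng, double tol) {
  int n = B.nrow();
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), rng);

  bool moved = false;
  std::vector<double> S(n, 0.0);   // community sums for current node
  for (int oi = 0; oi < n; ++oi) {
    int i = order[oi];
    int cur = lab[i];
    std::fill(S.begin(), S.end(), 0.0);
    for (int j = 0; j < n; ++j)
      if (j != i) S[lab[j]] += B(i, j);

    // candidate: best existing community (lowest index wins ties)
    int best = cur;
    double best_gain = 0.0;
    for (int c = 0; c < n; ++c) {
      if (size[c] == 0 || c == cur) continue;
      double gain = 2.0 * (S[c] - S[cur]);
      if (gain > best_gain + tol) { best = c; best_gain = gain; }
    }
    // candidate: isolate into a fresh singleton community
    if (size[cur] > 1) {
      double gain = 2.0 * (0.0 - S[cur]);
      if (gain > best_gain + tol) {
        int empty = -1;
        for (int c = 0; c < n; ++c) if (size[c] == 0) { empty = c; break; }
        best = empty;
        best_gain = gain;
      }
    }
    if (best != cur && best_gain > tol) {
      size[cur]--; size[best]++;
      lab[i] = best;
      moved = true;
    }
  }
  return moved;
}

// Merge the community pair with the largest positive between-block sum,
// repeatedly; returns true if any merge happened.
bool merge_pass(const NumericMatrix& B, std::vector<int>& lab,
                std::vector<int>& size, double tol) {
  int n = B.nrow();
  bool merged_any = false;
  for (;;) {
    // active community ids
    std::vector<int> comms;
    for (int c = 0; c < n; ++c) if (size[c] > 0) comms.push_back(c);
    int k = comms.size();
    if (k < 2) break;
    std::vector<int> pos(n, -1);
    for (int a = 0; a < k; ++a) pos[comms[a]] = a;
    // between-block sums E[a][b] = sum_{i in a, j in b} B_ij (a != b)
    std::vector<double> E(k * k, 0.0);
    for (int i = 0; i < n; ++i) {
      int a = pos[lab[i]];
      for (int j = 0; j < n; ++j) {
        int b = pos[lab[j]];
        if (a != b) E[a * k + b] += B(i, j);
      }
    }
    double best = tol;
    int ba = -1, bb = -1;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b) {
        double gain = E[a * k + b] + E[b * k + a];  // == 2 * sum over the block
        if (gain > best) { best = gain; ba = a; bb = b; }
      }
    if (ba < 0) break;
    int keep = comms[ba], drop = comms[bb];
    for (int i = 0; i < n; ++i) if (lab[i] == drop) lab[i] = keep;
    size[keep] += size[drop];
    size[drop] = 0;
    merged_any = true;
  }
  return merged_any;
}

}  // namespace

// [[Rcpp::export]]
List louvain_dense(NumericMatrix B, int n_restarts, int seed, double tol) {
  int n = B.nrow();
  if (B.ncol() != n) stop("modularity matrix must be square");
  if (n_restarts < 1) stop("n_restarts must be >= 1");

  std::vector<int> best_lab;
  double best_q = -std::numeric_limits<double>::infinity();

  for (int r = 0; r < n_restarts; ++r) {
    std::mt19937 rng(static_cast<unsigned>(seed) + 7919u * static_cast<unsigned>(r));
    std::vector<int> lab(n), size(n, 1);
    for (int i = 0; i < n; ++i) lab[i] = i;

    for (int guard = 0; guard < 10000; ++guard) {
      bool moved = false;
      // local moves to convergence
      for (int s = 0; s < 10000; ++s) {
        if (!local_sweep(B, lab, size, rng, tol)) break;
        moved = true;
      }
      bool merged = merge_pass(B, lab, size, tol);
      if (!moved && !merged) break;
      if (!merged) break;  // local moves converged and no merge available
    }

    double q = q_raw(B, lab);
    if (q > best_q + tol) {
      best_q = q;
      best_lab = lab;
    }
  }

  // relabel contiguously by order of first occurrence
  IntegerVector out(n);
  std::vector<int> map(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int c = best_lab[i];
    if (map[c] == 0) map[c] = ++next;
    out[i] = map[c];
  }
  return List::create(_["labels"] = out,
                      _["q_raw"] = best_q,
                      _["n_modules"] = next);
}
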