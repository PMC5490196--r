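#include <Rcpp.h>
using namespace Rcpp;

// Viterbi decoding specialised to the shifting-level transition structure
// A_i[j][k] = (1 - eta_i) * 1[j == k] + eta_i * pi_k.
//
// Because every jump lands on state k with the same probability eta_i * pi_k
// regardless of origin, the maximisation over predecessors reduces to
// comparing the "stay" candidate (j == k) with the best-scoring other state,
// giving an O(N*K) recursion instead of O(N*K^2).
//
// emis:     N x K matrix of log emission densities log N(x_i; level_k, s2e)
// logprior: length-K log initial state distribution
// log_stay: (N-1) x K, log((1 - eta_i) + eta_i * pi_k) for step i
// log_jump: (N-1) x K, log(eta_i * pi_k) for step i
//
// Ties are broken toward the lower level index: the returned path is the
// smallest optimal path in reverse-lexicographic order (last state first),
// which is what a backtrace with smallest-index argmax at every step yields.

// [[Rcpp::export]]
IntegerVector viterbi_path_structured(NumericMatrix emis,
                                      NumericVector logprior,
                                      NumericMatrix log_stay,
                                      NumericMatrix log_jump) {
  const int n = emis.nrow();
  const int K = emis.ncol();
  if (logprior.size() != K)
    stop("logprior length must equal ncol(emis)");
  if (n > 1 && (log_stay.nrow() != n - 1 || log_jump.nrow() != n - 1 ||
                log_stay.ncol() != K || log_jump.ncol() != K))
    stop("transition matrices must be (N-1) x K");

  IntegerVector path(n);
  if (n == 0) return path;

  std::vector<double> V(K), newV(K);
  for (int k = 0; k < K; ++k) V[k] = logprior[k] + emis(0, k);

  IntegerMatrix ptr(n, K);
  for (int i = 1; i < n; ++i) {
    // top two of V, smallest index wins ties
    int i1 = 0;
    for (int j = 1; j < K; ++j) if (V[j] > V[i1]) i1 = j;
    const double M1 = V[i1];
    int i2 = -1;
    double M2 = -std::numeric_limits<double>::infinity();
    for (int j = 0; j < K; ++j) {
      if (j == i1) continue;
      if (V[j] > M2) { M2 = V[j]; i2 = j; }
    }
    for (int k = 0; k < K; ++k) {
      const double stay = V[k] + log_stay(i - 1, k);
      int jo; double jv;
      if (i1 != k) { jo = i1; jv = M1; } else { jo = i2; jv = M2; }
      double jump = (jo >= 0)
        ? jv + log_jump(i - 1, k)
        : -std::numeric_limits<double>::infinity();
      double best; int pred;
      if (stay > jump)      { best = stay; pred = k; }
      else if (jump > stay) { best = jump; pred = jo; }
      else                  { best = stay; pred = (jo >= 0 && jo < k) ? jo : k; }
      newV[k] = best + emis(i, k);
      ptr(i, k) = pred;
    }
    std::swap(V, newV);
  }

  int last = 0;
  for (int k = 1; k < K; ++k) if (V[k] > V[last]) last = k;
  path[n - 1] = last;
  for (int i = n - 1; i > 0; --i) path[i - 1] = ptr(i, path[i]);
  for (int i = 0; i < n; ++i) path[i] += 1;  // 1-based level indices
  return path;
}
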