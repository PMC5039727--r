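#include <Rcpp.h>
using namespace Rcpp;

// Round-robin mean payoffs for a kin-mode population.
//
// `pop` columns, in order: offer_kin, demand_kin, offer_other, demand_other,
// tag, threshold. Every ordered pair (i, j), i != j, plays one game with i as
// proposer. Each side picks its branch from its OWN classification of the
// partner (strict |tag_i - tag_j| < threshold_i). An offer is accepted when
// offer >= demand; acceptance splits the unit resource, rejection pays zero.
// The score is the mean payoff over the 2(N-1) games an agent takes part in.

// [[Rcpp::export]]
NumericVector cpp_kin_scores(const NumericMatrix& pop) {
  const int N = pop.nrow();
  NumericVector score(N);
  std::vector<double> off(static_cast<size_t>(N) * N);
  std::vector<double> dem(static_cast<size_t>(N) * N);
  for (int i = 0; i < N; ++i) {
    const double tag_i = pop(i, 4), thr_i = pop(i, 5);
    for (int j = 0; j < N; ++j) {
      const bool kin = std::fabs(tag_i - pop(j, 4)) < thr_i;
      off[static_cast<size_t>(i) * N + j] = kin ? pop(i, 0) : pop(i, 2);
      dem[static_cast<size_t>(i) * N + j] = kin ? pop(i, 1) : pop(i, 3);
    }
  }
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < N; ++j) {
      if (i == j) continue;
      const double o = off[static_cast<size_t>(i) * N + j];
      // responder j's demand comes from j's classification of i
      if (o >= dem[static_cast<size_t>(j) * N + i]) {
        score[i] += 1.0 - o;
        score[j] += o;
      }
    }
  }
  const double games = 2.0 * (N - 1);
  for (int i = 0; i < N; ++i) score[i] /= games;
  return score;
}

// Same round-robin for a baseline population; `pop` columns: offer, demand.

// [[Rcpp::export]]
NumericVector cpp_baseline_scores(const NumericMatrix& pop) {
  const int N = pop.nrow();
  NumericVector score(N);
  for (int i = 0; i < N; ++i) {
    const double o = pop(i, 0);
    for (int j = 0; j < N; ++j) {
      if (i == j) continue;
      if (o >= pop(j, 1)) {
        score[i] += 1.0 - o;
        score[j] += o;
      }
    }
  }
  const double games = 2.0 * (N - 1);
  for (int i = 0; i < N; ++i) score[i] /= games;
  return score;
}
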