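# Independent reference implementations used as test oracles. These stay
# deliberately naive (double loops, grid search) and separate from the code
# paths they check.

# plain-R round-robin mean payoffs, both modes
oracle_scores <- function(pop) {
  mode <- ugevolve::ug_mode(pop)
  m <- as.matrix(as.data.frame(pop)[, if (mode == "kin") {
    c("offer_kin", "demand_kin", "offer_other", "demand_other",
      "tag", "threshold")
  } else {
    c("offer", "demand")
  }])
  n <- nrow(m)
  s <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (mode == "kin") {
        kin_ij <- abs(m[i, 5] - m[j, 5]) < m[i, 6]
        kin_ji <- abs(m[j, 5] - m[i, 5]) < m[j, 6]
        o <- if (kin_ij) m[i, 1] else m[i, 3]
        d <- if (kin_ji) m[j, 2] else m[j, 4]
      } else {
        o <- m[i, 1]
        d <- m[j, 2]
      }
      if (o >= d) {
        s[i] <- s[i] + (1 - o)
        s[j] <- s[j] + o
      }
    }
  }
  s / (2 * (n - 1))
}

# brute-force ESS verdict from the four role games, baseline strategies
oracle_ess_baseline <- function(res, inv) {
  pay <- function(x, y) {
    # x's mean payoff over both ordered games against y
    p1 <- if (x[1] >= y[2]) 1 - x[1] else 0
    p2 <- if (y[1] >= x[2]) y[1] else 0
    (p1 + p2) / 2
  }
  e_rr <- pay(res, res); e_ir <- pay(inv, res)
  if (e_rr > e_ir) return("stable")
  if (e_rr < e_ir) return("unstable")
  e_ri <- pay(res, inv); e_ii <- pay(inv, inv)
  if (e_ri > e_ii) return("stable")
  if (e_ri < e_ii) return("unstable")
  "neutral"
}

logistic_f <- function(x, k, X0) 1 / (1 + exp(-k * (x - X0)))

# Riemann-grid quadrature + bisection for the demand threshold
oracle_demand_threshold <- function(k, X0, grid_n = 200001) {
  x <- seq(0, 1, length.out = grid_n)
  fx <- logistic_f(x, k, X0)
  h <- x[2] - x[1]
  cum <- c(0, cumsum((fx[-1] + fx[-length(fx)]) / 2 * h))
  half <- cum[length(cum)] / 2
  i <- findInterval(half, cum)
  # linear interpolation inside the bracketing cell
  x[i] + (half - cum[i]) / (cum[i + 1] - cum[i]) * h
}

# exhaustive grid search for the payoff-maximising offer
oracle_optimal_offer <- function(k, X0, step = 1e-4) {
  o <- seq(0, 1, by = step)
  o[which.max((1 - o) * logistic_f(o, k, X0))]
}

random_kin_genome <- function() {
  v <- runif(6)
  ugevolve::ug_genome("kin", offer_kin = v[1], demand_kin = v[2],
                      offer_other = v[3], demand_other = v[4],
                      tag = v[5], threshold = v[6])
}

random_baseline_genome <- function() {
  v <- runif(2)
  ugevolve::ug_genome("baseline", offer = v[1], demand = v[2])
}

random_population <- function(n, mode = "kin") {
  gen <- if (mode == "kin") random_kin_genome else random_baseline_genome
  dplyr::bind_rows(lapply(seq_len(n), function(i) gen()))
}
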