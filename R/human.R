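#' Logistic acceptance curve
#'
#' The probability that an offer is accepted is modelled as
#' `f(offer) = 1 / (1 + exp(-k * (offer - X0)))` with slope `k > 0` and
#' midpoint `X0`: monotone increasing in the offer with `f(X0) = 0.5`.
#'
#' @param k Slope of the logistic (> 0).
#' @param X0 Midpoint offer, in `[0, 1]`.
#' @param residual_sum_of_squares Optional fit diagnostic (>= 0).
#' @param data Optional acceptance dataset the curve was fitted to.
#' @return An object of class `ug_logistic`.
#' @examples
#' fit <- logistic_acceptance(k = 15.52, X0 = 0.21)
#' acceptance_curve(fit, 0.21)  # 0.5 at the midpoint
#' @export
logistic_acceptance <- function(k, X0, residual_sum_of_squares = NA_real_,
                                data = NULL) {
  stopifnot(is.numeric(k), length(k) == 1, is.finite(k), k > 0)
  check_fraction(X0, "X0")
  structure(
    list(k = k, X0 = X0,
         residual_sum_of_squares = residual_sum_of_squares,
         data = data),
    class = "ug_logistic"
  )
}

#' @export
print.ug_logistic <- function(x, ...) {
  cat(sprintf("<ug_logistic> k = %.4g, X0 = %.4g", x$k, x$X0))
  if (is.finite(x$residual_sum_of_squares)) {
    cat(sprintf(", RSS = %.4g", x$residual_sum_of_squares))
  }
  cat("\n")
  invisible(x)
}

#' @describeIn logistic_acceptance Parameter table in broom style.
#' @param x An `ug_logistic`.
#' @param ... Unused.
#' @method tidy ug_logistic
#' @export
tidy.ug_logistic <- function(x, ...) {
  tibble::tibble(term = c("k", "X0"), estimate = c(x$k, x$X0))
}

#' @describeIn logistic_acceptance One-row model summary: parameters, RSS,
#'   the offer-independent demand threshold, and the payoff-optimal offer.
#' @method glance ug_logistic
#' @export
glance.ug_logistic <- function(x, ...) {
  tibble::tibble(
    k = x$k, X0 = x$X0,
    residual_sum_of_squares = x$residual_sum_of_squares,
    demand = demand_threshold(x),
    optimal_offer = optimal_offer(x)
  )
}

#' Evaluate the acceptance curve
#'
#' @param fit An `ug_logistic`.
#' @param offer Offers in `[0, 1]` (vectorised).
#' @return Acceptance probabilities in `(0, 1)`.
#' @export
acceptance_curve <- function(fit, offer) {
  stopifnot(inherits(fit, "ug_logistic"))
  check_fraction(offer, "offer")
  1 / (1 + exp(-fit$k * (offer - fit$X0)))
}

#' Simulate an acceptance-rate dataset from a known logistic curve
#'
#' Emulates a binned acceptance-rate table of the kind reported by
#' behavioural Ultimatum Game studies: for each offer bin, the number of
#' acceptances is drawn from a binomial with probability given by the
#' logistic curve. The default bins cover the empirically informative range
#' of offers (0.05 to 0.50 in steps of 0.05), where real studies concentrate
#' their observations.
#'
#' @param k,X0 Generating logistic parameters.
#' @param bins Offer bins in `[0, 1]`.
#' @param n_per_bin Responders observed per bin (>= 1).
#' @return A tibble with columns `offer_bin`, `n_accepted`, `n_total`.
#' @export
simulate_acceptance_data <- function(k, X0, bins = seq(0.05, 0.5, by = 0.05),
                                     n_per_bin = 100) {
  check_fraction(bins, "bins")
  stopifnot(n_per_bin >= 1)
  fit <- logistic_acceptance(k, X0)
  p <- acceptance_curve(fit, bins)
  tibble::tibble(
    offer_bin = bins,
    n_accepted = rbinom(length(bins), size = n_per_bin, prob = p),
    n_total = as.integer(n_per_bin)
  )
}

#' Read an acceptance dataset from delimited text
#'
#' Comma-separated with a header; either rate form (`offer_bin`,
#' `acceptance_rate`) or count form (`offer_bin`, `n_accepted`, `n_total`).
#'
#' @param path File path.
#' @return A validated tibble in the form found in the file.
#' @export
read_acceptance_data <- function(path) {
  validate_acceptance_data(readr::read_csv(path, show_col_types = FALSE))
}

validate_acceptance_data <- function(data) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  if (!"offer_bin" %in% names(data)) {
    stop("acceptance data needs an `offer_bin` column", call. = FALSE)
  }
  check_fraction(data$offer_bin, "offer_bin")
  if ("acceptance_rate" %in% names(data)) {
    check_fraction(data$acceptance_rate, "acceptance_rate")
  } else if (all(c("n_accepted", "n_total") %in% names(data))) {
    stopifnot(all(data$n_total >= 1), all(data$n_accepted >= 0),
              all(data$n_accepted <= data$n_total))
  } else {
    stop("acceptance data needs `acceptance_rate` or `n_accepted`/`n_total`",
         call. = FALSE)
  }
  data
}

#' Fit the logistic acceptance curve to an acceptance dataset
#'
#' Nonlinear least squares of acceptance rate on offer. Because offers above
#' half the resource are nearly always accepted but rarely observed, the fit
#' by default augments the data with synthetic rate-1.0 points on a grid of
#' high offers before fitting. Count-form data are weighted by `n_total`
#' (augmentation points receive the median weight); rate-form data are fitted
#' unweighted. Starts at `k = 10`, `X0 = mean(offer)` and falls back on a
#' coarse multi-start grid if that fails to converge.
#'
#' @param data Acceptance dataset: tibble with `offer_bin` and either
#'   `acceptance_rate` or `n_accepted`/`n_total`.
#' @param augment_above Offers above this value are taken as always
#'   accepted; augmentation points are placed above it.
#' @param augment_bins High-offer grid receiving synthetic rate-1.0 points
#'   (filtered to values `> augment_above`). Set `augment = FALSE` to
#'   disable.
#' @param augment Whether to add the synthetic saturation points.
#' @return An `ug_logistic` with the fitted `(k, X0)` and residual sum of
#'   squares; the (augmented) fitting data are kept in `$data`.
#' @export
fit_acceptance_curve <- function(data, augment_above = 0.5,
                                 augment_bins = seq(0.6, 1, by = 0.1),
                                 augment = TRUE) {
  data <- validate_acceptance_data(data)
  count_form <- "n_total" %in% names(data)
  pts <- if (count_form) {
    tibble::tibble(offer = data$offer_bin,
                   rate = data$n_accepted / data$n_total,
                   weight = as.numeric(data$n_total))
  } else {
    tibble::tibble(offer = data$offer_bin, rate = data$acceptance_rate,
                   weight = 1)
  }
  if (augment) {
    check_fraction(augment_above, "augment_above")
    high <- augment_bins[augment_bins > augment_above]
    if (length(high) > 0) {
      w_aug <- if (count_form) stats::median(pts$weight) else 1
      pts <- dplyr::bind_rows(
        pts, tibble::tibble(offer = high, rate = 1, weight = w_aug))
    }
  }
  if (dplyr::n_distinct(pts$offer) < 3) {
    stop("need at least 3 distinct offer bins to fit", call. = FALSE)
  }
  if (dplyr::n_distinct(pts$rate) < 2) {
    stop("degenerate data: all acceptance rates equal", call. = FALSE)
  }
  grid <- expand.grid(k = c(1, 5, 20, 50), X0 = c(0.2, 0.5, 0.8))
  starts <- c(list(list(k = 10, X0 = mean(pts$offer))),
              lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, ])))
  fit <- NULL
  failures <- character(0)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rate ~ 1 / (1 + exp(-k * (offer - X0))),
        data = pts, start = st, weights = pts$weight,
        lower = c(k = 1e-6, X0 = -1), upper = c(k = 1e4, X0 = 2),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) {
        failures <<- c(failures, conditionMessage(e))
        NULL
      }
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("acceptance-curve fit failed to converge; attempts reported: ",
         paste(unique(failures), collapse = "; "), call. = FALSE)
  }
  est <- stats::coef(fit)
  logistic_acceptance(
    k = unname(est["k"]),
    X0 = min(max(unname(est["X0"]), 0), 1),
    residual_sum_of_squares = sum(stats::resid(fit)^2),
    data = pts
  )
}

#' Offer-independent demand threshold
#'
#' The single demand implied by an acceptance curve, measured independently
#' of the offer distribution: the offer `d` below which half of the
#' accepted-offer mass lies when offers are uniform on `[0, 1]`, i.e. the
#' solution of `integral(f, 0, d) = integral(f, 0, 1) / 2`. Solved by
#' numerical quadrature plus bisection to `|delta d| <= 1e-6`.
#'
#' @param fit An `ug_logistic`.
#' @return The demand threshold, a fraction in `(0, 1)`.
#' @examples
#' demand_threshold(logistic_acceptance(15.52, 0.21))  # ~0.61
#' @export
demand_threshold <- function(fit) {
  stopifnot(inherits(fit, "ug_logistic"))
  f <- function(x) acceptance_curve(fit, x)
  half <- integrate(f, 0, 1, rel.tol = 1e-10)$value / 2
  uniroot(function(d) integrate(f, 0, d, rel.tol = 1e-10)$value - half,
          interval = c(0, 1), tol = 1e-8)$root
}

#' Expected proposer payoff at a given offer
#'
#' The proposer's retained share times the probability the offer is
#' accepted: `(1 - offer) * f(offer)`.
#'
#' @param fit An `ug_logistic`.
#' @param offer Offers in `[0, 1]` (vectorised).
#' @return Expected payoffs in `[0, 1]`.
#' @export
expected_payoff <- function(fit, offer) {
  (1 - offer) * acceptance_curve(fit, offer)
}

#' Payoff-maximising offer
#'
#' The offer in `[0, 1]` maximising [expected_payoff()], found by golden
#' -section search over a bracket of sub-intervals (plus the endpoints), and
#' accurate to better than 1e-4.
#'
#' @param fit An `ug_logistic`.
#' @return The maximising offer.
#' @export
optimal_offer <- function(fit) {
  stopifnot(inherits(fit, "ug_logistic"))
  obj <- function(o) expected_payoff(fit, o)
  cuts <- seq(0, 1, length.out = 33)
  cand <- purrr::map_dbl(seq_len(length(cuts) - 1), function(i) {
    optimize(obj, interval = c(cuts[i], cuts[i + 1]),
             maximum = TRUE, tol = 1e-9)$maximum
  })
  cand <- c(cand, 0, 1)
  cand[which.max(obj(cand))]
}

#' Label a strategy vector on the three behavioural dimensions
#'
#' A strategy `(offer, demand)` is *generous* when it offers appreciably
#' more than the minimal positive amount, *demanding* when it rejects
#' anything up to half the resource (`demand > 0.5`), and *unfair* when it
#' offers less than it demands (`offer < demand`).
#'
#' @param offer,demand Strategy fractions in `[0, 1]` (vectorised).
#' @param epsilon Generosity margin above a vanishing offer.
#' @return A tibble with the inputs and logical columns `generous`,
#'   `demanding`, `unfair`.
#' @examples
#' classify_strategy(0.4, 0.61)  # generous, demanding, unfair
#' @export
classify_strategy <- function(offer, demand, epsilon = 0.01) {
  check_fraction(offer, "offer")
  check_fraction(demand, "demand")
  tibble::tibble(
    offer = offer, demand = demand,
    generous = offer > epsilon,
    demanding = demand > 0.5,
    unfair = offer < demand
  )
}

#' Tabulate the expected-payoff curve of a fitted acceptance model
#'
#' @param fit An `ug_logistic`.
#' @param offers Offer grid.
#' @return A tibble with columns `offer`, `acceptance`, `expected_payoff`.
#' @export
payoff_curve <- function(fit, offers = seq(0, 1, by = 0.01)) {
  tibble::tibble(
    offer = offers,
    acceptance = acceptance_curve(fit, offers),
    expected_payoff = expected_payoff(fit, offers)
  )
}
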