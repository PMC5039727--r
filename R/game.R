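#' Construct a strategy genome
#'
#' A genome is a one-row tibble of heritable loci. Baseline genomes carry a
#' single unconditional `(offer, demand)` pair. Kin-mode genomes carry two
#' branches -- `(offer_kin, demand_kin)` played against partners classified as
#' kin and `(offer_other, demand_other)` against everyone else -- plus a `tag`
#' and a recognition `threshold` on the unit interval.
#'
#' @param mode `"baseline"` or `"kin"`.
#' @param offer,demand Baseline loci (fractions of the unit resource).
#' @param offer_kin,demand_kin,offer_other,demand_other Kin-mode branch loci.
#' @param tag,threshold Kin-mode recognition loci.
#' @return A one-row tibble with the loci of the requested mode.
#' @examples
#' ug_genome("baseline", offer = 0.4, demand = 0.1)
#' ug_genome("kin", offer_kin = 0.05, demand_kin = 0.05,
#'           offer_other = 0.4, demand_other = 0.6, tag = 0.5, threshold = 0.1)
#' @export
ug_genome <- function(mode = c("baseline", "kin"), offer = NULL, demand = NULL,
                      offer_kin = NULL, demand_kin = NULL,
                      offer_other = NULL, demand_other = NULL,
                      tag = NULL, threshold = NULL) {
  mode <- match.arg(mode)
  if (mode == "baseline") {
    vals <- list(offer = offer, demand = demand)
  } else {
    vals <- list(offer_kin = offer_kin, demand_kin = demand_kin,
                 offer_other = offer_other, demand_other = demand_other,
                 tag = tag, threshold = threshold)
  }
  missing <- names(vals)[vapply(vals, is.null, logical(1))]
  if (length(missing) > 0) {
    stop(mode, " genomes need loci: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(vals)) check_fraction(vals[[nm]], nm)
  tibble::as_tibble(vals)
}

#' One-sided kin classification
#'
#' An observer treats another agent as kin when the distance between their
#' tags is strictly smaller than the observer's own recognition threshold.
#' The judgement is one-sided: the other party, applying its own threshold,
#' may classify differently.
#'
#' @param observer_tag,other_tag Tags in `[0, 1]`.
#' @param observer_threshold Recognition threshold in `[0, 1]`.
#' @return Logical vector, `TRUE` where the observer classifies the other as
#'   kin. Arguments are recycled to a common length.
#' @examples
#' classify_kin(0.5, 0.3, 0.7)  # TRUE:  |0.5 - 0.7| < 0.3
#' classify_kin(0.7, 0.1, 0.5)  # FALSE: |0.7 - 0.5| >= 0.1
#' @export
classify_kin <- function(observer_tag, observer_threshold, other_tag) {
  check_fraction(observer_tag, "observer_tag")
  check_fraction(observer_threshold, "observer_threshold")
  check_fraction(other_tag, "other_tag")
  abs(observer_tag - other_tag) < observer_threshold
}

#' Play one Ultimatum Game
#'
#' The proposer offers a fraction of the unit resource; the responder accepts
#' when the offer meets its demand (`offer >= demand`, ties accept). On
#' acceptance the resource is split `(1 - offer, offer)`; on rejection both
#' sides receive nothing.
#'
#' @param proposer_offer,responder_demand Fractions in `[0, 1]`; recycled to a
#'   common length.
#' @return A tibble with columns `accepted`, `payoff_proposer`,
#'   `payoff_responder`, one row per game.
#' @examples
#' play_game(0.4, 0.6)  # rejected: both get 0
#' play_game(0.5, 0.5)  # accepted at the tie: (0.5, 0.5)
#' @export
play_game <- function(proposer_offer, responder_demand) {
  check_fraction(proposer_offer, "proposer_offer")
  check_fraction(responder_demand, "responder_demand")
  accepted <- proposer_offer >= responder_demand
  tibble::tibble(
    accepted = accepted,
    payoff_proposer = ifelse(accepted, 1 - proposer_offer, 0),
    payoff_responder = ifelse(accepted, proposer_offer, 0)
  )
}

#' Strategy branch an agent plays against a given partner
#'
#' Baseline agents always play their single `(offer, demand)` pair. A
#' kin-mode agent classifies the partner with its own tag and threshold and
#' plays its kin branch on a kin verdict, its other branch otherwise. Both
#' the offer it would make as proposer and the demand it would apply as
#' responder come from that same, own-side classification.
#'
#' @param self,other One-row genome tibbles (see [ug_genome()]) of the same
#'   mode.
#' @return A one-row tibble with columns `offer` and `demand`: the pair
#'   `self` plays against `other`.
#' @export
effective_strategy <- function(self, other) {
  mode_s <- ug_mode(self)
  if (mode_s != ug_mode(other)) {
    stop("genomes must share the same mode", call. = FALSE)
  }
  stopifnot(nrow(self) == 1, nrow(other) == 1)
  if (mode_s == "baseline") {
    return(tibble::tibble(offer = self$offer, demand = self$demand))
  }
  kin <- classify_kin(self$tag, self$threshold, other$tag)
  tibble::tibble(
    offer = if (kin) self$offer_kin else self$offer_other,
    demand = if (kin) self$demand_kin else self$demand_other
  )
}

#' Round-robin mean payoffs
#'
#' Every ordered pair of distinct agents plays exactly one game with the
#' first as proposer, so each agent proposes to and responds to every other
#' agent exactly once. Kin-mode agents choose branches per
#' [effective_strategy()], each side using its own classification. The score
#' is the mean payoff per game played and therefore lies in `[0, 1]`.
#'
#' @param population A tibble of genomes, one row per agent (at least 2).
#' @return The input tibble with a `score` column appended.
#' @examples
#' pop <- dplyr::bind_rows(
#'   ug_genome("baseline", offer = 0.4, demand = 0.1),
#'   ug_genome("baseline", offer = 0.2, demand = 0.3)
#' )
#' pairwise_payoffs(pop)$score  # 0.4, 0.6
#' @export
pairwise_payoffs <- function(population) {
  mode <- ug_mode(population)
  m <- pop_matrix(population, mode)
  if (nrow(m) < 2) {
    stop("population must contain at least 2 agents", call. = FALSE)
  }
  score <- if (mode == "kin") cpp_kin_scores(m) else cpp_baseline_scores(m)
  dplyr::mutate(tibble::as_tibble(population), score = as.numeric(score))
}

#' Expected payoff of one strategy against another
#'
#' `E(x, y)`: the mean payoff `x` receives over the two ordered role games
#' against `y` (once as proposer, once as responder), with kin classification
#' applied by each side as in [effective_strategy()].
#'
#' @param x,y One-row genome tibbles of the same mode.
#' @return A single number in `[0, 1]`.
#' @export
expected_game_payoff <- function(x, y) {
  ex <- effective_strategy(x, y)
  ey <- effective_strategy(y, x)
  as_proposer <- play_game(ex$offer, ey$demand)$payoff_proposer
  as_responder <- play_game(ey$offer, ex$demand)$payoff_responder
  (as_proposer + as_responder) / 2
}

#' Evolutionary stability of a resident strategy against an invader
#'
#' A resident is stable when it earns more against itself than the invader
#' earns against it: `E(resident, resident) > E(invader, resident)`. On a
#' tie, the classical second condition applies: stable if
#' `E(resident, invader) > E(invader, invader)`, neutral if that also ties;
#' unstable otherwise.
#'
#' @param resident,invader One-row genome tibbles of the same mode.
#' @return `"stable"`, `"neutral"`, or `"unstable"`.
#' @examples
#' nash <- ug_genome("baseline", offer = 0, demand = 0)
#' human <- ug_genome("baseline", offer = 0.4, demand = 0.6)
#' ess_status(nash, human)  # "stable"
#' @export
ess_status <- function(resident, invader) {
  e_rr <- expected_game_payoff(resident, resident)
  e_ir <- expected_game_payoff(invader, resident)
  if (e_rr > e_ir) return("stable")
  if (e_rr < e_ir) return("unstable")
  e_ri <- expected_game_payoff(resident, invader)
  e_ii <- expected_game_payoff(invader, invader)
  if (e_ri > e_ii) return("stable")
  if (e_ri < e_ii) return("unstable")
  "neutral"
}
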