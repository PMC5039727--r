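#' Configuration for an evolutionary run
#'
#' Defaults follow the study conditions of the simulator: population size
#' 100, per-site mutation rate 0.01 with uniform redraw, 200 replicates.
#' Selection strength `w` scales how strongly payoff differences translate
#' into reproduction; `w = 0` is neutral drift.
#'
#' @param population_size Number of agents per generation (>= 2).
#' @param mutation_rate Per-locus probability of a uniform redraw in `[0, 1]`.
#' @param selection_strength Non-negative selection strength `w`.
#' @param generations Number of Wright-Fisher generations.
#' @param mode `"kin"` (six loci) or `"baseline"` (two loci).
#' @param replicates Default replicate count for sweeps.
#' @param selection_scheme `"exponential"` fecundity `exp(w * score)`
#'   (default) or `"linear"` fecundity `1 - w + w * score` (requires
#'   `w <= 1`).
#' @return A list of class `ug_config`.
#' @export
ug_config <- function(population_size = 100, mutation_rate = 0.01,
                      selection_strength = 1, generations = 100000,
                      mode = c("kin", "baseline"), replicates = 200,
                      selection_scheme = c("exponential", "linear")) {
  mode <- match.arg(mode)
  selection_scheme <- match.arg(selection_scheme)
  stopifnot(
    population_size >= 2, population_size == as.integer(population_size),
    mutation_rate >= 0, mutation_rate <= 1,
    selection_strength >= 0,
    generations >= 1, generations == as.integer(generations),
    replicates >= 1
  )
  if (selection_scheme == "linear" && selection_strength > 1) {
    stop("linear fecundity needs selection_strength <= 1", call. = FALSE)
  }
  structure(
    list(population_size = as.integer(population_size),
         mutation_rate = mutation_rate,
         selection_strength = selection_strength,
         generations = as.integer(generations),
         mode = mode,
         replicates = as.integer(replicates),
         selection_scheme = selection_scheme),
    class = "ug_config"
  )
}

#' @export
print.ug_config <- function(x, ...) {
  cat("<ug_config> mode:", x$mode,
      " N:", x$population_size,
      " mu:", x$mutation_rate,
      " w:", x$selection_strength,
      " generations:", x$generations,
      " replicates:", x$replicates,
      " scheme:", x$selection_scheme, "\n")
  invisible(x)
}

#' Draw a random founding population
#'
#' Every heritable locus is drawn independently from the uniform distribution
#' on `[0, 1]`; baseline genomes carry 2 loci, kin genomes 6. Uses the
#' current RNG state, so wrap in [withr::with_seed()] or call [set.seed()]
#' for reproducibility.
#'
#' @param config An [ug_config()].
#' @return A tibble of genomes with `population_size` rows.
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "ug_config"))
  loci <- loci_for_mode(config$mode)
  n <- config$population_size
  m <- matrix(runif(n * length(loci)), nrow = n)
  pop_tibble(m, config$mode)
}

#' Selection probabilities from payoff scores
#'
#' Exponential fecundity (default) assigns each agent reproduction
#' probability `exp(w * score_i) / sum_j exp(w * score_j)`; probabilities are
#' strictly positive, sum to one, are invariant to adding a constant to every
#' score, and reduce to uniform at `w = 0` (including the all-zero-payoff
#' population). The linear scheme uses fecundity `1 - w + w * score`.
#'
#' @param scores Numeric vector of finite payoff scores.
#' @param w Non-negative selection strength (`<= 1` for the linear scheme).
#' @param scheme `"exponential"` or `"linear"`.
#' @return Numeric vector of selection probabilities summing to 1.
#' @examples
#' fecundity_weights(c(1, 0.5), w = 1)  # 0.6225, 0.3775
#' @export
fecundity_weights <- function(scores, w,
                              scheme = c("exponential", "linear")) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(scores), all(is.finite(scores)), w >= 0)
  if (scheme == "exponential") {
    f <- exp(w * (scores - max(scores)))  # shift for numerical safety
  } else {
    if (w > 1) stop("linear fecundity needs w <= 1", call. = FALSE)
    f <- 1 - w + w * scores
  }
  f / sum(f)
}

#' Mutate a population (or a single genome) per locus
#'
#' Each heritable locus independently, with probability `mutation_rate`, is
#' replaced by a fresh uniform draw on `[0, 1]`; otherwise it is copied
#' exactly. In kin mode the tag and recognition threshold mutate at the same
#' per-site rate as the strategy loci.
#'
#' @param population A tibble of genomes.
#' @param mutation_rate Per-locus mutation probability.
#' @return A tibble of the same shape with mutated loci.
#' @export
mutate_population <- function(population, mutation_rate) {
  check_fraction(mutation_rate, "mutation_rate")
  mode <- ug_mode(population)
  m <- pop_matrix(population, mode)
  hit <- which(runif(length(m)) < mutation_rate)
  m[hit] <- runif(length(hit))
  pop_tibble(m, mode)
}

# internal fast path: matrix population in kernel column order
step_matrix <- function(m, config) {
  score <- if (config$mode == "kin") cpp_kin_scores(m) else cpp_baseline_scores(m)
  p <- fecundity_weights(score, config$selection_strength,
                         config$selection_scheme)
  n <- nrow(m)
  parents <- sample.int(n, n, replace = TRUE, prob = p)
  off <- m[parents, , drop = FALSE]
  hit <- which(runif(length(off)) < config$mutation_rate)
  off[hit] <- runif(length(hit))
  list(pop = off, parents = parents, scores = as.numeric(score))
}

#' Advance one Wright-Fisher generation
#'
#' Computes round-robin payoffs, converts them to selection probabilities
#' with [fecundity_weights()], samples `population_size` parents with
#' replacement, and produces one mutated offspring per parent (full
#' generational replacement).
#'
#' @param population A tibble of genomes.
#' @param config An [ug_config()] whose mode matches the population.
#' @return A list with elements `population` (offspring tibble), `parents`
#'   (integer vector: `parents[i]` is the row of the parent of offspring
#'   `i`), and `scores` (the parent generation's payoff scores).
#' @export
step_generation <- function(population, config) {
  stopifnot(inherits(config, "ug_config"))
  mode <- ug_mode(population)
  if (mode != config$mode) {
    stop("population mode (", mode, ") does not match config mode (",
         config$mode, ")", call. = FALSE)
  }
  res <- step_matrix(pop_matrix(population, mode), config)
  list(population = pop_tibble(res$pop, mode),
       parents = res$parents,
       scores = res$scores)
}

#' Run one seeded evolutionary replicate
#'
#' Starts from a random founding population and advances `generations`
#' Wright-Fisher steps, recording the full ancestry (parent indices and
#' genome snapshots) needed for line-of-descent reconstruction, plus
#' per-generation population means of every locus and of the payoff score.
#' The trajectory is a deterministic function of `(config, seed)`.
#'
#' @param config An [ug_config()].
#' @param seed Integer seed for this replicate.
#' @return An object of class `ug_run`: a list with `config`, `seed`,
#'   `population` (final tibble), `parents` (`generations x N` integer
#'   matrix; row `g` maps individuals of generation `g` to their parents in
#'   generation `g - 1`), `history` (list of `generations + 1` locus
#'   matrices), and `summary` (tibble of per-generation means).
#' @export
run_replicate <- function(config, seed) {
  stopifnot(inherits(config, "ug_config"))
  withr::with_seed(as.integer(seed), {
    n <- config$population_size
    gens <- config$generations
    loci <- loci_for_mode(config$mode)
    m <- matrix(runif(n * length(loci)), nrow = n)
    history <- vector("list", gens + 1)
    history[[1]] <- m
    parents <- matrix(0L, nrow = gens, ncol = n)
    means <- matrix(0, nrow = gens + 1, ncol = length(loci) + 1)
    for (g in seq_len(gens)) {
      res <- step_matrix(m, config)
      means[g, ] <- c(colMeans(m), mean(res$scores))
      m <- res$pop
      history[[g + 1]] <- m
      parents[g, ] <- res$parents
    }
    final_scores <- if (config$mode == "kin") cpp_kin_scores(m) else cpp_baseline_scores(m)
    means[gens + 1, ] <- c(colMeans(m), mean(final_scores))
    summary <- tibble::as_tibble(as.data.frame(means))
    names(summary) <- c(loci, "mean_score")
    summary <- dplyr::mutate(summary, generation = 0:gens, .before = 1)
    structure(
      list(config = config, seed = as.integer(seed),
           population = pop_tibble(m, config$mode),
           parents = parents, history = history, summary = summary),
      class = "ug_run"
    )
  })
}

#' @export
print.ug_run <- function(x, ...) {
  cfg <- x$config
  cat("<ug_run> mode:", cfg$mode, " N:", cfg$population_size,
      " w:", cfg$selection_strength, " generations:", cfg$generations,
      " seed:", x$seed, "\n")
  final <- dplyr::slice_tail(x$summary, n = 1)
  cat("final population means:\n")
  print(final, n = 1)
  invisible(x)
}

#' @describeIn run_replicate Per-generation population means as a tibble.
#' @param x An `ug_run`.
#' @param ... Unused.
#' @method tidy ug_run
#' @export
tidy.ug_run <- function(x, ...) {
  x$summary
}

#' @describeIn run_replicate One-row overview of the run.
#' @method glance ug_run
#' @export
glance.ug_run <- function(x, ...) {
  cfg <- x$config
  final <- dplyr::select(dplyr::slice_tail(x$summary, n = 1), -"generation")
  dplyr::bind_cols(
    tibble::tibble(mode = cfg$mode, population_size = cfg$population_size,
                   mutation_rate = cfg$mutation_rate,
                   selection_strength = cfg$selection_strength,
                   generations = cfg$generations, seed = x$seed),
    dplyr::rename_with(final, ~ paste0("final_", .x))
  )
}
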