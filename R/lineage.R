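#' Reconstruct the line of descent of a final individual
#'
#' Follows parent pointers backwards from one individual of the final
#' generation to the founding generation and returns the forward-ordered
#' chain of ancestor genomes: one genome per generation, `generations + 1`
#' rows in all. Before the coalescence generation the chain is the same
#' whichever final individual is chosen, so the anchor is picked uniformly
#' at random (from the current RNG state) when not supplied.
#'
#' @param run An `ug_run` from [run_replicate()].
#' @param final_index Row of the final-generation individual to anchor the
#'   lineage at; defaults to a uniform random choice.
#' @return A tibble of class `ug_lod` with a `generation` column (0-based)
#'   and one column per locus; attributes `mode`, `final_index`, and
#'   `coalescence` (see [coalescence_generation()]).
#' @export
reconstruct_lod <- function(run, final_index = NULL) {
  stopifnot(inherits(run, "ug_run"))
  n <- run$config$population_size
  gens <- run$config$generations
  if (is.null(final_index)) {
    final_index <- sample.int(n, 1)
  }
  final_index <- as.integer(final_index)
  if (final_index < 1 || final_index > n) {
    stop("final_index must be in 1..", n, call. = FALSE)
  }
  path <- integer(gens + 1)
  idx <- final_index
  for (g in rev(seq_len(gens))) {
    path[g + 1] <- idx
    idx <- run$parents[g, idx]
    if (is.na(idx) || idx < 1 || idx > n) {
      stop("corrupted ancestry: dangling parent index at generation ", g,
           call. = FALSE)
    }
  }
  path[1] <- idx
  loci <- loci_for_mode(run$config$mode)
  m <- matrix(0, nrow = gens + 1, ncol = length(loci))
  for (g in seq_len(gens + 1)) {
    m[g, ] <- run$history[[g]][path[g], ]
  }
  out <- pop_tibble(m, run$config$mode)
  out <- dplyr::mutate(out, generation = 0:gens, .before = 1)
  structure(out, class = c("ug_lod", class(out)),
            mode = run$config$mode, final_index = final_index,
            coalescence = coalescence_generation(run))
}

#' Coalescence generation of a run's ancestry
#'
#' The latest generation `g` at which all final-generation individuals trace
#' back to a single common ancestor. Lines of descent anchored at any two
#' final individuals are identical up to (and including) this generation.
#' Returns 0 when the final generation only coalesces in the founding draw.
#'
#' @param run An `ug_run`, or a bare `generations x N` parent-index matrix.
#' @return A single integer in `[0, generations]`.
#' @export
coalescence_generation <- function(run) {
  parents <- if (inherits(run, "ug_run")) run$parents else run
  stopifnot(is.matrix(parents))
  n <- ncol(parents)
  anc <- seq_len(n)
  for (g in rev(seq_len(nrow(parents)))) {
    anc <- unique(parents[g, anc])
    if (length(anc) == 1) return(g - 1L)
  }
  0L
}

#' Summarise a line of descent
#'
#' Per-locus arithmetic means over the post-burn-in part of the lineage.
#' The default performs plain averaging over the whole chain; scaled-down
#' runs conventionally discard the first quarter as burn-in to reduce the
#' imprint of the random founding population.
#'
#' @param lod An `ug_lod` from [reconstruct_lod()] (or any data frame with a
#'   `generation` column and locus columns).
#' @param burn_in_fraction Fraction of leading generations to discard, in
#'   `[0, 1)`.
#' @return A one-row tibble with one mean per locus plus `burn_in_fraction`,
#'   `n_generations` (rows averaged), and `coalescence` (NA when unknown).
#' @export
summarize_lod <- function(lod, burn_in_fraction = 0) {
  stopifnot(is.data.frame(lod), "generation" %in% names(lod))
  if (!is.numeric(burn_in_fraction) || burn_in_fraction < 0 ||
      burn_in_fraction >= 1) {
    stop("burn_in_fraction must lie in [0, 1)", call. = FALSE)
  }
  total <- nrow(lod)
  keep <- lod[(floor(burn_in_fraction * total) + 1):total, , drop = FALSE]
  if (nrow(keep) == 0) stop("empty post-burn-in window", call. = FALSE)
  loci <- setdiff(names(keep), "generation")
  means <- dplyr::summarise(keep, dplyr::across(dplyr::all_of(loci), mean))
  coal <- attr(lod, "coalescence")
  dplyr::mutate(means,
                burn_in_fraction = burn_in_fraction,
                n_generations = nrow(keep),
                coalescence = if (is.null(coal)) NA_integer_ else coal)
}

#' Histogram of evolved kin-recognition thresholds
#'
#' Pools recognition-threshold values -- from a numeric vector, a kin-mode
#' line of descent, or a list of them -- into a fixed-bin histogram on
#' `[0, 1]`.
#'
#' @param x Numeric vector of thresholds, an `ug_lod`, or a list of
#'   `ug_lod`s/data frames with a `threshold` column.
#' @param bins Number of equal-width bins on `[0, 1]` (default 20), or a
#'   numeric vector of bin edges.
#' @return A tibble with columns `lower`, `upper`, `midpoint`, `count`.
#' @export
threshold_distribution <- function(x, bins = 20) {
  values <- pooled_thresholds(x)
  check_fraction(values, "threshold values")
  edges <- if (length(bins) == 1) seq(0, 1, length.out = bins + 1) else sort(bins)
  # right-closed bins (lower, upper], first bin closed on both sides
  counts <- graphics::hist(values, breaks = edges, right = TRUE,
                           include.lowest = TRUE, plot = FALSE)$counts
  tibble::tibble(
    lower = edges[-length(edges)],
    upper = edges[-1],
    midpoint = (edges[-length(edges)] + edges[-1]) / 2,
    count = counts
  )
}

pooled_thresholds <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.data.frame(x)) x <- list(x)
  if (!is.list(x)) stop("cannot extract thresholds from this input",
                        call. = FALSE)
  purrr::map(x, function(d) {
    if (!is.data.frame(d) || !"threshold" %in% names(d)) {
      stop("threshold distributions need kin-mode input ",
           "(a `threshold` column); baseline lineages carry none",
           call. = FALSE)
    }
    d$threshold
  }) |> unlist(use.names = FALSE)
}

#' Write / read a line-of-descent table
#'
#' One comma-separated file per replicate: a `generation` column followed by
#' one column per locus (`offer_kin`, `demand_kin`, `offer_other`,
#' `demand_other`, `tag`, `threshold` in kin mode; `offer`, `demand` in
#' baseline mode).
#'
#' @param lod An `ug_lod` (or compatible data frame).
#' @param path File path.
#' @return `write_lod()` returns `lod` invisibly; `read_lod()` returns an
#'   `ug_lod` tibble.
#' @export
write_lod <- function(lod, path) {
  stopifnot(is.data.frame(lod), "generation" %in% names(lod))
  readr::write_csv(as.data.frame(lod), path)
  invisible(lod)
}

#' @rdname write_lod
#' @export
read_lod <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  mode <- ug_mode(out)
  if (!"generation" %in% names(out)) {
    stop("not a LOD table: missing `generation` column", call. = FALSE)
  }
  structure(out, class = c("ug_lod", class(out)), mode = mode)
}
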