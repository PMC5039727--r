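#' Run a selection-strength sweep with replicate management
#'
#' For every combination of mode and selection strength `w`, runs the
#' requested number of independently seeded replicates, reconstructs and
#' summarises each line of descent, writes one LOD table per replicate plus
#' an aggregate summary table, and returns the aggregate. The sweep is
#' resumable: replicates whose LOD file already exists on disk are read back
#' and summarised instead of re-run, and the per-replicate seeds are a fixed
#' function of the master seed and the (mode, w, replicate) slot, so a rerun
#' with the same arguments reproduces the same summary byte for byte.
#'
#' @param w_values Selection strengths to sweep (default the four anchors
#'   0.01, 0.1, 1, 10).
#' @param modes Subset of `c("baseline", "kin")`.
#' @param config Base [ug_config()]; its `selection_strength` and `mode` are
#'   overridden per condition.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param replicates Replicates per condition (default `config$replicates`).
#' @param burn_in_fraction Burn-in used when summarising each LOD.
#' @return A `RunSummary` tibble in long form: one row per (mode, w, locus)
#'   with the grand mean across replicate-level LOD means, its standard
#'   error, and the replicate count. The per-replicate summaries are
#'   attached as attribute `"replicates"`.
#' @export
run_sweep <- function(w_values = c(0.01, 0.1, 1, 10),
                      modes = c("baseline", "kin"),
                      config = ug_config(),
                      out_dir,
                      seed = 1,
                      replicates = config$replicates,
                      burn_in_fraction = 0) {
  stopifnot(length(w_values) > 0, all(w_values >= 0))
  modes <- match.arg(modes, c("baseline", "kin"), several.ok = TRUE)
  stopifnot(inherits(config, "ug_config"), replicates >= 2)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }

  slots <- tidyr::expand_grid(mode = modes, w = w_values,
                              replicate = seq_len(replicates))
  drawn <- derive_seeds(seed, 2 * nrow(slots))
  slots$seed <- drawn[seq_len(nrow(slots))]
  slots$anchor_seed <- drawn[nrow(slots) + seq_len(nrow(slots))]
  log_lines <- c(
    paste0("ugevolve ", as.character(packageVersion("ugevolve"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("master_seed: ", seed),
    paste0("population_size: ", config$population_size),
    paste0("mutation_rate: ", config$mutation_rate),
    paste0("generations: ", config$generations),
    paste0("selection_scheme: ", config$selection_scheme),
    paste0("burn_in_fraction: ", burn_in_fraction),
    paste0("replicates: ", replicates),
    paste0("modes: ", paste(modes, collapse = ",")),
    paste0("w_values: ", paste(w_values, collapse = ","))
  )
  writeLines(log_lines, file.path(out_dir, "sweep.log"))

  per_rep <- purrr::pmap(slots, function(mode, w, replicate, seed,
                                         anchor_seed) {
    path <- file.path(out_dir, lod_filename(mode, w, replicate))
    lod <- if (file.exists(path)) {
      tryCatch(read_lod(path), error = function(e) {
        stop("corrupted partial output at ", path, ": ",
             conditionMessage(e), call. = FALSE)
      })
    } else {
      cfg <- config
      cfg$mode <- mode
      cfg$selection_strength <- w
      run <- run_replicate(cfg, seed)
      lod <- withr::with_seed(anchor_seed, reconstruct_lod(run))
      write_lod(lod, path)
      lod
    }
    # coalescence is dropped: it is unknown for replicates resumed from
    # disk, and keeping it would make resumed summaries differ
    s <- dplyr::select(summarize_lod(lod, burn_in_fraction), -"coalescence")
    dplyr::mutate(s, mode = mode, w = w, replicate = replicate,
                  .before = 1)
  }) |> purrr::list_rbind()

  summary <- aggregate_summary(per_rep)
  readr::write_csv(summary, file.path(out_dir, "summary.csv"))
  attr(summary, "replicates") <- per_rep
  summary
}

lod_filename <- function(mode, w, replicate) {
  sprintf("lod_%s_w%s_rep%03d.csv", mode, format(w, trim = TRUE), replicate)
}

# fixed, order-independent seed derivation: one substream draw per slot
derive_seeds <- function(master, n) {
  withr::with_seed(as.integer(master),
                   sample.int(.Machine$integer.max, n))
}

#' Aggregate replicate-level LOD summaries
#'
#' Grand means across replicates and their standard errors (sample standard
#' deviation of the replicate-level LOD means divided by the square root of
#' the replicate count), per condition and locus.
#'
#' @param replicate_summaries Tibble with columns `mode`, `w`, `replicate`,
#'   and one column per locus mean (as produced inside [run_sweep()]).
#' @return Long-form tibble with columns `mode`, `w`, `locus`, `mean`, `se`,
#'   `n_replicates`.
#' @export
aggregate_summary <- function(replicate_summaries) {
  stopifnot(is.data.frame(replicate_summaries),
            all(c("mode", "w", "replicate") %in% names(replicate_summaries)))
  loci <- intersect(names(replicate_summaries), c(KIN_LOCI, BASELINE_LOCI))
  long <- tidyr::pivot_longer(
    replicate_summaries,
    cols = dplyr::all_of(loci),
    names_to = "locus", values_to = "value"
  )
  long <- dplyr::filter(long, !is.na(.data$value))
  out <- long |>
    dplyr::group_by(.data$mode, .data$w, .data$locus) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = sd(.data$value) / sqrt(dplyr::n()),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n_replicates < 2)) {
    stop("standard errors need at least 2 replicates per condition",
         call. = FALSE)
  }
  stopifnot(!anyNA(out$mean), !anyNA(out$se))
  out
}
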