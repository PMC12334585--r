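#' Run configuration
#'
#' All stage parameters in one serialisable list, with the documented
#' defaults: POI minimum of 10 check-ins, 10-minute interval filter, 5 AM
#' day boundary, minimum merged length 2, and selection fractions 0.1%
#' (high-order) / 0.5% (low-order). Round-trips losslessly through a YAML
#' file via [read_run_config()] / [write_run_config()].
#'
#' @param min_poi_checkins,min_interval_minutes,boundary_hour,min_length
#'   preprocessing parameters.
#' @param f_high,f_low selection threshold fractions.
#' @param default_policy unmapped-category policy.
#' @param seed integer seed used by simulation subcommands.
#' @return list with class `run_config`.
#' @export
run_config <- function(min_poi_checkins = 10L, min_interval_minutes = 10,
                       boundary_hour = 5L, min_length = 2L,
                       f_high = 0.001, f_low = 0.005,
                       default_policy = "drop", seed = 1L) {
  structure(
    list(min_poi_checkins = as.integer(min_poi_checkins),
         min_interval_minutes = as.numeric(min_interval_minutes),
         boundary_hour = as.integer(boundary_hour),
         min_length = as.integer(min_length),
         f_high = as.numeric(f_high), f_low = as.numeric(f_low),
         default_policy = default_policy, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the whole motif-mining pipeline
#'
#' Chains preprocessing, counting (fast path), dual-threshold selection,
#' metrics and the distribution-table exports on a raw check-in table.
#'
#' @param records raw check-in tibble ([read_checkins()] or
#'   [generate_checkins()]).
#' @param map category map tibble.
#' @param config a [run_config()].
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @param quiet suppress stage messages.
#' @return list with `sequences`, `occ` (occurrence table), `thresholds`,
#'   `motifs`, `report`, `tables`.
#' @export
run_pipeline <- function(records, map = read_category_map(),
                         config = run_config(), out_dir = NULL,
                         quiet = FALSE) {
  seqs <- preprocess_checkins(
    records, map,
    min_poi_checkins = config$min_poi_checkins,
    min_interval_minutes = config$min_interval_minutes,
    boundary_hour = config$boundary_hour,
    min_length = config$min_length,
    default_policy = config$default_policy,
    quiet = quiet
  )
  occ <- fast_count(seqs)
  thresholds <- compute_thresholds(
    occ$n_sequences_total, c(f_high = config$f_high, f_low = config$f_low))
  motifs <- select_motifs(occ, thresholds)
  if (!quiet) {
    message(nrow(occ$table), " candidate structures; ", nrow(motifs),
            " motifs at thresholds ", thresholds$low_order, " (low-order) / ",
            thresholds$high_order, " (high-order)")
  }
  report <- if (nrow(motifs) > 0L) metrics_report(motifs, occ) else NULL
  tables <- export_distribution_tables(motifs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sequences(seqs, file.path(out_dir, "sequences.csv"))
    write_occurrences(occ, file.path(out_dir, "occurrences.csv"))
    readr::write_csv(motifs, file.path(out_dir, "motifs.csv"),
                     progress = FALSE)
    if (!is.null(report)) {
      write_metrics_report(report, file.path(out_dir, "metrics.json"))
    }
    export_distribution_tables(motifs, file.path(out_dir, "tables"))
  }
  list(sequences = seqs, occ = occ, thresholds = thresholds,
       motifs = motifs, report = report, tables = tables)
}
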