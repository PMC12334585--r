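#' Export distribution tables for the selected motifs
#'
#' Produces the three analysis tables, as data (rendering is left to the
#' caller):
#'
#' * `two_node`: for every 2-node topology among the motifs, a 7 x 7
#'   integer matrix of occurrence counts keyed by (type of node A, type of
#'   node B), with row and column marginal vectors.
#' * `three_node`: for every 3-node topology, one record per motif keyed by
#'   the types at labels A, B, C with its occurrence count.
#' * `co_occurrence`: the two-edge non-sequential motifs keyed by
#'   (transition 1, transition 2), with the bridging mode (type at the end
#'   of the earlier process, type at the start of the later one) as block
#'   labels — the full bridging-mode space has 7 x 7 = 49 blocks.
#'
#' Marginals are exact row/column sums of the exported matrices, and the
#' export is a pure function of (motif set, occurrence table).
#'
#' @param motifs motif tibble from [select_motifs()] (or any subset of an
#'   occurrence table's rows).
#' @param dir optional directory; when given, every table is also written
#'   as CSV.
#' @return list with elements `two_node` (named list of
#'   matrix/row_marginal/col_marginal), `three_node` (tibble),
#'   `co_occurrence` (tibble), invisibly returned after writing when `dir`
#'   is given.
#' @export
export_distribution_tables <- function(motifs, dir = NULL) {
  codes <- unname(activity_codes())
  two_node <- list()
  for (tp in unique(motifs$topology[motifs$n_nodes == 2L])) {
    sub <- motifs[motifs$topology == tp, ]
    mat <- matrix(0L, 7L, 7L, dimnames = list(codes, codes))
    for (i in seq_len(nrow(sub))) {
      lt <- pattern_label_types(sub$pattern[i])
      mat[lt[["A"]], lt[["B"]]] <- mat[lt[["A"]], lt[["B"]]] + sub$count[i]
    }
    two_node[[tp]] <- list(matrix = mat,
                           row_marginal = rowSums(mat),
                           col_marginal = colSums(mat))
  }
  three <- motifs[motifs$n_nodes == 3L, ]
  three_node <- if (nrow(three) > 0L) {
    lab <- t(vapply(three$pattern, function(p) {
      lt <- pattern_label_types(p)
      c(lt[["A"]], lt[["B"]], lt[["C"]])
    }, character(3L)))
    tibble::tibble(topology = three$topology, pattern = three$pattern,
                   type_A = lab[, 1L], type_B = lab[, 2L],
                   type_C = lab[, 3L], count = three$count)
  } else {
    tibble::tibble(topology = character(), pattern = character(),
                   type_A = character(), type_B = character(),
                   type_C = character(), count = integer())
  }
  ns2 <- motifs[!motifs$sequential & motifs$n_edges == 2L, ]
  co_occurrence <- if (nrow(ns2) > 0L) {
    parts <- strsplit(ns2$pattern, ",", fixed = TRUE)
    e1 <- vapply(parts, `[`, "", 1L)
    e2 <- vapply(parts, `[`, "", 2L)
    tibble::tibble(
      topology = ns2$topology,
      transition_1 = e1,
      transition_2 = e2,
      bridge_from = substr(e1, 3L, 3L),  # end of the earlier process
      bridge_to = substr(e2, 1L, 1L),    # start of the later process
      count = ns2$count
    )
  } else {
    tibble::tibble(topology = character(), transition_1 = character(),
                   transition_2 = character(), bridge_from = character(),
                   bridge_to = character(), count = integer())
  }
  out <- list(two_node = two_node, three_node = three_node,
              co_occurrence = co_occurrence)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (tp in names(two_node)) {
      mat <- two_node[[tp]]$matrix
      df <- as.data.frame(mat)
      df <- cbind(type_A = rownames(mat), df)
      readr::write_csv(tibble::as_tibble(df),
                       file.path(dir, paste0("two_node_", tp, ".csv")),
                       progress = FALSE)
    }
    readr::write_csv(three_node, file.path(dir, "three_node.csv"),
                     progress = FALSE)
    readr::write_csv(co_occurrence, file.path(dir, "co_occurrence.csv"),
                     progress = FALSE)
    return(invisible(out))
  }
  out
}

#' Standard metrics report
#'
#' Computes the per-group MCR values used in the analysis (Line; Ring +
#' Chain; sequential high-order, i.e. three or more edges; two-edge
#' non-sequential; three-edge non-sequential) over the SELECTED motifs,
#' plus a COR breakdown of each topology by the type at label A. Groups
#' with no motifs are omitted.
#'
#' @param motifs motif tibble from [select_motifs()].
#' @param occ the `occurrence_table` the motifs came from (with
#'   membership).
#' @return list with `mcr` (named list of [mcr()] results) and
#'   `cor_by_central_type` (tibble topology/type/value).
#' @export
metrics_report <- function(motifs, occ) {
  groups <- list(
    Line = motifs$pattern[motifs$topology == "Line"],
    Ring_Chain = motifs$pattern[motifs$topology %in% c("Ring", "Chain")],
    sequential_high_order =
      motifs$pattern[motifs$sequential & motifs$n_edges >= 3L],
    nonseq_two_edge =
      motifs$pattern[!motifs$sequential & motifs$n_edges == 2L],
    nonseq_three_edge =
      motifs$pattern[!motifs$sequential & motifs$n_edges == 3L]
  )
  groups <- groups[lengths(groups) > 0L]
  mcr_res <- lapply(groups, mcr, occ = occ)
  rows <- list()
  for (tp in unique(motifs$topology)) {
    scope <- motifs$pattern[motifs$topology == tp]
    for (cd in unname(activity_codes())) {
      target <- patterns_with_label_type(scope, "A", cd)
      if (length(target) == 0L) next
      res <- cor_ratio(target, scope, occ)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        topology = tp, type_A = cd, value = res$value,
        numerator = res$numerator, denominator = res$denominator)
    }
  }
  list(
    mcr = mcr_res,
    cor_by_central_type = if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(topology = character(), type_A = character(),
                     value = double(), numerator = integer(),
                     denominator = integer())
  )
}

#' Write a metrics report as JSON
#'
#' @param report list from [metrics_report()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  out <- list(
    mcr = report$mcr,
    cor_by_central_type = report$cor_by_central_type
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
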