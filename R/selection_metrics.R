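#' Dual frequency thresholds for motif selection
#'
#' Sequence lengths in check-in corpora are heavily imbalanced: only a
#' minority of daily sequences are long enough to contain high-order
#' patterns, so a single support threshold would drown them out. Two
#' thresholds are therefore derived from the corpus size: the low-order
#' threshold (`f_low`, default 0.5%) applies to sequential patterns with at
#' most two edges, the high-order threshold (`f_high`, default 0.1%)
#' applies to sequential patterns with three or more edges and to all
#' non-sequential patterns. Both are floored to integers; with the
#' reference corpus of 80,118 sequences the defaults give 400 and 80.
#'
#' @param n_total total number of daily sequences (> 0).
#' @param fractions named or positional pair `c(f_high, f_low)`, each in
#'   (0, 1).
#' @return list with integer `low_order`, `high_order` and the inputs.
#' @examples
#' compute_thresholds(80118)
#' @export
compute_thresholds <- function(n_total, fractions = c(f_high = 0.001,
                                                      f_low = 0.005)) {
  if (!is.numeric(n_total) || length(n_total) != 1L || n_total <= 0) {
    stop("n_total must be a positive count", call. = FALSE)
  }
  stopifnot(length(fractions) == 2L, all(fractions > 0), all(fractions < 1))
  f_high <- unname(fractions[1L])
  f_low <- unname(fractions[2L])
  list(
    low_order = max(1L, as.integer(floor(f_low * n_total))),
    high_order = max(1L, as.integer(floor(f_high * n_total))),
    f_high = f_high,
    f_low = f_low,
    n_total = as.integer(n_total)
  )
}

threshold_class <- function(tbl) {
  ifelse(tbl$sequential & tbl$n_edges <= 2L, "low_order", "high_order")
}

#' Select motifs from an occurrence table
#'
#' A pattern becomes a motif when its occurrence count reaches its class
#' threshold (count >= threshold): low-order sequential patterns (one or
#' two edges) are judged against the low-order threshold, everything else
#' against the high-order threshold. When the occurrence table carries
#' per-sequence membership, a per-topology summary with topology occurrence
#' (number of distinct sequences containing at least one motif of the
#' topology) is attached as attribute `topology_summary`.
#'
#' @param occ an `occurrence_table` from [fast_count()].
#' @param thresholds list from [compute_thresholds()]; defaults to the
#'   standard fractions applied to the table's own corpus size.
#' @return tibble of motifs (occurrence-table columns plus
#'   `threshold_class` and `threshold`), with attributes `thresholds` and
#'   (if membership is available) `topology_summary`.
#' @export
select_motifs <- function(occ, thresholds = NULL) {
  if (is.null(thresholds)) {
    thresholds <- compute_thresholds(occ$n_sequences_total)
  }
  tbl <- occ$table
  cls <- threshold_class(tbl)
  thr <- ifelse(cls == "low_order", thresholds$low_order,
                thresholds$high_order)
  motifs <- tbl[tbl$count >= thr, ]
  motifs$threshold_class <- cls[tbl$count >= thr]
  motifs$threshold <- as.integer(thr[tbl$count >= thr])
  attr(motifs, "thresholds") <- thresholds
  if (!is.null(occ$membership) && nrow(motifs) > 0L) {
    topo_occ <- vapply(unique(motifs$topology), function(tp) {
      members <- motifs$pattern[motifs$topology == tp]
      sum(vapply(occ$membership, function(s) any(members %in% s), TRUE))
    }, 0L)
    attr(motifs, "topology_summary") <- tibble::tibble(
      topology = names(topo_occ),
      n_motifs = as.integer(table(motifs$topology)[names(topo_occ)]),
      topology_occurrence = unname(topo_occ)
    )
  }
  motifs
}

#' Motif Coverage Ratio (MCR)
#'
#' MCR = Nc / Na for a group of motifs: Nc is the number of daily sequences
#' containing at least one motif of the group, Na the number of sequences
#' structurally able to contain one — those with at least k transitions,
#' where k is the group's minimum edge count (for mixed groups the minimum
#' applies, so a single denominator is used). It measures how much of the
#' eligible corpus the group explains, immune to the length imbalance.
#'
#' @param group character vector of motif pattern strings (non-empty).
#' @param occ an `occurrence_table` computed with `keep_membership = TRUE`.
#' @return list with `value` (in \[0, 1\]), `numerator` (Nc), `denominator`
#'   (Na), `min_edges`. If Na is 0 the value is `NA` (undefined, not an
#'   error).
#' @examples
#' seqs <- make_fixture_corpus("paper_ring")
#' occ <- fast_count(seqs)
#' lines <- occ$table$pattern[occ$table$topology == "Line"]
#' mcr(lines, occ)
#' @export
mcr <- function(group, occ) {
  stopifnot(length(group) > 0L)
  if (is.null(occ$membership)) {
    stop("occurrence table lacks membership; recount with keep_membership = TRUE",
         call. = FALSE)
  }
  k <- min(pattern_n_edges(group))
  na <- unname(occ$n_by_min_transitions[[paste0("ge_", k)]])
  nc <- sum(vapply(occ$membership, function(s) any(group %in% s), TRUE))
  list(
    value = if (na > 0L) nc / na else NA_real_,
    numerator = nc,
    denominator = na,
    min_edges = k
  )
}

#' Cumulative Occurrence Ratio (COR)
#'
#' COR = Cs / Ca: the summed occurrence counts of the target motifs over
#' the summed occurrence counts of all motifs in the scope (typically one
#' topology, or a topology group). Quantifies the weight of motifs with a
#' particular semantics inside their topology.
#'
#' @param target character vector of pattern strings, a subset of `scope`.
#' @param scope character vector of pattern strings defining the
#'   denominator.
#' @param occ an `occurrence_table` (membership not required).
#' @return list with `value`, `numerator` (Cs), `denominator` (Ca). If Ca
#'   is 0 the value is `NA`.
#' @export
cor_ratio <- function(target, scope, occ) {
  if (!all(target %in% scope)) {
    stop("target must be a subset of scope", call. = FALSE)
  }
  tbl <- occ$table
  cs <- sum(tbl$count[tbl$pattern %in% target])
  ca <- sum(tbl$count[tbl$pattern %in% scope])
  list(
    value = if (ca > 0L) cs / ca else NA_real_,
    numerator = cs,
    denominator = ca
  )
}

#' Map a motif's types onto its topology labels
#'
#' For COR selectors defined by node position ("all Star_pre motifs with
#' Food at the central node A"), returns the type filling each abstract
#' label of the pattern's topology template, in first-appearance order.
#'
#' @param pattern pattern string.
#' @return named character vector, label (A-D) to one-letter type code.
#' @examples
#' pattern_label_types("F>S,S>F,F>E")  # Star_pre: A = F (central)
#' @export
pattern_label_types <- function(pattern) {
  m <- parse_pattern(pattern)
  seen <- unique(as.vector(t(m)))
  stats::setNames(seen, LETTERS[seq_along(seen)])
}

#' Select motifs by the type at a template position
#'
#' @param patterns character vector of pattern strings (usually one
#'   topology's motifs).
#' @param label abstract node label, `"A"` to `"D"`.
#' @param type one-letter activity code the label must carry.
#' @return the subset of `patterns` whose `label` position is `type`.
#' @export
patterns_with_label_type <- function(patterns, label, type) {
  keep <- vapply(patterns, function(p) {
    lt <- pattern_label_types(p)
    !is.na(lt[label]) && unname(lt[label]) == type
  }, TRUE)
  unname(patterns[keep])
}
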