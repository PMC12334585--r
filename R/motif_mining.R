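#' Does a daily sequence contain a pattern?
#'
#' A sequence contains a pattern iff the pattern's typed edge list is an
#' order-preserving subsequence of the sequence's transition list: indices
#' strictly increasing, edges need not be adjacent (temporally
#' discontinuous edges are allowed), and because activity types are node
#' identity this single rule covers sequential and non-sequential patterns
#' alike. Checked greedily left to right.
#'
#' @param types character vector of one-letter codes (one daily sequence),
#'   or a sequence-table row's `types[[i]]`.
#' @param pattern pattern string such as `"R>C,C>R"`.
#' @return logical scalar.
#' @examples
#' contains_pattern(c("R", "C", "O", "C", "R"), "R>C,C>R")
#' contains_pattern(c("F", "S"), "S>F")
#' @export
contains_pattern <- function(types, pattern) {
  trans <- sequence_transitions(types)
  edges <- strsplit(pattern, ",", fixed = TRUE)[[1]]
  j <- 1L
  for (tc in trans) {
    if (tc == edges[j]) {
      j <- j + 1L
      if (j > length(edges)) return(TRUE)
    }
  }
  FALSE
}

# All DISTINCT subsequences (1-4 edges) of a transition list, by explicit
# enumeration of index subsets. Exponential in sequence length; this is the
# reference semantics the sweep is checked against.
enumerate_subsequences <- function(trans, max_edges = 4L) {
  m <- length(trans)
  if (m == 0L) return(character())
  keys <- character()
  for (k in seq_len(min(max_edges, m))) {
    sets <- utils::combn(m, k)
    keys <- c(keys, apply(sets, 2L, function(ix) {
      paste(trans[ix], collapse = ",")
    }))
  }
  unique(keys)
}

# Same output as enumerate_subsequences, by a single left-to-right sweep
# holding one boolean reachability flag per distinct typed prefix (the
# counter-expansion idea: counters are keyed by the full typed edge
# combination, and because each sequence contributes at most once per
# pattern the counters collapse to flags). States whose type set exceeds
# max_nodes can never re-enter the candidate space and are pruned.
sweep_subsequences <- function(trans, max_edges = 4L, max_nodes = 4L) {
  seen <- new.env(parent = emptyenv(), size = 256L)
  keys <- character()
  nedges <- integer()
  typesets <- list()
  for (tc in trans) {
    ends <- strsplit(tc, ">", fixed = TRUE)[[1]]
    ext <- which(nedges < max_edges)
    cand_keys <- c(tc, if (length(ext)) paste(keys[ext], tc, sep = ","))
    cand_nedges <- c(1L, nedges[ext] + 1L)
    cand_types <- c(list(unique(ends)),
                    lapply(typesets[ext], function(ts) unique(c(ts, ends))))
    ok <- lengths(cand_types) <= max_nodes &
      !vapply(cand_keys, exists, TRUE, envir = seen, inherits = FALSE)
    # a transition repeated within cand_keys cannot happen: extensions of
    # distinct states by one edge stay distinct
    if (any(ok)) {
      for (key in cand_keys[ok]) assign(key, TRUE, envir = seen)
      keys <- c(keys, cand_keys[ok])
      nedges <- c(nedges, cand_nedges[ok])
      typesets <- c(typesets, cand_types[ok])
    }
  }
  keys
}

#' Candidate patterns of one daily sequence
#'
#' The set of DISTINCT typed temporal patterns contained in the sequence
#' that lie in the candidate space: sequential walks of 1-4 edges with at
#' most 4 distinct types, plus cataloged connected non-sequential shapes of
#' 2-3 edges (see [candidate_space()]). Each pattern appears once
#' regardless of how many embeddings it has.
#'
#' @param types character vector of one-letter codes.
#' @param space a [candidate_space()].
#' @param method `"sweep"` (prefix-flag sweep, the fast path) or
#'   `"enumerate"` (index-subset enumeration, the reference oracle). Both
#'   return identical sets.
#' @return character vector of pattern strings (unordered set).
#' @examples
#' extract_candidates(c("F", "S", "F"))
#' @export
extract_candidates <- function(types, space = candidate_space(),
                               method = c("sweep", "enumerate")) {
  method <- match.arg(method)
  trans <- sequence_transitions(types)
  max_edges <- max(space$seq_edges, space$nonseq_edges)
  keys <- switch(method,
    sweep = sweep_subsequences(trans, max_edges, space$max_nodes),
    enumerate = enumerate_subsequences(trans, max_edges)
  )
  filter_candidate_space(keys, space)
}

new_occurrence_table <- function(counts, n_total, n_by_min, membership) {
  tbl <- pattern_info(as.character(names(counts)))
  tbl$count <- as.integer(unname(counts))
  tbl <- tbl[order(-tbl$count, tbl$pattern), ]
  structure(
    list(table = tbl,
         n_sequences_total = n_total,
         n_by_min_transitions = n_by_min,
         membership = membership),
    class = "occurrence_table"
  )
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat("Occurrence table: ", nrow(x$table), " distinct candidate patterns",
      " over ", x$n_sequences_total, " daily sequences\n", sep = "")
  print(x$table, ...)
  invisible(x)
}

count_patterns <- function(sequences, space, method, keep_membership) {
  per_seq <- lapply(sequences$types, extract_candidates,
                    space = space, method = method)
  counts <- table(unlist(per_seq))
  lens <- sequences$length
  n_by_min <- stats::setNames(
    vapply(1:4, function(k) sum(lens - 1L >= k), 0L),
    paste0("ge_", 1:4)
  )
  new_occurrence_table(counts, nrow(sequences), n_by_min,
                       if (keep_membership) per_seq else NULL)
}

#' Count pattern occurrences over a corpus of daily sequences
#'
#' For every candidate pattern, the occurrence count is the number of
#' DISTINCT daily sequences containing it (containment, not embedding
#' multiplicity). `count_occurrences()` uses the brute-force subsequence
#' enumeration per sequence (the reference semantics); [fast_count()]
#' computes the identical table with the prefix-flag sweep and is the path
#' used by the pipeline. Only observed patterns are stored.
#'
#' @param sequences daily-sequence tibble from [build_daily_sequences()].
#' @param space a [candidate_space()].
#' @param keep_membership keep the per-sequence candidate sets (needed by
#'   [mcr()] and topology-occurrence reporting; default `TRUE`).
#' @return an `occurrence_table` object: `$table` (tibble with `pattern`,
#'   `n_edges`, `n_nodes`, `sequential`, `recurrence`, `topology`,
#'   `count`), `$n_sequences_total`, `$n_by_min_transitions` (sequences
#'   with at least 1-4 transitions), `$membership`.
#' @export
count_occurrences <- function(sequences, space = candidate_space(),
                              keep_membership = TRUE) {
  count_patterns(sequences, space, "enumerate", keep_membership)
}

#' @rdname count_occurrences
#' @export
fast_count <- function(sequences, space = candidate_space(),
                       keep_membership = TRUE) {
  count_patterns(sequences, space, "sweep", keep_membership)
}

#' Export an occurrence table to CSV
#'
#' @param occ an `occurrence_table`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  readr::write_csv(occ$table, path, progress = FALSE)
  invisible(path)
}
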