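#' @title Typed temporal patterns
#'
#' @description
#' A typed temporal pattern is a temporally ordered list of activity-type
#' transitions, written as a pattern string such as `"F>S,S>E"`: edges are
#' comma-separated in temporal order, each edge is `src>dst` with one-letter
#' activity codes (see [activity_codes()]). Activity types ARE node identity:
#' two edges mentioning the same type touch the same node, so a pattern
#' needs no abstract-label matching when it is searched for in a sequence.
#'
#' `parse_pattern()` converts a pattern string into a two-column character
#' matrix of (src, dst) codes and validates it (no self-loop edges, at most
#' four edges).
#'
#' @param pattern a pattern string, e.g. `"R>C,C>R"`.
#' @return `parse_pattern()`: a k x 2 character matrix with columns
#'   `src`, `dst`.
#' @examples
#' parse_pattern("R>C,C>R")
#' is_sequential("F>S,S>E")
#' is_sequential("R>C,F>E")
#' has_recurrence("F>S,S>F")
#' classify_topology("F>S,S>F,F>S")
#' @name pattern
NULL

#' @rdname pattern
#' @export
parse_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, !is.na(pattern))
  edges <- strsplit(pattern, ",", fixed = TRUE)[[1]]
  if (length(edges) < 1L || length(edges) > 4L) {
    stop("pattern must have 1-4 edges, got ", length(edges), call. = FALSE)
  }
  parts <- strsplit(edges, ">", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed edge(s): ", paste(edges[bad], collapse = ", "),
         call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE,
              dimnames = list(NULL, c("src", "dst")))
  if (any(m[, 1L] == m[, 2L])) {
    stop("self-loop edges are not allowed (run-merging removes them): ",
         pattern, call. = FALSE)
  }
  m
}

pattern_key <- function(src, dst) {
  paste(paste0(src, ">", dst), collapse = ",")
}

pattern_n_edges <- function(pattern) {
  vapply(strsplit(pattern, ",", fixed = TRUE), length, 0L)
}

pattern_node_types <- function(pattern) {
  m <- parse_pattern(pattern)
  unique(as.vector(t(m)))
}

# Split a temporal edge list into maximal temporal walks: a walk breaks
# whenever the target of edge i differs from the source of edge i + 1.
maximal_walks <- function(edge_mat) {
  k <- nrow(edge_mat)
  if (k == 1L) return(list(edge_mat))
  breaks <- which(edge_mat[-k, 2L] != edge_mat[-1L, 1L])
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, k)
  lapply(seq_along(starts), function(i) {
    edge_mat[starts[i]:ends[i], , drop = FALSE]
  })
}

walk_visits <- function(walk_mat) {
  c(walk_mat[1L, 1L], walk_mat[, 2L])
}

#' @rdname pattern
#' @export
is_sequential <- function(pattern) {
  m <- parse_pattern(pattern)
  length(maximal_walks(m)) == 1L
}

#' @rdname pattern
#' @export
has_recurrence <- function(pattern) {
  m <- parse_pattern(pattern)
  walks <- maximal_walks(m)
  visits <- lapply(walks, walk_visits)
  # repetition inside one process, or a type shared across processes
  if (any(vapply(visits, anyDuplicated, 0L) > 0L)) return(TRUE)
  per_walk <- lapply(visits, unique)
  anyDuplicated(unlist(per_walk)) > 0L
}

# Canonical label form: relabel types A-D in order of first appearance
# (scanning edges in temporal order, source before target). Two patterns
# share a topology iff their canonical edge words are equal.
canonical_edge_word <- function(pattern) {
  m <- parse_pattern(pattern)
  seen <- unique(as.vector(t(m)))
  labels <- stats::setNames(LETTERS[seq_along(seen)], seen)
  paste(paste0(labels[m[, 1L]], ">", labels[m[, 2L]]), collapse = ",")
}

the <- new.env(parent = emptyenv())

#' Topology catalog
#'
#' The catalog of topology templates: every sequential shape of one to four
#' edges over at most four distinct activity types (22 templates, named
#' Line, Ring, Chain, Triple_line, Star_pre, Triad, Star_pos, Triple_chain,
#' Four_times_line, plus systematic `Seq4_*` names for the remaining
#' four-edge shapes) and the nine cataloged non-sequential shapes (`Ring_n`,
#' `Chain_n1`-`Chain_n3`, `Triple_line_n1`/`n2`, `Star_pos_n1`/`n2`,
#' `Triad_n`). Shipped as a data file so that non-sequential shape
#' corrections are data-only edits.
#'
#' @param path optional path to an alternative catalog file (CSV with
#'   columns name, edge_template, n_edges, n_nodes, sequential, recurrence).
#' @return a tibble with one row per template.
#' @examples
#' topology_catalog()
#' @export
topology_catalog <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the$catalog)) return(the$catalog)
    path <- system.file("extdata", "topology_catalog.csv",
                        package = "tamotif", mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  cat_tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      name = readr::col_character(),
      edge_template = readr::col_character(),
      n_edges = readr::col_integer(),
      n_nodes = readr::col_integer(),
      sequential = readr::col_logical(),
      recurrence = readr::col_logical()
    ),
    progress = FALSE
  )
  validate_catalog(cat_tbl)
  if (cache) the$catalog <- cat_tbl
  cat_tbl
}

validate_catalog <- function(cat_tbl) {
  stopifnot(!anyDuplicated(cat_tbl$name), !anyDuplicated(cat_tbl$edge_template))
  for (i in seq_len(nrow(cat_tbl))) {
    tmpl <- cat_tbl$edge_template[i]
    if (canonical_edge_word(tmpl) != tmpl) {
      stop("catalog template not in canonical label form: ", tmpl,
           call. = FALSE)
    }
    m <- parse_pattern(tmpl)
    if (nrow(m) != cat_tbl$n_edges[i] ||
        length(unique(as.vector(m))) != cat_tbl$n_nodes[i] ||
        is_sequential(tmpl) != cat_tbl$sequential[i] ||
        has_recurrence(tmpl) != cat_tbl$recurrence[i]) {
      stop("catalog row inconsistent with its template: ", cat_tbl$name[i],
           call. = FALSE)
    }
  }
  invisible(cat_tbl)
}

catalog_lookup <- function() {
  cat_tbl <- topology_catalog()
  stats::setNames(cat_tbl$name, cat_tbl$edge_template)
}

#' @rdname pattern
#' @return `classify_topology()`: the catalog name of the pattern's
#'   topology, or `"uncataloged"` for a pattern outside the catalog (never a
#'   silent guess).
#' @export
classify_topology <- function(pattern) {
  word <- canonical_edge_word(pattern)
  name <- catalog_lookup()[word]
  if (is.na(name)) "uncataloged" else unname(name)
}

#' Enumerate topology templates by brute force
#'
#' Independently of the shipped catalog file, enumerates the sequential
#' template space: all canonical adjacent-distinct label words of length
#' k + 1 over at most four distinct labels, for k up to `max_edges`
#' (1 one-edge, 2 two-edge, 5 three-edge and 14 four-edge shapes), plus the
#' cataloged non-sequential shapes (restricted to `max_edges`). Used to
#' cross-check the catalog and to size the candidate space.
#'
#' @param max_edges maximum number of edges, between 1 and 4.
#' @param max_nodes maximum number of distinct labels (default 4).
#' @return a tibble with columns `word` (node-visit label word, sequential
#'   templates only), `edge_template`, `n_edges`, `n_nodes`, `sequential`.
#' @examples
#' dplyr::count(enumerate_topologies(3), n_edges, sequential)
#' @export
enumerate_topologies <- function(max_edges = 4L, max_nodes = 4L) {
  stopifnot(max_edges >= 1L, max_edges <= 4L)
  words <- list("A")
  all_words <- character()
  for (len in seq_len(max_edges)) {
    words <- unlist(lapply(words, function(w) {
      chars <- strsplit(w, "")[[1]]
      used <- unique(chars)
      candidates <- unique(c(used, LETTERS[length(used) + 1L]))
      candidates <- candidates[candidates != chars[length(chars)]]
      candidates <- candidates[match(candidates, LETTERS) <= max_nodes]
      paste0(w, candidates)
    }))
    all_words <- c(all_words, words)
  }
  word_to_template <- function(w) {
    chars <- strsplit(w, "")[[1]]
    pattern_key(chars[-length(chars)], chars[-1L])
  }
  seq_tbl <- tibble::tibble(
    word = all_words,
    edge_template = vapply(all_words, word_to_template, ""),
    n_edges = nchar(all_words) - 1L,
    n_nodes = vapply(strsplit(all_words, ""),
                     function(x) length(unique(x)), 0L),
    sequential = TRUE
  )
  cat_tbl <- topology_catalog()
  nonseq <- cat_tbl[!cat_tbl$sequential & cat_tbl$n_edges <= max_edges, ]
  dplyr::bind_rows(
    seq_tbl,
    tibble::tibble(word = NA_character_,
                   edge_template = nonseq$edge_template,
                   n_edges = nonseq$n_edges,
                   n_nodes = nonseq$n_nodes,
                   sequential = FALSE)
  )
}

#' Describe a set of pattern strings
#'
#' Vectorised structural description used by the counting and selection
#' stages: edge and node counts, sequentiality, recurrence and topology
#' name for each pattern.
#'
#' @param patterns character vector of pattern strings.
#' @return a tibble with columns `pattern`, `n_edges`, `n_nodes`,
#'   `sequential`, `recurrence`, `topology`.
#' @examples
#' pattern_info(c("F>S", "F>S,S>F", "R>C,F>E"))
#' @export
pattern_info <- function(patterns) {
  info <- lapply(patterns, function(p) {
    m <- parse_pattern(p)
    list(
      n_edges = nrow(m),
      n_nodes = length(unique(as.vector(m))),
      sequential = is_sequential(p),
      recurrence = has_recurrence(p),
      topology = classify_topology(p)
    )
  })
  tibble::tibble(
    pattern = patterns,
    n_edges = vapply(info, function(x) as.integer(x$n_edges), 0L),
    n_nodes = vapply(info, function(x) as.integer(x$n_nodes), 0L),
    sequential = vapply(info, function(x) x$sequential, TRUE),
    recurrence = vapply(info, function(x) x$recurrence, TRUE),
    topology = vapply(info, function(x) x$topology, "")
  )
}

#' Candidate-space configuration
#'
#' The candidate space is the set of typed patterns eligible for counting:
#' sequential patterns (temporal walks) of `seq_edges` edges with at most
#' `max_nodes` distinct types, plus cataloged connected non-sequential
#' shapes with `nonseq_edges` edges. Four-edge non-sequential patterns are
#' excluded by default.
#'
#' @param seq_edges integer range of edge counts for sequential patterns.
#' @param nonseq_edges integer range for non-sequential patterns.
#' @param max_nodes maximum distinct activity types per pattern.
#' @return a list with class `candidate_space`.
#' @examples
#' candidate_space()
#' @export
candidate_space <- function(seq_edges = 1:4, nonseq_edges = 2:3,
                            max_nodes = 4L) {
  stopifnot(all(seq_edges %in% 1:4), all(nonseq_edges %in% 2:4),
            max_nodes >= 2L, max_nodes <= 4L)
  structure(
    list(seq_edges = as.integer(seq_edges),
         nonseq_edges = as.integer(nonseq_edges),
         max_nodes = as.integer(max_nodes)),
    class = "candidate_space"
  )
}

# Keep only pattern strings inside the candidate space. `patterns` may
# contain anything produced by subsequence enumeration; non-sequential
# patterns must additionally match a cataloged shape.
filter_candidate_space <- function(patterns, space = candidate_space()) {
  if (length(patterns) == 0L) return(character())
  keep <- vapply(patterns, function(p) {
    m <- parse_pattern(p)
    k <- nrow(m)
    if (length(unique(as.vector(m))) > space$max_nodes) return(FALSE)
    if (length(maximal_walks(m)) == 1L) {
      k %in% space$seq_edges
    } else {
      k %in% space$nonseq_edges &&
        !is.na(catalog_lookup()[canonical_edge_word(p)])
    }
  }, TRUE)
  unname(patterns[keep])
}
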