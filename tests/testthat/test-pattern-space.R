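test_that("sequentiality is the temporal-walk property", {
  expect_true(is_sequential("F>S"))
  expect_true(is_sequential("F>S,S>E"))
  expect_false(is_sequential("F>S,F>E"))
  expect_false(is_sequential("R>C,F>E"))
})

test_that("recurrence detects repeated types within and across processes", {
  expect_true(has_recurrence("F>S,S>F"))          # cycle
  expect_false(has_recurrence("F>S,S>E"))         # chain
  expect_true(has_recurrence("F>S,F>E"))          # F shared by two processes
  expect_false(has_recurrence("F>S"))
  expect_true(has_recurrence("F>S,S>F,F>S"))
})

test_that("pattern parsing rejects malformed and self-loop input", {
  expect_error(parse_pattern("F>F"), "self-loop")
  expect_error(parse_pattern("F-S"), "malformed")
  expect_error(parse_pattern("A>B,B>A,A>B,B>A,A>B"), "1-4 edges")
})

test_that("topology classification matches the named catalog shapes", {
  expect_equal(classify_topology("F>S"), "Line")
  expect_equal(classify_topology("F>S,S>F"), "Ring")
  expect_equal(classify_topology("C>F,F>T"), "Chain")
  expect_equal(classify_topology("F>S,S>F,F>S"), "Triple_line")
  expect_equal(classify_topology("F>S,S>F,F>E"), "Star_pre")
  expect_equal(classify_topology("T>C,C>F,F>T"), "Triad")
  expect_equal(classify_topology("C>F,F>E,E>F"), "Star_pos")
  expect_equal(classify_topology("R>C,C>F,F>E"), "Triple_chain")
  expect_equal(classify_topology("F>S,S>F,F>S,S>F"), "Four_times_line")
  # two-edge non-sequential shapes, per the catalog's name assignment
  expect_equal(classify_topology("F>S,F>S"), "Ring_n")
  expect_equal(classify_topology("F>S,F>E"), "Chain_n1")
  expect_equal(classify_topology("F>S,E>S"), "Chain_n2")
  expect_equal(classify_topology("F>S,E>F"), "Chain_n3")
  # disconnected two-process pattern: outside the catalog, never a guess
  expect_equal(classify_topology("R>C,F>E"), "uncataloged")
})

test_that("classification is invariant under type substitution", {
  withr::local_seed(21)
  codes <- unname(activity_codes())
  pats <- c("F>S", "F>S,S>F", "C>F,F>T", "F>S,S>F,F>E", "T>C,C>F,F>T",
            "F>S,F>E", "F>S,E>F", "R>C,C>F,F>E,E>C")
  for (p in pats) {
    for (rep in 1:5) {
      perm <- stats::setNames(sample(codes), codes)
      m <- parse_pattern(p)
      sub <- tamotif:::pattern_key(perm[m[, 1]], perm[m[, 2]])
      expect_equal(classify_topology(sub), classify_topology(p))
    }
  }
})

test_that("brute-force template enumeration gives the documented census", {
  et <- enumerate_topologies(4)
  seq_counts <- table(et$n_edges[et$sequential])
  expect_equal(as.integer(seq_counts[c("1", "2", "3", "4")]),
               c(1L, 2L, 5L, 14L))
  # 5 three-edge + 14 four-edge = 19 high-order sequential templates
  expect_equal(sum(et$sequential & et$n_edges >= 3), 19L)
  expect_equal(sum(!et$sequential & et$n_edges == 2), 4L)
  expect_equal(sort(et$word[et$sequential & et$n_edges == 2]),
               c("ABA", "ABC"))
  expect_equal(sort(et$word[et$sequential & et$n_edges == 3]),
               c("ABAB", "ABAC", "ABCA", "ABCB", "ABCD"))
})

test_that("the shipped catalog agrees with the independent enumeration", {
  cat_tbl <- topology_catalog()
  et <- enumerate_topologies(4)
  expect_setequal(cat_tbl$edge_template[cat_tbl$sequential],
                  et$edge_template[et$sequential])
  # every template canonical, classified to itself
  for (i in seq_len(nrow(cat_tbl))) {
    expect_equal(classify_topology(cat_tbl$edge_template[i]),
                 cat_tbl$name[i])
  }
})

test_that("recurrence flags on the named templates are as expected", {
  cat_tbl <- topology_catalog()
  flag <- stats::setNames(cat_tbl$recurrence, cat_tbl$name)
  expect_false(any(flag[c("Line", "Chain", "Triple_chain")]))
  expect_true(all(flag[c("Ring", "Triple_line", "Four_times_line",
                         "Star_pre", "Star_pos", "Triad")]))
  # every non-sequential shape shares a type across processes
  expect_true(all(cat_tbl$recurrence[!cat_tbl$sequential]))
})

test_that("typed-pattern census per template follows falling factorials", {
  census <- function(name) {
    tmpl <- topology_catalog()
    tmpl <- tmpl[tmpl$name == name, ]
    m <- parse_pattern(tmpl$edge_template)
    labels <- unique(as.vector(t(m)))
    codes <- unname(activity_codes())
    assignments <- utils::combn(codes, length(labels), simplify = FALSE)
    total <- 0L
    for (chosen in assignments) {
      perms <- if (length(chosen) == 1L) list(chosen) else {
        asplit(all_orderings(chosen), 1L)
      }
      for (ord in perms) {
        map <- stats::setNames(ord, labels)
        typed <- tamotif:::pattern_key(map[m[, 1]], map[m[, 2]])
        if (classify_topology(typed) == name) total <- total + 1L
      }
    }
    total
  }
  # small permutation helper (avoids a package dependency)
  all_orderings <- function(x) {
    if (length(x) == 1L) return(matrix(x, 1L))
    out <- NULL
    for (i in seq_along(x)) {
      rest <- all_orderings(x[-i])
      out <- rbind(out, cbind(x[i], rest))
    }
    out
  }
  expect_equal(census("Line"), 42L)
  expect_equal(census("Ring"), 42L)
  expect_equal(census("Chain"), 210L)
  expect_equal(census("Triad"), 210L)
  expect_equal(census("Triple_chain"), 840L)
})

test_that("no two-walk arrangement of the Triad edge multiset exists", {
  # the catalog's Triad_n is the unique non-walk temporal ordering of the
  # cycle's edges, and it decomposes into three single-edge processes
  edges <- list(c("R", "C"), c("C", "O"), c("O", "R"))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  shapes <- character()
  for (p in perms) {
    m <- do.call(rbind, edges[p])
    pat <- tamotif:::pattern_key(m[, 1], m[, 2])
    walks <- length(tamotif:::maximal_walks(parse_pattern(pat)))
    expect_true(walks %in% c(1L, 3L))  # never exactly two
    if (walks > 1L) shapes <- c(shapes, tamotif:::canonical_edge_word(pat))
  }
  expect_equal(unique(shapes), "A>B,C>A,B>C")  # the cataloged Triad_n
})
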