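test_that("threshold arithmetic floors fractions of the corpus size", {
  thr <- compute_thresholds(1000)
  expect_equal(thr$high_order, 1L)
  expect_equal(thr$low_order, 5L)
  sens <- compute_thresholds(80118, c(0.0008, 0.004))
  expect_equal(sens$high_order, 64L)
  expect_equal(sens$low_order, 320L)
  expect_error(compute_thresholds(0), "positive")
  expect_error(compute_thresholds(-5), "positive")
})

test_that("selection keeps patterns at or above their class threshold", {
  seqs <- sequence_table(c(
    rep(list(c("F", "S")), 5),             # Line F>S in 5 sequences
    rep(list(c("R", "C", "O", "C")), 2),   # high-order material
    list(c("E", "T"))
  ))
  occ <- fast_count(seqs)
  thr <- list(low_order = 5L, high_order = 2L)
  motifs <- select_motifs(occ, thr)
  # boundary: count == threshold is kept
  expect_true("F>S" %in% motifs$pattern)
  expect_false("E>T" %in% motifs$pattern)  # count 1 < 5
  expect_true("R>C,C>O,O>C" %in% motifs$pattern)  # count 2 >= 2
  # raising thresholds never grows the motif set
  for (bump in 1:3) {
    smaller <- select_motifs(occ, list(low_order = 5L + bump,
                                       high_order = 2L + bump))
    expect_true(all(smaller$pattern %in% motifs$pattern))
  }
})

test_that("low-order class is sequential with at most two edges", {
  seqs <- sequence_table(rep(list(c("F", "S", "F", "E")), 3))
  occ <- fast_count(seqs)
  motifs <- select_motifs(occ, list(low_order = 10L, high_order = 3L))
  # Lines and Rings need 10 and miss it; high-order and non-sequential
  # patterns need 3 and make it
  expect_false(any(motifs$n_edges <= 2 & motifs$sequential))
  expect_true("F>S,S>F,F>E" %in% motifs$pattern)   # Star_pre, 3 edges
  expect_true("F>S,F>E" %in% motifs$pattern)       # Chain_n1, non-sequential
})

test_that("MCR divides group coverage by structurally eligible sequences", {
  # corpus: 10 sequences with >= 3 transitions, of which 4 contain the
  # 3-edge group motif; plus short sequences excluded from the denominator
  long_with <- rep(list(c("F", "S", "F", "E")), 4)
  long_without <- rep(list(c("R", "C", "O", "T")), 6)
  short <- rep(list(c("F", "S")), 5)
  seqs <- sequence_table(c(long_with, long_without, short))
  occ <- fast_count(seqs)
  res <- mcr("F>S,S>F,F>E", occ)
  expect_equal(res$denominator, 10L)
  expect_equal(res$numerator, 4L)
  expect_equal(res$value, 0.4)
  # a group with no occurrences covers nothing
  none <- mcr("T>R,R>T", occ)
  expect_equal(none$numerator, 0L)
  expect_equal(none$value, 0)
})

test_that("mixed-edge-count groups use the minimum edge count for Na", {
  seqs <- sequence_table(c(rep(list(c("F", "S", "F", "E")), 2),
                           rep(list(c("F", "S")), 3)))
  occ <- fast_count(seqs)
  res <- mcr(c("F>S", "F>S,S>F,F>E"), occ)
  expect_equal(res$min_edges, 1L)
  expect_equal(res$denominator, 5L)
  expect_equal(res$value, 1)
})

test_that("MCR requires membership information", {
  seqs <- sequence_table(list(c("F", "S")))
  occ <- fast_count(seqs, keep_membership = FALSE)
  expect_error(mcr("F>S", occ), "membership")
})

test_that("Line MCR is exactly 1 when all observed Lines are motifs", {
  withr::local_seed(41)
  seqs <- sequence_table(lapply(sample(2:7, 80, replace = TRUE),
                                rand_merged_seq))
  occ <- fast_count(seqs)
  lines <- occ$table$pattern[occ$table$topology == "Line"]
  expect_equal(mcr(lines, occ)$value, 1)
})

test_that("COR is the occurrence-weighted share of the target", {
  seqs <- sequence_table(c(
    rep(list(c("F", "S")), 6),
    rep(list(c("C", "E")), 3),
    rep(list(c("R", "T")), 1)
  ))
  occ <- fast_count(seqs)
  scope <- c("F>S", "C>E", "R>T")
  expect_equal(cor_ratio("F>S", scope, occ)$value, 0.6)
  expect_equal(cor_ratio(scope, scope, occ)$value, 1)
  # disjoint selectors partitioning the scope sum to 1
  parts <- vapply(scope, function(p) cor_ratio(p, scope, occ)$value, 0)
  expect_equal(sum(parts), 1, tolerance = 1e-12)
  expect_error(cor_ratio("X>Y", scope, occ), "subset")
})

test_that("COR over an absent scope is undefined, not an error", {
  seqs <- sequence_table(list(c("F", "S")))
  occ <- fast_count(seqs)
  expect_true(is.na(cor_ratio("R>T", c("R>T", "T>R"), occ)$value))
})

test_that("label selectors pick motifs by node position and type", {
  pats <- c("F>S,S>F,F>E",  # Star_pre with central node A = F
            "S>F,F>S,S>E",  # Star_pre with central node A = S
            "F>E,E>F,F>C")  # Star_pre with central node A = F
  expect_setequal(patterns_with_label_type(pats, "A", "F"), pats[c(1, 3)])
  expect_equal(patterns_with_label_type(pats, "B", "S"), pats[1])
  lt <- pattern_label_types("F>S,S>F,F>E")
  expect_equal(unname(lt["A"]), "F")
  expect_equal(unname(lt["C"]), "E")
})

test_that("topology summary reports per-topology motif counts and coverage", {
  seqs <- sequence_table(c(rep(list(c("F", "S", "F")), 3),
                           rep(list(c("F", "S")), 2)))
  occ <- fast_count(seqs)
  motifs <- select_motifs(occ, list(low_order = 3L, high_order = 3L))
  ts <- attr(motifs, "topology_summary")
  expect_true(all(c("Line", "Ring") %in% ts$topology))
  # F>S occurs in all 5 sequences, S>F and the Ring in 3
  expect_equal(ts$topology_occurrence[ts$topology == "Line"], 5L)
  expect_equal(ts$topology_occurrence[ts$topology == "Ring"], 3L)
  # bounds: max single count <= topology occurrence <= sum of counts
  line_counts <- motifs$count[motifs$topology == "Line"]
  expect_gte(ts$topology_occurrence[ts$topology == "Line"], max(line_counts))
  expect_lte(ts$topology_occurrence[ts$topology == "Line"], sum(line_counts))
})
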