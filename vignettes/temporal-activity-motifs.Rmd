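---
title: "Mining temporal activity motifs: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining temporal activity motifs: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tamotif)
```

## The object of study

A check-in stream is a sequence of timestamped, categorized visit events.
`tamotif` abstracts it twice: categories collapse to seven activity types
(Residence, Community, Entertainment, Food, Outdoors, Shopping, Travel),
and each user's events collapse to one *daily activity sequence* per
5 AM-anchored day — time-ordered, with consecutive repeats of the same type
merged into a single item. Transitions between adjacent items are the
edges of a daily activity transition graph whose nodes are activity types.

A *typed temporal pattern* is a temporally ordered list of one to four
such transitions, written `"F>S,S>F"`. Two modeling commitments shape
everything downstream:

* **Types are node identity.** Two edges mentioning Food touch the same
  node. Patterns therefore need no subgraph-isomorphism machinery: a
  pattern occurs in a sequence exactly when its edge list is an
  order-preserving subsequence of the sequence's transition list. Edges
  need not be adjacent in time (intermediate activities may be skipped),
  and they need not form a single walk (two separate processes may
  co-occur).
* **Occurrence is containment, not embedding count.** A pattern's
  occurrence is the number of distinct daily sequences containing it at
  least once. A sequence that embeds a pattern five times still counts
  once. This makes counts directly comparable to corpus size and is what
  the selection thresholds and both metrics are defined over.

Durations and spatial information are deliberately outside the pattern
definition; the day boundary is the only temporal constraint.

## The topology catalog

Patterns group into topologies by relabeling their types A–D in order of
first appearance. Sequential topologies (temporal walks) are enumerable by
brute force: canonical adjacent-distinct label words of length k+1 with at
most four distinct labels give 1, 2, 5, and 14 shapes for k = 1–4
(`enumerate_topologies()`), carrying the conventional names Line (AB),
Ring (ABA), Chain (ABC), Triple_line (ABAB), Star_pre (ABAC), Triad
(ABCA), Star_pos (ABCB), Triple_chain (ABCD), and Four_times_line (ABABA);
the remaining four-edge shapes get systematic `Seq4_*` names.

Non-sequential shapes are restricted to a *catalog*
(`inst/extdata/topology_catalog.csv` — a data file, so corrections never
require code changes). The two-edge case is exactly derivable: given a
first edge A→B, a second edge that shares a node but does not continue the
walk is one of four shapes — the repeated transition (Ring_n), shared
source (Chain_n1), shared target (Chain_n2), and target-to-source
(Chain_n3). The three-edge shapes were an open design point; we derive
them by a rotation construction: split a sequential walk into a prefix and
a suffix and emit suffix-then-prefix. For Triple_line and Star_pos this
yields exactly two non-walk shapes each (`Triple_line_n1/n2`,
`Star_pos_n1/n2`). For Triad it yields none — the cycle's edges re-join
into a walk under every rotation — and enumeration shows every non-walk
ordering of the Triad edge multiset decomposes into *three* single-edge
processes, all relabeling to one canonical shape; that unique shape is
cataloged as `Triad_n`. The same rotation applied to Star_pre would also
produce two non-walk shapes, but no such topologies appear in the standard
topology vocabulary, so they are not cataloged and hence excluded from the
default candidate space; a user who wants them can extend the catalog
file. Four-edge non-sequential patterns are likewise excluded by default
(`candidate_space()` exposes the choice). Disconnected two-process
patterns (no shared type) are outside the candidate space entirely,
although `contains_pattern()` will still test for them.

## Counting

The reference semantics is explicit: enumerate all index subsets of up to
four transitions per sequence, deduplicate, filter to the candidate space
(`count_occurrences()`). The production path (`fast_count()`) sweeps each
sequence left to right, maintaining one boolean flag per distinct typed
prefix seen so far — the counter-expansion idea of counter-based temporal
motif counting, specialized to containment, where boolean flags suffice
because each sequence contributes at most once per pattern. States whose
type set exceeds four are pruned, since no extension can re-enter the
candidate space. On repetitive sequences the state count is bounded by the
number of distinct patterns rather than the number of index subsets (a
length-20 alternating sequence has 5,036 subsets but at most 30 states).
The two paths are asserted equal, pattern for pattern and count for count,
on randomized corpora in the test suite; the oracle never shares code with
the sweep.

## Selection and metrics

Sequence lengths are heavily imbalanced, so a single support threshold
would drown out high-order patterns that only long sequences can contain.
Two thresholds are derived from corpus size N: `floor(f_low · N)` for
sequential patterns of at most two edges and `floor(f_high · N)` for
everything else, with defaults `f_low = 0.005`, `f_high = 0.001` (and
sensitivity alternatives 0.0008/0.004 and 0.0012/0.006 supported via
configuration). Three boundary conventions are fixed and documented rather
than left implicit:

* *Flooring*: thresholds round down (with a reference corpus of 80,118
  sequences the defaults give exactly 80 and 400).
* *Inclusive comparison*: a pattern whose count equals its threshold is
  selected (count ≥ threshold).
* *Group denominators*: MCR for a mixed-edge-count group uses the group's
  minimum edge count k, so N_a counts sequences with at least k
  transitions and the group reports a single coverage value.

MCR = N_c/N_a and COR = C_s/C_a are returned with their numerators and
denominators; a zero denominator yields `NA` (an undefined result, not an
error). COR selectors by node position use the catalog's labels (the
central node of Star_pre, Star_pos, and Triad is label A under
first-appearance relabeling, except Star_pos where the catalog's word ABCB
places the cycle on B–C; `pattern_label_types()` exposes the mapping so
selectors are explicit rather than positional conventions).

## Preprocessing conventions

The cleaning order is fixed: POI filter first (counts computed on the raw
input, single pass, no re-iteration), then the interval filter, then
typing, segmentation, and merging. The interval filter is per-user and
greedy: a record is kept iff it is at least 10 minutes after the last
*kept* record of that user, the first record always kept — deterministic
and single-pass, at the cost of being one of several defensible readings
of "remove check-ins with short intervals". Timestamps are wall-clock with
no timezone conversion (the 5 AM boundary is a wall-clock rule; a fixed
UTC label keeps arithmetic away from DST rules). Day windows are
half-open: 04:59 belongs to the previous day's window, 05:00 to the
current one. Run-merged items are stamped with the run's first timestamp,
so transition times reflect the earliest evidence of a type change. Ties
in time resolve by input order (stable sort). Duplicate rows are kept.
Sequences are never split by long within-day gaps. Each choice is a
package decision where the procedure's usual description is silent; all
are covered by unit tests.

Degenerate inputs are defined rather than accidental: an empty corpus
yields an empty occurrence table with zero totals; a sequence of merged
length one is dropped before counting; a pattern outside the catalog
classifies as `"uncataloged"`, and the default candidate space provably
never produces one.

## The simulator: what it emulates, and what it does not

`generate_checkins()` draws, per user-day, a check-in count
`1 + Geom(0.42)` (mean ≈ 2.4), a type chain from a first-order Markov
kernel with 0.2 self-transition mass (producing the pre-merge runs that
run-merging collapses), ordered uniform minute-precision timestamps within
the anchored day, and a POI from per-type pools sized so popular POIs
average ~25 check-ins while a sparse tail averages ~3 — keeping the
minimum-check-in filter meaningfully exercised at any corpus size. The
resulting merged-length distribution is imbalanced in the way real
check-in corpora are: most kept sequences have length 2–3, a minority
length ≥ 4.

The default marginals (R .16, C .18, E .16, F .11, O .14, S .11, T .14)
keep any single two-edge combination's baseline frequency well below the
0.5% selection fraction, so planted-pattern recovery is a sharp test: a
20× boost on the Food↔Shopping edges lifts that ring far above threshold,
and removing the boost drops it clearly below. Real corpora are more
heavily skewed toward Food and against Residence than this; the simulator
also has no weekly rhythm, no user heterogeneity beyond sampling noise, no
social structure, and no spatial realism. Passing tests on simulated data
therefore validate the *mechanics* of the pipeline — filters, counting
semantics, thresholds, metrics — not any behavioral claim about real
populations.

Test and acceptance problem sizes are the package's own choices: unit
tests use corpora of tens to hundreds of sequences; the oracle-equivalence
property uses 200 random sequences of length ≤ 8; planted-pattern recovery
uses 200 users × 30 days; the acceptance script uses 100 users × 10 days.

## Known limitations

* The non-sequential three-edge catalog is a structural derivation, not a
  transcription of a published figure; the name↔shape pairing within the
  `_n1`/`_n2` pairs (and for Chain_n1–3) is a convention of this package.
* Reflexive self-loops (same-type persistence) are not representable;
  run-merging removes them by construction.
* Occurrence counting is containment-based; embedding-instance counts are
  out of scope.
* The interval and POI filters interact with the simulator's timestamp
  model (uniform within the day), which slightly thins long sequences
  compared to clustered real-world check-in times.
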