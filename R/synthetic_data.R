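#' Default activity-type transition kernel
#'
#' Row-stochastic 7 x 7 matrix over the one-letter type codes. Each row
#' puts `self` mass on staying in the same type (producing the runs of
#' repeated check-ins that run-merging later collapses) and distributes the
#' rest across the other types proportionally to the stationary marginals.
#'
#' @param marginals length-7 positive weight vector in canonical type
#'   order; normalised internally.
#' @param self self-transition probability per row (default 0.2).
#' @return 7 x 7 matrix with dimnames = type codes, rows summing to 1.
#' @export
default_kernel <- function(marginals = c(R = 0.16, C = 0.18, E = 0.16,
                                         F = 0.11, O = 0.14, S = 0.11,
                                         T = 0.14),
                           self = 0.2) {
  codes <- unname(activity_codes())
  w <- marginals / sum(marginals)
  k <- matrix(0, 7L, 7L, dimnames = list(codes, codes))
  for (i in seq_len(7L)) {
    off <- w[-i] / sum(w[-i])
    k[i, -i] <- (1 - self) * off
    k[i, i] <- self
  }
  k
}

#' Simulation configuration
#'
#' Defines a synthetic check-in corpus: a population of users whose daily
#' check-in counts are geometric-tailed (most days have one or two
#' check-ins, a minority four or more, matching the imbalanced length
#' distribution of real check-in corpora) and whose activity-type chains
#' follow a first-order Markov kernel. Patterns can be planted by boosting
#' the kernel entries of their edges (rows renormalised), which makes
#' threshold-recovery behaviour testable end to end.
#'
#' @param n_users number of users.
#' @param days number of simulated days per user.
#' @param type_marginals length-7 weight vector (initial-type and POI-pool
#'   distribution).
#' @param transition_kernel 7 x 7 row-stochastic matrix; default
#'   [default_kernel()].
#' @param planted_patterns list of `list(pattern =, boost =)` entries;
#'   boost >= 1 multiplies the kernel entries of the pattern's edges.
#' @param length_prob geometric parameter: daily check-in count is
#'   `1 + rgeom(length_prob)` (default 0.42, mean about 2.4 check-ins).
#' @param boundary_hour day-anchor hour (default 5).
#' @param n_pois_per_type size of each type's POI pool; `NULL` (default)
#'   scales the pool with the expected corpus size so that popular POIs
#'   average about 25 check-ins (clearing the usual minimum of 10) while
#'   sparse ones average about 3 (falling under it).
#' @param sparse_poi_fraction fraction of each pool visited rarely, so the
#'   minimum-check-in POI filter has work to do (default 0.3). Sparse POIs
#'   receive 10% of the traffic collectively.
#' @param start_date first simulated calendar date.
#' @param seed integer; fully determines the output.
#' @return list with class `simulation_config`.
#' @export
simulation_config <- function(n_users = 100L, days = 10L,
                              type_marginals = c(R = 0.16, C = 0.18,
                                                 E = 0.16, F = 0.11,
                                                 O = 0.14, S = 0.11,
                                                 T = 0.14),
                              transition_kernel = NULL,
                              planted_patterns = list(),
                              length_prob = 0.42,
                              boundary_hour = 5L,
                              n_pois_per_type = NULL,
                              sparse_poi_fraction = 0.3,
                              start_date = as.Date("2010-01-01"),
                              seed = 1L) {
  if (is.null(transition_kernel)) {
    transition_kernel <- default_kernel(type_marginals)
  }
  validate_kernel(transition_kernel)
  for (pp in planted_patterns) {
    stopifnot(is.list(pp), !is.null(pp$pattern), pp$boost >= 1)
    parse_pattern(pp$pattern)
  }
  stopifnot(length_prob > 0, length_prob < 1)
  structure(
    list(n_users = as.integer(n_users), days = as.integer(days),
         type_marginals = type_marginals / sum(type_marginals),
         transition_kernel = transition_kernel,
         planted_patterns = planted_patterns,
         length_prob = length_prob,
         boundary_hour = as.integer(boundary_hour),
         n_pois_per_type = if (!is.null(n_pois_per_type))
           as.integer(n_pois_per_type),
         sparse_poi_fraction = sparse_poi_fraction,
         start_date = as.Date(start_date),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

validate_kernel <- function(k) {
  codes <- unname(activity_codes())
  if (!is.matrix(k) || !all(dim(k) == c(7L, 7L))) {
    stop("transition kernel must be 7 x 7", call. = FALSE)
  }
  if (is.null(dimnames(k)) || !identical(rownames(k), codes) ||
      !identical(colnames(k), codes)) {
    stop("kernel dimnames must be the activity codes in canonical order",
         call. = FALSE)
  }
  if (any(k < 0) || any(abs(rowSums(k) - 1) > 1e-9)) {
    stop("kernel rows must be non-negative and sum to 1", call. = FALSE)
  }
  invisible(k)
}

# Multiply the kernel entries of each planted pattern's edges by its boost
# factor, then renormalise every row.
apply_boosts <- function(kernel, planted_patterns) {
  for (pp in planted_patterns) {
    m <- parse_pattern(pp$pattern)
    for (i in seq_len(nrow(m))) {
      kernel[m[i, 1L], m[i, 2L]] <- kernel[m[i, 1L], m[i, 2L]] * pp$boost
    }
  }
  sweep(kernel, 1L, rowSums(kernel), "/")
}

category_pools <- function() {
  map <- read_category_map()
  split(map$category_id, type_to_code(map$activity_type))
}

#' Generate a synthetic check-in corpus
#'
#' Draws, for every user and day, a geometric check-in count, a Markov
#' type chain from the (boost-adjusted) kernel, ordered uniform timestamps
#' within the anchored day at minute precision, and a POI consistent with
#' each record's type (drawn mostly from the pool's popular head, sometimes
#' from its sparse tail). Output is byte-identical for equal seeds and uses
#' the same delimited layout [read_checkins()] reads.
#'
#' @param config a [simulation_config()].
#' @return raw check-in tibble (columns as [read_checkins()]; activity
#'   types unassigned, category ids covered by the shipped default map).
#' @export
generate_checkins <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  kernel <- apply_boosts(config$transition_kernel, config$planted_patterns)
  codes <- unname(activity_codes())
  pools <- category_pools()
  if (!is.null(config$n_pois_per_type)) {
    n_poi <- config$n_pois_per_type
    n_popular <- max(1L, round((1 - config$sparse_poi_fraction) * n_poi))
  } else {
    # expected records per type; popular POIs target ~25 check-ins each,
    # sparse ones ~3, so the min-check-in filter separates them cleanly
    per_type <- config$n_users * config$days / config$length_prob / 7
    n_popular <- max(2L, as.integer(round(0.9 * per_type / 25)))
    n_sparse <- max(3L, as.integer(round(0.1 * per_type / 3)))
    n_poi <- n_popular + n_sparse
  }
  poi_ids <- lapply(codes, function(cd) sprintf("%s_%03d", cd, seq_len(n_poi)))
  names(poi_ids) <- codes
  withr::with_seed(config$seed, {
    poi_lat <- stats::setNames(40.7 + stats::runif(7L * n_poi, -0.4, 0.4),
                               unlist(poi_ids))
    poi_lon <- stats::setNames(-74.0 + stats::runif(7L * n_poi, -0.4, 0.4),
                               unlist(poi_ids))
    out <- vector("list", config$n_users * config$days)
    slot <- 0L
    for (u in seq_len(config$n_users)) {
      uid <- sprintf("u%04d", u)
      for (d in seq_len(config$days)) {
        n <- min(1L + stats::rgeom(1L, config$length_prob), 50L)
        chain <- character(n)
        chain[1L] <- sample(codes, 1L, prob = config$type_marginals)
        if (n > 1L) {
          for (i in 2L:n) {
            chain[i] <- sample(codes, 1L, prob = kernel[chain[i - 1L], ])
          }
        }
        day_start <- as.POSIXct(
          paste0(config$start_date + (d - 1L), " ",
                 sprintf("%02d", config$boundary_hour), ":00:00"),
          tz = "UTC")
        mins <- sort(sample.int(24L * 60L, n, replace = FALSE)) - 1L
        stamp <- day_start + mins * 60
        poi <- vapply(chain, function(cd) {
          pool <- poi_ids[[cd]]
          if (stats::runif(1L) < 0.9) {
            pool[sample.int(n_popular, 1L)]
          } else {
            pool[n_popular + sample.int(n_poi - n_popular, 1L)]
          }
        }, "")
        cat_id <- vapply(chain, function(cd) {
          pool <- pools[[cd]]
          pool[sample.int(length(pool), 1L)]
        }, "")
        slot <- slot + 1L
        out[[slot]] <- tibble::tibble(
          user_id = uid,
          poi_id = unname(poi),
          lat = unname(poi_lat[poi]),
          lon = unname(poi_lon[poi]),
          timestamp = stamp,
          category_id = unname(cat_id),
          activity_type = NA_character_
        )
      }
    }
    dplyr::bind_rows(out)
  })
}

#' Hand-written fixture corpora
#'
#' Tiny, exhaustively hand-verifiable inputs used throughout the tests and
#' examples. `"paper_ring"` is the single five-item sequence
#' R, C, O, C, R (Residence to Community to Outdoors and back);
#' `"two_process"` is R, C, O, F, E, containing the two-process pattern
#' `"R>C,F>E"` non-adjacently; `"boundary"` returns CHECK-IN RECORDS (not
#' sequences) for one user straddling a 04:59 / 05:00 day boundary.
#'
#' @param name one of `"paper_ring"`, `"two_process"`, `"boundary"`.
#' @return a daily-sequence tibble, or a check-in tibble for
#'   `"boundary"`.
#' @export
make_fixture_corpus <- function(name) {
  switch(
    name,
    paper_ring = sequence_table(list(c("R", "C", "O", "C", "R"))),
    two_process = sequence_table(list(c("R", "C", "O", "F", "E"))),
    boundary = tibble::tibble(
      user_id = "u0001",
      poi_id = c("F_001", "F_001", "S_001"),
      lat = 40.7, lon = -74.0,
      timestamp = as.POSIXct(c("2010-01-02 04:59:00", "2010-01-02 05:00:00",
                               "2010-01-02 23:00:00"), tz = "UTC"),
      category_id = c("food", "food", "shopping"),
      activity_type = NA_character_
    ),
    stop("unknown fixture corpus: ", name, call. = FALSE)
  )
}

#' Build a daily-sequence table directly from type-code vectors
#'
#' Convenience constructor for tests and small examples: wraps lists of
#' one-letter code vectors in the container [build_daily_sequences()]
#' produces, bypassing the check-in stages. Adjacent duplicate codes are
#' rejected (real sequences are run-merged).
#'
#' @param types_list list of character vectors of one-letter codes, each of
#'   length >= 2.
#' @param user_id optional character vector of user ids (default one user
#'   per sequence).
#' @return daily-sequence tibble.
#' @examples
#' sequence_table(list(c("F", "S", "F"), c("R", "C")))
#' @export
sequence_table <- function(types_list, user_id = NULL) {
  stopifnot(is.list(types_list), all(lengths(types_list) >= 2L))
  for (ts in types_list) {
    if (any(ts[-1L] == ts[-length(ts)])) {
      stop("adjacent duplicate types; sequences must be run-merged",
           call. = FALSE)
    }
    stopifnot(all(ts %in% unname(activity_codes())))
  }
  n <- length(types_list)
  if (is.null(user_id)) user_id <- sprintf("u%04d", seq_len(n))
  anchor <- as.Date("2010-01-01") + seq_len(n) - 1L
  tibble::tibble(
    user_id = user_id,
    day_anchor = anchor,
    types = types_list,
    first_ts = lapply(seq_len(n), function(i) {
      as.POSIXct(paste(anchor[i], "08:00:00"), tz = "UTC") +
        (seq_along(types_list[[i]]) - 1L) * 3600
    }),
    length = lengths(types_list)
  )
}
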