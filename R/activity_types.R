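#' The seven activity types
#'
#' Check-in analyses in this package use a closed set of seven activity
#' types. Every typed check-in record, daily sequence item and pattern node
#' carries exactly one of them. The ordering below is the canonical ordering
#' used in all table exports.
#'
#' @return `activity_types()` returns the seven full type names in canonical
#'   order; `activity_codes()` returns the corresponding one-letter codes
#'   (`R`, `C`, `E`, `F`, `O`, `S`, `T`) used in pattern strings such as
#'   `"F>S,S>E"`.
#' @examples
#' activity_types()
#' activity_codes()
#' @export
activity_types <- function() {
  c("Residence", "Community", "Entertainment", "Food", "Outdoors",
    "Shopping", "Travel")
}

#' @rdname activity_types
#' @export
activity_codes <- function() {
  c(Residence = "R", Community = "C", Entertainment = "E", Food = "F",
    Outdoors = "O", Shopping = "S", Travel = "T")
}

#' Convert between activity type names and one-letter codes
#'
#' @param x character vector of type names (for `type_to_code()`) or
#'   one-letter codes (for `code_to_type()`).
#' @return character vector of the same length.
#' @examples
#' type_to_code(c("Food", "Shopping"))
#' code_to_type(c("F", "S"))
#' @export
type_to_code <- function(x) {
  codes <- activity_codes()
  out <- unname(codes[x])
  if (anyNA(out) && !anyNA(x)) {
    bad <- unique(x[is.na(codes[x])])
    stop("unknown activity type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @rdname type_to_code
#' @export
code_to_type <- function(x) {
  codes <- activity_codes()
  rev_map <- stats::setNames(names(codes), codes)
  out <- unname(rev_map[x])
  if (anyNA(out) && !anyNA(x)) {
    bad <- unique(x[is.na(rev_map[x])])
    stop("unknown activity code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

is_activity_type <- function(x) x %in% activity_types()
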