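#' Column schema for check-in tables
#'
#' Maps the canonical record fields onto the column names of a delimited
#' check-in file. The default matches the documented layout (`user_id`,
#' `poi_id`, `lat`, `lon`, `datetime`, `category_id`); deposits with other
#' headers are read by overriding individual entries, never by editing code.
#'
#' @param user_id,poi_id,lat,lon,datetime,category_id column names in the
#'   input file.
#' @return named character vector of length 6.
#' @examples
#' checkin_schema(datetime = "checkin_time")
#' @export
checkin_schema <- function(user_id = "user_id", poi_id = "poi_id",
                           lat = "lat", lon = "lon", datetime = "datetime",
                           category_id = "category_id") {
  c(user_id = user_id, poi_id = poi_id, lat = lat, lon = lon,
    datetime = datetime, category_id = category_id)
}

parse_wallclock <- function(x) {
  # Local wall-clock instants, minute precision; no timezone conversion.
  # UTC is used as a fixed label so arithmetic never crosses DST rules.
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  iso <- is.na(out) & !is.na(x)
  if (any(iso)) {
    out[iso] <- as.POSIXct(x[iso], tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  }
  short <- is.na(out) & !is.na(x)
  if (any(short)) {
    out[short] <- as.POSIXct(x[short], tz = "UTC", format = "%Y-%m-%d %H:%M")
  }
  out
}

#' Read a raw check-in table
#'
#' Reads a delimited check-in file into a tibble of check-in records with
#' parsed timestamps, preserving row order. Malformed rows (unparseable
#' timestamp, latitude or longitude out of range) are reported with their
#' line numbers; in strict mode any malformed row fails the run.
#'
#' @param path file path; must exist and carry a header row.
#' @param schema a [checkin_schema()].
#' @param delim field delimiter (default `","`).
#' @param strict if `TRUE` (default), malformed rows are an error; if
#'   `FALSE` they are dropped with a message.
#' @return tibble with columns `user_id`, `poi_id`, `lat`, `lon`,
#'   `timestamp` (POSIXct), `category_id`, `activity_type` (`NA` until
#'   [assign_activity_types()]).
#' @export
read_checkins <- function(path, schema = checkin_schema(), delim = ",",
                          strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  missing <- setdiff(unname(schema), names(raw))
  if (length(missing) > 0L) {
    stop("input is missing column(s) named in the schema: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    user_id = raw[[schema[["user_id"]]]],
    poi_id = raw[[schema[["poi_id"]]]],
    lat = suppressWarnings(as.numeric(raw[[schema[["lat"]]]])),
    lon = suppressWarnings(as.numeric(raw[[schema[["lon"]]]])),
    timestamp = parse_wallclock(raw[[schema[["datetime"]]]]),
    category_id = raw[[schema[["category_id"]]]],
    activity_type = NA_character_
  )
  bad_time <- which(is.na(out$timestamp))
  bad_coord <- which(is.na(out$lat) | is.na(out$lon) |
                       abs(out$lat) > 90 | abs(out$lon) > 180)
  bad <- sort(unique(c(bad_time, bad_coord)))
  if (length(bad) > 0L) {
    # +1 for the header row so numbers match the file as seen in an editor
    msg <- paste0("malformed row(s) at line ",
                  paste(bad + 1L, collapse = ", "),
                  " (bad timestamp or coordinate)")
    if (strict) stop(msg, call. = FALSE)
    message(msg, "; dropped ", length(bad), " row(s)")
    out <- out[-bad, ]
  }
  out
}

#' Write typed or untyped check-in records
#'
#' Inverse of [read_checkins()]: timestamps are serialised as
#' `YYYY-mm-dd HH:MM:SS` wall-clock strings so that a write/read round trip
#' is the identity on all fields.
#'
#' @param records check-in tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_checkins <- function(records, path) {
  out <- records
  out$datetime <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  out$timestamp <- NULL
  out <- out[, c("user_id", "poi_id", "lat", "lon", "datetime",
                 "category_id",
                 intersect("activity_type", names(out)))]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and validate a category-to-activity-type map
#'
#' A two-column delimited file mapping POI category identifiers to the
#' seven activity types. Every target must be one of [activity_types()] and
#' no category may map to two types. A default map covering the raw
#' first-level categories (with nightlife folded into Entertainment and a
#' set of residential subcategories mapped to Residence) ships with the
#' package.
#'
#' @param path map file path; `NULL` (default) loads the shipped map.
#' @param delim field delimiter.
#' @return tibble with columns `category_id`, `activity_type`.
#' @examples
#' head(read_category_map())
#' @export
read_category_map <- function(path = NULL, delim = ",") {
  if (is.null(path)) {
    path <- system.file("extdata", "default_category_map.csv",
                        package = "tamotif", mustWork = TRUE)
  }
  map <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  if (!all(c("category_id", "activity_type") %in% names(map))) {
    stop("category map needs columns category_id, activity_type",
         call. = FALSE)
  }
  map <- map[, c("category_id", "activity_type")]
  bad <- !is_activity_type(map$activity_type)
  if (any(bad)) {
    stop("category map targets outside the seven activity types: ",
         paste(unique(map$activity_type[bad]), collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(map$category_id[duplicated(map$category_id)])
  conflicting <- dup[vapply(dup, function(d) {
    length(unique(map$activity_type[map$category_id == d])) > 1L
  }, TRUE)]
  if (length(conflicting) > 0L) {
    stop("category mapped to two types: ",
         paste(conflicting, collapse = ", "), call. = FALSE)
  }
  dplyr::distinct(map)
}

#' Assign activity types to check-in records
#'
#' Per-record, order-independent lookup of each record's `category_id` in
#' the category map. Unmapped categories are handled by `default_policy`:
#' `"error"` aborts listing the offending categories, `"drop"` removes the
#' records (count reported via message and the `dropped` attribute),
#' `"fallback"` assigns `fallback_type`.
#'
#' @param records check-in tibble from [read_checkins()].
#' @param map tibble from [read_category_map()].
#' @param default_policy one of `"error"`, `"drop"`, `"fallback"`.
#' @param fallback_type activity type used when `default_policy =
#'   "fallback"`.
#' @return the records with `activity_type` filled in; attribute `dropped`
#'   holds the number of records removed under the drop policy.
#' @export
assign_activity_types <- function(records, map = read_category_map(),
                                  default_policy = c("error", "drop", "fallback"),
                                  fallback_type = NULL) {
  default_policy <- match.arg(default_policy)
  lookup <- stats::setNames(map$activity_type, map$category_id)
  typed <- unname(lookup[records$category_id])
  unmapped <- is.na(typed) & !is.na(records$category_id)
  n_dropped <- 0L
  if (any(unmapped)) {
    cats <- unique(records$category_id[unmapped])
    if (default_policy == "error") {
      stop("unmapped category id(s): ", paste(cats, collapse = ", "),
           call. = FALSE)
    } else if (default_policy == "drop") {
      n_dropped <- sum(unmapped)
      message("dropped ", n_dropped, " record(s) with unmapped categories: ",
              paste(cats, collapse = ", "))
      records <- records[!unmapped, ]
      typed <- typed[!unmapped]
    } else {
      if (is.null(fallback_type) || !is_activity_type(fallback_type)) {
        stop("fallback policy needs a valid fallback_type", call. = FALSE)
      }
      typed[unmapped] <- fallback_type
    }
  }
  records$activity_type <- typed
  attr(records, "dropped") <- n_dropped
  records
}
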