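# Shared fixture builders: everything is generated in code at test time.

# A random run-merged sequence of one-letter codes (adjacent types differ).
rand_merged_seq <- function(len) {
  codes <- unname(activity_codes())
  out <- character(len)
  out[1L] <- sample(codes, 1L)
  for (i in seq_len(len - 1L) + 1L) {
    out[i] <- sample(setdiff(codes, out[i - 1L]), 1L)
  }
  out
}

# A small check-in tibble built by hand; times are minutes after the given
# wall-clock start.
checkin_fixture <- function(user_id, minutes, poi_id = "F_001",
                            category_id = "food",
                            start = "2010-01-01 12:00:00") {
  t0 <- as.POSIXct(start, tz = "UTC")
  tibble::tibble(
    user_id = user_id,
    poi_id = poi_id,
    lat = 40.7,
    lon = -74.0,
    timestamp = t0 + minutes * 60,
    category_id = category_id,
    activity_type = NA_character_
  )
}

# Write a raw check-in CSV with the default column layout.
write_raw_csv <- function(rows, path) {
  writeLines(c("user_id,poi_id,lat,lon,datetime,category_id", rows), path)
  path
}
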