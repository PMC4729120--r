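# Domain tables and CSV readers/writers.
#
# Three plain-text tables drive the pipeline:
#   receivers.csv  station_id,name,lat,lon,region,coast_order,active_from,active_to
#   tags.csv       tag_id,burst_interval_s,bird_id,age,sex,deploy_time,expected_life_days
#   detections.csv ts,tag_id,station_id,antenna_id,signal
# Timestamps are ISO-8601 with an explicit zone designator and are stored as
# POSIXct in UTC.  Region membership is an input attribute of each station
# (a study-design label), never inferred from coordinates.

#' Receiver region labels, ordered along the fall migration axis
#' @export
REGIONS <- c("SABLE", "NS_COAST", "BPI", "GULF_NORTH", "GULF_SOUTH", "CAPE_COD")

#' Age classes
#' @export
AGES <- c("ADULT", "JUVENILE")

#' Route classes assigned to tracks
#' @export
ROUTE_CLASSES <- c("NOT_DETECTED_MAINLAND", "NS_ONLY", "GULF_VIA_NORTH",
                   "GULF_VIA_SOUTH", "PRESUMED_DIRECT_SOUTH")

# -- timestamps ---------------------------------------------------------------

#' Parse ISO-8601 timestamps to POSIXct (UTC)
#'
#' Accepts a trailing \code{Z} or a numeric zone offset (\code{+HH:MM} or
#' \code{+HHMM}).  Unparseable values are a hard error naming the offending
#' value.
#' @param x character vector
#' @return POSIXct vector in UTC
#' @export
parse_ts <- function(x) {
  x0 <- as.character(x)
  y <- sub("Z$", "+0000", x0)
  y <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", y)
  out <- as.POSIXct(y, format = "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC")
  # fall back: bare timestamp without zone is taken as UTC
  bare <- is.na(out)
  if (any(bare))
    out[bare] <- as.POSIXct(y[bare], format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (anyNA(out) & !all(is.na(x0[is.na(out)])))
    stop("unparseable timestamp(s): ",
         paste(utils::head(x0[is.na(out) & !is.na(x0)], 3), collapse = ", "))
  out
}

#' Format POSIXct as ISO-8601 UTC
#' @param ts POSIXct vector
#' @return character vector like \code{2013-10-03T02:10:00Z}
#' @export
format_ts <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Local calendar date of a UTC timestamp
#'
#' Applies the configured display offset (default UTC-3, Atlantic Daylight
#' Time) before truncating to a date, so that nocturnal events shortly after
#' midnight UTC fall on the local evening's date.
#' @param ts POSIXct (UTC)
#' @param tz_offset_h offset from UTC in hours
#' @return Date vector
#' @export
local_date <- function(ts, tz_offset_h = -3) {
  as.Date(ts + tz_offset_h * 3600, tz = "UTC")
}

# -- receivers ----------------------------------------------------------------

.validate_receivers <- function(df) {
  req <- c("station_id", "name", "lat", "lon", "region", "coast_order",
           "active_from", "active_to")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("receivers: missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(df)
  bad <- which(!is.finite(df$lat) | df$lat < -90 | df$lat > 90 |
               !is.finite(df$lon) | df$lon < -180 | df$lon > 180)
  if (length(bad))
    stop("receivers: malformed coordinates in row(s) ",
         paste(bad, collapse = ", "), " (station ",
         paste(df$station_id[bad], collapse = ", "), ")")
  dup <- df$station_id[duplicated(df$station_id)]
  if (length(dup)) stop("receivers: duplicate station_id: ",
                        paste(unique(dup), collapse = ", "))
  if (!all(df$region %in% REGIONS))
    stop("receivers: unknown region: ",
         paste(setdiff(unique(df$region), REGIONS), collapse = ", "))
  if (any(df$active_from >= df$active_to))
    stop("receivers: active_from must precede active_to (station ",
         paste(df$station_id[df$active_from >= df$active_to], collapse = ", "),
         ")")
  if (anyDuplicated(df$coast_order))
    stop("receivers: coast_order must be unique along the chain")
  df
}

#' Read the receiver-station table
#'
#' @param path CSV file with header
#'   \code{station_id,name,lat,lon,region,coast_order,active_from,active_to}
#' @return validated data.frame (timestamps parsed to POSIXct UTC)
#' @export
read_receivers <- function(path) {
  if (!file.exists(path)) stop("receivers file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(station_id = "character"))
  df$active_from <- parse_ts(df$active_from)
  df$active_to <- parse_ts(df$active_to)
  .validate_receivers(df)
}

#' Write the receiver-station table
#' @param receivers validated receiver data.frame
#' @param path output CSV path
#' @export
write_receivers <- function(receivers, path) {
  out <- receivers
  out$active_from <- format_ts(out$active_from)
  out$active_to <- format_ts(out$active_to)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# -- tags ---------------------------------------------------------------------

.validate_tags <- function(df) {
  req <- c("tag_id", "burst_interval_s", "bird_id", "age", "sex",
           "deploy_time", "expected_life_days")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("tags: missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(df)
  if (any(!is.finite(df$burst_interval_s) | df$burst_interval_s <= 0))
    stop("tags: burst_interval_s must be > 0 (tag ",
         paste(df$tag_id[!is.finite(df$burst_interval_s) |
                         df$burst_interval_s <= 0], collapse = ", "), ")")
  dup <- df$tag_id[duplicated(df$tag_id)]
  if (length(dup)) stop("tags: duplicate tag_id (one active deployment per ",
                        "tag): ", paste(unique(dup), collapse = ", "))
  if (anyNA(df$age) || !all(df$age %in% AGES))
    stop("tags: age must be one of ", paste(AGES, collapse = "/"))
  if (!all(df$sex %in% c("M", "F", "UNKNOWN")))
    stop("tags: sex must be M/F/UNKNOWN")
  df
}

#' Read the tag-deployment table
#' @param path CSV file with header
#'   \code{tag_id,burst_interval_s,bird_id,age,sex,deploy_time,expected_life_days}
#' @return validated data.frame
#' @export
read_tags <- function(path) {
  if (!file.exists(path)) stop("tags file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(tag_id = "character",
                                       bird_id = "character"))
  df$deploy_time <- parse_ts(df$deploy_time)
  .validate_tags(df)
}

#' Write the tag-deployment table
#' @param tags validated tag data.frame
#' @param path output CSV path
#' @export
write_tags <- function(tags, path) {
  out <- tags
  out$deploy_time <- format_ts(out$deploy_time)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# -- detections ---------------------------------------------------------------

#' Sort detections by (tag, time); ties by station then antenna
#' @param det detection data.frame
#' @return sorted data.frame (row names dropped)
#' @export
sort_detections <- function(det) {
  ord <- order(det$tag_id, det$ts, det$station_id, det$antenna_id,
               method = "radix")
  out <- det[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read raw detection records
#'
#' Records naming a tag or station absent from the registries cannot be
#' placed on the array and are dropped; the number dropped is reported via a
#' message and attached as attribute \code{n_dropped}.  Output is sorted by
#' (tag_id, ts) with ties broken by station_id then antenna_id.
#'
#' @param path CSV file with header \code{ts,tag_id,station_id,antenna_id,signal}
#' @param receivers validated receiver table (registry)
#' @param tags validated tag table (registry)
#' @return sorted data.frame of detections with attribute \code{n_dropped}
#' @export
read_detections <- function(path, receivers, tags) {
  if (!file.exists(path)) stop("detections file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(tag_id = "character",
                                       station_id = "character",
                                       antenna_id = "character"))
  df$ts <- parse_ts(df$ts)
  keep <- df$tag_id %in% tags$tag_id & df$station_id %in% receivers$station_id
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("read_detections: dropped ", n_dropped,
            " record(s) with unknown tag or station")
  out <- sort_detections(df[keep, , drop = FALSE])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write detection records
#' @param detections detection data.frame
#' @param path output CSV path
#' @export
write_detections <- function(detections, path) {
  out <- detections[, c("ts", "tag_id", "station_id", "antenna_id", "signal")]
  out$ts <- format_ts(out$ts)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
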