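# Burst-interval detection filtering.
#
# Coded tags transmit every b seconds, so genuine receptions of one tag at
# one station arrive on a fixed time grid.  Receiver noise decoded as a tag
# does not.  Chaining detections whose successive gaps match the tag's burst
# interval and keeping only chains of >= 3 removes essentially all false
# positives at the cost of discarding brief genuine contacts.

#' Group detections into candidate runs
#'
#' Builds maximal chains of detections of one tag at one station in which
#' every successive gap g satisfies |g - b| <= \code{burst_tolerance_s} for
#' that tag's burst interval b (optionally also |g - 2b|, bridging one
#' missed burst, when \code{allow_skip}).  Singletons become length-1
#' candidates, so the candidates partition the input detections.
#'
#' @param detections sorted detection data.frame (see
#'   \code{\link{read_detections}})
#' @param tags tag table giving \code{burst_interval_s} per tag
#' @param burst_tolerance_s gap tolerance in seconds (default 0.2)
#' @param allow_skip allow a chain to bridge a single missed burst
#' @return data.frame of candidate runs: \code{run_id, tag_id, station_id,
#'   start_ts, end_ts, n_detections}, plus attribute \code{membership}
#'   mapping each input detection row to its run, and \code{n_unknown_tags}
#'   counting skipped detections of unregistered tags
#' @export
group_candidate_runs <- function(detections, tags, burst_tolerance_s = 0.2,
                                 allow_skip = FALSE) {
  det <- sort_detections(detections)
  known <- det$tag_id %in% tags$tag_id
  n_unknown <- sum(!known)
  if (n_unknown > 0)
    message("group_candidate_runs: skipped ", n_unknown,
            " detection(s) of unknown tags")
  det <- det[known, , drop = FALSE]
  n <- nrow(det)
  if (n == 0) {
    out <- data.frame(run_id = integer(), tag_id = character(),
                      station_id = character(), start_ts = parse_ts(character()),
                      end_ts = parse_ts(character()), n_detections = integer())
    attr(out, "membership") <- integer()
    attr(out, "n_unknown_tags") <- n_unknown
    return(out)
  }
  # chains live within one tag at one station: a bird in range of two
  # stations at once interleaves detections in the time-sorted log, so the
  # grouping must be per (tag, station), not per consecutive log rows
  ord <- order(det$tag_id, det$station_id, det$ts, det$antenna_id,
               method = "radix")
  det <- det[ord, , drop = FALSE]
  b <- tags$burst_interval_s[match(det$tag_id, tags$tag_id)]
  ts <- as.numeric(det$ts)
  gap <- c(NA, diff(ts))
  same <- c(FALSE, det$tag_id[-1] == det$tag_id[-n] &
                   det$station_id[-1] == det$station_id[-n])
  ok_gap <- abs(gap - b) <= burst_tolerance_s
  # zero gap at one station = the same burst heard on another antenna
  ok_gap <- ok_gap | gap == 0
  if (allow_skip) ok_gap <- ok_gap | abs(gap - 2 * b) <= burst_tolerance_s
  chain <- same & ok_gap
  chain[is.na(chain)] <- FALSE
  run_id <- cumsum(!chain)
  out <- data.frame(
    run_id = unique(run_id),
    tag_id = det$tag_id[!chain],
    station_id = det$station_id[!chain],
    start_ts = det$ts[!chain],
    n_detections = as.integer(tabulate(run_id)),
    stringsAsFactors = FALSE)
  # last detection of each run (input is sorted, so the max per run)
  out$end_ts <- .POSIXct(vapply(split(ts, run_id), max, numeric(1)),
                         tz = "UTC")
  out <- out[, c("run_id", "tag_id", "station_id", "start_ts", "end_ts",
                 "n_detections")]
  rownames(out) <- NULL
  attr(out, "membership") <- run_id
  attr(out, "n_unknown_tags") <- n_unknown
  out
}

#' Accept candidate runs of sufficient length
#'
#' Runs with at least \code{min_run} detections (default 3 consecutive
#' bursts) are accepted; shorter candidates are held for the optional
#' 2-detection rescue.
#'
#' @param candidates output of \code{\link{group_candidate_runs}}
#' @param min_run minimum run length (default 3)
#' @return list with data.frames \code{accepted} (with \code{rescued =
#'   FALSE}) and \code{held}
#' @export
filter_runs <- function(candidates, min_run = 3) {
  acc <- candidates[candidates$n_detections >= min_run, , drop = FALSE]
  held <- candidates[candidates$n_detections < min_run, , drop = FALSE]
  if (nrow(acc)) acc$rescued <- FALSE
  else acc$rescued <- logical(0)
  rownames(acc) <- rownames(held) <- NULL
  list(accepted = acc, held = held)
}

#' Rescue plausible 2-detection runs
#'
#' The published analysis hand-checked a few 2-detection sets and kept those
#' consistent with the bird's movement.  This automates that judgement with
#' explicit criteria: a held 2-detection candidate is accepted iff (a) its
#' internal gap matches the tag's burst interval within tolerance, and (b)
#' relative to the nearest accepted runs of the same tag before and after it
#' in time, the implied ground speeds are at most \code{max_speed_mps} and
#' the candidate's station lies between theirs in \code{coast_order}.
#' Disabled by default (\code{rescue_enabled} in
#' \code{\link{study_config}}).
#'
#' @param held held candidates from \code{\link{filter_runs}}
#' @param accepted accepted runs (fixed; not re-evaluated)
#' @param tags tag table
#' @param receivers receiver table (coordinates and coast order)
#' @param max_speed_mps maximum plausible ground speed
#' @param burst_tolerance_s gap tolerance in seconds
#' @return data.frame of additionally accepted runs with \code{rescued = TRUE}
#' @export
rescue_two_detection_runs <- function(held, accepted, tags, receivers,
                                      max_speed_mps = 25,
                                      burst_tolerance_s = 0.2) {
  res <- held[0, , drop = FALSE]
  if (nrow(held) == 0 || nrow(accepted) == 0) {
    res$rescued <- logical(0)
    return(res)
  }
  two <- held[held$n_detections == 2, , drop = FALSE]
  keep <- logical(nrow(two))
  for (i in seq_len(nrow(two))) {
    cand <- two[i, ]
    b <- tags$burst_interval_s[match(cand$tag_id, tags$tag_id)]
    gap <- as.numeric(cand$end_ts) - as.numeric(cand$start_ts)
    if (is.na(b) || abs(gap - b) > burst_tolerance_s) next
    acc <- accepted[accepted$tag_id == cand$tag_id, , drop = FALSE]
    before <- acc[acc$end_ts <= cand$start_ts, , drop = FALSE]
    after <- acc[acc$start_ts >= cand$end_ts, , drop = FALSE]
    if (nrow(before) == 0 || nrow(after) == 0) next
    prev <- before[which.max(as.numeric(before$end_ts)), ]
    nxt <- after[which.min(as.numeric(after$start_ts)), ]
    ri <- match(c(prev$station_id, cand$station_id, nxt$station_id),
                receivers$station_id)
    if (anyNA(ri)) next
    co <- receivers$coast_order[ri]
    between <- (co[2] >= min(co[1], co[3])) && (co[2] <= max(co[1], co[3]))
    sp_in <- if (cand$station_id == prev$station_id) 0 else
      ground_speed(receivers$lat[ri[1]], receivers$lon[ri[1]],
                   receivers$lat[ri[2]], receivers$lon[ri[2]],
                   prev$end_ts, cand$start_ts)
    sp_out <- if (cand$station_id == nxt$station_id) 0 else
      ground_speed(receivers$lat[ri[2]], receivers$lon[ri[2]],
                   receivers$lat[ri[3]], receivers$lon[ri[3]],
                   cand$end_ts, nxt$start_ts)
    keep[i] <- between && sp_in <= max_speed_mps && sp_out <= max_speed_mps
  }
  res <- two[keep, , drop = FALSE]
  if (nrow(res)) res$rescued <- TRUE else res$rescued <- logical(0)
  rownames(res) <- NULL
  res
}

#' Full detection-filtering stage
#'
#' Convenience wrapper: group candidates, accept runs of >= \code{min_run},
#' optionally apply the 2-detection rescue.  Returns accepted runs sorted by
#' (tag, start time).
#'
#' @param detections sorted detection table
#' @param tags tag table
#' @param receivers receiver table (needed only when rescue is enabled)
#' @param config \code{\link{study_config}}
#' @return data.frame of accepted detection runs
#' @export
filter_detections <- function(detections, tags, receivers = NULL,
                              config = study_config()) {
  cand <- group_candidate_runs(detections, tags,
                               burst_tolerance_s = config$burst_tolerance_s,
                               allow_skip = config$allow_skip)
  fr <- filter_runs(cand, min_run = config$min_run)
  acc <- fr$accepted
  if (config$rescue_enabled) {
    if (is.null(receivers))
      stop("filter_detections: rescue requires the receiver table")
    resc <- rescue_two_detection_runs(fr$held, acc, tags, receivers,
                                      max_speed_mps = config$max_speed_mps,
                                      burst_tolerance_s =
                                        config$burst_tolerance_s)
    acc <- rbind(acc, resc)
  }
  acc <- acc[order(acc$tag_id, acc$start_ts), , drop = FALSE]
  rownames(acc) <- NULL
  acc
}
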