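# Track segmentation: departure, flights, stopovers, reversals, routes.
#
# Accepted detection runs for one bird are assembled in time order.
# Departure is the local date of first mainland detection.  Consecutive runs
# at different stations become flight segments with rhumb-line geometry.
# Stopovers follow the published operational rules: a detection span > 8 h
# at one receiver with nothing heard elsewhere, or a gap > 10 h between
# adjacent receivers along the coastal chain.  Movement toward the
# northeast sector is a reverse migration.  Detections at Cape Cod are
# excluded from stopover statistics (spans > 16 days there mark a completed
# migration), and detections on Sable Island itself are pre-departure
# residence, not migration stopover.

.station_lookup <- function(receivers) {
  receivers[order(receivers$coast_order), ]
}

.runs_with_stations <- function(runs, receivers) {
  i <- match(runs$station_id, receivers$station_id)
  if (anyNA(i))
    stop("runs reference unknown station(s): ",
         paste(unique(runs$station_id[is.na(i)]), collapse = ", "))
  runs$lat <- receivers$lat[i]
  runs$lon <- receivers$lon[i]
  runs$region <- receivers$region[i]
  runs$coast_order <- receivers$coast_order[i]
  runs
}

.leg_label <- function(from_region, to_region) {
  ns <- c("NS_COAST", "BPI")
  if (from_region == "SABLE" && to_region %in% ns) return("SABLE_TO_NS")
  if (from_region %in% ns && to_region %in% ns) return("WITHIN_NS")
  if (from_region == "BPI" &&
      to_region %in% c("GULF_NORTH", "GULF_SOUTH")) return("GULF_CROSSING")
  "OTHER"
}

#' Assemble one bird's track from its accepted runs
#'
#' Orders the runs, derives flight segments between consecutive runs at
#' different stations (with rhumb-line distance, bearing and ground speed),
#' assigns leg labels from the region pair, and classifies the route:
#' \itemize{
#'   \item \code{NOT_DETECTED_MAINLAND}: runs only on Sable Island;
#'   \item \code{GULF_VIA_NORTH} / \code{GULF_VIA_SOUTH}: first Gulf of
#'     Maine detection in the northern / southern group;
#'   \item \code{PRESUMED_DIRECT_SOUTH}: final Nova Scotia detection at BPI
#'     with no Gulf detection afterwards (flag \code{censored = TRUE}: a
#'     direct overwater flight beyond the array and an unsuccessful crossing
#'     are indistinguishable);
#'   \item \code{NS_ONLY}: mainland Nova Scotia detections only, ending away
#'     from BPI.
#' }
#'
#' @param runs_for_bird accepted runs of one bird's tag
#' @param receivers receiver table
#' @param tags tag table (age lookup)
#' @param config \code{\link{study_config}}
#' @return object of class \code{bird_track}: list with \code{bird_id},
#'   \code{age}, \code{runs}, \code{flights}, \code{departure_date},
#'   \code{last_ns_date}, \code{route_class}, \code{final_ns_station},
#'   \code{censored}, \code{cape_span_days}, \code{migration_complete}
#' @export
build_track <- function(runs_for_bird, receivers, tags,
                        config = study_config()) {
  if (nrow(runs_for_bird) == 0) stop("build_track: no runs")
  tag <- unique(runs_for_bird$tag_id)
  if (length(tag) != 1) stop("build_track: runs span multiple tags")
  ti <- match(tag, tags$tag_id)
  if (is.na(ti)) stop("build_track: unknown tag ", tag)
  runs <- .runs_with_stations(runs_for_bird, receivers)
  runs <- runs[order(runs$start_ts), , drop = FALSE]
  rownames(runs) <- NULL
  # warn (retain) if a run falls outside its station's operational window
  off <- runs$start_ts < receivers$active_from[match(runs$station_id,
                                                     receivers$station_id)] |
         runs$end_ts > receivers$active_to[match(runs$station_id,
                                                 receivers$station_id)]
  if (any(off))
    warning("build_track: ", sum(off), " run(s) outside station's ",
            "operational period (retained)")
  n <- nrow(runs)
  flights <- NULL
  if (n > 1) {
    moved <- which(runs$station_id[-n] != runs$station_id[-1])
    if (length(moved)) {
      i <- moved; j <- moved + 1
      dist <- rhumb_distance(runs$lat[i], runs$lon[i], runs$lat[j], runs$lon[j])
      brg <- rhumb_bearing(runs$lat[i], runs$lon[i], runs$lat[j], runs$lon[j])
      dt <- as.numeric(runs$start_ts[j]) - as.numeric(runs$end_ts[i])
      # overlapping detection windows (both stations in range at once) give
      # no measurable transit time: geometry is kept, speed is undefined
      spd <- ifelse(dt > 0, dist * 1000 / dt, NA_real_)
      flights <- data.frame(
        bird_id = tags$bird_id[ti],
        from_station = runs$station_id[i], to_station = runs$station_id[j],
        depart_ts = runs$end_ts[i], arrive_ts = runs$start_ts[j],
        distance_km = dist, bearing_deg = brg, speed_mps = spd,
        direct = spd >= config$direct_speed_mps,
        leg = mapply(.leg_label, runs$region[i], runs$region[j]),
        stringsAsFactors = FALSE)
    }
  }
  if (is.null(flights))
    flights <- data.frame(bird_id = character(), from_station = character(),
                          to_station = character(),
                          depart_ts = parse_ts(character()),
                          arrive_ts = parse_ts(character()),
                          distance_km = numeric(), bearing_deg = numeric(),
                          speed_mps = numeric(), direct = logical(),
                          leg = character())
  mainland <- runs$region != "SABLE"
  ns <- runs$region %in% c("NS_COAST", "BPI")
  gulf <- runs$region %in% c("GULF_NORTH", "GULF_SOUTH")
  cape <- runs$region == "CAPE_COD"
  departure_date <- if (any(mainland))
    local_date(min(runs$start_ts[mainland]), config$tz_offset_h) else
      as.Date(NA)
  last_ns_date <- if (any(ns))
    local_date(max(runs$end_ts[ns]), config$tz_offset_h) else as.Date(NA)
  final_ns_station <- if (any(ns))
    runs$station_id[max(which(ns))] else NA_character_
  cape_span <- if (any(cape))
    as.numeric(max(runs$end_ts[cape]) - min(runs$start_ts[cape]),
               units = "days") else NA_real_
  route_class <- if (!any(mainland)) {
    "NOT_DETECTED_MAINLAND"
  } else if (any(gulf)) {
    first_gulf <- runs$region[min(which(gulf))]
    if (first_gulf == "GULF_NORTH") "GULF_VIA_NORTH" else "GULF_VIA_SOUTH"
  } else if (!is.na(final_ns_station) &&
             runs$region[max(which(ns))] == "BPI") {
    "PRESUMED_DIRECT_SOUTH"
  } else {
    "NS_ONLY"
  }
  censored <- route_class == "PRESUMED_DIRECT_SOUTH"
  structure(list(
    bird_id = tags$bird_id[ti], age = tags$age[ti], tag_id = tag,
    runs = runs, flights = flights, departure_date = departure_date,
    last_ns_date = last_ns_date, route_class = route_class,
    final_ns_station = final_ns_station, censored = censored,
    cape_span_days = cape_span,
    migration_complete = !is.na(cape_span) &&
      cape_span > config$cape_complete_days),
    class = "bird_track")
}

#' @export
print.bird_track <- function(x, ...) {
  cat("<bird_track>", x$bird_id, "(", x$age, ")\n")
  cat("  runs:", nrow(x$runs), " route:", x$route_class,
      " departure:", format(x$departure_date), "\n")
  invisible(x)
}

#' Departure date of a track
#'
#' Local calendar date (display offset applied) of the earliest run at a
#' non-Sable station; \code{NA} when the bird was never detected on the
#' mainland.  First mainland detection is used as the departure proxy, which
#' assumes the initial overwater flight is made promptly after leaving the
#' island.
#'
#' @param track a \code{bird_track}
#' @param tz_offset_h display offset from UTC in hours
#' @return Date (possibly NA)
#' @export
departure_date <- function(track, tz_offset_h = -3) {
  mainland <- track$runs$region != "SABLE"
  if (!any(mainland)) return(as.Date(NA))
  local_date(min(track$runs$start_ts[mainland]), tz_offset_h)
}

#' Detect stopover events along a track
#'
#' Two operational rules: (a) a maximal period of detections at one station
#' with no intervening detections elsewhere whose span exceeds
#' \code{same_recv_h} (8 h) is a \code{SAME_RECEIVER} stopover; (b) a gap
#' exceeding \code{adjacent_h} (10 h) between consecutive runs at adjacent
#' stations (|coast_order difference| = 1) is an \code{ADJACENT_GAP}
#' stopover located at the earlier station, with duration equal to the full
#' gap.  Periods at Cape Cod are excluded (overwintering, not stopover);
#' periods on Sable Island are pre-departure residence and likewise
#' excluded.
#'
#' @param track a \code{bird_track}
#' @param same_recv_h same-receiver span threshold (hours)
#' @param adjacent_h adjacent-receiver gap threshold (hours)
#' @return data.frame of stopover events: \code{bird_id, station_id,
#'   start_ts, end_ts, duration_days, kind}
#' @export
detect_stopovers <- function(track, same_recv_h = 8, adjacent_h = 10) {
  runs <- track$runs
  empty <- data.frame(bird_id = character(), station_id = character(),
                      start_ts = parse_ts(character()),
                      end_ts = parse_ts(character()),
                      duration_days = numeric(), kind = character())
  if (nrow(runs) == 0) return(empty)
  # (a) same-receiver periods: group maximal blocks of equal station
  blk <- cumsum(c(TRUE, runs$station_id[-1] != runs$station_id[-nrow(runs)]))
  ev <- lapply(split(seq_len(nrow(runs)), blk), function(ix) {
    span_h <- as.numeric(runs$end_ts[ix[length(ix)]] - runs$start_ts[ix[1]],
                         units = "hours")
    reg <- runs$region[ix[1]]
    if (span_h > same_recv_h && !(reg %in% c("CAPE_COD", "SABLE")))
      data.frame(bird_id = track$bird_id, station_id = runs$station_id[ix[1]],
                 start_ts = runs$start_ts[ix[1]],
                 end_ts = runs$end_ts[ix[length(ix)]],
                 duration_days = span_h / 24, kind = "SAME_RECEIVER",
                 stringsAsFactors = FALSE)
    else NULL
  })
  # (b) adjacent-receiver gaps, measured between consecutive station blocks
  firsts <- vapply(split(seq_len(nrow(runs)), blk), function(ix) ix[1], 1L)
  lasts <- vapply(split(seq_len(nrow(runs)), blk), function(ix)
    ix[length(ix)], 1L)
  nb <- length(firsts)
  gaps <- NULL
  if (nb > 1) {
    i <- lasts[-nb]; j <- firsts[-1]
    gap_h <- as.numeric(runs$start_ts[j]) - as.numeric(runs$end_ts[i])
    gap_h <- gap_h / 3600
    adj <- abs(runs$coast_order[j] - runs$coast_order[i]) == 1
    sel <- which(adj & gap_h > adjacent_h &
                 !(runs$region[i] %in% c("CAPE_COD", "SABLE")))
    if (length(sel))
      gaps <- data.frame(bird_id = track$bird_id,
                         station_id = runs$station_id[i[sel]],
                         start_ts = runs$end_ts[i[sel]],
                         end_ts = runs$start_ts[j[sel]],
                         duration_days = gap_h[sel] / 24,
                         kind = "ADJACENT_GAP", stringsAsFactors = FALSE)
  }
  out <- rbind(do.call(rbind, ev), gaps)
  if (is.null(out) || nrow(out) == 0) return(empty)
  out <- out[order(out$start_ts), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect reverse-migration events
#'
#' Each consecutive pair of runs at different stations whose rhumb bearing
#' falls inside the northeast sector \code{(lo, hi]} (default (0, 90]) is a
#' reversal.  Context is \code{PRE_STOPOVER} when a stopover begins at the
#' destination on arrival, \code{POST_STOPOVER} when one ended at the
#' origin on departure, otherwise \code{OTHER}.
#'
#' @param track a \code{bird_track}
#' @param stopovers stopover events of this track (for context); detected on
#'   the fly when \code{NULL}
#' @param ne_sector numeric length-2 half-open bearing sector, degrees
#' @return data.frame: \code{bird_id, from_station, to_station,
#'   displacement_km, bearing_deg, context}
#' @export
detect_reversals <- function(track, stopovers = NULL, ne_sector = c(0, 90)) {
  if (is.null(stopovers)) stopovers <- detect_stopovers(track)
  fl <- track$flights
  empty <- data.frame(bird_id = character(), from_station = character(),
                      to_station = character(), displacement_km = numeric(),
                      bearing_deg = numeric(), context = character())
  if (nrow(fl) == 0) return(empty)
  # reverse migration is movement along the coastal migration axis; hops
  # between the closely spaced towers on Sable Island itself are
  # pre-departure (island) movement, not reversals
  region_of <- stats::setNames(track$runs$region, track$runs$station_id)
  on_island <- region_of[fl$from_station] == "SABLE" &
    region_of[fl$to_station] == "SABLE"
  fl <- fl[!on_island, , drop = FALSE]
  if (nrow(fl) == 0) return(empty)
  ne <- fl$bearing_deg > ne_sector[1] & fl$bearing_deg <= ne_sector[2]
  if (!any(ne)) return(empty)
  fl <- fl[ne, , drop = FALSE]
  ctx <- vapply(seq_len(nrow(fl)), function(i) {
    pre <- any(stopovers$station_id == fl$to_station[i] &
               abs(as.numeric(stopovers$start_ts) -
                   as.numeric(fl$arrive_ts[i])) < 1)
    post <- any(stopovers$station_id == fl$from_station[i] &
                abs(as.numeric(stopovers$end_ts) -
                    as.numeric(fl$depart_ts[i])) < 1)
    if (pre) "PRE_STOPOVER" else if (post) "POST_STOPOVER" else "OTHER"
  }, character(1))
  data.frame(bird_id = track$bird_id, from_station = fl$from_station,
             to_station = fl$to_station, displacement_km = fl$distance_km,
             bearing_deg = fl$bearing_deg, context = ctx,
             stringsAsFactors = FALSE)
}

#' Eligibility of a track's overwater-crossing bearing
#'
#' Bearings are only meaningful when the bird crossed promptly and, for the
#' Gulf of Maine, from the southwestern terminus (BPI): a final Nova Scotia
#' detection northeast of BPI admits a partially overland route whose
#' receiver-to-receiver bearing would not be a true overwater heading.
#'
#' @param track a \code{bird_track}
#' @param leg \code{"SABLE_TO_NS"} or \code{"GULF_CROSSING"}
#' @param max_delay_h maximum hours between last pre-crossing and first
#'   post-crossing detection (default 100)
#' @return list: \code{eligible} (logical), \code{reason} (\code{NA},
#'   \code{"DELAY_EXCEEDED"}, \code{"NOT_BPI"}, \code{"NO_ARRIVAL"}),
#'   \code{bearing_deg}, \code{from_station}, \code{to_station},
#'   \code{delay_h}
#' @export
crossing_bearing_eligibility <- function(track, leg = c("SABLE_TO_NS",
                                                        "GULF_CROSSING"),
                                         max_delay_h = 100) {
  leg <- match.arg(leg)
  runs <- track$runs
  res <- function(eligible, reason = NA_character_, bearing = NA_real_,
                  from = NA_character_, to = NA_character_,
                  delay = NA_real_) {
    list(eligible = eligible, reason = reason, bearing_deg = bearing,
         from_station = from, to_station = to, delay_h = delay)
  }
  if (leg == "SABLE_TO_NS") {
    sab <- which(runs$region == "SABLE")
    main <- which(runs$region != "SABLE")
    if (!length(sab) || !length(main)) return(res(FALSE, "NO_ARRIVAL"))
    pre <- sab[sab < min(main)]
    if (!length(pre)) return(res(FALSE, "NO_ARRIVAL"))
    i <- max(pre)
    j <- min(main)
    delay <- as.numeric(runs$start_ts[j] - runs$end_ts[i], units = "hours")
    if (delay >= max_delay_h) return(res(FALSE, "DELAY_EXCEEDED",
                                         delay = delay))
    brg <- rhumb_bearing(runs$lat[i], runs$lon[i], runs$lat[j], runs$lon[j])
    return(res(TRUE, NA_character_, brg, runs$station_id[i],
               runs$station_id[j], delay))
  }
  # GULF_CROSSING
  ns <- which(runs$region %in% c("NS_COAST", "BPI"))
  gulf <- which(runs$region %in% c("GULF_NORTH", "GULF_SOUTH"))
  if (!length(ns) || !length(gulf)) return(res(FALSE, "NO_ARRIVAL"))
  j <- min(gulf)
  ns <- ns[ns < j]
  if (!length(ns)) return(res(FALSE, "NO_ARRIVAL"))
  i <- max(ns)
  if (runs$region[i] != "BPI") return(res(FALSE, "NOT_BPI"))
  delay <- as.numeric(runs$start_ts[j] - runs$end_ts[i], units = "hours")
  if (delay >= max_delay_h) return(res(FALSE, "DELAY_EXCEEDED", delay = delay))
  brg <- rhumb_bearing(runs$lat[i], runs$lon[i], runs$lat[j], runs$lon[j])
  res(TRUE, NA_character_, brg, runs$station_id[i], runs$station_id[j], delay)
}

#' Classify a flight segment as direct
#'
#' A flight is direct when the implied ground speed meets the threshold
#' (default 5 m/s; observed direct crossings were 10 and 13 m/s).
#' @param segment one row of a track's \code{flights}
#' @param min_speed_mps threshold speed
#' @return logical
#' @export
classify_direct_flight <- function(segment, min_speed_mps = 5) {
  segment$speed_mps >= min_speed_mps
}

#' Segment a whole cohort
#'
#' Builds tracks for every bird with accepted runs and collects flights,
#' stopovers, reversals and crossing-bearing eligibility into tables.
#'
#' @param runs accepted runs (all tags)
#' @param receivers receiver table
#' @param tags tag table
#' @param config \code{\link{study_config}}
#' @return list: \code{tracks} (list of \code{bird_track}), \code{track_table}
#'   (one row per bird), \code{flights}, \code{stopovers}, \code{reversals},
#'   \code{bearings} (per leg, with eligibility)
#' @export
segment_cohort <- function(runs, receivers, tags, config = study_config()) {
  tracks <- list(); fl <- list(); st <- list(); rv <- list(); be <- list()
  tt <- list()
  for (tag in unique(runs$tag_id)) {
    r <- runs[runs$tag_id == tag, , drop = FALSE]
    tr <- build_track(r, receivers, tags, config)
    tracks[[tr$bird_id]] <- tr
    s <- detect_stopovers(tr, config$same_recv_h, config$adjacent_h)
    st[[tr$bird_id]] <- s
    rv[[tr$bird_id]] <- detect_reversals(tr, s, config$ne_sector)
    fl[[tr$bird_id]] <- tr$flights
    bel <- lapply(c("SABLE_TO_NS", "GULF_CROSSING"), function(lg) {
      e <- crossing_bearing_eligibility(tr, lg, config$max_delay_h)
      data.frame(bird_id = tr$bird_id, age = tr$age, leg = lg,
                 eligible = e$eligible, reason = e$reason,
                 bearing_deg = e$bearing_deg, delay_h = e$delay_h,
                 stringsAsFactors = FALSE)
    })
    be[[tr$bird_id]] <- do.call(rbind, bel)
    tt[[tr$bird_id]] <- data.frame(
      bird_id = tr$bird_id, age = tr$age, tag_id = tr$tag_id,
      n_runs = nrow(tr$runs),
      departure_date = tr$departure_date, last_ns_date = tr$last_ns_date,
      route_class = tr$route_class, final_ns_station = tr$final_ns_station,
      censored = tr$censored, cape_span_days = tr$cape_span_days,
      migration_complete = tr$migration_complete,
      n_stopovers = nrow(s), stringsAsFactors = FALSE)
  }
  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  out <- list(
    tracks = tracks,
    track_table = bind(tt, NULL),
    flights = bind(fl, NULL),
    stopovers = bind(st, NULL),
    reversals = bind(rv, NULL),
    bearings = bind(be, NULL))
  for (nm in c("track_table", "flights", "stopovers", "reversals",
               "bearings"))
    if (!is.null(out[[nm]])) rownames(out[[nm]]) <- NULL
  out
}
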