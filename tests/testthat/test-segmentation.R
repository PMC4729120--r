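# Handcrafted run tables exercising each segmentation rule, plus
# simulator-truth recovery for the full stage.

test_that("route classes follow the regions visited", {
  rcv <- fixture_receivers(); tg <- fixture_tags(1)
  # Sable only
  tr <- build_track(make_runs("T01", "SAB1", "2013-10-01T00:00:00Z",
                              "2013-10-01T01:00:00Z"), rcv, tg)
  expect_equal(tr$route_class, "NOT_DETECTED_MAINLAND")
  expect_true(is.na(tr$departure_date))
  # Sable -> NS chain -> BPI -> southern Gulf
  runs <- rbind(
    make_runs("T01", "SAB1", "2013-10-01T00:00:00Z", "2013-10-01T01:00:00Z"),
    make_runs("T01", "NS1", "2013-10-01T10:00:00Z", "2013-10-01T10:10:00Z"),
    make_runs("T01", "BPI", "2013-10-01T13:00:00Z", "2013-10-01T13:10:00Z"),
    make_runs("T01", "GS1", "2013-10-02T02:00:00Z", "2013-10-02T02:10:00Z"))
  tr <- build_track(runs, rcv, tg)
  expect_equal(tr$route_class, "GULF_VIA_SOUTH")
  expect_false(tr$censored)
  # first Gulf detection in the north
  runs$station_id[4] <- "GN1"
  expect_equal(build_track(runs, rcv, tg)$route_class, "GULF_VIA_NORTH")
  # ends at BPI, never seen again: presumed direct south, censored
  tr <- build_track(runs[1:3, ], rcv, tg)
  expect_equal(tr$route_class, "PRESUMED_DIRECT_SOUTH")
  expect_true(tr$censored)
  # ends mid-chain
  tr <- build_track(runs[1:2, ], rcv, tg)
  expect_equal(tr$route_class, "NS_ONLY")
})

test_that("departure date is the local date of first mainland detection", {
  rcv <- fixture_receivers(); tg <- fixture_tags(1)
  runs <- rbind(
    make_runs("T01", "SAB1", "2013-10-02T20:00:00Z", "2013-10-02T23:00:00Z"),
    make_runs("T01", "NS1", "2013-10-03T02:10:00Z", "2013-10-03T02:20:00Z"))
  tr <- build_track(runs, rcv, tg)
  expect_equal(tr$departure_date, as.Date("2013-10-02"))
  expect_equal(departure_date(tr, tz_offset_h = -3), as.Date("2013-10-02"))
  expect_equal(departure_date(tr, tz_offset_h = 0), as.Date("2013-10-03"))
})

test_that("stopover rules: >8 h same receiver, >10 h adjacent gap", {
  rcv <- fixture_receivers(); tg <- fixture_tags(1)
  # 9 h span at one station -> SAME_RECEIVER of 0.375 days
  runs <- rbind(
    make_runs("T01", "NS1", "2013-10-03T00:00:00Z", "2013-10-03T05:00:00Z"),
    make_runs("T01", "NS1", "2013-10-03T08:00:00Z", "2013-10-03T09:00:00Z"))
  st <- detect_stopovers(build_track(runs, rcv, tg))
  expect_equal(st$kind, "SAME_RECEIVER")
  expect_equal(st$duration_days, 0.375)
  # adjacent stations 12 h apart -> ADJACENT_GAP at the earlier station
  runs <- rbind(
    make_runs("T01", "NS1", "2013-10-03T00:00:00Z", "2013-10-03T00:10:00Z"),
    make_runs("T01", "NS2", "2013-10-03T12:10:00Z", "2013-10-03T12:20:00Z"))
  st <- detect_stopovers(build_track(runs, rcv, tg))
  expect_equal(st$kind, "ADJACENT_GAP")
  expect_equal(st$station_id, "NS1")
  expect_equal(st$duration_days, 0.5)
  # 5 h gap: no event
  runs$start_ts[2] <- parse_ts("2013-10-03T05:10:00Z")
  runs$end_ts[2] <- parse_ts("2013-10-03T05:20:00Z")
  expect_equal(nrow(detect_stopovers(build_track(runs, rcv, tg))), 0)
  # non-adjacent stations never yield a gap event
  runs <- rbind(
    make_runs("T01", "NS1", "2013-10-03T00:00:00Z", "2013-10-03T00:10:00Z"),
    make_runs("T01", "NS3", "2013-10-04T00:00:00Z", "2013-10-04T00:10:00Z"))
  expect_equal(nrow(detect_stopovers(build_track(runs, rcv, tg))), 0)
})

test_that("Cape Cod detections never count as stopover and long spans
           complete the migration", {
  rcv <- fixture_receivers(); tg <- fixture_tags(1)
  runs <- rbind(
    make_runs("T01", "GS1", "2013-10-10T00:00:00Z", "2013-10-10T00:10:00Z"),
    make_runs("T01", "CC1", "2013-10-11T00:00:00Z", "2013-10-28T12:00:00Z"))
  tr <- build_track(runs, rcv, tg)
  st <- detect_stopovers(tr)
  expect_false(any(st$station_id == "CC1"))
  expect_equal(tr$cape_span_days, 17.5)
  expect_true(tr$migration_complete)
  # a short Cape Cod span does not complete the migration
  runs$end_ts[2] <- parse_ts("2013-10-15T00:00:00Z")
  expect_false(build_track(runs, rcv, tg)$migration_complete)
})

test_that("reversals are northeast hops with stopover context", {
  rcv <- fixture_receivers(); tg <- fixture_tags(1)
  # monotone southwest progression: no reversal
  runs <- rbind(
    make_runs("T01", "NS1", "2013-10-03T00:00:00Z", "2013-10-03T00:10:00Z"),
    make_runs("T01", "NS2", "2013-10-03T01:10:00Z", "2013-10-03T01:20:00Z"),
    make_runs("T01", "NS3", "2013-10-03T02:20:00Z", "2013-10-03T02:30:00Z"))
  expect_equal(nrow(detect_reversals(build_track(runs, rcv, tg))), 0)
  # NE hop NS2 -> NS1 followed by an 11 h stay at NS1: PRE_STOPOVER
  runs <- rbind(
    make_runs("T01", "NS2", "2013-10-03T00:00:00Z", "2013-10-03T00:10:00Z"),
    make_runs("T01", "NS1", "2013-10-03T01:10:00Z", "2013-10-03T12:10:00Z"),
    make_runs("T01", "NS2", "2013-10-03T13:00:00Z", "2013-10-03T13:10:00Z"))
  tr <- build_track(runs, rcv, tg)
  rv <- detect_reversals(tr)
  expect_equal(nrow(rv), 1)
  expect_equal(rv$from_station, "NS2")
  expect_equal(rv$to_station, "NS1")
  expect_gt(rv$bearing_deg, 0); expect_lte(rv$bearing_deg, 90)
  expect_equal(rv$context, "PRE_STOPOVER")
  # stopover at NS2 then NE hop on departure: POST_STOPOVER
  runs <- rbind(
    make_runs("T01", "NS2", "2013-10-03T00:00:00Z", "2013-10-03T11:00:00Z"),
    make_runs("T01", "NS1", "2013-10-03T12:00:00Z", "2013-10-03T12:10:00Z"),
    make_runs("T01", "NS2", "2013-10-03T13:10:00Z", "2013-10-03T13:20:00Z"))
  rv <- detect_reversals(build_track(runs, rcv, tg))
  expect_equal(rv$context[1], "POST_STOPOVER")
})

test_that("crossing bearings are eligible only for prompt crossings from the
           right terminus", {
  rcv <- fixture_receivers(); tg <- fixture_tags(1)
  base <- rbind(
    make_runs("T01", "SAB1", "2013-10-01T00:00:00Z", "2013-10-01T02:00:00Z"),
    make_runs("T01", "NS1", "2013-10-01T08:00:00Z", "2013-10-01T08:10:00Z"),
    make_runs("T01", "BPI", "2013-10-01T12:00:00Z", "2013-10-01T12:10:00Z"),
    make_runs("T01", "GS1", "2013-10-02T02:00:00Z", "2013-10-02T02:10:00Z"))
  tr <- build_track(base, rcv, tg)
  e <- crossing_bearing_eligibility(tr, "SABLE_TO_NS")
  expect_true(e$eligible)
  expect_equal(e$delay_h, 6)
  expect_equal(e$bearing_deg,
               rhumb_bearing(43.93, -59.91, 44.35, -64.30), tolerance = 1e-9)
  g <- crossing_bearing_eligibility(tr, "GULF_CROSSING")
  expect_true(g$eligible)
  # arrival 9 days after the last Sable detection: removed
  late <- rbind(base[1, ],
                make_runs("T01", "NS1", "2013-10-10T02:00:00Z",
                          "2013-10-10T02:10:00Z"))
  e <- crossing_bearing_eligibility(build_track(late, rcv, tg),
                                    "SABLE_TO_NS")
  expect_false(e$eligible)
  expect_equal(e$reason, "DELAY_EXCEEDED")
  # final NS detection northeast of BPI: Gulf bearing not computed
  nb <- rbind(base[1:2, ],
              make_runs("T01", "GS1", "2013-10-02T02:00:00Z",
                        "2013-10-02T02:10:00Z"))
  g <- crossing_bearing_eligibility(build_track(nb, rcv, tg), "GULF_CROSSING")
  expect_false(g$eligible)
  expect_equal(g$reason, "NOT_BPI")
  # no arrival at all
  g <- crossing_bearing_eligibility(build_track(base[1:3, ], rcv, tg),
                                    "GULF_CROSSING")
  expect_equal(g$reason, "NO_ARRIVAL")
})

test_that("direct-flight classification is a monotone speed threshold", {
  rcv <- fixture_receivers(); tg <- fixture_tags(1)
  runs <- rbind(
    make_runs("T01", "BPI", "2013-10-01T12:00:00Z", "2013-10-01T12:10:00Z"),
    make_runs("T01", "GS1", "2013-10-01T19:10:00Z", "2013-10-01T19:20:00Z"))
  tr <- build_track(runs, rcv, tg)
  fl <- tr$flights
  expect_equal(nrow(fl), 1)
  expect_gt(fl$speed_mps, 5)           # ~420 km in 7 h
  expect_true(classify_direct_flight(fl, 5))
  expect_false(classify_direct_flight(fl, 100))
  # counts non-increasing over a threshold sweep
  speeds <- c(1, 3, 5, 10, 16, 25)
  n_direct <- vapply(speeds, function(s) sum(classify_direct_flight(fl, s)),
                     numeric(1))
  expect_true(all(diff(n_direct) <= 0))
})

test_that("segmentation recovers simulator ground truth exactly under
           perfect detection", {
  p <- cohort_params(n_adult = 12, n_juvenile = 12, detection_p_flight = 1,
                     detection_p_ground = 1, false_positive_rate = 0,
                     seed = 47)
  sim <- simulate_study(p)
  runs <- filter_detections(sim$detections, sim$tags, sim$receivers)
  seg <- segment_cohort(runs, sim$receivers, sim$tags)
  m <- merge(seg$track_table, sim$truth$tracks, by = "bird_id",
             suffixes = c(".det", ".tru"))
  expect_equal(nrow(m), 24)
  expect_equal(m$route_class.det, m$route_class.tru)
  expect_equal(m$migration_complete.det, m$migration_complete.tru)
  # stopovers: every behavioural stopover longer than the 8 h rule is
  # recovered at its station; every detected event maps to a true stopover
  ts <- sim$truth$stopovers
  t8 <- ts[ts$duration_days > 8 / 24, ]
  ds <- seg$stopovers
  key <- function(b, s) paste(b, s)
  expect_true(all(key(t8$bird_id, t8$station_id) %in%
                  key(ds$bird_id, ds$station_id)))
  expect_true(all(key(ds$bird_id, ds$station_id) %in%
                  key(ts$bird_id, ts$station_id)))
  # endpoints agree within the in-range approach window
  mm <- merge(ds, t8, by.x = c("bird_id", "station_id"),
              by.y = c("bird_id", "station_id"))
  win_s <- p$flight_range_km * 1000 / p$flight_speed_mps +
    p$burst_interval_s + 10
  expect_true(all(abs(as.numeric(mm$start_ts) - as.numeric(mm$start)) <=
                  win_s))
  expect_true(all(abs(as.numeric(mm$end_ts) - as.numeric(mm$end)) <= win_s))
  # per-age mean departure dates track the generator means
  p2 <- cohort_params(n_adult = 1000, n_juvenile = 1000, seed = 53)
  d <- simulate_departures(p2)
  mu <- tapply(as.numeric(local_date(d$departure, -3)), d$age, mean)
  expect_lt(abs(mu[["ADULT"]] -
                as.numeric(as.Date(p2$departure_mean_by_age[["ADULT"]]))), 1)
  expect_lt(abs(mu[["JUVENILE"]] -
                as.numeric(as.Date(p2$departure_mean_by_age[["JUVENILE"]]))),
            1)
})
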