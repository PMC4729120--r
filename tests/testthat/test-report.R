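# Cohort summary engineered to the study's detection-by-location table, and
# pipeline orchestration.

empty_stopovers <- function() {
  data.frame(bird_id = character(), station_id = character(),
             start_ts = parse_ts(character()), end_ts = parse_ts(character()),
             duration_days = numeric(), kind = character())
}

table2_segmented <- function() {
  mk <- function(n, age, route, final, censored = FALSE) {
    if (n == 0) return(NULL)
    data.frame(bird_id = character(n), age = age, tag_id = "",
               n_runs = 1, departure_date = as.Date("2013-10-03"),
               last_ns_date = as.Date("2013-10-05"), route_class = route,
               final_ns_station = final, censored = censored,
               cape_span_days = NA_real_, migration_complete = FALSE,
               n_stopovers = 0, stringsAsFactors = FALSE)
  }
  tt <- rbind(
    mk(20, "ADULT", "NOT_DETECTED_MAINLAND", NA_character_),
    mk(4, "ADULT", "GULF_VIA_SOUTH", "BPI"),
    mk(3, "ADULT", "PRESUMED_DIRECT_SOUTH", "BPI", TRUE),
    mk(4, "ADULT", "NS_ONLY", "NS1"),
    mk(5, "JUVENILE", "NOT_DETECTED_MAINLAND", NA_character_),
    mk(12, "JUVENILE", "GULF_VIA_SOUTH", "BPI"),
    mk(3, "JUVENILE", "PRESUMED_DIRECT_SOUTH", "BPI", TRUE),
    mk(12, "JUVENILE", "GULF_VIA_NORTH", "NS2"),
    mk(1, "JUVENILE", "GULF_VIA_SOUTH", "NS3"))
  tt$bird_id <- sprintf("B%03d", seq_len(nrow(tt)))
  mainland <- tt$bird_id[tt$route_class != "NOT_DETECTED_MAINLAND"]
  bearings <- data.frame(
    bird_id = mainland, age = tt$age[match(mainland, tt$bird_id)],
    leg = "SABLE_TO_NS", eligible = TRUE, reason = NA_character_,
    bearing_deg = 290,
    delay_h = c(rep(5, 28), rep(50, 11)),
    stringsAsFactors = FALSE)
  list(track_table = tt, stopovers = empty_stopovers(), reversals = NULL,
       flights = NULL, bearings = bearings)
}

test_that("summary counts reproduce the engineered detection table", {
  seg <- table2_segmented()
  tags <- data.frame(age = c(rep("ADULT", 31), rep("JUVENILE", 33)))
  s <- summarize_cohort(seg, tags, fixture_receivers())
  cts <- s$counts
  expect_equal(cts$tagged, c(31, 33, 64))
  expect_equal(cts$detected_ns, c(11, 28, 39))
  expect_equal(cts$final_ns_bpi, c(7, 15, 22))
  expect_equal(cts$final_ns_not_bpi, c(4, 13, 17))
  expect_equal(cts$detected_gulf, c(4, 25, 29))
  expect_equal(cts$gulf_north, c(0, 12, 12))
  expect_equal(cts$gulf_south, c(4, 13, 17))
  # consistency partitions
  expect_equal(cts$final_ns_bpi + cts$final_ns_not_bpi, cts$detected_ns)
  # percentages recompute exactly from the counts
  expect_equal(cts$pct_detected_ns,
               round(100 * cts$detected_ns / cts$tagged))
  expect_equal(cts$pct_gulf_of_mainland[2], 89)
  expect_equal(cts$pct_gulf_of_mainland[1], 36)
  expect_equal(cts$pct_detected_ns[2], 85)
  expect_equal(s$pct_within_12h, 72)
  expect_equal(s$n_within_12h, 28)
})

test_that("an empty cohort summarizes to zeros with absent percentages", {
  seg <- table2_segmented()
  seg$track_table <- seg$track_table[0, ]
  seg$bearings <- seg$bearings[0, ]
  s <- summarize_cohort(seg, data.frame(age = character()),
                        fixture_receivers())
  expect_true(all(s$counts$tagged == 0))
  expect_true(all(is.na(s$counts$pct_detected_ns)))
  expect_true(is.na(s$pct_within_12h))
})

test_that("pipeline reruns are bit-identical and cover all comparisons", {
  p <- cohort_params(n_adult = 12, n_juvenile = 16, seed = 61)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_pipeline(d1, params = p)
  r2 <- run_pipeline(d2, params = p)
  for (f in c("detections.csv", "runs.csv", "results.csv",
              "summary_counts.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # every published age comparison is fitted
  res <- r1$results
  expect_true(all(c("departure_date", "last_ns_date", "stopover_count",
                    "stopover_duration", "gulf_detection_by_age",
                    "gulf_north_south_by_age", "sable_bearing_mean",
                    "sable_bearing_homogeneity", "gulf_bearing_mean",
                    "gulf_bearing_homogeneity") %in% res$comparison))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  # intermediate files exist
  expect_true(all(file.exists(file.path(d1,
    c("receivers.csv", "tags.csv", "stopovers.csv", "flights.csv",
      "pipeline.log")))))
})

test_that("pipeline input errors name the missing file", {
  expect_error(run_pipeline(withr::local_tempdir(), simulate = FALSE,
                            receivers = "no-such-receivers.csv",
                            tags = "x.csv", detections = "y.csv"),
               "no-such-receivers")
})
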