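make_det <- function(tag, station, times) {
  data.frame(ts = parse_ts("2013-10-01T00:00:00Z") + times, tag_id = tag,
             station_id = station, antenna_id = "a1", signal = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("candidate grouping chains gaps matching the burst interval", {
  tg <- fixture_tags(1)           # burst 11 s
  b <- tg$burst_interval_s[1]
  det <- make_det("T01", "NS1", c(0, b, 2 * b))
  cand <- group_candidate_runs(det, tg, burst_tolerance_s = 0.2)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$n_detections, 3)
  # gap of b then 2.5 b breaks the chain into 2 + 1
  det <- make_det("T01", "NS1", c(0, b, b + 2.5 * b))
  cand <- group_candidate_runs(det, tg, burst_tolerance_s = 0.2)
  expect_equal(sort(cand$n_detections), c(1, 2))
  # allow_skip bridges exactly one missed burst
  det <- make_det("T01", "NS1", c(0, b, 3 * b, 4 * b))
  expect_equal(nrow(group_candidate_runs(det, tg, 0.2, allow_skip = TRUE)), 1)
  expect_equal(nrow(group_candidate_runs(det, tg, 0.2, allow_skip = FALSE)), 2)
  # a station change always breaks the chain
  det <- rbind(make_det("T01", "NS1", c(0, b)), make_det("T01", "NS2", 2 * b))
  expect_equal(nrow(group_candidate_runs(det, tg, 0.2)), 2)
})

test_that("every detection belongs to exactly one candidate run", {
  set.seed(21)
  tg <- fixture_tags(3)
  det <- do.call(rbind, lapply(1:3, function(i)
    make_det(tg$tag_id[i], sample(c("NS1", "NS2"), 40, replace = TRUE),
             cumsum(runif(40, 5, 30)))))
  cand <- group_candidate_runs(det, tg, burst_tolerance_s = 0.2)
  expect_equal(sum(cand$n_detections), nrow(det))
  membership <- attr(cand, "membership")
  expect_equal(length(membership), nrow(det))
  expect_equal(as.integer(tabulate(membership)), cand$n_detections)
})

test_that("run filtering keeps length >= 3 and rescue applies its criteria", {
  tg <- fixture_tags(1)
  b <- tg$burst_interval_s[1]
  det <- rbind(
    make_det("T01", "NS1", c(0, b, 2 * b, 3 * b)),          # accepted, 4
    make_det("T01", "NS2", 7200 + c(0, b)),                 # held, 2
    make_det("T01", "NS3", 14400 + c(0, b, 2 * b)),         # accepted, 3
    make_det("T01", "BPI", 20000),                          # singleton
    make_det("T01", "GS1", 25000 + c(0, 3.3 * b)))          # off-interval 2
  cand <- group_candidate_runs(det, tg, 0.2)
  fr <- filter_runs(cand, min_run = 3)
  expect_equal(sort(fr$accepted$n_detections), c(3, 4))
  expect_true(all(!fr$accepted$rescued))
  # held: the NS2 pair, the BPI singleton, and two off-grid GS1 singletons
  expect_equal(nrow(fr$held), 4)
  rcv <- fixture_receivers()
  resc <- rescue_two_detection_runs(fr$held, fr$accepted, tg, rcv,
                                    max_speed_mps = 25,
                                    burst_tolerance_s = 0.2)
  # NS2 lies between NS1 and NS3 in coast order, implied speeds ~ 2 m/s
  expect_equal(resc$station_id, "NS2")
  expect_true(all(resc$rescued))
  # the off-burst-interval pair at GS1 is never rescued
  expect_false("GS1" %in% resc$station_id)
  # an implied speed above the cap rejects the candidate
  rcv2 <- rcv; rcv2$lat[rcv2$station_id == "NS2"] <- 40  # ~460 km detour
  resc2 <- rescue_two_detection_runs(fr$held, fr$accepted, tg, rcv2, 25, 0.2)
  expect_equal(nrow(resc2), 0)
  # disabled by default: filter_detections adds nothing
  acc <- filter_detections(det, tg, rcv, study_config())
  expect_equal(nrow(acc), 2)
})

test_that("lowering the tolerance never admits more detections", {
  set.seed(22)
  p <- cohort_params(n_adult = 2, n_juvenile = 2, jitter_sd = 0.15,
                     false_positive_rate = 0, seed = 31)
  sim <- simulate_study(p)
  tol <- c(0.5, 0.3, 0.2, 0.1, 0.05)
  n_acc <- vapply(tol, function(tl) {
    cand <- group_candidate_runs(sim$detections, sim$tags, tl)
    sum(filter_runs(cand)$accepted$n_detections)
  }, numeric(1))
  expect_true(all(diff(n_acc) <= 0))
})

test_that("accepted runs equal simulator ground-truth runs of length >= 3", {
  p <- cohort_params(n_adult = 5, n_juvenile = 5, detection_p_flight = 1,
                     detection_p_ground = 1, false_positive_rate = 0,
                     jitter_sd = 0, seed = 29)
  sim <- simulate_study(p)
  cand <- group_candidate_runs(sim$detections, sim$tags, 0.2)
  acc <- filter_runs(cand)$accepted
  tru <- truth_runs(sim$detections)
  tru3 <- tru[tru$n_detections >= 3, ]
  expect_setequal(run_key(acc), run_key(tru3))
})
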