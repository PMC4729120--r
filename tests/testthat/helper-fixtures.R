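# Shared fixtures and independent oracles, built in code at test time.

# A small hand-laid receiver chain: Sable origin, three NS coast stations,
# BPI terminus, one northern and one southern Gulf station, one Cape Cod
# station.  Coordinates follow the study region's geography closely enough
# that chain bearings run southwest and reverse hops run northeast.
fixture_receivers <- function() {
  df <- data.frame(
    station_id = c("SAB1", "NS1", "NS2", "NS3", "BPI", "GN1", "GS1", "CC1"),
    name = c("Sable", "NS coast 1", "NS coast 2", "NS coast 3",
             "Bon Portage Island", "Gulf north", "Gulf south", "Cape Cod"),
    lat = c(43.93, 44.35, 44.13, 43.90, 43.47, 44.30, 43.00, 41.90),
    lon = c(-59.91, -64.30, -64.70, -65.10, -65.74, -68.00, -70.60, -70.00),
    region = c("SABLE", "NS_COAST", "NS_COAST", "NS_COAST", "BPI",
               "GULF_NORTH", "GULF_SOUTH", "CAPE_COD"),
    coast_order = 0:7,
    stringsAsFactors = FALSE)
  df$active_from <- parse_ts("2013-08-01T00:00:00Z")
  df$active_to <- parse_ts("2014-01-31T00:00:00Z")
  df
}

fixture_tags <- function(n = 2, age = c("ADULT", "JUVENILE")) {
  data.frame(
    tag_id = sprintf("T%02d", seq_len(n)),
    burst_interval_s = 10 + seq_len(n),
    bird_id = sprintf("B%02d", seq_len(n)),
    age = rep(age, length.out = n),
    sex = "UNKNOWN",
    deploy_time = parse_ts("2013-08-12T12:00:00Z"),
    expected_life_days = 124,
    stringsAsFactors = FALSE)
}

# quick constructor for accepted-run tables used by segmentation tests
make_runs <- function(tag_id, station_id, start, end = start, n = 5) {
  data.frame(tag_id = tag_id, station_id = station_id,
             start_ts = parse_ts(start), end_ts = parse_ts(end),
             n_detections = n, rescued = FALSE, stringsAsFactors = FALSE)
}

# -- independent oracles ------------------------------------------------------

# Constant-bearing walk in 1 m steps on the sphere.  Along such a path
# latitude advances linearly, so the longitude sum is the only integral:
# it is evaluated exactly over the stepped latitudes.  Returns the endpoint
# after walking `dist_km` at compass bearing `brg` from (lat, lon).
walk_constant_bearing <- function(lat, lon, brg, dist_km, step_m = 1) {
  R <- EARTH_RADIUS_KM * 1000
  n <- max(1, round(dist_km * 1000 / step_m))
  th <- brg * pi / 180
  dlat_step <- step_m * cos(th) / R
  lat0 <- lat * pi / 180
  lats <- lat0 + dlat_step * (seq_len(n) - 1)
  dlon <- step_m * sin(th) / R * sum(1 / cos(lats))
  list(lat = (lat0 + dlat_step * n) * 180 / pi,
       lon = lon + dlon * 180 / pi)
}

# Oracle bearing: bisect the compass bearing until the 1 m-step walk from a
# lands on b (matching longitude at b's latitude for meridional closure).
oracle_rhumb_bearing <- function(lat1, lon1, lat2, lon2, tol = 1e-4) {
  dist <- rhumb_distance(lat1, lon1, lat2, lon2)
  target <- normalize_lon(lon2 - lon1)
  north <- lat2 >= lat1
  east <- target >= 0
  lo <- if (north && east) 0 else if (!north && east) 90
        else if (!north) 180 else 270
  hi <- lo + 90
  f <- function(brg) {
    p <- walk_constant_bearing(lat1, lon1, brg, dist)
    normalize_lon(p$lon - lon1) - target
  }
  # longitude displacement increases with bearing within each quadrant for
  # northward halves and decreases for southward: handle by sign probing
  flo <- f(lo + 1e-9); fhi <- f(hi - 1e-9)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# Exhaustive Fisher oracle: enumerate every 2x2 table with the observed
# margins, computing each probability from binomial coefficients directly.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m == 0 || n == 0 || k == 0 || sum(tab[, 2]) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(a)
    choose(m, a) * choose(n, k - a) / choose(m + n, k), numeric(1))
  p_obs <- probs[support == tab[1, 1]]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Ground-truth detection runs from simulator labels: maximal blocks of
# consecutive burst indices of one tag at one station.
truth_runs <- function(detections) {
  det <- detections[!detections$is_false_positive, , drop = FALSE]
  det <- det[order(det$tag_id, det$station_id, det$burst_k), , drop = FALSE]
  n <- nrow(det)
  newblk <- c(TRUE, !(det$tag_id[-1] == det$tag_id[-n] &
                      det$station_id[-1] == det$station_id[-n] &
                      det$burst_k[-1] == det$burst_k[-n] + 1))
  blk <- cumsum(newblk)
  data.frame(
    tag_id = det$tag_id[newblk],
    station_id = det$station_id[newblk],
    start_ts = det$ts[newblk],
    end_ts = .POSIXct(vapply(split(as.numeric(det$ts), blk), max,
                             numeric(1)), tz = "UTC"),
    n_detections = as.integer(tabulate(blk)),
    stringsAsFactors = FALSE)
}

# run-set comparison key
run_key <- function(runs) {
  paste(runs$tag_id, runs$station_id, format_ts(runs$start_ts),
        format_ts(runs$end_ts), runs$n_detections)
}
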