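# Synthetic cohorts and detection logs.
#
# The generator emulates the study system: sparrows breed on Sable Island,
# depart on a fall night, make an overwater flight to the Nova Scotia coastal
# receiver chain, travel southwest, and either cross the Gulf of Maine from
# Bon Portage Island (BPI), cut overland across Nova Scotia to the northern
# Gulf, or vanish south over open water from BPI.  Every behavioural event
# is recorded as ground truth so that detection filtering and track
# segmentation can be scored against a known answer.

#' Cohort simulation parameters
#'
#' Defaults encode the study conditions: 31 adults and 33 juveniles tagged;
#' juveniles depart around 3 October and adults around 27 October (24 days
#' apart) with a 9-day spread; mean overwater bearings 288 deg (adult) vs
#' 299 deg (juvenile) for the Sable-to-mainland leg and 252 vs 282 deg for
#' the Gulf of Maine crossing; mean stopover counts 1.6 vs 3.8 and mean
#' durations 2.8 vs 5.8 days; reversal displacements between receivers 18-34
#' km.  Detection ranges follow the array's behaviour: a few km for birds on
#' the ground, up to 15 km in flight.
#'
#' @param n_adult,n_juvenile cohort sizes
#' @param departure_mean_by_age named character/Date: mean departure date per
#'   age class
#' @param departure_sd_days spread (days) of departure dates, both ages
#' @param route_probs_by_age named list of length-3 probability vectors over
#'   routes \code{OVERLAND_FUNDY}, \code{COASTAL_GULF}, \code{DIRECT_SOUTH};
#'   each must sum to 1
#' @param bearing_mu_by_age_leg named list \code{SABLE_TO_NS} /
#'   \code{GULF_CROSSING}, each a named vector of mean bearings (deg) per age
#' @param bearing_kappa von Mises concentration of intended headings
#' @param stopover_rate_by_age mean stopover count (Poisson) per age
#' @param stopover_dur_mean_by_age mean stopover duration (days, exponential,
#'   truncated at 0.1 d) per age
#' @param reversal_prob_by_age per-bird probability of attempting one
#'   inserted reverse migration; an attempt succeeds only when the bird has
#'   a stopover on the coastal chain with a neighbouring receiver 18-34 km
#'   away, so the realized frequency is lower (the adult/juvenile defaults
#'   0 / 0.30 realize about 0.11 reversals per juvenile, the observed rate)
#' @param p_continue_cape_by_age probability a Gulf bird continues to Cape Cod
#' @param cape_span_mean_days_by_age mean detection span (days) at Cape Cod
#' @param flight_speed_mps cruise ground speed, m/s
#' @param detection_p_flight,detection_p_ground per-burst detection
#'   probability in flight (15 km range) and on the ground (2 km range)
#' @param flight_range_km,ground_range_km detection ranges
#' @param false_positive_rate false positives per station-hour (receiver
#'   noise decoded as a tag; timing not aligned to any burst grid)
#' @param burst_interval_s base tag burst interval, seconds (per-tag
#'   intervals vary slightly around this)
#' @param jitter_sd optional Gaussian jitter (s) on detection timestamps
#' @param sable_presim_h hours of on-island residence simulated before
#'   departure (tags run for weeks beforehand; only the final hours matter
#'   for departure timing)
#' @param n_ns_coast number of mainland Nova Scotia chain stations (besides
#'   BPI)
#' @param seed integer random seed
#' @return object of class \code{cohort_params}
#' @export
cohort_params <- function(n_adult = 31, n_juvenile = 33,
                          departure_mean_by_age = c(ADULT = "2013-10-27",
                                                    JUVENILE = "2013-10-03"),
                          departure_sd_days = 9,
                          route_probs_by_age = list(
                            ADULT = c(OVERLAND_FUNDY = 0.00,
                                      COASTAL_GULF = 0.36,
                                      DIRECT_SOUTH = 0.64),
                            JUVENILE = c(OVERLAND_FUNDY = 0.43,
                                         COASTAL_GULF = 0.46,
                                         DIRECT_SOUTH = 0.11)),
                          bearing_mu_by_age_leg = list(
                            SABLE_TO_NS = c(ADULT = 288, JUVENILE = 299),
                            GULF_CROSSING = c(ADULT = 252, JUVENILE = 282)),
                          bearing_kappa = 8,
                          stopover_rate_by_age = c(ADULT = 1.6,
                                                   JUVENILE = 3.8),
                          stopover_dur_mean_by_age = c(ADULT = 2.8,
                                                       JUVENILE = 5.8),
                          reversal_prob_by_age = c(ADULT = 0,
                                                   JUVENILE = 0.30),
                          p_continue_cape_by_age = c(ADULT = 0.25,
                                                     JUVENILE = 0.16),
                          cape_span_mean_days_by_age = c(ADULT = 4,
                                                         JUVENILE = 28),
                          flight_speed_mps = 12,
                          detection_p_flight = 0.9,
                          detection_p_ground = 0.6,
                          flight_range_km = 15,
                          ground_range_km = 2,
                          false_positive_rate = 0.005,
                          burst_interval_s = 300,
                          jitter_sd = 0,
                          sable_presim_h = 24,
                          n_ns_coast = 12,
                          seed = 42L) {
  p <- as.list(environment())
  if (!is.numeric(p$n_adult) || !is.numeric(p$n_juvenile) ||
      p$n_adult < 0 || p$n_juvenile < 0 || p$n_adult + p$n_juvenile < 1)
    stop("cohort_params: cohort sizes must be non-negative with total >= 1")
  for (age in AGES) {
    rp <- p$route_probs_by_age[[age]]
    if (any(rp < 0) || any(rp > 1) || abs(sum(rp) - 1) > 1e-8)
      stop("cohort_params: route probabilities for ", age, " must sum to 1")
  }
  if (p$bearing_kappa < 0) stop("cohort_params: kappa must be >= 0")
  for (nm in c("departure_sd_days", "flight_speed_mps", "burst_interval_s"))
    if (p[[nm]] <= 0) stop("cohort_params: ", nm, " must be positive")
  for (nm in c("detection_p_flight", "detection_p_ground"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop("cohort_params: ", nm, " must be a probability")
  if (any(p$stopover_rate_by_age < 0) || any(p$stopover_dur_mean_by_age <= 0))
    stop("cohort_params: stopover rates/means must be positive")
  p$seed <- as.integer(p$seed)
  class(p) <- "cohort_params"
  p
}

#' Draw from a von Mises distribution (compass degrees)
#'
#' Best-Fisher rejection sampler.  \code{kappa = 0} gives the circular
#' uniform.  Very large \code{kappa} collapses onto \code{mu}.
#'
#' @param n number of draws
#' @param mu mean direction, degrees
#' @param kappa concentration (>= 0)
#' @return bearings in \code{[0, 360)}
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("rvonmises: kappa must be >= 0")
  if (kappa == 0) return(runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      theta <- sign(u[3] - 0.5) * acos(f)
      out[i] <- (mu + theta * 180 / pi) %% 360
      i <- i + 1L
    }
  }
  out
}

# smallest absolute angular difference in degrees
.ang_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Generate the default receiver array
#'
#' Builds a synthetic 34-station array shaped like the study's: four towers
#' on Sable Island, a mainland Nova Scotia coastal chain terminating at Bon
#' Portage Island (BPI) with adjacent-station spacing drawn uniformly in
#' [20, 50] km, groups along the northern and southern Gulf of Maine, and a
#' Cape Cod terminus.  \code{coast_order} increases strictly toward the
#' southwest.  Coordinates are invented (plausible, seed-reproducible);
#' the published array's tower coordinates are not printed anywhere, so the
#' geometry here is synthetic by necessity.
#'
#' @param params a \code{\link{cohort_params}} object (uses the seed and
#'   \code{n_ns_coast})
#' @return validated receiver data.frame (see \code{\link{read_receivers}})
#' @export
default_array <- function(params = cohort_params()) {
  set.seed(params$seed)
  n_ns <- params$n_ns_coast
  sable <- data.frame(
    station_id = paste0("SAB", 1:4),
    name = paste("Sable", 1:4),
    lat = c(43.97, 43.94, 43.92, 43.95),
    lon = c(-60.11, -59.96, -59.81, -59.68),
    region = "SABLE", stringsAsFactors = FALSE)
  # NS chain grown northeastward from BPI so BPI anchors the SW terminus
  lat <- 43.47; lon <- -65.74
  ns_lat <- numeric(n_ns); ns_lon <- numeric(n_ns)
  for (i in seq_len(n_ns)) {
    d_km <- runif(1, 20, 50)
    brg <- runif(1, 48, 72)              # coast trends NE from BPI
    dlat <- d_km * cos(brg * pi / 180) / 111.195
    dlon <- d_km * sin(brg * pi / 180) / (111.195 * cos(lat * pi / 180))
    lat <- lat + dlat; lon <- lon + dlon
    ns_lat[i] <- lat; ns_lon[i] <- lon
  }
  ns <- data.frame(
    station_id = paste0("NS", sprintf("%02d", seq_len(n_ns))),
    name = paste("NS coast", seq_len(n_ns)),
    lat = rev(ns_lat), lon = rev(ns_lon),  # listed NE -> SW
    region = "NS_COAST", stringsAsFactors = FALSE)
  bpi <- data.frame(station_id = "BPI", name = "Bon Portage Island",
                    lat = 43.47, lon = -65.74, region = "BPI",
                    stringsAsFactors = FALSE)
  gn_base <- cbind(lat = c(44.85, 44.66, 44.47, 44.28, 44.10, 43.92),
                   lon = c(-66.95, -67.40, -67.85, -68.30, -68.72, -69.10))
  gs_base <- cbind(lat = c(43.65, 43.38, 43.11, 42.84, 42.57, 42.31, 42.05),
                   lon = c(-70.22, -70.45, -70.62, -70.74, -70.84, -70.92,
                           -70.98))
  cc_base <- cbind(lat = c(42.05, 41.92, 41.78, 41.66),
                   lon = c(-70.18, -69.98, -69.95, -70.22))
  jit <- function(m) m + rnorm(length(m), 0, 0.015)
  gn <- data.frame(station_id = paste0("GN", seq_len(nrow(gn_base))),
                   name = paste("Gulf north", seq_len(nrow(gn_base))),
                   lat = jit(gn_base[, "lat"]), lon = jit(gn_base[, "lon"]),
                   region = "GULF_NORTH", stringsAsFactors = FALSE)
  gs <- data.frame(station_id = paste0("GS", seq_len(nrow(gs_base))),
                   name = paste("Gulf south", seq_len(nrow(gs_base))),
                   lat = jit(gs_base[, "lat"]), lon = jit(gs_base[, "lon"]),
                   region = "GULF_SOUTH", stringsAsFactors = FALSE)
  cc <- data.frame(station_id = paste0("CC", seq_len(nrow(cc_base))),
                   name = paste("Cape Cod", seq_len(nrow(cc_base))),
                   lat = jit(cc_base[, "lat"]), lon = jit(cc_base[, "lon"]),
                   region = "CAPE_COD", stringsAsFactors = FALSE)
  arr <- rbind(sable, ns, bpi, gn, gs, cc)
  arr$coast_order <- seq_len(nrow(arr)) - 1L
  arr$active_from <- parse_ts("2013-08-01T00:00:00Z")
  arr$active_to <- parse_ts("2014-01-31T00:00:00Z")
  .validate_receivers(arr)
}

# departure timestamp: nocturnal, drawn date + 21:00-02:00 local (UTC-3)
.draw_departures <- function(n, mean_date, sd_days) {
  day <- round(rnorm(n, 0, sd_days))
  hour_local <- 21 + runif(n, 0, 5)
  base <- as.POSIXct(paste0(mean_date, "T00:00:00Z"),
                     format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  base + day * 86400 + (hour_local + 3) * 3600
}

#' Draw departure timing for a cohort
#'
#' The departure component of the generator on its own: per-age Gaussian
#' calendar dates (mean date per age class, common spread) with nocturnal
#' departure times.  Used for departure-timing studies where the full
#' movement simulation is not needed; \code{\link{simulate_cohort}} draws
#' from the same model.
#'
#' @param params \code{\link{cohort_params}}
#' @return data.frame: \code{bird_id, age, departure} (POSIXct UTC)
#' @export
simulate_departures <- function(params = cohort_params()) {
  set.seed(params$seed + 1L)
  n <- params$n_adult + params$n_juvenile
  age <- c(rep("ADULT", params$n_adult), rep("JUVENILE", params$n_juvenile))
  departure <- .POSIXct(numeric(n), tz = "UTC")
  for (a in AGES) {
    idx <- which(age == a)
    if (length(idx))
      departure[idx] <- .draw_departures(length(idx),
                                         params$departure_mean_by_age[[a]],
                                         params$departure_sd_days)
  }
  data.frame(bird_id = sprintf("B%03d", seq_len(n)), age = age,
             departure = departure, stringsAsFactors = FALSE)
}

#' Simulate a tagged cohort with ground-truth tracks
#'
#' Draws per-bird departures (Gaussian around the age-specific mean date),
#' routes (per-age multinomial), intended overwater headings (von Mises) that
#' select the landfall station nearest in bearing, stopovers (Poisson counts,
#' exponential durations truncated at 0.1 d, BPI over-weighted as the major
#' staging site), and occasional reverse migrations (a northeast hop between
#' receivers 18-34 km apart, either just before a stopover or on departure
#' from one).  Movement between stations is constant-speed along the rhumb
#' line.
#'
#' @param params \code{\link{cohort_params}}
#' @param array receiver table; defaults to \code{\link{default_array}(params)}
#' @return list with elements \code{tags} (deployment table), \code{truth}
#'   (list of data.frames: \code{tracks}, \code{waypoints}, \code{stopovers},
#'   \code{reversals}, \code{bearings})
#' @export
simulate_cohort <- function(params = cohort_params(),
                            array = default_array(params)) {
  set.seed(params$seed + 1L)
  n <- params$n_adult + params$n_juvenile
  age <- c(rep("ADULT", params$n_adult), rep("JUVENILE", params$n_juvenile))
  bird_id <- sprintf("B%03d", seq_len(n))
  tag_id <- sprintf("T%03d", seq_len(n))
  # tags: per-tag burst interval varies slightly around the base
  burst <- params$burst_interval_s + (seq_len(n) %% 5) * 1.1
  deploy <- parse_ts("2013-08-12T12:00:00Z") +
    sample(0:6, n, replace = TRUE) * 86400
  tags <- data.frame(tag_id = tag_id, burst_interval_s = burst,
                     bird_id = bird_id, age = age,
                     sex = ifelse(age == "ADULT",
                                  sample(c("M", "F"), n, replace = TRUE),
                                  "UNKNOWN"),
                     deploy_time = deploy, expected_life_days = 124,
                     stringsAsFactors = FALSE)
  tags <- .validate_tags(tags)

  arr <- array[order(array$coast_order), ]
  sable_rows <- which(arr$region == "SABLE")
  chain_rows <- which(arr$region %in% c("NS_COAST", "BPI"))  # NE -> SW order
  bpi_row <- which(arr$region == "BPI")
  gn_rows <- which(arr$region == "GULF_NORTH")
  gs_rows <- which(arr$region == "GULF_SOUTH")
  cc_rows <- which(arr$region == "CAPE_COD")
  n_chain <- length(chain_rows)
  # bearings Sable station x chain station (landfall selection)
  brg_sable <- outer(seq_along(sable_rows), seq_len(n_chain),
                     function(i, j) rhumb_bearing(arr$lat[sable_rows[i]],
                                                  arr$lon[sable_rows[i]],
                                                  arr$lat[chain_rows[j]],
                                                  arr$lon[chain_rows[j]]))
  # spacing between consecutive chain stations (NE -> SW)
  chain_gap <- rhumb_distance(arr$lat[chain_rows[-n_chain]],
                              arr$lon[chain_rows[-n_chain]],
                              arr$lat[chain_rows[-1]],
                              arr$lon[chain_rows[-1]])

  departure <- .POSIXct(numeric(n), tz = "UTC")
  for (a in AGES) {
    idx <- which(age == a)
    if (length(idx))
      departure[idx] <- .draw_departures(length(idx),
                                         params$departure_mean_by_age[[a]],
                                         params$departure_sd_days)
  }
  routes <- character(n)
  for (a in AGES) {
    idx <- which(age == a)
    if (length(idx)) {
      rp <- params$route_probs_by_age[[a]]
      routes[idx] <- sample(names(rp), length(idx), replace = TRUE, prob = rp)
    }
  }

  wp_list <- vector("list", n); st_list <- vector("list", n)
  rv_list <- vector("list", n); br_list <- vector("list", n)
  trk_list <- vector("list", n)
  speed_kmh <- params$flight_speed_mps * 3.6

  for (b in seq_len(n)) {
    a <- age[b]; route <- routes[b]
    home_i <- sample(seq_along(sable_rows), 1)
    home <- sable_rows[home_i]
    mu_s <- params$bearing_mu_by_age_leg$SABLE_TO_NS[[a]]
    brg_draw <- rvonmises(1, mu_s, params$bearing_kappa)
    land_j <- which.min(.ang_diff(brg_sable[home_i, ], brg_draw))
    # path along the chain toward BPI (chain is NE->SW so indices increase)
    if (route == "OVERLAND_FUNDY") {
      # leave the chain NE of BPI when possible (partially overland route);
      # the exit is never northeast of the landfall
      exit_j <- if (land_j < n_chain - 2) {
        sample(seq(land_j, n_chain - 2), 1)
      } else land_j
      path <- chain_rows[land_j:exit_j]
    } else {
      path <- chain_rows[land_j:n_chain]   # down to BPI
    }
    stop_flag <- rep(FALSE, length(path))
    # gulf landfall
    gulf_brg <- NA_real_
    if (route == "COASTAL_GULF") {
      mu_g <- params$bearing_mu_by_age_leg$GULF_CROSSING[[a]]
      gdraw <- rvonmises(1, mu_g, params$bearing_kappa)
      cand <- rhumb_bearing(arr$lat[bpi_row], arr$lon[bpi_row],
                            arr$lat[gs_rows], arr$lon[gs_rows])
      gl <- gs_rows[which.min(.ang_diff(cand, gdraw))]
      gulf_path <- gs_rows[gs_rows >= gl]
      gulf_brg <- rhumb_bearing(arr$lat[bpi_row], arr$lon[bpi_row],
                                arr$lat[gl], arr$lon[gl])
    } else if (route == "OVERLAND_FUNDY") {
      exit_row <- path[length(path)]
      cand <- rhumb_bearing(arr$lat[exit_row], arr$lon[exit_row],
                            arr$lat[gn_rows], arr$lon[gn_rows])
      gdraw <- rvonmises(1, params$bearing_mu_by_age_leg$GULF_CROSSING[[a]],
                         params$bearing_kappa)
      gl <- gn_rows[which.min(.ang_diff(cand, gdraw))]
      gulf_path <- c(gn_rows[gn_rows >= gl], gs_rows)
    } else {
      gulf_path <- integer(0)
    }
    full <- c(path, gulf_path)
    stopover_at <- rep(FALSE, length(full))
    # stopovers: Poisson count placed along the mainland/gulf path
    cand_idx <- seq_along(full)
    n_stop <- min(rpois(1, params$stopover_rate_by_age[[a]]), length(cand_idx))
    if (n_stop > 0) {
      w <- ifelse(arr$region[full] == "BPI", 4, 1)
      sel <- sample(cand_idx, n_stop, prob = w[cand_idx])
      stopover_at[sel] <- TRUE
    }
    # cape cod continuation (only birds that reached the Gulf)
    cape_span <- NA_real_
    if (length(gulf_path) &&
        runif(1) < params$p_continue_cape_by_age[[a]]) {
      cape_span <- max(0.1,
                       rexp(1, 1 / params$cape_span_mean_days_by_age[[a]]))
      # land at the nearest Cape station reached on a southward heading
      lastg <- gulf_path[length(gulf_path)]
      cb <- rhumb_bearing(arr$lat[lastg], arr$lon[lastg],
                          arr$lat[cc_rows], arr$lon[cc_rows])
      cd <- rhumb_distance(arr$lat[lastg], arr$lon[lastg],
                           arr$lat[cc_rows], arr$lon[cc_rows])
      south <- cb > 95 & cb < 265
      cc_target <- if (any(south)) cc_rows[south][which.min(cd[south])] else
        cc_rows[which.min(cd)]
      full <- c(full, cc_target)
      stopover_at <- c(stopover_at, FALSE)
    }
    # stations sequence with stopover flags; insert a reversal if drawn
    seq_rows <- full
    seq_stop <- stopover_at
    rv <- NULL
    if (runif(1) < params$reversal_prob_by_age[[a]] && any(seq_stop)) {
      st_pos <- which(seq_stop & seq_rows %in% chain_rows)
      if (length(st_pos)) {
        pos <- st_pos[sample.int(length(st_pos), 1)]
        ci <- match(seq_rows[pos], chain_rows)
        pre <- runif(1) < 2 / 3
        if (pre && ci < n_chain && chain_gap[ci] >= 18 &&
            chain_gap[ci] <= 34) {
          # overfly one station SW, double back NE, then stop over:
          # ..., i, i+1, i(stopover), ...
          nxt <- chain_rows[ci + 1]
          stn <- seq_rows[pos]
          seq_rows <- append(seq_rows, c(nxt, stn), after = pos)
          seq_stop <- append(seq_stop, c(FALSE, TRUE), after = pos)
          seq_stop[pos] <- FALSE
          rv <- data.frame(bird_id = bird_id[b],
                           from_station = arr$station_id[nxt],
                           to_station = arr$station_id[stn],
                           displacement_km = chain_gap[ci],
                           context = "PRE_STOPOVER",
                           stringsAsFactors = FALSE)
        } else if (!pre && ci > 1 && chain_gap[ci - 1] >= 18 &&
                   chain_gap[ci - 1] <= 34) {
          # after the stopover, hop NE to the previous station, then resume
          prv <- chain_rows[ci - 1]
          seq_rows <- append(seq_rows, c(prv, seq_rows[pos]), after = pos)
          seq_stop <- append(seq_stop, c(FALSE, FALSE), after = pos)
          rv <- data.frame(bird_id = bird_id[b],
                           from_station = arr$station_id[seq_rows[pos]],
                           to_station = arr$station_id[prv],
                           displacement_km = chain_gap[ci - 1],
                           context = "POST_STOPOVER",
                           stringsAsFactors = FALSE)
        }
      }
    }
    # timing walk: Sable residency, then constant-speed legs
    dep <- departure[b]
    n_wp <- length(seq_rows) + 1L
    wlat <- c(arr$lat[home], arr$lat[seq_rows])
    wlon <- c(arr$lon[home], arr$lon[seq_rows])
    leg_h <- rhumb_distance(wlat[-n_wp], wlon[-n_wp], wlat[-1], wlon[-1]) /
      speed_kmh
    t_arr <- .POSIXct(numeric(n_wp), tz = "UTC")
    t_dep <- t_arr
    t_arr[1] <- dep - params$sable_presim_h * 3600
    t_dep[1] <- dep
    # dwell times at each arrived station
    stop_durs <- rep(0, n_wp)
    for (i in seq_len(n_wp - 1)) {
      if (seq_stop[i])
        stop_durs[i + 1] <- max(0.1, rexp(1,
                                1 / params$stopover_dur_mean_by_age[[a]]))
    }
    if (!is.na(cape_span)) stop_durs[n_wp] <- cape_span
    for (i in seq_len(n_wp - 1)) {
      t_arr[i + 1] <- t_dep[i] + leg_h[i] * 3600
      t_dep[i + 1] <- t_arr[i + 1] + stop_durs[i + 1] * 86400
    }
    wp <- data.frame(bird_id = bird_id[b], seq = seq_len(n_wp),
                     station_id = arr$station_id[c(home, seq_rows)],
                     t_arrive = t_arr, t_depart = t_dep,
                     is_stopover = stop_durs > 0 &
                       arr$region[c(home, seq_rows)] != "CAPE_COD",
                     stringsAsFactors = FALSE)
    wp_list[[b]] <- wp
    ss <- wp[wp$is_stopover, , drop = FALSE]
    if (nrow(ss))
      st_list[[b]] <- data.frame(bird_id = bird_id[b],
                                 station_id = ss$station_id,
                                 start = ss$t_arrive, end = ss$t_depart,
                                 duration_days =
                                   as.numeric(ss$t_depart - ss$t_arrive,
                                              units = "days"),
                                 stringsAsFactors = FALSE)
    rv_list[[b]] <- rv
    br_list[[b]] <- data.frame(
      bird_id = bird_id[b],
      leg = c("SABLE_TO_NS", "GULF_CROSSING"),
      bearing_deg = c(brg_sable[home_i, land_j], gulf_brg),
      stringsAsFactors = FALSE)
    route_class <- switch(route,
                          OVERLAND_FUNDY = "GULF_VIA_NORTH",
                          COASTAL_GULF = "GULF_VIA_SOUTH",
                          DIRECT_SOUTH = "PRESUMED_DIRECT_SOUTH")
    trk_list[[b]] <- data.frame(
      bird_id = bird_id[b], tag_id = tag_id[b], age = a,
      true_departure = dep, true_route = route, route_class = route_class,
      landfall_station = arr$station_id[chain_rows[land_j]],
      cape_span_days = cape_span,
      migration_complete = !is.na(cape_span) & cape_span > 16,
      end_time = t_dep[n_wp], stringsAsFactors = FALSE)
  }
  truth <- list(
    tracks = do.call(rbind, trk_list),
    waypoints = do.call(rbind, wp_list),
    stopovers = if (length(st_list)) do.call(rbind, st_list) else NULL,
    reversals = do.call(rbind, rv_list),
    bearings = do.call(rbind, br_list))
  if (is.null(truth$stopovers))
    truth$stopovers <- data.frame(bird_id = character(), station_id =
                                    character(), start = parse_ts(character()),
                                  end = parse_ts(character()),
                                  duration_days = numeric())
  list(tags = tags, truth = truth, array = arr)
}

#' Simulate the detection log an imperfect array would record
#'
#' Walks each ground-truth track.  While a bird is stationary at a station,
#' each tag burst within ground range (2 km: effectively the station it sits
#' at) is recorded with probability \code{detection_p_ground}.  While in
#' flight along a rhumb-line leg, each burst within \code{flight_range_km}
#' (15 km) of any active station is recorded with probability
#' \code{detection_p_flight}.  Receiver false positives are appended as a
#' Poisson process per station-hour with uniformly random timing (not
#' aligned to any tag's burst grid) and random tag identities.
#'
#' The returned table carries truth columns used only for validation:
#' \code{is_false_positive} and \code{burst_k} (burst index on the tag's
#' grid; consecutive true detections of one tag differ by integer multiples
#' of its burst interval).
#'
#' @param cohort result of \code{\link{simulate_cohort}}
#' @param params \code{\link{cohort_params}}
#' @return detection data.frame sorted by (tag_id, ts, station_id, antenna_id)
#' @export
simulate_detections <- function(cohort, params = cohort_params()) {
  set.seed(params$seed + 2L)
  arr <- cohort$array; tags <- cohort$tags
  wp <- cohort$truth$waypoints
  out <- list(); oi <- 0L
  emit <- function(ts, tag, station, k, fp = FALSE) {
    oi <<- oi + 1L
    out[[oi]] <<- data.frame(ts = ts, tag_id = tag, station_id = station,
                             antenna_id = "a1", signal = NA_real_,
                             is_false_positive = fp, burst_k = k,
                             stringsAsFactors = FALSE)
  }
  # stations within ground range of each station (usually just itself)
  nst <- nrow(arr)
  gmat <- outer(seq_len(nst), seq_len(nst), function(i, j)
    rhumb_distance(arr$lat[i], arr$lon[i], arr$lat[j], arr$lon[j]))
  ground_nb <- lapply(seq_len(nst), function(i)
    which(gmat[i, ] <= params$ground_range_km))
  active_ok <- function(st_rows, ts) {
    arr$active_from[st_rows] <= ts & ts <= arr$active_to[st_rows]
  }
  for (b in seq_len(nrow(cohort$truth$tracks))) {
    bid <- cohort$truth$tracks$bird_id[b]
    trow <- tags[tags$bird_id == bid, ]
    bint <- trow$burst_interval_s
    t0 <- as.numeric(trow$deploy_time)
    w <- wp[wp$bird_id == bid, , drop = FALSE]
    nW <- nrow(w)
    st_row <- match(w$station_id, arr$station_id)
    for (i in seq_len(nW)) {
      # stationary interval at this station
      a0 <- as.numeric(w$t_arrive[i]); a1 <- as.numeric(w$t_depart[i])
      if (a1 > a0) {
        ks <- seq.int(ceiling((a0 - t0) / bint), floor((a1 - t0) / bint))
        if (length(ks) && ks[1] >= 0) {
          keep <- runif(length(ks)) < params$detection_p_ground
          ks <- ks[keep]
          for (nb in ground_nb[[st_row[i]]]) {
            if (!length(ks)) next
            ts <- .POSIXct(t0 + ks * bint, tz = "UTC")
            ok <- active_ok(nb, ts)
            if (any(ok)) emit(ts[ok], trow$tag_id, arr$station_id[nb], ks[ok])
          }
        }
      }
      # flight to the next waypoint
      if (i < nW) {
        f0 <- as.numeric(w$t_depart[i]); f1 <- as.numeric(w$t_arrive[i + 1])
        if (f1 > f0) {
          ks <- seq.int(ceiling((f0 - t0) / bint), floor((f1 - t0) / bint))
          ks <- ks[ks >= 0]
          if (length(ks)) {
            frac <- (t0 + ks * bint - f0) / (f1 - f0)
            pos <- rhumb_point(arr$lat[st_row[i]], arr$lon[st_row[i]],
                               arr$lat[st_row[i + 1]], arr$lon[st_row[i + 1]],
                               frac)
            dmat <- outer(seq_along(ks), seq_len(nst), function(p, s)
              rhumb_distance(pos$lat[p], pos$lon[p], arr$lat[s], arr$lon[s]))
            hit <- which(dmat <= params$flight_range_km, arr.ind = TRUE)
            if (nrow(hit)) {
              keep <- runif(nrow(hit)) < params$detection_p_flight
              hit <- hit[keep, , drop = FALSE]
              if (nrow(hit)) {
                ts <- .POSIXct(t0 + ks[hit[, 1]] * bint, tz = "UTC")
                ok <- arr$active_from[hit[, 2]] <= ts &
                  ts <= arr$active_to[hit[, 2]]
                if (any(ok))
                  emit(ts[ok], trow$tag_id, arr$station_id[hit[ok, 2]],
                       ks[hit[ok, 1]])
              }
            }
          }
        }
      }
    }
  }
  det <- if (oi) do.call(rbind, out) else
    data.frame(ts = parse_ts(character()), tag_id = character(),
               station_id = character(), antenna_id = character(),
               signal = numeric(), is_false_positive = logical(),
               burst_k = numeric())
  if (params$jitter_sd > 0 && nrow(det))
    det$ts <- det$ts + rnorm(nrow(det), 0, params$jitter_sd)
  # false positives: uniform in each station's active overlap with the study
  if (params$false_positive_rate > 0 && nrow(det)) {
    w0 <- min(as.numeric(det$ts)); w1 <- max(as.numeric(det$ts))
    fp_list <- list()
    for (s in seq_len(nst)) {
      o0 <- max(w0, as.numeric(arr$active_from[s]))
      o1 <- min(w1, as.numeric(arr$active_to[s]))
      if (o1 <= o0) next
      hours <- (o1 - o0) / 3600
      nf <- rpois(1, params$false_positive_rate * hours)
      if (nf > 0)
        fp_list[[length(fp_list) + 1]] <- data.frame(
          ts = .POSIXct(runif(nf, o0, o1), tz = "UTC"),
          tag_id = sample(tags$tag_id, nf, replace = TRUE),
          station_id = arr$station_id[s], antenna_id = "a1",
          signal = NA_real_, is_false_positive = TRUE, burst_k = NA_real_,
          stringsAsFactors = FALSE)
    }
    if (length(fp_list)) det <- rbind(det, do.call(rbind, fp_list))
  }
  # a burst on the boundary of two movement segments must appear only once
  det <- det[!duplicated(det[c("tag_id", "station_id", "ts")]), , drop = FALSE]
  sort_detections(det)
}

#' One-call simulation of tables ready for the pipeline
#'
#' Convenience wrapper returning receivers, tags, detections and ground
#' truth for a parameter set.
#' @param params \code{\link{cohort_params}}
#' @return list(receivers, tags, detections, truth)
#' @export
simulate_study <- function(params = cohort_params()) {
  cohort <- simulate_cohort(params)
  det <- simulate_detections(cohort, params)
  list(receivers = cohort$array, tags = cohort$tags, detections = det,
       truth = cohort$truth)
}
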