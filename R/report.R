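# Cohort summary tables and the end-to-end pipeline.

#' Integer percentage of a count ratio
#'
#' Percentages in the summary tables are always recomputed from counts and
#' rounded to the nearest integer for display.  Undefined ratios (zero
#' denominator) are returned as NA.
#' @param count,total non-negative counts
#' @return integer percentage or NA
#' @export
pct_of <- function(count, total) {
  if (is.na(total) || total == 0) return(NA_real_)
  round(100 * count / total)
}

# location-category counts per age from the track table
.age_counts <- function(tt, tagged_by_age) {
  one_age <- function(a) {
    tagged <- tagged_by_age[[a]]
    t_a <- tt[tt$age == a, , drop = FALSE]
    mainland <- t_a$route_class != "NOT_DETECTED_MAINLAND"
    det_ns <- sum(mainland)
    bpi_final <- sum(mainland & !is.na(t_a$final_ns_station) &
                     t_a$final_ns_station == "BPI")
    gulf <- t_a$route_class %in% c("GULF_VIA_NORTH", "GULF_VIA_SOUTH")
    data.frame(
      age = a, tagged = tagged, detected_ns = det_ns,
      final_ns_bpi = bpi_final, final_ns_not_bpi = det_ns - bpi_final,
      detected_gulf = sum(gulf),
      gulf_north = sum(t_a$route_class == "GULF_VIA_NORTH"),
      gulf_south = sum(t_a$route_class == "GULF_VIA_SOUTH"),
      pct_detected_ns = pct_of(det_ns, tagged),
      pct_gulf_of_mainland = pct_of(sum(gulf), det_ns),
      stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, lapply(AGES, one_age))
  total <- counts[1, ]
  total$age <- "TOTAL"
  for (nm in c("tagged", "detected_ns", "final_ns_bpi", "final_ns_not_bpi",
               "detected_gulf", "gulf_north", "gulf_south"))
    total[[nm]] <- sum(counts[[nm]])
  total$pct_detected_ns <- pct_of(total$detected_ns, total$tagged)
  total$pct_gulf_of_mainland <- pct_of(total$detected_gulf,
                                       total$detected_ns)
  rbind(counts, total)
}

#' Summarize a segmented cohort by age and location
#'
#' Reproduces the study's two summary tables from segmentation output:
#' counts of birds tagged, detected in Nova Scotia, with final NS detection
#' on/off BPI, detected around the Gulf of Maine and initially detected in
#' its northern/southern group, with integer percentages recomputed from
#' the counts; and per-age means of stopover count, stopover duration
#' (excluding and at Cape Cod) and rhumb-line flight distance between
#' consecutive stopover sites.  Also reports the share of mainland arrivals
#' first detected within 12 h of their last Sable Island detection (a
#' descriptive statistic of array efficiency, not a filter).
#'
#' @param segmented output of \code{\link{segment_cohort}}
#' @param tags tag table (for tagged totals)
#' @param receivers receiver table
#' @return object of class \code{cohort_summary}: list of data.frames
#'   \code{counts} (one row per age + total), \code{behaviour} (means per
#'   age), and scalars \code{n_within_12h}, \code{n_mainland},
#'   \code{pct_within_12h}
#' @export
summarize_cohort <- function(segmented, tags, receivers) {
  tt <- segmented$track_table
  tagged_by_age <- lapply(setNames(AGES, AGES),
                          function(a) sum(tags$age == a))
  counts <- .age_counts(tt, tagged_by_age)

  st <- segmented$stopovers
  beh <- do.call(rbind, lapply(AGES, function(a) {
    t_a <- tt[tt$age == a & tt$route_class != "NOT_DETECTED_MAINLAND", ,
              drop = FALSE]
    ids <- t_a$bird_id
    s_a <- st[st$bird_id %in% ids, , drop = FALSE]
    n_stop <- if (nrow(t_a)) {
      counts_by_bird <- table(factor(s_a$bird_id, levels = ids))
      mean(as.numeric(counts_by_bird))
    } else NA_real_
    # mean flight distance between consecutive stopover sites, per bird
    fdist <- unlist(lapply(ids, function(bid) {
      s_b <- s_a[s_a$bird_id == bid, , drop = FALSE]
      if (nrow(s_b) < 2) return(numeric(0))
      s_b <- s_b[order(s_b$start_ts), ]
      i <- match(s_b$station_id, receivers$station_id)
      keep <- which(s_b$station_id[-1] != s_b$station_id[-nrow(s_b)])
      if (!length(keep)) return(numeric(0))
      rhumb_distance(receivers$lat[i[keep]], receivers$lon[i[keep]],
                     receivers$lat[i[keep + 1]], receivers$lon[i[keep + 1]])
    }))
    cape <- tt$cape_span_days[tt$age == a]
    data.frame(
      age = a,
      mean_stopovers = n_stop,
      mean_stopover_duration_days = if (nrow(s_a)) mean(s_a$duration_days)
        else NA_real_,
      n_stopovers = nrow(s_a),
      mean_cape_span_days = if (any(!is.na(cape))) mean(cape, na.rm = TRUE)
        else NA_real_,
      n_cape = sum(!is.na(cape)),
      mean_flight_distance_km = if (length(fdist)) mean(fdist) else NA_real_,
      stringsAsFactors = FALSE)
  }))

  # share of mainland arrivals first detected < 12 h after leaving Sable
  be <- segmented$bearings
  sab <- be[be$leg == "SABLE_TO_NS" & !is.na(be$delay_h), , drop = FALSE]
  n_mainland <- sum(tt$route_class != "NOT_DETECTED_MAINLAND")
  n_12 <- sum(sab$delay_h < 12)
  structure(list(counts = counts, behaviour = beh,
                 n_within_12h = n_12, n_mainland = n_mainland,
                 pct_within_12h = pct_of(n_12, n_mainland)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Detections by location and age\n")
  print(x$counts, row.names = FALSE)
  cat("\nStopover behaviour\n")
  print(x$behaviour, row.names = FALSE)
  cat(sprintf("\nMainland arrivals within 12 h of leaving Sable: %d/%d (%s%%)\n",
              x$n_within_12h, x$n_mainland,
              format(x$pct_within_12h)))
  invisible(x)
}

#' Fit the eight age comparisons of a segmented cohort
#'
#' Runs, in order: Gaussian GLM on migration-initiation date, Gaussian GLM
#' on last Nova Scotia date, Poisson GLM on stopover count, mixed model on
#' stopover duration, Fisher's exact tests on Gulf-of-Maine detection by
#' age and on north/south initial Gulf detection by age, and
#' Watson-Williams plus Watson U2 tests on the Sable and Gulf crossing
#' bearings.
#'
#' @param segmented output of \code{\link{segment_cohort}}
#' @param config \code{\link{study_config}}
#' @return data.frame with one row per comparison: \code{comparison, model,
#'   estimate, se, statistic, p_value, p_bracket, n1, n2}
#' @export
analyze_cohort <- function(segmented, config = study_config()) {
  tt <- segmented$track_table
  tt_m <- tt[tt$route_class != "NOT_DETECTED_MAINLAND", , drop = FALSE]
  rows <- list()
  add <- function(comparison, model, estimate = NA, se = NA, statistic = NA,
                  p = NA, bracket = NA_character_, n1 = NA, n2 = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      comparison = comparison, model = model, estimate = estimate, se = se,
      statistic = statistic, p_value = p, p_bracket = bracket,
      n1 = n1, n2 = n2, stringsAsFactors = FALSE)
  }
  both_ages <- function(df) length(unique(df$age)) == 2
  ref_date <- as.Date("2013-09-01")

  if (nrow(tt_m) && both_ages(tt_m)) {
    y <- as.numeric(tt_m$departure_date - ref_date)
    r <- fit_glm(y, tt_m$age, "gaussian")
    add("departure_date", r$model, r$estimate, r$se, r$statistic, r$p_value,
        n1 = r$n_per_group[1], n2 = r$n_per_group[2])
    ok <- !is.na(tt_m$last_ns_date)
    if (sum(ok) && both_ages(tt_m[ok, ])) {
      r <- fit_glm(as.numeric(tt_m$last_ns_date[ok] - ref_date),
                   tt_m$age[ok], "gaussian")
      add("last_ns_date", r$model, r$estimate, r$se, r$statistic, r$p_value,
          n1 = r$n_per_group[1], n2 = r$n_per_group[2])
    }
    r <- fit_glm(tt_m$n_stopovers, tt_m$age, "poisson")
    add("stopover_count", r$model, r$estimate, r$se, r$statistic, r$p_value,
        n1 = r$n_per_group[1], n2 = r$n_per_group[2])
  }
  st <- segmented$stopovers
  if (!is.null(st) && nrow(st)) {
    age_of <- setNames(tt$age, tt$bird_id)
    a <- age_of[st$bird_id]
    if (length(unique(a)) == 2 &&
        all(tapply(st$bird_id, a, function(x) length(unique(x))) >= 2)) {
      r <- tryCatch(
        suppressWarnings(fit_duration_lmm(st$duration_days, st$bird_id, a)),
        error = function(e) NULL)
      if (!is.null(r))
        add("stopover_duration", r$model, r$estimate, r$se, r$statistic,
            r$p_value, n1 = r$n_per_group[1], n2 = r$n_per_group[2])
    }
  }
  # contingency comparisons
  cs <- .age_counts(tt, list(ADULT = sum(tt$age == "ADULT"),
                             JUVENILE = sum(tt$age == "JUVENILE")))
  ad <- cs[cs$age == "ADULT", ]; ju <- cs[cs$age == "JUVENILE", ]
  if (ad$detected_ns > 0 && ju$detected_ns > 0) {
    tab <- matrix(c(ju$detected_gulf, ju$detected_ns - ju$detected_gulf,
                    ad$detected_gulf, ad$detected_ns - ad$detected_gulf),
                  2, 2, byrow = TRUE)
    r <- fisher_exact(tab)
    add("gulf_detection_by_age", r$model, r$estimate, p = r$p_value,
        n1 = ju$detected_ns, n2 = ad$detected_ns)
  }
  if (ad$detected_gulf + ju$detected_gulf > 0) {
    tab <- matrix(c(ju$gulf_north, ju$gulf_south,
                    ad$gulf_north, ad$gulf_south), 2, 2, byrow = TRUE)
    r <- fisher_exact(tab)
    add("gulf_north_south_by_age", r$model, r$estimate, p = r$p_value,
        n1 = ju$detected_gulf, n2 = ad$detected_gulf)
  }
  # bearing comparisons on eligible crossings
  be <- segmented$bearings
  for (lg in c("SABLE_TO_NS", "GULF_CROSSING")) {
    bl <- be[be$leg == lg & be$eligible, , drop = FALSE]
    aa <- bl$bearing_deg[bl$age == "ADULT"]
    jj <- bl$bearing_deg[bl$age == "JUVENILE"]
    nm <- if (lg == "SABLE_TO_NS") "sable_bearing" else "gulf_bearing"
    if (length(aa) >= 2 && length(jj) >= 2) {
      ww <- suppressWarnings(watson_williams(aa, jj))
      add(paste0(nm, "_mean"), "WATSON_WILLIAMS_F", statistic = ww$statistic,
          p = ww$p_value, n1 = length(aa), n2 = length(jj))
      u2 <- suppressWarnings(watson_two_sample(aa, jj, mode = "table"))
      add(paste0(nm, "_homogeneity"), "WATSON_U2", statistic = u2$statistic,
          bracket = u2$p_bracket, n1 = length(aa), n2 = length(jj))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline
#'
#' Orchestrates simulate (optional) -> filter -> segment -> analyze ->
#' summarize, writing every intermediate table, a results table, and a log
#' of seeds and thresholds to \code{out_dir}.  Re-running with an identical
#' configuration reproduces the outputs bit for bit.
#'
#' @param out_dir output directory (created if needed)
#' @param config \code{\link{study_config}}
#' @param params \code{\link{cohort_params}} (used when simulating)
#' @param simulate generate inputs with the cohort simulator; otherwise
#'   \code{receivers}/\code{tags}/\code{detections} CSV paths must be given
#' @param receivers,tags,detections input CSV paths when
#'   \code{simulate = FALSE}
#' @return (invisibly) list with all stage outputs
#' @export
run_pipeline <- function(out_dir, config = study_config(),
                         params = cohort_params(), simulate = TRUE,
                         receivers = NULL, tags = NULL, detections = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (simulate) {
    sim <- simulate_study(params)
    rcv <- sim$receivers; tg <- sim$tags; det <- sim$detections
    write_receivers(rcv, file.path(out_dir, "receivers.csv"))
    write_tags(tg, file.path(out_dir, "tags.csv"))
    write_detections(det, file.path(out_dir, "detections.csv"))
    truth_st <- sim$truth$stopovers
    truth_st$start <- format_ts(truth_st$start)
    truth_st$end <- format_ts(truth_st$end)
    utils::write.csv(truth_st, file.path(out_dir, "truth_stopovers.csv"),
                     row.names = FALSE, quote = FALSE)
    tr <- sim$truth$tracks
    tr$true_departure <- format_ts(tr$true_departure)
    tr$end_time <- format_ts(tr$end_time)
    utils::write.csv(tr, file.path(out_dir, "truth_tracks.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    for (p in c(receivers, tags, detections))
      if (!file.exists(p)) stop("run_pipeline: input file not found: ", p)
    rcv <- read_receivers(receivers)
    tg <- read_tags(tags)
    det <- read_detections(detections, rcv, tg)
  }
  runs <- filter_detections(det, tg, rcv, config)
  utils::write.csv(
    data.frame(tag_id = runs$tag_id, station_id = runs$station_id,
               start_ts = format_ts(runs$start_ts),
               end_ts = format_ts(runs$end_ts),
               n_detections = runs$n_detections, rescued = runs$rescued),
    file.path(out_dir, "runs.csv"), row.names = FALSE, quote = FALSE)
  seg <- segment_cohort(runs, rcv, tg, config)
  for (nm in c("track_table", "flights", "stopovers", "reversals",
               "bearings")) {
    df <- seg[[nm]]
    if (is.null(df)) next
    for (cl in names(df))
      if (inherits(df[[cl]], "POSIXct")) df[[cl]] <- format_ts(df[[cl]])
    utils::write.csv(df, file.path(out_dir, paste0(sub("_table", "s", nm),
                                                   ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  results <- analyze_cohort(seg, config)
  utils::write.csv(results, file.path(out_dir, "results.csv"),
                   row.names = FALSE, quote = FALSE)
  summary <- summarize_cohort(seg, tg, rcv)
  utils::write.csv(summary$counts, file.path(out_dir, "summary_counts.csv"),
                   row.names = FALSE, quote = FALSE)
  log <- c(sprintf("sparrowtrack pipeline %s", format(Sys.time(), "%Y-%m-%d")),
           sprintf("seed: %d", if (simulate) params$seed else config$seed),
           sprintf("config: %s",
                   paste(names(unclass(config)),
                         vapply(unclass(config), function(v)
                           paste(format(v), collapse = ","), ""),
                         sep = "=", collapse = "; ")))
  writeLines(log, file.path(out_dir, "pipeline.log"))
  invisible(list(receivers = rcv, tags = tg, detections = det, runs = runs,
                 segmented = seg, results = results, summary = summary))
}
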