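#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one object.  The
#' defaults reproduce the published filtering and segmentation rules:
#' detection runs need at least 3 consecutive bursts, stopovers are >8 h at
#' one receiver or >10 h gaps between adjacent receivers, overwater bearings
#' are only computed when the crossing gap is under 100 h, and detections at
#' Cape Cod spanning more than 16 days mark a completed migration.
#'
#' @param burst_tolerance_s tolerance (s) on the per-tag burst interval when
#'   chaining consecutive detections.  SensorGnome clocks drift little over
#'   one burst; 0.2 s is permissive for true bursts and still essentially
#'   never matched by uniformly-timed false positives.
#' @param min_run minimum detections for an accepted run (3)
#' @param allow_skip if TRUE a chain may bridge one missed burst (gap of two
#'   burst intervals); default FALSE (strict consecutive)
#' @param rescue_enabled apply the automated 2-detection rescue rule
#'   (default FALSE; see \code{\link{rescue_two_detection_runs}})
#' @param max_speed_mps maximum plausible ground speed (m/s) used by the
#'   rescue rule; observed direct flights were 10-13 m/s, 25 leaves headroom
#'   for wind assistance
#' @param same_recv_h same-receiver stopover threshold, hours (>8)
#' @param adjacent_h adjacent-receiver gap stopover threshold, hours (>10)
#' @param direct_speed_mps minimum ground speed (m/s) for a flight to be
#'   classed direct
#' @param ne_sector numeric length-2, half-open bearing sector \code{(lo, hi]}
#'   in degrees defining "northeast" for reverse-migration detection
#' @param max_delay_h crossing-bearing eligibility window, hours (<100)
#' @param cape_complete_days detection span at Cape Cod (days) beyond which a
#'   bird is considered to have completed migration (>16)
#' @param tz_offset_h display offset from UTC, hours, used only to derive
#'   calendar dates (default -3, Atlantic Daylight Time); nocturnal
#'   departures near midnight UTC must not flip dates arbitrarily
#' @param seed integer random seed recorded in pipeline logs
#' @return an object of class \code{study_config} (a named list)
#' @export
study_config <- function(burst_tolerance_s = 0.2,
                         min_run = 3,
                         allow_skip = FALSE,
                         rescue_enabled = FALSE,
                         max_speed_mps = 25,
                         same_recv_h = 8,
                         adjacent_h = 10,
                         direct_speed_mps = 5,
                         ne_sector = c(0, 90),
                         max_delay_h = 100,
                         cape_complete_days = 16,
                         tz_offset_h = -3,
                         seed = 1L) {
  cfg <- list(burst_tolerance_s = burst_tolerance_s, min_run = min_run,
              allow_skip = allow_skip, rescue_enabled = rescue_enabled,
              max_speed_mps = max_speed_mps, same_recv_h = same_recv_h,
              adjacent_h = adjacent_h, direct_speed_mps = direct_speed_mps,
              ne_sector = ne_sector, max_delay_h = max_delay_h,
              cape_complete_days = cape_complete_days,
              tz_offset_h = tz_offset_h, seed = as.integer(seed))
  for (nm in c("burst_tolerance_s", "min_run", "max_speed_mps", "same_recv_h",
               "adjacent_h", "direct_speed_mps", "max_delay_h",
               "cape_complete_days")) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0)
      stop("study_config: '", nm, "' must be a positive scalar")
  }
  if (length(ne_sector) != 2 || ne_sector[1] >= ne_sector[2])
    stop("study_config: ne_sector must be (lo, hi] with lo < hi")
  class(cfg) <- "study_config"
  cfg
}

#' Read a configuration file
#'
#' Reads a flat key-value YAML file and merges it over the defaults of
#' \code{\link{study_config}} and/or \code{\link{cohort_params}}.  Unknown
#' keys are an error so typos cannot silently fall back to defaults.
#'
#' @param path path to a YAML file
#' @return list with elements \code{config} (study_config) and
#'   \code{params} (cohort_params)
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  kv <- yaml::read_yaml(path)
  if (is.null(kv)) kv <- list()
  cfg_names <- names(formals(study_config))
  par_names <- names(formals(cohort_params))
  unknown <- setdiff(names(kv), c(cfg_names, par_names))
  if (length(unknown))
    stop("read_config: unknown keys: ", paste(unknown, collapse = ", "))
  cfg <- do.call(study_config, kv[intersect(names(kv), cfg_names)])
  par <- do.call(cohort_params, kv[intersect(names(kv), par_names)])
  list(config = cfg, params = par)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}
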