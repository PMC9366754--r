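#' Read GPS telemetry from CSV
#'
#' Expects a header `animal_id,timestamp,x,y` with ISO 8601 timestamps in
#' local clock time and planar coordinates in metres. Rows are sorted by
#' animal and time; strictly increasing timestamps within each animal are
#' enforced.
#'
#' @param path CSV path.
#' @param tz timezone label used to interpret timestamps (a clock label only;
#'   the pipeline never converts between zones).
#' @return a `data.frame` with columns `animal_id` (character),
#'   `timestamp` (POSIXct), `x`, `y`.
#' @export
read_telemetry <- function(path, tz = "UTC") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp", "x", "y")
  if (!all(need %in% names(d)))
    stop("telemetry CSV must have columns: ", paste(need, collapse = ","))
  d$animal_id <- as.character(d$animal_id)
  d$timestamp <- as.POSIXct(d$timestamp, tz = tz,
                            tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                           "%Y-%m-%d %H:%M:%OS",
                                           "%Y-%m-%d %H:%M",
                                           "%Y-%m-%d"))
  validate_telemetry(d)
}

#' Write telemetry to CSV
#' @param locations telemetry `data.frame` (see [read_telemetry()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_telemetry <- function(locations, path) {
  d <- locations
  d$timestamp <- format(d$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(d[, c("animal_id", "timestamp", "x", "y")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_telemetry <- function(d) {
  if (any(!is.finite(d$x)) || any(!is.finite(d$y)))
    stop("telemetry coordinates must be finite")
  if (any(is.na(d$timestamp))) stop("unparseable timestamps in telemetry")
  d <- d[order(d$animal_id, d$timestamp), , drop = FALSE]
  dup <- unlist(tapply(as.numeric(d$timestamp), d$animal_id,
                       function(t) c(FALSE, diff(t) <= 0)), use.names = FALSE)
  if (any(dup))
    stop("timestamps must be strictly increasing within each animal")
  rownames(d) <- NULL
  d
}

#' Keep one location per animal per day
#'
#' Home ranges are estimated from one location per animal per calendar day to
#' damp autocorrelation from sub-daily fix schedules. The earliest fix of
#' each day is kept (a deterministic tie rule).
#'
#' @param locations telemetry `data.frame`.
#' @return telemetry `data.frame` with one row per (animal, date).
#' @export
subsample_daily <- function(locations) {
  d <- locations[order(locations$animal_id, locations$timestamp), ,
                 drop = FALSE]
  day <- format(d$timestamp, "%Y-%m-%d")
  keep <- !duplicated(paste(d$animal_id, day))
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict telemetry to the summer foraging window
#'
#' Keeps fixes whose date falls in the summer season (default July 1 -
#' August 31, inclusive, any year) and whose local clock time is outside the
#' midday rest window. The rest window is half-open: a fix at exactly 11:00
#' is dropped, a fix at exactly 18:00 is kept.
#'
#' @param locations telemetry `data.frame`.
#' @param season character vector `c("07-01", "08-31")` of month-day bounds,
#'   inclusive.
#' @param rest_window character vector `c("11:00", "18:00")`; fixes with
#'   `rest_window[1] <= time < rest_window[2]` are removed. `NULL` disables
#'   the time filter.
#' @return filtered telemetry `data.frame`.
#' @export
filter_foraging_locations <- function(locations,
                                      season = c("07-01", "08-31"),
                                      rest_window = c("11:00", "18:00")) {
  d <- locations
  md <- format(d$timestamp, "%m-%d")
  keep <- md >= season[1] & md <= season[2]
  if (!is.null(rest_window)) {
    hm <- format(d$timestamp, "%H:%M")
    keep <- keep & !(hm >= rest_window[1] & hm < rest_window[2])
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
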