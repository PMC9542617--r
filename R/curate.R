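#' Restrict count events to the breeding-season window
#'
#' Keeps events whose date falls between `start` and `end` (month-day,
#' inclusive on both ends) in any calendar year. The defaults, June 1 through
#' August 31, bound the summer window within which day-of-year differences
#' among sites are small.
#'
#' @param events data frame with at least a `date` column (`Date` or
#'   ISO-8601 character).
#' @param start,end month-day strings `"MM-DD"`.
#' @param skip_bad if `TRUE`, rows with unparseable dates are dropped with a
#'   warning instead of aborting.
#' @return the filtered table; attribute `audit` records rows in/retained/
#'   dropped.
#' @export
filter_season <- function(events, start = "06-01", end = "08-31",
                          skip_bad = FALSE) {
  d <- events$date
  if (!inherits(d, "Date")) d <- as.Date(as.character(d), format = "%Y-%m-%d")
  bad <- which(is.na(d))
  if (length(bad)) {
    msg <- paste0("unparseable date in rows: ",
                  paste(utils::head(bad, 10L), collapse = ", "))
    if (!skip_bad) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  md <- format(d, "%m-%d")
  keep <- !is.na(d) & md >= start & md <= end
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- c(rows_in = nrow(events), rows_retained = nrow(out),
                          rows_dropped = nrow(events) - nrow(out))
  out
}

#' Apply the site-inclusion rules
#'
#' Retains a count circle only if it has at least `min_detection_years`
#' calendar years with a positive count (a "detection year"; zero-count visits
#' contribute to the span but not to detections) and its sampled years span at
#' least `min_span` calendar years (`last - first + 1`). Sites failing either
#' rule are removed. Events should already be season-filtered.
#'
#' @param events data frame with `circle_id`, `year` (or `date`), `count`.
#' @param min_detection_years minimum detection years (default 5).
#' @param min_span minimum calendar span in years (default 10).
#' @return list with `events` (filtered) and `site_summary` (per circle:
#'   `circle_id`, `n_detection_years`, `span_years`, `retained`,
#'   `drop_reason`).
#' @export
filter_sites <- function(events, min_detection_years = 5, min_span = 10) {
  yr <- if ("year" %in% names(events)) events$year else
    as.integer(format(as.Date(events$date), "%Y"))
  ids <- sort(unique(events$circle_id))
  det <- vapply(ids, function(k) {
    length(unique(yr[events$circle_id == k & events$count > 0]))
  }, integer(1))
  span <- vapply(ids, function(k) {
    y <- yr[events$circle_id == k]
    as.integer(max(y) - min(y) + 1L)
  }, integer(1))
  retained <- det >= min_detection_years & span >= min_span
  reason <- rep(NA_character_, length(ids))
  reason[det < min_detection_years & span < min_span] <- "few_detections;short_span"
  reason[det < min_detection_years & span >= min_span] <- "few_detections"
  reason[det >= min_detection_years & span < min_span] <- "short_span"
  summary <- data.frame(circle_id = ids, n_detection_years = det,
                        span_years = span, retained = retained,
                        drop_reason = reason)
  out <- events[events$circle_id %in% ids[retained], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- c(rows_in = nrow(events), rows_retained = nrow(out),
                          rows_dropped = nrow(events) - nrow(out))
  list(events = out, site_summary = summary)
}

#' Validate and attach grid-cell assignments to events
#'
#' Maps each circle (by its `lon`/`lat` planar coordinates, km) to the grid
#' cell containing its centre under the half-open cell convention of
#' [assign_grid()], and adds/overwrites the `cell_id` column. Rejects
#' nonpositive party-hours, the one effort value the model cannot use.
#'
#' @param events event table with `lon`, `lat` and `party_hours`.
#' @param grid an [make_grid()] object.
#' @return the table with `cell_id` set.
#' @export
curate_events <- function(events, grid) {
  if (any(events$party_hours <= 0)) {
    stop("party_hours must be > 0 for every event", call. = FALSE)
  }
  events$cell_id <- assign_grid(events$lon, events$lat, grid)
  events
}
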