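#' Check mouth-lock exclusivity of an event log
#'
#' Returns every bite/strike or surface-breath event whose start time falls
#' inside a mouth-lock interval `[start, start + duration)`. An empty
#' result means the log respects the observed exclusivity (those behaviors
#' happen only between mouth-locks). Intervals are half-open, so an event
#' exactly at the end of an episode is not a violation.
#'
#' @param events Event data frame (`pair_id`, `fish_id`, `behavior`,
#'   `start_min`, `duration_min`).
#' @return Data frame of violating rows (possibly empty).
#' @export
interval_check <- function(events) {
  need <- c("pair_id", "fish_id", "behavior", "start_min", "duration_min")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("malformed log, missing column(s): ",
                         paste(miss, collapse = ", "))
  bad_row <- which(!is.finite(events$start_min) |
                     !is.finite(events$duration_min) |
                     events$duration_min < 0)
  if (length(bad_row))
    stop("malformed record at line ", bad_row[1])
  ml <- events[events$behavior == "mouth_lock", , drop = FALSE]
  pt <- events[events$behavior != "mouth_lock", , drop = FALSE]
  if (nrow(ml) == 0 || nrow(pt) == 0) return(pt[0, , drop = FALSE])
  viol <- vapply(seq_len(nrow(pt)), function(i) {
    m <- ml[ml$pair_id == pt$pair_id[i], , drop = FALSE]
    any(pt$start_min[i] >= m$start_min &
          pt$start_min[i] < m$start_min + m$duration_min)
  }, logical(1))
  pt[viol, , drop = FALSE]
}

#' First occurrence of each behavior
#'
#' @param events Event data frame.
#' @return Named numeric vector of minimum start times for `bite_strike`,
#'   `surface_breath` and `mouth_lock`; `NA` for behaviors absent from the
#'   log (absent means unobserved, not time zero).
#' @export
first_occurrences <- function(events) {
  if (nrow(events) == 0) stop("empty event log")
  behaviors <- c("bite_strike", "surface_breath", "mouth_lock")
  vapply(behaviors, function(b) {
    s <- events$start_min[events$behavior == b]
    if (length(s)) min(s) else NA_real_
  }, numeric(1))
}

#' Mouth-locking summary
#'
#' @param events Event data frame (mouth-lock rows may be duplicated per
#'   fish; episodes are deduplicated on start time within a pair).
#' @param duration Observation duration in minutes (taken from the log's
#'   `duration` attribute if present).
#' @return List with `count` (episodes), `mean_duration` (`NA` if none)
#'   and `fraction_time` (total mouth-lock time / observation time).
#' @export
mouthlock_summary <- function(events, duration = NULL) {
  duration <- duration %||% attr(events, "duration") %||% 60
  ml <- events[events$behavior == "mouth_lock", , drop = FALSE]
  ml <- ml[!duplicated(ml[, c("pair_id", "start_min")]), , drop = FALSE]
  if (nrow(ml) == 0)
    return(list(count = 0L, mean_duration = NA_real_, fraction_time = 0))
  list(count = nrow(ml),
       mean_duration = mean(ml$duration_min),
       fraction_time = sum(ml$duration_min) / duration)
}

#' Sliding-window event series
#'
#' Cuts the observation into overlapping windows `[k * step,
#' k * step + width)` and reports, per window, the event frequency (count
#' of events whose start falls inside; half-open convention) and the total
#' event duration clipped to the window.
#'
#' @param events Event data frame.
#' @param fish Fish id to select (`NULL`: all fish).
#' @param behavior Behavior to select.
#' @param width Window width in minutes (default 2).
#' @param step Window step in minutes (default 1; `step > width` leaves
#'   gaps and warns).
#' @param duration Observation duration (defaults to the log's `duration`
#'   attribute, else 60).
#' @return Data frame of class `"pibs_window_series"` with `window_start`,
#'   `frequency`, `total_duration`; `width` and `step` attributes.
#' @export
window_series <- function(events, fish = NULL, behavior, width = 2, step = 1,
                          duration = NULL) {
  stopifnot(width > 0, step > 0)
  if (step > width) warning("step > width leaves unobserved gaps")
  duration <- duration %||% attr(events, "duration") %||% 60
  if (width > duration) stop("window wider than the observation")
  ev <- events[events$behavior == behavior, , drop = FALSE]
  if (!is.null(fish)) ev <- ev[ev$fish_id == fish, , drop = FALSE]
  starts <- seq(0, duration - width, by = step)
  freq <- integer(length(starts)); dur <- numeric(length(starts))
  for (k in seq_along(starts)) {
    w0 <- starts[k]; w1 <- w0 + width
    inside <- ev$start_min >= w0 & ev$start_min < w1
    freq[k] <- sum(inside)
    # duration clipped to the window, for any event overlapping it
    e0 <- ev$start_min; e1 <- ev$start_min + ev$duration_min
    ov <- pmin(e1, w1) - pmax(e0, w0)
    dur[k] <- sum(ov[ov > 0 & ev$duration_min > 0])
  }
  out <- data.frame(window_start = starts, frequency = freq,
                    total_duration = dur)
  attr(out, "width") <- width; attr(out, "step") <- step
  class(out) <- c("pibs_window_series", "data.frame")
  out
}

#' Behavioral synchrony between two opponents
#'
#' Pearson correlation of the windowed frequency series of the two fish of
#' a pair for one behavior.
#'
#' @param series_a,series_b Results of [window_series()] on the same
#'   window grid.
#' @return Pearson r.
#' @export
behavior_synchrony <- function(series_a, series_b) {
  if (!isTRUE(all.equal(series_a$window_start, series_b$window_start)))
    stop("window grids differ")
  if (nrow(series_a) < 3) stop("need at least 3 windows")
  if (stats::sd(series_a$frequency) == 0 || stats::sd(series_b$frequency) == 0)
    stop("zero-variance series: correlation undefined")
  stats::cor(series_a$frequency, series_b$frequency)
}
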