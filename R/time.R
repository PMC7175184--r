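#' Encode a clock time as hours after an anchor
#'
#' Maps an `"HH:MM"` (24-hour) clock time to continuous hours elapsed
#' since the most recent anchor hour (default noon), so that evening
#' and after-midnight times form a single monotone scale: 21:40 maps to
#' 9.667, 02:00 to 14.0. This makes clock-time attributes (bed time,
#' meal time) usable as ordered attributes in cutpoint models without
#' midnight wraparound artifacts.
#'
#' @param clock_time character vector of `"HH:MM"` times (24-hour).
#' @param anchor anchor hour in `[0, 24)`; default 12 (noon).
#' @return numeric vector of hours in `[0, 24)` after the anchor.
#' @seealso [format_time_of_day()] for the inverse.
#' @export
encode_time_of_day <- function(clock_time, anchor = 12) {
  stopifnot(is.numeric(anchor), anchor >= 0, anchor < 24)
  out <- rep(NA_real_, length(clock_time))
  ok <- !is.na(clock_time)
  m <- regmatches(clock_time[ok],
                  regexec("^([0-9]{1,2}):([0-9]{2})$", clock_time[ok]))
  bad <- vapply(m, length, 0L) != 3L
  hh <- vapply(m, function(g) if (length(g) == 3) as.numeric(g[2]) else NA_real_, 0)
  mm <- vapply(m, function(g) if (length(g) == 3) as.numeric(g[3]) else NA_real_, 0)
  if (any(bad) || any(hh > 23, na.rm = TRUE) || any(mm > 59, na.rm = TRUE))
    stop("malformed clock time: ",
         paste(clock_time[ok][bad | hh > 23 | mm > 59], collapse = ", "))
  h <- hh + mm / 60
  out[ok] <- (h - anchor) %% 24
  out
}

#' Format hours-after-anchor back to a 12-hour clock time
#'
#' Inverse of [encode_time_of_day()], rounded to the minute, rendered
#' as `"h:mm am"` / `"h:mm pm"` (the style used in recommendation
#' statements, e.g. `"9:40 pm"`).
#'
#' @param hours numeric vector of hours after the anchor.
#' @param anchor anchor hour; default 12.
#' @return character vector of formatted times.
#' @export
format_time_of_day <- function(hours, anchor = 12) {
  stopifnot(is.numeric(hours))
  tot <- (round(hours * 60) + round(anchor * 60)) %% (24 * 60)
  hh <- tot %/% 60
  mm <- tot %% 60
  ap <- ifelse(hh < 12, "am", "pm")
  h12 <- hh %% 12
  h12[h12 == 0] <- 12
  ifelse(is.na(hours), NA_character_, sprintf("%d:%02d %s", h12, mm, ap))
}
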