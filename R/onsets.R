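#' Detect daily activity onsets and offsets
#'
#' Applies the classical actogram rule: within each cycle (one
#' folding-period window), after centred moving-average smoothing, the
#' onset is the first bin whose smoothed value reaches \code{onset_frac}
#' (default 20\%) of that cycle's maximum, and the offset is the last bin
#' still at \code{offset_frac} (default 5\%) of the cycle maximum.  Cycles
#' with no suprathreshold activity yield no entry.  Thresholds are
#' relative, so detection is invariant to a global rescaling of counts.
#'
#' When a free-running rhythm drifts across the folding windows, a window
#' can open in the middle of an activity bout, so the plain
#' first-crossing rule would latch onto the tail of the previous cycle's
#' bout.  The crossing is therefore taken from the main activity bout of
#' the window: the contiguous suprathreshold run carrying the largest
#' total activity.  The onset is that run's first bin and the offset the
#' corresponding run's last bin, which reduces to the plain first/last
#' crossing in a clean single-bout cycle.
#'
#' @param trace an \code{\link{activity_trace}} covering at least 2 cycles.
#' @param folding_period cycle length used to window the trace, hours.
#' @param onset_frac,offset_frac relative thresholds.
#' @param smooth_minutes width of the centred moving average; defaults to
#'   15 min for mouse traces and 30 min for fly 1-min traces.
#' @param cycle_offset start of the first cycle window, hours after the
#'   trace start (use to align windows with the expected rest phase).
#' @return an \code{onset_series}: a data frame with columns \code{day}
#'   (1-based cycle index), \code{onset}, \code{offset} (hours within the
#'   cycle) and \code{onset_abs}, \code{offset_abs} (hours on the schedule
#'   axis); attributes record the folding period and parameters.
#' @export
detect_onsets <- function(trace, folding_period = 24,
                          onset_frac = 0.20, offset_frac = 0.05,
                          smooth_minutes = NULL, cycle_offset = 0) {
  stopifnot(inherits(trace, "activity_trace"))
  bw <- trace$bin_minutes / 60
  n <- length(trace$counts)
  if (n * bw < 2 * folding_period)
    stop("trace must cover at least 2 cycles")
  if (is.null(smooth_minutes))
    smooth_minutes <- if (trace$species == "mouse") 15 else 30
  k <- max(1L, round(smooth_minutes / trace$bin_minutes))
  if (k %% 2L == 0L) k <- k + 1L
  sm <- if (k > 1L)
    stats::filter(trace$counts, rep(1 / k, k), sides = 2)
  else trace$counts
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- trace$counts[is.na(sm)]
  tm <- trace_times(trace)
  t0 <- trace$start + cycle_offset
  n_cyc <- floor((n * bw - cycle_offset) / folding_period)
  rows <- vector("list", n_cyc)
  for (d in seq_len(n_cyc)) {
    lo <- t0 + (d - 1) * folding_period
    hi <- lo + folding_period
    idx <- which(tm >= lo & tm < hi)
    if (length(idx) == 0L) next
    m <- max(sm[idx])
    if (m <= 0) next
    on_i <- idx[.main_run(sm[idx] >= onset_frac * m, sm[idx])[1]]
    off_i <- idx[.main_run(sm[idx] >= offset_frac * m, sm[idx])[2]]
    rows[[d]] <- data.frame(day = d,
                            onset = tm[on_i] - lo,
                            offset = tm[off_i] - lo,
                            onset_abs = tm[on_i],
                            offset_abs = tm[off_i])
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(day = integer(0), onset = numeric(0),
                      offset = numeric(0), onset_abs = numeric(0),
                      offset_abs = numeric(0))
  structure(out,
            folding_period = folding_period,
            params = list(onset_frac = onset_frac,
                          offset_frac = offset_frac,
                          smooth_minutes = smooth_minutes,
                          cycle_offset = cycle_offset),
            class = c("onset_series", "data.frame"))
}

# first and last index of the contiguous above-threshold run with the
# largest total activity (the window's main bout); a run touching the
# window start is the spill-over of the previous cycle's bout, so it is
# excluded whenever another run exists
.main_run <- function(above, values) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) > 1L && starts[runs[1]] == 1L)
    runs <- runs[-1L]
  sums <- vapply(runs, function(j) sum(values[starts[j]:ends[j]]),
                 numeric(1))
  j <- runs[which.max(sums)]
  c(starts[j], ends[j])
}

# unwrap within-cycle onset times: successive differences mapped into
# (-T/2, T/2], then accumulated from the first onset
unwrap_onsets <- function(onset, period) {
  if (length(onset) < 2L) return(onset)
  d <- diff(onset)
  d <- d - period * round(d / period)
  cumsum(c(onset[1], d))
}

#' Free-running period from an onset regression
#'
#' Unwraps the daily onset times (successive differences mapped into
#' \code{(-T/2, T/2]}) and fits ordinary least squares of onset time
#' against day; the implied period is the folding period plus the slope
#' (hours/day).  Days are subjective cycles: when a fast-drifting rhythm
#' packs two onsets into one folding window (or skips one), the cycle
#' index is recovered from the absolute onset spacing so the slope is not
#' biased by the window grid.
#'
#' @param onsets an \code{\link{detect_onsets}} result.
#' @param day_range optional length-2 vector restricting the fit to days
#'   in \code{[day_range[1], day_range[2]]}.
#' @param folding_period folding period; defaults to the one recorded in
#'   \code{onsets}.
#' @return an object of class \code{regression_fit} with \code{slope}
#'   (h/day), \code{intercept}, \code{r2}, \code{n_days} and
#'   \code{implied_period} (h).
#' @export
onset_regression <- function(onsets, day_range = NULL,
                             folding_period = attr(onsets,
                                                   "folding_period")) {
  stopifnot(inherits(onsets, "onset_series"))
  df <- as.data.frame(onsets)
  if (!is.null(day_range))
    df <- df[df$day >= day_range[1] & df$day <= day_range[2], ,
             drop = FALSE]
  if (nrow(df) < 3L) stop("need at least 3 onsets for a regression")
  # cycle index from absolute onset spacing; equals day spacing for a
  # well-behaved rhythm, but stays correct when a window holds two bouts
  k <- c(0, cumsum(pmax(1, round(diff(df$onset_abs) / folding_period))))
  y <- df$onset_abs - k * folding_period
  fit <- stats::lm(y ~ k)
  s <- suppressWarnings(summary(fit))  # noise-free fits are legitimate
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = s$r.squared,
                 n_days = nrow(df),
                 implied_period = folding_period +
                   unname(stats::coef(fit)[2])),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat("<regression_fit> period ", round(x$implied_period, 3), " h (",
      x$n_days, " onsets, r2 = ", round(x$r2, 3), ")\n", sep = "")
  invisible(x)
}

#' Phase shift from extended regression lines around a pulse
#'
#' Fits separate onset regressions to a pre-pulse window and a post-pulse
#' window (the latter starting \code{transient_skip} days after the pulse
#' to skip transients), extends both lines to the day after the pulse, and
#' returns (pre-line onset) - (post-line onset) there: positive values are
#' phase advances, negative values delays.
#'
#' @param onsets an \code{\link{detect_onsets}} result.
#' @param pulse_day day index of the light pulse.
#' @param pre_days,post_days window lengths in days.
#' @param transient_skip days skipped after the pulse.
#' @return signed phase shift in hours.
#' @export
phase_shift_from_pulse <- function(onsets, pulse_day, pre_days = 10,
                                   post_days = 10, transient_skip = 3) {
  stopifnot(inherits(onsets, "onset_series"))
  period <- attr(onsets, "folding_period")
  df <- as.data.frame(onsets)
  df$y <- unwrap_onsets(df$onset, period)
  pre <- df[df$day >= pulse_day - pre_days & df$day < pulse_day, ,
            drop = FALSE]
  post <- df[df$day > pulse_day + transient_skip &
               df$day <= pulse_day + transient_skip + post_days, ,
             drop = FALSE]
  if (nrow(pre) < 3L || nrow(post) < 3L)
    stop("insufficient onsets on one side of the pulse")
  f_pre <- stats::lm(y ~ day, data = pre)
  f_post <- stats::lm(y ~ day, data = post)
  eval_day <- data.frame(day = pulse_day + 1)
  unname(stats::predict(f_pre, eval_day) -
           stats::predict(f_post, eval_day))
}

#' Phase angle of entrainment
#'
#' Mean signed difference between activity onset and lights-off over
#' \code{n_days} consecutive detected onsets; negative values mean the
#' onset precedes lights-off.
#'
#' @param onsets an \code{\link{detect_onsets}} result.
#' @param schedule the \code{\link{build_schedule}} the animal was under.
#' @param n_days number of consecutive days (default 6); the last
#'   \code{n_days} detected onsets are used.
#' @return mean phase angle in hours.
#' @export
phase_angle_of_entrainment <- function(onsets, schedule, n_days = 6) {
  stopifnot(inherits(onsets, "onset_series"),
            inherits(schedule, "light_schedule"))
  df <- as.data.frame(onsets)
  if (nrow(df) < n_days) stop("fewer than n_days onsets available")
  df <- utils::tail(df, n_days)
  if (any(diff(df$day) != 1L))
    stop("onsets in the window are not consecutive")
  offs <- lights_off_times(schedule)
  if (length(offs) == 0L) stop("schedule has no lights-off events")
  ang <- vapply(df$onset_abs, function(o) o - offs[which.min(abs(offs - o))],
                numeric(1))
  mean(ang)
}

#' Mean daily activity
#'
#' Total counts divided by the number of days over a selected window.
#'
#' @param trace an \code{\link{activity_trace}}.
#' @param n_days number of consecutive days to average.
#' @param start_day first day of the window (0-based; default 0).
#' @return counts per day.
#' @export
mean_daily_activity <- function(trace, n_days, start_day = 0) {
  stopifnot(inherits(trace, "activity_trace"))
  bw <- trace$bin_minutes / 60
  tm <- trace_times(trace) - trace$start
  lo <- start_day * 24
  hi <- lo + n_days * 24
  if (hi > length(trace$counts) * bw + 1e-9)
    stop("window exceeds the trace")
  sum(trace$counts[tm >= lo & tm < hi]) / n_days
}
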