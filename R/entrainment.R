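#' Daily phase shifts after a jetlag schedule shift
#'
#' Measures the cumulative re-entrainment curve after an abrupt schedule
#' shift.  The baseline is the mean onset phase relative to the OLD
#' (pre-shift) schedule over the last \code{baseline_days} pre-shift days;
#' for each post-shift day the cumulative shift is the signed displacement
#' of that day's onset from the baseline, with positive values pointing in
#' the direction of the schedule shift.
#'
#' @param onsets a \code{\link{detect_onsets}} result (folded at the
#'   pre-shift cycle length, normally 24 h).
#' @param schedule the \code{acute_jetlag} \code{\link{build_schedule}}.
#' @param shift_day day index of the shift; defaults to the schedule's
#'   \code{shift_day}.
#' @param baseline_days pre-shift days averaged for the baseline
#'   (default 6).
#' @param tolerance,consecutive stability criterion echoed into the
#'   result (see \code{\link{days_to_reentrain}}).
#' @return an object of class \code{reentrainment} with \code{daily_shift}
#'   (data frame: \code{day_post}, \code{shift} in hours),
#'   \code{total_shift}, \code{direction} and \code{criterion}.
#' @export
daily_phase_shifts <- function(onsets, schedule,
                               shift_day = schedule$params$shift_day,
                               baseline_days = 6,
                               tolerance = 0.5, consecutive = 3) {
  stopifnot(inherits(onsets, "onset_series"),
            inherits(schedule, "light_schedule"))
  if (is.null(shift_day)) stop("no shift day available")
  period <- attr(onsets, "folding_period")
  df <- as.data.frame(onsets)
  df$y <- unwrap_onsets(df$onset, period)
  pre <- df[df$day > shift_day - baseline_days & df$day <= shift_day, ,
            drop = FALSE]
  if (nrow(pre) == 0L) stop("no pre-shift baseline onsets")
  # baseline onset phase on the old (unshifted) cycle grid; the folding
  # windows keep running on that grid after the shift, so post-shift
  # displacement from this baseline is the cumulative re-entrainment
  base <- mean(pre$y)
  post <- df[df$day > shift_day, , drop = FALSE]
  sgn <- if (schedule$params$direction == "advance") -1 else 1
  shift <- sgn * (post$y - base)
  structure(list(daily_shift = data.frame(day_post = post$day - shift_day,
                                          shift = shift),
                 total_shift = schedule$params$shift_h,
                 direction = schedule$params$direction,
                 criterion = list(tolerance = tolerance,
                                  consecutive = consecutive)),
            class = "reentrainment")
}

#' @export
print.reentrainment <- function(x, ...) {
  cat("<reentrainment> ", x$direction, " of ", x$total_shift, " h, ",
      nrow(x$daily_shift), " post-shift days\n", sep = "")
  invisible(x)
}

#' Days to re-entrain after a schedule shift
#'
#' The first post-shift day on which the cumulative shift is within
#' \code{tolerance} of the full schedule shift and stays there for
#' \code{consecutive} days.
#'
#' @param result a \code{\link{daily_phase_shifts}} result.
#' @param total_shift full shift magnitude, hours; defaults to the value
#'   recorded in \code{result}.
#' @param tolerance stability tolerance, hours (default 0.5).
#' @param consecutive days the criterion must hold (default 3).
#' @return a list with \code{days} (integer, \code{NA} if never attained)
#'   and \code{entrained} (logical).
#' @export
days_to_reentrain <- function(result, total_shift = result$total_shift,
                              tolerance = 0.5, consecutive = 3) {
  stopifnot(inherits(result, "reentrainment"))
  ds <- result$daily_shift
  ok_days <- ds$day_post[abs(ds$shift - total_shift) <= tolerance]
  for (d in sort(ok_days)) {
    need <- d + seq_len(consecutive) - 1
    if (all(need %in% ok_days))
      return(list(days = as.integer(d), entrained = TRUE))
  }
  list(days = NA_integer_, entrained = FALSE)
}

#' Morning and evening anticipation indices
#'
#' Morning AI = (activity in the 3 h preceding lights-on) / (activity in
#' the 6 h preceding lights-on); evening AI likewise around lights-off.
#' Counts are summed over the last \code{last_n_days} full LD cycles; an
#' index of 0.5 is the no-anticipation null (uniform activity in the 6-h
#' window), values above 0.5 indicate anticipatory behaviour.  Indices
#' are undefined (NA, flagged) when the 6-h window holds no activity.
#'
#' @param traces an \code{\link{activity_trace}} or list of traces.
#' @param schedule the LD \code{\link{build_schedule}}.
#' @param last_n_days number of trailing LD cycles summed (default 3).
#' @return data frame with one row per subject: \code{subject_id},
#'   \code{morning_AI}, \code{evening_AI}, \code{morning_defined},
#'   \code{evening_defined}.
#' @export
anticipation_indices <- function(traces, schedule, last_n_days = 3) {
  if (inherits(traces, "activity_trace")) traces <- list(traces)
  stopifnot(inherits(schedule, "light_schedule"))
  cyc <- schedule$cycles
  if (nrow(cyc) < last_n_days) stop("not enough LD cycles in schedule")
  ai_one <- function(trace, events) {
    tm <- trace_times(trace)
    s3 <- s6 <- 0
    for (ev in events) {
      s3 <- s3 + sum(trace$counts[tm >= ev - 3 & tm < ev])
      s6 <- s6 + sum(trace$counts[tm >= ev - 6 & tm < ev])
    }
    if (s6 == 0) NA_real_ else s3 / s6
  }
  out <- lapply(traces, function(tr) {
    span <- tr$start + length(tr$counts) * tr$bin_minutes / 60
    usable <- cyc[cyc$lights_off <= span, , drop = FALSE]
    if (nrow(usable) < last_n_days)
      stop("trace covers fewer than last_n_days LD cycles")
    usable <- utils::tail(usable, last_n_days)
    # lights-on of the NEXT cycle bounds each night; morning windows end
    # at each lights-on event after the first usable cycle
    ons <- cyc$lights_on[cyc$lights_on > min(usable$lights_on) &
                           cyc$lights_on <= span]
    ons <- utils::tail(ons, last_n_days)
    m <- ai_one(tr, ons)
    e <- ai_one(tr, usable$lights_off)
    data.frame(subject_id = tr$subject_id,
               morning_AI = m, evening_AI = e,
               morning_defined = !is.na(m),
               evening_defined = !is.na(e))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group relative-activity profile
#'
#' Averages each subject's activity over the last \code{last_n_days} LD
#' days on a zeitgeber-time axis, converts to 1-h bins, averages across
#' subjects and normalizes to the group maximum (peak value exactly 1).
#'
#' @param traces list of \code{\link{activity_trace}} objects (one group).
#' @param schedule the LD \code{\link{build_schedule}}.
#' @param last_n_days trailing LD days used (default 3).
#' @return numeric vector of length 24 (ZT 0-23), max exactly 1.
#' @export
relative_activity_profile <- function(traces, schedule, last_n_days = 3) {
  if (inherits(traces, "activity_trace")) traces <- list(traces)
  if (length(traces) == 0L) stop("empty group")
  stopifnot(inherits(schedule, "light_schedule"))
  prof_one <- function(tr) {
    span <- tr$start + length(tr$counts) * tr$bin_minutes / 60
    ons <- lights_on_times(schedule)
    ons <- ons[ons + 24 <= span + 1e-9]
    if (length(ons) < last_n_days)
      stop("trace covers fewer than last_n_days LD cycles")
    ons <- utils::tail(ons, last_n_days)
    tm <- trace_times(tr)
    acc <- numeric(24)
    for (o in ons) {
      zt <- tm - o
      keep <- zt >= 0 & zt < 24
      hr <- floor(zt[keep]) + 1L
      acc <- acc + as.numeric(tapply(tr$counts[keep], factor(hr, 1:24),
                                     sum, default = 0))
    }
    acc / last_n_days
  }
  mat <- vapply(traces, prof_one, numeric(24))
  grp <- rowMeans(mat)
  if (max(grp) == 0) stop("group has no activity")
  prof <- grp / max(grp)
  names(prof) <- paste0("ZT", 0:23)
  prof
}

#' Classify a fly's free-running phenotype in constant darkness
#'
#' A window is called rhythmic when the chi-squared periodogram shows a
#' significant peak AND the FFT relative power exceeds
#' \code{fft_threshold}.  Labels: \code{rhythmic} (both windows rhythmic,
#' stable period), \code{arrhythmic} (neither), \code{delayed_arrhythmic}
#' (first window only), \code{rhythmic_unstable_period} (both windows but
#' the SD of the period across sliding 6-day windows exceeds
#' \code{period_sd_threshold}).
#'
#' @param trace a DD \code{\link{activity_trace}} of at least 12 days.
#' @param week1,week2 day ranges (1-based, inclusive) of the two analysis
#'   windows; defaults DD days 1-6 and 7-12.
#' @param fft_threshold FFT rhythm-power threshold (default 0.01).
#' @param alpha periodogram significance level.
#' @param period_sd_threshold stability threshold on the SD of
#'   sliding-window periods, hours (default 0.5).
#' @param scan periodogram scan range, hours.
#' @param analysis_bin_minutes bin width the trace is rebinned to before
#'   the periodogram scans (default 5 min; 1-min records carry no extra
#'   period information at circadian scales and cost a 5-fold slower
#'   scan).
#' @return an object of class \code{rhythm_class}: a list with
#'   \code{label} and \code{evidence} (per-window peaks, powers, periods).
#' @export
classify_fly_dd <- function(trace, week1 = c(1, 6), week2 = c(7, 12),
                            fft_threshold = 0.01, alpha = 0.05,
                            period_sd_threshold = 0.5,
                            scan = c(18, 30),
                            analysis_bin_minutes = 5) {
  stopifnot(inherits(trace, "activity_trace"))
  if (trace$bin_minutes < analysis_bin_minutes &&
      analysis_bin_minutes %% trace$bin_minutes == 0)
    trace <- rebin_trace(trace, analysis_bin_minutes)
  bw <- trace$bin_minutes / 60
  ndays <- length(trace$counts) * bw / 24
  if (ndays < week2[2]) stop("DD segment shorter than the analysis windows")
  win_stats <- function(d1, d2) {
    sub <- trace_window(trace, trace$start + (d1 - 1) * 24,
                        trace$start + d2 * 24)
    pg <- tryCatch(chi_square_periodogram(sub, scan[1], scan[2],
                                          alpha = alpha),
                   error = function(e) NULL)
    fp <- fft_relative_power(sub, band = scan)
    peak <- if (!is.null(pg) && nrow(pg$peaks) > 0) pg$peaks$period[1]
            else NA_real_
    list(sig = !is.null(pg) && nrow(pg$peaks) > 0,
         power = fp$rhythm_power, period = peak)
  }
  w1 <- win_stats(week1[1], week1[2])
  w2 <- win_stats(week2[1], week2[2])
  r1 <- w1$sig && w1$power > fft_threshold
  r2 <- w2$sig && w2$power > fft_threshold
  # sliding windows across the full segment for period stability; short
  # windows track day-to-day period fluctuation that longer windows
  # average away (window length bounded below by 3 x max scan period)
  stability_window <- max(4, ceiling(3 * scan[2] / 24))
  periods <- c()
  if (r1 && r2) {
    for (d in seq_len(floor(ndays) - stability_window + 1)) {
      ws <- win_stats(d, d + stability_window - 1)
      if (!is.na(ws$period)) periods <- c(periods, ws$period)
    }
  }
  # de-biased per-day period-fluctuation estimate: windows sliding by one
  # day differ by (tau(d+W) - tau(d)) / W under a drifting period, so the
  # SD of successive window-period differences, scaled by W / sqrt(W) =
  # sqrt(W), estimates the day-to-day period-change SD that the window
  # averaging would otherwise understate
  period_sd <- if (length(periods) >= 3)
    stats::sd(diff(periods)) * sqrt(stability_window)
  else 0
  label <- if (r1 && r2) {
    if (period_sd > period_sd_threshold) "rhythmic_unstable_period"
    else "rhythmic"
  } else if (r1 && !r2) "delayed_arrhythmic"
  else "arrhythmic"
  structure(list(label = label,
                 evidence = list(week1 = w1, week2 = w2,
                                 period_sd = period_sd)),
            class = "rhythm_class")
}

#' Classify entrainment vs internal desynchrony under chronic jetlag
#'
#' Runs the chi-squared periodogram over 16-28 h on the chronic-jetlag
#' segment.  A significant peak in \code{short_band} (near the effective
#' zeitgeber period, ~21 h) marks an entrained component; an additional
#' significant peak in \code{long_band} marks internal desynchrony,
#' subtyped by whether the long component's period exceeds 24 h
#' (\code{desynchronized}) or not (\code{desynchronized_short_period}).
#' No significant peak at all gives \code{arrhythmic}.
#'
#' Because a strong periodic component produces chi-squared-periodogram
#' sidelobes at rational multiples of its period (which can exceed the
#' significance line and mimic a second rhythm), the long-band search is
#' run on a pre-whitened trace.  An entrained component is periodic at
#' the schedule's shift-block length (e.g. 2 x 24 h - 6 h = 42 h for a
#' 6-h advance every 2 days, whose cycles alternate 24 h and 18 h), so
#' the mean waveform folded at the block period is subtracted before the
#' residual is scanned for the second, free-running component.
#'
#' @param trace an \code{\link{activity_trace}} covering the jetlag
#'   segment (>= 21 days).
#' @param schedule the chronic-jetlag \code{\link{build_schedule}}
#'   (optional, used only to centre the short band on the effective
#'   zeitgeber period).
#' @param short_band,long_band period bands in hours.
#' @param alpha periodogram significance level.
#' @param scan periodogram scan range.
#' @param prewhiten subtract the short-component waveform before the
#'   long-band search (default TRUE).
#' @param settle_days days discarded at the start of the segment before
#'   analysis (default 4): the first cycles after the paradigm begins are
#'   a re-entrainment transient that belongs to neither steady-state
#'   component.
#' @return an object of class \code{rhythm_class} with \code{label} in
#'   \{entrained, desynchronized, desynchronized_short_period,
#'   arrhythmic\} and the supporting peak evidence.
#' @export
classify_chronic_jetlag <- function(trace, schedule = NULL,
                                    short_band = c(20, 22),
                                    long_band = c(22.5, 28),
                                    alpha = 0.05, scan = c(16, 28),
                                    prewhiten = TRUE, settle_days = 4) {
  stopifnot(inherits(trace, "activity_trace"))
  bw <- trace$bin_minutes / 60
  if (length(trace$counts) * bw < 21 * 24)
    stop("chronic-jetlag segment must cover at least 21 days")
  if (settle_days > 0 &&
      length(trace$counts) * bw >= (21 + settle_days) * 24)
    trace <- trace_window(trace, trace$start + settle_days * 24,
                          trace$start + length(trace$counts) * bw)
  pg <- tryCatch(chi_square_periodogram(trace, scan[1], scan[2],
                                        alpha = alpha, bonferroni = TRUE),
                 error = function(e) NULL)
  pk <- if (is.null(pg)) data.frame(period = numeric(0),
                                    Q = numeric(0), excess = numeric(0))
        else pg$peaks
  in_short <- pk[pk$period >= short_band[1] & pk$period <= short_band[2], ,
                 drop = FALSE]
  short_period <- if (nrow(in_short) > 0) in_short$period[1] else NA_real_

  long_pk <- pk[pk$period >= long_band[1] & pk$period <= long_band[2], ,
                drop = FALSE]
  if (prewhiten && !is.na(short_period)) {
    # subtract the mean waveform folded at the zeitgeber block period;
    # the residual retains a genuine second (free-running) rhythm but
    # not the entrained component or its sidelobes
    block_h <- if (!is.null(schedule) &&
                   schedule$paradigm == "chronic_jetlag") {
      p <- schedule$params
      sgn <- if (p$direction == "advance") -1 else 1
      p$every_n_days * p$cycle_length + sgn * p$shift_h
    } else 2 * short_period
    # square-root transform stabilizes the Poisson variance so the
    # chi-squared significance line is valid for the residual scan
    x <- sqrt(trace$counts)
    P <- round(block_h / bw)
    K <- length(x) %/% P
    xu <- x[seq_len(K * P)]
    mh <- rowMeans(matrix(xu, nrow = P, ncol = K))
    res <- xu - rep(mh, K)
    res_tr <- trace
    res_tr$counts <- res - min(res)  # shift to keep counts non-negative
    pg2 <- tryCatch(chi_square_periodogram(res_tr, scan[1], scan[2],
                                           alpha = alpha,
                                           bonferroni = TRUE),
                    error = function(e) NULL)
    pk2 <- if (is.null(pg2)) data.frame(period = numeric(0),
                                        Q = numeric(0),
                                        excess = numeric(0))
           else pg2$peaks
    long_pk <- pk2[pk2$period >= long_band[1] &
                     pk2$period <= long_band[2], , drop = FALSE]
  }
  long_period <- if (nrow(long_pk) > 0) long_pk$period[1] else NA_real_

  label <- if (nrow(pk) == 0) "arrhythmic"
  else if (!is.na(short_period) && is.na(long_period)) "entrained"
  else if (!is.na(long_period)) {
    if (long_period > 24) "desynchronized" else "desynchronized_short_period"
  } else "arrhythmic"
  structure(list(label = label,
                 evidence = list(peaks = pk, long_peaks = long_pk,
                                 short_period = short_period,
                                 long_period = long_period)),
            class = "rhythm_class")
}

#' @export
print.rhythm_class <- function(x, ...) {
  cat("<rhythm_class> ", x$label, "\n", sep = "")
  invisible(x)
}

#' Pearson chi-squared test on a category table
#'
#' Two-sided Pearson chi-squared test without continuity correction on a
#' groups x categories contingency table, as used for comparing the
#' distribution of behavioural phenotype categories between genotypes.
#'
#' @param table integer matrix (at least 2 x 2) of non-negative counts
#'   with no all-zero margin.
#' @return a list with \code{statistic}, \code{dof} and \code{p.value}.
#' @examples
#' category_table_test(rbind(c(4, 5, 0), c(11, 0, 2)))$p.value  # 0.0072
#' @export
category_table_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("table must be at least 2 x 2")
  if (any(table < 0) || any(table != round(table)))
    stop("table must hold non-negative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table has an all-zero margin")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic),
       dof = unname(ht$parameter),
       p.value = unname(ht$p.value))
}
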