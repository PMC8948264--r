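#' Build a light schedule
#'
#' Constructs the piecewise-constant light-intensity function used throughout
#' the package: standard 12:12 LD, constant darkness (DD), constant light
#' (LL), stepped-intensity LL, an abrupt single jetlag shift, or a chronic
#' jetlag paradigm that shifts the LD cycle by a fixed number of hours every
#' few days (e.g. a 6-h advance every 2 days, effective zeitgeber period
#' 21 h).
#'
#' Time is measured in real-valued hours from an origin placed at the first
#' lights-on; all intervals are half-open \code{[start, end)}.  Schedule
#' shifts are implemented, by default, by truncating the dark phase of the
#' transition night (an advance brings lights-on forward), the standard
#' implementation of LD advances; set \code{truncate = "light"} to shorten
#' the light phase instead.
#'
#' @param paradigm one of \code{"LD"}, \code{"DD"}, \code{"LL"},
#'   \code{"stepped_LL"}, \code{"acute_jetlag"}, \code{"chronic_jetlag"}.
#' @param days total span of the schedule in (24-h) days; ignored for
#'   \code{stepped_LL}, whose span is the sum of the dwell times.
#' @param photoperiod hours of light per cycle (default 12).
#' @param cycle_length nominal cycle length in hours (default 24).
#' @param intensity light intensity in lux during the light phase.
#' @param shift_h shift magnitude in hours (jetlag paradigms).
#' @param direction \code{"advance"} or \code{"delay"} (jetlag paradigms).
#' @param shift_day for \code{acute_jetlag}: the shift takes effect after
#'   this many complete baseline cycles.
#' @param every_n_days for \code{chronic_jetlag}: days between shifts.
#' @param baseline_days for \code{chronic_jetlag}: plain LD cycles before
#'   the shifting block structure starts (default 0).
#' @param intensities for \code{stepped_LL}: vector of lux levels.
#' @param dwell_days for \code{stepped_LL}: days spent at each level.
#' @param truncate which phase of the transition cycle absorbs a shift:
#'   \code{"dark"} (default) or \code{"light"}.
#'
#' @return an object of class \code{light_schedule} with components
#'   \code{paradigm}, \code{span} (hours), \code{cycles} (data frame of
#'   per-cycle \code{lights_on}/\code{lights_off} times, empty for DD/LL),
#'   \code{intervals} (data frame of light intervals with intensities) and
#'   \code{params}.
#' @examples
#' sch <- build_schedule("chronic_jetlag", days = 28, shift_h = 6,
#'                       every_n_days = 2)
#' effective_zeitgeber_period(sch)  # 21
#' @export
build_schedule <- function(paradigm = c("LD", "DD", "LL", "stepped_LL",
                                        "acute_jetlag", "chronic_jetlag"),
                           days = NULL,
                           photoperiod = 12,
                           cycle_length = 24,
                           intensity = 200,
                           shift_h = NULL,
                           direction = c("advance", "delay"),
                           shift_day = NULL,
                           every_n_days = NULL,
                           baseline_days = 0,
                           intensities = NULL,
                           dwell_days = NULL,
                           truncate = c("dark", "light")) {
  paradigm <- match.arg(paradigm)
  direction <- match.arg(direction)
  truncate <- match.arg(truncate)
  if (paradigm != "stepped_LL") {
    if (!is.numeric(days) || length(days) != 1L || is.na(days) ||
        days <= 0)
      stop("'days' must be a single positive number")
  } else if (is.null(days) || is.na(days)) {
    days <- 1  # span is determined by the dwell times below
  }
  if (photoperiod < 0 || photoperiod > cycle_length)
    stop("'photoperiod' must lie in [0, cycle_length]")
  if (intensity < 0) stop("'intensity' must be >= 0")
  span <- days * 24

  make_cycles <- function(lights_on, photoperiods, lux) {
    data.frame(cycle = seq_along(lights_on),
               lights_on = lights_on,
               lights_off = lights_on + photoperiods,
               intensity = lux)
  }

  if (paradigm == "LD") {
    on <- seq(0, span - cycle_length, by = cycle_length)
    cycles <- make_cycles(on, photoperiod, intensity)
  } else if (paradigm == "DD") {
    cycles <- make_cycles(numeric(0), numeric(0), numeric(0))
  } else if (paradigm == "LL") {
    cycles <- make_cycles(0, span, intensity)
  } else if (paradigm == "stepped_LL") {
    if (is.null(intensities) || is.null(dwell_days))
      stop("stepped_LL requires 'intensities' and 'dwell_days'")
    if (any(intensities < 0) || any(dwell_days <= 0))
      stop("invalid stepped_LL parameters")
    dwell_days <- rep_len(dwell_days, length(intensities))
    on <- cumsum(c(0, utils::head(dwell_days, -1) * 24))
    cycles <- make_cycles(on, dwell_days * 24, intensities)
    span <- sum(dwell_days) * 24
  } else if (paradigm == "acute_jetlag") {
    if (is.null(shift_h) || is.null(shift_day))
      stop("acute_jetlag requires 'shift_h' and 'shift_day'")
    if (shift_h <= 0 || shift_h >= cycle_length)
      stop("'shift_h' must lie in (0, cycle_length)")
    sgn <- if (direction == "advance") -1 else 1
    n_cyc <- ceiling((span + abs(shift_h)) / cycle_length) + 1L
    i <- seq_len(n_cyc) - 1L
    on <- i * cycle_length + ifelse(i >= shift_day, sgn * shift_h, 0)
    pp <- rep(photoperiod, n_cyc)
    if (truncate == "light") {
      # lights-off of the transition cycle moves instead of lights-on
      on[i >= shift_day] <- on[i >= shift_day] - sgn * shift_h
      pp[i == shift_day] <- photoperiod + sgn * shift_h
      on[i > shift_day] <- on[i > shift_day] + sgn * shift_h
    }
    keep <- on < span & on >= 0
    cycles <- make_cycles(on[keep], pp[keep], intensity)
  } else { # chronic_jetlag
    if (is.null(shift_h) || is.null(every_n_days))
      stop("chronic_jetlag requires 'shift_h' and 'every_n_days'")
    if (shift_h <= 0 || every_n_days < 1)
      stop("invalid chronic_jetlag parameters")
    sgn <- if (direction == "advance") -1 else 1
    base_on <- if (baseline_days > 0)
      seq(0, baseline_days * 24 - cycle_length, by = cycle_length)
    else numeric(0)
    t0 <- baseline_days * 24
    on <- numeric(0)
    i <- 0L
    repeat {
      block <- i %/% every_n_days
      t_on <- t0 + i * cycle_length + block * sgn * shift_h
      if (t_on >= span) break
      on <- c(on, t_on)
      i <- i + 1L
    }
    on <- c(base_on, on)
    cycles <- make_cycles(on[on >= 0 & on < span], photoperiod, intensity)
  }

  ivl <- cycles[cycles$lights_off > cycles$lights_on, , drop = FALSE]
  intervals <- data.frame(on = ivl$lights_on,
                          off = pmin(ivl$lights_off, span),
                          intensity = ivl$intensity)
  structure(list(paradigm = paradigm,
                 span = span,
                 cycles = cycles,
                 intervals = intervals,
                 params = list(photoperiod = photoperiod,
                               cycle_length = cycle_length,
                               intensity = intensity,
                               shift_h = shift_h,
                               direction = direction,
                               shift_day = shift_day,
                               every_n_days = every_n_days,
                               baseline_days = baseline_days,
                               truncate = truncate)),
            class = "light_schedule")
}

#' Query light intensity at given times
#'
#' @param schedule a \code{light_schedule}.
#' @param t vector of times (hours since the schedule origin).
#' @return numeric vector of lux values (0 in darkness).
#' @export
light_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "light_schedule"))
  out <- numeric(length(t))
  iv <- schedule$intervals
  if (nrow(iv) == 0L) return(out)
  for (j in seq_len(nrow(iv))) {
    hit <- t >= iv$on[j] & t < iv$off[j]
    out[hit] <- iv$intensity[j]
  }
  out
}

#' Lights-on / lights-off transition times
#'
#' @param schedule a \code{light_schedule}.
#' @return numeric vector of transition times in hours.
#' @export
lights_on_times <- function(schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  schedule$cycles$lights_on
}

#' @rdname lights_on_times
#' @export
lights_off_times <- function(schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  schedule$cycles$lights_off
}

#' Effective zeitgeber period of a shifting light schedule
#'
#' For a schedule whose shift pattern repeats in blocks (e.g. a 6-h advance
#' every 2 days), the effective zeitgeber period is the block duration
#' divided by the number of full cycles per block: (2 x 24 - 6) / 2 = 21 h
#' for the 6-h/2-day advance paradigm; plain 12:12 LD gives 24 h.
#'
#' @param schedule a \code{light_schedule} with a periodic light/dark cycle.
#' @return the effective zeitgeber period in hours.
#' @export
effective_zeitgeber_period <- function(schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  p <- schedule$params
  if (schedule$paradigm %in% c("DD", "LL", "stepped_LL"))
    stop("schedule has no light/dark cycle: zeitgeber period undefined")
  if (schedule$paradigm == "chronic_jetlag") {
    sgn <- if (p$direction == "advance") -1 else 1
    return((p$every_n_days * p$cycle_length + sgn * p$shift_h) /
             p$every_n_days)
  }
  p$cycle_length
}

#' Zeitgeber time of absolute schedule times
#'
#' ZT 0 is defined as the most recent lights-on.
#'
#' @param schedule a \code{light_schedule} with at least one light interval.
#' @param t vector of times in hours.
#' @return hours since the most recent lights-on.
#' @export
zeitgeber_time <- function(schedule, t) {
  on <- lights_on_times(schedule)
  if (length(on) == 0L) stop("schedule has no lights-on events")
  idx <- findInterval(t, on)
  if (any(idx == 0L)) stop("time precedes the first lights-on")
  t - on[idx]
}

#' @export
print.light_schedule <- function(x, ...) {
  cat("<light_schedule> ", x$paradigm, ": ", x$span / 24, " days, ",
      nrow(x$cycles), " light cycles\n", sep = "")
  invisible(x)
}

#' Export schedule transitions as a table
#'
#' @param schedule a \code{light_schedule}.
#' @return data frame with one row per cycle: cycle index, lights-on and
#'   lights-off hours.
#' @export
schedule_transitions <- function(schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  schedule$cycles[, c("cycle", "lights_on", "lights_off")]
}
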