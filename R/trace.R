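#' Binned activity trace
#'
#' The universal behavioural record: non-negative event counts per bin for
#' one subject (wheel revolutions for mouse, infrared beam crosses for
#' fly), together with the bin width and the trace's start time on the
#' schedule time axis.
#'
#' @param subject_id subject label.
#' @param species \code{"mouse"} or \code{"fly"}.
#' @param bin_minutes bin width in minutes (> 0).
#' @param start start time of the first bin, hours on the schedule axis.
#' @param counts ordered non-negative integer counts, one per bin.
#' @return an object of class \code{activity_trace}.
#' @export
activity_trace <- function(subject_id, species = c("mouse", "fly"),
                           bin_minutes, start = 0, counts) {
  species <- match.arg(species)
  if (length(counts) < 1L) stop("'counts' must be non-empty")
  if (any(is.na(counts)) || any(counts < 0))
    stop("'counts' must be non-negative and non-missing")
  if (bin_minutes <= 0) stop("'bin_minutes' must be > 0")
  structure(list(subject_id = as.character(subject_id),
                 species = species,
                 bin_minutes = bin_minutes,
                 start = start,
                 counts = as.numeric(counts)),
            class = "activity_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  cat("<activity_trace> ", x$subject_id, " (", x$species, "): ",
      length(x$counts), " bins x ", x$bin_minutes, " min = ",
      round(length(x$counts) * x$bin_minutes / 60, 2), " h\n", sep = "")
  invisible(x)
}

# bin mid-point times (hours) of a trace
trace_times <- function(trace) {
  trace$start + (seq_along(trace$counts) - 0.5) * trace$bin_minutes / 60
}

# subset a trace to [from, to) hours on the schedule axis
trace_window <- function(trace, from, to) {
  tm <- trace_times(trace)
  keep <- tm >= from & tm < to
  if (!any(keep)) stop("window contains no bins")
  activity_trace(trace$subject_id, trace$species, trace$bin_minutes,
                 start = from, counts = trace$counts[keep])
}

#' Rebin an activity trace to wider bins
#'
#' Sums counts over consecutive bins; the new width must be a multiple of
#' the old one.  Used e.g. to analyze 1-min fly records at 5-min
#' resolution.
#'
#' @param trace an \code{\link{activity_trace}}.
#' @param bin_minutes target bin width in minutes.
#' @return a rebinned \code{activity_trace}.
#' @export
rebin_trace <- function(trace, bin_minutes) {
  stopifnot(inherits(trace, "activity_trace"))
  k <- bin_minutes / trace$bin_minutes
  if (k != round(k) || k < 1)
    stop("'bin_minutes' must be a multiple of the current bin width")
  k <- as.integer(k)
  if (k == 1L) return(trace)
  n <- (length(trace$counts) %/% k) * k
  x <- colSums(matrix(trace$counts[seq_len(n)], nrow = k))
  activity_trace(trace$subject_id, trace$species, bin_minutes,
                 trace$start, x)
}
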