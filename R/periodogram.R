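#' Chi-squared (Sokolove-Bushell) periodogram
#'
#' For each candidate period of \code{P} bins the trace is folded into
#' \code{K = floor(N / P)} complete cycles (the trailing partial cycle is
#' discarded) and the statistic
#' \deqn{Q_P = K N_u \sum_h (M_h - \bar M)^2 / \sum_i (x_i - \bar M)^2}
#' is computed, where \eqn{M_h} is the mean of fold column \eqn{h},
#' \eqn{\bar M} the grand mean and \eqn{N_u = K P} the number of bins
#' used.  Under the white-noise null \eqn{Q_P} is approximately
#' chi-squared with \eqn{P - 1} degrees of freedom, which supplies the
#' significance line; peaks are local maxima of \eqn{Q} exceeding it.
#'
#' The periodogram amplitude reported by \code{\link{periodogram_amplitude}}
#' is \eqn{Q} at the main peak minus the significance line at that period
#' (the common actigraphy-software convention).
#'
#' @param trace an \code{\link{activity_trace}} covering at least three
#'   times \code{max_period} and with non-zero variance.
#' @param min_period,max_period scan range in hours; candidate periods are
#'   the integer bin multiples inside the range.
#' @param alpha pointwise significance level of the chi-squared line.
#' @param bonferroni if \code{TRUE}, divide \code{alpha} by the number of
#'   tested periods.
#' @return an object of class \code{periodogram} with components
#'   \code{periods}, \code{Q}, \code{dof}, \code{sig_line}, \code{alpha}
#'   and \code{peaks} (data frame of period, Q and excess Q - sig_line,
#'   sorted by excess, descending).
#' @examples
#' sch <- build_schedule("LD", days = 10)
#' x <- activity_trace("m1", "mouse", 60, 0,
#'                     rep(c(rep(0, 12), rep(20, 12)), 10))
#' pg <- chi_square_periodogram(x, 20, 28)
#' pg$peaks$period[1]  # 24
#' @export
chi_square_periodogram <- function(trace, min_period = 16,
                                   max_period = 28, alpha = 0.05,
                                   bonferroni = FALSE) {
  stopifnot(inherits(trace, "activity_trace"))
  x <- trace$counts
  if (stats::var(x) == 0)
    stop("trace has zero variance: periodogram undefined")
  bw <- trace$bin_minutes / 60
  n <- length(x)
  if (n * bw < 3 * max_period)
    stop("trace must cover at least 3 * max_period")
  p_lo <- ceiling(min_period / bw - 1e-9)
  p_hi <- floor(max_period / bw + 1e-9)
  if (p_hi < p_lo)
    stop("scan range narrower than one bin step")
  p_bins <- p_lo:p_hi
  a_eff <- if (bonferroni) alpha / length(p_bins) else alpha
  Q <- numeric(length(p_bins))
  for (i in seq_along(p_bins)) {
    P <- p_bins[i]
    K <- n %/% P
    nu <- K * P
    xu <- x[seq_len(nu)]
    mh <- rowMeans(matrix(xu, nrow = P, ncol = K))
    mbar <- mean(xu)
    denom <- sum((xu - mbar)^2)
    Q[i] <- if (denom == 0) 0 else K * nu * sum((mh - mbar)^2) / denom
  }
  dof <- p_bins - 1
  sig <- stats::qchisq(1 - a_eff, df = dof)
  periods <- p_bins * bw
  excess <- Q - sig
  is_peak <- excess > 0 &
    Q >= c(-Inf, Q[-length(Q)]) & Q > c(Q[-1], -Inf)
  peaks <- data.frame(period = periods[is_peak], Q = Q[is_peak],
                      excess = excess[is_peak])
  peaks <- peaks[order(-peaks$excess), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(periods = periods, Q = Q, dof = dof, sig_line = sig,
                 alpha = a_eff, peaks = peaks),
            class = "periodogram")
}

#' @export
print.periodogram <- function(x, ...) {
  cat("<periodogram> ", length(x$periods), " candidate periods (",
      min(x$periods), "-", max(x$periods), " h), ",
      nrow(x$peaks), " significant peak(s)\n", sep = "")
  if (nrow(x$peaks) > 0) print(utils::head(x$peaks, 3))
  invisible(x)
}

#' Periodogram amplitude at the main peak
#'
#' Q minus the significance line at the highest-excess peak; \code{NA}
#' when no peak exceeds the line.
#'
#' @param pg a \code{\link{chi_square_periodogram}} result.
#' @return numeric amplitude (or \code{NA}).
#' @export
periodogram_amplitude <- function(pg) {
  stopifnot(inherits(pg, "periodogram"))
  if (nrow(pg$peaks) == 0) return(NA_real_)
  pg$peaks$excess[1]
}

#' FFT relative power in a circadian band
#'
#' Mean-subtracts the series, takes the discrete Fourier transform, and
#' normalizes the power spectrum to sum to one over positive frequencies.
#' The rhythm power is the maximum normalized power at periods inside the
#' band (default 18-30 h); a value above about 0.01 is the conventional
#' fly rhythmicity threshold.
#'
#' @param trace an \code{\link{activity_trace}} of at least 2 days.
#' @param band numeric length-2: (min_period, max_period) hours.
#' @return an object of class \code{spectral_power} with components
#'   \code{frequencies} (cycles/h), \code{normalized_power}, \code{band},
#'   \code{rhythm_power}, \code{peak_period} and \code{flat} (TRUE for a
#'   constant trace, whose power is defined as 0).
#' @export
fft_relative_power <- function(trace, band = c(18, 30)) {
  stopifnot(inherits(trace, "activity_trace"))
  x <- trace$counts
  bw <- trace$bin_minutes / 60
  if (length(x) * bw < 48) stop("trace must cover at least 2 days")
  if (stats::var(x) == 0) {
    warning("constant trace: rhythm power defined as 0")
    return(structure(list(frequencies = numeric(0),
                          normalized_power = numeric(0),
                          band = band, rhythm_power = 0,
                          peak_period = NA_real_, flat = TRUE),
                     class = "spectral_power"))
  }
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(stats::fft(x))^2
  half <- seq(2, floor(n / 2) + 1)     # positive frequencies
  pw <- sp[half]
  pw <- pw / sum(pw)
  freq <- (half - 1) / (n * bw)        # cycles per hour
  per <- 1 / freq
  in_band <- per >= band[1] & per <= band[2]
  if (!any(in_band)) {
    rp <- 0
    pk <- NA_real_
  } else {
    j <- which(in_band)[which.max(pw[in_band])]
    rp <- pw[j]
    pk <- per[j]
  }
  structure(list(frequencies = freq, normalized_power = pw, band = band,
                 rhythm_power = rp, peak_period = pk, flat = FALSE),
            class = "spectral_power")
}
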