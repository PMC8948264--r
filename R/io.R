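#' Read a TriKinetics DAM monitor file
#'
#' Parses the standard 42-column tab-separated monitor dialect: reading
#' index, date, time, a status code, six auxiliary fields, then 32
#' channel counts (1-min bins).  Rows whose status code is not 1 are
#' treated as gaps: their counts are set to 0 and the affected reading
#' indices are reported in the \code{"gaps"} attribute.
#'
#' @param path file path.
#' @return list of 32 \code{\link{activity_trace}} objects (one per
#'   channel, \code{bin_minutes = 1}) with a \code{"gaps"} attribute.
#' @export
read_dam_monitor <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty DAM monitor file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 42L)
  if (length(bad))
    stop("malformed DAM row at line ", bad[1], ": expected 42 fields, got ",
         nf[bad[1]])
  idx <- as.integer(vapply(fields, `[[`, character(1), 1L))
  status <- as.integer(vapply(fields, `[[`, character(1), 4L))
  tm <- vapply(fields, function(f) paste(f[2], f[3]), character(1))
  stamp <- as.POSIXct(tm, format = "%d %b %y %H:%M:%S", tz = "UTC")
  if (any(is.na(stamp)))
    stop("unparseable timestamp at line ", which(is.na(stamp))[1])
  if (any(diff(as.numeric(stamp)) <= 0))
    stop("non-monotonic timestamps at line ",
         which(diff(as.numeric(stamp)) <= 0)[1] + 1L)
  counts <- t(vapply(fields, function(f) as.numeric(f[11:42]), numeric(32)))
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("channel counts must be non-negative integers")
  gaps <- idx[status != 1L]
  counts[status != 1L, ] <- 0
  traces <- lapply(seq_len(32), function(ch)
    activity_trace(subject_id = sprintf("ch%02d", ch), species = "fly",
                   bin_minutes = 1, start = 0, counts = counts[, ch]))
  attr(traces, "gaps") <- gaps
  traces
}

#' Read and write the activity CSV dialect
#'
#' A plain-text cohort format: a header row of subject ids, column 1 the
#' bin start hour, remaining cells the per-bin counts.  \code{read} of a
#' \code{write} round-trips bit-exactly.
#'
#' @param path file path.
#' @param traces list of \code{\link{activity_trace}} objects sharing bin
#'   width and start.
#' @param species species tag applied on read (the CSV does not carry it).
#' @return \code{read_activity_csv}: a list of traces;
#'   \code{write_activity_csv}: the path, invisibly.
#' @export
read_activity_csv <- function(path, species = "mouse") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("activity CSV needs a time column and subjects")
  if (names(df)[1] != "hour") stop("missing 'hour' header column")
  hours <- df[[1]]
  if (any(is.na(hours))) stop("non-numeric hour column")
  bw_h <- if (length(hours) > 1) hours[2] - hours[1] else 1
  counts <- df[-1]
  if (any(is.na(as.matrix(counts)))) stop("ragged or non-numeric rows")
  if (any(as.matrix(counts) < 0)) stop("negative count cell")
  lapply(names(counts), function(id)
    activity_trace(subject_id = id, species = species,
                   bin_minutes = bw_h * 60, start = hours[1],
                   counts = counts[[id]]))
}

#' @rdname read_activity_csv
#' @export
write_activity_csv <- function(traces, path) {
  if (inherits(traces, "activity_trace")) traces <- list(traces)
  bw <- unique(vapply(traces, `[[`, numeric(1), "bin_minutes"))
  st <- unique(vapply(traces, `[[`, numeric(1), "start"))
  n <- unique(lengths(lapply(traces, `[[`, "counts")))
  if (length(bw) != 1L || length(st) != 1L || length(n) != 1L)
    stop("traces must share bin width, start and length")
  df <- data.frame(hour = st + (seq_len(n) - 1) * bw / 60)
  for (tr in traces) df[[tr$subject_id]] <- tr$counts
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a MaxQuant proteinGroups table
#'
#' Parses a proteinGroups TSV: intensities from the
#' \code{"LFQ intensity <sample>"} columns (zeros and blanks become
#' missing, per the MaxQuant convention), flags from the
#' \code{"Only identified by site"}, \code{"Reverse"} and
#' \code{"Potential contaminant"} columns (\code{"+"} when set).
#'
#' @param path file path.
#' @param id_column column holding protein ids (default
#'   \code{"Protein IDs"}; the first column is used if absent).
#' @return a raw-scale \code{\link{protein_table}}.
#' @export
read_protein_groups <- function(path, id_column = "Protein IDs") {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  lfq <- grep("^LFQ intensity ", names(df), value = TRUE)
  if (length(lfq) == 0L) stop("no 'LFQ intensity' columns found")
  samples <- sub("^LFQ intensity ", "", lfq)
  y <- vapply(lfq, function(cn) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    v[!is.na(v) & v == 0] <- NA
    v
  }, numeric(nrow(df)))
  y <- matrix(y, nrow = nrow(df), dimnames = list(NULL, samples))
  flag <- function(cn)
    if (cn %in% names(df)) trimws(df[[cn]]) == "+" else
      logical(nrow(df))
  ids <- if (id_column %in% names(df)) df[[id_column]] else df[[1]]
  protein_table(ids = ids, intensities = y, samples = samples,
                flags = data.frame(
                  site_only = flag("Only identified by site"),
                  reverse = flag("Reverse"),
                  contaminant = flag("Potential contaminant")),
                log2 = FALSE)
}

#' Write a differential-expression table as TSV
#'
#' @param dep a \code{\link{two_sample_s0_test}} result.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_dep_table <- function(dep, path) {
  stopifnot(inherits(dep, "dep_table"))
  utils::write.table(as.data.frame(dep), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a (double-plotted) actogram
#'
#' Draws the standard raster of successive folding periods, one row per
#' period (top to bottom), optionally double-plotted (each row shows two
#' consecutive periods), with light phases of an overlaid schedule
#' shaded.
#'
#' @param trace an \code{\link{activity_trace}}.
#' @param folding_period row length in hours (default 24).
#' @param double_plot show two periods per row (default TRUE).
#' @param schedule optional \code{\link{build_schedule}} overlay.
#' @param file optional PNG path; when given the plot is written there.
#' @param max_frac counts are clipped at this fraction of the trace
#'   maximum before scaling bar heights (robustness to outlier bins).
#' @return the file path (or \code{NULL} when plotting to the active
#'   device), invisibly.
#' @export
render_actogram <- function(trace, folding_period = 24,
                            double_plot = TRUE, schedule = NULL,
                            file = NULL, max_frac = 0.9) {
  stopifnot(inherits(trace, "activity_trace"))
  bw <- trace$bin_minutes / 60
  n_rows <- floor(length(trace$counts) * bw / folding_period)
  if (n_rows < 1L) stop("trace shorter than one folding period")
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 60 * n_rows + 80)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  width <- if (double_plot) 2 * folding_period else folding_period
  cap <- max_frac * max(trace$counts, 1)
  graphics::plot(NULL, xlim = c(0, width), ylim = c(n_rows, 0),
                 xlab = "time (h)", ylab = "day", yaxs = "i",
                 main = trace$subject_id)
  tm <- trace_times(trace) - trace$start
  for (r in seq_len(n_rows)) {
    row_t0 <- (r - 1) * folding_period
    idx <- which(tm >= row_t0 & tm < row_t0 + width)
    if (!is.null(schedule)) {
      iv <- schedule$intervals
      for (j in seq_len(nrow(iv))) {
        lo <- max(iv$on[j] - row_t0, 0)
        hi <- min(iv$off[j] - row_t0, width)
        if (hi > lo)
          graphics::rect(lo, r, hi, r - 1, col = "#FFF3B0", border = NA)
      }
    }
    h <- pmin(trace$counts[idx], cap) / cap
    graphics::segments(tm[idx] - row_t0, r, tm[idx] - row_t0, r - h)
  }
  invisible(file)
}
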