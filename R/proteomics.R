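#' Protein intensity table
#'
#' Container for a proteinGroups-level quantification table: one row per
#' protein group, one column per sample, plus the three MaxQuant flag
#' columns used for filtering.  Missing cells are \code{NA}; the
#' \code{log2} flag records whether intensities are raw-scale or
#' log2-transformed.
#'
#' @param ids character vector of protein (group) identifiers.
#' @param intensities numeric matrix, proteins x samples; raw-scale
#'   values must be positive where present.
#' @param samples sample names (column names of \code{intensities}).
#' @param flags data frame with logical columns \code{site_only},
#'   \code{reverse}, \code{contaminant}.
#' @param log2 logical scale flag.
#' @return an object of class \code{protein_table}.
#' @export
protein_table <- function(ids, intensities, samples = colnames(intensities),
                          flags = NULL, log2 = FALSE) {
  intensities <- as.matrix(intensities)
  if (ncol(intensities) < 2L) stop("need at least 2 sample columns")
  if (length(ids) != nrow(intensities))
    stop("'ids' must match the number of rows")
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(intensities)))
  colnames(intensities) <- samples
  if (is.null(flags))
    flags <- data.frame(site_only = logical(length(ids)),
                        reverse = logical(length(ids)),
                        contaminant = logical(length(ids)))
  if (!all(c("site_only", "reverse", "contaminant") %in% names(flags)))
    stop("'flags' needs columns site_only, reverse, contaminant")
  if (!log2 && any(intensities <= 0, na.rm = TRUE))
    stop("raw-scale intensities must be positive where present")
  structure(list(ids = as.character(ids), intensities = intensities,
                 samples = samples, flags = flags, log2 = log2),
            class = "protein_table")
}

#' @export
print.protein_table <- function(x, ...) {
  cat("<protein_table> ", length(x$ids), " proteins x ",
      ncol(x$intensities), " samples (",
      if (x$log2) "log2" else "raw", " scale), ",
      sum(is.na(x$intensities)), " missing cells\n", sep = "")
  invisible(x)
}

#' Sample-to-group design
#'
#' @param groups named character vector mapping sample name to group
#'   label.
#' @param exclude sample names excluded from the differential analysis
#'   (e.g. a replicate failing QC).
#' @return an object of class \code{group_design}.
#' @export
group_design <- function(groups, exclude = character(0)) {
  if (is.null(names(groups))) stop("'groups' must be a named vector")
  keep <- !(names(groups) %in% exclude)
  tab <- table(groups[keep])
  if (length(tab) < 2L || any(tab < 2))
    stop("need >= 2 groups with >= 2 samples each after exclusions")
  structure(list(groups = groups, exclude = exclude),
            class = "group_design")
}

design_samples <- function(design) {
  setdiff(names(design$groups), design$exclude)
}

#' Perseus-style preprocessing of a protein table
#'
#' Stage 1 removes rows flagged as identified-by-site, reverse (decoy) or
#' potential contaminant; stage 2 log2-transforms the intensities of the
#' retained samples; stage 3 keeps proteins with at least
#' \code{min_valid} present (quantified) values across the retained
#' samples.
#'
#' @param table a raw-scale \code{\link{protein_table}}.
#' @param design optional \code{\link{group_design}}; excluded samples
#'   are dropped before the valid-value filter.
#' @param min_valid minimum number of present values per protein
#'   (default 4).
#' @return a list with \code{table} (log2 \code{protein_table}) and
#'   \code{stage_counts} (rows at input, after flag removal, after the
#'   valid-value filter).
#' @export
preprocess_protein_table <- function(table, design = NULL, min_valid = 4) {
  stopifnot(inherits(table, "protein_table"))
  if (table$log2)
    stop("table is already log2-transformed")
  n0 <- length(table$ids)
  keep <- !(table$flags$site_only | table$flags$reverse |
              table$flags$contaminant)
  ids <- table$ids[keep]
  y <- log2(table$intensities[keep, , drop = FALSE])
  flags <- table$flags[keep, , drop = FALSE]
  if (!is.null(design)) {
    stopifnot(inherits(design, "group_design"))
    y <- y[, design_samples(design), drop = FALSE]
  }
  n1 <- nrow(y)
  valid <- rowSums(!is.na(y)) >= min_valid
  y <- y[valid, , drop = FALSE]
  out <- protein_table(ids = ids[valid], intensities = y,
                       flags = flags[valid, , drop = FALSE], log2 = TRUE)
  list(table = out, stage_counts = c(input = n0, flag_filtered = n1,
                                     valid_filtered = nrow(y)))
}

#' Downshifted-normal imputation of missing values
#'
#' Replaces missing log2 intensities with draws from a normal
#' distribution estimated per sample column and shifted down: with
#' observed column mean \eqn{\mu} and SD \eqn{\sigma}, missing cells are
#' drawn from \eqn{N(\mu - downshift \cdot \sigma,
#' (width \cdot \sigma)^2)}.  The defaults (downshift 1.8, width 0.3)
#' model the left-censored nature of label-free missingness.
#'
#' @param table a log2-scale \code{\link{protein_table}}.
#' @param downshift downward shift in observed-SD units (default 1.8).
#' @param width width of the imputation distribution as a fraction of
#'   the observed SD (default 0.3).
#' @param per_column estimate \eqn{\mu, \sigma} per sample column
#'   (default, the standard behaviour) or once over the whole matrix.
#' @param seed RNG seed; imputation is deterministic given the seed.
#' @return the completed \code{protein_table}.
#' @export
impute_downshifted_normal <- function(table, downshift = 1.8,
                                      width = 0.3, per_column = TRUE,
                                      seed = 1L) {
  stopifnot(inherits(table, "protein_table"))
  if (!table$log2) stop("imputation requires a log2-scale table")
  set.seed(as.integer(seed))
  y <- table$intensities
  if (per_column) {
    for (j in seq_len(ncol(y))) {
      obs <- y[, j][!is.na(y[, j])]
      if (length(obs) < 2L)
        stop("column ", colnames(y)[j], " has fewer than 2 observed values")
      mu <- mean(obs); sg <- stats::sd(obs)
      miss <- which(is.na(y[, j]))
      if (length(miss))
        y[miss, j] <- stats::rnorm(length(miss), mu - downshift * sg,
                                   width * sg)
    }
  } else {
    obs <- y[!is.na(y)]
    if (length(obs) < 2L) stop("fewer than 2 observed values")
    mu <- mean(obs); sg <- stats::sd(obs)
    miss <- which(is.na(y))
    if (length(miss))
      y[miss] <- stats::rnorm(length(miss), mu - downshift * sg,
                              width * sg)
  }
  out <- table
  out$intensities <- y
  out
}

#' Pairwise Pearson correlation QC
#'
#' Pearson r for every pair of sample columns over mutually present rows
#' (pairwise-complete, computed before imputation); pairs at or below the
#' threshold are flagged.
#'
#' @param table a log2-scale \code{\link{protein_table}}.
#' @param threshold QC threshold on r (default 0.90).
#' @return a list with \code{r} (correlation matrix; \code{NA} where a
#'   pair shares fewer than 3 rows) and \code{flagged} (data frame of
#'   failing or undefined pairs).
#' @export
sample_correlation_qc <- function(table, threshold = 0.90) {
  stopifnot(inherits(table, "protein_table"))
  if (!table$log2) stop("QC correlations require a log2-scale table")
  y <- table$intensities
  ns <- ncol(y)
  r <- matrix(NA_real_, ns, ns, dimnames = list(colnames(y), colnames(y)))
  diag(r) <- 1
  flagged <- list()
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    both <- !is.na(y[, i]) & !is.na(y[, j])
    if (sum(both) < 3L) {
      flagged[[length(flagged) + 1L]] <-
        data.frame(sample1 = colnames(y)[i], sample2 = colnames(y)[j],
                   r = NA_real_, reason = "fewer than 3 shared rows")
      next
    }
    rij <- stats::cor(y[both, i], y[both, j])
    r[i, j] <- r[j, i] <- rij
    if (rij <= threshold)
      flagged[[length(flagged) + 1L]] <-
        data.frame(sample1 = colnames(y)[i], sample2 = colnames(y)[j],
                   r = rij, reason = "low correlation")
  }
  list(r = r,
       flagged = if (length(flagged)) do.call(rbind, flagged)
                 else data.frame(sample1 = character(0),
                                 sample2 = character(0),
                                 r = numeric(0), reason = character(0)))
}

#' S0-modified two-sample t test per protein
#'
#' Pooled-variance two-sample statistic with SAM-style stabilization,
#' \deqn{d = (\bar m_2 - \bar m_1) /
#'       (s_p \sqrt{1/n_1 + 1/n_2} + S_0),}
#' evaluated two-sided against the t distribution with
#' \eqn{n_1 + n_2 - 2} degrees of freedom.  With \code{s0 = 0} this is
#' the ordinary Student t test.  Benjamini-Hochberg q values and
#' up/down direction labels (in group 2 relative to group 1) are
#' attached.
#'
#' @param table a complete (imputed) log2-scale
#'   \code{\link{protein_table}}.
#' @param design a \code{\link{group_design}} with exactly two groups.
#' @param s0 stabilization constant added to the denominator
#'   (default 0.1).
#' @param fdr significance threshold on the BH q value (default 0.05).
#' @return a \code{dep_table} data frame: \code{id}, \code{mean_g1},
#'   \code{mean_g2}, \code{log2fc}, \code{d}, \code{p}, \code{q},
#'   \code{significant}, \code{direction}.
#' @export
two_sample_s0_test <- function(table, design, s0 = 0.1, fdr = 0.05) {
  stopifnot(inherits(table, "protein_table"),
            inherits(design, "group_design"))
  if (!table$log2) stop("test requires a log2-scale table")
  samples <- design_samples(design)
  g <- design$groups[samples]
  lev <- sort(unique(g))
  if (length(lev) != 2L) stop("design must define exactly 2 groups")
  y <- table$intensities[, samples, drop = FALSE]
  if (any(is.na(y))) stop("table has missing values: impute first")
  i1 <- which(g == lev[1]); i2 <- which(g == lev[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")
  m1 <- rowMeans(y[, i1, drop = FALSE])
  m2 <- rowMeans(y[, i2, drop = FALSE])
  v1 <- apply(y[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(y[, i2, drop = FALSE], 1, stats::var)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  se <- sp * sqrt(1 / n1 + 1 / n2)
  d <- (m2 - m1) / (se + s0)
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(abs(d), df = df, lower.tail = FALSE)
  q <- bh_adjust(p)
  sig <- q < fdr
  out <- data.frame(id = table$ids, mean_g1 = m1, mean_g2 = m2,
                    log2fc = m2 - m1, d = d, p = p, q = q,
                    significant = sig,
                    direction = ifelse(!sig, "ns",
                                       ifelse(m2 > m1, "up", "down")),
                    row.names = NULL)
  attr(out, "groups") <- lev
  attr(out, "s0") <- s0
  class(out) <- c("dep_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \code{q(i) = min_{j >= i} m p(j) / j} on the sorted p values, mapped
#' back to input order (capped at 1).
#'
#' @param pvals numeric vector of p values in [0, 1].
#' @return vector of BH q values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Fisher's exact over-representation test per annotation term
#'
#' One-sided hypergeometric tail test of term over-representation in a
#' foreground protein set relative to a background set, keeping only
#' terms with at least \code{min_per_term} foreground members.
#'
#' @param foreground character vector of foreground ids (must be a
#'   subset of \code{background}).
#' @param background character vector of background ids.
#' @param annotations named list: term id -> character vector of
#'   annotated ids (mapped into the background).
#' @param min_per_term minimum foreground members per reported term
#'   (default 3).
#' @param alpha significance threshold (default 0.05).
#' @return data frame sorted by p: \code{term}, \code{k} (foreground
#'   hits), \code{n} (foreground size), \code{K} (background hits),
#'   \code{M} (background size), \code{p}, \code{enrichment} (fold) and
#'   \code{significant}.
#' @export
fisher_enrichment <- function(foreground, background, annotations,
                              min_per_term = 3, alpha = 0.05) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  n <- length(foreground); M <- length(background)
  rows <- lapply(names(annotations), function(term) {
    ann <- intersect(unique(annotations[[term]]), background)
    K <- length(ann)
    k <- length(intersect(ann, foreground))
    if (k < min_per_term) return(NULL)
    p <- stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, n = n, K = K, M = M, p = p,
               enrichment = (k / n) / (K / M))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(term = character(0), k = integer(0), n = integer(0),
                  K = integer(0), M = integer(0), p = numeric(0),
                  enrichment = numeric(0))
  out <- out[order(out$p), , drop = FALSE]
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}
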