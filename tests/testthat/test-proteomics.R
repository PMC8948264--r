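sim_preprocessed <- function(seed, n_proteins = 800, dep_fraction = 0.1,
                             ...) {
  cfg <- proteome_sim_config(n_proteins = n_proteins,
                             dep_fraction = dep_fraction, seed = seed,
                             ...)
  tab <- simulate_protein_table(cfg)
  des <- attr(tab, "design")
  pp <- preprocess_protein_table(tab, des)
  list(raw = tab, table = pp$table, counts = pp$stage_counts,
       design = des, truth = attr(tab, "truth"))
}

test_that("preprocessing drops flagged rows, log2-transforms and filters valid values", {
  cfg <- proteome_sim_config(n_proteins = 300, n_decoy = 10,
                             n_contaminant = 5, n_site_only = 3,
                             seed = 11)
  tab <- simulate_protein_table(cfg)
  pp <- preprocess_protein_table(tab, attr(tab, "design"))
  expect_equal(unname(pp$stage_counts["input"]), 318)
  expect_equal(unname(pp$stage_counts["flag_filtered"]), 300)  # exactly 18 removed
  expect_true(pp$table$log2)
  expect_true(all(rowSums(!is.na(pp$table$intensities)) >= 4))
  # a fully observed table loses nothing at stage 3
  cfg2 <- proteome_sim_config(n_proteins = 100, missing_slope = 1,
                              missing_midpoint = -1000, seed = 12)
  tab2 <- simulate_protein_table(cfg2)
  pp2 <- preprocess_protein_table(tab2, attr(tab2, "design"))
  expect_equal(unname(pp2$stage_counts["valid_filtered"]), 100)
  # double-transform guard
  expect_error(preprocess_protein_table(pp$table), "already log2")
})

test_that("downshifted-normal imputation has the stated marginal distribution", {
  # one column with mu = 25, sigma = 2 and many missing cells
  set.seed(21)
  n_obs <- 4000; n_miss <- 10000
  y <- matrix(NA_real_, n_obs + n_miss, 2)
  y[, 1] <- stats::rnorm(n_obs + n_miss, 25, 2)
  y[seq_len(n_obs), 2] <- stats::rnorm(n_obs, 25, 2)
  tab <- protein_table(sprintf("p%d", seq_len(nrow(y))), y,
                       samples = c("A", "B"), log2 = TRUE)
  imp <- impute_downshifted_normal(tab, seed = 22)
  filled <- imp$intensities[-seq_len(n_obs), 2]
  mu <- mean(y[seq_len(n_obs), 2]); sg <- stats::sd(y[seq_len(n_obs), 2])
  expect_equal(mean(filled), mu - 1.8 * sg, tolerance = 0.02)
  expect_equal(stats::sd(filled), 0.3 * sg, tolerance = 0.02)
  ks <- stats::ks.test(filled, "pnorm", mu - 1.8 * sg, 0.3 * sg)
  expect_gt(ks$p.value, 0.01)
  # identity case: downshift 0, width 1 reproduces the observed fit
  imp0 <- impute_downshifted_normal(tab, downshift = 0, width = 1,
                                    seed = 23)
  filled0 <- imp0$intensities[-seq_len(n_obs), 2]
  expect_equal(mean(filled0), mu, tolerance = 0.05)
  expect_equal(stats::sd(filled0), sg, tolerance = 0.05)
  # determinism
  expect_identical(impute_downshifted_normal(tab, seed = 9)$intensities,
                   impute_downshifted_normal(tab, seed = 9)$intensities)
})

test_that("imputation requires a log2 table and enough observed values", {
  y <- matrix(c(1000, 2000, NA, 4000), 2, 2)
  raw <- protein_table(c("a", "b"), y, c("s1", "s2"), log2 = FALSE)
  expect_error(impute_downshifted_normal(raw), "log2")
  y2 <- matrix(c(20, 21, 22, NA, NA, 19), 3, 2)
  tab <- protein_table(c("a", "b", "c"), y2, c("s1", "s2"), log2 = TRUE)
  expect_error(impute_downshifted_normal(tab), "fewer than 2")
})

test_that("sample correlation QC flags duplicates, noise and replicates correctly", {
  set.seed(31)
  base <- stats::rnorm(4000, 26, 1.5)
  y <- cbind(base + stats::rnorm(4000, 0, 0.3),
             base + stats::rnorm(4000, 0, 0.3),
             stats::rnorm(4000, 26, 1.5))
  y <- cbind(y, y[, 1])  # duplicated column
  tab <- protein_table(sprintf("p%d", 1:4000), y,
                       c("r1", "r2", "noise", "dup"), log2 = TRUE)
  qc <- sample_correlation_qc(tab)
  expect_equal(qc$r["r1", "dup"], 1)
  # replicate-pair correlation ~ sigma_b^2 / (sigma_b^2 + sigma_e^2)
  expect_gt(qc$r["r1", "r2"], 0.90)
  expect_lt(abs(qc$r["r1", "noise"]), 0.05)
  expect_true("noise" %in% c(qc$flagged$sample1, qc$flagged$sample2))
})

test_that("s0 = 0 reduces the moderated statistic to Student's t", {
  pre <- sim_preprocessed(41, n_proteins = 300)
  imp <- impute_downshifted_normal(pre$table, seed = 42)
  dep <- two_sample_s0_test(imp, pre$design, s0 = 0)
  samples <- names(attr(pre$raw, "design")$groups)
  g1 <- grep("^G1", samples); g2 <- grep("^G2", samples)
  for (i in c(1, 57, 200)) {
    y <- imp$intensities[i, ]
    tt <- stats::t.test(y[g2], y[g1], var.equal = TRUE)
    expect_equal(dep$d[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(dep$p[i], tt$p.value, tolerance = 1e-12)
  }
  # two identical groups: d = 0, p = 1
  y <- matrix(rep(c(20, 21, 22, 20, 21, 22), each = 2), nrow = 2)
  tab <- protein_table(c("a", "b"), y, sprintf("s%d", 1:6), log2 = TRUE)
  des <- group_design(stats::setNames(rep(c("A", "B"), each = 3),
                                      sprintf("s%d", 1:6)))
  dep0 <- two_sample_s0_test(tab, des, s0 = 0.1)
  expect_equal(dep0$d, c(0, 0))
  expect_equal(dep0$p, c(1, 1))
})

test_that("null p values are uniform when s0 = 0", {
  pre <- sim_preprocessed(51, n_proteins = 4000, dep_fraction = 0,
                          n_per_group = c(4, 3))
  imp <- impute_downshifted_normal(pre$table, seed = 52)
  dep <- two_sample_s0_test(imp, pre$design, s0 = 0)
  ks <- stats::ks.test(dep$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment matches the hand oracle, including permutations", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5))
  expect_equal(bh_adjust(rep(1, 6)), rep(1, 6))
  expect_equal(bh_adjust(0.37), 0.37)
  grid <- c(0.001, 0.012, 0.04, 0.21, 0.87)
  # all 120 orderings of the 5-value grid
  idx <- expand.grid(1:5, 1:5, 1:5, 1:5, 1:5)
  idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 5), ]
  for (r in seq_len(nrow(idx))) {
    p <- grid[as.numeric(idx[r, ])]
    expect_equal(bh_adjust(p), naive_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("Fisher enrichment follows the hypergeometric closed form", {
  bg <- sprintf("p%03d", 1:100)
  fg <- bg[1:10]
  ann <- list(all_in = bg[1:10],       # K = 10, k = 10
              whole = bg,              # covers the background
              tiny = bg[1:2])          # below min_per_term
  out <- fisher_enrichment(fg, bg, ann)
  expect_false("tiny" %in% out$term)
  expect_equal(out$p[out$term == "all_in"], 1 / choose(100, 10),
               tolerance = 1e-9)
  expect_equal(out$p[out$term == "whole"], 1)
  # exact tail for a partial overlap, from the closed form
  ann2 <- list(t = bg[6:25])  # K = 20, overlap k = 5
  out2 <- fisher_enrichment(fg, bg, ann2)
  p_manual <- sum(stats::dhyper(5:10, 20, 80, 10))
  expect_equal(out2$p, p_manual, tolerance = 1e-12)
  expect_error(fisher_enrichment(c("zzz"), bg, ann), "subset")
})

test_that("full pipeline controls the false discovery proportion with planted effects", {
  fdp <- vapply(1:20, function(r) {
    pre <- sim_preprocessed(600 + r, n_proteins = 800,
                            dep_fraction = 0.1)
    imp <- impute_downshifted_normal(pre$table, seed = 700 + r)
    dep <- two_sample_s0_test(imp, pre$design, s0 = 0.1)
    m <- merge(as.data.frame(dep)[, c("id", "significant")],
               pre$truth, by = "id")
    if (!any(m$significant)) return(0)
    mean(m$delta[m$significant] == 0)
  }, numeric(1))
  expect_lte(mean(fdp), 0.10)
})

test_that("recovered true positives increase with the planted effect size", {
  tp <- vapply(c(0.5, 1, 2), function(eff) {
    pre <- sim_preprocessed(801, n_proteins = 800, dep_fraction = 0.1,
                            effect_mean = eff)
    imp <- impute_downshifted_normal(pre$table, seed = 802)
    dep <- two_sample_s0_test(imp, pre$design, s0 = 0.1)
    m <- merge(as.data.frame(dep)[, c("id", "significant")],
               pre$truth, by = "id")
    sum(m$significant & m$delta != 0)
  }, numeric(1))
  expect_true(all(diff(tp) >= 0))
})

test_that("null simulation keeps the significant fraction at the BH level", {
  frac <- vapply(1:10, function(r) {
    pre <- sim_preprocessed(900 + r, n_proteins = 800, dep_fraction = 0)
    imp <- impute_downshifted_normal(pre$table, seed = 950 + r)
    dep <- two_sample_s0_test(imp, pre$design, s0 = 0.1)
    mean(dep$significant)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("group designs validate sizes and exclusions", {
  expect_error(group_design(c(a = "X", b = "X", c = "Y")), ">= 2")
  d <- group_design(stats::setNames(rep(c("WT", "KO"), each = 4),
                                    sprintf("s%d", 1:8)),
                    exclude = "s5")
  expect_equal(length(design_samples <- setdiff(names(d$groups),
                                                d$exclude)), 7)
})
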