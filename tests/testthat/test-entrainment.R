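make_onsets <- function(onset_within, folding = 24) {
  day <- seq_along(onset_within)
  df <- data.frame(day = day,
                   onset = onset_within %% folding,
                   offset = (onset_within + 8) %% folding,
                   onset_abs = (day - 1) * folding + onset_within,
                   offset_abs = (day - 1) * folding + onset_within + 8)
  structure(df, folding_period = folding,
            class = c("onset_series", "data.frame"))
}

test_that("re-entrainment curve reflects instant, absent and gradual shifting", {
  sch <- build_schedule("acute_jetlag", days = 24, shift_h = 7,
                        shift_day = 10)
  # instant shifter: onsets jump 7 h earlier from day 11
  inst <- make_onsets(c(rep(12, 10), rep(5, 14)))
  r <- daily_phase_shifts(inst, sch)
  expect_equal(r$daily_shift$shift, rep(7, 14))
  expect_equal(days_to_reentrain(r)$days, 1)
  # never-shifter: curve all zero, flagged never entrained
  never <- make_onsets(rep(12, 24))
  r0 <- daily_phase_shifts(never, sch)
  expect_equal(r0$daily_shift$shift, rep(0, 14))
  d0 <- days_to_reentrain(r0)
  expect_false(d0$entrained)
  expect_true(is.na(d0$days))
  # 1-h-per-day shifter reaches the 7-h plateau on day 7
  grad <- make_onsets(c(rep(12, 10), 12 - pmin(1:14, 7)))
  rg <- daily_phase_shifts(grad, sch)
  expect_equal(days_to_reentrain(rg)$days, 7)
})

test_that("simulated cohort re-entrains at the clamp-limited rate", {
  sch <- build_schedule("acute_jetlag", days = 30, shift_h = 7,
                        shift_day = 10)
  tr <- mouse_cohort(5, tau = 24, sch, seed = 51, max_advance = 1,
                     max_delay = 2)
  days <- vapply(tr, function(t) {
    r <- daily_phase_shifts(detect_onsets(t, 24), sch)
    days_to_reentrain(r)$days
  }, integer(1))
  expect_true(all(abs(days - 7) <= 1))
})

test_that("days to re-entrain does not increase with a faster clamp", {
  sch <- build_schedule("acute_jetlag", days = 30, shift_h = 7,
                        shift_day = 10)
  med <- vapply(c(0.5, 1, 2, 3.5), function(ma) {
    tr <- mouse_cohort(4, tau = 24, sch, seed = 52, max_advance = ma,
                       max_delay = 2)
    stats::median(vapply(tr, function(t) {
      r <- daily_phase_shifts(detect_onsets(t, 24), sch)
      d <- days_to_reentrain(r)
      if (d$entrained) as.numeric(d$days) else Inf
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) <= 0))
})

test_that("anticipation index null, extremes and scaling invariance", {
  ld <- build_schedule("LD", days = 5)
  # uniform activity: AI exactly 0.5
  unif <- activity_trace("u", "fly", 60, 0, rep(4, 120))
  ai <- anticipation_indices(unif, ld)
  expect_identical(ai$morning_AI, 0.5)
  expect_identical(ai$evening_AI, 0.5)
  # scaling invariance
  ai2 <- anticipation_indices(activity_trace("u9", "fly", 60, 0,
                                             rep(4, 120) * 9), ld)
  expect_equal(ai2$morning_AI, ai$morning_AI)
  # all activity in the last 3 h before lights-on (ZT 21-24) -> morning 1
  x <- rep(c(rep(0, 21), rep(5, 3)), 5)
  ai3 <- anticipation_indices(activity_trace("a", "fly", 60, 0, x), ld)
  expect_equal(ai3$morning_AI, 1)
  # activity only in hours 6-3 before lights-on -> morning 0
  x4 <- rep(c(rep(0, 18), rep(10, 3), rep(0, 3)), 5)
  ai4 <- anticipation_indices(activity_trace("b", "fly", 60, 0, x4), ld)
  expect_equal(ai4$morning_AI, 0)
  # zero 6-h window -> undefined, flagged
  x5 <- rep(c(rep(3, 12), rep(0, 12)), 5)
  ai5 <- anticipation_indices(activity_trace("c", "fly", 60, 0, x5), ld)
  expect_true(is.na(ai5$morning_AI))
  expect_false(ai5$morning_defined)
})

test_that("simulated fly anticipation exceeds the 0.5 null", {
  ld <- build_schedule("LD", days = 7)
  cfg <- behavior_sim_config("fly", n_subjects = 6,
    components = list(list(params = oscillator_params(
      tau = 24, phase0 = 0, alpha = 12, rate_active = 3,
      rate_rest = 0.05, masking = 0.2), weight = 1)), seed = 61)
  ai <- anticipation_indices(simulate_activity(cfg, ld), ld)
  expect_true(all(ai$morning_AI > 0.5))
  expect_true(all(ai$evening_AI > 0.5))
})

test_that("relative activity profile normalizes to a unit peak", {
  ld <- build_schedule("LD", days = 5)
  x <- rep(c(rep(1, 12), rep(7, 12)), 5)
  tr1 <- activity_trace("p1", "fly", 60, 0, x)
  prof <- relative_activity_profile(list(tr1, tr1), ld)
  expect_equal(max(prof), 1)
  expect_equal(length(prof), 24)
  # identical subjects: group profile equals either subject profile
  expect_equal(prof, relative_activity_profile(list(tr1), ld))
  expect_error(relative_activity_profile(list(), ld), "empty")
})

test_that("simulated evening ramp rises over the 3 h before lights-off", {
  ld <- build_schedule("LD", days = 7)
  cfg <- behavior_sim_config("fly", n_subjects = 8,
    components = list(list(params = oscillator_params(
      tau = 24, phase0 = 0, alpha = 12, rate_active = 3,
      rate_rest = 0.05, masking = 0.2), weight = 1)), seed = 62)
  prof <- relative_activity_profile(simulate_activity(cfg, ld), ld)
  ramp <- prof[c("ZT9", "ZT10", "ZT11")]
  expect_true(all(diff(ramp) > 0))
})

test_that("fly DD phenotypes are recovered from simulated ground truth", {
  lab <- function(decay, drift, seed, n = 5) {
    tr <- fly_cohort(n, seed, decay = decay, drift = drift)
    vapply(tr, function(t) classify_fly_dd(t)$label, character(1))
  }
  expect_true(all(lab(1, 0, 71) == "rhythmic"))
  expect_true(all(lab(0.55, 0, 72) == "delayed_arrhythmic"))
  # fluctuating-period flies: unstable label in the majority
  expect_gt(mean(lab(1, 0.6, 73, n = 10) == "rhythmic_unstable_period"),
            0.5)
  tr0 <- fly_cohort(5, 74, rate_active = 0)
  expect_true(all(vapply(tr0, function(t) classify_fly_dd(t)$label,
                         character(1)) == "arrhythmic"))
})

test_that("chronic-jetlag classification separates one- and two-rhythm animals", {
  chr <- build_schedule("chronic_jetlag", days = 28, shift_h = 6,
                        every_n_days = 2)
  one <- mouse_cohort(4, tau = 23.6, chr, seed = 81, max_advance = 4,
                      max_delay = 4)
  expect_true(all(vapply(one, function(t)
    classify_chronic_jetlag(t, chr)$label, character(1)) == "entrained"))
  two <- mouse_cohort(4, tau = 23.6, chr, seed = 82, max_advance = 4,
                      max_delay = 4, weight2 = 0.5, tau2 = 24.5)
  cls <- lapply(two, classify_chronic_jetlag, schedule = chr)
  expect_true(all(vapply(cls, `[[`, character(1), "label") ==
                    "desynchronized"))
  expect_true(all(abs(vapply(cls, function(cl)
    cl$evidence$long_period, numeric(1)) - 24.5) <= 0.2))
  short <- mouse_cohort(4, tau = 23.6, chr, seed = 83, max_advance = 4,
                        max_delay = 4, weight2 = 0.5, tau2 = 23.4)
  expect_true(all(vapply(short, function(t)
    classify_chronic_jetlag(t, chr)$label, character(1)) ==
      "desynchronized_short_period"))
})

test_that("category table test reproduces published contingency p values", {
  # 2x3 genotype-by-phenotype table
  r1 <- category_table_test(rbind(c(4, 5, 0), c(11, 0, 2)))
  expect_equal(r1$p.value, 0.0072, tolerance = 1e-2)
  expect_equal(r1$dof, 2)
  # 2x2 rescue-experiment table
  r2 <- category_table_test(rbind(c(9, 0), c(4, 4)))
  expect_equal(r2$p.value, 0.0153, tolerance = 1e-2)
  # balanced table: no association
  r3 <- category_table_test(rbind(c(5, 5), c(5, 5)))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p.value, 1)
})

test_that("category table test equals the hand-computed Pearson oracle", {
  # all 2x2 tables with cell counts 1..5 (margins always positive)
  for (a in 1:5) for (b in 1:5) for (cc in 1:5) for (d in 1:5) {
    tab <- rbind(c(a, b), c(cc, d))
    got <- category_table_test(tab)
    want <- naive_chisq(tab)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-12)
  }
  # a sample of 2x3 tables against the same oracle
  set.seed(91)
  for (r in 1:25) {
    tab <- matrix(sample(1:7, 6, replace = TRUE), nrow = 2)
    got <- category_table_test(tab)
    want <- naive_chisq(tab)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate contingency tables are rejected", {
  expect_error(category_table_test(rbind(c(1, 2))), "2 x 2")
  expect_error(category_table_test(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(category_table_test(rbind(c(1.5, 2), c(1, 2))), "integer")
})
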