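# Independent oracles used across tests.

# naive double-loop chi-squared periodogram: folds explicitly, loops over
# columns and cycles; deliberately unvectorized and independent of the
# production implementation
naive_qp <- function(x, p_bins) {
  K <- length(x) %/% p_bins
  nu <- K * p_bins
  xu <- x[1:nu]
  mh <- numeric(p_bins)
  for (h in 1:p_bins) {
    acc <- 0
    for (k in 0:(K - 1)) acc <- acc + xu[h + k * p_bins]
    mh[h] <- acc / K
  }
  mbar <- sum(xu) / nu
  num <- 0
  for (h in 1:p_bins) num <- num + (mh[h] - mbar)^2
  den <- 0
  for (i in 1:nu) den <- den + (xu[i] - mbar)^2
  K * nu * num / den
}

# hand-computed Pearson chi-squared statistic and upper-tail p
naive_chisq <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - e)^2 / e)
  dof <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, dof = dof,
       p.value = stats::pchisq(stat, dof, lower.tail = FALSE))
}

# step-up BH adjustment written out literally
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# single-component mouse cohort helper
mouse_cohort <- function(n, tau, schedule, seed, max_advance = 2,
                         max_delay = 2, masking = 0.9, phase0 = 12,
                         rate_active = 30, weight2 = 0, tau2 = NULL,
                         ...) {
  comps <- if (weight2 == 0)
    list(list(params = oscillator_params(tau = tau, phase0 = phase0,
                                         max_advance = max_advance,
                                         max_delay = max_delay,
                                         masking = masking,
                                         rate_active = rate_active, ...),
              weight = 1))
  else
    list(list(params = oscillator_params(tau = tau, phase0 = phase0,
                                         max_advance = max_advance,
                                         max_delay = max_delay,
                                         masking = masking,
                                         rate_active = rate_active, ...),
              weight = 1 - weight2),
         list(params = oscillator_params(tau = tau2, phase0 = phase0 + 2,
                                         max_advance = 0, max_delay = 0,
                                         masking = masking,
                                         rate_active = rate_active, ...),
              weight = weight2))
  cfg <- behavior_sim_config("mouse", n_subjects = n, components = comps,
                             seed = seed)
  simulate_activity(cfg, schedule)
}

fly_cohort <- function(n, seed, days = 12, tau = 24, decay = 1,
                       drift = 0, rate_active = 3, ...) {
  cfg <- behavior_sim_config("fly", n_subjects = n,
    components = list(list(params = oscillator_params(
      tau = tau, phase0 = 0, alpha = 10, rate_active = rate_active,
      rate_rest = 0.05, amplitude_decay = decay, tau_drift_sd = drift,
      ...), weight = 1)), seed = seed)
  simulate_activity(cfg, build_schedule("DD", days = days))
}
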