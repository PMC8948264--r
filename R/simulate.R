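#' Oscillator parameters for the activity simulator
#'
#' Describes one rhythmic component of a simulated animal as a phase-only
#' oscillator: an intrinsic free-running period \code{tau}, a daily phase
#' correction toward the zeitgeber bounded by \code{max_advance} /
#' \code{max_delay} (hours per cycle), and a rectangular (mouse) or bimodal
#' (fly) activity waveform emitting Poisson counts.
#'
#' @param tau intrinsic free-running period, hours (must lie in (16, 32)).
#' @param phase0 initial activity-onset time, hours after the schedule
#'   origin.
#' @param alpha active-phase duration, hours (mouse waveform; must lie in
#'   (0, tau)).
#' @param rate_active expected counts per bin at the peak of activity.
#' @param rate_rest expected counts per bin at rest.
#' @param max_advance largest daily phase advance toward the zeitgeber,
#'   hours/cycle.
#' @param max_delay largest daily phase delay, hours/cycle.
#' @param masking multiplicative suppression of activity by light, in
#'   [0, 1] (1 = complete suppression while lights are on).
#' @param amplitude_decay per-day multiplicative decay of
#'   \code{rate_active} under constant darkness (1 = none); values < 1
#'   model rhythms that damp out after release into DD.
#' @param tau_drift_sd per-day random-walk standard deviation of
#'   \code{tau}, hours (0 = stable period).
#' @param ramp_tau fly only: time constant (hours) of the exponential
#'   anticipation ramp preceding the morning and evening bouts.
#' @param ramp_amp fly only: amplitude of the anticipation ramp relative
#'   to the bout peak (0 = no anticipation).
#' @param bout_halfwidth fly only: half-width (hours) of the raised-cosine
#'   morning/evening bouts.
#' @param morning_frac fly only: amplitude of the morning bout relative to
#'   the evening bout (default 0.6; the evening bout dominates fly
#'   activity, and unequal bouts keep spectral power at the circadian
#'   fundamental rather than the 12-h harmonic).  For flies \code{alpha}
#'   is the morning-to-evening bout spacing in hours.
#' @return an object of class \code{oscillator_params}.
#' @export
oscillator_params <- function(tau = 23.6, phase0 = 12, alpha = 10,
                              rate_active = 30, rate_rest = 0.3,
                              max_advance = 2, max_delay = 2,
                              masking = 0.9, amplitude_decay = 1,
                              tau_drift_sd = 0,
                              ramp_tau = 1.5, ramp_amp = 0.6,
                              bout_halfwidth = 1.5, morning_frac = 0.6) {
  if (tau <= 16 || tau >= 32) stop("'tau' must lie in (16, 32)")
  if (alpha <= 0 || alpha >= tau) stop("'alpha' must lie in (0, tau)")
  if (max_advance < 0 || max_delay < 0)
    stop("'max_advance' and 'max_delay' must be >= 0")
  if (masking < 0 || masking > 1) stop("'masking' must lie in [0, 1]")
  if (rate_active < 0 || rate_rest < 0) stop("rates must be >= 0")
  if (amplitude_decay < 0 || amplitude_decay > 1)
    stop("'amplitude_decay' must lie in [0, 1]")
  if (tau_drift_sd < 0) stop("'tau_drift_sd' must be >= 0")
  if (morning_frac < 0 || morning_frac > 1)
    stop("'morning_frac' must lie in [0, 1]")
  structure(list(tau = tau, phase0 = phase0, alpha = alpha,
                 rate_active = rate_active, rate_rest = rate_rest,
                 max_advance = max_advance, max_delay = max_delay,
                 masking = masking, amplitude_decay = amplitude_decay,
                 tau_drift_sd = tau_drift_sd, ramp_tau = ramp_tau,
                 ramp_amp = ramp_amp, bout_halfwidth = bout_halfwidth,
                 morning_frac = morning_frac),
            class = "oscillator_params")
}

#' Behavioural simulation configuration
#'
#' @param species \code{"mouse"} (wheel-revolution counts, nocturnal,
#'   onsets referenced to lights-off) or \code{"fly"} (beam-cross counts,
#'   bimodal waveform, morning component referenced to lights-on).
#' @param n_subjects number of simulated animals.
#' @param bin_minutes bin width in minutes (must divide 60); defaults to
#'   6 for mouse and 1 for fly.
#' @param components list of rhythmic components; each element is a list
#'   with entries \code{params} (an \code{\link{oscillator_params}}) and
#'   \code{weight}.  One component models a coherent animal, two model an
#'   internally desynchronized animal.  Weights must be >= 0 and sum to 1.
#' @param seed master seed; per-subject streams are derived from it by
#'   fixed increments, so subject k is reproducible independently of
#'   \code{n_subjects}.
#' @return an object of class \code{behavior_sim_config}.
#' @export
behavior_sim_config <- function(species = c("mouse", "fly"),
                                n_subjects = 1,
                                bin_minutes = NULL,
                                components = list(
                                  list(params = oscillator_params(),
                                       weight = 1)),
                                seed = 1L) {
  species <- match.arg(species)
  if (is.null(bin_minutes))
    bin_minutes <- if (species == "mouse") 6 else 1
  if (60 %% bin_minutes != 0) stop("'bin_minutes' must divide 60")
  if (n_subjects < 1) stop("'n_subjects' must be >= 1")
  w <- vapply(components, function(cc) cc$weight, numeric(1))
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("component weights must be >= 0 and sum to 1")
  for (cc in components)
    if (!inherits(cc$params, "oscillator_params"))
      stop("each component needs an 'oscillator_params' object")
  structure(list(species = species, n_subjects = n_subjects,
                 bin_minutes = bin_minutes, components = components,
                 seed = as.integer(seed)),
            class = "behavior_sim_config")
}

# Onset sequence of one oscillator component under a schedule.
# Daily correction: Delta = (reference event time - current onset), the
# signed circular misalignment; a required advance is negative Delta, so
# the clamped step is s = clamp(Delta, -max_advance, +max_delay).  s = 0
# whenever no light occurs within half a cycle of the onset (free run).
.component_onsets <- function(par, schedule, ref_event, span,
                              phase_step_time = NULL, phase_step_h = 0) {
  cyc_ref <- tryCatch(effective_zeitgeber_period(schedule),
                      error = function(e) 24)
  refs <- if (ref_event == "lights_off") lights_off_times(schedule)
          else lights_on_times(schedule)
  onset <- par$phase0
  tau <- par$tau
  onsets <- numeric(0)
  taus <- numeric(0)
  stepped <- is.null(phase_step_time)
  while (onset < span + cyc_ref) {
    if (!stepped && onset >= phase_step_time) {
      onset <- onset + phase_step_h
      stepped <- TRUE
    }
    onsets <- c(onsets, onset)
    taus <- c(taus, tau)
    s <- 0
    if (length(refs) > 0L) {
      d <- refs - onset
      j <- which.min(abs(d))
      # entrain only while the schedule still has light cycles nearby
      if (abs(d[j]) <= cyc_ref / 2 + 1e-9 ||
          (onset < max(refs) && onset > min(refs))) {
        delta <- d[j]
        delta <- ((delta + cyc_ref / 2) %% cyc_ref) - cyc_ref / 2
        if (onset <= max(refs) + cyc_ref / 2)
          s <- min(max(delta, -par$max_advance), par$max_delay)
      }
    }
    onset <- onset + tau + s
    if (par$tau_drift_sd > 0) {
      tau <- tau + stats::rnorm(1, 0, par$tau_drift_sd)
      tau <- min(max(tau, 16.5), 31.5)
    }
  }
  list(onsets = onsets, taus = taus)
}

# Waveform value of one component on the bin-centre grid.
.component_waveform <- function(par, species, onsets, tmid) {
  w <- numeric(length(tmid))
  if (species == "mouse") {
    for (o in onsets) {
      idx <- tmid >= o & tmid < o + par$alpha
      w[idx] <- 1
    }
  } else {
    hw <- par$bout_halfwidth
    for (o in onsets) {
      for (centre in c(o, o + par$alpha)) {
        amp <- if (centre == o) par$morning_frac else 1
        idx <- abs(tmid - centre) < hw
        w[idx] <- pmax(w[idx],
                       amp * 0.5 * (1 + cos(pi * (tmid[idx] - centre) / hw)))
        pre <- tmid < centre & tmid >= centre - 6
        w[pre] <- pmax(w[pre],
                       amp * par$ramp_amp *
                         exp((tmid[pre] - centre) / par$ramp_tau))
      }
    }
  }
  w
}

#' Simulate locomotor activity traces
#'
#' Generates Poisson-count activity records from a mixture of entrainable
#' phase oscillators under a light schedule.  Each oscillator advances its
#' onset once per cycle by its period \code{tau} plus a clamped correction
#' toward the zeitgeber reference (lights-off for the mouse, lights-on for
#' the fly morning component); the correction is bounded by
#' \code{max_advance}/\code{max_delay} per cycle and is zero in constant
#' darkness.  Expected counts per bin are
#' \code{(rate_rest + sum_k weight_k * rate_active_k * W_k(t)) *
#' (1 - masking * [light on])} with a rectangular active window (mouse) or
#' a bimodal raised-cosine waveform with exponential anticipation ramps
#' (fly).  Deterministic given the seed.
#'
#' @param config a \code{\link{behavior_sim_config}}.
#' @param schedule a \code{\link{build_schedule}} result spanning the
#'   requested duration.
#' @param days number of days to simulate (default: the schedule span).
#' @param phase_step_time optional time (hours) at which an instantaneous
#'   phase step is injected into every component (e.g. the clock-resetting
#'   effect of a discrete light pulse); \code{NULL} for none.
#' @param phase_step_h signed step in hours (positive = delay of the
#'   onset to a later time).
#' @return list of \code{activity_trace} objects (one per subject) with a
#'   \code{"truth"} attribute holding, per subject, the component onset
#'   times and realized periods.
#' @export
simulate_activity <- function(config, schedule, days = schedule$span / 24,
                              phase_step_time = NULL, phase_step_h = 0) {
  stopifnot(inherits(config, "behavior_sim_config"),
            inherits(schedule, "light_schedule"))
  span <- days * 24
  if (span > schedule$span + 1e-9)
    stop("schedule is shorter than the requested duration")
  bw <- config$bin_minutes / 60
  n_bins <- round(span / bw)
  tmid <- (seq_len(n_bins) - 0.5) * bw
  lux <- light_at(schedule, tmid)
  light_on <- as.numeric(lux > 0)
  ref_event <- if (config$species == "mouse") "lights_off" else "lights_on"

  # onset of permanent darkness (for DD amplitude decay), Inf if light
  # persists to the end of the schedule
  iv <- schedule$intervals
  dd_start <- if (nrow(iv) == 0L) 0 else {
    last_off <- max(iv$off)
    if (last_off >= schedule$span - 1e-9) Inf else last_off
  }

  traces <- vector("list", config$n_subjects)
  truth <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    set.seed(config$seed + 1000L * s)
    lambda <- numeric(n_bins)
    comp_truth <- vector("list", length(config$components))
    for (k in seq_along(config$components)) {
      cc <- config$components[[k]]
      par <- cc$params
      ons <- .component_onsets(par, schedule, ref_event, span,
                               phase_step_time, phase_step_h)
      w <- .component_waveform(par, config$species, ons$onsets, tmid)
      amp <- par$rate_active
      if (par$amplitude_decay < 1) {
        dec <- rep(1, n_bins)
        in_dd <- tmid > dd_start
        dec[in_dd] <- par$amplitude_decay ^ ((tmid[in_dd] - dd_start) / 24)
        w <- w * dec
      }
      mask <- 1 - par$masking * light_on
      lambda <- lambda + cc$weight * amp * w * mask
      comp_truth[[k]] <- list(onsets = ons$onsets, taus = ons$taus,
                              weight = cc$weight)
    }
    rest <- config$components[[1]]$params$rate_rest
    lambda <- lambda + rest
    counts <- stats::rpois(n_bins, lambda)
    traces[[s]] <- activity_trace(
      subject_id = sprintf("%s_%02d", config$species, s),
      species = config$species,
      bin_minutes = config$bin_minutes,
      start = 0,
      counts = counts)
    truth[[s]] <- comp_truth
  }
  attr(traces, "truth") <- truth
  traces
}

#' Proteome simulation configuration
#'
#' Parameters of a synthetic label-free proteomics experiment with planted
#' group differences and abundance-dependent (left-censored) missingness,
#' emulating a MaxQuant proteinGroups table.
#'
#' @param n_proteins number of genuine protein rows.
#' @param n_per_group integer vector of length 2: samples per group.
#' @param baseline_mean,baseline_sd location/scale of per-protein log2
#'   LFQ baselines.
#' @param noise_sd within-group log2 standard deviation.
#' @param dep_fraction proportion of proteins with a true group effect.
#' @param effect_mean,effect_sd mean/SD of |log2 fold-change| for affected
#'   proteins (random sign).
#' @param missing_midpoint,missing_slope logistic left-censoring curve:
#'   each cell is missing with probability
#'   \code{plogis(-(y - missing_midpoint) * missing_slope)}, so lower
#'   abundance means more missing.
#' @param n_decoy,n_contaminant,n_site_only counts of flagged
#'   reverse/contaminant/identified-by-site rows appended to the table.
#' @param seed RNG seed.
#' @return an object of class \code{proteome_sim_config}.
#' @export
proteome_sim_config <- function(n_proteins = 2000, n_per_group = c(4, 4),
                                baseline_mean = 26, baseline_sd = 2,
                                noise_sd = 0.3, dep_fraction = 0.1,
                                effect_mean = 1, effect_sd = 0.3,
                                missing_midpoint = 22, missing_slope = 1,
                                n_decoy = 0, n_contaminant = 0,
                                n_site_only = 0, seed = 1L) {
  if (n_proteins < 1) stop("'n_proteins' must be >= 1")
  if (length(n_per_group) != 2L || any(n_per_group < 2))
    stop("'n_per_group' must give >= 2 samples in each of 2 groups")
  if (dep_fraction < 0 || dep_fraction > 1)
    stop("'dep_fraction' must lie in [0, 1]")
  if (noise_sd <= 0) stop("'noise_sd' must be > 0")
  if (any(c(n_decoy, n_contaminant, n_site_only) < 0))
    stop("flagged-row counts must be >= 0")
  structure(list(n_proteins = n_proteins, n_per_group = n_per_group,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, dep_fraction = dep_fraction,
                 effect_mean = effect_mean, effect_sd = effect_sd,
                 missing_midpoint = missing_midpoint,
                 missing_slope = missing_slope,
                 n_decoy = n_decoy, n_contaminant = n_contaminant,
                 n_site_only = n_site_only, seed = as.integer(seed)),
            class = "proteome_sim_config")
}

#' Simulate a proteinGroups-style protein intensity table
#'
#' Log2 intensities follow \code{y = a_p + delta_p * [group 2] + eps} with
#' protein baselines \code{a_p ~ N(baseline_mean, baseline_sd^2)}, noise
#' \code{eps ~ N(0, noise_sd^2)}, and effects \code{delta_p} zero with
#' probability \code{1 - dep_fraction}, otherwise a random-sign
#' \code{|N(effect_mean, effect_sd^2)|}.  Each cell is independently
#' censored with logistic probability decreasing in abundance, emulating
#' left-censored LFQ missingness.  Flagged decoy/contaminant/site-only
#' rows carry random intensities.  Intensities are emitted on the raw
#' scale (2^y).
#'
#' @param config a \code{\link{proteome_sim_config}}.
#' @return a \code{\link{protein_table}} (raw scale) with a
#'   \code{"truth"} data-frame attribute holding the planted per-protein
#'   effect \code{delta} (log2).
#' @export
simulate_protein_table <- function(config) {
  stopifnot(inherits(config, "proteome_sim_config"))
  set.seed(config$seed)
  n1 <- config$n_per_group[1]; n2 <- config$n_per_group[2]
  ns <- n1 + n2
  np <- config$n_proteins
  a <- stats::rnorm(np, config$baseline_mean, config$baseline_sd)
  has_eff <- stats::runif(np) < config$dep_fraction
  delta <- numeric(np)
  ne <- sum(has_eff)
  if (ne > 0)
    delta[has_eff] <- sample(c(-1, 1), ne, replace = TRUE) *
      abs(stats::rnorm(ne, config$effect_mean, config$effect_sd))
  grp2 <- c(rep(0, n1), rep(1, n2))
  y <- matrix(a, np, ns) +
    outer(delta, grp2) +
    matrix(stats::rnorm(np * ns, 0, config$noise_sd), np, ns)
  p_miss <- stats::plogis(-(y - config$missing_midpoint) *
                            config$missing_slope)
  y[matrix(stats::runif(np * ns), np, ns) < p_miss] <- NA

  n_flag <- config$n_decoy + config$n_contaminant + config$n_site_only
  if (n_flag > 0) {
    yf <- matrix(stats::rnorm(n_flag * ns, config$baseline_mean,
                              config$baseline_sd), n_flag, ns)
    y <- rbind(y, yf)
  }
  ids <- c(sprintf("PROT%04d", seq_len(np)),
           if (config$n_decoy > 0)
             sprintf("REV__PROT%04d", seq_len(config$n_decoy)),
           if (config$n_contaminant > 0)
             sprintf("CON__PROT%04d", seq_len(config$n_contaminant)),
           if (config$n_site_only > 0)
             sprintf("SITE_PROT%04d", seq_len(config$n_site_only)))
  flags <- data.frame(
    site_only = c(rep(FALSE, np + config$n_decoy + config$n_contaminant),
                  rep(TRUE, config$n_site_only)),
    reverse = c(rep(FALSE, np), rep(TRUE, config$n_decoy),
                rep(FALSE, config$n_contaminant + config$n_site_only)),
    contaminant = c(rep(FALSE, np + config$n_decoy),
                    rep(TRUE, config$n_contaminant),
                    rep(FALSE, config$n_site_only)))
  samples <- c(sprintf("G1_%d", seq_len(n1)), sprintf("G2_%d", seq_len(n2)))
  tab <- protein_table(ids = ids, intensities = 2 ^ y,
                       samples = samples, flags = flags, log2 = FALSE)
  attr(tab, "truth") <- data.frame(id = sprintf("PROT%04d", seq_len(np)),
                                   delta = delta)
  attr(tab, "design") <- group_design(
    stats::setNames(c(rep("G1", n1), rep("G2", n2)), samples))
  tab
}
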