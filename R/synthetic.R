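#' Configuration of the synthetic cohort generator
#'
#' Controls the signal model used to emulate a workload-by-stress EEG study:
#' per-band, per-region oscillator amplitudes; multiplicative condition
#' effects (difficult-vs-easy, stressed-vs-relaxed); inter-subject
#' variability; and the strength of the subject-specific channel-space
#' rotation that creates the cross-subject domain gap.
#'
#' Condition effects are multiplicative on oscillator amplitude.  The
#' defaults encode the canonical passive-BCI signatures: high workload
#' raises frontal theta and suppresses posterior alpha; stress suppresses
#' posterior alpha and raises frontal/temporal beta.  Their magnitudes were
#' fixed once so that within-subject shrinkage-LDA decoding of the default
#' cohort lands in the 70-90% accuracy range, and are not tuned per
#' analysis.
#'
#' @param iaf_mean,iaf_sd mean and sd (Hz) of the individual alpha
#'   frequency distribution, truncated to \[7, 13\].
#' @param workload_effect,stress_effect 5 x 5 band-by-region amplitude
#'   multipliers applied during difficult trials / stressed blocks.  Rows
#'   delta, theta, alpha, beta, gamma; columns frontal, central, temporal,
#'   parietal, occipital.  All entries must be positive.
#' @param base_amp band-by-region baseline oscillator amplitudes in uV.
#' @param eyes_closed_alpha_boost multiplier on posterior alpha during the
#'   initial eyes-closed baseline.
#' @param effect_jitter_sd lognormal sd of the per-subject exponent applied
#'   to the effect matrices (0 disables inter-subject effect variability).
#' @param channel_gain_sd lognormal sd of per-channel gains.
#' @param subject_amp_sd lognormal sd of each subject's global amplitude
#'   scale (inter-subject EEG amplitudes vary severalfold; this, with
#'   `band_amp_sd`, is the main correctable component of the domain gap).
#' @param band_amp_sd lognormal sd of per-subject, per-band amplitude
#'   multipliers (individual spectral profiles).
#' @param noise_scale amplitude (uV) of the per-channel 1/f background.
#' @param domain_shift scale of the random skew generating each subject's
#'   channel-space rotation; 0 removes that component of the cross-subject
#'   domain gap.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(iaf_mean = 10, iaf_sd = 1,
                          workload_effect = default_workload_effect(),
                          stress_effect = default_stress_effect(),
                          base_amp = default_base_amp(),
                          eyes_closed_alpha_boost = 2,
                          effect_jitter_sd = 0.1,
                          channel_gain_sd = 0.05,
                          subject_amp_sd = 0.3,
                          band_amp_sd = 0.25,
                          noise_scale = 4,
                          domain_shift = 0.4) {
  for (m in list(workload_effect, stress_effect, base_amp)) {
    stop_if_not(all(m > 0), "effect multipliers and amplitudes must be positive",
                class = "passivebci_config_error")
  }
  stop_if_not(eyes_closed_alpha_boost > 0, "alpha boost must be positive",
              class = "passivebci_config_error")
  structure(list(iaf_mean = iaf_mean, iaf_sd = iaf_sd,
                 workload_effect = workload_effect,
                 stress_effect = stress_effect,
                 base_amp = base_amp,
                 eyes_closed_alpha_boost = eyes_closed_alpha_boost,
                 effect_jitter_sd = effect_jitter_sd,
                 channel_gain_sd = channel_gain_sd,
                 subject_amp_sd = subject_amp_sd,
                 band_amp_sd = band_amp_sd,
                 noise_scale = noise_scale,
                 domain_shift = domain_shift),
            class = "cohort_config")
}

synth_bands <- function() c("delta", "theta", "alpha", "beta", "gamma")
synth_regions <- function() c("frontal", "central", "temporal", "parietal", "occipital")

#' Build a band-by-region effect-multiplier matrix
#'
#' All entries default to 1 (no effect); `entries` is a list of
#' `list(band, region, value)` triples.  `effect_matrix()` with no
#' arguments is the null effect used for chance-level cohorts.
#'
#' @param entries list of `list(band, region, value)` modifications.
#' @return 5 x 5 matrix (delta/theta/alpha/beta/gamma by
#'   frontal/central/temporal/parietal/occipital).
#' @export
effect_matrix <- function(entries = list()) {
  m <- matrix(1, 5, 5, dimnames = list(synth_bands(), synth_regions()))
  for (e in entries) m[e[[1]], e[[2]]] <- e[[3]]
  m
}

#' @rdname cohort_config
#' @export
default_workload_effect <- function() {
  effect_matrix(list(
    list("theta", "frontal", 1.9),
    list("theta", "central", 1.4),
    list("alpha", "parietal", 0.70),
    list("alpha", "occipital", 0.65)))
}

#' @rdname cohort_config
#' @export
default_stress_effect <- function() {
  effect_matrix(list(
    list("alpha", "parietal", 0.75),
    list("alpha", "occipital", 0.70),
    list("beta", "frontal", 1.7),
    list("beta", "temporal", 1.6)))
}

#' @rdname cohort_config
#' @export
default_base_amp <- function() {
  m <- matrix(1.5, 5, 5, dimnames = list(synth_bands(), synth_regions()))
  m["delta", ] <- 4
  m["theta", ] <- c(4, 3, 2.5, 2.5, 2.5)
  m["alpha", ] <- c(3, 3, 3, 6, 8)
  m["beta", ] <- c(2, 2, 2, 1.5, 1.5)
  m["gamma", ] <- 1
  m
}

#' Generate a cohort of subject profiles
#'
#' Draws deterministic, seed-reproducible subject profiles: an individual
#' alpha frequency from a truncated normal, per-subject jitter of the
#' condition-effect matrices, per-channel gains, and a subject-specific
#' rotation seed creating inter-subject covariance (domain) shift.  Half
#' the cohort starts with a relaxed block (order R1-S1-R2-S2), the other
#' half with a stressed block (S1-R1-S2-R2).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param config a [cohort_config()].
#' @return List of `subject_profile` objects.
#' @export
make_cohort <- function(n_subjects, seed, config = cohort_config()) {
  stop_if_not(n_subjects >= 1, "n_subjects must be >= 1")
  stop_if_not(inherits(config, "cohort_config"), "config must be a cohort_config",
              class = "passivebci_config_error")
  set.seed(seed)
  labels <- montage_1010()
  lapply(seq_len(n_subjects), function(i) {
    iaf <- Inf
    while (iaf < 7 || iaf > 13) iaf <- stats::rnorm(1, config$iaf_mean, config$iaf_sd)
    # per-entry exponents: effect topographies vary across subjects while
    # every effect keeps its direction (multiplier stays on the same side
    # of 1)
    jitter_w <- matrix(exp(stats::rnorm(25, 0, config$effect_jitter_sd)), 5, 5)
    jitter_s <- matrix(exp(stats::rnorm(25, 0, config$effect_jitter_sd)), 5, 5)
    structure(list(
      subject_id = i,
      iaf_hz = iaf,
      block_order = if (i %% 2 == 1) c("R1", "S1", "R2", "S2") else c("S1", "R1", "S2", "R2"),
      amp_scale = exp(stats::rnorm(1, 0, config$subject_amp_sd)),
      band_amp = stats::setNames(exp(stats::rnorm(5, 0, config$band_amp_sd)),
                                 synth_bands()),
      workload_effect = config$workload_effect^jitter_w,
      stress_effect = config$stress_effect^jitter_s,
      channel_gain = stats::setNames(
        exp(stats::rnorm(length(labels), 0, config$channel_gain_sd)), labels),
      mixing_rotation_seed = sample.int(.Machine$integer.max, 1),
      noise_scale = config$noise_scale,
      config = config), class = "subject_profile")
  })
}

#' Build a session plan
#'
#' A session is a one-minute eyes-closed baseline followed by four task
#' blocks alternating relaxed (R) and stressed (S) states.  Each block
#' holds ten trials: four eyes-open baseline, three easy and three
#' difficult arithmetic trials, ordered so that no two consecutive trials
#' share a difficulty level and with a different order in every block.
#'
#' @param block_order the four block ids in order, either R-first
#'   (`c("R1","S1","R2","S2")`) or S-first.
#' @param trial_duration_s duration of each trial in seconds (study value
#'   67; shorten for desk-scale simulation).
#' @param baseline_eyes_closed_s duration of the opening eyes-closed
#'   baseline (default 60).
#' @param fs_hz sampling rate (default 500).
#' @param seed seed for the per-block trial orders.
#' @return A list of class `session_plan` with a `trials` data frame
#'   (block, affect, kind, start_s, end_s).
#' @export
session_plan <- function(block_order = c("R1", "S1", "R2", "S2"),
                         trial_duration_s = 67,
                         baseline_eyes_closed_s = 60,
                         fs_hz = 500, seed = 1) {
  stop_if_not(length(block_order) == 4 &&
                sum(grepl("^R", block_order)) == 2 &&
                sum(grepl("^S", block_order)) == 2,
              "block_order must contain two relaxed and two stressed blocks")
  set.seed(seed)
  rows <- list()
  t0 <- baseline_eyes_closed_s
  for (b in block_order) {
    kinds <- block_trial_order()
    affect <- if (grepl("^R", b)) "relaxed" else "stressed"
    for (k in kinds) {
      rows[[length(rows) + 1L]] <- data.frame(
        block = b, affect = affect, kind = k,
        start_s = t0, end_s = t0 + trial_duration_s,
        stringsAsFactors = FALSE)
      t0 <- t0 + trial_duration_s
    }
  }
  structure(list(block_order = block_order,
                 trial_duration_s = trial_duration_s,
                 baseline_eyes_closed_s = baseline_eyes_closed_s,
                 fs_hz = fs_hz,
                 trials = do.call(rbind, rows)),
            class = "session_plan")
}

# Random order of 4 baseline / 3 easy / 3 difficult trials with no two
# consecutive trials of equal difficulty (baseline trials carry none).
block_trial_order <- function() {
  kinds <- c(rep("eyes_open_baseline", 4), rep("easy", 3), rep("difficult", 3))
  repeat {
    ord <- sample(kinds)
    ok <- !any(ord[-1] == ord[-length(ord)] & ord[-1] %in% c("easy", "difficult"))
    if (ok) return(ord)
  }
}

subject_rotation <- function(n, rotation_seed, scale) {
  if (scale <= 0) return(diag(n))
  set.seed(rotation_seed %% .Machine$integer.max)
  G <- matrix(stats::rnorm(n * n, 0, scale / sqrt(n)), n, n)
  qr_out <- qr(diag(n) + G)
  Q <- qr.Q(qr_out)
  # fix reflection signs so Q is close to the identity
  Q %*% diag(sign(diag(crossprod(Q, diag(n)))))
}

#' Simulate one subject's EEG session
#'
#' The signal model is additive: per scalp region and frequency band, a
#' shared amplitude-modulated narrow-band oscillator (alpha centred at the
#' subject's individual alpha frequency) plus independent per-channel 1/f
#' background noise.  Oscillator amplitudes are scaled by the active
#' condition's multipliers (difficult trials, stressed blocks, eyes-closed
#' alpha enhancement), channels receive subject-specific gains, and the
#' subject's channel-space rotation is applied last to create a
#' cross-subject domain gap.
#'
#' @param profile a `subject_profile` from [make_cohort()].
#' @param plan a [session_plan()]; its block order should match the
#'   profile's (the profile's order is used when they differ).
#' @param seed integer seed; (profile, plan, seed) fully determine the
#'   recording.
#' @return List with `recording` (an [eeg_recording()] with block/trial
#'   events) and `truth` (the plan's trial table plus the eyes-closed
#'   segment).
#' @export
simulate_session <- function(profile, plan = NULL, seed = 1) {
  stop_if_not(inherits(profile, "subject_profile"), "profile must be a subject_profile")
  if (is.null(plan)) plan <- session_plan(profile$block_order, seed = seed + 1L)
  set.seed(seed)
  cfg <- profile$config
  fs <- plan$fs_hz
  total_s <- plan$baseline_eyes_closed_s +
    nrow(plan$trials) * plan$trial_duration_s
  n <- as.integer(round(total_s * fs))
  labels <- montage_1010()
  nch <- length(labels)
  regions <- channel_region(labels)
  bands <- synth_bands()
  centers <- c(delta = 2.5, theta = 5, alpha = profile$iaf_hz,
               beta = 18, gamma = 35)
  tt <- seq_len(n) / fs

  # per-sample condition state (sample indices, not logical masks, for speed)
  diff_idx <- integer(0)
  stress_idx <- integer(0)
  closed_idx <- which(tt <= plan$baseline_eyes_closed_s)
  for (r in seq_len(nrow(plan$trials))) {
    tr <- plan$trials[r, ]
    idx <- which(tt > tr$start_s & tt <= tr$end_s)
    if (tr$kind == "difficult") diff_idx <- c(diff_idx, idx)
    if (tr$affect == "stressed") stress_idx <- c(stress_idx, idx)
  }

  # shared oscillators: one per (band, region), slow random AM envelope;
  # assemble samples x channels for column-major locality
  X <- matrix(0, n, nch)
  for (b in bands) {
    for (rg in unique(regions)) {
      env <- osc_envelope(n, fs)
      phase <- stats::runif(1, 0, 2 * pi)
      amp <- rep(cfg$base_amp[b, rg] * profile$amp_scale * profile$band_amp[[b]], n)
      amp[diff_idx] <- amp[diff_idx] * profile$workload_effect[b, rg]
      amp[stress_idx] <- amp[stress_idx] * profile$stress_effect[b, rg]
      if (b == "alpha" && rg %in% c("parietal", "occipital"))
        amp[closed_idx] <- amp[closed_idx] * cfg$eyes_closed_alpha_boost
      sig <- amp * env * sin(2 * pi * centers[[b]] * tt + phase)
      for (ch in which(regions == rg)) X[, ch] <- X[, ch] + sig
    }
  }
  for (s in seq(1L, nch, by = 8L)) {     # in-place, chunked: bounds memory
    e <- min(nch, s + 7L)
    X[, s:e] <- (X[, s:e, drop = FALSE] +
                   profile$noise_scale * profile$amp_scale *
                   pink_noise_matrix(n, e - s + 1L)) *
      rep(profile$channel_gain[s:e], each = n)
  }
  R <- subject_rotation(nch, profile$mixing_rotation_seed, cfg$domain_shift)
  X <- t(X %*% t(R))

  ev <- rbind(
    data.frame(onset_s = 0, duration_s = plan$baseline_eyes_closed_s,
               kind = "baseline_eyes_closed", label = "eyes_closed",
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(split(plan$trials, plan$trials$block)[unique(plan$trials$block)],
      function(bl) data.frame(onset_s = min(bl$start_s),
                              duration_s = sum(bl$end_s - bl$start_s),
                              kind = "block_start", label = bl$block[1],
                              stringsAsFactors = FALSE))),
    data.frame(onset_s = plan$trials$start_s,
               duration_s = plan$trials$end_s - plan$trials$start_s,
               kind = "trial_start", label = plan$trials$kind,
               stringsAsFactors = FALSE))
  ev <- ev[order(ev$onset_s), ]
  truth <- rbind(
    data.frame(block = "baseline", affect = "none", kind = "eyes_closed_baseline",
               start_s = 0, end_s = plan$baseline_eyes_closed_s,
               stringsAsFactors = FALSE),
    plan$trials)
  list(recording = eeg_recording(X, fs, labels, ev), truth = truth)
}

# Slow positive amplitude-modulation envelope (~0.2 Hz lowpass of noise),
# via an O(n) cumsum moving average.
osc_envelope <- function(n, fs) {
  k <- max(3L, as.integer(fs / 0.4))
  x <- stats::rnorm(n + k)
  cs <- cumsum(x)
  e <- (cs[(k + 1):(n + k)] - cs[1:n]) / k
  1 + 2 * e / max(stats::sd(e), 1e-12) * 0.25
}

#' Inject stereotyped artifacts into a recording
#'
#' Adds eye-blink transients (high-amplitude, low-frequency raised-cosine
#' bumps on frontal channels) and broadband EMG bursts (on temporal
#' channels) at Poisson-distributed times, recording ground-truth artifact
#' windows in the event table so cleaning can be scored.
#'
#' @param recording an [eeg_recording()].
#' @param blink_rate,emg_rate expected events per minute (>= 0).
#' @param seed integer seed.
#' @param blink_amp_uv,emg_amp_uv artifact amplitudes in uV.
#' @return The recording with artifacts added and `artifact` events
#'   appended.  Zero rates return the input unchanged.
#' @export
inject_artifacts <- function(recording, blink_rate = 10, emg_rate = 5, seed = 1,
                             blink_amp_uv = 120, emg_amp_uv = 60) {
  stop_if_not(blink_rate >= 0 && emg_rate >= 0, "rates must be non-negative")
  if (blink_rate == 0 && emg_rate == 0) return(recording)
  set.seed(seed)
  fs <- recording$fs_hz
  dur <- recording_duration(recording)
  X <- recording$data
  labels <- recording$channel_labels
  ev <- recording$events

  add_events <- function(rate, width_s, make_wave, chans, tag) {
    n_ev <- stats::rpois(1, rate * dur / 60)
    if (n_ev == 0) return(NULL)
    onsets <- sort(stats::runif(n_ev, 0, dur - width_s))
    for (t0 in onsets) {
      i0 <- as.integer(round(t0 * fs)) + 1L
      w <- make_wave(as.integer(round(width_s * fs)))
      idx <- i0:(i0 + length(w) - 1L)
      for (ch in chans) X[ch, idx] <<- X[ch, idx] + w
    }
    data.frame(onset_s = onsets, duration_s = width_s,
               kind = "artifact", label = tag, stringsAsFactors = FALSE)
  }

  frontal <- which(grepl("^(Fp|AF)", labels))
  temporal <- which(grepl("^(T|FT|TP)", labels))
  blink_wave <- function(m) blink_amp_uv * (0.5 - 0.5 * cos(2 * pi * seq_len(m) / m))
  emg_wave <- function(m) emg_amp_uv * stats::rnorm(m)
  ev_b <- add_events(blink_rate, 0.3, blink_wave, frontal, "blink")
  ev_e <- add_events(emg_rate, 0.3, emg_wave, temporal, "emg")
  eeg_recording(X, fs, labels, rbind(ev, ev_b, ev_e))
}
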