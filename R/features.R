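#' Estimate the individual alpha frequency
#'
#' Peak of the mean posterior-channel Welch spectrum within 7-13 Hz,
#' computed from the eyes-closed baseline.  The peak must be a local
#' maximum exceeding the surrounding 1/f trend; when no such peak exists
#' the canonical 10 Hz is returned with `attr(, "fallback") = TRUE`.
#'
#' @param baseline an [eeg_recording()] excerpt, >= 30 s, containing the
#'   posterior channels.
#' @param posterior channel labels averaged for the spectrum.
#' @return IAF in Hz with attribute `fallback`.
#' @export
estimate_iaf <- function(baseline, posterior = posterior_channels()) {
  stop_if_not(recording_duration(baseline) >= 30,
              "IAF estimation needs at least 30 s of eyes-closed data")
  idx <- match(posterior, baseline$channel_labels)
  stop_if_not(!anyNA(idx), "posterior channels missing from montage",
              class = "passivebci_montage_error")
  fs <- baseline$fs_hz
  nseg <- as.integer(min(ncol(baseline$data), round(4 * fs)))
  acc <- NULL
  for (i in idx) {
    w <- welch_psd(baseline$data[i, ], fs, nperseg = nseg)
    acc <- if (is.null(acc)) w$psd else acc + w$psd
  }
  psd <- acc / length(idx)
  freq <- welch_psd(baseline$data[idx[1], ], fs, nperseg = nseg)$freq
  inb <- which(freq >= 7 & freq <= 13)
  k <- inb[which.max(psd[inb])]
  # local-peak test against the 1/f trend interpolated from the band edges
  lo <- which(freq >= 5 & freq < 7)
  hi <- which(freq > 13 & freq <= 16)
  trend <- exp(stats::approx(c(mean(freq[lo]), mean(freq[hi])),
                             c(mean(log(psd[lo])), mean(log(psd[hi]))),
                             xout = freq[k])$y)
  is_peak <- k > 1 && k < length(psd) &&
    psd[k] >= psd[k - 1] && psd[k] >= psd[k + 1] && psd[k] > 1.2 * trend
  if (!is_peak) {
    return(structure(10, fallback = TRUE))
  }
  structure(freq[k], fallback = FALSE)
}

#' Build the seven IAF-anchored frequency bands
#'
#' Band edges are fixed offsets from the individual alpha frequency:
#' delta (IAF-8, IAF-6), theta (IAF-6, IAF-4), alpha1 (IAF-4, IAF-2),
#' alpha2 (IAF-2, IAF), alpha3 (IAF, IAF+2), beta (IAF+2, IAF+20) and
#' gamma (IAF+20, IAF+30); the seven bands tile \[IAF-8, IAF+30\] without
#' overlap.
#'
#' @param iaf_hz individual alpha frequency in \[7, 13\] Hz.
#' @return A `band_scheme`: named list of `(low, high)` pairs plus the IAF.
#' @export
make_bands <- function(iaf_hz) {
  stop_if_not(is.finite(iaf_hz) && iaf_hz >= 7 && iaf_hz <= 13,
              "iaf_hz must lie in [7, 13] Hz",
              class = "passivebci_parameter_error")
  offs <- list(delta = c(-8, -6), theta = c(-6, -4), alpha1 = c(-4, -2),
               alpha2 = c(-2, 0), alpha3 = c(0, 2), beta = c(2, 20),
               gamma = c(20, 30))
  structure(list(iaf_hz = iaf_hz,
                 bands = lapply(offs, function(o) iaf_hz + o)),
            class = "band_scheme")
}

#' Filter-Hilbert band power of one window
#'
#' Band-pass the window to the requested band (causal Butterworth, the
#' same family as the preprocessing filter), form the analytic signal, and
#' return the time-averaged squared Hilbert envelope per channel.  Under
#' this envelope-squared convention a unit-amplitude in-band sinusoid has
#' power 1; `convention = "msq"` instead returns the mean squared filtered
#' signal (half that value for a sinusoid).
#'
#' @param window channels x samples matrix.
#' @param band numeric `(low, high)` in Hz.
#' @param fs_hz sampling rate.
#' @param convention `"envelope"` (default) or `"msq"`.
#' @return Non-negative per-channel power vector (uV^2).
#' @export
band_power <- function(window, band, fs_hz, convention = c("envelope", "msq")) {
  convention <- match.arg(convention)
  window <- as.matrix(window)
  stop_if_not(band[1] > 0 && band[2] > band[1] && band[2] < fs_hz / 2,
              "band must lie within (0, fs/2)",
              class = "passivebci_parameter_error")
  bf <- signal::butter(2, band / (fs_hz / 2), type = "pass")
  Y <- causal_filter(bf$b, bf$a, t(window))
  p <- if (convention == "envelope") envelope_sq_mean(Y) else colMeans(Y^2)
  stats::setNames(p, rownames(window))
}

#' Assemble a per-epoch band-power feature vector
#'
#' Concatenates [band_power()] over the seven bands and a channel subset:
#' `all63` keeps every channel (63 x 7 = 441 features, used for affect
#' decoding); `workload49` removes the 14 motor/sensorimotor channels
#' (49 x 7 = 343 features, used for workload decoding).  Channels are
#' re-ordered canonically first, so the vector is invariant to the input
#' channel order.
#'
#' @param window channels x samples matrix with all 63 montage labels as
#'   rownames.
#' @param scheme a `band_scheme` from [make_bands()].
#' @param subset `"all63"` or `"workload49"`.
#' @param fs_hz sampling rate.
#' @param log_power take `log10` of (power + 1e-12) when `TRUE`.
#' @return Named numeric feature vector (length 441 or 343).
#' @export
extract_features <- function(window, scheme, subset = c("all63", "workload49"),
                             fs_hz, log_power = FALSE) {
  subset <- match.arg(subset)
  window <- as.matrix(window)
  labels <- montage_1010()
  stop_if_not(!is.null(rownames(window)), "window needs channel rownames",
              class = "passivebci_montage_error")
  idx <- match(labels, rownames(window))
  stop_if_not(!anyNA(idx), "window is missing montage channels",
              class = "passivebci_montage_error")
  window <- window[idx, , drop = FALSE]
  keep <- if (subset == "workload49") setdiff(labels, motor_channels()) else labels
  window <- window[keep, , drop = FALSE]
  out <- unlist(lapply(names(scheme$bands), function(b) {
    p <- band_power(window, scheme$bands[[b]], fs_hz)
    names(p) <- paste(keep, b, sep = ".")
    p
  }))
  if (log_power) out <- log10(out + 1e-12)
  out
}

#' Epoch a recording into chronological feature vectors
#'
#' Streams the recording with [stream_windows()] (4 s windows, 2 s steps
#' by default) and extracts one feature vector per step, labelling each
#' step by the trial active at the window's end time.
#'
#' @param recording a preprocessed [eeg_recording()] whose rows are named
#'   montage channels.
#' @param truth trial table (`start_s`, `end_s`, `kind`, `affect`) on the
#'   recording's own clock.
#' @param scheme a `band_scheme`.
#' @param subset feature subset passed to [extract_features()].
#' @param win_s,step_s epoching parameters.
#' @param task_only keep only epochs whose end falls in an easy or
#'   difficult trial (baseline epochs are dropped from analysis).
#' @param asr optional `asr_model` applied before feature extraction (to
#'   each window in the windowed path; to consecutive `win_s` blocks in
#'   the stream path).
#' @param windowed when `TRUE`, call [extract_features()] independently on
#'   every window, exactly as the online simulator does.  The default
#'   stream path band-filters the continuous recording once per band and
#'   averages the squared Hilbert envelope per window, the usual offline
#'   equivalent.
#' @return List with `features` (matrix, one row per epoch), `workload`,
#'   `affect`, `time_s`, `step_index`.
#' @export
epoch_features <- function(recording, truth, scheme,
                           subset = "all63", win_s = 4, step_s = 2,
                           task_only = TRUE, asr = NULL, windowed = FALSE) {
  rownames(recording$data) <- recording$channel_labels
  sw <- stream_windows(recording, win_s, step_s)
  lab_w <- character(sw$n_steps)
  lab_a <- character(sw$n_steps)
  for (i in seq_len(sw$n_steps)) {
    tend <- sw$step_times_s[i]
    tr <- truth[truth$start_s < tend & truth$end_s >= tend, , drop = FALSE]
    lab_w[i] <- if (nrow(tr)) tr$kind[1] else "none"
    lab_a[i] <- if (nrow(tr)) tr$affect[1] else "none"
  }
  feats <- if (windowed) {
    rows <- lapply(seq_len(sw$n_steps), function(i) {
      w <- sw$get_window(i)
      if (!is.null(asr)) {
        w2 <- asr_apply(w, asr)
        rownames(w2) <- rownames(w)
        w <- w2
      }
      extract_features(w, scheme, subset, sw$fs_hz)
    })
    do.call(rbind, rows)
  } else {
    stream_band_features(recording, scheme, subset, sw, asr)
  }
  keep <- if (task_only) lab_w %in% c("easy", "difficult") else rep(TRUE, sw$n_steps)
  list(features = feats[keep, , drop = FALSE],
       workload = lab_w[keep], affect = lab_a[keep],
       time_s = sw$step_times_s[keep], step_index = which(keep))
}

# Offline path: filter the whole stream once per band, take the squared
# Hilbert envelope, and average it over each (possibly left-padded)
# window with a cumulative sum.
stream_band_features <- function(recording, scheme, subset, sw, asr = NULL) {
  labels <- montage_1010()
  idx <- match(labels, recording$channel_labels)
  stop_if_not(!anyNA(idx), "recording is missing montage channels",
              class = "passivebci_montage_error")
  X <- recording$data[idx, , drop = FALSE]
  if (!is.null(asr)) {
    nwin <- as.integer(round(sw$win_s * sw$fs_hz))
    for (s in seq(1L, ncol(X), by = nwin)) {
      e <- min(ncol(X), s + nwin - 1L)
      X[, s:e] <- asr_apply(X[, s:e, drop = FALSE], asr)
    }
  }
  keep <- if (subset == "workload49") setdiff(labels, motor_channels()) else labels
  Xt <- t(X[keep, , drop = FALSE])                # samples x channels
  n <- nrow(Xt)
  nwin <- as.integer(round(sw$win_s * sw$fs_hz))
  ends <- pmin(n, as.integer(round(sw$step_times_s * sw$fs_hz)))
  starts <- pmax(1L, ends - nwin + 1L)
  h <- numeric(n)
  if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  pieces <- lapply(names(scheme$bands), function(b) {
    bf <- signal::butter(2, scheme$bands[[b]] / (sw$fs_hz / 2), type = "pass")
    Y <- causal_filter(bf$b, bf$a, Xt)
    out <- matrix(0, length(ends), ncol(Y))
    for (s in seq(1L, ncol(Y), by = 8L)) {       # bound the FFT workspace
      e <- min(ncol(Y), s + 7L)
      F <- stats::mvfft(Y[, s:e, drop = FALSE])
      E2 <- Mod(stats::mvfft(F * h, inverse = TRUE) / n)^2
      CS <- apply(E2, 2, cumsum)
      out[, s:e] <- (CS[ends, , drop = FALSE] -
                       rbind(0, CS)[starts, , drop = FALSE]) /
        (ends - starts + 1L)
    }
    colnames(out) <- paste(keep, b, sep = ".")
    out
  })
  do.call(cbind, pieces)
}
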