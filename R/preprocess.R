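#' Causal band-pass filter
#'
#' Fourth-order Butterworth band-pass (two poles per edge), applied
#' causally per channel.  A causal realization is used throughout because
#' zero-phase (forward-backward) filtering needs future samples and is
#' incompatible with the online, chronologically windowed processing this
#' package simulates.
#'
#' @param recording an [eeg_recording()].
#' @param low_hz,high_hz pass-band edges in Hz (defaults 1 and 50).
#' @return The filtered recording; DC is removed (it lies below `low_hz`).
#' @export
bandpass_filter <- function(recording, low_hz = 1, high_hz = 50) {
  fs <- recording$fs_hz
  stop_if_not(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2,
              "need 0 < low_hz < high_hz < fs/2",
              class = "passivebci_parameter_error")
  bf <- signal::butter(2, c(low_hz, high_hz) / (fs / 2), type = "pass")
  Y <- t(causal_filter(bf$b, bf$a, t(recording$data)))
  eeg_recording(Y, fs, recording$channel_labels, recording$events)
}

#' Anti-aliased rational-ratio resampling
#'
#' Resamples at the rational ratio `target_fs / fs` (128/250 for the
#' canonical 500 -> 256 Hz step): a linear-phase FIR low-pass at the new
#' Nyquist rate removes aliasing, its group delay is compensated, and the
#' output grid is evaluated by cubic fractional-delay interpolation of the
#' filtered signal.  Event onsets are kept in seconds so no rounding drift
#' accumulates.
#'
#' @param recording an [eeg_recording()].
#' @param target_fs new sampling rate in Hz (default 256, must be below the
#'   current rate).
#' @return The resampled recording with
#'   `round(n_samples * target_fs / fs)` samples.
#' @export
resample_recording <- function(recording, target_fs = 256) {
  fs <- recording$fs_hz
  stop_if_not(target_fs < fs, "target_fs must be below the current rate",
              class = "passivebci_parameter_error")
  X <- t(recording$data)                 # samples x channels
  n <- nrow(X)
  n_out <- as.integer(round(n * target_fs / fs))
  L <- 65L                               # FIR length (odd: integer delay)
  h <- signal::fir1(L - 1L, 0.9 * target_fs / fs)
  d <- (L - 1L) %/% 2L
  pad <- function(M, top, bot) rbind(M[rep(1L, top), , drop = FALSE], M,
                                     M[rep(nrow(M), bot), , drop = FALSE])
  Xf <- causal_filter(h, 1, pad(X, 0L, d + 3L))   # compensate delay below
  # output grid in filtered-sample coordinates (group delay removed)
  pos <- (seq_len(n_out) - 1) * fs / target_fs + 1 + d
  i0 <- floor(pos)
  fr <- pos - i0
  Xf <- pad(Xf, 1L, 0L)                  # so that index i0 - 1 >= 1
  i0 <- i0 + 1L
  # Catmull-Rom cubic interpolation, vectorized over channels
  p0 <- Xf[i0 - 1L, , drop = FALSE]; p1 <- Xf[i0, , drop = FALSE]
  p2 <- Xf[i0 + 1L, , drop = FALSE]; p3 <- Xf[i0 + 2L, , drop = FALSE]
  Y <- 0.5 * ((2 * p1) + fr * ((p2 - p0) + fr * ((2 * p0 - 5 * p1 + 4 * p2 - p3) +
         fr * (3 * (p1 - p2) + p3 - p0))))
  eeg_recording(t(Y), target_fs, recording$channel_labels, recording$events)
}

#' Calibrate an artifact subspace reconstruction model
#'
#' Euclidean (PCA) variant: the component basis is the eigenbasis of the
#' calibration covariance, and each component's rejection threshold is its
#' calibration RMS scaled by `cutoff_k`.  Calibration should use
#' artifact-poor data (here, the training blocks' eyes-open baseline
#' trials).
#'
#' @param clean an [eeg_recording()] (or channels x samples matrix plus
#'   `fs_hz`) of calibration data, at least 30 s in total.
#' @param cutoff_k threshold multiplier (default 20; thresholds are linear
#'   in it).
#' @param fs_hz sampling rate, required when `clean` is a bare matrix.
#' @return An `asr_model` with fields `calibration_mean`,
#'   `component_basis` (orthonormal), `component_thresholds` and
#'   `cutoff_k`.
#' @export
asr_calibrate <- function(clean, cutoff_k = 20, fs_hz = NULL) {
  if (inherits(clean, "eeg_recording")) {
    X <- clean$data
    fs_hz <- clean$fs_hz
    labels <- clean$channel_labels
  } else {
    X <- as.matrix(clean)
    stop_if_not(!is.null(fs_hz), "fs_hz required for matrix input")
    labels <- rownames(X) %||% paste0("ch", seq_len(nrow(X)))
  }
  stop_if_not(ncol(X) / fs_hz >= 30,
              "ASR calibration needs at least 30 s of clean data",
              class = "passivebci_calibration_error")
  stop_if_not(cutoff_k > 0, "cutoff_k must be positive",
              class = "passivebci_parameter_error")
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / (ncol(Xc) - 1)
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < max(eg$values) * 1e-10)
    stop(errorCondition("rank-deficient calibration covariance",
                        class = c("passivebci_calibration_error", "error", "condition")))
  structure(list(calibration_mean = mu,
                 component_basis = eg$vectors,
                 component_rms = sqrt(eg$values),
                 component_thresholds = cutoff_k * sqrt(eg$values),
                 cutoff_k = cutoff_k,
                 channel_labels = labels),
            class = "asr_model")
}

#' Apply artifact subspace reconstruction to one window
#'
#' Projects the window onto the calibration eigenbasis, flags components
#' whose in-window RMS exceeds their threshold, and reconstructs the
#' window from the retained components only.  The operator is linear, so
#' clean windows (all components under threshold) pass through unchanged
#' and zero input maps to zero.
#'
#' @param window channels x samples matrix (same channel count and order
#'   as the calibration data).
#' @param model an `asr_model` from [asr_calibrate()].
#' @return The cleaned window.
#' @export
asr_apply <- function(window, model) {
  window <- as.matrix(window)
  stop_if_not(nrow(window) == nrow(model$component_basis),
              "window channel count does not match ASR model",
              class = "passivebci_shape_error")
  V <- model$component_basis
  Y <- crossprod(V, window)
  rms <- sqrt(rowMeans(Y^2))
  keep <- rms <= model$component_thresholds
  if (all(keep)) return(window)
  V[, keep, drop = FALSE] %*% Y[keep, , drop = FALSE]
}

#' One-shot causal preprocessing of a window
#'
#' Band-pass, resample and ASR-clean a single raw window, exactly the
#' chain applied to each chronological test segment in online simulation.
#'
#' @param window channels x samples raw matrix.
#' @param fs_hz input sampling rate.
#' @param model optional `asr_model` (already at `target_fs`); `NULL`
#'   skips cleaning.
#' @param low_hz,high_hz,target_fs filter and resampling settings.
#' @param labels channel labels of the window.
#' @return channels x samples matrix at `target_fs`.
#' @export
preprocess_window <- function(window, fs_hz, model = NULL,
                              low_hz = 1, high_hz = 50, target_fs = 256,
                              labels = montage_1010()) {
  rec <- eeg_recording(window, fs_hz, labels)
  rec <- bandpass_filter(rec, low_hz, high_hz)
  rec <- resample_recording(rec, target_fs)
  out <- rec$data
  if (!is.null(model)) out <- asr_apply(out, model)
  rownames(out) <- labels
  out
}
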