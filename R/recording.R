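#' Construct a continuous multi-channel EEG recording
#'
#' The central data container: a channels-by-samples amplitude matrix in
#' microvolts with a sampling rate, unique 10-10 channel labels, and a table
#' of event markers.
#'
#' @param data numeric matrix, channels x samples, in uV.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param channel_labels character vector, one unique label per row of `data`.
#' @param events data frame of event markers with columns `onset_s`,
#'   `duration_s`, `kind`, and optionally `label` (free-form payload).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs_hz, channel_labels,
                          events = empty_events()) {
  data <- as.matrix(data)
  stop_if_not(is.numeric(fs_hz) && length(fs_hz) == 1 && fs_hz > 0,
              "fs_hz must be a single positive number")
  stop_if_not(nrow(data) == length(channel_labels),
              sprintf("channel count (%d) does not match label count (%d)",
                      nrow(data), length(channel_labels)),
              class = "passivebci_format_error")
  stop_if_not(!anyDuplicated(channel_labels),
              "duplicate channel labels",
              class = "passivebci_format_error")
  stop_if_not(all(is.finite(data)), "data contains NaN or Inf")
  events <- as_events(events)
  structure(
    list(data = data, fs_hz = fs_hz,
         channel_labels = as.character(channel_labels), events = events),
    class = "eeg_recording")
}

empty_events <- function() {
  data.frame(onset_s = numeric(0), duration_s = numeric(0),
             kind = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

as_events <- function(events) {
  events <- as.data.frame(events)
  if (is.null(events$label)) events$label <- rep("", nrow(events))
  stop_if_not(all(c("onset_s", "duration_s", "kind") %in% names(events)),
              "events need onset_s, duration_s and kind columns")
  stop_if_not(all(events$onset_s >= 0) && all(events$duration_s >= 0),
              "event onsets and durations must be non-negative")
  events[, c("onset_s", "duration_s", "kind", "label")]
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs_hz,
              ncol(x$data) / x$fs_hz, nrow(x$events)))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording an `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$data) / recording$fs_hz
}

#' Extract a time slice of a recording
#'
#' @param recording an `eeg_recording`.
#' @param start_s,end_s slice boundaries in seconds (half-open, clamped to
#'   the recording).
#' @return An `eeg_recording` holding the slice; event onsets are shifted so
#'   the slice starts at 0 and events outside the slice are dropped.
#' @export
crop_recording <- function(recording, start_s, end_s) {
  fs <- recording$fs_hz
  i0 <- max(1L, as.integer(floor(start_s * fs)) + 1L)
  i1 <- min(ncol(recording$data), as.integer(round(end_s * fs)))
  stop_if_not(i1 >= i0, "empty crop interval")
  ev <- recording$events
  keep <- ev$onset_s >= start_s & ev$onset_s < end_s
  ev <- ev[keep, , drop = FALSE]
  ev$onset_s <- ev$onset_s - start_s
  eeg_recording(recording$data[, i0:i1, drop = FALSE], fs,
                recording$channel_labels, ev)
}

#' Chronological sliding-window iterator over a recording
#'
#' Emits one item per `step_s` of data, each carrying the most recent
#' `win_s` seconds.  The convention is per-step emission: a recording of
#' duration T yields `floor(T / step_s)` items, and windows whose nominal
#' start precedes the recording are left-padded by repeating the first
#' sample, so the stream produces an item from the very first step on.  A
#' 4 s window with a 2 s step over an 804 s stream therefore yields 402
#' items, one decode every 2 s.
#'
#' @param recording an `eeg_recording`.
#' @param win_s window length in seconds (default 4).
#' @param step_s step between successive windows in seconds (default 2).
#' @return A list with `n_steps`, `step_times_s` (window end times) and
#'   `get_window(i)` returning the channels x samples matrix for step i.
#'   Windows never extend past their own end time: step i sees only samples
#'   up to `i * step_s`.
#' @export
stream_windows <- function(recording, win_s = 4, step_s = 2) {
  fs <- recording$fs_hz
  dur <- recording_duration(recording)
  stop_if_not(dur >= step_s, "recording shorter than one step")
  n_steps <- as.integer(floor(dur / step_s + 1e-9))
  nwin <- as.integer(round(win_s * fs))
  get_window <- function(i) {
    stop_if_not(i >= 1 && i <= n_steps, "step index out of range")
    end <- as.integer(round(i * step_s * fs))
    start <- end - nwin + 1L
    if (start >= 1L) {
      recording$data[, start:end, drop = FALSE]
    } else {
      pad <- recording$data[, rep(1L, 1L - start), drop = FALSE]
      cbind(pad, recording$data[, 1:end, drop = FALSE])
    }
  }
  list(n_steps = n_steps,
       step_times_s = seq_len(n_steps) * step_s,
       win_s = win_s, step_s = step_s, fs_hz = fs,
       get_window = get_window)
}
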