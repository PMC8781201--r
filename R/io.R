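#' Read an EEG recording from disk
#'
#' Supports EDF+ (16-bit, continuous, with an annotations channel) and
#' BrainVision triplets (.vhdr/.eeg/.vmrk, multiplexed IEEE float32).
#' Amplitudes are returned in uV; annotations and markers are mapped to the
#' event table.
#'
#' @param path path to the .edf or .vhdr file.
#' @param format `"edf"` or `"brainvision"`; inferred from the extension
#'   when missing.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "brainvision")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "brainvision"
  }
  switch(format, edf = read_edf(path), brainvision = read_brainvision(path))
}

format_error <- function(msg) {
  stop(errorCondition(msg, class = c("passivebci_format_error", "error", "condition")))
}

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

## ---- EDF+ ------------------------------------------------------------

#' Write a recording as EDF+
#'
#' Continuous EDF+ with one-second data records, per-channel symmetric
#' 16-bit scaling, and events stored as time-stamped annotation lists in an
#' `EDF Annotations` signal.  Signals are padded with zeros to a whole
#' number of records.
#'
#' @param recording an [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  X <- recording$data
  fs <- recording$fs_hz
  stop_if_not(abs(fs - round(fs)) < 1e-9, "EDF writer needs an integer sampling rate")
  fs <- as.integer(round(fs))
  nch <- nrow(X)
  n_rec <- as.integer(ceiling(ncol(X) / fs))
  if (ncol(X) < n_rec * fs) {
    X <- cbind(X, matrix(0, nch, n_rec * fs - ncol(X)))
  }
  pmin_ <- pmax(apply(abs(X), 1, max), 1e-6)
  dig_max <- 32767L

  # annotation TALs (NUL-separated): record onset stamps plus all events
  # in record 1
  ev <- recording$events
  tal_events <- if (nrow(ev)) {
    paste0(vapply(seq_len(nrow(ev)), function(i) {
      sprintf("+%.6g\x15%.6g\x14%s\x14", ev$onset_s[i], ev$duration_s[i],
              paste0(ev$kind[i], ifelse(nzchar(ev$label[i]),
                                        paste0(":", ev$label[i]), "")))
    }, ""), collapse = "\x01")          # placeholder, replaced by NUL below
  } else ""
  ann_bytes_per_rec <- 2L * as.integer(ceiling((nchar(tal_events, "bytes") + 32) / 2))
  ann_spr <- ann_bytes_per_rec %/% 2L

  ns <- nch + 1L
  header_bytes <- 256L * (ns + 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(pad_field(x, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(header_bytes, 8); wr("EDF+C", 44)
  wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  labs <- c(recording$channel_labels, "EDF Annotations")
  for (l in labs) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)                       # transducer
  for (i in seq_len(ns)) wr(if (i <= nch) "uV" else "", 8) # dimension
  for (i in seq_len(ns)) wr(if (i <= nch) sprintf("%.6g", -pmin_[i]) else "-1", 8)
  for (i in seq_len(ns)) wr(if (i <= nch) sprintf("%.6g", pmin_[i]) else "1", 8)
  for (i in seq_len(ns)) wr(-dig_max - 1L, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)                        # prefiltering
  for (i in seq_len(ns)) wr(if (i <= nch) fs else ann_spr, 8)
  for (i in seq_len(ns)) wr("", 32)

  dig_min <- -dig_max - 1L
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nch)) {
      seg <- X[i, ((r - 1L) * fs + 1L):(r * fs)]
      dig <- as.integer(round(dig_min +
        (seg - (-pmin_[i])) / (2 * pmin_[i]) * (dig_max - dig_min)))
      writeBin(pmin(pmax(dig, dig_min), dig_max), con, size = 2,
               endian = "little")
    }
    stamp <- sprintf("+%d\x14\x14", r - 1L)
    body <- if (r == 1L && nzchar(tal_events)) {
      paste0(stamp, "\x01", tal_events)
    } else stamp
    raw_body <- charToRaw(body)
    raw_body[raw_body == as.raw(1L)] <- as.raw(0L)   # TAL separators
    raw_ann <- c(raw_body, raw(ann_bytes_per_rec - length(raw_body)))
    writeBin(raw_ann, con)
  }
  invisible(path)
}

read_edf <- function(path) {
  stop_if_not(file.exists(path), sprintf("file not found: %s", path),
              class = "passivebci_format_error")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    out <- readChar(con, w, useBytes = TRUE)
    if (length(out) == 0) format_error("EDF: file truncated inside the header")
    trimws(out)
  }
  version <- rd(8)
  if (version != "0") format_error("EDF header: unsupported version field")
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(header_bytes, n_rec, rec_dur, ns)) || ns < 1)
    format_error("EDF header: malformed record-count/duration/signal fields")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (anyNA(spr) || any(spr < 1)) format_error("EDF header: bad samples-per-record")
  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  if (length(unique(spr[sig_idx])) > 1)
    format_error("EDF: signals with differing sampling rates are not supported")
  if (anyDuplicated(labels[sig_idx]))
    format_error("EDF header: duplicate channel labels")
  fs <- spr[sig_idx][1] / rec_dur

  expected <- header_bytes + as.double(n_rec) * 2 * sum(spr)
  if (file.size(path) < expected)
    format_error("EDF: file truncated (sample count does not match header)")

  nch <- length(sig_idx)
  X <- matrix(0, nch, n_rec * spr[sig_idx][1])
  ann_txt <- character(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        bytes <- readBin(con, "raw", n = 2L * spr[i])
        bytes[bytes == as.raw(0)] <- as.raw(1)   # TALs are NUL-terminated
        ann_txt <- c(ann_txt, strsplit(rawToChar(bytes), "\x01+")[[1]])
      } else {
        dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
        if (length(dig) < spr[i])
          format_error("EDF: file truncated (sample count does not match header)")
        j <- match(i, sig_idx)
        scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
        X[j, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
          phys_min[i] + (dig - dig_min[i]) * scale
      }
    }
  }
  events <- parse_tals(ann_txt)
  eeg_recording(X, fs, labels[sig_idx], events)
}

# Parse EDF+ time-stamped annotation lists into the event table.
parse_tals <- function(tals) {
  rows <- list()
  for (tal in tals) {
    if (!nzchar(tal)) next
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2) next           # bare record time stamp
    head <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head[1]))
    dur <- if (length(head) > 1) suppressWarnings(as.numeric(head[2])) else 0
    for (txt_i in parts[-1]) {
      if (!nzchar(txt_i) || is.na(onset)) next
      kl <- strsplit(txt_i, ":", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        onset_s = onset, duration_s = if (is.na(dur)) 0 else dur, kind = kl[1],
        label = if (length(kl) > 1) paste(kl[-1], collapse = ":") else "",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_events())
  do.call(rbind, rows)
}

## ---- BrainVision -----------------------------------------------------

#' Write a recording as a BrainVision triplet
#'
#' Produces `.vhdr` (text header), `.eeg` (multiplexed IEEE float32 binary)
#' and `.vmrk` (text markers) files.
#'
#' @param recording an [eeg_recording()].
#' @param basepath output path without extension.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(recording, basepath) {
  base <- basename(basepath)
  vhdr <- paste0(basepath, ".vhdr")
  X <- recording$data
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(X)),
    sprintf("SamplingInterval=%.6f", 1e6 / recording$fs_hz),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(X)), recording$channel_labels))
  writeLines(hdr, vhdr)
  con <- file(paste0(basepath, ".eeg"), "wb")
  writeBin(as.numeric(X), con, size = 4, endian = "little")
  close(con)
  ev <- recording$events
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000")
  if (nrow(ev)) {
    mrk <- c(mrk, sprintf(
      "Mk%d=Stimulus,%s,%d,%d,0",
      seq_len(nrow(ev)) + 1L,
      paste0(ev$kind, ifelse(nzchar(ev$label), paste0(":", ev$label), "")),
      as.integer(round(ev$onset_s * recording$fs_hz)) + 1L,
      pmax(1L, as.integer(round(ev$duration_s * recording$fs_hz)))))
  }
  writeLines(mrk, paste0(basepath, ".vmrk"))
  invisible(vhdr)
}

read_brainvision <- function(vhdr_path) {
  stop_if_not(file.exists(vhdr_path), sprintf("file not found: %s", vhdr_path),
              class = "passivebci_format_error")
  lines <- readLines(vhdr_path, warn = FALSE, encoding = "UTF-8")
  get_key <- function(key) {
    hit <- grep(sprintf("^%s=", key), lines, value = TRUE)
    if (!length(hit)) format_error(sprintf("BrainVision header: missing key %s", key))
    sub(sprintf("^%s=", key), "", hit[1])
  }
  dir <- dirname(vhdr_path)
  data_file <- file.path(dir, get_key("DataFile"))
  marker_file <- file.path(dir, get_key("MarkerFile"))
  if (!file.exists(marker_file))
    format_error(sprintf("BrainVision: marker file %s missing", basename(marker_file)))
  if (!file.exists(data_file))
    format_error(sprintf("BrainVision: data file %s missing", basename(data_file)))
  if (toupper(get_key("DataFormat")) != "BINARY" ||
      toupper(get_key("DataOrientation")) != "MULTIPLEXED")
    format_error("BrainVision: only binary multiplexed data are supported")
  fmt <- toupper(get_key("BinaryFormat"))
  nch <- as.integer(get_key("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_key("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  if (length(ch_lines) != nch)
    format_error("BrainVision header: channel info count mismatches NumberOfChannels")
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                   function(p) p[1], "")

  sz <- file.size(data_file)
  if (fmt == "IEEE_FLOAT_32") {
    n_val <- sz %/% 4L
    con <- file(data_file, "rb")
    vals <- readBin(con, "numeric", n = n_val, size = 4, endian = "little")
    close(con)
  } else if (fmt == "INT_16") {
    n_val <- sz %/% 2L
    con <- file(data_file, "rb")
    vals <- readBin(con, "integer", n = n_val, size = 2, endian = "little")
    close(con)
    res <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                  function(p) if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1,
                  1.0)
    vals <- vals * rep(res, length.out = length(vals))  # multiplexed order
  } else format_error(sprintf("BrainVision: unsupported BinaryFormat %s", fmt))
  if (n_val %% nch != 0)
    format_error("BrainVision: sample count not divisible by channel count")
  X <- matrix(vals, nrow = nch)

  mlines <- readLines(marker_file, warn = FALSE, encoding = "UTF-8")
  mk <- grep("^Mk[0-9]+=", mlines, value = TRUE)
  rows <- list()
  for (m in mk) {
    p <- strsplit(sub("^Mk[0-9]+=", "", m), ",")[[1]]
    if (length(p) < 4 || p[1] == "New Segment") next
    kl <- strsplit(p[2], ":", fixed = TRUE)[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      onset_s = (as.numeric(p[3]) - 1) / fs,
      duration_s = as.numeric(p[4]) / fs,
      kind = kl[1],
      label = if (length(kl) > 1) paste(kl[-1], collapse = ":") else "",
      stringsAsFactors = FALSE)
  }
  ev <- if (length(rows)) do.call(rbind, rows) else empty_events()
  eeg_recording(X, fs, labels, ev)
}
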