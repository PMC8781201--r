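#' Welch power spectral density estimate
#'
#' Averaged modified periodograms with a Hann window.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples.
#' @param overlap fractional overlap between segments.
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @keywords internal
welch_psd <- function(x, fs, nperseg = min(length(x), 1024L), overlap = 0.5) {
  nperseg <- as.integer(nperseg)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, length(x) - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  norm <- fs * sum(win^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    P <- Mod(stats::fft(seg))^2 / norm
    acc <- acc + P[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC and (even n) Nyquist
  scale2 <- rep(2, nf)
  scale2[1] <- 1
  if (nperseg %% 2 == 0) scale2[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / nperseg, psd = psd * scale2)
}

# 1/f ("pink") noise via spectral shaping of white Gaussian noise.
pink_noise <- function(n, slope = 1) {
  pink_noise_matrix(n, 1L, slope)[, 1]
}

# Generated in channel chunks: the complex FFT workspace for a full
# session (1.4 M samples x 63 channels) would otherwise dominate memory.
pink_noise_matrix <- function(n, k, slope = 1, chunk = 8L) {
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)              # symmetric frequency index
  shape <- 1 / f^(slope / 2)
  out <- matrix(0, n, k)
  for (s in seq(1L, k, by = chunk)) {
    e <- min(k, s + chunk - 1L)
    W <- stats::mvfft(matrix(stats::rnorm(n * (e - s + 1L)), n)) * shape
    out[, s:e] <- Re(stats::mvfft(W, inverse = TRUE) / n)
  }
  out
}

# Causal direct-form IIR filtering of every column of X (samples x
# channels) with zero initial conditions; numerically identical to
# filtering each column with signal::filter(b, a, .).
causal_filter <- function(b, a, X) {
  X <- as.matrix(X)
  b <- b / a[1]; a <- a / a[1]
  n <- nrow(X); k <- length(b)
  if (k > 16L && length(a) == 1L) {
    V <- fir_filter_fft(b, X)             # long FIR, no feedback: use FFT
  } else {
    V <- b[1] * X
    if (k > 1) {
      for (j in 2:k) {
        if (b[j] != 0 && j <= n)
          V[j:n, ] <- V[j:n, , drop = FALSE] + b[j] * X[1:(n - j + 1), , drop = FALSE]
      }
    }
  }
  if (length(a) > 1) V <- stats::filter(V, -a[-1], method = "recursive")
  matrix(as.numeric(V), n, ncol(X))
}

# Causal FIR filtering of matrix columns by overlap-free FFT convolution
# (zero initial conditions, output truncated to the input length).
# Channels are processed in chunks to bound the complex FFT workspace on
# session-length inputs.
fir_filter_fft <- function(b, X, chunk = 8L) {
  n <- nrow(X); k <- length(b)
  m <- stats::nextn(n + k - 1L, 2)
  H <- stats::fft(c(b, numeric(m - k)))
  out <- matrix(0, n, ncol(X))
  for (s in seq(1L, ncol(X), by = chunk)) {
    e <- min(ncol(X), s + chunk - 1L)
    Xp <- rbind(X[, s:e, drop = FALSE], matrix(0, m - n, e - s + 1L))
    Y <- Re(stats::mvfft(stats::mvfft(Xp) * H, inverse = TRUE)) / m
    out[, s:e] <- Y[seq_len(n), , drop = FALSE]
  }
  out
}

# Mean squared Hilbert envelope of every column of X (samples x channels).
envelope_sq_mean <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  F <- stats::mvfft(X)
  h <- numeric(n)
  if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  A <- stats::mvfft(F * h, inverse = TRUE) / n
  colMeans(Mod(A)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg, class = "passivebci_error") {
  if (!cond) stop(errorCondition(msg, class = c(class, "error", "condition")))
  invisible(TRUE)
}
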