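#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible child seed from a base seed and a stream label.
# Kept below 2^31 so it is always a valid R integer.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 2654435761 + sum(utf8ToInt(as.character(stream)))) %%
    2147483647
}

# Zero-phase 4th-order Butterworth band-pass applied in the frequency
# domain: the spectrum of each channel is multiplied by |H(w)|^2, the
# magnitude-squared response of the digital Butterworth design, which is the
# transfer function of forward-backward (zero-phase) filtering. Operating per
# FFT bin avoids per-trial transient handling and is fast for many short
# epochs.
#
# x: samples x channels matrix; returns the filtered matrix.
bandpass_zero_phase <- function(x, fs, band) {
  x <- as.matrix(x)
  n <- nrow(x)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  w <- 2 * pi * (seq_len(n) - 1) / n
  ejw <- exp(-1i * outer(w, seq_along(bf$b) - 1))
  H <- as.vector(ejw %*% bf$b) / as.vector(ejw %*% bf$a)
  gain <- Mod(H)^2
  X <- stats::mvfft(x)
  Re(stats::mvfft(X * gain, inverse = TRUE)) / n
}

# Unit-RMS 1/f ("pink") noise series of length n, one column per series.
pink_noise <- function(n, n_series = 1L) {
  wn <- matrix(stats::rnorm(n * n_series), n, n_series)
  W <- stats::mvfft(wn)
  f <- c(1, seq_len(n - 1))           # avoid DC blow-up
  f <- pmin(f, n - f + 1)             # two-sided frequency index
  W <- W / sqrt(f)
  x <- Re(stats::mvfft(W, inverse = TRUE)) / n
  sweep(x, 2, sqrt(colMeans(x^2)), "/")
}

# Time axis in ms for an epoch window at a sampling rate.
epoch_times <- function(epoch_window, sampling_rate) {
  dt <- 1000 / sampling_rate
  n <- round(diff(epoch_window) / dt)
  epoch_window[1] + (0:(n - 1)) * dt
}
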