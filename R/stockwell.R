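#' Discrete Stockwell transform of a single time course
#'
#' FFT formulation of the S-transform: for each frequency bin k the signal
#' spectrum is shifted by k, multiplied by a Gaussian voice window
#' `exp(-2 pi^2 m^2 / k^2)` (evaluated on the principal-alias frequency
#' offsets m), and inverse transformed. The window width scales inversely
#' with frequency, so low frequencies get fine frequency / coarse time
#' resolution and vice versa. The zero-offset term passes unchanged, which
#' yields the marginal identity: the time average of `S(tau, f_k)` equals
#' the discrete Fourier coefficient `H(f_k)`.
#'
#' @param x numeric vector (>= 8 samples).
#' @param sampling_rate Hz.
#' @param f_range length-2 Hz range of voices to return (default 5-50 Hz);
#'   must lie within (0, Nyquist].
#' @return object of class `stransform`: complex matrix `S` (time x
#'   frequency), `freqs` (Hz per column), `times` index, `sampling_rate`.
#' @export
stockwell <- function(x, sampling_rate, f_range = c(5, 50)) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("signal must have at least 8 samples")
  if (f_range[1] <= 0 || f_range[2] > sampling_rate / 2)
    stop("f_range must lie within (0, Nyquist]")
  X <- stats::fft(x)
  df <- sampling_rate / n
  kset <- which((0:(n - 1)) * df >= f_range[1] &
                (0:(n - 1)) * df <= f_range[2] &
                (0:(n - 1)) <= n / 2) - 1L
  if (!length(kset)) stop("no frequency bins fall inside f_range")
  m <- 0:(n - 1)
  m_alias <- ifelse(m <= n / 2, m, m - n)   # signed frequency offsets
  S <- matrix(0 + 0i, n, length(kset))
  for (j in seq_along(kset)) {
    k <- kset[j]
    Xs <- X[((k + m) %% n) + 1L]
    G <- exp(-2 * pi^2 * m_alias^2 / k^2)
    S[, j] <- stats::fft(Xs * G, inverse = TRUE) / n
  }
  structure(list(S = S, freqs = kset * df, sampling_rate = sampling_rate),
            class = "stransform")
}

st_power_sum <- function(ve_data_trial, sampling_rate, f_range) {
  # sum of squared S-transform magnitudes over the three orientations
  p <- NULL
  for (o in 1:3) {
    st <- stockwell(ve_data_trial[o, ], sampling_rate, f_range)
    p <- if (is.null(p)) Mod(st$S)^2 else p + Mod(st$S)^2
    freqs <- st$freqs
  }
  list(power = p, freqs = freqs)
}

#' Evoked time-frequency power at a virtual electrode
#'
#' Averages the trials first (cancelling non-phase-locked activity), then
#' transforms the average and sums squared magnitude over the three source
#' orientations.
#'
#' @param ve a `virtual_electrode`.
#' @param f_range length-2 Hz range (default 5-50).
#' @param conditions optional condition subset to average.
#' @return object of class `tf_power`: `power` (time x frequency, >= 0),
#'   `times` ms, `freqs` Hz, `mode = "evoked"`, `baseline = NULL`.
#' @export
evoked_power <- function(ve, f_range = c(5, 50), conditions = NULL) {
  stopifnot(inherits(ve, "virtual_electrode"))
  keep <- if (is.null(conditions)) seq_along(ve$labels)
          else which(ve$labels %in% conditions)
  if (!length(keep)) stop("no trials in the requested conditions")
  avg <- apply(ve$data[keep, , , drop = FALSE], c(2, 3), mean)
  ps <- st_power_sum(avg, ve$sampling_rate, f_range)
  structure(list(power = ps$power, times = ve$times, freqs = ps$freqs,
                 mode = "evoked", baseline = NULL),
            class = "tf_power")
}

#' Total time-frequency power at a virtual electrode
#'
#' Transforms every trial, squares, sums orientations and averages across
#' trials, retaining both evoked and induced components. By convexity the
#' evoked power never exceeds the total power at any time-frequency point.
#'
#' @inheritParams evoked_power
#' @return a `tf_power` with `mode = "total"`.
#' @export
total_power <- function(ve, f_range = c(5, 50), conditions = NULL) {
  stopifnot(inherits(ve, "virtual_electrode"))
  keep <- if (is.null(conditions)) seq_along(ve$labels)
          else which(ve$labels %in% conditions)
  if (!length(keep)) stop("no trials in the requested conditions")
  acc <- NULL
  for (tr in keep) {
    ps <- st_power_sum(ve$data[tr, , ], ve$sampling_rate, f_range)
    acc <- if (is.null(acc)) ps$power else acc + ps$power
  }
  structure(list(power = acc / length(keep), times = ve$times,
                 freqs = ps$freqs, mode = "total", baseline = NULL),
            class = "tf_power")
}

#' Baseline normalisation to percent signal change
#'
#' Per frequency bin, power is expressed relative to its mean over a
#' pre-trial baseline window: `100 * (P - P_base) / P_base`. Values are
#' bounded below by -100.
#'
#' @param tf a `tf_power` in raw power mode.
#' @param baseline length-2 ms window (default -700..-500 ms).
#' @param baseline_power optional per-frequency-bin baseline levels to use
#'   instead of this map's own baseline-window mean. Pass the output of
#'   [baseline_levels()] pooled across the conditions entering an analysis,
#'   so that all conditions share one denominator per participant and
#'   baseline noise cancels from condition differences.
#' @return a `tf_power` whose `power` is percent signal change and whose
#'   `baseline` records the window used.
#' @export
baseline_normalize <- function(tf, baseline = c(-700, -500),
                               baseline_power = NULL) {
  stopifnot(inherits(tf, "tf_power"))
  sel <- tf$times >= baseline[1] & tf$times < baseline[2]
  if (!any(sel)) stop("baseline window lies outside the map's time range")
  base <- baseline_power %||% colMeans(tf$power[sel, , drop = FALSE])
  if (length(base) != ncol(tf$power))
    stop("baseline_power must have one value per frequency bin")
  bad <- which(base <= 0)
  if (length(bad))
    stop("zero baseline power in frequency bin(s) ",
         paste(round(tf$freqs[bad], 2), collapse = ", "), " Hz")
  out <- tf
  out$power <- 100 * sweep(sweep(tf$power, 2, base), 2, base, "/")
  out$baseline <- baseline
  out$mode <- paste0(tf$mode, "_pct_change")
  out
}

#' Per-frequency baseline power of a time-frequency map
#'
#' Mean raw power per frequency bin over a baseline window; average the
#' result across the conditions entering an analysis to build the pooled
#' per-participant baseline for [baseline_normalize()].
#'
#' @param tf a `tf_power` in raw power mode.
#' @param baseline length-2 ms window (default -700..-500 ms).
#' @return numeric vector, one value per frequency bin.
#' @export
baseline_levels <- function(tf, baseline = c(-700, -500)) {
  stopifnot(inherits(tf, "tf_power"))
  sel <- tf$times >= baseline[1] & tf$times < baseline[2]
  if (!any(sel)) stop("baseline window lies outside the map's time range")
  colMeans(tf$power[sel, , drop = FALSE])
}

#' Resample a time-frequency map onto 25 ms x 2 Hz tiles
#'
#' Averages native-resolution values over half-open tiles
#' `[t, t + t_step) x [f, f + f_step)`. Under the defaults (epoch -800..700
#' ms, 5-50 Hz) the grid is 60 x 23 tiles labelled by their lower-left edge.
#'
#' @param tf a `tf_power` (any mode).
#' @param t_step tile width, ms (default 25).
#' @param f_step tile height, Hz (default 2).
#' @param t_range,f_range tiling extents; default the conventional
#'   -800..700 ms and 5-50 Hz.
#' @return object of class `tile_grid`: matrix `values` (time tiles x
#'   frequency tiles), `tile_times` and `tile_freqs` (lower edges).
#' @export
resample_tiles <- function(tf, t_step = 25, f_step = 2,
                           t_range = c(-800, 700), f_range = c(5, 50)) {
  stopifnot(inherits(tf, "tf_power"))
  tt <- seq(t_range[1], by = t_step,
            length.out = ceiling(diff(t_range) / t_step))
  ff <- seq(f_range[1], by = f_step,
            length.out = ceiling(diff(f_range) / f_step))
  vals <- matrix(NA_real_, length(tt), length(ff))
  t_bin <- floor((tf$times - t_range[1]) / t_step) + 1L
  f_bin <- floor((tf$freqs - f_range[1]) / f_step) + 1L
  for (i in seq_along(tt)) {
    ts <- which(t_bin == i)
    if (!length(ts)) stop("empty tile: no samples in time tile ", tt[i], " ms")
    for (j in seq_along(ff)) {
      fs <- which(f_bin == j)
      if (!length(fs))
        stop("empty tile: no voices in frequency tile ", ff[j], " Hz")
      vals[i, j] <- mean(tf$power[ts, fs])
    }
  }
  structure(list(values = vals, tile_times = tt, tile_freqs = ff,
                 t_step = t_step, f_step = f_step, mode = tf$mode),
            class = "tile_grid")
}

#' Write a tile grid as TSV (time_ms, freq_hz, value)
#' @param grid a `tile_grid`.
#' @param path output TSV.
#' @export
write_tiles_tsv <- function(grid, path) {
  df <- expand.grid(time_ms = grid$tile_times, freq_hz = grid$tile_freqs)
  df$value <- as.vector(grid$values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
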