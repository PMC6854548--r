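#' Simulation configuration
#'
#' Bundles recording, design and noise parameters for [simulate_epochs()].
#' Defaults emulate a whole-head magnetometer recording of a two-word
#' semantic judgement task: 248 channels sampled at 678.17 Hz, epochs of
#' 1500 ms starting 800 ms before onset of the second word, and four
#' conditions (taxonomic, strong thematic, weak thematic, unrelated).
#'
#' @param sampling_rate Hz.
#' @param epoch_window length-2 ms window relative to second-word onset.
#' @param conditions character vector of condition labels.
#' @param n_trials trials per condition (the full design uses 95 per related
#'   condition; scale down with `trial_scale` for fast simulations).
#' @param trial_scale multiplicative factor applied to `n_trials`.
#' @param n_participants number of simulated participants.
#' @param sensors a `sensor_array` (default built on the fly).
#' @param head a `head_model`.
#' @param sensor_noise_sd white sensor noise SD, tesla.
#' @param n_noise_dipoles number of random background dipoles whose 1/f
#'   time courses provide spatially structured brain noise.
#' @param noise_dipole_amp RMS amplitude of each background dipole, A m.
#' @param participant_amp_sd relative between-participant SD of effect
#'   amplitudes (0.1 = 10\%).
#' @param catch_fraction fraction of trials per condition marked as catch
#'   trials (these are flagged and dropped from analyses by default).
#' @param seed integer master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 678.17,
                       epoch_window = c(-800, 700),
                       conditions = c("taxonomic", "thematic_strong",
                                      "thematic_weak", "unrelated"),
                       n_trials = 95, trial_scale = 1,
                       n_participants = 19,
                       sensors = NULL, head = NULL,
                       sensor_noise_sd = 2e-14,
                       n_noise_dipoles = 200,
                       noise_dipole_amp = 5e-9,
                       participant_amp_sd = 0.1,
                       catch_fraction = 0,
                       seed = 1L) {
  if (length(conditions) < 1) stop("at least one condition required")
  n_tr <- max(1L, round(n_trials * trial_scale))
  if (is.null(head)) head <- spherical_head_model()
  if (is.null(sensors)) sensors <- build_sensor_array(seed = seed)
  nsamp <- round(diff(epoch_window) * sampling_rate / 1000)
  if (nsamp < 2) stop("epoch must span at least 2 samples")
  structure(list(
    sampling_rate = sampling_rate, epoch_window = epoch_window,
    conditions = conditions, n_trials = n_tr,
    n_participants = n_participants, sensors = sensors, head = head,
    sensor_noise_sd = sensor_noise_sd, n_noise_dipoles = n_noise_dipoles,
    noise_dipole_amp = noise_dipole_amp,
    participant_amp_sd = participant_amp_sd,
    catch_fraction = catch_fraction, seed = seed
  ), class = "sim_config")
}

#' Ground-truth oscillatory source specification
#'
#' Describes one dipolar source injected by [simulate_epochs()]: a windowed
#' cosine at a carrier frequency with a Hann amplitude envelope. The
#' phase-locked fraction of the amplitude has constant phase across trials
#' (an evoked response); the remainder gets a fresh uniform random phase per
#' trial (induced activity that cancels in the trial average).
#'
#' @param location 3-vector, metres, head frame (inside the head sphere).
#' @param freq carrier frequency, Hz.
#' @param window length-2 ms window (within the epoch) of the burst.
#' @param amplitude named numeric vector of dipole amplitudes per condition,
#'   A m; conditions missing from the vector get amplitude 0.
#' @param phase_locked_fraction share of amplitude with constant phase, 0..1.
#' @param orientation optional dipole orientation (3-vector); defaults to a
#'   tangential direction at `location`.
#' @return list of class `dipole_effect`.
#' @export
dipole_effect <- function(location, freq, window, amplitude,
                          phase_locked_fraction = 1, orientation = NULL) {
  if (any(amplitude < 0)) stop("amplitudes must be >= 0")
  if (phase_locked_fraction < 0 || phase_locked_fraction > 1)
    stop("phase_locked_fraction must lie in [0, 1]")
  if (is.null(orientation)) {
    loc <- as.numeric(location)
    orientation <- c(-loc[2], loc[1], 0)
    if (sqrt(sum(orientation^2)) < 1e-12) orientation <- c(1, 0, 0)
  }
  orientation <- as.numeric(orientation) / sqrt(sum(as.numeric(orientation)^2))
  structure(list(location = as.numeric(location), freq = freq,
                 window = as.numeric(window), amplitude = amplitude,
                 phase_locked_fraction = phase_locked_fraction,
                 orientation = orientation),
            class = "dipole_effect")
}

hann_window <- function(t_ms, window) {
  u <- (t_ms - window[1]) / diff(window)
  ifelse(u >= 0 & u <= 1, 0.5 - 0.5 * cos(2 * pi * u), 0)
}

#' Simulate multi-participant MEG epochs with known ground truth
#'
#' Each trial is the sum of the injected `effects` (windowed oscillations
#' forward-projected through the spherical-conductor lead field), background
#' brain noise from random interior dipoles with 1/f time courses, and white
#' sensor noise. Reproducible under the config seed.
#'
#' @param config a `sim_config`.
#' @param effects list of `dipole_effect` ground-truth sources (may be empty).
#' @return list with `epochs` (one `epochs_set` per participant) and
#'   `ground_truth` (the effects, per-participant amplitude factors, seed).
#' @export
simulate_epochs <- function(config, effects = list()) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(effects, "dipole_effect")) effects <- list(effects)
  nyq <- config$sampling_rate / 2
  for (e in effects) {
    if (e$freq >= nyq)
      stop("effect frequency ", e$freq, " Hz is at or above Nyquist (",
           nyq, " Hz)")
    d <- sqrt(sum((e$location - config$head$center)^2))
    if (d >= config$head$radius)
      stop("effect location lies outside the head sphere")
  }
  times <- epoch_times(config$epoch_window, config$sampling_rate)
  nsamp <- length(times)
  n_ch <- nrow(config$sensors$positions)
  labels <- rep(config$conditions, each = config$n_trials)
  n_total <- length(labels)

  # forward projection of each effect: channels vector per effect
  eff_gain <- lapply(effects, function(e) {
    point_lead_field(config$head, e$location, config$sensors) %*% e$orientation
  })

  epochs <- vector("list", config$n_participants)
  amp_factors <- matrix(1, config$n_participants, length(effects))
  for (p in seq_len(config$n_participants)) {
    set.seed(child_seed(config$seed, paste0("participant", p)))
    # background dipole mixing matrix, fixed within participant
    if (config$n_noise_dipoles > 0) {
      nd <- config$n_noise_dipoles
      u <- matrix(stats::rnorm(3 * nd), nd, 3)
      u <- u / sqrt(rowSums(u^2))
      rad <- config$head$radius * 0.85 * stats::runif(nd)^(1 / 3)
      locs <- sweep(u * rad, 2, config$head$center, "+")
      ori <- matrix(stats::rnorm(3 * nd), nd, 3)
      ori <- ori / sqrt(rowSums(ori^2))
      M <- vapply(seq_len(nd), function(i) {
        point_lead_field(config$head, locs[i, ], config$sensors) %*% ori[i, ]
      }, numeric(n_ch))
    } else M <- NULL
    if (length(effects))
      amp_factors[p, ] <- pmax(0, 1 + stats::rnorm(length(effects),
                                                   0, config$participant_amp_sd))
    dat <- array(0, dim = c(n_total, n_ch, nsamp))
    for (tr in seq_len(n_total)) {
      x <- matrix(0, n_ch, nsamp)
      for (k in seq_along(effects)) {
        e <- effects[[k]]
        a <- if (is.null(names(e$amplitude))) e$amplitude[1]
             else e$amplitude[labels[tr]]
        a <- if (is.na(a)) 0 else as.numeric(a)
        if (a > 0) {
          a <- a * amp_factors[p, k]
          env <- hann_window(times, e$window)
          ph <- 2 * pi * e$freq * (times - e$window[1]) / 1000
          plf <- e$phase_locked_fraction
          s <- a * env * (plf * cos(ph) +
                          (1 - plf) * cos(ph + stats::runif(1, 0, 2 * pi)))
          x <- x + eff_gain[[k]] %*% matrix(s, 1)
        }
      }
      if (!is.null(M))
        x <- x + M %*% t(pink_noise(nsamp, config$n_noise_dipoles)) *
          config$noise_dipole_amp
      if (config$sensor_noise_sd > 0)
        x <- x + matrix(stats::rnorm(n_ch * nsamp, 0, config$sensor_noise_sd),
                        n_ch, nsamp)
      dat[tr, , ] <- x
    }
    is_catch <- rep(FALSE, n_total)
    if (config$catch_fraction > 0) {
      per_cond <- max(1L, round(config$catch_fraction * config$n_trials))
      for (cond in config$conditions) {
        idx <- which(labels == cond)
        is_catch[sample(idx, min(per_cond, length(idx)))] <- TRUE
      }
    }
    epochs[[p]] <- structure(list(
      data = dat, times = times, labels = labels, is_catch = is_catch,
      participant = p, sensors = config$sensors,
      sampling_rate = config$sampling_rate
    ), class = "epochs_set")
  }
  list(epochs = epochs,
       ground_truth = list(effects = effects, amp_factors = amp_factors,
                           seed = config$seed))
}

#' Drop high-amplitude epochs
#'
#' Automatic stand-in for visual artefact rejection: trials whose peak
#' absolute value on any channel exceeds `amplitude_threshold` are removed.
#'
#' @param epochs an `epochs_set`.
#' @param amplitude_threshold tesla (> 0; `Inf` keeps everything).
#' @return list with the filtered `epochs` and a `report` giving the number
#'   and fraction rejected (an empty result is allowed and flagged).
#' @export
reject_epochs <- function(epochs, amplitude_threshold) {
  stopifnot(inherits(epochs, "epochs_set"))
  if (!is.numeric(amplitude_threshold) || amplitude_threshold <= 0)
    stop("amplitude_threshold must be > 0")
  peak <- apply(abs(epochs$data), 1, max)
  keep <- peak <= amplitude_threshold
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$labels <- epochs$labels[keep]
  out$is_catch <- epochs$is_catch[keep]
  list(epochs = out,
       report = list(participant = epochs$participant,
                     n_in = length(keep), n_rejected = sum(!keep),
                     fraction_rejected = mean(!keep),
                     empty = !any(keep)))
}

#' Simulate catch-trial behavioural tables
#'
#' Per-participant mean reaction time and accuracy per condition:
#' condition mean + participant offset + residual noise, with accuracy
#' clipped to \[0, 1\]. Reproducible under `seed`.
#'
#' @param n_participants number of participants.
#' @param condition_means data.frame with columns `condition`, `rt_ms`,
#'   `accuracy` (defaults give a strong>weak thematic accuracy/RT effect and
#'   matched taxonomic vs weak thematic performance).
#' @param sd_between named list, between-participant SDs (`rt_ms`, `accuracy`).
#' @param sd_within named list, residual SDs per condition cell.
#' @param n_catch catch trials per participant per condition.
#' @param seed integer.
#' @return data.frame (`behavioural_table`) with columns participant,
#'   condition, rt_ms, accuracy, n_catch.
#' @export
simulate_behaviour <- function(n_participants = 19,
                               condition_means = NULL,
                               sd_between = list(rt_ms = 60, accuracy = 0.04),
                               sd_within = list(rt_ms = 25, accuracy = 0.03),
                               n_catch = 24, seed = 1L) {
  if (is.null(condition_means))
    condition_means <- data.frame(
      condition = c("taxonomic", "thematic_strong", "thematic_weak",
                    "unrelated"),
      rt_ms = c(980, 930, 995, 1010),
      accuracy = c(0.88, 0.96, 0.86, 0.90))
  if (any(condition_means$accuracy < 0 | condition_means$accuracy > 1))
    stop("condition mean accuracies must lie in [0, 1]")
  set.seed(as.integer(child_seed(seed, "behaviour")))
  rows <- list()
  for (p in seq_len(n_participants)) {
    off_rt <- stats::rnorm(1, 0, sd_between$rt_ms)
    off_acc <- stats::rnorm(1, 0, sd_between$accuracy)
    rt <- condition_means$rt_ms + off_rt +
      stats::rnorm(nrow(condition_means), 0, sd_within$rt_ms)
    acc <- condition_means$accuracy + off_acc +
      stats::rnorm(nrow(condition_means), 0, sd_within$accuracy)
    rows[[p]] <- data.frame(
      participant = p, condition = condition_means$condition,
      rt_ms = pmax(1, rt), accuracy = pmin(1, pmax(0, acc)),
      n_catch = n_catch)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("behavioural_table", "data.frame")
  out
}
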