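# Shared fixtures and independent oracles, all built in code.

tiny_head <- function() spherical_head_model(radius = 0.09)

tiny_sensors <- function(n = 24, seed = 3) {
  build_sensor_array(n, helmet_radius = 0.12, coverage_angle = 120,
                     seed = seed)
}

# "Multiple spheres": per-channel sphere centres jittered a few mm, which
# makes per-point lead fields full rank (no common silent orientation).
multi_sphere_head <- function(n_channels, jitter = 0.004, seed = 11) {
  set.seed(seed)
  spherical_head_model(
    channel_centers = matrix(rnorm(n_channels * 3, 0, jitter), n_channels, 3),
    channel_radii = rep(0.09, n_channels))
}

quick_config <- function(..., n_channels = 24, seed = 7) {
  sim_config(sensors = tiny_sensors(n_channels),
             head = tiny_head(), seed = seed, ...)
}

# Independent coding of the closed-form field of a current dipole in a
# conducting sphere, written directly from the literature formula with
# different intermediate algebra than the package implementation.
oracle_sphere_field <- function(r0, q, r_sensor) {
  mu0 <- 4 * pi * 1e-7
  a <- r_sensor - r0
  na <- sqrt(sum(a * a)); nr <- sqrt(sum(r_sensor * r_sensor))
  F_ <- na * (nr * na + nr^2 - sum(r0 * r_sensor))
  dF <- (na^2 / nr + sum(a * r_sensor) / na + 2 * na + 2 * nr) * r_sensor -
    (na + 2 * nr + sum(a * r_sensor) / na) * r0
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  m <- cr(q, r0)
  mu0 / (4 * pi * F_^2) * (F_ * m - sum(m * r_sensor) * dF)
}

# Radial field component of the primary (free-space) current dipole: for a
# spherical conductor the volume currents add nothing radially, so this is
# an independent closed-form check on B . r_hat.
oracle_radial_component <- function(r0, q, r_sensor) {
  mu0 <- 4 * pi * 1e-7
  d <- r_sensor - r0
  nd <- sqrt(sum(d * d))
  B_primary <- mu0 / (4 * pi) * c(
    q[2] * d[3] - q[3] * d[2],
    q[3] * d[1] - q[1] * d[3],
    q[1] * d[2] - q[2] * d[1]) / nd^3
  sum(B_primary * r_sensor / sqrt(sum(r_sensor^2)))
}

# Direct-summation (non-FFT) S-transform oracle: double loop over the
# frequency-shifted spectrum, spectrum itself computed by explicit DFT.
oracle_stockwell <- function(x, sampling_rate, f_range) {
  n <- length(x)
  X <- vapply(0:(n - 1), function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)), complex(1))
  df <- sampling_rate / n
  kset <- which((0:(n - 1)) * df >= f_range[1] &
                (0:(n - 1)) * df <= f_range[2] &
                (0:(n - 1)) <= n / 2) - 1L
  m <- 0:(n - 1)
  m_alias <- ifelse(m <= n / 2, m, m - n)
  S <- matrix(0 + 0i, n, length(kset))
  for (j in seq_along(kset)) {
    k <- kset[j]
    for (tau in 0:(n - 1)) {
      S[tau + 1, j] <- sum(X[((k + m) %% n) + 1] *
                             exp(-2 * pi^2 * m_alias^2 / k^2) *
                             exp(2i * pi * m * tau / n)) / n
    }
  }
  list(S = S, freqs = kset * df)
}

# Brute-force flood fill (recursive, scalar) for cluster labelling.
oracle_flood_fill <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (lab[cur[1], cur[2]] != 0L) next
        lab[cur[1], cur[2]] <- nxt
        for (o in offs) {
          ni <- cur[1] + o[1]; nj <- cur[2] + o[2]
          if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
              mask[ni, nj] && lab[ni, nj] == 0L)
            stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# Exact distribution of the maximal cluster size for k filled tiles placed
# uniformly on a small grid: full enumeration of all placements.
oracle_max_cluster_exact <- function(grid_shape, n_fill, connectivity) {
  n_tiles <- prod(grid_shape)
  combs <- utils::combn(n_tiles, n_fill)
  sizes <- apply(combs, 2, function(idx) {
    mask <- matrix(FALSE, grid_shape[1], grid_shape[2])
    mask[idx] <- TRUE
    lab <- oracle_flood_fill(mask, connectivity)
    if (max(lab) == 0) 0L else max(tabulate(lab[lab > 0]))
  })
  table(sizes) / ncol(combs)
}

# A tf_power object built directly from a value matrix, for tile-level tests.
make_tf_power <- function(values, times, freqs, mode = "total") {
  structure(list(power = values, times = times, freqs = freqs,
                 mode = mode, baseline = NULL), class = "tf_power")
}

# A tile_test object built directly from p-value matrices.
make_tile_test <- function(p_diff, p_baseA, p_baseB) {
  structure(list(diff_mean = p_diff * 0, t_diff = p_diff * 0,
                 p_diff = p_diff, t_baseA = p_baseA * 0, p_baseA = p_baseA,
                 t_baseB = p_baseB * 0, p_baseB = p_baseB,
                 df = 9, n_participants = 10,
                 tile_times = seq_len(nrow(p_diff)),
                 tile_freqs = seq_len(ncol(p_diff))),
            class = "tile_test")
}

# A minimal epochs_set built directly from a data array.
make_epochs <- function(data, sampling_rate = 678.17, t0 = -800,
                        labels = NULL, sensors = NULL) {
  nt <- dim(data)[1]; ns <- dim(data)[3]
  structure(list(
    data = data,
    times = t0 + (0:(ns - 1)) * 1000 / sampling_rate,
    labels = labels %||% rep("taxonomic", nt),
    is_catch = rep(FALSE, nt),
    participant = 1L,
    sensors = sensors %||% tiny_sensors(dim(data)[2]),
    sampling_rate = sampling_rate), class = "epochs_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

epoch_times_test <- function(window, fs) {
  n <- round(diff(window) * fs / 1000)
  window[1] + (0:(n - 1)) * 1000 / fs
}
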