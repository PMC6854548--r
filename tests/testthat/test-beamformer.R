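test_that("covariance estimation matches first principles", {
  # constant-zero data gives the zero matrix
  ep0 <- make_epochs(array(0, dim = c(3, 4, 64)))
  C0 <- estimate_covariance(ep0, c(-800, -750))
  expect_true(all(C0$cov == 0))

  # unit-variance white noise, broadband: variance within 5% at 1e4 samples
  set.seed(5)
  ep1 <- make_epochs(array(rnorm(1 * 1 * 10000), dim = c(1, 1, 10000)),
                     sampling_rate = 678.17, t0 = 0)
  C1 <- estimate_covariance(ep1, c(0, 1e7))
  expect_equal(as.numeric(C1$cov), 1, tolerance = 0.05)
  expect_equal(C1$n_samples, 10000)

  # two perfectly correlated channels: off-diagonal equals the geometric
  # mean of the diagonals
  x <- rnorm(500)
  dat <- array(0, dim = c(1, 2, 500))
  dat[1, 1, ] <- x; dat[1, 2, ] <- 3 * x
  ep2 <- make_epochs(dat, t0 = 0)
  C2 <- estimate_covariance(ep2, c(0, 1e7))$cov
  expect_equal(C2[1, 2], sqrt(C2[1, 1] * C2[2, 2]), tolerance = 1e-9)

  expect_error(estimate_covariance(ep0, c(-800, -799.5)), "3 samples")
  expect_error(estimate_covariance(ep0, c(-800, -750), band = c(5, 1000)),
               "Nyquist")
})

test_that("band-passing concentrates covariance power in the band", {
  set.seed(8)
  fs <- 678.17
  n <- 2000
  t <- (0:(n - 1)) / fs
  x <- cos(2 * pi * 10 * t) + cos(2 * pi * 40 * t)
  dat <- array(x, dim = c(1, 1, n))
  ep <- make_epochs(dat, sampling_rate = fs, t0 = 0)
  v_all <- as.numeric(estimate_covariance(ep, c(500, 2500))$cov)
  v_low <- as.numeric(estimate_covariance(ep, c(500, 2500), c(5, 15))$cov)
  v_high <- as.numeric(estimate_covariance(ep, c(500, 2500), c(35, 50))$cov)
  expect_equal(v_low, 0.5, tolerance = 0.05)
  expect_equal(v_high, 0.5, tolerance = 0.05)
  expect_equal(v_all, 1.0, tolerance = 0.05)
})

test_that("diagonal loading shifts the spectrum as specified", {
  set.seed(6)
  A <- matrix(rnorm(64), 8, 8); C <- crossprod(A)
  ce <- structure(list(cov = C, window = c(0, 1), band = NULL,
                       n_samples = 100, lambda = 0), class = "cov_estimate")
  noise <- structure(list(cov = diag(2, 8), window = c(0, 1), band = NULL,
                          n_samples = 100, lambda = 0),
                     class = "cov_estimate")
  # lambda 0: identity operation
  expect_equal(regularize_covariance(ce, noise, 0)$cov, C)
  # C = 0, mean noise diagonal sigma^2, lambda 1 -> sigma^2 I
  zero <- ce; zero$cov <- C * 0
  expect_equal(regularize_covariance(zero, noise, 1)$cov, diag(2, 8))
  # eigenvalue shift
  lam <- 0.3
  reg <- regularize_covariance(ce, noise, lam)
  ev <- eigen(reg$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), lam * 2 - 1e-12)
  expect_equal(reg$lambda, lam * 2)
})

test_that("LCMV weights satisfy the unit-gain constraint", {
  set.seed(9)
  for (r in 1:20) {
    L <- matrix(rnorm(24 * 3), 24, 3)
    A <- matrix(rnorm(24 * 24), 24, 24)
    C <- crossprod(A) + diag(0.1, 24)
    ce <- structure(list(cov = C, window = NULL, band = NULL,
                         n_samples = 1, lambda = 0), class = "cov_estimate")
    W <- lcmv_weights(L, ce)$W
    expect_lt(max(abs(W %*% L - diag(3))), 1e-8)
  }
  # identity covariance: the weights reduce to the pseudoinverse
  L <- matrix(rnorm(24 * 3), 24, 3)
  ci <- structure(list(cov = diag(24), window = NULL, band = NULL,
                       n_samples = 1, lambda = 0), class = "cov_estimate")
  W <- lcmv_weights(L, ci)$W
  expect_equal(W, solve(crossprod(L), t(L)), tolerance = 1e-10)
  # a rank-1 lead field is rejected with a condition report
  L1 <- cbind(L[, 1], L[, 1] * 2, L[, 1] * 3)
  expect_error(lcmv_weights(L1, ci), "rank")
})

test_that("the minimum-variance property holds in a single-source scene", {
  head <- tiny_head()
  sens <- tiny_sensors(24)
  cfg <- sim_config(sensors = sens, head = head, n_trials = 20,
                    n_participants = 1, conditions = "taxonomic",
                    n_noise_dipoles = 30, noise_dipole_amp = 1e-9,
                    sensor_noise_sd = 5e-15, seed = 17)
  src <- c(0.02, 0.01, 0.04)
  eff <- dipole_effect(src, 20, c(0, 500), c(taxonomic = 5e-8), 1)
  ep <- simulate_epochs(cfg, list(eff))$epochs[[1]]
  noise <- estimate_covariance(ep, c(-700, -500), c(15, 25))
  Ca <- estimate_covariance(ep, c(0, 500), c(15, 25))
  Creg <- regularize_covariance(Ca, noise)
  out_var <- function(loc) {
    W <- lcmv_weights(point_lead_field(head, loc, sens), Creg)$W
    sum(diag(W %*% Ca$cov %*% t(W)))
  }
  v_src <- out_var(src)
  for (shift in list(c(0.03, 0, 0), c(0, -0.04, 0), c(-0.02, 0.02, -0.02)))
    expect_lte(out_var(src + shift), v_src)
})

test_that("virtual electrodes are linear and recover a known source", {
  head <- tiny_head()
  sens <- tiny_sensors(24)
  mh <- multi_sphere_head(24)
  loc <- c(0.015, -0.01, 0.035)
  L <- point_lead_field(mh, loc, sens)
  ns <- 128
  s_true <- rbind(sin(2 * pi * (1:ns) / 32), cos(2 * pi * (1:ns) / 24),
                  sin(2 * pi * (1:ns) / 50 + 1))
  dat <- array(0, dim = c(2, 24, ns))
  dat[1, , ] <- L %*% s_true
  dat[2, , ] <- 2 * (L %*% s_true)
  ep <- make_epochs(dat * 1e-8, t0 = 0)
  ci <- structure(list(cov = diag(24), window = NULL, band = NULL,
                       n_samples = 1, lambda = 0), class = "cov_estimate")
  flt <- lcmv_weights(L, ci)
  ve <- virtual_electrode(flt, ep)
  # unit gain implies exact recovery of the injected time course
  expect_equal(ve$data[1, , ], s_true * 1e-8, tolerance = 1e-8)
  # linearity: doubled input, doubled output
  expect_equal(ve$data[2, , ], 2 * ve$data[1, , ], tolerance = 1e-12)
  # zero data gives zero output
  ep0 <- make_epochs(array(0, dim = c(1, 24, ns)), t0 = 0)
  ve0 <- virtual_electrode(flt, ep0)
  expect_true(all(ve0$data == 0))
})

test_that("NAI equals one under the null and is scale invariant", {
  head <- tiny_head()
  sens <- tiny_sensors(16)
  cfg <- sim_config(sensors = sens, head = head, n_trials = 6,
                    n_participants = 1, conditions = "taxonomic",
                    n_noise_dipoles = 20, seed = 23)
  ep <- simulate_epochs(cfg)$epochs[[1]]
  lat <- source_lattice(head, 0.02, extent = c(0.03, 0.03, 0.03))
  LF <- lead_field(head, lat, sens)
  band <- c(15, 25); win <- c(0, 200)
  noise <- estimate_covariance(ep, win, band)   # same window: data == noise
  vol <- nai_volume(ep, LF, band, win, noise)
  expect_equal(vol$nai, rep(1, length(vol$nai)), tolerance = 1e-6)

  # global rescaling of data (hence of both covariances) leaves NAI fixed
  noise2 <- estimate_covariance(ep, c(-700, -500), band)
  v1 <- nai_volume(ep, LF, band, win, noise2)
  ep2 <- ep; ep2$data <- ep$data * 3.7
  noise3 <- estimate_covariance(ep2, c(-700, -500), band)
  v2 <- nai_volume(ep2, LF, band, win, noise3)
  expect_equal(v1$nai, v2$nai, tolerance = 1e-9)
})

test_that("NAI is invariant to consistent channel reordering", {
  head <- tiny_head()
  sens <- tiny_sensors(16)
  cfg <- sim_config(sensors = sens, head = head, n_trials = 8,
                    n_participants = 1, conditions = "taxonomic",
                    n_noise_dipoles = 20, seed = 29)
  eff <- dipole_effect(c(0.01, 0, 0.03), 20, c(0, 400),
                       c(taxonomic = 2e-8), 1)
  ep <- simulate_epochs(cfg, list(eff))$epochs[[1]]
  lat <- source_lattice(head, 0.02, extent = c(0.02, 0.02, 0.02))
  LF <- lead_field(head, lat, sens)
  noise <- estimate_covariance(ep, c(-700, -500), c(15, 25))
  v1 <- nai_volume(ep, LF, c(15, 25), c(0, 400), noise)

  perm <- sample(16)
  ep2 <- ep; ep2$data <- ep$data[, perm, ]
  sens2 <- sens
  sens2$positions <- sens$positions[perm, ]
  sens2$orientations <- sens$orientations[perm, ]
  ep2$sensors <- sens2
  LF2 <- LF
  LF2$L <- lapply(LF$L, function(m) m[perm, ])
  noise2 <- estimate_covariance(ep2, c(-700, -500), c(15, 25))
  v2 <- nai_volume(ep2, LF2, c(15, 25), c(0, 400), noise2)
  expect_equal(v1$nai, v2$nai, tolerance = 1e-8)
})

test_that("a single injected dipole is localised to its lattice point", {
  head <- tiny_head()
  sens <- tiny_sensors(32)
  src <- c(0.02, 0.01, 0.05)
  cfg <- sim_config(sensors = sens, head = head, n_trials = 20,
                    n_participants = 1, conditions = "taxonomic",
                    n_noise_dipoles = 50, noise_dipole_amp = 5e-9,
                    sensor_noise_sd = 2e-14, seed = 31)
  eff <- dipole_effect(src, 30, c(150, 450), c(taxonomic = 5e-8), 0.5)
  ep <- simulate_epochs(cfg, list(eff))$epochs[[1]]
  lat <- source_lattice(head, 0.005, extent = c(0.02, 0.02, 0.02),
                        origin = src)
  LF <- lead_field(head, lat, sens)
  noise <- estimate_covariance(ep, c(-700, -500), c(25, 35))
  vol <- nai_volume(ep, LF, c(25, 35), c(150, 450), noise)
  best <- lat$points[which.max(vol$nai), ]
  expect_lte(sqrt(sum((best - src)^2)), 0.005)
})

test_that("two distant uncorrelated dipoles both appear as local maxima", {
  head <- tiny_head()
  sens <- tiny_sensors(32)
  srcA <- c(0.025, 0.0, 0.045); srcB <- c(-0.025, 0.0, 0.015)
  cfg <- sim_config(sensors = sens, head = head, n_trials = 20,
                    n_participants = 1, conditions = "taxonomic",
                    n_noise_dipoles = 50, noise_dipole_amp = 2e-9,
                    sensor_noise_sd = 1e-14, seed = 37)
  effs <- list(
    dipole_effect(srcA, 22, c(0, 500), c(taxonomic = 5e-8), 0),
    dipole_effect(srcB, 27, c(0, 500), c(taxonomic = 5e-8), 0))
  ep <- simulate_epochs(cfg, effs)$epochs[[1]]
  lat <- source_lattice(head, 0.005, extent = c(0.04, 0.01, 0.03),
                        origin = c(0, 0, 0.03))
  LF <- lead_field(head, lat, sens)
  noise <- estimate_covariance(ep, c(-700, -500), c(15, 35))
  vol <- nai_volume(ep, LF, c(15, 35), c(0, 500), noise)
  near <- function(s) which(sqrt(rowSums(sweep(lat$points, 2, s)^2)) <= 0.0051)
  far_max <- max(vol$nai[-c(near(srcA), near(srcB))])
  expect_gt(max(vol$nai[near(srcA)]), far_max * 0.99)
  expect_gt(max(vol$nai[near(srcB)]), far_max * 0.6)
  bestA <- lat$points[near(srcA)[which.max(vol$nai[near(srcA)])], ]
  bestB <- lat$points[near(srcB)[which.max(vol$nai[near(srcB)])], ]
  expect_lte(sqrt(sum((bestA - srcA)^2)), 0.0051)
  expect_lte(sqrt(sum((bestB - srcB)^2)), 0.0051)
})
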