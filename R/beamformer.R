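#' Band-limited sensor covariance over an epoch window
#'
#' Band-passes every trial with a zero-phase 4th-order Butterworth filter,
#' then pools the samples falling in `window` across trials and computes the
#' sample covariance (about the pooled mean).
#'
#' @param epochs an `epochs_set`.
#' @param window length-2 ms window within the epoch.
#' @param band length-2 Hz pass band within (0, Nyquist), or `NULL` for
#'   broadband (no filtering).
#' @param conditions optional subset of condition labels to pool (default
#'   all non-catch trials).
#' @return object of class `cov_estimate` with fields `cov` (channels x
#'   channels, tesla^2), `window`, `band`, `n_samples`, `lambda` (0 here).
#' @export
estimate_covariance <- function(epochs, window, band = NULL,
                                conditions = NULL) {
  stopifnot(inherits(epochs, "epochs_set"))
  fs <- epochs$sampling_rate
  if (!is.null(band)) {
    if (band[1] <= 0 || band[2] >= fs / 2)
      stop("band must lie strictly within (0, Nyquist)")
  }
  sel <- epochs$times >= window[1] & epochs$times < window[2]
  if (sum(sel) < 3) stop("covariance window spans fewer than 3 samples")
  keep <- !epochs$is_catch
  if (!is.null(conditions)) keep <- keep & epochs$labels %in% conditions
  trials <- which(keep)
  if (!length(trials)) stop("no trials left after condition selection")
  n_ch <- dim(epochs$data)[2]
  pooled <- matrix(0, sum(sel) * length(trials), n_ch)
  row0 <- 0
  for (tr in trials) {
    x <- t(matrix(epochs$data[tr, , ], n_ch))   # samples x channels
    if (!is.null(band)) x <- bandpass_zero_phase(x, fs, band)
    pooled[row0 + seq_len(sum(sel)), ] <- x[sel, , drop = FALSE]
    row0 <- row0 + sum(sel)
  }
  pooled <- sweep(pooled, 2, colMeans(pooled))
  C <- crossprod(pooled) / max(1, nrow(pooled) - 1)
  C <- (C + t(C)) / 2
  structure(list(cov = C, window = window, band = band,
                 n_samples = nrow(pooled), lambda = 0),
            class = "cov_estimate")
}

#' Diagonal-loading regularisation scaled by the noise floor
#'
#' Adds `lambda_rel` times the mean diagonal of the noise covariance to the
#' diagonal: `C + lambda_rel * mean(diag(N)) * I`. The amount applied is
#' recorded on the result.
#'
#' @param cov a `cov_estimate` to regularise.
#' @param noise_cov a `cov_estimate` providing the noise floor.
#' @param lambda_rel non-negative loading fraction (default 0.05).
#' @return regularised `cov_estimate`.
#' @export
regularize_covariance <- function(cov, noise_cov, lambda_rel = 0.05) {
  stopifnot(inherits(cov, "cov_estimate"), inherits(noise_cov, "cov_estimate"))
  if (lambda_rel < 0) stop("lambda_rel must be >= 0")
  amount <- lambda_rel * mean(diag(noise_cov$cov))
  out <- cov
  out$cov <- cov$cov + diag(amount, nrow(cov$cov))
  out$lambda <- cov$lambda + amount
  out
}

#' Identity-based noise covariance
#'
#' Alternative noise estimator: the identity scaled by the smallest
#' eigenvalue of a data covariance (a white-noise floor).
#'
#' @param cov a `cov_estimate`.
#' @return a `cov_estimate` whose matrix is `min(eigenvalues) * I`.
#' @export
identity_noise_cov <- function(cov) {
  ev <- eigen(cov$cov, symmetric = TRUE, only.values = TRUE)$values
  out <- cov
  out$cov <- diag(max(0, min(ev)), nrow(cov$cov))
  out
}

#' Vectorised LCMV beamformer weights for one source point
#'
#' Minimum-variance spatial filter with a unit-gain constraint on the
#' orthogonal dipole orientations at the point:
#' `W = (L' C^-1 L)^-1 L' C^-1` (3 x channels). With a full-rank lead field
#' and covariance, `W %*% L` is the 3 x 3 identity.
#'
#' In a single-sphere conductor the radial source orientation is externally
#' silent, so the per-point lead field has exact rank 2. The silent
#' direction is then removed by SVD (singular values below `rank_tol` times
#' the largest are truncated) and the constraint is enforced on the
#' remaining subspace: `W %*% L` is the orthogonal projector onto the
#' non-silent orientations, and the filter output along the silent
#' direction is zero. Lead fields of effective rank < 2 are rejected.
#'
#' @param leadfield_point channels x 3 lead-field matrix at the point.
#' @param cov a (regularised) `cov_estimate`.
#' @param rank_tol relative singular-value cut-off for silent orientations
#'   (default 1e-7).
#' @return object of class `spatial_filter` with `W` (3 x channels), the
#'   effective `rank`, and the covariance metadata.
#' @export
lcmv_weights <- function(leadfield_point, cov, rank_tol = 1e-7) {
  stopifnot(inherits(cov, "cov_estimate"))
  L <- as.matrix(leadfield_point)
  if (ncol(L) != 3) stop("lead field at a point must be channels x 3")
  sv <- svd(L)
  keep <- sv$d > rank_tol * sv$d[1]
  r <- sum(keep)
  if (r < 2 || sv$d[1] == 0)
    stop(sprintf(
      "rank-deficient lead field (effective rank %d, singular values %s)",
      r, paste(signif(sv$d, 3), collapse = ", ")))
  V <- sv$v[, keep, drop = FALSE]
  Lr <- L %*% V                        # channels x r, full column rank
  Ci_L <- solve(cov$cov, Lr)
  G <- crossprod(Lr, Ci_L)             # Lr' C^-1 Lr, r x r
  rc <- rcond(G)
  if (!is.finite(rc) || rc < 1e-14)
    stop(sprintf(
      "rank-deficient constrained Gram matrix (reciprocal condition %.3e)",
      rc))
  W <- V %*% solve(G, t(Ci_L))         # 3 x channels
  structure(list(W = W, rank = r, window = cov$window, band = cov$band,
                 lambda = cov$lambda),
            class = "spatial_filter")
}

#' Virtual-electrode time courses
#'
#' Applies a spatial filter to every trial, giving the reconstructed
#' three-orientation source time course at the filter's point. Linear in
#' the sensor data.
#'
#' @param filter a `spatial_filter`.
#' @param epochs an `epochs_set` with matching channel count.
#' @param drop_catch drop catch trials (default TRUE).
#' @param conditions optional condition subset.
#' @return object of class `virtual_electrode`: `data` array (trials x 3 x
#'   samples), `times`, `labels`, `sampling_rate`.
#' @export
virtual_electrode <- function(filter, epochs, drop_catch = TRUE,
                              conditions = NULL) {
  stopifnot(inherits(filter, "spatial_filter"), inherits(epochs, "epochs_set"))
  n_ch <- dim(epochs$data)[2]
  if (ncol(filter$W) != n_ch)
    stop("filter has ", ncol(filter$W), " channels, data has ", n_ch)
  keep <- if (drop_catch) !epochs$is_catch else rep(TRUE, dim(epochs$data)[1])
  if (!is.null(conditions)) keep <- keep & epochs$labels %in% conditions
  trials <- which(keep)
  nsamp <- dim(epochs$data)[3]
  out <- array(0, dim = c(length(trials), 3, nsamp))
  for (i in seq_along(trials)) {
    out[i, , ] <- filter$W %*% epochs$data[trials[i], , ]
  }
  structure(list(data = out, times = epochs$times,
                 labels = epochs$labels[trials],
                 sampling_rate = epochs$sampling_rate),
            class = "virtual_electrode")
}

#' Neural Activity Index volume
#'
#' Noise-normalised total source power at every lattice point:
#' `NAI(p) = tr(W C_active W') / tr(W N W')`, with `W` the LCMV weights from
#' the regularised active-window covariance. The trace sums power over the
#' three source orientations; using total (per-trial) covariance keeps both
#' evoked and induced components. Points where the weights are degenerate
#' are skipped (NA) and logged.
#'
#' @param epochs an `epochs_set`.
#' @param leadfield a `lead_field` over the lattice to scan.
#' @param band length-2 Hz band.
#' @param active_window length-2 ms window.
#' @param noise_cov a `cov_estimate` of the noise floor (e.g. from the
#'   passive window, identically band-passed).
#' @param lambda_rel diagonal-loading fraction (default 0.05).
#' @param conditions optional condition subset pooled into the covariance.
#' @return object of class `nai_volume`: `nai` per lattice point, `lattice`,
#'   `band`, `window`, `skipped` (indices of degenerate points).
#' @export
nai_volume <- function(epochs, leadfield, band, active_window, noise_cov,
                       lambda_rel = 0.05, conditions = NULL) {
  stopifnot(inherits(leadfield, "lead_field"),
            inherits(noise_cov, "cov_estimate"))
  Ca <- estimate_covariance(epochs, active_window, band, conditions)
  Creg <- regularize_covariance(Ca, noise_cov, lambda_rel)
  n_pt <- length(leadfield$L)
  nai <- rep(NA_real_, n_pt)
  skipped <- integer(0)
  for (p in seq_len(n_pt)) {
    res <- tryCatch({
      flt <- lcmv_weights(leadfield$L[[p]], Creg)
      num <- sum(diag(flt$W %*% Ca$cov %*% t(flt$W)))
      den <- sum(diag(flt$W %*% noise_cov$cov %*% t(flt$W)))
      num / den
    }, error = function(e) NA_real_)
    if (is.na(res)) skipped <- c(skipped, p) else nai[p] <- res
  }
  structure(list(nai = nai, lattice = leadfield$lattice, band = band,
                 window = active_window, skipped = skipped),
            class = "nai_volume")
}

#' Export an NAI (or any per-point) volume to NIfTI
#'
#' Rasterises lattice values onto the lattice's box grid (isotropic voxels
#' at the lattice spacing, head frame; no anatomical warp) and writes a
#' NIfTI file. Points outside the head are zero-filled.
#'
#' @param values numeric vector, one value per lattice point, or an
#'   `nai_volume`.
#' @param lattice the `source_lattice` (taken from the volume if omitted).
#' @param path output file (.nii or .nii.gz).
#' @export
write_volume_nifti <- function(values, lattice = NULL, path) {
  if (inherits(values, "nai_volume")) {
    lattice <- values$lattice
    values <- values$nai
  }
  stopifnot(inherits(lattice, "source_lattice"))
  arr <- array(0, dim = lattice$grid_dim)
  arr[lattice$grid_index] <- ifelse(is.na(values), 0, values)
  img <- RNifti::asNifti(arr, pixdim = rep(lattice$spacing * 1000, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a per-point volume as TSV (x, y, z, value)
#' @param values numeric per-point values or an `nai_volume`.
#' @param lattice the `source_lattice` (taken from the volume if omitted).
#' @param path output TSV file.
#' @export
write_volume_tsv <- function(values, lattice = NULL, path) {
  if (inherits(values, "nai_volume")) {
    lattice <- values$lattice
    values <- values$nai
  }
  df <- data.frame(x = lattice$points[, 1], y = lattice$points[, 2],
                   z = lattice$points[, 3], value = values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
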