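#' Paired t map between two per-participant volumes
#'
#' Per lattice point, the paired-samples t statistic across participants for
#' the difference between an "active" and a "passive" volume (e.g. NAI maps
#' from post-stimulus vs pre-trial windows). Points with zero variance of
#' the paired difference get t = 0 and are flagged rather than dropped.
#'
#' @param active,passive participants x points matrices (or lists of
#'   `nai_volume` on identical lattices).
#' @return object of class `t_map`: `t` per point, `df`, `zero_variance`
#'   logical flags, and the number of participants.
#' @export
active_passive_tmap <- function(active, passive) {
  active <- as_volume_matrix(active)
  passive <- as_volume_matrix(passive)
  if (!all(dim(active) == dim(passive)))
    stop("active and passive volumes differ in shape (",
         paste(dim(active), collapse = "x"), " vs ",
         paste(dim(passive), collapse = "x"), ")")
  n <- nrow(active)
  if (n < 2) stop("at least 2 participants required for a paired t map")
  d <- active - passive
  m <- colMeans(d)
  v <- colSums(sweep(d, 2, m)^2) / (n - 1)
  zero_var <- v <= 0
  tval <- ifelse(zero_var, 0, m / sqrt(v / n))
  structure(list(t = tval, df = n - 1, zero_variance = zero_var,
                 n_participants = n),
            class = "t_map")
}

as_volume_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x) && length(x) && inherits(x[[1]], "nai_volume")) {
    lat <- x[[1]]$lattice
    for (v in x)
      if (!identical(dim(v$lattice$points), dim(lat$points)) ||
          max(abs(v$lattice$points - lat$points)) > 0)
        stop("volumes computed on mismatched lattices")
    return(do.call(rbind, lapply(x, function(v) v$nai)))
  }
  as.matrix(x)
}

# Vectorised paired-t for sign-flipped differences.
# D: participants x points; S: permutations x participants sign matrix.
# Because (s_i d_i)^2 = d_i^2, only the mean depends on the signs.
flip_t <- function(D, S) {
  n <- nrow(D)
  M <- (S %*% D) / n
  SS <- matrix(colSums(D^2), nrow(S), ncol(D), byrow = TRUE)
  V <- (SS - n * M^2) / (n - 1)
  Tm <- ifelse(V <= 0, 0, M / sqrt(V / n))
  Tm
}

#' Permutation maximum-statistic threshold for a paired contrast
#'
#' Builds a null distribution by randomly relabelling the two windows for
#' each participant (equivalently, flipping the sign of the paired
#' difference), records the maximum |t| over all points per permutation, and
#' thresholds the observed map at the configured quantile of those maxima.
#' In `whole_map` mode (default) each participant's entire volume is flipped
#' at once, preserving the spatial covariance of the map; `per_point` flips
#' independently at every point. With `exhaustive = TRUE` all `2^n` sign
#' patterns are enumerated instead of sampled (feasible for n <= 20).
#'
#' @param active,passive participants x points matrices (or lists of
#'   `nai_volume`).
#' @param n_permutations number of random relabellings (>= 100; the full
#'   analysis uses 10000).
#' @param quantile the quantile of the max-|t| null used as threshold
#'   (default 0.95, i.e. the top 5\%).
#' @param seed integer seed for the relabelling.
#' @param mode `"whole_map"` or `"per_point"`.
#' @param exhaustive enumerate all sign patterns instead of sampling.
#' @return object of class `permutation_null`: observed `t_map`, `max_abs_t`
#'   per permutation, `threshold`, `survivors` (logical per point), `seed`,
#'   `mode`.
#' @export
permutation_threshold <- function(active, passive, n_permutations = 10000,
                                  quantile = 0.95, seed = 1L,
                                  mode = c("whole_map", "per_point"),
                                  exhaustive = FALSE) {
  mode <- match.arg(mode)
  active <- as_volume_matrix(active)
  passive <- as_volume_matrix(passive)
  if (nrow(active) < 2) stop("at least 2 participants required")
  if (!exhaustive && n_permutations < 100)
    stop("n_permutations must be >= 100")
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  obs <- active_passive_tmap(active, passive)
  D <- active - passive
  n <- nrow(D); p <- ncol(D)
  set.seed(as.integer(child_seed(seed, "permute")))
  if (exhaustive) {
    if (n > 20) stop("exhaustive enumeration limited to n <= 20 participants")
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    storage.mode(S) <- "double"
    n_permutations <- nrow(S)
  } else {
    S <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                n_permutations, n)
  }
  if (mode == "whole_map") {
    Tm <- flip_t(D, S)
    max_abs <- apply(abs(Tm), 1, max)
  } else {
    max_abs <- numeric(n_permutations)
    for (b in seq_len(n_permutations)) {
      Sp <- if (exhaustive) matrix(S[b, ], n, p)
            else matrix(sample(c(-1, 1), n * p, replace = TRUE), n, p)
      m <- colSums(Sp * D) / n
      v <- (colSums(D^2) - n * m^2) / (n - 1)
      tb <- ifelse(v <= 0, 0, m / sqrt(v / n))
      max_abs[b] <- max(abs(tb))
    }
  }
  thr <- sort(max_abs)[ceiling(quantile * n_permutations)]
  structure(list(t_map = obs, max_abs_t = max_abs, threshold = thr,
                 survivors = abs(obs$t) >= thr & abs(obs$t) > 0,
                 n_permutations = n_permutations, quantile = quantile,
                 seed = seed, mode = mode),
            class = "permutation_null")
}

#' Write a permutation null distribution as TSV
#' @param null a `permutation_null`.
#' @param path output TSV.
#' @export
write_null_tsv <- function(null, path) {
  df <- data.frame(permutation = seq_along(null$max_abs_t),
                   max_abs_t = null$max_abs_t)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
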