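#' Paired condition tests on time-frequency tiles
#'
#' Per tile, across participants: a paired t test of condition A minus
#' condition B, plus one-sample t tests of each condition's percent signal
#' change against zero (the baseline). Tiles with zero variance and zero
#' mean get t = 0, p = 1.
#'
#' @param gridsA,gridsB per-participant lists of `tile_grid` (identical
#'   shapes), e.g. baseline-normalised evoked power per condition.
#' @return object of class `tile_test`: matrices `diff_mean`, `t_diff`,
#'   `p_diff`, `t_baseA`, `p_baseA`, `t_baseB`, `p_baseB`, plus `df`,
#'   `n_participants` and the tile axes.
#' @export
tile_condition_test <- function(gridsA, gridsB) {
  stack <- function(gr) {
    v <- lapply(gr, function(g) {
      if (inherits(g, "tile_grid")) g$values else as.matrix(g)
    })
    dims <- dim(v[[1]])
    for (m in v) if (!all(dim(m) == dims)) stop("tile grids differ in shape")
    array(unlist(v), dim = c(dims, length(v)))
  }
  A <- stack(gridsA); B <- stack(gridsB)
  if (!all(dim(A) == dim(B)))
    stop("condition A and B grids differ in shape")
  n <- dim(A)[3]
  if (n < 3) stop("at least 3 participants required")
  tile_t <- function(X) {
    m <- apply(X, c(1, 2), mean)
    s <- apply(X, c(1, 2), stats::sd)
    tv <- ifelse(s <= 0, ifelse(m == 0, 0, sign(m) * Inf), m / (s / sqrt(n)))
    pv <- ifelse(s <= 0 & m == 0, 1,
                 2 * stats::pt(-abs(tv), df = n - 1))
    list(m = m, t = tv, p = pv)
  }
  d <- tile_t(A - B)
  a <- tile_t(A)
  b <- tile_t(B)
  g1 <- gridsA[[1]]
  structure(list(diff_mean = d$m, t_diff = d$t, p_diff = d$p,
                 t_baseA = a$t, p_baseA = a$p,
                 t_baseB = b$t, p_baseB = b$p,
                 df = n - 1, n_participants = n,
                 tile_times = if (inherits(g1, "tile_grid")) g1$tile_times,
                 tile_freqs = if (inherits(g1, "tile_grid")) g1$tile_freqs),
            class = "tile_test")
}

#' Dual significance criteria for tiles
#'
#' A tile is retained iff (a) the condition difference reaches
#' `p < alpha_diff` and (b) at least one of the two contributing conditions
#' differs from baseline at `p < alpha_base`. Inequalities are strict.
#'
#' The difference p-values are first adjusted for multiplicity across the
#' tiles of the analysis (default Holm), mirroring mixed-model tile tests
#' whose contrasts control experiment-wise error within one site-by-contrast
#' analysis; the subsequent cluster-extent correction then only has to
#' handle the family of analyses. Set `p_adjust_method = "none"` for raw
#' tile-wise thresholds.
#'
#' @param result a `tile_test`.
#' @param alpha_diff threshold for the condition difference (default .05).
#' @param alpha_base threshold for the baseline departure (default .01).
#' @param p_adjust_method multiplicity adjustment for the difference
#'   p-values, any [stats::p.adjust()] method (default `"holm"`).
#' @return logical matrix of retained tiles, with the adjusted difference
#'   p-values attached as attribute `p_diff_adjusted`.
#' @export
dual_criteria_mask <- function(result, alpha_diff = 0.05, alpha_base = 0.01,
                               p_adjust_method = "holm") {
  stopifnot(inherits(result, "tile_test"))
  if (alpha_diff <= 0 || alpha_diff >= 1 || alpha_base <= 0 || alpha_base >= 1)
    stop("alpha thresholds must lie in (0, 1)")
  p_adj <- matrix(stats::p.adjust(result$p_diff, method = p_adjust_method),
                  nrow(result$p_diff), ncol(result$p_diff))
  mask <- p_adj < alpha_diff &
    (result$p_baseA < alpha_base | result$p_baseB < alpha_base)
  attr(mask, "p_diff_adjusted") <- p_adj
  mask
}

#' Label connected clusters of significant tiles
#'
#' Maximal connected components of a logical grid under 4- (edge) or
#' 8- (edge+corner) adjacency, labelled 1, 2, ... in order of each
#' cluster's first tile in column-major order.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return list with `labels` (integer matrix, 0 = background), `sizes`
#'   (tile count per cluster id) and `connectivity`.
#' @export
label_clusters <- function(mask, connectivity = 4) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  mask <- as.matrix(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0, nr, nc)
  lab[mask] <- which(mask)            # provisional: own column-major index
  pad_shift <- function(m, di, dj) {
    out <- matrix(Inf, nr, nc)
    ri <- seq_len(nr); rj <- seq_len(nc)
    si <- ri - di; sj <- rj - dj
    ok_i <- si >= 1 & si <= nr; ok_j <- sj >= 1 & sj <= nc
    out[ri[ok_i], rj[ok_j]] <- m[si[ok_i], sj[ok_j]]
    out
  }
  offsets <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    offsets <- c(offsets, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  work <- matrix(Inf, nr, nc)
  work[mask] <- lab[mask]
  repeat {
    new <- work
    for (o in offsets) new <- pmin(new, pad_shift(work, o[1], o[2]))
    new[!mask] <- Inf
    if (identical(new, work)) break
    work <- new
  }
  lab[] <- 0
  lab[mask] <- work[mask]
  # relabel in order of first (minimum) tile index per component
  ids <- sort(unique(lab[lab > 0]))
  relab <- match(lab, ids)
  lab[mask] <- relab[mask]
  sizes <- if (length(ids)) tabulate(lab[lab > 0], nbins = length(ids))
           else integer(0)
  list(labels = lab, sizes = sizes, connectivity = connectivity)
}

#' Monte-Carlo null distribution of the maximal cluster extent
#'
#' Under the null that significant tiles are scattered at random over the
#' grid, places `round(fill_rate * n_tiles)` tiles uniformly without
#' replacement and records the largest connected cluster, repeating
#' `n_simulations` times.
#'
#' @param grid_shape length-2 (rows, cols) of the tile grid (default the
#'   60 x 23 grid of a -800..700 ms x 5-50 Hz analysis).
#' @param fill_rate fraction of tiles filled, in \[0, 1\].
#' @param connectivity 4 or 8.
#' @param n_simulations >= 100.
#' @param seed integer.
#' @return object of class `cluster_null`: `max_sizes` per simulation,
#'   `prob` (named empirical distribution), and the parameters.
#' @export
cluster_null <- function(grid_shape = c(60, 23), fill_rate,
                         connectivity = 4, n_simulations = 10000, seed = 1L) {
  if (fill_rate < 0 || fill_rate > 1) stop("fill_rate must lie in [0, 1]")
  if (n_simulations < 100) stop("n_simulations must be >= 100")
  n_tiles <- prod(grid_shape)
  n_fill <- round(fill_rate * n_tiles)
  set.seed(as.integer(child_seed(seed, "clusternull")))
  max_sizes <- integer(n_simulations)
  if (n_fill > 0) {
    for (s in seq_len(n_simulations)) {
      mask <- matrix(FALSE, grid_shape[1], grid_shape[2])
      mask[sample.int(n_tiles, n_fill)] <- TRUE
      cl <- label_clusters(mask, connectivity)
      max_sizes[s] <- if (length(cl$sizes)) max(cl$sizes) else 0L
    }
  }
  tb <- table(max_sizes) / n_simulations
  structure(list(max_sizes = max_sizes, prob = tb,
                 grid_shape = grid_shape, fill_rate = fill_rate,
                 connectivity = connectivity,
                 n_simulations = n_simulations, seed = seed),
            class = "cluster_null")
}

#' Minimum significant cluster size from a cluster-extent null
#'
#' The smallest cluster size k whose family-wise chance probability
#' `P(max cluster >= k)` falls below `alpha / n_analyses` (Bonferroni over
#' the number of POI x contrast analyses, default 12).
#'
#' @param null a `cluster_null`.
#' @param alpha family-wise level (default .05).
#' @param n_analyses Bonferroni divisor (default 12).
#' @return integer k, or `NA` (with a warning) if no size satisfies the
#'   bound.
#' @export
min_cluster_size <- function(null, alpha = 0.05, n_analyses = 12) {
  stopifnot(inherits(null, "cluster_null"))
  target <- alpha / n_analyses
  ms <- null$max_sizes
  for (k in 0:(max(ms) + 1L)) {
    if (mean(ms >= k) < target) return(as.integer(k))
  }
  warning("no cluster size satisfies the bound at this fill rate")
  NA_integer_
}

#' Apply the cluster-extent threshold to a significance mask
#'
#' Removes clusters smaller than `k_min` tiles; sub-threshold clusters are
#' reported separately (the "dashed-contour" set).
#'
#' @param mask logical tile mask (dual-criteria output).
#' @param clusters output of [label_clusters()] on that mask.
#' @param k_min minimum cluster extent.
#' @return object of class `stat_contour_mask`: `retained` logical matrix,
#'   `labels` of surviving clusters (original ids), `dashed` logical matrix
#'   of sub-threshold clusters, `k_min`, `connectivity`.
#' @export
apply_cluster_threshold <- function(mask, clusters, k_min) {
  mask <- as.matrix(mask)
  if (!all(dim(clusters$labels) == dim(mask)))
    stop("cluster labels inconsistent with mask")
  big <- which(clusters$sizes >= k_min)
  retained <- clusters$labels %in% big & mask
  dim(retained) <- dim(mask)
  labs <- clusters$labels
  labs[!retained] <- 0
  dashed <- mask & !retained
  structure(list(retained = retained, labels = labs, dashed = dashed,
                 k_min = k_min, connectivity = clusters$connectivity),
            class = "stat_contour_mask")
}

#' Catch-trial behavioural tests
#'
#' Applies the participant exclusion rule (overall catch accuracy below
#' `exclusion_threshold` removes the participant), then runs paired
#' two-tailed t tests for each pairwise contrast among the related
#' conditions, on mean RT and accuracy.
#'
#' @param table a `behavioural_table` (participant, condition, rt_ms,
#'   accuracy, n_catch).
#' @param exclusion_threshold accuracy cut-off (default 0.75; strictly
#'   below is excluded).
#' @param contrasts list of length-2 character vectors of condition pairs;
#'   default the three related-condition contrasts.
#' @return object of class `behavioural_report`: data.frame `tests`
#'   (measure, contrast, t, df, p), `excluded` participant ids,
#'   `n_retained`.
#' @export
behavioural_tests <- function(table, exclusion_threshold = 0.75,
                              contrasts = NULL) {
  if (is.null(contrasts))
    contrasts <- list(c("taxonomic", "thematic_strong"),
                      c("taxonomic", "thematic_weak"),
                      c("thematic_strong", "thematic_weak"))
  tb <- as.data.frame(table)
  overall <- tapply(tb$accuracy * tb$n_catch, tb$participant, sum) /
    tapply(tb$n_catch, tb$participant, sum)
  excluded <- as.numeric(names(overall))[overall < exclusion_threshold]
  tb <- tb[!tb$participant %in% excluded, ]
  n <- length(unique(tb$participant))
  if (n < 3) stop("fewer than 3 participants retained after exclusion")
  rows <- list()
  for (measure in c("rt_ms", "accuracy")) {
    for (ct in contrasts) {
      a <- tb[tb$condition == ct[1], ]
      b <- tb[tb$condition == ct[2], ]
      a <- a[order(a$participant), ]; b <- b[order(b$participant), ]
      d <- a[[measure]] - b[[measure]]
      m <- mean(d); s <- stats::sd(d)
      tval <- if (s <= 0) 0 else m / (s / sqrt(n))
      pval <- if (s <= 0 && m == 0) 1 else 2 * stats::pt(-abs(tval), n - 1)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = ifelse(measure == "rt_ms", "reaction_time", measure),
        contrast = paste(ct, collapse = " vs "),
        t = tval, df = n - 1, p = pval)
    }
  }
  structure(list(tests = do.call(rbind, rows), excluded = excluded,
                 n_retained = n),
            class = "behavioural_report")
}

#' Write tile test results and masks as TSV
#' @param result a `tile_test`.
#' @param contour optional `stat_contour_mask`.
#' @param path output TSV.
#' @export
write_tile_test_tsv <- function(result, contour = NULL, path) {
  df <- expand.grid(time_ms = result$tile_times %||% seq_len(nrow(result$t_diff)),
                    freq_hz = result$tile_freqs %||% seq_len(ncol(result$t_diff)))
  df$t_diff <- as.vector(result$t_diff)
  df$p_diff <- as.vector(result$p_diff)
  df$p_baseA <- as.vector(result$p_baseA)
  df$p_baseB <- as.vector(result$p_baseB)
  if (!is.null(contour)) {
    df$retained <- as.vector(contour$retained)
    df$cluster_id <- as.vector(contour$labels)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
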