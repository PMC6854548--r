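#' Pipeline configuration
#'
#' Collects the analysis settings binding the stages together: the
#' simulation config (or epochs source), analysis windows and bands, POI
#' coordinates, and statistical thresholds. Defaults mirror the two-phase
#' design: coarse whole-brain localisation (four bands x three 200 ms
#' active windows against the -700..-500 ms passive window), then
#' fine-grained time-frequency contrasts at named points of interest.
#'
#' @param sim a `sim_config` (used when epochs are simulated on demand).
#' @param bands list of length-2 Hz bands (default 5-15, 15-25, 25-35,
#'   35-50).
#' @param active_windows list of length-2 ms windows (default 0-200,
#'   200-400, 400-600).
#' @param passive_window length-2 ms (default -700..-500).
#' @param pois named list of 3-vectors, metres, head frame. The default
#'   names mirror the anterior/posterior temporal, parietal and frontal
#'   sites of interest; coordinates are synthetic head-frame positions.
#' @param alpha_map whole-brain max-statistic tail (default .05).
#' @param n_permutations permutations for the whole-brain null.
#' @param alpha_diff,alpha_base dual-criteria thresholds.
#' @param p_adjust_method multiplicity adjustment applied to the tile
#'   difference p-values within each analysis (see [dual_criteria_mask()]).
#' @param cluster_alpha,n_analyses cluster-extent level and Bonferroni
#'   divisor.
#' @param connectivity 4 or 8.
#' @param n_cluster_sims Monte-Carlo draws for the cluster-extent null.
#' @param lambda_rel beamformer diagonal loading.
#' @param contrast_conditions list of condition pairs contrasted at POIs.
#' @param seed master analysis seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            bands = list(c(5, 15), c(15, 25), c(25, 35),
                                         c(35, 50)),
                            active_windows = list(c(0, 200), c(200, 400),
                                                  c(400, 600)),
                            passive_window = c(-700, -500),
                            pois = list(aSTG = c(-0.045, 0.035, -0.030),
                                        pMTG = c(-0.055, -0.040, 0.000),
                                        AG = c(-0.045, -0.055, 0.035),
                                        IFG = c(-0.045, 0.040, 0.005)),
                            alpha_map = 0.05, n_permutations = 10000,
                            alpha_diff = 0.05, alpha_base = 0.01,
                            p_adjust_method = "holm",
                            cluster_alpha = 0.05, n_analyses = 12,
                            connectivity = 4, n_cluster_sims = 10000,
                            lambda_rel = 0.05,
                            contrast_conditions = list(
                              c("taxonomic", "thematic_strong"),
                              c("taxonomic", "thematic_weak"),
                              c("thematic_strong", "thematic_weak")),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Whole-brain localisation phase
#'
#' For each participant, band and active window: estimates the passive
#' (noise) covariance and the active covariance, scans the lattice with
#' LCMV beamformers, and forms Neural Activity Index maps; then contrasts
#' active vs passive maps across participants with a paired t map
#' thresholded by the permutation maximum statistic. Related conditions are
#' pooled (the unrelated condition is excluded).
#'
#' @param config a `pipeline_config`.
#' @param epochs_list optional list of `epochs_set` (one per participant);
#'   simulated from `config$sim` with `effects` when omitted.
#' @param effects ground-truth effects passed to the simulator.
#' @param lattice a `source_lattice`; a coarse default is built when
#'   omitted.
#' @param bands,active_windows optional subsets of the configured bands and
#'   windows to run.
#' @param out_dir optional directory for TSV outputs.
#' @return list of class `wholebrain_result`: per band x window, the t map,
#'   permutation null and surviving points; plus the lattice and a log.
#' @export
run_wholebrain <- function(config, epochs_list = NULL, effects = list(),
                           lattice = NULL, bands = NULL,
                           active_windows = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))
  if (is.null(epochs_list)) {
    say("INFO simulating ", config$sim$n_participants, " participants, seed ",
        config$sim$seed)
    epochs_list <- simulate_epochs(config$sim, effects)$epochs
  }
  if (is.null(lattice))
    lattice <- source_lattice(config$sim$head, spacing = 0.02)
  bands <- bands %||% config$bands
  active_windows <- active_windows %||% config$active_windows
  related <- setdiff(config$sim$conditions, "unrelated")
  head <- config$sim$head
  sensors <- epochs_list[[1]]$sensors
  LF <- lead_field(head, lattice, sensors)
  results <- list()
  for (band in bands) {
    for (win in active_windows) {
      key <- sprintf("band_%g_%g_win_%g_%g", band[1], band[2], win[1], win[2])
      say("INFO contrast ", key)
      act <- list(); pas <- list()
      for (p in seq_along(epochs_list)) {
        ep <- epochs_list[[p]]
        noise_cov <- estimate_covariance(ep, config$passive_window, band,
                                         conditions = related)
        act[[p]] <- nai_volume(ep, LF, band, win, noise_cov,
                               config$lambda_rel, conditions = related)
        pas[[p]] <- nai_volume(ep, LF, band, config$passive_window,
                               noise_cov, config$lambda_rel,
                               conditions = related)
      }
      pt <- permutation_threshold(act, pas,
                                  n_permutations = config$n_permutations,
                                  quantile = 1 - config$alpha_map,
                                  seed = child_seed(config$seed, key))
      results[[key]] <- list(band = band, window = win, null = pt,
                             n_suprathreshold = sum(pt$survivors))
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_volume_tsv(pt$t_map$t, lattice,
                         file.path(out_dir, paste0("tmap_", key, ".tsv")))
        write_null_tsv(pt, file.path(out_dir, paste0("null_", key, ".tsv")))
      }
    }
  }
  structure(list(results = results, lattice = lattice, log = log,
                 seed = config$seed),
            class = "wholebrain_result")
}

#' Point-of-interest time-frequency phase
#'
#' Reconstructs the virtual electrode at a named POI with condition-specific
#' beamformer weights, computes baseline-normalised evoked (or total) power
#' per participant and condition, resamples to 25 ms x 2 Hz tiles, and runs
#' the configured condition contrasts with dual significance criteria and
#' Monte-Carlo cluster-extent correction at the observed fill rate.
#'
#' @param config a `pipeline_config`.
#' @param poi_name name of a POI in `config$pois`.
#' @param epochs_list optional list of `epochs_set`; simulated when omitted.
#' @param effects ground-truth effects for the simulator.
#' @param mode `"evoked"` (default) or `"total"` power.
#' @param weight_window ms window for the beamformer covariance (default
#'   0..600 ms, the post-stimulus period).
#' @param weight_band Hz band for the beamformer covariance (default 5-50).
#' @param out_dir optional directory for TSV outputs.
#' @return list of class `poi_result`: per contrast, the `tile_test`,
#'   dual-criteria mask, fill rate, cluster null, `k_min` and the
#'   `stat_contour_mask`; plus per-condition mean tile grids.
#' @export
run_poi <- function(config, poi_name, epochs_list = NULL, effects = list(),
                    mode = c("evoked", "total"),
                    weight_window = c(0, 600), weight_band = c(5, 50),
                    out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  mode <- match.arg(mode)
  if (!poi_name %in% names(config$pois))
    stop("unknown POI '", poi_name, "'; configured: ",
         paste(names(config$pois), collapse = ", "))
  poi <- config$pois[[poi_name]]
  head <- config$sim$head
  if (sqrt(sum((poi - head$center)^2)) >= head$radius)
    stop("POI '", poi_name, "' lies outside the head sphere")
  if (is.null(epochs_list))
    epochs_list <- simulate_epochs(config$sim, effects)$epochs
  conds <- unique(unlist(config$contrast_conditions))
  missing <- setdiff(conds, unique(epochs_list[[1]]$labels))
  if (length(missing))
    stop("condition(s) missing from the data: ",
         paste(missing, collapse = ", "))
  sensors <- epochs_list[[1]]$sensors
  Lp <- point_lead_field(head, poi, sensors)
  # per participant x condition tile grids; percent signal change uses a
  # baseline pooled across the conditions entering the analysis, so all
  # conditions of a participant share one denominator per frequency bin and
  # baseline noise cancels from condition differences
  grids <- list()
  for (p in seq_along(epochs_list)) {
    ep <- epochs_list[[p]]
    raw <- list()
    for (cond in conds) {
      noise_cov <- estimate_covariance(ep, config$passive_window,
                                       weight_band, conditions = cond)
      Ca <- estimate_covariance(ep, weight_window, weight_band,
                                conditions = cond)
      Creg <- regularize_covariance(Ca, noise_cov, config$lambda_rel)
      flt <- lcmv_weights(Lp, Creg)
      ve <- virtual_electrode(flt, ep, conditions = cond)
      raw[[cond]] <- if (mode == "evoked") evoked_power(ve)
                     else total_power(ve)
    }
    pooled_base <- Reduce(`+`, lapply(raw, baseline_levels,
                                      baseline = config$passive_window)) /
      length(raw)
    for (cond in conds) {
      pw <- baseline_normalize(raw[[cond]], config$passive_window,
                               baseline_power = pooled_base)
      grids[[cond]][[p]] <- resample_tiles(
        pw, t_range = config$sim$epoch_window)
    }
  }
  cond_means <- lapply(grids, function(gl) {
    Reduce(`+`, lapply(gl, function(g) g$values)) / length(gl)
  })
  contrasts <- list()
  for (ct in config$contrast_conditions) {
    key <- paste(ct, collapse = "_vs_")
    tt <- tile_condition_test(grids[[ct[1]]], grids[[ct[2]]])
    mask <- dual_criteria_mask(tt, config$alpha_diff, config$alpha_base,
                               config$p_adjust_method)
    # fill rate counts tiles showing a significant between-condition
    # difference (criterion a alone), the quantity the cluster-extent null
    # is parameterised by
    fill <- mean(attr(mask, "p_diff_adjusted") < config$alpha_diff)
    cl <- label_clusters(mask, config$connectivity)
    if (fill > 0) {
      nul <- cluster_null(dim(mask), fill, config$connectivity,
                          config$n_cluster_sims,
                          seed = child_seed(config$seed, key))
      k_min <- min_cluster_size(nul, config$cluster_alpha, config$n_analyses)
    } else {
      nul <- NULL
      k_min <- 1L
    }
    contour <- apply_cluster_threshold(mask, cl, k_min)
    contrasts[[key]] <- list(conditions = ct, test = tt, mask = mask,
                             fill_rate = fill, cluster_null = nul,
                             k_min = k_min, contour = contour)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_tile_test_tsv(tt, contour,
                          file.path(out_dir,
                                    paste0("tiles_", poi_name, "_", key,
                                           ".tsv")))
    }
  }
  structure(list(poi = poi_name, location = poi, mode = mode,
                 contrasts = contrasts, condition_means = cond_means,
                 seed = config$seed),
            class = "poi_result")
}

#' Plot a POI contrast in the difference / condition A / condition B layout
#'
#' Writes a PNG with three panels: the condition difference with the
#' retained statistical contours, and the two condition maps.
#'
#' @param poi_result a `poi_result`.
#' @param contrast name of a contrast in the result.
#' @param path output PNG path.
#' @export
plot_poi_contrast <- function(poi_result, contrast, path) {
  ct <- poi_result$contrasts[[contrast]]
  if (is.null(ct)) stop("unknown contrast '", contrast, "'")
  tt <- ct$test
  grDevices::png(path, width = 1500, height = 500)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  panel <- function(z, main) {
    graphics::image(tt$tile_times, tt$tile_freqs, z,
                    xlab = "time (ms)", ylab = "frequency (Hz)", main = main,
                    col = grDevices::hcl.colors(64, "RdBu", rev = TRUE))
  }
  panel(tt$diff_mean, paste0(contrast, " (difference)"))
  if (any(ct$contour$retained))
    graphics::contour(tt$tile_times, tt$tile_freqs,
                      ct$contour$retained * 1, levels = 0.5, add = TRUE,
                      drawlabels = FALSE, lwd = 2)
  a <- poi_result$condition_means[[ct$conditions[1]]]
  b <- poi_result$condition_means[[ct$conditions[2]]]
  panel(a, ct$conditions[1])
  panel(b, ct$conditions[2])
  invisible(path)
}

#' Write an epochs set to a plain-text layout
#'
#' A directory with `meta.yaml` (sampling rate, participant, labels, catch
#' flags, time axis, sensor geometry) and `data.tsv` (columns trial,
#' channel, sample, value, with values printed at full double precision so
#' the round trip is lossless).
#'
#' @param epochs an `epochs_set`.
#' @param path directory to create.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epochs_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(sampling_rate = epochs$sampling_rate,
               participant = epochs$participant,
               labels = as.list(epochs$labels),
               is_catch = as.list(epochs$is_catch),
               times = as.list(format(epochs$times, digits = 17)),
               n_trials = dim(epochs$data)[1],
               n_channels = dim(epochs$data)[2],
               n_samples = dim(epochs$data)[3])
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  write_geometry_yaml(epochs$sensors, file.path(path, "sensors.yaml"))
  idx <- expand.grid(sample = seq_len(dim(epochs$data)[3]),
                     channel = seq_len(dim(epochs$data)[2]),
                     trial = seq_len(dim(epochs$data)[1]))
  df <- data.frame(trial = idx$trial, channel = idx$channel,
                   sample = idx$sample,
                   value = as.vector(formatC(aperm(epochs$data, c(3, 2, 1)),
                                             format = "g", digits = 17)))
  utils::write.table(df, file.path(path, "data.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an epochs set written by [write_epochs()]
#' @param path directory containing `meta.yaml`, `sensors.yaml`, `data.tsv`.
#' @return an `epochs_set`.
#' @export
read_epochs <- function(path) {
  meta_path <- file.path(path, "meta.yaml")
  if (!file.exists(meta_path)) stop("missing meta.yaml in ", path)
  meta <- yaml::read_yaml(meta_path)
  for (field in c("sampling_rate", "labels", "times", "n_trials",
                  "n_channels", "n_samples"))
    if (is.null(meta[[field]])) stop("meta.yaml missing field '", field, "'")
  if (!file.exists(file.path(path, "data.tsv")))
    stop("missing data.tsv in ", path)
  df <- utils::read.table(file.path(path, "data.tsv"), header = TRUE,
                          sep = "\t")
  dat <- array(0, dim = c(meta$n_trials, meta$n_channels, meta$n_samples))
  dat[cbind(df$trial, df$channel, df$sample)] <- df$value
  sensors <- read_geometry_yaml(file.path(path, "sensors.yaml"))
  structure(list(data = dat,
                 times = as.numeric(unlist(meta$times)),
                 labels = unlist(meta$labels),
                 is_catch = as.logical(unlist(meta$is_catch)),
                 participant = meta$participant,
                 sensors = sensors,
                 sampling_rate = meta$sampling_rate),
            class = "epochs_set")
}
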