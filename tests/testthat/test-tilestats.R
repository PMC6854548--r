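test_that("tile condition tests match hand arithmetic", {
  # 3 participants, one tile, A - B = (1, 2, 3): t = 2*sqrt(3) = 3.4641
  A <- list(matrix(1), matrix(2), matrix(3))
  B <- list(matrix(0), matrix(0), matrix(0))
  tt <- tile_condition_test(A, B)
  expect_equal(as.numeric(tt$t_diff), 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(tt$df, 2)

  # identical grids: t = 0, p = 1 at every tile
  G <- lapply(1:4, function(i) matrix(rnorm(6), 2, 3))
  t0 <- tile_condition_test(G, G)
  expect_true(all(t0$t_diff == 0))
  expect_true(all(t0$p_diff == 1))

  # permuting participant order leaves all statistics unchanged
  A2 <- lapply(1:5, function(i) matrix(rnorm(4), 2, 2))
  B2 <- lapply(1:5, function(i) matrix(rnorm(4), 2, 2))
  r1 <- tile_condition_test(A2, B2)
  ord <- c(3, 1, 5, 2, 4)
  r2 <- tile_condition_test(A2[ord], B2[ord])
  expect_equal(r1$t_diff, r2$t_diff, tolerance = 1e-12)
  expect_equal(r1$p_baseA, r2$p_baseA, tolerance = 1e-12)

  expect_error(tile_condition_test(A2[1:2], B2[1:2]), "3 participants")
  expect_error(
    tile_condition_test(A2, lapply(1:5, function(i) matrix(0, 3, 3))),
    "shape")
})

test_that("dual criteria apply strict thresholds jointly", {
  p_diff <- matrix(c(0.04, 0.04, 0.05, 0.2), 2, 2)
  p_baseA <- matrix(c(0.5, 0.005, 0.001, 0.001), 2, 2)
  p_baseB <- matrix(0.5, 2, 2)
  tt <- make_tile_test(p_diff, p_baseA, p_baseB)
  m <- dual_criteria_mask(tt, p_adjust_method = "none")
  # p_diff .04 but both baselines weak: excluded
  expect_false(m[1, 1])
  # p_diff .04 and baseline .005: included
  expect_true(m[2, 1])
  # p_diff exactly .05: excluded by the strict inequality
  expect_false(m[1, 2])
  expect_false(m[2, 2])
  expect_error(dual_criteria_mask(tt, alpha_diff = 1.5), "alpha")

  # the default multiplicity adjustment is at least as conservative as the
  # raw thresholds, and its adjusted p-values are exposed
  m_adj <- dual_criteria_mask(tt)
  expect_true(all(m_adj <= m))
  expect_equal(attr(m_adj, "p_diff_adjusted"),
               matrix(p.adjust(p_diff, "holm"), 2, 2))
  # a strong isolated difference still passes after adjustment
  tt2 <- make_tile_test(matrix(c(1e-6, 0.6, 0.7, 0.8), 2, 2),
                        matrix(0.001, 2, 2), matrix(0.5, 2, 2))
  expect_true(dual_criteria_mask(tt2)[1, 1])
})

test_that("cluster labelling matches a brute-force flood fill", {
  # a 1 x 6 run is one cluster of size 6
  run <- matrix(TRUE, 1, 6)
  cl <- label_clusters(run, 4)
  expect_equal(cl$sizes, 6L)
  expect_true(all(cl$labels == 1L))

  # diagonal touching: split under 4-connectivity, joined under 8
  diagm <- matrix(FALSE, 2, 2); diagm[1, 1] <- diagm[2, 2] <- TRUE
  expect_equal(sort(label_clusters(diagm, 4)$sizes), c(1L, 1L))
  expect_equal(label_clusters(diagm, 8)$sizes, 2L)

  # 50 random 8x8 masks against the recursive flood-fill oracle
  set.seed(19)
  for (r in 1:50) {
    mask <- matrix(runif(64) < runif(1, 0.1, 0.6), 8, 8)
    for (conn in c(4, 8)) {
      got <- label_clusters(mask, conn)
      want <- oracle_flood_fill(mask, conn)
      # same partition: labels must be a relabelling of each other
      expect_equal(got$labels > 0, want > 0)
      if (max(want) > 0) {
        expect_equal(max(got$labels), max(want))
        expect_equal(sort(got$sizes), sort(tabulate(want[want > 0])))
        # ids ordered by first (column-major) tile index
        firsts <- vapply(seq_len(max(got$labels)),
                         function(id) min(which(got$labels == id)), 1L)
        expect_true(all(diff(firsts) > 0))
      }
    }
  }
  expect_error(label_clusters(run, 6), "connectivity")
})

test_that("cluster-extent null matches exact enumeration", {
  # degenerate fills
  n0 <- cluster_null(c(4, 4), 0, 4, n_simulations = 200, seed = 1)
  expect_true(all(n0$max_sizes == 0))
  n1 <- cluster_null(c(3, 3), 1, 4, n_simulations = 200, seed = 1)
  expect_true(all(n1$max_sizes == 9))

  # 2 x 2 grid with 2 filled tiles: P(max = 2) = 4/6 under 4-connectivity
  n2 <- cluster_null(c(2, 2), 0.5, 4, n_simulations = 4000, seed = 2)
  p2 <- mean(n2$max_sizes == 2)
  ci <- qbinom(c(0.005, 0.995), 4000, 4 / 6) / 4000
  expect_gte(p2, ci[1]); expect_lte(p2, ci[2])

  # all grids up to 3 x 3, every fill count, both connectivities:
  # Monte-Carlo distribution inside the 99% binomial envelope of the exact
  # enumeration
  for (shape in list(c(2, 2), c(2, 3), c(3, 3))) {
    nt <- prod(shape)
    for (k in 1:nt) {
      for (conn in c(4, 8)) {
        exact <- oracle_max_cluster_exact(shape, k, conn)
        mc <- cluster_null(shape, k / nt, conn, n_simulations = 800,
                           seed = 100 + k)
        for (sz in names(exact)) {
          phat <- mean(mc$max_sizes == as.integer(sz))
          env <- qbinom(c(0.005, 0.995), 800, as.numeric(exact[sz])) / 800
          expect_gte(phat, env[1]); expect_lte(phat, env[2])
        }
      }
    }
  }
})

test_that("minimum cluster size scans the tail correctly", {
  # a null that never produces any cluster: k = 1
  n0 <- cluster_null(c(4, 4), 0, 4, n_simulations = 200, seed = 1)
  expect_equal(min_cluster_size(n0, alpha = 0.05, n_analyses = 1), 1L)

  # distribution concentrated at max = 10: k = 11 for small alpha
  fake <- structure(list(max_sizes = rep(10L, 500)), class = "cluster_null")
  expect_equal(min_cluster_size(fake, alpha = 0.01, n_analyses = 1), 11L)

  # non-decreasing in fill rate, non-increasing in alpha (reduced scale)
  ks <- vapply(c(0.01, 0.05, 0.075, 0.15), function(fr) {
    min_cluster_size(cluster_null(c(20, 12), fr, 4, 600, seed = 5))
  }, 1L)
  expect_true(all(diff(ks) >= 0))
  nul <- cluster_null(c(20, 12), 0.075, 4, 600, seed = 6)
  k_small_alpha <- min_cluster_size(nul, alpha = 0.01)
  k_big_alpha <- min_cluster_size(nul, alpha = 0.2)
  expect_gte(k_small_alpha, k_big_alpha)
})

test_that("cluster-extent thresholding retains exactly the big clusters", {
  mask <- matrix(FALSE, 5, 5)
  mask[1, 1:4] <- TRUE          # size 4
  mask[3:4, 1] <- TRUE          # size 2
  mask[5, 5] <- TRUE            # size 1
  cl <- label_clusters(mask, 4)
  # all clusters >= k_min: identity
  all_in <- apply_cluster_threshold(mask, cl, 1)
  expect_equal(all_in$retained, mask)
  # single cluster of size k_min - 1 goes to the dashed set
  res <- apply_cluster_threshold(mask, cl, 3)
  expect_equal(sum(res$retained), 4)
  expect_equal(sum(res$dashed), 3)
  expect_true(all(res$retained[1, 1:4]))

  # random masks: retained set equals the brute-force filter of components
  set.seed(23)
  for (r in 1:20) {
    m <- matrix(runif(48) < 0.4, 6, 8)
    cl <- label_clusters(m, 8)
    k <- sample(1:5, 1)
    got <- apply_cluster_threshold(m, cl, k)
    want <- oracle_flood_fill(m, 8)
    keep <- which(tabulate(want[want > 0]) >= k)
    expect_equal(got$retained, matrix(want %in% keep & m, 6, 8))
  }
})

test_that("behavioural tests apply the exclusion rule and df contract", {
  means <- data.frame(
    condition = c("taxonomic", "thematic_strong", "thematic_weak"),
    rt_ms = c(980, 930, 995), accuracy = c(0.88, 0.96, 0.86))
  tb <- simulate_behaviour(20, means,
                           sd_between = list(rt_ms = 50, accuracy = 0.02),
                           sd_within = list(rt_ms = 25, accuracy = 0.02),
                           seed = 8)
  # force participant 20 below the accuracy cut-off
  tb$accuracy[tb$participant == 20] <- 0.5
  rep <- behavioural_tests(tb)
  expect_equal(rep$excluded, 20)
  expect_equal(rep$n_retained, 19)
  expect_true(all(rep$tests$df == 18))
  expect_equal(nrow(rep$tests), 6)  # 3 contrasts x 2 measures

  # boundary: accuracy exactly at the threshold is retained
  tb2 <- tb[tb$participant <= 4, ]
  tb2$accuracy <- 0.9
  tb2$accuracy[tb2$participant == 1] <- 0.74
  tb2$accuracy[tb2$participant == 2] <- 0.75
  rep2 <- behavioural_tests(tb2)
  expect_equal(rep2$excluded, 1)
  expect_equal(rep2$n_retained, 3)

  # identical condition columns: t = 0, p = 1
  tb3 <- tb[tb$participant <= 5, ]
  for (p in 1:5) {
    tb3$rt_ms[tb3$participant == p] <- 900 + p
    tb3$accuracy[tb3$participant == p] <- 0.9
  }
  rep3 <- behavioural_tests(tb3)
  expect_true(all(rep3$tests$t == 0))
  expect_true(all(rep3$tests$p == 1))

  # everyone excluded is an error
  tb4 <- tb; tb4$accuracy <- 0.1
  expect_error(behavioural_tests(tb4), "participants")
})
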