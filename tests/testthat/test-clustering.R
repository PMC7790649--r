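make_blobs <- function(n_per, centers, sd = 0.1, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_per * ncol(centers), mean = rep(centers[i, ], each = n_per),
                 sd = sd), n_per)))
  rownames(x) <- sprintf("b%03d", seq_len(nrow(x)))
  x
}

test_that("k equal to the number of distinct points gives zero within-SS", {
  x <- matrix(c(0, 0, 1, 1, 2, 2, 3, 3), 4, byrow = TRUE)
  rownames(x) <- paste0("t", 1:4)
  p <- best_kmeans(x, 4, n_restarts = 5, seed = 1)
  expect_equal(p$tot_withinss, 0)
  expect_equal(sort(unname(p$size)), rep(1L, 4))
})

test_that("well-separated blobs are recovered and runs are seed-deterministic", {
  x <- make_blobs(15, rbind(c(0, 0), c(5, 5)))
  p1 <- best_kmeans(x, 2, n_restarts = 20, seed = 42)
  truth <- rep(1:2, each = 15)
  agree <- max(mean(p1$cluster == truth), mean(p1$cluster == 3 - truth))
  expect_equal(agree, 1)
  p2 <- best_kmeans(x, 2, n_restarts = 20, seed = 42)
  expect_identical(p1$cluster, p2$cluster)
  expect_identical(p1$centers, p2$centers)
})

test_that("within-SS is non-increasing in the number of nested restarts", {
  x <- make_blobs(8, rbind(c(0, 0), c(2, 0), c(0, 2), c(3, 3)), sd = 0.8)
  wss <- vapply(c(1, 5, 20, 80), function(r)
    best_kmeans(x, 4, n_restarts = r, seed = 9)$tot_withinss, 0)
  expect_true(all(diff(wss) <= 1e-12))
})

test_that("SSI matches an independently coded direct-formula oracle", {
  set.seed(7)
  for (r in 1:25) {
    n <- sample(6:10, 1); p <- sample(2:5, 1); k <- sample(2:3, 1)
    x <- matrix(rnorm(n * p), n)
    km <- suppressWarnings(stats::kmeans(x, k, nstart = 5))
    expect_equal(ssi_score(km$centers, km$size),
                 ssi_oracle(km$centers, km$size), tolerance = 1e-12)
  }
})

test_that("SSI agrees with the reference implementation in vegan", {
  skip_if_not_installed("vegan")
  set.seed(17)
  for (r in 1:10) {
    x <- matrix(rnorm(40 * 4), 40)
    km <- suppressWarnings(stats::kmeans(x, 3, nstart = 5))
    expect_equal(ssi_score(km$centers, km$size),
                 unname(vegan::cIndexKM(km, x, index = "ssi")),
                 tolerance = 1e-12)
  }
})

test_that("SSI is invariant to cluster relabeling and to duplicating trees", {
  set.seed(2)
  centers <- matrix(rnorm(8), 4)
  sizes <- c(5, 9, 3, 7)
  s0 <- ssi_score(centers, sizes)
  perm <- c(3, 1, 4, 2)
  expect_equal(ssi_score(centers[perm, ], sizes[perm]), s0)
  expect_equal(ssi_score(centers, 2L * sizes), s0)
  expect_error(ssi_score(centers[1, , drop = FALSE], sizes[1]), "2 clusters")
})

test_that("separated centers score higher than pulled-together centers", {
  x <- make_blobs(10, rbind(c(-3, 0), c(3, 0)), sd = 0.2, seed = 4)
  far <- best_kmeans(x, 2, n_restarts = 10, seed = 1)
  near_centers <- far$centers * 0.2
  expect_gt(ssi_score(far$centers, far$size),
            ssi_score(near_centers, far$size))
})

test_that("pattern-count selection honours the range and flags null data", {
  x <- make_blobs(12, rbind(c(0, 0), c(4, 0), c(0, 4)), sd = 0.15)
  sel <- select_pattern_count(x, 2:6, n_restarts = 30, seed = 1)
  expect_equal(sel$k_best, 3L)
  expect_false(sel$low_confidence)
  one <- select_pattern_count(x, 4L, n_restarts = 10, seed = 1)
  expect_equal(one$k_best, 4L)
  expect_error(select_pattern_count(x, integer()), "empty")
  expect_error(select_pattern_count(x, 1:3), "within")
  set.seed(31)
  null_x <- matrix(rnorm(80 * 5), 80)
  rownames(null_x) <- paste0("n", 1:80)
  expect_true(select_pattern_count(null_x, 2:8, n_restarts = 30,
                                   seed = 2)$low_confidence)
})

test_that("shape rules label canonical centers as defined", {
  S <- 20
  flat_low <- rep(0.4, S) + c(0.01, rep(0, S - 1))
  expect_equal(classify_center_shape(flat_low)$shape, "linear")
  rising <- seq(0.2, 1.6, length.out = S)
  expect_equal(classify_center_shape(rising)$shape, "ascending")
  mid_peak <- c(rep(0.3, 9), seq(0.4, 1.5, length.out = 3),
                seq(1.4, 0.5, length.out = 8))
  expect_equal(classify_center_shape(mid_peak)$shape, "sine")
  early_peak <- c(seq(0.8, 1.5, length.out = 4),
                  seq(1.45, 0.4, length.out = 16))
  expect_equal(classify_center_shape(early_peak)$shape, "bell")
})

test_that("the nine archetype templates are named as themselves", {
  # build the generative partition directly: one cluster per template,
  # centers = mean zero-noise profiles over each birth window
  cfg <- sim_config(noise_sigma = 0)
  tm <- pattern_templates()
  centers <- t(vapply(seq_len(nrow(tm)), function(i) {
    births <- c(tm$birth_min[i],
                (tm$birth_min[i] + tm$birth_max[i]) %/% 2, tm$birth_max[i])
    colMeans(do.call(rbind, lapply(births, function(b)
      segment_series(simulate_ring_series(tm[i, ], b, config = cfg,
                                          seed = 1)$series)$means)))
  }, numeric(20)))
  part <- structure(
    list(k = 9L,
         cluster = stats::setNames(seq_len(9L), tm$name),
         centers = NULL, centers_raw = centers,
         size = rep(3L, 9L), labels = NULL),
    class = "pattern_partition")
  part <- name_patterns(part)
  expect_equal(part$labels$pattern, tm$name)
  expect_false(any(part$labels$ambiguous))
})

test_that("k-means input validation", {
  x <- make_blobs(5, rbind(c(0, 0), c(3, 3)))
  expect_error(best_kmeans(x, 11, n_restarts = 5, seed = 1), "between")
  expect_error(name_patterns(best_kmeans(x, 2, n_restarts = 5, seed = 1)),
               "raw-scale centers")
})
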