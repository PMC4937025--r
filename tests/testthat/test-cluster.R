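test_that("the 5 mm connection radius at 3 mm voxels gives 18-connectivity", {
  off <- neighbor_offsets(c(3, 3, 3), 5)
  expect_equal(nrow(off), 18)               # 6 faces + 12 edges, no corners
  d <- sqrt(rowSums((off * 3)^2))
  expect_true(all(d <= 5))
  off3 <- neighbor_offsets(c(3, 3, 3), 3)
  expect_equal(nrow(off3), 6)               # faces only
  expect_error(neighbor_offsets(c(3, 3, 3), 2.9), "no neighbors")
})

test_that("cluster labeling matches hand-worked geometries", {
  g <- tiny_grid(c(5, 5, 5))
  m <- full_mask(g)
  s <- array(0, dim = c(5, 5, 5))
  expect_equal(nrow(label_clusters(scalar_map(s, g, "tstat"), m, 1, 5)), 0)
  # two voxels sharing an edge (offset (1,1,0), ~4.24 mm): one cluster at
  # radius 5, two singletons at radius 3
  s[2, 2, 2] <- 3; s[3, 3, 2] <- 4
  sm <- scalar_map(s, g, "tstat")
  t5 <- label_clusters(sm, m, 1, 5)
  expect_equal(t5$n_voxels, 2)
  expect_equal(t5$peak_stat, 4)
  t3 <- label_clusters(sm, m, 1, 3)
  expect_equal(t3$n_voxels, c(1, 1))
  # a 7-voxel cross is one cluster with its peak reported in mm
  s <- array(0, dim = c(5, 5, 5))
  s[3, 3, 3] <- 5
  s[c(2, 4), 3, 3] <- 2; s[3, c(2, 4), 3] <- 2; s[3, 3, c(2, 4)] <- 2
  tc <- label_clusters(scalar_map(s, g, "tstat"), m, 1, 5)
  expect_equal(nrow(tc), 1)
  expect_equal(tc$n_voxels, 7)
  expect_equal(tc$peak_stat, 5)
  expect_equal(c(tc$peak_x, tc$peak_y, tc$peak_z), c(voxel_to_mm(g, c(2, 2, 2))))
})

test_that("negative and two-sided labeling threshold the expected tails", {
  g <- tiny_grid(c(4, 4, 1))
  m <- full_mask(g)
  s <- array(0, dim = c(4, 4, 1)); s[1, 1, 1] <- -3; s[4, 4, 1] <- 3
  sm <- scalar_map(s, g, "tstat")
  expect_equal(nrow(label_clusters(sm, m, 2, 5, "positive")), 1)
  tn <- label_clusters(sm, m, 2, 5, "negative")
  expect_equal(tn$peak_stat, -3)
  expect_equal(nrow(label_clusters(sm, m, 2, 5, "two_sided")), 2)
})

test_that("labeling agrees with an independent union-find oracle on random maps", {
  skip_if_not_installed("igraph")
  set.seed(33)
  for (rep in 1:12) {
    dims <- c(sample(4:7, 1), sample(4:7, 1), sample(4:7, 1))
    g <- tiny_grid(dims)
    s <- array(rnorm(prod(dims)), dim = dims)
    m <- binary_mask(array(runif(prod(dims)) > 0.2, dims), g)
    radius <- sample(c(3, 5, 6), 1)
    got <- label_clusters(scalar_map(s, g, "tstat"), m, 0.8, radius)
    expect_identical(sort(got$n_voxels, decreasing = TRUE),
                     brute_clusters(scalar_map(s, g, "tstat"), m, 0.8, radius))
  }
})

test_that("the Monte-Carlo threshold honours its own null distribution and seed", {
  g <- tiny_grid(c(10, 10, 10))
  m <- full_mask(g)
  mc <- estimate_cluster_threshold(m, 0.01, 0.01, n_sims = 300, fwhm_mm = 0,
                                   seed = 9)
  expect_lte(mean(mc$null_max_cluster_sizes >= mc$min_cluster_size), 0.01)
  expect_gt(mean(mc$null_max_cluster_sizes >= mc$min_cluster_size - 1), 0.01)
  mc2 <- estimate_cluster_threshold(m, 0.01, 0.01, n_sims = 300, fwhm_mm = 0,
                                    seed = 9)
  expect_identical(mc$null_max_cluster_sizes, mc2$null_max_cluster_sizes)
  expect_warning(
    estimate_cluster_threshold(m, 0.01, 0.001, n_sims = 300, fwhm_mm = 0,
                               seed = 9),
    "minimum achievable")
})

test_that("independent-voxel null thresholds match a brute-force simulation", {
  # independent oracle: iid Bernoulli suprathreshold fields + igraph
  # components, written apart from the package's labeling/simulation code
  skip_if_not_installed("igraph")
  g <- tiny_grid(c(10, 10, 10))
  m <- full_mask(g)
  mc <- estimate_cluster_threshold(m, 0.01, 0.01, n_sims = 1500, fwhm_mm = 0,
                                   seed = 101)
  set.seed(777)   # separate RNG stream
  off_mm <- 5
  maxes <- integer(1500)
  for (i in seq_len(1500)) {
    z <- array(rnorm(1000), dim = c(10, 10, 10))
    z <- (z - mean(z)) / sd(z)
    sizes <- brute_clusters(scalar_map(z, g, "tstat"), m, qnorm(0.99), off_mm)
    maxes[i] <- if (length(sizes)) sizes[1] else 0L
  }
  k <- 1L
  while (mean(maxes >= k) > 0.01) k <- k + 1L
  expect_equal(mc$min_cluster_size, k)
})

test_that("cluster-extent correction keeps only clusters at or above the minimum", {
  g <- tiny_grid(c(12, 12, 4))
  m <- full_mask(g)
  s <- array(0, dim = c(12, 12, 4))
  s[2:7, 2:5, 2:3] <- 3        # 48-voxel block
  s[10:11, 10, 2] <- 3         # 2-voxel blip
  sm <- scalar_map(s, g, "tstat")
  mc <- list(min_cluster_size = 44L)
  out <- apply_correction(sm, m, 2, mc, 5, "positive")
  expect_equal(nrow(out$clusters), 1)
  expect_equal(out$clusters$n_voxels, 48)
  expect_equal(sum(out$map$data > 0), 48)
  # min 1 reduces to plain thresholding
  out1 <- apply_correction(sm, m, 2, list(min_cluster_size = 1L), 5, "positive")
  expect_equal(sum(out1$clusters$n_voxels), sum(s > 2))
  # everything below the minimum leaves an empty table and zero map
  out0 <- apply_correction(sm, m, 2, list(min_cluster_size = 100L), 5, "positive")
  expect_equal(nrow(out0$clusters), 0)
  expect_true(all(out0$map$data == 0))
})
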