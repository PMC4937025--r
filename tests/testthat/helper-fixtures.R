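# Fixtures are built in code; nothing is stored on disk.

tiny_grid <- function(dims = c(4, 1, 1), voxel = 3, origin = c(0, 0, 0)) {
  volume_grid(dims, voxel_size = rep(voxel, 3), origin = origin)
}

full_mask <- function(grid) {
  binary_mask(array(TRUE, grid$dims), grid)
}

# the 4-voxel worked instance: v1 = v2 = ramp, v3 = reversed ramp,
# v4 = shuffled ramp with r(v1, v4) = 0.8
worked_bold <- function() {
  g <- tiny_grid()
  dat <- array(0, dim = c(4, 1, 1, 5))
  dat[1, 1, 1, ] <- 1:5
  dat[2, 1, 1, ] <- 1:5
  dat[3, 1, 1, ] <- 5:1
  dat[4, 1, 1, ] <- c(1, 3, 2, 5, 4)
  bold_series(dat, g, tr_seconds = 2)
}

random_bold <- function(dims, n_frames, seed) {
  set.seed(seed)
  g <- tiny_grid(dims)
  bold_series(array(rnorm(prod(dims) * n_frames), dim = c(dims, n_frames)),
              g, tr_seconds = 2)
}

# independent all-pairs brute-force degree oracle built on stats::cor
brute_degree <- function(bold, mask, r_threshold, flavor) {
  idx <- which(mask$data)
  d <- dim(bold$data)
  Y <- t(matrix(bold$data, prod(d[1:3]), d[4]))[, idx, drop = FALSE]
  n <- ncol(Y)
  D <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (sd(Y[, i]) == 0 || sd(Y[, j]) == 0) next
      r <- cor(Y[, i], Y[, j])
      if (r > r_threshold) D[i] <- D[i] + if (flavor == "binarized") 1 else r
    }
  }
  D
}

# independent connected-components oracle: pairwise mm distances + igraph
brute_clusters <- function(stat, mask, thr, radius_mm, sign = "positive") {
  supra <- switch(sign,
                  positive = stat$data > thr,
                  negative = stat$data < -thr,
                  two_sided = abs(stat$data) > thr)
  supra <- supra & mask$data
  vox <- which(supra, arr.ind = TRUE)
  if (nrow(vox) == 0) return(integer(0))
  mm <- voxel_to_mm(stat$grid, vox - 1L)
  dd <- as.matrix(dist(mm))
  adj <- dd <= radius_mm & dd > 0
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  sort(as.integer(table(comp$membership)), decreasing = TRUE)
}

# small synthetic cohort for pipeline-level tests
small_cohort <- function(seed = 1, ...) {
  generate_cohort(n_patients = 5, n_controls = 5, n_volumes = 60,
                  seed = seed, ...)
}

small_config <- function(seed = 1) {
  study_config(n_mc_sims = 200, rng_seed = seed)
}
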