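make_stack <- function(mat, grid) {
  # rows of mat = subjects; columns = voxels (full grid, column-major)
  lapply(seq_len(nrow(mat)), function(i)
    scalar_map(array(mat[i, ], dim = grid$dims), grid, "degree_z"))
}

test_that("one-sample t maps match the textbook formula and its symmetries", {
  g <- tiny_grid(c(2, 2, 1))
  m <- full_mask(g)
  mat <- rbind(c(1, 0, 5, -2), c(2, 0, 5, -4), c(3, 0, 5, -6))
  tm <- one_sample_map(make_stack(mat, g), m)
  expect_equal(tm$data[1, 1, 1], 2 * sqrt(3), tolerance = 1e-10)  # {1,2,3}
  expect_equal(tm$data[2, 2, 1], -2 * sqrt(3), tolerance = 1e-10) # {-2,-4,-6}
  expect_equal(tm$data[2, 1, 1], 0)          # zero-variance voxel flagged
  expect_equal(attr(tm, "n_degenerate"), 2)  # the all-0 and all-5 voxels
  expect_equal(attr(tm, "df"), 2)
  # sign flip of every map flips t exactly
  tneg <- one_sample_map(make_stack(-mat, g), m)
  expect_equal(c(tneg$data), -c(tm$data))
})

test_that("the covariate GLM reduces to the pooled two-sample t without covariates", {
  set.seed(19)
  g <- tiny_grid(c(3, 2, 2))
  m <- full_mask(g)
  n1 <- 7; n2 <- 6
  mat <- matrix(rnorm((n1 + n2) * 12), n1 + n2, 12)
  subjects <- tibble::tibble(
    group = rep(c("tinnitus", "control"), c(n1, n2)),
    age = rep(50, n1 + n2), sex = rep("male", n1 + n2),
    education = rep(12, n1 + n2))
  X <- design_matrix(subjects)           # constant covariates drop out
  expect_equal(colnames(X), c("intercept", "group"))
  tm <- two_sample_glm_map(make_stack(mat, g), X, m)
  for (j in 1:12) {
    tt <- t.test(mat[1:n1, j], mat[n1 + (1:n2), j], var.equal = TRUE)
    expect_lt(abs(tm$data[j] - unname(tt$statistic)), 1e-8)
  }
  expect_equal(attr(tm, "df"), n1 + n2 - 2)
})

test_that("the GLM group t matches an independent normal-equations oracle", {
  set.seed(23)
  g <- tiny_grid(c(2, 2, 1))
  m <- full_mask(g)
  subjects <- tibble::tibble(
    group = c("tinnitus", "tinnitus", "tinnitus", "control", "control", "control"),
    age = c(44, 61, 52, 39, 58, 49),
    sex = c("male", "female", "female", "male", "female", "male"),
    education = c(12, 16, 10, 14, 12, 15))
  mat <- matrix(rnorm(24), 6, 4)
  X <- design_matrix(subjects)
  tm <- two_sample_glm_map(make_stack(mat, g), X, m)
  for (j in 1:4) {
    # brute-force pseudoinverse route, computed independently per voxel
    beta <- MASS::ginv(X) %*% mat[, j]
    res <- mat[, j] - X %*% beta
    df <- 6 - qr(X)$rank
    s2 <- sum(res^2) / df
    cov_g <- (MASS::ginv(t(X) %*% X))[2, 2]
    t_ref <- beta[2] / sqrt(s2 * cov_g)
    expect_lt(abs(tm$data[j] - t_ref), 1e-8)
  }
  # permuting subjects (rows and maps together) leaves the map unchanged
  perm <- c(4, 2, 6, 1, 3, 5)
  Xp <- design_matrix(subjects[perm, ])
  tmp <- two_sample_glm_map(make_stack(mat[perm, ], g), Xp, m)
  expect_equal(c(tmp$data), c(tm$data), tolerance = 1e-10)
})

test_that("combined one-sample masks take the union of surviving clusters", {
  g <- tiny_grid(c(10, 6, 1))
  m <- full_mask(g)
  mk_t <- function(cols) {
    a <- array(0, dim = c(10, 6, 1)); a[cols, , 1] <- 5
    out <- scalar_map(a, g, "tstat"); attr(out, "df") <- 10; out
  }
  mc <- list(min_cluster_size = 3L)
  # identical groups: union equals either mask
  u1 <- combine_group_masks(list(mk_t(1:3), mk_t(1:3)), m, mc, c(2, 2), 5)
  expect_equal(u1$n_true, 18)
  # disjoint regions: union size is the sum
  u2 <- combine_group_masks(list(mk_t(1:3), mk_t(6:8)), m, mc, c(2, 2), 5)
  expect_equal(u2$n_true, 36)
  # nothing survives: fall back to the full mask with a warning
  expect_warning(
    u3 <- combine_group_masks(list(mk_t(integer(0)), mk_t(integer(0))), m, mc,
                              c(2, 2), 5),
    "falling back")
  expect_equal(u3$n_true, m$n_true)
})

test_that("cluster means extract the arithmetic mean of member voxels", {
  g <- tiny_grid(c(3, 1, 1))
  maps <- make_stack(rbind(c(1, 2, 3), c(4, 5, 6)), g)
  one <- binary_mask(array(c(TRUE, FALSE, FALSE), c(3, 1, 1)), g)
  expect_equal(cluster_mean_values(maps, one), c(1, 4))
  all3 <- binary_mask(array(TRUE, c(3, 1, 1)), g)
  expect_equal(cluster_mean_values(maps, all3), c(2, 5))
  # voxel-matrix form (0-based), as stored in cluster tables
  vx <- rbind(c(0L, 0L, 0L), c(2L, 0L, 0L))
  expect_equal(cluster_mean_values(maps, vx), c(2, 5))
  expect_error(cluster_mean_values(maps,
                                   binary_mask(array(FALSE, c(3, 1, 1)), g)),
               "empty")
})

test_that("partial correlation equals residualise-then-correlate and its reductions", {
  set.seed(29)
  n <- 10
  cov_df <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                       education = rnorm(n))
  x <- rnorm(n); y <- 0.6 * x + rnorm(n)
  got <- partial_pearson(x, y, cov_df)
  # independent two-stage lm oracle
  rx <- resid(lm(x ~ age + sex + education, cov_df))
  ry <- resid(lm(y ~ age + sex + education, cov_df))
  r_ref <- cor(rx, ry)
  expect_lt(abs(got$r - r_ref), 1e-10)
  t_ref <- r_ref * sqrt((n - 3 - 2) / (1 - r_ref^2))
  expect_lt(abs(got$p - 2 * pt(-abs(t_ref), n - 5)), 1e-10)
  # a covariate orthogonal to x, y and the intercept leaves r unchanged
  xc <- x - mean(x); yc <- y - mean(y)
  Q <- qr.Q(qr(cbind(1, xc, yc)))
  z <- rnorm(n)
  z <- drop(z - Q %*% crossprod(Q, z))
  got2 <- partial_pearson(x, y, data.frame(z = z))
  expect_lt(abs(got2$r - cor(x, y)), 1e-10)
  # y = x gives r = 1 with a vanishing p
  ident <- partial_pearson(1:10, 1:10, NULL)
  expect_equal(ident$r, 1)
  expect_lt(ident$p, 1e-12)
  expect_error(partial_pearson(1:4, 1:4, cov_df[1:4, ]), "n >")
})

test_that("correlation reports apply Bonferroni over all tests and never undercorrect", {
  set.seed(37)
  n <- 12
  patients <- tibble::tibble(
    group = rep("tinnitus", n), age = rnorm(n, 50, 10),
    sex = sample(c("male", "female"), n, TRUE), education = rnorm(n, 12, 3),
    thq = runif(n, 20, 80), tinnitus_duration = runif(n, 6, 120))
  vals <- list(c1 = rnorm(n), c2 = rnorm(n))
  rep_tab <- correlate_clusters(vals, patients)
  expect_equal(nrow(rep_tab), 4)           # 2 clusters x 2 variables
  expect_equal(rep_tab$p_bonferroni, pmin(1, rep_tab$p_raw * 4))
  expect_true(all(rep_tab$p_bonferroni >= rep_tab$p_raw))
  expect_true(all(abs(rep_tab$r) <= 1))
})

test_that("demographics tables reproduce printed-summary statistics", {
  # pooled t from the printed group summaries
  tt <- pooled_t_from_summary(50.8, 12.4, 24, 44.7, 15.4, 22)
  expect_equal(tt$p, 0.1446, tolerance = 5e-4)
  # identical summaries give p = 1
  expect_equal(pooled_t_from_summary(10, 2, 15, 10, 2, 15)$p, 1)
  # raw-data table: equal groups give p = 1 for the t tests
  subj <- tibble::tibble(
    group = rep(c("tinnitus", "control"), each = 4),
    age = rep(c(40, 50, 60, 45), 2), sex = rep(c("male", "female"), 4),
    education = rep(c(10, 12, 14, 16), 2),
    tinnitus_duration = c(10, 20, 30, 40, NA, NA, NA, NA),
    thq = c(40, 50, 60, 45, NA, NA, NA, NA),
    hearing_left = rep(13, 8), hearing_right = rep(14, 8))
  tab <- demographics_table(subj)
  expect_equal(tab$p[tab$variable == "age"], 1)
  expect_true(is.na(tab$p[tab$variable == "thq"]))
  # sex chi-square equals the base test without continuity correction
  cs <- suppressWarnings(chisq.test(rbind(c(2, 2), c(2, 2)), correct = FALSE))
  expect_equal(tab$p[tab$variable == "sex"], round(unname(cs$p.value), 3))
})
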