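# Group-level inference on per-subject maps: one-sample and
# covariate-adjusted two-sample voxel-wise tests, cluster-mean extraction,
# covariate-corrected clinical correlations, and the demographics table.

# stack a list of scalar_maps to an n_subjects x n_maskvox matrix
stack_matrix <- function(maps, mask) {
  idx <- mask_indices(mask)
  for (m in maps) stop_if_grid_mismatch(m$grid, mask$grid)
  do.call(rbind, lapply(maps, function(m) m$data[idx]))
}

map_from_vector <- function(v, mask, kind = "tstat") {
  a <- array(0, dim = mask$grid$dims)
  a[mask_indices(mask)] <- v
  scalar_map(a, mask$grid, kind)
}

#' One-sample t map
#'
#' Per-voxel one-sample t statistic of the subject stack against zero,
#' `df = n - 1`. Voxels with zero between-subject variance get `t = 0` and
#' are counted in the `n_degenerate` attribute.
#'
#' @param maps List of per-subject [scalar_map]s (>= 3).
#' @param mask A [binary_mask].
#' @return A [scalar_map] of t values with attributes `df` and
#'   `n_degenerate`.
#' @export
one_sample_map <- function(maps, mask) {
  stopifnot(length(maps) >= 3)
  Y <- stack_matrix(maps, mask)
  n <- nrow(Y)
  mu <- colMeans(Y)
  sdv <- sqrt(colSums(sweep(Y, 2, mu)^2) / (n - 1))
  t <- ifelse(sdv == 0, 0, mu / (sdv / sqrt(n)))
  out <- map_from_vector(t, mask)
  attr(out, "df") <- n - 1
  attr(out, "n_degenerate") <- sum(sdv == 0)
  out
}

#' Group design matrix with nuisance covariates
#'
#' Columns: intercept, group contrast (+1 patient / -1 control), and
#' mean-centred age, sex (0 male / 1 female) and education. Built from a
#' subjects tibble with `group`, `age`, `sex`, `education`; rows follow the
#' table order.
#'
#' @param subjects Subjects tibble (see [generate_cohort]).
#' @param covariates Character vector of nuisance columns to include.
#' @return A numeric design matrix with a `"group_col"` attribute.
#' @export
design_matrix <- function(subjects, covariates = c("age", "sex", "education")) {
  grp <- ifelse(subjects$group == "tinnitus", 1, -1)
  X <- cbind(intercept = 1, group = grp)
  for (cv in covariates) {
    v <- subjects[[cv]]
    if (cv == "sex") v <- ifelse(v == "female", 1, 0)
    v <- as.numeric(v) - mean(as.numeric(v))
    if (stats::sd(v) == 0) next          # constant columns dropped
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  attr(X, "group_col") <- 2L
  X
}

#' Two-sample GLM t map with nuisance covariates
#'
#' Per-voxel least-squares fit of the subject stack on the design; the
#' returned map is the t statistic of the group-contrast column with
#' `df = n - rank(design)`.
#'
#' @param maps List of per-subject [scalar_map]s, in design row order.
#' @param design Design matrix from [design_matrix].
#' @param mask A [binary_mask].
#' @return A [scalar_map] of t values with attribute `df`.
#' @export
two_sample_glm_map <- function(maps, design, mask) {
  Y <- stack_matrix(maps, mask)
  n <- nrow(Y)
  stopifnot(n == nrow(design))
  g <- attr(design, "group_col") %||% 2L
  XtXi <- solve(crossprod(design))
  B <- XtXi %*% crossprod(design, Y)
  R <- Y - design %*% B
  df <- n - qr(design)$rank
  sigma2 <- colSums(R^2) / df
  se <- sqrt(sigma2 * XtXi[g, g])
  t <- ifelse(se == 0, 0, B[g, ] / se)
  out <- map_from_vector(t, mask)
  attr(out, "df") <- df
  out
}

#' Union mask of significant one-sample clusters of both groups
#'
#' Runs cluster correction on each group's one-sample t map and returns the
#' union of surviving cluster voxels; the between-group comparison is
#' restricted to this mask. An empty union falls back to the full analysis
#' mask with a warning.
#'
#' @param t_maps List of two one-sample t [scalar_map]s (one per group).
#' @param mask Analysis [binary_mask].
#' @param mc An `mc_result` computed on `mask`.
#' @param stat_thresholds Cluster-forming thresholds, one per map (e.g. the
#'   `voxel_p` t quantile at each group's df).
#' @param connect_radius_mm Connection radius (default 5).
#' @param sign Tail for the one-sample maps (default two-sided).
#' @return A [binary_mask].
#' @export
combine_group_masks <- function(t_maps, mask, mc, stat_thresholds,
                                connect_radius_mm = 5, sign = "two_sided") {
  stopifnot(length(t_maps) == 2, length(stat_thresholds) == 2)
  un <- array(FALSE, dim = mask$grid$dims)
  for (i in 1:2) {
    cc <- apply_correction(t_maps[[i]], mask, stat_thresholds[i], mc,
                           connect_radius_mm, sign)
    for (vx in cc$clusters$voxels) un[vx + 1L] <- TRUE
  }
  if (!any(un)) {
    warning("no significant one-sample clusters in either group; falling back to full mask")
    return(mask)
  }
  binary_mask(un & mask$data, mask$grid)
}

#' Per-subject mean values within a cluster
#'
#' @param maps List of per-subject [scalar_map]s.
#' @param cluster A nonempty [binary_mask] (or 0-based voxel index matrix).
#' @return Numeric vector, one mean per subject.
#' @export
cluster_mean_values <- function(maps, cluster) {
  idx <- if (inherits(cluster, "binary_mask")) {
    if (cluster$n_true == 0) stop("empty cluster")
    mask_indices(cluster)
  } else {
    if (nrow(cluster) == 0) stop("empty cluster")
    v1 <- cluster + 1L
    dims <- maps[[1]]$grid$dims
    v1[, 1] + (v1[, 2] - 1L) * dims[1] + (v1[, 3] - 1L) * prod(dims[1:2])
  }
  vapply(maps, function(m) mean(m$data[idx]), numeric(1))
}

#' Covariate-corrected Pearson correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' removal of the covariates (with intercept); the p-value uses
#' `t = r sqrt((n - k - 2) / (1 - r^2))` with `k` covariates, two-tailed.
#' With no covariates this is the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data frame / matrix of covariate columns
#'   (factors such as sex must already be numeric).
#' @return A one-row tibble with `r`, `p`, `n`, `df`.
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 2) stop("need n > number of covariates + 2")
  if (k > 0) {
    Z <- cbind(1, as.matrix(covariates))
    qz <- qr(Z)
    x <- qr.resid(qz, x)
    y <- qr.resid(qz, y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate residual variance")
  r <- stats::cor(x, y)
  df <- n - k - 2
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  tibble::tibble(r = r, p = p, n = n, df = df)
}

#' Correlate cluster means with clinical variables
#'
#' For each significant cluster and each clinical variable, computes the
#' covariate-corrected Pearson correlation of per-patient cluster means
#' against the score, with Bonferroni correction over all tests performed
#' (`p_bonferroni = min(1, p * n_tests)`).
#'
#' @param cluster_values Named list of per-patient mean-value vectors (one
#'   per cluster/region).
#' @param patients Patient rows of the subjects tibble (must contain the
#'   clinical variables and covariates).
#' @param variables Clinical columns to test (default THQ and duration).
#' @param covariates Covariate columns (default age, sex, education);
#'   `NULL` for plain Pearson.
#' @return A `correlation_report` tibble: `cluster_id`, `clinical_variable`,
#'   `r`, `p_raw`, `p_bonferroni`, `n`.
#' @export
correlate_clusters <- function(cluster_values, patients,
                               variables = c("thq", "tinnitus_duration"),
                               covariates = c("age", "sex", "education")) {
  cov_df <- NULL
  if (!is.null(covariates)) {
    cov_df <- patients[, covariates, drop = FALSE]
    if ("sex" %in% covariates)
      cov_df$sex <- ifelse(cov_df$sex == "female", 1, 0)
    cov_df <- as.data.frame(lapply(cov_df, as.numeric))
  }
  rows <- list()
  for (cid in names(cluster_values)) {
    for (v in variables) {
      yv <- as.numeric(patients[[v]])
      ok <- is.finite(yv)
      pr <- partial_pearson(cluster_values[[cid]][ok], yv[ok],
                            if (is.null(cov_df)) NULL else cov_df[ok, , drop = FALSE])
      rows[[length(rows) + 1]] <- tibble::tibble(
        cluster_id = cid, clinical_variable = v,
        r = pr$r, p_raw = pr$p, n = pr$n)
    }
  }
  rep <- dplyr::bind_rows(rows)
  n_tests <- nrow(rep)
  rep$p_bonferroni <- pmin(1, rep$p_raw * n_tests)
  attr(rep, "n_tests") <- n_tests
  class(rep) <- c("correlation_report", class(rep))
  rep
}

#' Two-sample pooled t test from summary statistics
#'
#' Student's t with pooled variance computed from group means, SDs and
#' sizes (as printed in a demographics table).
#'
#' @param m1,s1,n1 Mean, SD, size of group 1.
#' @param m2,s2,n2 Mean, SD, size of group 2.
#' @return A one-row tibble with `t`, `df`, `p`.
#' @export
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  tibble::tibble(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Demographics comparison table
#'
#' Group means +/- SD with p-values: pooled-variance two-sample t tests for
#' continuous variables, Pearson chi-square without continuity correction
#' for sex. Patient-only variables (duration, THQ) are summarised without a
#' test.
#'
#' @param subjects Subjects tibble (excluded subjects should be dropped
#'   first).
#' @return A tibble with one row per characteristic: `variable`,
#'   `tinnitus`, `control` (formatted mean +/- SD), `statistic`, `p`.
#' @export
demographics_table <- function(subjects) {
  pat <- subjects[subjects$group == "tinnitus", ]
  ctl <- subjects[subjects$group == "control", ]
  if (nrow(pat) == 0 || nrow(ctl) == 0) stop("both groups must be present")
  fmt <- function(v) sprintf("%.1f ± %.1f", mean(v), stats::sd(v))
  cont_row <- function(var, both = TRUE) {
    pv <- as.numeric(pat[[var]]); cv <- as.numeric(ctl[[var]])
    if (!both) {
      return(tibble::tibble(variable = var, tinnitus = fmt(pv[is.finite(pv)]),
                            control = NA_character_, statistic = NA_real_,
                            p = NA_real_))
    }
    tt <- pooled_t_from_summary(mean(pv), stats::sd(pv), length(pv),
                                mean(cv), stats::sd(cv), length(cv))
    tibble::tibble(variable = var, tinnitus = fmt(pv), control = fmt(cv),
                   statistic = tt$t, p = round(tt$p, 3))
  }
  sex_tab <- rbind(table(factor(pat$sex, c("male", "female"))),
                   table(factor(ctl$sex, c("male", "female"))))
  cs <- suppressWarnings(stats::chisq.test(sex_tab, correct = FALSE))
  sex_row <- tibble::tibble(
    variable = "sex",
    tinnitus = sprintf("%d:%d", sex_tab[1, 1], sex_tab[1, 2]),
    control = sprintf("%d:%d", sex_tab[2, 1], sex_tab[2, 2]),
    statistic = unname(cs$statistic), p = round(unname(cs$p.value), 3))
  dplyr::bind_rows(
    cont_row("age"), sex_row, cont_row("education"),
    cont_row("tinnitus_duration", both = FALSE), cont_row("thq", both = FALSE),
    cont_row("hearing_left"), cont_row("hearing_right"))
}
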