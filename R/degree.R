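# Voxel-wise degree centrality: each in-mask voxel's time course is
# correlated with every other in-mask voxel; positive correlations above a
# threshold define edges; degree is the edge count (binarized) or the sum of
# edge weights (weighted); maps are z-standardised over the mask as
# Z_i = (D_i - Dbar) / sigma_D with the population standard deviation.

# centre + unit-norm columns; zero-variance columns -> all-zero columns.
# center = FALSE for representations that are already mean-free (e.g.
# spectral coefficients of band-passed series).
scale_unit <- function(X, center = TRUE) {
  if (center) X <- sweep(X, 2, colMeans(X))
  nrm <- sqrt(colSums(X^2))
  zv <- nrm == 0
  nrm[zv] <- 1
  X <- sweep(X, 2, nrm, "/")
  X[, zv] <- 0
  attr(X, "zero_variance") <- zv
  X
}

#' Correlations of one voxel with every other mask voxel
#'
#' @param bold A preprocessed [bold_series].
#' @param mask A [binary_mask] on the same grid.
#' @param voxel 0-based voxel index triple; must lie inside the mask.
#' @return Numeric vector over mask voxels (column-major mask order) of
#'   Pearson correlations, `NA` at the query voxel itself. A zero-variance
#'   query voxel yields all zeros with attribute `zero_variance = TRUE`.
#' @export
voxel_correlations <- function(bold, mask, voxel) {
  stopifnot(inherits(bold, "bold_series"), inherits(mask, "binary_mask"))
  stop_if_grid_mismatch(bold$grid, mask$grid)
  if (bold$n_volumes < 3) stop("need at least 3 frames")
  v1 <- as.integer(voxel) + 1L
  if (!mask$data[v1[1], v1[2], v1[3]]) stop("query voxel is outside the mask")
  idx <- mask_indices(mask)
  X <- as_voxel_matrix(bold)[, idx, drop = FALSE]
  Xs <- scale_unit(X)
  self <- match(v1[1] + (v1[2] - 1L) * mask$grid$dims[1] +
                  (v1[3] - 1L) * prod(mask$grid$dims[1:2]), idx)
  zv <- attr(Xs, "zero_variance")
  r <- drop(crossprod(Xs[, self], Xs))
  if (zv[self]) {
    r <- rep(0, length(idx))
    attr(r, "zero_variance") <- TRUE
  }
  r[self] <- NA_real_
  r
}

degree_from_raw <- function(D, mask, flavor, r_threshold, zero_variance) {
  dims <- mask$grid$dims
  raw_arr <- array(0, dim = dims)
  raw_arr[mask_indices(mask)] <- D
  dbar <- mean(D)
  sdd <- sqrt(mean((D - dbar)^2))         # population SD over mask voxels
  if (sdd == 0) {
    warning("degree map has zero variance over the mask; z map set to 0")
    Z <- rep(0, length(D))
  } else {
    Z <- (D - dbar) / sdd
  }
  z_arr <- array(0, dim = dims)
  z_arr[mask_indices(mask)] <- Z
  structure(
    list(raw = scalar_map(raw_arr, mask$grid, "degree_raw"),
         z = scalar_map(z_arr, mask$grid, "degree_z"),
         flavor = flavor, r_threshold = r_threshold, mask = mask,
         mean_degree = dbar, sd_degree = sdd,
         n_zero_variance = sum(zero_variance)),
    class = "degree_result"
  )
}

#' @export
print.degree_result <- function(x, ...) {
  cat(sprintf("<degree_result> %s, r > %g, %d mask voxels, mean D %.3f (sd %.3f)\n",
              x$flavor, x$r_threshold, x$mask$n_true, x$mean_degree, x$sd_degree))
  invisible(x)
}

#' Voxel-wise degree-centrality map
#'
#' Builds the full in-mask correlation matrix, thresholds at
#' `r > r_threshold` (strict; negative correlations never contribute) and
#' accumulates per-voxel degree: edge counts (`binarized`) or summed edge
#' weights (`weighted`). Zero-variance voxels stay in the mask with degree 0.
#'
#' @param bold A preprocessed [bold_series].
#' @param mask A [binary_mask] with at least 2 voxels.
#' @param r_threshold Correlation threshold (default 0.25).
#' @param flavor `"weighted"` (default) or `"binarized"`.
#' @return A `degree_result`: raw and z [scalar_map]s plus the mask and the
#'   mean/SD used for standardisation.
#' @export
degree_map <- function(bold, mask, r_threshold = 0.25,
                       flavor = c("weighted", "binarized")) {
  flavor <- match.arg(flavor)
  stopifnot(inherits(bold, "bold_series"), inherits(mask, "binary_mask"))
  stop_if_grid_mismatch(bold$grid, mask$grid)
  if (mask$n_true < 2) stop("mask must contain at least 2 voxels")
  idx <- mask_indices(mask)
  Xs <- scale_unit(as_voxel_matrix(bold)[, idx, drop = FALSE])
  zv <- attr(Xs, "zero_variance")
  C <- crossprod(Xs)
  diag(C) <- 0
  E <- C > r_threshold
  D <- if (flavor == "binarized") rowSums(E) else rowSums(C * E)
  degree_from_raw(D, mask, flavor, r_threshold, zv)
}

#' Memory-bounded degree-centrality map
#'
#' Computes the identical quantity as [degree_map] in row blocks of the
#' correlation matrix, never materialising the full N x N matrix.
#'
#' @inheritParams degree_map
#' @param block_size Rows per block (default 1024).
#' @return A `degree_result`, equal to [degree_map]'s within 1e-10.
#' @export
block_degree_map <- function(bold, mask, r_threshold = 0.25,
                             flavor = c("weighted", "binarized"),
                             block_size = 1024L) {
  flavor <- match.arg(flavor)
  stopifnot(inherits(bold, "bold_series"), inherits(mask, "binary_mask"))
  stop_if_grid_mismatch(bold$grid, mask$grid)
  if (mask$n_true < 2) stop("mask must contain at least 2 voxels")
  block_size <- max(1L, as.integer(block_size))
  Xs <- scale_unit(as_voxel_matrix(bold)[, mask_indices(mask), drop = FALSE])
  zv <- attr(Xs, "zero_variance")
  sums <- deg_block_sums(Xs, r_threshold, block_size)
  D <- if (flavor == "binarized") sums$binarized else sums$weighted
  degree_from_raw(D, mask, flavor, r_threshold, zv)
}
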