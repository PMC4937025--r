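# broom-style tidiers for the fitted result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a degree-centrality result
#'
#' One row per mask voxel with MNI coordinates, raw degree and z score.
#'
#' @param x A `degree_result`.
#' @param ... Unused.
#' @return A tibble with `x`, `y`, `z` (mm), `degree`, `degree_z`.
#' @export
tidy.degree_result <- function(x, ...) {
  vx <- mask_coords(x$mask)
  mm <- voxel_to_mm(x$mask$grid, vx)
  idx <- mask_indices(x$mask)
  raw_v <- x$raw$data[idx]
  z_v <- x$z$data[idx]
  tibble::tibble(x = mm[, 1], y = mm[, 2], z = mm[, 3],
                 degree = raw_v, degree_z = z_v)
}

#' @rdname tidy.degree_result
#' @return For `glance`: a one-row tibble with `flavor`, `r_threshold`,
#'   `n_mask_voxels`, `mean_degree`, `sd_degree`, `n_zero_variance`.
#' @export
glance.degree_result <- function(x, ...) {
  tibble::tibble(flavor = x$flavor, r_threshold = x$r_threshold,
                 n_mask_voxels = x$mask$n_true, mean_degree = x$mean_degree,
                 sd_degree = x$sd_degree, n_zero_variance = x$n_zero_variance)
}

#' Tidy a Granger causality result
#'
#' One row per mask voxel and direction with F and z values.
#'
#' @param x A `gc_result`.
#' @param ... Unused.
#' @return A tibble with `x`, `y`, `z`, `direction` (`"seed_to_voxel"` /
#'   `"voxel_to_seed"`), `f`, `f_z`.
#' @export
tidy.gc_result <- function(x, ...) {
  vx <- mask_coords(x$mask)
  mm <- voxel_to_mm(x$mask$grid, vx)
  idx <- mask_indices(x$mask)
  f_xy <- x$f_xy$data[idx]; z_xy <- x$z_xy$data[idx]
  f_yx <- x$f_yx$data[idx]; z_yx <- x$z_yx$data[idx]
  base <- tibble::tibble(x = mm[, 1], y = mm[, 2], z = mm[, 3])
  dplyr::bind_rows(
    dplyr::mutate(base, direction = "seed_to_voxel", f = f_xy, f_z = z_xy),
    dplyr::mutate(base, direction = "voxel_to_seed", f = f_yx, f_z = z_yx))
}

#' @rdname tidy.gc_result
#' @return For `glance`: one row with seed centre, radius, order, mask size
#'   and flagged-voxel count.
#' @export
glance.gc_result <- function(x, ...) {
  tibble::tibble(seed_x = x$seed_center[1], seed_y = x$seed_center[2],
                 seed_z = x$seed_center[3], seed_radius = x$seed_radius,
                 order = x$order, n_mask_voxels = x$mask$n_true,
                 n_degenerate = x$n_degenerate)
}

#' Tidy a Monte-Carlo cluster-threshold result
#'
#' The simulated null distribution of maximum cluster sizes with tail
#' probabilities.
#'
#' @param x An `mc_result`.
#' @param ... Unused.
#' @return A tibble with `max_cluster_size`, `n_sims`, `p_tail`
#'   (`P(max >= k)`).
#' @export
tidy.mc_result <- function(x, ...) {
  ks <- sort(unique(c(0L, x$null_max_cluster_sizes)))
  tibble::tibble(
    max_cluster_size = ks,
    n_sims = vapply(ks, function(k) sum(x$null_max_cluster_sizes == k),
                    integer(1)),
    p_tail = vapply(ks, function(k) mean(x$null_max_cluster_sizes >= k),
                    numeric(1)))
}

#' @rdname tidy.mc_result
#' @return For `glance`: one row with the derived minimum cluster size and
#'   simulation parameters.
#' @export
glance.mc_result <- function(x, ...) {
  tibble::tibble(min_cluster_size = x$min_cluster_size,
                 voxel_p = x$voxel_p, corrected_alpha = x$corrected_alpha,
                 n_sims = x$n_sims, fwhm_mm = x$fwhm_mm,
                 alpha_attainable = x$alpha_attainable)
}
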