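# Seed-based bivariate Granger causality. For seed series x and voxel
# series y, the directed influence F_{x->y} is the residual-based F
# statistic comparing the restricted autoregression of y on its own lags
# (plus intercept) with the full model adding x's lags:
#   F = [(RSS_restricted - RSS_full) / p] / [RSS_full / (T - 2p - 1)]
# with p the model order and T the series length. Both directions are
# computed; maps are z-standardised over the mask per direction.

#' Sphere mask around an MNI coordinate
#'
#' In-mask voxels whose centres lie within `radius_mm` of `center_mni`.
#'
#' @param grid A [volume_grid].
#' @param center_mni MNI mm triple.
#' @param radius_mm Sphere radius in mm.
#' @param mask Optional [binary_mask] to intersect with.
#' @return A [binary_mask].
#' @export
sphere_mask <- function(grid, center_mni, radius_mm, mask = NULL) {
  dims <- grid$dims
  ijk <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  mm <- voxel_to_mm(grid, ijk)
  d2 <- (mm[, 1] - center_mni[1])^2 + (mm[, 2] - center_mni[2])^2 +
    (mm[, 3] - center_mni[3])^2
  arr <- array(d2 <= radius_mm^2, dim = dims)
  if (!is.null(mask)) {
    stop_if_grid_mismatch(grid, mask$grid)
    arr <- arr & mask$data
  }
  binary_mask(arr, grid)
}

#' Extract a seed time series
#'
#' Mean time course over in-mask voxels within `radius_mm` of the seed
#' centre.
#'
#' @param bold A preprocessed [bold_series].
#' @param center_mni MNI mm triple (e.g. `c(-18, 42, 27)`).
#' @param radius_mm Sphere radius (default 6 mm).
#' @param mask A [binary_mask]; the sphere is intersected with it.
#' @return A `seed_series`: list with `values`, `center`, `radius_mm`,
#'   `n_voxels`.
#' @export
extract_seed <- function(bold, center_mni, radius_mm = 6, mask) {
  stopifnot(inherits(bold, "bold_series"), inherits(mask, "binary_mask"))
  stop_if_grid_mismatch(bold$grid, mask$grid)
  sph <- sphere_mask(bold$grid, center_mni, radius_mm, mask)
  if (sph$n_true == 0) stop("seed sphere does not intersect the mask")
  idx <- mask_indices(sph)
  vals <- rowMeans(as_voxel_matrix(bold)[, idx, drop = FALSE])
  structure(list(values = vals, center = center_mni, radius_mm = radius_mm,
                 n_voxels = sph$n_true),
            class = "seed_series")
}

# RSS of regressing b on lag columns L (with intercept), via QR
rss_ols <- function(b, L) {
  X <- cbind(1, L)
  qrx <- qr(X)
  sum(qr.resid(qrx, b)^2)
}

#' Bivariate Granger causality between two series
#'
#' @param x Seed series (numeric vector or `seed_series`).
#' @param y Target series, same length.
#' @param order Autoregressive model order `p` (default 1); requires
#'   `T > 2 * order + 2`.
#' @return Named list `f_xy`, `f_yx` (both >= 0, clamped at 0) and
#'   `degenerate` (`TRUE` when either series is constant, in which case both
#'   F are 0).
#' @export
bivariate_gc <- function(x, y, order = 1) {
  if (inherits(x, "seed_series")) x <- x$values
  p <- as.integer(order)
  stopifnot(p >= 1, length(x) == length(y))
  T_len <- length(x)
  if (T_len <= 2 * p + 2) stop("series too short for order ", p)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(f_xy = 0, f_yx = 0, degenerate = TRUE))
  df2 <- T_len - 2 * p - 1
  lags <- function(v) sapply(seq_len(p), function(k) v[(p + 1 - k):(T_len - k)])
  resp <- function(v) v[(p + 1):T_len]
  Lx <- lags(x); Ly <- lags(y)
  f_dir <- function(b, own, other) {
    rss_r <- rss_ols(b, own)
    rss_f <- rss_ols(b, cbind(own, other))
    max(0, ((rss_r - rss_f) / p) / (rss_f / df2))
  }
  list(f_xy = f_dir(resp(y), Ly, Lx),
       f_yx = f_dir(resp(x), Lx, Ly),
       degenerate = FALSE)
}

# Vectorised order-1 bivariate GC of seed x against every column of Y.
# Returns list(f_xy, f_yx, degenerate) vectors.
gc_order1_vec <- function(x, Y) {
  T_len <- length(x)
  df2 <- T_len - 3
  s <- x[1:(T_len - 1)]                      # seed lag
  bx <- x[2:T_len]                           # seed response
  A <- Y[1:(T_len - 1), , drop = FALSE]      # voxel lags
  B <- Y[2:T_len, , drop = FALSE]            # voxel responses
  n <- T_len - 1
  cs <- s - mean(s); cbx <- bx - mean(bx)
  cA <- sweep(A, 2, colMeans(A)); cB <- sweep(B, 2, colMeans(B))
  Saa <- colSums(cA^2); Sbb <- colSums(cB^2)
  Sab <- colSums(cA * cB)
  Sas <- drop(crossprod(cs, cA)); Ssb <- drop(crossprod(cs, cB))
  Sss <- sum(cs^2)
  Sxb <- colSums(cA * cbx)                   # y-lag vs seed response
  Ssx <- sum(cs * cbx); Sxx <- sum(cbx^2)
  degen <- Saa == 0 | Sbb == 0
  safe <- function(v) { v[!is.finite(v)] <- 0; v }
  # direction x -> y: response cB on [cA, cs]
  rss_r_xy <- Sbb - safe(Sab^2 / Saa)
  det_xy <- Saa * Sss - Sas^2
  b1 <- safe((Sab * Sss - Ssb * Sas) / det_xy)
  b2 <- safe((Ssb * Saa - Sab * Sas) / det_xy)
  rss_f_xy <- Sbb - b1 * Sab - b2 * Ssb
  f_xy <- pmax(0, safe((rss_r_xy - rss_f_xy) / (rss_f_xy / df2)))
  # direction y -> x: response cbx on [cs, cA]
  rss_r_yx <- Sxx - Ssx^2 / Sss
  det_yx <- Sss * Saa - Sas^2
  c1 <- safe((Ssx * Saa - Sxb * Sas) / det_yx)
  c2 <- safe((Sxb * Sss - Ssx * Sas) / det_yx)
  rss_f_yx <- Sxx - c1 * Ssx - c2 * Sxb
  f_yx <- pmax(0, safe((rss_r_yx - rss_f_yx) / (rss_f_yx / df2)))
  f_xy[degen] <- 0; f_yx[degen] <- 0
  list(f_xy = f_xy, f_yx = f_yx, degenerate = degen)
}

#' Seed-to-whole-brain Granger causality maps
#'
#' Computes `F_{x->y}` and `F_{y->x}` between the seed series and every
#' in-mask voxel, then z-standardises each direction over the mask
#' (subtracting the in-mask mean and dividing by the in-mask SD).
#'
#' @param bold A preprocessed [bold_series].
#' @param seed A `seed_series` from [extract_seed].
#' @param mask A [binary_mask].
#' @param order Model order (default 1).
#' @return A `gc_result` with [scalar_map]s `f_xy`, `f_yx`, `z_xy`, `z_yx`,
#'   the seed metadata, and `n_degenerate` flagged voxels.
#' @export
gc_map <- function(bold, seed, mask, order = 1) {
  stopifnot(inherits(bold, "bold_series"), inherits(seed, "seed_series"),
            inherits(mask, "binary_mask"))
  stop_if_grid_mismatch(bold$grid, mask$grid)
  Y <- as_voxel_matrix(bold)[, mask_indices(mask), drop = FALSE]
  gc_maps_from_matrix(Y, seed, mask, order)
}

# core of gc_map on a prepared T x (mask voxels) matrix
gc_maps_from_matrix <- function(Y, seed, mask, order = 1) {
  idx <- mask_indices(mask)
  if (order == 1) {
    r <- gc_order1_vec(seed$values, Y)
  } else {
    rs <- lapply(seq_along(idx), function(j)
      bivariate_gc(seed$values, Y[, j], order))
    r <- list(f_xy = vapply(rs, `[[`, 0, "f_xy"),
              f_yx = vapply(rs, `[[`, 0, "f_yx"),
              degenerate = vapply(rs, `[[`, TRUE, "degenerate"))
  }
  to_map <- function(v, kind) {
    a <- array(0, dim = mask$grid$dims)
    a[idx] <- v
    scalar_map(a, mask$grid, kind)
  }
  zstd <- function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  structure(
    list(f_xy = to_map(r$f_xy, "gc_f"), f_yx = to_map(r$f_yx, "gc_f"),
         z_xy = to_map(zstd(r$f_xy), "gc_z"),
         z_yx = to_map(zstd(r$f_yx), "gc_z"),
         seed_center = seed$center, seed_radius = seed$radius_mm,
         order = as.integer(order), mask = mask,
         n_degenerate = sum(r$degenerate)),
    class = "gc_result"
  )
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf("<gc_result> seed (%s) r=%g mm, order %d, %d mask voxels\n",
              paste(x$seed_center, collapse = ", "), x$seed_radius, x$order,
              x$mask$n_true))
  invisible(x)
}
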