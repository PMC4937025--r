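# Temporal and spatial preprocessing of BOLD series. Registration-dependent
# steps (slice timing, realignment, normalisation) are out of scope: inputs
# are assumed to be in template space already.

# ---- internal reshaping helpers ------------------------------------------

# 4D (x,y,z,t) -> T x V matrix of voxel time courses
as_voxel_matrix <- function(bold) {
  d <- dim(bold$data)
  t(matrix(bold$data, prod(d[1:3]), d[4]))
}

# T x V matrix -> bold_series on the same grid
from_voxel_matrix <- function(mat, template) {
  d <- c(template$grid$dims, nrow(mat))
  bold_series(array(t(mat), dim = d), template$grid, template$tr_seconds)
}

# mask voxel linear indices (1-based, column-major)
mask_indices <- function(mask) which(mask$data)

# mask voxel 0-based (i,j,k) coordinates, n x 3
mask_coords <- function(mask) {
  which(mask$data, arr.ind = TRUE) - 1L
}

#' Discard initial volumes
#'
#' Drops the first `n` frames of a BOLD series (signal-equilibrium discard;
#' default leaves 230 of 240 acquired frames when `n = 10`).
#'
#' @param bold A [bold_series].
#' @param n Number of leading frames to drop; must be `< n_volumes`.
#' @return A shorter [bold_series].
#' @export
discard_initial <- function(bold, n = 10) {
  stopifnot(inherits(bold, "bold_series"))
  n <- as.integer(n)
  if (n < 0) stop("n must be non-negative")
  if (n >= bold$n_volumes) stop("cannot discard all ", bold$n_volumes, " volumes")
  if (n == 0) return(bold)
  bold_series(bold$data[, , , (n + 1):bold$n_volumes, drop = FALSE],
              bold$grid, bold$tr_seconds)
}

#' Read a 6-column motion-parameter file
#'
#' Whitespace-delimited text, one row per volume: three translations (mm)
#' then three rotations (degrees).
#'
#' @param path Path to the text file.
#' @return A `motion_trace`: list with `translations` and `rotations`
#'   matrices (n_volumes x 3).
#' @export
read_motion_trace <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6) stop("motion file must have 6 columns, got ", ncol(m))
  motion_trace(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE])
}

#' Construct a motion trace
#'
#' @param translations n x 3 matrix of per-volume translations (mm).
#' @param rotations n x 3 matrix of per-volume rotations (degrees).
#' @return A `motion_trace` object.
#' @export
motion_trace <- function(translations, rotations) {
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  stopifnot(ncol(translations) == 3, ncol(rotations) == 3,
            nrow(translations) == nrow(rotations), nrow(translations) >= 1)
  structure(list(translations = translations, rotations = rotations),
            class = "motion_trace")
}

#' Head-motion quality control
#'
#' A subject fails when any per-axis absolute translation exceeds `limit_mm`
#' or any rotation exceeds `limit_deg` (strict inequality: a worst value
#' exactly at the limit passes).
#'
#' @param trace A `motion_trace` (see [read_motion_trace]).
#' @param limit_mm Translation limit in mm (default 2).
#' @param limit_deg Rotation limit in degrees (default 2).
#' @return A one-row [tibble::tibble] with `pass`, `worst_translation_mm`,
#'   `worst_rotation_deg`.
#' @export
motion_qc <- function(trace, limit_mm = 2.0, limit_deg = 2.0) {
  stopifnot(inherits(trace, "motion_trace"))
  wt <- max(abs(trace$translations))
  wr <- max(abs(trace$rotations))
  tibble::tibble(pass = wt <= limit_mm && wr <= limit_deg,
                 worst_translation_mm = wt, worst_rotation_deg = wr)
}

#' Remove per-voxel linear trends
#'
#' Least-squares removal of intercept and slope from every voxel time
#' course; output voxel means are zero.
#'
#' @param bold A [bold_series] with at least 3 frames.
#' @return A detrended [bold_series].
#' @export
detrend_linear <- function(bold) {
  stopifnot(inherits(bold, "bold_series"))
  if (bold$n_volumes < 3) stop("need at least 3 frames to detrend")
  from_voxel_matrix(detrend_matrix(as_voxel_matrix(bold)), bold)
}

# least-squares line removal on a T x V matrix (time in rows)
detrend_matrix <- function(Y) {
  n <- nrow(Y)
  tt <- seq_len(n) - (n + 1) / 2              # centred time
  slope <- crossprod(tt, Y)[1, ] / sum(tt^2)
  Y <- sweep(Y, 2, colMeans(Y))
  Y - outer(tt, slope)
}

#' Ideal band-pass filter
#'
#' Frequency-domain rectangular filter on the discrete Fourier transform:
#' frequency bins with `low_hz <= f <= high_hz` are retained, all others
#' (including the zero-frequency mean when `low_hz > 0`) are zeroed.
#'
#' @param bold A [bold_series].
#' @param low_hz,high_hz Passband edges; require
#'   `0 <= low < high < 1/(2 TR)`.
#' @return A filtered [bold_series].
#' @export
bandpass <- function(bold, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(bold, "bold_series"))
  nyq <- 1 / (2 * bold$tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyq))
    stop("invalid band for TR ", bold$tr_seconds, " s (Nyquist ", nyq, " Hz)")
  from_voxel_matrix(
    bandpass_matrix(as_voxel_matrix(bold), bold$tr_seconds, low_hz, high_hz),
    bold)
}

band_keep_bins <- function(n, tr, low_hz, high_hz) {
  k <- seq_len(n) - 1
  # fold the integer bin index first so conjugate bins map to the exact
  # same frequency value (keeps the filtered signal exactly real)
  freqs <- pmin(k, n - k) / (n * tr)
  freqs >= low_hz & freqs <= high_hz
}

# ideal filter on a T x V matrix
bandpass_matrix <- function(Y, tr, low_hz, high_hz) {
  n <- nrow(Y)
  keep <- band_keep_bins(n, tr, low_hz, high_hz)
  F <- stats::mvfft(Y)
  F[!keep, ] <- 0
  Re(stats::mvfft(F, inverse = TRUE)) / n
}

# One FFT pass returning both the band-passed series and a compressed real
# representation (real/imaginary parts of the retained positive-frequency
# bins) whose column correlations equal those of the filtered series
# exactly (Parseval; the zero-frequency and Nyquist bins are outside any
# valid band so every retained bin has a conjugate partner).
bandpass_and_compress <- function(Y, tr, low_hz, high_hz) {
  n <- nrow(Y)
  keep <- band_keep_bins(n, tr, low_hz, high_hz)
  F <- stats::mvfft(Y)
  F[!keep, ] <- 0
  half <- which(keep[seq_len(floor(n / 2) + 1)])
  comp <- rbind(Re(F[half, , drop = FALSE]), Im(F[half, , drop = FALSE]))
  list(series = Re(stats::mvfft(F, inverse = TRUE)) / n, compressed = comp)
}

# Band-limited random signal of unit variance (internal; used by the
# synthetic generator): white noise restricted to [low, high] Hz.
band_limited_signal <- function(n, tr, low = 0.01, high = 0.08) {
  x <- stats::rnorm(n)
  keep <- band_keep_bins(n, tr, low, high)
  f <- stats::fft(x)
  f[!keep] <- 0
  y <- Re(stats::fft(f, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) stop("degenerate band-limited signal")
  y / s
}

# ---- spatial smoothing ----------------------------------------------------

# 1D Gaussian convolution matrix (zero padding: rows are truncated kernels)
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  k <- ceiling(4 * sigma_vox)
  w <- exp(-(seq(-k, k))^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - k):(i + k)
    ok <- j >= 1 & j <= n
    S[i, j[ok]] <- w[ok]
  }
  S
}

# Apply separable kernel matrices along the first three dims of a 3D/4D array
apply_separable <- function(arr, mats) {
  d <- dim(arr)
  # axis 1
  m <- matrix(arr, d[1], prod(d[-1]))
  arr <- array(mats[[1]] %*% m, dim = d)
  # axis 2
  perm <- c(2, 1, 3, seq_along(d)[-(1:3)])
  a2 <- aperm(arr, perm)
  d2 <- dim(a2)
  a2 <- array(mats[[2]] %*% matrix(a2, d2[1], prod(d2[-1])), dim = d2)
  arr <- aperm(a2, order(perm))
  # axis 3
  perm <- c(3, 2, 1, seq_along(d)[-(1:3)])
  a3 <- aperm(arr, perm)
  d3 <- dim(a3)
  a3 <- array(mats[[3]] %*% matrix(a3, d3[1], prod(d3[-1])), dim = d3)
  aperm(a3, order(perm))
}

fwhm_to_sigma <- function(fwhm_mm) fwhm_mm / (2 * sqrt(2 * log(2)))

#' Isotropic Gaussian spatial smoothing
#'
#' Separable 3D Gaussian convolution with `sigma = FWHM / (2 sqrt(2 ln 2))`
#' per axis in mm (converted by voxel size). Applied per frame for 4D input.
#' Boundary handling is zero padding, so edge voxels are attenuated; away
#' from the boundary the kernel sums to 1 and mean intensity is preserved.
#' `fwhm_mm = 0` is the identity.
#'
#' @param obj A [scalar_map], [bold_series] or plain 3D/4D array (with
#'   `voxel_size` then required).
#' @param fwhm_mm Full width at half maximum, mm (>= 0).
#' @param voxel_size Only for plain arrays: mm per axis.
#' @return Same type as `obj`.
#' @export
smooth_gaussian <- function(obj, fwhm_mm, voxel_size = NULL) {
  if (fwhm_mm < 0) stop("fwhm must be non-negative")
  if (inherits(obj, "scalar_map") || inherits(obj, "bold_series")) {
    vs <- obj$grid$voxel_size
    if (fwhm_mm == 0) return(obj)
    sig <- fwhm_to_sigma(fwhm_mm) / vs
    mats <- lapply(1:3, function(a) gauss_conv_matrix(dim(obj$data)[a], sig[a]))
    out <- apply_separable(obj$data, mats)
    if (inherits(obj, "scalar_map")) return(scalar_map(out, obj$grid, obj$kind))
    return(bold_series(out, obj$grid, obj$tr_seconds))
  }
  stopifnot(is.array(obj), !is.null(voxel_size))
  if (fwhm_mm == 0) return(obj)
  sig <- fwhm_to_sigma(fwhm_mm) / voxel_size
  mats <- lapply(1:3, function(a) gauss_conv_matrix(dim(obj)[a], sig[a]))
  apply_separable(obj, mats)
}

#' Gray-matter mask from a probability map
#'
#' Voxels with probability strictly greater than `threshold` (default 20%)
#' enter the mask.
#'
#' @param prob A [scalar_map] with values in `[0, 1]`.
#' @param threshold Probability cut (strict >).
#' @return A [binary_mask].
#' @export
gm_mask_from_prob <- function(prob, threshold = 0.20) {
  stopifnot(inherits(prob, "scalar_map"))
  if (min(prob$data) < 0 || max(prob$data) > 1)
    stop("probability map has values outside [0, 1]")
  binary_mask(prob$data > threshold, prob$grid)
}

#' Standard preprocessing chain
#'
#' Applies, in order: initial-volume discard, spatial Gaussian smoothing,
#' per-voxel linear detrending, ideal band-pass filtering. Smoothing
#' precedes the temporal operations, mirroring the conventional
#' normalise-smooth-detrend-filter resting-state stream.
#'
#' @param bold A [bold_series].
#' @param config A [study_config].
#' @return A preprocessed [bold_series].
#' @export
preprocess_bold <- function(bold, config = study_config()) {
  bold |>
    discard_initial(config$discard_volumes) |>
    smooth_gaussian(config$fwhm_mm) |>
    detrend_linear() |>
    bandpass(config$band[1], config$band[2])
}
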