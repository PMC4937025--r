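#' Volume grid: dimensions, voxel size and voxel-to-world affine
#'
#' A `volume_grid` ties a 3D voxel lattice to MNI millimetre space through a
#' 4x4 affine (NIfTI sform convention, 0-based voxel indices). All maps,
#' masks and BOLD series in this package carry one, and operations that
#' combine objects require their grids to agree.
#'
#' @param dims Integer triple, voxels per axis.
#' @param voxel_size Numeric triple, mm per axis (default 3 mm isotropic).
#' @param origin MNI mm coordinate of voxel (0,0,0). Ignored when `affine`
#'   is supplied.
#' @param affine Optional full 4x4 voxel-to-mm affine; overrides
#'   `voxel_size`/`origin` diagonal construction.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(dims, voxel_size = c(3, 3, 3), origin = c(0, 0, 0),
                        affine = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims > 0))
  if (is.null(affine)) {
    stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- origin
  } else {
    stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
    if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
      stop("affine is not invertible")
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  structure(
    list(dims = dims, voxel_size = as.numeric(voxel_size), affine = affine),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat("  origin (mm):", paste(signif(x$affine[1:3, 4], 6), collapse = ", "), "\n")
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-4) {
  identical(a$dims, b$dims) && max(abs(a$affine - b$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!grids_equal(a, b))
    stop("objects are defined on different grids (same dims and affine within 1e-4 mm required)")
  invisible(TRUE)
}

#' Default synthetic-cohort grid
#'
#' A 20 x 24 x 20 lattice of 3 mm isotropic voxels with origin (-27, -18, -21)
#' mm, sized so that mirrored frontal seed spheres at (+/-18, 42, 27) with a
#' 9 mm radius fit inside.
#'
#' @return A [volume_grid].
#' @export
default_grid <- function() {
  volume_grid(c(20L, 24L, 20L), voxel_size = c(3, 3, 3), origin = c(-27, -18, -21))
}

#' 4D BOLD time series on a grid
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param grid A [volume_grid] matching the first three dimensions.
#' @param tr_seconds Repetition time in seconds (default 2).
#' @return An object of class `bold_series` with fields `data`, `grid`,
#'   `tr_seconds`, `n_volumes`.
#' @export
bold_series <- function(data, grid, tr_seconds = 2) {
  stopifnot(is.array(data), length(dim(data)) == 4, tr_seconds > 0)
  if (!identical(as.integer(dim(data)[1:3]), grid$dims))
    stop("data spatial dimensions do not match grid")
  structure(
    list(data = data, grid = grid, tr_seconds = as.numeric(tr_seconds),
         n_volumes = dim(data)[4]),
    class = "bold_series"
  )
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %d volumes, TR %.3g s, grid %s\n",
              x$n_volumes, x$tr_seconds, paste(x$grid$dims, collapse = "x")))
  invisible(x)
}

#' 3D scalar map on a grid
#'
#' @param data 3D numeric array.
#' @param grid A [volume_grid].
#' @param kind Label describing the quantity, one of `degree_raw`,
#'   `degree_z`, `tstat`, `gc_f`, `gc_z`, `gm_prob`.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(data, grid,
                       kind = c("degree_raw", "degree_z", "tstat",
                                "gc_f", "gc_z", "gm_prob")) {
  kind <- match.arg(kind)
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!identical(as.integer(dim(data)), grid$dims))
    stop("data dimensions do not match grid")
  structure(list(data = data, grid = grid, kind = kind), class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("<scalar_map:%s> grid %s, range [%.4g, %.4g]\n", x$kind,
              paste(x$grid$dims, collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Binary voxel mask on a grid
#'
#' @param data 3D logical (or coercible) array.
#' @param grid A [volume_grid].
#' @return An object of class `binary_mask` with `n_true` voxels set.
#' @export
binary_mask <- function(data, grid) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  data <- array(as.logical(data), dim = dim(data))
  if (!identical(as.integer(dim(data)), grid$dims))
    stop("data dimensions do not match grid")
  structure(list(data = data, grid = grid, n_true = sum(data)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d / %d voxels, grid %s\n", x$n_true,
              prod(x$grid$dims), paste(x$grid$dims, collapse = "x")))
  invisible(x)
}

#' Convert MNI mm coordinates to 0-based voxel indices
#'
#' Applies the inverse of the grid affine and rounds to the nearest voxel.
#' Coordinates mapping outside the grid are an error.
#'
#' @param grid A [volume_grid].
#' @param mni_xyz Numeric triple (or n x 3 matrix) of mm coordinates.
#' @return Integer triple (or n x 3 matrix) of 0-based voxel indices.
#' @export
mm_to_voxel <- function(grid, mni_xyz) {
  m <- if (is.matrix(mni_xyz)) mni_xyz else matrix(mni_xyz, nrow = 1)
  stopifnot(ncol(m) == 3)
  inv <- solve(grid$affine)
  v <- t(inv %*% rbind(t(m), 1))[, 1:3, drop = FALSE]
  idx <- round(v)
  bad <- idx < 0 | idx >= matrix(grid$dims, nrow(idx), 3, byrow = TRUE)
  if (any(bad))
    stop("coordinate maps outside the grid: ",
         paste(m[which(rowSums(bad) > 0)[1], ], collapse = ", "))
  idx <- matrix(as.integer(idx), nrow(idx), 3)
  if (is.matrix(mni_xyz)) idx else idx[1, ]
}

#' Convert 0-based voxel indices to MNI mm coordinates
#'
#' @param grid A [volume_grid].
#' @param ijk Integer triple (or n x 3 matrix) of 0-based voxel indices.
#' @return Numeric triple (or n x 3 matrix) of mm coordinates (voxel centres).
#' @export
voxel_to_mm <- function(grid, ijk) {
  m <- if (is.matrix(ijk)) ijk else matrix(ijk, nrow = 1)
  stopifnot(ncol(m) == 3)
  mm <- t(grid$affine %*% rbind(t(m), 1))[, 1:3, drop = FALSE]
  if (is.matrix(ijk)) mm else mm[1, ]
}

grid_from_nifti <- function(img) {
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  volume_grid(dim(img)[1:3], affine = aff)
}

#' Read a NIfTI-1 volume
#'
#' 3D files load as a [scalar_map] (default `kind = "gm_prob"` may be
#' overridden), 4D files as a [bold_series] with the TR taken from
#' `pixdim[4]`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param kind Kind label for 3D maps (see [scalar_map]).
#' @return A [bold_series] or [scalar_map].
#' @export
read_volume <- function(path, kind = "gm_prob") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  grid <- grid_from_nifti(img)
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(dat))
  if (nd == 3) {
    scalar_map(dat, grid, kind = kind)
  } else if (nd == 4) {
    tr <- RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0) tr <- 2
    bold_series(dat, grid, tr_seconds = tr)
  } else {
    stop("expected a 3D or 4D NIfTI volume, got ", nd, " dimensions")
  }
}

#' Write a volume object as NIfTI-1
#'
#' Writes the affine (sform and qform, code 2), spatial pixdim and, for BOLD
#' series, the TR in `pixdim[4]`. Data are stored as float64 so that a
#' read/write round trip is bit-identical.
#'
#' @param obj A [bold_series], [scalar_map] or [binary_mask].
#' @param path Destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(obj, path) {
  dat <- if (inherits(obj, "binary_mask")) obj$data + 0 else obj$data
  if (!all(is.finite(dat))) stop("refusing to write non-finite data")
  img <- RNifti::asNifti(dat)
  tr <- if (inherits(obj, "bold_series")) obj$tr_seconds else 0
  pd <- c(obj$grid$voxel_size, tr)[seq_len(length(dim(dat)))]
  RNifti::pixdim(img) <- pd
  RNifti::sform(img) <- structure(obj$grid$affine, code = 2L)
  RNifti::qform(img) <- structure(obj$grid$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles every numeric threshold of the pipeline. Defaults follow the
#' standard parameterisation of voxel-wise degree-centrality studies:
#' correlation threshold r > 0.25, gray-matter probability > 20%, voxel-level
#' p = 0.01 with cluster-level alpha = 0.01 from 5000 Monte-Carlo
#' simulations, 6 mm FWHM smoothing, 5 mm cluster connection radius, a
#' 40-voxel minimum cluster fallback, 0.01-0.08 Hz band, 10 discarded
#' volumes, 2 mm / 2 degree motion limits and a lag-1 autoregressive Granger
#' model.
#'
#' @param r_threshold Correlation threshold for degree centrality, in (0,1).
#' @param gm_prob_threshold Gray-matter probability cut (strict >).
#' @param voxel_p Single-voxel p for cluster-forming thresholds.
#' @param corrected_alpha Cluster-corrected family-wise alpha.
#' @param n_mc_sims Monte-Carlo simulations for the cluster threshold.
#' @param fwhm_mm Gaussian smoothing FWHM in mm.
#' @param connect_radius_mm Cluster connection radius in mm.
#' @param min_cluster_voxels Fallback minimum cluster extent (voxels).
#' @param band Passband in Hz, `c(low, high)`.
#' @param discard_volumes Initial volumes dropped for signal equilibrium.
#' @param motion_limit_mm,motion_limit_deg Head-motion exclusion limits.
#' @param gc_order Autoregressive model order for Granger maps.
#' @param seed_radius_mm Seed-sphere radius in mm.
#' @param rng_seed Integer seed controlling all simulation randomness.
#' @param dc_flavor Degree flavor used at group level.
#' @param tr_seconds Repetition time assumed for simulated data.
#' @return An object of class `study_config` (a named list).
#' @export
study_config <- function(r_threshold = 0.25, gm_prob_threshold = 0.20,
                         voxel_p = 0.01, corrected_alpha = 0.01,
                         n_mc_sims = 5000, fwhm_mm = 6,
                         connect_radius_mm = 5, min_cluster_voxels = 40,
                         band = c(0.01, 0.08), discard_volumes = 10,
                         motion_limit_mm = 2.0, motion_limit_deg = 2.0,
                         gc_order = 1, seed_radius_mm = 6,
                         rng_seed = 1L, dc_flavor = c("weighted", "binarized"),
                         tr_seconds = 2) {
  dc_flavor <- match.arg(dc_flavor)
  stopifnot(r_threshold > 0, r_threshold < 1,
            gm_prob_threshold >= 0, gm_prob_threshold < 1,
            voxel_p > 0, voxel_p < 1,
            corrected_alpha > 0, corrected_alpha < 1,
            n_mc_sims >= 100, fwhm_mm >= 0, connect_radius_mm > 0,
            min_cluster_voxels >= 1, discard_volumes >= 0,
            gc_order >= 1, tr_seconds > 0)
  if (!(band[1] >= 0 && band[1] < band[2] && band[2] < 1 / (2 * tr_seconds)))
    stop("band must satisfy 0 <= low < high < Nyquist = ", 1 / (2 * tr_seconds), " Hz")
  structure(
    list(r_threshold = r_threshold, gm_prob_threshold = gm_prob_threshold,
         voxel_p = voxel_p, corrected_alpha = corrected_alpha,
         n_mc_sims = as.integer(n_mc_sims), fwhm_mm = fwhm_mm,
         connect_radius_mm = connect_radius_mm,
         min_cluster_voxels = as.integer(min_cluster_voxels),
         band = band, discard_volumes = as.integer(discard_volumes),
         motion_limit_mm = motion_limit_mm, motion_limit_deg = motion_limit_deg,
         gc_order = as.integer(gc_order), seed_radius_mm = seed_radius_mm,
         rng_seed = as.integer(rng_seed), dc_flavor = dc_flavor,
         tr_seconds = tr_seconds),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

#' Read a key = value configuration file into a study_config
#'
#' Lines of the form `key = value` (comma-separated pairs for `band`);
#' unknown keys are an error, missing keys take defaults.
#'
#' @param path Path to the text file.
#' @return A [study_config].
#' @export
read_config <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  kv <- strsplit(ln, "\\s*=\\s*")
  args <- list()
  for (p in kv) {
    if (length(p) != 2) stop("malformed config line: ", paste(p, collapse = "="))
    key <- p[1]
    val <- strsplit(p[2], "\\s*,\\s*")[[1]]
    num <- suppressWarnings(as.numeric(val))
    args[[key]] <- if (anyNA(num)) val else num
  }
  bad <- setdiff(names(args), names(formals(study_config)))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(study_config, args)
}
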