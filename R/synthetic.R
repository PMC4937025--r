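# Synthetic two-group rs-fMRI cohort generator. Emulates the statistical
# structure the analysis assumes: AR(1) Gaussian voxel noise smoothed to
# ~6 mm FWHM, shared band-limited (0.01-0.08 Hz) network signals mixed into
# gray matter, a patient-only connectivity hub (two mirrored frontal
# spheres), patient-only lag-1 directed coupling from the left hub sphere to
# target regions, and clinical scores correlated with the injected coupling
# strength. Ground truth is recorded in a manifest for recovery tests.

#' Specification of injected group effects
#'
#' @param hub_center MNI mm triple of the right-hemisphere hub peak; the hub
#'   is mirrored to `(-x, y, z)` (default `c(18, 42, 27)`).
#' @param hub_radius Hub sphere radius in mm (default 9).
#' @param hub_gain Patient-only amplitude of the shared hub signal added to
#'   hub voxels (0 disables; default 1.6, calibrated for detectability at
#'   n = 24 + 22).
#' @param coupling_targets List of MNI mm triples receiving lagged input
#'   from the left hub sphere (defaults inside the default grid).
#' @param coupling_strength Mean patient coupling strength (default 0.9);
#'   per-patient strengths are drawn around it.
#' @param coupling_sd Between-patient SD of coupling strength (default 0.25).
#' @param coupling_radius Target/source sphere radius in mm (default 6).
#' @param coupling_lag Lag in volumes (default 1).
#' @param thq_coupling_r Target correlation between patient coupling
#'   strength and THQ (default 0.5).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(hub_center = c(18, 42, 27), hub_radius = 9,
                        hub_gain = 1.6,
                        coupling_targets = list(c(-6, 6, -9), c(9, -9, 27)),
                        coupling_strength = 0.9, coupling_sd = 0.25,
                        coupling_radius = 6, coupling_lag = 1,
                        thq_coupling_r = 0.5) {
  stopifnot(hub_radius > 0, hub_gain >= 0, coupling_strength >= 0,
            coupling_lag >= 1, thq_coupling_r >= 0, thq_coupling_r < 1)
  structure(list(hub_center = hub_center, hub_radius = hub_radius,
                 hub_gain = hub_gain, coupling_targets = coupling_targets,
                 coupling_strength = coupling_strength,
                 coupling_sd = coupling_sd,
                 coupling_radius = coupling_radius,
                 coupling_lag = as.integer(coupling_lag),
                 thq_coupling_r = thq_coupling_r),
            class = "effect_spec")
}

#' Deterministic gray-matter probability map for a grid
#'
#' A smooth ellipsoidal "brain" of probabilities in `[0, 1]`: 1 deep inside,
#' falling to 0 at the edge of the field of view.
#'
#' @param grid A [volume_grid].
#' @return A [scalar_map] of kind `gm_prob`.
#' @export
gm_probability_map <- function(grid) {
  d <- grid$dims
  ii <- (seq_len(d[1]) - (d[1] + 1) / 2) / (d[1] / 2)
  jj <- (seq_len(d[2]) - (d[2] + 1) / 2) / (d[2] / 2)
  kk <- (seq_len(d[3]) - (d[3] + 1) / 2) / (d[3] / 2)
  # rounded-box superellipsoid (6-norm) so frontal seed regions near the
  # field-of-view corner still carry gray matter
  r6 <- outer(outer(ii^6, jj^6, "+"), kk^6, "+")^(1 / 6)
  prob <- pmin(1, pmax(0, 1.8 * (1 - r6)))
  scalar_map(array(prob, dim = d), grid, "gm_prob")
}

#' Inject a connectivity hub into a BOLD series
#'
#' Adds `gain` times a shared band-limited signal to voxels within
#' `radius` of `center`; the same signal is also mixed at low amplitude
#' (`gm_mix`) into all gray-matter voxels, so hub voxels acquire
#' supra-threshold correlations across gray matter. `gain = 0` returns the
#' input unchanged. Set `gm_mix = 0` when the shared signal is already part
#' of the series' background mixture.
#'
#' @param bold A [bold_series].
#' @param center MNI mm triple.
#' @param radius Sphere radius in mm (> 0).
#' @param gain Amplitude multiplier (>= 0).
#' @param shared_signal Numeric vector of length `n_volumes` (unit-scale).
#' @param gm_mask Optional [binary_mask] of gray matter receiving the
#'   low-amplitude mix (defaults to all voxels).
#' @param gm_mix Amplitude of the gray-matter-wide mix (default 0.3).
#' @return A [bold_series].
#' @export
inject_hub <- function(bold, center, radius, gain, shared_signal,
                       gm_mask = NULL, gm_mix = 0.3) {
  stopifnot(inherits(bold, "bold_series"), gain >= 0)
  if (radius <= 0) stop("radius must be positive")
  if (gain == 0) return(bold)
  stopifnot(length(shared_signal) == bold$n_volumes)
  sph <- sphere_mask(bold$grid, center, radius)
  d4 <- dim(bold$data)
  M <- matrix(bold$data, prod(d4[1:3]), d4[4])   # voxels x time view
  if (gm_mix > 0) {
    gm_idx <- if (is.null(gm_mask)) seq_len(nrow(M)) else mask_indices(gm_mask)
    M[gm_idx, ] <- M[gm_idx, ] + outer(rep(gm_mix, length(gm_idx)), shared_signal)
  }
  idx <- mask_indices(sph)
  M[idx, ] <- M[idx, ] + outer(rep(gain, length(idx)), shared_signal)
  bold_series(array(M, dim = d4), bold$grid, bold$tr_seconds)
}

#' Inject lagged directed coupling between two regions
#'
#' Target-sphere voxels receive `strength` times the source-sphere mean
#' signal delayed by `lag` volumes; the source is unchanged. `strength = 0`
#' is the identity. Overlapping source and target spheres are an error.
#'
#' @param bold A [bold_series].
#' @param source_center,target_center MNI mm triples.
#' @param radius Sphere radius in mm.
#' @param strength Coupling amplitude (>= 0).
#' @param lag Delay in volumes (>= 1).
#' @return A [bold_series].
#' @export
inject_directed_coupling <- function(bold, source_center, target_center,
                                     radius, strength, lag = 1) {
  stopifnot(inherits(bold, "bold_series"), strength >= 0, lag >= 1)
  if (strength == 0) return(bold)
  src <- sphere_mask(bold$grid, source_center, radius)
  tgt <- sphere_mask(bold$grid, target_center, radius)
  if (any(src$data & tgt$data)) stop("source and target spheres overlap")
  d4 <- dim(bold$data)
  M <- matrix(bold$data, prod(d4[1:3]), d4[4])   # voxels x time view
  s <- colMeans(M[mask_indices(src), , drop = FALSE])
  s <- s / stats::sd(s)
  lagged <- c(rep(0, lag), s[seq_len(length(s) - lag)])
  idx <- mask_indices(tgt)
  M[idx, ] <- M[idx, ] + outer(rep(strength, length(idx)), lagged)
  bold_series(array(M, dim = d4), bold$grid, bold$tr_seconds)
}

#' Attach clinical scores correlated with coupling strength
#'
#' Draws patient THQ scores as a linear-plus-noise function of the injected
#' coupling strengths so that the sample Pearson correlation lands within
#' +/- 0.15 of `target_r` (redrawing up to `max_tries` times), with mean and
#' SD near 49.5 +/- 15.5, clipped to the 0-100 scale. Control rows are
#' untouched (`thq` stays absent).
#'
#' @param records Subjects tibble with a `group` column.
#' @param coupling_strengths Per-patient coupling strengths, in patient row
#'   order.
#' @param target_r Target correlation in `[0, 1)` (default 0.5).
#' @param seed Optional RNG seed.
#' @param max_tries Redraw budget (default 50).
#' @return The records tibble with patient `thq` filled in.
#' @export
assign_clinical_scores <- function(records, coupling_strengths,
                                   target_r = 0.5, seed = NULL,
                                   max_tries = 50) {
  stopifnot(target_r >= 0, target_r < 1)
  if (!is.null(seed)) set.seed(seed)
  pat <- which(records$group == "tinnitus")
  n <- length(pat)
  if (n < 3) stop("need at least 3 patients")
  stopifnot(length(coupling_strengths) == n)
  constant <- stats::sd(coupling_strengths) == 0
  cs <- if (constant) rep(0, n) else as.numeric(scale(coupling_strengths))
  for (i in seq_len(max_tries)) {
    noise <- stats::rnorm(n)
    z <- target_r * cs + sqrt(1 - target_r^2) * as.numeric(scale(noise))
    thq <- pmin(100, pmax(0, round(49.5 + 15.5 * z, 1)))
    if (constant) break
    r_obs <- stats::cor(thq, coupling_strengths)
    if (abs(r_obs - target_r) <= 0.15) break
  }
  records$thq[pat] <- thq
  records
}

truncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# demographics drawn to match the target cohort's printed moments
draw_subjects <- function(n_patients, n_controls) {
  n <- n_patients + n_controls
  grp <- c(rep("tinnitus", n_patients), rep("control", n_controls))
  age <- c(truncnorm(n_patients, 50.8, 12.4, 26, 67),
           truncnorm(n_controls, 44.7, 15.4, 26, 70))
  sex <- c(sample(c("male", "female"), n_patients, TRUE, prob = c(9, 15) / 24),
           sample(c("male", "female"), n_controls, TRUE, prob = c(9, 13) / 22))
  edu <- c(round(truncnorm(n_patients, 12.3, 3.1, 8, 18)),
           round(truncnorm(n_controls, 13.4, 3.8, 8, 22)))
  dur <- c(round(truncnorm(n_patients, 46.5, 39.1, 6, 120)),
           rep(NA_real_, n_controls))
  hl <- truncnorm(n, 13.3, 2.5, 5, 24.9)
  hr <- truncnorm(n, 14.2, 3.5, 5, 24.9)
  tibble::tibble(
    subject_id = sprintf("sub-%02d", seq_len(n)),
    group = grp, age = age, sex = sex, education = edu,
    tinnitus_duration = dur, thq = NA_real_,
    hearing_left = hl, hearing_right = hr,
    max_translation = NA_real_, max_rotation = NA_real_,
    excluded = FALSE)
}

# one subject's baseline BOLD: smoothed AR(1) noise + shared GM network
# signals with random smooth spatial loadings
simulate_baseline_bold <- function(grid, n_volumes, tr, shared_signals,
                                   gm_mask, noise_ar = 0.3,
                                   noise_fwhm_mm = 6, loading_sd = 0.5) {
  d <- grid$dims
  V <- prod(d)
  # voxels-as-rows matrix view avoids transposes; AR(1) recursion over time
  M <- matrix(stats::rnorm(V * n_volumes), V, n_volumes)
  for (t in 2:n_volumes) M[, t] <- M[, t] + noise_ar * M[, t - 1]
  arr <- smooth_gaussian(array(M, dim = c(d, n_volumes)), noise_fwhm_mm,
                         voxel_size = grid$voxel_size)
  # rescale so voxel noise has roughly unit SD after smoothing
  M <- matrix(arr, V, n_volumes) / stats::sd(arr)
  gm_idx <- mask_indices(gm_mask)
  for (s in shared_signals) {
    load <- smooth_gaussian(array(stats::rnorm(V), dim = d), noise_fwhm_mm,
                            voxel_size = grid$voxel_size)
    load <- load / stats::sd(load) * loading_sd
    M[gm_idx, ] <- M[gm_idx, ] + outer(load[gm_idx], s)
  }
  bold_series(array(M, dim = c(d, n_volumes)), grid, tr)
}

#' Generate a synthetic two-group rs-fMRI cohort
#'
#' Produces demographics matched to the target cohort's summary moments,
#' per-subject 4D BOLD with the generator's noise model, the gray-matter
#' probability map, per-subject motion parameters (optionally one patient
#' above the exclusion limits), injected patient-only hub and directed
#' coupling effects, and THQ scores correlated with coupling strength.
#' Fully deterministic given `seed`.
#'
#' @param n_patients,n_controls Group sizes (defaults 24 and 22).
#' @param grid A [volume_grid] (default [default_grid()]).
#' @param n_volumes Acquired volumes per subject (default 240).
#' @param effects An [effect_spec].
#' @param seed Integer RNG seed.
#' @param tr_seconds Repetition time (default 2).
#' @param motion_outlier Give the last patient above-limit motion so the
#'   exclusion path is exercised (default `FALSE`).
#' @param dir Optional directory: when given, BOLD volumes, the GM map, the
#'   subjects CSV, motion files and the ground-truth manifest are written
#'   there and `bold` holds file paths instead of in-memory series.
#' @return A `cohort` list: `subjects` tibble, `bold` (list of
#'   [bold_series] or file paths), `gm_prob` map, `motion` (list of
#'   `motion_trace`), `manifest` (injected ground truth).
#' @export
generate_cohort <- function(n_patients = 24, n_controls = 22,
                            grid = default_grid(), n_volumes = 240,
                            effects = effect_spec(), seed = 1,
                            tr_seconds = 2, motion_outlier = FALSE,
                            dir = NULL) {
  stopifnot(n_patients > 0, n_controls > 0, n_volumes >= 20)
  set.seed(seed)
  # validate hub centres are inside the grid
  hub_r <- c(-1, 1)
  for (s in hub_r)
    mm_to_voxel(grid, effects$hub_center * c(s, 1, 1))
  gm_prob <- gm_probability_map(grid)
  gm_mask <- gm_mask_from_prob(gm_prob, 0.20)
  subjects <- draw_subjects(n_patients, n_controls)
  n <- nrow(subjects)
  pat_rows <- which(subjects$group == "tinnitus")

  coupling <- pmax(0.1, stats::rnorm(n_patients, effects$coupling_strength,
                                     effects$coupling_sd))
  if (effects$coupling_strength == 0) coupling <- rep(0, n_patients)
  if (n_patients >= 3) {
    subjects <- assign_clinical_scores(subjects, coupling,
                                       effects$thq_coupling_r)
  } else {
    subjects$thq[pat_rows] <- pmin(100, pmax(0, stats::rnorm(n_patients, 49.5, 15.5)))
  }

  n_signals <- sample(3:5, 1)
  shared <- lapply(seq_len(n_signals), function(i)
    band_limited_signal(n_volumes, tr_seconds))
  hub_signal <- shared[[1]]   # mixed into all subjects' GM at low amplitude

  left_hub <- effects$hub_center * c(-1, 1, 1)
  motion <- vector("list", n)
  bolds <- vector("list", n)
  for (i in seq_len(n)) {
    b <- simulate_baseline_bold(grid, n_volumes, tr_seconds, shared, gm_mask)
    # low-amplitude hub-signal mix shared by BOTH groups (keeps groups
    # exchangeable when effects are zero)
    b <- inject_hub(b, effects$hub_center, effects$hub_radius, 0.15,
                    hub_signal, gm_mask, gm_mix = 0)
    b <- inject_hub(b, left_hub, effects$hub_radius, 0.15, hub_signal,
                    gm_mask, gm_mix = 0)
    if (i %in% pat_rows) {
      j <- match(i, pat_rows)
      if (effects$hub_gain > 0) {
        b <- inject_hub(b, effects$hub_center, effects$hub_radius,
                        effects$hub_gain, hub_signal, gm_mask, gm_mix = 0)
        b <- inject_hub(b, left_hub, effects$hub_radius, effects$hub_gain,
                        hub_signal, gm_mask, gm_mix = 0)
      }
      if (coupling[j] > 0) {
        for (tgt in effects$coupling_targets) {
          b <- inject_directed_coupling(b, left_hub, tgt,
                                        effects$coupling_radius, coupling[j],
                                        effects$coupling_lag)
        }
      }
    }
    bolds[[i]] <- b
    # small realistic motion; optionally one patient above limits
    amp <- stats::runif(1, 0.1, 0.8)
    tr_m <- matrix(stats::rnorm(n_volumes * 3, 0, amp / 3), n_volumes, 3)
    ro_m <- matrix(stats::rnorm(n_volumes * 3, 0, amp / 3), n_volumes, 3)
    if (motion_outlier && i == pat_rows[length(pat_rows)])
      tr_m[n_volumes %/% 2, 1] <- 2.6
    motion[[i]] <- motion_trace(tr_m, ro_m)
    subjects$max_translation[i] <- max(abs(tr_m))
    subjects$max_rotation[i] <- max(abs(ro_m))
  }
  qc <- dplyr::bind_rows(lapply(motion, motion_qc))
  subjects$excluded <- !qc$pass

  manifest <- list(
    seed = seed, n_patients = n_patients, n_controls = n_controls,
    n_volumes = n_volumes, tr_seconds = tr_seconds,
    grid = list(dims = grid$dims, affine = grid$affine),
    effects = unclass(effects), coupling_strengths = coupling,
    hub_centers = list(left_hub, effects$hub_center),
    n_shared_signals = n_signals)

  cohort <- structure(
    list(subjects = subjects, bold = bolds, gm_prob = gm_prob,
         motion = motion, manifest = manifest, grid = grid),
    class = "cohort")
  if (!is.null(dir)) cohort <- write_cohort(cohort, dir)
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients + %d controls, %s grid, %d volumes\n",
              sum(x$subjects$group == "tinnitus"),
              sum(x$subjects$group == "control"),
              paste(x$grid$dims, collapse = "x"),
              x$manifest$n_volumes))
  invisible(x)
}

#' Write a cohort to disk
#'
#' NIfTI BOLD volumes (one per subject), the GM probability map, 6-column
#' motion files, the subjects CSV and a JSON ground-truth manifest.
#'
#' @param cohort A `cohort` from [generate_cohort].
#' @param dir Destination directory (created if needed).
#' @return The cohort with `bold` replaced by file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(cohort$bold))
  for (i in seq_along(cohort$bold)) {
    id <- cohort$subjects$subject_id[i]
    paths[i] <- file.path(dir, paste0(id, "_bold.nii.gz"))
    if (inherits(cohort$bold[[i]], "bold_series"))
      write_volume(cohort$bold[[i]], paths[i])
    mt <- cohort$motion[[i]]
    utils::write.table(cbind(mt$translations, mt$rotations),
                       file.path(dir, paste0(id, "_motion.txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  write_volume(cohort$gm_prob, file.path(dir, "gm_prob.nii.gz"))
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cohort$bold <- as.list(paths)
  cohort
}

#' Read a cohort written by [write_cohort]
#'
#' @param dir Cohort directory.
#' @param in_memory Load BOLD volumes into memory (default `FALSE`: keep
#'   paths; the pipeline streams subjects one at a time).
#' @return A `cohort`.
#' @export
read_cohort <- function(dir, in_memory = FALSE) {
  subjects <- tibble::as_tibble(utils::read.csv(file.path(dir, "subjects.csv")))
  gm_prob <- read_volume(file.path(dir, "gm_prob.nii.gz"), kind = "gm_prob")
  paths <- file.path(dir, paste0(subjects$subject_id, "_bold.nii.gz"))
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing BOLD files: ", paste(subjects$subject_id[missing], collapse = ", "))
  motion <- lapply(file.path(dir, paste0(subjects$subject_id, "_motion.txt")),
                   read_motion_trace)
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else NULL
  bolds <- if (in_memory) lapply(paths, read_volume) else as.list(paths)
  structure(list(subjects = subjects, bold = bolds, gm_prob = gm_prob,
                 motion = motion, manifest = manifest, grid = gm_prob$grid),
            class = "cohort")
}
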