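# End-to-end study pipeline: preprocessing, per-subject degree and Granger
# maps, Monte-Carlo-corrected group inference, and clinical correlations.
# `run_study` works on an in-memory or on-disk cohort; `run_pipeline` is the
# file-based entry point that also writes all outputs.

stage_log <- function(stage, t0) {
  message(sprintf("[%s] done in %.1f s", stage,
                  as.numeric(Sys.time()) - t0))
}

get_bold <- function(cohort, i) {
  b <- cohort$bold[[i]]
  if (inherits(b, "bold_series")) b else read_volume(b)
}

#' Default mirrored seed coordinates
#'
#' The left/right superior-frontal seed pair at (+/-18, 42, 27) mm used for
#' directed-connectivity mapping.
#'
#' @param effects_center Right-hemisphere peak (mm); mirrored across x.
#' @return Named list with `left` and `right` MNI triples.
#' @export
default_seeds <- function(effects_center = c(18, 42, 27)) {
  list(left = effects_center * c(-1, 1, 1), right = effects_center)
}

cluster_overlaps_sphere <- function(voxels, grid, center, radius) {
  if (nrow(voxels) == 0) return(FALSE)
  mm <- voxel_to_mm(grid, voxels)
  any((mm[, 1] - center[1])^2 + (mm[, 2] - center[2])^2 +
        (mm[, 3] - center[3])^2 <= radius^2)
}

#' Run the full analysis on a cohort
#'
#' Stages: motion QC and exclusion; preprocessing (discard, smooth,
#' detrend, band-pass); per-subject degree-centrality z maps (block
#' computation) and seed-based Granger z maps; Monte-Carlo cluster
#' threshold; group-level one-sample maps, combined-mask two-sample GLM
#' with age/sex/education covariates, corrected clusters per direction;
#' per-seed Granger group contrasts; covariate-corrected correlations of
#' significant-cluster means with THQ and duration (Bonferroni over all
#' tests); demographics table.
#'
#' @param cohort A `cohort` from [generate_cohort] or [read_cohort].
#' @param config A [study_config].
#' @param seeds Named list of seed MNI coordinates (default mirrored
#'   frontal peaks at `(+/-18, 42, 27)`).
#' @param mc Optional precomputed `mc_result` for the analysis mask (e.g.
#'   when analysing several cohorts that share one grid and mask); computed
#'   from scratch when `NULL`.
#' @param verbose Emit per-stage timing messages (default `TRUE`).
#' @return A `study_result` list; see Details in the package vignette.
#' @export
run_study <- function(cohort, config = study_config(),
                      seeds = default_seeds(), mc = NULL, verbose = TRUE) {
  say <- if (verbose) stage_log else function(...) invisible()
  set.seed(config$rng_seed)

  # ---- QC / exclusion ----
  t0 <- as.numeric(Sys.time())
  qc <- dplyr::bind_rows(lapply(cohort$motion, function(m)
    motion_qc(m, config$motion_limit_mm, config$motion_limit_deg)))
  qc$subject_id <- cohort$subjects$subject_id
  keep <- which(qc$pass)
  excluded <- cohort$subjects$subject_id[!qc$pass]
  if (length(excluded))
    message("excluded for motion: ", paste(excluded, collapse = ", "))
  subjects <- cohort$subjects[keep, , drop = FALSE]
  subjects$excluded <- FALSE
  n_pat <- sum(subjects$group == "tinnitus")
  n_ctl <- sum(subjects$group == "control")
  say("qc", t0)

  # ---- mask ----
  gm_mask <- gm_mask_from_prob(cohort$gm_prob, config$gm_prob_threshold)

  # ---- per-subject maps ----
  t0 <- as.numeric(Sys.time())
  dc_z <- vector("list", length(keep))
  gc_z <- lapply(seeds, function(s) list(xy = vector("list", length(keep)),
                                         yx = vector("list", length(keep))))
  gm_idx <- mask_indices(gm_mask)
  # seed-sphere positions within the mask column order
  seed_cols <- lapply(seeds, function(s) {
    sph <- sphere_mask(gm_mask$grid, s, config$seed_radius_mm, gm_mask)
    if (sph$n_true == 0) stop("seed sphere does not intersect the mask")
    match(mask_indices(sph), gm_idx)
  })
  for (ii in seq_along(keep)) {
    b <- get_bold(cohort, keep[ii])
    stop_if_grid_mismatch(b$grid, gm_mask$grid)
    b <- smooth_gaussian(discard_initial(b, config$discard_volumes),
                         config$fwhm_mm)
    tr <- b$tr_seconds
    X <- detrend_matrix(as_voxel_matrix(b)[, gm_idx, drop = FALSE])
    bc <- bandpass_and_compress(X, tr, config$band[1], config$band[2])
    X <- bc$series
    # degree on the spectral representation: identical correlations,
    # fewer rows (band-limited data)
    Xs <- scale_unit(bc$compressed, center = FALSE)
    sums <- deg_block_sums(Xs, config$r_threshold, 2048L)
    D <- if (config$dc_flavor == "binarized") sums$binarized else sums$weighted
    dres <- degree_from_raw(D, gm_mask, config$dc_flavor,
                            config$r_threshold, attr(Xs, "zero_variance"))
    dc_z[[ii]] <- dres$z
    for (sn in names(seeds)) {
      sv <- rowMeans(X[, seed_cols[[sn]], drop = FALSE])
      seed_obj <- structure(list(values = sv, center = seeds[[sn]],
                                 radius_mm = config$seed_radius_mm,
                                 n_voxels = length(seed_cols[[sn]])),
                            class = "seed_series")
      g <- gc_maps_from_matrix(X, seed_obj, gm_mask, config$gc_order)
      gc_z[[sn]]$xy[[ii]] <- g$z_xy
      gc_z[[sn]]$yx[[ii]] <- g$z_yx
    }
  }
  say("subject_maps", t0)

  # ---- Monte-Carlo cluster threshold ----
  t0 <- as.numeric(Sys.time())
  if (is.null(mc)) {
    mc <- estimate_cluster_threshold(
      gm_mask, config$voxel_p, config$corrected_alpha, config$n_mc_sims,
      config$fwhm_mm, config$connect_radius_mm,
      seed = config$rng_seed + 1000L)
  }
  say("cluster_mc", t0)

  # ---- DC group inference ----
  t0 <- as.numeric(Sys.time())
  pat_idx <- subjects$group == "tinnitus"
  one_pat <- one_sample_map(dc_z[pat_idx], gm_mask)
  one_ctl <- one_sample_map(dc_z[!pat_idx], gm_mask)
  thr_one <- stats::qt(1 - config$voxel_p,
                       c(attr(one_pat, "df"), attr(one_ctl, "df")))
  combined <- combine_group_masks(list(one_pat, one_ctl), gm_mask, mc,
                                  thr_one, config$connect_radius_mm)
  X <- design_matrix(subjects)
  dc_t <- two_sample_glm_map(dc_z, X, combined)
  thr_two <- stats::qt(1 - config$voxel_p, attr(dc_t, "df"))
  dc_pos <- apply_correction(dc_t, combined, thr_two, mc,
                             config$connect_radius_mm, "positive")
  dc_neg <- apply_correction(dc_t, combined, thr_two, mc,
                             config$connect_radius_mm, "negative")
  say("dc_group", t0)

  # ---- GC group inference ----
  t0 <- as.numeric(Sys.time())
  gc_group <- list()
  for (sn in names(seeds)) {
    seed_sph <- sphere_mask(gm_mask$grid, seeds[[sn]], config$seed_radius_mm)
    gmask <- binary_mask(gm_mask$data & !seed_sph$data, gm_mask$grid)
    res <- list()
    for (dir in c("xy", "yx")) {
      t_map <- two_sample_glm_map(gc_z[[sn]][[dir]], X, gmask)
      thr <- stats::qt(1 - config$voxel_p, attr(t_map, "df"))
      res[[dir]] <- list(
        t_map = t_map,
        pos = apply_correction(t_map, gmask, thr, mc,
                               config$connect_radius_mm, "positive"),
        neg = apply_correction(t_map, gmask, thr, mc,
                               config$connect_radius_mm, "negative"))
    }
    gc_group[[sn]] <- res
  }
  say("gc_group", t0)

  # ---- correlations with clinical scores ----
  t0 <- as.numeric(Sys.time())
  cluster_values <- list()
  region_tables <- list()
  add_clusters <- function(tab, maps, prefix) {
    if (nrow(tab) == 0) return()
    for (r in seq_len(nrow(tab))) {
      cid <- sprintf("%s_%d", prefix, tab$label[r])
      cluster_values[[cid]] <<- cluster_mean_values(maps[pat_idx],
                                                    tab$voxels[[r]])
      region_tables[[cid]] <<- tab[r, ]
    }
  }
  add_clusters(dc_pos$clusters, dc_z, "dc_pos")
  add_clusters(dc_neg$clusters, dc_z, "dc_neg")
  for (sn in names(seeds)) {
    add_clusters(gc_group[[sn]]$xy$pos$clusters, gc_z[[sn]]$xy,
                 sprintf("gc_%s_xy_pos", sn))
    add_clusters(gc_group[[sn]]$yx$pos$clusters, gc_z[[sn]]$yx,
                 sprintf("gc_%s_yx_pos", sn))
  }
  patients <- subjects[pat_idx, , drop = FALSE]
  correlations <- if (length(cluster_values) > 0 && nrow(patients) > 5) {
    correlate_clusters(cluster_values, patients)
  } else {
    empty <- tibble::tibble(cluster_id = character(),
                            clinical_variable = character(), r = numeric(),
                            p_raw = numeric(), n = integer(),
                            p_bonferroni = numeric())
    class(empty) <- c("correlation_report", class(empty))
    empty
  }
  demo <- demographics_table(subjects)
  say("correlate", t0)

  structure(
    list(subjects = subjects, excluded = excluded, qc = qc,
         n_patients = n_pat, n_controls = n_ctl,
         gm_mask = gm_mask, combined_mask = combined, mc = mc,
         dc = list(z_maps = dc_z, one_sample = list(tinnitus = one_pat,
                                                    control = one_ctl),
                   group_t = dc_t, pos = dc_pos, neg = dc_neg),
         gc = gc_group, gc_z = gc_z, seeds = seeds,
         cluster_values = cluster_values,
         correlations = correlations, demographics = demo,
         config = config),
    class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d patients + %d controls (excluded: %d)\n",
              x$n_patients, x$n_controls, length(x$excluded)))
  cat(sprintf("  min cluster size: %d voxels\n", x$mc$min_cluster_size))
  cat(sprintf("  DC clusters (+/-): %d / %d\n", nrow(x$dc$pos$clusters),
              nrow(x$dc$neg$clusters)))
  for (sn in names(x$gc))
    cat(sprintf("  GC %s seed->brain clusters (+): %d\n", sn,
                nrow(x$gc[[sn]]$xy$pos$clusters)))
  cat(sprintf("  correlation tests: %d\n", nrow(x$correlations)))
  invisible(x)
}

#' Evaluate recovery of injected effects
#'
#' Checks a `study_result` against a synthetic cohort's ground-truth
#' manifest: (a) the largest corrected positive between-group DC cluster
#' overlaps an injected hub sphere; (b) some corrected positive seed-to-
#' brain contrast cluster (left seed, x->y) overlaps an injected coupling
#' target; (c) among THQ correlations of coupling-target clusters, the one
#' with the smallest p has the sign of the generator's target correlation.
#'
#' @param result A `study_result`.
#' @param cohort The synthetic `cohort` that produced it.
#' @return A one-row tibble of logicals `hub_recovered`,
#'   `coupling_recovered`, `thq_sign_ok`.
#' @export
evaluate_recovery <- function(result, cohort) {
  man <- cohort$manifest
  eff <- man$effects
  grid <- result$gm_mask$grid
  hub_centers <- list(unlist(eff$hub_center) * c(-1, 1, 1),
                      unlist(eff$hub_center))
  # (a) hub
  dc_tab <- result$dc$pos$clusters
  hub_ok <- FALSE
  if (nrow(dc_tab) > 0) {
    top <- dc_tab$voxels[[1]]
    hub_ok <- any(vapply(hub_centers, function(h)
      cluster_overlaps_sphere(top, grid, h, eff$hub_radius), logical(1)))
  }
  # (b) coupling at targets (left seed drives them)
  targets <- eff$coupling_targets
  if (is.matrix(targets)) targets <- asplit(targets, 1)
  gc_tab <- result$gc$left$xy$pos$clusters
  target_hits <- character()
  coupling_ok <- FALSE
  if (nrow(gc_tab) > 0) {
    for (r in seq_len(nrow(gc_tab))) {
      hit <- any(vapply(targets, function(tg)
        cluster_overlaps_sphere(gc_tab$voxels[[r]], grid, unlist(tg),
                                eff$coupling_radius + 3), logical(1)))
      if (hit) {
        coupling_ok <- TRUE
        target_hits <- c(target_hits, sprintf("gc_left_xy_pos_%d", gc_tab$label[r]))
      }
    }
  }
  # (c) THQ correlation sign at target clusters
  thq_ok <- FALSE
  cr <- result$correlations
  if (length(target_hits) > 0 && nrow(cr) > 0) {
    rows <- cr[cr$cluster_id %in% target_hits & cr$clinical_variable == "thq", ]
    if (nrow(rows) > 0) {
      best <- rows[which.min(rows$p_raw), ]
      thq_ok <- sign(best$r) == sign(eff$thq_coupling_r)
    }
  }
  tibble::tibble(hub_recovered = hub_ok, coupling_recovered = coupling_ok,
                 thq_sign_ok = thq_ok)
}

#' File-based pipeline entry point
#'
#' Reads a cohort directory (BOLD NIfTIs, GM map, subjects CSV, motion
#' files), runs [run_study] and writes all outputs: group statistic maps,
#' corrected cluster tables (CSV mirroring the peak-coordinate/extent
#' layout), the correlation and demographics reports, and a
#' machine-readable `summary.json` recording thresholds, clusters and
#' correlations. Deterministic given `config$rng_seed`.
#'
#' @param config A [study_config].
#' @param data_dir Cohort directory (see [write_cohort]).
#' @param out_dir Output directory (created if needed).
#' @param seeds Seed coordinates as in [run_study].
#' @return The `study_result`, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(config = study_config(), data_dir, out_dir,
                         seeds = default_seeds()) {
  cohort <- read_cohort(data_dir)
  res <- run_study(cohort, config, seeds = seeds)
  write_study_result(res, out_dir)
  invisible(res)
}

cluster_table_csv <- function(tab) {
  tab <- tab[, c("label", "n_voxels", "peak_stat", "peak_x", "peak_y",
                 "peak_z")]
  tab$peak_stat <- round(tab$peak_stat, 4)
  tab
}

#' Write a study result to a directory
#'
#' @param res A `study_result`.
#' @param out_dir Destination directory.
#' @return `out_dir`, invisibly.
#' @export
write_study_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(res$dc$group_t, file.path(out_dir, "dc_group_t.nii.gz"))
  write_volume(res$dc$pos$map, file.path(out_dir, "dc_group_t_corrected_pos.nii.gz"))
  utils::write.csv(cluster_table_csv(res$dc$pos$clusters),
                   file.path(out_dir, "dc_clusters_pos.csv"), row.names = FALSE)
  utils::write.csv(cluster_table_csv(res$dc$neg$clusters),
                   file.path(out_dir, "dc_clusters_neg.csv"), row.names = FALSE)
  for (sn in names(res$gc)) {
    for (dir in c("xy", "yx")) {
      g <- res$gc[[sn]][[dir]]
      write_volume(g$t_map,
                   file.path(out_dir, sprintf("gc_%s_%s_group_t.nii.gz", sn, dir)))
      utils::write.csv(cluster_table_csv(g$pos$clusters),
                       file.path(out_dir, sprintf("gc_%s_%s_clusters_pos.csv", sn, dir)),
                       row.names = FALSE)
    }
  }
  utils::write.csv(res$correlations, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(res$demographics, file.path(out_dir, "demographics.csv"),
                   row.names = FALSE)
  summary <- list(
    config = unclass(res$config),
    n_patients = res$n_patients, n_controls = res$n_controls,
    excluded = res$excluded,
    min_cluster_size = res$mc$min_cluster_size,
    mask_voxels = res$gm_mask$n_true,
    combined_mask_voxels = res$combined_mask$n_true,
    dc_clusters = list(
      positive = as.data.frame(cluster_table_csv(res$dc$pos$clusters)),
      negative = as.data.frame(cluster_table_csv(res$dc$neg$clusters))),
    gc_clusters = lapply(res$gc, function(s) list(
      xy_positive = as.data.frame(cluster_table_csv(s$xy$pos$clusters)),
      yx_positive = as.data.frame(cluster_table_csv(s$yx$pos$clusters)))),
    correlations = as.data.frame(res$correlations),
    n_correlation_tests = nrow(res$correlations))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(out_dir)
}
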