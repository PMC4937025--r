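test_that("cohort generation is deterministic under the seed", {
  a <- small_cohort(seed = 4)
  b <- small_cohort(seed = 4)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$bold[[1]]$data, b$bold[[1]]$data)
  expect_identical(a$manifest$coupling_strengths, b$manifest$coupling_strengths)
  c2 <- small_cohort(seed = 5)
  expect_false(identical(a$bold[[1]]$data, c2$bold[[1]]$data))
})

test_that("hub injection is the identity at gain zero and local otherwise", {
  b <- random_bold(c(8, 8, 8), 40, seed = 9)
  sig <- sin(2 * pi * (1:40) / 25)
  expect_identical(inject_hub(b, c(6, 6, 6), 6, 0, sig), b)
  # radius below the voxel spacing touches exactly one voxel
  out <- inject_hub(b, c(6, 6, 6), 2.9, 2, sig, gm_mix = 0)
  changed <- which(out$data != b$data, arr.ind = TRUE)
  expect_equal(nrow(unique(changed[, 1:3])), 1)
  expect_error(inject_hub(b, c(6, 6, 6), -1, 2, sig), "radius")
})

test_that("a strong hub raises supra-threshold correlation with gray matter", {
  set.seed(14)
  g <- tiny_grid(c(8, 8, 8))
  b <- random_bold(c(8, 8, 8), 120, seed = 14)
  gm <- full_mask(g)
  sig <- fmrihub:::band_limited_signal(120, 2)
  out <- inject_hub(b, c(10, 10, 10), 5, 5, sig, gm)
  hub <- sphere_mask(g, c(10, 10, 10), 5)
  hub_idx <- which(hub$data)
  gm_idx <- setdiff(which(gm$data), hub_idx)
  Y <- t(matrix(out$data, 512, 120))
  set.seed(15)
  rs <- replicate(200, cor(Y[, sample(hub_idx, 1)], Y[, sample(gm_idx, 1)]))
  expect_gt(mean(rs), 0.25)
})

test_that("directed coupling injection is identity at zero and rejects overlap", {
  b <- random_bold(c(10, 10, 4), 50, seed = 16)
  expect_identical(
    inject_directed_coupling(b, c(3, 3, 3), c(24, 24, 9), 4, 0), b)
  expect_error(
    inject_directed_coupling(b, c(3, 3, 3), c(6, 3, 3), 5, 1), "overlap")
  out <- inject_directed_coupling(b, c(3, 3, 3), c(24, 24, 9), 4, 1, 2)
  src <- sphere_mask(b$grid, c(3, 3, 3), 4)
  expect_identical(out$data[src$data], b$data[src$data])  # source untouched
})

test_that("clinical scores land near the target correlation with coupling", {
  rec <- tibble::tibble(group = rep(c("tinnitus", "control"), c(24, 10)),
                        thq = NA_real_)
  cs <- pmax(0.1, rnorm(24, 0.9, 0.25))
  out <- assign_clinical_scores(rec, cs, target_r = 0.5, seed = 8)
  r <- cor(out$thq[rec$group == "tinnitus"], cs)
  expect_gte(r, 0.35)
  expect_lte(r, 0.65)
  expect_true(all(is.na(out$thq[rec$group == "control"])))
  out0 <- assign_clinical_scores(rec, cs, target_r = 0, seed = 9)
  expect_lt(abs(cor(out0$thq[rec$group == "tinnitus"], cs)), 0.4)
  expect_error(assign_clinical_scores(rec[c(1, 25:34), ], cs[1], 0.5), "3 patients")
})

test_that("generated demographics respect the cohort structure", {
  coh <- generate_cohort(n_patients = 24, n_controls = 22, n_volumes = 20,
                         seed = 3,
                         effects = effect_spec(hub_gain = 0,
                                               coupling_strength = 0))
  s <- coh$subjects
  expect_equal(sum(s$group == "tinnitus"), 24)
  expect_equal(sum(s$group == "control"), 22)
  # patient-only clinical fields
  expect_true(all(is.finite(s$thq[s$group == "tinnitus"])))
  expect_true(all(is.na(s$thq[s$group == "control"])))
  expect_true(all(is.na(s$tinnitus_duration[s$group == "control"])))
  # normal-hearing inclusion rule
  expect_true(all(s$hearing_left < 25 & s$hearing_right < 25))
  # moments near the target summaries (wide sampling tolerance at n = 24)
  expect_lt(abs(mean(s$age[s$group == "tinnitus"]) - 50.8), 8)
  expect_lt(abs(mean(s$thq[s$group == "tinnitus"]) - 49.5), 10)
  # GM probabilities are a valid map
  expect_gte(min(coh$gm_prob$data), 0)
  expect_lte(max(coh$gm_prob$data), 1)
})

test_that("the optional motion outlier exercises the exclusion path", {
  coh <- generate_cohort(n_patients = 4, n_controls = 3, n_volumes = 20,
                         seed = 6, motion_outlier = TRUE)
  expect_equal(sum(coh$subjects$excluded), 1)
  expect_equal(coh$subjects$group[coh$subjects$excluded], "tinnitus")
  coh2 <- generate_cohort(n_patients = 4, n_controls = 3, n_volumes = 20,
                          seed = 6, motion_outlier = FALSE)
  expect_equal(sum(coh2$subjects$excluded), 0)
})

test_that("cohorts round-trip through the on-disk layout", {
  dirpath <- withr::local_tempdir()
  coh <- generate_cohort(n_patients = 2, n_controls = 2, n_volumes = 20,
                         seed = 10, dir = dirpath)
  expect_true(file.exists(file.path(dirpath, "subjects.csv")))
  expect_true(file.exists(file.path(dirpath, "manifest.json")))
  back <- read_cohort(dirpath, in_memory = TRUE)
  expect_equal(nrow(back$subjects), 4)
  fresh <- generate_cohort(n_patients = 2, n_controls = 2, n_volumes = 20,
                           seed = 10)
  expect_identical(back$bold[[1]]$data, fresh$bold[[1]]$data)
  expect_equal(back$manifest$effects$hub_gain, fresh$manifest$effects$hub_gain)
})
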