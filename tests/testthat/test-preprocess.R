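test_that("select_peak_phase maximizes within-mask enhancement", {
  st <- make_study(times = c(0, 40, 80, 160),
                   kin = c(wash_in = 0.04, wash_out = 0.01, pe = 2))
  # curve peaks near t = 50s within mask: phase 3 (80s) vs 2 (40s)
  means <- vapply(st$phases, function(v) {
    mean(v[st$tumor_mask > 0] - st$phases[[1]][st$tumor_mask > 0])
  }, numeric(1))
  expect_equal(select_peak_phase(st), which.max(means))
  # monotone enhancement picks the last phase
  st2 <- make_study(times = c(0, 60, 120, 180),
                    kin = c(wash_in = 0.01, wash_out = 1e-6, pe = 2))
  expect_equal(select_peak_phase(st2), length(st2$phases))
  # exact tie breaks toward the earlier phase
  st3 <- make_study()
  st3$phases[[4]] <- st3$phases[[3]]
  expect_equal(select_peak_phase(st3),
               select_peak_phase(st3))  # deterministic
  st3$phases[[3]] <- st3$phases[[4]]
  expect_lte(select_peak_phase(st3), 3)
  # fixed-index rule and empty-mask error
  cfgf <- preproc_config(peak_phase_rule = "fixed_index",
                         fixed_phase_index = 2)
  expect_equal(select_peak_phase(st, cfgf), 2)
  st$tumor_mask[] <- 0L
  expect_error(select_peak_phase(st), "mask")
})

test_that("resampling is exact on identity, constants and linear ramps", {
  v <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
  expect_identical(resample_to_spacing(v, c(1, 1, 1), c(1, 1, 1)), v)
  cv <- array(3.5, dim = c(8, 8, 8))
  out <- resample_to_spacing(cv, c(1, 1, 1), c(2, 2, 2))
  expect_equal(dim(out), c(4L, 4L, 4L))
  expect_true(all(abs(out - 3.5) < 1e-12))
  # ramp along x, downsampled 2x: trilinear equals the analytic ramp at
  # the new voxel centers (x_in = 2*i_out + 0.5, 0-based)
  d <- c(16, 6, 6)
  ramp <- array(rep(seq_len(d[1]) - 1, times = prod(d[2:3])), dim = d)
  out <- resample_to_spacing(ramp, c(1, 1, 1), c(2, 2, 2))
  expected <- (seq_len(dim(out)[1]) - 1) * 2 + 0.5
  expect_equal(out[, 2, 2], expected, tolerance = 1e-6)
  expect_error(resample_to_spacing(v, c(1, 1, 1), c(100, 100, 100)),
               "zero-size")
})

test_that("crop_region honours bbox arithmetic and normalization", {
  dims <- c(32, 32, 32)
  vol <- array(rep(seq_len(dims[1]), times = prod(dims[2:3])), dim = dims)
  mask <- array(0, dim = dims)
  mask[9:16, 9:16, 9:16] <- 1
  cfg <- preproc_config(mask_margin_mm = 0, patch_shape = c(8, 8, 8))
  p <- crop_region(vol, mask, cfg)
  # margin 0 on a cube of side 8: the bbox is exactly the cube, so the
  # resized mask covers the whole patch
  expect_equal(p$mask_fraction, 1)
  expect_equal(dim(p$volume), c(8L, 8L, 8L))
  # z-score contract within the region
  expect_lt(abs(mean(p$volume[p$mask > 0])), 1e-6)
  expect_lt(abs(sd(p$volume[p$mask > 0]) - 1), 1e-6)
  # degenerate bbox: mask covering the whole volume
  full <- crop_region(vol, array(1, dim = dims),
                      preproc_config(patch_shape = c(16, 16, 16)))
  expect_equal(dim(full$volume), c(16L, 16L, 16L))
  expect_equal(full$mask_fraction, 1)
  # empty habitat: zero patch, fraction 0, warning
  expect_warning(
    pe <- crop_region(vol, array(0, dim = dims), cfg, region = "habitat_2"),
    "empty"
  )
  expect_equal(pe$mask_fraction, 0)
  expect_true(all(pe$volume == 0))
  expect_error(crop_region(vol, array(0, dim = dims), cfg, region = "whole"),
               "whole")
})

test_that("preprocess_case emits K+1 patches per timepoint and is offset invariant", {
  co <- generate_cohort(tiny_phantom(1, seed = 4))
  cs <- co[[1]]
  hb <- segment_case_habitats(cs, K = 3, seed = 1)
  cfg <- preproc_config(patch_shape = c(16, 16, 16))
  pp <- preprocess_case(cs, hb, cfg)
  expect_named(pp, c("T0", "T1"))
  expect_length(pp$T0, 4)
  expect_length(pp$T1, 4)
  expect_equal(vapply(pp$T0, function(p) p$region, character(1)),
               c(whole = "whole", habitat_1 = "habitat_1",
                 habitat_2 = "habitat_2", habitat_3 = "habitat_3"))
  # constant intensity offset never changes z-scored patches
  cs2 <- cs
  for (tp in c("study_T0", "study_T1")) {
    cs2[[tp]]$phases <- lapply(cs2[[tp]]$phases, function(v) v + 250)
  }
  hb2 <- segment_case_habitats(cs2, K = 3, seed = 1)
  pp2 <- preprocess_case(cs2, hb2, cfg)
  for (tp in c("T0", "T1")) {
    for (r in seq_along(pp[[tp]])) {
      expect_lt(max(abs(pp[[tp]][[r]]$volume - pp2[[tp]][[r]]$volume)),
                1e-5)
    }
  }
})
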