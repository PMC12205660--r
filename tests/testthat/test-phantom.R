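test_that("enhancement_curve has the documented shape and closed-form peak", {
  expect_equal(enhancement_curve(0, 0.03, 0.002, 1.5), 0)
  expect_error(enhancement_curve(-1, 0.03, 0.002, 1.5), "negative")
  expect_true(all(enhancement_curve(seq(0, 600, 5), 0.03, 0.002, 1.5) >= 0))
  # wash_out -> 0 limit: monotone nondecreasing with asymptote pe
  e <- enhancement_curve(seq(0, 2000, 10), 0.03, 1e-12, 1.5)
  expect_true(all(diff(e) >= -1e-8))
  expect_equal(e[length(e)], 1.5, tolerance = 1e-3)
  # dense-grid argmax equals the closed form
  for (kin in list(c(0.045, 0.004), c(0.018, 0.0015), c(0.007, 4e-4))) {
    tg <- seq(0, 3000, 0.25)
    ee <- enhancement_curve(tg, kin[1], kin[2], 1)
    expect_equal(tg[which.max(ee)], enhancement_peak_time(kin[1], kin[2]),
                 tolerance = 0.5)
  }
})

test_that("phantom_config validates its invariants", {
  expect_error(phantom_config(pcr_prevalence = 1.2), "prevalence")
  expect_error(phantom_config(phase_times_s = c(0, 60, 60, 120, 180)),
               "increasing")
  expect_error(phantom_config(grid_shape = c(6, 6, 6)), "grid too small")
  expect_error(phantom_config(response_effect = list(
    volume_shrink = 1.2, enhancement_attenuation = c(0.3, 0.15, 0.05),
    localized_fraction = 0.45)), "volume_shrink")
  kp <- rbind(c(0.04, 0.004, 2.9), c(0.04, 0.004, 2.9), c(0.008, 4e-4, 0.6))
  expect_error(phantom_config(habitat_kinetic_params = kp), "distinct")
})

test_that("cohort generation is deterministic and matches the prevalence", {
  c1 <- generate_cohort(tiny_phantom(6, seed = 7))
  c2 <- generate_cohort(tiny_phantom(6, seed = 7))
  expect_identical(unclass(c1), unclass(c2))
  c3 <- generate_cohort(tiny_phantom(6, seed = 8))
  expect_false(identical(c1[[1]]$study_T0$phases, c3[[1]]$study_T0$phases))
  big <- generate_cohort(tiny_phantom(1000, seed = 3, pcr_prevalence = 0.3))
  frac <- mean(cohort_labels(big))
  sd3 <- 3 * sqrt(0.3 * 0.7 / 1000)
  expect_lt(abs(frac - 0.3), sd3)
  expect_gt(frac, 0.20)   # within the published multi-cohort pCR range
  expect_lt(frac, 0.40)
})

test_that("clinical covariates respect subtype consistency", {
  co <- generate_cohort(tiny_phantom(150, seed = 5))
  clin <- cohort_clinical(co)
  hr_pos <- clin$er == "positive" | clin$pr == "positive"
  expect_true(all((clin$subtype == "HR+/HER2-") ==
                    (hr_pos & clin$her2 == "negative")))
  expect_true(all((clin$subtype == "HER2+") == (clin$her2 == "positive")))
  expect_true(all((clin$subtype == "HR-/HER2-") ==
                    (!hr_pos & clin$her2 == "negative")))
  expect_true(all(clin$ld_mm > 0))
  expect_true(all(clin$t_stage %in% c("T1-T2", "T3-T4")))
  # HER2+ patients are enriched among responders by construction
  expect_gt(mean(clin$pcr[clin$subtype == "HER2+"]),
            mean(clin$pcr[clin$subtype == "HR+/HER2-"]))
})

test_that("responders change more than non-responders between timepoints", {
  co <- generate_cohort(tiny_phantom(200, seed = 9))
  labs <- cohort_labels(co)
  change <- vapply(co, function(cs) {
    m <- cs$study_T0$tumor_mask > 0
    peak0 <- cs$study_T0$phases[[3]][m] - cs$study_T0$phases[[1]][m]
    peak1 <- cs$study_T1$phases[[3]][m] - cs$study_T1$phases[[1]][m]
    mean(abs(peak1 - peak0))
  }, numeric(1))
  expect_gt(mean(change[labs]), mean(change[!labs]))
})

test_that("survival is linked to response", {
  co <- generate_cohort(tiny_phantom(500, seed = 13))
  labs <- cohort_labels(co)
  surv <- cohort_survival(co)
  r <- logrank_test(surv$rfs_months[labs], surv$rfs_event[labs],
                    surv$rfs_months[!labs], surv$rfs_event[!labs])
  expect_lt(r$p, 0.05)
  expect_true(all(surv$rfs_months >= 0 & surv$os_months >= 0))
})

test_that("cohort serialization round-trips and fails loudly", {
  co <- generate_cohort(tiny_phantom(2, seed = 2))
  dir <- file.path(tempdir(), "cohort_rt")
  unlink(dir, recursive = TRUE)
  manifest <- write_cohort(co, dir)
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  n <- length(co)
  n_ph <- length(co[[1]]$study_T0$phases)
  expect_equal(length(man$images), 2 * n_ph * n + 2 * n)
  back <- read_cohort(dir)
  expect_equal(length(back), n)
  for (i in seq_len(n)) {
    expect_equal(back[[i]]$patient_id, co[[i]]$patient_id)
    expect_equal(back[[i]]$pcr_label, co[[i]]$pcr_label)
    expect_equal(back[[i]]$study_T0$tumor_mask, co[[i]]$study_T0$tumor_mask)
    for (p in seq_len(n_ph)) {
      expect_equal(back[[i]]$study_T1$phases[[p]],
                   co[[i]]$study_T1$phases[[p]], tolerance = 1e-5)
    }
    expect_equal(back[[i]]$survival$rfs_time, co[[i]]$survival$rfs_time)
    expect_equal(back[[i]]$truth_habitats$T0, co[[i]]$truth_habitats$T0)
  }
  # deleting one mask names the patient and timepoint in the error
  unlink(file.path(dir, "images",
                   sprintf("%s_T1_mask.nii.gz", co[[2]]$patient_id)))
  expect_error(read_cohort(dir), "P0002.*T1")
})

test_that("external configs shift acquisition and case-mix parameters", {
  base <- tiny_phantom(5, seed = 1)
  ext <- external_phantom_config(base, n_patients = 3, seed = 99)
  expect_gt(ext$noise_sigma, base$noise_sigma)
  expect_gt(ext$tumor_size_range[1], base$tumor_size_range[1])
  co <- generate_cohort(ext)
  expect_length(co, 3)
})
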