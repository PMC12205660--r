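test_that("kinetic maps recover planted kinetics and scale invariance", {
  st <- make_study(times = c(0, 40, 80, 140, 220),
                   kin = c(wash_in = 0.04, wash_out = 0.004, pe = 2))
  km <- compute_kinetic_maps(st)
  m <- st$tumor_mask > 0
  true_peak <- max(enhancement_curve(st$phase_times_s, 0.04, 0.004, 2))
  expect_lt(abs(mean(km$peak_enhancement[m]) - true_peak) / true_peak, 0.1)
  expect_true(all(km$wash_out_slope[m] <= 0))   # decaying after the peak
  expect_true(all(km$wash_in_slope[m] > 0))
  # constant phases: all maps zero
  stc <- make_study(kin = c(wash_in = 0.03, wash_out = 0.002, pe = 0))
  kmc <- compute_kinetic_maps(stc)
  expect_true(all(kmc$peak_enhancement == 0))
  expect_true(all(kmc$wash_in_slope == 0))
  # relative enhancement is invariant to intensity rescaling
  st2 <- st
  st2$phases <- lapply(st$phases, function(v) v * 2)
  km2 <- compute_kinetic_maps(st2)
  expect_equal(km$peak_enhancement, km2$peak_enhancement, tolerance = 1e-10)
  st3 <- st
  st3$phases <- st$phases[1:2]
  st3$phase_times_s <- st$phase_times_s[1:2]
  expect_error(compute_kinetic_maps(st3), "phases")
  st4 <- st
  st4$phase_times_s <- rev(st$phase_times_s)
  expect_error(compute_kinetic_maps(st4), "increasing")
})

test_that("segment_habitats is canonical, deterministic and degenerate-safe", {
  st <- make_study()
  km <- compute_kinetic_maps(st)
  expect_warning(hm <- segment_habitats(km, K = 3, seed = 1), "distinct")
  expect_true(all(hm$labels[st$tumor_mask > 0] == 1))
  expect_true(all(hm$labels[st$tumor_mask == 0] == 0))
  expect_error(segment_habitats(km, K = 0), "K")
  co <- generate_cohort(tiny_phantom(1, seed = 6))
  km <- compute_kinetic_maps(co[[1]]$study_T0)
  h1 <- segment_habitats(km, K = 3, seed = 9)
  h2 <- segment_habitats(km, K = 3, seed = 9)
  expect_identical(h1$labels, h2$labels)
  # partition property and canonical ordering by mean peak enhancement
  mask <- co[[1]]$study_T0$tumor_mask > 0
  expect_true(all(h1$labels[mask] %in% 1:3))
  expect_true(all(h1$labels[!mask] == 0))
  mp <- vapply(1:3, function(h) mean(km$peak_enhancement[h1$labels == h]),
               numeric(1))
  expect_true(all(diff(mp) <= 1e-12))
})

test_that("planted partitions are recovered on the standard phantom", {
  co <- generate_cohort(phantom_config(n_patients = 20, seed = 31))
  ari <- vapply(co, function(cs) {
    km <- compute_kinetic_maps(cs$study_T0)
    hm <- segment_habitats(km, K = 3, seed = 1)
    m <- cs$study_T0$tumor_mask > 0
    adjusted_rand_index(hm$labels[m], cs$truth_habitats$T0[m])
  }, numeric(1))
  expect_gte(mean(ari), 0.9)
})

test_that("habitat matching recovers constructed permutations", {
  co <- generate_cohort(tiny_phantom(1, seed = 12))
  km <- compute_kinetic_maps(co[[1]]$study_T0)
  hm <- segment_habitats(km, K = 3, seed = 2)
  # identical studies: identity permutation
  m <- match_habitats_across_time(hm, hm, km, km)
  expect_equal(m$permutation, 1:3)
  expect_identical(m$mapT1$labels, hm$labels)
  # manually permute labels of a copy: the inverse must be recovered
  perm <- c(3L, 1L, 2L)   # old label h -> new label perm[h]
  lab2 <- hm$labels
  for (h in 1:3) lab2[hm$labels == h] <- perm[h]
  hm2 <- structure(list(labels = lab2, K = 3L), class = "habitat_map")
  m2 <- match_habitats_across_time(hm, hm2, km, km)
  expect_identical(m2$mapT1$labels, hm$labels)
  expect_equal(m2$permutation, perm)
  # K = 1 is trivially the identity
  one <- structure(list(labels = (hm$labels > 0) + 0L, K = 1L),
                   class = "habitat_map")
  m3 <- match_habitats_across_time(one, one, km, km)
  expect_equal(m3$permutation, 1L)
  expect_error(match_habitats_across_time(hm, one, km, km), "mismatch")
})

test_that("adjusted_rand_index scores identical and independent partitions", {
  a <- rep(1:3, each = 20)
  expect_equal(adjusted_rand_index(a, a), 1)
  b <- rep(c(2, 3, 1), each = 20)
  expect_equal(adjusted_rand_index(a, b), 1)   # label names are irrelevant
  set.seed(8)
  expect_lt(abs(adjusted_rand_index(a, sample(a))), 0.15)
})
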