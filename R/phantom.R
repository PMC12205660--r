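#' Relative enhancement curve of the phantom kinetic model
#'
#' Difference-of-exponentials forcing used by the phantom generator:
#' `E(t) = pe * (1 - exp(-wash_in * t)) * exp(-wash_out * t)`.
#' The curve is 0 at t = 0, rises at rate `wash_in` toward the plateau scale
#' `pe` and decays at rate `wash_out`; in the `wash_out -> 0` limit it is
#' monotone nondecreasing with asymptote `pe`.  Its maximum has the closed
#' form `t* = log((wash_in + wash_out) / wash_out) / wash_in`.
#'
#' @param t Time in seconds, nonnegative (vectorized).
#' @param wash_in Uptake rate (1/s), > 0.
#' @param wash_out Washout rate (1/s), > 0.
#' @param pe Peak-enhancement scale (ratio), >= 0.
#' @return Relative enhancement values, same length as `t`.
#' @export
enhancement_curve <- function(t, wash_in, wash_out, pe) {
  if (any(t < 0)) stop("negative time")
  stopifnot(wash_in > 0, wash_out > 0, pe >= 0)
  pe * (1 - exp(-wash_in * t)) * exp(-wash_out * t)
}

#' Time of peak enhancement (closed form)
#' @inheritParams enhancement_curve
#' @return Time in seconds at which [enhancement_curve()] is maximal.
#' @export
enhancement_peak_time <- function(wash_in, wash_out) {
  log((wash_in + wash_out) / wash_out) / wash_in
}

#' Configuration of the longitudinal phantom cohort
#'
#' Defines the study conditions the synthetic cohort emulates: a two-timepoint
#' multi-phase DCE series per patient with an ellipsoidal tumor partitioned
#' into kinetic habitats, a treatment-response effect applied at the second
#' timepoint of responders, clinical covariates whose subtype tilts the
#' response odds, and survival linked to the latent response.
#'
#' @param n_patients Number of patients.
#' @param pcr_prevalence Target marginal pCR probability (default 0.30,
#'   inside the 24--36\% range spanned by published NAC cohorts).
#' @param grid_shape Voxel grid (3 ints).
#' @param voxel_spacing_mm Voxel spacing (3 floats, mm).
#' @param n_phases Post-contrast phase count (>= 3 including the baseline
#'   phase at t = 0).
#' @param phase_times_s Strictly increasing acquisition times (s).
#' @param n_habitats Planted habitat count K (default 3).
#' @param habitat_kinetic_params K x 3 matrix, columns
#'   `wash_in`, `wash_out`, `pe`; rows must be pairwise distinct and are
#'   ordered by descending `pe` (habitat 1 = most enhancing).
#' @param response_effect List with `volume_shrink` (center of the diffuse
#'   responders' T1 volume loss, fraction < 1), `enhancement_attenuation`
#'   (length-K fractional attenuation of `pe` at T1 of diffuse responders;
#'   habitat 1 carries the largest planted change) and `localized_fraction`
#'   (share of responders with the redistribution phenotype: little
#'   shrinkage, habitat peak-enhancement levels reflected around the
#'   tumor's own range while wash rates stay in place; diffuse responders
#'   shrink strongly with the configured attenuation).  Non-responders
#'   change only at the level of inter-visit variability (global
#'   enhancement drift, outline wobble, re-drawn voxel texture).
#' @param noise_sigma Additive Gaussian noise SD relative to the baseline
#'   tissue signal.
#' @param subtype_freq Sampling frequencies of the molecular subtypes
#'   HR+/HER2-, HER2+, HR-/HER2-.
#' @param subtype_pcr_odds Odds multipliers of pCR per subtype (relative to
#'   HR+/HER2-).
#' @param kinetic_jitter_sd SDs of the patient-level log-normal jitter on
#'   (wash_in, wash_out, pe) (recycled if length 1).  Models
#'   scanner/physiology variability between patients; it is why a baseline
#'   study is needed to read the early-treatment change.  The jitter on `pe`
#'   is kept moderate so the planted habitat contrast stays identifiable
#'   within every patient.
#' @param tumor_size_range Range of tumor semi-axes as a fraction of the
#'   grid extent (uniform per axis); shift it to emulate a centre with a
#'   different case mix.
#' @param survival_link Log-hazard per unit of latent response (negative:
#'   responders live longer).
#' @param seed Master seed; per-patient substreams are derived by a fixed
#'   offset so cohorts extend without reshuffling.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(n_patients = 100,
                           pcr_prevalence = 0.30,
                           grid_shape = c(32L, 32L, 24L),
                           voxel_spacing_mm = c(1, 1, 1),
                           n_phases = 5L,
                           phase_times_s = c(0, 60, 120, 180, 240),
                           n_habitats = 3L,
                           habitat_kinetic_params = rbind(
                             c(0.045, 0.0040, 2.9),
                             c(0.018, 0.0015, 1.5),
                             c(0.007, 0.0004, 0.6)),
                           response_effect = list(
                             volume_shrink = 0.35,
                             enhancement_attenuation = c(0.30, 0.15, 0.05),
                             localized_fraction = 0.45),
                           noise_sigma = 0.05,
                           subtype_freq = c(0.474, 0.421, 0.105),
                           subtype_pcr_odds = c(1, 18.5, 4.7),
                           kinetic_jitter_sd = c(0.25, 0.25, 0.12),
                           tumor_size_range = c(0.34, 0.46),
                           survival_link = -1.0,
                           seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              pcr_prevalence = pcr_prevalence,
              grid_shape = as.integer(grid_shape),
              voxel_spacing_mm = voxel_spacing_mm,
              n_phases = as.integer(n_phases),
              phase_times_s = phase_times_s,
              n_habitats = as.integer(n_habitats),
              habitat_kinetic_params = habitat_kinetic_params,
              response_effect = response_effect,
              noise_sigma = noise_sigma,
              subtype_freq = subtype_freq / sum(subtype_freq),
              subtype_pcr_odds = subtype_pcr_odds,
              kinetic_jitter_sd = rep_len(kinetic_jitter_sd, 3L),
              tumor_size_range = tumor_size_range,
              survival_link = survival_link,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

validate_phantom_config <- function(cfg) {
  if (cfg$pcr_prevalence <= 0 || cfg$pcr_prevalence >= 1) {
    stop("pcr_prevalence must lie strictly inside (0, 1)")
  }
  if (any(diff(cfg$phase_times_s) <= 0)) {
    stop("phase_times_s must be strictly increasing")
  }
  if (length(cfg$phase_times_s) != cfg$n_phases || cfg$n_phases < 3L) {
    stop("need >= 3 phases with matching phase_times_s")
  }
  if (cfg$n_habitats < 1L) stop("n_habitats must be >= 1")
  kp <- cfg$habitat_kinetic_params
  if (nrow(kp) != cfg$n_habitats || ncol(kp) != 3L) {
    stop("habitat_kinetic_params must be n_habitats x 3")
  }
  if (anyDuplicated(kp)) stop("habitat kinetic parameter rows must be distinct")
  if (is.unsorted(rev(kp[, 3]))) {
    stop("habitat_kinetic_params rows must be ordered by descending pe")
  }
  if (cfg$response_effect$volume_shrink >= 1 ||
      cfg$response_effect$volume_shrink < 0) {
    stop("invalid config: volume_shrink must lie in [0, 1)")
  }
  if (length(cfg$response_effect$enhancement_attenuation) != cfg$n_habitats) {
    stop("enhancement_attenuation must have one entry per habitat")
  }
  if (min(cfg$grid_shape) < 10L) {
    stop("invalid config: grid too small to contain a tumor")
  }
  if (length(cfg$subtype_freq) != 3L || length(cfg$subtype_pcr_odds) != 3L) {
    stop("subtype_freq and subtype_pcr_odds must have length 3")
  }
  invisible(cfg)
}

#' Shifted configuration emulating an external centre
#'
#' Same study design as `base` but with shifted acquisition and case-mix
#' parameters (noise level, inter-patient kinetic spread, tumor sizes),
#' emulating the heterogeneity of an external validation centre.
#'
#' @param base A [phantom_config()].
#' @param n_patients Cohort size (default: as in `base`).
#' @param seed Seed of the external cohort.
#' @param noise_scale Multiplier on `noise_sigma`.
#' @param size_shift Added to `tumor_size_range`.
#' @param jitter_scale Multiplier on `kinetic_jitter_sd`.
#' @return A `phantom_config`.
#' @export
external_phantom_config <- function(base, n_patients = base$n_patients,
                                    seed = base$seed + 1000L,
                                    noise_scale = 1.5, size_shift = 0.05,
                                    jitter_scale = 1.2) {
  cfg <- unclass(base)
  cfg$n_patients <- as.integer(n_patients)
  cfg$seed <- as.integer(seed)
  cfg$noise_sigma <- base$noise_sigma * noise_scale
  cfg$tumor_size_range <- base$tumor_size_range + size_shift
  cfg$kinetic_jitter_sd <- base$kinetic_jitter_sd * jitter_scale
  validate_phantom_config(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

# Logistic intercept such that the marginal pCR probability over the subtype
# mixture equals the configured prevalence.
pcr_intercept <- function(prev, freq, odds) {
  stats::uniroot(function(b0) {
    sum(freq * stats::plogis(b0 + log(odds))) - prev
  }, c(-30, 30))$root
}

# Smooth random field on the grid: a handful of low-frequency cosine modes.
smooth_field <- function(coords_mm, extent_mm, n_modes = 6) {
  f <- numeric(nrow(coords_mm))
  for (m in seq_len(n_modes)) {
    freq <- stats::runif(3, 0.5, 1.5) / extent_mm
    phase <- stats::runif(1, 0, 2 * pi)
    f <- f + stats::rnorm(1, 0, 1) *
      cos(2 * pi * (coords_mm %*% freq) + phase)
  }
  as.numeric(f) / sqrt(n_modes)
}

subtype_levels <- c("HR+/HER2-", "HER2+", "HR-/HER2-")

# Draw one clinical record given subtype (consistency invariants hold by
# construction: HR+ iff ER or PR positive, HER2+ iff HER2 positive).
draw_clinical <- function(subtype) {
  posneg <- function(p) if (stats::runif(1) < p) "positive" else "negative"
  if (subtype == "HR+/HER2-") {
    er <- posneg(0.95)
    pr <- posneg(0.75)
    if (er == "negative" && pr == "negative") er <- "positive"
    her2 <- "negative"
  } else if (subtype == "HER2+") {
    her2 <- "positive"
    er <- posneg(0.5)
    pr <- posneg(0.4)
  } else {
    er <- pr <- her2 <- "negative"
  }
  age <- round(min(max(stats::rnorm(1, 51.5, 9.8), 25), 82))
  ld <- min(max(stats::rlnorm(1, log(35), 0.42), 8), 120)
  list(age = age,
       menopause = if (stats::runif(1) < stats::plogis((age - 50) / 4)) {
         "post"
       } else "pre",
       ld_mm = round(ld, 1),
       t_stage = if (ld > 50) "T3-T4" else "T1-T2",
       er = er, pr = pr, her2 = her2,
       ki67 = posneg(0.85),
       subtype = subtype)
}

# Build one DCE study on the configured grid.  `scale` shrinks the ellipsoid
# (responders at T1); `kin` is the K x 3 kinetic matrix already jittered and,
# at T1 of responders, attenuated.
build_study <- function(cfg, patient_id, timepoint, geom, kin, scale,
                        seed_off = geom$seed_offsets_mm,
                        boundary = geom$boundary_field,
                        pe_jitter = geom$pe_voxel_jitter) {
  gs <- cfg$grid_shape
  sp <- cfg$voxel_spacing_mm
  coords <- cbind(
    rep(seq_len(gs[1]) - 0.5, times = gs[2] * gs[3]) * sp[1],
    rep(rep(seq_len(gs[2]) - 0.5, each = gs[1]), times = gs[3]) * sp[2],
    rep(seq_len(gs[3]) - 0.5, each = gs[1] * gs[2]) * sp[3]
  )
  centered <- sweep(coords, 2, geom$center_mm)
  q <- rowSums(sweep(centered, 2, geom$semi_axes_mm * scale, "/")^2)
  inside <- q <= (1 + 0.25 * boundary)
  mask <- array(as.integer(inside), dim = gs)
  # habitats: nearest planted seed (seed offsets shrink with the tumor)
  seeds <- sweep(seed_off * scale, 2, geom$center_mm, "+")
  vox <- which(inside)
  d2 <- vapply(seq_len(nrow(seeds)), function(h) {
    rowSums(sweep(coords[vox, , drop = FALSE], 2, seeds[h, ])^2) /
      geom$habitat_weights[h]
  }, numeric(length(vox)))
  hab <- max.col(-d2, ties.method = "first")
  labels <- array(0L, dim = gs)
  labels[vox] <- hab
  # voxel signal: S0 * (1 + E_h(t)) inside, flat background outside
  s0 <- 100
  background <- 0.35 * s0
  pe_vox <- kin[hab, 3] * pe_jitter[vox]
  phases <- lapply(seq_len(cfg$n_phases), function(p) {
    t <- cfg$phase_times_s[p]
    vol <- array(background, dim = gs)
    e <- pe_vox * (1 - exp(-kin[hab, 1] * t)) * exp(-kin[hab, 2] * t)
    vol[vox] <- s0 * (1 + e)
    vol + array(stats::rnorm(prod(gs), 0, cfg$noise_sigma * s0), dim = gs)
  })
  structure(list(patient_id = patient_id, timepoint = timepoint,
                 phases = phases, phase_times_s = cfg$phase_times_s,
                 voxel_spacing_mm = sp, tumor_mask = mask,
                 truth_habitats = labels),
            class = "dce_study")
}

generate_case <- function(cfg, i, intercept) {
  set.seed((cfg$seed * 1000003L + i * 7919L) %% .Machine$integer.max)
  patient_id <- sprintf("P%04d", i)
  subtype <- sample(subtype_levels, 1, prob = cfg$subtype_freq)
  odds <- cfg$subtype_pcr_odds[match(subtype, subtype_levels)]
  pcr <- stats::runif(1) < stats::plogis(intercept + log(odds))
  clinical <- draw_clinical(subtype)
  clinical$pcr <- pcr

  gs_mm <- cfg$grid_shape * cfg$voxel_spacing_mm
  center <- gs_mm / 2 + stats::runif(3, -1.5, 1.5)
  semi <- gs_mm * stats::runif(3, cfg$tumor_size_range[1],
                               cfg$tumor_size_range[2]) / 2
  # smooth boundary perturbation, evaluated once on the full grid
  coords <- cbind(
    rep(seq_len(cfg$grid_shape[1]) - 0.5, times = prod(cfg$grid_shape[2:3])) *
      cfg$voxel_spacing_mm[1],
    rep(rep(seq_len(cfg$grid_shape[2]) - 0.5, each = cfg$grid_shape[1]),
        times = cfg$grid_shape[3]) * cfg$voxel_spacing_mm[2],
    rep(seq_len(cfg$grid_shape[3]) - 0.5,
        each = prod(cfg$grid_shape[1:2])) * cfg$voxel_spacing_mm[3]
  )
  boundary <- smooth_field(coords, gs_mm)
  # habitat seed points inside the unperturbed ellipsoid
  K <- cfg$n_habitats
  seed_off <- matrix(0, K, 3)
  for (h in seq_len(K)) {
    repeat {
      u <- stats::runif(3, -0.75, 0.75)
      if (sum(u^2) <= 0.6) break
    }
    seed_off[h, ] <- u * semi
  }
  pe_jitter <- array(1 + 0.05 * stats::rnorm(prod(cfg$grid_shape)),
                     dim = cfg$grid_shape)
  # weighted-Voronoi cell sizes: habitat 1 is a small hyper-enhancing
  # hot spot, habitats 2-3 split the remainder
  geom <- list(center_mm = center, semi_axes_mm = semi,
               boundary_field = boundary, seed_offsets_mm = seed_off,
               pe_voxel_jitter = pe_jitter,
               habitat_weights = c(0.62, rep(1.15, K - 1))[seq_len(K)])

  # patient-level kinetic jitter shared by both timepoints; the per-habitat
  # jitter on pe makes the baseline habitat-contrast pattern vary between
  # patients, so the T1 appearance alone is ambiguous
  kin <- cfg$habitat_kinetic_params
  global_mult <- exp(stats::rnorm(3) * cfg$kinetic_jitter_sd)
  hab_mult <- cbind(exp(stats::rnorm(K, 0, 0.05)),
                    exp(stats::rnorm(K, 0, 0.05)),
                    exp(stats::rnorm(K, 0, 0.15)))
  kin <- sweep(kin, 2, global_mult, "*") * hab_mult

  # responders split into two phenotypes.  "Redistribution": little volume
  # loss, but the habitat peak-enhancement levels reflect around the
  # tumor's own level range (formerly hyper-perfused habitats collapse,
  # formerly dormant ones reperfuse) while the wash-in/wash-out rates stay
  # with their regions -- the static appearance of the tumor stays
  # plausible and the intensity histogram is nearly preserved, so the
  # change is essentially only readable by comparing matched habitats
  # across time.  "Diffuse": strong shrinkage plus habitat-wise
  # attenuation, readable at the whole-tumor level.
  re <- cfg$response_effect
  shrink <- 0
  atten <- rep(0, K)
  invert <- FALSE
  if (pcr) {
    if (stats::runif(1) < re$localized_fraction && K >= 2) {
      shrink <- stats::runif(1, 0.02, 0.12)
      invert <- TRUE
    } else {
      shrink <- stats::runif(1, max(0, re$volume_shrink - 0.1),
                             min(0.95, re$volume_shrink + 0.1))
      atten <- re$enhancement_attenuation
    }
  }
  kin_t1 <- kin
  if (invert) {
    depth <- stats::runif(1, 0.6, 0.9)
    kin_t1[1, 3] <- kin[1, 3] + depth * (min(kin[, 3]) - kin[1, 3])
    kin_t1[1, 1] <- kin[1, 1] * (1 - 0.3 * depth)
  }
  kin_t1[, 3] <- kin_t1[, 3] * (1 - atten)
  kin_t1[, 1] <- kin_t1[, 1] * (1 - 0.5 * pmax(atten, 0))
  # inter-visit variability affecting every patient at T1 (contrast dose,
  # scanner drift, segmentation wobble): a global enhancement multiplier
  # and a small volume jitter, so whole-tumor level changes alone do not
  # identify responders
  kin_t1[, 3] <- kin_t1[, 3] * exp(stats::rnorm(1, 0, 0.10))
  kin_t1[, 1] <- kin_t1[, 1] * exp(stats::rnorm(1, 0, 0.10))
  scale_t1 <- ((1 - shrink) * (1 + stats::runif(1, -0.06, 0.06)))^(1 / 3)
  # visit-level appearance nuisance for every patient: the tumor outline
  # wobbles (re-delineation) and the voxel texture is redrawn
  boundary_t1 <- boundary + 0.6 * smooth_field(coords, gs_mm)
  pe_jitter_t1 <- array(1 + 0.09 * stats::rnorm(prod(cfg$grid_shape)),
                        dim = cfg$grid_shape)

  study_t0 <- build_study(cfg, patient_id, "T0", geom, kin, scale = 1)
  study_t1 <- build_study(cfg, patient_id, "T1", geom, kin_t1,
                          scale = scale_t1, boundary = boundary_t1,
                          pe_jitter = pe_jitter_t1)

  latent <- as.numeric(pcr) + stats::rnorm(1, 0, 0.1)
  haz_mult <- exp(cfg$survival_link * latent)
  censor <- stats::runif(2, 24, 84)
  rfs_event_time <- stats::rexp(1, log(2) / 48 * haz_mult)
  os_event_time <- stats::rexp(1, log(2) / 90 * haz_mult)
  survival <- list(
    rfs_time = round(min(rfs_event_time, censor[1]), 2),
    rfs_event = rfs_event_time <= censor[1],
    os_time = round(min(os_event_time, censor[2]), 2),
    os_event = os_event_time <= censor[2]
  )

  structure(list(patient_id = patient_id,
                 study_T0 = study_t0, study_T1 = study_t1,
                 clinical = clinical, pcr_label = pcr,
                 survival = survival,
                 truth_habitats = list(T0 = study_t0$truth_habitats,
                                       T1 = study_t1$truth_habitats),
                 latent_response = latent),
            class = "longitudinal_case")
}

#' Generate a longitudinal phantom cohort
#'
#' Draws `n_patients` reproducible [longitudinal cases][phantom_config]:
#' two-timepoint multi-phase DCE volumes with a planted habitat partition,
#' clinical covariates whose molecular subtype tilts the pCR odds, and
#' exponential survival whose log-hazard is `survival_link` times the latent
#' response.  Responders shrink by the configured volume fraction and show
#' habitat-specific enhancement attenuation at T1; non-responders change only
#' at noise level.  Identical config + seed reproduces identical cohorts.
#'
#' @param config A [phantom_config()].
#' @return Object of class `sti_cohort`: a list of `longitudinal_case`
#'   objects with the config stored as an attribute.
#' @export
generate_cohort <- function(config) {
  validate_phantom_config(config)
  intercept <- pcr_intercept(config$pcr_prevalence, config$subtype_freq,
                             config$subtype_pcr_odds)
  cases <- lapply(seq_len(config$n_patients), function(i) {
    generate_case(config, i, intercept)
  })
  structure(cases, class = "sti_cohort", config = config)
}

#' @export
print.sti_cohort <- function(x, ...) {
  labs <- cohort_labels(x)
  cat(sprintf("Longitudinal DCE-MRI cohort: %d patients, %.1f%% pCR\n",
              length(x), 100 * mean(labs)))
  cfg <- attr(x, "config")
  if (!is.null(cfg)) {
    cat(sprintf("  grid %s, %d phases, K = %d habitats\n",
                paste(cfg$grid_shape, collapse = "x"), cfg$n_phases,
                cfg$n_habitats))
  }
  invisible(x)
}

#' Cohort accessors
#'
#' `cohort_labels` extracts the pCR labels, `cohort_clinical` the clinical
#' table and `cohort_survival` the survival table of a cohort.
#'
#' @param cohort An `sti_cohort` or plain list of `longitudinal_case`s.
#' @return Logical vector / data frame.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort, function(cs) cs$pcr_label, logical(1))
}

#' @rdname cohort_labels
#' @export
cohort_clinical <- function(cohort) {
  do.call(rbind, lapply(cohort, function(cs) {
    data.frame(patient_id = cs$patient_id, cs$clinical,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname cohort_labels
#' @export
cohort_survival <- function(cohort) {
  do.call(rbind, lapply(cohort, function(cs) {
    s <- cs$survival
    data.frame(patient_id = cs$patient_id,
               rfs_months = s$rfs_time, rfs_event = as.integer(s$rfs_event),
               os_months = s$os_time, os_event = as.integer(s$os_event))
  }))
}

nifti_write_vol <- function(arr, spacing, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Serialize / load a cohort
#'
#' `write_cohort` stores every phase volume and tumor mask as NIfTI
#' (spacing in the header), the clinical and survival tables as CSV, planted
#' habitat truth as NIfTI under `truth/`, and a JSON manifest listing all
#' files.  `read_cohort` reverses it; a missing or unreadable file raises an
#' error naming the patient and timepoint.
#'
#' @param cases Cohort to write.
#' @param directory Target directory (created if needed).
#' @return `write_cohort`: the manifest path (invisibly the manifest list as
#'   attribute); `read_cohort`: an `sti_cohort`.
#' @export
write_cohort <- function(cases, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(directory, "images"), showWarnings = FALSE)
  dir.create(file.path(directory, "truth"), showWarnings = FALSE)
  images <- character(0)
  truth_files <- character(0)
  for (cs in cases) {
    for (tp in c("T0", "T1")) {
      st <- cs[[paste0("study_", tp)]]
      for (p in seq_along(st$phases)) {
        f <- sprintf("images/%s_%s_phase%02d.nii.gz", cs$patient_id, tp, p)
        nifti_write_vol(st$phases[[p]], st$voxel_spacing_mm,
                        file.path(directory, f))
        images <- c(images, f)
      }
      f <- sprintf("images/%s_%s_mask.nii.gz", cs$patient_id, tp)
      nifti_write_vol(st$tumor_mask, st$voxel_spacing_mm,
                      file.path(directory, f))
      images <- c(images, f)
      if (!is.null(cs$truth_habitats[[tp]])) {
        ft <- sprintf("truth/%s_%s_habitats.nii.gz", cs$patient_id, tp)
        nifti_write_vol(cs$truth_habitats[[tp]], st$voxel_spacing_mm,
                        file.path(directory, ft))
        truth_files <- c(truth_files, ft)
      }
    }
  }
  clin <- cohort_clinical(cases)
  utils::write.csv(clin, file.path(directory, "clinical.csv"),
                   row.names = FALSE)
  surv <- cohort_survival(cases)
  utils::write.csv(surv, file.path(directory, "survival.csv"),
                   row.names = FALSE)
  latent <- data.frame(
    patient_id = vapply(cases, `[[`, character(1), "patient_id"),
    latent_response = vapply(cases, function(cs) {
      if (is.null(cs$latent_response)) NA_real_ else cs$latent_response
    }, numeric(1)))
  utils::write.csv(latent, file.path(directory, "latent.csv"),
                   row.names = FALSE)
  manifest <- list(
    n_patients = length(cases),
    patient_ids = vapply(cases, `[[`, character(1), "patient_id"),
    n_phases = length(cases[[1]]$study_T0$phases),
    phase_times_s = cases[[1]]$study_T0$phase_times_s,
    voxel_spacing_mm = cases[[1]]$study_T0$voxel_spacing_mm,
    images = images,
    truth = truth_files,
    tables = c("clinical.csv", "survival.csv", "latent.csv")
  )
  path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  path <- file.path(directory, "manifest.json")
  if (!file.exists(path)) stop("manifest.json not found in ", directory)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  clin <- utils::read.csv(file.path(directory, "clinical.csv"),
                          stringsAsFactors = FALSE)
  surv <- utils::read.csv(file.path(directory, "survival.csv"),
                          stringsAsFactors = FALSE)
  latent <- utils::read.csv(file.path(directory, "latent.csv"),
                            stringsAsFactors = FALSE)
  read_vol <- function(f, pid, tp) {
    full <- file.path(directory, f)
    if (!file.exists(full)) {
      stop(sprintf("cohort I/O error: missing file %s (patient %s, timepoint %s)",
                   f, pid, tp))
    }
    img <- RNifti::readNifti(full)
    arr <- array(as.numeric(img), dim = dim(img))
    attr(arr, "spacing") <- RNifti::pixdim(img)
    arr
  }
  cases <- lapply(man$patient_ids, function(pid) {
    studies <- lapply(c("T0", "T1"), function(tp) {
      phases <- lapply(seq_len(man$n_phases), function(p) {
        read_vol(sprintf("images/%s_%s_phase%02d.nii.gz", pid, tp, p), pid, tp)
      })
      mask_arr <- read_vol(sprintf("images/%s_%s_mask.nii.gz", pid, tp),
                           pid, tp)
      structure(list(patient_id = pid, timepoint = tp,
                     phases = lapply(phases, function(a) {
                       attr(a, "spacing") <- NULL; a
                     }),
                     phase_times_s = man$phase_times_s,
                     voxel_spacing_mm = man$voxel_spacing_mm,
                     tumor_mask = array(as.integer(round(mask_arr)),
                                        dim = dim(mask_arr))),
                class = "dce_study")
    })
    truth <- NULL
    tf0 <- sprintf("truth/%s_T0_habitats.nii.gz", pid)
    if (file.exists(file.path(directory, tf0))) {
      truth <- lapply(c("T0", "T1"), function(tp) {
        a <- read_vol(sprintf("truth/%s_%s_habitats.nii.gz", pid, tp), pid, tp)
        attr(a, "spacing") <- NULL
        array(as.integer(round(a)), dim = dim(a))
      })
      names(truth) <- c("T0", "T1")
    }
    row <- clin[clin$patient_id == pid, , drop = FALSE]
    srow <- surv[surv$patient_id == pid, , drop = FALSE]
    lrow <- latent[latent$patient_id == pid, , drop = FALSE]
    structure(list(patient_id = pid,
                   study_T0 = studies[[1]], study_T1 = studies[[2]],
                   clinical = as.list(row[, setdiff(names(row),
                                                    c("patient_id", "pcr"))]),
                   pcr_label = as.logical(row$pcr),
                   survival = list(rfs_time = srow$rfs_months,
                                   rfs_event = as.logical(srow$rfs_event),
                                   os_time = srow$os_months,
                                   os_event = as.logical(srow$os_event)),
                   truth_habitats = truth,
                   latent_response = lrow$latent_response),
              class = "longitudinal_case")
  })
  structure(cases, class = "sti_cohort")
}
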