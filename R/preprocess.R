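#' Preprocessing configuration
#'
#' @param target_spacing_mm Isotropic resampling target (3 floats, mm).
#' @param patch_shape Output patch grid (3 ints); each dimension must be
#'   divisible by `2^n` for the encoder's `n` pooling stages.
#' @param mask_margin_mm Margin added around the region bounding box (mm).
#' @param normalization `"zscore_within_mask"` (subtract within-mask mean,
#'   divide by within-mask SD) or `"minmax_volume"`.
#' @param peak_phase_rule `"max_mean_mask_enhancement"` (default) or
#'   `"fixed_index"`.
#' @param fixed_phase_index Phase used when `peak_phase_rule = "fixed_index"`.
#' @return Object of class `preproc_config`.
#' @export
preproc_config <- function(target_spacing_mm = c(1, 1, 1),
                           patch_shape = c(32L, 32L, 32L),
                           mask_margin_mm = 4,
                           normalization = c("zscore_within_mask",
                                             "minmax_volume"),
                           peak_phase_rule = c("max_mean_mask_enhancement",
                                               "fixed_index"),
                           fixed_phase_index = NULL) {
  normalization <- match.arg(normalization)
  peak_phase_rule <- match.arg(peak_phase_rule)
  stopifnot(all(patch_shape > 0), all(target_spacing_mm > 0))
  structure(list(target_spacing_mm = target_spacing_mm,
                 patch_shape = as.integer(patch_shape),
                 mask_margin_mm = mask_margin_mm,
                 normalization = normalization,
                 peak_phase_rule = peak_phase_rule,
                 fixed_phase_index = fixed_phase_index),
            class = "preproc_config")
}

#' Select the peak-enhancement phase of a study
#'
#' Returns the index of the phase maximizing the mean within-mask
#' enhancement relative to the first (baseline) phase.  Ties break toward
#' the earliest index.  With `peak_phase_rule = "fixed_index"` the configured
#' index is returned unchanged.
#'
#' @param study A `dce_study`.
#' @param config A [preproc_config()].
#' @return Integer phase index (1-based).
#' @export
select_peak_phase <- function(study, config = preproc_config()) {
  if (length(study$phases) < 2L) stop("need >= 2 phases")
  if (config$peak_phase_rule == "fixed_index") {
    idx <- config$fixed_phase_index
    if (is.null(idx) || idx < 1L || idx > length(study$phases)) {
      stop("fixed_phase_index out of range")
    }
    return(as.integer(idx))
  }
  inmask <- study$tumor_mask > 0
  if (!any(inmask)) stop("empty tumor mask")
  base <- study$phases[[1]][inmask]
  means <- vapply(study$phases, function(v) mean(v[inmask] - base),
                  numeric(1))
  which.max(means)  # which.max returns the earliest maximum
}

#' Resample a volume to a new voxel spacing
#'
#' Trilinear interpolation (or nearest-neighbour for masks) onto the grid
#' of shape `round(shape * spacing_in / spacing_out)` with voxel-center
#' alignment.  Resampling at identical spacing is the identity.
#'
#' @param volume 3D array.
#' @param spacing_in,spacing_out Voxel spacings (3 floats, mm), positive.
#' @param method `"trilinear"` or `"nearest"`.
#' @return Resampled 3D array.
#' @export
resample_to_spacing <- function(volume, spacing_in, spacing_out,
                                method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(all(spacing_in > 0), all(spacing_out > 0))
  if (isTRUE(all.equal(spacing_in, spacing_out))) return(volume)
  d <- dim(volume)
  out_dim <- as.integer(round(d * spacing_in / spacing_out))
  if (any(out_dim < 1L)) stop("zero-size output grid")
  scale <- spacing_out / spacing_in
  .resample3d(volume, out_dim, scale, method == "nearest")
}

# Resize an arbitrary box to a fixed patch shape (trilinear for intensities,
# nearest for masks).
resize_to_shape <- function(volume, out_shape, nearest = FALSE) {
  d <- dim(volume)
  if (all(d == out_shape)) return(volume)
  .resample3d(volume, as.integer(out_shape), d / out_shape, nearest)
}

#' Crop and normalize a region patch
#'
#' Extracts the bounding box of `region_mask` expanded by
#' `mask_margin_mm`, resizes it to `patch_shape` and normalizes per the
#' configuration (`zscore_within_mask`: the patch minus the within-region
#' mean, divided by the within-region SD).  An empty region yields a
#' zero-filled patch with `mask_fraction = 0` and a warning, so the region
#' count per case stays fixed.
#'
#' @param volume 3D intensity array (typically the peak-enhancement phase).
#' @param region_mask Binary 3D array of the region (whole tumor or one
#'   habitat).
#' @param config A [preproc_config()].
#' @param spacing_mm Voxel spacing of `volume`.
#' @param region Label recorded in the patch (e.g. `"whole"`,
#'   `"habitat_1"`).
#' @param patient_id,timepoint Identifiers carried along.
#' @param norm_stats Optional list `(mu, sd)` of study-level normalization
#'   statistics (typically whole-tumor mean/SD); when supplied, all region
#'   patches of the study share them, so the relative enhancement level of
#'   each habitat is preserved.  Default: the region's own statistics.
#' @return Object of class `region_patch`: list with `volume`
#'   (patch_shape array), `mask` (resized region mask), `mask_fraction`,
#'   and identifiers.
#' @export
crop_region <- function(volume, region_mask, config = preproc_config(),
                        spacing_mm = c(1, 1, 1), region = "whole",
                        patient_id = NA_character_,
                        timepoint = NA_character_, norm_stats = NULL) {
  ps <- config$patch_shape
  if (!any(region_mask > 0)) {
    if (region == "whole") stop("empty whole-tumor mask")
    warning(sprintf("empty region %s (%s %s): emitting zero patch",
                    region, patient_id, timepoint))
    return(structure(list(patient_id = patient_id, timepoint = timepoint,
                          region = region,
                          volume = array(0, dim = ps),
                          mask = array(0, dim = ps),
                          mask_fraction = 0),
                     class = "region_patch"))
  }
  idx <- which(region_mask > 0, arr.ind = TRUE)
  margin_vox <- ceiling(config$mask_margin_mm / spacing_mm)
  lo <- pmax(apply(idx, 2, min) - margin_vox, 1)
  hi <- pmin(apply(idx, 2, max) + margin_vox, dim(volume))
  box <- volume[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mbox <- region_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  patch <- resize_to_shape(box, ps)
  mpatch <- resize_to_shape(mbox + 0, ps, nearest = TRUE)
  inmask <- mpatch > 0
  if (config$normalization == "zscore_within_mask") {
    if (is.null(norm_stats)) {
      mu <- mean(patch[inmask])
      sd <- stats::sd(patch[inmask])
    } else {
      mu <- norm_stats$mu
      sd <- norm_stats$sd
    }
    if (!is.finite(sd) || sd < 1e-8) sd <- 1
    patch <- (patch - mu) / sd
  } else {
    rng <- range(patch)
    if (diff(rng) < 1e-12) {
      patch <- patch * 0
    } else {
      patch <- (patch - rng[1]) / diff(rng)
    }
  }
  structure(list(patient_id = patient_id, timepoint = timepoint,
                 region = region, volume = patch, mask = mpatch,
                 mask_fraction = mean(inmask)),
            class = "region_patch")
}

#' Preprocess one longitudinal case into region patches
#'
#' For each timepoint: resamples the peak-enhancement phase and masks to the
#' target spacing, then crops the whole tumor plus the K habitat regions into
#' normalized patches.  Every case yields exactly `(K + 1)` patches per
#' timepoint regardless of empty habitats.
#'
#' @param case A `longitudinal_case`.
#' @param habitats List with entries `T0` and `T1`, each a `habitat_map` as
#'   returned by [segment_habitats()] (T1 relabeled by
#'   [match_habitats_across_time()]).
#' @param config A [preproc_config()].
#' @return List with entries `T0` and `T1`, each a list of `region_patch`
#'   objects named `whole`, `habitat_1`, ..., `habitat_K`.
#' @export
preprocess_case <- function(case, habitats, config = preproc_config()) {
  out <- list()
  for (tp in c("T0", "T1")) {
    study <- case[[paste0("study_", tp)]]
    sp <- study$voxel_spacing_mm
    peak <- select_peak_phase(study, config)
    vol <- resample_to_spacing(study$phases[[peak]], sp,
                               config$target_spacing_mm)
    mask <- resample_to_spacing(study$tumor_mask + 0, sp,
                                config$target_spacing_mm, method = "nearest")
    hab <- resample_to_spacing(habitats[[tp]]$labels + 0, sp,
                               config$target_spacing_mm, method = "nearest")
    K <- habitats[[tp]]$K
    patches <- vector("list", K + 1L)
    names(patches) <- c("whole", paste0("habitat_", seq_len(K)))
    # all regions of one study share the whole-tumor normalization, so a
    # habitat's enhancement level relative to the tumor is preserved
    stats_tp <- list(mu = mean(vol[mask > 0]), sd = stats::sd(vol[mask > 0]))
    patches[["whole"]] <- crop_region(vol, mask, config,
                                      config$target_spacing_mm, "whole",
                                      case$patient_id, tp,
                                      norm_stats = stats_tp)
    for (h in seq_len(K)) {
      patches[[h + 1L]] <- crop_region(vol, (hab == h) + 0, config,
                                       config$target_spacing_mm,
                                       paste0("habitat_", h),
                                       case$patient_id, tp,
                                       norm_stats = stats_tp)
    }
    out[[tp]] <- patches
  }
  out
}
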