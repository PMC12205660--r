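#' Voxelwise kinetic maps from a multi-phase study
#'
#' Relative enhancement per phase is
#' `E(t_p) = (S(t_p) - S(t_1)) / max(S(t_1), eps)` with the first phase as
#' pre-contrast baseline.  Per mask voxel: `peak_enhancement = max_p E`,
#' `time_to_peak` the time of that maximum, `wash_in_slope` the least-squares
#' slope of E against time over phases up to and including the peak, and
#' `wash_out_slope` the (signed) slope from the peak to the last phase
#' (zero when the peak is the last phase).  Maps are relative, hence
#' invariant to global intensity rescaling.
#'
#' @param study A `dce_study` with at least 3 phases and strictly
#'   increasing times.
#' @param eps Guard for the baseline division.
#' @return Object of class `kinetic_maps`: list of four arrays on the study
#'   grid (values outside the mask are 0) plus the mask.
#' @export
compute_kinetic_maps <- function(study, eps = 1e-6) {
  P <- length(study$phases)
  if (P < 3L) stop("need >= 3 phases")
  tt <- study$phase_times_s
  if (any(diff(tt) <= 0)) stop("phase times must be strictly increasing")
  inmask <- study$tumor_mask > 0
  if (!any(inmask)) stop("empty tumor mask")
  n <- sum(inmask)
  base <- study$phases[[1]][inmask]
  E <- vapply(study$phases, function(v) {
    (v[inmask] - base) / pmax(base, eps)
  }, numeric(n))                              # n x P
  peak_idx <- max.col(E, ties.method = "first")
  peak <- E[cbind(seq_len(n), peak_idx)]
  ttp <- tt[peak_idx]
  slope_upto <- function(upto) {
    # least-squares slope of E[v, 1:upto[v]] on t[1:upto[v]], vectorized by
    # grouping voxels with the same peak index
    s <- numeric(n)
    for (k in unique(upto)) {
      v <- which(upto == k)
      if (k < 2L) next
      tk <- tt[seq_len(k)]
      tc <- tk - mean(tk)
      s[v] <- as.numeric(E[v, seq_len(k), drop = FALSE] %*% tc) / sum(tc^2)
    }
    s
  }
  slope_from <- function(from) {
    s <- numeric(n)
    for (k in unique(from)) {
      v <- which(from == k)
      if (k >= P) next
      tk <- tt[k:P]
      tc <- tk - mean(tk)
      s[v] <- as.numeric(E[v, k:P, drop = FALSE] %*% tc) / sum(tc^2)
    }
    s
  }
  to_map <- function(vals) {
    m <- array(0, dim = dim(study$tumor_mask))
    m[inmask] <- vals
    m
  }
  structure(list(wash_in_slope = to_map(slope_upto(peak_idx)),
                 wash_out_slope = to_map(slope_from(peak_idx)),
                 peak_enhancement = to_map(peak),
                 time_to_peak = to_map(ttp),
                 mask = study$tumor_mask),
            class = "kinetic_maps")
}

#' Segment kinetic habitats within a tumor
#'
#' Per-tumor k-means (10 restarts, fixed seed) on the z-scored per-voxel
#' feature vectors (wash-in slope, wash-out slope, peak enhancement).
#' Clusters are relabeled canonically by descending mean peak enhancement,
#' so habitat 1 is the most enhancing subregion in every patient.  If fewer
#' distinct feature vectors than K exist, surplus habitats are empty and a
#' warning is issued.
#'
#' @param kinetics A [compute_kinetic_maps()] result.
#' @param mask Binary tumor mask (defaults to the mask stored in
#'   `kinetics`).
#' @param K Habitat count, >= 1.
#' @param seed Integer seed for the k-means restarts.
#' @return Object of class `habitat_map`: list with `labels` (integer array,
#'   0 = background) and `K`.
#' @export
segment_habitats <- function(kinetics, mask = kinetics$mask, K = 3L,
                             seed = 1L) {
  if (K <= 0L) stop("K must be >= 1")
  inmask <- mask > 0
  if (!any(inmask)) stop("empty mask")
  feat <- cbind(kinetics$wash_in_slope[inmask],
                kinetics$wash_out_slope[inmask],
                kinetics$peak_enhancement[inmask])
  fz <- apply(feat, 2, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s < 1e-12) return(col * 0)
    (col - mean(col)) / s
  })
  n_distinct <- nrow(unique(fz))
  labels_in <- rep(1L, nrow(fz))
  if (n_distinct < K) {
    warning(sprintf("only %d distinct feature vectors for K = %d: surplus habitats empty",
                    n_distinct, K))
    if (n_distinct > 1L) {
      km <- withr_seed(seed, stats::kmeans(fz, centers = n_distinct,
                                           nstart = 10))
      labels_in <- km$cluster
    }
  } else if (K > 1L) {
    km <- withr_seed(seed, stats::kmeans(fz, centers = K, nstart = 10,
                                         iter.max = 50))
    labels_in <- km$cluster
  }
  # canonical relabeling: descending mean peak enhancement
  pe <- kinetics$peak_enhancement[inmask]
  means <- tapply(pe, labels_in, mean)
  ord <- order(-means)
  relabel <- integer(max(labels_in))
  relabel[as.integer(names(means))[ord]] <- seq_along(ord)
  labels_in <- relabel[labels_in]
  labels <- array(0L, dim = dim(mask))
  labels[inmask] <- labels_in
  structure(list(labels = labels, K = as.integer(K)),
            class = "habitat_map")
}

# Mean kinetic profile (wash-in, wash-out, peak) per habitat; empty habitats
# get NA rows.
habitat_profiles <- function(map, kinetics) {
  K <- map$K
  prof <- matrix(NA_real_, K, 3)
  for (h in seq_len(K)) {
    v <- map$labels == h
    if (any(v)) {
      prof[h, ] <- c(mean(kinetics$wash_in_slope[v]),
                     mean(kinetics$wash_out_slope[v]),
                     mean(kinetics$peak_enhancement[v]))
    }
  }
  prof
}

#' Match habitat labels across timepoints
#'
#' Permutes the T1 habitat labels so that habitat mean-kinetic profiles best
#' match the T0 habitats (optimal assignment over the K x K
#' profile-distance matrix, solved exactly by enumeration).  The canonical
#' ordering of the T0 map is preserved.
#'
#' @param mapT0,mapT1 `habitat_map`s with identical K.
#' @param kineticsT0,kineticsT1 Matching [compute_kinetic_maps()] results.
#' @return List with `mapT0` (unchanged), `mapT1` (relabeled) and the
#'   `permutation` applied (index: new label, value: old T1 label).
#' @export
match_habitats_across_time <- function(mapT0, mapT1, kineticsT0,
                                       kineticsT1) {
  if (mapT0$K != mapT1$K) stop("mismatched habitat counts")
  K <- mapT0$K
  if (K == 1L) {
    return(list(mapT0 = mapT0, mapT1 = mapT1, permutation = 1L))
  }
  p0 <- habitat_profiles(mapT0, kineticsT0)
  p1 <- habitat_profiles(mapT1, kineticsT1)
  # z-scale features jointly so no single feature dominates the distance
  all <- rbind(p0, p1)
  for (j in seq_len(ncol(all))) {
    s <- stats::sd(all[, j], na.rm = TRUE)
    if (is.finite(s) && s > 1e-12) all[, j] <- all[, j] / s
  }
  p0 <- all[seq_len(K), , drop = FALSE]
  p1 <- all[K + seq_len(K), , drop = FALSE]
  cost <- matrix(0, K, K)
  for (a in seq_len(K)) {
    for (b in seq_len(K)) {
      d <- (p0[a, ] - p1[b, ])^2
      cost[a, b] <- if (all(is.na(d))) 1e6 else sum(d, na.rm = TRUE)
    }
  }
  perms <- all_permutations(K)
  costs <- vapply(seq_len(nrow(perms)), function(r) {
    sum(cost[cbind(seq_len(K), perms[r, ])])
  }, numeric(1))
  best <- perms[which.min(costs), ]
  labels <- mapT1$labels
  new_labels <- array(0L, dim = dim(labels))
  for (h in seq_len(K)) {
    new_labels[labels == best[h]] <- h
  }
  list(mapT0 = mapT0,
       mapT1 = structure(list(labels = new_labels, K = K),
                         class = "habitat_map"),
       permutation = best)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Segment and match habitats for a longitudinal case
#'
#' Convenience wrapper: kinetic maps and habitat segmentation at both
#' timepoints, then cross-timepoint label matching.
#'
#' @param case A `longitudinal_case`.
#' @param K Habitat count.
#' @param seed Seed for the k-means restarts.
#' @return List with `T0` and `T1` `habitat_map`s (T1 relabeled) and the
#'   kinetic maps of both studies.
#' @export
segment_case_habitats <- function(case, K = 3L, seed = 1L) {
  k0 <- compute_kinetic_maps(case$study_T0)
  k1 <- compute_kinetic_maps(case$study_T1)
  m0 <- segment_habitats(k0, K = K, seed = seed)
  m1 <- segment_habitats(k1, K = K, seed = seed)
  matched <- suppressWarnings(match_habitats_across_time(m0, m1, k0, k1))
  list(T0 = matched$mapT0, T1 = matched$mapT1,
       kinetics_T0 = k0, kinetics_T1 = k1)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same voxel set;
#' used to score habitat recovery against the planted truth.
#'
#' @param a,b Integer label vectors of equal length.
#' @return ARI in \[-1, 1\] (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
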