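# FMT-PET quantification: SUV, occipital normalization, ROI uptake,
# baseline-derived transduction masks and the longitudinal voxel-wise
# contrast with sign-flip cluster-level correction.

#' PET scan with dosing metadata
#'
#' @param volume \code{volume_grid} of radioactivity concentration (MBq/g).
#' @param injected_dose injected tracer dose, MBq (> 0).
#' @param body_weight patient body weight, g (> 0).
#' @param timepoint one of "baseline", "6M", "2Y".
#' @param patient patient identifier.
#' @return An object of class \code{pet_scan}.
#' @export
pet_scan <- function(volume, injected_dose, body_weight,
                     timepoint = c("baseline", "6M", "2Y"),
                     patient = "unknown") {
  timepoint <- match.arg(timepoint)
  if (injected_dose <= 0) stop("injected dose must be > 0 MBq")
  if (body_weight <= 0) stop("body weight must be > 0 g")
  structure(
    list(volume = volume, injected_dose = injected_dose,
         body_weight = body_weight, timepoint = timepoint, patient = patient),
    class = "pet_scan"
  )
}

#' Standardized uptake value
#'
#' Voxel-wise SUV = concentration (MBq/g) / (injected dose (MBq) / body
#' weight (g)); unit-free.
#'
#' @param scan a \code{pet_scan}.
#' @return \code{volume_grid} of SUV.
#' @export
compute_suv <- function(scan) {
  g <- scan$volume
  volume_grid(g$data / (scan$injected_dose / scan$body_weight),
              spacing = g$spacing, origin = g$origin)
}

#' Region-to-occipital ratio normalization
#'
#' Divides every voxel by the mean uptake of the occipital reference region,
#' normalizing across scan sessions; the occipital mean of the output is 1.
#'
#' @param volume a \code{volume_grid} (SUV or raw; the ratio is
#'   scale-invariant).
#' @param occipital occipital \code{roi_mask}.
#' @return normalized \code{volume_grid}.
#' @export
to_occipital_ratio <- function(volume, occipital) {
  m <- mask_stats(volume, occipital, "mean")
  if (m <= 0)
    stop("unusable reference: occipital mean is ", m, " (must be > 0)")
  volume_grid(volume$data / m, spacing = volume$spacing,
              origin = volume$origin)
}

#' Median ROI uptake table
#'
#' Long-format table of the median normalized uptake per ROI and timepoint.
#'
#' @param ratio_volumes named list (by timepoint) of occipital-ratio
#'   \code{volume_grid}s.
#' @param rois list of \code{roi_mask}s.
#' @param patient patient identifier for the table.
#' @return tibble (patient, timepoint, roi, median_ratio).
#' @export
roi_uptake_table <- function(ratio_volumes, rois, patient = "unknown") {
  rows <- list()
  for (tp in names(ratio_volumes)) {
    for (roi in rois) {
      med <- mask_stats(ratio_volumes[[tp]], roi, "median")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient = patient, timepoint = tp, roi = roi$name,
        median_ratio = med)
    }
  }
  do.call(rbind, rows)
}

#' Baseline-derived transduction masks and volume fractions
#'
#' Thresholds are the maximum and the 95th percentile of the baseline
#' occipital-ratio values within the putamen of the same patient. The
#' transduction masks are putamen voxels whose post-treatment ratio strictly
#' exceeds the threshold; fractions are percentages of the whole bilateral
#' putamen. The spatial spread of the supra-maximum mask is summarized as
#' the maximum distance to the nearest same-side injection point.
#'
#' @param baseline_ratio,post_ratio occipital-ratio \code{volume_grid}s of
#'   the same patient on one lattice.
#' @param putamen bilateral putamen \code{roi_mask}.
#' @param injections an \code{injection_set} (optional; omit to skip the
#'   distance profile).
#' @return An object of class \code{transduction_result} with thresholds,
#'   masks, fractions (percent of whole putamen) and \code{max_distance_mm}.
#' @export
transduction_mask <- function(baseline_ratio, post_ratio, putamen,
                              injections = NULL) {
  stopifnot_same_lattice(baseline_ratio, post_ratio, "baseline and post volumes")
  stopifnot_same_lattice(baseline_ratio, putamen$grid, "volumes and putamen")
  n_put <- mask_size(putamen)
  if (n_put == 0L) stop("empty putamen mask")
  thr_max <- mask_stats(baseline_ratio, putamen, "max")
  thr_p95 <- mask_stats(baseline_ratio, putamen, "percentile", q = 95)

  supra <- function(thr) {
    m <- array(as.numeric(putamen$grid$data != 0 & post_ratio$data > thr),
               dim = dim(post_ratio$data))
    roi_mask(volume_grid(m, post_ratio$spacing, post_ratio$origin),
             name = paste0("supra_", format(thr, digits = 6)))
  }
  mask_max <- supra(thr_max)
  mask_p95 <- supra(thr_p95)

  dist <- list(max_mm = NA_real_,
               per_side = c(left = NA_real_, right = NA_real_))
  if (!is.null(injections) && mask_size(mask_max) > 0)
    dist <- max_distance_from_points(mask_max, injections)

  structure(
    list(
      threshold_max = thr_max, threshold_p95 = thr_p95,
      mask_max = mask_max, mask_p95 = mask_p95,
      fraction_max = 100 * mask_size(mask_max) / n_put,
      fraction_p95 = 100 * mask_size(mask_p95) / n_put,
      max_distance_mm = dist$max_mm, max_distance_per_side = dist$per_side,
      n_putamen = n_put
    ),
    class = "transduction_result"
  )
}

#' @export
print.transduction_result <- function(x, ...) {
  cat("<transduction_result>\n",
      "  supra-max:  ", round(x$fraction_max, 2), "% of putamen (thr ",
      round(x$threshold_max, 4), ")\n",
      "  supra-p95:  ", round(x$fraction_p95, 2), "% of putamen (thr ",
      round(x$threshold_p95, 4), ")\n",
      "  max spread: ", round(x$max_distance_mm, 2), " mm\n", sep = "")
  invisible(x)
}

#' Voxel-wise paired longitudinal contrast with cluster-extent correction
#'
#' For each voxel the paired difference (post - baseline) across patients is
#' regressed on an intercept plus centered age; the intercept t statistic is
#' the age-adjusted paired contrast. Clusters are formed at an uncorrected
#' two-sided voxel threshold; family-wise error over cluster extent is
#' controlled by sign-flipping the patient difference maps and recording the
#' maximum supra-threshold cluster size per flip. Difference maps are
#' smoothed (default 3 mm FWHM) before testing.
#'
#' @param baseline,post lists of occipital-ratio \code{volume_grid}s, one
#'   pair per patient, all on one lattice.
#' @param age numeric vector of ages at treatment (years).
#' @param voxel_p uncorrected two-sided voxel-level alpha for cluster
#'   formation.
#' @param cluster_p family-wise cluster-level alpha.
#' @param n_perm number of sign-flip permutations; when 2^n <= n_perm all
#'   sign combinations are enumerated (exact test).
#' @param smooth_fwhm_mm Gaussian smoothing applied to difference maps, mm.
#' @param connectivity cluster connectivity (6/18/26).
#' @param cluster_stat cluster summary compared against its sign-flip null:
#'   "mass" (default; sum over the cluster of the excess |t| above the
#'   cluster-forming threshold) or "extent" (voxel count). Mass is the
#'   default because at 2 mm resolution with mild smoothing the extent
#'   statistic is so heavily tied that a 5 percent family-wise level is not
#'   achievable; extent matches the published convention.
#' @param mask optional \code{roi_mask} restricting the analysis.
#' @return list with \code{t_map} (\code{volume_grid}), \code{df},
#'   \code{clusters} (tibble: cluster, size_vox, size_mm3, mass,
#'   corrected_p), \code{cluster_map} (\code{label_map} of supra-threshold
#'   clusters), \code{significant_map} (\code{roi_mask} of clusters with
#'   corrected p <= cluster_p), \code{null_max_stats}, \code{exact}.
#' @export
voxelwise_paired_contrast <- function(baseline, post, age,
                                      voxel_p = 0.001, cluster_p = 0.05,
                                      n_perm = 1000,
                                      smooth_fwhm_mm = 3,
                                      connectivity = 26,
                                      cluster_stat = c("mass", "extent"),
                                      mask = NULL) {
  cluster_stat <- match.arg(cluster_stat)
  n <- length(baseline)
  if (length(post) != n || length(age) != n)
    stop("baseline, post and age must have one entry per patient")
  if (n < 3) stop("need at least 3 patients for the paired contrast")
  if (n_perm < 100)
    warning("n_perm < 100 gives a very coarse cluster-extent null")
  ref <- baseline[[1]]
  d <- dim(ref$data)
  V <- prod(d)

  D <- matrix(0, n, V)
  for (i in seq_len(n)) {
    stopifnot_same_lattice(baseline[[i]], ref, "cohort volumes")
    stopifnot_same_lattice(post[[i]], ref, "cohort volumes")
    diff_grid <- volume_grid(post[[i]]$data - baseline[[i]]$data,
                             ref$spacing, ref$origin)
    diff_grid <- gaussian_smooth(diff_grid, smooth_fwhm_mm)
    D[i, ] <- as.vector(diff_grid$data)
  }
  in_mask <- if (is.null(mask)) rep(TRUE, V) else as.vector(mask$grid$data != 0)

  X <- cbind(1, age - mean(age))
  XtXi <- solve(crossprod(X))
  A <- XtXi %*% t(X)             # 2 x n
  H <- X %*% A
  M <- diag(n) - H               # residual maker, symmetric idempotent
  c00 <- XtXi[1, 1]
  df <- n - ncol(X)

  # sign-flip matrix (first row = identity = observed data)
  exact <- 2^n <= n_perm
  if (exact) {
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))[, n:1, drop = FALSE]
    S <- S[order(rowSums(S == -1)), , drop = FALSE]
  } else {
    # fixed permutation stream, insulated from the caller's RNG state
    rng <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(rng)) assign(".Random.seed", rng, .GlobalEnv))
    set.seed(n_perm + n)
    S <- rbind(rep(1, n),
               matrix(sample(c(1, -1), (n_perm - 1) * n, replace = TRUE),
                      n_perm - 1, n))
  }
  n_flips <- nrow(S)

  # t statistics for every flip at once:
  #   b0_s(v)  = sum_i a0_i s_i D_iv
  #   RSS_s(v) = sum_ij s_i s_j M_ij D_iv D_jv
  a0 <- A[1, ]
  B0 <- (S * matrix(a0, n_flips, n, byrow = TRUE)) %*% D
  P <- matrix(0, n * n, V)
  for (i in seq_len(n))
    for (j in seq_len(n))
      P[(i - 1) * n + j, ] <- M[i, j] * D[i, ] * D[j, ]
  Spair <- matrix(0, n_flips, n * n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      Spair[, (i - 1) * n + j] <- S[, i] * S[, j]
  RSS <- Spair %*% P
  RSS[RSS < 0] <- 0  # numerical guard
  Tmat <- B0 / sqrt(pmax(RSS / df * c00, .Machine$double.xmin))
  Tmat[RSS == 0] <- 0  # all-zero differences carry no evidence

  t_crit <- stats::qt(1 - voxel_p / 2, df)
  excess <- abs(Tmat) - t_crit
  if (!all(in_mask)) excess[, !in_mask] <- -1

  null_stats <- cluster_null_cpp(excess, as.integer(d),
                                 as.integer(connectivity))
  null_max <- if (cluster_stat == "mass") null_stats$max_mass
              else null_stats$max_size

  obs_supra <- array(excess[1, ] > 0, dim = d)
  lab <- array(label_components_cpp(as.logical(obs_supra), as.integer(d),
                                    as.integer(connectivity)), dim = d)
  nclus <- max(lab)
  sizes <- if (nclus > 0) tabulate(lab[lab > 0]) else integer(0)
  masses <- vapply(seq_len(nclus), function(k)
    sum(excess[1, as.vector(lab) == k]), 0)
  obs_stat <- if (cluster_stat == "mass") masses else sizes
  corrected_p <- vapply(obs_stat, function(st) mean(null_max >= st), 0)
  clusters <- tibble::tibble(
    cluster = seq_len(nclus),
    size_vox = sizes,
    size_mm3 = sizes * prod(ref$spacing),
    mass = masses,
    corrected_p = corrected_p
  )
  sig <- array(0, dim = d)
  keep <- which(corrected_p <= cluster_p)
  if (length(keep)) sig[lab %in% keep] <- 1

  list(
    t_map = volume_grid(array(Tmat[1, ], dim = d), ref$spacing, ref$origin),
    df = df,
    clusters = clusters,
    cluster_map = label_map(volume_grid(lab, ref$spacing, ref$origin)),
    significant_map = roi_mask(volume_grid(sig, ref$spacing, ref$origin),
                               "significant_clusters"),
    null_max_stats = null_max,
    cluster_stat = cluster_stat,
    exact = exact,
    t_threshold = t_crit
  )
}
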