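# Synthetic phantom cohort with known ground truth.
#
# The phantom emulates the inputs of the transduction/connectivity pipeline:
# bilateral putamen ellipsoids on a common grid, an occipital reference box,
# two injection tracks per putamen, low baseline uptake plus Gaussian
# post-treatment hotspots, multinomial streamline counts around a banded
# anterior-posterior ground-truth parcellation, and motor scores with a
# designed dependence on the prefrontal transduced fraction plus age.

NETWORKS <- c("visual", "somato/motor", "dorsal attention",
              "ventral attention", "limbic", "frontoparietal control",
              "default")
REGIONS <- c("PFC", "PMC", "SMA", "M1", "other")

#' Derive a reproducible seed for a sub-stream of randomness
#'
#' All stochastic stages consume seeds derived from one master seed by this
#' scheme, so a whole run is a pure function of the master seed.
#'
#' @param master master seed (integer).
#' @param i,j stream indices (e.g. patient, stage).
#' @return an integer seed below 2^31.
#' @export
seed_stream <- function(master, i = 0L, j = 0L) {
  as.integer((as.numeric(master) + 7919 * i + 104729 * j) %% 2147483647)
}

#' Phantom cohort specification
#'
#' Defaults define the study conditions: a 64^3 grid at 2 mm (PET voxel
#' size), putamen ellipsoids of realistic volume (~6 cm^3 per side), two
#' injection tracks per side, 5000 streamline draws per seed voxel, and a
#' motor-score model whose designed effect is carried by the prefrontal
#' transduced fraction only.
#'
#' @param shape grid dimensions (voxels).
#' @param spacing voxel size, mm.
#' @param putamen_center_x lateral offset of the putamen centers, mm.
#' @param putamen_semi_axes ellipsoid semi-axes (x, y, z), mm.
#' @param occipital_box list of x/y/z mm ranges for the reference region.
#' @param injection_offsets list with `anterior`/`posterior` offsets (mm)
#'   from each putamen center; two tracks per side.
#' @param band_edges_mm named y thresholds (mm) separating the PFC / PMC /
#'   SMA / M1 / other territories of the ground-truth parcellation
#'   (anterior = positive y).
#' @param n_targets number of cortical target ROIs (K).
#' @param region_alloc named integer vector: targets per structural region.
#' @param baseline_putamen,background,occipital_level mean intensities in
#'   occipital-ratio units.
#' @param noise_sd additive Gaussian noise sd (ratio units).
#' @param hotspot_amplitude mean hotspot peak amplitude (ratio units).
#' @param amplitude_range multiplicative per-track amplitude range (uniform).
#' @param hotspot_sigma_mm Gaussian hotspot width, mm.
#' @param decay_2y multiplicative amplitude decay from 6M to 2Y.
#' @param n_streamlines streamline draws per seed voxel.
#' @param kappa probability mass on the true target label, in (0, 1].
#' @param beta designed motor-score slope, AIMS points per percent
#'   prefrontal transduced fraction.
#' @param gamma_age age covariate slope, AIMS points per year.
#' @param score_intercept baseline improvement, AIMS points.
#' @param score_noise_sd motor-score noise sd, AIMS points.
#' @param aims_max AIMS ceiling used for clipping.
#' @param age_range treatment-age range, years.
#' @param weight_range_g body-weight range, grams.
#' @param dose_mbq_per_kg injected tracer dose per kg, MBq.
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         spacing = c(2, 2, 2),
                         putamen_center_x = 26,
                         putamen_semi_axes = c(8, 18, 10),
                         occipital_box = list(x = c(-30, 30),
                                              y = c(-60, -40),
                                              z = c(-10, 20)),
                         injection_offsets = list(anterior = c(0, 13, 2),
                                                  posterior = c(0, -6, 4)),
                         band_edges_mm = c(pfc = 3, pmc = 0, sma = -4, m1 = -12),
                         n_targets = 60,
                         region_alloc = c(PFC = 16, PMC = 8, SMA = 8,
                                          M1 = 12, other = 16),
                         baseline_putamen = 1.05,
                         background = 1.0,
                         occipital_level = 1.0,
                         noise_sd = 0.02,
                         hotspot_amplitude = 1.0,
                         amplitude_range = c(0.4, 1.6),
                         hotspot_sigma_mm = 3.5,
                         decay_2y = 0.9,
                         n_streamlines = 5000,
                         kappa = 0.5,
                         beta = 1.5,
                         gamma_age = -0.4,
                         score_intercept = 8,
                         score_noise_sd = 1.5,
                         aims_max = 58,
                         age_range = c(4, 19),
                         weight_range_g = c(12000, 50000),
                         dose_mbq_per_kg = 4.44) {
  spec <- list(
    shape = as.integer(shape), spacing = as.numeric(spacing),
    putamen_center_x = putamen_center_x,
    putamen_semi_axes = as.numeric(putamen_semi_axes),
    occipital_box = occipital_box,
    injection_offsets = injection_offsets,
    band_edges_mm = band_edges_mm,
    n_targets = as.integer(n_targets), region_alloc = region_alloc,
    baseline_putamen = baseline_putamen, background = background,
    occipital_level = occipital_level, noise_sd = noise_sd,
    hotspot_amplitude = hotspot_amplitude,
    amplitude_range = as.numeric(amplitude_range),
    hotspot_sigma_mm = hotspot_sigma_mm, decay_2y = decay_2y,
    n_streamlines = as.integer(n_streamlines), kappa = kappa,
    beta = beta, gamma_age = gamma_age,
    score_intercept = score_intercept, score_noise_sd = score_noise_sd,
    aims_max = aims_max, age_range = as.numeric(age_range),
    weight_range_g = as.numeric(weight_range_g),
    dose_mbq_per_kg = dose_mbq_per_kg
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  if (any(spec$shape <= 0)) note("grid shape must be positive")
  if (any(spec$spacing <= 0)) note("voxel spacing must be positive")
  if (any(spec$putamen_semi_axes <= 0))
    note("degenerate putamen ellipsoid: all semi-axes must be > 0")
  if (spec$hotspot_sigma_mm <= 0) note("hotspot width sigma must be > 0")
  if (spec$hotspot_amplitude < 0) note("hotspot amplitude must be >= 0")
  if (spec$noise_sd < 0) note("noise sd must be >= 0")
  if (spec$kappa <= 0 || spec$kappa > 1) note("kappa must be in (0, 1]")
  if (spec$n_streamlines < 1) note("n_streamlines must be >= 1")
  if (spec$n_targets < 2) note("need at least K = 2 targets")
  if (sum(spec$region_alloc) != spec$n_targets)
    note("region_alloc must sum to n_targets")
  if (!identical(sort(names(spec$region_alloc)), sort(REGIONS)))
    note("region_alloc must name exactly the regions PFC/PMC/SMA/M1/other")
  if (length(problems))
    stop("invalid phantom spec:\n  - ", paste(problems, collapse = "\n  - "))
  invisible(spec)
}

#' Reduced-grid phantom spec for simulation studies
#'
#' Same model on a 32^3 grid with scaled anatomy; used where many phantom
#' cohorts are generated (e.g. family-wise error calibration).
#'
#' @param ... overrides passed on to \code{\link{phantom_spec}}.
#' @return a \code{phantom_spec}.
#' @export
small_phantom_spec <- function(...) {
  args <- utils::modifyList(list(
    shape = c(32, 32, 32), spacing = c(2, 2, 2),
    putamen_center_x = 13, putamen_semi_axes = c(5, 9, 6),
    occipital_box = list(x = c(-15, 15), y = c(-30, -20), z = c(-6, 10)),
    injection_offsets = list(anterior = c(0, 6, 1), posterior = c(0, -3, 2)),
    band_edges_mm = c(pfc = 1.5, pmc = 0, sma = -2, m1 = -6),
    hotspot_sigma_mm = 3
  ), list(...))
  do.call(phantom_spec, args)
}

spec_grid <- function(spec) {
  origin <- -(spec$shape - 1) / 2 * spec$spacing
  volume_grid(array(0, dim = spec$shape), spacing = spec$spacing,
              origin = origin)
}

grid_coordinates <- function(grid) {
  d <- dim(grid$data)
  x <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  y <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  z <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  list(
    x = array(rep(x, times = d[2] * d[3]), dim = d),
    y = array(rep(rep(y, each = d[1]), times = d[3]), dim = d),
    z = array(rep(z, each = d[1] * d[2]), dim = d)
  )
}

# ---- anatomy ---------------------------------------------------------------

#' Build phantom anatomy
#'
#' Produces bilateral putamen ellipsoid masks, the occipital reference box,
#' the cortical target hierarchy table and the injection points, all on the
#' common grid.
#'
#' @param spec a \code{phantom_spec}.
#' @return list with \code{putamen_left}, \code{putamen_right},
#'   \code{putamen} (bilateral), \code{occipital} (\code{roi_mask}s),
#'   \code{hierarchy} (\code{target_hierarchy}), \code{injections}
#'   (\code{injection_set}), \code{grid} and \code{spec}.
#' @export
make_anatomy <- function(spec) {
  validate_phantom_spec(spec)
  grid <- spec_grid(spec)
  co <- grid_coordinates(grid)
  semi <- spec$putamen_semi_axes
  ellipsoid <- function(center) {
    inside <- ((co$x - center[1]) / semi[1])^2 +
      ((co$y - center[2]) / semi[2])^2 +
      ((co$z - center[3]) / semi[3])^2 <= 1
    array(as.numeric(inside), dim = spec$shape)
  }
  c_l <- c(-spec$putamen_center_x, 0, 0)
  c_r <- c(spec$putamen_center_x, 0, 0)
  put_l <- ellipsoid(c_l)
  put_r <- ellipsoid(c_r)
  box <- spec$occipital_box
  occ <- array(as.numeric(
    co$x >= box$x[1] & co$x <= box$x[2] &
    co$y >= box$y[1] & co$y <= box$y[2] &
    co$z >= box$z[1] & co$z <= box$z[2]), dim = spec$shape)
  if (any((put_l + put_r) * occ > 0))
    stop("phantom definition invalid: putamen and occipital regions overlap")
  if (sum(put_l) == 0 || sum(put_r) == 0 || sum(occ) == 0)
    stop("phantom regions must be nonempty on this grid")
  mk <- function(a, nm) roi_mask(volume_grid(a, grid$spacing, grid$origin), nm)
  bilateral <- mk(pmin(put_l + put_r, 1), "putamen")
  pts <- rbind(
    c_l + spec$injection_offsets$anterior,
    c_l + spec$injection_offsets$posterior,
    c_r + spec$injection_offsets$anterior,
    c_r + spec$injection_offsets$posterior
  )
  list(
    putamen_left = mk(put_l, "putamen_left"),
    putamen_right = mk(put_r, "putamen_right"),
    putamen = bilateral,
    occipital = mk(occ, "occipital"),
    hierarchy = make_hierarchy(spec),
    injections = injection_set(pts, c("left", "left", "right", "right")),
    grid = grid,
    spec = spec
  )
}

# Deterministic target hierarchy: K targets allocated to structural regions,
# each region's targets spread over a fixed set of plausible networks.
make_hierarchy <- function(spec) {
  pools <- list(
    PFC = rep(c("frontoparietal control", "default", "limbic",
                "ventral attention"),
              times = pmax(0, round(spec$region_alloc[["PFC"]] *
                                      c(0.5, 0.3, 0.13, 0.07)))),
    PMC = rep(c("somato/motor", "dorsal attention"),
              times = pmax(0, round(spec$region_alloc[["PMC"]] * c(0.5, 0.5)))),
    SMA = rep(c("somato/motor", "ventral attention"),
              times = pmax(0, round(spec$region_alloc[["SMA"]] * c(0.75, 0.25)))),
    M1 = rep("somato/motor", spec$region_alloc[["M1"]]),
    other = rep(c("visual", "limbic", "default"),
                times = pmax(0, round(spec$region_alloc[["other"]] *
                                        c(0.5, 0.25, 0.25))))
  )
  region <- character(0); network <- character(0)
  for (r in REGIONS) {
    k <- spec$region_alloc[[r]]
    pool <- pools[[r]]
    # pad/trim the pool to exactly k entries
    nets <- rep(pool, length.out = k)
    region <- c(region, rep(r, k))
    network <- c(network, nets)
  }
  target_hierarchy(tibble::tibble(
    target_id = seq_len(spec$n_targets),
    network = network,
    region = region
  ))
}

# ---- ground-truth parcellation --------------------------------------------

# Structural-region band of each putamen voxel from its anterior-posterior
# (y) coordinate; anterior is PFC-like, posterior sensorimotor.
band_region <- function(y, edges) {
  r <- rep("other", length(y))
  r[y > edges[["m1"]]] <- "M1"
  r[y > edges[["sma"]]] <- "SMA"
  r[y > edges[["pmc"]]] <- "PMC"
  r[y > edges[["pfc"]]] <- "PFC"
  r
}

#' Ground-truth parcellation of the phantom putamen
#'
#' Each voxel's structural region is fixed by its anterior-posterior band;
#' within a band, voxels are split among that region's targets by nearest
#' target centroid (centroids drawn within the band, per side), giving a
#' spatially smooth piecewise-constant label field.
#'
#' @param anatomy output of \code{\link{make_anatomy}}.
#' @param seed integer seed for centroid placement.
#' @return list with \code{labels} (\code{label_map} over the bilateral
#'   putamen), \code{voxels} (0-based n x 3 index matrix), \code{label_vec}
#'   (per-voxel target ids, aligned with \code{voxels}).
#' @export
make_truth_parcellation <- function(anatomy, seed) {
  if (missing(seed)) stop("`seed` is required: generators must be reproducible")
  spec <- anatomy$spec
  set.seed(seed)
  hier <- anatomy$hierarchy$table
  lab_arr <- array(0L, dim = spec$shape)
  for (side in c("left", "right")) {
    m <- if (side == "left") anatomy$putamen_left else anatomy$putamen_right
    idx <- which(m$grid$data != 0, arr.ind = TRUE) - 1L
    xyz <- voxel_to_world(m$grid, idx)
    vox_region <- band_region(xyz[, 2], spec$band_edges_mm)
    lab <- integer(nrow(idx))
    for (r in REGIONS) {
      in_band <- which(vox_region == r)
      targets <- hier$target_id[hier$region == r]
      if (!length(in_band)) next
      if (length(targets) == 1L) { lab[in_band] <- targets; next }
      cent_rows <- sample(in_band, length(targets),
                          replace = length(in_band) < length(targets))
      cent <- xyz[cent_rows, , drop = FALSE]
      d2 <- matrix(0, length(in_band), length(targets))
      for (tcol in seq_along(targets))
        d2[, tcol] <- (xyz[in_band, 1] - cent[tcol, 1])^2 +
          (xyz[in_band, 2] - cent[tcol, 2])^2 +
          (xyz[in_band, 3] - cent[tcol, 3])^2
      lab[in_band] <- targets[max.col(-d2, ties.method = "first")]
    }
    lab_arr[idx + 1L] <- lab  # n x 3 matrix indexing
  }
  g <- volume_grid(lab_arr, anatomy$grid$spacing, anatomy$grid$origin)
  vox <- which(anatomy$putamen$grid$data != 0, arr.ind = TRUE) - 1L
  list(
    labels = label_map(g),
    voxels = vox,
    label_vec = lab_arr[vox + 1L]
  )
}

# ---- PET volumes -----------------------------------------------------------

#' Per-patient generative parameters
#'
#' Anterior and posterior track amplitudes are drawn independently, so the
#' prefrontal transduced fraction (driven by the anterior track) varies
#' independently of the motor-territory fractions (posterior track).
#'
#' @param spec a \code{phantom_spec}.
#' @param seed integer seed.
#' @return list of per-patient parameters.
#' @export
patient_params <- function(spec, seed) {
  if (missing(seed)) stop("`seed` is required: generators must be reproducible")
  set.seed(seed)
  list(
    amp_anterior = spec$hotspot_amplitude *
      stats::runif(1, spec$amplitude_range[1], spec$amplitude_range[2]),
    amp_posterior = spec$hotspot_amplitude *
      stats::runif(1, spec$amplitude_range[1], spec$amplitude_range[2]),
    weight_g = stats::runif(1, spec$weight_range_g[1], spec$weight_range_g[2]),
    age = stats::runif(1, spec$age_range[1], spec$age_range[2])
  )
}

#' Generate a phantom PET scan
#'
#' Baseline is background noise plus a low uniform putamen uptake; the
#' post-treatment timepoints add one Gaussian hotspot per injection track,
#' truncated to the putamen. The returned volume is raw radioactivity
#' concentration (MBq/g) so the SUV arithmetic downstream is exercised.
#'
#' @param spec a \code{phantom_spec}.
#' @param anatomy output of \code{\link{make_anatomy}}.
#' @param timepoint one of "baseline", "6M", "2Y".
#' @param seed integer seed (mandatory).
#' @param params per-patient parameters from \code{\link{patient_params}};
#'   drawn from \code{seed} when omitted.
#' @param patient patient identifier carried along.
#' @return a \code{pet_scan}.
#' @export
make_pet <- function(spec, anatomy, timepoint = c("baseline", "6M", "2Y"),
                     seed, params = NULL, patient = "phantom") {
  if (missing(seed)) stop("`seed` is required: generators must be reproducible")
  timepoint <- match.arg(timepoint)
  if (is.null(params)) params <- patient_params(spec, seed)
  set.seed(seed)
  dose_jitter <- stats::runif(1, 0.95, 1.05)
  noise <- stats::rnorm(prod(spec$shape), 0, spec$noise_sd)

  grid <- anatomy$grid
  put <- anatomy$putamen$grid$data != 0
  occ <- anatomy$occipital$grid$data != 0
  s <- array(spec$background, dim = spec$shape)
  s[occ] <- spec$occipital_level
  s[put] <- spec$baseline_putamen

  if (timepoint != "baseline") {
    decay <- if (timepoint == "2Y") spec$decay_2y else 1
    xyz <- mask_coordinates(anatomy$putamen)
    hot <- numeric(nrow(xyz))
    pts <- anatomy$injections$points
    amp <- rep(c(params$amp_anterior, params$amp_posterior), times = 2)
    for (p in seq_len(nrow(pts))) {
      d2 <- (xyz[, 1] - pts[p, 1])^2 + (xyz[, 2] - pts[p, 2])^2 +
            (xyz[, 3] - pts[p, 3])^2
      hot <- hot + decay * amp[p] * exp(-d2 / (2 * spec$hotspot_sigma_mm^2))
    }
    s[put] <- s[put] + hot
  }
  s <- s + array(noise, dim = spec$shape)

  weight <- params$weight_g
  dose <- spec$dose_mbq_per_kg * weight / 1000 * dose_jitter
  conc <- s * (dose / weight)  # MBq/g, so SUV recovers the ratio-scale field
  pet_scan(volume_grid(conc, grid$spacing, grid$origin),
           injected_dose = dose, body_weight = weight,
           timepoint = timepoint, patient = patient)
}

# ---- connectivity ----------------------------------------------------------

#' Generate phantom streamline counts
#'
#' For each putamen voxel, counts toward the K targets are multinomial with
#' probability \code{kappa} on the voxel's true label and the remaining mass
#' spread evenly, emulating probabilistic-tractography output around the
#' ground-truth parcellation.
#'
#' @param spec a \code{phantom_spec}.
#' @param anatomy output of \code{\link{make_anatomy}}.
#' @param truth output of \code{\link{make_truth_parcellation}}.
#' @param seed integer seed (mandatory).
#' @return a \code{connectivity_map}.
#' @export
make_connectivity <- function(spec, anatomy, truth, seed) {
  if (missing(seed)) stop("`seed` is required: generators must be reproducible")
  K <- spec$n_targets
  if (K < 2) stop("need at least K = 2 targets")
  set.seed(seed)
  lab <- truth$label_vec
  n <- length(lab)
  counts <- matrix(0L, n, K)
  for (t in sort(unique(lab))) {
    rows <- which(lab == t)
    p <- rep((1 - spec$kappa) / (K - 1), K)
    p[t] <- spec$kappa
    counts[rows, ] <- t(stats::rmultinom(length(rows), spec$n_streamlines, p))
  }
  connectivity_map(anatomy$putamen, truth$voxels, counts,
                   target_ids = seq_len(K))
}

# ---- motor scores ----------------------------------------------------------

#' Generate phantom motor scores
#'
#' AIMS change from baseline to 6M is
#' \code{intercept + beta * prefrontal_fraction + gamma_age * age + noise},
#' optionally discretized to integers and clipped to the AIMS range; the 2Y
#' score adds a further improvement increment. A Cognition-Adaptation (C-A)
#' score with the same designed dependence is generated alongside.
#'
#' @param spec a \code{phantom_spec}.
#' @param truth_tbl data frame with columns \code{patient}, \code{age} and
#'   \code{frac_pfc} (prefrontal transduced fraction at 6M, percent).
#' @param seed integer seed (mandatory).
#' @param discretize round scores to integers and clip to [0, aims_max].
#' @return tibble with AIMS per timepoint, AIMS changes and C-A scores.
#' @export
make_motor_scores <- function(spec, truth_tbl, seed, discretize = TRUE) {
  if (missing(seed)) stop("`seed` is required: generators must be reproducible")
  stopifnot(all(c("patient", "age", "frac_pfc") %in% names(truth_tbl)))
  set.seed(seed)
  n <- nrow(truth_tbl)
  clip <- function(v) pmin(pmax(v, 0), spec$aims_max)
  disc <- function(v) if (discretize) clip(round(v)) else v

  aims_bl <- disc(stats::rnorm(n, 4, 1.5))
  delta_6m <- spec$score_intercept + spec$beta * truth_tbl$frac_pfc +
    spec$gamma_age * truth_tbl$age + stats::rnorm(n, 0, spec$score_noise_sd)
  aims_6m <- disc(aims_bl + delta_6m)
  delta_2y <- 6 + stats::rnorm(n, 0, spec$score_noise_sd)
  aims_2y <- disc(aims_6m + delta_2y)
  ca_bl <- disc(stats::rnorm(n, 5, 1.5))
  ca_2y <- disc(ca_bl + 0.8 * delta_6m + stats::rnorm(n, 0, spec$score_noise_sd))

  tibble::tibble(
    patient = truth_tbl$patient,
    age = truth_tbl$age,
    aims_baseline = aims_bl,
    aims_6m = aims_6m,
    aims_2y = aims_2y,
    delta_aims_6m = aims_6m - aims_bl,
    delta_aims_2y = aims_2y - aims_bl,
    ca_baseline = ca_bl,
    ca_2y = ca_2y
  )
}

# ---- whole-patient and whole-cohort simulation -----------------------------

#' Simulate one phantom patient through the full pipeline
#'
#' Generates the three PET timepoints and two connectivity draws, then runs
#' the quantification chain (SUV, occipital ratio, transduction masks,
#' winner-take-all parcellation, volume fractions) exactly as it would run
#' on real data. Ground truth (stored alongside) uses the true label field
#' with the same transduction masks.
#'
#' @param spec a \code{phantom_spec}.
#' @param anatomy from \code{\link{make_anatomy}}.
#' @param truth from \code{\link{make_truth_parcellation}}.
#' @param patient patient identifier.
#' @param seed integer seed (mandatory).
#' @param keep_volumes keep scans/ratio maps/label maps in the result
#'   (memory-heavy; disable for large simulated cohorts).
#' @return list with per-timepoint results, fraction profiles, truth values
#'   and the drawn parameters.
#' @export
simulate_patient <- function(spec, anatomy, truth, patient, seed,
                             keep_volumes = TRUE) {
  if (missing(seed)) stop("`seed` is required: generators must be reproducible")
  params <- patient_params(spec, seed_stream(seed, 0, 1))
  scans <- list(
    baseline = make_pet(spec, anatomy, "baseline",
                        seed = seed_stream(seed, 0, 2), params = params,
                        patient = patient),
    `6M` = make_pet(spec, anatomy, "6M", seed = seed_stream(seed, 0, 3),
                    params = params, patient = patient),
    `2Y` = make_pet(spec, anatomy, "2Y", seed = seed_stream(seed, 0, 4),
                    params = params, patient = patient)
  )
  ratio <- lapply(scans, function(sc)
    to_occipital_ratio(compute_suv(sc), anatomy$occipital))

  trans <- list(
    `6M` = transduction_mask(ratio$baseline, ratio$`6M`, anatomy$putamen,
                             anatomy$injections),
    `2Y` = transduction_mask(ratio$baseline, ratio$`2Y`, anatomy$putamen,
                             anatomy$injections)
  )

  conn <- list(
    baseline = make_connectivity(spec, anatomy, truth,
                                 seed = seed_stream(seed, 0, 5)),
    `2Y` = make_connectivity(spec, anatomy, truth,
                             seed = seed_stream(seed, 0, 6))
  )
  labels <- lapply(conn, winner_take_all)

  hier <- anatomy$hierarchy
  put <- anatomy$putamen
  # pairing scheme: baseline parcellation masked with the 6M transduction
  # mask; 2Y parcellation masked with the 2Y mask
  profiles <- list(
    whole_baseline = connection_fractions(labels$baseline, put, hier),
    whole_2y = connection_fractions(labels$`2Y`, put, hier),
    transduced_6m = transduced_connection_fractions(
      labels$baseline, trans$`6M`$mask_max, put, hier),
    transduced_2y = transduced_connection_fractions(
      labels$`2Y`, trans$`2Y`$mask_max, put, hier)
  )
  pfc_control <- c(
    `6M` = pfc_control_overlap_fraction(labels$baseline, trans$`6M`$mask_max,
                                        put, hier),
    `2Y` = pfc_control_overlap_fraction(labels$`2Y`, trans$`2Y`$mask_max,
                                        put, hier)
  )

  truth_profiles <- list(
    whole = connection_fractions(truth$labels, put, hier),
    transduced_6m = transduced_connection_fractions(
      truth$labels, trans$`6M`$mask_max, put, hier),
    transduced_2y = transduced_connection_fractions(
      truth$labels, trans$`2Y`$mask_max, put, hier)
  )
  truth_pfc_control <- c(
    `6M` = pfc_control_overlap_fraction(truth$labels, trans$`6M`$mask_max,
                                        put, hier),
    `2Y` = pfc_control_overlap_fraction(truth$labels, trans$`2Y`$mask_max,
                                        put, hier)
  )

  wta_accuracy <- mean(wta_labels_vector(labels$baseline, truth$voxels) ==
                         truth$label_vec)

  out <- list(
    patient = patient, params = params,
    transduction = trans, profiles = profiles, pfc_control = pfc_control,
    truth = list(profiles = truth_profiles, pfc_control = truth_pfc_control,
                 frac_max = vapply(trans, function(t) t$fraction_max, 0),
                 frac_p95 = vapply(trans, function(t) t$fraction_p95, 0)),
    wta_accuracy = wta_accuracy
  )
  if (keep_volumes) {
    out$scans <- scans
    out$ratio <- ratio
    out$conn <- conn
    out$labels <- labels
  }
  out
}

wta_labels_vector <- function(labels, voxels) {
  labels$grid$data[voxels + 1L]
}

#' Simulate a phantom cohort
#'
#' One shared anatomy and ground-truth parcellation (template-like), with
#' per-patient amplitudes, noise, connectivity draws and scores. Returns the
#' cohort table that feeds the statistics layer, with both estimated
#' (pipeline-derived) and ground-truth fraction columns.
#'
#' @param spec a \code{phantom_spec}.
#' @param n_patients number of phantom patients.
#' @param seed master seed (mandatory).
#' @param keep_volumes keep per-patient volumes (see
#'   \code{\link{simulate_patient}}).
#' @return list with \code{anatomy}, \code{truth}, \code{patients},
#'   \code{cohort} (a \code{\link{cohort_table}}).
#' @export
simulate_cohort <- function(spec, n_patients = 8, seed,
                            keep_volumes = FALSE) {
  if (missing(seed)) stop("`seed` is required: generators must be reproducible")
  anatomy <- make_anatomy(spec)
  truth <- make_truth_parcellation(anatomy, seed = seed_stream(seed, 0, 100))
  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    patients[[i]] <- simulate_patient(
      spec, anatomy, truth, patient = sprintf("pt%02d", i),
      seed = seed_stream(seed, i, 0), keep_volumes = keep_volumes)
  }
  frac_row <- function(p) {
    pr <- p$profiles$transduced_6m
    tr <- p$truth$profiles$transduced_6m
    nets <- stats::setNames(pr$per_network, paste0("net_", gsub("[ /]", "_", names(pr$per_network))))
    c(
      stats::setNames(pr$per_region[REGIONS],
                      paste0("frac_", tolower(REGIONS))),
      nets,
      frac_pfc_control = unname(p$pfc_control[["6M"]]),
      fraction_max_6m = p$transduction$`6M`$fraction_max,
      fraction_p95_6m = p$transduction$`6M`$fraction_p95,
      fraction_max_2y = p$transduction$`2Y`$fraction_max,
      fraction_p95_2y = p$transduction$`2Y`$fraction_p95,
      max_distance_mm_6m = p$transduction$`6M`$max_distance_mm,
      truth_frac_pfc = unname(tr$per_region[["PFC"]]),
      wta_accuracy = p$wta_accuracy
    )
  }
  fr <- do.call(rbind, lapply(patients, frac_row))
  truth_tbl <- tibble::tibble(
    patient = vapply(patients, function(p) p$patient, ""),
    age = vapply(patients, function(p) p$params$age, 0),
    frac_pfc = fr[, "truth_frac_pfc"]
  )
  scores <- make_motor_scores(spec, truth_tbl,
                              seed = seed_stream(seed, 0, 200))
  cohort <- cohort_table(cbind(scores, tibble::as_tibble(fr)))
  list(anatomy = anatomy, truth = truth, patients = patients,
       cohort = cohort, spec = spec)
}
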