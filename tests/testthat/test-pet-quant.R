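# SUV arithmetic, occipital normalization, ROI uptake, transduction masks
# and the voxel-wise longitudinal contrast.

test_that("SUV formula: concentration over dose-per-weight, voxel-wise", {
  g <- make_grid(array(0.002, dim = c(4, 4, 4)))
  scan <- pet_scan(g, injected_dose = 100, body_weight = 50000)
  expect_equal(compute_suv(scan)$data, array(1, dim = c(4, 4, 4)))

  g0 <- make_grid(array(0, dim = c(4, 4, 4)))
  expect_equal(compute_suv(pet_scan(g0, 10, 1000))$data,
               array(0, dim = c(4, 4, 4)))

  set.seed(12)
  conc <- array(runif(64, 0, 0.01), dim = c(4, 4, 4))
  suv <- compute_suv(pet_scan(make_grid(conc), 77, 23456))
  # element-by-element scalar oracle
  for (i in sample(64, 10))
    expect_equal(suv$data[i], conc[i] / (77 / 23456))
  expect_error(pet_scan(g, injected_dose = 0, body_weight = 100), "dose")
  expect_error(pet_scan(g, injected_dose = 10, body_weight = -5), "weight")
})

test_that("occipital ratio normalizes to the reference mean and is scale invariant", {
  arr <- array(2, dim = c(4, 4, 4))
  occ <- array(0, dim = c(4, 4, 4)); occ[1:8] <- 1
  m <- make_mask(occ)
  r <- to_occipital_ratio(make_grid(arr), m)
  expect_equal(r$data, array(1, dim = c(4, 4, 4)))

  set.seed(2)
  v <- array(runif(64, 0.5, 2), dim = c(4, 4, 4))
  r1 <- to_occipital_ratio(make_grid(v), m)
  expect_equal(mask_stats(r1, m, "mean"), 1)
  for (c in c(0.1, 3, 10))
    expect_equal(to_occipital_ratio(make_grid(c * v), m)$data, r1$data)

  expect_error(to_occipital_ratio(make_grid(array(-1, c(4, 4, 4))), m),
               "unusable reference")
})

test_that("ROI uptake table reports medians per ROI and timepoint", {
  occ <- array(0, dim = c(5, 5, 5)); occ[1:10] <- 1
  m_occ <- make_mask(occ, name = "occipital")
  roi_a <- array(0, dim = c(5, 5, 5)); roi_a[30:39] <- 1
  roi_b <- array(0, dim = c(5, 5, 5)); roi_b[60:69] <- 1
  ones <- make_grid(array(1, dim = c(5, 5, 5)))
  tab <- roi_uptake_table(list(baseline = ones),
                          list(make_mask(roi_a, name = "a"),
                               make_mask(roi_b, name = "b")))
  expect_equal(tab$median_ratio, c(1, 1))
  # permuting the ROI list permutes rows only
  tab2 <- roi_uptake_table(list(baseline = ones),
                           list(make_mask(roi_b, name = "b"),
                                make_mask(roi_a, name = "a")))
  expect_equal(tab2$roi, rev(tab$roi))

  # phantom: putamen median rises after treatment
  spec <- small_phantom_spec()
  anat <- make_anatomy(spec)
  params <- patient_params(spec, seed = 5)
  r_bl <- to_occipital_ratio(compute_suv(
    make_pet(spec, anat, "baseline", seed = 11, params = params)), anat$occipital)
  r_6m <- to_occipital_ratio(compute_suv(
    make_pet(spec, anat, "6M", seed = 12, params = params)), anat$occipital)
  tab3 <- roi_uptake_table(list(baseline = r_bl, `6M` = r_6m),
                           list(anat$putamen), patient = "pt01")
  expect_gt(tab3$median_ratio[tab3$timepoint == "6M"],
            tab3$median_ratio[tab3$timepoint == "baseline"])
})

test_that("transduction masks: strict threshold, nesting, and fraction limits", {
  spec <- small_phantom_spec()
  anat <- make_anatomy(spec)
  params <- patient_params(spec, seed = 5)
  r_bl <- to_occipital_ratio(compute_suv(
    make_pet(spec, anat, "baseline", seed = 21, params = params)), anat$occipital)

  # post identical to baseline: strict ">" leaves the mask empty
  tr_same <- transduction_mask(r_bl, r_bl, anat$putamen)
  expect_equal(tr_same$fraction_max, 0)
  expect_equal(mask_size(tr_same$mask_max), 0)

  # uniform +1 inside the putamen: everything supra-max
  plus <- r_bl$data + anat$putamen$grid$data
  tr_plus <- transduction_mask(r_bl, make_grid(plus, spacing = r_bl$spacing,
                                               origin = r_bl$origin),
                               anat$putamen)
  expect_equal(tr_plus$fraction_max, 100)

  # effect phantom: p95 mask contains the max mask, fractions ordered
  r_6m <- to_occipital_ratio(compute_suv(
    make_pet(spec, anat, "6M", seed = 22, params = params)), anat$occipital)
  tr <- transduction_mask(r_bl, r_6m, anat$putamen, anat$injections)
  expect_lte(tr$threshold_p95, tr$threshold_max)
  expect_gte(tr$fraction_p95, tr$fraction_max)
  expect_true(all(tr$mask_p95$grid$data >= tr$mask_max$grid$data))
  expect_true(tr$fraction_max >= 0 && tr$fraction_p95 <= 100)
  expect_gt(tr$max_distance_mm, 0)
})

test_that("paired voxel-wise contrast finds nothing when post equals baseline", {
  spec <- small_phantom_spec()
  anat <- make_anatomy(spec)
  vols <- lapply(1:4, function(i) {
    params <- patient_params(spec, seed = i)
    to_occipital_ratio(compute_suv(
      make_pet(spec, anat, "baseline", seed = 30 + i, params = params)),
      anat$occipital)
  })
  vw <- voxelwise_paired_contrast(vols, vols, age = c(5, 9, 12, 16),
                                  n_perm = 200)
  expect_equal(nrow(vw$clusters), 0)
  expect_true(all(vw$t_map$data == 0))
  # the extent statistic is available as an alternative cluster summary
  vw2 <- voxelwise_paired_contrast(vols, vols, age = c(5, 9, 12, 16),
                                   n_perm = 200, cluster_stat = "extent")
  expect_equal(nrow(vw2$clusters), 0)
})

test_that("paired voxel-wise contrast recovers a designed hotspot (Dice > 0.5)", {
  spec <- small_phantom_spec(noise_sd = 0.05, amplitude_range = c(1, 1))
  anat <- make_anatomy(spec)
  n <- 8
  bl <- list(); po <- list(); ages <- numeric(0)
  for (i in seq_len(n)) {
    params <- patient_params(spec, seed = 100 + i)
    bl[[i]] <- to_occipital_ratio(compute_suv(
      make_pet(spec, anat, "baseline", seed = 200 + i, params = params)),
      anat$occipital)
    po[[i]] <- to_occipital_ratio(compute_suv(
      make_pet(spec, anat, "6M", seed = 300 + i, params = params)),
      anat$occipital)
    ages <- c(ages, params$age)
  }
  vw <- voxelwise_paired_contrast(bl, po, ages, n_perm = 256)
  expect_true(any(vw$clusters$corrected_p <= 0.05))

  # truth support: noiseless hotspot field above half the baseline noise sd
  xyz <- mask_coordinates(anat$putamen)
  pts <- anat$injections$points
  hot <- numeric(nrow(xyz))
  for (p in seq_len(nrow(pts))) {
    d2 <- (xyz[, 1] - pts[p, 1])^2 + (xyz[, 2] - pts[p, 2])^2 +
      (xyz[, 3] - pts[p, 3])^2
    hot <- hot + spec$hotspot_amplitude * exp(-d2 / (2 * spec$hotspot_sigma_mm^2))
  }
  truth_arr <- array(0, dim = dim(anat$putamen$grid$data))
  truth_arr[anat$putamen$grid$data != 0] <- as.numeric(hot > 0.1)
  sig <- vw$significant_map$grid$data
  dice <- 2 * sum(sig * truth_arr) / (sum(sig) + sum(truth_arr))
  expect_gt(dice, 0.5)
})
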