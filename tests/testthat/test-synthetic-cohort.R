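# Phantom generator: anatomy construction, PET fields, connectivity draws,
# ground-truth consistency and the designed motor-score model.

spec32 <- small_phantom_spec()
anat32 <- make_anatomy(spec32)

test_that("phantom anatomy is well formed", {
  expect_gt(mask_size(anat32$putamen_left), 0)
  expect_gt(mask_size(anat32$putamen_right), 0)
  # putamen and occipital reference are disjoint
  expect_equal(sum(anat32$putamen$grid$data * anat32$occipital$grid$data), 0)
  # hierarchy is a total function over K targets
  h <- anat32$hierarchy$table
  expect_equal(nrow(h), spec32$n_targets)
  expect_equal(anyDuplicated(h$target_id), 0)

  expect_error(phantom_spec(putamen_semi_axes = c(0, 18, 10)), "degenerate")
  expect_error(phantom_spec(kappa = 0), "kappa")
  expect_error(phantom_spec(n_targets = 1,
                            region_alloc = c(PFC = 1, PMC = 0, SMA = 0,
                                             M1 = 0, other = 0)),
               "K = 2")
})

test_that("ellipsoid voxel volume is within 15% of the analytic volume", {
  for (spec in list(spec32, phantom_spec())) {
    anat <- make_anatomy(spec)
    vox_vol <- mask_size(anat$putamen_left) * prod(spec$spacing)
    analytic <- 4 / 3 * pi * prod(spec$putamen_semi_axes)
    expect_lt(abs(vox_vol - analytic) / analytic, 0.15)
  }
})

test_that("PET generation is a pure function of seed, with null and saturating limits", {
  params <- patient_params(spec32, seed = 3)
  a <- make_pet(spec32, anat32, "6M", seed = 10, params = params)
  b <- make_pet(spec32, anat32, "6M", seed = 10, params = params)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$injected_dose, b$injected_dose)
  expect_error(make_pet(spec32, anat32, "6M"), "seed")

  # zero amplitude: post-treatment bitwise identical to baseline at one seed
  spec0 <- small_phantom_spec(hotspot_amplitude = 0)
  p0 <- patient_params(spec0, seed = 3)
  bl <- make_pet(spec0, anat32, "baseline", seed = 5, params = p0)
  po <- make_pet(spec0, anat32, "6M", seed = 5, params = p0)
  expect_identical(bl$volume$data, po$volume$data)

  # very wide hotspot: the whole putamen goes supra-baseline
  specw <- small_phantom_spec(hotspot_sigma_mm = 60, hotspot_amplitude = 3,
                              amplitude_range = c(1, 1))
  pw <- patient_params(specw, seed = 3)
  blw <- make_pet(specw, anat32, "baseline", seed = 5, params = pw)
  pow <- make_pet(specw, anat32, "6M", seed = 6, params = pw)
  occ <- anat32$occipital
  r_bl <- to_occipital_ratio(compute_suv(blw), occ)
  r_po <- to_occipital_ratio(compute_suv(pow), occ)
  tr <- transduction_mask(r_bl, r_po, anat32$putamen)
  expect_equal(tr$fraction_max, 100)
})

test_that("connectivity counts are multinomial around the truth with row sums n_s", {
  truth <- make_truth_parcellation(anat32, seed = 2)
  conn <- make_connectivity(spec32, anat32, truth, seed = 4)
  expect_true(all(rowSums(conn$counts) == spec32$n_streamlines))
  expect_equal(nrow(conn$counts), mask_size(anat32$putamen))

  # kappa = 1: counts concentrate on the true label, recovery is perfect
  spec1 <- small_phantom_spec(kappa = 1)
  conn1 <- make_connectivity(spec1, anat32, truth, seed = 4)
  wta <- winner_take_all(conn1)
  rec <- wta$grid$data[truth$voxels + 1L]
  expect_equal(rec, truth$label_vec)

  # kappa = 1/K: counts carry no information, recovery near chance
  specK <- small_phantom_spec(kappa = 1 / spec32$n_targets)
  acc <- mean(vapply(1:10, function(s) {
    cK <- make_connectivity(specK, anat32, truth, seed = 100 + s)
    mean(winner_take_all(cK)$grid$data[truth$voxels + 1L] == truth$label_vec)
  }, 0))
  expect_lt(acc, 3 / spec32$n_targets)
})

test_that("stored phantom truth is exactly recomputable from its own volumes", {
  spec <- small_phantom_spec()
  co <- simulate_cohort(spec, n_patients = 2, seed = 21, keep_volumes = TRUE)
  p <- co$patients[[1]]
  # recompute the supra-max fraction from the generated volumes
  r_bl <- to_occipital_ratio(compute_suv(p$scans$baseline), co$anatomy$occipital)
  r_6m <- to_occipital_ratio(compute_suv(p$scans$`6M`), co$anatomy$occipital)
  tr <- transduction_mask(r_bl, r_6m, co$anatomy$putamen)
  expect_identical(tr$fraction_max, p$transduction$`6M`$fraction_max)
  expect_identical(tr$mask_max$grid$data, p$transduction$`6M`$mask_max$grid$data)
  # truth fractions re-derive exactly from the stored truth label map
  prof <- transduced_connection_fractions(co$truth$labels, tr$mask_max,
                                          co$anatomy$putamen,
                                          co$anatomy$hierarchy)
  expect_identical(prof$per_region,
                   p$truth$profiles$transduced_6m$per_region)
})

test_that("winner-take-all recovery accuracy is nondecreasing in kappa", {
  truth <- make_truth_parcellation(anat32, seed = 6)
  kappas <- c(0.05, 0.1, 0.3, 1.0)
  acc <- vapply(kappas, function(k) {
    sp <- small_phantom_spec(kappa = k, n_streamlines = 50)
    cn <- make_connectivity(sp, anat32, truth, seed = 77)  # matched seed
    mean(winner_take_all(cn)$grid$data[truth$voxels + 1L] == truth$label_vec)
  }, 0)
  expect_true(all(diff(acc) >= 0))
  expect_equal(acc[length(acc)], 1)
})

test_that("motor-score generator realizes the designed dependence", {
  n <- 60
  tbl <- tibble::tibble(patient = sprintf("p%02d", 1:n),
                        age = runif(n, 4, 19),
                        frac_pfc = runif(n, 4, 12))
  # no effect, no noise, no age slope: identical improvement for everyone
  spec_flat <- small_phantom_spec(beta = 0, score_noise_sd = 0, gamma_age = 0)
  sc <- make_motor_scores(spec_flat, tbl, seed = 1)
  expect_equal(length(unique(sc$delta_aims_6m)), 1L)

  # strong effect, no noise, no age slope: perfect partial rank correlation
  spec_strong <- small_phantom_spec(beta = 40, score_noise_sd = 0,
                                    gamma_age = 0, aims_max = 1e6)
  sc2 <- make_motor_scores(spec_strong, tbl, seed = 1, discretize = FALSE)
  r <- partial_spearman(tbl$frac_pfc, sc2$delta_aims_6m, tbl$age)
  expect_equal(r$statistic, 1)

  # default model: integer AIMS within range, delta consistent
  sc3 <- make_motor_scores(small_phantom_spec(), tbl, seed = 2)
  expect_true(all(sc3$aims_6m == round(sc3$aims_6m)))
  expect_true(all(sc3$aims_6m >= 0 & sc3$aims_6m <= 58))
  expect_equal(sc3$delta_aims_6m, sc3$aims_6m - sc3$aims_baseline)
})

test_that("designed partial correlation matches a large-replicate score oracle", {
  spec <- small_phantom_spec()
  frac_pool <- runif(500, 4, 12)
  oracle <- simulate_score_cohort(spec, frac_pool, n = 100000, seed = 9)
  rho_oracle <- partial_spearman(oracle$frac_pfc, oracle$aims_6m,
                                 oracle$age)$statistic
  est <- simulate_score_cohort(spec, frac_pool, n = 200, seed = 10)
  rho_est <- partial_spearman(est$frac_pfc, est$aims_6m, est$age)$statistic
  # n = 200 estimate within ~3 sd of the oracle value (Fisher z scale)
  expect_lt(abs(atanh(rho_est) - atanh(rho_oracle)), 3 / sqrt(200 - 4))
})
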