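# Winner-take-all classification, volume-fraction bookkeeping and profile
# similarity.

# tiny seed region on a 6^3 lattice shared by most cases
tiny_seed <- function(n_vox = 20, seed = 1) {
  set.seed(seed)
  arr <- array(0, dim = c(6, 6, 6))
  pick <- sample(216, n_vox)
  arr[pick] <- 1
  mask <- make_mask(arr, spacing = c(2, 2, 2))
  list(mask = mask, voxels = which(arr != 0, arr.ind = TRUE) - 1L)
}

flat_hierarchy <- function(K, region = "PFC", network = "frontoparietal control") {
  target_hierarchy(tibble::tibble(
    target_id = seq_len(K),
    network = rep(network, K),
    region = rep(region, K)))
}

test_that("winner-take-all labels by count argmax with smallest-id ties", {
  s <- tiny_seed()
  # all mass on target 1
  cm <- connectivity_map(s$mask, s$voxels,
                         matrix(rep(c(5000, 0), each = 20), 20, 2),
                         target_ids = 1:2)
  wta <- winner_take_all(cm)
  expect_true(all(wta$grid$data[s$voxels + 1L] == 1))

  # exact tie goes to the smallest target id, zero rows stay unlabeled
  counts <- rbind(c(7, 7, 0), c(0, 0, 0), c(1, 2, 2))
  s3 <- tiny_seed(3)
  cm2 <- connectivity_map(s3$mask, s3$voxels, counts, target_ids = c(4, 2, 9))
  lab <- winner_take_all(cm2)$grid$data[s3$voxels + 1L]
  expect_equal(lab, c(2, 0, 2))
})

test_that("winner-take-all equals a brute-force argmax oracle on random maps", {
  set.seed(31)
  arr <- array(0, dim = c(10, 10, 10)); arr[sample(1000, 500)] <- 1
  mask <- make_mask(arr)
  vox <- which(arr != 0, arr.ind = TRUE) - 1L
  for (rep in 1:5) {
    counts <- matrix(rpois(500 * 10, 2), 500, 10)  # small counts force ties
    counts[sample(500, 20), ] <- 0
    cm <- connectivity_map(mask, vox, counts, target_ids = 1:10)
    expect_equal(winner_take_all(cm)$grid$data[vox + 1L],
                 argmax_oracle(counts, 1:10))
  }
})

test_that("winner-take-all is equivariant under consistent target relabeling", {
  set.seed(32)
  s <- tiny_seed(30, seed = 3)
  counts <- matrix(rpois(30 * 6, 3), 30, 6)
  ids <- 1:6
  base <- winner_take_all(connectivity_map(s$mask, s$voxels, counts, ids))
  perm <- sample(6)  # new id of old target k is perm[k]
  relab <- winner_take_all(connectivity_map(s$mask, s$voxels, counts, perm[ids]))
  v_base <- base$grid$data[s$voxels + 1L]
  v_relab <- relab$grid$data[s$voxels + 1L]
  # equivariance holds wherever the argmax is unique (ties re-break by id)
  unique_max <- apply(counts, 1, function(r) sum(r == max(r)) == 1 && max(r) > 0)
  expect_equal(v_relab[unique_max], perm[v_base[unique_max]])
})

test_that("connection fractions follow the printed formula and conserve totals", {
  arr <- array(0, dim = c(6, 6, 6)); arr[1:100] <- 1
  put <- make_mask(arr)
  lab <- array(0L, dim = c(6, 6, 6)); lab[1:25] <- 7L
  lm <- label_map(make_grid(lab))
  h <- flat_hierarchy(8)
  prof <- connection_fractions(lm, put, h)
  expect_equal(unname(prof$per_target[["7"]]), 25)
  expect_equal(sum(prof$per_target), 25)  # 75 voxels unlabeled

  # fully labeled putamen: fractions sum to exactly 100
  lab2 <- array(0L, dim = c(6, 6, 6)); lab2[1:100] <- rep(1:4, 25)
  prof2 <- connection_fractions(label_map(make_grid(lab2)), put, h)
  expect_identical(sum(prof2$per_target), 100)
  expect_error(
    connection_fractions(label_map(make_grid(array(9L, c(6, 6, 6)) * arr)),
                         put, flat_hierarchy(3)),
    "not in hierarchy: 9")
})

test_that("network and region aggregates equal member sums exactly", {
  set.seed(33)
  spec <- small_phantom_spec()
  anat <- make_anatomy(spec)
  truth <- make_truth_parcellation(anat, seed = 4)
  prof <- connection_fractions(truth$labels, anat$putamen, anat$hierarchy)
  tab <- anat$hierarchy$table
  for (nw in unique(tab$network)) {
    members <- as.character(tab$target_id[tab$network == nw])
    expect_identical(unname(prof$per_network[[nw]]),
                     sum(prof$per_target[members]))
  }
  for (rg in unique(tab$region)) {
    members <- as.character(tab$target_id[tab$region == rg])
    expect_identical(unname(prof$per_region[[rg]]),
                     sum(prof$per_target[members]))
  }
  # counting oracle: per-network percentages from a per-voxel scan
  lab_vec <- truth$labels$grid$data[truth$voxels + 1L]
  net_of <- setNames(tab$network, tab$target_id)
  for (nw in unique(tab$network)) {
    cnt <- sum(net_of[as.character(lab_vec)] == nw, na.rm = TRUE)
    expect_equal(unname(prof$per_network[[nw]]),
                 100 * cnt / mask_size(anat$putamen))
  }
})

test_that("transduced fractions use the whole-putamen denominator and are monotone", {
  arr <- array(0, dim = c(6, 6, 6)); arr[1:100] <- 1
  put <- make_mask(arr)
  lab2 <- array(0L, dim = c(6, 6, 6)); lab2[1:100] <- rep(1:4, each = 25)
  lm <- label_map(make_grid(lab2))
  h <- flat_hierarchy(4)

  empty <- make_mask(array(0, dim = c(6, 6, 6)))
  prof0 <- transduced_connection_fractions(lm, empty, put, h)
  expect_true(all(prof0$per_target == 0))

  full <- transduced_connection_fractions(lm, put, put, h)
  whole <- connection_fractions(lm, put, h)
  expect_equal(full$per_target, whole$per_target)

  set.seed(8)
  sub <- array(0, dim = c(6, 6, 6)); sub[sample(1:100, 40)] <- 1
  part <- transduced_connection_fractions(lm, make_mask(sub), put, h)
  expect_true(all(part$per_target <= whole$per_target))
  expect_equal(sum(part$per_target), 40)
})

test_that("PFC-in-control overlap counts doubly-qualified targets only", {
  arr <- array(0, dim = c(6, 6, 6)); arr[1:100] <- 1
  put <- make_mask(arr)
  lab <- array(0L, dim = c(6, 6, 6)); lab[1:100] <- rep(1:4, each = 25)
  lm <- label_map(make_grid(lab))

  h_none <- target_hierarchy(tibble::tibble(
    target_id = 1:4, network = rep("somato/motor", 4),
    region = c("PFC", "PFC", "M1", "M1")))
  expect_equal(pfc_control_overlap_fraction(lm, put, put, h_none), 0)

  h_all <- flat_hierarchy(4)  # every target is PFC x control
  expect_equal(pfc_control_overlap_fraction(lm, put, put, h_all), 100)

  # set-intersection counting oracle on a random configuration
  set.seed(44)
  h_mix <- target_hierarchy(tibble::tibble(
    target_id = 1:4,
    network = sample(c("frontoparietal control", "default"), 4, replace = TRUE),
    region = sample(c("PFC", "PMC"), 4, replace = TRUE)))
  tmask_arr <- array(0, dim = c(6, 6, 6)); tmask_arr[sample(1:100, 30)] <- 1
  tmask <- make_mask(tmask_arr)
  got <- pfc_control_overlap_fraction(lm, tmask, put, h_mix)
  tab <- h_mix$table
  good <- tab$target_id[tab$region == "PFC" &
                          tab$network == "frontoparietal control"]
  cnt <- sum(lab %in% good & tmask_arr != 0 & arr != 0)
  expect_equal(got, 100 * cnt / 100)
})

test_that("profile cosine similarity matches hand values and its invariances", {
  expect_equal(profile_similarity(c(1, 2, 3), 2.5 * c(1, 2, 3)), 1)
  expect_equal(profile_similarity(c(1, 0, 2, 0), c(0, 3, 0, 4)), 0)
  expect_equal(profile_similarity(c(1, 2, 3, 0, 0, 0, 0),
                                  c(3, 2, 1, 0, 0, 0, 0)), 10 / 14,
               tolerance = 1e-12)
  v1 <- c(0.3, 1.2, 0, 4); v2 <- c(1, 0.5, 2, 0.1)
  expect_equal(profile_similarity(v1, v2), profile_similarity(v2, v1))
  expect_equal(profile_similarity(7 * v1, v2), profile_similarity(v1, v2))
  expect_error(profile_similarity(c(0, 0), c(1, 1)), "all-zero")
})
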