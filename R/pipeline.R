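# Orchestration: a single structured config drives simulate -> petquant ->
# parcellate -> analyze, with deterministic seed derivation and a run
# manifest of output digests. Every stage reads only the on-disk outputs of
# the stages before it, so any stage can be re-run in isolation.

pipeline_defaults <- function() {
  list(
    output_dir = NULL,
    master_seed = NULL,
    n_patients = 8,
    stages = list(simulate = TRUE, petquant = TRUE, parcellate = TRUE,
                  analyze = TRUE),
    phantom = list(),      # overrides for phantom_spec()
    small_grid = FALSE,    # use the reduced 32^3 spec
    stats = list(alpha_voxel = 0.001, alpha_cluster = 0.05, n_perm = 1000,
                 holm = TRUE, run_voxelwise = FALSE,
                 outcome = "aims_6m")
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, and either returns
#' the typed config or stops with the full list of violations. Unknown keys
#' are rejected to guard against silent typos.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated config list of class \code{run_config}.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file or a named list")
  defaults <- pipeline_defaults()
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    note(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))

  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])

  if (is.null(cfg$output_dir)) note("`output_dir` is required")
  if (is.null(cfg$master_seed)) {
    if (isTRUE(cfg$stages$simulate))
      note("`master_seed` is mandatory when the simulate stage is enabled")
  } else if (!is.numeric(cfg$master_seed) ||
             cfg$master_seed != round(cfg$master_seed)) {
    note("`master_seed` must be an integer")
  }
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 1)
    note("`n_patients` must be a positive integer")

  known_stats <- names(defaults$stats)
  bad <- setdiff(names(cfg$stats), known_stats)
  if (length(bad))
    note(paste0("unknown stats key(s): ", paste(bad, collapse = ", ")))
  if (!is.null(cfg$stats$alpha_voxel) &&
      (cfg$stats$alpha_voxel <= 0 || cfg$stats$alpha_voxel >= 1))
    note("`stats.alpha_voxel` must be in (0, 1)")
  if (!is.null(cfg$stats$alpha_cluster) &&
      (cfg$stats$alpha_cluster <= 0 || cfg$stats$alpha_cluster >= 1))
    note("`stats.alpha_cluster` must be in (0, 1)")

  # phantom overrides must be valid phantom_spec arguments, and the composed
  # spec must validate (catches e.g. negative hotspot widths by field name)
  base_spec <- if (isTRUE(cfg$small_grid)) "small_phantom_spec" else "phantom_spec"
  bad_ph <- setdiff(names(cfg$phantom), names(formals(phantom_spec)))
  if (length(bad_ph))
    note(paste0("unknown phantom key(s): ", paste(bad_ph, collapse = ", ")))
  else {
    spec_try <- tryCatch(
      do.call(base_spec, cfg$phantom),
      error = function(e) {
        note(conditionMessage(e)); NULL
      })
    if (!is.null(spec_try)) cfg$spec <- spec_try
  }

  if (length(problems))
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "))
  class(cfg) <- "run_config"
  cfg
}

#' Run the phantom pipeline
#'
#' Executes the enabled stages in dependency order under the configured
#' output directory and writes \code{manifest.json} last. The manifest
#' contains the config echo, the seed ledger and an MD5 digest per output
#' file; re-running with the same config and seed reproduces it byte for
#' byte.
#'
#' @param config a \code{run_config} from \code{\link{validate_config}} (or
#'   anything it accepts).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- c("simulate", "petquant", "parcellate", "analyze")
  written <- list()
  for (st in stages) {
    if (!isTRUE(cfg$stages[[st]])) next
    message("stage: ", st)
    files <- tryCatch(
      switch(st,
        simulate = stage_simulate(cfg),
        petquant = stage_petquant(cfg),
        parcellate = stage_parcellate(cfg),
        analyze = stage_analyze(cfg)),
      error = function(e)
        stop("stage '", st, "' failed: ", conditionMessage(e),
             " (partial outputs retained under ", out, ")", call. = FALSE))
    written[[st]] <- sort(files)
  }
  digests <- lapply(written, function(fs)
    as.list(stats::setNames(unname(tools::md5sum(file.path(out, fs))), fs)))
  manifest <- list(
    package = "putaparc",
    version = as.character(utils::packageVersion("putaparc")),
    master_seed = cfg$master_seed,
    n_patients = cfg$n_patients,
    seed_scheme = "seed_stream(master, patient, stage): (master + 7919*i + 104729*j) mod 2147483647",
    config = cfg[setdiff(names(cfg), c("spec"))],
    stage_files = digests
  )
  path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}

patient_ids <- function(cfg) sprintf("pt%02d", seq_len(cfg$n_patients))

# ---- stage: simulate -------------------------------------------------------

stage_simulate <- function(cfg) {
  out <- cfg$output_dir
  spec <- cfg$spec
  seed <- cfg$master_seed
  anatomy <- make_anatomy(spec)
  truth <- make_truth_parcellation(anatomy, seed = seed_stream(seed, 0, 100))
  files <- character(0)
  wv <- function(grid, f) { write_volume(grid, file.path(out, f)); files <<- c(files, f) }

  wv(anatomy$putamen$grid, "mask_putamen.nii")
  wv(anatomy$putamen_left$grid, "mask_putamen_left.nii")
  wv(anatomy$putamen_right$grid, "mask_putamen_right.nii")
  wv(anatomy$occipital$grid, "mask_occipital.nii")
  wv(truth$labels$grid, "truth_labels.nii")

  utils::write.csv(anatomy$hierarchy$table,
                   file.path(out, "hierarchy.csv"), row.names = FALSE)
  inj <- data.frame(side = anatomy$injections$side,
                    x_mm = anatomy$injections$points[, 1],
                    y_mm = anatomy$injections$points[, 2],
                    z_mm = anatomy$injections$points[, 3])
  utils::write.csv(inj, file.path(out, "injections.csv"), row.names = FALSE)
  files <- c(files, "hierarchy.csv", "injections.csv")

  pts <- patient_ids(cfg)
  meta <- list()
  truth_fracs <- list()
  for (i in seq_along(pts)) {
    pseed <- seed_stream(seed, i, 0)
    params <- patient_params(spec, seed_stream(pseed, 0, 1))
    tps <- c(baseline = 2L, `6M` = 3L, `2Y` = 4L)
    for (tp in names(tps)) {
      scan <- make_pet(spec, anatomy, tp, seed = seed_stream(pseed, 0, tps[[tp]]),
                       params = params, patient = pts[i])
      f <- sprintf("pet_%s_%s.nii", pts[i], tolower(tp))
      wv(scan$volume, f)
      meta[[length(meta) + 1L]] <- data.frame(
        patient = pts[i], timepoint = tp, injected_dose_mbq = scan$injected_dose,
        body_weight_g = scan$body_weight, age = params$age)
    }
    conn_streams <- c(baseline = 5L, `2Y` = 6L)
    for (nm in names(conn_streams)) {
      conn <- make_connectivity(spec, anatomy, truth,
                                seed = seed_stream(pseed, 0, conn_streams[[nm]]))
      cdf <- data.frame(i = conn$voxels[, 1], j = conn$voxels[, 2],
                        k = conn$voxels[, 3])
      cdf <- cbind(cdf, as.data.frame(conn$counts))
      names(cdf)[-(1:3)] <- paste0("t", conn$target_ids)
      f <- sprintf("counts_%s_%s.csv", pts[i], tolower(nm))
      utils::write.csv(cdf, file.path(out, f), row.names = FALSE)
      files <- c(files, f)
    }
    # ground-truth prefrontal fraction for the score generator: the truth
    # parcellation masked by this patient's supra-max area at 6M
    sc_bl <- make_pet(spec, anatomy, "baseline",
                      seed = seed_stream(pseed, 0, 2), params = params)
    sc_6m <- make_pet(spec, anatomy, "6M", seed = seed_stream(pseed, 0, 3),
                      params = params)
    r_bl <- to_occipital_ratio(compute_suv(sc_bl), anatomy$occipital)
    r_6m <- to_occipital_ratio(compute_suv(sc_6m), anatomy$occipital)
    tr <- transduction_mask(r_bl, r_6m, anatomy$putamen)
    tp_prof <- transduced_connection_fractions(truth$labels, tr$mask_max,
                                               anatomy$putamen,
                                               anatomy$hierarchy)
    truth_fracs[[i]] <- tp_prof$per_region[["PFC"]]
  }
  meta <- do.call(rbind, meta)
  utils::write.csv(meta, file.path(out, "patients.csv"), row.names = FALSE)
  files <- c(files, "patients.csv")

  truth_tbl <- tibble::tibble(patient = pts,
                              age = meta$age[match(pts, meta$patient)],
                              frac_pfc = unlist(truth_fracs))
  scores <- make_motor_scores(spec, truth_tbl, seed = seed_stream(seed, 0, 200))
  utils::write.csv(scores, file.path(out, "cohort_scores.csv"),
                   row.names = FALSE)
  files <- c(files, "cohort_scores.csv")

  truth_json <- list(
    note = paste("synthetic phantom ground truth; Gaussian hotspot spread is",
                 "a modeling assumption, not an empirical transduction model"),
    master_seed = cfg$master_seed,
    truth_frac_pfc = stats::setNames(as.list(truth_tbl$frac_pfc), pts),
    spec = cfg$spec[!vapply(cfg$spec, is.list, TRUE)]
  )
  jsonlite::write_json(truth_json, file.path(out, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "truth.json")
  files
}

# ---- stage: petquant -------------------------------------------------------

read_stage_masks <- function(out) {
  list(
    putamen = read_mask(file.path(out, "mask_putamen.nii"), "putamen"),
    occipital = read_mask(file.path(out, "mask_occipital.nii"), "occipital")
  )
}

read_injections <- function(out) {
  inj <- utils::read.csv(file.path(out, "injections.csv"))
  injection_set(as.matrix(inj[, c("x_mm", "y_mm", "z_mm")]), inj$side)
}

stage_petquant <- function(cfg) {
  out <- cfg$output_dir
  masks <- read_stage_masks(out)
  inj <- read_injections(out)
  meta <- utils::read.csv(file.path(out, "patients.csv"))
  files <- character(0)
  uptake <- list()
  ratios_bl <- list(); ratios_6m <- list(); ages <- numeric(0)

  for (pt in unique(meta$patient)) {
    ratio <- list()
    for (tp in c("baseline", "6M", "2Y")) {
      row <- meta[meta$patient == pt & meta$timepoint == tp, ]
      vol <- read_volume(file.path(out, sprintf("pet_%s_%s.nii", pt, tolower(tp))))
      scan <- pet_scan(vol, row$injected_dose_mbq, row$body_weight_g,
                       timepoint = tp, patient = pt)
      ratio[[tp]] <- to_occipital_ratio(compute_suv(scan), masks$occipital)
      f <- sprintf("ratio_%s_%s.nii", pt, tolower(tp))
      write_volume(ratio[[tp]], file.path(out, f))
      files <- c(files, f)
    }
    uptake[[pt]] <- roi_uptake_table(ratio, list(masks$putamen), patient = pt)
    for (tp in c("6M", "2Y")) {
      tr <- transduction_mask(ratio$baseline, ratio[[tp]], masks$putamen, inj)
      f <- sprintf("transduction_mask_%s_%s.nii", pt, tolower(tp))
      write_volume(tr$mask_max$grid, file.path(out, f))
      files <- c(files, f)
      j <- sprintf("transduction_%s_%s.json", pt, tolower(tp))
      jsonlite::write_json(
        list(patient = pt, timepoint = tp,
             threshold_max = tr$threshold_max, threshold_p95 = tr$threshold_p95,
             fraction_max = tr$fraction_max, fraction_p95 = tr$fraction_p95,
             max_distance_mm = tr$max_distance_mm,
             max_distance_per_side = as.list(tr$max_distance_per_side)),
        file.path(out, j), auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files <- c(files, j)
    }
    ratios_bl[[pt]] <- ratio$baseline
    ratios_6m[[pt]] <- ratio$`6M`
    ages <- c(ages, meta$age[meta$patient == pt][1])
  }
  utils::write.csv(do.call(rbind, uptake), file.path(out, "roi_uptake.csv"),
                   row.names = FALSE)
  files <- c(files, "roi_uptake.csv")

  if (isTRUE(cfg$stats$run_voxelwise) && length(ratios_bl) >= 3) {
    vw <- voxelwise_paired_contrast(
      ratios_bl, ratios_6m, ages,
      voxel_p = cfg$stats$alpha_voxel, cluster_p = cfg$stats$alpha_cluster,
      n_perm = cfg$stats$n_perm)
    write_volume(vw$t_map, file.path(out, "contrast_tmap.nii"))
    write_volume(vw$significant_map$grid,
                 file.path(out, "contrast_significant.nii"))
    utils::write.csv(vw$clusters, file.path(out, "contrast_clusters.csv"),
                     row.names = FALSE)
    files <- c(files, "contrast_tmap.nii", "contrast_significant.nii",
               "contrast_clusters.csv")
  }
  files
}

# ---- stage: parcellate -----------------------------------------------------

read_connectivity_csv <- function(path, putamen) {
  cdf <- utils::read.csv(path)
  vox <- as.matrix(cdf[, c("i", "j", "k")])
  counts <- as.matrix(cdf[, grep("^t", names(cdf)), drop = FALSE])
  ids <- as.integer(sub("^t", "", colnames(counts)))
  connectivity_map(putamen, vox, counts, ids)
}

stage_parcellate <- function(cfg) {
  out <- cfg$output_dir
  masks <- read_stage_masks(out)
  hier <- target_hierarchy(utils::read.csv(file.path(out, "hierarchy.csv")))
  meta <- utils::read.csv(file.path(out, "patients.csv"))
  files <- character(0)
  profs <- list()

  add_prof <- function(pt, tp, flag, prof) {
    for (lev in c("target", "network", "region")) {
      v <- switch(lev, target = prof$per_target, network = prof$per_network,
                  region = prof$per_region)
      profs[[length(profs) + 1L]] <<- tibble::tibble(
        patient = pt, timepoint = tp, flag = flag, level = lev,
        unit = names(v), percent = unname(v))
    }
  }

  for (pt in unique(meta$patient)) {
    labels <- list()
    for (tp in c("baseline", "2Y")) {
      conn <- read_connectivity_csv(
        file.path(out, sprintf("counts_%s_%s.csv", pt, tolower(tp))),
        masks$putamen)
      labels[[tp]] <- winner_take_all(conn)
      f <- sprintf("labels_%s_%s.nii", pt, tolower(tp))
      write_volume(labels[[tp]]$grid, file.path(out, f))
      files <- c(files, f)
      add_prof(pt, tp, "whole",
               connection_fractions(labels[[tp]], masks$putamen, hier))
    }
    # pairing: baseline parcellation x 6M mask; 2Y parcellation x 2Y mask
    pairing <- list(`6M` = list(lab = "baseline", mask = "6m"),
                    `2Y` = list(lab = "2Y", mask = "2y"))
    for (tp in names(pairing)) {
      tmask <- read_mask(file.path(out, sprintf("transduction_mask_%s_%s.nii",
                                                pt, pairing[[tp]]$mask)))
      prof <- transduced_connection_fractions(labels[[pairing[[tp]]$lab]],
                                              tmask, masks$putamen, hier)
      add_prof(pt, tp, "transduced", prof)
      pc <- pfc_control_overlap_fraction(labels[[pairing[[tp]]$lab]], tmask,
                                         masks$putamen, hier)
      profs[[length(profs) + 1L]] <- tibble::tibble(
        patient = pt, timepoint = tp, flag = "transduced",
        level = "region_network", unit = "PFC x frontoparietal control",
        percent = pc)
    }
  }
  utils::write.csv(do.call(rbind, profs), file.path(out, "profiles.csv"),
                   row.names = FALSE)
  c(files, "profiles.csv")
}

# ---- stage: analyze --------------------------------------------------------

stage_analyze <- function(cfg) {
  out <- cfg$output_dir
  prof <- utils::read.csv(file.path(out, "profiles.csv"))
  scores <- utils::read.csv(file.path(out, "cohort_scores.csv"))

  tr6 <- prof[prof$flag == "transduced" & prof$timepoint == "6M", ]
  wide <- function(level, unit_map) {
    sub <- tr6[tr6$level == level, ]
    sapply(unit_map, function(u)
      sapply(scores$patient, function(pt)
        sum(sub$percent[sub$patient == pt & sub$unit == u])))
  }
  regions <- wide("region", stats::setNames(REGIONS, paste0("frac_", tolower(REGIONS))))
  nets <- unique(tr6$unit[tr6$level == "network"])
  networks <- wide("network", stats::setNames(nets, paste0("net_", gsub("[ /]", "_", nets))))
  pc <- sapply(scores$patient, function(pt)
    sum(tr6$percent[tr6$level == "region_network" & tr6$patient == pt]))

  cohort <- cohort_table(cbind(tibble::as_tibble(scores),
                               tibble::as_tibble(regions),
                               tibble::as_tibble(networks),
                               tibble::tibble(frac_pfc_control = unname(pc))))
  res <- run_headline_analyses(cohort, outcome = cfg$stats$outcome)
  utils::write.csv(res, file.path(out, "results.csv"), row.names = FALSE)
  jsonlite::write_json(res, file.path(out, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(cohort, file.path(out, "cohort_table.csv"),
                   row.names = FALSE)
  c("results.csv", "results.json", "cohort_table.csv")
}
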