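# Winner-take-all connectivity-based parcellation of the putamen and the
# volume-fraction bookkeeping built on it.

#' Streamline-count map over a seed region
#'
#' One row of counts per seed voxel, one column per cortical target ROI;
#' the emulated equivalent of probabilistic-tractography output.
#'
#' @param seed_mask \code{roi_mask} of the seed region (bilateral putamen).
#' @param voxels 0-based n x 3 integer matrix of seed voxel indices.
#' @param counts n x K matrix of nonnegative integer streamline counts.
#' @param target_ids integer vector of K target labels.
#' @return An object of class \code{connectivity_map}.
#' @export
connectivity_map <- function(seed_mask, voxels, counts, target_ids) {
  voxels <- as.matrix(voxels)
  counts <- as.matrix(counts)
  if (nrow(voxels) != nrow(counts))
    stop("one count vector per seed voxel required")
  if (ncol(counts) != length(target_ids))
    stop("counts must have one column per target id")
  if (length(target_ids) < 2L) stop("need at least K = 2 targets")
  if (any(counts < 0)) stop("streamline counts must be nonnegative")
  structure(
    list(seed_mask = seed_mask, voxels = voxels, counts = counts,
         target_ids = as.integer(target_ids)),
    class = "connectivity_map"
  )
}

#' Target hierarchy table
#'
#' Total mapping from cortical target ROI to one of the seven cortical
#' networks and one structural region (PFC/PMC/SMA/M1/other). Boundary
#' assignments (e.g. PMC-SMA-PFC border ROIs counted as PFC) are encoded in
#' the table itself, not at runtime.
#'
#' @param table data frame with columns \code{target_id}, \code{network},
#'   \code{region}.
#' @return An object of class \code{target_hierarchy}.
#' @export
target_hierarchy <- function(table) {
  req <- c("target_id", "network", "region")
  if (!all(req %in% names(table)))
    stop("hierarchy needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(table$target_id))
    stop("each target id must appear exactly once in the hierarchy")
  bad_net <- setdiff(unique(table$network), NETWORKS)
  if (length(bad_net))
    stop("unknown network(s): ", paste(bad_net, collapse = ", "))
  bad_reg <- setdiff(unique(table$region), REGIONS)
  if (length(bad_reg))
    stop("unknown region(s): ", paste(bad_reg, collapse = ", "))
  structure(list(table = tibble::as_tibble(table)),
            class = "target_hierarchy")
}

#' Winner-take-all classification of seed voxels
#'
#' Each seed voxel is labeled with the target receiving its largest
#' streamline count. Voxels whose counts are all zero stay unlabeled
#' (label 0); ties go to the smallest target id (deterministic convention).
#'
#' @param conn a \code{connectivity_map}.
#' @return a \code{label_map} on the seed lattice.
#' @export
winner_take_all <- function(conn) {
  ord <- order(conn$target_ids)  # so column-order ties resolve to smallest id
  counts <- conn$counts[, ord, drop = FALSE]
  win <- conn$target_ids[ord][max.col(counts, ties.method = "first")]
  win[rowSums(counts) == 0] <- 0L
  g <- conn$seed_mask$grid
  arr <- array(0L, dim = dim(g$data))
  arr[conn$voxels + 1L] <- win
  label_map(volume_grid(arr, g$spacing, g$origin))
}

profile_levels <- function(per_target, hierarchy) {
  tab <- hierarchy$table
  per_network <- vapply(NETWORKS, function(nw)
    sum(per_target[as.character(tab$target_id[tab$network == nw])]), 0)
  per_region <- vapply(REGIONS, function(r)
    sum(per_target[as.character(tab$target_id[tab$region == r])]), 0)
  list(network = per_network, region = per_region)
}

#' Cortico-putaminal connection-area volume fractions
#'
#' Per-target fraction = 100 * (putaminal voxels labeled with that target) /
#' (total voxels of the whole bilateral putamen). Network and region values
#' are exact sums of their member targets. Unlabeled voxels are excluded
#' from every numerator but never from the denominator.
#'
#' @param labels a \code{label_map} (winner-take-all output).
#' @param putamen bilateral putamen \code{roi_mask} (the denominator).
#' @param hierarchy a \code{target_hierarchy}.
#' @param flag "whole" or "transduced", carried along for bookkeeping.
#' @return An object of class \code{connection_profile} with fields
#'   \code{per_target}, \code{per_network}, \code{per_region} (percent),
#'   \code{flag}, \code{n_putamen}.
#' @export
connection_fractions <- function(labels, putamen, hierarchy, flag = "whole") {
  stopifnot_same_lattice(labels$grid, putamen$grid, "labels and putamen")
  lab <- labels$grid$data[putamen$grid$data != 0]
  outside <- setdiff(unique(as.vector(labels$grid$data[putamen$grid$data == 0])), 0)
  if (length(outside))
    stop("labels outside the putamen support: ",
         paste(outside, collapse = ", "))
  n_put <- sum(putamen$grid$data != 0)
  if (n_put == 0L) stop("empty putamen mask")
  ids <- hierarchy$table$target_id
  present <- setdiff(unique(lab), 0)
  unknown <- setdiff(present, ids)
  if (length(unknown))
    stop("label(s) not in hierarchy: ", paste(unknown, collapse = ", "))
  cnt <- vapply(ids, function(t) sum(lab == t), 0L)
  per_target <- stats::setNames(100 * cnt / n_put, as.character(ids))
  lev <- profile_levels(per_target, hierarchy)
  structure(
    list(per_target = per_target, per_network = lev$network,
         per_region = lev$region, flag = flag, n_putamen = n_put),
    class = "connection_profile"
  )
}

#' @export
print.connection_profile <- function(x, ...) {
  cat("<connection_profile> (", x$flag, "), total ",
      round(sum(x$per_target), 2), "% of ", x$n_putamen,
      " putamen voxels\n", sep = "")
  print(round(x$per_region, 2))
  invisible(x)
}

#' Transduced connection-area volume fractions
#'
#' Same formula as \code{\link{connection_fractions}} with the numerator
#' intersected with the highly transduced mask; the denominator stays the
#' whole bilateral putamen.
#'
#' @param labels a \code{label_map}.
#' @param transduction \code{roi_mask} of supra-baseline voxels (intersected
#'   with the putamen).
#' @param putamen bilateral putamen \code{roi_mask}.
#' @param hierarchy a \code{target_hierarchy}.
#' @return a \code{connection_profile} with flag "transduced".
#' @export
transduced_connection_fractions <- function(labels, transduction, putamen,
                                            hierarchy) {
  stopifnot_same_lattice(labels$grid, transduction$grid,
                         "labels and transduction mask")
  masked <- labels$grid
  keep <- transduction$grid$data != 0 & putamen$grid$data != 0
  arr <- array(0L, dim = dim(masked$data))
  arr[keep] <- masked$data[keep]
  lm <- label_map(volume_grid(arr, masked$spacing, masked$origin))
  out <- connection_fractions(lm, putamen, hierarchy, flag = "transduced")
  out
}

#' Transduced fraction connected to both the PFC and the frontoparietal
#' control network
#'
#' Percent of the whole putamen whose voxels are transduced and labeled with
#' a target classified as PFC (structural region) and frontoparietal control
#' (network) simultaneously.
#'
#' @inheritParams transduced_connection_fractions
#' @return scalar percent.
#' @export
pfc_control_overlap_fraction <- function(labels, transduction, putamen,
                                         hierarchy) {
  tab <- hierarchy$table
  both <- tab$target_id[tab$region == "PFC" &
                          tab$network == "frontoparietal control"]
  prof <- transduced_connection_fractions(labels, transduction, putamen,
                                          hierarchy)
  sum(prof$per_target[as.character(both)])
}

#' Cosine similarity of two connection-area profiles
#'
#' @param p1,p2 \code{connection_profile}s (or bare nonnegative numeric
#'   vectors on the same level and ordering).
#' @param level "network", "region" or "target".
#' @return cosine similarity in [0, 1] (0: no match, 1: the same pattern).
#' @export
profile_similarity <- function(p1, p2, level = c("network", "region", "target")) {
  level <- match.arg(level)
  pick <- function(p) {
    if (inherits(p, "connection_profile"))
      switch(level, network = p$per_network, region = p$per_region,
             target = p$per_target)
    else as.numeric(p)
  }
  v1 <- pick(p1); v2 <- pick(p2)
  if (length(v1) != length(v2)) stop("profiles have different lengths")
  if (any(v1 < 0) || any(v2 < 0)) stop("profiles must be nonnegative")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop("cosine similarity undefined for an all-zero profile")
  sum(v1 * v2) / (n1 * n2)
}
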