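#' @useDynLib putaparc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- volumetric data model -------------------------------------------------

#' Volumetric scalar lattice
#'
#' Container for a 3D scalar image on an axis-aligned grid. World coordinates
#' follow the convention \code{world = origin + index * spacing} with 0-based
#' voxel indices, i.e. \code{origin} is the world position of voxel (0,0,0).
#' Rotated affines are out of scope: all stages operate in a single native
#' space per patient.
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, voxel edge lengths in mm, all > 0.
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @return An object of class \code{volume_grid}.
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimension(s)")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || anyNA(spacing))
    stop("`spacing` must be three finite numbers")
  for (ax in 1:3)
    if (spacing[ax] <= 0)
      stop("non-positive spacing on axis ", c("x", "y", "z")[ax])
  if (length(origin) != 3L || anyNA(origin))
    stop("`origin` must be three finite numbers")
  structure(
    list(data = data, spacing = spacing, origin = origin),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = " x "),
      " mm, origin (", paste(x$origin, collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' World coordinates of voxel centers
#'
#' @param grid a \code{volume_grid}.
#' @param index integer matrix (n x 3) of 0-based voxel indices, or a
#'   length-3 vector for a single voxel.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(grid, index) {
  if (is.null(dim(index))) index <- matrix(index, nrow = 1L)
  sweep(index %*% diag(grid$spacing), 2L, grid$origin, "+")
}

#' Voxel-center world coordinates of all TRUE voxels of a mask
#' @param mask a \code{roi_mask}.
#' @return n x 3 matrix of world mm coordinates.
#' @export
mask_coordinates <- function(mask) {
  idx <- which(mask$grid$data != 0, arr.ind = TRUE) - 1L
  voxel_to_world(mask$grid, idx)
}

same_lattice <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stopifnot_same_lattice <- function(a, b, what = "volumes") {
  if (!same_lattice(a, b))
    stop(what, " are not on the same lattice (shape/spacing/origin mismatch)")
  invisible(TRUE)
}

# ---- ROI masks -------------------------------------------------------------

#' Binary region-of-interest mask
#'
#' @param grid a \code{volume_grid} whose data contains only 0 and 1.
#' @param name text label for the region.
#' @return An object of class \code{roi_mask}.
#' @export
roi_mask <- function(grid, name = "roi") {
  vals <- unique(as.vector(grid$data))
  if (!all(vals %in% c(0, 1)))
    stop("mask `", name, "` contains values other than 0/1")
  structure(list(grid = grid, name = name), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> '", x$name, "': ", sum(x$grid$data), " voxels\n", sep = "")
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask a \code{roi_mask}.
#' @return integer voxel count.
#' @export
mask_size <- function(mask) sum(mask$grid$data != 0)

#' Label map over a seed region
#'
#' Nonnegative integer labels; 0 is reserved for "unlabeled".
#'
#' @param grid \code{volume_grid} with nonnegative integer data.
#' @param label_names named character vector mapping label id (names) to
#'   target ROI name, or NULL.
#' @return An object of class \code{label_map}.
#' @export
label_map <- function(grid, label_names = NULL) {
  vals <- as.vector(grid$data)
  if (any(vals < 0) || any(vals != round(vals)))
    stop("label map data must be nonnegative integers")
  present <- setdiff(unique(vals), 0)
  if (!is.null(label_names)) {
    missing <- setdiff(present, as.integer(names(label_names)))
    if (length(missing))
      stop("labels without names: ", paste(missing, collapse = ", "))
  }
  structure(list(grid = grid, label_names = label_names), class = "label_map")
}

#' Injection point set
#'
#' Stereotactic delivery uses two target points per putamen side; distances
#' are always taken to the nearest point on the same side.
#'
#' @param points numeric matrix (n x 3) of world coordinates in mm.
#' @param side character vector, "left"/"right" per point.
#' @return An object of class \code{injection_set}.
#' @export
injection_set <- function(points, side) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("`points` must be an n x 3 matrix of mm coordinates")
  side <- as.character(side)
  if (length(side) != nrow(points)) stop("`side` must have one entry per point")
  if (!all(side %in% c("left", "right")))
    stop("`side` entries must be 'left' or 'right'")
  structure(list(points = points, side = side), class = "injection_set")
}

# ---- NIfTI I/O -------------------------------------------------------------

#' Read a 3D NIfTI volume
#'
#' Spacing and origin are taken from the stored affine (diagonal part and
#' translation); intensities are returned unmodified.
#'
#' @param path path to a .nii or .nii.gz file.
#' @return a \code{volume_grid}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D single-frame NIfTI, got ", length(d), " dimensions: ", path)
  aff <- RNifti::xform(img)
  spacing <- abs(diag(aff[1:3, 1:3]))
  for (ax in 1:3)
    if (spacing[ax] <= 0)
      stop("non-positive spacing on axis ", c("x", "y", "z")[ax], " in ", path)
  origin <- aff[1:3, 4]
  volume_grid(array(as.vector(img), dim = d), spacing = spacing, origin = origin)
}

#' Write a volume as uncompressed NIfTI
#'
#' Uncompressed output keeps byte-identical reruns trivially comparable.
#'
#' @param grid a \code{volume_grid}.
#' @param path output path ending in .nii.
#' @return the path, invisibly.
#' @export
write_volume <- function(grid, path) {
  arr <- grid$data
  attr(arr, "pixdim") <- grid$spacing
  img <- RNifti::asNifti(arr, datatype = "double")
  aff <- rbind(cbind(diag(grid$spacing), grid$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a binary mask
#' @param path file path.
#' @param name mask name.
#' @return a \code{roi_mask}.
#' @export
read_mask <- function(path, name = basename(path)) {
  g <- read_volume(path)
  g$data <- array(as.numeric(g$data != 0), dim = dim(g$data))
  roi_mask(g, name = name)
}

# ---- mask statistics -------------------------------------------------------

#' Summary statistic of a volume inside a mask
#'
#' Percentiles use linear interpolation between order statistics
#' (\code{stats::quantile} type 7), fixed so percentile-derived thresholds
#' are reproducible.
#'
#' @param volume a \code{volume_grid}.
#' @param mask a \code{roi_mask} on the same lattice.
#' @param statistic one of "mean", "median", "max", "percentile".
#' @param q percentile in [0, 100] when \code{statistic = "percentile"}.
#' @return scalar statistic over voxels where the mask is 1.
#' @export
mask_stats <- function(volume, mask,
                       statistic = c("mean", "median", "max", "percentile"),
                       q = NULL) {
  statistic <- match.arg(statistic)
  stopifnot_same_lattice(volume, mask$grid, "volume and mask")
  v <- volume$data[mask$grid$data != 0]
  if (length(v) == 0L) stop("empty mask: ", mask$name)
  switch(statistic,
    mean = mean(v),
    median = stats::median(v),
    max = max(v),
    percentile = {
      if (is.null(q) || q < 0 || q > 100)
        stop("`q` must be a percentile in [0, 100]")
      unname(stats::quantile(v, q / 100, type = 7))
    }
  )
}

# ---- connected components --------------------------------------------------

#' Connected components of a binary mask
#'
#' @param mask a \code{roi_mask}.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
#' @return list with \code{labels} (a \code{label_map}), \code{sizes}
#'   (voxel count per component, decreasing) and \code{sizes_mm3}.
#' @export
connected_components <- function(mask, connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  d <- dim(mask$grid$data)
  lab <- label_components_cpp(as.logical(mask$grid$data != 0),
                              as.integer(d), as.integer(connectivity))
  lab <- array(lab, dim = d)
  sizes <- if (max(lab) > 0) tabulate(lab[lab > 0]) else integer(0)
  ord <- order(sizes, decreasing = TRUE)
  # relabel so component 1 is the largest
  relab <- integer(length(sizes)); relab[ord] <- seq_along(ord)
  lab[lab > 0] <- relab[lab[lab > 0]]
  g <- volume_grid(lab, spacing = mask$grid$spacing, origin = mask$grid$origin)
  list(
    labels = label_map(g),
    sizes = sizes[ord],
    sizes_mm3 = sizes[ord] * prod(mask$grid$spacing)
  )
}

# ---- geometry --------------------------------------------------------------

#' Maximum distance from mask voxels to their nearest same-side injection point
#'
#' For each voxel of the mask (voxel centers, world mm) the Euclidean distance
#' to the nearest injection point on the matching side is computed; the
#' maximum is returned, per side and overall. Used for the spatial-spread
#' profile of the supra-baseline uptake region around the delivery tracks.
#'
#' Each mask voxel is assigned to the side whose injection-point centroid is
#' nearest (a translation-invariant stand-in for anatomical laterality), so
#' a bilateral mask is profiled against each putamen's own tracks.
#'
#' @param mask a \code{roi_mask} (e.g. a supra-threshold uptake mask).
#' @param points an \code{injection_set}.
#' @return list with \code{max_mm} (overall) and \code{per_side} (named
#'   numeric, NA for a side with no mask voxels).
#' @export
max_distance_from_points <- function(mask, points) {
  if (mask_size(mask) == 0L)
    stop("no supra-threshold voxels: mask '", mask$name, "' is empty")
  if (nrow(points$points) == 0L) stop("no injection points")
  xyz <- mask_coordinates(mask)
  sides <- intersect(c("left", "right"), unique(points$side))
  cent <- t(vapply(sides, function(s)
    colMeans(points$points[points$side == s, , drop = FALSE]), numeric(3)))
  # voxel laterality: nearest side centroid
  cd2 <- vapply(seq_along(sides), function(k)
    (xyz[, 1] - cent[k, 1])^2 + (xyz[, 2] - cent[k, 2])^2 +
      (xyz[, 3] - cent[k, 3])^2, numeric(nrow(xyz)))
  cd2 <- matrix(cd2, nrow = nrow(xyz))
  vox_side <- sides[max.col(-cd2, ties.method = "first")]
  per_side <- c(left = NA_real_, right = NA_real_)
  for (s in sides) {
    vox <- xyz[vox_side == s, , drop = FALSE]
    pts <- points$points[points$side == s, , drop = FALSE]
    if (nrow(vox) == 0L) next
    d2 <- matrix(0, nrow(vox), nrow(pts))
    for (p in seq_len(nrow(pts)))
      d2[, p] <- (vox[, 1] - pts[p, 1])^2 + (vox[, 2] - pts[p, 2])^2 +
                 (vox[, 3] - pts[p, 3])^2
    per_side[s] <- sqrt(max(apply(d2, 1L, min)))
  }
  list(max_mm = max(per_side, na.rm = TRUE), per_side = per_side)
}

# ---- smoothing -------------------------------------------------------------

#' Separable Gaussian smoothing of a volume
#'
#' Truncated (3 sigma) kernel, renormalized at the boundary so a constant
#' field stays constant. FWHM is specified in mm and converted per axis.
#'
#' @param grid a \code{volume_grid}.
#' @param fwhm_mm full width at half maximum of the Gaussian kernel, mm.
#' @return smoothed \code{volume_grid}.
#' @export
gaussian_smooth <- function(grid, fwhm_mm) {
  if (fwhm_mm <= 0) return(grid)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  arr <- grid$data
  d <- dim(arr)
  for (ax in 1:3) {
    sig_vox <- sigma_mm / grid$spacing[ax]
    r <- max(1L, ceiling(3 * sig_vox))
    k <- exp(-(seq(-r, r))^2 / (2 * sig_vox^2))
    n <- d[ax]
    # banded convolution matrix with boundary renormalization
    K <- matrix(0, n, n)
    for (off in -r:r) {
      idx <- seq_len(n)
      j <- idx + off
      ok <- j >= 1 & j <= n
      K[cbind(idx[ok], j[ok])] <- K[cbind(idx[ok], j[ok])] + k[off + r + 1]
    }
    K <- K / rowSums(K)
    arr <- apply_along_axis(arr, ax, K)
  }
  volume_grid(arr, spacing = grid$spacing, origin = grid$origin)
}

# multiply an n_ax x n_ax matrix along one axis of a 3D array
apply_along_axis <- function(arr, ax, K) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[ax])
  m <- K %*% m
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}
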