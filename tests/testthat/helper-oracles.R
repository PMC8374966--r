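# Independent oracles, deliberately naive and separate from the package's
# implementation paths.

# percentile by explicit sorting and linear interpolation between order
# statistics
sort_percentile_oracle <- function(v, q) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * q / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# recursive-free flood fill over an explicit voxel list
flood_fill_oracle <- function(arr, connectivity) {
  d <- dim(arr)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  manh <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- manh > 0 & manh <= switch(as.character(connectivity),
                                    "6" = 1, "18" = 2, "26" = 3)
  offs <- as.matrix(offs[keep, ])
  lab <- array(0L, dim = d)
  nxt <- 0L
  vox <- which(arr != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(vox))) {
    v <- vox[r, ]
    if (lab[v[1], v[2], v[3]] != 0) next
    nxt <- nxt + 1L
    stack <- list(v)
    lab[v[1], v[2], v[3]] <- nxt
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(offs))) {
        nb <- cur + offs[o, ]
        if (any(nb < 1) || any(nb > d)) next
        if (arr[nb[1], nb[2], nb[3]] != 0 && lab[nb[1], nb[2], nb[3]] == 0) {
          lab[nb[1], nb[2], nb[3]] <- nxt
          stack[[length(stack) + 1L]] <- nb
        }
      }
    }
  }
  lab
}

# brute-force per-voxel argmax with smallest-id tie rule
argmax_oracle <- function(counts, target_ids) {
  out <- integer(nrow(counts))
  for (r in seq_len(nrow(counts))) {
    row <- counts[r, ]
    if (all(row == 0)) { out[r] <- 0L; next }
    best <- -Inf; best_id <- NA_integer_
    for (k in seq_along(row)) {
      if (row[k] > best || (row[k] == best && target_ids[k] < best_id)) {
        best <- row[k]; best_id <- target_ids[k]
      }
    }
    out[r] <- best_id
  }
  out
}

# exhaustive nearest-point maximum distance
max_distance_oracle <- function(xyz, pts_by_voxel) {
  best <- -Inf
  for (r in seq_len(nrow(xyz))) {
    pts <- pts_by_voxel[[r]]
    dmin <- Inf
    for (p in seq_len(nrow(pts)))
      dmin <- min(dmin, sqrt(sum((xyz[r, ] - pts[p, ])^2)))
    best <- max(best, dmin)
  }
  best
}

make_grid <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  volume_grid(arr, spacing = spacing, origin = origin)
}

make_mask <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      name = "m") {
  roi_mask(make_grid(array(as.numeric(arr != 0), dim = dim(arr)),
                     spacing, origin), name)
}
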