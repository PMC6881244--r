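#' Discretize ROI intensities to integer gray levels
#'
#' Linear min-max binning of in-mask intensities into `G` equal-width bins,
#' mapped to levels 1..G. Out-of-mask voxels carry `NA` and are excluded
#' from every downstream count. A constant ROI maps entirely to level 1.
#'
#' @param volume an [hr_volume].
#' @param mask an [hr_mask] on the same grid.
#' @param G number of gray levels (>= 2, default 64).
#' @return A list of class `hr_qroi`: `levels` (3D integer array, NA outside
#'   the mask), `G`, `n_voxels`, `spacing`.
#' @export
quantize <- function(volume, mask, G = 64L) {
  stopifnot(inherits(volume, "hr_volume"), inherits(mask, "hr_mask"))
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("volume and mask grids differ")
  G <- as.integer(G)
  if (G < 2L) stop("G must be >= 2")
  inmask <- mask$data != 0
  x <- volume$data[inmask]
  rng <- range(x)
  lev <- array(NA_integer_, dim = dim(volume$data))
  if (rng[2] > rng[1]) {
    lev[inmask] <- pmin(G, as.integer(floor((x - rng[1]) / (rng[2] - rng[1]) * G)) + 1L)
  } else {
    lev[inmask] <- 1L
  }
  structure(list(levels = lev, G = G, n_voxels = sum(inmask),
                 spacing = volume$spacing),
            class = "hr_qroi")
}

# Entropies throughout the package use log base 2.
.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' First-order histogram statistics of an ROI
#'
#' Computes the catalog's 42 first-order features from the raw in-mask
#' intensities. Distribution-shape statistics (entropy, uniformity, mode)
#' are computed on a `G`-bin equal-width histogram over the ROI's min-max
#' range; uniformity is the sum of squared bin probabilities, maximal (= 1)
#' for a constant region. Moments use the population convention
#' (denominator n); skewness and kurtosis follow the standardized-moment
#' definitions (kurtosis not excess-corrected, so a point mass has
#' kurtosis 0 by the 0/0 -> 0 convention used for all degenerate ratios).
#'
#' @param x numeric vector of in-mask intensities.
#' @param G number of histogram bins for the distribution statistics.
#' @return Named numeric vector of length 42 (names match the catalog).
#' @export
histogram_features <- function(x, G = 64L) {
  stopifnot(length(x) > 0, all(is.finite(x)))
  n <- length(x)
  m <- mean(x)
  v <- sum((x - m)^2) / n
  s <- sqrt(v)
  skew <- if (s > 0) sum((x - m)^3) / n / s^3 else 0
  kurt <- if (s > 0) sum((x - m)^4) / n / s^4 else 0
  med <- stats::median(x)
  rng <- range(x)
  # equal-width histogram over the ROI range
  if (rng[2] > rng[1]) {
    lev <- pmin(G, floor((x - rng[1]) / (rng[2] - rng[1]) * G) + 1L)
  } else {
    lev <- rep(1L, n)
  }
  p <- tabulate(lev, nbins = G) / n
  qs <- stats::quantile(x, probs = c(0.025, 0.975, 0.01, seq(0.05, 0.95, by = 0.05),
                                     0.99, 0.25, 0.75),
                        names = FALSE, type = 7)
  mode_level <- which.max(p)
  mode_val <- if (rng[2] > rng[1])
    rng[1] + (mode_level - 0.5) / G * (rng[2] - rng[1]) else rng[1]
  out <- c(
    mean = m, median = med, min = rng[1], max = rng[2],
    range = rng[2] - rng[1], variance = v, stdev = s,
    skewness = skew, kurtosis = kurt, sum = sum(x),
    energy = sum(x^2), RMS = sqrt(mean(x^2)),
    MeanDeviation = mean(abs(x - m)),
    MedianDeviation = stats::median(abs(x - med)),
    RelativeDeviation = if (m != 0) mean(abs(x - m)) / abs(m) else 0,
    InterquartileRange = qs[25] - qs[24],
    entropy = .entropy(p), uniformity = sum(p^2), mode = mode_val,
    Percentile2.5 = qs[1], Percentile97.5 = qs[2]
  )
  pct <- qs[3:23]
  names(pct) <- paste0("Percentile", c(1, seq(5, 95, by = 5), 99))
  c(out, pct)
}

#' Form-factor (shape) descriptors of a binary mask
#'
#' Surface area is computed by exposed-voxel-face counting (each in-mask
#' voxel face not shared with another in-mask voxel contributes its physical
#' face area), a convention that is exact for the voxel model but biased
#' upward versus mesh-based estimates. Maximum 3D Diameter is the largest
#' pairwise Euclidean distance in mm between centers of boundary voxels
#' (voxels with at least one exposed face).
#'
#' @param mask an [hr_mask].
#' @param spacing voxel spacing in mm; defaults to the mask's own.
#' @return Named numeric vector of the 9 catalog shape features.
#' @export
shape_features <- function(mask, spacing = mask$spacing) {
  stopifnot(inherits(mask, "hr_mask"))
  b <- mask$data != 0
  d <- dim(b)
  n <- sum(b)
  voxvol <- prod(spacing)
  vol <- n * voxvol
  # exposed faces along each axis: pad with background and diff
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  pad <- function(a, axis) {
    dd <- dim(a)
    dd[axis] <- dd[axis] + 2L
    out <- array(FALSE, dd)
    idx <- lapply(seq_along(dd), function(k)
      if (k == axis) seq_len(dim(a)[k]) + 1L else seq_len(dd[k]))
    do.call(`[<-`, c(list(out), idx, list(a)))
  }
  exposed <- array(0L, d)  # per-voxel count of exposed faces
  area <- 0
  for (axis in 1:3) {
    pb <- pad(b, axis)
    n_ax <- dim(pb)[axis]
    # exposed faces on each side, restricted back to the original grid
    core <- lapply(1:3, function(k) if (k == axis) 2:(n_ax - 1L) else seq_len(dim(pb)[k]))
    shift_m <- lapply(1:3, function(k) if (k == axis) 1:(n_ax - 2L) else seq_len(dim(pb)[k]))
    shift_p <- lapply(1:3, function(k) if (k == axis) 3:n_ax else seq_len(dim(pb)[k]))
    bb <- do.call(`[`, c(list(pb), core, list(drop = FALSE)))
    bm <- do.call(`[`, c(list(pb), shift_m, list(drop = FALSE)))
    bp <- do.call(`[`, c(list(pb), shift_p, list(drop = FALSE)))
    exp_ax <- array(bb & !bm, d) + array(bb & !bp, d)
    exposed <- exposed + exp_ax
    area <- area + sum(exp_ax) * face_area[axis]
  }
  boundary <- which(b & exposed > 0, arr.ind = TRUE)
  if (nrow(boundary) >= 2) {
    pts <- sweep(boundary, 2, spacing, `*`)
    g <- rowSums(pts^2)
    d2 <- outer(g, g, `+`) - 2 * tcrossprod(pts)
    max_diam <- sqrt(max(0, max(d2)))
  } else {
    max_diam <- 0
  }
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  c(
    "VoxelCount" = n,
    "Volume" = vol,
    "SurfaceArea" = area,
    "Surface Volume Ratio" = area / vol,
    "Maximum 3D Diameter" = max_diam,
    "Sphericity" = pi^(1 / 3) * (6 * vol)^(2 / 3) / area,
    "Compactness1" = vol / (sqrt(pi) * area^(3 / 2)),
    "Compactness2" = 36 * pi * vol^2 / area^3,
    "Spherical Disproportion" = area / (4 * pi * r_eq^2)
  )
}
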