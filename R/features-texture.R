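# In-plane texture directions. Displacements are (drow, dcol) within an
# axial (x-y) slice, scaled by the offset d:
#   0 deg   -> (0,  d)
#   45 deg  -> (-d, d)
#   90 deg  -> (-d, 0)
#   135 deg -> (-d, -d)
.DIR_STEPS <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                   `90` = c(-1L, 0L), `135` = c(-1L, -1L))

#' Gray-level co-occurrence matrix
#'
#' Counts in-mask voxel pairs separated by `offset` steps along the given
#' in-plane direction, accumulated over axial slices, symmetrized, and
#' normalized to sum 1. If the ROI admits no pair at this displacement the
#' result is flagged empty and downstream features are `NA`.
#'
#' @param qroi an `hr_qroi` from [quantize()].
#' @param offset step length in voxels (>= 1).
#' @param angle direction in degrees, one of 0, 45, 90, 135.
#' @return A list of class `hr_glcm`: `p` (G x G matrix summing to 1, or all
#'   zero if empty), `n_pairs`, `offset`, `angle`, `empty`.
#' @export
glcm <- function(qroi, offset, angle) {
  stopifnot(inherits(qroi, "hr_qroi"), offset >= 1)
  step <- .DIR_STEPS[[as.character(angle)]]
  if (is.null(step)) stop("angle must be one of 0, 45, 90, 135")
  dr <- step[1] * offset
  dc <- step[2] * offset
  lev <- qroi$levels
  d <- dim(lev)
  G <- qroi$G
  # source voxel window such that (r+dr, c+dc) stays in the grid
  r1 <- max(1L, 1L - dr); r2 <- min(d[1], d[1] - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(d[2], d[2] - dc)
  counts <- numeric(G * G)
  if (r1 <= r2 && c1 <= c2) {
    a <- lev[r1:r2, c1:c2, , drop = FALSE]
    bm <- lev[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc), , drop = FALSE]
    ok <- !is.na(a) & !is.na(bm)
    if (any(ok)) {
      i <- a[ok]; j <- bm[ok]
      counts <- tabulate(i + G * (j - 1L), nbins = G * G)
    }
  }
  m <- matrix(counts, G, G)
  m <- m + t(m)   # symmetrize (each ordered pair counted both ways)
  n_pairs <- sum(m) / 2
  empty <- n_pairs == 0
  p <- if (empty) matrix(0, G, G) else m / sum(m)
  structure(list(p = p, n_pairs = n_pairs, offset = offset,
                 angle = angle, empty = empty),
            class = "hr_glcm")
}

#' Base GLCM (Haralick-family) texture statistics
#'
#' Eight statistics of a normalized co-occurrence matrix: Energy, Entropy,
#' Inertia (contrast), Correlation, Inverse Difference Moment, Cluster
#' Shade, Cluster Prominence, and Haralick Correlation. Correlation-type
#' features of a degenerate matrix (zero marginal variance) are 0 by
#' convention. An empty matrix yields all-`NA`.
#'
#' @param g an `hr_glcm`.
#' @return Named numeric vector of 8 values.
#' @export
glcm_features <- function(g) {
  stopifnot(inherits(g, "hr_glcm"))
  nm <- .GLCM_BASE
  if (g$empty) return(stats::setNames(rep(NA_real_, length(nm)), nm))
  p <- g$p
  G <- nrow(p)
  i <- row(p); j <- col(p)
  mu_x <- sum(i * p); mu_y <- sum(j * p)
  var_x <- sum((i - mu_x)^2 * p); var_y <- sum((j - mu_y)^2 * p)
  corr <- if (var_x > 0 && var_y > 0)
    sum((i - mu_x) * (j - mu_y) * p) / sqrt(var_x * var_y) else 0
  hcorr <- if (var_x > 0)
    (sum(i * j * p) - mu_x * mu_y) / sqrt(var_x * var_y) else 0
  stats::setNames(c(
    sum(p^2),
    .entropy(p),
    sum((i - j)^2 * p),
    corr,
    sum(p / (1 + (i - j)^2)),
    sum((i + j - mu_x - mu_y)^3 * p),
    sum((i + j - mu_x - mu_y)^4 * p),
    hcorr
  ), nm)
}

#' Haralick sum/difference statistics at offset 1
#'
#' Computes the ten sum- and difference-distribution statistics from the
#' four directional co-occurrence matrices at offset 1 and averages them
#' over directions: Sum Average ("sum of the means"), Sum Variance, Sum
#' Entropy, Difference Average/Variance/Entropy, the two information
#' measures of correlation, Maximum Probability, and Joint Average.
#'
#' @param qroi an `hr_qroi`.
#' @param glcms optional precomputed list of the four offset-1 `hr_glcm`s
#'   (angles 0, 45, 90, 135) to avoid recomputation.
#' @return Named numeric vector of 10 values (direction means; directions
#'   with no voxel pairs are excluded).
#' @export
haralick_block <- function(qroi, glcms = NULL) {
  if (is.null(glcms))
    glcms <- lapply(.ANGLES, function(a) glcm(qroi, 1L, a))
  vals <- vapply(glcms, function(g) {
    if (g$empty) return(rep(NA_real_, 10))
    p <- g$p
    G <- nrow(p)
    i <- row(p); j <- col(p)
    # p_{x+y}(k), k = 2..2G and p_{|x-y|}(k), k = 0..G-1
    psum <- as.vector(rowsum(as.vector(p), as.vector(i + j)))
    pdif <- as.vector(rowsum(as.vector(p), as.vector(abs(i - j))))
    ks <- 2:(2 * G); kd <- 0:(G - 1)
    sa <- sum(ks * psum)
    sv <- sum((ks - sa)^2 * psum)
    se <- .entropy(psum)
    da <- sum(kd * pdif)
    dv <- sum((kd - da)^2 * pdif)
    de <- .entropy(pdif)
    px <- rowSums(p); py <- colSums(p)
    hxy <- .entropy(p)
    hx <- .entropy(px); hy <- .entropy(py)
    pxy <- outer(px, py)
    nz <- p > 0 & pxy > 0
    hxy1 <- -sum(p[nz] * log2(pxy[nz]))
    hxy2 <- .entropy(pxy)
    imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
    imc2 <- sqrt(max(0, 1 - exp(-2 * log(2) * (hxy2 - hxy))))
    c(sa, sv, se, da, dv, de, imc1, imc2, max(p), sum(i * p))
  }, numeric(10))
  ok <- colSums(is.na(vals)) == 0
  if (!any(ok)) return(stats::setNames(rep(NA_real_, 10), .HARALICK_NAMES))
  stats::setNames(rowMeans(vals[, ok, drop = FALSE]), .HARALICK_NAMES)
}

# Decompose a slice into 1D chains along (drow, dcol) at stride d and
# return in-chain ordered level sequences. Chains are residue classes of
# the lattice generated by the step; out-of-mask voxels (NA) break runs.
.slice_chains <- function(sl, step, d) {
  nr <- nrow(sl); nc <- ncol(sl)
  r <- as.integer(row(sl)); c <- as.integer(col(sl))
  dr <- step[1]; dc <- step[2]
  if (dr == 0L) {            # horizontal: chains are (row, col residue)
    key <- r + nr * (c %% d)
    ord <- order(key, c)
  } else if (dc == 0L) {     # vertical
    key <- c + nc * (r %% d)
    ord <- order(key, r)
  } else {                   # diagonal: constant r*dc - c*dr, same residue
    key <- (dc * r - dr * c) * d + (r %% d)
    ord <- order(key, r * dr + c * dc)
  }
  split(as.vector(sl)[ord], key[ord])
}

#' Gray-level run-length matrix
#'
#' Runs are maximal sequences of equal gray levels visited at stride
#' `offset` along an in-plane direction, accumulated over axial slices.
#' Out-of-mask voxels break runs. At stride 1 this reduces to the classical
#' Galloway run-length matrix.
#'
#' @inheritParams glcm
#' @return A list of class `hr_rlm`: `r` (G x R count matrix), `n_runs`,
#'   `n_voxels` (in-mask voxels visited), `offset`, `angle`, `empty`.
#' @export
rlm <- function(qroi, offset, angle) {
  stopifnot(inherits(qroi, "hr_qroi"), offset >= 1)
  step <- .DIR_STEPS[[as.character(angle)]]
  if (is.null(step)) stop("angle must be one of 0, 45, 90, 135")
  lev <- qroi$levels
  d <- dim(lev)
  G <- qroi$G
  lev_i <- integer(0); len_i <- integer(0)
  for (z in seq_len(d[3])) {
    chains <- .slice_chains(matrix(lev[, , z], d[1], d[2]), step,
                            as.integer(offset))
    for (ch in chains) {
      rl <- rle(ch)
      keep <- !is.na(rl$values)
      if (any(keep)) {
        lev_i <- c(lev_i, rl$values[keep])
        len_i <- c(len_i, rl$lengths[keep])
      }
    }
  }
  if (length(lev_i) == 0L) {
    return(structure(list(r = matrix(0, G, 1), n_runs = 0, n_voxels = 0,
                          offset = offset, angle = angle, empty = TRUE),
                     class = "hr_rlm"))
  }
  R <- max(len_i)
  m <- matrix(0, G, R)
  idx <- lev_i + G * (len_i - 1L)
  tab <- tabulate(idx, nbins = G * R)
  m[] <- tab
  structure(list(r = m, n_runs = sum(m), n_voxels = sum(len_i),
                 offset = offset, angle = angle, empty = FALSE),
            class = "hr_rlm")
}

#' Run-length texture statistics
#'
#' Ten statistics of the run-length matrix, including Long Run Emphasis
#' (sum of r(i,l) * l^2 / N_runs) and Low Gray Level Run Emphasis
#' (sum of r(i,l) / i^2 / N_runs). Run Percentage divides the number of
#' runs by the number of in-mask voxels visited at this stride.
#'
#' @param rl an `hr_rlm`.
#' @return Named numeric vector of 10 values.
#' @export
rlm_features <- function(rl) {
  stopifnot(inherits(rl, "hr_rlm"))
  nm <- .RLM_BASE
  if (rl$empty) return(stats::setNames(rep(NA_real_, length(nm)), nm))
  m <- rl$r
  Nr <- sum(m)
  i <- row(m); l <- col(m)
  ri <- rowSums(m)   # runs per gray level
  rl_ <- colSums(m)  # runs per length
  lev <- seq_len(nrow(m))
  stats::setNames(c(
    sum(m / l^2) / Nr,
    sum(m * l^2) / Nr,
    sum(ri^2) / Nr,
    sum(rl_^2) / Nr,
    Nr / rl$n_voxels,
    sum(m / i^2) / Nr,
    sum(m * i^2) / Nr,
    sum(m / (i^2 * l^2)) / Nr,
    sum(m * l^2 / i^2) / Nr,
    sum(m * l^2 * i^2) / Nr
  ), nm)
}

#' Aggregate per-direction texture values
#'
#' Arithmetic mean and population standard deviation over the available
#' directions; directions with missing values are excluded. If all four are
#' missing both aggregates are `NA`.
#'
#' @param values numeric vector of per-direction feature values (length 4).
#' @return Named numeric vector `c(mean = ..., SD = ...)`.
#' @export
aggregate_directions <- function(values) {
  ok <- is.finite(values)
  if (!any(ok)) return(c(mean = NA_real_, SD = NA_real_))
  v <- values[ok]
  m <- mean(v)
  c(mean = m, SD = sqrt(mean((v - m)^2)))
}
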