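# Separable Gaussian smoothing of a 3D array via per-axis kernel matrices.
# Kernel rows are renormalized at the edges (truncated-kernel convention),
# so a constant field stays constant.
.gauss_smooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  smooth_axis <- function(a, axis) {
    n <- dim(a)[axis]
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, `-`)^2 / (2 * sigma^2))
    K[abs(outer(idx, idx, `-`)) > ceiling(4 * sigma)] <- 0
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- K %*% matrix(ap, nrow = dp[1])
    aperm(array(m, dp), order(perm))
  }
  for (ax in 1:3) a <- smooth_axis(a, ax)
  a
}

#' Specification of a synthetic two-group cohort
#'
#' Defines the study conditions for a simulated case-control imaging cohort:
#' group sizes, grid geometry, per-group texture smoothness (the Gaussian
#' correlation length of the intensity field, in voxels), per-group
#' intensity mean/SD, per-group hippocampus-like ellipsoid semi-axes (mm)
#' with a radial surface-perturbation amplitude (fractional), and additive
#' acquisition noise. Cases emulate amnestic MCI: smaller, more
#' heterogeneous (less smooth, higher intensity spread) hippocampi.
#'
#' @param n_per_group integer c(cases, controls); default c(42, 44).
#' @param grid volume dimensions in voxels.
#' @param spacing voxel spacing in mm.
#' @param sigma_tex per-group smoothing length c(case, control), voxels.
#' @param mu per-group intensity mean.
#' @param s per-group intensity SD.
#' @param semi_axes list of two length-3 numeric vectors (mm),
#'   case and control.
#' @param perturbation fractional radial surface perturbation amplitude.
#' @param noise_sd additive i.i.d. Gaussian noise SD.
#' @param subject_sd between-subject heterogeneity: per-subject Gaussian
#'   jitter SDs around the group parameters, as `sigma_tex` (voxels), `s`
#'   (intensity units), and `size` (fractional scale applied to the
#'   semi-axes). Draws are clamped to 2.5 SD so every ROI stays in-grid.
#' @param seed master seed for the cohort.
#' @return A list of class `hr_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(42L, 44L),
                        grid = c(44L, 40L, 28L),
                        spacing = c(1, 1, 1),
                        sigma_tex = c(case = 1.1, control = 1.3),
                        mu = c(case = 100, control = 100),
                        s = c(case = 22, control = 19),
                        semi_axes = list(case = c(7.7, 4.8, 3.84),
                                         control = c(8.0, 5.0, 4.0)),
                        perturbation = 0.12,
                        noise_sd = 4,
                        subject_sd = c(sigma_tex = 0.25, s = 3, size = 0.05),
                        seed = 1L) {
  stopifnot(all(n_per_group >= 1), all(grid >= 8), all(spacing > 0),
            all(sigma_tex >= 0), all(s >= 0), noise_sd >= 0,
            all(unlist(semi_axes) > 0), perturbation >= 0,
            all(subject_sd >= 0))
  structure(list(n_per_group = as.integer(n_per_group), grid = as.integer(grid),
                 spacing = spacing, sigma_tex = sigma_tex, mu = mu, s = s,
                 semi_axes = semi_axes, perturbation = perturbation,
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 seed = as.integer(seed)),
            class = "hr_cohort_spec")
}

#' Generate a textured 3D volume
#'
#' White Gaussian noise smoothed with an isotropic Gaussian kernel of width
#' `sigma_tex` voxels, rescaled to exact sample mean `mu` and SD `s`, plus
#' independent additive Gaussian noise of SD `noise_sd`. Larger `sigma_tex`
#' yields smoother texture (higher GLCM Inverse Difference Moment, longer
#' runs); larger `s` spreads the intensity histogram.
#'
#' @param grid volume dimensions in voxels.
#' @param spacing voxel spacing in mm.
#' @param mu,s target sample mean and SD of the smoothed field.
#' @param sigma_tex Gaussian smoothing length in voxels (0 = i.i.d. field).
#' @param noise_sd additive noise SD.
#' @param seed RNG seed; the result is a deterministic function of the
#'   arguments.
#' @return An [hr_volume].
#' @export
generate_textured_volume <- function(grid, spacing = c(1, 1, 1), mu = 100,
                                     s = 20, sigma_tex = 1, noise_sd = 0,
                                     seed = 1L) {
  stopifnot(all(grid > 0), s >= 0, sigma_tex >= 0, noise_sd >= 0)
  set.seed(seed)
  a <- array(stats::rnorm(prod(grid)), dim = grid)
  a <- .gauss_smooth3d(a, sigma_tex)
  sd0 <- stats::sd(as.vector(a))
  a <- if (sd0 > 0) (a - mean(a)) / sd0 * s + mu else a * 0 + mu
  if (noise_sd > 0) a <- a + array(stats::rnorm(prod(grid), sd = noise_sd), dim = grid)
  hr_volume(a, spacing)
}

#' Generate an (optionally perturbed) ellipsoid mask
#'
#' A voxel belongs to the mask iff its center lies inside the ellipsoid,
#' i.e. sum((x_k - c_k)^2 / a_k^2) <= (1 + eps)^2 where eps is a smooth
#' random radial perturbation field of amplitude `perturbation` (fraction
#' of the local radius). With `perturbation = 0` the mask is the exact
#' voxel-center ellipsoid.
#'
#' @param grid volume dimensions in voxels.
#' @param spacing voxel spacing in mm.
#' @param center ellipsoid center in mm (voxel-center coordinates,
#'   axis k spans spacing[k] * (1..grid[k])).
#' @param semi_axes length-3 semi-axes in mm.
#' @param perturbation fractional radial perturbation amplitude (>= 0).
#' @param seed RNG seed for the perturbation field.
#' @param side optional left/right label.
#' @return An [hr_mask].
#' @export
generate_ellipsoid_mask <- function(grid, spacing = c(1, 1, 1), center,
                                    semi_axes, perturbation = 0, seed = 1L,
                                    side = NA_character_) {
  stopifnot(all(semi_axes > 0), perturbation >= 0)
  # worst-case extent including perturbation must fit in the grid
  ext <- semi_axes * (1 + perturbation)
  lo <- center - ext
  hi <- center + ext
  if (any(lo < spacing * 0.5) || any(hi > spacing * (grid + 0.5)))
    stop("ellipsoid exceeds grid bounds")
  co <- lapply(1:3, function(k) spacing[k] * seq_len(grid[k]) - center[k])
  rho2 <- outer(outer((co[[1]] / semi_axes[1])^2, (co[[2]] / semi_axes[2])^2, `+`),
                (co[[3]] / semi_axes[3])^2, `+`)
  thr <- 1
  if (perturbation > 0) {
    set.seed(seed)
    f <- .gauss_smooth3d(array(stats::rnorm(prod(grid)), dim = grid), 2)
    f <- f / stats::sd(as.vector(f))
    thr <- (1 + perturbation * f)^2
  }
  hr_mask(array(as.numeric(rho2 <= thr), dim = grid), spacing, side)
}

# deterministic per-subject seed streams derived from the master seed
.derive_seed <- function(seed, i, stream) {
  (as.integer(seed) * 7919L + i * 104729L + stream * 31L) %% 2147483647L
}

#' Generate a synthetic cohort on disk
#'
#' Writes one textured volume and mirrored left/right ellipsoid masks per
#' subject (NIfTI), plus a manifest CSV with labels and simulated
#' demographics. Group differences follow the cohort specification: cases
#' have smaller ROIs, rougher texture, and wider intensity spread. The
#' cohort is fully reproducible from the specification (including its seed).
#'
#' @param spec an `hr_cohort_spec`.
#' @param dir output directory (created if needed).
#' @return The manifest (invisibly also written to `dir/manifest.csv`).
#' @export
generate_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "hr_cohort_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- rep(c("aMCI", "NC"), spec$n_per_group)
  n <- length(groups)
  grid <- spec$grid
  sp <- spec$spacing
  # mirrored ROI centers in the left/right halves of the x axis
  cz <- sp * (grid + 1) / 2
  off_x <- grid[1] * sp[1] * 0.25
  centers <- list(left = c(cz[1] - off_x, cz[2], cz[3]),
                  right = c(cz[1] + off_x, cz[2], cz[3]))
  rows <- vector("list", n)
  ssd <- spec$subject_sd
  if (is.null(ssd)) ssd <- c(sigma_tex = 0, s = 0, size = 0)
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  for (i in seq_len(n)) {
    g <- if (groups[i] == "aMCI") "case" else "control"
    # subject-level biological heterogeneity around the group parameters
    set.seed(.derive_seed(spec$seed, i, 5L))
    jit <- stats::rnorm(3)
    sig_i <- max(0, spec$sigma_tex[[g]] +
                   clamp(jit[1], -2.5, 2.5) * ssd[["sigma_tex"]])
    s_i <- max(0.1, spec$s[[g]] + clamp(jit[2], -2.5, 2.5) * ssd[["s"]])
    scale_i <- 1 + clamp(jit[3], -2.5, 2.5) * ssd[["size"]]
    vol <- generate_textured_volume(grid, sp, mu = spec$mu[[g]], s = s_i,
                                    sigma_tex = sig_i,
                                    noise_sd = spec$noise_sd,
                                    seed = .derive_seed(spec$seed, i, 1L))
    sid <- sprintf("S%03d", i)
    vpath <- file.path(dir, paste0(sid, "_vol.nii.gz"))
    write_nifti(vol, vpath)
    mpaths <- list()
    for (side in c("left", "right")) {
      stream <- if (side == "left") 2L else 3L
      msk <- generate_ellipsoid_mask(grid, sp, centers[[side]],
                                     spec$semi_axes[[g]] * scale_i,
                                     perturbation = spec$perturbation,
                                     seed = .derive_seed(spec$seed, i, stream),
                                     side = side)
      mpaths[[side]] <- file.path(dir, paste0(sid, "_mask_", side, ".nii.gz"))
      write_nifti(msk, mpaths[[side]])
    }
    set.seed(.derive_seed(spec$seed, i, 4L))
    rows[[i]] <- data.frame(
      subject_id = sid, label = groups[i],
      volume = vpath, mask_left = mpaths$left, mask_right = mpaths$right,
      age = round(stats::rnorm(1, if (g == "case") 64.2 else 65.4,
                               if (g == "case") 10.6 else 9.7), 1),
      sex = sample(c("M", "F"), 1, prob = c(0.44, 0.56)),
      education = round(stats::rnorm(1, if (g == "case") 7.7 else 7.1,
                                     if (g == "case") 2.8 else 3.4), 1),
      mmse = round(stats::rnorm(1, if (g == "case") 25.9 else 29.1,
                                if (g == "case") 0.9 else 0.8), 0),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  class(manifest) <- c("hr_manifest", "data.frame")
  invisible(manifest)
}
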