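# The default radiomic catalog: 385 features =
#   42 first-order histogram statistics
# +  9 form-factor (shape) descriptors
# + 144 GLCM texture features (8 base x 6 direction variants x 3 offsets)
# +  10 Haralick sum/difference statistics (offset 1, direction-averaged)
# + 180 RLM features (10 base x 6 direction variants x 3 offsets)
#
# Direction variants: the four in-plane angles 0/45/90/135 degrees plus
# "All Direction" mean and SD aggregates, rendered in the naming dialect
# "<Base>_All Direction_offset<d>[_SD]".

.HIST_NAMES <- c(
  "mean", "median", "min", "max", "range", "variance", "stdev",
  "skewness", "kurtosis", "sum", "energy", "RMS",
  "MeanDeviation", "MedianDeviation", "RelativeDeviation",
  "InterquartileRange", "entropy", "uniformity", "mode",
  "Percentile2.5", "Percentile97.5",
  paste0("Percentile", c(1, seq(5, 95, by = 5), 99))
)

.SHAPE_NAMES <- c(
  "VoxelCount", "Volume", "SurfaceArea", "Surface Volume Ratio",
  "Maximum 3D Diameter", "Sphericity", "Compactness1", "Compactness2",
  "Spherical Disproportion"
)

.GLCM_BASE <- c(
  "Energy", "GLCMEntropy", "Inertia", "Correlation",
  "Inverse Difference Moment", "Cluster Shade", "Cluster Prominence",
  "Haralick Correlation"
)

.HARALICK_NAMES <- c(
  "Sum Average", "Sum Variance", "Sum Entropy",
  "Difference Average", "Difference Variance", "Difference Entropy",
  "Information Measure Correlation 1", "Information Measure Correlation 2",
  "Maximum Probability", "Joint Average"
)

# Ten run-length statistics (the classical set of eleven minus Short Run
# High Gray Level Emphasis, to keep the catalog at its declared size; the
# retained set covers every run-length family used downstream).
.RLM_BASE <- c(
  "Short Run Emphasis", "Long Run Emphasis",
  "Gray Level Nonuniformity", "Run Length Nonuniformity",
  "Run Percentage",
  "Low Gray Level Run Emphasis", "High Gray Level Run Emphasis",
  "Short Run Low Gray Level Emphasis",
  "Long Run Low Gray Level Emphasis", "Long Run High Gray Level Emphasis"
)

.ANGLES <- c(0L, 45L, 90L, 135L)
.OFFSETS <- c(1L, 4L, 7L)

.texture_names <- function(base, offset) {
  c(paste0(base, "_angle", .ANGLES, "_offset", offset),
    paste0(base, "_All Direction_offset", offset),
    paste0(base, "_All Direction_offset", offset, "_SD"))
}

#' The default feature catalog
#'
#' Enumerates the full 385-feature catalog as a data.frame of descriptors:
#' feature family, base statistic, direction variant, and offset. Feature
#' names are unique and follow the "All Direction" naming dialect, e.g.
#' `"Long Run Emphasis_All Direction_offset7_SD"`.
#'
#' @param offsets integer offsets (voxel step lengths) for the GLCM and RLM
#'   families; default `c(1, 4, 7)`.
#' @param n_levels number of gray levels used for discretization (recorded
#'   in the catalog metadata; default 64).
#' @return A data.frame of class `hr_catalog` with columns `name`, `family`,
#'   `base`, `variant`, `offset`; attribute `n_levels`.
#' @export
feature_catalog <- function(offsets = .OFFSETS, n_levels = 64L) {
  variants <- c(paste0("angle", .ANGLES), "AllDirection_mean", "AllDirection_SD")
  rows <- list(
    data.frame(name = .HIST_NAMES, family = "histogram",
               base = .HIST_NAMES, variant = NA_character_,
               offset = NA_integer_, stringsAsFactors = FALSE),
    data.frame(name = .SHAPE_NAMES, family = "form_factor",
               base = .SHAPE_NAMES, variant = NA_character_,
               offset = NA_integer_, stringsAsFactors = FALSE)
  )
  for (d in offsets) for (b in .GLCM_BASE) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = .texture_names(b, d), family = "glcm", base = b,
      variant = variants, offset = d, stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    name = .HARALICK_NAMES, family = "haralick", base = .HARALICK_NAMES,
    variant = "AllDirection_mean", offset = 1L, stringsAsFactors = FALSE)
  for (d in offsets) for (b in .RLM_BASE) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = .texture_names(b, d), family = "rlm", base = b,
      variant = variants, offset = d, stringsAsFactors = FALSE)
  }
  cat <- do.call(rbind, rows)
  rownames(cat) <- NULL
  stopifnot(!anyDuplicated(cat$name))
  attr(cat, "n_levels") <- as.integer(n_levels)
  class(cat) <- c("hr_catalog", "data.frame")
  cat
}
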