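# Spacing comparisons tolerate float32 header round-trips.
.SPACING_TOL <- 1e-4

#' Construct a 3D volume object
#'
#' A `hr_volume` bundles a 3D scalar array with its voxel spacing in mm.
#' All downstream geometry (shape features, mm distances) uses the spacing.
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3 vector of positive voxel sizes in mm.
#' @return An object of class `hr_volume` with elements `data` and `spacing`.
#' @export
hr_volume <- function(data, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) stop("expected 3D volume")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values (mm)")
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L)
    stop(sprintf("volume contains %d non-finite voxel(s)", n_bad))
  structure(list(data = data, spacing = spacing), class = "hr_volume")
}

#' Construct a binary mask object
#'
#' Nonzero voxels are binarized to 1; binarization is idempotent. A mask must
#' share grid shape and spacing with its reference volume and contain at
#' least one foreground voxel.
#'
#' @param data numeric/logical 3D array; any nonzero value marks foreground.
#' @param spacing voxel spacing in mm.
#' @param side optional label, `"left"` or `"right"`.
#' @return An object of class `hr_mask` with binary `data` in {0,1}.
#' @export
hr_mask <- function(data, spacing = c(1, 1, 1), side = NA_character_) {
  if (length(dim(data)) != 3L) stop("expected 3D mask")
  if (any(!is.finite(data))) stop("mask contains non-finite values")
  bin <- array(as.numeric(data != 0), dim = dim(data))
  if (sum(bin) < 1) stop("empty mask: no foreground voxels")
  if (!is.na(side) && !side %in% c("left", "right"))
    stop("side must be 'left' or 'right'")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("invalid spacing")
  structure(list(data = bin, spacing = spacing, side = side),
            class = "hr_mask")
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file holding a 3D image.
#' @return An [hr_volume] with spacing taken from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected 3D volume, got ", length(dim(img)), "D: ", path)
  hr_volume(array(as.numeric(img), dim = dim(img)),
            spacing = RNifti::pixdim(img))
}

#' Read a NIfTI-1 binary mask and validate it against a reference volume
#'
#' @param path path to the mask file.
#' @param reference the [hr_volume] the mask must be co-registered with.
#' @param side optional `"left"`/`"right"` label attached to the mask.
#' @return An [hr_mask] on the reference grid.
#' @export
read_mask <- function(path, reference, side = NA_character_) {
  stopifnot(inherits(reference, "hr_volume"))
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected 3D mask: ", path)
  if (!identical(dim(img), dim(reference$data)))
    stop(sprintf("geometric mismatch: mask grid %s vs reference %s",
                 paste(dim(img), collapse = "x"),
                 paste(dim(reference$data), collapse = "x")))
  sp <- RNifti::pixdim(img)
  if (any(abs(sp - reference$spacing) > .SPACING_TOL))
    stop("geometric mismatch: mask spacing differs from reference")
  hr_mask(array(as.numeric(img), dim = dim(img)),
          spacing = reference$spacing, side = side)
}

#' Write a volume or mask to NIfTI-1
#'
#' @param x an [hr_volume] or [hr_mask].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  stopifnot(inherits(x, "hr_volume") || inherits(x, "hr_mask"))
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with one row per subject: `subject_id`, `label`
#' (exactly two classes, e.g. aMCI/NC), `volume`, `mask_left`, `mask_right`
#' paths, and optional demographics (`age`, `sex`, `education`, `mmse`).
#'
#' @param path CSV path.
#' @return A data.frame of class `hr_manifest`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("subject_id", "label")
  miss <- setdiff(req, names(m))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(m$subject_id))
    stop("duplicate subject ids in manifest")
  labs <- unique(m$label)
  if (length(labs) != 2L)
    stop("manifest must contain exactly two label values, found: ",
         paste(labs, collapse = ", "))
  class(m) <- c("hr_manifest", "data.frame")
  m
}

#' Write and read feature tables
#'
#' A feature table has one row per (subject, side) with columns
#' `subject_id`, `label`, `side`, then one column per catalog feature.
#' Feature names (which contain spaces, in the "All Direction" dialect)
#' round-trip verbatim.
#'
#' @param table feature table data.frame.
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the data.frame.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
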