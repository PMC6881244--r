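# Crop a volume/mask pair to the mask bounding box (plus one voxel of
# context is unnecessary: all statistics are mask-restricted).
.crop_to_mask <- function(volume, mask) {
  idx <- which(mask$data != 0, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  v <- volume$data[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                   rng[1, 3]:rng[2, 3], drop = FALSE]
  m <- mask$data[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                 rng[1, 3]:rng[2, 3], drop = FALSE]
  list(volume = hr_volume(v, volume$spacing),
       mask = hr_mask(m, mask$spacing, mask$side))
}

#' Extract the full radiomic feature vector from a volume/mask pair
#'
#' Computes every feature of the catalog, in catalog order: 42 first-order
#' histogram statistics, 9 form-factor descriptors, the GLCM family at
#' offsets 1/4/7 in four in-plane directions plus All Direction mean/SD
#' aggregates, the ten Haralick sum/difference statistics at offset 1, and
#' the RLM family with the same direction/offset layout. Features whose
#' matrix is empty (e.g. no voxel pair at offset 7 in a thin ROI) are
#' emitted as `NA` for downstream mean-imputation.
#'
#' @param volume an [hr_volume].
#' @param mask an [hr_mask] on the same grid.
#' @param catalog a catalog from [feature_catalog()].
#' @return Named numeric vector, one value per catalog entry (default 385).
#' @export
extract_all <- function(volume, mask, catalog = feature_catalog()) {
  stopifnot(inherits(volume, "hr_volume"), inherits(mask, "hr_mask"))
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("volume and mask grids differ")
  cr <- .crop_to_mask(volume, mask)
  G <- attr(catalog, "n_levels")
  offsets <- sort(unique(catalog$offset[catalog$family == "glcm"]))
  q <- quantize(cr$volume, cr$mask, G)

  out <- stats::setNames(rep(NA_real_, nrow(catalog)), catalog$name)
  x <- cr$volume$data[cr$mask$data != 0]
  hf <- histogram_features(x, G)
  out[names(hf)] <- hf
  sf <- shape_features(cr$mask)
  out[names(sf)] <- sf

  glcm1 <- NULL
  for (d in offsets) {
    gs <- lapply(.ANGLES, function(a) glcm(q, d, a))
    if (d == 1L) glcm1 <- gs
    vals <- vapply(gs, glcm_features, numeric(length(.GLCM_BASE)))
    for (k in seq_along(.GLCM_BASE)) {
      b <- .GLCM_BASE[k]
      out[paste0(b, "_angle", .ANGLES, "_offset", d)] <- vals[k, ]
      ag <- aggregate_directions(vals[k, ])
      out[paste0(b, "_All Direction_offset", d)] <- ag["mean"]
      out[paste0(b, "_All Direction_offset", d, "_SD")] <- ag["SD"]
    }
    rs <- lapply(.ANGLES, function(a) rlm(q, d, a))
    rvals <- vapply(rs, function(r) rlm_features(r), numeric(length(.RLM_BASE)))
    for (k in seq_along(.RLM_BASE)) {
      b <- .RLM_BASE[k]
      out[paste0(b, "_angle", .ANGLES, "_offset", d)] <- rvals[k, ]
      ag <- aggregate_directions(rvals[k, ])
      out[paste0(b, "_All Direction_offset", d)] <- ag["mean"]
      out[paste0(b, "_All Direction_offset", d, "_SD")] <- ag["SD"]
    }
  }
  if (is.null(glcm1)) glcm1 <- lapply(.ANGLES, function(a) glcm(q, 1L, a))
  hb <- haralick_block(q, glcm1)
  out[names(hb)] <- hb
  out
}

#' Extract features for every subject and side in a cohort
#'
#' @param manifest an `hr_manifest` from [read_manifest()], with `volume`,
#'   `mask_left`, `mask_right` path columns.
#' @param catalog a catalog from [feature_catalog()].
#' @param sides which hippocampi to process.
#' @param verbose print progress.
#' @return A feature table data.frame: `subject_id`, `label`, `side`, then
#'   one column per catalog feature.
#' @export
extract_cohort <- function(manifest, catalog = feature_catalog(),
                           sides = c("left", "right"), verbose = FALSE) {
  sides <- match.arg(sides, c("left", "right"), several.ok = TRUE)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    vol <- read_volume(manifest$volume[i])
    for (side in sides) {
      msk <- read_mask(manifest[[paste0("mask_", side)]][i], vol, side)
      fv <- extract_all(vol, msk, catalog)
      rows[[length(rows) + 1L]] <- c(
        list(subject_id = manifest$subject_id[i],
             label = manifest$label[i], side = side),
        as.list(fv))
    }
    if (verbose && i %% 10 == 0)
      message("extracted ", i, "/", nrow(manifest), " subjects")
  }
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  tab
}

#' Names of the feature columns of a feature table
#' @param table a feature table.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "label", "side"))
}
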