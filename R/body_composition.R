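#' Voxelwise fat fraction from a Dixon water/fat image pair
#'
#' `FF = F / (W + F)` per voxel. Voxels whose total signal `W + F` falls
#' below `background_tol` times the robust (99.9th percentile) maximum are
#' background and set to `NA` rather than 0/0.
#'
#' @param water,fat [voxel_image()]s on the same grid, signals >= 0.
#' @param background_tol background threshold as a fraction of the robust
#'   maximum total signal (default 0.05).
#' @return A [voxel_image()] with values in \[0, 1\] on body voxels and `NA`
#'   on background.
#' @export
fat_fraction <- function(water, fat, background_tol = 0.05) {
  check_same_grid(water, fat)
  if (min(water$data) < 0 || min(fat$data) < 0) {
    stop("water/fat signals must be non-negative", call. = FALSE)
  }
  total <- water$data + fat$data
  thr <- background_tol * stats::quantile(total, 0.999, names = FALSE)
  ff <- fat$data / total
  ff[total <= thr] <- NA_real_
  voxel_image(ff, water$vox_mm)
}

#' Segment body, adipose and non-adipose tissue from a fat-fraction map
#'
#' Transparent threshold rule standing in for vendor "automated image
#' analysis": body = all non-background voxels; adipose = body voxels with
#' `FF >= threshold`; non-adipose = the rest of the body. The three masks
#' partition the body exactly, so adipose + non-adipose volume equals
#' whole-body volume by construction.
#'
#' @param ff a [fat_fraction()] image (`NA` = background).
#' @param threshold adipose fat-fraction cut-off (default 0.5).
#' @return List of logical [voxel_image()]s: `body`, `adipose`, `non_adipose`.
#' @export
segment_body_and_adipose <- function(ff, threshold = 0.5) {
  body <- !is.na(ff$data)
  adipose <- body & !is.na(ff$data) & ff$data >= threshold
  adipose[is.na(adipose)] <- FALSE
  list(
    body = voxel_image(array(body, dim(ff$data)), ff$vox_mm),
    adipose = voxel_image(array(adipose, dim(ff$data)), ff$vox_mm),
    non_adipose = voxel_image(array(body & !adipose, dim(ff$data)), ff$vox_mm)
  )
}

#' Volume of a voxel mask in litres
#'
#' @param mask logical [voxel_image()] (or numeric treated as non-zero).
#' @return Volume in litres.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "voxel_image"))
  n <- sum(mask$data != 0, na.rm = TRUE)
  n * voxel_volume_ml(mask) / 1000
}

#' Mean fat percentage over a region of interest
#'
#' Mean fat fraction over the ROI voxels, times 100. Used for liver and
#' pancreas fat on delineated fat-fraction maps.
#'
#' @param ff a [fat_fraction()] image.
#' @param roi_mask logical [voxel_image()] on the same grid.
#' @return Fat content in percent.
#' @export
roi_fat_percent <- function(ff, roi_mask) {
  check_same_grid(ff, roi_mask)
  sel <- roi_mask$data != 0
  if (!any(sel)) stop("empty ROI", call. = FALSE)
  vals <- ff$data[sel]
  if (all(is.na(vals))) stop("ROI lies entirely in background", call. = FALSE)
  mean(vals, na.rm = TRUE) * 100
}

#' Body-composition summary for one water/fat image pair
#'
#' Runs fat-fraction mapping, body/adipose segmentation and volume
#' quantification; liver and pancreas fat are computed when their ROI masks
#' are supplied.
#'
#' @param water,fat [voxel_image()]s.
#' @param liver_mask,pancreas_mask optional logical [voxel_image()] ROIs.
#' @param threshold adipose fat-fraction cut-off.
#' @param background_tol see [fat_fraction()].
#' @return One-row data.frame: `whole_body_volume_l`, `adipose_volume_l`,
#'   `non_adipose_volume_l`, `liver_fat_pct`, `pancreas_fat_pct`.
#' @export
body_composition <- function(water, fat, liver_mask = NULL, pancreas_mask = NULL,
                             threshold = 0.5, background_tol = 0.05) {
  ff <- fat_fraction(water, fat, background_tol)
  masks <- segment_body_and_adipose(ff, threshold)
  data.frame(
    whole_body_volume_l = mask_volume(masks$body),
    adipose_volume_l = mask_volume(masks$adipose),
    non_adipose_volume_l = mask_volume(masks$non_adipose),
    liver_fat_pct = if (is.null(liver_mask)) NA_real_ else roi_fat_percent(ff, liver_mask),
    pancreas_fat_pct = if (is.null(pancreas_mask)) NA_real_ else roi_fat_percent(ff, pancreas_mask)
  )
}
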