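#' Binary region-of-interest mask
#'
#' @param mask 3D logical (or 0/1 numeric) array.
#' @param label one of `"gtv"`, `"cystic_necrotic"`, `"viable"`.
#' @param voxel_spacing_mm length-3 voxel spacing, mm.
#' @return a `roi_mask` object.
#' @export
roi_mask <- function(mask, label = c("gtv", "cystic_necrotic", "viable"),
                     voxel_spacing_mm) {
  label <- match.arg(label)
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) stop("mask must be logical or 0/1")
    mask <- array(mask != 0, dim(mask))
  }
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  stopifnot(length(voxel_spacing_mm) == 3L, all(voxel_spacing_mm > 0))
  structure(list(mask = mask, label = label,
                 voxel_spacing = as.numeric(voxel_spacing_mm)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s: %d voxels (%.3f cm^3) on %s grid\n",
              x$label, sum(x$mask), compute_volume(x),
              paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

.check_same_grid <- function(a_dim, b_dim, what) {
  if (!identical(a_dim, b_dim))
    stop("grid mismatch between ", what, ": ",
         paste(a_dim, collapse = "x"), " vs ", paste(b_dim, collapse = "x"),
         "; resampling is not performed, supply masks on the ADC grid")
}

#' Viable tumor by Boolean ROI subtraction
#'
#' Implements viable = GTV AND NOT cystic. Cystic voxels lying outside the
#' GTV contribute nothing; their count is reported as a warning (and stored
#' as attribute `n_outside`) since it usually indicates a contouring or
#' registration problem.
#'
#' @param gtv `roi_mask` labeled gtv (whole gross tumor volume).
#' @param cystic `roi_mask` of the cystic/necrotic component.
#' @return `roi_mask` labeled `"viable"`.
#' @export
subtract_rois <- function(gtv, cystic) {
  stopifnot(inherits(gtv, "roi_mask"), inherits(cystic, "roi_mask"))
  .check_same_grid(dim(gtv$mask), dim(cystic$mask), "GTV and cystic masks")
  n_outside <- sum(cystic$mask & !gtv$mask)
  if (n_outside > 0)
    warning(sprintf("%d cystic voxel(s) fall outside the GTV and are ignored",
                    n_outside))
  viable <- gtv$mask & !cystic$mask
  if (!any(viable))
    stop("viable mask is empty after subtracting cystic from the '",
         gtv$label, "' ROI")
  out <- roi_mask(viable, "viable", gtv$voxel_spacing)
  attr(out, "n_outside") <- n_outside
  out
}

#' ROI volume in cm^3
#'
#' Voxel count times the voxel volume (product of spacings, mm^3) divided by
#' 1000. An empty mask yields 0 with a warning.
#'
#' @param mask a `roi_mask`.
#' @return volume in cm^3.
#' @export
compute_volume <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  n <- sum(mask$mask)
  if (n == 0) warning("empty ROI mask: volume is 0")
  n * (prod(mask$voxel_spacing) / 1000)
}

#' Extract valid ADC values within an ROI
#'
#' Returns ADC values at ROI voxels where the fit is valid, in deterministic
#' (column-major voxel index) order. The number of ROI voxels excluded for
#' invalid fits is reported as a message and stored as attribute
#' `n_excluded`.
#'
#' @param adc an `adc_map`.
#' @param roi a `roi_mask` on the same grid.
#' @return numeric vector of ADC values (mm^2/s).
#' @export
extract_values <- function(adc, roi) {
  stopifnot(inherits(adc, "adc_map"), inherits(roi, "roi_mask"))
  .check_same_grid(dim(adc$values), dim(roi$mask), "ADC map and ROI")
  if (!any(roi$mask)) stop("ROI is empty")
  sel <- roi$mask & adc$valid
  n_excluded <- sum(roi$mask) - sum(sel)
  if (sum(sel) == 0L)
    stop("no valid ADC voxels inside the '", roi$label, "' ROI")
  if (n_excluded > 0)
    message(sprintf("extract_values: %d invalid voxel(s) excluded from '%s'",
                    n_excluded, roi$label))
  out <- adc$values[sel]
  attr(out, "n_excluded") <- n_excluded
  out
}
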