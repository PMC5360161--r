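#' Multi-b-value DWI series
#'
#' Container for co-registered diffusion-weighted volumes acquired at one
#' timepoint: one 3D signal array per b-value, all on a single grid.
#'
#' @param b_values numeric diffusion weightings, s/mm^2 (>= 0, >= 2 distinct).
#' @param volumes list of 3D arrays, one per b-value, same shape.
#' @param voxel_spacing_mm length-3 voxel spacing, mm.
#' @param week week index (0 = pretreatment); optional metadata.
#' @param days_from_rt_start days from radiotherapy start; optional metadata.
#' @return a `dwi_series` object.
#' @export
dwi_series <- function(b_values, volumes, voxel_spacing_mm,
                       week = NA_integer_, days_from_rt_start = NA_integer_) {
  b_values <- as.numeric(b_values)
  if (length(unique(b_values)) < 2L) stop("need at least 2 distinct b-values")
  if (any(b_values < 0)) stop("b-values must be >= 0")
  if (length(volumes) != length(b_values))
    stop("one volume per b-value required")
  shp <- dim(volumes[[1]])
  if (length(shp) != 3L) stop("volumes must be 3D arrays")
  for (v in volumes) {
    if (!identical(dim(v), shp))
      stop("grid mismatch: all volumes must share one shape")
  }
  stopifnot(length(voxel_spacing_mm) == 3L, all(voxel_spacing_mm > 0))
  structure(list(b_values = b_values, volumes = volumes,
                 voxel_spacing = as.numeric(voxel_spacing_mm),
                 week = week, days_from_rt_start = days_from_rt_start),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("<dwi_series> grid %s, b = {%s} s/mm^2, week %s\n",
              paste(dim(x$volumes[[1]]), collapse = "x"),
              paste(x$b_values, collapse = ", "),
              x$week))
  invisible(x)
}

.adc_map <- function(values, valid, voxel_spacing, n_negative) {
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid,
                 voxel_spacing = voxel_spacing,
                 n_negative = n_negative),
            class = "adc_map")
}

#' @export
print.adc_map <- function(x, ...) {
  cat(sprintf("<adc_map> grid %s, %d/%d valid voxels, %d negative ADC\n",
              paste(dim(x$values), collapse = "x"),
              sum(x$valid), length(x$valid), x$n_negative))
  invisible(x)
}

.apply_negative_policy <- function(values, valid, policy) {
  neg <- valid & values < 0
  n_neg <- sum(neg)
  if (n_neg > 0) {
    if (policy == "clip") {
      values[neg] <- 0
    } else if (policy == "invalidate") {
      valid[neg] <- FALSE
    }
    message(sprintf("ADC fit: %d voxel(s) with negative ADC (policy: %s)",
                    n_neg, policy))
  }
  list(values = values, valid = valid, n_negative = n_neg)
}

#' Voxel-wise ADC from a two-point acquisition
#'
#' Inverts the monoexponential decay `S(b) = S(0) * exp(-b * ADC)` for an
#' acquisition with exactly two b-values, one of which is 0:
#' `ADC = ln(S(0) / S(b)) / b`, in mm^2/s. Voxels where either signal is
#' non-positive or non-finite are marked invalid (the log is undefined) and
#' excluded from all downstream statistics. Noise can drive `S(b) > S(0)` and
#' hence negative ADC; the policy for such voxels is configurable and the
#' count is reported via `message()` and stored on the map.
#'
#' @param series a [dwi_series()] with exactly two b-values, one equal to 0.
#' @param negative_policy `"retain"` (default: keep the negative value),
#'   `"clip"` (set to 0), or `"invalidate"` (mark invalid).
#' @return an `adc_map`: `values` (mm^2/s, `NA` where invalid), `valid`
#'   (logical array), `voxel_spacing`, `n_negative`.
#' @export
fit_adc_pair <- function(series,
                         negative_policy = c("retain", "clip", "invalidate")) {
  stopifnot(inherits(series, "dwi_series"))
  negative_policy <- match.arg(negative_policy)
  if (length(series$b_values) != 2L)
    stop("fit_adc_pair requires exactly two b-values; use fit_adc_multib")
  ord <- order(series$b_values)
  b_low <- series$b_values[ord[1]]; b_high <- series$b_values[ord[2]]
  if (b_low != 0) stop("fit_adc_pair requires one b-value equal to 0")
  if (b_high == 0) stop("the high b-value must be > 0")
  s0 <- series$volumes[[ord[1]]]
  sb <- series$volumes[[ord[2]]]

  valid <- is.finite(s0) & is.finite(sb) & s0 > 0 & sb > 0
  values <- array(NA_real_, dim(s0))
  values[valid] <- log(s0[valid] / sb[valid]) / b_high
  res <- .apply_negative_policy(values, valid, negative_policy)
  .adc_map(res$values, res$valid, series$voxel_spacing, res$n_negative)
}

#' Voxel-wise ADC from two or more b-values (log-linear least squares)
#'
#' Fits the monoexponential model per voxel by ordinary least squares of
#' `ln S(b)` on `b`; the negative slope is the ADC. With exactly two b-values
#' (one of them 0) this reduces to the two-point formula of [fit_adc_pair()].
#' Voxels with any non-positive or non-finite signal across the b-values are
#' invalid.
#'
#' @inheritParams fit_adc_pair
#' @param series a [dwi_series()] with >= 2 distinct b-values.
#' @return an `adc_map` (see [fit_adc_pair()]).
#' @export
fit_adc_multib <- function(series,
                           negative_policy = c("retain", "clip", "invalidate")) {
  stopifnot(inherits(series, "dwi_series"))
  negative_policy <- match.arg(negative_policy)
  b <- series$b_values
  if (length(unique(b)) < 2L) stop("need at least 2 distinct b-values")
  shp <- dim(series$volumes[[1]])

  sig <- vapply(series$volumes, as.vector, numeric(prod(shp)))  # nvox x nb
  valid_v <- rowSums(!is.finite(sig) | sig <= 0) == 0L

  values_v <- rep(NA_real_, nrow(sig))
  if (any(valid_v)) {
    logs <- log(sig[valid_v, , drop = FALSE])
    bc <- b - mean(b)
    # OLS slope per voxel: sum(bc * logS) / sum(bc^2); ADC = -slope
    values_v[valid_v] <- -(logs %*% bc) / sum(bc^2)
  }
  values <- array(values_v, shp)
  valid <- array(valid_v, shp)
  res <- .apply_negative_policy(values, valid, negative_policy)
  .adc_map(res$values, res$valid, series$voxel_spacing, res$n_negative)
}

#' Write an ADC map as NIfTI (values + validity mask)
#'
#' @param adc an `adc_map`.
#' @param path output `.nii`/`.nii.gz` for the values (float32, mm^2/s);
#'   invalid voxels are written as 0 and flagged 0 in the companion mask
#'   `<path basename>_valid.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_adc_map <- function(adc, path) {
  stopifnot(inherits(adc, "adc_map"))
  vals <- adc$values
  vals[!adc$valid] <- 0
  write_nifti(vals, path, spacing = adc$voxel_spacing,
              datatype = "float32", description = "ADC mm^2/s")
  mask_path <- sub("(\\.nii(\\.gz)?)$", "_valid\\1", path)
  write_nifti(adc$valid, mask_path, spacing = adc$voxel_spacing,
              datatype = "uint8", description = "ADC validity")
  invisible(path)
}
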