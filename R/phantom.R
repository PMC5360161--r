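#' @importFrom stats rnorm rlnorm qnorm quantile median sd var kmeans dnorm
#'   pt qf pf aggregate
NULL

#' Tumor compartment specification
#'
#' Describes one ellipsoidal compartment of the digital phantom and the
#' parametric distribution its voxel-wise true ADC values are drawn from.
#' The viable compartment uses a log-normal law (strictly positive, positively
#' skewed and kurtotic, as observed pretreatment in nodal tumors); the
#' cystic/necrotic compartment uses a zero-truncated normal at a higher ADC
#' level, which makes the whole-GTV histogram bimodal when both are present.
#'
#' @param label `"viable"` or `"cystic"`.
#' @param adc_family `"lognormal"` (parameters `median`, `sdlog`) or
#'   `"truncnormal"` (parameters `mean`, `sd`). ADC units are mm^2/s.
#' @param adc_params named list of distribution parameters.
#' @param center ellipsoid center in voxel coordinates (length 3, 1-based).
#' @param semi_axes ellipsoid semi-axes in voxels (length 3, each >= 1).
#' @return a `compartment_spec` object.
#' @export
compartment_spec <- function(label = c("viable", "cystic"),
                             adc_family = c("lognormal", "truncnormal"),
                             adc_params, center, semi_axes) {
  label <- match.arg(label)
  adc_family <- match.arg(adc_family)
  stopifnot(length(center) == 3L, length(semi_axes) == 3L)
  if (any(semi_axes < 1)) stop("compartment semi-axes must be >= 1 voxel")
  need <- if (adc_family == "lognormal") c("median", "sdlog") else c("mean", "sd")
  if (!all(need %in% names(adc_params)))
    stop("adc_params for ", adc_family, " needs: ", paste(need, collapse = ", "))
  if (adc_family == "lognormal" && adc_params$median <= 0)
    stop("lognormal median must be > 0")
  if (adc_family == "truncnormal" && adc_params$mean <= 0)
    stop("truncnormal mean must be > 0")
  structure(list(label = label, adc_family = adc_family,
                 adc_params = adc_params,
                 center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes)),
            class = "compartment_spec")
}

#' Weekly trajectory specification
#'
#' Multiplicative weekly schedules applied to the phantom: the viable
#' compartment's ADC scale, the GTV volume (applied to semi-axes as the cube
#' root), and the cystic compartment's size (0 removes it for that week).
#' Week 0 is the pretreatment baseline and all its multipliers must be 1.
#'
#' Defaults follow the population trend reported for nodal tumors under
#' chemoradiotherapy: median ADC +14/25/41/42/45/58 percent and volume
#' -8/10/16/22/40/42 percent over weeks 1-6.
#'
#' @param weeks strictly increasing integer week indices starting at 0.
#' @param adc_median_multipliers per-week factor on viable ADC scale (> 0).
#' @param volume_multipliers per-week factor on GTV volume (> 0).
#' @param cystic_schedule per-week size factor for the cystic compartment
#'   (>= 0; 0 means absent that week).
#' @return a `trajectory_spec` object.
#' @export
trajectory_spec <- function(weeks = 0:6,
                            adc_median_multipliers = c(1, 1.14, 1.25, 1.41, 1.42, 1.45, 1.58),
                            volume_multipliers = c(1, 0.92, 0.90, 0.84, 0.78, 0.60, 0.58),
                            cystic_schedule = rep(1, length(weeks))) {
  n <- length(weeks)
  stopifnot(length(adc_median_multipliers) == n,
            length(volume_multipliers) == n,
            length(cystic_schedule) == n)
  if (any(diff(weeks) <= 0)) stop("week indices must be strictly increasing")
  if (weeks[1] != 0) stop("trajectory must start at week 0 (pretreatment)")
  if (any(adc_median_multipliers <= 0) || any(volume_multipliers <= 0))
    stop("ADC and volume multipliers must be > 0")
  if (any(cystic_schedule < 0)) stop("cystic_schedule must be >= 0")
  if (adc_median_multipliers[1] != 1 || volume_multipliers[1] != 1)
    stop("week-0 multipliers must equal 1")
  structure(list(weeks = as.integer(weeks),
                 adc_median_multipliers = adc_median_multipliers,
                 volume_multipliers = volume_multipliers,
                 cystic_schedule = cystic_schedule),
            class = "trajectory_spec")
}

#' Digital phantom specification
#'
#' Full description of a seeded weekly DWI phantom: grid, acquisition
#' (b-values), signal levels, Rician noise scale, compartments, and trajectory.
#' Defaults mirror the acquisition the pipeline targets: b = 0 and 800 s/mm^2,
#' 1.7 x 1.7 x 5 mm voxels, 28 slices, viable median ADC 1.19e-3 mm^2/s and a
#' cystic level of 2.4e-3 mm^2/s.
#'
#' @param grid_shape integer length-3 voxel grid dimensions.
#' @param voxel_spacing_mm voxel spacing, mm.
#' @param b_values diffusion weightings, s/mm^2; must contain 0 and at least
#'   one positive value.
#' @param s0_tissue,s0_background baseline b = 0 signal (arbitrary units).
#' @param background_adc ADC assigned to non-tumor voxels, mm^2/s.
#' @param noise_sigma Rician noise scale, signal units (>= 0).
#' @param compartments list of [compartment_spec()] (at most one per label).
#' @param trajectory a [trajectory_spec()].
#' @param seed integer seed driving every random draw.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 28L),
                         voxel_spacing_mm = c(1.7, 1.7, 5),
                         b_values = c(0, 800),
                         s0_tissue = 1000,
                         s0_background = 60,
                         background_adc = 0.8e-3,
                         noise_sigma = 15,
                         compartments = default_compartments(grid_shape),
                         trajectory = trajectory_spec(),
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            length(voxel_spacing_mm) == 3L, all(voxel_spacing_mm > 0))
  b_values <- sort(unique(as.numeric(b_values)))
  if (length(b_values) < 2L) stop("need at least 2 distinct b-values")
  if (b_values[1] != 0) stop("b-values must include 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  labels <- vapply(compartments, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("at most one compartment per label; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (!"viable" %in% labels) stop("phantom requires a viable compartment")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 b_values = b_values,
                 s0_tissue = s0_tissue,
                 s0_background = s0_background,
                 background_adc = background_adc,
                 noise_sigma = noise_sigma,
                 compartments = compartments,
                 trajectory = trajectory,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default two-compartment geometry for a grid
#'
#' A viable ellipsoid in the grid center with a smaller cystic ellipsoid
#' offset into it (cystic wins where they overlap, matching the subtraction
#' construction viable = GTV minus cystic).
#'
#' @param grid_shape integer length-3 grid dimensions.
#' @param cystic include a cystic/necrotic compartment?
#' @return list of [compartment_spec()].
#' @export
default_compartments <- function(grid_shape = c(64L, 64L, 28L), cystic = TRUE) {
  ctr <- (grid_shape + 1) / 2
  ax <- pmax(1, round(grid_shape * c(0.18, 0.18, 0.22)))
  out <- list(compartment_spec(
    "viable", "lognormal",
    list(median = 1.19e-3, sdlog = 0.15),
    center = ctr, semi_axes = ax))
  if (cystic) {
    out <- c(out, list(compartment_spec(
      "cystic", "truncnormal",
      list(mean = 2.4e-3, sd = 0.3e-3),
      center = ctr + c(round(ax[1] / 2), 0, 0),
      semi_axes = pmax(1, round(ax * 0.45)))))
  }
  out
}

#' Apply Rician noise to a magnitude signal
#'
#' Returns `sqrt((signal + g1 * sigma)^2 + (g2 * sigma)^2)` with `g1`, `g2`
#' independent standard normal draws — the magnitude of a complex Gaussian
#' perturbation, the standard MR magnitude noise model. `sigma = 0` returns
#' the input unchanged (no RNG consumed).
#'
#' @param signal non-negative numeric array or vector.
#' @param sigma noise scale in signal units (>= 0).
#' @return noisy signal, same shape as `signal`.
#' @export
rician_noise <- function(signal, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(signal)
  n <- length(signal)
  out <- sqrt((signal + rnorm(n) * sigma)^2 + (rnorm(n) * sigma)^2)
  if (is.array(signal)) dim(out) <- dim(signal)
  out
}

.ellipsoid_mask <- function(grid_shape, center, semi_axes) {
  ix <- seq_len(grid_shape[1]); iy <- seq_len(grid_shape[2]); iz <- seq_len(grid_shape[3])
  dx2 <- ((ix - center[1]) / semi_axes[1])^2
  dy2 <- ((iy - center[2]) / semi_axes[2])^2
  dz2 <- ((iz - center[3]) / semi_axes[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

.lognormal_true_stats <- function(median, sdlog)
  list(median = median, mean = median * exp(sdlog^2 / 2))

.truncnormal_true_stats <- function(mean, sd) {
  # zero-truncated normal; alpha = -mean/sd
  a <- -mean / sd
  z <- 1 - stats::pnorm(a)
  tmean <- mean + sd * stats::dnorm(a) / z
  tmed <- mean + sd * stats::qnorm((stats::pnorm(a) + 1) / 2)
  list(median = tmed, mean = tmean)
}

.draw_compartment_adc <- function(comp, n, scale = 1) {
  p <- comp$adc_params
  if (comp$adc_family == "lognormal") {
    scale * rlnorm(n, meanlog = log(p$median), sdlog = p$sdlog)
  } else {
    # rejection-free truncation: resample the (rare) non-positive draws
    x <- rnorm(n, p$mean, p$sd)
    while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), p$mean, p$sd)
    scale * x
  }
}

#' Generate a seeded weekly digital phantom
#'
#' For each week of the trajectory, builds the GTV / cystic / viable masks
#' from the (volume-scaled) ellipsoid geometry, draws a true ADC per voxel
#' from the compartment distributions (viable ADC scale multiplied by the
#' week's schedule factor), synthesizes the noiseless diffusion signal
#' `S(b) = S0 * exp(-b * ADC)` at every b-value, and corrupts it with Rician
#' noise. Where viable and cystic geometry overlap, the cystic compartment
#' wins, so viable = GTV AND NOT cystic by construction.
#'
#' All randomness flows from `spec$seed`; identical specs give bit-identical
#' output. Masks and the ground-truth table are deterministic functions of
#' the geometry and trajectory, so they are identical across seeds.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_output` list with per-week elements `weeks` (each with
#'   `series` ([dwi_series()]), `masks` (gtv/cystic/viable [roi_mask()]), and
#'   `true_adc` array), plus `ground_truth`: a data.frame with columns
#'   `week`, `compartment`, `true_median_adc`, `true_mean_adc`, `volume_cm3`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  tr <- spec$trajectory
  comps <- spec$compartments
  labels <- vapply(comps, `[[`, "", "label")
  viable_comp <- comps[[which(labels == "viable")]]
  cystic_comp <- if ("cystic" %in% labels) comps[[which(labels == "cystic")]] else NULL
  vox_cm3 <- prod(spec$voxel_spacing_mm) / 1000
  days_per_week <- 7L

  weeks_out <- vector("list", length(tr$weeks))
  gt_rows <- list()

  for (i in seq_along(tr$weeks)) {
    wk <- tr$weeks[i]
    size_fac <- tr$volume_multipliers[i]^(1 / 3)
    adc_fac <- tr$adc_median_multipliers[i]

    gtv_geom <- .ellipsoid_mask(spec$grid_shape, viable_comp$center,
                                pmax(1, viable_comp$semi_axes * size_fac))
    cys_fac <- if (is.null(cystic_comp)) 0 else tr$cystic_schedule[i]
    if (cys_fac > 0) {
      cys_geom <- .ellipsoid_mask(spec$grid_shape, cystic_comp$center,
                                  pmax(1, cystic_comp$semi_axes * cys_fac * size_fac))
    } else {
      cys_geom <- array(FALSE, spec$grid_shape)
    }
    gtv <- gtv_geom | cys_geom
    cystic <- cys_geom
    viable <- gtv & !cystic

    true_adc <- array(spec$background_adc, spec$grid_shape)
    n_v <- sum(viable)
    if (n_v > 0) true_adc[viable] <- .draw_compartment_adc(viable_comp, n_v, adc_fac)
    n_c <- sum(cystic)
    if (n_c > 0) true_adc[cystic] <- .draw_compartment_adc(cystic_comp, n_c)

    s0 <- array(spec$s0_background, spec$grid_shape)
    s0[gtv] <- spec$s0_tissue
    vols <- lapply(spec$b_values, function(b) {
      rician_noise(s0 * exp(-b * true_adc), spec$noise_sigma)
    })

    # weekly scans land ~day 7w-1 (6, 13, ..., 41); pretreatment ~2 weeks before RT
    days <- if (wk == 0L) -15L else wk * days_per_week - 1L
    series <- dwi_series(spec$b_values, vols, spec$voxel_spacing_mm,
                         week = wk, days_from_rt_start = days)
    masks <- list(
      gtv = roi_mask(gtv, "gtv", spec$voxel_spacing_mm),
      cystic = roi_mask(cystic, "cystic_necrotic", spec$voxel_spacing_mm),
      viable = roi_mask(viable, "viable", spec$voxel_spacing_mm))

    vstats <- .lognormal_true_stats(viable_comp$adc_params$median * adc_fac,
                                    viable_comp$adc_params$sdlog)
    gt_rows[[length(gt_rows) + 1L]] <- data.frame(
      week = wk, compartment = "viable",
      true_median_adc = vstats$median, true_mean_adc = vstats$mean,
      volume_cm3 = n_v * vox_cm3)
    if (!is.null(cystic_comp)) {
      cstats <- .truncnormal_true_stats(cystic_comp$adc_params$mean,
                                        cystic_comp$adc_params$sd)
      gt_rows[[length(gt_rows) + 1L]] <- data.frame(
        week = wk, compartment = "cystic",
        true_median_adc = cstats$median, true_mean_adc = cstats$mean,
        volume_cm3 = n_c * vox_cm3)
    }
    gt_rows[[length(gt_rows) + 1L]] <- data.frame(
      week = wk, compartment = "gtv",
      true_median_adc = NA_real_, true_mean_adc = NA_real_,
      volume_cm3 = sum(gtv) * vox_cm3)

    weeks_out[[i]] <- list(week = wk, series = series, masks = masks,
                           true_adc = true_adc)
  }

  structure(list(weeks = weeks_out,
                 ground_truth = do.call(rbind, gt_rows),
                 spec = spec),
            class = "phantom_output")
}

#' Write a phantom to disk (NIfTI volumes + ground-truth CSV)
#'
#' One NIfTI per b-value per week (`week<w>_b<b>.nii.gz`, float32), uint8
#' masks (`week<w>_mask_<label>.nii.gz`), and `ground_truth.csv`.
#'
#' @param phantom a `phantom_output` from [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom_output"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- phantom$spec$voxel_spacing_mm
  for (w in phantom$weeks) {
    for (j in seq_along(w$series$b_values)) {
      b <- w$series$b_values[j]
      write_nifti(w$series$volumes[[j]],
                  file.path(dir, sprintf("week%d_b%g.nii.gz", w$week, b)),
                  spacing = sp, datatype = "float32",
                  description = sprintf("DWI b=%g week=%d", b, w$week))
    }
    for (lab in names(w$masks)) {
      write_nifti(w$masks[[lab]]$mask,
                  file.path(dir, sprintf("week%d_mask_%s.nii.gz", w$week, lab)),
                  spacing = sp, datatype = "uint8",
                  description = sprintf("mask %s week=%d", lab, w$week))
    }
  }
  utils::write.csv(phantom$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a phantom specification from YAML or JSON
#'
#' The config mirrors [phantom_spec()] field for field; `compartments` is a
#' list of objects with `label`, `adc_family`, `adc_params`, `center`,
#' `semi_axes`, and `trajectory` mirrors [trajectory_spec()]. Missing fields
#' fall back to package defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @param seed optional seed overriding the config's.
#' @return a [phantom_spec()].
#' @export
read_phantom_config <- function(path, seed = NULL) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  for (f in c("grid_shape", "voxel_spacing_mm", "b_values", "s0_tissue",
              "s0_background", "background_adc", "noise_sigma", "seed"))
    if (!is.null(cfg[[f]])) args[[f]] <- unlist(cfg[[f]])
  if (!is.null(cfg$compartments)) {
    args$compartments <- lapply(cfg$compartments, function(cc)
      compartment_spec(cc$label, cc$adc_family, as.list(cc$adc_params),
                       unlist(cc$center), unlist(cc$semi_axes)))
  } else if (!is.null(args$grid_shape)) {
    args$compartments <- default_compartments(args$grid_shape)
  }
  if (!is.null(cfg$trajectory)) {
    tcfg <- cfg$trajectory
    args$trajectory <- do.call(trajectory_spec,
                               lapply(tcfg, unlist)[intersect(names(tcfg),
                                 c("weeks", "adc_median_multipliers",
                                   "volume_multipliers", "cystic_schedule"))])
  }
  if (!is.null(seed)) args$seed <- as.integer(seed)
  do.call(phantom_spec, args)
}
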