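#' First-order histogram summary of ADC values
#'
#' Computes the standard first-order descriptors of an ROI's ADC
#' distribution: count, mean, median, standard deviation (n-1 denominator),
#' the 10/25/75/90 percentiles (linear interpolation between order
#' statistics, i.e. `quantile` type 7), skewness (Fisher-Pearson standardized
#' third moment g1, population-moment version) and excess kurtosis
#' (`m4/m2^2 - 3`; 0 for a normal distribution). Skewness and kurtosis
#' require at least 3 values and nonzero spread; degenerate inputs yield
#' `NA` with `shape_defined = FALSE` rather than a number.
#'
#' @param values numeric vector of ADC values (mm^2/s), length >= 1.
#' @param volume_cm3 optional ROI volume carried through for reporting.
#' @return a `histogram_summary`: `n_voxels`, `mean`, `median`, `sd`, `p10`,
#'   `p25`, `p75`, `p90`, `skewness`, `kurtosis`, `shape_defined`,
#'   `volume_cm3`.
#' @export
summarize_histogram <- function(values, volume_cm3 = NA_real_) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("cannot summarize an empty value list")
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite; filter invalid voxels first")
  n <- length(values)
  m <- mean(values)
  s <- if (n >= 2L) sd(values) else 0
  q <- unname(quantile(values, c(0.10, 0.25, 0.75, 0.90), type = 7))

  m2 <- mean((values - m)^2)   # population central moments for g1/g2
  shape_defined <- n >= 3L && m2 > 0
  if (shape_defined) {
    skew <- mean((values - m)^3) / m2^1.5
    kurt <- mean((values - m)^4) / m2^2 - 3
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }

  structure(list(n_voxels = n, mean = m, median = median(values), sd = s,
                 p10 = q[1], p25 = q[2], p75 = q[3], p90 = q[4],
                 skewness = skew, kurtosis = kurt,
                 shape_defined = shape_defined,
                 volume_cm3 = volume_cm3),
            class = "histogram_summary")
}

#' @export
print.histogram_summary <- function(x, ...) {
  cat(sprintf(paste0("<histogram_summary> n=%d  mean=%.4g  median=%.4g  sd=%.3g\n",
                     "  p10/p25/p75/p90 = %.4g/%.4g/%.4g/%.4g  skew=%.3g  exkurt=%.3g\n"),
              x$n_voxels, x$mean, x$median, x$sd,
              x$p10, x$p25, x$p75, x$p90,
              if (x$shape_defined) x$skewness else NA,
              if (x$shape_defined) x$kurtosis else NA))
  invisible(x)
}

#' Convert a histogram summary to a one-row data.frame
#'
#' @param x a `histogram_summary`.
#' @param ... unused.
#' @return one-row data.frame of the summary fields.
#' @export
as.data.frame.histogram_summary <- function(x, ...) {
  data.frame(n_voxels = x$n_voxels, mean = x$mean, median = x$median,
             sd = x$sd, p10 = x$p10, p25 = x$p25, p75 = x$p75, p90 = x$p90,
             skewness = x$skewness, kurtosis = x$kurtosis,
             volume_cm3 = x$volume_cm3)
}

# One-dimensional two-component Gaussian mixture via EM, k-means initialised.
# Returns parameters ordered by ascending mean plus the maximized loglik.
.em_gmm2 <- function(x, max_iter = 300L, tol = 1e-10) {
  n <- length(x)
  km <- kmeans(x, centers = 2L, nstart = 5L)
  mu <- as.numeric(km$centers)
  grp <- km$cluster
  sdev <- vapply(1:2, function(k) {
    s <- sd(x[grp == k])
    if (!is.finite(s) || s <= 0) sd(x) / 10 else s
  }, numeric(1))
  w <- tabulate(grp, 2L) / n
  sd_floor <- max(sd(x), .Machine$double.eps) * 1e-6

  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sdev[1])
    d2 <- w[2] * dnorm(x, mu[2], sdev[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r2 <- d2 / tot
    r1 <- 1 - r2
    w <- c(mean(r1), mean(r2))
    mu <- c(sum(r1 * x) / sum(r1), sum(r2 * x) / sum(r2))
    sdev <- c(sqrt(sum(r1 * (x - mu[1])^2) / sum(r1)),
              sqrt(sum(r2 * (x - mu[2])^2) / sum(r2)))
    sdev <- pmax(sdev, sd_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  ord <- order(mu)
  post2 <- (w[2] * dnorm(x, mu[2], sdev[2])) /
    (w[1] * dnorm(x, mu[1], sdev[1]) + w[2] * dnorm(x, mu[2], sdev[2]))
  post_hi <- if (ord[1] == 1L) post2 else 1 - post2
  list(means = mu[ord], sds = sdev[ord], weights = w[ord],
       posterior_high = post_hi, loglik = ll)
}

#' Two-component separation of an ADC histogram
#'
#' Advisory helper for the bimodality that a persistent cystic/necrotic
#' component produces in a whole-GTV ADC histogram. Fits a two-component
#' Gaussian mixture (seeded EM with k-means initialisation) and compares it
#' to a single Gaussian by BIC. The verdict is "bimodal" only when the
#' two-component model is preferred by BIC AND the component means are
#' further apart than the pooled within-component standard deviation —
#' preventing two heavily overlapping components from being called separate
#' modes.
#'
#' This is a decision aid: the pipeline never subtracts a component
#' automatically on the strength of this verdict alone.
#'
#' @param values numeric ADC values, length >= 50.
#' @param seed integer seed making k-means initialisation deterministic.
#' @return a `component_split`: `means`, `sds`, `weights` (ascending-mean
#'   order), `assignment` (per-value component, 1 = low mode), `bimodal`
#'   (verdict), `bic_1`, `bic_2`, `separation` (mean gap / pooled sd).
#' @export
split_components <- function(values, seed = 1L) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 50L)
    stop("need at least 50 values for mixture separation; ",
         "review the histogram manually")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  # 1-component reference: MLE Gaussian
  mu0 <- mean(x); s0 <- sqrt(mean((x - mu0)^2))
  ll1 <- sum(dnorm(x, mu0, s0, log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)

  if (sd(x) == 0) {
    # all values identical: indistinguishable components, trivially unimodal
    return(structure(list(means = c(mu0, mu0), sds = c(0, 0),
                          weights = c(0.5, 0.5),
                          assignment = rep(1L, n), bimodal = FALSE,
                          bic_1 = bic1, bic_2 = Inf, separation = 0),
                     class = "component_split"))
  }

  fit <- .em_gmm2(x)
  bic2 <- -2 * fit$loglik + 5 * log(n)
  pooled_sd <- sqrt(sum(fit$weights * fit$sds^2))
  separation <- (fit$means[2] - fit$means[1]) / pooled_sd
  bimodal <- (bic2 < bic1) && (separation > 1)

  structure(list(means = fit$means, sds = fit$sds, weights = fit$weights,
                 assignment = ifelse(fit$posterior_high > 0.5, 2L, 1L),
                 bimodal = bimodal, bic_1 = bic1, bic_2 = bic2,
                 separation = separation),
            class = "component_split")
}

#' @export
print.component_split <- function(x, ...) {
  cat(sprintf("<component_split> verdict: %s\n",
              if (x$bimodal) "BIMODAL" else "unimodal"))
  cat(sprintf("  means %.4g / %.4g  sds %.3g / %.3g  weights %.2f / %.2f\n",
              x$means[1], x$means[2], x$sds[1], x$sds[2],
              x$weights[1], x$weights[2]))
  cat(sprintf("  BIC 1-comp %.1f vs 2-comp %.1f, separation %.2f pooled sd\n",
              x$bic_1, x$bic_2, x$separation))
  invisible(x)
}

#' Full ROI analysis for one timepoint
#'
#' Convenience wrapper chaining the per-timepoint steps: optional viable
#' isolation ([subtract_rois()]), value extraction, histogram summary of the
#' viable tumor ADC, and whole-GTV volume (volume statistics always use the
#' entire GTV, cystic parts included, per clinical volumetric practice).
#'
#' @param adc an `adc_map`.
#' @param gtv `roi_mask` of the whole GTV.
#' @param cystic optional `roi_mask` of the cystic/necrotic component.
#' @param week week index carried into the output.
#' @return list with `summary` ([summarize_histogram()] of viable ADC),
#'   `gtv_volume_cm3`, `viable` mask, `week`.
#' @export
analyze_timepoint <- function(adc, gtv, cystic = NULL, week = NA_integer_) {
  viable <- if (is.null(cystic) || !any(cystic$mask)) {
    roi_mask(gtv$mask, "viable", gtv$voxel_spacing)
  } else {
    subtract_rois(gtv, cystic)
  }
  vals <- extract_values(adc, viable)
  list(summary = summarize_histogram(vals, volume_cm3 = compute_volume(viable)),
       gtv_volume_cm3 = compute_volume(gtv),
       viable = viable,
       week = week)
}
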