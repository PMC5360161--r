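mask_of <- function(idx, shp = c(10L, 10L, 3L)) {
  m <- array(FALSE, shp)
  m[idx] <- TRUE
  m
}

test_that("subtract_rois implements GTV AND NOT cystic with warnings", {
  shp <- c(10L, 10L, 3L)
  sp <- c(1, 1, 1)
  gtv <- roi_mask(mask_of(1:100, shp), "gtv", sp)

  # 30 cystic voxels fully inside -> 70 viable
  cys <- roi_mask(mask_of(1:30, shp), "cystic_necrotic", sp)
  v <- subtract_rois(gtv, cys)
  expect_identical(sum(v$mask), 70L)
  expect_identical(v$label, "viable")
  expect_identical(attr(v, "n_outside"), 0L)

  # empty cystic -> viable == gtv
  v2 <- subtract_rois(gtv, roi_mask(mask_of(integer(0), shp),
                                    "cystic_necrotic", sp))
  expect_identical(v2$mask, gtv$mask)

  # 30 cystic, 10 outside the GTV -> viable 80, warned count 10
  cys3 <- roi_mask(mask_of(c(81:100, 101:110), shp), "cystic_necrotic", sp)
  expect_warning(v3 <- subtract_rois(gtv, cys3), "10 cystic voxel")
  expect_identical(sum(v3$mask), 80L)
  expect_identical(attr(v3, "n_outside"), 10L)

  # full overlap -> empty viable is an error naming the GTV ROI
  expect_error(suppressWarnings(
    subtract_rois(gtv, roi_mask(mask_of(1:120, shp), "cystic_necrotic", sp))),
    "gtv")
  # grid mismatch
  expect_error(subtract_rois(gtv, roi_mask(array(FALSE, c(9, 10, 3)),
                                           "cystic_necrotic", sp)),
               "grid mismatch")
})

test_that("compute_volume converts voxel counts to cm^3", {
  shp <- c(10L, 10L, 10L)
  m <- roi_mask(mask_of(1:1000, shp), "gtv", c(2, 2, 5))
  expect_identical(compute_volume(m), 20)
  one <- roi_mask(mask_of(1L, shp), "gtv", c(1, 1, 1))
  expect_identical(compute_volume(one), 0.001)
  expect_warning(v <- compute_volume(roi_mask(mask_of(integer(0), shp),
                                              "gtv", c(1, 1, 1))),
                 "empty")
  expect_identical(v, 0)
})

test_that("extract_values respects validity, order, and counts", {
  shp <- c(10L, 10L, 3L)
  vals <- array(seq_len(prod(shp)) * 1e-5, shp)
  valid <- array(TRUE, shp)
  roi <- roi_mask(mask_of(11:80, shp), "viable", c(1, 1, 1))

  adc <- adctrack:::.adc_map(vals, valid, c(1, 1, 1), 0L)
  x <- extract_values(adc, roi)
  expect_length(x, 70L)
  expect_identical(attr(x, "n_excluded"), 0L)
  # deterministic column-major order
  expect_identical(as.numeric(x), as.numeric(vals[11:80]))

  valid2 <- valid; valid2[c(11, 12, 13, 14, 15)] <- FALSE
  adc2 <- adctrack:::.adc_map(vals, valid2, c(1, 1, 1), 0L)
  expect_message(x2 <- extract_values(adc2, roi), "5 invalid")
  expect_length(x2, 65L)

  const <- adctrack:::.adc_map(array(1.2e-3, shp), valid, c(1, 1, 1), 0L)
  expect_true(all(extract_values(const, roi) == 1.2e-3))

  none <- adctrack:::.adc_map(vals, array(FALSE, shp), c(1, 1, 1), 0L)
  expect_error(extract_values(none, roi), "no valid")
  expect_error(extract_values(adc, roi_mask(mask_of(integer(0), shp),
                                            "viable", c(1, 1, 1))),
               "empty")
})

test_that("summarize_histogram matches hand-checked values", {
  s <- summarize_histogram(c(1, 2, 3, 4, 5))
  expect_identical(s$mean, 3)
  expect_identical(s$median, 3)
  expect_identical(s$p25, 2)
  expect_identical(s$p75, 4)
  expect_equal(s$sd, sqrt(2.5))
  expect_identical(s$n_voxels, 5L)

  expect_error(summarize_histogram(numeric(0)), "empty")
  expect_error(summarize_histogram(c(1, NA, 3)), "finite")

  # degenerate spread: shape statistics flagged undefined
  const <- summarize_histogram(rep(2e-3, 10))
  expect_identical(const$sd, 0)
  expect_false(const$shape_defined)
  expect_true(is.na(const$skewness) && is.na(const$kurtosis))
})

test_that("summary fields equal brute-force oracles on random lists", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(3:2000, 1)
    x <- switch(1 + i %% 3,
                rnorm(n, 1.2e-3, 2e-4),
                rlnorm(n, log(1e-3), 0.3),
                runif(n, 0.5e-3, 3e-3))
    s <- summarize_histogram(x)
    o <- bf_summary(x)
    for (f in c("mean", "median", "sd", "p10", "p25", "p75", "p90")) {
      expect_lt(rel_err(s[[f]], o[[f]]), 1e-10)
    }
    for (f in c("skewness", "kurtosis")) {
      expect_lt(shape_err(s[[f]], o[[f]]), 1e-10)
    }
    expect_true(s$p10 <= s$p25 && s$p25 <= s$median &&
                  s$median <= s$p75 && s$p75 <= s$p90)
  }
})

test_that("large normal samples have near-zero skewness and excess kurtosis", {
  set.seed(32)
  n <- 5e4
  s <- summarize_histogram(rnorm(n, 1.2e-3, 2e-4))
  expect_lt(abs(s$skewness), 3 * sqrt(6 / n))
  expect_lt(abs(s$kurtosis), 3 * sqrt(24 / n))
})

test_that("volume additivity and disjointness hold on random mask pairs", {
  set.seed(33)
  shp <- c(12L, 12L, 5L)
  sp <- c(1.7, 1.7, 5)
  for (i in 1:10) {
    g <- array(runif(prod(shp)) > 0.5, shp)
    if (!any(g)) g[1] <- TRUE
    c_ <- array(runif(prod(shp)) > 0.8, shp) & g  # keep viable non-empty
    c_[which(g)[1]] <- FALSE
    gtv <- roi_mask(g, "gtv", sp)
    cys <- roi_mask(c_, "cystic_necrotic", sp)
    v <- suppressWarnings(subtract_rois(gtv, cys))
    # additivity is exact in voxel counts; volumes agree to machine precision
    expect_identical(sum(g), sum(v$mask) + sum(g & c_))
    expect_equal(compute_volume(gtv),
                 suppressWarnings(compute_volume(v) +
                   compute_volume(roi_mask(g & c_, "cystic_necrotic", sp))),
                 tolerance = 1e-12)
    expect_false(any(v$mask & c_))
    expect_true(all(!v$mask | g))
  }
})

test_that("split_components separates a clear mixture and not a unimodal sample", {
  set.seed(34)
  n <- 5000
  k <- rbinom(n, 1, 0.3)
  x <- ifelse(k == 1, rnorm(n, 2.4e-3, 0.3e-3), rnorm(n, 1.1e-3, 0.15e-3))
  sp <- split_components(x, seed = 1)
  expect_true(sp$bimodal)
  expect_lt(abs(sp$means[1] - 1.1e-3), 0.05e-3)
  expect_lt(abs(sp$means[2] - 2.4e-3), 0.05e-3)
  expect_equal(sum(sp$weights), 1, tolerance = 1e-9)
  expect_true(all(sp$weights >= 0))
  expect_lte(sp$means[1], sp$means[2])
  # assignment tracks the mode: high-ADC values in component 2
  expect_gt(mean(sp$assignment[x > 2e-3] == 2L), 0.95)

  uni <- split_components(rnorm(n, 1.5e-3, 0.3e-3), seed = 1)
  expect_false(uni$bimodal)

  # two identical components are indistinguishable -> unimodal
  same <- split_components(rep(c(1e-3, 1e-3), 100), seed = 1)
  expect_false(same$bimodal)

  expect_error(split_components(rnorm(30)), "at least 50")

  # determinism under a fixed seed
  sp2 <- split_components(x, seed = 1)
  expect_identical(sp$means, sp2$means)
  expect_identical(sp$bimodal, sp2$bimodal)
})

test_that("viable-only phantom summary tracks the true weekly median; whole GTV does not", {
  spec <- phantom_spec(seed = 40)  # package defaults: the stated world
  ph <- generate_phantom(spec)
  gt <- ph$ground_truth
  err_v <- err_g <- numeric(length(ph$weeks))
  for (i in seq_along(ph$weeks)) {
    w <- ph$weeks[[i]]
    adc <- suppressMessages(fit_adc_pair(w$series))
    true_med <- gt$true_median_adc[gt$week == w$week & gt$compartment == "viable"]
    med_v <- summarize_histogram(
      suppressMessages(extract_values(adc, w$masks$viable)))$median
    med_g <- summarize_histogram(
      suppressMessages(extract_values(adc, w$masks$gtv)))$median
    err_v[i] <- rel_err(med_v, true_med)
    err_g[i] <- rel_err(med_g, true_med)
  }
  # viable isolation recovers the truth at every week
  expect_true(all(err_v < 0.02))
  # the contaminated whole-GTV median is always worse and breaks the band
  # in at least one week (the default cystic load is ~9% of GTV volume)
  expect_true(all(err_g > err_v))
  expect_gt(max(err_g), 0.02)

  # with a prominent cystic node (~30% of GTV volume, as in persistent
  # necrotic nodes) the whole-GTV median fails the 2% recovery every week
  grid <- c(64L, 64L, 28L)
  ctr <- (grid + 1) / 2
  ax <- pmax(1, round(grid * c(0.18, 0.18, 0.22)))
  comps <- list(
    compartment_spec("viable", "lognormal",
                     list(median = 1.19e-3, sdlog = 0.15), ctr, ax),
    compartment_spec("cystic", "truncnormal",
                     list(mean = 2.4e-3, sd = 0.3e-3),
                     ctr + c(round(ax[1] / 2), 0, 0),
                     pmax(1, round(ax * 0.67))))
  ph2 <- generate_phantom(phantom_spec(compartments = comps, seed = 40))
  gt2 <- ph2$ground_truth
  for (w in ph2$weeks) {
    adc <- suppressMessages(fit_adc_pair(w$series))
    true_med <- gt2$true_median_adc[gt2$week == w$week &
                                      gt2$compartment == "viable"]
    med_g <- summarize_histogram(
      suppressMessages(extract_values(adc, w$masks$gtv)))$median
    expect_gt(rel_err(med_g, true_med), 0.02)
  }
})
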