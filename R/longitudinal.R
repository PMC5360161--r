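#' One timepoint of a longitudinal series
#'
#' @param week week index; 0 is the pretreatment baseline.
#' @param adc_summary [summarize_histogram()] of the viable-tumor ADC.
#' @param gtv_volume_cm3 whole-GTV volume (cystic included), cm^3.
#' @param days_from_rt_start optional days metadata (weeks are the alignment
#'   key; days are carried along only).
#' @return a `time_point`.
#' @export
time_point <- function(week, adc_summary, gtv_volume_cm3,
                       days_from_rt_start = NA_integer_) {
  stopifnot(week >= 0, inherits(adc_summary, "histogram_summary"))
  structure(list(week = as.integer(week),
                 days_from_rt_start = days_from_rt_start,
                 adc_summary = adc_summary,
                 gtv_volume_cm3 = gtv_volume_cm3),
            class = "time_point")
}

#' Ordered weekly series for one GTV
#'
#' @param gtv_id identifier for the nodal volume.
#' @param timepoints list of [time_point()]; must contain exactly one week-0
#'   entry and strictly increasing weeks.
#' @return a `longitudinal_series`.
#' @export
longitudinal_series <- function(gtv_id, timepoints) {
  weeks <- vapply(timepoints, `[[`, integer(1), "week")
  if (any(diff(weeks) <= 0)) stop("timepoints must be strictly increasing in week")
  if (sum(weeks == 0L) != 1L)
    stop("series '", gtv_id, "' needs exactly one week-0 (pretreatment) entry")
  structure(list(gtv_id = gtv_id, timepoints = timepoints),
            class = "longitudinal_series")
}

#' @export
print.longitudinal_series <- function(x, ...) {
  cat(sprintf("<longitudinal_series> %s: weeks %s\n", x$gtv_id,
              paste(vapply(x$timepoints, `[[`, integer(1), "week"),
                    collapse = ", ")))
  invisible(x)
}

.metric_value <- function(tp, metric) {
  switch(metric,
         median_adc = tp$adc_summary$median,
         mean_adc = tp$adc_summary$mean,
         sd_adc = tp$adc_summary$sd,
         p10_adc = tp$adc_summary$p10,
         p25_adc = tp$adc_summary$p25,
         p75_adc = tp$adc_summary$p75,
         p90_adc = tp$adc_summary$p90,
         skewness = tp$adc_summary$skewness,
         kurtosis = tp$adc_summary$kurtosis,
         gtv_volume = tp$gtv_volume_cm3,
         stop("unknown metric '", metric, "'"))
}

.series_metric <- function(series, metric) {
  data.frame(week = vapply(series$timepoints, `[[`, integer(1), "week"),
             value = vapply(series$timepoints, .metric_value, numeric(1), metric))
}

#' Absolute and percent change versus the pretreatment baseline
#'
#' For each week `w`, `percent_change = 100 * (value_w - value_0) / value_0`
#' and `absolute_change = value_w - value_0`, where week 0 is the baseline.
#' A 1.58x-baseline value therefore reads as +58%.
#'
#' @param series a [longitudinal_series()].
#' @param metric metric name (`"median_adc"`, `"mean_adc"`, `"gtv_volume"`,
#'   `"sd_adc"`, percentile metrics, `"skewness"`, `"kurtosis"`).
#' @return data.frame: `gtv_id`, `week`, `metric`, `value`,
#'   `absolute_change`, `percent_change` (week-0 row has both changes 0).
#' @export
percent_change <- function(series, metric = "median_adc") {
  stopifnot(inherits(series, "longitudinal_series"))
  df <- .series_metric(series, metric)
  base <- df$value[df$week == 0L]
  if (!is.finite(base) || base == 0)
    stop("baseline (week 0) value of '", metric,
         "' is zero or undefined; percent change is not defined")
  data.frame(gtv_id = series$gtv_id, week = df$week, metric = metric,
             value = df$value,
             absolute_change = df$value - base,
             percent_change = 100 * (df$value - base) / base)
}

#' Label week-over-week intervals as increase / plateau / decrease
#'
#' An interval is a plateau when the week-over-week step, expressed as a
#' percentage of the baseline value, is within `plateau_tol` in magnitude;
#' otherwise the sign of the step decides. The 5% default tolerance is a
#' pragmatic convention of this package, not a literature value.
#'
#' @inheritParams percent_change
#' @param plateau_tol plateau half-width, percent of baseline per week.
#' @return data.frame: `from_week`, `to_week`, `step_pct`, `label`.
#' @export
classify_trend <- function(series, metric = "median_adc", plateau_tol = 5) {
  stopifnot(inherits(series, "longitudinal_series"))
  df <- .series_metric(series, metric)
  if (nrow(df) < 2L) stop("need at least 2 timepoints to classify a trend")
  base <- df$value[df$week == 0L]
  if (!is.finite(base) || base == 0) stop("baseline value must be nonzero")
  step_pct <- 100 * diff(df$value) / base
  label <- ifelse(abs(step_pct) <= plateau_tol, "plateau",
                  ifelse(step_pct > 0, "increase", "decrease"))
  data.frame(from_week = df$week[-nrow(df)], to_week = df$week[-1],
             step_pct = step_pct, label = label)
}

#' Early-ADC-change response rule
#'
#' Flags a GTV as a suspected poor responder when the percent change in
#' median viable-tumor ADC at the decision week falls strictly below the
#' threshold. The defaults (threshold 25%, decision week 3) follow the rule
#' that an ADC rise of less than 25% in the early weeks of radiotherapy
#' predicts poor response, with week 3 the typical adaptive-replanning
#' decision point; both are parameters, not constants. If the decision week
#' is missing from the series, the nearest earlier on-treatment week is used
#' and reported.
#'
#' @inheritParams percent_change
#' @param threshold_pct flagging threshold, percent (strict `<`).
#' @param decision_week week at which the rule is evaluated.
#' @return a `response_call`: `label` (`"flagged_poor_response"` or
#'   `"not_flagged"`), `threshold_pct`, `decision_week` (requested),
#'   `week_used`, `observed_pct`.
#' @export
classify_response <- function(series, threshold_pct = 25, decision_week = 3L,
                              metric = "median_adc") {
  stopifnot(inherits(series, "longitudinal_series"))
  pc <- percent_change(series, metric)
  cand <- pc[pc$week > 0L & pc$week <= decision_week, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("no on-treatment timepoint at or before week ", decision_week)
  row <- cand[which.max(cand$week), ]
  if (row$week != decision_week)
    message(sprintf("decision week %d missing; using nearest earlier week %d",
                    decision_week, row$week))
  flagged <- row$percent_change < threshold_pct
  structure(list(label = if (flagged) "flagged_poor_response" else "not_flagged",
                 threshold_pct = threshold_pct,
                 decision_week = as.integer(decision_week),
                 week_used = row$week,
                 observed_pct = row$percent_change,
                 gtv_id = series$gtv_id),
            class = "response_call")
}

#' @export
print.response_call <- function(x, ...) {
  cat(sprintf("<response_call> %s: %s (%.1f%% at week %d; rule: < %g%% at week %d)\n",
              x$gtv_id, x$label, x$observed_pct, x$week_used,
              x$threshold_pct, x$decision_week))
  invisible(x)
}

#' Per-week box-plot statistics across a cohort of series
#'
#' Tukey box-plot summaries per week: median, quartiles (type-7), whiskers
#' extending to the most extreme observation within 1.5 x IQR of the
#' quartiles, and outliers beyond the whiskers. Series missing a week are
#' excluded from that week only (no interpolation).
#'
#' @param series_list list of [longitudinal_series()].
#' @param metric metric name, see [percent_change()].
#' @param value `"raw"` for the metric itself or `"percent_change"` for its
#'   percent change from baseline.
#' @return list with `stats`: data.frame (`week`, `n`, `median`, `p25`,
#'   `p75`, `whisker_low`, `whisker_high`, `n_outliers`) and `outliers`:
#'   data.frame (`week`, `gtv_id`, `value`).
#' @export
cohort_summary <- function(series_list, metric = "median_adc",
                           value = c("raw", "percent_change")) {
  if (length(series_list) == 0L) stop("empty cohort")
  value <- match.arg(value)
  long <- do.call(rbind, lapply(series_list, function(s) {
    pc <- percent_change(s, metric)
    data.frame(gtv_id = pc$gtv_id, week = pc$week,
               value = if (value == "raw") pc$value else pc$percent_change)
  }))
  weeks <- sort(unique(long$week))
  stats_rows <- lapply(weeks, function(w) {
    v <- long$value[long$week == w]
    ids <- long$gtv_id[long$week == w]
    q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    lo_f <- q[1] - 1.5 * iqr; hi_f <- q[3] + 1.5 * iqr
    inside <- v >= lo_f & v <= hi_f
    out_idx <- which(!inside)
    list(stats = data.frame(week = w, n = length(v), median = q[2],
                            p25 = q[1], p75 = q[3],
                            whisker_low = min(v[inside]),
                            whisker_high = max(v[inside]),
                            n_outliers = length(out_idx)),
         outliers = if (length(out_idx)) data.frame(week = w,
                                                    gtv_id = ids[out_idx],
                                                    value = v[out_idx])
                    else NULL)
  })
  list(stats = do.call(rbind, lapply(stats_rows, `[[`, "stats")),
       outliers = {
         ol <- do.call(rbind, lapply(stats_rows, `[[`, "outliers"))
         if (is.null(ol)) data.frame(week = integer(), gtv_id = character(),
                                     value = numeric()) else ol
       },
       metric = metric, value = value)
}

#' Build a longitudinal series directly from a phantom
#'
#' Runs the full per-week analysis (ADC fit, viable isolation, histogram
#' summary, volumes) over a [generate_phantom()] output and assembles the
#' result into a [longitudinal_series()].
#'
#' @param phantom a `phantom_output`.
#' @param gtv_id identifier for the series.
#' @param negative_policy passed to [fit_adc_pair()]/[fit_adc_multib()].
#' @return a [longitudinal_series()].
#' @export
phantom_to_series <- function(phantom, gtv_id = "phantom",
                              negative_policy = "retain") {
  stopifnot(inherits(phantom, "phantom_output"))
  tps <- lapply(phantom$weeks, function(w) {
    adc <- suppressMessages(
      if (length(w$series$b_values) == 2L)
        fit_adc_pair(w$series, negative_policy)
      else fit_adc_multib(w$series, negative_policy))
    res <- suppressMessages(
      analyze_timepoint(adc, w$masks$gtv,
                        cystic = if (any(w$masks$cystic$mask)) w$masks$cystic,
                        week = w$week))
    time_point(w$week, res$summary, res$gtv_volume_cm3,
               days_from_rt_start = w$series$days_from_rt_start)
  })
  longitudinal_series(gtv_id, tps)
}
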