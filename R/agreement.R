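#' Ratings table for interobserver agreement
#'
#' @param x numeric matrix or data.frame: rows are targets (e.g. GTV-week
#'   observations), columns are raters. Rows with any missing cell are
#'   dropped with a warning (no imputation).
#' @return validated numeric matrix of class `ratings_table`.
#' @export
ratings_table <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (ncol(m) < 2L) stop("need at least 2 raters (columns)")
  complete <- rowSums(is.na(m)) == 0L
  if (!all(complete)) {
    warning(sprintf("%d incomplete rating row(s) dropped", sum(!complete)))
    m <- m[complete, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("need at least 2 complete targets (rows)")
  structure(m, class = c("ratings_table", "matrix", "array"))
}

#' Two-way random-effects ICC (absolute agreement, single rater)
#'
#' ICC(2,1): each target is rated by each rater, raters are treated as a
#' random sample of possible raters, and systematic rater offsets count
#' against agreement. Computed from the mean squares of the two-way layout:
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' with `n` targets, `k` raters, `MSR`/`MSC`/`MSE` the rows/columns/error
#' mean squares. The 95% confidence interval uses the F-distribution method
#' with a Satterthwaite approximation for the column degrees of freedom.
#'
#' With zero between-target variance the coefficient is undefined; `NA` is
#' returned with `defined = FALSE`.
#'
#' @param ratings a [ratings_table()] (or coercible matrix/data.frame).
#' @param conf_level confidence level for the interval.
#' @return an `icc_result`: `icc`, `ci_low`, `ci_high`, `form` ("ICC(2,1),
#'   two-way random, absolute agreement"), `n_targets`, `n_raters`,
#'   `defined`, and the mean squares `msr`, `msc`, `mse`.
#' @export
icc_two_way <- function(ratings, conf_level = 0.95) {
  m <- if (inherits(ratings, "ratings_table")) ratings else ratings_table(ratings)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m); col_means <- colMeans(m)

  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sse <- sum((m - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  form <- "ICC(2,1), two-way random, absolute agreement"
  if (msr <= .Machine$double.eps * grand^2 && ssr <= 0) {
    warning("zero between-target variance: ICC is undefined")
    return(structure(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          form = form, n_targets = n, n_raters = k,
                          defined = FALSE, msr = msr, msc = msc, mse = mse),
                     class = "icc_result"))
  }

  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- (msr - mse) / denom

  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    # perfect agreement: degenerate interval
    ci <- c(1, 1)
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  }

  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2], form = form,
                 n_targets = n, n_raters = k, defined = TRUE,
                 msr = msr, msc = msc, mse = mse),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (!x$defined) {
    cat("<icc_result> undefined (zero between-target variance)\n")
  } else {
    cat(sprintf("<icc_result> %s\n  ICC = %.3f [95%% CI %.3f, %.3f]  (n = %d targets, %d raters)\n",
                x$form, x$icc, x$ci_low, x$ci_high, x$n_targets, x$n_raters))
  }
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson r between paired observations (e.g. percent change in
#' viable-tumor median ADC vs percent change in GTV volume), with the
#' two-sided p-value from the t transform `t = r sqrt((n-2)/(1-r^2))` on
#' n - 2 degrees of freedom. Exactly affine pairs give r = +/-1 and p = 0.
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @return a `correlation_result`: `rho`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  if (!all(keep)) {
    warning(sprintf("%d incomplete pair(s) dropped", sum(!keep)))
    x <- x[keep]; y <- y[keep]
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (var(x) == 0) stop("x is constant: correlation undefined")
  if (var(y) == 0) stop("y is constant: correlation undefined")

  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = r, p_value = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> rho = %.3f, p = %.3g, n = %d\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' Read a tidy ratings CSV into a ratings table
#'
#' Expects columns `target_id`, `rater`, `value`; pivots to a
#' targets-by-raters matrix.
#'
#' @param path CSV file.
#' @return a [ratings_table()].
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("target_id", "rater", "value")
  if (!all(need %in% names(df)))
    stop("ratings CSV needs columns: ", paste(need, collapse = ", "))
  targets <- unique(df$target_id)
  raters <- sort(unique(df$rater))
  m <- matrix(NA_real_, length(targets), length(raters),
              dimnames = list(as.character(targets), as.character(raters)))
  m[cbind(match(df$target_id, targets), match(df$rater, raters))] <- df$value
  ratings_table(m)
}
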