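#' Dietary dissimilarity between two composition vectors
#'
#' Bray-Curtis dissimilarity on the compositional data (the default) or
#' one minus the Jaccard similarity on presence/absence of food types.
#'
#' @param comp_a,comp_b non-negative diet composition vectors over the
#'   same food vocabulary (same length, not both all-zero).
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return Dissimilarity in [0, 1].
#' @examples
#' diet_dissimilarity(c(2, 1, 0), c(1, 1, 1))            # 1/3
#' diet_dissimilarity(c(2, 1, 0), c(1, 1, 1), "jaccard") # 1 - 2/3
#' @export
diet_dissimilarity <- function(comp_a, comp_b,
                               metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  if (length(comp_a) != length(comp_b))
    stop("composition vectors must have the same length")
  if (any(comp_a < 0) || any(comp_b < 0)) stop("compositions must be non-negative")
  if (sum(comp_a) == 0 && sum(comp_b) == 0)
    stop("both composition vectors are all-zero")
  if (metric == "bray_curtis") {
    as.numeric(vegan::vegdist(rbind(comp_a, comp_b), method = "bray"))
  } else {
    a <- comp_a > 0; b <- comp_b > 0
    1 - sum(a & b) / sum(a | b)
  }
}

#' Circular distance between two calendar months
#'
#' Minimum distance between month numbers on the 12-month cycle,
#' regardless of year; bounded by 6.
#'
#' @param m1,m2 month numbers in 1-12.
#' @return Integer distance in 0-6.
#' @examples
#' month_distance(1, 12)  # 1
#' month_distance(3, 9)   # 6
#' @export
month_distance <- function(m1, m2) {
  m1 <- as.integer(m1); m2 <- as.integer(m2)
  if (anyNA(c(m1, m2)) || any(c(m1, m2) < 1L) || any(c(m1, m2) > 12L))
    stop("months must be integers in 1..12")
  d <- abs(m1 - m2)
  pmin(d, 12L - d)
}

#' Rainfall covariate for a sample dyad
#'
#' Sums the daily rain-gauge record by calendar month and combines the two
#' samples' collection months, either additively (default) or as a mean.
#'
#' @param daily_rain data.frame with `date` (Date) and `mm` (>= 0).
#' @param date_a,date_b collection dates.
#' @param mode `"sum_both_months"` or `"mean_both_months"`.
#' @return Millimetres of rain.
#' @export
rainfall_covariate <- function(daily_rain, date_a, date_b,
                               mode = c("sum_both_months", "mean_both_months")) {
  mode <- match.arg(mode)
  if (any(daily_rain$mm < 0)) stop("negative rainfall values")
  key <- format(as.Date(daily_rain$date), "%Y-%m")
  months <- format(as.Date(c(date_a, date_b)), "%Y-%m")
  missing <- setdiff(months, key)
  if (length(missing))
    stop("rainfall series does not cover month(s): ",
         paste(missing, collapse = ", "))
  sums <- vapply(months, function(m) sum(daily_rain$mm[key == m]), 0)
  if (mode == "sum_both_months") sum(sums) else mean(sums)
}

#' Simple linear regression of sharing rate on one predictor
#'
#' Ordinary least squares of a dyadic sharing response on a single dyad
#' covariate; the quantity reported throughout the covariate analyses is
#' the slope with its t-based two-sided p-value on n - 2 degrees of
#' freedom.
#'
#' @param x predictor vector (not constant).
#' @param y response vector (same length, n >= 3).
#' @return List of class `simple_regression` with `slope`, `intercept`,
#'   `se`, `df`, `t`, `p` and `n`.
#' @export
fit_simple_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (stats::var(x) == 0) stop("predictor is constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  structure(list(slope = sm["x", "Estimate"],
                 intercept = sm["(Intercept)", "Estimate"],
                 se = sm["x", "Std. Error"],
                 df = n - 2L,
                 t = sm["x", "t value"],
                 p = sm["x", "Pr(>|t|)"],
                 n = n),
            class = "simple_regression")
}

#' @export
print.simple_regression <- function(x, ...) {
  cat(sprintf("Simple linear regression (n = %d): slope = %.4g, df = %d, p = %s\n",
              x$n, x$slope, x$df, format.pval(x$p, digits = 3)))
  invisible(x)
}

#' Covariate report for a set of dyads
#'
#' Fits [fit_simple_regression()] of the dyadic sharing rate on each
#' supplied covariate and tabulates slope, df and p.
#'
#' @param covariates data.frame of dyad covariates (numeric columns).
#' @param sharing_rate response vector aligned with the rows.
#' @return data.frame `predictor`, `slope`, `df`, `p`.
#' @export
covariate_report <- function(covariates, sharing_rate) {
  rows <- lapply(names(covariates), function(nm) {
    fit <- tryCatch(fit_simple_regression(covariates[[nm]], sharing_rate),
                    error = function(e) NULL)
    data.frame(predictor = nm,
               slope = if (is.null(fit)) NA_real_ else fit$slope,
               df = if (is.null(fit)) NA_integer_ else fit$df,
               p = if (is.null(fit)) NA_real_ else fit$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
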