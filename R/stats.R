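# Correlation and regression, implemented from the product-moment and
# adjusted R-squared formulas as used in the analysis, plus a small S3
# model wrapper (ddg_trend) for the ddG-vs-structural-metric regressions.

#' Pearson product-moment correlation
#'
#' r = \[n sum(xy) - sum(x) sum(y)\] /
#' sqrt(\[n sum(x^2) - (sum x)^2\]\[n sum(y^2) - (sum y)^2\]).
#'
#' @param x,y numeric vectors of equal length n >= 3, each with non-zero
#'   variance.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("at least 3 points are required")
  sxx <- n * sum(x^2) - sum(x)^2
  syy <- n * sum(y^2) - sum(y)^2
  if (sxx <= 0 || syy <= 0) stop("x and y must each have non-zero variance")
  r <- (n * sum(x * y) - sum(x) * sum(y)) / sqrt(sxx * syy)
  max(-1, min(1, r))
}

#' Adjusted R-squared
#'
#' 1 - (1 - r^2)(n - 1)/(n - k - 1); may be negative for weak fits.
#'
#' @param r Pearson correlation coefficient.
#' @param n number of points (> k + 1).
#' @param k number of independent regressors (default 1).
#' @return adjusted R-squared value (<= r^2).
#' @export
adjusted_r2 <- function(r, n, k = 1) {
  if (n <= k + 1) stop("need n > k + 1")
  1 - (1 - r^2) * (n - 1) / (n - k - 1)
}

#' Simple least-squares line fit
#'
#' slope = sum((x - xbar)(y - ybar)) / sum((x - xbar)^2);
#' intercept = ybar - slope * xbar.
#'
#' @param x,y numeric vectors of equal length n >= 3; x must have
#'   non-zero variance.
#' @return list with `slope` and `intercept`.
#' @export
ols_fit <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("at least 3 points are required")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx <= 0) stop("x must have non-zero variance")
  slope <- sum(xc * (y - mean(y))) / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Fit the ddG-vs-structural-metric trend
#'
#' One-regressor linear model of a structural difference metric (e.g. the
#' interface-cavity change ddVcav in A^3) against the folding
#' free-energy change ddG (kcal/mol), reported the way the analysis
#' reports it: Pearson r, R^2, adjusted R^2, and the regression line.
#'
#' @param formula model formula with one regressor, e.g. `dd_vcav ~ ddg`.
#' @param data data.frame holding the variables.
#' @param k number of regressors for the adjustment (default 1).
#' @return object of class `ddg_trend` with fields `n`, `pearson_r`,
#'   `r_squared`, `adjusted_r_squared`, `slope`, `intercept`, `x`, `y`,
#'   and the variable names.
#' @export
ddg_trend <- function(formula, data, k = 1) {
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2L) stop("formula must have exactly one regressor")
  y <- mf[[1]]; x <- mf[[2]]
  r <- pearson(x, y)
  fit <- ols_fit(x, y)
  structure(list(n = length(x), pearson_r = r, r_squared = r^2,
                 adjusted_r_squared = adjusted_r2(r, length(x), k),
                 slope = fit$slope, intercept = fit$intercept,
                 k = k, x = x, y = y,
                 xname = names(mf)[2], yname = names(mf)[1],
                 call = match.call()),
            class = "ddg_trend")
}

#' @export
print.ddg_trend <- function(x, digits = 3, ...) {
  cat("<ddg_trend> ", x$yname, " ~ ", x$xname, " (n = ", x$n, ")\n",
      sep = "")
  cat(sprintf("  Pearson r = %.*f, R^2 = %.*f, adjusted R^2 = %.*f\n",
              digits, x$pearson_r, digits, x$r_squared, digits,
              x$adjusted_r_squared))
  cat(sprintf("  %s = %.*f x %s + %.*f\n", x$yname, digits, x$slope,
              x$xname, digits, x$intercept))
  invisible(x)
}

#' @export
summary.ddg_trend <- function(object, ...) {
  res <- residuals(object)
  out <- c(unclass(object)[c("n", "pearson_r", "r_squared",
                             "adjusted_r_squared", "slope", "intercept")],
           list(residual_sd = sd(res), residuals = res))
  class(out) <- "summary.ddg_trend"
  out
}

#' @export
print.summary.ddg_trend <- function(x, ...) {
  cat(sprintf(
    "n = %d, r = %.4f, R^2 = %.4f, adj R^2 = %.4f\nslope = %.4f, intercept = %.4f, residual sd = %.4f\n",
    x$n, x$pearson_r, x$r_squared, x$adjusted_r_squared, x$slope,
    x$intercept, x$residual_sd))
  invisible(x)
}

#' @export
coef.ddg_trend <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.ddg_trend <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else {
    if (is.data.frame(newdata)) newdata[[object$xname]] else newdata
  }
  object$intercept + object$slope * x
}

#' @export
fitted.ddg_trend <- function(object, ...) predict(object)

#' @export
residuals.ddg_trend <- function(object, ...) object$y - predict(object)

#' @export
plot.ddg_trend <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = x$xname, ylab = x$yname,
                 main = sprintf("r = %.2f, adj R^2 = %.2f", x$pearson_r,
                                x$adjusted_r_squared), ...)
  graphics::abline(a = x$intercept, b = x$slope, col = "red")
  invisible(x)
}

#' Correlation report as a one-row table
#'
#' @param trend a `ddg_trend`.
#' @return data.frame with n, r, r2, adj_r2, slope, intercept.
#' @export
correlation_report <- function(trend) {
  stopifnot(inherits(trend, "ddg_trend"))
  data.frame(n = trend$n, r = trend$pearson_r, r2 = trend$r_squared,
             adj_r2 = trend$adjusted_r_squared, slope = trend$slope,
             intercept = trend$intercept)
}
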