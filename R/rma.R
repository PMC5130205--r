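#' Reduced major axis (RMA) allometric fit
#'
#' Fits a reduced-major-axis (standardized major axis) line to a bivariate
#' sample, by default after log10 transformation of both variables, which
#' is the conventional scale for allometric comparisons of skeletal
#' structural properties. The RMA slope is `sign(r) * sd(y) / sd(x)` and
#' the line passes through the bivariate mean, making the fit symmetric in
#' x and y (swapping the variables gives the reciprocal slope).
#'
#' The standard error of estimate (SEE) is the standard deviation of the
#' vertical (y-direction) residuals about the RMA line with `n - 2`
#' degrees of freedom, on the log10 scale; `%SEE = (10^SEE - 1) * 100`
#' expresses it as a percent deviation on the raw scale. Deviations of
#' individual specimens from the line are scored in SEE units with
#' [see_units()], and 95% prediction intervals for graphing are available
#' through [predict.rma()].
#'
#' @param formula a two-sided formula `y ~ x` naming the response and
#'   predictor columns of `data`
#' @param data data frame containing the variables
#' @param log10 if `TRUE` (default) both variables are log10-transformed
#'   before fitting; they must then be strictly positive. Use `FALSE` for
#'   data already on a log (or otherwise linear) scale.
#' @param subset optional logical or integer vector selecting rows
#' @return an object of class `rma`: a list with components
#'   `coefficients` (named `intercept`, `slope`), `r` (correlation on the
#'   fitting scale), `see`, `pct_see`, `n`, `df` (`n - 2`), `xbar` (mean
#'   of the transformed x), `ssx` (corrected sum of squares of the
#'   transformed x), `x`, `y` (the transformed data), `fitted`,
#'   `residuals`, `log10`, `vars` and `call`.
#' @examples
#' d <- simulate_group(n = 200, slope = 1, intercept = 0.4, sigma = 0.05,
#'                     xlim = c(2.5, 3.5), seed = 1)
#' fit <- rma(y ~ x, d)
#' fit
#' predict(fit, newdata = c(500, 1000), interval = "prediction")
#' @export
rma <- function(formula, data, log10 = TRUE, subset = NULL) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  if (ncol(mf) != 2)
    stop("'formula' must have exactly one response and one predictor")
  y <- mf[[1]]
  x <- mf[[2]]
  if (!is.null(subset)) {
    x <- x[subset]
    y <- y[subset]
  }
  n <- length(x)
  if (n < 3)
    stop("at least 3 complete pairs are required (got ", n, ")")
  if (log10) {
    if (any(x <= 0) || any(y <= 0))
      stop("all values must be strictly positive for log10 transformation")
    x <- log10(x)
    y <- log10(y)
  }
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  b <- sign(r) * sy / sx
  if (b == 0) stop("degenerate fit: slope is zero")
  a <- mean(y) - b * mean(x)
  res <- y - (a + b * x)
  see <- sqrt(sum(res^2) / (n - 2))
  fit <- structure(
    list(
      coefficients = c(intercept = a, slope = b),
      r = r, see = see, pct_see = (10^see - 1) * 100,
      n = n, df = n - 2, xbar = mean(x), ssx = sum((x - mean(x))^2),
      x = x, y = y, fitted = a + b * x, residuals = res,
      log10 = log10,
      vars = c(y = deparse(formula[[2]]), x = deparse(formula[[3]])),
      call = match.call()
    ),
    class = "rma"
  )
  fit
}

#' @export
print.rma <- function(x, digits = 4, ...) {
  cat("Reduced major axis fit",
      if (x$log10) "(log10 scale)" else "", "\n")
  cat("  ", x$vars[["y"]], "~", x$vars[["x"]], "  n =", x$n, "\n")
  cat(sprintf("  slope %.*g   intercept %.*g   r %.*g\n",
              digits, x$coefficients[["slope"]],
              digits, x$coefficients[["intercept"]], digits, x$r))
  cat(sprintf("  SEE %.*g   %%SEE %.*g\n", digits, x$see, digits, x$pct_see))
  invisible(x)
}

#' @export
summary.rma <- function(object, ...) {
  structure(list(fit = object), class = "summary.rma")
}

#' @export
print.summary.rma <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat(sprintf("  df %d   mean(x) %.*g   SS(x) %.*g\n",
              f$df, digits, f$xbar, digits, f$ssx))
  cat(sprintf("  residuals (fitting scale): min %.3g  median %.3g  max %.3g\n",
              min(f$residuals), stats::median(f$residuals), max(f$residuals)))
  invisible(x)
}

#' @export
coef.rma <- function(object, ...) object$coefficients

#' @export
residuals.rma <- function(object, ...) object$residuals

#' @export
fitted.rma <- function(object, ...) object$fitted

#' Prediction-interval halfwidth about an RMA line
#'
#' Halfwidth of the two-sided `1 - alpha` prediction band at evaluation
#' point `xi` (on the fitting scale):
#' `t(alpha(2), df) * sqrt(2 * SEE^2 * (1 + 1/n + (xi - xbar)^2 / SSx)) * |slope|`.
#' The band is symmetric about `xbar`, narrowest there, and tends to
#' `t * sqrt(2) * SEE * |slope|` as `n` grows.
#'
#' @param fit an [rma()] fit
#' @param xi numeric vector of evaluation points on the fitting scale
#'   (log10 if the fit was log10)
#' @param alpha two-sided level (default 0.05 for a 95% band)
#' @return numeric vector of halfwidths on the fitting scale
#' @export
pi_halfwidth <- function(fit, xi, alpha = 0.05) {
  stopifnot(inherits(fit, "rma"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single value in (0, 1)")
  if (fit$df < 1)
    stop("prediction interval needs df >= 1")
  tcrit <- stats::qt(1 - alpha / 2, df = fit$df)
  bracket <- 1 + 1 / fit$n + (xi - fit$xbar)^2 / fit$ssx
  tcrit * sqrt(2 * fit$see^2 * bracket) * abs(fit$coefficients[["slope"]])
}

#' Predict from an RMA fit, with optional prediction interval
#'
#' @param object an [rma()] fit
#' @param newdata numeric vector of predictor values, or a data frame
#'   containing the predictor column. Values are on the original input
#'   scale (raw, if the fit log10-transformed its data). Defaults to the
#'   fitted x values.
#' @param interval `"none"` or `"prediction"`
#' @param level coverage of the prediction band (default 0.95)
#' @param scale `"log"` returns values on the fitting (log10) scale,
#'   `"raw"` back-transforms through `10^`. Ignored when the fit was not
#'   log10-transformed.
#' @param ... unused
#' @return with `interval = "none"` a numeric vector of predicted y;
#'   otherwise a data frame with columns `fit`, `lwr`, `upr`
#' @export
predict.rma <- function(object, newdata = NULL,
                        interval = c("none", "prediction"),
                        level = 0.95, scale = c("log", "raw"), ...) {
  interval <- match.arg(interval)
  scale <- match.arg(scale)
  if (is.null(newdata)) {
    xi <- object$x
  } else {
    if (is.data.frame(newdata))
      newdata <- newdata[[object$vars[["x"]]]]
    xi <- newdata
    if (object$log10) {
      if (any(xi <= 0)) stop("newdata must be strictly positive")
      xi <- log10(xi)
    }
  }
  a <- object$coefficients[["intercept"]]
  b <- object$coefficients[["slope"]]
  yhat <- a + b * xi
  back <- function(v) if (object$log10 && scale == "raw") 10^v else v
  if (interval == "none")
    return(back(yhat))
  hw <- pi_halfwidth(object, xi, alpha = 1 - level)
  data.frame(fit = back(yhat), lwr = back(yhat - hw), upr = back(yhat + hw))
}

#' Deviation from an RMA line in SEE units
#'
#' Scores points against a reference fit as
#' `(y - (a + b x)) / SEE` on the fitting scale: positive above the line,
#' `+1` exactly one standard error of estimate above it. This is the
#' standard way of placing individual (e.g. fossil) specimens relative to
#' a comparative sample's allometry.
#'
#' @param fit an [rma()] fit
#' @param x,y numeric vectors of coordinates for the points to score, on
#'   the original input scale of the fit (raw values if the fit was
#'   log10-transformed, already-logged values otherwise)
#' @return numeric vector of deviations in SEE units
#' @export
see_units <- function(fit, x, y) {
  stopifnot(inherits(fit, "rma"))
  if (fit$see == 0)
    stop("degenerate fit: SEE is zero")
  if (fit$log10) {
    if (any(x <= 0) || any(y <= 0))
      stop("values must be strictly positive")
    x <- log10(x)
    y <- log10(y)
  }
  (y - (fit$coefficients[["intercept"]] + fit$coefficients[["slope"]] * x)) /
    fit$see
}

#' Plot an RMA fit with its prediction band
#'
#' Scatter of the data on the fitting scale with the RMA line and the
#' `level` prediction band.
#'
#' @param x an [rma()] fit
#' @param level prediction-band coverage (default 0.95)
#' @param band draw the prediction band (default TRUE)
#' @param ... passed to [graphics::plot()]
#' @return `x`, invisibly
#' @export
plot.rma <- function(x, level = 0.95, band = TRUE, ...) {
  lab <- function(v) if (x$log10) paste0("log10(", v, ")") else v
  graphics::plot(x$x, x$y, xlab = lab(x$vars[["x"]]),
                 ylab = lab(x$vars[["y"]]), ...)
  xs <- seq(min(x$x), max(x$x), length.out = 200)
  a <- x$coefficients[["intercept"]]
  b <- x$coefficients[["slope"]]
  graphics::lines(xs, a + b * xs)
  if (band) {
    hw <- pi_halfwidth(x, xs, alpha = 1 - level)
    graphics::lines(xs, a + b * xs + hw, lty = 2)
    graphics::lines(xs, a + b * xs - hw, lty = 2)
  }
  invisible(x)
}

#' Simulate responses from an RMA fit
#'
#' Draws new responses at the fitted predictor values, on the fitting
#' scale: `y* = a + b x + N(0, SEE)`. Useful for parametric-bootstrap
#' style checks of downstream statistics.
#'
#' @param object an [rma()] fit
#' @param nsim number of simulated response vectors
#' @param seed optional integer seed (RNG state is restored on exit)
#' @param ... unused
#' @return data frame with `nsim` columns of simulated responses
#' @export
simulate.rma <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  out <- as.data.frame(replicate(nsim, object$fitted +
                                   stats::rnorm(object$n, 0, object$see)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
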