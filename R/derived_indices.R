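#' Bilateral asymmetry, percent
#'
#' Signed percent difference between paired right and left measurements,
#' `((R - L) / ((R + L) / 2)) * 100`. Positive values indicate right
#' dominance. The statistic is antisymmetric in its arguments and bounded
#' in (-200, 200).
#'
#' @param right,left positive paired measurements (vectorized)
#' @return signed percent asymmetry
#' @examples
#' bilateral_asymmetry(6028, 5336)  # humeral 80% polar SMA
#' @export
bilateral_asymmetry <- function(right, left) {
  if (any(!is.finite(right)) || any(!is.finite(left)) ||
      any(right <= 0) || any(left <= 0))
    stop("'right' and 'left' must be positive")
  (right - left) / ((right + left) / 2) * 100
}

#' Asymmetry over offset pairings (section-placement sensitivity)
#'
#' When the exact longitudinal concordance of right and left section
#' locations is uncertain, asymmetry is assessed over every pairing of
#' sections taken at offsets around the best estimate (typically 1-mm
#' steps within +/- 3 mm). Returns the full pairing table plus a
#' min/median/max summary of the asymmetry values.
#'
#' @param right_series,left_series data frames with columns `offset_mm`
#'   and `value`, one row per available section offset on that side
#' @return list with `table` (right offset, left offset, values,
#'   asymmetry for every pairing) and `summary` (named min/median/max)
#' @export
asymmetry_sensitivity <- function(right_series, left_series) {
  chk <- function(d, nm) {
    if (!is.data.frame(d) || !all(c("offset_mm", "value") %in% names(d)) ||
        nrow(d) == 0)
      stop("'", nm, "' must be a non-empty data frame with columns ",
           "'offset_mm' and 'value'")
  }
  chk(right_series, "right_series")
  chk(left_series, "left_series")
  g <- expand.grid(i = seq_len(nrow(right_series)),
                   j = seq_len(nrow(left_series)))
  tab <- data.frame(
    right_offset_mm = right_series$offset_mm[g$i],
    left_offset_mm = left_series$offset_mm[g$j],
    right = right_series$value[g$i],
    left = left_series$value[g$j]
  )
  tab$asymmetry_pct <- bilateral_asymmetry(tab$right, tab$left)
  list(
    table = tab,
    summary = c(min = min(tab$asymmetry_pct),
                median = stats::median(tab$asymmetry_pct),
                max = max(tab$asymmetry_pct))
  )
}

#' Power-law surrogate section modulus
#'
#' Converts a second moment of area to a section-modulus surrogate by a
#' power law: polar section modulus as `J^0.75`, and planar moduli as
#' `SMA^0.73`, for comparative samples lacking the contour distances
#' needed for true moduli.
#'
#' @param value positive second moment(s) of area (mm^4)
#' @param exponent power-law exponent; 0.75 for polar, 0.73 for planar
#'   conversions
#' @return section-modulus surrogate (mm^3)
#' @examples
#' power_convert(10000, 0.75)  # 1000
#' @export
power_convert <- function(value, exponent = 0.75) {
  if (any(!is.finite(value)) || any(value <= 0))
    stop("'value' must be positive")
  if (!is.numeric(exponent) || length(exponent) != 1 || exponent <= 0)
    stop("'exponent' must be a single positive number")
  value^exponent
}

#' Fit a conversion model between two structural measurements
#'
#' Fits the relationship used to transfer one property or section
#' location to another (e.g. approximate to true polar section moduli, or
#' a 40%-section value to the 35% location). Three kinds are supported:
#'
#' * `"power"`: `y = x^e`, the exponent estimated by least squares on
#'   log10 scale through the origin;
#' * `"loglinear"`: `log10 y = a + b log10 x`, ordinary least squares;
#' * `"mean-ratio"`: the arithmetic mean of the pairwise ratios `y/x`.
#'
#' Regression kinds report the correlation `r` and `%SEE` (the residual
#' standard error on log10 scale re-expressed as a percent); the
#' mean-ratio kind reports the coefficient of variation of the ratios as
#' its dispersion summary.
#'
#' @param x,y positive paired measurements; at least 3 pairs for the
#'   regression kinds, at least 1 for `"mean-ratio"`
#' @param kind `"power"`, `"loglinear"` or `"mean-ratio"`
#' @return an object of class `conversion_model`
#' @export
fit_conversion <- function(x, y, kind = c("power", "loglinear", "mean-ratio")) {
  kind <- match.arg(kind)
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0))
    stop("all values must be positive")
  n <- length(x)
  if (kind == "mean-ratio") {
    if (n < 1) stop("at least 1 pair required")
    ratios <- y / x
    m <- mean(ratios)
    cv <- if (n > 1) stats::sd(ratios) / m * 100 else 0
    return(new_conversion(kind, ratio = m, n = n, cv_pct = cv))
  }
  if (n < 3)
    stop("at least 3 pairs required for regression kinds")
  lx <- log10(x)
  ly <- log10(y)
  if (stats::sd(lx) == 0)
    stop("degenerate variance in x")
  r <- stats::cor(lx, ly)
  if (kind == "power") {
    if (sum(lx^2) == 0) stop("degenerate x (all values 1)")
    e <- sum(lx * ly) / sum(lx^2)
    res <- ly - e * lx
    see <- sqrt(sum(res^2) / max(n - 1, 1))
    new_conversion(kind, exponent = e, r = r,
                   pct_see = (10^see - 1) * 100, n = n)
  } else {
    fit <- stats::lm(ly ~ lx)
    see <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
    new_conversion(kind, slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   r = r, pct_see = (10^see - 1) * 100, n = n)
  }
}

new_conversion <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "conversion_model")
}

#' @export
print.conversion_model <- function(x, ...) {
  cat("Conversion model (", x$kind, "), n = ", x$n, "\n", sep = "")
  if (x$kind == "power")
    cat(sprintf("  y = x^%.4g   r %.4g   %%SEE %.3g\n",
                x$exponent, x$r, x$pct_see))
  else if (x$kind == "loglinear")
    cat(sprintf("  log10 y = %.4g + %.4g log10 x   r %.4g   %%SEE %.3g\n",
                x$intercept, x$slope, x$r, x$pct_see))
  else
    cat(sprintf("  mean ratio %.4g   CV %.3g%%\n", x$ratio, x$cv_pct))
  invisible(x)
}

#' Apply a conversion model
#'
#' @param model a [fit_conversion()] model, or a plain numeric scalar
#'   interpreted as a mean ratio
#' @param value positive value(s) to convert
#' @return converted value(s)
#' @export
apply_conversion <- function(model, value) {
  if (is.numeric(model) && length(model) == 1)
    model <- new_conversion("mean-ratio", ratio = model, n = NA)
  stopifnot(inherits(model, "conversion_model"))
  if (model$kind != "mean-ratio" && any(value <= 0))
    stop("'value' must be positive for log-scale conversion kinds")
  switch(model$kind,
    "power" = value^model$exponent,
    "loglinear" = 10^(model$intercept + model$slope * log10(value)),
    "mean-ratio" = model$ratio * value
  )
}

#' Ratio of two strength (or length) measurements
#'
#' Plain ratio used for the comparative shape indices: mediolateral to
#' anteroposterior bending strength of the proximal femur (`Zy/Zx` at the
#' 80% section), femoral to humeral polar section modulus, and femoral
#' biomechanical neck length relative to total bone length.
#'
#' @param numerator,denominator positive values (vectorized)
#' @return `numerator / denominator`
#' @export
strength_ratio <- function(numerator, denominator) {
  if (any(!is.finite(numerator)) || any(!is.finite(denominator)) ||
      any(numerator <= 0) || any(denominator <= 0))
    stop("both arguments must be positive")
  numerator / denominator
}
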