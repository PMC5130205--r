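#' Superior and inferior femoral-neck cortical thicknesses
#'
#' Measures the cortical thickness of a femoral-neck section along a
#' vertical (superoinferior) line and returns the superior thickness,
#' inferior thickness and their ratio. The section must be oriented with
#' the superior direction at the top of the image. The measurement line
#' passes through the cortical-area centroid by default; `axis_x` shifts
#' it mediolaterally (in mm) from the centroid.
#'
#' Thickness on each side is the full cortical intercept of the line: the
#' summed length of contiguous cortical runs superior (respectively
#' inferior) to the centroid, with run boundaries resolved at pixel edges.
#' The line must enter the cortex on both sides of the medullary cavity;
#' if it misses the section, passes through solid cortex (no cavity), or
#' finds cortex on only one side, an error reporting the crossing pattern
#' is raised.
#'
#' @param mask a [section_mask()] of a femoral-neck section, superior up
#' @param axis_x mediolateral offset of the measurement line from the
#'   cortical centroid, mm (default 0)
#' @param location `"mid-neck"` or `"neck-base"`; metadata only, the
#'   measurement is identical at either plane
#' @return an object of class `neck_cortex`: list with `superior_mm`,
#'   `inferior_mm`, `ratio` (superior/inferior), `location`, `axis_x`
#' @export
measure_neck_cortices <- function(mask, axis_x = 0,
                                  location = c("mid-neck", "neck-base")) {
  stopifnot(inherits(mask, "section_mask"))
  location <- match.arg(location)
  mask <- normalize_side(mask)
  p <- mask$pixel_size
  px <- mask$pixels
  if (!any(px)) stop("empty mask: no cortical pixels")
  cort <- which(px, arr.ind = TRUE)
  cen_col <- mean(cort[, 2] - 0.5)       # in pixels
  cen_row <- mean(cort[, 1] - 0.5)
  j <- round(cen_col + axis_x / p + 0.5)
  if (j < 1 || j > ncol(px))
    stop("measurement line at axis_x = ", axis_x, " mm falls outside the image")
  colv <- px[, j]
  if (!any(colv))
    stop("measurement line misses the section (0 cortical crossings)")
  r <- rle(colv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts, end = ends)[r$values, , drop = FALSE]
  # classify runs relative to the centroid row (row index grows inferiorly)
  cen_idx <- cen_row + 0.5
  through <- runs$start <= cen_idx & runs$end >= cen_idx
  if (any(through))
    stop("measurement line crosses cortex only once ",
         "(solid at the centroid; no medullary cavity on this line)")
  sup <- runs[runs$end < cen_idx, , drop = FALSE]
  inf <- runs[runs$start > cen_idx, , drop = FALSE]
  if (nrow(sup) == 0 || nrow(inf) == 0)
    stop("measurement line crosses cortex on only one side of the centroid (",
         nrow(sup) + nrow(inf), " crossing(s))")
  superior <- sum(sup$end - sup$start + 1) * p
  inferior <- sum(inf$end - inf$start + 1) * p
  structure(
    list(superior_mm = superior, inferior_mm = inferior,
         ratio = superior / inferior, location = location, axis_x = axis_x),
    class = "neck_cortex"
  )
}

#' @export
print.neck_cortex <- function(x, ...) {
  cat(sprintf(
    "Femoral neck cortices (%s): superior %.2f mm, inferior %.2f mm, S/I ratio %.3f\n",
    x$location, x$superior_mm, x$inferior_mm, x$ratio))
  invisible(x)
}
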