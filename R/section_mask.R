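#' Segmented bone cross-section mask
#'
#' Construct a `section_mask`, the raster representation of a segmented
#' long-bone cross section. Nonzero (or `TRUE`) pixels mark cortical bone;
#' everything else is background (air, matrix, medullary cavity).
#'
#' The default axis convention follows standard anatomical section images:
#' image columns run mediolaterally (M-L) and image rows run
#' anteroposteriorly (A-P), with anterior (or superior, for femoral-neck
#' sections) at the top of the image. Left-side sections are mirrored to
#' right-side orientation before any computation so that the medial
#' direction is consistent across specimens.
#'
#' @param pixels logical or numeric matrix; nonzero entries are cortical
#'   bone.
#' @param pixel_size physical edge length of one pixel, in mm. Must be a
#'   single positive number.
#' @param axis_convention `"columns-ML"` (default: columns are M-L, rows are
#'   A-P) or `"rows-ML"` (the transpose; the mask is transposed on
#'   construction so that stored pixels are always columns-ML).
#' @param side `"left"`, `"right"` or `"unknown"`. Left sections are
#'   mirrored about the vertical axis by [normalize_side()] prior to
#'   computing properties.
#' @return an object of class `section_mask`: a list with elements
#'   `pixels` (logical matrix, columns-ML), `pixel_size` and `side`.
#' @seealso [compute_section_properties()], [fill_periosteal()]
#' @export
section_mask <- function(pixels, pixel_size,
                         axis_convention = c("columns-ML", "rows-ML"),
                         side = c("unknown", "left", "right")) {
  axis_convention <- match.arg(axis_convention)
  side <- match.arg(side)
  if (!is.matrix(pixels))
    stop("'pixels' must be a matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 ||
      is.na(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (mm)")
  px <- if (is.logical(pixels)) pixels else pixels != 0
  px[is.na(px)] <- FALSE
  if (axis_convention == "rows-ML")
    px <- t(px)
  structure(
    list(pixels = px, pixel_size = pixel_size, side = side),
    class = "section_mask"
  )
}

#' @export
print.section_mask <- function(x, ...) {
  cat("Section mask:", nrow(x$pixels), "x", ncol(x$pixels),
      "pixels,", format(x$pixel_size), "mm/pixel\n")
  cat("  cortical pixels:", sum(x$pixels),
      sprintf("(CA approx. %.1f mm^2)", sum(x$pixels) * x$pixel_size^2), "\n")
  cat("  side:", x$side, "\n")
  invisible(x)
}

#' Mirror a left-side section into right-side orientation
#'
#' Sections from left-side elements are reflected about the vertical
#' (superoinferior / anteroposterior) image axis so that the medial
#' direction matches right-side sections. Right-side and unknown-side
#' masks are returned unchanged. All geometric properties are invariant
#' under this reflection; only the sign conventions of the principal-axis
#' angle are affected.
#'
#' @param mask a [section_mask()]
#' @return a `section_mask` in right-side orientation
#' @export
normalize_side <- function(mask) {
  stopifnot(inherits(mask, "section_mask"))
  if (identical(mask$side, "left")) {
    mask$pixels <- mask$pixels[, rev(seq_len(ncol(mask$pixels))), drop = FALSE]
    mask$side <- "right"
  }
  mask
}

#' Read a segmented section image from PNG or TIFF
#'
#' Reads a single-channel (or first-channel) raster image in which nonzero
#' pixels mark cortical bone. Greyscale images can be binarized with a
#' fixed threshold; segmentation itself (in particular tracing the
#' endosteal boundary) is the caller's responsibility.
#'
#' Pixel size and side may be given directly or through a JSON sidecar
#' file (same path with extension `.json`) with fields `pixel_size_mm`,
#' `side` and optionally `axis_convention`; explicit arguments win.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file
#' @param pixel_size pixel edge length in mm (overrides the sidecar)
#' @param side `"left"`, `"right"` or `"unknown"` (overrides the sidecar)
#' @param threshold pixels with intensity strictly greater than this value
#'   are cortical; default 0 (any nonzero pixel)
#' @param sidecar optional explicit path to a JSON sidecar
#' @return a [section_mask()]
#' @export
read_section_mask <- function(path, pixel_size = NULL,
                              side = NULL, threshold = 0,
                              sidecar = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: '", ext, "' (use PNG or TIFF)")
  )
  if (length(dim(img)) == 3)
    img <- img[, , 1]
  meta <- list(axis_convention = "columns-ML")
  sc <- if (is.null(sidecar)) paste0(tools::file_path_sans_ext(path), ".json")
        else sidecar
  if (file.exists(sc)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading a JSON sidecar requires the 'jsonlite' package")
    meta <- utils::modifyList(meta, jsonlite::read_json(sc, simplifyVector = TRUE))
  }
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size_mm
  if (is.null(pixel_size))
    stop("'pixel_size' missing: give it directly or in a sidecar file")
  if (is.null(side)) side <- if (is.null(meta$side)) "unknown" else meta$side
  section_mask(img > threshold, pixel_size = pixel_size,
               axis_convention = meta$axis_convention, side = side)
}

#' Fixed-threshold binarization of a greyscale image matrix
#'
#' Thin helper for callers holding greyscale arrays in memory: pixels
#' strictly above `threshold` become cortical.
#'
#' @param img numeric matrix
#' @param threshold scalar threshold
#' @return logical matrix
#' @export
binarize_image <- function(img, threshold) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("'img' must be a numeric matrix")
  img > threshold
}
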