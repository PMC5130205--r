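#' Packaged reference tables for the A.L. 288-1 analysis
#'
#' Loads the two reference tables shipped with the package:
#'
#' * `"table1"`: cross-sectional diaphyseal properties of the A.L. 288-1
#'   ("Lucy") femur and humeri, 13 sections (element, side, percent of
#'   biomechanical length, TA, CA, %CA, Ix, Iy, Imax, Imin, J, Zx, Zy,
#'   Zp).
#' * `"table2"`: 26 comparative fossil specimens with sparse fields
#'   (taxon, specimen, date, femoral 50% and humeral 35% polar section
#'   moduli, articular breadths, femoral 80% A-P and M-L section moduli
#'   derived as SMA^0.73).
#'
#' Missing cells of the sparse fossil table are `NA`.
#'
#' @param name `"table1"` or `"table2"`
#' @return a data frame
#' @examples
#' t1 <- load_fixture("table1")
#' subset(t1, element == "femur" & location_pct == 50)
#' @export
load_fixture <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  file <- switch(name,
    table1 = "table1_al288_sections.csv",
    table2 = "table2_comparative_fossils.csv"
  )
  path <- system.file("extdata", file, package = "bonexs", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' A.L. 288-1 as a single comparative record
#'
#' Assembles the measurements of A.L. 288-1 used in the comparative
#' analyses into one record shaped like a row of the fossil table:
#' femoral 50% and humeral 35% polar section moduli from the packaged
#' section properties, the published articular breadths (femoral head
#' superoinferior 28.6 mm, proximal tibial M-L 50.2 mm, distal humeral
#' M-L 30.1 mm), and femoral 80% section moduli derived as SMA^0.73 to
#' match the convention applied to every specimen in proximal-femur shape
#' comparisons.
#'
#' @return a one-row data frame with the fossil-table columns
#' @export
al288_record <- function() {
  t1 <- load_fixture("table1")
  f50 <- t1[t1$element == "femur" & t1$location_pct == 50, ]
  h35 <- t1[t1$element == "humerus" & t1$side == "right" &
              t1$location_pct == 35, ]
  f80 <- t1[t1$element == "femur" & t1$location_pct == 80, ]
  data.frame(
    taxon = "Australopithecus afarensis",
    specimen = "A.L. 288-1",
    date_myr = 3.2,
    graph_no = NA_integer_,
    F50Zp = f50$Zp,
    H35Zp = h35$Zp,
    FHDSI = 28.6,
    TPLML = 50.2,
    HDARTML = 30.1,
    F80Zx = power_convert(f80$Ix, 0.73),
    F80Zy = power_convert(f80$Iy, 0.73),
    notes = "F80 moduli derived as SMA^0.73"
  )
}
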