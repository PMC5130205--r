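#' Run the comparative allometric analysis
#'
#' Orchestrates the end-to-end comparison of individual (fossil) records
#' against reference group samples, for any number of bivariate
#' comparisons. For every comparison and reference group it fits the RMA
#' line, evaluates the prediction band, and scores each fossil with both
#' variables present in SEE units together with an inside/outside-band
#' flag; for every pair of reference groups it runs the Quick Test for
#' elevation and the permutation test for slope equality.
#'
#' Fossils missing a needed variable for a comparison are skipped for
#' that comparison (recorded in `skipped`, with a warning), not an error:
#' comparisons are pairwise-complete per record, matching the sparse
#' structure of comparative fossil tables.
#'
#' @param groups named list of reference-sample data frames; each must
#'   contain the variable columns named in `comparisons` (rows with NA in
#'   either variable are dropped per comparison)
#' @param fossils data frame of individual records with a `specimen`
#'   column plus variable columns (e.g. [load_fixture]`("table2")`)
#' @param comparisons list of length-2 character vectors `c(x, y)` naming
#'   the predictor and response variables of each comparison
#' @param alpha two-sided level for the prediction band (default 0.05)
#' @param n_perm permutations for the slope-equality test (default 999)
#' @param seed optional integer seed for the permutation tests
#' @param log10 fit on log10 scale (default TRUE)
#' @return an object of class `comparative_analysis`: list of data
#'   frames `fits` (comparison, group, n, slope, intercept, r, SEE,
#'   %SEE), `deviations` (comparison, group, specimen, x, y, SEE-unit
#'   deviation, inside-band flag), `tests` (pairwise Quick Test and
#'   slope-test p-values, with the Quick Test exclusion tally) and
#'   `skipped` (fossil/comparison pairs lacking data)
#' @examples
#' groups <- default_synthetic_groups(seed = 42)
#' groups <- lapply(groups, function(g) data.frame(H35Zp = g$x, F50Zp = g$y))
#' fossils <- load_fixture("table2")
#' res <- run_comparative_analysis(groups, fossils,
#'                                 comparisons = list(c("H35Zp", "F50Zp")))
#' res$fits
#' @export
run_comparative_analysis <- function(groups, fossils, comparisons,
                                     alpha = 0.05, n_perm = 999,
                                     seed = NULL, log10 = TRUE) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("'groups' must be a named list of data frames")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  if (is.null(fossils))
    fossils <- data.frame(specimen = character(0))
  if (!"specimen" %in% names(fossils))
    stop("'fossils' must have a 'specimen' column")
  fits <- devs <- tests <- skip <- list()
  for (cmp in comparisons) {
    if (length(cmp) != 2 || cmp[1] == cmp[2])
      stop("each comparison must name two distinct variables")
    xv <- cmp[1]; yv <- cmp[2]
    cmp_id <- paste(yv, "~", xv)
    grp_fits <- list()
    for (g in names(groups)) {
      gd <- groups[[g]]
      if (!all(c(xv, yv) %in% names(gd)))
        stop("group '", g, "' lacks variable(s) for comparison ", cmp_id)
      d <- data.frame(x = gd[[xv]], y = gd[[yv]])
      d <- d[stats::complete.cases(d), ]
      fit <- rma(y ~ x, d, log10 = log10)
      grp_fits[[g]] <- list(fit = fit, data = d)
      fits[[length(fits) + 1]] <- data.frame(
        comparison = cmp_id, group = g, n = fit$n,
        slope = fit$coefficients[["slope"]],
        intercept = fit$coefficients[["intercept"]],
        r = fit$r, see = fit$see, pct_see = fit$pct_see
      )
      for (i in seq_len(nrow(fossils))) {
        fx <- if (xv %in% names(fossils)) fossils[[xv]][i] else NA
        fy <- if (yv %in% names(fossils)) fossils[[yv]][i] else NA
        if (is.na(fx) || is.na(fy)) {
          skip[[length(skip) + 1]] <- data.frame(
            comparison = cmp_id, specimen = fossils$specimen[i],
            reason = "missing variable")
          next
        }
        dev <- see_units(fit, fx, fy)
        band <- predict(fit, newdata = fx, interval = "prediction",
                        level = 1 - alpha, scale = "raw")
        devs[[length(devs) + 1]] <- data.frame(
          comparison = cmp_id, group = g, specimen = fossils$specimen[i],
          x = fx, y = fy, see_units = dev,
          inside_pi = fy >= band$lwr & fy <= band$upr
        )
      }
    }
    gn <- names(grp_fits)
    if (length(gn) > 1) {
      for (i in seq_len(length(gn) - 1)) {
        for (j in seq(i + 1, length(gn))) {
          qt <- quick_test(grp_fits[[gn[i]]]$data, grp_fits[[gn[j]]]$data,
                           log10 = log10)
          st <- slope_equality_test(grp_fits[[gn[i]]]$data,
                                    grp_fits[[gn[j]]]$data,
                                    n_perm = n_perm, seed = seed,
                                    log10 = log10)
          tests[[length(tests) + 1]] <- data.frame(
            comparison = cmp_id, group_a = gn[i], group_b = gn[j],
            quick_p = qt$p.value, quick_excluded = qt$excluded,
            slope_p = st$p.value
          )
        }
      }
    }
  }
  bind <- function(l, proto) {
    if (length(l) == 0) proto else do.call(rbind, l)
  }
  skipped <- bind(skip, data.frame(comparison = character(0),
                                   specimen = character(0),
                                   reason = character(0)))
  if (nrow(skipped) > 0)
    warning(nrow(skipped), " fossil/comparison pair(s) skipped for ",
            "missing variables", call. = FALSE)
  structure(
    list(
      fits = bind(fits, data.frame()),
      deviations = bind(devs, data.frame(
        comparison = character(0), group = character(0),
        specimen = character(0), x = numeric(0), y = numeric(0),
        see_units = numeric(0), inside_pi = logical(0))),
      tests = bind(tests, data.frame(
        comparison = character(0), group_a = character(0),
        group_b = character(0), quick_p = numeric(0),
        quick_excluded = integer(0), slope_p = numeric(0))),
      skipped = skipped,
      alpha = alpha
    ),
    class = "comparative_analysis"
  )
}

#' @export
print.comparative_analysis <- function(x, ...) {
  cat("Comparative allometric analysis\n")
  cat("  fits:\n")
  print(x$fits, digits = 4, row.names = FALSE)
  if (nrow(x$tests) > 0) {
    cat("  between-group tests:\n")
    print(x$tests, digits = 4, row.names = FALSE)
  }
  cat("  ", nrow(x$deviations), " fossil deviation row(s), ",
      nrow(x$skipped), " skipped\n", sep = "")
  invisible(x)
}

#' Write comparative-analysis results to CSV files
#'
#' Writes `fits.csv`, `deviations.csv`, `tests.csv` and (when non-empty)
#' `skipped.csv` into `dir`. Files are plain UTF-8 CSV with a header row
#' and "." decimal, so a write/read round trip reproduces the values
#' exactly at full double precision.
#'
#' @param results a [run_comparative_analysis()] result
#' @param dir output directory (created if absent)
#' @return character vector of files written, invisibly
#' @export
write_results_csv <- function(results, dir) {
  stopifnot(inherits(results, "comparative_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- character(0)
  for (nm in c("fits", "deviations", "tests", "skipped")) {
    d <- results[[nm]]
    if (nm == "skipped" && nrow(d) == 0) next
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(d, f, row.names = FALSE, quote = FALSE)
    out <- c(out, f)
  }
  invisible(out)
}
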