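#' Quick Test for an elevation difference between two bivariate samples
#'
#' Nonparametric test for a difference in elevation (intercept) between
#' two groups sharing a common allometry. A pooled RMA line is fitted to
#' the combined samples; each point is classified as lying above or below
#' the pooled line; and the resulting group-by-side 2x2 table is tested
#' with Fisher's exact test (two-sided). Points falling exactly on the
#' pooled line carry no elevation information and are excluded, with the
#' exclusion count reported.
#'
#' @param a,b data frames with columns `x` and `y`, one row per specimen
#' @param log10 log10-transform both variables before fitting (default
#'   TRUE; values must then be positive)
#' @return a list of class `quick_test` with `p.value`, `table` (2x2
#'   counts, groups in rows, below/above in columns), `excluded` (number
#'   of on-line points dropped) and `pooled_fit` (the pooled [rma()] fit)
#' @examples
#' g1 <- simulate_group(50, 1, 0.30, 0.05, c(2.5, 3.5), seed = 1)
#' g2 <- simulate_group(50, 1, 0.45, 0.05, c(2.5, 3.5), seed = 2)
#' quick_test(g1, g2)
#' @export
quick_test <- function(a, b, log10 = TRUE) {
  check_sample(a)
  check_sample(b)
  pooled <- rbind(a[c("x", "y")], b[c("x", "y")])
  fit <- rma(y ~ x, pooled, log10 = log10)
  res <- stats::residuals(fit)
  grp <- rep(c("a", "b"), c(nrow(a), nrow(b)))
  keep <- res != 0
  excluded <- sum(!keep)
  side <- factor(ifelse(res[keep] > 0, "above", "below"),
                 levels = c("below", "above"))
  tab <- table(group = factor(grp[keep], levels = c("a", "b")), side = side)
  p <- stats::fisher.test(tab)$p.value
  structure(
    list(p.value = p, table = tab, excluded = excluded, pooled_fit = fit,
         method = "Quick Test (pooled RMA line, Fisher exact, two-sided)"),
    class = "quick_test"
  )
}

#' @export
print.quick_test <- function(x, ...) {
  cat(x$method, "\n")
  print(x$table)
  cat(sprintf("p-value = %.4g", x$p.value))
  if (x$excluded > 0)
    cat(sprintf("   (%d point(s) on the line excluded)", x$excluded))
  cat("\n")
  invisible(x)
}

#' Permutation test for equality of RMA slopes
#'
#' Tests whether two groups share a common RMA slope by permuting group
#' labels: the observed statistic is `|slope_a - slope_b|` and the p-value
#' is the proportion of label permutations (plus one, for the observed
#' arrangement) whose statistic is at least as large.
#'
#' @param a,b data frames with columns `x` and `y`
#' @param n_perm number of permutations (at least 100; default 999)
#' @param seed optional integer seed; the RNG state is restored on exit
#' @param log10 log10-transform before fitting (default TRUE)
#' @return a list of class `slope_test` with `p.value`, `statistic` (the
#'   observed absolute slope difference), `slopes` (the two group slopes)
#'   and `n_perm`
#' @export
slope_equality_test <- function(a, b, n_perm = 999, seed = NULL,
                                log10 = TRUE) {
  check_sample(a)
  check_sample(b)
  if (n_perm < 100)
    stop("'n_perm' must be at least 100")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  lx <- c(a$x, b$x)
  ly <- c(a$y, b$y)
  if (log10) {
    if (any(lx <= 0) || any(ly <= 0))
      stop("all values must be strictly positive for log10 transformation")
    lx <- log10(lx)
    ly <- log10(ly)
  }
  na <- nrow(a)
  ntot <- length(lx)
  slope_of <- function(idx) {
    rma_slope(lx[idx], ly[idx])
  }
  ia <- seq_len(na)
  obs_a <- slope_of(ia)
  obs_b <- slope_of(-ia)
  obs <- abs(obs_a - obs_b)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    pa <- sample.int(ntot, na)
    stat <- abs(slope_of(pa) - slope_of(-pa))
    if (stat >= obs) exceed <- exceed + 1L
  }
  structure(
    list(p.value = (1 + exceed) / (1 + n_perm), statistic = obs,
         slopes = c(a = obs_a, b = obs_b), n_perm = n_perm,
         method = "Permutation test for RMA slope equality"),
    class = "slope_test"
  )
}

#' @export
print.slope_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  slopes: %.4g vs %.4g   |diff| = %.4g\n",
              x$slopes[["a"]], x$slopes[["b"]], x$statistic))
  cat(sprintf("  p-value = %.4g  (%d permutations)\n", x$p.value, x$n_perm))
  invisible(x)
}

# bare RMA slope on already-transformed data (internal fast path)
rma_slope <- function(lx, ly) {
  sx <- stats::sd(lx)
  sy <- stats::sd(ly)
  if (sx == 0 || sy == 0) stop("zero variance within a group")
  sign(stats::cor(lx, ly)) * sy / sx
}

check_sample <- function(d) {
  nm <- deparse(substitute(d))
  if (!is.data.frame(d) || !all(c("x", "y") %in% names(d)))
    stop("'", nm, "' must be a data frame with columns 'x' and 'y'")
  if (nrow(d) < 3)
    stop("'", nm, "' needs at least 3 rows (got ", nrow(d), ")")
  invisible(d)
}
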