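# Independent oracles used across the test files. These recompute expected
# values from first principles (raw moment sums, closed-form geometry,
# direct arithmetic) without calling the code paths they check.

# Definitional RMA oracle from raw moment sums.
oracle_rma <- function(x, y) {
  n <- length(x)
  sx2 <- (sum(x^2) - sum(x)^2 / n) / (n - 1)
  sy2 <- (sum(y^2) - sum(y)^2 / n) / (n - 1)
  sxy <- (sum(x * y) - sum(x) * sum(y) / n) / (n - 1)
  r <- sxy / sqrt(sx2 * sy2)
  b <- sign(r) * sqrt(sy2 / sx2)
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  list(b = b, a = a, r = r, see = sqrt(sum(res^2) / (n - 2)),
       xbar = mean(x), ssx = sum((x - mean(x))^2), n = n)
}

# Closed-form properties of a centered hollow ellipse (no offset, no
# rotation): the textbook formulas, written out independently of
# closed_form_properties().
oracle_hollow_ellipse <- function(ao, bo, ai, bi) {
  TA <- pi * ao * bo
  CA <- TA - pi * ai * bi
  Ix <- pi / 4 * (ao * bo^3 - ai * bi^3)
  Iy <- pi / 4 * (bo * ao^3 - bi * ai^3)
  J <- Ix + Iy
  list(TA = TA, CA = CA, pctCA = 100 * CA / TA, Ix = Ix, Iy = Iy, J = J,
       Zx = Ix / bo, Zy = Iy / ao, Zp = J / max(ao, bo))
}

# Relative-error comparison across the scalar property fields.
max_rel_err <- function(got, want,
                        fields = c("TA", "CA", "pctCA", "Ix", "Iy",
                                   "Imax", "Imin", "J", "Zx", "Zy", "Zp")) {
  max(vapply(fields,
             function(f) abs(got[[f]] - want[[f]]) / abs(want[[f]]),
             numeric(1)))
}

# Annulus mask built directly from pixel-center membership (independent
# of render_section): outer radius R, inner radius r, canal center
# shifted (sx, sy) in mm, y up.
make_annulus <- function(R, r = 0, sx = 0, sy = 0, p = 0.05, margin = 1) {
  half <- R + abs(sx) + abs(sy) + margin
  n <- ceiling(2 * half / p)
  u <- (seq_len(n) - (n + 1) / 2) * p
  xg <- matrix(u, n, n, byrow = TRUE)
  yg <- matrix(rev(u), n, n)
  px <- (xg^2 + yg^2 <= R^2)
  if (r > 0)
    px <- px & !((xg - sx)^2 + (yg - sy)^2 < r^2)
  section_mask(px, pixel_size = p)
}

# The grid of ellipse specs used by the raster-vs-analytic agreement
# suite: centered, eccentric-canal and rotated cases.
oracle_spec_grid <- function(pixel_size) {
  list(
    ellipse_section_spec(15, 10, 9, 6, pixel_size = pixel_size),
    ellipse_section_spec(15, 10, 9, 6, dx = 2, dy = -1.5,
                         pixel_size = pixel_size),
    ellipse_section_spec(15, 10, 9, 6, angle = 30, pixel_size = pixel_size),
    ellipse_section_spec(15, 10, 9, 6, dx = 1.5, dy = 1, angle = -40,
                         pixel_size = pixel_size),
    ellipse_section_spec(12, 12, 7, 7, pixel_size = pixel_size),
    ellipse_section_spec(12, 12, 7, 7, dx = 1, dy = 1,
                         pixel_size = pixel_size),
    ellipse_section_spec(14, 9, 8, 5, angle = 25, pixel_size = pixel_size),
    ellipse_section_spec(10, 10, 0, 0, pixel_size = pixel_size),
    ellipse_section_spec(9, 13, 5, 8, dy = 2, pixel_size = pixel_size),
    ellipse_section_spec(11, 8, 6, 4, dx = -2, angle = 60,
                         pixel_size = pixel_size)
  )
}
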