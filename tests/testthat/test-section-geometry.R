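test_that("fill_periosteal closes the medullary canal and keeps cortex unchanged", {
  ring <- make_annulus(8, 5, p = 0.1)
  filled <- fill_periosteal(ring)
  disc <- make_annulus(8, 0, p = 0.1)
  expect_identical(filled$pixels, disc$pixels)
  # cortical pixel set unchanged
  expect_true(all(filled$pixels[ring$pixels]))

  # solid section is a fixed point
  refill <- fill_periosteal(disc)
  expect_identical(refill$pixels, disc$pixels)
})

test_that("fill_periosteal rejects defective masks", {
  ring <- make_annulus(3, 2, p = 0.1)
  two <- section_mask(cbind(ring$pixels, ring$pixels), pixel_size = 0.1)
  expect_error(fill_periosteal(two), "disconnected")

  empty <- section_mask(matrix(FALSE, 10, 10), pixel_size = 0.1)
  expect_error(fill_periosteal(empty), "empty")
})

test_that("solid disc matches circle closed forms at fine raster", {
  m <- make_annulus(10, p = 0.05)
  pr <- compute_section_properties(m)
  expect_equal(pr$TA, pi * 100, tolerance = 0.002)
  expect_equal(pr$CA, pi * 100, tolerance = 0.002)
  expect_equal(pr$Ix, pi * 1e4 / 4, tolerance = 0.002)
  expect_equal(pr$Iy, pi * 1e4 / 4, tolerance = 0.002)
  expect_equal(pr$J, pi * 1e4 / 2, tolerance = 0.002)
  expect_equal(pr$Zx, pi * 1e3 / 4, tolerance = 0.005)
  expect_equal(pr$Zy, pi * 1e3 / 4, tolerance = 0.005)
  expect_equal(pr$Zp, pi * 1e3 / 2, tolerance = 0.005)
})

test_that("hollow-ellipse raster properties agree with the closed-form oracle within 1%", {
  want <- oracle_hollow_ellipse(15, 10, 9, 6)
  got <- compute_section_properties(
    render_section(ellipse_section_spec(15, 10, 9, 6, pixel_size = 0.05)))
  for (f in c("TA", "CA", "pctCA", "Ix", "Iy", "J", "Zx", "Zy", "Zp"))
    expect_lt(abs(got[[f]] - want[[f]]) / want[[f]], 0.01)
  # frozen expected values from the closed forms
  expect_equal(want$TA, 471.23890, tolerance = 1e-7)
  expect_equal(want$CA, 301.59289, tolerance = 1e-7)
  expect_equal(want$Ix, 10254.158, tolerance = 1e-7)
  expect_equal(want$Iy, 23071.857, tolerance = 1e-7)
  expect_equal(want$J, 33326.015, tolerance = 1e-7)
  expect_equal(want$Zx, 1025.4158, tolerance = 1e-7)
  expect_equal(want$Zy, 1538.1238, tolerance = 1e-7)
  expect_equal(want$Zp, 2221.7343, tolerance = 1e-7)
})

test_that("eccentric-canal section agrees with the composite-area oracle within 1%", {
  sp <- ellipse_section_spec(15, 10, 9, 6, dx = 2, dy = -1.5,
                             pixel_size = 0.05)
  got <- compute_section_properties(render_section(sp))
  want <- closed_form_properties(sp)
  expect_lt(max_rel_err(got, want), 0.01)
})

test_that("percent cortical area follows its definition and validates input", {
  expect_equal(percent_cortical_area(330.1, 197.6), 100 * 197.6 / 330.1)
  expect_equal(percent_cortical_area(100, 100), 100)
  expect_error(percent_cortical_area(100, 120), "exceeds")
  expect_error(percent_cortical_area(-1, 1), "positive")
  expect_error(percent_cortical_area(1, 0), "positive")
})

test_that("structural invariants hold: J decomposition, principal sum, mirror", {
  sp <- ellipse_section_spec(14, 9, 8, 5, dx = 1, dy = -0.5, angle = 25,
                             pixel_size = 0.05)
  pr <- compute_section_properties(render_section(sp))
  expect_identical(pr$J, pr$Ix + pr$Iy)
  expect_equal(pr$Imax + pr$Imin, pr$Ix + pr$Iy, tolerance = 1e-12)
  expect_gte(pr$Imax, pr$Imin)
  expect_true(all(c(pr$TA, pr$CA, pr$Ix, pr$Iy, pr$Imax, pr$Imin,
                    pr$J, pr$Zx, pr$Zy, pr$Zp) > 0))

  # left-right mirroring (side normalization) leaves all properties intact
  m <- render_section(sp)
  mirrored <- m
  mirrored$pixels <- m$pixels[, rev(seq_len(ncol(m$pixels)))]
  mirrored$side <- "left"   # normalize_side will mirror it back
  pm <- compute_section_properties(mirrored)
  for (f in c("TA", "CA", "Ix", "Iy", "Imax", "Imin", "J", "Zx", "Zy", "Zp"))
    expect_equal(pm[[f]], pr[[f]], tolerance = 1e-12)
})

test_that("quarter-turn rotation permutes properties exactly", {
  sp <- ellipse_section_spec(15, 10, 9, 6, dx = 2, dy = -1.5,
                             pixel_size = 0.1)
  m <- render_section(sp)
  r90 <- m
  r90$pixels <- t(m$pixels)[, rev(seq_len(nrow(m$pixels)))]  # rotate 90 deg
  a <- compute_section_properties(m)
  b <- compute_section_properties(r90)
  expect_identical(a$TA, b$TA)
  expect_identical(a$CA, b$CA)
  for (f in c("J", "Imax", "Imin", "Zp"))
    expect_equal(a[[f]], b[[f]], tolerance = 1e-12)
  expect_equal(a$Ix, b$Iy, tolerance = 1e-12)
  expect_equal(a$Iy, b$Ix, tolerance = 1e-12)
  expect_equal(a$Zx, b$Zy, tolerance = 1e-12)
  expect_equal(a$Zy, b$Zx, tolerance = 1e-12)
})

test_that("arbitrary rotation changes rotation-invariant properties by < 1%", {
  base <- ellipse_section_spec(15, 10, 9, 6, pixel_size = 0.05)
  rot <- ellipse_section_spec(15, 10, 9, 6, angle = 37, pixel_size = 0.05)
  a <- compute_section_properties(render_section(base))
  b <- compute_section_properties(render_section(rot))
  for (f in c("TA", "CA", "J", "Imax", "Imin"))
    expect_lt(abs(a[[f]] - b[[f]]) / a[[f]], 0.01)
})

test_that("halving pixel size reduces the raster error for every property", {
  sp_c <- ellipse_section_spec(15, 10, 9, 6, dx = 1, dy = 1,
                               pixel_size = 0.2)
  sp_f <- ellipse_section_spec(15, 10, 9, 6, dx = 1, dy = 1,
                               pixel_size = 0.1)
  want <- closed_form_properties(sp_c)
  coarse <- compute_section_properties(render_section(sp_c))
  fine <- compute_section_properties(render_section(sp_f))
  for (f in c("TA", "CA", "Ix", "Iy", "Imax", "Imin", "J",
              "Zx", "Zy", "Zp")) {
    e_c <- abs(coarse[[f]] - want[[f]])
    e_f <- abs(fine[[f]] - want[[f]])
    expect_lt(e_f, e_c)
  }
})

test_that("properties_from_stack preserves order and validates lengths", {
  m <- make_annulus(8, 5, p = 0.1)
  one <- properties_from_stack(list(m), offsets = 0)
  direct <- as.data.frame(compute_section_properties(m))
  expect_equal(one$TA, direct$TA)
  expect_equal(one$offset_mm, 0)

  three <- properties_from_stack(list(m, m, m), offsets = c(-1, 0, 1))
  expect_equal(three$offset_mm, c(-1, 0, 1))
  expect_true(all(three$J == three$J[1]))

  discs <- lapply(c(10, 9, 8), make_annulus, p = 0.1)
  shrink <- properties_from_stack(discs, offsets = c(-1, 0, 1))
  expect_true(all(diff(shrink$TA) < 0))
  expect_equal(shrink$TA, pi * c(100, 81, 64), tolerance = 0.005)

  expect_error(properties_from_stack(list(m, m), offsets = 0), "length")
})

test_that("rounded CSV output follows the reporting convention", {
  m <- make_annulus(8, 5, p = 0.1)
  props <- properties_from_stack(list(m), offsets = 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write_properties_csv(props, f)
  back <- read.csv(f)
  expect_equal(back$TA, round(props$TA, 1))
  expect_equal(back$Ix, round(props$Ix))
  expect_equal(back$Zp, round(props$Zp))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_properties_csv(props, f2, rounded = FALSE)
  expect_equal(read.csv(f2)$Zp, props$Zp)
})
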