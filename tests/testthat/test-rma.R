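test_that("collinear pre-logged data give slope 1, r 1, SEE 0", {
  d <- data.frame(x = c(0, 1, 2), y = c(0.3, 1.3, 2.3))
  f <- rma(y ~ x, d, log10 = FALSE)
  expect_equal(unname(coef(f)), c(0.3, 1), tolerance = 1e-12)
  expect_equal(f$r, 1, tolerance = 1e-12)
  expect_equal(f$see, 0, tolerance = 1e-12)
})

test_that("fit matches the definitional moment-sum oracle to 1e-10", {
  d <- data.frame(x = c(1, 2, 3, 4, 5), y = c(1.2, 1.9, 3.2, 3.8, 5.1))
  f <- rma(y ~ x, d, log10 = FALSE)
  o <- oracle_rma(d$x, d$y)
  expect_equal(coef(f)[["slope"]], o$b, tolerance = 1e-10)
  expect_equal(coef(f)[["intercept"]], o$a, tolerance = 1e-10)
  expect_equal(f$r, o$r, tolerance = 1e-10)
  expect_equal(f$see, o$see, tolerance = 1e-10)
  expect_equal(f$xbar, o$xbar, tolerance = 1e-10)
  expect_equal(f$ssx, o$ssx, tolerance = 1e-10)
  # frozen oracle values
  expect_equal(o$b, 0.9763, tolerance = 1e-4)
  expect_equal(o$a, 0.1110, tolerance = 1e-3)
  expect_equal(o$r, 0.9935, tolerance = 1e-4)

  # a noisier, larger seeded case on raw scale with log10 transform
  g <- simulate_group(120, 1.2, -0.5, 0.08, c(2, 3.5), seed = 5)
  f2 <- rma(y ~ x, g)
  o2 <- oracle_rma(log10(g$x), log10(g$y))
  expect_equal(coef(f2)[["slope"]], o2$b, tolerance = 1e-10)
  expect_equal(f2$see, o2$see, tolerance = 1e-10)
  expect_equal(f2$pct_see, (10^o2$see - 1) * 100, tolerance = 1e-10)
})

test_that("RMA is symmetric: swapping x and y gives the reciprocal slope", {
  g <- simulate_group(80, 0.8, 0.2, 0.05, c(2, 3), seed = 8)
  fxy <- rma(y ~ x, g)
  fyx <- rma(x ~ y, g)
  expect_equal(coef(fyx)[["slope"]], 1 / coef(fxy)[["slope"]],
               tolerance = 1e-12)
  expect_equal(fyx$r, fxy$r, tolerance = 1e-12)
})

test_that("scaling raw x by a constant shifts only the intercept", {
  g <- simulate_group(60, 1.1, 0.1, 0.06, c(2, 3), seed = 9)
  f1 <- rma(y ~ x, g)
  g2 <- g
  g2$x <- g2$x * 7
  f2 <- rma(y ~ x, g2)
  expect_equal(coef(f2)[["slope"]], coef(f1)[["slope"]], tolerance = 1e-12)
  expect_equal(f2$r, f1$r, tolerance = 1e-12)
  expect_equal(f2$see, f1$see, tolerance = 1e-10)
  expect_equal(coef(f2)[["intercept"]],
               coef(f1)[["intercept"]] - coef(f1)[["slope"]] * log10(7),
               tolerance = 1e-10)
})

test_that("degenerate samples are rejected", {
  expect_error(rma(y ~ x, data.frame(x = 1:2, y = 2:3)), "at least 3")
  expect_error(rma(y ~ x, data.frame(x = rep(2, 5), y = 1:5), log10 = FALSE),
               "zero variance")
  expect_error(rma(y ~ x, data.frame(x = c(1, 2, -3), y = c(1, 2, 3))),
               "positive")
})

test_that("SEE-unit deviations score points relative to the line", {
  g <- simulate_group(100, 1, 0.3, 0.05, c(2.5, 3.5), seed = 3)
  f <- rma(y ~ x, g)
  a <- coef(f)[["intercept"]]
  b <- coef(f)[["slope"]]
  xi <- 3
  on_line <- 10^(a + b * xi)
  expect_equal(see_units(f, 10^xi, on_line), 0, tolerance = 1e-10)
  expect_equal(see_units(f, 10^xi, 10^(a + b * xi + f$see)), 1,
               tolerance = 1e-10)
  expect_equal(see_units(f, 10^xi, 10^(a + b * xi - 2 * f$see)), -2,
               tolerance = 1e-10)

  degen <- rma(y ~ x, data.frame(x = c(0, 1, 2), y = c(0, 1, 2)),
               log10 = FALSE)
  expect_error(see_units(degen, 1, 1), "SEE is zero")
})

test_that("prediction band is symmetric, widens away from xbar, and has the right limit", {
  g <- simulate_group(50, 1, 0.3, 0.06, c(2.5, 3.5), seed = 4)
  f <- rma(y ~ x, g)
  d <- c(0.2, 0.5, 1, 2)
  expect_equal(pi_halfwidth(f, f$xbar + d), pi_halfwidth(f, f$xbar - d),
               tolerance = 1e-12)
  widths <- pi_halfwidth(f, f$xbar + c(0, d))
  expect_true(all(diff(widths) > 0))
  # band contains the line everywhere
  expect_true(all(widths > 0))

  # n -> infinity limit at xbar: t * sqrt(2) * SEE * b
  big <- f
  big$n <- 1e9
  big$ssx <- 1e9
  lim <- stats::qt(0.975, big$df) * sqrt(2) * big$see *
    abs(coef(big)[["slope"]])
  expect_equal(pi_halfwidth(big, big$xbar), lim, tolerance = 1e-6)

  expect_error(pi_halfwidth(f, 3, alpha = 1.2), "alpha")
})

test_that("halfwidth matches direct arithmetic on a fixed small fit", {
  f <- rma(y ~ x, data.frame(x = 1:10, y = 1:10 + 0.01 * (1:10 %% 3)),
           log10 = FALSE)
  # overwrite with the reference configuration
  f$n <- 10; f$df <- 8; f$see <- 0.05
  f$coefficients <- c(intercept = 0, slope = 1)
  f$xbar <- 2; f$ssx <- 4
  want <- qt(0.975, 8) * sqrt(2 * 0.05^2 * (1 + 1 / 10 + 1 / 4)) * 1
  expect_equal(pi_halfwidth(f, f$xbar + 1), want, tolerance = 1e-12)
})

test_that("predict returns the line and band on log and raw scales", {
  g <- simulate_group(100, 1, 0.3, 0.05, c(2.5, 3.5), seed = 6)
  f <- rma(y ~ x, g)
  xi <- c(400, 900)
  pl <- predict(f, xi, interval = "prediction")
  pr <- predict(f, xi, interval = "prediction", scale = "raw")
  expect_equal(10^pl$fit, pr$fit, tolerance = 1e-12)
  expect_equal(10^pl$lwr, pr$lwr, tolerance = 1e-12)
  expect_true(all(pl$lwr < pl$fit & pl$fit < pl$upr))
  point <- predict(f, xi)
  expect_equal(point, pl$fit, tolerance = 1e-12)
})

test_that("simulate() reproduces responses with the fitted dispersion", {
  g <- simulate_group(400, 1, 0.3, 0.05, c(2.5, 3.5), seed = 10)
  f <- rma(y ~ x, g)
  s1 <- simulate(f, nsim = 2, seed = 42)
  s2 <- simulate(f, nsim = 2, seed = 42)
  expect_identical(s1, s2)
  expect_equal(sd(s1$sim_1 - f$fitted), f$see, tolerance = 0.15)
})
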