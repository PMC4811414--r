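test_that("xyY -> XYZ follows the projective formula and its edge cases", {
  # equal-energy symmetry
  expect_equal(xyY_to_XYZ(1 / 3, 1 / 3, 100), data.frame(X = 100, Y = 100,
                                                         Z = 100))
  # direct formula evaluation
  expect_equal(xyY_to_XYZ(0.3, 0.6, 60), data.frame(X = 30, Y = 60, Z = 10))
  # zero luminance collapses to black regardless of chromaticity
  expect_equal(xyY_to_XYZ(0.4, 0.4, 0), data.frame(X = 0, Y = 0, Z = 0))
  expect_equal(xyY_to_XYZ(0, 0, 0), data.frame(X = 0, Y = 0, Z = 0))
  # undefined chromaticity
  expect_error(xyY_to_XYZ(0.4, 0, 10), "undefined chromaticity")
  expect_error(xyY_to_XYZ(0.7, 0.5, 10), "invalid chromaticity")
  expect_error(xyY_to_XYZ(NaN, 0.3, 10), "non-finite")
})

test_that("XYZ -> Lab maps white, black and mid-grey to the CIE values", {
  w <- c(95.047, 100, 108.883)
  expect_equal(XYZ_to_Lab(w[1], w[2], w[3], w),
               data.frame(L = 100, a = 0, b = 0))
  expect_equal(XYZ_to_Lab(0, 0, 0, w), data.frame(L = 0, a = 0, b = 0))
  # neutral 18% grey: L = 116 * 0.18^(1/3) - 16, a = b = 0
  grey <- XYZ_to_Lab(0.18 * w[1], 0.18 * w[2], 0.18 * w[3], w)
  expect_equal(grey$L, 116 * 0.18^(1 / 3) - 16, tolerance = 1e-12)
  expect_equal(grey$a, 0)
  expect_equal(grey$b, 0)
  expect_error(XYZ_to_Lab(NA, 1, 1, w), "non-finite")
  expect_error(XYZ_to_Lab(1, 1, 1, c(1, 0, 1)), "Y > 0")
})

test_that("Lab -> LCh handles quadrants, achromatic convention, round trip", {
  expect_equal(Lab_to_LCh(50, 0, 0), data.frame(L = 50, C = 0, h = 0))
  # 3-4-5 right triangle
  x <- Lab_to_LCh(50, 3, 4)
  expect_equal(x$C, 5)
  expect_equal(x$h, atan2(4, 3) * 180 / pi, tolerance = 1e-12)
  # third quadrant via atan2
  y <- Lab_to_LCh(50, -3, -4)
  expect_equal(y$C, 5)
  expect_equal(y$h, 360 - (180 - atan2(4, 3) * 180 / pi), tolerance = 1e-10)
  expect_equal(y$h, 233.13, tolerance = 1e-2)
  # round trip Lab -> LCh -> Lab for chromatic colours
  set.seed(1)
  a <- runif(50, -100, 100); b <- runif(50, -100, 100); L <- runif(50, 0, 100)
  lch <- Lab_to_LCh(L, a, b)
  back <- LCh_to_Lab(lch$L, lch$C, lch$h)
  expect_equal(back$a, a, tolerance = 1e-9)
  expect_equal(back$b, b, tolerance = 1e-9)
})

test_that("chroma is invariant under hue rotation; hue shifts by the angle", {
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1, -80, 80); b <- runif(1, -80, 80)
    if (a == 0 && b == 0) next
    theta <- runif(1, 0, 360)
    rad <- theta * pi / 180
    a2 <- a * cos(rad) - b * sin(rad)
    b2 <- a * sin(rad) + b * cos(rad)
    l1 <- Lab_to_LCh(50, a, b); l2 <- Lab_to_LCh(50, a2, b2)
    expect_equal(l2$C, l1$C, tolerance = 1e-9)
    expect_equal((l2$h - l1$h) %% 360, theta %% 360, tolerance = 1e-6)
  }
})

test_that("conversion chain matches the frozen scikit-image oracle", {
  orc <- read_colour_oracle()
  xyz <- xyY_to_XYZ(orc$x, orc$y, orc$Y)
  expect_equal(xyz$X, orc$X, tolerance = 1e-9)
  expect_equal(xyz$Z, orc$Z, tolerance = 1e-9)
  lab <- XYZ_to_Lab(xyz$X, xyz$Y, xyz$Z, skimage_white)
  expect_lt(max(abs(lab$L - orc$L)), 1e-6)
  expect_lt(max(abs(lab$a - orc$a)), 1e-6)
  expect_lt(max(abs(lab$b - orc$b)), 1e-6)
  lch <- Lab_to_LCh(lab$L, lab$a, lab$b)
  expect_lt(max(abs(lch$C - orc$C)), 1e-6)
  expect_lt(max(abs(lch$h - orc$h)), 1e-6)
})

test_that("display model maps white to the white point and black to zero", {
  m <- default_display_model()
  w <- rgb_to_XYZ(255, 255, 255, m)
  expect_equal(unname(unlist(w)), unname(m$white), tolerance = 1e-12)
  expect_equal(unname(unlist(rgb_to_XYZ(0, 0, 0, m))), c(0, 0, 0))
  expect_error(rgb_to_XYZ(300, 0, 0, m), "0, 255")
  expect_error(rgb_to_XYZ(-1, 0, 0, m), "0, 255")
  # red primary at full signal: first matrix column
  r <- rgb_to_XYZ(255, 0, 0, m)
  expect_equal(unname(unlist(r)), unname(m$M[, 1]), tolerance = 1e-12)
})

test_that("sRGB display model agrees with the frozen scikit-image sRGB path", {
  # the published sRGB matrix is rounded to six decimals; agreement is to
  # that rounding, not machine precision
  orc <- read_srgb_oracle()
  got <- rgb_to_XYZ(orc$r, orc$g, orc$b)
  expect_lt(max(abs(got$X - orc$X)), 0.05)
  expect_lt(max(abs(got$Y - orc$Y)), 0.05)
  expect_lt(max(abs(got$Z - orc$Z)), 0.05)
})

test_that("a pure-gamma model differs from sRGB only in the transfer", {
  m22 <- display_model(gamma = 2.2)
  m <- default_display_model()
  expect_equal(m22$M, m$M)
  expect_equal(unname(unlist(rgb_to_XYZ(255, 255, 255, m22))),
               unname(m22$white), tolerance = 1e-12)
  mid_srgb <- rgb_to_XYZ(128, 128, 128, m)$Y
  mid_22 <- rgb_to_XYZ(128, 128, 128, m22)$Y
  expect_false(isTRUE(all.equal(mid_srgb, mid_22)))
})

test_that("convert_choice composes the chain and prefers measured xyY", {
  m <- default_display_model()
  # white maps to L = 100, C = 0 (and h = 0 by the achromatic convention)
  wxy <- m$white / sum(m$white)
  res <- convert_choice(xyY = c(wxy[1], wxy[2], m$white[2]), model = m)
  expect_equal(res$L, 100, tolerance = 1e-9)
  expect_equal(res$C, 0, tolerance = 1e-9)
  expect_equal(res$h, 0)
  # compositionality: one-shot equals step-by-step
  v <- c(0.35, 0.4, 55)
  xyz <- xyY_to_XYZ(v[1], v[2], v[3])
  lab <- XYZ_to_Lab(xyz$X, xyz$Y, xyz$Z, m$white)
  step <- Lab_to_LCh(lab$L, lab$a, lab$b)
  one <- convert_choice(xyY = v, model = m)
  expect_equal(one[, c("L", "C", "h")], step)
  expect_equal(one$source, "xyY")
  # rgb route flagged as such, output satisfies LCh invariants
  set.seed(3)
  rgbs <- matrix(sample(0:255, 300, replace = TRUE), ncol = 3)
  out <- convert_choice(rgb = rgbs, model = m)
  expect_true(all(out$C >= 0))
  expect_true(all(out$h >= 0 & out$h < 360))
  expect_true(all(out$L >= -1e-9 & out$L <= 100 + 1e-9))
  expect_error(convert_choice(), "supply a colour")
})
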