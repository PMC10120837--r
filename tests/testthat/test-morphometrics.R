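make_disc <- function(r, scale = 0.01, pad = 15) {
  n <- 2 * r + 2 * pad
  c0 <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) ((i - c0)^2 + (j - c0)^2) <= r^2) * 1
}

test_that("size measurement matches analytic shapes", {
  # disc r = 100 px at 0.01 cm/px
  sz <- measureSize(make_disc(100), 0.01)
  expect_equal(sz$LA, pi, tolerance = 0.01)
  expect_equal(sz$LL, 2, tolerance = 0.01)
  expect_equal(sz$LW, 2, tolerance = 0.01)
  expect_equal(sz$LP, 2 * pi, tolerance = 0.02)

  # ellipse a = 200, b = 100 px; Ramanujan perimeter as the oracle
  n <- 460; c0 <- (n + 1) / 2
  ell <- outer(seq_len(n), seq_len(n),
               function(i, j) ((i - c0) / 200)^2 + ((j - c0) / 100)^2 <= 1) * 1
  sz <- measureSize(ell, 0.01)
  a <- 2; b <- 1; h <- ((a - b) / (a + b))^2
  ram <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  expect_equal(sz$LA, pi * a * b, tolerance = 0.02 * pi * a * b)
  expect_equal(sz$LP, ram, tolerance = 0.02 * ram)
  expect_equal(sz$LL / sz$LW, 2, tolerance = 0.02)

  # axis-aligned rectangle 300 x 100 px
  m <- matrix(0, 150, 350); m[26:125, 26:325] <- 1
  sz <- measureSize(m, 0.01)
  expect_equal(sz$LL, 3, tolerance = 0.011)
  expect_equal(sz$LW, 1, tolerance = 0.011)
})

test_that("degenerate masks are rejected with diagnostics", {
  expect_error(measureSize(matrix(0, 10, 10), 0.01), "empty")
  two <- matrix(0, 60, 60)
  two[5:15, 5:15] <- 1
  two[40:55, 40:55] <- 1
  expect_error(measureSize(two, 0.01), "2 connected components")
  expect_error(measureSize(make_disc(20), -1))
})

test_that("shape indices follow the defining formulas", {
  r <- 3
  circ <- deriveShape(LA = pi * r^2, LP = 2 * pi * r, LL = 2 * r, LW = 2 * r)
  expect_equal(circ$Cir, 1)
  expect_equal(circ$AR, 1)
  expect_equal(circ$Rect, pi / 4)

  s <- 2.5
  sq <- deriveShape(LA = s^2, LP = 4 * s, LL = s, LW = s)
  expect_equal(sq$Rect, 1)
  expect_equal(sq$Cir, pi / 4)

  # population-mean arithmetic: perimeter over length + width
  tbl <- deriveShape(LA = 128.68, LP = 48.57, LL = 15.50, LW = 13.49)
  expect_equal(tbl$P_LW, 48.57 / 28.99, tolerance = 1e-10)
  expect_equal(round(tbl$P_LW, 2), 1.68)

  expect_error(deriveShape(0, 1, 1, 1), "positive")
})

test_that("colour traits are masked channel means with the composite value", {
  mk <- matrix(1, 5, 5)
  img <- array(0, c(5, 5, 3))
  expect_equal(measureColor(img, mk)$CV, 0)
  img[] <- 128
  expect_equal(measureColor(img, mk)$CV, 65536 * 128 + 256 * 128 + 128)
  # fractional channel means
  img[, , 1] <- 88.5; img[, , 2] <- 122.5; img[, , 3] <- 61
  expect_equal(measureColor(img, mk)$CV, 5831357)
  expect_error(measureColor(img, matrix(0, 5, 5)), "empty")
  expect_error(measureColor(img, matrix(1, 4, 4)), "dimensions")
})

test_that("measurements agree with generator ground truth within raster tolerance", {
  spec <- leafShapeSpec(length = 8, width = 6, lobeCount = 5, lobeDepth = 0.25,
                        pixelScale = 0.02, noiseSd = 4)
  leaf <- generateLeafImage(spec, seed = 3)
  got <- measureLeaf(leaf$image, leaf$mask, spec$pixelScale, lobes = spec$lobeCount)
  for (tr in c("LA", "LP", "LL", "LW"))
    expect_equal(got[[tr]], leaf$truth[[tr]], tolerance = 0.02 * leaf$truth[[tr]],
                 label = tr)
  # colour means are near the spec colour (noise is zero-mean)
  expect_equal(got$R, 57, tolerance = 1)

  # error shrinks with resolution: area error strictly, the mean size-trait
  # error overall (perimeter error saturates at the tracer's ~0.3% bias floor)
  err_at <- function(scale) {
    s <- leafShapeSpec(length = 8, width = 6, lobeCount = 5, lobeDepth = 0.25,
                       pixelScale = scale, noiseSd = 0)
    l <- generateLeafImage(s, seed = 3)
    m <- measureSize(l$mask, scale)
    vapply(c("LA", "LP", "LL", "LW"),
           function(tr) abs(m[[tr]] / l$truth[[tr]] - 1), 0)
  }
  errs <- sapply(c(0.04, 0.02, 0.01), err_at)
  expect_true(all(errs < 0.02))
  expect_true(all(diff(errs["LA", ]) < 0))
  expect_lt(mean(errs[, 3]), mean(errs[, 1]))
})

test_that("shape indices are scale-invariant and sizes scale-equivariant", {
  spec <- leafShapeSpec(length = 6, width = 4, lobeCount = 4, lobeDepth = 0.2,
                        pixelScale = 0.02, noiseSd = 0)
  mask <- generateLeafImage(spec, seed = 1)$mask
  s1 <- measureSize(mask, 0.02)
  s2 <- measureSize(mask, 0.04)
  expect_equal(s2$LL, 2 * s1$LL)
  expect_equal(s2$LP, 2 * s1$LP)
  expect_equal(s2$LA, 4 * s1$LA)
  d1 <- deriveShape(s1$LA, s1$LP, s1$LL, s1$LW)
  d2 <- deriveShape(s2$LA, s2$LP, s2$LL, s2$LW)
  expect_equal(d1, d2)
})

test_that("measurement is rotation-invariant to within 1%", {
  # the same ellipse rasterized at several orientations
  rot_ell <- function(phi, a = 150, b = 80, n = 360) {
    c0 <- (n + 1) / 2
    outer(seq_len(n), seq_len(n), function(i, j) {
      x <- (i - c0) * cos(phi) + (j - c0) * sin(phi)
      y <- -(i - c0) * sin(phi) + (j - c0) * cos(phi)
      (x / a)^2 + (y / b)^2 <= 1
    }) * 1
  }
  base <- measureSize(rot_ell(0), 0.01)
  for (phi in c(0.4, 1.0, pi / 2)) {
    m <- measureSize(rot_ell(phi), 0.01)
    expect_equal(m$LL, base$LL, tolerance = 0.01 * base$LL)
    expect_equal(m$LW, base$LW, tolerance = 0.01 * base$LW)
    expect_equal(m$LP, base$LP, tolerance = 0.01 * base$LP)
  }
})

test_that("circularity never exceeds 1 beyond raster tolerance", {
  specs <- list(
    leafShapeSpec(length = 2, width = 2, lobeCount = 0, lobeDepth = 0, pixelScale = 0.005),
    leafShapeSpec(length = 5, width = 3, lobeCount = 0, lobeDepth = 0, pixelScale = 0.01),
    leafShapeSpec(length = 6, width = 5, lobeCount = 7, lobeDepth = 0.4, pixelScale = 0.01))
  for (sp in specs) {
    mask <- generateLeafImage(sp, seed = 2)$mask
    sz <- measureSize(mask, sp$pixelScale)
    cir <- deriveShape(sz$LA, sz$LP, sz$LL, sz$LW)$Cir
    expect_lte(cir, 1.02)
  }
})
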