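test_that("recombination follows the Haldane map function", {
  # d = 0: perfectly dependent columns
  H0 <- simulateGametes(500, c(10, 10), seed = 1)
  expect_equal(H0[, 1], H0[, 2])

  # d = 10 cM: empirical recombinant fraction ~ (1 - exp(-0.2))/2 = 0.0906
  H <- simulateGametes(10000, c(0, 10), seed = 42)
  rf <- mean(H[, 1] != H[, 2])
  expect_equal(rf, (1 - exp(-0.2)) / 2, tolerance = 0.12)
  expect_lt(abs(rf - haldane(10)), 3 * sqrt(0.0906 * (1 - 0.0906) / 10000))

  # dependence decays monotonically with distance and tracks Haldane r
  H2 <- simulateGametes(20000, c(0, 5, 20, 60), seed = 7)
  rhat <- sapply(2:4, function(j) mean(H2[, 1] != H2[, j]))
  expect_true(all(diff(rhat) > 0))
  expect_equal(rhat, haldane(c(5, 20, 60)), tolerance = 0.1)
})

test_that("testcross markers segregate 1:1 across seeds", {
  pass <- vapply(1:200, function(s) {
    H <- simulateGametes(179, 0, seed = s)
    counts <- c(sum(H == 0), sum(H == 1))
    suppressWarnings(stats::chisq.test(counts, p = c(0.5, 0.5))$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("simulated crosses have valid structure and seed determinism", {
  cx <- tiny_cross(seed = 9)
  expect_s4_class(cx$map, "LinkageMap")
  expect_s4_class(cx$geno, "GenotypeMatrix")
  expect_equal(nMarkers(cx$geno), 24L)
  # intercross markers segregate close to 1:2:1 at large n
  big <- simulateCross(crossSpec(nProgeny = 5000, linkageGroups = 1,
                                 markersPerGroup = 2, markerSpacing = 5,
                                 testcrossFraction = 0, seed = 2))
  counts <- table(genotypeCalls(big$geno)[, 1])[c("AA", "Aa", "aa")]
  p <- suppressWarnings(stats::chisq.test(counts, p = c(1, 2, 1) / 4)$p.value)
  expect_gt(p, 0.001)
  # determinism
  cx2 <- tiny_cross(seed = 9)
  expect_identical(genotypeCalls(cx$geno), genotypeCalls(cx2$geno))
  expect_error(crossSpec(markerSpacing = -1))
})

test_that("planted phenotypes match the variance decomposition", {
  cx <- tiny_cross(seed = 5)
  mk <- markerIds(cx$geno)[segregationType(cx$geno) == "testcross2"][1]
  sim <- simulatePhenotypes(cx$geno,
                            qtlSpec("LA", mk, c(0, 2), residualSd = 2, module = "size"),
                            seed = 5)
  expect_equal(sim$truth$LA$theoreticalPVE, 20)  # 1 / (1 + 4)
  expect_identical(
    traitValues(simulatePhenotypes(cx$geno, qtlSpec("LA", mk, c(0, 2),
                                                    residualSd = 2), seed = 5)$pheno),
    traitValues(sim$pheno))
  # equal class means -> pure noise with the declared sd
  null <- simulatePhenotypes(cx$geno, qtlSpec("x", mk, c(3, 3), residualSd = 1,
                                              module = "shape"), seed = 8)
  expect_equal(null$truth$x$theoreticalPVE, 0)
  expect_equal(sd(traitValues(null$pheno)[, "x"]), 1, tolerance = 0.2)
  expect_error(simulatePhenotypes(cx$geno, qtlSpec("y", "nope", c(0, 1))),
               "unknown marker")
})

test_that("leaf generator ground truth matches closed forms", {
  ell <- generateLeafImage(leafShapeSpec(length = 4, width = 2, lobeCount = 0,
                                         lobeDepth = 0, pixelScale = 0.01,
                                         noiseSd = 0))
  expect_equal(ell$truth$LA, pi * 2 * 1, tolerance = 1e-4)
  expect_equal(ell$truth$AR, 2, tolerance = 1e-6)

  circ <- generateLeafImage(leafShapeSpec(length = 2, width = 2, lobeCount = 0,
                                          lobeDepth = 0, pixelScale = 0.005,
                                          noiseSd = 0))
  expect_equal(circ$truth$Cir, 1, tolerance = 1e-4)

  # lobes add perimeter at equal area-scale
  lobed <- generateLeafImage(leafShapeSpec(length = 4, width = 2, lobeCount = 6,
                                           lobeDepth = 0.3, pixelScale = 0.01,
                                           noiseSd = 0))
  expect_gt(lobed$truth$LP / sqrt(lobed$truth$LA),
            ell$truth$LP / sqrt(ell$truth$LA))
  expect_equal(lobed$truth$LLo, 6)

  expect_error(leafShapeSpec(lobeDepth = 0.7), "0.6")
  expect_error(leafShapeSpec(lobeCount = 0, lobeDepth = 0.2), "lobeCount")
  expect_error(generateLeafImage(leafShapeSpec(length = 1, pixelScale = 0.02)),
               "200 px")
})

test_that("expression generator produces the declared cluster structure", {
  clean <- simulateExpression(nGenes = 12, noiseSd = 0, seed = 1,
                              clusterSpec = list(
                                list(size = 6, up = "leaf", down = "xylem"),
                                list(size = 6, up = "xylem", down = "leaf")))
  x <- fpkm(clean)
  expect_true(all(x >= 0))
  # noise-free: within-cluster pairwise r = 1
  within_r <- cor(t(x[1:6, ]))
  expect_equal(unname(within_r[upper.tri(within_r)]), rep(1, 15))
  # opposing templates: between-cluster r below within-cluster r
  between_r <- cor(x[1, ], x[7, ])
  expect_lt(between_r, min(within_r))
  # determinism and size guard
  noisy1 <- simulateExpression(noiseSd = 0.4, seed = 3)
  noisy2 <- simulateExpression(noiseSd = 0.4, seed = 3)
  expect_identical(fpkm(noisy1), fpkm(noisy2))
  expect_error(simulateExpression(nGenes = 10,
                                  clusterSpec = list(list(size = 11, up = "leaf",
                                                          down = character()))),
               "exceed")
})
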