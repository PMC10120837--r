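# Brute-force group-means oracle for the likelihood-ratio statistic.
lr_oracle <- function(y, cls) {
  mu <- tapply(y, cls, mean)
  rss1 <- sum((y - mu[cls])^2)
  rss0 <- sum((y - mean(y))^2)
  length(y) * log(rss0 / rss1)
}

test_that("single-marker ML fit matches the hand-computed oracle", {
  y <- c(1, 2, 1, 2, 3, 4, 3, 4)
  cls <- rep(c("aa", "ab"), each = 4)
  f <- fitMarkerModel(y, cls, minClassN = 4)
  expect_equal(f@means, c(aa = 1.5, ab = 3.5))
  expect_equal(f@sigma20 * f@n, 10)  # RSS0
  expect_equal(f@sigma2 * f@n, 2)    # RSS1
  expect_equal(f@LR, 8 * log(5))
  expect_equal(f@pve, 80)
  expect_equal(f@effects, c(delta = 2))

  # identical class means sample-wise: LR = 0, PVE = 0
  y0 <- c(1, 3, 1, 3, 2, 2, 1, 3, 1, 3, 2, 2)
  f0 <- fitMarkerModel(y0, rep(c("aa", "ab"), each = 6), minClassN = 4)
  expect_equal(f0@LR, 0)
  expect_equal(f0@pve, 0)

  # intercross effect definitions with exact class means
  y3 <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2)
  f3 <- fitMarkerModel(y3, rep(c("AA", "Aa", "aa"), each = 5),
                       labels = c("AA", "Aa", "aa"))
  expect_equal(f3@effects, c(a = 1, d = 0))
  expect_true(is.infinite(f3@LR))  # zero residual variance flag

  expect_error(fitMarkerModel(c(1, 2, 1), c("aa", "aa", "ab")),
               class = "leafqtl_sparse_class")
})

test_that("LR is affine-invariant and equals n*log(1/(1 - R2))", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    k <- sample(2:3, 1)
    cls <- sample(letters[1:k], n, replace = TRUE)
    while (min(table(cls)) < 5) cls <- sample(letters[1:k], n, replace = TRUE)
    y <- rnorm(n) + as.integer(factor(cls)) * runif(1, 0, 1)
    f <- fitMarkerModel(y, cls)
    expect_equal(f@LR, lr_oracle(y, cls))
    r2 <- summary(lm(y ~ factor(cls)))$r.squared
    expect_equal(f@LR, n * log(1 / (1 - r2)))
    expect_equal(f@pve, 100 * r2)
    # affine transform of y leaves LR and PVE unchanged
    g <- fitMarkerModel(3.7 * y - 11, cls)
    expect_equal(g@LR, f@LR)
    expect_equal(g@pve, f@pve)
  }
})

test_that("LR increases monotonically with the pooled two-sample t^2", {
  set.seed(33)
  stats_ <- t(replicate(30, {
    y <- rnorm(40)
    cls <- rep(c("aa", "ab"), 20)
    y[cls == "ab"] <- y[cls == "ab"] + runif(1, 0, 1.5)
    f <- fitMarkerModel(y, cls)
    tt <- t.test(y ~ cls, var.equal = TRUE)$statistic
    c(LR = f@LR, t2 = unname(tt^2))
  }))
  o <- order(stats_[, "t2"])
  expect_true(all(diff(stats_[o, "LR"]) > 0))
})

test_that("genome scan agrees marker-by-marker with the single fit", {
  cx <- tiny_cross(seed = 13, n = 100, lgs = 2, mpg = 6)
  mk <- markerIds(cx$geno)[4]
  sim <- simulatePhenotypes(cx$geno, qtlSpec("LA", mk, c(0, 1, 2)[seq_along(classLabels(cx$geno)[[4]])],
                                             residualSd = 1.5, module = "size"),
                            seed = 13)
  scan <- genomeScan(sim$pheno, cx$geno, cx$map, "LA")
  prof <- lrProfile(scan)
  y <- traitValues(sim$pheno)[, "LA"]
  for (j in sample(nrow(prof), 5)) {
    m <- prof$marker[j]
    f <- fitMarkerModel(y, genotypeCalls(cx$geno)[, m],
                        labels = classLabels(cx$geno)[[m]])
    expect_equal(prof$LR[j], f@LR, tolerance = 1e-8)
    expect_equal(prof$pve[j], f@pve, tolerance = 1e-8)
  }
  # profile is ordered along the map
  expect_equal(prof$marker, intersect(markerIds(cx$map), prof$marker))
})

test_that("duplicate markers at zero distance give identical LR", {
  cx <- simulateCross(crossSpec(nProgeny = 80, linkageGroups = 1,
                                markersPerGroup = 4, markerSpacing = 5,
                                testcrossFraction = 1, seed = 17))
  j <- which(segregationType(cx$geno) == "testcross2")[1]
  mk <- markerIds(cx$geno)[j]
  g <- genotypeCalls(cx$geno)
  g <- cbind(g, dup = g[, j])
  colnames(g)[5] <- "dup"
  geno2 <- GenotypeMatrix(g, c(segregationType(cx$geno),
                               dup = unname(segregationType(cx$geno)[j])))
  mt <- mapTable(cx$map)
  map2 <- LinkageMap(c(mt$marker, "dup"), c(mt$lg, mt$lg[mt$marker == mk]),
                     c(mt$pos, mt$pos[mt$marker == mk]))
  sim <- simulatePhenotypes(cx$geno, qtlSpec("LA", mk, c(0, 1),
                                             residualSd = 1), seed = 17)
  scan <- genomeScan(sim$pheno, geno2, map2, "LA")
  prof <- lrProfile(scan)
  expect_equal(prof$LR[prof$marker == "dup"], prof$LR[prof$marker == mk])
})

test_that("sparse classes and missing data are excluded, not silently used", {
  cx <- tiny_cross(seed = 19, n = 60, lgs = 1, mpg = 5)
  g <- genotypeCalls(cx$geno)
  g[1:58, 3] <- NA  # only 2 informative individuals at marker 3
  geno2 <- GenotypeMatrix(g, segregationType(cx$geno))
  tc1 <- markerIds(cx$geno)[segregationType(cx$geno) == "testcross2"][1]
  sim <- simulatePhenotypes(cx$geno, qtlSpec("LA", tc1, c(0, 1),
                                             residualSd = 1), seed = 19)
  scan <- genomeScan(sim$pheno, geno2, cx$map, "LA")
  expect_true(markerIds(cx$geno)[3] %in% scan@skipped$marker)
  expect_equal(unique(scan@skipped$reason), "sparse_class")
  expect_false(markerIds(cx$geno)[3] %in% lrProfile(scan)$marker)
})

test_that("permutation threshold follows the order-statistic convention", {
  expect_equal(thresholdFromMaxima(1:100, alpha = 0.05), 95)
  expect_equal(thresholdFromMaxima(sample(1:100), alpha = 0.05), 95)
  expect_equal(thresholdFromMaxima(1:100, alpha = 1), 1)  # minimum of maxima
  expect_equal(thresholdFromMaxima(c(3.2, 1.1, 7.8), alpha = 0.5), 3.2)

  cx <- tiny_cross(seed = 23, n = 90, lgs = 2, mpg = 8)
  tc1 <- markerIds(cx$geno)[segregationType(cx$geno) == "testcross2"][3]
  sim <- simulatePhenotypes(cx$geno, qtlSpec("LA", tc1,
                                             c(0, 1.2), residualSd = 1), seed = 23)
  scan <- genomeScan(sim$pheno, cx$geno, cx$map, "LA")
  thr <- permutationThreshold(scan, sim$pheno, cx$geno, cx$map,
                              nPerm = 200, alpha = 0.05, seed = 5)
  expect_equal(length(permutationMaxima(thr)), 200L)
  expect_equal(threshold(thr),
               thresholdFromMaxima(permutationMaxima(thr), 0.05))
  # reproducible given the seed
  thr2 <- permutationThreshold(scan, sim$pheno, cx$geno, cx$map,
                               nPerm = 200, alpha = 0.05, seed = 5)
  expect_identical(permutationMaxima(thr), permutationMaxima(thr2))
  # every call sits at or above the threshold
  calls <- qtlCalls(thr)
  expect_true(all(calls$LR >= threshold(thr)))
})

test_that("a planted QTL is recovered at or next to its marker", {
  cx <- tiny_cross(seed = 29, n = 179, lgs = 3, mpg = 10)
  mks <- markerIds(cx$geno)
  tc <- which(segregationType(cx$geno) == "testcross2")
  planted <- mks[tc[6]]
  # class-mean gap for ~20% theoretical PVE: delta = 2, sd = 2
  sim <- simulatePhenotypes(cx$geno, qtlSpec("LA", planted, c(0, 2), residualSd = 2),
                            seed = 29)
  scan <- genomeScan(sim$pheno, cx$geno, cx$map, "LA")
  prof <- lrProfile(scan)
  peak <- prof$marker[which.max(prof$LR)]
  planted_idx <- match(planted, mks)
  expect_true(match(peak, mks) %in% (planted_idx + (-1:1)))
})

test_that("co-location and Venn counts aggregate calls across modules", {
  cx <- tiny_cross(seed = 31, n = 179, lgs = 2, mpg = 8)
  tc <- markerIds(cx$geno)[segregationType(cx$geno) == "testcross2"]
  planted <- tc[2]
  # one pleiotropic QTL driving a size and a shape trait
  sim <- simulatePhenotypes(cx$geno, list(
    qtlSpec("LA", planted, c(0, 3), residualSd = 1.5, module = "size"),
    qtlSpec("Cir", planted, c(0, 0.4), residualSd = 0.2, module = "shape"),
    qtlSpec("R", planted, c(10, 10), residualSd = 3, module = "color")),
    seed = 31)
  scans <- lapply(c("LA", "Cir", "R"), function(tr) {
    s <- genomeScan(sim$pheno, cx$geno, cx$map, tr)
    permutationThreshold(s, sim$pheno, cx$geno, cx$map, nPerm = 100,
                         alpha = 0.05, seed = 7)
  })
  res <- callAndColocate(scans, traitModules(sim$pheno))
  expect_true(planted %in% res$calls$marker[res$calls$trait == "LA"])
  expect_true(planted %in% res$calls$marker[res$calls$trait == "Cir"])
  shared <- res$coloc[res$coloc$marker_a == res$coloc$marker_b, ]
  expect_true(any(shared$trait_a == "LA" & shared$trait_b == "Cir" |
                  shared$trait_a == "Cir" & shared$trait_b == "LA"))
  expect_gte(res$venn$size_shape, 1)
  expect_equal(res$venn$size_shape_color, 0)
  expect_error(callAndColocate(scans, c(LA = "size", Cir = "shape")), "R")
})
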