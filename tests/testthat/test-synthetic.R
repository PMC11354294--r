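test_that("hexagonal centre generation satisfies the packing identity", {
  # D = sqrt(2 / (sqrt(3) * density)): 43,951 cells/mm^2 -> 5.1257 um
  expect_equal(hexSpacing(43951), sqrt(2 / (sqrt(3) * 0.043951)),
               tolerance = 1e-12)
  expect_equal(hexSpacing(43951), 5.1257, tolerance = 1e-4)

  geom <- FieldGeometry()
  pts <- generateHexCenters(43951, geom, jitter = 0, seed = 1)
  expected <- 43951 * 1e-6 * 90^2          # ~356 cells
  expect_lt(abs(nrow(pts) - expected) / expected, 0.10)

  # jitter-free lattice: all nearest-neighbour distances equal D
  nn <- nnDistances(pts)
  expect_lt(max(abs(nn - hexSpacing(43951))) / hexSpacing(43951), 1e-6)

  # packing identity from the realized pattern: density = 2/(sqrt(3) D^2);
  # averaged over lattice phases since a single realization carries ~1 row
  # of edge granularity
  counts <- vapply(1:5, function(s)
    nrow(generateHexCenters(43951, geom, jitter = 0, seed = s)), 1L)
  measuredDensity <- mean(counts) / (90^2 * 1e-6)
  impliedDensity <- 2 / (sqrt(3) * hexSpacing(43951)^2) * 1e6
  expect_lt(abs(measuredDensity - impliedDensity) / impliedDensity, 0.03)
})

test_that("centre generation is deterministic and validates its inputs", {
  geom <- smallGeom()
  a <- generateHexCenters(40000, geom, jitter = 0.12, seed = 7)
  b <- generateHexCenters(40000, geom, jitter = 0.12, seed = 7)
  expect_identical(a, b)
  c <- generateHexCenters(40000, geom, jitter = 0.12, seed = 8)
  expect_false(identical(a, c))
  expect_true(all(a >= 0 & a <= sideLength(geom)))

  expect_error(generateHexCenters(-1, geom), "positive")
  expect_error(generateHexCenters(40000, geom, jitter = 0.5), "jitter")
  # 9-cell floor: 10x10 um field at 50 cells/mm^2 holds far fewer
  expect_error(generateHexCenters(50, FieldGeometry(10, 64L)),
               "too small")
})

test_that("area assignment reproduces the mixture calibration", {
  set.seed(1)
  centers <- cbind(runif(10000, 0, 90), runif(10000, 0, 90))

  cells <- assignAreas(centers, controlProfile(), seed = 2)
  m <- attr(cells, "sampleMean")
  expect_lt(abs(mean(cells$trueArea) - m) / m, 0.02)
  expect_true(all(cells$trueArea > 0))
  expect_identical(sum(cells$inflamed), 0L)

  allIn <- assignAreas(centers, diabeticProfile(inflamedFraction = 1),
                       seed = 3)
  expect_true(all(allIn$inflamed))

  # mixture conservation and component ordering
  mix <- assignAreas(centers, diabeticProfile(), seed = 4)
  mMix <- attr(mix, "sampleMean")
  se <- sd(mix$trueArea) / sqrt(nrow(mix))
  expect_lt(abs(mean(mix$trueArea) - mMix), 4 * se)
  expect_gt(mean(mix$trueArea[mix$inflamed]),
            mean(mix$trueArea[!mix$inflamed]))
  # inflamed/healthy component mean ratio ~ inflamedAreaRatio
  expect_equal(mean(mix$trueArea[mix$inflamed]) /
                 mean(mix$trueArea[!mix$inflamed]), 1.5, tolerance = 0.03)

  expect_error(assignAreas(centers[0, , drop = FALSE], controlProfile()),
               "non-empty")
})

test_that("rendering conserves blob area, handles empty fields, is seeded", {
  geom <- FieldGeometry()     # 0.17578 um/px
  px <- pixelSize(geom)
  one <- data.frame(cellId = 1L, x = 45, y = 45, trueArea = 9.70,
                    inflamed = FALSE)
  img <- renderMosaic(one, geom, noise = noiseFree(0.05), seed = 1)
  fg <- sum(intensities(img) > 0.5)
  expect_lt(abs(fg - 9.70 / px^2), 4)   # 9.70/px^2 = 313.9 pixels

  empty <- renderMosaic(one[0, ], geom, noise = noiseFree(0.07), seed = 1)
  expect_true(all(intensities(empty) == 0.07))

  noisy1 <- renderMosaic(one, geom, seed = 5)
  noisy2 <- renderMosaic(one, geom, seed = 5)
  expect_identical(intensities(noisy1), intensities(noisy2))

  # disjoint mosaic: total foreground area = sum of true areas +- 1 px/cell
  sp <- sparseMosaic()
  gt <- groundTruth(sp)
  fgArea <- sum(intensities(sp) > 0.5) * pixelSize(sp)^2
  expect_lt(abs(fgArea - sum(gt$trueArea)),
            nrow(gt) * pixelSize(sp)^2 * 3)

  # heavy overlap triggers the ground-truth degradation warning
  pair <- data.frame(cellId = 1:2, x = c(45, 45.4), y = c(45, 45),
                     trueArea = 10, inflamed = FALSE)
  expect_warning(renderMosaic(pair, geom, noise = noiseFree(), seed = 1),
                 "overlap")
})

test_that("study generation produces the full sampling grid deterministically", {
  geom <- smallGeom()
  profs <- list(control = controlProfile(), diabetic = diabeticProfile())
  study <- generateStudy(nPerGroup = 1, profiles = profs, geometry = geom,
                         seed = 9)
  expect_length(study, 32)    # 1 retina x 4 quadrants x 4 locations x 2

  onlyControl <- generateStudy(nPerGroup = 1,
                               profiles = list(control = controlProfile()),
                               geometry = geom, seed = 9)
  expect_length(onlyControl, 16)
  expect_true(all(vapply(onlyControl, groupLabel, "") == "control"))
  quads <- vapply(onlyControl, function(i) scheme(i)@quadrant, "")
  locs <- vapply(onlyControl, function(i) scheme(i)@locationIndex, 1L)
  expect_identical(sort(unique(quads)), sort(c("IN", "IT", "SN", "ST")))
  expect_identical(sort(unique(locs)), 1:4)

  again <- generateStudy(nPerGroup = 1, profiles = profs, geometry = geom,
                         seed = 9)
  expect_identical(lapply(study, intensities), lapply(again, intensities))

  expect_error(generateStudy(profiles = list(controlProfile())), "named")
  expect_error(
    generateStudy(nPerGroup = 1, geometry = geom,
                  profiles = list(control = list(controlProfile()))),
    "4 elements")
})
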