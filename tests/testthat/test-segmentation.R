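test_that("seeds land on true centres of clean mosaics", {
  img <- latticeImage(D = 6, geom = smallGeom(), area = 10, jitter = 0.08,
                      seed = 2)
  gt <- groundTruth(img)
  seeds <- detectSeeds(img)
  expect_equal(nrow(seeds), nrow(gt))
  # every seed within 1 um of a true centre
  d <- as.matrix(dist(rbind(seeds, cbind(gt$x, gt$y))))
  ns <- nrow(seeds)
  nearest <- apply(d[seq_len(ns), -(seq_len(ns)), drop = FALSE], 1, min)
  expect_lt(max(nearest), 1)
})

test_that("seed suppression and degenerate images behave as specified", {
  geom <- smallGeom()
  flat <- MosaicImage(matrix(0.3, 160, 160), geometry = geom)
  expect_message(seeds <- detectSeeds(flat), "constant")
  expect_equal(nrow(seeds), 0)

  close2 <- suppressWarnings(touchingDisks(gap = 3, geom = geom))
  expect_equal(nrow(detectSeeds(close2, minSeparation = 5)), 1)
  expect_equal(nrow(detectSeeds(close2, minSeparation = 2)), 2)
})

test_that("binarization separates two-level images and records thresholds", {
  geom <- smallGeom()
  img <- touchingDisks(gap = 10, geom = geom, noise = noiseFree(0))
  two <- MosaicImage(10 + 90 * (intensities(img) > 0.5), geometry = geom)
  blob <- intensities(two) == 100

  for (thrCase in list(list(m = "otsu", p = NULL),
                    list(m = "fixed", p = 50),
                    list(m = "percentile", p = 98))) {
    mask <- binarize(two, method = thrCase$m, parameter = thrCase$p)
    expect_identical(unname(maskMatrix(mask)), unname(blob),
                     info = thrCase$m)
    expect_true(thresholdValue(mask) > 10 && thresholdValue(mask) <= 100)
  }

  expect_warning(binarize(two, method = "fixed", parameter = 101),
                 "degenerate")
  flat <- MosaicImage(matrix(0.5, 160, 160), geometry = geom)
  expect_error(binarize(flat), "constant")

  # noisy mosaic: foreground fraction within 10% of true blob coverage
  noisy <- latticeImage(D = 6, geom = geom, jitter = 0.08, seed = 3,
                        noise = list(background = 0.08, gaussianSD = 0.05))
  truthCov <- mean(intensities(latticeImage(D = 6, geom = geom,
                                            jitter = 0.08, seed = 3)) > 0.5)
  fg <- mean(maskMatrix(binarize(noisy)))
  expect_lt(abs(fg - truthCov) / truthCov, 0.10)
})

test_that("marker-controlled watershed splits touching cells evenly", {
  img <- touchingDisks(gap = 3.5)
  gt <- groundTruth(img)
  mask <- binarize(img)
  lm <- segmentCells(img, mask, seeds = cbind(gt$x, gt$y))
  expect_equal(nCells(lm), 2L)
  cnt <- tabulate(labelMatrix(lm)[labelMatrix(lm) > 0], 2)
  expect_lt(abs(cnt[1] - cnt[2]) / mean(cnt), 0.02)

  # one seed on one of two disjoint disks: a single label, covering only
  # the seeded component
  one <- touchingDisks(gap = 12)
  m1 <- binarize(one)
  lm1 <- segmentCells(one, m1, seeds = cbind(x = 9, y = 15))
  expect_equal(nCells(lm1), 1L)
  expect_lt(sum(labelMatrix(lm1) > 0), sum(maskMatrix(m1)))

  # empty mask: empty LabelMap, reported
  dark <- MosaicImage(matrix(0.1, 160, 160), geometry = smallGeom())
  mEmpty <- suppressWarnings(binarize(dark, method = "fixed", parameter = 1))
  expect_message(lm0 <- segmentCells(dark, mEmpty, seeds = cbind(5, 5)),
                 "empty mask")
  expect_equal(nCells(lm0), 0L)

  # off-mask seeds are dropped with a warning
  expect_warning(
    segmentCells(img, mask, seeds = rbind(cbind(gt$x, gt$y), c(1, 1))),
    "dropped")
})

test_that("auto segmentation recovers the exact cell count on clean mosaics", {
  img <- sparseMosaic(seed = 4)
  seg <- segmentMosaic(img)
  expect_equal(nCells(seg$labelmap), nrow(groundTruth(img)))

  # distance-transform fallback also finds every disjoint cell
  lmD <- segmentCells(img, seg$mask, seeds = NULL)
  expect_equal(nCells(lmD), nrow(groundTruth(img)))
  expect_identical(lmD@seedMode, "distance")
})

test_that("measurements use exact pixel arithmetic and the border policy", {
  geom <- smallGeom()
  px <- pixelSize(geom)
  lab <- matrix(0L, 160, 160)
  lab[10:19, 20:29] <- 1L      # 100 px interior square
  lab[1, 1:5] <- 2L            # touches the raster border
  lm <- new("LabelMap", labels = lab, nCells = 2L, seedMode = "provided",
            parameters = list())

  all_ <- measureCells(lm, geom, excludeBorder = FALSE)
  expect_equal(nrow(all_), 2)
  expect_equal(all_$area[1], 100 * px^2)
  expect_equal(all_$area[2], 5 * px^2)
  expect_false(all_$touchesBorder[1])
  expect_true(all_$touchesBorder[2])
  # centroid of the interior square, in pixel-centre coordinates
  expect_equal(all_$x[1], mean((20:29 - 0.5) * px))
  expect_equal(all_$y[1], mean((10:19 - 0.5) * px))

  inner <- measureCells(lm, geom)    # default excludes border cells
  expect_equal(inner$cellId, 1L)

  empty <- new("LabelMap", labels = matrix(0L, 160, 160), nCells = 0L,
               seedMode = "auto", parameters = list())
  expect_equal(nrow(measureCells(empty, geom)), 0)
})

test_that("measured areas match ground truth on noise-free disjoint mosaics", {
  img <- sparseMosaic(seed = 5)
  gt <- groundTruth(img)
  seg <- segmentMosaic(img)
  meas <- seg$measurements
  # match labels to the nearest true centre
  d <- as.matrix(dist(rbind(cbind(meas$x, meas$y), cbind(gt$x, gt$y))))
  nm <- nrow(meas)
  nn <- apply(d[seq_len(nm), -(seq_len(nm)), drop = FALSE], 1, which.min)
  mare <- mean(abs(meas$area - gt$trueArea[nn]) / gt$trueArea[nn])
  expect_lt(mare, 0.05)
})

test_that("lowering a fixed threshold never shrinks a cell", {
  img <- sparseMosaic(seed = 6)
  seeds <- detectSeeds(img)
  prev <- NULL
  for (thr in c(0.8, 0.6, 0.4, 0.2)) {
    mask <- binarize(img, method = "fixed", parameter = thr)
    lm <- segmentCells(img, mask, seeds = seeds)
    meas <- measureCells(lm, geometry(img), excludeBorder = FALSE)
    meas <- meas[order(meas$x, meas$y), ]
    if (!is.null(prev)) {
      expect_equal(nrow(meas), nrow(prev))
      expect_true(all(meas$area >= prev$area - 1e-12))
    }
    prev <- meas
  }
})

test_that("cell count is stable across noise realizations at high SNR", {
  geom <- smallGeom()
  pts <- generateHexCenters(40000, geom, jitter = 0.1, seed = 10)
  cells <- assignAreas(pts, controlProfile(), seed = 10)
  counts <- vapply(1:5, function(s) {
    img <- renderMosaic(cells, geom,
                        noise = list(background = 0.08, gaussianSD = 0.05),
                        seed = s)
    nCells(suppressWarnings(segmentMosaic(img))$labelmap)
  }, 1L)
  expect_lt((max(counts) - min(counts)) / mean(counts), 0.02 * 2 + 1e-9)
})
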