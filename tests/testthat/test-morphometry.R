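test_that("cell density is count over field area", {
  expect_equal(round(cellDensity(data.frame(cellId = 1:356), 0.0081)), 43951)
  expect_equal(round(cellDensity(data.frame(cellId = 1:269), 0.0081)), 33210)
  expect_equal(cellDensity(data.frame(cellId = integer()), 0.0081), 0)
  expect_error(cellDensity(data.frame(cellId = 1), 0), "positive")
})

test_that("area statistics follow the sample conventions", {
  m <- data.frame(area = c(9, 10, 11), touchesBorder = FALSE)
  st <- areaStats(m)
  expect_equal(st$mean, 10)
  expect_equal(st$sd, 1)
  expect_equal(st$n, 3L)

  single <- areaStats(data.frame(area = 12.5, touchesBorder = FALSE))
  expect_equal(single$mean, 12.5)
  expect_equal(single$sd, 0)
  expect_false(single$sdDefined)

  border <- data.frame(area = c(9, 10, 11, 99),
                       touchesBorder = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(areaStats(border)$mean, 10)
  expect_equal(areaStats(border, excludeBorder = FALSE)$n, 4L)

  expect_error(areaStats(data.frame(area = numeric(),
                                    touchesBorder = logical())), "no cells")
})

test_that("inflammation fractions reproduce the worked example", {
  a <- c(8, 9, 11, 12, 15)
  expect_equal(inflamedCountFraction(a), 60)            # 3 of 5 above 10
  expect_equal(inflamedAreaFraction(a), 100 * 38 / 55)  # ~69.09%

  expect_equal(inflamedCountFraction(c(8, 9, 10)), 0)   # ties are healthy
  expect_equal(inflamedAreaFraction(c(11, 12)), 100)
  expect_equal(inflamedAreaFraction(c(8, 9)), 0)
  expect_error(inflamedCountFraction(numeric()), "no cells")
})

test_that("fractions are monotone in the threshold and scale-equivariant", {
  set.seed(42)
  a <- rlnorm(500, log(10), 0.3)
  thresholds <- seq(5, 20, by = 0.5)
  cf <- vapply(thresholds, function(t) inflamedCountFraction(a, t), 1)
  af <- vapply(thresholds, function(t) inflamedAreaFraction(a, t), 1)
  expect_true(all(diff(cf) <= 0))
  expect_true(all(diff(af) <= 0))

  for (c_ in c(0.5, 2, 7.3)) {
    expect_equal(inflamedCountFraction(a * c_, 10 * c_),
                 inflamedCountFraction(a, 10))
    expect_equal(inflamedAreaFraction(a * c_, 10 * c_),
                 inflamedAreaFraction(a, 10))
  }

  # area fraction dominates count fraction when inflamed cells are larger
  expect_gt(inflamedAreaFraction(a), inflamedCountFraction(a))
})

test_that("percent increase matches the published group contrast", {
  # 100 * (14.82 - 10.04) / 10.04 = 47.61..., printed as "48% on average"
  expect_equal(round(percentIncrease(10.04, 14.82)), 48)
  expect_equal(percentIncrease(10.04, 14.82), 100 * 4.78 / 10.04)
  expect_equal(percentIncrease(7, 7), 0)
  expect_equal(percentIncrease(10, 12.5), 25)
  expect_lt(percentIncrease(10, 8), 0)
  expect_error(percentIncrease(0, 5), "positive")
})

test_that("per-image metrics carry the image metadata and both policies", {
  img <- sparseMosaic(seed = 3)
  seg <- segmentMosaic(img)
  row <- mosaicMetrics(seg$measurements, image = img)
  expect_equal(row$nCells, nrow(seg$measurements))
  fieldArea <- (sideLength(img) * 1e-3)^2
  expect_equal(row$density, nrow(seg$measurements) / fieldArea)
  inner <- seg$measurements[!seg$measurements$touchesBorder, ]
  expect_equal(row$meanArea, mean(inner$area))
  expect_true(row$inflamedCountFraction >= 0 &&
              row$inflamedCountFraction <= 100)
})

test_that("metric aggregation is order-invariant with correct group counts", {
  set.seed(8)
  metrics <- do.call(rbind, lapply(1:8, function(i) data.frame(
    group = rep(c("control", "diabetic"), each = 4)[i],
    quadrant = "ST", locationIndex = ((i - 1) %% 4) + 1L,
    nCells = 100L, density = rnorm(1, 40000, 500),
    meanArea = rnorm(1, 12, 1), sdArea = 1,
    inflamedCountFraction = runif(1, 0, 100),
    inflamedAreaFraction = runif(1, 0, 100))))

  byGroup <- aggregateMetrics(metrics, keys = "group")
  expect_equal(nrow(byGroup), 2)
  expect_equal(byGroup$n, c(4L, 4L))
  expect_equal(byGroup$meanArea_mean[byGroup$group == "control"],
               mean(metrics$meanArea[metrics$group == "control"]))

  byBoth <- aggregateMetrics(metrics, keys = c("group", "locationIndex"))
  expect_equal(nrow(byBoth), 8)

  shuffled <- metrics[sample(nrow(metrics)), ]
  expect_equal(aggregateMetrics(shuffled, keys = c("group", "locationIndex")),
               byBoth)

  expect_error(aggregateMetrics(metrics, keys = "retina"), "unknown")
})

test_that("large synthetic samples recover the generator calibration", {
  set.seed(2)
  centers <- cbind(runif(10000, 0, 90), runif(10000, 0, 90))
  cells <- assignAreas(centers, controlProfile(), seed = 12)
  st <- areaStats(data.frame(area = cells$trueArea, touchesBorder = FALSE))
  se <- st$sd / sqrt(st$n)
  expect_lt(abs(st$mean - attr(cells, "sampleMean")), 2 * se)
})
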