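# Background estimation, adaptive threshold, cubic upsampling,
# iso-contouring, contour selection, inter-slice interpolation.

test_that("background estimation tracks the histogram mode", {
  expect_equal(estimateBackground(matrix(800, 10L, 10L)), 800)
  # 90% background ~ N(700, 20), 10% bright tube ~ N(3000, 20)
  set.seed(42)
  v <- c(rnorm(9000, 700, 20), rnorm(1000, 3000, 20))
  expect_lt(abs(estimateBackground(matrix(v, 100L)) - 700), 5)
  # bimodal with the larger mode dark: estimate follows the dark mode
  img <- matrix(c(rep(300, 600), rep(3500, 400)), 100L)
  expect_equal(estimateBackground(img), 300)
  expect_error(estimateBackground(matrix(NA_real_, 2L, 2L)), "empty")
})

test_that("background is stable across noise seeds at SNR 20", {
  # estimator SE scales with 1 / sqrt(background pixel count), so this is
  # a property of the acquisition FOV: rendered at the 256 x 256 in-plane
  # grid (margin 28.9 mm around the 7 mm tube)
  bs <- vapply(1:4, function(s) {
    ph <- idealizedPhantom(PhantomSpec(snr = 20, seed = s,
                                       marginMm = 28.9, axialLengthMm = 3))
    estimateBackground(volumeData(ph$volume)[, , 3L])
  }, numeric(1))
  expect_lt(max(bs) - min(bs), 2)
})

test_that("adaptive threshold follows the stated rule in both conventions", {
  ctx <- ThresholdContext(c(a = 650, b = 750), commonValue = 1000)
  expect_equal(ctx@cohortMean, 700)
  expect_equal(as.numeric(computeThreshold(ctx, "a")), 1050)  # literal
  ctx2 <- ThresholdContext(c(a = 650, b = 750), commonValue = 1000,
                           signConvention = "brightness_tracking")
  expect_equal(as.numeric(computeThreshold(ctx2, "a")), 950)
  # equal backgrounds: T = C under both conventions
  ctx3 <- ThresholdContext(c(a = 700, b = 700), commonValue = 1000)
  expect_equal(as.numeric(computeThreshold(ctx3, "a")), 1000)
  expect_equal(attr(computeThreshold(ctx2, "b"), "convention"),
               "brightness_tracking")
  expect_error(computeThreshold(ctx, "zz"), "unknown scan")
})

test_that("cubic upsampling is identity at factor 1 and exact on ramps", {
  m <- matrix(runif(48), 6L, 8L)
  expect_identical(upsampleSlice(m, 1L), m)
  ramp <- outer(seq_len(9L), seq_len(11L), function(i, j) 3 * i + 5 * j)
  up <- upsampleSlice(ramp, 4L)
  # cubic convolution reproduces linear functions exactly
  iOut <- (seq_len(nrow(up)) - 1L) / 4 + 1
  jOut <- (seq_len(ncol(up)) - 1L) / 4 + 1
  expect_equal(up, outer(iOut, jOut, function(i, j) 3 * i + 5 * j),
               tolerance = 1e-12)
  # original pixel centers preserved
  expect_equal(up[seq(1L, nrow(up), 4L), seq(1L, ncol(up), 4L)], ramp,
               tolerance = 1e-12)
  expect_error(upsampleSlice(m, 0L), "integer >= 1")
})

test_that("cubic upsampling matches a direct convolution oracle incl. step overshoot", {
  # oracle: evaluate the Catmull-Rom kernel sum directly per output sample
  keys <- function(x) {
    x <- abs(x)
    ifelse(x <= 1, 1.5 * x^3 - 2.5 * x^2 + 1,
           ifelse(x < 2, -0.5 * x^3 + 2.5 * x^2 - 4 * x + 2, 0))
  }
  set.seed(3)
  v <- c(rep(0, 5), rep(1, 5)) + rnorm(10, 0, 0.05)
  # boundary handling: linearly extrapolated virtual samples at each end
  vPad <- c(2 * v[1L] - v[2L], v, 2 * v[10L] - v[9L])
  m <- matrix(v, nrow = 10L, ncol = 3L)
  up <- upsampleSlice(m, 3L)
  u <- (seq_len(nrow(up)) - 1L) / 3
  oracle <- vapply(u, function(pos) {
    base <- min(floor(pos), 8)
    taps <- base + (-1:2)
    sum(vPad[taps + 2L] * keys(pos - taps))
  }, numeric(1))
  expect_equal(up[, 2L], oracle, tolerance = 1e-12)
  # pure step edge: over/undershoot bounded by the Catmull-Rom step
  # response extremum, max |(f^3 - f^2)/2| = 2/27
  step <- matrix(rep(c(0, 1), each = 5L), nrow = 10L, ncol = 4L)
  upS <- upsampleSlice(step, 4L)
  expect_lte(max(upS), 1 + 2 / 27 + 1e-12)
  expect_gte(min(upS), -2 / 27 - 1e-12)
})

test_that("iso-contouring recovers disks and annuli, discards border hits", {
  expect_length(extractContours(matrix(500, 30L, 30L), 1850), 0L)
  d <- diskSlice(n = 64L, r = 2)
  cts <- extractContours(d$slice, 1850, pixelSizeMm = d$px)
  expect_length(cts, 1L)
  expect_equal(polygonArea(cts[[1L]]), 4 * pi, tolerance = 0.02 * 4 * pi)
  # annulus: bright ring gives two nested contours
  ann <- d
  x <- (seq_len(64L) - 1L) * d$px
  d2 <- outer(x, x, function(a, b) (a - d$center[1L])^2) +
    t(outer(x, x, function(a, b) (a - d$center[2L])^2))
  ring <- matrix(700, 64L, 64L)
  ring[d2 <= 3^2 & d2 >= 1.5^2] <- 3000
  cts2 <- extractContours(ring, 1850, pixelSizeMm = d$px)
  expect_length(cts2, 2L)
  areas <- sort(vapply(cts2, polygonArea, numeric(1)))
  expect_equal(areas, pi * c(1.5^2, 3^2), tolerance = 0.05 * pi * 9)
  # region clipped by the border yields an open contour, which is dropped
  half <- matrix(700, 20L, 20L)
  half[1:10, ] <- 3000
  expect_length(extractContours(half, 1850, pixelSizeMm = 0.25), 0L)
})

test_that("ON/ONS selection filters by point count and roundness", {
  d <- diskSlice(n = 80L, r = 1.675)
  x <- (seq_len(80L) - 1L) * d$px
  d2 <- outer(x, x, function(a, b) (a - d$center[1L])^2) +
    t(outer(x, x, function(a, b) (a - d$center[2L])^2))
  img <- matrix(700, 80L, 80L)
  img[d2 <= 3.35^2 & d2 >= 1.675^2] <- 3000  # CSF annulus
  # a long thin vessel-like streak (low Q)
  img[4:75, 4:6] <- 3000
  cts <- extractContours(img, 1850, pixelSizeMm = d$px)
  expect_gte(length(cts), 3L)
  pair <- selectOnOnsContours(cts, minPoints = 20, qMin = 0.6)
  expect_lt(polygonArea(pair$on), polygonArea(pair$ons))
  expect_equal(polygonArea(pair$on), pi * 1.675^2,
               tolerance = 0.05 * pi * 1.675^2)
  expect_gt(isoperimetricQuotient(pair$ons), 0.6)
  # single contour: no pair
  one <- extractContours(d$slice, 1850, pixelSizeMm = d$px)
  expect_error(selectOnOnsContours(one), "1 filter survivor")
  # two disjoint round contours: nesting required
  two <- matrix(700, 80L, 80L)
  two[d2 <= 1.2^2] <- 3000
  two[(outer(x, x, function(a, b) (a - 2)^2) +
         t(outer(x, x, function(a, b) (a - 8)^2))) <= 1.2^2] <- 3000
  cts3 <- extractContours(two, 1850, pixelSizeMm = d$px)
  expect_error(selectOnOnsContours(cts3), "ON/ONS not found")
})

test_that("contour interpolation blends radii linearly between slices", {
  mkCircle <- function(r, z) Contour(regularPolygon(128L, r,
                                                    center = c(5, 5)),
                                     slicePosition = z)
  perSlice <- list(
    list(slicePosition = 2.4, on = mkCircle(1.5, 2.4),
         ons = mkCircle(2, 2.4)),
    list(slicePosition = 3.6, on = mkCircle(1.5, 3.6),
         ons = mkCircle(3, 3.6)))
  m <- interpolateContourAtOffset(perSlice, onHead = c(5, 5, 0),
                                  offsetMm = 3)
  v <- measurementValues(m)
  # midway: ONS radius 2.5 -> area 6.25 pi (slight deficit: 128-gon)
  expect_equal(v[["ons_area_mm2"]], 6.25 * pi, tolerance = 0.002 * 6.25 * pi)
  expect_equal(v[["on_area_mm2"]], 1.5^2 * pi, tolerance = 0.002 * 2.25 * pi)
  # identical contours on both slices -> identical output
  perSame <- list(
    list(slicePosition = 2.4, on = mkCircle(1.5, 2.4), ons = mkCircle(2, 2.4)),
    list(slicePosition = 3.6, on = mkCircle(1.5, 3.6), ons = mkCircle(2, 3.6)))
  m2 <- interpolateContourAtOffset(perSame, c(5, 5, 0), 3)
  expect_equal(measurementValues(m2)[["ons_area_mm2"]],
               polygonArea(mkCircle(2, 0)), tolerance = 1e-9)
  # target exactly on a measured slice: returned unchanged
  m3 <- interpolateContourAtOffset(perSlice, c(5, 5, 0.6), offsetMm = 3)
  expect_identical(contourPoints(onsContour(m3)),
                   contourPoints(perSlice[[2L]]$ons))
  # out-of-range target is rejected with the coverage
  expect_error(interpolateContourAtOffset(perSlice, c(5, 5, 10), 3),
               "outside the measured range")
  # area mode blends scalar areas exactly
  m4 <- interpolateContourAtOffset(perSlice, c(5, 5, 0), 3, mode = "area")
  expect_equal(measurementValues(m4)[["ons_area_mm2"]],
               mean(c(polygonArea(mkCircle(2, 0)),
                      polygonArea(mkCircle(3, 0)))), tolerance = 1e-12)
})

test_that("measureVolume recovers phantom geometry end to end", {
  ph <- idealizedPhantom(PhantomSpec())
  res <- measureVolume(ph$volume, ph$truth$on_head_mm)
  v <- measurementValues(res$measurement)
  onTrue <- pi * (3.35 / 2)^2
  onsTrue <- pi * (6.7 / 2)^2
  expect_lt(abs(v[["on_area_mm2"]] - onTrue) / onTrue, 0.03)
  expect_lt(abs(v[["ons_area_mm2"]] - onsTrue) / onsTrue, 0.03)
  expect_equal(v[["on_diameter_mm"]],
               equivalentDiameter(v[["on_area_mm2"]]))
  # hard invariant: ON < ONS on every accepted slice
  expect_true(all(res$sliceTable$on_area_mm2 < res$sliceTable$ons_area_mm2))
  # recovered taper: equivalent ONS diameter vs z has slope -0.1 mm/mm
  fit <- stats::lm(equivalentDiameter(ons_area_mm2) ~ slice_position_mm,
                   data = res$sliceTable)
  expect_lt(abs(stats::coef(fit)[[2L]] + 0.1), 0.01)
  # provenance echoes the resolved parameters
  expect_equal(res$parameters$upsample_factor, 4L)
  expect_equal(res$threshold, 1850, tolerance = 1e-9)
  # ON head outside the grid is rejected
  expect_error(measureVolume(ph$volume, c(-5, 0, 0)), "outside the volume")
})

test_that("threshold choice within the CSF contrast moves ONS area predictably little", {
  ph <- idealizedPhantom(PhantomSpec())
  onsTrue <- pi * (6.7 / 2)^2
  # the partial-volume edge is one in-plane voxel wide, so sweeping the
  # threshold across a fraction q of the fat-CSF contrast shifts the
  # contour by q * 0.253 mm radially: bounded by 2 pi r q dx / A
  areas50 <- vapply(c(1275, 1850, 2425), function(C) {
    r <- measureVolume(ph$volume, ph$truth$on_head_mm, commonValue = C,
                       zRangeMm = c(1.8, 4.2))
    measurementValues(r$measurement)[["ons_area_mm2"]]
  }, numeric(1))
  bound50 <- 2 * pi * 3.35 * 0.5 * 0.253 / onsTrue  # ~7.5%
  expect_lt((max(areas50) - min(areas50)) / onsTrue, 1.3 * bound50)
  # across the middle quarter of the contrast the change is < 5%
  areas25 <- vapply(c(1562.5, 2137.5), function(C) {
    r <- measureVolume(ph$volume, ph$truth$on_head_mm, commonValue = C,
                       zRangeMm = c(1.8, 4.2))
    measurementValues(r$measurement)[["ons_area_mm2"]]
  }, numeric(1))
  expect_lt(abs(diff(areas25)) / onsTrue, 0.05)
})

test_that("doubling voxel spacing doubles diameters and quadruples areas", {
  base <- PhantomSpec(spacing = c(0.3, 0.3, 0.75))
  ph1 <- idealizedPhantom(base)
  r1 <- measureVolume(ph1$volume, ph1$truth$on_head_mm,
                      zRangeMm = c(1.5, 4.5))
  # same intensity grid with doubled spacing: the object is twice as large
  vol2 <- ImageVolume(volumeData(ph1$volume),
                      spacing = 2 * voxelSpacing(ph1$volume))
  r2 <- measureVolume(vol2, 2 * ph1$truth$on_head_mm, offsetMm = 6,
                      zRangeMm = c(3, 9))
  v1 <- measurementValues(r1$measurement)
  v2 <- measurementValues(r2$measurement)
  expect_equal(v2[["ons_area_mm2"]] / v1[["ons_area_mm2"]], 4,
               tolerance = 1e-6)
  expect_equal(v2[["on_diameter_mm"]] / v1[["on_diameter_mm"]], 2,
               tolerance = 1e-6)
})

test_that("measurement JSON carries values, threshold, and provenance", {
  ph <- idealizedPhantom(fastSpec())
  res <- measureVolume(ph$volume, ph$truth$on_head_mm, upsampleFactor = 4L)
  rec <- jsonlite::fromJSON(measurementToJSON(res))
  expect_equal(rec$measurement$ons_area_mm2,
               measurementValues(res$measurement)[["ons_area_mm2"]])
  expect_equal(rec$parameters$sign_convention, "literal")
  expect_equal(rec$threshold, 1850)
})
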