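test_that("local variance map equals the brute-force window variance", {
  # constant image -> all-zero map
  expect_true(all(localVarianceMap(matrix(3, 9, 9), 2) == 0))

  # random 7x7, r = 1: every interior pixel matches the explicit loop
  set.seed(11)
  img <- matrix(runif(49, 0, 255), 7, 7)
  v <- localVarianceMap(img, 1)
  bf <- bfVariance(img, 1)
  idx <- which(!is.na(bf))
  expect_lt(max(abs(v[idx] - bf[idx]) / bf[idx]), 1e-9)

  # larger window against the same oracle
  img2 <- matrix(rnorm(15 * 13, 100, 20), 15, 13)
  v2 <- localVarianceMap(img2, 3)
  bf2 <- bfVariance(img2, 3)
  idx2 <- which(!is.na(bf2))
  expect_lt(max(abs(v2[idx2] - bf2[idx2]) / bf2[idx2]), 1e-9)

  # step edge: maximal variance on the edge, zero far from it
  step <- cbind(matrix(0, 10, 5), matrix(100, 10, 5))
  vs <- localVarianceMap(step, 1)
  expect_equal(vs[5, 2], 0)
  expect_equal(vs[5, 9], 0)
  expect_gt(vs[5, 5], 0)
  expect_equal(vs[5, 5], var(as.vector(step[4:6, 4:6])))
})

test_that("segmentFrame finds rendered spots and applies the gates", {
  # blank noisy field -> nothing detected at default sensitivity
  blank <- renderFrame(emptyCellTable(), frameSpec(200, 200),
                       renderParams(noise_sd = 5), seed = 5)
  expect_equal(nrow(segmentFrame(blank)), 0)

  # 10 well-separated noiseless spots -> 10 records within 1 px of truth
  # (kept away from the frame border so no spot is truncated)
  arena <- rectArena(720, 720, origin = c(30, 30))
  pop <- makePopulation(arena, 10, 0, min_separation = 150, seed = 8)
  spec <- frameSpec(640, 640)
  img <- renderFrame(pop, spec, renderParams(noise_sd = 0))
  det <- segmentFrame(img)
  expect_equal(nrow(det), 10)
  for (i in seq_len(10)) {
    d <- min(sqrt((pop$x_um - det$x_um[i])^2 +
                    (pop$y_um - det$y_um[i])^2))
    expect_lt(d, spec@pixel_size)
  }

  # raising one spot's brightness above max_brightness drops exactly it
  pop2 <- pop
  pop2$brightness[4] <- pop2$brightness[4] * 3
  img2 <- renderFrame(pop2, spec, renderParams(noise_sd = 0))
  det2 <- segmentFrame(img2)
  expect_equal(nrow(det2), 10)
  bright <- det2$brightness
  cut <- (max(bright) + max(bright[-which.max(bright)])) / 2
  det3 <- segmentFrame(img2, detectionParams(max_brightness = cut))
  expect_equal(nrow(det3), 9)

  # records come sorted by y then x
  expect_true(!is.unsorted(det$y_um))
})

test_that("detection count is monotone in the min filters and the map is
          shift-invariant", {
  pop <- makePopulation(rectArena(700, 700), 8, 0, min_separation = 140,
                        seed = 12)
  pop$brightness <- seq(60, 200, length.out = 8)
  spec <- frameSpec(560, 560)
  img <- renderFrame(pop, spec, renderParams(noise_sd = 0))

  counts_b <- vapply(c(0, 20, 40, 60, 80),
                     function(b) nrow(segmentFrame(
                       img, detectionParams(min_brightness = b))), 0)
  expect_true(all(diff(counts_b) <= 0))

  counts_s <- vapply(c(0, 10, 18, 25, 40),
                     function(s) nrow(segmentFrame(
                       img, detectionParams(min_size = s))), 0)
  expect_true(all(diff(counts_s) <= 0))

  # adding a constant leaves the variance map (hence detections) unchanged
  # once the brightness gate is widened accordingly
  img_shift <- img + 40L
  attr(img_shift, "spec") <- spec
  d0 <- segmentFrame(img, detectionParams(max_brightness = Inf))
  d1 <- segmentFrame(img_shift, detectionParams(max_brightness = Inf))
  expect_equal(nrow(d1), nrow(d0))
  # centroids move only marginally (constant weight pulls toward the
  # component centre)
  expect_equal(d1$x_um, d0$x_um, tolerance = 0.5)
  expect_equal(localVarianceMap(img_shift, 2), localVarianceMap(img, 2),
               tolerance = 1e-9)
})

test_that("mosaic detection merges duplicates and maps to stage um", {
  arena <- rectArena(360, 200)
  spec <- frameSpec(160, 160, pixel_size = 1.25)
  # one cell inside the overlap strip of two adjacent tiles -> one record
  cell <- cellTable("c1", x_um = 175, y_um = 100, size_um = 16,
                    brightness = 200)
  mos <- generateMosaic(arena, cell, spec, overlap = 0.25,
                        renderParams(noise_sd = 0))
  det <- detectMosaic(mos, dedup_radius = 20)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_um - 175), 1.25)

  # single-tile mosaic reduces to segmentFrame
  arena1 <- rectArena(190, 190)
  pop <- makePopulation(arena1, 3, 0, min_separation = 60, seed = 3)
  mos1 <- generateMosaic(arena1, pop, spec, overlap = 0,
                         renderParams(noise_sd = 0))
  expect_length(mos1@tiles, 1)
  d_mos <- detectMosaic(mos1)
  d_one <- segmentFrame(mos1@tiles[[1]], detectionParams(),
                        mos1@specs[[1]])
  expect_equal(nrow(d_mos), nrow(d_one))
  expect_equal(d_mos$x_um, d_one$x_um)

  # k cells away from overlaps -> k records within 1 px of truth
  arena2 <- rectArena(600, 600)
  pop2 <- makePopulation(rectArena(500, 500, origin = c(30, 30)), 6, 0,
                         min_separation = 120, seed = 21)
  mos2 <- generateMosaic(arena2, pop2, spec, overlap = 0.1,
                         renderParams(noise_sd = 0))
  det2 <- detectMosaic(mos2, dedup_radius = 20)
  expect_equal(nrow(det2), 6)
  m <- detectionMetrics(det2, pop2, match_radius = 1.25)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)

  # inconsistent pixel sizes across tiles are rejected
  bad <- mos2
  bad@specs[[2]]@pixel_size <- 2
  expect_error(detectMosaic(bad), "pixel size")
})

test_that("external detection import handles the ImageJ dialect", {
  spec <- frameSpec(512, 512, pixel_size = 1.3, offset = c(100, 200))
  csv <- paste("  ,XStart,YStart,Width,Height,Mean",
               "1,10,20,12,14,88.5",
               "2,300,41,10,10,120.0",
               "3,0,511,8,12,60.25", sep = "\n")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(csv, f)
  det <- importExternalDetections(f, imagejDialect(), spec)
  expect_equal(nrow(det), 3)
  # hand conversion: x = px * 1.3 + 100, y = px * 1.3 + 200
  expect_equal(det$x_um, c(10, 300, 0) * 1.3 + 100)
  expect_equal(det$y_um, c(20, 41, 511) * 1.3 + 200)
  expect_equal(det$brightness, c(88.5, 120, 60.25))
  expect_equal(det$bbox_w_um, c(12, 10, 8) * 1.3)

  # header-only file -> empty table
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("X,Y,Mean", f2)
  expect_equal(nrow(importExternalDetections(f2, imagejDialect(), spec)), 0)

  # missing y column -> error naming the candidates
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("X,Mean\n1,2", f3)
  expect_error(importExternalDetections(f3, imagejDialect(), spec),
               "missing y column")

  # non-numeric cell -> error carrying the row number
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines("X,Y\n1,2\noops,4", f4)
  expect_error(importExternalDetections(f4, imagejDialect(), spec),
               "row 2")
})
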