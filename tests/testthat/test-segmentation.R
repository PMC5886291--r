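# A small absorbance cube with ellipse "beans" on a high-absorbance stage.
sceneCube <- function(seed = 1, nBeans = 3, lines = 40L, samples = 60L,
                      bands = 12L, noise = 0.005) {
  cfg <- simulationConfig(lines = lines, samples = samples,
                          beansPerCube = as.integer(nBeans))
  conc <- sampleConcentrations(cfg, nBeans, seed = seed)
  scene <- buildScene(cfg, conc, seed = seed + 1)
  set.seed(seed + 2)
  vals <- array(1.2 + rnorm(lines * samples * bands, 0, noise),
                c(lines, samples, bands))
  fg <- scene$labels > 0
  for (b in seq_len(bands)) {
    plane <- vals[, , b]
    plane[fg] <- 0.4 + rnorm(sum(fg), 0, noise)
    vals[, , b] <- plane
  }
  cube <- new("Hypercube", values = vals,
              wavelengths = seq(1000, 2100, length.out = bands),
              unit = "absorbance", metadata = list())
  list(cube = cube, scene = scene)
}

test_that("beans are found, counted and located on generated scenes", {
  sc <- sceneCube(seed = 21, nBeans = 3)
  seg <- segmentBeans(sc$cube)
  expect_length(beanRegions(seg), 3L)
  # centroids within one pixel of the ground-truth masks
  for (r in beanRegions(seg)) {
    gt <- which(sc$scene$labels == r@label, arr.ind = TRUE)
    expect_lt(max(abs(r@centroid - colMeans(gt))), 1)
  }
  # label image consistent with the regions
  expect_identical(sort(unique(as.vector(labelImage(seg)[labelImage(seg) != 0]))),
                   1:3)
})

test_that("an all-background cube yields an empty result with a warning", {
  vals <- array(1.2, c(20, 20, 4))
  cube <- new("Hypercube", values = vals, wavelengths = 1:4,
              unit = "absorbance", metadata = list())
  expect_warning(seg <- segmentBeans(cube), "no objects")
  expect_length(beanRegions(seg), 0L)
  expect_error(segmentBeans(new("Hypercube", values = vals, wavelengths = 1:4,
                                unit = "reflectance", metadata = list())),
               "absorbance")
})

test_that("region masks are disjoint, ordered row-major, and size-filtered", {
  sc <- sceneCube(seed = 22, nBeans = 6)
  seg <- segmentBeans(sc$cube)
  masks <- lapply(beanRegions(seg), function(r) r@mask)
  overlap <- Reduce(`+`, masks)
  expect_lte(max(overlap), 1)
  cents <- t(vapply(beanRegions(seg), function(r) r@centroid, numeric(2)))
  # row-major: labels increase with sample within a row, rows top to bottom
  rows <- cumsum(c(1, diff(cents[, 1]) > 10))
  expect_true(all(diff(rows) >= 0))
  for (rr in unique(rows))
    expect_true(all(diff(cents[rows == rr, 2]) > 0))
  # everything smaller than minSize is dropped
  expect_warning(segBig <- segmentBeans(sc$cube, minSize = 10000L), "no objects")
  expect_length(beanRegions(segBig), 0L)
})

test_that("mean spectra equal the brute-force per-band loop", {
  sc <- sceneCube(seed = 23, nBeans = 2)
  seg <- segmentBeans(sc$cube)
  r <- beanRegions(seg)[[1]]
  v <- cubeValues(sc$cube)
  oracle <- vapply(seq_len(dim(v)[3]), function(b) {
    acc <- c()
    for (i in which(r@mask)) {
      l <- (i - 1) %% dim(v)[1] + 1
      s <- (i - 1) %/% dim(v)[1] + 1
      acc <- c(acc, v[l, s, b])
    }
    mean(acc, na.rm = TRUE)
  }, numeric(1))
  expect_equal(meanSpectrum(r, sc$cube), oracle, tolerance = 1e-12)
  expect_equal(r@meanSpectrum, oracle, tolerance = 1e-12)
  # single pixel region
  single <- r
  single@mask[] <- FALSE
  idx <- which(r@mask)[1]
  single@mask[idx] <- TRUE
  single@pixelCount <- 1L
  l <- (idx - 1) %% dim(v)[1] + 1; s <- (idx - 1) %/% dim(v)[1] + 1
  expect_equal(meanSpectrum(single, sc$cube), v[l, s, ], tolerance = 1e-14)
  # symmetry: two opposite spectra average to zero
  two <- single
  vv <- v
  vv[l, s, ] <- 1:dim(v)[3]
  vv[l + 1, s, ] <- -(1:dim(v)[3])
  two@mask[idx + 1] <- TRUE
  two@pixelCount <- 2L
  cube2 <- new("Hypercube", values = vv, wavelengths = wavelengths(sc$cube),
               unit = "absorbance", metadata = list())
  expect_equal(meanSpectrum(two, cube2), rep(0, dim(v)[3]), tolerance = 1e-12)
})

test_that("crease exclusion removes a dark midline stripe but respects the cap", {
  cfg <- testConfig(creaseStripe = TRUE, badPixelCount = 0L)
  sim <- simulateCube(cfg, seed = 31)
  pp <- processScan(sim$scan, badPixels = sim$badPixels, creaseExclusion = TRUE)
  hits <- 0; stripe <- 0; spurious <- 0
  for (r in beanRegions(pp$segmentation)) {
    truth <- sim$scene$crease & sim$scene$labels == r@label
    stripe <- stripe + sum(truth)
    hits <- hits + sum(truth & r@creaseMask)
    spurious <- spurious + sum(r@creaseMask & !truth)
    expect_lte(sum(r@creaseMask), 0.2 * (r@pixelCount + sum(r@creaseMask)))
  }
  expect_gt(hits / stripe, 0.5)
  expect_lt(spurious / stripe, 0.1)
  # uniform bean: nothing excluded
  vals <- array(1.2, c(30, 30, 6))
  vals[10:20, 10:20, ] <- 0.4
  cube <- new("Hypercube", values = vals, wavelengths = 1:6,
              unit = "absorbance", metadata = list())
  seg <- segmentBeans(cube)
  r2 <- excludeCrease(beanRegions(seg)[[1]], cube)
  expect_identical(r2@mask, beanRegions(seg)[[1]]@mask)
})

test_that("side pairing matches by scan rank, honours reversal, checks counts", {
  sc <- sceneCube(seed = 24, nBeans = 4)
  up <- segmentBeans(sc$cube, side = "up")
  down <- segmentBeans(sc$cube, side = "down")
  p <- pairSides(up, down)
  expect_equal(p$pairs$labelDown, 1:4)
  expect_equal(p$spectra[2, ], beanRegions(up)[[2]]@meanSpectrum, tolerance = 1e-12)
  pr <- pairSides(up, down, reversed = TRUE)
  expect_equal(pr$pairs$labelDown, 4:1)
  down3 <- down
  down3@regions <- down3@regions[1:3]
  down3@labelImage[down3@labelImage == 4L] <- 0L
  expect_error(pairSides(up, down3), "counts differ")
  expect_error(pairSides(up, down3, pairing = c(1L, 2L, 3L, 3L)), "permutation")
})

test_that("segmentation artefacts are written and the table is faithful", {
  sc <- sceneCube(seed = 25, nBeans = 2)
  seg <- segmentBeans(sc$cube)
  d <- withr::local_tempdir()
  paths <- writeSegmentation(seg, sc$cube, d)
  expect_true(all(file.exists(paths)))
  tab <- read.csv(paths[2])
  expect_equal(tab$pixels, vapply(beanRegions(seg), function(r) r@pixelCount, integer(1)))
  spec <- read.csv(paths[3], check.names = FALSE)
  expect_equal(as.numeric(spec[1, -1]),
               beanRegions(seg)[[1]]@meanSpectrum, tolerance = 1e-6)
})
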