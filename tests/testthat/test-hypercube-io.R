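test_that("ENVI round trip preserves dimensions, wavelengths and values", {
  cube <- randomCube(1, lines = 5L, samples = 6L, bands = 7L, unit = "reflectance")
  base <- file.path(withr::local_tempdir(), "cube")
  writeENVI(cube, base, interleave = "bil")
  back <- readENVI(paste0(base, ".hdr"))
  expect_identical(dim(cubeValues(back)), dim(cubeValues(cube)))
  expect_equal(wavelengths(back), wavelengths(cube))
  expect_identical(cubeValues(back), cubeValues(cube))  # float64 is bit-exact
  expect_equal(unitTag(back), "reflectance")
})

test_that("all three interleaves store the same cube", {
  cube <- randomCube(2)
  dirs <- withr::local_tempdir()
  arrays <- lapply(c("bil", "bip", "bsq"), function(il) {
    base <- file.path(dirs, il)
    writeENVI(cube, base, interleave = il)
    cubeValues(readENVI(paste0(base, ".hdr")))
  })
  expect_identical(arrays[[1]], arrays[[2]])
  expect_identical(arrays[[1]], arrays[[3]])
  expect_identical(arrays[[1]], cubeValues(cube))
})

test_that("header declaring n bands yields an n-length wavelength vector", {
  cube <- randomCube(3, bands = 12L)
  base <- file.path(withr::local_tempdir(), "c")
  writeENVI(cube, base)
  back <- readENVI(paste0(base, ".hdr"))
  expect_length(wavelengths(back), 12L)
})

test_that("missing or malformed header fields give named format errors", {
  d <- withr::local_tempdir()
  hdr <- file.path(d, "bad.hdr")
  writeLines(c("ENVI", "samples = 4", "lines = 2", "bands = 3",
               "interleave = bil"), hdr)  # no data type
  writeBin(numeric(24), file.path(d, "bad.raw"))
  expect_error(readENVI(hdr), "data type")
  writeLines(c("ENVI", "samples = 4", "lines = 2", "bands = 3",
               "data type = 5", "interleave = zigzag"), hdr)
  expect_error(readENVI(hdr), "interleave")
})

test_that("reflectance calibration follows the exposure-corrected ratio", {
  # identity: I = W, zero darks, equal exposures
  r <- calibrateReflectance(flatRawScan(I = 100, Ds = 0, W = 100, Dw = 0, ts = 2, tw = 2))
  expect_true(all(abs(cubeValues(r) - 1) < 1e-12))
  # dark: I = Ds
  r <- calibrateReflectance(flatRawScan(I = 10, Ds = 10, W = 100, Dw = 0, ts = 1, tw = 1))
  expect_true(all(abs(cubeValues(r)) < 1e-12))
  # exposure-ratio hand case: ((60-10)/(110-10)) * (2/1) = 1.0
  r <- calibrateReflectance(flatRawScan(I = 60, Ds = 10, W = 110, Dw = 10, ts = 1, tw = 2))
  expect_true(all(abs(cubeValues(r) - 1.0) < 1e-12))
})

test_that("calibration is homogeneous in the dark-corrected intensity", {
  s1 <- flatRawScan(I = 60, Ds = 10, W = 210, Dw = 10, ts = 1, tw = 1)
  s2 <- flatRawScan(I = 10 + 3 * (60 - 10), Ds = 10, W = 210, Dw = 10, ts = 1, tw = 1)
  expect_equal(cubeValues(calibrateReflectance(s2)),
               3 * cubeValues(calibrateReflectance(s1)))
})

test_that("degenerate white-dark denominators are masked with a warning", {
  sc <- flatRawScan(I = 60, Ds = 10, W = 10, Dw = 10, ts = 1, tw = 1)
  expect_warning(r <- calibrateReflectance(sc), "non-positive")
  expect_true(all(is.na(cubeValues(r))))
})

test_that("absorbance is log10(1/R) and masks non-positive reflectance", {
  vals <- c(1, 0.1, 0.5, -0.2, 0)
  cube <- new("Hypercube", values = array(rep(vals, each = 2), c(1, 2, 5)),
              wavelengths = 1:5, unit = "reflectance", metadata = list())
  a <- toAbsorbance(cube)
  expect_equal(unitTag(a), "absorbance")
  got <- cubeValues(a)[1, 1, ]
  expect_equal(got[1], 0, tolerance = 1e-14)
  expect_equal(got[2], 1, tolerance = 1e-14)
  expect_equal(got[3], log10(2), tolerance = 1e-14)  # 0.30103
  expect_true(all(is.na(got[4:5])))
  expect_error(toAbsorbance(a), "reflectance")
})

test_that("absorbance inverts back to reflectance on valid elements", {
  cube <- randomCube(4, unit = "reflectance")
  a <- toAbsorbance(cube)
  expect_equal(10^(-cubeValues(a)), cubeValues(cube), tolerance = 1e-12)
})

test_that("band trimming drops leading bands and keeps bookkeeping", {
  cube <- randomCube(5, bands = 20L)
  t16 <- trimBands(cube, 4L)
  expect_identical(dim(cubeValues(t16))[3], 16L)
  expect_equal(wavelengths(t16)[1], wavelengths(cube)[5])
  expect_identical(cubeValues(trimBands(cube, 0L)), cubeValues(cube))
  expect_error(trimBands(cube, 20L), "trim")
  # the instrument case: 256 bands -> 240 after the 16-band sensor roll-off
  big <- randomCube(6, lines = 2L, samples = 2L, bands = 256L)
  expect_identical(dim(cubeValues(trimBands(big, 16L)))[3], 240L)
})

test_that("bad-pixel correction equals the neighbourhood-mean oracle", {
  cube <- randomCube(7, lines = 8L, samples = 9L, bands = 4L)
  # empty map: unchanged
  empty <- badPixelMap(NULL, c(9L, 4L))
  expect_identical(cubeValues(correctBadPixels(cube, empty)), cubeValues(cube))
  # constant neighbourhood: replaced by the constant
  cc <- cube
  cc@values[, , 2] <- 5
  cc@values[4, 5, 2] <- 99
  m1 <- badPixelMap(cbind(5L, 2L), c(9L, 4L))
  expect_equal(cubeValues(correctBadPixels(cc, m1))[4, 5, 2], 5)
  # random map vs brute force
  set.seed(42)
  coords <- cbind(sample(1:9, 5), sample(1:4, 5, replace = TRUE))
  coords <- coords[!duplicated(coords), , drop = FALSE]
  m2 <- badPixelMap(coords, c(9L, 4L))
  expect_equal(cubeValues(correctBadPixels(cube, m2)),
               badPixelOracle(cubeValues(cube), coords))
  # untouched elements unchanged
  got <- cubeValues(correctBadPixels(cube, m2))
  untouched <- array(TRUE, dim(got))
  for (r in seq_len(nrow(coords))) untouched[, coords[r, 1], coords[r, 2]] <- FALSE
  expect_identical(got[untouched], cubeValues(cube)[untouched])
})

test_that("zero-variance detector columns are auto-detected", {
  sc <- flatRawScan(I = 60, Ds = 10, W = 110, Dw = 10, ts = 1, tw = 2,
                    lines = 6L, samples = 5L, bands = 3L)
  set.seed(8)
  sc@intensity <- sc@intensity + array(rnorm(90), dim(sc@intensity))
  sc@intensity[, 2, 3] <- 7   # dead element
  m <- detectBadPixels(sc)
  expect_identical(m@coords, matrix(c(2L, 3L), 1, 2,
                                    dimnames = list(NULL, c("sample", "band"))))
})
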