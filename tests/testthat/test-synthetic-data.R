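test_that("component spectra peak at the compounds' absorption features", {
  wl <- seq(980, 2500, length.out = 256)
  lib <- componentLibrary(wl)
  localMaxNear <- function(spec, target, tolNm = 25) {
    i <- which(diff(sign(diff(spec))) == -2) + 1
    any(abs(wl[i] - target) <= tolNm)
  }
  caf <- lib@spectra[, "caffeine"]
  for (pk in c(1668, 2250, 2425)) expect_true(localMaxNear(caf, pk))
  tri <- lib@spectra[, "trigonelline"]
  for (pk in c(1668, 2269)) expect_true(localMaxNear(tri, pk))
  expect_true(localMaxNear(lib@spectra[, "sucrose"], 2070))
  expect_true(all(lib@spectra >= 0))
})

test_that("zero-SD configurations put every bean at its species mean", {
  cfg <- testConfig(concSDs = matrix(0, 2, 3,
                                     dimnames = dimnames(simulationConfig()@params$concSDs)))
  conc <- sampleConcentrations(cfg, 20, seed = 1)
  mm <- cfg@params$concMeans
  for (i in seq_len(20)) {
    expect_equal(as.numeric(conc[i, c("sucrose", "caffeine", "trigonelline")]),
                 unname(mm[conc$species[i], ]), tolerance = 1e-12)
  }
})

test_that("sampled concentrations respect the target correlations and ranges", {
  cfg <- simulationConfig(speciesMix = c(arabica = 1, robusta = 0))
  conc <- sampleConcentrations(cfg, 10000, seed = 2)
  cm <- cor(conc[c("sucrose", "caffeine", "trigonelline")])
  tgt <- cfg@params$corrMatrix
  expect_lt(abs(cm["sucrose", "caffeine"] - tgt["sucrose", "caffeine"]), 0.03)
  expect_lt(abs(cm["sucrose", "trigonelline"] - tgt["sucrose", "trigonelline"]), 0.03)
  expect_lt(abs(cm["caffeine", "trigonelline"] - tgt["caffeine", "trigonelline"]), 0.03)
  rng <- cfg@params$concRanges
  for (an in rownames(rng)) {
    expect_gte(min(conc[[an]]), rng[an, "min"])
    expect_lte(max(conc[[an]]), rng[an, "max"])
  }
})

test_that("per-species sample moments converge to the configured values", {
  cfg <- simulationConfig(speciesMix = c(arabica = 0, robusta = 1))
  n <- 5000
  conc <- sampleConcentrations(cfg, n, seed = 3)
  mu <- cfg@params$concMeans["robusta", ]
  sdv <- cfg@params$concSDs["robusta", ]
  for (an in names(mu)) {
    se <- sdv[[an]] / sqrt(n)
    # truncation pulls the sucrose mean slightly up; allow 3 SE + truncation drift
    expect_lt(abs(mean(conc[[an]]) - mu[[an]]), 3 * se + 0.05 * sdv[[an]])
    expect_lt(abs(sd(conc[[an]]) - sdv[[an]]), 0.1 * sdv[[an]])
  }
})

test_that("scenes hold the requested number of disjoint elliptical beans", {
  cfg <- testConfig()
  for (seed in c(5, 17, 99)) {
    conc <- sampleConcentrations(cfg, 10, seed = seed)
    scene <- buildScene(cfg, conc, seed = seed)
    expect_equal(sort(unique(as.vector(scene$labels))), 0:10)
    # per-bean fields are constant when the gradient is off
  }
  cfg0 <- testConfig(gradientAmplitude = 0)
  conc <- sampleConcentrations(cfg0, 5, seed = 7)
  scene <- buildScene(cfg0, conc, seed = 7)
  for (i in 1:5) {
    f <- scene$fields$caffeine[scene$labels == i]
    expect_equal(f, rep(conc$caffeine[i], length(f)), tolerance = 1e-12)
  }
})

test_that("noise-free rendering round-trips through the calibration equations", {
  cfg <- testConfig(noiseSD = 0, leadingNoiseSD = 0, scatterSlopeSD = 0,
                    scatterOffsetSD = 0, badPixelCount = 0L,
                    exposureSample = 1, exposureWhite = 1)
  sim <- simulateCube(cfg, seed = 8, keepAbsorbance = TRUE)
  ab <- toAbsorbance(calibrateReflectance(sim$scan))
  expect_lt(max(abs(cubeValues(ab) - sim$absorbance)), 1e-10)
})

test_that("a bean's spectral contribution is linear in its concentration", {
  cfg <- testConfig(noiseSD = 0, leadingNoiseSD = 0, scatterSlopeSD = 0,
                    scatterOffsetSD = 0, badPixelCount = 0L,
                    gradientAmplitude = 0, exposureSample = 1, exposureWhite = 1)
  conc <- sampleConcentrations(cfg, 4, seed = 9)
  conc2 <- conc
  conc2$caffeine[2] <- 2 * conc$caffeine[2]
  lib <- componentLibrary(seq(980, 2500, length.out = 256))
  s1 <- buildScene(cfg, conc, seed = 10)
  s2 <- buildScene(cfg, conc2, seed = 10)
  a1 <- renderRawScan(s1, lib, cfg, seed = 11, keepAbsorbance = TRUE)$absorbance
  a2 <- renderRawScan(s2, lib, cfg, seed = 11, keepAbsorbance = TRUE)$absorbance
  diffA <- a2 - a1
  idx <- which(s1$labels == 2)
  P <- matrix(NA_real_, length(idx), 256)
  npl <- prod(dim(diffA)[1:2])
  for (b in 1:256) P[, b] <- diffA[idx + (b - 1) * npl]
  expected <- outer(rep(conc$caffeine[2], length(idx)), lib@spectra[, "caffeine"])
  expect_equal(P, expected, tolerance = 1e-10, ignore_attr = TRUE)
  # other beans untouched
  expect_lt(max(abs(diffA[s1$labels != 2])), 1e-12)
})

test_that("fixtures round-trip and regenerate byte-for-byte under one seed", {
  cfg <- testConfig(lines = 32L, samples = 80L, beansPerCube = 4L)
  d1 <- file.path(withr::local_tempdir(), "f1")
  d2 <- file.path(withr::local_tempdir(), "f2")
  sim1 <- simulateCube(cfg, seed = 12)
  sim2 <- simulateCube(cfg, seed = 12)
  writeFixture(sim1, d1, config = cfg)
  writeFixture(sim2, d2, config = cfg)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  back <- readFixture(d1)
  expect_equal(back$truth$caffeine, sim1$truth$caffeine, tolerance = 1e-12)
  expect_identical(cubeValues(back$scan), cubeValues(sim1$scan))
  expect_equal(back$scan@white, sim1$scan@white, tolerance = 1e-12)
  # distinct seeds give distinct cubes
  sim3 <- simulateCube(cfg, seed = 13)
  expect_false(identical(cubeValues(sim3$scan), cubeValues(sim1$scan)))
  # and the fixture loads through the standard pipeline without warnings
  expect_no_warning(processScan(back$scan, badPixels = back$badPixels,
                                minSize = 30L))
})
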