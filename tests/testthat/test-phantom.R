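test_that("uniform phantoms measure their base thickness everywhere", {
  ph <- generatePhantom(phantomSpec(baseThickness = 2))
  res <- computeCDI(ph@contours)
  expect_true(all(abs(cdiSamples(res)$thickness - 2) < 0.05))

  # defect deeper than the cartilage measures 0 at its centre
  ph2 <- generatePhantom(phantomSpec(
    baseThickness = 2,
    defects = data.frame(bone = "tibia", u = 0.5, v = 0.5,
                         radius = 0.1, depth = 2.5)))
  r <- resolveLocation(ph2@contours, 0.5, 0.5, "tibia")
  expect_identical(measureThickness(r$slice, r$point), 0)
  expect_identical(ph2@truth(0.5, 0.5, "tibia"), 0)
})

test_that("phantom generation is deterministic (byte-identical files)", {
  spec <- phantomSpec(baseThickness = 1.8,
                      defects = data.frame(bone = "femur", u = 0.4,
                                           v = 0.6, radius = 0.1,
                                           depth = 1))
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  writeContourSet(generatePhantom(spec)@contours, f1)
  writeContourSet(generatePhantom(spec)@contours, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("progression thins the truth field and can only lower the CDI", {
  ph <- generatePhantom(phantomSpec(baseThickness = 2))
  same <- progressPhantom(ph, thinning = 0)
  expect_equal(cdiValues(computeCDI(same@contours)),
               cdiValues(computeCDI(ph@contours)))

  fu <- progressPhantom(ph, thinning = 0.1)
  dt <- cdiSamples(computeCDI(fu@contours))$thickness -
    cdiSamples(computeCDI(ph@contours))$thickness
  expect_true(all(abs(dt + 0.1) < 0.05))

  gone <- progressPhantom(ph, thinning = 5)
  expect_equal(unname(cdiValues(computeCDI(gone@contours))["tibiofemoral"]),
               0)
  expect_error(progressPhantom(ph, thinning = -1),
               class = "cdiValidationError")
})

test_that("reader noise is seeded, null at sd = 0, and realistic at sd = 0.1", {
  ph <- generatePhantom(phantomSpec(baseThickness = 2))
  cs <- ph@contours

  clean <- applyReaderNoise(cs, readerNoiseModel(sd = 0, slipProb = 0),
                            seed = 1)
  expect_equal(clean, cs)

  n1 <- applyReaderNoise(cs, readerNoiseModel(sd = 0.1), seed = 1)
  n2 <- applyReaderNoise(cs, readerNoiseModel(sd = 0.1), seed = 1)
  n3 <- applyReaderNoise(cs, readerNoiseModel(sd = 0.1), seed = 2)
  expect_equal(n1, n2)
  expect_false(isTRUE(all.equal(slices(n1)[[1]]@boneBoundary,
                                slices(n3)[[1]]@boneBoundary)))
  # original untouched
  expect_equal(cs, ph@contours)

  # thickness deviation sd over 100 jittered replicates at one location
  r <- resolveLocation(cs, 0.5, 0.5, "femur")
  t0 <- measureThickness(r$slice, r$point)
  devs <- vapply(1:100, function(i) {
    noisy <- applyReaderNoise(cs, readerNoiseModel(sd = 0.1), seed = 100 + i)
    rr <- resolveLocation(noisy, 0.5, 0.5, "femur")
    measureThickness(rr$slice, rr$point) - t0
  }, numeric(1))
  expect_gt(sd(devs), 0.05)
  expect_lt(sd(devs), 0.3)
})

test_that("endpoint slips move the extreme slices inward, reproducibly", {
  ph <- generatePhantom(phantomSpec(baseThickness = 2))
  cs <- ph@contours
  slipped <- applyReaderNoise(cs, readerNoiseModel(sd = 0, slipProb = 1),
                              seed = 5)
  expect_identical(slipped@medialSlice, cs@medialSlice + 1L)
  expect_identical(slipped@lateralSlice, cs@lateralSlice - 1L)
  expect_true(validObject(slipped))
})

test_that("generateCohort plants strata and reproduces from its seed", {
  expect_error(generateCohort(0), class = "cdiValidationError")
  expect_error(generateCohort(5, mixture = c(1, 2)),
               class = "cdiValidationError")
  expect_error(generateCohort(5, mixture = c(-1, 1, 0, 0)),
               class = "cdiValidationError")

  healthy <- generateCohort(5, mixture = c(1, 0, 0, 0), seed = 9)
  for (k in healthy$knees) {
    g <- expand.grid(u = seq(0.05, 0.95, by = 0.1),
                     v = seq(0.05, 0.95, by = 0.1))
    expect_true(all(k$baseline@truth(g$u, g$v, "femur") > 0))
    expect_true(all(k$baseline@truth(g$u, g$v, "tibia") > 0))
  }

  a <- generateCohort(4, seed = 33, followup = TRUE)
  b <- generateCohort(4, seed = 33, followup = TRUE)
  expect_equal(a$covariates, b$covariates)
  expect_equal(a$knees[[2]]$baseline@contours,
               b$knees[[2]]$baseline@contours)
  expect_identical(a$covariates$jsnProgressor,
                   a$covariates$jsnFollowup != a$covariates$jsnBaseline)
  expect_true(all(a$covariates$heightM > 1.3 & a$covariates$heightM < 2.1))
})

test_that("measured stratum contrast matches the planted (ground-truth) contrast", {
  n <- 20
  mild <- generateCohort(n, mixture = c(1, 0, 0, 0), seed = 101)
  severe <- generateCohort(n, mixture = c(0, 0, 0, 1), seed = 202)
  tf <- function(co, fun) vapply(co$knees, function(k)
    unname(fun(k$baseline)["tibiofemoral"]), numeric(1))
  measured <- function(k) cdiValues(computeCDI(k@contours))
  planted <- function(k) truthCDI(k)
  dMeasured <- mean(tf(mild, measured)) - mean(tf(severe, measured))
  dPlanted <- mean(tf(mild, planted)) - mean(tf(severe, planted))
  se <- sqrt(var(tf(mild, measured)) / n + var(tf(severe, measured)) / n)
  expect_gt(dPlanted, 0)
  expect_lt(abs(dMeasured - dPlanted), 3 * se)
})

test_that("simulated re-reads give a near-unit ICC when noise is small", {
  co <- generateCohort(8, seed = 77)
  m <- simulateRereads(lapply(co$knees, `[[`, "baseline"), k = 2,
                       model = readerNoiseModel(sd = 0.05), seed = 5)
  expect_identical(dim(m), c(8L, 2L))
  expect_gt(icc(m, "3,1"), 0.9)
})
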