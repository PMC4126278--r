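test_that("thickness is the normal-ray distance to the cartilage surface", {
  # parallel horizontal polylines 2 mm apart
  sl <- straightSlice(thickness = 2)
  for (x in c(5, 15, 25))
    expect_equal(measureThickness(sl, c(x, 0)), 2)

  # coincident contours (denuded) measure exactly 0
  den <- straightSlice(thickness = 0)
  expect_identical(measureThickness(den, c(15, 0)), 0)

  # concentric arcs radii 10 and 12.5: 2.5 +/- 0.02 at interior points
  arc <- arcSlice(rBone = 10, rCart = 12.5)
  par <- arcLengthParameterize(arc@boneBoundary)
  for (v in c(0.25, 0.5, 0.75)) {
    t <- measureThickness(arc, drop(par$point(v)))
    expect_equal(t, 2.5, tolerance = 0.02 / 2.5)
  }

  expect_error(measureThickness(sl, c(15, 5)), class = "cdiValidationError")
  expect_error(
    measureThickness(sliceContour(0L, "femur", cbind(c(0, 30), 0)), c(15, 0)),
    class = "cdiDegenerateContour")
})

test_that("cartilage length is the covered extent of the boundary", {
  expect_equal(measureLength(straightSlice(len = 30)), 30)
  mid <- straightSlice(len = 30, denudedFrom = 10, denudedTo = 20)
  expect_equal(measureLength(mid), 20, tolerance = 0.2 / 20)
  expect_equal(measureLength(straightSlice(thickness = 0)), 0)
})

test_that("computeCDI sums thickness x length x slice thickness per bone", {
  # 9 locations with t = 2, L = 30, dz = 0.7 -> 9*2*30*0.7 = 378 per bone
  cs <- flatKnee(nSlices = 5L, thickness = 2, len = 30, dz = 0.7)
  res <- computeCDI(cs)
  v <- cdiValues(res)
  expect_equal(unname(v["femur"]), 378)
  expect_equal(unname(v["tibia"]), 378)
  expect_equal(unname(v["tibiofemoral"]), 756)
  expect_true(all(cdiSamples(res)$measurable))

  # fully denuded knee scores 0
  denuded <- flatKnee(thickness = 0)
  expect_equal(unname(cdiValues(computeCDI(denuded))["tibiofemoral"]), 0)

  # dxdy voxel interpretation scales by in-plane area instead of dz
  alt <- cdiValues(computeCDI(cs, voxel = "dxdy"))
  expect_equal(unname(alt["femur"]), 9 * 2 * 30 * 0.365 * 0.456)
})

test_that("unmeasurable locations are flagged; empty bones error", {
  # tibia slices boundary-only: tibia unmeasurable everywhere
  sl <- list()
  for (i in 0:4) {
    sl[[length(sl) + 1L]] <- straightSlice(i, "femur")
    sl[[length(sl) + 1L]] <- sliceContour(i, "tibia", cbind(c(0, 30), 0))
  }
  cs <- contourSet("k", "baseline", "right", voxelGeometry(nSlices = 5L),
                   sl, 0L, 4L)
  expect_error(computeCDI(cs), class = "cdiEmptyMeasurement")

  # a single missing location is flagged and contributes 0
  locs <- informativeLocations(data.frame(
    name = c("F1", "F2"), bone = "femur", u = c(0.5, 0.5), v = c(0.2, 0.8)))
  partial <- contourSet("k", "baseline", "right",
                        voxelGeometry(nSlices = 5L),
                        list(straightSlice(0L, "femur"),
                             straightSlice(4L, "femur")), 0L, 4L)
  # u = 0.5 resolves to slice 2 which is absent -> both unmeasurable
  expect_error(computeCDI(partial, locs), class = "cdiEmptyMeasurement")
  locs2 <- informativeLocations(data.frame(
    name = c("F1", "F2"), bone = "femur", u = c(0, 0.5), v = c(0.2, 0.8)))
  res <- computeCDI(partial, locs2)
  expect_identical(sum(!cdiSamples(res)$measurable), 1L)
  expect_equal(unname(cdiValues(res)["femur"]), 2 * 30 * 0.7)
})

test_that("pipeline CDI matches the dense-integration ground truth on a phantom", {
  ph <- generatePhantom(phantomSpec(baseThickness = 2))
  got <- cdiValues(computeCDI(ph@contours))
  want <- truthCDI(ph)
  expect_equal(unname(got), unname(want), tolerance = 0.05)

  # with a focal defect the agreement still holds
  ph2 <- generatePhantom(phantomSpec(
    baseThickness = 2,
    defects = data.frame(bone = "femur", u = 0.5, v = 0.55,
                         radius = 0.15, depth = 3)))
  got2 <- cdiValues(computeCDI(ph2@contours))
  want2 <- truthCDI(ph2)
  expect_equal(unname(got2), unname(want2), tolerance = 0.05)
  expect_lt(got2["femur"], got["femur"])
})

test_that("CDI is monotone in thickness and linear in dz and global scale", {
  base <- cdiValues(computeCDI(flatKnee(thickness = 2)))
  thicker <- cdiValues(computeCDI(flatKnee(thickness = 2.4)))
  expect_true(all(thicker >= base))
  expect_equal(unname(thicker), unname(base) * 1.2, tolerance = 1e-6)

  dz2 <- cdiValues(computeCDI(flatKnee(thickness = 2, dz = 1.4)))
  expect_equal(unname(dz2), unname(base) * 2, tolerance = 1e-9)

  expect_equal(base[["tibiofemoral"]], base[["femur"]] + base[["tibia"]])
})

test_that("uniform thinning lowers every location and the CDI (sign contract)", {
  ph <- generatePhantom(phantomSpec(baseThickness = 2))
  fu <- progressPhantom(ph, thinning = 0.1)
  b <- computeCDI(ph@contours)
  f <- computeCDI(fu@contours)
  dt <- cdiSamples(f)$thickness - cdiSamples(b)$thickness
  expect_true(all(abs(dt + 0.1) < 0.05))
  ch <- changeScore(b, f)
  expect_true(all(ch$change < 0))
})

test_that("height adjustment divides by height and validates input", {
  cs <- flatKnee()
  res <- computeCDI(cs)
  raw <- cdiValues(res)
  adj <- heightAdjust(res, 1.70)
  expect_equal(unname(cdiValues(adj, adjusted = TRUE)),
               unname(raw) / 1.70)
  # worked numbers: raw 2000 at 1.70 m -> 1176.47
  expect_equal(round(2000 / 1.70, 2), 1176.47)
  expect_equal(cdiValues(heightAdjust(res, 1), adjusted = TRUE), raw)
  expect_error(heightAdjust(res, 0), class = "cdiValidationError")
  expect_error(heightAdjust(res, -1.6), class = "cdiValidationError")
  expect_error(cdiValues(res, adjusted = TRUE), class = "cdiValidationError")
})

test_that("change scores are follow-up minus baseline with validation", {
  cs <- flatKnee(thickness = 2)
  fu <- flatKnee(thickness = 1.8)
  fu@timepoint <- "followup"
  b <- computeCDI(cs)
  f <- computeCDI(fu)
  ch <- changeScore(b, f)
  expect_equal(ch$change, ch$followup - ch$baseline)
  expect_true(all(ch$change < 0))
  # antisymmetry and zero self-change
  expect_equal(changeScore(f, b)$change, -ch$change)
  expect_equal(changeScore(b, b)$change, rep(0, 3))

  other <- computeCDI(flatKnee(kneeId = "other"))
  expect_error(changeScore(b, other), class = "cdiValidationError")
  expect_error(changeScore(heightAdjust(b, 1.7), f),
               class = "cdiValidationError")
  # worked numbers: 1177.40 -> 1134.17 is a change of -43.23
  expect_equal(1134.17 - 1177.40, -43.23)
})
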