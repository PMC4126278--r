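# Fixture builders shared across test files. All coordinates mm.

# Straight parallel-line slice: bone at y = 0 over [0, len], cartilage at
# y = thickness. `denudedFrom`/`denudedTo` carve a coincident band.
straightSlice <- function(sliceIndex = 0L, bone = "femur", len = 30,
                          thickness = 2, n = 61,
                          denudedFrom = NA, denudedTo = NA) {
  x <- seq(0, len, length.out = n)
  t <- rep(thickness, n)
  if (!is.na(denudedFrom))
    t[x >= denudedFrom & x <= denudedTo] <- 0
  sliceContour(sliceIndex, bone, cbind(x, 0), cbind(x, t))
}

# Concentric circular-arc slice centred at the origin, opening downward.
arcSlice <- function(sliceIndex = 0L, bone = "femur", rBone = 10,
                     rCart = 12.5, spanDeg = 90, n = 91) {
  th <- seq(-spanDeg / 2, spanDeg / 2, length.out = n) * pi / 180
  dir <- cbind(sin(th), -cos(th))
  sliceContour(sliceIndex, bone, rBone * dir, rCart * dir)
}

# Stack of identical straight slices spanning medial..lateral indices.
toyStack <- function(medial, lateral, bone = "femur", thickness = 2,
                     len = 30, kneeId = "toy", side = "right",
                     geometry = voxelGeometry(
                       nSlices = abs(lateral - medial) + 1L)) {
  idx <- seq(min(medial, lateral), max(medial, lateral))
  sl <- lapply(idx, function(i)
    straightSlice(i, bone, len = len, thickness = thickness))
  contourSet(kneeId, "baseline", side, geometry, sl, medial, lateral)
}

# Both-bone parallel-line contour set: femur and tibia identical geometry.
flatKnee <- function(nSlices = 5L, thickness = 2, len = 30,
                     kneeId = "flat", dz = 0.7) {
  sl <- list()
  for (i in seq_len(nSlices) - 1L)
    for (b in c("femur", "tibia"))
      sl[[length(sl) + 1L]] <- straightSlice(i, b, len = len,
                                             thickness = thickness)
  contourSet(kneeId, "baseline", "right",
             voxelGeometry(dz = dz, nSlices = nSlices), sl,
             0L, nSlices - 1L)
}

# Binary-mask dilation by one bin (Chebyshev), for boundary-tolerant
# mask comparisons.
dilate1 <- function(m) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (di in -1:1) for (dj in -1:1) {
    ri <- pmin(pmax(seq_len(nr) + di, 1), nr)
    cj <- pmin(pmax(seq_len(nc) + dj, 1), nc)
    out <- out | m[ri, cj, drop = FALSE]
  }
  out
}
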