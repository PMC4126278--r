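#' @include geometry.R
NULL

# Numerical floor (mm) below which a measured thickness is treated as zero.
# Absorbs polyline-discretisation error when the cartilage surface is
# traced coincident with the bone boundary (denuded cartilage).
.denudedFloor <- 5e-3

# Vectorised thickness profile along a slice's bone boundary.
# v: vector of anterior-posterior coordinates in [0,1].
# For each v: cast a ray from the boundary point along the outward local
# normal (outward = toward the cartilage surface); thickness is the
# distance to the first cartilage-surface intersection, falling back to
# the nearest-point distance when no intersection lies within `cap`.
# Points outside the cartilage footprint (the arc interval spanned by the
# projections of the cartilage-surface endpoints) are denuded: 0.
.thicknessProfile <- function(slice, v, cap = 15, floor = .denudedFloor) {
  B <- slice@boneBoundary
  S <- slice@cartilageSurface
  if (is.null(S))
    .cdiStop("cdiDegenerateContour",
             sprintf("slice %d (%s) has no cartilage surface",
                     slice@sliceIndex, slice@bone))
  infoB <- .arcInfo(B)
  if (infoB$total <= 0)
    .cdiStop("cdiDegenerateContour", "bone boundary has zero length")
  pa <- .pointAtArc(B, v * infoB$total, infoB)
  pts <- pa$points
  normals <- cbind(-pa$tangents[, 2], pa$tangents[, 1])

  near <- .nearestOnPolyline(S, pts)
  # orient normals toward the cartilage side
  dots <- rowSums(normals * (near$point - pts))
  flip <- dots < 0
  normals[flip, ] <- -normals[flip, , drop = FALSE]

  hits <- .rayHits(pts, normals, S, cap = cap)
  t <- ifelse(is.finite(hits), hits, near$dist)

  # footprint: arc interval of the boundary covered by the cartilage trace
  ends <- .nearestOnPolyline(B, S[c(1L, nrow(S)), , drop = FALSE], infoB)
  sRange <- range(ends$s)
  sHere <- v * infoB$total
  outside <- sHere < sRange[1] - 1e-6 | sHere > sRange[2] + 1e-6

  t[outside] <- 0
  t[near$dist < floor] <- 0
  t[t < floor] <- 0
  list(thickness = t, points = pts)
}

#' Measure cartilage thickness at a point on the bone boundary
#'
#' Thickness is the distance from the bone-cartilage interface point to the
#' cartilage outer surface along the outward local normal of the boundary
#' (the normal of the containing segment; adjacent segments averaged at a
#' vertex). When no normal intersection exists within \code{cap} mm the
#' nearest-point distance is used instead, and a point outside the
#' footprint of the cartilage trace -- or one where the two contours
#' coincide -- is denuded and measures 0.
#'
#' @param slice a \linkS4class{SliceContour} with both polylines
#' @param bonePoint length-2 numeric: a point on (within 1e-6 mm of) the
#'   bone boundary
#' @param cap normal-ray search cap in mm (default 15)
#' @return thickness in mm (0 for denuded points)
#' @examples
#' sl <- sliceContour(0, "femur",
#'                    cbind(seq(0, 30, 1), 0),
#'                    cbind(seq(0, 30, 1), 2))
#' measureThickness(sl, c(15, 0))   # 2
#' @export
measureThickness <- function(slice, bonePoint, cap = 15) {
  .assert(is(slice, "SliceContour"), "slice must be a SliceContour")
  .assert(is.numeric(bonePoint) && length(bonePoint) == 2L,
          "bonePoint must be a length-2 numeric")
  B <- slice@boneBoundary
  infoB <- .arcInfo(B)
  pr <- .nearestOnPolyline(B, matrix(bonePoint, 1L), infoB)
  .assert(pr$dist < 1e-6, "bonePoint does not lie on the bone boundary")
  v <- pr$s / infoB$total
  .thicknessProfile(slice, v, cap = cap)$thickness
}

#' Measure the anterior-posterior cartilage length of a slice
#'
#' The cartilage-covered extent of the bone-cartilage boundary: the
#' boundary is divided into equal sub-segments of at most \code{step} mm,
#' thickness is evaluated at each midpoint, and the lengths of covered
#' (thickness > 0) sub-segments are summed.
#'
#' @param slice a \linkS4class{SliceContour} with both polylines
#' @param step sampling step in mm (default 0.2)
#' @param cap normal-ray search cap in mm
#' @return covered length in mm (0 for a fully denuded slice)
#' @export
measureLength <- function(slice, step = 0.2, cap = 15) {
  .assert(is(slice, "SliceContour"), "slice must be a SliceContour")
  .assert(is.numeric(step) && step > 0, "step must be positive")
  infoB <- .arcInfo(slice@boneBoundary)
  if (infoB$total <= 0)
    .cdiStop("cdiDegenerateContour", "bone boundary has zero length")
  m <- max(1L, ceiling(infoB$total / step))
  mids <- (seq_len(m) - 0.5) / m
  t <- .thicknessProfile(slice, mids, cap = cap)$thickness
  (infoB$total / m) * sum(t > 0)
}
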