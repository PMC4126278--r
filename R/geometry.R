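#' @include AllClasses.R
NULL

# Nearest-integer slice rounding with ties going to the candidate farther
# from the medial index `med` (the rule that commutes with mirroring).
.roundSlice <- function(x, med) {
  fl <- floor(x)
  r <- x - fl
  tie <- abs(r - 0.5) < 1e-9
  idx <- ifelse(r < 0.5, fl, fl + 1)
  if (any(tie)) {
    lo <- fl[tie]
    hi <- lo + 1
    idx[tie] <- ifelse(abs(hi - med) > abs(lo - med), hi, lo)
  }
  idx
}

# Find the SliceContour at a given (index, bone); NULL if absent.
.findSlice <- function(cs, sliceIndex, bone) {
  for (s in cs@slices)
    if (s@sliceIndex == sliceIndex && s@bone == bone) return(s)
  NULL
}

#' Map a medial-lateral coordinate u to a slice index
#'
#' The u axis of the universal coordinate system runs from the
#' reader-designated most medial slice (u = 0) to the most lateral slice
#' (u = 1); intermediate u values are mapped to the nearest slice. When u
#' falls exactly halfway between two slices, the tie goes to the slice
#' farther from the medial end, so the mapping commutes with left/right
#' mirroring of the stack.
#'
#' @param cs a \linkS4class{ContourSet}
#' @param u medial-lateral coordinate(s) in [0, 1]
#' @return integer slice index (vectorised over \code{u})
#' @examples
#' # toy set spanning slices 10..60
#' geom <- voxelGeometry(nSlices = 51)
#' sl <- lapply(10:60, function(i)
#'   sliceContour(i, "femur", cbind(0:1, 0)))
#' cs <- contourSet("k", "baseline", "right", geom, sl, 10, 60)
#' sliceForU(cs, c(0, 0.5, 1))
#' @export
sliceForU <- function(cs, u) {
  .assert(is(cs, "ContourSet"), "cs must be a ContourSet")
  .assert(is.numeric(u) && all(is.finite(u)) && all(u >= 0 & u <= 1),
          "u must lie in [0, 1]")
  med <- cs@medialSlice
  lat <- cs@lateralSlice
  idx <- .roundSlice(med + u * (lat - med), med)
  lo <- min(med, lat)
  hi <- max(med, lat)
  as.integer(pmin(pmax(idx, lo), hi))
}

#' Arc-length parameterisation of a bone-cartilage boundary
#'
#' Translates a traced boundary polyline into the standardized
#' anterior-to-posterior v axis: v = 0 is the anterior endpoint, v = 1 the
#' posterior endpoint, and intermediate v values interpolate linearly by
#' arc length within segments.
#'
#' @param boundary n x 2 numeric matrix (mm), ordered anterior first
#' @return list with \code{point}, a function mapping v in [0,1] (vector
#'   allowed) to points on the boundary (m x 2 matrix, mm), and
#'   \code{length}, the total arc length in mm
#' @examples
#' p <- arcLengthParameterize(cbind(c(0, 10), c(0, 0)))
#' p$point(0.3)   # (3, 0)
#' p$length       # 10
#' @export
arcLengthParameterize <- function(boundary) {
  P <- .polyMatrix(boundary, "boundary")
  if (is.null(P) || nrow(P) < 2L)
    .cdiStop("cdiDegenerateContour", "boundary needs at least 2 distinct points")
  info <- .arcInfo(P)
  if (info$total <= 0)
    .cdiStop("cdiDegenerateContour", "boundary has zero length")
  list(point = function(v) {
         .assert(all(is.finite(v)) && all(v >= 0 & v <= 1),
                 "v must lie in [0, 1]")
         .pointAtArc(P, v * info$total, info)$points
       },
       length = info$total)
}

#' Resolve an informative location to a physical point
#'
#' Composes \code{\link{sliceForU}} with the arc-length parameterisation of
#' the resolved slice's bone-cartilage boundary: the location (u, v) on a
#' bone becomes a slice index and a point (mm) on that slice's boundary.
#'
#' @param cs a \linkS4class{ContourSet}
#' @param u,v surface coordinates in [0, 1]
#' @param bone "femur" or "tibia"
#' @param name optional location name carried into error conditions
#' @return list with \code{sliceIndex}, \code{point} (length-2 numeric,
#'   mm) and the \linkS4class{SliceContour} as \code{slice}
#' @export
resolveLocation <- function(cs, u, v, bone, name = NA_character_) {
  idx <- sliceForU(cs, u)
  sc <- .findSlice(cs, idx, bone)
  if (is.null(sc))
    .cdiStop("cdiUnmeasurableLocation",
             sprintf("knee '%s': no %s contour on slice %d (location %s)",
                     cs@kneeId, bone, idx, name),
             kneeId = cs@kneeId, location = name)
  par <- arcLengthParameterize(sc@boneBoundary)
  list(sliceIndex = idx, point = drop(par$point(v)), slice = sc)
}

#' Mirror a contour set across the medial-lateral axis
#'
#' Re-expresses a knee in the opposite left/right convention by reversing
#' the slice-index axis (slice i becomes lo + hi - i) and flipping the side
#' label. In-plane coordinates are unchanged. Because one universal
#' location table serves both knees, resolving the same (u, v) on a
#' mirrored set selects the mirrored slice and the same physical point.
#'
#' @param cs a \linkS4class{ContourSet}
#' @return the mirrored \linkS4class{ContourSet}
#' @export
mirrorContourSet <- function(cs) {
  .assert(is(cs, "ContourSet"), "cs must be a ContourSet")
  lo <- min(cs@medialSlice, cs@lateralSlice)
  hi <- max(cs@medialSlice, cs@lateralSlice)
  flip <- function(i) lo + hi - i
  sl <- lapply(cs@slices, function(s) {
    s@sliceIndex <- as.integer(flip(s@sliceIndex))
    s
  })
  contourSet(cs@kneeId, cs@timepoint,
             if (cs@side == "left") "right" else "left",
             cs@geometry, sl, flip(cs@medialSlice), flip(cs@lateralSlice))
}

#' Flag slices whose stored point order disagrees with their neighbours
#'
#' Suppliers are expected to store boundary polylines anterior-first. This
#' checker compares each slice's boundary endpoints with those of the
#' previous slice of the same bone: a slice whose start point is closer to
#' the neighbour's end point than to its start point (and vice versa) has
#' probably been stored reversed.
#'
#' @param cs a \linkS4class{ContourSet}
#' @return data.frame(sliceIndex, bone) of flagged slices (zero rows when
#'   all orientations agree)
#' @export
checkBoundaryOrientation <- function(cs) {
  .assert(is(cs, "ContourSet"), "cs must be a ContourSet")
  out <- data.frame(sliceIndex = integer(), bone = character())
  for (b in c("femur", "tibia")) {
    scs <- Filter(function(s) s@bone == b, cs@slices)
    if (length(scs) < 2L) next
    ord <- order(vapply(scs, function(s) s@sliceIndex, integer(1)))
    scs <- scs[ord]
    for (i in 2:length(scs)) {
      a <- scs[[i - 1]]@boneBoundary
      p <- scs[[i]]@boneBoundary
      d <- function(x, y) sqrt(sum((x - y)^2))
      straight <- d(p[1, ], a[1, ]) + d(p[nrow(p), ], a[nrow(a), ])
      crossed <- d(p[1, ], a[nrow(a), ]) + d(p[nrow(p), ], a[1, ])
      if (crossed < straight)
        out <- rbind(out, data.frame(sliceIndex = scs[[i]]@sliceIndex,
                                     bone = b))
    }
  }
  out
}
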