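#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("functionOrNumeric", c("function", "numeric"))

#' VoxelGeometry: acquisition geometry of a sagittal MR stack
#'
#' Stores the in-plane resolutions, the slice thickness and the slice count
#' of a sagittal acquisition. The slice thickness \code{dz} is the voxel
#' dimension entering the CDI product, so the index carries mm^3 units.
#'
#' @slot dx in-plane x resolution (mm)
#' @slot dy in-plane y resolution (mm)
#' @slot dz slice thickness (mm)
#' @slot nSlices number of sagittal slices (>= 2)
#' @export
setClass("VoxelGeometry",
  representation(dx = "numeric", dy = "numeric", dz = "numeric",
                 nSlices = "integer"),
  validity = function(object) {
    msg <- character()
    for (s in c("dx", "dy", "dz")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v) || v <= 0)
        msg <- c(msg, sprintf("%s must be a single positive number", s))
    }
    if (length(object@nSlices) != 1L || is.na(object@nSlices) ||
        object@nSlices < 2L)
      msg <- c(msg, "nSlices must be >= 2")
    if (length(msg)) msg else TRUE
  })

#' Construct a VoxelGeometry
#'
#' Defaults reproduce the sagittal DESS protocol used by the Osteoarthritis
#' Initiative: 0.365 x 0.456 mm in plane, 0.7 mm slice thickness.
#'
#' @param dx,dy in-plane resolutions (mm)
#' @param dz slice thickness (mm)
#' @param nSlices number of sagittal slices
#' @return a \linkS4class{VoxelGeometry}
#' @examples
#' voxelGeometry()
#' @export
voxelGeometry <- function(dx = 0.365, dy = 0.456, dz = 0.7, nSlices = 31L) {
  new("VoxelGeometry", dx = as.numeric(dx), dy = as.numeric(dy),
      dz = as.numeric(dz), nSlices = as.integer(nSlices))
}

#' SliceContour: traced contours of one bone on one sagittal slice
#'
#' The bone-cartilage interface (\code{boneBoundary}) is an ordered
#' anterior-to-posterior polyline in slice-plane millimetres; the cartilage
#' outer surface (\code{cartilageSurface}) may be \code{NULL} for
#' boundary-only slices (flagged, not measurable).
#'
#' @slot sliceIndex integer sagittal slice index
#' @slot bone "femur" or "tibia"
#' @slot boneBoundary n x 2 numeric matrix (mm), anterior first
#' @slot cartilageSurface n x 2 numeric matrix (mm) or NULL
#' @export
setClass("SliceContour",
  representation(sliceIndex = "integer", bone = "character",
                 boneBoundary = "matrix", cartilageSurface = "matrixOrNULL"),
  validity = function(object) {
    msg <- character()
    if (!object@bone %in% c("femur", "tibia"))
      msg <- c(msg, "bone must be 'femur' or 'tibia'")
    if (nrow(object@boneBoundary) < 2L)
      msg <- c(msg, "boneBoundary needs at least 2 points")
    if (!is.null(object@cartilageSurface) &&
        nrow(object@cartilageSurface) < 2L)
      msg <- c(msg, "cartilageSurface needs at least 2 points when present")
    if (length(msg)) msg else TRUE
  })

#' Construct a SliceContour
#'
#' @param sliceIndex sagittal slice index
#' @param bone "femur" or "tibia"
#' @param boneBoundary bone-cartilage interface polyline, n x 2 (mm),
#'   ordered anterior to posterior
#' @param cartilageSurface cartilage outer-surface polyline or NULL
#' @return a \linkS4class{SliceContour}
#' @export
sliceContour <- function(sliceIndex, bone, boneBoundary,
                         cartilageSurface = NULL) {
  new("SliceContour", sliceIndex = as.integer(sliceIndex),
      bone = as.character(bone),
      boneBoundary = .polyMatrix(boneBoundary, "boneBoundary"),
      cartilageSurface = .polyMatrix(cartilageSurface, "cartilageSurface"))
}

#' ContourSet: all traced contours of one knee at one timepoint
#'
#' Holds the per-slice contours together with the acquisition geometry and
#' the reader-designated most medial and most lateral slices, which anchor
#' the medial-lateral axis of the universal coordinate system.
#'
#' @slot kneeId knee identifier
#' @slot timepoint "baseline" or "followup"
#' @slot side "left" or "right"
#' @slot geometry a \linkS4class{VoxelGeometry}
#' @slot slices list of \linkS4class{SliceContour}
#' @slot medialSlice index of the most medial slice (u = 0)
#' @slot lateralSlice index of the most lateral slice (u = 1)
#' @export
setClass("ContourSet",
  representation(kneeId = "character", timepoint = "character",
                 side = "character", geometry = "VoxelGeometry",
                 slices = "list", medialSlice = "integer",
                 lateralSlice = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@timepoint %in% c("baseline", "followup"))
      msg <- c(msg, "timepoint must be 'baseline' or 'followup'")
    if (!object@side %in% c("left", "right"))
      msg <- c(msg, "side must be 'left' or 'right'")
    if (object@medialSlice == object@lateralSlice)
      msg <- c(msg, "medialSlice and lateralSlice must differ")
    if (!all(vapply(object@slices, is, logical(1), "SliceContour")))
      msg <- c(msg, "slices must all be SliceContour objects")
    else if (length(object@slices)) {
      idx <- vapply(object@slices, function(s) s@sliceIndex, integer(1))
      lo <- min(object@medialSlice, object@lateralSlice)
      hi <- max(object@medialSlice, object@lateralSlice)
      if (any(idx < lo | idx > hi))
        msg <- c(msg, "slice indices must lie between medialSlice and lateralSlice")
      bone <- vapply(object@slices, function(s) s@bone, character(1))
      if (anyDuplicated(paste(idx, bone)))
        msg <- c(msg, "duplicate (sliceIndex, bone) contour")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a ContourSet
#'
#' @param kneeId knee identifier
#' @param timepoint "baseline" or "followup"
#' @param side "left" or "right"
#' @param geometry a \linkS4class{VoxelGeometry}
#' @param slices list of \linkS4class{SliceContour}
#' @param medialSlice,lateralSlice reader-designated extreme slice indices
#' @return a \linkS4class{ContourSet}
#' @export
contourSet <- function(kneeId, timepoint, side, geometry, slices,
                       medialSlice, lateralSlice) {
  new("ContourSet", kneeId = as.character(kneeId),
      timepoint = as.character(timepoint), side = as.character(side),
      geometry = geometry, slices = slices,
      medialSlice = as.integer(medialSlice),
      lateralSlice = as.integer(lateralSlice))
}

#' InformativeLocations: named (u,v) measurement sites per bone
#'
#' A table of named sites on the universal coordinate system at which
#' thickness is measured. The shipped defaults (see
#' \code{\link{defaultLocations}}) are illustrative 3x3 grids in the
#' central weight-bearing region; studies should substitute coordinates
#' derived from their own denuded-frequency analysis
#' (\code{\link{selectInformative}}).
#'
#' @slot locations data.frame with columns name, bone, u, v
#' @slot provenance "default", "discovered" or "user"
#' @export
setClass("InformativeLocations",
  representation(locations = "data.frame", provenance = "character"),
  validity = function(object) {
    msg <- character()
    df <- object@locations
    need <- c("name", "bone", "u", "v")
    if (!all(need %in% names(df)))
      msg <- c(msg, "locations must have columns name, bone, u, v")
    else {
      if (anyDuplicated(df$name)) msg <- c(msg, "location names must be unique")
      if (!all(df$bone %in% c("femur", "tibia")))
        msg <- c(msg, "bone must be 'femur' or 'tibia'")
      if (!all(is.finite(df$u)) || any(df$u < 0 | df$u > 1))
        msg <- c(msg, "u must lie in [0, 1]")
      if (!all(is.finite(df$v)) || any(df$v < 0 | df$v > 1))
        msg <- c(msg, "v must lie in [0, 1]")
    }
    if (!object@provenance %in% c("default", "discovered", "user"))
      msg <- c(msg, "provenance must be default, discovered or user")
    if (length(msg)) msg else TRUE
  })

#' Construct an InformativeLocations set
#'
#' @param locations data.frame with columns name, bone, u, v
#' @param provenance one of "default", "discovered", "user"
#' @return an \linkS4class{InformativeLocations}
#' @export
informativeLocations <- function(locations, provenance = "user") {
  locations <- as.data.frame(locations)
  locations$name <- as.character(locations$name)
  locations$bone <- as.character(locations$bone)
  new("InformativeLocations", locations = locations,
      provenance = provenance)
}

#' CDIResult: per-location samples and aggregate CDI of one knee-timepoint
#'
#' @slot kneeId knee identifier
#' @slot timepoint "baseline" or "followup"
#' @slot samples data.frame of per-location measurements (name, bone,
#'   sliceIndex, u, v, x, y, thickness, length, measurable)
#' @slot femurCDI,tibiaCDI,tibiofemoralCDI aggregate CDI (mm^3);
#'   tibiofemoral = femur + tibia by construction
#' @slot height participant height in metres (length 0 when absent)
#' @slot voxelMode "dz" (slice thickness, default) or "dxdy"
#' @export
setClass("CDIResult",
  representation(kneeId = "character", timepoint = "character",
                 samples = "data.frame", femurCDI = "numeric",
                 tibiaCDI = "numeric", tibiofemoralCDI = "numeric",
                 height = "numeric", voxelMode = "character"),
  validity = function(object) {
    msg <- character()
    if (object@femurCDI < 0 || object@tibiaCDI < 0)
      msg <- c(msg, "CDI values must be non-negative")
    if (abs(object@tibiofemoralCDI -
            (object@femurCDI + object@tibiaCDI)) > 1e-9)
      msg <- c(msg, "tibiofemoralCDI must equal femurCDI + tibiaCDI")
    if (length(object@height) == 1L &&
        (!is.finite(object@height) || object@height <= 0))
      msg <- c(msg, "height must be positive (metres)")
    if (length(msg)) msg else TRUE
  })

#' DenudedFrequencyMap: how often each (u,v) bin is denuded across knees
#'
#' Per-bone matrices of counts over a (u,v) bin grid; dividing by
#' \code{nKnees} gives the denuded frequency in [0,1] used to select
#' informative locations.
#'
#' @slot counts named list of integer matrices (femur, tibia), u bins in
#'   rows, v bins in columns
#' @slot nKnees number of knees accumulated
#' @export
setClass("DenudedFrequencyMap",
  representation(counts = "list", nKnees = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nKnees < 1L) msg <- c(msg, "nKnees must be >= 1")
    if (!length(object@counts) ||
        !all(vapply(object@counts, is.matrix, logical(1))))
      msg <- c(msg, "counts must be a non-empty list of matrices")
    else if (any(vapply(object@counts,
                        function(m) any(m < 0 | m > object@nKnees),
                        logical(1))))
      msg <- c(msg, "counts must lie in [0, nKnees]")
    if (length(msg)) msg else TRUE
  })

#' PhantomSpec: parameters of a synthetic knee
#'
#' Describes the analytic bone surfaces (a convex condylar arc for the
#' femur, a shallow concave arc for the tibial plateau), the ground-truth
#' thickness field, focal defects, and the acquisition geometry of a
#' simulated knee.
#'
#' @slot femurRadius condylar arc radius (mm)
#' @slot tibiaRadius plateau curvature radius (mm)
#' @slot femurSpan,tibiaSpan anterior-posterior angular span (degrees)
#' @slot baseThickness uniform thickness (mm) or function(u, v, bone)
#' @slot defects data.frame(bone, u, v, radius, depth): full-depth discs in
#'   (u,v) space subtracted from the base field, clamped at 0
#' @slot geometry a \linkS4class{VoxelGeometry}
#' @slot side "left" or "right"
#' @slot pointsPerContour vertices per generated polyline
#' @slot seed reproducibility seed carried with the spec (numeric, may be
#'   length 0)
#' @export
setClass("PhantomSpec",
  representation(femurRadius = "numeric", tibiaRadius = "numeric",
                 femurSpan = "numeric", tibiaSpan = "numeric",
                 baseThickness = "functionOrNumeric", defects = "data.frame",
                 geometry = "VoxelGeometry", side = "character",
                 pointsPerContour = "integer", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    for (s in c("femurRadius", "tibiaRadius", "femurSpan", "tibiaSpan")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v) || v <= 0)
        msg <- c(msg, sprintf("%s must be a single positive number", s))
    }
    d <- object@defects
    if (nrow(d)) {
      if (!all(c("bone", "u", "v", "radius", "depth") %in% names(d)))
        msg <- c(msg, "defects needs columns bone, u, v, radius, depth")
      else {
        if (any(d$radius <= 0)) msg <- c(msg, "defect radii must be > 0")
        if (any(d$depth < 0)) msg <- c(msg, "defect depths must be >= 0")
      }
    }
    if (is.numeric(object@baseThickness) &&
        (length(object@baseThickness) != 1L || object@baseThickness < 0))
      msg <- c(msg, "numeric baseThickness must be a single value >= 0")
    if (object@pointsPerContour < 8L)
      msg <- c(msg, "pointsPerContour must be >= 8")
    if (!object@side %in% c("left", "right"))
      msg <- c(msg, "side must be 'left' or 'right'")
    if (length(msg)) msg else TRUE
  })

#' Construct a PhantomSpec
#'
#' Default dimensions give a medial femoral condyle arc of about 42 mm and
#' a tibial plateau arc of about 38 mm anterior-posterior, spanning about
#' 21 mm medial-lateral at the default DESS geometry -- the scale of an
#' adult medial compartment.
#'
#' @param femurRadius,tibiaRadius arc radii (mm)
#' @param femurSpan,tibiaSpan angular spans (degrees)
#' @param baseThickness uniform thickness in mm, or function(u, v, bone)
#' @param defects data.frame(bone, u, v, radius, depth) of focal defects
#' @param geometry a \linkS4class{VoxelGeometry}
#' @param side "left" or "right"
#' @param pointsPerContour polyline vertices per contour
#' @param seed optional seed stored with the spec
#' @return a \linkS4class{PhantomSpec}
#' @examples
#' generatePhantom(phantomSpec(baseThickness = 2))
#' @export
phantomSpec <- function(femurRadius = 20, tibiaRadius = 55,
                        femurSpan = 120, tibiaSpan = 40,
                        baseThickness = 2.0,
                        defects = data.frame(bone = character(),
                                             u = numeric(), v = numeric(),
                                             radius = numeric(),
                                             depth = numeric()),
                        geometry = voxelGeometry(), side = "right",
                        pointsPerContour = 81L, seed = numeric()) {
  new("PhantomSpec", femurRadius = femurRadius, tibiaRadius = tibiaRadius,
      femurSpan = femurSpan, tibiaSpan = tibiaSpan,
      baseThickness = baseThickness, defects = as.data.frame(defects),
      geometry = geometry, side = side,
      pointsPerContour = as.integer(pointsPerContour),
      seed = as.numeric(seed))
}

#' KneePhantom: generated contours plus queryable ground truth
#'
#' @slot contours the generated \linkS4class{ContourSet}
#' @slot truth function(u, v, bone) returning ground-truth thickness (mm)
#' @slot spec the \linkS4class{PhantomSpec} that produced it
#' @export
setClass("KneePhantom",
  representation(contours = "ContourSet", truth = "function",
                 spec = "PhantomSpec"))

#' ReaderNoiseModel: simulated tracing variability
#'
#' Emulates intra-/inter-reader variability: independent Gaussian jitter on
#' every contour vertex and occasional misidentification of the extreme
#' (most medial / most lateral) slices by one slice.
#'
#' @slot sd per-point, per-axis jitter standard deviation (mm)
#' @slot slipProb probability that an extreme-slice designation slips
#'   inward by one slice
#' @slot seed reproducibility seed (numeric, may be length 0)
#' @export
setClass("ReaderNoiseModel",
  representation(sd = "numeric", slipProb = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@sd) != 1L || !is.finite(object@sd) || object@sd < 0)
      msg <- c(msg, "sd must be a single number >= 0")
    if (length(object@slipProb) != 1L || !is.finite(object@slipProb) ||
        object@slipProb < 0 || object@slipProb > 1)
      msg <- c(msg, "slipProb must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Construct a ReaderNoiseModel
#'
#' @param sd contour-vertex jitter sd (mm)
#' @param slipProb probability of an extreme-slice slip
#' @param seed optional seed
#' @return a \linkS4class{ReaderNoiseModel}
#' @export
readerNoiseModel <- function(sd = 0.05, slipProb = 0, seed = numeric()) {
  new("ReaderNoiseModel", sd = as.numeric(sd), slipProb = as.numeric(slipProb),
      seed = as.numeric(seed))
}
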