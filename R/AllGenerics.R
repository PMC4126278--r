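#' @include AllClasses.R
NULL

#' Accessors for kneeCDI objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a kneeCDI object
#' @return \code{kneeId}, \code{timepoint}: character scalars.
#'   \code{slices}: list of \linkS4class{SliceContour}.
#'   \code{cdiValues}: named numeric vector (femur, tibia, tibiofemoral),
#'   raw or height-adjusted. \code{locationsTable}: the data.frame of
#'   (name, bone, u, v). \code{denudedFrequency}: list of per-bone
#'   frequency matrices. \code{nKnees}: integer.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("kneeId", function(object) standardGeneric("kneeId"))

#' @rdname accessors
#' @export
setGeneric("timepoint", function(object) standardGeneric("timepoint"))

#' @rdname accessors
#' @export
setGeneric("slices", function(object) standardGeneric("slices"))

#' @rdname accessors
#' @param adjusted if TRUE, return CDI divided by height (requires height)
#' @export
setGeneric("cdiValues", function(object, adjusted = FALSE)
  standardGeneric("cdiValues"))

#' @rdname accessors
#' @export
setGeneric("locationsTable", function(object)
  standardGeneric("locationsTable"))

#' @rdname accessors
#' @export
setGeneric("denudedFrequency", function(object)
  standardGeneric("denudedFrequency"))

#' @rdname accessors
#' @export
setGeneric("nKnees", function(object) standardGeneric("nKnees"))

setMethod("kneeId", "ContourSet", function(object) object@kneeId)
setMethod("kneeId", "CDIResult", function(object) object@kneeId)
setMethod("timepoint", "ContourSet", function(object) object@timepoint)
setMethod("timepoint", "CDIResult", function(object) object@timepoint)
setMethod("slices", "ContourSet", function(object) object@slices)
setMethod("slices", "KneePhantom", function(object) object@contours@slices)

setMethod("cdiValues", "CDIResult", function(object, adjusted = FALSE) {
  v <- c(femur = object@femurCDI, tibia = object@tibiaCDI,
         tibiofemoral = object@tibiofemoralCDI)
  if (adjusted) {
    .assert(length(object@height) == 1L,
            "no height stored; call heightAdjust() first")
    v <- v / object@height
  }
  v
})

setMethod("locationsTable", "InformativeLocations",
          function(object) object@locations)

setMethod("denudedFrequency", "DenudedFrequencyMap", function(object)
  lapply(object@counts, function(m) m / object@nKnees))

setMethod("nKnees", "DenudedFrequencyMap", function(object) object@nKnees)

#' Per-location measurement samples of a CDI result
#'
#' @param result a \linkS4class{CDIResult}
#' @return data.frame with one row per informative location: name, bone,
#'   sliceIndex, u, v, bone-point coordinates (mm), thickness (mm),
#'   cartilage length (mm), and a measurable flag
#' @export
cdiSamples <- function(result) {
  .assert(is(result, "CDIResult"), "result must be a CDIResult")
  result@samples
}

#' Height stored with a CDI result
#'
#' @param result a \linkS4class{CDIResult}
#' @return height in metres, or NA when not set
#' @export
cdiHeight <- function(result) {
  if (length(result@height)) result@height else NA_real_
}

setMethod("show", "VoxelGeometry", function(object) {
  cat(sprintf("VoxelGeometry: %.3f x %.3f mm in-plane, dz = %.3f mm, %d slices\n",
              object@dx, object@dy, object@dz, object@nSlices))
})

setMethod("show", "SliceContour", function(object) {
  cat(sprintf("SliceContour: slice %d, %s, %d boundary points, %s\n",
              object@sliceIndex, object@bone, nrow(object@boneBoundary),
              if (is.null(object@cartilageSurface)) "boundary-only"
              else sprintf("%d surface points",
                           nrow(object@cartilageSurface))))
})

setMethod("show", "ContourSet", function(object) {
  bones <- vapply(object@slices, function(s) s@bone, character(1))
  cat(sprintf("ContourSet '%s' (%s, %s knee)\n", object@kneeId,
              object@timepoint, object@side))
  cat(sprintf("  slices %d..%d (medial -> lateral), %d femur + %d tibia contours\n",
              object@medialSlice, object@lateralSlice,
              sum(bones == "femur"), sum(bones == "tibia")))
  show(object@geometry)
})

setMethod("show", "InformativeLocations", function(object) {
  tab <- table(object@locations$bone)
  cat(sprintf("InformativeLocations (%s): %s\n", object@provenance,
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
})

setMethod("show", "CDIResult", function(object) {
  cat(sprintf("CDIResult '%s' (%s)\n", object@kneeId, object@timepoint))
  v <- cdiValues(object)
  cat(sprintf("  femur %.2f | tibia %.2f | tibiofemoral %.2f mm^3\n",
              v["femur"], v["tibia"], v["tibiofemoral"]))
  if (length(object@height))
    cat(sprintf("  height-adjusted (%.2f m): %s\n", object@height,
                paste(sprintf("%.2f", cdiValues(object, adjusted = TRUE)),
                      collapse = " | ")))
  nm <- sum(!object@samples$measurable)
  if (nm) cat(sprintf("  %d unmeasurable location(s) flagged\n", nm))
})

setMethod("show", "DenudedFrequencyMap", function(object) {
  dims <- dim(object@counts[[1]])
  cat(sprintf("DenudedFrequencyMap: %d x %d bins, bones: %s, %d knees\n",
              dims[1], dims[2], paste(names(object@counts), collapse = ", "),
              object@nKnees))
})

setMethod("show", "KneePhantom", function(object) {
  cat("KneePhantom with analytic ground truth\n")
  show(object@contours)
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: femur R=%.1f mm (%.0f deg), tibia R=%.1f mm (%.0f deg), %d defect(s)\n",
              object@femurRadius, object@femurSpan, object@tibiaRadius,
              object@tibiaSpan, nrow(object@defects)))
})
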