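#' @include thickness.R
NULL

#' Compute the Cartilage Damage Index of a knee
#'
#' For every informative location the containing slice is resolved via the
#' universal coordinate system, cartilage thickness is measured at the
#' location's boundary point, and the slice's anterior-posterior cartilage
#' length is measured. The per-bone CDI is the sum over locations of
#' thickness x length x voxel size, where voxel size defaults to the slice
#' thickness dz (yielding a volume proxy in mm^3). Lower CDI means more
#' cartilage damage.
#'
#' Locations that resolve to a missing or boundary-only contour are flagged
#' unmeasurable and contribute 0; if every location of a bone is
#' unmeasurable a \code{cdiEmptyMeasurement} error is signalled.
#'
#' @param cs a \linkS4class{ContourSet}
#' @param locations an \linkS4class{InformativeLocations} (defaults to the
#'   illustrative \code{\link{defaultLocations}})
#' @param voxel "dz" (slice thickness, default) or "dxdy" (in-plane voxel
#'   area, for sensitivity analysis; units then mm^4 / mm^2 scaled)
#' @param lengthStep sampling step for \code{\link{measureLength}} (mm)
#' @param cap normal-ray search cap for thickness (mm)
#' @return a \linkS4class{CDIResult}
#' @examples
#' ph <- generatePhantom(phantomSpec(baseThickness = 2))
#' computeCDI(ph@contours)
#' @export
computeCDI <- function(cs, locations = defaultLocations(),
                       voxel = c("dz", "dxdy"), lengthStep = 0.2, cap = 15) {
  .assert(is(cs, "ContourSet"), "cs must be a ContourSet")
  .assert(is(locations, "InformativeLocations"),
          "locations must be an InformativeLocations")
  voxel <- match.arg(voxel)
  loc <- locationsTable(locations)
  .assert(nrow(loc) > 0, "location table is empty")
  vox <- if (voxel == "dz") cs@geometry@dz else cs@geometry@dx * cs@geometry@dy

  samples <- data.frame(name = loc$name, bone = loc$bone, u = loc$u,
                        v = loc$v, sliceIndex = NA_integer_,
                        x = NA_real_, y = NA_real_,
                        thickness = NA_real_, length = NA_real_,
                        measurable = FALSE)
  lenCache <- new.env(parent = emptyenv())

  for (i in seq_len(nrow(loc))) {
    idx <- sliceForU(cs, loc$u[i])
    samples$sliceIndex[i] <- idx
    sc <- .findSlice(cs, idx, loc$bone[i])
    if (is.null(sc) || is.null(sc@cartilageSurface)) next
    prof <- .thicknessProfile(sc, loc$v[i], cap = cap)
    key <- paste(idx, loc$bone[i])
    if (is.null(lenCache[[key]]))
      lenCache[[key]] <- measureLength(sc, step = lengthStep, cap = cap)
    samples$x[i] <- prof$points[1, 1]
    samples$y[i] <- prof$points[1, 2]
    samples$thickness[i] <- prof$thickness[1]
    samples$length[i] <- lenCache[[key]]
    samples$measurable[i] <- TRUE
  }

  perBone <- function(b) {
    rows <- samples[samples$bone == b, , drop = FALSE]
    if (!nrow(rows)) return(0)
    if (!any(rows$measurable))
      .cdiStop("cdiEmptyMeasurement",
               sprintf("knee '%s': no measurable %s location", cs@kneeId, b))
    ok <- rows$measurable
    sum(rows$thickness[ok] * rows$length[ok]) * vox
  }
  fem <- perBone("femur")
  tib <- perBone("tibia")

  new("CDIResult", kneeId = cs@kneeId, timepoint = cs@timepoint,
      samples = samples, femurCDI = fem, tibiaCDI = tib,
      tibiofemoralCDI = fem + tib, height = numeric(), voxelMode = voxel)
}

#' Height-adjust a CDI result
#'
#' Stores the participant's height (metres) with the result; adjusted
#' values (raw CDI divided by height) are then available from
#' \code{cdiValues(result, adjusted = TRUE)}. Raw values are retained.
#'
#' @param result a \linkS4class{CDIResult}
#' @param height participant height in metres (> 0)
#' @return the updated \linkS4class{CDIResult}
#' @examples
#' \dontrun{cdiValues(heightAdjust(res, 1.70), adjusted = TRUE)}
#' @export
heightAdjust <- function(result, height) {
  .assert(is(result, "CDIResult"), "result must be a CDIResult")
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) ||
      height <= 0)
    .cdiStop("cdiValidationError", "height must be a single positive number (metres)")
  result@height <- as.numeric(height)
  validObject(result)
  result
}

#' Longitudinal change score between two CDI results
#'
#' Change is follow-up minus baseline, per region. Both results must belong
#' to the same knee and be in the same adjustment state (both raw, or both
#' carrying a height); with heights present the height-adjusted values are
#' differenced.
#'
#' @param baseline,followup \linkS4class{CDIResult} objects for the same
#'   knee at the two timepoints
#' @return data.frame with one row per region (femur, tibia, tibiofemoral):
#'   kneeId, region, baseline, followup, change, adjusted flag
#' @export
changeScore <- function(baseline, followup) {
  .assert(is(baseline, "CDIResult") && is(followup, "CDIResult"),
          "baseline and followup must be CDIResult objects")
  if (baseline@kneeId != followup@kneeId)
    .cdiStop("cdiValidationError", "kneeId mismatch between timepoints")
  hb <- length(baseline@height) == 1L
  hf <- length(followup@height) == 1L
  if (hb != hf)
    .cdiStop("cdiValidationError",
             "both results must be height-adjusted, or neither")
  b <- cdiValues(baseline, adjusted = hb)
  f <- cdiValues(followup, adjusted = hb)
  data.frame(kneeId = baseline@kneeId, region = names(b),
             baseline = unname(b), followup = unname(f),
             change = unname(f - b), adjusted = hb,
             row.names = NULL)
}

#' Illustrative default informative locations
#'
#' A 3x3 grid per bone in the central weight-bearing region of the medial
#' compartment. These are illustrative placeholders for site coordinates
#' that a study would derive from its own denuded-frequency analysis
#' (\code{\link{selectInformative}}); substitute exact coordinates via
#' \code{\link{informativeLocations}} when available.
#'
#' @return an \linkS4class{InformativeLocations} with 9 femur + 9 tibia
#'   sites, provenance "default"
#' @examples
#' locationsTable(defaultLocations())
#' @export
defaultLocations <- function() {
  grid <- function(bone, prefix, vs) {
    g <- expand.grid(u = c(0.3, 0.5, 0.7), v = vs)
    data.frame(name = paste0(prefix, seq_len(nrow(g))), bone = bone,
               u = g$u, v = g$v)
  }
  informativeLocations(
    rbind(grid("femur", "F", c(0.45, 0.60, 0.75)),
          grid("tibia", "T", c(0.35, 0.50, 0.65))),
    provenance = "default")
}
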