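#' @include cdi.R
NULL

.need <- function(x, field, where) {
  if (is.null(x[[field]]))
    .cdiStop("cdiParseError",
             sprintf("missing field '%s' in %s", field, where))
  x[[field]]
}

.coordsToMatrix <- function(x, field) {
  if (is.null(x)) return(NULL)
  m <- tryCatch(do.call(rbind, lapply(x, function(p) as.numeric(p[1:2]))),
                error = function(e) NULL)
  if (is.null(m) || !is.numeric(m) || anyNA(m))
    .cdiStop("cdiParseError",
             sprintf("field '%s' is not a list of [x, y] pairs", field))
  m
}

#' Read a contour set from JSON
#'
#' Schema (coordinates in mm, slice indices explicit):
#' \preformatted{
#' {knee_id, timepoint, side,
#'  geometry: {dx, dy, dz, n_slices},
#'  medial_slice, lateral_slice,
#'  slices: [{slice_index, bone,
#'            bone_boundary: [[x,y], ...],
#'            cartilage_surface: [[x,y], ...] | null}, ...]}
#' }
#' A slice without a cartilage surface loads as boundary-only (flagged
#' unmeasurable downstream). Schema violations raise a
#' \code{cdiParseError} naming the offending field; invariant violations
#' (e.g. medial_slice == lateral_slice) raise a validity error.
#'
#' @param path JSON file path
#' @param checkSimple also reject self-intersecting polylines
#' @return a \linkS4class{ContourSet}
#' @seealso \code{\link{writeContourSet}} for the lossless inverse
#' @export
readContourSet <- function(path, checkSimple = TRUE) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  g <- .need(j, "geometry", "contour set")
  geom <- voxelGeometry(dx = .need(g, "dx", "geometry"),
                        dy = .need(g, "dy", "geometry"),
                        dz = .need(g, "dz", "geometry"),
                        nSlices = .need(g, "n_slices", "geometry"))
  rawSlices <- .need(j, "slices", "contour set")
  sl <- lapply(rawSlices, function(s) {
    bb <- .coordsToMatrix(.need(s, "bone_boundary", "slice"),
                          "bone_boundary")
    cart <- .coordsToMatrix(s[["cartilage_surface"]], "cartilage_surface")
    sc <- sliceContour(.need(s, "slice_index", "slice"),
                       .need(s, "bone", "slice"), bb, cart)
    if (checkSimple) {
      .assert(.polylineSimple(sc@boneBoundary),
              sprintf("bone_boundary of slice %d (%s) self-intersects",
                      sc@sliceIndex, sc@bone))
      if (!is.null(sc@cartilageSurface))
        .assert(.polylineSimple(sc@cartilageSurface),
                sprintf("cartilage_surface of slice %d (%s) self-intersects",
                        sc@sliceIndex, sc@bone))
    }
    sc
  })
  contourSet(.need(j, "knee_id", "contour set"),
             .need(j, "timepoint", "contour set"),
             .need(j, "side", "contour set"),
             geom, sl,
             .need(j, "medial_slice", "contour set"),
             .need(j, "lateral_slice", "contour set"))
}

#' Write a contour set to JSON
#'
#' Full-precision coordinates; round-trips losslessly with
#' \code{\link{readContourSet}}.
#'
#' @param cs a \linkS4class{ContourSet}
#' @param path output file path
#' @return the path, invisibly
#' @export
writeContourSet <- function(cs, path) {
  .assert(is(cs, "ContourSet"), "cs must be a ContourSet")
  asPairs <- function(m) {
    if (is.null(m)) return(NULL)
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  }
  obj <- list(
    knee_id = cs@kneeId, timepoint = cs@timepoint, side = cs@side,
    geometry = list(dx = cs@geometry@dx, dy = cs@geometry@dy,
                    dz = cs@geometry@dz, n_slices = cs@geometry@nSlices),
    medial_slice = cs@medialSlice, lateral_slice = cs@lateralSlice,
    slices = lapply(cs@slices, function(s) {
      out <- list(slice_index = s@sliceIndex, bone = s@bone,
                  bone_boundary = asPairs(s@boneBoundary))
      out$cartilage_surface <- asPairs(s@cartilageSurface)
      out
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read / write an informative-location table as JSON
#'
#' Format: \code{\{provenance, locations: [\{name, bone, u, v\}, ...]\}}.
#'
#' @param path JSON file path
#' @return \code{readLocations}: an \linkS4class{InformativeLocations}
#' @export
readLocations <- function(path) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  raw <- j[["locations"]]
  if (is.null(raw))
    .cdiStop("cdiParseError", "missing field 'locations' in location table")
  empty <- data.frame(name = character(), bone = character(),
                      u = numeric(), v = numeric())
  rows <- lapply(raw, function(l)
    data.frame(name = .need(l, "name", "location"),
               bone = .need(l, "bone", "location"),
               u = .need(l, "u", "location"),
               v = .need(l, "v", "location")))
  informativeLocations(do.call(rbind, c(list(empty), rows)),
                       provenance = .need(j, "provenance", "location table"))
}

#' @rdname readLocations
#' @param locs an \linkS4class{InformativeLocations}
#' @export
writeLocations <- function(locs, path) {
  .assert(is(locs, "InformativeLocations"),
          "locs must be an InformativeLocations")
  df <- locationsTable(locs)
  obj <- list(provenance = locs@provenance,
              locations = lapply(seq_len(nrow(df)), function(i)
                list(name = df$name[i], bone = df$bone[i],
                     u = df$u[i], v = df$v[i])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write CDI results to a tidy CSV (plus optional per-location JSON)
#'
#' One row per knee-timepoint-region with raw and, when a height is
#' stored, height-adjusted CDI; reported values are rounded to 2 decimals
#' (full precision is retained in the objects). With \code{samplesPath},
#' the per-location thickness/length samples are written to a companion
#' JSON file. Re-running on identical input produces byte-identical files.
#'
#' @param results list of \linkS4class{CDIResult} objects (non-empty)
#' @param path output CSV path
#' @param samplesPath optional companion JSON path
#' @return the CSV path, invisibly
#' @export
writeResults <- function(results, path, samplesPath = NULL) {
  if (!is.list(results) || !length(results))
    .cdiStop("cdiValidationError", "results must be a non-empty list")
  .assert(all(vapply(results, is, logical(1), "CDIResult")),
          "results must all be CDIResult objects")
  rows <- lapply(results, function(r) {
    v <- cdiValues(r)
    adj <- if (length(r@height)) round(v / r@height, 2) else
      rep(NA_real_, 3)
    data.frame(knee_id = r@kneeId, timepoint = r@timepoint,
               region = names(v), cdi = round(unname(v), 2),
               cdi_height_adjusted = unname(adj),
               height_m = if (length(r@height)) r@height else NA_real_,
               n_locations = vapply(names(v), function(b)
                 if (b == "tibiofemoral") nrow(r@samples)
                 else sum(r@samples$bone == b), integer(1)),
               n_measurable = vapply(names(v), function(b)
                 if (b == "tibiofemoral") sum(r@samples$measurable)
                 else sum(r@samples$measurable[r@samples$bone == b]),
                 integer(1)),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(samplesPath)) {
    obj <- lapply(results, function(r) list(
      knee_id = r@kneeId, timepoint = r@timepoint,
      samples = r@samples))
    jsonlite::write_json(obj, samplesPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  }
  invisible(path)
}
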