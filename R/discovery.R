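#' @include cdi.R
NULL

#' Project the denuded-cartilage area of a knee onto the (u,v) grid
#'
#' Evaluates measured cartilage thickness at every bin centre of a (u,v)
#' grid and marks a bin denuded when the thickness is at or below
#' \code{threshold} (default 0 mm: truly denuded, bone exposed). Bins whose
#' slice has no usable contour are marked not-denuded rather than aborting
#' the knee.
#'
#' @param cs a \linkS4class{ContourSet}
#' @param bins grid dimensions c(u bins, v bins), default 50 x 50
#' @param threshold denuded thickness threshold in mm (default 0; values at
#'   or below threshold plus the internal discretisation floor count as
#'   denuded)
#' @param cap normal-ray search cap (mm)
#' @return named list of logical u x v matrices, one per bone present
#' @export
projectDenuded <- function(cs, bins = c(50L, 50L), threshold = 0, cap = 15) {
  .assert(is(cs, "ContourSet"), "cs must be a ContourSet")
  .assert(length(bins) == 2L && all(bins >= 2), "bins must be two counts >= 2")
  nu <- as.integer(bins[1]); nv <- as.integer(bins[2])
  uc <- (seq_len(nu) - 0.5) / nu
  vc <- (seq_len(nv) - 0.5) / nv
  idx <- sliceForU(cs, uc)
  bones <- unique(vapply(cs@slices, function(s) s@bone, character(1)))
  out <- list()
  for (b in bones) {
    mask <- matrix(FALSE, nu, nv)
    for (i in unique(idx)) {
      sc <- .findSlice(cs, i, b)
      if (is.null(sc) || is.null(sc@cartilageSurface)) next
      t <- .thicknessProfile(sc, vc, cap = cap)$thickness
      rows <- which(idx == i)
      mask[rows, ] <- matrix(t <= threshold + .denudedFloor,
                             length(rows), nv, byrow = TRUE)
    }
    out[[b]] <- mask
  }
  out
}

#' Accumulate denuded masks into a frequency map
#'
#' @param masks list of per-knee mask lists as returned by
#'   \code{\link{projectDenuded}}; all must share grid shape and bones
#' @return a \linkS4class{DenudedFrequencyMap}
#' @export
accumulateFrequency <- function(masks) {
  if (!is.list(masks) || !length(masks))
    .cdiStop("cdiValidationError", "masks must be a non-empty list")
  bones <- sort(names(masks[[1]]))
  dims <- dim(masks[[1]][[1]])
  counts <- lapply(bones, function(b) matrix(0L, dims[1], dims[2]))
  names(counts) <- bones
  for (m in masks) {
    if (!identical(sort(names(m)), bones))
      .cdiStop("cdiValidationError", "masks disagree on bones present")
    for (b in bones) {
      if (!identical(dim(m[[b]]), dims))
        .cdiStop("cdiValidationError", "masks disagree on grid shape")
      counts[[b]] <- counts[[b]] + (m[[b]] %in% TRUE) * 1L
    }
  }
  counts <- lapply(counts, function(x) matrix(as.integer(x), dims[1], dims[2]))
  new("DenudedFrequencyMap", counts = counts,
      nKnees = as.integer(length(masks)))
}

#' Select informative locations from a denuded-frequency map
#'
#' Identifies the region of the joint surface most frequently denuded of
#' cartilage and places measurement sites there. Two layouts:
#' \describe{
#'   \item{grid (default)}{the bins whose frequency reaches the top decile
#'     (the 0.9 quantile of positive frequencies) define a region; a
#'     sqrt(n) x sqrt(n) grid is placed at the tercile-band centres of the
#'     region's bounding box -- the 9-site pattern per bone.}
#'   \item{peaks}{the n highest-frequency bins subject to a minimum (u,v)
#'     separation, ties broken by (u, v) lexicographic order.}
#' }
#' Selection depends only on relative frequencies, so it is invariant to
#' rescaling all counts, and the fixed tie rule makes it deterministic.
#'
#' @param freq a \linkS4class{DenudedFrequencyMap}
#' @param n sites per bone (default 9; must be a perfect square for the
#'   grid layout)
#' @param layout "grid" or "peaks"
#' @param bones bones to select for (default both present)
#' @param minSep minimum (u,v) Euclidean separation for the peaks layout
#' @return an \linkS4class{InformativeLocations}, provenance "discovered"
#' @export
selectInformative <- function(freq, n = 9L, layout = c("grid", "peaks"),
                              bones = names(freq@counts), minSep = 0.05) {
  .assert(is(freq, "DenudedFrequencyMap"),
          "freq must be a DenudedFrequencyMap")
  layout <- match.arg(layout)
  .assert(n >= 1, "n must be >= 1")
  fr <- denudedFrequency(freq)
  rows <- list()
  for (b in bones) {
    F <- fr[[b]]
    .assert(!is.null(F), sprintf("no frequency map for bone '%s'", b))
    nu <- nrow(F); nv <- ncol(F)
    uc <- (seq_len(nu) - 0.5) / nu
    vc <- (seq_len(nv) - 0.5) / nv
    if (all(F <= 0))
      .cdiStop("cdiNoDenudedRegion",
               sprintf("frequency map for %s is identically zero", b))
    if (layout == "grid") {
      k <- round(sqrt(n))
      .assert(k * k == n, "grid layout requires n to be a perfect square")
      thr <- stats::quantile(F[F > 0], 0.9, names = FALSE, type = 7)
      sel <- which(F >= thr, arr.ind = TRUE)
      ur <- range(uc[sel[, 1]])
      vr <- range(vc[sel[, 2]])
      fracs <- (2 * seq_len(k) - 1) / (2 * k)
      g <- expand.grid(u = ur[1] + fracs * diff(ur),
                       v = vr[1] + fracs * diff(vr))
      pts <- g[order(g$v, g$u), ]
    } else {
      ord <- order(-F, rep(uc, nv), rep(vc, each = nu))
      cand <- cbind(u = rep(uc, nv), v = rep(vc, each = nu),
                    f = as.vector(F))[ord, , drop = FALSE]
      cand <- cand[cand[, "f"] > 0, , drop = FALSE]
      keep <- matrix(numeric(), 0, 2)
      for (i in seq_len(nrow(cand))) {
        p <- cand[i, 1:2]
        if (!nrow(keep) ||
            all(sqrt(rowSums((keep - matrix(p, nrow(keep), 2,
                                            byrow = TRUE))^2)) >= minSep))
          keep <- rbind(keep, p)
        if (nrow(keep) == n) break
      }
      if (nrow(keep) < n)
        .cdiStop("cdiValidationError",
                 sprintf("cannot place %d separated sites on the %s map", n, b))
      pts <- data.frame(u = keep[, 1], v = keep[, 2])
    }
    prefix <- toupper(substr(b, 1, 1))
    rows[[b]] <- data.frame(name = paste0(prefix, seq_len(nrow(pts))),
                            bone = b, u = pts$u, v = pts$v)
  }
  informativeLocations(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                       provenance = "discovered")
}
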