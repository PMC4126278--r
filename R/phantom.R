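#' @include cdi.R
NULL

# Ground-truth thickness field of a spec: base field minus full-depth
# defect discs in (u,v) space, clamped at 0.
.truthFunction <- function(spec) {
  base <- spec@baseThickness
  defects <- spec@defects
  function(u, v, bone) {
    t0 <- if (is.function(base)) base(u, v, bone) else rep(base, length(u))
    t0 <- rep_len(t0, length(u))
    if (nrow(defects)) {
      for (i in seq_len(nrow(defects))) {
        if (defects$bone[i] != bone) next
        inside <- (u - defects$u[i])^2 + (v - defects$v[i])^2 <=
          defects$radius[i]^2
        t0 <- t0 - inside * defects$depth[i]
      }
    }
    pmax(t0, 0)
  }
}

# Arc geometry per bone: the femoral condyle is a convex circular arc
# (cartilage on the outside), the tibial plateau a shallow concave arc
# (cartilage on the joint-space side, toward the centre).
.boneArc <- function(spec, bone) {
  if (bone == "femur")
    list(R = spec@femurRadius, span = spec@femurSpan * pi / 180,
         centre = c(0, spec@femurRadius + 5), outwardSign = +1)
  else
    list(R = spec@tibiaRadius, span = spec@tibiaSpan * pi / 180,
         centre = c(0, -20 + spec@tibiaRadius), outwardSign = -1)
}

.arcPolylines <- function(arc, thickness) {
  # thickness: vector, one value per vertex
  np <- length(thickness)
  th <- seq(-arc$span / 2, arc$span / 2, length.out = np)
  radial <- cbind(sin(th), -cos(th))       # unit, pointing "down" at th = 0
  bone <- sweep(arc$R * radial, 2, arc$centre, "+")
  cart <- bone + arc$outwardSign * radial * thickness
  list(bone = bone, cartilage = cart)
}

#' Generate a synthetic knee from a phantom specification
#'
#' Builds per-slice bone and cartilage polylines consistent with the
#' spec's analytic surfaces and thickness field. Slice i (i = 0 ..
#' nSlices-1) sits at u = i/(nSlices-1); boundary vertices are equally
#' spaced in arc angle, so the anterior-posterior v coordinate coincides
#' with the analytic angle fraction. Generation is deterministic: the same
#' spec always yields identical contours.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @param kneeId identifier for the generated knee
#' @param timepoint "baseline" or "followup"
#' @return a \linkS4class{KneePhantom} holding the
#'   \linkS4class{ContourSet} and the queryable ground-truth thickness
#'   function(u, v, bone)
#' @examples
#' ph <- generatePhantom(phantomSpec(baseThickness = 2))
#' ph@truth(0.5, 0.5, "femur")   # 2
#' @export
generatePhantom <- function(spec, kneeId = "phantom",
                            timepoint = "baseline") {
  .assert(is(spec, "PhantomSpec"), "spec must be a PhantomSpec")
  nS <- spec@geometry@nSlices
  if (nS < 2L)
    .cdiStop("cdiValidationError", "geometry must provide >= 2 slices")
  truth <- .truthFunction(spec)
  np <- spec@pointsPerContour
  vgrid <- seq(0, 1, length.out = np)
  sl <- vector("list", 2L * nS)
  k <- 0L
  for (i in seq_len(nS) - 1L) {
    u <- i / (nS - 1)
    for (b in c("femur", "tibia")) {
      arc <- .boneArc(spec, b)
      pl <- .arcPolylines(arc, truth(rep(u, np), vgrid, b))
      k <- k + 1L
      sl[[k]] <- sliceContour(i, b, pl$bone, pl$cartilage)
    }
  }
  cs <- contourSet(kneeId, timepoint, spec@side, spec@geometry, sl,
                   medialSlice = 0L, lateralSlice = nS - 1L)
  new("KneePhantom", contours = cs, truth = truth, spec = spec)
}

#' Simulate longitudinal progression of a phantom
#'
#' Produces the follow-up knee: the base thickness field is reduced by a
#' uniform \code{thinning}, existing defects deepen by
#' \code{defectDeepening} and widen by \code{defectWidening}, and the
#' ground truth is clamped at zero. With positive rates the follow-up CDI
#' can only be lower than (or equal to) baseline.
#'
#' @param phantom a \linkS4class{KneePhantom} (baseline)
#' @param thinning uniform cartilage loss in mm (>= 0)
#' @param defectDeepening added defect depth in mm (>= 0)
#' @param defectWidening added defect radius in (u,v) units (>= 0)
#' @return the follow-up \linkS4class{KneePhantom}
#' @export
progressPhantom <- function(phantom, thinning = 0, defectDeepening = 0,
                            defectWidening = 0) {
  .assert(is(phantom, "KneePhantom"), "phantom must be a KneePhantom")
  .assert(thinning >= 0 && defectDeepening >= 0 && defectWidening >= 0,
          "progression rates must be >= 0")
  spec <- phantom@spec
  base <- spec@baseThickness
  thinned <- if (is.function(base)) {
    force(base); force(thinning)
    function(u, v, bone) pmax(base(u, v, bone) - thinning, 0)
  } else max(base - thinning, 0)
  spec@baseThickness <- thinned
  if (nrow(spec@defects)) {
    spec@defects$depth <- spec@defects$depth + defectDeepening
    spec@defects$radius <- spec@defects$radius + defectWidening
  }
  generatePhantom(spec, kneeId = phantom@contours@kneeId,
                  timepoint = "followup")
}

#' Apply simulated reader noise to a contour set
#'
#' Adds independent Gaussian jitter (sd in mm, per vertex and axis) to
#' every polyline and, with probability \code{slipProb} per endpoint,
#' slips the medial or lateral extreme-slice designation inward by one
#' slice. The input object is untouched; the output is reproducible from
#' the model's seed.
#'
#' @param cs a \linkS4class{ContourSet}
#' @param model a \linkS4class{ReaderNoiseModel}
#' @param seed optional seed overriding the model's stored seed
#' @return a jittered \linkS4class{ContourSet}
#' @export
applyReaderNoise <- function(cs, model, seed = NULL) {
  .assert(is(cs, "ContourSet"), "cs must be a ContourSet")
  .assert(is(model, "ReaderNoiseModel"), "model must be a ReaderNoiseModel")
  if (is.null(seed) && length(model@seed)) seed <- model@seed
  .withSeed(seed, {
    sl <- lapply(cs@slices, function(s) {
      if (model@sd > 0) {
        s@boneBoundary <- s@boneBoundary +
          matrix(stats::rnorm(length(s@boneBoundary), 0, model@sd),
                 ncol = 2)
        if (!is.null(s@cartilageSurface))
          s@cartilageSurface <- s@cartilageSurface +
            matrix(stats::rnorm(length(s@cartilageSurface), 0, model@sd),
                   ncol = 2)
      }
      s
    })
    med <- cs@medialSlice
    lat <- cs@lateralSlice
    step <- sign(lat - med)
    if (model@slipProb > 0) {
      if (stats::runif(1) < model@slipProb && abs(lat - med) > 1L)
        med <- med + step
      if (stats::runif(1) < model@slipProb && abs(lat - med) > 1L)
        lat <- lat - step
    }
    keep <- Filter(function(s) {
      lo <- min(med, lat); hi <- max(med, lat)
      s@sliceIndex >= lo && s@sliceIndex <= hi
    }, sl)
    contourSet(cs@kneeId, cs@timepoint, cs@side, cs@geometry, keep, med, lat)
  })
}

#' Ground-truth CDI by dense numerical integration
#'
#' Computes the CDI a perfect measurement would yield, entirely from the
#' phantom's analytic ground truth (never from the generated contours):
#' per location, thickness is the truth field at (u, v) and the cartilage
#' length is the analytic arc length of the slice boundary times the
#' covered fraction, integrated on a dense v grid.
#'
#' @param phantom a \linkS4class{KneePhantom}
#' @param locations an \linkS4class{InformativeLocations}
#' @param nv number of v integration points for the covered fraction
#' @return named numeric: femur, tibia, tibiofemoral ground-truth CDI (mm^3)
#' @export
truthCDI <- function(phantom, locations = defaultLocations(), nv = 2001L) {
  .assert(is(phantom, "KneePhantom"), "phantom must be a KneePhantom")
  spec <- phantom@spec
  nS <- spec@geometry@nSlices
  dz <- spec@geometry@dz
  loc <- locationsTable(locations)
  vg <- (seq_len(nv) - 0.5) / nv
  out <- c(femur = 0, tibia = 0)
  for (b in c("femur", "tibia")) {
    arc <- .boneArc(spec, b)
    Lfull <- arc$R * arc$span
    rows <- loc[loc$bone == b, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      # u snaps to the same slice the pipeline would use
      uSlice <- .roundSlice(rows$u[i] * (nS - 1), 0) / (nS - 1)
      t <- phantom@truth(uSlice, rows$v[i], b)
      covered <- mean(phantom@truth(rep(uSlice, nv), vg, b) > 0)
      out[b] <- out[b] + t * (Lfull * covered) * dz
    }
  }
  c(out, tibiofemoral = unname(out["femur"] + out["tibia"]))
}

# Stratum parameters keyed by JSN-like grade 0..3: mean base thickness and
# focal-defect intensity encoding the planted denuded-area fraction
# (0: none, 1: <10%, 2: 10-30%, 3: >30% of the map).
.strata <- list(
  list(t0 = 2.2, nDefects = 0L, rRange = c(0, 0),       depth = c(0, 0)),
  list(t0 = 2.0, nDefects = 1L, rRange = c(0.08, 0.14), depth = c(1.0, 2.5)),
  list(t0 = 1.8, nDefects = 2L, rRange = c(0.10, 0.16), depth = c(2.5, 3.5)),
  list(t0 = 1.5, nDefects = 3L, rRange = c(0.15, 0.22), depth = c(2.5, 3.5)))

#' Generate a synthetic knee cohort with covariates
#'
#' Draws knees from severity strata encoding JSN-like grades 0-3 with
#' stratum-specific base cartilage thickness and focal-defect intensity
#' (planted denuded-area fraction: none, <10\%, 10-30\%, >30\%). Defect
#' discs are confined to \code{defectRegion} in (u,v) space (centres drawn
#' so discs fit inside it) -- the central weight-bearing region where
#' cartilage loss concentrates. Emits a covariate table (height, grades,
#' progression flags, synthetic alignment and joint-space width) and,
#' optionally, follow-up phantoms with progression applied. The default
#' stratum mixture reflects a JSN distribution typical of an OA-enriched
#' cohort (42/30/25/3 percent for grades 0-3).
#'
#' @param n number of knees (>= 1)
#' @param mixture length-4 non-negative weights over JSN-like grades 0-3
#' @param seed reproducibility seed
#' @param followup also generate 24-month-style follow-up phantoms
#' @param defectRegion c(umin, umax, vmin, vmax) confining defect discs
#' @param jsnProgressionProb probability a knee progresses in JSN grade
#' @param geometry acquisition geometry shared by the cohort
#' @return list with \code{knees} (per knee: \code{baseline} and, when
#'   requested, \code{followup} \linkS4class{KneePhantom}s) and
#'   \code{covariates} (data.frame)
#' @examples
#' co <- generateCohort(3, seed = 1)
#' co$covariates
#' @export
generateCohort <- function(n, mixture = c(0.42, 0.30, 0.25, 0.03),
                           seed = NULL, followup = FALSE,
                           defectRegion = c(0.15, 0.85, 0.15, 0.85),
                           jsnProgressionProb = 0.25,
                           geometry = voxelGeometry()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    .cdiStop("cdiValidationError", "n must be >= 1")
  if (length(mixture) != 4L || any(!is.finite(mixture)) ||
      any(mixture < 0) || sum(mixture) <= 0)
    .cdiStop("cdiValidationError",
             "mixture must be 4 non-negative weights with positive sum")
  mixture <- mixture / sum(mixture)
  .assert(length(defectRegion) == 4L && defectRegion[2] > defectRegion[1] &&
            defectRegion[4] > defectRegion[3],
          "defectRegion must be c(umin, umax, vmin, vmax)")
  .withSeed(seed, {
    knees <- vector("list", n)
    cov <- data.frame(kneeId = sprintf("knee%03d", seq_len(n)),
                      side = sample(c("left", "right"), n, replace = TRUE),
                      heightM = pmin(pmax(stats::rnorm(n, 1.69, 0.09),
                                          1.40), 2.00),
                      jsnBaseline = NA_integer_, jsnFollowup = NA_integer_,
                      klBaseline = NA_integer_, klFollowup = NA_integer_,
                      jsnProgressor = NA, klProgressor = NA,
                      hkaDeg = NA_real_, jswBaselineMm = NA_real_,
                      jswChangeMm = NA_real_)
    for (i in seq_len(n)) {
      grade <- sample(0:3, 1L, prob = mixture)
      st <- .strata[[grade + 1L]]
      t0 <- max(stats::rnorm(1, st$t0, 0.15), 0.8)
      defects <- data.frame(bone = character(), u = numeric(),
                            v = numeric(), radius = numeric(),
                            depth = numeric())
      if (st$nDefects > 0L) {
        for (b in c("femur", "tibia")) {
          r <- stats::runif(st$nDefects, st$rRange[1], st$rRange[2])
          halfU <- (defectRegion[2] - defectRegion[1]) / 2
          halfV <- (defectRegion[4] - defectRegion[3]) / 2
          r <- pmin(r, min(halfU, halfV) - 1e-3)
          defects <- rbind(defects, data.frame(
            bone = b,
            u = stats::runif(st$nDefects, defectRegion[1] + r,
                             defectRegion[2] - r),
            v = stats::runif(st$nDefects, defectRegion[3] + r,
                             defectRegion[4] - r),
            radius = r,
            depth = stats::runif(st$nDefects, st$depth[1], st$depth[2])))
        }
      }
      spec <- phantomSpec(baseThickness = t0, defects = defects,
                          geometry = geometry, side = cov$side[i])
      base <- generatePhantom(spec, kneeId = cov$kneeId[i])
      prog <- stats::runif(1) < jsnProgressionProb
      fu <- NULL
      if (followup) {
        thin <- if (prog) abs(stats::rnorm(1, 0.15, 0.05))
                else abs(stats::rnorm(1, 0.05, 0.02))
        fu <- progressPhantom(base, thinning = thin,
                              defectDeepening = if (prog) 0.5 else 0,
                              defectWidening = if (prog) 0.02 else 0)
      } else thin <- 0
      knees[[i]] <- list(baseline = base, followup = fu)
      klProg <- prog || stats::runif(1) < 0.19
      cov$jsnBaseline[i] <- grade
      cov$jsnFollowup[i] <- if (prog) min(grade + 1L, 3L) else grade
      cov$klBaseline[i] <- min(grade + 1L, 4L)
      cov$klFollowup[i] <- if (klProg) min(cov$klBaseline[i] + 1L, 4L)
                           else cov$klBaseline[i]
      cov$jsnProgressor[i] <- cov$jsnFollowup[i] != cov$jsnBaseline[i]
      cov$klProgressor[i] <- cov$klFollowup[i] != cov$klBaseline[i]
      cov$hkaDeg[i] <- stats::rnorm(1, -1.2 * grade, 2)
      cov$jswBaselineMm[i] <- max(stats::rnorm(1, 1.8 * t0 - 0.6 * grade, 0.4),
                                  0.2)
      cov$jswChangeMm[i] <- -2 * thin + stats::rnorm(1, 0, 0.15)
    }
    list(knees = knees, covariates = cov)
  })
}

#' Simulated repeated readings of a cohort for reliability analysis
#'
#' Re-measures each knee k times under independent reader noise and
#' returns the targets x sessions matrix of tibiofemoral (or per-bone) CDI
#' suitable for \code{\link{icc}}.
#'
#' @param phantoms list of \linkS4class{KneePhantom}s (one per knee)
#' @param k number of repeated readings
#' @param model a \linkS4class{ReaderNoiseModel} (its seed is ignored;
#'   per-reading seeds derive from \code{seed})
#' @param locations informative locations used for measurement
#' @param region "tibiofemoral", "femur" or "tibia"
#' @param seed base seed; reading j of knee i uses seed + (i-1)*k + j
#' @return numeric matrix, knees x readings
#' @export
simulateRereads <- function(phantoms, k = 2L,
                            model = readerNoiseModel(sd = 0.05),
                            locations = defaultLocations(),
                            region = "tibiofemoral", seed = 1L) {
  .assert(length(phantoms) >= 2L, "need at least 2 knees")
  .assert(k >= 2L, "need at least 2 readings")
  out <- matrix(NA_real_, length(phantoms), k)
  for (i in seq_along(phantoms)) {
    cs <- phantoms[[i]]@contours
    for (j in seq_len(k)) {
      noisy <- applyReaderNoise(cs, model,
                                seed = seed + (i - 1L) * k + j)
      out[i, j] <- cdiValues(computeCDI(noisy, locations))[region]
    }
  }
  dimnames(out) <- list(vapply(phantoms,
                               function(p) p@contours@kneeId, character(1)),
                        paste0("read", seq_len(k)))
  out
}
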