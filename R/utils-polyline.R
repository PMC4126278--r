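# Internal planar polyline primitives. All coordinates are millimetres in
# the sagittal slice plane; polylines are n x 2 matrices ordered
# anterior -> posterior.

# Drop consecutive duplicate vertices (zero-length segments break the
# arc-length parameterisation).
.dedupPolyline <- function(P) {
  if (nrow(P) < 2L) return(P)
  d <- diff(P)
  keep <- c(TRUE, rowSums(d^2) > 0)
  P[keep, , drop = FALSE]
}

.polyMatrix <- function(x, what = "polyline") {
  if (is.null(x)) return(NULL)
  m <- as.matrix(x)
  .assert(is.numeric(m) && ncol(m) == 2L,
          sprintf("%s must be an n x 2 numeric matrix", what))
  .assert(all(is.finite(m)), sprintf("%s contains non-finite coordinates", what))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  .dedupPolyline(m)
}

# Segment lengths / cumulative arc length.
.arcInfo <- function(P) {
  d <- diff(P)
  len <- sqrt(rowSums(d^2))
  cum <- c(0, cumsum(len))
  list(d = d, len = len, cum = cum, total = cum[length(cum)])
}

# Points (and unit tangents) at arc positions s along P. At an interior
# vertex the tangent is the normalised average of the adjacent segment
# directions, per the local-normal convention used for thickness rays.
.pointAtArc <- function(P, s, info = .arcInfo(P)) {
  n <- nrow(P)
  s <- pmin(pmax(s, 0), info$total)
  seg <- findInterval(s, info$cum, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), n - 1L)
  frac <- (s - info$cum[seg]) / info$len[seg]
  pts <- P[seg, , drop = FALSE] + info$d[seg, , drop = FALSE] * frac
  tang <- info$d[seg, , drop = FALSE] / info$len[seg]
  # vertex hits: average adjacent segment directions
  atVertex <- which(seg > 1L & abs(s - info$cum[seg]) < 1e-9)
  for (i in atVertex) {
    k <- seg[i]
    t2 <- info$d[k - 1L, ] / info$len[k - 1L] + info$d[k, ] / info$len[k]
    nt <- sqrt(sum(t2^2))
    if (nt > 0) tang[i, ] <- t2 / nt
  }
  list(points = pts, tangents = tang, segment = seg)
}

# Nearest point on polyline P for each query point (rows of Q).
# Returns distances, foot points, and arc positions s of the feet.
.nearestOnPolyline <- function(P, Q, info = .arcInfo(P)) {
  a <- P[-nrow(P), , drop = FALSE]
  d <- info$d
  m <- nrow(Q)
  ns <- nrow(a)
  qx <- matrix(Q[, 1], m, ns)
  qy <- matrix(Q[, 2], m, ns)
  ax <- matrix(a[, 1], m, ns, byrow = TRUE)
  ay <- matrix(a[, 2], m, ns, byrow = TRUE)
  dx <- matrix(d[, 1], m, ns, byrow = TRUE)
  dy <- matrix(d[, 2], m, ns, byrow = TRUE)
  len2 <- matrix(info$len^2, m, ns, byrow = TRUE)
  tt <- pmin(pmax(((qx - ax) * dx + (qy - ay) * dy) / len2, 0), 1)
  px <- ax + tt * dx
  py <- ay + tt * dy
  d2 <- (qx - px)^2 + (qy - py)^2
  j <- max.col(-d2, ties.method = "first")
  idx <- cbind(seq_len(m), j)
  list(dist = sqrt(d2[idx]),
       point = cbind(px[idx], py[idx]),
       s = info$cum[j] + tt[idx] * info$len[j])
}

# First intersection of rays (origins O, unit directions D, one ray per row)
# with polyline P, within distance cap. Returns the hit distance per ray
# (Inf where no hit).
.rayHits <- function(O, D, P, cap = Inf) {
  a <- P[-nrow(P), , drop = FALSE]
  e <- diff(P)
  m <- nrow(O)
  ns <- nrow(a)
  ox <- matrix(O[, 1], m, ns); oy <- matrix(O[, 2], m, ns)
  dxm <- matrix(D[, 1], m, ns); dym <- matrix(D[, 2], m, ns)
  ax <- matrix(a[, 1], m, ns, byrow = TRUE)
  ay <- matrix(a[, 2], m, ns, byrow = TRUE)
  ex <- matrix(e[, 1], m, ns, byrow = TRUE)
  ey <- matrix(e[, 2], m, ns, byrow = TRUE)
  wx <- ax - ox
  wy <- ay - oy
  denom <- dxm * ey - dym * ex          # cross(d, e)
  tnum <- wx * ey - wy * ex             # cross(w, e)
  unum <- wx * dym - wy * dxm           # cross(w, d)
  tt <- tnum / denom
  uu <- unum / denom
  eps <- 1e-9
  ok <- is.finite(tt) & abs(denom) > 1e-12 &
    uu >= -eps & uu <= 1 + eps & tt >= -eps & tt <= cap
  tt[!ok] <- Inf
  hit <- apply(tt, 1L, min)
  pmax(hit, 0)
}

# Does polyline P self-intersect (excluding shared endpoints of adjacent
# segments)? O(n^2) vectorised; used only at I/O boundaries.
.polylineSimple <- function(P) {
  n <- nrow(P) - 1L
  if (n < 3L) return(TRUE)
  a <- P[-nrow(P), , drop = FALSE]
  e <- diff(P)
  ii <- rep(seq_len(n), each = n)
  jj <- rep(seq_len(n), times = n)
  keep <- jj > ii + 1L
  ii <- ii[keep]; jj <- jj[keep]
  if (!length(ii)) return(TRUE)
  denom <- e[ii, 1] * e[jj, 2] - e[ii, 2] * e[jj, 1]
  wx <- a[jj, 1] - a[ii, 1]
  wy <- a[jj, 2] - a[ii, 2]
  tt <- (wx * e[jj, 2] - wy * e[jj, 1]) / denom
  uu <- (wx * e[ii, 2] - wy * e[ii, 1]) / denom
  eps <- 1e-12
  cross <- is.finite(tt) & is.finite(uu) &
    tt > eps & tt < 1 - eps & uu > eps & uu < 1 - eps
  !any(cross)
}

# Uniform resampling of a polyline to n points by arc length (test helper
# and contour normalisation utility).
.resamplePolyline <- function(P, n) {
  info <- .arcInfo(P)
  s <- seq(0, info$total, length.out = n)
  .pointAtArc(P, s, info)$points
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  .assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
          "seed must be a single finite number")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
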