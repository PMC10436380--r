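#' @include AllClasses.R
NULL

#' Geometry constructors
#'
#' Geometric realizations of shapes on a dimensionless 2-D canvas
#' (x rightward, y downward). Circles are center + radius; polygons are
#' simple vertex rings; polylines are open vertex chains; segments are
#' two-point polylines.
#'
#' @param center numeric 2-vector.
#' @param radius positive scalar.
#' @return a [Geometry] object.
#' @examples
#' circleGeom(c(0, 0), 1)
#' @export
circleGeom <- function(center, radius) {
  new("CircleGeom", center = as.numeric(center), radius = as.numeric(radius))
}

#' @rdname circleGeom
#' @param vertices n x 2 coordinate matrix.
#' @export
polygonGeom <- function(vertices) {
  new("PolygonGeom", vertices = asVertexMatrix(vertices))
}

#' @rdname circleGeom
#' @export
polylineGeom <- function(vertices) {
  new("PolylineGeom", vertices = asVertexMatrix(vertices))
}

#' @rdname circleGeom
#' @param p1,p2 segment endpoints.
#' @export
segmentGeom <- function(p1, p2) {
  new("SegmentGeom", vertices = rbind(as.numeric(p1), as.numeric(p2)))
}

#' Regular polygon vertices
#' @param center,radius circumscribed circle.
#' @param n number of vertices.
#' @param rotate rotation in radians.
#' @return a [PolygonGeom].
#' @export
regularPolygonGeom <- function(center, radius, n, rotate = 0) {
  th <- rotate + 2 * pi * (seq_len(n) - 1) / n
  polygonGeom(cbind(center[1] + radius * cos(th),
                    center[2] + radius * sin(th)))
}

asVertexMatrix <- function(v) {
  m <- as.matrix(v)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

# do two closed segments properly intersect (used for polygon simplicity)
segIntersect <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-14) return(FALSE)
  t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
  u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
  t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12
}

# non-adjacent edge pairs of the closed ring must not cross
selfIntersects <- function(v) {
  n <- nrow(v)
  if (n < 4) return(FALSE)
  idx <- rbind(cbind(seq_len(n), c(seq_len(n)[-1], 1)))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      if (segIntersect(v[idx[i, 1], ], v[idx[i, 2], ],
                       v[idx[j, 1], ], v[idx[j, 2], ])) return(TRUE)
    }
  }
  FALSE
}

#' Spatial evaluation configuration
#'
#' @param resolution grid step of the sampling lattice (canvas units).
#' @param eps boundary tolerance; a point within `eps` of a boundary is
#'   classified as boundary. Defaults to twice the resolution, so tangency
#'   detection depends on `eps` (documented, configurable).
#' @param strict use standard point-set DE-9IM predicate definitions
#'   (including exterior flags) instead of the four-flag truth table.
#' @return a config list.
#' @export
spatialConfig <- function(resolution = 0.01, eps = 2 * resolution,
                          strict = FALSE) {
  stopifnot(resolution > 0, eps > 0)
  list(resolution = resolution, eps = eps, strict = strict)
}

#' Bounding box of a geometry
#' @param g a [Geometry].
#' @return list with `xlim` and `ylim`.
#' @export
geomBBox <- function(g) {
  if (is(g, "CircleGeom")) {
    list(xlim = g@center[1] + c(-1, 1) * g@radius,
         ylim = g@center[2] + c(-1, 1) * g@radius)
  } else {
    list(xlim = range(g@vertices[, 1]), ylim = range(g@vertices[, 2]))
  }
}

geomExtent <- function(g) {
  bb <- geomBBox(g)
  max(diff(bb$xlim), diff(bb$ylim))
}

# squared distance from points (px, py) to each segment, returning the
# minimum over segments; fully vectorized over points
minSegmentDistance <- function(px, py, v, closed = FALSE) {
  n <- nrow(v)
  ends <- if (closed) c(seq_len(n)[-1], 1) else seq_len(n)[-1]
  starts <- seq_len(n - !closed)
  best <- rep(Inf, length(px))
  for (k in seq_along(starts)) {
    a <- v[starts[k], ]; b <- v[ends[k], ]
    dx <- b[1] - a[1]; dy <- b[2] - a[2]
    len2 <- dx * dx + dy * dy
    if (len2 < 1e-300) {
      d2 <- (px - a[1])^2 + (py - a[2])^2
    } else {
      t <- ((px - a[1]) * dx + (py - a[2]) * dy) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (px - (a[1] + t * dx))^2 + (py - (a[2] + t * dy))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Classify query points against a geometry
#'
#' Implements the membership contract: each point is interior (2), boundary
#' (1, within tolerance `eps`), or exterior (0). For 1-D geometries
#' (polylines, segments) the `eps`-tube around the curve plays the role of
#' the point set: points near the endpoints are boundary, other on-curve
#' points are interior.
#'
#' @param g a [Geometry].
#' @param pts n x 2 coordinate matrix.
#' @param eps boundary tolerance.
#' @return integer vector (0 exterior, 1 boundary, 2 interior).
#' @export
classifyPoints <- function(g, pts, eps) {
  px <- pts[, 1]; py <- pts[, 2]
  if (is(g, "CircleGeom")) {
    d <- sqrt((px - g@center[1])^2 + (py - g@center[2])^2)
    out <- integer(length(px))
    out[d < g@radius - eps] <- 2L
    out[abs(d - g@radius) <= eps] <- 1L
    out
  } else if (is(g, "PolygonGeom")) {
    db <- minSegmentDistance(px, py, g@vertices, closed = TRUE)
    inside <- pracma::inpolygon(px, py, g@vertices[, 1], g@vertices[, 2],
                                boundary = TRUE)
    out <- integer(length(px))
    out[inside & db > eps] <- 2L
    out[db <= eps] <- 1L
    out
  } else if (is(g, "PolylineGeom")) {
    d <- minSegmentDistance(px, py, g@vertices, closed = FALSE)
    n <- nrow(g@vertices)
    de <- pmin(sqrt((px - g@vertices[1, 1])^2 + (py - g@vertices[1, 2])^2),
               sqrt((px - g@vertices[n, 1])^2 + (py - g@vertices[n, 2])^2))
    out <- integer(length(px))
    out[d <= eps] <- 2L
    out[d <= eps & de <= eps] <- 1L
    out
  } else {
    dvStop("unsupported geometry", "geometryError")
  }
}

jointGrid <- function(a, b, resolution, eps) {
  ba <- geomBBox(a); bb <- geomBBox(b)
  xlim <- range(ba$xlim, bb$xlim) + c(-2, 2) * eps
  ylim <- range(ba$ylim, bb$ylim) + c(-2, 2) * eps
  # the lattice origin is offset by an irrational fraction of the step so
  # that lattice points never sit exactly on round-number boundaries
  shift <- resolution * (sqrt(5) - 1) / 2
  list(x = seq(xlim[1] - shift, xlim[2], by = resolution),
       y = seq(ylim[1] - shift, ylim[2], by = resolution))
}

#' Grid-sampling intersection state (the reference evaluation)
#'
#' Exhaustively samples the joint bounding box (expanded by `2 * eps`) on a
#' deterministic row-major lattice of step `resolution`, classifies every
#' lattice point against both geometries, and reports which
#' interior/boundary combinations are realized. No randomness is involved.
#'
#' @param a,b [Geometry] objects with positive extent relative to the
#'   resolution (a geometry smaller than twice the resolution raises a
#'   degenerate-geometry error so the caller refines the grid).
#' @param config a [spatialConfig()].
#' @return an [IntersectionState].
#' @export
gridIntersectionState <- function(a, b, config = spatialConfig()) {
  checkDegenerate(a, config); checkDegenerate(b, config)
  g <- jointGrid(a, b, config$resolution, config$eps)
  pts <- cbind(rep(g$x, times = length(g$y)),
               rep(g$y, each = length(g$x)))
  ca <- classifyPoints(a, pts, config$eps)
  cb <- classifyPoints(b, pts, config$eps)
  new("IntersectionState",
      bb = any(ca == 1L & cb == 1L),
      ii = any(ca == 2L & cb == 2L),
      bi = any(ca == 1L & cb == 2L),
      ib = any(ca == 2L & cb == 1L),
      extra = c(ie = any(ca == 2L & cb == 0L),
                be = any(ca == 1L & cb == 0L),
                ei = any(ca == 0L & cb == 2L),
                eb = any(ca == 0L & cb == 1L)))
}

checkDegenerate <- function(g, config) {
  if (geomExtent(g) < 2 * config$resolution)
    dvStop(paste0("geometry extent below twice the grid resolution; ",
                  "refine the resolution"), "degenerateGeometryError")
  invisible(TRUE)
}

# y-intervals of a circle band on one grid column x; returns a 2-column
# matrix of [lo, hi] intervals (in grid coordinates). Interior (d < r-eps)
# and exterior (d > r+eps) are open sets: their intervals are shrunk by a
# hair margin so ties go to the closed boundary band, exactly as the grid
# classifier resolves them.
circleColumnBand <- function(g, x, band, eps, ylim, hair = 1e-9) {
  cx <- g@center[1]; cy <- g@center[2]; r <- g@radius
  dx2 <- (x - cx)^2
  ival <- function(lo, hi) if (hi >= lo) rbind(c(lo, hi)) else NULL
  half <- function(rr) { t <- rr * rr - dx2; if (t > 0) sqrt(t) else NA }
  hOut <- half(r + eps)   # outer edge of the boundary annulus
  hIn  <- half(r - eps)   # inner edge
  out <- NULL
  if (band == "interior") {
    if (!is.na(hIn)) out <- ival(cy - hIn + hair, cy + hIn - hair)
  } else if (band == "boundary") {
    if (!is.na(hOut)) {
      if (!is.na(hIn)) {
        out <- rbind(ival(cy - hOut, cy - hIn), ival(cy + hIn, cy + hOut))
      } else {
        out <- ival(cy - hOut, cy + hOut)
      }
    }
  } else { # exterior
    if (!is.na(hOut)) {
      out <- rbind(ival(ylim[1], cy - hOut - hair),
                   ival(cy + hOut + hair, ylim[2]))
    } else {
      out <- ival(ylim[1], ylim[2])
    }
  }
  if (is.null(out)) matrix(numeric(0), ncol = 2) else out
}

# does any lattice point y0 + k*res fall inside [lo, hi]? interior bands
# are open, handled by shrinking with a hair tolerance
latticeHit <- function(iv, y0, res, open = FALSE) {
  if (!nrow(iv)) return(FALSE)
  pad <- if (open) 1e-12 else 0
  for (i in seq_len(nrow(iv))) {
    lo <- iv[i, 1] + pad; hi <- iv[i, 2] - pad
    k <- ceiling((lo - y0) / res - 1e-12)
    if (y0 + k * res <= hi + 1e-12) return(TRUE)
  }
  FALSE
}

intersectIntervals <- function(A, B) {
  if (!nrow(A) || !nrow(B)) return(matrix(numeric(0), ncol = 2))
  out <- NULL
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    lo <- max(A[i, 1], B[j, 1]); hi <- min(A[i, 2], B[j, 2])
    if (hi >= lo) out <- rbind(out, c(lo, hi))
  }
  if (is.null(out)) matrix(numeric(0), ncol = 2) else out
}

# exact-on-the-lattice circle-circle shortcut: per grid column the band
# conditions reduce to y-intervals, so lattice emptiness is decided in
# closed form; agrees with gridIntersectionState by construction
circleCircleState <- function(a, b, config) {
  g <- jointGrid(a, b, config$resolution, config$eps)
  ylim <- range(g$y)
  flags <- c(bb = FALSE, ii = FALSE, bi = FALSE, ib = FALSE,
             ie = FALSE, be = FALSE, ei = FALSE, eb = FALSE)
  combos <- list(bb = c("boundary", "boundary"), ii = c("interior", "interior"),
                 bi = c("boundary", "interior"), ib = c("interior", "boundary"),
                 ie = c("interior", "exterior"), be = c("boundary", "exterior"),
                 ei = c("exterior", "interior"), eb = c("exterior", "boundary"))
  for (x in g$x) {
    bands <- list(
      a = lapply(c(interior = "interior", boundary = "boundary",
                   exterior = "exterior"),
                 function(bn) circleColumnBand(a, x, bn, config$eps, ylim)),
      b = lapply(c(interior = "interior", boundary = "boundary",
                   exterior = "exterior"),
                 function(bn) circleColumnBand(b, x, bn, config$eps, ylim)))
    for (nm in names(combos)) {
      if (flags[[nm]]) next
      iv <- intersectIntervals(bands$a[[combos[[nm]][1]]],
                               bands$b[[combos[[nm]][2]]])
      if (latticeHit(iv, g$y[1], config$resolution)) flags[[nm]] <- TRUE
    }
    if (all(flags)) break
  }
  new("IntersectionState", bb = flags[["bb"]], ii = flags[["ii"]],
      bi = flags[["bi"]], ib = flags[["ib"]],
      extra = flags[c("ie", "be", "ei", "eb")])
}

#' Intersection state of two geometries
#'
#' Computes the four interior/boundary intersection flags underlying all
#' spatial predicates. Circle pairs take an analytic per-column shortcut
#' that is exact on the sampling lattice (and therefore agrees with
#' [gridIntersectionState()]); all other pairs are evaluated by grid
#' sampling.
#'
#' @inheritParams gridIntersectionState
#' @return an [IntersectionState].
#' @examples
#' st <- intersectionState(circleGeom(c(0, 0), 1), circleGeom(c(5, 0), 1))
#' st@bb  # FALSE: separated circles share nothing
#' @export
intersectionState <- function(a, b, config = spatialConfig()) {
  checkDegenerate(a, config); checkDegenerate(b, config)
  if (is(a, "CircleGeom") && is(b, "CircleGeom"))
    circleCircleState(a, b, config)
  else gridIntersectionState(a, b, config)
}

setMethod("show", "IntersectionState", function(object) {
  cat(sprintf("IntersectionState(bb=%s, ii=%s, bi=%s, ib=%s)\n",
              object@bb, object@ii, object@bi, object@ib))
})

# truth table mapping the four flags to predicate labels (first argument A)
predicateFromState <- function(name, st, strict = FALSE) {
  if (!strict) {
    switch(name,
      spatialDisjoint  = !st@bb && !st@ii && !st@bi && !st@ib,
      spatialOverlap   =  st@bb &&  st@ii &&  st@bi &&  st@ib,
      spatialMeet      =  st@bb && !st@ii && !st@bi && !st@ib,
      spatialEqual     =  st@bb &&  st@ii && !st@bi && !st@ib,
      spatialInside    =  st@ii &&  st@bi && !st@bb,
      spatialContains  =  st@ii &&  st@ib && !st@bb,
      spatialCoveredBy =  st@bb &&  st@ii &&  st@bi,
      spatialCovers    =  st@bb &&  st@ii &&  st@ib,
      dvStop(sprintf("unknown predicate '%s'; vocabulary: %s", name,
                     paste(spatialPredicates(), collapse = ", ")),
             "vocabularyError"))
  } else {
    ex <- st@extra
    switch(name,
      spatialDisjoint  = !st@bb && !st@ii && !st@bi && !st@ib,
      spatialOverlap   =  st@ii && ex[["ie"]] && ex[["ei"]],
      spatialMeet      = !st@ii && (st@bb || st@bi || st@ib),
      spatialEqual     =  st@ii && !ex[["ie"]] && !ex[["ei"]] &&
                          !ex[["be"]] && !ex[["eb"]],
      spatialInside    =  st@ii && !ex[["ie"]] && !ex[["be"]] && !st@bb,
      spatialContains  =  st@ii && !ex[["ei"]] && !ex[["eb"]] && !st@bb,
      spatialCoveredBy =  st@ii && !ex[["ie"]] && !ex[["be"]],
      spatialCovers    =  st@ii && !ex[["ei"]] && !ex[["eb"]],
      dvStop(sprintf("unknown predicate '%s'", name), "vocabularyError"))
  }
}

#' Evaluate one spatial predicate on a geometry pair
#'
#' The nine-predicate vocabulary maps the four intersection flags through a
#' fixed truth table: disjoint shares nothing; meet shares only boundary;
#' equal shares boundary and interior but neither boundary enters the
#' other's interior; overlap realizes all four combinations; inside/contains
#' and coveredBy/covers are converse pairs distinguished by which boundary
#' runs through which interior. `spatialSurround` takes a composite first
#' argument (see [spatialSurrounds()]).
#'
#' @param name predicate label from [spatialPredicates()].
#' @param a,b [Geometry] objects; for `spatialSurround`, `a` may be a list
#'   of geometries.
#' @param config a [spatialConfig()]; `strict = TRUE` switches to standard
#'   point-set definitions using exterior flags.
#' @return logical.
#' @examples
#' spatialPredicate("spatialMeet", circleGeom(c(0, 0), 1),
#'                  circleGeom(c(2, 0), 1))
#' @export
spatialPredicate <- function(name, a, b, config = spatialConfig()) {
  if (!name %in% spatialPredicates())
    dvStop(sprintf("unknown predicate '%s'; vocabulary: %s", name,
                   paste(spatialPredicates(), collapse = ", ")),
           "vocabularyError")
  if (name == "spatialSurround") return(spatialSurrounds(a, b, config))
  if (is.list(a) || is.list(b))
    dvStop("composite arguments are only supported by spatialSurround",
           "geometryError")
  predicateFromState(name, intersectionState(a, b, config), config$strict)
}

#' Does a composite geometry surround another?
#'
#' A (possibly composite) geometry `a` surrounds `b` when `b` lies inside
#' the region enclosed by the convex hull of `a`'s components and the
#' interiors of `a` and `b` do not overlap. This realizes assertions such
#' as "interconnecting lines surrounding large hypopigmented circles"; the
#' definition is a toolkit convention, since only the predicate's name is
#' fixed by the vocabulary.
#'
#' @param a [Geometry] or list of geometries (the surrounding composite).
#' @param b [Geometry] (the surrounded object).
#' @param config a [spatialConfig()].
#' @return logical.
#' @export
spatialSurrounds <- function(a, b, config = spatialConfig()) {
  parts <- if (is.list(a)) a else list(a)
  samples <- do.call(rbind, lapply(parts, boundarySamples))
  hull <- samples[grDevices::chull(samples), , drop = FALSE]
  if (nrow(hull) < 3) return(FALSE)
  hullPoly <- polygonGeom(hull)
  bpts <- boundarySamples(b)
  insideHull <- all(classifyPoints(hullPoly, bpts, config$eps) != 0L)
  if (!insideHull) return(FALSE)
  noOverlap <- all(vapply(parts, function(p) {
    !intersectionState(p, b, config)@ii
  }, logical(1)))
  noOverlap
}

# dense sample of a geometry's boundary (for hulls)
boundarySamples <- function(g, n = 90) {
  if (is(g, "CircleGeom")) {
    th <- 2 * pi * (seq_len(n) - 1) / n
    cbind(g@center[1] + g@radius * cos(th), g@center[2] + g@radius * sin(th))
  } else {
    v <- g@vertices
    closed <- is(g, "PolygonGeom")
    idx <- if (closed) rbind(v, v[1, , drop = FALSE]) else v
    out <- NULL
    for (i in seq_len(nrow(idx) - 1)) {
      t <- seq(0, 1, length.out = 12)[-12]
      out <- rbind(out, cbind(idx[i, 1] + t * (idx[i + 1, 1] - idx[i, 1]),
                              idx[i, 2] + t * (idx[i + 1, 2] - idx[i, 2])))
    }
    rbind(out, idx[nrow(idx), , drop = FALSE])
  }
}

#' All spatial predicates holding on a geometry pair
#'
#' Evaluates the full predicate vocabulary once from a single intersection
#' state and returns the labels that hold, in fixed vocabulary order.
#' `spatialSurround` is included only when `a` is given as a composite
#' (a list of geometries).
#'
#' @inheritParams spatialPredicate
#' @return character vector of predicate labels.
#' @examples
#' classifyRelations(circleGeom(c(0, 0), 1), circleGeom(c(0, 0), 1))
#' @export
classifyRelations <- function(a, b, config = spatialConfig()) {
  base <- spatialPredicates("core")
  if (is.list(a)) {
    hit <- "spatialSurround"[spatialSurrounds(a, b, config)]
    return(hit)
  }
  st <- intersectionState(a, b, config)
  hits <- base[vapply(base, predicateFromState, logical(1), st = st,
                      strict = config$strict)]
  if (spatialSurrounds(a, b, config)) hits <- c(hits, "spatialSurround")
  hits
}
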