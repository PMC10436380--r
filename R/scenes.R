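#' @include geometry.R catalog.R
NULL

# canvas conventions: unit square, y downward; "periphery" means centroid
# more than 0.35 from the canvas center, "center" less than 0.15
.canvasCenter <- c(0.5, 0.5)
.peripheryMin <- 0.35
.centerMax <- 0.15

geomCentroid <- function(g) {
  if (is(g, "CircleGeom")) g@center else colMeans(g@vertices)
}

newScene <- function(ids, geometries, fills, strokes, seed, provenance) {
  new("Scene", ids = ids, geometries = geometries, fills = fills,
      strokes = strokes, seed = as.integer(seed), provenance = provenance)
}

setMethod("show", "Scene", function(object) {
  cat(sprintf("Scene \"%s\" (seed %d): %d geometries\n", object@provenance,
              object@seed, length(object@geometries)))
})

firstColor <- function(cl, default = "Black") {
  if (cl@role == "shape-requirement" && length(cl@color)) cl@color[1]
  else default
}

# terms whose clause sets map onto supported geometry forms
.realizableTerms <- c(
  "pseudopods", "starburst pattern", "rosettes", "pigment network",
  "negative network", "dots regular", "dots irregular", "globules regular",
  "globules irregular", "rim of brown globules", "cobblestones",
  "radial streaming", "branched streaks", "shiny white streaks",
  "ridge pattern", "milia-like cyst", "annular granular pattern")

#' Instantiate a pattern term as a geometric scene
#'
#' Generates a deterministic, seeded geometric realization of a registered
#' term inside the unit canvas, such that the term's clauses hold under the
#' spatial calculus: pseudopod scenes place peripheral circles tangent to
#' radial lines (so `spatialMeet` holds pairwise), rosette scenes place
#' four bright white circles whose centers form a square, network scenes
#' surround hypopigmented circles with a mesh of lines, and so on.
#' Identical (term, seed) pairs yield identical scenes. Terms whose
#' clauses do not map onto supported geometry (e.g. structureless areas)
#' raise a not-realizable error.
#'
#' @param catalog a [Catalog].
#' @param term registered term (or alternative label).
#' @param seed integer seed.
#' @param config a [spatialConfig()]; tangency ("meet") constructions
#'   place geometries at the configured boundary tolerance, since meeting
#'   is an `eps`-dependent notion.
#' @return a [Scene].
#' @examples
#' sc <- renderScene(dermoscopyCatalog(), "Rosettes", seed = 1)
#' length(sc@geometries)
#' @export
renderScene <- function(catalog, term, seed = 1,
                        config = spatialConfig(0.005, 0.01)) {
  d <- resolveTerm(catalog, term)
  key <- foldTerm(d@term)
  if (!key %in% .realizableTerms)
    dvStop(sprintf(
      "term '%s' has no geometric realization (unrealizable clauses)",
      d@term), "notRealizableError")
  clauses <- decomposeTerm(catalog, d@term)
  shapeCl <- Filter(function(cl) cl@role == "shape-requirement", clauses)
  withSeed(seed, switch(key,
    "pseudopods" = ,
    "starburst pattern" = sceneRadialTangent(d@term, seed, shapeCl,
                                             gap = config$eps),
    "radial streaming" = ,
    "branched streaks" = sceneRadialLines(d@term, seed, shapeCl,
                                          branched = key == "branched streaks"),
    "rosettes" = sceneSquareCircles(d@term, seed, shapeCl),
    "pigment network" = ,
    "negative network" = sceneNetwork(d@term, seed, shapeCl),
    "dots regular" = ,
    "globules regular" = ,
    "milia-like cyst" = sceneScatter(d@term, seed, shapeCl,
                                     jitter = 0.0),
    "dots irregular" = ,
    "globules irregular" = ,
    "annular granular pattern" = sceneScatter(d@term, seed, shapeCl,
                                              jitter = 0.02),
    "rim of brown globules" = scenePeripheralRing(d@term, seed, shapeCl),
    "cobblestones" = sceneCobblestones(d@term, seed, shapeCl),
    "shiny white streaks" = ,
    "ridge pattern" = sceneParallelLines(d@term, seed, shapeCl,
                                         orthogonal = key ==
                                           "shiny white streaks")))
}

# peripheral circles meeting radial lines aimed at the canvas center; the
# circle stands off the line tip by the boundary tolerance, the offset at
# which the eps-band calculus reads a clean boundary-only contact
sceneRadialTangent <- function(term, seed, shapeCl, gap = 0.01) {
  k <- 5L
  rot <- stats::runif(1, 0, 2 * pi)
  rc <- 0.045
  circleColor <- "Brown"; lineColor <- "Brown"
  for (cl in shapeCl) {
    if (identical(cl@shapeKind, "Circle")) circleColor <- firstColor(cl, circleColor)
    if (identical(cl@shapeKind, "Line")) lineColor <- firstColor(cl, lineColor)
  }
  ids <- character(0); geoms <- list(); fills <- character(0)
  for (j in seq_len(k)) {
    th <- rot + 2 * pi * (j - 1) / k
    u <- c(cos(th), sin(th))
    p1 <- .canvasCenter + 0.26 * u
    p2 <- .canvasCenter + 0.38 * u        # line tip facing the circle
    ctr <- .canvasCenter + (0.38 + gap + rc) * u
    geoms <- c(geoms, list(segmentGeom(p1, p2), circleGeom(ctr, rc)))
    ids <- c(ids, sprintf("line%d", j), sprintf("circle%d", j))
    fills <- c(fills, lineColor, circleColor)
  }
  newScene(ids, geoms, fills, rep("none", length(ids)), seed, term)
}

sceneRadialLines <- function(term, seed, shapeCl, branched = FALSE) {
  k <- 6L
  rot <- stats::runif(1, 0, 2 * pi)
  col <- if (length(shapeCl)) firstColor(shapeCl[[1]]) else "Pigmented"
  ids <- character(0); geoms <- list(); fills <- character(0)
  for (j in seq_len(k)) {
    th <- rot + 2 * pi * (j - 1) / k
    u <- c(cos(th), sin(th))
    p1 <- .canvasCenter + 0.25 * u
    p2 <- .canvasCenter + 0.42 * u
    if (branched) {
      mid <- .canvasCenter + 0.34 * u
      v <- c(-u[2], u[1])
      geoms <- c(geoms, list(polylineGeom(rbind(p1, mid, p2)),
                             segmentGeom(mid, mid + 0.06 * v)))
      ids <- c(ids, sprintf("line%d", j), sprintf("branch%d", j))
      fills <- c(fills, col, col)
    } else {
      geoms <- c(geoms, list(segmentGeom(p1, p2)))
      ids <- c(ids, sprintf("line%d", j))
      fills <- c(fills, col)
    }
  }
  newScene(ids, geoms, fills, rep("none", length(ids)), seed, term)
}

# four circles whose centers form a square (square formation, no actual
# square shape present)
sceneSquareCircles <- function(term, seed, shapeCl) {
  rot <- stats::runif(1, 0, pi / 2)
  a <- 0.12; rc <- 0.05
  col <- if (length(shapeCl)) firstColor(shapeCl[[1]]) else "Bright White"
  th <- rot + pi / 4 + pi / 2 * (0:3)
  ctrs <- cbind(.canvasCenter[1] + a * sqrt(2) * cos(th),
                .canvasCenter[2] + a * sqrt(2) * sin(th))
  geoms <- lapply(seq_len(4), function(i) circleGeom(ctrs[i, ], rc))
  newScene(sprintf("circle%d", 1:4), geoms, rep(col, 4), rep("none", 4),
           seed, term)
}

# mesh of interconnecting lines surrounding circles in the mesh holes
sceneNetwork <- function(term, seed, shapeCl) {
  lineColor <- "Pigmented"; circleColor <- "Hypopigmented"
  for (cl in shapeCl) {
    if (identical(cl@shapeKind, "Line")) lineColor <- firstColor(cl, lineColor)
    if (identical(cl@shapeKind, "Circle")) circleColor <- firstColor(cl, circleColor)
  }
  at <- c(0.25, 0.5, 0.75)
  geoms <- list(); ids <- character(0); fills <- character(0)
  for (i in seq_along(at)) {
    geoms <- c(geoms, list(segmentGeom(c(0.1, at[i]), c(0.9, at[i])),
                           segmentGeom(c(at[i], 0.1), c(at[i], 0.9))))
    ids <- c(ids, sprintf("hline%d", i), sprintf("vline%d", i))
    fills <- c(fills, lineColor, lineColor)
  }
  holes <- rbind(c(0.375, 0.375), c(0.625, 0.375), c(0.375, 0.625),
                 c(0.625, 0.625))
  for (i in seq_len(nrow(holes))) {
    geoms <- c(geoms, list(circleGeom(holes[i, ], 0.08)))
    ids <- c(ids, sprintf("circle%d", i))
    fills <- c(fills, circleColor)
  }
  newScene(ids, geoms, fills, rep("none", length(ids)), seed, term)
}

# distributed (optionally jittered) small circles, pairwise disjoint
sceneScatter <- function(term, seed, shapeCl, jitter = 0) {
  col <- if (length(shapeCl)) firstColor(shapeCl[[1]]) else "Pigmented"
  sz <- if (length(shapeCl) && !is.na(shapeCl[[1]]@size))
    shapeCl[[1]]@size else NA
  base <- if (identical(sz, "Small")) 0.025 else 0.05
  centers <- as.matrix(expand.grid(x = c(0.25, 0.5, 0.75),
                                   y = c(0.25, 0.5, 0.75)))
  radii <- rep(base, nrow(centers))
  if (jitter > 0) {
    centers <- centers + matrix(stats::runif(length(centers), -jitter,
                                             jitter), ncol = 2)
    radii <- radii * stats::runif(nrow(centers), 0.7, 1.6)
  }
  geoms <- lapply(seq_len(nrow(centers)),
                  function(i) circleGeom(centers[i, ], radii[i]))
  newScene(sprintf("circle%d", seq_along(geoms)), geoms,
           rep(col, length(geoms)), rep("none", length(geoms)), seed, term)
}

scenePeripheralRing <- function(term, seed, shapeCl) {
  col <- if (length(shapeCl)) firstColor(shapeCl[[1]]) else "Brown"
  k <- 8L
  rot <- stats::runif(1, 0, 2 * pi)
  th <- rot + 2 * pi * (seq_len(k) - 1) / k
  geoms <- lapply(th, function(t) {
    circleGeom(.canvasCenter + 0.4 * c(cos(t), sin(t)), 0.04)
  })
  newScene(sprintf("circle%d", seq_len(k)), geoms, rep(col, k),
           rep("none", k), seed, term)
}

sceneCobblestones <- function(term, seed, shapeCl) {
  col <- if (length(shapeCl)) firstColor(shapeCl[[1]]) else "Pigmented"
  rot <- stats::runif(1, 0, pi / 3)
  centers <- rbind(c(0.35, 0.40), c(0.62, 0.40), c(0.48, 0.62))
  geoms <- lapply(seq_len(nrow(centers)), function(i) {
    regularPolygonGeom(centers[i, ], 0.11, 6L, rotate = rot)
  })
  newScene(sprintf("polygon%d", seq_along(geoms)), geoms,
           rep(col, length(geoms)), rep("none", length(geoms)), seed, term)
}

sceneParallelLines <- function(term, seed, shapeCl, orthogonal = FALSE) {
  col <- if (length(shapeCl)) firstColor(shapeCl[[1]]) else "Pigmented"
  rot <- stats::runif(1, 0, pi)
  u <- c(cos(rot), sin(rot)); v <- c(-u[2], u[1])
  geoms <- list(); ids <- character(0)
  offs <- seq(-0.15, 0.15, length.out = 4)
  for (i in seq_along(offs)) {
    m <- .canvasCenter + offs[i] * v
    geoms <- c(geoms, list(segmentGeom(m - 0.2 * u, m + 0.2 * u)))
    ids <- c(ids, sprintf("line%d", i))
  }
  if (orthogonal) {
    for (i in seq_len(2)) {
      m <- .canvasCenter + (0.28 + 0.06 * i) * v
      geoms <- c(geoms, list(segmentGeom(m - 0.08 * v, m + 0.08 * v)))
      ids <- c(ids, sprintf("cross%d", i))
    }
  }
  newScene(ids, geoms, rep(col, length(ids)), rep("none", length(ids)),
           seed, term)
}

#' Sample a geometry pair realizing one spatial relation
#'
#' Constructs a seeded pair of geometries for which the requested predicate
#' (and only it, apart from relations it implies under the truth table)
#' holds. `spatialSurround` returns a composite first element (a ring of
#' circles around the surrounded geometry).
#'
#' @param relation predicate label from [spatialPredicates()].
#' @param seed integer seed.
#' @return list with elements `a` (a [Geometry], or list of geometries for
#'   surround) and `b` (a [Geometry]).
#' @examples
#' pr <- sampleRelationPair("spatialMeet", seed = 3)
#' spatialPredicate("spatialMeet", pr$a, pr$b)
#' @export
sampleRelationPair <- function(relation, seed = 1) {
  if (!relation %in% spatialPredicates())
    dvStop(sprintf("unsupported relation '%s'; vocabulary: %s", relation,
                   paste(spatialPredicates(), collapse = ", ")),
           "vocabularyError")
  withSeed(seed, {
    c0 <- c(stats::runif(1, 0.4, 0.6), stats::runif(1, 0.4, 0.6))
    r1 <- stats::runif(1, 0.10, 0.16)
    switch(relation,
      spatialDisjoint = list(a = circleGeom(c0 - c(0.22, 0), r1 * 0.8),
                             b = circleGeom(c0 + c(0.22, 0), r1 * 0.8)),
      spatialMeet = {
        r2 <- stats::runif(1, 0.08, 0.12)
        list(a = circleGeom(c0 - c(r1, 0), r1),
             b = circleGeom(c0 + c(r2, 0), r2))   # external tangency
      },
      spatialEqual = list(a = circleGeom(c0, r1), b = circleGeom(c0, r1)),
      spatialInside = list(a = circleGeom(c0 + c(0.02, 0), r1 * 0.4),
                           b = circleGeom(c0, r1 * 2)),
      spatialContains = list(a = circleGeom(c0, r1 * 2),
                             b = circleGeom(c0 + c(0.02, 0), r1 * 0.4)),
      spatialCoveredBy = {
        R <- r1 * 2
        list(a = circleGeom(c0 + c(R - r1, 0), r1),  # internal tangency
             b = circleGeom(c0, R))
      },
      spatialCovers = {
        R <- r1 * 2
        list(a = circleGeom(c0, R),
             b = circleGeom(c0 + c(R - r1, 0), r1))
      },
      spatialOverlap = list(a = circleGeom(c0 - c(r1 / 2, 0), r1),
                            b = circleGeom(c0 + c(r1 / 2, 0), r1)),
      spatialSurround = {
        k <- 8L
        th <- stats::runif(1, 0, 2 * pi) + 2 * pi * (seq_len(k) - 1) / k
        ring <- lapply(th, function(t) {
          circleGeom(c0 + 0.3 * c(cos(t), sin(t)), 0.07)
        })
        list(a = ring, b = circleGeom(c0, 0.08))
      })
  })
}

## ---- SVG and JSON round trips ----

fmtNum <- function(x) formatC(x, format = "f", digits = 6)

svgFill <- function(name, palette) {
  col <- palette[[name]]
  if (!is.null(col) && !col@symbolic) col@hex
  else switch(name, none = "none", Pigmented = "#5D4037",
              Hypopigmented = "#E8D8C9", Dark = "#1B1B1B",
              "Non-pigmented" = "#F5F0EB", "#888888")
}

#' Serialize a scene as an SVG 1.1 document
#'
#' Uses the circle/line/polyline/polygon/rect subset; coordinates are
#' written with fixed precision so identical scenes give byte-identical
#' documents. Symbolic colors are rendered with fixed stand-in hex values.
#'
#' @param scene a [Scene].
#' @param path optional output file.
#' @param palette color palette for fill lookup.
#' @return the SVG text, invisibly when written to `path`.
#' @export
sceneToSVG <- function(scene, path = NULL, palette = loadPalette()) {
  body <- vapply(seq_along(scene@geometries), function(i) {
    g <- scene@geometries[[i]]
    fill <- svgFill(scene@fills[i], palette)
    id <- scene@ids[i]
    if (is(g, "CircleGeom")) {
      sprintf('  <circle id="%s" cx="%s" cy="%s" r="%s" fill="%s"/>',
              id, fmtNum(g@center[1]), fmtNum(g@center[2]),
              fmtNum(g@radius), fill)
    } else if (is(g, "SegmentGeom")) {
      v <- g@vertices
      sprintf(paste0('  <line id="%s" x1="%s" y1="%s" x2="%s" y2="%s" ',
                     'stroke="%s" stroke-width="0.004"/>'),
              id, fmtNum(v[1, 1]), fmtNum(v[1, 2]), fmtNum(v[2, 1]),
              fmtNum(v[2, 2]), fill)
    } else if (is(g, "PolygonGeom")) {
      pts <- paste(apply(g@vertices, 1, function(p)
        paste0(fmtNum(p[1]), ",", fmtNum(p[2]))), collapse = " ")
      sprintf('  <polygon id="%s" points="%s" fill="%s"/>', id, pts, fill)
    } else {
      pts <- paste(apply(g@vertices, 1, function(p)
        paste0(fmtNum(p[1]), ",", fmtNum(p[2]))), collapse = " ")
      sprintf(paste0('  <polyline id="%s" points="%s" fill="none" ',
                     'stroke="%s" stroke-width="0.004"/>'), id, pts, fill)
    }
  }, character(1))
  svg <- paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<svg xmlns="http://www.w3.org/2000/svg" viewBox="0 0 1 1" ',
           sprintf('data-provenance="%s" data-seed="%d">',
                   scene@provenance, scene@seed)),
    body, "</svg>", ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(svg, path, sep = "")
    return(invisible(svg))
  }
  svg
}

#' Import a scene from an SVG document
#'
#' Reads the circle/rect/polygon/polyline/line element subset back into
#' geometries; other elements are rejected.
#'
#' @param path SVG file or literal SVG text.
#' @return a [Scene].
#' @export
readSceneSVG <- function(path) {
  doc <- xml2::read_xml(path)
  kids <- xml2::xml_children(doc)
  ids <- character(0); geoms <- list(); fills <- character(0)
  strokes <- character(0)
  att <- function(node, a) as.numeric(xml2::xml_attr(node, a))
  parsePts <- function(node) {
    raw <- strsplit(trimws(xml2::xml_attr(node, "points")), "\\s+")[[1]]
    do.call(rbind, lapply(strsplit(raw, ","), as.numeric))
  }
  for (node in kids) {
    nm <- xml2::xml_name(node)
    g <- switch(nm,
      circle = circleGeom(c(att(node, "cx"), att(node, "cy")),
                          att(node, "r")),
      line = segmentGeom(c(att(node, "x1"), att(node, "y1")),
                         c(att(node, "x2"), att(node, "y2"))),
      rect = {
        x <- att(node, "x"); y <- att(node, "y")
        w <- att(node, "width"); h <- att(node, "height")
        polygonGeom(rbind(c(x, y), c(x + w, y), c(x + w, y + h),
                          c(x, y + h)))
      },
      polygon = polygonGeom(parsePts(node)),
      polyline = polylineGeom(parsePts(node)),
      dvStop(sprintf("unsupported SVG element '%s'", nm), "svgError"))
    ids <- c(ids, xml2::xml_attr(node, "id"))
    fills <- c(fills, xml2::xml_attr(node, "fill"))
    strokes <- c(strokes, xml2::xml_attr(node, "stroke"))
    geoms <- c(geoms, list(g))
  }
  ids[is.na(ids)] <- sprintf("g%d", which(is.na(ids)))
  fills[is.na(fills)] <- "none"; strokes[is.na(strokes)] <- "none"
  prov <- xml2::xml_attr(doc, "data-provenance")
  seed <- suppressWarnings(as.integer(xml2::xml_attr(doc, "data-seed")))
  newScene(ids, geoms, fills, strokes,
           if (is.na(seed)) 0L else seed,
           if (is.na(prov)) "adhoc" else prov)
}

#' Scene JSON round trip
#'
#' Scenes serialize to a JSON list of geometry records
#' (`id`, `type`, parameters, `fill`, `stroke`).
#'
#' @param scene a [Scene].
#' @param path output (input) file.
#' @return `writeSceneJSON` returns `path` invisibly; `readSceneJSON`
#'   returns a [Scene].
#' @export
writeSceneJSON <- function(scene, path) {
  recs <- lapply(seq_along(scene@geometries), function(i) {
    g <- scene@geometries[[i]]
    base <- list(id = scene@ids[i], fill = scene@fills[i],
                 stroke = scene@strokes[i])
    if (is(g, "CircleGeom")) {
      c(base, list(type = "circle", center = g@center, radius = g@radius))
    } else {
      type <- if (is(g, "SegmentGeom")) "segment"
              else if (is(g, "PolygonGeom")) "polygon" else "polyline"
      c(base, list(type = type, vertices = g@vertices))
    }
  })
  jsonlite::write_json(list(provenance = scene@provenance,
                            seed = scene@seed, geometries = recs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSceneJSON
#' @export
readSceneJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  geoms <- list(); ids <- character(0); fills <- character(0)
  strokes <- character(0)
  for (r in doc$geometries) {
    g <- switch(r$type,
      circle = circleGeom(unlist(r$center), r$radius),
      segment = segmentGeom(unlist(r$vertices[[1]]),
                            unlist(r$vertices[[2]])),
      polygon = polygonGeom(do.call(rbind, lapply(r$vertices, unlist))),
      polyline = polylineGeom(do.call(rbind, lapply(r$vertices, unlist))),
      dvStop(sprintf("unknown geometry type '%s'", r$type), "schemaError"))
    geoms <- c(geoms, list(g))
    ids <- c(ids, r$id); fills <- c(fills, r$fill)
    strokes <- c(strokes, r$stroke)
  }
  newScene(ids, geoms, fills, strokes, doc$seed %||% 0L,
           doc$provenance %||% "adhoc")
}
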