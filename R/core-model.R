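#' @include AllClasses.R
NULL

# registry backing the inverse navigation from a component color to the
# multi-colors it takes part in (Color > isComposedOfColors > MultiColor)
.multiColorRegistry <- new.env(parent = emptyenv())

#' Create a validated color
#'
#' A color carries a label plus two redundant encodings, an RGB triple and
#' a "#RRGGBB" hex string, which must agree.
#'
#' @param name color label.
#' @param rgb integer triple, each component in \[0, 255\].
#' @param hex 7-character "#RRGGBB" string.
#' @return a [Color] object.
#' @examples
#' makeColor("Black", c(0, 0, 0), "#000000")
#' @export
makeColor <- function(name, rgb, hex) {
  new("Color", name = name, rgb = as.integer(rgb), hex = toupper(hex))
}

#' Create a symbolic color (no fixed RGB value)
#'
#' Pigmentation classes (Non-pigmented, Hypopigmented, Pigmented, Dark) and
#' the Uniform/Variable qualifiers depend on the individual's skin color or
#' qualify a collection, so they carry no RGB encoding.
#'
#' @param name label.
#' @param qualifier `TRUE` for collection-level qualifiers.
#' @return a [Color] with `symbolic = TRUE`.
#' @export
symbolicColor <- function(name, qualifier = FALSE) {
  new("Color", name = name, rgb = integer(0), hex = NA_character_,
      symbolic = TRUE, qualifier = qualifier)
}

#' Create a multi-color from component colors
#'
#' Components form a set (duplicates are collapsed) and at least two
#' distinct colors must remain; a singleton is just a color. The inverse
#' navigation from each component back to the mix is registered and
#' readable via [composedOf()].
#'
#' @param components list of [Color] objects.
#' @param name optional label; defaults to the joined component names.
#' @return a [MultiColor].
#' @examples
#' pal <- list(makeColor("Blue", c(0, 0, 255), "#0000FF"),
#'             makeColor("Gray", c(128, 128, 128), "#808080"))
#' bg <- makeMultiColor(pal)
#' @export
makeMultiColor <- function(components, name = NULL) {
  if (!is.list(components)) components <- as.list(components)
  nm <- vapply(components, function(c) c@name, character(1))
  components <- components[!duplicated(nm)]
  if (length(components) < 2)
    dvStop("a multi-color needs at least 2 distinct components",
           "multiColorError")
  if (is.null(name))
    name <- paste(vapply(components, function(c) c@name, character(1)),
                  collapse = " ")
  mc <- new("MultiColor", name = name, components = components)
  for (c in mc@components) {
    prev <- .multiColorRegistry[[c@name]]
    have <- vapply(prev, function(m) m@name, character(1))
    if (!mc@name %in% have)
      .multiColorRegistry[[c@name]] <- c(prev, list(mc))
  }
  mc
}

#' Inverse navigation from a color to its multi-colors
#'
#' @param color a [Color].
#' @return list of [MultiColor] objects registered as containing `color`.
#' @export
composedOf <- function(color) {
  stopifnot(is(color, "Color"))
  out <- .multiColorRegistry[[color@name]]
  if (is.null(out)) list() else out
}

#' Create a stroke
#' @param width relative thickness (positive integer) or `NA`.
#' @param qualitativeWidth one of [qualitativeWidths()]; Uniform/Variable
#'   are dermoscopy-layer values and are rejected in core mode.
#' @param strokeColor optional [Color] or [MultiColor].
#' @param mode vocabulary mode.
#' @return a [Stroke].
#' @export
makeStroke <- function(width = NA, qualitativeWidth = NA,
                       strokeColor = NULL, mode = "dermoscopy") {
  mode <- checkMode(mode)
  if (!is.na(qualitativeWidth) &&
      !qualitativeWidth %in% qualitativeWidths(mode))
    dvStop(sprintf("qualitative width '%s' is not in the %s vocabulary",
                   qualitativeWidth, mode), "vocabularyError")
  new("Stroke", width = as.integer(width),
      qualitativeWidth = as.character(qualitativeWidth),
      strokeColor = strokeColor)
}

#' Create a texture
#' @param value Smooth/Rough, plus Shiny in dermoscopy mode.
#' @param mode vocabulary mode.
#' @export
makeTexture <- function(value, mode = "dermoscopy") {
  mode <- checkMode(mode)
  if (!value %in% textureValues(mode))
    dvStop(sprintf("texture '%s' is not in the %s vocabulary", value, mode),
           "vocabularyError")
  new("Texture", value = value)
}

#' Create a size
#' @param value one of [sizeValues()].
#' @export
makeSize <- function(value) new("Size", value = value)

#' Create a structural point
#' @param role Beginning/Middle/Ending/Unspecified.
#' @param coordinates optional 2-D pair.
#' @export
makePoint <- function(role = "Unspecified", coordinates = NULL) {
  new("VisualPoint", role = role, coordinates = coordinates)
}

#' Exact point cardinality of a named polygon subkind
#'
#' Named polygons carry an exact vertex-count restriction: a triangle has
#' exactly 3 points, a decagon exactly 10 (the restriction is "exactly",
#' not "at most").
#'
#' @param polygonKind one of [polygonKinds()] (case-insensitive).
#' @return the required point count.
#' @examples
#' pointCardinality("Triangle")  # 3
#' pointCardinality("Decagon")   # 10
#' @export
pointCardinality <- function(polygonKind) {
  key <- polygonKinds()[match(foldTerm(polygonKind),
                              foldTerm(polygonKinds()))]
  if (is.na(key))
    dvStop(sprintf(
      "'%s' is not a named polygon subkind (supported: %s)",
      polygonKind, paste(polygonKinds(), collapse = ", ")),
      "unsupportedKindError")
  .polygonCardinality[[key]]
}

#' Create a validated shape
#'
#' All slots of the shape model can be populated or explicitly absent:
#' fill color, stroke, texture, size, and structural points. Line-only
#' attributes are rejected for non-lines, an unspecified line style
#' defaults to Straight, and named polygon subkinds enforce their exact
#' point cardinality. Descriptive-terminology aliases ("dot", "clod",
#' "globule", "ellipse") are resolved to circle-based shapes via
#' [shapeAlias()].
#'
#' @param shapeKind one of [shapeKinds()], a named polygon subkind, or a
#'   shape alias.
#' @param lineStyle optional line style (lines only).
#' @param fill,stroke,texture,size optional attribute objects.
#' @param points list of [VisualPoint].
#' @param polygonSides optional side count for generic polygons.
#' @param mode vocabulary mode.
#' @return a [Shape].
#' @examples
#' dot <- makeShape("dot", fill = makeColor("Brown", c(150, 75, 0), "#964B00"))
#' dot@size@value  # "Small"
#' @export
makeShape <- function(shapeKind, lineStyle = NA, fill = NULL, stroke = NULL,
                      texture = NULL, size = NULL, points = list(),
                      polygonSides = NA, mode = "dermoscopy") {
  mode <- checkMode(mode)
  polygonKind <- NA_character_
  alias <- shapeAlias(shapeKind)
  if (!is.null(alias)) {
    if (is.null(size) && !is.na(alias$size)) size <- makeSize(alias$size)
    shapeKind <- alias$shapeKind
  }
  pk <- polygonKinds()[match(foldTerm(shapeKind), foldTerm(polygonKinds()))]
  if (!is.na(pk)) {
    polygonKind <- pk
    shapeKind <- "Polygon"
    need <- .polygonCardinality[[pk]]
    if (length(points) && length(points) != need)
      dvStop(sprintf("a %s has exactly %d points, got %d",
                     tolower(pk), need, length(points)),
             "cardinalityError")
    if (is.na(polygonSides)) polygonSides <- need
  }
  if (!shapeKind %in% shapeKinds())
    dvStop(sprintf("unknown shape kind '%s'", shapeKind), "vocabularyError")
  if (!is.na(lineStyle)) {
    if (shapeKind != "Line")
      dvStop("lineStyle applies to lines only", "vocabularyError")
    if (!lineStyle %in% lineStyles(mode))
      dvStop(sprintf("line style '%s' is not in the %s vocabulary",
                     lineStyle, mode), "vocabularyError")
  }
  if (shapeKind == "Line" && is.na(lineStyle)) lineStyle <- "Straight"
  if (!is.null(texture) && !texture@value %in% textureValues(mode))
    dvStop(sprintf("texture '%s' is not in the %s vocabulary",
                   texture@value, mode), "vocabularyError")
  if (!is.null(stroke) && !is.na(stroke@qualitativeWidth) &&
      !stroke@qualitativeWidth %in% qualitativeWidths(mode))
    dvStop(sprintf("qualitative width '%s' is not in the %s vocabulary",
                   stroke@qualitativeWidth, mode), "vocabularyError")
  new("Shape", shapeKind = shapeKind, polygonKind = polygonKind,
      lineStyle = as.character(lineStyle), fill = fill, stroke = stroke,
      texture = texture, size = size, points = points,
      polygonSides = as.integer(polygonSides))
}

# depth-first cycle search over the subpattern graph; returns the cycle
# path or NULL. Containment is by pattern name.
patternCycle <- function(pattern, stack = character(0)) {
  if (pattern@name %in% stack)
    return(c(stack[match(pattern@name, stack):length(stack)], pattern@name))
  for (sp in pattern@subpatterns) {
    cyc <- patternCycle(sp, c(stack, pattern@name))
    if (!is.null(cyc)) return(cyc)
  }
  NULL
}

#' Create a validated pattern
#'
#' A pattern is a composite of shapes and/or sub-patterns (several
#' sub-patterns are permitted; pattern containment is not functional), with
#' an optional overall spatial pattern and pairwise relationship
#' assertions. The composite must be non-empty, relation predicates must be
#' drawn from the registered vocabulary, and the sub-pattern graph must be
#' acyclic.
#'
#' @param name pattern label.
#' @param shapes list of [Shape].
#' @param subpatterns list of [Pattern].
#' @param spatialPattern optional [SpatialPattern] or its value label.
#' @param relations data.frame with subject/predicate/object columns.
#' @param mode vocabulary mode.
#' @return a [Pattern].
#' @export
makePattern <- function(name, shapes = list(), subpatterns = list(),
                        spatialPattern = NULL,
                        relations = NULL, mode = "dermoscopy") {
  mode <- checkMode(mode)
  if (length(shapes) + length(subpatterns) == 0)
    dvStop(sprintf("pattern '%s' is an empty composite", name),
           "compositeError")
  if (is.character(spatialPattern))
    spatialPattern <- new("SpatialPattern", value = spatialPattern)
  if (!is.null(spatialPattern) &&
      !spatialPattern@value %in% spatialPatternValues(mode))
    dvStop(sprintf("spatial pattern '%s' is not in the %s vocabulary",
                   spatialPattern@value, mode), "vocabularyError")
  if (is.null(relations))
    relations <- data.frame(subject = character(0), predicate = character(0),
                            object = character(0))
  vocabulary <- c(spatialPredicates(mode), relationshipValues())
  bad <- setdiff(relations$predicate, vocabulary)
  if (length(bad))
    dvStop(sprintf("unknown relation predicate(s): %s",
                   paste(bad, collapse = ", ")), "vocabularyError")
  p <- new("Pattern", name = name, shapes = shapes,
           subpatterns = subpatterns, spatialPattern = spatialPattern,
           relations = relations)
  cyc <- patternCycle(p)
  if (!is.null(cyc))
    dvStop(sprintf("pattern cycle: %s", paste(cyc, collapse = " -> ")),
           "cycleError")
  p
}

#' Create a visualization
#' @param elements list of [VisualElement] objects (non-empty).
#' @return a [Visualization].
#' @export
makeVisualization <- function(elements) {
  if (is(elements, "VisualElement")) elements <- list(elements)
  new("Visualization", elements = elements)
}

#' Kind of a visual element
#' @param x a [VisualElement].
#' @return the element-kind label (one of [elementKinds()]).
#' @export
setGeneric("elementKind", function(x) standardGeneric("elementKind"))

#' @rdname elementKind
setMethod("elementKind", "Shape", function(x)
  if (x@shapeKind == "Path") "Path" else "Shape")
#' @rdname elementKind
setMethod("elementKind", "Color", function(x) "Color")
#' @rdname elementKind
setMethod("elementKind", "MultiColor", function(x) "Color")
#' @rdname elementKind
setMethod("elementKind", "Texture", function(x) "Texture")
#' @rdname elementKind
setMethod("elementKind", "Stroke", function(x) "Stroke")
#' @rdname elementKind
setMethod("elementKind", "Size", function(x) "Size")
#' @rdname elementKind
setMethod("elementKind", "VisualPoint", function(x) "Point")
#' @rdname elementKind
setMethod("elementKind", "SpatialPattern", function(x) "SpatialPattern")
#' @rdname elementKind
setMethod("elementKind", "Pattern", function(x) "Pattern")

#' Enumerate the elements of a visualization
#'
#' Deterministic, order-stable enumeration of all elements, recursing
#' through patterns: a pattern contributes itself, then its shapes, then
#' its sub-patterns (depth-first, insertion order).
#'
#' @param x a [Visualization] or [Pattern].
#' @return flat list of [VisualElement] objects.
#' @export
setGeneric("elementsOf", function(x) standardGeneric("elementsOf"))

#' @rdname elementsOf
setMethod("elementsOf", "Visualization", function(x) {
  out <- list()
  for (e in x@elements) {
    out <- c(out, if (is(e, "Pattern")) elementsOf(e) else list(e))
  }
  out
})

#' @rdname elementsOf
setMethod("elementsOf", "Pattern", function(x) {
  out <- list(x)
  out <- c(out, x@shapes)
  for (sp in x@subpatterns) out <- c(out, elementsOf(sp))
  out
})

setMethod("show", "Color", function(object) {
  cat(sprintf("Color \"%s\"%s\n", object@name,
              if (object@symbolic) " (symbolic)"
              else sprintf(" %s rgb(%s)", object@hex,
                           paste(object@rgb, collapse = ","))))
})

setMethod("show", "Shape", function(object) {
  kind <- if (!is.na(object@polygonKind)) object@polygonKind
          else object@shapeKind
  bits <- c(
    if (!is.null(object@fill)) paste0("fill=", object@fill@name),
    if (!is.null(object@size)) paste0("size=", object@size@value),
    if (!is.na(object@lineStyle)) paste0("style=", object@lineStyle),
    if (length(object@points)) sprintf("%d points", length(object@points)))
  cat(sprintf("Shape <%s>%s\n", kind,
              if (length(bits)) paste0(" [", paste(bits, collapse = ", "), "]")
              else ""))
})

setMethod("show", "Pattern", function(object) {
  cat(sprintf("Pattern \"%s\": %d shape(s), %d subpattern(s), %d relation(s)\n",
              object@name, length(object@shapes),
              length(object@subpatterns), nrow(object@relations)))
})

setMethod("show", "Visualization", function(object) {
  kinds <- vapply(object@elements, elementKind, character(1))
  cat(sprintf("Visualization of %d element(s): %s\n", length(object@elements),
              paste(kinds, collapse = ", ")))
})
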