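#' @import methods
NULL

setClassUnion("OptionalNumeric", c("numeric", "NULL"))

#' Virtual parent of all visual elements
#'
#' Every concrete element (shape, color, texture, ...) belongs to exactly
#' one kind; [elementKind()] reports it.
#'
#' @export
setClass("VisualElement", representation("VIRTUAL"))

#' A named color with RGB and hex encodings
#'
#' Symbolic colors (pigmentation classes such as Hypopigmented, and the
#' Uniform/Variable collection qualifiers) carry no RGB/hex value; for all
#' others the two encodings must agree.
#'
#' @slot name color label, unique within a palette.
#' @slot rgb integer triple in \[0, 255\], or empty for symbolic colors.
#' @slot hex 7-character "#RRGGBB" string, or `NA` for symbolic colors.
#' @slot symbolic flag for colors without a fixed RGB value.
#' @slot qualifier flag for collection-level qualifiers (Uniform/Variable),
#'   which the source vocabulary lists under Color but which qualify a
#'   collection of elements rather than name a hue.
#' @export
setClass("Color", contains = "VisualElement",
  representation(name = "character", rgb = "integer", hex = "character",
                 symbolic = "logical", qualifier = "logical"),
  prototype(symbolic = FALSE, qualifier = FALSE))

setValidity("Color", function(object) {
  if (length(object@name) != 1 || !nzchar(object@name))
    return("color must have a non-empty name")
  if (object@symbolic) {
    if (length(object@rgb)) return("symbolic colors carry no rgb triple")
    return(TRUE)
  }
  if (length(object@rgb) != 3 || anyNA(object@rgb))
    return("rgb must be an integer triple")
  if (any(object@rgb < 0L | object@rgb > 255L))
    return("rgb components must lie in [0, 255]")
  if (length(object@hex) != 1 || !grepl("^#[0-9A-Fa-f]{6}$", object@hex))
    return("hex must match \"#RRGGBB\"")
  hexRGB <- strtoi(substring(object@hex, c(2, 4, 6), c(3, 5, 7)), 16L)
  if (!all(hexRGB == object@rgb))
    return(sprintf(
      "hex %s encodes rgb (%s) but rgb slot is (%s)", object@hex,
      paste(hexRGB, collapse = ","), paste(object@rgb, collapse = ",")))
  TRUE
})

#' A mix of two or more colors
#'
#' @slot name optional label for the mix.
#' @slot components list of at least two distinct [Color] objects; each
#'   component can navigate back to the mixes it takes part in via
#'   [composedOf()].
#' @export
setClass("MultiColor", contains = "VisualElement",
  representation(name = "character", components = "list"))

setValidity("MultiColor", function(object) {
  if (length(object@components) < 2)
    return("a multi-color needs at least 2 distinct component colors")
  if (!all(vapply(object@components, is, logical(1), "Color")))
    return("all components must be Color objects")
  nm <- vapply(object@components, function(c) c@name, character(1))
  if (anyDuplicated(nm)) return("component colors must be distinct (a set)")
  TRUE
})

setClassUnion("ColorSpec", c("Color", "MultiColor", "NULL"))

#' Outline (stroke) of a shape
#' @slot width relative thickness, positive integer or `NA`.
#' @slot qualitativeWidth Thin/Medium/Thick, plus Uniform/Variable in the
#'   dermoscopy layer; `NA` when unspecified.
#' @slot strokeColor optional [Color] or [MultiColor].
#' @export
setClass("Stroke", contains = "VisualElement",
  representation(width = "integer", qualitativeWidth = "character",
                 strokeColor = "ColorSpec"),
  prototype(width = NA_integer_, qualitativeWidth = NA_character_,
            strokeColor = NULL))

setValidity("Stroke", function(object) {
  if (!is.na(object@width) && object@width < 1L)
    return("stroke width must be >= 1 when present")
  if (!is.na(object@qualitativeWidth) &&
      !object@qualitativeWidth %in% qualitativeWidths("dermoscopy"))
    return(sprintf("unknown qualitative width '%s'", object@qualitativeWidth))
  TRUE
})

#' Perceived visual texture
#' @slot value Smooth or Rough; Shiny in the dermoscopy layer.
#' @export
setClass("Texture", contains = "VisualElement",
  representation(value = "character"))
setValidity("Texture", function(object) {
  if (!object@value %in% textureValues("dermoscopy"))
    return(sprintf("unknown texture '%s'", object@value))
  TRUE
})

#' Relative size of a visual element
#' @slot value Small, Large, Long, Uniform or Variable. Long applies only
#'   to shapes with an elongation axis (a long circle is an ellipse);
#'   Uniform/Variable qualify a collection.
#' @export
setClass("Size", contains = "VisualElement",
  representation(value = "character"))
setValidity("Size", function(object) {
  if (!object@value %in% sizeValues())
    return(sprintf("unknown size '%s'", object@value))
  TRUE
})

#' A structural point of a shape
#' @slot role Beginning, Middle, Ending or Unspecified.
#' @slot coordinates optional dimensionless 2-D position, x rightward and
#'   y downward (SVG convention).
#' @export
setClass("VisualPoint", contains = "VisualElement",
  representation(role = "character", coordinates = "OptionalNumeric"),
  prototype(role = "Unspecified", coordinates = NULL))
setValidity("VisualPoint", function(object) {
  if (!object@role %in% pointRoles())
    return(sprintf("unknown point role '%s'", object@role))
  if (!is.null(object@coordinates) && length(object@coordinates) != 2)
    return("coordinates must be a 2-D pair")
  TRUE
})

setClassUnion("OptionalStroke", c("Stroke", "NULL"))
setClassUnion("OptionalTexture", c("Texture", "NULL"))
setClassUnion("OptionalSize", c("Size", "NULL"))

#' A visual shape primitive
#'
#' @slot shapeKind one of [shapeKinds()].
#' @slot polygonKind optional named polygon subkind (Triangle ... Decagon);
#'   a named subkind has exactly its defining number of points.
#' @slot lineStyle line style (lines only); unspecified lines are straight.
#' @slot fill fill color ([Color], [MultiColor], or `NULL`).
#' @slot stroke optional [Stroke].
#' @slot texture optional [Texture].
#' @slot size optional [Size].
#' @slot points list of [VisualPoint].
#' @slot polygonSides optional side count for generic polygons.
#' @export
setClass("Shape", contains = "VisualElement",
  representation(shapeKind = "character", polygonKind = "character",
                 lineStyle = "character", fill = "ColorSpec",
                 stroke = "OptionalStroke", texture = "OptionalTexture",
                 size = "OptionalSize", points = "list",
                 polygonSides = "integer"),
  prototype(polygonKind = NA_character_, lineStyle = NA_character_,
            fill = NULL, stroke = NULL, texture = NULL, size = NULL,
            points = list(), polygonSides = NA_integer_))

setValidity("Shape", function(object) {
  if (!object@shapeKind %in% shapeKinds())
    return(sprintf("unknown shape kind '%s'", object@shapeKind))
  if (!is.na(object@lineStyle) && object@shapeKind != "Line")
    return("lineStyle applies to lines only")
  if (!is.na(object@polygonKind)) {
    if (object@shapeKind != "Polygon")
      return("polygonKind applies to polygons only")
    need <- .polygonCardinality[[object@polygonKind]]
    if (is.null(need))
      return(sprintf("unknown polygon subkind '%s'", object@polygonKind))
    if (length(object@points) && length(object@points) != need)
      return(sprintf("a %s has exactly %d points, got %d",
                     tolower(object@polygonKind), need,
                     length(object@points)))
  }
  if (!is.na(object@polygonSides) && object@polygonSides < 3L)
    return("polygonSides must be >= 3")
  if (length(object@points) &&
      !all(vapply(object@points, is, logical(1), "VisualPoint")))
    return("points must be VisualPoint objects")
  TRUE
})

#' Overall arrangement of the components of a pattern
#' @slot value one of [spatialPatternValues()].
#' @export
setClass("SpatialPattern", contains = "VisualElement",
  representation(value = "character"))
setValidity("SpatialPattern", function(object) {
  if (!object@value %in% spatialPatternValues("dermoscopy"))
    return(sprintf("unknown spatial pattern '%s'", object@value))
  TRUE
})

setClassUnion("OptionalSpatialPattern", c("SpatialPattern", "NULL"))

#' A named composite of shapes and/or sub-patterns
#'
#' A pattern is a composite: its shapes and sub-patterns together are
#' non-empty, a pattern may contain several sub-patterns, and the
#' sub-pattern graph is acyclic.
#'
#' @slot name pattern label.
#' @slot shapes list of [Shape].
#' @slot subpatterns list of [Pattern].
#' @slot spatialPattern optional [SpatialPattern].
#' @slot relations data.frame with columns subject/predicate/object holding
#'   pairwise relationship assertions between member elements.
#' @export
setClass("Pattern", contains = "VisualElement",
  representation(name = "character", shapes = "list", subpatterns = "list",
                 spatialPattern = "OptionalSpatialPattern",
                 relations = "data.frame"),
  prototype(spatialPattern = NULL,
            relations = data.frame(subject = character(0),
                                   predicate = character(0),
                                   object = character(0))))

setValidity("Pattern", function(object) {
  if (length(object@shapes) + length(object@subpatterns) == 0)
    return("a pattern is a composite: shapes + subpatterns must be non-empty")
  if (length(object@shapes) &&
      !all(vapply(object@shapes, is, logical(1), "Shape")))
    return("shapes must be Shape objects")
  if (length(object@subpatterns) &&
      !all(vapply(object@subpatterns, is, logical(1), "Pattern")))
    return("subpatterns must be Pattern objects")
  cyc <- patternCycle(object)
  if (!is.null(cyc))
    return(sprintf("pattern cycle: %s", paste(cyc, collapse = " -> ")))
  TRUE
})

#' An ordered, non-empty composite of visual elements
#' @slot elements list of [VisualElement] objects, size >= 1, enumerated
#'   deterministically in insertion order.
#' @export
setClass("Visualization",
  representation(elements = "list"))
setValidity("Visualization", function(object) {
  if (!length(object@elements))
    return("a visualization holds at least one element")
  if (!all(vapply(object@elements, is, logical(1), "VisualElement")))
    return("all members must be VisualElement objects")
  TRUE
})

## ---- geometry ----

#' Virtual parent of geometric realizations
#' @export
setClass("Geometry", representation("VIRTUAL"))

#' Circle geometry (loose circle: radial perturbation permitted elsewhere)
#' @slot center numeric 2-vector.
#' @slot radius positive radius.
#' @export
setClass("CircleGeom", contains = "Geometry",
  representation(center = "numeric", radius = "numeric"))
setValidity("CircleGeom", function(object) {
  if (length(object@center) != 2) return("center must be 2-D")
  if (length(object@radius) != 1 || object@radius <= 0)
    return("radius must be a positive scalar")
  TRUE
})

#' Simple polygon geometry
#' @slot vertices n x 2 matrix, n >= 3, non-self-intersecting.
#' @export
setClass("PolygonGeom", contains = "Geometry",
  representation(vertices = "matrix"))
setValidity("PolygonGeom", function(object) {
  v <- object@vertices
  if (ncol(v) != 2 || nrow(v) < 3) return("need an n x 2 matrix, n >= 3")
  if (selfIntersects(v)) return("polygon must be simple")
  TRUE
})

#' Open polyline geometry
#' @slot vertices n x 2 matrix, n >= 2.
#' @export
setClass("PolylineGeom", contains = "Geometry",
  representation(vertices = "matrix"))
setValidity("PolylineGeom", function(object) {
  v <- object@vertices
  if (ncol(v) != 2 || nrow(v) < 2) return("need an n x 2 matrix, n >= 2")
  TRUE
})

#' Straight segment geometry
#' @slot vertices 2 x 2 matrix (the two endpoints).
#' @export
setClass("SegmentGeom", contains = "PolylineGeom")
setValidity("SegmentGeom", function(object) {
  if (nrow(object@vertices) != 2) return("a segment has exactly 2 points")
  TRUE
})

#' Four-flag interior/boundary intersection state of a geometry pair
#'
#' The abstraction under all spatial predicates: whether the boundaries of
#' the two objects share points (`bb`), whether their interiors share
#' points (`ii`), whether the boundary of the first meets the interior of
#' the second (`bi`), and conversely (`ib`). Swapping the arguments maps
#' bb<->bb, ii<->ii, bi<->ib. The `extra` slot keeps the
#' interior/boundary-vs-exterior flags needed by the strict mode.
#'
#' @slot bb,ii,bi,ib logical flags.
#' @slot extra named logical vector (`ie`, `be`, `ei`, `eb`).
#' @export
setClass("IntersectionState",
  representation(bb = "logical", ii = "logical", bi = "logical",
                 ib = "logical", extra = "logical"),
  prototype(extra = c(ie = NA, be = NA, ei = NA, eb = NA)))

#' A synthetic geometric scene
#'
#' @slot ids geometry identifiers.
#' @slot geometries list of [Geometry], all within the unit canvas.
#' @slot fills fill color names (one per geometry).
#' @slot strokes stroke color names (one per geometry).
#' @slot seed generating seed; identical (provenance, seed) pairs produce
#'   identical scenes.
#' @slot provenance generating pattern term, or "adhoc".
#' @export
setClass("Scene",
  representation(ids = "character", geometries = "list", fills = "character",
                 strokes = "character", seed = "integer",
                 provenance = "character"))
setValidity("Scene", function(object) {
  n <- length(object@geometries)
  if (length(object@ids) != n || length(object@fills) != n ||
      length(object@strokes) != n)
    return("ids, fills and strokes must parallel the geometry list")
  if (anyDuplicated(object@ids)) return("geometry ids must be unique")
  TRUE
})

## ---- catalog ----

.clauseRoles <- c("shape-requirement", "subpattern-reference",
                  "relation-assertion", "spatial-pattern", "body-position",
                  "annotation")

#' One clause of a pattern definition
#'
#' Declarative building block of the decomposition of a metaphoric term.
#' Each role licenses its own fields: a `shape-requirement` constrains a
#' shape (kind, color, size, texture, stroke, relative position,
#' relationship qualifier), a `relation-assertion` holds a pairwise spatial
#' predicate between two named parts, a `subpattern-reference` pulls in
#' another term's clauses, `spatial-pattern` and `body-position` carry a
#' single value, and `annotation` carries free text (non-visual information
#' such as the imaging modality).
#'
#' @slot role one of the six clause roles.
#' @slot shapeKind,lineStyle,size,texture,strokeWidth shape constraints.
#' @slot color color constraint (possibly several acceptable names).
#' @slot relativePosition Center/OffCenter/Periphery.
#' @slot relationship spatial-relationship qualifier.
#' @slot predicate,subject,object pairwise predicate assertion.
#' @slot subpattern referenced term name.
#' @slot expand whether a subpattern reference is expanded by
#'   [decompose()].
#' @slot spatialPattern spatial-pattern value.
#' @slot bodyPosition Face/Volar.
#' @slot note annotation text.
#' @export
setClass("ElementClause",
  representation(role = "character", shapeKind = "character",
                 lineStyle = "character", color = "character",
                 size = "character", texture = "character",
                 strokeWidth = "character",
                 relativePosition = "character", relationship = "character",
                 predicate = "character", subject = "character",
                 object = "character", subpattern = "character",
                 expand = "logical", spatialPattern = "character",
                 bodyPosition = "character", note = "character"),
  prototype(shapeKind = NA_character_, lineStyle = NA_character_,
            color = character(0), size = NA_character_,
            texture = NA_character_, strokeWidth = NA_character_,
            relativePosition = NA_character_, relationship = NA_character_,
            predicate = NA_character_, subject = NA_character_,
            object = NA_character_, subpattern = NA_character_,
            expand = TRUE, spatialPattern = NA_character_,
            bodyPosition = NA_character_, note = NA_character_))

setValidity("ElementClause", function(object) {
  if (!object@role %in% .clauseRoles)
    return(sprintf("unknown clause role '%s'", object@role))
  licensed <- switch(object@role,
    "shape-requirement" = c("shapeKind", "lineStyle", "color", "size",
                            "texture", "strokeWidth", "relativePosition",
                            "relationship"),
    "subpattern-reference" = c("subpattern", "expand"),
    "relation-assertion" = c("predicate", "subject", "object"),
    "spatial-pattern" = "spatialPattern",
    "body-position" = "bodyPosition",
    "annotation" = "note")
  fields <- c("shapeKind", "lineStyle", "color", "size", "texture",
              "strokeWidth", "relativePosition", "relationship",
              "predicate", "subject", "object", "subpattern",
              "spatialPattern", "bodyPosition", "note")
  for (f in setdiff(fields, licensed)) {
    v <- slot(object, f)
    if (length(v) && !all(is.na(v)))
      return(sprintf("field '%s' is not licensed by role '%s'",
                     f, object@role))
  }
  if (object@role == "shape-requirement" && is.na(object@shapeKind))
    return("a shape-requirement clause needs a shapeKind")
  if (object@role == "relation-assertion" &&
      (is.na(object@predicate) || is.na(object@subject) ||
       is.na(object@object)))
    return("a relation-assertion needs predicate, subject and object")
  if (object@role == "subpattern-reference" && is.na(object@subpattern))
    return("a subpattern-reference needs a term name")
  TRUE
})

#' Declarative decomposition of one metaphoric term
#'
#' @slot term the metaphoric name.
#' @slot altLabels SKOS alternative labels.
#' @slot group optional higher-level pattern name.
#' @slot clauses non-empty list of [ElementClause].
#' @slot bodyPosition optional Face/Volar.
#' @slot annotations free-text notes.
#' @slot provisional marks clauses inferred from group structure where the
#'   source prints only the term name.
#' @export
setClass("PatternDefinition",
  representation(term = "character", altLabels = "character",
                 group = "character", clauses = "list",
                 bodyPosition = "character", annotations = "character",
                 provisional = "logical"),
  prototype(altLabels = character(0), group = NA_character_,
            bodyPosition = NA_character_, annotations = character(0),
            provisional = FALSE))
setValidity("PatternDefinition", function(object) {
  if (length(object@term) != 1 || !nzchar(object@term))
    return("term must be a non-empty label")
  if (!length(object@clauses)) return("clauses must be non-empty")
  if (!all(vapply(object@clauses, is, logical(1), "ElementClause")))
    return("clauses must be ElementClause objects")
  if (!is.na(object@bodyPosition) &&
      !object@bodyPosition %in% bodyPositionValues())
    return(sprintf("unknown body position '%s'", object@bodyPosition))
  TRUE
})

#' Catalog of pattern definitions with higher-level groups
#'
#' @slot definitions named list of [PatternDefinition]; names are the
#'   case-folded terms.
#' @slot groups named list mapping a higher-level pattern name to member
#'   terms.
#' @export
setClass("Catalog",
  representation(definitions = "list", groups = "list"),
  prototype(definitions = structure(list(), names = character(0)),
            groups = structure(list(), names = character(0))))
setValidity("Catalog", function(object) {
  terms <- vapply(object@definitions, function(d) d@term, character(1))
  if (anyDuplicated(foldTerm(terms)))
    return("terms must be unique after case-folding")
  for (g in names(object@groups)) {
    for (m in object@groups[[g]]) {
      d <- object@definitions[[foldTerm(m)]]
      if (is.null(d)) return(sprintf("group '%s' lists unknown term '%s'",
                                     g, m))
      if (is.na(d@group) || d@group != g)
        return(sprintf("group index '%s' disagrees with term '%s'", g, m))
    }
  }
  TRUE
})

## ---- ontology ----

#' In-memory OWL2 ontology model
#'
#' Holds declared entities (classes, object/data properties, individuals)
#' with SKOS preferred/alternative labels, and an axiom table. The axiom
#' table is kept in a canonical lexicographic order so exports are
#' deterministic and re-exports byte-identical.
#'
#' @slot iri ontology IRI.
#' @slot label ontology label.
#' @slot entities data.frame with columns label/type/prefLabel/altLabels
#'   (altLabels "|"-separated).
#' @slot axioms data.frame with columns kind/subject/property/object/value.
#' @slot imports list of imported `OntologyModel` objects.
#' @export
setClass("OntologyModel",
  representation(iri = "character", label = "character",
                 entities = "data.frame", axioms = "data.frame",
                 imports = "list"))
setValidity("OntologyModel", function(object) {
  e <- object@entities
  need <- c("label", "type", "prefLabel", "altLabels")
  if (!all(need %in% names(e)))
    return("entities needs label/type/prefLabel/altLabels columns")
  if (anyDuplicated(paste(e$label, e$type)))
    return("duplicate entity declarations")
  bad <- !e$type %in% c("class", "objectProperty", "dataProperty",
                        "individual")
  if (any(bad)) return("unknown entity type")
  if (any(!nzchar(e$prefLabel)))
    return("every entity has exactly one preferred label")
  TRUE
})

#' Rater annotation matrix of verbalized statements
#'
#' Rectangular Y/N/X matrix, statements in rows and raters in columns, with
#' no missing cells.
#'
#' @slot ratings character matrix with values in {Y, N, X}.
#' @slot statements row labels (statement ids).
#' @slot raters column labels.
#' @export
setClass("RatingMatrix",
  representation(ratings = "matrix", statements = "character",
                 raters = "character"))
setValidity("RatingMatrix", function(object) {
  m <- object@ratings
  if (!is.character(m)) return("ratings must be a character matrix")
  if (nrow(m) != length(object@statements) ||
      ncol(m) != length(object@raters))
    return("dimnames must parallel the matrix")
  if (anyNA(m)) return("no missing cells allowed")
  bad <- setdiff(unique(as.vector(m)), c("Y", "N", "X"))
  if (length(bad))
    return(sprintf("invalid rating value(s): %s", paste(bad, collapse = ", ")))
  TRUE
})
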