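#' @title Controlled vocabularies of the two-layer visual-element model
#'
#' @description
#' The model is layered: a generic visuals layer defines the basic elements
#' used to describe any visualization (shapes, colors, strokes, textures,
#' points, sizes, spatial patterns and relationships), and a dermoscopy
#' layer extends it with the vocabulary needed to decompose metaphoric
#' dermoscopic pattern terms (new colors, shiny texture, uniform/variable
#' stroke widths, line styles, relative and body positions). Constructors
#' take a `mode` argument: `"core"` accepts only the generic layer,
#' `"dermoscopy"` (the default) accepts both.
#'
#' @name vocabularies
NULL

.modes <- c("dermoscopy", "core")

checkMode <- function(mode) match.arg(mode, .modes)

#' Element kinds recognised by the model
#'
#' `RelativePosition` and `BodyPosition` exist only in the dermoscopy layer.
#'
#' @param mode `"dermoscopy"` or `"core"`.
#' @return character vector of element-kind labels.
#' @export
elementKinds <- function(mode = "dermoscopy") {
  mode <- checkMode(mode)
  core <- c("Shape", "Texture", "Color", "Pattern", "SpatialPattern",
            "Stroke", "Point", "SpatialRelationship", "Size", "Path")
  if (mode == "core") core else c(core, "RelativePosition", "BodyPosition")
}

#' @rdname vocabularies
#' @export
shapeKinds <- function() {
  c("Circle", "Ellipse", "Line", "Polygon", "Polyline", "Rectangle",
    "Path", "Structureless")
}

# named polygon subkinds with their exact point (vertex) cardinality
.polygonCardinality <- c(
  Triangle = 3L, Quadrilateral = 4L, Pentagon = 5L, Hexagon = 6L,
  Heptagon = 7L, Octagon = 8L, Nonagon = 9L, Decagon = 10L
)

#' @rdname vocabularies
#' @export
polygonKinds <- function() names(.polygonCardinality)

#' Line styles
#'
#' An unspecified line is assumed straight; the styled variants (sharp,
#' curved, serpiginous, wavy, dotted, double) belong to the dermoscopy layer.
#' @inheritParams elementKinds
#' @export
lineStyles <- function(mode = "dermoscopy") {
  mode <- checkMode(mode)
  if (mode == "core") "Straight"
  else c("Straight", "Sharp", "Curved", "Serpiginous", "Wavy", "Dotted",
         "Double")
}

#' @rdname vocabularies
#' @export
textureValues <- function(mode = "dermoscopy") {
  mode <- checkMode(mode)
  if (mode == "core") c("Smooth", "Rough") else c("Smooth", "Rough", "Shiny")
}

#' Qualitative stroke widths
#'
#' The generic layer carries Thin/Medium/Thick; Uniform and Variable widths
#' belong to the dermoscopy layer (used by typical/atypical network lines).
#' Whether Medium survives in the dermoscopy layer is ambiguous in the
#' source vocabulary; it is accepted in both modes here.
#' @inheritParams elementKinds
#' @export
qualitativeWidths <- function(mode = "dermoscopy") {
  mode <- checkMode(mode)
  if (mode == "core") c("Thin", "Medium", "Thick")
  else c("Thin", "Medium", "Thick", "Uniform", "Variable")
}

#' @rdname vocabularies
#' @export
sizeValues <- function() c("Small", "Large", "Long", "Uniform", "Variable")

#' @rdname vocabularies
#' @export
pointRoles <- function() c("Beginning", "Middle", "Ending", "Unspecified")

#' @rdname vocabularies
#' @export
spatialPatternValues <- function(mode = "dermoscopy") {
  mode <- checkMode(mode)
  core <- c("LinearFormation", "CircularFormation", "GridFormation")
  if (mode == "core") core
  else c(core, "PolygonFormation", "SquareFormation", "LeaflikePattern")
}

#' Spatial-relationship qualifiers of the dermoscopy layer
#' @export
relationshipValues <- function() {
  c("Interconnecting", "IncompleteConnection", "NonInterconnecting",
    "Parallel", "Orthogonal", "Radial", "Clustered", "Distributed",
    "Symmetrical", "Asymmetrical", "Uniform", "Variable")
}

#' Pairwise spatial predicates
#'
#' The nine predicate labels of the interior/boundary intersection calculus;
#' `spatialSurround` is a dermoscopy-layer addition.
#' @inheritParams elementKinds
#' @export
spatialPredicates <- function(mode = "dermoscopy") {
  core <- c("spatialDisjoint", "spatialOverlap", "spatialMeet",
            "spatialEqual", "spatialInside", "spatialCoveredBy",
            "spatialCovers", "spatialContains")
  mode <- checkMode(mode)
  if (mode == "core") core else c(core, "spatialSurround")
}

#' @rdname vocabularies
#' @export
relativePositionValues <- function() c("Center", "OffCenter", "Periphery")

#' @rdname vocabularies
#' @export
bodyPositionValues <- function() c("Face", "Volar")

# shape aliases of the descriptive terminology: dot = small circle,
# clod/globule = circle, ellipse = elongated circle
.shapeAliases <- list(
  dot     = list(shapeKind = "Circle", size = "Small"),
  clod    = list(shapeKind = "Circle", size = NA_character_),
  globule = list(shapeKind = "Circle", size = NA_character_),
  ellipse = list(shapeKind = "Circle", size = "Long")
)

#' Resolve a descriptive-terminology shape alias
#'
#' "Dot", "clod", "globule" and "ellipse" are alternative labels for
#' circle-based shapes rather than shape classes of their own: a dot is a
#' small circle, a clod or globule is a circle, and an ellipse is a circle
#' of long size (circles are modeled loosely, as rounded shapes that need
#' not have uniform radius).
#'
#' @param label alias label, case-insensitive.
#' @return list with `shapeKind` and `size` (`NA` when the alias implies
#'   none), or `NULL` when the label is not an alias.
#' @examples
#' shapeAlias("dot")
#' @export
shapeAlias <- function(label) {
  .shapeAliases[[foldTerm(label)]]
}

#' Load a color palette
#'
#' Reads a palette CSV with columns `name,r,g,b,hex`; rows with empty
#' r/g/b/hex are symbolic colors (pigmentation classes and collection
#' qualifiers that carry no fixed RGB value). The shipped default palette
#' covers the dermoscopy color list.
#'
#' @param path palette CSV; default is the shipped palette.
#' @param mode vocabulary mode; `"core"` drops dermoscopy-only colors.
#' @return named list of [Color] objects.
#' @export
loadPalette <- function(path = NULL, mode = "dermoscopy") {
  mode <- checkMode(mode)
  if (is.null(path)) {
    path <- system.file("extdata", "palette.csv", package = "dermvis")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "integer", "integer",
                                        "integer", "character", "character"))
  if (mode == "core") tab <- tab[tab$layer == "core", , drop = FALSE]
  cols <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    if (is.na(row$r) || !nzchar(row$hex)) {
      symbolicColor(row$name,
                    qualifier = row$name %in% c("Uniform", "Variable"))
    } else {
      makeColor(row$name, c(row$r, row$g, row$b), row$hex)
    }
  })
  names(cols) <- tab$name
  cols
}

# color subsumption for query matching in "subsumes" mode: an abstract
# color on the left subsumes the concrete colors on the right
.colorHierarchy <- list(
  "Dark"          = c("Dark", "Black", "Brown", "Gray Brown", "Blue Gray",
                      "Indigo", "Violet"),
  "Pigmented"     = c("Pigmented", "Brown", "Light Brown", "Gray Brown",
                      "Black", "Blue Gray", "Dark"),
  "Non-pigmented" = c("Non-pigmented", "White", "Bright White"),
  "White"         = c("White", "Bright White")
)

#' Color subsumption used by the query engine
#'
#' In `subsumes` match mode an abstract color constraint (e.g. `Dark`)
#' matches any concrete color it covers (e.g. `Black`). Pigmentation
#' classes are relative to the individual's skin color; the subsumption
#' table is a toolkit convention over the shipped palette.
#'
#' @param constraint color name used in the query.
#' @param value color name found in a clause.
#' @return logical.
#' @export
colorSubsumes <- function(constraint, value) {
  covered <- .colorHierarchy[[constraint]]
  if (is.null(covered)) covered <- constraint
  foldTerm(value) %in% foldTerm(covered)
}
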