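#' @include owl.R catalog.R
NULL

#' Build the generic visuals-layer ontology
#'
#' Assembles the foundational ontology of visual elements: the shape
#' taxonomy (circle, ellipse, line, polygon with named subkinds carrying
#' exact point-cardinality restrictions, polyline, rectangle, path,
#' structureless), points with beginning/middle/ending roles, colors with
#' RGB and hex data properties plus multi-color with inverse composition,
#' stroke with integer width, texture, size, spatial patterns, and the
#' eight pairwise spatial predicates.
#'
#' @param iri ontology IRI.
#' @return an [OntologyModel].
#' @examples
#' entityCounts(buildCoreOntology())
#' @export
buildCoreOntology <- function(iri = paste0(.dvBaseIRI, "/core")) {
  m <- ontologyModel(iri, "elements of visuals")
  cls <- function(m, label, parent = NULL, alts = character(0)) {
    m <- addEntity(m, label, "class", altLabels = alts)
    if (!is.null(parent)) m <- addAxiom(m, "SubClassOf", label,
                                        object = parent)
    m
  }
  m <- cls(m, "VisualElement")
  m <- cls(m, "Visualization")
  for (k in elementKinds("core"))
    if (!k %in% c("Path")) m <- cls(m, k, "VisualElement")
  m <- cls(m, "Path", "Shape")
  m <- cls(m, "Circle", "Shape", alts = c("clod", "globule"))
  m <- cls(m, "Ellipse", "Shape")
  m <- cls(m, "Line", "Shape")
  m <- cls(m, "Polygon", "Shape")
  m <- cls(m, "Polyline", "Shape")
  m <- cls(m, "Rectangle", "Shape")
  m <- cls(m, "Structureless", "Shape")
  for (pk in polygonKinds()) {
    m <- cls(m, pk, "Polygon")
    m <- addAxiom(m, "ObjectExactCardinality", pk, "hasPoints", "Point",
                  pointCardinality(pk))
  }
  m <- cls(m, "BeginningPoint", "Point")
  m <- cls(m, "MiddlePoint", "Point")
  m <- cls(m, "EndingPoint", "Point")
  m <- cls(m, "MultiColor", "Color")
  for (col in names(loadPalette(mode = "core")))
    m <- cls(m, camelFragment(col), "Color")
  m <- cls(m, "SmoothTexture", "Texture")
  m <- cls(m, "RoughTexture", "Texture")
  for (w in qualitativeWidths("core"))
    m <- cls(m, paste0(w, "Width"), "Stroke")
  for (s in c("Small", "Large", "Long"))
    m <- cls(m, paste0(s, "Size"), "Size")
  for (sp in spatialPatternValues("core")) m <- cls(m, sp, "SpatialPattern")
  m <- addAxiom(m, "DisjointClasses", "Shape", object = "Color")

  op <- function(m, label, domain = NULL, range = NULL) {
    m <- addEntity(m, label, "objectProperty")
    if (!is.null(domain)) m <- addAxiom(m, "ObjectPropertyDomain", label,
                                        object = domain)
    if (!is.null(range)) m <- addAxiom(m, "ObjectPropertyRange", label,
                                       object = range)
    m
  }
  m <- op(m, "hasShape", "Pattern", "Shape")
  m <- op(m, "hasPattern", "Pattern", "Pattern")  # deliberately not
                                                  # functional: a pattern
                                                  # may contain several
  m <- op(m, "hasColorFill", "Shape", "Color")
  m <- op(m, "hasStroke", "Shape", "Stroke")
  m <- op(m, "hasStrokeColor", "Stroke", "Color")
  m <- op(m, "hasVisualTexture", "Shape", "Texture")
  m <- op(m, "hasQualitativeSize", "Shape", "Size")
  m <- op(m, "hasSpatialPattern", "Pattern", "SpatialPattern")
  m <- op(m, "hasSpatialRelationship", "Shape", "SpatialRelationship")
  m <- op(m, "hasCategoryWidth", "Stroke", "Stroke")
  m <- op(m, "hasPoints", "Shape", "Point")
  m <- op(m, "hasMultipleColors", "MultiColor", "Color")
  m <- op(m, "isComposedOfColors", "Color", "MultiColor")
  m <- addAxiom(m, "InverseObjectProperties", "hasMultipleColors",
                object = "isComposedOfColors")
  for (p in spatialPredicates("core")) m <- op(m, p, "Shape", "Shape")

  dp <- function(m, label, domain, range) {
    m <- addEntity(m, label, "dataProperty")
    m <- addAxiom(m, "DataPropertyDomain", label, object = domain)
    addAxiom(m, "DataPropertyRange", label, object = range)
  }
  # ranges are typed numerics, not plain literals
  m <- dp(m, "strokeWidth", "Stroke", "integer")
  m <- dp(m, "redValue", "Color", "integer")
  m <- dp(m, "greenValue", "Color", "integer")
  m <- dp(m, "blueValue", "Color", "integer")
  m <- dp(m, "hexValue", "Color", "string")
  m
}

#' Build the dermoscopy-layer ontology from a catalog
#'
#' Extends the visuals layer (imported by IRI) with the dermoscopy
#' vocabulary — pigmentation colors, shiny texture, uniform/variable
#' widths and sizes, styled lines, relative and body positions, the
#' surround predicate and relationship qualifiers — and one pattern class
#' per registered term. Clause content is encoded as existential
#' restrictions (`hasShape some Circle`, `hasPattern some Pseudopods`,
#' `hasSpatialPattern some SquareFormation`, ...), with SKOS alternative
#' labels from the catalog.
#'
#' @param catalog a [Catalog]; defaults to the shipped one.
#' @param iri ontology IRI.
#' @return an [OntologyModel] importing the core model.
#' @export
buildDermoscopyOntology <- function(catalog = dermoscopyCatalog(),
                                    iri = paste0(.dvBaseIRI,
                                                 "/dermoscopy")) {
  core <- buildCoreOntology()
  m <- ontologyModel(iri, "dermoscopy elements of visuals")
  m@imports <- list(core)
  cls <- function(m, label, parent, alts = character(0)) {
    m <- addEntity(m, label, "class", altLabels = alts)
    addAxiom(m, "SubClassOf", label, object = parent)
  }
  for (col in c("NonPigmentedColor", "HypopigmentedColor",
                "PigmentedColor", "DarkColor", "UniformColor",
                "VariableColor"))
    m <- cls(m, col, "Color")
  m <- cls(m, "ShinyTexture", "Texture")
  for (w in c("Uniform", "Variable")) m <- cls(m, paste0(w, "Width"),
                                               "Stroke")
  for (s in c("Uniform", "Variable")) m <- cls(m, paste0(s, "Size"), "Size")
  for (ls in setdiff(lineStyles("dermoscopy"), "Straight"))
    m <- cls(m, paste0(ls, "Line"), "Line")
  m <- cls(m, "RelativePosition", "VisualElement")
  for (rp in relativePositionValues()) m <- cls(m, rp, "RelativePosition")
  m <- cls(m, "BodyPosition", "VisualElement")
  for (bp in bodyPositionValues()) m <- cls(m, bp, "BodyPosition")
  for (sr in relationshipValues())
    m <- cls(m, paste0(sr, "SpatialRelationship"), "SpatialRelationship")
  for (sp in setdiff(spatialPatternValues("dermoscopy"),
                     spatialPatternValues("core")))
    m <- cls(m, sp, "SpatialPattern")
  m <- addEntity(m, "hasRelativePosition", "objectProperty")
  m <- addAxiom(m, "ObjectPropertyDomain", "hasRelativePosition",
                object = "Shape")
  m <- addAxiom(m, "ObjectPropertyRange", "hasRelativePosition",
                object = "RelativePosition")
  m <- addEntity(m, "locatedAtBodyPosition", "objectProperty")
  m <- addAxiom(m, "ObjectPropertyDomain", "locatedAtBodyPosition",
                object = "Pattern")
  m <- addAxiom(m, "ObjectPropertyRange", "locatedAtBodyPosition",
                object = "BodyPosition")
  m <- addEntity(m, "spatialSurround", "objectProperty")
  m <- addAxiom(m, "SubObjectPropertyOf", "spatialSurround",
                object = "spatialCovers")

  groups <- catalogGroups(catalog)
  for (g in names(groups)) m <- cls(m, camelFragment(g), "Pattern")
  for (term in catalogTerms(catalog)) {
    d <- resolveTerm(catalog, term)
    frag <- camelFragment(d@term)
    parent <- if (!is.na(d@group)) camelFragment(d@group) else "Pattern"
    m <- addEntity(m, frag, "class", prefLabel = tolower(d@term),
                   altLabels = d@altLabels)
    m <- addAxiom(m, "SubClassOf", frag, object = parent)
    for (cl in d@clauses) {
      if (cl@role == "shape-requirement") {
        sk <- cl@shapeKind
        target <- if (foldTerm(sk) %in% foldTerm(polygonKinds())) sk
                  else sk
        m <- addAxiom(m, "ObjectSomeValuesFrom", frag, "hasShape", target)
      } else if (cl@role == "subpattern-reference") {
        m <- addAxiom(m, "ObjectSomeValuesFrom", frag, "hasPattern",
                      camelFragment(cl@subpattern))
      } else if (cl@role == "spatial-pattern") {
        m <- addAxiom(m, "ObjectSomeValuesFrom", frag, "hasSpatialPattern",
                      cl@spatialPattern)
      } else if (cl@role == "body-position") {
        m <- addAxiom(m, "ObjectSomeValuesFrom", frag,
                      "locatedAtBodyPosition", cl@bodyPosition)
      }
    }
  }
  m
}
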