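#' @include AllClasses.R
NULL

#' Clause constructors
#'
#' Build the declarative clauses that decompose a metaphoric term into
#' visual elements. `shapeClause()` constrains a shape and its attributes;
#' `relationClause()` asserts a pairwise spatial predicate between two
#' named parts; `subpatternClause()` references another term;
#' `spatialPatternClause()` and `bodyPositionClause()` carry one value;
#' `annotationClause()` carries non-visual free text (e.g. the imaging
#' modality), which by design never enters a visual clause.
#'
#' @param shapeKind shape kind, named polygon subkind, or alias
#'   ("dot", "globule", ...), resolved via [shapeAlias()].
#' @param color acceptable color name(s).
#' @param size,texture,lineStyle,strokeWidth optional attribute constraints.
#' @param relativePosition Center/OffCenter/Periphery.
#' @param relationship spatial-relationship qualifier.
#' @return an [ElementClause].
#' @export
shapeClause <- function(shapeKind, color = character(0), size = NA,
                        texture = NA, lineStyle = NA, strokeWidth = NA,
                        relativePosition = NA, relationship = NA) {
  alias <- shapeAlias(shapeKind)
  if (!is.null(alias)) {
    if (is.na(size) && !is.na(alias$size)) size <- alias$size
    shapeKind <- alias$shapeKind
  }
  if (!foldTerm(shapeKind) %in%
      foldTerm(c(shapeKinds(), polygonKinds())))
    dvStop(sprintf("unknown shape kind '%s'", shapeKind), "vocabularyError")
  if (!is.na(size) && !size %in% sizeValues())
    dvStop(sprintf("unknown size '%s'", size), "vocabularyError")
  if (!is.na(texture) && !texture %in% textureValues())
    dvStop(sprintf("unknown texture '%s'", texture), "vocabularyError")
  if (!is.na(relativePosition) &&
      !relativePosition %in% relativePositionValues())
    dvStop(sprintf("unknown relative position '%s'", relativePosition),
           "vocabularyError")
  if (!is.na(relationship) && !relationship %in% relationshipValues())
    dvStop(sprintf("unknown relationship '%s'", relationship),
           "vocabularyError")
  if (!is.na(strokeWidth) && !strokeWidth %in% qualitativeWidths())
    dvStop(sprintf("unknown stroke width '%s'", strokeWidth),
           "vocabularyError")
  new("ElementClause", role = "shape-requirement", shapeKind = shapeKind,
      color = color, size = as.character(size),
      texture = as.character(texture), lineStyle = as.character(lineStyle),
      strokeWidth = as.character(strokeWidth),
      relativePosition = as.character(relativePosition),
      relationship = as.character(relationship))
}

#' @rdname shapeClause
#' @param subject,object part names the predicate relates.
#' @param predicate pairwise predicate from [spatialPredicates()].
#' @export
relationClause <- function(subject, predicate, object) {
  if (!predicate %in% spatialPredicates())
    dvStop(sprintf("unknown predicate '%s'; vocabulary: %s", predicate,
                   paste(spatialPredicates(), collapse = ", ")),
           "vocabularyError")
  new("ElementClause", role = "relation-assertion", subject = subject,
      predicate = predicate, object = object)
}

#' @rdname shapeClause
#' @param term referenced term name.
#' @param expand expand the reference in [decomposeTerm()]?
#' @export
subpatternClause <- function(term, expand = TRUE) {
  new("ElementClause", role = "subpattern-reference", subpattern = term,
      expand = expand)
}

#' @rdname shapeClause
#' @param value vocabulary value for the role.
#' @export
spatialPatternClause <- function(value) {
  if (!value %in% spatialPatternValues())
    dvStop(sprintf("unknown spatial pattern '%s'", value), "vocabularyError")
  new("ElementClause", role = "spatial-pattern", spatialPattern = value)
}

#' @rdname shapeClause
#' @export
bodyPositionClause <- function(value) {
  if (!value %in% bodyPositionValues())
    dvStop(sprintf("unknown body position '%s'", value), "vocabularyError")
  new("ElementClause", role = "body-position", bodyPosition = value)
}

#' @rdname shapeClause
#' @param note free text.
#' @export
annotationClause <- function(note) {
  new("ElementClause", role = "annotation", note = note)
}

#' Create a pattern definition
#'
#' @param term metaphoric term name.
#' @param clauses non-empty list of [ElementClause].
#' @param altLabels SKOS alternative labels.
#' @param group optional higher-level pattern name.
#' @param bodyPosition optional Face/Volar.
#' @param annotations free-text notes.
#' @param provisional marks clause sets inferred from group structure where
#'   only the term name is attested.
#' @return a [PatternDefinition].
#' @export
patternDefinition <- function(term, clauses, altLabels = character(0),
                              group = NA, bodyPosition = NA,
                              annotations = character(0),
                              provisional = FALSE) {
  new("PatternDefinition", term = term, clauses = clauses,
      altLabels = altLabels, group = as.character(group),
      bodyPosition = as.character(bodyPosition), annotations = annotations,
      provisional = provisional)
}

#' Create an empty catalog
#' @return a [Catalog] with no definitions or groups.
#' @export
emptyCatalog <- function() new("Catalog")

#' Register a higher-level group
#' @param catalog a [Catalog].
#' @param name group name.
#' @return the updated catalog.
#' @export
registerGroup <- function(catalog, name) {
  if (name %in% names(catalog@groups))
    dvStop(sprintf("group '%s' already registered", name), "duplicateError")
  catalog@groups[[name]] <- character(0)
  catalog
}

#' Register a pattern definition
#'
#' Adds a definition to the catalog; the term (and its alternative labels)
#' must be new after case-folding, and the definition's group, when
#' present, must name a registered higher-level pattern.
#'
#' @param catalog a [Catalog].
#' @param d a [PatternDefinition].
#' @return the updated catalog, with group indexes maintained.
#' @export
registerPattern <- function(catalog, d) {
  stopifnot(is(catalog, "Catalog"), is(d, "PatternDefinition"))
  known <- catalogLabels(catalog)
  clash <- intersect(foldTerm(c(d@term, d@altLabels)), foldTerm(known))
  if (length(clash))
    dvStop(sprintf("term or label already registered: %s",
                   paste(clash, collapse = ", ")), "duplicateError")
  if (!is.na(d@group) && !d@group %in% names(catalog@groups))
    dvStop(sprintf("group '%s' is not registered", d@group),
           "danglingGroupError")
  catalog@definitions[[foldTerm(d@term)]] <- d
  if (!is.na(d@group))
    catalog@groups[[d@group]] <- c(catalog@groups[[d@group]], d@term)
  validObject(catalog)
  catalog
}

catalogLabels <- function(catalog) {
  unlist(lapply(catalog@definitions, function(d) c(d@term, d@altLabels)),
         use.names = FALSE)
}

#' Terms registered in a catalog
#' @param catalog a [Catalog].
#' @return character vector of canonical term names, sorted.
#' @export
catalogTerms <- function(catalog) {
  sort(unname(vapply(catalog@definitions, function(d) d@term,
                     character(1))),
       method = "radix")
}

#' Resolve a term or alternative label to its definition
#'
#' @param catalog a [Catalog].
#' @param term term or SKOS alternative label, case-insensitive.
#' @return the [PatternDefinition]; unknown labels raise an error carrying
#'   nearest-label suggestions.
#' @export
resolveTerm <- function(catalog, term) {
  key <- foldTerm(term)
  d <- catalog@definitions[[key]]
  if (!is.null(d)) return(d)
  for (d in catalog@definitions)
    if (key %in% foldTerm(d@altLabels)) return(d)
  sugg <- nearestLabels(term, catalogLabels(catalog))
  dvStop(sprintf("unknown term '%s'%s", term,
                 if (length(sugg)) paste0("; did you mean: ",
                                          paste(sugg, collapse = ", "))
                 else ""),
         "unknownTermError")
}

#' Decompose a term into its visual-element clauses
#'
#' Returns the term's clause set fully expanded through sub-pattern
#' references (cycle-safe): a reference with `expand = TRUE` is replaced by
#' the referenced term's own expanded clauses; references marked
#' `expand = FALSE` are kept as references.
#'
#' @param catalog a [Catalog].
#' @param term term or alternative label.
#' @return list of [ElementClause].
#' @examples
#' cat <- dermoscopyCatalog()
#' length(decomposeTerm(cat, "Pseudopods"))
#' @export
decomposeTerm <- function(catalog, term) {
  expandClauses <- function(name, seen) {
    d <- resolveTerm(catalog, name)
    if (foldTerm(d@term) %in% seen) return(list())  # cycle guard
    seen <- c(seen, foldTerm(d@term))
    out <- list()
    for (cl in d@clauses) {
      if (cl@role == "subpattern-reference" && isTRUE(cl@expand)) {
        out <- c(out, expandClauses(cl@subpattern, seen))
      } else {
        out <- c(out, list(cl))
      }
    }
    out
  }
  expandClauses(term, character(0))
}

#' Higher-level groups of a catalog
#' @param catalog a [Catalog].
#' @return named list mapping each group to its member terms.
#' @export
catalogGroups <- function(catalog) catalog@groups

# fixed category inventory, in report order
.auditCategories <- c("shape", "color", "size", "texture",
                      "spatial relationship", "relative position",
                      "body position")

clauseCategories <- function(cl) {
  out <- character(0)
  if (cl@role == "shape-requirement") {
    out <- c(out, "shape")
    if (length(cl@color)) out <- c(out, "color")
    if (!is.na(cl@size)) out <- c(out, "size")
    if (!is.na(cl@texture)) out <- c(out, "texture")
    if (!is.na(cl@relationship)) out <- c(out, "spatial relationship")
    if (!is.na(cl@relativePosition)) out <- c(out, "relative position")
  } else if (cl@role == "relation-assertion") {
    out <- c(out, "spatial relationship")
  } else if (cl@role == "body-position") {
    out <- c(out, "body position")
  }
  out
}

termCategories <- function(catalog, term) {
  d <- resolveTerm(catalog, term)
  cats <- unlist(lapply(decomposeTerm(catalog, d@term), clauseCategories))
  if (!is.na(d@bodyPosition)) cats <- c(cats, "body position")
  unique(cats)
}

#' Audit category coverage across a catalog
#'
#' Consistency check suggested by expert review: once a category (color,
#' shape, size, ...) is used by one definition it should be a feature of
#' all definitions. For every category used by at least one term, the
#' report lists the terms lacking it; the report is empty exactly when
#' coverage is complete. Categories are examined in a fixed order so the
#' report is deterministic.
#'
#' @param catalog a [Catalog].
#' @return named list, category -> character vector of terms missing it;
#'   only categories with at least one missing term appear.
#' @export
auditCategoryCoverage <- function(catalog) {
  terms <- catalogTerms(catalog)
  if (!length(terms)) return(structure(list(), names = character(0)))
  have <- lapply(terms, function(t) termCategories(catalog, t))
  names(have) <- terms
  used <- .auditCategories[.auditCategories %in% unique(unlist(have))]
  report <- list()
  for (cat in used) {
    missing <- terms[!vapply(have, function(h) cat %in% h, logical(1))]
    if (length(missing)) report[[cat]] <- missing
  }
  report
}

setMethod("show", "Catalog", function(object) {
  cat(sprintf("Catalog: %d term(s), %d group(s)\n",
              length(object@definitions), length(object@groups)))
  for (g in names(object@groups))
    cat(sprintf("  %s: %s\n", g, paste(object@groups[[g]], collapse = ", ")))
})

setMethod("show", "PatternDefinition", function(object) {
  cat(sprintf("PatternDefinition \"%s\"%s: %d clause(s)%s\n", object@term,
              if (!is.na(object@group)) sprintf(" [%s]", object@group) else "",
              length(object@clauses),
              if (object@provisional) " (provisional)" else ""))
})

setMethod("show", "ElementClause", function(object) {
  desc <- switch(object@role,
    "shape-requirement" = paste(stats::na.omit(c(
      object@shapeKind,
      if (length(object@color)) paste(object@color, collapse = "/"),
      object@size, object@texture, object@relativePosition,
      object@relationship)), collapse = ", "),
    "relation-assertion" = sprintf("%s %s %s", object@subject,
                                   object@predicate, object@object),
    "subpattern-reference" = object@subpattern,
    "spatial-pattern" = object@spatialPattern,
    "body-position" = object@bodyPosition,
    "annotation" = object@note)
  cat(sprintf("<%s> %s\n", object@role, desc))
})

#' The shipped dermoscopy pattern catalog
#'
#' Builds the built-in catalog of metaphoric dermoscopic pattern terms
#' decomposed into visual-element clauses, organised under six higher-level
#' groups (Blotch, Globules, Dots, Streaks, Shiny White Structures,
#' Network). Definitions whose full clause content is not attested in the
#' source vocabulary follow their group's stated structure and are marked
#' provisional. Non-visual information (such as the polarized-light
#' requirement of the rainbow pattern and shiny white structures) is
#' carried in annotations, never in clauses.
#'
#' @return a validated [Catalog].
#' @examples
#' cat <- dermoscopyCatalog()
#' catalogGroups(cat)[["Network Pattern"]]
#' @export
dermoscopyCatalog <- function() {
  cg <- emptyCatalog()
  for (g in c("Blotch Pattern", "Globules Pattern", "Dots Pattern",
              "Streaks Pattern", "Shiny White Structures",
              "Network Pattern"))
    cg <- registerGroup(cg, g)

  reg <- function(cg, ...) registerPattern(cg, patternDefinition(...))

  ## Streaks Pattern ------------------------------------------------------
  cg <- reg(cg, "Pseudopods", group = "Streaks Pattern", clauses = list(
    shapeClause("Circle", relativePosition = "Periphery"),
    shapeClause("Line", relationship = "Radial"),
    relationClause("Circle", "spatialMeet", "Line")))
  cg <- reg(cg, "Radial Streaming", group = "Streaks Pattern",
    provisional = TRUE, clauses = list(
    shapeClause("Line", color = "Pigmented", relationship = "Radial",
                relativePosition = "Periphery")))
  cg <- reg(cg, "Branched Streaks", group = "Streaks Pattern",
    provisional = TRUE, clauses = list(
    shapeClause("Line", color = "Pigmented",
                relationship = "IncompleteConnection",
                relativePosition = "Periphery")))

  ## Network Pattern ------------------------------------------------------
  cg <- reg(cg, "Pigment Network",
    altLabels = "Typical Pigment Network", group = "Network Pattern",
    clauses = list(
    shapeClause("Line", color = "Pigmented",
                relationship = "Interconnecting", strokeWidth = "Uniform"),
    shapeClause("Circle", color = "Hypopigmented", size = "Large"),
    relationClause("Line", "spatialSurround", "Circle")))
  cg <- reg(cg, "Negative Network", group = "Network Pattern",
    provisional = TRUE, clauses = list(
    shapeClause("Line", color = "Hypopigmented", lineStyle = "Serpiginous",
                relationship = "Interconnecting"),
    shapeClause("Circle", color = "Pigmented", size = "Long"),
    relationClause("Line", "spatialSurround", "Circle")))

  ## Blotch Pattern -------------------------------------------------------
  cg <- reg(cg, "Blotch Regular", group = "Blotch Pattern",
    provisional = TRUE, clauses = list(
    shapeClause("Structureless", color = "Dark",
                relationship = "Symmetrical", relativePosition = "Center")))
  cg <- reg(cg, "Blotch Irregular", group = "Blotch Pattern",
    provisional = TRUE, clauses = list(
    shapeClause("Structureless", color = "Dark",
                relationship = "Asymmetrical",
                relativePosition = "OffCenter")))

  ## Globules Pattern -----------------------------------------------------
  cg <- reg(cg, "Globules Regular", group = "Globules Pattern",
    provisional = TRUE, clauses = list(
    shapeClause("globule", color = "Pigmented", size = "Uniform",
                relationship = "Distributed")))
  cg <- reg(cg, "Cobblestones", group = "Globules Pattern",
    altLabels = "Cobblestone Pattern", provisional = TRUE, clauses = list(
    shapeClause("Polygon", color = "Pigmented", size = "Large",
                relationship = "Clustered")))
  cg <- reg(cg, "Rim of Brown Globules", group = "Globules Pattern",
    provisional = TRUE, clauses = list(
    shapeClause("globule", color = "Brown",
                relativePosition = "Periphery")))
  cg <- reg(cg, "Globules Irregular", group = "Globules Pattern",
    provisional = TRUE, clauses = list(
    shapeClause("globule", color = "Pigmented", size = "Variable",
                relationship = "Asymmetrical")))

  ## Dots Pattern ---------------------------------------------------------
  cg <- reg(cg, "Dots Regular", group = "Dots Pattern",
    provisional = TRUE, clauses = list(
    shapeClause("dot", color = "Pigmented", relationship = "Distributed")))
  cg <- reg(cg, "Dots Irregular", group = "Dots Pattern",
    provisional = TRUE, clauses = list(
    shapeClause("dot", color = "Pigmented", relationship = "Asymmetrical")))

  ## Shiny White Structures ----------------------------------------------
  polar <- "visible under polarized light dermoscopy"
  cg <- reg(cg, "Shiny White Streaks", group = "Shiny White Structures",
    annotations = polar, provisional = TRUE, clauses = list(
    shapeClause("Line", color = c("White", "Bright White"),
                size = "Small", relationship = "Orthogonal")))
  cg <- reg(cg, "Shiny White Blotches & Strands",
    group = "Shiny White Structures", annotations = polar,
    provisional = TRUE, clauses = list(
    shapeClause("Structureless", color = c("White", "Bright White")),
    shapeClause("Line", color = c("White", "Bright White"))))
  cg <- reg(cg, "Rosettes", group = "Shiny White Structures",
    annotations = polar, clauses = list(
    shapeClause("Circle", color = c("Bright White", "White"),
                size = "Small"),
    spatialPatternClause("SquareFormation")))

  ## ungrouped terms ------------------------------------------------------
  cg <- reg(cg, "Milia-Like Cyst", altLabels = "Milia-Like Cysts",
    annotations = "cloudy or starry appearance", clauses = list(
    shapeClause("Circle", color = c("White", "Yellow"), size = "Small",
                texture = "Shiny")))
  cg <- reg(cg, "Starburst Pattern", altLabels = "Starburst",
    clauses = list(
    subpatternClause("Pseudopods"),
    annotationClause("streak composite radiating at the lesion edge")))
  cg <- reg(cg, "Annular Granular Pattern", bodyPosition = "Face",
    provisional = TRUE,
    annotations = "grey-brown color is an essential property",
    clauses = list(
    shapeClause("dot", color = "Gray Brown", relationship = "Clustered"),
    bodyPositionClause("Face")))
  cg <- reg(cg, "Rainbow Pattern", provisional = TRUE,
    annotations = "detected under polarized light dermoscopy",
    clauses = list(
    shapeClause("Structureless", color = "Variable")))
  cg <- reg(cg, "Ridge Pattern", altLabels = "Parallel Ridge Pattern",
    bodyPosition = "Volar",
    annotations = "follows the skin lines (ridges) of volar skin",
    clauses = list(
    shapeClause("Line", color = "Pigmented", relationship = "Parallel"),
    bodyPositionClause("Volar")))
  cg <- reg(cg, "Blue White Veil", altLabels = "Blue-White Veil",
    provisional = TRUE, clauses = list(
    shapeClause("Structureless", color = "Blue White")))

  validObject(cg)
  cg
}
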