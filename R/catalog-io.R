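#' @include catalog.R
NULL

clauseToList <- function(cl) {
  out <- list(role = cl@role)
  put <- function(key, v) {
    if (length(v) && !all(is.na(v))) out[[key]] <<- v
  }
  put("shape_kind", cl@shapeKind); put("line_style", cl@lineStyle)
  put("color", cl@color); put("size", cl@size); put("texture", cl@texture)
  put("stroke_width", cl@strokeWidth)
  put("relative_position", cl@relativePosition)
  put("relationship", cl@relationship)
  put("predicate", cl@predicate); put("subject", cl@subject)
  put("object", cl@object); put("subpattern", cl@subpattern)
  if (cl@role == "subpattern-reference" && !isTRUE(cl@expand))
    out[["expand"]] <- FALSE
  put("spatial_pattern", cl@spatialPattern)
  put("body_position", cl@bodyPosition); put("note", cl@note)
  out
}

clauseFromList <- function(x, where) {
  if (is.null(x$role))
    dvStop(sprintf("%s: clause without a role", where), "schemaError")
  grab <- function(key, default = NA_character_) {
    v <- x[[key]]
    if (is.null(v)) default else as.character(v)
  }
  tryCatch(switch(x$role,
    "shape-requirement" = shapeClause(
      grab("shape_kind"), color = grab("color", character(0)),
      size = grab("size"), texture = grab("texture"),
      lineStyle = grab("line_style"), strokeWidth = grab("stroke_width"),
      relativePosition = grab("relative_position"),
      relationship = grab("relationship")),
    "relation-assertion" = relationClause(
      grab("subject"), grab("predicate"), grab("object")),
    "subpattern-reference" = subpatternClause(
      grab("subpattern"), expand = !identical(x$expand, FALSE)),
    "spatial-pattern" = spatialPatternClause(grab("spatial_pattern")),
    "body-position" = bodyPositionClause(grab("body_position")),
    "annotation" = annotationClause(grab("note")),
    dvStop(sprintf("%s: unknown clause role '%s'", where, x$role),
           "schemaError")),
    dermvisError = function(e) {
      dvStop(sprintf("%s: %s", where, conditionMessage(e)), "schemaError")
    })
}

definitionToList <- function(d) {
  out <- list(term = d@term)
  if (length(d@altLabels)) out$alt_labels <- d@altLabels
  if (!is.na(d@group)) out$group <- d@group
  out$clauses <- lapply(d@clauses, clauseToList)
  if (!is.na(d@bodyPosition)) out$body_position <- d@bodyPosition
  if (length(d@annotations)) out$annotations <- d@annotations
  if (d@provisional) out$provisional <- TRUE
  out
}

definitionFromList <- function(x, idx) {
  where <- sprintf("document %d%s", idx,
                   if (!is.null(x$term)) sprintf(" (term '%s')", x$term)
                   else "")
  allowed <- c("term", "alt_labels", "group", "clauses", "body_position",
               "annotations", "provisional")
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    dvStop(sprintf("%s: unknown key(s): %s", where,
                   paste(extra, collapse = ", ")), "schemaError")
  if (is.null(x$term) || !nzchar(x$term))
    dvStop(sprintf("%s: missing term", where), "schemaError")
  if (is.null(x$clauses) || !length(x$clauses))
    dvStop(sprintf("%s: clauses must be non-empty", where), "schemaError")
  clauses <- lapply(seq_along(x$clauses), function(i) {
    clauseFromList(x$clauses[[i]], sprintf("%s, clause %d", where, i))
  })
  patternDefinition(
    term = x$term, clauses = clauses,
    altLabels = as.character(x$alt_labels %||% character(0)),
    group = x$group %||% NA,
    bodyPosition = x$body_position %||% NA,
    annotations = as.character(x$annotations %||% character(0)),
    provisional = isTRUE(x$provisional))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a catalog to a structured text file
#'
#' One document per term with keys
#' `term/alt_labels/group/clauses/body_position/annotations`; the group
#' list is written alongside. JSON or YAML, chosen by file extension.
#'
#' @param catalog a [Catalog].
#' @param path output file ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  doc <- list(
    groups = names(catalog@groups),
    patterns = lapply(catalog@definitions, definitionToList))
  names(doc$patterns) <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' Read a catalog from a structured text file
#'
#' Strict schema validation: unknown keys, missing terms, empty clause
#' lists, unlicensed fields and out-of-vocabulary values all raise errors
#' naming the offending document and clause.
#'
#' @param path catalog file (JSON or YAML).
#' @return a validated [Catalog].
#' @export
readCatalog <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  cg <- emptyCatalog()
  for (g in unlist(doc$groups)) cg <- registerGroup(cg, g)
  pats <- doc$patterns %||% list()
  for (i in seq_along(pats)) {
    x <- pats[[i]]
    # scalar fields may arrive as length-1 lists from JSON
    x <- lapply(x, function(v) if (is.list(v) && !is.null(names(v))) v else v)
    if (is.list(x$alt_labels)) x$alt_labels <- unlist(x$alt_labels)
    if (is.list(x$annotations)) x$annotations <- unlist(x$annotations)
    cg <- registerPattern(cg, definitionFromList(x, i))
  }
  validObject(cg)
  cg
}

#' Validate the internal consistency of a catalog
#'
#' Checks that every clause references vocabulary defined by the model
#' (shape kinds, colors of the shipped palette, sizes, textures,
#' relationships, predicates, positions) and that every sub-pattern
#' reference and relation subject/object resolves. Returns a character
#' vector of problems; empty means the catalog validates with zero
#' dangling identifiers.
#'
#' @param catalog a [Catalog].
#' @param palette named color list, defaults to the shipped palette.
#' @return character vector of problem descriptions (empty if valid).
#' @export
validateCatalog <- function(catalog, palette = loadPalette()) {
  problems <- character(0)
  colorNames <- foldTerm(names(palette))
  for (key in names(catalog@definitions)) {
    d <- catalog@definitions[[key]]
    shapesSeen <- character(0)
    for (cl in d@clauses) {
      if (cl@role == "shape-requirement") {
        shapesSeen <- c(shapesSeen, cl@shapeKind)
        bad <- setdiff(foldTerm(cl@color), colorNames)
        if (length(bad))
          problems <- c(problems, sprintf("%s: unknown color(s) %s",
                                          d@term, paste(bad, collapse = ", ")))
      } else if (cl@role == "subpattern-reference") {
        ok <- tryCatch({resolveTerm(catalog, cl@subpattern); TRUE},
                       dermvisError = function(e) FALSE)
        if (!ok) problems <- c(problems,
          sprintf("%s: dangling subpattern reference '%s'", d@term,
                  cl@subpattern))
      }
    }
    for (cl in d@clauses) {
      if (cl@role == "relation-assertion") {
        for (part in c(cl@subject, cl@object)) {
          if (!foldTerm(part) %in% foldTerm(shapesSeen))
            problems <- c(problems, sprintf(
              "%s: relation part '%s' does not match any shape clause",
              d@term, part))
        }
      }
    }
  }
  problems
}
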