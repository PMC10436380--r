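#' @include catalog.R vocab.R
NULL

.queryCategories <- c("shape", "color", "size", "texture", "relationship",
                      "relativePosition", "bodyPosition", "spatialPattern")

#' Build a validated feature query
#'
#' A conjunction of (category, value) constraints over the catalog
#' vocabularies; an empty query matches every term. In `subsumes` match
#' mode (the default) abstract colors cover concrete ones (Dark covers
#' Black), the generic Polygon covers named subkinds, and shape aliases
#' fold ("dot" queries a small circle).
#'
#' @param shape,color,size,texture,relationship,relativePosition,bodyPosition,spatialPattern
#'   optional constraint values.
#' @param match `"subsumes"` or `"exact"`.
#' @return a `featureQuery` list.
#' @export
featureQuery <- function(shape = NULL, color = NULL, size = NULL,
                         texture = NULL, relationship = NULL,
                         relativePosition = NULL, bodyPosition = NULL,
                         spatialPattern = NULL,
                         match = c("subsumes", "exact")) {
  match <- match.arg(match)
  q <- list(shape = shape, color = color, size = size, texture = texture,
            relationship = relationship,
            relativePosition = relativePosition,
            bodyPosition = bodyPosition, spatialPattern = spatialPattern)
  q <- q[!vapply(q, is.null, logical(1))]
  vocabOf <- list(
    shape = c(shapeKinds(), polygonKinds(), names(.shapeAliases)),
    color = c(names(loadPalette()), "Bright White"),
    size = sizeValues(), texture = textureValues(),
    relationship = relationshipValues(),
    relativePosition = relativePositionValues(),
    bodyPosition = bodyPositionValues(),
    spatialPattern = spatialPatternValues())
  for (cat in names(q)) {
    vv <- vocabOf[[cat]]
    if (!foldTerm(q[[cat]]) %in% foldTerm(vv)) {
      sugg <- nearestLabels(q[[cat]], vv)
      dvStop(sprintf("unknown %s value '%s'; did you mean: %s", cat,
                     q[[cat]], paste(sugg, collapse = ", ")),
             "vocabularyError")
    }
  }
  structure(list(constraints = q, match = match), class = "featureQuery")
}

# does one shape clause satisfy the shape-attribute part of the query?
clauseSatisfies <- function(cl, q, subsumes) {
  cs <- q$constraints
  shapeOK <- function(want) {
    alias <- shapeAlias(want)
    wantKind <- if (!is.null(alias)) alias$shapeKind else want
    if (foldTerm(cl@shapeKind) == foldTerm(wantKind)) {
      if (!is.null(alias) && !is.na(alias$size))
        return(identical(cl@size, alias$size))
      return(TRUE)
    }
    if (subsumes && foldTerm(wantKind) == "polygon" &&
        foldTerm(cl@shapeKind) %in% foldTerm(polygonKinds()))
      return(TRUE)
    FALSE
  }
  if (!is.null(cs$shape) && !(cl@role == "shape-requirement" &&
                              shapeOK(cs$shape))) return(FALSE)
  if (!is.null(cs$color)) {
    vals <- cl@color
    hit <- if (subsumes) any(vapply(vals, function(v)
      colorSubsumes(cs$color, v), logical(1)))
      else any(foldTerm(vals) == foldTerm(cs$color))
    if (!hit) return(FALSE)
  }
  if (!is.null(cs$size) &&
      !identical(foldTerm(cl@size), foldTerm(cs$size))) return(FALSE)
  if (!is.null(cs$texture) &&
      !identical(foldTerm(cl@texture), foldTerm(cs$texture))) return(FALSE)
  if (!is.null(cs$relationship) &&
      !identical(foldTerm(cl@relationship),
                 foldTerm(cs$relationship))) return(FALSE)
  if (!is.null(cs$relativePosition) &&
      !identical(foldTerm(cl@relativePosition),
                 foldTerm(cs$relativePosition))) return(FALSE)
  TRUE
}

termMatch <- function(catalog, term, q) {
  clauses <- decomposeTerm(catalog, term)
  d <- resolveTerm(catalog, term)
  cs <- q$constraints
  subsumes <- q$match == "subsumes"
  shapeCats <- intersect(names(cs), c("shape", "color", "size", "texture",
                                      "relationship", "relativePosition"))
  shapeClauses <- Filter(function(cl) cl@role == "shape-requirement",
                         clauses)
  matched <- Filter(function(cl) clauseSatisfies(cl, q, subsumes),
                    shapeClauses)
  if (length(shapeCats) && !length(matched)) return(NULL)
  if (!is.null(cs$bodyPosition)) {
    bps <- c(d@bodyPosition,
             vapply(clauses, function(cl) cl@bodyPosition, character(1)))
    if (!foldTerm(cs$bodyPosition) %in% foldTerm(stats::na.omit(bps)))
      return(NULL)
  }
  if (!is.null(cs$spatialPattern)) {
    sps <- vapply(clauses, function(cl) cl@spatialPattern, character(1))
    if (!foldTerm(cs$spatialPattern) %in% foldTerm(stats::na.omit(sps)))
      return(NULL)
  }
  n <- if (length(shapeCats)) length(matched)
       else length(clauses)
  list(term = d@term, matched = if (length(shapeCats)) matched else clauses,
       count = n)
}

#' Find catalog patterns matching a feature query
#'
#' A term matches when its (expanded) clause set satisfies every
#' constraint; the shape-attribute constraints (shape, color, size,
#' texture, relationship, relative position) must be satisfied jointly by
#' a single shape clause — a query for dark circles is met by a
#' dark-colored circle clause, not by a dark line plus a white circle.
#' Results are ordered by matched-clause count (descending), then term
#' (ascending); the ordering and the match set are deterministic.
#'
#' @param catalog a [Catalog].
#' @param query a [featureQuery()].
#' @return data.frame with columns `term` and `matches`, plus a
#'   `matchedClauses` list column.
#' @examples
#' cat <- dermoscopyCatalog()
#' findPatterns(cat, featureQuery(shape = "Circle", color = "Dark"))$term
#' @export
findPatterns <- function(catalog, query = featureQuery()) {
  hits <- list()
  for (term in catalogTerms(catalog)) {
    h <- termMatch(catalog, term, query)
    if (!is.null(h)) hits[[length(hits) + 1]] <- h
  }
  if (!length(hits))
    return(data.frame(term = character(0), matches = integer(0)))
  terms <- vapply(hits, `[[`, character(1), "term")
  counts <- vapply(hits, `[[`, numeric(1), "count")
  ord <- order(-counts, terms, method = "radix")
  out <- data.frame(term = terms[ord], matches = as.integer(counts[ord]),
                    stringsAsFactors = FALSE)
  out$matchedClauses <- lapply(hits[ord], `[[`, "matched")
  out
}

#' List the features of one registered term
#'
#' The inverse of querying: a complete, deterministic listing of the
#' term's clause features by category (including spatial patterns and
#' pairwise predicates).
#'
#' @param catalog a [Catalog].
#' @param term registered term or alternative label.
#' @return named list of sorted unique values per category.
#' @export
featuresOf <- function(catalog, term) {
  d <- resolveTerm(catalog, term)
  clauses <- decomposeTerm(catalog, d@term)
  pull <- function(f) {
    v <- unlist(lapply(clauses, function(cl) slot(cl, f)))
    sort(unique(v[!is.na(v)]), method = "radix")
  }
  bps <- c(pull("bodyPosition"),
           if (!is.na(d@bodyPosition)) d@bodyPosition)
  list(shape = pull("shapeKind"), color = pull("color"),
       size = pull("size"), texture = pull("texture"),
       relationship = pull("relationship"),
       relativePosition = pull("relativePosition"),
       bodyPosition = sort(unique(bps), method = "radix"),
       spatialPattern = pull("spatialPattern"),
       predicate = pull("predicate"))
}

#' Parse a free-text feature query
#'
#' A fixed grammar, not natural-language processing: one or more color
#' adjectives followed by a shape noun, with plural folding ("dark
#' circles" or "white lines"). Anything else raises a
#' structured-query-required error.
#'
#' @param text query text.
#' @param match match mode passed to [featureQuery()].
#' @return a [featureQuery()].
#' @examples
#' parseFeatureQuery("dark circles")$constraints
#' @export
parseFeatureQuery <- function(text, match = "subsumes") {
  tokens <- strsplit(foldTerm(text), "\\s+")[[1]]
  if (!length(tokens))
    dvStop("empty query: a structured query is required",
           "queryParseError")
  noun <- sub("s$", "", tokens[length(tokens)])
  shapeVocab <- foldTerm(c(shapeKinds(), polygonKinds(),
                           names(.shapeAliases)))
  if (!noun %in% shapeVocab)
    dvStop(sprintf(
      "cannot parse '%s': expected [color] shape-noun; use featureQuery()",
      text), "queryParseError")
  colorTokens <- tokens[-length(tokens)]
  color <- NULL
  if (length(colorTokens)) {
    cand <- paste(colorTokens, collapse = " ")
    vocab <- c(names(loadPalette()), names(.colorHierarchy))
    hit <- vocab[match(foldTerm(cand), foldTerm(vocab))]
    if (is.na(hit))
      dvStop(sprintf(
        "cannot parse color '%s'; use featureQuery()", cand),
        "queryParseError")
    color <- hit
  }
  featureQuery(shape = noun, color = color, match = match)
}

#' Brute-force query oracle
#'
#' Independent check of [findPatterns()] for single-constraint queries: an
#' exhaustive flat scan over every term's expanded clauses with its own
#' inline per-category tests (no shared matcher code), returning the
#' matching terms sorted. The engine must agree with it on every
#' single-constraint query over every vocabulary value.
#'
#' @param catalog a [Catalog].
#' @param query a single-constraint [featureQuery()].
#' @return sorted character vector of matching terms.
#' @export
bruteForceFind <- function(catalog, query) {
  cs <- query$constraints
  if (length(cs) != 1)
    dvStop("the brute-force oracle handles single-constraint queries",
           "queryParseError")
  cat_ <- names(cs); val <- cs[[1]]
  subsumes <- query$match == "subsumes"
  out <- character(0)
  for (term in catalogTerms(catalog)) {
    d <- resolveTerm(catalog, term)
    hit <- FALSE
    for (cl in decomposeTerm(catalog, term)) {
      hit <- hit || switch(cat_,
        shape = {
          al <- shapeAlias(val)
          wk <- if (!is.null(al)) al$shapeKind else val
          ok <- !is.na(cl@shapeKind) &&
            tolower(cl@shapeKind) == tolower(wk)
          if (ok && !is.null(al) && !is.na(al$size))
            ok <- identical(cl@size, al$size)
          if (!ok && subsumes && tolower(wk) == "polygon")
            ok <- !is.na(cl@shapeKind) &&
              tolower(cl@shapeKind) %in% tolower(polygonKinds())
          ok
        },
        color = length(cl@color) > 0 && any(vapply(cl@color, function(v) {
          if (subsumes) colorSubsumes(val, v)
          else tolower(v) == tolower(val)
        }, logical(1))),
        size = !is.na(cl@size) && tolower(cl@size) == tolower(val),
        texture = !is.na(cl@texture) &&
          tolower(cl@texture) == tolower(val),
        relationship = !is.na(cl@relationship) &&
          tolower(cl@relationship) == tolower(val),
        relativePosition = !is.na(cl@relativePosition) &&
          tolower(cl@relativePosition) == tolower(val),
        bodyPosition = !is.na(cl@bodyPosition) &&
          tolower(cl@bodyPosition) == tolower(val),
        spatialPattern = !is.na(cl@spatialPattern) &&
          tolower(cl@spatialPattern) == tolower(val),
        FALSE)
    }
    if (cat_ == "bodyPosition" && !is.na(d@bodyPosition) &&
        tolower(d@bodyPosition) == tolower(val)) hit <- TRUE
    if (hit) out <- c(out, d@term)
  }
  sort(out, method = "radix")
}
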