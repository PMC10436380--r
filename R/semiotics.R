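#' @include owl.R
NULL

#' Inventory of OWL2 construct kinds used by the richness score
#'
#' A fixed 16-kind inventory of axiom/construct kinds; richness is the
#' fraction of the inventory an ontology exercises.
#'
#' @return character vector of 16 construct kinds.
#' @export
owlConstructInventory <- function() {
  c("SubClassOf", "EquivalentClasses", "DisjointClasses",
    "ObjectSomeValuesFrom", "ObjectAllValuesFrom",
    "ObjectExactCardinality", "ObjectMaxCardinality",
    "ObjectMinCardinality", "InverseObjectProperties",
    "FunctionalObjectProperty", "SubObjectPropertyOf",
    "ObjectPropertyDomain", "ObjectPropertyRange", "DataPropertyDomain",
    "DataPropertyRange", "AnnotationAssertion")
}

#' Richness: diversity of OWL2 expression use
#'
#' @param model an [OntologyModel].
#' @param inventory construct-kind inventory (non-empty).
#' @return proportion in \[0, 1\] of inventory kinds used; SKOS labels
#'   count as annotation assertions.
#' @export
richness <- function(model, inventory = owlConstructInventory()) {
  stopifnot(length(inventory) > 0)
  used <- unique(model@axioms$kind)
  if (nrow(model@entities)) used <- c(used, "AnnotationAssertion")
  length(intersect(used, inventory)) / length(inventory)
}

#' Lawfulness: syntactic correctness rate
#'
#' One minus the rate of violations among parsed statements (axioms plus
#' declarations): a cleanly parsed, structurally consistent document
#' scores 1, and an empty document scores 1 by convention (no statements,
#' no violations).
#'
#' @param model an [OntologyModel], or a path/text parseable by
#'   [importOWL()].
#' @param violations optional violation count; defaults to the findings of
#'   [structuralViolations()].
#' @return score in \[0, 1\].
#' @export
lawfulness <- function(model, violations = NULL) {
  if (!is(model, "OntologyModel")) model <- importOWL(model)
  total <- nrow(model@axioms) + nrow(model@entities)
  if (total == 0) return(1)
  if (is.null(violations)) violations <- length(structuralViolations(model))
  1 - min(violations, total) / total
}

#' Comprehensiveness: relative domain coverage
#'
#' Element count (classes, object and data properties, individuals) of the
#' ontology divided by the largest element count in the comparison corpus
#' (including the ontology itself), so the largest ontology scores 1.
#'
#' @param model an [OntologyModel] or its element count.
#' @param corpus list of [OntologyModel]s or numeric element counts
#'   (non-empty).
#' @return score in (0, 1\].
#' @export
comprehensiveness <- function(model, corpus) {
  stopifnot(length(corpus) > 0)
  count <- function(x) {
    if (is(x, "OntologyModel")) {
      sum(entityCounts(x)) + sum(x@entities$type == "individual")
    } else as.numeric(x)
  }
  n <- count(model)
  n / max(c(n, vapply(corpus, count, numeric(1))))
}

.leafNames <- c("richness", "lawfulness", "clarity", "consistency",
                "interpretability", "comprehensiveness")

#' Aggregate leaf metrics into semiotic composite scores
#'
#' Syntactic = weighted mean of richness and lawfulness; semantic =
#' weighted mean of clarity, consistency and interpretability; pragmatic =
#' comprehensiveness; overall = weighted mean of the three composites.
#' Weights default to uniform within each composite. The semantic leaves
#' (clarity, consistency, interpretability) require an external
#' word-sense inventory and are accepted as supplied values; see
#' [readLeafScores()].
#'
#' @param leaf named numeric vector (or 1-row data.frame) with entries
#'   from `r paste(.leafNames, collapse = ", ")`; each in \[0, 1\].
#' @param weights optional named list with numeric vectors `syntactic`
#'   (2), `semantic` (3) and `overall` (3); normalized internally.
#' @return named numeric vector with `syntactic`, `semantic`, `pragmatic`,
#'   `overall`.
#' @examples
#' aggregateScores(c(richness = 0.564, lawfulness = 1, clarity = 0.988,
#'                   consistency = 1, interpretability = 0.964,
#'                   comprehensiveness = 0.02))
#' @export
aggregateScores <- function(leaf, weights = NULL) {
  if (is.data.frame(leaf)) leaf <- unlist(leaf[1, , drop = TRUE])
  need <- function(names) {
    missing <- setdiff(names, names(leaf)[!is.na(leaf[names(leaf)])])
    missing <- missing[!missing %in% names(leaf) | is.na(leaf[missing])]
    if (length(missing))
      dvStop(sprintf("missing leaf score(s): %s",
                     paste(missing, collapse = ", ")), "missingLeafError")
    leaf[names]
  }
  wmean <- function(x, w) {
    if (is.null(w)) w <- rep(1, length(x))
    if (any(w < 0)) dvStop("weights must be non-negative", "weightError")
    sum(x * w) / sum(w)
  }
  syntactic <- wmean(need(c("richness", "lawfulness")),
                     weights$syntactic)
  semantic <- wmean(need(c("clarity", "consistency", "interpretability")),
                    weights$semantic)
  pragmatic <- unname(need("comprehensiveness"))
  overall <- wmean(c(syntactic, semantic, pragmatic), weights$overall)
  c(syntactic = unname(syntactic), semantic = unname(semantic),
    pragmatic = pragmatic, overall = unname(overall))
}

#' Cross-ontology z-scores
#'
#' Standardizes a metric across ontologies: `(x - mean(x)) / sd(x)` with
#' the sample (n - 1) standard deviation. At least two values are needed
#' and zero variance is an error.
#'
#' @param values named numeric vector of per-ontology scores.
#' @return named numeric vector of z-scores (sums to 0).
#' @examples
#' zScores(c(DEVO = 0.597, DL = 0.436, HDDO = 0.53, SPO = 0.516))
#' @export
zScores <- function(values) {
  if (length(values) < 2)
    dvStop("need at least two values to standardize", "zscoreError")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    dvStop("zero variance: z-scores undefined", "zscoreError")
  (values - mean(values)) / s
}

#' Read a leaf-score table
#'
#' CSV with one `ontology` column and one column per leaf metric
#' (`r paste(.leafNames, collapse = ", ")`). The shipped table
#' `semiotic_leaf_scores.csv` holds the published leaf scores of a
#' four-ontology dermatology comparison (DEVO, DL, HDDO, SPO);
#' `semiotic_composite_scores.csv` holds the corresponding published
#' composite rows.
#'
#' @param path CSV path; default is the shipped leaf table.
#' @return data.frame with ontologies as row names.
#' @export
readLeafScores <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "semiotic_leaf_scores.csv",
                        package = "dermvis")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  rownames(tab) <- tab$ontology
  tab$ontology <- NULL
  tab
}

#' @rdname readLeafScores
#' @export
readCompositeScores <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "semiotic_composite_scores.csv",
                        package = "dermvis")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  rownames(tab) <- tab$metric
  tab$metric <- NULL
  tab
}

#' Semiotic score report across ontologies
#'
#' Aggregates a leaf table row-wise and attaches cross-ontology z-scores
#' for every leaf and composite metric.
#'
#' @param leaves data.frame as returned by [readLeafScores()].
#' @param weights optional weights passed to [aggregateScores()].
#' @param digits display rounding (half-to-even); raw values are kept in
#'   the returned object.
#' @return list with `scores` (metrics x ontologies), `z` (same shape) and
#'   `display` (rounded character table).
#' @export
scoreReport <- function(leaves, weights = NULL, digits = 3) {
  comps <- vapply(rownames(leaves), function(o) {
    aggregateScores(unlist(leaves[o, ]), weights)
  }, numeric(4))
  scores <- rbind(t(as.matrix(leaves)), comps)
  z <- t(apply(scores, 1, function(v) {
    tryCatch(zScores(v), dermvisError = function(e) rep(NA_real_,
                                                        length(v)))
  }))
  display <- matrix(sprintf("%.*f", digits, roundHalfEven(scores, digits)),
                    nrow = nrow(scores), dimnames = dimnames(scores))
  list(scores = scores, z = z, display = display)
}
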