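#' @include owl.R
NULL

# axiom kinds the verbalizer supports
.verbalizableKinds <- c("SubClassOf", "ObjectExactCardinality",
                        "ObjectMaxCardinality", "ObjectSomeValuesFrom",
                        "DataPropertyRange")

propertyWords <- function(property) {
  labelWords(sub("^has", "", property))
}

#' Verbalize one axiom as an English review statement
#'
#' Deterministic sentence templates over entity labels (lower-cased inside
#' the sentence): a subclass axiom becomes "every X is a Y", an exact
#' cardinality "every X is something that has exactly N P", a max
#' cardinality the "at most" variant, an existential restriction "every X
#' is something that has P some Y", and a data-property range "the P of
#' something is a T value". Identical axioms always produce identical
#' sentences.
#'
#' @param axiom one-row data.frame or list with fields `kind`, `subject`,
#'   `property`, `object`, `value` (as in the model's axiom table).
#' @return list with `sentence`, `template` and the `axiom` reference.
#' @examples
#' verbalize(list(kind = "SubClassOf", subject = "Ellipse",
#'                object = "Shape"))$sentence
#' @export
verbalize <- function(axiom) {
  axiom <- as.list(axiom)
  kind <- axiom$kind
  if (is.null(kind) || !kind %in% .verbalizableKinds)
    dvStop(sprintf(
      "cannot verbalize axiom kind '%s' (supported: %s)",
      if (is.null(kind)) "<missing>" else kind,
      paste(.verbalizableKinds, collapse = ", ")), "verbalizeError")
  s <- labelWords(axiom$subject)
  sentence <- switch(kind,
    SubClassOf = sprintf("every %s is a %s", s, labelWords(axiom$object)),
    ObjectExactCardinality = sprintf(
      "every %s is something that has exactly %d %s", s, axiom$value,
      propertyWords(axiom$property)),
    ObjectMaxCardinality = sprintf(
      "every %s is something that has at most %d %s", s, axiom$value,
      propertyWords(axiom$property)),
    ObjectSomeValuesFrom = sprintf(
      "every %s is something that has %s some %s", s,
      propertyWords(axiom$property), labelWords(axiom$object)),
    DataPropertyRange = sprintf(
      "the %s of something is a %s value", labelWords(axiom$subject),
      if (axiom$object %in% c("integer", "decimal", "float",
                              "nonNegativeInteger"))
        "numerical" else axiom$object))
  list(sentence = sentence, template = kind, axiom = axiom)
}

#' Verbalize all supported axioms of a model
#'
#' @param model an [OntologyModel].
#' @return data.frame with columns `id`, `kind`, `subject`, `sentence`, in
#'   canonical axiom order.
#' @export
verbalizeOntology <- function(model) {
  ax <- canonicalAxioms(model@axioms)
  ax <- ax[ax$kind %in% .verbalizableKinds, , drop = FALSE]
  sentences <- vapply(seq_len(nrow(ax)), function(i) {
    verbalize(ax[i, ])$sentence
  }, character(1))
  data.frame(id = sprintf("S%03d", seq_len(nrow(ax))), kind = ax$kind,
             subject = ax$subject, sentence = sentences,
             stringsAsFactors = FALSE)
}

#' Construct a rating matrix
#' @param ratings character matrix of Y/N/X cells (statements x raters).
#' @param statements,raters row and column labels; default from dimnames.
#' @return a [RatingMatrix].
#' @export
ratingMatrix <- function(ratings,
                         statements = rownames(ratings),
                         raters = colnames(ratings)) {
  if (is.null(statements)) statements <- sprintf("S%03d", seq_len(nrow(ratings)))
  if (is.null(raters)) raters <- sprintf("R%d", seq_len(ncol(ratings)))
  new("RatingMatrix", ratings = unname(ratings),
      statements = statements, raters = raters)
}

#' Recode review answers numerically
#'
#' "Y" (agreement) recodes to 1; "N" (disagreement) and "X" (not sure)
#' both recode to 0 — an unclear axiom counts as a negative.
#'
#' @param cell character vector with values in {Y, N, X}.
#' @return integer vector of 0/1.
#' @examples
#' recodeRating(c("Y", "N", "X"))
#' @export
recodeRating <- function(cell) {
  bad <- setdiff(unique(cell), c("Y", "N", "X"))
  if (length(bad))
    dvStop(sprintf("invalid rating value(s): %s",
                   paste(bad, collapse = ", ")), "ratingError")
  as.integer(cell == "Y")
}

#' Rater-agreement statistics
#'
#' After recoding, computes the proportion of 1s per rater, the unweighted
#' mean of those proportions (the mean agreement with the encoded domain
#' knowledge), and the pairwise percent agreement: the mean over rater
#' pairs of the fraction of statements on which both raters give the same
#' value. Pairwise agreement can be computed on recoded values (default,
#' where N and X coincide) or on the raw Y/N/X symbols.
#'
#' @param m a [RatingMatrix].
#' @param pairwiseOn `"recoded"` or `"raw"`.
#' @return list with `perRater` (named numeric), `meanAgreement`,
#'   `pairwiseAgreement` (in \[0, 1\]).
#' @export
agreementStats <- function(m, pairwiseOn = c("recoded", "raw")) {
  pairwiseOn <- match.arg(pairwiseOn)
  stopifnot(is(m, "RatingMatrix"))
  r <- m@ratings
  if (!nrow(r) || ncol(r) < 2)
    dvStop("need at least one statement and two raters", "ratingError")
  rec <- matrix(recodeRating(as.vector(r)), nrow = nrow(r))
  perRater <- colMeans(rec)
  names(perRater) <- m@raters
  cmp <- if (pairwiseOn == "recoded") rec else r
  pairs <- utils::combn(ncol(r), 2)
  pw <- mean(apply(pairs, 2, function(p) {
    mean(cmp[, p[1]] == cmp[, p[2]])
  }))
  list(perRater = perRater, meanAgreement = mean(perRater),
       pairwiseAgreement = pw)
}

#' Statements contested by the raters
#'
#' Returns the statements whose recoded-zero count (N or X answers)
#' reaches the threshold, in input order.
#'
#' @param m a [RatingMatrix].
#' @param threshold minimum number of 0s (>= 1).
#' @return character vector of statement ids.
#' @export
contestedStatements <- function(m, threshold = 2) {
  stopifnot(threshold >= 1)
  rec <- matrix(recodeRating(as.vector(m@ratings)), nrow = nrow(m@ratings))
  zeros <- rowSums(rec == 0L)
  m@statements[zeros >= threshold]
}

#' Deterministic rating matrix with given per-rater proportions
#'
#' Builds an n-statement matrix in which rater j answers "Y" on the first
#' `round(p_j * n)` statements (interleaved with "N"/"X" so disagreements
#' are spread), giving exactly the requested per-rater proportions when
#' `p_j * n` is integral. Used to reconstruct agreement arithmetic from
#' reported per-rater values.
#'
#' @param proportions per-rater proportions of "Y".
#' @param nStatements number of statements.
#' @param raters rater labels.
#' @return a [RatingMatrix].
#' @export
ratingMatrixFromProportions <- function(proportions, nStatements = 100,
                                        raters = sprintf(
                                          "R%d", seq_along(proportions))) {
  cells <- vapply(proportions, function(p) {
    k <- round(p * nStatements)
    v <- rep("N", nStatements)
    if (k > 0) v[round(seq(1, nStatements, length.out = k))] <- "Y"
    # some negatives are "not sure" rather than "no"
    nn <- which(v == "N")
    if (length(nn) > 1) v[nn[seq(1, length(nn), by = 2)]] <- "X"
    v
  }, character(nStatements))
  ratingMatrix(cells, raters = raters)
}

#' Read/write rating matrices and review sheets as CSV
#'
#' The CSV layout has one `statement` column (optionally `sentence`)
#' followed by one column per rater. `writeReviewSheet` exports the
#' statements with empty rater columns for independent review.
#'
#' @param path CSV file.
#' @return `readRatingMatrix` returns a [RatingMatrix].
#' @export
readRatingMatrix <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  idCols <- intersect(c("statement", "sentence"), names(tab))
  raters <- setdiff(names(tab), idCols)
  m <- as.matrix(tab[raters])
  rownames(m) <- if ("statement" %in% names(tab)) tab$statement
                 else sprintf("S%03d", seq_len(nrow(tab)))
  ratingMatrix(m, statements = rownames(m), raters = raters)
}

#' @rdname readRatingMatrix
#' @param statements data.frame from [verbalizeOntology()].
#' @param raters rater labels for the empty review columns.
#' @export
writeReviewSheet <- function(statements, path,
                             raters = c("R1", "R2", "R3")) {
  sheet <- statements[c("id", "sentence")]
  names(sheet)[1] <- "statement"
  for (r in raters) sheet[[r]] <- ""
  utils::write.csv(sheet, path, row.names = FALSE)
  invisible(path)
}

#' Percentage of reviewed items flagged
#'
#' Expert-review bookkeeping: the share (in percent, rounded half-to-even)
#' of reviewed definitions an annotator flagged, e.g. 12 of 48 reviewed
#' terms is 25%.
#'
#' @param count items flagged.
#' @param total items reviewed.
#' @param digits decimal places for rounding.
#' @return percentage on the 0-100 scale.
#' @export
reviewPercent <- function(count, total, digits = 1) {
  stopifnot(total > 0, count >= 0, count <= total)
  roundHalfEven(100 * count / total, digits)
}

setMethod("show", "RatingMatrix", function(object) {
  cat(sprintf("RatingMatrix: %d statement(s) x %d rater(s)\n",
              length(object@statements), length(object@raters)))
})
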