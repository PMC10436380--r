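#' Round half to even at a decimal precision
#'
#' Decimal round-half-to-even ("banker's rounding") with a tolerance guard so
#' that exact decimal ties are recognised even when floating-point
#' representation places them a few ulp off the tie point. Used for display
#' rounding of composite quality scores; raw values are always retained
#' unrounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @param tol tie-detection tolerance on the scaled value.
#' @return numeric vector rounded at `digits` places.
#' @examples
#' roundHalfEven((0.385 + 1) / 2, 3)  # 0.692, not 0.693
#' @export
roundHalfEven <- function(x, digits = 3, tol = 1e-8) {
  scale <- 10^digits
  y <- x * scale
  lo <- floor(y)
  frac <- y - lo
  tie <- abs(frac - 0.5) < tol
  out <- round(y)
  # on a decimal tie, take the even neighbour
  out[tie] <- ifelse(lo[tie] %% 2 == 0, lo[tie], lo[tie] + 1)
  out / scale
}

#' Split a CamelCase label into lower-case words
#'
#' "BeginningPoint" becomes "beginning point". Used by the axiom verbalizer,
#' whose sentence templates use lower-case entity labels.
#'
#' @param x character vector of CamelCase labels.
#' @return character vector of space-separated lower-case words.
#' @export
labelWords <- function(x) {
  out <- gsub("([a-z0-9])([A-Z])", "\\1 \\2", x)
  out <- gsub("([A-Z]+)([A-Z][a-z])", "\\1 \\2", out)
  tolower(gsub("[_-]+", " ", out))
}

#' Convert a label to a CamelCase IRI fragment
#'
#' "Blue White" becomes "BlueWhite"; punctuation is dropped. All entity IRIs
#' are `<base>#<CamelCaseLabel>`.
#'
#' @param x character vector of labels.
#' @return character vector of CamelCase fragments.
#' @export
camelFragment <- function(x) {
  x <- gsub("[&]", " And ", x)
  x <- gsub("[^A-Za-z0-9 ]+", " ", x)
  vapply(strsplit(trimws(x), "\\s+"), function(w) {
    paste0(toupper(substring(w, 1, 1)), substring(w, 2), collapse = "")
  }, character(1))
}

# case-folded key used for term lookup
foldTerm <- function(x) tolower(trimws(x))

# stop() with a consistent error class so tests can assert on condition class
dvStop <- function(msg, class) {
  stop(structure(
    class = c(class, "dermvisError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# deterministic RNG scope: runs expr under a local seed without disturbing
# the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# nearest-label suggestions for error messages
nearestLabels <- function(x, candidates, n = 3) {
  if (!length(candidates)) return(character(0))
  d <- utils::adist(foldTerm(x), foldTerm(candidates))
  candidates[order(d)][seq_len(min(n, length(candidates)))]
}
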