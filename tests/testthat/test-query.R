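shipped <- dermoscopyCatalog()

test_that("the empty query matches every registered term", {
  hits <- findPatterns(shipped, featureQuery())
  expect_setequal(hits$term, catalogTerms(shipped))
})

test_that("dark circles and white lines find the documented terms", {
  dark <- findPatterns(shipped, featureQuery(shape = "Circle",
                                             color = "Dark"))
  expect_true(all(c("Annular Granular Pattern", "Rim of Brown Globules")
                  %in% dark$term))
  white <- findPatterns(shipped, featureQuery(shape = "Line",
                                              color = "White"))
  expect_true("Shiny White Streaks" %in% white$term)
  # exact mode does not walk the color hierarchy
  exact <- findPatterns(shipped, featureQuery(shape = "Circle",
                                              color = "Dark",
                                              match = "exact"))
  expect_false("Rim of Brown Globules" %in% exact$term)
})

test_that("shape-attribute constraints must hold on a single clause", {
  # pigment network has hypopigmented circles and pigmented lines;
  # a pigmented circle query must not match it
  hits <- findPatterns(shipped, featureQuery(shape = "Circle",
                                             color = "Pigmented"))
  expect_false("Pigment Network" %in% hits$term)
  expect_true("Globules Regular" %in% hits$term)
})

test_that("results are deterministically ordered", {
  q <- featureQuery(shape = "Circle")
  h1 <- findPatterns(shipped, q)
  h2 <- findPatterns(shipped, q)
  expect_identical(h1$term, h2$term)
  expect_true(all(diff(h1$matches) <= 0))
})

test_that("the engine agrees with the brute-force oracle on every
          single-constraint query", {
  vocabOf <- list(
    shape = c(shapeKinds(), polygonKinds(), "dot", "globule"),
    color = names(loadPalette()),
    size = sizeValues(), texture = textureValues(),
    relationship = relationshipValues(),
    relativePosition = relativePositionValues(),
    bodyPosition = bodyPositionValues(),
    spatialPattern = spatialPatternValues())
  for (cat_ in names(vocabOf)) {
    for (val in vocabOf[[cat_]]) {
      q <- do.call(featureQuery, stats::setNames(list(val), cat_))
      mine <- sort(findPatterns(shipped, q)$term, method = "radix")
      oracle <- bruteForceFind(shipped, q)
      expect_identical(mine, oracle, info = paste(cat_, val))
    }
  }
})

test_that("adding a constraint never enlarges the result set", {
  base <- findPatterns(shipped, featureQuery(shape = "Circle"))$term
  for (extra in list(featureQuery(shape = "Circle", color = "Pigmented"),
                     featureQuery(shape = "Circle", size = "Small"),
                     featureQuery(shape = "Circle",
                                  relativePosition = "Periphery"))) {
    narrowed <- findPatterns(shipped, extra)$term
    expect_true(all(narrowed %in% base))
  }
})

test_that("featuresOf lists a term's features completely", {
  ps <- featuresOf(shipped, "Pseudopods")
  expect_setequal(ps$shape, c("Circle", "Line"))
  expect_identical(ps$relativePosition, "Periphery")
  expect_identical(ps$relationship, "Radial")
  expect_identical(ps$predicate, "spatialMeet")
  ros <- featuresOf(shipped, "Rosettes")
  expect_identical(ros$spatialPattern, "SquareFormation")
  expect_error(featuresOf(shipped, "No Such Term"),
               class = "unknownTermError")
})

test_that("unknown vocabulary values fail with suggestions", {
  err <- expect_error(featureQuery(color = "Darkk"),
                      class = "vocabularyError")
  expect_match(conditionMessage(err), "Dark")
  expect_error(featureQuery(shape = "Blob"), class = "vocabularyError")
})

test_that("the fixed query grammar parses color-adjective shape-nouns", {
  q <- parseFeatureQuery("dark circles")
  expect_identical(tolower(q$constraints$shape), "circle")
  expect_identical(q$constraints$color, "Dark")
  q2 <- parseFeatureQuery("white lines")
  expect_identical(tolower(q2$constraints$shape), "line")
  expect_true("Shiny White Streaks" %in% findPatterns(shipped, q2)$term)
  expect_identical(parseFeatureQuery("dots")$constraints$shape, "dot")
  expect_error(parseFeatureQuery("patterns suggestive of melanoma"),
               class = "queryParseError")
  expect_error(parseFeatureQuery(""), class = "queryParseError")
})
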