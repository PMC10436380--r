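test_that("colors validate their dual rgb/hex encoding", {
  b <- makeColor("Black", c(0, 0, 0), "#000000")
  expect_s4_class(b, "Color")
  expect_identical(b@rgb, c(0L, 0L, 0L))
  err <- expect_error(makeColor("X", c(255, 0, 0), "#00FF00"))
  expect_match(conditionMessage(err), "#00FF00")
  expect_match(conditionMessage(err), "255,0,0")
  expect_error(makeColor("Y", c(300, 0, 0), "#FFFFFF"))
  expect_error(makeColor("Z", c(0, 0), "#000000"))
})

test_that("symbolic colors carry no rgb and flag qualifiers", {
  s <- symbolicColor("Hypopigmented")
  expect_true(s@symbolic)
  expect_length(s@rgb, 0)
  expect_true(symbolicColor("Uniform", qualifier = TRUE)@qualifier)
})

test_that("multi-colors need two distinct components and register inverse
          navigation", {
  bg <- makeMultiColor(list(blue, gray))
  expect_length(bg@components, 2)
  expect_error(makeMultiColor(list(blue)), class = "multiColorError")
  # duplicates collapse to a singleton, which is just a color
  expect_error(makeMultiColor(list(blue, blue)), class = "multiColorError")
  # inverse navigation holds both ways for every component
  for (comp in bg@components) {
    backs <- vapply(composedOf(comp), function(m) m@name, character(1))
    expect_true(bg@name %in% backs)
  }
})

test_that("the shipped palette loads and separates layers", {
  pal <- loadPalette()
  expect_true(all(c("Blue White", "Blue Gray", "Gray Brown",
                    "Hypopigmented", "Dark") %in% names(pal)))
  expect_true(pal[["Pigmented"]]@symbolic)
  expect_identical(pal[["Black"]]@hex, "#000000")
  core <- loadPalette(mode = "core")
  expect_false("Hypopigmented" %in% names(core))
})

test_that("a dot is a small circle and other aliases resolve", {
  dot <- makeShape("dot", fill = loadPalette()[["Brown"]])
  expect_identical(dot@shapeKind, "Circle")
  expect_identical(dot@size@value, "Small")
  expect_identical(makeShape("globule")@shapeKind, "Circle")
  expect_identical(makeShape("ellipse")@size@value, "Long")
})

test_that("named polygons enforce their exact point cardinality", {
  pts3 <- replicate(3, makePoint(), simplify = FALSE)
  tri <- makeShape("Triangle", points = pts3)
  expect_identical(tri@polygonKind, "Triangle")
  expect_length(tri@points, 3)
  pts9 <- replicate(9, makePoint(), simplify = FALSE)
  expect_error(makeShape("Decagon", points = pts9),
               class = "cardinalityError")
  # exhaustively: wrong count fails, right count succeeds
  for (pk in polygonKinds()) {
    n <- pointCardinality(pk)
    good <- replicate(n, makePoint(), simplify = FALSE)
    expect_length(makeShape(pk, points = good)@points, n)
    expect_error(makeShape(pk, points = good[-1]),
                 class = "cardinalityError")
  }
})

test_that("pointCardinality covers the polygon family and rejects others", {
  expect_identical(pointCardinality("Triangle"), 3L)
  expect_identical(pointCardinality("Decagon"), 10L)
  expect_error(pointCardinality("Circle"), class = "unsupportedKindError")
})

test_that("line styles apply to lines only and default to straight", {
  ln <- makeShape("Line")
  expect_identical(ln@lineStyle, "Straight")
  expect_error(makeShape("Circle", lineStyle = "Wavy"),
               class = "vocabularyError")
  expect_identical(makeShape("Line", lineStyle = "Serpiginous")@lineStyle,
                   "Serpiginous")
})

test_that("core mode rejects dermoscopy-layer vocabulary", {
  expect_error(makeTexture("Shiny", mode = "core"),
               class = "vocabularyError")
  expect_s4_class(makeTexture("Shiny", mode = "dermoscopy"), "Texture")
  expect_error(makeStroke(qualitativeWidth = "Variable", mode = "core"),
               class = "vocabularyError")
  expect_error(makeShape("Line", lineStyle = "Wavy", mode = "core"),
               class = "vocabularyError")
  expect_error(makePattern("p", shapes = list(makeShape("Circle")),
                           spatialPattern = "SquareFormation",
                           mode = "core"),
               class = "vocabularyError")
})

test_that("patterns are non-empty acyclic composites", {
  expect_error(makePattern("P"), class = "compositeError")
  inner <- makePattern("Pseudopods", shapes = list(makeShape("Circle")))
  star <- makePattern("Starburst", subpatterns = list(inner))
  expect_length(star@subpatterns, 1)
  # containment is not functional: several subpatterns are fine
  multi <- makePattern("M", subpatterns = list(
    inner, makePattern("Other", shapes = list(makeShape("Line")))))
  expect_length(multi@subpatterns, 2)
  # a self-referential composite is rejected with the cycle named
  p1 <- makePattern("P1", shapes = list(makeShape("Circle")))
  p2 <- makePattern("P2", subpatterns = list(p1))
  p2@subpatterns[[1]]@subpatterns <- list(p2)   # force a cycle
  err <- expect_error(validObject(p2))
  expect_match(conditionMessage(err), "cycle")
})

test_that("relation predicates must come from the registered vocabulary", {
  rel <- data.frame(subject = "a", predicate = "spatialMeet", object = "b")
  p <- makePattern("ok", shapes = list(makeShape("Circle")),
                   relations = rel)
  expect_identical(p@relations$predicate, "spatialMeet")
  bad <- data.frame(subject = "a", predicate = "touches", object = "b")
  expect_error(makePattern("bad", shapes = list(makeShape("Circle")),
                           relations = bad),
               class = "vocabularyError")
})

test_that("element enumeration recurses deterministically", {
  sh <- list(makeShape("Circle"), makeShape("Line"))
  pat <- makePattern("two", shapes = sh)
  vz <- makeVisualization(list(pat))
  els <- elementsOf(vz)
  expect_length(els, 3)   # the pattern plus its two shapes
  expect_identical(elementKind(els[[1]]), "Pattern")
  # order-stable and idempotent across runs
  expect_identical(vapply(els, elementKind, character(1)),
                   vapply(elementsOf(vz), elementKind, character(1)))
  expect_error(makeVisualization(list()))
  single <- makeVisualization(makeShape("Circle"))
  expect_length(elementsOf(single), 1)
})
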