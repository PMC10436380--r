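shipped <- dermoscopyCatalog()

test_that("registration rejects duplicates and dangling groups", {
  cg <- registerGroup(emptyCatalog(), "Streaks Pattern")
  d <- patternDefinition("Pseudopods", group = "Streaks Pattern",
                         clauses = list(shapeClause("Circle")))
  cg <- registerPattern(cg, d)
  expect_identical(catalogGroups(cg)[["Streaks Pattern"]], "Pseudopods")
  expect_error(registerPattern(cg, d), class = "duplicateError")
  expect_error(registerPattern(cg, patternDefinition(
    "Orphan", group = "Nonexistent",
    clauses = list(shapeClause("Circle")))),
    class = "danglingGroupError")
})

test_that("the shipped groups carry the expected membership", {
  g <- catalogGroups(shipped)
  expect_identical(lengths(g[c("Blotch Pattern", "Globules Pattern",
                               "Dots Pattern", "Streaks Pattern",
                               "Shiny White Structures",
                               "Network Pattern")]),
                   c("Blotch Pattern" = 2L, "Globules Pattern" = 4L,
                     "Dots Pattern" = 2L, "Streaks Pattern" = 3L,
                     "Shiny White Structures" = 3L,
                     "Network Pattern" = 2L))
  expect_setequal(g[["Network Pattern"]],
                  c("Pigment Network", "Negative Network"))
  expect_true("Pseudopods" %in% g[["Streaks Pattern"]])
  expect_identical(catalogGroups(emptyCatalog()),
                   structure(list(), names = character(0)))
})

test_that("pseudopods decompose into periphery circles meeting radial
          lines", {
  cl <- decomposeTerm(shipped, "Pseudopods")
  roles <- vapply(cl, function(x) x@role, character(1))
  expect_setequal(roles, c("shape-requirement", "relation-assertion"))
  circ <- cl[[which(vapply(cl, function(x)
    identical(x@shapeKind, "Circle"), logical(1)))]]
  expect_identical(circ@relativePosition, "Periphery")
  line <- cl[[which(vapply(cl, function(x)
    identical(x@shapeKind, "Line"), logical(1)))]]
  expect_identical(line@relationship, "Radial")
  rel <- cl[[which(roles == "relation-assertion")]]
  expect_identical(rel@predicate, "spatialMeet")
})

test_that("rosettes and pigment network decompose as documented", {
  ros <- decomposeTerm(shipped, "Rosettes")
  sp <- Filter(function(x) x@role == "spatial-pattern", ros)
  expect_identical(sp[[1]]@spatialPattern, "SquareFormation")
  expect_true("Bright White" %in% ros[[1]]@color)
  pn <- decomposeTerm(shipped, "Pigment Network")
  line <- pn[[which(vapply(pn, function(x)
    identical(x@shapeKind, "Line"), logical(1)))]]
  expect_identical(line@relationship, "Interconnecting")
  circ <- pn[[which(vapply(pn, function(x)
    identical(x@shapeKind, "Circle"), logical(1)))]]
  expect_identical(circ@color, "Hypopigmented")
  expect_identical(circ@size, "Large")
  rel <- Filter(function(x) x@role == "relation-assertion", pn)[[1]]
  expect_identical(rel@predicate, "spatialSurround")
})

test_that("subpattern references expand cycle-safely", {
  star <- decomposeTerm(shipped, "Starburst Pattern")
  # pseudopod clauses are pulled in by expansion
  kinds <- unlist(lapply(star, function(x) x@shapeKind))
  expect_true(all(c("Circle", "Line") %in% kinds))
  err <- expect_error(decomposeTerm(shipped, "Pseudopodz"),
                      class = "unknownTermError")
  expect_match(conditionMessage(err), "Pseudopods")
})

test_that("every alternative label resolves to exactly one term", {
  for (key in names(shipped@definitions)) {
    d <- shipped@definitions[[key]]
    for (al in d@altLabels) {
      hits <- Filter(function(dd) {
        tolower(al) %in% tolower(c(dd@term, dd@altLabels))
      }, shipped@definitions)
      expect_length(hits, 1)
      expect_identical(resolveTerm(shipped, al)@term, d@term)
    }
  }
})

test_that("category coverage audit flags missing categories", {
  toy <- toyCatalog()
  rep <- auditCategoryCoverage(toy)
  expect_identical(rep[["color"]], "Toy Plain")
  # complete coverage of a category leaves it out of the report
  expect_false("shape" %in% names(rep))
  expect_identical(auditCategoryCoverage(emptyCatalog()),
                   structure(list(), names = character(0)))
  # the shipped report is deterministic across runs
  expect_identical(auditCategoryCoverage(shipped),
                   auditCategoryCoverage(dermoscopyCatalog()))
  expect_true("texture" %in% names(auditCategoryCoverage(shipped)))
})

test_that("the shipped catalog validates with zero dangling identifiers", {
  expect_identical(validateCatalog(shipped), character(0))
})

test_that("non-visual information lives only in annotations", {
  for (key in names(shipped@definitions)) {
    d <- shipped@definitions[[key]]
    for (cl in d@clauses) {
      if (cl@role == "annotation") next
      fields <- c(cl@shapeKind, cl@color, cl@size, cl@texture,
                  cl@relationship, cl@relativePosition, cl@spatialPattern)
      expect_false(any(grepl("polarized|light", fields, ignore.case = TRUE)),
                   info = d@term)
    }
  }
  rainbow <- resolveTerm(shipped, "Rainbow Pattern")
  expect_match(paste(rainbow@annotations, collapse = " "), "polarized")
})

test_that("catalog files round-trip through JSON and YAML", {
  for (ext in c("json", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    writeCatalog(shipped, path)
    back <- readCatalog(path)
    expect_identical(catalogTerms(back), catalogTerms(shipped))
    expect_identical(catalogGroups(back), catalogGroups(shipped))
    for (term in catalogTerms(shipped)) {
      expect_identical(
        lapply(decomposeTerm(back, term), dermvis:::clauseToList),
        lapply(decomposeTerm(shipped, term), dermvis:::clauseToList),
        info = paste(ext, term))
    }
    # second write is byte-identical
    path2 <- withr::local_tempfile(fileext = paste0(".", ext))
    writeCatalog(back, path2)
    expect_identical(readLines(path2), readLines(path))
  }
})

test_that("catalog files are schema-checked with located errors", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(groups = list(), patterns = list(
    list(term = "Bad Term", clauses = list(list(role = "no-such-role"))))),
    path, auto_unbox = TRUE)
  err <- expect_error(readCatalog(path), class = "schemaError")
  expect_match(conditionMessage(err), "document 1")
  expect_match(conditionMessage(err), "Bad Term")
  jsonlite::write_json(list(groups = list(), patterns = list(
    list(term = "Empty", clauses = list()))), path, auto_unbox = TRUE)
  expect_error(readCatalog(path), class = "schemaError")
})

test_that("clauses only populate fields licensed by their role", {
  expect_error(new("ElementClause", role = "annotation",
                   shapeKind = "Circle", note = "x") |> validObject())
  expect_error(new("ElementClause", role = "relation-assertion",
                   predicate = "spatialMeet", subject = "a",
                   object = "b", color = "Black") |> validObject())
})
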