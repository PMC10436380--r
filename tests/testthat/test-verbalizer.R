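test_that("sentence templates are deterministic and match the house style", {
  expect_identical(
    verbalize(list(kind = "SubClassOf", subject = "Ellipse",
                   object = "Shape"))$sentence,
    "every ellipse is a shape")
  expect_identical(
    verbalize(list(kind = "ObjectExactCardinality", subject = "Decagon",
                   property = "hasPoints", object = "Point",
                   value = 10L))$sentence,
    "every decagon is something that has exactly 10 points")
  expect_identical(
    verbalize(list(kind = "ObjectMaxCardinality", subject = "Decagon",
                   property = "hasPoints", object = "Point",
                   value = 10L))$sentence,
    "every decagon is something that has at most 10 points")
  expect_identical(
    verbalize(list(kind = "DataPropertyRange", subject = "strokeWidth",
                   object = "integer"))$sentence,
    "the stroke width of something is a numerical value")
  expect_error(verbalize(list(kind = "AnnotationAssertion",
                              subject = "Circle")),
               class = "verbalizeError")
})

test_that("identical axioms verbalize identically across a model", {
  core <- buildCoreOntology()
  s1 <- verbalizeOntology(core)
  s2 <- verbalizeOntology(buildCoreOntology())
  expect_identical(s1, s2)
  expect_true("every ellipse is a shape" %in% s1$sentence)
  expect_gt(nrow(s1), 50)
})

test_that("recoding maps Y to 1 and N/X to 0, rejecting anything else", {
  expect_identical(recodeRating(c("Y", "N", "X")), c(1L, 0L, 0L))
  expect_error(recodeRating("maybe"), class = "ratingError")
})

test_that("agreement statistics reproduce the reported arithmetic", {
  m <- ratingMatrixFromProportions(c(0.90, 0.63, 0.92), 100)
  st <- agreementStats(m)
  expect_equal(unname(st$perRater), c(0.90, 0.63, 0.92))
  expect_equal(round(st$meanAgreement, 2), 0.82)
  expect_equal(st$meanAgreement, mean(st$perRater))
  expect_true(st$pairwiseAgreement >= 0 && st$pairwiseAgreement <= 1)
})

test_that("agreement is invariant under rater permutation", {
  m <- ratingMatrixFromProportions(c(0.8, 0.5, 0.9), 60)
  perm <- ratingMatrix(m@ratings[, c(3, 1, 2)],
                       statements = m@statements,
                       raters = m@raters[c(3, 1, 2)])
  expect_equal(agreementStats(m)$meanAgreement,
               agreementStats(perm)$meanAgreement)
  expect_equal(agreementStats(m)$pairwiseAgreement,
               agreementStats(perm)$pairwiseAgreement)
})

test_that("pairwise agreement hits its extremes", {
  all1 <- ratingMatrix(matrix("Y", 10, 3))
  expect_equal(agreementStats(all1)$pairwiseAgreement, 1)
  disag <- ratingMatrix(cbind(rep("Y", 8), rep("N", 8)))
  expect_equal(agreementStats(disag)$pairwiseAgreement, 0)
  # raw mode distinguishes N from X, recoded mode does not
  nx <- ratingMatrix(cbind(rep("N", 6), rep("X", 6)))
  expect_equal(agreementStats(nx, "recoded")$pairwiseAgreement, 1)
  expect_equal(agreementStats(nx, "raw")$pairwiseAgreement, 0)
  expect_error(agreementStats(ratingMatrix(matrix("Y", 4, 1))),
               class = "ratingError")
})

test_that("contested statements are found by zero-count threshold", {
  m <- ratingMatrix(rbind(c("N", "X", "Y"), c("Y", "Y", "Y")),
                    statements = c("s1", "s2"))
  expect_identical(contestedStatements(m, 2), "s1")
  expect_identical(contestedStatements(m, 3), character(0))
  # planted rows in a synthetic matrix, verified by brute-force counting
  withr::with_seed(7, {
    cells <- matrix(sample(c("Y", "N", "X"), 30, TRUE,
                           prob = c(0.7, 0.2, 0.1)), 10, 3)
    contestedRows <- which(rowSums(cells != "Y") >= 2)
    m2 <- ratingMatrix(cells, statements = sprintf("S%02d", 1:10))
    expect_identical(contestedStatements(m2, 2),
                     sprintf("S%02d", contestedRows))
  })
})

test_that("rating matrices round-trip through CSV and review sheets", {
  core <- buildCoreOntology()
  sheet <- verbalizeOntology(core)[1:5, ]
  path <- withr::local_tempfile(fileext = ".csv")
  writeReviewSheet(sheet, path)
  tab <- utils::read.csv(path)
  expect_identical(names(tab), c("statement", "sentence", "R1", "R2", "R3"))
  tab$R1 <- "Y"; tab$R2 <- c("Y", "N", "Y", "X", "Y"); tab$R3 <- "Y"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab[c("statement", "R1", "R2", "R3")], path2,
                   row.names = FALSE)
  m <- readRatingMatrix(path2)
  expect_identical(m@raters, c("R1", "R2", "R3"))
  expect_equal(unname(agreementStats(m)$perRater[2]), 3 / 5)
})

test_that("review percentages round at the reported precision", {
  expect_equal(reviewPercent(12, 48), 25)
  expect_equal(reviewPercent(5, 48), 10.4)
  expect_equal(reviewPercent(48, 48), 100)
})
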