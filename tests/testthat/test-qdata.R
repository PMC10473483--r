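test_that("reading and writing Q-sorts round-trips the numeric content", {
  f <- system.file("extdata", "example_qsorts.csv", package = "qrotate")
  q <- readQSorts(f)
  expect_s4_class(q, "QSortMatrix")
  expect_equal(dim(qValues(q)), c(9L, 6L))
  expect_equal(gridOf(q)@columnValues, -2:2)

  out <- file.path(tempdir(), "roundtrip.csv")
  writeQSorts(q, out)
  expect_identical(readLines(out), readLines(f))
  q2 <- readQSorts(out)
  expect_identical(qValues(q2), qValues(q))

  # the JSON grid spec shipped alongside matches the inferred grid
  g <- readGridSpec(system.file("extdata", "example_grid.json",
                                package = "qrotate"))
  expect_equal(g@columnCapacities, gridOf(q)@columnCapacities)

  st <- readStatements(system.file("extdata", "example_statements.tsv",
                                   package = "qrotate"))
  expect_equal(st$id, 1:9)
})

test_that("both file orientations produce the same canonical matrix", {
  q <- readQSorts(system.file("extdata", "example_qsorts.csv",
                              package = "qrotate"))
  # write the transposed (participants-in-rows) orientation by hand
  tf <- file.path(tempdir(), "transposed.csv")
  m <- qValues(q)
  df <- data.frame(participant = colnames(m), t(m), check.names = FALSE)
  write.table(df, tf, sep = ",", row.names = FALSE, quote = FALSE)
  qt <- readQSorts(tf, layout = "participants_by_statements")
  expect_identical(qValues(qt), qValues(q))
})

test_that("the smallest legal input and within-grid permutations validate", {
  f1 <- file.path(tempdir(), "one.csv")
  writeLines(c("statement,P1", "1,0"), f1)
  q1 <- readQSorts(f1, grid = gridSpec(0, 1))
  expect_equal(qValues(q1)[1, 1], 0L)

  # swapping two entries between grid cells keeps the histogram, so the
  # column remains a valid forced-distribution Q-sort
  q <- readQSorts(system.file("extdata", "example_qsorts.csv",
                              package = "qrotate"))
  m <- qValues(q)
  m[c(1, 2), 1] <- m[c(2, 1), 1]
  expect_s4_class(qSortMatrix(m, grid = gridOf(q)), "QSortMatrix")
})

test_that("malformed inputs fail with informative errors", {
  bad <- file.path(tempdir(), "bad.csv")
  writeLines(c("statement,P1,P2", "1,0,x", "2,1,-1", "3,-1,1"), bad)
  expect_error(readQSorts(bad), "non-integer cell 'x'.*row id '1'.*'P2'")

  oor <- file.path(tempdir(), "oor.csv")
  writeLines(c("statement,P1,P2", "1,0,5", "2,1,-1", "3,-1,1"), oor)
  expect_error(readQSorts(oor, grid = gridSpec(-1:1, c(1, 1, 1))),
               "outside the grid")

  # same values, wrong histogram: a forced-distribution violation
  viol <- file.path(tempdir(), "viol.csv")
  writeLines(c("statement,P1,P2", "1,0,1", "2,1,1", "3,-1,1"), viol)
  expect_error(readQSorts(viol, grid = gridSpec(-1:1, c(1, 1, 1))),
               "P2.*violates the forced distribution")
  # ...accepted in free-distribution mode (range checks only)
  expect_s4_class(readQSorts(viol, grid = gridSpec(-1:1, c(1, 1, 1)),
                             forced = FALSE), "QSortMatrix")
})

test_that("grid inference reads the histogram and rejects inconsistency", {
  g <- inferGrid(cbind(c(-1, 0, 1), c(1, -1, 0)))
  expect_equal(g@columnValues, -1:1)
  expect_equal(g@columnCapacities, c(1L, 1L, 1L))

  expect_error(inferGrid(cbind(A = c(0, 0), B = c(0, 1))),
               "deviating value histograms.*B")
})

test_that("grid inference recovers the generator's grid", {
  for (seed in c(3, 17, 91)) {
    d <- generateSynthetic(S = 19, kTrue = 2, groupSizes = c(5, 5),
                           noiseSd = 0.6, grid = grid19(), seed = seed)
    g <- inferGrid(qValues(d@qsorts))
    expect_equal(g@columnValues, grid19()@columnValues)
    expect_equal(g@columnCapacities, grid19()@columnCapacities)
  }
})
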