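test_that("the loading significance threshold follows z / sqrt(S)", {
  expect_equal(significanceThreshold(19), 0.44965, tolerance = 1e-4)
  expect_equal(significanceThreshold(42), 0.3024, tolerance = 1e-4)
  expect_lt(significanceThreshold(1e8), 1e-3)
  expect_error(significanceThreshold(1), "at least 2")
  expect_error(significanceThreshold(19, alpha = 1.2), "alpha")
})

test_that("flagging separates dominant, confounded and null sorts", {
  a <- rbind(dom = c(0.9, 0.0, 0.0),
             conf = c(0.5, 0.5, 0.0),
             nul = c(0.1, 0.2, 0.1))
  fl <- flagQSorts(a, tau = 0.45)
  expect_equal(loadedSorts(fl)[[1]], c("dom", "conf"))
  expect_equal(loadedSorts(fl)[[2]], "conf")
  expect_equal(flaggedSorts(fl)[[1]], "dom")
  # no factor holds a majority of conf's communality, so it is confounded
  expect_equal(fl@confounded, "conf")
  expect_equal(fl@null, "nul")
  expect_error(flagQSorts(a, tau = 0), "positive")
})

test_that("every sort lands in exactly one of flagged/confounded/null", {
  for (case in 1:5) {
    set.seed(300 + case)
    a <- matrix(runif(60, -1, 1), 20, 3)
    a <- a / pmax(sqrt(rowSums(a^2)), 1)   # keep h2 <= 1
    fl <- flagQSorts(a, tau = 0.45)
    ids <- paste0("P", 1:20)
    buckets <- c(unlist(flaggedSorts(fl)), fl@confounded, fl@null)
    expect_setequal(buckets, ids)
    expect_equal(length(buckets), length(ids))
    # flagged sets are subsets of the loaded sets and pairwise disjoint
    for (j in 1:3) {
      expect_true(all(flaggedSorts(fl)[[j]] %in% loadedSorts(fl)[[j]]))
    }
    expect_false(anyDuplicated(unlist(flaggedSorts(fl))) > 0)
  }
})

test_that("a single flagged sort reproduces its own Q-sort as the array", {
  d <- generateSynthetic(S = 19, kTrue = 2, groupSizes = c(1, 1),
                         noiseSd = 0.6, grid = grid19(), seed = 8)
  q <- d@qsorts
  a <- rbind(P1 = c(0.8, 0.0), P2 = c(0.0, 0.8))
  fl <- flagQSorts(a, tau = 0.45)
  sc <- factorZScores(q, fl, a)
  expect_equal(as.vector(factorArrays(sc)[, 1]), as.vector(qValues(q)[, 1]))
  expect_equal(as.vector(factorArrays(sc)[, 2]), as.vector(qValues(q)[, 2]))
})

test_that("Brown weights follow f / (1 - f^2)", {
  d <- generateSynthetic(S = 19, kTrue = 2, groupSizes = c(2, 2),
                         noiseSd = 0.6, grid = grid19(), seed = 9)
  a <- rbind(P1 = c(0.8, 0), P2 = c(0.4, 0.1), P3 = c(0, 0.7),
             P4 = c(0.1, 0.6))
  fl <- flagQSorts(a, tau = 0.3)
  sc <- factorZScores(d@qsorts, fl, a)
  expect_equal(unname(sc@weights[[1]]), c(2.2222, 0.4762), tolerance = 1e-4)
  # composite must match a hand-rolled weighted sum, standardized
  m <- qValues(d@qsorts)
  comp <- m[, 1] * 2.22222 + m[, 2] * 0.47619
  expect_equal(as.vector(zScores(sc)[, 1]),
               as.vector(scale(comp)), tolerance = 1e-4)
})

test_that("z-scores are standardized and arrays keep the grid histogram", {
  d <- synth3()
  rep <- runRotationImpact(d@qsorts, k = 3, extraction = "pca")
  for (key in names(rep@conditions)) {
    sc <- rep@conditions[[key]]$scores
    z <- zScores(sc)
    expect_lt(max(abs(colMeans(z))), 1e-8)
    expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-8)
    for (j in 1:3) {
      h <- table(factor(factorArrays(sc)[, j], levels = -5:5))
      expect_equal(as.integer(h), grid42()@columnCapacities)
    }
  }
})

test_that("loadings at or beyond 1 are clipped with a warning", {
  g <- grid19()
  d <- generateSynthetic(S = 19, kTrue = 2, groupSizes = c(1, 1),
                         noiseSd = 0.5, grid = g, seed = 10)
  a <- rbind(P1 = c(1.0, 0), P2 = c(0, 0.8))
  fl <- flagQSorts(a, tau = 0.45)
  expect_warning(sc <- factorZScores(d@qsorts, fl, a), "clipped")
  expect_s4_class(sc, "FactorScores")
})

test_that("an unflagged factor cannot be scored", {
  d <- generateSynthetic(S = 19, kTrue = 2, groupSizes = c(1, 1),
                         noiseSd = 0.5, grid = grid19(), seed = 13)
  a <- rbind(P1 = c(0.9, 0), P2 = c(0.8, 0.1))
  fl <- flagQSorts(a, tau = 0.45)
  expect_error(factorZScores(d@qsorts, fl, a), "factor 2 has no flagged")
})

test_that("negating a factor's loadings mirrors its scores and array", {
  d <- synth3()
  ext <- extractPCA(correlateQSorts(d@qsorts), k = 3)
  rot <- rotateVarimax(ext)
  tau <- significanceThreshold(42)
  a <- rot@rotated
  sc <- factorZScores(d@qsorts, flagQSorts(a, tau), a)
  aNeg <- a
  aNeg[, 2] <- -aNeg[, 2]
  scNeg <- factorZScores(d@qsorts, flagQSorts(aNeg, tau), aNeg)
  expect_equal(zScores(scNeg)[, 2], -zScores(sc)[, 2], tolerance = 1e-10)
  expect_equal(factorArrays(scNeg)[, 2], -factorArrays(sc)[, 2])
  # after aligning signs, distinguishing sets are unchanged
  zAligned <- zScores(scNeg)
  zAligned[, 2] <- -zAligned[, 2]
  expect_equal(distinguishing(distinguishingStatements(zAligned)),
               distinguishing(distinguishingStatements(zScores(sc))))
})

test_that("distinguishing statements honor the effect-size boundary", {
  z <- cbind(F1 = scale(1:10)[, 1], F2 = scale(1:10)[, 1])
  expect_equal(lengths(distinguishing(distinguishingStatements(z))),
               c(F1 = 0L, F2 = 0L))

  # an exact 0.80 gap distinguishes the statement on both factors
  z2 <- cbind(F1 = scale(c(4, 1:9))[, 1], F2 = scale(c(4, 1:9))[, 1])
  z2[1, 1] <- z2[1, 2] + 0.80
  rownames(z2) <- 1:10
  ds <- distinguishingStatements(z2, d = 0.80)
  expect_true(1L %in% distinguishing(ds)[[1]])
  expect_true(1L %in% distinguishing(ds)[[2]])
  expect_error(distinguishingStatements(z2[, 1, drop = FALSE]),
               "at least 2 factors")
})

test_that("lowering the effect size never removes a distinguishing statement", {
  d <- synth3()
  rep <- runRotationImpact(d@qsorts, k = 3, extraction = "pca")
  z <- zScores(rep@conditions[["pca:varimax"]]$scores)
  prev <- distinguishing(distinguishingStatements(z, d = 1.2))
  for (dd in c(1.0, 0.8, 0.5, 0.2)) {
    cur <- distinguishing(distinguishingStatements(z, d = dd))
    for (j in seq_along(cur)) expect_true(all(prev[[j]] %in% cur[[j]]))
    prev <- cur
  }
})
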