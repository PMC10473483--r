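test_that("factor-score self-correlation is the identity on the diagonal", {
  d <- synth3()
  rep <- runRotationImpact(d@qsorts, k = 3, extraction = "pca")
  sc <- rep@conditions[["pca:varimax"]]$scores
  cm <- factorCorrelations(sc, sc)
  expect_equal(diag(cm), rep(1, 3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(cm >= -1 - 1e-12 & cm <= 1 + 1e-12))

  flipped <- zScores(sc)
  flipped <- -flipped
  expect_equal(diag(factorCorrelations(sc, flipped)), rep(-1, 3),
               tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(factorCorrelations(zScores(sc), zScores(sc)[-1, ]),
               "same statements")
})

test_that("matching recovers identity and every signed 3x3 permutation", {
  m <- matchFactors(diag(3))
  expect_equal(m$reference, 1:3)
  expect_equal(m$factor, 1:3)
  expect_equal(m$r, rep(1, 3))

  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    for (signs in asplit(as.matrix(expand.grid(c(-1, 1), c(-1, 1),
                                               c(-1, 1))), 1)) {
      cm <- matrix(0, 3, 3)
      for (f in 1:3) cm[f, p[f]] <- signs[f]
      got <- matchFactors(cm)
      expect_equal(got$reference[order(got$factor)][p], 1:3)
      for (f in 1:3) {
        row <- got[got$reference == f, ]
        expect_equal(row$factor, p[f])
        expect_equal(row$sign, unname(signs[f]))
      }
      # the exhaustive assignment agrees on unambiguous matrices
      opt <- matchFactors(cm, method = "optimal")
      expect_equal(opt[order(opt$factor), "reference"],
                   got[order(got$factor), "reference"])
    }
  }
})

test_that("greedy matching carries its certificate and breaks ties low", {
  cm <- rbind(c(0.9, 0.8, 0.1),
              c(0.85, 0.7, 0.2),
              c(0.1, 0.2, 0.6))
  m <- matchFactors(cm)
  m <- m[order(m$factor), ]
  # picks 0.9 (F1<-ref1), then 0.7 is beaten by nothing left in row 2
  expect_equal(m$reference[m$factor == 1], 1)
  expect_equal(m$reference[m$factor == 2], 2)
  # exact ties: smaller reference index wins
  tie <- matrix(c(0.5, 0.5, 0.5, 0.5), 2)
  mt <- matchFactors(tie)
  expect_equal(mt$reference[mt$factor == 1], 1)
})

test_that("changed-statement ledgers are plain set algebra", {
  led <- diffDistinguishing(c(1, 2), c(2, 3))
  expect_equal(led$common, 2L)
  expect_equal(led$new, 3L)
  expect_equal(led$dropped, 1L)
  expect_equal(led$nChanged, 2L)
  expect_equal(diffDistinguishing(c(4, 5), c(4, 5))$nChanged, 0L)
  expect_length(intersect(led$new, led$dropped), 0)
})

test_that("a condition compared with itself yields identity and empty ledgers", {
  d <- synth3()
  rep <- runRotationImpact(d@qsorts, k = 3, extraction = "pca")
  sc <- rep@conditions[["pca:equamax"]]$scores
  ds <- rep@conditions[["pca:equamax"]]$distinguishing
  m <- matchFactors(factorCorrelations(sc, sc))
  expect_equal(m$reference, m$factor)
  expect_equal(m$r, rep(1, 3), tolerance = 1e-8)
  for (j in 1:3) {
    expect_equal(diffDistinguishing(distinguishing(ds)[[j]],
                                    distinguishing(ds)[[j]])$nChanged, 0L)
  }
})

test_that("matching is invariant to factor sign flips", {
  d <- synth3()
  rep <- runRotationImpact(d@qsorts, k = 3, extraction = "pca")
  cm <- factorCorrelations(rep@conditions[["pca:none"]]$scores,
                           rep@conditions[["pca:varimax"]]$scores)
  base <- matchFactors(cm)
  for (j in 1:3) {
    flipped <- cm
    flipped[, j] <- -flipped[, j]
    got <- matchFactors(flipped)
    expect_equal(got$reference, base$reference)
    expect_equal(abs(got$r), abs(base$r), tolerance = 1e-12)
  }
})

test_that("rotated factor scores stay in the unrotated factors' span", {
  d <- synth3()
  rep <- runRotationImpact(d@qsorts, k = 3, extraction = "pca")
  z0 <- zScores(rep@conditions[["pca:none"]]$scores)
  for (rot in c("varimax", "equamax", "quartimax")) {
    zr <- zScores(rep@conditions[[paste0("pca:", rot)]]$scores)
    for (j in 1:3) {
      r2 <- summary(stats::lm(zr[, j] ~ z0))$r.squared
      expect_gt(r2, 0.9)
    }
  }
})

test_that("the factorial report is internally consistent", {
  d <- synth3()
  rep <- runRotationImpact(d@qsorts, k = 3)
  s <- rep@summary
  expect_equal(nrow(s), 2 * 4 * 3)   # 2 extractions x 4 rotations x 3 factors
  expect_equal(rep@threshold, significanceThreshold(42))
  # baseline rows carry no match columns; rotated rows carry them all
  expect_true(all(is.na(s$matchR[s$rotation == "none"])))
  expect_true(all(!is.na(s$matchR[s$rotation != "none"])))
  expect_equal(s$nChanged[s$rotation != "none"],
               s$nNew[s$rotation != "none"] + s$nDropped[s$rotation != "none"])
  # every correlation-matrix block of the factorial is present
  expect_setequal(names(rep@correlations$pca),
                  c("varimax vs none", "equamax vs none", "quartimax vs none",
                    "equamax vs varimax", "quartimax vs varimax",
                    "quartimax vs equamax"))
})

test_that("a single-factor analysis skips matching and distinguishing", {
  d <- generateSynthetic(S = 19, kTrue = 1, groupSizes = 10, noiseSd = 0.6,
                         grid = grid19(), seed = 21)
  rep <- runRotationImpact(d@qsorts, k = 1, extraction = "pca")
  expect_true(all(is.na(rep@summary$distinguishing)))
  expect_length(rep@matches$pca, 0)
  expect_length(rep@ledgers$pca, 0)
  expect_equal(rep@summary$loaded[1], 10)
})

test_that("exportReport writes the full file set", {
  d <- synth3()
  rep <- runRotationImpact(d@qsorts, k = 3, extraction = "pca")
  dir <- file.path(tempdir(), "report_out")
  exportReport(rep, dir)
  expect_true(file.exists(file.path(dir, "counts.csv")))
  expect_true(file.exists(file.path(dir, "correlations.csv")))
  expect_true(file.exists(file.path(dir, "ledgers.csv")))
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_length(list.files(file.path(dir, "zscores")), 4)
  expect_length(list.files(file.path(dir, "arrays")), 4)
  counts <- read.csv(file.path(dir, "counts.csv"))
  expect_equal(nrow(counts), nrow(rep@summary))
})
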