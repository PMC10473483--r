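# Rotation-impact comparison: factor-score correlations, max-|r| matching,
# changed-statement ledgers, and the full extraction x rotation factorial.

#' Correlate factor scores between two conditions
#'
#' Pearson correlation across statements between every pair of factor
#' z-score columns: entry (f, g) correlates factor f of the reference
#' condition with factor g of the other condition.
#'
#' @param za reference-condition [FactorScores-class] or z matrix.
#' @param zb comparison-condition [FactorScores-class] or z matrix over the
#'   same statements in the same order.
#' @return k_a x k_b numeric matrix.
#' @export
factorCorrelations <- function(za, zb) {
  za <- if (is(za, "FactorScores")) za@z else as.matrix(za)
  zb <- if (is(zb, "FactorScores")) zb@z else as.matrix(zb)
  if (nrow(za) != nrow(zb)) {
    stop("factor scores must cover the same statements")
  }
  stats::cor(za, zb)
}

#' Match factors by maximum absolute correlation
#'
#' Greedy one-to-one assignment on a correlation matrix whose rows are
#' reference factors and columns the factors to match: repeatedly take the
#' largest remaining |r| among unmatched rows and columns (ties broken by
#' smaller reference index, then smaller column index). The sign of each
#' matched r is recorded so downstream z columns and arrays can be aligned.
#' `method = "optimal"` instead maximizes the total |r| over all one-to-one
#' assignments (exhaustive over permutations; intended for the small k used
#' in practice) — useful when greedy choices tie.
#'
#' @param c correlation matrix from [factorCorrelations()] (square).
#' @param method `"greedy"` (default, the reported behavior) or
#'   `"optimal"`.
#' @return data.frame with one row per matched pair: `factor` (column
#'   index), `reference` (row index), `r`, `sign`.
#' @examples
#' matchFactors(diag(3))
#' @export
matchFactors <- function(c, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  c <- as.matrix(c)
  if (nrow(c) != ncol(c)) stop("correlation matrix must be square")
  k <- nrow(c)
  if (method == "optimal") {
    if (k > 8L) stop("optimal matching supported for k <= 8")
    perms <- .permutations(k)
    tot <- vapply(seq_len(nrow(perms)), function(i) {
      sum(abs(c[cbind(seq_len(k), perms[i, ])]))
    }, numeric(1))
    p <- perms[which.max(tot), ]
    out <- data.frame(factor = p, reference = seq_len(k),
                      r = c[cbind(seq_len(k), p)])
  } else {
    rowsLeft <- rep(TRUE, k)
    colsLeft <- rep(TRUE, k)
    ref <- fac <- integer(k)
    rr <- numeric(k)
    for (step in seq_len(k)) {
      sub <- abs(c)
      sub[!rowsLeft, ] <- -Inf
      sub[, !colsLeft] <- -Inf
      best <- which(sub == max(sub), arr.ind = TRUE)
      best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
      ref[step] <- best[1]
      fac[step] <- best[2]
      rr[step] <- c[best[1], best[2]]
      rowsLeft[best[1]] <- FALSE
      colsLeft[best[2]] <- FALSE
    }
    out <- data.frame(factor = fac, reference = ref, r = rr)
  }
  out$sign <- ifelse(out$r >= 0, 1, -1)
  out[order(out$factor), , drop = FALSE]
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Changed distinguishing statements between matched factors
#'
#' Set differences between a reference factor's distinguishing statements
#' and those of its matched rotated factor: `new` appear only after
#' rotation, `dropped` only before, `common` in both;
#' `nChanged = nNew + nDropped`.
#'
#' @param ref integer vector (or [DistinguishingSet-class] factor entry) of
#'   reference distinguishing statement ids.
#' @param rot ids for the matched rotated factor.
#' @return list with `common`, `new`, `dropped`, `nNew`, `nDropped`,
#'   `nChanged`.
#' @examples
#' diffDistinguishing(c(1, 2), c(2, 3))
#' @export
diffDistinguishing <- function(ref, rot) {
  ref <- as.integer(ref)
  rot <- as.integer(rot)
  list(common = intersect(ref, rot),
       new = setdiff(rot, ref),
       dropped = setdiff(ref, rot),
       nNew = length(setdiff(rot, ref)),
       nDropped = length(setdiff(ref, rot)),
       nChanged = length(setdiff(rot, ref)) + length(setdiff(ref, rot)))
}

#' Run the full rotation-impact factorial
#'
#' For every requested extraction method and rotation technique: extract k
#' factors from the by-person correlations, rotate, flag sorts against the
#' significance threshold, compute factor z-scores and arrays, and detect
#' distinguishing statements. Each rotated condition is then matched to the
#' same extraction's no-rotation condition by maximum absolute correlation
#' of factor scores, changed-statement ledgers are drawn up per matched
#' pair, and rotation-vs-rotation correlation matrices are retained as well.
#'
#' @param q a [QSortMatrix-class].
#' @param k number of factors to extract (a required analysis choice; no
#'   automatic retention rule is applied).
#' @param extraction subset of `c("pca", "paf")`.
#' @param rotations subset of `c("none", "varimax", "equamax", "quartimax")`;
#'   `"none"` is always included (it is the comparison baseline).
#' @param alpha significance level for the loading threshold.
#' @param effectSize distinguishing-statement effect size d.
#' @param kaiserNormalize Kaiser row normalization during rotation.
#' @param useAllSignificant see [factorZScores()].
#' @param matchMethod see [matchFactors()].
#' @return a [ComparisonReport-class]. With k = 1 no distinguishing
#'   statements, matching or ledgers are produced (single-factor
#'   comparisons are undefined); loadings, flags and scores are still
#'   reported.
#' @export
runRotationImpact <- function(q, k = 3,
                              extraction = c("pca", "paf"),
                              rotations = c("none", "varimax", "equamax",
                                            "quartimax"),
                              alpha = 0.05, effectSize = 0.80,
                              kaiserNormalize = TRUE,
                              useAllSignificant = FALSE,
                              matchMethod = "greedy") {
  stopifnot(is(q, "QSortMatrix"))
  extraction <- match.arg(extraction, several.ok = TRUE)
  rotations <- match.arg(rotations,
                         c("none", "varimax", "equamax", "quartimax"),
                         several.ok = TRUE)
  rotations <- union("none", rotations)
  S <- nrow(q@values)
  tau <- significanceThreshold(S, alpha)
  r <- correlateQSorts(q)
  k <- as.integer(k)

  conditions <- list()
  correlations <- list()
  matches <- list()
  ledgers <- list()
  rows <- list()

  for (ex in extraction) {
    extRes <- if (ex == "pca") extractPCA(r, k, nStatements = S)
              else extractPAF(r, k, nStatements = S)
    exConds <- list()
    for (rot in rotations) {
      rotRes <- applyRotation(extRes, rot,
                              kaiserNormalize = kaiserNormalize)
      flags <- flagQSorts(rotRes, tau)
      scores <- factorZScores(q, flags, rotRes,
                              useAllSignificant = useAllSignificant,
                              fallback = TRUE)
      dist <- if (k >= 2L) distinguishingStatements(scores, effectSize)
              else NULL
      exConds[[rot]] <- list(extraction = extRes, rotation = rotRes,
                             flags = flags, scores = scores,
                             distinguishing = dist)
    }

    exCorr <- list()
    exMatch <- list()
    exLedger <- list()
    if (k >= 2L) {
      pairs <- utils::combn(rotations, 2, simplify = FALSE)
      for (pr in pairs) {
        key <- paste(pr[2], "vs", pr[1])
        exCorr[[key]] <- factorCorrelations(exConds[[pr[1]]]$scores,
                                            exConds[[pr[2]]]$scores)
      }
      for (rot in setdiff(rotations, "none")) {
        cm <- exCorr[[paste(rot, "vs none")]]
        mm <- matchFactors(cm, method = matchMethod)
        exMatch[[rot]] <- mm
        led <- lapply(seq_len(k), function(j) {
          refF <- mm$reference[mm$factor == j]
          diffDistinguishing(
            exConds[["none"]]$distinguishing@statements[[refF]],
            exConds[[rot]]$distinguishing@statements[[j]])
        })
        names(led) <- paste0("F", seq_len(k))
        exLedger[[rot]] <- led
      }
    }

    for (rot in rotations) {
      cond <- exConds[[rot]]
      for (j in seq_len(k)) {
        mm <- exMatch[[rot]]
        led <- exLedger[[rot]][[j]]
        rows[[length(rows) + 1L]] <- data.frame(
          extraction = ex, rotation = rot, factor = paste0("F", j),
          loaded = length(cond$flags@loaded[[j]]),
          flagged = length(cond$flags@flagged[[j]]),
          distinguishing = if (k >= 2L)
            length(cond$distinguishing@statements[[j]]) else NA_integer_,
          matchedRef = if (!is.null(mm))
            paste0("F", mm$reference[mm$factor == j]) else NA_character_,
          matchR = if (!is.null(mm)) mm$r[mm$factor == j] else NA_real_,
          nNew = if (!is.null(led)) led$nNew else NA_integer_,
          nDropped = if (!is.null(led)) led$nDropped else NA_integer_,
          nChanged = if (!is.null(led)) led$nChanged else NA_integer_)
      }
    }
    names(exConds) <- paste(ex, names(exConds), sep = ":")
    conditions <- c(conditions, exConds)
    correlations[[ex]] <- exCorr
    matches[[ex]] <- exMatch
    ledgers[[ex]] <- exLedger
  }

  new("ComparisonReport", k = k, threshold = tau,
      effectSize = effectSize, conditions = conditions,
      summary = do.call(rbind, rows), correlations = correlations,
      matches = matches, ledgers = ledgers)
}

#' Export a comparison report to CSV/JSON files
#'
#' Writes `counts.csv` (the per-condition factor summary),
#' `correlations.csv` (long-format factor-score correlations),
#' `ledgers.csv` (changed-statement sets per matched pair),
#' `zscores/<condition>.csv` and `arrays/<condition>.csv`, and a
#' `report.json` with thresholds and matches.
#'
#' @param report a [ComparisonReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
exportReport <- function(report, dir) {
  stopifnot(is(report, "ComparisonReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report@summary, file.path(dir, "counts.csv"),
                   row.names = FALSE)

  corrRows <- list()
  for (ex in names(report@correlations)) {
    for (key in names(report@correlations[[ex]])) {
      cm <- report@correlations[[ex]][[key]]
      for (i in seq_len(nrow(cm))) for (j in seq_len(ncol(cm))) {
        corrRows[[length(corrRows) + 1L]] <- data.frame(
          extraction = ex, comparison = key,
          referenceFactor = rownames(cm)[i], factor = colnames(cm)[j],
          r = cm[i, j])
      }
    }
  }
  if (length(corrRows)) {
    utils::write.csv(do.call(rbind, corrRows),
                     file.path(dir, "correlations.csv"), row.names = FALSE)
  }

  ledRows <- list()
  for (ex in names(report@ledgers)) {
    for (rot in names(report@ledgers[[ex]])) {
      led <- report@ledgers[[ex]][[rot]]
      for (f in names(led)) {
        ledRows[[length(ledRows) + 1L]] <- data.frame(
          extraction = ex, rotation = rot, factor = f,
          common = paste(led[[f]]$common, collapse = ";"),
          new = paste(led[[f]]$new, collapse = ";"),
          dropped = paste(led[[f]]$dropped, collapse = ";"),
          nChanged = led[[f]]$nChanged)
      }
    }
  }
  if (length(ledRows)) {
    utils::write.csv(do.call(rbind, ledRows),
                     file.path(dir, "ledgers.csv"), row.names = FALSE)
  }

  for (sub in c("zscores", "arrays")) {
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  }
  for (key in names(report@conditions)) {
    safe <- gsub(":", "_", key)
    sc <- report@conditions[[key]]$scores
    utils::write.csv(data.frame(statement = rownames(sc@z), sc@z,
                                check.names = FALSE),
                     file.path(dir, "zscores", paste0(safe, ".csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(statement = rownames(sc@arrays), sc@arrays,
                                check.names = FALSE),
                     file.path(dir, "arrays", paste0(safe, ".csv")),
                     row.names = FALSE)
  }

  jsonlite::write_json(
    list(k = report@k, threshold = report@threshold,
         effectSize = report@effectSize,
         matches = lapply(report@matches, function(mx) {
           lapply(mx, function(m) m[, c("factor", "reference", "r")])
         })),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
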