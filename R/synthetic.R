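# Synthetic Q-sort generator: latent viewpoint prototypes, Gaussian
# per-participant noise, rank transformation into the forced grid.

#' Generate latent viewpoint prototypes
#'
#' Draws `kTrue` standardized pseudo-random z-score profiles over S
#' statements. Any column pair correlating beyond `maxCorr` in absolute
#' value triggers a redraw of the later column, up to 1000 attempts, so the
#' prototypes represent distinct viewpoints.
#'
#' @param S number of statements (> kTrue).
#' @param kTrue number of prototypes (>= 1).
#' @param maxCorr maximum allowed absolute pairwise Pearson correlation
#'   between prototypes (default 0.3).
#' @param seed integer seed; the only source of randomness.
#' @return S x kTrue numeric matrix, columns standardized (mean 0, SD 1).
#' @export
generatePrototypes <- function(S, kTrue, maxCorr = 0.3, seed = NULL) {
  if (kTrue < 1L) stop("kTrue must be >= 1")
  if (S <= kTrue) stop("need more statements than prototypes")
  if (!is.null(seed)) set.seed(seed)
  std <- function(x) (x - mean(x)) / stats::sd(x)
  proto <- matrix(0, S, kTrue)
  proto[, 1] <- std(stats::rnorm(S))
  if (kTrue >= 2L) {
    for (j in 2:kTrue) {
      ok <- FALSE
      for (attempt in seq_len(1000L)) {
        cand <- std(stats::rnorm(S))
        if (all(abs(stats::cor(cand, proto[, 1:(j - 1), drop = FALSE])) <=
                  maxCorr)) {
          proto[, j] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not draw prototypes with |r| <= ", maxCorr,
             " in 1000 attempts; try a larger S or looser maxCorr")
      }
    }
  }
  rownames(proto) <- seq_len(S)
  colnames(proto) <- paste0("V", seq_len(kTrue))
  proto
}

# Rank-transform a continuous profile into the forced grid: descending value
# fills columns from the positive anchor, capacities respected, ties by
# statement id.
.forceToGrid <- function(x, grid) {
  ord <- order(-x, seq_along(x))
  assigned <- rep(rev(grid@columnValues), rev(grid@columnCapacities))
  out <- integer(length(x))
  out[ord] <- assigned
  out
}

#' Generate Q-sorts from viewpoint prototypes
#'
#' Each participant in group g receives the continuous profile
#' `prototypes[, g] + Normal(0, noiseSd)` per statement, which is then
#' rank-transformed into the forced grid distribution. With `noiseSd = 0`
#' all members of a group produce identical Q-sorts.
#'
#' @param prototypes S x kTrue matrix from [generatePrototypes()].
#' @param grid a [GridSpec-class] whose capacities sum to S.
#' @param groupSizes integer vector, participants per prototype.
#' @param noiseSd Gaussian noise SD (>= 0) in prototype z-score units.
#' @param seed integer seed.
#' @return a [SyntheticDataset-class].
#' @export
generateQSorts <- function(prototypes, grid, groupSizes, noiseSd = 0.5,
                           seed = NULL) {
  stopifnot(is(grid, "GridSpec"))
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (length(groupSizes) != ncol(prototypes)) {
    stop("one group size per prototype required")
  }
  S <- nrow(prototypes)
  if (sum(grid@columnCapacities) != S) {
    stop("grid capacities must sum to the number of statements")
  }
  if (!is.null(seed)) set.seed(seed)
  P <- sum(groupSizes)
  labels <- rep(seq_along(groupSizes), groupSizes)
  m <- matrix(NA_integer_, S, P)
  for (i in seq_len(P)) {
    profile <- prototypes[, labels[i]] + stats::rnorm(S, 0, noiseSd)
    m[, i] <- .forceToGrid(profile, grid)
  }
  ids <- paste0("P", seq_len(P))
  names(labels) <- ids
  q <- qSortMatrix(m, grid = grid, participantIds = ids,
                   statementIds = seq_len(S), forced = TRUE)
  new("SyntheticDataset", qsorts = q, trueLabels = labels,
      prototypes = prototypes)
}

#' Generate a complete synthetic Q-sort dataset
#'
#' Convenience wrapper: draws prototypes then Q-sorts under one seed. When
#' `grid` is omitted a quasi-normal symmetric grid for S statements is
#' built with [defaultGrid()].
#'
#' @param S number of statements.
#' @param kTrue number of latent viewpoints.
#' @param groupSizes participants per viewpoint.
#' @param noiseSd Gaussian noise SD (default 0.5).
#' @param maxCorr maximum absolute prototype correlation (default 0.3).
#' @param grid optional [GridSpec-class].
#' @param seed integer seed for the whole generation.
#' @return a [SyntheticDataset-class].
#' @examples
#' d <- generateSynthetic(S = 20, kTrue = 2, groupSizes = c(5, 5), seed = 7)
#' inferGrid(qValues(d@qsorts))
#' @export
generateSynthetic <- function(S, kTrue, groupSizes, noiseSd = 0.5,
                              maxCorr = 0.3, grid = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid)) grid <- defaultGrid(S)
  proto <- generatePrototypes(S, kTrue, maxCorr, seed = NULL)
  generateQSorts(proto, grid, groupSizes, noiseSd, seed = NULL)
}

#' A quasi-normal symmetric grid for S statements
#'
#' Builds a forced-distribution grid with symmetric integer anchors and
#' capacities shaped like a discretized bell: capacities start at 1 at the
#' anchors and grow toward the middle, with the center adjusted so the total
#' is exactly S. Intended for synthetic data; real studies supply their own
#' grid.
#'
#' @param S number of statements (>= 5).
#' @param nCols odd number of grid columns; default chooses 7 for S <= 25,
#'   9 for S <= 35, 11 otherwise.
#' @return a [GridSpec-class].
#' @examples
#' defaultGrid(19)
#' defaultGrid(42)
#' @export
defaultGrid <- function(S, nCols = NULL) {
  if (S < 5L) stop("need at least 5 statements")
  if (is.null(nCols)) {
    nCols <- if (S <= 25L) 7L else if (S <= 35L) 9L else 11L
  }
  if (nCols %% 2L == 0L) stop("nCols must be odd")
  half <- (nCols - 1L) %/% 2L
  vals <- seq(-half, half)
  # triangular base shape, then pour the remaining statements into the
  # middle columns from the center outwards
  caps <- pmin(half + 1L - abs(vals), half + 1L)
  caps <- pmax(caps, 1L)
  rem <- S - sum(caps)
  if (rem < 0L) stop("too few statements for ", nCols, " columns")
  ord <- order(abs(vals), vals)
  i <- 1L
  while (rem > 0L) {
    caps[ord[i]] <- caps[ord[i]] + 1L
    i <- if (i == nCols) 1L else i + 1L
    rem <- rem - 1L
  }
  gridSpec(vals, caps)
}

#' Recovery accuracy of the pipeline on synthetic data
#'
#' Runs extraction + rotation + flagging on a synthetic dataset, matches
#' each estimated factor to a true prototype by maximum absolute correlation
#' between factor z-scores and prototype profiles, and returns the fraction
#' of participants flagged on the factor matched to their true group.
#'
#' @param dataset a [SyntheticDataset-class] with as many prototypes as
#'   extracted factors.
#' @param extraction `"pca"` or `"paf"`.
#' @param rotation rotation name as in [applyRotation()].
#' @param alpha flagging significance level.
#' @return fraction in `[0, 1]`.
#' @export
flaggingAccuracy <- function(dataset, extraction = "pca",
                             rotation = "varimax", alpha = 0.05) {
  stopifnot(is(dataset, "SyntheticDataset"))
  q <- dataset@qsorts
  k <- ncol(dataset@prototypes)
  r <- correlateQSorts(q)
  ext <- if (extraction == "pca") extractPCA(r, k) else extractPAF(r, k)
  rot <- applyRotation(ext, rotation)
  tau <- significanceThreshold(nrow(q@values), alpha)
  flags <- flagQSorts(rot, tau)
  scores <- factorZScores(q, flags, rot)
  cm <- factorCorrelations(dataset@prototypes, scores)
  mm <- matchFactors(cm)   # reference = prototypes
  protoOf <- mm$reference[order(mm$factor)]
  hits <- 0L
  for (j in seq_len(k)) {
    members <- flags@flagged[[j]]
    hits <- hits + sum(dataset@trueLabels[members] == protoOf[j])
  }
  hits / length(dataset@trueLabels)
}
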