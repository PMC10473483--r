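# Flagging, factor z-scores, factor arrays, distinguishing statements.

#' Loading significance threshold
#'
#' The conventional Q-methodology criterion for a significant loading:
#' `tau = z_(1 - alpha/2) / sqrt(S)` with S the number of statements. For
#' S = 19 and alpha = 0.05 this is about 0.45; for S = 42 about 0.30.
#'
#' @param nStatements number of statements (>= 2).
#' @param alpha two-sided significance level, in (0, 1).
#' @return the threshold tau.
#' @export
significanceThreshold <- function(nStatements, alpha = 0.05) {
  if (nStatements < 2L) stop("need at least 2 statements")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stats::qnorm(1 - alpha / 2) / sqrt(nStatements)
}

#' Flag the Q-sorts defining each factor
#'
#' A sort is *loaded* on factor j when `|a_ij| >= tau` — non-exclusive, so
#' one sort can count on several factors (this is the count reported when
#' summarizing how many sorts each factor attracts). A sort is *flagged* for
#' scoring only when, additionally, factor j holds the majority of its
#' communality (`a_ij^2 > h2_i / 2`) — which at most one factor can, so
#' flagged sets are exclusive. Sorts significant somewhere but flagged
#' nowhere (typically significant on two or more factors) are *confounded*;
#' sorts significant nowhere are *null*, so the flagged sets, confounded and
#' null partition the participants.
#'
#' @param loadings a rotated P x k matrix, a [RotationResult-class] or an
#'   [ExtractionResult-class].
#' @param tau significance threshold (> 0), from [significanceThreshold()].
#' @return a [FlagResult-class].
#' @examples
#' flagQSorts(rbind(A = c(0.9, 0.1), B = c(0.5, 0.5)), tau = 0.45)
#' @export
flagQSorts <- function(loadings, tau) {
  a <- factorLoadingsOf(loadings)
  if (tau <= 0) stop("tau must be positive")
  ids <- rownames(a)
  if (is.null(ids)) ids <- paste0("P", seq_len(nrow(a)))
  k <- ncol(a)
  h2 <- rowSums(a^2)
  sig <- abs(a) >= tau
  major <- a^2 > h2 / 2
  loaded <- lapply(seq_len(k), function(j) ids[sig[, j]])
  flagged <- lapply(seq_len(k), function(j) ids[sig[, j] & major[, j]])
  names(loaded) <- names(flagged) <- colnames(a)
  isFlagged <- rowSums(sig & major) > 0
  nSig <- rowSums(sig)
  new("FlagResult", threshold = tau, loaded = loaded, flagged = flagged,
      confounded = ids[nSig >= 1 & !isFlagged],
      null = ids[nSig == 0])
}

# Accept a matrix, RotationResult or ExtractionResult wherever loadings are
# consumed.
factorLoadingsOf <- function(x) {
  if (is(x, "RotationResult")) return(x@rotated)
  if (is(x, "ExtractionResult")) return(x@loadings)
  as.matrix(x)
}

# Reflect grid values about the grid midpoint (min+max)/2; for a symmetric
# grid this is plain negation.
.mirrorValues <- function(v, grid) {
  lo <- min(grid@columnValues)
  hi <- max(grid@columnValues)
  (lo + hi) - v
}

#' Factor z-scores and factor arrays
#'
#' For each factor, the flagged Q-sorts are combined into a weighted
#' composite ranking using Brown-style weights `w = f / (1 - f^2)` where f
#' is the sort's loading (clipped to |f| <= 0.999). Flagged sorts with
#' negative loadings express the opposing view and enter with their
#' statement values reflected about the grid midpoint (and weight |w|). The
#' composite is standardized across statements into the factor z-scores, and
#' the z-scores are mapped back onto the grid — descending z fills grid
#' columns from the positive anchor downward, respecting capacities, ties
#' broken by ascending statement id — to give the integer factor array, an
#' idealized Q-sort for that factor.
#'
#' @param q the [QSortMatrix-class] the loadings came from.
#' @param flags a [FlagResult-class]; each factor needs at least one flagged
#'   sort.
#' @param loadings the rotated loadings the flags were computed from
#'   (matrix, [RotationResult-class] or [ExtractionResult-class]).
#' @param useAllSignificant use the non-exclusive `loaded` sets instead of
#'   the exclusive `flagged` sets (default FALSE).
#' @param fallback when a factor's member set is empty, fall back to its
#'   non-exclusive loaded set, and failing that to the single sort with the
#'   largest absolute loading, instead of erroring (default FALSE; the
#'   factorial runner enables it so unrotated solutions, whose later factors
#'   often hold no sort's communality majority, can still be scored).
#' @return a [FactorScores-class].
#' @export
factorZScores <- function(q, flags, loadings, useAllSignificant = FALSE,
                          fallback = FALSE) {
  stopifnot(is(q, "QSortMatrix"), is(flags, "FlagResult"))
  a <- factorLoadingsOf(loadings)
  ids <- rownames(a)
  if (is.null(ids)) ids <- paste0("P", seq_len(nrow(a)))
  if (!all(ids %in% q@participantIds)) {
    stop("loadings rows do not match the Q-sort participants")
  }
  m <- qValues(q)
  k <- ncol(a)
  sets <- if (useAllSignificant) flags@loaded else flags@flagged
  z <- matrix(NA_real_, nrow(m), k,
              dimnames = list(rownames(m), colnames(a)))
  arrays <- matrix(NA_integer_, nrow(m), k, dimnames = dimnames(z))
  weights <- vector("list", k)
  names(weights) <- colnames(a)

  for (j in seq_len(k)) {
    members <- sets[[j]]
    if (length(members) == 0L && fallback) {
      members <- flags@loaded[[j]]
      if (length(members) == 0L) {
        members <- ids[which.max(abs(a[, j]))]
      }
    }
    if (length(members) == 0L) {
      stop(sprintf("factor %d has no flagged Q-sorts; its scores are undefined",
                   j))
    }
    f <- a[match(members, ids), j]
    if (any(abs(f) >= 1)) {
      warning(sprintf("loading(s) with |f| >= 1 on factor %d clipped to 0.999",
                      j))
    }
    f <- pmax(pmin(f, 0.999), -0.999)
    w <- f / (1 - f^2)
    names(w) <- members
    weights[[j]] <- w
    vals <- m[, match(members, q@participantIds), drop = FALSE]
    neg <- f < 0
    if (any(neg)) {
      vals[, neg] <- .mirrorValues(vals[, neg, drop = FALSE], q@grid)
    }
    composite <- as.vector(vals %*% abs(w))
    sdc <- stats::sd(composite)
    if (sdc == 0) stop(sprintf("factor %d composite has zero variance", j))
    z[, j] <- (composite - mean(composite)) / sdc
    arrays[, j] <- .zToArray(z[, j], q@grid, q@statementIds)
  }
  new("FactorScores", z = z, weights = weights, arrays = arrays,
      grid = q@grid)
}

# Map a z column to the integer grid: sort statements by descending z (ties
# by ascending statement id), fill capacities from the positive anchor down.
.zToArray <- function(zcol, grid, statementIds) {
  ord <- order(-zcol, statementIds)
  vals <- rev(grid@columnValues)
  caps <- rev(grid@columnCapacities)
  assigned <- rep(vals, caps)
  out <- integer(length(zcol))
  out[ord] <- assigned
  out
}

#' Distinguishing statements per factor
#'
#' Statement s distinguishes factor f when `|z_sf - z_sg| >= d` for every
#' other factor g. Both z columns are unit variance, so d is a difference in
#' SD units (an effect size); the boundary is included.
#'
#' @param scores a [FactorScores-class] or an S x k z-score matrix (rows
#'   named by statement id); needs k >= 2.
#' @param d effect size threshold (default 0.80).
#' @return a [DistinguishingSet-class].
#' @export
distinguishingStatements <- function(scores, d = 0.80) {
  z <- if (is(scores, "FactorScores")) scores@z else as.matrix(scores)
  k <- ncol(z)
  if (k < 2L) stop("distinguishing statements need at least 2 factors")
  ids <- rownames(z)
  if (is.null(ids)) ids <- seq_len(nrow(z))
  ids <- as.integer(ids)
  sets <- lapply(seq_len(k), function(f) {
    gap <- apply(abs(z[, f] - z[, -f, drop = FALSE]), 1, min)
    ids[gap >= d]
  })
  names(sets) <- colnames(z)
  new("DistinguishingSet", statements = sets, effectSize = d)
}
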