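#' @import methods
NULL

#' GridSpec: a forced quasi-normal sorting grid
#'
#' Describes the grid participants sort statements into: the ordered column
#' values (e.g. -3..+3) and how many statements each column holds. The
#' capacities must sum to the number of statements in the Q-sample.
#'
#' @slot columnValues integer vector, strictly increasing (the grid anchors
#'   and the values between them).
#' @slot columnCapacities positive integer vector, one entry per column;
#'   `sum(columnCapacities)` equals the number of statements.
#'
#' @seealso [gridSpec()], [inferGrid()]
#' @export
setClass("GridSpec", representation(
  columnValues = "integer",
  columnCapacities = "integer"
))

setValidity("GridSpec", function(object) {
  v <- object@columnValues
  cap <- object@columnCapacities
  if (length(v) == 0L) return("columnValues must be non-empty")
  if (length(v) != length(cap)) {
    return("columnValues and columnCapacities must have equal length")
  }
  if (any(diff(v) <= 0L)) return("columnValues must be strictly increasing")
  if (any(cap <= 0L)) return("columnCapacities must be positive")
  TRUE
})

#' QSortMatrix: a statements-by-participants matrix of rankings
#'
#' The canonical Q-sort container: an S x P integer matrix with statements in
#' rows and participants (Q-sorts) in columns, together with the grid the
#' rankings were sorted into. With `forced = TRUE` every column's value
#' histogram must equal the grid capacities exactly (forced distribution);
#' with `forced = FALSE` only the value range is checked.
#'
#' @slot values integer matrix, S rows (statements) by P columns
#'   (participants).
#' @slot grid a [GridSpec-class].
#' @slot participantIds character vector of column labels.
#' @slot statementIds integer vector of row labels (unique, contiguous
#'   from 1).
#' @slot forced logical scalar; whether the forced-distribution constraint is
#'   enforced.
#'
#' @seealso [qSortMatrix()], [readQSorts()]
#' @export
setClass("QSortMatrix", representation(
  values = "matrix",
  grid = "GridSpec",
  participantIds = "character",
  statementIds = "integer",
  forced = "logical"
))

setValidity("QSortMatrix", function(object) {
  m <- object@values
  g <- object@grid
  if (!is.numeric(m)) return("values must be a numeric matrix")
  if (any(m != round(m))) return("values must be integers")
  if (nrow(m) != length(object@statementIds)) {
    return("statementIds length must equal nrow(values)")
  }
  if (ncol(m) != length(object@participantIds)) {
    return("participantIds length must equal ncol(values)")
  }
  if (anyDuplicated(object@participantIds)) {
    return("participantIds must be unique")
  }
  if (!identical(sort(object@statementIds), seq_len(nrow(m)))) {
    return("statementIds must be unique and contiguous from 1")
  }
  if (sum(g@columnCapacities) != nrow(m)) {
    return(sprintf("grid capacities sum to %d but there are %d statements",
                   sum(g@columnCapacities), nrow(m)))
  }
  bad <- !(m %in% g@columnValues)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(m)), arr.ind = TRUE)[1, ]
    return(sprintf(
      "value %s at statement %s, participant '%s' is outside the grid values",
      format(m[idx[1], idx[2]]), object@statementIds[idx[1]],
      object@participantIds[idx[2]]))
  }
  if (isTRUE(object@forced)) {
    for (j in seq_len(ncol(m))) {
      h <- tabulate(match(m[, j], g@columnValues), length(g@columnValues))
      if (!identical(h, as.integer(g@columnCapacities))) {
        return(sprintf(
          "participant '%s' violates the forced distribution: counts (%s) vs capacities (%s)",
          object@participantIds[j], paste(h, collapse = ","),
          paste(g@columnCapacities, collapse = ",")))
      }
    }
  }
  TRUE
})

#' ExtractionResult: loadings from a by-person factor extraction
#'
#' @slot loadings P x k numeric matrix of Q-sort loadings (rows named by
#'   participant id).
#' @slot eigenvalues numeric vector of length k, non-increasing.
#' @slot communalities numeric vector of length P; row sums of squared
#'   loadings.
#' @slot method `"pca"` or `"paf"`.
#' @slot nStatements integer; number of statements the correlations were
#'   computed over.
#' @slot iterations integer; PAF iterations to convergence (0 for PCA).
#'
#' @seealso [extractPCA()], [extractPAF()]
#' @export
setClass("ExtractionResult", representation(
  loadings = "matrix",
  eigenvalues = "numeric",
  communalities = "numeric",
  method = "character",
  nStatements = "integer",
  iterations = "integer"
))

setValidity("ExtractionResult", function(object) {
  k <- ncol(object@loadings)
  if (length(object@eigenvalues) != k) {
    return("eigenvalues length must equal ncol(loadings)")
  }
  if (is.unsorted(rev(object@eigenvalues), strict = FALSE)) {
    return("eigenvalues must be non-increasing")
  }
  if (length(object@communalities) != nrow(object@loadings)) {
    return("communalities length must equal nrow(loadings)")
  }
  if (any(object@communalities < -1e-8 | object@communalities > 1 + 1e-8)) {
    return("communalities must lie in [0, 1]")
  }
  if (!object@method %in% c("pca", "paf")) {
    return("method must be 'pca' or 'paf'")
  }
  TRUE
})

#' RotationResult: an orthogonally rotated loading matrix
#'
#' @slot rotated P x k numeric matrix of rotated loadings.
#' @slot transform k x k orthogonal matrix `T` with `rotated = loadings %*% T`.
#' @slot criterion orthomax objective of the rotated matrix at the stated
#'   gamma.
#' @slot gamma the orthomax weight used (0 Quartimax, 1 Varimax, k/2 Equamax).
#' @slot kaiserNormalize whether rows were Kaiser-normalized during rotation.
#' @slot sweeps number of full Jacobi sweeps performed.
#' @slot converged FALSE when `maxSweeps` was reached before the criterion
#'   change fell below tolerance.
#' @slot sweepCriteria criterion value (on the working, possibly normalized,
#'   matrix) after each sweep; non-decreasing.
#'
#' @seealso [rotateOrthomax()], [noRotation()]
#' @export
setClass("RotationResult", representation(
  rotated = "matrix",
  transform = "matrix",
  criterion = "numeric",
  gamma = "numeric",
  kaiserNormalize = "logical",
  sweeps = "integer",
  converged = "logical",
  sweepCriteria = "numeric"
))

setValidity("RotationResult", function(object) {
  Tm <- object@transform
  k <- ncol(object@rotated)
  if (!all(dim(Tm) == c(k, k))) return("transform must be k x k")
  if (max(abs(crossprod(Tm) - diag(k))) > 1e-8) {
    return("transform must be orthogonal")
  }
  TRUE
})

#' FlagResult: significant and flagged Q-sorts per factor
#'
#' `loaded` lists, per factor, every Q-sort whose absolute loading reaches
#' the significance threshold (non-exclusive: one sort may appear under
#' several factors). `flagged` additionally requires the factor to hold a
#' majority of the sort's communality (a_ij^2 > h2_i / 2), which can hold for
#' at most one factor, so the flagged sets are disjoint. Sorts significant
#' somewhere but flagged on none are `confounded`; sorts significant nowhere
#' are `null`; the flagged sets, confounded and null partition the
#' participants.
#'
#' @slot threshold the significance threshold tau applied to |loadings|.
#' @slot loaded named list (one element per factor) of participant ids with
#'   |a_ij| >= tau.
#' @slot flagged named list of participant ids used for factor scoring.
#' @slot confounded participant ids significant on some factor but flagged
#'   on none.
#' @slot null participant ids significant on no factor.
#'
#' @seealso [flagQSorts()], [significanceThreshold()]
#' @export
setClass("FlagResult", representation(
  threshold = "numeric",
  loaded = "list",
  flagged = "list",
  confounded = "character",
  null = "character"
))

setValidity("FlagResult", function(object) {
  fl <- unlist(object@flagged, use.names = FALSE)
  if (anyDuplicated(fl)) return("flagged sets must be pairwise disjoint")
  for (j in seq_along(object@flagged)) {
    if (!all(object@flagged[[j]] %in% object@loaded[[j]])) {
      return("every flagged id must also be loaded on the same factor")
    }
  }
  if (any(object@confounded %in% fl) || any(object@null %in% fl)) {
    return("flagged, confounded and null must be disjoint")
  }
  TRUE
})

#' FactorScores: factor z-scores and integer factor arrays
#'
#' @slot z S x k numeric matrix of factor z-scores (each column mean 0,
#'   SD 1 across statements), rows named by statement id.
#' @slot weights named list per factor: participant -> weight f / (1 - f^2).
#' @slot arrays S x k integer matrix; each column is an idealized Q-sort
#'   drawn from the grid values with the grid's exact histogram.
#' @slot grid the [GridSpec-class] the arrays satisfy.
#'
#' @seealso [factorZScores()]
#' @export
setClass("FactorScores", representation(
  z = "matrix",
  weights = "list",
  arrays = "matrix",
  grid = "GridSpec"
))

setValidity("FactorScores", function(object) {
  if (!all(dim(object@z) == dim(object@arrays))) {
    return("z and arrays must have identical dimensions")
  }
  mu <- colMeans(object@z)
  sdv <- apply(object@z, 2, stats::sd)
  if (any(abs(mu) > 1e-8) || any(abs(sdv - 1) > 1e-8)) {
    return("each z column must have mean 0 and SD 1")
  }
  g <- object@grid
  for (j in seq_len(ncol(object@arrays))) {
    h <- tabulate(match(object@arrays[, j], g@columnValues),
                  length(g@columnValues))
    if (!identical(h, as.integer(g@columnCapacities))) {
      return(sprintf("factor array %d does not satisfy the grid histogram", j))
    }
  }
  TRUE
})

#' DistinguishingSet: statements distinguishing each factor
#'
#' A statement distinguishes factor f when its z-score on f differs from its
#' z-score on every other factor by at least the effect size d (raw
#' difference of unit-variance scores, so in SD units; boundary included).
#'
#' @slot statements named list per factor of distinguishing statement ids.
#' @slot effectSize the effect size d used.
#'
#' @seealso [distinguishingStatements()]
#' @export
setClass("DistinguishingSet", representation(
  statements = "list",
  effectSize = "numeric"
))

#' SyntheticDataset: generated Q-sorts with known viewpoint structure
#'
#' @slot qsorts a [QSortMatrix-class] of forced-distribution rankings.
#' @slot trueLabels integer vector (named by participant id) giving each
#'   participant's latent prototype index.
#' @slot prototypes S x k_true matrix of standardized latent viewpoint
#'   profiles.
#'
#' @seealso [generateSynthetic()], [generateQSorts()]
#' @export
setClass("SyntheticDataset", representation(
  qsorts = "QSortMatrix",
  trueLabels = "integer",
  prototypes = "matrix"
))

setValidity("SyntheticDataset", function(object) {
  if (length(object@trueLabels) != ncol(object@qsorts@values)) {
    return("trueLabels must cover every participant")
  }
  if (any(object@trueLabels < 1L) ||
      any(object@trueLabels > ncol(object@prototypes))) {
    return("trueLabels must index prototype columns")
  }
  TRUE
})

#' ComparisonReport: the full rotation-impact factorial
#'
#' Produced by [runRotationImpact()]: for every extraction x rotation
#' condition, the loaded counts, distinguishing-statement counts,
#' changed-statement ledgers against no-rotation, factor-score correlation
#' matrices and max-|r| factor matches.
#'
#' @slot k number of factors extracted.
#' @slot threshold loading significance threshold used for flagging.
#' @slot effectSize distinguishing-statement effect size.
#' @slot conditions named list keyed `"<extraction>:<rotation>"`, each a list
#'   with elements `extraction`, `rotation`, `flags`, `scores`,
#'   `distinguishing`.
#' @slot summary data.frame: one row per condition x factor with loaded and
#'   distinguishing counts, the matched no-rotation factor, its correlation,
#'   and changed-statement counts.
#' @slot correlations nested list: per extraction, correlation matrices
#'   between every pair of rotation conditions' factor scores.
#' @slot matches nested list: per extraction and rotation, the match of its
#'   factors to the no-rotation factors.
#' @slot ledgers nested list: per extraction, rotation and matched factor,
#'   the common / new / dropped distinguishing statement sets.
#'
#' @seealso [runRotationImpact()], [exportReport()]
#' @export
setClass("ComparisonReport", representation(
  k = "integer",
  threshold = "numeric",
  effectSize = "numeric",
  conditions = "list",
  summary = "data.frame",
  correlations = "list",
  matches = "list",
  ledgers = "list"
))
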