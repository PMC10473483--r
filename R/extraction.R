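# By-person correlation and factor extraction (PCA, iterated PAF).
#
# Q-methodology factors the P x P correlation matrix between participants'
# Q-sorts computed across statements, so "variables" here are people.

#' Correlate Q-sorts across statements
#'
#' Pearson correlation between every pair of Q-sort columns, computed over
#' the S statements. This is the by-person correlation matrix that the
#' extraction step factors.
#'
#' @param q a [QSortMatrix-class] with at least 3 statements.
#' @return P x P symmetric numeric matrix with unit diagonal, dimnames the
#'   participant ids.
#' @examples
#' d <- generateSynthetic(S = 20, kTrue = 2, groupSizes = c(4, 4), seed = 1)
#' r <- correlateQSorts(d@qsorts)
#' @export
correlateQSorts <- function(q) {
  stopifnot(is(q, "QSortMatrix"))
  m <- qValues(q)
  if (nrow(m) < 3L) stop("need at least 3 statements to correlate Q-sorts")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance Q-sort(s): ",
         paste(q@participantIds[sds == 0], collapse = ", "))
  }
  r <- stats::cor(m)
  diag(r) <- 1
  r
}

# Fix loading signs so each column's largest-|.| element is positive.
# Deterministic: ties broken by the first such element.
.signFix <- function(a) {
  s <- apply(a, 2, function(col) {
    i <- which.max(abs(col))
    if (col[i] < 0) -1 else 1
  })
  sweep(a, 2, s, `*`)
}

.checkCorr <- function(r) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r) || max(abs(r - t(r))) > 1e-10) {
    stop("correlation matrix must be square and symmetric")
  }
  r
}

#' Extract factors by principal components
#'
#' Top-k eigenpairs of the by-person correlation matrix; loading column j is
#' eigenvector j scaled by the square root of its eigenvalue. Column signs
#' follow the largest-|loading|-positive convention; eigenvalue ties keep
#' the eigendecomposition's order.
#'
#' @param r P x P correlation matrix from [correlateQSorts()].
#' @param k number of factors, `1 <= k <= P`.
#' @param nStatements optional; number of statements the correlations were
#'   computed over, recorded for downstream thresholding.
#' @return an [ExtractionResult-class] with `method = "pca"`.
#' @examples
#' d <- generateSynthetic(S = 20, kTrue = 2, groupSizes = c(4, 4), seed = 1)
#' extractPCA(correlateQSorts(d@qsorts), k = 2)
#' @export
extractPCA <- function(r, k, nStatements = NA_integer_) {
  r <- .checkCorr(r)
  P <- nrow(r)
  if (k < 1L || k > P) stop("k must lie in 1..", P)
  e <- eigen(r, symmetric = TRUE)
  ev <- e$values[seq_len(k)]
  a <- .signFix(e$vectors[, seq_len(k), drop = FALSE] %*%
                  diag(sqrt(pmax(ev, 0)), k))
  rownames(a) <- rownames(r)
  colnames(a) <- paste0("F", seq_len(k))
  new("ExtractionResult", loadings = a, eigenvalues = ev,
      communalities = pmin(rowSums(a^2), 1), method = "pca",
      nStatements = as.integer(nStatements), iterations = 0L)
}

#' Extract factors by iterated principal-axis factoring
#'
#' Communalities start at the squared multiple correlations
#' h2_i = 1 - 1/(r^-1)_ii, then iterate: place h2 on the diagonal of r,
#' eigendecompose, rebuild h2 as the row sums of squared top-k loadings,
#' until the largest communality change falls below `tol`. Heywood cases
#' (h2 > 1) are clipped to 1 with a warning. The centroid method used
#' historically in Q-methodology is an approximation of this procedure, so
#' PAF serves as its modern stand-in.
#'
#' When there are more Q-sorts than statements the by-person correlation
#' matrix is rank-deficient and squared multiple correlations are undefined;
#' `init = "smc"` then falls back to unit initial communalities (with a
#' message), which `init = "ones"` selects directly.
#'
#' @param r P x P correlation matrix.
#' @param init initial communalities: `"smc"` (default) or `"ones"`.
#' @param k number of factors.
#' @param tol convergence tolerance on the max absolute communality change.
#' @param maxIter iteration cap; exceeding it is an error carrying the last
#'   change.
#' @param nStatements optional; as in [extractPCA()].
#' @return an [ExtractionResult-class] with `method = "paf"`.
#' @examples
#' d <- generateSynthetic(S = 20, kTrue = 2, groupSizes = c(4, 4), seed = 1)
#' extractPAF(correlateQSorts(d@qsorts), k = 2)
#' @export
extractPAF <- function(r, k, tol = 1e-6, maxIter = 200L,
                       nStatements = NA_integer_, init = c("smc", "ones")) {
  r <- .checkCorr(r)
  init <- match.arg(init)
  P <- nrow(r)
  if (k < 1L || k > P) stop("k must lie in 1..", P)
  h2 <- rep(1, P)
  if (init == "smc") {
    if (rcond(r) > 1e-10) {
      h2 <- 1 - 1 / diag(solve(r))
    } else {
      message("correlation matrix is rank-deficient; initializing ",
              "communalities at 1 instead of squared multiple correlations")
    }
  }
  heywood <- FALSE
  a <- NULL
  ev <- NULL
  for (it in seq_len(maxIter)) {
    rd <- r
    diag(rd) <- h2
    e <- eigen(rd, symmetric = TRUE)
    ev <- e$values[seq_len(k)]
    a <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(ev, 0)), k)
    h2new <- rowSums(a^2)
    if (any(h2new > 1)) {
      heywood <- TRUE
      h2new <- pmin(h2new, 1)
    }
    delta <- max(abs(h2new - h2))
    h2 <- h2new
    if (delta < tol) {
      if (heywood) {
        warning("Heywood case: communalities above 1 were clipped to 1")
      }
      a <- .signFix(a)
      rownames(a) <- rownames(r)
      colnames(a) <- paste0("F", seq_len(k))
      names(h2) <- rownames(r)
      return(new("ExtractionResult", loadings = a, eigenvalues = ev,
                 communalities = h2, method = "paf",
                 nStatements = as.integer(nStatements), iterations = it))
    }
  }
  stop(sprintf(
    "principal-axis factoring did not converge in %d iterations (last change %.3g)",
    maxIter, delta))
}
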