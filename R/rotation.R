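# Orthomax family of orthogonal rotations via pairwise Jacobi sweeps.
#
# The single criterion Q(L) = sum_j [ sum_i l_ij^4 - (gamma/P) (sum_i l_ij^2)^2 ]
# covers Quartimax (gamma = 0), Varimax (gamma = 1) and Equamax (gamma = k/2).
# Each sweep visits every factor pair in fixed lexicographic order and applies
# the closed-form optimal planar rotation for that pair, so results are
# bit-reproducible.

#' Orthomax rotation criterion
#'
#' Direct evaluation of the objective maximized by [rotateOrthomax()]:
#' `sum_j [ sum_i l_ij^4 - (gamma/P) (sum_i l_ij^2)^2 ]` with P the number of
#' rows.
#'
#' @param a numeric loading matrix.
#' @param gamma orthomax weight (0 Quartimax, 1 Varimax, k/2 Equamax).
#' @return the criterion value (scalar).
#' @export
orthomaxCriterion <- function(a, gamma) {
  P <- nrow(a)
  sum(colSums(a^4) - (gamma / P) * colSums(a^2)^2)
}

# Closed-form optimal angle for rotating columns (x, y) under orthomax.
# With u = x^2 - y^2, v = 2xy: tan(4 phi) resolves via atan2 of
#   num = 2 * (sum(uv) - gamma * sum(u) * sum(v) / P)
#   den = sum(u^2 - v^2) - gamma * (sum(u)^2 - sum(v)^2) / P
.pairAngle <- function(x, y, gamma) {
  P <- length(x)
  u <- x^2 - y^2
  v <- 2 * x * y
  num <- 2 * (sum(u * v) - gamma * sum(u) * sum(v) / P)
  den <- sum(u^2 - v^2) - gamma * (sum(u)^2 - sum(v)^2) / P
  if (num == 0 && den == 0) return(0)
  atan2(num, den) / 4
}

#' Rotate a loading matrix with an orthomax criterion
#'
#' Maximizes the orthomax objective by repeated sweeps of pairwise planar
#' (Jacobi) rotations over all factor pairs in lexicographic order, each
#' solving the closed-form optimal angle for that pair. With
#' `kaiserNormalize = TRUE` (the conventional default) rows are divided by
#' the square roots of their communalities before rotation and rescaled
#' after; zero-communality rows are passed through unnormalized. The sweep
#' loop stops when a full sweep improves the criterion by less than `tol`,
#' or flags non-convergence after `maxSweeps`. Finally columns are re-signed
#' (largest |loading| positive) and re-ordered by descending explained
#' variance, with the accumulated orthogonal transform updated to match, so
#' `rotated == loadings %*% transform` always holds.
#'
#' @param a an [ExtractionResult-class] or a plain P x k loading matrix.
#' @param gamma orthomax weight: 0 Quartimax, 1 Varimax, `k/2` Equamax.
#' @param kaiserNormalize logical; Kaiser row normalization (default TRUE).
#' @param tol convergence tolerance on the criterion change per sweep.
#' @param maxSweeps sweep cap; reaching it sets `converged = FALSE` on the
#'   result (with a warning) rather than erroring.
#' @return a [RotationResult-class].
#' @examples
#' d <- generateSynthetic(S = 20, kTrue = 2, groupSizes = c(4, 4), seed = 1)
#' a <- extractPCA(correlateQSorts(d@qsorts), k = 2)
#' rotateOrthomax(a, gamma = 1)   # Varimax
#' @export
rotateOrthomax <- function(a, gamma = 1, kaiserNormalize = TRUE,
                           tol = 1e-8, maxSweeps = 100L) {
  A <- if (is(a, "ExtractionResult")) a@loadings else as.matrix(a)
  k <- ncol(A)
  if (k < 1L) stop("loading matrix must have at least one column")
  if (!is.finite(gamma) || gamma < 0) stop("gamma must be finite and >= 0")

  h <- sqrt(rowSums(A^2))
  scale <- if (kaiserNormalize) ifelse(h > 0, h, 1) else rep(1, nrow(A))
  W <- A / scale
  Tm <- diag(k)
  sweepCrit <- numeric(0)
  crit <- orthomaxCriterion(W, gamma)
  converged <- TRUE
  sweeps <- 0L

  if (k >= 2L) {
    converged <- FALSE
    for (s in seq_len(maxSweeps)) {
      for (p in seq_len(k - 1L)) {
        for (q in seq((p + 1L), k)) {
          phi <- .pairAngle(W[, p], W[, q], gamma)
          if (abs(phi) < 1e-14) next
          cs <- cos(phi); sn <- sin(phi)
          R <- matrix(c(cs, -sn, sn, cs), 2, 2, byrow = TRUE)
          W[, c(p, q)] <- W[, c(p, q)] %*% R
          Tm[, c(p, q)] <- Tm[, c(p, q)] %*% R
        }
      }
      sweeps <- s
      newCrit <- orthomaxCriterion(W, gamma)
      sweepCrit <- c(sweepCrit, newCrit)
      if (newCrit - crit < tol) {
        crit <- newCrit
        converged <- TRUE
        break
      }
      crit <- newCrit
    }
    if (!converged) {
      warning(sprintf("orthomax rotation did not converge in %d sweeps",
                      maxSweeps))
    }
  }

  L <- (W * scale)
  # re-sign and re-order; fold both into the transform
  sgn <- apply(L, 2, function(col) if (col[which.max(abs(col))] < 0) -1 else 1)
  L <- sweep(L, 2, sgn, `*`)
  Tm <- sweep(Tm, 2, sgn, `*`)
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  Tm <- Tm[, ord, drop = FALSE]
  rownames(L) <- rownames(A)
  colnames(L) <- paste0("F", seq_len(k))

  new("RotationResult", rotated = L, transform = Tm,
      criterion = orthomaxCriterion(L, gamma), gamma = gamma,
      kaiserNormalize = kaiserNormalize, sweeps = sweeps,
      converged = converged, sweepCriteria = sweepCrit)
}

#' Varimax, Quartimax and Equamax shorthands
#'
#' Thin wrappers over [rotateOrthomax()] fixing gamma at 1, 0 and k/2
#' respectively.
#'
#' @inheritParams rotateOrthomax
#' @return a [RotationResult-class].
#' @export
rotateVarimax <- function(a, kaiserNormalize = TRUE, tol = 1e-8,
                          maxSweeps = 100L) {
  rotateOrthomax(a, gamma = 1, kaiserNormalize = kaiserNormalize,
                 tol = tol, maxSweeps = maxSweeps)
}

#' @rdname rotateVarimax
#' @export
rotateQuartimax <- function(a, kaiserNormalize = TRUE, tol = 1e-8,
                            maxSweeps = 100L) {
  rotateOrthomax(a, gamma = 0, kaiserNormalize = kaiserNormalize,
                 tol = tol, maxSweeps = maxSweeps)
}

#' @rdname rotateVarimax
#' @export
rotateEquamax <- function(a, kaiserNormalize = TRUE, tol = 1e-8,
                          maxSweeps = 100L) {
  k <- if (is(a, "ExtractionResult")) ncol(a@loadings) else ncol(a)
  rotateOrthomax(a, gamma = k / 2, kaiserNormalize = kaiserNormalize,
                 tol = tol, maxSweeps = maxSweeps)
}

#' The no-rotation pass-through
#'
#' Identity transform: the rotated loadings are the extraction's loadings
#' unchanged; the orthomax criterion is still evaluated for reporting.
#'
#' @param a an [ExtractionResult-class] or loading matrix.
#' @param gamma gamma at which to report the criterion (default 1).
#' @return a [RotationResult-class] with `transform = I` and `sweeps = 0`.
#' @export
noRotation <- function(a, gamma = 1) {
  A <- if (is(a, "ExtractionResult")) a@loadings else as.matrix(a)
  k <- ncol(A)
  new("RotationResult", rotated = A, transform = diag(k),
      criterion = orthomaxCriterion(A, gamma), gamma = gamma,
      kaiserNormalize = FALSE, sweeps = 0L, converged = TRUE,
      sweepCriteria = numeric(0))
}

#' Map a rotation name to its orthomax gamma and run it
#'
#' Convenience dispatcher used by the comparison pipeline:
#' `"none"`, `"varimax"`, `"equamax"`, `"quartimax"`.
#'
#' @param a an [ExtractionResult-class] or loading matrix.
#' @param rotation rotation name.
#' @param ... passed to [rotateOrthomax()].
#' @return a [RotationResult-class].
#' @export
applyRotation <- function(a, rotation = c("none", "varimax", "equamax",
                                          "quartimax"), ...) {
  rotation <- match.arg(rotation)
  switch(rotation,
         none = noRotation(a),
         varimax = rotateVarimax(a, ...),
         equamax = rotateEquamax(a, ...),
         quartimax = rotateQuartimax(a, ...))
}
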