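#' @include AllClasses.R mesh.R
NULL

## Kabsch: proper rotation R minimizing ||X R - Y||_F (X, Y centred M x 3).
.optimalRotation <- function(X, Y) {
  S <- crossprod(X, Y)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  sv$u %*% D %*% t(sv$v)
}

#' Generalized Procrustes alignment
#'
#' Removes pose (translation and rotation, never scale or reflection) from a
#' registered shape cohort: every shape is centred at the origin and rotated
#' by the proper rotation minimizing its summed squared vertex distance to an
#' iteratively re-estimated mean shape. Iteration stops when the Frobenius
#' change of the mean shape falls below \code{tol}. Size is deliberately
#' preserved so that volume-like phenotypes survive alignment.
#'
#' @param cohort a \linkS4class{ShapeCohort} with at least two subjects.
#' @param tol convergence tolerance on the mean-shape Frobenius change.
#' @param maxIter maximum number of mean-update iterations.
#' @return list with \code{cohort} (aligned \linkS4class{ShapeCohort}) and
#'   \code{meanShape} (\code{M x 3} matrix).
#' @examples
#' \donttest{
#' tpl <- makeTemplate(1)
#' coh <- shapeCohort(c("a","b"),
#'                    list(vertices(tpl), vertices(tpl) + 5), faces(tpl))
#' out <- generalizedProcrustes(coh)
#' isAligned(out$cohort)
#' }
#' @export
generalizedProcrustes <- function(cohort, tol = 1e-9, maxIter = 100L) {
  d <- dim(cohort@shapes)
  N <- d[1L]; M <- d[2L]
  if (N < 2L) stop("generalized Procrustes needs at least 2 shapes")
  sh <- cohort@shapes
  ## centre every shape
  for (i in seq_len(N)) {
    Xi <- sh[i, , ]
    sh[i, , ] <- sweep(Xi, 2L, colMeans(Xi))
  }
  meanShape <- apply(sh, c(2L, 3L), mean)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    for (i in seq_len(N)) {
      Xi <- sh[i, , ]
      sh[i, , ] <- Xi %*% .optimalRotation(Xi, meanShape)
    }
    newMean <- apply(sh, c(2L, 3L), mean)
    delta <- sqrt(sum((newMean - meanShape)^2))
    meanShape <- newMean
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("generalized Procrustes did not converge in ", maxIter,
            " iterations; returning current state")
  out <- methods::new("ShapeCohort", subjectIds = cohort@subjectIds,
                      shapes = sh, templateFaces = cohort@templateFaces,
                      aligned = TRUE)
  list(cohort = out, meanShape = meanShape)
}

#' Two-shape orthogonal Procrustes residual
#'
#' Root-mean-square vertex distance between two centred shapes after the
#' optimal proper rotation of the first onto the second. Exposed mainly as a
#' cross-check for the generalized alignment.
#'
#' @param X,Y \code{M x 3} coordinate matrices.
#' @return list with \code{rotation} and \code{rmsd}.
#' @export
procrustesPair <- function(X, Y) {
  X <- sweep(X, 2L, colMeans(X))
  Y <- sweep(Y, 2L, colMeans(Y))
  R <- .optimalRotation(X, Y)
  Xr <- X %*% R
  list(rotation = R, rmsd = sqrt(mean(rowSums((Xr - Y)^2))))
}
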