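#' @include AllClasses.R mesh.R
NULL

#' Fit a linear shape-PCA model
#'
#' Principal-component analysis of the vectorized, Procrustes-aligned shapes:
#' the components are the top right-singular vectors of the centred
#' \code{N x 3M} data matrix and the eigenvalues are the squared singular
#' values divided by \code{N - 1} (the eigenvalues of the shape covariance
#' with its N-1 divisor). Component signs are fixed so that the largest
#' absolute loading of each component is positive, making downstream
#' association effect signs reproducible.
#'
#' @param cohort an aligned \linkS4class{ShapeCohort}.
#' @param nComponents number of components, \code{1..min(N-1, 3M)};
#'   default 16.
#' @return a \linkS4class{ShapePcaModel}.
#' @export
fitShapePca <- function(cohort, nComponents = 16L) {
  if (!cohort@aligned) stop("fitShapePca requires an aligned cohort")
  X <- vectorizeShapes(cohort)
  N <- nrow(X); P <- ncol(X)
  if (N < 2L) stop("shape PCA needs at least 2 subjects")
  nComponents <- as.integer(nComponents)
  if (nComponents < 1L || nComponents > min(N - 1L, P))
    stop("nComponents must be in 1..min(N-1, 3M)")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  if (N <= P) {
    ## Gram trick: eigenvectors of Xc Xc^t give left singular vectors cheaply
    G <- tcrossprod(Xc)
    eg <- eigen(G, symmetric = TRUE)
    d2 <- pmax(eg$values, 0)
    keep <- seq_len(nComponents)
    dk <- sqrt(d2[keep])
    ## relative threshold ~ sqrt(machine eps): below it the Gram eigenvector
    ## carries no signal and the back-projected component would be noise
    ok <- dk > max(dk[1L], .Machine$double.xmin) * 1e-7
    V <- matrix(0, nComponents, P)
    V[ok, ] <- t(crossprod(Xc, eg$vectors[, keep[ok], drop = FALSE]) %*%
                   diag(1 / dk[ok], sum(ok)))
    if (any(!ok)) {
      ## null directions: complete with an arbitrary orthonormal basis
      Q <- qr.Q(qr(cbind(t(V[ok, , drop = FALSE]), diag(P)[, seq_len(sum(!ok)), drop = FALSE])))
      V[!ok, ] <- t(Q[, sum(ok) + seq_len(sum(!ok)), drop = FALSE])
    }
    ev <- d2 / (N - 1)
  } else {
    sv <- svd(Xc, nu = 0, nv = nComponents)
    V <- t(sv$v)
    ev <- sv$d^2 / (N - 1)
  }
  ## sign convention: largest-|loading| entry positive
  for (i in seq_len(nComponents)) {
    j <- which.max(abs(V[i, ]))
    if (V[i, j] < 0) V[i, ] <- -V[i, ]
  }
  methods::new("ShapePcaModel",
               meanShape = mu,
               components = V,
               eigenvalues = ev[seq_len(nComponents)],
               totalVariance = sum(Xc^2) / (N - 1),
               nComponents = nComponents)
}

#' Encode shapes into PCA latent scores
#'
#' Linear encoder \eqn{z = V (s - \bar s)}.
#'
#' @param model a \linkS4class{ShapePcaModel}.
#' @param x a shape vector of length 3M, an \code{N x 3M} matrix, or a
#'   \linkS4class{ShapeCohort}.
#' @return latent matrix \code{N x n_z} (a vector input gives one row).
#' @export
pcaEncode <- function(model, x) {
  if (methods::is(x, "ShapeCohort")) x <- vectorizeShapes(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model@meanShape))
    stop("shape length ", ncol(x), " does not match model (",
         length(model@meanShape), ")")
  sweep(x, 2L, model@meanShape) %*% t(model@components)
}

#' Decode PCA latent scores to shapes
#'
#' Linear decoder \eqn{\hat s = \bar s + V^t z}.
#'
#' @param model a \linkS4class{ShapePcaModel}.
#' @param z latent vector of length n_z or matrix \code{N x n_z}.
#' @return shape matrix \code{N x 3M}.
#' @export
pcaDecode <- function(model, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != model@nComponents)
    stop("latent length ", ncol(z), " does not match model (",
         model@nComponents, ")")
  sweep(z %*% model@components, 2L, model@meanShape, "+")
}

#' Explained-variance ratios
#'
#' @param model a \linkS4class{ShapePcaModel}.
#' @return per-component fraction of total shape variance.
#' @export
explainedVariance <- function(model) {
  model@eigenvalues / model@totalVariance
}

#' Sweep one principal mode
#'
#' Shapes along a single component, either parametrically at
#' \eqn{\bar s + k \sqrt{\lambda_i} v_i} for the offsets in \code{k}, or
#' empirically as the average of the subjects whose latent score falls in
#' each quantile bin (the display used for latent-traversal figures).
#'
#' @param model a \linkS4class{ShapePcaModel}.
#' @param component component index.
#' @param k numeric offsets in sd units (parametric mode).
#' @param latentScores optional numeric vector of subject scores for this
#'   component; switches to empirical-quantile mode.
#' @param cohort aligned \linkS4class{ShapeCohort}; required with
#'   \code{latentScores}.
#' @param quantileBins list of \code{c(lo, hi)} quantile bins
#'   (empirical mode).
#' @return list of \code{M x 3} shape matrices, one per offset or bin.
#' @export
pcaModeSweep <- function(model, component, k = c(-3, -1, 0, 1, 3),
                         latentScores = NULL, cohort = NULL,
                         quantileBins = list(c(0, 0.01), c(0.095, 0.105),
                                             c(0.495, 0.505), c(0.895, 0.905),
                                             c(0.99, 1))) {
  if (component < 1L || component > model@nComponents)
    stop("component index out of range")
  if (is.null(latentScores)) {
    sd_i <- sqrt(model@eigenvalues[component])
    lapply(k, function(kk)
      unvectorizeShape(model@meanShape + kk * sd_i * model@components[component, ]))
  } else {
    if (is.null(cohort)) stop("empirical mode sweep needs the cohort")
    averageShapeByQuantile(cohort, latentScores, quantileBins)
  }
}

#' Average shapes within latent quantile bins
#'
#' For each quantile bin \code{[lo, hi]} of \code{values}, averages the
#' shapes of the subjects whose empirical quantile falls inside the bin.
#'
#' @param cohort a \linkS4class{ShapeCohort}.
#' @param values per-subject numeric scores.
#' @param bins list of \code{c(lo, hi)} quantile intervals.
#' @return list of \code{M x 3} average-shape matrices (NULL for empty bins).
#' @export
averageShapeByQuantile <- function(cohort, values,
                                   bins = list(c(0, 0.01), c(0.095, 0.105),
                                               c(0.495, 0.505), c(0.895, 0.905),
                                               c(0.99, 1))) {
  N <- dim(cohort@shapes)[1L]
  if (length(values) != N) stop("values length must equal cohort size")
  q <- (rank(values, ties.method = "average") - 0.5) / N
  lapply(bins, function(b) {
    idx <- which(q >= b[1L] & q <= b[2L])
    if (!length(idx)) return(NULL)
    apply(cohort@shapes[idx, , , drop = FALSE], c(2L, 3L), mean)
  })
}
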