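#' @include AllClasses.R mesh.R
NULL

#' Dense spectral basis of a graph Laplacian
#'
#' Full eigendecomposition of the Laplacian; the eigenvector columns form the
#' graph Fourier basis. Intended as an exact reference on small meshes (it is
#' never used during network training, which relies on the Chebyshev
#' recursion instead).
#'
#' @param laplacian a \linkS4class{GraphLaplacian}.
#' @return a \linkS4class{SpectralBasis}.
#' @export
spectralBasis <- function(laplacian) {
  eg <- eigen(as.matrix(laplacian@laplacian), symmetric = TRUE)
  methods::new("SpectralBasis", fourierBasis = eg$vectors,
               eigenvalues = eg$values)
}

#' Exact spectral convolution of two vertex signals
#'
#' The graph convolution defined through the Fourier basis:
#' \eqn{x \star y = U (U^t x \odot U^t y)} with \eqn{\odot} the element-wise
#' product. Exact but cubic in the vertex count; used as a test oracle.
#'
#' @param x,y numeric vertex signals of length M.
#' @param basis a \linkS4class{SpectralBasis}.
#' @return convolved signal of length M.
#' @export
spectralConvolveReference <- function(x, y, basis) {
  U <- basis@fourierBasis
  if (length(x) != nrow(U) || length(y) != nrow(U))
    stop("signal length must equal the number of vertices")
  if (max(abs(crossprod(U) - diag(ncol(U)))) > 1e-8)
    stop("basis is not orthogonal")
  as.numeric(U %*% (crossprod(U, x) * crossprod(U, y)))
}

## T_k(L) x for k = 0..K-1 via the standard Chebyshev recursion
## T_0 = I, T_1 = L, T_k = 2 L T_{k-1} - T_{k-2}; returns list of K matrices.
.chebBasisSignals <- function(L, x, K) {
  out <- vector("list", K)
  out[[1L]] <- x
  if (K >= 2L) out[[2L]] <- as.matrix(L %*% x)
  if (K >= 3L) for (k in 3:K)
    out[[k]] <- as.matrix(2 * (L %*% out[[k - 1L]]) - out[[k - 2L]])
  out
}

#' Chebyshev polynomial graph filter
#'
#' Applies the localized spectral filter
#' \eqn{y = \sum_{k=0}^{K-1} T_k(\tilde L)\, x\, \xi_k}
#' where \eqn{T_k} are Chebyshev polynomials generated by the standard
#' recursion \eqn{T_0 = I}, \eqn{T_1 = \tilde L},
#' \eqn{T_k = 2 \tilde L T_{k-1} - T_{k-2}} on the rescaled Laplacian.
#' Only sparse matrix-vector products are used (no eigendecomposition), and
#' the output at a vertex depends on input values at most \eqn{K - 1} hops
#' away.
#'
#' @param laplacian a \linkS4class{GraphLaplacian}; the
#'   \code{"sym-normalized-scaled"} mode keeps the spectrum in \eqn{[-1,1]}
#'   as the recursion requires (the combinatorial mode is accepted for
#'   fidelity experiments).
#' @param x signal matrix \code{M x F_in} (a vector is treated as one
#'   channel).
#' @param weights numeric array \code{K x F_in x F_out} of filter
#'   coefficients \eqn{\xi}.
#' @return filtered signals, \code{M x F_out}.
#' @export
chebyshevFilter <- function(laplacian, x, weights) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  dw <- dim(weights)
  if (length(dw) != 3L) stop("weights must be a K x F_in x F_out array")
  K <- dw[1L]
  if (K < 1L) stop("Chebyshev order must be >= 1")
  if (dw[2L] != ncol(x)) stop("weights F_in does not match signal channels")
  Tx <- .chebBasisSignals(laplacian@laplacian, x, K)
  y <- matrix(0, nrow(x), dw[3L])
  for (k in seq_len(K))
    y <- y + Tx[[k]] %*% matrix(weights[k, , ], dw[2L], dw[3L])
  y
}
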