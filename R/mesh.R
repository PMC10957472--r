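#' @include AllClasses.R AllGenerics.R
NULL

## directed edge table of a face matrix: one row per half-edge (from, to)
.halfEdges <- function(faces) {
  cbind(
    from = as.vector(t(faces)),
    to   = as.vector(t(faces[, c(2L, 3L, 1L), drop = FALSE]))
  )
}

.edgeKey <- function(i, j, M) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (lo - 1) * as.numeric(M) + hi
}

#' Build a triangle mesh
#'
#' Constructs a \linkS4class{TriangleMesh} from vertex coordinates and a face
#' list, deriving the vertex adjacency matrix and checking structural
#' invariants (valid indices, no degenerate faces). When the face windings
#' are inconsistent they are repaired to the majority orientation of each
#' connected component, with a warning.
#'
#' @param vertices numeric matrix \code{M x 3} of coordinates (mm).
#' @param faces integer matrix \code{F x 3} of vertex indices; 1-based by
#'   default, set \code{zeroBased = TRUE} for 0-based input.
#' @param zeroBased logical; are face indices 0-based?
#' @param repairWinding logical; repair inconsistent face orientation.
#' @return a \linkS4class{TriangleMesh}.
#' @examples
#' tet <- buildMesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1)),
#'                  rbind(c(1,3,2), c(1,2,4), c(2,3,4), c(1,4,3)))
#' nVertices(tet)
#' @export
buildMesh <- function(vertices, faces, zeroBased = FALSE, repairWinding = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (zeroBased) faces <- faces + 1L
  M <- nrow(vertices)
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > M)
      stop("face index out of range [", if (zeroBased) "0" else "1", ", M]")
    dup <- faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
      faces[, 2L] == faces[, 3L]
    if (any(dup))
      stop("degenerate face with repeated vertex at row(s): ",
           paste(utils::head(which(dup), 5L), collapse = ", "))
  }
  if (repairWinding && nrow(faces) > 1L) faces <- .repairWinding(faces)
  he <- .halfEdges(faces)
  A <- sparseMatrix(i = c(he[, 1L], he[, 2L]), j = c(he[, 2L], he[, 1L]),
                    x = 1, dims = c(M, M), use.last.ij = TRUE)
  A <- methods::as(A, "generalMatrix")
  diag(A) <- 0
  A@x[] <- 1
  A <- Matrix::drop0(A)
  methods::new("TriangleMesh", vertices = vertices, faces = faces, adjacency = A)
}

## Orients all faces consistently by breadth-first propagation across shared
## edges, then flips whole components to majority winding. Returns faces.
.repairWinding <- function(faces) {
  nf <- nrow(faces)
  M <- max(faces)
  he <- .halfEdges(faces)
  key <- .edgeKey(he[, 1L], he[, 2L], M)
  faceOf <- rep(seq_len(nf), each = 3L)
  ord <- order(key)
  keyS <- key[ord]; faceS <- faceOf[ord]
  grp <- cumsum(c(TRUE, diff(keyS) != 0))
  flip <- logical(nf)
  visited <- logical(nf)
  ## adjacency between faces sharing an undirected edge
  splitIdx <- split(seq_along(keyS), grp)
  pairs <- splitIdx[lengths(splitIdx) == 2L]
  if (length(pairs)) {
    pm <- matrix(unlist(pairs, use.names = FALSE), ncol = 2L, byrow = TRUE)
    fa <- faceS[pm[, 1L]]; fb <- faceS[pm[, 2L]]
    ## same directed-edge direction within the pair means inconsistent winding
    sameDir <- he[ord[pm[, 1L]], 1L] == he[ord[pm[, 2L]], 1L]
    nbr <- split(data.frame(to = c(fb, fa), bad = c(sameDir, sameDir)),
                 c(fa, fb))
  } else nbr <- list()
  anyFlip <- FALSE
  for (start in seq_len(nf)) {
    if (visited[start]) next
    comp <- integer(0)
    queue <- start; visited[start] <- TRUE
    while (length(queue)) {
      f <- queue[[1L]]; queue <- queue[-1L]
      comp <- c(comp, f)
      nb <- nbr[[as.character(f)]]
      if (!is.null(nb)) for (k in seq_len(nrow(nb))) {
        g <- nb$to[k]
        want <- xor(flip[f], nb$bad[k])
        if (!visited[g]) {
          visited[g] <- TRUE
          flip[g] <- want
          queue <- c(queue, g)
        }
      }
    }
    ## majority winding within the component
    if (sum(flip[comp]) > length(comp) / 2) flip[comp] <- !flip[comp]
    if (any(flip[comp])) anyFlip <- TRUE
  }
  if (anyFlip) {
    warning("inconsistent face winding repaired on ", sum(flip), " face(s)")
    faces[flip, ] <- faces[flip, c(1L, 3L, 2L), drop = FALSE]
  }
  faces
}

#' Is a mesh closed?
#'
#' A mesh is closed (watertight) when every undirected edge is shared by
#' exactly two faces with consistent winding (each directed half-edge occurs
#' exactly once).
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return logical.
#' @export
isClosed <- function(mesh) {
  he <- .halfEdges(mesh@faces)
  M <- nrow(mesh@vertices)
  dirKey <- (he[, 1L] - 1) * as.numeric(M) + he[, 2L]
  if (anyDuplicated(dirKey)) return(FALSE)
  undKey <- .edgeKey(he[, 1L], he[, 2L], M)
  all(table(undKey) == 2L)
}

#' Graph Laplacian of a mesh
#'
#' Returns the combinatorial Laplacian \eqn{L = D - A} or, for spectral
#' filtering, the symmetric-normalized Laplacian rescaled to have spectrum in
#' \eqn{[-1, 1]}: \eqn{\tilde L = 2 L_{sym} / \lambda_{max} - I} with
#' \eqn{L_{sym} = I - D^{-1/2} A D^{-1/2}}. \eqn{\lambda_{max}} is obtained
#' by power iteration (tolerance 1e-6, at most 1000 iterations).
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param mode \code{"combinatorial"} or \code{"sym-normalized-scaled"}.
#' @return a \linkS4class{GraphLaplacian}.
#' @export
graphLaplacian <- function(mesh, mode = c("combinatorial", "sym-normalized-scaled")) {
  mode <- match.arg(mode)
  A <- mesh@adjacency
  deg <- Matrix::rowSums(A)
  if (mode == "combinatorial") {
    L <- Diagonal(x = deg) - A
    return(methods::new("GraphLaplacian", laplacian = L, mode = mode,
                        lambdaMax = NULL))
  }
  if (any(deg == 0))
    stop("isolated vertex (degree 0): symmetric normalization undefined")
  dm <- Diagonal(x = 1 / sqrt(deg))
  Lsym <- Diagonal(n = nrow(A)) - dm %*% A %*% dm
  ## slight inflation guards against power-iteration under-estimation so the
  ## rescaled spectrum stays inside [-1, 1]
  lmax <- .powerIterLambdaMax(Lsym) * (1 + 5e-4)
  Lt <- (2 / lmax) * Lsym - Diagonal(n = nrow(A))
  methods::new("GraphLaplacian", laplacian = Lt, mode = mode, lambdaMax = lmax)
}

## largest eigenvalue of a symmetric PSD sparse matrix by power iteration
.powerIterLambdaMax <- function(L, tol = 1e-6, maxIter = 1000L) {
  n <- nrow(L)
  v <- rep(1 / sqrt(n), n) + seq_len(n) / n^2  # deterministic, not an eigenvector
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (it in seq_len(maxIter)) {
    w <- as.numeric(L %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- w / nw
    lamNew <- as.numeric(crossprod(v, L %*% v))
    if (abs(lamNew - lam) < tol * max(1, abs(lamNew))) return(lamNew)
    lam <- lamNew
  }
  lam
}

#' Surface area of a triangle mesh
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return total area (mm^2).
#' @export
surfaceArea <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedron (divergence) sum over faces; positive when faces are
#' wound outward. Errors on an open mesh.
#'
#' @param mesh a closed, consistently oriented \linkS4class{TriangleMesh}.
#' @return volume in mm^3 (signed; positive for outward orientation).
#' @export
meshVolume <- function(mesh) {
  if (!isClosed(mesh)) stop("meshVolume requires a closed mesh")
  v <- mesh@vertices; f <- mesh@faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  det3 <- p1[, 1L] * (p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L]) -
          p1[, 2L] * (p2[, 1L] * p3[, 3L] - p2[, 3L] * p3[, 1L]) +
          p1[, 3L] * (p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L])
  sum(det3) / 6
}

#' Sphericity of a closed mesh
#'
#' Isoperimetric sphericity \eqn{\Psi = \pi^{1/3} (6V)^{2/3} / A}: the ratio
#' of the area of a sphere of equal volume to the actual surface area. Equals
#' 1 for a sphere and is strictly smaller for any other shape; it is
#' scale-invariant. Used as the end-diastolic sphericity index of a cavity
#' mesh.
#'
#' @param mesh a closed \linkS4class{TriangleMesh} with positive volume.
#' @return sphericity in \code{(0, 1]} (dimensionless).
#' @export
sphericity <- function(mesh) {
  V <- meshVolume(mesh)
  if (V <= 0) stop("sphericity requires positive enclosed volume (outward orientation)")
  A <- surfaceArea(mesh)
  if (A <= 0) stop("sphericity requires positive surface area")
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' Assemble a shape cohort
#'
#' @param subjectIds character vector of subject identifiers.
#' @param shapes numeric array \code{N x M x 3} of registered coordinates, or a
#'   list of \code{M x 3} matrices.
#' @param templateFaces shared face matrix (1-based).
#' @param aligned logical; set by \code{\link{generalizedProcrustes}}.
#' @return a \linkS4class{ShapeCohort}.
#' @export
shapeCohort <- function(subjectIds, shapes, templateFaces, aligned = FALSE) {
  if (is.list(shapes)) {
    arr <- array(0, dim = c(length(shapes), nrow(shapes[[1L]]), 3L))
    for (i in seq_along(shapes)) arr[i, , ] <- shapes[[i]]
    shapes <- arr
  }
  templateFaces <- as.matrix(templateFaces)
  storage.mode(templateFaces) <- "integer"
  methods::new("ShapeCohort", subjectIds = as.character(subjectIds),
               shapes = shapes, templateFaces = templateFaces,
               aligned = aligned)
}

#' Extract one subject's mesh from a cohort
#'
#' @param cohort a \linkS4class{ShapeCohort}.
#' @param i subject index or id.
#' @return a \linkS4class{TriangleMesh}.
#' @export
cohortMesh <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort@subjectIds)
  buildMesh(cohort@shapes[i, , ], cohort@templateFaces, repairWinding = FALSE)
}

#' Vectorize cohort shapes
#'
#' Flattens each subject's \code{M x 3} coordinates to a row vector
#' \code{(x1, y1, z1, ..., xM, yM, zM)}, the layout used by shape PCA.
#'
#' @param cohort a \linkS4class{ShapeCohort}.
#' @return numeric matrix \code{N x 3M}.
#' @export
vectorizeShapes <- function(cohort) {
  d <- dim(cohort@shapes)
  out <- matrix(0, d[1L], d[2L] * 3L)
  for (k in 1:3) out[, seq(k, by = 3L, length.out = d[2L])] <- cohort@shapes[, , k]
  dimnames(out) <- list(cohort@subjectIds, NULL)
  out
}

#' Fold a shape vector back to M x 3
#'
#' Inverse of \code{\link{vectorizeShapes}} for a single shape.
#'
#' @param s numeric vector of length 3M.
#' @return numeric matrix \code{M x 3}.
#' @export
unvectorizeShape <- function(s) {
  matrix(s, ncol = 3L, byrow = TRUE)
}
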