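#' @include AllClasses.R mesh.R
NULL

## symmetric 4x4 quadric stored as 10-vector:
## (q11,q12,q13,q14, q22,q23,q24, q33,q34, q44)
.faceQuadrics <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c3 <- vertices[faces[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- c3 - a
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  nn <- sqrt(rowSums(n^2))
  nn[nn == 0] <- 1
  n <- n / nn
  d <- -rowSums(n * a)
  cbind(n[, 1L]^2, n[, 1L] * n[, 2L], n[, 1L] * n[, 3L], n[, 1L] * d,
        n[, 2L]^2, n[, 2L] * n[, 3L], n[, 2L] * d,
        n[, 3L]^2, n[, 3L] * d,
        d^2)
}

## quadratic form v' Q v for homogeneous points (x,y,z,1), vectorized rows
.quadricCost <- function(Q, p) {
  x <- p[, 1L]; y <- p[, 2L]; z <- p[, 3L]
  Q[, 1L] * x * x + 2 * Q[, 2L] * x * y + 2 * Q[, 3L] * x * z + 2 * Q[, 4L] * x +
    Q[, 5L] * y * y + 2 * Q[, 6L] * y * z + 2 * Q[, 7L] * y +
    Q[, 8L] * z * z + 2 * Q[, 9L] * z +
    Q[, 10L]
}

## Greedy quadric-error half-edge collapse down to `target` vertices.
## Collapses always move a removed vertex onto a surviving original vertex, so
## the surviving vertex set is a subset of the input vertices (what a binary
## selection downsampling matrix requires).
.qemDecimate <- function(vertices, faces, target) {
  M <- nrow(vertices)
  alive <- rep(TRUE, M)
  Q <- matrix(0, M, 10L)
  fq <- .faceQuadrics(vertices, faces)
  for (k in 1:3) {
    agg <- rowsum(fq, faces[, k])
    idx <- as.integer(rownames(agg))
    Q[idx, ] <- Q[idx, ] + agg
  }
  f <- faces
  nAlive <- M
  while (nAlive > target) {
    ## current undirected edge list from faces
    e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    e <- e[!duplicated(e[, 1L] * (M + 1) + e[, 2L]), , drop = FALSE]
    cost1 <- .quadricCost(Q[e[, 1L], , drop = FALSE] + Q[e[, 2L], , drop = FALSE],
                          vertices[e[, 1L], , drop = FALSE])   # drop j, keep i
    cost2 <- .quadricCost(Q[e[, 1L], , drop = FALSE] + Q[e[, 2L], , drop = FALSE],
                          vertices[e[, 2L], , drop = FALSE])   # drop i, keep j
    keepFirst <- cost1 <= cost2
    cost <- ifelse(keepFirst, cost1, cost2)
    ord <- order(cost)
    collapsed <- FALSE
    for (ei in ord) {
      i <- if (keepFirst[ei]) e[ei, 1L] else e[ei, 2L]  # kept
      j <- if (keepFirst[ei]) e[ei, 2L] else e[ei, 1L]  # removed
      ## link condition: i and j must share exactly the 2 opposite vertices
      ni <- unique(c(f[f[, 1L] == i | f[, 2L] == i | f[, 3L] == i, ]))
      nj <- unique(c(f[f[, 1L] == j | f[, 2L] == j | f[, 3L] == j, ]))
      common <- setdiff(intersect(ni, nj), c(i, j))
      shared <- rowSums(matrix(f %in% c(i, j), nrow(f))) == 2L
      if (length(common) != sum(shared)) next
      ## collapse j -> i
      f[f == j] <- i
      degen <- f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]
      f <- f[!degen, , drop = FALSE]
      Q[i, ] <- Q[i, ] + Q[j, ]
      alive[j] <- FALSE
      nAlive <- nAlive - 1L
      collapsed <- TRUE
      break
    }
    if (!collapsed) stop("decimation stalled: no valid edge collapse remains")
  }
  kept <- which(alive)
  remap <- integer(M)
  remap[kept] <- seq_along(kept)
  list(kept = kept,
       vertices = vertices[kept, , drop = FALSE],
       faces = matrix(remap[f], ncol = 3L))
}

## Closest point on triangle (a,b,c) to p, vectorized over triangles.
## Returns barycentric coordinates (w_a, w_b, w_c) and squared distance.
.pointTriangleBary <- function(p, a, b, c3) {
  ab <- b - a; ac <- c3 - a
  ap <- sweep(-a, 2L, p, "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(-b, 2L, p, "+")
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- sweep(-c3, 2L, p, "+")
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  n <- nrow(a)
  u <- numeric(n); v <- numeric(n); w <- numeric(n)
  done <- logical(n)
  set <- function(mask, uu, vv, ww) {
    mask <- mask & !done
    u[mask] <<- uu[mask]; v[mask] <<- vv[mask]; w[mask] <<- ww[mask]
    done[mask] <<- TRUE
  }
  one <- rep(1, n); zero <- rep(0, n)
  set(d1 <= 0 & d2 <= 0, one, zero, zero)
  set(d3 >= 0 & d4 <= d3, zero, one, zero)
  t1 <- d1 / (d1 - d3)
  set(vc <= 0 & d1 >= 0 & d3 <= 0, 1 - t1, t1, zero)
  set(d6 >= 0 & d5 <= d6, zero, zero, one)
  t2 <- d2 / (d2 - d6)
  set(vb <= 0 & d2 >= 0 & d6 <= 0, 1 - t2, zero, t2)
  t3 <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, zero, 1 - t3, t3)
  denom <- va + vb + vc
  vi <- vb / denom; wi <- vc / denom
  set(rep(TRUE, n), 1 - vi - wi, vi, wi)
  q <- a * u + b * v + c3 * w
  dq <- sweep(q, 2L, p)
  list(bary = cbind(u, v, w), dist2 = rowSums(dq^2))
}

#' Build mesh down/upsampling operators
#'
#' Builds the pooling hierarchy for a mesh autoencoder from a single template
#' shape (the cohort mean): per level, greedy quadric-error-metric edge
#' collapse decimates the mesh to \code{ceiling(M/factor)} vertices; the
#' downsampling matrix selects the surviving vertices, and the upsampling
#' matrix stores, for each removed vertex, the barycentric coordinates of its
#' projection onto the nearest triangle of the decimated mesh (surviving
#' vertices get exact indicator rows).
#'
#' @param template a \linkS4class{TriangleMesh} (typically the cohort mean).
#' @param factors integer vector of per-level decimation factors.
#' @return a \linkS4class{SamplingOperators}.
#' @export
buildSamplingOperators <- function(template, factors) {
  factors <- as.integer(factors)
  if (any(factors < 1L)) stop("downsampling factors must be >= 1")
  levelMeshes <- list(template)
  downMaps <- list()
  upMaps <- list()
  cur <- template
  for (l in seq_along(factors)) {
    Mprev <- nrow(cur@vertices)
    target <- as.integer(ceiling(Mprev / factors[l]))
    if (target < 4L) stop("decimation below 4 vertices at level ", l)
    if (factors[l] == 1L) {
      dn <- Diagonal(n = Mprev)
      dn <- methods::as(methods::as(dn, "generalMatrix"), "CsparseMatrix")
      downMaps[[l]] <- dn
      upMaps[[l]] <- dn
      levelMeshes[[l + 1L]] <- cur
      next
    }
    dec <- .qemDecimate(cur@vertices, cur@faces, target)
    Mnew <- length(dec$kept)
    downMaps[[l]] <- sparseMatrix(i = seq_len(Mnew), j = dec$kept, x = 1,
                                  dims = c(Mnew, Mprev))
    ## upsampling: kept -> indicator; removed -> barycentric in nearest triangle
    iIdx <- dec$kept
    jIdx <- seq_len(Mnew)
    xVal <- rep(1, Mnew)
    removed <- setdiff(seq_len(Mprev), dec$kept)
    fNew <- dec$faces
    aM <- dec$vertices[fNew[, 1L], , drop = FALSE]
    bM <- dec$vertices[fNew[, 2L], , drop = FALSE]
    cM <- dec$vertices[fNew[, 3L], , drop = FALSE]
    for (r in removed) {
      pt <- .pointTriangleBary(cur@vertices[r, ], aM, bM, cM)
      best <- which.min(pt$dist2)
      bw <- pt$bary[best, ]
      nz <- which(bw > 1e-12)
      bw <- bw[nz] / sum(bw[nz])
      iIdx <- c(iIdx, rep(r, length(nz)))
      jIdx <- c(jIdx, fNew[best, nz])
      xVal <- c(xVal, bw)
    }
    upMaps[[l]] <- sparseMatrix(i = iIdx, j = jIdx, x = xVal,
                                dims = c(Mprev, Mnew))
    cur <- buildMesh(dec$vertices, dec$faces, repairWinding = FALSE)
    levelMeshes[[l + 1L]] <- cur
  }
  methods::new("SamplingOperators", levelMeshes = levelMeshes,
               downMaps = downMaps, upMaps = upMaps, factors = factors)
}
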