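test_that("buildMesh derives the adjacency and rejects bad faces", {
  tet <- tetrahedronMesh()
  A <- as.matrix(adjacency(tet))
  expect_equal(sum(A) / 2, 6)                  # K4 has 6 edges
  expect_true(all(Matrix::rowSums(adjacency(tet)) == 3))
  expect_true(all(diag(A) == 0))
  expect_true(isSymmetric(A))

  tri <- singleTriangleMesh()
  expect_equal(as.matrix(adjacency(tri)),
               matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3), ignore_attr = TRUE)

  v <- vertices(tri)
  expect_error(buildMesh(v, rbind(c(1, 1, 2))), "degenerate")
  expect_error(buildMesh(v, rbind(c(0, 1, 2))), "out of range")
  expect_error(buildMesh(v, rbind(c(1, 2, 4))), "out of range")
  ## 0-based input convention
  m0 <- buildMesh(v, rbind(c(0, 1, 2)), zeroBased = TRUE)
  expect_equal(faces(m0), faces(tri))
})

test_that("inconsistent winding is repaired to a consistent orientation", {
  tet <- tetrahedronMesh()
  f <- faces(tet)
  f[2, ] <- f[2, c(1, 3, 2)]
  expect_warning(m <- buildMesh(vertices(tet), f), "winding")
  expect_true(isClosed(m))
  ## orientation is consistent again (global in/out sign is unknowable)
  expect_equal(abs(meshVolume(m)), abs(meshVolume(tet)), tolerance = 1e-12)
})

test_that("combinatorial Laplacian is D - A with zero row sums", {
  tri <- singleTriangleMesh()
  L <- graphLaplacian(tri, "combinatorial")
  expect_equal(as.matrix(L@laplacian),
               rbind(c(2, -1, -1), c(-1, 2, -1), c(-1, -1, 2)),
               ignore_attr = TRUE)
  for (m in list(tetrahedronMesh(), icosphere(1), makeTemplate(1))) {
    Lc <- graphLaplacian(m, "combinatorial")@laplacian
    expect_lt(max(abs(Matrix::rowSums(Lc))), 1e-12)
    ## annihilates the constant vector exactly
    expect_true(all(as.numeric(Lc %*% rep(1, nVertices(m))) == 0))
  }
})

test_that("scaled Laplacian spectrum lies in [-1, 1] (dense eigen oracle)", {
  for (m in list(tetrahedronMesh(), icosphere(1), makeTemplate(1))) {
    L <- graphLaplacian(m, "sym-normalized-scaled")
    ev <- eigen(as.matrix(L@laplacian), symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(ev), 1 + 1e-6)
    expect_gte(min(ev), -1 - 1e-6)
    expect_equal(max(ev), 1, tolerance = 5e-3)  # top eigenvalue is rescaled to ~1
  }
})

test_that("mesh volume matches closed forms and analytic limits", {
  expect_equal(meshVolume(unitCubeMesh()), 1.0, tolerance = 1e-12)
  expect_equal(meshVolume(tetrahedronMesh(edge = 1)), 1 / (6 * sqrt(2)),
               tolerance = 1e-12)
  ## icosphere volume -> (4/3) pi r^3 with refinement; tolerance per level
  for (lvl in 1:3) {
    r <- 2
    v <- meshVolume(icosphere(lvl, radius = r))
    tol <- c(0.15, 0.04, 0.01)[lvl]  # inscribed-polyhedron deficit per level
    expect_equal(v, 4 / 3 * pi * r^3, tolerance = tol)
  }
  expect_error(meshVolume(singleTriangleMesh()), "closed")
})

test_that("volume is rigid-invariant and scales cubically; sphericity scale-free", {
  set.seed(42)
  m <- makeTemplate(1)
  V0 <- meshVolume(m); S0 <- sphericity(m)
  R <- randomRotation()
  mR <- buildMesh(vertices(m) %*% R + 7, faces(m), repairWinding = FALSE)
  expect_equal(meshVolume(mR), V0, tolerance = 1e-9)
  for (s in c(0.5, 2, 3.7)) {
    ms <- buildMesh(vertices(m) * s, faces(m), repairWinding = FALSE)
    expect_equal(meshVolume(ms), V0 * s^3, tolerance = 1e-9)
    expect_equal(sphericity(ms), S0, tolerance = 1e-9)
  }
})

test_that("sphericity matches closed forms and the ellipsoid quadrature oracle", {
  expect_equal(sphericity(unitCubeMesh()), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)
  expect_equal(sphericity(icosphere(3)), 1, tolerance = 1e-3)
  expect_lt(sphericity(icosphere(3)), 1)       # sphere is the maximizer
  ## prolate ellipsoid a = 2b = 2c: volume analytic, area by quadrature
  a <- 2; b <- 1
  sph <- icosphere(3)
  ell <- buildMesh(sweep(vertices(sph), 2, c(b, b, a), "*"), faces(sph),
                   repairWinding = FALSE)
  Vexact <- 4 / 3 * pi * a * b^2
  ## prolate surface area by numeric quadrature of the surface of revolution:
  ## A = 2*pi*b * integral of sqrt(1 + (dr/dz)^2) r(z) ... parametrize z = a cos t
  f <- function(t) {
    ## surface element of (b sin t cos p, b sin t sin p, a cos t)
    2 * pi * b * sin(t) * sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2)
  }
  Aexact <- stats::integrate(f, 0, pi, rel.tol = 1e-10)$value
  psiExact <- pi^(1 / 3) * (6 * Vexact)^(2 / 3) / Aexact
  expect_equal(sphericity(ell), psiExact, tolerance = 2e-3)
  expect_lt(psiExact, 1)
})

test_that("cohort accessors, vectorization and per-subject meshes agree", {
  rc <- randomCohort(n = 4, seed = 3)
  X <- vectorizeShapes(rc$cohort)
  expect_equal(dim(X), c(4, 3 * nVertices(rc$template)))
  expect_equal(unvectorizeShape(X[2, ]), shapes(rc$cohort)[2, , ])
  m2 <- cohortMesh(rc$cohort, 2)
  expect_equal(vertices(m2), shapes(rc$cohort)[2, , ])
  expect_equal(faces(m2), faces(rc$cohort))
  expect_error(shapeCohort(c("a", "a"), shapes(rc$cohort)[1:2, , ],
                           faces(rc$template)), "duplicated")
})
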