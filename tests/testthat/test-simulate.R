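test_that("the template is a closed ventricle-like surface of expected size", {
  tpl <- makeTemplate(2)
  expect_equal(nVertices(tpl), 642L)
  expect_equal(nVertices(makeTemplate(1)), 162L)
  expect_true(isClosed(tpl))
  ## analytic volume of the two half-spheroids: 2/3 pi a^2 (c_apex + c_cap)
  Vexact <- 2 / 3 * pi * 22^2 * (48 + 12)
  expect_equal(meshVolume(tpl), Vexact, tolerance = 0.2)
  ## long axis ~ 60 mm
  expect_equal(diff(range(vertices(tpl)[, 3])), 60, tolerance = 1)
})

test_that("displacement fields are unit-RMS, near-orthogonal and behave geometrically", {
  tpl <- makeTemplate(1)
  fld <- displacementFields(tpl)
  expect_named(fld, c("scale", "stretch", "taper", "tilt"))
  for (f in fld) expect_equal(mean(rowSums(f^2)), 1, tolerance = 1e-10)
  ## pairwise cosines below 0.3
  for (i in 1:3) for (j in (i + 1):4) {
    ci <- sum(fld[[i]] * fld[[j]]) /
      sqrt(sum(fld[[i]]^2) * sum(fld[[j]]^2))
    expect_lt(abs(ci), 0.3)
  }
  ## scale field changes volume like (1 + a / rbar)^3
  V0 <- meshVolume(tpl)
  ctr <- colMeans(vertices(tpl))
  rbar <- sqrt(mean(rowSums(sweep(vertices(tpl), 2, ctr)^2)))
  for (a in c(1, 3)) {
    m2 <- buildMesh(vertices(tpl) + a * fld$scale, faces(tpl),
                    repairWinding = FALSE)
    expect_equal(meshVolume(m2) / V0, (1 + a / rbar)^3, tolerance = 0.01)
  }
  ## tilt (basal shear) preserves volume to 1%
  m3 <- buildMesh(vertices(tpl) + 2 * fld$tilt, faces(tpl),
                  repairWinding = FALSE)
  expect_equal(meshVolume(m3), V0, tolerance = 0.01)
})

test_that("simulation is deterministic and respects degenerate settings", {
  cfg <- simConfig(nSubjects = 30L, subdiv = 1L, nVariants = 100L,
                   nRegions = 10L, nCausal = 4L, seed = 99L)
  s1 <- simulateCohort(cfg)
  s2 <- simulateCohort(cfg)
  expect_identical(shapes(s1$cohort), shapes(s2$cohort))
  expect_identical(dosages(s1$genotypes), dosages(s2$genotypes))
  expect_identical(s1$covariates, s2$covariates)
  ## all effects and noise off: every mesh equals the template exactly
  cfg0 <- simConfig(nSubjects = 5L, subdiv = 1L, factorSd = rep(0, 4),
                    vertexNoiseSd = 0, nVariants = 20L, nRegions = 10L,
                    nCausal = 0L, seed = 3L)
  s0 <- simulateCohort(cfg0)
  tpl <- makeTemplate(1)
  for (i in 1:5)
    expect_equal(shapes(s0$cohort)[i, , ], vertices(tpl), tolerance = 1e-12)
  ## causal variants exist in the panel and regions partition the variants
  expect_true(all(s1$truth$causal$variant_id %in%
                    variants(s1$genotypes)$variant_id))
  rid <- suppressWarnings(assignRegions(variants(s1$genotypes), s1$regions))
  expect_false(anyNA(rid))
})

test_that("planted causal variants explain the configured variance", {
  cfg <- simConfig(nSubjects = 5000L, subdiv = 1L, nVariants = 60L,
                   nRegions = 6L, nCausal = 4L, h2PerVariant = 0.03,
                   seed = 12L)
  sim <- simulateCohort(cfg)
  tr <- sim$truth
  for (i in seq_len(nrow(tr$causal))) {
    v <- match(tr$causal$variant_id[i], variants(sim$genotypes)$variant_id)
    f <- tr$factors[, tr$causal$factor[i]]
    r2 <- summary(lm(f ~ dosages(sim$genotypes)[v, ]))$r.squared
    expect_gt(r2, 0.02)
    expect_lt(r2, 0.04)
  }
})

test_that("allele frequencies and HWE are faithful to the generative model", {
  cfg <- simConfig(nSubjects = 2000L, subdiv = 1L, nVariants = 200L,
                   nRegions = 20L, nCausal = 0L, rhoLD = 0.9, seed = 13L)
  sim <- simulateCohort(cfg)
  vm <- variants(sim$genotypes)
  phat <- rowMeans(dosages(sim$genotypes)) / 2
  bound <- 3 * sqrt(vm$p_true * (1 - vm$p_true) / (2 * cfg@nSubjects))
  expect_gt(mean(abs(phat - vm$p_true) < bound), 0.98)
  ## HWE exact-test p-values are not enriched for small values
  hard <- dosages(sim$genotypes)
  hwe <- vapply(seq_len(nrow(hard)), function(i)
    hweExactTest(sum(hard[i, ] == 2), sum(hard[i, ] == 1),
                 sum(hard[i, ] == 0)), numeric(1))
  expect_lt(mean(hwe < 0.05), 0.1)
  expect_gt(mean(hwe), 0.35)                  # discrete p-values push the mean up
  ## LD: adjacent variants within a block are strongly correlated
  r2adj <- cor(dosages(sim$genotypes)[1, ], dosages(sim$genotypes)[2, ])^2
  expect_gt(r2adj, 0.5)
  ## across blocks: independent
  r2across <- cor(dosages(sim$genotypes)[10, ], dosages(sim$genotypes)[11, ])^2
  expect_lt(r2across, 0.05)
})

test_that("shape PCA on a noise-free 4-factor cohort finds a rank-4 subspace", {
  cfg <- simConfig(nSubjects = 200L, subdiv = 1L, vertexNoiseSd = 0,
                   nVariants = 20L, nRegions = 10L, nCausal = 4L, seed = 14L)
  sim <- simulateCohort(cfg)
  aligned <- generalizedProcrustes(sim$cohort)$cohort
  m <- fitShapePca(aligned, 8)
  ## Procrustes rotation mixes a little residual into higher modes; the
  ## dominant subspace is 4-dimensional by orders of magnitude
  expect_lt(m@eigenvalues[5] / m@eigenvalues[1], 1e-4)
  expect_gt(sum(explainedVariance(m)[1:4]), 0.999)
})
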