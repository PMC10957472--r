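## shared tiny training setup (built once per file)
comaFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(30)
    tpl <- makeTemplate(1)
    fld <- displacementFields(tpl)
    N <- 120
    amp <- rnorm(N, 0, 3)
    sh <- lapply(seq_len(N), function(i) vertices(tpl) + amp[i] * fld$scale)
    coh <- shapeCohort(sprintf("s%03d", seq_len(N)), sh, faces(tpl))
    gp <- generalizedProcrustes(coh)
    tplMean <- buildMesh(gp$meanShape, faces(tpl), repairWinding = FALSE)
    ops <- buildSamplingOperators(tplMean, c(4L, 4L))
    cache <<- list(aligned = gp$cohort, ops = ops, amp = amp)
    cache
  }
})

test_that("KL term closed forms and quadrature oracle", {
  expect_identical(klTerm(0, 1), 0)
  expect_equal(klTerm(1, 1), 0.5)               # direct substitution, n_z = 1
  expect_error(klTerm(0, 0), "positive")
  expect_error(klTerm(c(0, 0), 1), "lengths")
  ## numeric KL(N(mu, sigma^2) || N(0,1)) averaged over dimensions
  set.seed(1)
  for (rep in 1:5) {
    mu <- rnorm(4); sigma <- runif(4, 0.3, 2)
    klNum <- mean(vapply(1:4, function(j) {
      f <- function(x) {
        p <- dnorm(x, mu[j], sigma[j])
        lr <- dnorm(x, mu[j], sigma[j], log = TRUE) - dnorm(x, log = TRUE)
        p * lr
      }
      integrate(f, mu[j] - 12 * sigma[j], mu[j] + 12 * sigma[j],
                rel.tol = 1e-10)$value
    }, numeric(1)))
    expect_equal(klTerm(mu, sigma), klNum, tolerance = 1e-8)
  }
  ## non-negative, zero only at (0, 1)
  expect_gt(klTerm(c(0.1, 0), c(1, 1)), 0)
  expect_gt(klTerm(c(0, 0), c(1.2, 1)), 0)
})

test_that("reconstruction RMSD matches its definition and a brute-force oracle", {
  rc <- randomCohort(n = 5, noiseSd = 0.3, seed = 8)
  same <- reconstructionRmsd(rc$cohort, rc$cohort)
  expect_equal(unname(same), rep(0, 5))
  ## uniform 1 mm displacement along x -> exactly 1 mm
  sh2 <- shapes(rc$cohort)
  sh2[, , 1] <- sh2[, , 1] + 1
  moved <- methods::new("ShapeCohort", subjectIds = subjectIds(rc$cohort),
                        shapes = sh2, templateFaces = faces(rc$cohort),
                        aligned = FALSE)
  expect_equal(unname(reconstructionRmsd(rc$cohort, moved)), rep(1, 5))
  ## random displacement vs naive double loop
  set.seed(9)
  sh3 <- shapes(rc$cohort) + array(rnorm(length(sh2), 0, 0.7), dim(sh2))
  pert <- methods::new("ShapeCohort", subjectIds = subjectIds(rc$cohort),
                       shapes = sh3, templateFaces = faces(rc$cohort),
                       aligned = FALSE)
  got <- reconstructionRmsd(rc$cohort, pert)
  M <- dim(sh2)[2]
  for (i in 1:5) {
    acc <- 0
    for (j in seq_len(M))
      acc <- acc + sum((shapes(rc$cohort)[i, j, ] - sh3[i, j, ])^2)
    expect_equal(unname(got[i]), sqrt(acc / M), tolerance = 1e-12)
  }
  expect_error(reconstructionRmsd(rc$cohort, shapeCohort(
    subjectIds(rc$cohort)[1:4], sh3[1:4, , ], faces(rc$cohort))), "differ")
})

test_that("training is deterministic given the seeds", {
  fx <- comaFixture()
  cfg <- comaConfig(nZ = 1L, channels = c(4L, 8L), dsFactors = c(4L, 4L),
                    wKL = 1e-4, epochs = 3L, seedWeights = 5L, seedSplit = 9L)
  r1 <- trainComa(fx$aligned, fx$ops, cfg)
  r2 <- trainComa(fx$aligned, fx$ops, cfg)
  expect_identical(latents(r1), latents(r2))
  expect_identical(r1@perSubjectRmsd, r2@perSubjectRmsd)
  ## a different weight seed gives a different model
  cfg2 <- comaConfig(nZ = 1L, channels = c(4L, 8L), dsFactors = c(4L, 4L),
                     wKL = 1e-4, epochs = 3L, seedWeights = 6L, seedSplit = 9L)
  r3 <- trainComa(fx$aligned, fx$ops, cfg2)
  expect_false(identical(latents(r1), latents(r3)))
})

test_that("a single-factor noise-free cohort trains to a faithful 1-D code", {
  fx <- comaFixture()
  cfg <- comaConfig(nZ = 1L, channels = c(8L, 16L), dsFactors = c(4L, 4L),
                    wKL = 0, epochs = 150L, learningRate = 3e-3,
                    seedWeights = 7L, seedSplit = 7L)
  rr <- trainComa(fx$aligned, fx$ops, cfg)
  ampSd <- sd(fx$amp)
  ## test RMSD below 10% of the factor displacement amplitude
  expect_lt(testRmsd(rr), 0.1 * ampSd)
  ## the latent recovers the generative factor (up to sign)
  expect_gt(abs(cor(latents(rr)[, 1], fx$amp)), 0.99)
  ## smoothed training loss decreases
  h <- rr@history
  sm <- stats::filter(h$trainLoss, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], 0.5 * sm[1])
  ## nonlinear model at least matches the linear baseline on linear data
  pcaResid <- {
    m <- fitShapePca(fx$aligned, 1)
    X <- vectorizeShapes(fx$aligned)
    rec <- pcaDecode(m, pcaEncode(m, X))
    mean(sqrt(rowSums((rec - X)^2) / (ncol(X) / 3)))
  }
  expect_lt(testRmsd(rr), pcaResid + 0.1 * ampSd)
  ## encode path consistency: same latents from encodeCohort, and the
  ## decode(encode) RMSD equals the run RMSD
  z <- encodeCohort(rr, fx$aligned)
  expect_equal(z, latents(rr))
  rec <- reconstructCohort(rr, fx$aligned)
  expect_equal(unname(reconstructionRmsd(fx$aligned, rec)),
               unname(rr@perSubjectRmsd), tolerance = 1e-10)
})

test_that("a large KL weight shrinks the latent code toward posterior collapse", {
  fx <- comaFixture()
  vars <- vapply(c(0, 5), function(w) {
    cfg <- comaConfig(nZ = 1L, channels = c(4L, 8L), dsFactors = c(4L, 4L),
                      wKL = w, epochs = 30L, learningRate = 3e-3,
                      seedWeights = 3L, seedSplit = 3L)
    var(latents(trainComa(fx$aligned, fx$ops, cfg))[, 1])
  }, numeric(1))
  expect_lt(vars[2], 0.1 * vars[1])
})

test_that("training rejects invalid setups", {
  fx <- comaFixture()
  unaligned <- shapeCohort(subjectIds(fx$aligned), shapes(fx$aligned) + 1,
                           faces(fx$aligned))
  cfg <- comaConfig(nZ = 1L, channels = c(4L, 8L), dsFactors = c(4L, 4L),
                    epochs = 1L)
  expect_error(trainComa(unaligned, fx$ops, cfg), "aligned")
  expect_error(encodeCohort(methods::new("ComaModel"), unaligned), "aligned")
  badCfg <- comaConfig(nZ = 1L, channels = c(4L), dsFactors = c(4L),
                       epochs = 1L)
  expect_error(trainComa(fx$aligned, fx$ops, badCfg), "levels|layers")
})
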