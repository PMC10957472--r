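## Shared fixture builders; everything is generated in code.

tetrahedronMesh <- function(edge = 1) {
  ## regular tetrahedron with the requested edge length, outward winding
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    (edge / (2 * sqrt(2)))
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  buildMesh(v, f, repairWinding = FALSE)
}

unitCubeMesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  ## 12 outward-wound triangles
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),      # z = 0
    c(5, 6, 7), c(6, 8, 7),      # z = 1
    c(1, 2, 5), c(2, 6, 5),      # y = 0
    c(3, 7, 4), c(4, 7, 8),      # y = 1
    c(1, 5, 3), c(3, 5, 7),      # x = 0
    c(2, 4, 6), c(4, 8, 6))      # x = 1
  buildMesh(v, f, repairWinding = FALSE)
}

singleTriangleMesh <- function() {
  buildMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
            rbind(c(1, 2, 3)), repairWinding = FALSE)
}

## random registered cohort: template + random factor amplitudes (+ noise),
## optionally under random rigid motions
randomCohort <- function(n = 10, subdiv = 1, factorSd = c(3, 2, 1.5, 1),
                         noiseSd = 0, rigid = FALSE, seed = 1) {
  set.seed(seed)
  tpl <- makeTemplate(subdiv)
  fld <- displacementFields(tpl)
  M <- nVertices(tpl)
  sh <- lapply(seq_len(n), function(i) {
    amp <- stats::rnorm(4, 0, factorSd)
    X <- vertices(tpl) + amp[1] * fld$scale + amp[2] * fld$stretch +
      amp[3] * fld$taper + amp[4] * fld$tilt
    if (noiseSd > 0) X <- X + matrix(stats::rnorm(3 * M, 0, noiseSd), M, 3)
    if (rigid) {
      R <- randomRotation()
      X <- X %*% R + matrix(stats::rnorm(3, 0, 20), M, 3, byrow = TRUE)
    }
    X
  })
  list(cohort = shapeCohort(sprintf("s%03d", seq_len(n)), sh, faces(tpl)),
       template = tpl, fields = fld)
}

randomRotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## minimal RunResult for ensemble-stage tests
fakeRun <- function(runId, latents, testRmsd, subjectIds = rownames(latents)) {
  if (is.null(subjectIds)) subjectIds <- sprintf("s%04d", seq_len(nrow(latents)))
  if (is.null(colnames(latents))) colnames(latents) <- paste0("z", seq_len(ncol(latents)))
  methods::new("RunResult", runId = runId,
               config = comaConfig(nZ = ncol(latents)),
               latents = latents, subjectIds = subjectIds,
               perSubjectRmsd = numeric(0), testRmsdMean = testRmsd,
               history = data.frame(), model = NULL)
}

## small region partition on two chromosomes
toyRegions <- function(nPerChrom = 3, len = 1000) {
  do.call(rbind, lapply(c("1", "2"), function(ch)
    data.frame(region_id = paste0("r", ch, "_", seq_len(nPerChrom)),
               chrom = ch, start = (seq_len(nPerChrom) - 1) * len,
               end = seq_len(nPerChrom) * len)))
}

## random association table rows for counting tests
randomSumstats <- function(nRows, regions, seed) {
  set.seed(seed)
  idx <- sample(nrow(regions), nRows, replace = TRUE)
  pos <- floor(stats::runif(nRows, regions$start[idx], regions$end[idx]))
  data.frame(phenotype_id = sample(paste0("ph", 1:3), nRows, TRUE),
             variant_id = sprintf("v%04d", seq_len(nRows)),
             chrom = regions$chrom[idx], pos = pos,
             ea = "A", nea = "G", eaf = stats::runif(nRows, 0.05, 0.95),
             beta_hat = stats::rnorm(nRows), se = stats::runif(nRows, 0.1, 1),
             p = 10^stats::runif(nRows, -12, 0), n = 500L)
}
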