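#' @import methods
#' @importFrom Matrix Matrix sparseMatrix Diagonal t rowSums colSums bdiag crossprod tcrossprod
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Registered triangle surface mesh
#'
#' A closed (or open) triangle mesh with vertex coordinates in millimetres and
#' a shared, fixed connectivity. The vertex adjacency matrix is derived from
#' the face list at construction time and cached; it is the graph on which
#' spectral convolutions and Laplacians are defined.
#'
#' @slot vertices numeric matrix \code{M x 3}, coordinates in mm.
#' @slot faces integer matrix \code{F x 3} of 1-based vertex indices.
#' @slot adjacency symmetric sparse 0/1 matrix \code{M x M} with zero diagonal.
#' @export
setClass("TriangleMesh",
  representation(
    vertices  = "matrix",
    faces     = "matrix",
    adjacency = "Matrix"
  )
)

setValidity("TriangleMesh", function(object) {
  v <- object@vertices; f <- object@faces; A <- object@adjacency
  msg <- character()
  if (!is.numeric(v) || ncol(v) != 3L) msg <- c(msg, "vertices must be an M x 3 numeric matrix")
  if (nrow(v) < 3L) msg <- c(msg, "a mesh needs at least 3 vertices")
  if (!is.numeric(f) || ncol(f) != 3L) msg <- c(msg, "faces must be an F x 3 index matrix")
  if (anyNA(v)) msg <- c(msg, "vertices contain NA")
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v))
      msg <- c(msg, "face indices out of range")
    if (any(f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]))
      msg <- c(msg, "degenerate face (repeated vertex within a face)")
  }
  if (nrow(A) != nrow(v) || ncol(A) != nrow(v))
    msg <- c(msg, "adjacency dimension does not match vertex count")
  if (length(msg)) msg else TRUE
})

#' Cohort of registered shapes
#'
#' Holds \code{N} subjects' vertex coordinates over a shared template
#' connectivity: all subjects have the same number of vertices \code{M} in
#' correspondence. After generalized Procrustes alignment every shape is
#' centred at the origin and \code{aligned} is set.
#'
#' @slot subjectIds character vector of length N.
#' @slot shapes numeric array \code{N x M x 3} (mm).
#' @slot templateFaces integer matrix \code{F x 3}, 1-based, shared by all subjects.
#' @slot aligned logical flag.
#' @export
setClass("ShapeCohort",
  representation(
    subjectIds    = "character",
    shapes        = "array",
    templateFaces = "matrix",
    aligned       = "logical"
  )
)

setValidity("ShapeCohort", function(object) {
  msg <- character()
  d <- dim(object@shapes)
  if (length(d) != 3L || d[3L] != 3L) msg <- c(msg, "shapes must be an N x M x 3 array")
  if (length(object@subjectIds) != d[1L]) msg <- c(msg, "subjectIds length must equal N")
  if (anyDuplicated(object@subjectIds)) msg <- c(msg, "duplicated subject ids")
  if (nrow(object@templateFaces) > 0L &&
      (min(object@templateFaces) < 1L || max(object@templateFaces) > d[2L]))
    msg <- c(msg, "template face indices out of range")
  if (length(object@aligned) != 1L) msg <- c(msg, "aligned must be a single logical")
  if (isTRUE(object@aligned) && d[1L] > 0L) {
    cent <- apply(object@shapes, c(1L, 3L), mean)
    if (max(abs(cent)) > 1e-8) msg <- c(msg, "aligned cohort must have zero centroids")
  }
  if (length(msg)) msg else TRUE
})

#' Graph Laplacian of a mesh
#'
#' Either the combinatorial Laplacian \eqn{L = D - A} or the
#' symmetric-normalized Laplacian rescaled to spectrum \eqn{[-1, 1]},
#' \eqn{2 L_{sym}/\lambda_{max} - I}, as used by Chebyshev filters.
#'
#' @slot laplacian symmetric sparse matrix \code{M x M}.
#' @slot mode \code{"combinatorial"} or \code{"sym-normalized-scaled"}.
#' @slot lambdaMax largest eigenvalue of the un-rescaled operator (scaled mode).
#' @export
setClass("GraphLaplacian",
  representation(
    laplacian = "Matrix",
    mode      = "character",
    lambdaMax = "numericOrNULL"
  )
)

setValidity("GraphLaplacian", function(object) {
  msg <- character()
  if (!object@mode %in% c("combinatorial", "sym-normalized-scaled"))
    msg <- c(msg, "unknown Laplacian mode")
  L <- object@laplacian
  if (nrow(L) != ncol(L)) msg <- c(msg, "Laplacian must be square")
  if (max(abs(L - Matrix::t(L))) > 1e-10) msg <- c(msg, "Laplacian must be symmetric")
  if (object@mode == "combinatorial") {
    if (max(abs(Matrix::rowSums(L))) > 1e-10)
      msg <- c(msg, "combinatorial Laplacian rows must sum to 0")
  } else if (is.null(object@lambdaMax)) {
    msg <- c(msg, "scaled mode requires lambdaMax")
  }
  if (length(msg)) msg else TRUE
})

#' Spectral (Fourier) basis of a mesh graph
#'
#' Dense eigendecomposition of a Laplacian; used as the exact reference for
#' spectral convolution on small meshes, never during training.
#'
#' @slot fourierBasis orthogonal matrix U (columns are the basis).
#' @slot eigenvalues numeric vector.
#' @export
setClass("SpectralBasis",
  representation(fourierBasis = "matrix", eigenvalues = "numeric")
)

setValidity("SpectralBasis", function(object) {
  U <- object@fourierBasis
  if (nrow(U) != ncol(U)) return("U must be square")
  if (length(object@eigenvalues) != ncol(U)) return("eigenvalue count mismatch")
  if (max(abs(crossprod(U) - diag(nrow(U)))) > 1e-8) return("U must be orthogonal")
  TRUE
})

#' Linear shape-PCA model
#'
#' Principal components of the vectorized, aligned shapes: mean shape,
#' orthonormal component rows, and eigenvalues of the shape covariance with
#' the \eqn{N - 1} divisor.
#'
#' @slot meanShape numeric vector of length 3M (x1,y1,z1,...).
#' @slot components numeric matrix \code{n_z x 3M}, orthonormal rows.
#' @slot eigenvalues non-increasing, non-negative.
#' @slot totalVariance trace of the shape covariance (sum over all 3M eigenvalues).
#' @slot nComponents integer.
#' @export
setClass("ShapePcaModel",
  representation(
    meanShape     = "numeric",
    components    = "matrix",
    eigenvalues   = "numeric",
    totalVariance = "numeric",
    nComponents   = "integer"
  )
)

setValidity("ShapePcaModel", function(object) {
  msg <- character()
  k <- object@nComponents
  if (nrow(object@components) != k) msg <- c(msg, "component row count != nComponents")
  if (ncol(object@components) != length(object@meanShape))
    msg <- c(msg, "component length != mean shape length")
  if (length(object@eigenvalues) != k) msg <- c(msg, "eigenvalue count != nComponents")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (any(object@eigenvalues < -1e-12)) msg <- c(msg, "negative eigenvalue")
  G <- tcrossprod(object@components)
  if (max(abs(G - diag(k))) > 1e-8) msg <- c(msg, "component rows must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' Mesh down/upsampling operators
#'
#' A hierarchy of decimated template meshes with, per level, a binary
#' vertex-selection downsampling matrix and a barycentric upsampling matrix
#' (removed vertices are expressed in the barycentric coordinates of their
#' nearest surviving triangle, stored at decimation time).
#'
#' @slot levelMeshes list of \linkS4class{TriangleMesh}, finest first.
#' @slot downMaps list of sparse selection matrices, \code{M_{l+1} x M_l}.
#' @slot upMaps list of sparse barycentric matrices, \code{M_l x M_{l+1}}.
#' @slot factors integer vector of per-level decimation factors.
#' @export
setClass("SamplingOperators",
  representation(
    levelMeshes = "list",
    downMaps    = "list",
    upMaps      = "list",
    factors     = "integer"
  )
)

setValidity("SamplingOperators", function(object) {
  msg <- character()
  nl <- length(object@levelMeshes)
  if (length(object@downMaps) != nl - 1L || length(object@upMaps) != nl - 1L)
    msg <- c(msg, "need one down/up map per decimation step")
  for (i in seq_along(object@downMaps)) {
    Qd <- object@downMaps[[i]]
    if (!all(Qd@x == 1) || any(Matrix::rowSums(Qd) != 1))
      msg <- c(msg, sprintf("down map %d is not a row-selection matrix", i))
    Qu <- object@upMaps[[i]]
    if (max(abs(Matrix::rowSums(Qu) - 1)) > 1e-8)
      msg <- c(msg, sprintf("up map %d rows must sum to 1", i))
    nnzr <- diff(Matrix::t(Qu)@p)  # nonzeros per row via CSR of transpose
    if (any(nnzr > 3L))
      msg <- c(msg, sprintf("up map %d has a row with more than 3 nonzeros", i))
  }
  if (length(msg)) msg else TRUE
})

#' Configuration of one mesh-autoencoder run
#'
#' Hyperparameters of a single variational convolutional mesh autoencoder
#' training run: bottleneck width, Chebyshev order, channel widths,
#' per-layer downsampling factors, KL weight, loss, optimizer settings and
#' the two seeds (weight initialization and train/val/test split) that make
#' a run reproducible.
#'
#' @export
setClass("ComaConfig",
  representation(
    nZ             = "integer",
    chebOrder      = "integer",
    channels       = "integer",
    dsFactors      = "integer",
    wKL            = "numeric",
    reconLoss      = "character",
    learningRate   = "numeric",
    epochs         = "integer",
    batchSize      = "integer",
    seedWeights    = "integer",
    seedSplit      = "integer",
    splitFractions = "numeric",
    laplacianMode  = "character"
  )
)

setValidity("ComaConfig", function(object) {
  msg <- character()
  if (object@nZ < 1L) msg <- c(msg, "nZ must be >= 1")
  if (object@chebOrder < 1L) msg <- c(msg, "chebOrder must be >= 1")
  if (length(object@channels) != length(object@dsFactors))
    msg <- c(msg, "channels and dsFactors must have one entry per conv layer")
  if (object@wKL < 0) msg <- c(msg, "wKL must be >= 0")
  if (!object@reconLoss %in% c("L1", "L2", "MSE")) msg <- c(msg, "reconLoss must be L1, L2 or MSE")
  if (length(object@splitFractions) != 3L || abs(sum(object@splitFractions) - 1) > 1e-8)
    msg <- c(msg, "splitFractions must be three numbers summing to 1")
  if (!object@laplacianMode %in% c("combinatorial", "sym-normalized-scaled"))
    msg <- c(msg, "unknown laplacianMode")
  if (length(msg)) msg else TRUE
})

#' Trained mesh-autoencoder model
#'
#' Weights, sampling operators, per-level Laplacians and the coordinate
#' standardization learnt on the training split. Produced by
#' \code{\link{trainComa}}.
#'
#' @export
setClass("ComaModel",
  representation(
    config    = "ComaConfig",
    ops       = "SamplingOperators",
    params    = "list",
    laplacians = "list",
    standardize = "list",
    subjectSplit = "list"
  )
)

#' Result of one autoencoder run
#'
#' Latent representations (the posterior mode \eqn{\mu} per subject),
#' per-subject reconstruction RMSD in mm, and the mean test-set RMSD used by
#' ensemble run selection.
#'
#' @export
setClass("RunResult",
  representation(
    runId          = "character",
    config         = "ComaConfig",
    latents        = "matrix",
    subjectIds     = "character",
    perSubjectRmsd = "numeric",
    testRmsdMean   = "numeric",
    history        = "data.frame",
    model          = "ANY"
  )
)

setValidity("RunResult", function(object) {
  msg <- character()
  if (nrow(object@latents) != length(object@subjectIds))
    msg <- c(msg, "latents rows must match subjectIds")
  if (length(object@perSubjectRmsd) &&
      length(object@perSubjectRmsd) != length(object@subjectIds))
    msg <- c(msg, "perSubjectRmsd length must match subjectIds")
  if (length(object@perSubjectRmsd) && any(object@perSubjectRmsd < 0))
    msg <- c(msg, "RMSD must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Dosage genotype matrix with variant metadata
#'
#' Effect-allele dosages in \code{[0, 2]} (\code{NA} = missing), one row per
#' variant, one column per subject, plus a variant metadata table
#' (id, chromosome, 1-based position, effect/non-effect allele, imputation
#' INFO score).
#'
#' @export
setClass("GenotypeMatrix",
  representation(
    dosages    = "matrix",
    variants   = "data.frame",
    subjectIds = "character"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  need <- c("variant_id", "chrom", "pos", "ea", "nea", "info")
  if (!all(need %in% names(object@variants)))
    msg <- c(msg, paste("variants table needs columns:", paste(need, collapse = ", ")))
  if (nrow(object@dosages) != nrow(object@variants))
    msg <- c(msg, "dosage rows must match variants table")
  if (ncol(object@dosages) != length(object@subjectIds))
    msg <- c(msg, "dosage columns must match subjectIds")
  rng <- suppressWarnings(range(object@dosages, na.rm = TRUE))
  if (is.finite(rng[1L]) && (rng[1L] < -1e-9 || rng[2L] > 2 + 1e-9))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (anyDuplicated(object@variants$variant_id)) msg <- c(msg, "duplicated variant ids")
  ord <- order(object@variants$chrom, object@variants$pos)
  if (is.unsorted(ord) && any(ord != seq_along(ord)))
    msg <- c(msg, "variants must be sorted by (chrom, pos)")
  if (length(msg)) msg else TRUE
})

#' Adjusted, inverse-normalized phenotype scores
#'
#' Covariate-adjusted, rank-inverse-normalized latent phenotypes ready for
#' association testing, with provenance (which run and latent coordinate, or
#' which principal component / handcrafted index) per column.
#'
#' @export
setClass("PhenotypeScores",
  representation(
    scores       = "matrix",
    phenotypeIds = "character",
    subjectIds   = "character",
    provenance   = "data.frame"
  )
)

setValidity("PhenotypeScores", function(object) {
  msg <- character()
  if (ncol(object@scores) != length(object@phenotypeIds))
    msg <- c(msg, "score columns must match phenotypeIds")
  if (nrow(object@scores) != length(object@subjectIds))
    msg <- c(msg, "score rows must match subjectIds")
  if (anyDuplicated(object@phenotypeIds)) msg <- c(msg, "duplicated phenotype ids")
  if (nrow(object@scores) >= 100L) {
    mu <- colMeans(object@scores)
    v <- apply(object@scores, 2L, stats::var)
    if (any(abs(mu) > 0.02)) msg <- c(msg, "scores must be centred (|mean| < 0.02)")
    if (any(abs(v - 1) > 0.05)) msg <- c(msg, "scores must have variance ~= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Ensemble aggregation settings
#'
#' Thresholds controlling run selection, latent deduplication and locus
#' classification: the genome-wide p-value threshold, the run-selection
#' RMSD cut (mm), the Spearman deduplication cut, and the minimum run count
#' for a suggestive call.
#'
#' @export
setClass("EnsembleConfig",
  representation(
    pGw                = "numeric",
    rmsdKeepMm         = "numeric",
    spearmanMax        = "numeric",
    suggestiveMinCount = "integer",
    dedupSeed          = "integer",
    dedupMode          = "character"
  )
)

setValidity("EnsembleConfig", function(object) {
  msg <- character()
  if (object@pGw <= 0 || object@pGw >= 1) msg <- c(msg, "pGw must be in (0,1)")
  if (object@spearmanMax <= 0 || object@spearmanMax > 1)
    msg <- c(msg, "spearmanMax must be in (0,1]")
  if (!object@dedupMode %in% c("random", "drop-later"))
    msg <- c(msg, "dedupMode must be 'random' or 'drop-later'")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort generator settings
#'
#' Defines the study conditions of a simulated cohort: sample size, template
#' resolution, latent deformation factors and their standard deviations (mm),
#' vertex noise, genotype panel layout (variants, regions, LD copy
#' probability, allele-frequency range), planted causal variants with their
#' explained variance, covariate confounding, and the master seed.
#'
#' @export
setClass("SimConfig",
  representation(
    nSubjects      = "integer",
    subdiv         = "integer",
    factorSd       = "numeric",
    vertexNoiseSd  = "numeric",
    nVariants      = "integer",
    nRegions       = "integer",
    freqRange      = "numeric",
    rhoLD          = "numeric",
    nCausal        = "integer",
    h2PerVariant   = "numeric",
    covariateShare = "numeric",
    seed           = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 2L) msg <- c(msg, "need at least 2 subjects")
  if (length(object@factorSd) != 4L) msg <- c(msg, "factorSd must have 4 entries (one per deformation factor)")
  if (any(object@factorSd < 0) || object@vertexNoiseSd < 0) msg <- c(msg, "sds must be >= 0")
  if (object@rhoLD < 0 || object@rhoLD >= 1) msg <- c(msg, "rhoLD must be in [0,1)")
  if (length(object@freqRange) != 2L || object@freqRange[1L] <= 0 ||
      object@freqRange[2L] >= 1 || diff(object@freqRange) < 0)
    msg <- c(msg, "freqRange must be 0 < lo <= hi < 1")
  if (object@nCausal > 0L) {
    perFactor <- tabulate(rep_len(seq_len(4L), object@nCausal), 4L)
    if (any(perFactor * object@h2PerVariant + object@covariateShare >= 1))
      msg <- c(msg, "per-factor explained variance (genetic + covariate) must be < 1")
  }
  if (object@nVariants %% object@nRegions != 0L)
    msg <- c(msg, "nVariants must be a multiple of nRegions")
  if (length(msg)) msg else TRUE
})
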