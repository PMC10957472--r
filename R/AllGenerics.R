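#' @include AllClasses.R
NULL

#' Accessors for mesh and cohort objects
#'
#' @param x an object.
#' @param ... unused.
#' @return the requested slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x, ...) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(x, ...) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(x, ...) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("nVertices", function(x, ...) standardGeneric("nVertices"))
#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x, ...) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x, ...) standardGeneric("nSubjects"))
#' @rdname accessors
#' @export
setGeneric("shapes", function(x, ...) standardGeneric("shapes"))
#' @rdname accessors
#' @export
setGeneric("isAligned", function(x, ...) standardGeneric("isAligned"))
#' @rdname accessors
#' @export
setGeneric("latents", function(x, ...) standardGeneric("latents"))
#' @rdname accessors
#' @export
setGeneric("testRmsd", function(x, ...) standardGeneric("testRmsd"))
#' @rdname accessors
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("variants", function(x, ...) standardGeneric("variants"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x, ...) standardGeneric("provenance"))

setMethod("vertices", "TriangleMesh", function(x, ...) x@vertices)
setMethod("faces", "TriangleMesh", function(x, ...) x@faces)
setMethod("adjacency", "TriangleMesh", function(x, ...) x@adjacency)
setMethod("nVertices", "TriangleMesh", function(x, ...) nrow(x@vertices))
setMethod("subjectIds", "ShapeCohort", function(x, ...) x@subjectIds)
setMethod("nSubjects", "ShapeCohort", function(x, ...) dim(x@shapes)[1L])
setMethod("nVertices", "ShapeCohort", function(x, ...) dim(x@shapes)[2L])
setMethod("shapes", "ShapeCohort", function(x, ...) x@shapes)
setMethod("faces", "ShapeCohort", function(x, ...) x@templateFaces)
setMethod("isAligned", "ShapeCohort", function(x, ...) x@aligned)
setMethod("latents", "RunResult", function(x, ...) x@latents)
setMethod("subjectIds", "RunResult", function(x, ...) x@subjectIds)
setMethod("testRmsd", "RunResult", function(x, ...) x@testRmsdMean)
setMethod("dosages", "GenotypeMatrix", function(x, ...) x@dosages)
setMethod("variants", "GenotypeMatrix", function(x, ...) x@variants)
setMethod("subjectIds", "GenotypeMatrix", function(x, ...) x@subjectIds)
setMethod("nSubjects", "GenotypeMatrix", function(x, ...) length(x@subjectIds))
setMethod("scores", "PhenotypeScores", function(x, ...) x@scores)
setMethod("subjectIds", "PhenotypeScores", function(x, ...) x@subjectIds)
setMethod("provenance", "PhenotypeScores", function(x, ...) x@provenance)

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces, %d edges\n",
              nrow(object@vertices), nrow(object@faces),
              as.integer(Matrix::nnzero(object@adjacency) / 2)))
})

setMethod("show", "ShapeCohort", function(object) {
  d <- dim(object@shapes)
  cat(sprintf("ShapeCohort: %d subjects x %d vertices (%s)\n",
              d[1L], d[2L], if (object@aligned) "aligned" else "unaligned"))
})

setMethod("show", "GraphLaplacian", function(object) {
  cat(sprintf("GraphLaplacian (%s): %d x %d\n",
              object@mode, nrow(object@laplacian), ncol(object@laplacian)))
})

setMethod("show", "ShapePcaModel", function(object) {
  evr <- sum(object@eigenvalues) / object@totalVariance
  cat(sprintf("ShapePcaModel: %d components over %d coordinates (%.1f%% variance)\n",
              object@nComponents, length(object@meanShape), 100 * evr))
})

setMethod("show", "SamplingOperators", function(object) {
  ms <- vapply(object@levelMeshes, function(m) nrow(m@vertices), integer(1))
  cat("SamplingOperators:", paste(ms, collapse = " -> "), "vertices\n")
})

setMethod("show", "ComaConfig", function(object) {
  cat(sprintf(
    "ComaConfig: nZ=%d K=%d channels=(%s) ds=(%s) wKL=%g loss=%s seeds=(%d,%d)\n",
    object@nZ, object@chebOrder, paste(object@channels, collapse = ","),
    paste(object@dsFactors, collapse = ","), object@wKL, object@reconLoss,
    object@seedWeights, object@seedSplit))
})

setMethod("show", "RunResult", function(object) {
  cat(sprintf("RunResult %s: %d subjects x %d latents, test RMSD %.3f mm\n",
              object@runId, nrow(object@latents), ncol(object@latents),
              object@testRmsdMean))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d variants x %d subjects\n",
              nrow(object@dosages), length(object@subjectIds)))
})

setMethod("show", "PhenotypeScores", function(object) {
  cat(sprintf("PhenotypeScores: %d subjects x %d phenotypes\n",
              nrow(object@scores), ncol(object@scores)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: N=%d, M~%d (subdiv %d), V=%d in %d regions, %d causal (h2=%g), seed=%d\n",
    object@nSubjects, 10L * 4L^(object@subdiv + 1L) + 2L, object@subdiv,
    object@nVariants, object@nRegions, object@nCausal, object@h2PerVariant,
    object@seed))
})
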