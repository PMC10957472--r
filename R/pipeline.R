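#' @include AllClasses.R AllGenerics.R mesh.R procrustes.R shape_pca.R coma.R gwas.R upe.R simulate.R io.R
NULL

## small stable hash for provenance stamping (no external digest dependency)
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Handcrafted geometric phenotypes of a cohort
#'
#' Per-subject cavity volume (ml) and isoperimetric sphericity computed from
#' each subject's mesh. The sphericity definition is the isoperimetric index
#' \eqn{\pi^{1/3}(6V)^{2/3}/A} (flagged in the column metadata as such).
#'
#' @param cohort a \linkS4class{ShapeCohort}.
#' @return data.frame with subject_id, volume_ml, sphericity.
#' @export
handcraftedPhenotypes <- function(cohort) {
  ## closedness/orientation is a property of the shared connectivity: check once
  if (!isClosed(cohortMesh(cohort, 1L)))
    stop("handcrafted phenotypes need a closed template")
  f <- cohort@templateFaces
  S <- cohort@shapes
  p1 <- list(S[, f[, 1L], 1L], S[, f[, 1L], 2L], S[, f[, 1L], 3L])
  p2 <- list(S[, f[, 2L], 1L], S[, f[, 2L], 2L], S[, f[, 2L], 3L])
  p3 <- list(S[, f[, 3L], 1L], S[, f[, 3L], 2L], S[, f[, 3L], 3L])
  det3 <- p1[[1L]] * (p2[[2L]] * p3[[3L]] - p2[[3L]] * p3[[2L]]) -
          p1[[2L]] * (p2[[1L]] * p3[[3L]] - p2[[3L]] * p3[[1L]]) +
          p1[[3L]] * (p2[[1L]] * p3[[2L]] - p2[[2L]] * p3[[1L]])
  vol <- rowSums(det3) / 6
  if (any(vol <= 0)) stop("non-positive cavity volume (inward orientation?)")
  e1 <- lapply(1:3, function(k) p2[[k]] - p1[[k]])
  e2 <- lapply(1:3, function(k) p3[[k]] - p1[[k]])
  cx <- e1[[2L]] * e2[[3L]] - e1[[3L]] * e2[[2L]]
  cy <- e1[[3L]] * e2[[1L]] - e1[[1L]] * e2[[3L]]
  cz <- e1[[1L]] * e2[[2L]] - e1[[2L]] * e2[[1L]]
  area <- rowSums(sqrt(cx^2 + cy^2 + cz^2)) / 2
  out <- data.frame(subject_id = cohort@subjectIds, volume_ml = vol / 1000,
                    sphericity = pi^(1 / 3) * (6 * vol)^(2 / 3) / area)
  attr(out, "sphericity_definition") <- "isoperimetric"
  out
}

#' Manhattan plot of one phenotype's association results
#'
#' @param gwasTable association table (single phenotype or pre-filtered).
#' @param pGw,pSw thresholds drawn as horizontal lines.
#' @return a ggplot object (requires \pkg{ggplot2}).
#' @export
manhattanPlot <- function(gwasTable, pGw = 5e-8, pSw = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for manhattanPlot")
  df <- gwasTable
  df$chrom <- factor(df$chrom, levels = unique(df$chrom[order(
    suppressWarnings(as.numeric(df$chrom)), df$chrom)]))
  ## cumulative genome coordinate
  offs <- c(0, cumsum(tapply(df$pos, df$chrom, max)))
  df$x <- df$pos + offs[as.integer(df$chrom)]
  df$logp <- -log10(df$p)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$logp,
                                         colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(pGw), linetype = 2) +
    ggplot2::labs(x = "genome position", y = expression(-log[10](P))) +
    ggplot2::theme_minimal()
  if (!is.null(pSw))
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(pSw), linetype = 3)
  gg
}

#' Run the full discovery pipeline on a fixture directory
#'
#' Executes align -> shape PCA -> autoencoder ensemble training -> run
#' selection -> latent pooling/deduplication -> handcrafted indices ->
#' covariate-adjusted GWAS per run -> region counting -> locus
#' classification -> nearest-gene annotation -> report. Artifacts are
#' written per stage under \code{outDir} with a MANIFEST carrying the
#' configuration hash and seeds; a stage whose artifact already exists with
#' a matching hash is skipped, making the pipeline resumable.
#'
#' @param fixtureDir directory from \code{\link{writeFixture}} (or with the
#'   same layout).
#' @param outDir output directory.
#' @param ensemble list of \linkS4class{ComaConfig} for autoencoder runs
#'   (may be empty: the ensemble then consists of the PCA baseline and
#'   handcrafted indices only).
#' @param ensembleCfg an \linkS4class{EnsembleConfig}.
#' @param nPcaComponents PCA baseline width (default 16).
#' @param covariateCols covariate columns used for adjustment.
#' @param qc list of QC thresholds (mafMin, hwePMin, infoMin).
#' @param makePlots write Manhattan plots (needs ggplot2).
#' @param verbose print stage progress.
#' @return invisibly, a list with the locus table, per-run association
#'   tables, pooled phenotype info and file paths.
#' @export
runPipeline <- function(fixtureDir, outDir, ensemble = list(),
                        ensembleCfg = ensembleConfig(),
                        nPcaComponents = 16L,
                        covariateCols = c("sex", "age", "height", "weight", "bmi"),
                        qc = list(mafMin = 0.01, hwePMin = 1e-5, infoMin = 0.3),
                        makePlots = FALSE, verbose = TRUE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[upekit] ", ...)
  cfgHash <- .configHash(list(ensemble = lapply(ensemble, function(c)
    list(c@nZ, c@chebOrder, c@channels, c@dsFactors, c@wKL, c@reconLoss,
         c@learningRate, c@epochs, c@batchSize, c@seedWeights, c@seedSplit)),
    pGw = ensembleCfg@pGw, rmsd = ensembleCfg@rmsdKeepMm,
    sp = ensembleCfg@spearmanMax, sg = ensembleCfg@suggestiveMinCount,
    ds = ensembleCfg@dedupSeed, nPca = nPcaComponents, cov = covariateCols,
    qc = qc))
  manifestPath <- file.path(outDir, "MANIFEST.json")
  manifest <- if (file.exists(manifestPath))
    jsonlite::read_json(manifestPath, simplifyVector = TRUE) else list()
  if (!identical(manifest$config_hash, cfgHash)) {
    manifest <- list(config_hash = cfgHash, created = as.character(Sys.time()),
                     stages = list())
  }
  stageDone <- function(stage, files) {
    isTRUE(stage %in% names(manifest$stages)) && all(file.exists(files))
  }
  markStage <- function(stage, files) {
    manifest$stages[[stage]] <<- list(files = files,
                                      time = as.character(Sys.time()))
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         pretty = TRUE)
  }

  fx <- readFixture(fixtureDir)

  ## stage: align
  alignedPath <- file.path(outDir, "aligned.upec")
  if (!stageDone("align", alignedPath)) {
    say("aligning cohort (generalized Procrustes)")
    gp <- generalizedProcrustes(fx$cohort)
    writeCohortArchive(gp$cohort, alignedPath)
    writePly(buildMesh(gp$meanShape, fx$cohort@templateFaces,
                       repairWinding = FALSE),
             file.path(outDir, "mean_shape.ply"))
    markStage("align", alignedPath)
  } else say("align: cached")
  aligned <- readCohortArchive(alignedPath)
  meanShape <- apply(aligned@shapes, c(2L, 3L), mean)

  ## stage: pca
  pcaPath <- file.path(outDir, "pca_latents.tsv")
  if (!stageDone("pca", pcaPath)) {
    say("fitting shape PCA (", nPcaComponents, " components)")
    pcaModel <- fitShapePca(aligned, nPcaComponents)
    pcaLat <- pcaEncode(pcaModel, aligned)
    colnames(pcaLat) <- paste0("PC", seq_len(ncol(pcaLat)))
    utils::write.table(data.frame(subject_id = aligned@subjectIds, pcaLat),
                       pcaPath, sep = "\t", quote = FALSE, row.names = FALSE)
    markStage("pca", pcaPath)
  } else say("pca: cached")
  pcaLat <- as.matrix(utils::read.table(pcaPath, sep = "\t", header = TRUE,
                                        row.names = 1L))

  ## stage: train (autoencoder ensemble)
  runResults <- list()
  if (length(ensemble)) {
    trainDir <- file.path(outDir, "runs")
    dir.create(trainDir, showWarnings = FALSE)
    template <- buildMesh(meanShape, aligned@templateFaces,
                          repairWinding = FALSE)
    opsCache <- list()
    for (ri in seq_along(ensemble)) {
      cfg <- ensemble[[ri]]
      runId <- sprintf("coma%02d", ri)
      latPath <- file.path(trainDir, paste0(runId, "_latents.tsv"))
      rmsdPath <- file.path(trainDir, paste0(runId, "_rmsd.tsv"))
      if (stageDone(paste0("train_", runId), c(latPath, rmsdPath))) {
        say("train ", runId, ": cached")
        lat <- as.matrix(utils::read.table(latPath, sep = "\t", header = TRUE,
                                           row.names = 1L))
        rm <- utils::read.table(rmsdPath, sep = "\t", header = TRUE)
        runResults[[runId]] <- methods::new(
          "RunResult", runId = runId, config = cfg, latents = lat,
          subjectIds = rownames(lat), perSubjectRmsd = rm$rmsd_mm,
          testRmsdMean = rm$test_mean[1L],
          history = data.frame(), model = NULL)
        next
      }
      key <- paste(cfg@dsFactors, collapse = "x")
      if (is.null(opsCache[[key]]))
        opsCache[[key]] <- buildSamplingOperators(template, cfg@dsFactors)
      say("training ", runId, " (nZ=", cfg@nZ, ", wKL=", cfg@wKL,
          ", seeds=", cfg@seedWeights, "/", cfg@seedSplit, ")")
      rr <- trainComa(aligned, opsCache[[key]], cfg, runId = runId)
      runResults[[runId]] <- rr
      utils::write.table(data.frame(subject_id = rr@subjectIds, rr@latents),
                         latPath, sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(data.frame(subject_id = rr@subjectIds,
                                    rmsd_mm = rr@perSubjectRmsd,
                                    test_mean = rr@testRmsdMean),
                         rmsdPath, sep = "\t", quote = FALSE, row.names = FALSE)
      markStage(paste0("train_", runId), c(latPath, rmsdPath))
    }
    say("selecting runs with test RMSD < ", ensembleCfg@rmsdKeepMm, " mm")
    runResults <- selectRuns(runResults, ensembleCfg@rmsdKeepMm)
  }

  ## stage: handcrafted indices
  hcPath <- file.path(outDir, "handcrafted.tsv")
  if (!stageDone("handcrafted", hcPath)) {
    say("computing handcrafted indices (volume, sphericity)")
    hc <- handcraftedPhenotypes(aligned)
    utils::write.table(hc, hcPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    markStage("handcrafted", hcPath)
  } else say("handcrafted: cached")
  hc <- utils::read.table(hcPath, sep = "\t", header = TRUE)

  ## pool + dedup over all phenotype sources (runs keep their identity)
  latentSets <- list()
  for (runId in names(runResults)) latentSets[[runId]] <- runResults[[runId]]@latents
  latentSets[["pca"]] <- pcaLat
  hcm <- as.matrix(hc[, c("volume_ml", "sphericity")])
  rownames(hcm) <- hc$subject_id
  latentSets[["handcrafted"]] <- hcm
  say("pooling ", length(latentSets), " phenotype sets")
  pool <- poolAndDeduplicate(latentSets, ensembleCfg@spearmanMax,
                             ensembleCfg@dedupSeed, ensembleCfg@dedupMode)
  kPheno <- pool$kPheno
  pSw <- studyWideThreshold(ensembleCfg@pGw, kPheno)
  say("K = ", kPheno, " phenotypes after dedup; P_SW = ", signif(pSw, 3))

  ## stage: genotype QC
  say("variant QC")
  qcRes <- variantQc(fx$genotypes, qc$mafMin, qc$hwePMin, qc$infoMin)
  geno <- subsetVariants(fx$genotypes, qcRes$keep)
  utils::write.table(qcRes$report, file.path(outDir, "variant_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage: gwas per run
  covM <- as.matrix(fx$covariates[match(aligned@subjectIds,
                                        fx$covariates$subject_id),
                                  covariateCols, drop = FALSE])
  gwasDir <- file.path(outDir, "gwas")
  gwasTables <- list()
  for (runId in unique(pool$provenance$run_id)) {
    colsSel <- pool$provenance$phenotype_id[pool$provenance$run_id == runId]
    mat <- pool$pooled[, colsSel, drop = FALSE]
    say("GWAS for ", runId, " (", ncol(mat), " phenotypes)")
    ps <- phenotypeScores(stats::setNames(list(mat), runId), covM,
                          aligned@subjectIds)
    gwasTables[[runId]] <- linearScan(ps, geno)
    writeGwasTables(gwasTables[[runId]], gwasDir)
  }

  ## stage: aggregate + classify + annotate
  say("aggregating over ", nrow(fx$regions), " regions")
  counts <- countRegionHits(gwasTables, fx$regions, ensembleCfg@pGw)
  loci <- classifyLoci(counts, gwasTables, fx$regions, pSw,
                       ensembleCfg@pGw, ensembleCfg@suggestiveMinCount)
  loci <- annotateNearestGene(loci, fx$genes)
  lociPath <- file.path(outDir, "locus_table.tsv")
  utils::write.table(loci, lociPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## stage: report
  report <- list(config_hash = cfgHash, n_subjects = nSubjects(aligned),
                 n_variants_post_qc = nrow(geno@variants),
                 k_pheno = kPheno, p_sw = pSw, p_gw = ensembleCfg@pGw,
                 n_runs = length(gwasTables),
                 dedup_dropped = nrow(pool$dropLog),
                 n_significant = sum(loci$classification == "significant"),
                 n_suggestive = sum(loci$classification == "suggestive"))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  ## latent-traversal report: average meshes within latent quantile bins for
  ## the phenotype carrying the overall best association
  bestTab <- do.call(rbind, gwasTables)
  if (nrow(bestTab)) {
    bestPh <- bestTab$phenotype_id[which.min(bestTab$p)]
    if (bestPh %in% colnames(pool$pooled)) {
      sweepDir <- file.path(outDir, "latent_sweep")
      dir.create(sweepDir, showWarnings = FALSE)
      qs <- averageShapeByQuantile(aligned, pool$pooled[, bestPh])
      for (b in seq_along(qs)) if (!is.null(qs[[b]]))
        writePly(buildMesh(qs[[b]], aligned@templateFaces,
                           repairWinding = FALSE),
                 file.path(sweepDir, sprintf("%s_bin%d.ply",
                                             gsub("[^A-Za-z0-9_.-]", "_", bestPh), b)))
    }
  }
  if (makePlots && requireNamespace("ggplot2", quietly = TRUE)) {
    for (runId in names(gwasTables)) {
      tab <- gwasTables[[runId]]
      best <- tab[tab$p == min(tab$p), "phenotype_id"][1L]
      gg <- manhattanPlot(tab[tab$phenotype_id == best, ], ensembleCfg@pGw, pSw)
      ggplot2::ggsave(file.path(outDir, paste0("manhattan_", runId, ".png")),
                      gg, width = 8, height = 3, dpi = 120)
    }
  }
  markStage("report", c(lociPath, file.path(outDir, "report.json")))
  say("done: ", report$n_significant, " significant, ",
      report$n_suggestive, " suggestive loci")
  invisible(list(loci = loci, gwasTables = gwasTables, pool = pool,
                 pSw = pSw, report = report, runResults = runResults,
                 paths = list(out = outDir, loci = lociPath)))
}
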