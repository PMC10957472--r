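#' @include AllClasses.R AllGenerics.R
NULL

#' Ensemble configuration
#'
#' @param pGw genome-wide significance threshold (default 5e-8).
#' @param rmsdKeepMm run-selection cut on mean test RMSD, strict (default 1 mm).
#' @param spearmanMax absolute Spearman correlation above which one of a pair
#'   of latents is dropped (default 0.95).
#' @param suggestiveMinCount minimum number of runs for a suggestive call
#'   (default 5, i.e. "five or more").
#' @param dedupSeed seed for the random member-of-pair drop.
#' @param dedupMode \code{"random"} (seeded coin) or \code{"drop-later"}
#'   (deterministic: always drop the later column).
#' @return an \linkS4class{EnsembleConfig}.
#' @export
ensembleConfig <- function(pGw = 5e-8, rmsdKeepMm = 1.0, spearmanMax = 0.95,
                           suggestiveMinCount = 5L, dedupSeed = 1L,
                           dedupMode = "random") {
  methods::new("EnsembleConfig", pGw = pGw, rmsdKeepMm = rmsdKeepMm,
               spearmanMax = spearmanMax,
               suggestiveMinCount = as.integer(suggestiveMinCount),
               dedupSeed = as.integer(dedupSeed), dedupMode = dedupMode)
}

#' Select runs by reconstruction error
#'
#' Keeps the runs whose mean test-set reconstruction RMSD is strictly below
#' the threshold. Selection depends only on reconstruction error, never on
#' association results, so the null p-value distribution of the kept runs
#' stays uniform.
#'
#' @param runs list of \linkS4class{RunResult}.
#' @param rmsdKeepMm threshold in mm (strict inequality; default 1).
#' @return the kept subset of \code{runs}.
#' @export
selectRuns <- function(runs, rmsdKeepMm = 1.0) {
  rmsds <- vapply(runs, function(r) r@testRmsdMean, numeric(1))
  keep <- rmsds < rmsdKeepMm
  if (!any(keep))
    stop("no run has test RMSD below ", rmsdKeepMm, " mm (min was ",
         signif(min(rmsds), 3), ")")
  runs[keep]
}

#' Pool latents across runs and deduplicate
#'
#' Concatenates the latent matrices of the kept runs (columns labelled
#' run.latent), then scans all column pairs in order and, whenever a pair
#' has absolute Spearman correlation above the threshold, drops one member:
#' at random with a seeded coin (default, reproducible) or always the later
#' column. The surviving column count is the K that divides the genome-wide
#' threshold.
#'
#' @param runs list of \linkS4class{RunResult} with identical subject
#'   ordering, or a named list of latent matrices.
#' @param spearmanMax absolute-correlation threshold (default 0.95).
#' @param dedupSeed integer seed for the coin.
#' @param dedupMode \code{"random"} or \code{"drop-later"}.
#' @return list with \code{pooled} (N x K matrix), \code{kPheno},
#'   \code{provenance} (data.frame) and \code{dropLog}.
#' @export
poolAndDeduplicate <- function(runs, spearmanMax = 0.95, dedupSeed = 1L,
                               dedupMode = c("random", "drop-later")) {
  dedupMode <- match.arg(dedupMode)
  if (length(runs) && methods::is(runs[[1L]], "RunResult")) {
    ids <- lapply(runs, function(r) r@subjectIds)
    for (i in seq_along(runs)[-1L])
      if (!identical(ids[[i]], ids[[1L]]))
        stop("runs have different subject orderings")
    mats <- lapply(runs, function(r) {
      m <- r@latents
      colnames(m) <- paste0(r@runId, ".", colnames(m))
      m
    })
  } else {
    mats <- lapply(names(runs), function(nm) {
      m <- runs[[nm]]
      if (is.null(colnames(m))) colnames(m) <- paste0("z", seq_len(ncol(m)))
      colnames(m) <- paste0(nm, ".", colnames(m))
      m
    })
  }
  pooled <- do.call(cbind, mats)
  N <- nrow(pooled)
  if (N < 10L) stop("rank correlation needs at least 10 subjects")
  K0 <- ncol(pooled)
  rho <- stats::cor(pooled, method = "spearman")
  alive <- rep(TRUE, K0)
  drops <- list()
  coin <- .withSeed(dedupSeed, stats::runif(K0 * (K0 - 1L) / 2L))
  ci <- 0L
  for (i in seq_len(K0 - 1L)) {
    for (j in (i + 1L):K0) {
      ci <- ci + 1L
      if (!alive[i] || !alive[j]) next
      if (abs(rho[i, j]) > spearmanMax) {
        drop <- if (dedupMode == "drop-later") j
                else if (coin[ci] < 0.5) i else j
        alive[drop] <- FALSE
        drops[[length(drops) + 1L]] <- data.frame(
          kept = colnames(pooled)[if (drop == i) j else i],
          dropped = colnames(pooled)[drop],
          rho = rho[i, j])
      }
    }
  }
  runIds <- rep(vapply(seq_along(mats), function(k) {
    if (length(runs) && methods::is(runs[[1L]], "RunResult"))
      runs[[k]]@runId else names(runs)[k]
  }, character(1)), vapply(mats, ncol, integer(1)))
  list(pooled = pooled[, alive, drop = FALSE],
       kPheno = sum(alive),
       provenance = data.frame(phenotype_id = colnames(pooled)[alive],
                               run_id = runIds[alive]),
       dropLog = if (length(drops)) do.call(rbind, drops) else
         data.frame(kept = character(0), dropped = character(0),
                    rho = numeric(0)))
}

#' Study-wide significance threshold
#'
#' Bonferroni division of the genome-wide threshold by the number of pooled,
#' deduplicated phenotypes: \eqn{P_{SW} = P_{GW} / K}.
#'
#' @param pGw genome-wide threshold (default 5e-8).
#' @param kPheno number of phenotypes after deduplication.
#' @return the corrected threshold.
#' @examples
#' studyWideThreshold(5e-8, 324)  # 1.5e-10
#' @export
studyWideThreshold <- function(pGw = 5e-8, kPheno) {
  if (kPheno < 1) stop("kPheno must be >= 1")
  pGw / kPheno
}

#' Generic Bonferroni threshold
#'
#' \code{alpha / nTests}; used e.g. for transcriptome-wide follow-up tests
#' where the family is phenotypes x tissue-gene pairs.
#'
#' @param alpha family-wise error target in (0, 1).
#' @param nTests number of tests (>= 1).
#' @return adjusted threshold.
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (nTests < 1) stop("nTests must be >= 1")
  alpha / nTests
}

#' Read a region partition from BED
#'
#' BED-style 0-based half-open intervals, columns chrom/start/end (a fourth
#' column is used as region id when present). Regions must be
#' non-overlapping within a chromosome.
#'
#' @param path BED file path.
#' @return region data.frame (region_id, chrom, start, end).
#' @export
readRegionsBed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  regions <- data.frame(
    region_id = if (ncol(bed) >= 4L) as.character(bed[[4L]]) else
      paste0(bed[[1L]], ":", bed[[2L]], "-", bed[[3L]]),
    chrom = as.character(bed[[1L]]),
    start = as.numeric(bed[[2L]]), end = as.numeric(bed[[3L]]))
  validateRegions(regions)
}

#' Validate a region partition
#'
#' @param regions data.frame with region_id, chrom, start, end (half-open).
#' @return the regions, sorted by (chrom, start).
#' @export
validateRegions <- function(regions) {
  if (any(regions$end <= regions$start)) stop("empty or negative-length region")
  if (anyDuplicated(regions$region_id)) stop("duplicated region ids")
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  for (ch in unique(regions$chrom)) {
    sub <- regions[regions$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("overlapping regions on chromosome ", ch)
  }
  rownames(regions) <- NULL
  regions
}

#' Assign association rows to regions
#'
#' Half-open interval assignment: a variant belongs to the region with
#' \code{start <= pos < end} on its chromosome. Rows outside every region
#' get NA with a warning.
#'
#' @param gwasTable association table with chrom and pos columns.
#' @param regions region partition (see \code{\link{validateRegions}}).
#' @return character vector of region ids aligned with the table rows.
#' @export
assignRegions <- function(gwasTable, regions) {
  regions <- validateRegions(regions)
  out <- rep(NA_character_, nrow(gwasTable))
  chroms <- as.character(gwasTable$chrom)
  bad <- is.na(chroms) | chroms == ""
  if (any(bad))
    stop("malformed chromosome names at rows: ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  for (ch in unique(chroms)) {
    sub <- regions[regions$chrom == ch, , drop = FALSE]
    ri <- which(chroms == ch)
    if (!nrow(sub)) next
    pos <- gwasTable$pos[ri]
    k <- findInterval(pos, sub$start)         # regions sorted by start
    hit <- k >= 1L & pos < sub$end[pmax(k, 1L)]
    out[ri[hit]] <- sub$region_id[k[hit]]
  }
  if (anyNA(out))
    warning(sum(is.na(out)), " row(s) fall outside every region")
  out
}

#' Count per-region hits across runs
#'
#' For each run r and region l, takes the minimum association p-value over
#' that run's phenotypes and the region's variants, \eqn{p_{l,r}}; the
#' region's count is the number of runs with \eqn{p_{l,r} < p_{GW}} and
#' \eqn{P_{best}} is the minimum over all runs.
#'
#' @param gwasTables list of association tables, one per run (each may hold
#'   several phenotypes).
#' @param regions region partition.
#' @param pGw genome-wide threshold (default 5e-8).
#' @return list with \code{stats} (data.frame region_id, pBest, count) and
#'   \code{pMatrix} (regions x runs matrix of \eqn{p_{l,r}}).
#' @export
countRegionHits <- function(gwasTables, regions, pGw = 5e-8) {
  regions <- validateRegions(regions)
  if (!nrow(regions)) stop("empty region set")
  R <- length(gwasTables)
  pMat <- matrix(NA_real_, nrow(regions), R,
                 dimnames = list(regions$region_id,
                                 if (!is.null(names(gwasTables)))
                                   names(gwasTables) else paste0("run", seq_len(R))))
  for (r in seq_len(R)) {
    tab <- gwasTables[[r]]
    rid <- assignRegions(tab, regions)
    ok <- !is.na(rid)
    if (!any(ok)) next
    mins <- tapply(tab$p[ok], rid[ok], min)
    pMat[names(mins), r] <- as.numeric(mins)
  }
  count <- rowSums(pMat < pGw, na.rm = TRUE)
  pBest <- suppressWarnings(apply(pMat, 1L, min, na.rm = TRUE))
  pBest[!is.finite(pBest)] <- NA_real_
  list(stats = data.frame(region_id = regions$region_id, pBest = pBest,
                          count = as.integer(count)),
       pMatrix = pMat)
}

#' Classify loci
#'
#' Applies the ensemble classification rules: a region is significant when
#' \eqn{P_{best} < P_{SW}}; suggestive when
#' \eqn{P_{SW} \le P_{best} < P_{GW}} and it passed the genome-wide
#' threshold in at least \code{suggestiveMinCount} runs; otherwise
#' non-significant. The lead variant (and its phenotype/run, effect size,
#' standard error and EAF) is the overall argmin p in the region, ties
#' broken by position then variant id.
#'
#' @param regionStats output of \code{\link{countRegionHits}}.
#' @param gwasTables the same per-run association tables, for lead-variant
#'   lookup.
#' @param regions region partition.
#' @param pSw study-wide threshold.
#' @param pGw genome-wide threshold (default 5e-8).
#' @param suggestiveMinCount minimum count for suggestive (default 5).
#' @return the locus table: one row per region with pBest, count,
#'   classification, lead variant columns.
#' @export
classifyLoci <- function(regionStats, gwasTables, regions, pSw,
                         pGw = 5e-8, suggestiveMinCount = 5L) {
  regions <- validateRegions(regions)
  st <- regionStats$stats
  cls <- rep("non_significant", nrow(st))
  sig <- !is.na(st$pBest) & st$pBest < pSw
  sug <- !is.na(st$pBest) & !sig & st$pBest < pGw &
    st$count >= suggestiveMinCount
  cls[sig] <- "significant"
  cls[sug] <- "suggestive"
  ## lead variant per region over all runs/phenotypes
  all <- do.call(rbind, lapply(seq_along(gwasTables), function(r) {
    tab <- gwasTables[[r]]
    runId <- if (!is.null(names(gwasTables))) names(gwasTables)[r]
             else paste0("run", r)
    data.frame(run_id = runId, tab[c("phenotype_id", "variant_id", "chrom",
                                     "pos", "ea", "nea", "eaf", "beta_hat",
                                     "se", "p")])
  }))
  all$region_id <- assignRegions(all, regions)
  lead <- data.frame(region_id = st$region_id,
                     lead_variant_id = NA_character_,
                     lead_phenotype_id = NA_character_,
                     lead_run_id = NA_character_,
                     chrom = NA_character_, pos = NA_real_,
                     ea = NA_character_, nea = NA_character_,
                     eaf = NA_real_, beta_hat = NA_real_, se = NA_real_)
  byRegion <- split(seq_len(nrow(all)), all$region_id)
  for (rid in names(byRegion)) {
    rows <- all[byRegion[[rid]], , drop = FALSE]
    rows <- rows[order(rows$p, rows$pos, rows$variant_id), , drop = FALSE]
    k <- match(rid, lead$region_id)
    lead$lead_variant_id[k] <- rows$variant_id[1L]
    lead$lead_phenotype_id[k] <- rows$phenotype_id[1L]
    lead$lead_run_id[k] <- rows$run_id[1L]
    lead$chrom[k] <- as.character(rows$chrom[1L])
    lead$pos[k] <- rows$pos[1L]
    lead$ea[k] <- rows$ea[1L]; lead$nea[k] <- rows$nea[1L]
    lead$eaf[k] <- rows$eaf[1L]
    lead$beta_hat[k] <- rows$beta_hat[1L]; lead$se[k] <- rows$se[1L]
  }
  out <- cbind(st, classification = cls,
               lead[match(st$region_id, lead$region_id),
                    -1L, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Annotate lead variants with the nearest gene
#'
#' For each classified locus with a lead variant, finds the gene with the
#' smallest distance to its gene body on the same chromosome and reports
#' strand-aware signed distances to the transcription start and end sites
#' (TSS = start for +, end for -; positive = downstream of the site in the
#' gene's reading direction; 0 when the variant lies inside the gene body).
#'
#' @param loci locus table from \code{\link{classifyLoci}}.
#' @param genes data.frame with columns gene, chrom, tss, tes, strand
#'   ("+"/"-").
#' @return the locus table with nearest_gene, distance_to_tss,
#'   distance_to_tes columns.
#' @export
annotateNearestGene <- function(loci, genes) {
  loci$nearest_gene <- NA_character_
  loci$distance_to_tss <- NA_real_
  loci$distance_to_tes <- NA_real_
  if (is.null(genes) || !nrow(genes)) {
    warning("empty gene table; nearest-gene annotation skipped")
    return(loci)
  }
  gstart <- pmin(genes$tss, genes$tes)
  gend <- pmax(genes$tss, genes$tes)
  for (i in seq_len(nrow(loci))) {
    if (is.na(loci$lead_variant_id[i])) next
    sel <- which(genes$chrom == loci$chrom[i])
    if (!length(sel)) next
    pos <- loci$pos[i]
    bodyDist <- pmax(gstart[sel] - pos, 0) + pmax(pos - gend[sel], 0)
    j <- sel[which.min(bodyDist)]
    sgn <- if (genes$strand[j] == "-") -1 else 1
    inside <- pos >= gstart[j] && pos <= gend[j]
    loci$nearest_gene[i] <- genes$gene[j]
    loci$distance_to_tss[i] <- if (inside) 0 else sgn * (pos - genes$tss[j])
    loci$distance_to_tes[i] <- if (inside) 0 else sgn * (pos - genes$tes[j])
  }
  loci
}
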