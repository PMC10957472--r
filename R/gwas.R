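#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a genotype matrix
#'
#' @param dosages numeric matrix \code{V x N} of effect-allele dosages in
#'   \code{[0, 2]} (NA = missing).
#' @param variants data.frame with columns \code{variant_id, chrom, pos, ea,
#'   nea, info} (1-based positions).
#' @param subjectIds character vector of length N.
#' @return a \linkS4class{GenotypeMatrix} (variants sorted by chrom, pos).
#' @export
genotypeMatrix <- function(dosages, variants, subjectIds) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- as.data.frame(variants)
  variants$chrom <- as.character(variants$chrom)
  ord <- order(variants$chrom, variants$pos, variants$variant_id)
  methods::new("GenotypeMatrix", dosages = dosages[ord, , drop = FALSE],
               variants = variants[ord, , drop = FALSE],
               subjectIds = as.character(subjectIds))
}

#' Effect-allele frequency of a dosage vector
#'
#' \code{mean(dose)/2} over non-missing entries.
#'
#' @param doses numeric dosages in \code{[0, 2]}, NA allowed.
#' @return EAF in \code{[0, 1]}.
#' @export
effectAlleleFrequency <- function(doses) {
  ok <- !is.na(doses)
  if (!any(ok)) stop("all dosages missing")
  mean(doses[ok]) / 2
}

#' Minor-allele frequency
#'
#' @param doses numeric dosages.
#' @return \code{min(EAF, 1 - EAF)}.
#' @export
minorAlleleFrequency <- function(doses) {
  eaf <- effectAlleleFrequency(doses)
  min(eaf, 1 - eaf)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the sum of the probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count (heterozygote
#' counts share the parity of the minor-allele count).
#'
#' @param nAA,nAa,naa non-negative genotype counts.
#' @return two-sided exact p-value in \code{(0, 1]}.
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) stop("negative genotype counts")
  n <- nAA + nAa + naa
  if (n == 0) stop("no observations")
  nA <- 2L * nAA + nAa
  na <- 2L * naa + nAa
  nMinor <- min(nA, na)
  if (nMinor == 0L) return(1)
  hets <- seq(nMinor %% 2L, nMinor, by = 2L)
  ## log P(het = h | allele counts) up to a constant:
  ## P ~ 2^h * n! / (nAA! nAa! naa!) with nAA = (nA - h)/2 etc.
  logp <- hets * log(2) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2)
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hets)]
  if (is.na(obs)) stop("observed heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Variant quality control
#'
#' Keeps a variant iff its minor-allele frequency, Hardy-Weinberg exact-test
#' p-value (computed on hard calls, i.e. dosages rounded to 0/1/2) and
#' imputation INFO score all pass their thresholds (MAF >= 1%, HWE p >=
#' 1e-5, INFO >= 0.3 by default).
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param mafMin,hwePMin,infoMin thresholds.
#' @return list with \code{keep} (logical mask) and \code{report}
#'   (per-variant data.frame of maf, hweP, info, keep and drop reason).
#' @export
variantQc <- function(genotypes, mafMin = 0.01, hwePMin = 1e-5, infoMin = 0.3) {
  D <- genotypes@dosages
  V <- nrow(D)
  eaf <- rowMeans(D, na.rm = TRUE) / 2
  maf <- pmin(eaf, 1 - eaf)
  hard <- pmin(pmax(round(D), 0), 2)
  nAA <- rowSums(hard == 2, na.rm = TRUE)
  nAa <- rowSums(hard == 1, na.rm = TRUE)
  naa <- rowSums(hard == 0, na.rm = TRUE)
  hweP <- vapply(seq_len(V), function(i) hweExactTest(nAA[i], nAa[i], naa[i]),
                 numeric(1))
  info <- genotypes@variants$info
  keep <- maf >= mafMin & hweP >= hwePMin & info >= infoMin
  reason <- character(V)
  reason[maf < mafMin] <- "low_maf"
  reason[hweP < hwePMin] <- paste0(reason[hweP < hwePMin], ";hwe")
  reason[info < infoMin] <- paste0(reason[info < infoMin], ";low_info")
  reason <- sub("^;", "", reason)
  if (!any(keep)) warning("no variant passed QC")
  list(keep = keep,
       report = data.frame(variant_id = genotypes@variants$variant_id,
                           maf = maf, hweP = hweP, info = info,
                           keep = keep, reason = reason))
}

#' Subset a genotype matrix
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param keep logical or integer index over variants.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
subsetVariants <- function(genotypes, keep) {
  methods::new("GenotypeMatrix",
               dosages = genotypes@dosages[keep, , drop = FALSE],
               variants = genotypes@variants[keep, , drop = FALSE],
               subjectIds = genotypes@subjectIds)
}

#' Rank-based inverse-normal transform
#'
#' Maps values to standard-normal quantiles by
#' \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))} with Blom offsets; ties receive
#' average ranks.
#'
#' @param x numeric vector without NA.
#' @return transformed vector.
#' @export
rankInverseNormal <- function(x) {
  if (anyNA(x)) stop("NA in input to rank inverse-normal transform")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

#' Covariate-adjust and inverse-normalize a phenotype
#'
#' Residualizes the raw phenotype on the covariates (with intercept) by
#' ordinary least squares, then applies the rank-based inverse-normal
#' transform; the result is the phenotypic score tested in association
#' scans.
#'
#' @param raw numeric vector of length N.
#' @param covariates numeric matrix \code{N x C} (no intercept column
#'   needed) or NULL for no adjustment.
#' @return numeric score vector, approximately N(0, 1).
#' @export
adjustPhenotype <- function(raw, covariates = NULL) {
  if (anyNA(raw)) stop("missing phenotype values; filter rows first")
  if (is.null(covariates) || NCOL(covariates) == 0L)
    return(rankInverseNormal(raw))
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  if (anyNA(X)) stop("missing covariate values; filter rows first")
  if (ncol(X) >= length(raw)) stop("more covariates than observations")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient covariates; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res <- qr.resid(qrX, raw)
  rankInverseNormal(res)
}

#' Build phenotype scores from latent matrices
#'
#' Applies \code{\link{adjustPhenotype}} column-wise to one or more latent
#' matrices (or handcrafted index vectors) and assembles a
#' \linkS4class{PhenotypeScores} object with per-column provenance.
#'
#' @param latentList named list of numeric matrices \code{N x k} (names
#'   become run ids in the provenance) or vectors.
#' @param covariates numeric matrix \code{N x C} or NULL.
#' @param subjectIds character vector of length N.
#' @return a \linkS4class{PhenotypeScores}.
#' @export
phenotypeScores <- function(latentList, covariates = NULL, subjectIds) {
  cols <- list(); ids <- character(); prov <- list()
  for (nm in names(latentList)) {
    Lm <- latentList[[nm]]
    if (is.null(dim(Lm))) Lm <- matrix(Lm, ncol = 1L,
                                       dimnames = list(NULL, nm))
    if (is.null(colnames(Lm))) colnames(Lm) <- paste0("z", seq_len(ncol(Lm)))
    for (j in seq_len(ncol(Lm))) {
      cn <- colnames(Lm)[j]
      pid <- if (startsWith(cn, paste0(nm, "."))) cn else paste0(nm, ".", cn)
      cols[[pid]] <- adjustPhenotype(Lm[, j], covariates)
      ids <- c(ids, pid)
      prov[[pid]] <- data.frame(phenotype_id = pid, run_id = nm,
                                source = colnames(Lm)[j])
    }
  }
  methods::new("PhenotypeScores",
               scores = do.call(cbind, cols),
               phenotypeIds = ids,
               subjectIds = as.character(subjectIds),
               provenance = do.call(rbind, prov))
}

#' Per-variant linear association scan
#'
#' For every (phenotype, variant) pair fits the univariate linear additive
#' model score ~ intercept + dosage by OLS and reports the effect estimate,
#' its standard error, the t statistic and the two-sided p-value from the t
#' distribution with n - 2 degrees of freedom. Missing dosages are
#' mean-imputed per variant (keeping n constant); monomorphic variants are
#' skipped with a reason. P-values that underflow are clamped to the
#' smallest positive double and flagged.
#'
#' @param phenoScores a \linkS4class{PhenotypeScores}.
#' @param genotypes a \linkS4class{GenotypeMatrix} over the same subjects in
#'   the same order.
#' @return a data.frame (the association table) with one row per
#'   (phenotype, variant), ordered by phenotype then (chrom, pos,
#'   variant_id), plus attribute \code{"skipped"} listing skipped variants.
#' @export
linearScan <- function(phenoScores, genotypes) {
  if (!identical(phenoScores@subjectIds, genotypes@subjectIds))
    stop("subject ids of scores and genotypes must match exactly (intersect and order first)")
  D <- genotypes@dosages
  n <- ncol(D)
  if (n < 3L) stop("need at least 3 subjects")
  ## per-variant mean imputation of missing dosages
  nas <- which(is.na(D))
  if (length(nas)) {
    rm <- rowMeans(D, na.rm = TRUE)
    D[nas] <- rm[((nas - 1L) %% nrow(D)) + 1L]
  }
  eaf <- rowMeans(D) / 2
  G <- D - rowMeans(D)
  sxx <- rowSums(G^2)
  poly <- sxx > 0
  skipped <- genotypes@variants$variant_id[!poly]
  Y <- phenoScores@scores
  Yc <- sweep(Y, 2L, colMeans(Y))
  syy <- colSums(Yc^2)
  Sxy <- G[poly, , drop = FALSE] %*% Yc          # V_kept x K
  out <- vector("list", ncol(Y))
  vmeta <- genotypes@variants[poly, , drop = FALSE]
  sxxk <- sxx[poly]
  for (j in seq_len(ncol(Y))) {
    beta <- Sxy[, j] / sxxk
    sse <- pmax(syy[j] - beta * Sxy[, j], 0)
    sigma2 <- sse / (n - 2)
    se <- sqrt(sigma2 / sxxk)
    t <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
    under <- p < .Machine$double.xmin
    p[under] <- .Machine$double.xmin
    out[[j]] <- data.frame(
      phenotype_id = phenoScores@phenotypeIds[j],
      variant_id = vmeta$variant_id, chrom = vmeta$chrom, pos = vmeta$pos,
      ea = vmeta$ea, nea = vmeta$nea, eaf = eaf[poly],
      beta_hat = beta, se = se, t_stat = t, p = p, n = n,
      p_underflow = under)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "skipped") <- data.frame(variant_id = skipped,
                                     reason = rep("zero dosage variance",
                                                  length(skipped)))
  res
}

#' Write per-phenotype summary-statistic files
#'
#' One gzip TSV per phenotype with the association-table columns, rows
#' ordered by (chrom, pos, variant_id).
#'
#' @param gwasTable output of \code{\link{linearScan}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeGwasTables <- function(gwasTable, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (ph in unique(gwasTable$phenotype_id)) {
    sub <- gwasTable[gwasTable$phenotype_id == ph, , drop = FALSE]
    sub <- sub[order(sub$chrom, sub$pos, sub$variant_id), , drop = FALSE]
    path <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", ph),
                                  ".sumstats.tsv.gz"))
    con <- gzfile(path, "w")
    utils::write.table(sub, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}
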