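test_that("run selection applies the strict 1 mm rule", {
  set.seed(31)
  lat <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("s%02d", 1:20), NULL))
  runs <- list(fakeRun("a", lat, 0.8), fakeRun("b", lat, 1.2),
               fakeRun("c", lat, 0.99))
  kept <- selectRuns(runs, 1.0)
  expect_equal(vapply(kept, function(r) r@runId, character(1)), c("a", "c"))
  ## boundary exactly 1.0 is excluded
  expect_equal(length(selectRuns(list(fakeRun("d", lat, 1.0),
                                      fakeRun("e", lat, 0.5)), 1.0)), 1L)
  expect_error(selectRuns(list(fakeRun("f", lat, 1.5)), 1.0), "no run")
})

test_that("pooling deduplicates correlated latents", {
  set.seed(32)
  N <- 200
  z <- matrix(rnorm(N * 3), N, 3)
  runA <- fakeRun("A", z, 0.5, sprintf("s%03d", 1:N))
  ## run B duplicates A's first column and negates its second
  zB <- cbind(z[, 1], -z[, 2], rnorm(N))
  runB <- fakeRun("B", zB, 0.5, sprintf("s%03d", 1:N))
  pool <- poolAndDeduplicate(list(runA, runB), 0.95, dedupSeed = 4L)
  expect_equal(pool$kPheno, 4L)               # 6 columns, 2 dropped
  expect_equal(nrow(pool$dropLog), 2L)
  ## never both members of a pair dropped: each duplicated pair has a survivor
  surv <- colnames(pool$pooled)
  expect_true(("A.z1" %in% surv) || ("B.z1" %in% surv))
  expect_true(("A.z2" %in% surv) || ("B.z2" %in% surv))
  ## deterministic drop-later mode keeps the earlier columns
  pool2 <- poolAndDeduplicate(list(runA, runB), 0.95, dedupMode = "drop-later")
  expect_true(all(c("A.z1", "A.z2") %in% colnames(pool2$pooled)))
  ## same seed reproduces the same choice
  pool3 <- poolAndDeduplicate(list(runA, runB), 0.95, dedupSeed = 4L)
  expect_identical(colnames(pool$pooled), colnames(pool3$pooled))
  expect_error(poolAndDeduplicate(list(fakeRun("A", z[1:5, ], 0.5))), "10")
})

test_that("independent Gaussian columns survive pooling", {
  set.seed(33)
  N <- 500
  z <- matrix(rnorm(N * 50), N, 50)
  pool <- poolAndDeduplicate(list(X = z), 0.95)
  expect_equal(pool$kPheno, 50L)
  expect_equal(nrow(pool$dropLog), 0L)
  expect_lte(pool$kPheno, 50L)                # K <= sum of latent widths
})

test_that("threshold arithmetic reproduces the published corrections", {
  expect_equal(signif(studyWideThreshold(5e-8, 324), 2), 1.5e-10)
  expect_equal(signif(studyWideThreshold(5e-8, 16), 2), 3.1e-9)
  expect_equal(studyWideThreshold(0.05, 1), 0.05)
  expect_error(studyWideThreshold(5e-8, 0), ">= 1")
  expect_equal(signif(bonferroniThreshold(0.05, 324 * 68919), 2), 2.2e-9)
  expect_equal(signif(bonferroniThreshold(0.05, 324 * 187535), 2), 8.2e-10)
  expect_equal(bonferroniThreshold(0.01, 1), 0.01)
  expect_error(bonferroniThreshold(1.2, 10), "alpha")
  expect_error(bonferroniThreshold(0.05, 0), ">= 1")
})

test_that("region assignment is half-open and matches a linear-scan oracle", {
  reg <- toyRegions()
  tab <- data.frame(chrom = c("1", "1", "2", "2", "1"),
                    pos = c(0, 1000, 2999, 3000, 2500),
                    p = runif(5))
  expect_warning(got <- assignRegions(tab, reg), "outside")
  expect_equal(got[1], "r1_1")                # pos == start assigned
  expect_equal(got[2], "r1_2")                # end of r1_1 belongs to r1_2
  expect_equal(got[3], "r2_3")
  expect_true(is.na(suppressWarnings(
    assignRegions(data.frame(chrom = "2", pos = 3000), reg))))  # pos == end
  expect_equal(got[5], "r1_3")
  ## brute-force oracle on random rows
  set.seed(34)
  rnd <- data.frame(chrom = sample(c("1", "2", "3"), 300, TRUE),
                    pos = sample(0:3500, 300, TRUE))
  got2 <- suppressWarnings(assignRegions(rnd, reg))
  oracle <- vapply(seq_len(nrow(rnd)), function(i) {
    hit <- which(reg$chrom == rnd$chrom[i] & reg$start <= rnd$pos[i] &
                   rnd$pos[i] < reg$end)
    if (length(hit)) reg$region_id[hit] else NA_character_
  }, character(1))
  expect_identical(got2, oracle)
  expect_error(assignRegions(data.frame(chrom = NA, pos = 1), reg),
               "malformed")
})

test_that("region hit counting matches the exhaustive triple-loop oracle", {
  reg <- toyRegions()
  ## deterministic two-run example first
  t1 <- data.frame(phenotype_id = "p1", variant_id = "v1", chrom = "1",
                   pos = 10, ea = "A", nea = "G", eaf = 0.3, beta_hat = 1,
                   se = 0.1, p = 1e-9, n = 100L)
  t2 <- t1; t2$p <- 1e-7
  got <- countRegionHits(list(r1 = t1, r2 = t2), reg, 5e-8)
  expect_equal(got$stats$count[got$stats$region_id == "r1_1"], 1L)
  expect_equal(got$stats$pBest[got$stats$region_id == "r1_1"], 1e-9)
  expect_equal(sum(got$stats$count), 1L)
  ## randomized sumstats vs brute force
  for (case in 1:4) {
    tabs <- lapply(1:3, function(r) randomSumstats(120, reg, seed = case * 10 + r))
    got <- countRegionHits(tabs, reg, 1e-6)
    for (l in seq_len(nrow(reg))) {
      pBestOracle <- Inf; cntOracle <- 0L
      for (r in seq_along(tabs)) {
        pMin <- Inf
        for (i in seq_len(nrow(tabs[[r]]))) {
          row <- tabs[[r]][i, ]
          if (row$chrom == reg$chrom[l] && row$pos >= reg$start[l] &&
              row$pos < reg$end[l] && row$p < pMin) pMin <- row$p
        }
        if (pMin < 1e-6) cntOracle <- cntOracle + 1L
        pBestOracle <- min(pBestOracle, pMin)
      }
      expect_equal(got$stats$count[l], cntOracle)
      if (is.finite(pBestOracle))
        expect_equal(got$stats$pBest[l], pBestOracle)
    }
    ## count never exceeds the number of runs; monotone in the threshold
    expect_true(all(got$stats$count <= 3L))
    gotStrict <- countRegionHits(tabs, reg, 1e-8)
    expect_true(all(gotStrict$stats$count <= got$stats$count))
  }
  expect_error(countRegionHits(list(t1), reg[0, ], 5e-8), "empty")
})

test_that("locus classification follows the ensemble rules", {
  reg <- toyRegions()
  mkTab <- function(p, pos = 10, run = "r") data.frame(
    phenotype_id = "p1", variant_id = paste0("v", seq_along(p)), chrom = "1",
    pos = pos, ea = "A", nea = "G", eaf = 0.4, beta_hat = 0.1, se = 0.02,
    p = p, n = 100L)
  pSw <- 1.5e-10
  ## significant: below P_SW
  tabs <- lapply(1:6, function(r) mkTab(1e-11))
  got <- countRegionHits(tabs, reg, 5e-8)
  loci <- classifyLoci(got, tabs, reg, pSw)
  expect_equal(loci$classification[loci$region_id == "r1_1"], "significant")
  ## suggestive: P_SW <= p < P_GW with count >= 5
  tabs <- lapply(1:6, function(r) mkTab(1e-9))
  got <- countRegionHits(tabs, reg, 5e-8)
  loci <- classifyLoci(got, tabs, reg, pSw)
  expect_equal(loci$classification[loci$region_id == "r1_1"], "suggestive")
  ## same p but too few runs passing: non-significant
  tabs2 <- c(lapply(1:2, function(r) mkTab(1e-9)),
             lapply(1:4, function(r) mkTab(1e-4)))
  got2 <- countRegionHits(tabs2, reg, 5e-8)
  expect_equal(got2$stats$count[got2$stats$region_id == "r1_1"], 2L)
  loci2 <- classifyLoci(got2, tabs2, reg, pSw)
  expect_equal(loci2$classification[loci2$region_id == "r1_1"],
               "non_significant")
  ## lead variant: argmin p with position tie-break
  tie <- data.frame(phenotype_id = "p1",
                    variant_id = c("vB", "vA", "vC"), chrom = "1",
                    pos = c(500, 200, 200), ea = "A", nea = "G", eaf = 0.4,
                    beta_hat = 0.1, se = 0.02, p = c(1e-12, 1e-12, 1e-12),
                    n = 100L)
  got3 <- countRegionHits(list(tie), reg, 5e-8)
  loci3 <- classifyLoci(got3, list(tie), reg, pSw)
  lead <- loci3[loci3$region_id == "r1_1", ]
  expect_equal(lead$lead_variant_id, "vA")    # smallest pos, then id
  expect_equal(lead$pos, 200)
  ## classification is threshold-monotone: significant would be at least
  ## suggestive-band at any weaker threshold
  lociWeak <- classifyLoci(got, tabs, reg, pSw * 100)
  sigIdx <- loci$classification == "significant"
  expect_true(all(lociWeak$classification[sigIdx] != "non_significant" |
                    lociWeak$count[sigIdx] < 5))
})

test_that("nearest-gene annotation is strand-aware with body containment", {
  genes <- data.frame(gene = c("G1", "G2", "G3"),
                      chrom = c("1", "1", "2"),
                      tss = c(1000, 5000, 800),
                      tes = c(2000, 3000, 1500),
                      strand = c("+", "-", "+"))
  mkLoci <- function(chrom, pos) data.frame(
    region_id = "r", pBest = 1e-12, count = 1L, classification = "significant",
    lead_variant_id = "v", lead_phenotype_id = "p", lead_run_id = "run",
    chrom = chrom, pos = pos, ea = "A", nea = "G", eaf = 0.5,
    beta_hat = 0.1, se = 0.01)
  ## at the TSS
  a <- annotateNearestGene(mkLoci("1", 1000), genes)
  expect_equal(a$nearest_gene, "G1")
  expect_equal(a$distance_to_tss, 0)
  ## inside the gene body (minus strand gene: body 3000..5000)
  b <- annotateNearestGene(mkLoci("1", 4000), genes)
  expect_equal(b$nearest_gene, "G2")
  expect_equal(b$distance_to_tss, 0)
  ## outside: signed, strand-aware distance
  c3 <- annotateNearestGene(mkLoci("1", 2400), genes)
  expect_equal(c3$nearest_gene, "G1")        # 400 from G1 body, 600 from G2
  expect_equal(c3$distance_to_tss, 1400)     # downstream of + TSS at 1000
  d <- annotateNearestGene(mkLoci("1", 2700), genes)
  expect_equal(d$nearest_gene, "G2")
  expect_equal(d$distance_to_tss, 2300)      # minus-strand sign: -(2700 - 5000)
  ## exhaustive oracle on a random layout
  set.seed(35)
  rgenes <- data.frame(gene = sprintf("g%02d", 1:12),
                       chrom = sample(c("1", "2"), 12, TRUE),
                       tss = sample(1e4, 12), strand = sample(c("+", "-"), 12, TRUE))
  rgenes$tes <- rgenes$tss + ifelse(rgenes$strand == "+", 1, -1) * sample(500:900, 12)
  for (i in 1:20) {
    ch <- sample(c("1", "2"), 1); pos <- sample(1e4, 1)
    res <- annotateNearestGene(mkLoci(ch, pos), rgenes)
    cand <- rgenes[rgenes$chrom == ch, ]
    bd <- pmax(pmin(cand$tss, cand$tes) - pos, 0) +
      pmax(pos - pmax(cand$tss, cand$tes), 0)
    expect_equal(res$nearest_gene, cand$gene[which.min(bd)])
    if (min(bd) == 0) expect_equal(res$distance_to_tss, 0)
  }
  expect_warning(out <- annotateNearestGene(mkLoci("1", 5), genes[0, ]),
                 "skipped")
  expect_true(is.na(out$nearest_gene))
})

test_that("region partitions are validated", {
  reg <- toyRegions()
  expect_silent(validateRegions(reg))
  bad <- reg; bad$end[1] <- bad$start[1]
  expect_error(validateRegions(bad), "empty")
  bad2 <- reg; bad2$start[2] <- 500                 # overlaps region 1
  expect_error(validateRegions(bad2), "overlap")
  ## BED round trip
  path <- tempfile(fileext = ".bed")
  write.table(data.frame(reg$chrom, reg$start, reg$end, reg$region_id),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  back <- readRegionsBed(path)
  expect_equal(back$region_id, reg$region_id)
  expect_equal(back$start, reg$start)
})
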