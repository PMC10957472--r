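test_that("effect-allele frequency and MAF", {
  expect_equal(effectAlleleFrequency(rep(1, 10)), 0.5)
  expect_equal(effectAlleleFrequency(c(0, 0, 1, 2)), 0.375)
  expect_error(effectAlleleFrequency(c(NA_real_, NA_real_)), "missing")
  ## missing entries: explicit allele-count oracle
  d <- c(0, 1, 2, NA, 2, NA, 1)
  ok <- d[!is.na(d)]
  expect_equal(effectAlleleFrequency(d), sum(ok) / (2 * length(ok)))
  expect_equal(minorAlleleFrequency(c(2, 2, 2, 1)), 1 - 7 / 8)
})

test_that("HWE exact test matches full enumeration and is symmetric", {
  expect_equal(hweExactTest(5, 0, 0), 1.0)
  expect_error(hweExactTest(-1, 0, 2), "negative")
  ## (1, 2, 1): enumerate het counts of parity 0 for nA = na = 4, n = 4
  enumOracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa
    hets <- seq(min(nA, 2 * n - nA) %% 2, min(nA, 2 * n - nA), by = 2)
    pr <- vapply(hets, function(h) {
      aa <- (nA - h) / 2
      exp(h * log(2) + lfactorial(n) - lfactorial(aa) - lfactorial(h) -
            lfactorial(n - aa - h) + lfactorial(nA) + lfactorial(2 * n - nA) -
            lfactorial(2 * n))
    }, numeric(1))
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(nAa, hets)] * (1 + 1e-12)])
  }
  cases <- rbind(c(1, 2, 1), c(3, 1, 6), c(0, 8, 2), c(10, 5, 1), c(2, 2, 2))
  for (i in seq_len(nrow(cases))) {
    expect_equal(hweExactTest(cases[i, 1], cases[i, 2], cases[i, 3]),
                 enumOracle(cases[i, 1], cases[i, 2], cases[i, 3]),
                 tolerance = 1e-12)
    ## swapping homozygote labels leaves p unchanged
    expect_equal(hweExactTest(cases[i, 1], cases[i, 2], cases[i, 3]),
                 hweExactTest(cases[i, 3], cases[i, 2], cases[i, 1]))
  }
})

test_that("variant QC drops exactly the violating variants", {
  set.seed(21)
  N <- 400
  mkRow <- function(p) rbinom(N, 2, p)
  D <- rbind(
    good1 = mkRow(0.3),
    lowMaf = rbinom(N, 2, 0.004),
    good2 = mkRow(0.45),
    hweBad = c(rep(0, N / 2), rep(2, N / 2)),   # no hets at p = 0.5
    lowInfo = mkRow(0.2),
    good3 = mkRow(0.1))
  vm <- data.frame(variant_id = rownames(D), chrom = "1",
                   pos = seq_len(nrow(D)) * 100, ea = "A", nea = "G",
                   info = c(0.99, 0.95, 0.9, 0.97, 0.29, 0.85))
  g <- genotypeMatrix(D, vm, sprintf("s%03d", seq_len(N)))
  qc <- variantQc(g)
  rep_ <- qc$report
  ## recount oracle
  for (i in seq_len(nrow(rep_))) {
    vid <- rep_$variant_id[i]
    d <- D[vid, ]
    maf <- min(mean(d) / 2, 1 - mean(d) / 2)
    hweP <- hweExactTest(sum(d == 2), sum(d == 1), sum(d == 0))
    info <- vm$info[match(vid, vm$variant_id)]
    expect_equal(rep_$maf[i], maf)
    expect_equal(rep_$hweP[i], hweP)
    expect_identical(rep_$keep[i], maf >= 0.01 && hweP >= 1e-5 && info >= 0.3)
  }
  expect_false(rep_$keep[rep_$variant_id == "lowMaf"])
  expect_false(rep_$keep[rep_$variant_id == "lowInfo"])
  expect_false(rep_$keep[rep_$variant_id == "hweBad"])
  expect_true(all(rep_$keep[rep_$variant_id %in% c("good1", "good2", "good3")]))
  ## boundary: info exactly 0.3 is kept, 0.29 dropped
  vm2 <- vm; vm2$info <- c(0.3, 0.99, 0.99, 0.99, 0.99, 0.99)
  qc2 <- variantQc(genotypeMatrix(D, vm2, sprintf("s%03d", seq_len(N))))
  expect_true(qc2$report$keep[qc2$report$variant_id == "good1"])
})

test_that("phenotype adjustment: INT properties and covariate residualization", {
  set.seed(22)
  n <- 300
  raw <- rexp(n)                                # skewed on purpose
  s <- adjustPhenotype(raw, NULL)
  expect_equal(order(s), order(raw))            # rank-preserving without covariates
  expect_lt(abs(mean(s)), 0.02)
  expect_lt(abs(var(s) - 1), 0.05)
  ## strictly monotone transform of raw leaves the INT scores unchanged
  expect_equal(adjustPhenotype(exp(raw), NULL), s)
  ## Blom formula spot check
  expect_equal(sort(s), qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4)))
  ## residualization removes covariate signal
  cov <- cbind(age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.5))
  raw2 <- 0.5 * cov[, 1] - 2 * cov[, 2] + rnorm(n)
  s2 <- adjustPhenotype(raw2, cov)
  expect_lt(abs(cor(s2, cov[, 1])), 0.1)
  ## idempotence up to ties
  expect_equal(adjustPhenotype(s2, cov), s2, tolerance = 0.05)
  ## collinear covariates named in the error
  expect_error(adjustPhenotype(raw2, cbind(a = cov[, 1], b = 2 * cov[, 1])),
               "collinear.*b")
})

test_that("linear scan matches the closed-form OLS oracle (n = 8)", {
  doses <- c(0, 1, 2, 0, 1, 2, 1, 0)
  y <- c(0.2, 1.1, 2.3, -0.1, 0.8, 2.6, 1.4, 0.3)
  vm <- data.frame(variant_id = "v1", chrom = "1", pos = 100, ea = "A",
                   nea = "G", info = 1)
  g <- genotypeMatrix(matrix(doses, 1), vm, paste0("s", 1:8))
  ps <- methods::new("PhenotypeScores",
                     scores = matrix(y, dimnames = list(NULL, "ph1")),
                     phenotypeIds = "ph1", subjectIds = paste0("s", 1:8),
                     provenance = data.frame(phenotype_id = "ph1"))
  tab <- linearScan(ps, g)
  fit <- summary(lm(y ~ doses))$coefficients
  expect_equal(tab$beta_hat, fit["doses", "Estimate"], tolerance = 1e-10)
  expect_equal(tab$se, fit["doses", "Std. Error"], tolerance = 1e-10)
  expect_equal(tab$t_stat, fit["doses", "t value"], tolerance = 1e-10)
  expect_equal(tab$p, fit["doses", "Pr(>|t|)"], tolerance = 1e-10)
  expect_equal(tab$eaf, mean(doses) / 2)
  expect_equal(tab$n, 8L)
  ## internal consistency invariants
  expect_equal(tab$t_stat, tab$beta_hat / tab$se, tolerance = 1e-8)
  expect_equal(tab$p, 2 * pt(-abs(tab$t_stat), 6), tolerance = 1e-12)
})

test_that("degenerate scans: constant score, perfect fit, monomorphic variant", {
  set.seed(23)
  n <- 50
  doses <- rbinom(n, 2, 0.4)
  D <- rbind(v1 = doses, v2 = rep(1, n))       # v2 monomorphic
  vm <- data.frame(variant_id = c("v1", "v2"), chrom = "1", pos = c(1, 2) * 10,
                   ea = "A", nea = "G", info = 1)
  g <- genotypeMatrix(D, vm, paste0("s", 1:n))
  mkScores <- function(y, id = "ph") methods::new("PhenotypeScores",
    scores = matrix(y, dimnames = list(NULL, id)), phenotypeIds = id,
    subjectIds = paste0("s", 1:n), provenance = data.frame(phenotype_id = id))
  ## constant score
  tab <- linearScan(mkScores(rep(2.5, n)), g)
  expect_equal(tab$beta_hat, 0)
  expect_equal(tab$p, 1)
  ## monomorphic variant skipped with reason
  expect_equal(attr(tab, "skipped")$variant_id, "v2")
  expect_match(attr(tab, "skipped")$reason, "variance")
  ## score proportional to dosage: p underflows and is flagged
  tab2 <- linearScan(mkScores(3 * doses - 1), g)
  expect_true(tab2$p_underflow[tab2$variant_id == "v1"])
  expect_equal(tab2$p[tab2$variant_id == "v1"], .Machine$double.xmin)
  expect_true(all(tab2$p > 0 & tab2$p <= 1))
  ## mean imputation of missing dosages keeps n constant
  D3 <- rbind(v1 = replace(doses, 1:5, NA))
  g3 <- genotypeMatrix(D3, vm[1, ], paste0("s", 1:n))
  y <- rnorm(n)
  tab3 <- linearScan(mkScores(y), g3)
  expect_equal(tab3$n, n)
  imp <- replace(as.numeric(D3[1, ]), 1:5, mean(D3[1, ], na.rm = TRUE))
  fit <- summary(lm(y ~ imp))$coefficients
  expect_equal(tab3$beta_hat, fit["imp", "Estimate"], tolerance = 1e-10)
})

test_that("flipping effect and non-effect alleles flips beta and EAF, not p", {
  set.seed(24)
  n <- 200
  doses <- rbinom(n, 2, 0.3)
  y <- 0.2 * doses + rnorm(n)
  mk <- function(d) genotypeMatrix(
    matrix(d, 1, dimnames = list("v1", NULL)),
    data.frame(variant_id = "v1", chrom = "1", pos = 5, ea = "A", nea = "G",
               info = 1), paste0("s", 1:n))
  ps <- methods::new("PhenotypeScores",
                     scores = matrix(scale(y), dimnames = list(NULL, "ph")),
                     phenotypeIds = "ph", subjectIds = paste0("s", 1:n),
                     provenance = data.frame(phenotype_id = "ph"))
  t1 <- linearScan(ps, mk(doses))
  t2 <- linearScan(ps, mk(2 - doses))
  expect_equal(t1$beta_hat, -t2$beta_hat, tolerance = 1e-10)
  expect_equal(t1$eaf, 1 - t2$eaf, tolerance = 1e-12)
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
})

test_that("null scan p-values are calibrated (small-scale sanity)", {
  set.seed(25)
  n <- 300; V <- 400
  D <- t(vapply(runif(V, 0.1, 0.5), function(p) rbinom(n, 2, p),
                numeric(n)))
  vm <- data.frame(variant_id = sprintf("v%04d", 1:V), chrom = "1",
                   pos = 1:V * 100, ea = "A", nea = "G", info = 1)
  g <- genotypeMatrix(D, vm, paste0("s", 1:n))
  ps <- phenotypeScores(list(null = matrix(rnorm(n), ncol = 1)),
                        NULL, paste0("s", 1:n))
  tab <- linearScan(ps, g)
  frac <- mean(tab$p < 0.05)
  ci <- qbinom(c(0.005, 0.995), V, 0.05) / V
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("phenotype score assembly carries provenance and moments", {
  set.seed(26)
  n <- 150
  lat <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("z1", "z2", "z3")))
  cov <- cbind(age = rnorm(n, 60, 7))
  ps <- phenotypeScores(list(runA = lat, vol = rexp(n)), cov, paste0("s", 1:n))
  expect_equal(ps@phenotypeIds, c("runA.z1", "runA.z2", "runA.z3", "vol.vol"))
  expect_equal(ps@provenance$run_id, c(rep("runA", 3), "vol"))
  expect_true(all(abs(colMeans(scores(ps))) < 0.02))
  expect_true(all(abs(apply(scores(ps), 2, var) - 1) < 0.05))
})
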