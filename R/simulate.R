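#' @include AllClasses.R AllGenerics.R mesh.R coma.R
NULL

.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

.subdivideSphere <- function(v, f) {
  M <- nrow(v)
  key <- function(i, j) pmin(i, j) * (M + 1) + pmax(i, j)
  edges <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  ek <- key(edges[, 1L], edges[, 2L])
  uk <- !duplicated(ek)
  mids <- (v[edges[uk, 1L], , drop = FALSE] + v[edges[uk, 2L], , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  midIdx <- M + match(ek, ek[uk])
  m12 <- midIdx[seq_len(nrow(f))]
  m23 <- midIdx[nrow(f) + seq_len(nrow(f))]
  m31 <- midIdx[2L * nrow(f) + seq_len(nrow(f))]
  newF <- rbind(cbind(f[, 1L], m12, m31),
                cbind(f[, 2L], m23, m12),
                cbind(f[, 3L], m31, m23),
                cbind(m12, m23, m31))
  list(vertices = rbind(v, mids), faces = newF)
}

#' Icosphere mesh
#'
#' Unit sphere from a subdivided icosahedron; \code{10 * 4^subdiv + 2}
#' vertices, outward winding.
#'
#' @param subdiv number of subdivision rounds (>= 0).
#' @param radius sphere radius.
#' @return a \linkS4class{TriangleMesh}.
#' @export
icosphere <- function(subdiv = 2L, radius = 1) {
  s <- .icosahedron()
  for (i in seq_len(subdiv)) s <- .subdivideSphere(s$vertices, s$faces)
  buildMesh(s$vertices * radius, s$faces, repairWinding = FALSE)
}

#' Synthetic ventricle-like template mesh
#'
#' A closed, consistently wound surface resembling a left-ventricular cavity
#' at end diastole: a prolate hemispheroid forming the apex, closed by a
#' flattened basal cap, obtained by anisotropically mapping a subdivided
#' icosphere. With the default radii the long axis is 60 mm and the cavity
#' volume is about 61 ml, in the physiological range.
#'
#' @param subdiv template resolution level: \code{10 * 4^(subdiv+1) + 2}
#'   vertices, so level 1 gives 162 and level 2 gives 642.
#' @param shortAxisMm equatorial semi-axis (mm).
#' @param apexMm apex depth below the equator (mm).
#' @param capMm basal cap height above the equator (mm).
#' @return a \linkS4class{TriangleMesh}.
#' @export
makeTemplate <- function(subdiv = 2L, shortAxisMm = 22, apexMm = 48, capMm = 12) {
  if (subdiv < 1L) stop("subdiv must be >= 1")
  sph <- icosphere(subdiv + 1L)
  v <- sph@vertices
  z <- v[, 3L]
  out <- cbind(shortAxisMm * v[, 1L], shortAxisMm * v[, 2L],
               ifelse(z <= 0, apexMm * z, capMm * z))
  buildMesh(out, sph@faces, repairWinding = FALSE)
}

#' Analytic deformation fields of the template
#'
#' Four vertex displacement fields driving synthetic shape variation,
#' mimicking the dominant modes of ventricular remodelling: isotropic scale,
#' long-axis stretch (with compensatory short-axis thinning, making it
#' orthogonal to scale), apex taper (conicity) and basal-cap shear (tilting
#' the basal plane). Fields after the first two are Gram-Schmidt
#' orthogonalized against their predecessors, and every field is normalized
#' to unit per-vertex root-mean-square displacement, so a factor amplitude
#' of a mm produces an RMS vertex displacement of a mm.
#'
#' @param template a \linkS4class{TriangleMesh} from
#'   \code{\link{makeTemplate}}.
#' @return named list of \code{M x 3} fields: scale, stretch, taper, tilt.
#' @export
displacementFields <- function(template) {
  v <- template@vertices
  ctr <- colMeans(v)
  u <- sweep(v, 2L, ctr)
  z <- u[, 3L]
  ## 1: isotropic scale
  f1 <- u
  ## 2: long-axis stretch, thinned radially to be orthogonal to scale
  beta <- sum(z^2) / sum(u[, 1L]^2 + u[, 2L]^2)
  f2 <- cbind(-beta * u[, 1L], -beta * u[, 2L], z)
  ## 3: apex taper (radial pinch weighted toward the apex)
  w3 <- pmax(-z / max(-min(z), 1e-9), 0)^2
  f3 <- cbind(-w3 * u[, 1L], -w3 * u[, 2L], 0 * z)
  ## 4: basal-cap shear (tilts the basal plane; volume-preserving shear)
  w4 <- pmax(z / max(max(z), 1e-9), 0)
  f4 <- cbind(w4 * max(z), 0 * z, 0 * z)
  flat <- function(f) as.vector(f)
  proj <- function(f, g) f - sum(flat(f) * flat(g)) / sum(flat(g)^2) * g
  f3 <- proj(proj(f3, f1), f2)
  f4 <- proj(proj(proj(f4, f1), f2), f3)
  norm1 <- function(f) f / sqrt(mean(rowSums(f^2)))
  list(scale = norm1(f1), stretch = norm1(f2), taper = norm1(f3),
       tilt = norm1(f4))
}

#' Synthetic cohort configuration
#'
#' Default study conditions: 2,000 subjects on a 642-vertex template, four
#' deformation factors with standard deviations (3, 2, 1.5, 1) mm and 0.5 mm
#' vertex noise; 5,000 variants in 50 LD blocks of 2 Mb with block-wise
#' allele frequencies from U(0.05, 0.5) and haplotype copy probability 0.9;
#' six causal variants in distinct regions, each explaining 3% of its
#' factor's variance; a 5% covariate (confounder) variance share per
#' factor.
#'
#' @param nSubjects cohort size N.
#' @param subdiv template subdivision level (2 gives M = 642).
#' @param factorSd per-factor amplitude sd in mm (scale, stretch, taper,
#'   tilt).
#' @param vertexNoiseSd iid vertex noise sd (mm).
#' @param nVariants,nRegions panel size and number of LD blocks (regions).
#' @param freqRange allele-frequency range (drawn per block).
#' @param rhoLD per-haplotype copy probability within a block.
#' @param nCausal number of planted causal variants (round-robin over
#'   factors, each in its own region).
#' @param h2PerVariant variance fraction of the factor explained per causal
#'   variant.
#' @param covariateShare variance fraction of each factor explained by its
#'   confounding covariate.
#' @param seed master seed.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(nSubjects = 2000L, subdiv = 2L,
                      factorSd = c(3, 2, 1.5, 1), vertexNoiseSd = 0.5,
                      nVariants = 5000L, nRegions = 50L,
                      freqRange = c(0.05, 0.5), rhoLD = 0.9,
                      nCausal = 6L, h2PerVariant = 0.03,
                      covariateShare = 0.05, seed = 1L) {
  methods::new("SimConfig", nSubjects = as.integer(nSubjects),
               subdiv = as.integer(subdiv), factorSd = factorSd,
               vertexNoiseSd = vertexNoiseSd, nVariants = as.integer(nVariants),
               nRegions = as.integer(nRegions), freqRange = freqRange,
               rhoLD = rhoLD, nCausal = as.integer(nCausal),
               h2PerVariant = h2PerVariant, covariateShare = covariateShare,
               seed = as.integer(seed))
}

#' Simulate a complete synthetic cohort
#'
#' Generates, deterministically from the master seed: (1) covariates with
#' realistic demographic structure; (2) Hardy-Weinberg genotypes in LD
#' blocks via haplotype copying (block-constant allele frequency, so
#' marginal frequencies are exact); (3) four latent deformation factors,
#' each a sum of its planted causal variants' standardized dosages (exact
#' per-variant explained variance), a confounding covariate share and a
#' Gaussian residual; (4) registered meshes: template + per-subject factor
#' amplitudes times the deformation fields + iid vertex noise; and (5)
#' ground-truth tables.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return list with \code{cohort} (\linkS4class{ShapeCohort}, unaligned),
#'   \code{genotypes} (\linkS4class{GenotypeMatrix}), \code{covariates}
#'   (data.frame), \code{regions}, \code{genes} and \code{truth} (factor
#'   values, causal-variant table, field dictionary).
#' @export
simulateCohort <- function(cfg) {
  stopifnot(methods::validObject(cfg))
  .withSeed(cfg@seed, {
    N <- cfg@nSubjects; V <- cfg@nVariants; B <- cfg@nRegions
    perBlock <- V %/% B
    subjects <- sprintf("sub%05d", seq_len(N))

    ## covariates: sex-dependent height, weight tracking height
    sex <- stats::rbinom(N, 1L, 0.5)
    age <- stats::rnorm(N, 62, 7)
    height <- stats::rnorm(N, 163 + 13 * sex, 7)
    weight <- stats::rnorm(N, 70 + 0.55 * (height - 168), 11)
    bmi <- weight / (height / 100)^2
    covariates <- data.frame(subject_id = subjects, sex = sex, age = age,
                             height = height, weight = weight, bmi = bmi)

    ## genotype panel: B blocks of 2 Mb, 5 blocks per chromosome
    blocksPerChrom <- 5L
    blockChrom <- as.character(((seq_len(B) - 1L) %/% blocksPerChrom) + 1L)
    blockIdx <- ((seq_len(B) - 1L) %% blocksPerChrom)
    blockStart <- blockIdx * 2e6
    regions <- data.frame(region_id = sprintf("R%03d", seq_len(B)),
                          chrom = blockChrom, start = blockStart,
                          end = blockStart + 2e6)
    pBlock <- stats::runif(B, cfg@freqRange[1L], cfg@freqRange[2L])
    H1 <- matrix(0L, N, V); H2 <- matrix(0L, N, V)
    pos <- numeric(V); vChrom <- character(V); vRegion <- character(V)
    pTrue <- numeric(V)
    for (b in seq_len(B)) {
      cols <- (b - 1L) * perBlock + seq_len(perBlock)
      offs <- sort(sample.int(2e6 - 2L, perBlock)) + 1
      pos[cols] <- blockStart[b] + offs     # 0-based region + 1-based offset
      vChrom[cols] <- blockChrom[b]
      vRegion[cols] <- regions$region_id[b]
      pTrue[cols] <- pBlock[b]
      for (k in seq_along(cols)) {
        v <- cols[k]
        if (k == 1L) {
          H1[, v] <- stats::rbinom(N, 1L, pBlock[b])
          H2[, v] <- stats::rbinom(N, 1L, pBlock[b])
        } else {
          fresh1 <- stats::rbinom(N, 1L, pBlock[b])
          fresh2 <- stats::rbinom(N, 1L, pBlock[b])
          cp1 <- stats::runif(N) < cfg@rhoLD
          cp2 <- stats::runif(N) < cfg@rhoLD
          H1[, v] <- ifelse(cp1, H1[, v - 1L], fresh1)
          H2[, v] <- ifelse(cp2, H2[, v - 1L], fresh2)
        }
      }
    }
    X <- H1 + H2
    alleles <- c("A", "C", "G", "T")
    eaIdx <- sample.int(4L, V, replace = TRUE)
    neaIdx <- ((eaIdx + sample.int(3L, V, replace = TRUE) - 1L) %% 4L) + 1L
    vmeta <- data.frame(variant_id = sprintf("var%05d", seq_len(V)),
                        chrom = vChrom, pos = pos,
                        ea = alleles[eaIdx], nea = alleles[neaIdx],
                        info = round(stats::runif(V, 0.9, 1), 4),
                        region_id = vRegion, p_true = pTrue)

    ## planted causal variants: nCausal distinct regions, middle variant
    causalRegions <- unique(round(seq(1L, B, length.out = max(cfg@nCausal, 1L))))
    causalRegions <- causalRegions[seq_len(min(cfg@nCausal, length(causalRegions)))]
    causalIdx <- (causalRegions - 1L) * perBlock + (perBlock %/% 2L)
    causalFactor <- rep_len(1:4, length(causalIdx))

    ## factors on a unit-variance scale, then scaled to mm amplitudes
    covChannel <- cbind(scale(height), scale(weight), scale(age), scale(sex))
    factors <- matrix(0, N, 4L,
                      dimnames = list(subjects,
                                      c("scale", "stretch", "taper", "tilt")))
    betaTrue <- numeric(length(causalIdx))
    for (j in 1:4) {
      vs <- causalIdx[causalFactor == j]
      g <- 0
      for (v in vs) {
        xs <- as.numeric(scale(X[, v]))
        g <- g + sqrt(cfg@h2PerVariant) * xs
      }
      betaTrue[causalFactor == j] <- sqrt(cfg@h2PerVariant)
      h2tot <- cfg@h2PerVariant * length(vs)
      resid <- sqrt(max(1 - h2tot - cfg@covariateShare, 0)) * stats::rnorm(N)
      factors[, j] <- g + sqrt(cfg@covariateShare) * covChannel[, j] + resid
    }
    amplitudes <- sweep(factors, 2L, cfg@factorSd, "*")

    ## meshes
    template <- makeTemplate(cfg@subdiv)
    fields <- displacementFields(template)
    M <- nrow(template@vertices)
    shapes <- array(0, c(N, M, 3L))
    base <- template@vertices
    Fmat <- lapply(fields, identity)
    for (k in 1:3) {
      comp <- matrix(rep(base[, k], each = N), N, M)
      for (j in 1:4) comp <- comp + outer(amplitudes[, j], Fmat[[j]][, k])
      if (cfg@vertexNoiseSd > 0)
        comp <- comp + matrix(stats::rnorm(N * M, 0, cfg@vertexNoiseSd), N, M)
      shapes[, , k] <- comp
    }
    cohort <- methods::new("ShapeCohort", subjectIds = subjects,
                           shapes = shapes, templateFaces = template@faces,
                           aligned = FALSE)

    ## synthetic gene layout: two genes per region
    genes <- do.call(rbind, lapply(seq_len(B), function(b) {
      starts <- regions$start[b] + c(4e5, 12e5)
      lens <- c(3e4, 5e4)
      strands <- if (b %% 2L == 0L) c("+", "-") else c("-", "+")
      data.frame(gene = sprintf("GENE%04d", 2L * (b - 1L) + 1:2),
                 chrom = regions$chrom[b],
                 tss = ifelse(strands == "+", starts, starts + lens),
                 tes = ifelse(strands == "+", starts + lens, starts),
                 strand = strands)
    }))

    genotypes <- genotypeMatrix(t(X), vmeta, subjects)
    truth <- list(
      factors = factors,
      amplitudes = amplitudes,
      causal = data.frame(variant_id = vmeta$variant_id[causalIdx],
                          region_id = vmeta$region_id[causalIdx],
                          factor = colnames(factors)[causalFactor],
                          h2 = rep(cfg@h2PerVariant, length(causalIdx)),
                          beta_true = betaTrue),
      fieldNames = names(fields))
    list(cohort = cohort, genotypes = genotypes, covariates = covariates,
         regions = regions, genes = genes, truth = truth,
         template = template, fields = fields, config = cfg)
  })
}
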