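#' @include AllClasses.R AllGenerics.R mesh.R chebyshev.R sampling.R
NULL

## run expr with a local, restored RNG state
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Autoencoder run configuration
#'
#' Builds a \linkS4class{ComaConfig}. Defaults: 16 latents, Chebyshev order
#' 6, four convolution layers with channels (16, 16, 16, 32) and 4x
#' downsampling each, KL weight 1e-4, L1 reconstruction loss, Adam with
#' learning rate 1e-3, 300 epochs, batch size 32, 0.8/0.1/0.1
#' train/validation/test split, and the rescaled symmetric-normalized
#' Laplacian for filtering.
#'
#' @param nZ bottleneck width (ensembles typically mix 8 and 16).
#' @param chebOrder number of Chebyshev terms K (degrees 0..K-1).
#' @param channels output channels per encoder convolution layer.
#' @param dsFactors per-layer decimation factor.
#' @param wKL KL regularization weight (>= 0; 0 gives a plain autoencoder).
#' @param reconLoss "L1", "L2" or "MSE".
#' @param learningRate,epochs,batchSize Adam settings.
#' @param seedWeights,seedSplit seeds for weight init and the data split.
#' @param splitFractions train/val/test fractions summing to 1.
#' @param laplacianMode Laplacian used inside the filters.
#' @return a \linkS4class{ComaConfig}.
#' @export
comaConfig <- function(nZ = 16L, chebOrder = 6L,
                       channels = c(16L, 16L, 16L, 32L),
                       dsFactors = rep(4L, length(channels)),
                       wKL = 1e-4, reconLoss = "L1",
                       learningRate = 1e-3, epochs = 300L, batchSize = 32L,
                       seedWeights = 1L, seedSplit = 1L,
                       splitFractions = c(0.8, 0.1, 0.1),
                       laplacianMode = "sym-normalized-scaled") {
  methods::new("ComaConfig", nZ = as.integer(nZ), chebOrder = as.integer(chebOrder),
               channels = as.integer(channels), dsFactors = as.integer(dsFactors),
               wKL = wKL, reconLoss = reconLoss, learningRate = learningRate,
               epochs = as.integer(epochs), batchSize = as.integer(batchSize),
               seedWeights = as.integer(seedWeights), seedSplit = as.integer(seedSplit),
               splitFractions = splitFractions, laplacianMode = laplacianMode)
}

#' KL divergence regularizer of a diagonal Gaussian posterior
#'
#' Per-subject regularization term
#' \eqn{-(1/(2 n_z)) \sum_j (\log \sigma_j^2 - \sigma_j^2 - \mu_j^2 + 1)},
#' the KL divergence between \eqn{N(\mu, diag(\sigma^2))} and the standard
#' normal, averaged over latent dimensions. Non-negative, zero exactly at
#' \eqn{\mu = 0, \sigma = 1}.
#'
#' @param mu,sigma numeric vectors of length n_z (sigma > 0).
#' @return scalar KL term.
#' @export
klTerm <- function(mu, sigma) {
  if (length(mu) != length(sigma)) stop("mu and sigma lengths differ")
  if (any(sigma <= 0)) stop("sigma must be positive")
  nz <- length(mu)
  -(1 / (2 * nz)) * sum(log(sigma^2) - sigma^2 - mu^2 + 1)
}

#' Per-subject reconstruction RMSD
#'
#' Root mean squared deviation between original and reconstructed meshes:
#' \eqn{\sqrt{(1/M) \sum_j \| x_{ij} - \hat x_{ij} \|_2^2}} per subject, in
#' mm. The ensemble keeps runs whose test-set mean is below 1 mm.
#'
#' @param original,reconstructed \linkS4class{ShapeCohort}s over the same
#'   subjects and template.
#' @return numeric vector of per-subject RMSD (mm), named by subject id.
#' @export
reconstructionRmsd <- function(original, reconstructed) {
  if (!identical(dim(original@shapes), dim(reconstructed@shapes)))
    stop("cohort dimensions differ")
  if (!identical(original@subjectIds, reconstructed@subjectIds))
    stop("subject ids differ")
  d2 <- (original@shapes - reconstructed@shapes)^2
  out <- sqrt(apply(d2, 1L, function(s) mean(rowSums(matrix(s, ncol = 3L)))))
  names(out) <- original@subjectIds
  out
}

## ---- internal network machinery ------------------------------------------
## Signals for a batch of B meshes at a level with M vertices and F channels
## are stored as an (M*B) x F matrix, vertex index fastest; the same buffer
## re-dimensioned to M x (B*F) exposes per-sample-channel vertex signals for
## sparse operator application. The two views share one layout, so Laplacian
## and weight multiplications are plain BLAS/sparse products with no copies
## beyond R semantics.

.opApply <- function(Q, Xf, M) {
  B <- nrow(Xf) / M
  F1 <- ncol(Xf)
  Xv <- Xf
  dim(Xv) <- c(M, B * F1)
  Y <- as.matrix(Q %*% Xv)
  dim(Y) <- c(nrow(Q) * B, F1)
  Y
}

.chebSignalsB <- function(L, Xf, M, K) {
  B <- nrow(Xf) / M
  F1 <- ncol(Xf)
  Xv <- Xf
  dim(Xv) <- c(M, B * F1)
  Tlist <- vector("list", K)
  Tlist[[1L]] <- Xf
  if (K >= 2L) {
    T2 <- as.matrix(L %*% Xv); dim(T2) <- dim(Xf); Tlist[[2L]] <- T2
  }
  if (K >= 3L) for (k in 3:K) {
    prev <- Tlist[[k - 1L]]; dim(prev) <- c(M, B * F1)
    Tk <- as.matrix(2 * (L %*% prev)) ; dim(Tk) <- dim(Xf)
    Tlist[[k]] <- Tk - Tlist[[k - 2L]]
  }
  Tlist
}

.chebConvFwd <- function(L, Xf, W, b, M) {
  K <- dim(W)[1L]; Fin <- dim(W)[2L]; Fout <- dim(W)[3L]
  Tx <- .chebSignalsB(L, Xf, M, K)
  Y <- matrix(0, nrow(Xf), Fout)
  for (k in seq_len(K)) Y <- Y + Tx[[k]] %*% matrix(W[k, , ], Fin, Fout)
  Y <- sweep(Y, 2L, b, "+")
  list(Y = Y, Tx = Tx)
}

.chebConvBwd <- function(L, dY, W, Tx, M) {
  K <- dim(W)[1L]; Fin <- dim(W)[2L]; Fout <- dim(W)[3L]
  dW <- array(0, dim(W))
  for (k in seq_len(K)) dW[k, , ] <- crossprod(Tx[[k]], dY)
  db <- colSums(dY)
  Td <- .chebSignalsB(L, dY, M, K)
  dX <- matrix(0, nrow(dY), Fin)
  for (k in seq_len(K)) dX <- dX + Td[[k]] %*% t(matrix(W[k, , ], Fin, Fout))
  list(dX = dX, dW = dW, db = db)
}

.flattenTop <- function(Xf, M, B) {
  F1 <- ncol(Xf)
  arr <- array(Xf, c(M, B, F1))
  t(matrix(aperm(arr, c(1L, 3L, 2L)), M * F1, B))
}

.unflattenTop <- function(H, M, F1) {
  B <- nrow(H)
  arr <- aperm(array(t(H), c(M, F1, B)), c(1L, 3L, 2L))
  matrix(arr, M * B, F1)
}

.glorot <- function(nin, nout, dims) {
  lim <- sqrt(6 / (nin + nout))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

.initParams <- function(config, ops) {
  Lc <- length(config@channels)
  K <- config@chebOrder
  chan <- c(3L, config@channels)
  Mtop <- nrow(ops@levelMeshes[[Lc + 1L]]@vertices)
  topDim <- Mtop * config@channels[Lc]
  p <- list()
  for (l in seq_len(Lc)) {
    p[[paste0("encW", l)]] <- .glorot(K * chan[l], chan[l + 1L],
                                      c(K, chan[l], chan[l + 1L]))
    p[[paste0("encB", l)]] <- numeric(chan[l + 1L])
  }
  p$Wmu <- .glorot(topDim, config@nZ, c(topDim, config@nZ))
  p$bmu <- numeric(config@nZ)
  p$Wlv <- .glorot(topDim, config@nZ, c(topDim, config@nZ))
  p$blv <- numeric(config@nZ)
  p$Wd <- .glorot(config@nZ, topDim, c(config@nZ, topDim))
  p$bd <- numeric(topDim)
  for (l in rev(seq_len(Lc))) {
    p[[paste0("decW", l)]] <- .glorot(K * chan[l + 1L], chan[l],
                                      c(K, chan[l + 1L], chan[l]))
    p[[paste0("decB", l)]] <- numeric(chan[l])
  }
  p
}

## forward pass; returns activations needed for backprop
.forward <- function(p, config, ops, laps, Xf, M1, sample = FALSE, eps = NULL) {
  Lc <- length(config@channels)
  B <- nrow(Xf) / M1
  Ms <- vapply(ops@levelMeshes, function(m) nrow(m@vertices), integer(1))
  act <- list(input = Xf)
  X <- Xf
  encIn <- vector("list", Lc); encTx <- vector("list", Lc)
  encPre <- vector("list", Lc)
  for (l in seq_len(Lc)) {
    encIn[[l]] <- X
    cv <- .chebConvFwd(laps[[l]], X, p[[paste0("encW", l)]],
                       p[[paste0("encB", l)]], Ms[l])
    encTx[[l]] <- cv$Tx
    encPre[[l]] <- cv$Y
    X <- pmax(cv$Y, 0)
    X <- .opApply(ops@downMaps[[l]], X, Ms[l])
  }
  Mtop <- Ms[Lc + 1L]
  H <- .flattenTop(X, Mtop, B)
  mu <- sweep(H %*% p$Wmu, 2L, p$bmu, "+")
  logvar <- sweep(H %*% p$Wlv, 2L, p$blv, "+")
  logvar <- pmin(pmax(logvar, -15), 15)  # numeric guard
  if (sample) {
    if (is.null(eps)) eps <- matrix(stats::rnorm(length(mu)), nrow(mu))
    z <- mu + exp(0.5 * logvar) * eps
  } else {
    eps <- NULL
    z <- mu
  }
  Hd <- sweep(z %*% p$Wd, 2L, p$bd, "+")
  X <- .unflattenTop(Hd, Mtop, config@channels[Lc])
  decIn <- vector("list", Lc); decTx <- vector("list", Lc)
  decPre <- vector("list", Lc)
  for (l in rev(seq_len(Lc))) {
    X <- .opApply(ops@upMaps[[l]], X, Ms[l + 1L])
    decIn[[l]] <- X
    cv <- .chebConvFwd(laps[[l]], X, p[[paste0("decW", l)]],
                       p[[paste0("decB", l)]], Ms[l])
    decTx[[l]] <- cv$Tx
    decPre[[l]] <- cv$Y
    X <- if (l > 1L) pmax(cv$Y, 0) else cv$Y
  }
  list(recon = X, mu = mu, logvar = logvar, z = z, eps = eps, H = H, Hd = Hd,
       encIn = encIn, encTx = encTx, encPre = encPre,
       decIn = decIn, decTx = decTx, decPre = decPre, B = B)
}

.reconLossGrad <- function(recon, target, kind) {
  n <- length(target)
  diff <- recon - target
  switch(kind,
    L1 = list(loss = mean(abs(diff)), grad = sign(diff) / n),
    MSE = list(loss = mean(diff^2), grad = 2 * diff / n),
    L2 = {
      ## mean over batch of per-entry root-mean-square error
      l <- sqrt(mean(diff^2))
      list(loss = l, grad = if (l > 0) diff / (n * l) else diff * 0)
    },
    stop("unknown reconstruction loss"))
}

.backward <- function(p, config, ops, laps, fw, target) {
  Lc <- length(config@channels)
  Ms <- vapply(ops@levelMeshes, function(m) nrow(m@vertices), integer(1))
  Mtop <- Ms[Lc + 1L]
  B <- fw$B
  nz <- config@nZ
  g <- list()
  lg <- .reconLossGrad(fw$recon, target, config@reconLoss)
  dX <- lg$grad
  for (l in seq_len(Lc)) {
    if (l > 1L) dX <- dX * (fw$decPre[[l]] > 0)
    bk <- .chebConvBwd(laps[[l]], dX, p[[paste0("decW", l)]], fw$decTx[[l]], Ms[l])
    g[[paste0("decW", l)]] <- bk$dW
    g[[paste0("decB", l)]] <- bk$db
    dX <- .opApply(Matrix::t(ops@upMaps[[l]]), bk$dX, Ms[l])
  }
  dHd <- .flattenTop(dX, Mtop, B)
  g$Wd <- crossprod(fw$z, dHd)
  g$bd <- colSums(dHd)
  dz <- dHd %*% t(p$Wd)
  dmu <- dz
  dlogvar <- matrix(0, B, nz)
  if (!is.null(fw$eps))
    dlogvar <- dz * fw$eps * 0.5 * exp(0.5 * fw$logvar)
  if (config@wKL > 0) {
    ## Omega averaged over batch; d/dmu = mu/nz, d/dlogvar = -(1 - sigma^2)/(2 nz)
    dmu <- dmu + config@wKL * fw$mu / (nz * B)
    dlogvar <- dlogvar - config@wKL * (1 - exp(fw$logvar)) / (2 * nz * B)
  }
  g$Wmu <- crossprod(fw$H, dmu); g$bmu <- colSums(dmu)
  g$Wlv <- crossprod(fw$H, dlogvar); g$blv <- colSums(dlogvar)
  dH <- dmu %*% t(p$Wmu) + dlogvar %*% t(p$Wlv)
  dX <- .unflattenTop(dH, Mtop, config@channels[Lc])
  for (l in rev(seq_len(Lc))) {
    dX <- .opApply(Matrix::t(ops@downMaps[[l]]), dX, Ms[l + 1L])
    dX <- dX * (fw$encPre[[l]] > 0)
    bk <- .chebConvBwd(laps[[l]], dX, p[[paste0("encW", l)]], fw$encTx[[l]], Ms[l])
    g[[paste0("encW", l)]] <- bk$dW
    g[[paste0("encB", l)]] <- bk$db
    dX <- bk$dX
  }
  list(grads = g, reconLoss = lg$loss)
}

.klOmega <- function(mu, logvar, nz) {
  -mean(rowSums(sweep(logvar - exp(logvar) - mu^2, 2L, -1, "+")) / (2 * nz))
}

#' Train a variational convolutional mesh autoencoder
#'
#' Minimizes reconstruction loss plus \code{wKL} times the KL regularizer
#' over the training split with reparameterized latent sampling, using Adam.
#' Vertex coordinates are standardized per coordinate over the training set
#' before entering the network and de-standardized before any RMSD is
#' computed, so reconstruction errors are in mm. Fully deterministic given
#' the two seeds in the configuration.
#'
#' @param cohort an aligned \linkS4class{ShapeCohort}.
#' @param ops \linkS4class{SamplingOperators} built on the cohort template
#'   (typically the Procrustes mean shape) with factors matching
#'   \code{config@dsFactors}.
#' @param config a \linkS4class{ComaConfig}.
#' @param runId identifier stored in the result.
#' @param verbose print per-epoch losses.
#' @return a \linkS4class{RunResult} with latents (posterior mode \eqn{\mu})
#'   for all subjects, per-subject RMSD (mm), the mean test-set RMSD and the
#'   training history.
#' @export
trainComa <- function(cohort, ops, config, runId = "run1", verbose = FALSE) {
  if (!cohort@aligned) stop("trainComa requires an aligned cohort")
  Lc <- length(config@channels)
  if (length(ops@downMaps) != Lc)
    stop("sampling operators have ", length(ops@downMaps),
         " levels but config has ", Lc, " layers")
  if (!identical(as.integer(ops@factors), config@dsFactors))
    stop("sampling operator factors do not match config dsFactors")
  N <- dim(cohort@shapes)[1L]
  M1 <- dim(cohort@shapes)[2L]
  if (nrow(ops@levelMeshes[[1L]]@vertices) != M1)
    stop("operator template vertex count does not match cohort")
  ## per-level filter Laplacians, stored as plain sparse matrices
  laps <- lapply(ops@levelMeshes[seq_len(Lc)], function(m)
    graphLaplacian(m, config@laplacianMode)@laplacian)

  ## split
  idx <- .withSeed(config@seedSplit, sample.int(N))
  nTr <- max(1L, round(config@splitFractions[1L] * N))
  nVa <- round(config@splitFractions[2L] * N)
  nVa <- min(nVa, N - nTr)
  train <- sort(idx[seq_len(nTr)])
  val <- if (nVa > 0) sort(idx[nTr + seq_len(nVa)]) else integer(0)
  test <- sort(idx[setdiff(seq_len(N), seq_len(nTr + nVa))])
  if (!length(train)) stop("empty training split")
  if (!length(test)) stop("empty test split")

  ## standardization on the training split: centre per (vertex, coordinate),
  ## but scale by one pooled sd. A per-coordinate variance whitening would
  ## turn smooth deformation fields into high-spatial-frequency sign
  ## patterns that low-order spectral filters represent poorly; the pooled
  ## scale keeps the network inputs O(1) while preserving the spatial
  ## smoothness (and the mm geometry, up to one global factor).
  muC <- apply(cohort@shapes[train, , , drop = FALSE], c(2L, 3L), mean)
  resid <- sweep(cohort@shapes[train, , , drop = FALSE], c(2L, 3L), muC)
  gsd <- max(stats::sd(as.numeric(resid)), 1e-8)
  sdC <- matrix(gsd, dim(cohort@shapes)[2L], 3L)
  std <- list(mean = muC, sd = sdC)

  stdShape <- function(ii) {
    ## (M*B) x 3, vertex fastest
    S <- cohort@shapes[ii, , , drop = FALSE]
    B <- length(ii)
    out <- matrix(0, M1 * B, 3L)
    for (k in 1:3) {
      Xk <- t(S[, , k])                       # M x B
      out[, k] <- (Xk - muC[, k]) / sdC[, k]
    }
    out
  }

  p <- .withSeed(config@seedWeights, .initParams(config, ops))
  mState <- lapply(p, function(a) a * 0)
  vState <- lapply(p, function(a) a * 0)
  b1 <- 0.9; b2 <- 0.999; adamEps <- 1e-8
  stepT <- 0
  lr <- config@learningRate

  valX <- if (length(val)) stdShape(val) else NULL
  history <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                        trainRecon = numeric(0), valLoss = numeric(0))
  trainRng <- (as.numeric(config@seedSplit) * 10007 + config@seedWeights) %%
    .Machine$integer.max
  .withSeed(trainRng, {
    for (ep in seq_len(config@epochs)) {
      ordIdx <- sample(train)
      bs <- min(config@batchSize, length(train))
      nb <- ceiling(length(train) / bs)
      epLoss <- 0; epRecon <- 0
      for (bi in seq_len(nb)) {
        ii <- ordIdx[((bi - 1L) * bs + 1L):min(bi * bs, length(train))]
        Xf <- stdShape(ii)
        ## reparameterized sampling only in the variational regime; with
        ## wKL = 0 the model is a plain autoencoder
        fw <- .forward(p, config, ops, laps, Xf, M1, sample = config@wKL > 0)
        bk <- .backward(p, config, ops, laps, fw, Xf)
        loss <- bk$reconLoss +
          config@wKL * .klOmega(fw$mu, fw$logvar, config@nZ)
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at epoch %d batch %d (recon=%g)",
                       ep, bi, bk$reconLoss))
        epLoss <- epLoss + loss * length(ii)
        epRecon <- epRecon + bk$reconLoss * length(ii)
        stepT <- stepT + 1
        c1 <- 1 - b1^stepT; c2 <- 1 - b2^stepT
        for (nm in names(p)) {
          gr <- bk$grads[[nm]]
          mState[[nm]] <- b1 * mState[[nm]] + (1 - b1) * gr
          vState[[nm]] <- b2 * vState[[nm]] + (1 - b2) * gr^2
          p[[nm]] <- p[[nm]] - lr * (mState[[nm]] / c1) /
            (sqrt(vState[[nm]] / c2) + adamEps)
        }
      }
      epLoss <- epLoss / length(train)
      epRecon <- epRecon / length(train)
      vl <- NA_real_
      if (!is.null(valX)) {
        fwv <- .forward(p, config, ops, laps, valX, M1, sample = FALSE)
        lv <- .reconLossGrad(fwv$recon, valX, config@reconLoss)
        vl <- lv$loss + config@wKL * .klOmega(fwv$mu, fwv$logvar, config@nZ)
      }
      history <- rbind(history, data.frame(epoch = ep, trainLoss = epLoss,
                                           trainRecon = epRecon, valLoss = vl))
      if (verbose && (ep %% 10L == 0L || ep == 1L))
        message(sprintf("epoch %3d  train %.5f  val %.5f", ep, epLoss, vl))
    }
  })

  model <- methods::new("ComaModel", config = config, ops = ops, params = p,
                        laplacians = laps, standardize = std,
                        subjectSplit = list(train = train, val = val, test = test))
  res <- .evaluateModel(model, cohort)
  methods::new("RunResult", runId = runId, config = config,
               latents = res$latents, subjectIds = cohort@subjectIds,
               perSubjectRmsd = res$rmsd,
               testRmsdMean = mean(res$rmsd[test]),
               history = history, model = model)
}

## deterministic latents + reconstruction RMSD for all subjects
.evaluateModel <- function(model, cohort, chunk = 256L) {
  config <- model@config; ops <- model@ops
  N <- dim(cohort@shapes)[1L]; M1 <- dim(cohort@shapes)[2L]
  nz <- config@nZ
  latents <- matrix(0, N, nz,
                    dimnames = list(cohort@subjectIds,
                                    paste0("z", seq_len(nz))))
  rmsd <- numeric(N)
  muC <- model@standardize$mean; sdC <- model@standardize$sd
  for (start in seq(1L, N, by = chunk)) {
    ii <- start:min(start + chunk - 1L, N)
    B <- length(ii)
    Xf <- matrix(0, M1 * B, 3L)
    for (k in 1:3)
      Xf[, k] <- (t(cohort@shapes[ii, , k, drop = FALSE][, , 1L]) - muC[, k]) / sdC[, k]
    fw <- .forward(model@params, config, ops, model@laplacians, Xf, M1,
                   sample = FALSE)
    latents[ii, ] <- fw$mu
    ## de-standardize and accumulate squared deviations in mm
    d2 <- matrix(0, M1, B)
    for (k in 1:3) {
      dk <- (fw$recon[, k] - Xf[, k]) * sdC[, k]  # recycles sdC over batch
      d2 <- d2 + matrix(dk, M1, B)^2
    }
    rmsd[ii] <- sqrt(colMeans(d2))
  }
  names(rmsd) <- cohort@subjectIds
  list(latents = latents, rmsd = rmsd)
}

#' Encode a cohort into latent phenotypes
#'
#' Deterministic inference: each subject's latent representation is the mode
#' \eqn{\mu(S)} of the approximate posterior; no sampling is involved, and
#' training and held-out subjects go through the identical path.
#'
#' @param model a \linkS4class{ComaModel} (from a \linkS4class{RunResult}'s
#'   \code{model} slot or \code{\link{trainComa}}).
#' @param cohort an aligned \linkS4class{ShapeCohort}.
#' @return latent matrix \code{N x n_z} with subject ids as row names.
#' @export
encodeCohort <- function(model, cohort) {
  if (methods::is(model, "RunResult")) model <- model@model
  if (!cohort@aligned) stop("encodeCohort requires an aligned cohort")
  .evaluateModel(model, cohort)$latents
}

#' Decode latent vectors to meshes
#'
#' @param model a \linkS4class{ComaModel} or \linkS4class{RunResult}.
#' @param z latent matrix \code{B x n_z} (or vector).
#' @return array \code{B x M x 3} of reconstructed coordinates (mm).
#' @export
decodeLatents <- function(model, z) {
  if (methods::is(model, "RunResult")) model <- model@model
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  config <- model@config; ops <- model@ops
  Lc <- length(config@channels)
  Ms <- vapply(ops@levelMeshes, function(m) nrow(m@vertices), integer(1))
  Mtop <- Ms[Lc + 1L]
  p <- model@params
  Hd <- sweep(z %*% p$Wd, 2L, p$bd, "+")
  X <- .unflattenTop(Hd, Mtop, config@channels[Lc])
  for (l in rev(seq_len(Lc))) {
    X <- .opApply(ops@upMaps[[l]], X, Ms[l + 1L])
    cv <- .chebConvFwd(model@laplacians[[l]], X, p[[paste0("decW", l)]],
                       p[[paste0("decB", l)]], Ms[l])
    X <- if (l > 1L) pmax(cv$Y, 0) else cv$Y
  }
  M1 <- Ms[1L]; B <- nrow(z)
  out <- array(0, c(B, M1, 3L))
  for (k in 1:3)
    out[, , k] <- t(matrix(X[, k], M1, B) * model@standardize$sd[, k] +
                      model@standardize$mean[, k])
  out
}

#' Reconstruct a cohort through the autoencoder
#'
#' Encode (posterior mode) then decode every subject.
#'
#' @param model a \linkS4class{ComaModel} or \linkS4class{RunResult}.
#' @param cohort an aligned \linkS4class{ShapeCohort}.
#' @return a \linkS4class{ShapeCohort} of reconstructions.
#' @export
reconstructCohort <- function(model, cohort) {
  if (methods::is(model, "RunResult")) model <- model@model
  z <- encodeCohort(model, cohort)
  arr <- decodeLatents(model, z)
  methods::new("ShapeCohort", subjectIds = cohort@subjectIds, shapes = arr,
               templateFaces = cohort@templateFaces, aligned = FALSE)
}
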