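# Training: Adam ascent of the volumetric loss through a temperature-
# annealed logistic threshold, with hand-written reverse-mode gradients.
# The constrained parameters are re-parameterized to an unconstrained
# vector: alpha via softmax, theta via the logistic, sigma via a softplus
# with floor 0.25 * spacing. Kernel tap support is frozen at the radius
# implied by the initial sigma so the parameter space has fixed dimension.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplusInv <- function(y) ifelse(y > 30, y, log(expm1(y)))

# run code under a temporary RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Bundle a channel stack and truth mask as a training example
#'
#' @param stack A \linkS4class{ChannelStack} (normalized or raw; normalized
#'   on the fly).
#' @param truth The matching \linkS4class{TruthMask}.
#' @param id Identifier string.
#' @return list(stack, truth, id) with the grids checked to agree.
#' @export
trainingExample <- function(stack, truth, id = "example") {
  if (!identical(stack@grid@dims, truth@grid@dims) ||
      !isTRUE(all.equal(stack@grid@origin, truth@grid@origin)))
    geneoStop("geneo_bad_argument",
              "stack and truth mask must share one grid")
  if (!isTRUE(stack@normalized)) stack <- normalizeChannels(stack)
  list(stack = stack, truth = truth, id = id)
}

#' Training configuration
#'
#' @param k Background weight of the volumetric loss, in [0, 1]. Default
#'   0.02, the center of the working range in which results are stable.
#' @param epochs Number of passes over the training set (default 50).
#' @param lr Adam learning rate (default 0.01).
#' @param seed Seed controlling example shuffling (default 1).
#' @param tempStart,tempEnd Temperature schedule of the soft threshold,
#'   annealed linearly over the epochs (defaults 0.1 to 0.01).
#' @param truncation Kernel truncation in units of sigma (default 3).
#' @param beta1,beta2,adamEps Adam moment parameters.
#' @return list of settings.
#' @export
trainingConfig <- function(k = 0.02, epochs = 50, lr = 0.01, seed = 1L,
                           tempStart = 0.1, tempEnd = 0.01, truncation = 3,
                           beta1 = 0.9, beta2 = 0.999, adamEps = 1e-8) {
  if (k < 0 || k > 1) geneoStop("geneo_config_error", "k must lie in [0, 1]")
  if (epochs < 1) geneoStop("geneo_config_error", "epochs must be >= 1")
  if (lr <= 0) geneoStop("geneo_config_error", "lr must be > 0")
  if (tempStart <= 0 || tempEnd <= 0)
    geneoStop("geneo_config_error", "temperatures must be > 0")
  list(k = k, epochs = as.integer(epochs), lr = lr, seed = as.integer(seed),
       tempStart = tempStart, tempEnd = tempEnd, truncation = truncation,
       beta1 = beta1, beta2 = beta2, adamEps = adamEps)
}

prepExamples <- function(examples) {
  lapply(examples, function(ex) {
    stack <- ex$stack
    if (!isTRUE(stack@normalized)) stack <- normalizeChannels(stack)
    list(ch = stack@channels, mask = stack@emptyMask,
         tau = as.numeric(ex$truth@values), dims = stack@grid@dims,
         spacing = stack@grid@spacing, id = ex$id)
  })
}

# pack/unpack the unconstrained parameter vector per variant
packInit <- function(init, variant, floorSigma, radii, spacing, truncation) {
  a <- log(pmax(init@alpha, 1e-8))
  b <- qlogis(min(max(init@theta, 1e-6), 1 - 1e-6))
  if (variant == "E-NE") {
    cc <- softplusInv(pmax(init@sigma - floorSigma, 1e-6))
    list(par = c(a, b, cc), taps = NULL)
  } else {
    taps <- if (length(init@taps) == 8L) init@taps
    else lapply(seq_len(8), function(i)
      buildKernel(init@families[i], init@sigma[i], spacing, truncation,
                  radius = radii[i])$taps)
    list(par = c(a, b, unlist(lapply(taps, as.numeric))),
         tapDims = lapply(taps, dim))
  }
}

unpackPars <- function(par, variant, floorSigma, tapDims = NULL) {
  a <- par[1:8]
  alpha <- exp(a - max(a)); alpha <- alpha / sum(alpha)
  theta <- plogis(par[9])
  if (variant == "E-NE") {
    list(alpha = alpha, theta = theta,
         sigma = floorSigma + softplus(par[10:17]))
  } else {
    W <- list(); off <- 9L
    for (i in seq_len(8)) {
      n <- prod(tapDims[[i]])
      W[[i]] <- array(par[off + seq_len(n)], dim = tapDims[[i]])
      off <- off + n
    }
    list(alpha = alpha, theta = theta, W = W)
  }
}

# forward + gradient of the soft loss for one example; kernels prebuilt
exampleGrad <- function(ex, kern, alpha, theta, temp, k) {
  dims <- ex$dims
  u <- lapply(seq_len(8), function(i)
    cpp_conv3d(ex$ch[[i]], dims, kern[[i]]$taps, dim(kern[[i]]$taps)))
  comb <- Reduce(`+`, Map(`*`, u, as.list(alpha)))
  mvals <- comb[ex$mask]
  lo <- min(mvals); hi <- max(mvals)
  scale <- if (hi > lo) 1 / (hi - lo) else 0
  psi <- if (scale > 0) pmin(pmax((comb - lo) * scale, 0), 1)
  else rep(0.5, length(comb))
  sRaw <- plogis((psi - theta) / temp)
  s <- sRaw * as.numeric(ex$mask)
  parts <- softLossParts(s, ex$tau, k)
  gs <- parts$dL_ds * sRaw * (1 - sRaw) / temp * as.numeric(ex$mask)
  gpsi_theta <- -sum(gs)                       # d/d(theta)
  gc <- gs * scale                             # d/d(combined), stop-grad min/max
  dAlpha <- vapply(u, function(ui) sum(gc * ui), numeric(1))
  dTaps <- lapply(seq_len(8), function(i) {
    kd <- dim(kern[[i]]$taps)
    g <- cpp_conv3d_adjoint(gc, ex$ch[[i]], dims, kd)
    alpha[i] * g
  })
  list(value = parts$value, dAlpha = dAlpha, dTheta = gpsi_theta,
       dTaps = dTaps)
}

# mean hard-threshold loss over examples for fixed parameters
hardLossMean <- function(exs, kern, alpha, theta, k) {
  vals <- vapply(exs, function(ex) {
    u <- lapply(seq_len(8), function(i)
      cpp_conv3d(ex$ch[[i]], ex$dims, kern[[i]]$taps, dim(kern[[i]]$taps)))
    comb <- Reduce(`+`, Map(`*`, u, as.list(alpha)))
    mvals <- comb[ex$mask]
    lo <- min(mvals); hi <- max(mvals)
    psi <- if (hi > lo) pmin(pmax((comb - lo) / (hi - lo), 0), 1)
    else rep(0.5, length(comb))
    pred <- (psi > theta) & as.logical(ex$mask)
    tv <- sum(ex$tau)
    denom <- tv + k * (length(ex$tau) - tv)
    (sum(pred & (ex$tau > 0)) + k * sum(!pred & !(ex$tau > 0))) / denom
  }, numeric(1))
  mean(vals)
}

buildTrainKernels <- function(variant, p, families, spacing, radii,
                              truncation) {
  if (variant == "E-NE") {
    lapply(seq_len(8), function(i)
      buildKernel(families[i], p$sigma[i], spacing, truncation,
                  radius = radii[i], grad = TRUE))
  } else if (variant == "NE-NE") {
    lapply(p$W, function(W) {
      S <- sum(abs(W))
      list(taps = if (S > 0) W / S else W, S = S)
    })
  } else {
    lapply(p$W, function(W) list(taps = W))
  }
}

#' Fit a model by maximizing the volumetric loss
#'
#' Per-example (batch size 1) Adam ascent of the soft-threshold surrogate
#' loss, with seeded shuffling and a linear temperature anneal; the
#' recorded per-epoch losses use the hard threshold. The "E-NE" variant
#' learns the 17 constrained parameters; "NE-NE" learns free kernel taps
#' re-normalized to unit L1 norm in the forward pass; "NE-E" learns fully
#' free taps.
#'
#' @param examples List of \code{\link{trainingExample}}s.
#' @param config \code{\link{trainingConfig}}.
#' @param variant "E-NE" (default), "NE-NE" or "NE-E".
#' @param init Initial \linkS4class{GENEOModel} (default
#'   \code{geneoModel()}: sigma 2 A, uniform alpha, theta 0.5).
#' @param heldout Optional list of examples for a per-epoch held-out loss.
#' @return A \linkS4class{FitResult}.
#' @export
fitGeneo <- function(examples, config = trainingConfig(), variant = "E-NE",
                     init = geneoModel(), heldout = NULL) {
  if (length(examples) < 1L)
    geneoStop("geneo_config_error", "at least one training example required")
  exs <- prepExamples(examples)
  held <- if (!is.null(heldout)) prepExamples(heldout)
  spacing <- exs[[1]]$spacing
  floorSigma <- 0.25 * spacing
  radii <- vapply(seq_len(8), function(i)
    kernelRadius(init@families[i], init@sigma[i], spacing,
                 config$truncation), integer(1))
  maxDim <- min(vapply(exs, function(e) min(e$dims), integer(1)))
  radii <- pmin(radii, as.integer((maxDim - 1) %/% 2))
  packed <- packInit(init, variant, floorSigma, radii, spacing,
                     config$truncation)
  par <- packed$par
  mAdam <- vAdam <- numeric(length(par))
  trainLoss <- heldLoss <- numeric(config$epochs)
  stepN <- 0L
  withSeed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      frac <- if (config$epochs > 1) (epoch - 1) / (config$epochs - 1) else 0
      temp <- config$tempStart + frac * (config$tempEnd - config$tempStart)
      for (ei in sample.int(length(exs))) {
        p <- unpackPars(par, variant, floorSigma, packed$tapDims)
        kern <- buildTrainKernels(variant, p, init@families, spacing, radii,
                                  config$truncation)
        g <- exampleGrad(exs[[ei]], kern, p$alpha, p$theta, temp, config$k)
        # chain through the re-parameterizations
        da <- p$alpha * (g$dAlpha - sum(p$alpha * g$dAlpha))
        db <- g$dTheta * p$theta * (1 - p$theta)
        grad <- c(da, db)
        if (variant == "E-NE") {
          dsig <- vapply(seq_len(8), function(i)
            sum(g$dTaps[[i]] * kern[[i]]$dtaps), numeric(1))
          grad <- c(grad, dsig * plogis(par[10:17]))
        } else if (variant == "NE-NE") {
          dW <- lapply(seq_len(8), function(i) {
            W <- p$W[[i]]; S <- kern[[i]]$S
            if (S == 0) return(g$dTaps[[i]])
            (g$dTaps[[i]] - sum(g$dTaps[[i]] * kern[[i]]$taps) * sign(W)) / S
          })
          grad <- c(grad, unlist(lapply(dW, as.numeric)))
        } else {
          grad <- c(grad, unlist(lapply(g$dTaps, as.numeric)))
        }
        if (any(!is.finite(grad)))
          geneoStop("geneo_training_diverged",
                    "non-finite gradient at epoch ", epoch)
        stepN <- stepN + 1L
        mAdam <- config$beta1 * mAdam + (1 - config$beta1) * grad
        vAdam <- config$beta2 * vAdam + (1 - config$beta2) * grad^2
        mh <- mAdam / (1 - config$beta1^stepN)
        vh <- vAdam / (1 - config$beta2^stepN)
        par <- par + config$lr * mh / (sqrt(vh) + config$adamEps)  # ascent
      }
      p <- unpackPars(par, variant, floorSigma, packed$tapDims)
      kern <- buildTrainKernels(variant, p, init@families, spacing, radii,
                                config$truncation)
      trainLoss[epoch] <- hardLossMean(exs, kern, p$alpha, p$theta, config$k)
      if (!is.null(held))
        heldLoss[epoch] <- hardLossMean(held, kern, p$alpha, p$theta,
                                        config$k)
    }
  })
  p <- unpackPars(par, variant, floorSigma, packed$tapDims)
  model <- if (variant == "E-NE")
    geneoModel(sigma = p$sigma, alpha = p$alpha, theta = p$theta,
               families = init@families, connectivity = init@connectivity,
               volumeRef = init@volumeRef, smallVolume = init@smallVolume)
  else
    geneoModel(sigma = init@sigma, alpha = p$alpha, theta = p$theta,
               families = init@families, variant = variant, taps = p$W,
               connectivity = init@connectivity, volumeRef = init@volumeRef,
               smallVolume = init@smallVolume)
  new("FitResult", model = model, trainLoss = trainLoss,
      heldoutLoss = if (is.null(held)) numeric(0) else heldLoss,
      seed = config$seed, config = config)
}

#' Multi-restart training with validation-based selection
#'
#' Trains one model per training set and returns the one with the highest
#' top-n identification coefficient (H at j = 0) on the validation
#' examples; ties go to the lower restart index.
#'
#' @param trainSets List of training-example lists.
#' @param validation List of validation examples.
#' @param config Base \code{\link{trainingConfig}}; restart r uses seed
#'   \code{config$seed + r - 1}.
#' @param variant,init Passed to \code{\link{fitGeneo}}.
#' @param n Number of true pockets per validation protein (default 1).
#' @return The selected \linkS4class{FitResult}, with the per-restart
#'   validation coefficients in \code{attr(, "validationH1")}.
#' @export
multiRestartSelect <- function(trainSets, validation,
                               config = trainingConfig(), variant = "E-NE",
                               init = geneoModel(), n = 1) {
  if (length(trainSets) < 1L)
    geneoStop("geneo_config_error", "need at least one training set")
  fits <- vector("list", length(trainSets))
  h1 <- numeric(length(trainSets))
  for (r in seq_along(trainSets)) {
    cfg <- config; cfg$seed <- config$seed + r - 1L
    fits[[r]] <- fitGeneo(trainSets[[r]], cfg, variant, init)
    ranks <- vapply(validation, function(ex) {
      pred <- detectPockets(ex$stack, fits[[r]]@model)
      mr <- matchRank(pred, ex$truth)
      if (is.na(mr)) Inf else mr
    }, numeric(1))
    h1[r] <- mean(ranks <= n)
  }
  best <- which.max(h1)   # ties: first (lower restart index)
  out <- fits[[best]]
  attr(out, "validationH1") <- h1
  out
}
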