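# Minimal feed-forward NN with optional 1-D convolutions over the one-hot
# block, dense hidden layers, and two output heads. Written against plain
# matrix algebra; everything is deterministic given the training seed.
#
# Layout of the 500-long input: columns 1..160 are the one-hot block
# (position-major, 4 channels per position), 161..500 the k-mer counts.
# Convolutions see the one-hot block as a 40 x 4 signal; the k-mer block
# joins at the first dense layer.

ONEHOT_DIM <- 160L
SEQ_LEN <- 40L
N_CHANNELS <- 4L

.actFun <- function(name) {
  switch(name,
         relu = list(f = function(z) pmax(z, 0),
                     df = function(z, a) (z > 0) * 1),
         tanh = list(f = tanh, df = function(z, a) 1 - a^2))
}

# im2col index for a 1-D convolution: rows = output positions, cols = the
# flattened (position-major, channel-minor) input indices of each window
.convIndex <- function(inLen, channels, width) {
  nOut <- inLen - width + 1L
  idx <- matrix(0L, nrow = nOut, ncol = width * channels)
  for (p in seq_len(nOut)) {
    cols <- as.vector(vapply(seq_len(width), function(w) {
      (p + w - 2L) * channels + seq_len(channels)
    }, integer(channels)))
    idx[p, ] <- cols
  }
  idx
}

# He-initialized weight matrix
.heInit <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nrow = nin, ncol = nout)
}

#' Construct a model specification
#'
#' @param convFilters integer vector: filters per convolutional layer
#'   (0-3 layers; `integer(0)` for none). Convolutions run over the
#'   one-hot block (40 positions x 4 channels) with window `convWidth`.
#' @param convWidth convolution window in nt (default 5).
#' @param hidden integer vector of fully connected layer sizes (0-4
#'   layers).
#' @param activation `"relu"` (default) or `"tanh"`.
#' @param dropout dropout probability in hidden layers (default 0).
#' @param head `"fully_connected"` or `"latent_affinity"`.
#' @param optimizer `"sgd"` (momentum SGD, default) or `"adam"`.
#' @param learningRate,momentum,batchSize,epochs training
#'   hyperparameters.
#' @param upsampleFloor minimum positive fraction per training batch
#'   (default 0.1).
#' @return a [ModelSpec].
#' @export
modelSpec <- function(convFilters = integer(0), convWidth = 5L,
                      hidden = 64L, activation = "relu", dropout = 0,
                      head = "fully_connected", optimizer = "sgd",
                      learningRate = 0.002, momentum = 0.9,
                      batchSize = 64L, epochs = 20L,
                      upsampleFloor = 0.1) {
  new("ModelSpec", convFilters = as.integer(convFilters),
      convWidth = as.integer(convWidth), hidden = as.integer(hidden),
      activation = activation, dropout = as.numeric(dropout), head = head,
      optimizer = optimizer, learningRate = as.numeric(learningRate),
      momentum = as.numeric(momentum), batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), upsampleFloor = as.numeric(upsampleFloor))
}

#' Selected hyperparameter presets for the three model formulations
#'
#' The per-formulation selections: Counts uses the latent-affinity output
#' head with mini-batch 64 and learning rate 0.00138; Binned uses the
#' fully connected head with learning rate 0.00388 and momentum 0.737;
#' SuperBin uses the fully connected head with learning rate 0.00203 and
#' momentum 0.498. All train with squared-error loss. Binned and
#' SuperBin default to momentum SGD; the Counts preset defaults to Adam
#' because its multiplicative latent-affinity bottleneck is effectively
#' untrainable by plain momentum SGD at the selected rate (the
#' per-output multipliers barely move; see the package vignette), while
#' Adam's per-parameter scaling trains it reliably. Either optimizer can
#' be requested explicitly for any formulation.
#'
#' @param formulation `"counts"`, `"binned"` or `"superbin"`.
#' @param optimizer `NULL` (formulation default), `"sgd"` or `"adam"`.
#' @param epochs training epochs (default 20).
#' @return a [ModelSpec].
#' @export
modelPreset <- function(formulation = c("counts", "binned", "superbin"),
                        optimizer = NULL, epochs = 20L) {
  formulation <- match.arg(formulation)
  spec <- switch(formulation,
    counts = modelSpec(head = "latent_affinity", batchSize = 64L,
                       learningRate = 0.00138, momentum = 0.903,
                       optimizer = "adam", hidden = c(64L, 32L)),
    binned = modelSpec(head = "fully_connected", batchSize = 64L,
                       learningRate = 0.00388, momentum = 0.737,
                       hidden = c(64L, 32L)),
    superbin = modelSpec(head = "fully_connected", batchSize = 64L,
                         learningRate = 0.00203, momentum = 0.498,
                         hidden = c(64L, 32L)))
  spec@epochs <- as.integer(epochs)
  if (!is.null(optimizer)) {
    spec@optimizer <- match.arg(optimizer, c("sgd", "adam"))
  }
  spec
}

#' Initialize an untrained network
#'
#' @param spec a [ModelSpec].
#' @param nOutputs number of output units (pools, stringency levels, or 1
#'   for a scalar target).
#' @param inputDim input dimension (default 500).
#' @param seed weight-initialization seed.
#' @return an opaque weights list (layers + head), consumed by
#'   [nnForward()] and [trainModel()].
#' @export
buildNetwork <- function(spec, nOutputs, inputDim = 500L, seed = 1L) {
  validObject(spec)
  if (spec@head == "latent_affinity" && nOutputs < 2L) {
    stop("latent_affinity head is meaningless for a scalar target; ",
         "use the fully_connected head")
  }
  set.seed(deriveSeed(seed, "init"))
  net <- list(spec = spec, nOutputs = as.integer(nOutputs),
              inputDim = as.integer(inputDim))
  conv <- list()
  inLen <- SEQ_LEN
  inCh <- N_CHANNELS
  for (f in spec@convFilters) {
    conv[[length(conv) + 1L]] <- list(
      W = .heInit(spec@convWidth * inCh, f), b = rep(0, f),
      idx = .convIndex(inLen, inCh, spec@convWidth),
      inLen = inLen, inCh = inCh)
    inLen <- inLen - spec@convWidth + 1L
    inCh <- f
  }
  net$conv <- conv
  denseIn <- inLen * inCh + (inputDim - ONEHOT_DIM)
  if (length(spec@convFilters) == 0L) denseIn <- inputDim
  dense <- list()
  for (h in spec@hidden) {
    dense[[length(dense) + 1L]] <- list(W = .heInit(denseIn, h),
                                        b = rep(0, h))
    denseIn <- h
  }
  net$dense <- dense
  if (spec@head == "latent_affinity") {
    net$head <- list(wA = .heInit(denseIn, 1L), bA = 0,
                     m = rep(1, nOutputs) + rnorm(nOutputs, sd = 0.1),
                     bOut = rep(0, nOutputs))
  } else {
    net$head <- list(W = .heInit(denseIn, nOutputs), b = rep(0, nOutputs))
  }
  net
}

# forward pass; keepCache=TRUE retains intermediates for backprop.
# dropMask: optional list of dropout masks per dense layer (training only).
nnForward <- function(net, X, keepCache = FALSE, dropMask = NULL) {
  act <- .actFun(net$spec@activation)
  cache <- list()
  useConv <- length(net$conv) > 0L
  if (useConv) {
    H <- X[, seq_len(ONEHOT_DIM), drop = FALSE]
    rest <- X[, -seq_len(ONEHOT_DIM), drop = FALSE]
    convCache <- list()
    for (ci in seq_along(net$conv)) {
      ly <- net$conv[[ci]]
      n <- nrow(H)
      nOut <- nrow(ly$idx)
      # im2col: (n*nOut) x (width*inCh)
      cols <- H[, as.vector(t(ly$idx)), drop = FALSE]
      dim(cols) <- c(n, ncol(ly$idx), nOut)
      Xc <- matrix(aperm(cols, c(1L, 3L, 2L)), nrow = n * nOut)
      Z <- Xc %*% ly$W
      Z <- sweep(Z, 2L, ly$b, "+")
      A <- act$f(Z)
      if (keepCache) convCache[[ci]] <- list(Xc = Xc, Z = Z, A = A, n = n,
                                             nOut = nOut)
      # back to (n, nOut*filters), position-major channel-minor
      H <- matrix(aperm(array(A, c(n, nOut, ncol(ly$W))), c(1L, 3L, 2L)),
                  nrow = n)
    }
    H <- cbind(H, rest)
    if (keepCache) cache$conv <- convCache
  } else {
    H <- X
  }
  denseCache <- list()
  for (di in seq_along(net$dense)) {
    ly <- net$dense[[di]]
    Z <- sweep(H %*% ly$W, 2L, ly$b, "+")
    A <- act$f(Z)
    if (!is.null(dropMask) && !is.null(dropMask[[di]])) {
      A <- A * dropMask[[di]]
    }
    if (keepCache) denseCache[[di]] <- list(H = H, Z = Z, A = A)
    H <- A
  }
  if (keepCache) cache$dense <- denseCache
  if (net$spec@head == "latent_affinity") {
    latent <- as.vector(H %*% net$head$wA) + net$head$bA
    Y <- outer(latent, net$head$m) +
      matrix(net$head$bOut, nrow = nrow(H), ncol = net$nOutputs,
             byrow = TRUE)
    if (keepCache) cache$head <- list(H = H, latent = latent)
    out <- list(Y = Y, latent = latent)
  } else {
    Y <- sweep(H %*% net$head$W, 2L, net$head$b, "+")
    if (keepCache) cache$head <- list(H = H)
    out <- list(Y = Y, latent = NULL)
  }
  if (keepCache) out$cache <- cache
  out
}

# backprop of masked squared error; returns gradients shaped like the net
.nnBackward <- function(net, X, fwd, dY, dropMask = NULL) {
  act <- .actFun(net$spec@activation)
  cache <- fwd$cache
  grads <- list(conv = list(), dense = list(), head = list())
  if (net$spec@head == "latent_affinity") {
    H <- cache$head$H
    latent <- cache$head$latent
    grads$head$m <- as.vector(crossprod(dY, latent))
    grads$head$bOut <- colSums(dY)
    dLatent <- as.vector(dY %*% net$head$m)
    grads$head$wA <- crossprod(H, dLatent)
    grads$head$bA <- sum(dLatent)
    dH <- outer(dLatent, as.vector(net$head$wA))
  } else {
    H <- cache$head$H
    grads$head$W <- crossprod(H, dY)
    grads$head$b <- colSums(dY)
    dH <- dY %*% t(net$head$W)
  }
  for (di in rev(seq_along(net$dense))) {
    cc <- cache$dense[[di]]
    if (!is.null(dropMask) && !is.null(dropMask[[di]])) {
      dH <- dH * dropMask[[di]]
    }
    dZ <- dH * act$df(cc$Z, cc$A)
    grads$dense[[di]] <- list(W = crossprod(cc$H, dZ), b = colSums(dZ))
    dH <- dZ %*% t(net$dense[[di]]$W)
  }
  if (length(net$conv)) {
    # dH currently w.r.t. cbind(convOut, kmerBlock): drop the kmer part
    lastLy <- net$conv[[length(net$conv)]]
    lastOutDim <- nrow(lastLy$idx) * ncol(lastLy$W)
    dH <- dH[, seq_len(lastOutDim), drop = FALSE]
    for (ci in rev(seq_along(net$conv))) {
      ly <- net$conv[[ci]]
      cc <- cache$conv[[ci]]
      nF <- ncol(ly$W)
      # dH: (n, nOut*nF) position-major channel-minor -> (n*nOut, nF)
      dA <- matrix(aperm(array(dH, c(cc$n, nF, cc$nOut)), c(1L, 3L, 2L)),
                   nrow = cc$n * cc$nOut)
      dZ <- dA * act$df(cc$Z, cc$A)
      grads$conv[[ci]] <- list(W = crossprod(cc$Xc, dZ), b = colSums(dZ))
      dXc <- dZ %*% t(ly$W)
      # col2im: scatter-add window gradients back to the input signal
      dIn <- matrix(0, nrow = cc$n, ncol = ly$inLen * ly$inCh)
      dXcArr <- aperm(array(dXc, c(cc$n, cc$nOut, ncol(ly$idx))),
                      c(1L, 3L, 2L))
      for (p in seq_len(cc$nOut)) {
        cols <- ly$idx[p, ]
        dIn[, cols] <- dIn[, cols] + dXcArr[, , p]
      }
      dH <- dIn
    }
  }
  grads
}

# flatten/unflatten parameters for the optimizers
.paramRefs <- function(net) {
  refs <- list()
  for (ci in seq_along(net$conv)) {
    refs[[length(refs) + 1L]] <- c("conv", ci, "W")
    refs[[length(refs) + 1L]] <- c("conv", ci, "b")
  }
  for (di in seq_along(net$dense)) {
    refs[[length(refs) + 1L]] <- c("dense", di, "W")
    refs[[length(refs) + 1L]] <- c("dense", di, "b")
  }
  if (net$spec@head == "latent_affinity") {
    for (p in c("wA", "bA", "m", "bOut")) {
      refs[[length(refs) + 1L]] <- c("head", NA, p)
    }
  } else {
    for (p in c("W", "b")) refs[[length(refs) + 1L]] <- c("head", NA, p)
  }
  refs
}

.getParam <- function(net, ref) {
  if (ref[1L] == "head") net$head[[ref[3L]]]
  else net[[ref[1L]]][[as.integer(ref[2L])]][[ref[3L]]]
}

.setParam <- function(net, ref, value) {
  if (ref[1L] == "head") net$head[[ref[3L]]] <- value
  else net[[ref[1L]]][[as.integer(ref[2L])]][[ref[3L]]] <- value
  net
}

.getGrad <- function(grads, ref) {
  if (ref[1L] == "head") grads$head[[ref[3L]]]
  else grads[[ref[1L]]][[as.integer(ref[2L])]][[ref[3L]]]
}

.setGrad <- function(grads, ref, value) {
  if (ref[1L] == "head") grads$head[[ref[3L]]] <- value
  else grads[[ref[1L]]][[as.integer(ref[2L])]][[ref[3L]]] <- value
  grads
}

# top up a batch so positives make at least the requested count: negatives
# are replaced in-place by positives resampled with replacement
.upsampleBatch <- function(idx, positive, posIdx, nPosNeeded) {
  if (length(posIdx) == 0L) return(idx)
  got <- sum(positive[idx])
  need <- min(nPosNeeded, length(idx))
  if (got >= need) return(idx)
  negSlots <- which(!positive[idx])
  swap <- negSlots[sample.int(length(negSlots), need - got)]
  idx[swap] <- posIdx[sample.int(length(posIdx), need - got,
                                 replace = TRUE)]
  idx
}
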