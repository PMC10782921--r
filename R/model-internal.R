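## Hand-written forward/backward passes for the hybrid classifier.  The
## convolutional branch keeps activations as channels x (positions*nodes)
## matrices (position fastest within a node along columns) so convolution
## is one contiguous column gather (src/kernels.cpp) plus a BLAS product,
## pooling is a grouped column maximum with explicit argmax for the
## backward pass, and the input gradient is the transpose convolution
## expressed through the same gather.  Verified against finite differences
## in the test suite.

## 'same' padding for stride-1 convolution: kernel tap k reads offset
## k - 1 - floor((K-1)/2).
convOffsets <- function(K) seq_len(K) - 1L - (K - 1L) %/% 2L

## Column groups of non-overlapping position pools (floor mode: remainder
## positions beyond the last full pool are dropped).
poolGroups <- function(L, n, pool) {
  Lout <- L %/% pool
  if (Lout < 1L) stopf("window too short for pooling (length %d, pool %d)", L, pool)
  keep <- rep((seq_len(n) - 1L) * L, each = Lout * pool) +
    rep(seq_len(Lout * pool), n)
  dim(keep) <- c(pool, Lout * n)
  keep
}

dropoutMask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((runif(nr * nc) >= p) / (1 - p), nr, nc)
}

## Row-normalized aggregation operator of the mean-aggregator GraphSAGE
## update: node v averages its own previous representation with those of
## its neighbors (a self-loop edge contributes one extra copy of v).
buildAggregation <- function(graph) {
  n <- length(graph@nodes)
  e <- graph@edges
  self <- e[, 1L] == e[, 2L]
  i <- c(e[!self, 1L], e[!self, 2L], e[self, 1L], seq_len(n))
  j <- c(e[!self, 2L], e[!self, 1L], e[self, 2L], seq_len(n))
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  Matrix::Diagonal(x = 1 / Matrix::rowSums(A)) %*% A
}

initParams <- function(cfg) {
  p <- list()
  cin <- cfg$inChannels
  for (l in seq_along(cfg$cnnChannels)) {
    cout <- cfg$cnnChannels[l]
    p[[paste0("convW", l)]] <- matrix(rnorm(cfg$kernel * cin * cout,
                                            sd = sqrt(2 / (cfg$kernel * cin))),
                                      nrow = cfg$kernel * cin, ncol = cout)
    p[[paste0("convB", l)]] <- numeric(cout)
    cin <- cout
  }
  din <- cfg$descriptorDim
  for (r in seq_along(cfg$sageChannels)) {
    dout <- cfg$sageChannels[r]
    p[[paste0("sageW", r)]] <- matrix(rnorm(din * dout, sd = sqrt(2 / din)),
                                      nrow = din, ncol = dout)
    din <- dout
  }
  din <- cfg$cnnChannels[length(cfg$cnnChannels)] +
    cfg$sageChannels[length(cfg$sageChannels)]
  nm <- length(cfg$mlp)
  for (j in seq_len(nm)) {
    dout <- cfg$mlp[j]
    if (j < nm) {
      p[[paste0("mlpW", j)]] <- matrix(rnorm(din * dout, sd = sqrt(2 / din)),
                                       nrow = din, ncol = dout)
    } else {
      ## zero-started classifier head: logits begin at 0 and every score
      ## difference thereafter is learned signal
      p[[paste0("mlpW", j)]] <- matrix(0, nrow = din, ncol = dout)
    }
    p[[paste0("mlpB", j)]] <- numeric(dout)
    din <- dout
  }
  p
}

## Full forward pass.  X: (C, L, nBatch) linear features of the batch nodes;
## M: aggregation operator over all graph nodes; D: descriptor matrix
## (nAll x descriptorDim); batchIdx: graph row index of each batch node.
forwardModel <- function(params, cfg, X, M, D, batchIdx, training = FALSE) {
  cache <- list(convs = list(), sage = list(), mlp = list())
  slope <- cfg$leakySlope
  n <- dim(X)[3L]
  L <- dim(X)[2L]
  cur <- X
  dim(cur) <- c(dim(X)[1L], L * n)              # channels x (positions*nodes)
  off <- convOffsets(cfg$kernel)
  for (l in seq_along(cfg$cnnChannels)) {
    W <- params[[paste0("convW", l)]]
    Y <- .convFwd(cur, W, params[[paste0("convB", l)]], off, L, n)
    act <- .leakyFwd(Y, slope)
    pm <- .groupMax(act, poolGroups(L, n, cfg$pool))
    dmask <- if (training) dropoutMask(nrow(pm$out), ncol(pm$out), cfg$dropout)
    else NULL
    cache$convs[[l]] <- list(inp = cur, pre = Y, arg = pm$arg, dmask = dmask,
                             L = L, N = ncol(act))
    cur <- if (is.null(dmask)) pm$out else pm$out * dmask
    L <- L %/% cfg$pool
  }
  gm <- .groupMax(cur, matrix(seq_len(L * n), nrow = L))
  cnnOut <- t(gm$out)                           # (nBatch, cLast)
  cache$gm <- gm
  cache$gmN <- L * n

  H <- D
  for (r in seq_along(cfg$sageChannels)) {
    A <- as.matrix(M %*% H)
    Z <- A %*% params[[paste0("sageW", r)]]
    Hn <- .leakyFwd(Z, slope)
    dmask <- if (training) dropoutMask(nrow(Hn), ncol(Hn), cfg$dropout) else NULL
    if (!is.null(dmask)) Hn <- Hn * dmask
    cache$sage[[r]] <- list(A = A, Z = Z, dmask = dmask)
    H <- Hn
  }
  sageOut <- H[batchIdx, , drop = FALSE]        # (nBatch, sLast)

  feat <- cbind(cnnOut, sageOut)
  cache$concat <- list(nc = ncol(cnnOut), ns = ncol(sageOut))
  cur <- feat
  nm <- length(cfg$mlp)
  for (j in seq_len(nm)) {
    Z <- cur %*% params[[paste0("mlpW", j)]]
    Z <- Z + rep(params[[paste0("mlpB", j)]], each = nrow(Z))
    if (j < nm) {
      Hn <- .leakyFwd(Z, slope)
      dmask <- if (training) dropoutMask(nrow(Hn), ncol(Hn), cfg$dropout)
      else NULL
      if (!is.null(dmask)) Hn <- Hn * dmask
      cache$mlp[[j]] <- list(inp = cur, Z = Z, dmask = dmask)
      cur <- Hn
    } else {
      cache$mlp[[j]] <- list(inp = cur, Z = Z, dmask = NULL)
      cur <- Z
    }
  }
  list(logits = cur, cache = cache, embed = feat)
}

## Class-weighted softmax cross-entropy.  y: integer vector (1 = negative,
## 2 = silencer); returns torch-style weighted mean and d(loss)/d(logits).
weightedCELoss <- function(logits, y, classWeight) {
  n <- nrow(logits)
  m <- pmax(logits[, 1L], logits[, 2L])
  ex <- exp(logits - m)
  probs <- ex / rowSums(ex)
  w <- ifelse(y == 2L, classWeight, 1)
  ll <- -log(pmax(probs[cbind(seq_len(n), y)], 1e-300))
  loss <- sum(w * ll) / sum(w)
  dlogits <- probs
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  dlogits <- dlogits * (w / sum(w))
  list(loss = loss, probs = probs, dlogits = dlogits)
}

backwardModel <- function(params, cfg, fwd, dlogits, M, nAll, batchIdx) {
  cache <- fwd$cache
  slope <- cfg$leakySlope
  n <- length(batchIdx)
  grads <- list()
  nm <- length(cfg$mlp)
  dcur <- dlogits
  for (j in rev(seq_len(nm))) {
    cc <- cache$mlp[[j]]
    dZ <- if (j < nm) {
      dh <- dcur
      if (!is.null(cc$dmask)) dh <- dh * cc$dmask
      .leakyBack(dh, cc$Z, slope)
    } else dcur
    grads[[paste0("mlpW", j)]] <- crossprod(cc$inp, dZ)
    grads[[paste0("mlpB", j)]] <- colSums(dZ)
    dcur <- dZ %*% t(params[[paste0("mlpW", j)]])
  }
  nc <- cache$concat$nc
  dCnn <- dcur[, seq_len(nc), drop = FALSE]
  dSage <- dcur[, nc + seq_len(cache$concat$ns), drop = FALSE]

  ## GraphSAGE branch
  dH <- matrix(0, nrow = nAll, ncol = ncol(dSage))
  dH[batchIdx, ] <- dSage
  for (r in rev(seq_along(cfg$sageChannels))) {
    cc <- cache$sage[[r]]
    if (!is.null(cc$dmask)) dH <- dH * cc$dmask
    dZ <- .leakyBack(dH, cc$Z, slope)
    grads[[paste0("sageW", r)]] <- crossprod(cc$A, dZ)
    dA <- dZ %*% t(params[[paste0("sageW", r)]])
    dH <- as.matrix(Matrix::crossprod(M, dA))
  }

  ## CNN branch
  dcur <- .groupMaxBack(t(dCnn), cache$gm$arg, cache$gmN)
  off <- convOffsets(cfg$kernel)
  for (l in rev(seq_along(cfg$cnnChannels))) {
    cc <- cache$convs[[l]]
    if (!is.null(cc$dmask)) dcur <- dcur * cc$dmask
    dAct <- .groupMaxBack(dcur, cc$arg, cc$N)
    dPre <- .leakyBack(dAct, cc$pre, slope)
    W <- params[[paste0("convW", l)]]
    grads[[paste0("convW", l)]] <- .convBwdWeight(cc$inp, dPre, off, cc$L, n)
    grads[[paste0("convB", l)]] <- rowSums(dPre)
    ## the first unit's input is the data: its gradient is never used
    if (l > 1L) dcur <- .convBwdInput(dPre, W, off, cc$L, n)
  }
  grads
}

adamInit <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## L2 term enters through the gradient (weight matrices only, not biases).
addL2 <- function(grads, params, l2) {
  if (l2 <= 0) return(grads)
  for (nm in names(params)) {
    if (grepl("W", nm, fixed = TRUE))
      grads[[nm]] <- grads[[nm]] + l2 * params[[nm]]
  }
  grads
}
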