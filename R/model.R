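#' Mean-aggregator GraphSAGE update for one node
#'
#' Computes `activation(W %*% m)` where `m` is the mean of the node's own
#' previous representation together with its neighbors' representations —
#' the single-node form of the aggregation used by the network branch of
#' the classifier.
#'
#' @param hSelf Numeric vector, the node's previous representation.
#' @param neighborHs Matrix with one neighbor representation per column (or
#'   `NULL` for an isolated node).
#' @param W Weight matrix, `output dim x input dim`.
#' @param activation Activation function (default identity).
#' @return Numeric vector of length `nrow(W)`.
#' @examples
#' sageAggregate(c(2, 4), NULL, diag(2))          # isolated node: c(2, 4)
#' sageAggregate(2, matrix(4), matrix(1))         # mean(2, 4) = 3
#' @export
sageAggregate <- function(hSelf, neighborHs = NULL, W = diag(length(hSelf)),
                          activation = identity) {
  if (!is.null(neighborHs)) {
    neighborHs <- as.matrix(neighborHs)
    if (nrow(neighborHs) != length(hSelf))
      stopf("neighbor representations must have the same dimension as hSelf")
  }
  m <- rowMeans(cbind(hSelf, neighborHs))
  if (ncol(W) != length(m))
    stopf("W has %d columns but representations have dimension %d", ncol(W),
          length(m))
  activation(as.vector(W %*% m))
}

## Gather the linear feature tensor of the given node ids from a
## REINFeatures object; errors on any node without features.
gatherLinear <- function(features, nodes) {
  idx <- match(nodes, features@linearNodes)
  if (anyNA(idx))
    stopf("no linear features for node '%s'", nodes[which(is.na(idx))[1L]])
  features@linear[, , idx, drop = FALSE]
}

## Map node ids to row indices of the graph/descriptor matrix.
graphIndex <- function(graph, nodes) {
  idx <- match(nodes, names(graph@nodes))
  if (anyNA(idx)) stopf("unknown node id: %s", nodes[which(is.na(idx))[1L]])
  idx
}

## Drop nodes from message passing: remove their incident edges and zero
## their descriptors, used by the masked cross-validation mode.
maskGraph <- function(graph, D, maskNodes) {
  if (length(maskNodes) == 0L) return(list(graph = graph, D = D))
  idx <- graphIndex(graph, maskNodes)
  e <- graph@edges
  keep <- !(e[, 1L] %in% idx | e[, 2L] %in% idx)
  g <- initialize(graph, edges = e[keep, , drop = FALSE])
  D[idx, ] <- 0
  list(graph = g, D = D)
}

#' Train the hybrid silencer classifier
#'
#' Fits the convolutional + GraphSAGE model by minibatch Adam on
#' class-weighted cross-entropy (weight `classWeight` on the silencer
#' class) with L2 regularization.  The learning rate is multiplied by
#' `gamma` after any epoch whose training loss exceeds the previous
#' epoch's.  A stratified validation split drives early stopping: training
#' ends at `maxEpochs` or after `patience` epochs without validation-loss
#' improvement, and the parameters from the best validation epoch are kept.
#' Message passing runs over the full graph; labels of non-training nodes
#' are never used.  Pass `maskNodes` to exclude held-out nodes from message
#' passing entirely.
#'
#' @param graph A [REINGraph-class].
#' @param features A [REINFeatures-class] covering all training nodes.
#' @param dataset A [REINDataset-class] (both classes must be present).
#' @param config A [reinConfig()] list.
#' @param maskNodes Node ids to remove from message passing (optional).
#' @return A [REINFit-class].
#' @export
trainREIN <- function(graph, features, dataset, config = reinConfig(),
                      maskNodes = character(0)) {
  nodes <- dataset@node
  y <- ifelse(dataset@role == "positive", 2L, 1L)
  if (length(unique(y)) < 2L)
    stopf("training dataset must contain both classes")
  X <- gatherLinear(features, nodes)
  D <- features@descriptors
  mk <- maskGraph(graph, D, maskNodes)
  M <- buildAggregation(mk$graph)
  D <- mk$D
  nAll <- nrow(D)
  batchIdx <- graphIndex(graph, nodes)

  cfg <- config
  withSeed(cfg$seed, {
    params <- initParams(cfg)
    state <- adamInit(params)
    n <- length(nodes)

    ## stratified validation split
    valIdx <- integer(0)
    if (cfg$valFraction > 0) {
      for (cls in c(1L, 2L)) {
        ic <- which(y == cls)
        k <- max(1L, floor(cfg$valFraction * length(ic)))
        valIdx <- c(valIdx, sample(ic, k))
      }
    }
    trIdx <- setdiff(seq_len(n), valIdx)
    lr <- cfg$lr
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          valLoss = numeric(0), lr = numeric(0))
    bestVal <- Inf
    bestParams <- params
    wait <- 0L
    prevLoss <- Inf

    for (epoch in seq_len(cfg$maxEpochs)) {
      ord <- sample(trIdx)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batchSize))
      lossNum <- 0; lossDen <- 0
      for (b in batches) {
        fwd <- forwardModel(params, cfg, X[, , b, drop = FALSE], M, D,
                            batchIdx[b], training = TRUE)
        ls <- weightedCELoss(fwd$logits, y[b], cfg$classWeight)
        grads <- backwardModel(params, cfg, fwd, ls$dlogits, M, nAll,
                               batchIdx[b])
        grads <- addL2(grads, params, cfg$l2)
        upd <- adamStep(params, grads, state, lr)
        params <- upd$params
        state <- upd$state
        wsum <- sum(ifelse(y[b] == 2L, cfg$classWeight, 1))
        lossNum <- lossNum + ls$loss * wsum
        lossDen <- lossDen + wsum
      }
      epochLoss <- lossNum / lossDen
      valLoss <- NA_real_
      if (length(valIdx) > 0L) {
        fwd <- forwardModel(params, cfg, X[, , valIdx, drop = FALSE], M, D,
                            batchIdx[valIdx], training = FALSE)
        valLoss <- weightedCELoss(fwd$logits, y[valIdx], cfg$classWeight)$loss
      }
      history <- rbind(history, data.frame(epoch = epoch, loss = epochLoss,
                                           valLoss = valLoss, lr = lr))
      ## decay on training-loss rise
      if (epochLoss > prevLoss) lr <- lr * cfg$gamma
      prevLoss <- epochLoss
      ## early stopping on validation loss
      if (length(valIdx) > 0L) {
        if (valLoss < bestVal - 1e-12) {
          bestVal <- valLoss
          bestParams <- params
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$patience) break
        }
      }
    }
    if (length(valIdx) > 0L) params <- bestParams
    new("REINFit", params = params, config = unclass(cfg), history = history,
        trainNodes = nodes)
  })
}

evalForward <- function(fit, graph, features, nodes, maskNodes = character(0)) {
  cfg <- fit@config
  X <- gatherLinear(features, nodes)
  D <- features@descriptors
  mk <- maskGraph(graph, D, maskNodes)
  M <- buildAggregation(mk$graph)
  forwardModel(fit@params, cfg, X, M, mk$D, graphIndex(graph, nodes),
               training = FALSE)
}

#' Score nodes with a trained classifier
#'
#' Runs the model in evaluation mode (dropout off, deterministic) and
#' returns the softmax silencer probability per node; a node is called a
#' silencer when its score is at least `threshold`.
#'
#' @param fit A [REINFit-class] from [trainREIN()].
#' @param graph The [REINGraph-class] the features refer to.
#' @param features A [REINFeatures-class] covering `nodes`.
#' @param nodes Node ids to score.
#' @param threshold Decision threshold on the silencer probability
#'   (default 0.5).
#' @return `data.frame` with columns `node`, `score` (silencer probability)
#'   and `label` (`"silencer"` or `"non_silencer"`).
#' @export
predictREIN <- function(fit, graph, features, nodes, threshold = 0.5) {
  fwd <- evalForward(fit, graph, features, nodes)
  sm <- weightedCELoss(fwd$logits, rep(1L, length(nodes)), 1)$probs
  score <- sm[, 2L]
  data.frame(node = nodes, score = score,
             label = ifelse(score >= threshold, "silencer", "non_silencer"),
             stringsAsFactors = FALSE)
}

#' Pre-classifier embeddings
#'
#' Returns the concatenated CNN + GraphSAGE representation of each node
#' (the vector fed to the MLP head), useful for separation analyses such as
#' the Davies-Bouldin index or low-dimensional visualization.
#'
#' @inheritParams predictREIN
#' @return Numeric matrix, one row per node.
#' @export
embedREIN <- function(fit, graph, features, nodes) {
  fwd <- evalForward(fit, graph, features, nodes)
  rownames(fwd$embed) <- nodes
  fwd$embed
}
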