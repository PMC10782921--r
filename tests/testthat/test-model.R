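test_that("single-node mean aggregation matches hand evaluation", {
  ## isolated node: mean of a singleton is itself
  expect_equal(sageAggregate(c(2, 4), NULL, diag(2)), c(2, 4))
  ## one neighbor: mean(2, 4) = 3
  expect_equal(sageAggregate(2, matrix(4), matrix(1)), 3)
  ## a self-loop neighbor equal to self leaves the mean unchanged
  expect_equal(sageAggregate(c(2, 4), cbind(c(2, 4)), diag(2)),
               sageAggregate(c(2, 4), NULL, diag(2)))
  ## activation applies after the linear map
  expect_equal(sageAggregate(c(-2, 2), NULL, diag(2), activation = function(x) pmax(x, 0)),
               c(0, 2))
  expect_error(sageAggregate(c(1, 2), matrix(1), diag(2)), "dimension")
  expect_error(sageAggregate(c(1, 2), NULL, matrix(1, 2, 3)), "columns")
})

test_that("graph aggregation equals a per-node mean oracle on random graphs", {
  ns <- asNamespace("rein")
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(5:20, 1L)
    nEdge <- sample(3:15, 1L)
    e <- cbind(sample(n, nEdge, replace = TRUE), sample(n, nEdge, replace = TRUE))
    e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    g <- makeGraph((seq_len(n) - 1L) * 1000L, 500L, edges = e)
    M <- ns$buildAggregation(g)
    H <- matrix(rnorm(n * 3L), n, 3L)
    W <- matrix(rnorm(12L), 4L, 3L)               # output dim 4, input dim 3
    agg <- as.matrix(M %*% H) %*% t(W)
    for (v in seq_len(n)) {
      nb <- c(e[e[, 1L] == v, 2L], e[e[, 2L] == v & e[, 1L] != v, 1L])
      oracle <- sageAggregate(H[v, ], if (length(nb)) t(H[nb, , drop = FALSE]),
                              W)
      expect_equal(unname(agg[v, ]), oracle, tolerance = 1e-6)
    }
  }
})

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("rein")
  cfg <- tinyConfig(dropout = 0)
  md <- makeModelData(nAll = 8L, nLab = 4L, seed = 11L)
  set.seed(11)
  params <- ns$initParams(cfg)
  ## make the zero head non-trivial so gradients flow everywhere
  params$mlpW2 <- matrix(rnorm(length(params$mlpW2), sd = 0.1),
                         nrow = nrow(params$mlpW2))
  X <- array(rnorm(5 * 32 * 3), dim = c(5, 32, 3))
  D <- md$features@descriptors[1:8, , drop = FALSE]
  M <- ns$buildAggregation(md$graph)[1:8, 1:8]
  batchIdx <- c(2L, 5L, 7L)
  y <- c(1L, 2L, 2L)
  lossOf <- function(p) {
    fwd <- ns$forwardModel(p, cfg, X, M, D, batchIdx, training = FALSE)
    ns$weightedCELoss(fwd$logits, y, cfg$classWeight)$loss
  }
  fwd <- ns$forwardModel(params, cfg, X, M, D, batchIdx, training = FALSE)
  ls <- ns$weightedCELoss(fwd$logits, y, cfg$classWeight)
  grads <- ns$backwardModel(params, cfg, fwd, ls$dlogits, M, 8L, batchIdx)
  set.seed(42)
  for (nm in names(params)) {
    if (nm == "convW1") next                      # layer-1 input grad unused
    for (ii in sample(length(params[[nm]]), min(5L, length(params[[nm]])))) {
      eps <- 1e-6
      p1 <- params; p1[[nm]][ii] <- p1[[nm]][ii] + eps
      p2 <- params; p2[[nm]][ii] <- p2[[nm]][ii] - eps
      num <- (lossOf(p1) - lossOf(p2)) / (2 * eps)
      rel <- abs(num - grads[[nm]][ii]) /
        max(1e-8, abs(num) + abs(grads[[nm]][ii]))
      expect_lt(rel, 1e-4)
    }
  }
  ## layer-1 weights checked too (only its input gradient is skipped)
  i1 <- 1L
  eps <- 1e-6
  p1 <- params; p1$convW1[i1] <- p1$convW1[i1] + eps
  p2 <- params; p2$convW1[i1] <- p2$convW1[i1] - eps
  num <- (lossOf(p1) - lossOf(p2)) / (2 * eps)
  expect_lt(abs(num - grads$convW1[i1]) / max(1e-8, abs(num)), 1e-4)
})

test_that("forward contract: shape, eval determinism, permutation equivariance", {
  md <- makeModelData(nAll = 16L, nLab = 10L, sep = 1, seed = 2L)
  cfg <- tinyConfig(maxEpochs = 2L)
  fit <- trainREIN(md$graph, md$features, md$dataset, cfg)
  pr <- predictREIN(fit, md$graph, md$features, md$ids)
  expect_equal(nrow(pr), 10L)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  ## eval mode is deterministic bit-for-bit
  pr2 <- predictREIN(fit, md$graph, md$features, md$ids)
  expect_identical(pr$score, pr2$score)
  ## permuting the node order permutes the outputs identically
  perm <- sample(length(md$ids))
  pr3 <- predictREIN(fit, md$graph, md$features, md$ids[perm])
  expect_equal(pr3$score, pr$score[perm])
  ## softmax scores complement to 1: score at threshold > 1 yields nothing
  pr4 <- predictREIN(fit, md$graph, md$features, md$ids, threshold = 1 + 1e-9)
  expect_true(all(pr4$label == "non_silencer"))
})

test_that("training is seed-reproducible and seed-sensitive", {
  md <- makeModelData(nAll = 16L, nLab = 10L, sep = 1, seed = 3L)
  cfg <- tinyConfig(maxEpochs = 3L)
  f1 <- trainREIN(md$graph, md$features, md$dataset, cfg)
  f2 <- trainREIN(md$graph, md$features, md$dataset, cfg)
  expect_identical(trainingHistory(f1)$loss, trainingHistory(f2)$loss)
  expect_identical(f1@params, f2@params)
  f3 <- trainREIN(md$graph, md$features, md$dataset, tinyConfig(maxEpochs = 3L, seed = 2L))
  expect_false(identical(trainingHistory(f1)$loss, trainingHistory(f3)$loss))
})

test_that("the learning rate decays by gamma exactly on training-loss rises", {
  md <- makeModelData(nAll = 16L, nLab = 10L, seed = 4L)   # pure noise
  cfg <- tinyConfig(maxEpochs = 12L, seed = 6L)
  fit <- trainREIN(md$graph, md$features, md$dataset, cfg)
  h <- trainingHistory(fit)
  expect_gt(nrow(h), 2L)
  ## a rise at epoch e+1 (relative to epoch e) decays the rate in force
  ## from epoch e+2 onward
  rose <- diff(h$loss) > 0
  expect_true(any(rose))                       # noise training must wobble
  for (e in seq_len(nrow(h) - 2L)) {
    if (rose[e]) {
      expect_equal(h$lr[e + 2L], h$lr[e + 1L] * cfg$gamma, tolerance = 1e-12)
    } else {
      expect_equal(h$lr[e + 2L], h$lr[e + 1L])
    }
  }
})

test_that("training requires both classes and survives an edgeless graph", {
  md <- makeModelData(nAll = 12L, nLab = 6L, seed = 5L)
  oneClass <- new("REINDataset", node = md$ids,
                  role = factor(rep("positive", 6L),
                                levels = c("positive", "negative")),
                  provenance = rep("x", 6L), component = rep(1L, 6L))
  expect_error(trainREIN(md$graph, md$features, oneClass, tinyConfig()),
               "both classes")
  ## isolated nodes: the aggregation reduces to per-node transforms
  bare <- initialize(md$graph, edges = matrix(integer(0), ncol = 2L))
  fit <- trainREIN(bare, md$features, md$dataset, tinyConfig(maxEpochs = 2L))
  expect_true(all(is.finite(trainingHistory(fit)$loss)))
})

test_that("swapping class labels swaps the learned decision on separable data", {
  md <- makeModelData(nAll = 24L, nLab = 16L, sep = 4, seed = 6L)
  cfg <- tinyConfig(maxEpochs = 30L, classWeight = 1, lr = 1e-3, dropout = 0)
  fit <- trainREIN(md$graph, md$features, md$dataset, cfg)
  sc <- predictREIN(fit, md$graph, md$features, md$ids)$score
  expect_gt(aurocScore(sc, md$y), 0.9)
  flipped <- new("REINDataset", node = md$ids,
                 role = factor(ifelse(md$y, "negative", "positive"),
                               levels = c("positive", "negative")),
                 provenance = rep("x", 16L), component = rep(1L, 16L))
  fitF <- trainREIN(md$graph, md$features, flipped, cfg)
  scF <- predictREIN(fitF, md$graph, md$features, md$ids)$score
  expect_gt(aurocScore(scF, !md$y), 0.9)
})

test_that("masking nodes removes them from message passing", {
  ns <- asNamespace("rein")
  md <- makeModelData(nAll = 10L, nLab = 6L, seed = 7L)
  mk <- ns$maskGraph(md$graph, md$features@descriptors, md$ids[1:2])
  expect_equal(unname(mk$D[1:2, ]), matrix(0, 2L, 4L), ignore_attr = TRUE)
  e <- mk$graph@edges
  expect_false(any(e %in% 1:2))
})
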