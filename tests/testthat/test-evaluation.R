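test_that("confusion metrics reproduce hand-computed values", {
  m <- confusionMetrics(TP = 50, TN = 50, FP = 0, FN = 0)
  expect_equal(unname(m), c(1, 1, 1, 1, 1, 1))
  m <- confusionMetrics(TP = 40, TN = 30, FP = 20, FN = 10)
  expect_equal(m[["Acc"]], 0.7)
  expect_equal(m[["Sen"]], 0.8)
  expect_equal(m[["Spe"]], 0.6)
  expect_equal(m[["PPV"]], 2 / 3, tolerance = 1e-6)
  expect_equal(m[["F1"]], 0.72727, tolerance = 1e-4)
  expect_equal(m[["MCC"]], 0.40825, tolerance = 1e-4)
})

test_that("zero denominators yield NaN with a warning, all-zero errors", {
  w <- capture_warnings(m <- confusionMetrics(TP = 0, TN = 30, FP = 0, FN = 10))
  expect_match(w, "PPV|F1|MCC", all = TRUE)
  expect_length(w, 3L)
  expect_true(is.nan(m[["PPV"]]))
  expect_true(is.nan(m[["F1"]]))
  expect_true(is.nan(m[["MCC"]]))
  expect_error(confusionMetrics(0, 0, 0, 0), "zero")
  expect_error(confusionMetrics(-1, 1, 1, 1), "non-negative")
})

test_that("MCC is flip-invariant and Sen/Spe swap under label flips", {
  m <- suppressWarnings(confusionMetrics(TP = 13, TN = 41, FP = 7, FN = 3))
  flip <- suppressWarnings(confusionMetrics(TP = 41, TN = 13, FP = 3, FN = 7))
  expect_equal(m[["MCC"]], flip[["MCC"]])
  expect_equal(m[["Sen"]], flip[["Spe"]])
  expect_equal(m[["Spe"]], flip[["Sen"]])
  expect_equal(m[["Acc"]], flip[["Acc"]])
})

test_that("rank-based AUROC equals the pairwise-comparison estimator", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(10:60, 1L)
    y <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2L, replace = TRUE))
    s <- sample(round(rnorm(n), 1L))           # coarse scores force ties
    expect_equal(aurocScore(s, y), aurocOracle(s, y), tolerance = 1e-9)
  }
  expect_error(aurocScore(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUPR behaves at the extremes", {
  y <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(auprScore(10:1, y), 1)
  expect_lt(auprScore(1:10, y), 0.5)
  set.seed(1)
  expect_gt(auprScore(rnorm(200), rep(c(TRUE, FALSE), 100)), 0.3)
})

test_that("repeated CV with a perfect oracle scorer is exact", {
  md <- makeModelData(nAll = 40L, nLab = 40L, seed = 8L)
  oracle <- function(trainNodes, trainY, testNodes)
    as.numeric(md$y[match(testNodes, md$ids)])
  cv <- repeatedCV(md$dataset, k = 5L, reps = 3L, seed = 4L, trainer = oracle)
  expect_equal(cv$summary$mean[cv$summary$metric == "AUROC"], 1)
  expect_equal(cv$summary$sd[cv$summary$metric == "AUROC"], 0)
  expect_equal(cv$summary$mean[cv$summary$metric == "Acc"], 1)
})

test_that("repeated CV with random scores sits at chance on balanced labels", {
  set.seed(10)
  n <- 1000L
  nodes <- sprintf("n%06d", seq_len(n))
  ds <- new("REINDataset", node = nodes,
            role = factor(rep(c("positive", "negative"), n / 2L),
                          levels = c("positive", "negative")),
            provenance = rep("x", n), component = rep(1L, n))
  rng <- function(trainNodes, trainY, testNodes) runif(length(testNodes))
  cv <- repeatedCV(ds, k = 5L, reps = 5L, seed = 21L, trainer = rng)
  auroc <- cv$summary$mean[cv$summary$metric == "AUROC"]
  expect_gt(auroc, 0.45)
  expect_lt(auroc, 0.55)
})

test_that("repeated CV is deterministic given its seed and supports folds", {
  md <- makeModelData(nAll = 30L, nLab = 30L, seed = 9L)
  rng <- function(trainNodes, trainY, testNodes) {
    seq_along(testNodes) / length(testNodes)
  }
  cv1 <- repeatedCV(md$dataset, k = 3L, reps = 2L, seed = 5L, trainer = rng)
  cv2 <- repeatedCV(md$dataset, k = 3L, reps = 2L, seed = 5L, trainer = rng)
  expect_identical(cv1$perRep, cv2$perRep)
  cvf <- repeatedCV(md$dataset, k = 3L, reps = 2L, seed = 5L, trainer = rng,
                    level = "fold")
  expect_equal(nrow(cvf$perRep), 6L)           # k folds x reps rows
  ## stratification guard: a class smaller than k cannot be split
  tiny <- new("REINDataset", node = md$ids[1:4],
              role = factor(c("positive", rep("negative", 3L)),
                            levels = c("positive", "negative")),
              provenance = rep("x", 4L), component = rep(1L, 4L))
  expect_error(repeatedCV(tiny, k = 3L, reps = 1L, trainer = rng),
               "fewer members than folds")
})

test_that("Davies-Bouldin follows the population-variance formula", {
  ## singleton sets have zero spread
  expect_equal(daviesBouldin(rbind(c(0, 0)), rbind(c(1, 0))), 0)
  ## hand-evaluated example: v = 1 each, center distance^2 = 100
  expect_equal(daviesBouldin(rbind(c(0, 0), c(2, 0)),
                             rbind(c(10, 0), c(12, 0))), 0.02)
  ## scale invariance: numerator and denominator both scale by c^2
  set.seed(2)
  p <- matrix(rnorm(40), 10); n <- matrix(rnorm(40, mean = 2), 10)
  expect_equal(daviesBouldin(p, n), daviesBouldin(3.7 * p, 3.7 * n))
  ## separation index decreases as the centers move apart at fixed spread
  d <- vapply(c(2, 4, 8, 16), function(sep)
    daviesBouldin(p, sweep(n, 2, sep, `+`)), numeric(1))
  expect_true(all(diff(d) < 0))
  expect_error(daviesBouldin(p, p), "identical centers")
  expect_error(daviesBouldin(p, matrix(1, 2, 5)), "dimension")
})

test_that("motif enrichment scores are negative log relative frequencies", {
  expect_equal(unname(motifEnrichmentScores(c(m = 5))), 0)
  expect_equal(unname(motifEnrichmentScores(c(a = 1, b = 1))),
               c(log(2), log(2)))
  e <- motifEnrichmentScores(c(a = 1, b = 3))
  expect_equal(unname(e), c(log(4), -log(0.75)), tolerance = 1e-9)
  expect_equal(unname(e), c(1.3863, 0.2877), tolerance = 1e-4)
  expect_warning(e0 <- motifEnrichmentScores(c(a = 2, b = 0)), "zero matches")
  expect_identical(names(e0), "a")
  expect_error(motifEnrichmentScores(c(0, 0)), "positive")
  expect_error(motifEnrichmentScores(c(-1, 2)), "non-negative")
})

test_that("APA scores match direct computation on constructed windows", {
  flat <- matrix(1, 11, 11)
  expect_equal(unname(apaScores(list(flat), scores = "P2LL")), 1)
  expect_error(apaScores(list(flat)), "standard deviation is zero")
  ## center 10 over a corner block of 2s: P2LL = 5
  w <- matrix(2, 11, 11)
  w[6, 6] <- 10
  w[1, 1] <- 7                                  # far from the lower-left block
  s <- apaScores(list(w), corner = 3, scores = "P2LL")
  expect_equal(unname(s["P2LL"]), 5)
  ## corner {1,3} alternating: mean 2, population sd 1, center 4 -> Z = 2
  w2 <- matrix(0, 11, 11)
  w2[6, 6] <- 4
  w2[9:11, 1:3] <- rep(c(1, 3), length.out = 9)
  w2[9:11, 1:3][9] <- 2                         # force mean 2, sd 1 exactly
  corner <- w2[9:11, 1:3]
  mu <- mean(corner); sdp <- sqrt(mean((corner - mu)^2))
  s2 <- apaScores(list(w2), corner = 3)
  expect_equal(unname(s2["ZscoreLL"]), (4 - mu) / sdp)
  ## aggregation linearity: a stack equals its precomputed mean window
  set.seed(5)
  stack <- lapply(1:7, function(i) matrix(rnorm(121, mean = 1), 11, 11))
  avg <- Reduce(`+`, stack) / 7
  expect_equal(apaScores(stack, corner = 3), apaScores(list(avg), corner = 3))
  ## geometry validation
  expect_error(apaScores(list(matrix(1, 10, 10))), "odd")
  expect_error(apaScores(list(matrix(1, 11, 11)), corner = 6), "half")
  expect_error(apaScores(list()), "empty")
})

test_that("ablation modes reshape the inputs as documented", {
  md <- makeModelData(nAll = 10L, nLab = 6L, seed = 12L)
  full <- ablate(md$features, md$graph, "full")
  expect_identical(full$features@descriptors, md$features@descriptors)
  expect_identical(full$graph@edges, md$graph@edges)
  lin <- ablate(md$features, md$graph, "linear_only")
  expect_true(all(lin$features@descriptors == 0))
  expect_equal(nrow(lin$graph@edges), 0L)
  expect_identical(lin$features@linear, md$features@linear)
  top <- ablate(md$features, md$graph, "topology_only")
  expect_true(all(top$features@linear == 0))
  expect_identical(top$features@descriptors, md$features@descriptors)
  expect_error(ablate(md$features, md$graph, "nope"))
})

test_that("the Welch comparison utility returns a two-sided t-test", {
  set.seed(6)
  ht <- compareAUROC(rnorm(5, 0.79, 0.01), rnorm(5, 0.75, 0.01))
  expect_s3_class(ht, "htest")
  expect_match(ht$method, "Welch")
  expect_identical(ht$alternative, "two.sided")
})
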