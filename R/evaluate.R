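#' Confusion-matrix point metrics
#'
#' Computes accuracy, sensitivity (recall), specificity, positive
#' predictive value (precision), F1 and the Matthews correlation
#' coefficient from confusion counts.  Any metric with a zero denominator
#' is reported as `NaN` with a warning rather than silently coerced to 0.
#'
#' @param TP,TN,FP,FN Non-negative integer counts; their sum must be
#'   positive.
#' @return Named numeric vector with elements `Acc`, `Sen`, `Spe`, `PPV`,
#'   `F1`, `MCC`.
#' @examples
#' confusionMetrics(TP = 40, TN = 30, FP = 20, FN = 10)
#' @export
confusionMetrics <- function(TP, TN, FP, FN) {
  TP <- unname(TP); TN <- unname(TN); FP <- unname(FP); FN <- unname(FN)
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0)) stopf("confusion counts must be non-negative")
  if (sum(counts) == 0) stopf("all confusion counts are zero")
  ratio <- function(num, den, name) {
    if (den == 0) {
      warnf("%s undefined (zero denominator); reported as NaN", name)
      return(NaN)
    }
    num / den
  }
  acc <- (TP + TN) / sum(counts)
  sen <- ratio(TP, TP + FN, "Sen")
  spe <- ratio(TN, TN + FP, "Spe")
  ppv <- ratio(TP, TP + FP, "PPV")
  f1 <- if (is.nan(ppv) || is.nan(sen) || (ppv + sen) == 0) {
    warnf("F1 undefined; reported as NaN")
    NaN
  } else 2 * ppv * sen / (ppv + sen)
  mccDen <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
    sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
  mcc <- if (mccDen == 0) {
    warnf("MCC undefined (zero denominator); reported as NaN")
    NaN
  } else (as.numeric(TP) * TN - as.numeric(FN) * FP) / mccDen
  c(Acc = acc, Sen = sen, Spe = spe, PPV = ppv, F1 = f1, MCC = mcc)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator with midrank tie handling: ties
#' between a positive and a negative score contribute 1/2.
#'
#' @param scores Numeric scores, larger meaning more silencer-like.
#' @param labels Logical or 0/1 vector, `TRUE`/1 for positives.
#' @return AUROC in `[0, 1]`.
#' @export
aurocScore <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stopf("both classes needed for AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Trapezoidal area over the precision-recall points obtained at every
#' distinct score threshold (tied scores enter as one threshold step).
#'
#' @inheritParams aurocScore
#' @return AUPR in `[0, 1]`.
#' @export
auprScore <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  if (n1 == 0L || sum(!labels) == 0L) stopf("both classes needed for AUPR")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  recall <- c(0, tp / n1)
  precision <- c(1, tp / (tp + fp))
  sum(diff(recall) * (head(precision, -1L) + tail(precision, -1L)) / 2)
}

#' Welch t-test between two sets of per-repetition metric values
#'
#' Report utility for method comparisons on repeated cross-validation
#' results (e.g. per-repetition AUROC), two-tailed, unequal variances.
#'
#' @param a,b Numeric vectors of per-repetition metric values.
#' @return The `htest` object from [stats::t.test()].
#' @export
compareAUROC <- function(a, b) {
  t.test(a, b, alternative = "two.sided", var.equal = FALSE)
}

stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    ic <- sample(which(y == cls))
    fold[ic] <- rep_len(seq_len(k), length(ic))
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs `reps` independent stratified `k`-fold partitions (distinct seeds),
#' trains a scorer on each training fold and scores the held-out fold.
#' Fold-level confusion metrics (threshold 0.5) and curve areas are pooled
#' to one value per repetition (default) or kept per fold, then summarized
#' as mean and sample standard deviation across repetitions.
#'
#' The default trainer fits the full hybrid model; any function
#' `f(trainData, testData)` returning held-out scores can be substituted
#' (e.g. reference scorers in benchmarking).
#'
#' @param dataset A [REINDataset-class].
#' @param graph A [REINGraph-class] (passed to the default trainer).
#' @param features A [REINFeatures-class] (passed to the default trainer).
#' @param config A [reinConfig()] list for the default trainer.
#' @param k Number of folds (default 5).
#' @param reps Number of repetitions (default 5).
#' @param seed Base seed; repetition `r` uses a seed derived from it.
#' @param trainer Optional scorer `function(trainNodes, trainY, testNodes)`
#'   returning a numeric score per test node (`trainY` is logical,
#'   `TRUE` = silencer).  Defaults to training the hybrid model.
#' @param level `"rep"` (default) to compute metrics on each repetition's
#'   pooled out-of-fold scores, or `"fold"` for per-fold metrics.
#' @param maskTestNodes If `TRUE`, held-out nodes are removed from message
#'   passing during training (stricter inductive evaluation).
#' @return List with `perRep` (`data.frame` of metric values, one row per
#'   repetition or fold) and `summary` (mean and sd per metric).
#' @export
repeatedCV <- function(dataset, graph = NULL, features = NULL,
                       config = reinConfig(), k = 5L, reps = 5L, seed = 1L,
                       trainer = NULL, level = c("rep", "fold"),
                       maskTestNodes = FALSE) {
  level <- match.arg(level)
  stopifnot(k >= 2L)
  nodes <- dataset@node
  y <- dataset@role == "positive"
  if (!any(y) || all(y)) stopf("dataset must contain both classes")
  if (is.null(trainer)) {
    if (is.null(graph) || is.null(features))
      stopf("graph and features are required for the default trainer")
    trainer <- function(trainNodes, trainY, testNodes) {
      sub <- new("REINDataset", node = trainNodes,
                 role = factor(ifelse(trainY, "positive", "negative"),
                               levels = c("positive", "negative")),
                 provenance = rep("cv", length(trainNodes)),
                 component = rep(NA_integer_, length(trainNodes)))
      fit <- trainREIN(graph, features, sub, config,
                       maskNodes = if (maskTestNodes) testNodes else character(0))
      predictREIN(fit, graph, features, testNodes)$score
    }
  }
  rows <- list()
  for (r in seq_len(reps)) {
    repSeed <- childSeed(seed, r)
    withSeed(repSeed, {
      fold <- stratifiedFolds(y, k)
      ## guard: every fold must contain both classes (guaranteed by
      ## stratification when each class has >= k members; re-draw otherwise)
      tries <- 0L
      while (any(vapply(seq_len(k), function(f)
        length(unique(y[fold == f])) < 2L, logical(1L)))) {
        tries <- tries + 1L
        if (tries > 100L) stopf("cannot stratify: a class has fewer members than folds")
        fold <- stratifiedFolds(y, k)
      }
      scores <- numeric(length(nodes))
      for (f in seq_len(k)) {
        te <- fold == f
        scores[te] <- trainer(nodes[!te], y[!te], nodes[te])
        if (level == "fold") {
          cm <- confusionTable(scores[te], y[te])
          rows[[length(rows) + 1L]] <- c(rep = r, fold = f,
                                          metricRow(cm, scores[te], y[te]))
        }
      }
      if (level == "rep") {
        cm <- confusionTable(scores, y)
        rows[[length(rows) + 1L]] <- c(rep = r, fold = NA,
                                        metricRow(cm, scores, y))
      }
    })
  }
  perRep <- as.data.frame(do.call(rbind, rows))
  metricCols <- setdiff(names(perRep), c("rep", "fold"))
  summary <- data.frame(metric = metricCols,
                        mean = vapply(perRep[metricCols], mean, numeric(1L)),
                        sd = vapply(perRep[metricCols], sd, numeric(1L)),
                        row.names = NULL)
  list(perRep = perRep, summary = summary)
}

confusionTable <- function(scores, y, threshold = 0.5) {
  pred <- scores >= threshold
  c(TP = sum(pred & y), TN = sum(!pred & !y), FP = sum(pred & !y),
    FN = sum(!pred & y))
}

metricRow <- function(cm, scores, y) {
  pm <- suppressWarnings(confusionMetrics(cm["TP"], cm["TN"], cm["FP"], cm["FN"]))
  c(pm, AUROC = aurocScore(scores, y), AUPR = auprScore(scores, y))
}

#' Davies-Bouldin separation index for two vector sets
#'
#' `d = (v(T+) + v(T-)) / |m(T+) - m(T-)|^2` where `m` is the centroid and
#' `v` the mean squared Euclidean deviation from the centroid (population
#' form, dividing by n).  Smaller values indicate better separation.
#'
#' @param positiveVectors,negativeVectors Numeric matrices, one vector per
#'   row, equal column count.
#' @return A single non-negative number.
#' @examples
#' daviesBouldin(rbind(c(0, 0), c(2, 0)), rbind(c(10, 0), c(12, 0)))  # 0.02
#' @export
daviesBouldin <- function(positiveVectors, negativeVectors) {
  p <- as.matrix(positiveVectors); n <- as.matrix(negativeVectors)
  if (nrow(p) == 0L || nrow(n) == 0L) stopf("both sets must be non-empty")
  if (ncol(p) != ncol(n)) stopf("vector sets must have the same dimension")
  mp <- colMeans(p); mn <- colMeans(n)
  sep <- sum((mp - mn)^2)
  if (sep == 0) stopf("identical centers: separation undefined")
  vp <- mean(rowSums(sweep(p, 2L, mp)^2))
  vn <- mean(rowSums(sweep(n, 2L, mn)^2))
  (vp + vn) / sep
}

#' Motif enrichment scores
#'
#' For motif match counts `c_1..c_m` over a region set, the enrichment
#' score of motif k is `e_k = -ln(c_k / sum_j c_j)`: the negative log
#' relative frequency among all matches.  Motifs with zero matches have an
#' infinite score and are omitted with a warning.
#'
#' @param matchCounts Named non-negative numeric vector of match counts
#'   with positive sum.
#' @return Named numeric vector of scores for motifs with at least one
#'   match.
#' @examples
#' motifEnrichmentScores(c(a = 1, b = 3))   # ln(4), -ln(0.75)
#' @export
motifEnrichmentScores <- function(matchCounts) {
  if (any(matchCounts < 0)) stopf("match counts must be non-negative")
  total <- sum(matchCounts)
  if (total <= 0) stopf("total match count must be positive")
  zero <- matchCounts == 0
  if (any(zero)) {
    warnf("omitting %d motif(s) with zero matches (infinite score)", sum(zero))
    matchCounts <- matchCounts[!zero]
  }
  -log(matchCounts / total)
}

#' Aggregate peak analysis scores
#'
#' Element-wise mean of a stack of square, odd-sided contact submatrices
#' centered on locus pairs, then two enrichment scores on the aggregated
#' window: `P2LL`, the ratio of the central pixel to the mean of the
#' `corner x corner` block at the lower-left of the window, and
#' `ZscoreLL`, the z-score of the central pixel against that block
#' (population standard deviation).
#'
#' @param windowStack A list of equal-sized square matrices with odd side,
#'   or a 3-d array with the stack along the third dimension.
#' @param corner Corner block side; defaults to `floor(side / 4)` with a
#'   minimum of 3, and must stay below half the window side.
#' @param scores Which scores to compute (both by default); a score whose
#'   denominator degenerates (zero corner mean for P2LL, zero corner
#'   standard deviation for ZscoreLL) raises an error only when requested.
#' @return Named numeric vector of the requested scores.
#' @export
apaScores <- function(windowStack, corner = NULL,
                      scores = c("P2LL", "ZscoreLL")) {
  scores <- match.arg(scores, several.ok = TRUE)
  if (is.array(windowStack) && length(dim(windowStack)) == 3L) {
    windowStack <- lapply(seq_len(dim(windowStack)[3L]),
                          function(i) windowStack[, , i])
  }
  if (length(windowStack) == 0L) stopf("empty window stack")
  dims <- vapply(windowStack, function(m) dim(m), integer(2L))
  side <- dims[1L, 1L]
  if (any(dims != side)) stopf("all windows must be square with equal side")
  if (side %% 2L == 0L) stopf("window side must be odd")
  if (is.null(corner)) corner <- max(3L, side %/% 4L)
  if (corner >= side / 2) stopf("corner block must be smaller than half the side")
  agg <- Reduce(`+`, windowStack) / length(windowStack)
  c0 <- (side + 1L) %/% 2L
  center <- agg[c0, c0]
  block <- agg[(side - corner + 1L):side, 1L:corner]
  mu <- mean(block)
  sigma <- sqrt(mean((block - mu)^2))
  out <- numeric(0)
  if ("P2LL" %in% scores) {
    if (mu == 0) stopf("corner mean is zero: P2LL undefined")
    out <- c(out, P2LL = center / mu)
  }
  if ("ZscoreLL" %in% scores) {
    if (sigma == 0)
      stopf("corner standard deviation is zero: ZscoreLL undefined")
    out <- c(out, ZscoreLL = (center - mu) / sigma)
  }
  out
}

#' Ablate one input branch
#'
#' Produces the feature/graph view for the three evaluation conditions:
#' `"full"` leaves the inputs untouched; `"linear_only"` feeds the network
#' branch zero descriptors on an edgeless graph; `"topology_only"` zeroes
#' the linear feature tensor.
#'
#' @param features A [REINFeatures-class].
#' @param graph A [REINGraph-class].
#' @param mode One of `"full"`, `"linear_only"`, `"topology_only"`.
#' @return List with elements `features` and `graph`.
#' @export
ablate <- function(features, graph, mode = c("full", "linear_only",
                                             "topology_only")) {
  mode <- match.arg(mode)
  if (mode == "linear_only") {
    features@descriptors[] <- 0
    graph <- initialize(graph, edges = matrix(integer(0), ncol = 2L))
  } else if (mode == "topology_only") {
    features@linear[] <- 0
  }
  list(features = features, graph = graph)
}
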