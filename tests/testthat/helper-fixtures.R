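labelLevels <- c("silencer", "non_silencer", "enhancer", "promoter", "unlabeled")

makeNodes <- function(starts0, widths, chrom = "chr1", labels = "unlabeled",
                      component = NA_integer_) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts0 + 1L,
                                                       width = widths))
  names(gr) <- sprintf("n%06d", seq_along(gr))
  gr$label <- factor(rep_len(labels, length(gr)), levels = labelLevels)
  gr$component <- rep_len(as.integer(component), length(gr))
  gr
}

makeGraph <- function(starts0, widths, edges = matrix(integer(0), ncol = 2L),
                      ...) {
  new("REINGraph", nodes = makeNodes(starts0, widths, ...),
      edges = if (is.matrix(edges)) edges else matrix(edges, ncol = 2L,
                                                      byrow = TRUE))
}

makeLoops <- function(startsA0, widthsA, startsB0, widthsB, chrom = "chr1",
                      support = NULL) {
  a <- GenomicRanges::GRanges(chrom, IRanges::IRanges(startsA0 + 1L, width = widthsA))
  b <- GenomicRanges::GRanges(chrom, IRanges::IRanges(startsB0 + 1L, width = widthsB))
  if (is.null(support)) support <- rep(NA_integer_, length(a))
  S4Vectors::Pairs(a, b, support = support)
}

## Brute-force fixpoint oracle for anchor merging: repeatedly merge any two
## overlapping intervals until none overlap.  Intervals as 0-based [s, e).
mergeOracle <- function(s, e) {
  repeat {
    n <- length(s)
    merged <- FALSE
    for (i in seq_len(n - 1L)) {
      if (merged) break
      for (j in (i + 1L):n) {
        if (s[i] < e[j] && s[j] < e[i]) {   # strict overlap
          s[i] <- min(s[i], s[j]); e[i] <- max(e[i], e[j])
          s <- s[-j]; e <- e[-j]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  ord <- order(s)
  list(s = s[ord], e = e[ord])
}

## Pairwise-comparison AUROC estimator: P(score+ > score-) + 0.5 P(tie).
aurocOracle <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

## Down-sized model configuration for fast unit tests.
tinyConfig <- function(...) {
  base <- list(inChannels = 5L, seqLen = 32L, cnnChannels = c(6L, 6L),
               kernel = 3L, pool = 2L, descriptorDim = 4L,
               sageChannels = c(6L, 6L), mlp = c(8L, 2L), batchSize = 8L,
               valFraction = 0, dropout = 0.2, maxEpochs = 3L, seed = 1L)
  do.call(reinConfig, utils::modifyList(base, list(...)))
}

## Small synthetic model inputs built directly in memory: a chain graph,
## random tiny linear features and descriptors, with an optional planted
## class shift on the first channel / first descriptor column.
makeModelData <- function(nAll = 20L, nLab = 12L, sep = 0, seed = 1L) {
  set.seed(seed)
  nodes <- makeNodes(starts0 = (seq_len(nAll) - 1L) * 1000L, widths = 500L)
  g <- new("REINGraph", nodes = nodes,
           edges = cbind(seq_len(nAll - 1L), seq_len(nAll - 1L) + 1L))
  ids <- names(nodes)[seq_len(nLab)]
  y <- rep(c(TRUE, FALSE), length.out = nLab)
  lin <- array(rnorm(5L * 32L * nLab), dim = c(5L, 32L, nLab),
               dimnames = list(NULL, NULL, ids))
  lin[1L, , y] <- lin[1L, , y] + sep
  desc <- matrix(rnorm(nAll * 4L), nAll, 4L,
                 dimnames = list(names(nodes), NULL))
  desc[match(ids[y], names(nodes)), 1L] <-
    desc[match(ids[y], names(nodes)), 1L] + sep
  feats <- new("REINFeatures", linear = lin, linearNodes = ids,
               descriptors = desc, trackNames = "trackA")
  ds <- new("REINDataset", node = ids,
            role = factor(ifelse(y, "positive", "negative"),
                          levels = c("positive", "negative")),
            provenance = rep("synthetic", nLab),
            component = rep(1L, nLab))
  list(graph = g, features = feats, dataset = ds, y = y, ids = ids)
}

## One small on-disk fixture shared across test files (generated once per
## session).
.fxCache <- new.env(parent = emptyenv())
smallFixture <- function() {
  if (is.null(.fxCache$fx)) {
    d <- file.path(tempdir(), "rein-shared-fixture")
    spec <- fixtureSpec(nChroms = 2L, chromLength = 5e5, nLoops = 300L,
                        nElements = c(silencer = 40L, non_silencer = 15L,
                                      enhancer = 15L, promoter = 60L),
                        seed = 7L)
    .fxCache$fx <- generateFixture(spec, d)
    .fxCache$fx$dir <- d
  }
  .fxCache$fx
}
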