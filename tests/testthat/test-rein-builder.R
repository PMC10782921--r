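test_that("loop filtering keeps only loops with both anchors strictly short", {
  loops <- makeLoops(c(0L, 2000L, 6000L), c(800L, 1000L, 1200L),
                     c(10000L, 14000L, 20000L), c(950L, 500L, 1200L))
  kept <- filterLoops(loops, maxAnchorLen = 1000L)
  expect_length(kept, 1L)
  expect_equal(GenomicRanges::width(S4Vectors::first(kept)), 800L)
})

test_that("anchor merging is the connected-overlap closure", {
  ## two overlapping anchors merge to their union
  m <- mergeAnchors(makeNodes(c(100L, 600L), c(600L, 600L)))
  expect_equal(GenomicRanges::start(m$merged) - 1L, 100L)
  expect_equal(GenomicRanges::end(m$merged), 1200L)
  ## an overlap chain whose ends are disjoint still merges to one interval
  m <- mergeAnchors(makeNodes(c(0L, 90L, 190L), c(100L, 110L, 110L)))
  expect_length(m$merged, 1L)
  expect_equal(GenomicRanges::end(m$merged), 300L)
  expect_equal(m$map, c(1L, 1L, 1L))
  ## disjoint anchors pass through; abutting intervals are NOT merged
  m <- mergeAnchors(makeNodes(c(0L, 200L), c(100L, 100L)))
  expect_length(m$merged, 2L)
  m <- mergeAnchors(makeNodes(c(0L, 100L), c(100L, 100L)))
  expect_length(m$merged, 2L)
})

test_that("anchor merging equals the brute-force fixpoint oracle", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:25, 1L)
    s <- sample(0:400, n, replace = TRUE)
    w <- sample(1:80, n, replace = TRUE)
    m <- mergeAnchors(makeNodes(s, w))
    o <- mergeOracle(s, s + w)
    expect_equal(GenomicRanges::start(m$merged) - 1L, o$s)
    expect_equal(GenomicRanges::end(m$merged), o$e)
    ## every anchor maps to a merged interval covering it
    expect_true(all(GenomicRanges::start(m$merged)[m$map] <= s + 1L &
                      GenomicRanges::end(m$merged)[m$map] >= s + w))
  }
})

test_that("graph construction merges anchors into nodes and dedupes edges", {
  ## two loops sharing no overlapping anchors: 4 nodes, 2 edges
  g <- buildREIN(makeLoops(c(0L, 10000L), 500L, c(5000L, 15000L), 500L))
  expect_length(g, 4L)
  expect_equal(nrow(reinEdges(g)), 2L)
  ## a loop whose two anchors overlap each other: 1 node with a self-loop
  g <- buildREIN(makeLoops(0L, 600L, 400L, 600L))
  expect_length(g, 1L)
  expect_equal(reinEdges(g), cbind(1L, 1L))
  ## two loops connecting the same merged pair collapse to one edge
  g <- buildREIN(makeLoops(c(0L, 100L), 500L, c(5000L, 5100L), 500L))
  expect_length(g, 2L)
  expect_equal(nrow(reinEdges(g)), 1L)
  ## node intervals never overlap after a build (validity enforces this)
  expect_true(validObject(g))
})

test_that("element normalization recenters to fixed windows and clamps at 0", {
  e <- makeNodes(1000L, 1000L)                       # [1000, 2000)
  n <- normalizeElements(e)
  expect_equal(GenomicRanges::start(n) - 1L, 1200L)
  expect_equal(GenomicRanges::end(n), 1800L)
  expect_equal(GenomicRanges::width(n), 600L)
  ## a 1-nt element near the start clamps with a warning
  expect_warning(n <- normalizeElements(makeNodes(100L, 1L)), "clamped")
  expect_equal(GenomicRanges::start(n) - 1L, 0L)
  expect_equal(GenomicRanges::end(n), 400L)
  ## identity when already a centered 600-nt window
  n <- normalizeElements(makeNodes(0L, 600L))
  expect_equal(GenomicRanges::start(n) - 1L, 0L)
  expect_equal(GenomicRanges::end(n), 600L)
})

test_that("label assignment uses strict overlap and the class priority", {
  g <- makeGraph(0L, 600L)                            # node [0, 600)
  ## overlap 350 labels; overlap exactly 300 does not
  el <- makeNodes(250L, 600L, labels = "silencer")
  expect_identical(as.character(reinLabels(assignLabels(g, el))), "silencer")
  el <- makeNodes(300L, 600L, labels = "silencer")
  expect_identical(as.character(reinLabels(assignLabels(g, el))), "unlabeled")
  ## silencer outranks promoter regardless of overlap size
  el <- c(makeNodes(100L, 600L, labels = "promoter"),    # overlap 500
          makeNodes(250L, 600L, labels = "silencer"))    # overlap 350
  expect_identical(as.character(reinLabels(assignLabels(g, el))), "silencer")
  ## priority is order-sensitive: enhancer beats promoter the same way
  el <- c(makeNodes(100L, 600L, labels = "promoter"),
          makeNodes(150L, 600L, labels = "enhancer"))
  expect_identical(as.character(reinLabels(assignLabels(g, el))), "enhancer")
})

test_that("an element spanning two abutting nodes labels the larger overlap", {
  g <- makeGraph(c(0L, 600L), c(600L, 600L))
  ## window [250, 850): overlap 350 with node 1, 250 with node 2
  el <- makeNodes(250L, 600L, labels = "silencer")
  lab <- as.character(reinLabels(assignLabels(g, el, minOverlap = 200L)))
  expect_identical(lab, c("silencer", "unlabeled"))
})

test_that("component extraction keeps strictly-large components only", {
  ## chain of 6 plus chain of 3, threshold 5: only the 6-chain survives
  g <- makeGraph((0:8) * 1000L, 500L,
                 edges = rbind(cbind(1:5, 2:6), cbind(7:8, 8:9)))
  out <- extractComponents(g, minSize = 5L)
  expect_length(out, 6L)
  expect_equal(unname(reinComponents(out)), rep(1L, 6L))
  ## a component of exactly minSize nodes is dropped
  out <- extractComponents(g, minSize = 6L)
  expect_length(out, 0L)
  ## component node counts sum to the retained node count
  out <- extractComponents(g, minSize = 2L)
  expect_equal(sum(table(reinComponents(out))), length(out))
  ## edges are reindexed against the surviving nodes
  expect_true(all(reinEdges(out) >= 1L & reinEdges(out) <= length(out)))
})

test_that("negative sampling follows the per-component floor(10%) rule", {
  labs <- c(rep("silencer", 3L),
            rep("non_silencer", 5L), rep("enhancer", 7L),
            rep("promoter", 40L),                      # component 1
            rep("promoter", 25L))                      # component 2
  comp <- c(rep(1L, 55L), rep(2L, 25L))
  g <- makeGraph((0:79) * 1000L, 500L, labels = labs, component = comp)
  ds <- sampleNegatives(g, promoterFraction = 0.10, seed = 9L)
  expect_length(positives(ds), 3L)
  prov <- datasetTable(ds)
  negs <- prov[prov$role == "negative", ]
  expect_equal(sum(negs$provenance == "non_silencer"), 5L)
  expect_equal(sum(negs$provenance == "enhancer"), 7L)
  ## floor(0.10 * 40) = 4 from component 1, floor(0.10 * 25) = 2 from comp 2
  expect_equal(sum(negs$provenance == "promoter_sampled" & negs$component == 1L), 4L)
  expect_equal(sum(negs$provenance == "promoter_sampled" & negs$component == 2L), 2L)
  expect_length(negatives(ds), 5L + 7L + 4L + 2L)
  ## positives and negatives never intersect; sampling is seed-reproducible
  expect_length(intersect(positives(ds), negatives(ds)), 0L)
  ds2 <- sampleNegatives(g, promoterFraction = 0.10, seed = 9L)
  expect_identical(datasetTable(ds), datasetTable(ds2))
  ds3 <- sampleNegatives(g, promoterFraction = 0.10, seed = 10L)
  expect_false(identical(negatives(ds), negatives(ds3)))
})

test_that("a component with no promoters contributes fixed negatives only", {
  g <- makeGraph((0:4) * 1000L, 500L,
                 labels = c("silencer", "non_silencer", "enhancer",
                            "enhancer", "unlabeled"),
                 component = 1L)
  ds <- sampleNegatives(g, seed = 1L)
  expect_length(negatives(ds), 3L)
  expect_false(any(datasetTable(ds)$provenance == "promoter_sampled"))
})

test_that("graph JSON serialization round-trips", {
  fx <- smallFixture()
  g <- buildREIN(filterLoops(readBedpe(fx$paths$loops)))
  g <- assignLabels(g, normalizeElements(readBedElements(fx$paths$elements)))
  g <- extractComponents(g, minSize = 50L)
  p <- withr::local_tempfile(fileext = ".json")
  writeREIN(g, p)
  back <- readREIN(p)
  expect_identical(names(reinNodes(back)), names(reinNodes(g)))
  expect_identical(GenomicRanges::start(reinNodes(back)),
                   GenomicRanges::start(reinNodes(g)))
  expect_identical(as.character(reinLabels(back)), as.character(reinLabels(g)))
  expect_identical(reinEdges(back), reinEdges(g))
  expect_identical(unname(reinComponents(back)), unname(reinComponents(g)))
})
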