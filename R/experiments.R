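## Canned synthetic experiments: the study protocols used to validate the
## method end-to-end.  Each generates its fixture, runs the pipeline and
## returns the headline numbers; sizes and epoch budgets are the package's
## documented evaluation protocol (see the methods vignette).

## Train on a stratified split of a prepared dataset and score the held-out
## nodes (shared by reinPipeline and the ablation experiment).
fitAndScore <- function(graph, features, dataset, config, trainFraction = 0.7) {
  y <- dataset@role == "positive"
  idx <- withSeed(childSeed(config$seed, 202L), {
    tr <- integer(0)
    for (cls in c(TRUE, FALSE)) {
      ic <- which(y == cls)
      tr <- c(tr, sample(ic, round(trainFraction * length(ic))))
    }
    sort(tr)
  })
  sub <- new("REINDataset", node = dataset@node[idx],
             role = droplevels2(dataset@role[idx]),
             provenance = dataset@provenance[idx],
             component = dataset@component[idx])
  fit <- trainREIN(graph, features, sub, config)
  testNodes <- dataset@node[-idx]
  prediction <- predictREIN(fit, graph, features, testNodes)
  yTest <- y[-idx]
  cm <- confusionTable(prediction$score, yTest)
  metrics <- c(suppressWarnings(confusionMetrics(cm["TP"], cm["TN"], cm["FP"],
                                                 cm["FN"])),
               AUROC = aurocScore(prediction$score, yTest),
               AUPR = auprScore(prediction$score, yTest))
  list(fit = fit, trainNodes = dataset@node[idx], testNodes = testNodes,
       prediction = prediction, metrics = metrics)
}

#' Planted-effect recovery experiment
#'
#' Generates the default synthetic benchmark (2 chromosomes x 2 Mb, 1500
#' loops, 150 silencers and mixed negatives, +2 SD planted shifts on
#' H3K27me3/CTCF/H3K9me3), runs the full pipeline and reports the held-out
#' metrics plus the Davies-Bouldin separation of the learned embeddings
#' with and without the network branch.
#'
#' @param seed Integer seed for the fixture and the model.
#' @param maxEpochs Training epoch budget (default 25; ranking converges
#'   long before the full default budget on this strong planted signal).
#' @param dir Scratch directory (a temporary one by default, removed on
#'   exit).
#' @return List with held-out `metrics`, `dbiFull` (200-d embedding DBI),
#'   `dbiLinearOnly` (convolutional block only) and the pipeline `result`.
#' @export
plantedEffectExperiment <- function(seed = 1L, maxEpochs = 25L, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("rein-planted-")
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  }
  spec <- fixtureSpec(seed = childSeed(seed, 11L))
  generateFixture(spec, dir)
  cfg <- reinConfig(seed = childSeed(seed, 12L), maxEpochs = maxEpochs)
  res <- reinPipeline(dir, cfg)
  emb <- embedREIN(res$fit, res$graph, res$features, res$dataset@node)
  pos <- res$dataset@node[res$dataset@role == "positive"]
  neg <- res$dataset@node[res$dataset@role == "negative"]
  nc <- res$fit@config$cnnChannels[length(res$fit@config$cnnChannels)]
  list(metrics = res$metrics,
       dbiFull = daviesBouldin(emb[pos, ], emb[neg, ]),
       dbiLinearOnly = daviesBouldin(emb[pos, seq_len(nc)],
                                     emb[neg, seq_len(nc)]),
       result = res)
}

#' Null-effect calibration experiment
#'
#' Generates a larger fixture (about 1500 labeled nodes) with zero planted
#' effects and no motif, trains the classifier and reports the held-out
#' metrics; the AUROC calibrates the pipeline against chance.
#'
#' @param seed Integer seed.
#' @param maxEpochs Training epoch budget (default 10).
#' @param dir Scratch directory (temporary by default).
#' @return List with held-out `metrics` and the test-set size `nTest`.
#' @export
nullEffectExperiment <- function(seed = 1L, maxEpochs = 10L, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("rein-null-")
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  }
  spec <- fixtureSpec(nChroms = 2L, chromLength = 8e6, nLoops = 7500L,
                      nElements = c(silencer = 750L, non_silencer = 300L,
                                    enhancer = 300L, promoter = 1500L),
                      effects = list(), motifRate = 0,
                      seed = childSeed(seed, 21L))
  generateFixture(spec, dir)
  cfg <- reinConfig(seed = childSeed(seed, 22L), maxEpochs = maxEpochs)
  res <- reinPipeline(dir, cfg, trainFraction = 0.5)
  list(metrics = res$metrics, nTest = length(res$testNodes))
}

#' Topology-signal ablation experiment
#'
#' Plants a pure topology signal on small fixtures over several seeds —
#' assortative extra loops among silencer anchors, raising their degree and
#' homophily with no signal-track or sequence effects — then trains the
#' full model and the linear-only ablation (zeroed descriptors on an
#' edgeless graph) on each.  With the class signal confined to the network
#' branch, the full model should not lose to the ablated one on average.
#' Training uses a 40% split so most labeled nodes serve as a large
#' held-out set, keeping the per-seed AUROC estimates tight.
#'
#' @param seed Base seed.
#' @param nSeeds Number of independent fixtures (default 10).
#' @param maxEpochs Training epoch budget per run (default 15).
#' @return `data.frame` with one row per seed and the held-out AUROC of
#'   both conditions.
#' @export
topologyAblationExperiment <- function(seed = 1L, nSeeds = 10L,
                                       maxEpochs = 15L) {
  rows <- vector("list", nSeeds)
  for (s in seq_len(nSeeds)) {
    dir <- tempfile("rein-ablate-")
    spec <- fixtureSpec(nChroms = 2L, chromLength = 1e6, nLoops = 800L,
                        nElements = c(silencer = 80L, non_silencer = 80L,
                                      enhancer = 0L, promoter = 0L),
                        effects = list(), motifRate = 0, degreeBoost = 6L,
                        seed = childSeed(seed, 100L + s))
    generateFixture(spec, dir)
    loops <- filterLoops(readBedpe(file.path(dir, "loops.bedpe")))
    graph <- buildREIN(loops)
    els <- normalizeElements(readBedElements(file.path(dir, "elements.bed")))
    graph <- assignLabels(graph, els)
    graph <- extractComponents(graph, 100L)
    dataset <- sampleNegatives(graph, seed = childSeed(seed, 300L + s))
    genome <- readGenome(file.path(dir, "genome.fa"))
    tracks <- lapply(setNames(nm = reinTrackNames()), function(tn)
      readBedgraph(file.path(dir, "tracks", paste0(tn, ".bedGraph")), tn))
    features <- buildFeatures(graph, genome, tracks, nodes = dataset@node)
    cfg <- reinConfig(seed = childSeed(seed, 500L + s), maxEpochs = maxEpochs)
    auroc <- vapply(c("full", "linear_only"), function(mode) {
      ab <- ablate(features, graph, mode)
      fitAndScore(ab$graph, ab$features, dataset, cfg,
                  trainFraction = 0.4)$metrics[["AUROC"]]
    }, numeric(1L))
    rows[[s]] <- data.frame(seed = s, full = auroc[["full"]],
                            linear_only = auroc[["linear_only"]])
    unlink(dir, recursive = TRUE)
  }
  do.call(rbind, rows)
}
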