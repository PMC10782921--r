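#' Specification of a synthetic fixture
#'
#' Parameters of the synthetic data generator: a random genome, chromatin
#' loops whose anchors lie along each chromosome (a connected backbone plus
#' random short-range loops, with a configurable fraction of overlapping
#' twin anchors to exercise merging), regulatory elements planted on anchor
#' centers, and per-base signal tracks in which element-bearing windows
#' receive class-conditional mean shifts over Gaussian noise.
#'
#' The defaults describe the small benchmark condition used throughout the
#' package: 2 chromosomes of 2 Mb, 1500 loops, 150 silencers, 150 mixed
#' negatives-to-be (60 non-silencers, 60 enhancers, 300 promoters of which
#' 10\% are later sampled), and a 2-standard-deviation mean shift on three
#' repressive/architectural tracks (H3K27me3, CTCF, H3K9me3) over noise of
#' unit standard deviation.
#'
#' @param nChroms Number of chromosomes.
#' @param chromLength Chromosome length in nt.
#' @param nLoops Total number of loops.
#' @param anchorLenRange Two integers, uniform range of anchor lengths in
#'   nt.
#' @param overlapRate Fraction of base anchors receiving an overlapping
#'   twin anchor.
#' @param nElements Named integer vector of element counts per class.
#' @param effects Named list: per element class, a named vector of mean
#'   shifts (in noise-SD units when `noiseSd` is 1) applied to that class's
#'   windows on the named tracks.
#' @param motif DNA motif planted at silencer window centers.
#' @param motifRate Probability that a silencer window carries the motif.
#' @param noiseSd Standard deviation of the per-bin Gaussian signal noise.
#' @param binWidth Signal bin width in nt.
#' @param degreeBoost Extra loops connecting each silencer anchor to other
#'   silencer anchors on its chromosome (plants an assortative topology
#'   signal; 0 by default).
#' @param seed Integer seed; the whole fixture is a deterministic function
#'   of the spec.
#' @return A list of class `"fixtureSpec"`.
#' @export
fixtureSpec <- function(nChroms = 2L, chromLength = 2e6, nLoops = 1500L,
                        anchorLenRange = c(200L, 900L), overlapRate = 0.10,
                        nElements = c(silencer = 150L, non_silencer = 60L,
                                      enhancer = 60L, promoter = 300L),
                        effects = list(silencer = c(H3K27me3 = 2, CTCF = 2,
                                                    H3K9me3 = 2)),
                        motif = "GCGCATTCCGGC", motifRate = 0.3, noiseSd = 1,
                        binWidth = 25L, degreeBoost = 0L, seed = 1L) {
  spec <- list(nChroms = as.integer(nChroms), chromLength = as.numeric(chromLength),
               nLoops = as.integer(nLoops),
               anchorLenRange = as.integer(anchorLenRange),
               overlapRate = overlapRate, nElements = nElements,
               effects = effects, motif = motif, motifRate = motifRate,
               noiseSd = noiseSd, binWidth = as.integer(binWidth),
               degreeBoost = as.integer(degreeBoost), seed = as.integer(seed))
  stopifnot(spec$nChroms >= 1L, spec$nLoops >= 0L,
            all(spec$nElements >= 0L), spec$overlapRate >= 0,
            spec$overlapRate <= 1, spec$motifRate >= 0, spec$motifRate <= 1,
            spec$noiseSd >= 0, length(spec$anchorLenRange) == 2L)
  badClass <- setdiff(names(spec$nElements), elementClasses())
  if (length(badClass) > 0L)
    stopf("unknown element class in nElements: %s", paste(badClass, collapse = ", "))
  class(spec) <- "fixtureSpec"
  spec
}

#' Generate a synthetic fixture on disk
#'
#' Writes a complete, internally consistent input set: `genome.fa`,
#' `loops.bedpe`, `elements.bed`, one bedGraph per configured track under
#' `tracks/`, and `truth.json` recording every planted node label.  Signal
#' planting acts on the normalized 600-nt node windows — exactly where the
#' featurizer reads — so the planted effect is visible to the model by
#' construction.  The same spec (same seed) always reproduces byte-identical
#' files.
#'
#' @param spec A [fixtureSpec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `truth`
#'   (`data.frame`: node id, coordinates, planted class) and `spec`.
#' @export
generateFixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixtureSpec"))
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  withSeed(spec$seed, {
    chroms <- paste0("chr", seq_len(spec$nChroms))
    margin <- 5000
    loopsPerChrom <- diff(round(seq(0, spec$nLoops, length.out = spec$nChroms + 1L)))
    anchorGr <- GRanges()
    loopA <- integer(0); loopB <- integer(0)
    twinOf <- integer(0)                 # base index of each twin anchor
    offset <- 0L
    for (ci in seq_len(spec$nChroms)) {
      lc <- loopsPerChrom[ci]
      m <- max(2L, round(2 / 3 * lc))    # base anchors; backbone uses m - 1 loops
      spacing <- (spec$chromLength - 2 * margin) / m
      if (spacing < 1600)
        stopf("infeasible spec: anchor spacing %.0f nt < 1600 (more loops than the chromosome can hold)",
              spacing)
      centers <- margin + (seq_len(m) - 0.5) * spacing +
        runif(m, -spacing / 16, spacing / 16)
      lens <- round(runif(m, spec$anchorLenRange[1L], spec$anchorLenRange[2L]))
      s0 <- round(centers - lens / 2)
      base <- GRanges(factor(chroms[ci], levels = chroms),
                      IRanges(s0 + 1L, s0 + lens))
      ## twin anchors overlapping a sampled subset of base anchors
      nTwin <- round(spec$overlapRate * m)
      twinHost <- if (nTwin > 0L) sort(sample(m, nTwin)) else integer(0)
      if (nTwin > 0L) {
        tl <- round(runif(nTwin, spec$anchorLenRange[1L], spec$anchorLenRange[2L]))
        ts0 <- round(centers[twinHost] + runif(nTwin, -100, 100) - tl / 2)
        twins <- GRanges(factor(chroms[ci], levels = chroms),
                         IRanges(ts0 + 1L, ts0 + tl))
      } else twins <- GRanges()
      ## loops: consecutive backbone plus random short-range extras
      a <- seq_len(m - 1L); b <- a + 1L
      nExtra <- lc - (m - 1L)
      if (nExtra > 0L) {
        ea <- sample(m, nExtra, replace = TRUE)
        eb <- pmin(m, ea + sample(50L, nExtra, replace = TRUE))
        fix <- eb == ea
        eb[fix] <- pmax(1L, ea[fix] - 1L)
        a <- c(a, ea); b <- c(b, eb)
      }
      ## route some loop endpoints through twin anchors
      if (nTwin > 0L) {
        twinIdx <- m + seq_len(nTwin)    # local index of twins
        for (t in seq_len(nTwin)) {
          hit <- which(a == twinHost[t])
          hit <- hit[runif(length(hit)) < 0.5]
          a[hit] <- twinIdx[t]
        }
        ## a few base-twin loops: these merge into one node -> self-loops
        nSelf <- min(nTwin, max(1L, round(0.02 * lc)))
        sel <- sample(nTwin, nSelf)
        a <- c(a, twinHost[sel]); b <- c(b, twinIdx[sel])
      }
      chromAnchors <- c(base, twins)
      anchorGr <- c(anchorGr, chromAnchors)
      loopA <- c(loopA, offset + a)
      loopB <- c(loopB, offset + b)
      twinOf <- c(twinOf, rep(NA_integer_, m), offset + twinHost)
      offset <- offset + length(chromAnchors)
    }

    ## plant elements on non-twinned base anchors long enough to exceed the
    ## 300-nt labeling overlap after window normalization
    isTwin <- !is.na(twinOf)
    hasTwin <- seq_along(anchorGr) %in% twinOf
    plantable <- which(!isTwin & !hasTwin & width(anchorGr) >= 400L)
    totalEl <- sum(spec$nElements)
    if (totalEl > length(plantable))
      stopf("infeasible spec: %d elements requested but only %d plantable anchors",
            totalEl, length(plantable))
    hosts <- sample(plantable, totalEl)
    hostClass <- rep(names(spec$nElements), spec$nElements)

    ## topology signal: assortative extra loops among silencer anchors of a
    ## chromosome (silencer-dense regions loop within their own cluster),
    ## raising both the degree and the homophily of silencer nodes
    if (spec$degreeBoost > 0L) {
      silHosts <- hosts[hostClass == "silencer"]
      for (h in silHosts) {
        peers <- silHosts[silHosts != h &
                            as.logical(seqnames(anchorGr)[silHosts] ==
                                         as.character(seqnames(anchorGr)[h]))]
        if (length(peers) == 0L) next
        tgt <- sample(peers, min(spec$degreeBoost, length(peers)))
        loopA <- c(loopA, rep(h, length(tgt)))
        loopB <- c(loopB, tgt)
      }
    }

    ## element intervals: even lengths centered exactly on anchor centers
    hc <- (start(anchorGr)[hosts] - 1L + end(anchorGr)[hosts]) %/% 2L
    elLen <- 2L * sample(150:300, totalEl, replace = TRUE)
    elements <- GRanges(seqnames(anchorGr)[hosts],
                        IRanges(hc - elLen %/% 2L + 1L, hc + elLen %/% 2L))
    elements$label <- factor(hostClass, levels = elementClasses())
    ord <- order(as.character(seqnames(elements)), start(elements))
    elements <- elements[ord]

    ## assemble loops and the reference graph used for signal planting
    loops <- S4Vectors::Pairs(anchorGr[loopA], anchorGr[loopB],
                              support = rpois(length(loopA), 4) + 1L)
    graph <- buildREIN(filterLoops(loops, maxAnchorLen = 1001L +
                                     max(spec$anchorLenRange)))
    nodeOfAnchor <- findOverlaps(anchorGr, graph@nodes, select = "first")
    truth <- data.frame(node = names(graph@nodes)[nodeOfAnchor[hosts]],
                        class = hostClass, stringsAsFactors = FALSE)
    bed <- grangesToBed0(graph@nodes[truth$node])
    truth <- cbind(truth, bed)
    truth <- truth[order(truth$node), ]
    rownames(truth) <- NULL

    ## genome with optional motif planted at silencer window centers
    dna <- lapply(chroms, function(ch)
      sample(c("A", "C", "G", "T"), spec$chromLength, replace = TRUE))
    names(dna) <- chroms
    if (nchar(spec$motif) > 0L && spec$motifRate > 0) {
      silNodes <- truth$node[truth$class == "silencer"]
      carry <- silNodes[runif(length(silNodes)) < spec$motifRate]
      win <- nodeWindows(graph, carry)
      mchars <- strsplit(spec$motif, "")[[1L]]
      for (i in seq_along(win)) {
        ch <- as.character(seqnames(win)[i])
        at <- start(win)[i] + 300L - length(mchars) %/% 2L
        dna[[ch]][at:(at + length(mchars) - 1L)] <- mchars
      }
    }
    genome <- Biostrings::DNAStringSet(vapply(dna, paste, character(1L),
                                              collapse = ""))

    ## signal tracks: binned Gaussian noise over every node window, plus
    ## class-conditional mean shifts on the planted windows
    allWin <- nodeWindows(graph)
    winClass <- setNames(rep("unlabeled", length(allWin)), names(allWin))
    winClass[truth$node] <- truth$class
    nBins <- width(allWin)[1L] %/% spec$binWidth
    binStart <- rep(start(allWin), each = nBins) +
      rep(seq_len(nBins) - 1L, length(allWin)) * spec$binWidth
    binChrom <- rep(as.character(seqnames(allWin)), each = nBins)
    binClass <- rep(winClass, each = nBins)
    ord <- order(binChrom, binStart)
    trackPaths <- character(0)
    for (tn in reinTrackNames()) {
      mu <- numeric(length(binClass))
      for (cls in names(spec$effects)) {
        eff <- spec$effects[[cls]]
        if (tn %in% names(eff)) mu[binClass == cls] <- eff[[tn]]
      }
      vals <- round(rnorm(length(mu), mu, spec$noiseSd), 4L)
      gr <- GRanges(binChrom[ord], IRanges(binStart[ord],
                                           binStart[ord] + spec$binWidth - 1L),
                    score = vals[ord])
      p <- file.path(dir, "tracks", paste0(tn, ".bedGraph"))
      writeBedgraph(SignalTrack(tn, gr), p)
      trackPaths <- c(trackPaths, setNames(p, tn))
    }

    paths <- list(genome = file.path(dir, "genome.fa"),
                  loops = file.path(dir, "loops.bedpe"),
                  elements = file.path(dir, "elements.bed"),
                  tracks = trackPaths, truth = file.path(dir, "truth.json"))
    Biostrings::writeXStringSet(genome, paths$genome, width = 80L)
    writeBedpe(loops, paths$loops)
    writeBedElements(elements, paths$elements)
    jsonlite::write_json(list(spec = spec[setdiff(names(unclass(spec)), "effects")],
                              effects = spec$effects, nodes = truth),
                         paths$truth, dataframe = "columns", auto_unbox = TRUE,
                         digits = NA)
    invisible(list(paths = paths, truth = truth, spec = spec))
  })
}

#' Read the planted truth of a fixture
#'
#' @param path Path to a `truth.json` written by [generateFixture()].
#' @return `data.frame` with node ids, coordinates and planted classes.
#' @export
readFixtureTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.data.frame(obj$nodes)
}

#' Run the full pipeline on a fixture directory
#'
#' Reads the fixture files, builds and labels the interaction network,
#' extracts large components, draws the positive/negative dataset,
#' featurizes, trains the classifier on a stratified split and scores the
#' held-out nodes.
#'
#' @param dir Fixture directory from [generateFixture()].
#' @param config A [reinConfig()]; its seed also drives the data splits.
#' @param minComponent Strict component-size threshold (default 100).
#' @param promoterFraction Promoter sampling fraction (default 0.10).
#' @param trainFraction Fraction of dataset nodes used for training
#'   (stratified; the rest are held out).
#' @param maxAnchorLen Strict anchor-length threshold (default 1000).
#' @return List with the graph, dataset, features, fit, the train/test node
#'   ids, the held-out prediction `data.frame` and held-out `metrics`
#'   (confusion metrics, AUROC, AUPR).
#' @export
reinPipeline <- function(dir, config = reinConfig(), minComponent = 100L,
                         promoterFraction = 0.10, trainFraction = 0.7,
                         maxAnchorLen = 1000L) {
  loops <- filterLoops(readBedpe(file.path(dir, "loops.bedpe")), maxAnchorLen)
  graph <- buildREIN(loops)
  elements <- normalizeElements(readBedElements(file.path(dir, "elements.bed")))
  graph <- assignLabels(graph, elements)
  graph <- extractComponents(graph, minComponent)
  dataset <- sampleNegatives(graph, promoterFraction,
                             seed = childSeed(config$seed, 101L))
  genome <- readGenome(file.path(dir, "genome.fa"))
  tracks <- lapply(setNames(nm = reinTrackNames()), function(tn)
    readBedgraph(file.path(dir, "tracks", paste0(tn, ".bedGraph")), tn))
  features <- buildFeatures(graph, genome, tracks, nodes = dataset@node)

  fs <- fitAndScore(graph, features, dataset, config, trainFraction)
  c(list(graph = graph, dataset = dataset, features = features), fs)
}

## keep factor levels stable on subsetting
droplevels2 <- function(f) factor(as.character(f), levels = levels(f))

#' Recovery metrics of a trained model against planted truth
#'
#' Scores held-out predictions against the planted node classes of a
#' fixture: AUROC and AUPR with silencer as the positive class.
#'
#' @param prediction `data.frame` from [predictREIN()] on held-out nodes.
#' @param truth Truth table from [generateFixture()] or
#'   [readFixtureTruth()].
#' @return Named numeric vector `c(AUROC, AUPR)`.
#' @export
plantedRecoveryReport <- function(prediction, truth) {
  cls <- truth$class[match(prediction$node, truth$node)]
  if (anyNA(cls)) stopf("prediction contains nodes absent from the truth table")
  y <- cls == "silencer"
  c(AUROC = aurocScore(prediction$score, y),
    AUPR = auprScore(prediction$score, y))
}
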