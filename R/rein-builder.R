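#' Filter chromatin loops by anchor length
#'
#' Keeps only loops in which both anchors are strictly shorter than
#' `maxAnchorLen` nucleotides.  Short anchors give near-element resolution;
#' loops with a long anchor are discarded entirely.
#'
#' @param loops `Pairs` of anchor `GRanges` from [readBedpe()].
#' @param maxAnchorLen Strict upper bound on anchor length in nt (default
#'   1000).
#' @return The filtered `Pairs` object.
#' @export
filterLoops <- function(loops, maxAnchorLen = 1000L) {
  keep <- width(S4Vectors::first(loops)) < maxAnchorLen &
    width(S4Vectors::second(loops)) < maxAnchorLen
  loops[keep]
}

#' Merge overlapping loop anchors
#'
#' Computes the connected-overlap closure of a set of anchors: any chain of
#' pairwise-overlapping anchors collapses into the single interval spanning
#' the chain, iterated until no two remaining intervals overlap.  Abutting
#' (non-overlapping) intervals are NOT merged.
#'
#' @param anchors `GRanges` of anchors.
#' @return A list with `merged` (the disjoint merged `GRanges`, sorted) and
#'   `map` (integer vector: for each input anchor, the index of the merged
#'   interval covering it).
#' @export
mergeAnchors <- function(anchors) {
  ## reduce() with min.gapwidth = 0 merges exactly the overlapping chains:
  ## intervals separated by a gap >= 0 (i.e. merely abutting) stay apart.
  merged <- reduce(anchors, min.gapwidth = 0L)
  hits <- findOverlaps(anchors, merged)
  if (length(hits) != length(anchors))
    stopf("internal error: anchor not covered by exactly one merged interval")
  map <- integer(length(anchors))
  map[queryHits(hits)] <- subjectHits(hits)
  list(merged = merged, map = map)
}

#' Build a regulatory element interaction network from loops
#'
#' Merged anchors become nodes; each loop contributes one undirected edge
#' between the merged nodes of its two anchors.  A loop whose anchors merged
#' into the same node yields a self-loop, and multiple loops between the
#' same node pair collapse to a single edge.
#'
#' @param loops Filtered `Pairs` of anchor `GRanges` (see [filterLoops()]).
#' @return A [REINGraph-class] with all nodes `unlabeled` and no component
#'   annotation.
#' @export
buildREIN <- function(loops) {
  n <- length(loops)
  anchors <- c(granges(S4Vectors::first(loops)), granges(S4Vectors::second(loops)))
  m <- mergeAnchors(anchors)
  nodes <- m$merged
  names(nodes) <- sprintf("n%06d", seq_along(nodes))
  nodes$label <- factor(rep("unlabeled", length(nodes)), levels = nodeLabelLevels())
  nodes$component <- rep(NA_integer_, length(nodes))
  if (n > 0L) {
    ia <- m$map[seq_len(n)]
    ib <- m$map[n + seq_len(n)]
    e <- cbind(pmin(ia, ib), pmax(ia, ib))
    e <- unique(e)
    e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  } else {
    e <- matrix(integer(0), ncol = 2L)
  }
  new("REINGraph", nodes = nodes, edges = e)
}

#' Normalize element intervals to a fixed window
#'
#' Re-centers every interval on its midpoint and extends `halfFlank`
#' nucleotides on each side, giving windows of exactly `2 * halfFlank` nt
#' (600 by default).  The midpoint is `floor((start0 + end0) / 2)` in
#' 0-based coordinates.  A window that would run past the chromosome start
#' is clamped at 0 with a warning (and is then shorter than the target).
#'
#' @param elements `GRanges` (metadata columns are preserved).
#' @param halfFlank Flank length in nt on each side of the center (default
#'   300).
#' @return `GRanges` of normalized windows.
#' @export
normalizeElements <- function(elements, halfFlank = 300L) {
  s0 <- start(elements) - 1L
  e0 <- end(elements)
  center <- (s0 + e0) %/% 2L
  ns0 <- center - halfFlank
  ne0 <- center + halfFlank
  clamped <- ns0 < 0L
  if (any(clamped)) {
    warnf("%d element window(s) clamped at chromosome start", sum(clamped))
    ns0[clamped] <- 0L
  }
  out <- elements
  GenomicRanges::ranges(out) <- IRanges(ns0 + 1L, ne0)
  out
}

#' Label network nodes with element classes
#'
#' A node receives an element's class when the element's normalized window
#' overlaps the node interval by strictly more than `minOverlap` nt.  An
#' element that would so label more than one node (possible only when nodes
#' abut) is assigned to the node with the larger overlap, leftmost on a tie.
#' A node hit by elements of several classes takes the highest-priority
#' class in the order silencer > non_silencer > enhancer > promoter.
#'
#' @param graph A [REINGraph-class].
#' @param elements Normalized element `GRanges` with a `label` column (see
#'   [normalizeElements()]).
#' @param minOverlap Strict overlap threshold in nt (default 300).
#' @return The graph with updated node labels.
#' @export
assignLabels <- function(graph, elements, minOverlap = 300L) {
  nodes <- graph@nodes
  hits <- findOverlaps(elements, nodes)
  if (length(hits) > 0L) {
    qh <- queryHits(hits); sh <- subjectHits(hits)
    ov <- pmin(end(elements)[qh], end(nodes)[sh]) -
      pmax(start(elements)[qh], start(nodes)[sh]) + 1L
    keep <- ov > minOverlap
    qh <- qh[keep]; sh <- sh[keep]; ov <- ov[keep]
    if (length(qh) > 0L) {
      ## one node per element: larger overlap wins, leftmost node on a tie
      ord <- order(qh, -ov, start(nodes)[sh])
      qh <- qh[ord]; sh <- sh[ord]
      first <- !duplicated(qh)
      qh <- qh[first]; sh <- sh[first]
      ## one class per node: highest priority (lowest factor code) wins
      cls <- as.integer(elements$label[qh])
      best <- tapply(cls, sh, min)
      idx <- as.integer(names(best))
      lab <- as.integer(nodes$label)
      lab[idx] <- pmin(lab[idx], as.integer(best))
      nodes$label <- factor(nodeLabelLevels()[lab], levels = nodeLabelLevels())
    }
  }
  initialize(graph, nodes = nodes)
}

#' Extract large connected components
#'
#' Finds connected components by breadth-first search and keeps those with
#' strictly more than `minSize` nodes; smaller components are removed along
#' with their edges.  Retained components are annotated on the nodes with
#' consecutive integer ids.
#'
#' @param graph A [REINGraph-class].
#' @param minSize Strict lower bound on component node count (default 100).
#' @return The reduced, component-annotated graph.
#' @export
extractComponents <- function(graph, minSize = 100L) {
  n <- length(graph@nodes)
  g <- igraph::make_graph(edges = as.vector(t(graph@edges)), n = n,
                          directed = FALSE)
  comp <- igraph::components(g)
  big <- which(comp$csize > minSize)
  keep <- comp$membership %in% big
  newId <- match(comp$membership, big)
  nodes <- graph@nodes[keep]
  nodes$component <- newId[keep]
  oldToNew <- integer(n)
  oldToNew[keep] <- seq_len(sum(keep))
  e <- graph@edges
  e <- e[keep[e[, 1L]] & keep[e[, 2L]], , drop = FALSE]
  e[] <- oldToNew[e]
  initialize(graph, nodes = nodes, edges = e)
}

#' Draw the supervised positive/negative node sets
#'
#' Positives are all silencer nodes.  Negatives are all non-silencer nodes,
#' all enhancer nodes and, within each connected component, a seeded uniform
#' subsample without replacement of `floor(promoterFraction * n_promoters)`
#' promoter nodes.  Unlabeled nodes enter neither set.
#'
#' @param graph A labeled, component-annotated [REINGraph-class].
#' @param promoterFraction Fraction of promoters sampled per component
#'   (default 0.10).
#' @param seed Integer seed making the promoter subsample reproducible.
#' @return A [REINDataset-class].
#' @export
sampleNegatives <- function(graph, promoterFraction = 0.10, seed = 1L) {
  nodes <- graph@nodes
  if (all(is.na(nodes$component)))
    stopf("components not annotated; run extractComponents() first")
  id <- names(nodes)
  lab <- as.character(nodes$label)
  comp <- nodes$component
  pos <- which(lab == "silencer")
  negFixed <- which(lab %in% c("non_silencer", "enhancer"))
  promSampled <- withSeed(seed, {
    unlist(lapply(sort(unique(comp)), function(cc) {
      prom <- which(lab == "promoter" & comp == cc)
      k <- floor(promoterFraction * length(prom))
      if (k < 1L) integer(0) else sort(sample(prom, k))
    }), use.names = FALSE)
  })
  sel <- c(pos, negFixed, promSampled)
  role <- factor(c(rep("positive", length(pos)),
                   rep("negative", length(negFixed) + length(promSampled))),
                 levels = c("positive", "negative"))
  prov <- c(lab[pos], lab[negFixed], rep("promoter_sampled", length(promSampled)))
  new("REINDataset", node = id[sel], role = role, provenance = prov,
      component = as.integer(comp[sel]))
}

#' Serialize a REINGraph to JSON
#'
#' Writes nodes (id, chrom, 0-based half-open start/end, label, component)
#' and the undirected edge list (pairs of node ids) as a single JSON object.
#'
#' @param graph A [REINGraph-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeREIN <- function(graph, path) {
  nodes <- graph@nodes
  bed <- grangesToBed0(nodes)
  obj <- list(
    nodes = data.frame(id = names(nodes), chrom = bed$chrom, start = bed$start,
                       end = bed$end, label = as.character(nodes$label),
                       component = nodes$component, stringsAsFactors = FALSE),
    edges = data.frame(from = names(nodes)[graph@edges[, 1L]],
                       to = names(nodes)[graph@edges[, 2L]],
                       stringsAsFactors = FALSE))
  jsonlite::write_json(obj, path, dataframe = "columns", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a REINGraph from JSON
#'
#' @param path Path written by [writeREIN()].
#' @return A [REINGraph-class].
#' @export
readREIN <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nd <- obj$nodes
  nodes <- bed0ToGRanges(nd$chrom, nd$start, nd$end)
  names(nodes) <- nd$id
  nodes$label <- factor(nd$label, levels = nodeLabelLevels())
  comp <- nd$component
  if (is.null(comp)) comp <- rep(NA_integer_, length(nodes))
  nodes$component <- as.integer(comp)
  if (length(obj$edges) && length(obj$edges$from)) {
    i <- match(obj$edges$from, nd$id)
    j <- match(obj$edges$to, nd$id)
    e <- cbind(pmin(i, j), pmax(i, j))
  } else {
    e <- matrix(integer(0), ncol = 2L)
  }
  new("REINGraph", nodes = nodes, edges = e)
}
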