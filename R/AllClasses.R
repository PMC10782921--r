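#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomicRanges GRanges granges seqnames start end width
#'   findOverlaps reduce ranges<-
#' @importFrom IRanges IRanges
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' SignalTrack: a sparse per-base genomic signal
#'
#' Holds one epigenomic signal track (histone-modification or TF-binding
#' ChIP-seq coverage) as a set of non-overlapping scored intervals.  Any
#' base not covered by an interval reads as signal 0.
#'
#' @slot name Single string, the assay name (e.g. `"H3K27me3"`).
#' @slot ranges A [GenomicRanges::GRanges] with a numeric `score` metadata
#'   column; ranges must be pairwise non-overlapping.
#' @export
setClass("SignalTrack", representation(name = "character", ranges = "GRanges"))

setValidity("SignalTrack", function(object) {
  msg <- NULL
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be a single string")
  if (is.null(object@ranges$score) || !is.numeric(object@ranges$score))
    msg <- c(msg, "'ranges' must carry a numeric 'score' column")
  if (length(object@ranges) > 1L) {
    ov <- findOverlaps(object@ranges, drop.self = TRUE)
    if (length(ov) > 0L)
      msg <- c(msg, "signal intervals overlap (ambiguous per-base signal)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a SignalTrack
#'
#' @param name Assay name.
#' @param ranges `GRanges` with a numeric `score` column; intervals must not
#'   overlap one another.
#' @return A [SignalTrack-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10), score = 2.5)
#' SignalTrack("CTCF", gr)
#' @export
SignalTrack <- function(name, ranges) {
  new("SignalTrack", name = name, ranges = ranges)
}

setMethod("show", "SignalTrack", function(object) {
  cat("SignalTrack '", object@name, "' with ", length(object@ranges),
      " scored intervals\n", sep = "")
})

#' @describeIn SignalTrack-class number of scored intervals
#' @param x A `SignalTrack`.
#' @export
setMethod("length", "SignalTrack", function(x) length(x@ranges))

#' REINGraph: a regulatory element interaction network
#'
#' Nodes are merged chromatin-loop anchors (pairwise non-overlapping
#' intervals); edges connect node pairs joined by at least one chromatin
#' loop, with self-loops where a loop's two anchors merged into the same
#' node.  Nodes carry an element-class label and, after component
#' extraction, a connected-component id.
#'
#' @slot nodes [GenomicRanges::GRanges] of merged anchors, named by node id,
#'   with metadata columns `label` (factor over silencer / non_silencer /
#'   enhancer / promoter / unlabeled) and `component` (integer, `NA` before
#'   component extraction).
#' @slot edges Two-column integer matrix of node indices, one row per
#'   undirected edge, first column \eqn{\le} second; self-loops are rows with
#'   equal entries; duplicate loop-derived edges are collapsed.
#' @export
setClass("REINGraph", representation(nodes = "GRanges", edges = "matrix"))

setValidity("REINGraph", function(object) {
  msg <- NULL
  n <- length(object@nodes)
  if (is.null(names(object@nodes)) && n > 0L)
    msg <- c(msg, "nodes must be named by node id")
  if (ncol(object@edges) != 2L) msg <- c(msg, "edges must have two columns")
  e <- object@edges
  if (nrow(e) > 0L) {
    if (any(e < 1L) || any(e > n))
      msg <- c(msg, "edge endpoints must index nodes")
    if (any(e[, 1L] > e[, 2L]))
      msg <- c(msg, "edges must be stored with first index <= second")
  }
  if (is.null(object@nodes$label))
    msg <- c(msg, "nodes must carry a 'label' column")
  if (n > 1L) {
    ov <- findOverlaps(object@nodes, drop.self = TRUE)
    if (length(ov) > 0L)
      msg <- c(msg, "node intervals overlap within a chromosome after merging")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "REINGraph", function(object) {
  lab <- table(object@nodes$label)
  lab <- lab[lab > 0L]
  comp <- object@nodes$component
  ncomp <- if (all(is.na(comp))) NA_integer_ else length(unique(comp[!is.na(comp)]))
  cat("REINGraph with ", length(object@nodes), " nodes and ",
      nrow(object@edges), " edges (", sum(object@edges[, 1L] == object@edges[, 2L]),
      " self-loops)\n", sep = "")
  if (!is.na(ncomp)) cat("  components:", ncomp, "\n")
  if (length(lab)) cat("  labels:", paste(names(lab), lab, sep = "=", collapse = " "), "\n")
})

#' @describeIn REINGraph-class node intervals as a `GRanges`
#' @param object,x A `REINGraph`.
#' @export
setGeneric("reinNodes", function(object) standardGeneric("reinNodes"))

#' @rdname REINGraph-class
#' @export
setMethod("reinNodes", "REINGraph", function(object) object@nodes)

#' @describeIn REINGraph-class undirected edge matrix (node indices)
#' @export
setGeneric("reinEdges", function(object) standardGeneric("reinEdges"))

#' @rdname REINGraph-class
#' @export
setMethod("reinEdges", "REINGraph", function(object) object@edges)

#' @describeIn REINGraph-class node labels, named by node id
#' @export
setGeneric("reinLabels", function(object) standardGeneric("reinLabels"))

#' @rdname REINGraph-class
#' @export
setMethod("reinLabels", "REINGraph", function(object)
  setNames(object@nodes$label, names(object@nodes)))

#' @describeIn REINGraph-class component id per node, named by node id
#' @export
setGeneric("reinComponents", function(object) standardGeneric("reinComponents"))

#' @rdname REINGraph-class
#' @export
setMethod("reinComponents", "REINGraph", function(object)
  setNames(object@nodes$component, names(object@nodes)))

#' @rdname REINGraph-class
#' @export
setMethod("length", "REINGraph", function(x) length(x@nodes))

#' REINDataset: labeled positive/negative node sets
#'
#' The supervised dataset drawn from a labeled [REINGraph-class]: all
#' silencer nodes as positives and all non-silencer and enhancer nodes plus
#' a per-component 10\% promoter subsample as negatives.  `provenance`
#' records which admission rule brought each node in.
#'
#' @slot node Character vector of node ids.
#' @slot role Factor with levels `positive` / `negative`.
#' @slot provenance Character vector (`"silencer"`, `"non_silencer"`,
#'   `"enhancer"`, `"promoter_sampled"`).
#' @slot component Integer component id per node.
#' @export
setClass("REINDataset", representation(node = "character", role = "factor",
                                       provenance = "character",
                                       component = "integer"))

setValidity("REINDataset", function(object) {
  msg <- NULL
  n <- length(object@node)
  if (length(object@role) != n || length(object@provenance) != n ||
      length(object@component) != n)
    msg <- c(msg, "all slots must have equal length")
  if (!identical(levels(object@role), c("positive", "negative")))
    msg <- c(msg, "role levels must be positive/negative")
  pos <- object@node[object@role == "positive"]
  neg <- object@node[object@role == "negative"]
  if (length(intersect(pos, neg)) > 0L)
    msg <- c(msg, "positives and negatives must be disjoint")
  if (anyDuplicated(object@node)) msg <- c(msg, "duplicate node ids")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "REINDataset", function(object) {
  cat("REINDataset:", sum(object@role == "positive"), "positives,",
      sum(object@role == "negative"), "negatives\n")
})

#' @describeIn REINDataset-class positive (silencer) node ids
#' @param object,x A `REINDataset`.
#' @export
setGeneric("positives", function(object) standardGeneric("positives"))

#' @rdname REINDataset-class
#' @export
setMethod("positives", "REINDataset", function(object)
  object@node[object@role == "positive"])

#' @describeIn REINDataset-class negative node ids
#' @export
setGeneric("negatives", function(object) standardGeneric("negatives"))

#' @rdname REINDataset-class
#' @export
setMethod("negatives", "REINDataset", function(object)
  object@node[object@role == "negative"])

#' @rdname REINDataset-class
#' @export
setMethod("length", "REINDataset", function(x) length(x@node))

#' @describeIn REINDataset-class as a `data.frame` (node, role, provenance,
#'   component)
#' @export
setGeneric("datasetTable", function(object) standardGeneric("datasetTable"))

#' @rdname REINDataset-class
#' @export
setMethod("datasetTable", "REINDataset", function(object)
  data.frame(node = object@node, role = object@role,
             provenance = object@provenance, component = object@component,
             stringsAsFactors = FALSE))

#' REINFeatures: per-node model inputs
#'
#' Bundles the two inputs of the classifier: the linear feature tensor
#' (one-hot sequence rows plus one row per configured signal track, over the
#' 600-nt node window) for a chosen node subset, and the 10-dimensional
#' structural/signal descriptor for every graph node (the GraphSAGE input).
#'
#' @slot linear Numeric array `channels x positions x nodes` (by default
#'   `21 x 600 x n`); channel order is A,T,C,G then the configured tracks.
#' @slot linearNodes Character vector of node ids for the third dimension.
#' @slot descriptors Numeric matrix, one row per graph node (rownames are
#'   node ids), 10 columns.
#' @slot trackNames Character vector of configured track names.
#' @export
setClass("REINFeatures", representation(linear = "array",
                                        linearNodes = "character",
                                        descriptors = "matrix",
                                        trackNames = "character"))

setValidity("REINFeatures", function(object) {
  msg <- NULL
  d <- dim(object@linear)
  if (length(d) != 3L) msg <- c(msg, "linear must be a 3-d array")
  else {
    if (d[1L] != 4L + length(object@trackNames))
      msg <- c(msg, "linear channel count must be 4 + number of tracks")
    if (d[3L] != length(object@linearNodes))
      msg <- c(msg, "third dimension must match linearNodes")
  }
  if (is.null(rownames(object@descriptors)))
    msg <- c(msg, "descriptors must have node-id rownames")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "REINFeatures", function(object) {
  d <- dim(object@linear)
  cat("REINFeatures: linear ", d[1L], "x", d[2L], " for ", d[3L],
      " nodes; descriptors ", ncol(object@descriptors), "-d for ",
      nrow(object@descriptors), " nodes\n", sep = "")
})

#' @describeIn REINFeatures-class linear feature array
#' @param object A `REINFeatures`.
#' @export
setGeneric("linearFeatures", function(object) standardGeneric("linearFeatures"))

#' @rdname REINFeatures-class
#' @export
setMethod("linearFeatures", "REINFeatures", function(object) object@linear)

#' @describeIn REINFeatures-class node descriptor matrix
#' @export
setGeneric("nodeDescriptors", function(object) standardGeneric("nodeDescriptors"))

#' @rdname REINFeatures-class
#' @export
setMethod("nodeDescriptors", "REINFeatures", function(object) object@descriptors)

#' REINFit: a trained silencer classifier
#'
#' Parameter state, configuration and per-epoch training history of the
#' hybrid convolutional / GraphSAGE model returned by [trainREIN()].
#'
#' @slot params Named list of parameter matrices/vectors.
#' @slot config Model configuration list (see [reinConfig()]).
#' @slot history `data.frame` with one row per epoch: training loss,
#'   validation loss and the learning rate in force.
#' @slot trainNodes Character vector of node ids the model was fitted on.
#' @export
setClass("REINFit", representation(params = "list", config = "list",
                                   history = "data.frame",
                                   trainNodes = "character"))

setMethod("show", "REINFit", function(object) {
  h <- object@history
  cat("REINFit: ", nrow(h), " epochs; final training loss ",
      signif(h$loss[nrow(h)], 4L), "\n", sep = "")
})

#' @describeIn REINFit-class per-epoch training history
#' @param object A `REINFit`.
#' @export
setGeneric("trainingHistory", function(object) standardGeneric("trainingHistory"))

#' @rdname REINFit-class
#' @export
setMethod("trainingHistory", "REINFit", function(object) object@history)
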