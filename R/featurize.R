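#' Configured signal track names
#'
#' The 17 assay names expected by the featurizer, in the fixed channel
#' order used throughout the package: 12 histone modifications followed by
#' 5 transcription-factor binding signals.
#'
#' @return Character vector of length 17.
#' @export
reinTrackNames <- function() {
  c("H3K9me3", "H3K27me3", "H3K27ac", "H3K36me3", "H3K4me3", "H3K4me1",
    "H3K79me2", "H2AFZ", "H4K20me1", "H3K4me2", "H3K9ac", "H3K9me1",
    "RAD21", "POLR2A", "SMC3", "ZNF143", "CTCF")
}

## Tracks summarized into the node descriptor (GraphSAGE input), chosen for
## their association with loop anchors (cohesin/CTCF), transcription
## (POLR2A, H3K4me3) and repressive vs active chromatin (H3K27me3, H3K27ac).
descriptorTrackNames <- function() {
  c("CTCF", "POLR2A", "RAD21", "SMC3", "H3K27me3", "H3K27ac", "H3K4me3")
}

#' One-hot encode a DNA sequence
#'
#' Encodes a sequence over \{A,C,G,T,N\} (case-insensitive) as a 4-row
#' binary matrix with row order A, T, C, G; `N` encodes as an all-zero
#' column.
#'
#' @param sequence A single DNA string.
#' @return A `4 x nchar(sequence)` 0/1 matrix with rownames A,T,C,G.
#' @examples
#' oneHotEncode("ACGT")
#' @export
oneHotEncode <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  code <- match(chars, c("A", "T", "C", "G", "N"))
  if (anyNA(code)) {
    i <- which(is.na(code))[1L]
    stopf("invalid nucleotide symbol '%s' at position %d", chars[i], i)
  }
  m <- matrix(0, nrow = 4L, ncol = length(chars),
              dimnames = list(c("A", "T", "C", "G"), NULL))
  ok <- code <= 4L
  m[cbind(code[ok], which(ok))] <- 1
  m
}

## Per-base signal values of equal-width windows, as a width x n matrix.
## Windows may start before base 1; out-of-range bases read 0 like any
## uncovered base.
signalMatrix <- function(track, windows) {
  w <- unique(width(windows))
  stopifnot(length(w) == 1L)
  m <- matrix(0, nrow = w, ncol = length(windows))
  hits <- findOverlaps(windows, track@ranges)
  if (length(hits) > 0L) {
    qh <- queryHits(hits); sh <- subjectHits(hits)
    ws <- start(windows)[qh]
    os <- pmax(ws, start(track@ranges)[sh]) - ws + 1L
    oe <- pmin(end(windows)[qh], end(track@ranges)[sh]) - ws + 1L
    lens <- oe - os + 1L
    idx <- sequence(lens, from = os + (qh - 1L) * w)
    m[idx] <- rep(track@ranges$score[sh], lens)
  }
  m
}

#' Extract the per-base signal over a 600-nt window
#'
#' @param track A [SignalTrack-class].
#' @param window A length-1 `GRanges` of width exactly `2 * halfFlank`.
#' @param halfFlank Half window width (default 300, i.e. 600-nt windows).
#' @return Numeric vector of per-base values; uncovered bases are 0.
#' @export
extractSignalWindow <- function(track, window, halfFlank = 300L) {
  if (length(window) != 1L)
    stopf("window must be a single interval")
  if (width(window) != 2L * halfFlank)
    stopf("window must be exactly %d nt wide, got %d", 2L * halfFlank,
          width(window))
  as.vector(signalMatrix(track, window))
}

#' Normalized feature windows of network nodes
#'
#' Applies the element normalization rule to node (merged anchor)
#' intervals: each window is centered on the anchor midpoint and spans
#' `2 * halfFlank` nt.  Windows are not clamped; any part outside the
#' chromosome is later read as `N` sequence and zero signal.
#'
#' @param graph A [REINGraph-class].
#' @param nodes Node ids (default all).
#' @param halfFlank Half window width in nt (default 300).
#' @return `GRanges` of fixed-width windows, named by node id.
#' @export
nodeWindows <- function(graph, nodes = NULL, halfFlank = 300L) {
  gr <- graph@nodes
  if (!is.null(nodes)) {
    idx <- match(nodes, names(gr))
    if (anyNA(idx)) stopf("unknown node id: %s", nodes[which(is.na(idx))[1L]])
    gr <- gr[idx]
  }
  s0 <- start(gr) - 1L
  e0 <- end(gr)
  center <- (s0 + e0) %/% 2L
  out <- GRanges(seqnames(gr), IRanges(center - halfFlank + 1L,
                                       center + halfFlank))
  names(out) <- names(gr)
  out
}

checkTracks <- function(tracks, needed, zeroFill) {
  missing <- setdiff(needed, names(tracks))
  if (length(missing) > 0L && !zeroFill)
    stopf("missing signal track(s): %s\nexpected tracks: %s",
          paste(missing, collapse = ", "), paste(needed, collapse = ", "))
  missing
}

#' Build the linear feature tensor
#'
#' For each requested node, stacks the one-hot encoded sequence of its
#' normalized window (4 rows) with the per-base values of the configured
#' signal tracks (one row each), giving a `(4 + n_tracks) x window` matrix
#' per node — `21 x 600` (12600 values) with the default 17 tracks.
#'
#' @param graph A [REINGraph-class].
#' @param genome `DNAStringSet` from [readGenome()].
#' @param tracks Named list of [SignalTrack-class] objects covering
#'   `trackNames`.
#' @param nodes Node ids to featurize (default all).
#' @param trackNames Track channel order (default [reinTrackNames()]).
#' @param halfFlank Half window width (default 300).
#' @param zeroFill If `TRUE`, tracks absent from `tracks` contribute
#'   all-zero rows instead of raising an error.
#' @return Numeric array `channels x window x nodes` with channel dimnames.
#' @export
buildLinearFeatures <- function(graph, genome, tracks, nodes = NULL,
                                trackNames = reinTrackNames(),
                                halfFlank = 300L, zeroFill = FALSE) {
  missing <- checkTracks(tracks, trackNames, zeroFill)
  win <- nodeWindows(graph, nodes, halfFlank)
  n <- length(win)
  w <- 2L * halfFlank
  seqs <- genomeSequence(genome, win)
  arr <- array(0, dim = c(4L + length(trackNames), w, n),
               dimnames = list(c("A", "T", "C", "G", trackNames), NULL,
                               names(win)))
  for (i in seq_len(n)) arr[1:4, , i] <- oneHotEncode(seqs[i])
  for (k in seq_along(trackNames)) {
    nm <- trackNames[k]
    if (nm %in% missing) next
    arr[4L + k, , ] <- signalMatrix(tracks[[nm]], win)
  }
  arr
}

#' Build the 10-d node descriptors
#'
#' The GraphSAGE input for each node: `log1p(degree)` (self-loops
#' excluded), a self-loop indicator, `log1p(anchor length)` and the mean
#' window signal of seven anchor-associated tracks (CTCF, POLR2A, RAD21,
#' SMC3, H3K27me3, H3K27ac, H3K4me3).  Uses only information available for
#' unlabeled nodes, so descriptors carry no label leakage.
#'
#' @param graph A [REINGraph-class].
#' @param tracks Named list of [SignalTrack-class] objects.
#' @param halfFlank Half window width for the signal means (default 300).
#' @param zeroFill If `TRUE`, absent descriptor tracks contribute zeros.
#' @return Numeric matrix `n_nodes x 10` with node-id rownames.
#' @export
buildNodeDescriptors <- function(graph, tracks, halfFlank = 300L,
                                 zeroFill = FALSE) {
  dtracks <- descriptorTrackNames()
  missing <- checkTracks(tracks, dtracks, zeroFill)
  n <- length(graph@nodes)
  e <- graph@edges
  self <- e[, 1L] == e[, 2L]
  deg <- tabulate(e[!self, ], nbins = n)
  selfFlag <- as.numeric(tabulate(e[self, 1L], nbins = n) > 0L)
  win <- nodeWindows(graph, NULL, halfFlank)
  d <- matrix(0, nrow = n, ncol = 3L + length(dtracks),
              dimnames = list(names(graph@nodes),
                              c("log1p_degree", "self_loop", "log1p_length",
                                paste0("mean_", dtracks))))
  d[, 1L] <- log1p(deg)
  d[, 2L] <- selfFlag
  d[, 3L] <- log1p(width(graph@nodes))
  for (k in seq_along(dtracks)) {
    nm <- dtracks[k]
    if (nm %in% missing) next
    d[, 3L + k] <- colMeans(signalMatrix(tracks[[nm]], win))
  }
  d
}

#' Assemble model features for a graph
#'
#' Convenience wrapper building both the linear tensor (for `nodes`) and
#' the descriptors (for all nodes) into one [REINFeatures-class] object.
#'
#' @inheritParams buildLinearFeatures
#' @return A [REINFeatures-class].
#' @export
buildFeatures <- function(graph, genome, tracks, nodes = NULL,
                          trackNames = reinTrackNames(), halfFlank = 300L,
                          zeroFill = FALSE) {
  lin <- buildLinearFeatures(graph, genome, tracks, nodes, trackNames,
                             halfFlank, zeroFill)
  desc <- buildNodeDescriptors(graph, tracks, halfFlank, zeroFill)
  new("REINFeatures", linear = lin, linearNodes = dimnames(lin)[[3L]],
      descriptors = desc, trackNames = trackNames)
}
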