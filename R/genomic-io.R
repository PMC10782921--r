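## File formats are consumed in their native 0-based half-open convention
## (BED/BEDPE/bedGraph) and converted exactly once, here, to the 1-based
## closed convention of GRanges.  length([a,b)) == b - a == width(GRanges).

bed0ToGRanges <- function(chrom, start0, end0, ...) {
  GRanges(chrom, IRanges(start = start0 + 1L, end = end0), ...)
}

grangesToBed0 <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
             end = end(gr), stringsAsFactors = FALSE)
}

#' Read chromatin loops from a BEDPE file
#'
#' Parses a tab-separated BEDPE file (6+ columns) into paired loop anchors.
#' Column 8, when present and numeric, is taken as the PET support count.
#' Lines starting with `#` are skipped.  Inter-chromosomal pairs are either
#' skipped with a warning (default) or rejected, since the interaction
#' network is built from intra-chromosomal loops only.
#'
#' @param path Path to a BEDPE file.
#' @param strict If `TRUE`, an inter-chromosomal pair is an error instead of
#'   a skipped record.
#' @return A [S4Vectors::Pairs] object of anchor `GRanges`, with a `support`
#'   metadata column (`NA` where absent).
#' @seealso [writeBedpe()], [filterLoops()], [buildREIN()]
#' @export
readBedpe <- function(path, strict = FALSE) {
  if (!file.exists(path)) stopf("BEDPE file not found: %s", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    gr0 <- GRanges()
    return(S4Vectors::Pairs(gr0, gr0, support = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stopf("malformed BEDPE line %d: fewer than 6 tab-separated columns",
          lineno[which(nf < 6L)[1L]])
  getcol <- function(i) vapply(fields, `[[`, character(1L), i)
  chromA <- getcol(1L); chromB <- getcol(4L)
  startA <- suppressWarnings(as.integer(getcol(2L)))
  endA <- suppressWarnings(as.integer(getcol(3L)))
  startB <- suppressWarnings(as.integer(getcol(5L)))
  endB <- suppressWarnings(as.integer(getcol(6L)))
  bad <- is.na(startA) | is.na(endA) | is.na(startB) | is.na(endB)
  if (any(bad))
    stopf("malformed BEDPE line %d: non-numeric coordinate", lineno[which(bad)[1L]])
  bad <- startA < 0L | startB < 0L | endA <= startA | endB <= startB
  if (any(bad))
    stopf("malformed BEDPE line %d: invalid interval (need 0 <= start < end)",
          lineno[which(bad)[1L]])
  support <- rep(NA_integer_, length(lines))
  has8 <- nf >= 8L
  if (any(has8)) {
    s8 <- suppressWarnings(as.integer(vapply(fields[has8], `[[`, character(1L), 8L)))
    support[has8] <- s8
  }
  inter <- chromA != chromB
  if (any(inter)) {
    if (strict)
      stopf("inter-chromosomal pair at BEDPE line %d", lineno[which(inter)[1L]])
    warnf("skipping %d inter-chromosomal pair(s)", sum(inter))
  }
  keep <- !inter
  S4Vectors::Pairs(bed0ToGRanges(chromA[keep], startA[keep], endA[keep]),
                   bed0ToGRanges(chromB[keep], startB[keep], endB[keep]),
                   support = support[keep])
}

#' Write chromatin loops to a BEDPE file
#'
#' @param loops A `Pairs` of anchor `GRanges` as returned by [readBedpe()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedpe <- function(loops, path) {
  a <- grangesToBed0(S4Vectors::first(loops))
  b <- grangesToBed0(S4Vectors::second(loops))
  support <- mcols(loops)$support
  if (is.null(support)) support <- rep(NA_integer_, length(loops))
  df <- cbind(a, b, name = ".", support = ifelse(is.na(support), ".",
                                                 as.character(support)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read regulatory elements from a BED file
#'
#' Reads BED3+ records; the element class is taken from column 4 unless a
#' single class is supplied for the whole file via `classMap`.
#'
#' @param path Path to a BED file.
#' @param classMap Either `NULL` (class token read from column 4) or a single
#'   class name applied to every record.
#' @return A `GRanges` with a `label` factor column over the four element
#'   classes.
#' @seealso [elementClasses()], [normalizeElements()], [assignLabels()]
#' @export
readBedElements <- function(path, classMap = NULL) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  gr <- rtracklayer::import(path, format = "bed")
  if (!is.null(classMap)) {
    if (length(classMap) != 1L || !classMap %in% elementClasses())
      stopf("classMap must be one of: %s", paste(elementClasses(), collapse = ", "))
    lab <- rep(classMap, length(gr))
  } else {
    lab <- gr$name
    if (is.null(lab) || anyNA(lab))
      stopf("BED file lacks a class token in column 4; pass classMap")
    bad <- !lab %in% elementClasses()
    if (any(bad))
      stopf("unknown element class token '%s'; allowed tokens: %s",
            lab[which(bad)[1L]], paste(elementClasses(), collapse = ", "))
  }
  out <- granges(gr)
  mcols(out) <- NULL
  out$label <- factor(lab, levels = elementClasses())
  out
}

#' Write regulatory elements to a BED file
#'
#' @param elements `GRanges` with a `label` column, as from
#'   [readBedElements()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedElements <- function(elements, path) {
  df <- grangesToBed0(elements)
  df$name <- as.character(elements$label)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a signal track from a bedGraph file
#'
#' @param path Path to a 4-column bedGraph file.
#' @param name Assay name to attach to the track; defaults to the file name
#'   without extension.
#' @return A [SignalTrack-class]; overlapping records are rejected because
#'   the per-base signal would be ambiguous.
#' @seealso [signalAt()], [extractSignalWindow()]
#' @export
readBedgraph <- function(path, name = NULL) {
  if (!file.exists(path)) stopf("bedGraph file not found: %s", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gr <- rtracklayer::import(path, format = "bedGraph")
  SignalTrack(name, gr)
}

#' Write a signal track to a bedGraph file
#'
#' @param track A [SignalTrack-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedgraph <- function(track, path) {
  df <- grangesToBed0(track@ranges)
  df$score <- format(track@ranges$score, trim = TRUE, scientific = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Query a signal track at single bases
#'
#' @param track A [SignalTrack-class].
#' @param chrom Chromosome name.
#' @param pos0 Integer vector of 0-based base positions.
#' @return Numeric vector of signal values; uncovered bases read 0.
#' @export
signalAt <- function(track, chrom, pos0) {
  q <- GRanges(chrom, IRanges(pos0 + 1L, pos0 + 1L))
  hits <- findOverlaps(q, track@ranges)
  out <- numeric(length(pos0))
  out[queryHits(hits)] <- track@ranges$score[subjectHits(hits)]
  out
}

#' Load a genome from a FASTA file
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return An uppercase [Biostrings::DNAStringSet] named by chromosome.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Extract window sequences from a genome
#'
#' Returns the uppercase sequence of each query interval; any part of a
#' window that falls outside the chromosome reads as `N`, so all returned
#' strings have exactly the query width.
#'
#' @param genome `DNAStringSet` from [readGenome()].
#' @param gr Query `GRanges`.
#' @return Character vector of sequences, one per range.
#' @export
genomeSequence <- function(genome, gr) {
  chroms <- as.character(seqnames(gr))
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing) > 0L)
    stopf("chromosome(s) absent from genome: %s", paste(missing, collapse = ", "))
  vapply(seq_along(gr), function(i) {
    s <- start(gr)[i]; e <- end(gr)[i]
    chromSeq <- genome[[chroms[i]]]
    cl <- length(chromSeq)
    si <- max(1L, s); ei <- min(cl, e)
    core <- if (si <= ei) toupper(as.character(Biostrings::subseq(chromSeq, si, ei))) else ""
    paste0(strrep("N", si - s), core, strrep("N", e - ei))
  }, character(1L))
}
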