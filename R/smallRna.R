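#' Collect 5' and 3' read-end coordinates from alignments
#'
#' For a plus-strand alignment the 5' end is the leftmost aligned base and
#' the 3' end the rightmost; reversed for minus-strand alignments.
#' Soft-clipped bases are excluded (alignment coordinates only). Accepts
#' either a data.frame of placements (columns \code{start, end, strand};
#' 1-based inclusive — e.g. from \code{\link{simulateSmallRna}}), a
#' \code{GAlignments} object, or a SAM/BAM file path (primary mapped
#' records only).
#'
#' @param alignments Placements as described above.
#' @param locusLen Locus length in nt.
#' @return An \linkS4class{EndHistogram}.
#' @export
collectEnds <- function(alignments, locusLen) {
  if (is.character(alignments) && length(alignments) == 1L)
    alignments <- readSamAlignments(alignments)
  if (is(alignments, "GAlignments")) {
    alignments <- data.frame(
      start = BiocGenerics::start(alignments),
      end = BiocGenerics::end(alignments),
      strand = as.character(BiocGenerics::strand(alignments)),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("start", "end", "strand") %in% names(alignments)))
  aln <- alignments[alignments$strand %in% c("+", "-"), , drop = FALSE]
  bad <- aln$start < 1 | aln$end > locusLen | aln$end < aln$start
  if (any(bad)) {
    warning(sum(bad), " malformed alignment record(s) skipped")
    aln <- aln[!bad, , drop = FALSE]
  }
  five <- ifelse(aln$strand == "+", aln$start, aln$end)
  three <- ifelse(aln$strand == "+", aln$end, aln$start)
  tab <- function(pos, strand, type) {
    if (!length(pos)) return(NULL)
    ag <- aggregate(list(count = rep(1L, length(pos))),
                    by = list(pos = pos, strand = strand), FUN = sum)
    ag$type <- type
    ag
  }
  ends <- rbind(tab(five, aln$strand, "five_prime"),
                tab(three, aln$strand, "three_prime"))
  if (is.null(ends))
    ends <- data.frame(pos = integer(0), strand = character(0),
                       type = character(0), count = integer(0))
  new("EndHistogram", ends = ends[, c("pos", "strand", "type", "count")],
      reads = aln[, c("start", "end", "strand")],
      locusLen = as.integer(locusLen))
}

## call processing sites for one strand/end-type: local maxima of the end
## histogram (greedy peak pruning within +/- window), count >= minSupport
.callSites <- function(ends, minSupport, window) {
  cand <- ends[ends$count >= minSupport, , drop = FALSE]
  if (!nrow(cand)) return(integer(0))
  cand <- cand[order(-cand$count, cand$pos), , drop = FALSE]
  sites <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!length(sites) || all(abs(sites - cand$pos[i]) > window))
      sites <- c(sites, cand$pos[i])
  }
  sort(sites)
}

#' Reconstruct RNA species from end histograms
#'
#' Calls 5' and 3' processing sites as local maxima of the strand-specific
#' end histograms (the maximum within \code{+/- endWindow}, with at least
#' \code{minSupport} reads), then pairs each 5' site with every
#' transcriptionally downstream 3' site on the same strand whose implied
#' length falls in \code{lenBand} and whose joint support — reads whose
#' both ends lie within \code{endWindow} of the respective sites — reaches
#' \code{minSupport}. One species is reported per supported pair.
#'
#' @param hist An \linkS4class{EndHistogram}.
#' @param minSupport Minimum site and joint read support (default 5).
#' @param endWindow Site-calling / end-matching window in nt (default 3).
#' @param lenBand Allowed species length range in nt, inclusive (default
#'   c(40, 130), the standard small-RNA length filter).
#' @return A \code{GRanges} (seqname \code{"locus"}) with metadata column
#'   \code{support}; zero-length when nothing is called.
#' @export
reconstructSpecies <- function(hist, minSupport = 5L, endWindow = 3L,
                               lenBand = c(40L, 130L)) {
  stopifnot(is(hist, "EndHistogram"), minSupport >= 1L)
  ends <- endCounts(hist)
  reads <- readIntervals(hist)
  out <- list()
  for (st in c("+", "-")) {
    e5 <- ends[ends$strand == st & ends$type == "five_prime", ]
    e3 <- ends[ends$strand == st & ends$type == "three_prime", ]
    s5 <- .callSites(e5, minSupport, endWindow)
    s3 <- .callSites(e3, minSupport, endWindow)
    if (!length(s5) || !length(s3)) next
    rd <- reads[reads$strand == st, , drop = FALSE]
    r5 <- if (st == "+") rd$start else rd$end
    r3 <- if (st == "+") rd$end else rd$start
    for (a in s5) for (b in s3) {
      lo <- min(a, b); hi <- max(a, b)
      len <- hi - lo + 1L
      ok <- if (st == "+") b >= a else b <= a
      if (!ok || len < lenBand[1] || len > lenBand[2]) next
      support <- sum(abs(r5 - a) <= endWindow & abs(r3 - b) <= endWindow)
      if (support < minSupport) next
      out[[length(out) + 1L]] <- data.frame(start = lo, end = hi,
                                            strand = st, support = support)
    }
  }
  if (!length(out))
    return(GenomicRanges::GRanges(seqnames = character(0),
                                  ranges = IRanges::IRanges()))
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end), ]
  GenomicRanges::GRanges("locus", IRanges::IRanges(df$start, df$end),
                         strand = df$strand, support = df$support)
}

#' Annotate RNA species against a CRISPR array and tracrRNA region
#'
#' A species overlapping exactly one spacer is annotated as the mature
#' crRNA of that spacer (indexed from the transcription-proximal end of
#' the array), with the lengths of its spacer-derived and repeat-derived
#' segments. A species overlapping the tracrRNA region is annotated
#' tracrRNA with its product length; everything else is "other", including
#' species spanning two or more spacers (with a warning).
#'
#' @param species \code{GRanges} from \code{\link{reconstructSpecies}}.
#' @param array A \linkS4class{CrisprArray}.
#' @param tracrRegion \code{IRanges} (or \code{GRanges}) of the tracrRNA
#'   gene region; may be empty.
#' @param txStrand Transcription strand of the array, used for crRNA
#'   indexing: on \code{"-"} the rightmost spacer is spacer 1. Defaults to
#'   the majority strand of the species.
#' @return The input \code{GRanges} with added metadata columns
#'   \code{annotation} ("crRNA", "tracrRNA" or "other"), \code{crIndex},
#'   \code{spacerPartLen}, \code{drPartLen}, \code{productLen}.
#' @export
annotateSpecies <- function(species, array, tracrRegion = IRanges::IRanges(),
                            txStrand = NULL) {
  stopifnot(is(array, "CrisprArray"))
  if (is(tracrRegion, "GRanges"))
    tracrRegion <- IRanges::ranges(tracrRegion)
  n <- length(species)
  annotation <- rep("other", n)
  crIndex <- spacerPartLen <- drPartLen <- productLen <- rep(NA_integer_, n)
  if (n == 0L) {
    S4Vectors::mcols(species)[, c("annotation", "crIndex", "spacerPartLen",
                                  "drPartLen", "productLen")] <-
      list(character(0), integer(0), integer(0), integer(0), integer(0))
    return(species)
  }
  if (is.null(txStrand)) {
    st <- as.character(BiocGenerics::strand(species))
    txStrand <- if (sum(st == "-") >= sum(st == "+")) "-" else "+"
  }
  spc <- spacerRanges(array)
  reps <- repeatRanges(array)
  spR <- IRanges::ranges(species)
  ovSp <- IRanges::findOverlaps(spR, spc)
  ovTr <- if (length(tracrRegion))
    IRanges::findOverlaps(spR, tracrRegion) else NULL
  nSpacerHits <- tabulate(S4Vectors::queryHits(ovSp), n)
  multi <- which(nSpacerHits >= 2L)
  if (length(multi))
    warning(length(multi), " species overlap >= 2 spacers; annotated 'other'")
  for (i in which(nSpacerHits == 1L)) {
    j <- S4Vectors::subjectHits(ovSp)[S4Vectors::queryHits(ovSp) == i]
    annotation[i] <- "crRNA"
    crIndex[i] <- if (txStrand == "-") length(spc) - j + 1L else j
    ivl <- IRanges::IRanges(BiocGenerics::start(spR[i]),
                            BiocGenerics::end(spR[i]))
    spacerPartLen[i] <- sum(IRanges::width(IRanges::intersect(ivl, spc[j])))
    drPartLen[i] <- sum(IRanges::width(IRanges::intersect(ivl, reps)))
  }
  if (!is.null(ovTr) && length(ovTr)) {
    trHit <- unique(S4Vectors::queryHits(ovTr))
    trHit <- trHit[annotation[trHit] != "crRNA"]
    annotation[trHit] <- "tracrRNA"
    productLen[trHit] <- IRanges::width(spR)[trHit]
  }
  S4Vectors::mcols(species)$annotation <- annotation
  S4Vectors::mcols(species)$crIndex <- crIndex
  S4Vectors::mcols(species)$spacerPartLen <- spacerPartLen
  S4Vectors::mcols(species)$drPartLen <- drPartLen
  S4Vectors::mcols(species)$productLen <- productLen
  species
}

#' Call the transcription orientation of a CRISPR array
#'
#' The strand carrying the majority of array-overlapping reads wins;
#' confidence is the majority fraction. The call is withheld when the
#' confidence does not exceed 0.5 by more than \code{margin}, or when no
#' read overlaps the array.
#'
#' @param hist An \linkS4class{EndHistogram}.
#' @param array A \linkS4class{CrisprArray}.
#' @param margin Required excess over 0.5 (default 0.05).
#' @return A list: \code{arrayStrand} (\code{"+"}, \code{"-"} or
#'   \code{NA}), \code{readCountPlus}, \code{readCountMinus},
#'   \code{confidence}, \code{called}, \code{status}.
#' @export
callOrientation <- function(hist, array, margin = 0.05) {
  stopifnot(is(hist, "EndHistogram"), is(array, "CrisprArray"))
  reads <- readIntervals(hist)
  reps <- repeatRanges(array)
  lo <- min(BiocGenerics::start(reps)); hi <- max(BiocGenerics::end(reps))
  ov <- reads$end >= lo & reads$start <= hi
  nPlus <- sum(ov & reads$strand == "+")
  nMinus <- sum(ov & reads$strand == "-")
  tot <- nPlus + nMinus
  if (tot == 0L)
    return(list(arrayStrand = NA_character_, readCountPlus = 0L,
                readCountMinus = 0L, confidence = NA_real_,
                called = FALSE, status = "uncalled: no array-overlapping reads"))
  conf <- max(nPlus, nMinus) / tot
  if (conf <= 0.5 + margin)
    return(list(arrayStrand = NA_character_, readCountPlus = nPlus,
                readCountMinus = nMinus, confidence = conf,
                called = FALSE, status = "uncalled: below confidence margin"))
  list(arrayStrand = if (nPlus > nMinus) "+" else "-",
       readCountPlus = nPlus, readCountMinus = nMinus,
       confidence = conf, called = TRUE, status = "called")
}
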