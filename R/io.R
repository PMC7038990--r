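#' Read a FASTQ file with qualities
#'
#' Thin wrapper over Biostrings' FASTQ reader returning a
#' \code{QualityScaledDNAStringSet} (Phred+33). Gzipped input is accepted.
#'
#' @param path FASTQ file path.
#' @return A \code{QualityScaledDNAStringSet}.
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  ## the reader constructs its result from a DNAStringSet carrying internal
  ## metadata columns, emitting a harmless drop warning; muffle just that
  out <- withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path),
      error = function(e) stop("malformed FASTQ '", path, "': ",
                               conditionMessage(e))),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  seqs <- as(out, "DNAStringSet")
  S4Vectors::mcols(seqs) <- NULL
  Biostrings::QualityScaledDNAStringSet(seqs, Biostrings::quality(out))
}

#' Write FASTQ records
#'
#' @param seqs Character vector of read sequences.
#' @param quals Character vector of Phred+33 quality strings (same
#'   lengths as \code{seqs}).
#' @param ids Read identifiers.
#' @param path Output path (".gz" suffix gzip-compresses).
#' @return \code{path}, invisibly.
#' @export
writeFastqRecords <- function(seqs, quals, ids, path) {
  stopifnot(length(seqs) == length(quals), length(seqs) == length(ids))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  invisible(path)
}

#' Read primary mapped alignments from SAM or BAM
#'
#' SAM input is converted to BAM via Rsamtools; secondary, supplementary
#' and unmapped records are dropped. Coordinates are 1-based inclusive and
#' exclude soft clips.
#'
#' @param path SAM or BAM file path.
#' @return A \code{GAlignments} object.
#' @export
readSamAlignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flag))
}

#' Write simulated placements as a SAM file
#'
#' Emits one primary record per placement with a pure-match CIGAR, so the
#' file round-trips exactly through \code{\link{readSamAlignments}} and
#' \code{\link{collectEnds}}.
#'
#' @param alignments data.frame with \code{start, end, strand} (1-based
#'   inclusive).
#' @param locusSeq Locus sequence (character).
#' @param path Output SAM path.
#' @param locusName Reference name in the header.
#' @return \code{path}, invisibly.
#' @export
writeSamAlignments <- function(alignments, locusSeq, path,
                               locusName = "locus") {
  L <- nchar(locusSeq)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", locusName, L))
  w <- alignments$end - alignments$start + 1L
  seqs <- substr(rep(locusSeq, nrow(alignments)),
                 alignments$start, alignments$end)
  minus <- alignments$strand == "-"
  if (any(minus)) seqs[minus] <- .revComp(seqs[minus])
  rec <- sprintf("read%06d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                 seq_len(nrow(alignments)), ifelse(minus, 16L, 0L),
                 locusName, alignments$start, w, seqs, strrep("I", w))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write a CRISPR array as TSV (one row per unit), GFF3 and JSON summary
#'
#' Reports use 1-based inclusive coordinates (the internal convention).
#'
#' @param arrays List of \linkS4class{CrisprArray}.
#' @param antiRepeats Optional \code{GRanges} from
#'   \code{\link{findAntiRepeat}}.
#' @param prefix Output path prefix; writes \code{<prefix>.tsv},
#'   \code{<prefix>.gff3} and \code{<prefix>.json}.
#' @return Named character vector of the written paths, invisibly.
#' @export
writeArrayReport <- function(arrays, prefix, antiRepeats = NULL) {
  rows <- list(); feats <- list()
  for (ai in seq_along(arrays)) {
    a <- arrays[[ai]]
    r <- repeatRanges(a); s <- spacerRanges(a)
    for (i in seq_along(r)) {
      rows[[length(rows) + 1L]] <- data.frame(
        array = ai, contig = a@contigId, strand = a@strand, unit = i,
        repeat_start = BiocGenerics::start(r)[i],
        repeat_end = BiocGenerics::end(r)[i],
        spacer_start = if (i <= length(s)) BiocGenerics::start(s)[i] else NA,
        spacer_end = if (i <= length(s)) BiocGenerics::end(s)[i] else NA,
        repeat_consensus = repeatConsensus(a))
    }
    feats[[length(feats) + 1L]] <- GenomicRanges::GRanges(
      a@contigId, r, strand = a@strand, type = "repeat_unit",
      ID = sprintf("array%d_repeat%d", ai, seq_along(r)))
    if (length(s))
      feats[[length(feats) + 1L]] <- GenomicRanges::GRanges(
        a@contigId, s, strand = a@strand, type = "spacer",
        ID = sprintf("array%d_spacer%d", ai, seq_along(s)))
  }
  if (!is.null(antiRepeats) && length(antiRepeats)) {
    ar <- antiRepeats
    S4Vectors::mcols(ar) <- S4Vectors::DataFrame(
      type = "anti_repeat",
      ID = sprintf("anti_repeat%d", seq_along(ar)))
    feats[[length(feats) + 1L]] <- ar
  }
  tsv <- paste0(prefix, ".tsv"); gff <- paste0(prefix, ".gff3")
  js <- paste0(prefix, ".json")
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(array = integer(0))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(feats)) {
    gr <- suppressWarnings(do.call(c, feats))
    rtracklayer::export(gr, gff, format = "GFF3")
  } else writeLines("##gff-version 3", gff)
  summary <- lapply(seq_along(arrays), function(ai) {
    a <- arrays[[ai]]
    list(array = ai, contig = a@contigId, n_repeats = nRepeats(a),
         repeat_consensus = repeatConsensus(a),
         spacer_lengths = spacerLengths(a))
  })
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, gff3 = gff, json = js))
}

#' Write per-PAM counts as TSV
#'
#' Columns: \code{pam}, \code{count}.
#' @param counts A \linkS4class{PamCountTable}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCountsTsv <- function(counts, path) {
  cnt <- pamCounts(counts)
  write.table(data.frame(pam = names(cnt), count = unname(cnt)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a DepletionTable as TSV
#'
#' Fixed columns: pam, count_exp, count_ctrl, freq_exp, freq_ctrl,
#' depletion_score, chi2, p_one_sided, depleted_flag.
#' @param table A \linkS4class{DepletionTable}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeDepletionTsv <- function(table, path) {
  s <- depletionStats(table)
  names(s) <- c("pam", "count_exp", "count_ctrl", "freq_exp", "freq_ctrl",
                "depletion_score", "chi2", "p_one_sided", "depleted_flag")
  write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a PositionProfile as TSV
#'
#' Long format: position, base, depletion_value, freq_exp, freq_ctrl,
#' freq_depleted_set.
#' @param profile A \linkS4class{PositionProfile}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writePositionProfileTsv <- function(profile, path) {
  dv <- profile@depletionValue
  df <- expand.grid(position = seq_len(nrow(dv)), base = colnames(dv),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- cbind(df$position, match(df$base, colnames(dv)))
  df$depletion_value <- dv[idx]
  df$freq_exp <- profile@freqExp[idx]
  df$freq_ctrl <- profile@freqCtrl[idx]
  df$freq_depleted_set <- profile@freqDepleted[idx]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write end histograms as BedGraph (one track per strand and end type)
#'
#' @param hist An \linkS4class{EndHistogram}.
#' @param prefix Output prefix; writes four files
#'   \code{<prefix>.<type>.<strand>.bedgraph} (0-based half-open intervals,
#'   the BedGraph convention).
#' @param locusName Reference name.
#' @return Character vector of written paths, invisibly.
#' @export
writeEndBedgraph <- function(hist, prefix, locusName = "locus") {
  e <- endCounts(hist)
  paths <- character(0)
  for (ty in c("five_prime", "three_prime")) for (st in c("+", "-")) {
    sel <- e[e$type == ty & e$strand == st, , drop = FALSE]
    p <- sprintf("%s.%s.%s.bedgraph", prefix, ty,
                 if (st == "+") "plus" else "minus")
    df <- data.frame(chrom = rep(locusName, nrow(sel)),
                     start = sel$pos - 1L, end = sel$pos,
                     count = sel$count)
    df <- df[order(df$start), ]
    write.table(df, p, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write annotated RNA species as a BED-like TSV
#'
#' Columns: chrom, start, end, strand, length, support, annotation,
#' cr_index, spacer_part_len, dr_part_len, product_len (1-based inclusive
#' start/end, as in all human-readable reports).
#' @param species Annotated \code{GRanges} from
#'   \code{\link{annotateSpecies}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeSpeciesTsv <- function(species, path) {
  mc <- S4Vectors::mcols(species)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(species)),
    start = BiocGenerics::start(species), end = BiocGenerics::end(species),
    strand = as.character(BiocGenerics::strand(species)),
    length = BiocGenerics::width(species),
    support = mc$support, annotation = mc$annotation,
    cr_index = mc$crIndex, spacer_part_len = mc$spacerPartLen,
    dr_part_len = mc$drPartLen, product_len = mc$productLen)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a screen design from JSON or YAML
#'
#' Expects keys \code{left_anchor}, \code{right_anchor} and optionally
#' \code{degenerate_len}, \code{pam_side}. YAML needs the yaml package.
#'
#' @param path JSON (.json) or YAML (.yaml/.yml) file.
#' @return A \linkS4class{ScreenDesign}.
#' @export
readScreenDesign <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML input needs the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("left_anchor", "right_anchor"))
    if (is.null(cfg[[key]])) stop("design file misses key: ", key)
  screenDesign(cfg$left_anchor, cfg$right_anchor,
               degenerateLen = cfg$degenerate_len %||% 7L,
               pamSide = cfg$pam_side %||% "3prime")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
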