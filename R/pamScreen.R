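#' Filter reads by mean Phred quality
#'
#' Retains exactly the reads whose arithmetic mean Phred score is at least
#' \code{minMeanQ} (boundary inclusive), preserving input order. This is
#' the standard first step of screen-read processing.
#'
#' @param reads A \code{QualityScaledDNAStringSet} (e.g. from
#'   \code{\link{readFastq}}) or a FASTQ file path.
#' @param minMeanQ Minimum mean Phred score (default 20).
#' @return The filtered \code{QualityScaledDNAStringSet}, with attribute
#'   \code{nInput} giving the input read count.
#' @examples
#' qs <- Biostrings::QualityScaledDNAStringSet(
#'   Biostrings::DNAStringSet(c(a = "ACGT")),
#'   Biostrings::PhredQuality("IIII"))
#' length(qcFilterReads(qs, 20))
#' @export
qcFilterReads <- function(reads, minMeanQ = 20) {
  if (is.character(reads)) reads <- readFastq(reads)
  if (!is(reads, "QualityScaledDNAStringSet"))
    stop("reads must be a QualityScaledDNAStringSet or a FASTQ path")
  n <- length(reads)
  if (n == 0L) {
    out <- reads
    attr(out, "nInput") <- 0L
    return(out)
  }
  q <- as(Biostrings::quality(reads), "IntegerList")
  meanQ <- sum(q) / lengths(q)
  out <- reads[meanQ >= minMeanQ]
  attr(out, "nInput") <- n
  out
}

## mean Phred per read, exposed for tests/reporting
meanPhred <- function(reads) {
  q <- as(Biostrings::quality(reads), "IntegerList")
  sum(q) / lengths(q)
}

## locate `anchor` in each read allowing <= maxMM mismatches; returns the
## start of the first hit whose downstream right-anchor also matches.
.anchorReads <- function(seqs, design, maxMM) {
  la <- design@leftAnchor; ra <- design@rightAnchor
  dl <- design@degenerateLen
  laLen <- nchar(la); raLen <- nchar(ra)
  pam <- rep(NA_character_, length(seqs))
  hits <- Biostrings::vmatchPattern(la, Biostrings::DNAStringSet(seqs),
                                    max.mismatch = maxMM, with.indels = FALSE)
  starts <- IRanges::start(hits)
  idx <- which(lengths(starts) > 0L)
  if (!length(idx)) return(pam)
  maxRank <- max(lengths(starts[idx]))
  unresolved <- idx
  for (r in seq_len(maxRank)) {
    if (!length(unresolved)) break
    cand <- unresolved[lengths(starts[unresolved]) >= r]
    if (!length(cand)) break
    s <- vapply(starts[cand], `[`, integer(1), r)
    pamStart <- s + laLen
    raStart <- pamStart + dl
    ok <- raStart + raLen - 1L <= nchar(seqs[cand])
    candOk <- cand[ok]
    if (length(candOk)) {
      raSub <- substr(seqs[candOk], raStart[ok], raStart[ok] + raLen - 1L)
      mm <- .hammingToPattern(raSub, ra)
      pamSub <- substr(seqs[candOk], pamStart[ok], pamStart[ok] + dl - 1L)
      good <- !is.na(mm) & mm <= maxMM & !grepl("[^ACGT]", pamSub)
      pam[candOk[good]] <- pamSub[good]
      unresolved <- setdiff(unresolved, candOk[good])
    }
  }
  pam
}

#' Extract the degenerate PAM region from anchored reads
#'
#' For each read (or its reverse complement), locates the fixed left and
#' right anchors of the screen construct, each with at most
#' \code{maxAnchorMismatches} mismatches and separated by exactly
#' \code{degenerateLen} unambiguous bases, and tallies the intervening PAM
#' word. Reads that fail anchoring on both strands are counted but
#' discarded, mirroring the "unmapped reads discarded" step of a
#' mapping-based workflow.
#'
#' @param reads A \code{QualityScaledDNAStringSet}, \code{DNAStringSet},
#'   character vector of read sequences, or FASTQ path. Reads should
#'   already be QC-filtered (see \code{\link{qcFilterReads}}).
#' @param design A \linkS4class{ScreenDesign}.
#' @param maxAnchorMismatches Per-anchor mismatch budget (default 2).
#' @param sampleId Sample label for the resulting table.
#' @param nReadsTotal Optional pre-QC read count for the accounting chain;
#'   defaults to \code{length(reads)} (i.e. QC happened upstream).
#' @param minAnchoredFrac Warn (not error) when fewer than this fraction of
#'   reads anchor.
#' @return A \linkS4class{PamCountTable}.
#' @export
extractPamRegions <- function(reads, design, maxAnchorMismatches = 2L,
                              sampleId = "sample", nReadsTotal = NULL,
                              minAnchoredFrac = 0.5) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- readFastq(reads)
  seqs <- if (is(reads, "XStringSet")) as.character(reads) else as.character(reads)
  seqs <- toupper(unname(seqs))
  nPass <- length(seqs)
  if (is.null(nReadsTotal)) nReadsTotal <- nPass
  pam <- character(0)
  if (nPass) {
    pam <- .anchorReads(seqs, design, maxAnchorMismatches)
    miss <- which(is.na(pam))
    if (length(miss)) {
      rc <- .revComp(seqs[miss])
      pam[miss] <- .anchorReads(rc, design, maxAnchorMismatches)
    }
    pam <- pam[!is.na(pam)]
  }
  if (nPass > 0 && length(pam) / nPass < minAnchoredFrac)
    warning(sprintf("only %.1f%% of reads anchored (threshold %.0f%%)",
                    100 * length(pam) / nPass, 100 * minAnchoredFrac))
  counts <- if (length(pam)) table(pam) else integer(0)
  counts <- setNames(as.integer(counts), names(counts))
  pamCountTable(counts, sampleId = sampleId,
                nReadsTotal = as.integer(nReadsTotal),
                nReadsPassQC = as.integer(nPass),
                nReadsAnchored = length(pam),
                degenerateLen = design@degenerateLen)
}

## Pearson chi-square on the 2x2 table [c1, n1-c1; c2, n2-c2], vectorized.
## Returns 0 for degenerate margins (no information).
.chisq2x2 <- function(c1, n1, c2, n2) {
  a <- c1; b <- n1 - c1; cc <- c2; d <- n2 - c2
  N <- n1 + n2
  num <- N * (a * d - b * cc)^2
  den <- (a + cc) * (b + d) * as.numeric(n1) * as.numeric(n2)
  out <- ifelse(den > 0, num / den, 0)
  as.numeric(out)
}

#' Per-PAM depletion statistics from experimental vs control counts
#'
#' Joins the two count tables over the union of PAM words and computes, per
#' word: pseudocounted frequencies, the log2 control/experimental frequency
#' ratio (depletion score), the Pearson chi-square statistic of the 2x2
#' variant-vs-rest-of-library table, and a one-sided p-value. One-sidedness
#' is the upper normal tail of the signed square root of the chi-square
#' statistic, with positive sign when the variant is rarer in the
#' experimental sample — so variants enriched in the experiment get
#' p >= 0.5. This is equivalent to the one-sided two-proportion z-test.
#'
#' @param exp,ctrl \linkS4class{PamCountTable}s for the selected
#'   (experimental) and unselected (control) samples.
#' @param pseudocount Added to every count for frequencies and scores
#'   (default 0.5); the chi-square uses raw counts.
#' @param pThreshold Significance threshold stored with the table and used
#'   for \code{depletedFlag} (default 1e-12).
#' @return A \linkS4class{DepletionTable}.
#' @export
computeDepletion <- function(exp, ctrl, pseudocount = 0.5,
                             pThreshold = 1e-12) {
  stopifnot(is(exp, "PamCountTable"), is(ctrl, "PamCountTable"))
  if (exp@degenerateLen != ctrl@degenerateLen)
    stop("count tables come from different screen designs")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  ce <- pamCounts(exp); cc <- pamCounts(ctrl)
  if (!length(cc)) stop("control table is empty")
  if (!length(ce)) stop("experimental table is empty")
  keys <- sort(union(names(ce), names(cc)))
  countExp <- ifelse(keys %in% names(ce), ce[keys], 0L)
  countCtrl <- ifelse(keys %in% names(cc), cc[keys], 0L)
  countExp[is.na(countExp)] <- 0L; countCtrl[is.na(countCtrl)] <- 0L
  nExp <- sum(countExp); nCtrl <- sum(countCtrl)
  if (nExp == 0L || nCtrl == 0L) stop("zero total counts")
  freqExp <- (countExp + pseudocount) / (nExp + pseudocount * length(keys))
  freqCtrl <- (countCtrl + pseudocount) / (nCtrl + pseudocount * length(keys))
  depletionScore <- log2(freqCtrl / freqExp)
  chi2 <- .chisq2x2(countExp, nExp, countCtrl, nCtrl)
  sgn <- sign(countCtrl / nCtrl - countExp / nExp)
  pOneSided <- pnorm(sgn * sqrt(chi2), lower.tail = FALSE)
  pOneSided <- pmin(pmax(pOneSided, .Machine$double.xmin), 1)
  depletedFlag <- freqExp < freqCtrl & pOneSided < pThreshold
  stats <- data.frame(pam = unname(keys), countExp = unname(countExp),
                      countCtrl = unname(countCtrl),
                      freqExp = unname(freqExp), freqCtrl = unname(freqCtrl),
                      depletionScore = unname(depletionScore),
                      chi2 = unname(chi2), pOneSided = unname(pOneSided),
                      depletedFlag = unname(depletedFlag),
                      stringsAsFactors = FALSE)
  new("DepletionTable", stats = stats, nExp = as.integer(nExp),
      nCtrl = as.integer(nCtrl), pseudocount = pseudocount,
      pThreshold = pThreshold)
}

#' Call significantly depleted PAM variants
#'
#' Returns exactly the variants with experimental frequency below control
#' and one-sided p-value below the threshold (the negative-selection call).
#'
#' @param table A \linkS4class{DepletionTable}.
#' @param pThreshold Significance threshold (default 1e-12).
#' @return Character vector of depleted PAM words.
#' @export
callDepleted <- function(table, pThreshold = 1e-12) {
  stopifnot(is(table, "DepletionTable"))
  if (pThreshold <= 0 || pThreshold >= 1)
    stop("pThreshold must lie in (0, 1)")
  s <- depletionStats(table)
  s$pam[s$freqExp < s$freqCtrl & s$pOneSided < pThreshold]
}

#' Positional depletion profile
#'
#' For each PAM position i and base b, the count-weighted frequency of b at
#' i in each sample, F_s(i, b) (pseudocounted per position), and the
#' positional depletion value log2(F_ctrl / F_exp). Also reports the
#' unweighted base frequencies at each position within the depleted set,
#' the basis for consensus calling and the sequence logo.
#'
#' @param table A \linkS4class{DepletionTable}.
#' @param depleted Character vector of depleted PAM words; defaults to the
#'   table's own flagged set. May be empty, in which case only the
#'   depletion-weighted part of the profile is populated.
#' @param pseudocount Per-cell pseudocount (default 0.5).
#' @return A \linkS4class{PositionProfile}.
#' @export
positionDepletion <- function(table, depleted = NULL, pseudocount = 0.5) {
  stopifnot(is(table, "DepletionTable"))
  s <- depletionStats(table)
  if (is.null(depleted)) depleted <- depletedPams(table)
  len <- nchar(s$pam[1])
  cntExp <- .positionBaseCounts(s$pam, s$countExp, len)
  cntCtrl <- .positionBaseCounts(s$pam, s$countCtrl, len)
  fExp <- (cntExp + pseudocount) / rowSums(cntExp + pseudocount)
  fCtrl <- (cntCtrl + pseudocount) / rowSums(cntCtrl + pseudocount)
  dv <- log2(fCtrl / fExp)
  if (length(depleted)) {
    cntDep <- .positionBaseCounts(depleted, len = len)
    fDep <- cntDep / rowSums(cntDep)
  } else {
    fDep <- matrix(NA_real_, nrow = len, ncol = 4,
                   dimnames = list(seq_len(len), DNA_BASES))
  }
  new("PositionProfile", depletionValue = dv, freqExp = fExp,
      freqCtrl = fCtrl, freqDepleted = fDep,
      nDepleted = length(depleted))
}

#' Call the IUPAC PAM consensus from depleted-set base frequencies
#'
#' Per position, collects bases greedily by descending frequency within the
#' depleted set (alphabetical order on ties) until their summed frequency
#' reaches \code{dominanceThreshold}, then emits the IUPAC code of that
#' set. A position whose greedy set needs three or more bases carries no
#' usable constraint at screen resolution and is reported as N.
#'
#' @param profile A \linkS4class{PositionProfile} with a non-empty depleted
#'   set, or a position x base frequency matrix.
#' @param dominanceThreshold Summed-frequency threshold in (0.25, 1]
#'   (default 0.75).
#' @return A \linkS4class{PamConsensus}.
#' @export
callConsensus <- function(profile, dominanceThreshold = 0.75) {
  if (dominanceThreshold <= 0.25 || dominanceThreshold > 1)
    stop("dominanceThreshold must lie in (0.25, 1]")
  fDep <- if (is(profile, "PositionProfile")) profile@freqDepleted else profile
  if (any(is.na(fDep)))
    stop("depleted-set frequencies unavailable (empty depleted set)")
  sets <- vector("list", nrow(fDep))
  codes <- character(nrow(fDep))
  for (i in seq_len(nrow(fDep))) {
    f <- fDep[i, DNA_BASES]
    ord <- order(-f, DNA_BASES)   # descending freq, alphabetical ties
    cum <- cumsum(f[ord])
    k <- which(cum >= dominanceThreshold - 1e-12)[1]
    if (is.na(k)) k <- 4L
    bases <- DNA_BASES[ord][seq_len(k)]
    if (length(bases) >= 3L) bases <- DNA_BASES  # no constraint -> N
    sets[[i]] <- bases
    codes[i] <- iupacCode(bases)
  }
  new("PamConsensus", iupac = paste(codes, collapse = ""),
      dominanceThreshold = dominanceThreshold, baseSets = sets)
}
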