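#' ScreenDesign: geometry of a randomized-PAM screen construct
#'
#' Describes the amplicon layout of a degenerate-PAM library: a fixed left
#' anchor, a randomized region of \code{degenerateLen} nucleotides, and a
#' fixed right anchor. The randomized region is read on the non-target
#' strand immediately downstream (3') of the protospacer in the default
#' design.
#'
#' @slot leftAnchor,rightAnchor Fixed flanking sequences (upper-case DNA).
#' @slot degenerateLen Length of the randomized region (default 7).
#' @slot pamSide Which side of the protospacer carries the PAM,
#'   \code{"3prime"} or \code{"5prime"}; informational.
#' @export
setClass("ScreenDesign",
  representation(leftAnchor = "character", rightAnchor = "character",
                 degenerateLen = "integer", pamSide = "character"),
  prototype(degenerateLen = 7L, pamSide = "3prime"))

setValidity("ScreenDesign", function(object) {
  msg <- character()
  if (nchar(object@leftAnchor) < 12L || nchar(object@rightAnchor) < 12L)
    msg <- c(msg, "anchors must each be at least 12 nt")
  if (grepl("[^ACGT]", object@leftAnchor) || grepl("[^ACGT]", object@rightAnchor))
    msg <- c(msg, "anchors must be plain A/C/G/T")
  if (object@degenerateLen < 1L)
    msg <- c(msg, "degenerateLen must be >= 1")
  if (!object@pamSide %in% c("3prime", "5prime"))
    msg <- c(msg, "pamSide must be '3prime' or '5prime'")
  if (length(msg)) msg else TRUE
})

#' Construct a ScreenDesign
#'
#' @param leftAnchor,rightAnchor Fixed sequences flanking the randomized
#'   region (at least 12 nt each).
#' @param degenerateLen Number of randomized nucleotides between the anchors.
#' @param pamSide \code{"3prime"} (default) or \code{"5prime"}.
#' @return A \linkS4class{ScreenDesign} object.
#' @examples
#' screenDesign("GACGTTGTAAAACGACGGCC", "CATGGTCATAGCTGTTTCCT")
#' @export
screenDesign <- function(leftAnchor, rightAnchor, degenerateLen = 7L,
                         pamSide = "3prime") {
  new("ScreenDesign",
      leftAnchor = .checkDna(leftAnchor, "leftAnchor"),
      rightAnchor = .checkDna(rightAnchor, "rightAnchor"),
      degenerateLen = as.integer(degenerateLen), pamSide = pamSide)
}

setMethod("show", "ScreenDesign", function(object) {
  cat("ScreenDesign:", object@leftAnchor, "-",
      strrep("N", object@degenerateLen), "-", object@rightAnchor,
      sprintf("(PAM %s of protospacer)\n", object@pamSide))
})

#' PamCountTable: per-sample PAM variant counts with QC metadata
#'
#' Maps each observed PAM word to its read count for one sample, together
#' with the read-accounting chain: total reads, reads passing the mean-Q
#' filter, and reads whose anchors were located (only the last contribute
#' counts).
#'
#' @slot sampleId Sample label.
#' @slot counts Named integer vector, names are PAM words.
#' @slot degenerateLen PAM word length.
#' @slot nReadsTotal,nReadsPassQC,nReadsAnchored Read accounting;
#'   \code{sum(counts) == nReadsAnchored <= nReadsPassQC <= nReadsTotal}.
#' @export
setClass("PamCountTable",
  representation(sampleId = "character", counts = "integer",
                 degenerateLen = "integer", nReadsTotal = "integer",
                 nReadsPassQC = "integer", nReadsAnchored = "integer"))

setValidity("PamCountTable", function(object) {
  msg <- character()
  cnt <- object@counts
  if (length(cnt) && is.null(names(cnt)))
    msg <- c(msg, "counts must be named by PAM word")
  if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(cnt) && any(nchar(names(cnt)) != object@degenerateLen))
    msg <- c(msg, "all PAM words must have length degenerateLen")
  if (length(cnt) && any(grepl("[^ACGT]", names(cnt))))
    msg <- c(msg, "PAM words must be over A/C/G/T")
  if (sum(cnt) != object@nReadsAnchored)
    msg <- c(msg, "sum(counts) must equal nReadsAnchored")
  if (object@nReadsAnchored > object@nReadsPassQC ||
      object@nReadsPassQC > object@nReadsTotal)
    msg <- c(msg, "require nReadsAnchored <= nReadsPassQC <= nReadsTotal")
  if (length(msg)) msg else TRUE
})

#' Construct a PamCountTable
#'
#' @param counts Named integer vector of per-PAM read counts.
#' @param sampleId Sample label.
#' @param nReadsTotal,nReadsPassQC,nReadsAnchored Read accounting; default
#'   to \code{sum(counts)} (counts-only provenance, e.g. simulation).
#' @param degenerateLen PAM word length; inferred from names by default.
#' @return A \linkS4class{PamCountTable}.
#' @export
pamCountTable <- function(counts, sampleId = "sample",
                          nReadsTotal = NULL, nReadsPassQC = NULL,
                          nReadsAnchored = NULL, degenerateLen = NULL) {
  counts <- counts[counts > 0]
  storage.mode(counts) <- "integer"
  if (is.null(degenerateLen))
    degenerateLen <- if (length(counts)) nchar(names(counts)[1]) else 7L
  tot <- sum(counts)
  if (is.null(nReadsAnchored)) nReadsAnchored <- tot
  if (is.null(nReadsPassQC)) nReadsPassQC <- nReadsAnchored
  if (is.null(nReadsTotal)) nReadsTotal <- nReadsPassQC
  new("PamCountTable", sampleId = sampleId, counts = counts,
      degenerateLen = as.integer(degenerateLen),
      nReadsTotal = as.integer(nReadsTotal),
      nReadsPassQC = as.integer(nReadsPassQC),
      nReadsAnchored = as.integer(nReadsAnchored))
}

setMethod("show", "PamCountTable", function(object) {
  cat(sprintf(
    "PamCountTable '%s': %d distinct %d-mers, %d anchored / %d passQC / %d total reads\n",
    object@sampleId, length(object@counts), object@degenerateLen,
    object@nReadsAnchored, object@nReadsPassQC, object@nReadsTotal))
})

#' DepletionTable: joined per-PAM depletion statistics
#'
#' One row per PAM word (union of experimental and control keys):
#' counts, pseudocounted frequencies, log2 depletion score, Pearson
#' chi-square statistic from the variant-vs-rest 2x2 table, one-sided
#' p-value, and the significance flag at the stored threshold.
#'
#' @slot stats data.frame with columns \code{pam, countExp, countCtrl,
#'   freqExp, freqCtrl, depletionScore, chi2, pOneSided, depletedFlag}.
#' @slot nExp,nCtrl Total anchored reads per sample.
#' @slot pseudocount Pseudocount used for frequencies and scores.
#' @slot pThreshold Significance threshold used for \code{depletedFlag}.
#' @export
setClass("DepletionTable",
  representation(stats = "data.frame", nExp = "integer", nCtrl = "integer",
                 pseudocount = "numeric", pThreshold = "numeric"))

setValidity("DepletionTable", function(object) {
  need <- c("pam", "countExp", "countCtrl", "freqExp", "freqCtrl",
            "depletionScore", "chi2", "pOneSided", "depletedFlag")
  msg <- character()
  if (!all(need %in% names(object@stats)))
    msg <- c(msg, paste("stats must have columns:", paste(need, collapse = ", ")))
  else {
    s <- object@stats
    if (abs(sum(s$freqExp) - 1) > 1e-9 || abs(sum(s$freqCtrl) - 1) > 1e-9)
      msg <- c(msg, "frequencies must each sum to 1")
    if (any(s$chi2 < 0)) msg <- c(msg, "chi2 must be non-negative")
    if (any(s$pOneSided <= 0 | s$pOneSided > 1))
      msg <- c(msg, "pOneSided must lie in (0, 1]")
    bad <- s$depletedFlag & !(s$freqExp < s$freqCtrl & s$pOneSided < object@pThreshold)
    if (any(bad)) msg <- c(msg, "depletedFlag inconsistent with its definition")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "DepletionTable", function(object) {
  cat(sprintf(
    "DepletionTable: %d PAM variants, %d flagged depleted at p < %.3g (nExp=%d, nCtrl=%d)\n",
    nrow(object@stats), sum(object@stats$depletedFlag), object@pThreshold,
    object@nExp, object@nCtrl))
})

#' PositionProfile: per-position, per-base depletion values
#'
#' For each PAM position and nucleotide: the log2 ratio of control to
#' experimental count-weighted base frequencies (pseudocounted), plus the
#' unweighted base frequencies within the depleted set.
#'
#' @slot depletionValue,freqExp,freqCtrl Position x base (A,C,G,T) matrices.
#' @slot freqDepleted Position x base frequencies within the depleted set
#'   (all-NA when the depleted set is empty).
#' @slot nDepleted Size of the depleted set used.
#' @export
setClass("PositionProfile",
  representation(depletionValue = "matrix", freqExp = "matrix",
                 freqCtrl = "matrix", freqDepleted = "matrix",
                 nDepleted = "integer"))

setMethod("show", "PositionProfile", function(object) {
  cat(sprintf("PositionProfile over %d positions (depleted set: %d PAMs)\n",
              nrow(object@depletionValue), object@nDepleted))
  am <- which(object@depletionValue == max(object@depletionValue),
              arr.ind = TRUE)[1, ]
  cat(sprintf("  max depletion value %.3f at position %d, base %s\n",
              max(object@depletionValue), am[1], colnames(object@depletionValue)[am[2]]))
})

#' PamConsensus: IUPAC consensus of the depleted PAM set
#'
#' @slot iupac IUPAC string, one code per PAM position.
#' @slot dominanceThreshold Summed-frequency threshold used per position.
#' @slot baseSets List of the per-position base sets behind each code.
#' @export
setClass("PamConsensus",
  representation(iupac = "character", dominanceThreshold = "numeric",
                 baseSets = "list"))

setMethod("show", "PamConsensus", function(object) {
  cat(sprintf("PamConsensus: 5'-%s-3' (dominance threshold %.2f)\n",
              object@iupac, object@dominanceThreshold))
})

#' LogoMatrix: sequence-logo probabilities and information content
#'
#' @slot prob Position x base probability matrix (rows sum to 1).
#' @slot informationContent Per-position information content in bits,
#'   computed as 2 - Shannon entropy (no small-sample correction).
#' @slot nSequences Number of sequences (or total weight) behind the logo.
#' @export
setClass("LogoMatrix",
  representation(prob = "matrix", informationContent = "numeric",
                 nSequences = "numeric"))

setValidity("LogoMatrix", function(object) {
  msg <- character()
  if (any(abs(rowSums(object@prob) - 1) > 1e-9))
    msg <- c(msg, "per-position probabilities must sum to 1")
  ic <- object@informationContent
  if (any(ic < -1e-9 | ic > 2 + 1e-9))
    msg <- c(msg, "information content must lie in [0, 2] bits")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LogoMatrix", function(object) {
  cat(sprintf("LogoMatrix over %d positions; IC (bits):\n",
              nrow(object@prob)))
  print(round(object@informationContent, 3))
})

#' CrisprArray: a detected repeat-spacer array
#'
#' Ordered repeat and spacer intervals (1-based, inclusive) on one contig,
#' with the consensus of the repeat copies. The last repeat is not followed
#' by a spacer, so \code{length(spacers) == length(repeats) - 1} for a
#' complete array.
#'
#' @slot contigId Contig the array lies on.
#' @slot strand Strand the array was reported on (\code{"+"} or \code{"-"};
#'   detection reports the strand as given, transcription orientation is a
#'   downstream small-RNA call).
#' @slot repeats,spacers \linkS4class{IRanges} of repeat and spacer units.
#' @slot repeatConsensus Majority-rule consensus of the repeat copies.
#' @export
setClass("CrisprArray",
  representation(contigId = "character", strand = "character",
                 repeats = "IRanges", spacers = "IRanges",
                 repeatConsensus = "character"))

setValidity("CrisprArray", function(object) {
  msg <- character()
  r <- object@repeats; s <- object@spacers
  if (length(r) < 2L) msg <- c(msg, "an array needs at least 2 repeats")
  if (length(s) != length(r) - 1L)
    msg <- c(msg, "need exactly one spacer between consecutive repeats")
  if (is.unsorted(IRanges::start(r)))
    msg <- c(msg, "repeats must be sorted by start")
  if (length(r) > 1L &&
      any(IRanges::start(r)[-1] <= IRanges::end(r)[-length(r)]))
    msg <- c(msg, "repeat intervals must be non-overlapping")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CrisprArray", function(object) {
  r <- object@repeats
  cat(sprintf(
    "CrisprArray on %s[%s]: %d repeats (%d bp consensus), %d spacers (%s bp), span %d-%d\n",
    object@contigId, object@strand, length(r),
    nchar(object@repeatConsensus), length(object@spacers),
    paste(unique(range(IRanges::width(object@spacers))), collapse = "-"),
    min(IRanges::start(r)), max(IRanges::end(r))))
})

#' EndHistogram: strand-specific 5'/3' read-end coordinate counts
#'
#' Built from alignments; keeps both the aggregated end histograms and the
#' per-read intervals (needed for joint-support species calling).
#'
#' @slot ends data.frame with columns \code{pos, strand, type
#'   ("five_prime"/"three_prime"), count}.
#' @slot reads data.frame with columns \code{start, end, strand}, one row
#'   per used alignment (1-based, inclusive).
#' @slot locusLen Length of the locus the reads were aligned to.
#' @export
setClass("EndHistogram",
  representation(ends = "data.frame", reads = "data.frame",
                 locusLen = "integer"))

setValidity("EndHistogram", function(object) {
  msg <- character()
  e <- object@ends
  if (!all(c("pos", "strand", "type", "count") %in% names(e)))
    msg <- c(msg, "ends needs columns pos, strand, type, count")
  else {
    if (any(e$count < 0)) msg <- c(msg, "counts must be non-negative")
    for (st in unique(e$strand)) {
      n5 <- sum(e$count[e$strand == st & e$type == "five_prime"])
      n3 <- sum(e$count[e$strand == st & e$type == "three_prime"])
      if (n5 != n3)
        msg <- c(msg, sprintf("5' and 3' totals differ on strand %s", st))
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EndHistogram", function(object) {
  cat(sprintf("EndHistogram: %d alignments over a %d nt locus (%d end sites)\n",
              nrow(object@reads), object@locusLen, nrow(object@ends)))
})

#' RecognitionModel: planted PAM-recognition rules for simulation
#'
#' Survival of a library member through selection (colony formation in an
#' interference screen, or escaping cleavage in vitro) as a function of its
#' PAM word. Required rules gate recognition entirely; preferred rules
#' interpolate linearly between the unrecognized and recognized survival by
#' their strength.
#'
#' @slot rules data.frame with columns \code{position, bases, mode
#'   ("required"/"preferred"), strength}.
#' @slot baseSurvival Survival probability of an unrecognized PAM.
#' @slot recognizedSurvival Survival probability of a fully recognized PAM
#'   (must be below \code{baseSurvival}: recognized members are depleted).
#' @export
setClass("RecognitionModel",
  representation(rules = "data.frame", baseSurvival = "numeric",
                 recognizedSurvival = "numeric"))

setValidity("RecognitionModel", function(object) {
  msg <- character()
  r <- object@rules
  if (nrow(r)) {
    if (!all(c("position", "bases", "mode", "strength") %in% names(r)))
      msg <- c(msg, "rules needs columns position, bases, mode, strength")
    else {
      if (!all(r$mode %in% c("required", "preferred")))
        msg <- c(msg, "rule mode must be 'required' or 'preferred'")
      if (any(r$strength < 0 | r$strength > 1))
        msg <- c(msg, "rule strengths must lie in [0, 1]")
      if (any(grepl("[^ACGT]", r$bases)))
        msg <- c(msg, "rule bases must be over A/C/G/T")
    }
  }
  if (object@recognizedSurvival >= object@baseSurvival)
    msg <- c(msg, "recognizedSurvival must be < baseSurvival (depletion)")
  if (object@baseSurvival <= 0 || object@baseSurvival > 1 ||
      object@recognizedSurvival < 0)
    msg <- c(msg, "survival probabilities must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a RecognitionModel
#'
#' @param rules data.frame of recognition rules (\code{position} 1-based in
#'   the PAM, \code{bases} e.g. \code{"G"} or \code{"AG"}, \code{mode}
#'   \code{"required"} or \code{"preferred"}, \code{strength} in [0,1];
#'   ignored for required rules).
#' @param baseSurvival,recognizedSurvival Survival of unrecognized and fully
#'   recognized PAMs.
#' @return A \linkS4class{RecognitionModel}.
#' @examples
#' recognitionModel(data.frame(position = 5, bases = "G", mode = "required",
#'                             strength = 1))
#' @export
recognitionModel <- function(rules = data.frame(), baseSurvival = 1.0,
                             recognizedSurvival = 0.05) {
  if (nrow(rules) && !"strength" %in% names(rules)) rules$strength <- 1
  new("RecognitionModel", rules = rules,
      baseSurvival = as.numeric(baseSurvival),
      recognizedSurvival = as.numeric(recognizedSurvival))
}

setMethod("show", "RecognitionModel", function(object) {
  cat(sprintf("RecognitionModel: survival %.3g (unrecognized) -> %.3g (recognized)\n",
              object@baseSurvival, object@recognizedSurvival))
  if (nrow(object@rules)) {
    with(object@rules, cat(sprintf("  pos %d: %s [%s, strength %.2f]\n",
                                   position, bases, mode, strength), sep = ""))
  }
})
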