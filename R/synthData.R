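#' Default screen construct design for simulation
#'
#' A generic amplicon layout: 60 nt backbone, 20 nt left anchor, the
#' randomized region, 20 nt right anchor, 60 nt backbone. The anchor and
#' backbone sequences are arbitrary fixed words (no natural plasmid
#' sequence), chosen once for the package.
#'
#' @param degenerateLen Randomized-region length (default 7).
#' @return A list with the \code{design} (\linkS4class{ScreenDesign}) and
#'   the \code{backbone5}/\code{backbone3} context sequences.
#' @export
defaultScreenDesign <- function(degenerateLen = 7L) {
  list(
    design = screenDesign(
      leftAnchor  = "GACGTTGTAAAACGACGGCC",
      rightAnchor = "CATGGTCATAGCTGTTTCCT",
      degenerateLen = degenerateLen),
    backbone5 = paste0("TTGCGTATTGGGCGCTCTTCCGCTTCCTCGCTCACTGACTCGCTGCGCTC",
                       "GGTCGTTCGG"),
    backbone3 = paste0("CTGCGGCGAGCGGTATCAGCTCACTCAAAGGCGGTAATACGGTTATCCAC",
                       "AGAATCAGGG"))
}

#' Read model for simulated sequencing
#'
#' @param readLen Read length in nt (default 150).
#' @param meanQ,qSd Mean and SD of the per-base Phred quality (clipped
#'   normal, clipped to [2, 40]).
#' @param subErrorFromQ If TRUE, each base is substituted with probability
#'   10^(-Q/10) given its drawn quality.
#' @return A list of class parameters used by the simulators.
#' @export
readModel <- function(readLen = 150L, meanQ = 30, qSd = 3,
                      subErrorFromQ = TRUE) {
  list(readLen = as.integer(readLen), meanQ = meanQ, qSd = qSd,
       subErrorFromQ = isTRUE(subErrorFromQ))
}

#' Survival probability of a PAM under a planted recognition model
#'
#' If any required rule fails, the member is unrecognized and survives with
#' \code{baseSurvival}. Otherwise the survival interpolates linearly
#' between base and recognized survival: each matched preferred rule
#' contributes its full effect, each unmatched preferred rule scales the
#' recognition effect by (1 - strength). With required rules only, a full
#' match survives with \code{recognizedSurvival} exactly.
#'
#' @param pam Character vector of PAM words.
#' @param model A \linkS4class{RecognitionModel}.
#' @return Numeric vector of survival probabilities in [0, 1].
#' @examples
#' m <- recognitionModel(data.frame(position = 7, bases = "A",
#'                                  mode = "preferred", strength = 0.5),
#'                       baseSurvival = 1, recognizedSurvival = 0.2)
#' survivalProbability("AAAAAAA", m)  # 0.6
#' @export
survivalProbability <- function(pam, model) {
  stopifnot(is(model, "RecognitionModel"))
  if (any(grepl("[^ACGT]", pam))) stop("invalid base in PAM")
  rules <- model@rules
  eff <- rep(1, length(pam))  # recognition efficacy in [0, 1]
  if (nrow(rules)) {
    for (j in seq_len(nrow(rules))) {
      b <- substr(pam, rules$position[j], rules$position[j])
      matched <- vapply(b, grepl, logical(1), x = rules$bases[j], fixed = TRUE)
      if (rules$mode[j] == "required") {
        eff[!matched] <- 0
      } else {
        eff[!matched] <- eff[!matched] * (1 - rules$strength[j])
      }
    }
  }
  model@baseSurvival + eff * (model@recognizedSurvival - model@baseSurvival)
}

## draw per-base qualities and apply substitution errors to a character
## vector of read sequences; returns list(seqs, quals as Phred+33 strings)
.applyReadModel <- function(seqs, rm) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  q <- matrix(pmin(40L, pmax(2L, as.integer(round(
    rnorm(n * L, rm$meanQ, rm$qSd))))), nrow = n)
  if (rm$subErrorFromQ) {
    pErr <- 10^(-q / 10)
    err <- matrix(runif(n * L) < pErr, nrow = n)
    if (any(err)) {
      chars <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                      nrow = n, byrow = TRUE)
      idx <- which(err)
      # substitute with one of the three other bases, uniformly
      repl <- vapply(chars[idx], function(b)
        sample(setdiff(DNA_BASES, b), 1L), character(1))
      chars[idx] <- repl
      seqs <- apply(chars, 1, paste, collapse = "")
    }
  }
  quals <- substring(paste(rawToChar(as.raw(33L + as.vector(t(q)))), collapse = ""),
                     seq(1, n * L, by = L), seq(L, n * L, by = L))
  list(seqs = seqs, quals = quals)
}

#' Simulate a randomized-PAM depletion screen
#'
#' Draws control molecule counts from a uniform multinomial over the
#' library and experimental counts from a multinomial with weights
#' proportional to each member's survival probability under the planted
#' recognition model. In \code{output = "counts"} mode the multinomial
#' counts are returned directly as \linkS4class{PamCountTable}s (the
#' statistical model with no read plumbing, suitable for large-n
#' simulations); in \code{output = "fastq"} mode each molecule becomes a
#' read built as backbone-anchor-PAM-anchor-backbone with per-base
#' qualities and substitution errors per the read model, written to FASTQ.
#'
#' @param model A \linkS4class{RecognitionModel}.
#' @param nMoleculesExp,nMoleculesCtrl Sampled molecules per sample.
#' @param library Character vector of library members; defaults to the full
#'   degenerate library of the design's \code{degenerateLen}.
#' @param design A \linkS4class{ScreenDesign}; default
#'   \code{defaultScreenDesign()}.
#' @param rm A \code{\link{readModel}} (FASTQ mode only).
#' @param seed Integer seed; all randomness is derived from it.
#' @param output \code{"counts"} or \code{"fastq"}.
#' @param dir Output directory for FASTQ mode.
#' @return A list with elements \code{exp} and \code{ctrl}
#'   (\linkS4class{PamCountTable}s in counts mode; FASTQ paths in fastq
#'   mode) and \code{truth} (seed, per-member survival and expected
#'   frequencies — sufficient for downstream checks).
#' @export
simulateScreen <- function(model, nMoleculesExp, nMoleculesCtrl,
                           library = NULL, design = NULL, rm = readModel(),
                           seed = 1L, output = c("counts", "fastq"),
                           dir = tempdir()) {
  output <- match.arg(output)
  ds <- if (is.null(design)) defaultScreenDesign()$design else design
  if (is.null(library)) library <- enumeratePamLibrary(ds@degenerateLen)
  if (any(nchar(library) != ds@degenerateLen))
    stop("library member length does not match the design")
  .setSeedIfGiven(seed)
  surv <- survivalProbability(library, model)
  pCtrl <- rep(1 / length(library), length(library))
  pExp <- surv / sum(surv)
  cntCtrl <- as.integer(rmultinom(1, nMoleculesCtrl, pCtrl))
  cntExp <- as.integer(rmultinom(1, nMoleculesExp, pExp))
  names(cntCtrl) <- names(cntExp) <- library
  truth <- list(seed = seed, library_size = length(library),
                survival = setNames(surv, library),
                expected_freq_exp = setNames(pExp, library),
                expected_freq_ctrl = setNames(pCtrl, library))
  if (output == "counts") {
    return(list(exp = pamCountTable(cntExp, "exp"),
                ctrl = pamCountTable(cntCtrl, "ctrl"),
                truth = truth))
  }
  ctx <- defaultScreenDesign(ds@degenerateLen)
  mk <- function(cnt, stem) {
    pams <- rep(names(cnt), cnt)
    if (length(pams) > 1L) pams <- sample(pams)  # shuffle read order
    construct <- paste0(ctx$backbone5, ds@leftAnchor, pams,
                        ds@rightAnchor, ctx$backbone3)
    reads <- substr(construct, 1L, min(rm$readLen, nchar(construct[1])))
    out <- .applyReadModel(reads, rm)
    path <- file.path(dir, paste0(stem, ".fastq"))
    writeFastqRecords(out$seqs, out$quals,
                      ids = sprintf("%s_read%06d", stem, seq_along(out$seqs)),
                      path = path)
    path
  }
  list(exp = mk(cntExp, "exp"), ctrl = mk(cntCtrl, "ctrl"), truth = truth)
}

#' Build a toy CRISPR locus with known arrays, tracrRNA and small-RNA truth
#'
#' Lays out, left to right: upstream flank, a tracrRNA-encoding region
#' containing an anti-repeat (reverse complement of part of the repeat),
#' a gap standing in for the cas operon promoter region, and a
#' repeat-spacer array of \code{nSpacers + 1} repeats. Transcription of the
#' array and tracrRNA runs on the minus strand (opposite to the cas genes),
#' as in natural Type II-C loci. Mature crRNA species cover the last
#' \code{crSpacerPart} nt of a spacer plus the adjacent
#' \code{crDrPart} nt of the upstream (transcriptionally downstream)
#' repeat; tracrRNA products share a 5' end and vary at the 3' end.
#'
#' @param nSpacers Number of spacers (default 9; repeats = nSpacers + 1).
#' @param repeatLen,spacerLen Unit lengths (defaults 36 and 31 nt).
#' @param crSpacerPart,crDrPart Mature crRNA segment lengths (defaults 25
#'   and 26 nt).
#' @param tracrLens tracrRNA product lengths (default c(70, 90, 107)).
#' @param depth Read depth per species.
#' @param seed Integer seed for the random sequence content.
#' @return A list: \code{sequence} (character), \code{array}
#'   (\linkS4class{CrisprArray}), \code{tracrRegion} (\code{IRanges}),
#'   \code{species} (data.frame with start, end, strand, depth, label) and
#'   \code{repeatSeq}.
#' @export
makeToyLocus <- function(nSpacers = 9L, repeatLen = 36L, spacerLen = 31L,
                         crSpacerPart = 25L, crDrPart = 26L,
                         tracrLens = c(70L, 90L, 107L), depth = 100L,
                         seed = 1L) {
  .setSeedIfGiven(seed)
  rnd <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
  repeatSeq <- rnd(repeatLen)
  spacers <- replicate(nSpacers, rnd(spacerLen))
  flank5 <- rnd(40L)
  antiRep <- .revComp(substr(repeatSeq, 1L, 24L))
  tracrLen <- max(tracrLens) + 13L
  tracrBody <- paste0(rnd(tracrLen - nchar(antiRep) - 10L), antiRep, rnd(10L))
  gap <- rnd(60L)
  arraySeq <- paste0(paste0(rep(repeatSeq, nSpacers), spacers, collapse = ""),
                     repeatSeq)
  flank3 <- rnd(40L)
  sequence <- paste0(flank5, tracrBody, gap, arraySeq, flank3)
  tracrStart <- nchar(flank5) + 1L
  tracrRegion <- IRanges::IRanges(tracrStart, tracrStart + tracrLen - 1L)
  arrayStart <- nchar(flank5) + tracrLen + nchar(gap) + 1L
  period <- repeatLen + spacerLen
  repStarts <- arrayStart + period * (0:nSpacers)
  reps <- IRanges::IRanges(repStarts, width = repeatLen)
  spc <- IRanges::IRanges(IRanges::end(reps)[-(nSpacers + 1L)] + 1L,
                          width = spacerLen)
  array <- new("CrisprArray", contigId = "toy_locus", strand = "+",
               repeats = reps, spacers = spc, repeatConsensus = repeatSeq)
  # crRNA i (array order, left to right): DR_i tail + spacer_i head.
  # Minus-strand transcription: 5' end at the higher coordinate (spacer part).
  crStart <- IRanges::end(reps)[seq_len(nSpacers)] - crDrPart + 1L
  crEnd <- IRanges::start(spc) + crSpacerPart - 1L
  # transcription order: rightmost spacer is transcribed first
  txIndex <- rev(seq_len(nSpacers))
  species <- data.frame(
    start = crStart, end = crEnd, strand = "-", depth = depth,
    label = sprintf("crRNA_%d", txIndex), stringsAsFactors = FALSE)
  species <- species[order(species$start), ]
  # tracr products: shared 5' end at the region's right edge (minus strand)
  t5 <- IRanges::end(tracrRegion) - 3L
  tr <- data.frame(start = t5 - tracrLens + 1L, end = t5, strand = "-",
                   depth = depth,
                   label = sprintf("tracrRNA_%d", tracrLens),
                   stringsAsFactors = FALSE)
  list(sequence = sequence, array = array, tracrRegion = tracrRegion,
       species = rbind(species, tr), repeatSeq = repeatSeq)
}

#' Simulate small-RNA reads from planted RNA species
#'
#' Samples \code{depth} reads per planted species, jittering each end
#' independently and uniformly within \code{+/- endJitter} nt (clamped to
#' the locus). Reads longer than the read model's capacity are truncated
#' at the 3' end and flagged \code{partial} in the truth.
#'
#' @param locus A toy locus as from \code{\link{makeToyLocus}}, or any list
#'   with \code{sequence} and \code{species} elements.
#' @param rm A \code{\link{readModel}}; only \code{readLen} is used as the
#'   capacity cap.
#' @param endJitter Max absolute end displacement in nt (default 0).
#' @param seed Integer seed.
#' @return A list: \code{alignments} (data.frame start, end, strand — the
#'   exact placements), \code{truth} (planted species table with
#'   \code{partial} flags and the seed).
#' @export
simulateSmallRna <- function(locus, rm = readModel(), endJitter = 0L,
                             seed = 1L) {
  .setSeedIfGiven(seed)
  sp <- locus$species
  stopifnot(all(sp$start >= 1), all(sp$end <= nchar(locus$sequence)))
  L <- nchar(locus$sequence)
  rows <- vector("list", nrow(sp))
  partial <- logical(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    d <- sp$depth[i]
    jit <- function() if (endJitter > 0)
      sample(seq(-endJitter, endJitter), d, replace = TRUE) else integer(d)
    s <- rep(sp$start[i], d) + jit()
    e <- rep(sp$end[i], d) + jit()
    s <- pmax(1L, s); e <- pmin(L, e)
    keep <- e > s
    s <- s[keep]; e <- e[keep]
    tooLong <- (e - s + 1L) > rm$readLen
    if (any(tooLong)) {
      partial[i] <- TRUE
      if (sp$strand[i] == "+") e[tooLong] <- s[tooLong] + rm$readLen - 1L
      else s[tooLong] <- e[tooLong] - rm$readLen + 1L
    }
    rows[[i]] <- data.frame(start = s, end = e, strand = sp$strand[i],
                            stringsAsFactors = FALSE)
  }
  truth <- sp
  truth$partial <- partial
  list(alignments = do.call(rbind, rows),
       truth = list(seed = seed, species = truth, endJitter = endJitter))
}
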