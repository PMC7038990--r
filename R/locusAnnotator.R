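#' Detect repeat-spacer arrays in a locus sequence
#'
#' Reimplements CRISPR array detection at locus scale: seed k-mers (k = 8)
#' recurring with a period inside the combined repeat+spacer band nominate
#' candidate repeat runs; each run is then extended greedily to the full
#' repeat under a per-copy mismatch budget against the run consensus.
#' Arrays are reported on the strand as given — transcription orientation
#' is decided downstream from small-RNA data.
#'
#' @param sequence Locus DNA (character or \code{DNAString}).
#' @param repeatLenBand,spacerLenBand Allowed (min, max) repeat and spacer
#'   lengths in nt; defaults 23-50 and 20-60, wide enough for typical
#'   Type II arrays without hard-coding one architecture.
#' @param minUnits Minimum number of repeat copies (default 3).
#' @param maxRepeatMismatches Per-copy mismatch budget against the run
#'   consensus (default 3).
#' @param contigId Contig label for reporting.
#' @param k Seed k-mer length (default 8).
#' @return A list of \linkS4class{CrisprArray} objects sorted by start;
#'   empty list when no array is found.
#' @export
detectArray <- function(sequence, repeatLenBand = c(23L, 50L),
                        spacerLenBand = c(20L, 60L), minUnits = 3L,
                        maxRepeatMismatches = 3L, contigId = "contig",
                        k = 8L) {
  seq <- .checkDna(sequence, "sequence")
  stopifnot(repeatLenBand[1] <= repeatLenBand[2],
            spacerLenBand[1] <= spacerLenBand[2], minUnits >= 2L)
  n <- nchar(seq)
  if (n < minUnits * (repeatLenBand[1] + spacerLenBand[1])) return(list())
  chars <- strsplit(seq, "")[[1]]
  periodMin <- repeatLenBand[1] + spacerLenBand[1]
  periodMax <- repeatLenBand[2] + spacerLenBand[2]

  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  posByKmer <- split(seq_len(n - k + 1L), kmers)
  posByKmer <- posByKmer[lengths(posByKmer) >= minUnits]
  if (!length(posByKmer)) return(list())

  ## chain k-mer occurrences with successive gaps inside the period band
  chains <- list()
  for (pos in posByKmer) {
    used <- logical(length(pos))
    for (i in seq_along(pos)) {
      if (used[i]) next
      chain <- pos[i]
      used[i] <- TRUE
      repeat {
        nxt <- which(!used & pos >= chain[length(chain)] + periodMin &
                       pos <= chain[length(chain)] + periodMax)
        if (!length(nxt)) break
        j <- nxt[1]
        chain <- c(chain, pos[j])
        used[j] <- TRUE
      }
      if (length(chain) >= minUnits) chains[[length(chains) + 1L]] <- chain
    }
  }
  if (!length(chains)) return(list())
  ## longest chains first; drop chains inside an already-claimed footprint
  chains <- chains[order(-lengths(chains), vapply(chains, `[`, integer(1), 1L))]

  claimed <- logical(n)
  arrays <- list()
  for (chain in chains) {
    if (any(claimed[chain])) next
    m <- length(chain)
    gaps <- diff(chain)
    maxRepLen <- min(repeatLenBand[2], min(gaps) - spacerLenBand[1])
    if (maxRepLen < repeatLenBand[1]) next
    budget <- rep(maxRepeatMismatches, m)
    ## greedy per-column extension; a column is accepted when at most one
    ## copy dissents from the column consensus and no copy overruns budget
    extend <- function(offsets, left, right, budget) {
      repeat {
        if (k + left + right >= maxRepLen) break
        tryLeft <- left < maxRepLen  # alternate: prefer left then right
        done <- TRUE
        for (side in c("L", "R")) {
          if (k + left + right >= maxRepLen) break
          colPos <- if (side == "L") offsets - left - 1L
                    else offsets + k + right
          if (any(colPos < 1L | colPos > n)) next
          cc <- chars[colPos]
          tab <- table(factor(cc, levels = DNA_BASES))
          cons <- DNA_BASES[which.max(tab)]
          dissent <- cc != cons
          if (sum(dissent) > 1L) next
          if (any(budget - dissent < 0L)) next
          budget <- budget - dissent
          if (side == "L") left <- left + 1L else right <- right + 1L
          done <- FALSE
        }
        if (done) break
      }
      list(left = left, right = right, budget = budget)
    }
    ext <- extend(chain, 0L, 0L, budget)
    repLen <- k + ext$left + ext$right
    starts <- chain - ext$left
    ends <- starts + repLen - 1L
    if (starts[1] < 1L || ends[m] > n) next
    ## trim terminal columns with any dissent: greedy extension tolerates
    ## one dissenting copy per column, which lets chance agreements in the
    ## flanks creep in at the boundaries
    colUnanimous <- function(off) {
      cc <- chars[starts + off]
      all(cc == cc[1])
    }
    while (repLen > repeatLenBand[1] && !colUnanimous(0L)) {
      starts <- starts + 1L; repLen <- repLen - 1L
    }
    while (repLen > repeatLenBand[1] && !colUnanimous(repLen - 1L)) {
      repLen <- repLen - 1L
    }
    ends <- starts + repLen - 1L
    if (repLen < repeatLenBand[1]) next
    spacerW <- starts[-1] - ends[-m] - 1L
    ## split the run at out-of-band spacers, keep sub-runs >= minUnits
    okGap <- spacerW >= spacerLenBand[1] & spacerW <= spacerLenBand[2]
    runId <- cumsum(c(TRUE, !okGap))
    for (g in split(seq_len(m), runId)) {
      if (length(g) < minUnits) next
      st <- starts[g]; en <- ends[g]
      if (any(claimed[st[1]:en[length(en)]])) next
      copies <- substring(seq, st, en)
      consensus <- .majorityConsensus(copies)
      mm <- .hammingToPattern(copies, consensus)
      if (any(mm > maxRepeatMismatches)) next
      reps <- IRanges::IRanges(st, en)
      spc <- IRanges::IRanges(en[-length(en)] + 1L, st[-1] - 1L)
      arrays[[length(arrays) + 1L]] <-
        new("CrisprArray", contigId = contigId, strand = "+",
            repeats = reps, spacers = spc, repeatConsensus = consensus)
      claimed[st[1]:en[length(en)]] <- TRUE
    }
  }
  arrays[order(vapply(arrays, function(a) IRanges::start(a@repeats)[1],
                      integer(1)))]
}

.majorityConsensus <- function(copies) {
  L <- nchar(copies[1])
  out <- character(L)
  for (i in seq_len(L)) {
    tab <- table(factor(substr(copies, i, i), levels = DNA_BASES))
    out[i] <- DNA_BASES[which.max(tab)]  # alphabetical tie-break
  }
  paste(out, collapse = "")
}

#' Find anti-repeat (tracrRNA) candidates for a repeat consensus
#'
#' Local alignment (match +1, mismatch -1, gap open/extend 2/1) of the
#' repeat consensus against the sequence and its reverse complement,
#' restricted to regions outside the excluded intervals (normally the
#' array's own repeats). A hit on the minus strand corresponds to a region
#' complementary to the repeat — the anti-repeat signature of a tracrRNA
#' gene.
#'
#' @param sequence Locus DNA (character or \code{DNAString}).
#' @param repeatConsensus Repeat consensus sequence.
#' @param exclude \code{IRanges} of intervals to mask (1-based inclusive).
#' @param minMatchedLen Minimum aligned length on the subject (default 15).
#' @param minIdentity Minimum fraction of matching columns in the local
#'   alignment, in [0, 1] (default 0.8).
#' @return A \code{GRanges} with metadata columns \code{matchedLen},
#'   \code{identityFraction} and \code{alignmentScore}, sorted by
#'   descending score; zero-length when nothing passes.
#' @export
findAntiRepeat <- function(sequence, repeatConsensus,
                           exclude = IRanges::IRanges(), minMatchedLen = 15L,
                           minIdentity = 0.8) {
  seq <- .checkDna(sequence, "sequence")
  cons <- .checkDna(repeatConsensus, "repeatConsensus")
  if (minIdentity < 0 || minIdentity > 1) stop("minIdentity must lie in [0, 1]")
  if (minMatchedLen < 1) stop("minMatchedLen must be >= 1")
  n <- nchar(seq)
  keep <- IRanges::setdiff(IRanges::IRanges(1L, n),
                           IRanges::reduce(exclude))
  keep <- keep[IRanges::width(keep) >= minMatchedLen]
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = TRUE)
  scanSegment <- function(segSeq, segStart, strand) {
    hits <- list()
    recurse <- function(s, offset) {
      if (nchar(s) < minMatchedLen) return()
      aln <- Biostrings::pairwiseAlignment(
        cons, s, type = "local", substitutionMatrix = submat,
        gapOpening = 2, gapExtension = 1)
      w <- Biostrings::nchar(aln)  # alignment length incl. gaps
      if (w == 0) return()
      ident <- Biostrings::nmatch(aln) / w
      hs <- BiocGenerics::start(Biostrings::subject(aln))
      he <- BiocGenerics::end(Biostrings::subject(aln))
      mlen <- he - hs + 1L
      if (mlen >= minMatchedLen && ident >= minIdentity) {
        st <- offset + hs - 1L
        en <- offset + he - 1L
        hits[[length(hits) + 1L]] <<- data.frame(
          start = st, end = en, matchedLen = mlen,
          identityFraction = ident,
          alignmentScore = Biostrings::score(aln))
      } else return()
      # recurse on the flanks of the accepted hit
      if (hs - 1L >= minMatchedLen) recurse(substr(s, 1L, hs - 1L), offset)
      if (nchar(s) - he >= minMatchedLen)
        recurse(substr(s, he + 1L, nchar(s)), offset + he)
    }
    recurse(segSeq, 1L)
    if (!length(hits)) return(NULL)
    df <- do.call(rbind, hits)
    if (strand == "+") {
      df$gstart <- segStart + df$start - 1L
      df$gend <- segStart + df$end - 1L
    } else {
      segLen <- nchar(segSeq)
      df$gstart <- segStart + (segLen - df$end)
      df$gend <- segStart + (segLen - df$start)
    }
    df$strand <- strand
    df
  }
  res <- list()
  for (i in seq_along(keep)) {
    st <- IRanges::start(keep)[i]; en <- IRanges::end(keep)[i]
    segSeq <- substr(seq, st, en)
    res[[length(res) + 1L]] <- scanSegment(segSeq, st, "+")
    res[[length(res) + 1L]] <- scanSegment(.revComp(segSeq), st, "-")
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(GenomicRanges::GRanges(seqnames = character(0),
                                  ranges = IRanges::IRanges()))
  df <- do.call(rbind, res)
  df <- df[order(-df$alignmentScore, df$gstart), ]
  GenomicRanges::GRanges(
    seqnames = "locus",
    ranges = IRanges::IRanges(df$gstart, df$gend),
    strand = df$strand,
    matchedLen = df$matchedLen,
    identityFraction = df$identityFraction,
    alignmentScore = df$alignmentScore)
}

#' Score an extended -10 promoter-like element inside a repeat
#'
#' Slides a 9-nt window over the terminal region of the repeat and scores
#' each window against an extended -10 consensus model (default
#' "TGNTATAAT"): the score is the count of consensus-matching positions,
#' with N model positions always matching (and not counted). Ties are
#' broken towards the window closest to the repeat 3' terminus, where the
#' element sits in repeat-embedded promoters.
#'
#' @param repeatConsensus Repeat sequence (>= 9 nt).
#' @param model Consensus model string over A/C/G/T/N (default
#'   \code{"TGNTATAAT"}; configurable since the exact pattern is a modeling
#'   choice).
#' @param terminalRegion Restrict windows to the last this-many nt of the
#'   repeat (default 15).
#' @return A list: \code{score}, \code{windowStartInRepeat} (1-based),
#'   \code{matchedWindow}, \code{model}.
#' @export
scorePromoterMotif <- function(repeatConsensus, model = "TGNTATAAT",
                               terminalRegion = 15L) {
  rep <- .checkDna(repeatConsensus, "repeatConsensus")
  model <- toupper(model)
  if (grepl("[^ACGTN]", model)) stop("model must be over A/C/G/T/N")
  w <- nchar(model)
  L <- nchar(rep)
  if (L < w) stop("repeat shorter than the model window")
  firstStart <- max(1L, L - min(terminalRegion, L) + 1L)
  starts <- firstStart:(L - w + 1L)
  modelChars <- strsplit(model, "")[[1]]
  informative <- modelChars != "N"
  best <- NULL
  for (s in starts) {  # increasing start: later (more 3') windows win ties
    win <- substr(rep, s, s + w - 1L)
    sc <- sum(strsplit(win, "")[[1]][informative] == modelChars[informative])
    if (is.null(best) || sc >= best$score)
      best <- list(score = sc, windowStartInRepeat = s, matchedWindow = win,
                   model = model)
  }
  best
}
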