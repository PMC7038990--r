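#' Build a sequence-logo matrix from a depleted PAM set
#'
#' Per-position base probabilities over the set (each member counted once,
#' as a logo built on a sequence list, unless weights are supplied) and the
#' per-position information content 2 - H in bits (Shannon entropy, log
#' base 2, no small-sample correction).
#'
#' @param depleted Character vector of PAM words (non-empty, equal length).
#' @param weights Optional non-negative per-PAM weights.
#' @return A \linkS4class{LogoMatrix}.
#' @examples
#' informationContent(buildLogoMatrix("AAAAAAA"))  # 2 bits everywhere
#' @export
buildLogoMatrix <- function(depleted, weights = NULL) {
  if (!length(depleted)) stop("depleted set is empty")
  if (length(unique(nchar(depleted))) != 1L)
    stop("all PAM words must have equal length")
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(depleted), all(weights >= 0))
    if (sum(weights) == 0) stop("all weights are zero")
  }
  cnt <- .positionBaseCounts(depleted, weights)
  prob <- cnt / rowSums(cnt)
  h <- apply(prob, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  ic <- pmin(2, pmax(0, 2 - h))
  new("LogoMatrix", prob = prob, informationContent = unname(ic),
      nSequences = if (is.null(weights)) length(depleted) else sum(weights))
}

#' Build the hierarchical PAM wheel geometry
#'
#' Rings correspond to PAM positions in the given inner-to-outer order;
#' each ring's sectors subdivide their parent sector in fixed base order
#' A, C, G, T, with angular spans proportional to the aggregated weight of
#' the base combination. A PAM's weight is its relative depletion:
#' max(0, freqCtrl - freqExp), normalized globally (default) or, as an
#' alternative, the positive log2 depletion score.
#'
#' @param table A \linkS4class{DepletionTable}.
#' @param positions PAM positions, inner ring first (default c(5, 6, 7)).
#' @param weightDef \code{"depletion_fraction"} (default; frequency
#'   difference floored at 0) or \code{"log_ratio"} (positive part of the
#'   log2 depletion score).
#' @param normalize \code{"global"} (spans proportional to overall weight;
#'   default) or \code{"per_ring"} (each parent's children renormalized to
#'   fill the parent span even when the parent aggregate differs).
#'   With proportional allocation the two coincide for spans; the switch
#'   exists because published wheels do not state their convention.
#' @return data.frame with columns \code{ring, position, path, base,
#'   parentPath, weight, startAngle, endAngle} (angles in degrees, full
#'   circle = 360, sectors ordered A < C < G < T within each parent).
#' @export
buildPamWheel <- function(table, positions = c(5L, 6L, 7L),
                          weightDef = c("depletion_fraction", "log_ratio"),
                          normalize = c("global", "per_ring")) {
  weightDef <- match.arg(weightDef)
  normalize <- match.arg(normalize)
  stopifnot(is(table, "DepletionTable"))
  s <- depletionStats(table)
  len <- nchar(s$pam[1])
  if (!length(positions) || any(positions < 1L | positions > len))
    stop("positions must be a non-empty subset of 1..", len)
  w <- switch(weightDef,
              depletion_fraction = pmax(0, s$freqCtrl - s$freqExp),
              log_ratio = pmax(0, s$depletionScore))
  if (sum(w) == 0) stop("nothing depleted to draw: all weights are zero")
  w <- w / sum(w)
  ## aggregate weights over the selected positions' base combinations
  combo <- vapply(positions, function(p) substr(s$pam, p, p), character(nrow(s)))
  if (is.null(dim(combo))) combo <- matrix(combo, nrow = nrow(s))
  rows <- list()
  alloc <- function(prefixBases, ring, parentPath, span, keep, parentW) {
    if (ring > length(positions)) return()
    width <- span[2] - span[1]
    cursor <- span[1]
    for (b in DNA_BASES) {
      sel <- keep & combo[, ring] == b
      wb <- sum(w[sel])
      ## spans always partition the parent proportionally; the switch only
      ## changes the reported weight (global fraction vs within-parent)
      frac <- if (parentW > 0) wb / parentW else 0
      childSpan <- c(cursor, cursor + frac * width)
      path <- paste0(parentPath, b)
      rows[[length(rows) + 1L]] <<- data.frame(
        ring = ring, position = positions[ring], path = path, base = b,
        parentPath = parentPath,
        weight = if (normalize == "global") wb else frac,
        startAngle = childSpan[1], endAngle = childSpan[2],
        stringsAsFactors = FALSE)
      alloc(c(prefixBases, b), ring + 1L, path, childSpan, sel, wb)
      cursor <- childSpan[2]
    }
  }
  alloc(character(0), 1L, "", c(0, 360), rep(TRUE, nrow(s)), sum(w))
  do.call(rbind, rows)
}

#' Fraction table for a fixed (defined-member) PAM library
#'
#' Restricts a count table to the listed members and reports each member's
#' count and fraction of the total, with non-member reads aggregated into
#' an \code{"other"} row. This is the pie-chart input for small defined
#' libraries (e.g. four PAM variants plus a no-PAM control).
#'
#' @param counts A \linkS4class{PamCountTable}.
#' @param members data.frame with columns \code{label} and \code{sequence}
#'   (unique, all of the design's PAM length).
#' @return data.frame with columns \code{label, sequence, count, fraction};
#'   fractions sum to 1 over members plus "other".
#' @export
fixedLibraryFractions <- function(counts, members) {
  stopifnot(is(counts, "PamCountTable"),
            all(c("label", "sequence") %in% names(members)))
  if (anyDuplicated(members$sequence))
    stop("duplicate member sequences")
  if (any(nchar(members$sequence) != counts@degenerateLen))
    stop("member sequences must have the design's PAM length")
  cnt <- pamCounts(counts)
  memberCount <- ifelse(members$sequence %in% names(cnt),
                        cnt[members$sequence], 0L)
  memberCount[is.na(memberCount)] <- 0L
  otherCount <- sum(cnt) - sum(memberCount)
  out <- data.frame(label = c(members$label, "other"),
                    sequence = c(members$sequence, NA_character_),
                    count = c(unname(memberCount), otherCount),
                    stringsAsFactors = FALSE)
  total <- sum(out$count)
  out$fraction <- if (total > 0) out$count / total else 0
  out
}
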