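#' @import methods
#' @importFrom stats pnorm rnorm runif rmultinom setNames aggregate
#' @importFrom utils write.table read.table packageVersion head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Enumerate the full degenerate PAM library
#'
#' Generates every DNA word of the given length, i.e. the complete
#' randomized library a 7N PAM screen draws from (4^7 = 16,384 members
#' at the default length).
#'
#' @param len Word length in nucleotides.
#' @return Character vector of all \code{4^len} distinct words, in
#'   lexicographic order.
#' @examples
#' length(enumeratePamLibrary(7)) # 16384
#' @export
enumeratePamLibrary <- function(len = 7L) {
  len <- as.integer(len)
  stopifnot(len >= 1L, len <= 12L)
  grid <- do.call(expand.grid,
                  c(rep(list(DNA_BASES), len),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  do.call(paste0, rev(grid))
}

## minimal IUPAC code lookup keyed by sorted base set
.IUPAC_BY_SET <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  setNames(names(m),
           vapply(m, function(x) paste(sort(strsplit(x, "")[[1]]), collapse = ""),
                  character(1)))
})

iupacCode <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- .IUPAC_BY_SET[[key]]
  if (is.null(code)) stop("no IUPAC code for base set: ", key)
  code
}

.checkDna <- function(x, what = "sequence", allowEmpty = FALSE) {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop(what, " must be a single character string or DNAString")
  if (!allowEmpty && nchar(x) == 0L) stop(what, " is empty")
  if (grepl("[^ACGTacgt]", x))
    stop(what, " contains characters outside the DNA alphabet A/C/G/T")
  toupper(x)
}

.revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## vectorized Hamming distance between equal-length strings and one pattern
.hammingToPattern <- function(strings, pattern) {
  pl <- nchar(pattern)
  mm <- integer(length(strings))
  pat <- strsplit(pattern, "")[[1]]
  for (j in seq_len(pl)) {
    mm <- mm + (substr(strings, j, j) != pat[j])
  }
  mm[nchar(strings) != pl] <- NA_integer_
  mm
}

.setSeedIfGiven <- function(seed) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(!is.na(seed))
    set.seed(seed)
  }
  invisible(seed)
}

## split positions of PAM strings into a position x base count matrix,
## weighted by `w` (default 1 per sequence)
.positionBaseCounts <- function(pams, w = NULL, len = NULL) {
  if (is.null(len)) len <- nchar(pams[1])
  if (is.null(w)) w <- rep(1, length(pams))
  mat <- matrix(0, nrow = len, ncol = 4,
                dimnames = list(seq_len(len), DNA_BASES))
  for (i in seq_len(len)) {
    b <- substr(pams, i, i)
    s <- vapply(split(w, factor(b, levels = DNA_BASES)), sum, numeric(1))
    mat[i, ] <- s
  }
  mat
}
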