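## shared fixtures: all synthetic, built in code under fixed seeds

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## the canonical planted recognition model: G required at position 5,
## A preferred at position 7 with 3:1 recognition efficacy (strength 2/3)
plantedModel <- function(baseSurvival = 1.0, recognizedSurvival = 0.05) {
  recognitionModel(
    data.frame(position = c(5L, 7L), bases = c("G", "A"),
               mode = c("required", "preferred"), strength = c(1, 2/3)),
    baseSurvival = baseSurvival, recognizedSurvival = recognizedSurvival)
}

testDesign <- function() defaultScreenDesign()$design

## quality-scaled reads with explicit per-read mean quality
readsWithQuality <- function(seqs, qualStrings) {
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(qualStrings))
}

revComp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

## independent textbook chi-square oracle: sum (O-E)^2 / E over the 2x2
bruteChisq <- function(c1, n1, c2, n2) {
  O <- matrix(c(c1, n1 - c1, c2, n2 - c2), nrow = 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

## build a contig holding an exact repeat-spacer array plus random flanks;
## spacers are drawn with boundary bases distinct from the repeat's
## terminal bases so unit edges are unambiguous by construction
arrayContig <- function(repeatSeq, spacers, flank = 200L) {
  paste0(randomDna(flank),
         paste0(paste0(repeatSeq, spacers), collapse = ""),
         repeatSeq, randomDna(flank))
}
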