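test_that("collectEnds follows the strand-aware end coordinate contract", {
  # single plus-strand read covering bases 101..150
  h <- collectEnds(data.frame(start = 101L, end = 150L, strand = "+"), 500L)
  e <- endCounts(h)
  expect_equal(e$pos[e$type == "five_prime"], 101L)
  expect_equal(e$pos[e$type == "three_prime"], 150L)
  # minus strand mirrors the ends
  hm <- collectEnds(data.frame(start = 101L, end = 150L, strand = "-"), 500L)
  em <- endCounts(hm)
  expect_equal(em$pos[em$type == "five_prime"], 150L)
  expect_equal(em$pos[em$type == "three_prime"], 101L)
  # additivity over identical reads
  h10 <- collectEnds(data.frame(start = rep(101L, 10), end = rep(150L, 10),
                                strand = rep("+", 10)), 500L)
  expect_equal(endCounts(h10)$count, c(10L, 10L))
  # malformed records are skipped with a warning, totals stay balanced
  expect_warning(
    hb <- collectEnds(data.frame(start = c(101L, 600L), end = c(150L, 700L),
                                 strand = c("+", "+")), 500L),
    "malformed")
  expect_equal(nrow(readIntervals(hb)), 1L)
})

test_that("SAM output round-trips through Rsamtools into identical histograms", {
  set.seed(90)
  locus <- randomDna(400)
  aln <- data.frame(start = c(50L, 50L, 200L), end = c(120L, 120L, 260L),
                    strand = c("+", "+", "-"))
  sam <- tempfile(fileext = ".sam")
  writeSamAlignments(aln, locus, sam)
  h1 <- collectEnds(aln, 400L)
  h2 <- collectEnds(sam, 400L)
  o <- function(h) {
    e <- endCounts(h)
    e[order(e$type, e$strand, e$pos), ]
  }
  expect_equal(o(h2)$pos, o(h1)$pos)
  expect_equal(o(h2)$count, o(h1)$count)
  expect_equal(o(h2)$strand, o(h1)$strand)
})

test_that("reconstructSpecies recovers a noiseless species and applies the length filter", {
  reads <- data.frame(start = rep(201L, 100), end = rep(250L, 100),
                      strand = rep("+", 100))
  sp <- reconstructSpecies(collectEnds(reads, 1000L))
  expect_length(sp, 1)
  expect_equal(BiocGenerics::start(sp), 201L)
  expect_equal(BiocGenerics::end(sp), 250L)
  expect_equal(S4Vectors::mcols(sp)$support, 100L)
  # an implied 30-nt species is outside the 40-130 band
  short <- data.frame(start = rep(201L, 100), end = rep(230L, 100),
                      strand = rep("+", 100))
  expect_length(reconstructSpecies(collectEnds(short, 1000L)), 0)
  # but passes with a band that admits it
  expect_length(reconstructSpecies(collectEnds(short, 1000L),
                                   lenBand = c(20L, 130L)), 1)
})

test_that("round-trip recovery is exact for up to 10 planted species across seeds", {
  for (seed in 1:5) {
    loc <- makeToyLocus(nSpacers = 7L, depth = 50L, seed = seed)  # 10 species
    sim <- simulateSmallRna(loc, endJitter = 0L, seed = seed + 100L)
    sp <- reconstructSpecies(collectEnds(sim$alignments,
                                         nchar(loc$sequence)))
    truth <- loc$species[order(loc$species$start, loc$species$end), ]
    got <- as.data.frame(sp)
    got <- got[order(got$start, got$end), ]
    expect_equal(nrow(got), nrow(truth))
    expect_equal(got$start, truth$start)
    expect_equal(got$end, truth$end)
    expect_equal(got$support, rep(50L, nrow(truth)))
  }
})

test_that("jittered ends are recovered within the jitter bound", {
  loc <- makeToyLocus(seed = 3L, depth = 100L)
  sim <- simulateSmallRna(loc, endJitter = 2L, seed = 9L)
  sp <- reconstructSpecies(collectEnds(sim$alignments, nchar(loc$sequence)))
  expect_gt(length(sp), 0)
  truth <- loc$species
  for (i in seq_along(sp)) {
    dStart <- min(abs(truth$start - BiocGenerics::start(sp)[i]))
    dEnd <- min(abs(truth$end - BiocGenerics::end(sp)[i]))
    expect_lte(dStart, 2L)
    expect_lte(dEnd, 2L)
  }
})

test_that("annotateSpecies classifies crRNA, tracrRNA and other species", {
  loc <- makeToyLocus(seed = 11L)
  arr <- loc$array
  spc <- spacerRanges(arr)
  reps <- repeatRanges(arr)
  # species: 24 nt of spacer 1 + 26 nt of the adjacent upstream repeat
  s1 <- IRanges::start(spc)[1]
  gr <- GenomicRanges::GRanges("locus", IRanges::IRanges(
    start = c(s1 - 26L, IRanges::start(loc$tracrRegion) + 5L, 1L),
    end = c(s1 + 23L, IRanges::start(loc$tracrRegion) + 94L, 40L)),
    strand = "-", support = c(50L, 50L, 50L))
  ann <- annotateSpecies(gr, arr, loc$tracrRegion, txStrand = "-")
  mc <- S4Vectors::mcols(ann)
  expect_equal(mc$annotation, c("crRNA", "tracrRNA", "other"))
  expect_equal(mc$spacerPartLen[1], 24L)
  expect_equal(mc$drPartLen[1], 26L)
  # transcription-order index: leftmost spacer is transcribed last
  expect_equal(mc$crIndex[1], length(spc))
  expect_equal(mc$productLen[2], 90L)
  # a species spanning two spacers degrades to "other" with a warning
  wide <- GenomicRanges::GRanges("locus", IRanges::IRanges(
    IRanges::start(spc)[1], IRanges::end(spc)[2]), strand = "-",
    support = 50L)
  expect_warning(annW <- annotateSpecies(wide, arr, loc$tracrRegion),
                 "other")
  expect_equal(S4Vectors::mcols(annW)$annotation, "other")
})

test_that("annotation is invariant to a constant coordinate shift", {
  loc <- makeToyLocus(seed = 12L)
  sim <- simulateSmallRna(loc, endJitter = 0L, seed = 13L)
  sp <- reconstructSpecies(collectEnds(sim$alignments, nchar(loc$sequence)))
  ann <- annotateSpecies(sp, loc$array, loc$tracrRegion)
  shift <- 5000L
  spS <- GenomicRanges::shift(sp, shift)
  arrS <- new("CrisprArray", contigId = "toy_locus", strand = "+",
              repeats = IRanges::shift(repeatRanges(loc$array), shift),
              spacers = IRanges::shift(spacerRanges(loc$array), shift),
              repeatConsensus = repeatConsensus(loc$array))
  annS <- annotateSpecies(spS, arrS, IRanges::shift(loc$tracrRegion, shift))
  expect_equal(S4Vectors::mcols(annS)$annotation,
               S4Vectors::mcols(ann)$annotation)
  expect_equal(S4Vectors::mcols(annS)$crIndex, S4Vectors::mcols(ann)$crIndex)
  expect_equal(S4Vectors::mcols(annS)$spacerPartLen,
               S4Vectors::mcols(ann)$spacerPartLen)
})

test_that("callOrientation applies the majority rule with a confidence margin", {
  loc <- makeToyLocus(seed = 14L)
  arr <- loc$array
  span <- range(IRanges::start(repeatRanges(arr)))
  mkReads <- function(nPlus, nMinus) {
    data.frame(start = rep(span[1] + 5L, nPlus + nMinus),
               end = rep(span[1] + 60L, nPlus + nMinus),
               strand = c(rep("+", nPlus), rep("-", nMinus)))
  }
  allMinus <- callOrientation(collectEnds(mkReads(0L, 80L),
                                          nchar(loc$sequence)), arr)
  expect_equal(allMinus$arrayStrand, "-")
  expect_equal(allMinus$confidence, 1.0)
  split60 <- callOrientation(collectEnds(mkReads(40L, 60L),
                                         nchar(loc$sequence)), arr,
                             margin = 0.05)
  expect_true(split60$called)
  expect_equal(split60$arrayStrand, "-")
  expect_equal(split60$confidence, 0.6)
  tie <- callOrientation(collectEnds(mkReads(50L, 50L),
                                     nchar(loc$sequence)), arr)
  expect_false(tie$called)
  # reads that never touch the array leave the orientation uncalled
  off <- data.frame(start = 1L, end = 30L, strand = "+")
  none <- callOrientation(collectEnds(off, nchar(loc$sequence)), arr)
  expect_false(none$called)
  expect_match(none$status, "no array")
})
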