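test_that("detectArray recovers an exact 4-unit 36/31 array with exact coordinates", {
  set.seed(42)
  rep36 <- randomDna(36)
  sp <- replicate(3, randomDna(31))
  contig <- arrayContig(rep36, sp, flank = 200L)
  arrays <- detectArray(contig)
  expect_length(arrays, 1)
  a <- arrays[[1]]
  expect_equal(nRepeats(a), 4L)
  expect_equal(spacerLengths(a), c(31L, 31L, 31L))
  expect_equal(repeatConsensus(a), rep36)
  expect_equal(IRanges::start(repeatRanges(a))[1], 201L)
  expect_equal(IRanges::width(repeatRanges(a)), rep(36L, 4))
})

test_that("detectArray tolerates mismatched repeat copies within the budget", {
  set.seed(43)
  rep36 <- randomDna(36)
  sp <- replicate(3, randomDna(31))
  r3 <- rep36
  # two interior substitutions in the third copy
  substr(r3, 10, 10) <- if (substr(r3, 10, 10) == "A") "C" else "A"
  substr(r3, 20, 20) <- if (substr(r3, 20, 20) == "G") "T" else "G"
  contig <- paste0(randomDna(150), rep36, sp[1], rep36, sp[2], r3, sp[3],
                   rep36, randomDna(150))
  arrays <- detectArray(contig, maxRepeatMismatches = 3L)
  expect_length(arrays, 1)
  expect_equal(nRepeats(arrays[[1]]), 4L)
  # brute-force confirmation: each detected copy is within 3 mismatches of
  # the consensus computed independently from the constructed copies
  a <- arrays[[1]]
  copies <- substring(contig, IRanges::start(repeatRanges(a)),
                      IRanges::end(repeatRanges(a)))
  cons <- repeatConsensus(a)
  mm <- vapply(copies, function(cp)
    sum(strsplit(cp, "")[[1]] != strsplit(cons, "")[[1]]), integer(1))
  expect_true(all(mm <= 3L))
})

test_that("detectArray finds nothing in unstructured sequence and rejects bad input", {
  set.seed(44)
  expect_identical(detectArray(randomDna(5000)), list())
  expect_error(detectArray("ACGTNNNACGT"), "alphabet")
  expect_error(detectArray(""), "empty")
})

test_that("detectArray is invariant to random flanks and mirrors under reverse complement", {
  set.seed(45)
  rep36 <- randomDna(36)
  contig <- arrayContig(rep36, replicate(4, randomDna(31)), flank = 120L)
  a <- detectArray(contig)[[1]]
  set.seed(46)
  shifted <- paste0(randomDna(1000), contig, randomDna(1000))
  a2 <- detectArray(shifted)
  expect_length(a2, 1)
  expect_equal(IRanges::start(repeatRanges(a2[[1]])),
               IRanges::start(repeatRanges(a)) + 1000L)
  expect_equal(IRanges::width(spacerRanges(a2[[1]])),
               IRanges::width(spacerRanges(a)))
  # reverse complement: coordinates reflect through the sequence length
  n <- nchar(contig)
  a3 <- detectArray(revComp(contig))
  expect_length(a3, 1)
  expect_equal(sort(n - IRanges::end(repeatRanges(a3[[1]])) + 1L),
               IRanges::start(repeatRanges(a)))
  expect_equal(repeatConsensus(a3[[1]]), revComp(repeatConsensus(a)))
})

test_that("findAntiRepeat locates a planted exact anti-repeat", {
  set.seed(47)
  rep36 <- randomDna(36)
  anti <- revComp(substr(rep36, 1, 24))
  contig <- paste0(randomDna(100), anti, randomDna(300))
  hits <- findAntiRepeat(contig, rep36, minMatchedLen = 15, minIdentity = 0.8)
  expect_gte(length(hits), 1)
  top <- hits[1]
  expect_equal(S4Vectors::mcols(top)$identityFraction, 1.0)
  expect_equal(as.character(BiocGenerics::strand(top)), "-")
  expect_equal(BiocGenerics::start(top), 101L)
  expect_equal(BiocGenerics::end(top), 124L)
})

test_that("findAntiRepeat scores a substituted anti-repeat near 20/24 identity", {
  set.seed(48)
  rep36 <- randomDna(36)
  anti <- strsplit(revComp(substr(rep36, 1, 24)), "")[[1]]
  for (p in c(5, 10, 15, 20)) {  # interior substitutions
    anti[p] <- setdiff(c("A", "C", "G", "T"), anti[p])[1]
  }
  contig <- paste0(randomDna(100), paste(anti, collapse = ""), randomDna(300))
  hits <- findAntiRepeat(contig, rep36, minMatchedLen = 15, minIdentity = 0.75)
  expect_gte(length(hits), 1)
  ident <- S4Vectors::mcols(hits[1])$identityFraction
  # local alignment may trim mismatched edges; identity stays near 20/24
  expect_gte(ident, 0.75)
  expect_lte(ident, 0.92)
  expect_gte(S4Vectors::mcols(hits[1])$matchedLen, 15)
})

test_that("findAntiRepeat honours exclusion intervals and threshold validation", {
  set.seed(49)
  rep36 <- randomDna(36)
  contig <- paste0(randomDna(100), rep36, randomDna(100))
  # the only repeat copy lies inside the excluded interval
  hits <- findAntiRepeat(contig, rep36,
                         exclude = IRanges::IRanges(101L, 136L),
                         minMatchedLen = 20, minIdentity = 0.9)
  expect_length(hits, 0)
  expect_error(findAntiRepeat(contig, rep36, minIdentity = 1.5), "minIdentity")
})

test_that("strict findAntiRepeat equals exact-substring search of the reverse complement", {
  set.seed(50)
  rep20 <- randomDna(20)
  rc <- revComp(rep20)
  contig <- paste0(randomDna(80), rc, randomDna(150), rc, randomDna(80))
  hits <- findAntiRepeat(contig, rep20, minMatchedLen = 20, minIdentity = 1.0)
  minus <- hits[BiocGenerics::strand(hits) == "-"]
  got <- sort(BiocGenerics::start(minus))
  expected <- as.integer(gregexpr(rc, contig, fixed = TRUE)[[1]])
  expect_equal(got, expected)
  expect_true(all(S4Vectors::mcols(minus)$identityFraction == 1))
})

test_that("scorePromoterMotif scores windows against the extended -10 model", {
  set.seed(51)
  # repeat ending in the model's own consensus (N at position 3 set to C)
  perfect <- paste0(randomDna(27), "TGCTATAAT")
  res <- scorePromoterMotif(perfect)
  expect_equal(res$score, 8L)  # 8 informative (non-N) model positions
  expect_equal(res$matchedWindow, "TGCTATAAT")
  expect_equal(res$windowStartInRepeat, 28L)
  # all-A repeat: matches exactly the A positions of the model (3 of them)
  resA <- scorePromoterMotif(strrep("A", 36))
  expect_equal(resA$score, 3L)
  # ties break towards the 3' terminus
  tied <- paste0(strrep("A", 18), "TGCTATAAT", "TGCTATAAT")
  resT <- scorePromoterMotif(tied, terminalRegion = 18L)
  expect_equal(resT$windowStartInRepeat, 28L)
  expect_error(scorePromoterMotif("ACGT"), "shorter")
})
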