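test_that("qcFilterReads keeps the Q20 boundary inclusive and preserves order", {
  # 10-base reads: all-Q20 (mean 20), nine Q20 + one Q19 (mean 19.9), high Q
  q20 <- strrep(rawToChar(as.raw(33L + 20L)), 10)
  q199 <- paste0(strrep(rawToChar(as.raw(33L + 20L)), 9),
                 rawToChar(as.raw(33L + 19L)))
  qhi <- strrep("I", 10)
  reads <- readsWithQuality(rep("ACGTACGTAC", 3), c(q20, q199, qhi))
  names(reads) <- c("boundary", "below", "high")
  kept <- qcFilterReads(reads, minMeanQ = 20)
  expect_equal(names(kept), c("boundary", "high"))
  expect_equal(attr(kept, "nInput"), 3L)
  # empty input stays empty
  empty <- qcFilterReads(reads[0], minMeanQ = 20)
  expect_length(empty, 0)
})

test_that("extractPamRegions counts anchored PAMs on both strands and rejects broken anchors", {
  ds <- testDesign()
  ctx <- defaultScreenDesign()
  mk <- function(pam) paste0(ctx$backbone5, ds@leftAnchor, pam,
                             ds@rightAnchor, ctx$backbone3)
  fwd <- mk("ACAGGTA")               # the consensus PAM word
  rev <- revComp(mk("CGGTGTA"))
  broken <- mk("TGAAGAA")
  # three substitutions in the left anchor exceed the budget of 2
  substr(broken, 61, 63) <- "TTT"    # left anchor starts at 61
  stopifnot(substr(fwd, 61, 63) != "TTT")
  tab <- suppressWarnings(
    extractPamRegions(c(fwd, rev, broken), ds, maxAnchorMismatches = 2L))
  expect_equal(unname(pamCounts(tab)[c("ACAGGTA", "CGGTGTA")]), c(1L, 1L))
  expect_false("TGAAGAA" %in% names(pamCounts(tab)))
  qc <- qcStats(tab)
  expect_equal(unname(qc["anchored"]), 2L)
  expect_equal(unname(qc["passQC"]), 3L)
  expect_true(qc["anchored"] <= qc["passQC"] && qc["passQC"] <= qc["total"])
})

test_that("computeDepletion handles the null case and pseudocounted zeros", {
  cnt <- c(AAAAAAA = 50L, CCCCCCC = 50L, GGGGGGG = 50L, TTTTTTT = 50L)
  d <- computeDepletion(pamCountTable(cnt, "exp"), pamCountTable(cnt, "ctrl"))
  s <- depletionStats(d)
  expect_equal(s$depletionScore, rep(0, 4))
  expect_true(all(s$pOneSided >= 0.5))
  expect_equal(sum(s$freqExp), 1, tolerance = 1e-9)
  expect_equal(sum(s$freqCtrl), 1, tolerance = 1e-9)
  expect_length(callDepleted(d), 0)
  # zero experimental count stays finite and positive under the pseudocount
  d2 <- computeDepletion(
    pamCountTable(c(CCCCCCC = 100L)),
    pamCountTable(c(AAAAAAA = 50L, CCCCCCC = 100L)), pseudocount = 0.5)
  s2 <- depletionStats(d2)
  row <- s2[s2$pam == "AAAAAAA", ]
  expect_true(is.finite(row$depletionScore))
  expect_gt(row$depletionScore, 0)
})

test_that("computeDepletion matches the textbook chi-square oracle on a 4-variant toy", {
  pams <- c("AAAAAAA", "CCCCCCC", "GGGGGGG", "TTTTTTT")
  expC <- c(10L, 100L, 100L, 100L)
  ctrlC <- c(100L, 70L, 70L, 70L)
  d <- computeDepletion(pamCountTable(setNames(expC, pams)),
                        pamCountTable(setNames(ctrlC, pams)))
  s <- depletionStats(d)
  s <- s[match(pams, s$pam), ]
  oracle <- mapply(bruteChisq, expC, sum(expC), ctrlC, sum(ctrlC))
  expect_equal(s$chi2, unname(oracle), tolerance = 1e-9)
  expect_equal(which.max(s$chi2), 1L)
  expect_equal(which.min(s$pOneSided), 1L)
  # enriched variants sit in the upper half of the p scale
  expect_true(all(s$pOneSided[2:4] >= 0.5))
})

test_that("chi-square equals the independent oracle across random 2x2 tables", {
  set.seed(60)
  for (i in 1:200) {
    n1 <- sample(50:10000, 1); n2 <- sample(50:10000, 1)
    c1 <- sample(0:n1, 1); c2 <- sample(0:n2, 1)
    got <- crisprScreen:::.chisq2x2(c1, n1, c2, n2)
    O <- matrix(c(c1, n1 - c1, c2, n2 - c2), 2, byrow = TRUE)
    if (any(colSums(O) == 0)) {
      expect_equal(got, 0)
    } else {
      expect_equal(got, bruteChisq(c1, n1, c2, n2), tolerance = 1e-9)
    }
  }
})

test_that("depletion evidence is monotone in the experimental count", {
  ctrl <- pamCountTable(c(AAAAAAA = 200L, CCCCCCC = 200L, GGGGGGG = 200L))
  prev <- NULL
  for (cnt in c(180L, 120L, 60L, 20L, 0L)) {
    expTab <- pamCountTable(
      c(AAAAAAA = cnt, CCCCCCC = 200L, GGGGGGG = 200L))
    s <- depletionStats(computeDepletion(expTab, ctrl))
    row <- s[s$pam == "AAAAAAA", ]
    if (!is.null(prev)) {
      expect_gte(row$chi2, prev$chi2)
      expect_lte(row$pOneSided, prev$pOneSided)
    }
    prev <- row
  }
})

test_that("positionDepletion is zero under the null and localized to the differing position", {
  cnt <- setNames(rep(25L, 4), paste0("AA", c("A", "C", "G", "T"), "AAAA"))
  d <- computeDepletion(pamCountTable(cnt), pamCountTable(cnt))
  prof <- positionDepletion(d, depleted = character(0))
  expect_true(all(abs(positionDepletionValues(prof)) < 1e-12))
  # differ only at position 3
  expC <- setNames(c(10L, 10L, 40L, 40L), names(cnt))
  d2 <- computeDepletion(pamCountTable(expC), pamCountTable(cnt))
  dv <- positionDepletionValues(positionDepletion(d2, depleted = character(0)))
  expect_true(all(abs(dv[-3, ]) < 1e-12))
  expect_gt(max(abs(dv[3, ])), 0.1)
})

test_that("callConsensus applies greedy dominance with IUPAC collapse", {
  uni <- matrix(0.25, nrow = 7, ncol = 4,
                dimnames = list(1:7, c("A", "C", "G", "T")))
  expect_equal(consensusIupac(callConsensus(uni, 0.75)), "NNNNNNN")
  # two-base greedy set at a high threshold -> purine code
  m <- uni
  m[5, ] <- c(A = 0.45, C = 0.03, G = 0.5, T = 0.02)
  cons <- callConsensus(m, 0.9)
  expect_equal(substr(consensusIupac(cons), 5, 5), "R")
  # dominant single base
  m[5, ] <- c(A = 0.05, C = 0.1, G = 0.8, T = 0.05)
  expect_equal(substr(consensusIupac(callConsensus(m, 0.75)), 5, 5), "G")
  expect_error(callConsensus(uni, 0.2), "dominanceThreshold")
})

test_that("a planted G5-required screen yields G5-dominated calls", {
  model <- recognitionModel(
    data.frame(position = 5L, bases = "G", mode = "required", strength = 1))
  sim <- simulateScreen(model, 1638400L, 1638400L, seed = 71L)
  dep <- callDepleted(computeDepletion(sim$exp, sim$ctrl))
  expect_gt(length(dep), 100)
  expect_gte(mean(substr(dep, 5, 5) == "G"), 0.95)
})
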