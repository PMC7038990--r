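test_that("buildLogoMatrix reproduces closed-form information content", {
  # single sequence: 2 bits at every position
  lg <- buildLogoMatrix("AAAAAAA")
  expect_equal(informationContent(lg), rep(2, 7))
  expect_equal(unname(logoProbabilities(lg)[, "A"]), rep(1, 7))
  # the full degenerate library: maximal entropy, 0 bits
  lg0 <- buildLogoMatrix(enumeratePamLibrary(7))
  expect_equal(informationContent(lg0), rep(0, 7), tolerance = 1e-12)
  expect_equal(unname(logoProbabilities(lg0)), matrix(0.25, 7, 4))
  # NNNNGNA expansions: IC = 2 exactly at positions 5 and 7, 0 elsewhere
  expand <- enumeratePamLibrary(5)
  pams <- paste0(substr(expand, 1, 4), "G", substr(expand, 5, 5), "A")
  lgE <- buildLogoMatrix(pams)
  expect_equal(informationContent(lgE), c(0, 0, 0, 0, 2, 0, 2),
               tolerance = 1e-12)
  expect_error(buildLogoMatrix(character(0)), "empty")
})

test_that("logo IC equals 2 - H for a hand-computed distribution", {
  # weights 2:1:1:0 at one position -> H = 1.5 bits, IC = 0.5
  lg <- buildLogoMatrix(c("A", "A", "C", "G"))
  p <- logoProbabilities(lg)[1, ]
  H <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_equal(informationContent(lg)[1], 2 - H)
  expect_equal(informationContent(lg)[1], 0.5)
  # explicit weights behave like repetition
  lgW <- buildLogoMatrix(c("A", "C", "G"), weights = c(2, 1, 1))
  expect_equal(informationContent(lgW), informationContent(lg))
})

test_that("buildPamWheel allocates spans proportionally and conserves parents", {
  # hand-assigned counts over the 64 combinations of positions 5-7
  set.seed(80)
  lib <- paste0("AAAA", enumeratePamLibrary(3))
  ctrlC <- setNames(rep(500L, 64), lib)
  expC <- setNames(pmax(0L, 500L - sample(0:400, 64)), lib)
  d <- computeDepletion(pamCountTable(expC), pamCountTable(ctrlC))
  wheel <- buildPamWheel(d, positions = c(5L, 6L, 7L))
  # root ring spans cover the full circle
  ring1 <- wheel[wheel$ring == 1, ]
  expect_equal(sum(ring1$endAngle - ring1$startAngle), 360, tolerance = 1e-9)
  # children partition their parent's span at every node
  for (p in unique(wheel$parentPath[wheel$ring > 1])) {
    kids <- wheel[wheel$parentPath == p & wheel$ring > 1, ]
    parent <- wheel[wheel$path == p, ]
    expect_equal(sum(kids$endAngle - kids$startAngle),
                 parent$endAngle - parent$startAngle, tolerance = 1e-9)
  }
  # arithmetic oracle: outer-ring span fraction equals the weight fraction
  s <- depletionStats(d)
  w <- pmax(0, s$freqCtrl - s$freqExp)
  w <- w / sum(w)
  combos <- substr(s$pam, 5, 7)
  leaf <- wheel[wheel$ring == 3, ]
  for (i in seq_len(nrow(leaf))) {
    expected <- sum(w[combos == leaf$path[i]]) * 360
    expect_equal(leaf$endAngle[i] - leaf$startAngle[i], expected,
                 tolerance = 1e-9)
  }
})

test_that("buildPamWheel handles degenerate weight layouts", {
  # only G at the inner position depleted: inner ring is one full G sector
  cnt <- setNames(rep(100L, 4), paste0("AAAA", c("A", "C", "G", "T"), "AA"))
  expC <- cnt; expC["AAAAGAA"] <- 10L
  d <- computeDepletion(pamCountTable(expC), pamCountTable(cnt))
  wheel <- buildPamWheel(d, positions = 5L)
  g <- wheel[wheel$base == "G", ]
  expect_equal(g$endAngle - g$startAngle, 360, tolerance = 1e-9)
  expect_true(all((wheel$endAngle - wheel$startAngle)[wheel$base != "G"] == 0))
  # uniform weights: every ring splits into equal quarters per parent;
  # an enriched sink variant (weight floored at 0) absorbs the frequency
  # mass so the 16 members share one uniform positive depletion weight
  expC2 <- setNames(rep(50L, 16),
                    paste0("AAAA", enumeratePamLibrary(2), "A"))
  ctrl2 <- setNames(rep(100L, 16), names(expC2))
  expC2["CCCCCCC"] <- 1700L
  ctrl2["CCCCCCC"] <- 100L
  d2 <- computeDepletion(pamCountTable(expC2), pamCountTable(ctrl2))
  w2 <- buildPamWheel(d2, positions = c(5L, 6L))
  expect_equal(w2$endAngle - w2$startAngle,
               ifelse(w2$ring == 1, 90, 22.5), tolerance = 1e-6)
  # nothing depleted -> error
  dNull <- computeDepletion(pamCountTable(cnt), pamCountTable(cnt))
  expect_error(buildPamWheel(dNull), "nothing depleted")
})

test_that("fixedLibraryFractions reports member fractions with an 'other' row", {
  members <- data.frame(
    label = c("PAM 1", "PAM 2", "PAM 3", "PAM 4", "no PAM"),
    sequence = c("ACAGGTA", "CGGTGTA", "TGAAGAA", "ATTGGAA", "TTCATAT"))
  # only the no-PAM control present
  tab <- pamCountTable(c(TTCATAT = 100L))
  fr <- fixedLibraryFractions(tab, members)
  expect_equal(fr$fraction[fr$label == "no PAM"], 1.0)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-9)
  # equal counts -> 0.2 each
  tab2 <- pamCountTable(setNames(rep(1000L, 5), members$sequence))
  fr2 <- fixedLibraryFractions(tab2, members)
  expect_equal(fr2$fraction[seq_len(5)], rep(0.2, 5))
  # permutation invariance in member order
  perm <- members[c(3, 1, 5, 2, 4), ]
  fr3 <- fixedLibraryFractions(tab2, perm)
  expect_equal(fr3$fraction[match(members$label, fr3$label)],
               fr2$fraction[seq_len(5)])
  expect_error(fixedLibraryFractions(tab2, rbind(members, members[1, ])),
               "duplicate")
})

test_that("an interference run on the five-member library inflates the no-PAM fraction", {
  members <- data.frame(
    label = c("PAM 1", "PAM 2", "PAM 3", "PAM 4", "no PAM"),
    sequence = c("ACAGGTA", "CGGTGTA", "TGAAGAA", "ATTGGAA", "TTCATAT"))
  model <- recognitionModel(
    data.frame(position = 5L, bases = "G", mode = "required", strength = 1),
    baseSurvival = 1, recognizedSurvival = 0.1)  # G5 members cleaved at 90%
  sim <- simulateScreen(model, 20000L, 20000L, library = members$sequence,
                        seed = 81L)
  fr <- fixedLibraryFractions(sim$exp, members)
  noPam <- fr$fraction[fr$label == "no PAM"]
  expect_true(all(noPam > fr$fraction[fr$label != "no PAM"]))
  # control stays near-uniform
  frC <- fixedLibraryFractions(sim$ctrl, members)
  expect_equal(frC$fraction[seq_len(5)], rep(0.2, 5), tolerance = 0.05)
})
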