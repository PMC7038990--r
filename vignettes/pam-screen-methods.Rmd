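---
title: "Methods: PAM depletion screens and CRISPR locus profiling with crisprScreen"
author: "crisprScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PAM depletion screens and CRISPR locus profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprScreen)
```

# Scope and model

`crisprScreen` implements the computational side of characterizing a
Type II CRISPR–Cas nuclease from sequencing data:

1. **Locus annotation** — finding the repeat–spacer array, anti-repeat
   (tracrRNA) candidates and repeat-embedded promoter-like elements in a
   locus sequence.
2. **PAM depletion screens** — turning reads from a randomized-PAM (7N)
   library, selected either by in vivo interference or by in vitro
   cleavage, into per-variant depletion statistics, significance calls, a
   positional depletion profile and an IUPAC consensus.
3. **Reporting** — sequence-logo matrices, the hierarchical PAM wheel
   geometry, and fraction tables for small defined libraries.
4. **Small-RNA profiling** — reconstructing mature crRNA and tracrRNA
   species from 5'/3' read-end coordinates and calling the array's
   transcription orientation.
5. **Synthetic data** — generators for all of the above with recorded
   ground truth, which are the package's primary test surface.

## The depletion screen statistic

A depletion screen compares a selected (experimental) sample against an
unselected control. Each library member $v$ contributes counts
$c^{exp}_v$ and $c^{ctrl}_v$ out of totals $n_{exp}$ and $n_{ctrl}$.
Per member we form the 2×2 contingency table

$$\begin{pmatrix} c^{exp}_v & n_{exp}-c^{exp}_v \\
                  c^{ctrl}_v & n_{ctrl}-c^{ctrl}_v \end{pmatrix}$$

(member versus rest-of-library, selected versus control) and compute the
Pearson chi-square statistic $X^2 = \sum (O-E)^2/E$ on raw counts. This
construction uses every read and reduces to the standard two-proportion
test. One-sidedness — only *depletion* is evidence of recognition — is
obtained as the upper normal tail of the signed root,
$p = 1 - \Phi(s\sqrt{X^2})$ with $s = +1$ when the member is rarer in
the experimental sample; enriched members therefore get $p \ge 0.5$.
A member is called depleted when $p < 10^{-12}$ (the conventional hard
threshold for this assay family) **and** its pseudocounted experimental
frequency is below control.

Frequencies and the per-member depletion score
$\log_2(f^{ctrl}_v / f^{exp}_v)$ use a symmetric Jeffreys-style
pseudocount of 0.5 on both samples, so zero counts stay finite. The
chi-square itself uses raw counts — pseudocounting a test statistic
would bias its null distribution.

**Positional profile.** For position $i$ and base $b$, the
count-weighted base frequency in sample $s$ is
$F_s(i,b) = \sum_{v: v_i = b} c^s_v / n_s$ (pseudocounted per cell); the
positional depletion value is $\log_2 F_{ctrl}(i,b) / F_{exp}(i,b)$.
The literature this follows cites the definition only indirectly, so
the formula is documented here precisely so an alternate definition can
be swapped in; it is the natural positional marginal of the per-variant
score.

**Consensus calling.** Within the depleted set, bases at each position
are collected greedily by descending frequency (alphabetical order on
ties) until their summed frequency reaches the dominance threshold
(default 0.75), and the IUPAC code of the set is emitted. One
deliberate deviation from a literal "minimal set ≥ threshold" rule: a
greedy set of three or more bases is collapsed to N. Taken literally,
the top three of four empirical frequencies always sum to at least
0.75 (the minimum frequency cannot exceed 0.25), so no position could
ever be reported as N at the default threshold — collapsing ≥3-base
sets restores the intended semantics, and a 3-of-4 base "requirement"
carries no usable constraint at screen resolution anyway.

## Read processing

Reads are first filtered on arithmetic mean Phred quality ≥ 20
(boundary inclusive). Instead of genome mapping, the degenerate region
is located by **anchored extraction**: the fixed construct sequences
flanking the randomized region must each match with at most 2
mismatches, separated by exactly the degenerate length with no
ambiguous base; both read orientations are tried. For amplicon reads
this is equivalent to mapping followed by region extraction, but
deterministic and dependency-free. Reads failing anchoring are counted
(the accounting chain `anchored ≤ passQC ≤ total` is enforced by the
`PamCountTable` validity) but contribute nothing. A SAM/BAM ingestion
path (`readSamAlignments`) exists for externally aligned data.

## Reporting artifacts

The **logo matrix** gives per-position base probabilities over the
depleted set (each member counted once, unless weights are supplied)
and information content $2 - H$ bits with no small-sample correction —
negligible at depleted-set sizes in the hundreds.

The **PAM wheel** is a Krona-style nested disc: ring = PAM position
(inner to outer in the order given, typically 5→7), sectors subdivide
their parent in fixed base order A, C, G, T with angular span
proportional to the aggregated weight of the base combination. The
weight of a PAM is its *relative depletion*, defined as
$\max(0, f^{ctrl} - f^{exp})$ normalized globally; a log-ratio variant
sits behind a switch. Published wheels do not state whether weights are
normalized globally or per ring; both are available (the spans are
identical — proportional subdivision makes the choice affect only the
reported weight column), default global. The module emits geometry
(start/end angles in degrees), not pixels, so tests are numeric.

## Small-RNA species reconstruction

Alignments yield strand-specific 5'/3' end histograms (5' end =
leftmost aligned base on plus, rightmost on minus). Processing sites
are local maxima of these histograms: a coordinate with at least
`minSupport` (default 5) reads that is maximal within ±`endWindow`
(default 3 nt), extracted by greedy peak pruning (highest count first,
ties to the lower coordinate). Each 5' site is paired with every
transcriptionally downstream 3' site whose implied length falls in the
40–130 nt filter band and whose **joint support** — reads with both
ends within the window of the respective sites — reaches `minSupport`.
Pairing on joint support rather than marginal peak heights keeps
unrelated peaks from combining into phantom species.

With end jitter at the window scale (±2 nt jitter against a ±3 nt
window) a single true site can occasionally split into two called
peaks 4 nt apart; downstream assertions should therefore be on end
*accuracy*, not species count, for jittered data. Noiseless data round
trips exactly.

Annotation is interval arithmetic against the array: a species
overlapping exactly one spacer is the mature crRNA of that spacer
(indexed from the transcription-proximal end), with its spacer-derived
and repeat-derived segment lengths; species overlapping the anti-repeat
region are tracrRNA products; everything else — including species
spanning two spacers — is "other". Transcription orientation is a
majority vote of array-overlapping read strands with a confidence
margin (default 0.05 above 0.5); ties and empty overlaps stay uncalled.

## Locus annotation

Array detection nominates candidate repeats by recurring 8-mers whose
occurrence gaps fall inside the combined repeat+spacer period band,
then greedily extends each run column-by-column under a per-copy
mismatch budget (default 3) against the run consensus, accepting a
column when at most one copy dissents. Because that tolerance lets
chance flank agreements creep in, terminal columns with any dissent are
trimmed back. Defaults (repeat 23–50 nt, spacer 20–60 nt, ≥3 units)
cover typical Type II architectures — including the 36 bp repeat /
31 bp spacer layout this package's generators emulate — without
hard-coding one. Detection reports the strand as given; orientation is
a small-RNA question.

Anti-repeat search is local alignment (match +1, mismatch −1, gap
open/extend 2/1) of the repeat consensus against the unexcluded parts
of the sequence and its reverse complement, recursing into flanks of
accepted hits; hits need ≥15 aligned nt at ≥0.8 identity by default.
With thresholds at their strict limits this reduces exactly to
exact-substring search of the reverse-complemented repeat.

The extended −10 promoter-like element inside repeats is scored as
matches to the configurable consensus model `TGNTATAAT` over 9-nt
windows in the terminal region (default last 15 nt; ties go to the
window nearest the 3' terminus). The model default is a choice, not a
measurement — the source observation names the element but not the
matched pattern.

## The synthetic world

The generators state the world the tests assume:

* **Screen simulation.** Control counts are multinomial-uniform over
  the library (the full $4^7 = 16{,}384$ member set by default);
  experimental counts are multinomial with weights proportional to each
  member's survival. Survival comes from a planted recognition model:
  required rules gate recognition entirely; preferred rules interpolate
  linearly — an unmatched preferred rule of strength $\sigma$ keeps
  $(1-\sigma)$ of the recognition effect. The canonical planted model is
  "G required at position 5; A preferred at position 7 with 3:1
  efficacy" ($\sigma = 2/3$), with survival 1.0 for unrecognized and
  0.05 for recognized members — strong selection, as in a functional
  interference or cleavage screen. Interference and cleavage modes share
  this abstraction (survival = colony formation in vivo, or escaping
  cleavage in vitro); they differ only in parameterization.
* **Read-level mode** wraps each molecule as
  backbone–anchor–PAM–anchor–backbone (arbitrary fixed context
  sequences; no natural plasmid sequence is reproduced), drawing
  per-base Phred qualities from a clipped normal (mean 30, sd 3,
  clipped to [2, 40]) and substituting bases with probability
  $10^{-Q/10}$. Counts-level mode skips the read plumbing and returns
  the multinomial counts directly: statistically identical inputs to
  the depletion machinery, used where simulations at $10^6$ molecules ×
  many seeds must stay inside test-time budgets. The full FASTQ → QC →
  anchoring → statistics path is exercised end-to-end at smaller depth.
* **Small-RNA simulation** samples reads per planted species with
  optional uniform end jitter; the toy locus lays out a
  10-repeat/9-spacer array (36/31 nt), an anti-repeat region upstream,
  minus-strand transcription (opposite to the cas genes, as in natural
  Type II-C loci), mature crRNAs of 25 nt spacer + 26 nt repeat, and
  tracrRNA products of 70/90/107 nt sharing a 5' end.

What a green test does **not** establish: the generators model neither
PCR/chimera/index-hopping artifacts nor real library composition skew
(real 7N libraries show ~15,700 of 16,384 variants; the uniform
multinomial at $10^6$ molecules covers essentially all), nor indels or
adapter read-through. Conclusions about real screens still require the
usual upstream QC.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout (IRanges convention);
  BedGraph output converts to its native 0-based half-open form.
* Chi-square of a table with a degenerate margin is defined as 0; the
  one-sided p-value is clamped into $(0, 1]$ (never exactly 0).
* Consensus greedy ties break alphabetically; wheel sectors order
  A, C, G, T within a parent; zero-weight parents get zero-width child
  spans.
* An all-zero wheel ("nothing depleted to draw") and an empty logo set
  are input errors, not empty outputs; an array-free sequence returns
  an empty list, not an error.
* All simulators take an explicit integer seed; no hidden global RNG
  state is relied upon (the same seed gives byte-identical FASTQ).

## Worked example

```{r example, eval = FALSE}
model <- recognitionModel(
  data.frame(position = c(5, 7), bases = c("G", "A"),
             mode = c("required", "preferred"), strength = c(1, 2/3)))
sim <- simulateScreen(model, 1638400, 1638400, seed = 1)
depl <- computeDepletion(sim$exp, sim$ctrl)
depleted <- callDepleted(depl)               # ~1024 variants
profile <- positionDepletion(depl, depleted)
consensusIupac(callConsensus(profile))       # "NNNNGNA"
```

## Known limitations

* Paired-end mates are not merged; the anchored extractor takes the
  degenerate region from whichever mate anchors (simulated data is
  single-end).
* Array detection assumes near-identical repeat copies; highly degraded
  terminal repeats beyond the mismatch budget truncate the array.
* The hard $p < 10^{-12}$ regime is the only multiple-testing control,
  matching the assay convention; no FDR machinery is provided.
* Species reconstruction reports every supported 5'/3' pairing; nested
  products (as real tracrRNA loci produce) are intended output, not
  duplicates.
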