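## End-to-end pipeline wrappers behind the command-line entry points.
## Results go to files; progress goes to message() (stderr). Each run
## writes a manifest (inputs, parameters, seed, package version) so
## deterministic outputs can be reproduced byte-identically.

.writeManifest <- function(outDir, command, params) {
  manifest <- list(command = command,
                   package_version = as.character(packageVersion("crisprScreen")),
                   parameters = params)
  path <- file.path(outDir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Annotate a locus FASTA: arrays, anti-repeats, promoter-like elements
#'
#' Detects repeat-spacer arrays in every record of the FASTA, searches for
#' anti-repeat (tracrRNA) candidates outside the arrays, scores the
#' extended -10-like element in each repeat consensus, and writes the
#' array TSV, GFF3 features and a JSON summary.
#'
#' @param fasta Locus FASTA path (multi-record allowed).
#' @param outDir Output directory (created if needed).
#' @param repeatLenBand,spacerLenBand,minUnits,maxRepeatMismatches Array
#'   detection parameters, see \code{\link{detectArray}}.
#' @param minMatchedLen,minIdentity Anti-repeat thresholds, see
#'   \code{\link{findAntiRepeat}}.
#' @return Invisibly, a list with \code{arrays}, \code{antiRepeats} and
#'   the output \code{files}.
#' @export
runAnnotate <- function(fasta, outDir, repeatLenBand = c(23L, 50L),
                        spacerLenBand = c(20L, 60L), minUnits = 3L,
                        maxRepeatMismatches = 3L, minMatchedLen = 15L,
                        minIdentity = 0.8) {
  if (!file.exists(fasta)) stop("input FASTA not found: ", fasta)
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (!length(seqs)) stop("input FASTA is empty: ", fasta)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  arrays <- list(); anti <- NULL
  for (i in seq_along(seqs)) {
    contig <- names(seqs)[i] %||% sprintf("contig%d", i)
    contig <- sub("\\s.*", "", contig)
    found <- detectArray(as.character(seqs[[i]]),
                         repeatLenBand = repeatLenBand,
                         spacerLenBand = spacerLenBand, minUnits = minUnits,
                         maxRepeatMismatches = maxRepeatMismatches,
                         contigId = contig)
    arrays <- c(arrays, found)
    for (a in found) {
      hits <- findAntiRepeat(as.character(seqs[[i]]), repeatConsensus(a),
                             exclude = repeatRanges(a),
                             minMatchedLen = minMatchedLen,
                             minIdentity = minIdentity)
      if (length(hits)) {
        hits <- GenomicRanges::GRanges(
          contig, IRanges::ranges(hits),
          strand = BiocGenerics::strand(hits),
          S4Vectors::mcols(hits))
        anti <- if (is.null(anti)) hits else suppressWarnings(c(anti, hits))
      }
    }
  }
  message(length(arrays), " array(s) detected")
  files <- writeArrayReport(arrays, file.path(outDir, "arrays"),
                            antiRepeats = anti)
  promoter <- lapply(arrays, function(a)
    scorePromoterMotif(repeatConsensus(a)))
  jsonlite::write_json(promoter, file.path(outDir, "promoter_motifs.json"),
                       auto_unbox = TRUE, digits = NA)
  .writeManifest(outDir, "annotate",
                 list(fasta = fasta, repeat_len_band = repeatLenBand,
                      spacer_len_band = spacerLenBand, min_units = minUnits,
                      max_repeat_mismatches = maxRepeatMismatches,
                      min_matched_len = minMatchedLen,
                      min_identity = minIdentity))
  invisible(list(arrays = arrays, antiRepeats = anti, files = files))
}

#' Run the full PAM screen analysis on experimental and control FASTQ
#'
#' QC-filters both samples, extracts anchored PAM regions, computes
#' depletion statistics, calls the depleted set and the IUPAC consensus,
#' and writes the complete output bundle: per-sample counts TSV, depletion
#' TSV, position profile TSV, consensus JSON, logo matrix TSV and PAM
#' wheel geometry TSV.
#'
#' @param expFastq,ctrlFastq FASTQ paths for the selected and control
#'   samples.
#' @param design A \linkS4class{ScreenDesign} or a design JSON/YAML path.
#' @param outDir Output directory.
#' @param minMeanQ Mean-quality filter threshold (default 20).
#' @param maxAnchorMismatches Per-anchor mismatch budget (default 2).
#' @param pseudocount Frequency pseudocount (default 0.5).
#' @param pThreshold Depletion significance threshold (default 1e-12).
#' @param dominanceThreshold Consensus dominance threshold (default 0.75).
#' @param wheelPositions PAM wheel positions, inner first (default 5:7).
#' @return Invisibly, a list with the main result objects and the output
#'   file paths.
#' @export
runScreen <- function(expFastq, ctrlFastq, design, outDir, minMeanQ = 20,
                      maxAnchorMismatches = 2L, pseudocount = 0.5,
                      pThreshold = 1e-12, dominanceThreshold = 0.75,
                      wheelPositions = c(5L, 6L, 7L)) {
  for (f in c(expFastq, ctrlFastq))
    if (!file.exists(f)) stop("input FASTQ not found: ", f)
  if (is.character(design)) design <- readScreenDesign(design)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  process <- function(path, id) {
    raw <- readFastq(path)
    filt <- qcFilterReads(raw, minMeanQ)
    message(sprintf("%s: %d/%d reads pass mean Q >= %g", id, length(filt),
                    length(raw), minMeanQ))
    extractPamRegions(filt, design, maxAnchorMismatches, sampleId = id,
                      nReadsTotal = length(raw))
  }
  expTab <- process(expFastq, "exp")
  ctrlTab <- process(ctrlFastq, "ctrl")
  depl <- computeDepletion(expTab, ctrlTab, pseudocount = pseudocount,
                           pThreshold = pThreshold)
  depleted <- callDepleted(depl, pThreshold)
  message(length(depleted), " depleted PAM variant(s) at p < ", pThreshold)
  profile <- positionDepletion(depl, depleted, pseudocount = pseudocount)
  files <- c(
    exp_counts = writeCountsTsv(expTab, file.path(outDir, "counts_exp.tsv")),
    ctrl_counts = writeCountsTsv(ctrlTab, file.path(outDir, "counts_ctrl.tsv")),
    depletion = writeDepletionTsv(depl, file.path(outDir, "depletion.tsv")),
    profile = writePositionProfileTsv(profile,
                                      file.path(outDir, "position_profile.tsv")))
  consensus <- NULL
  if (length(depleted)) {
    consensus <- callConsensus(profile, dominanceThreshold)
    logo <- buildLogoMatrix(depleted)
    logoDf <- data.frame(position = seq_len(nrow(logoProbabilities(logo))),
                         logoProbabilities(logo),
                         information_content = informationContent(logo))
    write.table(logoDf, file.path(outDir, "logo_matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    wheel <- tryCatch(buildPamWheel(depl, positions = wheelPositions),
                      error = function(e) NULL)
    if (!is.null(wheel))
      write.table(wheel, file.path(outDir, "pam_wheel.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(consensus = consensusIupac(consensus),
           dominance_threshold = dominanceThreshold,
           n_depleted = length(depleted),
           qc = list(exp = as.list(qcStats(expTab)),
                     ctrl = as.list(qcStats(ctrlTab)))),
      file.path(outDir, "consensus.json"), auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(
      list(consensus = NULL, n_depleted = 0L,
           qc = list(exp = as.list(qcStats(expTab)),
                     ctrl = as.list(qcStats(ctrlTab)))),
      file.path(outDir, "consensus.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  .writeManifest(outDir, "screen",
                 list(exp_fastq = expFastq, ctrl_fastq = ctrlFastq,
                      min_mean_q = minMeanQ,
                      max_anchor_mismatches = maxAnchorMismatches,
                      pseudocount = pseudocount, p_threshold = pThreshold,
                      dominance_threshold = dominanceThreshold))
  invisible(list(exp = expTab, ctrl = ctrlTab, depletion = depl,
                 depleted = depleted, profile = profile,
                 consensus = consensus, outDir = outDir))
}

#' Simulate a synthetic dataset bundle from a config
#'
#' Drives \code{\link{simulateScreen}} or \code{\link{simulateSmallRna}}
#' from a config list or JSON/YAML file and writes the dataset plus a
#' truth JSON and a config echo into \code{outDir}.
#'
#' @param config A list, or a JSON/YAML path, with elements:
#'   \code{mode} ("screen" or "small_rna"); for screen mode
#'   \code{n_molecules_exp}, \code{n_molecules_ctrl}, optional
#'   \code{members} (custom library), \code{rules} (recognition rule
#'   table), \code{base_survival}, \code{recognized_survival}; for
#'   small_rna mode \code{end_jitter} plus \code{\link{makeToyLocus}}
#'   parameters. \code{seed} everywhere.
#' @param outDir Output directory.
#' @return Invisibly, the simulation result (with output file paths).
#' @export
runSimulate <- function(config, outDir) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config needs the 'yaml' package; use JSON instead")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  mode <- config$mode %||% "screen"
  seed <- as.integer(config$seed %||% 1L)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (mode == "screen") {
    rules <- if (!is.null(config$rules))
      as.data.frame(config$rules) else data.frame()
    model <- recognitionModel(rules,
                              baseSurvival = config$base_survival %||% 1.0,
                              recognizedSurvival =
                                config$recognized_survival %||% 0.05)
    res <- simulateScreen(
      model,
      nMoleculesExp = config$n_molecules_exp %||% 100000L,
      nMoleculesCtrl = config$n_molecules_ctrl %||% 100000L,
      library = config$members, seed = seed, output = "fastq", dir = outDir)
    truthPath <- file.path(outDir, "truth.json")
    jsonlite::write_json(lapply(res$truth, function(x)
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x),
      truthPath, auto_unbox = TRUE, digits = NA)
    res$files <- c(exp = res$exp, ctrl = res$ctrl, truth = truthPath)
  } else if (mode == "small_rna") {
    locus <- makeToyLocus(
      nSpacers = config$n_spacers %||% 9L,
      tracrLens = config$tracr_lens %||% c(70L, 90L, 107L),
      depth = config$depth %||% 100L, seed = seed)
    sim <- simulateSmallRna(locus, endJitter = config$end_jitter %||% 0L,
                            seed = seed + 1L)
    sam <- file.path(outDir, "small_rna.sam")
    writeSamAlignments(sim$alignments, locus$sequence, sam)
    fa <- file.path(outDir, "locus.fasta")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(c(locus = locus$sequence)), fa)
    truthPath <- file.path(outDir, "truth.json")
    jsonlite::write_json(list(seed = seed, species = sim$truth$species,
                              end_jitter = sim$truth$endJitter),
                         truthPath, auto_unbox = TRUE, digits = NA)
    res <- list(locus = locus, sim = sim,
                files = c(sam = sam, fasta = fa, truth = truthPath))
  } else stop("unknown simulation mode: ", mode)
  cfgPath <- file.path(outDir, "config_echo.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  .writeManifest(outDir, "simulate", list(mode = mode, seed = seed))
  invisible(res)
}

#' Profile small-RNA reads against an annotated locus
#'
#' Collects 5'/3' read ends from a SAM/BAM (or placement table),
#' reconstructs RNA species, annotates them against the locus array and
#' tracrRNA region, calls the array transcription orientation, and writes
#' the species TSV, end-histogram BedGraphs and orientation JSON.
#'
#' @param alignments SAM/BAM path or placements data.frame.
#' @param locusFasta Locus FASTA path (single record).
#' @param outDir Output directory.
#' @param array Optional \linkS4class{CrisprArray}; detected from the
#'   locus when omitted.
#' @param tracrRegion Optional \code{IRanges} of the tracrRNA region;
#'   taken from the top anti-repeat hit when omitted.
#' @param minSupport,endWindow,lenBand Species calling parameters, see
#'   \code{\link{reconstructSpecies}}.
#' @param margin Orientation confidence margin.
#' @return Invisibly, a list with \code{species} (annotated GRanges),
#'   \code{orientation}, \code{hist} and output \code{files}.
#' @export
runSmallRna <- function(alignments, locusFasta, outDir, array = NULL,
                        tracrRegion = NULL, minSupport = 5L, endWindow = 3L,
                        lenBand = c(40L, 130L), margin = 0.05) {
  if (!file.exists(locusFasta)) stop("locus FASTA not found: ", locusFasta)
  locus <- Biostrings::readDNAStringSet(locusFasta)
  if (!length(locus)) stop("locus FASTA is empty")
  locusSeq <- as.character(locus[[1]])
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hist <- collectEnds(alignments, nchar(locusSeq))
  if (is.null(array)) {
    arrays <- detectArray(locusSeq)
    if (!length(arrays)) stop("no CRISPR array found in the locus")
    array <- arrays[[1]]
  }
  if (is.null(tracrRegion)) {
    hits <- findAntiRepeat(locusSeq, repeatConsensus(array),
                           exclude = repeatRanges(array))
    tracrRegion <- if (length(hits)) IRanges::ranges(hits[1])
                   else IRanges::IRanges()
  }
  species <- reconstructSpecies(hist, minSupport = minSupport,
                                endWindow = endWindow, lenBand = lenBand)
  species <- annotateSpecies(species, array, tracrRegion)
  orientation <- callOrientation(hist, array, margin = margin)
  if (!orientation$called) message("orientation ", orientation$status)
  files <- c(
    species = writeSpeciesTsv(species, file.path(outDir, "species.tsv")),
    writeEndBedgraph(hist, file.path(outDir, "ends")))
  jsonlite::write_json(orientation,
                       file.path(outDir, "orientation.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  .writeManifest(outDir, "smallrna",
                 list(locus_fasta = locusFasta, min_support = minSupport,
                      end_window = endWindow, len_band = lenBand,
                      margin = margin))
  invisible(list(species = species, orientation = orientation, hist = hist,
                 array = array, tracrRegion = tracrRegion, files = files))
}
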