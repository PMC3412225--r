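## Pipeline commands: thin reproducible wrappers that tie the modules to
## files on disk.  Every command resolves its parameters, writes them
## alongside its outputs, and logs the package version, so a run is pure
## given (inputs, config, seed).

.logLine <- function(cmd, params) {
  message(sprintf("[retrotrap %s] %s: %s",
                  as.character(utils::packageVersion("retrotrap")), cmd,
                  paste(names(params), unlist(lapply(params, format)),
                        sep = "=", collapse = " ")))
}

.writeResolved <- function(params, outDir, cmd) {
  path <- file.path(outDir, paste0(cmd, "_config.json"))
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML with a \code{global} block (must contain \code{seed}; optional
#' \code{outdir}) and per-command blocks.  Unknown keys are rejected so
#' typos cannot silently fall back to defaults.
#'
#' @param path YAML file.
#' @return nested list of parameters.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- list(
    global = c("seed", "outdir", "verbose"),
    simulate = c("n_genuine", "n_chimera", "n_empty", "l1_length",
                 "target_length", "gc_fraction", "polyA_length",
                 "tsd_length", "truncation_offset", "orientation",
                 "n_oligos", "oligo_length", "en_sites",
                 "true_lambda", "inputs_pg", "replicates"),
    estimate_dilution = c("table", "alpha"),
    model_enrichment = c("mass_ug", "genome_pg", "filled_start",
                         "gain_empty", "gain_filled", "cycles",
                         "recovery_filled", "recovery_empty", "rounds",
                         "n_targets"),
    screen_depth = c("loci", "dna_mass_ug", "pg_per_haploid",
                     "filled_site_efficiency", "haploid_genome_kb",
                     "diploid_genome_pg", "alpha", "observed"),
    classify = c("amplicons", "target", "l1"),
    scan_target = c("target", "oligos", "repeats", "max_mismatch",
                    "motif", "min_window"))
  bad <- setdiff(names(cfg), names(known))
  if (length(bad))
    stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (blk in names(cfg)) {
    extra <- setdiff(names(cfg[[blk]]), known[[blk]])
    if (length(extra))
      stop("unknown key(s) in '", blk, "': ", paste(extra, collapse = ", "))
  }
  if (is.null(cfg$global$seed))
    stop("config must set global: seed (explicit seeds keep runs reproducible)")
  cfg
}

#' Simulate a full fixture bundle
#'
#' Writes everything the pipeline consumes, with ground truth: an L1
#' reference and probe oligos (FASTA), a target locus and a chimera
#' donor (FASTA), planted endonuclease sites (BED), genuine/chimeric/
#' empty amplicons (FASTA) with a truth JSON sidecar, and a
#' limiting-dilution table (TSV).  Byte-identical under a fixed seed.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed; required, no default.
#' @param nGenuine,nChimera,nEmpty amplicon counts per class.
#' @param config a \linkS4class{SimConfig} used as the base structural
#'   parameter set (per-amplicon seeds and structure vary around it).
#' @param nOligos,oligoLength probe oligo set shape.
#' @param enSites planted endonuclease sites per target.
#' @param trueLambda,inputsPg,replicates dilution-series parameters.
#' @return invisibly, a list of the paths written.
#' @export
runSimulate <- function(outDir, seed, nGenuine = 5, nChimera = 5,
                        nEmpty = 2, config = simConfig(),
                        nOligos = 4, oligoLength = 30, enSites = 5,
                        trueLambda = 1 / 12,
                        inputsPg = c(1, 3, 10, 30, 100), replicates = 8) {
  if (missing(seed)) stop("an explicit seed is required")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  params <- list(seed = seed, n_genuine = nGenuine, n_chimera = nChimera,
                 n_empty = nEmpty, l1_length = config@l1Length,
                 target_length = config@targetLength,
                 n_oligos = nOligos, oligo_length = oligoLength,
                 en_sites = enSites, true_lambda = trueLambda,
                 inputs_pg = inputsPg, replicates = replicates)
  .logLine("simulate", params)

  base <- simConfig(seed = seed, l1Length = config@l1Length,
                    targetLength = config@targetLength,
                    gcFraction = config@gcFraction,
                    l1GcFraction = config@l1GcFraction,
                    polyALength = config@polyALength,
                    tsdLength = config@tsdLength,
                    truncationOffset = config@truncationOffset,
                    orientation = config@orientation,
                    polyAErrorRate = config@polyAErrorRate)
  l1 <- genL1Reference(base)
  oligos <- genBioOligos(l1, n = nOligos, length = oligoLength)
  tl <- genTargetLocus(base@targetLength, gc = base@gcFraction,
                       plantedEnSites = enSites, seed = seed,
                       oligos = oligos, aLinker = TRUE)

  maxTrunc <- max(0L, base@l1Length - 400L)
  amps <- list(); truths <- list()
  addAmp <- function(id, res) {
    amps[[id]] <<- res$sequence
    truths[[id]] <<- res$truth
  }
  for (i in seq_len(nGenuine)) {
    ci <- withSeed(.deriveSeed(seed, paste0("g", i)), simConfig(
      seed = .deriveSeed(seed, paste0("gen", i)),
      l1Length = base@l1Length, targetLength = base@targetLength,
      gcFraction = base@gcFraction, l1GcFraction = base@l1GcFraction,
      polyALength = base@polyALength,
      tsdLength = sample(7:20, 1L),
      truncationOffset = sample(0:maxTrunc, 1L),
      orientation = sample(c("plus", "minus"), 1L),
      polyAErrorRate = base@polyAErrorRate))
    addAmp(sprintf("genuine%03d", i), genInsertionAmplicon(tl, l1, ci))
  }
  for (i in seq_len(nChimera)) {
    ci <- withSeed(.deriveSeed(seed, paste0("c", i)), simConfig(
      seed = .deriveSeed(seed, paste0("chi", i)),
      l1Length = base@l1Length, targetLength = base@targetLength,
      gcFraction = base@gcFraction, l1GcFraction = base@l1GcFraction,
      polyALength = base@polyALength,
      truncationOffset = sample(0:maxTrunc, 1L)))
    donor <- genChimeraDonor(l1, ci)
    addAmp(sprintf("chimera%03d", i),
           genChimericAmplicon(tl, donor, seed = ci@seed,
                               donorLocusId = sprintf("donor%03d", i)))
  }
  for (i in seq_len(nEmpty)) {
    truth <- new("TruthRecord", kind = "empty",
                 ampliconLength = length(tl$sequence))
    addAmp(sprintf("empty%03d", i),
           list(sequence = tl$sequence, truth = truth))
  }

  paths <- list(
    l1 = file.path(outDir, "l1_reference.fasta"),
    oligos = file.path(outDir, "bio_oligos.fasta"),
    target = file.path(outDir, "target.fasta"),
    enSites = file.path(outDir, "en_sites.bed"),
    amplicons = file.path(outDir, "amplicons.fasta"),
    truth = file.path(outDir, "amplicons_truth.json"),
    dilution = file.path(outDir, "dilution.tsv"))
  writeXStringSet(Biostrings::DNAStringSet(list(L1 = l1)), paths$l1)
  writeXStringSet(oligos, paths$oligos)
  writeXStringSet(Biostrings::DNAStringSet(list(target = tl$sequence)),
                  paths$target)
  rtracklayer::export.bed(
    GenomicRanges::GRanges("target",
                           IRanges::IRanges(tl$enSites$position + 1L,
                                            width = 6L),
                           strand = tl$enSites$strand,
                           name = paste0("EN", seq_len(nrow(tl$enSites)))),
    paths$enSites)
  writeXStringSet(Biostrings::DNAStringSet(amps), paths$amplicons)
  writeTruthJSON(truths, paths$truth)
  writeDilutionSeries(genDilutionSeries(trueLambda, inputsPg, replicates,
                                        seed = seed), paths$dilution)
  .writeResolved(params, outDir, "simulate")
  invisible(paths)
}

#' Estimate molecules from a dilution table on disk
#'
#' @param tablePath dilution TSV (see \code{\link{readDilutionSeries}}).
#' @param outPath optional JSON output path.
#' @param alpha significance level.
#' @return the \linkS4class{MoleculeEstimate}, invisibly.
#' @export
runEstimateDilution <- function(tablePath, outPath = NULL, alpha = 0.05) {
  .logLine("estimate-dilution", list(table = tablePath, alpha = alpha))
  est <- estimateMolecules(readDilutionSeries(tablePath), alpha = alpha)
  message(estimateSummary(est))
  if (!is.null(outPath)) writeEstimateJSON(est, outPath)
  invisible(est)
}

#' Run the enrichment accounting ledger to disk
#'
#' @param outPath TSV output path (stage, filled, empty, ratio).
#' @inheritParams enrichmentLedger
#' @return the ledger data.frame, invisibly.
#' @export
runModelEnrichment <- function(outPath = NULL, massUg = 0.5, genomePg = 6,
                               filledStart = 1,
                               params = amplificationParams(),
                               nTargets = 10,
                               eparams = enrichmentParams()) {
  .logLine("model-enrichment",
           list(mass_ug = massUg, genome_pg = genomePg,
                filled_start = filledStart, cycles = params@cycles,
                rounds = eparams@rounds, n_targets = nTargets))
  led <- enrichmentLedger(massUg, genomePg, filledStart, params, nTargets,
                          eparams)
  if (!is.null(outPath)) {
    con <- file(outPath, "w")
    writeLines("# enrichment ledger: molecule counts (expected) per stage",
               con)
    utils::write.table(led, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(led)
}

#' Compute screening depth and the frequency bound to disk
#'
#' @param lociPath locus table (default: the packaged ten-locus panel).
#' @param outPath optional JSON output path.
#' @param dnaMassUg,pgPerHaploid,filledSiteEfficiency,haploidGenomeKb
#'   design constants (see \code{\link{screeningDesign}}).
#' @param diploidGenomePg design constant.
#' @param observed observed genuine-insertion count.
#' @param alpha significance level.
#' @return the \code{\link{screenChain}} result, invisibly.
#' @export
runScreenDepth <- function(lociPath = NULL, outPath = NULL, dnaMassUg = 576,
                           pgPerHaploid = 3, filledSiteEfficiency = 0.5,
                           haploidGenomeKb = 3e6, diploidGenomePg = 6,
                           observed = 0, alpha = 0.05) {
  loci <- if (is.null(lociPath)) targetLoci() else targetLoci(lociPath)
  design <- screeningDesign(loci, dnaMassUg, pgPerHaploid,
                            filledSiteEfficiency, haploidGenomeKb,
                            diploidGenomePg)
  .logLine("screen-depth",
           list(loci = nrow(loci), dna_mass_ug = dnaMassUg,
                observed = observed, alpha = alpha))
  chain <- screenChain(design, observed = observed, alpha = alpha)
  message(chain$summary)
  if (!is.null(outPath)) {
    b <- chain$bound
    jsonlite::write_json(list(
      total_bp = chain$totalBp, effective_bp = chain$effectiveBp,
      total_kb_rounded = round(chain$totalBp / 1000),
      effective_kb_rounded = round(chain$effectiveBp / 1000),
      sperm = chain$sperm,
      molecules_per_target = chain$moleculesPerTarget,
      kb_screened = chain$kbScreened,
      events_upper_bound = eventsUb(b), alpha = b@alpha,
      rate_per_kb = b@ratePerKb,
      genomes_per_event = genomesPerEvent(b),
      genomes_per_event_floored = chain$genomesPerEventFloored,
      summary = chain$summary),
      outPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(chain)
}

#' Classify a FASTA of candidate amplicons
#'
#' Writes a tab-separated verdict table, an annotation JSON and a BED of
#' feature tracks in amplicon coordinates.  A record whose sequence
#' cannot be read (invalid characters) is reported as an error row and
#' the run continues.
#'
#' @param ampliconFasta FASTA of candidate amplicons.
#' @param targetFasta FASTA with the target reference (first record).
#' @param l1Fasta FASTA with the element reference (first record).
#' @param outDir output directory.
#' @param thresholds see \code{\link{classifierThresholds}}.
#' @return invisibly, list with \code{annotations} and \code{verdicts}
#'   (data.frame).
#' @export
runClassify <- function(ampliconFasta, targetFasta, l1Fasta, outDir = NULL,
                        thresholds = classifierThresholds()) {
  ## read as raw strings so one bad record cannot abort the batch;
  ## per-record validation happens in classifyAmplicon
  amps <- Biostrings::readBStringSet(ampliconFasta)
  target <- readDNAStringSet(targetFasta)[[1L]]
  l1 <- readDNAStringSet(l1Fasta)[[1L]]
  .logLine("classify", list(amplicons = length(amps),
                            target = targetFasta, l1 = l1Fasta))
  ids <- if (is.null(names(amps))) paste0("amp", seq_along(amps))
         else names(amps)
  anns <- list(); rows <- list()
  for (i in seq_along(amps)) {
    res <- tryCatch(
      classifyAmplicon(as.character(amps[[i]]), target, l1, thresholds,
                       id = ids[i]),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(id = ids[i], verdict = "error",
                              evidence = conditionMessage(res))
    } else {
      anns[[ids[i]]] <- res
      rows[[i]] <- data.frame(id = ids[i], verdict = verdict(res),
                              evidence = paste(evidence(res),
                                               collapse = "; "))
    }
  }
  verdicts <- if (length(rows)) do.call(rbind, rows)
    else data.frame(id = character(), verdict = character(),
                    evidence = character())
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    con <- file(file.path(outDir, "verdicts.tsv"), "w")
    writeLines("# amplicon verdicts (genuine | chimera | no_insertion | unresolved | error)",
               con)
    utils::write.table(verdicts, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    writeAnnotationJSON(anns, file.path(outDir, "annotations.json"))
    if (length(anns))
      writeAnnotationBed(anns, file.path(outDir, "features.bed"))
  }
  invisible(list(annotations = anns, verdicts = verdicts))
}

#' Screen a target FASTA against probe oligos and repeats
#'
#' @param targetFasta FASTA with the target (first record).
#' @param oligosFasta FASTA of probe oligos.
#' @param repeatsBed optional BED of repeat intervals.
#' @param outPath optional JSON output path.
#' @param maxMismatch,motif,minWindow see \code{\link{screenTarget}}.
#' @return the \linkS4class{ScreenReport}, invisibly.
#' @export
runScanTarget <- function(targetFasta, oligosFasta, repeatsBed = NULL,
                          outPath = NULL, maxMismatch = 3,
                          motif = "TTAAAA", minWindow = 200) {
  target <- readDNAStringSet(targetFasta)
  oligos <- readDNAStringSet(oligosFasta)
  reps <- if (is.null(repeatsBed)) NULL else readRepeatsBed(repeatsBed)
  .logLine("scan-target", list(target = targetFasta, oligos = length(oligos),
                               max_mismatch = maxMismatch))
  rep1 <- screenTarget(target[[1L]], oligos, reps, maxMismatch, motif,
                       minWindow,
                       targetId = if (is.null(names(target))) "target"
                                  else names(target)[1L])
  if (!is.null(outPath)) {
    jsonlite::write_json(list(
      target_id = rep1@targetId,
      passes_oligo_screen = rep1@passesOligoScreen,
      oligo_hits = rep1@oligoHits,
      en_sites = rep1@enSites, en_density = rep1@enDensity,
      primer_windows = .iranges0(rep1@primerWindows)),
      outPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(rep1)
}
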