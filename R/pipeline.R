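# End-to-end orchestration: simulate -> mine -> TSD -> date -> target ->
# ChIP -> report, with one reproducibility seed from which per-stage seeds
# are derived so toggling a stage does not perturb the others.

#' Jaccard index of two interval sets
#'
#' Intersection width over union width, strand-ignored.
#'
#' @param a,b \link[GenomicRanges]{GRanges}.
#' @return Jaccard index in [0, 1] (0 if both sets are empty).
#' @export
intervalJaccard <- function(a, b) {
  a <- GenomicRanges::reduce(a, ignore.strand = TRUE)
  b <- GenomicRanges::reduce(b, ignore.strand = TRUE)
  un <- sum(GenomicRanges::width(
    suppressWarnings(GenomicRanges::union(a, b))))
  if (un == 0) return(0)
  inter <- sum(GenomicRanges::width(
    suppressWarnings(GenomicRanges::intersect(a, b))))
  inter / un
}

.stageSeed <- function(seed, stage) {
  (as.integer(seed) * 131L + stage * 7919L) %% 2147483587L
}

#' Run the full simulation-and-analysis pipeline
#'
#' Generates a synthetic genome with planted insertions, mines copies back
#' with an anchor cut from the master element, classifies them, detects
#' TSDs, dates the full-length copies, scores domain targeting against the
#' random-placement null, detects nesting, simulates and analyzes ChIP
#' reads, and writes all stage outputs plus a summary report to
#' \code{outdir}.
#'
#' @param outdir Output directory (created if needed).
#' @param cfg A \linkS4class{SimConfig}.
#' @param master Optional \linkS4class{ReferenceElement}; by default a
#'   master element is generated from the pipeline seed.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param enrichmentFold,nReads ChIP simulation parameters.
#' @param minHitLen,minIdentity Mining thresholds.
#' @return Invisibly, a list with the per-stage results and the
#'   \code{summary} data.frame that is also written to
#'   \code{report.tsv}.
#' @export
runPipeline <- function(outdir, cfg = simConfig(), master = NULL,
                        seed = cfg@seed, enrichmentFold = 30,
                        nReads = 50000L, minHitLen = 200L,
                        minIdentity = 0.8) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(master))
    master <- makeMasterElement(utr5 = 150L, orf1 = 600L, orf2 = 1200L,
                                utr3 = 80L, seed = .stageSeed(seed, 0L))

  # -- simulate -------------------------------------------------------
  sim <- simulateGenome(cfg, seed = .stageSeed(seed, 1L))
  sim <- plantInsertions(sim, master, seed = .stageSeed(seed, 2L))
  writeGenome(sim@genome, file.path(outdir, "genome.fa"))
  writeBed(sim@domains, file.path(outdir, "domains.bed"))
  writeTsv(truthTable(sim), file.path(outdir, "truth.tsv"))

  # -- mine -----------------------------------------------------------
  L <- length(master@sequence)
  anchorRange <- c(max(1L, round(L * 0.3)), min(L, round(L * 0.75)))
  anchor <- as.character(Biostrings::subseq(master@sequence,
                                            anchorRange[1], anchorRange[2]))
  hits <- findElementCopies(sim@genome, anchor, minHitLen = minHitLen,
                            minIdentity = minIdentity)
  classified <- classifyElements(hits, sim@genome, master)
  writeGff3(classified, file.path(outdir, "elements.gff3"))

  # -- TSDs -----------------------------------------------------------
  countable <- classified[classified$class != "fragment"]
  tsds <- tsdTable(sim@genome, countable)
  writeTsv(tsds, file.path(outdir, "tsd.tsv"))

  # -- dating ---------------------------------------------------------
  full <- classified[classified$class == "full_length"]
  dating <- NULL
  if (length(full) >= 2L) {
    seqs <- Biostrings::DNAStringSet(vapply(seq_along(full), function(i) {
      ch <- as.character(GenomicRanges::seqnames(full))[i]
      s <- as.character(Biostrings::subseq(
        sim@genome[[ch]], GenomicRanges::start(full)[i],
        GenomicRanges::end(full)[i]))
      if (as.character(GenomicRanges::strand(full))[i] == "-")
        .revcompChar(s) else s
    }, character(1)))
    names(seqs) <- paste0("copy", seq_along(full))
    dating <- dateElements(seqs, mu = cfg@mu)
    writeTsv(dating, file.path(outdir, "ages.tsv"))
  }

  # -- targeting ------------------------------------------------------
  pctIn <- percentInDomains(countable, sim@domains)
  nullRes <- randomPlacementNull(sim@genome, sim@domains, countable,
                                 nReplicates = 100L,
                                 seed = .stageSeed(seed, 3L))
  writeTsv(data.frame(replicate = seq_along(nullReplicates(nullRes)),
                      percent = nullReplicates(nullRes)),
           file.path(outdir, "null.tsv"))
  nested <- detectNested(countable, sim@donorLibrary, sim@genome)
  track <- binnedDensity(countable, sim@genome,
                         bin = max(10000L, cfg@chromLength %/% 50L))

  # -- ChIP -----------------------------------------------------------
  reads <- simulateReads(sim, enrichmentFold = enrichmentFold,
                         nChip = nReads, nInput = nReads,
                         seed = .stageSeed(seed, 4L))
  writeTsv(reads$chip, file.path(outdir, "reads_chip.tsv"))
  writeTsv(reads$input, file.path(outdir, "reads_input.tsv"))
  chipTrack <- windowDensity(reads$chip, sim@genome)
  inputTrack <- windowDensity(reads$input, sim@genome)
  islands <- callDomains(chipTrack, inputTrack)
  writeBed(islands, file.path(outdir, "islands.bed"))

  # -- report ---------------------------------------------------------
  truth <- truthTable(sim)
  summary <- data.frame(
    metric = c("n_hits", "n_full_length", "n_truncated", "n_fragment",
               "copy_number", "pct_in_domains", "null_mean_pct",
               "pct_below_1My", "n_tsd_high_confidence",
               "pct_nested", "n_islands", "island_jaccard_vs_truth"),
    value = c(length(hits),
              sum(classified$class == "full_length"),
              sum(classified$class == "truncated"),
              sum(classified$class == "fragment"),
              copyNumber(classified),
              round(pctIn, 2),
              round(nullMean(nullRes), 2),
              if (is.null(dating)) NA else
                fractionBelow(dating$age_years, 1e6),
              sum(tsds$high_confidence),
              round(100 * mean(!is.na(nested)), 2),
              length(islands),
              round(intervalJaccard(islands, sim@domains), 4)))
  writeTsv(summary, file.path(outdir, "report.tsv"))
  invisible(list(sim = sim, hits = hits, classified = classified,
                 tsds = tsds, dating = dating, pctInDomains = pctIn,
                 null = nullRes, nested = nested, track = track,
                 islands = islands, summary = summary))
}
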