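# Simplified CENH3 enrichment analysis on 1-kb windows: unique-read density
# per mappable bp, a Poisson count model against the input-scaled
# expectation, Benjamini-Hochberg FDR across windows, and island merging
# under the stated fold > 5 / FDR < 0.001 thresholds.

#' Windowed unique-read density
#'
#' Collapses duplicate read positions (unique reads), counts read starts
#' per fixed-width window, and divides by the mappable bp of the window
#' (fully mappable by default).
#'
#' @param reads data.frame with columns \code{chrom}, \code{start} and
#'   optionally \code{strand}.
#' @param chromLengths Named numeric vector of chromosome lengths, or a
#'   named \link[Biostrings]{DNAStringSet}.
#' @param window Window width, bp (default 1000).
#' @param mappability Optional \link[GenomicRanges]{GRanges} of mappable
#'   regions; windows outside it get reduced mappable bp, and density is
#'   \code{NA} where mappable bp is 0.
#' @return A \link[GenomicRanges]{GRanges} of windows with metadata columns
#'   \code{count}, \code{mappable}, \code{density}.
#' @export
windowDensity <- function(reads, chromLengths, window = 1000L,
                          mappability = NULL) {
  lens <- if (methods::is(chromLengths, "DNAStringSet")) {
    stats::setNames(Biostrings::width(chromLengths), names(chromLengths))
  } else chromLengths
  keyCols <- intersect(c("chrom", "start", "strand"), names(reads))
  reads <- unique(reads[keyCols])
  bad <- !(reads$chrom %in% names(lens)) | reads$start < 1 |
    reads$start > lens[reads$chrom]
  if (any(bad)) stop("read positions outside the assembly")
  bins <- suppressWarnings(do.call(c, lapply(names(lens), function(ch) {
    starts <- seq(1L, lens[[ch]], by = window)
    GenomicRanges::GRanges(ch, IRanges::IRanges(
      start = starts, end = pmin(starts + window - 1L, lens[[ch]])))
  })))
  counts <- rep(0L, length(bins))
  if (nrow(reads) > 0L) {
    rg <- GenomicRanges::GRanges(reads$chrom,
                                 IRanges::IRanges(reads$start, width = 1L))
    counts <- GenomicRanges::countOverlaps(bins, rg)
  }
  mappable <- GenomicRanges::width(bins)
  if (!is.null(mappability)) {
    mappable <- rep(0L, length(bins))
    ov <- GenomicRanges::findOverlaps(bins, mappability)
    if (length(ov) > 0L) {
      inter <- IRanges::pintersect(bins[S4Vectors::queryHits(ov)],
                                   mappability[S4Vectors::subjectHits(ov)])
      mb <- tapply(GenomicRanges::width(inter),
                   S4Vectors::queryHits(ov), sum)
      mappable[as.integer(names(mb))] <- mb
    }
  }
  bins$count <- counts
  bins$mappable <- mappable
  bins$density <- ifelse(mappable > 0, counts / mappable, NA_real_)
  bins
}

#' Call enrichment domains from ChIP and input window tracks
#'
#' Per-window p-values come from a Poisson model: the ChIP count is tested
#' against the input count scaled by the library-size ratio,
#' \eqn{\lambda = input \times chipLib / inputLib}. P-values are adjusted
#' by Benjamini-Hochberg across all windows with at least one input read.
#' Windows passing both \code{fold > foldMin} and \code{q < fdrMax} are
#' merged into islands across up to \code{gap} failing windows.
#'
#' @param chip,input Window tracks from [windowDensity()] on matching
#'   windows.
#' @param foldMin Fold-change threshold (exclusive; default 5).
#' @param fdrMax FDR threshold (exclusive; default 0.001).
#' @param gap Maximum failing windows bridged inside an island (default 1).
#' @param chipLib,inputLib Library sizes used for normalization; by default
#'   the total counts of the supplied tracks, but totals of the full
#'   libraries can be given when the tracks cover only part of the genome.
#' @return A \link[GenomicRanges]{GRanges} of islands with metadata columns
#'   \code{meanFold} and \code{minQ}. The window-level statistics are
#'   attached as attribute \code{"windows"} (a data.frame with \code{fold},
#'   \code{p}, \code{q}).
#' @export
callDomains <- function(chip, input, foldMin = 5, fdrMax = 0.001,
                        gap = 1L, chipLib = sum(chip$count),
                        inputLib = sum(input$count)) {
  stopifnot(length(chip) == length(input))
  if (inputLib == 0 || chipLib == 0) stop("zero input library")
  scale <- chipLib / inputLib
  lambda <- input$count * scale
  p <- rep(NA_real_, length(chip))
  testable <- input$count >= 1L
  p[testable] <- stats::ppois(chip$count[testable] - 1L,
                              lambda[testable], lower.tail = FALSE)
  q <- rep(NA_real_, length(chip))
  q[testable] <- stats::p.adjust(p[testable], method = "BH")
  fold <- ifelse(input$count > 0,
                 (chip$count / chipLib) / (input$count / inputLib),
                 NA_real_)
  pass <- !is.na(q) & q < fdrMax & !is.na(fold) & fold > foldMin
  win <- data.frame(fold = fold, p = p, q = q, pass = pass)
  if (!any(pass)) {
    res <- GenomicRanges::GRanges()
    attr(res, "windows") <- win
    return(res)
  }
  window <- max(GenomicRanges::width(chip))
  islands <- GenomicRanges::reduce(chip[pass],
                                   min.gapwidth = gap * window + 1L)
  ov <- GenomicRanges::findOverlaps(islands, chip[pass])
  mf <- tapply(fold[pass][S4Vectors::subjectHits(ov)],
               S4Vectors::queryHits(ov), mean)
  mq <- tapply(q[pass][S4Vectors::subjectHits(ov)],
               S4Vectors::queryHits(ov), min)
  islands$meanFold <- as.numeric(mf)
  islands$minQ <- as.numeric(mq)
  attr(islands, "windows") <- win
  islands
}

#' Per-cluster ChIP enrichment and genome proportion
#'
#' For each repeat cluster, the enrichment fold is
#' \code{(chip_hits / chip_lib) / (input_hits / input_lib)} (a pseudocount
#' of 1 is added to both hit counts when either is zero) and the genome
#' proportion is \code{input_hits / input_lib}.
#'
#' @param chipAssignments,inputAssignments Character vectors of cluster ids,
#'   one entry per read assigned to a cluster.
#' @param chipLib,inputLib Total library sizes (>= the number of assigned
#'   reads; default: the number of assignments).
#' @return A data.frame with columns \code{cluster}, \code{chip_hits},
#'   \code{input_hits}, \code{fold}, \code{genome_proportion}.
#' @export
clusterEnrichment <- function(chipAssignments, inputAssignments,
                              chipLib = length(chipAssignments),
                              inputLib = length(inputAssignments)) {
  if (chipLib <= 0 || inputLib <= 0) stop("empty library")
  clusters <- sort(unique(c(chipAssignments, inputAssignments)))
  chipN <- table(factor(chipAssignments, levels = clusters))
  inputN <- table(factor(inputAssignments, levels = clusters))
  chipH <- as.numeric(chipN)
  inputH <- as.numeric(inputN)
  zero <- chipH == 0 | inputH == 0
  chipAdj <- ifelse(zero, chipH + 1, chipH)
  inputAdj <- ifelse(zero, inputH + 1, inputH)
  data.frame(
    cluster = clusters,
    chip_hits = as.integer(chipH),
    input_hits = as.integer(inputH),
    fold = (chipAdj / chipLib) / (inputAdj / inputLib),
    genome_proportion = inputH / inputLib,
    stringsAsFactors = FALSE)
}
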