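# Centromere-targeting statistics: element/domain overlap classes, the
# random-placement null, binned density tracks, and nested-insertion
# detection from the downstream flanking sequence.

#' Classify elements relative to centromeric domains
#'
#' \code{inside}: at least 1 bp of overlap with a domain; \code{near}:
#' within \code{flank} bp of the nearest domain; \code{outside}: otherwise.
#' The three classes are mutually exclusive and exhaustive.
#'
#' @param elements \link[GenomicRanges]{GRanges} of elements.
#' @param domains \link[GenomicRanges]{GRanges} of domains.
#' @param flank Distance defining \code{near}, bp (default 20 kb).
#' @param genome Optional named \link[Biostrings]{DNAStringSet}; if given,
#'   element chromosomes are validated against it.
#' @return Character vector (\code{"inside"}, \code{"near"},
#'   \code{"outside"}) parallel to \code{elements}.
#' @export
assignDomainRelation <- function(elements, domains, flank = 20000L,
                                 genome = NULL) {
  if (!is.null(genome)) {
    bad <- !(as.character(GenomicRanges::seqnames(elements)) %in%
               names(genome))
    if (any(bad))
      stop("unknown chromosome: ",
           paste(unique(as.character(
             GenomicRanges::seqnames(elements))[bad]), collapse = ", "))
  }
  rel <- rep("outside", length(elements))
  inside <- IRanges::overlapsAny(elements, domains, ignore.strand = TRUE)
  rel[inside] <- "inside"
  near <- rep(FALSE, length(elements))
  dn <- GenomicRanges::distanceToNearest(elements, domains,
                                         ignore.strand = TRUE)
  near[S4Vectors::queryHits(dn)] <-
    S4Vectors::mcols(dn)$distance <= flank
  rel[!inside & near] <- "near"
  rel
}

#' Percentage of elements inside domains
#'
#' @inheritParams assignDomainRelation
#' @return \code{100 * n_inside / n_elements}.
#' @export
percentInDomains <- function(elements, domains) {
  if (length(elements) == 0L) stop("empty element list")
  100 * mean(IRanges::overlapsAny(elements, domains, ignore.strand = TRUE))
}

# Uniform non-overlapping placement of interval lengths on [1, L]:
# stick-breaking over the free space.
.placeLengths <- function(lens, L) {
  k <- length(lens)
  free <- L - sum(lens)
  if (free < 0) stop("impossible placement: intervals exceed chromosome")
  if (k > 1L) lens <- sample(lens)           # random order
  gaps <- sort(sample.int(free + 1L, k, replace = TRUE) - 1L)
  starts <- gaps + cumsum(c(0L, lens[-k])) + 1L
  IRanges::IRanges(start = starts, width = lens)
}

#' Random-placement null for domain targeting
#'
#' Re-places the domain set \code{nReplicates} times, preserving each
#' domain's length and chromosome, uniformly without overlap within each
#' chromosome, and scores the percentage of elements falling inside the
#' random regions. The expectation is the genome fraction covered by the
#' domains.
#'
#' @param genome Named \link[Biostrings]{DNAStringSet}, or a named numeric
#'   vector of chromosome lengths.
#' @param domains \link[GenomicRanges]{GRanges} of domains to re-place.
#' @param elements \link[GenomicRanges]{GRanges} of elements to score.
#' @param nReplicates Number of replicates (default 100).
#' @param seed RNG seed.
#' @return A \linkS4class{NullResult}.
#' @export
randomPlacementNull <- function(genome, domains, elements,
                                nReplicates = 100L, seed = NULL) {
  lens <- if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else genome
  byChrom <- split(GenomicRanges::width(domains),
                   as.character(GenomicRanges::seqnames(domains)))
  withSeed(seed, {
    reps <- vapply(seq_len(nReplicates), function(r) {
      placed <- lapply(names(byChrom), function(ch) {
        ir <- .placeLengths(byChrom[[ch]], lens[[ch]])
        GenomicRanges::GRanges(ch, ir)
      })
      percentInDomains(elements,
                       suppressWarnings(do.call(c, placed)))
    }, numeric(1))
    methods::new("NullResult", replicates = reps, mean = mean(reps),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })
}

#' Binned element-density track normalized to a maximum of 100
#'
#' Computes the fraction of each fixed-width bin covered by elements and
#' rescales so the densest bin is 100.
#'
#' @param elements \link[GenomicRanges]{GRanges} of elements.
#' @param genome Named \link[Biostrings]{DNAStringSet} or named numeric
#'   chromosome lengths.
#' @param bin Bin width in bp (default 100 kb).
#' @return A \link[GenomicRanges]{GRanges} of bins with metadata columns
#'   \code{fraction} (covered fraction) and \code{value} (normalized to max
#'   100). With no elements, all values are 0 and attribute
#'   \code{"empty"} is set.
#' @export
binnedDensity <- function(elements, genome, bin = 100000L) {
  if (bin <= 0) stop("bin must be positive")
  lens <- if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else genome
  bins <- suppressWarnings(do.call(c, lapply(names(lens), function(ch) {
    starts <- seq(1L, lens[[ch]], by = bin)
    GenomicRanges::GRanges(ch, IRanges::IRanges(
      start = starts, end = pmin(starts + bin - 1L, lens[[ch]])))
  })))
  cov <- rep(0, length(bins))
  if (length(elements) > 0L) {
    red <- GenomicRanges::reduce(elements, ignore.strand = TRUE)
    ov <- GenomicRanges::findOverlaps(bins, red)
    if (length(ov) > 0L) {
      inter <- IRanges::pintersect(bins[S4Vectors::queryHits(ov)],
                                   red[S4Vectors::subjectHits(ov)])
      covBp <- tapply(GenomicRanges::width(inter),
                      S4Vectors::queryHits(ov), sum)
      cov[as.integer(names(covBp))] <- covBp
    }
  }
  frac <- cov / GenomicRanges::width(bins)
  bins$fraction <- frac
  if (max(frac) > 0) {
    bins$value <- 100 * frac / max(frac)
  } else {
    bins$value <- frac
    attr(bins, "empty") <- TRUE
  }
  bins
}

#' Detect nested insertions from the downstream flanking sequence
#'
#' For each element, the \code{flank} bp immediately downstream (3',
#' strand-aware) are aligned locally against a labeled donor library. If
#' the best hit covers at least \code{minLen} bp at identity
#' \code{minIdentity} or better, the element is labeled with that donor
#' family (it inserted into such an element); otherwise \code{NA}.
#'
#' @param elements \link[GenomicRanges]{GRanges} of elements.
#' @param donorLib Named \link[Biostrings]{DNAStringSet} of donor family
#'   consensus sequences.
#' @param genome Named \link[Biostrings]{DNAStringSet}.
#' @param flank Downstream window, bp (default 150).
#' @param minIdentity Identity threshold (default 0.8).
#' @param minLen Minimum aligned length, bp (default 50).
#' @return Character vector of donor family labels (NA when unnested),
#'   parallel to \code{elements}.
#' @export
detectNested <- function(elements, donorLib, genome, flank = 150L,
                         minIdentity = 0.8, minLen = 50L) {
  if (flank <= 0L) stop("flank must be positive")
  labels <- rep(NA_character_, length(elements))
  for (i in seq_along(elements)) {
    ch <- as.character(GenomicRanges::seqnames(elements))[i]
    chromSeq <- genome[[ch]]
    st <- GenomicRanges::start(elements)[i]
    en <- GenomicRanges::end(elements)[i]
    strand <- as.character(GenomicRanges::strand(elements))[i]
    if (strand == "-") {
      a <- max(1L, st - flank)
      b <- st - 1L
      if (b < a) next
      fl <- .revcompChar(as.character(Biostrings::subseq(chromSeq, a, b)))
    } else {
      a <- en + 1L
      b <- min(length(chromSeq), en + flank)
      if (b < a) next
      fl <- as.character(Biostrings::subseq(chromSeq, a, b))
    }
    bestFam <- NA_character_
    bestScore <- -Inf
    # donor orientation is unknown: test the flank in both orientations
    for (query in c(fl, .revcompChar(fl))) {
      for (fam in names(donorLib)) {
        aln <- alignGlobal(query, donorLib[[fam]], type = "local")
        alen <- Biostrings::nchar(Biostrings::pattern(aln))
        if (alen < minLen) next
        ident <- pairwiseIdentity(aln, mode = "all_columns")
        if (ident >= minIdentity && Biostrings::score(aln) > bestScore) {
          bestScore <- Biostrings::score(aln)
          bestFam <- fam
        }
      }
    }
    labels[i] <- bestFam
  }
  labels
}
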