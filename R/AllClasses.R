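#' @import methods
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges IRanges
NULL

#' Reference (master) element with annotated structure
#'
#' Holds the sequence of a full-length LINE element together with the
#' coordinates (element-local, 1-based inclusive) of its 5' UTR, the two
#' open reading frames, the 3' UTR and the poly(A) tail. ORF1 and ORF2 are
#' allowed to overlap.
#'
#' @slot sequence \link[Biostrings]{DNAString} of the element.
#' @slot utr5,orf1,orf2,utr3,polyA \link[IRanges]{IRanges} of length 1 giving
#'   each feature in element coordinates.
#' @seealso [referenceElement()], [makeMasterElement()]
#' @export
setClass("ReferenceElement",
  representation(sequence = "DNAString", utr5 = "IRanges", orf1 = "IRanges",
                 orf2 = "IRanges", utr3 = "IRanges", polyA = "IRanges"))

setValidity("ReferenceElement", function(object) {
  len <- length(object@sequence)
  feats <- list(utr5 = object@utr5, orf1 = object@orf1, orf2 = object@orf2,
                utr3 = object@utr3, polyA = object@polyA)
  for (nm in names(feats)) {
    f <- feats[[nm]]
    if (length(f) != 1L)
      return(sprintf("feature '%s' must be a single range", nm))
    if (IRanges::start(f) < 1L || IRanges::end(f) > len)
      return(sprintf("feature '%s' outside [1, %d]", nm, len))
  }
  TRUE
})

#' Construct a ReferenceElement
#'
#' @param sequence Element sequence (character or
#'   \link[Biostrings]{DNAString}).
#' @param utr5,orf1,orf2,utr3,polyA Numeric length-2 vectors
#'   \code{c(start, end)} in element coordinates, or
#'   \link[IRanges]{IRanges} of length 1.
#' @return A \linkS4class{ReferenceElement}.
#' @export
referenceElement <- function(sequence, utr5, orf1, orf2, utr3, polyA) {
  asRange <- function(x) {
    if (methods::is(x, "IRanges")) return(x)
    IRanges::IRanges(start = as.integer(x[1]), end = as.integer(x[2]))
  }
  methods::new("ReferenceElement",
               sequence = Biostrings::DNAString(as.character(sequence)),
               utr5 = asRange(utr5), orf1 = asRange(orf1),
               orf2 = asRange(orf2), utr3 = asRange(utr3),
               polyA = asRange(polyA))
}

#' @describeIn ReferenceElement-class element sequence as a
#'   \link[Biostrings]{DNAString}
#' @param x,object A \code{ReferenceElement}.
#' @export
setMethod("show", "ReferenceElement", function(object) {
  cat(sprintf("ReferenceElement of %d bp\n", length(object@sequence)))
  cat(sprintf("  5' UTR %d..%d | ORF1 %d..%d | ORF2 %d..%d | 3' UTR %d..%d | polyA %d..%d\n",
              IRanges::start(object@utr5), IRanges::end(object@utr5),
              IRanges::start(object@orf1), IRanges::end(object@orf1),
              IRanges::start(object@orf2), IRanges::end(object@orf2),
              IRanges::start(object@utr3), IRanges::end(object@utr3),
              IRanges::start(object@polyA), IRanges::end(object@polyA)))
})

#' @rdname ReferenceElement-class
#' @export
elementSequence <- function(x) x@sequence

#' @rdname ReferenceElement-class
#' @export
elementOrfs <- function(x) list(orf1 = x@orf1, orf2 = x@orf2)

#' Simulation configuration
#'
#' Parameters of the synthetic-genome generator. Defaults emulate the
#' biological setting the package targets, at a scale suited to desk-top
#' runs: a genome of a few chromosomes, one centromeric (CENH3-like) domain
#' per chromosome, a background GC content of 33.8\%, a molecular clock of
#' \eqn{\mu = 1.3 \times 10^{-8}} substitutions/bp/year, TSD lengths on
#' [10, 30] bp with mean 15, 5' nick-site motifs AAGA/AATA, and strong
#' insertion bias into the domains.
#'
#' @slot nChromosomes Number of chromosomes.
#' @slot chromLength Chromosome length, bp.
#' @slot gcBackground Background GC fraction.
#' @slot mu Substitution rate per bp per year.
#' @slot nInsertions Number of planted element insertions.
#' @slot ageDistribution \code{list(name, mean, min)}; insertion ages in years
#'   are drawn from the named distribution (currently \code{"exponential"} or
#'   \code{"uniform"}) with the given mean, truncated below at \code{min}.
#' @slot tsdRange Integer TSD length bounds (lengths are sampled as
#'   \code{min + Binomial(max - min, p)} with p chosen so the mean is 15).
#' @slot pTruncation Probability an insertion is 5'-truncated.
#' @slot truncationRange Truncation length bounds, bp.
#' @slot nickMotifs,nickWeights 5' nick-site motifs (4-mers spanning junction
#'   positions -1, 0, 1, 2) and their sampling weights.
#' @slot motifWindow Half-width (bp) of the window searched for a motif
#'   around the sampled insertion site.
#' @slot domainLengthRange Centromeric-domain length bounds, bp (one domain
#'   per chromosome).
#' @slot pTargetInDomain Probability a (non-nested) insertion targets a
#'   domain.
#' @slot nDonors,donorLength Number and length of planted donor (LTR-like)
#'   elements available as nesting targets.
#' @slot donorDivergence Per-base divergence of each planted donor copy from
#'   the donor consensus.
#' @slot pDonorInDomain Probability a donor is planted inside a domain.
#' @slot pNested Probability an insertion is planted inside a donor element.
#' @slot seed Default RNG seed used when a function is not given one.
#' @export
setClass("SimConfig",
  representation(nChromosomes = "integer", chromLength = "integer",
                 gcBackground = "numeric", mu = "numeric",
                 nInsertions = "integer", ageDistribution = "list",
                 tsdRange = "integer", pTruncation = "numeric",
                 truncationRange = "numeric", nickMotifs = "character",
                 nickWeights = "numeric", motifWindow = "integer",
                 domainLengthRange = "numeric", pTargetInDomain = "numeric",
                 nDonors = "integer", donorLength = "integer",
                 donorDivergence = "numeric", pDonorInDomain = "numeric",
                 pNested = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  p <- c(object@gcBackground, object@pTruncation, object@pTargetInDomain,
         object@pDonorInDomain, object@pNested, object@donorDivergence)
  if (any(p < 0 | p > 1)) return("probabilities must lie in [0, 1]")
  if (object@mu <= 0) return("mu must be positive")
  if (object@nChromosomes < 1L || object@chromLength < 1L)
    return("genome dimensions must be positive")
  if (length(object@nickMotifs) != length(object@nickWeights))
    return("nickMotifs and nickWeights lengths differ")
  if (any(object@domainLengthRange > object@chromLength))
    return("domain longer than chromosome")
  if (any(diff(object@tsdRange) < 0) || any(object@tsdRange < 1L))
    return("invalid tsdRange")
  TRUE
})

#' Construct a SimConfig
#'
#' See \linkS4class{SimConfig} for the meaning of each parameter.
#'
#' @param nChromosomes,chromLength,gcBackground,mu,nInsertions,ageDistribution
#'   See \linkS4class{SimConfig}.
#' @param tsdRange,pTruncation,truncationRange,nickMotifs,nickWeights
#'   See \linkS4class{SimConfig}.
#' @param motifWindow,domainLengthRange,pTargetInDomain,nDonors,donorLength
#'   See \linkS4class{SimConfig}.
#' @param donorDivergence,pDonorInDomain,pNested,seed See
#'   \linkS4class{SimConfig}.
#' @return A \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nChromosomes = 2, chromLength = 100000L, nInsertions = 20)
#' @export
simConfig <- function(nChromosomes = 3L, chromLength = 500000L,
                      gcBackground = 0.338, mu = 1.3e-8, nInsertions = 60L,
                      ageDistribution = list(name = "exponential",
                                             mean = 5e5, min = 0),
                      tsdRange = c(10L, 30L), pTruncation = 0.6,
                      truncationRange = c(100, 4500),
                      nickMotifs = c("AAGA", "AATA"),
                      nickWeights = c(1, 1), motifWindow = 150L,
                      domainLengthRange = c(10400, 30900),
                      pTargetInDomain = 0.84, nDonors = 30L,
                      donorLength = 3000L, donorDivergence = 0.05,
                      pDonorInDomain = 0.5, pNested = 0.65, seed = 1L) {
  methods::new("SimConfig",
    nChromosomes = as.integer(nChromosomes),
    chromLength = as.integer(chromLength),
    gcBackground = gcBackground, mu = mu,
    nInsertions = as.integer(nInsertions),
    ageDistribution = ageDistribution,
    tsdRange = as.integer(tsdRange), pTruncation = pTruncation,
    truncationRange = truncationRange, nickMotifs = toupper(nickMotifs),
    nickWeights = nickWeights, motifWindow = as.integer(motifWindow),
    domainLengthRange = domainLengthRange,
    pTargetInDomain = pTargetInDomain, nDonors = as.integer(nDonors),
    donorLength = as.integer(donorLength),
    donorDivergence = donorDivergence, pDonorInDomain = pDonorInDomain,
    pNested = pNested, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  genome: %d chromosome(s) x %s bp, GC %.3f\n",
              object@nChromosomes, format(object@chromLength, big.mark = ","),
              object@gcBackground))
  cat(sprintf("  clock: mu = %.3g subs/bp/yr; insertions: %d (%s ages, mean %.3g yr)\n",
              object@mu, object@nInsertions, object@ageDistribution$name,
              object@ageDistribution$mean))
  cat(sprintf("  targeting: P(in domain) = %.2f, P(nested) = %.2f, motifs %s\n",
              object@pTargetInDomain, object@pNested,
              paste(object@nickMotifs, collapse = "/")))
})

#' Simulated genome with planted ground truth
#'
#' The product of the synthetic-data generator: the emitted genome, the
#' centromeric domain set, the planted element annotations (the truth
#' table), the planted donor elements, and the master element and donor
#' library the insertions were copied from.
#'
#' @slot genome Named \link[Biostrings]{DNAStringSet}.
#' @slot domains \link[GenomicRanges]{GRanges} of centromeric domains.
#' @slot elements \link[GenomicRanges]{GRanges} of planted insertions with
#'   truth metadata columns (\code{id}, \code{age}, \code{tsd},
#'   \code{truncation5}, \code{nestedInto}, \code{intactOrfs}, \code{motif},
#'   \code{inDomain}).
#' @slot donors \link[GenomicRanges]{GRanges} of planted donor elements.
#' @slot master \linkS4class{ReferenceElement} the insertions derive from.
#' @slot donorLibrary Named \link[Biostrings]{DNAStringSet} of donor
#'   consensus sequences.
#' @slot config The \linkS4class{SimConfig} used.
#' @export
setClass("SimulatedGenome",
  representation(genome = "DNAStringSet", domains = "GRanges",
                 elements = "GRanges", donors = "GRanges",
                 master = "ReferenceElement", donorLibrary = "DNAStringSet",
                 config = "SimConfig"))

setValidity("SimulatedGenome", function(object) {
  if (anyDuplicated(names(object@genome)))
    return("duplicate chromosome names")
  chroms <- names(object@genome)
  for (gr in list(object@domains, object@elements, object@donors)) {
    if (length(gr) == 0L) next
    if (!all(as.character(GenomicRanges::seqnames(gr)) %in% chroms))
      return("interval on unknown chromosome")
    lens <- Biostrings::width(object@genome)[
      match(as.character(GenomicRanges::seqnames(gr)), chroms)]
    if (any(GenomicRanges::start(gr) < 1L) ||
        any(GenomicRanges::end(gr) > lens))
      return("interval outside chromosome bounds")
  }
  TRUE
})

setMethod("show", "SimulatedGenome", function(object) {
  cat(sprintf("SimulatedGenome: %d chromosome(s), %s bp total\n",
              length(object@genome),
              format(sum(Biostrings::width(object@genome)), big.mark = ",")))
  cat(sprintf("  %d domain(s) (%s bp), %d planted element(s), %d donor(s)\n",
              length(object@domains),
              format(sum(GenomicRanges::width(object@domains)), big.mark = ","),
              length(object@elements), length(object@donors)))
})

#' @rdname SimulatedGenome-class
#' @param x A \code{SimulatedGenome}.
#' @export
genomeSequences <- function(x) x@genome

#' @rdname SimulatedGenome-class
#' @export
domainRanges <- function(x) x@domains

#' @rdname SimulatedGenome-class
#' @export
elementRanges <- function(x) x@elements

#' @rdname SimulatedGenome-class
#' @export
donorRanges <- function(x) x@donors

#' @rdname SimulatedGenome-class
#' @export
donorLibrary <- function(x) x@donorLibrary

#' @rdname SimulatedGenome-class
#' @export
masterElement <- function(x) x@master

#' Truth table of planted insertions
#'
#' One row per planted insertion: coordinates, strand, age in years, TSD
#' sequence and length, 5' truncation, nesting target, ORF intactness, the
#' nick motif used (NA when the site fell back to a uniform draw) and
#' whether the insertion lies in a centromeric domain.
#'
#' @param x A \linkS4class{SimulatedGenome}.
#' @return A data.frame.
#' @export
truthTable <- function(x) {
  gr <- x@elements
  data.frame(
    id = gr$id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    age = gr$age,
    tsd = gr$tsd,
    tsd_len = nchar(gr$tsd),
    truncation5 = gr$truncation5,
    nested_into = gr$nestedInto,
    intact_orfs = gr$intactOrfs,
    motif = gr$motif,
    in_domain = gr$inDomain,
    stringsAsFactors = FALSE
  )
}

#' Junction base-composition matrix
#'
#' Per-position base frequencies around an insertion junction. Positions are
#' labeled in the field's convention: position 1 is the first TSD base,
#' position 0 the base immediately upstream of the TSD.
#'
#' @slot side \code{"five_prime"} or \code{"three_prime"} (or
#'   \code{"crm"} for the 5+10+10 donor layout).
#' @slot positions Character vector of position labels.
#' @slot freq 4 x n matrix of base fractions (rows A, C, G, T).
#' @slot counts Integer observations per position.
#' @export
setClass("JunctionMatrix",
  representation(side = "character", positions = "character",
                 freq = "matrix", counts = "integer"))

setValidity("JunctionMatrix", function(object) {
  if (nrow(object@freq) != 4L) return("freq must have 4 rows (A, C, G, T)")
  if (ncol(object@freq) != length(object@positions))
    return("freq columns must match positions")
  sums <- colSums(object@freq)
  ok <- object@counts == 0L | abs(sums - 1) < 1e-9
  if (!all(ok)) return("column frequencies must sum to 1")
  TRUE
})

setMethod("show", "JunctionMatrix", function(object) {
  cat(sprintf("JunctionMatrix (%s), %d positions, n = %d..%d\n", object@side,
              length(object@positions), min(object@counts), max(object@counts)))
  m <- round(object@freq, 2)
  colnames(m) <- object@positions
  print(m)
})

#' @rdname JunctionMatrix-class
#' @param x A \code{JunctionMatrix}.
#' @export
jmFrequencies <- function(x) {
  m <- x@freq
  colnames(m) <- x@positions
  m
}

#' @rdname JunctionMatrix-class
#' @export
jmPositions <- function(x) x@positions

#' @rdname JunctionMatrix-class
#' @export
jmCounts <- function(x) x@counts

#' Random-placement null result
#'
#' Result of re-placing domain-length-matched random regions and scoring the
#' element fraction that falls inside them, replicate by replicate.
#'
#' @slot replicates Per-replicate in-region percentages.
#' @slot mean Arithmetic mean of the replicates.
#' @slot seed Seed used (NA if none was set).
#' @export
setClass("NullResult",
  representation(replicates = "numeric", mean = "numeric", seed = "integer"))

setValidity("NullResult", function(object) {
  if (length(object@replicates) < 1L) return("needs at least one replicate")
  if (abs(object@mean - mean(object@replicates)) > 1e-9)
    return("mean must equal the mean of the replicates")
  TRUE
})

setMethod("show", "NullResult", function(object) {
  cat(sprintf("NullResult: %d replicates, mean %.2f%% in random regions\n",
              length(object@replicates), object@mean))
})

#' @rdname NullResult-class
#' @param x A \code{NullResult}.
#' @export
nullReplicates <- function(x) x@replicates

#' @rdname NullResult-class
#' @export
nullMean <- function(x) x@mean
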