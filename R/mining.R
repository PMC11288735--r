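# Element discovery and classification. Discovery is seed-and-extend: exact
# k-mer seed matches from the anchor are clustered into candidate regions and
# refined by local alignment of the anchor into the region. Copy-number
# thresholds follow the field's convention: full-length requires < 100 bp 5'
# truncation and < 500 bp internal deletion with the 3' end present;
# fragments (neither end) are excluded from copy counts.

# Candidate regions from exact k-mer seeds, chained by diagonal
# (genomic position - anchor offset) so that tandem or nested copies of
# the anchor yield separate candidates. Highly repeated k-mers (in the
# anchor or the genome) are dropped, as seed-and-extend searches do.
.seedRegions <- function(chromSeq, anchorChar, k, diagSlack = 30L,
                         gapBridge = 400L, maxAnchorOcc = 10L,
                         maxGenomeOcc = 200L) {
  if (nchar(anchorChar) < k) stop("anchor shorter than seed length")
  starts <- seq_len(nchar(anchorChar) - k + 1L)
  kmers <- substring(anchorChar, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  offs <- split(starts[ok], kmers[ok])
  offs <- offs[lengths(offs) <= maxAnchorOcc]
  if (length(offs) == 0L) return(IRanges::IRanges())
  uk <- names(offs)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(uk))
  mi <- Biostrings::matchPDict(pd, chromSeq)
  st <- Biostrings::startIndex(mi)
  gpos <- integer(0)
  apos <- integer(0)
  for (p in seq_along(uk)) {
    sp <- st[[p]]
    if (is.null(sp) || length(sp) == 0L || length(sp) > maxGenomeOcc) next
    ao <- offs[[p]]
    gpos <- c(gpos, rep(sp, each = length(ao)))
    apos <- c(apos, rep(ao, times = length(sp)))
  }
  if (length(gpos) == 0L) return(IRanges::IRanges())
  diag <- gpos - apos
  ord <- order(diag, gpos)
  diag <- diag[ord]
  gpos <- gpos[ord]
  grp <- cumsum(c(TRUE, diff(diag) > diagSlack))
  regions <- lapply(split(gpos, grp), function(gp) {
    gp <- sort(gp)
    sub <- cumsum(c(TRUE, diff(gp) > gapBridge))
    vapply(split(gp, sub), function(x) c(min(x), max(x) + k - 1L),
           numeric(2))
  })
  m <- do.call(cbind, regions)
  IRanges::IRanges(start = m[1, ], end = m[2, ])
}

#' Find copies of an anchor sequence in a genome
#'
#' Seed-and-extend homology search: exact \code{minSeed}-mers of the anchor
#' (and of its reverse complement) are located in each chromosome, clustered
#' into candidate regions, and each region is refined by local alignment of
#' the anchor. Hits shorter than \code{minHitLen} or below
#' \code{minIdentity} are discarded; overlapping same-strand hits closer
#' than 50 bp are merged.
#'
#' @param genome Named \link[Biostrings]{DNAStringSet}.
#' @param anchor Anchor sequence (character or
#'   \link[Biostrings]{DNAString}).
#' @param minSeed Seed k-mer length (anchor must be at least this long).
#' @param minHitLen Minimum hit length in bp.
#' @param minIdentity Minimum alignment identity of a hit.
#' @return A \link[GenomicRanges]{GRanges} of hits with metadata columns
#'   \code{identity} and \code{score}.
#' @export
findElementCopies <- function(genome, anchor, minSeed = 14L,
                              minHitLen = 200L, minIdentity = 0.8) {
  anchorF <- toupper(as.character(anchor))
  if (nchar(anchorF) < minSeed) stop("anchor shorter than seed length")
  anchorR <- .revcompChar(anchorF)
  pad <- 150L
  out <- list()
  for (ch in names(genome)) {
    chromSeq <- genome[[ch]]
    chromLen <- length(chromSeq)
    for (strand in c("+", "-")) {
      a <- if (strand == "+") anchorF else anchorR
      regions <- .seedRegions(chromSeq, a, as.integer(minSeed))
      if (length(regions) == 0L) next
      for (i in seq_along(regions)) {
        rs <- max(1L, IRanges::start(regions)[i] - pad)
        re <- min(chromLen, IRanges::end(regions)[i] + pad)
        regionSeq <- Biostrings::subseq(chromSeq, rs, re)
        aln <- alignGlobal(a, regionSeq, type = "local")
        sw <- Biostrings::nchar(Biostrings::subject(aln))
        if (sw < minHitLen) next
        ident <- pairwiseIdentity(aln, mode = "all_columns")
        if (ident < minIdentity) next
        gs <- rs + Biostrings::start(Biostrings::subject(aln)) - 1L
        ge <- rs + Biostrings::end(Biostrings::subject(aln)) - 1L
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = gs, end = ge, strand = strand,
          identity = ident, score = Biostrings::score(aln),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(GenomicRanges::GRanges())
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand, identity = df$identity,
                               score = df$score)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 50L,
                                  ignore.strand = FALSE)
  if (length(merged) == length(gr)) {
    gr <- sort(gr)
    return(gr)
  }
  # recompute identity/score for intervals altered by merging
  hitsOf <- GenomicRanges::findOverlaps(merged, gr)
  ident <- score <- numeric(length(merged))
  for (i in seq_len(length(merged))) {
    ch <- as.character(GenomicRanges::seqnames(merged))[i]
    sq <- Biostrings::subseq(genome[[ch]], GenomicRanges::start(merged)[i],
                             GenomicRanges::end(merged)[i])
    a <- if (as.character(GenomicRanges::strand(merged))[i] == "+") anchorF
         else anchorR
    aln <- alignGlobal(a, sq, type = "local")
    ident[i] <- pairwiseIdentity(aln, mode = "all_columns")
    score[i] <- Biostrings::score(aln)
  }
  merged$identity <- ident
  merged$score <- score
  sort(merged)
}

.alignmentColumns <- function(aln) {
  rows <- .gappedRows(aln)
  refpos <- cumsum(rows$b != "-")          # subject = reference
  list(elem = rows$a, ref = rows$b, refpos = refpos)
}

#' Classify a mined hit against a reference element
#'
#' Aligns the reference element into the genomic neighborhood of a hit and
#' measures the 5' truncation, the internal deletion (reference positions
#' unaligned between the first and last aligned positions) and whether the
#' 3' end is present (alignment reaching within 50 bp of the reference 3'
#' terminus). Classes: \code{full_length} (truncation < 100 bp, internal
#' deletion < 500 bp, 3' end present), \code{truncated} (3' end present but
#' thresholds exceeded), \code{fragment} (3' end absent). Fragments are
#' excluded from copy counts.
#'
#' @param hit A length-1 \link[GenomicRanges]{GRanges} (a row of
#'   [findElementCopies()] output).
#' @param genome Named \link[Biostrings]{DNAStringSet}.
#' @param reference A \linkS4class{ReferenceElement}.
#' @param flank Bp of genomic context added on each side of the hit before
#'   alignment (default: the reference length).
#' @param threePrimeSlack Bp tolerance for "3' end present" (default 50).
#' @param assessOrfs Also score ORF intactness via
#'   [assessOrfIntactness()].
#' @return A length-1 \code{GRanges} with refined element boundaries and
#'   metadata columns \code{class}, \code{truncation5},
#'   \code{internalDeletion} and (optionally) \code{orfStatus}.
#' @export
classifyElement <- function(hit, genome, reference, flank = NULL,
                            threePrimeSlack = 50L, assessOrfs = TRUE) {
  stopifnot(length(hit) == 1L)
  refSeq <- as.character(reference@sequence)
  refLen <- nchar(refSeq)
  if (is.null(flank)) flank <- refLen
  ch <- as.character(GenomicRanges::seqnames(hit))
  chromLen <- length(genome[[ch]])
  rs <- max(1L, GenomicRanges::start(hit) - flank)
  re <- min(chromLen, GenomicRanges::end(hit) + flank)
  regionSeq <- as.character(Biostrings::subseq(genome[[ch]], rs, re))
  strand <- as.character(GenomicRanges::strand(hit))
  if (strand == "-") regionSeq <- .revcompChar(regionSeq)

  # length-lenient gap costs so that internal deletions of hundreds of bp
  # are bridged (and measured) instead of clipped by the local alignment
  aln <- alignGlobal(refSeq, regionSeq, type = "local",
                     gapOpen = 10, gapExtend = 0.1)
  r1 <- Biostrings::start(Biostrings::pattern(aln))
  r2 <- Biostrings::end(Biostrings::pattern(aln))
  if (r2 - r1 + 1L < 30L)
    stop("hit fails to align to the reference element")
  # columns with a gap in the copy row are reference positions missing from
  # the copy (local alignment has no terminal gaps)
  rows <- .gappedRows(aln)
  internalDel <- sum(rows$b == "-")
  trunc5 <- r1 - 1L
  threePrime <- (refLen - r2) <= threePrimeSlack
  class <- if (threePrime && trunc5 < 100L && internalDel < 500L)
    "full_length" else if (threePrime) "truncated" else "fragment"

  # refined boundaries: the region-local subject interval mapped to genome
  s1 <- Biostrings::start(Biostrings::subject(aln))
  s2 <- Biostrings::end(Biostrings::subject(aln))
  if (strand == "-") {
    w <- nchar(regionSeq)
    gs <- rs + (w - s2)
    ge <- rs + (w - s1)
  } else {
    gs <- rs + s1 - 1L
    ge <- rs + s2 - 1L
  }
  res <- GenomicRanges::GRanges(ch, IRanges::IRanges(gs, ge),
                                strand = strand)
  res$class <- class
  res$truncation5 <- trunc5
  res$internalDeletion <- internalDel
  if (assessOrfs) {
    elemSeq <- as.character(Biostrings::subseq(genome[[ch]], gs, ge))
    if (strand == "-") elemSeq <- .revcompChar(elemSeq)
    res$orfStatus <- assessOrfIntactness(elemSeq, reference)
  }
  res
}

#' @rdname classifyElement
#' @param hits A \link[GenomicRanges]{GRanges} of hits.
#' @export
classifyElements <- function(hits, genome, reference, ...) {
  if (length(hits) == 0L) return(hits)
  res <- lapply(seq_along(hits), function(i)
    classifyElement(hits[i], genome, reference, ...))
  suppressWarnings(do.call(c, res))
}

#' Copy number under the field's counting rule
#'
#' Full-length plus truncated elements; fragments are excluded.
#'
#' @param classified Output of [classifyElements()].
#' @return Integer copy number.
#' @export
copyNumber <- function(classified) {
  sum(classified$class %in% c("full_length", "truncated"))
}

#' Score ORF intactness of an element copy
#'
#' The element is aligned to the reference (ends-free), and each reference
#' ORF is projected onto the copy. The copy is \code{intact_both} iff, for
#' both ORFs: the whole ORF span is covered, every indel within the ORF has
#' a length that is a multiple of 3 (no frameshift), the start codon is ATG,
#' the terminal codon is a stop, and there is no premature stop in the
#' reference frame. Anything else (including an unalignable copy) is
#' \code{disrupted}.
#'
#' @param elementSeq Element sequence, 5' to 3' (character or
#'   \link[Biostrings]{DNAString}).
#' @param reference A \linkS4class{ReferenceElement} with annotated ORFs.
#' @return \code{"intact_both"} or \code{"disrupted"}.
#' @export
assessOrfIntactness <- function(elementSeq, reference) {
  elem <- toupper(as.character(elementSeq))
  refSeq <- as.character(reference@sequence)
  ok <- tryCatch({
    aln <- alignGlobal(elem, refSeq, type = "overlap")
    cols <- .alignmentColumns(aln)
    all(vapply(list(reference@orf1, reference@orf2), function(orf)
      .orfIntactAligned(cols, IRanges::start(orf), IRanges::end(orf)),
      logical(1)))
  }, error = function(e) FALSE)
  if (isTRUE(ok)) "intact_both" else "disrupted"
}

.orfIntactAligned <- function(cols, a, b) {
  # reference-consuming columns inside the ORF, plus insertion columns
  # (ref gap) whose left neighbour lies strictly inside the ORF
  inOrf <- (cols$ref != "-" & cols$refpos >= a & cols$refpos <= b) |
    (cols$ref == "-" & cols$refpos >= a & cols$refpos < b)
  if (!any(inOrf)) return(FALSE)
  e <- cols$elem[inOrf]
  r <- cols$ref[inOrf]
  # ORF must be fully represented in the reference row
  if (sum(r != "-") != b - a + 1L) return(FALSE)
  # every gap run (either row) must preserve frame
  runsOk <- function(isGap) {
    rl <- rle(isGap)
    all(rl$lengths[rl$values] %% 3L == 0L)
  }
  if (!runsOk(e == "-") || !runsOk(r == "-")) return(FALSE)
  sq <- paste(e[e != "-"], collapse = "")
  if (nchar(sq) %% 3L != 0L || nchar(sq) < 6L) return(FALSE)
  codons <- substring(sq, seq(1, nchar(sq) - 2, 3), seq(3, nchar(sq), 3))
  stops <- c("TAA", "TAG", "TGA")
  if (any(grepl("[^ACGT]", codons))) return(FALSE)
  codons[1] == "ATG" && codons[length(codons)] %in% stops &&
    !any(codons[-length(codons)] %in% stops)
}
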