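# Target-site duplication detection and junction base-composition analysis.
# Position numbering follows the field's convention: position 1 is the first
# TSD base and position 0 the base immediately upstream of the TSD, so the
# 5' junction window (10 bp upstream + 10 bp into the TSD) spans -9..10.

#' Detect a target-site duplication at an element boundary
#'
#' Finds the longest suffix of the upstream flank that equals a prefix of
#' the downstream flank, allowing a boundary-offset slack of up to
#' \code{slack} bp on each side (to tolerate imperfect boundary refinement).
#' Ties between equally long candidates are resolved by the smallest total
#' offset, then lexicographically. TSDs of at least 10 bp are flagged high
#' confidence.
#'
#' @param leftFlank Sequence immediately upstream of the element (its last
#'   character abuts the element start).
#' @param rightFlank Sequence immediately downstream of the element.
#' @param maxTsd Longest TSD considered, bp.
#' @param minReport Shortest TSD reported, bp (shorter matches return
#'   \code{NULL}).
#' @param slack Boundary offset slack, bp.
#' @return \code{NULL}, or a list with elements \code{tsd}, \code{length},
#'   \code{highConfidence}, \code{offsetLeft}, \code{offsetRight}.
#' @export
detectTsd <- function(leftFlank, rightFlank, maxTsd = 30L, minReport = 5L,
                      slack = 2L) {
  lf <- toupper(as.character(leftFlank))
  rf <- toupper(as.character(rightFlank))
  nL <- nchar(lf)
  best <- NULL
  for (a in 0:slack) {
    for (b in 0:slack) {
      lmax <- min(maxTsd, nL - a, nchar(rf) - b)
      if (lmax < 1L) next
      len <- 0L
      for (l in seq_len(lmax)) {
        sfx <- substring(lf, nL - a - l + 1L, nL - a)
        pfx <- substring(rf, b + 1L, b + l)
        if (sfx == pfx && !grepl("N", sfx, fixed = TRUE)) len <- l
      }
      if (len == 0L) next
      tsd <- substring(lf, nL - a - len + 1L, nL - a)
      cand <- list(tsd = tsd, length = len, highConfidence = len >= 10L,
                   offsetLeft = a, offsetRight = b)
      if (is.null(best) || cand$length > best$length ||
          (cand$length == best$length &&
           (a + b < best$offsetLeft + best$offsetRight ||
            (a + b == best$offsetLeft + best$offsetRight &&
             cand$tsd < best$tsd)))) {
        best <- cand
      }
    }
  }
  if (is.null(best) || best$length < minReport) return(NULL)
  best
}

# Strand-aware junction context strings for one element whose TSD occupies
# [s0, s0 + len - 1] (left copy) and [e0 - len + 1, e0] (right copy) in
# genome coordinates. Returns 20-mers as read on the element strand.
.junctionContext <- function(chromSeq, strand, s0left, e0right, len,
                             up = 10L, into = 10L) {
  chromLen <- length(chromSeq)
  grab <- function(a, b) {
    if (a < 1L || b > chromLen) return(NA_character_)
    as.character(Biostrings::subseq(chromSeq, a, b))
  }
  if (strand == "-") {
    five <- grab(e0right - into + 1L, e0right + up)
    three <- grab(s0left - up, s0left + into - 1L)
    if (!is.na(five)) five <- .revcompChar(five)
    if (!is.na(three)) three <- .revcompChar(three)
  } else {
    five <- grab(s0left - up, s0left + into - 1L)
    three <- grab(e0right - into + 1L, e0right + up)
  }
  c(five = five, three = three)
}

#' TSD records for a set of elements
#'
#' Runs [detectTsd()] on the genomic flanks of each element and extracts
#' the 5' and 3' junction context strings (10 bp flank + 10 bp of TSD, read
#' on the element strand).
#'
#' @param genome Named \link[Biostrings]{DNAStringSet}.
#' @param elements \link[GenomicRanges]{GRanges} of elements (strand-aware).
#' @param maxTsd,minReport,slack Passed to [detectTsd()].
#' @return A data.frame with one row per element with a detected TSD:
#'   \code{id}, \code{tsd}, \code{length}, \code{high_confidence},
#'   \code{context5}, \code{context3}.
#' @export
tsdTable <- function(genome, elements, maxTsd = 30L, minReport = 5L,
                     slack = 2L) {
  if (length(elements) == 0L)
    return(data.frame(id = character(), tsd = character(),
                      length = integer(), high_confidence = logical(),
                      context5 = character(), context3 = character(),
                      stringsAsFactors = FALSE))
  ids <- if (!is.null(elements$id)) elements$id
         else paste0("element", seq_along(elements))
  out <- vector("list", length(elements))
  flankLen <- maxTsd + slack + 12L
  for (i in seq_along(elements)) {
    ch <- as.character(GenomicRanges::seqnames(elements))[i]
    chromSeq <- genome[[ch]]
    st <- GenomicRanges::start(elements)[i]
    en <- GenomicRanges::end(elements)[i]
    lf_a <- max(1L, st - flankLen)
    if (st - 1L < 1L || en + 1L > length(chromSeq)) next
    lf <- as.character(Biostrings::subseq(chromSeq, lf_a, st - 1L))
    rf <- as.character(Biostrings::subseq(
      chromSeq, en + 1L, min(length(chromSeq), en + flankLen)))
    rec <- detectTsd(lf, rf, maxTsd = maxTsd, minReport = minReport,
                     slack = slack)
    if (is.null(rec)) next
    s0 <- st - rec$offsetLeft - rec$length
    e0 <- en + rec$offsetRight + rec$length
    strand <- as.character(GenomicRanges::strand(elements))[i]
    ctx <- .junctionContext(chromSeq, strand, s0, e0, rec$length)
    out[[i]] <- data.frame(
      id = ids[i], tsd = rec$tsd, length = rec$length,
      high_confidence = rec$highConfidence,
      context5 = ctx[["five"]], context3 = ctx[["three"]],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                   list(make.row.names = FALSE)))
}

.baseFrequency <- function(contexts, labels, side) {
  contexts <- contexts[!is.na(contexts)]
  if (length(contexts) == 0L) stop("no junction contexts supplied")
  w <- length(labels)
  chars <- t(vapply(contexts, function(x) {
    v <- strsplit(toupper(x), "")[[1]]
    length(v) <- w
    v
  }, character(w), USE.NAMES = FALSE))
  freq <- matrix(0, 4L, w, dimnames = list(c("A", "C", "G", "T"), labels))
  counts <- integer(w)
  for (j in seq_len(w)) {
    col <- chars[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    counts[j] <- length(col)
    if (length(col) > 0L)
      freq[, j] <- tabulate(factor(col, levels = c("A", "C", "G", "T")),
                            nbins = 4L) / length(col)
  }
  methods::new("JunctionMatrix", side = side, positions = as.character(labels),
               freq = freq, counts = counts)
}

#' Junction base-composition matrix
#'
#' Per-position base frequencies over the 5' (or 3') junction contexts of a
#' set of TSD records. Only high-confidence records (TSD >= 10 bp) are
#' used, mirroring the convention that shorter duplications are reported
#' but excluded from composition tables. Positions with insufficient
#' context in a record are skipped for that record.
#'
#' @param records Output of [tsdTable()].
#' @param side \code{"five_prime"} or \code{"three_prime"}.
#' @return A \linkS4class{JunctionMatrix}. For the 5' side the columns are
#'   labeled -9..0 (upstream flank, 0 = base immediately upstream of the
#'   TSD) and 1..10 (first 10 TSD bases); for the 3' side -9..0 are the
#'   last 10 TSD bases (0 = last) and 1..10 the downstream flank.
#' @export
junctionMatrix <- function(records, side = c("five_prime", "three_prime")) {
  side <- match.arg(side)
  if (nrow(records) == 0L) stop("empty record list")
  rec <- records[records$high_confidence, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no high-confidence TSD records")
  ctx <- if (side == "five_prime") rec$context5 else rec$context3
  .baseFrequency(ctx, as.character(c(-9:0, 1:10)), side)
}

#' Junction matrix for donor (CRM-like) elements with 5 bp TSDs
#'
#' Layout: 10 bp upstream flank, the 5 bp TSD, 10 bp downstream flank
#' (25 positions).
#'
#' @param contexts Character vector of 25 bp context strings.
#' @return A \linkS4class{JunctionMatrix} with side \code{"crm"}.
#' @export
crmJunctionMatrix <- function(contexts) {
  if (length(contexts) == 0L) stop("empty record list")
  labels <- c(as.character(-10:-1), paste0("T", 1:5), paste0("+", 1:10))
  .baseFrequency(contexts, labels, "crm")
}

#' Donor junction contexts from a simulation
#'
#' Extracts the 10 + 5 + 10 bp context around each planted donor element's
#' TSD for use with [crmJunctionMatrix()].
#'
#' @param sim A \linkS4class{SimulatedGenome}.
#' @return Character vector of 25 bp contexts.
#' @export
donorJunctionContexts <- function(sim) {
  gr <- sim@donors
  if (length(gr) == 0L) return(character())
  vapply(seq_along(gr), function(i) {
    ch <- as.character(GenomicRanges::seqnames(gr))[i]
    chromSeq <- sim@genome[[ch]]
    s0 <- GenomicRanges::start(gr)[i] - 5L   # left TSD copy start
    a <- s0 - 10L
    b <- s0 + 4L + 10L
    if (a < 1L || b > length(chromSeq)) return(NA_character_)
    as.character(Biostrings::subseq(chromSeq, a, b))
  }, character(1))
}

#' GC content of a set of sequences
#'
#' (G + C) / (A + C + G + T) over the concatenation; N and other ambiguity
#' codes are excluded from both numerator and denominator.
#'
#' @param sequences Character vector, \link[Biostrings]{DNAString} or
#'   \link[Biostrings]{DNAStringSet}.
#' @return GC fraction in [0, 1].
#' @export
gcContent <- function(sequences) {
  x <- Biostrings::DNAStringSet(as.character(sequences))
  counts <- colSums(Biostrings::letterFrequency(x, c("A", "C", "G", "T")))
  tot <- sum(counts)
  if (tot == 0) stop("gc content undefined: zero counted bases")
  unname((counts["C"] + counts["G"]) / tot)
}
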