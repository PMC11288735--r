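# Pairwise alignment primitives shared by mining, dating and nesting
# detection. Scoring convention: a gap run of length k costs open + k * extend.

.alignAlphabet <- c("A", "C", "G", "T", "N")

.substitutionMatrix <- function(match = 1, mismatch = -1) {
  m <- matrix(mismatch, 5, 5, dimnames = list(.alignAlphabet, .alignAlphabet))
  diag(m) <- match
  # N is treated as unknown: it never matches anything, including another N
  m["N", ] <- mismatch
  m[, "N"] <- mismatch
  m
}

#' Global pairwise alignment of two DNA sequences
#'
#' Needleman-Wunsch global alignment with affine gap costs, used as the shared
#' kernel for pairwise-identity computations. Defaults: match +1, mismatch -1,
#' and a gap run of length k costs \code{gapOpen + k * gapExtend}. \code{N}
#' bases never match anything, including \code{N}.
#'
#' @param a,b DNA sequences (character scalars or \link[Biostrings]{DNAString}
#'   objects), non-empty.
#' @param match,mismatch Substitution scores.
#' @param gapOpen,gapExtend Gap penalties (positive costs).
#' @param type Alignment type passed to
#'   \link[Biostrings]{pairwiseAlignment}: \code{"global"} (default),
#'   \code{"local"}, \code{"overlap"} (ends-free) or \code{"global-local"}.
#' @return A \link[Biostrings]{PairwiseAlignments} object.
#' @seealso [pairwiseIdentity()]
#' @export
alignGlobal <- function(a, b, match = 1, mismatch = -1,
                        gapOpen = 2, gapExtend = 1, type = "global") {
  if (length(a) == 0L || length(b) == 0L)
    stop("empty sequence")
  achar <- as.character(a)
  bchar <- as.character(b)
  if (any(nchar(achar) == 0L) || nchar(bchar) == 0L)
    stop("empty sequence")
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(achar),
    subject = Biostrings::DNAString(bchar),
    type = type,
    substitutionMatrix = .substitutionMatrix(match, mismatch),
    gapOpening = gapOpen,
    gapExtension = gapExtend
  )
}

.gappedRows <- function(aln, row_b = NULL) {
  if (methods::is(aln, "PairwiseAlignments")) {
    if (length(aln) != 1L)
      stop("expected a single alignment; got ", length(aln))
    a <- as.character(Biostrings::alignedPattern(aln))
    b <- as.character(Biostrings::alignedSubject(aln))
  } else {
    a <- as.character(aln)
    b <- as.character(row_b)
  }
  if (nchar(a) != nchar(b))
    stop("aligned rows differ in length")
  list(a = strsplit(a, "", fixed = TRUE)[[1]],
       b = strsplit(b, "", fixed = TRUE)[[1]])
}

#' Fraction of identical columns in a pairwise alignment
#'
#' Identity is the number of identical columns divided by the number of
#' counted columns. With \code{mode = "exclude_terminal_gaps"} (the default)
#' leading and trailing columns in which either row is gapped (terminal
#' overhangs) are not counted; internal gap columns always count as
#' non-identical. \code{N} never matches anything.
#'
#' @param aln A \link[Biostrings]{PairwiseAlignments} object of length 1, or a
#'   gapped character string (first row) with the second row given in \code{b}.
#' @param mode \code{"exclude_terminal_gaps"} or \code{"all_columns"}.
#' @param b Optional second gapped row when \code{aln} is a character string.
#' @return Identity fraction in [0, 1].
#' @export
pairwiseIdentity <- function(aln, mode = c("exclude_terminal_gaps", "all_columns"),
                             b = NULL) {
  mode <- match.arg(mode)
  rows <- .gappedRows(aln, b)
  ga <- rows$a
  gb <- rows$b
  keep <- rep(TRUE, length(ga))
  if (mode == "exclude_terminal_gaps") {
    gap <- ga == "-" | gb == "-"
    nongap <- which(!gap)
    if (length(nongap) > 0L) {
      keep[seq_along(keep) < nongap[1L]] <- FALSE
      keep[seq_along(keep) > nongap[length(nongap)]] <- FALSE
    } else {
      keep[] <- FALSE
    }
  }
  n <- sum(keep)
  if (n == 0L)
    stop("identity undefined: zero counted columns")
  ident <- ga == gb & ga %in% c("A", "C", "G", "T")
  sum(ident & keep) / n
}

#' Banded global alignment of two near-identical DNA sequences
#'
#' Needleman-Wunsch restricted to a band of diagonals around the main
#' diagonal (shifted by the length difference), with the same scoring
#' convention as [alignGlobal()]. For sequences that differ mostly by
#' substitutions -- retroelement copies, LTR pairs -- a modest band is
#' exact and orders of magnitude faster than the full dynamic program; the
#' band is widened as needed for any length difference.
#'
#' @inheritParams alignGlobal
#' @param band Number of extra diagonals allowed on each side of the
#'   length-difference corridor.
#' @return A list with \code{score} and the two gapped rows \code{a} and
#'   \code{b}, suitable for [pairwiseIdentity()].
#' @export
alignBandedGlobal <- function(a, b, match = 1, mismatch = -1,
                              gapOpen = 2, gapExtend = 1, band = 50L) {
  achar <- toupper(as.character(a))
  bchar <- toupper(as.character(b))
  if (nchar(achar) == 0L || nchar(bchar) == 0L) stop("empty sequence")
  .bandedAlignCpp(achar, bchar, match, mismatch, gapOpen, gapExtend,
                  as.integer(band))
}

#' Alignment-based identity of two sequences
#'
#' Convenience wrapper: globally aligns \code{a} and \code{b} with
#' [alignGlobal()] and returns [pairwiseIdentity()] of the result.
#'
#' @inheritParams alignGlobal
#' @inheritParams pairwiseIdentity
#' @return Identity fraction in [0, 1].
#' @export
sequenceIdentity <- function(a, b, mode = "exclude_terminal_gaps", ...) {
  pairwiseIdentity(alignGlobal(a, b, ...), mode = mode)
}
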