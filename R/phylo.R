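# Distance-based phylogeny of aligned reverse-transcriptase domains:
# p-distances with pairwise gap deletion, neighbor-joining, and bootstrap
# supports with a 50% collapse cutoff.

.blockMatrix <- function(block) {
  rows <- stats::setNames(as.character(block), names(block))
  if (is.null(names(rows)))
    stop("block rows must be named by taxon")
  if (anyDuplicated(names(rows))) stop("duplicate taxon names")
  if (length(unique(nchar(rows))) != 1L)
    stop("aligned rows differ in length")
  m <- do.call(rbind, strsplit(toupper(rows), ""))
  rownames(m) <- names(rows)
  m
}

#' P-distance matrix of an aligned block
#'
#' \code{d(i, j)} is the fraction of mismatching sites among compared
#' columns. With \code{gapHandling = "pairwise"} (default) columns with a
#' gap in either of the two rows are skipped per pair; with
#' \code{"complete"} any column containing a gap in any row is removed
#' before all comparisons. Gap characters are \code{-}, \code{.} and
#' \code{?}. No substitution-model correction is applied.
#'
#' @param block Named character vector, \link[Biostrings]{AAStringSet} or
#'   \link[Biostrings]{DNAStringSet} of equal-length aligned rows
#'   (>= 3 taxa).
#' @param gapHandling \code{"pairwise"} or \code{"complete"}.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pDistance <- function(block, gapHandling = c("pairwise", "complete")) {
  gapHandling <- match.arg(gapHandling)
  m <- .blockMatrix(block)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 taxa")
  isGap <- m %in% c("-", ".", "?")
  dim(isGap) <- dim(m)
  if (gapHandling == "complete") {
    keep <- colSums(isGap) == 0L
    if (!any(keep)) stop("no gap-free columns for complete deletion")
    m <- m[, keep, drop = FALSE]
    isGap <- isGap[, keep, drop = FALSE]
  }
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !isGap[i, ] & !isGap[j, ]
      if (!any(ok))
        stop(sprintf("no comparable columns for pair (%s, %s)",
                     rownames(m)[i], rownames(m)[j]))
      d <- mean(m[i, ok] != m[j, ok])
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# Clamp negative NJ branch lengths to zero, shifting the deficit onto a
# sister branch so path lengths are approximately preserved.
.clampNegative <- function(tree) {
  for (iter in 1:200) {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1L]
    p <- tree$edge[e, 1L]
    sib <- setdiff(which(tree$edge[, 1L] == p), e)
    if (length(sib) > 0L)
      tree$edge.length[sib[1L]] <-
        tree$edge.length[sib[1L]] + tree$edge.length[e]
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via \link[ape]{nj}); negative
#' branch lengths are clamped to zero with the deficit shifted to the
#' sister branch.
#'
#' @param D Symmetric, non-negative distance matrix (>= 3 taxa).
#' @return An unrooted \code{phylo} tree.
#' @export
njTree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(D < 0)) stop("negative distances")
  .clampNegative(ape::nj(stats::as.dist(D)))
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Columns of the aligned block are resampled with replacement
#' \code{nReps} times; the support of each internal branch of the original
#' tree is the percentage of replicate trees containing the same
#' bipartition. Supports are stored as node labels; branches below
#' \code{cutoff} are collapsed into polytomies in the returned
#' \code{collapsed} tree.
#'
#' @param block Aligned block, as in [pDistance()].
#' @param nReps Bootstrap replicates (>= 1; the conventional setting is
#'   1000).
#' @param seed RNG seed.
#' @param cutoff Collapse threshold in percent (default 50).
#' @param gapHandling Passed to [pDistance()].
#' @return A list with \code{tree} (the NJ tree with support node labels)
#'   and \code{collapsed} (the same tree with unsupported branches
#'   collapsed).
#' @export
bootstrapSupport <- function(block, nReps = 1000L, seed = NULL,
                             cutoff = 50, gapHandling = "pairwise") {
  if (nReps < 1L) stop("nReps must be >= 1")
  m <- .blockMatrix(block)
  toBlock <- function(mm) {
    stats::setNames(apply(mm, 1L, paste, collapse = ""), rownames(mm))
  }
  base <- njTree(pDistance(toBlock(m), gapHandling = gapHandling))
  reps <- withSeed(seed, {
    lapply(seq_len(nReps), function(r) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      tryCatch(njTree(pDistance(toBlock(m[, cols, drop = FALSE]),
                                gapHandling = gapHandling)),
               error = function(e) NULL)
    })
  })
  reps <- reps[!vapply(reps, is.null, logical(1))]
  counts <- ape::prop.clades(base, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / nReps
  base$node.label <- as.character(round(support, 1))
  list(tree = base, collapsed = collapseUnsupported(base, cutoff))
}

#' Collapse internal branches below a support cutoff
#'
#' Contracts every internal branch whose child node's support label is
#' below \code{cutoff} percent, producing polytomies.
#'
#' @param tree A \code{phylo} with numeric node labels (supports in
#'   percent).
#' @param cutoff Support threshold in percent.
#' @return The collapsed \code{phylo}.
#' @export
collapseUnsupported <- function(tree, cutoff = 50) {
  supports <- suppressWarnings(as.numeric(tree$node.label))
  ntip <- length(tree$tip.label)
  repeat {
    isInternalChild <- tree$edge[, 2L] > ntip
    childSup <- rep(NA_real_, nrow(tree$edge))
    childSup[isInternalChild] <-
      supports[tree$edge[isInternalChild, 2L] - ntip]
    bad <- which(isInternalChild & !is.na(childSup) & childSup < cutoff)
    if (length(bad) == 0L) break
    e <- bad[1L]
    p <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    tree$edge[tree$edge[, 1L] == child, 1L] <- p
    tree$edge <- tree$edge[-e, , drop = FALSE]
    tree$edge.length <- tree$edge.length[-e]
    supports <- supports[-(child - ntip)]
    tree$edge[tree$edge > child] <- tree$edge[tree$edge > child] - 1L
    tree$Nnode <- tree$Nnode - 1L
  }
  tree$node.label <- as.character(supports)
  tree
}
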