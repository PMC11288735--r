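# File I/O. Standard formats go through Biostrings / rtracklayer / ape;
# internal coordinates are 1-based inclusive, and rtracklayer performs the
# BED 0-based half-open conversion at the file boundary.

#' Read and write genome assemblies as FASTA
#'
#' A genome assembly is represented as a named
#' \link[Biostrings]{DNAStringSet}; chromosome names must be unique. FASTA
#' output is wrapped at 60 columns.
#'
#' @param path File path.
#' @param genome A named \link[Biostrings]{DNAStringSet}.
#' @return \code{readGenome} returns a \link[Biostrings]{DNAStringSet}.
#' @export
readGenome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g)))
    stop("duplicate chromosome names in ", path)
  g
}

#' @rdname readGenome
#' @export
writeGenome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' Read and write interval files (BED / GFF3)
#'
#' Thin wrappers around \link[rtracklayer]{import} returning
#' \link[GenomicRanges]{GRanges} in 1-based inclusive coordinates.
#'
#' @param path File path.
#' @param gr A \link[GenomicRanges]{GRanges} object.
#' @return A \link[GenomicRanges]{GRanges} for the readers; the path,
#'   invisibly, for the writers.
#' @export
readBed <- function(path) rtracklayer::import(path, format = "BED")

#' @rdname readBed
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname readBed
#' @export
readGff3 <- function(path) rtracklayer::import(path, format = "GFF3")

#' @rdname readBed
#' @export
writeGff3 <- function(gr, path) {
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read and write Newick trees
#'
#' @param path File path.
#' @param tree An \link[ape]{ape} \code{phylo} object.
#' @return A \code{phylo} object / the path, invisibly.
#' @export
readNewick <- function(path) ape::read.tree(path)

#' @rdname readNewick
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' Read and write tab-separated tables with a header line
#'
#' @param path File path.
#' @param x A data.frame.
#' @return A data.frame / the path, invisibly.
#' @export
readTsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "", quote = "")
}

#' @rdname readTsv
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
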