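# Synthetic genomes with planted LINE insertions. Every planted feature is
# recorded in a truth table so downstream stages (mining, TSD detection,
# dating, targeting, domain calling) can be scored against known parameters.

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so stage seeds do not perturb each other.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

.BASES <- c("A", "C", "G", "T")

.randomBases <- function(n, gc) {
  sample(.BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.senseCodons <- local({
  codons <- apply(expand.grid(.BASES, .BASES, .BASES), 1, paste0, collapse = "")
  setdiff(codons, c("TAA", "TAG", "TGA"))
})

.randomOrf <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  paste0("ATG", paste(sample(.senseCodons, len / 3 - 2, replace = TRUE),
                      collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

#' Generate a random master element with intact ORFs
#'
#' Builds a synthetic full-length LINE element: 5' UTR, ORF1, ORF2
#' (each with a start codon, no internal stop, and a terminal stop codon),
#' 3' UTR and a poly(A) tail. Defaults yield a 6.1 kb element mirroring the
#' canonical structure of the family the package models; shorter ORFs give
#' fast test fixtures.
#'
#' @param utr5,orf1,orf2,utr3,polyA Feature lengths in bp; ORF lengths must
#'   be multiples of 3.
#' @param gc GC fraction of the UTRs.
#' @param seed Optional RNG seed.
#' @return A \linkS4class{ReferenceElement}.
#' @export
makeMasterElement <- function(utr5 = 635L, orf1 = 1617L, orf2 = 3663L,
                              utr3 = 187L, polyA = 12L, gc = 0.4,
                              seed = NULL) {
  withSeed(seed, {
    seqs <- c(paste(.randomBases(utr5, gc), collapse = ""),
              .randomOrf(orf1), .randomOrf(orf2),
              paste(.randomBases(utr3, gc), collapse = ""),
              strrep("A", polyA))
    ends <- cumsum(c(utr5, orf1, orf2, utr3, polyA))
    starts <- c(1L, ends[-5] + 1L)
    referenceElement(paste(seqs, collapse = ""),
                     utr5 = c(starts[1], ends[1]), orf1 = c(starts[2], ends[2]),
                     orf2 = c(starts[3], ends[3]), utr3 = c(starts[4], ends[4]),
                     polyA = c(starts[5], ends[5]))
  })
}

#' Simulate a background genome with centromeric domains
#'
#' Chromosome sequences are i.i.d. draws with the configured GC content; one
#' centromeric (CENH3-like) domain per chromosome is placed uniformly, with
#' length drawn from \code{domainLengthRange}.
#'
#' @param cfg A \linkS4class{SimConfig}.
#' @param seed RNG seed (default: the seed in \code{cfg}).
#' @return A \linkS4class{SimulatedGenome} with no planted elements yet.
#' @export
simulateGenome <- function(cfg, seed = cfg@seed) {
  methods::validObject(cfg)
  withSeed(seed, {
    chroms <- paste0("chr", seq_len(cfg@nChromosomes))
    seqs <- vapply(chroms, function(ch)
      paste(.randomBases(cfg@chromLength, cfg@gcBackground), collapse = ""),
      character(1))
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chroms
    dlen <- round(stats::runif(cfg@nChromosomes,
                               cfg@domainLengthRange[1],
                               cfg@domainLengthRange[2]))
    dstart <- vapply(dlen, function(l)
      sample.int(cfg@chromLength - l + 1L, 1L), numeric(1))
    domains <- GenomicRanges::GRanges(
      chroms, IRanges::IRanges(start = dstart, end = dstart + dlen - 1L))
    methods::new("SimulatedGenome", genome = genome, domains = domains,
                 elements = GenomicRanges::GRanges(),
                 donors = GenomicRanges::GRanges(),
                 master = methods::new("ReferenceElement"),
                 donorLibrary = Biostrings::DNAStringSet(),
                 config = cfg)
  })
}

# -- internal feature bookkeeping ------------------------------------------
# Features are kept as plain lists of data.frames (chrom, start, end, ...)
# while strings are being edited; an insertion of `ins` bp at TSD-start `s`
# shifts starts >= s and extends features spanning s.

.shiftFeatures <- function(df, chrom, s, ins) {
  if (is.null(df) || nrow(df) == 0L) return(df)
  on_c <- df$chrom == chrom
  shift <- on_c & df$start >= s
  span <- on_c & df$start < s & df$end >= s
  df$start[shift] <- df$start[shift] + ins
  df$end[shift] <- df$end[shift] + ins
  df$end[span] <- df$end[span] + ins
  df
}

.mutateChars <- function(chars, nsub) {
  if (nsub <= 0L) return(chars)
  pos <- sample.int(length(chars), min(nsub, length(chars)))
  for (p in pos) {
    chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
  }
  chars
}

# Find a TSD-start site near `s` whose junction matches `motif` for the given
# strand and TSD length; returns s unchanged (with attr hit = FALSE) if no
# match lies within the window.
.motifSite <- function(chromSeq, s, l, motif, strand, window, chromLen) {
  lo <- max(10L, s - window)
  hi <- min(chromLen - l - 10L, s + window)
  if (hi < lo) return(structure(s, hit = FALSE))
  cand <- lo:hi
  ctx <- if (strand == "+") {
    substring(chromSeq, cand - 2L, cand + 1L)
  } else {
    vapply(substring(chromSeq, cand + l - 2L, cand + l + 1L), .revcompChar,
           character(1), USE.NAMES = FALSE)
  }
  ok <- which(ctx == motif)
  if (length(ok) == 0L) return(structure(s, hit = FALSE))
  best <- ok[which.min(abs(cand[ok] - s))]
  structure(cand[best], hit = TRUE)
}

.orfIntactInCopy <- function(chars, orf, offset) {
  # orf: IRanges in master coordinates; offset: bp removed at the 5' end
  st <- IRanges::start(orf) - offset
  en <- IRanges::end(orf) - offset
  if (st < 1L || en > length(chars)) return(FALSE)
  sq <- paste(chars[st:en], collapse = "")
  codons <- substring(sq, seq(1, nchar(sq) - 2, 3), seq(3, nchar(sq), 3))
  stops <- c("TAA", "TAG", "TGA")
  codons[1] == "ATG" &&
    codons[length(codons)] %in% stops &&
    !any(codons[-length(codons)] %in% stops)
}

.sampleAges <- function(n, dist) {
  ages <- switch(dist$name,
    exponential = stats::rexp(n, rate = 1 / dist$mean),
    uniform = stats::runif(n, 0, 2 * dist$mean),
    constant = rep(dist$mean, n),
    # recent transposition burst plus an older cohort -- the bimodal
    # pattern of a family with many recent and a few old copies
    burst = {
      ny <- round(n * dist$youngFrac)
      c(stats::runif(ny, dist$youngRange[1], dist$youngRange[2]),
        stats::runif(n - ny, dist$oldRange[1], dist$oldRange[2]))
    },
    stop("unknown age distribution: ", dist$name))
  mn <- if (is.null(dist$min)) 0 else dist$min
  pmax(ages, mn)
}

.sampleTsdLength <- function(n, range) {
  # binomial thinning keeps lengths on [min, max] with mean 15 at the default
  # (10, 30) bounds
  span <- range[2] - range[1]
  p <- if (span > 0) min(1, (15 - range[1]) / span) else 0.5
  range[1] + stats::rbinom(n, span, p)
}

# Uniform integer draw on [lo, hi] that is safe for lo == hi (base sample()
# would expand a length-1 vector).
.runifInt <- function(lo, hi) {
  if (hi <= lo) return(as.integer(lo))
  as.integer(floor(stats::runif(1, lo, hi + 1)))
}

# Pick a TSD-start site: the in-domain decision is made first, then the
# nesting decision is restricted to donors in the chosen stratum, so the
# in-domain and nested marginals are controlled independently.
.sampleSite <- function(chromLens, domains, donors, l, pNested, pInDomain) {
  wantDomain <- nrow(domains) > 0L && stats::runif(1) < pInDomain
  if (!is.null(donors) && nrow(donors) > 0L && stats::runif(1) < pNested) {
    donorInDom <- vapply(seq_len(nrow(donors)), function(i) {
      dm <- domains[domains$chrom == donors$chrom[i], , drop = FALSE]
      nrow(dm) > 0L && any(donors$start[i] <= dm$end &
                             donors$end[i] >= dm$start)
    }, logical(1))
    pool <- donors[donorInDom == wantDomain, , drop = FALSE]
    if (nrow(pool) == 0L) pool <- donors
    d <- pool[sample.int(nrow(pool), 1L), ]
    s <- .runifInt(d$start + 2L, d$end - l - 2L)
    return(list(chrom = d$chrom, s = s, mode = "nested"))
  }
  if (wantDomain) {
    w <- pmax(domains$end - domains$start + 1L - l, 1)
    d <- domains[sample.int(nrow(domains), 1L, prob = w), ]
    s <- .runifInt(d$start, d$end - l)
    return(list(chrom = d$chrom, s = s, mode = "domain"))
  }
  # uniform over non-domain space, weighted by chromosome outside length
  out <- vapply(names(chromLens), function(ch) {
    chromLens[[ch]] - sum(with(domains[domains$chrom == ch, , drop = FALSE],
                               end - start + 1L))
  }, numeric(1))
  ch <- sample(names(chromLens), 1L, prob = pmax(out, 1))
  dch <- domains[domains$chrom == ch, , drop = FALSE]
  for (try in 1:1000) {
    s <- .runifInt(11L, chromLens[[ch]] - l - 11L)
    inside <- nrow(dch) > 0L && any(s >= dch$start & s <= dch$end)
    if (!inside) break
  }
  list(chrom = ch, s = s, mode = "background")
}

#' Plant element insertions with known ages, TSDs, truncations and nesting
#'
#' Inserts \code{cfg@nInsertions} copies of \code{master} into the genome,
#' oldest first. Divergence follows a linear clock: the source lineage
#' accumulates Poisson(\eqn{\mu \Delta t L}) substitutions between
#' successive births and each copy accumulates Poisson(\eqn{\mu t L})
#' private substitutions after its birth, so a copy of age \emph{t} and its
#' closest younger relative differ by \eqn{2 \mu t L} substitutions in
#' expectation. Donor (LTR-like) elements are planted first, at AT-biased
#' target sites with 5 bp TSDs, and a configurable fraction of the LINE
#' insertions nests inside them. Each LINE insertion receives an exact TSD
#' of sampled length; its 5' junction is matched to a sampled nick motif
#' when one occurs within the search window (uniform fallback otherwise);
#' 5' truncation is applied with probability \code{cfg@pTruncation}.
#'
#' @param sim A \linkS4class{SimulatedGenome} from [simulateGenome()].
#' @param master A \linkS4class{ReferenceElement}; see
#'   [makeMasterElement()].
#' @param seed RNG seed (default: config seed + 1).
#' @return The \linkS4class{SimulatedGenome} with planted elements, donors
#'   and an updated truth table ([truthTable()]).
#' @export
plantInsertions <- function(sim, master, seed = sim@config@seed + 1L) {
  cfg <- sim@config
  withSeed(seed, {
    chromSeqs <- as.list(as.character(sim@genome))
    chromLens <- lapply(chromSeqs, nchar)
    dom <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(sim@domains)),
      start = GenomicRanges::start(sim@domains),
      end = GenomicRanges::end(sim@domains), stringsAsFactors = FALSE)

    # ---- donors (LTR-like nesting targets), AT-biased 5 bp TSD sites ----
    donorCons <- paste(.randomBases(cfg@donorLength, cfg@gcBackground),
                       collapse = "")
    donors <- NULL
    if (cfg@nDonors > 0L) {
      rows <- vector("list", cfg@nDonors)
      for (i in seq_len(cfg@nDonors)) {
        site <- .sampleSite(chromLens, dom, NULL, 5L, 0,
                            cfg@pDonorInDomain)
        ch <- site$chrom
        # donor endonucleases prefer AT-rich targets: take the most AT-rich
        # 5-mer among nearby candidate sites
        cand <- site$s + seq(-40L, 40L, by = 10L)
        cand <- cand[cand > 10 & cand < chromLens[[ch]] - 20]
        if (length(cand) == 0L) cand <- site$s
        at <- vapply(cand, function(s) {
          tsd <- substring(chromSeqs[[ch]], s, s + 4L)
          sum(strsplit(tsd, "")[[1]] %in% c("A", "T"))
        }, numeric(1))
        s <- cand[which.max(at)]
        dchars <- .mutateChars(strsplit(donorCons, "")[[1]],
                               stats::rbinom(1, cfg@donorLength,
                                             cfg@donorDivergence))
        dseq <- paste(dchars, collapse = "")
        l <- 5L
        tsd <- substring(chromSeqs[[ch]], s, s + l - 1L)
        m <- nchar(dseq)
        chromSeqs[[ch]] <- paste0(
          substring(chromSeqs[[ch]], 1L, s + l - 1L), dseq,
          substring(chromSeqs[[ch]], s, chromLens[[ch]]))
        chromLens[[ch]] <- chromLens[[ch]] + l + m
        dom <- .shiftFeatures(dom, ch, s, l + m)
        donors <- .shiftFeatures(donors, ch, s, l + m)
        rows[[i]] <- data.frame(
          id = sprintf("donor%03d", i), family = "CRM", chrom = ch,
          start = s + l, end = s + l + m - 1L, tsd = tsd,
          stringsAsFactors = FALSE)
        donors <- rbind(donors, rows[[i]])
      }
    }

    # ---- LINE insertions, oldest first -------------------------------
    n <- cfg@nInsertions
    ages <- sort(.sampleAges(n, cfg@ageDistribution), decreasing = TRUE)
    masterChars <- strsplit(as.character(master@sequence), "")[[1]]
    L <- length(masterChars)
    lineage <- masterChars
    tPrev <- if (n > 0L) ages[1] else 0
    el <- NULL
    for (i in seq_len(n)) {
      lineage <- .mutateChars(lineage,
                              stats::rpois(1, cfg@mu * (tPrev - ages[i]) * L))
      tPrev <- ages[i]
      copy <- .mutateChars(lineage, stats::rpois(1, cfg@mu * ages[i] * L))

      trunc5 <- 0L
      if (stats::runif(1) < cfg@pTruncation) {
        tmax <- min(cfg@truncationRange[2], L - 500L)
        tmin <- min(cfg@truncationRange[1], tmax)
        trunc5 <- as.integer(round(stats::runif(1, tmin, tmax)))
        copy <- copy[(trunc5 + 1L):L]
      }
      intact <- .orfIntactInCopy(copy, master@orf1, trunc5) &&
        .orfIntactInCopy(copy, master@orf2, trunc5)

      strand <- sample(c("+", "-"), 1L)
      l <- .sampleTsdLength(1L, cfg@tsdRange)
      motif <- sample(cfg@nickMotifs, 1L, prob = cfg@nickWeights)
      # resample until the duplication cannot extend by accident (the base
      # upstream of the target site differing from the base following it
      # keeps the emitted TSD exactly the sampled duplication)
      for (try in 1:100) {
        site <- .sampleSite(chromLens, dom, donors, l,
                            cfg@pNested, cfg@pTargetInDomain)
        ch <- site$chrom
        s <- .motifSite(chromSeqs[[ch]], site$s, l, motif, strand,
                        cfg@motifWindow, chromLens[[ch]])
        hit <- attr(s, "hit")
        s <- as.integer(s)
        if (s > 1L && s + l <= chromLens[[ch]] &&
            substring(chromSeqs[[ch]], s - 1L, s - 1L) !=
              substring(chromSeqs[[ch]], s + l, s + l)) break
      }

      nested <- NA_character_
      if (!is.null(donors) && nrow(donors) > 0L) {
        idx <- which(donors$chrom == ch & donors$start <= s & donors$end >= s)
        if (length(idx) > 0L) nested <- donors$id[idx[1L]]
      }

      insSeq <- paste(copy, collapse = "")
      if (strand == "-") insSeq <- .revcompChar(insSeq)
      m <- nchar(insSeq)
      tsd <- substring(chromSeqs[[ch]], s, s + l - 1L)
      chromSeqs[[ch]] <- paste0(
        substring(chromSeqs[[ch]], 1L, s + l - 1L), insSeq,
        substring(chromSeqs[[ch]], s, chromLens[[ch]]))
      chromLens[[ch]] <- chromLens[[ch]] + l + m
      dom <- .shiftFeatures(dom, ch, s, l + m)
      donors <- .shiftFeatures(donors, ch, s, l + m)
      el <- .shiftFeatures(el, ch, s, l + m)
      el <- rbind(el, data.frame(
        id = sprintf("ins%03d", i), chrom = ch, start = s + l,
        end = s + l + m - 1L, strand = strand, age = ages[i], tsd = tsd,
        truncation5 = trunc5, nestedInto = nested, intactOrfs = intact,
        motif = if (isTRUE(hit)) motif else NA_character_,
        stringsAsFactors = FALSE))
    }

    genome <- Biostrings::DNAStringSet(unlist(chromSeqs))
    names(genome) <- names(sim@genome)
    domains <- GenomicRanges::GRanges(
      dom$chrom, IRanges::IRanges(dom$start, dom$end))
    donorGr <- if (is.null(donors)) GenomicRanges::GRanges() else
      GenomicRanges::GRanges(donors$chrom,
                             IRanges::IRanges(donors$start, donors$end),
                             id = donors$id, family = donors$family,
                             tsd = donors$tsd)
    if (is.null(el)) {
      elGr <- GenomicRanges::GRanges()
    } else {
      elGr <- GenomicRanges::GRanges(
        el$chrom, IRanges::IRanges(el$start, el$end), strand = el$strand,
        id = el$id, age = el$age, tsd = el$tsd, truncation5 = el$truncation5,
        nestedInto = el$nestedInto, intactOrfs = el$intactOrfs,
        motif = el$motif)
      elGr$inDomain <- IRanges::overlapsAny(elGr, domains, ignore.strand = TRUE)
    }
    methods::new("SimulatedGenome", genome = genome, domains = domains,
                 elements = elGr, donors = donorGr, master = master,
                 donorLibrary = {
                   dl <- Biostrings::DNAStringSet(donorCons)
                   names(dl) <- "CRM"
                   dl
                 },
                 config = cfg)
  })
}

#' Extract the planted element sequences
#'
#' Returns each planted insertion as read 5' to 3' on the element strand
#' (minus-strand insertions are reverse-complemented).
#'
#' @param sim A \linkS4class{SimulatedGenome} after [plantInsertions()].
#' @return A named \link[Biostrings]{DNAStringSet}.
#' @export
extractElements <- function(sim) {
  gr <- sim@elements
  if (length(gr) == 0L) return(Biostrings::DNAStringSet())
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
    ch <- as.character(GenomicRanges::seqnames(gr))[i]
    s <- substring(as.character(sim@genome[[ch]]),
                   GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])
    if (as.character(GenomicRanges::strand(gr))[i] == "-") .revcompChar(s)
    else s
  }, character(1)))
  names(seqs) <- gr$id
  seqs
}

#' Which planted insertions kept undisturbed junctions
#'
#' A later insertion can land inside an older element's TSD or flank,
#' destroying the junction evidence -- in real genomes, too, TSDs are
#' recoverable for only part of a family's copies. This helper flags the
#' elements whose junction windows are free of other planted features, the
#' set on which exact TSD recovery can be expected.
#'
#' @param sim A \linkS4class{SimulatedGenome}.
#' @param window Junction window on each side of the element, bp.
#' @return Logical vector parallel to [elementRanges()].
#' @export
undisturbedJunctions <- function(sim, window = 45L) {
  el <- sim@elements
  n <- length(el)
  if (n == 0L) return(logical(0))
  # insertions are planted oldest first in id order, so only elements with
  # a larger index can modify an existing junction; a host feature planted
  # earlier (e.g. the donor an element nested into) is part of the
  # junction, not a disturbance. Later elements are padded by the maximum
  # TSD length to cover their own duplication.
  pad <- max(sim@config@tsdRange) + 5L
  ok <- logical(n)
  for (i in seq_len(n)) {
    ch <- as.character(GenomicRanges::seqnames(el))[i]
    st <- GenomicRanges::start(el)[i]
    en <- GenomicRanges::end(el)[i]
    win <- GenomicRanges::GRanges(
      rep(ch, 2),
      IRanges::IRanges(c(max(1L, st - window), en + 1L),
                       c(st - 1L, en + window)))
    later <- el[seq_len(n) > i]
    later <- GenomicRanges::resize(GenomicRanges::granges(later),
                                   GenomicRanges::width(later) + 2L * pad,
                                   fix = "center")
    ok[i] <- !any(IRanges::overlapsAny(win, later, ignore.strand = TRUE))
  }
  ok
}

#' Simulate ChIP and input read-start tables
#'
#' Input read starts are uniform over the genome; ChIP read starts are drawn
#' from a mixture with an \code{enrichmentFold}-times higher per-bp rate
#' inside the centromeric domains.
#'
#' @param sim A \linkS4class{SimulatedGenome}.
#' @param enrichmentFold ChIP/input per-bp rate ratio inside domains
#'   (\eqn{\ge} 1).
#' @param nChip,nInput Read counts for the two libraries.
#' @param readLen Read length in bp (starts are kept \code{readLen} away from
#'   the chromosome end).
#' @param seed RNG seed.
#' @return A list with data.frames \code{chip} and \code{input}, each with
#'   columns \code{chrom}, \code{start}, \code{strand}.
#' @export
simulateReads <- function(sim, enrichmentFold = 30, nChip = 1e5,
                          nInput = 1e5, readLen = 100L,
                          seed = sim@config@seed + 2L) {
  if (enrichmentFold < 1) stop("enrichmentFold must be >= 1")
  if (nChip <= 0 || nInput <= 0) stop("read counts must be positive")
  withSeed(seed, {
    lens <- Biostrings::width(sim@genome)
    names(lens) <- names(sim@genome)
    dom <- sim@domains
    sampleTrack <- function(n, fold) {
      # per-chromosome stratified mixture: inside domains at rate `fold`
      rows <- lapply(names(lens), function(ch) {
        L <- lens[[ch]] - readLen + 1L
        d <- dom[GenomicRanges::seqnames(dom) == ch]
        d <- IRanges::restrict(d, start = 1L, end = L)
        din <- sum(GenomicRanges::width(d))
        list(ch = ch, L = L, din = max(din, 0L), d = d)
      })
      w <- vapply(rows, function(r) r$L - r$din + fold * r$din, numeric(1))
      counts <- stats::rmultinom(1, n, w)[, 1]
      out <- vector("list", length(rows))
      for (i in seq_along(rows)) {
        r <- rows[[i]]
        if (counts[i] == 0L) next
        nin <- stats::rbinom(1, counts[i],
                             fold * r$din / (r$L - r$din + fold * r$din))
        pos_in <- integer(0)
        if (nin > 0L && r$din > 0L) {
          offs <- sample.int(r$din, nin, replace = TRUE) - 1L
          cs <- cumsum(GenomicRanges::width(r$d))
          didx <- findInterval(offs, c(0, cs), rightmost.closed = FALSE)
          pos_in <- GenomicRanges::start(r$d)[didx] + offs -
            c(0, cs)[didx]
        }
        nout <- counts[i] - length(pos_in)
        pos_out <- integer(0)
        if (nout > 0L) {
          pos_out <- sample.int(r$L, nout, replace = TRUE)
          if (length(r$d) > 0L) {
            bad <- IRanges::overlapsAny(
              IRanges::IRanges(pos_out, width = 1L),
              IRanges::ranges(r$d))
            while (any(bad)) {
              pos_out[bad] <- sample.int(r$L, sum(bad), replace = TRUE)
              bad <- IRanges::overlapsAny(
                IRanges::IRanges(pos_out, width = 1L),
                IRanges::ranges(r$d))
            }
          }
        }
        pos <- c(pos_in, pos_out)
        out[[i]] <- data.frame(
          chrom = r$ch, start = pos,
          strand = sample(c("+", "-"), length(pos), replace = TRUE),
          stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    }
    list(chip = sampleTrack(nChip, enrichmentFold),
         input = sampleTrack(nInput, 1))
  })
}
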