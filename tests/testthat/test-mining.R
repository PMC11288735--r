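# Seed-and-extend mining, boundary refinement, classification thresholds
# and ORF intactness.

test_that("an exact planted copy is found once with exact boundaries", {
  set.seed(41)
  anchor <- randomDna(600)
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(randomDna(5000), anchor,
                                                randomDna(5000))))
  hits <- findElementCopies(g, anchor)
  expect_length(hits, 1)
  expect_equal(GenomicRanges::start(hits), 5001)
  expect_equal(GenomicRanges::end(hits), 5600)
  expect_equal(hits$identity, 1.0)
  # reverse-strand copy
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(anchor)))
  g2 <- Biostrings::DNAStringSet(c(chr1 = paste0(randomDna(3000), rc,
                                                 randomDna(3000))))
  h2 <- findElementCopies(g2, anchor)
  expect_length(h2, 1)
  expect_equal(as.character(GenomicRanges::strand(h2)), "-")
  expect_equal(GenomicRanges::start(h2), 3001)
})

test_that("a diverged copy is recovered with near-exact boundaries", {
  set.seed(43)
  anchor <- randomDna(400)
  copy <- mutateDna(anchor, 20)          # 95% identity
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(randomDna(2000), copy,
                                                randomDna(2000))))
  hits <- findElementCopies(g, anchor, minHitLen = 200, minIdentity = 0.8)
  expect_length(hits, 1)
  expect_lte(abs(GenomicRanges::start(hits) - 2001), 5)
  expect_lte(abs(GenomicRanges::end(hits) - 2400), 5)
  # the refined alignment score matches an independent Smith-Waterman on
  # a window around the hit
  region <- substring(as.character(g[[1]]), 1950, 2450)
  expect_equal(hits$score, oracleLocalScore(anchor, region))
})

test_that("random sequence yields no hits across seeded replicates", {
  set.seed(47)
  anchor <- randomDna(2816)
  for (r in 1:20) {
    g <- Biostrings::DNAStringSet(c(chr1 = randomDna(250000)))
    hits <- findElementCopies(g, anchor, minHitLen = 200, minIdentity = 0.8)
    expect_length(hits, 0)
  }
})

test_that("classification applies the full-length/truncated/fragment rules", {
  m <- testMaster()
  mseq <- as.character(elementSequence(m))
  L <- nchar(mseq)
  set.seed(53)
  plant <- function(piece) {
    g <- Biostrings::DNAStringSet(c(chr1 = paste0(randomDna(2000), piece,
                                                  randomDna(2000))))
    hit <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(2001, 2000 + nchar(piece)), strand = "+")
    classifyElement(hit, g, m)
  }
  # 80 bp 5' truncation, 3' end present -> full length
  res <- plant(substring(mseq, 81, L))
  expect_equal(res$class, "full_length")
  expect_equal(res$truncation5, 80L)
  # 600 bp internal deletion -> truncated
  res <- plant(paste0(substring(mseq, 1, 200), substring(mseq, 801, L)))
  expect_equal(res$class, "truncated")
  expect_gte(res$internalDeletion, 550L)
  # internal piece with neither end -> fragment
  res <- plant(substring(mseq, 301, 700))
  expect_equal(res$class, "fragment")
  # counting rule: fragments excluded
  cl <- GenomicRanges::GRanges(rep("chr1", 3), IRanges::IRanges(1:3, 11:13))
  cl$class <- c("full_length", "truncated", "fragment")
  expect_equal(copyNumber(cl), 2L)
})

test_that("ORF intactness requires frame, start/stop and no premature stop", {
  m <- testMaster()
  mseq <- as.character(elementSequence(m))
  expect_equal(assessOrfIntactness(mseq, m), "intact_both")
  orf2 <- elementOrfs(m)$orf2
  # substitution creating an in-frame premature stop inside ORF2
  pos <- IRanges::start(orf2) + 30L    # codon start within ORF2
  v <- strsplit(mseq, "")[[1]]
  v[pos:(pos + 2)] <- c("T", "A", "A")
  expect_equal(assessOrfIntactness(paste(v, collapse = ""), m), "disrupted")
  # 1 bp deletion inside ORF1 -> frameshift
  orf1 <- elementOrfs(m)$orf1
  v <- strsplit(mseq, "")[[1]]
  v <- v[-(IRanges::start(orf1) + 10L)]
  expect_equal(assessOrfIntactness(paste(v, collapse = ""), m), "disrupted")
  # 3 bp in-frame deletion that removes no stop -> still intact
  v <- strsplit(mseq, "")[[1]]
  del <- IRanges::start(orf1) + 12L
  v <- v[-(del:(del + 2))]
  expect_equal(assessOrfIntactness(paste(v, collapse = ""), m),
               "intact_both")
  # unalignable garbage -> disrupted, not an error
  expect_equal(assessOrfIntactness(randomDna(300), m), "disrupted")
})

test_that("mining recovers planted copies with high recall and full precision", {
  sim <- cleanSim()
  m <- testMaster()
  tt <- truthTable(sim)
  anchor <- as.character(Biostrings::subseq(elementSequence(m), 150, 900))
  hits <- findElementCopies(genomeSequences(sim), anchor,
                            minHitLen = 200, minIdentity = 0.8)
  truthGr <- GenomicRanges::GRanges(tt$chrom,
                                    IRanges::IRanges(tt$start, tt$end))
  # precision: every hit overlaps a planted element
  expect_true(all(IRanges::overlapsAny(hits, truthGr,
                                       ignore.strand = TRUE)))
  # recall over planted copies long enough to retain the anchor region
  minable <- tt$truncation5 <= 700
  found <- IRanges::overlapsAny(truthGr, hits, ignore.strand = TRUE)
  expect_gte(mean(found[minable]), 0.95)
})
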