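# Domain-relation classes, the random-placement null, binned density and
# nested-insertion detection.

library(GenomicRanges)

test_that("domain relation partitions inside / near / outside", {
  domains <- GRanges("chr1", IRanges::IRanges(100000, 150000))
  el <- GRanges(rep("chr1", 3),
                IRanges::IRanges(c(120000, 85000, 20000),
                                 c(121000, 90000, 21000)))
  rel <- assignDomainRelation(el, domains)
  expect_equal(rel, c("inside", "near", "outside"))
  # 1 bp of overlap counts as inside
  touch <- GRanges("chr1", IRanges::IRanges(99000, 100000))
  expect_equal(assignDomainRelation(touch, domains), "inside")
  # exhaustive partition on random inputs
  set.seed(101)
  el2 <- GRanges("chr1", IRanges::IRanges(sample(3e5, 200), width = 500))
  rel2 <- assignDomainRelation(el2, domains)
  expect_true(all(rel2 %in% c("inside", "near", "outside")))
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
  expect_error(assignDomainRelation(GRanges("chrX", IRanges::IRanges(1, 2)),
                                    domains, genome = g), "unknown chromosome")
})

test_that("percent in domains is plain arithmetic", {
  domains <- GRanges("chr1", IRanges::IRanges(1000, 2000))
  inside <- GRanges("chr1", IRanges::IRanges(seq(1000, 1960, length.out = 21),
                                             width = 10))
  outside <- GRanges("chr1", IRanges::IRanges(seq(5000, 9000,
                                                  length.out = 4), width = 10))
  expect_equal(percentInDomains(c(inside, outside), domains), 84)
  expect_equal(percentInDomains(inside, domains), 100)
  expect_error(percentInDomains(GRanges(), domains), "empty")
})

test_that("the random-placement null matches the covered genome fraction", {
  set.seed(103)
  lens <- c(chr1 = 300000, chr2 = 300000)
  domains <- GRanges(c("chr1", "chr2"),
                     IRanges::IRanges(c(50000, 120000), width = c(30000, 30000)))
  el <- GRanges(sample(names(lens), 500, replace = TRUE),
                IRanges::IRanges(sample(299000, 500, replace = TRUE),
                                 width = 100))
  nr <- randomPlacementNull(lens, domains, el, nReplicates = 100L, seed = 7L)
  f <- 100 * sum(width(domains)) / sum(lens)
  mcSd <- stats::sd(nullReplicates(nr)) / sqrt(100)
  expect_lt(abs(nullMean(nr) - f), 3 * mcSd + 1)
  # determinism
  nr2 <- randomPlacementNull(lens, domains, el, nReplicates = 100L, seed = 7L)
  expect_identical(nullReplicates(nr), nullReplicates(nr2))
  # domains covering the whole genome: every replicate is 100
  all_dom <- GRanges(c("chr1", "chr2"), IRanges::IRanges(1, width = lens))
  nrAll <- randomPlacementNull(lens, all_dom, el, nReplicates = 10L, seed = 1L)
  expect_true(all(nullReplicates(nrAll) == 100))
})

test_that("binned density normalizes the densest bin to 100", {
  lens <- c(chr1 = 500000)
  one <- GRanges("chr1", IRanges::IRanges(120001, 121000))
  tr <- binnedDensity(one, lens, bin = 100000)
  expect_equal(tr$value, c(0, 100, 0, 0, 0))
  two <- GRanges("chr1", IRanges::IRanges(c(1, 100001), width = c(2000, 1000)))
  tr2 <- binnedDensity(two, lens, bin = 100000)
  expect_equal(tr2$value[1:2], c(100, 50))
  empty <- binnedDensity(GRanges(), lens, bin = 100000)
  expect_true(all(empty$value == 0))
  expect_true(isTRUE(attr(empty, "empty")))
})

test_that("nesting is detected from the downstream flank and matches truth", {
  sim <- cleanSim()
  tt <- truthTable(sim)
  el <- elementRanges(sim)
  dn <- donorRanges(sim)
  labels <- detectNested(el, donorLibrary(sim), genomeSequences(sim))
  expect_true(all(labels[!is.na(labels)] == "CRM"))
  # detection needs donor sequence in the 150 bp downstream window: the
  # donor remnant past the element must be long enough and not occupied by
  # another element inserted in between (tandem nesting)
  downstream <- GenomicRanges::GRanges(
    tt$chrom,
    IRanges::IRanges(ifelse(tt$strand == "+", tt$end + 1L,
                            pmax(1L, tt$start - 150L)),
                     ifelse(tt$strand == "+", tt$end + 150L,
                            tt$start - 1L)))
  donorLeft <- rep(0L, nrow(tt))
  nestedIdx <- which(!is.na(tt$nested_into))
  for (i in nestedIdx) {
    d <- dn[dn$id == tt$nested_into[i]]
    if (tt$strand[i] == "+") {
      donorLeft[i] <- max(0L, GenomicRanges::end(d) - tt$end[i])
    } else {
      donorLeft[i] <- max(0L, tt$start[i] - GenomicRanges::start(d))
    }
  }
  blocked <- IRanges::overlapsAny(downstream,
                                  GenomicRanges::GRanges(
                                    tt$chrom,
                                    IRanges::IRanges(tt$start, tt$end)),
                                  ignore.strand = TRUE)
  detectable <- !is.na(tt$nested_into) & donorLeft >= 80 & !blocked
  expect_true(all(!is.na(labels[detectable])))
  # unnested elements with no donor near the downstream window stay NA
  nearDonor <- IRanges::overlapsAny(
    GenomicRanges::GRanges(tt$chrom,
                           IRanges::IRanges(pmax(1L, tt$start - 160L),
                                            tt$end + 160L)),
    dn, ignore.strand = TRUE)
  cleanBg <- is.na(tt$nested_into) & !nearDonor
  expect_true(all(is.na(labels[cleanBg])))
  # the planted nested fraction tracks the configured probability
  pN <- 0.65
  n <- nrow(tt)
  expect_lt(abs(mean(!is.na(tt$nested_into)) - pN),
            3 * sqrt(pN * (1 - pN) / n) + 0.02)
})

test_that("planted in-domain probability is recovered", {
  cfg <- simConfig(nChromosomes = 2L, chromLength = 200000L,
                   nInsertions = 60L, domainLengthRange = c(4000, 6000),
                   nDonors = 0L, pNested = 0, pTargetInDomain = 0.8,
                   pTruncation = 1, truncationRange = c(700, 900),
                   ageDistribution = list(name = "constant", mean = 0,
                                          min = 0),
                   seed = 107L)
  m <- makeMasterElement(utr5 = 100L, orf1 = 300L, orf2 = 600L, utr3 = 60L,
                         seed = 6L)
  sim <- plantInsertions(simulateGenome(cfg), m)
  pct <- percentInDomains(elementRanges(sim), domainRanges(sim))
  expect_lt(abs(pct - 80), 100 * 3 * sqrt(0.8 * 0.2 / 60))
})
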