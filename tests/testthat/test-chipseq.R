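# Windowed density, Poisson/BH island calling, cluster enrichment.

library(GenomicRanges)

mkTrack <- function(counts, window = 1000L, chrom = "chr1") {
  n <- length(counts)
  gr <- GRanges(chrom, IRanges::IRanges(seq(1L, by = window, length.out = n),
                                        width = window))
  gr$count <- as.integer(counts)
  gr$mappable <- rep(window, n)
  gr$density <- counts / window
  gr
}

test_that("window density counts unique read starts per mappable bp", {
  lens <- c(chr1 = 3000)
  reads <- data.frame(chrom = "chr1",
                      start = c(rep(101:200, each = 1), 150, 2500),
                      strand = "+")
  wd <- windowDensity(reads, lens, window = 1000)
  # duplicate position 150 collapses; 100 unique starts in window 1
  expect_equal(wd$count, c(100L, 0L, 1L))
  expect_equal(wd$density[1], 0.1)
  # halved mappable bp doubles the density
  map <- GRanges("chr1", IRanges::IRanges(1, 500))
  wd2 <- windowDensity(reads, lens, window = 1000, mappability = map)
  expect_equal(wd2$mappable, c(500L, 0L, 0L))
  expect_equal(wd2$density[1], 100 / 500)
  expect_true(is.na(wd2$density[2]))
  expect_error(windowDensity(data.frame(chrom = "chr9", start = 1,
                                        strand = "+"), lens),
               "outside the assembly")
})

test_that("island calling matches exact Poisson tails on a printed toy track", {
  chip <- mkTrack(c(10, 10, 10, 200, 200, 10, 10, 10, 10, 10))
  input <- mkTrack(rep(10, 10))
  # the toy windows cover a sliver of the genome: equal full-library sizes
  islands <- callDomains(chip, input, foldMin = 5, fdrMax = 0.001, gap = 1,
                         chipLib = 1e5, inputLib = 1e5)
  expect_length(islands, 1)
  expect_equal(start(islands), 3001)
  expect_equal(end(islands), 5000)
  win <- attr(islands, "windows")
  for (i in seq_len(10)) {
    expect_equal(win$p[i], oraclePoissonTail(chip$count[i], 10))
  }
  expect_equal(win$fold[4], 20)
  # BH adjusted q-values are monotone in p
  ord <- order(win$p)
  expect_true(all(diff(win$q[ord]) >= -1e-12))
  expect_error(callDomains(chip, mkTrack(rep(0, 10))), "input")
})

test_that("island calls are invariant to uniform library rescaling", {
  chip <- mkTrack(c(10, 10, 10, 200, 200, 10, 10, 10, 10, 10))
  input <- mkTrack(rep(10, 10))
  chip3 <- chip; chip3$count <- chip$count * 3L
  input3 <- input; input3$count <- input$count * 3L
  a <- callDomains(chip, input, chipLib = 1e5, inputLib = 1e5)
  b <- callDomains(chip3, input3, chipLib = 3e5, inputLib = 3e5)
  expect_equal(as.data.frame(a)[1:3], as.data.frame(b)[1:3])
  wa <- attr(a, "windows"); wb <- attr(b, "windows")
  expect_equal(wa$fold, wb$fold)
})

test_that("no islands are called in unenriched simulations", {
  cfg <- simConfig(nChromosomes = 1L, chromLength = 100000L,
                   nInsertions = 0L, domainLengthRange = c(10000, 12000),
                   seed = 109L)
  sim <- simulateGenome(cfg)
  for (r in 1:20) {
    rd <- simulateReads(sim, enrichmentFold = 1, nChip = 5000,
                        nInput = 5000, seed = 200L + r)
    isl <- callDomains(windowDensity(rd$chip, genomeSequences(sim)),
                       windowDensity(rd$input, genomeSequences(sim)))
    expect_length(isl, 0)
  }
})

test_that("a planted enrichment domain is recovered almost exactly", {
  cfg <- simConfig(nChromosomes = 2L, chromLength = 250000L,
                   nInsertions = 0L, domainLengthRange = c(20000, 30000),
                   seed = 113L)
  sim <- simulateGenome(cfg)
  rd <- simulateReads(sim, enrichmentFold = 30, nChip = 100000,
                      nInput = 100000, seed = 9L)
  isl <- callDomains(windowDensity(rd$chip, genomeSequences(sim)),
                     windowDensity(rd$input, genomeSequences(sim)))
  expect_gte(intervalJaccard(isl, domainRanges(sim)), 0.9)
})

test_that("cluster enrichment reproduces the fold and proportion arithmetic", {
  chip <- c(rep("cenRepeat", 290), rep("other", 710))
  input <- c(rep("cenRepeat", 10), rep("other", 990))
  res <- clusterEnrichment(chip, input)
  expect_equal(res$fold[res$cluster == "cenRepeat"], 29)
  res2 <- clusterEnrichment(rep("x", 100), rep("x", 100))
  expect_equal(res2$fold, 1)
  # genome proportion: 7,500 of 5,000,000 input reads -> 0.15%
  res3 <- clusterEnrichment(character(0), rep("cenRepeat", 7500),
                            chipLib = 5e6, inputLib = 5e6)
  expect_equal(100 * res3$genome_proportion, 0.15)
  # pseudocount applies when a count is zero
  expect_true(is.finite(res3$fold))
  # proportions sum to <= 1
  expect_lte(sum(res3$genome_proportion), 1)
  expect_error(clusterEnrichment("a", "b", chipLib = 0), "empty")
})
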