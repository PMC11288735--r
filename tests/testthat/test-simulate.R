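# Synthetic-genome generator: determinism, base composition, truth-table
# bookkeeping, the substitution clock, and read simulation.

test_that("simulation is deterministic under a fixed seed", {
  cfg <- simConfig(nChromosomes = 2L, chromLength = 30000L,
                   nInsertions = 8L, domainLengthRange = c(3000, 5000),
                   nDonors = 4L, donorLength = 800L, seed = 3L)
  m <- makeMasterElement(utr5 = 50L, orf1 = 150L, orf2 = 300L, utr3 = 30L,
                         seed = 4L)
  s1 <- plantInsertions(simulateGenome(cfg), m)
  s2 <- plantInsertions(simulateGenome(cfg), m)
  expect_identical(as.character(genomeSequences(s1)),
                   as.character(genomeSequences(s2)))
  expect_identical(truthTable(s1), truthTable(s2))
  r1 <- simulateReads(s1, nChip = 2000, nInput = 2000, seed = 9)
  r2 <- simulateReads(s2, nChip = 2000, nInput = 2000, seed = 9)
  expect_identical(r1, r2)
})

test_that("background GC content matches the configured value", {
  cfg <- simConfig(nChromosomes = 1L, chromLength = 200000L,
                   gcBackground = 0.5, nInsertions = 0L,
                   domainLengthRange = c(5000, 6000), seed = 8L)
  g <- genomeSequences(simulateGenome(cfg))
  sdev <- sqrt(0.5 * 0.5 / 200000)
  expect_lt(abs(gcContent(g) - 0.5), 3 * sdev)
  cfg0 <- simConfig(nChromosomes = 1L, chromLength = 5000L,
                    gcBackground = 0, nInsertions = 0L,
                    domainLengthRange = c(500, 600), seed = 8L)
  g0 <- as.character(genomeSequences(simulateGenome(cfg0))[[1]])
  expect_false(grepl("[GC]", g0))
})

test_that("planted TSDs flank every insertion verbatim in the emitted genome", {
  sim <- cleanSim()
  tt <- truthTable(sim)
  g <- genomeSequences(sim)
  okJ <- undisturbedJunctions(sim)
  expect_gt(mean(okJ), 0.6)
  tt <- tt[okJ, ]
  for (i in seq_len(nrow(tt))) {
    chrom <- g[[tt$chrom[i]]]
    l <- tt$tsd_len[i]
    left <- as.character(Biostrings::subseq(chrom, tt$start[i] - l,
                                            tt$start[i] - 1))
    right <- as.character(Biostrings::subseq(chrom, tt$end[i] + 1,
                                             tt$end[i] + l))
    expect_identical(left, tt$tsd[i])
    expect_identical(right, tt$tsd[i])
  }
})

test_that("age-zero unmutated copies equal the master and keep intact ORFs", {
  sim <- cleanSim()   # constant age 0
  tt <- truthTable(sim)
  seqs <- extractElements(sim)
  mseq <- as.character(elementSequence(testMaster()))
  # copies that themselves received a nested insertion are longer than
  # planted; compare the pristine ones (the majority)
  pristine <- Biostrings::width(seqs) == nchar(mseq) - tt$truncation5
  expect_gt(mean(pristine), 0.5)
  for (i in which(pristine)) {
    expected <- substring(mseq, tt$truncation5[i] + 1, nchar(mseq))
    expect_identical(as.character(seqs[[i]]), expected)
  }
  # at age 0 the only ORF-disrupting force is truncation into ORF1
  utr5len <- IRanges::start(elementOrfs(testMaster())$orf1) - 1L
  expect_identical(tt$intact_orfs, tt$truncation5 <= utr5len)
})

test_that("nick motif sits at the 5' junction when the truth table says so", {
  sim <- cleanSim()
  tt <- truthTable(sim)
  g <- genomeSequences(sim)
  okJ <- undisturbedJunctions(sim)
  hits <- which(!is.na(tt$motif) & okJ)
  expect_gt(length(hits), 0)
  for (i in hits) {
    chrom <- g[[tt$chrom[i]]]
    l <- tt$tsd_len[i]
    ctx <- if (tt$strand[i] == "+") {
      s0 <- tt$start[i] - l
      as.character(Biostrings::subseq(chrom, s0 - 2, s0 + 1))
    } else {
      e0 <- tt$end[i] + l
      as.character(Biostrings::reverseComplement(
        Biostrings::subseq(chrom, e0 - 1, e0 + 2)))
    }
    expect_identical(ctx, tt$motif[i])
  }
})

test_that("pairwise divergence between copies follows the 2*mu*t clock", {
  mu <- 1.3e-8
  t_age <- 1e6
  cfg <- simConfig(nChromosomes = 1L, chromLength = 400000L,
                   nInsertions = 24L, domainLengthRange = c(5000, 6000),
                   nDonors = 0L, pNested = 0, pTruncation = 0,
                   pTargetInDomain = 0,
                   ageDistribution = list(name = "constant", mean = t_age,
                                          min = 0),
                   mu = mu, seed = 31L)
  m <- makeMasterElement(utr5 = 100L, orf1 = 300L, orf2 = 600L,
                         utr3 = 60L, seed = 5L)
  sim <- plantInsertions(simulateGenome(cfg), m)
  seqs <- as.character(extractElements(sim))
  L <- length(elementSequence(m))
  seqs <- seqs[nchar(seqs) == L]   # drop rare chance-nested copies
  # at a shared constant age every copy carries independent private
  # mutations, so inter-copy divergence is Poisson(2 mu t L)
  lambda <- 2 * mu * t_age * L
  pairs <- utils::combn(length(seqs), 2)
  keep <- pairs[, seq(1, ncol(pairs), by = 3)]   # thin correlated pairs
  dv <- apply(keep, 2, function(ij) {
    a <- strsplit(seqs[ij[1]], "")[[1]]
    b <- strsplit(seqs[ij[2]], "")[[1]]
    sum(a != b)
  })
  # correlated pairs inflate the Monte-Carlo error beyond the iid bound and
  # multiple hits at one site shave the observed count slightly, so allow
  # a 5% systematic margin on top of the sampling term
  expect_lt(abs(mean(dv) - lambda),
            3 * sqrt(lambda / length(dv)) + lambda / 20)
})

test_that("ChIP read mixture matches the enrichment algebra", {
  cfg <- simConfig(nChromosomes = 1L, chromLength = 100000L,
                   nInsertions = 0L, domainLengthRange = c(10000, 10000),
                   seed = 12L)
  sim <- simulateGenome(cfg)
  rd <- simulateReads(sim, enrichmentFold = 30, nChip = 20000,
                      nInput = 20000, seed = 5)
  f <- sum(GenomicRanges::width(domainRanges(sim))) /
    sum(Biostrings::width(genomeSequences(sim)))
  p <- 30 * f / (30 * f + 1 - f)
  rg <- GenomicRanges::GRanges(rd$chip$chrom,
                               IRanges::IRanges(rd$chip$start, width = 1))
  obs <- mean(IRanges::overlapsAny(rg, domainRanges(sim)))
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 20000) + 0.01)
  expect_error(simulateReads(sim, enrichmentFold = 0.5), "enrichmentFold")
  expect_error(simulateReads(sim, nChip = 0), "positive")
})

test_that("fold-1 ChIP is indistinguishable from input on 1-kb windows", {
  cfg <- simConfig(nChromosomes = 1L, chromLength = 50000L,
                   nInsertions = 0L, domainLengthRange = c(5000, 6000),
                   seed = 14L)
  sim <- simulateGenome(cfg)
  rd <- simulateReads(sim, enrichmentFold = 1, nChip = 25000,
                      nInput = 25000, seed = 6)
  chip <- windowDensity(rd$chip, genomeSequences(sim))
  inp <- windowDensity(rd$input, genomeSequences(sim))
  p <- suppressWarnings(
    stats::chisq.test(cbind(chip$count, inp$count))$p.value)
  expect_gt(p, 0.01)
})
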