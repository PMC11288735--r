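# TSD detection, junction base-composition matrices, GC content.

test_that("detectTsd finds the longest flanking duplication", {
  rec <- detectTsd("AAGAGTACGTACGTAC", "GTACGTACGTACTTTTTTTTTTTTTTTTTT")
  expect_equal(rec$tsd, "GTACGTACGTAC")
  expect_equal(rec$length, 12L)
  expect_true(rec$highConfidence)
  # no shared word at the junction
  expect_null(detectTsd(strrep("A", 20), strrep("C", 20)))
  # 9-bp duplication is reported but not high confidence
  set.seed(61)
  tsd9 <- "GATCCATGG"
  rec9 <- detectTsd(paste0(strrep("T", 12), tsd9),
                    paste0(tsd9, strrep("T", 12)))
  expect_equal(rec9$length, 9L)
  expect_false(rec9$highConfidence)
})

test_that("detectTsd tolerates boundary offsets within the slack", {
  tsd <- "ACGTACGTACGT"
  left <- paste0(strrep("T", 10), tsd, "G")      # one stray base after TSD
  right <- paste0("C", tsd, strrep("T", 10))     # one stray base before TSD
  rec <- detectTsd(left, right, slack = 2)
  expect_equal(rec$tsd, tsd)
  expect_equal(rec$offsetLeft, 1L)
  expect_equal(rec$offsetRight, 1L)
  expect_null(detectTsd(left, right, slack = 0, minReport = 5))
})

test_that("junction matrices are proper frequency tables", {
  ctx <- c(rep("AAAAAAAAAAGTTTTTTTTT", 5))
  rec <- data.frame(id = paste0("e", 1:5), tsd = strrep("G", 12),
                    length = 12L, high_confidence = TRUE,
                    context5 = ctx, context3 = ctx,
                    stringsAsFactors = FALSE)
  jm <- junctionMatrix(rec, "five_prime")
  f <- jmFrequencies(jm)
  expect_equal(unname(f["A", "0"]), 1.0)   # base upstream of TSD
  expect_equal(unname(f["G", "1"]), 1.0)   # first TSD base
  expect_true(all(abs(colSums(f) - 1) < 1e-9))
  expect_error(junctionMatrix(rec[0, ], "five_prime"), "empty")

  # uniform random contexts: every frequency near 0.25
  set.seed(67)
  n <- 10000
  rnd <- vapply(seq_len(n), function(i) randomDna(20), character(1))
  rec2 <- data.frame(id = paste0("r", seq_len(n)), tsd = strrep("A", 10),
                     length = 10L, high_confidence = TRUE,
                     context5 = rnd, context3 = rnd,
                     stringsAsFactors = FALSE)
  f2 <- jmFrequencies(junctionMatrix(rec2, "three_prime"))
  expect_true(all(abs(f2 - 0.25) < 0.02))
})

test_that("gc content follows its definition", {
  expect_equal(gcContent("GGCC"), 1.0)
  expect_equal(gcContent("AATT"), 0.0)
  expect_equal(gcContent("GATC"), 0.5)
  expect_equal(gcContent(c("GG", "AT", "NN")), 0.5)
  expect_error(gcContent("NNN"), "zero counted")
})

test_that("TSDs and junction bias are recovered from a mutation-free simulation", {
  sim <- cleanSim()
  tt <- truthTable(sim)
  rec <- tsdTable(genomeSequences(sim), elementRanges(sim))
  # every insertion with an undisturbed junction is recovered with the
  # exact planted TSD (a later insertion can destroy older junctions)
  okJ <- undisturbedJunctions(sim)
  expect_gt(mean(okJ), 0.6)
  expect_identical(rec$tsd[match(tt$id, rec$id)][okJ], tt$tsd[okJ])
  # planted nick-motif bias direction: positions -1,0 and 2 A-dominant,
  # position 1 dominated by G/T
  jm <- jmFrequencies(junctionMatrix(rec, "five_prime"))
  expect_equal(unname(rownames(jm)[apply(jm[, c("-1", "0")], 2,
                                         which.max)]), c("A", "A"))
  expect_gt(jm["G", "1"] + jm["T", "1"], 0.5)
  expect_equal(unname(rownames(jm)[which.max(jm[, "2"])]), "A")
  # background GC of the generator matches the configured value
  sdev <- sqrt(0.338 * 0.662 / 150000)
  cfgGc <- simConfig(nChromosomes = 1L, chromLength = 150000L,
                     nInsertions = 0L, domainLengthRange = c(5000, 6000),
                     seed = 71L)
  expect_lt(abs(gcContent(genomeSequences(simulateGenome(cfgGc))) - 0.338),
            3 * sdev)
})

test_that("donor junction matrix reflects AT-biased 5-bp target sites", {
  ctxAll <- c("AAAAAAAAAATTTTTCCCCCCCCCC")
  jm <- crmJunctionMatrix(rep(ctxAll, 3))
  f <- jmFrequencies(jm)
  expect_true(all(f["T", paste0("T", 1:5)] == 1))
  expect_true(all(abs(colSums(f) - 1) < 1e-9))
  set.seed(73)
  rnd <- vapply(1:5000, function(i) randomDna(25), character(1))
  f2 <- jmFrequencies(crmJunctionMatrix(rnd))
  expect_true(all(abs(f2 - 0.25) < 0.03))
  # simulator donors: A+T at TSD positions above the background expectation
  sim <- cleanSim()
  ctx <- donorJunctionContexts(sim)
  f3 <- jmFrequencies(crmJunctionMatrix(ctx))
  at <- colSums(f3[c("A", "T"), paste0("T", 1:5)])
  expect_gt(mean(at), 0.662)
  expect_error(crmJunctionMatrix(character()), "empty")
})
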