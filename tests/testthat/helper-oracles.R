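# Independent oracles used by the tests. These deliberately share no code
# with the package: alignment scores come from exhaustive enumeration /
# textbook dynamic programs, Poisson tails from explicit density summation.

# Exhaustive global-alignment score by recursive enumeration of all
# alignments, affine gaps (a run of length k costs open + k * extend),
# N matches nothing. Only feasible for tiny sequences.
oracleGlobalScore <- function(a, b, match = 1, mismatch = -1,
                              open = 2, extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  rec <- function(i, j, state) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb) {
      s <- if (A[i] == B[j] && A[i] %in% c("A", "C", "G", "T")) match
           else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= na) {
      cost <- extend + if (state == 1L) 0 else open
      best <- max(best, -cost + rec(i + 1L, j, 1L))
    }
    if (j <= nb) {
      cost <- extend + if (state == 2L) 0 else open
      best <- max(best, -cost + rec(i, j + 1L, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# Textbook affine-gap Smith-Waterman, score only (three-state DP written
# independently of the package's alignment code).
oracleLocalScore <- function(a, b, match = 1, mismatch = -1,
                             open = 2, extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  M <- X <- Y <- matrix(-Inf, na + 1, nb + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(na + 1)) {
    for (j in 2:(nb + 1)) {
      s <- if (A[i - 1] == B[j - 1] && A[i - 1] %in% c("A", "C", "G", "T"))
        match else mismatch
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Upper Poisson tail P(X >= k) by explicit density summation.
oraclePoissonTail <- function(k, lambda) {
  if (k <= 0) return(1)
  1 - sum(stats::dpois(0:(k - 1), lambda))
}

randomDna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutateDna <- function(x, nsub) {
  v <- strsplit(x, "")[[1]]
  p <- sample(length(v), min(nsub, length(v)))
  for (i in p) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

# Small reusable master element and a mutation-free planted simulation,
# built once per test run.
testMaster <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- makeMasterElement(utr5 = 100L, orf1 = 300L, orf2 = 600L,
                                utr3 = 60L, seed = 99L)
    val
  }
})

cleanSim <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cfg <- simConfig(nChromosomes = 2L, chromLength = 150000L,
                       nInsertions = 30L,
                       domainLengthRange = c(10000, 15000),
                       nDonors = 10L, donorLength = 1200L,
                       pTruncation = 0.4, truncationRange = c(100, 600),
                       ageDistribution = list(name = "constant", mean = 0,
                                              min = 0),
                       seed = 21L)
      val <<- plantInsertions(simulateGenome(cfg), testMaster())
    }
    val
  }
})
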