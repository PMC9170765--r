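# Fixture builders and independent oracle implementations used across the
# suite. Oracles are deliberately naive (loops, enumeration) and share no
# code with the package internals they check.

# random small genotype panel
randomGenotypeMatrix <- function(nCase = 4, nControl = 6, nSites = 30,
                                 missingRate = 0.1, seed = 1,
                                 chrom = "chr1", maxPos = 60000) {
  withr::with_seed(seed, {
    pos <- sort(sample.int(maxPos, nSites))
    p <- runif(nSites, 0.05, 0.95)
    n <- nCase + nControl
    g <- matrix(rbinom(nSites * n, 2, rep(p, n)), nrow = nSites)
    if (missingRate > 0) g[runif(length(g)) < missingRate] <- NA_integer_
    ref <- sample(c("A", "C", "G", "T"), nSites, TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                        type = sample(c("SNP", "indel"), nSites, TRUE,
                                      prob = c(0.9, 0.1)))
    panel <- data.frame(
      sample = sprintf("S%02d", seq_len(n)),
      population = rep(c("case", "control"), c(nCase, nControl)))
    genotypeMatrix(sites, g, panel)
  })
}

# exhaustive mean-pairwise-difference pi for one site: enumerate all allele
# pairs from the called genotypes
oracleSitePi <- function(genoRow) {
  g <- genoRow[!is.na(genoRow)]
  alleles <- unlist(lapply(g, function(x) switch(as.character(x),
    "0" = c(0L, 0L), "1" = c(0L, 1L), "2" = c(1L, 1L))))
  m <- length(alleles)
  if (m < 2) return(NA_real_)
  pairs <- utils::combn(m, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# brute-force windowed pi (per bp) for one population
oracleWindowPi <- function(gm, population, window = 40000, step = 20000) {
  idx <- which(gm@panel$population == population)
  g <- genotypeCalls(gm)[, idx, drop = FALSE]
  pis <- vapply(seq_len(nrow(g)), function(i) oracleSitePi(g[i, ]),
                numeric(1))
  sites <- variantSites(gm)
  res <- list()
  for (ch in unique(sites$chrom)) {
    inCh <- sites$chrom == ch
    starts <- seq(0, max(sites$pos[inCh]) - 1, by = step)
    for (s in starts) {
      sel <- inCh & (sites$pos - 1) >= s & (sites$pos - 1) < s + window
      if (!any(sel)) next
      res[[sprintf("%s:%d-%d", ch, as.integer(s), as.integer(s + window))]] <-
        sum(pis[sel], na.rm = TRUE) / window
    }
  }
  unlist(res)
}

# exhaustive genotype-frequency filter, looping over sites and individuals
oracleDiffSites <- function(gm, minCase = 16, minCtl = 51,
                            caseGt = 0.8, ctlLt = 0.06) {
  g <- genotypeCalls(gm)
  pop <- gm@panel$population
  out <- logical(nrow(g))
  elig <- logical(nrow(g))
  for (i in seq_len(nrow(g))) {
    cc <- ck <- altC <- altK <- 0
    for (j in seq_len(ncol(g))) {
      v <- g[i, j]
      if (is.na(v)) next
      if (pop[j] == "case") {
        cc <- cc + 1
        altC <- altC + v
      } else {
        ck <- ck + 1
        altK <- altK + v
      }
    }
    elig[i] <- cc >= minCase && ck >= minCtl
    out[i] <- elig[i] && (altC / (2 * cc)) > caseGt && (altK / (2 * ck)) < ctlLt
  }
  list(eligible = elig, pass = out)
}

# hand-coded BH step-up
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  run <- Inf
  for (i in m:1) {
    run <- min(run, m * sorted[i] / i)
    q[i] <- min(1, run)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# triple-loop topological overlap
oracleTOM <- function(A) {
  n <- nrow(A)
  k <- rowSums(A) - diag(A)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + A[i, u] * A[u, j]
    tom[i, j] <- (s + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  tom
}

# small expression fixture
smallExprSim <- function(seed = 1, ...) {
  simulateExpression(exprSimConfig(seed = seed, ...))
}
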