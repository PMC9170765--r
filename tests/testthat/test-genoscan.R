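test_that("sitePi matches exhaustive pairwise enumeration and edge cases", {
  expect_equal(sitePi(0, 40), 0)
  expect_equal(sitePi(40, 40), 0)
  expect_equal(sitePi(2, 4), 2 / 3)
  # exhaustive oracle over random sites
  gm <- randomGenotypeMatrix(nCase = 5, nControl = 5, nSites = 40, seed = 21)
  g <- genotypeCalls(gm)
  for (i in seq_len(nrow(g))) {
    m <- 2 * sum(!is.na(g[i, ]))
    alt <- sum(g[i, ], na.rm = TRUE)
    expect_equal(sitePi(alt, m), oracleSitePi(g[i, ]), tolerance = 1e-12)
  }
  expect_true(is.na(sitePi(1, 1)))
})

test_that("siteFst evaluates the Hudson formula and is label-symmetric", {
  f <- siteFst(1, 40, 0, 40)
  expect_equal(f$numerator / f$denominator, 1)
  f <- siteFst(0.5, 20, 0.5, 20)
  expect_equal(f$numerator, -0.25 / 19 * 2)
  expect_equal(f$denominator, 0.5)
  expect_equal(f$numerator / f$denominator, -0.0526316, tolerance = 1e-6)
  # symmetry for both estimators
  for (est in c("hudson", "wc84")) {
    a <- siteFst(0.3, 24, 0.7, 36, 0.4, 0.35, estimator = est)
    b <- siteFst(0.7, 36, 0.3, 24, 0.35, 0.4, estimator = est)
    expect_equal(a, b)
  }
  expect_true(is.na(siteFst(0.5, 1, 0.5, 20)$numerator))
})

test_that("windowScan boundary bookkeeping follows the half-open convention", {
  # sites exactly at positions 1..40000 fall in windows 0 and 20000 only
  pos <- c(1L, 15000L, 20000L, 20001L, 39999L, 40000L)
  n <- length(pos)
  sites <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                      type = "SNP")
  geno <- matrix(rep(c(0L, 1L, 2L, 1L), each = n), nrow = n)
  panel <- data.frame(sample = paste0("S", 1:4),
                      population = c("case", "case", "control", "control"))
  gm <- genotypeMatrix(sites, geno, panel)
  w <- windowScan(gm, minSites = 1)
  expect_setequal(w$start, c(0, 20000))
  expect_equal(w$n_sites[w$start == 0], 6L)      # all P-1 in [0, 40000)
  expect_equal(w$n_sites[w$start == 20000], 3L)  # P in 20001..40000
  expect_equal(w$median_site, w$start + 20000)
  expect_equal(w$end - w$start, rep(40000, 2))
})

test_that("monomorphic input yields zero pi and delta-pi everywhere", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 50L, 90L), ref = "A",
                      alt = "G", type = "SNP")
  geno <- matrix(0L, 3, 6)
  panel <- data.frame(sample = paste0("S", 1:6),
                      population = rep(c("case", "control"), each = 3))
  gm <- genotypeMatrix(sites, geno, panel)
  w <- windowScan(gm, minSites = 1)
  expect_equal(w$pi_case, 0)
  expect_equal(w$pi_control, 0)
  expect_equal(w$delta_pi, 0)
})

test_that("window pi equals the exhaustive pairwise oracle", {
  gm <- randomGenotypeMatrix(nCase = 5, nControl = 5, nSites = 200,
                             missingRate = 0.1, seed = 33, maxPos = 120000)
  w <- windowScan(gm, minSites = 1)
  for (popn in c("case", "control")) {
    oracle <- oracleWindowPi(gm, popn)
    got <- setNames(if (popn == "case") w$pi_case else w$pi_control, w$id)
    expect_equal(got[names(oracle)], oracle, tolerance = 1e-12)
  }
})

test_that("delta-pi is antisymmetric and the scan ignores individual order", {
  gm <- randomGenotypeMatrix(nCase = 6, nControl = 8, nSites = 60, seed = 7)
  w <- windowScan(gm, minSites = 1)
  # swap population labels
  panel2 <- samplePanel(gm)
  panel2$population <- ifelse(panel2$population == "case", "control", "case")
  gm2 <- genotypeMatrix(variantSites(gm), genotypeCalls(gm), panel2)
  w2 <- windowScan(gm2, minSites = 1)
  expect_equal(w2$delta_pi, -w$delta_pi, tolerance = 1e-12)
  # permute individuals
  perm <- withr::with_seed(1, sample(ncol(genotypeCalls(gm))))
  gm3 <- genotypeMatrix(variantSites(gm),
                        genotypeCalls(gm)[, perm, drop = FALSE],
                        samplePanel(gm)[perm, , drop = FALSE])
  w3 <- windowScan(gm3, minSites = 1)
  expect_equal(w3, w, tolerance = 1e-12)
  ds <- differentiatedSites(gm, minCaseCalled = 2, minControlCalled = 2)
  ds3 <- differentiatedSites(gm3, minCaseCalled = 2, minControlCalled = 2)
  expect_equal(ds3, ds)
})

test_that("unsorted sites are rejected", {
  sites <- data.frame(chrom = "chr1", pos = c(50L, 10L), ref = "A",
                      alt = "G", type = "SNP")
  expect_error(
    genotypeMatrix(sites, matrix(0L, 2, 2),
                   data.frame(sample = c("a", "b"),
                              population = c("case", "control"))),
    "strictly increasing")
})

test_that("selectCandidates uses nearest-rank thresholds with tie inclusion", {
  # 300 windows with independently permuted distinct ranks
  withr::with_seed(5, {
    n <- 300
    fst <- sample(seq_len(n)) / n
    dpi <- sample(seq_len(n)) / n
  })
  w <- data.frame(chrom = "chr1", start = seq_len(n) * 20000 - 20000,
                  end = seq_len(n) * 20000 + 20000,
                  median_site = 0, n_sites = 10, fst = fst,
                  pi_case = 0, pi_control = 0, delta_pi = dpi,
                  id = paste0("w", seq_len(n)))
  cs <- selectCandidates(w, q = 0.01)
  expect_length(cs$topFst, 3L)
  expect_length(cs$topDpi, 3L)
  # brute-force set logic
  topF <- w$id[order(-w$fst)][1:3]
  topD <- w$id[order(-w$delta_pi)][1:3]
  expect_setequal(cs$topFst, topF)
  expect_setequal(cs$candidates$id, intersect(topF, topD))
  # tie saturation: all equal values -> everything is a candidate
  w$fst <- 1
  w$delta_pi <- 2
  expect_equal(nrow(selectCandidates(w, q = 0.01)$candidates), n)
  # q = 1 keeps everything
  expect_equal(nrow(selectCandidates(w, q = 1)$candidates), n)
})

test_that("recovery ratio is exactly 1 when the subsample equals the pool", {
  gm <- randomGenotypeMatrix(nCase = 5, nControl = 8, nSites = 120,
                             seed = 13, maxPos = 200000)
  w <- windowScan(gm, minSites = 1)
  cs <- selectCandidates(w, q = 0.3)
  rr <- recoveryRatio(gm, cs, nReplicates = 10, subsample = 8, q = 0.3,
                      seed = 1, minSites = 1)
  expect_equal(rr$candidates$rr_fst, rep(1, nrow(rr$candidates)))
  expect_equal(rr$candidates$rr_dpi, rep(1, nrow(rr$candidates)))
  expect_equal(rr$candidates$rr_joint, rep(1, nrow(rr$candidates)))
  expect_true(all(rr$candidates$selected))
})

test_that("recovery ratios are multiples of 1/n and monotone in q", {
  gm <- randomGenotypeMatrix(nCase = 6, nControl = 10, nSites = 150,
                             seed = 17, maxPos = 300000)
  w <- windowScan(gm, minSites = 1)
  cs <- selectCandidates(w, q = 0.2)
  one <- recoveryRatio(gm, cs, nReplicates = 1, subsample = 5, q = 0.2,
                       seed = 3, minSites = 1)
  expect_true(all(one$candidates$rr_fst %in% c(0, 1)))
  r1 <- recoveryRatio(gm, cs, nReplicates = 30, subsample = 5, q = 0.1,
                      seed = 3, minSites = 1)
  r2 <- recoveryRatio(gm, cs, nReplicates = 30, subsample = 5, q = 0.2,
                      seed = 3, minSites = 1)
  expect_true(all(r2$candidates$rr_fst >= r1$candidates$rr_fst))
  expect_true(all(r2$candidates$rr_dpi >= r1$candidates$rr_dpi))
  expect_true(all(abs(r1$candidates$rr_fst * 30 -
                        round(r1$candidates$rr_fst * 30)) < 1e-9))
  expect_error(recoveryRatio(gm, cs, nReplicates = 5, subsample = 11),
               "exceeds control pool")
})

test_that("differentiated-site filter matches the worked count example", {
  # case: 16 called = 15 hom-alt + 1 het -> 31/32; control: 60 called, 4 het
  caseG <- c(rep(2L, 15), 1L, rep(NA_integer_, 4))
  ctlG <- c(rep(1L, 4), rep(0L, 56), rep(NA_integer_, 40))
  sites <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                      type = "SNP")
  panel <- data.frame(sample = sprintf("S%03d", 1:120),
                      population = rep(c("case", "control"), c(20, 100)))
  gm <- genotypeMatrix(sites, matrix(c(caseG, ctlG), nrow = 1), panel)
  ds <- differentiatedSites(gm, minControlCalled = 51)
  expect_equal(ds$case_called, 16)
  expect_equal(ds$case_ratio, 31 / 32)
  expect_equal(ds$control_ratio, 4 / 120)
  expect_true(ds$eligible)
  expect_true(ds$pass)
  # 15 called cases -> ineligible regardless of ratios
  gm15 <- genotypeMatrix(sites,
                         matrix(c(rep(2L, 15), rep(NA_integer_, 5), ctlG),
                                nrow = 1), panel)
  ds15 <- differentiatedSites(gm15)
  expect_false(ds15$eligible)
  expect_false(ds15$pass)
})

test_that("boundary ratios fail the strict inequalities", {
  # case ratio exactly 0.8: 20 called, 32/40 alt alleles
  caseG <- c(rep(2L, 12), rep(1L, 8))
  # control ratio exactly 0.06: 100 called, 12/200 alt alleles
  ctlG <- c(rep(1L, 12), rep(0L, 88))
  sites <- data.frame(chrom = "chr1", pos = 5L, ref = "A", alt = "T",
                      type = "SNP")
  panel <- data.frame(sample = sprintf("S%03d", 1:120),
                      population = rep(c("case", "control"), c(20, 100)))
  gm <- genotypeMatrix(sites, matrix(c(caseG, ctlG), nrow = 1), panel)
  ds <- differentiatedSites(gm)
  expect_true(ds$eligible)
  expect_equal(ds$case_ratio, 0.8)
  expect_equal(ds$control_ratio, 0.06)
  expect_false(ds$pass)
})

test_that("GF filter agrees with the exhaustive oracle on random panels", {
  for (s in 1:25) {
    gm <- randomGenotypeMatrix(nCase = 20, nControl = 60, nSites = 40,
                               missingRate = 0.3, seed = s)
    ds <- differentiatedSites(gm, minCaseCalled = 10, minControlCalled = 30,
                              caseRatioGt = 0.5, controlRatioLt = 0.2)
    oracle <- oracleDiffSites(gm, minCase = 10, minCtl = 30,
                              caseGt = 0.5, ctlLt = 0.2)
    expect_identical(unname(ds$eligible), oracle$eligible)
    expect_identical(unname(ds$pass), oracle$pass)
  }
})

test_that("carrier-frequency mode counts individuals, not alleles", {
  caseG <- c(rep(1L, 17), rep(0L, 3))   # 17/20 carriers, 17/40 alleles
  ctlG <- rep(0L, 60)
  sites <- data.frame(chrom = "chr1", pos = 9L, ref = "A", alt = "T",
                      type = "SNP")
  panel <- data.frame(sample = sprintf("S%03d", 1:80),
                      population = rep(c("case", "control"), c(20, 60)))
  gm <- genotypeMatrix(sites, matrix(c(caseG, ctlG), nrow = 1), panel)
  expect_equal(differentiatedSites(gm)$case_ratio, 17 / 40)
  expect_equal(differentiatedSites(gm, ratio = "carrier")$case_ratio,
               17 / 20)
})
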