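test_that("signed adjacency evaluates the transform and validates input", {
  C <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(signedAdjacency(C, 12)[1, 2], 0.5^12)
  expect_equal(signedAdjacency(matrix(c(1, 1, 1, 1), 2), 12)[1, 2], 1)
  expect_equal(signedAdjacency(matrix(c(1, -1, -1, 1), 2), 12)[1, 2], 0)
  expect_error(signedAdjacency(matrix(c(1, 0.5, 0.2, 1), 2)), "symmetric")
  expect_error(signedAdjacency(matrix(c(1, 2, 2, 1), 2)), "\\[-1, 1\\]")
})

test_that("TOM matches closed forms and the triple-loop oracle", {
  # complete triad with unit weights
  A3 <- matrix(1, 3, 3)
  expect_equal(topologicalOverlap(A3)[1, 2], 1)
  # isolated pair: TOM equals the adjacency
  x <- 0.37
  A2 <- matrix(c(1, x, x, 1), 2)
  expect_equal(topologicalOverlap(A2)[1, 2], x)
  # single nonzero entry: no shared neighbors, no direct edge
  A <- diag(3)
  A[1, 2] <- A[2, 1] <- 0.5
  expect_equal(topologicalOverlap(A)[1, 3], 0)
  # random networks vs the oracle
  withr::with_seed(81, {
    for (rep in 1:5) {
      C <- cor(matrix(rnorm(30 * 15), 15, 30))
      Ar <- signedAdjacency(C, 6)
      expect_lt(max(abs(topologicalOverlap(Ar) - oracleTOM(Ar))), 1e-10)
    }
  })
})

test_that("adjacency and TOM are invariant to gene reordering", {
  withr::with_seed(82, {
    expr <- matrix(rnorm(25 * 12), 25, 12,
                   dimnames = list(paste0("g", 1:25), paste0("s", 1:12)))
    perm <- sample(25)
  })
  A1 <- signedAdjacency(cor(t(expr)), 12)
  T1 <- topologicalOverlap(A1)
  A2 <- signedAdjacency(cor(t(expr[perm, ])), 12)
  T2 <- topologicalOverlap(A2)
  expect_equal(A2, A1[perm, perm], tolerance = 1e-12)
  expect_equal(T2, T1[perm, perm], tolerance = 1e-12)
})

test_that("scale-free fit flags degenerate connectivity and honours forcing", {
  expr <- matrix(rep(rnorm(12), each = 15), 15, 12,
                 dimnames = list(paste0("g", 1:15), NULL))
  w <- capture_warnings(sp <- softPowerFit(expr, powers = 1:3))
  expect_true(any(grepl("degenerate", w)))
  expect_equal(sp$fitIndices$rsq, rep(0, 3))
  withr::with_seed(83, {
    modExpr <- rbind(
      matrix(rep(rnorm(12), each = 20), 20, 12) + matrix(rnorm(240, 0, 0.3), 20),
      matrix(rnorm(30 * 12), 30, 12))
    rownames(modExpr) <- paste0("g", 1:50)
  })
  forced <- suppressWarnings(softPowerFit(modExpr, powers = 12))
  expect_equal(forced$power, 12)
  # determinism: same data, same choice
  s1 <- suppressWarnings(softPowerFit(modExpr))
  s2 <- suppressWarnings(softPowerFit(modExpr))
  expect_identical(s1, s2)
  # independent recomputation of the fit R^2 at one power
  A <- signedAdjacency(cor(t(modExpr)), s1$fitIndices$power[3])
  k <- rowSums(A) - 1
  lk <- log10(k)
  br <- seq(min(lk), max(lk), length.out = 11)
  br[1] <- br[1] - 1e-9
  bin <- cut(lk, br)
  tab <- table(bin)
  keep <- tab > 0
  d <- data.frame(x = log10(tapply(k, bin, mean)[keep]),
                  y = log10(as.numeric(tab[keep]) / length(k)))
  expect_equal(s1$fitIndices$rsq[3], summary(lm(y ~ x, d))$r.squared,
               tolerance = 1e-10)
})

test_that("module eigengene matches an eigendecomposition oracle", {
  withr::with_seed(84, {
    expr <- matrix(rnorm(30 * 14), 30, 14,
                   dimnames = list(paste0("g", 1:30), paste0("s", 1:14)))
  })
  me <- moduleEigengene(expr, rownames(expr))
  Z <- t(scale(t(expr)))
  ev <- eigen(crossprod(Z) / (nrow(Z) - 1))$vectors[, 1]
  expect_lt(1 - abs(cor(me, ev)), 1e-8)
  expect_equal(sum(me^2), 1)
  # single-gene module: the standardized profile itself
  one <- moduleEigengene(expr, "g1")
  expect_equal(abs(cor(one, expr["g1", ])), 1)
  # rank-1 case: both genes have |kME| = 1
  rank1 <- rbind(a = expr[1, ], b = 2 * expr[1, ] + 3)
  me2 <- moduleEigengene(rank1, c("a", "b"))
  expect_equal(abs(cor(me2, rank1["a", ])), 1, tolerance = 1e-12)
})

test_that("static cut recovers planted blocks and respects minSize", {
  withr::with_seed(85, {
    f1 <- rnorm(21)
    f2 <- rnorm(21)
    blocks <- rbind(
      matrix(rep(f1, each = 40), 40, 21) + matrix(rnorm(40 * 21, 0, 0.25), 40),
      matrix(rep(f2, each = 40), 40, 21) + matrix(rnorm(40 * 21, 0, 0.25), 40))
    rownames(blocks) <- paste0("g", 1:80)
  })
  net <- buildCoexNetwork(blocks, power = 12)
  mods <- detectModules(net, minSize = 30)
  lab <- moduleLabels(mods)
  truth <- rep(c("A", "B"), each = 40)
  expect_equal(length(setdiff(unique(lab), "M0")), 2L)
  expect_equal(mclust::adjustedRandIndex(lab, truth), 1)
  # a 29-gene block cannot form a module at minSize = 30
  sub <- blocks[c(1:29, 41:80), ]
  net2 <- buildCoexNetwork(sub, power = 12)
  lab2 <- moduleLabels(detectModules(net2, minSize = 30))
  expect_true(all(lab2[1:29] == "M0"))
})

test_that("module merging follows the eigengene-correlation rule", {
  makeBlocks <- function(fs, n = 31, noise = 0.1, seed = 1) {
    withr::with_seed(seed, {
      m <- do.call(rbind, lapply(fs, function(f)
        matrix(rep(f, each = n), n, length(f)) +
          matrix(rnorm(n * length(f), 0, noise), n)))
    })
    rownames(m) <- paste0("g", seq_len(nrow(m)))
    m
  }
  mkLabels <- function(k, n = 31) {
    stats::setNames(rep(paste0("M", seq_len(k)), each = n),
                    paste0("g", seq_len(k * n)))
  }
  withr::with_seed(86, {
    f1 <- rnorm(20)
    fHi <- 0.9 * f1 + sqrt(1 - 0.81) * rnorm(20)   # ME cor ~ 0.9
    fLo <- 0.5 * f1 + sqrt(1 - 0.25) * rnorm(20)   # ME cor ~ 0.5
  })
  exprHi <- makeBlocks(list(f1, fHi), seed = 2)
  mHi <- new("ModuleSet", labels = mkLabels(2), eigengenes = matrix(0, 0, 0),
             mergeHistory = data.frame(from = character(0),
                                       into = character(0),
                                       cor = numeric(0)))
  merged <- mergeModules(exprHi, mHi)
  expect_equal(length(setdiff(unique(moduleLabels(merged)), "M0")), 1L)
  expect_equal(nrow(merged@mergeHistory), 1L)
  exprLo <- makeBlocks(list(f1, fLo), seed = 3)
  notMerged <- mergeModules(exprLo, mHi)
  expect_equal(length(setdiff(unique(moduleLabels(notMerged)), "M0")), 2L)
  # three modules pairwise ~0.8 collapse into one by iterative recomputation
  withr::with_seed(87, {
    gshared <- rnorm(20)
    fs <- lapply(1:3, function(i)
      sqrt(0.8) * gshared + sqrt(0.2) * rnorm(20))
  })
  expr3 <- makeBlocks(fs, seed = 4)
  m3 <- new("ModuleSet", labels = mkLabels(3), eigengenes = matrix(0, 0, 0),
            mergeHistory = data.frame(from = character(0),
                                      into = character(0),
                                      cor = numeric(0)))
  all3 <- mergeModules(expr3, m3)
  expect_equal(length(setdiff(unique(moduleLabels(all3)), "M0")), 1L)
  # idempotence: a second pass merges nothing
  again <- mergeModules(exprLo, notMerged)
  expect_identical(moduleLabels(again), moduleLabels(notMerged))
  expect_equal(nrow(again@mergeHistory), 0L)
})

test_that("module-trait correlation matches the t-distribution oracle", {
  withr::with_seed(88, {
    ME <- matrix(rnorm(21 * 3), 21, 3,
                 dimnames = list(NULL, paste0("M", 1:3)))
    trait <- rep(c(1, 0), c(9, 12))
  })
  ts <- moduleTrait(ME, trait)
  for (i in 1:3) {
    ct <- cor.test(ME[, i], trait)
    expect_equal(ts$r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(ts$p[i], ct$p.value, tolerance = 1e-10)
  }
  # closed form at n = 21, r = 0.6
  r <- 0.6
  tval <- r * sqrt(19 / (1 - r^2))
  expect_equal(tval, 3.2691742, tolerance = 1e-6)
  # perfect correlation reports p = 0; constant trait errors
  ME2 <- cbind(M1 = as.numeric(trait))
  out <- moduleTrait(ME2, trait)
  expect_equal(out$r, 1)
  expect_equal(out$p, 0)
  expect_error(moduleTrait(ME, rep(1, 21)), "constant")
})

test_that("hub selection applies strict GS/kME bounds and exports edges", {
  withr::with_seed(89, {
    trait <- rep(c(1, 0), c(9, 12))
    n <- 35
    satur <- matrix(rep(trait, each = n), n, 21) +
      matrix(rnorm(n * 21, 0, 0.1), n)
    noise <- matrix(rnorm(40 * 21), 40, 21)
    expr <- rbind(satur, noise)
    rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  })
  net <- buildCoexNetwork(expr, power = 12)
  mods <- detectModules(net, minSize = 30)
  mods <- mergeModules(expr, mods)
  expect_equal(sum(moduleLabels(mods) != "M0"), n)
  hs <- hubSelection(expr, trait, mods, net)
  inMod <- hs$hubTable[hs$hubTable$module == "M1", ]
  # every member tracks the trait: all hubs
  expect_true(all(inMod$is_hub))
  expect_true(all(abs(inMod$GS) > 0.2 & abs(inMod$kME) > 0.8))
  # edge list: pairs among the top hubs passing the TOM threshold,
  # verified against brute-force counting
  top <- inMod$gene[inMod$is_top]
  tm <- tomMatrix(net)
  cnt <- 0
  for (i in seq_along(top)[-length(top)])
    for (j in (i + 1):length(top))
      if (tm[top[i], top[j]] > 0.1) cnt <- cnt + 1
  expect_equal(nrow(hs$edges), cnt)
  expect_true(all(hs$edges$weight > 0.1))
  expect_true(all(hs$edges$source %in% top & hs$edges$target %in% top))
  # tom_edge = 1 empties the export
  hs1 <- hubSelection(expr, trait, mods, net, tomEdge = 1)
  expect_equal(nrow(hs1$edges), 0L)
  # strict GS bound: a gene below it is never a hub
  expect_false(any(hs$hubTable$is_hub[abs(hs$hubTable$GS) <= 0.2]))
})

test_that("kME to the own module exceeds a random relabeling on average", {
  es <- smallExprSim(nGenes = 200, nDe = 0, moduleSizes = c(40, 40),
                     seed = 14)
  norm <- normalizeLog2(SummarizedExperiment::assay(es$se, "fpkm"))
  truth <- es$truth$moduleAssignment[rownames(norm)]
  m1 <- names(truth)[truth == "M1"]
  m2 <- names(truth)[truth == "M2"]
  me1 <- moduleEigengene(norm, m1)
  me2 <- moduleEigengene(norm, m2)
  own <- abs(cor(t(norm[m1, ]), me1))
  other <- abs(cor(t(norm[m1, ]), me2))
  expect_gt(mean(own), mean(other))
})
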