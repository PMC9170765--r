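#' Configuration for the genotype simulator
#'
#' Bundles and validates the parameters of [simulateGenotypes()]. Defaults
#' emulate the study design the scan is built for: 20 case versus 98
#' control birds, one 10-Mb chromosome scanned in 40-kb windows, mild
#' background divergence, and five planted 40-kb sweep regions.
#'
#' @param nCase,nControl individuals per population (defaults 20 and 98).
#' @param chromLengths named integer vector of chromosome lengths in bp.
#' @param siteDensity expected variant sites per bp (Poisson process).
#' @param backgroundFst Balding-Nichols divergence parameter F in [0, 1).
#' @param sweepRegions `data.frame` with columns `chrom`, `start`, `end`
#'   (1-based inclusive bounds in bp) of planted sweep regions; may have
#'   zero rows.
#' @param sweepShift case-population allele-frequency displacement toward
#'   the nearer of {0, 1} inside sweep regions, in [0, 1].
#' @param diffSiteCount number of planted highly differentiated sites.
#' @param indelRate fraction of sites simulated as indels (type flag only).
#' @param missingRate per-genotype missing probability in [0, 0.5).
#' @param seed integer RNG seed.
#' @return A validated list of class `GenoSimConfig`.
#' @export
genoSimConfig <- function(nCase = 20, nControl = 98,
                          chromLengths = c(chr1 = 10020000L),
                          siteDensity = 0.005,
                          backgroundFst = 0.05,
                          sweepRegions = data.frame(
                            chrom = "chr1",
                            start = c(1000001L, 3000001L, 5000001L,
                                      7000001L, 9000001L),
                            end   = c(1040000L, 3040000L, 5040000L,
                                      7040000L, 9040000L)),
                          sweepShift = 0.6,
                          diffSiteCount = 50,
                          indelRate = 0.1,
                          missingRate = 0,
                          seed = 1) {
  stopifnot(nCase >= 1, nControl >= 1, all(chromLengths > 0),
            siteDensity > 0, sweepShift >= 0, sweepShift <= 1,
            diffSiteCount >= 0, indelRate >= 0, indelRate <= 1)
  if (backgroundFst < 0 || backgroundFst >= 1)
    stop("backgroundFst must lie in [0, 1)")
  if (missingRate < 0 || missingRate >= 0.5)
    stop("missingRate must lie in [0, 0.5)")
  sweepRegions <- as.data.frame(sweepRegions)
  if (nrow(sweepRegions)) {
    if (!all(sweepRegions$chrom %in% names(chromLengths)))
      stop("sweep region on unknown chromosome: ",
           paste(setdiff(sweepRegions$chrom, names(chromLengths)),
                 collapse = ", "))
    len <- chromLengths[sweepRegions$chrom]
    bad <- sweepRegions$start < 1 | sweepRegions$end > len |
      sweepRegions$start > sweepRegions$end
    if (any(bad))
      stop("sweep region outside chromosome bounds: ",
           paste(sprintf("%s:%d-%d", sweepRegions$chrom[bad],
                         sweepRegions$start[bad], sweepRegions$end[bad]),
                 collapse = ", "))
    for (ch in unique(sweepRegions$chrom)) {
      r <- sweepRegions[sweepRegions$chrom == ch, , drop = FALSE]
      r <- r[order(r$start), , drop = FALSE]
      if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)]))
        stop("sweep regions overlap on ", ch)
    }
  }
  structure(list(nCase = nCase, nControl = nControl,
                 chromLengths = chromLengths, siteDensity = siteDensity,
                 backgroundFst = backgroundFst, sweepRegions = sweepRegions,
                 sweepShift = sweepShift, diffSiteCount = diffSiteCount,
                 indelRate = indelRate, missingRate = missingRate,
                 seed = as.integer(seed)),
            class = "GenoSimConfig")
}

#' Simulate a case/control genotype panel with planted selection signals
#'
#' Draws biallelic sites at Poisson-spaced positions. Each site has an
#' ancestral frequency p0 ~ Uniform(0.05, 0.95); case and control
#' population frequencies are drawn independently from the Balding-Nichols
#' distribution Beta(p0(1-F)/F, (1-p0)(1-F)/F) with F = `backgroundFst`
#' (F = 0 keeps p0 in both populations). Inside sweep regions the case
#' frequency is additionally displaced by `sweepShift` toward the nearer of
#' {0, 1} (truncated), which jointly elevates FST and depresses case-side
#' nucleotide diversity. `diffSiteCount` sites are forced to pass the
#' genotype-frequency differentiation filter by construction (case
#' frequency 1, control frequency 0 before missingness). Genotypes are
#' Binomial(2, population frequency); missingness is i.i.d.
#'
#' @param config a [genoSimConfig()] object.
#' @param window,step window scheme (bp) used only to derive the planted
#'   sweep window ids recorded in the truth (defaults match [windowScan()]).
#' @return A list with elements
#'   \describe{
#'     \item{genotypes}{a [GenotypeMatrix-class].}
#'     \item{truth}{list with `sweepWindowIds` (windows fully contained in
#'       a sweep region, as `"chrom:start-end"` in the 0-based half-open
#'       window convention), `diffSiteIds` (`"chrom:pos"`), and the
#'       population allele frequencies used (`pCase`, `pControl`).}
#'   }
#' @examples
#' cfg <- genoSimConfig(chromLengths = c(chr1 = 2e5), sweepRegions =
#'   data.frame(chrom = "chr1", start = 40001, end = 80000),
#'   diffSiteCount = 5, seed = 7)
#' sim <- simulateGenotypes(cfg)
#' sim$genotypes
#' @export
simulateGenotypes <- function(config, window = 40000, step = 20000) {
  stopifnot(inherits(config, "GenoSimConfig"))
  withr::with_seed(config$seed, {
    chroms <- names(config$chromLengths)
    siteL <- lapply(chroms, function(ch) {
      L <- config$chromLengths[[ch]]
      n <- stats::rpois(1, L * config$siteDensity)
      n <- min(n, L)
      pos <- sort(sample.int(L, n))
      data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
    })
    sites <- do.call(rbind, siteL)
    n <- nrow(sites)
    F <- config$backgroundFst
    p0 <- stats::runif(n, 0.05, 0.95)
    if (F > 0) {
      a <- p0 * (1 - F) / F
      b <- (1 - p0) * (1 - F) / F
      pCase <- stats::rbeta(n, a, b)
      pCtl <- stats::rbeta(n, a, b)
    } else {
      pCase <- p0
      pCtl <- p0
    }
    inSweep <- rep(FALSE, n)
    if (nrow(config$sweepRegions)) {
      for (i in seq_len(nrow(config$sweepRegions))) {
        r <- config$sweepRegions[i, ]
        inSweep <- inSweep | (sites$chrom == r$chrom &
                              sites$pos >= r$start & sites$pos <= r$end)
      }
      sh <- config$sweepShift
      up <- inSweep & pCase >= 0.5
      dn <- inSweep & pCase < 0.5
      pCase[up] <- pmin(1, pCase[up] + sh)
      pCase[dn] <- pmax(0, pCase[dn] - sh)
    }
    # planted highly differentiated sites: fixed difference by construction
    diffIdx <- integer(0)
    if (config$diffSiteCount > 0) {
      pool <- which(!inSweep)
      if (length(pool) < config$diffSiteCount)
        stop("not enough background sites to plant differentiated sites")
      diffIdx <- sort(sample(pool, config$diffSiteCount))
      pCase[diffIdx] <- 1
      pCtl[diffIdx] <- 0
    }
    nC <- config$nCase
    nK <- config$nControl
    gCase <- matrix(stats::rbinom(n * nC, 2, rep(pCase, nC)), nrow = n)
    gCtl <- matrix(stats::rbinom(n * nK, 2, rep(pCtl, nK)), nrow = n)
    geno <- cbind(gCase, gCtl)
    if (config$missingRate > 0) {
      geno[stats::runif(length(geno)) < config$missingRate] <- NA_integer_
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    altSnp <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    isIndel <- stats::runif(n) < config$indelRate
    alt <- ifelse(isIndel, paste0(ref, sample(bases, n, replace = TRUE)),
                  altSnp)
    sites$ref <- ref
    sites$alt <- alt
    sites$type <- ifelse(isIndel, "indel", "SNP")
    samples <- c(sprintf("CASE_%02d", seq_len(nC)),
                 sprintf("CTRL_%02d", seq_len(nK)))
    colnames(geno) <- samples
    panel <- data.frame(sample = samples,
                        population = rep(c("case", "control"), c(nC, nK)),
                        stringsAsFactors = FALSE)
    gm <- genotypeMatrix(sites, geno, panel)
    truth <- list(
      sweepWindowIds = .sweepWindows(config, window, step),
      diffSiteIds = sprintf("%s:%d", sites$chrom[diffIdx],
                            sites$pos[diffIdx]),
      pCase = pCase, pControl = pCtl, sweepSite = inSweep
    )
    list(genotypes = gm, truth = truth)
  })
}

# windows (0-based half-open, anchored at 0) fully inside a sweep region
.sweepWindows <- function(config, window, step) {
  out <- character(0)
  if (!nrow(config$sweepRegions)) return(out)
  for (i in seq_len(nrow(config$sweepRegions))) {
    r <- config$sweepRegions[i, ]
    s0 <- r$start - 1L  # 0-based region bounds [s0, e0)
    e0 <- r$end
    starts <- seq(0L, max(0L, e0 - 1L), by = step)
    keep <- starts >= s0 & (starts + window) <= e0
    if (any(keep))
      out <- c(out, sprintf("%s:%d-%d", r$chrom, starts[keep],
                            starts[keep] + window))
  }
  out
}
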