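#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity: `pi = (m/(m-1)) * 2*p*(1-p)` with
#' `m` called alleles and `p = altCount/m`, which equals the mean number of
#' pairwise differences among the `m` sampled alleles at the site.
#'
#' @param altCount alternate-allele count at the site (vectorized).
#' @param nAlleles number of called alleles `m`.
#' @return Per-site pi; `NA` where `m < 2` (such sites are excluded from
#'   window sums rather than raising an error).
#' @examples
#' sitePi(2, 4)   # 4 differing pairs of C(4,2)=6 -> 2/3
#' sitePi(0, 40)  # monomorphic -> 0
#' @export
sitePi <- function(altCount, nAlleles) {
  p <- altCount / nAlleles
  out <- (nAlleles / (nAlleles - 1)) * 2 * p * (1 - p)
  out[nAlleles < 2] <- NA_real_
  out
}

#' Per-site FST components
#'
#' Returns the per-site numerator and denominator of a two-population FST
#' estimator; windowed FST is the ratio of their sums ("ratio of sums").
#' The default is Hudson's estimator:
#' `N = (p1-p2)^2 - p1(1-p1)/(m1-1) - p2(1-p2)/(m2-1)`,
#' `D = p1(1-p2) + p2(1-p1)`.
#' `"wc84"` gives the Weir-Cockerham (1984) variance components for two
#' populations: numerator `a`, denominator `a + b + c`, computed from the
#' allele frequencies and observed heterozygote fractions.
#'
#' @param p1,p2 alternate-allele frequencies in the two populations.
#' @param m1,m2 called allele counts (must be >= 2; smaller values yield
#'   `NA` components, excluding the site).
#' @param h1,h2 observed heterozygote fractions (individuals), required for
#'   `"wc84"` only.
#' @param estimator `"hudson"` (default) or `"wc84"`.
#' @return list with vectors `numerator` and `denominator`. Per-site ratios
#'   may be negative; they are not clamped.
#' @examples
#' # fixed difference
#' s <- siteFst(1, 40, 0, 40)
#' s$numerator / s$denominator  # 1
#' @export
siteFst <- function(p1, m1, p2, m2, h1 = NULL, h2 = NULL,
                    estimator = c("hudson", "wc84")) {
  estimator <- match.arg(estimator)
  bad <- m1 < 2 | m2 < 2
  if (estimator == "hudson") {
    N <- (p1 - p2)^2 - p1 * (1 - p1) / (m1 - 1) - p2 * (1 - p2) / (m2 - 1)
    D <- p1 * (1 - p2) + p2 * (1 - p1)
  } else {
    if (is.null(h1) || is.null(h2))
      stop("wc84 requires observed heterozygote fractions h1, h2")
    n1 <- m1 / 2
    n2 <- m2 / 2
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    N <- a
    D <- a + b + cc
  }
  N[bad] <- NA_real_
  D[bad] <- NA_real_
  list(numerator = N, denominator = D)
}

# vectorized per-site stats for one population: alt counts, called alleles,
# frequency, het fraction, per-site pi
.popSiteStats <- function(geno) {
  called <- rowSums(!is.na(geno))
  alt <- rowSums(geno, na.rm = TRUE)
  m <- 2 * called
  p <- ifelse(m > 0, alt / m, NA_real_)
  het <- rowSums(geno == 1L, na.rm = TRUE)
  h <- ifelse(called > 0, het / called, NA_real_)
  list(alt = alt, m = m, p = p, h = h, pi = sitePi(alt, m))
}

#' Sliding-window FST, Pi and delta-Pi scan
#'
#' Scans the genome in `window`-bp windows stepped every `step` bp,
#' anchored at 0 per chromosome (0-based half-open; a site at 1-based
#' position P belongs to window `[start, start+window)` iff
#' `P - 1` lies in it). Per window: per-population nucleotide diversity
#' per bp (site-pi summed and divided by the window width), FST as a
#' ratio of summed per-site components, and
#' `delta_pi = pi_control - pi_case`. Sites with fewer than 2 called
#' alleles in a population are excluded from that population's sums.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param window,step window width and step in bp (defaults 40000/20000).
#' @param minSites windows with fewer used sites are dropped (default 10).
#' @param estimator FST estimator, see [siteFst()].
#' @param chromLengths optional named chromosome lengths; when supplied,
#'   terminal windows are truncated, their true width is used as the per-bp
#'   denominator, and truncated windows shorter than half a window are
#'   dropped. Without lengths all windows use the nominal width.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `median_site`,
#'   `n_sites`, `fst`, `pi_case`, `pi_control`, `delta_pi` and a window
#'   `id` (`"chrom:start-end"`).
#' @export
windowScan <- function(gm, window = 40000, step = 20000, minSites = 10,
                       estimator = c("hudson", "wc84"),
                       chromLengths = NULL) {
  estimator <- match.arg(estimator)
  sites <- gm@sites
  if (nrow(sites) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), median_site = integer(0),
                      n_sites = integer(0), fst = numeric(0),
                      pi_case = numeric(0), pi_control = numeric(0),
                      delta_pi = numeric(0), id = character(0)))
  ord <- order(sites$chrom, sites$pos)
  if (any(ord != seq_len(nrow(sites))))
    stop("GenotypeMatrix sites must be sorted by chromosome and position")
  caseIdx <- which(gm@panel$population == "case")
  ctlIdx <- which(gm@panel$population == "control")
  sc <- .popSiteStats(gm@geno[, caseIdx, drop = FALSE])
  sk <- .popSiteStats(gm@geno[, ctlIdx, drop = FALSE])
  fst <- siteFst(sc$p, sc$m, sk$p, sk$m, sc$h, sk$h, estimator = estimator)
  .aggregateWindows(sites, sc$pi, sk$pi, fst$numerator, fst$denominator,
                    window, step, minSites, chromLengths)
}

# shared window aggregation used by windowScan and recoveryRatio
.aggregateWindows <- function(sites, piCase, piCtl, fstN, fstD,
                              window, step, minSites, chromLengths,
                              index = NULL) {
  if (is.null(index)) index <- .buildWindowIndex(sites, window, step)
  si <- index$site
  key <- index$key
  # pi sums (NA site-pi excluded per population)
  pc <- piCase[si]
  pk <- piCtl[si]
  fn <- fstN[si]
  fd <- fstD[si]
  sumPiC <- rowsum(ifelse(is.na(pc), 0, pc), key)
  sumPiK <- rowsum(ifelse(is.na(pk), 0, pk), key)
  okF <- !is.na(fn) & !is.na(fd)
  sumN <- rowsum(ifelse(okF, fn, 0), key)
  sumD <- rowsum(ifelse(okF, fd, 0), key)
  nSites <- rowsum(rep(1L, length(si)), key)
  keys <- rownames(sumPiC)
  meta <- index$meta[keys, , drop = FALSE]
  width <- rep(as.numeric(window), length(keys))
  keep <- rep(TRUE, length(keys))
  if (!is.null(chromLengths)) {
    len <- chromLengths[meta$chrom]
    end <- pmin(meta$start + window, len)
    width <- end - meta$start
    keep <- width >= window / 2
  }
  out <- data.frame(
    chrom = meta$chrom,
    start = meta$start,
    end = meta$start + as.integer(window),
    median_site = meta$start + as.integer(window / 2),
    n_sites = as.integer(nSites[, 1]),
    fst = as.numeric(sumN[, 1] / sumD[, 1]),
    pi_case = as.numeric(sumPiC[, 1] / width),
    pi_control = as.numeric(sumPiK[, 1] / width),
    stringsAsFactors = FALSE
  )
  out$delta_pi <- out$pi_control - out$pi_case
  out$id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out <- out[keep & out$n_sites >= minSites, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.buildWindowIndex <- function(sites, window, step) {
  p0 <- sites$pos - 1
  wmax <- p0 %/% step
  wmin <- pmax(0, (p0 - window) %/% step + 1)
  nrep <- as.integer(wmax - wmin + 1)
  si <- rep.int(seq_len(nrow(sites)), nrep)
  off <- sequence(nrep) - 1L
  w <- rep.int(wmin, nrep) + off
  start <- as.integer(w * step)
  chrom <- sites$chrom[si]
  key <- paste0(chrom, ":", start)
  meta <- data.frame(chrom = chrom, start = start, stringsAsFactors = FALSE)
  meta <- meta[!duplicated(key), , drop = FALSE]
  rownames(meta) <- paste0(meta$chrom, ":", meta$start)
  list(site = si, key = key, meta = meta)
}

#' Top-quantile candidate windows
#'
#' Computes the nearest-rank upper `q` quantile separately for window FST
#' and delta-Pi over all retained windows (threshold = value at descending
#' rank `ceiling(q * n)`); a window enters a top set iff its value is
#' greater than or equal to the threshold (ties at the threshold are
#' included), and candidates are the intersection of the two top sets.
#'
#' @param windows output of [windowScan()].
#' @param q upper-tail fraction (default 0.01).
#' @return list of class `CandidateSet`: `candidates` (the candidate rows
#'   of `windows`), `fstThreshold`, `dpiThreshold`, `topFst`, `topDpi`
#'   (window id vectors), and `q`.
#' @export
selectCandidates <- function(windows, q = 0.01) {
  if (nrow(windows) == 0)
    return(structure(list(candidates = windows, fstThreshold = NA_real_,
                          dpiThreshold = NA_real_, topFst = character(0),
                          topDpi = character(0), q = q),
                     class = "CandidateSet"))
  stopifnot(q > 0, q <= 1)
  thr <- function(x) sort(x, decreasing = TRUE)[ceiling(q * length(x))]
  tF <- thr(windows$fst)
  tD <- thr(windows$delta_pi)
  topFst <- windows$id[windows$fst >= tF]
  topDpi <- windows$id[windows$delta_pi >= tD]
  cand <- windows[windows$id %in% intersect(topFst, topDpi), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(candidates = cand, fstThreshold = tF, dpiThreshold = tD,
                 topFst = topFst, topDpi = topDpi, q = q),
            class = "CandidateSet")
}

#' @export
print.CandidateSet <- function(x, ...) {
  cat("CandidateSet:", nrow(x$candidates), "candidate windows",
      sprintf("(top %.3g%% FST >= %.4g, delta-Pi >= %.4g)\n",
              100 * x$q, x$fstThreshold, x$dpiThreshold))
  if (!is.null(x$candidates$rr_fst))
    cat("  selected (RR criterion):", sum(x$candidates$selected), "\n")
  invisible(x)
}

#' Control-subsampling recovery ratio
#'
#' Re-validates candidate windows by repeatedly subsampling the control
#' panel: each replicate draws `subsample` controls without replacement
#' (the case set is unchanged), recomputes windowed FST and delta-Pi and
#' the two top-`q` sets, and records whether each candidate re-enters
#' them. `rr_fst` and `rr_dpi` are the fractions of replicates in which
#' the candidate is in the respective top set; `rr_joint` the fraction in
#' the intersection. With `rule = "each"` (default) a candidate is
#' `selected` iff `rr_fst >= rrMin` and `rr_dpi >= rrMin`; with
#' `rule = "joint"`, iff `rr_joint >= rrMin`.
#'
#' Replicate r uses a deterministic child seed derived from (`seed`, r),
#' so individual replicates are reproducible independently of execution
#' order.
#'
#' @param gm the full [GenotypeMatrix-class].
#' @param candidates a `CandidateSet` from [selectCandidates()].
#' @param nReplicates number of control subsamples (default 1000).
#' @param subsample controls drawn per replicate (default 20).
#' @param q top-set fraction, normally the one used for the candidates.
#' @param seed integer seed.
#' @param rrMin selection threshold on the recovery ratios (default 0.95).
#' @param rule `"each"` or `"joint"` (see above).
#' @inheritParams windowScan
#' @return the `CandidateSet` with columns `rr_fst`, `rr_dpi`, `rr_joint`
#'   and `selected` added to `$candidates`.
#' @export
recoveryRatio <- function(gm, candidates, nReplicates = 1000, subsample = 20,
                          q = 0.01, seed = 1, rrMin = 0.95,
                          rule = c("each", "joint"),
                          window = 40000, step = 20000, minSites = 10,
                          estimator = c("hudson", "wc84"),
                          chromLengths = NULL) {
  rule <- match.arg(rule)
  estimator <- match.arg(estimator)
  cand <- candidates$candidates
  caseIdx <- which(gm@panel$population == "case")
  ctlIdx <- which(gm@panel$population == "control")
  if (subsample > length(ctlIdx))
    stop("subsample (", subsample, ") exceeds control pool (",
         length(ctlIdx), ")")
  sc <- .popSiteStats(gm@geno[, caseIdx, drop = FALSE])
  gctl <- gm@geno[, ctlIdx, drop = FALSE]
  index <- .buildWindowIndex(gm@sites, window, step)
  nCand <- nrow(cand)
  hitF <- hitD <- hitJ <- integer(nCand)
  for (r in seq_len(nReplicates)) {
    pick <- withr::with_seed(childSeed(seed, r),
                             sample(ncol(gctl), subsample))
    sk <- .popSiteStats(gctl[, pick, drop = FALSE])
    fst <- siteFst(sc$p, sc$m, sk$p, sk$m, sc$h, sk$h, estimator = estimator)
    win <- .aggregateWindows(gm@sites, sc$pi, sk$pi, fst$numerator,
                             fst$denominator, window, step, minSites,
                             chromLengths, index = index)
    sel <- selectCandidates(win, q)
    hitF <- hitF + (cand$id %in% sel$topFst)
    hitD <- hitD + (cand$id %in% sel$topDpi)
    hitJ <- hitJ + (cand$id %in% sel$candidates$id)
  }
  cand$rr_fst <- hitF / nReplicates
  cand$rr_dpi <- hitD / nReplicates
  cand$rr_joint <- hitJ / nReplicates
  cand$selected <- if (rule == "each")
    cand$rr_fst >= rrMin & cand$rr_dpi >= rrMin
  else cand$rr_joint >= rrMin
  candidates$candidates <- cand
  candidates$nReplicates <- nReplicates
  candidates$subsample <- subsample
  candidates$rule <- rule
  candidates
}

#' Genotype-frequency highly differentiated sites
#'
#' Flags sites whose altered-allele ratio is sharply split between the
#' populations. A site is *eligible* iff it is called in at least
#' `minCaseCalled` cases and `minControlCalled` controls (the defaults
#' 16/51 encode "more than 15" and "more than 50" for a 20 vs 98 panel).
#' The altered-allele ratio is, per population, the alternate-allele
#' frequency among called alleles, `(het + 2*homAlt) / (2*called)`
#' (`ratio = "allele"`), or the fraction of called individuals carrying at
#' least one alternate allele (`ratio = "carrier"`). A site *passes* iff it
#' is eligible, its case ratio is strictly greater than `caseRatioGt` and
#' its control ratio strictly less than `controlRatioLt`. SNPs and indels
#' are treated identically and reported with their type.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param minCaseCalled,minControlCalled minimum called individuals.
#' @param caseRatioGt,controlRatioLt strict ratio bounds (defaults 0.8 and
#'   0.06).
#' @param ratio `"allele"` (default) or `"carrier"`.
#' @return `data.frame` with one row per site: `chrom`, `pos`, `type`,
#'   `case_called`, `control_called`, `case_ratio`, `control_ratio`,
#'   `eligible`, `pass`, `id`.
#' @export
differentiatedSites <- function(gm, minCaseCalled = 16, minControlCalled = 51,
                                caseRatioGt = 0.8, controlRatioLt = 0.06,
                                ratio = c("allele", "carrier")) {
  ratio <- match.arg(ratio)
  caseIdx <- which(gm@panel$population == "case")
  ctlIdx <- which(gm@panel$population == "control")
  gc <- gm@geno[, caseIdx, drop = FALSE]
  gk <- gm@geno[, ctlIdx, drop = FALSE]
  cc <- rowSums(!is.na(gc))
  ck <- rowSums(!is.na(gk))
  if (ratio == "allele") {
    rc <- rowSums(gc, na.rm = TRUE) / (2 * cc)
    rk <- rowSums(gk, na.rm = TRUE) / (2 * ck)
  } else {
    rc <- rowSums(gc >= 1L, na.rm = TRUE) / cc
    rk <- rowSums(gk >= 1L, na.rm = TRUE) / ck
  }
  eligible <- cc >= minCaseCalled & ck >= minControlCalled
  pass <- eligible & rc > caseRatioGt & rk < controlRatioLt
  data.frame(chrom = gm@sites$chrom, pos = gm@sites$pos,
             type = gm@sites$type,
             case_called = cc, control_called = ck,
             case_ratio = rc, control_ratio = rk,
             eligible = eligible, pass = pass,
             id = sprintf("%s:%d", gm@sites$chrom, gm@sites$pos),
             stringsAsFactors = FALSE)
}
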