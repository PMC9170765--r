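#' Configuration for the expression simulator
#'
#' Defaults emulate the embryonic tail study design: 9 case embryos (3 per
#' development day D7-D9, one case breed) versus 12 controls (2 control
#' breeds x 2 replicates x 3 days), sequenced over several lanes, with
#' planted differentially expressed genes and planted correlated modules.
#'
#' @param nCase,nControl sample counts (defaults 9 and 12).
#' @param days number of development-day levels (default 3; labelled D7..).
#' @param controlBreeds number of control breeds (default 2).
#' @param lanes number of sequencing lanes (default 3).
#' @param nGenes number of genes (default 2000).
#' @param nDe planted DE genes (default 100).
#' @param deLog2fc DE effect size in log2 units (default 2, i.e. 4-fold);
#'   signs alternate between planted genes.
#' @param moduleSizes integer vector of planted co-expression module sizes
#'   (default none).
#' @param moduleCor within-module latent-factor loading in (0, 1)
#'   (default 0.8).
#' @param dispersion negative-binomial dispersion (default 0.05).
#' @param covariateEffects named list of log2-scale effect sizes:
#'   `day` (slope per day code), `breed` and `lane` (sd of per-level
#'   offsets).
#' @param baselineMean,baselineSd log2-scale baseline distribution of gene
#'   means (defaults 5 and 1.5).
#' @param seed integer RNG seed.
#' @return validated list of class `ExprSimConfig`.
#' @export
exprSimConfig <- function(nCase = 9, nControl = 12, days = 3,
                          controlBreeds = 2, lanes = 3,
                          nGenes = 2000, nDe = 100, deLog2fc = 2,
                          moduleSizes = integer(0), moduleCor = 0.8,
                          dispersion = 0.05,
                          covariateEffects = list(day = 0.2, breed = 0.3,
                                                  lane = 0.1),
                          baselineMean = 5, baselineSd = 1.5, seed = 1) {
  stopifnot(nCase >= 2, nControl >= 2, days >= 1, controlBreeds >= 1,
            lanes >= 1, nGenes >= 1, nDe >= 0, deLog2fc >= 0,
            moduleCor > 0, moduleCor < 1)
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (nDe > nGenes) stop("nDe exceeds nGenes")
  if (sum(moduleSizes) > nGenes)
    stop("sum(moduleSizes) exceeds nGenes")
  structure(list(nCase = nCase, nControl = nControl, days = days,
                 controlBreeds = controlBreeds, lanes = lanes,
                 nGenes = nGenes, nDe = nDe, deLog2fc = deLog2fc,
                 moduleSizes = as.integer(moduleSizes),
                 moduleCor = moduleCor, dispersion = dispersion,
                 covariateEffects = covariateEffects,
                 baselineMean = baselineMean, baselineSd = baselineSd,
                 seed = as.integer(seed)),
            class = "ExprSimConfig")
}

#' Simulate a case/control expression experiment with planted truth
#'
#' Per-gene baseline log2 means are Normal(`baselineMean`, `baselineSd`).
#' Each sample's log2 mean adds: the group effect (`deLog2fc`, alternating
#' sign, for planted DE genes), a linear development-day effect (days coded
#' 1, 2, 3, ...), per-breed and per-lane offsets, a per-sample depth
#' offset, and for module genes `moduleCor * tau * f_m` where `f_m` is a
#' per-module standard-normal latent factor over samples (tau = 2 log2
#' units). Counts under the union-exon model are negative-binomial with
#' the configured dispersion; whole-gene counts add independent Poisson
#' intronic reads, so `countsWhole >= countsUnion` elementwise. Gene
#' length is LogUniform(200, 1e5) bp and GC Uniform(0.3, 0.7). FPKM is
#' computed from the union counts with column-sum library sizes.
#'
#' @param config an [exprSimConfig()] object.
#' @return list with
#'   \describe{
#'     \item{se}{a [SummarizedExperiment::SummarizedExperiment] with assays
#'       `countsUnion`, `countsWhole`, `fpkm`; `rowData` columns `length`,
#'       `gc`; `colData` columns `group`, `day`, `breed`, `lane`,
#'       `libSize`.}
#'     \item{truth}{list with `deGeneIds`, `deSign` (named +/-1),
#'       `moduleAssignment` (named gene -> `"M1"`,... or `"M0"`).}
#'   }
#' @export
simulateExpression <- function(config) {
  stopifnot(inherits(config, "ExprSimConfig"))
  withr::with_seed(config$seed, {
    nS <- config$nCase + config$nControl
    dayLabels <- paste0("D", 6 + seq_len(config$days))
    # design: cases one breed, cycled over days; controls cycled over
    # breed x day
    caseDay <- rep_len(seq_len(config$days), config$nCase)
    ctlBreed <- rep_len(seq_len(config$controlBreeds), config$nControl)
    ctlDay <- rep_len(rep(seq_len(config$days),
                          each = config$controlBreeds),
                      config$nControl)
    meta <- data.frame(
      sample = c(sprintf("CASE_%02d", seq_len(config$nCase)),
                 sprintf("CTRL_%02d", seq_len(config$nControl))),
      group = rep(c("case", "control"), c(config$nCase, config$nControl)),
      day = dayLabels[c(caseDay, ctlDay)],
      breed = c(rep("CaseBreed", config$nCase),
                paste0("CtrlBreed", ctlBreed)),
      lane = paste0("L", rep_len(seq_len(config$lanes), nS)),
      stringsAsFactors = FALSE
    )
    dayCode <- c(caseDay, ctlDay)
    nG <- config$nGenes
    genes <- sprintf("gene%04d", seq_len(nG))
    base <- stats::rnorm(nG, config$baselineMean, config$baselineSd)
    # planted DE genes, alternating sign
    deIdx <- if (config$nDe > 0) sort(sample.int(nG, config$nDe)) else integer(0)
    deSign <- rep_len(c(1, -1), length(deIdx))
    groupEff <- numeric(nG)
    groupEff[deIdx] <- deSign * config$deLog2fc
    # planted modules over genes not used sequentially: random disjoint sets
    modAssign <- rep("M0", nG)
    if (length(config$moduleSizes)) {
      pool <- sample.int(nG)
      off <- 0
      for (m in seq_along(config$moduleSizes)) {
        sz <- config$moduleSizes[m]
        modAssign[pool[(off + 1):(off + sz)]] <- paste0("M", m)
        off <- off + sz
      }
    }
    # covariate effects are per gene (each gene responds differently to
    # stage, breed and lane). Breed effects apply to the control subtypes
    # only, with the case breed at reference: a shared case-breed offset
    # is indistinguishable from a group effect under this confounded
    # design, so it belongs to the group-effect parameter, not here.
    eff <- config$covariateEffects
    depth <- stats::rnorm(nS, 0, 0.1)
    daySlope <- stats::rnorm(nG, 0, eff$day %||% 0)
    grp <- as.numeric(meta$group == "case")
    mu <- matrix(base, nG, nS) +
      outer(groupEff, grp) +
      outer(daySlope, dayCode) +
      matrix(depth, nG, nS, byrow = TRUE)
    ctlBreeds <- sort(unique(meta$breed[meta$group == "control"]))
    for (b in ctlBreeds[-1]) {
      idx <- which(meta$breed == b)
      mu[, idx] <- mu[, idx] + stats::rnorm(nG, 0, eff$breed %||% 0)
    }
    laneLevels <- sort(unique(meta$lane))
    for (l in laneLevels[-1]) {
      idx <- which(meta$lane == l)
      mu[, idx] <- mu[, idx] + stats::rnorm(nG, 0, eff$lane %||% 0)
    }
    # planted module genes are kept highly expressed (floor at baseline
    # mean + 1.5 log2 units): co-expression planted on genes dominated by
    # counting shot noise, or dropped by the expressed-gene filter when
    # the shared factor swings low, would leave a truth that does not
    # describe the emitted data. Real module hubs are well-expressed.
    modTau <- 2
    modFloor <- config$baselineMean + 1.5
    for (m in unique(modAssign[modAssign != "M0"])) {
      f <- stats::rnorm(nS)
      idx <- which(modAssign == m)
      lowBase <- base[idx] < modFloor
      if (any(lowBase)) {
        bump <- modFloor - base[idx][lowBase]
        mu[idx[lowBase], ] <- mu[idx[lowBase], ] + bump
      }
      mu[idx, ] <- mu[idx, ] +
        config$moduleCor * modTau * matrix(f, length(idx), nS, byrow = TRUE)
    }
    mean2 <- 2^mu
    countsUnion <- matrix(
      stats::rnbinom(nG * nS, mu = mean2, size = 1 / config$dispersion),
      nG, nS)
    countsWhole <- countsUnion +
      matrix(stats::rpois(nG * nS, lambda = 0.05 * mean2), nG, nS)
    dimnames(countsUnion) <- dimnames(countsWhole) <-
      list(genes, meta$sample)
    length <- round(exp(stats::runif(nG, log(200), log(1e5))))
    gc <- stats::runif(nG, 0.3, 0.7)
    # library size = whole-transcriptome mapped total: the simulated genes
    # stand for ~5% of the library, so per-sample totals track sequencing
    # depth, not the planted module/DE fluctuations of this gene subset
    libSize <- round(20 * sum(2^base) * 2^depth)
    fpkm <- computeFPKM(countsUnion, length, libSize)
    se <- makeExpressionSet(countsUnion, countsWhole,
                            data.frame(length = length, gc = gc,
                                       row.names = genes),
                            meta, fpkm = fpkm, libSize = libSize)
    names(modAssign) <- genes
    list(se = se,
         truth = list(deGeneIds = genes[deIdx],
                      deSign = stats::setNames(deSign, genes[deIdx]),
                      moduleAssignment = modAssign))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble an expression SummarizedExperiment
#'
#' Bundles the two HTSeq-style count models, FPKM, gene annotations and
#' sample metadata into one [SummarizedExperiment::SummarizedExperiment].
#'
#' @param countsUnion,countsWhole gene x sample nonnegative integer
#'   matrices (whole-gene counts must be >= union-exon counts).
#' @param geneMeta `data.frame` with columns `length` (bp, > 0) and `gc`
#'   (in [0, 1]), rownames = gene ids.
#' @param sampleMeta `data.frame` with columns `sample`, `group`
#'   (`"case"`/`"control"`), `day`, `breed`, `lane`.
#' @param fpkm optional precomputed FPKM; computed from `countsUnion` and
#'   `libSize` when omitted.
#' @param libSize per-sample mapped-fragment totals; defaults to the
#'   column sums of `countsUnion`.
#' @return a `SummarizedExperiment`.
#' @export
makeExpressionSet <- function(countsUnion, countsWhole, geneMeta,
                              sampleMeta, fpkm = NULL,
                              libSize = colSums(countsUnion)) {
  stopifnot(all(dim(countsUnion) == dim(countsWhole)),
            nrow(geneMeta) == nrow(countsUnion),
            nrow(sampleMeta) == ncol(countsUnion))
  if (any(countsWhole < countsUnion))
    stop("countsWhole must be >= countsUnion elementwise")
  if (any(geneMeta$length <= 0)) stop("gene lengths must be > 0")
  if (any(geneMeta$gc < 0 | geneMeta$gc > 1)) stop("gc must lie in [0, 1]")
  if (!all(sampleMeta$group %in% c("case", "control")))
    stop("sample group must be 'case' or 'control'")
  if (is.null(fpkm))
    fpkm <- computeFPKM(countsUnion, geneMeta$length, libSize)
  cd <- S4Vectors::DataFrame(sampleMeta, libSize = libSize,
                             row.names = sampleMeta$sample)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(countsUnion = countsUnion, countsWhole = countsWhole,
                  fpkm = fpkm),
    rowData = S4Vectors::DataFrame(geneMeta),
    colData = cd)
}
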