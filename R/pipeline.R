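#' Run the full case/control selection scan
#'
#' Windowed FST / Pi / delta-Pi scan, top-quantile candidate intersection,
#' control-subsampling recovery-ratio validation, and the
#' genotype-frequency differentiated-site filter, with all result tables
#' written as TSV. Identical inputs and seed give byte-identical outputs.
#'
#' @param gm a [GenotypeMatrix-class] (e.g. from [readVCF()] or
#'   [simulateGenotypes()]).
#' @param outDir output directory (created if needed); writes
#'   `windows.tsv` (chrom, start, end, median_site, n_sites, fst, pi_case,
#'   pi_control, delta_pi, id), `candidates.tsv` (candidate windows with
#'   rr_fst, rr_dpi, rr_joint, selected) and `diffsites.tsv`.
#' @param q top-set fraction (default 0.01).
#' @param nReplicates,subsample,seed,rrMin,rule recovery-ratio parameters,
#'   see [recoveryRatio()].
#' @inheritParams windowScan
#' @param diffSiteArgs list of overrides for [differentiatedSites()].
#' @return invisibly, list with `windows`, `candidates` (a `CandidateSet`)
#'   and `diffSites`.
#' @export
runSelectionScan <- function(gm, outDir, window = 40000, step = 20000,
                             minSites = 10,
                             estimator = c("hudson", "wc84"),
                             chromLengths = NULL, q = 0.01,
                             nReplicates = 1000, subsample = 20, seed = 1,
                             rrMin = 0.95, rule = c("each", "joint"),
                             diffSiteArgs = list()) {
  estimator <- match.arg(estimator)
  rule <- match.arg(rule)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  windows <- windowScan(gm, window, step, minSites, estimator, chromLengths)
  message(sprintf("window scan: %d windows [%.1fs]", nrow(windows),
                  proc.time()[["elapsed"]] - t0))
  cand <- selectCandidates(windows, q)
  t0 <- proc.time()[["elapsed"]]
  cand <- recoveryRatio(gm, cand, nReplicates = nReplicates,
                        subsample = subsample, q = q, seed = seed,
                        rrMin = rrMin, rule = rule, window = window,
                        step = step, minSites = minSites,
                        estimator = estimator, chromLengths = chromLengths)
  message(sprintf("recovery ratio: %d replicates [%.1fs]", nReplicates,
                  proc.time()[["elapsed"]] - t0))
  ds <- do.call(differentiatedSites, c(list(gm), diffSiteArgs))
  writeTSV(windows, file.path(outDir, "windows.tsv"))
  writeTSV(cand$candidates, file.path(outDir, "candidates.tsv"))
  writeTSV(ds, file.path(outDir, "diffsites.tsv"))
  invisible(list(windows = windows, candidates = cand, diffSites = ds))
}

#' Run the expression pipeline: filter, normalize, adjust, call DEGs
#'
#' Expressed-gene filtering, log2(FPKM + offset) normalization (optional
#' GC/length correction), covariate removal, the linear-model DEG test,
#' the Welch second method, fold changes, and multi-method intersection
#' with any external DEG lists. Writes `normalized.tsv`, `adjusted.tsv`,
#' `degs.tsv` and `intersection.tsv` under `outDir`.
#'
#' @param se `SummarizedExperiment` from [makeExpressionSet()] /
#'   [simulateExpression()].
#' @param outDir output directory.
#' @param externalDEGs named list of external DEG gene-id vectors (e.g.
#'   read from one-id-per-line files); may be empty.
#' @param gcCorrect,offset see [normalizeLog2()].
#' @param frac,minCount see [filterExpressed()].
#' @param fdrThreshold DEG threshold on BH q (default 0.05).
#' @return invisibly, list with `retained`, `normalized`, `adjusted`,
#'   `lm` (the DEG table), `welch`, `fc`, `intersection`.
#' @export
runExpressionPipeline <- function(se, outDir, externalDEGs = list(),
                                  gcCorrect = FALSE, offset = 1,
                                  frac = 0.8, minCount = 10,
                                  fdrThreshold = 0.05) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  meta <- as.data.frame(SummarizedExperiment::colData(se))
  keep <- filterExpressed(se, frac = frac, minCount = minCount)
  fpkm <- SummarizedExperiment::assay(se, "fpkm")[keep, , drop = FALSE]
  gmeta <- as.data.frame(SummarizedExperiment::rowData(se))[keep, ,
                                                            drop = FALSE]
  norm <- normalizeLog2(fpkm, gmeta, gcCorrect = gcCorrect, offset = offset)
  covs <- encodeCovariates(meta)
  adj <- adjustCovariates(norm, covs)
  lm <- lmDEG(norm, meta$group, covariates = covs,
              fdrThreshold = fdrThreshold)
  welch <- welchDEG(adj, meta$group, fdrThreshold = fdrThreshold)
  fc <- foldChange(fpkm, meta$group)
  sets <- c(list(lm = lm$gene[lm$deg], welch = welch$gene[welch$deg]),
            externalDEGs)
  inter <- intersectDEGs(sets, universe = rownames(se))
  writeTSV(data.frame(gene = rownames(norm), norm, check.names = FALSE),
           file.path(outDir, "normalized.tsv"))
  writeTSV(data.frame(gene = rownames(adj), adj, check.names = FALSE),
           file.path(outDir, "adjusted.tsv"))
  degTab <- merge(lm, fc[, c("gene", "fc", "higher")], by = "gene",
                  sort = TRUE)
  writeTSV(degTab, file.path(outDir, "degs.tsv"))
  interTab <- data.frame(
    set = c(names(inter$sizes), "final"),
    n = c(unname(inter$sizes), inter$nOverall))
  writeTSV(interTab, file.path(outDir, "intersection.tsv"))
  invisible(list(retained = keep, normalized = norm, adjusted = adj,
                 lm = lm, welch = welch, fc = fc, intersection = inter))
}

#' Run the co-expression network arm
#'
#' Builds the signed network on the adjusted matrix, detects and merges
#' modules, computes eigengenes, module-trait correlations and hub genes,
#' and writes `modules.tsv`, `MEs.tsv`, `trait_stats.tsv`, `hubs.tsv` and
#' `edges.tsv` under `outDir`.
#'
#' @param adjusted gene x sample covariate-adjusted log2 matrix.
#' @param trait binary trait per sample (case = 1, control = 0).
#' @param outDir output directory.
#' @param power soft power (default 12; `NULL` fits it by scale-free
#'   topology).
#' @param minSize,cutHeight see [detectModules()].
#' @param mergeHeight see [mergeModules()].
#' @param gsMin,kmeMin,topN,tomEdge see [hubSelection()].
#' @return invisibly, list with `network`, `modules`, `traitStats`,
#'   `hubs`.
#' @export
runCoexpression <- function(adjusted, trait, outDir, power = 12,
                            minSize = 30, cutHeight = 0.95,
                            mergeHeight = 0.25, gsMin = 0.2, kmeMin = 0.8,
                            topN = 50, tomEdge = 0.1) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  net <- buildCoexNetwork(adjusted, power = power)
  mods <- detectModules(net, minSize = minSize, cutHeight = cutHeight)
  mods <- mergeModules(adjusted, mods, mergeHeight = mergeHeight)
  MEs <- moduleEigengenes(mods)
  ts <- if (ncol(MEs)) moduleTrait(MEs, trait)
        else data.frame(module = character(0), r = numeric(0),
                        p = numeric(0), significant = logical(0))
  hubs <- hubSelection(adjusted, trait, mods, net, gsMin = gsMin,
                       kmeMin = kmeMin, topN = topN, tomEdge = tomEdge)
  writeTSV(data.frame(gene = names(moduleLabels(mods)),
                      module = unname(moduleLabels(mods))),
           file.path(outDir, "modules.tsv"))
  writeTSV(data.frame(sample = rownames(MEs), MEs, check.names = FALSE),
           file.path(outDir, "MEs.tsv"))
  writeTSV(ts, file.path(outDir, "trait_stats.tsv"))
  writeTSV(hubs$hubTable, file.path(outDir, "hubs.tsv"))
  writeTSV(hubs$edges, file.path(outDir, "edges.tsv"))
  invisible(list(network = net, modules = mods, traitStats = ts,
                 hubs = hubs))
}
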