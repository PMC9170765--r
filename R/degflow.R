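#' FPKM from counts
#'
#' `FPKM = counts * 1e9 / (length * libSize)`.
#'
#' @param counts gene x sample nonnegative matrix.
#' @param geneLength per-gene length in bp (> 0).
#' @param libSize per-sample mapped-fragment totals; defaults to the column
#'   sums of `counts`.
#' @return gene x sample FPKM matrix.
#' @examples
#' computeFPKM(matrix(100), 1000, 1e6)  # 100
#' @export
computeFPKM <- function(counts, geneLength, libSize = colSums(counts)) {
  stopifnot(all(geneLength > 0), length(geneLength) == nrow(counts),
            length(libSize) == ncol(counts))
  if (any(libSize <= 0)) {
    nm <- colnames(counts) %||% as.character(seq_len(ncol(counts)))
    stop("zero library size for sample(s): ",
         paste(nm[libSize <= 0], collapse = ", "))
  }
  out <- sweep(counts * 1e9 / geneLength, 2, libSize, "/")
  dimnames(out) <- dimnames(counts)
  out
}

#' Expressed-gene filter
#'
#' A sample *supports* a gene iff `countsUnion >= minCount` AND
#' `countsWhole >= minCount` AND `fpkm > 0` in that sample. A gene is
#' retained iff the supporting samples cover at least `frac` of the case
#' samples OR at least `frac` of the control samples (fractional
#' comparison, no rounding).
#'
#' @param se a `SummarizedExperiment` from [makeExpressionSet()] /
#'   [simulateExpression()].
#' @param frac required support fraction (default 0.8).
#' @param minCount count threshold applied to both models (default 10).
#' @return character vector of retained gene ids.
#' @export
filterExpressed <- function(se, frac = 0.8, minCount = 10) {
  cu <- SummarizedExperiment::assay(se, "countsUnion")
  cw <- SummarizedExperiment::assay(se, "countsWhole")
  fp <- SummarizedExperiment::assay(se, "fpkm")
  group <- SummarizedExperiment::colData(se)$group
  support <- cu >= minCount & cw >= minCount & fp > 0
  caseFrac <- rowMeans(support[, group == "case", drop = FALSE])
  ctlFrac <- rowMeans(support[, group == "control", drop = FALSE])
  rownames(se)[caseFrac >= frac | ctlFrac >= frac]
}

#' Log2 normalization with optional GC/length correction
#'
#' `value = log2(fpkm + offset)`. With `gcCorrect = TRUE`, a per-sample
#' robust regression (Huber M-estimation) of the values on GC fraction and
#' log gene length is fitted and its centred fit subtracted, removing
#' systematic GC/length trends while preserving each sample's mean
#' exactly. This is a transparent correction in the spirit of conditional
#' quantile normalization, not a re-implementation of it.
#'
#' @param fpkm gene x sample FPKM matrix.
#' @param geneMeta `data.frame` with `gc` and `length` (required when
#'   `gcCorrect = TRUE`).
#' @param gcCorrect remove GC/length trends? (default `FALSE`)
#' @param offset pseudo-FPKM added before the log (default 1; must be > 0
#'   unless all fpkm values are positive).
#' @return gene x sample log2 matrix with attributes `gcCorrected` and
#'   `covariatesRemoved` (provenance flags).
#' @export
normalizeLog2 <- function(fpkm, geneMeta = NULL, gcCorrect = FALSE,
                          offset = 1) {
  if (offset <= 0 && any(fpkm <= 0))
    stop("offset must be > 0 when fpkm contains zeros")
  val <- log2(fpkm + offset)
  if (gcCorrect) {
    if (is.null(geneMeta) || !all(c("gc", "length") %in% names(geneMeta)))
      stop("gcCorrect requires geneMeta with columns gc and length")
    x1 <- geneMeta$gc
    x2 <- log(geneMeta$length)
    for (j in seq_len(ncol(val))) {
      fit <- MASS::rlm(val[, j] ~ x1 + x2, maxit = 50)
      trend <- stats::fitted(fit)
      val[, j] <- val[, j] - (trend - mean(trend))
    }
  }
  attr(val, "gcCorrected") <- gcCorrect
  attr(val, "covariatesRemoved") <- character(0)
  val
}

#' Numeric covariate encoding for the expression designs
#'
#' Encodes the standard nuisance covariates: development day as the
#' numeric codes 1, 2, 3 (D7, D8, D9, ...); breed as control-subtype
#' indicator columns (the case breed and the first control breed are the
#' reference, so the encoding never absorbs the case/control contrast);
#' lane as one-hot columns with the first level as reference. Constant
#' columns are dropped.
#'
#' @param sampleMeta `data.frame` with columns `day`, `breed`, `lane` and
#'   `group`.
#' @return numeric sample x covariate matrix.
#' @export
encodeCovariates <- function(sampleMeta) {
  day <- as.integer(factor(sampleMeta$day, sort(unique(sampleMeta$day))))
  out <- cbind(day = day)
  ctlBreeds <- sort(unique(sampleMeta$breed[sampleMeta$group == "control"]))
  if (length(ctlBreeds) > 1) {
    for (b in ctlBreeds[-1])
      out <- cbind(out, as.numeric(sampleMeta$breed == b))
    colnames(out)[(ncol(out) - length(ctlBreeds) + 2):ncol(out)] <-
      paste0("breed", ctlBreeds[-1])
  }
  lanes <- sort(unique(sampleMeta$lane))
  if (length(lanes) > 1) {
    for (l in lanes[-1]) out <- cbind(out, as.numeric(sampleMeta$lane == l))
    colnames(out)[(ncol(out) - length(lanes) + 2):ncol(out)] <-
      paste0("lane", lanes[-1])
  }
  keep <- apply(out, 2, function(x) stats::sd(x) > 0)
  out[, keep, drop = FALSE]
}

.checkCollinear <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("collinear covariate(s): ", paste(drop, collapse = ", "))
  }
  invisible(q)
}

#' Remove covariate-driven variability from a normalized matrix
#'
#' Per gene, fits ordinary least squares of the log2 values on the
#' covariates (with intercept) and subtracts the covariate terms
#' `sum_c beta_c * x_c`, retaining intercept plus residual. The operation
#' is idempotent: residuals are orthogonal to the covariates. The group
#' label must not be among the covariates.
#'
#' @param mat gene x sample log2 matrix.
#' @param covariates numeric sample x covariate matrix (e.g. from
#'   [encodeCovariates()]).
#' @return adjusted gene x sample matrix (attribute `covariatesRemoved`
#'   lists the covariate names).
#' @examples
#' adjustCovariates(matrix(c(3, 5, 7), 1), cbind(day = 1:3))  # 1 1 1
#' @export
adjustCovariates <- function(mat, covariates) {
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == ncol(mat))
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("c", seq_len(ncol(covariates)))
  X <- cbind(`(Intercept)` = 1, covariates)
  q <- .checkCollinear(X)
  B <- qr.coef(q, t(mat))           # (1 + p) x genes
  adj <- mat - t(covariates %*% B[-1, , drop = FALSE])
  dimnames(adj) <- dimnames(mat)
  attr(adj, "gcCorrected") <- attr(mat, "gcCorrected")
  attr(adj, "covariatesRemoved") <- colnames(covariates)
  adj
}

#' Linear-model differential expression
#'
#' Per gene, ordinary least squares of the log2 values on
#' (intercept, case indicator, covariates); the p value is a two-sided
#' classical t-test on the group coefficient, and q values are
#' Benjamini-Hochberg over all tested genes. The matrix fit goes through
#' \pkg{limma}'s `lmFit` with ordinary (not moderated) statistics.
#'
#' @param mat gene x sample log2 matrix.
#' @param group character/factor of `"case"`/`"control"` per sample.
#' @param covariates optional numeric sample x covariate matrix.
#' @param fdrThreshold DEG call threshold on q (default 0.05).
#' @return `data.frame` per gene: `gene`, `log2fc` (group coefficient,
#'   case minus control), `t`, `p`, `q`, `deg`.
#' @export
lmDEG <- function(mat, group, covariates = NULL, fdrThreshold = 0.05) {
  grp <- as.numeric(group == "case")
  if (length(unique(grp)) < 2 || min(table(grp)) < 2)
    stop("need >= 2 samples in each group")
  X <- cbind(`(Intercept)` = 1, case = grp)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (nrow(X) - ncol(X) < 1) stop("residual degrees of freedom < 1")
  .checkCollinear(X)
  fit <- limma::lmFit(mat, design = X)
  tstat <- fit$coefficients[, "case"] /
    (fit$stdev.unscaled[, "case"] * fit$sigma)
  df <- fit$df.residual
  p <- 2 * stats::pt(-abs(tstat), df)
  p[fit$sigma == 0 & fit$coefficients[, "case"] == 0] <- 1
  q <- bhFDR(p)
  data.frame(gene = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             log2fc = unname(fit$coefficients[, "case"]),
             t = unname(tstat), p = unname(p), q = unname(q),
             deg = unname(q < fdrThreshold),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q values
#'
#' Standard step-up FDR adjustment,
#' `q_i = min over p_(j) >= p_(i) of min(1, m * p_(j) / j)`.
#'
#' @param p vector of p values in [0, 1].
#' @return q values in the input order.
#' @export
bhFDR <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Group fold change on the FPKM scale
#'
#' `FC = (mean fpkm of the higher group + pseudo) /
#' (mean fpkm of the lower group + pseudo)`, reported with the higher
#' group's label; the pseudo-count guards against near-zero denominators
#' from almost undetectable expression.
#'
#' @param fpkm gene x sample FPKM matrix.
#' @param group `"case"`/`"control"` per sample.
#' @param pseudo pseudo-count (default 0.01).
#' @return `data.frame`: `gene`, `mean_case`, `mean_control`, `fc`,
#'   `higher` (`"case"`, `"control"` or `"equal"`).
#' @export
foldChange <- function(fpkm, group, pseudo = 0.01) {
  mc <- rowMeans(fpkm[, group == "case", drop = FALSE])
  mk <- rowMeans(fpkm[, group == "control", drop = FALSE])
  hi <- pmax(mc, mk)
  lo <- pmin(mc, mk)
  data.frame(
    gene = rownames(fpkm) %||% as.character(seq_len(nrow(fpkm))),
    mean_case = mc, mean_control = mk,
    fc = (hi + pseudo) / (lo + pseudo),
    higher = ifelse(mc > mk, "case", ifelse(mk > mc, "control", "equal")),
    stringsAsFactors = FALSE
  )
}

#' Intersect DEG calls from several methods
#'
#' Final DEGs are the genes present in every set; per-set sizes and all
#' pairwise and overall overlap counts (the Venn numbers) are reported.
#' Ids absent from `universe` (when given) are excluded with a warning.
#'
#' @param sets named list (>= 2) of gene-id character vectors.
#' @param universe optional character vector of known gene ids.
#' @return list: `final` (intersection), `sizes`, `pairwise`
#'   (`data.frame` of pairwise overlap counts), `nOverall`, `nExcluded`.
#' @export
intersectDEGs <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  nExcluded <- 0L
  if (!is.null(universe)) {
    for (nm in names(sets)) {
      unknown <- setdiff(sets[[nm]], universe)
      if (length(unknown)) {
        warning(length(unknown), " unknown gene id(s) in set '", nm,
                "' excluded")
        nExcluded <- nExcluded + length(unknown)
        sets[[nm]] <- intersect(sets[[nm]], universe)
      }
    }
  }
  nm <- names(sets)
  pairs <- utils::combn(nm, 2)
  pairwise <- data.frame(
    set1 = pairs[1, ], set2 = pairs[2, ],
    overlap = apply(pairs, 2, function(p)
      length(intersect(sets[[p[1]]], sets[[p[2]]]))),
    stringsAsFactors = FALSE
  )
  final <- sort(Reduce(intersect, sets))
  list(final = final,
       sizes = vapply(sets, length, integer(1)),
       pairwise = pairwise,
       nOverall = length(final),
       nExcluded = nExcluded)
}

#' Welch t-test DEG method
#'
#' Per-gene Welch two-sample t-test on the normalized values with BH
#' adjustment. Provided as a second, model-free DEG caller to exercise
#' multi-method intersection; it is not a count-model method.
#'
#' @inheritParams lmDEG
#' @return `data.frame`: `gene`, `t`, `df`, `p`, `q`, `deg`.
#' @export
welchDEG <- function(mat, group, fdrThreshold = 0.05) {
  a <- mat[, group == "case", drop = FALSE]
  b <- mat[, group == "control", drop = FALSE]
  n1 <- ncol(a)
  n2 <- ncol(b)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- rowMeans(a)
  m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  sse <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(sse)
  df <- sse^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[sse == 0 & m1 == m2] <- 1
  q <- bhFDR(p)
  data.frame(gene = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             t = unname(tt), df = unname(df), p = unname(p), q = unname(q),
             deg = unname(q < fdrThreshold), stringsAsFactors = FALSE)
}
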