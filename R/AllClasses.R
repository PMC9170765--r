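#' @import methods
NULL

#' Biallelic genotype matrix with sample panel
#'
#' Container for a case/control resequencing panel: an ordered table of
#' biallelic variant sites, a site-by-individual matrix of diploid genotype
#' codes, and the panel assigning each individual to the case or control
#' population.
#'
#' Genotype codes follow the usual 0/1/2 dosage convention: 0 = homozygous
#' reference ("00"), 1 = heterozygous ("01"), 2 = homozygous alternate
#' ("11"), `NA` = missing. Exactly one alternate allele per site;
#' multiallelic records must be split or dropped upstream.
#'
#' @slot sites `data.frame` with columns `chrom`, `pos` (1-based, strictly
#'   increasing within chromosome), `ref`, `alt`, `type` (`"SNP"` or
#'   `"indel"`).
#' @slot geno integer matrix, sites x individuals, entries in {0, 1, 2, NA};
#'   column names are sample ids.
#' @slot panel `data.frame` with columns `sample`, `population`
#'   (`"case"`/`"control"`) and optionally `subgroup`; one row per genotype
#'   column, same order.
#'
#' @seealso [genotypeMatrix()], [simulateGenotypes()], [readVCF()],
#'   [windowScan()]
#' @export
setClass("GenotypeMatrix",
  representation(sites = "data.frame", geno = "matrix", panel = "data.frame")
)

setValidity("GenotypeMatrix", function(object) {
  msgs <- character(0)
  s <- object@sites
  g <- object@geno
  p <- object@panel
  need <- c("chrom", "pos", "ref", "alt", "type")
  if (!all(need %in% names(s)))
    msgs <- c(msgs, paste0("sites must have columns: ",
                           paste(need, collapse = ", ")))
  if (nrow(s) != nrow(g))
    msgs <- c(msgs, "nrow(sites) must equal nrow(geno)")
  if (ncol(g) != nrow(p))
    msgs <- c(msgs, "ncol(geno) must equal nrow(panel)")
  if (!all(c("sample", "population") %in% names(p)))
    msgs <- c(msgs, "panel must have columns sample, population")
  else {
    if (!all(p$population %in% c("case", "control")))
      msgs <- c(msgs, "panel population must be 'case' or 'control'")
    if (!is.null(colnames(g)) && !identical(colnames(g), as.character(p$sample)))
      msgs <- c(msgs, "colnames(geno) must match panel$sample in order")
  }
  if (nrow(s) > 0 && all(need %in% names(s))) {
    byc <- split(s$pos, s$chrom)
    if (any(vapply(byc, function(x) any(diff(x) <= 0), logical(1))))
      msgs <- c(msgs, "positions must be strictly increasing within chromosome")
    if (!all(s$type %in% c("SNP", "indel")))
      msgs <- c(msgs, "site type must be 'SNP' or 'indel'")
  }
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% 0:2))
    msgs <- c(msgs, "genotype codes must be 0, 1, 2 or NA")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param sites site table (`chrom`, `pos`, `ref`, `alt`, `type`).
#' @param geno sites x individuals matrix of codes {0,1,2,NA}.
#' @param panel sample panel (`sample`, `population`, optional `subgroup`).
#' @return A [GenotypeMatrix-class] object.
#' @export
genotypeMatrix <- function(sites, geno, panel) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  rownames(geno) <- NULL
  if (is.null(colnames(geno))) colnames(geno) <- as.character(panel$sample)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  panel <- as.data.frame(panel, stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  rownames(panel) <- NULL
  new("GenotypeMatrix", sites = sites, geno = geno, panel = panel)
}

#' @describeIn GenotypeMatrix-class number of sites and individuals
#' @param x,object a `GenotypeMatrix`
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@geno))

setMethod("show", "GenotypeMatrix", function(object) {
  n <- table(factor(object@panel$population, c("case", "control")))
  cat("GenotypeMatrix:", nrow(object@geno), "sites x",
      ncol(object@geno), "individuals\n")
  cat("  populations:", n[["case"]], "case /", n[["control"]], "control\n")
  cat("  chromosomes:", length(unique(object@sites$chrom)),
      "| SNP:", sum(object@sites$type == "SNP"),
      "indel:", sum(object@sites$type == "indel"), "\n")
  miss <- mean(is.na(object@geno))
  cat(sprintf("  missingness: %.3f\n", miss))
})

#' Accessors for GenotypeMatrix
#'
#' `genotypeCalls()` returns the site x individual code matrix,
#' `variantSites()` the site table, `samplePanel()` the panel.
#'
#' @param x a [GenotypeMatrix-class]
#' @return matrix or data.frame as described.
#' @export
genotypeCalls <- function(x) x@geno

#' @rdname genotypeCalls
#' @export
variantSites <- function(x) x@sites

#' @rdname genotypeCalls
#' @export
samplePanel <- function(x) x@panel

#' Signed weighted co-expression network
#'
#' Holds the signed adjacency `a_ij = ((1 + cor_ij)/2)^beta` (diagonal 1),
#' the topological overlap matrix, and whole-network connectivity
#' `k_i = sum_{j != i} a_ij`.
#'
#' @slot genes character vector of gene ids (row/col names of the matrices).
#' @slot beta soft-thresholding power used.
#' @slot adjacency gene x gene signed adjacency, entries in [0, 1].
#' @slot tom gene x gene topological overlap, entries in [0, 1], diagonal 1.
#' @slot connectivity per-gene connectivity (adjacency row sums minus the
#'   diagonal).
#' @slot fitIndices `data.frame` of per-power scale-free fit statistics
#'   (empty when the power was forced).
#' @seealso [buildCoexNetwork()], [topologicalOverlap()], [detectModules()]
#' @export
setClass("CoexNetwork",
  representation(genes = "character", beta = "numeric", adjacency = "matrix",
                 tom = "matrix", connectivity = "numeric",
                 fitIndices = "data.frame")
)

setValidity("CoexNetwork", function(object) {
  A <- object@adjacency
  T <- object@tom
  n <- length(object@genes)
  msgs <- character(0)
  if (!all(dim(A) == n) || !all(dim(T) == n))
    msgs <- c(msgs, "adjacency and tom must be n x n for n genes")
  else {
    if (max(abs(A - t(A))) > 1e-8) msgs <- c(msgs, "adjacency must be symmetric")
    if (min(A) < -1e-10 || max(A) > 1 + 1e-10)
      msgs <- c(msgs, "adjacency entries must lie in [0, 1]")
    if (min(T) < -1e-10 || max(T) > 1 + 1e-10)
      msgs <- c(msgs, "TOM entries must lie in [0, 1]")
  }
  if (length(object@connectivity) != n)
    msgs <- c(msgs, "connectivity must have one entry per gene")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CoexNetwork", function(object) {
  cat("CoexNetwork:", length(object@genes), "genes, signed, beta =",
      object@beta, "\n")
  k <- object@connectivity
  cat(sprintf("  connectivity: mean %.3f, max %.3f\n", mean(k), max(k)))
})

#' @rdname adjacencyMatrix
#' @export
tomMatrix <- function(x) x@tom

#' Accessors for CoexNetwork
#'
#' @param x a [CoexNetwork-class]
#' @return `adjacencyMatrix()`/`tomMatrix()` return gene x gene matrices;
#'   `networkConnectivity()` a named numeric vector; `softPower()` the beta
#'   used.
#' @export
adjacencyMatrix <- function(x) x@adjacency

#' @rdname adjacencyMatrix
#' @export
networkConnectivity <- function(x) x@connectivity

#' @rdname adjacencyMatrix
#' @export
softPower <- function(x) x@beta

#' Module assignment with eigengenes
#'
#' Gene-to-module labels (`"M0"` holds genes not assigned to any module),
#' sample x module eigengene matrix for the non-M0 modules, and the merge
#' history when modules have been merged.
#'
#' @slot labels named character vector, gene -> module label (`"M0"`,
#'   `"M1"`, ...; `"M1"` is the largest).
#' @slot eigengenes sample x module matrix of module eigengenes (unit-norm
#'   first principal components); may have zero columns before eigengene
#'   computation.
#' @slot mergeHistory `data.frame` recording each merge (`from`, `into`,
#'   `cor`).
#' @seealso [detectModules()], [mergeModules()], [moduleTrait()]
#' @export
setClass("ModuleSet",
  representation(labels = "character", eigengenes = "matrix",
                 mergeHistory = "data.frame")
)

setValidity("ModuleSet", function(object) {
  msgs <- character(0)
  if (is.null(names(object@labels)))
    msgs <- c(msgs, "labels must be named by gene id")
  if (!all(grepl("^M[0-9]+$", object@labels)))
    msgs <- c(msgs, "module labels must look like M0, M1, ...")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ModuleSet", function(object) {
  tab <- table(object@labels)
  mods <- setdiff(names(tab), "M0")
  cat("ModuleSet:", length(mods), "modules over", length(object@labels),
      "genes (M0:", if ("M0" %in% names(tab)) tab[["M0"]] else 0, "genes)\n")
  if (length(mods)) {
    mods <- mods[order(as.integer(sub("M", "", mods)))]
    cat("  sizes:", paste0(mods, "=", tab[mods], collapse = " "), "\n")
  }
  if (nrow(object@mergeHistory))
    cat("  merges:", nrow(object@mergeHistory), "\n")
})

#' Accessors for ModuleSet
#'
#' @param x a [ModuleSet-class]
#' @return `moduleLabels()` the named gene -> module vector;
#'   `moduleEigengenes()` the sample x module eigengene matrix.
#' @export
moduleLabels <- function(x) x@labels

#' @rdname moduleLabels
#' @export
moduleEigengenes <- function(x) x@eigengenes
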