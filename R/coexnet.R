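#' Signed adjacency from a correlation matrix
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta`, the signed soft-thresholding
#' transform; anticorrelated genes get adjacency near 0, perfectly
#' correlated genes 1. The diagonal is set to 1.
#'
#' @param corMat symmetric gene x gene correlation matrix, entries in
#'   [-1, 1] (tolerance 1e-8).
#' @param beta soft-thresholding power (default 12).
#' @return gene x gene adjacency, entries in [0, 1].
#' @examples
#' signedAdjacency(matrix(c(1, 0, 0, 1), 2), beta = 12)[1, 2]  # 0.5^12
#' @export
signedAdjacency <- function(corMat, beta = 12) {
  if (max(abs(corMat - t(corMat))) > 1e-8)
    stop("correlation matrix must be symmetric")
  if (max(abs(corMat)) > 1 + 1e-8)
    stop("correlation entries must lie in [-1, 1]")
  corMat <- pmin(pmax(corMat, -1), 1)
  A <- ((1 + corMat) / 2)^beta
  diag(A) <- 1
  A
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_{u != i,j} a_iu * a_uj + a_ij) /
#' (min(k_i, k_j) + 1 - a_ij)` with `k_i = sum_{j != i} a_ij`, and
#' `TOM_ii = 1`. High overlap means the two genes share network
#' neighborhoods as well as a direct connection.
#'
#' @param A adjacency from [signedAdjacency()] (symmetric, in [0, 1],
#'   diagonal 1).
#' @return symmetric TOM, entries in [0, 1], diagonal 1.
#' @export
topologicalOverlap <- function(A) {
  stopifnot(nrow(A) == ncol(A))
  k <- rowSums(A) - diag(A)
  AA <- A %*% A
  # remove the u = i and u = j terms (diag(A) = 1 assumed)
  L <- AA - A * (matrix(diag(A), nrow(A), ncol(A)) +
                 matrix(diag(A), nrow(A), ncol(A), byrow = TRUE))
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Scale-free topology fit over candidate soft powers
#'
#' For each power, builds the signed adjacency, computes connectivity k,
#' bins log10(k) into `nBins` equal-width bins (empty bins dropped), and
#' regresses log10(bin frequency) on log10(mean bin k). The chosen power
#' is the first whose fit R-squared exceeds `rsqCut`; when none does, the
#' power with the largest R-squared is chosen with a warning. Degenerate
#' connectivity (all k equal) yields R-squared 0 with a warning.
#'
#' @param expr gene x sample expression matrix (>= 10 genes).
#' @param powers candidate powers (default 1:20).
#' @param rsqCut fit threshold (default 0.8).
#' @param nBins connectivity histogram bins (default 10).
#' @return list: `power` (chosen), `fitIndices` (`data.frame` with
#'   `power`, `rsq`, `slope`, `meanK`).
#' @export
softPowerFit <- function(expr, powers = 1:20, rsqCut = 0.8, nBins = 10) {
  stopifnot(nrow(expr) >= 10)
  corMat <- stats::cor(t(expr))
  fits <- lapply(powers, function(b) {
    A <- signedAdjacency(corMat, beta = b)
    k <- rowSums(A) - 1
    c(rsq = .scaleFreeRsq(k, nBins), slope = .scaleFreeSlope(k, nBins),
      meanK = mean(k))
  })
  fi <- data.frame(power = powers, do.call(rbind, fits))
  chosen <- powers[which(fi$rsq > rsqCut)[1]]
  if (is.na(chosen)) {
    chosen <- powers[which.max(fi$rsq)]
    warning("no power reached scale-free R^2 > ", rsqCut,
            "; using argmax power ", chosen)
  }
  list(power = chosen, fitIndices = fi)
}

.scaleFreeBins <- function(k, nBins) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) return(NULL)
  lk <- log10(k)
  br <- seq(min(lk), max(lk), length.out = nBins + 1)
  br[1] <- br[1] - 1e-9
  bin <- cut(lk, br)
  tab <- table(bin)
  keep <- tab > 0
  if (sum(keep) < 3) return(NULL)
  meanK <- tapply(k, bin, mean)[keep]
  freq <- as.numeric(tab[keep]) / length(k)
  data.frame(x = log10(meanK), y = log10(freq))
}

.scaleFreeRsq <- function(k, nBins) {
  d <- .scaleFreeBins(k, nBins)
  if (is.null(d)) {
    warning("degenerate connectivity distribution; scale-free R^2 set to 0")
    return(0)
  }
  summary(stats::lm(y ~ x, data = d))$r.squared
}

.scaleFreeSlope <- function(k, nBins) {
  d <- .scaleFreeBins(k, nBins)
  if (is.null(d)) return(NA_real_)
  unname(stats::coef(stats::lm(y ~ x, data = d))[2])
}

#' Build a signed co-expression network
#'
#' Pearson correlation across samples, signed adjacency at the given (or
#' scale-free-fitted) power, topological overlap, and connectivity,
#' bundled as a [CoexNetwork-class].
#'
#' @param expr gene x sample expression matrix (rownames = gene ids).
#' @param power soft power; `NULL` selects it via [softPowerFit()].
#' @param powers candidate powers when `power` is `NULL`.
#' @return a [CoexNetwork-class].
#' @export
buildCoexNetwork <- function(expr, power = 12, powers = 1:20) {
  stopifnot(!is.null(rownames(expr)))
  fi <- data.frame()
  if (is.null(power)) {
    sp <- softPowerFit(expr, powers)
    power <- sp$power
    fi <- sp$fitIndices
  }
  corMat <- stats::cor(t(expr))
  A <- signedAdjacency(corMat, beta = power)
  tom <- topologicalOverlap(A)
  new("CoexNetwork", genes = rownames(expr), beta = as.numeric(power),
      adjacency = A, tom = tom, connectivity = rowSums(A) - 1,
      fitIndices = fi)
}

#' Detect modules by clustering the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut statically at
#' `cutHeight`. Clusters with at least `minSize` genes become modules
#' `M1`, `M2`, ... ordered by decreasing size; all remaining genes fall in
#' `M0`.
#'
#' @param network a [CoexNetwork-class] (or a TOM matrix).
#' @param minSize minimum module size (default 30).
#' @param cutHeight static dissimilarity cut (default 0.95).
#' @return a [ModuleSet-class] (eigengenes not yet computed).
#' @export
detectModules <- function(network, minSize = 30, cutHeight = 0.95) {
  tom <- if (is(network, "CoexNetwork")) network@tom else network
  genes <- rownames(tom) %||% as.character(seq_len(nrow(tom)))
  if (nrow(tom) < 2) {
    labels <- stats::setNames(rep("M0", nrow(tom)), genes)
    return(new("ModuleSet", labels = labels,
               eigengenes = matrix(0, 0, 0), mergeHistory = .emptyMerge()))
  }
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(h, h = cutHeight)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= minSize]
  # order by decreasing size, ties by first occurrence
  big <- big[order(-sizes[big], as.integer(big))]
  labels <- stats::setNames(rep("M0", length(cl)), genes)
  for (i in seq_along(big)) labels[cl == as.integer(big[i])] <- paste0("M", i)
  new("ModuleSet", labels = labels, eigengenes = matrix(0, 0, 0),
      mergeHistory = .emptyMerge())
}

.emptyMerge <- function() {
  data.frame(from = character(0), into = character(0), cor = numeric(0),
             stringsAsFactors = FALSE)
}

#' Module eigengene
#'
#' First principal component of the module's standardized gene x sample
#' submatrix, scaled to unit norm and sign-oriented so that it correlates
#' nonnegatively with the module's mean standardized expression. A
#' single-gene module yields that gene's standardized profile (unit
#' norm).
#'
#' @param expr gene x sample expression matrix.
#' @param genes gene ids of the module members.
#' @return numeric eigengene, one value per sample.
#' @export
moduleEigengene <- function(expr, genes) {
  stopifnot(length(genes) >= 1)
  X <- expr[genes, , drop = FALSE]
  sds <- apply(X, 1, stats::sd)
  if (all(sds == 0)) stop("all module genes have zero variance")
  X <- X[sds > 0, , drop = FALSE]
  Z <- t(scale(t(X)))          # standardize each gene across samples
  sv <- svd(t(Z), nu = 1, nv = 0)
  me <- sv$u[, 1]
  s <- stats::cor(me, colMeans(Z))
  if (!is.na(s) && s < 0) me <- -me
  stats::setNames(me, colnames(expr))
}

# eigengene matrix (samples x modules) for all non-M0 modules
.allEigengenes <- function(expr, labels) {
  mods <- setdiff(unique(labels), "M0")
  mods <- mods[order(as.integer(sub("M", "", mods)))]
  if (!length(mods))
    return(matrix(0, ncol(expr), 0, dimnames = list(colnames(expr), NULL)))
  me <- vapply(mods, function(m)
    moduleEigengene(expr, names(labels)[labels == m]),
    numeric(ncol(expr)))
  me <- matrix(me, ncol = length(mods),
               dimnames = list(colnames(expr), mods))
  me
}

#' Compute eigengenes for a ModuleSet
#'
#' @param expr gene x sample matrix covering the ModuleSet's genes.
#' @param modules a [ModuleSet-class].
#' @return the ModuleSet with its sample x module eigengene matrix filled.
#' @export
computeEigengenes <- function(expr, modules) {
  modules@eigengenes <- .allEigengenes(expr, modules@labels)
  modules
}

#' Merge highly co-expressed modules
#'
#' Iteratively merges the pair of modules whose eigengenes are most
#' correlated while that correlation exceeds `1 - mergeHeight` (default:
#' correlation > 0.75). Eigengenes are recomputed after every merge; ties
#' are broken toward the smaller module indices. After merging, modules
#' are relabelled `M1`, `M2`, ... by decreasing size.
#'
#' After merging, genes whose module membership `|kME|` falls below
#' `minKME` are moved to `M0` (the guard a dynamic tree cut's PAM stage
#' provides against weakly attached genes; 0.5 sits well above the
#' chance-correlation level of small-n designs), and modules dropping
#' below `minSize` dissolve into `M0`.
#'
#' @param expr gene x sample expression matrix.
#' @param modules a [ModuleSet-class].
#' @param mergeHeight eigengene-dissimilarity cut (default 0.25).
#' @param minKME membership pruning threshold (default 0.5; 0 disables).
#' @param minSize modules smaller than this after pruning dissolve into
#'   `M0` (default 30).
#' @return merged [ModuleSet-class] with eigengenes and merge history.
#' @export
mergeModules <- function(expr, modules, mergeHeight = 0.25, minKME = 0.5,
                         minSize = 30) {
  labels <- modules@labels
  hist <- .emptyMerge()
  thr <- 1 - mergeHeight
  repeat {
    mods <- setdiff(unique(labels), "M0")
    if (length(mods) < 2) break
    me <- .allEigengenes(expr, labels)
    C <- stats::cor(me)
    diag(C) <- -Inf
    best <- -Inf
    pick <- NULL
    ord <- colnames(C)[order(as.integer(sub("M", "", colnames(C))))]
    for (i in seq_along(ord)[-length(ord)]) {
      for (j in (i + 1):length(ord)) {
        v <- C[ord[i], ord[j]]
        if (v > best + 1e-12) {
          best <- v
          pick <- c(ord[i], ord[j])
        }
      }
    }
    if (best <= thr) break
    labels[labels == pick[2]] <- pick[1]
    hist <- rbind(hist, data.frame(from = pick[2], into = pick[1],
                                   cor = best, stringsAsFactors = FALSE))
  }
  # prune weakly attached members, dissolve undersized modules
  if (minKME > 0) {
    for (m in setdiff(unique(labels), "M0")) {
      members <- names(labels)[labels == m]
      me <- moduleEigengene(expr, members)
      kme <- as.numeric(stats::cor(t(expr[members, , drop = FALSE]), me))
      labels[members[abs(kme) < minKME]] <- "M0"
    }
  }
  sz <- table(labels)
  for (m in setdiff(names(sz), "M0"))
    if (sz[[m]] < minSize) labels[labels == m] <- "M0"
  # relabel by decreasing size
  mods <- setdiff(unique(labels), "M0")
  if (length(mods)) {
    sz <- table(labels)[mods]
    mods <- mods[order(-sz, as.integer(sub("M", "", mods)))]
    map <- stats::setNames(paste0("M", seq_along(mods)), mods)
    labels[labels != "M0"] <- map[labels[labels != "M0"]]
  }
  out <- new("ModuleSet", labels = labels, eigengenes = matrix(0, 0, 0),
             mergeHistory = hist)
  computeEigengenes(expr, out)
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with a binary trait
#' (case = 1, control = 0); p values from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' two-sided.
#'
#' @param MEs sample x module eigengene matrix.
#' @param trait numeric/binary vector per sample (non-constant, n >= 3).
#' @param alpha significance threshold on p (default 0.05).
#' @return `data.frame`: `module`, `r`, `p`, `significant`.
#' @export
moduleTrait <- function(MEs, trait, alpha = 0.05) {
  n <- nrow(MEs)
  if (n < 3) stop("need at least 3 samples")
  if (stats::sd(trait) == 0) stop("trait is constant")
  r <- as.numeric(stats::cor(MEs, trait))
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), n - 2)
  p[abs(r) >= 1] <- 0
  data.frame(module = colnames(MEs), r = r, p = p,
             significant = p < alpha, stringsAsFactors = FALSE)
}

#' Hub-gene selection and thresholded edge export
#'
#' Per gene: gene significance `GS = cor(gene, trait)`, module membership
#' `kME = cor(gene, eigengene of its module)`, and intramodular
#' connectivity `kIM` (sum of adjacency to same-module members). Hubs are
#' module members with `|GS| > gsMin` and `|kME| > kmeMin`, ranked by kIM
#' descending (ties by gene id). Edges are the unordered pairs among each
#' module's top `topN` hubs with `TOM > tomEdge`.
#'
#' @param expr gene x sample expression matrix.
#' @param trait binary trait per sample (case = 1, control = 0).
#' @param modules a [ModuleSet-class] with eigengenes computed.
#' @param network the [CoexNetwork-class] built on the same genes.
#' @param gsMin,kmeMin strict lower bounds on |GS| and |kME| (defaults 0.2
#'   and 0.8).
#' @param topN hubs per module entering the edge export (default 50).
#' @param tomEdge TOM threshold for exported edges (default 0.1).
#' @return list: `hubTable` (`gene`, `module`, `GS`, `kME`, `kIM`,
#'   `is_hub`, `rank`, `is_top`), `edges` (`module`, `source`, `target`,
#'   `weight`).
#' @export
hubSelection <- function(expr, trait, modules, network,
                         gsMin = 0.2, kmeMin = 0.8, topN = 50,
                         tomEdge = 0.1) {
  labels <- modules@labels
  MEs <- modules@eigengenes
  stopifnot(ncol(MEs) > 0 || all(labels == "M0"))
  A <- network@adjacency
  tom <- network@tom
  genes <- names(labels)
  GS <- as.numeric(stats::cor(t(expr[genes, , drop = FALSE]), trait))
  kME <- rep(NA_real_, length(genes))
  kIM <- rep(NA_real_, length(genes))
  names(GS) <- names(kME) <- names(kIM) <- genes
  hubTable <- NULL
  edges <- data.frame(module = character(0), source = character(0),
                      target = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE)
  for (m in setdiff(colnames(MEs), "M0")) {
    members <- genes[labels == m]
    kME[members] <- as.numeric(
      stats::cor(t(expr[members, , drop = FALSE]), MEs[, m]))
    sub <- A[members, members, drop = FALSE]
    kIM[members] <- rowSums(sub) - diag(sub)
    isHub <- abs(GS[members]) > gsMin & abs(kME[members]) > kmeMin
    hubs <- members[isHub]
    hubs <- hubs[order(-kIM[hubs], hubs)]
    top <- utils::head(hubs, topN)
    if (length(top) >= 2) {
      idx <- which(upper.tri(matrix(0, length(top), length(top))),
                   arr.ind = TRUE)
      w <- tom[top, top][idx]
      keep <- w > tomEdge
      if (any(keep))
        edges <- rbind(edges, data.frame(
          module = m, source = top[idx[keep, 1]],
          target = top[idx[keep, 2]], weight = w[keep],
          stringsAsFactors = FALSE))
    }
    hubTable <- rbind(hubTable, data.frame(
      gene = members, module = m, GS = GS[members], kME = kME[members],
      kIM = kIM[members],
      is_hub = isHub,
      rank = match(members, hubs),
      is_top = members %in% top,
      stringsAsFactors = FALSE))
  }
  if (is.null(hubTable))
    hubTable <- data.frame(gene = character(0), module = character(0),
                           GS = numeric(0), kME = numeric(0),
                           kIM = numeric(0), is_hub = logical(0),
                           rank = integer(0), is_top = logical(0))
  rownames(hubTable) <- NULL
  list(hubTable = hubTable, edges = edges)
}
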