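#' Write a GenotypeMatrix as VCF 4.2
#'
#' Emits a minimal VCFv4.2 file with a GT FORMAT field; codes 0/1/2/NA are
#' written as `0/0`, `0/1`, `1/1`, `./.`. The matrix round-trips exactly
#' through [readVCF()].
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output file path (uncompressed).
#' @param panelPath optional path for the accompanying sample-panel TSV
#'   (`sample`, `population`, `subgroup`).
#' @return `path`, invisibly.
#' @export
writeVCF <- function(gm, path, panelPath = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=SweepNet",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gm@geno)), collapse = "\t"))
  writeLines(hdr, con)
  if (nrow(gm@sites) > 0) {
    code <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow(gm@geno), ncol(gm@geno))
    ok <- !is.na(gm@geno)
    gt[ok] <- code[gm@geno[ok] + 1L]
    body <- paste(gm@sites$chrom, gm@sites$pos, ".", gm@sites$ref,
                  gm@sites$alt, ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  if (!is.null(panelPath)) writeTSV(gm@panel, panelPath)
  invisible(path)
}

#' Read a VCF into a GenotypeMatrix
#'
#' Maps GT calls to dosage codes: `0/0 -> 0`, `0/1` or `1/0 -> 1`,
#' `1/1 -> 2`; phased separators (`|`) are treated identically, and any
#' call containing a missing allele (`.`) becomes `NA`. Multiallelic
#' records (comma in ALT) are dropped with a message giving the count.
#' Sites are classified `"SNP"` iff both REF and ALT are single bases,
#' `"indel"` otherwise.
#'
#' @param path VCF file (uncompressed or bgzipped; parsed via
#'   \pkg{vcfR}).
#' @param panel sample panel `data.frame` (`sample`, `population`), or a
#'   path to a TSV with those columns. Every VCF sample must be present.
#' @return a [GenotypeMatrix-class].
#' @export
readVCF <- function(path, panel) {
  if (is.character(panel) && length(panel) == 1)
    panel <- utils::read.delim(panel, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "population") %in% names(panel)))
  nvar <- .countVcfRecords(path)
  if (nvar == 0) {
    samples <- .vcfHeaderSamples(path)
    .checkPanel(samples, panel)
    geno <- matrix(integer(0), nrow = 0, ncol = length(samples),
                   dimnames = list(NULL, samples))
    return(genotypeMatrix(
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), type = character(0)),
      geno, panel[match(samples, panel$sample), , drop = FALSE]))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-record files come back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    message(sum(multi), " multiallelic record(s) dropped")
  gtRaw <- vcfR::extract.gt(v, element = "GT")
  keep <- which(!multi)
  fix <- fix[keep, , drop = FALSE]
  gtRaw <- gtRaw[keep, , drop = FALSE]
  samples <- colnames(gtRaw)
  .checkPanel(samples, panel)
  gt <- gsub("|", "/", gtRaw, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt),
                 dimnames = dimnames(gt))
  code[gt %in% c("0/0")] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt %in% c("1/1")] <- 2L
  missing <- is.na(gt) | grepl(".", gt, fixed = TRUE) | gt %in% "."
  known <- gt %in% c("0/0", "0/1", "1/0", "1/1")
  bad <- which(!known & !missing, arr.ind = TRUE)
  if (nrow(bad))
    stop("malformed GT '", gt[bad[1, 1], bad[1, 2]], "' at record ",
         bad[1, 1], " sample ", samples[bad[1, 2]])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  sites <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = ref, alt = alt,
    type = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP", "indel"),
    stringsAsFactors = FALSE
  )
  genotypeMatrix(sites, code,
                 panel[match(samples, panel$sample), , drop = FALSE])
}

.checkPanel <- function(samples, panel) {
  missing <- setdiff(samples, panel$sample)
  if (length(missing))
    stop("VCF sample(s) absent from panel: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

.countVcfRecords <- function(path) {
  lines <- readLines(path)
  sum(!startsWith(lines, "#") & nzchar(lines))
}

.vcfHeaderSamples <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (!length(hdr)) stop("no #CHROM header line in ", path)
  f <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]]
  if (length(f) <= 9) character(0) else f[-(1:9)]
}
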