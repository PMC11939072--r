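# Readers/writers for the on-disk formats, expression normalisation, and the
# sparse-gene prefilter.  All files are plain TSV (tab separated, UTF-8, '.'
# decimal, no quoting) except signatures, which are JSON.

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.  Row and
#' column order are preserved.  Duplicate ids, ragged rows and non-numeric
#' cells are rejected with informative errors; missing cells are rejected
#' unless `imputeZero = TRUE` (log2 input only).
#'
#' @param path TSV file path.
#' @param valueKind `"zscore"` or `"log2"`.
#' @param imputeZero replace missing cells by 0 (allowed for log2 input only).
#' @return An [ExpressionMatrix-class].
#' @export
readExpression <- function(path, valueKind = c("zscore", "log2"),
                           imputeZero = FALSE) {
  valueKind <- match.arg(valueKind)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged TSV: line %d has %d fields, expected %d",
                 bad, nf[bad], nf[1]))
  }
  df <- utils::read.delim(path, check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("expression TSV needs a gene column and >= 1 sample")
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "", "nan", "NaN")),
               arr.ind = TRUE)
  if (nrow(bad)) {
    # header occupies line 1, so data row i lives on file line i + 1
    stop(sprintf("non-numeric cell '%s' at line %d (gene %s, sample %s)",
                 vals[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L,
                 genes[bad[1, 1]], samples[bad[1, 2]]))
  }
  if (anyNA(num)) {
    if (imputeZero && valueKind == "log2") num[is.na(num)] <- 0
    else stop("missing cells present; rejected (imputeZero applies to log2 input only)")
  }
  dimnames(num) <- list(genes, samples)
  ExpressionMatrix(num, valueKind)
}

#' Write an expression matrix to TSV
#'
#' @param matrix an [ExpressionMatrix-class].
#' @param path output file path.
#' @param geneColumn name of the first (gene id) column.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(matrix, path, geneColumn = "gene") {
  v <- asExprMatrix(matrix)
  df <- data.frame(rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- geneColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove genes that are zero in more than a given fraction of samples
#'
#' Mirrors the standard RNA-seq prefilter on log2 abundances: genes with a
#' zero fraction strictly above `maxZeroFrac` (default 75%) are dropped.
#' Zeros are not meaningful on the z-score scale, so z-score input is
#' returned unchanged with a warning.
#'
#' @param matrix an [ExpressionMatrix-class].
#' @param maxZeroFrac retained genes have zero-fraction <= this value.
#' @return Filtered [ExpressionMatrix-class].
#' @export
filterSparseGenes <- function(matrix, maxZeroFrac = 0.75) {
  stopifnot(is(matrix, "ExpressionMatrix"))
  if (valueKind(matrix) != "log2") {
    warning("filterSparseGenes skipped: zeros are not meaningful for z-score input")
    return(matrix)
  }
  zf <- rowMeans(matrix@values == 0)
  matrix[zf <= maxZeroFrac, ]
}

#' Standardise each gene to mean 0, SD 1
#'
#' Population (divide-by-n) standard deviation is used.  Genes that are
#' constant across samples have no z-score and raise an error naming them;
#' drop them first (e.g. with [filterSparseGenes]) if they are expected.
#'
#' @param matrix an [ExpressionMatrix-class] with >= 2 samples.
#' @return An [ExpressionMatrix-class] with `valueKind = "zscore"`.
#' @examples
#' m <- ExpressionMatrix(matrix(c(1, 2, 3), 1, 3,
#'                              dimnames = list("g1", c("a", "b", "c"))), "log2")
#' exprValues(zscoreByGene(m))  # -1.2247, 0, 1.2247
#' @export
zscoreByGene <- function(matrix) {
  v <- asExprMatrix(matrix)
  if (ncol(v) < 2) stop("zscoreByGene needs >= 2 samples")
  m <- rowMeans(v)
  sdev <- sqrt(rowMeans((v - m)^2))  # population SD
  if (any(sdev == 0))
    stop("constant gene(s), z-score undefined: ",
         paste(rownames(v)[sdev == 0], collapse = ", "))
  ExpressionMatrix((v - m) / sdev, "zscore")
}

# Variant-class alias table.  The status rules know truncating / splice /
# missense only; protein-preserving classes collapse to "other" and are
# ignored by the calling rules.
.variantAliases <- c(
  truncating = "truncating", nonsense = "truncating",
  frameshift = "truncating", "stop-gain" = "truncating",
  stop_gain = "truncating", nonsense_mutation = "truncating",
  frame_shift_del = "truncating", frame_shift_ins = "truncating",
  splice = "splice", splice_site = "splice",
  missense = "missense", missense_mutation = "missense",
  silent = "other", intron = "other", utr = "other", "3'utr" = "other",
  "5'utr" = "other", in_frame_del = "other", in_frame_ins = "other",
  other = "other", none = "none", wt = "none", wild_type = "none")

#' Normalise a variant-class token
#'
#' @param class character vector of variant-class tokens (case-insensitive).
#' @return Character vector over \{truncating, splice, missense, other, none\}.
#' @export
normalizeVariantClass <- function(class) {
  key <- tolower(trimws(class))
  out <- .variantAliases[key]
  if (anyNA(out))
    stop("unknown variant_class token(s): ",
         paste(unique(class[is.na(out)]), collapse = ", "),
         "; allowed: ", paste(names(.variantAliases), collapse = ", "))
  unname(out)
}

#' Read mutation records (sample, gene, variant_class) from TSV
#'
#' Variant classes are normalised through the alias table (e.g. `nonsense`
#' becomes `truncating`); unknown tokens raise an error listing the allowed
#' values.
#'
#' @param path TSV file with columns sample, gene, variant_class.
#' @return data.frame with normalised variant_class.
#' @export
readMutations <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  need <- c("sample", "gene", "variant_class")
  if (!all(need %in% colnames(df)))
    stop("mutations TSV must have columns: ", paste(need, collapse = ", "))
  df$variant_class <- normalizeVariantClass(df$variant_class)
  df[need]
}

#' Write mutation records to TSV
#' @param mutations data.frame with columns sample, gene, variant_class.
#' @param path output path.
#' @export
writeMutations <- function(mutations, path) {
  utils::write.table(mutations[c("sample", "gene", "variant_class")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-gene copy-number log2 ratios from TSV
#' @param path TSV with columns sample, gene, log2_ratio.
#' @return data.frame(sample, gene, log2_ratio).
#' @export
readCnaGenes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  need <- c("sample", "gene", "log2_ratio")
  if (!all(need %in% colnames(df)))
    stop("per-gene CNA TSV must have columns: ", paste(need, collapse = ", "))
  if (!is.numeric(df$log2_ratio) || anyNA(df$log2_ratio))
    stop("log2_ratio must be numeric and complete")
  df[need]
}

#' Read SEG-like copy-number segments from TSV
#'
#' Coordinates are 1-based inclusive; rows with `end < start` are rejected.
#'
#' @param path TSV with columns sample, chrom, start, end, log2_ratio.
#' @return data.frame(sample, chrom, start, end, log2_ratio).
#' @export
readSeg <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "log2_ratio")
  if (!all(need %in% colnames(df)))
    stop("SEG TSV must have columns: ", paste(need, collapse = ", "))
  bad <- which(df$end < df$start)
  if (length(bad))
    stop(sprintf("SEG row %d has end < start (%d < %d)",
                 bad[1], df$end[bad[1]], df$start[bad[1]]))
  df[need]
}

#' Write SEG-like segments to TSV
#' @param segments data.frame(sample, chrom, start, end, log2_ratio).
#' @param path output path.
#' @export
writeSeg <- function(segments, path) {
  utils::write.table(
    segments[c("sample", "chrom", "start", "end", "log2_ratio")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature from JSON
#'
#' Schema: `{"genes": [{"id": ..., "direction": +-1, "mean_z": ...}, ...],
#' "meta": {...}}`.  `mean_z` is optional.
#'
#' @param path JSON file path.
#' @return An [RbSignature-class].
#' @export
readSignature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- obj$genes
  if (is.null(g) || !nrow(as.data.frame(g)))
    stop("signature JSON has no genes")
  g <- as.data.frame(g)
  meanZ <- if ("mean_z" %in% colnames(g)) as.numeric(g$mean_z)
           else rep(NA_real_, nrow(g))
  RbSignature(genes = g$id, directions = g$direction, meanZ = meanZ,
              metadata = if (is.null(obj$meta)) list() else as.list(obj$meta),
              valid = if (is.null(obj$valid)) nrow(g) > 0 else isTRUE(obj$valid))
}

#' Write a signature to JSON
#' @param signature an [RbSignature-class].
#' @param path output path.
#' @export
writeSignature <- function(signature, path) {
  stopifnot(is(signature, "RbSignature"))
  obj <- list(
    genes = data.frame(id = signature@genes, direction = signature@directions,
                       mean_z = signature@meanZ, stringsAsFactors = FALSE),
    meta = signature@metadata, valid = signature@valid)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write phospho-site values in long format (sample, site, value)
#' @param phospho named list of numeric site-value vectors, one per sample.
#' @param path output path.
#' @export
writePhospho <- function(phospho, path) {
  rows <- lapply(names(phospho), function(s) {
    v <- phospho[[s]]
    if (!length(v)) return(NULL)
    sites <- if (is.null(names(v))) paste0("site_", seq_along(v)) else names(v)
    data.frame(sample = s, site = sites, value = as.numeric(v),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(
    data.frame(sample = character(), site = character(), value = numeric()))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read long-format phospho-site values
#'
#' Samples listed in `allSamples` but absent from the file get an empty
#' vector, preserving the missing-phospho semantics of the calling rules.
#'
#' @param path TSV with columns sample, site, value.
#' @param allSamples optional character vector of the full sample universe.
#' @return named list of numeric per-site vectors.
#' @export
readPhospho <- function(path, allSamples = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  need <- c("sample", "site", "value")
  if (!all(need %in% colnames(df)))
    stop("phospho TSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$sample),
                function(d) stats::setNames(as.numeric(d$value), d$site))
  if (!is.null(allSamples)) {
    missing <- setdiff(allSamples, names(out))
    out[missing] <- replicate(length(missing), numeric(0), simplify = FALSE)
    out <- out[allSamples]
  }
  out
}
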