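# Signature direction, per-sample alignment scoring and classification, the
# SVD metagene benchmarking score, pan-cancer core aggregation, and overlap
# coefficients.

#' Derive signature directions from the defective discovery group
#'
#' Direction of each gene is the sign of its mean z-score across the
#' RB1-defective samples.  Genes whose mean is exactly zero have no direction
#' and are dropped with a warning (cannot occur after [finalGeneFilter],
#' which requires |mean z| >= 0.2).
#'
#' @param matrix z-scored [ExpressionMatrix-class] or named matrix.
#' @param defectiveSamples nonempty sample-id vector.
#' @param genes gene ids to include.
#' @param metadata metadata list for the signature.
#' @return An [RbSignature-class].
#' @export
signatureDirection <- function(matrix, defectiveSamples, genes,
                               metadata = list()) {
  v <- asExprMatrix(matrix)
  if (!length(defectiveSamples)) stop("defectiveSamples must be nonempty")
  missing <- setdiff(genes, rownames(v))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  mz <- rowMeans(v[genes, defectiveSamples, drop = FALSE])
  zero <- mz == 0
  if (any(zero)) {
    warning("dropping gene(s) with mean z exactly 0: ",
            paste(genes[zero], collapse = ", "))
    genes <- genes[!zero]; mz <- mz[!zero]
  }
  if (!length(genes)) stop("all genes dropped: every mean z is exactly 0")
  RbSignature(genes, sign(mz), unname(mz), metadata = metadata)
}

#' Alignment of one sample with a signature
#'
#' The fraction of signature genes available in the sample whose z-score sign
#' matches the signature direction.  A z of exactly 0 counts as discordant.
#' Signature genes absent from the sample's dataset are ignored (only the
#' measured genes enter the denominator).
#'
#' @param sampleZ named numeric vector of per-gene z-scores for one sample.
#' @param signature an [RbSignature-class].
#' @return alignment score in `[0, 1]`.
#' @examples
#' sig <- RbSignature(c("a", "b"), c(1, -1))
#' alignmentScore(c(a = 0.7, b = -0.1), sig)  # 1
#' @export
alignmentScore <- function(sampleZ, signature) {
  stopifnot(is(signature, "RbSignature"))
  d <- signatureDirections(signature)
  avail <- intersect(names(d), names(sampleZ))
  if (!length(avail))
    stop("no signature gene available in the sample (signature: ",
         paste(utils::head(names(d), 3), collapse = ", "), " ...)")
  mean(sign(sampleZ[avail]) == d[avail])
}

#' Classify alignment scores into high / low / no-confidence
#'
#' Bands: > 0.55 high, < 0.45 low, the inclusive middle `[0.45, 0.55]` is
#' no-confidence.  Every score in `[0, 1]` maps to exactly one class.
#'
#' @param score numeric vector of alignment scores in `[0, 1]`.
#' @return character vector over \{low, no_confidence, high\}.
#' @export
classifyAlignment <- function(score) {
  if (any(!is.finite(score)) || any(score < 0 | score > 1))
    stop("alignment scores must lie in [0, 1]")
  ifelse(score > 0.55, "high", ifelse(score < 0.45, "low", "no_confidence"))
}

#' Score every sample of a matrix against a signature
#'
#' @param matrix z-scored [ExpressionMatrix-class] or named matrix.
#' @param signature an [RbSignature-class].
#' @return data.frame(sample, alignment, n_genes_used, class).
#' @export
scoreAlignment <- function(matrix, signature) {
  v <- asExprMatrix(matrix)
  d <- signatureDirections(signature)
  avail <- intersect(names(d), rownames(v))
  if (!length(avail))
    stop("no signature gene available in the dataset")
  conc <- sign(v[avail, , drop = FALSE]) == d[avail]
  al <- colMeans(conc)
  data.frame(sample = colnames(v), alignment = unname(al),
             n_genes_used = length(avail),
             class = classifyAlignment(unname(al)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' SVD metagene score for a gene-list signature
#'
#' Signature genes are standardised to mean 0, SD 1, and each sample is
#' scored by the first right-singular vector of the standardised gene x
#' sample matrix (the first principal metagene).  The sign of the score is
#' oriented so that it correlates positively with the mean of the
#' up-regulated signature genes (all genes, when no directions are
#' supplied).  Samples are trichotomised by tertiles of the score.
#'
#' @param matrix [ExpressionMatrix-class] or named matrix.
#' @param genes signature gene ids (>= 2 present required).
#' @param directions optional named +1/-1 vector used for sign orientation.
#' @return data.frame(sample, score, tertile) with tertile in
#'   \{low, intermediate, high\}.
#' @export
svdSignatureScore <- function(matrix, genes, directions = NULL) {
  v <- asExprMatrix(matrix)
  if (ncol(v) < 3) stop("need >= 3 samples")
  genes <- intersect(genes, rownames(v))
  x <- v[genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    x <- x[sds > 0, , drop = FALSE]
    genes <- rownames(x)
  }
  if (nrow(x) < 2) stop("fewer than 2 non-constant signature genes present")
  xs <- t(scale(t(x)))  # per-gene mean 0, SD 1
  sv <- svd(xs, nu = 0, nv = 1)
  score <- drop(sv$v[, 1]) * sv$d[1]
  up <- if (!is.null(directions)) genes[directions[genes] > 0] else genes
  ref <- if (length(up)) colMeans(xs[up, , drop = FALSE])
         else -colMeans(xs)  # all-down signature: flip the reference
  if (stats::cor(score, ref) < 0) score <- -score
  qs <- stats::quantile(score, c(1 / 3, 2 / 3))
  tert <- ifelse(score <= qs[1], "low",
                 ifelse(score <= qs[2], "intermediate", "high"))
  data.frame(sample = colnames(v), score = unname(score),
             tertile = unname(tert), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Aggregate cancer-type signatures into a pan-cancer core
#'
#' Core genes occur in at least `minTypes` of the input signatures (default
#' `max(3, ceiling(0.2 * n))`, which reproduces "3 of 14").  The core
#' direction of a gene is the majority sign of its member directions;
#' zero-sum genes are dropped with a warning.
#'
#' @param signatures list of >= 2 [RbSignature-class] objects.
#' @param minTypes minimum number of signatures a core gene must appear in.
#' @param metadata metadata list for the core signature.
#' @return An [RbSignature-class]; flagged invalid when empty.
#' @export
buildCoreSignature <- function(signatures,
                               minTypes = max(3, ceiling(0.2 *
                                                           length(signatures))),
                               metadata = list()) {
  if (length(signatures) < 2) stop("need >= 2 input signatures")
  stopifnot(all(vapply(signatures, is, TRUE, "RbSignature")))
  dirs <- lapply(signatures, signatureDirections)
  allGenes <- unlist(lapply(dirs, names))
  counts <- table(allGenes)
  core <- names(counts)[counts >= minTypes]
  sumDir <- vapply(core, function(g)
    sum(vapply(dirs, function(d) if (g %in% names(d)) d[[g]] else 0,
               numeric(1))), numeric(1))
  zero <- sumDir == 0
  if (any(zero)) {
    warning("dropping core gene(s) with tied directions: ",
            paste(core[zero], collapse = ", "))
    core <- core[!zero]; sumDir <- sumDir[!zero]
  }
  metadata <- utils::modifyList(metadata, list(
    n_types = length(signatures), min_types = minTypes))
  RbSignature(core, sign(sumDir), metadata = metadata,
              valid = length(core) > 0)
}

#' Overlap coefficient between two gene sets
#'
#' `O(A, B) = |A intersect B| / min(|A|, |B|)`, computed after removing the
#' genes in `exclude` (RB1 by default, to avoid the single shared anchor gene
#' inflating every pairwise overlap).
#'
#' @param genesA,genesB gene-id vectors, nonempty after exclusion.
#' @param exclude genes removed from both sets first.
#' @return list(oc, intersection, min_size).
#' @examples
#' overlapCoefficient(c("a", "b", "c"), c("b", "c", "d", "e"))$oc  # 2/3
#' @export
overlapCoefficient <- function(genesA, genesB, exclude = "RB1") {
  a <- setdiff(unique(genesA), exclude)
  b <- setdiff(unique(genesB), exclude)
  if (!length(a) || !length(b))
    stop("a gene set is empty after exclusion")
  inter <- length(intersect(a, b))
  mn <- min(length(a), length(b))
  list(oc = inter / mn, intersection = inter, min_size = mn)
}
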