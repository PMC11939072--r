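# Multiscale relevance-network refinement of a candidate signature.
#
# At each RB1 expression scale alpha, samples with |RB1 z| beyond alpha are
# selected, a Spearman correlation network over the signature genes is built,
# and the edge threshold c is grid-searched for the value whose connected
# genes best separate the RB1-high from the RB1-low samples by alignment.
# Genes surviving a cross-scale consensus (all scales, or >= 2 scales) form
# the refined signature.

# The threshold grid: [0.1, 0.8] in steps of 0.02, endpoints inclusive.
.cGrid <- function() seq(0.10, 0.80, by = 0.02)

#' Select RB1-characteristic samples at one expression scale
#'
#' Strict inequalities on both sides: high set has RB1 z > alpha, low set has
#' RB1 z < -alpha; samples with |z| <= alpha are excluded.
#'
#' @param matrix z-scored [ExpressionMatrix-class] or named matrix.
#' @param rb1Gene RB1 gene row id.
#' @param alpha positive scale value.
#' @return list(high, low) of sample-id vectors (either may be empty; the
#'   caller decides whether the scale is usable).
#' @export
selectScaleSamples <- function(matrix, rb1Gene = "RB1", alpha) {
  v <- asExprMatrix(matrix)
  stopifnot(alpha > 0)
  if (!rb1Gene %in% rownames(v))
    stop(sprintf("RB1 gene '%s' not present in the matrix", rb1Gene))
  z <- v[rb1Gene, ]
  list(high = colnames(v)[z > alpha], low = colnames(v)[z < -alpha])
}

#' Build a Spearman relevance network over a gene set
#'
#' Spearman correlations (average ranks for ties) across the selected
#' samples; the adjacency has an edge where the correlation is `>= c`
#' off-diagonal (self-correlations never create edges).  Genes that are
#' constant over the selected samples have undefined correlations and are
#' treated as disconnected, with a warning.
#'
#' @param matrix z-scored [ExpressionMatrix-class] or named matrix.
#' @param genes gene ids (>= 2).
#' @param samples selected sample ids (>= 3).
#' @param c edge threshold.
#' @param alpha scale tag recorded on the result (informational).
#' @return list(alpha, c, correlation, adjacency, connectedGenes).
#' @export
buildRelevanceNetwork <- function(matrix, genes, samples, c, alpha = NA_real_) {
  v <- asExprMatrix(matrix)
  missing <- setdiff(genes, rownames(v))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  if (length(genes) < 2) stop("need >= 2 genes")
  if (length(samples) < 3) stop("need >= 3 selected samples")
  x <- t(v[genes, samples, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    warning("constant gene(s) over selected samples treated as disconnected: ",
            paste(genes[sds == 0], collapse = ", "))
  C <- suppressWarnings(stats::cor(x, method = "spearman"))
  C[!is.finite(C)] <- -Inf  # undefined correlation: never an edge
  A <- (C >= c) * 1
  diag(A) <- 0
  list(alpha = alpha, c = c, correlation = C, adjacency = A,
       connectedGenes = genes[rowSums(A) >= 1])
}

#' Classification accuracy of a connected gene set at one scale
#'
#' Each sample is scored by its alignment over the connected genes and
#' predicted "defective-like" when the alignment exceeds 0.5 (a tie at
#' exactly 0.5 is assigned proficient-like).  By default the RB1-low side is
#' the one expected to look defective-like, since signature directions are
#' defined on RB1-defective samples; `invertSides` swaps the mapping.
#'
#' @param connectedGenes nonempty gene set.
#' @param directions named +1/-1 vector covering `connectedGenes`.
#' @param high,low nonempty sample-id sets (RB1 z > alpha / < -alpha).
#' @param matrix z-scored [ExpressionMatrix-class] or named matrix.
#' @param invertSides map the RB1-high side to defective-like instead.
#' @return accuracy in `[0, 1]`.
#' @export
scaleAccuracy <- function(connectedGenes, directions, high, low, matrix,
                          invertSides = FALSE) {
  if (!length(connectedGenes)) stop("empty connected gene set")
  if (!length(high) || !length(low)) stop("both sample sides must be nonempty")
  v <- asExprMatrix(matrix)
  d <- directions[connectedGenes]
  sig <- RbSignature(connectedGenes, unname(d))
  score <- function(s) alignmentScore(v[connectedGenes, s], sig)
  defLike <- vapply(c(low, high), score, numeric(1)) > 0.5
  expected <- rep(c(!invertSides, invertSides), c(length(low), length(high)))
  mean(defLike == expected)
}

#' Grid-search the relevance threshold at one scale
#'
#' Evaluates every c in \{0.10, 0.12, ..., 0.80\} (36 values, endpoints
#' inclusive), builds the network, and scores the accuracy of its connected
#' genes; c* is the smallest c achieving the maximal accuracy.  Thresholds
#' with an empty connected set are skipped; if none yields a connected gene
#' the scale is unusable.
#'
#' @inheritParams scaleAccuracy
#' @param matrix z-scored [ExpressionMatrix-class] or named matrix.
#' @param genes candidate signature genes.
#' @param alpha scale value recorded on the result.
#' @return A [ScaleResult-class] (`usable = FALSE` when either sample side is
#'   empty, when fewer than 3 samples are selected, or when no threshold
#'   leaves a connected gene).
#' @export
optimizeThreshold <- function(matrix, genes, directions, high, low,
                              alpha = NA_real_, invertSides = FALSE) {
  unusable <- function() new("ScaleResult", alpha = alpha, cStar = NA_real_,
                             accuracy = NA_real_,
                             connectedGenes = character(0), usable = FALSE,
                             nHigh = length(high), nLow = length(low))
  if (!length(high) || !length(low) || length(high) + length(low) < 3 ||
      length(genes) < 2) {
    warning(sprintf("scale alpha=%.2f unusable: too few samples or genes", alpha))
    return(unusable())
  }
  samples <- c(high, low)
  best <- NULL
  for (cv in .cGrid()) {
    net <- suppressWarnings(
      buildRelevanceNetwork(matrix, genes, samples, cv, alpha))
    if (!length(net$connectedGenes)) next
    acc <- scaleAccuracy(net$connectedGenes, directions, high, low, matrix,
                         invertSides)
    # strict > keeps the smallest c among accuracy maximizers
    if (is.null(best) || acc > best$acc)
      best <- list(c = cv, acc = acc, genes = net$connectedGenes)
  }
  if (is.null(best)) {
    warning(sprintf("scale alpha=%.2f unusable: no threshold leaves a connected gene",
                    alpha))
    return(unusable())
  }
  new("ScaleResult", alpha = alpha, cStar = best$c, accuracy = best$acc,
      connectedGenes = best$genes, usable = TRUE,
      nHigh = length(high), nLow = length(low))
}

#' Cross-scale consensus of connected gene sets
#'
#' Strict mode keeps genes connected at every usable scale (intended: all
#' four); tolerant mode keeps genes connected at >= 2 scales (or at all
#' scales when fewer than two are usable).  `"auto"` picks strict for
#' candidate sets of more than 50 genes and tolerant otherwise (exactly 50
#' is tolerant).  If any scale is unusable, strict consensus is impossible
#' and the run falls back to tolerant with a warning.
#'
#' @param scaleResults list of [ScaleResult-class] objects.
#' @param mode `"auto"`, `"strict"` or `"tolerant"`.
#' @param candidateGenes the candidate gene set (drives auto mode and the
#'   returned ordering).
#' @param directions named +1/-1 vector over the candidate genes.
#' @param meanZ optional named mean-z vector carried into the signature.
#' @param metadata metadata list for the refined signature.
#' @return An [RbSignature-class]; flagged invalid when the consensus is empty.
#' @export
multiscaleConsensus <- function(scaleResults, mode = c("auto", "strict",
                                                       "tolerant"),
                                candidateGenes, directions,
                                meanZ = NULL, metadata = list()) {
  mode <- match.arg(mode)
  if (mode == "auto")
    mode <- if (length(candidateGenes) > 50) "strict" else "tolerant"
  usable <- Filter(function(s) s@usable, scaleResults)
  if (!length(usable)) stop("no usable scale; cannot form a consensus")
  if (mode == "strict" && length(usable) < length(scaleResults)) {
    warning("unusable scale(s) present: strict consensus impossible, falling back to tolerant")
    mode <- "tolerant"
  }
  counts <- table(unlist(lapply(usable, function(s) s@connectedGenes)))
  need <- if (mode == "strict") length(usable) else min(2L, length(usable))
  keep <- candidateGenes[candidateGenes %in%
                           names(counts)[counts >= need]]
  mz <- if (is.null(meanZ)) rep(NA_real_, length(keep)) else unname(meanZ[keep])
  metadata <- utils::modifyList(metadata, list(
    consensus_mode = mode,
    scales = lapply(scaleResults, function(s) list(
      alpha = s@alpha, c_star = s@cStar, accuracy = s@accuracy,
      usable = s@usable, n_connected = length(s@connectedGenes)))))
  RbSignature(keep, unname(directions[keep]), mz, metadata = metadata,
              valid = length(keep) > 0)
}

#' Refine a signature through the multiscale relevance-network procedure
#'
#' Runs [selectScaleSamples] and [optimizeThreshold] at each scale in
#' `alphas` (default 0.4, 0.6, 0.8, 1.0) and combines the per-scale
#' connected sets with [multiscaleConsensus].
#'
#' @param matrix z-scored [ExpressionMatrix-class] or named matrix covering
#'   the cohort the signature is being generalised on.
#' @param signature candidate [RbSignature-class] (directions required).
#' @param rb1Gene RB1 gene row id.
#' @param mode consensus mode, `"auto"` (default), `"strict"` or `"tolerant"`.
#' @param alphas RB1 z-score scales.
#' @param invertSides see [scaleAccuracy].
#' @return A refined [RbSignature-class]; per-scale results are stored in
#'   `signatureMetadata()$scales`.
#' @export
refineSignature <- function(matrix, signature, rb1Gene = "RB1",
                            mode = c("auto", "strict", "tolerant"),
                            alphas = c(0.4, 0.6, 0.8, 1.0),
                            invertSides = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is(signature, "RbSignature"))
  genes <- intersect(signatureGenes(signature), rownames(asExprMatrix(matrix)))
  if (length(genes) < 2)
    stop("fewer than 2 signature genes present in the matrix")
  directions <- signatureDirections(signature)
  scales <- lapply(alphas, function(a) {
    sides <- selectScaleSamples(matrix, rb1Gene, a)
    optimizeThreshold(matrix, genes, directions, sides$high, sides$low,
                      alpha = a, invertSides = invertSides)
  })
  multiscaleConsensus(scales, mode, genes, directions,
                      meanZ = signatureMeanZ(signature),
                      metadata = signatureMetadata(signature))
}
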