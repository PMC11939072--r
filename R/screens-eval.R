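# Evaluation metrics, aggressiveness markers and screen-gating procedures:
# confusion-matrix statistics, hypergeometric enrichment, percent genome
# altered, median gene scores (hypoxia-style), and the gated Welch tests for
# CRISPR gene-effect and drug-response screens.

#' Sensitivity and specificity of binary calls against truth
#'
#' @param truth,calls equal-length logical (or 0/1) vectors.
#' @return list(sensitivity, specificity, table) with percentages on the
#'   0-100 scale; a class with no members yields an `NA` sentinel for the
#'   corresponding metric.  `table` is a list(TP, FP, TN, FN).
#' @examples
#' confusionMetrics(rep(TRUE, 7), rep(TRUE, 7))$sensitivity  # 100
#' @export
confusionMetrics <- function(truth, calls) {
  truth <- as.logical(truth); calls <- as.logical(calls)
  if (!length(truth) || length(truth) != length(calls))
    stop("truth and calls must be nonempty vectors of equal length")
  if (anyNA(truth) || anyNA(calls)) stop("NA labels are not allowed")
  tp <- sum(truth & calls); fn <- sum(truth & !calls)
  tn <- sum(!truth & !calls); fp <- sum(!truth & calls)
  list(sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
       table = list(TP = tp, FP = fp, TN = tn, FN = fn))
}

#' Hypergeometric enrichment of a 2x2 table
#'
#' One-sided overrepresentation p-value for the `a` cell of the table
#' `rbind(c(a, b), c(c, d))` given fixed margins, plus the sample odds ratio
#' `ad / bc`.  When a zero cell makes the odds ratio degenerate, 0.5 is added
#' to every cell for the reported ratio and the result is flagged.
#'
#' @param a,b,c,d nonnegative integer cell counts (`a` = in-set successes).
#' @return list(odds_ratio, p, degenerate).
#' @examples
#' fisherEnrichment(5, 0, 0, 5)$p  # 1/choose(10, 5)
#' @export
fisherEnrichment <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  if (sum(cells) == 0) stop("table total must be > 0")
  degenerate <- any(cells == 0)
  or <- if (degenerate) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
        else (a * d) / (b * c)
  # P(X >= a) with X ~ Hypergeometric(white = a+b, black = c+d, drawn = a+c)
  p <- stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
  list(odds_ratio = or, p = p, degenerate = degenerate)
}

#' Percent genome altered from copy-number segments
#'
#' Fraction of the segmented genome whose |log2 ratio| exceeds `cut`
#' (default 0.2).  The default weights segments by their length (1-based
#' inclusive, width `end - start + 1`); `byCount = TRUE` uses the unweighted
#' fraction of altered segments instead.
#'
#' @param segments data.frame(sample, chrom, start, end, log2_ratio), e.g.
#'   from [readSeg].
#' @param cut alteration threshold on |log2 ratio|.
#' @param byCount use the segment-count convention.
#' @return named numeric vector of per-sample PGA fractions in `[0, 1]`.
#' @export
computePga <- function(segments, cut = 0.2, byCount = FALSE) {
  need <- c("sample", "start", "end", "log2_ratio")
  if (!all(need %in% colnames(segments)))
    stop("segments must have columns: ", paste(need, collapse = ", "))
  if (any(segments$end < segments$start)) stop("segment with end < start")
  altered <- abs(segments$log2_ratio) > cut
  w <- if (byCount) rep(1, nrow(segments))
       else segments$end - segments$start + 1
  tot <- tapply(w, segments$sample, sum)
  if (any(tot == 0)) stop("sample with zero total segment length")
  alt <- tapply(w * altered, segments$sample, sum)
  out <- alt / tot
  out[unique(segments$sample)]
}

#' Per-sample median score over a gene list
#'
#' Median expression of the available listed genes in each sample (the
#' hypoxia-score convention); genes absent from the matrix are ignored.
#'
#' @param matrix [ExpressionMatrix-class] or named matrix.
#' @param genes gene ids (>= 1 present required).
#' @return named numeric vector, one value per sample.
#' @export
medianGeneScore <- function(matrix, genes) {
  v <- asExprMatrix(matrix)
  avail <- intersect(genes, rownames(v))
  if (!length(avail)) stop("none of the listed genes is present")
  apply(v[avail, , drop = FALSE], 2, stats::median)
}

# One-sided Welch t p-value (alternative: mean(x) < mean(y)), Satterthwaite df.
.welchLessP <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x) / nx; vy <- stats::var(y) / ny
  se <- sqrt(vx + vy)
  if (se == 0) return(if (mean(x) < mean(y)) 0 else 1)
  t <- (mean(x) - mean(y)) / se
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  stats::pt(t, df)
}

#' Synthetic-lethality candidates from a CRISPR gene-effect screen
#'
#' A gene is testable only if it passes all three gates: mean gene effect in
#' `groupA` < -0.5 (at least synthetic sickness), mean gene effect in the
#' signature-low group > -0.75 (not already essential there), and mean(A) <
#' mean(low).  Testable genes get a one-sided Welch t p-value for groupA
#' being lower; candidates are the testable genes with p < `pCut` (default
#' 0.05, uncorrected).  Genes failing the gates are never tested (their p is
#' `NA`).
#'
#' @param geneEffect gene x cell-line numeric matrix of gene-effect scores.
#' @param groupLabels named per-line labels over \{rb1_defective, rbness,
#'   low, other\}.
#' @param groupA `"rb1_defective"` or `"rbness"`.
#' @param pCut candidate p-value cut.
#' @param fdr apply a BH correction before the cut (off by default, matching
#'   the uncorrected convention).
#' @return data.frame(gene, mean_groupA, mean_low, testable, p, candidate).
#' @export
crisprSlCandidates <- function(geneEffect, groupLabels,
                               groupA = c("rb1_defective", "rbness"),
                               pCut = 0.05, fdr = FALSE) {
  groupA <- match.arg(groupA)
  linesA <- names(groupLabels)[groupLabels == groupA]
  linesLow <- names(groupLabels)[groupLabels == "low"]
  if (length(linesA) < 3)
    stop(sprintf("group '%s' has %d lines; need >= 3", groupA, length(linesA)))
  if (length(linesLow) < 3)
    stop(sprintf("group 'low' has %d lines; need >= 3", length(linesLow)))
  A <- geneEffect[, linesA, drop = FALSE]
  L <- geneEffect[, linesLow, drop = FALSE]
  mA <- rowMeans(A); mL <- rowMeans(L)
  testable <- mA < -0.5 & mL > -0.75 & mA < mL
  p <- rep(NA_real_, nrow(geneEffect))
  idx <- which(testable)
  p[idx] <- vapply(idx, function(i) .welchLessP(A[i, ], L[i, ]), numeric(1))
  padj <- p
  if (fdr && length(idx)) padj[idx] <- bhAdjust(p[idx])
  data.frame(gene = rownames(geneEffect), mean_groupA = unname(mA),
             mean_low = unname(mL), testable = unname(testable),
             p = unname(p), candidate = unname(!is.na(padj) & padj < pCut),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Candidates from an isogenic knockout-vs-parent CRISPR screen
#'
#' Keeps genes whose knockout-line z-score drops by more than 2 relative to
#' the parental line (delta < -2), is itself strongly depleted (z_knockout <
#' -2), and whose parental z-score is not already near-lethal (z_parent > -4).
#'
#' @param records data.frame with columns gene, z_knockout, z_parent.
#' @return data.frame(gene, z_knockout, z_parent, delta, candidate).
#' @export
isogenicScreenCandidates <- function(records) {
  need <- c("gene", "z_knockout", "z_parent")
  missing <- setdiff(need, colnames(records))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  delta <- records$z_knockout - records$z_parent
  data.frame(gene = records$gene, z_knockout = records$z_knockout,
             z_parent = records$z_parent, delta = delta,
             candidate = delta < -2 & records$z_knockout < -2 &
               records$z_parent > -4,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Drug-sensitivity candidates from a dose-response screen
#'
#' A compound is testable only if the signature-low group is on average
#' non-sensitive (mean dr-AUC >= 0) while `groupA` is clearly sensitive
#' (mean dr-AUC < -0.5); testable compounds get a one-sided Welch t p-value
#' for `groupA` being lower, with candidates at p < `pCut`.
#'
#' @param drAuc compound x cell-line matrix of z-transformed dose-response
#'   AUC values.
#' @param groupLabels named per-line labels (`low` plus the groupA label).
#' @param groupA `"rb1_defective"` or `"rbness"`.
#' @param pCut candidate p-value cut.
#' @param fdr apply BH before the cut (off by default).
#' @return data.frame(compound, mean_groupA, mean_low, testable, p, candidate).
#' @export
drugSensitivityCandidates <- function(drAuc, groupLabels,
                                      groupA = c("rb1_defective", "rbness"),
                                      pCut = 0.05, fdr = FALSE) {
  groupA <- match.arg(groupA)
  linesA <- names(groupLabels)[groupLabels == groupA]
  linesLow <- names(groupLabels)[groupLabels == "low"]
  if (length(linesA) < 3)
    stop(sprintf("group '%s' has %d lines; need >= 3", groupA, length(linesA)))
  if (length(linesLow) < 3)
    stop(sprintf("group 'low' has %d lines; need >= 3", length(linesLow)))
  A <- drAuc[, linesA, drop = FALSE]
  L <- drAuc[, linesLow, drop = FALSE]
  mA <- rowMeans(A); mL <- rowMeans(L)
  testable <- mL >= 0 & mA < -0.5
  p <- rep(NA_real_, nrow(drAuc))
  idx <- which(testable)
  p[idx] <- vapply(idx, function(i) .welchLessP(A[i, ], L[i, ]), numeric(1))
  padj <- p
  if (fdr && length(idx)) padj[idx] <- bhAdjust(p[idx])
  data.frame(compound = rownames(drAuc), mean_groupA = unname(mA),
             mean_low = unname(mL), testable = unname(testable),
             p = unname(p), candidate = unname(!is.na(padj) & padj < pCut),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' RB1-defective call for a cell line
#'
#' A line is RB1-defective if it carries a damaging RB1 mutation, an RB1 deep
#' deletion, an RB1 gene fusion, or RB1 mRNA z-score < -2.  Missing
#' modalities may be `NA`, but not all of them.
#'
#' @param mutationDamaging,deepDeletion,rb1Fusion logical flags (NA allowed).
#' @param mrnaZ RB1 mRNA z-score (NA allowed).
#' @return logical.
#' @export
cellLineRb1Defective <- function(mutationDamaging = NA, deepDeletion = NA,
                                 rb1Fusion = NA, mrnaZ = NA) {
  if (is.na(mutationDamaging) && is.na(deepDeletion) && is.na(rb1Fusion) &&
      is.na(mrnaZ))
    stop("all modalities missing")
  isTRUE(mutationDamaging) || isTRUE(deepDeletion) || isTRUE(rb1Fusion) ||
    (!is.na(mrnaZ) && mrnaZ < -2)
}
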