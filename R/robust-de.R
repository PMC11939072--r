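# Moderated-t differential expression, the leave-one-out subsampling
# robustness procedure (all n*m single-pair deletions), and the final gene
# filters that turn a robustness table into an unrefined signature.

# Solve trigamma(y) = x by Newton iteration (monotone, convex target).
trigammaInverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(NA_real_)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1))
}

# Empirical-Bayes fit of a scaled inverse-chi-square prior to gene variances:
# moment matching on log s^2 for the prior df; the prior variance falls back
# to the mean gene variance when the log-variances show no excess spread
# (infinite prior df), so that equal gene variances shrink to themselves.
squeezeVarMoments <- function(s2, df) {
  s2 <- pmax(s2, 0)
  ok <- s2 > 0
  if (sum(ok) < 2) return(list(df.prior = 0, var.prior = NA_real_,
                               var.post = s2))
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar > 0) {
    df.prior <- 2 * trigammaInverse(evar)
    var.prior <- exp(emean + digamma(df.prior / 2) - log(df.prior / 2))
    var.post <- (df.prior * var.prior + df * s2) / (df.prior + df)
  } else {
    df.prior <- Inf
    var.prior <- mean(s2[ok])
    var.post <- rep(var.prior, length(s2))
  }
  list(df.prior = df.prior, var.prior = var.prior, var.post = var.post)
}

# Moderated two-group statistics from sufficient statistics.  Shared by the
# full fit and the leave-one-out fast path so the two stay numerically
# identical.
.moderatedStats <- function(meanA, meanB, s2, nA, nB, priorDf = NULL) {
  df <- nA + nB - 2
  if (is.null(priorDf)) {
    sq <- squeezeVarMoments(s2, df)
  } else if (priorDf == 0) {
    sq <- list(df.prior = 0, var.prior = NA_real_, var.post = s2)
  } else {
    stop("priorDf must be NULL (estimate) or 0 (disable shrinkage)")
  }
  se <- sqrt(sq$var.post * (1 / nA + 1 / nB))
  t <- (meanA - meanB) / se
  t[!is.finite(t)] <- 0
  dfTotal <- df + sq$df.prior
  p <- 2 * stats::pt(-abs(t), df = dfTotal)
  list(log2FC = meanA - meanB, t = t, p = p, df.prior = sq$df.prior,
       var.prior = sq$var.prior, var.post = sq$var.post, df.total = dfTotal)
}

#' Two-group moderated-t differential expression
#'
#' Per-gene two-group linear model with empirical-Bayes variance shrinkage: a
#' scaled inverse-chi-square prior is fitted to the gene-wise pooled
#' variances by moment matching on the log variances, each gene's variance is
#' shrunk towards the prior, and the t statistic is referred to a t
#' distribution with residual + prior degrees of freedom.  `log2FC` is the
#' plain group-mean difference on the input scale (z-score or log2), with
#' sign `mean(groupA) - mean(groupB)`.
#'
#' @param matrix an [ExpressionMatrix-class] or plain named matrix.
#' @param groupA,groupB disjoint sample-id vectors, >= 2 samples each
#'   (defective first, so positive log2FC means up in defective).
#' @param priorDf `NULL` to estimate the prior df (default) or `0` to disable
#'   shrinkage, in which case the statistics are the ordinary pooled t.
#' @return data.frame(gene, log2FC, t, p, q) plus attributes `df.prior`,
#'   `var.prior`, `df.total`.
#' @export
fitModeratedDE <- function(matrix, groupA, groupB, priorDf = NULL) {
  v <- asExprMatrix(matrix)
  if (length(intersect(groupA, groupB)))
    stop("groupA and groupB overlap")
  missing <- setdiff(c(groupA, groupB), colnames(v))
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("need >= 2 samples per group")
  a <- v[, groupA, drop = FALSE]
  b <- v[, groupB, drop = FALSE]
  nA <- length(groupA); nB <- length(groupB)
  s2 <- ((nA - 1) * rowVars(a) + (nB - 1) * rowVars(b)) / (nA + nB - 2)
  st <- .moderatedStats(rowMeans(a), rowMeans(b), s2, nA, nB, priorDf)
  out <- data.frame(gene = rownames(v), log2FC = st$log2FC, t = st$t,
                    p = st$p, q = bhAdjust(st$p), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "df.prior") <- st$df.prior
  attr(out, "var.prior") <- st$var.prior
  attr(out, "df.total") <- st$df.total
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return monotone step-up adjusted q-values.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Initial gene selection from a differential-expression table
#'
#' Keeps genes with `|log2FC| >= fcCut` (default 0.585, i.e. 1.5-fold) and
#' BH-adjusted `q < qCut` (default 0.1, strict).
#'
#' @param de data.frame from [fitModeratedDE].
#' @param fcCut,qCut selection thresholds.
#' @return character vector of selected genes.
#' @export
initialGeneSelection <- function(de, fcCut = 0.585, qCut = 0.1) {
  de$gene[abs(de$log2FC) >= fcCut & de$q < qCut]
}

#' Leave-one-out subsampling robustness of differential expression
#'
#' For each of the n*m subsets formed by removing one defective and one
#' proficient sample, the moderated-t fit is rerun restricted to
#' `candidateGenes` (BH adjustment within the candidate set) and each gene's
#' pass at the strict thresholds `|log2FC| >= fcCut` (default 1) and
#' `q < qCut` (default 0.1) is recorded.  The robustness fraction is the
#' share of subsets passed.  `meanZDefective` (mean expression over the full
#' defective group) and `directionConsistency` (fraction of defective samples
#' whose value-sign matches the sign of the mean; exact zeros count as
#' non-matching) are computed once on the full defective group.
#'
#' The subset loop uses an incremental sufficient-statistics update (group
#' sums and sums of squares with one sample deleted), which is exact and
#' identical to refitting each subset from scratch.
#'
#' @param matrix an [ExpressionMatrix-class] or named matrix (z-score scale
#'   expected; the mean-z filter downstream assumes it).
#' @param groups a [DiscoveryGroups-class] with n >= 2 and m >= 2.
#' @param candidateGenes genes to track (typically [initialGeneSelection]).
#' @param fcCut,qCut strict per-subset thresholds.
#' @param maxSubsets guard against accidental huge enumerations.
#' @param priorDf passed to the moderated fit.
#' @return data.frame(gene, robustness_fraction, mean_z_defective,
#'   direction_consistency) with attribute `n_subsets = n * m`.
#' @export
lool <- function(matrix, groups, candidateGenes, fcCut = 1, qCut = 0.1,
                 maxSubsets = 250000, priorDf = NULL) {
  v <- asExprMatrix(matrix)
  def <- defectiveSamples(groups)
  prof <- proficientSamples(groups)
  if (length(def) < 3 || length(prof) < 3)
    stop("leave-one-out requires >= 3 samples per group (each subset must retain >= 2)")
  missing <- setdiff(candidateGenes, rownames(v))
  if (length(missing))
    stop("candidate gene(s) not in matrix: ", paste(missing, collapse = ", "))
  n <- length(def); m <- length(prof)
  if (n * m > maxSubsets)
    stop(sprintf(paste0("n*m = %d exceeds maxSubsets = %d; subsample the ",
                        "groups or raise maxSubsets"), n * m, maxSubsets))
  x <- v[candidateGenes, , drop = FALSE]
  a <- x[, def, drop = FALSE]
  b <- x[, prof, drop = FALSE]
  sumA <- rowSums(a); sqA <- rowSums(a^2)
  sumB <- rowSums(b); sqB <- rowSums(b^2)
  passes <- stats::setNames(numeric(length(candidateGenes)), candidateGenes)
  for (i in seq_len(n)) {
    sA <- sumA - a[, i]; qA <- sqA - a[, i]^2
    mA <- sA / (n - 1)
    ssA <- pmax(qA - (n - 1) * mA^2, 0)
    for (j in seq_len(m)) {
      sB <- sumB - b[, j]; qB <- sqB - b[, j]^2
      mB <- sB / (m - 1)
      ssB <- pmax(qB - (m - 1) * mB^2, 0)
      s2 <- (ssA + ssB) / (n - 1 + m - 1 - 2)
      st <- .moderatedStats(mA, mB, s2, n - 1, m - 1, priorDf)
      qv <- bhAdjust(st$p)
      passes <- passes + (abs(st$log2FC) >= fcCut & qv < qCut)
    }
  }
  meanZ <- rowMeans(a)
  # column-major recycling compares every sample column against the per-gene
  # mean sign; exact zeros never match
  consistency <- rowMeans(sign(a) == sign(meanZ) & sign(a) != 0)
  out <- data.frame(gene = candidateGenes,
                    robustness_fraction = unname(passes) / (n * m),
                    mean_z_defective = unname(meanZ),
                    direction_consistency = unname(consistency),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_subsets") <- n * m
  out
}

#' Final gene filter on a leave-one-out robustness table
#'
#' Retains genes with robustness fraction >= `minFraction`, absolute mean
#' defective-group z >= `minMeanZ` (default 0.2) and direction consistency
#' >= `minConsistency` (default 0.6).  Per-gene directions are the signs of
#' the mean defective-group z.  An empty result yields a signature flagged
#' invalid rather than an error.
#'
#' @param loolResult data.frame from [lool].
#' @param minFraction robustness-fraction threshold (0.20 proteogenomic;
#'   see [loolPancancerFraction] for the genomic variant).
#' @param minMeanZ,minConsistency remaining thresholds.
#' @param metadata metadata list stored in the signature.
#' @return An [RbSignature-class]; `isValidSignature()` is FALSE when empty.
#' @export
finalGeneFilter <- function(loolResult, minFraction = 0.20, minMeanZ = 0.2,
                            minConsistency = 0.60, metadata = list()) {
  keep <- loolResult$robustness_fraction >= minFraction &
    abs(loolResult$mean_z_defective) >= minMeanZ &
    loolResult$direction_consistency >= minConsistency
  sel <- loolResult[keep, , drop = FALSE]
  metadata <- utils::modifyList(metadata, list(
    min_fraction = minFraction, min_mean_z = minMeanZ,
    min_consistency = minConsistency))
  RbSignature(genes = sel$gene, directions = sign(sel$mean_z_defective),
              meanZ = sel$mean_z_defective, metadata = metadata,
              valid = nrow(sel) > 0)
}

#' Robustness-fraction threshold for the genomic (pan-cancer) variant
#'
#' Cancer types with more than 20 initially selected genes use the stringent
#' 50% fraction; 20 or fewer use the lenient 20% (the boundary count of
#' exactly 20 is assigned to the lenient branch).
#'
#' @param nInitialGenes number of initially selected genes.
#' @return 0.50 or 0.20.
#' @export
loolPancancerFraction <- function(nInitialGenes) {
  stopifnot(nInitialGenes >= 0)
  if (nInitialGenes > 20) 0.50 else 0.20
}

#' Run the full discovery chain: initial selection, leave-one-out, final filter
#'
#' @param matrix z-scored [ExpressionMatrix-class] (or named matrix).
#' @param groups a [DiscoveryGroups-class].
#' @param metadata metadata list stored in the signature.
#' @param ... passed to [lool] (e.g. `maxSubsets`, `priorDf`).
#' @return An [RbSignature-class] with the robustness table in
#'   `signatureMetadata()$lool_report`.
#' @export
discoverSignature <- function(matrix, groups, metadata = list(), ...) {
  de <- fitModeratedDE(matrix, defectiveSamples(groups),
                       proficientSamples(groups))
  candidates <- initialGeneSelection(de)
  genomic <- platformTag(groups) == "genomic"
  minFraction <- if (genomic) loolPancancerFraction(length(candidates))
                 else 0.20
  if (!length(candidates)) {
    return(RbSignature(character(0), numeric(0), numeric(0),
                       metadata = utils::modifyList(metadata, list(
                         min_fraction = minFraction)), valid = FALSE))
  }
  lr <- lool(matrix, groups, candidates, ...)
  sig <- finalGeneFilter(lr, minFraction = minFraction, metadata = metadata)
  sig@metadata$lool_report <- lr
  sig@metadata$n_initial_genes <- length(candidates)
  sig
}
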