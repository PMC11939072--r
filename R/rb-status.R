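# RB1 functional-status calling and discovery-group assembly.
#
# Two variants exist.  The proteogenomic variant (platforms "tcga" and
# "cptac23") uses total Rb protein, median phospho-Rb, truncating mutations
# and deep deletions to call defective samples, and requires high Rb protein
# plus an RB1 mRNA z-score soft filter for proficient samples.  The genomic
# variant (pan-cancer, no proteomics) calls defective on truncating/splice
# mutations or copy-number deletion and takes the top-M RB1-mRNA samples as
# the proficient group.

# Platform-specific low-Rb protein cutoffs.
.lowRbCut <- c(tcga = -0.2, cptac23 = -0.7)

#' Classify a copy-number log2 ratio into a discrete CNA state
#'
#' Bands: |r| < 0.3 neutral; 0.3 <= |r| <= 1 gain/loss by sign; |r| > 1
#' amplification / deep deletion by sign.
#'
#' @param log2Ratio numeric vector of finite log2 copy-number ratios.
#' @return character vector over
#'   \{deep_deletion, loss, neutral, gain, amplification\}.
#' @examples
#' callCnaState(c(-1.2, 0.5, 0))  # deep_deletion, gain, neutral
#' @export
callCnaState <- function(log2Ratio) {
  if (!is.numeric(log2Ratio) || any(!is.finite(log2Ratio)))
    stop("log2Ratio must be finite numeric")
  a <- abs(log2Ratio)
  state <- rep("neutral", length(log2Ratio))
  state[a >= 0.3 & a <= 1 & log2Ratio > 0] <- "gain"
  state[a >= 0.3 & a <= 1 & log2Ratio < 0] <- "loss"
  state[a > 1 & log2Ratio > 0] <- "amplification"
  state[a > 1 & log2Ratio < 0] <- "deep_deletion"
  state
}

#' Median phospho-Rb across measured sites
#'
#' Empty site lists return `NA` (the "no phospho data" sentinel): the
#' hyperphosphorylation rule is then unevaluable, not failed, and the sample
#' can still be called defective by the other rules.
#'
#' @param siteValues numeric vector of per-site phospho-Rb values.
#' @return median value, or `NA_real_` for an empty list.
#' @export
medianPrb <- function(siteValues) {
  if (length(siteValues) == 0) return(NA_real_)
  stats::median(as.numeric(siteValues))
}

#' Call RB1 status for one sample
#'
#' Proteogenomic rules (platforms `"tcga"`, `"cptac23"`): defective iff
#' total Rb <= platform low-Rb cut (-0.2 for TCGA, -0.7 for CPTAC phase 2/3),
#' OR hyperphosphorylation (median pRb >= 0.3 AND Rb <= 0.2 AND
#' pRb - Rb >= 0.2), OR a truncating RB1 mutation, OR an RB1 deep deletion.
#' Proficient iff no truncating mutation, no deep deletion, Rb > 0 and RB1
#' mRNA z >= 0.2 (the soft filter against occult loss).  Missense mutations
#' force indeterminate regardless of the other modalities.  With platform
#' `"genomic"` only the mutation (truncating or splice) and CNA rules apply.
#' Any modality may be missing (`NA`/`NULL`), but not all of them.
#'
#' @param rb total Rb protein abundance (iTRAQ-ratio-like), or NA.
#' @param prbSites numeric vector of phospho-site values (possibly empty).
#' @param mutationClass one of truncating, splice, missense, other, none, or NA.
#' @param cnaLog2 RB1 copy-number log2 ratio, or NA.
#' @param mrnaZ RB1 mRNA z-score, or NA.
#' @param platform `"tcga"`, `"cptac23"` or `"genomic"`.
#' @param includeLoss genomic variant only: also count shallow loss
#'   (-1 <= r <= -0.3) as a copy-number defect.
#' @return list with elements `status` (defective/proficient/indeterminate)
#'   and `evidence` (character vector of evidence flags).
#' @export
callRbStatus <- function(rb = NA, prbSites = numeric(0),
                         mutationClass = "none", cnaLog2 = NA, mrnaZ = NA,
                         platform = c("tcga", "cptac23", "genomic"),
                         includeLoss = FALSE) {
  platform <- match.arg(platform)
  if (is.null(rb)) rb <- NA_real_
  if (is.null(cnaLog2)) cnaLog2 <- NA_real_
  if (is.null(mrnaZ)) mrnaZ <- NA_real_
  if (is.null(mutationClass) || is.na(mutationClass)) mutationClass <- "none"
  prb <- medianPrb(prbSites)
  if (is.na(rb) && is.na(prb) && mutationClass == "none" && is.na(cnaLog2) &&
      is.na(mrnaZ) && length(prbSites) == 0)
    stop("all modalities missing; cannot call RB1 status")

  cnaState <- if (is.na(cnaLog2)) "neutral" else callCnaState(cnaLog2)
  flags <- character(0)
  if (mutationClass == "truncating") flags <- c(flags, "truncating_mut")
  if (mutationClass == "splice") flags <- c(flags, "splice_mut")
  if (cnaState == "deep_deletion") flags <- c(flags, "deep_deletion")
  if (includeLoss && platform == "genomic" && cnaState == "loss")
    flags <- c(flags, "deep_deletion")

  if (mutationClass == "missense")
    return(list(status = "indeterminate",
                evidence = c(flags, "missense_excluded")))

  if (platform == "genomic") {
    defect <- any(c("truncating_mut", "splice_mut", "deep_deletion") %in% flags)
    return(list(status = if (defect) "defective" else "indeterminate",
                evidence = flags))
  }

  if (!is.na(rb) && rb <= .lowRbCut[[platform]]) flags <- c(flags, "low_rb")
  # the subtraction gets a tiny tolerance so printed values like
  # pRb 0.35 / Rb 0.15 (difference exactly 0.2) are not lost to rounding
  if (!is.na(rb) && !is.na(prb) && prb >= 0.3 && rb <= 0.2 &&
      prb - rb >= 0.2 - 1e-9)
    flags <- c(flags, "hyperphospho")

  defectFlags <- c("low_rb", "hyperphospho", "truncating_mut", "deep_deletion")
  if (any(defectFlags %in% flags))
    return(list(status = "defective", evidence = flags))

  if (!("truncating_mut" %in% flags) && !("deep_deletion" %in% flags) &&
      !is.na(rb) && rb > 0 && !is.na(mrnaZ) && mrnaZ >= 0.2)
    return(list(status = "proficient", evidence = c(flags, "high_rb_mrna")))

  list(status = "indeterminate", evidence = flags)
}

# Per-sample modalities of a cohort, assembled for calling.
.cohortModalities <- function(cohort, rb1Gene = "RB1") {
  samples <- sampleIds(cohort@expression)
  z <- zscoreByGene(cohort@expression)
  mrnaZ <- if (rb1Gene %in% geneIds(z))
    exprValues(z)[rb1Gene, ] else stats::setNames(rep(NA_real_,
                                                      length(samples)), samples)
  mut <- cohort@mutations
  mut <- mut[mut$gene == rb1Gene, , drop = FALSE]
  mutClass <- stats::setNames(rep("none", length(samples)), samples)
  mutClass[mut$sample] <- mut$variant_class
  cna <- cohort@cna
  cna <- cna[cna$gene == rb1Gene, , drop = FALSE]
  cnaLog2 <- stats::setNames(rep(NA_real_, length(samples)), samples)
  cnaLog2[cna$sample] <- cna$log2_ratio
  list(samples = samples, rb = cohort@protein[samples],
       phospho = cohort@phospho[samples], mutClass = mutClass,
       cnaLog2 = cnaLog2, mrnaZ = mrnaZ[samples])
}

#' Call RB1 status for every sample of a cohort
#'
#' @param cohort a [SyntheticCohort-class] (or any object with the same slots).
#' @param platform `"tcga"`, `"cptac23"` or `"genomic"`.
#' @param rb1Gene id of the RB1 gene row in the expression matrix.
#' @param includeLoss see [callRbStatus].
#' @return data.frame(sample, status, evidence) with `evidence` a
#'   comma-separated flag list.
#' @export
callRbStatusCohort <- function(cohort, platform = c("tcga", "cptac23",
                                                    "genomic"),
                               rb1Gene = "RB1", includeLoss = FALSE) {
  platform <- match.arg(platform)
  mod <- .cohortModalities(cohort, rb1Gene)
  calls <- lapply(seq_along(mod$samples), function(i) {
    callRbStatus(rb = mod$rb[[i]], prbSites = mod$phospho[[i]],
                 mutationClass = mod$mutClass[[i]], cnaLog2 = mod$cnaLog2[[i]],
                 mrnaZ = mod$mrnaZ[[i]], platform = platform,
                 includeLoss = includeLoss)
  })
  data.frame(sample = mod$samples,
             status = vapply(calls, `[[`, "", "status"),
             evidence = vapply(calls, function(x)
               paste(x$evidence, collapse = ","), ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble proteogenomic discovery groups
#'
#' Defective group = union (deduplicated) of all samples called defective by
#' any rule; proficient group = all samples called proficient.  Either group
#' empty is an error.
#'
#' @param statusCalls data.frame from [callRbStatusCohort], or a
#'   [SyntheticCohort-class] to call first.
#' @param platform `"tcga"` or `"cptac23"`.
#' @param ... passed to [callRbStatusCohort] when a cohort is supplied.
#' @return A [DiscoveryGroups-class].
#' @export
selectDiscoveryGroups <- function(statusCalls, platform = c("tcga", "cptac23"),
                                  ...) {
  platform <- match.arg(platform)
  if (is(statusCalls, "SyntheticCohort"))
    statusCalls <- callRbStatusCohort(statusCalls, platform = platform, ...)
  defective <- unique(statusCalls$sample[statusCalls$status == "defective"])
  proficient <- unique(statusCalls$sample[statusCalls$status == "proficient"])
  if (!length(defective)) stop("empty RB1-defective group")
  if (!length(proficient)) stop("empty RB1-proficient group")
  DiscoveryGroups(defective, proficient, platform)
}

#' Assemble genomic (pan-cancer) discovery groups
#'
#' Defective group (size M) = samples with a truncating or splice RB1
#' mutation or an RB1 copy-number deletion; requires M >= 3.  Proficient
#' group = the top-M samples by RB1 mRNA z-score among samples that are
#' neither defective nor missense carriers, so the groups are balanced.
#' Ties at the M-th z value break by lexicographic sample id.
#'
#' @param cohort a [SyntheticCohort-class]-like object.
#' @param rb1Gene RB1 gene id.
#' @param includeLoss also count shallow loss as a copy-number defect.
#' @return A [DiscoveryGroups-class] with `platform = "genomic"`.
#' @export
selectDiscoveryGroupsGenomic <- function(cohort, rb1Gene = "RB1",
                                         includeLoss = FALSE) {
  calls <- callRbStatusCohort(cohort, platform = "genomic",
                              rb1Gene = rb1Gene, includeLoss = includeLoss)
  defective <- calls$sample[calls$status == "defective"]
  M <- length(defective)
  if (M < 3)
    stop(sprintf("genomic variant needs at least 3 defective samples, found %d", M))
  missense <- calls$sample[grepl("missense_excluded", calls$evidence)]
  pool <- setdiff(calls$sample, c(defective, missense))
  z <- exprValues(zscoreByGene(cohort@expression))[rb1Gene, pool]
  if (length(pool) < M)
    stop("not enough non-defective samples for a balanced proficient group")
  ord <- order(-z, pool)  # ties break by sample id
  DiscoveryGroups(defective, pool[ord][seq_len(M)], "genomic")
}
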