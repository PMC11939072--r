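#' @import methods
NULL

#' Gene-by-sample expression matrix with a declared value kind
#'
#' Thin S4 container for a numeric gene x sample matrix tagged with the scale
#' its values live on: per-gene `"zscore"` standardised values or `"log2"`
#' abundances.  Gene and sample identifiers are the (unique) dimnames.
#'
#' @slot values numeric matrix, genes in rows, samples in columns.
#' @slot valueKind `"zscore"` or `"log2"`.
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", valueKind = "character"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must carry gene rownames and sample colnames")
  else {
    if (anyDuplicated(rownames(v))) msgs <- c(msgs, "duplicate gene ids")
    if (anyDuplicated(colnames(v))) msgs <- c(msgs, "duplicate sample ids")
  }
  if (length(object@valueKind) != 1L ||
      !object@valueKind %in% c("zscore", "log2"))
    msgs <- c(msgs, "valueKind must be 'zscore' or 'log2'")
  if (any(!is.finite(v))) msgs <- c(msgs, "values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix with gene rownames and sample colnames.
#' @param valueKind `"zscore"` or `"log2"`.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' ExpressionMatrix(m, "log2")
#' @export
ExpressionMatrix <- function(values, valueKind = c("zscore", "log2")) {
  valueKind <- match.arg(valueKind)
  new("ExpressionMatrix", values = as.matrix(values), valueKind = valueKind)
}

#' A gene signature with per-gene directions
#'
#' Ordered gene list with per-gene direction (+1 for genes up in the
#' RB1-defective state, -1 for genes down), the mean defective-group z-score
#' the direction was derived from (NA when unknown), free-form metadata, and a
#' validity flag (a discovery or consensus step that ends empty marks the
#' signature invalid rather than erroring).
#'
#' @slot genes character vector of unique gene ids.
#' @slot directions numeric vector of +1/-1, parallel to `genes`.
#' @slot meanZ numeric vector parallel to `genes` (NA allowed).
#' @slot metadata list of provenance fields (cancer-type tag, thresholds, ...).
#' @slot valid logical scalar.
#' @export
setClass("RbSignature",
  representation(genes = "character", directions = "numeric",
                 meanZ = "numeric", metadata = "list", valid = "logical"))

setValidity("RbSignature", function(object) {
  msgs <- character()
  n <- length(object@genes)
  if (anyDuplicated(object@genes)) msgs <- c(msgs, "duplicate signature genes")
  if (length(object@directions) != n || length(object@meanZ) != n)
    msgs <- c(msgs, "genes, directions and meanZ must be parallel")
  if (n > 0 && !all(object@directions %in% c(-1, 1)))
    msgs <- c(msgs, "directions must be +1 or -1")
  if (length(object@valid) != 1L) msgs <- c(msgs, "valid must be a scalar")
  if (length(msgs)) msgs else TRUE
})

#' Construct an RbSignature
#'
#' @param genes character vector of gene ids.
#' @param directions +1/-1 per gene.
#' @param meanZ optional mean defective-group z per gene.
#' @param metadata list of provenance fields.
#' @param valid logical; empty signatures are invalid by construction.
#' @return An [RbSignature-class] object.
#' @export
RbSignature <- function(genes, directions, meanZ = rep(NA_real_, length(genes)),
                        metadata = list(), valid = length(genes) > 0) {
  new("RbSignature", genes = as.character(genes),
      directions = as.numeric(directions), meanZ = as.numeric(meanZ),
      metadata = metadata, valid = isTRUE(valid))
}

#' Discovery groups of RB1-defective and RB1-proficient samples
#'
#' @slot defective character vector of sample ids (size n; M in the
#'   genomic/pan-cancer variant).
#' @slot proficient character vector of sample ids (size m).
#' @slot platform `"tcga"`, `"cptac23"` or `"genomic"`.
#' @export
setClass("DiscoveryGroups",
  representation(defective = "character", proficient = "character",
                 platform = "character"))

setValidity("DiscoveryGroups", function(object) {
  msgs <- character()
  if (length(intersect(object@defective, object@proficient)))
    msgs <- c(msgs, "defective and proficient groups must be disjoint")
  if (!object@platform %in% c("tcga", "cptac23", "genomic"))
    msgs <- c(msgs, "platform must be tcga, cptac23 or genomic")
  if (object@platform == "genomic") {
    if (length(object@defective) < 3)
      msgs <- c(msgs, "genomic variant requires at least 3 defective samples")
    if (length(object@defective) != length(object@proficient))
      msgs <- c(msgs, "genomic variant requires balanced groups")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DiscoveryGroups object
#'
#' @param defective,proficient character vectors of sample ids.
#' @param platform `"tcga"`, `"cptac23"` or `"genomic"`.
#' @export
DiscoveryGroups <- function(defective, proficient, platform = "tcga") {
  new("DiscoveryGroups", defective = as.character(defective),
      proficient = as.character(proficient), platform = platform)
}

#' Specification of a synthetic cohort
#'
#' Parameters of the simulated discovery population: cohort dimensions, the
#' planted signature, the fractions of truly RB1-defective and of phenocopy
#' (expression-only) samples, effect and noise sizes on the log2 scale, and
#' the fraction of samples with no phospho-site measurements.
#'
#' @slot nGenes,nSamples,nSignatureGenes integer counts.
#' @slot fracDefective,fracPhenocopy fractions in `[0, 1]` summing to at most 1.
#' @slot effectLog2fc planted |log2 fold change| on signature genes.
#' @slot noiseSd residual SD of the log2 values (> 0).
#' @slot fracMissingPhospho fraction of samples with an empty phospho-site list.
#' @slot seed integer RNG seed; identical spec + seed gives identical cohorts.
#' @export
setClass("CohortSpec",
  representation(nGenes = "integer", nSamples = "integer",
                 nSignatureGenes = "integer", fracDefective = "numeric",
                 fracPhenocopy = "numeric", effectLog2fc = "numeric",
                 noiseSd = "numeric", fracMissingPhospho = "numeric",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  msgs <- character()
  chkCount <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 1L)
      sprintf("%s must be a positive count", nm) else character()
  }
  chkFrac <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
      sprintf("%s must be a fraction in [0, 1]", nm) else character()
  }
  msgs <- c(msgs, chkCount(object@nGenes, "nGenes"),
            chkCount(object@nSamples, "nSamples"),
            chkCount(object@nSignatureGenes, "nSignatureGenes"),
            chkFrac(object@fracDefective, "fracDefective"),
            chkFrac(object@fracPhenocopy, "fracPhenocopy"),
            chkFrac(object@fracMissingPhospho, "fracMissingPhospho"))
  if (length(object@noiseSd) != 1L || is.na(object@noiseSd) ||
      object@noiseSd <= 0)
    msgs <- c(msgs, "noiseSd must be > 0")
  if (length(object@effectLog2fc) != 1L || is.na(object@effectLog2fc) ||
      object@effectLog2fc < 0)
    msgs <- c(msgs, "effectLog2fc must be >= 0")
  if (!length(msgs)) {
    if (object@fracDefective + object@fracPhenocopy > 1)
      msgs <- c(msgs, "fracDefective + fracPhenocopy must be <= 1")
    if (object@nSignatureGenes >= object@nGenes)
      msgs <- c(msgs, "nSignatureGenes must be < nGenes")
  }
  if (length(msgs)) msgs else TRUE
})

#' A generated synthetic cohort
#'
#' Matched expression / protein / phospho / mutation / copy-number tables with
#' known ground truth: per-sample labels (defective, phenocopy, background)
#' and the planted signature genes with their planted directions.
#'
#' @slot expression [ExpressionMatrix-class] of log2 values (includes an RB1 row).
#' @slot protein named numeric vector of per-sample total Rb abundance.
#' @slot phospho named list of per-sample phospho-Rb site values (possibly empty).
#' @slot mutations data.frame with columns sample, gene, variant_class.
#' @slot cna data.frame with columns sample, gene, log2_ratio.
#' @slot truth named character vector: defective / phenocopy / background.
#' @slot truthGenes data.frame with columns gene, direction (+1/-1).
#' @slot spec the [CohortSpec-class] the cohort was generated from.
#' @export
setClass("SyntheticCohort",
  representation(expression = "ExpressionMatrix", protein = "numeric",
                 phospho = "list", mutations = "data.frame",
                 cna = "data.frame", truth = "character",
                 truthGenes = "data.frame", spec = "CohortSpec"))

#' One expression scale of the relevance-network refinement
#'
#' Result of the threshold grid search at a single RB1 expression scale alpha:
#' the accuracy-optimal Spearman threshold c*, the accuracy it achieves, and
#' the genes still connected (degree >= 1) at c*.  Scales with an empty RB1
#' high or low sample side are flagged unusable.
#'
#' @slot alpha RB1 z-score scale.
#' @slot cStar optimal threshold (NA if unusable).
#' @slot accuracy classification accuracy at cStar (NA if unusable).
#' @slot connectedGenes character vector of connected genes at cStar.
#' @slot usable logical.
#' @slot nHigh,nLow sizes of the RB1-high and RB1-low sample sets.
#' @export
setClass("ScaleResult",
  representation(alpha = "numeric", cStar = "numeric", accuracy = "numeric",
                 connectedGenes = "character", usable = "logical",
                 nHigh = "integer", nLow = "integer"))
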