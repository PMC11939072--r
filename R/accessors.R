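#' @describeIn ExpressionMatrix-class the numeric gene x sample matrix.
#' @param object an object of the documented class.
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))
#' @export
setMethod("exprValues", "ExpressionMatrix", function(object) object@values)

#' @describeIn ExpressionMatrix-class value kind, `"zscore"` or `"log2"`.
#' @export
setGeneric("valueKind", function(object) standardGeneric("valueKind"))
#' @export
setMethod("valueKind", "ExpressionMatrix", function(object) object@valueKind)

#' @describeIn ExpressionMatrix-class gene identifiers (row order).
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @export
setMethod("geneIds", "ExpressionMatrix", function(object) rownames(object@values))

#' @describeIn ExpressionMatrix-class sample identifiers (column order).
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(object) colnames(object@values))

#' Subset an ExpressionMatrix by gene and/or sample
#'
#' @param x an [ExpressionMatrix-class].
#' @param i,j gene and sample indices (names, integers or logicals).
#' @param ... ignored.
#' @param drop ignored; the class is always preserved.
#' @export
setMethod("[", "ExpressionMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  new("ExpressionMatrix", values = v, valueKind = x@valueKind)
})

#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s values)\n",
              nrow(object@values), ncol(object@values), object@valueKind))
})

#' @describeIn RbSignature-class signature gene ids.
#' @export
setGeneric("signatureGenes", function(object) standardGeneric("signatureGenes"))
#' @export
setMethod("signatureGenes", "RbSignature", function(object) object@genes)

#' @describeIn RbSignature-class named vector of +1/-1 directions.
#' @export
setGeneric("signatureDirections",
           function(object) standardGeneric("signatureDirections"))
#' @export
setMethod("signatureDirections", "RbSignature",
          function(object) stats::setNames(object@directions, object@genes))

#' @describeIn RbSignature-class named vector of mean defective-group z-scores.
#' @export
setGeneric("signatureMeanZ", function(object) standardGeneric("signatureMeanZ"))
#' @export
setMethod("signatureMeanZ", "RbSignature",
          function(object) stats::setNames(object@meanZ, object@genes))

#' @describeIn RbSignature-class TRUE unless a discovery/consensus step ended empty.
#' @export
setGeneric("isValidSignature", function(object) standardGeneric("isValidSignature"))
#' @export
setMethod("isValidSignature", "RbSignature", function(object) object@valid)

#' @describeIn RbSignature-class provenance metadata list.
#' @export
setGeneric("signatureMetadata",
           function(object) standardGeneric("signatureMetadata"))
#' @export
setMethod("signatureMetadata", "RbSignature", function(object) object@metadata)

#' @export
setMethod("length", "RbSignature", function(x) length(x@genes))

setMethod("show", "RbSignature", function(object) {
  up <- sum(object@directions > 0)
  cat(sprintf("RbSignature: %d genes (%d up, %d down)%s\n",
              length(object@genes), up, length(object@genes) - up,
              if (object@valid) "" else " [INVALID: empty discovery result]"))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' @describeIn DiscoveryGroups-class defective sample ids.
#' @export
setGeneric("defectiveSamples",
           function(object) standardGeneric("defectiveSamples"))
#' @export
setMethod("defectiveSamples", "DiscoveryGroups", function(object) object@defective)

#' @describeIn DiscoveryGroups-class proficient sample ids.
#' @export
setGeneric("proficientSamples",
           function(object) standardGeneric("proficientSamples"))
#' @export
setMethod("proficientSamples", "DiscoveryGroups",
          function(object) object@proficient)

#' @describeIn DiscoveryGroups-class platform tag.
#' @export
setGeneric("platformTag", function(object) standardGeneric("platformTag"))
#' @export
setMethod("platformTag", "DiscoveryGroups", function(object) object@platform)

setMethod("show", "DiscoveryGroups", function(object) {
  cat(sprintf("DiscoveryGroups (%s): %d defective, %d proficient\n",
              object@platform, length(object@defective),
              length(object@proficient)))
})

#' @describeIn SyntheticCohort-class the log2 [ExpressionMatrix-class].
#' @export
setGeneric("cohortExpression",
           function(object) standardGeneric("cohortExpression"))
#' @export
setMethod("cohortExpression", "SyntheticCohort",
          function(object) object@expression)

#' @describeIn SyntheticCohort-class named per-sample truth labels.
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(object) object@truth)

#' @describeIn SyntheticCohort-class planted signature genes and directions.
#' @export
setGeneric("cohortTruthGenes",
           function(object) standardGeneric("cohortTruthGenes"))
#' @export
setMethod("cohortTruthGenes", "SyntheticCohort",
          function(object) object@truthGenes)

#' @describeIn SyntheticCohort-class named per-sample total Rb abundance.
#' @export
setGeneric("cohortProtein", function(object) standardGeneric("cohortProtein"))
#' @export
setMethod("cohortProtein", "SyntheticCohort", function(object) object@protein)

#' @describeIn SyntheticCohort-class named list of per-sample phospho-site values.
#' @export
setGeneric("cohortPhospho", function(object) standardGeneric("cohortPhospho"))
#' @export
setMethod("cohortPhospho", "SyntheticCohort", function(object) object@phospho)

#' @describeIn SyntheticCohort-class mutation records (sample, gene, variant_class).
#' @export
setGeneric("cohortMutations",
           function(object) standardGeneric("cohortMutations"))
#' @export
setMethod("cohortMutations", "SyntheticCohort", function(object) object@mutations)

#' @describeIn SyntheticCohort-class copy-number records (sample, gene, log2_ratio).
#' @export
setGeneric("cohortCna", function(object) standardGeneric("cohortCna"))
#' @export
setMethod("cohortCna", "SyntheticCohort", function(object) object@cna)

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(factor(object@truth,
                      c("defective", "phenocopy", "background")))
  cat(sprintf(paste0("SyntheticCohort: %d genes x %d samples ",
                     "(%d defective, %d phenocopy, %d background)\n"),
              nrow(object@expression@values), ncol(object@expression@values),
              tab[["defective"]], tab[["phenocopy"]], tab[["background"]]))
  cat(sprintf("  planted signature: %d genes\n", nrow(object@truthGenes)))
})

setMethod("show", "ScaleResult", function(object) {
  if (object@usable)
    cat(sprintf(
      "ScaleResult alpha=%.1f: c*=%.2f, accuracy=%.3f, %d connected genes (%d high / %d low samples)\n",
      object@alpha, object@cStar, object@accuracy,
      length(object@connectedGenes), object@nHigh, object@nLow))
  else
    cat(sprintf("ScaleResult alpha=%.1f: unusable (%d high / %d low samples)\n",
                object@alpha, object@nHigh, object@nLow))
})
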