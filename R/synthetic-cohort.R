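# Synthetic cohort generator.  Emulates the statistical structure of a
# proteogenomic discovery cohort: a defective group whose samples each carry
# one randomly chosen RB1 lesion (low Rb protein, hyperphosphorylated Rb,
# truncating mutation, or deep deletion), a phenocopy group that shares only
# the planted expression shift, correlated or exchangeable noise genes,
# missing phospho-sites, and matched screen tables with planted
# synthetic-lethal genes.

#' Construct a CohortSpec
#'
#' Defaults describe the reference discovery population used throughout the
#' package's validation: 2000 genes, 100 samples, 40 planted signature genes
#' at |log2FC| 1.5, 20% defective and 10% phenocopy samples, residual SD 0.5
#' and 10% of samples without phospho data.
#'
#' @param nGenes,nSamples,nSignatureGenes cohort dimensions.
#' @param fracDefective,fracPhenocopy group fractions (round-half-up of
#'   `frac * nSamples` samples each).
#' @param effectLog2fc planted |log2 fold change| on signature genes
#'   (per-gene sign drawn 50/50).
#' @param noiseSd residual SD of the log2 values.
#' @param fracMissingPhospho fraction of samples with an empty phospho list.
#' @param seed RNG seed.
#' @return A validated [CohortSpec-class].
#' @export
cohortSpec <- function(nGenes = 2000, nSamples = 100, nSignatureGenes = 40,
                       fracDefective = 0.2, fracPhenocopy = 0.1,
                       effectLog2fc = 1.5, noiseSd = 0.5,
                       fracMissingPhospho = 0.1, seed = 1) {
  new("CohortSpec", nGenes = as.integer(nGenes),
      nSamples = as.integer(nSamples),
      nSignatureGenes = as.integer(nSignatureGenes),
      fracDefective = fracDefective, fracPhenocopy = fracPhenocopy,
      effectLog2fc = effectLog2fc, noiseSd = noiseSd,
      fracMissingPhospho = fracMissingPhospho, seed = as.integer(seed))
}

# Offsets of the RB1 mRNA row relative to the gene baseline: clearly low in
# defective and phenocopy samples, clearly high in background samples, so the
# proficiency soft filter (z >= 0.2) and the refinement scale selection both
# see a well-separated RB1 axis.
.rb1LowShift <- -3
.rb1HighShift <- 1

#' Generate a synthetic proteogenomic cohort
#'
#' Expression is drawn as Gaussian log2-like values (per-gene baseline
#' N(7, 1), residual SD `noiseSd`); planted signature genes are shifted by
#' `sign * effectLog2fc` in defective and phenocopy samples.  Each defective
#' sample is made to pass exactly one randomly chosen defective rule; each
#' phenocopy sample passes none (normal protein, no mutation, neutral copy
#' number) while carrying the full expression shift.  The matrix includes an
#' `RB1` row that is low in defective/phenocopy and high in background
#' samples.  Identical spec + seed gives bit-identical cohorts.
#'
#' @param spec a [CohortSpec-class] (see [cohortSpec]).
#' @return A [SyntheticCohort-class] with a log2 [ExpressionMatrix-class];
#'   z-score it with [zscoreByGene] before discovery.
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    nG <- spec@nGenes; nS <- spec@nSamples
    genes <- c("RB1", sprintf("gene_%04d", seq_len(nG - 1)))
    samples <- sprintf("s%04d", seq_len(nS))
    nDef <- roundHalfUp(spec@fracDefective * nS)
    nPhe <- roundHalfUp(spec@fracPhenocopy * nS)
    if (nDef + nPhe > nS)
      stop("rounded group sizes exceed the cohort size")
    truth <- stats::setNames(rep("background", nS), samples)
    truth[seq_len(nDef)] <- "defective"
    if (nPhe > 0) truth[nDef + seq_len(nPhe)] <- "phenocopy"
    shifted <- truth %in% c("defective", "phenocopy")

    sigGenes <- sample(genes[-1], spec@nSignatureGenes)
    sigDir <- sample(c(-1, 1), spec@nSignatureGenes, replace = TRUE)

    base <- stats::rnorm(nG, mean = 7, sd = 1)
    vals <- base + matrix(stats::rnorm(nG * nS, sd = spec@noiseSd), nG, nS)
    dimnames(vals) <- list(genes, samples)
    vals[sigGenes, shifted] <- vals[sigGenes, shifted] +
      sigDir * spec@effectLog2fc
    vals["RB1", ] <- base[1] + ifelse(shifted, .rb1LowShift, .rb1HighShift) +
      stats::rnorm(nS, sd = spec@noiseSd)

    mechanism <- stats::setNames(rep("none", nS), samples)
    mechanism[truth == "defective"] <-
      sample(c("low_rb", "hyperphospho", "truncating", "deep_deletion"),
             nDef, replace = TRUE)
    rb <- stats::runif(nS, 0.25, 0.9)
    rb[mechanism == "low_rb"] <- stats::runif(sum(mechanism == "low_rb"),
                                              -1, -0.25)
    rb[mechanism == "hyperphospho"] <-
      stats::runif(sum(mechanism == "hyperphospho"), -0.1, 0.15)
    names(rb) <- samples

    phospho <- lapply(samples, function(s) {
      if (mechanism[[s]] == "hyperphospho")
        stats::setNames(stats::runif(3, 0.35, 0.6), paste0("S", c(780, 795, 807)))
      else
        stats::setNames(stats::runif(3, -0.2, 0.1), paste0("S", c(780, 795, 807)))
    })
    names(phospho) <- samples
    nMiss <- roundHalfUp(spec@fracMissingPhospho * nS)
    missable <- samples[mechanism != "hyperphospho"]
    if (nMiss > 0 && length(missable)) {
      drop <- sample(missable, min(nMiss, length(missable)))
      phospho[drop] <- replicate(length(drop), numeric(0), simplify = FALSE)
    }

    variant <- ifelse(mechanism == "truncating", "truncating", "none")
    mutations <- data.frame(sample = samples, gene = "RB1",
                            variant_class = unname(variant),
                            stringsAsFactors = FALSE)
    cnaRatio <- stats::runif(nS, -0.2, 0.2)
    cnaRatio[mechanism == "deep_deletion"] <-
      stats::runif(sum(mechanism == "deep_deletion"), -2, -1.1)
    cna <- data.frame(sample = samples, gene = "RB1",
                      log2_ratio = unname(cnaRatio), stringsAsFactors = FALSE)

    new("SyntheticCohort",
        expression = ExpressionMatrix(vals, "log2"),
        protein = rb, phospho = phospho, mutations = mutations, cna = cna,
        truth = truth,
        truthGenes = data.frame(gene = sigGenes, direction = sigDir,
                                stringsAsFactors = FALSE),
        spec = spec)
  })
}

#' Plant a correlated gene block into an expression matrix
#'
#' Replaces the listed gene rows by a single-factor construction
#' `mean_g + sd_g * (sqrt(rho) * f + sqrt(1 - rho) * eps_g)` with a shared
#' latent factor `f` per sample, preserving each row's mean and SD while
#' inducing pairwise (Pearson) correlation `rho`; being monotone in the
#' latent factor, the induced Spearman correlation is close to `rho` as
#' well.  Non-block genes are untouched.
#'
#' @param matrix an [ExpressionMatrix-class].
#' @param genes genes to correlate (subset of the matrix genes).
#' @param rho target correlation in (0, 1].
#' @param seed RNG seed.
#' @return The modified [ExpressionMatrix-class].
#' @export
plantCorrelatedBlock <- function(matrix, genes, rho, seed = 1) {
  stopifnot(is(matrix, "ExpressionMatrix"))
  if (!is.numeric(rho) || rho <= 0 || rho > 1)
    stop("rho must lie in (0, 1]")
  if (!length(genes)) return(matrix)
  missing <- setdiff(genes, geneIds(matrix))
  if (length(missing))
    stop("unknown gene(s): ", paste(missing, collapse = ", "))
  withSeed(seed, {
    v <- matrix@values
    nS <- ncol(v)
    f <- stats::rnorm(nS)
    for (g in genes) {
      m <- mean(v[g, ]); s <- stats::sd(v[g, ])
      eps <- stats::rnorm(nS)
      v[g, ] <- m + s * (sqrt(rho) * f + sqrt(1 - rho) * eps)
    }
    ExpressionMatrix(v, matrix@valueKind)
  })
}

#' Generate matched CRISPR gene-effect and drug-response screen tables
#'
#' Cell lines fall into the groups `rb1_defective`, `rbness` and `low`
#' (`nLines` each unless explicit `groupLabels` are given).  The planted
#' `slGenes` have their mean gene effect lowered by `margin` in the
#' defective and rbness lines relative to the signature-low lines; all other
#' genes are exchangeable.  The drug table gets `nPlantedCompounds`
#' compounds that are selectively sensitive (lower dr-AUC) in the same
#' lines.
#'
#' @param nGenes number of genes in the dependency table.
#' @param nLines cell lines per group (ignored when `groupLabels` given).
#' @param slGenes planted synthetic-lethal gene ids (subset of
#'   `gene_0001 ...` or arbitrary new names prepended to the universe).
#' @param groupLabels optional named per-line group labels.
#' @param margin planted gene-effect separation between groupA and low lines.
#' @param nCompounds,nPlantedCompounds drug-response table dimensions.
#' @param seed RNG seed.
#' @return list(geneEffect, drAuc, groupLabels, slGenes, plantedCompounds).
#' @export
generateScreenTables <- function(nGenes = 200, nLines = 20,
                                 slGenes = character(0), groupLabels = NULL,
                                 margin = 0.6, nCompounds = 20,
                                 nPlantedCompounds = 4, seed = 1) {
  universe <- sprintf("gene_%04d", seq_len(nGenes))
  extra <- setdiff(slGenes, universe)
  if (length(extra) > nGenes)
    stop("more planted genes than the gene universe")
  universe[seq_along(extra)] <- extra  # planted names join the universe
  if (is.null(groupLabels)) {
    lines <- sprintf("line_%03d", seq_len(3 * nLines))
    groupLabels <- stats::setNames(
      rep(c("rb1_defective", "rbness", "low"), each = nLines), lines)
  }
  lines <- names(groupLabels)
  withSeed(seed, {
    ge <- matrix(stats::rnorm(length(universe) * length(lines),
                              mean = -0.1, sd = 0.15),
                 length(universe), length(lines),
                 dimnames = list(universe, lines))
    aLines <- lines[groupLabels %in% c("rb1_defective", "rbness")]
    ge[slGenes, aLines] <- ge[slGenes, aLines] - margin
    compounds <- sprintf("cmpd_%03d", seq_len(nCompounds))
    planted <- compounds[seq_len(min(nPlantedCompounds, nCompounds))]
    da <- matrix(stats::rnorm(nCompounds * length(lines),
                              mean = 0.1, sd = 0.15),
                 nCompounds, length(lines),
                 dimnames = list(compounds, lines))
    da[planted, aLines] <- da[planted, aLines] - (margin + 0.2)
    list(geneEffect = ge, drAuc = da, groupLabels = groupLabels,
         slGenes = slGenes, plantedCompounds = planted)
  })
}

#' Generate a tiny SEG-like segment table
#'
#' Convenience fixture generator for percent-genome-altered computations:
#' per sample, `nSegments` contiguous segments on one chromosome with a
#' given fraction of altered (|log2 ratio| > 0.2) segments.
#'
#' @param nSamples,nSegments table dimensions.
#' @param fracAltered fraction of segments drawn from the altered regime.
#' @param seed RNG seed.
#' @return data.frame(sample, chrom, start, end, log2_ratio).
#' @export
generateSegments <- function(nSamples = 3, nSegments = 10, fracAltered = 0.3,
                             seed = 1) {
  withSeed(seed, {
    rows <- lapply(seq_len(nSamples), function(i) {
      widths <- sample(1e5:5e6, nSegments)
      ends <- cumsum(widths)
      starts <- c(1, utils::head(ends, -1) + 1)
      altered <- stats::runif(nSegments) < fracAltered
      ratio <- ifelse(altered,
                      sample(c(-1, 1), nSegments, TRUE) *
                        stats::runif(nSegments, 0.3, 1.5),
                      stats::runif(nSegments, -0.15, 0.15))
      data.frame(sample = sprintf("s%03d", i), chrom = "chr1",
                 start = starts, end = ends, log2_ratio = ratio,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Write all cohort tables to a directory
#'
#' Emits `expression.tsv`, `protein.tsv`, `phospho.tsv` (long format),
#' `mutations.tsv`, `cna_genes.tsv` and `truth.tsv`.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeExpression(cohort@expression, file.path(dir, "expression.tsv"))
  utils::write.table(
    data.frame(sample = names(cohort@protein), rb = unname(cohort@protein)),
    file.path(dir, "protein.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writePhospho(cohort@phospho, file.path(dir, "phospho.tsv"))
  writeMutations(cohort@mutations, file.path(dir, "mutations.tsv"))
  utils::write.table(cohort@cna, file.path(dir, "cna_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(cohort@truth), label = unname(cohort@truth)),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
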