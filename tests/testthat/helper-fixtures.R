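# Shared fixtures and independent oracles.  Oracles are deliberately naive
# (explicit loops, closed forms) and never call the code paths they check.

# Small named random matrix.
makeMatrix <- function(nGenes, nSamples, seed = 1, sd = 1,
                       genes = sprintf("g%03d", seq_len(nGenes)),
                       samples = sprintf("s%03d", seq_len(nSamples))) {
  set.seed(seed)
  matrix(rnorm(nGenes * nSamples, sd = sd), nGenes, nSamples,
         dimnames = list(genes, samples))
}

# Ordinary pooled two-sample t statistics, gene by gene (oracle for the
# shrinkage-disabled moderated fit).
pooledTOracle <- function(m, A, B) {
  apply(m, 1, function(x) {
    a <- x[A]; b <- x[B]
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  })
}

# Naive leave-one-pair-out enumeration: materialises every subset and refits
# through the public fitModeratedDE interface.
naiveLoolOracle <- function(m, def, prof, genes, fcCut = 1, qCut = 0.1) {
  passes <- setNames(numeric(length(genes)), genes)
  for (i in def) for (j in prof) {
    keep <- setdiff(colnames(m), c(i, j))
    de <- fitModeratedDE(m[genes, keep, drop = FALSE],
                         setdiff(def, i), setdiff(prof, j))
    passes <- passes + (abs(de$log2FC) >= fcCut & de$q < qCut)
  }
  unname(passes) / (length(def) * length(prof))
}

# Exhaustive one-sided enrichment p for a 2x2 table with fixed margins:
# sums the probabilities of all tables at least as enriched, using direct
# products of binomial coefficients (no dhyper/phyper).
enrichPOracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  num <- sum(sapply(a:hi, function(k)
    choose(r1, k) * choose(n - r1, c1 - k)))
  num / choose(n, c1)
}

# Exhaustive (c*, accuracy) grid search re-implemented from first principles
# with plain cor() and explicit loops (oracle for optimizeThreshold).
gridSearchOracle <- function(m, genes, directions, high, low) {
  best <- NULL
  for (cv in seq(0.10, 0.80, by = 0.02)) {
    C <- suppressWarnings(cor(t(m[genes, c(high, low), drop = FALSE]),
                              method = "spearman"))
    A <- (C >= cv) * 1; diag(A) <- 0
    conn <- genes[rowSums(A) >= 1]
    if (!length(conn)) next
    right <- 0
    for (s in c(low, high)) {
      al <- mean(sign(m[conn, s]) == directions[conn])
      defLike <- al > 0.5
      if (defLike == (s %in% low)) right <- right + 1
    }
    acc <- right / (length(high) + length(low))
    if (is.null(best) || acc > best$acc)
      best <- list(c = cv, acc = acc, genes = conn)
  }
  best
}

# Stratified split of a cohort's samples into discovery and held-out halves
# (odd/even within each truth label, so the label mix is preserved).
splitCohortSamples <- function(cohort) {
  truth <- cohortTruth(cohort)
  ids <- names(truth)
  disc <- unlist(lapply(split(ids, truth),
                        function(v) v[seq_along(v) %% 2 == 1]),
                 use.names = FALSE)
  list(discovery = disc, heldout = setdiff(ids, disc))
}

# Discovery groups (called defective + first `nProf` called proficient) from
# a cohort restricted to the given samples.
discoveryGroupsFrom <- function(cohort, samples = NULL, nProf = 25) {
  calls <- callRbStatusCohort(cohort, "tcga")
  if (!is.null(samples)) calls <- calls[calls$sample %in% samples, ]
  DiscoveryGroups(calls$sample[calls$status == "defective"],
                  head(calls$sample[calls$status == "proficient"], nProf),
                  "tcga")
}

# Refinement fixture: bimodal RB1 axis driven by a defective-like group, a
# planted signature block riding that group, and pure-noise decoy genes with
# random fixed directions.
makeRefinementFixture <- function(seed, nSamples = 300, nBlock = 20,
                                  nDecoy = 80, effect = 1.5, noiseSd = 0.5) {
  set.seed(seed)
  grp <- rep(c(TRUE, FALSE), c(round(0.3 * nSamples),
                               nSamples - round(0.3 * nSamples)))
  genes <- c("RB1", sprintf("blk%02d", seq_len(nBlock)),
             sprintf("dcy%02d", seq_len(nDecoy)))
  dirBlock <- sample(c(-1, 1), nBlock, replace = TRUE)
  m <- rbind(ifelse(grp, -2, 2) + rnorm(nSamples, sd = noiseSd),
             t(sapply(dirBlock,
                      function(d) d * effect * grp + rnorm(nSamples, sd = noiseSd))),
             matrix(rnorm(nDecoy * nSamples, sd = noiseSd), nDecoy, nSamples))
  dimnames(m) <- list(genes, sprintf("s%03d", seq_len(nSamples)))
  dirs <- setNames(c(dirBlock, sample(c(-1, 1), nDecoy, replace = TRUE)),
                   genes[-1])
  list(z = zscoreByGene(ExpressionMatrix(m, "log2")),
       block = genes[2:(nBlock + 1)], decoys = genes[-(1:(nBlock + 1))],
       directions = dirs)
}
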