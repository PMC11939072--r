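test_that("BH adjustment matches the step-up closed forms", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(c(0.04, 0.01)), c(0.04, 0.02))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # agrees with the stock implementation on random input
  set.seed(1)
  p <- runif(200)
  expect_equal(bhAdjust(p), p.adjust(p, "BH"))
})

test_that("shrinkage-disabled moderated t equals an ordinary pooled t oracle", {
  m <- makeMatrix(50, 12, seed = 101)
  A <- colnames(m)[1:6]; B <- colnames(m)[7:12]
  de <- fitModeratedDE(m, A, B, priorDf = 0)
  expect_lt(max(abs(de$t - pooledTOracle(m, A, B))), 1e-9)
  expect_equal(attr(de, "df.prior"), 0)
})

test_that("equal gene variances make the moderated t the pooled t exactly", {
  # identical within-group deviation pattern per gene -> identical variances
  dev <- c(1, -1, 0.5, -0.5, 0)
  set.seed(7)
  m <- t(sapply(1:20, function(i) c(rnorm(1, 0, 2) + dev,
                                    rnorm(1, 0, 2) + dev)))
  dimnames(m) <- list(paste0("g", 1:20), paste0("s", 1:10))
  A <- paste0("s", 1:5); B <- paste0("s", 6:10)
  de <- fitModeratedDE(m, A, B)
  expect_lt(max(abs(de$t - pooledTOracle(m, A, B))), 1e-9)
})

test_that("a gene identical across groups gets zero effect and p of 1", {
  m <- makeMatrix(10, 8, seed = 3)
  m["g001", ] <- rep(c(2, -1, 0.5, 1), 2)  # same values in both groups
  A <- colnames(m)[1:4]; B <- colnames(m)[5:8]
  de <- fitModeratedDE(m, A, B)
  row <- de[de$gene == "g001", ]
  expect_equal(row$log2FC, 0)
  expect_equal(row$t, 0)
  expect_equal(row$p, 1)
})

test_that("group handling errors are informative", {
  m <- makeMatrix(5, 6)
  expect_error(fitModeratedDE(m, colnames(m)[1:3], colnames(m)[3:6]),
               "overlap")
  expect_error(fitModeratedDE(m, colnames(m)[1:3], c("s004", "ghost")),
               "ghost")
  expect_error(fitModeratedDE(m, colnames(m)[1], colnames(m)[2:6]),
               ">= 2")
})

test_that("moderated statistics agree with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(42)
  m <- matrix(rnorm(200 * 12), 200, 12) * rchisq(200, 4) / 4
  dimnames(m) <- list(paste0("g", 1:200), paste0("s", 1:12))
  A <- paste0("s", 1:6); B <- paste0("s", 7:12)
  de <- fitModeratedDE(m, A, B)
  fit <- limma::eBayes(limma::lmFit(m, cbind(1, c(rep(1, 6), rep(0, 6)))))
  expect_equal(attr(de, "df.prior"), fit$df.prior, tolerance = 1e-8)
  expect_lt(max(abs(de$t - fit$t[, 2])), 1e-8)
  expect_lt(max(abs(de$p - fit$p.value[, 2])), 1e-8)
})

test_that("initial selection applies both thresholds with printed boundaries", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log2FC = c(0.60, 0.58, 2.0, -0.7),
                   t = 0, p = 0,
                   q = c(0.05, 0.01, 0.10, 0.09))
  expect_setequal(initialGeneSelection(de), c("a", "d"))
})

test_that("leave-one-out enumerates exactly n*m subsets and matches the naive oracle", {
  m <- makeMatrix(12, 10, seed = 55)
  def <- colnames(m)[1:4]; prof <- colnames(m)[5:10]
  g <- DiscoveryGroups(def, prof, "tcga")
  lr <- lool(m, g, rownames(m), fcCut = 0.5)
  expect_identical(attr(lr, "n_subsets"), 24L)
  expect_equal(lr$robustness_fraction,
               naiveLoolOracle(m, def, prof, rownames(m), fcCut = 0.5))

  # n = 3, m = 3 gives exactly 9 subsets
  g2 <- DiscoveryGroups(colnames(m)[1:3], colnames(m)[4:6], "tcga")
  expect_identical(attr(lool(m[, 1:6], g2, rownames(m)), "n_subsets"), 9L)
})

test_that("leave-one-out fractions match the oracle on random small instances", {
  set.seed(77)
  for (rep in 1:8) {
    n <- sample(3:6, 1); mm <- sample(3:6, 1)
    m <- makeMatrix(10, n + mm, seed = 1000 + rep)
    m[1:2, seq_len(n)] <- m[1:2, seq_len(n)] + 2  # a couple of real effects
    def <- colnames(m)[seq_len(n)]
    prof <- colnames(m)[n + seq_len(mm)]
    lr <- lool(m, DiscoveryGroups(def, prof, "tcga"), rownames(m))
    expect_equal(lr$robustness_fraction,
                 naiveLoolOracle(m, def, prof, rownames(m)),
                 tolerance = 1e-12)
  }
})

test_that("a strongly planted gene is robust in every subset", {
  m <- makeMatrix(20, 14, seed = 6, sd = 0.1)
  m["g001", 1:6] <- m["g001", 1:6] + 2
  g <- DiscoveryGroups(colnames(m)[1:6], colnames(m)[7:14], "tcga")
  lr <- lool(m, g, rownames(m))
  expect_equal(lr$robustness_fraction[lr$gene == "g001"], 1.0)
  expect_error(lool(m, g, rownames(m), maxSubsets = 10), "maxSubsets")
})

test_that("final filter applies all three thresholds and assigns directions", {
  lr <- data.frame(
    gene = c("keep", "lowfrac", "lowz", "lowcons"),
    robustness_fraction = c(0.25, 0.10, 0.30, 0.40),
    mean_z_defective = c(0.5, 0.5, 0.15, -0.8),
    direction_consistency = c(0.8, 0.9, 0.9, 0.5))
  sig <- finalGeneFilter(lr)
  expect_identical(signatureGenes(sig), "keep")
  expect_equal(unname(signatureDirections(sig)), 1)
  expect_true(isValidSignature(sig))

  none <- finalGeneFilter(lr[lr$gene == "lowfrac", ])
  expect_length(signatureGenes(none), 0)
  expect_false(isValidSignature(none))

  # raising the fraction threshold never adds genes
  fr <- seq(0, 1, 0.1)
  sizes <- sapply(fr, function(f) length(finalGeneFilter(lr, minFraction = f)))
  expect_true(all(diff(sizes) <= 0))
})

test_that("the pan-cancer fraction branches at 20 initial genes", {
  expect_equal(loolPancancerFraction(30), 0.50)
  expect_equal(loolPancancerFraction(10), 0.20)
  expect_equal(loolPancancerFraction(20), 0.20)
})

test_that("direction consistency counts exact zeros as non-matching", {
  m <- rbind(g1 = c(1, 0, 2, -1, 5, 5, 5), g2 = rnorm(7))
  colnames(m) <- paste0("s", 1:7)
  g <- DiscoveryGroups(paste0("s", 1:4), paste0("s", 5:7), "tcga")
  lr <- lool(m, g, "g1", fcCut = 0)
  # defective values (1, 0, 2, -1): mean > 0, matching signs = 2 of 4
  expect_equal(lr$direction_consistency, 0.5)
  expect_equal(lr$mean_z_defective, 0.5)
})
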