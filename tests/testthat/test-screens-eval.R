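test_that("confusion metrics reproduce the printed trial arithmetic", {
  # 7 resistant samples all called signature-high
  expect_equal(confusionMetrics(rep(TRUE, 7), rep(TRUE, 7))$sensitivity, 100)
  # 38 sensitive samples, 12 called high
  truth <- rep(FALSE, 38)
  calls <- rep(c(TRUE, FALSE), c(12, 26))
  expect_equal(confusionMetrics(truth, calls)$specificity, 100 * 26 / 38,
               tolerance = 1e-12)
  # sentinels instead of crashes for one-class inputs
  allPos <- confusionMetrics(rep(TRUE, 5), rep(TRUE, 5))
  expect_true(is.na(allPos$specificity))
  expect_error(confusionMetrics(logical(0), logical(0)), "nonempty")
})

test_that("hypergeometric enrichment matches closed forms and the exhaustive oracle", {
  bal <- fisherEnrichment(10, 10, 10, 10)
  expect_equal(bal$odds_ratio, 1.0)
  expect_false(bal$degenerate)

  ext <- fisherEnrichment(5, 0, 0, 5)
  expect_true(ext$degenerate)
  expect_equal(ext$p, 1 / choose(10, 5))

  mid <- fisherEnrichment(2, 8, 8, 2)
  expect_equal(mid$p, enrichPOracle(2, 8, 8, 2), tolerance = 1e-12)

  # exhaustive check over tables with margins up to 12
  set.seed(91)
  for (i in 1:60) {
    a <- sample(0:6, 1); b <- sample(0:6, 1)
    c <- sample(0:6, 1); d <- sample(0:6, 1)
    if (a + b == 0 || c + d == 0 || a + b + c + d == 0) next
    expect_equal(fisherEnrichment(a, b, c, d)$p, enrichPOracle(a, b, c, d),
                 tolerance = 1e-10)
  }
  expect_error(fisherEnrichment(-1, 2, 3, 4), "nonnegative")
})

test_that("PGA supports both conventions and is split-invariant", {
  seg <- data.frame(sample = "s1", chrom = "chr1",
                    start = c(1, 101), end = c(100, 400),
                    log2_ratio = c(0.5, 0.1))
  expect_equal(unname(computePga(seg)), 0.25)            # 100 of 400 bases
  expect_equal(unname(computePga(seg, byCount = TRUE)), 0.5)

  none <- seg; none$log2_ratio <- c(0.2, -0.2)           # strict > 0.2
  expect_equal(unname(computePga(none)), 0)

  eq <- data.frame(sample = "s1", chrom = "chr1",
                   start = c(1, 101), end = c(100, 200),
                   log2_ratio = c(0.5, 0))
  expect_equal(unname(computePga(eq)), 0.5)

  # splitting a segment into contiguous halves leaves the weighted PGA alone
  split <- rbind(seg[2, ], seg[2, ])
  split$start <- c(101, 251); split$end <- c(250, 400)
  both <- rbind(seg[1, ], split)
  expect_equal(computePga(both), computePga(seg))
  # and segment order is irrelevant
  expect_equal(computePga(seg[2:1, ]), computePga(seg))
})

test_that("median gene score uses the available listed genes", {
  m <- rbind(h1 = c(1, 4), h2 = c(2, 5), h3 = c(9, 6))
  colnames(m) <- c("s1", "s2")
  expect_equal(unname(medianGeneScore(m, c("h1", "h2", "h3"))), c(2, 5))
  expect_equal(unname(medianGeneScore(m, c("h1", "h2", "absent"))),
               c(1.5, 4.5))
  expect_equal(unname(medianGeneScore(m, "h3")), c(9, 6))
  expect_error(medianGeneScore(m, c("x", "y")), "none of the listed genes")
})

test_that("CRISPR gating admits only genes passing all three mean thresholds", {
  lines <- sprintf("l%02d", 1:20)
  labels <- setNames(rep(c("rb1_defective", "low"), each = 10), lines)
  set.seed(17)
  ge <- rbind(pass = c(rnorm(10, -0.8, 0.1), rnorm(10, -0.2, 0.1)),
              lowEssential = c(rnorm(10, -0.8, 0.1), rnorm(10, -0.9, 0.1)),
              weak = c(rnorm(10, -0.4, 0.1), rnorm(10, 0, 0.1)))
  colnames(ge) <- lines
  out <- crisprSlCandidates(ge, labels, "rb1_defective")
  expect_true(out$testable[out$gene == "pass"])
  expect_true(out$candidate[out$gene == "pass"])
  expect_lt(out$p[out$gene == "pass"], 0.05)
  expect_false(out$testable[out$gene == "lowEssential"])
  expect_false(out$testable[out$gene == "weak"])
  # gating before testing: untestable genes never receive a p-value
  expect_true(all(is.na(out$p[!out$testable])))

  few <- labels[c(1:2, 11:20)]
  expect_error(crisprSlCandidates(ge[, names(few)], few, "rb1_defective"),
               "rb1_defective")
})

test_that("planted synthetic-lethal genes are recovered with low FDP", {
  res <- t(sapply(1:10, function(s) {
    sl <- sprintf("sl_%02d", 1:15)
    tab <- generateScreenTables(nGenes = 200, nLines = 20, slGenes = sl,
                                margin = 0.6, seed = s)
    out <- crisprSlCandidates(tab$geneEffect, tab$groupLabels,
                              "rb1_defective")
    cand <- out$gene[out$candidate]
    c(recall = mean(sl %in% cand),
      fdp = if (length(cand)) mean(!cand %in% sl) else 0)
  }))
  expect_gte(median(res[, "recall"]), 0.9)
  expect_lte(median(res[, "fdp"]), 0.1)
})

test_that("isogenic screen filters implement the three threshold rules", {
  rec <- data.frame(gene = c("hit", "parentDead", "smallDelta"),
                    z_knockout = c(-3.0, -3.0, -2.5),
                    z_parent = c(-0.5, -5.0, -1.0))
  out <- isogenicScreenCandidates(rec)
  expect_equal(out$delta, c(-2.5, 2.0, -1.5))
  expect_identical(out$candidate, c(TRUE, FALSE, FALSE))
  expect_error(isogenicScreenCandidates(rec[, 1:2]), "z_parent")
})

test_that("drug gating requires a non-sensitive low group and sensitive groupA", {
  lines <- sprintf("l%02d", 1:12)
  labels <- setNames(rep(c("rbness", "low"), each = 6), lines)
  set.seed(19)
  da <- rbind(testable = c(rnorm(6, -0.6, 0.05), rnorm(6, 0.1, 0.05)),
              lowSensitive = c(rnorm(6, -0.8, 0.05), rnorm(6, -0.2, 0.05)),
              weakA = c(rnorm(6, -0.4, 0.05), rnorm(6, 0.3, 0.05)))
  colnames(da) <- lines
  out <- drugSensitivityCandidates(da, labels, "rbness")
  expect_identical(out$testable, c(TRUE, FALSE, FALSE))
  expect_true(out$candidate[1])
  expect_true(all(is.na(out$p[-1])))
})

test_that("cell-line RB1 defect calls combine flags with the mRNA threshold", {
  expect_true(cellLineRb1Defective(mrnaZ = -2.5))
  expect_true(cellLineRb1Defective(rb1Fusion = TRUE, mrnaZ = 0))
  expect_false(cellLineRb1Defective(mrnaZ = -1.9))
  expect_true(cellLineRb1Defective(mutationDamaging = TRUE))
  expect_false(cellLineRb1Defective(mutationDamaging = FALSE,
                                    deepDeletion = FALSE))
  expect_error(cellLineRb1Defective(), "all modalities missing")
})
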