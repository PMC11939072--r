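test_that("scale sample selection uses strict inequalities on both sides", {
  m <- matrix(c(1.2, -0.5, -1.1, 1.0), 1, 4,
              dimnames = list("RB1", paste0("s", 1:4)))
  sides <- selectScaleSamples(m, "RB1", 1.0)
  expect_identical(sides$high, "s1")
  expect_identical(sides$low, "s3")   # s4 sits exactly at alpha -> excluded

  flat <- matrix(runif(4, -0.3, 0.3), 1, 4,
                 dimnames = list("RB1", paste0("s", 1:4)))
  sides2 <- selectScaleSamples(flat, "RB1", 0.4)
  expect_length(sides2$high, 0)
  expect_length(sides2$low, 0)
  expect_error(selectScaleSamples(m, "TP53", 0.4), "TP53")
})

test_that("relevance networks follow the adjacency rule", {
  m <- makeMatrix(4, 10, seed = 31)
  m["g002", ] <- m["g001", ]                     # identical pair
  m["g003", ] <- rnorm(10)                       # uncorrelated
  net <- suppressWarnings(
    buildRelevanceNetwork(m, rownames(m), colnames(m), c = 0.9))
  expect_true(all(c("g001", "g002") %in% net$connectedGenes))
  expect_false("g003" %in% net$connectedGenes)
  expect_true(all(diag(net$adjacency) == 0))     # no self edges
  expect_equal(net$adjacency, t(net$adjacency))

  # constant gene: warned and disconnected
  m["g004", ] <- 1
  expect_warning(
    net2 <- buildRelevanceNetwork(m, rownames(m), colnames(m), c = 0.2),
    "g004")
  expect_false("g004" %in% net2$connectedGenes)

  expect_error(buildRelevanceNetwork(m, rownames(m), colnames(m)[1:2], 0.5),
               ">= 3")
})

test_that("edge sets shrink monotonically as the threshold rises", {
  m <- makeMatrix(8, 40, seed = 32)
  prev <- NULL
  for (cv in seq(0.1, 0.8, 0.1)) {
    net <- buildRelevanceNetwork(m, rownames(m), colnames(m), cv)
    if (!is.null(prev))
      expect_true(all(net$adjacency <= prev))   # edges only disappear
    prev <- net$adjacency
  }
})

test_that("scale accuracy separates a clean toy and assigns ties to proficient-like", {
  # two genes, direction +1; low-side samples positive, high-side negative
  m <- cbind(l1 = c(1, 1), l2 = c(2, 0.5), h1 = c(-1, -1), h2 = c(-0.2, -2))
  rownames(m) <- c("a", "b")
  dirs <- c(a = 1, b = 1)
  acc <- scaleAccuracy(c("a", "b"), dirs, high = c("h1", "h2"),
                       low = c("l1", "l2"), m)
  expect_equal(acc, 1.0)

  # a sample aligned exactly 0.5 counts as proficient-like
  m2 <- cbind(l1 = c(1, -1), h1 = c(-1, -1), h2 = c(-1, 1))
  rownames(m2) <- c("a", "b")
  acc2 <- scaleAccuracy(c("a", "b"), dirs, high = c("h1", "h2"), low = "l1", m2)
  # l1 aligns 0.5 -> proficient-like -> wrong side; h1 (0.0) and h2 (0.5) right
  expect_equal(acc2, 2 / 3)
  expect_error(scaleAccuracy(character(0), dirs, "h1", "l1", m2), "empty")
})

test_that("random directions on symmetric noise give chance-level accuracy", {
  set.seed(33)
  accs <- replicate(20, {
    m <- matrix(rnorm(10 * 200), 10, 200,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:200)))
    dirs <- setNames(sample(c(-1, 1), 10, TRUE), rownames(m))
    scaleAccuracy(rownames(m), dirs, high = colnames(m)[1:100],
                  low = colnames(m)[101:200], m)
  })
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("threshold optimization matches an exhaustive grid oracle", {
  fix <- makeRefinementFixture(seed = 201, nSamples = 120, nBlock = 6,
                               nDecoy = 4)
  m <- exprValues(fix$z)
  sides <- selectScaleSamples(m, "RB1", 0.6)
  res <- optimizeThreshold(m, c(fix$block, fix$decoys), fix$directions,
                           sides$high, sides$low, alpha = 0.6)
  oracle <- gridSearchOracle(m, c(fix$block, fix$decoys), fix$directions,
                             sides$high, sides$low)
  expect_equal(res@cStar, oracle$c)
  expect_equal(res@accuracy, oracle$acc)
  expect_setequal(res@connectedGenes, oracle$genes)
  # grid endpoints are evaluated inclusively
  grid <- rbnsig:::.cGrid()
  expect_equal(range(grid), c(0.10, 0.80))
  expect_length(grid, 36)
})

test_that("unusable scales are reported, not fatal", {
  m <- makeMatrix(5, 10, seed = 35)
  m["g001", ] <- runif(10, -0.1, 0.1)  # RB1 stand-in with no tail samples
  dirs <- setNames(rep(1, 4), rownames(m)[2:5])
  expect_warning(
    res <- optimizeThreshold(m, rownames(m)[2:5], dirs,
                             high = character(0), low = character(0),
                             alpha = 0.4),
    "unusable")
  expect_false(res@usable)
})

test_that("consensus modes implement strict/tolerant/auto with documented edges", {
  mk <- function(genes, alpha) new("ScaleResult", alpha = alpha, cStar = 0.2,
                                   accuracy = 0.9, connectedGenes = genes,
                                   usable = TRUE, nHigh = 5L, nLow = 5L)
  cand <- c("a", "b", "c")
  dirs <- c(a = 1, b = -1, c = 1)
  scales <- list(mk(c("a", "b"), 0.4), mk(c("a", "b"), 0.6),
                 mk("a", 0.8), mk("a", 1.0))
  strict <- multiscaleConsensus(scales, "strict", cand, dirs)
  expect_identical(signatureGenes(strict), "a")   # b connected at 2 scales only
  tol <- multiscaleConsensus(scales, "tolerant", cand, dirs)
  expect_setequal(signatureGenes(tol), c("a", "b"))
  # tolerant always contains strict
  expect_true(all(signatureGenes(strict) %in% signatureGenes(tol)))

  # auto: > 50 genes -> strict; exactly 50 -> tolerant
  many <- paste0("g", 1:60)
  dirsMany <- setNames(rep(1, 60), many)
  sc <- list(mk(many[1:55], 0.4), mk(many[1:10], 0.6),
             mk(many[1:10], 0.8), mk(many[1:10], 1.0))
  auto <- multiscaleConsensus(sc, "auto", many, dirsMany)
  expect_identical(signatureMetadata(auto)$consensus_mode, "strict")
  auto50 <- multiscaleConsensus(sc, "auto", many[1:50], dirsMany[1:50])
  expect_identical(signatureMetadata(auto50)$consensus_mode, "tolerant")

  # an unusable scale forces strict to fall back to tolerant with a warning
  bad <- new("ScaleResult", alpha = 1.0, cStar = NA_real_,
             accuracy = NA_real_, connectedGenes = character(0),
             usable = FALSE, nHigh = 0L, nLow = 3L)
  expect_warning(
    fb <- multiscaleConsensus(list(mk(c("a", "b"), 0.4),
                                   mk(c("a", "b"), 0.6), bad),
                              "strict", cand, dirs),
    "falling back")
  expect_identical(signatureMetadata(fb)$consensus_mode, "tolerant")

  empty <- multiscaleConsensus(scales, "strict", "zzz",
                               c(zzz = 1))
  expect_false(isValidSignature(empty))
})

test_that("refinement keeps the correlated block and prunes uncorrelated decoys", {
  res <- t(sapply(1:5, function(s) {
    fix <- makeRefinementFixture(seed = s)
    ref <- refineSignature(fix$z,
                           RbSignature(names(fix$directions),
                                       unname(fix$directions)),
                           mode = "auto")
    expect_identical(signatureMetadata(ref)$consensus_mode, "strict")
    c(block = mean(fix$block %in% signatureGenes(ref)),
      decoy = mean(!fix$decoys %in% signatureGenes(ref)))
  }))
  expect_gte(median(res[, "block"]), 0.9)
  expect_gte(median(res[, "decoy"]), 0.9)
})
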