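test_that("dinucleotide o/e follows the stated formula", {
  p <- dinucleotideProfile(c(g = "CGCGCGCGCG"))
  expect_equal(p$length, 10L)
  expect_equal(p$n_C, 5L)
  expect_equal(p$CG, 5L)
  expect_equal(p$oe_CG, (5 / 9) / (0.5 * 0.5), tolerance = 1e-12)
  # no C anywhere: the ratio is undefined
  expect_true(is.na(dinucleotideProfile(c(g = "GATTGATT"))$oe_CG))
  expect_error(dinucleotideProfile(c(g = "A")), "short")
})

test_that("dinucleotide counts are conserved on unambiguous sequences", {
  set.seed(2)
  seqs <- vapply(1:25, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(50:500, 1), TRUE),
          collapse = ""), character(1))
  p <- dinucleotideProfile(seqs)
  diSum <- rowSums(p[, Biostrings::mkAllStrings(c("A", "C", "G", "T"), 2)])
  expect_equal(diSum, p$length - 1L)
})

test_that("iid uniform sequences centre the CpG ratio at 1", {
  set.seed(4)
  seqs <- vapply(1:300, function(i)
    paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = ""),
    character(1))
  p <- dinucleotideProfile(seqs)
  expect_lt(abs(mean(p$oe_CG) - 1), 0.05)
})

test_that("genome tiling follows the window and tail rules", {
  set.seed(6)
  mk <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                          collapse = "")
  w <- windowProfiles(c(scf1 = mk(10000)), window = 1000)
  expect_equal(nrow(w), 10L)
  w2 <- windowProfiles(c(scf1 = mk(10499)), window = 1000)
  expect_equal(nrow(w2), 10L)
  expect_equal(attr(w2, "n_dropped_short"), 1L)
  # a tail of at least half a window is kept
  w3 <- windowProfiles(c(scf1 = mk(10500)), window = 1000)
  expect_equal(nrow(w3), 11L)
  expect_error(windowProfiles(c(s = mk(500)), window = 50), ">= 100")
})

test_that("windows over an island-bearing genome separate into two classes", {
  set.seed(13)
  plain <- replicate(60, paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                               collapse = ""))
  island <- replicate(25, paste(vapply(1:500, function(i)
    if (runif(1) < 0.35) "CG" else
      paste(sample(c("A", "C", "G", "T"), 2, TRUE), collapse = ""),
    character(1)), collapse = ""))
  genome <- c(scf1 = paste(c(plain, island)[sample(85)], collapse = ""))
  w <- windowProfiles(genome, window = 1000)
  fit <- fitGaussianMixture(w$oe_CG, kRange = 1:3, seed = 2)
  expect_equal(mixtureK(fit), 2L)
})

test_that("a single normal population is recovered as one component", {
  set.seed(10)
  fit <- fitGaussianMixture(rnorm(5000, 1.0, 0.1), kRange = 1:4, seed = 1)
  expect_equal(mixtureK(fit), 1L)
  expect_lt(abs(mixtureMeans(fit) - 1.0), 0.01)
  expect_true(fit@converged)
})

test_that("the three-class methylation signature is recovered at study scale", {
  sim <- simulateCpgGenes(seed = 1)
  fit <- fitGaussianMixture(sim$values, seed = 1)
  expect_equal(mixtureK(fit), 3L)
  expect_lt(max(abs(mixtureMeans(fit) - c(0.62, 1.00, 1.48))), 0.03)
  expect_lt(abs(mixtureWeights(fit)[1] - 0.095), 0.015)
  cls <- classifyMethylation(fit)
  expect_lt(abs(cls$low_fraction_soft - 0.095), 0.015)
  expect_setequal(unique(cls$classes), c("low", "medium", "high"))
})

test_that("component reporting is invariant to the restart stream", {
  sim <- simulateCpgGenes(n = 4000, seed = 6)
  f1 <- fitGaussianMixture(sim$values, seed = 3)
  f2 <- fitGaussianMixture(sim$values, seed = 104729)
  expect_equal(mixtureK(f1), mixtureK(f2))
  expect_equal(mixtureMeans(f1), mixtureMeans(f2), tolerance = 5e-3)
  # deterministic given one seed
  f3 <- fitGaussianMixture(sim$values, seed = 3)
  expect_identical(mixtureMeans(f1), mixtureMeans(f3))
})

test_that("the EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(require(mclust, quietly = TRUE))
  sim <- simulateCpgGenes(n = 6000, seed = 15)
  fit <- fitGaussianMixture(sim$values, kRange = 3, seed = 2)
  mc <- mclust::Mclust(sim$values, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(sort(as.numeric(mc$parameters$mean)), mixtureMeans(fit),
               tolerance = 0.02)
  expect_equal(fit@logLik, mc$loglik, tolerance = 1e-3)
})

test_that("BIC selects the true k on well-separated mixtures", {
  hits <- 0L
  nRep <- 30L
  for (i in seq_len(nRep)) {
    sim <- simulateCpgGenes(n = 2000, weights = c(0.3, 0.4, 0.3),
                            means = c(0.4, 1.0, 1.6),
                            sds = c(0.08, 0.1, 0.08), seed = 400 + i)
    fit <- fitGaussianMixture(sim$values, kRange = 1:4, nInit = 4,
                              seed = i)
    if (mixtureK(fit) == 3L) hits <- hits + 1L
  }
  expect_gte(hits / nRep, 0.95)
})

test_that("hard-assignment fractions meet the weights when classes separate", {
  sim <- simulateCpgGenes(n = 3000, weights = c(0.2, 0.8),
                          means = c(0.3, 2.0), sds = c(0.05, 0.05),
                          seed = 19)
  fit <- fitGaussianMixture(sim$values, kRange = 1:3, seed = 4)
  expect_equal(mixtureK(fit), 2L)
  cls <- classifyMethylation(fit)
  expect_equal(cls$low_fraction_hard, cls$low_fraction_soft,
               tolerance = 1e-3)
  expect_setequal(unique(cls$classes), c("low", "high"))
})

test_that("only the CpG dinucleotide departs from unimodality on signature sequences", {
  sim <- simulateCpgGenes(n = 400, seed = 8, emitSequences = TRUE,
                          seqLength = 600)
  p <- dinucleotideProfile(sim$sequences)
  ks <- vapply(Biostrings::mkAllStrings(c("A", "C", "G", "T"), 2),
               function(d) {
                 v <- p[[paste0("oe_", d)]]
                 mixtureK(fitGaussianMixture(v, kRange = 1:3, nInit = 4,
                                             seed = 5))
               }, integer(1))
  expect_gt(ks[["CG"]], 1)
  expect_true(all(ks[setdiff(names(ks), "CG")] == 1L))
})
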