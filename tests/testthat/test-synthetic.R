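test_that("generators are pure functions of parameters and seed", {
  a <- simulateMacrosyntenyPair(nAlgs = 4, familiesPerAlg = 10,
                                scaffoldsPerGenome = 8,
                                translocationRate = 0.2, lossRate = 0.1,
                                seed = 42)
  b <- simulateMacrosyntenyPair(nAlgs = 4, familiesPerAlg = 10,
                                scaffoldsPerGenome = 8,
                                translocationRate = 0.2, lossRate = 0.1,
                                seed = 42)
  expect_identical(a, b)
  expect_identical(simulateCpgGenes(n = 500, seed = 7),
                   simulateCpgGenes(n = 500, seed = 7))
  expect_identical(simulateCoverage(nScaffolds = 100, seed = 3),
                   simulateCoverage(nScaffolds = 100, seed = 3))
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_identical(simulateDollo(tr, nFamilies = 50, seed = 5),
                   simulateDollo(tr, nFamilies = 50, seed = 5))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(1234)
  before <- .Random.seed
  invisible(simulateCpgGenes(n = 100, seed = 9))
  invisible(simulateCoverage(nScaffolds = 50, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("written scenario files are checksum-reproducible", {
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  runSimulate("synteny", d1, seed = 42, nAlgs = 4, familiesPerAlg = 10,
              scaffoldsPerGenome = 8)
  runSimulate("synteny", d2, seed = 42, nAlgs = 4, familiesPerAlg = 10,
              scaffoldsPerGenome = 8)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f2))))
})

test_that("every generated entity appears in the truth exactly once", {
  sim <- simulateMacrosyntenyPair(nAlgs = 4, familiesPerAlg = 10,
                                  scaffoldsPerGenome = 8,
                                  translocationRate = 0.3, lossRate = 0.2,
                                  seed = 2)
  pl <- sim$truth$placement$genomeQ
  expect_false(anyDuplicated(pl$gene_id) > 0)
  expect_setequal(sim$queryGenes$gene_id, pl$gene_id[!pl$lost])
  expect_setequal(names(sim$truth$familyAlg),
                  unique(c(sim$orthologs$family_id,
                           names(sim$truth$familyAlg))))
  cov <- simulateCoverage(nScaffolds = 200, seed = 4)
  expect_setequal(unique(cov$depths$scaffold_id), cov$truth$scaffold_id)
  expect_false(anyDuplicated(cov$truth$scaffold_id) > 0)
})

test_that("generator moments match their targets", {
  sim <- simulateCpgGenes(n = 10000, seed = 12)
  expect_lt(abs(mean(sim$values) -
                sum(c(0.095, 0.80, 0.105) * c(0.62, 1.00, 1.48))), 0.01)
  expect_equal(as.numeric(table(sim$truth$component)) / 10000,
               c(0.095, 0.80, 0.105), tolerance = 0.1)
  cov <- simulateCoverage(nScaffolds = 2000, seed = 5)
  male <- cov$depths[cov$depths$sample_id == "male1", ]
  cls <- cov$truth$sex_class[match(male$scaffold_id,
                                   cov$truth$scaffold_id)]
  expect_lt(abs(mean(male$mean_depth[cls == "autosome"]) - 30), 0.5)
  expect_lt(abs(mean(male$mean_depth[cls == "X"]) - 15), 1)
})

test_that("noise-free coverage sits exactly on the dosage expectations", {
  cov <- simulateCoverage(nScaffolds = 100, overdispersion = 0, seed = 6)
  male <- cov$depths[cov$depths$sample_id == "male1", ]
  cls <- cov$truth$sex_class[match(male$scaffold_id,
                                   cov$truth$scaffold_id)]
  expect_true(all(male$mean_depth[cls == "autosome"] == 30))
  expect_true(all(male$mean_depth[cls %in% c("X", "Y")] == 15))
  fem <- cov$depths[cov$depths$sample_id == "female1", ]
  expect_true(all(fem$mean_depth[cls == "Y"] == 0))
})

test_that("without a Y fraction no Y calls arise", {
  cov <- simulateCoverage(nScaffolds = 500, propY = 0, seed = 8)
  expect_false("Y" %in% cov$truth$sex_class)
  tab <- classTable(classifySexLinkage(
    normalizeDepths(cov$depths, cov$sexes)))
  expect_lte(sum(tab$sex_class == "Y"), 1L)
})

test_that("emitted sequences realise their target CpG ratio", {
  sim <- simulateCpgGenes(n = 15, seed = 3, emitSequences = TRUE,
                          seqLength = 1500)
  p <- dinucleotideProfile(sim$sequences)
  expect_lt(max(abs(p$oe_CG - sim$values)), 0.02 + 1e-9)
})

test_that("noise-free linkage simulation is block-perfect", {
  sim <- simulateMacrosyntenyPair(nAlgs = 3, familiesPerAlg = 10,
                                  scaffoldsPerGenome = 6,
                                  translocationRate = 0, lossRate = 0,
                                  seed = 1)
  pl <- sim$truth$placement$genomeQ
  expect_true(all(pl$scaffold == pl$home_scaffold))
  expect_error(simulateMacrosyntenyPair(translocationRate = 2),
               "rates")
})
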