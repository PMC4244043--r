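test_that("one-sided Fisher matches hand values and the enumeration oracle", {
  expect_equal(fisherOneSided(3, 1, 1, 3), 17 / 70, tolerance = 1e-12)
  expect_equal(fisherOneSided(0, 4, 0, 9), 1)
  expect_equal(fisherOneSided(0, 0, 3, 5), 1)
  set.seed(5)
  for (i in 1:200) {
    tb <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(1 / 4, 4)))
    expect_equal(fisherOneSided(tb[1], tb[2], tb[3], tb[4]),
                 enumFisherUpper(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
  }
})

test_that("enrichment p decreases as the overlap grows with margins fixed", {
  r1 <- 12; c1 <- 10; N <- 40
  as_ <- max(0, r1 + c1 - N):min(r1, c1)
  ps <- vapply(as_, function(a)
    fisherOneSided(a, r1 - a, c1 - a, N - r1 - c1 + a), numeric(1))
  expect_true(all(diff(ps) <= 1e-14))
})

test_that("a noise-free genome pair is significant for exactly its true ALG", {
  sim <- simulateMacrosyntenyPair(nAlgs = 6, familiesPerAlg = 30,
                                  scaffoldsPerGenome = 12,
                                  translocationRate = 0, lossRate = 0,
                                  seed = 42)
  sc <- scoreScaffoldAlg(buildIncidence(sim$queryGenes),
                         buildIncidence(sim$refGenes), refAlgTable(sim),
                         queryGenes = sim$queryGenes)
  res <- enrichmentTable(sc)
  truth <- sim$truth$scaffoldAlg$genomeQ
  for (s in unique(res$scaffold_id)) {
    sig <- res$alg_id[res$scaffold_id == s & res$significant_strict]
    expect_equal(sig, unname(truth[s]))
  }
  sm <- syntenySummary(sc)
  expect_equal(sm$pct_genes_conserved_context, 100)
  expect_equal(sm$n_tests, 12 * 6)
})

test_that("scaffolds below the 20-ancestral-gene filter are not tested", {
  g <- rbind(tinyGeneDf("big", 25, family = sprintf("f%02d", 1:25)),
             tinyGeneDf("small", 19, family = sprintf("f%02d", 26:44),
                        prefix = "s"))
  famAlg <- stats::setNames(rep(c("ALG1", "ALG2"), 22), sprintf("f%02d", 1:44))
  sc <- scoreScaffoldAlg(buildIncidence(g), familyAlg = famAlg)
  expect_setequal(unique(enrichmentTable(sc)$scaffold_id), "big")
  expect_equal(syntenySummary(sc)$n_scaffolds_tested, 1L)
  expect_equal(sc@params$m, 2L)
})

test_that("m tracks tested units and p_adj is the Bonferroni cap", {
  sim <- simulateMacrosyntenyPair(nAlgs = 4, familiesPerAlg = 20,
                                  scaffoldsPerGenome = 8, seed = 3)
  sc <- scoreScaffoldAlg(buildIncidence(sim$queryGenes),
                         buildIncidence(sim$refGenes), refAlgTable(sim))
  res <- enrichmentTable(sc)
  m <- sc@params$m
  expect_equal(m, syntenySummary(sc)$n_scaffolds_tested * 4)
  expect_equal(res$p_adj, pmin(1, m * res$p_raw))
  expect_true(all(res$significant_relaxed[res$significant_strict]))
  # a+b equals the number of (reference-anchored) families on the scaffold
  expect_true(all(tapply(res$a + res$b, res$scaffold_id,
                         function(x) length(unique(x)) == 1)))
})

test_that("a fused two-ALG scaffold is split at the junction and m is recomputed", {
  sim <- simulateMacrosyntenyPair(nAlgs = 4, familiesPerAlg = 40,
                                  scaffoldsPerGenome = 4,
                                  genesPerFamily = 1L,
                                  translocationRate = 0, lossRate = 0,
                                  seed = 8)
  g <- sim$queryGenes
  truth <- sim$truth$scaffoldAlg$genomeQ
  s12 <- names(truth)[truth %in% c("ALG01", "ALG02")][1:2]
  fuse <- g$scaffold_id %in% s12
  # concatenate the second scaffold after the first along coordinates
  off <- max(g$start[g$scaffold_id == s12[1]]) + 1000L
  sel2 <- g$scaffold_id == s12[2]
  g$start[sel2] <- g$start[sel2] + off
  g$end[sel2] <- g$end[sel2] + off
  g$scaffold_id[fuse] <- "fused"
  sc <- scoreScaffoldAlg(buildIncidence(g), buildIncidence(sim$refGenes),
                         refAlgTable(sim), queryGenes = g)
  nSig <- tapply(enrichmentTable(sc)$significant_strict,
                 enrichmentTable(sc)$scaffold_id, sum)
  expect_equal(unname(nSig[["fused"]]), 2L)
  sp <- splitMultiAlgScaffolds(sc, g)
  expect_equal(sp$splits, "fused")
  res2 <- enrichmentTable(sp$screen)
  expect_setequal(intersect(unique(res2$scaffold_id),
                            c("fused:1", "fused:2", "fused")),
                  c("fused:1", "fused:2"))
  expect_equal(sp$screen@params$m,
               syntenySummary(sp$screen)$n_scaffolds_tested * 4)
  # the two segments back the two different ALGs
  segAlg <- vapply(c("fused:1", "fused:2"), function(s) {
    rr <- res2[res2$scaffold_id == s & res2$significant_strict, ]
    rr$alg_id[which.min(rr$p_raw)]
  }, character(1))
  expect_setequal(unname(segAlg), c("ALG01", "ALG02"))
})

test_that("a scaffold significant for a single ALG is left whole", {
  sim <- simulateMacrosyntenyPair(nAlgs = 4, familiesPerAlg = 20,
                                  scaffoldsPerGenome = 8,
                                  translocationRate = 0, seed = 12)
  sc <- scoreScaffoldAlg(buildIncidence(sim$queryGenes),
                         buildIncidence(sim$refGenes), refAlgTable(sim))
  sp <- splitMultiAlgScaffolds(sc, sim$queryGenes)
  expect_length(sp$splits, 0)
  expect_identical(enrichmentTable(sp$screen), enrichmentTable(sc))
})

test_that("linkage groups are re-derived exactly against a chromosome-scale outgroup", {
  # the outgroup genome keeps one scaffold per linkage group, the way
  # chromosome-level anchors are used to cluster a fragmented assembly
  sim <- simulateMacrosyntenyPair(nAlgs = 5, familiesPerAlg = 60,
                                  scaffoldsPerGenome = 5,
                                  scaffoldsRef = 15,
                                  translocationRate = 0, lossRate = 0,
                                  seed = 77)
  algs <- deriveAlgs(buildIncidence(sim$refGenes),
                     buildIncidence(sim$queryGenes))
  truth <- sim$truth$scaffoldAlg$genomeR
  expect_setequal(algs$scaffold_id, names(truth))
  expect_equal(normalizedMutualInfo(algs$alg_id,
                                    truth[algs$scaffold_id]), 1)
})

test_that("independent genomes yield no linkage edges after correction", {
  ok <- 0L
  for (seed in 1:5) {
    sim <- simulateMacrosyntenyPair(nAlgs = 5, familiesPerAlg = 60,
                                    scaffoldsPerGenome = 5,
                                    scaffoldsRef = 15,
                                    translocationRate = 1, lossRate = 0,
                                    seed = seed)
    algs <- deriveAlgs(buildIncidence(sim$refGenes),
                       buildIncidence(sim$queryGenes))
    if (attr(algs, "n_edges") == 0L) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("a one-scaffold reference genome forms a single ALG", {
  g <- tinyGeneDf("only", 30, species = "ref",
                  family = sprintf("f%02d", 1:30))
  o <- tinyGeneDf("out", 30, species = "out",
                  family = sprintf("f%02d", 1:30), prefix = "o")
  algs <- deriveAlgs(buildIncidence(g), buildIncidence(o))
  expect_equal(nrow(algs), 1L)
  expect_equal(algs$scaffold_id, "only")
})

test_that("dot-plot export conserves pairs and is block-diagonal without noise", {
  sim <- simulateMacrosyntenyPair(nAlgs = 4, familiesPerAlg = 25,
                                  scaffoldsPerGenome = 8,
                                  translocationRate = 0, lossRate = 0,
                                  seed = 4)
  algs <- refAlgTable(sim)
  sc <- scoreScaffoldAlg(buildIncidence(sim$queryGenes),
                         buildIncidence(sim$refGenes), algs)
  dots <- exportDotplot(sc, sim$queryGenes, sim$refGenes, algs)
  nq <- table(sim$queryGenes$family_id)
  nr <- table(sim$refGenes$family_id)
  expect_equal(nrow(dots), sum(as.numeric(nq) * as.numeric(nr[names(nq)])))
  expect_equal(mean(dots$query_alg != dots$ref_alg), 0)
  # deterministic ordering
  dots2 <- exportDotplot(sc, sim$queryGenes, sim$refGenes, algs)
  expect_identical(dots, dots2)
})

test_that("full shuffling pushes the off-block dot fraction towards (A-1)/A", {
  sim <- simulateMacrosyntenyPair(nAlgs = 10, familiesPerAlg = 80,
                                  scaffoldsPerGenome = 10,
                                  genesPerFamily = 1L,
                                  translocationRate = 1, lossRate = 0,
                                  seed = 14)
  algs <- refAlgTable(sim)
  sc <- scoreScaffoldAlg(buildIncidence(sim$queryGenes),
                         buildIncidence(sim$refGenes), algs)
  dots <- exportDotplot(sc, sim$queryGenes, sim$refGenes, algs)
  expect_gt(mean(dots$query_alg != dots$ref_alg), 0.8)
})

test_that("ALG recovery stays high under moderate translocation", {
  sim <- simulateMacrosyntenyPair(nAlgs = 8, familiesPerAlg = 40,
                                  scaffoldsPerGenome = 16,
                                  genesPerFamily = 2:3,
                                  translocationRate = 0.2, lossRate = 0.1,
                                  seed = 31)
  sc <- scoreScaffoldAlg(buildIncidence(sim$queryGenes),
                         buildIncidence(sim$refGenes), refAlgTable(sim))
  s <- syntenySummary(sc)$scaffolds
  truth <- sim$truth$scaffoldAlg$genomeQ[s$scaffold_id]
  expect_gte(normalizedMutualInfo(s$best_alg, truth), 0.9)
})
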