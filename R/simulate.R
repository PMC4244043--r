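#' Simulate a pair of genomes descended from block-structured linkage
#' groups
#'
#' An ancestral gene set is partitioned into \code{nAlgs} linkage
#' groups; each descendant genome lays the families of one group down
#' contiguously over its scaffolds, then degrades the signal: every gene
#' is independently relocated to a uniformly random scaffold with
#' probability \code{translocationRate} and deleted with probability
#' \code{lossRate}. The returned truth records every placement, so
#' macro-synteny recovery can be scored exactly.
#'
#' @param nAlgs number of ancestral linkage groups (default 18).
#' @param familiesPerAlg families per group (default 60).
#' @param scaffoldsPerGenome scaffolds in the query genome (default
#'   40); scaffolds are assigned to ALGs round-robin.
#' @param scaffoldsRef scaffolds in the reference genome (defaults to
#'   \code{scaffoldsPerGenome}; set to \code{nAlgs} for a
#'   chromosome-scale reference with one scaffold per linkage group).
#' @param genesPerFamily integer vector; each genome draws its copy
#'   number per family uniformly from it (default 1:3).
#' @param translocationRate,lossRate per-gene probabilities in [0, 1].
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return list: \code{queryGenes}, \code{refGenes} (gene tables with
#'   family_id set), \code{orthologs} (family_id/species/gene_id
#'   data.frame) and \code{truth} (family -> ALG, scaffold -> ALG per
#'   genome, per-gene translocation flags, echoed params).
#' @export
simulateMacrosyntenyPair <- function(nAlgs = 18, familiesPerAlg = 60,
                                     scaffoldsPerGenome = 40,
                                     scaffoldsRef = scaffoldsPerGenome,
                                     genesPerFamily = 1:3,
                                     translocationRate = 0, lossRate = 0,
                                     seed = 1) {
  if (translocationRate < 0 || translocationRate > 1 ||
      lossRate < 0 || lossRate > 1)
    stop("rates must lie in [0, 1]")
  if (nAlgs < 2 || scaffoldsPerGenome < nAlgs || scaffoldsRef < nAlgs)
    stop("need nAlgs >= 2 and at least one scaffold per ALG")
  withSeed(seed, {
    algIds <- sprintf("ALG%02d", seq_len(nAlgs))
    nFam <- nAlgs * familiesPerAlg
    famIds <- sprintf("fam%05d", seq_len(nFam))
    famAlg <- stats::setNames(rep(algIds, each = familiesPerAlg), famIds)

    makeGenome <- function(species, nScf) {
      scf <- sprintf("%s_scf%03d", species, seq_len(nScf))
      scfAlg <- stats::setNames(
        algIds[((seq_len(nScf) - 1L) %% nAlgs) + 1L], scf)
      # families of an ALG split contiguously over that ALG's scaffolds
      homeScf <- character(nFam)
      for (a in algIds) {
        s <- scf[scfAlg == a]
        f <- which(famAlg == a)
        homeScf[f] <- s[ceiling(seq_along(f) / (length(f) / length(s)))]
      }
      nCopies <- sample(genesPerFamily, nFam, replace = TRUE)
      fam <- rep(famIds, nCopies)
      home <- rep(homeScf, nCopies)
      nG <- length(fam)
      trans <- stats::runif(nG) < translocationRate
      dest <- home
      dest[trans] <- sample(scf, sum(trans), replace = TRUE)
      lost <- stats::runif(nG) < lossRate
      geneId <- sprintf("%s_g%05d", species, seq_len(nG))
      keep <- !lost
      # order genes along each scaffold: native genes keep ancestral
      # order, translocated genes land at uniform random ranks
      key <- ifelse(trans, stats::runif(nG, 0, nG), seq_len(nG))
      df <- data.frame(gene_id = geneId[keep], species = species,
                       scaffold_id = dest[keep],
                       key = key[keep],
                       strand = sample(c("+", "-"), sum(keep),
                                       replace = TRUE),
                       family_id = fam[keep], stringsAsFactors = FALSE)
      df <- df[order(df$scaffold_id, df$key), , drop = FALSE]
      rank <- stats::ave(seq_len(nrow(df)), df$scaffold_id, FUN = seq_along)
      df$start <- (rank - 1L) * 1000L
      df$end <- df$start + 600L
      df$key <- NULL
      df <- df[, c("gene_id", "species", "scaffold_id", "start", "end",
                   "strand", "family_id")]
      rownames(df) <- NULL
      list(genes = df, scaffoldAlg = scfAlg,
           placement = data.frame(gene_id = geneId, family_id = fam,
                                  home_scaffold = home, scaffold = dest,
                                  translocated = trans, lost = lost,
                                  stringsAsFactors = FALSE))
    }
    q <- makeGenome("genomeQ", scaffoldsPerGenome)
    r <- makeGenome("genomeR", scaffoldsRef)
    orth <- rbind(
      data.frame(family_id = q$genes$family_id, species = "genomeQ",
                 gene_id = q$genes$gene_id, stringsAsFactors = FALSE),
      data.frame(family_id = r$genes$family_id, species = "genomeR",
                 gene_id = r$genes$gene_id, stringsAsFactors = FALSE))
    list(queryGenes = q$genes, refGenes = r$genes, orthologs = orth,
         truth = list(familyAlg = famAlg,
                      scaffoldAlg = list(genomeQ = q$scaffoldAlg,
                                         genomeR = r$scaffoldAlg),
                      placement = list(genomeQ = q$placement,
                                       genomeR = r$placement),
                      params = list(n_algs = nAlgs,
                                    families_per_alg = familiesPerAlg,
                                    scaffolds_per_genome = scaffoldsPerGenome,
                                    scaffolds_ref = scaffoldsRef,
                                    genes_per_family = genesPerFamily,
                                    translocation_rate = translocationRate,
                                    loss_rate = lossRate, seed = seed)))
  })
}

#' Simulate gene-body CpG o/e values from a three-class methylation
#' signature
#'
#' Draws one mixture component per gene and a truncated-normal (at 0)
#' value from it. The defaults are the study conditions of the gene-body
#' methylation analysis: n = 14,992 genes, component means 0.62 / 1.00 /
#' 1.48 with the low (historically methylated) class carrying 9.5\% of
#' the mass.
#'
#' With \code{emitSequences = TRUE} an actual DNA sequence is emitted per
#' gene whose realised CpG o/e hits the drawn target within ±0.02, by
#' iterative CpG thinning/seeding with rejection on the realised profile.
#'
#' @param n number of genes.
#' @param weights,means,sds component parameters (means ascending).
#' @param seed integer seed.
#' @param emitSequences also emit sequences (slow; intended for small n).
#' @param seqLength emitted sequence length in bp (default 1500).
#' @return list: \code{values}, \code{truth} (data.frame gene/component/
#'   value + echoed params), and \code{sequences} (named character) when
#'   requested.
#' @export
simulateCpgGenes <- function(n = 14992,
                             weights = c(0.095, 0.80, 0.105),
                             means = c(0.62, 1.00, 1.48),
                             sds = c(0.10, 0.15, 0.12),
                             seed = 1, emitSequences = FALSE,
                             seqLength = 1500) {
  stopifnot(length(weights) == length(means), length(means) == length(sds))
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (is.unsorted(means)) stop("means must be ascending")
  withSeed(seed, {
    comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    val <- stats::rnorm(n, means[comp], sds[comp])
    while (any(val <= 0))                    # truncate at 0 by rejection
      val[val <= 0] <- stats::rnorm(sum(val <= 0), means[comp[val <= 0]],
                                    sds[comp[val <= 0]])
    out <- list(values = val,
                truth = data.frame(gene = sprintf("gene%05d", seq_len(n)),
                                   component = comp, value = val),
                params = list(n = n, weights = weights, means = means,
                              sds = sds, seed = seed))
    if (emitSequences)
      out$sequences <- stats::setNames(
        vapply(val, emitCpgSequence, character(1), length = seqLength),
        out$truth$gene)
    out
  })
}

# Build one sequence whose realised CpG o/e is within tol of target, by
# destroying or seeding CG dinucleotides one site at a time.
emitCpgSequence <- function(target, length = 1500, tol = 0.02,
                            maxIter = NULL) {
  if (target < 0) stop("target o/e must be non-negative")
  if (is.null(maxIter)) maxIter <- 5L * length
  s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  oeCG <- function(s) {
    L <- base::length(s)
    nC <- sum(s == "C"); nG <- sum(s == "G")
    if (nC == 0 || nG == 0) return(NA_real_)
    cg <- sum(s[-L] == "C" & s[-1] == "G")
    (cg / (L - 1)) / ((nC / L) * (nG / L))
  }
  # Edits mimic the strand-symmetric deamination path (CpG -> TpG on
  # one strand, CpG -> CpA on the other, and the reverse to seed CpG),
  # so no single other dinucleotide absorbs the whole compositional
  # shift.
  for (i in seq_len(maxIter)) {
    cur <- oeCG(s)
    if (is.na(cur)) stop("degenerate sequence (no C or no G)")
    if (abs(cur - target) <= tol) return(paste(s, collapse = ""))
    L <- base::length(s)
    isCG <- which(s[-L] == "C" & s[-1] == "G")
    if (cur > target) {
      if (!length(isCG))
        stop("cannot lower o/e to ", target, ": no CpG left")
      j <- isCG[sample.int(length(isCG), 1)]
      if (stats::runif(1) < 0.5) s[j] <- sample(c("T", "A"), 1)
      else s[j + 1L] <- sample(c("A", "T"), 1)
    } else {
      cSide <- which(s[-L] %in% c("T", "A") & s[-1] == "G")
      gSide <- which(s[-L] == "C" & s[-1] %in% c("A", "T"))
      pickC <- if (length(cSide) && length(gSide)) stats::runif(1) < 0.5
               else length(cSide) > 0
      if (pickC && length(cSide)) {
        j <- cSide[sample.int(length(cSide), 1)]
        s[j] <- "C"
      } else if (length(gSide)) {
        j <- gSide[sample.int(length(gSide), 1)]
        s[j + 1L] <- "G"
      } else stop("infeasible target o/e ", target, " for length ", L)
    }
  }
  stop("could not reach target o/e ", target, " within ", maxIter,
       " edits")
}

#' Simulate male/female per-scaffold read depths under an XY system
#'
#' Expected depth per scaffold is \code{meanDepth} times the dosage of
#' its class in each sex (male X and Y: 0.5; female X: 1; female Y: 0;
#' autosomes: 1), with multiplicative gamma noise. The noise coefficient
#' of variation is \code{overdispersion * sqrt(10kb / length)}: a
#' scaffold's mean depth averages over its length, so depth noise
#' shrinks with scaffold size (the 10 kb reference length anchors the
#' scale).
#'
#' @param nScaffolds number of scaffolds (default 1000).
#' @param propX,propY class proportions (defaults 0.05 and 0.01); exact
#'   counts \code{round(prop * n)} are used so the truth is fixed.
#' @param meanDepth autosomal depth (default 30).
#' @param overdispersion noise cv at the 10 kb reference length.
#' @param lengthMeanlog,lengthSdlog lognormal scaffold-length parameters
#'   (default median 50 kb).
#' @param nFemales number of female samples (default 3, plus one male).
#' @param seed integer seed.
#' @return list: \code{depths} (long table as [readDepthTable()]),
#'   \code{sexes} (sample_id/sex) and \code{truth} (scaffold_id, length,
#'   sex_class, echoed params).
#' @export
simulateCoverage <- function(nScaffolds = 1000, propX = 0.05, propY = 0.01,
                             meanDepth = 30, overdispersion = 0.1,
                             lengthMeanlog = log(5e4), lengthSdlog = 0.6,
                             nFemales = 3, seed = 1) {
  if (propX + propY >= 1) stop("class proportions must sum to < 1")
  withSeed(seed, {
    nX <- round(propX * nScaffolds); nY <- round(propY * nScaffolds)
    cls <- sample(c(rep("X", nX), rep("Y", nY),
                    rep("autosome", nScaffolds - nX - nY)))
    len <- round(stats::rlnorm(nScaffolds, lengthMeanlog, lengthSdlog))
    ids <- sprintf("scf%05d", seq_len(nScaffolds))
    samples <- c("male1", paste0("female", seq_len(nFemales)))
    sexes <- data.frame(sample_id = samples,
                        sex = c("male", rep("female", nFemales)),
                        stringsAsFactors = FALSE)
    dosage <- function(cls, sex) {
      ifelse(cls == "autosome", 1,
        ifelse(cls == "X", ifelse(sex == "male", 0.5, 1),
               ifelse(sex == "male", 0.5, 0)))       # Y
    }
    cv <- overdispersion * sqrt(1e4 / len)
    rows <- lapply(seq_along(samples), function(i) {
      d <- meanDepth * dosage(cls, sexes$sex[i])
      noise <- rep(1, nScaffolds)
      pos <- cv > 0 & d > 0
      noise[pos] <- stats::rgamma(sum(pos), shape = 1 / cv[pos]^2,
                                  rate = 1 / cv[pos]^2)
      data.frame(scaffold_id = ids, length = len, sample_id = samples[i],
                 mean_depth = d * noise, stringsAsFactors = FALSE)
    })
    list(depths = do.call(rbind, rows), sexes = sexes,
         truth = data.frame(scaffold_id = ids, length = len,
                            sex_class = cls, stringsAsFactors = FALSE),
         params = list(n_scaffolds = nScaffolds, prop_x = propX,
                       prop_y = propY, mean_depth = meanDepth,
                       overdispersion = overdispersion,
                       length_meanlog = lengthMeanlog,
                       length_sdlog = lengthSdlog,
                       n_females = nFemales, seed = seed))
  })
}

#' Simulate gene-family presence/absence under single-gain /
#' multiple-loss (Dollo) dynamics
#'
#' Each family is gained once at a node (the root with probability
#' \code{fracRootFamilies}, otherwise a uniformly chosen non-root
#' internal node) and then lost independently on every branch of the
#' surviving subtree with probability \code{lossProb}; everything below
#' a lost branch stays absent. Tip states form the matrix; all gain and
#' loss events are recorded as truth.
#'
#' @param tree rooted \code{ape::phylo}.
#' @param nFamilies number of families (default 200).
#' @param lossProb per-branch loss probability in [0, 0.5].
#' @param fracRootFamilies fraction gained at the root (default 0.8).
#' @param seed integer seed.
#' @return list: \code{pa} (families x tips 0/1 matrix), \code{truth}
#'   (data.frame family/gain_node/loss_branches/n_losses) and echoed
#'   \code{params}.
#' @export
simulateDollo <- function(tree, nFamilies = 200, lossProb = 0.1,
                          fracRootFamilies = 0.8, seed = 1) {
  if (lossProb < 0 || lossProb > 0.5)
    stop("lossProb must lie in [0, 0.5]")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  withSeed(seed, {
    nTip <- ape::Ntip(tree)
    root <- nTip + 1L
    names <- nodeNames(tree)
    ch <- childrenList(tree)
    internal <- setdiff((nTip + 1L):(nTip + tree$Nnode), root)
    fams <- sprintf("fam%04d", seq_len(nFamilies))
    pa <- matrix(0L, nFamilies, nTip, dimnames = list(fams, tree$tip.label))
    truth <- vector("list", nFamilies)
    for (f in seq_len(nFamilies)) {
      gain <- if (!length(internal) || stats::runif(1) < fracRootFamilies)
        root else internal[sample.int(length(internal), 1)]
      lossEdges <- character(0)
      stack <- gain
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (v <= nTip) { pa[f, v] <- 1L; next }
        for (w in ch[[v]]) {
          if (stats::runif(1) < lossProb)
            lossEdges <- c(lossEdges, paste0(names[v], "->", names[w]))
          else stack <- c(stack, w)
        }
      }
      truth[[f]] <- data.frame(family_id = fams[f], gain_node = names[gain],
                               n_losses = length(lossEdges),
                               loss_branches = paste(lossEdges,
                                                     collapse = ";"),
                               stringsAsFactors = FALSE)
    }
    list(pa = pa, truth = do.call(rbind, truth),
         params = list(n_families = nFamilies, loss_prob = lossProb,
                       frac_root_families = fracRootFamilies, seed = seed))
  })
}
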