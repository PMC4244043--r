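writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stopMissing <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop(structure(class = c("agt_missing_input", "error", "condition"),
                   list(message = paste0("missing ", what, ": ",
                                         if (is.null(path)) "(not given)"
                                         else path),
                        call = sys.call(-1))))
  path
}

stopInvalid <- function(msg) {
  stop(structure(class = c("agt_validation", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

writeParams <- function(config, outPrefix) {
  jsonlite::write_json(config, paste0(outPrefix, ".params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

#' Run the macro-synteny screen end to end from files
#'
#' Reads the two gene tables, the ortholog families and the ALG
#' definitions (or derives ALGs from the reference against the query
#' when none are given), runs [scoreScaffoldAlg()] with scaffold
#' splitting, and writes \code{<out>.enrichment.tsv},
#' \code{<out>.summary.tsv}, \code{<out>.dotplot.tsv} and
#' \code{<out>.params.json}.
#'
#' @param queryGenes,refGenes gene table paths.
#' @param orthologs ortholog TSV path (family_id, species, gene_id).
#' @param algs ALG definition TSV path (alg_id, scaffold_id), optional.
#' @param format gene table format, \code{"bed"} or \code{"gff3"}.
#' @param querySpecies,refSpecies species labels used in the ortholog
#'   table.
#' @param minGenes,strict,relaxed screen parameters.
#' @param split try to split scaffolds significant for two ALGs.
#' @param out output prefix.
#' @return the final [SyntenyScreen-class], invisibly.
#' @export
runSynteny <- function(queryGenes, refGenes, orthologs, algs = NULL,
                       format = "bed", querySpecies = "genomeQ",
                       refSpecies = "genomeR", minGenes = 20,
                       strict = 1e-4, relaxed = 1e-2, split = TRUE,
                       out = "synteny") {
  stopMissing(queryGenes, "query gene table")
  stopMissing(refGenes, "reference gene table")
  stopMissing(orthologs, "ortholog table")
  if (!is.numeric(minGenes) || minGenes < 1)
    stopInvalid("minGenes must be a positive number")
  q <- readGeneTable(queryGenes, format, species = querySpecies)
  r <- readGeneTable(refGenes, format, species = refSpecies)
  fam <- readOrthologPairs(orthologs)
  q <- assignFamilies(q, fam)
  r <- assignFamilies(r, fam)
  qInc <- buildIncidence(q)
  rInc <- buildIncidence(r)
  algDf <- if (is.null(algs)) deriveAlgs(rInc, qInc, edgeP = strict,
                                         minGenes = minGenes)
           else readAlgTable(stopMissing(algs, "ALG table"))
  screen <- scoreScaffoldAlg(qInc, rInc, algDf, minGenes = minGenes,
                             thresholds = c(strict, relaxed),
                             queryGenes = q)
  if (split) {
    sp <- splitMultiAlgScaffolds(screen, q)
    screen <- sp$screen
    q <- sp$genes
  }
  writeTsv(enrichmentTable(screen), paste0(out, ".enrichment.tsv"))
  s <- syntenySummary(screen)
  writeTsv(data.frame(metric = setdiff(names(s), "scaffolds"),
                      value = vapply(s[setdiff(names(s), "scaffolds")],
                                     function(v) as.character(v[1]),
                                     character(1))),
           paste0(out, ".summary.tsv"))
  writeTsv(exportDotplot(screen, q, r, algDf), paste0(out, ".dotplot.tsv"))
  writeParams(list(subcommand = "synteny", query_genes = queryGenes,
                   ref_genes = refGenes, orthologs = orthologs,
                   algs = algs, format = format, min_genes = minGenes,
                   strict = strict, relaxed = relaxed, split = split,
                   out = out), out)
  invisible(screen)
}

#' Run the CpG methylation-signature analysis from FASTA input
#'
#' Profiles gene-body sequences (and optionally 1 kb genome windows),
#' fits the Gaussian mixture to the CpG o/e values and writes
#' \code{<out>.profiles.tsv}, \code{<out>.mixture.json},
#' \code{<out>.classes.tsv} and \code{<out>.params.json}.
#'
#' @param fasta gene-body FASTA path.
#' @param windowsFasta optional genome FASTA to tile.
#' @param window window size in bp.
#' @param kmax largest mixture size tried.
#' @param seed seed for the mixture restarts.
#' @param minLength gene bodies shorter than this are excluded from the
#'   mixture (ratio noise; default 200 bp).
#' @param out output prefix.
#' @return list with the profile table, the [MixtureFit-class] and the
#'   classification, invisibly.
#' @export
runCpg <- function(fasta, windowsFasta = NULL, window = 1000, kmax = 4,
                   seed = 17, minLength = 200, out = "cpg") {
  stopMissing(fasta, "gene-body FASTA")
  if (file.size(fasta) == 0) stopMissing(NULL, "gene-body FASTA (empty file)")
  if (kmax < 1) stopInvalid("kmax must be >= 1")
  prof <- dinucleotideProfile(fasta)
  writeTsv(prof, paste0(out, ".profiles.tsv"))
  vals <- prof$oe_CG[prof$length >= minLength]
  fit <- fitGaussianMixture(vals, kRange = seq_len(kmax), seed = seed)
  cls <- classifyMethylation(fit)
  jsonlite::write_json(
    list(k = mixtureK(fit), means = mixtureMeans(fit),
         sds = mixtureSds(fit), weights = mixtureWeights(fit),
         logLik = fit@logLik, bic = fit@bic,
         bic_table = fit@bicTable,
         low_fraction_soft = cls$low_fraction_soft,
         low_fraction_hard = cls$low_fraction_hard),
    paste0(out, ".mixture.json"), auto_unbox = TRUE, digits = NA)
  keep <- prof$length >= minLength
  writeTsv(data.frame(seq_id = prof$seq_id[keep], oe_CG = vals,
                      class = cls$classes),
           paste0(out, ".classes.tsv"))
  res <- list(profiles = prof, fit = fit, classes = cls)
  if (!is.null(windowsFasta)) {
    wp <- windowProfiles(stopMissing(windowsFasta, "genome FASTA"),
                         window = window)
    writeTsv(wp, paste0(out, ".windows.tsv"))
    res$windowProfiles <- wp
  }
  writeParams(list(subcommand = "cpg", fasta = fasta,
                   windows_fasta = windowsFasta, window = window,
                   kmax = kmax, seed = seed, min_length = minLength,
                   out = out), out)
  invisible(res)
}

#' Run the sex-linkage coverage classification from depth tables
#'
#' Writes \code{<out>.classes.tsv}, \code{<out>.summary.tsv} and a
#' histogram table \code{<out>.hist.tsv} of normalised depths per sex
#' (the male histogram of an XY genome shows the underrepresented
#' half-depth scaffold fraction; the female one does not).
#'
#' @param depths depth TSV path (scaffold_id, length, sample_id,
#'   mean_depth).
#' @param sexes sample-sex TSV path.
#' @param minLength ambiguity flag for short scaffolds (bp).
#' @param out output prefix.
#' @return the [SexLinkageCall-class], invisibly.
#' @export
runSexcov <- function(depths, sexes, minLength = 10000, out = "sexcov") {
  d <- readDepthTable(stopMissing(depths, "depth table"))
  s <- readSampleSexes(stopMissing(sexes, "sample-sex table"))
  norm <- normalizeDepths(d, s, minLength = minLength)
  call <- classifySexLinkage(norm)
  writeTsv(classTable(call), paste0(out, ".classes.tsv"))
  sm <- callSummary(call)
  writeTsv(data.frame(class = names(sm$class_counts),
                      n = as.integer(sm$class_counts),
                      span_fraction = as.numeric(sm$span_fraction),
                      mean_fm_copy_ratio =
                        as.numeric(sm$mean_fm_copy_ratio)),
           paste0(out, ".summary.tsv"))
  breaks <- seq(0, max(norm$norm_depth) + 0.05, by = 0.05)
  hist <- do.call(rbind, lapply(split(norm, norm$sex), function(x) {
    h <- graphics::hist(x$norm_depth, breaks = breaks, plot = FALSE)
    data.frame(sex = x$sex[1], bin_low = utils::head(h$breaks, -1),
               bin_high = h$breaks[-1], count = h$counts)
  }))
  writeTsv(hist, paste0(out, ".hist.tsv"))
  writeParams(list(subcommand = "sexcov", depths = depths, sexes = sexes,
                   min_length = minLength, out = out), out)
  invisible(call)
}

#' Run the Dollo gene-content reconstruction from files
#'
#' Writes \code{<out>.nodes.tsv} (ancestral content per node) and
#' \code{<out>.branches.tsv} (per-branch gains and losses) — the
#' annotation table of a gains/losses tree figure.
#'
#' @param tree rooted newick path.
#' @param matrix presence/absence TSV path (family_id + 0/1 species
#'   columns).
#' @param outgroupSpecies optional character vector of outgroup columns
#'   for the root rule.
#' @param minPresent outgroup-rule threshold (default 2).
#' @param out output prefix.
#' @return the [DolloReconstruction-class], invisibly.
#' @export
runDollo <- function(tree, matrix, outgroupSpecies = NULL, minPresent = 2,
                     out = "dollo") {
  tr <- readSpeciesTree(stopMissing(tree, "species tree"))
  pa <- readPresenceAbsence(stopMissing(matrix, "presence/absence matrix"))
  flags <- if (!is.null(outgroupSpecies))
    applyOutgroupRule(pa, outgroupSpecies, minPresent) else NULL
  keep <- setdiff(colnames(pa), outgroupSpecies)
  rec <- dolloReconstruct(tr, pa[, keep, drop = FALSE], flags)
  writeTsv(data.frame(node = names(nodeContent(rec)),
                      n_families = as.integer(nodeContent(rec))),
           paste0(out, ".nodes.tsv"))
  writeTsv(branchEvents(rec), paste0(out, ".branches.tsv"))
  writeParams(list(subcommand = "dollo", tree = tree, matrix = matrix,
                   outgroup_species = outgroupSpecies,
                   min_present = minPresent, out = out), out)
  invisible(rec)
}

#' Write a synthetic scenario to disk
#'
#' Generates one of the four ground-truthed scenarios and writes its
#' input files plus \code{truth.tsv} and \code{params.json} into
#' \code{dir}.
#'
#' @param scenario one of \code{"synteny"}, \code{"cpg"},
#'   \code{"coverage"}, \code{"dollo"}.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param ... passed to the scenario's generator.
#' @return the generator's return value, invisibly.
#' @export
runSimulate <- function(scenario = c("synteny", "cpg", "coverage", "dollo"),
                        dir, seed = 1, ...) {
  scenario <- match.arg(scenario)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  if (scenario == "synteny") {
    sim <- simulateMacrosyntenyPair(seed = seed, ...)
    writeGeneTable(sim$queryGenes, p("query_genes.bed"))
    writeGeneTable(sim$refGenes, p("ref_genes.bed"))
    writeTsv(sim$orthologs, p("orthologs.tsv"))
    writeTsv(data.frame(alg_id = unname(sim$truth$scaffoldAlg$genomeR),
                        scaffold_id = names(sim$truth$scaffoldAlg$genomeR)),
             p("algs.tsv"))
    writeTsv(data.frame(family_id = names(sim$truth$familyAlg),
                        alg_id = unname(sim$truth$familyAlg)),
             p("truth.tsv"))
    jsonlite::write_json(sim$truth$params, p("params.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (scenario == "cpg") {
    sim <- simulateCpgGenes(seed = seed, ...)
    writeTsv(sim$truth, p("cpg_values.tsv"))
    if (!is.null(sim$sequences))
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(sim$sequences), p("genes.fa"))
    writeTsv(sim$truth, p("truth.tsv"))
    jsonlite::write_json(sim$params, p("params.json"), auto_unbox = TRUE,
                         digits = NA)
  } else if (scenario == "coverage") {
    sim <- simulateCoverage(seed = seed, ...)
    writeTsv(sim$depths, p("depths.tsv"))
    writeTsv(sim$sexes, p("samples.tsv"))
    writeTsv(sim$truth, p("truth.tsv"))
    jsonlite::write_json(sim$params, p("params.json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    args <- list(...)
    if (is.null(args$tree))
      stopInvalid("simulate dollo needs a 'tree' (phylo or newick path)")
    tr <- if (inherits(args$tree, "phylo")) args$tree
          else readSpeciesTree(args$tree)
    args$tree <- tr
    sim <- do.call(simulateDollo, c(args, list(seed = seed)))
    writeTsv(data.frame(family_id = rownames(sim$pa),
                        as.data.frame(sim$pa), check.names = FALSE),
             p("matrix.tsv"))
    ape::write.tree(tr, p("tree.nwk"))
    writeTsv(sim$truth, p("truth.tsv"))
    jsonlite::write_json(sim$params, p("params.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(sim)
}

#' Re-run the synteny screen from a published gene-pair/ALG table
#'
#' For reproducing a published scaffold-vs-ALG analysis from its
#' deposited gene-pair table: one row per ancestral-orthology gene with
#' the query scaffold it sits on, its family and the reference ALG of
#' that family. Column names are mapped explicitly — the reader never
#' guesses semantics.
#'
#' @param path TSV path with a header.
#' @param cols named character vector mapping the required roles
#'   \code{scaffold}, \code{family}, \code{alg} (and optionally
#'   \code{gene}) to column names in the file.
#' @param minGenes,thresholds screen parameters (defaults: the published
#'   filter of 20 ancestral genes and thresholds 1e-4 / 1e-2 on the
#'   Bonferroni-adjusted p).
#' @return a [SyntenyScreen-class].
#' @export
reproduceSynteny <- function(path,
                             cols = c(scaffold = "scaffold",
                                      family = "family_id",
                                      alg = "alg_id", gene = "gene_id"),
                             minGenes = 20,
                             thresholds = c(1e-4, 1e-2)) {
  df <- utils::read.delim(stopMissing(path, "gene-pair table"),
                          comment.char = "#", check.names = FALSE)
  need <- cols[c("scaffold", "family", "alg")]
  if (!all(need %in% names(df)))
    stopInvalid(paste("gene-pair table lacks column(s):",
                      paste(setdiff(need, names(df)), collapse = ", ")))
  genes <- data.frame(
    gene_id = if (!is.na(cols["gene"]) && cols["gene"] %in% names(df))
      as.character(df[[cols["gene"]]])
      else sprintf("row%06d", seq_len(nrow(df))),
    species = "query",
    scaffold_id = as.character(df[[cols["scaffold"]]]),
    start = seq_len(nrow(df)), end = seq_len(nrow(df)) + 1L,
    strand = ".", family_id = as.character(df[[cols["family"]]]),
    stringsAsFactors = FALSE)
  famAlg <- tapply(as.character(df[[cols["alg"]]]),
                   as.character(df[[cols["family"]]]),
                   function(x) names(sort(table(x), decreasing = TRUE))[1])
  famAlg <- stats::setNames(as.character(famAlg), names(famAlg))
  scoreScaffoldAlg(buildIncidence(genes), familyAlg = famAlg,
                   minGenes = minGenes, thresholds = thresholds,
                   queryGenes = genes)
}

#' Refit the methylation-signature mixture from a published value table
#'
#' @param path TSV with a header; \code{column} names the CpG o/e
#'   column.
#' @param column column holding the per-gene CpG o/e values.
#' @param kmax,seed mixture-selection parameters.
#' @return list: the [MixtureFit-class] and the [classifyMethylation()]
#'   result.
#' @export
reproduceCpg <- function(path, column = "cpg_oe", kmax = 4, seed = 17) {
  df <- utils::read.delim(stopMissing(path, "CpG value table"),
                          comment.char = "#", check.names = FALSE)
  if (!column %in% names(df))
    stopInvalid(paste0("no '", column, "' column in ", path))
  vals <- as.numeric(df[[column]])
  fit <- fitGaussianMixture(vals, kRange = seq_len(kmax), seed = seed)
  list(fit = fit, classes = classifyMethylation(fit))
}

#' Dispatch a validated run configuration
#'
#' Single programmatic entry point behind the command-line wrapper:
#' \code{config} is a named list with \code{subcommand} plus that
#' subcommand's arguments; unknown keys are rejected. Outputs are
#' deterministic given the config (stochastic stages consume
#' \code{config$seed} through a fixed per-stage derivation).
#'
#' @param config named list; see [runSynteny()], [runCpg()],
#'   [runSexcov()], [runDollo()], [runSimulate()].
#' @return the subcommand's return value, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.null(config$subcommand))
    stopInvalid("config needs a 'subcommand'")
  sub <- config$subcommand
  config$subcommand <- NULL
  fun <- switch(sub,
    synteny = runSynteny, cpg = runCpg, sexcov = runSexcov,
    dollo = runDollo, simulate = runSimulate,
    stopInvalid(paste("unknown subcommand:", sub)))
  known <- names(formals(fun))
  bad <- setdiff(names(config), c(known, if (sub == "simulate") "..."))
  bad <- setdiff(bad, "...")
  if (length(bad) && !("..." %in% known))
    stopInvalid(paste("unknown config key(s):", paste(bad, collapse = ", ")))
  do.call(fun, config)
}
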