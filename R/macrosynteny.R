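#' One-sided Fisher's exact test for a 2x2 enrichment table
#'
#' Upper-tail hypergeometric probability \eqn{P(X \ge a)} under the null
#' of independence with the table's margins fixed, i.e. the probability
#' of an overlap at least as large as observed. This is the enrichment
#' alternative used for every scaffold-vs-ALG comparison.
#'
#' @param a,b,c,d non-negative integer (vectors recycle): \code{a} shared,
#'   \code{b} first-set-only, \code{c} second-set-only, \code{d} neither.
#' @return probability in (0, 1]; exactly 1 when a margin is empty (only
#'   one table is possible).
#' @examples
#' fisherOneSided(3, 1, 1, 3)   # 17/70
#' @export
fisherOneSided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != floor(c(a, b, c, d))))
    stop("table entries must be non-negative integers")
  # margins: draw (a+b) items from N with (a+c) "successes"
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Map each family to the ALG of its reference-genome location
#'
#' A family whose reference genes sit on scaffolds of more than one ALG
#' is assigned to the modal ALG (ties broken lexicographically) with a
#' warning; families on scaffolds outside every ALG get no assignment.
#'
#' @param refIncidence [FamilyIncidence-class] of the reference genome.
#' @param algs data.frame (alg_id, scaffold_id), e.g. [readAlgTable()].
#' @return named character vector family_id -> alg_id.
#' @export
familyAlgMap <- function(refIncidence, algs) {
  needCols(algs, c("alg_id", "scaffold_id"), "ALG table")
  cnt <- incidenceCounts(refIncidence)
  scfAlg <- stats::setNames(algs$alg_id, algs$scaffold_id)
  out <- character(0)
  multi <- 0L
  for (j in seq_len(ncol(cnt))) {
    scf <- rownames(cnt)[cnt[, j] > 0]
    a <- scfAlg[scf]
    a <- a[!is.na(a)]
    if (!length(a)) next
    tab <- sort(table(a), decreasing = TRUE)
    if (length(tab) > 1L) multi <- multi + 1L
    out[colnames(cnt)[j]] <- names(tab)[1]
  }
  if (multi > 0L)
    warning(multi, " families touch more than one reference ALG; ",
            "assigned to their modal ALG")
  out
}

.screenSummary <- function(results, scaffolds, nAlgs, familyAlg,
                           queryGenes = NULL) {
  nTested <- nrow(scaffolds)
  strictScf <- unique(results$scaffold_id[results$significant_strict])
  relaxScf <- unique(results$scaffold_id[results$significant_relaxed])
  algsHit <- unique(results$alg_id[results$significant_relaxed])
  pctGenes <- NA_real_
  pctFams <- NA_real_
  if (!is.null(queryGenes) && length(strictScf)) {
    g <- queryGenes[!is.na(queryGenes$family_id), , drop = FALSE]
    g$alg <- unname(familyAlg[g$family_id])
    g <- g[!is.na(g$alg) & g$scaffold_id %in% scaffolds$scaffold_id, ,
           drop = FALSE]
    if (nrow(g)) {
      sig <- results[results$significant_strict, c("scaffold_id", "alg_id")]
      key <- paste(sig$scaffold_id, sig$alg_id)
      gOnSig <- g[g$scaffold_id %in% strictScf, , drop = FALSE]
      if (nrow(gOnSig)) {
        hit <- paste(gOnSig$scaffold_id, gOnSig$alg) %in% key
        pctGenes <- 100 * mean(hit)
        fams <- !duplicated(paste(gOnSig$scaffold_id, gOnSig$family_id))
        pctFams <- 100 * mean(hit[fams])
      }
    }
  }
  list(n_scaffolds_tested = nTested,
       n_tests = nTested * nAlgs,
       n_significant_strict = length(strictScf),
       pct_scaffolds_relaxed = if (nTested) 100 * length(relaxScf) / nTested
                               else 0,
       n_algs_hit = length(algsHit),
       pct_genes_conserved_context = pctGenes,
       pct_families_conserved_context = pctFams,
       scaffolds = scaffolds)
}

#' Score every query scaffold against every ancestral linkage group
#'
#' The screen behind the conserved macro-synteny analysis: each query
#' scaffold carrying at least \code{minGenes} ancestral-orthology genes
#' is tested against all A ALGs by a one-sided Fisher's exact test on
#' family counts, Bonferroni-corrected over the full m = tested x A
#' comparisons, with significance called at a strict and a relaxed
#' threshold on the adjusted p.
#'
#' The 2x2 counts \emph{families}, not genes (rows: family present /
#' absent on the scaffold; columns: family's reference location in the
#' tested ALG / in another ALG), so tandem duplications cannot inflate
#' enrichment. Families absent from the reference or unassigned to any
#' ALG are excluded from the universe.
#'
#' @param queryIncidence [FamilyIncidence-class] of the query genome.
#' @param refIncidence reference [FamilyIncidence-class]; may be omitted
#'   when \code{familyAlg} is supplied directly.
#' @param algs ALG definitions data.frame (alg_id, scaffold_id); ignored
#'   when \code{familyAlg} is supplied.
#' @param familyAlg optional precomputed family -> ALG map (named
#'   character), e.g. from a published gene-pair table.
#' @param minGenes scaffold filter: minimum ancestral-orthology genes
#'   (default 20).
#' @param thresholds length-2 numeric, strict then relaxed threshold on
#'   the Bonferroni-adjusted p (defaults 1e-4 and 1e-2).
#' @param queryGenes optional query gene table; when given, the summary
#'   includes the percentage of ancestral-orthology genes (and families)
#'   on strictly significant scaffolds that lie in a conserved
#'   macro-synteny context (scaffold's significant ALG matches the
#'   gene's own family's ALG).
#' @return a [SyntenyScreen-class].
#' @export
scoreScaffoldAlg <- function(queryIncidence, refIncidence = NULL,
                             algs = NULL, familyAlg = NULL,
                             minGenes = 20,
                             thresholds = c(strict = 1e-4, relaxed = 1e-2),
                             queryGenes = NULL) {
  if (is.null(familyAlg)) {
    if (is.null(refIncidence) || is.null(algs))
      stop("supply either familyAlg or refIncidence + algs")
    familyAlg <- familyAlgMap(refIncidence, algs)
  }
  if (length(unique(familyAlg)) < 2L)
    stop("need at least 2 ALGs to test enrichment")
  thresholds <- as.numeric(thresholds)
  algIds <- sort(unique(familyAlg))
  A <- length(algIds)
  universe <- names(familyAlg)
  N <- length(universe)
  algSize <- table(factor(familyAlg, levels = algIds))

  totals <- scaffoldTotals(queryIncidence)
  tested <- names(totals)[totals >= minGenes]
  if (!length(tested)) {
    warning("no scaffold passes the >= ", minGenes, " ancestral-gene filter")
    empty <- data.frame(scaffold_id = character(), alg_id = character(),
                        a = integer(), b = integer(), c = integer(),
                        d = integer(), p_raw = numeric(), p_adj = numeric(),
                        significant_strict = logical(),
                        significant_relaxed = logical())
    return(new("SyntenyScreen", results = empty,
               summary = .screenSummary(empty,
                 data.frame(scaffold_id = character(), n_genes = integer(),
                            best_alg = character(), p_raw_best = numeric()),
                 A, familyAlg),
               familyALG = familyAlg,
               params = list(min_genes = minGenes, thresholds = thresholds,
                             m = 0L, n_algs = A)))
  }
  m <- length(tested) * A
  cnt <- incidenceCounts(queryIncidence)

  rows <- vector("list", length(tested))
  for (i in seq_along(tested)) {
    s <- tested[i]
    famOn <- colnames(cnt)[cnt[s, ] > 0]
    famOn <- intersect(famOn, universe)
    onAlg <- table(factor(familyAlg[famOn], levels = algIds))
    nOn <- length(famOn)
    a <- as.integer(onAlg)
    b <- nOn - a
    c_ <- as.integer(algSize) - a
    d <- N - nOn - c_
    p <- fisherOneSided(a, b, c_, d)
    rows[[i]] <- data.frame(scaffold_id = s, alg_id = algIds,
                            a = a, b = b, c = c_, d = d, p_raw = p,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$p_adj <- pmin(1, m * res$p_raw)
  res$significant_strict <- res$p_adj < thresholds[1]
  res$significant_relaxed <- res$p_adj < thresholds[2]
  rownames(res) <- NULL

  # per-scaffold best ALG: smallest raw p, then lexicographic alg_id
  ord <- order(res$scaffold_id, res$p_raw, res$alg_id)
  first <- !duplicated(res$scaffold_id[ord])
  best <- res[ord, ][first, , drop = FALSE]
  scaffolds <- data.frame(scaffold_id = best$scaffold_id,
                          n_genes = as.integer(totals[best$scaffold_id]),
                          best_alg = best$alg_id,
                          p_raw_best = best$p_raw,
                          stringsAsFactors = FALSE)
  scaffolds <- scaffolds[order(scaffolds$scaffold_id), , drop = FALSE]
  rownames(scaffolds) <- NULL

  new("SyntenyScreen", results = res,
      summary = .screenSummary(res, scaffolds, A, familyAlg, queryGenes),
      familyALG = familyAlg,
      params = list(min_genes = minGenes, thresholds = thresholds,
                    m = m, n_algs = A))
}

#' Split scaffolds that are strictly significant for two or more ALGs
#'
#' For each multi-ALG scaffold a single breakpoint is sought along gene
#' order that minimises family-ALG label mismatches between the two
#' sides; the scaffold is replaced by its two segments only if both
#' segments pass the gene filter and, after re-screening, are strictly
#' significant for two different ALGs. Otherwise the scaffold is left
#' whole. The screen (including m and the Bonferroni correction) is
#' recomputed over the revised tested units.
#'
#' @param screen a [SyntenyScreen-class] from [scoreScaffoldAlg()].
#' @param queryGenes the query gene table with family assignments.
#' @return a list: \code{screen} (the re-scored [SyntenyScreen-class]),
#'   \code{splits} (character vector of scaffolds actually split) and
#'   \code{genes} (the gene table with segment-suffixed scaffold ids).
#' @export
splitMultiAlgScaffolds <- function(screen, queryGenes) {
  res <- enrichmentTable(screen)
  famAlg <- familyALG(screen)
  minGenes <- screen@params$min_genes
  thresholds <- screen@params$thresholds
  nSig <- tapply(res$significant_strict, res$scaffold_id, sum)
  cand <- names(nSig)[nSig >= 2L]
  if (!length(cand))
    return(list(screen = screen, splits = character(0), genes = queryGenes))

  genes <- queryGenes
  trySplit <- function(scf) {
    g <- genes[genes$scaffold_id == scf & !is.na(genes$family_id), ,
               drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    lab <- unname(famAlg[g$family_id])
    sig <- res[res$scaffold_id == scf & res$significant_strict, ,
               drop = FALSE]
    sig <- sig[order(sig$p_raw, sig$alg_id), , drop = FALSE]
    a1 <- sig$alg_id[1]; a2 <- sig$alg_id[2]
    n <- nrow(g)
    bestMis <- Inf; bestCut <- NA_integer_; bestOrient <- c(a1, a2)
    for (cut in seq_len(n - 1L)) {
      if (cut < minGenes || n - cut < minGenes) next
      left <- lab[seq_len(cut)]; right <- lab[(cut + 1L):n]
      m1 <- sum(left != a1, na.rm = TRUE) + sum(right != a2, na.rm = TRUE)
      m2 <- sum(left != a2, na.rm = TRUE) + sum(right != a1, na.rm = TRUE)
      if (m1 < bestMis) { bestMis <- m1; bestCut <- cut; bestOrient <- c(a1, a2) }
      if (m2 < bestMis) { bestMis <- m2; bestCut <- cut; bestOrient <- c(a2, a1) }
    }
    if (is.na(bestCut)) return(NULL)
    list(cut_after = g$start[bestCut], orient = bestOrient)
  }

  planned <- list()
  for (scf in cand) {
    p <- trySplit(scf)
    if (!is.null(p)) planned[[scf]] <- p
  }
  if (!length(planned))
    return(list(screen = screen, splits = character(0), genes = queryGenes))

  relabel <- function(genes, planned) {
    for (scf in names(planned)) {
      sel <- genes$scaffold_id == scf
      seg <- ifelse(genes$start[sel] <= planned[[scf]]$cut_after,
                    paste0(scf, ":1"), paste0(scf, ":2"))
      genes$scaffold_id[sel] <- seg
    }
    genes
  }
  g2 <- relabel(genes, planned)
  inc2 <- buildIncidence(g2)
  sc2 <- scoreScaffoldAlg(inc2, familyAlg = famAlg, minGenes = minGenes,
                          thresholds = thresholds, queryGenes = g2)
  r2 <- enrichmentTable(sc2)
  okSplit <- character(0)
  for (scf in names(planned)) {
    segs <- paste0(scf, ":", 1:2)
    bestStrict <- vapply(segs, function(s) {
      rr <- r2[r2$scaffold_id == s & r2$significant_strict, , drop = FALSE]
      if (!nrow(rr)) return(NA_character_)
      rr <- rr[order(rr$p_raw, rr$alg_id), , drop = FALSE]
      rr$alg_id[1]
    }, character(1))
    if (!anyNA(bestStrict) && bestStrict[1] != bestStrict[2])
      okSplit <- c(okSplit, scf)
  }
  if (!length(okSplit))
    return(list(screen = screen, splits = character(0), genes = queryGenes))
  gFinal <- relabel(genes, planned[okSplit])
  incF <- buildIncidence(gFinal)
  scF <- scoreScaffoldAlg(incF, familyAlg = famAlg, minGenes = minGenes,
                          thresholds = thresholds, queryGenes = gFinal)
  list(screen = scF, splits = okSplit, genes = gFinal)
}

#' Derive ancestral linkage groups from two genomes
#'
#' Putnam-style surrogate for ALG identification: a bipartite graph is
#' built over reference and outgroup scaffolds with an edge wherever the
#' two scaffolds share significantly more families than expected
#' (one-sided Fisher, Bonferroni over all scaffold pairs,
#' \code{p_adj < edgeP}); the reference-side members of each connected
#' component with at least two reference scaffolds (or \code{minGenes}
#' ancestral genes) form one ALG.
#'
#' @param refIncidence,outgroupIncidence [FamilyIncidence-class] objects
#'   sharing the family namespace.
#' @param edgeP adjusted-p threshold for an edge (default 1e-4).
#' @param minGenes minimum ancestral genes for a single-scaffold ALG.
#' @return data.frame (alg_id, scaffold_id) over reference scaffolds.
#' @export
deriveAlgs <- function(refIncidence, outgroupIncidence, edgeP = 1e-4,
                       minGenes = 20) {
  rc <- incidenceCounts(refIncidence)
  oc <- incidenceCounts(outgroupIncidence)
  if (nrow(rc) == 1L)
    return(data.frame(alg_id = "ALG01", scaffold_id = rownames(rc),
                      stringsAsFactors = FALSE))
  shared <- intersect(colnames(rc), colnames(oc))
  if (length(shared) < 2L) stop("genomes share too few families")
  R <- (rc[, shared, drop = FALSE] > 0) * 1
  O <- (oc[, shared, drop = FALSE] > 0) * 1
  N <- length(shared)
  ov <- as.matrix(R %*% Matrix::t(O))          # shared families per pair
  nr <- Matrix::rowSums(R); no <- Matrix::rowSums(O)
  m <- nrow(R) * nrow(O)
  a <- ov
  b <- matrix(nr, nrow(R), nrow(O)) - a
  c_ <- matrix(no, nrow(R), nrow(O), byrow = TRUE) - a
  d <- N - a - b - c_
  p <- matrix(fisherOneSided(as.vector(a), as.vector(b), as.vector(c_),
                             as.vector(d)), nrow(R), nrow(O))
  padj <- matrix(pmin(1, m * as.vector(p)), nrow(R), nrow(O))
  edge <- which(padj < edgeP, arr.ind = TRUE)
  refNodes <- paste0("R:", rownames(R))
  outNodes <- paste0("O:", rownames(O))
  gr <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c(refNodes, outNodes))
  if (nrow(edge))
    gr <- igraph::add_edges(gr, c(rbind(refNodes[edge[, 1]],
                                        outNodes[edge[, 2]])))
  comp <- igraph::components(gr)
  memb <- comp$membership[refNodes]
  totals <- scaffoldTotals(refIncidence)
  out <- data.frame(scaffold_id = rownames(R),
                    comp = as.integer(memb), stringsAsFactors = FALSE)
  keep <- vapply(split(out$scaffold_id, out$comp), function(scfs)
    length(scfs) >= 2L || sum(totals[scfs]) >= minGenes, logical(1))
  comps <- names(keep)[keep]
  if (length(comps) == 1L && sum(out$comp == as.integer(comps)) == nrow(R) &&
      nrow(edge) > 0)
    warning("all reference scaffolds fall in a single connected component; ",
            "returning one ALG")
  res <- out[out$comp %in% as.integer(comps), , drop = FALSE]
  ids <- stats::setNames(sprintf("ALG%02d", seq_along(comps)), comps)
  res$alg_id <- unname(ids[as.character(res$comp)])
  res <- res[order(res$alg_id, res$scaffold_id), c("alg_id", "scaffold_id")]
  rownames(res) <- NULL
  attr(res, "n_edges") <- nrow(edge)
  res
}

#' Recompute the macro-synteny summary, optionally with gene context
#'
#' @param screen a [SyntenyScreen-class].
#' @param queryGenes optional gene table for the conserved-context
#'   percentages (see [scoreScaffoldAlg()]).
#' @return the summary list (also stored back on the object returned
#'   invisibly by the screen functions).
#' @export
summarizeSynteny <- function(screen, queryGenes = NULL) {
  .screenSummary(enrichmentTable(screen), syntenySummary(screen)$scaffolds,
                 screen@params$n_algs, familyALG(screen), queryGenes)
}

#' Export a macro-synteny dot-plot table
#'
#' One row per orthologous gene pair (one gene in each genome, same
#' family), with each genome's ALG cluster index and the gene's offset
#' within its cluster, ordered deterministically by (ALG, scaffold,
#' position). Plotting query cluster against reference cluster gives the
#' block-diagonal dot plot characteristic of retained macro-synteny.
#'
#' @param screen a [SyntenyScreen-class]; each query scaffold contributes
#'   dots at its best ALG (smallest raw p, ties lexicographic).
#' @param queryGenes,refGenes gene tables with \code{family_id} set.
#' @param algs reference ALG definitions (alg_id, scaffold_id).
#' @return data.frame (family_id, query_gene, ref_gene, query_scaffold,
#'   ref_scaffold, query_alg, ref_alg, query_offset, ref_offset).
#' @export
exportDotplot <- function(screen, queryGenes, refGenes, algs) {
  famAlg <- familyALG(screen)
  scfBest <- syntenySummary(screen)$scaffolds
  bestOf <- stats::setNames(scfBest$best_alg, scfBest$scaffold_id)
  scfAlg <- stats::setNames(algs$alg_id, algs$scaffold_id)

  q <- queryGenes[!is.na(queryGenes$family_id), , drop = FALSE]
  r <- refGenes[!is.na(refGenes$family_id), , drop = FALSE]
  q$alg <- unname(bestOf[q$scaffold_id])
  r$alg <- unname(scfAlg[r$scaffold_id])
  q <- q[!is.na(q$alg), , drop = FALSE]
  r <- r[!is.na(r$alg), , drop = FALSE]
  q <- q[order(q$alg, q$scaffold_id, q$start), , drop = FALSE]
  r <- r[order(r$alg, r$scaffold_id, r$start), , drop = FALSE]
  q$offset <- stats::ave(seq_len(nrow(q)), q$alg, FUN = seq_along)
  r$offset <- stats::ave(seq_len(nrow(r)), r$alg, FUN = seq_along)

  qs <- split(seq_len(nrow(q)), q$family_id)
  rs <- split(seq_len(nrow(r)), r$family_id)
  fams <- intersect(names(qs), names(rs))
  out <- vector("list", length(fams))
  for (i in seq_along(fams)) {
    qi <- qs[[fams[i]]]; ri <- rs[[fams[i]]]
    grid <- expand.grid(qi = qi, ri = ri)
    out[[i]] <- data.frame(
      family_id = fams[i],
      query_gene = q$gene_id[grid$qi], ref_gene = r$gene_id[grid$ri],
      query_scaffold = q$scaffold_id[grid$qi],
      ref_scaffold = r$scaffold_id[grid$ri],
      query_alg = q$alg[grid$qi], ref_alg = r$alg[grid$ri],
      query_offset = q$offset[grid$qi], ref_offset = r$offset[grid$ri],
      stringsAsFactors = FALSE)
  }
  dots <- do.call(rbind, out)
  if (is.null(dots)) return(data.frame())
  dots <- dots[order(dots$ref_alg, dots$ref_scaffold, dots$ref_offset,
                     dots$query_alg, dots$query_scaffold,
                     dots$query_offset), , drop = FALSE]
  rownames(dots) <- NULL
  dots
}
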