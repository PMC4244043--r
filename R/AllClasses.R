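#' @import methods
#' @importFrom Matrix sparseMatrix rowSums colSums
NULL

#' Scaffold-by-family incidence of ancestral orthology genes
#'
#' Per-genome bookkeeping of which ancestral orthology families occur on
#' which scaffold, with gene counts. This is the input table of the
#' macro-synteny enrichment screen: the per-scaffold totals carry the
#' "at least 20 ancestral genes" filter and the presence/absence pattern
#' of families over scaffolds feeds the 2x2 contingency tables.
#'
#' @slot genome single character, label of the genome.
#' @slot counts a sparse integer matrix (\code{dgCMatrix}), scaffolds in
#'   rows, families in columns; entry = number of genes of that family
#'   on that scaffold (0 where absent).
#' @export
setClass("FamilyIncidence",
  representation(genome = "character", counts = "Matrix"))

setValidity("FamilyIncidence", function(object) {
  msg <- character()
  if (length(object@genome) != 1L || !nzchar(object@genome))
    msg <- c(msg, "'genome' must be a single non-empty string")
  if (any(object@counts@x < 0))
    msg <- c(msg, "incidence counts must be non-negative")
  if (is.null(rownames(object@counts)) || is.null(colnames(object@counts)))
    msg <- c(msg, "counts must carry scaffold rownames and family colnames")
  if (length(msg)) msg else TRUE
})

#' Macro-synteny enrichment screen result
#'
#' One row of \code{results} per scaffold (or split scaffold segment) x
#' ancestral linkage group (ALG) test: the 2x2 family counts, the raw
#' one-sided Fisher p-value, the Bonferroni-adjusted p over all m tests,
#' and significance flags at the strict and relaxed thresholds.
#'
#' @slot results data.frame with columns \code{scaffold_id, alg_id, a, b,
#'   c, d, p_raw, p_adj, significant_strict, significant_relaxed}.
#' @slot summary named list: \code{n_scaffolds_tested}, \code{n_tests},
#'   \code{n_significant_strict}, \code{pct_scaffolds_relaxed},
#'   \code{n_algs_hit}, \code{pct_genes_conserved_context} (NA until
#'   gene-level context is supplied), \code{pct_families_conserved_context}.
#' @slot familyALG named character vector mapping family_id to the ALG of
#'   its reference location (modal ALG where a family touches several).
#' @slot params the screen parameters (min_genes, thresholds, m).
#' @export
setClass("SyntenyScreen",
  representation(results = "data.frame", summary = "list",
                 familyALG = "character", params = "list"))

setValidity("SyntenyScreen", function(object) {
  r <- object@results
  need <- c("scaffold_id", "alg_id", "a", "b", "c", "d", "p_raw", "p_adj",
            "significant_strict", "significant_relaxed")
  if (!all(need %in% names(r)))
    return(paste("results is missing columns:",
                 paste(setdiff(need, names(r)), collapse = ", ")))
  if (nrow(r)) {
    if (any(r$p_raw <= 0 | r$p_raw > 1)) return("p_raw out of (0, 1]")
    m <- object@params$m
    if (!is.null(m) && any(abs(r$p_adj - pmin(1, m * r$p_raw)) > 1e-12))
      return("p_adj must equal min(1, m * p_raw)")
  }
  TRUE
})

#' Univariate Gaussian mixture fit
#'
#' Result of seeded-restart EM over a range of component numbers with the
#' best k chosen by BIC. Components are reported sorted by ascending mean,
#' so the "low" methylation-signature component is always first.
#'
#' @slot k selected number of components.
#' @slot means,sds,weights component parameters, length k, mean-ascending.
#' @slot logLik maximised log-likelihood of the selected model.
#' @slot bic BIC of the selected model (lower is better).
#' @slot bicTable data.frame (k, logLik, bic, converged) over the k range.
#' @slot assignments per-observation maximum-responsibility component
#'   index (into the sorted components).
#' @slot responsibilities n x k posterior membership matrix.
#' @slot converged logical, EM convergence of the selected model.
#' @slot seed integer seed the fit consumed.
#' @export
setClass("MixtureFit",
  representation(k = "integer", means = "numeric", sds = "numeric",
                 weights = "numeric", logLik = "numeric", bic = "numeric",
                 bicTable = "data.frame", assignments = "integer",
                 responsibilities = "matrix", converged = "logical",
                 seed = "integer"))

setValidity("MixtureFit", function(object) {
  k <- object@k
  if (length(object@means) != k || length(object@sds) != k ||
      length(object@weights) != k)
    return("means/sds/weights must have length k")
  if (abs(sum(object@weights) - 1) > 1e-9)
    return("weights must sum to 1")
  if (any(object@sds <= 0)) return("sds must be positive")
  if (is.unsorted(object@means)) return("components must be mean-sorted")
  TRUE
})

#' Sex-linkage classification of scaffolds from read depth
#'
#' @slot records data.frame with one row per scaffold: length, per-sex
#'   mean normalised depth, log2 male/female and female/male ratios,
#'   female:male copy-ratio estimate and the assigned class
#'   (X / Y / autosome / ambiguous).
#' @slot summary named list of class counts, assembly-span fractions and
#'   mean female:male copy ratio per class.
#' @slot params thresholds used.
#' @export
setClass("SexLinkageCall",
  representation(records = "data.frame", summary = "list", params = "list"))

#' Dollo-parsimony reconstruction of gene-family content
#'
#' Single-gain / unlimited-loss reconstruction of family presence over a
#' rooted species tree: each family is gained once (at its forced root or
#' at the most recent common ancestor of the tips carrying it) and lost on
#' the root edges of the maximal subtrees below the gain that contain no
#' carrier tip.
#'
#' @slot tree the rooted \code{ape::phylo} the reconstruction ran on.
#' @slot nodeCounts named integer, ancestral (and tip) family content per
#'   node; names are tip labels or \code{node_<i>} for internal nodes.
#' @slot branchTable data.frame (parent, child, gains, losses) per edge,
#'   plus an extra row with parent NA for gains at the root itself.
#' @slot familyEvents data.frame (family_id, gain_node, n_losses,
#'   loss_branches) per family.
#' @slot nodeFamilies list of character vectors, families present per node.
#' @export
setClass("DolloReconstruction",
  representation(tree = "ANY", nodeCounts = "integer",
                 branchTable = "data.frame", familyEvents = "data.frame",
                 nodeFamilies = "list"))

setValidity("DolloReconstruction", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be a phylo")
  nf <- lengths(object@nodeFamilies)
  if (length(nf) && !identical(unname(nf), unname(as.integer(object@nodeCounts))))
    return("nodeCounts must equal the size of each node's family set")
  TRUE
})
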