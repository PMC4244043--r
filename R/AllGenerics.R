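#' Accessors for AncestralGenomics result objects
#'
#' Small generic accessors so downstream code never touches slots.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeLabel", function(x) standardGeneric("genomeLabel"))

#' @rdname accessors
#' @export
setGeneric("incidenceCounts", function(x) standardGeneric("incidenceCounts"))

#' @rdname accessors
#' @export
setGeneric("scaffoldTotals", function(x) standardGeneric("scaffoldTotals"))

#' @rdname accessors
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))

#' @rdname accessors
#' @export
setGeneric("syntenySummary", function(x) standardGeneric("syntenySummary"))

#' @rdname accessors
#' @export
setGeneric("familyALG", function(x) standardGeneric("familyALG"))

#' @rdname accessors
#' @export
setGeneric("mixtureK", function(x) standardGeneric("mixtureK"))

#' @rdname accessors
#' @export
setGeneric("mixtureMeans", function(x) standardGeneric("mixtureMeans"))

#' @rdname accessors
#' @export
setGeneric("mixtureSds", function(x) standardGeneric("mixtureSds"))

#' @rdname accessors
#' @export
setGeneric("mixtureWeights", function(x) standardGeneric("mixtureWeights"))

#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname accessors
#' @export
setGeneric("classTable", function(x) standardGeneric("classTable"))

#' @rdname accessors
#' @export
setGeneric("callSummary", function(x) standardGeneric("callSummary"))

#' @rdname accessors
#' @export
setGeneric("nodeContent", function(x) standardGeneric("nodeContent"))

#' @rdname accessors
#' @export
setGeneric("branchEvents", function(x) standardGeneric("branchEvents"))

#' @rdname accessors
#' @export
setGeneric("familyEvents", function(x) standardGeneric("familyEvents"))

#' @rdname accessors
#' @export
setMethod("genomeLabel", "FamilyIncidence", function(x) x@genome)

#' @rdname accessors
#' @export
setMethod("incidenceCounts", "FamilyIncidence", function(x) x@counts)

#' Per-scaffold totals of ancestral-orthology genes
#'
#' @return named integer vector: for each scaffold, the number of genes
#'   belonging to any ancestral orthology family (the quantity the
#'   \eqn{\ge} min_genes filter of the synteny screen operates on).
#' @rdname accessors
#' @export
setMethod("scaffoldTotals", "FamilyIncidence",
  function(x) stats::setNames(as.integer(Matrix::rowSums(x@counts)),
                              rownames(x@counts)))

#' @rdname accessors
#' @export
setMethod("enrichmentTable", "SyntenyScreen", function(x) x@results)

#' @rdname accessors
#' @export
setMethod("syntenySummary", "SyntenyScreen", function(x) x@summary)

#' @rdname accessors
#' @export
setMethod("familyALG", "SyntenyScreen", function(x) x@familyALG)

#' @rdname accessors
#' @export
setMethod("mixtureK", "MixtureFit", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("mixtureMeans", "MixtureFit", function(x) x@means)

#' @rdname accessors
#' @export
setMethod("mixtureSds", "MixtureFit", function(x) x@sds)

#' @rdname accessors
#' @export
setMethod("mixtureWeights", "MixtureFit", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("assignments", "MixtureFit", function(x) x@assignments)

#' @rdname accessors
#' @export
setMethod("classTable", "SexLinkageCall", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("callSummary", "SexLinkageCall", function(x) x@summary)

#' @rdname accessors
#' @export
setMethod("nodeContent", "DolloReconstruction", function(x) x@nodeCounts)

#' @rdname accessors
#' @export
setMethod("branchEvents", "DolloReconstruction", function(x) x@branchTable)

#' @rdname accessors
#' @export
setMethod("familyEvents", "DolloReconstruction", function(x) x@familyEvents)

setMethod("show", "FamilyIncidence", function(object) {
  cat("FamilyIncidence for genome '", object@genome, "': ",
      nrow(object@counts), " scaffolds x ", ncol(object@counts),
      " families, ", sum(object@counts), " genes\n", sep = "")
})

setMethod("show", "SyntenyScreen", function(object) {
  s <- object@summary
  cat("SyntenyScreen: ", s$n_scaffolds_tested, " tested units x ",
      object@params$n_algs, " ALGs = ", s$n_tests, " tests; ",
      s$n_significant_strict, " units significant (strict), ",
      round(s$pct_scaffolds_relaxed, 1), "% (relaxed), ",
      s$n_algs_hit, " ALGs hit\n", sep = "")
})

setMethod("show", "MixtureFit", function(object) {
  cat("MixtureFit: k = ", object@k, " (BIC-selected), logLik = ",
      format(object@logLik, digits = 8), "\n", sep = "")
  print(data.frame(component = seq_len(object@k), mean = object@means,
                   sd = object@sds, weight = object@weights))
})

setMethod("show", "SexLinkageCall", function(object) {
  cat("SexLinkageCall:", nrow(object@records), "scaffolds;",
      paste(names(object@summary$class_counts),
            object@summary$class_counts, sep = "=", collapse = " "), "\n")
})

setMethod("show", "DolloReconstruction", function(object) {
  root <- ape::Ntip(object@tree) + 1L
  cat("DolloReconstruction: ", nrow(object@familyEvents), " families on ",
      ape::Ntip(object@tree), " tips; root content ",
      object@nodeCounts[[paste0("node_", root)]], " families; total losses ",
      sum(object@familyEvents$n_losses), "\n", sep = "")
})
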