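nodeNames <- function(tree) {
  n <- ape::Ntip(tree)
  c(tree$tip.label, paste0("node_", (n + 1L):(n + tree$Nnode)))
}

# children[[v]] = integer vector of v's children (empty for tips)
childrenList <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  ch
}

# postorder: children before parents
postorderNodes <- function(tree) {
  unique(c(tree$edge[ape::postorder(tree), 2],
           ape::Ntip(tree) + 1L))
}

#' Root-presence flags from an outgroup rule
#'
#' A family observed in at least \code{minPresent} of the named outgroup
#' species is taken to predate the ingroup ancestor and is forced
#' present at the ingroup root, so absences inside the ingroup are
#' counted as losses rather than late gains.
#'
#' @param pa presence/absence matrix (families x species, 0/1), with the
#'   outgroup species among its columns.
#' @param outgroupSpecies character vector of outgroup column names
#'   (not tips of the ingroup tree).
#' @param minPresent minimum outgroup species carrying the family
#'   (default 2).
#' @return named logical vector over families.
#' @export
applyOutgroupRule <- function(pa, outgroupSpecies, minPresent = 2) {
  miss <- setdiff(outgroupSpecies, colnames(pa))
  if (length(miss))
    stop("outgroup species absent from the matrix: ",
         paste(miss, collapse = ", "))
  if (length(outgroupSpecies) < minPresent)
    stop("need at least minPresent = ", minPresent, " outgroup species; got ",
         length(outgroupSpecies))
  n <- rowSums(pa[, outgroupSpecies, drop = FALSE])
  stats::setNames(n >= minPresent, rownames(pa))
}

#' Dollo-parsimony reconstruction of ancestral gene-family content
#'
#' Under Dollo parsimony each family is gained exactly once — at the
#' ingroup root when the outgroup rule forces it there, otherwise at the
#' most recent common ancestor of the tips carrying it — and lost on the
#' root edges of the maximal subtrees below the gain that contain no
#' carrier tip. This minimises the number of losses subject to the
#' single-gain constraint, and reproduces every tip's observed state.
#'
#' @param tree rooted \code{ape::phylo} (binary or multifurcating).
#' @param pa presence/absence matrix (families x species, 0/1); every
#'   column used must be a tip label. Outgroup columns (if still in the
#'   matrix) are ignored. Tips absent from the matrix are treated as
#'   lacking every family, with a warning.
#' @param rootFlags optional named logical ([applyOutgroupRule()]);
#'   families flagged TRUE are gained at the root regardless of their
#'   tip distribution.
#' @return a [DolloReconstruction-class].
#' @export
dolloReconstruct <- function(tree, pa, rootFlags = NULL) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape::phylo")
  if (!ape::is.rooted(tree)) stop("'tree' must be rooted")
  nTip <- ape::Ntip(tree)
  nn <- nTip + tree$Nnode
  root <- nTip + 1L
  tips <- tree$tip.label
  used <- intersect(colnames(pa), tips)
  if (!length(used)) stop("no matrix species matches a tip label")
  missingTips <- setdiff(tips, colnames(pa))
  if (length(missingTips))
    warning("tip(s) without a matrix column treated as all-absent: ",
            paste(missingTips, collapse = ", "))
  if (is.null(rootFlags))
    rootFlags <- stats::setNames(rep(FALSE, nrow(pa)), rownames(pa))

  names <- nodeNames(tree)
  post <- postorderNodes(tree)
  ch <- childrenList(tree)
  edge <- tree$edge

  nodeFam <- vector("list", nn)
  gains <- integer(nrow(edge)); losses <- integer(nrow(edge))
  rootGains <- 0L
  events <- vector("list", nrow(pa))
  skipped <- 0L

  # tip carrier indicator per family, matrix tips x families
  carrier <- matrix(FALSE, nTip, nrow(pa),
                    dimnames = list(tips, rownames(pa)))
  carrier[used, ] <- t(pa[, used, drop = FALSE] == 1L)

  edgeIndex <- stats::setNames(seq_len(nrow(edge)),
                               paste(edge[, 1], edge[, 2]))

  for (f in seq_len(nrow(pa))) {
    fam <- rownames(pa)[f]
    pres <- which(carrier[, fam])
    flagged <- isTRUE(rootFlags[[fam]])
    if (!length(pres) && !flagged) { skipped <- skipped + 1L; next }

    # hasCarrier per node, postorder
    has <- logical(nn)
    has[pres] <- TRUE
    for (v in post) if (v > nTip) has[v] <- any(has[ch[[v]]])

    gain <- if (flagged) root
            else if (length(pres) == 1L) pres
            else ape::getMRCA(tree, pres)

    # state within the gain clade: 1 iff subtree holds a carrier
    # (the gain node itself is 1 by definition)
    state <- has
    state[gain] <- TRUE

    if (gain > nTip) {
      stack <- gain
      lossEdges <- integer(0)
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        for (w in ch[[v]]) {
          ei <- edgeIndex[[paste(v, w)]]
          if (state[v] && !state[w]) lossEdges <- c(lossEdges, ei)
          else if (state[w]) stack <- c(stack, w)
        }
      }
      for (ei in lossEdges) losses[ei] <- losses[ei] + 1L
    } else lossEdges <- integer(0)

    # record the gain
    if (gain == root) rootGains <- rootGains + 1L
    else gains[edgeIndex[[paste(edge[match(gain, edge[, 2]), 1], gain)]]] <-
      gains[edgeIndex[[paste(edge[match(gain, edge[, 2]), 1], gain)]]] + 1L

    # node content: every state-1 node inside the gain clade
    present <- gain
    if (gain > nTip) {
      stack <- gain
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        for (w in ch[[v]]) if (state[w]) {
          present <- c(present, w)
          if (w > nTip) stack <- c(stack, w)
        }
      }
    }
    for (v in present) nodeFam[[v]] <- c(nodeFam[[v]], fam)

    events[[f]] <- data.frame(
      family_id = fam,
      gain_node = names[gain],
      n_losses = length(lossEdges),
      loss_branches = if (length(lossEdges))
        paste(paste0(names[edge[lossEdges, 1]], "->",
                     names[edge[lossEdges, 2]]), collapse = ";")
      else "",
      stringsAsFactors = FALSE)
  }
  if (skipped)
    warning(skipped, " families present in zero tips and not root-flagged ",
            "were skipped")

  familyEvents <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  if (is.null(familyEvents))
    familyEvents <- data.frame(family_id = character(),
                               gain_node = character(),
                               n_losses = integer(),
                               loss_branches = character())

  branchTable <- data.frame(parent = names[edge[, 1]],
                            child = names[edge[, 2]],
                            gains = gains, losses = losses,
                            stringsAsFactors = FALSE)
  branchTable <- rbind(
    data.frame(parent = NA_character_, child = names[root],
               gains = rootGains, losses = 0L, stringsAsFactors = FALSE),
    branchTable)
  rownames(branchTable) <- NULL

  nodeFam <- lapply(nodeFam, function(x) sort(unique(x)))
  names(nodeFam) <- names
  new("DolloReconstruction", tree = tree,
      nodeCounts = stats::setNames(lengths(nodeFam), names),
      branchTable = branchTable,
      familyEvents = familyEvents,
      nodeFamilies = nodeFam)
}
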