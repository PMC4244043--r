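# Independent oracles and tiny fixture builders shared across tests.

# Exhaustive one-sided Fisher p by enumerating every 2x2 table with the
# observed margins; exact binomial-coefficient arithmetic, no
# distribution functions.
enumFisherUpper <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  prob <- choose(c1, xs) * choose(N - c1, r1 - xs) / choose(N, r1)
  sum(prob[xs >= a])
}

# Brute-force minimum Dollo loss count: try every feasible single-gain
# node and count the lost maximal subtrees directly from the edge list.
bruteDolloLosses <- function(tree, presentTips) {
  nTip <- ape::Ntip(tree)
  nn <- nTip + tree$Nnode
  ch <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  descTips <- function(v) {
    if (v <= nTip) return(v)
    unlist(lapply(ch[[v]], descTips))
  }
  lossesFor <- function(g) {
    has <- logical(nn)
    has[presentTips] <- TRUE
    fill <- function(v) {
      if (v > nTip) {
        for (w in ch[[v]]) fill(w)
        has[v] <<- any(has[ch[[v]]])
      }
    }
    fill(g)
    state <- has
    state[g] <- TRUE
    count <- 0L
    walk <- function(v) {
      for (w in ch[[v]]) {
        if (state[v] && !state[w]) count <<- count + 1L
        else if (state[w] && w > nTip) walk(w)
      }
    }
    if (g > nTip) walk(g)
    count
  }
  best <- Inf
  for (g in seq_len(nn)) {
    tipsUnder <- descTips(g)
    if (all(presentTips %in% tipsUnder))
      best <- min(best, lossesFor(g))
  }
  best
}

# Minimal one-record fixture builders.
tinyGeneDf <- function(scaffold, n, species = "sp", family = NULL,
                       prefix = "g") {
  data.frame(gene_id = paste0(prefix, seq_len(n)), species = species,
             scaffold_id = scaffold, start = (seq_len(n) - 1L) * 100L,
             end = (seq_len(n) - 1L) * 100L + 50L, strand = "+",
             family_id = if (is.null(family)) NA_character_ else family,
             stringsAsFactors = FALSE)
}

writeLinesTmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Study-scale synthetic genome pair: 62 scaffolds that all pass the
# 20-ancestral-gene filter against the 18 reference linkage groups.
studyScalePair <- function(translocationRate = 0.05, lossRate = 0,
                           seed = 101) {
  simulateMacrosyntenyPair(nAlgs = 18, familiesPerAlg = 60,
                           scaffoldsPerGenome = 62,
                           genesPerFamily = 2:3,
                           translocationRate = translocationRate,
                           lossRate = lossRate, seed = seed)
}

refAlgTable <- function(sim) {
  data.frame(alg_id = unname(sim$truth$scaffoldAlg$genomeR),
             scaffold_id = names(sim$truth$scaffoldAlg$genomeR),
             stringsAsFactors = FALSE)
}
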