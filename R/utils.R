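# internal helpers shared across modules

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is restored afterwards, so generators are pure in (params, seed).
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of one user seed into per-stage seeds, kept well
# inside 32-bit integer range.
deriveSeed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 20011L + match(stage,
    c("synteny", "cpg", "coverage", "dollo", "mixture", "extra")) * 7L
}

#' Normalised mutual information between two labelings
#'
#' Used to score recovery of ancestral-linkage-group assignments against
#' simulation truth. NMI = 2 I(X;Y) / (H(X) + H(Y)); 1 for identical
#' partitions (up to label permutation), 0 for independence.
#'
#' @param x,y equal-length label vectors (any atomic type).
#' @return a number in [0, 1]; 1 when either partition is trivial and the
#'   two agree, NaN only if both are empty.
#' @export
normalizedMutualInfo <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
  if (hx + hy == 0) return(1)  # both trivial partitions: perfect agreement
  2 * mi / (hx + hy)
}

# Assert a data.frame has the named columns; `what` names the table in
# the error message.
needCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}
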