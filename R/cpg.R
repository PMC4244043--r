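#' Dinucleotide observed/expected profiles
#'
#' Counts the four mononucleotides and all 16 overlapping dinucleotides
#' of each sequence and forms the observed/expected ratio
#' \deqn{o/e(XY) = \frac{n_{XY}/(L-1)}{(n_X/L)(n_Y/L)}}
#' where L is the number of unambiguous (A/C/G/T) bases. The CpG ratio
#' (\code{oe_CG}) is the classical indicator of germ-line DNA
#' methylation: methylated cytosines deaminate to thymine over
#' evolutionary time, depleting CpG below expectation.
#'
#' Ambiguity codes are excluded from all counts (Biostrings never counts
#' a dinucleotide spanning one); the ratio is \code{NA} whenever either
#' mononucleotide is absent.
#'
#' @param x a \code{Biostrings::DNAStringSet}, a named character vector
#'   of sequences, or a FASTA file path.
#' @return data.frame: \code{seq_id}, \code{length} (unambiguous bases),
#'   \code{n_A..n_T}, the 16 dinucleotide counts (\code{AA..TT}) and the
#'   16 ratios (\code{oe_AA..oe_TT}).
#' @examples
#' dinucleotideProfile(c(gene1 = "CGCGCGCGCG"))$oe_CG  # (5/9)/(0.25)
#' @export
dinucleotideProfile <- function(x) {
  seqs <- asDNAStringSet(x)
  if (!length(seqs)) stop("no sequences supplied")
  mono <- Biostrings::alphabetFrequency(seqs)[, c("A", "C", "G", "T"),
                                              drop = FALSE]
  L <- rowSums(mono)
  if (any(L < 2))
    stop("sequence(s) too short after removing ambiguity codes: ",
         paste(utils::head(names(seqs)[L < 2], 5), collapse = ", "))
  di <- Biostrings::dinucleotideFrequency(seqs)
  oe <- matrix(NA_real_, nrow = length(seqs), ncol = 16,
               dimnames = list(NULL, paste0("oe_", colnames(di))))
  for (j in seq_len(ncol(di))) {
    xy <- strsplit(colnames(di)[j], "")[[1]]
    denom <- (mono[, xy[1]] / L) * (mono[, xy[2]] / L)
    oe[, j] <- ifelse(denom > 0, (di[, j] / (L - 1)) / denom, NA_real_)
  }
  out <- data.frame(seq_id = if (is.null(names(seqs)))
                      paste0("seq", seq_along(seqs)) else names(seqs),
                    length = as.integer(L), stringsAsFactors = FALSE)
  colnames(mono) <- paste0("n_", colnames(mono))
  cbind(out, as.data.frame(mono), as.data.frame(di), as.data.frame(oe))
}

asDNAStringSet <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  if (is.character(x))
    return(Biostrings::DNAStringSet(toupper(trimws(x))))
  stop("cannot interpret 'x' as sequences")
}

#' Tile a genome into windows and profile each window
#'
#' Non-overlapping tiling by default. A terminal window shorter than
#' \code{window/2} is dropped; windows with more than 10\% ambiguity
#' codes are dropped, and both counts are reported as attributes
#' (\code{n_dropped_short}, \code{n_dropped_ambiguous}).
#'
#' @param x genome FASTA path, DNAStringSet or character vector.
#' @param window window size in bp (>= 100); default 1000.
#' @param step step between window starts; defaults to \code{window}.
#' @return the [dinucleotideProfile()] data.frame of the retained
#'   windows; \code{seq_id} is \code{<scaffold>:<start>-<end>} (0-based,
#'   half-open).
#' @export
windowProfiles <- function(x, window = 1000, step = window) {
  if (window < 100) stop("'window' must be >= 100")
  seqs <- asDNAStringSet(x)
  if (!length(seqs) || sum(Biostrings::width(seqs)) == 0)
    stop("empty genome input")
  pieces <- list()
  nShort <- 0L
  widths <- Biostrings::width(seqs)
  for (i in seq_along(seqs)) {
    L <- widths[i]
    starts <- seq.int(1L, L, by = step)
    ends <- pmin(starts + window - 1L, L)
    w <- ends - starts + 1L
    short <- w < window / 2
    nShort <- nShort + sum(short)
    starts <- starts[!short]; ends <- ends[!short]
    if (!length(starts)) next
    v <- Biostrings::DNAStringSet(Biostrings::Views(seqs[[i]], starts, ends))
    names(v) <- paste0(names(seqs)[i], ":", starts - 1L, "-", ends)
    pieces[[length(pieces) + 1L]] <- v
  }
  if (!length(pieces)) stop("no windows survive the tiling rules")
  win <- do.call(c, pieces)
  ambig <- 1 - rowSums(Biostrings::alphabetFrequency(
    win)[, c("A", "C", "G", "T"), drop = FALSE]) / Biostrings::width(win)
  keep <- ambig <= 0.10
  prof <- dinucleotideProfile(win[keep])
  attr(prof, "n_dropped_short") <- nShort
  attr(prof, "n_dropped_ambiguous") <- sum(!keep)
  prof
}

logRowSumExp <- function(m) {
  mx <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

# One EM run from a given start; returns NULL for a degenerate run.
# The iteration itself lives in compiled code (src/em.cpp).
.emRun <- function(x, mu, sd, w, tol, maxIter) {
  .emRunCpp(x, mu, sd, w, tol, as.integer(maxIter))
}

#' Fit a univariate Gaussian mixture by EM with BIC model selection
#'
#' For each candidate k, EM is run from \code{nInit} seeded starts (a
#' quantile-spread start plus random restarts); restarts that collapse a
#' component (sd below 1e-4, or an emptied component) are discarded. The
#' per-iteration log-likelihood is asserted non-decreasing. The k with
#' the lowest BIC wins, and components are reported sorted by ascending
#' mean so restarts and label permutations cannot change the report.
#'
#' @param values numeric vector; non-finite entries are dropped.
#' @param kRange candidate component counts (default 1:4).
#' @param nInit restarts per k (default 10).
#' @param seed integer seed; the fit is deterministic given it.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param maxIter EM iteration cap per restart.
#' @return a [MixtureFit-class].
#' @export
fitGaussianMixture <- function(values, kRange = 1:4, nInit = 10, seed = 1,
                               tol = 1e-6, maxIter = 500) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 10 * max(kRange))
    stop("need at least 10*max(kRange) = ", 10 * max(kRange),
         " finite values; got ", n)
  withSeed(seed, {
    sdAll <- stats::sd(x)
    fits <- list()
    bicTable <- data.frame(k = integer(), logLik = numeric(),
                           bic = numeric(), converged = logical())
    for (k in sort(kRange)) {
      # short EM runs from every start, then a full-tolerance polish of
      # the best one (the usual multi-restart economy)
      best <- NULL
      for (init in seq_len(if (k == 1L) 1L else nInit)) {
        if (init == 1L) {
          # spread start over the empirical quantiles
          mu <- as.numeric(stats::quantile(x, (seq_len(k) - 0.5) / k))
          sd0 <- rep(max(sdAll / k, 1e-3), k)
          w0 <- rep(1 / k, k)
        } else {
          # k-means start from random centres: sharp, mode-seeking
          km <- tryCatch(
            stats::kmeans(x, centers = matrix(sample(x, k), ncol = 1),
                          iter.max = 20),
            error = function(e) NULL)
          if (is.null(km)) {
            mu <- sort(sample(x, k))
            sd0 <- rep(max(sdAll / k, 1e-3), k)
            w0 <- rep(1 / k, k)
          } else {
            mu <- as.numeric(km$centers)
            sd0 <- pmax(sqrt(km$withinss / pmax(km$size, 1)), sdAll / 50)
            w0 <- pmax(km$size, 1) / sum(pmax(km$size, 1))
          }
        }
        fit <- .emRun(x, mu, sd0, w0, max(tol, 1e-3), min(maxIter, 100L))
        if (!is.null(fit) &&
            (is.null(best) || fit$logLik > best$logLik)) best <- fit
      }
      if (is.null(best)) next                  # every restart degenerate
      polished <- .emRun(x, best$mu, best$sd, best$w, tol, maxIter)
      if (!is.null(polished)) best <- polished
      bic <- -2 * best$logLik + (3 * k - 1) * log(n)
      bicTable <- rbind(bicTable,
                        data.frame(k = k, logLik = best$logLik, bic = bic,
                                   converged = best$converged))
      fits[[as.character(k)]] <- best
    }
    if (!nrow(bicTable))
      stop("no mixture converged for any k in ", deparse(kRange),
           " over ", nInit, " restarts (n = ", n, ")")
    kBest <- bicTable$k[which.min(bicTable$bic)]
    best <- fits[[as.character(kBest)]]
    ord <- order(best$mu)
    resp <- best$resp[, ord, drop = FALSE]
    new("MixtureFit",
        k = as.integer(kBest),
        means = best$mu[ord], sds = best$sd[ord], weights = best$w[ord],
        logLik = best$logLik,
        bic = bicTable$bic[bicTable$k == kBest],
        bicTable = bicTable,
        assignments = max.col(resp),
        responsibilities = resp,
        converged = bicTable$converged[bicTable$k == kBest],
        seed = as.integer(seed))
  })
}

#' Classify items into methylation-signature classes from a mixture fit
#'
#' Items are hard-assigned to their maximum-responsibility component;
#' the class fractions are reported both as mixture weights (soft: the
#' mass of each component, the reading under which the low-CpG class is
#' the historically methylated gene fraction) and as hard-assignment
#' proportions.
#'
#' @param fit a [MixtureFit-class].
#' @param labels class labels for k = 3 (low/medium/high ascending
#'   mean); for k = 2 the outer two are used (low/high); for k = 1 the
#'   single class is \code{"undifferentiated"}.
#' @return list: \code{classes} (character per item),
#'   \code{soft_fractions}, \code{hard_fractions} (named by label) and
#'   \code{low_fraction_soft} / \code{low_fraction_hard} (NA at k = 1).
#' @export
classifyMethylation <- function(fit, labels = c("low", "medium", "high")) {
  k <- mixtureK(fit)
  lab <- if (k == 1L) "undifferentiated"
         else if (k == 2L) labels[c(1, length(labels))]
         else if (k == length(labels)) labels
         else paste0("class", seq_len(k))
  cls <- lab[assignments(fit)]
  soft <- stats::setNames(mixtureWeights(fit), lab)
  hard <- stats::setNames(as.numeric(
    table(factor(cls, levels = lab))) / length(cls), lab)
  list(classes = cls,
       soft_fractions = soft,
       hard_fractions = hard,
       low_fraction_soft = if (k >= 2L) unname(soft[1]) else NA_real_,
       low_fraction_hard = if (k >= 2L) unname(hard[1]) else NA_real_)
}
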