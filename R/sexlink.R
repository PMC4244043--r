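#' Normalise per-scaffold read depths per sample
#'
#' Each sample's scaffold depths are divided by the sample's
#' length-weighted median depth so that autosomal scaffolds sit near 1
#' regardless of sequencing effort. The median is taken in two passes —
#' a provisional length-weighted median over all scaffolds, then a final
#' median over the scaffolds that look autosomal under the provisional
#' scaling (|log2 depth ratio| < 0.25) — so a sizeable sex-linked
#' fraction cannot drag the normaliser.
#'
#' @param depths long data.frame (scaffold_id, length, sample_id,
#'   mean_depth), e.g. [readDepthTable()].
#' @param sexes data.frame (sample_id, sex in male/female),
#'   e.g. [readSampleSexes()].
#' @param minLength scaffolds shorter than this (bp) are flagged; they
#'   are classified as \code{ambiguous} downstream (default 10 kb).
#' @return data.frame with one row per scaffold x sample:
#'   \code{scaffold_id, length, sample_id, sex, mean_depth, norm_depth,
#'   short}.
#' @export
normalizeDepths <- function(depths, sexes, minLength = 10000) {
  needCols(depths, c("scaffold_id", "length", "sample_id", "mean_depth"),
           "depth table")
  needCols(sexes, c("sample_id", "sex"), "sample-sex table")
  if (length(unique(sexes$sample_id)) < 2L)
    stop("need at least two samples with labelled sex")
  depths$sex <- sexes$sex[match(depths$sample_id, sexes$sample_id)]
  if (anyNA(depths$sex))
    stop("sample(s) without a sex label: ",
         paste(unique(depths$sample_id[is.na(depths$sex)]), collapse = ", "))
  wMedian <- function(x, w) {
    o <- order(x)
    x <- x[o]; w <- w[o]
    x[which(cumsum(w) >= sum(w) / 2)[1]]
  }
  out <- lapply(split(depths, depths$sample_id), function(d) {
    if (all(d$mean_depth == 0))
      stop("sample '", d$sample_id[1], "' has all-zero depth")
    m1 <- wMedian(d$mean_depth, d$length)
    prov <- d$mean_depth / m1
    auto <- prov > 0 & abs(log2(prov)) < 0.25
    m2 <- if (any(auto)) wMedian(d$mean_depth[auto], d$length[auto]) else m1
    d$norm_depth <- d$mean_depth / m2
    d
  })
  out <- do.call(rbind, out)
  out$short <- out$length < minLength
  rownames(out) <- NULL
  out
}

#' Classify scaffolds as X-linked, Y-derived, autosomal or ambiguous
#'
#' In an XY system the X is present in one copy in males and two in
#' females, so X-linked scaffolds sit at half depth in male data —
#' the underrepresented scaffold fraction — and at a female:male copy
#' ratio near 2; Y-derived scaffolds have male depth but essentially no
#' female depth. Depths of same-sex samples are averaged after
#' normalisation.
#'
#' Rules, on normalised depths: Y if female depth < \code{yFemaleMax}
#' and male depth > \code{yMaleMin}; X if log2(female/male) lies in
#' \code{xBand}; autosome if |log2(female/male)| < 0.25; otherwise
#' (or when flagged short) ambiguous.
#'
#' @param normalized output of [normalizeDepths()].
#' @param xBand log2(female/male) interval called X (default
#'   \code{c(0.75, 1.25)}, centred on the one-vs-two-copy value 1).
#' @param yFemaleMax,yMaleMin Y-call thresholds on normalised depth.
#' @return a [SexLinkageCall-class]; \code{classTable()} has one row per
#'   scaffold with the per-sex depths, log2 ratios, female:male copy
#'   ratio and class; \code{callSummary()} reports class counts,
#'   assembly-span fractions and mean copy ratio per class.
#' @export
classifySexLinkage <- function(normalized, xBand = c(0.75, 1.25),
                               yFemaleMax = 0.1, yMaleMin = 0.3) {
  needCols(normalized, c("scaffold_id", "length", "sex", "norm_depth",
                         "short"), "normalised depth table")
  if (!all(c("male", "female") %in% normalized$sex))
    stop("need at least one male and one female sample")
  agg <- stats::aggregate(norm_depth ~ scaffold_id + sex, normalized, mean)
  male <- agg[agg$sex == "male", ]
  female <- agg[agg$sex == "female", ]
  ids <- sort(unique(normalized$scaffold_id))
  info <- normalized[!duplicated(normalized$scaffold_id),
                     c("scaffold_id", "length", "short")]
  rec <- data.frame(scaffold_id = ids,
                    length = info$length[match(ids, info$scaffold_id)],
                    depth_male = male$norm_depth[match(ids, male$scaffold_id)],
                    depth_female =
                      female$norm_depth[match(ids, female$scaffold_id)],
                    short = info$short[match(ids, info$scaffold_id)],
                    stringsAsFactors = FALSE)
  rec$log2_fm <- ifelse(rec$depth_male > 0 & rec$depth_female > 0,
                        log2(rec$depth_female / rec$depth_male), NA_real_)
  rec$log2_mf <- -rec$log2_fm
  rec$fm_copy_ratio <- ifelse(rec$depth_male > 0,
                              rec$depth_female / rec$depth_male, Inf)

  cls <- rep("ambiguous", nrow(rec))
  isY <- rec$depth_female < yFemaleMax & rec$depth_male > yMaleMin
  isX <- !isY & !is.na(rec$log2_fm) &
    rec$log2_fm >= xBand[1] & rec$log2_fm <= xBand[2]
  isA <- !isY & !isX & !is.na(rec$log2_fm) & abs(rec$log2_fm) < 0.25
  cls[isY] <- "Y"; cls[isX] <- "X"; cls[isA] <- "autosome"
  cls[rec$short] <- "ambiguous"
  rec$sex_class <- cls

  lv <- c("X", "Y", "autosome", "ambiguous")
  counts <- table(factor(cls, levels = lv))
  span <- tapply(rec$length, factor(cls, levels = lv), sum, default = 0)
  ratio <- tapply(ifelse(is.finite(rec$fm_copy_ratio), rec$fm_copy_ratio,
                         NA_real_),
                  factor(cls, levels = lv), mean, na.rm = TRUE)
  new("SexLinkageCall", records = rec,
      summary = list(class_counts = counts,
                     span_fraction = span / sum(rec$length),
                     mean_fm_copy_ratio = ratio),
      params = list(x_band = xBand, y_female_max = yFemaleMax,
                    y_male_min = yMaleMin))
}
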