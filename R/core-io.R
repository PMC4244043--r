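#' Read a gene coordinate table (GFF3 or BED) into the shared gene model
#'
#' Genes are represented internally as a data.frame with 0-based,
#' half-open coordinates (BED convention); GFF3's 1-based inclusive
#' coordinates are converted on the way in (\code{start - 1}) and nowhere
#' else. Records are returned sorted by (scaffold, start).
#'
#' A validating pre-scan runs before the actual parser so that malformed
#' lines are reported with their line number, and intervals with
#' \code{end <= start} (in the internal convention) are dropped with a
#' warning carrying the rejected-record count; the surviving lines are
#' then parsed by \pkg{rtracklayer}.
#'
#' @param path file path.
#' @param format \code{"gff3"} or \code{"bed"}. BED may carry a seventh
#'   column which is read as \code{family_id}.
#' @param species species label stored on every record.
#' @param featureType for GFF3, the feature type to keep (column 3);
#'   default \code{"gene"}.
#' @param idAttr for GFF3, the attribute holding the gene identifier.
#' @return data.frame with columns \code{gene_id, species, scaffold_id,
#'   start, end, strand, family_id} (family_id NA unless provided by the
#'   file), sorted by (scaffold_id, start).
#' @export
readGeneTable <- function(path, format = c("gff3", "bed"), species,
                          featureType = "gene", idAttr = "ID") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))

  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines) & !grepl("^(track|browser)\\b", lines)
  idx <- which(keep)
  nf <- if (format == "bed") 3L else 9L
  rejected <- 0L
  ok <- logical(length(idx))
  extra <- FALSE
  for (j in seq_along(idx)) {
    f <- strsplit(lines[idx[j]], "\t", fixed = TRUE)[[1]]
    if (length(f) < nf)
      stop("malformed ", toupper(format), " line ", idx[j], " in ", path,
           ": expected >= ", nf, " tab-separated fields, got ", length(f))
    co <- if (format == "bed") f[2:3] else f[4:5]
    if (anyNA(suppressWarnings(as.numeric(co))))
      stop("malformed ", toupper(format), " line ", idx[j], " in ", path,
           ": non-numeric coordinates")
    s <- as.numeric(co[1]); e <- as.numeric(co[2])
    # internal convention is 0-based half-open; a GFF3 record spans
    # [start-1, end), so end < start is the only impossible GFF3 case
    bad <- if (format == "bed") e <= s else e < s
    if (bad) { rejected <- rejected + 1L; ok[j] <- FALSE } else ok[j] <- TRUE
    if (format == "bed" && length(f) >= 7L) extra <- TRUE
  }
  if (rejected > 0L)
    warning(rejected, " record(s) rejected (end <= start) in ", path)
  kept <- lines[idx[ok]]
  if (!length(kept)) stop("no usable records in ", path)

  tmp <- tempfile(fileext = paste0(".", if (format == "bed") "bed" else "gff3"))
  on.exit(unlink(tmp))
  writeLines(kept, tmp)

  if (format == "bed") {
    gr <- if (extra)
      rtracklayer::import(tmp, format = "bed",
                          extraCols = c(family_id = "character"))
    else rtracklayer::import(tmp, format = "bed")
    df <- data.frame(
      gene_id = if (!is.null(gr$name)) as.character(gr$name)
                else paste0("gene", seq_along(gr)),
      species = species,
      scaffold_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # back to 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      family_id = if (extra) as.character(gr$family_id) else NA_character_,
      stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(tmp, format = "gff3")
    gr <- gr[as.character(gr$type) == featureType]
    if (!length(gr)) stop("no '", featureType, "' features in ", path)
    ids <- GenomicRanges::mcols(gr)[[idAttr]]
    if (is.null(ids)) stop("GFF3 attribute '", idAttr, "' absent in ", path)
    df <- data.frame(
      gene_id = as.character(ids),
      species = species,
      scaffold_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      family_id = NA_character_,
      stringsAsFactors = FALSE)
  }
  df$strand[!df$strand %in% c("+", "-")] <- "."
  df$family_id[!is.na(df$family_id) & df$family_id %in% c(".", "")] <-
    NA_character_
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id within species '", species, "': ",
         paste(unique(df$gene_id[duplicated(df$gene_id)])[1:5], collapse = ", "))
  df <- df[order(df$scaffold_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a gene table as BED6(+family) — the round-trip partner of
#' \code{readGeneTable(format = "bed")}
#'
#' @param genes a gene data.frame as returned by [readGeneTable()].
#' @param path output path.
#' @export
writeGeneTable <- function(genes, path) {
  needCols(genes, c("gene_id", "scaffold_id", "start", "end", "strand"),
           "gene table")
  hasFam <- "family_id" %in% names(genes) && any(!is.na(genes$family_id))
  out <- data.frame(genes$scaffold_id, genes$start, genes$end,
                    genes$gene_id, 0L, genes$strand)
  if (hasFam) out[[7]] <- ifelse(is.na(genes$family_id), ".", genes$family_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an orthology family table (family_id, species, gene_id TSV)
#'
#' Duplicated rows are tolerated and dropped; a gene listed under two
#' different families violates the disjoint-families model and is a hard
#' error naming the offenders.
#'
#' @param path TSV path; `#` comment lines and an optional header row
#'   (exactly \code{family_id species gene_id}) are skipped.
#' @return data.frame (family_id, species, gene_id), deduplicated, with
#'   attribute \code{provenance} = the path.
#' @export
readOrthologPairs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("family_id", "species", "gene_id"),
                          colClasses = "character")
  if (nrow(df) && identical(tolower(unlist(df[1, ], use.names = FALSE)),
                            c("family_id", "species", "gene_id")))
    df <- df[-1, , drop = FALSE]
  if (!nrow(df)) stop("no ortholog rows in ", path)
  df <- unique(df)
  key <- paste(df$species, df$gene_id, sep = "\r")
  nfam <- tapply(df$family_id, key, function(x) length(unique(x)))
  if (any(nfam > 1L)) {
    bad <- sub("\r.*", "", names(nfam)[nfam > 1L])
    badg <- sub(".*\r", "", names(nfam)[nfam > 1L])
    stop("gene(s) assigned to more than one family: ",
         paste(utils::head(paste0(bad, ":", badg), 10), collapse = ", "))
  }
  rownames(df) <- NULL
  attr(df, "provenance") <- path
  df
}

#' Attach family assignments to a gene table
#'
#' @param genes gene data.frame ([readGeneTable()]).
#' @param familyMap ortholog table ([readOrthologPairs()]).
#' @return the gene table with \code{family_id} filled where the
#'   (species, gene_id) pair appears in the map.
#' @export
assignFamilies <- function(genes, familyMap) {
  needCols(familyMap, c("family_id", "species", "gene_id"), "family map")
  fm <- familyMap[familyMap$species == genes$species[1], , drop = FALSE]
  idx <- match(genes$gene_id, fm$gene_id)
  genes$family_id <- fm$family_id[idx]
  genes
}

#' Build the scaffold-by-family incidence of ancestral-orthology genes
#'
#' Only genes carrying a family assignment contribute; the per-scaffold
#' totals returned by [scaffoldTotals()] are the quantity the
#' "at least 20 ancestral genes" screen filter is applied to.
#'
#' @param genes gene data.frame; \code{family_id} either already present
#'   or supplied through \code{familyMap}.
#' @param familyMap optional ortholog table used to fill \code{family_id}.
#' @param genome label for the resulting object (defaults to the species).
#' @return a [FamilyIncidence-class] object.
#' @export
buildIncidence <- function(genes, familyMap = NULL, genome = NULL) {
  needCols(genes, c("gene_id", "species", "scaffold_id"), "gene table")
  if (!is.null(familyMap)) genes <- assignFamilies(genes, familyMap)
  if (is.null(genes$family_id)) genes$family_id <- NA_character_
  gf <- genes[!is.na(genes$family_id), , drop = FALSE]
  if (!nrow(gf))
    stop("no genes with a family assignment: cannot build incidence")
  if (is.null(genome)) genome <- gf$species[1]
  scf <- factor(gf$scaffold_id)
  fam <- factor(gf$family_id)
  counts <- Matrix::sparseMatrix(
    i = as.integer(scf), j = as.integer(fam),
    x = rep(1, nrow(gf)),
    dims = c(nlevels(scf), nlevels(fam)),
    dimnames = list(levels(scf), levels(fam)))
  new("FamilyIncidence", genome = genome, counts = counts)
}

#' Read a per-scaffold read-depth table
#'
#' Schema: \code{scaffold_id<TAB>length<TAB>sample_id<TAB>mean_depth},
#' optional header, `#` comments. Depth extraction from alignments is
#' upstream of this package (e.g.
#' \code{samtools depth -a aln.bam | awk} per scaffold).
#'
#' @param path TSV path.
#' @return data.frame (scaffold_id, length, sample_id, mean_depth).
#' @export
readDepthTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("scaffold_id", "length",
                                        "sample_id", "mean_depth"),
                          colClasses = c("character", "character",
                                         "character", "character"))
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df$length[1]))))
    df <- df[-1, , drop = FALSE]
  df$length <- as.numeric(df$length)
  df$mean_depth <- as.numeric(df$mean_depth)
  if (anyNA(df$length) || anyNA(df$mean_depth))
    stop("non-numeric length/mean_depth in ", path)
  if (any(df$mean_depth < 0)) stop("negative depths in ", path)
  rownames(df) <- NULL
  df
}

#' Read a sample-sex table (sample_id, sex)
#'
#' @param path TSV path; sex values are normalised to "male"/"female".
#' @export
readSampleSexes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("sample_id", "sex"),
                          colClasses = "character")
  if (nrow(df) && tolower(df$sex[1]) == "sex") df <- df[-1, , drop = FALSE]
  sx <- tolower(substr(df$sex, 1, 1))
  df$sex <- c(m = "male", f = "female")[sx]
  if (anyNA(df$sex)) stop("unrecognised sex label in ", path)
  rownames(df) <- NULL
  df
}

#' Read ancestral-linkage-group definitions (alg_id, scaffold_id TSV)
#'
#' Each reference scaffold (or scaffold segment) belongs to exactly one
#' ALG; a scaffold listed twice is an error.
#'
#' @param path TSV path with columns alg_id, scaffold_id.
#' @export
readAlgTable <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("alg_id", "scaffold_id"),
                          colClasses = "character")
  if (nrow(df) && tolower(df$alg_id[1]) == "alg_id") df <- df[-1, , drop = FALSE]
  df <- unique(df)
  if (anyDuplicated(df$scaffold_id))
    stop("scaffold(s) assigned to more than one ALG: ",
         paste(unique(df$scaffold_id[duplicated(df$scaffold_id)]),
               collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Read a binary gene-family presence/absence matrix
#'
#' TSV with a header row: first column \code{family_id}, remaining
#' columns one species each, entries 0/1.
#'
#' @param path TSV path.
#' @return integer matrix, families in rows (rownames), species in
#'   columns (colnames).
#' @export
readPresenceAbsence <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "family_id")
    stop("presence/absence matrix must have a 'family_id' first column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L)))
    stop("presence/absence entries must all be 0 or 1")
  rownames(m) <- df$family_id
  m
}

#' Read a rooted species tree in newick format
#'
#' @param path newick file.
#' @return an \code{ape::phylo}; errors if the tree is unrooted.
#' @export
readSpeciesTree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse a tree from ", path)
  if (!ape::is.rooted(tr)) stop("tree in ", path, " is not rooted")
  tr
}
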