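#' @include AllClasses.R
NULL

# write a tab table with a '#'-prefixed header line
.writeHashTSV <- function(dt, path) {
  writeLines(paste0("#", paste(names(dt), collapse = "\t")), path)
  if (nrow(dt))
    fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE,
           append = TRUE)
  invisible(path)
}

.readHashTSV <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#"))
    stop("expected a '#'-prefixed header line in ", path)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  if (length(readLines(path, n = 2L)) < 2L)
    return(as.data.table(setNames(rep(list(character()), length(cols)),
                                  cols)))
  dt <- fread(path, sep = "\t", header = FALSE, skip = 1L, quote = "")
  setnames(dt, cols)
  dt
}

#' Write and read editing-site tables
#'
#' Site tables are UTF-8 tab-separated files with a '#'-prefixed header and
#' 1-based closed coordinates. Editing levels are serialized with 10
#' significant digits and recomputed from the integer counts on read (the
#' class invariant `level = nTarget / nTotal` makes the round trip exact).
#' Duplicate (chrom, pos, strand, change) rows are an error on read unless
#' `allowDuplicates = TRUE`.
#'
#' @param x a [SiteCalls-class] object.
#' @param path file path.
#' @return `writeSiteTable` returns `path` invisibly; `readSiteTable` a
#'   [SiteCalls-class] object.
#' @export
writeSiteTable <- function(x, path) {
  stopifnot(is(x, "SiteCalls"))
  dt <- as.data.table(siteTable(x))
  if (nrow(dt)) dt[, level := sprintf("%.10g", level)]
  .writeHashTSV(dt, path)
}

#' @rdname writeSiteTable
#' @param allowDuplicates keep duplicate site rows instead of erroring.
#' @export
readSiteTable <- function(path, allowDuplicates = FALSE) {
  dt <- .readHashTSV(path)
  miss <- base::setdiff(.SITE_COLS, names(dt))
  if (length(miss))
    stop("site table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(dt)) {
    dup <- duplicated(dt[, .(chrom, pos, strand, change)])
    if (any(dup) && !allowDuplicates)
      stop("duplicate site rows in ", path, " (first at data row ",
           which(dup)[1], "); set allowDuplicates = TRUE to keep them")
    dt[, `:=`(pos = as.integer(pos), nTarget = as.integer(nTarget),
              nOther = as.integer(nOther), nTotal = as.integer(nTotal),
              level = as.numeric(level))]
    dt[nTotal > 0L, level := nTarget / nTotal]
    for (cl in c("region", "geneId", "status")) {
      if (!is.character(dt[[cl]])) dt[, (cl) := as.character(get(cl))]
      dt[get(cl) == "", (cl) := NA_character_]
    }
  }
  SiteCalls(as.data.frame(dt))
}

#' Read a genomic variant mask
#'
#' Masks list DNA-derived changes (DNA-seq variants, SNP catalogues) as
#' (chrom, pos) or (chrom, pos, alt) rows in a '#'-headed TSV. A position
#' masked without an alt removes every mismatch there; with an alt, only
#' that alternative allele.
#'
#' @param path TSV path with columns chrom, pos and optionally alt.
#' @return a keyed `data.table` with columns chrom, pos, alt (alt is NA for
#'   position-wide masks).
#' @export
readVariantMask <- function(path) {
  dt <- .readHashTSV(path)
  if (!all(c("chrom", "pos") %in% names(dt)))
    stop("variant mask must have columns chrom, pos")
  dt[, pos := as.integer(pos)]
  if (!"alt" %in% names(dt)) dt[, alt := NA_character_]
  dt[alt == "", alt := NA_character_]
  out <- dt[, .(chrom = as.character(chrom), pos, alt = as.character(alt))]
  setkey(out, chrom, pos)
  out
}

#' @rdname readVariantMask
#' @param mask a variant mask from `readVariantMask`.
#' @param chrom,pos,alt position (and optionally allele) to look up.
#' @return `maskContains` returns a logical: TRUE when the position is
#'   masked entirely, or masked for the queried alt.
#' @export
maskContains <- function(mask, chrom, pos, alt = NULL) {
  # local names must not collide with mask columns inside the join
  qChrom <- as.character(chrom)
  qPos <- as.integer(pos)
  hit <- mask[list(qChrom, qPos), on = c("chrom", "pos"), nomatch = 0L]
  if (nrow(hit) == 0L) return(FALSE)
  if (is.null(alt)) return(TRUE)
  any(is.na(hit$alt)) || alt %in% hit$alt
}

#' Read a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that truncates names at
#' the first whitespace and enforces uniqueness.
#'
#' @param path FASTA path.
#' @return a `DNAStringSet` named by sequence.
#' @export
readGenome <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g)))
    stop("duplicate sequence names in ", path)
  g
}

#' Read a gene-by-sample count table
#'
#' Counts are non-negative integers in a '#'-headed TSV whose first column is
#' the gene identifier; remaining columns are samples.
#'
#' @param path TSV path.
#' @return an integer matrix with genes as rownames, samples as colnames.
#' @export
readCountsTable <- function(path) {
  dt <- .readHashTSV(path)
  genes <- as.character(dt[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene row in ", path, ": ", genes[duplicated(genes)][1])
  m <- as.matrix(dt[, -1, with = FALSE])
  storage.mode(m) <- "double"
  if (any(is.na(m)) || any(m != round(m)) || any(m < 0))
    stop("counts in ", path, " must be non-negative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' @rdname readCountsTable
#' @param counts integer matrix of counts (genes x samples).
#' @export
writeCountsTable <- function(counts, path) {
  dt <- data.table(gene_id = rownames(counts))
  dt <- cbind(dt, as.data.table(counts))
  .writeHashTSV(dt, path)
}
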