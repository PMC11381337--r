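#' @include gene-models.R
NULL

.REGION_RANK <- c(cds_exon = 1L, utr5 = 2L, utr3 = 2L, noncoding_exon = 3L,
                  intron = 4L)

#' Infer the edited strand from an A-to-I mismatch signature
#'
#' A-to-I editing reads out as A>G on the strand carrying the edited
#' adenosine; a T>C mismatch on the reference therefore marks editing of the
#' reverse strand. Any other change is not an A-to-I signature.
#'
#' @param ref reference base at the site ("A" or "T").
#' @param change change string, "A>G" or "T>C".
#' @return "+" for A>G, "-" for T>C.
#' @export
inferEditingStrand <- function(ref, change) {
  ok <- (ref == "A" & change == "A>G") | (ref == "T" & change == "T>C")
  if (!all(ok))
    stop("not an A-to-I signature: ",
         paste(unique(paste0(ref[!ok], " with ", change[!ok])),
               collapse = ", "))
  ifelse(change == "A>G", "+", "-")
}

#' Annotate genomic positions with gene region labels
#'
#' Assigns each (chrom, pos) exactly one region label using the feature index
#' of a [GeneModels-class]. When several features overlap a position the
#' precedence is cds_exon > utr5/utr3 > noncoding_exon > intron; positions
#' overlapping no gene are intergenic. When a site strand is supplied and
#' genes on both strands overlap the position, features on the matching
#' strand win before precedence is applied. Ties are broken by gene_id order
#' so annotation is deterministic.
#'
#' @param models a [GeneModels-class] object.
#' @param chrom,pos character / integer vectors of positions (1-based).
#' @param strand optional vector of site strands ("+"/"-"; NA to ignore).
#' @return data.frame with columns chrom, pos, region, geneId.
#' @export
annotatePositions <- function(models, chrom, pos, strand = NULL) {
  stopifnot(is(models, "GeneModels"))
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  if (is.null(strand)) strand <- rep(NA_character_, n)
  strand <- rep_len(as.character(strand), n)
  qry <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
  feats <- geneFeatures(models)
  hits <- findOverlaps(qry, feats, ignore.strand = TRUE)
  out <- data.table(chrom = chrom, pos = as.integer(pos),
                    region = "intergenic", geneId = NA_character_)
  if (length(hits)) {
    h <- data.table(q = queryHits(hits),
                    type = mcols(feats)$type[subjectHits(hits)],
                    geneId = mcols(feats)$gene_id[subjectHits(hits)],
                    fstrand = as.character(strand(feats))[subjectHits(hits)])
    h[, rank := .REGION_RANK[type]]
    h[, smatch := !is.na(strand[q]) & fstrand == strand[q]]
    # strand-matching features take priority when the query is stranded and
    # at least one overlapping feature matches
    h[, anyMatch := any(smatch), by = q]
    h <- h[!anyMatch | smatch]
    setkey(h, q, rank, geneId)
    best <- h[, .SD[1L], by = q]
    out[best$q, `:=`(region = best$type, geneId = best$geneId)]
  }
  as.data.frame(out)
}

#' Summarize region composition of a site set
#'
#' Fraction of sites per region label, optionally merging utr5/utr3 into a
#' single "utr" group (the three-group exon / intron / UTR view used for
#' pie-chart style summaries).
#'
#' @param sites a [SiteCalls-class] object or data.frame with a `region`
#'   column.
#' @param mergeUTR merge utr5/utr3 into "utr" (default TRUE).
#' @return data.frame with columns region, n, fraction (fractions sum to 1).
#' @export
regionSummary <- function(sites, mergeUTR = TRUE) {
  s <- if (is(sites, "SiteCalls")) siteTable(sites) else as.data.frame(sites)
  reg <- s$region
  if (mergeUTR) reg[reg %in% c("utr5", "utr3")] <- "utr"
  tb <- table(reg)
  data.frame(region = names(tb), n = as.integer(tb),
             fraction = as.numeric(tb) / sum(tb), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Annotate a SiteCalls object in place
#'
#' Fills the region and geneId columns of a site table using
#' [annotatePositions()], passing each site's strand so genes on the edited
#' strand win at dual-gene loci.
#'
#' @param sites a [SiteCalls-class] object.
#' @param models a [GeneModels-class] object.
#' @return the annotated [SiteCalls-class] object.
#' @export
annotateSites <- function(sites, models) {
  stopifnot(is(sites, "SiteCalls"))
  s <- siteTable(sites)
  if (nrow(s) == 0L) return(sites)
  ann <- annotatePositions(models, s$chrom, s$pos, s$strand)
  s$region <- ann$region
  s$geneId <- ann$geneId
  SiteCalls(s)
}
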