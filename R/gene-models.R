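#' @include AllClasses.R
NULL

#' Build gene models from a feature table
#'
#' Constructs a [GeneModels-class] from a flat table of transcript features.
#' Introns are derived as the gaps between consecutive exons of each
#' transcript; for coding transcripts the UTRs are derived as the exon
#' portions outside the CDS span, assigned 5'/3' by transcriptional
#' orientation. All coordinates are 1-based closed intervals.
#'
#' @param tab data.frame with columns chrom, start, end, strand, type (one of
#'   exon, CDS), gene_id, transcript_id, and optionally biotype (coding,
#'   lncRNA, other; inferred from CDS presence when absent).
#' @return a [GeneModels-class] object.
#' @export
geneModelsFromTable <- function(tab) {
  dt <- as.data.table(tab)
  need <- c("chrom", "start", "end", "strand", "type", "gene_id",
            "transcript_id")
  miss <- base::setdiff(need, names(dt))
  if (length(miss))
    stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(dt$strand %in% c("+", "-")))
    stop("unknown strand in gene models (must be '+' or '-')")
  stc <- dt[, .(n = length(unique(strand)), chrom_n = length(unique(chrom))),
            by = gene_id]
  if (any(stc$n > 1L))
    stop("inconsistent strand within gene ", stc[n > 1L]$gene_id[1])
  if (any(stc$chrom_n > 1L))
    stop("gene on multiple chromosomes: ", stc[chrom_n > 1L]$gene_id[1])

  exons <- dt[type == "exon"][order(chrom, start)]
  cds <- dt[type == "CDS"][order(chrom, start)]
  if (nrow(exons) == 0L) stop("no exon features in gene models")
  # overlap check within transcript
  chk <- exons[order(transcript_id, start)]
  chk[, prevEnd := data.table::shift(end), by = transcript_id]
  if (any(!is.na(chk$prevEnd) & chk$start <= chk$prevEnd))
    stop("overlapping exons within transcript ",
         chk[!is.na(prevEnd) & start <= prevEnd]$transcript_id[1])

  if ("biotype" %in% names(dt)) {
    bio <- dt[, .(biotype = biotype[!is.na(biotype)][1]), by = gene_id]
  } else {
    bio <- data.table(gene_id = unique(dt$gene_id), biotype = NA_character_)
  }
  codingTx <- unique(cds$transcript_id)
  txGene <- unique(exons[, .(transcript_id, gene_id, chrom,
                             strand = strand)])
  codingGenes <- unique(txGene[transcript_id %in% codingTx]$gene_id)
  bio[is.na(biotype), biotype := fifelse(gene_id %in% codingGenes,
                                         "coding", "other")]

  feats <- list()
  ## introns: gaps between consecutive exons
  introns <- exons[order(transcript_id, start)]
  introns[, nxtStart := data.table::shift(start, type = "lead"),
          by = transcript_id]
  introns <- introns[!is.na(nxtStart) & nxtStart > end + 1L,
                     .(chrom, start = end + 1L, end = nxtStart - 1L,
                       strand, gene_id, transcript_id, type = "intron")]
  feats$intron <- introns

  ## coding transcripts: cds_exon + UTR pieces
  if (nrow(cds)) {
    feats$cds <- cds[, .(chrom, start, end, strand, gene_id, transcript_id,
                         type = "cds_exon")]
    span <- cds[, .(cdsStart = min(start), cdsEnd = max(end)),
                by = transcript_id]
    ce <- merge(exons[transcript_id %in% codingTx], span,
                by = "transcript_id")
    left <- ce[start < cdsStart,
               .(chrom, start, end = pmin(end, cdsStart - 1L), strand,
                 gene_id, transcript_id, cdsStart)]
    right <- ce[end > cdsEnd,
                .(chrom, start = pmax(start, cdsEnd + 1L), end, strand,
                  gene_id, transcript_id)]
    left[, type := fifelse(strand == "+", "utr5", "utr3")]
    right[, type := fifelse(strand == "+", "utr3", "utr5")]
    feats$utr <- rbind(left[, .(chrom, start, end, strand, gene_id,
                                transcript_id, type)],
                       right[, .(chrom, start, end, strand, gene_id,
                                 transcript_id, type)])
  }
  ## noncoding transcripts: exons as noncoding_exon
  nc <- exons[!transcript_id %in% codingTx]
  if (nrow(nc))
    feats$nc <- nc[, .(chrom, start, end, strand, gene_id, transcript_id,
                       type = "noncoding_exon")]

  fdt <- rbindlist(feats, use.names = TRUE)
  fdt <- merge(fdt, bio, by = "gene_id")
  fgr <- GRanges(fdt$chrom, IRanges(fdt$start, fdt$end), strand = fdt$strand)
  mcols(fgr) <- DataFrame(gene_id = fdt$gene_id,
                          transcript_id = fdt$transcript_id,
                          type = fdt$type, biotype = fdt$biotype)

  gspan <- exons[, .(start = min(start), end = max(end), chrom = chrom[1],
                     strand = strand[1]), by = gene_id]
  gspan <- merge(gspan, bio, by = "gene_id")
  ggr <- GRanges(gspan$chrom, IRanges(gspan$start, gspan$end),
                 strand = gspan$strand)
  mcols(ggr) <- DataFrame(gene_id = gspan$gene_id, biotype = gspan$biotype)
  new("GeneModels", features = sort(fgr), genes = sort(ggr))
}

.gffAttr <- function(gr, keys) {
  mc <- mcols(gr)
  for (k in keys) if (k %in% names(mc)) {
    v <- mc[[k]]
    if (is(v, "List") || is.list(v))
      v <- vapply(v, function(z) if (length(z)) as.character(z[1])
                  else NA_character_, character(1))
    return(as.character(v))
  }
  rep(NA_character_, length(gr))
}

#' Read gene models from a GFF3-like annotation
#'
#' Imports gene / transcript / exon / CDS features (via rtracklayer), walks
#' the Parent hierarchy, validates that exons fall inside their transcript
#' span, and derives introns and UTRs as in [geneModelsFromTable()]. Gene
#' biotype is taken from a `biotype` attribute when present, else inferred
#' (coding when the gene has CDS, otherwise "other").
#'
#' @param path GFF3 path.
#' @return a [GeneModels-class] object.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  ids <- .gffAttr(gr, c("ID"))
  parents <- .gffAttr(gr, c("Parent"))

  txTypes <- c("mRNA", "transcript", "ncRNA", "lnc_RNA", "lincRNA",
               "pre_miRNA", "snoRNA", "tRNA", "rRNA")
  isGene <- type == "gene"
  isTx <- type %in% txTypes
  tx2gene <- setNames(parents[isTx], ids[isTx])
  txStrand <- setNames(as.character(strand(gr))[isTx], ids[isTx])
  txStart <- setNames(start(gr)[isTx], ids[isTx])
  txEnd <- setNames(end(gr)[isTx], ids[isTx])

  pick <- type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  sub <- gr[pick]
  subType <- type[pick]
  par <- parents[pick]
  if (anyNA(par))
    stop("exon/CDS feature without Parent in ", path)
  unknown <- base::setdiff(unique(par), names(tx2gene))
  if (length(unknown))
    stop("feature Parent(s) not matching any transcript: ",
         paste(head(unknown, 3), collapse = ", "))
  ex <- subType == "exon"
  if (any(start(sub)[ex] < txStart[par[ex]] |
          end(sub)[ex] > txEnd[par[ex]]))
    stop("exon outside its transcript span in ", path)

  tab <- data.table(chrom = as.character(seqnames(sub)),
                    start = start(sub), end = end(sub),
                    strand = txStrand[par],
                    type = subType,
                    gene_id = unname(tx2gene[par]),
                    transcript_id = par)
  if (!all(tab$strand %in% c("+", "-")))
    stop("unknown strand in ", path)
  bioAttr <- .gffAttr(gr, c("biotype", "gene_biotype"))
  bio <- data.table(gene_id = ids[isGene], biotype = bioAttr[isGene])
  models <- tab[type %in% c("exon", "CDS")]
  models <- merge(models, bio, by = "gene_id", all.x = TRUE)
  gm <- geneModelsFromTable(models)

  ## honor explicit UTR features when the annotation provides them
  utr <- tab[type %in% c("five_prime_UTR", "three_prime_UTR")]
  if (nrow(utr)) {
    utr[, type := fifelse(type == "five_prime_UTR", "utr5", "utr3")]
    utr <- merge(utr, bio, by = "gene_id", all.x = TRUE)
    keepF <- gm@features[!mcols(gm@features)$type %in% c("utr5", "utr3")]
    ugr <- GRanges(utr$chrom, IRanges(utr$start, utr$end),
                   strand = utr$strand)
    bt <- utr$biotype
    bt[is.na(bt)] <- "coding"
    mcols(ugr) <- DataFrame(gene_id = utr$gene_id,
                            transcript_id = utr$transcript_id,
                            type = utr$type, biotype = bt)
    gm@features <- sort(c(keepF, ugr))
    validObject(gm)
  }
  gm
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA/transcript, exon and CDS records (UTRs and introns are
#' derived on read). Used by the synthetic-data generator.
#'
#' @param models a [GeneModels-class] object.
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  f <- geneFeatures(models)
  g <- geneSpans(models)
  fdt <- data.table(chrom = as.character(seqnames(f)), start = start(f),
                    end = end(f), strand = as.character(strand(f)),
                    type = mcols(f)$type, gene_id = mcols(f)$gene_id,
                    transcript_id = mcols(f)$transcript_id)
  ## reconstitute exons: union of cds/utr/noncoding pieces per transcript
  exonish <- fdt[type %in% c("cds_exon", "utr5", "utr3", "noncoding_exon")]
  exonish <- exonish[order(transcript_id, start)]
  exonish[, prevEnd := data.table::shift(end), by = transcript_id]
  exonish[, grp := cumsum(is.na(prevEnd) | start > prevEnd + 1L),
          by = transcript_id]
  exons <- exonish[, .(start = min(start), end = max(end)),
                   by = .(chrom, strand, gene_id, transcript_id, grp)]
  cds <- fdt[type == "cds_exon"]
  txs <- exons[, .(start = min(start), end = max(end)),
               by = .(chrom, strand, gene_id, transcript_id)]

  lines <- c("##gff-version 3")
  gdt <- data.table(chrom = as.character(seqnames(g)), start = start(g),
                    end = end(g), strand = as.character(strand(g)),
                    gene_id = mcols(g)$gene_id, biotype = mcols(g)$biotype)
  lines <- c(lines, gdt[, sprintf(
    "%s\tedicall\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
    chrom, start, end, strand, gene_id, biotype)])
  lines <- c(lines, txs[, sprintf(
    "%s\tedicall\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
    chrom, start, end, strand, transcript_id, gene_id)])
  lines <- c(lines, exons[, sprintf(
    "%s\tedicall\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
    chrom, start, end, strand, transcript_id)])
  if (nrow(cds))
    lines <- c(lines, cds[, sprintf(
      "%s\tedicall\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
      chrom, start, end, strand, transcript_id)])
  writeLines(lines, path)
  invisible(path)
}
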