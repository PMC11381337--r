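#' @include context.R
NULL

# exon intervals per transcript, reconstructed from the typed features
transcriptExons <- function(models) {
  f <- geneFeatures(models)
  fdt <- data.table(chrom = as.character(seqnames(f)), start = start(f),
                    end = end(f), strand = as.character(strand(f)),
                    type = mcols(f)$type, gene_id = mcols(f)$gene_id,
                    transcript_id = mcols(f)$transcript_id)
  ex <- fdt[type %in% c("cds_exon", "utr5", "utr3", "noncoding_exon")]
  ex <- ex[order(transcript_id, start)]
  ex[, prevEnd := data.table::shift(end), by = transcript_id]
  ex[, grp := cumsum(is.na(prevEnd) | start > prevEnd + 1L),
     by = transcript_id]
  ex[, .(start = min(start), end = max(end)),
     by = .(chrom, strand, gene_id, transcript_id, grp)][, grp := NULL][]
}

#' Extract folding windows around editing sites
#'
#' Returns the `2 * flank + 1` nucleotide sequence centred on each site, on
#' the edited strand (minus-strand sites are reverse-complemented so the
#' centre base is always A). `form = "unspliced"` extracts from the genome;
#' `form = "spliced"` maps the site into its transcript (the gene's isoform
#' with the longest mature sequence) and extracts from the spliced sequence,
#' so windows spanning splice junctions differ between the two forms. Sites
#' that do not fit (within `flank` of a sequence end, intronic for the
#' spliced form, or off-transcript) are returned as exclusion records.
#'
#' @param sites a [SiteCalls-class] or data.frame with chrom, pos, strand.
#' @param genome a `DNAStringSet`.
#' @param models a [GeneModels-class]; required for `form = "spliced"`.
#' @param form `"unspliced"` (genomic) or `"spliced"` (transcript).
#' @param flank nucleotides on each side (default 50, i.e. 101-nt windows).
#' @return list with `windows` (data.frame: chrom, pos, strand, form, seq)
#'   and `excluded` (data.frame: chrom, pos, reason).
#' @export
extractWindows <- function(sites, genome, models = NULL,
                           form = c("unspliced", "spliced"), flank = 50L) {
  form <- match.arg(form)
  flank <- as.integer(flank)
  stopifnot(flank >= 1L)
  s <- if (is(sites, "SiteCalls")) siteTable(sites) else as.data.frame(sites)
  s <- as.data.frame(s)
  if (form == "unspliced") {
    sw <- .siteWindows(genome, as.character(s$chrom), as.integer(s$pos),
                       as.character(s$strand), flank)
    windows <- data.frame(chrom = s$chrom[sw$kept], pos = s$pos[sw$kept],
                          strand = s$strand[sw$kept],
                          form = rep(form, length(sw$kept)),
                          seq = as.character(sw$windows),
                          stringsAsFactors = FALSE)
    excluded <- data.frame(chrom = s$chrom[sw$excluded],
                           pos = s$pos[sw$excluded],
                           reason = rep("end_proximal_or_ambiguous",
                                        length(sw$excluded)),
                           stringsAsFactors = FALSE)
    return(list(windows = windows, excluded = excluded))
  }
  if (is.null(models))
    stop("spliced windows require gene models")
  ex <- transcriptExons(models)
  ex[, txLen := sum(end - start + 1L), by = transcript_id]
  ## longest isoform per gene
  best <- ex[, .(txLen = txLen[1]), by = .(gene_id, transcript_id)]
  best <- best[order(gene_id, -txLen, transcript_id)][, .SD[1L], by = gene_id]
  ex <- ex[transcript_id %in% best$transcript_id][order(transcript_id, start)]
  ex[, cumBefore := cumsum(data.table::shift(end - start + 1L, fill = 0L)),
     by = transcript_id]
  txSeqCache <- new.env(parent = emptyenv())
  txSeq <- function(tid) {
    if (!is.null(txSeqCache[[tid]])) return(txSeqCache[[tid]])
    e <- ex[transcript_id == tid]
    sq <- paste(vapply(seq_len(nrow(e)), function(i)
      as.character(subseq(genome[[e$chrom[i]]], e$start[i], e$end[i])),
      character(1)), collapse = "")
    if (e$strand[1] == "-")
      sq <- as.character(reverseComplement(DNAString(sq)))
    txSeqCache[[tid]] <- sq
    sq
  }
  win <- list(); exc <- list()
  for (i in seq_len(nrow(s))) {
    hit <- ex[chrom == s$chrom[i] & start <= s$pos[i] & end >= s$pos[i]]
    if (nrow(hit) == 0L) {
      exc[[length(exc) + 1L]] <- data.frame(
        chrom = s$chrom[i], pos = s$pos[i], reason = "not_in_transcriptome",
        stringsAsFactors = FALSE)
      next
    }
    hit <- hit[1L]
    sq <- txSeq(hit$transcript_id)
    plusCoord <- hit$cumBefore + (s$pos[i] - hit$start + 1L)
    cen <- if (hit$strand == "+") plusCoord else nchar(sq) - plusCoord + 1L
    if (cen - flank < 1L || cen + flank > nchar(sq)) {
      exc[[length(exc) + 1L]] <- data.frame(
        chrom = s$chrom[i], pos = s$pos[i], reason = "end_proximal",
        stringsAsFactors = FALSE)
      next
    }
    wsq <- substr(sq, cen - flank, cen + flank)
    if (grepl("[^ACGT]", wsq)) {
      exc[[length(exc) + 1L]] <- data.frame(
        chrom = s$chrom[i], pos = s$pos[i], reason = "ambiguous_base",
        stringsAsFactors = FALSE)
      next
    }
    win[[length(win) + 1L]] <- data.frame(
      chrom = s$chrom[i], pos = s$pos[i], strand = s$strand[i],
      form = form, seq = wsq, stringsAsFactors = FALSE)
  }
  empty <- function(reason = character(0))
    data.frame(chrom = character(), pos = integer(), reason = reason,
               stringsAsFactors = FALSE)
  list(windows = if (length(win)) do.call(rbind, win) else
         data.frame(chrom = character(), pos = integer(),
                    strand = character(), form = character(),
                    seq = character(), stringsAsFactors = FALSE),
       excluded = if (length(exc)) do.call(rbind, exc) else empty())
}

#' Minimum free energy of RNA sequences
#'
#' Computes the thermodynamic minimum free energy (kcal/mol) of each
#' sequence with a nearest-neighbor folding backend. The default backend is
#' the ViennaRNA `RNAfold` executable; the backend is pluggable behind this
#' stable contract (deterministic given sequence, temperature and backend
#' version). DNA input is transcribed (T to U) before folding. Ambiguous
#' bases raise an error unless `ambiguous = "skip"` returns NA for those
#' sequences.
#'
#' @param seqs character vector of sequences over A/C/G/T/U.
#' @param temperature folding temperature in Celsius (default 37).
#' @param backend folding backend; only `"rnafold"` is built in.
#' @param ambiguous `"error"` (default) or `"skip"`.
#' @return numeric vector of free energies, kcal/mol.
#' @export
foldMFE <- function(seqs, temperature = 37, backend = "rnafold",
                    ambiguous = c("error", "skip")) {
  ambiguous <- match.arg(ambiguous)
  if (length(seqs) == 0L) return(numeric(0))
  rna <- chartr("tu", "TU", toupper(seqs))
  rna <- gsub("T", "U", rna, fixed = TRUE)
  bad <- grepl("[^ACGU]", rna)
  if (any(bad)) {
    if (ambiguous == "error")
      stop("ambiguous base(s) in sequence(s) ",
           paste(head(which(bad), 3), collapse = ", "))
  }
  if (!identical(backend, "rnafold"))
    stop("unknown folding backend: ", backend)
  exe <- Sys.which("RNAfold")
  if (exe == "")
    stop("RNAfold executable not found on PATH (ViennaRNA is required ",
         "for MFE computation)")
  dg <- rep(NA_real_, length(rna))
  todo <- which(!bad)
  if (length(todo)) {
    outlines <- system2(exe, args = c("--noPS", paste0("--temp=", temperature)),
                        input = rna[todo], stdout = TRUE)
    elines <- grep("\\(\\s*-?[0-9.]+\\)\\s*$", outlines, value = TRUE)
    if (length(elines) != length(todo))
      stop("RNAfold returned ", length(elines), " energies for ",
           length(todo), " sequences")
    dg[todo] <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", elines))
  }
  dg
}

#' Welch comparison of free-energy groups
#'
#' Removes outliers (free-energy magnitude above `outlierBound` kcal/mol by
#' default; set `signedOutlier = TRUE` for the literal `dG > bound` rule)
#' and compares group means with the two-sided Welch two-sample t-test
#' (unequal variances, Welch-Satterthwaite degrees of freedom).
#'
#' @param groupA,groupB numeric vectors of free energies.
#' @param outlierBound magnitude cutoff (default 100; NULL disables).
#' @param signedOutlier use the literal `dG > bound` removal instead of
#'   `|dG| > bound`.
#' @return list with t, df, p, meanA, meanB, nA, nB.
#' @export
compareMFEGroups <- function(groupA, groupB, outlierBound = 100,
                             signedOutlier = FALSE) {
  trim <- function(x) {
    x <- x[!is.na(x)]
    if (is.null(outlierBound)) return(x)
    if (signedOutlier) x[x <= outlierBound] else x[abs(x) <= outlierBound]
  }
  a <- trim(groupA); b <- trim(groupB)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values after outlier removal")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1,
                  meanA = mean(a), meanB = mean(b),
                  nA = length(a), nB = length(b)))
    stop("degenerate variance: both groups constant with unequal means")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanA = mean(a), meanB = mean(b),
       nA = length(a), nB = length(b))
}
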