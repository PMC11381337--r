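#' @include AllClasses.R
NULL

#' Prefilter a count table
#'
#' Keeps genes with at least `minReads` total reads and a coefficient of
#' variation (sd / mean across samples) below `cvMax`. Genes with zero mean
#' (CV undefined) are dropped. The filter is idempotent.
#'
#' @param counts integer matrix, genes x samples.
#' @param minReads minimum total reads (default 10).
#' @param cvMax coefficient-of-variation bound (default 1; exclusive).
#' @return the filtered count matrix.
#' @export
filterCounts <- function(counts, minReads = 10, cvMax = 1) {
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  mu <- rowMeans(counts)
  cv <- rep(Inf, nrow(counts))
  pos <- mu > 0
  cv[pos] <- apply(counts[pos, , drop = FALSE], 1, sd) / mu[pos]
  keep <- tot >= minReads & cv < cvMax
  counts[keep, , drop = FALSE]
}

#' Per-gene expression log-ratios between strains
#'
#' Library-size-normalizes the (already filtered) counts per sample
#' (counts-per-million over the filtered universe), averages within strain
#' and returns `log2((mean CPM mutant + pseudo) / (mean CPM reference +
#' pseudo))` per gene — the per-gene statistic used by the editing-class
#' shift tests.
#'
#' @param counts filtered count matrix (genes x samples).
#' @param colStrain character vector: strain of each column.
#' @param strain,reference strain labels to compare (mutant vs reference).
#' @param pseudo pseudo-CPM added to both means (default 1).
#' @return named numeric vector of log2 ratios.
#' @export
geneLogRatios <- function(counts, colStrain, strain, reference = "wild_type",
                          pseudo = 1) {
  counts <- as.matrix(counts)
  stopifnot(length(colStrain) == ncol(counts))
  libs <- colSums(counts)
  if (any(libs == 0)) stop("sample with zero library size")
  cpm <- sweep(counts, 2, libs / 1e6, "/")
  mMut <- rowMeans(cpm[, colStrain == strain, drop = FALSE])
  mRef <- rowMeans(cpm[, colStrain == reference, drop = FALSE])
  setNames(log2((mMut + pseudo) / (mRef + pseudo)), rownames(counts))
}

#' Editing-class expression shift test
#'
#' Welch two-sample t-test (two-sided) of a per-gene statistic between a
#' gene class (e.g. 3'UTR-edited genes or lncRNAs) and its complement in the
#' analyzed universe. The complement keeps the two groups disjoint; the sign
#' of the class mean minus the complement mean reports the direction
#' (negative = class downregulated).
#'
#' @param stat named numeric vector of per-gene statistics (e.g.
#'   [geneLogRatios()]).
#' @param classGenes character vector of gene ids in the class.
#' @return list with t, df, p, meanClass, meanRest, nClass, nRest, shift.
#' @export
classShiftTest <- function(stat, classGenes) {
  cls <- stat[names(stat) %in% classGenes]
  rest <- stat[!names(stat) %in% classGenes]
  if (length(cls) < 2L)
    stop("gene class has fewer than 2 genes in the analyzed universe")
  if (length(rest) < 2L)
    stop("complement has fewer than 2 genes")
  tt <- t.test(cls, rest, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       meanClass = mean(cls), meanRest = mean(rest),
       nClass = length(cls), nRest = length(rest),
       shift = mean(cls) - mean(rest))
}

#' Flag differentially expressed genes by stage-specific thresholds
#'
#' Applies the printed flagging rule to externally computed differential
#' expression statistics: a gene is DE when `|log2FC|` strictly exceeds the
#' stage threshold (1 at embryo, 2 at L4) and `padj` is strictly below
#' `padjMax`. Genes with missing padj are skipped.
#'
#' @param deStats data.frame with columns gene_id, log2FC, padj.
#' @param stage `"embryo"` or `"L4"`.
#' @param lfcThreshold named vector of stage thresholds
#'   (default c(embryo = 1, L4 = 2)).
#' @param padjMax adjusted-p cutoff (default 0.05, exclusive).
#' @return character vector of DE gene ids.
#' @export
flagDE <- function(deStats, stage = c("embryo", "L4"),
                   lfcThreshold = c(embryo = 1, L4 = 2), padjMax = 0.05) {
  stage <- match.arg(stage)
  dt <- as.data.frame(deStats)
  stopifnot(all(c("gene_id", "log2FC", "padj") %in% names(dt)))
  usable <- !is.na(dt$padj) & !is.na(dt$log2FC)
  thr <- lfcThreshold[[stage]]
  de <- usable & abs(dt$log2FC) > thr & dt$padj < padjMax
  dt$gene_id[de]
}

#' Hypergeometric significance of a set overlap
#'
#' Upper-tail hypergeometric probability of observing an overlap of at least
#' `k` genes between two sets drawn from a universe of size `N` (the
#' standard enrichment convention, tail inclusive of the observed overlap).
#'
#' @param nA,nB sizes of the two sets.
#' @param k observed overlap.
#' @param N universe size.
#' @return list with nA, nB, k, N and the upper-tail p.
#' @export
overlapSignificance <- function(nA, nB, k, N) {
  stopifnot(nA <= N, nB <= N, nA >= 0, nB >= 0, N >= 1)
  if (k > min(nA, nB))
    stop("overlap k cannot exceed the smaller set")
  if (k < max(0, nA + nB - N))
    stop("overlap k below the minimum forced by the universe size")
  p <- phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE)
  list(nA = nA, nB = nB, k = k, N = N, p = p)
}
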