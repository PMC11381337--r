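#' @include edicall-package.R
NULL

.STRAINS <- c("wild_type", "adbp1_mutant", "adar_null")
.STAGES <- c("embryo", "L4")
.NUCS <- c("A", "C", "G", "T")
.REGIONS <- c("cds_exon", "utr5", "utr3", "noncoding_exon", "intron",
              "intergenic")

#' Sample metadata record
#'
#' One row of per-sample metadata: strain, developmental stage and biological
#' replica index. The (strain, stage, replica) triple must be unique within a
#' run; `sampleId` defaults to `"strain_stage_rN"`.
#'
#' @param strain one of `"wild_type"`, `"adbp1_mutant"`, `"adar_null"`.
#' @param stage one of `"embryo"`, `"L4"`.
#' @param replica positive integer replica index.
#' @param sampleId unique sample label.
#' @return a one-row `data.frame` with columns strain, stage, replica,
#'   sampleId.
#' @export
sampleMeta <- function(strain, stage, replica = 1L,
                       sampleId = paste(strain, stage, paste0("r", replica),
                                        sep = "_")) {
  strain <- match.arg(strain, .STRAINS)
  stage <- match.arg(stage, .STAGES)
  replica <- as.integer(replica)
  stopifnot(length(replica) == 1L, replica >= 1L)
  data.frame(strain = strain, stage = stage, replica = replica,
             sampleId = sampleId, stringsAsFactors = FALSE)
}

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Decoded pileup base calls
#'
#' Call-level representation of a pileup file: one row per decoded base call
#' (nucleotide, strand, Phred quality) keyed by (chrom, pos), plus the
#' per-position table with reference base and decoded depth (zero-depth
#' positions appear only there). Coordinates are 1-based.
#'
#' @slot calls data.frame with columns chrom, pos, ref, nuc, strand, qual.
#' @slot positions data.frame with columns chrom, pos, ref, depth.
#' @slot sample one-row sample-metadata data.frame (see [sampleMeta()]), or
#'   NULL when unknown.
#' @export
setClass("PileupCalls",
         representation(calls = "data.frame", positions = "data.frame",
                        sample = "data.frameOrNULL"))

setValidity("PileupCalls", function(object) {
  need <- c("chrom", "pos", "ref", "nuc", "strand", "qual")
  if (!all(need %in% names(object@calls)))
    return(sprintf("calls must have columns %s", paste(need, collapse = ", ")))
  if (nrow(object@calls)) {
    if (!all(object@calls$nuc %in% .NUCS))
      return("call nucleotides must be A/C/G/T")
    if (!all(object@calls$strand %in% c("+", "-")))
      return("call strand must be '+' or '-'")
    if (any(object@calls$qual < 0))
      return("Phred qualities must be >= 0")
  }
  TRUE
})

#' Quality-filtered per-position nucleotide counts
#'
#' Compact pileup representation used by the callers: per position, counts of
#' quality-passing calls by nucleotide (columns A, C, G, T), the decoded call
#' depth before filtering (`nCalls`) and the number of sub-threshold calls
#' dropped (`nLowQ`). The quality-passing depth at a position is
#' `A + C + G + T`.
#'
#' @slot counts data.frame with columns chrom, pos, ref, A, C, G, T, nCalls,
#'   nLowQ.
#' @slot sample one-row sample-metadata data.frame or NULL.
#' @slot qMin the Phred threshold the counts were filtered at.
#' @export
setClass("PileupCounts",
         representation(counts = "data.frame", sample = "data.frameOrNULL",
                        qMin = "numeric"))

setValidity("PileupCounts", function(object) {
  need <- c("chrom", "pos", "ref", .NUCS, "nCalls", "nLowQ")
  if (!all(need %in% names(object@counts)))
    return(sprintf("counts must have columns %s", paste(need, collapse = ", ")))
  if (length(object@qMin) != 1L || object@qMin < 0)
    return("qMin must be a single non-negative number")
  TRUE
})

#' Strand-aware gene models
#'
#' Gene structure derived from a GFF3-like annotation: a feature-level
#' `GRanges` (types cds_exon, utr5, utr3, noncoding_exon, intron, with
#' gene/transcript identity and biotype) and a gene-span `GRanges`. Introns
#' are derived as the gaps between consecutive exons of each transcript; UTRs
#' by transcriptional orientation. All intervals are 1-based and closed.
#'
#' @slot features GRanges with mcols gene_id, transcript_id, type, biotype.
#' @slot genes GRanges of gene spans with mcols gene_id, biotype.
#' @export
setClass("GeneModels",
         representation(features = "GRanges", genes = "GRanges"))

setValidity("GeneModels", function(object) {
  mc <- mcols(object@features)
  need <- c("gene_id", "transcript_id", "type", "biotype")
  if (!all(need %in% names(mc)))
    return(sprintf("features must carry mcols %s", paste(need, collapse = ", ")))
  bad <- base::setdiff(unique(mc$type),
                       c("cds_exon", "utr5", "utr3", "noncoding_exon", "intron"))
  if (length(bad))
    return(sprintf("unknown feature type(s): %s", paste(bad, collapse = ", ")))
  if (any(as.character(strand(object@features)) == "*"))
    return("all features must be stranded")
  TRUE
})

#' Called editing sites
#'
#' A table of called editing sites. `level = nTarget / nTotal` where
#' `nTotal` is the quality-passing depth, `nTarget` the reads carrying the
#' target change (A>G, or T>C for minus-strand sites) and `nOther` the
#' remaining mismatching reads. `status` distinguishes catalogued (`known`)
#' from newly discovered (`de_novo`) sites.
#'
#' @slot sites data.frame with columns chrom, pos, strand, ref, change,
#'   level, nTarget, nOther, nTotal, region, geneId, status.
#' @export
setClass("SiteCalls", representation(sites = "data.frame"))

.SITE_COLS <- c("chrom", "pos", "strand", "ref", "change", "level",
                "nTarget", "nOther", "nTotal", "region", "geneId", "status")

setValidity("SiteCalls", function(object) {
  s <- object@sites
  if (!all(.SITE_COLS %in% names(s)))
    return(sprintf("sites must have columns %s",
                   paste(.SITE_COLS, collapse = ", ")))
  if (nrow(s)) {
    if (!all(s$strand %in% c("+", "-")))
      return("site strand must be '+' or '-'")
    if (any(s$nTarget + s$nOther > s$nTotal))
      return("nTarget + nOther must not exceed nTotal")
    pos <- s$nTotal > 0
    if (any(abs(s$level[pos] - s$nTarget[pos] / s$nTotal[pos]) > 1e-9))
      return("level must equal nTarget / nTotal")
  }
  TRUE
})

#' Construct a SiteCalls object
#'
#' @param sites data.frame of site records; missing optional columns
#'   (region, geneId, status) are filled with NA / "known".
#' @return a [SiteCalls-class] object.
#' @export
SiteCalls <- function(sites = NULL) {
  if (is.null(sites) || nrow(sites) == 0L) {
    sites <- data.frame(chrom = character(), pos = integer(),
                        strand = character(), ref = character(),
                        change = character(), level = numeric(),
                        nTarget = integer(), nOther = integer(),
                        nTotal = integer(), region = character(),
                        geneId = character(), status = character(),
                        stringsAsFactors = FALSE)
  } else {
    sites <- as.data.frame(sites, stringsAsFactors = FALSE)
    if (is.null(sites$region)) sites$region <- NA_character_
    if (is.null(sites$geneId)) sites$geneId <- NA_character_
    if (is.null(sites$status)) sites$status <- "known"
    sites <- sites[, .SITE_COLS]
  }
  new("SiteCalls", sites = sites)
}

#' Nucleotide context profile around editing sites
#'
#' Position-by-nucleotide count and probability matrices for the sequence
#' context of a site set: rows are offsets -w..+w relative to the edited
#' adenosine (position 0), columns A/C/G/T on the edited strand.
#' Probabilities use the pseudocount rule
#' `P[i,c] = (n[i,c] + lambda) / (sum_c' n[i,c'] + C * lambda)` with C = 4.
#'
#' @slot counts integer matrix (2w+1) x 4 of context nucleotide counts.
#' @slot probs numeric matrix of the same shape; every row sums to 1.
#' @slot nSites number of sequences contributing to the profile.
#' @slot halfWidth the half-window w.
#' @slot lambda the pseudocount used for `probs`.
#' @export
setClass("ContextProfile",
         representation(counts = "matrix", probs = "matrix",
                        nSites = "integer", halfWidth = "integer",
                        lambda = "numeric"))

setValidity("ContextProfile", function(object) {
  if (!identical(colnames(object@counts), .NUCS))
    return("counts columns must be A, C, G, T")
  if (nrow(object@probs)) {  # probs may be empty until probabilityMatrix()
    if (!identical(dim(object@counts), dim(object@probs)))
      return("counts and probs must have identical shape")
    if (any(abs(rowSums(object@probs) - 1) > 1e-9))
      return("probability rows must sum to 1")
  }
  TRUE
})

## ---- configuration objects --------------------------------------------

#' Known-site editing caller configuration
#'
#' Thresholds for the catalogued-site analysis: calls below Phred `qMin` are
#' discarded; a site is edited when the target change (A>G / T>C) reaches at
#' least `thetaSite` of the quality-passing depth while all other mismatches
#' together stay at or below `thetaOther`; sites whose target change exceeds
#' `thetaMut` in the editing-null (ADAR mutant) strain are blacklisted as
#' non-editing artifacts.
#'
#' @param qMin Phred threshold (default 25).
#' @param thetaSite minimum target-change fraction (default 0.01; inclusive).
#' @param thetaOther maximum aggregate other-mismatch fraction (default 0.01;
#'   inclusive).
#' @param thetaMut editing-null blacklist threshold (default 0.03; exclusive,
#'   i.e. strictly above 3\% is removed).
#' @param minExpressedDepth minimum quality-passing depth for a site to count
#'   as expressed in the unthresholded editing matrix (default 1).
#' @param perChangeOther if TRUE, compare each non-target mismatch fraction
#'   to `thetaOther` separately instead of their sum.
#' @return an `EditingConfig` object.
#' @export
editingConfig <- function(qMin = 25, thetaSite = 0.01, thetaOther = 0.01,
                          thetaMut = 0.03, minExpressedDepth = 1L,
                          perChangeOther = FALSE) {
  new("EditingConfig", qMin = qMin, thetaSite = thetaSite,
      thetaOther = thetaOther, thetaMut = thetaMut,
      minExpressedDepth = as.integer(minExpressedDepth),
      perChangeOther = perChangeOther)
}

#' @rdname editingConfig
#' @export
setClass("EditingConfig",
         representation(qMin = "numeric", thetaSite = "numeric",
                        thetaOther = "numeric", thetaMut = "numeric",
                        minExpressedDepth = "integer",
                        perChangeOther = "logical"))

setValidity("EditingConfig", function(object) {
  th <- c(object@thetaSite, object@thetaOther, object@thetaMut)
  if (any(th < 0 | th > 1)) return("fraction thresholds must lie in [0, 1]")
  if (object@qMin < 0) return("qMin must be >= 0")
  TRUE
})

#' De-novo editing caller configuration
#'
#' The five-criterion caller: quality-passing calls only (`qMin`); the most
#' abundant mismatch must be supported by at least `kMin` reads and reach at
#' least `thetaDn` of the quality-passing depth; every other mismatch must
#' stay at or below `thetaOther`; the site must recur in at least `rMin`
#' biological replicas of the strain and stage.
#'
#' @param qMin Phred threshold (default 25).
#' @param kMin minimum reads supporting the top change (default 2).
#' @param thetaDn minimum top-change fraction (default 0.05; inclusive).
#' @param thetaOther maximum per-other-change fraction (default 0.01;
#'   inclusive).
#' @param rMin minimum number of supporting replicas (default 2).
#' @return a `DenovoConfig` object.
#' @export
denovoConfig <- function(qMin = 25, kMin = 2L, thetaDn = 0.05,
                         thetaOther = 0.01, rMin = 2L) {
  new("DenovoConfig", qMin = qMin, kMin = as.integer(kMin),
      thetaDn = thetaDn, thetaOther = thetaOther, rMin = as.integer(rMin))
}

#' @rdname denovoConfig
#' @export
setClass("DenovoConfig",
         representation(qMin = "numeric", kMin = "integer",
                        thetaDn = "numeric", thetaOther = "numeric",
                        rMin = "integer"))

setValidity("DenovoConfig", function(object) {
  if (object@kMin < 1L) return("kMin must be >= 1")
  th <- c(object@thetaDn, object@thetaOther)
  if (any(th < 0 | th > 1)) return("fractions must lie in [0, 1]")
  TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "PileupCalls", function(object) {
  cat(sprintf("PileupCalls: %d calls over %d positions",
              nrow(object@calls), nrow(object@positions)))
  if (!is.null(object@sample) && nrow(object@sample))
    cat(sprintf(" [%s]", object@sample$sampleId[1]))
  cat("\n")
})

setMethod("show", "PileupCounts", function(object) {
  cat(sprintf("PileupCounts: %d positions (Phred >= %g)",
              nrow(object@counts), object@qMin))
  if (!is.null(object@sample) && nrow(object@sample))
    cat(sprintf(" [%s]", object@sample$sampleId[1]))
  cat("\n")
})

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels: %d genes, %d features (%s)\n",
              length(object@genes), length(object@features),
              paste(names(table(mcols(object@features)$type)),
                    collapse = "/")))
})

setMethod("show", "SiteCalls", function(object) {
  s <- object@sites
  cat(sprintf("SiteCalls: %d sites (%d known, %d de_novo)\n", nrow(s),
              sum(s$status == "known"), sum(s$status == "de_novo")))
})

setMethod("show", "ContextProfile", function(object) {
  cat(sprintf("ContextProfile: w = %d, lambda = %g, n = %d sites\n",
              object@halfWidth, object@lambda, object@nSites))
})

## ---- accessors --------------------------------------------------------

#' Accessors for edicall S4 containers
#'
#' `pileupCalls()` / `pileupPositions()` return the call-level and
#' position-level tables of a [PileupCalls-class]; `pileupCounts()` the
#' per-position count table of a [PileupCounts-class]; `sampleInfo()` the
#' attached sample metadata; `siteTable()` the site data.frame of a
#' [SiteCalls-class]; `geneFeatures()` / `geneSpans()` the feature and gene
#' `GRanges` of a [GeneModels-class]; `profileCounts()` / `profileProbs()`
#' the matrices of a [ContextProfile-class].
#'
#' @param x an edicall S4 object.
#' @return the underlying table, GRanges or matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
pileupCalls <- function(x) { stopifnot(is(x, "PileupCalls")); x@calls }

#' @rdname accessors
#' @export
pileupPositions <- function(x) { stopifnot(is(x, "PileupCalls")); x@positions }

#' @rdname accessors
#' @export
pileupCounts <- function(x) { stopifnot(is(x, "PileupCounts")); x@counts }

#' @rdname accessors
#' @export
sampleInfo <- function(x) x@sample

#' @rdname accessors
#' @export
siteTable <- function(x) { stopifnot(is(x, "SiteCalls")); x@sites }

#' @rdname accessors
#' @export
geneFeatures <- function(x) { stopifnot(is(x, "GeneModels")); x@features }

#' @rdname accessors
#' @export
geneSpans <- function(x) { stopifnot(is(x, "GeneModels")); x@genes }

#' @rdname accessors
#' @export
profileCounts <- function(x) { stopifnot(is(x, "ContextProfile")); x@counts }

#' @rdname accessors
#' @export
profileProbs <- function(x) { stopifnot(is(x, "ContextProfile")); x@probs }

setMethod("length", "SiteCalls", function(x) nrow(x@sites))
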