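#' @include formats-pileup.R annotate.R
NULL

.TARGET_ALT <- c(A = "G", T = "C")
.TARGET_CHANGE <- c(A = "A>G", T = "T>C")

# per-site quantification table for catalogued sites against pooled counts
.siteQuant <- function(counts, catalogue) {
  stopifnot(is(counts, "PileupCounts"))
  cat <- as.data.table(catalogue)
  if (!all(c("chrom", "pos", "ref") %in% names(cat)))
    stop("site catalogue needs columns chrom, pos, ref")
  if (!all(cat$ref %in% c("A", "T")))
    stop("catalogued A-to-I sites must have reference base A or T")
  cdt <- as.data.table(pileupCounts(counts))
  q <- merge(cat[, .(chrom = as.character(chrom), pos = as.integer(pos),
                     ref = as.character(ref))],
             cdt[, .(chrom, pos, cref = ref, A, C, G, T)],
             by = c("chrom", "pos"), all.x = TRUE, sort = TRUE)
  if (any(!is.na(q$cref) & q$cref != "N" & q$cref != q$ref))
    stop("catalogue reference base disagrees with pileup at ",
         q[!is.na(cref) & cref != "N" & cref != ref][1, paste0(chrom, ":", pos)])
  for (cl in .NUCS) q[is.na(get(cl)), (cl) := 0L]
  q[, nTotal := A + C + G + T]
  q[, nTarget := fifelse(ref == "A", G, C)]
  q[, nRef := fifelse(ref == "A", A, T)]
  q[, nOther := nTotal - nRef - nTarget]
  # largest single non-target mismatch, for the per-change interpretation
  q[, maxOther := fifelse(ref == "A", pmax(C, T), pmax(A, G))]
  q[, cref := NULL]
  q
}

#' Blacklist catalogued sites using the editing-null strain
#'
#' A catalogued site is blacklisted when its target change (A>G / T>C)
#' exceeds `thetaMut` (strictly; "above 3\%") of the quality-passing depth in
#' the pooled editing-null (ADAR mutant) pileup, marking it as a non-editing
#' artifact. Sites with zero editing-null coverage cannot be assessed and are
#' retained, flagged `unassessable`.
#'
#' @param adarNull pooled [PileupCounts-class] for the editing-null strain.
#' @param catalogue data.frame of catalogued sites (chrom, pos, ref).
#' @param thetaMut blacklist threshold (default 0.03, exclusive).
#' @return data.frame with columns chrom, pos, ref, mutLevel, blacklisted,
#'   unassessable.
#' @export
buildAdarBlacklist <- function(adarNull, catalogue, thetaMut = 0.03) {
  q <- .siteQuant(adarNull, catalogue)
  q[, mutLevel := fifelse(nTotal > 0L, nTarget / nTotal, NA_real_)]
  q[, unassessable := nTotal == 0L]
  q[, blacklisted := !unassessable & mutLevel > thetaMut]
  as.data.frame(q[, .(chrom, pos, ref, mutLevel, blacklisted, unassessable)])
}

#' Call editing at catalogued sites
#'
#' Quantifies editing at known sites in pooled (strain + stage) pileup
#' counts. A site is called edited when the target change reaches at least
#' `thetaSite` of the quality-passing depth and the remaining mismatches
#' together stay at or below `thetaOther` (with `perChangeOther = TRUE`, each
#' non-target change separately). Sites with zero quality-passing depth are
#' `not_expressed`, which is distinct from `not_edited`; blacklisted sites
#' are excluded before calling.
#'
#' @param counts pooled [PileupCounts-class] for one strain and stage.
#' @param catalogue data.frame of catalogued sites (chrom, pos, ref).
#' @param config an [editingConfig()] object.
#' @param blacklist optional result of [buildAdarBlacklist()].
#' @return list with `calls` (a [SiteCalls-class] of edited sites) and
#'   `table` (per-site quantification with an `outcome` column:
#'   edited / not_edited / not_expressed / blacklisted).
#' @export
callKnownSites <- function(counts, catalogue, config = editingConfig(),
                           blacklist = NULL) {
  stopifnot(is(config, "EditingConfig"))
  q <- .siteQuant(counts, catalogue)
  q[, outcome := "not_edited"]
  q[nTotal == 0L, outcome := "not_expressed"]
  otherStat <- if (config@perChangeOther) q$maxOther else q$nOther
  # ratio comparisons: correctly-rounded division makes printed boundaries
  # (e.g. 2/200 against 1%) compare exactly
  ed <- q$nTotal > 0L &
    q$nTarget / q$nTotal >= config@thetaSite &
    otherStat / q$nTotal <= config@thetaOther
  q[ed, outcome := "edited"]
  if (!is.null(blacklist)) {
    bl <- as.data.table(blacklist)[blacklisted == TRUE, .(chrom, pos)]
    if (nrow(bl)) {
      q[bl, on = c("chrom", "pos"), outcome := "blacklisted"]
    }
  }
  q[, level := fifelse(nTotal > 0L, nTarget / nTotal, NA_real_)]
  called <- q[outcome == "edited"]
  calls <- SiteCalls(if (nrow(called)) data.frame(
    chrom = called$chrom, pos = called$pos,
    strand = ifelse(called$ref == "A", "+", "-"),
    ref = called$ref, change = .TARGET_CHANGE[called$ref],
    level = called$level, nTarget = called$nTarget,
    nOther = called$nOther, nTotal = called$nTotal,
    status = "known", stringsAsFactors = FALSE) else NULL)
  list(calls = calls,
       table = as.data.frame(q[, .(chrom, pos, ref, nTarget, nOther, nTotal,
                                   level, outcome)]))
}

#' Gene-level editing by pooling catalogued sites
#'
#' Merges the quality-passing bases over all catalogued sites of each gene:
#' the gene editing fraction is (sum of target reads) / (sum of
#' quality-passing depth), exactly the coverage-weighted pooling of the
#' per-site levels. Genes whose pooled depth is zero are reported
#' `not_expressed`.
#'
#' @param siteTable per-site quantification (the `table` of
#'   [callKnownSites()]) carrying a `geneId` column, e.g. merged from
#'   [annotatePositions()].
#' @return data.frame with columns geneId, nTarget, nTotal, level, expressed.
#' @export
geneLevelEditing <- function(siteTable) {
  dt <- as.data.table(siteTable)
  if (!"geneId" %in% names(dt))
    stop("siteTable must carry a geneId column (annotate the sites first)")
  dt <- dt[!is.na(geneId)]
  g <- dt[, .(nTarget = sum(nTarget), nTotal = sum(nTotal)), by = geneId]
  g[, expressed := nTotal > 0L]
  g[, level := fifelse(expressed, nTarget / nTotal, NA_real_)]
  as.data.frame(g[order(geneId)])
}

#' Unthresholded editing-by-sample matrix
#'
#' Builds the site-by-sample matrix of raw target-change fractions with no
#' calling thresholds, discriminating lack of editing from lack of
#' expression: a cell is `expressed` when its quality-passing depth reaches
#' `minExpressedDepth`, otherwise its level is undefined (NA), never zero.
#'
#' @param countsList named list of [PileupCounts-class] objects (one per
#'   sample or pool); names become column names.
#' @param catalogue data.frame of sites to quantify (chrom, pos, ref).
#' @param minExpressedDepth minimum depth to count as expressed (default 1).
#' @return a [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#'   with assays `level`, `depth` and `expressed`, rowData the sites and
#'   colData the sample metadata when attached.
#' @export
editingMatrix <- function(countsList, catalogue, minExpressedDepth = 1L) {
  stopifnot(is.list(countsList), length(countsList) >= 1L)
  if (is.null(names(countsList)))
    names(countsList) <- paste0("sample", seq_along(countsList))
  cat <- as.data.table(catalogue)
  quants <- lapply(countsList, function(x) .siteQuant(x, cat))
  nsite <- nrow(quants[[1]])
  lvl <- dep <- matrix(NA_real_, nsite, length(countsList),
                       dimnames = list(NULL, names(countsList)))
  for (j in seq_along(quants)) {
    qj <- quants[[j]]
    dep[, j] <- qj$nTotal
    ok <- qj$nTotal >= minExpressedDepth
    lvl[ok, j] <- qj$nTarget[ok] / qj$nTotal[ok]
  }
  expressed <- dep >= minExpressedDepth
  rd <- quants[[1]][, .(chrom, pos, ref)]
  cd <- rbindlist(lapply(countsList, function(x) {
    s <- sampleInfo(x)
    if (is.null(s) || !nrow(s))
      data.table(strain = NA_character_, stage = NA_character_,
                 replica = NA_integer_, sampleId = NA_character_)
    else as.data.table(s)
  }))
  SummarizedExperiment(
    assays = list(level = lvl, depth = dep, expressed = expressed),
    rowData = DataFrame(rd), colData = DataFrame(cd))
}
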