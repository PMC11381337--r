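#' @include known-sites.R
NULL

#' Remove DNA-derived changes from pileup counts
#'
#' Positions masked without an alt have all mismatch calls removed (the
#' reference-matching calls are kept); positions masked with an alt have only
#' that allele's calls removed. Genomic variants (DNA-seq differences, SNPs)
#' are thereby prevented from surfacing as RNA editing candidates.
#'
#' @param counts a [PileupCounts-class] object.
#' @param mask a variant mask from [readVariantMask()].
#' @return a [PileupCounts-class] with masked changes zeroed.
#' @export
subtractGenomicVariants <- function(counts, mask) {
  stopifnot(is(counts, "PileupCounts"))
  dt <- as.data.table(pileupCounts(counts))
  m <- as.data.table(mask)
  wide <- m[is.na(alt), .(chrom, pos)]
  if (nrow(wide)) {
    for (nu in .NUCS)
      dt[wide, on = c("chrom", "pos"),
         (nu) := fifelse(ref == nu, get(nu), 0L)]
  }
  altSpec <- m[!is.na(alt)]
  if (nrow(altSpec)) {
    for (nu in .NUCS) {
      tgt <- altSpec[alt == nu, .(chrom, pos)]
      if (nrow(tgt))
        dt[tgt, on = c("chrom", "pos"),
           (nu) := fifelse(ref == nu, get(nu), 0L)]
    }
  }
  new("PileupCounts", counts = as.data.frame(dt), sample = counts@sample,
      qMin = counts@qMin)
}

#' Remove changes observed in the editing-null strain
#'
#' Any (position, alt) change carried by at least one quality-passing read in
#' the pooled editing-null (ADAR mutant) pileup is removed from the test
#' counts; other alts at the position are retained. Applying the subtraction
#' twice equals applying it once.
#'
#' @param counts test-sample [PileupCounts-class].
#' @param adarNull pooled editing-null [PileupCounts-class] (same quality
#'   threshold).
#' @return a [PileupCounts-class] with mutant-observed changes zeroed.
#' @export
subtractMutantChanges <- function(counts, adarNull) {
  stopifnot(is(counts, "PileupCounts"), is(adarNull, "PileupCounts"))
  if (!isTRUE(all.equal(counts@qMin, adarNull@qMin)))
    warning("subtracting mutant changes filtered at a different quality threshold")
  dt <- as.data.table(pileupCounts(counts))
  mut <- as.data.table(pileupCounts(adarNull))
  for (nu in .NUCS) {
    seen <- mut[get(nu) > 0L & ref != nu, .(chrom, pos)]
    if (nrow(seen))
      dt[seen, on = c("chrom", "pos"),
         (nu) := fifelse(ref == nu, get(nu), 0L)]
  }
  new("PileupCounts", counts = as.data.frame(dt), sample = counts@sample,
      qMin = counts@qMin)
}

#' Call per-sample de-novo editing candidates
#'
#' Applies the per-site candidate criteria to quality-filtered,
#' variant-subtracted counts: the most abundant mismatch at the position
#' (ties broken in fixed A < C < G < T order, with a warning) must be
#' supported by at least `kMin` reads and make up at least `thetaDn` of the
#' quality-passing depth, while every other mismatch stays at or below
#' `thetaOther`. Candidates record whatever change won (not only A>G);
#' A-to-I classification happens at [classifyNovelty()].
#'
#' @param counts a [PileupCounts-class] (after subtractions).
#' @param config a [denovoConfig()] object.
#' @return data.frame of candidates: chrom, pos, ref, alt, nTarget, nOther,
#'   nTotal, level, plus replica/sampleId when sample metadata is attached.
#' @export
callCandidateSites <- function(counts, config = denovoConfig()) {
  stopifnot(is(counts, "PileupCounts"), is(config, "DenovoConfig"))
  dt <- as.data.table(pileupCounts(counts))
  cm <- as.matrix(dt[, .(A, C, G, T)])
  refIdx <- match(dt$ref, .NUCS)
  mm <- cm
  mm[cbind(seq_len(nrow(mm)), refIdx)] <- -1L  # exclude reference column
  mm[is.na(refIdx), ] <- -1L                   # N reference: no defined change
  top <- max.col(mm, ties.method = "first")    # fixed A<C<G<T tie order
  topCnt <- mm[cbind(seq_len(nrow(mm)), top)]
  depth <- rowSums(cm)
  sumMM <- rowSums(pmax(mm, 0L))
  secondCnt <- {
    mm2 <- mm
    mm2[cbind(seq_len(nrow(mm2)), top)] <- -1L
    mm2[cbind(seq_len(nrow(mm2)), max.col(mm2, ties.method = "first"))]
  }
  ok <- depth > 0 & topCnt >= config@kMin &
    topCnt / depth >= config@thetaDn &
    # remaining mismatches each at or below thetaOther
    secondCnt / depth <= config@thetaOther &
    (sumMM - topCnt - pmax(secondCnt, 0L)) / depth <= config@thetaOther
  ok[is.na(ok)] <- FALSE
  # a tie among changes passing the top-change criteria can never survive the
  # other-change bound (the runner-up carries the same count); log it anyway
  topPass <- !is.na(depth) & depth > 0 & topCnt >= config@kMin &
    topCnt / depth >= config@thetaDn
  topPass[is.na(topPass)] <- FALSE
  nTies <- sum(topPass & secondCnt == topCnt)
  if (nTies > 0)
    warning(nTies, " position(s) had tied most-abundant changes; ",
            "fixed A<C<G<T order applied")
  out <- dt[ok, .(chrom, pos, ref)]
  out[, alt := .NUCS[top[ok]]]
  out[, nTarget := topCnt[ok]]
  out[, nTotal := as.integer(depth[ok])]
  out[, nOther := as.integer(sumMM[ok] - topCnt[ok])]
  out[, level := nTarget / nTotal]
  s <- sampleInfo(counts)
  if (!is.null(s) && nrow(s)) {
    out[, `:=`(sampleId = s$sampleId[1], replica = s$replica[1])]
  }
  as.data.frame(out)
}

#' Consolidate candidates across biological replicas
#'
#' Keeps a site when the same (chrom, pos, change) is a candidate in at least
#' `rMin` replicas of the strain and stage. Counts are pooled over the
#' supporting replicas; output is ordered by (chrom, pos).
#'
#' @param candidates list of per-replica candidate data.frames from
#'   [callCandidateSites()], or one data.frame with a `replica` column.
#' @param rMin minimum number of supporting replicas (default 2).
#' @return data.frame with chrom, pos, ref, alt, nReplicas, nTarget,
#'   nOther, nTotal, level.
#' @export
consolidateReplicas <- function(candidates, rMin = 2L) {
  if (is.data.frame(candidates)) {
    dt <- as.data.table(candidates)
  } else {
    cl <- lapply(seq_along(candidates), function(i) {
      x <- as.data.table(candidates[[i]])
      if (!"replica" %in% names(x)) x[, replica := i]
      x
    })
    dt <- rbindlist(cl, use.names = TRUE, fill = TRUE)
  }
  if (nrow(dt) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      nReplicas = integer(), nTarget = integer(),
                      nOther = integer(), nTotal = integer(),
                      level = numeric(), stringsAsFactors = FALSE))
  g <- dt[, .(nReplicas = length(unique(replica)),
              nTarget = sum(nTarget), nOther = sum(nOther),
              nTotal = sum(nTotal)), by = .(chrom, pos, ref, alt)]
  g <- g[nReplicas >= rMin]
  g[, level := fifelse(nTotal > 0L, nTarget / nTotal, NA_real_)]
  as.data.frame(g[order(chrom, pos, alt)])
}

#' Classify novelty and A-to-I signature of consolidated sites
#'
#' A site is `de_novo` when its position is edited in neither the wild-type
#' catalogued-site analysis nor the wild-type de-novo search; otherwise it is
#' `known`. Only A-to-I signature changes (A>G on the plus strand, T>C on
#' the minus strand) enter the editing report; other surviving changes are
#' returned on a diagnostics channel.
#'
#' @param sites consolidated candidates from [consolidateReplicas()].
#' @param wtEdited data.frame(s) of wild-type edited sites (chrom, pos), e.g.
#'   the union of known-site calls and wild-type de-novo calls; NULL for an
#'   empty set.
#' @return list with `calls` (a [SiteCalls-class]; status known/de_novo) and
#'   `diagnostics` (non-A-to-I changes, data.frame).
#' @export
classifyNovelty <- function(sites, wtEdited = NULL) {
  dt <- as.data.table(sites)
  isAI <- nrow(dt) > 0 &
    ((dt$ref == "A" & dt$alt == "G") | (dt$ref == "T" & dt$alt == "C"))
  ai <- dt[isAI]
  diag <- dt[!isAI]
  wt <- if (is.null(wtEdited)) {
    data.table(chrom = character(), pos = integer())
  } else if (is.data.frame(wtEdited)) {
    as.data.table(wtEdited)[, .(chrom, pos)]
  } else {
    rbindlist(lapply(wtEdited, function(w) {
      if (is(w, "SiteCalls")) w <- siteTable(w)
      as.data.table(w)[, .(chrom, pos)]
    }))
  }
  wt <- unique(wt)
  status <- rep("de_novo", nrow(ai))
  if (nrow(ai) && nrow(wt)) {
    hit <- !is.na(wt[ai, on = c("chrom", "pos"), which = TRUE])
    status[hit] <- "known"
  }
  calls <- SiteCalls(if (nrow(ai)) data.frame(
    chrom = ai$chrom, pos = ai$pos,
    strand = ifelse(ai$ref == "A", "+", "-"),
    ref = ai$ref, change = paste0(ai$ref, ">", ai$alt),
    level = ai$level, nTarget = ai$nTarget, nOther = ai$nOther,
    nTotal = ai$nTotal, status = status, stringsAsFactors = FALSE) else NULL)
  list(calls = calls, diagnostics = as.data.frame(diag))
}

#' Run the full de-novo detection for one strain and stage
#'
#' Per replica: subtract genomic variants and editing-null changes, then call
#' candidates; consolidate across replicas; classify novelty against the
#' wild-type edited sets and keep only A-to-I signature changes in the
#' report.
#'
#' @param countsList list of per-replica [PileupCounts-class] objects.
#' @param adarNull pooled editing-null [PileupCounts-class], or NULL to skip
#'   mutant subtraction.
#' @param mask variant mask from [readVariantMask()], or NULL.
#' @param config a [denovoConfig()] object.
#' @param wtEdited wild-type edited site set(s) for novelty classification.
#' @return list with `calls`, `diagnostics` and the per-replica `candidates`.
#' @export
denovoPipeline <- function(countsList, adarNull = NULL, mask = NULL,
                           config = denovoConfig(), wtEdited = NULL) {
  cands <- lapply(countsList, function(x) {
    if (!is.null(mask)) x <- subtractGenomicVariants(x, mask)
    if (!is.null(adarNull)) x <- subtractMutantChanges(x, adarNull)
    callCandidateSites(x, config)
  })
  cons <- consolidateReplicas(cands, rMin = config@rMin)
  res <- classifyNovelty(cons, wtEdited)
  res$candidates <- cands
  res
}
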