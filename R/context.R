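#' @include annotate.R
NULL

# site windows as DNAStringSet on the edited strand; returns the set plus
# the indices of sites excluded (too close to an end, or ambiguous base)
.siteWindows <- function(genome, chrom, pos, strand, w) {
  n <- length(pos)
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (any(!chrom %in% names(genome)))
    stop("site chromosome(s) absent from genome: ",
         paste(unique(chrom[!chrom %in% names(genome)]), collapse = ", "))
  ok <- pos - w >= 1L & pos + w <= lens[chrom]
  idx <- which(ok)
  if (!length(idx))
    return(list(windows = DNAStringSet(), kept = integer(0),
                excluded = which(!ok)))
  win <- DNAStringSet(rep("N", length(idx)))
  for (ch in unique(chrom[idx])) {
    ii <- which(chrom[idx] == ch)
    win[ii] <- Biostrings::extractAt(
      genome[[ch]], IRanges(pos[idx][ii] - w, pos[idx][ii] + w))
  }
  minus <- strand[idx] == "-"
  if (any(minus)) win[minus] <- reverseComplement(win[minus])
  hasN <- grepl("[^ACGT]", as.character(win))
  if (any(hasN)) {
    excluded <- c(which(!ok), idx[hasN])
    idx <- idx[!hasN]
    win <- win[!hasN]
  } else {
    excluded <- which(!ok)
  }
  list(windows = win, kept = idx, excluded = sort(excluded))
}

#' Count context nucleotides around editing sites
#'
#' Extracts the +/- w window around each site on the edited strand
#' (minus-strand sites contribute reverse-complemented context, so offset -1
#' is always the 5' neighbor of the edited adenosine) and tallies
#' nucleotides per offset. Sites within w of a sequence end, or with an
#' ambiguous base in the window, are excluded with a message.
#'
#' @param sites a [SiteCalls-class] or data.frame with chrom, pos, strand.
#' @param genome a `DNAStringSet` (see [readGenome()]).
#' @param w half-window width (default 3).
#' @return a [ContextProfile-class] with counts only (`lambda = NA`); apply
#'   [probabilityMatrix()] to obtain probabilities.
#' @export
contextCounts <- function(sites, genome, w = 3L) {
  s <- if (is(sites, "SiteCalls")) siteTable(sites) else as.data.frame(sites)
  w <- as.integer(w)
  stopifnot(w >= 1L)
  sw <- .siteWindows(genome, as.character(s$chrom), as.integer(s$pos),
                     as.character(s$strand), w)
  if (length(sw$excluded))
    message(length(sw$excluded), " site(s) excluded from context profile ",
            "(end-proximal or ambiguous window)")
  offs <- seq(-w, w)
  if (length(sw$windows) == 0L) {
    counts <- matrix(0L, 2L * w + 1L, 4L,
                     dimnames = list(offs, .NUCS))
  } else {
    cm <- consensusMatrix(sw$windows, baseOnly = TRUE)[.NUCS, , drop = FALSE]
    counts <- t(cm)
    dimnames(counts) <- list(offs, .NUCS)
    storage.mode(counts) <- "integer"
  }
  new("ContextProfile", counts = counts,
      probs = matrix(numeric(0), 0, 4, dimnames = list(NULL, .NUCS)),
      nSites = length(sw$windows), halfWidth = w, lambda = NA_real_)
}

#' Pseudocount probability matrix
#'
#' Converts context counts into per-position nucleotide probabilities with
#' the Laplace-style pseudocount rule
#' `P[i,c] = (n[i,c] + lambda) / (sum_c' n[i,c'] + C * lambda)`,
#' where C is the alphabet size (4). With `lambda = 0` this is the empirical
#' frequency; a position with zero counts and `lambda = 0` is undefined and
#' raises an error.
#'
#' @param x a [ContextProfile-class] or a position-by-nucleotide count
#'   matrix.
#' @param lambda pseudocount (default 1).
#' @param C alphabet size (default 4).
#' @return with a matrix input, the probability matrix; with a
#'   [ContextProfile-class], the profile with `probs` and `lambda` filled.
#' @export
probabilityMatrix <- function(x, lambda = 1, C = 4L) {
  stopifnot(lambda >= 0)
  counts <- if (is(x, "ContextProfile")) profileCounts(x) else as.matrix(x)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("context counts must be non-negative integers")
  tot <- rowSums(counts)
  if (lambda == 0 && any(tot == 0))
    stop("all-zero count row with lambda = 0: probabilities undefined")
  probs <- (counts + lambda) / (tot + C * lambda)
  if (is(x, "ContextProfile")) {
    x@probs <- probs
    x@lambda <- lambda
    validObject(x)
    x
  } else probs
}

#' Sample random adenosines stratified by gene region
#'
#' Draws control positions that carry an adenosine on the transcribed strand
#' (reference A in plus-strand genes, reference T in minus-strand genes),
#' stratified by region label. Reproducible given `seed`.
#'
#' @param genome a `DNAStringSet`.
#' @param models a [GeneModels-class].
#' @param strata named integer vector: region label (cds_exon, intron, utr5,
#'   utr3, noncoding_exon, or merged "utr") -> requested count.
#' @param seed optional integer seed.
#' @return data.frame with chrom, pos, strand, region.
#' @export
sampleRandomAdenosines <- function(genome, models, strata, seed = NULL) {
  stopifnot(is(models, "GeneModels"), length(strata) >= 1L,
            !is.null(names(strata)))
  feats <- geneFeatures(models)
  withSeed(seed, {
    out <- vector("list", length(strata))
    for (k in seq_along(strata)) {
      lab <- names(strata)[k]
      want <- as.integer(strata[[k]])
      if (want == 0L) next
      sel <- if (lab == "utr") mcols(feats)$type %in% c("utr5", "utr3")
             else mcols(feats)$type == lab
      fr <- feats[sel]
      if (!length(fr))
        stop("no features for stratum '", lab, "'")
      cand <- rbindlist(lapply(seq_along(fr), function(i) {
        sq <- as.character(subseq(genome[[as.character(seqnames(fr)[i])]],
                                  start(fr)[i], end(fr)[i]))
        str <- as.character(strand(fr)[i])
        hit <- if (str == "+") gregexpr("A", sq, fixed = TRUE)[[1]]
               else gregexpr("T", sq, fixed = TRUE)[[1]]
        if (hit[1] == -1L) return(NULL)
        data.table(chrom = as.character(seqnames(fr)[i]),
                   pos = start(fr)[i] + as.integer(hit) - 1L,
                   strand = str)
      }))
      if (is.null(cand) || nrow(cand) == 0L)
        stop("no adenosines available in stratum '", lab, "'")
      cand <- unique(cand)
      if (nrow(cand) < want)
        stop("stratum '", lab, "' has only ", nrow(cand),
             " adenosines; ", want, " requested")
      pick <- cand[sample.int(nrow(cand), want)]
      pick[, region := lab]
      out[[k]] <- pick
    }
    as.data.frame(rbindlist(out))
  })
}

#' Region-stratified context profiles with random-adenosine controls
#'
#' Builds one context profile per stratum (all sites, cds_exon, intron, and
#' merged UTR) together with a random-adenosine control of matched size per
#' stratum. Strata with no sites are omitted with a warning (small strata
#' make the probabilities unstable).
#'
#' @param sites annotated [SiteCalls-class] (region column filled).
#' @param genome a `DNAStringSet`.
#' @param models a [GeneModels-class].
#' @param w half-window width (default 3).
#' @param lambda pseudocount (default 1).
#' @param seed seed for the random controls.
#' @return named list of strata; each element is a list with `observed` and
#'   `control` [ContextProfile-class] objects.
#' @export
stratifiedProfiles <- function(sites, genome, models, w = 3L, lambda = 1,
                               seed = NULL) {
  s <- if (is(sites, "SiteCalls")) siteTable(sites) else as.data.frame(sites)
  if (any(is.na(s$region)))
    stop("sites must be annotated before stratified profiling")
  grp <- s$region
  grp[grp %in% c("utr5", "utr3")] <- "utr"
  strata <- list(all = rep(TRUE, nrow(s)),
                 cds_exon = grp == "cds_exon",
                 intron = grp == "intron",
                 utr = grp == "utr")
  out <- list()
  for (lab in names(strata)) {
    sub <- s[strata[[lab]], , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("stratum '", lab, "' has no sites; profile omitted")
      next
    }
    obs <- probabilityMatrix(contextCounts(sub, genome, w), lambda)
    ctrlStrata <- if (lab == "all") {
      tb <- table(grp[strata[[lab]]])
      tb <- tb[names(tb) %in% c("cds_exon", "intron", "utr", "noncoding_exon")]
      if (length(tb) == 0L) c(cds_exon = nrow(sub)) else tb
    } else setNames(nrow(sub), lab)
    ctrlStrata <- setNames(as.integer(ctrlStrata), names(ctrlStrata))
    rnd <- sampleRandomAdenosines(genome, models, ctrlStrata, seed = seed)
    rnd$strand <- ifelse(rnd$strand == "+", "+", "-")
    ctl <- probabilityMatrix(contextCounts(rnd, genome, w), lambda)
    out[[lab]] <- list(observed = obs, control = ctl)
  }
  out
}
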