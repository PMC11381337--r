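#' @include AllClasses.R
NULL

# run code under a temporary RNG state when seed is given
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.readPileupFields <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE, quote = "",
              colClasses = list(character = c(1, 3, 5, 6), integer = c(2, 4)),
              fill = TRUE, na.strings = NULL)
  if (ncol(dt) < 6L) {
    if (ncol(dt) == 4L && all(dt[[4]] == 0L)) {
      dt[, c("V5", "V6") := list("*", "*")]
    } else {
      stop("malformed pileup: expected 6 tab-separated fields, got ", ncol(dt))
    }
  }
  setnames(dt, 1:6, c("chrom", "pos", "ref", "depth", "bases", "quals"))
  bad <- which(is.na(dt$pos) | is.na(dt$depth) | nchar(dt$ref) != 1L)
  if (length(bad))
    stop("malformed pileup line ", bad[1], " in ", path)
  dt
}

#' Read a pileup file into base calls
#'
#' Parses the samtools 6-column pileup dialect into one decoded base call per
#' aligned, base-called read position. Reference-match symbols ('.' and ',')
#' resolve to the reference base with forward/reverse strand; letter case
#' carries strand for mismatches. Read-start marks (`^` plus mapping-quality
#' character), read-end marks (`$`), indel runs (`+n...`/`-n...`), deletion
#' placeholders (`*`) and reference skips (`<`/`>`) are consumed without
#' emitting calls; qualities (Phred+33 by default) pair positionally with
#' emitted calls only.
#'
#' @param path path to a pileup text file.
#' @param sample optional one-row sample metadata from [sampleMeta()].
#' @param phredOffset quality character encoding offset (default 33).
#' @return a [PileupCalls-class] object.
#' @export
readPileup <- function(path, sample = NULL, phredOffset = 33L) {
  dt <- .readPileupFields(path)
  dec <- decodePileupCpp(dt$bases, dt$quals, dt$ref, dt$depth,
                         as.integer(phredOffset))
  calls <- data.table(chrom = dt$chrom[dec$line], pos = dt$pos[dec$line],
                      ref = toupper(dt$ref)[dec$line], nuc = dec$nuc,
                      strand = dec$strand, qual = dec$qual)
  depth <- integer(nrow(dt))
  tabl <- tabulate(dec$line, nbins = nrow(dt))
  positions <- data.table(chrom = dt$chrom, pos = dt$pos,
                          ref = toupper(dt$ref), depth = tabl)
  new("PileupCalls", calls = calls, positions = positions, sample = sample)
}

#' Read a pileup file into quality-filtered counts
#'
#' One-pass decode of a pileup file into per-position counts of
#' quality-passing calls by nucleotide. This is the representation the
#' editing callers operate on; the call-level reader [readPileup()] retains
#' full per-read detail.
#'
#' @inheritParams readPileup
#' @param qMin Phred threshold; calls below it are counted in `nLowQ` only.
#' @return a [PileupCounts-class] object.
#' @export
readPileupCounts <- function(path, sample = NULL, qMin = 25,
                             phredOffset = 33L) {
  dt <- .readPileupFields(path)
  m <- countPileupCpp(dt$bases, dt$quals, dt$ref, dt$depth,
                      as.integer(qMin), as.integer(phredOffset))
  counts <- data.table(chrom = dt$chrom, pos = dt$pos,
                       ref = toupper(dt$ref))
  counts <- cbind(counts, as.data.table(m))
  new("PileupCounts", counts = counts, sample = sample, qMin = qMin)
}

#' Write base calls to a pileup file
#'
#' Inverse of [readPileup()]: encodes call-level data back into the samtools
#' 6-column pileup dialect (reference matches as '.'/',' by strand, mismatch
#' letters cased by strand, qualities Phred+33). Zero-depth positions from
#' the position table are written as `0 * *` columns.
#'
#' @param x a [PileupCalls-class] object.
#' @param path output path.
#' @param phredOffset quality encoding offset (default 33).
#' @return `path`, invisibly.
#' @export
writePileup <- function(x, path, phredOffset = 33L) {
  stopifnot(is(x, "PileupCalls"))
  calls <- as.data.table(pileupCalls(x))
  pdt <- as.data.table(pileupPositions(x))
  if (nrow(calls)) {
    calls[, `:=`(sym = fifelse(nuc == ref,
                               fifelse(strand == "+", ".", ","),
                               fifelse(strand == "+", nuc, tolower(nuc))),
                 qch = sapply(qual + phredOffset, function(q)
                   rawToChar(as.raw(q))))]
    enc <- calls[, .(bases = paste(sym, collapse = ""),
                     quals = paste(qch, collapse = ""),
                     depth = .N), by = .(chrom, pos)]
    out <- merge(pdt[, .(chrom, pos, ref)], enc, by = c("chrom", "pos"),
                 all.x = TRUE, sort = FALSE)
  } else {
    out <- pdt[, .(chrom, pos, ref)]
    out[, `:=`(bases = NA_character_, quals = NA_character_,
               depth = NA_integer_)]
  }
  out[is.na(depth), `:=`(depth = 0L, bases = "*", quals = "*")]
  fwrite(out[, .(chrom, pos, ref, depth, bases, quals)], path, sep = "\t",
         col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merge replicate pileups of one strain and stage
#'
#' Pools call-level pileups position-wise: pooled calls are the concatenation
#' of the replicas' calls, so pooled depth is additive and the pooled target
#' fraction is the coverage-weighted mean of per-replica fractions. Positions
#' present in only some replicas are pooled over the replicas carrying them.
#'
#' @param ... two or more [PileupCalls-class] objects (or a single list).
#' @return a [PileupCalls-class] object with no attached sample metadata.
#' @export
mergeReplicates <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !is(xs[[1]], "PileupCalls"))
    xs <- xs[[1]]
  stopifnot(length(xs) >= 1L, all(vapply(xs, is, TRUE, "PileupCalls")))
  pos <- rbindlist(lapply(xs, pileupPositions))
  refchk <- pos[, .(n = length(unique(ref))), by = .(chrom, pos)]
  if (any(refchk$n > 1L))
    stop("reference base disagreement between replicas at ",
         refchk[n > 1L][1, paste0(chrom, ":", pos)])
  calls <- rbindlist(lapply(xs, pileupCalls))
  posu <- pos[, .(ref = ref[1], depth = sum(depth)), by = .(chrom, pos)]
  setkey(posu, chrom, pos)
  new("PileupCalls", calls = calls, positions = as.data.frame(posu),
      sample = NULL)
}

#' Pool per-position counts across replicates
#'
#' Count-level analogue of [mergeReplicates()]: sums the quality-passing
#' nucleotide counts of several [PileupCounts-class] objects position-wise.
#' All inputs must share the same quality threshold.
#'
#' @param ... two or more [PileupCounts-class] objects (or a single list).
#' @return a pooled [PileupCounts-class] with no attached sample metadata.
#' @export
poolCounts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !is(xs[[1]], "PileupCounts"))
    xs <- xs[[1]]
  stopifnot(length(xs) >= 1L, all(vapply(xs, is, TRUE, "PileupCounts")))
  qmins <- unique(vapply(xs, function(x) x@qMin, numeric(1)))
  if (length(qmins) != 1L)
    stop("cannot pool counts filtered at different quality thresholds")
  dt <- rbindlist(lapply(xs, pileupCounts))
  refchk <- dt[, .(n = length(unique(ref))), by = .(chrom, pos)]
  if (any(refchk$n > 1L))
    stop("reference base disagreement between replicas at ",
         refchk[n > 1L][1, paste0(chrom, ":", pos)])
  pooled <- dt[, .(ref = ref[1], A = sum(A), C = sum(C), G = sum(G),
                   T = sum(T), nCalls = sum(nCalls), nLowQ = sum(nLowQ)),
               by = .(chrom, pos)]
  setkey(pooled, chrom, pos)
  new("PileupCounts", counts = as.data.frame(pooled), sample = NULL,
      qMin = qmins)
}

#' Quality-filter decoded calls into per-position counts
#'
#' Converts a call-level pileup into the count representation, dropping calls
#' below the Phred threshold before any fraction is computed.
#'
#' @param x a [PileupCalls-class] object.
#' @param qMin Phred threshold (default 25).
#' @return a [PileupCounts-class] object.
#' @export
qualityFilter <- function(x, qMin = 25) {
  stopifnot(is(x, "PileupCalls"))
  calls <- as.data.table(pileupCalls(x))
  pdt <- as.data.table(pileupPositions(x))
  if (nrow(calls)) {
    agg <- calls[, .(A = sum(nuc == "A" & qual >= qMin),
                     C = sum(nuc == "C" & qual >= qMin),
                     G = sum(nuc == "G" & qual >= qMin),
                     T = sum(nuc == "T" & qual >= qMin),
                     nCalls = .N,
                     nLowQ = sum(qual < qMin)), by = .(chrom, pos)]
    counts <- merge(pdt[, .(chrom, pos, ref)], agg, by = c("chrom", "pos"),
                    all.x = TRUE, sort = FALSE)
    for (cl in c(.NUCS, "nCalls", "nLowQ"))
      counts[is.na(get(cl)), (cl) := 0L]
  } else {
    counts <- pdt[, .(chrom, pos, ref)]
    counts[, (c(.NUCS, "nCalls", "nLowQ")) := 0L]
  }
  new("PileupCounts", counts = as.data.frame(counts), sample = x@sample,
      qMin = qMin)
}
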