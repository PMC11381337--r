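# Shared fixture builders and independent oracles. Oracles re-implement the
# printed calling criteria directly from counts, independent of the package's
# decode/count code paths.

NUCS <- c("A", "C", "G", "T")

writePileupLines <- function(lines) {
  tf <- tempfile(fileext = ".pileup")
  writeLines(lines, tf)
  tf
}

# random call-level pileup over a handful of positions
randomPileupCalls <- function(nPos = 5, maxDepth = 10) {
  pos <- sort(sample.int(1e4, nPos))
  ref <- sample(NUCS, nPos, replace = TRUE)
  calls <- do.call(rbind, lapply(seq_len(nPos), function(i) {
    d <- sample(0:maxDepth, 1)
    if (d == 0) return(NULL)
    data.frame(chrom = "chrT", pos = pos[i], ref = ref[i],
               nuc = sample(NUCS, d, replace = TRUE,
                            prob = ifelse(NUCS == ref[i], 5, 1)),
               strand = sample(c("+", "-"), d, replace = TRUE),
               qual = sample(0:60, d, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(calls))
    calls <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), nuc = character(),
                        strand = character(), qual = integer(),
                        stringsAsFactors = FALSE)
  positions <- data.frame(chrom = "chrT", pos = pos, ref = ref,
                          depth = as.integer(tabulate(match(calls$pos, pos),
                                                      nPos)),
                          stringsAsFactors = FALSE)
  new("PileupCalls", calls = calls, positions = positions, sample = NULL)
}

# brute-force evaluation of the catalogued-site criteria from raw counts
# (target >= 1% of quality-passing depth, all other mismatches together
# <= 1%); returns "edited" / "not_edited" / "not_expressed"
oracleKnownCall <- function(cnt, ref, thetaSite = 0.01, thetaOther = 0.01) {
  depth <- sum(cnt)
  if (depth == 0) return("not_expressed")
  targetNuc <- c(A = "G", T = "C")[[ref]]
  target <- cnt[[targetNuc]]
  others <- depth - cnt[[ref]] - target
  if (target / depth >= thetaSite && others / depth <= thetaOther)
    "edited" else "not_edited"
}

# brute-force evaluation of the de-novo candidate criteria: most abundant
# mismatch with >= kMin reads, >= thetaDn of depth, all other mismatches
# each <= thetaOther; ties resolved in A < C < G < T order
oracleCandidate <- function(cnt, ref, kMin = 2, thetaDn = 0.05,
                            thetaOther = 0.01) {
  depth <- sum(cnt)
  if (depth == 0) return(NULL)
  mm <- cnt[setdiff(NUCS, ref)]
  m <- names(mm)[which.max(mm)]      # which.max takes the first on ties
  if (mm[[m]] < kMin) return(NULL)
  if (mm[[m]] / depth < thetaDn) return(NULL)
  rest <- mm[names(mm) != m]
  if (any(rest / depth > thetaOther)) return(NULL)
  list(alt = m, count = mm[[m]], depth = depth)
}

# all count compositions (nA, nC, nG, nT) with total depth <= maxDepth
allCompositions <- function(maxDepth) {
  grid <- expand.grid(A = 0:maxDepth, C = 0:maxDepth, G = 0:maxDepth,
                      T = 0:maxDepth)
  grid[rowSums(grid) <= maxDepth, , drop = FALSE]
}

# PileupCounts object from a single-position count vector
countsFromVector <- function(cnt, ref, qMin = 25) {
  df <- data.frame(chrom = "chrT", pos = 100L, ref = ref,
                   A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]],
                   T = cnt[["T"]], nCalls = sum(cnt), nLowQ = 0L,
                   stringsAsFactors = FALSE)
  new("PileupCounts", counts = df, sample = NULL, qMin = qMin)
}

# hand-built two-exon plus/minus gene pair on a known sequence
handGenomeModels <- function() {
  set.seed(77)
  seqs <- paste(sample(NUCS, 2000, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrH = seqs))
  tab <- data.frame(
    chrom = "chrH",
    start = c(101, 301, 150, 301, 701, 901, 721, 901),
    end   = c(200, 400, 200, 350, 800, 1000, 800, 980),
    strand = c("+", "+", "+", "+", "-", "-", "-", "-"),
    type = c("exon", "exon", "CDS", "CDS", "exon", "exon", "CDS", "CDS"),
    gene_id = c(rep("gPlus", 4), rep("gMinus", 4)),
    transcript_id = c(rep("gPlus.1", 4), rep("gMinus.1", 4)),
    stringsAsFactors = FALSE)
  list(genome = genome, models = geneModelsFromTable(tab))
}

# independent Welch t-test from the closed-form formulas
oracleWelch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# exact upper-tail hypergeometric by combinatorial enumeration
oracleHyper <- function(nA, nB, k, N) {
  ks <- k:min(nA, nB)
  sum(choose(nA, ks) * choose(N - nA, nB - ks)) / choose(N, nB)
}
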