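test_that("quality filtering drops sub-threshold calls before any fraction", {
  tf <- writePileupLines("chrI\t1005\tA\t8\t..,,GGg.\tIIIII#II")
  ct <- pileupCounts(readPileupCounts(tf, qMin = 25))
  # hand tally: 5 reference A calls, 3 G calls of which one at Q2
  expect_equal(ct$A, 5L)
  expect_equal(ct$G, 2L)
  expect_equal(ct$A + ct$C + ct$G + ct$T, 7L)
  expect_equal(ct$nLowQ, 1L)
  # all calls high quality: unchanged; all low: empty
  ctHi <- pileupCounts(readPileupCounts(
    writePileupLines("chrI\t1\tA\t3\t..G\tIII"), qMin = 25))
  expect_equal(ctHi$A + ctHi$G, 3L)
  ctLo <- pileupCounts(readPileupCounts(
    writePileupLines("chrI\t1\tA\t3\t..G\t555"), qMin = 25))  # Q20
  expect_equal(ctLo$A + ctLo$C + ctLo$G + ctLo$T, 0L)
})

test_that("Phred 24 calls are excluded and Phred 25 included", {
  # '9' = Q24, ':' = Q25
  tf <- writePileupLines("chrI\t10\tA\t4\t..GG\tII9:")
  ct <- pileupCounts(readPileupCounts(tf, qMin = 25))
  expect_equal(ct$G, 1L)   # only the Q25 G survives
  expect_equal(ct$nLowQ, 1L)
})

test_that("known-site calling honors both printed boundaries exactly", {
  cfg <- editingConfig()
  # depth 200: target 2 (exactly 1.0%), others 2 (exactly 1.0%) -> edited
  r <- callKnownSites(countsFromVector(c(A = 196, C = 1, G = 2, T = 1), "A"),
                      data.frame(chrom = "chrT", pos = 100L, ref = "A"), cfg)
  expect_equal(r$table$outcome, "edited")
  expect_equal(siteTable(r$calls)$level, 0.01)
  # others 1.5% -> rejected
  r2 <- callKnownSites(countsFromVector(c(A = 195, C = 3, G = 2, T = 0), "A"),
                       data.frame(chrom = "chrT", pos = 100L, ref = "A"), cfg)
  expect_equal(r2$table$outcome, "not_edited")
  # depth 100, 5 G -> edited at level 0.05
  r3 <- callKnownSites(countsFromVector(c(A = 95, C = 0, G = 5, T = 0), "A"),
                       data.frame(chrom = "chrT", pos = 100L, ref = "A"), cfg)
  expect_equal(siteTable(r3$calls)$level, 0.05)
  # depth 0 -> not expressed, distinct from not edited
  r4 <- callKnownSites(countsFromVector(c(A = 0, C = 0, G = 0, T = 0), "A"),
                       data.frame(chrom = "chrT", pos = 100L, ref = "A"), cfg)
  expect_equal(r4$table$outcome, "not_expressed")
  # minus-strand signature: T reference, C target
  r5 <- callKnownSites(countsFromVector(c(A = 0, C = 4, G = 0, T = 96), "T"),
                       data.frame(chrom = "chrT", pos = 100L, ref = "T"), cfg)
  st <- siteTable(r5$calls)
  expect_equal(st$strand, "-")
  expect_equal(st$change, "T>C")
})

test_that("the editing-null blacklist is strict at 'above 3%'", {
  cat <- data.frame(chrom = "chrT", pos = 100L, ref = "A")
  # 3 of 100 = 3.0%: retained
  bl <- buildAdarBlacklist(countsFromVector(c(A = 97, C = 0, G = 3, T = 0),
                                            "A"), cat)
  expect_false(bl$blacklisted)
  # 31 of 1000 = 3.1%: blacklisted
  bl2 <- buildAdarBlacklist(countsFromVector(c(A = 969, C = 0, G = 31,
                                               T = 0), "A"), cat)
  expect_true(bl2$blacklisted)
  # zero coverage: retained but unassessable
  bl3 <- buildAdarBlacklist(countsFromVector(c(A = 0, C = 0, G = 0, T = 0),
                                             "A"), cat)
  expect_false(bl3$blacklisted)
  expect_true(bl3$unassessable)
  # blacklisted sites are excluded from calling
  r <- callKnownSites(countsFromVector(c(A = 90, C = 0, G = 10, T = 0), "A"),
                      cat, editingConfig(), blacklist = bl2)
  expect_equal(r$table$outcome, "blacklisted")
  expect_equal(length(r$calls), 0L)
})

test_that("replicate merging is depth-additive and fraction-weighted", {
  mkP <- function(lines) readPileup(writePileupLines(lines))
  p1 <- mkP("chrI\t5\tA\t10\t........GG\tIIIIIIIIII")
  p2 <- mkP("chrI\t5\tA\t12\t..........GG\tIIIIIIIIIIII")
  p3 <- mkP("chrI\t5\tA\t8\t.......G\tIIIIIIII")
  m <- mergeReplicates(p1, p2, p3)
  expect_equal(pileupPositions(m)$depth, 30L)
  ct <- pileupCounts(qualityFilter(m, 25))
  expect_equal(ct$G, 5L)
  expect_equal(ct$G / (ct$A + ct$G), (2 + 2 + 1) / 30)
  # missing position in one replica: pool over those present
  p4 <- mkP(c("chrI\t5\tA\t2\t..\tII", "chrI\t6\tC\t3\t,,,\tIII"))
  m2 <- mergeReplicates(p1, p4)
  pos <- pileupPositions(m2)
  expect_equal(pos$depth[pos$pos == 5], 12L)
  expect_equal(pos$depth[pos$pos == 6], 3L)
  # reference disagreement is an error
  pBad <- mkP("chrI\t5\tT\t2\t..\tII")
  expect_error(mergeReplicates(p1, pBad), "disagreement")
  # pooled fraction equals the coverage-weighted mean of replica fractions
  set.seed(11)
  for (i in 1:20) {
    d <- sample(5:40, 3)
    g <- vapply(d, function(x) sample(0:x, 1), integer(1))
    ps <- lapply(seq_len(3), function(j) mkP(sprintf(
      "chrI\t9\tA\t%d\t%s%s\t%s", d[j],
      strrep(".", d[j] - g[j]), strrep("G", g[j]), strrep("I", d[j]))))
    mm <- pileupCounts(qualityFilter(mergeReplicates(ps), 25))
    expect_equal(mm$G / (mm$A + mm$G), sum(g) / sum(d))
  }
})

test_that("gene-level editing pools target and total counts exactly", {
  tab <- data.frame(chrom = "chrT", pos = c(1L, 2L, 3L),
                    ref = "A", nTarget = c(2L, 8L, 0L),
                    nOther = 0L, nTotal = c(100L, 100L, 50L),
                    level = c(0.02, 0.08, 0),
                    outcome = "edited",
                    geneId = c("g1", "g1", "g2"),
                    stringsAsFactors = FALSE)
  g <- geneLevelEditing(tab)
  expect_equal(g$level[g$geneId == "g1"], 10 / 200)
  expect_equal(g$level[g$geneId == "g2"], 0)
  # single site: gene level equals site level
  g1 <- geneLevelEditing(tab[2, ])
  expect_equal(g1$level, 0.08)
  # zero pooled depth: not expressed
  tab0 <- tab; tab0$nTotal <- 0L; tab0$nTarget <- 0L
  g0 <- geneLevelEditing(tab0)
  expect_false(any(g0$expressed))
  expect_true(all(is.na(g0$level)))
})

test_that("the editing matrix is unthresholded and distinguishes non-expression", {
  cat <- data.frame(chrom = "chrT", pos = 100L, ref = "A")
  cl <- list(s1 = countsFromVector(c(A = 49, C = 0, G = 1, T = 0), "A"),
             s2 = countsFromVector(c(A = 0, C = 0, G = 0, T = 0), "A"),
             s3 = countsFromVector(c(A = 400, C = 0, G = 1, T = 0), "A"))
  se <- editingMatrix(cl, cat)
  lvl <- SummarizedExperiment::assay(se, "level")
  expr <- SummarizedExperiment::assay(se, "expressed")
  expect_equal(dim(lvl), c(1L, 3L))
  expect_equal(unname(lvl[1, "s1"]), 0.02)          # below calling threshold, kept
  expect_true(is.na(lvl[1, "s2"]))          # not expressed, not zero
  expect_false(expr[1, "s2"])
  expect_equal(unname(lvl[1, "s3"]), 1 / 401)
})

test_that("threshold monotonicity holds across random columns", {
  set.seed(202)
  cat <- data.frame(chrom = "chrT", pos = 100L, ref = "A")
  for (i in 1:50) {
    cnt <- c(A = sample(0:60, 1), C = sample(0:3, 1), G = sample(0:6, 1),
             T = sample(0:3, 1))
    pc <- countsFromVector(cnt, "A")
    # raising thetaSite never grows the edited set
    ed <- vapply(c(0.01, 0.05, 0.2), function(th)
      callKnownSites(pc, cat, editingConfig(thetaSite = th))$table$outcome ==
        "edited", logical(1))
    expect_true(all(diff(as.integer(ed)) <= 0))
    # raising thetaMut never shrinks the retained (non-blacklisted) set
    bl <- vapply(c(0.0, 0.03, 0.2), function(th)
      buildAdarBlacklist(pc, cat, th)$blacklisted, logical(1))
    expect_true(all(diff(as.integer(bl)) <= 0))
  }
  # raising qMin never increases quality-passing depth
  tf <- writePileupLines("chrI\t10\tA\t6\t...GGG\tI5:9#I")
  d <- vapply(c(0, 15, 25, 41), function(q) {
    ct <- pileupCounts(readPileupCounts(tf, qMin = q))
    ct$A + ct$C + ct$G + ct$T
  }, integer(1))
  expect_true(all(diff(d) <= 0))
})
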