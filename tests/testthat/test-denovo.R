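mkCounts <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = "chrT", pos = r$pos, ref = r$ref,
               A = r$cnt[["A"]], C = r$cnt[["C"]], G = r$cnt[["G"]],
               T = r$cnt[["T"]], nCalls = sum(r$cnt), nLowQ = 0L,
               stringsAsFactors = FALSE)))
  new("PileupCounts", counts = df, sample = NULL, qMin = 25)
}

test_that("genomic-variant subtraction removes masked changes only", {
  pc <- mkCounts(list(
    list(pos = 1005L, ref = "A", cnt = c(A = 10, C = 2, G = 3, T = 0)),
    list(pos = 2000L, ref = "A", cnt = c(A = 10, C = 2, G = 3, T = 0)),
    list(pos = 3000L, ref = "A", cnt = c(A = 10, C = 2, G = 3, T = 0))))
  tf <- tempfile()
  writeLines(c("#chrom\tpos\talt", "chrT\t1005\t", "chrT\t2000\tG"), tf)
  mask <- readVariantMask(tf)
  out <- pileupCounts(subtractGenomicVariants(pc, mask))
  # position-wide mask: all mismatches dropped, reference kept
  expect_equal(unlist(out[out$pos == 1005, c("A", "C", "G", "T")],
                      use.names = FALSE), c(10L, 0L, 0L, 0L))
  # allele mask: only the masked alt dropped
  expect_equal(unlist(out[out$pos == 2000, c("A", "C", "G", "T")],
                      use.names = FALSE), c(10L, 2L, 0L, 0L))
  # unmasked position unchanged
  expect_equal(unlist(out[out$pos == 3000, c("A", "C", "G", "T")],
                      use.names = FALSE), c(10L, 2L, 3L, 0L))
})

test_that("mutant-change subtraction erases any change seen in the editing-null", {
  test <- mkCounts(list(
    list(pos = 10L, ref = "A", cnt = c(A = 50, C = 0, G = 6, T = 0)),
    list(pos = 20L, ref = "A", cnt = c(A = 50, C = 0, G = 6, T = 0)),
    list(pos = 30L, ref = "A", cnt = c(A = 50, C = 0, G = 6, T = 0))))
  adar <- mkCounts(list(
    list(pos = 10L, ref = "A", cnt = c(A = 80, C = 0, G = 1, T = 0)),
    list(pos = 20L, ref = "A", cnt = c(A = 80, C = 2, G = 0, T = 0))))
  out <- pileupCounts(subtractMutantChanges(test, adar))
  expect_equal(out$G[out$pos == 10], 0L)  # one ADAR-null read suffices
  expect_equal(out$G[out$pos == 20], 6L)  # A>C in mutant does not erase A>G
  expect_equal(out$G[out$pos == 30], 6L)  # no ADAR-null coverage: unchanged
  # idempotence
  once <- subtractMutantChanges(test, adar)
  twice <- subtractMutantChanges(once, adar)
  expect_equal(pileupCounts(twice), pileupCounts(once))
})

test_that("candidate calling applies the five printed criteria at their boundaries", {
  cfg <- denovoConfig()
  # depth 40, top change 2 reads = exactly 5%: candidate
  c1 <- callCandidateSites(mkCounts(list(
    list(pos = 1L, ref = "A", cnt = c(A = 38, C = 0, G = 2, T = 0)))), cfg)
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$alt, "G")
  expect_equal(c1$level, 0.05)
  # depth 41, 2 reads = 4.88%: rejected
  c2 <- callCandidateSites(mkCounts(list(
    list(pos = 1L, ref = "A", cnt = c(A = 39, C = 0, G = 2, T = 0)))), cfg)
  expect_equal(nrow(c2), 0L)
  # second change above 1%: rejected
  c3 <- callCandidateSites(mkCounts(list(
    list(pos = 1L, ref = "A", cnt = c(A = 88, C = 2, G = 10, T = 0)))), cfg)
  expect_equal(nrow(c3), 0L)
  # single supporting read: rejected even at high fraction
  c4 <- callCandidateSites(mkCounts(list(
    list(pos = 1L, ref = "A", cnt = c(A = 9, C = 0, G = 1, T = 0)))), cfg)
  expect_equal(nrow(c4), 0L)
  # non-A-to-I top change is still a candidate at this stage
  c5 <- callCandidateSites(mkCounts(list(
    list(pos = 1L, ref = "A", cnt = c(A = 38, C = 2, G = 0, T = 0)))), cfg)
  expect_equal(c5$alt, "C")
})

test_that("tied top changes are logged and cannot satisfy the purity bound", {
  # the runner-up of a tie carries the top count, so the <=1% other-change
  # bound always rejects the position; the tie is still logged
  pc <- mkCounts(list(
    list(pos = 1L, ref = "A", cnt = c(A = 16, C = 2, G = 2, T = 0))))
  expect_warning(cand <- callCandidateSites(pc, denovoConfig()), "tied")
  expect_equal(nrow(cand), 0L)
})

test_that("replica consolidation keeps sites recurring in >= rMin replicas", {
  cand <- function(rep, pos = 5L) data.frame(
    chrom = "chrT", pos = pos, ref = "A", alt = "G", nTarget = 3L,
    nOther = 0L, nTotal = 50L, level = 0.06, replica = rep,
    stringsAsFactors = FALSE)
  # replicas {1,3} of 3: kept
  k <- consolidateReplicas(list(cand(1L), cand(3L)), rMin = 2)
  expect_equal(nrow(k), 1L)
  expect_equal(k$nReplicas, 2L)
  expect_equal(k$nTotal, 100L)
  # replica {2} only: dropped
  expect_equal(nrow(consolidateReplicas(list(cand(2L)), rMin = 2)), 0L)
  # all three: kept
  expect_equal(nrow(consolidateReplicas(list(cand(1L), cand(2L), cand(3L)),
                                        rMin = 2)), 1L)
  # same position, different change does not pool
  other <- cand(2L); other$alt <- "T"
  expect_equal(nrow(consolidateReplicas(list(cand(1L), other), rMin = 2)), 0L)
  # raising rMin never grows the set
  sets <- vapply(1:3, function(r)
    nrow(consolidateReplicas(list(cand(1L), cand(3L)), rMin = r)),
    integer(1))
  expect_true(all(diff(sets) <= 0))
})

test_that("novelty classification splits known / de-novo and filters A-to-I", {
  cons <- data.frame(
    chrom = "chrT", pos = c(5L, 9L, 12L), ref = c("A", "A", "A"),
    alt = c("G", "G", "C"), nReplicas = 2L, nTarget = 4L, nOther = 0L,
    nTotal = 60L, level = 4 / 60, stringsAsFactors = FALSE)
  wt <- data.frame(chrom = "chrT", pos = 5L)
  res <- classifyNovelty(cons, wt)
  st <- siteTable(res$calls)
  expect_equal(st$status[st$pos == 5], "known")
  expect_equal(st$status[st$pos == 9], "de_novo")
  # A>C survives the criteria but goes to diagnostics, not the report
  expect_false(12 %in% st$pos)
  expect_equal(res$diagnostics$pos, 12L)
  # T>C maps to the minus strand in the report
  consM <- data.frame(chrom = "chrT", pos = 7L, ref = "T", alt = "C",
                      nReplicas = 2L, nTarget = 4L, nOther = 0L,
                      nTotal = 60L, level = 4 / 60,
                      stringsAsFactors = FALSE)
  stM <- siteTable(classifyNovelty(consM, NULL)$calls)
  expect_equal(stM$strand, "-")
  expect_equal(stM$change, "T>C")
})
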