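smallProfile <- function(...) {
  simProfile(nGenes = 20L, nSitesWT = 30L, nSitesAdbp1 = 30L,
             nArtifact = 5L, nSNPs = 15L, nDNAVariants = 15L,
             stages = "embryo", ...)
}

test_that("genome and model generation is seed-deterministic and well-formed", {
  gm1 <- makeGenomeAndModels(nGenes = 20, seed = 3)
  gm2 <- makeGenomeAndModels(nGenes = 20, seed = 3)
  expect_identical(as.character(gm1$genome), as.character(gm2$genome))
  expect_identical(geneFeatures(gm1$models), geneFeatures(gm2$models))
  gm3 <- makeGenomeAndModels(nGenes = 20, seed = 4)
  expect_false(identical(as.character(gm1$genome),
                         as.character(gm3$genome)))
  # intron count = exon count - 1 per transcript
  ex <- edicall:::transcriptExons(gm1$models)
  f <- geneFeatures(gm1$models)
  intr <- data.frame(tx = S4Vectors::mcols(f)$transcript_id[
    S4Vectors::mcols(f)$type == "intron"])
  nEx <- table(ex$transcript_id)
  nIn <- table(factor(intr$tx, levels = names(nEx)))
  expect_equal(as.integer(nIn), as.integer(nEx) - 1L)
  # GC content within generator bounds
  gc <- sum(Biostrings::letterFrequency(gm1$genome, c("G", "C"))) /
    sum(Biostrings::width(gm1$genome))
  expect_gt(gc, 0.3); expect_lt(gc, 0.7)
})

test_that("planned truth sites follow the strain region mixes", {
  prof <- simProfile(nGenes = 80L, nSitesWT = 200L, nSitesAdbp1 = 200L,
                     stages = "embryo")
  gm <- makeGenomeAndModels(prof$nGenes, seed = 21)
  plan <- planTruthSites(gm$genome, gm$models, prof, seed = 22)
  truth <- plan$truth
  wt <- truth[truth$level_wild_type > 0, ]
  ab <- truth[truth$level_adbp1_mutant > 0, ]
  ar <- truth[truth$level_adar_null > 0, ]
  expect_equal(nrow(wt), 200L)
  # ADAR-null has artifact changes but zero true editing with the WT/adbp1
  # strains, and the three site classes are disjoint
  expect_equal(nrow(ar), prof$nArtifact)
  expect_true(all(ar$level_wild_type == 0 & ar$level_adbp1_mutant == 0))
  key <- paste(truth$chrom, truth$pos)
  expect_false(anyDuplicated(key) > 0)
  # region mixes within 95% binomial CI of the injected fractions
  frIntron <- mean(wt$region == "intron")
  expect_lt(abs(frIntron - 0.8), 1.96 * sqrt(0.8 * 0.2 / nrow(wt)))
  frExon <- mean(ab$region == "cds_exon")
  expect_lt(abs(frExon - 0.655), 1.96 * sqrt(0.655 * 0.345 / nrow(ab)))
  # all sites are adenosines on their edited strand
  base <- vapply(seq_len(nrow(truth)), function(i)
    as.character(Biostrings::subseq(gm$genome[[truth$chrom[i]]],
                                    truth$pos[i], truth$pos[i])),
    character(1))
  expect_true(all(base == truth$ref))
  expect_true(all(truth$ref[truth$strand == "+"] == "A"))
  expect_true(all(truth$ref[truth$strand == "-"] == "T"))
  # variants disjoint from sites
  vkey <- paste(c(plan$snps$chrom, plan$dnaVariants$chrom),
                c(plan$snps$pos, plan$dnaVariants$pos))
  expect_equal(length(intersect(vkey, key)), 0L)
})

test_that("simulated pileups are seed-deterministic with faithful site levels", {
  prof <- smallProfile()
  gm <- makeGenomeAndModels(prof$nGenes, seed = 31)
  plan <- planTruthSites(gm$genome, gm$models, prof, seed = 32)
  sm <- sampleMeta("wild_type", "embryo", 1)
  f1 <- tempfile(); f2 <- tempfile()
  simulateSamplePileup(gm$genome, gm$models, plan, prof, sm, f1, seed = 33)
  simulateSamplePileup(gm$genome, gm$models, plan, prof, sm, f2, seed = 33)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile()
  simulateSamplePileup(gm$genome, gm$models, plan, prof, sm, f3, seed = 34)
  expect_false(identical(readLines(f1), readLines(f3)))
  # ADAR-null sample shows only error-level changes at WT-only truth sites
  fAdar <- tempfile()
  simulateSamplePileup(gm$genome, gm$models, plan, prof,
                       sampleMeta("adar_null", "embryo", 1), fAdar,
                       seed = 35)
  ct <- data.table::as.data.table(pileupCounts(readPileupCounts(fAdar,
                                                                qMin = 0)))
  wt <- data.table::as.data.table(plan$truth)[level_wild_type > 0]
  j <- ct[wt, on = c("chrom", "pos"), nomatch = 0L]
  tgt <- ifelse(j$ref == "A", j$G, j$C)
  expect_lt(mean(tgt / (j$A + j$C + j$G + j$T)), 0.005)
})

test_that("injected editing levels converge to the draw at extreme depth", {
  prof <- simProfile(nGenes = 3L, nSitesWT = 5L, nSitesAdbp1 = 2L,
                     nArtifact = 1L, nSNPs = 2L, nDNAVariants = 2L,
                     coverageMean = 10000, coverageSize = 50,
                     stages = "embryo")
  gm <- makeGenomeAndModels(prof$nGenes, seed = 41)
  plan <- planTruthSites(gm$genome, gm$models, prof, seed = 42)
  f <- tempfile()
  simulateSamplePileup(gm$genome, gm$models, plan, prof,
                       sampleMeta("wild_type", "embryo", 1), f, seed = 43)
  ct <- data.table::as.data.table(pileupCounts(readPileupCounts(f, qMin = 0)))
  wt <- data.table::as.data.table(plan$truth)[level_wild_type > 0]
  j <- ct[wt, on = c("chrom", "pos"), nomatch = 0L]
  depth <- j$A + j$C + j$G + j$T
  obs <- ifelse(j$ref == "A", j$G, j$C) / depth
  se <- sqrt(j$level_wild_type * (1 - j$level_wild_type) / depth)
  expect_true(all(abs(obs - j$level_wild_type) <= 3 * se + 3 * 0.001))
})

test_that("background mismatch rate matches the error model", {
  prof <- smallProfile()
  gm <- makeGenomeAndModels(prof$nGenes, seed = 51)
  plan <- planTruthSites(gm$genome, gm$models, prof, seed = 52)
  f <- tempfile()
  simulateSamplePileup(gm$genome, gm$models, plan, prof,
                       sampleMeta("wild_type", "embryo", 1), f, seed = 53)
  ct <- data.table::as.data.table(pileupCounts(readPileupCounts(f, qMin = 0)))
  truth <- data.table::as.data.table(plan$truth)
  vkey <- rbind(data.table::as.data.table(plan$snps)[, .(chrom, pos)],
                data.table::as.data.table(plan$dnaVariants)[, .(chrom, pos)])
  clean <- ct[!truth, on = c("chrom", "pos")][!vkey, on = c("chrom", "pos")]
  mm <- with(clean, A + C + G + T -
               ifelse(ref == "A", A, ifelse(ref == "C", C,
                      ifelse(ref == "G", G, T))))
  rate <- sum(mm) / sum(clean$A + clean$C + clean$G + clean$T)
  expect_gt(rate, 0.0008)
  expect_lt(rate, 0.0012)
})

test_that("fixture directories are complete and reproducible", {
  d1 <- file.path(tempdir(), "fxA"); d2 <- file.path(tempdir(), "fxB")
  unlink(c(d1, d2), recursive = TRUE)
  prof <- simProfile(nGenes = 8L, nSitesWT = 10L, nSitesAdbp1 = 10L,
                     nArtifact = 3L, nSNPs = 5L, nDNAVariants = 5L)
  emitSampleSet(d1, prof, seed = 61)
  emitSampleSet(d2, prof, seed = 61)
  # 3 strains x 2 stages x 3 replicas = 18 pileups
  expect_equal(length(list.files(file.path(d1, "pileups"))), 18L)
  digest <- function(d) tools::md5sum(list.files(d, recursive = TRUE,
                                                 full.names = TRUE))
  expect_identical(unname(digest(d1)), unname(digest(d2)))
  # truth and catalogue agree on wild-type site coordinates
  truth <- edicall:::.readHashTSV(file.path(d1, "truth.tsv"))
  known <- edicall:::.readHashTSV(file.path(d1, "known_sites.tsv"))
  expect_setequal(paste(known$chrom, known$pos),
                  paste(truth$chrom, truth$pos)[truth$level_wild_type > 0])
  unlink(c(d1, d2), recursive = TRUE)
})
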