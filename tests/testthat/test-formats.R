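test_that("pileup decode resolves bases, strands and qualities", {
  tf <- writePileupLines(c(
    "chrI\t1005\tA\t8\t..,,GGg.\tIIIII#II",
    "chrI\t7\tT\t0\t*\t*",
    "chrI\t9\tA\t2\t.^].\tII"))
  p <- readPileup(tf)
  calls <- pileupCalls(p)
  c1 <- calls[calls$pos == 1005, ]
  expect_equal(nrow(c1), 8L)
  expect_equal(sum(c1$nuc == "A"), 5L)  # 3 dots + 2 commas
  expect_equal(sum(c1$nuc == "G"), 3L)
  expect_equal(sum(c1$nuc == "A" & c1$strand == "-"), 2L)
  expect_equal(sum(c1$nuc == "G" & c1$strand == "-"), 1L)
  expect_equal(sort(c1$qual), c(2, rep(40, 7)))  # '#' pairs with the 6th call
  expect_equal(c1$qual[c1$nuc == "G" & c1$strand == "+"], c(40, 2))
  # zero-depth column: no calls, position retained
  expect_equal(nrow(calls[calls$pos == 7, ]), 0L)
  expect_equal(pileupPositions(p)$depth, c(8L, 0L, 2L))
  # '^]' consumed as read-start + mapping quality, never as a base
  c9 <- calls[calls$pos == 9, ]
  expect_equal(c9$nuc, c("A", "A"))
  expect_equal(c9$qual, c(40, 40))
})

test_that("indels, deletion placeholders and reference skips are consumed", {
  tf <- writePileupLines(c(
    "chrI\t50\tA\t6\t.+2AG.-1t.*<>\tIIIIII",
    "chrI\t60\tC\t3\t.$,N\tII#"))
  p <- readPileup(tf)
  calls <- pileupCalls(p)
  c50 <- calls[calls$pos == 50, ]
  # 3 reference-matching calls; '*', '<', '>' consume qualities silently
  expect_equal(nrow(c50), 3L)
  expect_true(all(c50$nuc == "A"))
  c60 <- calls[calls$pos == 60, ]
  # N consumes its quality but emits nothing
  expect_equal(nrow(c60), 2L)
  expect_equal(c60$strand, c("+", "-"))
})

test_that("malformed pileup lines raise errors naming the line", {
  tf <- writePileupLines("chrI\t10\tA\t3\t...\tII")  # quality too short
  expect_error(readPileup(tf), "line 1")
  tf2 <- writePileupLines(c("chrI\t10\tA\t1\t.\tI",
                            "chrI\t11\tA\t2\t.x\tII"))
  expect_error(readPileup(tf2), "unknown base symbol")
  tf3 <- writePileupLines("chrI\t10\tA\t2\t..\tIII")  # quality too long
  expect_error(readPileup(tf3), "mismatch")
})

test_that("counting decode equals filtering the full decode", {
  set.seed(42)
  for (i in 1:20) {
    p <- randomPileupCalls(nPos = 6, maxDepth = 12)
    tf <- tempfile()
    writePileup(p, tf)
    viaCounts <- pileupCounts(readPileupCounts(tf, qMin = 25))
    viaCalls <- pileupCounts(qualityFilter(readPileup(tf), qMin = 25))
    setkeyv(data.table::setDT(viaCounts), c("chrom", "pos"))
    setkeyv(data.table::setDT(viaCalls), c("chrom", "pos"))
    expect_equal(as.data.frame(viaCounts), as.data.frame(viaCalls))
  }
})

test_that("pileup write -> read reproduces the call multiset", {
  set.seed(7)
  for (i in 1:50) {
    p <- randomPileupCalls(nPos = 4, maxDepth = 8)
    tf <- tempfile()
    writePileup(p, tf)
    p2 <- readPileup(tf)
    srt <- function(x) x[order(x$pos, x$nuc, x$strand, x$qual), ,
                         drop = FALSE]
    expect_equal(srt(pileupCalls(p2)), srt(pileupCalls(p)),
                 ignore_attr = TRUE)
    expect_equal(p2@positions$depth, p@positions$depth)
  }
})

test_that("site tables round-trip exactly, including empty and boundary levels", {
  s <- SiteCalls(data.frame(
    chrom = c("chrI", "chrI", "chrII"), pos = c(10L, 20L, 30L),
    strand = c("+", "-", "+"), ref = c("A", "T", "A"),
    change = c("A>G", "T>C", "A>G"),
    level = c(5 / 210, 1, 2 / 84),
    nTarget = c(5L, 7L, 2L), nOther = c(1L, 0L, 0L),
    nTotal = c(210L, 7L, 84L),
    region = c("intron", "cds_exon", NA), geneId = c("g1", "g2", NA),
    status = c("known", "de_novo", "known")))
  tf <- tempfile()
  writeSiteTable(s, tf)
  s2 <- readSiteTable(tf)
  expect_equal(siteTable(s2), siteTable(s))
  # empty table
  tf2 <- tempfile()
  writeSiteTable(SiteCalls(), tf2)
  expect_equal(nrow(siteTable(readSiteTable(tf2))), 0L)
  # duplicates rejected unless allowed
  dup <- siteTable(s)[c(1, 1, 2), ]
  tf3 <- tempfile()
  writeSiteTable(SiteCalls(dup), tf3)
  expect_error(readSiteTable(tf3), "duplicate")
  expect_equal(length(readSiteTable(tf3, allowDuplicates = TRUE)), 3L)
})

test_that("variant masks support position and allele lookups", {
  tf <- tempfile()
  writeLines(c("#chrom\tpos\talt", "chrI\t1005\t", "chrI\t2000\tG"), tf)
  m <- readVariantMask(tf)
  expect_true(maskContains(m, "chrI", 1005))
  expect_true(maskContains(m, "chrI", 1005, "C"))   # position-wide
  expect_false(maskContains(m, "chrI", 1006))
  expect_true(maskContains(m, "chrI", 2000, "G"))
  expect_false(maskContains(m, "chrI", 2000, "C"))  # allele-specific
})

test_that("count tables enforce integer counts and unique genes", {
  m <- matrix(1:12, 3, 4,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  tf <- tempfile()
  writeCountsTable(m, tf)
  expect_identical(readCountsTable(tf), m)
  writeLines(c("#gene_id\ts1", "g1\t1.5"), tf)
  expect_error(readCountsTable(tf), "integer")
  writeLines(c("#gene_id\ts1", "g1\t1", "g1\t2"), tf)
  expect_error(readCountsTable(tf), "duplicate")
})

test_that("genome FASTA reading preserves sequences and rejects name clashes", {
  tf <- tempfile(fileext = ".fa")
  writeLines(c(">s1 descr", "ACGTACGT", ">s2", "GGGCCC"), tf)
  g <- readGenome(tf)
  expect_equal(names(g), c("s1", "s2"))
  expect_equal(as.integer(Biostrings::width(g)), c(8L, 6L))
  writeLines(c(">s1", "AC", ">s1", "GT"), tf)
  expect_error(readGenome(tf), "duplicate")
})

test_that("introns are the gaps between consecutive exons", {
  tab <- data.frame(chrom = "c1", start = c(100, 301), end = c(200, 400),
                    strand = "+", type = "exon", gene_id = "g",
                    transcript_id = "t", stringsAsFactors = FALSE)
  gm <- geneModelsFromTable(tab)
  f <- geneFeatures(gm)
  intr <- f[mcols(f)$type == "intron"]
  expect_equal(GenomicRanges::start(intr), 201)
  expect_equal(GenomicRanges::end(intr), 300)
  # single-exon gene: no introns
  gm1 <- geneModelsFromTable(tab[1, ])
  expect_equal(sum(mcols(geneFeatures(gm1))$type == "intron"), 0L)
  # exon union + intron union tile the transcript span disjointly
  ex <- f[mcols(f)$type != "intron"]
  covered <- GenomicRanges::reduce(c(GenomicRanges::granges(ex),
                                     GenomicRanges::granges(intr)))
  expect_equal(GenomicRanges::start(covered), 100)
  expect_equal(GenomicRanges::end(covered), 400)
})

test_that("minus-strand UTRs are assigned by transcriptional orientation", {
  # minus-strand: the 5' UTR is genomically rightmost
  tab <- data.frame(chrom = "c1", start = c(100, 301, 150, 301),
                    end = c(200, 400, 200, 350),
                    strand = "-", type = c("exon", "exon", "CDS", "CDS"),
                    gene_id = "g", transcript_id = "t",
                    stringsAsFactors = FALSE)
  gm <- geneModelsFromTable(tab)
  f <- geneFeatures(gm)
  u5 <- f[mcols(f)$type == "utr5"]
  u3 <- f[mcols(f)$type == "utr3"]
  expect_equal(GenomicRanges::start(u5), 351)
  expect_equal(GenomicRanges::end(u5), 400)
  expect_equal(GenomicRanges::start(u3), 100)
  expect_equal(GenomicRanges::end(u3), 149)
})

test_that("gene model GFF3 writing and reading round-trips the features", {
  hm <- handGenomeModels()
  tf <- tempfile(fileext = ".gff3")
  writeGeneModels(hm$models, tf)
  gm2 <- readGeneModels(tf)
  f1 <- geneFeatures(hm$models)
  f2 <- geneFeatures(gm2)
  key <- function(f) paste(GenomicRanges::seqnames(f),
                           GenomicRanges::start(f), GenomicRanges::end(f),
                           GenomicRanges::strand(f), mcols(f)$type,
                           mcols(f)$gene_id)
  expect_setequal(key(f2), key(f1))
  # exon outside its transcript span is rejected
  bad <- c("##gff-version 3",
           "c1\tx\tgene\t100\t200\t.\t+\t.\tID=g1",
           "c1\tx\tmRNA\t100\t200\t.\t+\t.\tID=t1;Parent=g1",
           "c1\tx\texon\t100\t250\t.\t+\t.\tParent=t1")
  tf2 <- tempfile(fileext = ".gff3")
  writeLines(bad, tf2)
  expect_error(readGeneModels(tf2), "transcript span")
})
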