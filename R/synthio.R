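#' @include context.R denovo.R
NULL

#' Synthetic study design profile
#'
#' Parameters of the synthetic-data generator, which emulates the
#' statistical structure of a three-strain (wild-type, adbp-1 mutant,
#' ADAR-null), two-stage, three-replicate RNA-seq editing study at desk
#' scale. Defaults encode the study conditions: intron-biased editing in
#' wild-type (80\% of sites), exon-biased editing in the adbp-1 mutant
#' (65.5\%), an editing-free ADAR-null strain carrying artifact changes,
#' coverage-dependent binomial edited-read counts, Phred-distributed base
#' qualities, sequencing errors and genomic variants.
#'
#' @param nGenes number of genes in the synthetic genome (default 150).
#' @param lncFraction fraction of genes that are lncRNA (default 0.15).
#' @param nSitesWT,nSitesAdbp1 true editing sites per strain (default 200).
#' @param regionMixWT,regionMixAdbp1 named region mixes (cds_exon, intron,
#'   utr) for true sites; defaults intron 0.80 for wild-type and cds_exon
#'   0.655 for the adbp-1 mutant.
#' @param levelRange editing-level range, uniform per site (default
#'   0.05-0.5).
#' @param nArtifact ADAR-null-only artifact change sites (default 20).
#' @param artifactLevelRange artifact change levels (default 0.05-0.10).
#' @param coverageMean,coverageSize negative-binomial coverage model
#'   (default mean 60, size 10).
#' @param errorRate per-base sequencing error rate (default 0.001).
#' @param qualHigh,qualLow,lowQualFraction base-quality model: Phred
#'   `qualHigh` with a `lowQualFraction` mass at `qualLow` (defaults 37, 15,
#'   0.05), exercising the Phred >= 25 filter.
#' @param nReplicas biological replicas per strain and stage (default 3).
#' @param stages developmental stages to simulate.
#' @param stageLevelMultiplier multiplier applied to editing levels at the
#'   L4 stage (default 1, i.e. shared levels).
#' @param nSNPs,nDNAVariants genomic variant counts for the SNP catalogue
#'   (allele-specific mask) and DNA-seq variants (position-wide mask).
#' @return a `simProfile` list.
#' @export
simProfile <- function(nGenes = 150L, lncFraction = 0.15,
                       nSitesWT = 200L, nSitesAdbp1 = 200L,
                       regionMixWT = c(intron = 0.80, cds_exon = 0.10,
                                       utr = 0.10),
                       regionMixAdbp1 = c(cds_exon = 0.655, intron = 0.115,
                                          utr = 0.23),
                       levelRange = c(0.05, 0.5),
                       nArtifact = 20L, artifactLevelRange = c(0.05, 0.10),
                       coverageMean = 60, coverageSize = 10,
                       errorRate = 0.001,
                       qualHigh = 37L, qualLow = 15L, lowQualFraction = 0.05,
                       nReplicas = 3L, stages = c("embryo", "L4"),
                       stageLevelMultiplier = 1.0,
                       nSNPs = 150L, nDNAVariants = 150L) {
  p <- as.list(environment())
  stopifnot(abs(sum(regionMixWT) - 1) < 1e-9,
            abs(sum(regionMixAdbp1) - 1) < 1e-9,
            errorRate >= 0, errorRate <= 1,
            lowQualFraction >= 0, lowQualFraction <= 1,
            nReplicas >= 1L, all(stages %in% .STAGES))
  structure(p, class = "simProfile")
}

#' Generate a synthetic genome and gene models
#'
#' Random-sequence genome (two chromosomes) with multi-exon genes on both
#' strands, derived introns and UTRs and a lncRNA fraction. Deterministic
#' given the seed.
#'
#' @param nGenes number of genes.
#' @param lncFraction fraction of lncRNA genes.
#' @param seed integer seed.
#' @return list with `genome` (DNAStringSet) and `models`
#'   ([GeneModels-class]).
#' @export
makeGenomeAndModels <- function(nGenes = 150L, lncFraction = 0.15,
                                seed = NULL) {
  withSeed(seed, {
    chroms <- c("chrI_sim", "chrII_sim")
    geneChrom <- rep(chroms, length.out = nGenes)
    feat <- list()
    cursor <- setNames(rep(1L, length(chroms)), chroms)
    for (g in seq_len(nGenes)) {
      ch <- geneChrom[g]
      cursor[ch] <- cursor[ch] + sample(200:800, 1L)
      strand <- sample(c("+", "-"), 1L)
      lnc <- runif(1) < lncFraction
      nEx <- if (lnc) sample(1:3, 1L) else sample(2:5, 1L)
      exLens <- sample(120:400, nEx, replace = TRUE)
      inLens <- if (nEx > 1L) sample(60:300, nEx - 1L, replace = TRUE)
                else integer(0)
      starts <- integer(nEx); ends <- integer(nEx)
      p <- cursor[ch]
      for (e in seq_len(nEx)) {
        starts[e] <- p
        ends[e] <- p + exLens[e] - 1L
        p <- ends[e] + (if (e < nEx) inLens[e] else 0L) + 1L
      }
      cursor[ch] <- ends[nEx] + 1L
      gid <- sprintf("gene%04d", g)
      tid <- paste0(gid, ".1")
      rows <- data.table(chrom = ch, start = starts, end = ends,
                         strand = strand, type = "exon", gene_id = gid,
                         transcript_id = tid,
                         biotype = if (lnc) "lncRNA" else "coding")
      if (!lnc) {
        txLen <- sum(exLens)
        u5 <- sample(30:min(120L, max(31L, txLen %/% 6L)), 1L)
        u3 <- sample(50:min(250L, max(51L, txLen %/% 4L)), 1L)
        if (txLen - u5 - u3 < 60L) { u5 <- 30L; u3 <- 50L }
        cdsTx <- c(u5 + 1L, txLen - u3)  # transcript coordinates
        ## map transcript interval to genomic CDS pieces
        exOrd <- if (strand == "+") seq_len(nEx) else rev(seq_len(nEx))
        off <- 0L
        cdsRows <- list()
        for (e in exOrd) {
          w <- exLens[e]
          lo <- max(cdsTx[1], off + 1L); hi <- min(cdsTx[2], off + w)
          if (lo <= hi) {
            if (strand == "+") {
              gs <- starts[e] + (lo - off - 1L); ge <- starts[e] + (hi - off - 1L)
            } else {
              ge <- ends[e] - (lo - off - 1L); gs <- ends[e] - (hi - off - 1L)
            }
            cdsRows[[length(cdsRows) + 1L]] <-
              data.table(chrom = ch, start = gs, end = ge, strand = strand,
                         type = "CDS", gene_id = gid, transcript_id = tid,
                         biotype = "coding")
          }
          off <- off + w
        }
        rows <- rbind(rows, rbindlist(cdsRows))
      }
      feat[[g]] <- rows
    }
    tab <- rbindlist(feat)
    lens <- tab[, .(len = max(end) + 400L), by = chrom]
    genome <- DNAStringSet(vapply(chroms, function(ch) {
      L <- lens[chrom == ch, len]
      paste(sample(.NUCS, L, replace = TRUE), collapse = "")
    }, character(1)))
    names(genome) <- chroms
    list(genome = genome, models = geneModelsFromTable(tab))
  })
}

#' Plan ground-truth editing sites
#'
#' Draws true editing sites per strain according to the profile's region
#' mixes, always at an adenosine on the transcribed strand (so minus-strand
#' genes yield T>C plus-strand signatures), plus ADAR-null-only artifact
#' change sites and genomic variants (SNPs and DNA-seq variants). All site
#' classes are mutually disjoint.
#'
#' @param genome,models from [makeGenomeAndModels()].
#' @param profile a [simProfile()].
#' @param seed integer seed.
#' @return list with `truth` (data.frame: chrom, pos, strand, ref, region,
#'   geneId, alt, level_wild_type, level_adbp1_mutant, level_adar_null),
#'   `snps` and `dnaVariants` (data.frames: chrom, pos, alt / chrom, pos).
#' @export
planTruthSites <- function(genome, models, profile = simProfile(),
                           seed = NULL) {
  feats <- geneFeatures(models)
  withSeed(seed, {
    ## candidate adenosines per region stratum (coding-gene regions)
    pool <- list()
    for (lab in c("cds_exon", "intron", "utr")) {
      sel <- if (lab == "utr") mcols(feats)$type %in% c("utr5", "utr3")
             else mcols(feats)$type == lab
      fr <- feats[sel & mcols(feats)$biotype == "coding"]
      cand <- rbindlist(lapply(seq_along(fr), function(i) {
        ch <- as.character(seqnames(fr)[i])
        sq <- as.character(subseq(genome[[ch]], start(fr)[i], end(fr)[i]))
        str <- as.character(strand(fr)[i])
        hit <- if (str == "+") gregexpr("A", sq, fixed = TRUE)[[1]]
               else gregexpr("T", sq, fixed = TRUE)[[1]]
        if (hit[1] == -1L) return(NULL)
        data.table(chrom = ch, pos = start(fr)[i] + as.integer(hit) - 1L,
                   strand = str, geneId = mcols(fr)$gene_id[i])
      }))
      cand <- unique(cand, by = c("chrom", "pos"))
      cand[, region := lab]
      pool[[lab]] <- cand
    }
    used <- data.table(chrom = character(), pos = integer())
    drawSites <- function(n, mix) {
      nPer <- as.vector(stats::rmultinom(1, n, mix[c("cds_exon", "intron",
                                                     "utr")]))
      names(nPer) <- c("cds_exon", "intron", "utr")
      out <- list()
      for (lab in names(nPer)) {
        if (nPer[[lab]] == 0L) next
        cand <- pool[[lab]][!used, on = c("chrom", "pos")]
        if (nrow(cand) < nPer[[lab]])
          stop("not enough adenosines in stratum '", lab, "'")
        pick <- cand[sample.int(nrow(cand), nPer[[lab]])]
        out[[lab]] <- pick
        used <<- rbind(used, pick[, .(chrom, pos)])
      }
      rbindlist(out)
    }
    wt <- drawSites(profile$nSitesWT, profile$regionMixWT)
    wt[, `:=`(level_wild_type = runif(.N, profile$levelRange[1],
                                      profile$levelRange[2]),
              level_adbp1_mutant = 0, level_adar_null = 0)]
    ab <- drawSites(profile$nSitesAdbp1, profile$regionMixAdbp1)
    ab[, `:=`(level_wild_type = 0,
              level_adbp1_mutant = runif(.N, profile$levelRange[1],
                                         profile$levelRange[2]),
              level_adar_null = 0)]
    ## ADAR-null artifact changes, in exons of coding genes
    arte <- pool$cds_exon[!used, on = c("chrom", "pos")]
    arte <- arte[sample.int(nrow(arte), profile$nArtifact)]
    used <- rbind(used, arte[, .(chrom, pos)])
    arte[, `:=`(level_wild_type = 0, level_adbp1_mutant = 0,
                level_adar_null = runif(.N, profile$artifactLevelRange[1],
                                        profile$artifactLevelRange[2]))]
    truth <- rbind(wt, ab, arte)
    truth[, ref := fifelse(strand == "+", "A", "T")]
    truth[, alt := fifelse(strand == "+", "G", "C")]
    ## refine the region label through the annotator so truth and pipeline
    ## agree on precedence at overlapping loci
    ann <- annotatePositions(models, truth$chrom, truth$pos, truth$strand)
    truth[, region := ann$region]
    truth[, geneId := ann$geneId]
    setkey(truth, chrom, pos)

    ## genomic variants, disjoint from all sites
    genomeDT <- rbindlist(lapply(names(genome), function(ch)
      data.table(chrom = ch,
                 pos = seq_len(Biostrings::width(genome[ch])))))
    free <- genomeDT[!used, on = c("chrom", "pos")]
    vpick <- free[sample.int(nrow(free), profile$nSNPs + profile$nDNAVariants)]
    refAt <- function(dt) {
      vapply(seq_len(nrow(dt)), function(i)
        as.character(subseq(genome[[dt$chrom[i]]], dt$pos[i], dt$pos[i])),
        character(1))
    }
    vref <- refAt(vpick)
    valt <- vapply(vref, function(r)
      sample(base::setdiff(.NUCS, r), 1L), character(1))
    snps <- vpick[seq_len(profile$nSNPs), .(chrom, pos)]
    snps[, alt := valt[seq_len(profile$nSNPs)]]
    dna <- vpick[profile$nSNPs + seq_len(profile$nDNAVariants),
                 .(chrom, pos)]
    dna[, alt := valt[profile$nSNPs + seq_len(profile$nDNAVariants)]]
    list(truth = as.data.frame(truth
           [, .(chrom, pos, strand, ref, alt, region, geneId,
                level_wild_type, level_adbp1_mutant, level_adar_null)]),
         snps = as.data.frame(snps),
         dnaVariants = as.data.frame(dna))
  })
}

# cased mismatch character by strand
.caseBy <- function(nuc, plus) fifelse(plus, nuc, tolower(nuc))

#' Simulate one sample's pileup file
#'
#' Per position: coverage from the negative-binomial model; at true sites of
#' the sample's strain, edited reads Binomial(depth, level); everywhere,
#' sequencing errors at the profile's rate split uniformly over the three
#' alternative bases; genomic variant positions emit homozygous alternative
#' alleles; base qualities follow the two-point Phred model; strand encoding
#' ('.'/',' and letter case) follows the gene strand. Deterministic given
#' the seed.
#'
#' @param genome,models from [makeGenomeAndModels()].
#' @param plan result of [planTruthSites()].
#' @param profile a [simProfile()].
#' @param sample one-row metadata from [sampleMeta()].
#' @param path output pileup path.
#' @param seed integer seed.
#' @return `path`, invisibly.
#' @export
simulateSamplePileup <- function(genome, models, plan, profile, sample,
                                 path, seed = NULL) {
  stopifnot(nrow(sample) == 1L)
  strain <- sample$strain[1]
  stage <- sample$stage[1]
  lvlCol <- paste0("level_", strain)
  truth <- as.data.table(plan$truth)
  variants <- rbind(as.data.table(plan$snps)[, .(chrom, pos, alt)],
                    as.data.table(plan$dnaVariants)[, .(chrom, pos, alt)])
  gspans <- geneSpans(models)
  mult <- if (stage == "L4") profile$stageLevelMultiplier else 1.0
  qHi <- rawToChar(as.raw(profile$qualHigh + 33L))
  qLo <- rawToChar(as.raw(profile$qualLow + 33L))
  withSeed(seed, {
    chunks <- lapply(names(genome), function(ch) {
      refv <- strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1]]
      L <- length(refv)
      depth <- rnbinom(L, size = profile$coverageSize,
                       mu = profile$coverageMean)
      ## strand template from gene spans (intergenic: '+')
      plus <- rep(TRUE, L)
      gch <- gspans[as.character(seqnames(gspans)) == ch]
      if (length(gch)) {
        minus <- gch[as.character(strand(gch)) == "-"]
        for (i in seq_along(minus))
          plus[start(minus)[i]:end(minus)[i]] <- FALSE
      }
      ## edited reads at this strain's true sites
      kEdit <- integer(L)
      editAlt <- character(L)
      tch <- truth[chrom == ch & get(lvlCol) > 0]
      if (nrow(tch)) {
        lv <- pmin(tch[[lvlCol]] * mult, 0.95)
        kEdit[tch$pos] <- rbinom(nrow(tch), depth[tch$pos], lv)
        editAlt[tch$pos] <- tch$alt
      }
      ## sequencing errors on the remaining reads, split over the 3 alts
      nRemain <- depth - kEdit
      nErr <- rbinom(L, nRemain, profile$errorRate)
      e1 <- rbinom(L, nErr, 1 / 3)
      e2 <- rbinom(L, nErr - e1, 1 / 2)
      e3 <- nErr - e1 - e2
      refIdx <- match(refv, .NUCS)
      cnt <- matrix(0L, L, 4L, dimnames = list(NULL, .NUCS))
      othersIdx <- matrix(0L, L, 3L)
      for (r in 1:4) {
        rows <- which(refIdx == r)
        othersIdx[rows, ] <- matrix(rep(base::setdiff(1:4, r),
                                        each = length(rows)),
                                    ncol = 3L)
      }
      ok <- !is.na(refIdx)
      cnt[cbind(which(ok), othersIdx[ok, 1])] <- e1[ok]
      cnt[cbind(which(ok), othersIdx[ok, 2])] <- e2[ok]
      cnt[cbind(which(ok), othersIdx[ok, 3])] <- e3[ok]
      eIdx <- which(kEdit > 0L)
      if (length(eIdx)) {
        ec <- cbind(eIdx, match(editAlt[eIdx], .NUCS))
        cnt[ec] <- cnt[ec] + kEdit[eIdx]
      }
      refCnt <- depth - as.integer(rowSums(cnt))
      ## homozygous genomic variants override the position
      vch <- variants[chrom == ch]
      if (nrow(vch)) {
        cnt[vch$pos, ] <- 0L
        cnt[cbind(vch$pos, match(vch$alt, .NUCS))] <- depth[vch$pos]
        refCnt[vch$pos] <- 0L
      }
      ## two-point quality model per call group
      lowOf <- function(n) rbinom(L, n, profile$lowQualFraction)
      refLo <- lowOf(refCnt)
      aLo <- lowOf(cnt[, "A"]); cLo <- lowOf(cnt[, "C"])
      gLo <- lowOf(cnt[, "G"]); tLo <- lowOf(cnt[, "T"])
      mchar <- fifelse(plus, ".", ",")
      bases <- paste0(strrep(mchar, refCnt),
                      strrep(.caseBy("A", plus), cnt[, "A"]),
                      strrep(.caseBy("C", plus), cnt[, "C"]),
                      strrep(.caseBy("G", plus), cnt[, "G"]),
                      strrep(.caseBy("T", plus), cnt[, "T"]))
      quals <- paste0(strrep(qHi, refCnt - refLo), strrep(qLo, refLo),
                      strrep(qHi, cnt[, "A"] - aLo), strrep(qLo, aLo),
                      strrep(qHi, cnt[, "C"] - cLo), strrep(qLo, cLo),
                      strrep(qHi, cnt[, "G"] - gLo), strrep(qLo, gLo),
                      strrep(qHi, cnt[, "T"] - tLo), strrep(qLo, tLo))
      ## reference-base N positions carry no calls; drop with zero-depth
      keepPos <- depth > 0L & ok
      data.table(chrom = ch, pos = which(keepPos), ref = refv[keepPos],
                 depth = depth[keepPos], bases = bases[keepPos],
                 quals = quals[keepPos])
    })
    fwrite(rbindlist(chunks), path, sep = "\t", col.names = FALSE,
           quote = FALSE)
  })
  invisible(path)
}

#' Emit a complete synthetic fixture directory
#'
#' Generates genome, annotation, ground truth, variant masks, known-site
#' catalogue (the wild-type truth serves as the catalogue), a per-gene count
#' table, and one pileup per strain, stage and replica. The directory is
#' self-describing and consumable by every analysis function with no
#' external data; regenerating with the same seed reproduces it exactly.
#'
#' @param outDir output directory (created).
#' @param profile a [simProfile()].
#' @param seed integer master seed; per-sample seeds are derived from it.
#' @return invisible list with paths, the plan and sample metadata.
#' @export
emitSampleSet <- function(outDir, profile = simProfile(), seed = 1L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "pileups"), showWarnings = FALSE)
  gm <- makeGenomeAndModels(profile$nGenes, profile$lncFraction, seed = seed)
  plan <- planTruthSites(gm$genome, gm$models, profile,
                         seed = seed + 1000L)
  writeXStringSet(gm$genome, file.path(outDir, "genome.fa"))
  writeGeneModels(gm$models, file.path(outDir, "models.gff3"))
  truthDT <- as.data.table(plan$truth)
  .writeHashTSV(truthDT, file.path(outDir, "truth.tsv"))
  .writeHashTSV(as.data.table(plan$snps), file.path(outDir, "snp_mask.tsv"))
  .writeHashTSV(as.data.table(plan$dnaVariants)[, .(chrom, pos)],
                file.path(outDir, "dna_variants.tsv"))
  known <- truthDT[level_wild_type > 0,
                   .(chrom, pos, ref, strand)]
  .writeHashTSV(known, file.path(outDir, "known_sites.tsv"))

  samples <- list(); k <- 0L
  paths <- character(0)
  for (strain in .STRAINS) for (stage in profile$stages)
    for (r in seq_len(profile$nReplicas)) {
      k <- k + 1L
      sm <- sampleMeta(strain, stage, r)
      f <- file.path(outDir, "pileups", paste0(sm$sampleId, ".pileup"))
      simulateSamplePileup(gm$genome, gm$models, plan, profile, sm, f,
                           seed = (seed + 7L * k) %% 2147483647L)
      samples[[k]] <- sm
      paths <- c(paths, f)
    }
  samples <- do.call(rbind, samples)

  ## simple per-gene count table for the expression module
  counts <- withSeed(seed + 5000L, {
    genes <- mcols(geneSpans(gm$models))$gene_id
    mu <- exp(rnorm(length(genes), mean = 5, sd = 1))
    m <- vapply(seq_len(nrow(samples)), function(j)
      rnbinom(length(genes), size = 8, mu = mu), numeric(length(genes)))
    storage.mode(m) <- "integer"
    dimnames(m) <- list(genes, samples$sampleId)
    m
  })
  writeCountsTable(counts, file.path(outDir, "counts.tsv"))
  .writeHashTSV(as.data.table(samples), file.path(outDir, "samples.tsv"))
  jsonlite::write_json(list(seed = seed,
                            profile = profile[names(profile)]),
                       file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = outDir, genome = gm$genome, models = gm$models,
                 plan = plan, samples = samples, pileups = paths))
}
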