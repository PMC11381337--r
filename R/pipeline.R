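#' @include synthio.R structure.R expression.R
NULL

# load, quality-filter and pool the pileups of one strain+stage
.loadStrainCounts <- function(fixtureDir, samples, strain, stage, qMin) {
  sel <- samples[samples$strain == strain & samples$stage == stage, ,
                 drop = FALSE]
  if (nrow(sel) == 0L)
    stop("no samples for ", strain, " at ", stage, " in ", fixtureDir)
  lapply(seq_len(nrow(sel)), function(i)
    readPileupCounts(file.path(fixtureDir, "pileups",
                               paste0(sel$sampleId[i], ".pileup")),
                     sample = sel[i, , drop = FALSE], qMin = qMin))
}

#' Run the editing-detection pipeline on a fixture directory
#'
#' Orchestrates the analysis stages over a directory laid out like
#' [emitSampleSet()] output: known-site quantification (with editing-null
#' blacklist), de-novo detection for wild-type and the adbp-1 mutant (with
#' variant and mutant-change subtraction and novelty classification),
#' region annotation and region summaries. Writes per-stage TSV outputs and
#' a machine-readable run manifest under `outDir`; inputs are never
#' modified.
#'
#' @param fixtureDir input directory with pileups/, genome.fa, models.gff3,
#'   known_sites.tsv, snp_mask.tsv, dna_variants.tsv, samples.tsv.
#' @param outDir output directory (created).
#' @param stage developmental stage to analyze.
#' @param config an [editingConfig()].
#' @param denovoCfg a [denovoConfig()].
#' @return invisible list with the stage results (knownSites per strain,
#'   denovo per strain, annotated site tables, manifest path).
#' @export
runPipeline <- function(fixtureDir, outDir, stage = "embryo",
                        config = editingConfig(),
                        denovoCfg = denovoConfig()) {
  stage <- match.arg(stage, .STAGES)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  warningsLog <- character(0)
  note <- function(...) warningsLog <<- c(warningsLog, paste0(...))

  samples <- as.data.frame(.readHashTSV(file.path(fixtureDir, "samples.tsv")))
  models <- readGeneModels(file.path(fixtureDir, "models.gff3"))
  catalogue <- as.data.frame(.readHashTSV(file.path(fixtureDir,
                                                    "known_sites.tsv")))
  mask <- rbind(readVariantMask(file.path(fixtureDir, "snp_mask.tsv")),
                readVariantMask(file.path(fixtureDir, "dna_variants.tsv")))

  adarCounts <- .loadStrainCounts(fixtureDir, samples, "adar_null", stage,
                                  config@qMin)
  adarPool <- poolCounts(adarCounts)
  blacklist <- buildAdarBlacklist(adarPool, catalogue, config@thetaMut)
  if (any(blacklist$unassessable))
    note(sum(blacklist$unassessable),
         " catalogued site(s) unassessable in the editing-null strain")

  res <- list(stage = stage)
  wtEditedSets <- list()
  for (strain in c("wild_type", "adbp1_mutant")) {
    cl <- .loadStrainCounts(fixtureDir, samples, strain, stage, config@qMin)
    pooled <- poolCounts(cl)
    ks <- callKnownSites(pooled, catalogue, config, blacklist)
    ks$calls <- annotateSites(ks$calls, models)
    ann <- annotatePositions(models, ks$table$chrom, ks$table$pos)
    ks$table$geneId <- ann$geneId
    ks$table$region <- ann$region
    writeSiteTable(ks$calls, file.path(outDir,
                                       paste0(strain, "_known_sites.tsv")))
    .writeHashTSV(as.data.table(ks$table),
                  file.path(outDir, paste0(strain, "_known_table.tsv")))
    gl <- geneLevelEditing(ks$table)
    .writeHashTSV(as.data.table(gl),
                  file.path(outDir, paste0(strain, "_gene_editing.tsv")))
    if (strain == "wild_type")
      wtEditedSets$known <- siteTable(ks$calls)
    res[[paste0("known_", strain)]] <- ks
  }

  for (strain in c("wild_type", "adbp1_mutant")) {
    cl <- .loadStrainCounts(fixtureDir, samples, strain, stage,
                            denovoCfg@qMin)
    dn <- denovoPipeline(cl, adarNull = adarPool, mask = mask,
                         config = denovoCfg,
                         wtEdited = if (strain == "wild_type") NULL
                                    else wtEditedSets)
    dn$calls <- annotateSites(dn$calls, models)
    if (strain == "wild_type") {
      st <- siteTable(dn$calls)
      st$status <- "known"   # wild-type de-novo hits define the WT set
      wtEditedSets$denovo <- st
    }
    writeSiteTable(dn$calls, file.path(outDir, paste0(strain, "_denovo.tsv")))
    if (nrow(dn$diagnostics))
      .writeHashTSV(as.data.table(dn$diagnostics),
                    file.path(outDir, paste0(strain, "_denovo_diagnostics.tsv")))
    res[[paste0("denovo_", strain)]] <- dn
  }

  for (strain in c("wild_type", "adbp1_mutant")) {
    summ <- regionSummary(res[[paste0("known_", strain)]]$calls)
    .writeHashTSV(as.data.table(summ),
                  file.path(outDir, paste0(strain, "_region_summary.tsv")))
  }

  manifest <- list(
    inputDir = normalizePath(fixtureDir),
    stage = stage,
    config = list(qMin = config@qMin, thetaSite = config@thetaSite,
                  thetaOther = config@thetaOther, thetaMut = config@thetaMut),
    denovoConfig = list(qMin = denovoCfg@qMin, kMin = denovoCfg@kMin,
                        thetaDn = denovoCfg@thetaDn,
                        thetaOther = denovoCfg@thetaOther,
                        rMin = denovoCfg@rMin),
    inputDigests = as.list(tools::md5sum(
      Filter(file.exists, file.path(fixtureDir,
                                    c("known_sites.tsv", "snp_mask.tsv",
                                      "dna_variants.tsv", "models.gff3"))))),
    version = as.character(utils::packageVersion("edicall")),
    warnings = warningsLog,
    outputs = list.files(outDir))
  manifestPath <- file.path(outDir, "run_manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE)
  res$manifest <- manifestPath
  res$blacklist <- blacklist
  invisible(res)
}
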