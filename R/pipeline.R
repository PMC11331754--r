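emptyEpitopes <- function() {
  data.frame(patient_id = character(), peptide = character(),
             length = integer(), mhc_class = character(),
             allele = character(), ic50_nM = numeric(),
             category = character(), source_id = character(),
             gene_symbol = character(), rna_vaf = numeric(),
             expression_tpm = numeric(), novel = logical(),
             stringsAsFactors = FALSE)
}

## transcripts of `models` whose CDS contains the variant locus
modelsAtVariant <- function(variant, models) {
  hits <- vapply(models, function(m) {
    m@chrom == variant$chrom && !is.na(genomicToCds(m, variant$pos))
  }, logical(1))
  models[hits]
}

#' Predict neoantigen epitopes for one patient
#'
#' For every variant, evaluates all expressed (transcript TPM strictly
#' above `tpmMin`), usable transcripts overlapping it, extracts
#' mutation-spanning peptides per MHC class (deduplicated across
#' transcripts of the same variant), scores them against the patient's
#' alleles, applies the filter cascade and the proteome novelty screen.
#'
#' @param variants Variant data.frame from [readVcfVariants()].
#' @param models Named list of [TranscriptModel-class].
#' @param tumorExpr Transcript-level `ExpressionMatrix`.
#' @param alleles Named list with elements `I` and `II` (character vectors).
#' @param proteome [Biostrings::AAStringSet] reference proteome.
#' @param config A [PipelineConfig-class].
#' @param backend `"surrogate"` or an `AffinityTable`.
#' @return Passing epitope data.frame (see [filterEpitopes()]).
#' @export
predictNeoantigenEpitopes <- function(variants, models, tumorExpr, alleles,
                                      proteome, config = pipelineConfig(),
                                      backend = "surrogate") {
  if (!nrow(variants)) return(emptyEpitopes())
  pt <- variants$patient_id[1L]
  tpm <- tumorExpr$values[, pt]
  fm <- tumorExpr$featureMap
  out <- list()
  for (vi in seq_len(nrow(variants))) {
    v <- variants[vi, , drop = FALSE]
    cand <- modelsAtVariant(v, models)
    cand <- cand[vapply(cand, function(m)
      isUsable(m) && !is.na(tpm[transcriptId(m)]) &&
        tpm[transcriptId(m)] > config@tpmMin, logical(1))]
    if (!length(cand)) next
    for (cl in c("I", "II")) {
      peps <- unique(do.call(rbind, lapply(cand, function(m) {
        pair <- tryCatch(buildMutantProtein(v, m),
                         warning = function(w) NULL)
        extractMutationPeptides(pair, cl, config)
      })))
      if (is.null(peps) || !nrow(peps)) next
      gene <- geneId(cand[[1L]])
      geneTpm <- sum(tpm[fm$transcript_id[fm$gene_id == gene]])
      peps$patient_id <- pt
      peps$category <- if (v$vtype == "SNV") "SNV" else "indel"
      peps$source_id <- v$id
      peps$gene_symbol <- geneSymbol(cand[[1L]])
      peps$rna_vaf <- v$rna_vaf
      peps$expression_tpm <- geneTpm
      out[[length(out) + 1L]] <-
        predictAffinity(peps, alleles[[cl]], cl, backend, config)
    }
  }
  if (!length(out)) return(emptyEpitopes())
  cands <- do.call(rbind, out)
  passed <- filterEpitopes(cands, config)
  noveltyFilter(passed, proteome, mode = "neoantigen")
}

#' Predict fusion junction epitopes for one patient
#'
#' Builds each fusion protein, enumerates junction-spanning peptides,
#' scores and filters them (no VAF gate; expression support is the smaller
#' of the two partner genes' TPM).
#'
#' @inheritParams predictNeoantigenEpitopes
#' @param fusions Fusion data.frame from [readFusionCalls()].
#' @return Passing epitope data.frame.
#' @export
predictFusionEpitopes <- function(fusions, models, tumorExpr, alleles,
                                  proteome, config = pipelineConfig(),
                                  backend = "surrogate") {
  if (is.null(fusions) || !nrow(fusions)) return(emptyEpitopes())
  pt <- fusions$patient_id[1L]
  tpm <- tumorExpr$values[, pt]
  fm <- tumorExpr$featureMap
  geneTpm <- function(tx) {
    g <- fm$gene_id[fm$transcript_id == tx]
    sum(tpm[fm$transcript_id[fm$gene_id == g]])
  }
  out <- list()
  for (fi in seq_len(nrow(fusions))) {
    ev <- fusions[fi, , drop = FALSE]
    fp <- buildFusionProtein(ev, models)
    for (cl in c("I", "II")) {
      peps <- extractFusionPeptides(fp, cl, config)
      if (!nrow(peps)) next
      peps$patient_id <- pt
      peps$category <- "fusion"
      peps$source_id <- ev$id
      peps$gene_symbol <- paste0(ev$left_gene, "--", ev$right_gene)
      peps$rna_vaf <- NA_real_
      peps$expression_tpm <- min(geneTpm(ev$left_transcript),
                                 geneTpm(ev$right_transcript))
      out[[length(out) + 1L]] <-
        predictAffinity(peps, alleles[[cl]], cl, backend, config)
    }
  }
  if (!length(out)) return(emptyEpitopes())
  passed <- filterEpitopes(do.call(rbind, out), config)
  noveltyFilter(passed, proteome, mode = "neoantigen")
}

#' Predict TAA epitopes for one patient
#'
#' Identifies tumor-associated genes against the normal panel, enumerates
#' their peptides, scores and filters them; the novelty screen exempts
#' hits within the TAA's own gene.
#'
#' @inheritParams predictNeoantigenEpitopes
#' @param stats A [NormalPanelStats-class].
#' @param patientId Patient/sample id.
#' @return List with `epitopes` (passing epitope data.frame) and `tags`
#'   (the [identifyTags()] table).
#' @export
predictTaaEpitopes <- function(tumorExpr, stats, patientId, models, alleles,
                               proteome, config = pipelineConfig(),
                               backend = "surrogate") {
  tags <- suppressWarnings(
    identifyTags(tumorExpr, stats, patientId, config))
  qual <- tags[tags$qualifies, , drop = FALSE]
  out <- list()
  for (ti in seq_len(nrow(qual))) {
    tag <- qual[ti, , drop = FALSE]
    for (cl in c("I", "II")) {
      peps <- suppressWarnings(
        enumerateTagPeptides(tag, models, tumorExpr, cl, config))
      if (!nrow(peps)) next
      peps$patient_id <- patientId
      peps$category <- "TAA"
      peps$source_id <- tag$gene_id
      peps$gene_symbol <- tag$gene_symbol
      peps$rna_vaf <- NA_real_
      peps$expression_tpm <- tag$tumor_gene_tpm
      out[[length(out) + 1L]] <-
        predictAffinity(peps, alleles[[cl]], cl, backend, config)
    }
  }
  ep <- if (length(out)) {
    passed <- filterEpitopes(do.call(rbind, out), config)
    noveltyFilter(passed, proteome, mode = "TAA")
  } else emptyEpitopes()
  list(epitopes = ep, tags = tags)
}

#' Run the full antigen-discovery pipeline on an input directory
#'
#' Expects the layout written by [generateCohortData()] (`genome.fa`,
#' `models.gtf`, `proteome.fa`, `manifest.tsv`, `tumor_expression.tsv`,
#' `normal_panel.tsv`, `organ_map.tsv`, `vcf/<patient>.vcf`,
#' `fusions/<patient>.tsv`, optional `ms_peptides.tsv`). Runs the three
#' antigen arms for both MHC classes on every patient, aggregates antigen
#' calls, and computes the cohort landscape. When `outDir` is given, writes
#' the epitope/antigen reports and the landscape tables there with
#' deterministic content.
#'
#' @param inputDir Input directory.
#' @param config A [PipelineConfig-class].
#' @param backend `"surrogate"` or an `AffinityTable`.
#' @param outDir Optional output directory.
#' @return List: `epitopes`, `calls`, `tags`, `taaCategories`, `burden`,
#'   `targetable` (list of tables), `recurring`, `shared`, `comparisons`,
#'   `survival`, `msConcordance`, `manifest`.
#' @export
runPipeline <- function(inputDir, config = pipelineConfig(),
                        backend = "surrogate", outDir = NULL) {
  manifest <- readCohortManifest(file.path(inputDir, "manifest.tsv"))
  models <- suppressWarnings(readTranscriptModels(
    file.path(inputDir, "models.gtf"), file.path(inputDir, "genome.fa")))
  proteome <- readProteome(file.path(inputDir, "proteome.fa"))
  tumorExpr <- readExpressionTable(file.path(inputDir, "tumor_expression.tsv"),
                                   level = "transcript")
  panel <- readExpressionTable(file.path(inputDir, "normal_panel.tsv"),
                               level = "gene")
  organMap <- utils::read.delim(file.path(inputDir, "organ_map.tsv"),
                                stringsAsFactors = FALSE)
  stats <- suppressMessages(computeNormalStats(
    panel, stats::setNames(organMap$organ, organMap$sample)))

  allEp <- list(); allTags <- list()
  for (i in seq_len(nrow(manifest))) {
    pt <- manifest$patient_id[i]
    alleles <- list(I = manifest$hla_i[[i]], II = manifest$hla_ii[[i]])
    vcfPath <- file.path(inputDir, "vcf", paste0(pt, ".vcf"))
    if (file.exists(vcfPath)) {
      variants <- suppressWarnings(readVcfVariants(vcfPath, pt))
      allEp[[length(allEp) + 1L]] <- predictNeoantigenEpitopes(
        variants, models, tumorExpr, alleles, proteome, config, backend)
    }
    fusPath <- file.path(inputDir, "fusions", paste0(pt, ".tsv"))
    if (file.exists(fusPath)) {
      fus <- suppressWarnings(readFusionCalls(fusPath, pt))
      allEp[[length(allEp) + 1L]] <- predictFusionEpitopes(
        fus, models, tumorExpr, alleles, proteome, config, backend)
    }
    taa <- predictTaaEpitopes(tumorExpr, stats, pt, models, alleles,
                              proteome, config, backend)
    allEp[[length(allEp) + 1L]] <- taa$epitopes
    allTags[[length(allTags) + 1L]] <- taa$tags
  }
  epitopes <- do.call(rbind, allEp)
  rownames(epitopes) <- NULL
  tags <- do.call(rbind, allTags)
  calls <- callAntigens(epitopes)

  taaGenes <- unique(calls$source_id[calls$category == "TAA"])
  taaCategories <- if (length(taaGenes))
    classifyTaaCategory(sort(taaGenes), stats) else
    data.frame(gene_id = character(), category = character(),
               testis_hi = numeric(), fetal_hi = numeric())

  burden <- burdenTable(calls, manifest)
  targetable <- list(
    neoantigen_I = targetableFractionTable(burden, "I", NULL),
    neoantigen_II = targetableFractionTable(burden, "II", NULL),
    taa_I = targetableFractionTable(burden, "I", "TAA"),
    taa_II = targetableFractionTable(burden, "II", "TAA"))
  recurring <- rbind(recurringAntigens(calls, manifest, "subgroup"),
                     recurringAntigens(calls, manifest, "pan"))
  shared <- sharedAntigens(calls, manifest)
  comparisons <- tryCatch(
    subgroupComparison(burden, "I", NULL), error = function(e) NULL)
  survival <- suppressWarnings(rbind(
    antigenSurvivalCorrelation(burden, manifest, "OS", "spearman"),
    antigenSurvivalCorrelation(burden, manifest, "PFS", "spearman")))
  msPath <- file.path(inputDir, "ms_peptides.tsv")
  conc <- if (file.exists(msPath))
    msConcordance(epitopes, msPath, config) else NULL

  res <- list(epitopes = epitopes, calls = calls, tags = tags,
              taaCategories = taaCategories, burden = burden,
              targetable = targetable, recurring = recurring,
              shared = shared, comparisons = comparisons,
              survival = survival, msConcordance = conc,
              manifest = manifest)
  if (!is.null(outDir)) writePipelineOutputs(res, outDir)
  res
}

writePipelineOutputs <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeAntigenReport(res$calls, res$epitopes, file.path(outDir, "report"))
  wt <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.table(df, file.path(outDir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(res$burden, "burden.tsv")
  for (nm in names(res$targetable))
    wt(res$targetable[[nm]], paste0("targetable_", nm, ".tsv"))
  wt(res$recurring, "recurring.tsv")
  wt(res$shared, "shared.tsv")
  if (!is.null(res$comparisons)) {
    wt(data.frame(overall_p = res$comparisons$overall_p),
       "comparison_overall.tsv")
    wt(res$comparisons$pairwise, "comparison_pairwise.tsv")
  }
  wt(res$survival, "survival_corr.tsv")
  wt(res$msConcordance, "ms_concordance.tsv")
  wt(res$taaCategories, "taa_categories.tsv")
  invisible(outDir)
}
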