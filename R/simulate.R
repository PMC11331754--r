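STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation parameters for the synthetic cohort
#'
#' Defaults define the reference study conditions of the test cohort: a
#' 200-gene reference, a 29-organ normal panel (3 samples per organ) with
#' held-out testis and fetal cerebellum, and 24 patients split across the
#' four medulloblastoma subgroups in roughly the published 18/46/41/65
#' proportions. Planted effects keep at least a two-fold margin from every
#' strict decision threshold: planted tumor-associated genes have normal
#' ceilings below 0.5 TPM and tumor expression above 2 TPM; planted
#' variants carry RNA-VAF above 0.7 and supporting expression above
#' 1.5 TPM.
#'
#' @param nGenes Number of reference genes.
#' @param secondTranscriptProb Probability a gene carries a second isoform.
#' @param proteinCodons Range of protein lengths (codons, excluding stop).
#' @param nOrgans Number of included normal organs.
#' @param samplesPerOrgan Samples per organ (also for testis/fetal).
#' @param cohortSizes Named integer vector of patients per subgroup.
#' @param tagPoolSize Genes in the tumor-restricted pool from which
#'   patient TAGs are planted.
#' @param nCta,nOncofetal Pool genes additionally given testis /
#'   fetal-cerebellum expression (for category calls).
#' @param tagsPerPatientRange Range of planted TAGs per patient.
#' @param variantsPerPatient Planted variants per patient
#'   (named: missense, synonymous, frameshift, lowvaf_decoy).
#' @param fusionsPerPatient Planted fusions per patient.
#' @param normalHiMargin Ceiling for planted-TAG normal expression (TPM).
#' @param tumorTpmMin Floor for planted tumor expression (TPM).
#' @param vafRange RNA-VAF range for planted variants.
#' @return List of class `SimParams`.
#' @export
simParams <- function(nGenes = 200L,
                      secondTranscriptProb = 0.25,
                      proteinCodons = c(40L, 120L),
                      nOrgans = 29L,
                      samplesPerOrgan = 3L,
                      cohortSizes = c(WNT = 3L, SHH = 7L, Group3 = 6L,
                                      Group4 = 8L),
                      tagPoolSize = 10L,
                      nCta = 3L,
                      nOncofetal = 2L,
                      tagsPerPatientRange = c(1L, 5L),
                      variantsPerPatient = c(missense = 4L, synonymous = 1L,
                                             frameshift = 1L,
                                             lowvaf_decoy = 1L),
                      fusionsPerPatient = 1L,
                      normalHiMargin = 0.5,
                      tumorTpmMin = 2,
                      vafRange = c(0.72, 0.95)) {
  stopifnot(nGenes > 0, nOrgans > 0, samplesPerOrgan > 0,
            all(cohortSizes >= 0), tagPoolSize <= nGenes,
            nCta + nOncofetal <= tagPoolSize,
            normalHiMargin < 1, tumorTpmMin > 1, all(vafRange > 0.6))
  structure(as.list(environment()), class = "SimParams")
}

randomCodingCds <- function(nCodons) {
  codons <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  body <- sample(codons, nCodons - 1L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1L))
}

#' Generate the synthetic reference (genome, transcript models, proteome)
#'
#' Builds random coding sequences (start codon, no internal stop, terminal
#' stop), some multi-exon, on both strands, lays them out on two synthetic
#' chromosomes, and derives the matching transcript models and proteome.
#'
#' @param params A `SimParams` list.
#' @param seed Integer seed.
#' @return List with `genome` ([Biostrings::DNAStringSet]), `gtf`
#'   ([GenomicRanges::GRanges] of CDS features), `models` (named list of
#'   [TranscriptModel-class]), `proteome` ([Biostrings::AAStringSet]) and
#'   `geneTable` (data.frame gene_id, gene_symbol, transcript_id).
#' @export
generateReference <- function(params = simParams(), seed = 1L) {
  set.seed(seed)
  chroms <- c("chr1", "chr2")
  pieces <- stats::setNames(vector("list", length(chroms)), chroms)
  cursor <- stats::setNames(rep(0L, length(chroms)), chroms)
  gtfRows <- list()
  geneTable <- list()

  addPiece <- function(chrom, seqChr) {
    pieces[[chrom]][[length(pieces[[chrom]]) + 1L]] <<- seqChr
    start <- cursor[[chrom]] + 1L
    cursor[[chrom]] <<- cursor[[chrom]] + nchar(seqChr)
    c(start, cursor[[chrom]])
  }
  randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

  for (gi in seq_len(params$nGenes)) {
    geneId <- sprintf("GENE%04d", gi)
    geneSym <- sprintf("SG%04d", gi)
    nTx <- 1L + (stats::runif(1) < params$secondTranscriptProb)
    chrom <- chroms[(gi %% length(chroms)) + 1L]
    for (ti in seq_len(nTx)) {
      txId <- sprintf("%s.T%d", geneId, ti)
      nCod <- sample(params$proteinCodons[1L]:params$proteinCodons[2L], 1L)
      cds <- randomCodingCds(nCod + 1L)           # +1 for the stop codon
      strand <- sample(c("+", "-"), 1L)
      nExons <- sample(1:3, 1L)
      cuts <- if (nExons > 1L)
        sort(sample(seq_len(nchar(cds) - 1L), nExons - 1L)) else integer()
      bounds <- c(0L, cuts, nchar(cds))
      exons <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
      # transcription-order exons; genomic layout ascends, so minus-strand
      # genes are laid down reversed and reverse-complemented
      layout <- if (strand == "+") exons else
        rev(vapply(exons, revcompChr, character(1)))
      addPiece(chrom, randSeq(sample(60:120, 1L)))
      segs <- matrix(0L, nrow = length(layout), ncol = 2L)
      for (e in seq_along(layout)) {
        if (e > 1L) addPiece(chrom, randSeq(sample(20:80, 1L)))
        segs[e, ] <- addPiece(chrom, layout[e])
      }
      gtfRows[[length(gtfRows) + 1L]] <- data.frame(
        chrom = chrom, start = segs[, 1L], end = segs[, 2L], strand = strand,
        transcript_id = txId, gene_id = geneId, gene_name = geneSym,
        stringsAsFactors = FALSE)
      geneTable[[length(geneTable) + 1L]] <- data.frame(
        gene_id = geneId, gene_symbol = geneSym, transcript_id = txId,
        stringsAsFactors = FALSE)
    }
  }
  for (ch in chroms) addPiece(ch, randSeq(100L))

  genome <- Biostrings::DNAStringSet(vapply(pieces, function(p)
    paste(unlist(p), collapse = ""), character(1)))
  names(genome) <- chroms
  gtfDf <- do.call(rbind, gtfRows)
  gtf <- GenomicRanges::GRanges(
    gtfDf$chrom, IRanges::IRanges(gtfDf$start, gtfDf$end),
    strand = gtfDf$strand, type = "CDS", source = "sim",
    transcript_id = gtfDf$transcript_id, gene_id = gtfDf$gene_id,
    gene_name = gtfDf$gene_name)

  models <- list()
  for (txId in unique(gtfDf$transcript_id)) {
    rows <- gtfDf[gtfDf$transcript_id == txId, , drop = FALSE]
    models[[txId]] <- transcriptModel(
      txId, rows$gene_id[1L], rows$gene_name[1L], rows$chrom[1L],
      rows$strand[1L],
      IRanges::IRanges(rows$start, rows$end), genome[[rows$chrom[1L]]])
  }
  proteome <- Biostrings::AAStringSet(vapply(models, function(m)
    as.character(m@protein), character(1)))
  names(proteome) <- sprintf("PROT_%s gene=%s", names(models),
                             vapply(models, geneSymbol, character(1)))
  list(genome = genome, gtf = gtf, models = models, proteome = proteome,
       geneTable = do.call(rbind, geneTable))
}

#' Generate the synthetic normal-tissue panel
#'
#' Gene-level TPM for 29 included organs plus held-out testis and fetal
#' cerebellum. Background genes carry expression comfortably above 1 TPM
#' in every organ (they can never qualify as tumor-associated); the
#' tumor-restricted pool is kept below the planted margin across the 29
#' organs, with designated cancer-testis genes upregulated in testis and
#' designated oncofetal genes in fetal cerebellum.
#'
#' @param params A `SimParams`.
#' @param reference Output of [generateReference()].
#' @param seed Integer seed.
#' @return List with `panel` (gene-level `ExpressionMatrix`), `organMap`
#'   (data.frame sample, organ), and the pool gene id vectors `tagPool`,
#'   `ctaGenes`, `oncofetalGenes`.
#' @export
generateNormalPanel <- function(params, reference, seed = 2L) {
  set.seed(seed)
  genes <- unique(reference$geneTable$gene_id)
  tagPool <- sort(sample(genes, params$tagPoolSize))
  ctaGenes <- sort(sample(tagPool, params$nCta))
  oncofetalGenes <- sort(sample(setdiff(tagPool, ctaGenes),
                                params$nOncofetal))
  organs <- c(sprintf("organ%02d", seq_len(params$nOrgans)),
              "testis", "fetal_cerebellum")
  organCol <- rep(organs, each = params$samplesPerOrgan)
  samples <- paste0(organCol, "_s",
                    rep(seq_len(params$samplesPerOrgan), length(organs)))
  vals <- matrix(1.5 + stats::rlnorm(length(genes) * length(samples),
                                     meanlog = log(4), sdlog = 0.5),
                 nrow = length(genes), dimnames = list(genes, samples))
  isPool <- rownames(vals) %in% tagPool
  low <- function(n) stats::runif(n, 0, 0.1)
  inc <- organCol %in% sprintf("organ%02d", seq_len(params$nOrgans))
  vals[isPool, inc] <- low(sum(isPool) * sum(inc))
  tes <- organCol == "testis"; fet <- organCol == "fetal_cerebellum"
  vals[isPool, tes] <- low(sum(isPool) * sum(tes))
  vals[isPool, fet] <- low(sum(isPool) * sum(fet))
  vals[rownames(vals) %in% ctaGenes, tes] <-
    stats::runif(sum(rownames(vals) %in% ctaGenes) * sum(tes), 3, 6)
  vals[rownames(vals) %in% oncofetalGenes, fet] <-
    stats::runif(sum(rownames(vals) %in% oncofetalGenes) * sum(fet), 2, 5)
  fm <- unique(reference$geneTable[, c("gene_id", "gene_symbol")])
  fm <- fm[match(genes, fm$gene_id), ]
  panel <- structure(list(level = "gene", values = vals, featureMap = fm),
                     class = "ExpressionMatrix")
  list(panel = panel,
       organMap = data.frame(sample = samples, organ = organCol,
                             stringsAsFactors = FALSE),
       tagPool = tagPool, ctaGenes = ctaGenes,
       oncofetalGenes = oncofetalGenes)
}

## pick a codon index whose third base can change silently (4-fold family)
fourfoldCodons <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

plantSnv <- function(model, wantSynonymous) {
  cds <- as.character(model@cds)
  nCod <- nchar(cds) %/% 3L
  for (ci in sample(2:(nCod - 1L))) {
    codon <- substr(cds, (ci - 1L) * 3L + 1L, ci * 3L)
    if (wantSynonymous) {
      if (!substr(codon, 1L, 2L) %in% fourfoldCodons) next
      newBase <- sample(setdiff(c("A", "C", "G", "T"),
                                substr(codon, 3L, 3L)), 1L)
      cdsPos <- (ci - 1L) * 3L + 3L
      return(list(cdsPos = cdsPos, refBase = substr(codon, 3L, 3L),
                  altBase = newBase))
    }
    offs <- sample(1:3)
    for (o in offs) {
      old <- substr(codon, o, o)
      for (nb in sample(setdiff(c("A", "C", "G", "T"), old))) {
        cand <- codon
        substr(cand, o, o) <- nb
        aaOld <- Biostrings::GENETIC_CODE[[codon]]
        aaNew <- Biostrings::GENETIC_CODE[[cand]]
        if (aaNew != aaOld && aaNew != "*")
          return(list(cdsPos = (ci - 1L) * 3L + o, refBase = old,
                      altBase = nb))
      }
    }
  }
  NULL
}

## CDS position (not in first/last codon) whose predecessor is in the same
## exon, for a left-anchored 1-nt deletion. The resulting shifted frame must
## leave a mutant protein long enough for class II windows with at least one
## novel residue before its stop.
plantDeletionPos <- function(model) {
  cds <- as.character(model@cds)
  n <- nchar(cds)
  refProt <- as.character(model@protein)
  for (p in sample(5:(n %/% 2L))) {
    g1 <- cdsToGenomic(model, p - 1L)
    g2 <- cdsToGenomic(model, p)
    if (abs(g2 - g1) != 1L) next
    mutProt <- translateToStop(paste0(substr(cds, 1L, p - 1L),
                                      substring(cds, p + 1L)))
    span <- alteredSpan(refProt, mutProt, "frameshift")
    if (nchar(mutProt) >= 15L && span[2L] > span[1L]) return(p)
  }
  NULL
}

#' Generate the synthetic tumor cohort
#'
#' Creates patients across the four subgroups with HLA genotypes, plants
#' tumor-associated genes (drawn from the panel's tumor-restricted pool),
#' somatic variants (missense, synonymous, frameshift deletions, plus a
#' low-VAF decoy per patient) with reference alleles read from the genome,
#' and in-frame/frameshift fusions; emits tumor expression consistent with
#' every planted event, survival times anti-correlated with planted TAG
#' burden, a mass-spectrometry peptide list containing substrings of known
#' planted mutant epitopes, and a truth manifest.
#'
#' @param params A `SimParams`.
#' @param reference Output of [generateReference()].
#' @param panelInfo Output of [generateNormalPanel()].
#' @param seed Integer seed.
#' @return List with `manifest`, `tumorExpr`, `variants` (per-patient
#'   data.frame list), `fusions`, `msPeptides`, `truth` (data.frame).
#' @export
generateTumorCohort <- function(params, reference, panelInfo, seed = 3L) {
  set.seed(seed)
  models <- reference$models
  usableTx <- names(models)[vapply(models, isUsable, logical(1))]
  poolGenes <- panelInfo$tagPool
  backgroundTx <- usableTx[!vapply(models[usableTx], geneId,
                                   character(1)) %in% poolGenes]
  plusTx <- backgroundTx[vapply(models[backgroundTx], function(m)
    m@strand == "+", logical(1))]

  subgroups <- rep(names(params$cohortSizes), params$cohortSizes)
  nPt <- length(subgroups)
  patients <- sprintf("PT%02d", seq_len(nPt))
  hlaIPool <- c("HLA-A*01:01", "HLA-A*02:01", "HLA-B*07:02", "HLA-B*08:01",
                "HLA-C*07:01", "HLA-C*07:02")
  hlaIIPool <- c("DRB1*07:01", "DRB1*15:01", "DQB1*06:02", "DPB1*04:01")

  txByGene <- split(reference$geneTable$transcript_id,
                    reference$geneTable$gene_id)
  allTx <- reference$geneTable$transcript_id
  tpm <- matrix(stats::rlnorm(length(allTx) * nPt, log(8), 0.6),
                nrow = length(allTx), dimnames = list(allTx, patients))
  poolTx <- unlist(txByGene[poolGenes])
  tpm[poolTx, ] <- stats::runif(length(poolTx) * nPt, 0, 0.45)

  truth <- list(); variants <- list(); fusions <- list(); msRows <- list()
  tagCount <- integer(nPt)

  for (i in seq_len(nPt)) {
    pt <- patients[i]
    nTags <- sample(params$tagsPerPatientRange[1L]:
                      params$tagsPerPatientRange[2L], 1L)
    tags <- sample(poolGenes, nTags)
    tagCount[i] <- nTags
    for (g in tags) {
      txs <- txByGene[[g]]
      top <- txs[1L]
      tpm[top, pt] <- stats::runif(1L, max(params$tumorTpmMin, 2), 8)
      truth[[length(truth) + 1L]] <- data.frame(
        patient_id = pt, kind = "TAG", id = g, detail = "planted",
        planted = TRUE, stringsAsFactors = FALSE)
    }

    vp <- params$variantsPerPatient
    kinds <- c(rep("missense", vp[["missense"]]),
               rep("synonymous", vp[["synonymous"]]),
               rep("frameshift", vp[["frameshift"]]),
               rep("lowvaf_decoy", vp[["lowvaf_decoy"]]))
    chosen <- sample(setdiff(backgroundTx, character()), length(kinds))
    fsNeeded <- kinds == "frameshift"
    chosen[fsNeeded] <- sample(setdiff(plusTx, chosen[!fsNeeded]),
                               sum(fsNeeded))
    vrows <- list()
    for (k in seq_along(kinds)) {
      kind <- kinds[k]
      m <- models[[chosen[k]]]
      tpm[transcriptId(m), pt] <- max(tpm[transcriptId(m), pt],
                                      stats::runif(1L, 2, 8))
      if (kind == "frameshift") {
        p <- plantDeletionPos(m)
        tries <- 0L
        while (is.null(p) && tries < 25L) {
          alt <- sample(setdiff(plusTx, chosen), 1L)
          chosen[k] <- alt
          m <- models[[alt]]
          tpm[transcriptId(m), pt] <- max(tpm[transcriptId(m), pt],
                                          stats::runif(1L, 2, 8))
          p <- plantDeletionPos(m)
          tries <- tries + 1L
        }
        if (is.null(p))
          stop("could not place a frameshift deletion with a usable ",
               "shifted frame")
        gAnchor <- cdsToGenomic(m, p - 1L)
        gDel <- cdsToGenomic(m, p)
        lo <- min(gAnchor, gDel)
        chromSeq <- reference$genome[[m@chrom]]
        ref <- as.character(Biostrings::subseq(chromSeq, lo, lo + 1L))
        alt <- substr(ref, 1L, 1L)
        pos <- lo
        vaf <- stats::runif(1L, params$vafRange[1L], params$vafRange[2L])
      } else {
        sv <- plantSnv(m, kind == "synonymous")
        gPos <- cdsToGenomic(m, sv$cdsPos)
        chromSeq <- reference$genome[[m@chrom]]
        ref <- as.character(Biostrings::subseq(chromSeq, gPos, gPos))
        alt <- if (m@strand == "+") sv$altBase else revcompChr(sv$altBase)
        pos <- gPos
        vaf <- if (kind == "lowvaf_decoy")
          stats::runif(1L, 0.2, 0.55) else
          stats::runif(1L, params$vafRange[1L], params$vafRange[2L])
      }
      vrows[[k]] <- data.frame(
        patient_id = pt, chrom = m@chrom, pos = pos, ref = ref, alt = alt,
        rna_vaf = round(vaf, 3L), kind = kind,
        transcript_id = transcriptId(m), stringsAsFactors = FALSE)
    }
    vdf <- do.call(rbind, vrows)
    vdf$id <- sprintf("%s:%d:%s>%s", vdf$chrom, vdf$pos, vdf$ref, vdf$alt)
    variants[[pt]] <- vdf
    planted <- vdf$kind %in% c("missense", "frameshift")
    truth[[length(truth) + 1L]] <- data.frame(
      patient_id = pt, kind = "variant", id = vdf$id, detail = vdf$kind,
      planted = planted, stringsAsFactors = FALSE)

    nFus <- params$fusionsPerPatient
    if (nFus > 0L) {
      frows <- list()
      for (f in seq_len(nFus)) {
        prt <- sample(backgroundTx, 2L)
        while (geneId(models[[prt[1L]]]) == geneId(models[[prt[2L]]]))
          prt <- sample(backgroundTx, 2L)
        lm <- models[[prt[1L]]]; rm <- models[[prt[2L]]]
        tpm[prt, pt] <- pmax(tpm[prt, pt], stats::runif(2L, 2, 8))
        llen <- length(lm@cds); rlen <- length(rm@cds)
        inFrame <- (i + f) %% 2L == 0L
        lb <- if (inFrame) 3L * sample(4:((llen %/% 3L) - 4L), 1L)
              else 3L * sample(4:((llen %/% 3L) - 4L), 1L) + 1L
        rb <- 3L * sample(3:((rlen %/% 3L) - 4L), 1L) + 1L
        frows[[f]] <- data.frame(
          fusion_name = paste0(geneSymbol(lm), "--", geneSymbol(rm)),
          junction_reads = sample(10:100, 1L),
          left_gene = geneSymbol(lm), left_transcript = prt[1L],
          left_cds_break = lb,
          right_gene = geneSymbol(rm), right_transcript = prt[2L],
          right_cds_break = rb, stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          patient_id = pt, kind = "fusion",
          id = sprintf("%s--%s:%d-%d", geneSymbol(lm), geneSymbol(rm),
                       lb, rb),
          detail = if (inFrame) "in_frame" else "frameshift",
          planted = TRUE, stringsAsFactors = FALSE)
      }
      fusions[[pt]] <- do.call(rbind, frows)
    }
  }

  tumorExpr <- structure(list(
    level = "transcript", values = tpm,
    featureMap = reference$geneTable[
      match(rownames(tpm), reference$geneTable$transcript_id),
      c("transcript_id", "gene_id", "gene_symbol")]),
    class = "ExpressionMatrix")

  # MS peptides: substrings of known planted mutant epitopes for the first
  # five patients, plus sub-threshold and decoy rows
  for (pt in patients[seq_len(min(5L, nPt))]) {
    vdf <- variants[[pt]]
    mis <- vdf[vdf$kind == "missense", ][1L, ]
    pair <- buildMutantProtein(
      list(chrom = mis$chrom, pos = mis$pos, ref = mis$ref, alt = mis$alt,
           vtype = "SNV", id = mis$id, patient_id = pt),
      models[[mis$transcript_id]])
    a <- pair$altered_start
    prot <- pair$mut_protein
    start <- max(1L, a + 1L - 4L)
    core <- substr(prot, start, min(nchar(prot), start + 8L))
    flank <- substr(prot, max(1L, start - 3L),
                    min(nchar(prot), start + 11L))
    msRows[[length(msRows) + 1L]] <- data.frame(
      patient_id = pt, peptide = flank,
      probability = round(stats::runif(1L, 0.75, 0.98), 3L),
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      patient_id = pt, kind = "ms_epitope", id = core, detail = mis$id,
      planted = TRUE, stringsAsFactors = FALSE)
    msRows[[length(msRows) + 1L]] <- data.frame(
      patient_id = pt,
      peptide = paste(sample(Biostrings::AA_STANDARD, 12L, replace = TRUE),
                      collapse = ""),
      probability = round(stats::runif(1L, 0.3, 0.65), 3L),
      stringsAsFactors = FALSE)
  }

  os <- round(pmax(120, 3600 - 450 * tagCount +
                     stats::rnorm(nPt, 0, 150)))
  pfs <- round(os * stats::runif(nPt, 0.5, 0.9))
  manifest <- data.frame(
    patient_id = patients,
    subgroup = factor(subgroups, levels = MB_SUBGROUPS),
    sex = sample(c("M", "F"), nPt, replace = TRUE),
    age_years = sample(3:17, nPt, replace = TRUE),
    vital_status = sample(c("alive", "deceased"), nPt, replace = TRUE),
    os_days = os, pfs_days = pfs,
    hla_i = I(lapply(seq_len(nPt), function(i) sample(hlaIPool, 3L))),
    hla_ii = I(lapply(seq_len(nPt), function(i) sample(hlaIIPool, 2L))),
    stringsAsFactors = FALSE)

  list(manifest = manifest, tumorExpr = tumorExpr, variants = variants,
       fusions = fusions,
       msPeptides = if (length(msRows)) do.call(rbind, msRows) else
         data.frame(patient_id = character(), peptide = character(),
                    probability = numeric()),
       truth = do.call(rbind, truth))
}

#' Write a complete synthetic input directory
#'
#' Generates reference, normal panel and tumor cohort under one seed
#' lineage (`seed`, `seed + 1`, `seed + 2`) and writes every standard-format
#' input the pipeline reads: `genome.fa`, `models.gtf`, `proteome.fa`,
#' `manifest.tsv`, `tumor_expression.tsv`, `normal_panel.tsv`,
#' `organ_map.tsv`, per-patient `vcf/` and `fusions/`, `ms_peptides.tsv`
#' and `truth_manifest.tsv`. Regenerating with the same seed produces a
#' byte-identical file tree.
#'
#' @param outDir Output directory (created if needed).
#' @param params A `SimParams`.
#' @param seed Integer seed.
#' @return Invisibly, a list with the in-memory `reference`, `panelInfo`,
#'   `cohort` and the directory path.
#' @export
generateCohortData <- function(outDir, params = simParams(), seed = 1L) {
  reference <- generateReference(params, seed)
  panelInfo <- generateNormalPanel(params, reference, seed + 1L)
  cohort <- generateTumorCohort(params, reference, panelInfo, seed + 2L)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "vcf"), showWarnings = FALSE)
  dir.create(file.path(outDir, "fusions"), showWarnings = FALSE)

  Biostrings::writeXStringSet(reference$genome,
                              file.path(outDir, "genome.fa"))
  Biostrings::writeXStringSet(reference$proteome,
                              file.path(outDir, "proteome.fa"))
  gtfPath <- file.path(outDir, "models.gtf")
  suppressWarnings(rtracklayer::export(reference$gtf, gtfPath, format = "gtf"))
  # drop the run-date comment header so regeneration is byte-identical
  lines <- readLines(gtfPath)
  writeLines(lines[!startsWith(lines, "##")], gtfPath)

  writeExpressionTable(cohort$tumorExpr,
                       file.path(outDir, "tumor_expression.tsv"))
  writeExpressionTable(panelInfo$panel,
                       file.path(outDir, "normal_panel.tsv"))
  utils::write.table(panelInfo$organMap, file.path(outDir, "organ_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  mf <- cohort$manifest
  mfOut <- data.frame(
    patient_id = mf$patient_id, subgroup = as.character(mf$subgroup),
    sex = mf$sex, age = mf$age_years, vital_status = mf$vital_status,
    os_days = mf$os_days, pfs_days = mf$pfs_days,
    hla_i = vapply(mf$hla_i, paste, character(1), collapse = ";"),
    hla_ii = vapply(mf$hla_ii, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(mfOut, file.path(outDir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  for (pt in names(cohort$variants)) {
    v <- cohort$variants[[pt]]
    v <- v[order(v$chrom, v$pos), , drop = FALSE]
    con <- file(file.path(outDir, "vcf", paste0(pt, ".vcf")), "w")
    writeLines(c(
      "##fileformat=VCFv4.1",
      paste0("##INFO=<ID=RVAF,Number=1,Type=Float,",
             "Description=\"RNA variant allele fraction\">"),
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tRVAF=%s",
                       v$chrom, v$pos, v$ref, v$alt,
                       format(v$rna_vaf, trim = TRUE)), con)
    close(con)
  }
  for (pt in names(cohort$fusions)) {
    utils::write.table(cohort$fusions[[pt]],
                       file.path(outDir, "fusions", paste0(pt, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(cohort$msPeptides,
                     file.path(outDir, "ms_peptides.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(outDir, "truth_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(reference = reference, panelInfo = panelInfo,
                 cohort = cohort, dir = outDir))
}
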