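HELD_OUT_ORGANS <- c("testis", "fetal_cerebellum")

#' Compute normal-panel expression statistics
#'
#' For every gene and organ, the mean TPM (\eqn{\mu}), the sample standard
#' deviation (\eqn{\sigma}, n-1 denominator; single-sample organs get
#' \eqn{\sigma = 0} with a caveat message) and the ceiling
#' \eqn{\mu + 2\sigma}. Organs named `"testis"` and `"fetal_cerebellum"`
#' are held out of the panel maximum and kept separately: they categorize
#' antigens (cancer-testis vs oncofetal) instead of disqualifying genes.
#'
#' @param panel Gene-level `ExpressionMatrix` of normal samples.
#' @param organLabels Character vector naming the organ of every panel
#'   sample (parallel to the matrix columns, or named by sample).
#' @return A [NormalPanelStats-class].
#' @export
computeNormalStats <- function(panel, organLabels) {
  stopifnot(inherits(panel, "ExpressionMatrix"), panel$level == "gene")
  vals <- panel$values
  if (!is.null(names(organLabels)))
    organLabels <- organLabels[colnames(vals)]
  if (length(organLabels) != ncol(vals) || any(is.na(organLabels)) ||
      any(!nzchar(organLabels)))
    stop("every panel sample must carry exactly one organ label")
  organLabels <- as.character(organLabels)
  allOrgans <- sort(unique(organLabels))
  n <- as.vector(table(organLabels)[allOrgans])
  mu <- t(rowsum(t(vals), organLabels)[allOrgans, , drop = FALSE]) /
    rep(n, each = nrow(vals))
  sq <- t(rowsum(t(vals^2), organLabels)[allOrgans, , drop = FALSE])
  ss <- sq - rep(n, each = nrow(vals)) * mu^2
  sigma <- sqrt(pmax(ss, 0) / rep(pmax(n - 1L, 1L), each = nrow(vals)))
  sigma[, n == 1L] <- 0
  if (any(n == 1L))
    message("organ(s) with a single sample get sigma = 0: ",
            paste(allOrgans[n == 1L], collapse = ", "))
  hi <- mu + 2 * sigma
  held <- allOrgans %in% HELD_OUT_ORGANS
  included <- allOrgans[!held]
  pull <- function(organ) {
    if (organ %in% allOrgans) stats::setNames(hi[, organ], rownames(vals))
    else stats::setNames(rep(NA_real_, nrow(vals)), rownames(vals))
  }
  new("NormalPanelStats",
      geneIds = rownames(vals),
      organs = included,
      mu = mu[, included, drop = FALSE],
      sigma = sigma[, included, drop = FALSE],
      hi = hi[, included, drop = FALSE],
      normalMax = stats::setNames(
        apply(hi[, included, drop = FALSE], 1L, max), rownames(vals)),
      testisHi = pull("testis"),
      fetalHi = pull("fetal_cerebellum"))
}

#' @describeIn computeNormalStats Per-gene maximum \eqn{\mu+2\sigma} over
#'   the included organs.
#' @param object A [NormalPanelStats-class].
#' @export
normalMax <- function(object) object@normalMax
#' @describeIn computeNormalStats Held-out testis \eqn{\mu+2\sigma}.
#' @export
testisHi <- function(object) object@testisHi
#' @describeIn computeNormalStats Held-out fetal cerebellum \eqn{\mu+2\sigma}.
#' @export
fetalHi <- function(object) object@fetalHi

setMethod("show", "NormalPanelStats", function(object) {
  cat(sprintf("NormalPanelStats: %d genes x %d organs (held out: %s)\n",
              length(object@geneIds), length(object@organs),
              paste(HELD_OUT_ORGANS, collapse = ", ")))
  cat(sprintf("  genes with normal max (mu+2sigma) < 1 TPM: %d\n",
              sum(object@normalMax < 1)))
})

#' Identify tumor-associated genes in one patient
#'
#' A gene qualifies as a tumor-associated gene (TAG) when its normal-panel
#' ceiling \eqn{\mu+2\sigma} is strictly below `normalMaxLt` in every
#' included organ, its tumor gene TPM (sum over transcripts) is strictly
#' above `tpmMin`, and its highest-expressed transcript is itself strictly
#' above `tpmMin`. Ties at a threshold disqualify. Genes absent from the
#' panel are treated as normal-max 0 but flagged `unverified_normal`.
#'
#' @param tumorExpr Transcript-level `ExpressionMatrix` containing the
#'   patient's sample.
#' @param stats A [NormalPanelStats-class].
#' @param patientId Sample/patient column to evaluate.
#' @param config A [PipelineConfig-class].
#' @return data.frame with one row per gene: `patient_id`, `gene_id`,
#'   `gene_symbol`, `tumor_gene_tpm`, `top_transcript_id`,
#'   `top_transcript_tpm`, `normal_max`, `unverified_normal`, `qualifies`.
#' @export
identifyTags <- function(tumorExpr, stats, patientId,
                         config = pipelineConfig()) {
  stopifnot(inherits(tumorExpr, "ExpressionMatrix"),
            tumorExpr$level == "transcript")
  if (!patientId %in% colnames(tumorExpr$values))
    stop("patient ", patientId, " not found in tumor expression matrix")
  tpm <- tumorExpr$values[, patientId]
  fm <- tumorExpr$featureMap
  geneIds <- unique(fm$gene_id)
  geneTpm <- rowsum(tpm, fm$gene_id)[geneIds, 1L]
  topIdx <- vapply(split(seq_len(nrow(fm)), fm$gene_id)[geneIds],
                   function(i) i[which.max(tpm[i])], integer(1))
  nm <- unname(stats@normalMax[geneIds])
  unverified <- is.na(nm)
  if (any(unverified)) {
    warning(sum(unverified), " gene(s) absent from the normal panel; ",
            "treated as normal max 0 (unverified_normal)")
    nm[unverified] <- 0
  }
  sym <- fm$gene_symbol[match(geneIds, fm$gene_id)]
  out <- data.frame(
    patient_id = patientId,
    gene_id = geneIds,
    gene_symbol = sym,
    tumor_gene_tpm = as.numeric(geneTpm),
    top_transcript_id = fm$transcript_id[topIdx],
    top_transcript_tpm = as.numeric(tpm[topIdx]),
    normal_max = as.numeric(nm),
    unverified_normal = unverified,
    stringsAsFactors = FALSE
  )
  out$qualifies <- out$normal_max < config@normalMaxLt &
    out$tumor_gene_tpm > config@tpmMin &
    out$top_transcript_tpm > config@tpmMin
  rownames(out) <- NULL
  out
}

#' Enumerate candidate TAA peptides for a qualifying gene
#'
#' All k-mers (class I: 9--12; class II: 15) of the protein of every
#' non-partial coding transcript of the gene whose tumor TPM is strictly
#' above `tpmMin`, deduplicated across transcripts.
#'
#' @param tag One qualifying row from [identifyTags()].
#' @param models Named list of [TranscriptModel-class] objects.
#' @param tumorExpr Transcript-level `ExpressionMatrix`.
#' @param mhcClass `"I"` or `"II"`.
#' @param config A [PipelineConfig-class].
#' @return data.frame with columns `peptide`, `length`.
#' @export
enumerateTagPeptides <- function(tag, models, tumorExpr, mhcClass,
                                 config = pipelineConfig()) {
  stopifnot(isTRUE(tag$qualifies))
  ks <- peptideLengths(config, mhcClass, category = "TAA")
  tpm <- tumorExpr$values[, tag$patient_id]
  txIds <- tumorExpr$featureMap$transcript_id[
    tumorExpr$featureMap$gene_id == tag$gene_id]
  txIds <- txIds[tpm[txIds] > config@tpmMin]
  usable <- txIds[vapply(txIds, function(id)
    !is.null(models[[id]]) && isUsable(models[[id]]), logical(1))]
  if (!length(usable)) {
    warning("gene ", tag$gene_id, " has no usable coding transcript above ",
            config@tpmMin, " TPM; no TAA peptides")
    return(data.frame(peptide = character(), length = integer()))
  }
  out <- do.call(rbind, lapply(usable, function(id) {
    prot <- as.character(proteinSeq(models[[id]]))
    do.call(rbind, lapply(ks, function(k)
      windowsOverlapping(prot, 0L, nchar(prot), k)))
  }))
  unique(out)
}

#' Classify an immunogenic TAA as cancer-testis, oncofetal or other
#'
#' Cancer-testis (CTA) when the held-out testis \eqn{\mu+2\sigma} exceeds
#' 1 TPM; otherwise oncofetal when the fetal-cerebellum ceiling exceeds
#' 1 TPM; otherwise other. Genes missing from the held-out stats are
#' treated as ceiling 0.
#'
#' @param geneId Gene identifier.
#' @param stats A [NormalPanelStats-class].
#' @param threshold Held-out expression ceiling defining "upregulated";
#'   default 1 TPM.
#' @return data.frame row: `gene_id`, `category`, `testis_hi`, `fetal_hi`.
#' @export
classifyTaaCategory <- function(geneId, stats, threshold = 1) {
  th <- stats@testisHi[geneId]
  fh <- stats@fetalHi[geneId]
  th <- ifelse(is.na(th), 0, th)
  fh <- ifelse(is.na(fh), 0, fh)
  category <- ifelse(th > threshold, "CTA",
                     ifelse(fh > threshold, "oncofetal", "other"))
  data.frame(gene_id = geneId, category = category,
             testis_hi = as.numeric(th), fetal_hi = as.numeric(fh),
             stringsAsFactors = FALSE, row.names = NULL)
}
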