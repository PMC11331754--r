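#' Read somatic variants from a VCF
#'
#' Reads a single-patient VCF (4.1) through
#' [VariantAnnotation::readVcf()] and classifies each record by allele
#' lengths: equal length 1 is an SNV, longer ALT an insertion, longer REF a
#' deletion. Multi-nucleotide substitutions (equal length > 1) are skipped
#' with a warning, as are records lacking the RNA-VAF INFO key.
#'
#' @param path VCF path.
#' @param patientId Patient identifier attached to every variant.
#' @param vafKey INFO key carrying the RNA variant allele fraction.
#'   Default `"RVAF"`.
#' @return data.frame with columns `patient_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `vtype`, `rna_vaf`, `id` (`chrom:pos:ref>alt`).
#' @export
readVcfVariants <- function(path, patientId, vafKey = "RVAF") {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(altL)
  idx <- rep(seq_along(rr), nalt)
  alt <- as.character(unlist(altL))
  chrom <- as.character(GenomicRanges::seqnames(rr))[idx]
  pos <- GenomicRanges::start(rr)[idx]
  ref <- ref[idx]

  info <- VariantAnnotation::info(vcf)
  if (vafKey %in% names(info)) {
    vaf <- as.numeric(info[[vafKey]])[idx]
  } else {
    vaf <- rep(NA_real_, length(idx))
  }

  nr <- nchar(ref); na <- nchar(alt)
  vtype <- rep(NA_character_, length(idx))
  vtype[nr == 1L & na == 1L] <- "SNV"
  vtype[nr < na] <- "insertion"
  vtype[nr > na] <- "deletion"
  mnv <- nr == na & nr > 1L

  if (any(mnv))
    warning(sum(mnv), " MNV record(s) skipped (multi-nucleotide variants excluded)")
  noVaf <- is.na(vaf) & !mnv
  if (any(noVaf))
    warning(sum(noVaf), " record(s) skipped: missing RNA-VAF key '", vafKey, "'")
  keep <- !mnv & !is.na(vaf)
  bad <- keep & ref == alt
  if (any(bad)) stop("record with ref == alt at ", chrom[bad][1L], ":", pos[bad][1L])

  data.frame(
    patient_id = rep(patientId, sum(keep)),
    chrom = chrom[keep], pos = pos[keep],
    ref = ref[keep], alt = alt[keep],
    vtype = vtype[keep], rna_vaf = vaf[keep],
    id = sprintf("%s:%d:%s>%s", chrom[keep], pos[keep], ref[keep], alt[keep]),
    stringsAsFactors = FALSE
  )
}
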