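# Fixture builders: everything is constructed in code at test time.

# Build a TranscriptModel (plus its host genome sequence) from a spliced CDS
# string given in transcription order. exonLens splits the CDS into segments;
# minus-strand models are laid on the genome reverse-complemented in
# descending genomic order, as in a real annotation.
mkModel <- function(cdsChr, strand = "+", exonLens = nchar(cdsChr),
                    id = "TX1", gene = "G1", sym = "S1", flank = 25L) {
  stopifnot(sum(exonLens) == nchar(cdsChr))
  bounds <- cumsum(c(0L, exonLens))
  exons <- substring(cdsChr, bounds[-length(bounds)] + 1L, bounds[-1L])
  rnt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  layout <- if (strand == "+") exons else
    rev(vapply(exons, function(e)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(e))),
      character(1)))
  pieces <- character(); segs <- matrix(0L, length(layout), 2L)
  cursor <- 0L
  add <- function(s) {
    pieces <<- c(pieces, s)
    st <- cursor + 1L; cursor <<- cursor + nchar(s)
    c(st, cursor)
  }
  add(rnt(flank))
  for (e in seq_along(layout)) {
    if (e > 1L) add(rnt(20L))
    segs[e, ] <- add(layout[e])
  }
  add(rnt(flank))
  genome <- Biostrings::DNAString(paste(pieces, collapse = ""))
  model <- transcriptModel(id, gene, sym, "chrT", strand,
                           IRanges::IRanges(segs[, 1L], segs[, 2L]), genome)
  list(model = model, genome = genome)
}

translateChr <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return("")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(substr(nt, 1, n))))
  s <- regexpr("*", aa, fixed = TRUE)
  if (s == -1L) aa else substr(aa, 1L, s - 1L)
}

randomPeptide <- function(k) {
  paste(sample(Biostrings::AA_STANDARD, k, TRUE), collapse = "")
}

mkVariant <- function(chrom, pos, ref, alt, vaf = 0.8, patient = "PT01") {
  vtype <- if (nchar(ref) == 1L && nchar(alt) == 1L) "SNV"
           else if (nchar(ref) < nchar(alt)) "insertion" else "deletion"
  data.frame(patient_id = patient, chrom = chrom, pos = pos, ref = ref,
             alt = alt, vtype = vtype, rna_vaf = vaf,
             id = sprintf("%s:%d:%s>%s", chrom, pos, ref, alt),
             stringsAsFactors = FALSE)
}

mkExprMatrix <- function(values, featureMap, level = "transcript") {
  structure(list(level = level, values = values, featureMap = featureMap),
            class = "ExpressionMatrix")
}

mkProteome <- function(seqs, genes = names(seqs)) {
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- sprintf("P%02d gene=%s", seq_along(seqs), genes)
  S4Vectors::mcols(aa)$gene <- genes
  names(aa) <- sub("\\s.*$", "", names(aa))
  aa
}

mkManifest <- function(subgroups, os = NULL, pfs = NULL) {
  n <- length(subgroups)
  data.frame(
    patient_id = sprintf("PT%02d", seq_len(n)),
    subgroup = factor(subgroups, levels = c("WNT", "SHH", "Group3", "Group4")),
    sex = rep("F", n), age_years = rep(8, n),
    vital_status = rep("alive", n),
    os_days = if (is.null(os)) rep(NA_real_, n) else os,
    pfs_days = if (is.null(pfs)) rep(NA_real_, n) else pfs,
    hla_i = I(rep(list(c("HLA-A*02:01")), n)),
    hla_ii = I(rep(list(c("DRB1*07:01")), n)),
    stringsAsFactors = FALSE)
}

mkEpitope <- function(patient = "PT01", peptide = "SIINFEKLM",
                      mhc_class = "I", category = "SNV",
                      source_id = "chr1:1:A>T", gene_symbol = "S1",
                      ic50 = 100, vaf = 0.8, tpm = 5, allele = "HLA-A*02:01") {
  data.frame(patient_id = patient, peptide = peptide,
             length = nchar(peptide), mhc_class = mhc_class,
             allele = allele, ic50_nM = ic50, category = category,
             source_id = source_id, gene_symbol = gene_symbol,
             rna_vaf = vaf, expression_tpm = tpm, novel = TRUE,
             stringsAsFactors = FALSE)
}
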