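#' Read transcript models from a GTF and genome FASTA
#'
#' Only `CDS` features are required; each must carry `transcript_id`,
#' `gene_id` and `gene_name` attributes. CDS sequences are spliced
#' strand-aware and translated with the standard genetic code. Models whose
#' CDS length is not divisible by three are flagged partial; models with an
#' internal stop codon or ambiguous base are flagged with a warning. All
#' flagged models are retained but excluded from peptide operations
#' (see [isUsable()]).
#'
#' @param gtfPath Path to a GTF file with CDS features.
#' @param genomeFastaPath Path to the genome FASTA.
#' @return Named list of [TranscriptModel-class] objects (by transcript id).
#' @export
readTranscriptModels <- function(gtfPath, genomeFastaPath) {
  gr <- rtracklayer::import(gtfPath, format = "gtf")
  gr <- gr[gr$type == "CDS"]
  if (!length(gr)) stop("no CDS features found in ", gtfPath)
  genome <- Biostrings::readDNAStringSet(genomeFastaPath)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                     names(genome))
  if (length(missing))
    stop("CDS references contig(s) absent from genome FASTA: ",
         paste(missing, collapse = ", "))
  byTx <- split(seq_along(gr), gr$transcript_id)
  models <- lapply(byTx, function(idx) {
    g <- gr[idx]
    chrom <- as.character(GenomicRanges::seqnames(g))[1L]
    strand <- as.character(GenomicRanges::strand(g))[1L]
    transcriptModel(
      transcriptId = g$transcript_id[1L],
      geneId = g$gene_id[1L],
      geneSymbol = if (!is.null(g$gene_name)) g$gene_name[1L] else g$gene_id[1L],
      chrom = chrom, strand = strand,
      cdsSegments = IRanges::IRanges(GenomicRanges::start(g),
                                     GenomicRanges::end(g)),
      genomeSeq = genome[[chrom]])
  })
  flagged <- vapply(models, function(m) length(m@flags) > 0L, logical(1))
  if (any(flagged))
    warning(sum(flagged), " transcript model(s) flagged (",
            paste(unique(unlist(lapply(models[flagged], slot, "flags"))),
                  collapse = ","), ") and excluded from peptide operations")
  models
}

#' Read a reference proteome FASTA
#'
#' Headers follow the dialect `>protein_id gene=SYMBOL`. The gene tag is
#' required by the TAA novelty filter (self-gene hits are exempt there);
#' mutation/fusion novelty screening works without it.
#'
#' @param path Proteome FASTA path.
#' @return An [Biostrings::AAStringSet] with `mcols()$gene` holding the
#'   parsed gene symbol (`NA` when absent).
#' @export
readProteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  gene <- ifelse(grepl("gene=", names(aa)),
                 sub(".*gene=([^ ]+).*", "\\1", names(aa)), NA_character_)
  S4Vectors::mcols(aa)$gene <- gene
  names(aa) <- sub("\\s.*$", "", names(aa))
  aa
}
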