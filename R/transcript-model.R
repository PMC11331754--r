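#' Construct a transcript model from CDS segments and genome sequence
#'
#' Splices the CDS out of the genome strand-aware (minus-strand segments are
#' reverse-complemented and read in decreasing genomic order), translates it
#' with the standard genetic code, and derives quality flags. The stored CDS
#' includes the terminal stop codon; the stored protein does not.
#'
#' @param transcriptId,geneId,geneSymbol,chrom,strand Identity fields.
#' @param cdsSegments [IRanges::IRanges] of genomic CDS intervals (1-based
#'   closed). May be given in any order; they are re-ordered into
#'   transcription order.
#' @param genomeSeq [Biostrings::DNAString] for `chrom`.
#' @return A [TranscriptModel-class].
#' @export
transcriptModel <- function(transcriptId, geneId, geneSymbol, chrom, strand,
                            cdsSegments, genomeSeq) {
  o <- order(IRanges::start(cdsSegments), decreasing = (strand == "-"))
  cdsSegments <- cdsSegments[o]
  pieces <- lapply(seq_along(cdsSegments), function(i) {
    s <- Biostrings::subseq(genomeSeq,
                            IRanges::start(cdsSegments)[i],
                            IRanges::end(cdsSegments)[i])
    if (strand == "-") Biostrings::reverseComplement(s) else s
  })
  cds <- do.call(Biostrings::xscat, pieces)
  buildModel(transcriptId, geneId, geneSymbol, chrom, strand, cdsSegments, cds)
}

## Assemble a TranscriptModel from an already-spliced CDS, deriving
## partial/flag state and the protein (translated to the first stop).
buildModel <- function(transcriptId, geneId, geneSymbol, chrom, strand,
                       cdsSegments, cds) {
  flags <- character()
  partial <- (length(cds) %% 3L) != 0L
  chr <- as.character(cds)
  if (grepl("[^ACGT]", chr)) flags <- c(flags, "ambiguous_base")
  protein <- Biostrings::AAString("")
  if (!partial && !("ambiguous_base" %in% flags) && length(cds) >= 3L) {
    aa <- suppressWarnings(Biostrings::translate(cds))
    aach <- as.character(aa)
    stops <- unlist(gregexpr("*", aach, fixed = TRUE))
    if (stops[1L] == -1L) {
      flags <- c(flags, "no_stop")
      protein <- aa
    } else {
      if (stops[1L] < nchar(aach)) flags <- c(flags, "internal_stop")
      protein <- Biostrings::AAString(substr(aach, 1L, stops[1L] - 1L))
    }
  }
  new("TranscriptModel",
      transcriptId = transcriptId, geneId = geneId, geneSymbol = geneSymbol,
      chrom = chrom, strand = strand, cdsSegments = cdsSegments,
      cds = cds, protein = protein, partial = partial, flags = flags)
}

#' @describeIn transcriptModel Transcript identifier.
#' @param x A [TranscriptModel-class].
#' @export
transcriptId <- function(x) x@transcriptId
#' @describeIn transcriptModel Gene identifier.
#' @export
geneId <- function(x) x@geneId
#' @describeIn transcriptModel Gene symbol.
#' @export
geneSymbol <- function(x) x@geneSymbol
#' @describeIn transcriptModel Spliced, strand-corrected CDS (with stop codon).
#' @export
cdsSeq <- function(x) x@cds
#' @describeIn transcriptModel Protein sequence (no terminal stop).
#' @export
proteinSeq <- function(x) x@protein
#' @describeIn transcriptModel `TRUE` when the model is excluded from peptide
#'   operations (partial CDS, internal stop, or ambiguous bases).
#' @export
isUsable <- function(x) {
  !x@partial && !any(c("internal_stop", "ambiguous_base") %in% x@flags)
}

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf("TranscriptModel %s (%s / %s) %s%s\n", object@transcriptId,
              object@geneId, object@geneSymbol, object@chrom, object@strand))
  cat(sprintf("  %d CDS segment(s), %d nt, protein %d aa%s%s\n",
              length(object@cdsSegments), length(object@cds),
              length(object@protein),
              if (object@partial) " [partial]" else "",
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ","), "]") else ""))
})

#' Map genomic positions to CDS coordinates and back
#'
#' CDS coordinates are 1-based along the spliced, strand-corrected CDS.
#' For minus-strand models, CDS position 1 is the genomically highest base
#' of the first (transcription-order) segment.
#'
#' @param model A [TranscriptModel-class].
#' @param pos Integer vector of genomic (1-based) or CDS positions.
#' @return Integer vector; `NA` where a genomic position falls outside the CDS.
#' @export
genomicToCds <- function(model, pos) {
  segs <- model@cdsSegments
  starts <- IRanges::start(segs); ends <- IRanges::end(segs)
  offs <- c(0L, cumsum(IRanges::width(segs)))
  out <- rep(NA_integer_, length(pos))
  for (i in seq_along(segs)) {
    hit <- !is.na(pos) & pos >= starts[i] & pos <= ends[i]
    if (!any(hit)) next
    out[hit] <- if (model@strand == "+") offs[i] + (pos[hit] - starts[i] + 1L)
                else offs[i] + (ends[i] - pos[hit] + 1L)
  }
  out
}

#' @rdname genomicToCds
#' @export
cdsToGenomic <- function(model, pos) {
  segs <- model@cdsSegments
  starts <- IRanges::start(segs); ends <- IRanges::end(segs)
  offs <- c(0L, cumsum(IRanges::width(segs)))
  out <- rep(NA_integer_, length(pos))
  for (i in seq_along(segs)) {
    hit <- !is.na(pos) & pos > offs[i] & pos <= offs[i + 1L]
    if (!any(hit)) next
    rel <- pos[hit] - offs[i]
    out[hit] <- if (model@strand == "+") starts[i] + rel - 1L
                else ends[i] - rel + 1L
  }
  out
}

## Translate a (possibly frame-broken) CDS string up to the first stop codon.
## Trailing bases short of a full codon are dropped. Returns the AA string
## without the stop symbol.
translateToStop <- function(nt) {
  n <- nchar(nt)
  n3 <- n - (n %% 3L)
  if (n3 < 3L) return("")
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(substr(nt, 1L, n3)))))
  stop1 <- regexpr("*", aa, fixed = TRUE)
  if (stop1 == -1L) aa else substr(aa, 1L, stop1 - 1L)
}
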