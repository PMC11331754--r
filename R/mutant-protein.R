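revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Apply a somatic variant to a transcript and derive the mutant protein
#'
#' Maps the genomic variant into the spliced CDS (strand-aware), edits the
#' CDS, and translates the edited sequence up to the first stop codon
#' (frameshifts translate the shifted frame until a stop or the end of the
#' stored CDS). The altered residue span records every residue of the
#' mutant protein that differs from reference; for frameshift and stop-loss
#' it extends to the mutant protein's end.
#'
#' @param variant One row of a variant data.frame from [readVcfVariants()].
#' @param model A usable [TranscriptModel-class] (see [isUsable()]).
#' @return `NULL` when the variant does not touch the model's CDS (or an
#'   indel spans a CDS boundary); otherwise a list with `variant_id`,
#'   `transcript_id`, `ref_protein`, `mut_protein`, `altered_start`,
#'   `altered_end` (0-based half-open residue interval on the mutant
#'   protein) and `consequence` (`synonymous`, `missense`, `inframe_ins`,
#'   `inframe_del`, `frameshift`, `stop_gain`, `stop_loss`).
#' @export
buildMutantProtein <- function(variant, model) {
  stopifnot(isUsable(model))
  if (variant$chrom != model@chrom) return(NULL)
  cds <- as.character(model@cds)
  minus <- model@strand == "-"
  ref <- variant$ref; alt <- variant$alt
  pos <- variant$pos

  if (variant$vtype == "SNV") {
    cpos <- genomicToCds(model, pos)
    if (is.na(cpos)) return(NULL)
    refC <- if (minus) revcompChr(ref) else ref
    altC <- if (minus) revcompChr(alt) else alt
    if (substr(cds, cpos, cpos) != refC)
      stop("reference mismatch at ", variant$chrom, ":", pos,
           " for transcript ", model@transcriptId)
    mut <- cds
    substr(mut, cpos, cpos) <- altC
  } else if (variant$vtype == "deletion") {
    d <- nchar(ref) - nchar(alt)
    delPos <- (pos + nchar(alt)):(pos + nchar(ref) - 1L)
    cdel <- genomicToCds(model, delPos)
    if (all(is.na(cdel))) return(NULL)
    if (any(is.na(cdel))) {
      warning("deletion at ", variant$chrom, ":", pos,
              " spans a CDS boundary; transcript ", model@transcriptId,
              " skipped")
      return(NULL)
    }
    cdel <- sort(cdel)
    if (any(diff(cdel) != 1L)) {
      warning("deletion at ", variant$chrom, ":", pos,
              " spans an intron; transcript ", model@transcriptId, " skipped")
      return(NULL)
    }
    delSeq <- substring(ref, nchar(alt) + 1L)
    want <- if (minus) revcompChr(delSeq) else delSeq
    if (substr(cds, cdel[1L], cdel[length(cdel)]) != want)
      stop("reference mismatch at ", variant$chrom, ":", pos,
           " for transcript ", model@transcriptId)
    mut <- paste0(substr(cds, 1L, cdel[1L] - 1L),
                  substring(cds, cdel[length(cdel)] + 1L))
  } else if (variant$vtype == "insertion") {
    ins <- substring(alt, nchar(ref) + 1L)
    # inserted between genomic pos and pos+1; k = CDS bases transcribed
    # before the insertion point
    if (minus) {
      kpos <- genomicToCds(model, pos + 1L)
      k <- if (is.na(kpos)) {
        anchor <- genomicToCds(model, pos)
        if (is.na(anchor)) return(NULL)
        anchor - 1L
      } else kpos
      insC <- revcompChr(ins)
    } else {
      k <- genomicToCds(model, pos)
      if (is.na(k)) return(NULL)
      insC <- ins
    }
    mut <- paste0(substr(cds, 1L, k), insC, substring(cds, k + 1L))
  } else {
    return(NULL)
  }

  refProt <- as.character(model@protein)
  mutProt <- translateToStop(mut)
  indelShift <- (nchar(alt) - nchar(ref)) %% 3L != 0L

  cons <- classifyConsequence(variant$vtype, indelShift, refProt, mutProt)
  span <- alteredSpan(refProt, mutProt, cons)
  list(variant_id = variant$id,
       transcript_id = model@transcriptId,
       ref_protein = refProt, mut_protein = mutProt,
       altered_start = span[1L], altered_end = span[2L],
       consequence = cons)
}

classifyConsequence <- function(vtype, indelShift, refProt, mutProt) {
  if (identical(refProt, mutProt)) return("synonymous")
  if (vtype == "SNV") {
    if (nchar(mutProt) < nchar(refProt)) return("stop_gain")
    if (nchar(mutProt) > nchar(refProt)) return("stop_loss")
    return("missense")
  }
  if (indelShift) return("frameshift")
  if (vtype == "insertion") "inframe_ins" else "inframe_del"
}

## 0-based half-open interval of mutant-protein residues differing from
## reference; frameshift/stop_loss extend to the mutant protein end.
alteredSpan <- function(refProt, mutProt, cons) {
  if (cons == "synonymous") return(c(0L, 0L))
  nr <- nchar(refProt); nm <- nchar(mutProt)
  r <- if (nr) utf8ToInt(refProt) else integer()
  m <- if (nm) utf8ToInt(mutProt) else integer()
  nmin <- min(nr, nm)
  pre <- if (nmin) which(r[seq_len(nmin)] != m[seq_len(nmin)]) else integer()
  s <- if (length(pre)) pre[1L] - 1L else nmin
  if (cons %in% c("frameshift", "stop_loss")) return(c(min(s, nm), nm))
  if (s == nmin && nm <= nr) return(c(nm, nm))   # pure truncation (stop_gain)
  suf <- if (nmin) which(rev(r)[seq_len(nmin)] != rev(m)[seq_len(nmin)]) else integer()
  k <- if (length(suf)) suf[1L] - 1L else nmin
  k <- min(k, nmin - s)                          # suffix must not eat the prefix
  c(s, nm - k)
}
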