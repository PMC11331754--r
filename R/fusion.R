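#' Build a fusion protein from a fusion call
#'
#' The fused CDS keeps the left partner's CDS through `left_break` (1-based,
#' last retained base) and appends the right partner's CDS from
#' `right_break` (first retained base) onward. The fusion is in frame when
#' the retained right bases land in their native codon frame
#' (`left_break mod 3 == (right_break - 1) mod 3`); otherwise the right
#' portion is retranslated in the shifted frame. Translation stops at the
#' first stop codon. When the left break falls inside a codon, the chimeric
#' codon's residue is assigned to the junction and flagged novel.
#'
#' @param event One row of a fusion data.frame from [readFusionCalls()].
#' @param models Named list of [TranscriptModel-class] objects containing
#'   both partner transcripts.
#' @return List with `fusion_id`, `protein`, `junction_index` (0-based index
#'   of the first residue using any right-partner nucleotide),
#'   `novel_start`/`novel_end` (0-based half-open novel residue span),
#'   `frame` (`in_frame`/`frameshift`), `left_protein`, `right_protein`.
#' @export
buildFusionProtein <- function(event, models) {
  lm <- models[[event$left_transcript]]
  rm <- models[[event$right_transcript]]
  if (is.null(lm) || is.null(rm))
    stop("fusion ", event$id, ": partner transcript(s) not found")
  stopifnot(isUsable(lm), isUsable(rm))
  lcds <- as.character(lm@cds); rcds <- as.character(rm@cds)
  lb <- event$left_break; rb <- event$right_break
  if (lb < 1L || lb > nchar(lcds))
    stop("fusion ", event$id, ": left breakpoint outside CDS (1..",
         nchar(lcds), ")")
  if (rb < 1L || rb > nchar(rcds))
    stop("fusion ", event$id, ": right breakpoint outside CDS (1..",
         nchar(rcds), ")")
  fused <- paste0(substr(lcds, 1L, lb), substring(rcds, rb))
  inFrame <- (lb %% 3L) == ((rb - 1L) %% 3L)
  prot <- translateToStop(fused)
  junction <- lb %/% 3L                 # residues wholly encoded by the left CDS
  np <- nchar(prot)
  if (junction >= np) {
    # stop codon formed at or before the junction: no novel contribution
    novel <- c(np, np)
    junction <- min(junction, np)
  } else if (!inFrame) {
    novel <- c(junction, np)
  } else {
    # only a chimeric codon (left break inside a codon) yields a novel residue
    novel <- c(junction, min(np, junction + as.integer(lb %% 3L != 0L)))
  }
  list(fusion_id = event$id,
       protein = prot,
       junction_index = junction,
       novel_start = novel[1L], novel_end = novel[2L],
       frame = if (inFrame) "in_frame" else "frameshift",
       left_protein = as.character(lm@protein),
       right_protein = as.character(rm@protein))
}

#' Enumerate junction-spanning fusion peptides
#'
#' Takes every k-window of the fusion protein that overlaps the novel
#' residue span or straddles the junction boundary (covering residues from
#' both partners), then drops windows that occur verbatim in either parent
#' protein — a junction peptide must be absent from both parents alone.
#' Lengths follow the mutation length sets (class I 8--12, class II 15).
#'
#' @param fp Fusion protein from [buildFusionProtein()].
#' @param mhcClass `"I"` or `"II"`.
#' @param config A [PipelineConfig-class].
#' @return data.frame with columns `peptide`, `length`.
#' @export
extractFusionPeptides <- function(fp, mhcClass, config = pipelineConfig()) {
  ks <- peptideLengths(config, mhcClass, category = "fusion")
  prot <- fp$protein
  L <- nchar(prot)
  out <- do.call(rbind, lapply(ks, function(k) {
    w1 <- windowsOverlapping(prot, fp$novel_start, fp$novel_end, k)
    # windows covering both residues junction_index-1 and junction_index
    # (1-based starts w with w <= j and w + k - 1 >= j + 1)
    j <- fp$junction_index
    w2 <- data.frame(peptide = character(), length = integer())
    if (j >= 1L && j <= L - 1L && k >= 2L) {
      lo <- max(1L, j + 2L - k)
      hi <- min(L - k + 1L, j)
      if (hi >= lo) {
        w <- lo:hi
        w2 <- data.frame(peptide = substring(prot, w, w + k - 1L),
                         length = rep(k, length(w)), stringsAsFactors = FALSE)
      }
    }
    unique(rbind(w1, w2))
  }))
  out <- unique(out)
  if (!nrow(out)) return(out)
  inParent <- vapply(out$peptide, function(p) {
    grepl(p, fp$left_protein, fixed = TRUE) ||
      grepl(p, fp$right_protein, fixed = TRUE)
  }, logical(1), USE.NAMES = FALSE)
  out[!inParent, , drop = FALSE]
}
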