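#' Apply the epitope filter cascade
#'
#' Pure conjunction of strict inequalities, applied stepwise with per-step
#' drop counts reported via `message()`:
#' \enumerate{
#'   \item binding: IC50 strictly below the class ceiling (500 nM class I,
#'     1000 nM class II);
#'   \item expression: supporting TPM strictly above `tpmMin`;
#'   \item RNA-VAF: strictly above `rnaVafMin` — applied to SNV and indel
#'     epitopes only (fusion and TAA epitopes carry no VAF).
#' }
#' Because the cascade is a conjunction, the surviving set does not depend
#' on the order the predicates are applied.
#'
#' @param candidates Epitope candidate data.frame with `ic50_nM`,
#'   `mhc_class`, `category`, `expression_tpm` and (for SNV/indel)
#'   `rna_vaf` columns.
#' @param config A [PipelineConfig-class].
#' @param verbose Report per-step drop counts. Default `FALSE`.
#' @return The passing subset of `candidates`.
#' @export
filterEpitopes <- function(candidates, config = pipelineConfig(),
                           verbose = FALSE) {
  if (!nrow(candidates)) return(candidates)
  ceiling <- ifelse(candidates$mhc_class == "I",
                    config@ic50MaxClassI, config@ic50MaxClassII)
  passIc50 <- candidates$ic50_nM < ceiling
  passTpm <- candidates$expression_tpm > config@tpmMin
  isMut <- candidates$category %in% c("SNV", "indel")
  passVaf <- !isMut | (!is.na(candidates$rna_vaf) &
                         candidates$rna_vaf > config@rnaVafMin)
  if (verbose) {
    message(sum(!passIc50), " candidate(s) dropped by binding affinity; ",
            sum(passIc50 & !passTpm), " by expression; ",
            sum(passIc50 & passTpm & !passVaf), " by RNA-VAF")
  }
  candidates[passIc50 & passTpm & passVaf, , drop = FALSE]
}

#' Proteome novelty filter
#'
#' Screens candidate epitopes against a reference proteome by exact
#' (fixed-string) substring search, case-insensitive after uppercasing.
#' In `"neoantigen"` mode (mutations and fusions) a peptide found anywhere
#' in the proteome is removed — a mutant peptide matching any normal
#' protein is by definition not novel. In `"TAA"` mode only hits in
#' proteins of a *different* gene remove the peptide: a TAA's peptides are
#' expected in its own gene's proteins.
#'
#' @param candidates Epitope candidate data.frame with a `peptide` column
#'   and, for TAA mode, a `gene_symbol` column.
#' @param proteome [Biostrings::AAStringSet] from [readProteome()]; TAA
#'   mode requires its `mcols()$gene` tags.
#' @param mode `"neoantigen"` or `"TAA"`.
#' @return `candidates` restricted to novel peptides, with a `novel`
#'   logical column (all `TRUE` on return).
#' @export
noveltyFilter <- function(candidates, proteome, mode = c("neoantigen", "TAA")) {
  mode <- match.arg(mode)
  if (!nrow(candidates)) {
    candidates$novel <- logical(0)
    return(candidates)
  }
  seqs <- toupper(as.character(proteome))
  genes <- S4Vectors::mcols(proteome)$gene
  if (mode == "TAA" && (is.null(genes) || anyNA(genes)))
    stop("TAA novelty mode requires a 'gene=' tag on every proteome entry")
  peps <- toupper(candidates$peptide)
  own <- if (mode == "TAA") candidates$gene_symbol else rep("", length(peps))
  key <- paste(peps, own, sep = "\r")
  uniqIdx <- which(!duplicated(key))
  novelByKey <- vapply(uniqIdx, function(i) {
    hit <- grepl(peps[i], seqs, fixed = TRUE)
    if (!any(hit)) return(TRUE)
    if (mode == "neoantigen") return(FALSE)
    all(genes[hit] == own[i])
  }, logical(1))
  keep <- novelByKey[match(key, key[uniqIdx])]
  out <- candidates[keep, , drop = FALSE]
  out$novel <- rep(TRUE, nrow(out))
  out
}
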