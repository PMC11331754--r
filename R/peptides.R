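## k-mer windows of `protein` (character) overlapping the 0-based half-open
## residue interval [a, b) by at least one residue. Returns a data.frame
## (peptide, length); empty span or protein shorter than k gives zero rows.
windowsOverlapping <- function(protein, a, b, k) {
  L <- nchar(protein)
  if (L < k || b <= a) return(data.frame(peptide = character(),
                                         length = integer()))
  # 1-based window starts w with [w, w+k-1] intersecting [a+1, b]
  lo <- max(1L, a + 1L - (k - 1L))
  hi <- min(L - k + 1L, b)
  if (hi < lo) return(data.frame(peptide = character(), length = integer()))
  w <- lo:hi
  data.frame(peptide = substring(protein, w, w + k - 1L),
             length = rep(k, length(w)), stringsAsFactors = FALSE)
}

#' Enumerate mutation-spanning candidate peptides
#'
#' For each peptide length of the requested MHC class (class I: 8--12mers;
#' class II: 15mers), extracts every window of the mutant protein that
#' overlaps the altered residue span by at least one residue, clipped to the
#' protein bounds and deduplicated. Synonymous variants yield nothing.
#'
#' @param pair Mutant protein pair from [buildMutantProtein()].
#' @param mhcClass `"I"` or `"II"`.
#' @param config A [PipelineConfig-class].
#' @return data.frame with columns `peptide`, `length`.
#' @export
extractMutationPeptides <- function(pair, mhcClass, config = pipelineConfig()) {
  if (is.null(pair) || pair$consequence == "synonymous")
    return(data.frame(peptide = character(), length = integer()))
  ks <- peptideLengths(config, mhcClass, category = "SNV")
  out <- do.call(rbind, lapply(ks, function(k)
    windowsOverlapping(pair$mut_protein, pair$altered_start,
                       pair$altered_end, k)))
  unique(out)
}

#' Aggregate passing epitopes into antigen calls
#'
#' A mutation, fusion or TAA harboring any number of passing epitopes is
#' one antigen: epitopes are grouped by `(patient_id, mhc_class,
#' source_id)` and each non-empty group becomes a single call carrying the
#' epitope count and the best (lowest) IC50.
#'
#' @param epitopes data.frame of epitopes that passed the filter cascade,
#'   with columns `patient_id`, `mhc_class`, `category`, `source_id`,
#'   `gene_symbol`, `ic50_nM`.
#' @return data.frame with one row per antigen call: `patient_id`,
#'   `mhc_class`, `category`, `source_id`, `gene_symbol`, `n_epitopes`,
#'   `best_ic50_nM`.
#' @export
callAntigens <- function(epitopes) {
  cols <- c("patient_id", "mhc_class", "category", "source_id",
            "gene_symbol", "n_epitopes", "best_ic50_nM")
  if (!nrow(epitopes))
    return(stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 7)), cols))
  key <- paste(epitopes$patient_id, epitopes$mhc_class, epitopes$source_id,
               sep = "\r")
  sp <- split(seq_len(nrow(epitopes)), key)
  out <- do.call(rbind, lapply(sp, function(i) {
    e <- epitopes[i, , drop = FALSE]
    data.frame(patient_id = e$patient_id[1L], mhc_class = e$mhc_class[1L],
               category = e$category[1L], source_id = e$source_id[1L],
               gene_symbol = e$gene_symbol[1L],
               n_epitopes = nrow(e), best_ic50_nM = min(e$ic50_nM),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$patient_id, out$mhc_class, out$category, out$source_id), ,
      drop = FALSE]
}
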