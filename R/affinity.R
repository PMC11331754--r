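#' Deterministic hash-based affinity surrogate
#'
#' A platform-independent stand-in predictor used to exercise the filter
#' cascade: the SHA-256 digest of `"allele|peptide|salt"` supplies a uniform
#' deviate \eqn{u \in [0, 1)} (first 8 bytes, big-endian, divided by
#' \eqn{2^{64}}), and the predicted affinity is
#' \eqn{IC50 = \exp(u \ln 50000)} nM, i.e. log-uniform on (1, 50000] with
#' \eqn{u = 0 \mapsto 1} nM. Identical inputs always give identical output;
#' changing any residue re-randomizes the score (hash avalanche).
#'
#' @param peptide Character vector of peptides.
#' @param allele Character vector of allele names (recycled against
#'   `peptide`).
#' @param salt Salt string, from `PipelineConfig@surrogateSalt`.
#' @return Numeric vector of IC50 values in nM.
#' @export
surrogateAffinity <- function(peptide, allele, salt = "antigenscape") {
  n <- max(length(peptide), length(allele))
  peptide <- rep_len(peptide, n); allele <- rep_len(allele, n)
  hx <- as.character(openssl::sha256(paste0(allele, "|", peptide, "|", salt)))
  bytes <- matrix(strtoi(substring(rep(hx, each = 8L),
                                   seq(1L, 16L, by = 2L),
                                   seq(2L, 16L, by = 2L)),
                         base = 16L), nrow = 8L)
  u <- colSums(bytes / 256^(1:8))
  exp(u * log(50000))
}

#' Read a precomputed affinity table
#'
#' Adapter for affinities computed by an external MHC-binding predictor:
#' a TSV with columns `peptide`, `allele`, `ic50_nM` and no duplicate
#' (peptide, allele) pairs.
#'
#' @param path TSV path.
#' @return data.frame of class `AffinityTable`.
#' @export
readAffinityTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("peptide", "allele", "ic50_nM"), names(df))
  if (length(missing))
    stop("affinity table missing column(s): ", paste(missing, collapse = ", "))
  key <- paste(df$peptide, df$allele)
  if (anyDuplicated(key))
    stop("duplicate (peptide, allele) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (any(!is.finite(df$ic50_nM) | df$ic50_nM <= 0))
    stop("ic50_nM must be positive")
  class(df) <- c("AffinityTable", "data.frame")
  df
}

#' Score peptides against alleles
#'
#' Produces one epitope candidate per (peptide, allele) pair, scored either
#' by the deterministic surrogate or by lookup in a precomputed affinity
#' table (which errors on missing pairs).
#'
#' @param peptides data.frame with at least `peptide` and `length` columns;
#'   any further columns (category, source id, gene, VAF, expression) are
#'   carried through.
#' @param alleles Character vector of HLA alleles of one MHC class.
#' @param mhcClass `"I"` or `"II"`.
#' @param backend `"surrogate"` or an `AffinityTable` from
#'   [readAffinityTable()].
#' @param config A [PipelineConfig-class] (supplies the surrogate salt).
#' @return data.frame of candidates with `allele`, `mhc_class` and
#'   `ic50_nM` columns appended.
#' @export
predictAffinity <- function(peptides, alleles, mhcClass,
                            backend = "surrogate",
                            config = pipelineConfig()) {
  mhcClass <- match.arg(mhcClass, c("I", "II"))
  if (!nrow(peptides) || !length(alleles)) {
    out <- peptides[integer(0), , drop = FALSE]
    out$allele <- character(0); out$mhc_class <- character(0)
    out$ic50_nM <- numeric(0)
    return(out)
  }
  idx <- rep(seq_len(nrow(peptides)), times = length(alleles))
  out <- peptides[idx, , drop = FALSE]
  out$allele <- rep(alleles, each = nrow(peptides))
  out$mhc_class <- mhcClass
  if (identical(backend, "surrogate")) {
    out$ic50_nM <- surrogateAffinity(out$peptide, out$allele,
                                     config@surrogateSalt)
  } else if (inherits(backend, "AffinityTable")) {
    key <- paste(out$peptide, out$allele)
    m <- match(key, paste(backend$peptide, backend$allele))
    if (anyNA(m))
      stop("affinity table is missing pair(s): ",
           paste(unique(key[is.na(m)]), collapse = "; "))
    out$ic50_nM <- backend$ic50_nM[m]
  } else {
    stop("backend must be \"surrogate\" or an AffinityTable")
  }
  rownames(out) <- NULL
  out
}
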