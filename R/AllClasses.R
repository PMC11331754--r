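#' @import methods
#' @importFrom S4Vectors isSingleString
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom Biostrings DNAString AAString
NULL

#' Pipeline configuration
#'
#' Holds every tunable threshold of the antigen-discovery cascade. Defaults
#' reproduce the published filtering rules: MHC class I epitopes require
#' predicted IC50 < 500 nM, class II < 1000 nM; mutation-derived epitopes
#' additionally require RNA variant allele fraction > 0.6 and supporting
#' expression > 1 TPM; tumor-associated genes require normal-panel
#' \eqn{\mu + 2\sigma} < 1 TPM. All inequalities are strict: a candidate
#' sitting exactly on a threshold fails.
#'
#' @slot ic50MaxClassI numeric(1). Class I IC50 ceiling in nM (strict `<`).
#' @slot ic50MaxClassII numeric(1). Class II IC50 ceiling in nM (strict `<`).
#' @slot rnaVafMin numeric(1). RNA-VAF floor for SNV/indel epitopes (strict `>`).
#' @slot tpmMin numeric(1). Expression floor in TPM (strict `>`).
#' @slot normalMaxLt numeric(1). Normal-panel \eqn{\mu+2\sigma} ceiling (strict `<`).
#' @slot lengthsMutClassI integer. Peptide lengths for mutation/fusion class I (8--12).
#' @slot lengthsTagClassI integer. Peptide lengths for TAA class I (9--12).
#' @slot lengthsClassII integer. Peptide lengths for class II (15).
#' @slot msProbabilityMin numeric(1). Mass-spec identification probability floor (strict `>`).
#' @slot surrogateSalt character(1). Salt string for the hash-based affinity surrogate.
#'
#' @seealso [pipelineConfig()]
#' @export
setClass("PipelineConfig",
  representation(
    ic50MaxClassI    = "numeric",
    ic50MaxClassII   = "numeric",
    rnaVafMin        = "numeric",
    tpmMin           = "numeric",
    normalMaxLt      = "numeric",
    lengthsMutClassI = "integer",
    lengthsTagClassI = "integer",
    lengthsClassII   = "integer",
    msProbabilityMin = "numeric",
    surrogateSalt    = "character"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  for (s in c("ic50MaxClassI", "ic50MaxClassII", "rnaVafMin", "tpmMin",
              "normalMaxLt", "msProbabilityMin")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
  }
  for (s in c("lengthsMutClassI", "lengthsTagClassI", "lengthsClassII")) {
    v <- slot(object, s)
    if (length(v) == 0L || any(v < 1L))
      msg <- c(msg, sprintf("'%s' must be a non-empty set of positive lengths", s))
  }
  if (length(object@surrogateSalt) != 1L)
    msg <- c(msg, "'surrogateSalt' must be a single string")
  if (length(msg)) msg else TRUE
})

#' Strand-aware coding transcript model
#'
#' A coding transcript with its CDS segments (in transcription order, so for
#' minus-strand models genomic coordinates decrease along the list), the
#' strand-corrected CDS nucleotide sequence including the terminal stop
#' codon, and the derived protein (terminal stop dropped). Models whose CDS
#' length is not a multiple of three, or whose CDS carries an internal stop
#' or ambiguous base, are flagged and excluded from peptide operations.
#'
#' @slot transcriptId character(1).
#' @slot geneId character(1).
#' @slot geneSymbol character(1).
#' @slot chrom character(1).
#' @slot strand character(1), `"+"` or `"-"`.
#' @slot cdsSegments [IRanges::IRanges] of genomic CDS intervals (1-based,
#'   closed), ordered in transcription order.
#' @slot cds [Biostrings::DNAString], spliced strand-corrected CDS.
#' @slot protein [Biostrings::AAString], translation without terminal stop.
#' @slot partial logical(1). `TRUE` when CDS length is not divisible by 3.
#' @slot flags character. Quality flags, e.g. `"internal_stop"`, `"ambiguous_base"`.
#'
#' @export
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    geneId       = "character",
    geneSymbol   = "character",
    chrom        = "character",
    strand       = "character",
    cdsSegments  = "IRanges",
    cds          = "DNAString",
    protein      = "AAString",
    partial      = "logical",
    flags        = "character"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  segw <- sum(IRanges::width(object@cdsSegments))
  if (segw != length(object@cds))
    msg <- c(msg, "CDS segment widths do not sum to CDS sequence length")
  if (!object@partial && segw %% 3L != 0L)
    msg <- c(msg, "non-partial model must have CDS length divisible by 3")
  n <- length(object@cdsSegments)
  if (n > 1L) {
    o <- order(IRanges::start(object@cdsSegments))
    if (any(IRanges::end(object@cdsSegments)[o][-n] >=
            IRanges::start(object@cdsSegments)[o][-1L]))
      msg <- c(msg, "CDS segments overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Normal-tissue panel expression statistics
#'
#' Per-gene, per-organ mean (\eqn{\mu}), standard deviation (\eqn{\sigma})
#' and ceiling \eqn{\mu + 2\sigma} of TPM across a multi-organ normal
#' panel. `normalMax` is the maximum ceiling across the included organs
#' only; testis and fetal cerebellum are held out of that maximum and kept
#' separately for antigen categorization (cancer-testis vs oncofetal).
#'
#' @slot geneIds character.
#' @slot organs character. Included (non-held-out) organ names.
#' @slot mu,sigma,hi gene x organ numeric matrices.
#' @slot normalMax named numeric, per-gene max of `hi` over included organs.
#' @slot testisHi,fetalHi named numeric, held-out \eqn{\mu+2\sigma};
#'   `NA` when the organ was absent from the panel.
#'
#' @seealso [computeNormalStats()]
#' @export
setClass("NormalPanelStats",
  representation(
    geneIds   = "character",
    organs    = "character",
    mu        = "matrix",
    sigma     = "matrix",
    hi        = "matrix",
    normalMax = "numeric",
    testisHi  = "numeric",
    fetalHi   = "numeric"
  )
)

setValidity("NormalPanelStats", function(object) {
  msg <- character()
  ng <- length(object@geneIds)
  no <- length(object@organs)
  for (s in c("mu", "sigma", "hi")) {
    m <- slot(object, s)
    if (!all(dim(m) == c(ng, no)))
      msg <- c(msg, sprintf("'%s' must be a %d x %d matrix", s, ng, no))
  }
  if (length(object@normalMax) != ng)
    msg <- c(msg, "'normalMax' length must equal number of genes")
  if (!length(msg)) {
    if (any(object@hi < object@mu - 1e-12, na.rm = TRUE))
      msg <- c(msg, "'hi' must be >= 'mu'")
    if (any(object@mu < 0, na.rm = TRUE))
      msg <- c(msg, "'mu' must be non-negative")
  }
  if (length(msg)) msg else TRUE
})
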