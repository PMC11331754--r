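#' Build a pipeline configuration
#'
#' Constructor for [PipelineConfig-class] with the published defaults.
#' Mutation and fusion peptides use class I lengths 8--12; TAA peptides use
#' 9--12; class II always 15.
#'
#' @param ic50MaxClassI Class I binding-affinity ceiling, nM. Default 500.
#' @param ic50MaxClassII Class II ceiling, nM. Default 1000.
#' @param rnaVafMin RNA variant allele fraction floor for SNV/indel epitopes.
#'   Default 0.6.
#' @param tpmMin Expression floor (TPM). Default 1.
#' @param normalMaxLt Normal-panel \eqn{\mu+2\sigma} ceiling for TAG calling.
#'   Default 1.
#' @param lengthsMutClassI Integer vector of class I peptide lengths for
#'   mutations and fusions. Default `8:12`.
#' @param lengthsTagClassI Class I lengths for TAA enumeration. Default `9:12`.
#' @param lengthsClassII Class II lengths. Default `15`.
#' @param msProbabilityMin Mass-spec identification probability floor.
#'   Default 0.7.
#' @param surrogateSalt Salt for the deterministic affinity surrogate.
#'
#' @return A [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig()
#' cfg
#' @export
pipelineConfig <- function(ic50MaxClassI = 500,
                           ic50MaxClassII = 1000,
                           rnaVafMin = 0.6,
                           tpmMin = 1,
                           normalMaxLt = 1,
                           lengthsMutClassI = 8:12,
                           lengthsTagClassI = 9:12,
                           lengthsClassII = 15L,
                           msProbabilityMin = 0.7,
                           surrogateSalt = "antigenscape") {
  new("PipelineConfig",
      ic50MaxClassI = as.numeric(ic50MaxClassI),
      ic50MaxClassII = as.numeric(ic50MaxClassII),
      rnaVafMin = as.numeric(rnaVafMin),
      tpmMin = as.numeric(tpmMin),
      normalMaxLt = as.numeric(normalMaxLt),
      lengthsMutClassI = as.integer(lengthsMutClassI),
      lengthsTagClassI = as.integer(lengthsTagClassI),
      lengthsClassII = as.integer(lengthsClassII),
      msProbabilityMin = as.numeric(msProbabilityMin),
      surrogateSalt = as.character(surrogateSalt))
}

#' @describeIn pipelineConfig Peptide lengths for a given MHC class and
#'   antigen category (`"SNV"`, `"indel"`, `"fusion"` share the mutation set;
#'   `"TAA"` has its own class I set).
#' @param config A [PipelineConfig-class].
#' @param mhcClass `"I"` or `"II"`.
#' @param category Antigen category.
#' @export
peptideLengths <- function(config, mhcClass, category = "SNV") {
  mhcClass <- match.arg(mhcClass, c("I", "II"))
  if (mhcClass == "II") return(config@lengthsClassII)
  if (category == "TAA") config@lengthsTagClassI else config@lengthsMutClassI
}

#' @describeIn pipelineConfig IC50 ceiling (nM) for an MHC class.
#' @export
ic50Max <- function(config, mhcClass) {
  if (match.arg(mhcClass, c("I", "II")) == "I") config@ic50MaxClassI
  else config@ic50MaxClassII
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  IC50 < %g nM (class I) / %g nM (class II)\n",
              object@ic50MaxClassI, object@ic50MaxClassII))
  cat(sprintf("  RNA-VAF > %g; expression > %g TPM; normal mu+2sigma < %g\n",
              object@rnaVafMin, object@tpmMin, object@normalMaxLt))
  cat(sprintf("  lengths: mutation/fusion I {%s}, TAA I {%s}, II {%s}\n",
              paste(object@lengthsMutClassI, collapse = ","),
              paste(object@lengthsTagClassI, collapse = ","),
              paste(object@lengthsClassII, collapse = ",")))
  cat(sprintf("  MS probability > %g; surrogate salt '%s'\n",
              object@msProbabilityMin, object@surrogateSalt))
})
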