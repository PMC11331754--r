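#' Write epitope- and antigen-level reports
#'
#' Writes two TSVs with deterministic row order (patient, class, category,
#' gene, peptide, allele): `<prefix>_epitopes.tsv` with one row per passing
#' epitope, and `<prefix>_antigens.tsv` with one row per antigen call (a
#' mutation, fusion or TAA harboring one or more epitopes counts once).
#'
#' @param calls Antigen-call data.frame (see [callAntigens()]).
#' @param epitopes Passing epitope data.frame.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
writeAntigenReport <- function(calls, epitopes, prefix) {
  epCols <- c("patient_id", "mhc_class", "category", "source_id",
              "gene_symbol", "peptide", "allele", "ic50_nM", "novel")
  anCols <- c("patient_id", "mhc_class", "category", "source_id",
              "gene_symbol", "n_epitopes", "best_ic50_nM")
  ep <- if (nrow(epitopes)) epitopes[, epCols, drop = FALSE]
        else stats::setNames(as.data.frame(
          matrix(nrow = 0, ncol = length(epCols))), epCols)
  an <- if (nrow(calls)) calls[, anCols, drop = FALSE]
        else stats::setNames(as.data.frame(
          matrix(nrow = 0, ncol = length(anCols))), anCols)
  if (nrow(ep))
    ep <- ep[order(ep$patient_id, ep$mhc_class, ep$category,
                   ep$gene_symbol, ep$peptide, ep$allele), , drop = FALSE]
  if (nrow(an))
    an <- an[order(an$patient_id, an$mhc_class, an$category,
                   an$gene_symbol, an$source_id), , drop = FALSE]
  epPath <- paste0(prefix, "_epitopes.tsv")
  anPath <- paste0(prefix, "_antigens.tsv")
  for (p in c(epPath, anPath)) {
    d <- dirname(p)
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  }
  utils::write.table(format(ep, digits = 15, trim = TRUE, scientific = FALSE),
                     epPath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(an, digits = 15, trim = TRUE, scientific = FALSE),
                     anPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(epitopes = epPath, antigens = anPath))
}
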