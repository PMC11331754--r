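#' Read a TPM expression table
#'
#' Transcript-level tables are TSVs whose first three columns are
#' `transcript_id`, `gene_id`, `gene_symbol`, followed by one column per
#' sample; gene-level tables start with `gene_id`, `gene_symbol`. Values
#' are TPM and must be non-negative.
#'
#' @param path TSV path.
#' @param level `"transcript"` or `"gene"`.
#' @return A list of class `ExpressionMatrix` with elements `level`,
#'   `values` (numeric matrix, features x samples), and `featureMap`
#'   (data.frame mapping transcript to gene for transcript-level tables).
#' @export
readExpressionTable <- function(path, level = c("transcript", "gene")) {
  level <- match.arg(level)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  idCols <- if (level == "transcript") c("transcript_id", "gene_id", "gene_symbol")
            else c("gene_id", "gene_symbol")
  missing <- setdiff(idCols, names(df))
  if (length(missing))
    stop("expression table missing column(s): ", paste(missing, collapse = ", "))
  ids <- df[[idCols[1L]]]
  if (anyDuplicated(ids))
    stop("duplicated feature id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (level == "transcript" &&
      any(!nzchar(df$gene_id) | is.na(df$gene_id)))
    stop("transcript(s) missing gene mapping: ",
         paste(ids[!nzchar(df$gene_id) | is.na(df$gene_id)], collapse = ", "))
  vals <- as.matrix(df[, setdiff(names(df), idCols), drop = FALSE])
  storage.mode(vals) <- "double"
  if (any(is.na(vals))) stop("non-numeric or missing TPM value(s)")
  if (any(vals < 0)) stop("negative TPM value(s) found")
  rownames(vals) <- ids
  structure(list(
    level = level,
    values = vals,
    featureMap = if (level == "transcript")
      df[, idCols, drop = FALSE] else df[, idCols, drop = FALSE]
  ), class = "ExpressionMatrix")
}

#' Collapse a transcript-level matrix to gene level
#'
#' Gene TPM is the sum of the TPM of all transcripts of the gene within
#' each sample.
#'
#' @param expr An `ExpressionMatrix` at transcript level.
#' @return An `ExpressionMatrix` at gene level.
#' @export
geneExpression <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"), expr$level == "transcript")
  g <- rowsum(expr$values, group = expr$featureMap$gene_id)
  fm <- unique(expr$featureMap[, c("gene_id", "gene_symbol")])
  fm <- fm[match(rownames(g), fm$gene_id), , drop = FALSE]
  structure(list(level = "gene", values = g, featureMap = fm),
            class = "ExpressionMatrix")
}

#' Write an expression table (round-trip format of [readExpressionTable()])
#' @param expr An `ExpressionMatrix`.
#' @param path Output TSV path.
#' @export
writeExpressionTable <- function(expr, path) {
  df <- cbind(expr$featureMap,
              as.data.frame(expr$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
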