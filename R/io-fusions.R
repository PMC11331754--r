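#' Read fusion calls
#'
#' Ingests a fusion-caller TSV dialect with columns `fusion_name`,
#' `junction_reads`, `left_gene`, `left_transcript`, `left_cds_break`,
#' `right_gene`, `right_transcript`, `right_cds_break`. Breakpoints are
#' CDS coordinates (1-based): `left_cds_break` is the last retained base of
#' the left partner's CDS, `right_cds_break` the first retained base of the
#' right partner's. Self-fusions (same gene on both sides) are skipped with
#' a warning. Breakpoint bounds are validated downstream when the fusion
#' protein is built.
#'
#' @param path TSV path.
#' @param patientId Patient identifier attached to every event.
#' @return data.frame with one row per retained fusion and an `id` column
#'   `"LEFT--RIGHT:leftbreak-rightbreak"`.
#' @export
readFusionCalls <- function(path, patientId) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("fusion_name", "junction_reads", "left_gene", "left_transcript",
                "left_cds_break", "right_gene", "right_transcript",
                "right_cds_break")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("fusion table missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("junction_reads", "left_cds_break", "right_cds_break")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (any(is.na(v) & !is.na(df[[col]])))
      stop("non-integer value in column '", col, "'")
    df[[col]] <- v
  }
  if (any(df$junction_reads < 0)) stop("negative junction_reads")
  self <- df$left_gene == df$right_gene
  if (any(self)) {
    warning(sum(self), " self-fusion call(s) skipped")
    df <- df[!self, , drop = FALSE]
  }
  data.frame(
    patient_id = rep(patientId, nrow(df)),
    left_gene = df$left_gene, left_transcript = df$left_transcript,
    left_break = df$left_cds_break,
    right_gene = df$right_gene, right_transcript = df$right_transcript,
    right_break = df$right_cds_break,
    junction_reads = df$junction_reads,
    id = sprintf("%s--%s:%d-%d", df$left_gene, df$right_gene,
                 df$left_cds_break, df$right_cds_break),
    stringsAsFactors = FALSE
  )
}
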