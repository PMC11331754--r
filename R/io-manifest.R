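MB_SUBGROUPS <- c("WNT", "SHH", "Group3", "Group4")

#' Read a cohort manifest
#'
#' The manifest is a TSV with one row per patient and columns
#' `patient_id`, `subgroup` (WNT/SHH/Group3/Group4), `sex`, `age`,
#' `vital_status`, `os_days`, `pfs_days`, `hla_i`, `hla_ii` (HLA allele
#' lists semicolon-joined). Allele lists are deduplicated; empty survival
#' fields become `NA`.
#'
#' @param path Path to the manifest TSV.
#' @return A data.frame with one row per patient; `hla_i` and `hla_ii` are
#'   list-columns of character vectors.
#' @export
readCohortManifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  required <- c("patient_id", "subgroup", "sex", "age", "vital_status",
                "os_days", "pfs_days", "hla_i", "hla_ii")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id in manifest: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))
  bad <- setdiff(unique(df$subgroup), MB_SUBGROUPS)
  if (length(bad))
    stop("unknown subgroup value(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(MB_SUBGROUPS, collapse = ", "))
  splitAlleles <- function(x) {
    lapply(strsplit(x, ";", fixed = TRUE),
           function(v) unique(v[nzchar(v)]))
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "" | x == "NA", NA, x)))
  vital <- df$vital_status
  vital[!vital %in% c("alive", "deceased")] <- "unknown"
  data.frame(
    patient_id = df$patient_id,
    subgroup = factor(df$subgroup, levels = MB_SUBGROUPS),
    sex = ifelse(df$sex %in% c("M", "F"), df$sex, "unknown"),
    age_years = num(df$age),
    vital_status = vital,
    os_days = num(df$os_days),
    pfs_days = num(df$pfs_days),
    hla_i = I(splitAlleles(df$hla_i)),
    hla_ii = I(splitAlleles(df$hla_ii)),
    stringsAsFactors = FALSE
  )
}
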