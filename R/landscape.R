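ANTIGEN_CATEGORIES <- c("SNV", "indel", "fusion", "TAA")

## Gene-level antigen identity used for recurrence/sharing: the gene symbol
## for mutations and TAAs, the unordered gene pair for fusions.
antigenKey <- function(calls) {
  key <- calls$gene_symbol
  isFus <- calls$category == "fusion"
  if (any(isFus)) {
    parts <- strsplit(calls$gene_symbol[isFus], "--", fixed = TRUE)
    key[isFus] <- vapply(parts, function(p)
      paste(sort(p), collapse = "--"), character(1))
  }
  key
}

#' Per-patient antigen burden table
#'
#' One row per cohort patient (zero-filled when a patient has no calls),
#' one count column per MHC class x category combination (`I.SNV`,
#' `I.indel`, ..., `II.TAA`). An antigen restricted by both classes counts
#' in both class columns.
#'
#' @param calls Antigen-call data.frame from [callAntigens()].
#' @param manifest Cohort manifest from [readCohortManifest()].
#' @return data.frame with `patient_id`, `subgroup` and the eight count
#'   columns.
#' @export
burdenTable <- function(calls, manifest) {
  if (!NROW(calls) || is.null(calls$patient_id))
    calls <- data.frame(patient_id = character(), mhc_class = character(),
                        category = character(), stringsAsFactors = FALSE)
  unknown <- setdiff(unique(calls$patient_id), manifest$patient_id)
  if (length(unknown))
    stop("call(s) reference unknown patient(s): ",
         paste(unknown, collapse = ", "))
  out <- data.frame(patient_id = manifest$patient_id,
                    subgroup = manifest$subgroup,
                    stringsAsFactors = FALSE)
  for (cl in c("I", "II")) for (cat in ANTIGEN_CATEGORIES) {
    cnt <- table(calls$patient_id[calls$mhc_class == cl &
                                    calls$category == cat])
    col <- paste(cl, cat, sep = ".")
    out[[col]] <- as.integer(cnt[out$patient_id])
    out[[col]][is.na(out[[col]])] <- 0L
  }
  out
}

#' Targetable-fraction table
#'
#' For each subgroup, the percentage of patients carrying at least 1, 2 and
#' 3 antigens of the selected class (and optionally category). Rows are
#' monotone non-increasing across thresholds.
#'
#' @param burden Burden table from [burdenTable()].
#' @param mhcClass `"I"` or `"II"`.
#' @param category One of `"SNV"`, `"indel"`, `"fusion"`, `"TAA"`, or
#'   `NULL` to sum SNV+indel (the neoantigen total of the published
#'   tables).
#' @param thresholds Integer thresholds; default `c(1, 2, 3)`.
#' @return data.frame with `subgroup`, `n_patients` and one percentage
#'   column per threshold (`one_plus`, `two_plus`, `three_plus`, or
#'   `ge_<t>` beyond three).
#' @export
targetableFractionTable <- function(burden, mhcClass = "I", category = NULL,
                                    thresholds = c(1L, 2L, 3L)) {
  counts <- patientAntigenCounts(burden, mhcClass, category)
  groups <- levels(burden$subgroup)
  present <- groups[groups %in% as.character(burden$subgroup)]
  if (!length(present)) stop("no patients in any subgroup")
  out <- data.frame(subgroup = present,
                    n_patients = vapply(present, function(g)
                      sum(burden$subgroup == g), integer(1)),
                    stringsAsFactors = FALSE)
  nice <- c("one_plus", "two_plus", "three_plus")
  for (j in seq_along(thresholds)) {
    t <- thresholds[j]
    col <- if (t <= 3L && all(thresholds[seq_len(j)] == seq_len(j)))
      nice[t] else paste0("ge_", t)
    out[[col]] <- vapply(present, function(g)
      100 * sum(counts[burden$subgroup == g] >= t) /
        sum(burden$subgroup == g), numeric(1))
  }
  rownames(out) <- NULL
  out
}

patientAntigenCounts <- function(burden, mhcClass, category = NULL) {
  cats <- if (is.null(category)) c("SNV", "indel") else category
  cols <- paste(mhcClass, cats, sep = ".")
  missing <- setdiff(cols, names(burden))
  if (length(missing)) stop("burden table lacks column(s): ",
                            paste(missing, collapse = ", "))
  rowSums(burden[, cols, drop = FALSE])
}

#' Recurring antigens
#'
#' Groups antigen calls by gene-level identity within each subgroup
#' (`scope = "subgroup"`) or cohort-wide (`scope = "pan"`) and keeps
#' identities observed in at least two distinct patients, sorted by patient
#' count (descending), then key.
#'
#' @param calls Antigen-call data.frame.
#' @param manifest Cohort manifest.
#' @param scope `"subgroup"` or `"pan"`.
#' @return data.frame: `antigen_key`, `category`, `scope` (subgroup name or
#'   `"pan"`), `n_patients`, `patients` (semicolon-joined).
#' @export
recurringAntigens <- function(calls, manifest, scope = c("subgroup", "pan")) {
  scope <- match.arg(scope)
  empty <- data.frame(antigen_key = character(), category = character(),
                      scope = character(), n_patients = integer(),
                      patients = character(), stringsAsFactors = FALSE)
  if (!nrow(calls)) return(empty)
  calls$antigen_key <- antigenKey(calls)
  calls$scopeLabel <- if (scope == "pan") "pan" else
    as.character(manifest$subgroup[match(calls$patient_id,
                                         manifest$patient_id)])
  sp <- split(calls, paste(calls$scopeLabel, calls$category,
                           calls$antigen_key, sep = "\r"))
  out <- do.call(rbind, lapply(sp, function(g) {
    pts <- sort(unique(g$patient_id))
    data.frame(antigen_key = g$antigen_key[1L], category = g$category[1L],
               scope = g$scopeLabel[1L], n_patients = length(pts),
               patients = paste(pts, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$n_patients >= 2L, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out <- out[order(-out$n_patients, out$antigen_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shared antigens across the cohort
#'
#' An antigen identity expressed by at least two patients cohort-wide is
#' shared; the subgroup membership sets drive upset-style counts, and
#' `cross_subgroup` flags identities spanning two or more subgroups.
#'
#' @param calls Antigen-call data.frame.
#' @param manifest Cohort manifest.
#' @return data.frame: `antigen_key`, `category`, `n_patients`,
#'   `n_subgroups`, `subgroups` (semicolon-joined), `cross_subgroup`.
#' @export
sharedAntigens <- function(calls, manifest) {
  empty <- data.frame(antigen_key = character(), category = character(),
                      n_patients = integer(), n_subgroups = integer(),
                      subgroups = character(), cross_subgroup = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(calls)) return(empty)
  calls$antigen_key <- antigenKey(calls)
  calls$subgroup <- as.character(manifest$subgroup[match(calls$patient_id,
                                                         manifest$patient_id)])
  sp <- split(calls, paste(calls$category, calls$antigen_key, sep = "\r"))
  out <- do.call(rbind, lapply(sp, function(g) {
    pts <- unique(g$patient_id)
    sgs <- sort(unique(g$subgroup))
    data.frame(antigen_key = g$antigen_key[1L], category = g$category[1L],
               n_patients = length(pts), n_subgroups = length(sgs),
               subgroups = paste(sgs, collapse = ";"),
               cross_subgroup = length(sgs) >= 2L,
               stringsAsFactors = FALSE)
  }))
  out <- out[out$n_patients >= 2L, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out <- out[order(-out$n_patients, out$antigen_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Significance codes for adjusted p values
#'
#' `ns` for p >= 0.05, `*` below 0.05, `**` below 0.01, `***` below 0.001,
#' `****` below 0.0001.
#'
#' @param p Numeric vector of (adjusted) p values.
#' @return Character vector of codes.
#' @export
significanceCode <- function(p) {
  ifelse(is.na(p), NA_character_,
  ifelse(p < 0.0001, "****",
  ifelse(p < 0.001, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*", "ns")))))
}

#' Compare antigen burden among subgroups
#'
#' Overall Kruskal--Wallis test across subgroups plus all pairwise
#' two-sided Wilcoxon rank-sum tests, Bonferroni-corrected over the number
#' of pairs, with significance codes. Degenerate (all-identical) data give
#' p = 1 rather than an error.
#'
#' @param burden Burden table from [burdenTable()].
#' @param mhcClass `"I"` or `"II"`.
#' @param category Category or `NULL` for the SNV+indel neoantigen total.
#' @return List with `overall_p` and a `pairwise` data.frame (`group1`,
#'   `group2`, `p`, `p_adj`, `code`).
#' @export
subgroupComparison <- function(burden, mhcClass = "I", category = NULL) {
  counts <- patientAntigenCounts(burden, mhcClass, category)
  g <- droplevels(burden$subgroup)
  ok <- names(which(table(g) >= 2L))
  if (length(ok) < 2L)
    stop("need at least two subgroups with at least two patients")
  keep <- g %in% ok
  counts <- counts[keep]; g <- droplevels(g[keep])
  overall <- if (stats::var(counts) == 0) 1 else
    suppressWarnings(stats::kruskal.test(counts, g)$p.value)
  pairs <- utils::combn(levels(g), 2L)
  praw <- apply(pairs, 2L, function(pr) {
    x <- counts[g == pr[1L]]; y <- counts[g == pr[2L]]
    if (stats::var(c(x, y)) == 0) return(1)
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  })
  padj <- stats::p.adjust(praw, method = "bonferroni")
  list(overall_p = as.numeric(overall),
       pairwise = data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                             p = as.numeric(praw), p_adj = as.numeric(padj),
                             code = significanceCode(padj),
                             stringsAsFactors = FALSE))
}

#' Correlate antigen burden with survival
#'
#' Per subgroup, class and category, the correlation between each patient's
#' antigen count and the survival endpoint. Strata with fewer than three
#' patients with a non-missing endpoint, or with zero variance in either
#' variable, are skipped with a warning.
#'
#' @param burden Burden table.
#' @param manifest Cohort manifest (supplies `os_days` / `pfs_days`).
#' @param endpoint `"OS"` or `"PFS"`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame: `subgroup`, `mhc_class`, `category`, `endpoint`,
#'   `method`, `coefficient`, `n`.
#' @export
antigenSurvivalCorrelation <- function(burden, manifest,
                                       endpoint = c("OS", "PFS"),
                                       method = c("spearman", "pearson")) {
  endpoint <- match.arg(endpoint)
  method <- match.arg(method)
  time <- if (endpoint == "OS") manifest$os_days else manifest$pfs_days
  time <- time[match(burden$patient_id, manifest$patient_id)]
  out <- list(); skipped <- 0L
  for (sg in levels(droplevels(burden$subgroup))) {
    for (cl in c("I", "II")) for (cat in ANTIGEN_CATEGORIES) {
      sel <- burden$subgroup == sg & !is.na(time)
      x <- burden[[paste(cl, cat, sep = ".")]][sel]
      y <- time[sel]
      if (length(x) < 3L || stats::var(x) == 0 || stats::var(y) == 0) {
        skipped <- skipped + 1L
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        subgroup = sg, mhc_class = cl, category = cat,
        endpoint = endpoint, method = method,
        coefficient = suppressWarnings(stats::cor(x, y, method = method)),
        n = length(x), stringsAsFactors = FALSE)
    }
  }
  if (skipped) warning(skipped, " stratum/strata skipped (n < 3 or zero variance)")
  if (!length(out))
    return(data.frame(subgroup = character(), mhc_class = character(),
                      category = character(), endpoint = character(),
                      method = character(), coefficient = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Mass-spectrometry concordance of predicted epitopes
#'
#' MS-identified peptides are filtered to identification probability
#' strictly above `msProbabilityMin`; a predicted epitope counts as matched
#' when it equals, or is an exact substring of, a retained MS peptide of
#' the same patient.
#'
#' @param epitopes Predicted (passing) epitope data.frame with
#'   `patient_id` and `peptide`.
#' @param msPeptides data.frame (or TSV path) with `patient_id`, `peptide`,
#'   `probability`.
#' @param config A [PipelineConfig-class].
#' @return data.frame: `patient_id`, `n_predicted` (distinct predicted
#'   peptides), `n_ms_matched`, `matched` (semicolon-joined peptides).
#' @export
msConcordance <- function(epitopes, msPeptides, config = pipelineConfig()) {
  if (is.character(msPeptides))
    msPeptides <- utils::read.delim(msPeptides, stringsAsFactors = FALSE)
  ms <- msPeptides[msPeptides$probability > config@msProbabilityMin, ,
                   drop = FALSE]
  pts <- sort(unique(epitopes$patient_id))
  out <- lapply(pts, function(pt) {
    pred <- unique(epitopes$peptide[epitopes$patient_id == pt])
    obs <- toupper(ms$peptide[ms$patient_id == pt])
    matched <- if (length(obs))
      pred[vapply(toupper(pred), function(p)
        any(grepl(p, obs, fixed = TRUE)), logical(1))]
    else character()
    data.frame(patient_id = pt, n_predicted = length(pred),
               n_ms_matched = length(matched),
               matched = paste(sort(matched), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
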