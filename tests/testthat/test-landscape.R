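mkCall <- function(patient, mhc_class = "I", category = "SNV",
                   source_id = "v1", gene_symbol = "GENEA") {
  data.frame(patient_id = patient, mhc_class = mhc_class,
             category = category, source_id = source_id,
             gene_symbol = gene_symbol, n_epitopes = 1L,
             best_ic50_nM = 100, stringsAsFactors = FALSE)
}

test_that("burden table zero-fills and counts each MHC class separately", {
  mf <- mkManifest(c("WNT", "WNT", "SHH"))
  calls <- rbind(mkCall("PT01"), mkCall("PT01", source_id = "v2"),
                 mkCall("PT01", source_id = "v3"),
                 mkCall("PT01", mhc_class = "II"),
                 mkCall("PT02", category = "TAA", source_id = "G1"))
  b <- burdenTable(calls, mf)
  expect_equal(nrow(b), 3L)
  expect_equal(b$I.SNV, c(3L, 0L, 0L))
  expect_equal(b$II.SNV, c(1L, 0L, 0L))
  expect_equal(b$I.TAA, c(0L, 1L, 0L))
  expect_true(all(b[b$patient_id == "PT03",
                    grep("^I\\.|^II\\.", names(b))] == 0))
  expect_equal(nrow(burdenTable(calls[0, ], mf)), 3L)
  expect_error(burdenTable(mkCall("NOPE"), mf), "unknown patient")
})

test_that("targetable fractions count patients at each threshold", {
  mf <- mkManifest(rep("SHH", 4))
  calls <- do.call(rbind, c(
    lapply(sprintf("v%d", 1:1), function(v) mkCall("PT02", source_id = v)),
    lapply(sprintf("v%d", 1:2), function(v) mkCall("PT03", source_id = v)),
    lapply(sprintf("v%d", 1:3), function(v) mkCall("PT04", source_id = v))))
  b <- burdenTable(calls, mf)
  tf <- targetableFractionTable(b, "I")
  expect_equal(tf$one_plus, 75)
  expect_equal(tf$two_plus, 50)
  expect_equal(tf$three_plus, 25)
  # all zero and all >= 3
  expect_equal(unlist(targetableFractionTable(
    burdenTable(calls[0, ], mf), "I")[, 3:5]), c(one_plus = 0, two_plus = 0,
                                                 three_plus = 0))
})

test_that("targetable fractions are monotone non-increasing over thresholds", {
  set.seed(61)
  for (i in 1:25) {
    mf <- mkManifest(sample(c("WNT", "SHH", "Group3", "Group4"), 20, TRUE))
    b <- burdenTable(data.frame(), mf)[, 1:2]
    b$I.SNV <- rpois(20, 2); b$I.indel <- rpois(20, 1)
    b$I.fusion <- 0L; b$I.TAA <- rpois(20, 3)
    b$II.SNV <- rpois(20, 2); b$II.indel <- 0L
    b$II.fusion <- 0L; b$II.TAA <- rpois(20, 3)
    for (cls in c("I", "II")) {
      tf <- targetableFractionTable(b, cls)
      expect_true(all(tf$one_plus >= tf$two_plus))
      expect_true(all(tf$two_plus >= tf$three_plus))
    }
  }
})

test_that("recurrence requires two distinct patients within scope", {
  mf <- mkManifest(c("SHH", "SHH", "Group3"))
  # gene G in two SHH patients -> recurring in SHH
  calls <- rbind(mkCall("PT01", gene_symbol = "G", source_id = "a"),
                 mkCall("PT02", gene_symbol = "G", source_id = "b"))
  rec <- recurringAntigens(calls, mf, "subgroup")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$scope, "SHH")
  expect_equal(rec$n_patients, 2L)

  # gene split across subgroups: no subgroup recurrence, pan n = 2
  calls2 <- rbind(mkCall("PT01", gene_symbol = "G", source_id = "a"),
                  mkCall("PT03", gene_symbol = "G", source_id = "b"))
  expect_equal(nrow(recurringAntigens(calls2, mf, "subgroup")), 0L)
  pan <- recurringAntigens(calls2, mf, "pan")
  expect_equal(pan$n_patients, 2L)

  # two antigens in one patient are not recurrence
  calls3 <- rbind(mkCall("PT01", gene_symbol = "G", source_id = "a"),
                  mkCall("PT01", gene_symbol = "G", source_id = "b"))
  expect_equal(nrow(recurringAntigens(calls3, mf, "subgroup")), 0L)
})

test_that("pan recurrence patient counts sum the per-subgroup counts", {
  set.seed(62)
  mf <- mkManifest(sample(c("WNT", "SHH", "Group3", "Group4"), 16, TRUE))
  calls <- do.call(rbind, lapply(1:40, function(i)
    mkCall(sample(mf$patient_id, 1), gene_symbol = sample(LETTERS[1:5], 1),
           source_id = sprintf("v%d", i))))
  pan <- recurringAntigens(calls, mf, "pan")
  sub <- recurringAntigens(calls, mf, "subgroup")
  for (k in pan$antigen_key) {
    pts <- unique(calls$patient_id[calls$gene_symbol == k])
    bySub <- table(as.character(mf$subgroup[match(pts, mf$patient_id)]))
    expect_equal(pan$n_patients[pan$antigen_key == k], sum(bySub))
  }
})

test_that("shared antigens track subgroup membership sets", {
  mf <- mkManifest(c("WNT", "WNT", "WNT", "Group4"))
  calls <- rbind(mkCall("PT01", gene_symbol = "G1", source_id = "a"),
                 mkCall("PT02", gene_symbol = "G1", source_id = "b"),
                 mkCall("PT03", gene_symbol = "G1", source_id = "c"),
                 mkCall("PT01", gene_symbol = "G2", source_id = "d"),
                 mkCall("PT04", gene_symbol = "G2", source_id = "e"),
                 mkCall("PT01", gene_symbol = "G3", source_id = "f"))
  sh <- sharedAntigens(calls, mf)
  expect_setequal(sh$antigen_key, c("G1", "G2"))      # singleton G3 excluded
  g1 <- sh[sh$antigen_key == "G1", ]
  expect_equal(g1$n_patients, 3L)
  expect_false(g1$cross_subgroup)
  g2 <- sh[sh$antigen_key == "G2", ]
  expect_equal(g2$n_subgroups, 2L)
  expect_true(g2$cross_subgroup)
})

test_that("fusion antigen identity is the unordered gene pair", {
  mf <- mkManifest(c("SHH", "SHH"))
  calls <- rbind(mkCall("PT01", category = "fusion", gene_symbol = "GA--GB",
                        source_id = "f1"),
                 mkCall("PT02", category = "fusion", gene_symbol = "GB--GA",
                        source_id = "f2"))
  rec <- recurringAntigens(calls, mf, "subgroup")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$antigen_key, "GA--GB")
  expect_equal(rec$n_patients, 2L)
})

test_that("significance codes are exact at every boundary", {
  expect_equal(significanceCode(c(0.05, 0.04999, 0.01, 0.00999,
                                  0.001, 0.000999, 0.0001, 0.0000999, 0.2)),
               c("ns", "*", "*", "**", "**", "***", "***", "****", "ns"))
})

test_that("subgroup comparison applies Bonferroni over the pair count", {
  set.seed(63)
  mf <- mkManifest(rep(c("WNT", "SHH", "Group3", "Group4"), each = 6))
  b <- burdenTable(data.frame(), mf)[, 1:2]
  for (col in c("I.SNV", "I.indel", "I.fusion", "I.TAA",
                "II.SNV", "II.indel", "II.fusion", "II.TAA"))
    b[[col]] <- 0L
  b$I.SNV <- c(rpois(6, 1), rpois(6, 3), rpois(6, 6), rpois(6, 10))
  res <- subgroupComparison(b, "I", "SNV")
  expect_equal(nrow(res$pairwise), 6L)
  expect_equal(res$pairwise$p_adj, pmin(1, res$pairwise$p * 6))
  expect_equal(res$pairwise$code, significanceCode(res$pairwise$p_adj))
  # independent check of the overall test
  expect_equal(res$overall_p,
               stats::kruskal.test(b$I.SNV, b$subgroup)$p.value)
  # raw p 0.01 with 6 pairs -> 0.06 -> ns
  expect_equal(significanceCode(min(1, 0.01 * 6)), "ns")
  # degenerate all-identical data give p = 1
  b$I.SNV <- 2L
  expect_equal(subgroupComparison(b, "I", "SNV")$overall_p, 1)
})

test_that("survival correlation matches a textbook implementation", {
  mf <- mkManifest(rep("Group3", 3), os = c(10, 20, 30), pfs = c(5, 10, 15))
  b <- burdenTable(data.frame(), mf)[, 1:2]
  for (col in c("I.SNV", "I.indel", "I.fusion", "I.TAA",
                "II.SNV", "II.indel", "II.fusion", "II.TAA"))
    b[[col]] <- 0L
  b$I.TAA <- c(1L, 2L, 3L)
  res <- suppressWarnings(
    antigenSurvivalCorrelation(b, mf, "OS", "spearman"))
  expect_equal(res$coefficient[res$category == "TAA"], 1)
  mf2 <- mf; mf2$os_days <- c(30, 20, 10)
  res2 <- suppressWarnings(
    antigenSurvivalCorrelation(b, mf2, "OS", "spearman"))
  expect_equal(res2$coefficient[res2$category == "TAA"], -1)
  # constant counts are skipped
  expect_false("SNV" %in% res$category)

  # textbook pearson and spearman agree with the stats routines to 1e-12
  set.seed(64)
  pearsonRef <- function(x, y) {
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  for (i in 1:100) {
    x <- rnorm(20); y <- rnorm(20)
    expect_equal(stats::cor(x, y), pearsonRef(x, y), tolerance = 1e-12)
    expect_equal(stats::cor(x, y, method = "spearman"),
                 pearsonRef(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("MS concordance gates on probability and matches substrings", {
  ep <- rbind(mkEpitope(peptide = "SIINFEKL"),
              mkEpitope(peptide = "QQQQQQQQQ"))
  ms <- data.frame(patient_id = c("PT01", "PT01"),
                   peptide = c("KSIINFEKLM", "AQQQQQQQQQA"),
                   probability = c(0.9, 0.6), stringsAsFactors = FALSE)
  rep <- msConcordance(ep, ms)
  expect_equal(rep$n_predicted, 2L)
  expect_equal(rep$n_ms_matched, 1L)       # low-probability match excluded
  expect_equal(rep$matched, "SIINFEKL")
  # exact equality also matches
  ms2 <- data.frame(patient_id = "PT01", peptide = "SIINFEKL",
                    probability = 0.8)
  expect_equal(msConcordance(ep, ms2)$n_ms_matched, 1L)
  # patient with no MS rows
  ep2 <- mkEpitope(patient = "PT09", peptide = "WWWWWWWWW")
  expect_equal(msConcordance(ep2, ms)$n_ms_matched, 0L)
})
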