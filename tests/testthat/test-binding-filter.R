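test_that("surrogate affinity is deterministic, in range, and hash-derived", {
  a <- surrogateAffinity("SIINFEKL", "HLA-A*02:01", "salt")
  b <- surrogateAffinity("SIINFEKL", "HLA-A*02:01", "salt")
  expect_identical(a, b)
  expect_true(a > 1 && a <= 50000)
  # independent oracle: recompute u from a second SHA-256 implementation
  skip_if_not_installed("digest")
  hx <- digest::digest("HLA-A*02:01|SIINFEKL|salt", algo = "sha256",
                       serialize = FALSE)
  bytes <- strtoi(substring(hx, seq(1, 16, 2), seq(2, 16, 2)), 16L)
  u <- sum(bytes / 256^(1:8))
  expect_equal(a, exp(u * log(50000)), tolerance = 1e-12)
})

test_that("changing one residue re-randomizes the surrogate score", {
  set.seed(51)
  n <- 1000
  peps <- vapply(seq_len(n), function(i) randomPeptide(9), character(1))
  mutped <- vapply(peps, function(p) {
    i <- sample(9, 1)
    substr(p, i, i) <- sample(setdiff(Biostrings::AA_STANDARD,
                                      substr(p, i, i)), 1)
    p
  }, character(1), USE.NAMES = FALSE)
  s1 <- surrogateAffinity(peps, "HLA-A*02:01", "s")
  s2 <- surrogateAffinity(mutped, "HLA-A*02:01", "s")
  expect_equal(sum(s1 == s2), 0L)
  expect_true(all(s1 > 1 & s1 <= 50000))
})

test_that("affinity prediction is the cartesian product; tables look up exactly", {
  peps <- data.frame(peptide = c("AAAAAAAAK", "AAAAAAAKL", "AAAAAAKLM"),
                     length = 9L, stringsAsFactors = FALSE)
  cand <- predictAffinity(peps, c("HLA-A*01:01", "HLA-A*02:01"), "I")
  expect_equal(nrow(cand), 6L)
  expect_true(all(cand$ic50_nM > 0))

  tf <- withr::local_tempfile(fileext = ".tsv")
  grid <- expand.grid(peptide = peps$peptide,
                      allele = c("HLA-A*01:01", "HLA-A*02:01"),
                      stringsAsFactors = FALSE)
  grid$ic50_nM <- seq(10, 60, by = 10)
  utils::write.table(grid, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- readAffinityTable(tf)
  got <- predictAffinity(peps, c("HLA-A*01:01", "HLA-A*02:01"), "I", tab)
  m <- match(paste(got$peptide, got$allele), paste(grid$peptide, grid$allele))
  expect_equal(got$ic50_nM, grid$ic50_nM[m])

  tab2 <- tab[-1, ]
  class(tab2) <- class(tab)
  expect_error(predictAffinity(peps, c("HLA-A*01:01", "HLA-A*02:01"), "I", tab2),
               "missing pair")
  # duplicate keys rejected at read time
  utils::write.table(rbind(grid, grid[1, ]), tf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(readAffinityTable(tf), "duplicate")
})

test_that("filter thresholds are strict at the boundary", {
  base <- mkEpitope()
  at <- function(...) {
    e <- base
    args <- list(...)
    for (nm in names(args)) e[[nm]] <- args[[nm]]
    e
  }
  expect_equal(nrow(filterEpitopes(at(ic50_nM = 499.9))), 1L)
  expect_equal(nrow(filterEpitopes(at(ic50_nM = 500))), 0L)
  expect_equal(nrow(filterEpitopes(at(mhc_class = "II", ic50_nM = 999))), 1L)
  expect_equal(nrow(filterEpitopes(at(mhc_class = "II", ic50_nM = 1000))), 0L)
  expect_equal(nrow(filterEpitopes(at(rna_vaf = 0.6))), 0L)
  expect_equal(nrow(filterEpitopes(at(rna_vaf = 0.601))), 1L)
  expect_equal(nrow(filterEpitopes(at(expression_tpm = 1))), 0L)
  expect_equal(nrow(filterEpitopes(at(expression_tpm = 1.001))), 1L)
  # VAF rule does not apply to TAA/fusion candidates
  expect_equal(nrow(filterEpitopes(at(category = "TAA", rna_vaf = NA))), 1L)
  expect_equal(nrow(filterEpitopes(at(category = "fusion", rna_vaf = NA))), 1L)
})

randomCandidates <- function(n) {
  data.frame(
    patient_id = "PT01",
    peptide = vapply(seq_len(n), function(i) randomPeptide(9), character(1)),
    length = 9L,
    mhc_class = sample(c("I", "II"), n, TRUE),
    allele = "HLA-A*02:01",
    ic50_nM = exp(runif(n, 0, log(50000))),
    category = sample(c("SNV", "indel", "fusion", "TAA"), n, TRUE),
    source_id = "src", gene_symbol = "S1",
    rna_vaf = runif(n), expression_tpm = runif(n, 0, 5),
    stringsAsFactors = FALSE)
}

test_that("tightening any threshold yields a subset; order never matters", {
  set.seed(52)
  for (i in 1:20) {
    cand <- randomCandidates(200)
    cfg <- pipelineConfig()
    pass <- filterEpitopes(cand, cfg)
    tighter <- list(pipelineConfig(ic50MaxClassI = 200),
                    pipelineConfig(ic50MaxClassII = 300),
                    pipelineConfig(rnaVafMin = 0.8),
                    pipelineConfig(tpmMin = 2.5))
    for (tc in tighter) {
      sub <- filterEpitopes(cand, tc)
      expect_true(all(rownames(sub) %in% rownames(pass)))
    }
    # order invariance: apply the three predicates one at a time in every order
    preds <- list(
      ic50 = function(d) d[d$ic50_nM < ifelse(d$mhc_class == "I", 500, 1000), ],
      tpm = function(d) d[d$expression_tpm > 1, ],
      vaf = function(d) d[!(d$category %in% c("SNV", "indel")) | d$rna_vaf > 0.6, ])
    for (ord in list(c(1, 2, 3), c(3, 2, 1), c(2, 1, 3))) {
      d <- cand
      for (j in ord) d <- preds[[j]](d)
      expect_identical(rownames(d), rownames(pass))
    }
  }
})

test_that("novelty filter agrees exactly with a naive substring scan", {
  set.seed(53)
  for (rep in 1:4) {
    prots <- vapply(seq_len(50), function(i)
      randomPeptide(sample(30:80, 1)), character(1))
    genes <- sprintf("GEN%02d", sample(1:20, 50, TRUE))
    proteome <- mkProteome(prots, genes)
    peps <- vapply(seq_len(75), function(i) randomPeptide(9), character(1))
    # plant 25 peptides taken from proteome proteins so hits exist
    planted <- vapply(seq_len(25), function(i) {
      j <- sample(50, 1)
      s <- sample(nchar(prots[j]) - 8L, 1)
      substr(prots[j], s, s + 8L)
    }, character(1))
    peps <- c(peps, planted)
    ownGene <- sample(unique(genes), length(peps), TRUE)
    cand <- data.frame(patient_id = "PT01", peptide = peps,
                       gene_symbol = ownGene, stringsAsFactors = FALSE)

    # naive O(n*m) scans
    naiveNeo <- vapply(peps, function(p)
      !any(vapply(prots, function(pr)
        grepl(p, pr, fixed = TRUE), logical(1))), logical(1))
    naiveTaa <- vapply(seq_along(peps), function(i) {
      hits <- vapply(prots, function(pr)
        grepl(peps[i], pr, fixed = TRUE), logical(1))
      !any(hits & genes != ownGene[i])
    }, logical(1))

    gotNeo <- noveltyFilter(cand, proteome, "neoantigen")
    gotTaa <- noveltyFilter(cand, proteome, "TAA")
    expect_setequal(gotNeo$peptide, peps[naiveNeo])
    expect_identical(sort(paste(gotTaa$peptide, gotTaa$gene_symbol)),
                     sort(paste(peps[naiveTaa], ownGene[naiveTaa])))
  }
})

test_that("TAA novelty exempts hits confined to the antigen's own gene", {
  proteome <- mkProteome(c("MAAAWWWKKKLLL", "MCCCDDDEEEFFF"),
                         c("GENE_SELF", "GENE_OTHER"))
  cand <- data.frame(patient_id = "PT01",
                     peptide = c("AAAWWWKKK", "CCCDDDEEE"),
                     gene_symbol = c("GENE_SELF", "GENE_SELF"),
                     stringsAsFactors = FALSE)
  got <- noveltyFilter(cand, proteome, "TAA")
  expect_equal(got$peptide, "AAAWWWKKK")   # own-gene hit kept, cross-gene removed
  # the same peptides in neoantigen mode are both removed
  expect_equal(nrow(noveltyFilter(cand, proteome, "neoantigen")), 0L)
  # TAA mode without gene tags errors
  unt <- Biostrings::AAStringSet("MAAAWWWKKK")
  names(unt) <- "P1"
  S4Vectors::mcols(unt)$gene <- NA_character_
  expect_error(noveltyFilter(cand, unt, "TAA"), "gene")
})
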