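refCds <- "ATGGCTTACTGGAAAGTACCGGATTTCTGA"   # MAYWKVPDF + stop

test_that("missense SNV yields the oracle mutant protein and altered span", {
  set.seed(21)
  fx <- mkModel(refCds, "+", exonLens = c(12L, 18L))
  m <- fx$model
  # CDS position 5: C>A turns codon 2 GCT (A) into GAT (D)
  g <- cdsToGenomic(m, 5L)
  v <- mkVariant("chrT", g, "C", "A")
  pair <- buildMutantProtein(v, m)
  edited <- refCds
  substr(edited, 5, 5) <- "A"
  expect_equal(pair$mut_protein, translateChr(edited))
  expect_equal(pair$mut_protein, "MDYWKVPDF")
  expect_equal(pair$consequence, "missense")
  expect_equal(c(pair$altered_start, pair$altered_end), c(1L, 2L))
})

test_that("synonymous SNV is classified and produces no peptides", {
  set.seed(22)
  fx <- mkModel(refCds, "+")
  m <- fx$model
  # codon 2 GCT -> GCA: both alanine
  g <- cdsToGenomic(m, 6L)
  pair <- buildMutantProtein(mkVariant("chrT", g, "T", "A"), m)
  expect_equal(pair$consequence, "synonymous")
  expect_equal(pair$altered_start, pair$altered_end)
  expect_equal(nrow(extractMutationPeptides(pair, "I")), 0L)
})

test_that("1-nt deletion causes a frameshift matching the oracle translation", {
  set.seed(23)
  fx <- mkModel(refCds, "+", exonLens = 30L)
  m <- fx$model
  # delete CDS base 5 (left-anchored at base 4)
  g4 <- cdsToGenomic(m, 4L)
  ref2 <- substr(refCds, 4, 5)
  v <- mkVariant("chrT", g4, ref2, substr(ref2, 1, 1))
  pair <- buildMutantProtein(v, m)
  edited <- paste0(substr(refCds, 1, 4), substring(refCds, 6))
  expect_equal(pair$consequence, "frameshift")
  expect_equal(pair$mut_protein, translateChr(edited))
  expect_equal(pair$altered_start, 1L)
  expect_equal(pair$altered_end, nchar(pair$mut_protein))
})

test_that("variants on minus-strand transcripts edit the strand-corrected CDS", {
  set.seed(24)
  fx <- mkModel(refCds, "-", exonLens = c(13L, 17L))
  m <- fx$model
  # same missense as on the plus strand: CDS pos 5 C>A; on the genome the
  # reference base is the complement
  g <- cdsToGenomic(m, 5L)
  refBase <- as.character(Biostrings::subseq(fx$genome, g, g))
  expect_equal(refBase, "G")          # complement of C
  pair <- buildMutantProtein(mkVariant("chrT", g, "G", "T"), m)
  edited <- refCds
  substr(edited, 5, 5) <- "A"
  expect_equal(pair$mut_protein, translateChr(edited))
  expect_equal(pair$consequence, "missense")

  # minus-strand 1-nt deletion of CDS base 5: genomic deletion anchored
  # one base rightward (higher genomic coordinate transcribes earlier)
  g5 <- cdsToGenomic(m, 5L)
  anchor <- g5  # delete genomic base g5; anchor at g5's left neighbour
  refDel <- as.character(Biostrings::subseq(fx$genome, g5 - 1L, g5))
  v <- mkVariant("chrT", g5 - 1L, refDel, substr(refDel, 1, 1))
  pair2 <- buildMutantProtein(v, m)
  expect_equal(pair2$consequence, "frameshift")
  # oracle: genomic base g5 corresponds to CDS base genomicToCds(g5)
  delCds <- genomicToCds(m, g5)
  edited2 <- paste0(substr(refCds, 1, delCds - 1L), substring(refCds, delCds + 1L))
  expect_equal(pair2$mut_protein, translateChr(edited2))
})

test_that("in-frame insertion adds residues with a correct altered span", {
  set.seed(25)
  fx <- mkModel(refCds, "+")
  m <- fx$model
  # insert GAT (D) after CDS pos 6 (codon boundary)
  g <- cdsToGenomic(m, 6L)
  v <- mkVariant("chrT", g, substr(refCds, 6, 6),
                 paste0(substr(refCds, 6, 6), "GAT"))
  pair <- buildMutantProtein(v, m)
  edited <- paste0(substr(refCds, 1, 6), "GAT", substring(refCds, 7))
  expect_equal(pair$mut_protein, translateChr(edited))
  expect_equal(pair$consequence, "inframe_ins")
  expect_equal(pair$mut_protein, "MADYWKVPDF")
  expect_equal(c(pair$altered_start, pair$altered_end), c(2L, 3L))
})

test_that("SNV creating a stop codon truncates the protein (stop gain)", {
  set.seed(26)
  fx <- mkModel(refCds, "+")
  m <- fx$model
  # codon 4 TGG (W) -> TGA (stop): CDS pos 12 G>A
  g <- cdsToGenomic(m, 12L)
  pair <- buildMutantProtein(mkVariant("chrT", g, "G", "A"), m)
  expect_equal(pair$consequence, "stop_gain")
  expect_equal(pair$mut_protein, "MAY")
})

test_that("reference mismatch raises an error", {
  set.seed(27)
  fx <- mkModel(refCds, "+")
  g <- cdsToGenomic(fx$model, 5L)
  expect_error(buildMutantProtein(mkVariant("chrT", g, "G", "A"), fx$model),
               "reference mismatch")
})

test_that("applying then reverting a variant reproduces the reference protein", {
  set.seed(28)
  for (rep in 1:20) {
    nCod <- sample(20:50, 1)
    codons <- setdiff(names(Biostrings::GENETIC_CODE),
                      c("TAA", "TAG", "TGA"))
    cds <- paste0("ATG", paste(sample(codons, nCod, TRUE), collapse = ""),
                  "TAA")
    strand <- sample(c("+", "-"), 1)
    fx <- mkModel(cds, strand, exonLens = nchar(cds))
    m <- fx$model
    p <- sample(4:(nchar(cds) - 4L), 1)
    g <- cdsToGenomic(m, p)
    refG <- as.character(Biostrings::subseq(fx$genome, g, g))
    altG <- sample(setdiff(c("A", "C", "G", "T"), refG), 1)
    pair <- buildMutantProtein(mkVariant("chrT", g, refG, altG), m)
    expect_equal(pair$ref_protein, as.character(proteinSeq(m)))
    # revert: the mutant CDS with the edit undone is the reference CDS
    cpos <- genomicToCds(m, g)
    altC <- if (strand == "-") chartr("ACGT", "TGCA", altG) else altG
    mutCds <- cds
    substr(mutCds, cpos, cpos) <- altC
    reverted <- mutCds
    substr(reverted, cpos, cpos) <- substr(cds, cpos, cpos)
    expect_identical(reverted, cds)
  }
})

test_that("mutation peptide windows match the closed form and brute force", {
  set.seed(29)
  # interior missense with >= 11 flanking residues: 50 class I windows
  prot <- randomPeptide(40)
  pair <- list(mut_protein = prot, altered_start = 15L, altered_end = 16L,
               consequence = "missense")
  pepI <- extractMutationPeptides(pair, "I")
  expect_equal(nrow(pepI), 50L)       # sum over k = 8..12 of k windows
  expect_equal(nrow(extractMutationPeptides(pair, "II")), 15L)

  # boundary clipping: first residue of a 9-residue protein, k = 9
  shortPair <- list(mut_protein = randomPeptide(9), altered_start = 0L,
                    altered_end = 1L, consequence = "missense")
  cfg <- pipelineConfig(lengthsMutClassI = 9L)
  expect_equal(nrow(extractMutationPeptides(shortPair, "I", cfg)), 1L)

  # oracle property over random (L, p, k)
  for (i in 1:1000) {
    k <- sample(8:15, 1)
    L <- sample(k:60, 1)
    p <- sample(seq_len(L), 1) - 1L   # 0-based altered position
    prot <- randomPeptide(L)
    pair <- list(mut_protein = prot, altered_start = p, altered_end = p + 1L,
                 consequence = "missense")
    got <- extractMutationPeptides(pair, "I",
                                   pipelineConfig(lengthsMutClassI = k))
    # brute force: all k-windows containing 0-based position p
    starts <- which(vapply(seq_len(L - k + 1L), function(w)
      p >= w - 1L && p <= w + k - 2L, logical(1)))
    brute <- unique(substring(prot, starts, starts + k - 1L))
    expect_setequal(got$peptide, brute)
    expect_equal(nrow(got), length(unique(brute)))
  }
})

test_that("antigen aggregation keys on (patient, class, source)", {
  ep <- rbind(
    mkEpitope(patient = "PT01", peptide = "AAAAAAAAK", source_id = "v1"),
    mkEpitope(patient = "PT01", peptide = "AAAAAAAKL", source_id = "v1",
              ic50 = 50),
    mkEpitope(patient = "PT01", peptide = "AAAAAAKLM", source_id = "v1",
              mhc_class = "II"),
    mkEpitope(patient = "PT02", peptide = "AAAAAAAAK", source_id = "v1"))
  calls <- callAntigens(ep)
  expect_equal(nrow(calls), 3L)
  c1 <- calls[calls$patient_id == "PT01" & calls$mhc_class == "I", ]
  expect_equal(c1$n_epitopes, 2L)
  expect_equal(c1$best_ic50_nM, 50)
  # same source in two patients -> two calls
  expect_equal(sum(calls$patient_id == "PT02"), 1L)
  expect_equal(nrow(callAntigens(ep[0, ])), 0L)
})
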