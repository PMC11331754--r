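# AntigenScape

Tumor antigen discovery and cohort antigen-landscape analytics in R, built
for cancer immunogenomics: which peptides presented by a patient's tumor
could T cells recognize, and how much of that antigen repertoire is shared
across patients?

The package predicts three classes of candidate tumor antigens from bulk
tumor sequencing inputs and then summarizes them cohort-wide. It was
designed around pediatric brain tumor cohorts (medulloblastoma, with its
four molecular subgroups WNT, SHH, Group 3 and Group 4), but the machinery
is generic.

## The method

**Neoantigens (SNVs/indels).** Each somatic variant is applied to every
expressed, usable transcript model it overlaps; the mutant CDS is
translated (frameshifts in the shifted frame to the first stop), and every
8–12mer (MHC class I) or 15mer (class II) window overlapping an altered
residue becomes a candidate epitope. Candidates are scored per patient HLA
allele and pass the filter cascade

&nbsp;&nbsp;IC50 < 500 nM (class I) / < 1000 nM (class II),&nbsp;
RNA-VAF > 0.6,&nbsp; expression > 1 TPM,

followed by an exact-substring novelty screen against the reference
proteome. A mutation harboring any number of passing epitopes counts as a
*single* neoantigen.

**Fusion antigens.** Fusion calls (CDS-coordinate breakpoints) are
assembled into chimeric coding sequences; junction-spanning and
frame-shifted novel peptides — never substrings of either parent protein —
go through the same scoring and filtering (no VAF gate).

**Tumor-associated antigens (TAAs).** For every gene, the normal-tissue
panel supplies a per-organ expression ceiling μ + 2σ of TPM. A
tumor-associated gene (TAG) requires μ + 2σ < 1 TPM in all 29 included
organs, tumor gene TPM (sum over isoforms) > 1 and its top isoform > 1 TPM.
All 9–12mers / 15mers of its expressed isoforms are scored; the novelty
screen here removes only peptides shared with *other* genes' proteins.
Testis and fetal cerebellum are held out of the panel ceiling and instead
classify immunogenic TAAs as cancer-testis (testis μ+2σ > 1) or oncofetal
(fetal cerebellum μ+2σ > 1).

**Landscape analytics.** Per-patient antigen burden by MHC class and
category; targetable fractions (% of patients with ≥1/≥2/≥3 antigens);
recurring antigens (gene-level identity in ≥2 patients of a subgroup) and
shared antigens (≥2 patients cohort-wide, upset-style subgroup sets);
Kruskal–Wallis and pairwise Wilcoxon rank-sum tests with Bonferroni
correction and `ns`/`*`/`**`/`***`/`****` codes; Spearman/Pearson
correlation of burden with OS/PFS; and concordance with mass-spectrometry
peptides (identification probability > 0.7, substring matching).

MHC binding prediction is pluggable: a deterministic SHA-256-based
surrogate (log-uniform IC50 on (1, 50000] nM) keeps everything hermetic,
and precomputed affinity tables from an external predictor (NetMHCpan-class
tools) can be dropped in via `readAffinityTable()`.

Because the real patient data such pipelines consume are access-controlled,
the package ships a synthetic-cohort generator (`generateCohortData()`)
that emits every input format — genome FASTA, GTF, proteome, VCFs, fusion
tables, expression matrices, normal panel, HLA genotypes, MS peptides —
with a planted truth manifest, so every stage is testable end to end.

## Worked example

```r
library(AntigenScape)

dir <- tempfile("cohort")
generateCohortData(dir, simParams(), seed = 1)   # 200 genes, 24 patients
res <- runPipeline(dir)                          # ~30 s, surrogate predictor

table(res$calls$category, res$calls$mhc_class)
#>           I II
#>   fusion 22 21
#>   indel  24 23
#>   SNV    96 96
#>   TAA    77 77
```

Each count is an antigen call: a mutation, fusion or TAA with at least one
passing epitope for that MHC class. The per-patient burden and the
TAA targetable-fraction table:

```r
head(res$burden[, c("patient_id", "subgroup", "I.SNV", "I.indel", "I.fusion", "I.TAA")])
#>   patient_id subgroup I.SNV I.indel I.fusion I.TAA
#> 1       PT01      WNT     4       1        1     1
#> 2       PT02      WNT     4       1        1     5
#> 3       PT03      WNT     4       1        1     3

res$targetable$taa_I
#>   subgroup n_patients one_plus  two_plus three_plus
#> 1      WNT          3      100  66.66667   66.66667
#> 2      SHH          7      100  85.71429   57.14286
#> 3   Group3          6      100 100.00000  100.00000
#> 4   Group4          8      100 100.00000   37.50000
```

so e.g. every simulated Group 3 patient carries at least three class-I
TAAs. Recurring antigens and survival correlation behave the same way as
the other tables:

```r
head(res$recurring[res$recurring$scope != "pan", ], 3)
#>   antigen_key category  scope n_patients                 patients
#> 1      SG0006      TAA Group4          5 PT18;PT20;PT22;PT23;PT24
#> 2      SG0198      TAA Group3          5 PT11;PT12;PT13;PT14;PT16
#> 3      SG0198      TAA Group4          5 PT17;PT18;PT19;PT20;PT21

head(res$survival[res$survival$category == "TAA", ], 2)
#>   subgroup mhc_class category endpoint   method coefficient n
#> 1      WNT         I      TAA       OS spearman          -1 3
#> 2      WNT        II      TAA       OS spearman          -1 3
```

(The generator plants survival times anti-correlated with TAG burden, which
these coefficients recover.)

A command-line wrapper with `simulate`, `run`, `neoantigen`, `fusion`,
`taa` and `landscape` subcommands is installed at
`inst/exec/antigenscape.R`.

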