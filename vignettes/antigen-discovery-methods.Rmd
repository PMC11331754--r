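---
title: "Tumor antigen discovery with AntigenScape: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor antigen discovery with AntigenScape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AntigenScape)
```

# Scope and model

AntigenScape predicts candidate T-cell antigens of a tumor from three
sources and analyzes them cohort-wide. The unit of prediction is the
**epitope candidate**: a peptide, an HLA allele, an MHC class, a predicted
binding affinity (IC50, nM) and the genomic event it derives from. The
unit of reporting is the **antigen call**: an event (mutation, fusion or
tumor-associated gene) carrying at least one epitope that survived every
filter, counted once per patient and MHC class regardless of how many of
its peptides pass.

## Neoantigens

A somatic variant is applied to each transcript model whose CDS contains
it, provided the transcript is expressed above the TPM floor in that
patient and the model is usable (complete codons, no internal stop, no
ambiguous base). Variant application happens in spliced-CDS space:
minus-strand models edit the reverse-complemented alleles. The mutant CDS
is translated with the standard genetic code up to the first stop codon;
frameshifts translate the shifted frame, and a variant destroying the stop
codon reads through to the end of the stored CDS (3'UTR sequence is not
carried, a deliberate simplification — such read-through proteins are
truncated at the annotation boundary and the generator never plants them).

The altered residue span is the minimal interval of mutant-protein
residues that differ from reference, computed by trimming the common
prefix and suffix; for frameshift and stop-loss it extends to the mutant
protein's end, and a pure truncation (stop gain at the substituted codon)
has an empty span and therefore yields no peptides — the truncated
sequence contains nothing the reference did not. Candidate peptides are
all k-mer windows overlapping the span by at least one residue, for k in
8–12 (class I) or 15 (class II), clipped to the protein and deduplicated
across isoforms of the same variant. A closed form gives the expected
window count for a single altered residue at 0-based position p of an
L-residue protein: `min(p, L-k) - max(0, p-k+1) + 1`; the test suite
checks the implementation against brute-force enumeration over random
(L, p, k).

## Fusion antigens

Fusion calls arrive with CDS-coordinate breakpoints (the genomic-to-CDS
mapping is the caller's concern): the fused CDS keeps the left partner
through `left_break` and appends the right partner from `right_break`. The
fusion is in frame when the retained right bases sit in their native codon
frame (`left_break mod 3 == (right_break - 1) mod 3`); otherwise the right
side is retranslated in the shifted frame. When the left break falls
inside a codon the chimeric codon's residue is assigned to the junction
and treated as novel. Peptides are windows that overlap the novel span or
straddle the junction; any window occurring verbatim in either parent
protein is discarded, which makes the degenerate self-fusion (a protein
split at a codon boundary and rejoined) yield exactly zero peptides.
Fusion epitopes skip the VAF gate — there is no allele fraction for a
junction — and use the smaller of the two partner genes' TPM as expression
support.

## Tumor-associated antigens

The normal panel is summarized per gene and organ as mu + 2*sigma of TPM,
with sigma the sample standard deviation (n-1 denominator; single-sample
organs get sigma = 0 with a logged caveat — the estimator is undefined
there and 0 is the conservative completion). The panel ceiling
`normal_max` is the maximum over the 29 included organs; testis and fetal
cerebellum are held out and never disqualify a gene. A tumor-associated
gene (TAG) in a patient requires:

* `normal_max` strictly below 1 TPM,
* tumor gene TPM (sum of isoform TPMs) strictly above 1,
* the top isoform itself strictly above 1 TPM.

All thresholds are strict on both sides, so a value exactly at 1 always
disqualifies. This is the stricter of the two readings the rule admits
(the published wording uses both "< 1" and "excluded > 1"); one
consistent convention beats two. Genes absent from the panel are treated
as ceiling 0 but flagged `unverified_normal` — absence of evidence is
surfaced, not silently trusted.

TAG peptides are all 9–12mers / 15mers of every expressed usable isoform.
After filtering, an immunogenic TAA is classified cancer-testis when its
held-out testis ceiling exceeds 1 TPM, else oncofetal when the fetal
cerebellum ceiling exceeds 1 TPM, else other. The published analysis
assigned these categories by visual clustering of expression heatmaps; the
1 TPM ceiling rule here is an explicit operationalization of that cluster
boundary and is documented as such.

## Filters

The cascade is a pure conjunction of strict inequalities — IC50 below
500 nM (class I) or 1000 nM (class II), expression above 1 TPM, RNA-VAF
above 0.6 for SNV/indel epitopes only — so the passing set is invariant to
the order the predicates are applied, a property the tests assert. The
0.6 VAF gate is applied to indels as well as SNVs: one stated cascade, one
behavior. The class II 1000 nM "cutoff score" is read as strict `<` for
symmetry with the class I rule. Percentile-rank filtering, proteasomal
cleavage and TAP transport scores are intentionally out of scope.

The novelty screen is exact fixed-string substring search against the
reference proteome (case-insensitive after uppercasing), not approximate
homology. Mutation and fusion peptides are removed on any hit — a mutant
peptide present anywhere in the normal proteome is by definition not
novel, including in its own gene. TAA peptides are removed only when
found in a protein of a *different* gene, since a TAA's own peptides are
necessarily present in its own protein entries; this requires a
`gene=SYMBOL` tag on every proteome FASTA header.

## Binding prediction backends

The package does not reimplement neural-network MHC predictors. Two
backends exist behind one interface: a precomputed affinity table (TSV of
peptide, allele, ic50_nM; missing pairs are an error, never silently
imputed), and a deterministic surrogate for hermetic testing. The
surrogate maps SHA-256("allele|peptide|salt") to u in [0,1) via the first
8 bytes big-endian over 2^64 and returns IC50 = exp(u * ln 50000), i.e.
log-uniform on (1, 50000] nM. The 53-bit double mantissa represents the
8-byte fraction identically on every IEEE-754 platform, so results are
bit-reproducible. The surrogate has no biochemical meaning; it exists so
that filter logic, aggregation and landscape analytics can be exercised
with realistic pass rates (about 57% of class I candidates fall below
500 nM under a log-uniform law) and perfect determinism.

## Cohort analytics

Antigen identity for recurrence and sharing is the gene symbol (the
unordered gene pair for fusions), matching how oncoprint rows are usually
keyed. Recurring = at least two distinct patients within a subgroup (or
cohort-wide in pan scope); shared = at least two patients cohort-wide,
with the subgroup membership set retained for upset-style summaries.
Subgroup burden comparisons use Kruskal–Wallis overall and pairwise
two-sided Wilcoxon rank-sum tests with Bonferroni correction over the
number of pairs and the usual significance codes (`ns` at adjusted
p >= 0.05, then `*`, `**`, `***`, `****` at 0.05/0.01/0.001/0.0001). The
source analysis names the *signed-rank* test for pairwise comparisons, but
subgroups are independent groups of unequal size, where a paired test is
undefined; the rank-sum test is the coherent choice and the divergence is
deliberate. Degenerate all-identical data return p = 1 rather than
erroring.

Survival correlation is computed on per-patient (antigen count, time)
pairs per subgroup, class and category, Spearman by default (robust to
survival-time skew; Pearson available), requiring at least three patients
with a non-missing endpoint and non-zero variance. No binning or
aggregation is applied; published coefficients derived from undocumented
aggregation are not reproduction targets. Mass-spectrometry concordance
keeps MS peptides with identification probability strictly above 0.7 and
counts a predicted epitope as matched when it equals or is an exact
substring of a retained MS peptide of the same patient.

# The synthetic cohort

`generateCohortData()` writes a complete, internally consistent input set
from one seed lineage (reference at `seed`, panel at `seed + 1`, cohort at
`seed + 2`, all below 2^31), so regenerating one component never perturbs
the others and two generations are byte-identical.

Defaults — the package's reference study conditions — are: 200 genes with
a 25% chance of a second isoform, proteins of 40–120 residues, 1–3 exons,
both strands, on two synthetic chromosomes; a 29-organ panel with 3
samples per organ plus held-out testis and fetal cerebellum; 24 patients
split 3/7/6/8 across WNT/SHH/Group 3/Group 4, mirroring the published
18/46/41/65 cohort proportions at desk scale. Planted effects keep at
least a two-fold margin from every strict threshold so boundary decisions
never flip truth labels: planted TAGs have normal ceilings below 0.5 TPM
(background genes are kept above 1.5 TPM in every organ, so they can never
qualify), tumor expression above 2 TPM, and planted variants carry VAF in
0.72–0.95 with supporting expression above 2 TPM. Each patient receives
1–5 planted TAGs (the variation drives the survival-correlation
analytics: OS is generated as 3600 − 450 × TAG-count plus noise), four
missense, one synonymous and one frameshift-deletion variant plus one
low-VAF missense decoy, and one fusion alternating in-frame and
frameshift breakpoints. Frameshift deletions are only planted where the
shifted frame leaves at least 15 mutant residues including a novel one,
so every planted non-synonymous variant yields candidate peptides in both
MHC classes. Indels are planted on plus-strand transcripts (the
minus-strand indel path is exercised by hand-built models in the unit
tests); SNVs are planted on both strands. MS peptide lists embed
substrings of known planted mutant epitopes at probability above 0.75,
with sub-threshold decoys.

What the generator does *not* emulate: realistic gene structure, UTRs,
mutational signatures, germline variation, expression covariance between
organs, and real MHC binding specificity. Passing tests therefore
demonstrate the correctness of the rules and plumbing, not predictive
performance on real tumors.

# Numerical and convention choices

* CDS segments are stored as 1-based closed `IRanges` in transcription
  order, the Bioconductor convention; VCF positions map in directly.
* Indels spanning an intron boundary are skipped with a warning rather
  than guessed at.
* The stored CDS includes the terminal stop codon; the stored protein does
  not. Proteins are compared as character vectors of codepoints when
  computing altered spans, with the suffix trim capped so it never eats
  the prefix (relevant for repeat-region indels).
* Panel statistics are computed via sums and sums of squares with a
  non-negativity clamp before the square root; the acceptance tests
  compare the resulting qualify decisions against a literal `mean + 2*sd`
  reimplementation on random panels.
* Report writers sort on (patient, class, category, gene, peptide, allele)
  so identical inputs give byte-identical files.

# Problem sizes

The test suite runs the rule-oracle comparison on 50 random 200-gene
panels, the window oracle on 1000 random (L, p, k), the novelty oracle on
100 peptides against 50-protein proteomes, and the full pipeline twice on
the default 24-patient cohort for the determinism check; the complete
suite takes under two minutes on one CPU. These sizes were chosen as the
smallest at which every rule path and aggregation branch is exercised with
planted ground truth.

# Known limitations

* No phasing of nearby variants; each variant is applied to the reference
  CDS independently.
* No germline subtraction; inputs are assumed somatic.
* Stop-loss read-through ends at the annotated CDS.
* The novelty screen is exact-match, as in the original design; a
  one-mismatch neighborhood would be stricter but is out of scope.
* Affinity tables must cover every requested (peptide, allele) pair;
  partial tables error by design.
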