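---
title: "Variant interpretation for NGS-based expanded carrier screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant interpretation for NGS-based expanded carrier screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cilioscreen)
```

## The screening problem

Expanded carrier screening asks, for a healthy individual, whether they
carry heterozygous disease alleles in any gene of a recessive-disease
panel, and, for a couple, whether both partners carry qualifying alleles
in the *same* gene — the configuration that gives a 25% risk of affected
offspring. `cilioscreen` implements this interpretation workflow for a
118-gene ciliopathy panel: ciliopathies are rare recessive disorders of
the primary cilium with pronounced locus heterogeneity, which makes them
a demanding test bed — many genes, many very rare variants, and a large
fraction of missense variation that cannot be classified confidently in
a person with no phenotype.

The pipeline runs in four stages, each a module of the package:

1. **Call QC** (`sample_quality_gate()`, `preprocess_filter()`,
   `train_call_classifier()`, `score_calls()`) — remove low-quality
   samples and calls, then separate true calls from residual calling
   artefacts with a linear support vector machine.
2. **Tier classification** (`classify_cohort()`) — assign each
   high-confidence call to PATHOGENIC, NOVEL_LOF, STRONG_VUS or
   EXCLUDED by an ordered rule set.
3. **Prioritization** (`missense_score()`, `vipur_category()`,
   `prioritize()`, `spectrum_comparison()`) — rank strong VUS for future
   functional work using gene-level knowledge and protein-structure
   scores.
4. **Cohort reporting** (`build_report()` and friends) — carrier
   frequencies per tier set, per-individual burden, recurrence,
   trio-based phase inference, couples at risk, and observed versus
   Hardy–Weinberg-expected carrier frequencies.

## Quality control

Two rule-based gates come first. A *sample* is unusable when less than
85% of the exome target is covered at ≥ 20×
(`exome_cov_fraction_min = 0.85`, `exome_cov_depth = 20`); the
comparison is strict, so a fraction of exactly 0.85 passes. A *call* is
excluded when its alternate-read fraction is below 16% or its depth
below 20× (`alt_fraction_min = 0.16`, `depth_min = 20`); both are read
as inclusive minima, so a call sitting exactly on a cut-off is retained.
Counts are conserved at every stage — retained + excluded = input — and
the suite asserts monotonicity: raising either cut-off can only shrink
the retained set.

Residual artefacts that pass the hard cut-offs are handled by a linear
SVM over per-call quality features (depth, alternate-read fraction and,
when available, strand balance and mean base quality). Features are
z-standardized with constants stored in the model, so a serialized model
(JSON) reproduces its decisions exactly. Decision ties (`w·x + b = 0`)
classify as true calls: at the QC stage the screening favors
sensitivity, since the interpretation rules downstream are the
specificity filter. The fit is delegated to libsvm (via e1071) with a
linear kernel; the package stores only the weight vector, bias and
standardization constants, which makes scoring self-contained.

## The tier rules

Classification applies the first matching rule, with an audit trail of
the criteria that fired:

1. *Whitelist*: a curated recurring disease allele (e.g. *BBS1*
   p.M309R, *KIAA0586* p.R143Kfs\*4) is PATHOGENIC regardless of its
   population frequency. These alleles exceed the rarity cut-off yet are
   unambiguous disease alleles — rarity is evidence, not a definition.
2. *Benign override*: a ClinVar benign/likely-benign assertion excludes
   the call, even when HGMD labels it DM. Database conflicts of this
   shape are frequent enough that treating the benign assertion as
   controlling is the conservative choice for a screening report; the
   flag `benign_override` makes the behaviour configurable.
3. *Rarity*: gnomAD MAF above 0.1% (`maf_max = 0.001`) excludes. A
   missing MAF means the allele is unobserved in gnomAD and counts as 0;
   the boundary is inclusive (MAF of exactly 0.001 survives).
4. A loss-of-function call (nonsense, frameshift, canonical splice)
   with a ClinVar P or HGMD DM assertion is PATHOGENIC (PVS1 + PM2 with
   prior disease association).
5. A non-LOF call asserted P in ClinVar *and* DM in HGMD, with
   sufficient supporting information, is PATHOGENIC. "Sufficient" is
   operationalized as the absence of the `clinvar_limited` input flag —
   the judgement itself is upstream curation, not something the package
   can derive.
6. A LOF call with a ClinVar VUS assertion stays a strong VUS: the
   existing uncertain assertion blocks both the pathogenic and the
   novel-LOF route.
7. A LOF call absent from both databases is NOVEL_LOF — formally a
   likely-pathogenic PVS1 + PM2 combination, reported as its own tier
   because whether to disclose such alleles is a policy question.
8. ClinVar LP with limited supporting information is a strong VUS.
9. An HGMD DM/DM? assertion without ClinVar P support is a strong VUS.
10. The predictor ensemble: CADD ≥ 20, M-CAP ≥ 0.025 and at least 4 of
    the 7 remaining tools (SIFT, Polyphen2, LRT, MutationAssessor,
    MutationTaster, FATHMM, PROVEAN) calling the variant deleterious.
    CADD and M-CAP are counted separately because they partly
    incorporate the other tools; a call with either score missing
    cannot pass. Both score boundaries are inclusive.
11. Everything else is EXCLUDED.

ClinVar `CONFLICTING` deserves a note: it is treated as *unclassified*
for the pathogenic rules (conflicts are mostly VUS-versus-P/LP, too weak
to report) but it does *not* make a LOF variant "novel" — the variant
has been seen and argued about, so rule 7 requires a genuinely absent
assertion. Conflicting calls remain eligible for rules 9–10.

Tiers are mutually exclusive and exhaustive. The suite checks this as a
property, and additionally checks the whole ordered implementation
against an independent brute-force evaluator (every rule predicate
computed separately, precedence resolved afterwards) on 10^5 randomized
calls — zero discrepancies allowed.

## Prioritizing strong VUS

Most missense variants in healthy individuals are not disease alleles.
Two orthogonal signals rank the strong VUS:

* the **missense score** of a gene, m/M — missense P/LP disease alleles
  over all P/LP disease alleles. A gene whose known disease alleles are
  almost all truncating (score near 0) makes a novel missense VUS
  unlikely to be causal; the score is undefined when M = 0 and such
  genes are flagged `NO_PLP_DATA` and cannot qualify.
* the **structural deleteriousness score** in [0, 1] per variant:
  \> 0.7 strongly suggests deleteriousness, > 0.5 suggests it, ≤ 0.5 is
  neutral, and variants without structural coverage are `UNSCORED`.
  Both cut-offs are strict inequalities.

A variant is *first priority* when its gene's missense score exceeds 0.1
and its structural score exceeds 0.7. Output ordering is a deterministic
total order (first priority, then structural score descending, ties by
gene and variant key), and recurrent observations collapse to unique
variants before counting.

`spectrum_comparison()` contrasts the cohort's per-gene truncating vs
missense proportions with a patient cohort's. The divergence measure is
the total-variation distance over the two categories, i.e. the absolute
difference of the missense proportions — chosen because with two
categories it is the simplest distance with a direct reading (1 =
opposite spectra, 0 = identical).

## Cohort statistics

An individual is a carrier for a tier set when they hold ≥ 1 variant in
the set; zygosity does not change carrier status. A couple is at risk
when some gene carries qualifying variants in *both* partners; two
same-gene variants proven *cis* within one partner collapse to a single
carrier allele and never put a couple at risk on their own. Risk is
prospective: offspring genotypes cannot remove a couple. The couples
denominator is always the number of couple records in the pedigree
input, never a constant.

Phase inference uses the classical trio argument: if a child carries
both or neither of a parent's two same-gene variants, they were *cis* in
the parent; exactly one means *trans*; missing child genotypes are
uninformative.

For a fully penetrant single-locus recessive disease of prevalence K,
Hardy–Weinberg equilibrium gives allele frequency q = √K and expected
carrier fraction 2q(1−q). The per-gene report compares observed carrier
frequencies against this expectation — the observed/expected ratio is
the quantitative form of the argument that carrier frequencies in
healthy cohorts are far above what disease prevalence predicts, implying
underestimated prevalence, non-viable genotype combinations, or
presumed-LOF alleles that do not cause disease.

Display percentages round half-up at the printed precision (base R's
`round()` is round-half-even, which would turn a mean of 7.375 into
7.37); raw fractions are always retained in the JSON report.

## The synthetic cohort generator

Real screening cohorts cannot be redistributed, so the package is
exercised end-to-end on synthetic data with the statistical structure
the pipeline assumes. Defaults describe the primary study conditions:
395 individuals forming 177 couples (21 consanguineous) plus 41 single
parents, one sequenced child per couple, mean coverage 286.9×, a mean of
9.32 calls per individual in the range 1–24, and a tier mix of 1.3%
pathogenic, 1.0% novel LOF, 7.2% strong VUS, 90.5% benign (the
proportions implied by 48/38/265 qualifying calls among 3702
high-confidence calls). `uk_cohort_params()` switches to the
confirmation-cohort settings (999 individuals, 57.2×, 7.38
calls/individual). Since only the mean and range of the per-individual
call count are known, the count is drawn from a negative binomial
(size 3) truncated to [1, 24] — a standard overdispersed stand-in.

Predictor scores come from a latent-variable model: each variant has a
deleteriousness z (normal, shifted up for qualifying tiers), and tool t
scores λ_t·z + √(1−λ_t²)·ε. The loadings (0.85, 0.80, 0.60, 0.75, 0.70,
−0.15, 0.80 for the seven tools; 0.85 and 0.70 for CADD and M-CAP) were
fixed once so that pairwise score correlations span roughly −0.13 to
0.68 — one anti-correlated tool reproduces the well-known fact that the
tools disagree substantially, which is the motivation for requiring a
qualified majority rather than any single predictor. The suite asserts
the empirical correlations stay inside [−0.2, 0.8], the calibrated range
widened for sampling error.

Each call carries a hidden truth tier, and annotations are generated so
the classifier recovers it on artifact-free data — which is what makes
truth-recovery tests possible. Artifact calls (`artifact_rate`, default
0.1) violate the 16%/20× cut-offs and look artefactual in the auxiliary
features. Parents' same-gene variants are placed on haplotypes A/B and
children inherit one haplotype per parent, so Mendelian transmission
holds by construction and phase inference can be validated against the
planted configuration.

What the generator does *not* emulate: linkage between variants, gene
length (variants land on genes uniformly), site-specific error profiles,
population structure in allele frequencies, and relatedness beyond the
declared couples and trios. Passing tests on synthetic data therefore
demonstrate the correctness of the *rules and accounting*, not the
field performance of the SVM or of the predictor ensemble on real
variants.

## The deterministic benchmark cohort

`generate_table1_fixture()` builds, without randomness, a 395-individual
cohort whose classification outcome is known exactly: 48 pathogenic
calls (26 LOF / 22 other) in 43 carriers, 38 novel-LOF calls in 37
carriers, 265 strong VUS (262 missense/non-coding/in-frame observations
over 239 unique variants with 23 recurring in exactly two individuals,
plus 3 LOF variants with ClinVar VUS assertions) in 197 carriers each
holding 1–5; 2 consanguineous couples share reportable variants in one
gene (one via a pathogenic pair, one via a pathogenic/novel-LOF pair —
so the pathogenic-only tier set finds 1 and the reportable set 2) and 7
non-consanguineous couples share strong VUS in one gene. Distractor
calls violating each individual rule are interleaved and must classify
EXCLUDED. Every rule branch of the classifier is exercised positively
and negatively by at least one row. Because the construction is
hand-placed rather than sampled, the acceptance checks on these counts
are exact equalities, not tolerances.

Two deliberate choices in its construction: the pedigree holds 177
couple records and 41 single parents (the carrier-frequency and
couple-risk denominators are taken from the pedigree, whatever it
contains), and the 38 novel-LOF calls sit in 37 individuals so that
reportable carriers total exactly 80 alongside the 43 pathogenic
carriers.

## Numerical and design choices

* All rule boundaries at published cut-offs are inclusive (CADD ≥ 20,
  M-CAP ≥ 0.025, MAF ≤ 0.001, alt fraction ≥ 0.16, depth ≥ 20); the
  structural-score categories are strict (> 0.5, > 0.7).
* SVM decision ties retain the call; identical feature rows always land
  on the same side.
* `variant_key` is `chrom:pos:ref:alt` with 1-based VCF-style
  coordinates; indel normalization (left alignment) is expected from
  upstream annotation. Multi-allelic VCF records split into one call
  per alternate allele.
* Predictor inputs are categorical calls (DELETERIOUS / TOLERATED /
  MISSING), not raw scores: per-tool numeric cut-offs are an annotation
  concern and differ between tool versions.
* Degenerate inputs: empty cohorts yield all-zero reports; N = 0
  denominators report NA; a single-class SVM training set is an error,
  not a degenerate fit.
* Test problem sizes: the oracle-equivalence check runs on 10^5
  randomized calls, property suites on cohorts of 120–500 individuals,
  and the benchmark accounting on the fixed 395-individual cohort —
  sizes chosen to exercise every branch while keeping the default suite
  fast.

## Limitations

The package interprets *annotated* calls: alignment, variant calling,
and annotation against gnomAD/ClinVar/HGMD/CADD and the structural
scorer are upstream, and their errors propagate. The ACMG/AMP subset
implemented is the operational core used for screening healthy
individuals (where phenotype-match and segregation criteria are
unusable), not a full 28-criteria engine. Residual risk after a
negative test is deliberately not computed: with this many VUS, a
post-test probability would suggest a precision the data cannot
support.
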