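# cilioscreen

Variant interpretation for NGS-based expanded carrier screening of
recessive disease genes, built around a 118-gene ciliopathy panel.

Carrier screening reports, for healthy individuals, heterozygous disease
alleles in recessive genes, and flags *couples at risk* — both partners
carrying a qualifying allele in the same gene (25% affected-offspring
risk). Interpreting variants in people with no phenotype is the hard
part: segregation and phenotype-match evidence is unavailable, so most
rare missense variation ends up as variants of uncertain significance
(VUS). `cilioscreen` implements the full interpretation workflow as
tested, reusable functions:

* **Call QC** — a sample-level coverage gate (< 85% of the exome at
  ≥ 20× fails), rule-based per-call cut-offs (alternate-read fraction
  ≥ 16%, depth ≥ 20×), and a linear SVM separating true calls from
  calling artefacts.
* **Tier classification** — an ordered rule set assigning each
  high-confidence call exactly one tier with an audit trail:
  - `PATHOGENIC`: PVS1 (loss of function) + PM2 (gnomAD MAF ≤ 0.1%)
    with a ClinVar *P* or HGMD *DM* assertion; or a non-LOF variant
    asserted *P* AND *DM* with sufficient supporting information; or a
    whitelisted recurring disease allele (kept at any MAF);
  - `NOVEL_LOF`: very rare LOF absent from both databases
    (PVS1 + PM2, formally likely pathogenic);
  - `STRONG_VUS`: very rare and either HGMD *DM/DM?*, ClinVar *LP*
    with limited evidence, a LOF with a ClinVar VUS assertion, or an
    in-silico ensemble pass — CADD ≥ 20 AND M-CAP ≥ 0.025 AND ≥ 4 of 7
    tools (SIFT, Polyphen2, LRT, MutationAssessor, MutationTaster,
    FATHMM, PROVEAN) deleterious;
  - `EXCLUDED`: common alleles, ClinVar-benign assertions (which
    override HGMD *DM*), and everything failing every rule.
* **VUS prioritization** — per-gene missense score m/M (missense P/LP
  disease alleles over all P/LP), structural deleteriousness categories
  (score > 0.7 strongly deleterious, > 0.5 deleterious), first-priority
  VUS = ms-score > 0.1 AND structural score > 0.7, and per-gene
  cohort-vs-patient variant-type spectrum divergence.
* **Cohort reporting** — carrier frequencies per tier set, per-individual
  burden, variant recurrence and unique-variant accounting, trio-based
  cis/trans phase inference ("both or neither inherited ⇒ cis"),
  couples at risk with a consanguineous stratum, and per-gene observed
  vs Hardy–Weinberg-expected carrier frequency (prevalence K ⇒
  q = √K, expected carrier fraction 2q(1−q)).
* **Synthetic cohorts** — a seeded generator with latent-factor
  predictor correlations, planted QC artifacts, Mendelian trios and
  hidden truth tiers, plus a fully deterministic 395-individual
  benchmark cohort whose tier accounting is known exactly.

See `vignettes/carrier-screening-methods.Rmd` for the model, parameter
defaults and design rationale.

## Worked example

```r
library(cilioscreen)

fx <- generate_table1_fixture()            # deterministic benchmark cohort
cc <- classify_cohort(fx$calls, fx$whitelist, default_thresholds())
rep <- build_report(cc$calls, fx$pedigree, fx$sample_ids,
                    panel = ciliopathy_panel())
print(rep)
#> Cohort report: 395 individuals, 366 post-QC calls
#>   PATHOGENIC    48 (LOF 26 / other 22)
#>   NOVEL_LOF     38 (LOF 38 / other 0)
#>   STRONG_VUS   265 (LOF 3 / other 262)
#>   EXCLUDED      15 (LOF 2 / other 13)
#>   carriers [pathogenic]: 43/395 (10.9%)
#>   carriers [reportable]: 80/395 (20.3%)
#>   carriers [vus]: 197/395 (49.9%)
#>   couples at risk [pathogenic]: 1/177 (consanguineous 1/21)
#>   couples at risk [reportable]: 2/177 (consanguineous 2/21)
#>   couples at risk [vus]: 7/177 (consanguineous 0/21)
```

Reading: ~11% of these healthy individuals carry a pathogenic ciliopathy
allele, ~20% carry something reportable (pathogenic or novel LOF), and
half carry at least one "strong" VUS — variants too suspicious to
dismiss but not reportable, which is what limits the negative predictive
value of the screen. Two consanguineous couples share reportable
variants in one gene; seven further couples share strong VUS in one
gene, so a reproductive risk cannot be excluded for them.

The `analysis/` directory runs the same pipeline as a narrative
workflow on simulated cohorts (`01_simulate.R` → `05_report.R`, outputs
under `results/`):

```sh
Rscript analysis/01_simulate.R --seed=1
Rscript analysis/02_qc.R
Rscript analysis/03_classify.R
Rscript analysis/04_prioritize.R
Rscript analysis/05_report.R
```

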