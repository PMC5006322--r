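# miratlas

Build a microRNA body atlas from small-RNA sequencing and nominate
tissue-specific, tissue-enriched and sex-specific miRNAs — candidate serum
biomarkers of organ injury — by three independent statistical routes, then
validate serum qPCR panels against the atlas.

Tissue-restricted miRNAs (think miR-122 in liver, miR-208 in heart,
miR-216/217 in pancreas) leak into blood when their tissue is damaged, so a
reliable catalogue of which miRNA belongs to which tissue is the foundation
of miRNA safety biomarker work. `miratlas` covers the full desk-side chain:

* **Read processing** — 3' adapter trimming (prefix-match rule, profile
  presets for 16–35, 14–24 and ≥17 nt windows), collapsing identical reads
  to `NNN_#_x#` records, exact substring mapping against precursor hairpins
  (all occurrences, no mismatches), isomiR naming
  (`<precursor>_<arm>_<start>_<end>`), composite identities for ambiguous
  sequences (`let-7a-5p;let-7f-5p`), `-pre` fallback for hairpin-only hits,
  cross-species fallback tiers, and even division of multi-locus counts.
* **Quantification** — animal-to-tissue summation, tissue-to-organ maximum
  over a configurable 23-tissue / 14-organ map, TMM normalisation with a
  low-count filter, and TPM with zero-imputation and ceiling.
* **Three classifiers** —
  1. an expression-quorum rule: count > 1 in ≥ 8 of 10 animals defines an
     "expressed" tissue; one expressed tissue ⇒ *specific*, 2–5 ⇒
     *enriched*, and a 4-of-5 versus 0-of-5 sex split ⇒ *sex-specific*;
  2. a KL non-negative matrix factorisation of the miRNA × organ matrix
     (X ≈ WH, multiplicative updates) whose organ-dominant factors seed
     candidates that a two-component Poisson mixture (EM) refines to
     tissue-level calls;
  3. read-fraction thresholds: > 90 % of a miRNA's reads in one tissue ⇒
     *specific*, > 50 % ⇒ *enriched* (tissue groups supported); plus
  4. a one-vs-rest quasi-Poisson test (DEMiR) with log-Q3 offsets,
     shrunken Pearson dispersions and a nominal p < 0.01 cut.

  `venn_compare()` reports every overlap among the methods' call sets.
* **Serum qPCR module** — Ct quality control (10-cycle clearance over
  detected NTC/no-RT controls, melt-curve filter), spike-in–normalised
  ΔΔCt fold changes (FC = 2^−ΔΔCt; vehicle- or pre-dose-referenced), a
  repeated-measures two-way ANOVA with within-animal AR(1) errors fitted by
  GLS (estimates and 95 % CIs as in-model contrasts against the reference
  cell), and Ct-versus-sequencing correlation (perfect agreement = −1).
* **Synthetic data with planted truth** — seeded generators for tiered
  precursor sets, isomiR reads, Poisson atlas count matrices (23 tissues,
  5 + 5 animals, 215 samples by default) and AR(1) qPCR time courses, so
  every stage above is testable without external data.

## Worked example

Simulate a small atlas with three planted miRNAs — one liver-specific, one
brain-enriched (all four brain tissues), one heart-specific — over a shallow
Poisson(1) background, and run all three classifiers:

```r
library(miratlas)

design <- atlas_design(
  n_mirnas = 50,
  enrichment_patterns = c(
    list("liver",
         c("cerebrum", "cerebellum", "hippocampus", "brainstem"),
         "heart"),
    rep(list(character(0)), 47)),
  lambda_high = 500, lambda_low = 1, seed = 42)
atlas <- generate_atlas_counts(design)
atlas$counts
#> atlas_counts: 50 miRNAs x 215 samples (23 tissues, 14 organs)

tissue_mat <- aggregate_tissue(atlas$counts)
rule  <- classify_rule_based(atlas$counts)
pct   <- classify_percentage(tissue_mat, organ_map = default_organ_map())
demir <- demir_one_vs_rest(atlas$counts)

subset(pct, label != "none")[, c("mirna", "label", "tissues", "score")]
#>     mirna    label                                   tissues    score
#> 1 mir_001 specific                                     liver 96.13426
#> 2 mir_002 enriched brainstem;cerebellum;cerebrum;hippocampus 99.18192
#> 3 mir_003 specific                                     heart 96.15160

head(demir[order(demir$p), c("mirna", "tissue", "log2fd", "p")], 4)
#>        mirna    tissue   log2fd             p
#> 1    mir_001     liver 8.903590 5.247241e-187
#> 53   mir_003     heart 8.864995 1.340319e-177
#> 1102 mir_002 brainstem 2.842035  2.009360e-06
#> 952  mir_002  cerebrum 2.730301  4.324301e-06
```

The read-fraction route recovers exactly the planted three. The quorum rule
and the nominal-threshold DEMiR screen each add a few background flukes at
this shallow background (that is inherent to fixed thresholds, not a bug) —
and the three-way intersection is exactly the planted truth:

```r
sets <- list(
  rule       = rule$mirna[rule$label %in% c("specific", "enriched")],
  percentage = pct$mirna[pct$label %in% c("specific", "enriched")],
  demir      = demir_enriched_set(demir))
venn_compare(sets)[, c("sets", "n", "members")]
#>                    sets n                 members
#> ...
#> 7 rule;percentage;demir 3 mir_001;mir_002;mir_003
```

A serum qPCR time course with a planted 8-fold (log2 FC = 3) rise at 8 h:

```r
lfc <- matrix(0, 2, 5); lfc[2, 3] <- 3
study <- generate_qpcr_study(groups = c("vehicle", "treated"),
                             timepoints = c(1, 4, 8, 24, 48),
                             n_animals = 6, true_log2fc = lfc,
                             rho = 0.5, sigma = 0.5, seed = 7)
fc  <- spike_normalized_fold_change(study, reference = "vehicle")
fit <- fit_repeated_anova(fc)
subset(fit, group == "treated")[, c("timepoint", "log2fc", "ci_low",
                                    "ci_high", "fc", "p")]
#>   timepoint  log2fc ci_low ci_high    fc        p
#> 1         1 -0.0824 -0.704   0.539 0.944 7.91e-01
#> 2         4 -0.2285 -0.850   0.393 0.854 4.64e-01
#> 3         8  2.7455  2.124   3.367 6.706 7.68e-12
#> 4        24 -0.1072 -0.729   0.514 0.928 7.30e-01
#> 5        48 -0.3392 -0.961   0.282 0.790 2.78e-01
attr(fit, "rho")
#> [1] 0.658
```

The 8 h fold change is estimated at 6.7× (CI 4.4–10.3×), the other cells'
intervals cover 1, and the AR(1) correlation is recovered near its true
0.5.

`make_demo_fixtures()` writes a complete toy bundle (precursor FASTA +
annotation, reads, counts, truth, qPCR wells, YAML config) and
`run_atlas()` executes the whole pipeline from such a config, writing call
tables, the venn table and a seed-stamped run log; re-running with the same
seed is byte-identical.

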