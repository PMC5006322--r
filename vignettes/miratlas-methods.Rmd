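---
title: "Methods: building a miRNA body atlas and calling tissue-specific miRNAs"
author: "miratlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a miRNA body atlas and calling tissue-specific miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miratlas)
```

## The problem

Tissue-restricted microRNAs are attractive safety biomarkers: a miRNA
expressed almost exclusively in, say, pancreas or heart will leak into serum
when that organ is injured, giving an organ-resolved signal that ordinary
clinical chemistry often lacks. Building such a catalogue from small-RNA
sequencing of a whole-body tissue panel requires (i) turning raw reads into
miRNA/isomiR counts against precursor hairpins, (ii) normalising and
aggregating counts across animals, tissues and organs, and (iii) deciding,
by more than one statistical route, which miRNAs are tissue-specific or
tissue-enriched. `miratlas` implements the three independent classification
routes that are commonly combined for this purpose — an expression-quorum
rule with NMF/Poisson-mixture support, a read-fraction threshold rule, and a
one-vs-rest quasi-Poisson test — together with the upstream read processing
and a downstream serum qPCR biomarker module, and ships synthetic-data
generators with planted truth so the whole chain is testable end to end.

The default experimental layout mirrors a rat body atlas: 23 tissues drawn
from 14 organs (brain contributes cerebrum, cerebellum, hippocampus and
brainstem; kidney, muscle, stomach and intestine are also multi-tissue),
sampled in 5 males and 5 females. Testis, ovary and uterus exist in one sex
only, so the full design has $20 \times 10 + 3 \times 5 = 215$ samples. The
23-to-14 tissue/organ map is a reconstruction from the organ and tissue
panel — only the brain grouping and the two totals are fixed by the design —
and is therefore fully user-overridable (`default_organ_map()`).

## Read processing

**Trimming.** The 3' adapter (default `TGGAATTCTCGGGTGCCAAGG`) is located by
an exact match to its first 8 bases and the read truncated there. Three
named profiles bundle the length windows in common use: `maastricht`
(16–35 nt), `niehs` (14–24 nt) and `lilly` (minimum 17 nt, reads containing
`N` discarded). A read with no adapter hit cannot be distinguished from an
insert that ran through the adapter, so by default it is kept when its
length already fits the window; a strict mode discards such reads. Quality
trimming is configuration-only and a no-op on FASTA input.

**Collapsing and mapping.** Identical sequences within a sample collapse to
one record with id `NNN_#_x#` (sample code, running integer, multiplicity).
Collapsed sequences are matched against precursor hairpins by exact
substring search — no mismatches, no gaps — reporting *all* occurrences,
overlapping ones included, in 1-based inclusive coordinates. The matcher is
indexed by read length but is required (and tested) to agree exactly with a
naive scan of every hairpin window.

**isomiR assignment.** Each locus yields a label: the mature miRNA name
when the locus is *associated with* an annotated mature window, otherwise
`<precursor>-pre`. Association uses a tolerance rule: the locus start must
lie within ±3 nt of the window start and the locus must cover at least 75%
of the window. These two knobs operationalise the usual extent of isomiR
5'/3' end variation and are configurable; there is no community-standard
cut-off, so the defaults are a design choice, not a constant of nature.
A sequence hitting several loci receives the lexicographically sorted,
`;`-joined composite of all its labels (e.g. `let-7a-5p;let-7f-5p`), making
ambiguity explicit rather than resolving it arbitrarily. The isomiR name
`<precursor>_<arm>_<start>_<end>` (e.g. `mir-127_3p_57_78`) is taken from
the first locus in (precursor, start) order. The arm of a locus that
overlaps no mature window is assigned by the hairpin midpoint. Sequences
unmatched in the first species tier fall through to later tiers (rat, then
mouse, human, C. elegans in the motivating design); the claiming tier is
recorded. Multi-locus counts are divided evenly across loci (fractions
allowed), so totals are conserved exactly — the suite checks conservation at
every stage.

## Quantification

Animal-level counts are summed to tissue level; organ level takes the
*maximum* over an organ's tissues, so a hippocampus-only signal still
registers at the brain column. Two normalisations are provided:

* **TMM.** Implemented from the method's canonical definition (trimmed,
  weighted mean of per-gene log2 ratios against a reference; 30% trim on M,
  5% on A, inverse-variance weights; reference defaults to the sample whose
  upper quartile is closest to the mean). Factors are returned on the
  effective-library-size scale, so an exact 2x copy of the reference gets
  factor 2 and identical normalised counts. One numerical caveat: with the
  canonical weights, scaling a library by $c$ scales its factor by $c$ only
  to ~1% (the per-gene weights shift with depth); `weighted = FALSE` makes
  the identity exact. The low-count filter then keeps a miRNA iff at least
  one sample reaches 10 normalised reads.
* **TPM** with optional zero-imputation at 1.0 (before totals are taken)
  and optional ceiling to integers for count-based downstream models.
  Without those two perturbations, columns sum to exactly $10^6$.

All percentiles anywhere in the package use linear interpolation
(`quantile` type 7), stated once and reused.

## Three classification routes

**Expression-quorum rule.** A tissue is *expressed* for a miRNA when a
quorum of its animals (ceiling of 80%, i.e. 8 of 10, or 4 of 5 for
single-sex tissues) exceed a raw count of 1. Exactly one expressed tissue
gives `specific`; 2–5 gives `enriched` (the upper bound is deliberately
loose and configurable — a biomarker enriched in a handful of organs can
still be useful); a tissue where one sex meets a 4-of-5 quorum while the
other sex has no expressing animal gives `sex_specific`. Precedence is
specific > sex_specific > enriched. The classifier runs on raw counts by
default, with a normalised mode available, and is tested for exact
agreement with a brute-force evaluation of the stated thresholds.

**NMF + Poisson mixture.** The miRNA-by-organ matrix $X \ge 0$ is
factorised as $X \approx WH$ by multiplicative updates minimising the
generalised Kullback–Leibler divergence — the natural objective for counts.
The rank defaults to one factor per organ (14); 10 seeded random restarts
are run and the best objective kept; convergence is declared at a relative
objective change below $10^{-6}$ or 500 iterations. A factor whose `H` row
concentrates more than half its mass on one organ is an organ-private
pattern, and the miRNAs whose `W` row peaks at that factor become
organ-specific candidates. Each candidate is then refined at tissue
resolution with a two-component Poisson mixture fitted by EM to its
animal-level counts: the high-intensity component models expression, the
low-intensity one background. EM stops when the log-likelihood moves less
than $10^{-8}$ (or 1000 iterations); components are ordered so
$\lambda_{high} \ge \lambda_{low}$; if BIC prefers a single component the
fit collapses (no high/low separation, no call). A tissue is *high* when a
majority of its animals have posterior probability of the high component of
at least 0.5; one high tissue refines the candidate to `specific`, several
to `enriched`.

**Read-fraction thresholds.** On the tissue-level matrix, a tissue carrying
more than 90% of a miRNA's total reads makes it `specific`, more than 50%
`enriched`. Because a signal genuinely spread over one organ's tissues
(e.g. the four brain tissues) never crosses 50% in any single tissue, the
classifier optionally evaluates tissue groups from the organ map; a
multi-tissue group crossing a threshold yields an `enriched` call over its
members. Zero-total miRNAs are flagged, not silently labelled.

**One-vs-rest quasi-Poisson (DEMiR test).** For each (miRNA, tissue),
counts are regressed on an indicator of the target tissue with a per-sample
offset $\log Q_3$ (third quartile of that sample's counts; samples with
$Q_3 = 0$ fall back to their mean count). For a single binary factor the
quasi-Poisson fit is closed-form — each group's rate is its count total over
its offset total — and the implementation uses that form; the test suite
verifies it is algebraically identical to `glm(..., family =
quasipoisson)`. Per-miRNA Pearson dispersions $\hat\phi$ are shrunk toward
a 10%-trimmed pooled value with prior weight $d_0 = 10$:
$\tilde\phi = (d_0\,\bar\phi + \mathrm{df}\,\hat\phi)/(d_0 + \mathrm{df})$,
an empirical-Bayes-style compromise chosen because the exact weighting
behind published shrunken-dispersion quasi-likelihood tools is not fully
specified; the report labels it as an approximation. The tissue effect is
tested by $F = \Delta\mathrm{deviance}/\tilde\phi$ on $(1, \mathrm{df} +
d_0)$ degrees of freedom. Significance is nominal $p < 0.01$ with no
multiplicity correction by default (a BH mode exists but is off), matching
the screening character of the analysis. Zero-variance miRNAs get $p = 1$
and a flag. A miRNA enters the method's enriched set when it is
significantly *up* in at least one tissue.

`venn_compare()` reports the size and membership of every intersection of
the methods' call sets, mirroring the usual three-institution overlap
figure.

## Serum qPCR biomarker module

Ct values pass QC when they clear every *detected* negative control
(no-template and no-RT) by at least 10 cycles — an undetected control
imposes no constraint — and the assay's melt curve has a single peak.
Fold changes are spike-normalised:
$\Delta Ct = Ct_{target} - Ct_{spike}$ per sample,
$\Delta\Delta Ct$ subtracts the reference mean, and
$FC = 2^{-\Delta\Delta Ct}$. Two reference conventions are supported, as
both occur in practice: vehicle group at the matched timepoint, or the
earliest (pre-dose) timepoint within each group. Undetected Cts are
excluded, never imputed at 40.

The repeated-measures analysis fits group-by-timepoint cell means by
generalised least squares with within-animal AR(1) correlation (compound
symmetry optional), estimated by REML via `nlme::gls`. "Auto-correlated"
alone does not pin down a structure; AR(1) is the natural default for a
time course. Each cell's fold change is reported as the *contrast* between
its cell mean and the reference cell mean, with the standard error taken
from the joint covariance of the two means. This matters: subtracting the
observed reference mean from the data before fitting leaves the reference's
sampling noise unmodelled, and in our simulations the naive approach's
nominal 95% intervals covered only ~84%, versus 93–96% for the contrast
formulation. Because the contrast cancels any per-timepoint constant, the
fit is identical whether it receives raw $\Delta Ct$-derived values or
already-normalised log2 fold changes. Reference cells are fixed at fold
change 1.

`correlate_qpcr_seq()` correlates Ct with $\log_{10}(\mathrm{count}+1)$
(Pearson, with Spearman co-reported so the transform choice is auditable);
a perfect agreement gives $-1$ since Ct falls as abundance rises.

## The synthetic-data generators

`generate_precursor_set()` builds random 60–90 nt hairpins with 19–25 nt
mature windows and tiered species sets (later tiers always contain at least
one tier-exclusive hairpin). `generate_reads()` emits mature subsequences
with 5'/3' end offsets drawn from an isomiR profile, plus adapter, with
full provenance. `generate_atlas_counts()` draws each (miRNA, animal,
tissue) cell from $\mathrm{Poisson}(\lambda_{high} \cdot s)$ in planted
tissues and $\mathrm{Poisson}(\lambda_{low} \cdot s)$ elsewhere ($s$ a
per-sample depth factor), zeroing the opposite sex for planted sex-specific
miRNAs; counts are pure Poisson to match the mixture model the classifiers
assume, with an optional negative-binomial size knob for overdispersion
experiments. `generate_qpcr_study()` produces per-animal time series whose
noise is stationary AR(1) with *marginal* sd `sigma` (innovation sd
$\sigma\sqrt{1-\rho^2}$), plus spike-in wells and NTC/no-RT/water controls.

What the generators deliberately do not emulate: sequencing errors,
ligation bias, batch structure, library-composition artefacts, and
between-miRNA count correlation. Green tests therefore demonstrate that the
algorithms implement their definitions and recover planted structure under
the stated noise model — not that the biological conclusions of any
particular real dataset would reproduce.

## Validation design and problem sizes

The validation suite exercises, per run: the exact matcher against a naive
scan (1,000 queries vs 50 hairpins), isomiR semantics on a hand-built
panel, the quorum rule against brute force (200 random 50 x 23-tissue
atlases at background intensities 0.5–8), mixture recovery on 80/20
Poisson(2)/Poisson(300) draws against a grid-search ML oracle, NMF
exactness on rank-1 input and 15/15 recovery of a planted 3-organ block
design, the DEMiR test's size (2,000 null miRNAs at Poisson(50), 10
animals x 14 organs) and power (500 replicate 10-fold enrichments at base
intensity 20, spread across organs so the Q3 offsets stay representative —
planting a quarter of the miRNAome in one tissue would shift that tissue's
offsets and absorb the signal, a physically meaningless configuration),
AR(1) interval coverage (500 replicates at $\rho \in \{0, 0.5, 0.9\}$), and
byte-identical re-runs of the demo pipeline.

The cross-method comparison atlas plants 30 of 300 miRNAs (15 specific,
15 enriched as whole multi-tissue organs, covering all 23 tissues) at
$\lambda_{high} = 500$ over a *silent* background ($\lambda_{low} = 0$).
This emulates the defining property of a tissue-specific miRNA — absence
elsewhere — and is the regime in which all three classifiers can be held to
high sensitivity *and* precision simultaneously: with any appreciable
diffuse background, a screen run at nominal $p < 0.01$ over thousands of
null one-vs-rest tests (and, likewise, the quorum rule's own small
false-call rate over 270 x 23 null cells) necessarily admits false
positives, which is precisely why null behaviour is measured separately by
the brute-force-agreement and type-I-calibration checks rather than folded
into the recovery benchmark.

## Known limitations

* Exact matching only: a read with a single sequencing error is dropped,
  biasing against low-abundance isomiRs; the motivating pipelines share
  this property for quantification.
* The mature-association rule (±3 nt / 75% overlap) is a convention;
  shifting it reclassifies borderline isomiRs between mature and `-pre`.
* The dispersion-shrinkage weighting and the F-test's denominator degrees
  of freedom are a stated approximation to published quasi-likelihood
  practice, calibrated empirically (type-I error ~0.010 at nominal 0.01)
  rather than derived.
* GLS interval coverage relies on REML's plug-in $\hat\rho$; at very small
  animal numbers or $\rho$ near 1 intervals can undercover slightly
  (~93–96% observed at the simulated sizes).
* The default organ map beyond brain is a plausible reconstruction and
  should be overridden when the real panel differs.
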