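---
title: "Evaluating DBS-derived wgaDNA exomes by genotype concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DBS-derived wgaDNA exomes by genotype concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbsconcord)
```

## The evaluation problem

Dried blood spots (DBS) archived by neonatal screening programmes hold
nanogram quantities of DNA; exome sequencing of them requires whole-genome
amplification (WGA), which can introduce allele dropout (one allele of a
heterozygote fails to amplify, so the call looks homozygous) and
amplification errors. Whether such calls are usable is decided by comparing
them, subject by subject, with calls from a high-quality whole-blood (WB)
reference, while replicated sequencing of the same WB DNA sets the
technical baseline: variability beyond the WB-vs-WB level is attributed to
the amplified sample.

`dbsconcord` implements the post-calling half of that study design. The
upstream steps — alignment, duplicate marking, the two callers, VQSR — are
out of scope; their outputs (multi-sample VCFs with PASS/tranche FILTER
values) are this package's inputs, and the synthetic generator emulates
them.

## Pipeline model

**Merge.** The two callers are merged at the record level by PASS priority
on the `(chrom, pos)` anchor: the priority caller's PASS records always
win; the secondary caller contributes its PASS records at keys the priority
caller filtered or never emitted. "Overlap" is deliberately defined as an
identical anchor, not REF-interval overlap: both callers run on the same
alignments in multi-sample mode, so allele representations at a site share
an anchor, and interval semantics would require an allele normalisation
step the merge rule does not contemplate. When both callers PASS a key with
different alleles, the priority record is kept wholesale — the rule is
stated at the call level, and no allele-level reconciliation is attempted.

**Classification.** Each ALT is typed against REF by length: SNP (both
length 1), insertion (ALT longer), deletion (ALT shorter), complex (equal
length above 1, i.e. an MNP). Records are then classed: single-ALT records
take their allele's type; multi-ALT all-SNP records remain SNPs; multi-ALT
records with only insertions/deletions are multiallelic-complex; any
mixture (or any complex allele) is multiallelic-mixed. The two multiallelic
classes are reported as one `multiallelic` group. This typing was
cross-checked against `bcftools` `%TYPE` on a fixture covering every rule
before the expectations were frozen. A single-ALT MNP has no bucket in the
four-group taxonomy; we report it under `multiallelic` and count it in the
`n_single_alt_complex` attribute rather than absorbing it silently, since
equal-length substitutions are neither insertions nor deletions and
behave like multi-nucleotide events in callers.

**Filtering.** Two criteria, both strict inequalities, both defaulting to
the study's settings:

* variant-level: average sample depth `site_DP / n_samples > 20`, where
  `n_samples` is the full roster size of the pilot's calling — not the
  number of non-missing calls — because the multi-sample depth is emitted
  over all samples included in the calling;
* sample-level: `minGQ_WB > 30`, the minimum genotype quality across the
  designated reference-standard (WB_ref) samples, with a missing reference
  call or absent GQ contributing 0. This keeps sites where the high-quality
  standard is itself confidently genotyped, whatever the other samples
  show.

Strictness matters at the boundary: average depth exactly 20 or
`minGQ_WB` exactly 30 removes the record. Filtering is a pure subset
operation — idempotent, order-preserving, monotone in both thresholds.

Whether WB_ref_replica samples should join the reference-standard set is
not decidable from the study design alone; the manifest's
`is_reference_standard` flag (and the generator's `replica_is_reference`
switch, default `FALSE`) makes it an explicit user choice instead of a
hard-coded guess.

**Concordance.** Each compared site falls into exactly one of five
categories: concordant (identical unordered genotypes, including both calls
missing), het/homo discordant, homo/homo discordant (0/0 vs 1/1), other
discordant (any allele index ≥ 2 in a differing pair), and missing (a
no-call on one side only). Two conventions deserve note:

* *Denominator.* The rate is `100 · concordant / all sites` of the group,
  with both-missing sites in the numerator and one-sided no-calls in the
  denominator. This is the only denominator under which the five categories
  are a partition; since low-coverage sites can inflate the both-missing
  count pre-filtering, the report also emits all five category fractions so
  any alternative denominator can be recomputed.
* *Identity precedence.* Identical genotypes carrying higher alternate
  alleles (1/2 vs 1/2) are concordant, not "other": the other-discordant
  category applies only to differing pairs.

Half-calls (`./1`) are normalised to missing at read time — the category
scheme only distinguishes a present diploid call from a no-call, and a
sixth half-present category is undefined. Phased separators are accepted
and compared unordered. Comparison is symmetric and self-comparison is 100%
concordant in every group (both are property-tested).

Pairing is within subject via the manifest. Where a sample type is
replicated (DBS_2x1.6 triplicates), each replicate is compared first and
the per-subject value is the arithmetic mean of those comparison rates — a
mean of rates, not of pooled counts — before averaging over subjects.

**Coverage.** Per sample, the percentage of target bases with depth
strictly above a threshold (10X, 30X by default). The alternative reading —
the share of whole regions whose *mean* depth exceeds the threshold — is
implemented behind `mode = "region_mean"`; per-base is the default since
the quantity plotted is a percentage of exome positions. Box summaries use
linear-interpolation quartiles (R's default type 7, the convention of the
plotting systems these figures come from) and Tukey whiskers at the most
extreme points within 1.5·IQR of the quartiles. BED inputs are 0-based
half-open; conversion to 1-based coordinates happens only inside the
coverage module. Contig names are matched exactly, with no "chr"
normalisation, for bit-exact determinism.

## The synthetic cohort generator

`sim_config()` encodes the three pilot layouts (7, 8 and 7 subjects;
Pilot 3 adds triplicated 2x1.6 mm DBS samples and a WGA-amplified WB
sample, giving 42 samples). Per site the generator draws a variant class, an
allele template, and a Beta-distributed alternate allele frequency; per
subject, truth genotypes under Hardy–Weinberg; per sample, observations
through the artifact chain in fixed order — dropout, then error, then
missingness — so analytic expectations stay computable (e.g. with only
dropout active, the het/homo discordant fraction at truth-het sites is
exactly the dropout probability; the test suite recovers it within
binomial error).

Generator parameters, defaults, and rationale:

| parameter | default | meaning |
|---|---|---|
| `class_mix` | SNP 0.89, ins 0.05, del 0.04, multiallelic 0.02 | keeps the SNP share inside the 84–94% band observed for exome call sets, with SNPs > insertions > deletions > multiallelic |
| `alt_af_beta` | Beta(1, 3) | skewed allele-frequency spectrum; ~30% of truth genotypes heterozygous |
| `depth_model$mean` | 60 reads | typical exome mean depth |
| `depth_model$dispersion` | 3 | Gamma site factor shared across samples (capture efficiency); Poisson per sample, so depth is negative-binomial marginally and low-depth sites co-locate across samples |
| `depth_model$attenuation` | DBS 0.70–0.75, WB_WGA 0.85, WB 1.0 | amplified samples sequence shallower, reproducing the DBS coverage deficit |
| `dropout_prob` | 0.05 | het → random homozygote, WGA-derived types only (the artifact is attributed to amplification, so WB_WGA_ref is included and native WB never drops out) |
| `error_prob` | 0.002 | genotype perturbed to a uniformly chosen different genotype |
| `missing_prob` | max 0.25, midpoint 12, scale 3 | logistic-in-depth no-call probability: negligible above ~25X, rising below ~12X |
| `gq_model` | 3 GQ/read, sd 6, artifact factor 0.3, cap 99 | GQ grows with depth (≈99 above ~35X) and collapses on artifact calls |
| `caller_disagreement` | unique 0.04, HC-filtered 0.03 | sites emitted by one caller only, or VQSR-filtered in the priority caller and rescued from the secondary |

No quantitative artifact rates exist for the real assay, so these are
chosen once for test power — large enough that a 10,000–20,000-site cohort
detects them against binomial noise, small enough that concordance stays in
a realistic 95–100% range. They are not calibrated to any published cohort
and are never adjusted to meet a test.

The generator emulates VCF-level features only: there are no reads, no
reference genome, no capture-kit differences, and GQ is generated rather
than derived from genotype likelihoods. Consequently, passing tests show
that the *evaluation machinery* is correct under a mechanistic artifact
model — they do not certify performance claims about real DBS samples,
where artifact rates are unknown and depth, quality and dropout correlate
in messier ways.

## Problem sizes and determinism

The test suite runs cohorts of 200–20,000 sites and 4–42 samples; the
analysis scripts use 8,000 sites per pilot and the acceptance script
10,000–20,000 — sizes at which binomial standard errors on the recovered
rates drop below half a percentage point while a full run stays in seconds.
All randomness flows from a single integer seed per simulated object;
identical configurations produce byte-identical VCF, manifest and table
outputs, which the tests assert file-for-file.

## Known limitations

* Merge keys anchor on position only; two callers representing one indel
  with different left-alignments would not be reconciled (inputs are
  assumed internally consistent per caller, as they are when both callers
  run on the same alignments).
* Ploidy is fixed at 2; symbolic alleles and structural variants are
  skipped with a logged count.
* The sample-level filter trusts the WB reference: a site where the
  reference is confidently wrong is not caught, exactly as in the original
  filtering scheme.
* Concordance is computed on one merged call set per cohort
  (multi-sample calling); comparing independently called, differently
  normalised call sets would require allele matching this package does not
  perform.
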