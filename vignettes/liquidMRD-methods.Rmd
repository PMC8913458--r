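---
title: "Models and methods behind liquidMRD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind liquidMRD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liquidMRD)
```

liquidMRD implements two peripheral-blood assays for monitoring
multiple myeloma, and the cohort statistics that link them. This
vignette documents the models, the tunable parameters and why their
defaults are what they are, what the synthetic-data generators do and
do not emulate, and the design decisions taken where the procedure was
genuinely open.

## 1. Light-chain repertoire analysis (NGS of cfDNA)

Multiple myeloma is a plasma-cell malignancy; the malignant clone
carries a unique rearranged immunoglobulin light-chain (IGK or IGL)
sequence that is stable over time, making it a patient-specific
tracking marker in circulating cell-free DNA. The package consumes
clonotype tables (count, frequency, CDR3 nucleotide and amino-acid
sequence, V and J segment) rather than raw reads: alignment and
clonotype assembly are upstream concerns.

**Clonotype identity.** A clonotype is keyed by
(CDR3 nucleotide sequence, V segment, J segment). The amino-acid
sequence is carried but never used for matching: nucleotide-level
identity is the stricter choice and the appropriate one for MRD, where
a false cross-patient or cross-clone match is costlier than a missed
synonym. Frequencies are always recomputed from counts on load
(`repertoire()`, `read_clonotype_table()`), which enforces the
invariants `sum(count) == total_reads` and `sum(freq) == 1 ± 1e-6`, and
duplicate keys are merged by summing counts.

**Read-depth QC.** `qc_pass()` requires at least 20,000 reads on the
involved chain, boundary inclusive (a sample with exactly 20,000 reads
passes). Samples failing QC never contribute to clone identification
or classification.

**Diversity.** `chao1_bc()` implements the bias-corrected Chao1
richness estimator
\[
\hat S = S_{obs} + \frac{f_1 (f_1 - 1)}{2 (f_2 + 1)},
\]
with $f_1, f_2$ the singleton and doubleton counts. It is always
$\ge S_{obs}$, with equality when $f_1 \in \{0, 1\}$. The test suite
cross-checks it against `vegan::estimateR()`.

**Myeloma-clone identification.** `identify_mm_clone()` pools all of a
patient's QC-passing repertoires on the involved chain and applies two
rules:

* *overrepresentation* — frequency strictly above 1/3 of the spectrum
  in a sample taken at a diagnostic phase (initial diagnosis, relapse,
  or progression). The restriction to diagnostic-phase samples avoids
  mistaking post-treatment oligoclonal immune reconstitution — which
  can dominate a deep-remission repertoire — for the malignant clone;
* *cross-compartment overlap* — frequency strictly above 5% in both a
  cfDNA sample and a genomic-DNA/FFPE specimen (bone marrow, pleural
  effusion, tissue).

A candidate seen in at least two samples, or supported by a
cross-compartment pair, is *confirmed*; a clone seen only in a single
cfDNA sample is returned but flagged unconfirmed, since cfDNA alone
does not suffice for confident identification. With several candidates
the one with the highest maximal frequency wins; remaining ties break
on the clonotype key. The full supplementary definition used on the
real cohort is not public; the rule here is reconstructed from the
published anchors (the two thresholds and the multi-specimen
confirmation requirement), and that reconstruction is a documented
limitation.

**Per-sample classification.** `classify_ngs()` yields one of four
categories: `NO_CLONE_DEFINED` (no clone identifiable for the patient;
excluded from concordance), `MM_TOP` (the clone is the sample's most
abundant clonotype), `MM_DETECTED` (present at any read count — a
single read counts, positivity is irrespective of frequency), or
`MM_NOT_DETECTED`. The most-abundant-clonotype comparison is evaluated
on the involved chain only. `top_clonotype()` breaks count ties by
lexicographic CDR3 sequence so classification is reproducible.

## 2. Plasma-cell cytometry (me-MFC)

Circulating plasma cells are magnetically enriched on CD138 and
measured on a fixed nine-marker panel (CD81, CD45, CD38, CD138, CD27,
CD19, CD117, CD56, CD200). The event table reaching the package is
post-cleanup: scatter gating, doublet exclusion and compensation are
upstream.

**Transform.** `transform_intensities()` applies
$x \mapsto \operatorname{asinh}(x / c)$ with cofactor $c = 150$ raw
fluorescence units, the conventional variance-stabilizing transform
for this class of instrument. All cutoffs are expressed in transformed
units.

**Gate.** A plasma cell is CD138-positive with CD38 and/or CD27
positive (`gate_pc()`). **Subsets.** Each gated event receives seven
aberrancy flags — CD45, CD19, CD81, CD27 below the low/negative
cutoff; CD117, CD56, CD200 at or above the positive cutoff — and
events with at least two flags form the ABERRANT subset
(`split_pc_subsets()`). Each population's `aberrancy_score` counts the
criteria met by its per-marker *median*: phenotypic aberrancy is a
population property, while per-event flags only decide membership. For
phenotypically coherent subsets the two views agree; an adversarial
subset mixing disjoint two-flag profiles could score below 2 at the
median while still being labelled ABERRANT — a known edge of this
operationalization, not exercised by the generators.

**Sample category.** `classify_flow()`: more than `min_events`
(default 10) gated events is a significant number of circulating
plasma cells; at or below it the sample is `NO_PC`. The published rule
is stated as "more than ten" for significance but "less than ten" for
No-PC, leaving exactly ten ambiguous; we resolve the boundary
conservatively (exactly ten is *not* conclusive) and make it
configurable. A sample with both conclusive subsets is `MM_AND_N_PC`;
only aberrant, `MM_PC`; only normal, `N_PC`. "Conclusive clustering"
is operationalized purely as this count threshold — the original calls
involved manual clustering judgment, for which a reproducible
surrogate is required.

**Cutoffs.** No numeric gate cutoffs are published, and none would
transfer across instruments. `default_gate_thresholds()` places both
cutoffs midway between the low and high population means that the
synthetic generator is calibrated to (1 and 6 transformed units →
cutoff 3.5), and everything is overridable per marker via
`gate_thresholds()` or a YAML file (`read_gate_thresholds()`).

**MFI.** `mfi()` reports the arithmetic mean of *raw* intensities (the
estimator behind the published comparisons is unstated; raw-scale mean
is the common instrument-software convention).
`compare_mfi_paired()` runs per-marker paired t-tests with Holm-Sidak
step-down adjustment, $\tilde p_{(i)} = \max_{j \le i}
\left(1 - (1 - p_{(j)})^{m - j + 1}\right)$, clipped to 1.

## 3. Cohort statistics

* `dedup_samples()` drops a sample taken fewer than 16 days after the
  most recent *retained* sample of the same patient and material
  stream (cfDNA and whole blood deduplicate independently). Anchoring
  on the retained sample, rather than a pairwise sliding rule, matches
  sequential collection and makes the operation deterministic and
  idempotent.
* `map_response_group()` merges stringent CR into CR and minor response
  into SD, and pools ID with RD and SD with PD for group statistics;
  PR before/after transplant reports under PR with the sublabel
  available separately.
* `concordance()` computes the 2×2 cross-classification, percent
  agreement $100(a+d)/n$, and unweighted Cohen's kappa
  $(p_o - p_e)/(1 - p_e)$ with
  $p_e = ((a{+}b)(a{+}c) + (c{+}d)(b{+}d))/n^2$. When $p_e = 1$, kappa
  is 1 under perfect agreement and an error otherwise. Undefined
  (no-clone) samples must be excluded before pairing.
* `spearman_clone_correlation()` uses average-rank Spearman correlation
  with the t-approximation p-value (`stats::cor.test`,
  `exact = FALSE`); with roughly a dozen pairs, exact-permutation and
  approximate p-values differ in the third decimal, so we report rho as
  primary and document the approximation rather than claim any printed
  p-value.

## 4. Synthetic data: what it emulates, and what it does not

The study's raw sequencing and cytometry data are not deposited, so the
generators reproduce the *statistical structure the classification
rules assume*, with ground truth known by construction.

* `make_repertoire()` draws clone-rank base frequencies from a power
  law (Zipf) with exponent 1.2, renormalized around an optional planted
  myeloma clone, and samples read counts multinomially. The exponent
  was chosen once because it yields several clonotypes above 5% of the
  spectrum — the observed oligoclonality of light-chain cfDNA
  repertoires at every disease stage; a log-normal clone-size law would
  also be defensible but buys nothing for rule testing. CDR3s are
  random in-frame 30–60-mers with V/J labels from fixed IGKV/J and
  IGLV/J lists.
* `make_paired_compartments()` plants the myeloma clone in both
  compartments, reuses a configurable fraction of *low-frequency-tail*
  background keys across compartments (so background sharing does not
  create spurious >5% overlaps), and can plant extra shared
  high-frequency clonotypes to emulate pairs with more than one
  prominent shared rearrangement.
* `make_flow_sample()` draws each population's marker intensities as
  Gaussians in transformed space (low mean 1, high mean 6, σ = 0.35,
  i.e. ≥ 14σ of separation) mapped back to raw units. With these
  defaults the per-event misclassification probability is below
  10⁻¹², so fixture compositions are recovered deterministically for
  any seed.
* `build_fixture()` pins named cohorts to the published group sizes and
  headline counts (114 cfDNA samples in five response groups with 27
  detected; 24 + 81 flow samples; 22 initial-diagnosis flow samples
  with 19 MM-PC; 13 compartment pairs with 9 single-overlap; 12
  EP-positive samples with 11 detected; the 25-pair concordance table
  (16, 4; 1, 4)). Compositions the publication does not pin — how
  detected samples distribute within SD/PD, PR and VGPR; how
  non-detected samples split into clone-defined-but-absent versus
  no-clone; the serology subset's response mix — are fixed once in the
  registry and are *not* constrained by any published number. The
  2×2 concordance cell counts are likewise not published; (16, 4; 1, 4)
  is one of the tables consistent with n = 25, 20 concordant and
  κ ≈ 0.490.

What the generators deliberately do **not** model: sequencing error and
PCR bias, somatic hypermutation, the uninvolved chain's biology beyond
an independent background repertoire, doublets and debris, spillover,
and real marker-expression correlation structure. Consequently,
passing fixtures demonstrates that the classification rules are
implemented correctly and are mutually consistent with the published
cohort percentages — not that the assays would achieve those
percentages on new patients.

## 5. Numerical choices and problem sizes

All thresholds are strict or inclusive exactly as stated above
(QC ≥ 20,000; overrepresentation > 1/3; overlap > 5%; conclusive
events > 10; dedup gap < 16 days drops). Percentages are stored at
full precision and rounded to one decimal only for reporting.
Repertoire fixtures use 150 background clonotypes at 30,000 reads —
deep enough that a planted clone at 0.2% of reads is present with
probability 1 − e⁻⁶⁰ and multinomial noise cannot move any clone
across a decision threshold; flow fixtures use 10⁴ events per sample
(50-event plasma-cell spikes), matching the instrument's acquisition
scale. Every generator is a pure function of its parameters and seed
(`withr::with_seed`), so reruns are byte-identical.

## 6. Known limitations

* The clone-definition rule is a reconstruction from published anchors,
  not the authors' full supplementary procedure.
* Gate cutoffs are generator-calibrated defaults, not instrument
  truths; real deployments must set them per panel.
* Patient-level results on the real cohort (individual clone
  trajectories, the observed Spearman rho, which MFI differences reach
  significance) depend on unreleased data and are covered here only by
  parameter-recovery tests on synthetic analogues.
* No survival analysis and no CD38-therapy panel adaptation.
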