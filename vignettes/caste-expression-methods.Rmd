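---
title: "Methods: interval-based differential expression for larval caste transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interval-based differential expression for larval caste transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casteDE)
```

# The analysis problem

Bumblebee (*Bombus terrestris*) female larvae commit to a queen or worker
developmental pathway during defined sensitive periods. casteDE implements a
pipeline for profiling caste-associated gene expression across three larval
stages (early, mid, late) and two caste pathways (Q, W), six phenotype
groups in all, from bulk mRNA-seq count matrices with small replicate
numbers (2–4 libraries per phenotype), plus a qRT-PCR validation arm and
cross-species comparison machinery.

The package's statistical core is deliberately nonparametric. With two or
three replicates per group, parametric variance estimation per gene is
fragile; the pipeline instead uses depth-equalising subsampling and a
replicate-interval decision rule whose null behaviour is available in
closed form.

# Subsampling normalization

`subsample_normalize()` equalises library depth by drawing, for each
library, `n_draws` subsamples of a common target depth *without
replacement* — an exact multivariate hypergeometric sample over features —
and returning the per-feature mean across draws. Each single draw's column
sum equals the target exactly, and the expectation of a normalized count is
`raw * target / library_total`. Defaults: target = the minimum library
total, `n_draws = 10`, explicit seed. The choice of without-replacement
draws keeps normalized counts bounded above by raw counts and preserves the
count scale that the interval rule below operates on; the mean over draws
(rather than a single draw) is used downstream to reduce subsampling noise.

Replicate quality is assessed by `replicate_qc()`: mean Pearson correlation
of `log2(count + 20)` between a library and its same-phenotype replicates,
flagged below a threshold (default 0.9). Flagged libraries are *reported*;
removal is an explicit user action (`drop_samples()` or the
`excluded_samples` config entry), never automatic — QC thresholds encode
judgement that should stay visible.

# The interval DE rule and the offset fold change

For each feature and phenotype, `group_intervals()` records the interval
between the minimum and maximum normalized count across that phenotype's
biological replicates. Within a stage, a feature is a **DEG** when the Q
and W intervals are disjoint; touching endpoints count as overlap (read
strictly: the intervals must *not* overlap at all). Effect size is the
**offset fold change**

$$\mathrm{OFC} = \log_2\frac{\min_k + 20}{\max_{k'} + 20},$$

where *k* is the up-regulated caste, min/max are taken across replicates,
and the offset of 20 counts prevents low-abundance features from dominating
the OFC ranking. Because the up-group's minimum must exceed the down-group's
maximum for disjoint intervals, every DEG has OFC > 0. **HDEGs** are DEGs
with OFC strictly greater than 1.

The rule's null behaviour is exact: for iid continuous replicate values the
two intervals are disjoint only when one group occupies the top of the
pooled order statistics, so

$$P(\mathrm{DEG}) = \frac{2}{\binom{n_1+n_2}{n_1}},$$

0.1 for 3 vs 3 replicates and 2/70 ≈ 0.0286 for 4 vs 4. The test suite and
acceptance script verify this on 100,000 simulated null features. This
false-positive rate is a property of the rule, not a significance level the
user sets; no per-gene p-values or multiple-testing corrections are
involved in the caller itself.

## Multi-exon merging

Unannotated transcribed regions are often fragments (exons) of a single
longer transcript, and counting each fragment as an HDEG would inflate
totals. `call_hdegs()` merges unannotated HDEG candidates that belong to
one transcript unit: member counts are summed, the interval and OFC are
recomputed on the sums, and the unit contributes at most one HDEG. When no
unit definitions are supplied, `build_transcript_units()` chains
unannotated features on the same strand within 1,000 bp whose expression
profiles correlate at Pearson r ≥ 0.9 — a conservative, configurable rule
recorded in the output; both thresholds are arguments.

## Genes of interest

`genes_of_interest()` applies five overlapping criteria: (a) top OFC among
each phenotype's up-regulated DEGs (ties all retained); (b) HDEG in ≥ 1
stage; (c) HDEG in ≥ 2 stages; (d) gene family containing another HDEG;
(e) membership of a user-supplied literature list. Selection requires (a)
or at least two of (b)–(e).

# Annotation classes and novelty

`classify_features()` assigns each transcript one of four classes:
annotated; unannotated but not novel (significant homology outside the
genus *Bombus*); novel non-coding; novel coding. Novelty means every
homology hit at E ≤ 1e-5 (either nucleotide or protein search) is confined
to *Bombus*. Features with no hits at all satisfy that condition vacuously
and are classed novel, with `n_hits = 0` exposed so downstream users can
distinguish "no-hit novels". Coding status uses a simple ORF rule
(`coding_status()`): an ATG-to-stop reading frame of ≥ 100 codons on either
strand. This is a configurable stand-in for heavier coding predictors and
is adequate for the taxonomically restricted, mostly long-non-coding
transcripts the novelty analysis targets.

`novelty_enrichment()` tests, per stage, whether novel genes are
differently represented among queen-up vs worker-up HDEGs with a two-sided
Fisher's exact test. The default table layout compares novel counts against
the *total* upregulated-HDEG counts of each pathway (columns novel, total)
— the layout under which the published late- and mid-instar comparisons
(7/14 vs 5/40 → p = 0.042; 14/92 vs 7/54 → p = 0.813) reproduce exactly —
with the strict novel/non-novel partition available via
`layout = "novel_vs_rest"`. Stages where either pathway has no HDEGs are
reported untestable rather than given p = 1.

# Orthology and gene-list overlap

`rbh()` computes reciprocal best hits from two directional hit tables with
a fixed, deterministic tie-break chain (E-value, then bitscore, then
lexicographic subject id), yielding a one-to-one orthologue map;
`project_lists()` restricts DEG/HDEG lists to mapped features (DEOs /
HDEOs). `overlap_test()` builds the 2×2 joint-membership table over a
shared orthologue background and applies a two-sided Fisher test with
Bonferroni correction; the family size is supplied per comparison batch
(the motivating design used 36 and 18), never inferred from the data.
`exclude_and_retest()` supports sensitivity re-analyses with a gene set
(e.g. diapause-associated genes) removed from lists and background alike.

# The qRT-PCR arm

`calibrate_plates()` removes between-plate offsets using inter-plate
calibrator wells (subtracting each plate's deviation from the grand IPC
mean), preserving within-plate Cq differences exactly.
`genorm_stability()` implements the geNorm stability statistic: a
candidate's M is the mean standard deviation of its pairwise log2
expression ratios with the other candidates; candidates are ranked by
iterative exclusion of the highest-M gene, and the pairwise variation
V(n/n+1) between normalization factors of the best n and n+1 genes
determines how many references to use (smallest n with V < 0.15, floor 2).
BestKeeper-style per-gene Cq standard deviations are reported alongside.

`relative_quantify()` performs efficiency-corrected relative
quantification: `RQ(g, s) = E_g^(mean Cq_g − Cq_{g,s})`, calibrated against
each gene's mean Cq over all samples (so the quantification is invariant to
any constant shift of one gene's Cqs), normalized by the geometric mean of
the reference genes' RQs. Efficiencies default to 2.0 where a
standard-curve estimate is absent. Caste differences are tested per stage
with two-sided Mann–Whitney U tests (`caste_rank_test()`), exact for
tie-free data, normal-approximated and flagged when ties occur; sidedness
is two-sided by default since rank tests on six replicates per group rarely
justify directional pre-commitment.

`platform_congruence()` scores, per target gene and stage, whether the
mRNA-seq outcome (HDEG with direction) and the qRT-PCR outcome
(Mann–Whitney p < 0.05 with the median pointing the same way) agree — both
significant in the same direction, or both non-significant — and
`congruence_binomial()` tests the match proportion against 0.5 with a
one-sided exact binomial test. One-sided is the package default because
the question is whether agreement exceeds chance, not whether it differs.

# The synthetic-data generator

`simulate_counts()` emulates the study design the pipeline expects:
negative-binomial counts (dispersion 0.05 by default) over a log-normal
baseline; a shared log-normal stage effect applied to 60% of features so
replicates cluster by developmental stage more strongly than by caste, as
observed in real larval ordinations; caste effects only on designated
true-DE features at their designated stage; and library depths drawn
uniformly from the design range (default 0.9–1.1 million reads). Defaults
mirror the motivating 17-library configuration (replicates 3, 3, 3, 2, 3, 3
for EQ–LW) with caste effects concentrated in mid instars and absent in
early instars, and annotation-class fractions (52.5% unannotated, 31.4% of
those novel, 3% of novels coding) taken from the proportions the field
reports for caste-associated transcripts. Where the underlying
distributions are not identifiable from published summaries (effect-size
distribution of true caste-DE genes, dispersion, depth), the defaults are
explicit, tunable parameters rather than inferred values.

`simulate_hit_tables()` emits outfmt-6-style homology rows engineered so
the classifier recovers the simulated classes exactly (non-novel features
receive a significant outside-genus hit; novel features only *Bombus* hits
below threshold plus decoys above it), together with sequences whose ORF
content matches the coding truth. `simulate_cq_plates()` produces Cq plates
with eight reference candidates of graded noise (the two most stable
near-proportional), targets with known fold changes, per-plate offsets with
IPC wells, and efficiencies in [1.8, 2.1].

What passing recovery tests on these data shows — and does not. The
generator reproduces the *statistical skeleton* of the design: group
structure, depth variation, overdispersion, stage-dominant clustering,
annotation mixture. It does not emulate GC/length biases, correlated gene
modules, batch structure, or mapping artefacts; recovery results
(sensitivity ≥ 0.9 at log2-fold 4 with dispersion 0.05, perfect HDEG
precision) therefore characterise the method under its assumed noise model,
not performance on any real library.

# Numerical choices and degenerate inputs

* Problem sizes: test-suite simulations use 100,000 features for the
  analytic-null check (Monte-Carlo SE ≈ 0.001 at p = 0.1) and a
  15,000-feature × 17-library study for end-to-end recovery, matching the
  scale of a real larval transcriptome.
* Ties: equal interval maxima fall back to comparing minima; fully
  identical intervals are never DEGs (OFC 0). Criterion (a) ties flag all
  tied features.
* Zero-depth libraries and single-replicate phenotypes are errors, not
  silent exclusions.
* All generators and the normalizer take explicit seeds; no function
  mutates global RNG state.
* Fisher, binomial and Mann–Whitney tests are delegated to base R's exact
  implementations; the test suite cross-checks each against independent
  brute-force enumeration oracles (all 2×2 tables with N ≤ 20 and margin
  sweeps to N = 40; binomial tails to n = 48; full labeling enumeration for
  rank tests with groups ≤ 7).

# Known limitations

The interval rule's sensitivity depends steeply on replicate number (its
null rate is 0.1 at 3 vs 3 and 0.2 at 3 vs 2), so DEG totals are not
comparable across phenotypes with different replicate counts without that
caveat. Depth normalization is compositional: strongly asymmetric DE —
especially when a high-abundance gene is involved — shifts every other
feature's normalized count in the opposite direction, and at small
replicate numbers the interval rule registers some of those shifts as
DEGs. Raw DEG totals therefore mix signal, the analytic null share and
composition; the HDEG tier (OFC > 1) is robust to both in all simulated
settings tested. The exon
merging rule is a heuristic proxy for transcript models. The ORF-based
coding call ignores codon usage and homology evidence. The qRT-PCR
calibrator convention (per-gene sample mean) is one of several in use;
ratios are comparable within a run, not across studies.

# A worked run

```{r, eval = FALSE}
design <- sim_design(n_features = 2000, seed = 1)
study <- simulate_study(design)
report <- run_pipeline(
  list(counts = study$counts, features = study$features,
       hits = study$hits, sequences = study$sequences,
       ortho_map = study$truth$orthologues,
       partner_de = study$truth$partner_de, qpcr = study$qpcr),
  pipeline_config(seed = 2))
report$summary          # per-phenotype DEG/HDEG counts, top OFC
report$novelty          # per-stage novelty Fisher tests
report$congruence_test  # mRNA-seq vs qRT-PCR binomial
write_report(report, "caste_report")
```
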