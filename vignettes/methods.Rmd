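---
title: "Cross-species analysis of dioxin-elicited gene expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species analysis of dioxin-elicited gene expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahrcompare)
```

## The scientific problem

2,3,7,8-tetrachlorodibenzo-p-dioxin (TCDD) acts through the aryl
hydrocarbon receptor (AhR): the ligand-activated AhR/ARNT dimer binds
dioxin response elements (DREs) — DNA elements with the invariant 5-bp
core GCGTG — in the regulatory regions of target genes. Although the
receptor itself is conserved across mammals, the downstream
transcriptional programs are not: sensitivity to TCDD varies by orders of
magnitude between species. The workflow in this package asks, for
human, mouse and rat hepatoma models, *which* transcriptional responses
to TCDD are conserved across species, which are species-specific, and
which are outright divergent (the same ortholog induced in one species
and repressed in another) — and whether DRE sequences near orthologous
genes track those patterns.

The package implements the full analysis chain as tested, reusable
functions: synthetic data generation with known ground truth,
normalization of two-color microarray intensities, empirical-Bayes
differential expression with a posterior probability of activity P1(t),
ortholog-anchored cross-species classification, cycloheximide-based
separation of primary from secondary responses, and computational DRE
promoter analysis with cross-species conservation clustering. The
numbered scripts under `analysis/` run the stages in order; `run_all()`
executes them end-to-end under one configuration and one seed.

## Synthetic data as the test substrate

The original microarray intensities and genome assemblies are not
packaged, so every stage runs against generated data whose ground truth
is known exactly. The generators define the study conditions and are
first-class, tested code:

* **Time course** (`generate_experiment()`): three species, a 7-point
  time course (1, 2, 4, 8, 12, 24, 48 h), three biological replicates
  each hybridised twice with dyes swapped — 42 two-color arrays per
  species. Ortholog groups cover 60% of each platform by default with
  memberships thinned 15% per species so platforms overlap only
  partially. Planted categories default to 90% null, 3% conserved up,
  1% conserved down, 1% specific per species, and the rest divergent
  (one member species flips sign). The default planted effect is
  2 log2 units with replicate noise sd 0.2 — chosen once as a clearly
  detectable but not extreme response against typical two-color array
  noise.
* **Noise model**: each array's log2 ratio is
  `M = effect + bias(A) * s + N(0, sd^2)`, realised as multiplicative
  lognormal noise on the two channels. `bias(A)` is a smooth cubic
  polynomial in the mean log2 intensity A (the classic banana-shaped
  dye effect), and `s` flips sign on dye-swap arrays because the bias
  belongs to the dyes, not the treatment. This gives the normalization
  stage something real to remove.
* **CHX factorial** (`generate_chx_experiment()`): direct-ratio arrays
  for TCDD vs vehicle and TCDD+CHX vs CHX at 4 and 12 h. Planted
  primary genes keep or exceed their TCDD effect under co-treatment
  (modifier drawn uniformly in [1, 2], so superinduction occurs);
  secondary genes are attenuated to [0, 0.2] of the effect.
* **Promoters** (`generate_promoters()`): TSS-anchored windows, 10 kb
  upstream to 1 kb downstream. The background is i.i.d. uniform
  nucleotides rejection-sampled so that neither GCGTG nor its reverse
  complement occurs anywhere except at planted sites; planted-core
  counts are therefore exact, and scanner tests assert equality rather
  than statistical agreement. Planting on the minus strand inserts the
  reverse complement of the given 19-mer.

What the generators do **not** emulate: probe-level spatial artifacts,
print-tip effects, cross-hybridization, many-to-many paralogy,
non-uniform promoter base composition, or CpG islands. Passing tests
therefore demonstrate that the algorithms are implemented correctly and
are well calibrated under an idealised noise model — not that the
biological conclusions of any particular study replicate.

## Normalization

`normalize_expression()` forms, per array, `M = log2(treated/control)`
and `A = (log2 T + log2 C)/2`, fits a smooth trend of M on A (lowess
with span 0.4 by default; a cubic polynomial is available via
`method = "poly"`), and subtracts it. Because M is always oriented
treated-over-control — with the control channel identified by treatment
rank (vehicle < CHX < TCDD < TCDD+CHX), so co-treatment arrays are
expressed relative to CHX alone — dye-swap replicates come out
sign-aligned without further bookkeeping. Arrays with fewer than 20
usable probes are refused rather than silently fitted. Constant offsets
are absorbed by the trend; the intensity-trend removal leaves the rank
order of probes at equal A unchanged.

## Empirical-Bayes differential expression and P1(t)

For one condition (species × time × contrast) with n replicate arrays,
`fit_empirical_bayes()` computes per gene the mean log2 ratio m̄ and a
moderated t statistic in which the residual variance is shrunk toward a
pooled prior:

  s²_mod = (d0·s0² + d·s²) / (d0 + d),  t_mod = m̄ / (s_mod/√n)

with prior degrees of freedom d0 = 4 and s0² the mean of the per-gene
variances. The posterior probability of activity is a two-component
mixture on the moderated statistic, in the theoretical-null form
standard in large-scale testing: under the null the statistic is
N(0, 1); under the active component its variance is inflated to 1 + c,

  P1 = π1·f1(t) / (π1·f1(t) + (1 − π1)·f0(t)),

with prior active proportion π1 = 0.01 and effect-variance scale c = 25
(prior effect sd of five standard errors). P1 is strictly increasing in
|t|, reaches 0.999 near |t| ≈ 4.7, and saturates for large effects.
The Gaussian rather than t-density form was chosen deliberately: a
t/t likelihood ratio plateaus at (1+c)^(df/2), which caps the posterior
and makes moderate but real effects unreachable at stringent cutoffs;
the variance shrinkage (augmented degrees of freedom d0 + d) is what
justifies the Gaussian approximation. All four hyperparameters are
exposed as arguments and in the `eb` config section.

A gene is called differentially expressed when **P1 > 0.999 and
|fold change| > 1.4, both strict inequalities**, per condition; the
any-time call is the union over conditions. Fold change uses the signed
magnitude-≥1 convention (−1.56 means 1.56-fold down). The calibration
contract, enforced by the test suite: on all-null data (5000 genes,
3 replicates × 2 labelings) at most 0.5% of genes pass; on planted
2-log2 effects at noise sd 0.2 at least 95% are recovered.

## Profile clustering

Any-time DE genes are clustered by `cluster_de_profiles()`:
agglomerative, Euclidean distance, average linkage. Missing cells use
pairwise-complete distances rescaled by √(total/observed dimensions)
(the behaviour of `stats::dist`, which implements exactly this
convention). Rows are ordered by gene id before clustering so the tree
is invariant to input order. Dendrograms serialise to Newick with leaf
depth equal to merge height (leaves at height zero).

## Cross-species classification

`map_calls()` projects per-species calls onto ortholog groups. Status
per species is `up`/`down`/`ns`, or `absent` when the gene is off that
platform; direction for a time-course call is the sign of the fold
change at the significant time point with maximal |fold change| (the
strongest signal; deterministic). Categories:

* **conserved** — every represented species significant, same sign,
  ≥ 2 represented;
* **divergent** — significant calls with opposite signs in ≥ 2 species;
* **specific** — exactly one significant species among ≥ 2 represented;
* **partial** — ≥ 2 same-sign significant species but at least one
  represented species not significant (kept separate so that
  *conserved* is strict);
* **none** — no significant species. Groups represented on fewer than
  two platforms are also `none`: a cross-species category is undefined
  there.

Groups absent from a platform are excluded from that comparison's
denominator. Pairwise overlaps and the three-way Venn partition operate
on the same statuses, and their region sums reconcile by construction
(tested). Percentages are rounded half-up to one decimal, matching the
summary convention used for reported response rates.

## Primary vs secondary responses (cycloheximide)

Cycloheximide blocks protein synthesis, so a transcriptional response
that persists under co-treatment cannot depend on a newly synthesised
intermediate transcription factor: it is a putative primary (direct
AhR) response. `classify_chx()` estimates r0 (TCDD vs vehicle) and r1
(TCDD+CHX vs CHX — contrasting against CHX alone absorbs CHX's own
effect on baseline) at 4 and 12 h with the same EB machinery, then:

* **nonresponsive** if r0 fails the DE thresholds;
* **primary** if r1 passes the thresholds, keeps r0's sign, and retains
  at least `retention_alpha` = 0.5 of its magnitude — superinduction
  (|r1| > |r0|), the hallmark of genes such as CYP1A1, always
  qualifies;
* **secondary** if r1 fails the thresholds (blocked) or falls below the
  retention cut (attenuated);
* **unclassified** for a significant sign flip.

"Attenuated" has no canonical quantitative definition, so the
half-retention cut is an explicit, configurable design choice.
Classification is monotone in |r1|/|r0| (tested). The 4 h and 12 h
calls merge conservatively: identical classes stand; a classified call
beats nonresponsive; a primary/secondary conflict — and any combination
involving unclassified — is unclassified.

## DRE promoter analysis

`scan_cores()` finds every occurrence of the substitution-intolerant
core GCGTG on the plus strand and CACGC (its reverse complement) on the
minus strand of the promoter window, reporting the TSS-relative
position of the **center of the 5-bp core** (third base; signed, TSS = 0,
upstream negative). Both strands are scanned because DRE function is
strand-independent; `strand = "+"` restricts the scan. N never matches.

Each core hit is extended by 7 bp on both sides to a 19-mer
(`extend_to_19mer()`); minus-strand hits are reverse-complemented so
the reported 19-mer always carries the core at positions 8–12 in DRE
orientation. Hits with insufficient flank are dropped with a warning —
padding would fabricate sequence.

`build_pwm()` derives a position weight matrix from a training set of
functional DRE 19-mers: pseudocount-smoothed column probabilities
((count + 0.25)/(n + 1)) and per-position information weights
c_i = 2 + Σ_b p log2 p. The **matrix similarity** of a 19-mer is the
information-weighted score rescaled by the attainable extrema,
MS = (S − S_min)/(S_max − S_min), so the consensus scores exactly 1 and
a per-position worst-base sequence exactly 0.

Cross-species conservation uses the Euclidean distance between one-hot
encodings of 19-mers, which reduces to the closed form
d = √(2·mismatches). The clustering threshold θ = 3.0 therefore admits
at most 4 mismatches (√8 ≈ 2.83) and rejects 5 (√10 ≈ 3.16) — a
consequence worth stating prominently, since the metric alone does not
make it obvious. `cluster_orthologous_dres()` applies complete-linkage
agglomerative clustering cut at θ (complete linkage guarantees every
within-cluster pair is within θ); a cluster is *orthologous* when it
spans ≥ 2 species. Positional conservation is reported descriptively
(positions and spread), with no threshold.

## Numerical and degenerate-input choices

* Strict inequalities at both DE thresholds, verified at exactly
  P1 = 0.999 and |FC| = 1.4.
* Percentages round half-up at one decimal (9.879 → 9.9, 2.427 → 2.4);
  `round_half_up` avoids banker's rounding surprises.
* Ties in clustering are broken by ordering rows (gene id) or hits
  (species, position) before distance computation.
* Empty inputs: an empty hit list writes a header-only file; a
  promoter with no cores returns a zero-row table; a single hit forms a
  singleton cluster without invoking the tree machinery.
* Missing expression values stay missing (never imputed to zero);
  conditions are fit on the observed arrays per gene, and genes never
  measured in a condition are excluded from its platform universe.
* All randomness flows from one master seed through
  `derive_seed(seed, stage)`, kept within 32-bit integer range;
  re-running with the same configuration and seed reproduces identical
  output digests (recorded in the run manifest).

## Problem sizes

The default analysis scripts simulate 1000/1000/800 genes across the
three species with the full 7-point design (126 arrays), which runs in
well under a minute. The test suite uses the same generators at sizes
between 100 and 5000 genes — 5000 for the null-calibration check, the
scale at which a ≤ 0.5% false-positive bound is meaningfully
measurable — and 200–1000 random promoters for scanner/oracle
equivalence. These sizes are the package's own choices for a
convincing yet quick demonstration.

## Known limitations

* The normalization and EB posterior reproduce the *intent* of the
  original study's cited methods (intensity-trend removal; a monotone
  posterior probability of activity), not their exact internals, which
  are not public. Absolute DE counts from the original arrays are
  therefore out of reach by design, and the package scores itself on
  planted-truth recovery instead.
* Probe-to-gene collapse is best-P1-per-gene; both probe-level and
  gene-collapsed counts are exposed because the two conventions give
  different totals.
* The DRE scanner supports genome-scale runs mechanically, but
  genome-wide census counts depend on assemblies not packaged here.
* One-hot Euclidean distance weights all 19 positions equally; a
  PWM-weighted distance would rank core-adjacent mismatches
  differently. The simple metric is kept because its θ = 3.0 ⇔ ≤ 4
  mismatches correspondence is transparent and testable.
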