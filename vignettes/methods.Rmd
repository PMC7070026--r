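---
title: "Methods: nucleosome positioning stability and mutation rate variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome positioning stability and mutation rate variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

`nucmut` implements an analysis chain that asks whether the
*translational* stability of nucleosome positioning — how tightly a
nucleosome's genomic location is fixed across cells — modulates local
mutation rates, and which repair processes are involved. The chain has
five stages: per-site positioning metrics, a penalized logistic
regression with a likelihood-ratio variable scan, background-corrected
96-type mutation spectra with signature refitting, randomization
enrichment and dyad-anchored meta-profiles, and repair escape-ratio
profiles. A synthetic-data generator provides every input class with
recorded ground truth, so each stage has parameter-recovery tests.

## Positioning metrics

For a focal site and the set of MNase-seq fragment midpoints within
±95 bp, we compute the count `n`, the mean `d_mean` of the absolute
distances, and their sample variance `d_var` (denominator `n − 1`).
Distances are absolute, and the ±95 bound is *closed*: a midpoint at
exactly 95 bp counts. 95 bp is half the nucleosome repeat length
(~191 bp), so the window spans roughly one nucleosome. Sites with no
midpoint have *missing* statistics (never zero); `d_var` needs `n ≥ 2`.
Sites are usable when `n ≥ 10` and, when a mappability track is
supplied, the focal base has a non-missing score ≥ 90. We apply the
mappability threshold at the focal base only — the minimal
interpretation — and expose a window option for regional filtering.

`d_mean` enters models as a five-level categorical variable with bins
[0,18], [19,36], [37,54], [55,73], [74,95] (its relationship with
mutation rate is not monotone). The printed integer bins leave gaps for
real-valued means; we assign `d_mean` to bin *k* iff it lies in
(upper(k−1), upper(k)] with upper = (18, 36, 54, 73, 95), which
preserves the integer behavior (18.5 falls in bin 2).

Occupancy is the per-10-bp-bin ratio of observed fragment coverage to
control coverage from composition-matched simulated fragments; bins are
anchored at coordinate 0 of each chromosome, and bins with zero control
coverage propagate as missing rather than 0 or infinity.

Fragment midpoints for even-length fragments are taken left of center,
`start + (length − 1) %/% 2`; the convention matters only at 1-bp
resolution and is stated because no standard exists.

## Regression

Mutation status of a site is Bernoulli with
`logit Pr(y=1) = Xβ`. Covariates: strand-normalized context nucleotides
at offsets −5..+5 (reference base A at each offset), `d_mean` bin
(reference bin 1), `log(d_var + 1)`, occupancy (value of the 10-bp
occupancy bin at the focal base), per-track ±10 bp means (missing bases
skipped), and repeat status with precedence Alu > L1 > other_repeat >
nonrepeat. Strand normalization reverse-complements sites whose
reference base is a purine, so site classes are A/T, CpG and non-CpG
C/G; SNV strata are fitted separately. The natural log and the +1
offset for `d_var` handle exact-zero variances (perfectly stable
nucleosome stacks); the offset is exposed as an argument.

Because mutated sites are rare, controls are a uniform subsample of
usable non-mutated sites at 10× the mutated count. Case-control
subsampling biases only the intercept of a logistic model, not the
slopes, so coefficient recovery is unaffected.

Fitting is MAP estimation under independent Student-t priors — scale
2.5, df 1 (Cauchy) on standardized coefficients, scale 10 on the
intercept — the configuration known to keep estimates finite under the
complete separation that rare-event regressions produce. We standardize
continuous predictors to SD 0.5 and center binary ones, iterate
weighted least squares with an EM update of the per-coefficient prior
variances (`V_j ← (β_j² + ν s_j²)/(1 + ν)`), and declare convergence at
`max |Δβ| < 1e-8` (cap 200 iterations; non-convergence is flagged).
The *unpenalized* binomial log-likelihood at the MAP estimates is what
we report and what likelihood-ratio statistics compare; this choice is
stated explicitly because penalized fits admit several deviance
definitions, and it reduces to the classical LRT as the prior widens.
A numerically negative LRT (possible at convergence tolerance) is
clamped to zero, with a warning beyond 1e-3. McFadden's pseudo-R²
(`1 − ll/ll₀`) is computed against the intercept-only MAP fit, and the
drop for each variable is reported as a percent of the full-model
pseudo-R². BH correction is applied within one stratum's scan; the
family choice (per stratum vs pooled across the nine per-type tests) is
genuinely ambiguous, so pooling is available by flag. Optional
`pairwise_context` interactions add all two-way products of context
dummies.

## Spectra and signatures

SNVs are classified into the 96 pyrimidine-strand types. Trinucleotide
context counts are strand-collapsed and exclude contig edges (a center
needs both flanks). The corrected occurrence of type *i* in a region
set is `F_i / N_i,region × N_i,genome`; a type observed in a region with
zero matching contexts is an inconsistency and errors. Fisher tests per
type use the raw-count 2×2 table
`[[F_r, N_r − F_r], [F_g − F_r, (N_g − N_r) − (F_g − F_r)]]` with BH
across the 96 types; the direction arrow is the sign of the sample odds
ratio minus 1 computed from the same raw table; corrected,
composition-adjusted counts feed only the signature refit, where the
comparison across region sets is the point. Refitting solves non-negative least squares
`argmin_{w≥0} ‖S w − spectrum‖₂` (Lawson–Hanson via
`pracma::lsqnonneg`); corrected, non-integer spectra are accepted
as-is. The signature matrix is a user input; tests use synthetic
orthogonal-support matrices whose mixtures are exactly recoverable.

## Enrichment, meta-profiles, escape ratios

Randomization enrichment re-places each event uniformly in the
workspace, preserving per-chromosome counts (avoiding composition
artifacts) and, for interval events, lengths and containment in a
single workspace segment. The empirical p uses the +1 correction (never
exactly 0) and the two-sided p doubles the smaller tail, capped at 1;
the CI of the fold is the 2.5/97.5 percentile band of
observed/sample-count.

Meta-profile bin 0 starts at the anchor (offsets [0,10)); upstream bins
carry negative labels. In event mode the profile conserves counts
exactly (`Σ value × bin × n_anchors` = anchored events); in signal mode
missing bases are skipped per bin.

The escape ratio per 10-bp bin is
`R_i = (m_i^A/m_i^B)/(m̄^A/m̄^B)` with backgrounds from an equal number
of random 1600-bp windows in the workspace (sampled without replacement
from non-overlapping candidates when feasible, otherwise with a
warning). Bins where cohort B has no mutations are missing by default;
a +0.5 pseudocount is optional. The ratio is scale-invariant in the
cohort sizes by construction. The region-level association test uses
the 2×2 table of strong-region vs all-region counts for the two
cohorts.

# Synthetic data: what it emulates and what it does not

The generator's defaults describe the study system: GC fraction 0.41
with CpG dinucleotides depleted to 0.2 of independence via a
first-order Markov chain (the chain's input GC is calibrated so the
*stationary* GC matches the requested value); nucleosome repeat length
191.4 bp with spacing ~ Normal(NRL, NRL/10) truncated positive; 147-bp
core-particle fragments, 20 per dyad; and per-dyad midpoint jitter
σ_k ~ Uniform(3, 35) bp. The jitter distribution around a dyad is
Gaussian — a modeling choice, since no generative model of midpoint
scatter is established — and the uniform σ range gives cleanly
separated stability terciles. "Strong" regions are dyad ±73 bp for the
lowest-jitter tercile, mirroring the three-way equal split of stability
scores; the middle tercile stands in for rotationally-but-not-
translationally stable regions so the genome partition is exercisable.
When a constant jitter sampler makes all dyads equally stable, all are
labelled strong (no tercile ordering exists).

Mutation generators write their ground truth (β and calibrated
intercept, per-bin escape ratio, mixture weights) and recovery tests
read truth only from there. The paired-cohort generator thins dyads so
their ±window neighborhoods are disjoint — otherwise overlapping
profiles would make the recorded truth inexact — and applies the offset
profiles inside windows with uniform background outside. Background
windows for escape estimation are drawn from the whole workspace, so
study designs keep dyad windows a small fraction of the genome
(coverage × bump mass is the size of the residual bias, ~2–3% in the
shipped configurations, well inside per-bin Poisson noise).

What the generator does *not* emulate: MNase sequence bias, diploidy,
read-level errors, mappability structure (the default track is
constant 100), selection, and real covariate correlation structure
(tracks are independent smooth Gaussian fields). Passing tests
therefore demonstrate that the estimators recover known parameters
under clean conditions — not that real data meet those conditions.

# Numerical and design choices

- Interval sets are held as `GRanges` (1-based closed, the Bioconductor
  convention); BED/bedGraph coordinates convert at the I/O boundary,
  and point coordinates (variants, midpoints, dyads) are 0-based
  throughout, matching the file formats. All conversions are tested
  round-trip identities.
- Missing track data is a distinct state, never imputed as 0; averages
  skip missing bases and report coverage.
- Readers reject malformed records with line numbers; dropped records
  (long INDELs, unclassifiable variants, edge anchors, incomplete
  feature rows) are always counted, never silent.
- Stability terciles break score ties by (chrom, pos) and send
  remainders to the lower-score groups first, so labels are invariant
  to input order.
- The `d_var` quintile split, tercile boundaries and control sampling
  are deterministic given the seed; every CLI subcommand writes a
  timestamp-free JSON manifest so identical seeds give byte-identical
  outputs.

Problem sizes used by the shipped tests were chosen as the smallest
that give stable statistics: 1-Mb genomes with ~5,000 events and 10×
controls for coefficient recovery (estimate SD ≈ 0.013 over seeds),
200 replicates for p-value calibration, 10,000 randomization samples
for enrichment, and ~350 dyads at 0.004 mutations/bp for escape-ratio
recovery.

# Limitations

- The regression treats sites as independent; clustered mutation
  processes (e.g. multi-nucleotide events) violate this.
- Penalized LRTs are compared to the χ² reference; this is accurate for
  the weak default prior at the shipped sample sizes (verified by the
  calibration tests) but not for strong priors or tiny strata.
- The occupancy control model matches composition only through a 5-mer
  GC summary in `gc_weighted` mode.
- Signature refitting inherits the usual non-identifiability of
  correlated signature matrices; orthogonal synthetic matrices used in
  tests avoid rather than solve this.
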