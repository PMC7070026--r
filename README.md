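# nucmut

Nucleosomes that keep a nearly fixed genomic position across cells
("strong", translationally stable nucleosomes) are associated with locally
elevated germline mutation rates. `nucmut` is an R package for
quantifying that relationship: it measures translational positioning
stability from MNase-seq fragment midpoints, models per-site mutation
probability against positioning and functional covariates, compares
mutation spectra between region sets with proper trinucleotide background
correction, and profiles how repair pathways perform around nucleosome
dyads. Every stage can be exercised end-to-end on synthetic data with
recorded ground truth, so the statistical machinery is testable without
any external dataset.

It is aimed at computational genomicists studying mutation rate
variation, nucleosome organization, or DNA repair.

## The statistics at the core

**Positioning stability.** For a focal genomic position, let
`d_i = |midpoint_i − site|` over all MNase-seq fragment midpoints with
`d_i ≤ 95` bp (about half the nucleosome repeat length). Then

    d_mean = (1/n) Σ d_i            0 ≤ d ≤ 95
    d_var  = Σ (d_i − d_mean)² / (n − 1)

Small `d_mean` means the site is near a dyad; small `d_var` means the
surrounding nucleosomes are translationally stable. Sites need ≥ 10
midpoints within ±95 bp to be usable; `d_mean` is binned into the five
categories [0,18], [19,36], [37,54], [55,73], [74,95]. Occupancy is the
10-bp-bin ratio of observed to composition-matched simulated fragment
coverage.

**Mutation-rate model.** Site mutation status is modeled by binary
logistic regression, `logit Pr(y = 1) = Xβ`, where X holds the
strand-normalized ±5 bp sequence context, `d_mean` bin, `log(d_var + 1)`,
occupancy, functional-track means (±10 bp) and repeat status. Fits use
independent Cauchy priors on standardized coefficients (scale 2.5,
intercept scale 10), which keep estimates finite under complete
separation. Each variable's contribution is assessed by a
likelihood-ratio test of the full model against the model without that
variable, with Benjamini–Hochberg correction and McFadden pseudo-R²
deltas.

**Spectra and signatures.** SNVs are classified into the 96
pyrimidine-strand trinucleotide mutation types. Counts in a region set
are corrected for its trinucleotide composition,
`N′_i = F_i / N_i,region × N_i,genome`, per-type differences are tested
with two-sided Fisher exact tests, and spectra are refit against a fixed
signature matrix by non-negative least squares.

**Enrichment and escape ratios.** Observed event counts in an annotation
are compared with 10,000 chromosome-preserving uniform re-placements of
the events in the workspace (expected count, fold, sampling CI, empirical
p). Around dyads, the background-normalized repair escape ratio per
10-bp bin is

    R_i = (m_i^A / m_i^B) / (m̄^A / m̄^B)

where `m_i` are per-bin mutation densities of a repair-proficient (A) and
repair-deficient (B) cohort and `m̄` are their densities in random
1600-bp background windows; `R_i > 1` means replication errors
disproportionately escape repair in that bin.

## Worked example

```r
library(nucmut)

# 1. Simulate a study system with known ground truth
cfg    <- sim_config(seed = 1L, chrom_lengths = c(chr1 = 500000L))
genome <- gen_genome(cfg)
land   <- gen_nucleosome_landscape(genome, cfg)

# 2. Per-site positioning statistics at candidate sites
sites <- candidate_sites(genome, land$midpoints, n = 40000L, seed = 2L)
head(sites[, c("pos0", "n", "d_mean", "d_var", "d_mean_bin")], 3)
#>     pos0  n   d_mean     d_var d_mean_bin
#> 1 327863 20 49.25000 819.35526          3
#> 2  41540 12 82.00000 170.18182          5
#> 3 254904 18 84.27778  63.97712          5

# 3. Mutations from a logistic model with a known stability effect
mut <- gen_mutations_from_model(genome, sites,
                                beta = c(log_d_var = -0.5),
                                n_target = 2500, seed = 3L)
ctl <- sample_control_sites(sites,
                            data.frame(chrom = mut$variants$chrom,
                                       pos0 = mut$variants$pos0),
                            ratio = 10, seed = 4L)

# 4. Fit the Cauchy-prior logistic model and scan log_d_var
allp <- rbind(data.frame(chrom = mut$variants$chrom,
                         pos0 = mut$variants$pos0, y = 1L),
              cbind(ctl, y = 0L))
idx <- match(paste(allp$chrom, allp$pos0), paste(sites$chrom, sites$pos0))
tab <- data.frame(y = allp$y,
                  log_d_var  = sites$log_d_var[idx],
                  d_mean_bin = factor(sites$d_mean_bin[idx], levels = 1:5))
fit <- fit_penalized_logistic(tab[, -1], tab$y)
round(fit$coefficients["log_d_var"], 3)
#> log_d_var
#>     -0.53

scan <- likelihood_ratio_scan(tab, c("log_d_var", "d_mean_bin"),
                              drop = "log_d_var")
scan[, c("variable", "lrt", "df", "p_adj", "coef_sign")]
#>    variable lrt df     p_adj coef_sign
#> 1 log_d_var 726  1 7.61e-160        -1

# 5. Enrichment of the mutations in strong-nucleosome regions
enr <- randomized_enrichment(
  data.frame(chrom = mut$variants$chrom, pos0 = mut$variants$pos0),
  land$strong, GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500000)),
  n_samples = 5000, seed = 5L)
sprintf("observed %d expected %.1f fold %.2f p %.3g",
        enr$observed, enr$expected, enr$fold, enr$p)
#> "observed 1113 expected 667.6 fold 1.67 p 0.0004"
```

The fitted `log_d_var` coefficient (−0.53) recovers the generating value
(−0.5): lower distance variance — i.e. higher translational stability —
means higher mutation probability. Consistently, the simulated mutations
are 1.67-fold enriched in the strong-nucleosome regions the landscape
generator derived from its lowest-jitter dyads.

## Command line

A thin CLI wraps the same functions
(`inst/cli/nucmut.R`; after installation,
`Rscript $(Rscript -e 'cat(system.file("cli/nucmut.R", package="nucmut"))')`):

```sh
nucmut simulate  --out-dir sim --seed 11
nucmut nucstats  --midpoints sim/midpoints.bed --sites sim/mutations.tsv --out stats.tsv
nucmut enrich    --events sim/mutations.tsv --annotation sim/strong.bed \
                 --workspace ws.bed --samples 10000 --seed 7 --out enr.tsv
```

Subcommands: `simulate`, `nucstats`, `occupancy`, `enrich`, `profile`,
`regress`, `spectrum`, `signatures`, `escape`. Every run writes TSV
outputs plus a JSON manifest; identical inputs and `--seed` give
byte-identical outputs.

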