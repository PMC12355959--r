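# meltshift

Thermal proteome profiling (TPP) melting-curve analysis and differential
PTM proteomics, with a ground-truth synthetic-data generator.

meltshift is for proteomics analysts who have (or want to benchmark
against) TPP melting series and protein/PTM-site intensity matrices. It
implements:

* **Melting-curve fitting and Tm-shift discovery.** Each
  reference-normalized melting series is fit with the sigmoid
  denaturation model

  *f*(T) = (1 − plateau) / (1 + e^−(a/T − b)) + plateau,

  the melting point solved in closed form from *f*(Tm) = 0.5,
  per-protein vehicle-versus-treated shifts tested with a two-sided
  Student's *t*-test, and candidates screened by the three-criterion
  cascade: p < 0.05, curve-fit R² > 0.9 for all replicates, and a shift
  direction shared by all pairwise vehicle/treatment comparisons.
* **Differential PTM analysis.** Reliability filtering (e.g. detection
  in ≥ 3/4 of a group's replicates), log2 transform with MAD-based
  variance stabilization, site-to-protein normalization
  (site log2 − parent protein log2, per sample), per-feature Student's
  *t*-tests with Benjamini–Hochberg FDR control.
* **Soft clustering.** Fuzzy c-means over standardized abundance
  profiles (defaults: 10 clusters, fuzzifier 1.765, membership
  assignment at > 0.2).
* **Set-level statistics.** One-sided Fisher's exact
  over-representation of GMT gene sets with per-set median log2FC, and
  one-factor PERMANOVA (permutation p on the distance-matrix pseudo-F).
* **Synthetic data.** Seeded generators for two-arm TMT melting
  experiments on the 10-temperature gradient (37.1–67.2 °C), protein +
  PTM-site intensity matrices with planted effects and dropout, and
  clustered condition profiles — each returning the ground truth used by
  the recovery tests.

## Worked example

Simulate a 100-protein TPP experiment in which 10% of proteins carry a
true −3 °C melting-point shift, then run the discovery pipeline:

```r
library(meltshift)

sim <- simulate_melting_dataset(
  tpp_sim_config(n_proteins = 100, frac_interactors = 0.1, seed = 42))
res <- run_tpp(sim$tpp)
#> quantified: 100 -> tested: 98 -> significant: 11 -> good_fit: 11 -> candidates: 10

head(res$candidates[res$candidates$candidate,
                    c("protein_id", "delta_tm", "p_value", "min_r2")], 5)
#>   protein_id  delta_tm      p_value    min_r2
#> 1      P0043 -2.953967 1.313281e-10 0.9962909
#> 2      P0089 -3.085676 8.995602e-10 0.9973247
#> 3      P0022 -3.028834 2.057440e-09 0.9982058
#> 4      P0026 -3.090096 1.426855e-08 0.9971647
#> 5      P0054 -3.041605 3.394504e-08 0.9977795
```

The funnel line mirrors the candidate-filtering cascade: of 100
simulated proteins, 98 had at least two defined melting points per arm,
11 passed the significance screen, all 11 also passed the R² criterion,
and 10 survived direction consistency — the estimated shifts of the true
interactors cluster tightly around the planted −3 °C. Individual curves
can be fit directly:

```r
fit <- fit_melting_curve(
  melt_model(tpp_gradient(), a = 2000, b = 40, plateau = 0.1))
fit
#> melt_fit: a=2000 b=40 plateau=0.1  R2=1.0000  Tm=50.28 C  converged=TRUE (n=10)
```

`run_ptm()` is the analogous driver for intensity matrices (filtering →
stabilization → site-to-protein normalization → differential testing →
optional GMT enrichment); see the methods vignette
(`vignettes/meltshift-methods.Rmd`) for the models, parameter defaults
and design choices.

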