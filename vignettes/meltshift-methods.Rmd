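---
title: "Models and methods in meltshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in meltshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltshift)
```

meltshift implements the computational core of a thermal proteome
profiling (TPP) and PTM-proteomics workflow: melting-curve fitting with
melting-point (Tm) shift candidate discovery, site-to-protein-normalized
differential abundance with FDR control, fuzzy c-means profile
clustering, and set-level statistics. Every stage is paired with a
seeded synthetic-data generator carrying known ground truth, so the
whole pipeline is verifiable by parameter recovery without any raw mass
spectrometry data.

## The melting model

In a TPP experiment, aliquots of a lysate are heated across a
temperature gradient (here the ten-point TMT gradient 37.1–67.2 °C),
the soluble fraction is quantified per protein, and each series is
normalized to the lowest temperature so the reference point is exactly 1.
Relative solubility is modeled by the sigmoid

$$f(T) = \frac{1 - \text{plateau}}{1 + e^{-(a/T - b)}} + \text{plateau}$$

with slope constant $a > 0$ (°C-scaled), offset $b$ (dimensionless) and
a lower asymptote `plateau` (the residual soluble fraction at high
temperature). The exponent uses $a/T - b$: the superficially similar
$aT - b$ form is *increasing* in $T$ for $a > 0$ and cannot describe
melting, so the decreasing form is the only physically sensible reading.
Temperatures are in °C throughout; the model is scale-sensitive, so the
unit is fixed in the I/O contract.

The melting point is the temperature at which the relative abundance
falls to half its initial value, $f(T_m) = 0.5$, giving the closed form

$$T_m = \frac{a}{\,b - \ln\!\big(0.5/(0.5 - \text{plateau})\big)}$$

defined only for `plateau` < 0.5 with a positive denominator; otherwise
the curve never crosses 0.5 and Tm is *undefined* (a value, not an
error). `melting_point_numeric()` solves $f(T) = 0.5$ by root finding
and agrees with the closed form to better than $10^{-6}$ °C across
$a \in [500, 5000]$, $b \in [10, 100]$, plateau $\in [0, 0.45]$; the
test suite asserts this on a $10^3$ grid.

### Fitting

`fit_melting_curve()` estimates $(a, b, \text{plateau})$ by bounded
Levenberg–Marquardt least squares (minpack.lm), with plateau constrained
to $[0, 1)$ — unbounded plateaus produce non-identifiable curves. Start
values are data driven: since the model is linear on the logit scale in
$1/T$, regressing $\mathrm{logit}\big((y - p_0)/(1 - p_0)\big)$ on $1/T$
(with $p_0$ the smallest observed value floored at 0) yields a
near-exact start; a small ladder of heuristic starts
($b_0 \in \{10, 25, 50\}$, $a_0 = b_0 \times$ the temperature nearest
the half-maximum) guards against degenerate regressions, and the fit
with the lowest residual sum of squares is kept. A failed optimization
never raises an error: the fit is flagged `converged = FALSE` with an
undefined Tm. $R^2 = 1 - SS_{res}/SS_{tot}$ is computed on the
normalized values and may be negative for pathological series; a
constant series has undefined $R^2$. Fits proceed on any series with at
least 5 finite points, mirroring tolerant MS pipelines that lose
individual temperature channels.

## Tm-shift candidates

For each protein, per-replicate melting points in the vehicle and
treated arms give $\Delta T_m$ = mean(treated) − mean(vehicle) and a
two-sided Student's *t*-test. The default is the unpaired equal-variance
test; because split-lysate designs pair the arms per replicate, a
`paired = TRUE` mode is provided (whether pairing is appropriate depends
on how the arms were physically derived, which the data alone cannot
decide — we default to the generic unpaired TPP convention).

Candidates must pass all three criteria of the screening cascade:

* **significance** — raw $p < \alpha$ (default 0.05). No
  multiple-testing correction enters the decision, matching the raw-p
  screening convention of thermal-shift candidate discovery; a BH
  `q_value` column is emitted for transparency.
* **fit quality** — $R^2 > 0.9$ (strict) for *every* contributing
  replicate fit, enforced through the minimum $R^2$.
* **direction consistency** — every pairwise treated-versus-vehicle
  difference shares one sign: per-replicate differences in paired mode,
  all cross-pairs in unpaired mode (the strictest reading of "all
  pairwise comparisons"). A zero difference is not "the same direction"
  and fails.

Manual curve inspection, part of bench practice, cannot be automated and
is not emulated; the per-criterion audit flags are retained on every
record so that downstream curation has the full cascade visible.
Proteins with fewer than two defined melting points in an arm are
excluded with exactly one primary reason.

## Differential PTM analysis

Intensity matrices (features × samples with group metadata) pass through
four stages:

1. **Reliability filter.** A feature is kept iff it is observed in at
   least `ceiling(min_fraction × group size)` replicates of at least one
   group (default 3/4; presets matching common designs — 5/7, 2/3, 3/3 —
   are just values of `min_fraction`). Filtering per group with an
   any-group-passes rule lets a feature present only under treatment
   survive; a global mode is available by flag.
2. **Log2 transform and variance stabilization.** Values are
   log2-transformed, each sample is median-centered, and each sample is
   rescaled so its median absolute deviation equals the pooled median
   MAD. This stabilizer was chosen because it is deterministic,
   idempotent, and invariant to per-sample scalar factors; workflows
   differ in what "variance stabilization" means concretely, and a plain
   `log2_only` switch is provided.
3. **Site-to-protein normalization.** On the log2 scale, the normalized
   site value is site minus parent protein, per sample. A site whose
   parent protein is unquantified (globally or in a sample) becomes
   missing there — a site is never carried unnormalized, since the
   quantity of interest is modification change *net of* protein change.
4. **Differential test.** Per feature, log2FC = mean(A) − mean(B) and a
   two-sided equal-variance Student's *t* (Welch by flag), requiring at
   least two observations per group. BH adjustment runs across all
   tested features of the matrix and significance is called at
   $q \le 0.05$ (reading the "p ≤ 0.05 after FDR adjustment" convention
   as a q-value threshold).

A consequence worth knowing: protein-normalized site values carry the
measurement noise of *both* the site and the protein ($\sqrt{2}$ times
the single-matrix noise). At the default simulation conditions
(noise 0.3 log2 units, n = 4 per group, +1 log2 planted effects), BH at
$q \le 0.05$ across thousands of sites then has very little power — the
planted *effect sizes* are still recovered essentially unbiased, and the
FDR is controlled, but few individual sites are called. This is a real
property of site-level designs at these sample sizes, not an artifact.

## Soft clustering of abundance profiles

Differential-feature profiles are row-standardized (mean 0, sd 1;
zero-variance rows carry no shape and are dropped with a warning) and
clustered by fuzzy c-means with defaults `n_clusters = 10` and
fuzzifier $m = 1.765$, the configuration customary for soft-clustered
differential protein profiles; the membership threshold for reporting
assignments is a strict > 0.2. The fuzzifier is a plain parameter — the
dimension-based estimation heuristic some packages apply is not
implemented, since only its customary result is relevant here.

The updates are the standard alternating scheme: memberships
proportional to inverse squared Euclidean distance to the power
$1/(m-1)$, centers as membership$^m$-weighted means; the weighted
within-cluster dispersion is recorded per iteration and is
non-increasing. Iteration stops when the largest membership change drops
below `tol` (default $10^{-6}$, `max_iter` 1000).

Two numerical choices deserve explanation:

* **Initialization.** The default is a deterministic farthest-point
  ("maximin") scheme with value-based tie-breaks. We chose it over
  seeded random data rows (available as `init = "random"`) because it
  makes the result independent of row order — permuting the input rows
  permutes the output identically — which random row sampling cannot
  guarantee. Initial centers are then shrunk halfway toward the global
  centroid: seeding a center *exactly on* a data row creates a
  degenerate fixed point in which that center stays locked onto its row
  (reference FCM implementations show the same lock-in), and the
  shrinkage removes it while keeping the symmetry-breaking directions.
* **Zero distances.** Squared distances are floored at
  $10^{-12}\times$ their mean, so a point coinciding with a center gets
  near-crisp membership at moderate fuzzifiers without producing the
  locked solutions above.

For very large fuzzifiers, memberships approach the uniform $1/c$ —
exactly so only in the $m \to \infty$ limit. On strongly separated
clusters the *optimal* finite-$m$ solution retains slight structure (at
$m = 100$ on well-separated synthetic profiles we measure a maximum
membership deviation of about 0.01, and its objective is lower than that
of full center collapse); on moderately separated profiles the collapse
is complete and deviations drop below $10^{-5}$. The acceptance checks
demonstrate the limit on moderately separated profiles for this reason.

## Set-level statistics

`fisher_enrichment()` performs one-sided over-representation tests: for
each gene set, the overlap $k$ of the differential features with the
set's in-universe members follows the hypergeometric distribution under
the null, and $P(X \ge k)$ is the Fisher's exact one-sided p
(two-sided by flag). The universe is the set of features actually
tested — all features surviving the reliability filter — because
enrichment against a larger universe than was measurable inflates
significance. Sets with fewer than 3 in-universe members are skipped as
vacuous. BH q-values and the median log2FC of the differential members
accompany every record.

`permanova()` is one-factor permutational MANOVA on a distance matrix
(Euclidean by default in the pipeline; any distance can be supplied):
pseudo-$F$ from the among/within decomposition of squared distances, and
$p = (1 + \#\{F^* \ge F\})/(n_{perm} + 1)$ under seeded label
permutation, so the smallest attainable p is $1/(n_{perm}+1)$. With
small equal groups, the chance that a random permutation reproduces the
observed partition — tying $F^* = F$ — is non-negligible (2/70 for two
groups of 4) and makes the test slightly conservative; calibration
checks therefore use groups of 5, where the tie probability is 2/252.

## The synthetic-data generator

`simulate_melting_dataset()` emulates a two-arm (vehicle/treated)
TMT melting experiment: per-protein sigmoid parameters drawn uniformly
from `a_range` (default [1800, 2200]), `b_range` ([38, 44]) and
`plateau_range` ([0, 0.2]) — ranges chosen once so that true melting
points fall inside the gradient (roughly 42–59 °C) — four replicates
per arm, and additive Gaussian noise of sd 0.02 relative-abundance
units, a typical scatter for reference-normalized TMT reporter series
(the noise magnitude is a documented choice exposed as a parameter, as
no measurement model accompanies such experiments). The reference
temperature is noise-free and exactly 1, matching the normalization
contract, and values are clipped at 0. A planted fraction of
"interactors" (default 10%) receives a true shift of `delta_tm_true`
(default −3 °C), realized by solving for $b'$ in closed form with $a$
and plateau held fixed — so the planted quantity is exactly the Tm
difference, isolating what the shift test measures. Each replicate's
vehicle/treated pair shares its baseline parameters, emulating split
lysates, which makes both paired and unpaired testing meaningful.

`simulate_ptm_dataset()` generates log-normal protein intensities with
group structure (two groups of 4 by default, log2 noise sd 0.3),
planted ±1 log2 effects in 10% of proteins and, independently, 10% of
sites; site values are the parent protein's true signal plus a site
offset plus the site-level effect plus independent noise, so
site-to-protein normalization isolates the site effect by construction.
Missingness is independent (missing-at-random) dropout.
`simulate_profile_clusters()` draws rows around phase-shifted cosine
templates as a clustering test bed.

What the generator does *not* emulate: reporter-ion interference and
ratio compression, correlated (non-MAR) missingness such as
intensity-dependent dropout, shared-peptide ambiguity, and batch
effects. Passing recovery tests on these simulations therefore
demonstrates the correctness of the statistical machinery under its own
assumptions — not robustness to every artifact of real MS data.

## Problem sizes and determinism

The shipped checks run at desk scale, chosen to keep the whole suite
fast while leaving the statistical assertions well-powered: a
$10\times10\times10$ parameter grid for the Tm closed form; 200 proteins
for the zero-noise round trip; 100 proteins × 4 replicates for noisy
recovery; 1000 unperturbed proteins for null calibration; 500 proteins
(10% perturbed) for cascade power; 800 proteins × 2 sites for the PTM
round trip; 150 profiles for clustering; 500–1000 null datasets for the
PERMANOVA calibration. All simulators take integer seeds and are
bit-reproducible; all tabular outputs are written without timestamps so
repeated runs are byte-identical.

## Known limitations

* The TPP stage normalizes each series to its reference temperature
  only; some TPP-TR workflows add a joint cross-condition curve
  normalization, which is out of scope here.
* The candidate cascade screens at raw p < 0.05 by design; its false
  discovery proportion is bounded only empirically (the simulation
  conditions give ≈ 20% at default settings), not by a formal FDR
  guarantee.
* Equal-variance *t*-tests follow the printed convention of the
  workflows emulated; with heteroscedastic groups, prefer the Welch
  flag. No variance moderation (limma-style shrinkage) is applied.
* Fuzzy c-means finds local optima; the deterministic initialization
  makes results reproducible, not globally optimal.
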