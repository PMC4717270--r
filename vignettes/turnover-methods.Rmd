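---
title: "Models and methods behind turnoverMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind turnoverMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnoverMS)
```

`turnoverMS` analyses heavy-label (²H₃-leucine) diet-switch proteomics: it
turns peptide isotopologue envelopes into per-peptide fractions of newly
synthesized protein, fits first-order turnover kinetics per protein,
compares turnover between experimental groups, and computes differential
protein abundance from peptide areas. This vignette explains the models,
the tunable parameters, the numerical choices, and what the simulation-based
validation does and does not establish.

## The envelope mixture model

A tryptic peptide with $n$ leucines, synthesized while the free-leucine
pool has heavy-label enrichment $p$, incorporates each leucine heavy
independently. Its label-count channel (0..$n$ heavy leucines) is therefore
$\mathrm{Binomial}(n, p)$. Molecules made before the diet switch carry no
label and sit in channel 0. If a fraction $f$ of the pool has turned over,
the normalized envelope is the mixture

$$E_k(f, p) = (1 - f)\,[k = 0] + f\binom{n}{k} p^k (1-p)^{n-k}.$$

Natural-abundance isotope fine structure is assumed already collapsed by
the upstream envelope quantitation; channels are label-count resolved.

**Deconvolution.** Given $p$, the mixture is linear in $f$, so the
least-squares estimate on the normalized envelope is a one-dimensional
projection with a closed form, clamped to $[0, 1]$. This makes the
inversion exact (zero residual) for any envelope on the model manifold,
invariant to intensity rescaling, and convex — no iteration or
initialization is involved. We use least squares on normalized envelopes
rather than a multinomial likelihood because the input is MS1 peak areas,
not counts.

**Enrichment estimation.** $p$ is shared by all peptides in a sample while
each peptide has its own $f$, so $p$ is estimated by profile least squares:
for each candidate $p$, every peptide's $f$ is profiled out by the closed
form above, and $\hat p$ minimizes the summed residual over $(0, 1]$. A
200-point grid scan brackets the minimum before golden-section refinement
(`stats::optimize`, tolerance $10^{-10}$), and the boundary $p = 1$ is
checked explicitly since interior optimization cannot land exactly on it.
Only peptides with $n \ge 2$ leucines contribute: for $n = 1$ the envelope
depends on $(f, p)$ only through the product $fp$, so single-leucine
peptides cannot separate the two (this confounding is asserted by a test).
Estimating $p$ per sample, not per group, is what makes the analysis
robust to groups that achieve different pool enrichments.

## Turnover kinetics and the group comparison

The percent newly synthesized follows $y(t) = 100 + \beta_1 e^{\alpha t}$,
with $\beta_1$ free (the fit does not force $y(0) = 0$). Taking logs gives
the linear form $\ln(100 - y) = b + \alpha t$, which we fit by unweighted
least squares. When a protein has several peptides, each peptide gets its
own intercept $b$ — a fixed-effect blocking factor absorbing systematic
peptide-to-peptide offsets — while the slope $\alpha$ is shared; this is
the classical ANCOVA reading of a "blocking factor", applied at the
peptide level rather than on protein-aggregated values. The half-life is
$t_{1/2} = \ln 2 / |\alpha|$ (slopes are negative by construction, so the
absolute value just fixes the sign convention). Observations at exactly
$y = 100$ are clipped to $100 - \varepsilon$ with $\varepsilon = 0.01$
before the transform; $\alpha$ numerically indistinguishable from zero
(|slope| < 1e-12/d) is reported as an infinite half-life and flagged.
A direct nonlinear fit of the exponential form (`fit_turnover_nls`) is
provided as a cross-check; on noiseless data the two agree exactly.

Proteins whose fitted half-life exceeds one year in any group are excluded
from all summaries — such slopes are dominated by noise at a 17-day
horizon — and the exclusion is idempotent and order-independent.

**ANCOVA.** Group differences in turnover are tested on the joint blocked
model with a common time slope and a group × time interaction; the
interaction coefficient is $\Delta\alpha = \alpha_B - \alpha_A$ and its
t-test is the reported p-value. The covariance matrix for this test is
heteroskedasticity-robust (HC3) by default. The reason is structural: a
roughly constant error in $\hat f$ is amplified by $1/(1-f)$ under the log
transform, so residual variance grows several-fold from day 3 to day 17,
and the classical homoskedastic standard error understates the
slope-contrast uncertainty. In null simulations at the study's design
scale (1000 proteins, envelope noise CV 0.1), the classical test rejects
at ~7.7% for a nominal 5%, while HC3 rejects at ~4–5.5% across seeds. HC3
is very slightly conservative in the mid-range of the null distribution
(mean null p ≈ 0.51), a trade-off we accept because the rejection rate is
the error-controlling quantity; HC2 centers the distribution better but
pushes the rejection rate to the edge of nominal. Slope estimates remain
unweighted OLS; `robust = FALSE` restores the classical covariance.
Whether the test runs on peptide-level values with blocks (implemented)
or on protein-aggregated values is a genuine choice; peptide-level
blocking uses all observations and matches the blocking-factor framing.

A zero-residual fit (noiseless identical groups) makes the t-statistic
0/0; we report p = 1 when the slope contrast is numerically zero and p = 0
otherwise, the correct limits.

## Differential abundance

Peptide areas are modelled on log2 scale with peptide-block intercepts and
a group effect; the group coefficient is the protein's log2 fold change
and its t-test the p-value — a blocked two-sample t-test. Areas are
log-transformed because MS1 intensities are multiplicative; the blocking
makes the estimate invariant to rescaling any single peptide's areas (its
ionization efficiency is absorbed by its intercept). Missing observations
are dropped per observation, not per peptide, and no cross-run
normalization or imputation is applied.

Multiplicity is adjusted per analysis family (per muscle) with
Benjamini–Hochberg step-up by default; Storey $\pi_0$-estimated q-values
(single-$\lambda$ estimator, $\lambda = 0.5$) are available as
`method = "storey"` for closer fidelity to q-value-based FDR control. BH
is the default because it is deterministic and assumption-light.

## Reporting surfaces

Compartment annotation takes plain identifier lists; a protein on both the
mitochondrial and cytosolic lists is assigned mitochondrial (the
mitochondrial reference is treated as the more specific claim) and the
conflict is logged. Half-life summaries report median, mean, and count per
stratum (total / mito / cyto × group) after the one-year exclusion;
medians and means can rank differently because a few very long-lived
proteins dominate the mean. Change classification labels each tested
protein longer-lived, shorter-lived, or unchanged from the sign of its
half-life change at q below the threshold, in half-life language rather
than rate sign. Venn overlaps between muscles are computed on proteins
detected and testable in both muscles — the stricter and better-defined
denominator — with both the per-muscle tested counts and the
tested-in-both count reported so either universe can be quoted. The
abundance–turnover comparison regresses per-protein half-life log-ratios
on abundance log2 fold changes (both axes as aged/young log ratios, the
symmetric choice). Gene-set enrichment uses the one-sided Fisher's exact
test on the hit/non-hit × in-set/out-of-set table, reports the
hits-in-set/set-size ratio, and excludes sets with fewer than 4 hits.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream guarantee is validated. The default design is
a cross-sectional diet-switch study — sacrifice at days 3, 7, 12, 17, four
animals per group per time point, two age groups — with one dataset per
muscle; the pipeline runs two muscles over a shared protein catalogue so
cross-muscle overlaps are well-defined. Each animal is sacrificed once, so
samples are group × time × animal.

Parameters and defaults, with the reasoning:

- **Half-life law**: log-normal, median 22 d, `sdlog` 1.3, giving ~1.5% of
  proteins beyond one year — matching the observed range in muscle
  mitochondrial fractions (median ~20–25 d, a small tail excluded at one
  year). Per-compartment laws allow studies where mitochondrial proteins
  are longer-lived by construction.
- **Enrichment**: constant $p = 0.5$ per group by default. Achieved pool
  enrichment and its time course are rarely reported, so both are
  parameters: an exponential rise `enrichment_rate` and per-group plateaus
  `enrichment_max_by_group` (to exercise robustness to pool differences)
  are available rather than asserted.
- **Noise**: multiplicative log-normal with CV 0.15 on channel intensities
  and peptide areas — the simplest model consistent with label-free MS1
  quantitation. Missingness is completely at random at rate 0.05 and drops
  whole peptide-by-sample envelopes: partial-channel dropout would corrupt
  the envelope shape, and in practice a failed peak match loses the whole
  observation.
- **Peptides**: truncated Poisson (mean 4, ≥ 1) peptides per protein;
  Poisson(1.5) leucines per peptide, matching short tryptic peptides.
  Zero-leucine peptides are deliberately generated — they carry no label
  information and downstream code must exclude them.
- **Age effects**: a configurable fraction of proteins gets an abundance
  log2 fold change (optionally compartment-restricted), and configurable
  numbers of proteins get half-life multipliers in the aged group.

What the generator does **not** emulate: raw spectra, chromatographic peak
shape, chimeric spectra, identification error, natural-isotope fine
structure, peptide-correlated (non-MCAR) missingness, or animal-level
random effects. Passing tests therefore validate the estimators under the
stated forward model, not robustness to every pathology of real data.

## Validation scale and results

The acceptance-style checks run at these sizes, chosen to exercise the
study design while keeping the whole suite in a few minutes: the
deconvolution roundtrip on a 21 × 21 (f, p) grid for 1–6 leucines (exact
to ~1e-15); enrichment recovery from 50 noiseless samples at each of
p = 0.3/0.5/0.8 (within 1e-6); half-life recovery over 200 proteins at
noise CV 0.15 with per-sample enrichment estimation (median relative error
~3–6%, exact to 1e-9 when noiseless); null ANCOVA calibration over 1000
proteins; 200 replicate abundance studies (empirical FDR ~4–5% at
q < 0.05, power ~1 at log2FC = 1); brute-force oracles for BH and the
hypergeometric tail; and an end-to-end two-muscle study with longer-lived
mitochondrial proteins, a 50-longer/7-shorter aged shift in one muscle
(half-life doubling/halving, comfortably above the design's detection
limit so recovered counts estimate the ground truth), and a mito-skewed
abundance increase in the other. In the positive-control scenario the
turnover and abundance effects are assigned independently, so the
abundance–turnover r² stays below 0.05.

Noiseless exactness checks supply the true enrichment to the
deconvolution: the estimated-p path carries its own ~1e-8 optimization
error, which is tested at its own tolerance but would mask the 1e-9 slope
tolerance. All noisy-path checks estimate enrichment per sample.

## Known limitations

- Fixed-effect peptide blocks consume one degree of freedom per peptide;
  proteins with many peptides and few observations per peptide lose
  efficiency relative to a mixed model (deliberately out of scope).
- The enrichment profile objective is unimodal in practice but is guarded
  by a grid scan, not proven unimodal.
- No amino-acid recycling correction beyond the enrichment parameter
  itself; recycled heavy leucine appears as pool enrichment.
- Run alignment is a straight least-squares line in one retention
  coordinate; nonlinear drift would need a spline, and perfectly collinear
  anchors legitimately give a zero-width matching window.
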