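---
title: "Quantifying relative protein isoform abundance from immunoblots with tagged standards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying relative protein isoform abundance from immunoblots with tagged standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starpa)
```

## The problem

Western-blot densitometry yields band intensities in arbitrary units that
confound three things: how much protein is in the lane, how avidly the
antibody binds it, and how strongly the blot was exposed. Comparing one
isoform across samples on one blot is easy; comparing *different isoforms to
each other* is not, because each isoform is detected by a different antibody
with a different (and unknown) affinity. The motivating application is the
panel of ubiquitously expressed G protein-coupled receptor kinases (GRK2,
GRK3, GRK5, GRK6), whose relative cellular levels matter for receptor
signalling but cannot be read off raw blot intensities.

`starpa` implements a tag-guided calibration strategy that makes
cross-isoform comparison valid:

1. Each isoform is overexpressed as a tagged construct (one tag epitope per
   molecule) in a knockout background, so the lysate contains exactly one
   (tagged) isoform.
2. The standards are diluted until they all give the *same anti-tag signal*.
   Since the tag is a molar reporter, equal tag signal means equal molar
   amounts loaded.
3. These matched standards run on every blot next to the unknown samples.
   Each isoform-specific antibody signal is normalised to its own standard
   on the same blot, which cancels both the blot-wide gain and the
   antibody's affinity.
4. Residual antibody cross-reactivity between isoforms is estimated from
   the standards themselves and subtracted.

## The model

For antibody A with target isoform a, unknown sample U and matched standard
S_a on the same blot, the relative molar abundance is the within-blot ratio

$$y_a = \frac{d_A(U)}{d_A(S_a)},$$

where $d$ is the densitometric band intensity. Because the standards were
equalised to one molar unit each, $y$ values of *different* isoforms are on
a common molar scale.

If antibody B (target b) also detects isoform a, its cross-reactivity
coefficient is measured on the molar-equalised standards:

$$c_B = \frac{d_B(S_a)}{d_B(S_b)},$$

and the contaminated ratio is corrected by subtraction:

$$y_b = \frac{d_B(U)}{d_B(S_b)} - y_a \, c_B .$$

The subtraction is only valid when $y_a$ itself comes from an antibody
without detectable cross-reactivity, which is why the pipeline quantifies
clean-antibody isoforms first. For arbitrary crosstalk patterns (including
circular ones) the package generalises the subtraction to the linear system
$C\,y = v$, where row B of $C$ holds antibody B's coefficients against every
isoform (1 on its own target) and $v$ is the vector of uncorrected ratios;
`solve_cross_reactivity_system()` solves it directly and refuses
ill-conditioned systems (condition number above `1e8`).

Both routes agree to machine precision on the one-level pattern (two
contaminated antibodies, each contaminated by a cleanly measured isoform),
which is the pattern the bundled GRK panel exhibits.

## The synthetic immunoblot simulator

The original densitometry underlying this kind of study is rarely published,
so the package ships a forward model that generates studies with known
ground truth. The expected density of a band is

$$d = g_\text{blot}\cdot \mathrm{sat}\!\left(\alpha \sum_i c_i\, x_i / f\right)\cdot \varepsilon + b,$$

with blot gain $g_\text{blot} = e^{N(0,\sigma_g^2)}$ shared by all lanes of
a blot (exposure and developing time scale whole blots), antibody affinity
$\alpha$, cross-reactivity fractions $c_i$, molar abundances $x_i$, dilution
factor $f$, an optional Michaelis–Menten saturation
$\mathrm{sat}(x) = v_\text{max}x/(x+k_\text{half})$ (off by default — film
and CCD responses are linear over the useful range), a noiseless additive
background $b$ (default 0), and unbiased lognormal band noise $\varepsilon$
with coefficient of variation `noise_cv`
($\sigma^2=\log(1+\mathrm{cv}^2)$, mean log $-\sigma^2/2$ so that
$E[\varepsilon]=1$).

Two consequences of this model are worth knowing:

* **Identifiability.** Only the products gain × affinity × abundance are
  observable, which is exactly why matched standards are needed at all; the
  simulator tests assert this invariance explicitly.
* **Ratio bias.** The ratio of two unbiased lognormal signals has
  expectation $\text{truth}\cdot e^{\sigma^2}$, i.e. a finite-sample
  overestimate of $\mathrm{cv}^2$ (1% at 10% band noise). No estimator built
  on within-blot ratios avoids it; the validation suite bounds the pooled
  bias of corrected estimates by $\mathrm{cv}^2$ plus three Monte-Carlo
  standard errors rather than pretending the bias is exactly zero.

What the simulator deliberately does **not** emulate: uneven lane loading,
spatial blot artefacts (smears, bubbles), antibody lot-to-lot variation,
membrane stripping effects, and phosphorylation-induced size shifts. Passing
tests therefore demonstrate correctness of the *arithmetic and the
calibration logic* under a realistic noise model, not robustness to every
failure mode of a wet-lab blot.

## Calibrating the standards

The dilution response is modelled as exact inverse proportionality,
$d = k/f$; $k$ is estimated as $\exp(\mathrm{median}(\log(d\cdot f)))$, the
L1-optimal fit in log space, robust to the occasional outlier band.
Calibration proceeds in the field's two stages:

1. **Coarse grid.** All standards' serial dilutions (default grid 1:10 to
   1:100) run side by side on shared blots; every blot is normalised to its
   own reference lane (default: the reference isoform at 1:20) and the grid
   dilution with mean signal nearest the reference is selected
   (`select_matching_dilution()`; ties break toward the larger dilution,
   which conserves lysate). Sharing blots matters: with per-series
   independent gains the picks become unreliable, with shared blots and
   per-blot normalisation they are essentially deterministic at 10% band
   noise.
2. **Refinement.** A new dilution $f^* = k/d_\text{ref}$ is proposed at
   which the fitted model reproduces the reference signal exactly
   (`propose_refined_dilution()`); on noiseless simulator output the
   refined standards equalise anti-tag signals to float tolerance.

**Validation** (`validate_standard_set()`) applies two explicit gates to the
per-blot-normalised anti-tag signals of the final standards: the maximum
pairwise relative deviation of the isoform means must not exceed
`cv_tolerance` (default 0.15), and a one-way ANOVA across isoforms must be
non-significant (default `alpha = 0.05`); Tukey's post-hoc comparisons are
reported descriptively but do not gate. Conventions for degenerate input:
signals identical to within a relative spread of 1e-9 give p = 1 (nothing
to distinguish); zero residual variance with genuinely distinct means gives
p = 0. With a single replicate per isoform the ANOVA is skipped and
flagged, leaving the deviation gate alone.

One property of this gate should be understood before using it: dividing by
a single noisy reference band gives every normalised signal roughly
$\sqrt{2}\cdot\mathrm{cv}$ relative noise, so at 10% band noise and six
replicate datasets the maximum pairwise deviation of four isoform means sits
near the 15% tolerance, and the gate fails a substantial fraction of
honestly calibrated standard sets. That is a property of the declared
tolerance under this noise level, not of the calibration; the acceptance
script therefore reports a pass *rate* over repeated validations.

## Running the pipeline

`run_starpa()` executes, per blot: ratios of every sample against that
blot's own standard lanes, then the cross-reactivity matrix from that blot's
standards; across blots: coefficients are averaged first (the default —
a single mean coefficient per antibody mirrors how such panels report
cross-reactivity; `cross_reactivity = "per_blot"` applies each blot's own
matrix instead, and the two agree exactly in the noiseless limit), the
correction is applied per blot, and per-blot corrected ratios are averaged
(mean of ratios, sample SD with $n-1$). Mean-of-ratios rather than
ratio-of-means is deliberate: each blot is normalised to its own standard,
so each blot contributes one complete, gain-free estimate.

Key parameters, defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `detect_threshold` | 0.05 | mean cross-reactivity below this is treated as non-detectable (set to 0; raw value retained) |
| `correction` | `"sequential"` | subtraction ordered clean-antibodies-first; `"solver"` for arbitrary patterns |
| `cross_reactivity` | `"pooled"` | average coefficients across blots before correcting |
| `background` | 0 | constant subtracted from all densities before ratios (off: the forward model's background policy is left to the user) |
| `cv_tolerance` | 0.15 | standard-equality gate on pairwise deviation |
| `alpha` | 0.05 | ANOVA gate level |
| `max_condition` | 1e8 | solver refuses worse-conditioned systems |

Corrected values can be negative when noise or an overestimated coefficient
drives the subtraction past zero; the raw mean is retained
(`y_corrected_raw_mean`), the headline estimate is floored at zero and the
row is flagged (`negative_flag`) rather than silently truncated.

## Study conditions used in the validation suite

The bundled scenario mirrors a realistic panel study: 4 isoforms, 5
antibodies (4 specific, of which two cross-react at fractions 0.33 and
0.75, plus anti-tag), 4 standards and 9 unknown cell-line lysates on each
of 3 replicate blots (195 bands per study); band noise CV 0.10 and blot
log-gain SD 0.2. The ground-truth abundance profile of the nine cell lines
(`grk_cell_line_truth()`) is synthetic, chosen once to echo the
qualitative pattern reported for such panels (GRK2 highest everywhere,
GRK6/GRK2 between 0.18 and 0.83, one GRK3-rich line). The stochastic
recovery checks use 200 replicate studies; the calibration pick check uses
100 seeded runs; the solver-equivalence check uses 1000 random systems.
These sizes give Monte-Carlo standard errors comfortably below the
tolerances being asserted while keeping the whole suite fast.

```{r example, eval = FALSE}
sc <- default_study_scenario(seed = 1)
st <- simulate_study(sc)
res <- run_starpa(
  st$signals,
  c("anti-GRK2" = "GRK2", "anti-GRK3" = "GRK3",
    "anti-GRK5" = "GRK5", "anti-GRK6" = "GRK6")
)
res$cross_reactivity   # recovered coefficient matrix
res$estimates          # corrected and uncorrected relative abundances
```

## Known limitations

* Relative, not absolute, quantification: $y$ is a molar ratio to the
  isoform's standard; no concentrations are produced.
* Estimates never cross blots that lack standards; there is no inter-blot
  normalisation model beyond the within-blot ratios.
* The subtraction correction propagates the noise of $y_a$ and of $c_B$
  into $y_b$; with low true $y_b$ and large $c_B y_a$ the corrected value
  is noise-dominated (and may be flagged negative).
* The gel-image renderer/quantifier is a demonstration of the densitometry
  round trip on synthetic images, not a processor for real scans.
* Standards must each contain a single isoform; mixed multi-isoform
  standards would make the cross-reactivity coefficients inseparable,
  which is precisely why one standard per isoform is required.
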