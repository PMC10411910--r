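---
title: "Methods: modeling and measuring sub-Poissonian mRNA noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling and measuring sub-Poissonian mRNA noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subpoisson)
```

## The model

Constitutive gene expression is usually modeled with a single rate-limiting
step for mRNA synthesis, which makes synthesis a Poisson process and the
steady-state mRNA count Poisson-distributed (Fano factor
$F = \mathrm{Var}/\mathrm{mean} = 1$) no matter how degradation is
structured. Measured distributions for some low-noise genes are *narrower*
than that, and the model in this package explains how: synthesis wait
times become narrower than exponential when the promoter has to traverse
several sequential states between synthesis events.

The reaction scheme is

$$U_0 \rightleftharpoons U_1 \to U_2 \to \cdots \to U_S
  \xrightarrow{k_B} U_1 + M_N, \qquad
  M_N \xrightarrow{k_C} MC_1 \xrightarrow{k_D} \cdots
  \xrightarrow{k_D} MC_R \xrightarrow{k_D} \varnothing$$

with $S$ promoter states traversed at remodeling rate $k_A$ (each
$U_i \to U_{i+1}$), promoter freeing at $k_B$ releasing one mature nuclear
mRNA $M_N$, nuclear export at $k_C$, and $R$ sequential cytoplasmic
degradation steps at $k_D$ each. The optional closed-chromatin state
$U_0$ (rates `k_open`, `k_close` — the switching rates carry no standard
symbols, so the package names them by what they do) turns the $S = 1$ case
into the classical two-state telegraph model. Two special cases anchor the
noise spectrum:

* $S = 1$, chromatin open: Poisson synthesis, $F = 1$ in both
  compartments, zero nuclear–cytoplasmic covariance;
* $S = 1$ with chromatin switching: the telegraph model, $F > 1$.

For $S > 1$ with open chromatin the model is sub-Poissonian: both Fano
factors fall below 1, further below the more steps there are.

**Units.** Inference and optimization use *effective-lifetime* units: all
rates are expressed relative to the effective cytoplasmic degradation rate
(the inverse of the summed mean lifetimes of the $R$ degradation
intermediates, i.e. $k_D/R$), which is therefore fixed at 1 by setting
$k_D = R$. This removes the overall timescale, which count snapshots
cannot constrain anyway; a global rescaling of all rates provably leaves
every Fano factor and covariance unchanged (and the test suite checks
this).

**Cytoplasmic counts are totals.** smFISH cannot distinguish degradation
intermediates, so all cytoplasmic statistics refer to
$C = \sum_i MC_i$. The degradation steps share one rate $k_D$; the
internal network representation would admit heterogeneous step rates, but
the public surface deliberately does not.

## Exact moments instead of closed forms

Every reaction is a first-order conversion, so the moment hierarchy of the
chemical master equation closes exactly. `steady_state_moments()` treats
the promoter-state indicators as Bernoulli species, eliminates $U_1$
through the conservation law $\sum_i U_i = 1$, and solves the resulting
affine system: a linear solve for the means and a Lyapunov equation for
the covariance matrix. This is exact up to linear-solver tolerance —
machine precision for these tiny systems — and avoids transcribing any
closed-form Fano expressions. The independent check is the other route
through the same model: the Gillespie SSA ensemble (`sample_population()`,
with the inner loop in C++), which the test suite requires to agree with
the moment solver within three standard errors for random models up to
$S = R = 4$, in means, both Fano factors, and the covariance.

```{r moments}
spec <- model_spec(S = 3, R = 3, k_A = 10, k_B = 10, k_C = 5)
steady_state_moments(spec)
```

The covariance between nuclear and cytoplasmic counts deserves a note.
Across random parameter grids (tested over both open-chromatin and
telegraph variants), its sign tracks the *cytoplasmic* noise regime:
negative when the cytoplasmic Fano factor is below 1, zero in the Poisson
case, positive above. Whether the rule should be stated against the
nuclear or cytoplasmic regime is not obvious a priori — the two regimes
can disagree (e.g. telegraph switching combined with multi-step
degradation can give $F_N < 1 < F_C$, and there the covariance is
positive). The package therefore asserts the rule empirically against the
cytoplasmic regime rather than as a theorem.

## Noise floor and export crossover

`min_fano()` minimizes the analytic Fano factor over
$(k_A, k_B, k_C)$ at fixed effective degradation rate, multi-start
L-BFGS-B on $\log_{10}$ rates in $[10^{-1}, 10^3]$ (bounds spanning
several decades around the degradation rate; 24 starts by default, flagged
if no start converges). For the nuclear compartment the optimizer
reproduces the renewal-theory limit $(S+1)/(2S)$ at equal step rates and
slow export; cytoplasmic minima keep falling as degradation steps are
added. The infimum typically sits on the fast-rate boundary of the box —
more steps at faster rates always help — so the reported minimum is the
attainable-within-bounds value, which is the experimentally meaningful
one.

`export_crossover()` locates the export rate at which the nuclear and
cytoplasmic Fano factors are equal, by bracketing the sign change of
their difference on a log grid ($10^{-2}$ to $10^3$ by default) and
bisecting to a relative tolerance of $10^{-6}$. Below the crossover the
cytoplasm is noisier than the nucleus; above it, quieter. A grid with no
sign change returns an explicit `"no crossover in range"` status, and the
Poissonian $S = 1$ case (identically zero difference) returns
`"degenerate"` rather than a root.

## From spot tables to counts

The quantification stack consumes per-spot tables (image, cell,
compartment, 3D position, PSF amplitude) and per-cell tables (length,
width, nuclei count, replicate). It never touches images; segmentation
and spot detection are upstream.

* **Normalization.** Spot amplitudes are divided by the per-image median
  of the *cytoplasmic* spots, so a typical single-mRNA spot scores 1 and
  image-to-image gain cancels. Images without cytoplasmic spots cannot be
  normalized and are dropped with a warning.
* **Counting.** Three methods: `spot` (count spots), `intensity` (sum
  normalized intensities), and the default `hybrid`: spots at or below the
  empirical 95th percentile of the cytoplasmic spots *in the same
  replicate* count as one molecule; brighter spots contribute their
  normalized intensity. The percentile is computed per sample because
  staining efficiency and illumination differ between experiments. Hybrid
  counts are provably at least the spot counts, and at least 95% of the
  cytoplasmic reference spots are counted as singletons by construction.
* **Nascent classification.** With labeled transcription sites, the 3D
  distance of each spot to its nearest TS is bimodal; a per-image cutoff
  at the gap separates nascent from mature nuclear spots. The split is an
  Otsu-style two-class threshold on log distances (a KDE-valley backend is
  also exposed); a unimodal image falls back to a fixed cutoff with a
  warning. Cells whose TS fell just outside the nuclear mask are handled
  either by relabeling near-TS "cytoplasmic" spots as nascent
  (`mask_mode = "expand"`) or by excluding the cell (`"filter"`).
* **Filters.** Length outliers beyond 4 SD of the sample mean (applied
  once, per replicate), optional width (1.5–4 µm) and length (16 µm) caps
  for reanalysis-style data, and TS-labeling QC (exactly 1–2 GFP spots
  per nucleus, no cytoplasmic GFP). Every exclusion is logged with its
  triggering rule. Cell volume, where used as the size covariate, assumes
  a cylinder with hemispherical caps.

## Size correction and windowed profiles

Mean counts scale with cell size, and that extrinsic component inflates
raw Fano factors — enough to make a sub-Poissonian gene look Poissonian.
`size_corrected_fano()` removes it by ordinary least squares:
$F_{\mathrm{corr}} = (\mathrm{Var}(n) - b^2 \mathrm{Var}(s))/\bar n$ with
$b$ the regression slope of count on size. The variance-subtraction and
residual-variance formulations are algebraically identical (both are
exposed); the estimator is invariant to rescaling the size covariate, so
length and volume give consistent answers. Confidence intervals are
percentile bootstrap over cells, 10,000 resamples by default, seeded.

The sliding-window profile is the non-parametric alternative: mean,
variance and Fano factor of all cells within a 1 µm length window, stepped
by 0.1 µm. Windows are retained only in runs that meet the per-stratum
thresholds — at least (50 pooled / 40 per-replicate) cells for 20
consecutive windows for all cells, (40/30, 10) for mononucleated, and
(30/20, 6) for binucleated cells.

## The synthetic-data generator

`generate_population()` + `render_spot_table()` emit ground-truthed
datasets with the statistical structure the estimators assume: cell
lengths uniform on 7–14 µm (a typical fission-yeast interphase range; the
length distribution of real samples is not known to the package, so this
is a stand-in, and configurable), widths normal around 3.3 µm,
transcription scaled linearly with length (applied to the whole synthesis
cycle, $k_A$ and $k_B$ jointly, so concentration homeostasis emerges;
scaling $k_B$ alone is exposed as an alternative), per-cell counts drawn
by exact SSA, 20% binucleated cells emulated as two independent gene
dosages (a phenomenological multiplier — no cell-cycle simulation),
log-normal single-molecule intensities with median 1 and configurable CV
(default 0.3, within the 0.24–0.37 range measured for calibration data;
log-normal keeps intensities positive), nascent transcripts merged into
one TS spot per nucleus whose intensity is the *sum* of its molecules'
intensities, per-image gain variation, and a 2% rate of TS-outside-mask
label corruption.

What the generator does *not* emulate: optics (PSF overlap, detection
misses), segmentation errors beyond the TS-mask flag, cell-cycle
structure beyond the mono/bi dichotomy, and extrinsic rate variability
other than size scaling. Passing calibration tests therefore show that
the estimators are correct *given* clean spot tables, not that upstream
image processing is.

One deliberate property worth knowing: with purely single-molecule
cytoplasmic spots, the hybrid rule assigns the top ~5% of spots their
intensity value, which biases counts up by the tail mass
(≈ 4% of the mean at CV 0.3) and the Fano factor up by
$F\,(\mu_m - 1) + \sigma_m^2/\mu_m \approx 0.05$, where $\mu_m, \sigma_m$
are the per-molecule weight moments. That is the price of robustly
counting genuine multi-mRNA TS spots; the spot count, which is exactly
unbiased for singleton spots, is reported alongside (and is what the
calibration scripts show recovering the analytic Fano most closely in the
cytoplasm). The intensity count is always the noisiest of the three —
summing per-spot technical variation into every cell's count — and the
estimator ordering intensity ≥ hybrid ≥ spot in cytoplasmic Fano is
asserted in the tests.

## ABC inference

`abc_rejection()` fits $(k_A, k_B, k_C)$ for fixed $(S, R)$ in
effective-lifetime units. Summaries are the nuclear and cytoplasmic means
and Fano factors; the nuclear fraction is deliberately *excluded* so it
remains an independent check of a fitted model. Data-side Fano factors
should be size-corrected; model-side summaries are raw analytic moments —
the model has no size covariate, and the size-corrected statistic is the
comparable intrinsic quantity. Distances are Euclidean after dividing
each summary by its SD across proposals, which makes acceptance invariant
to rescaling any summary. Proposals are log-uniform on $[10^{-1}, 10^3]$
per rate (configurable; these are package defaults, not values inherited
from any particular study), and the accepted set is the
`tolerance_quantile` fraction (default 1%) with smallest distance.

Using analytic moments as the model summaries — rather than simulating a
population per proposal — is exact for this model class and roughly three
orders of magnitude faster; the SSA path remains available for
validation. Model selection over candidate $(S, R)$ draws the same number
of proposals per candidate, pools them to standardize distances, applies
one common absolute tolerance, and reports acceptance-proportional
probabilities under a uniform model prior; ties are reported, never
broken. Single-step candidates cannot reach Fano factors below 1, so
sub-Poissonian data exclude them cleanly, while moment-level summaries
genuinely cannot distinguish, say, $S = 3$ from $S = 4$ — the
model-choice table shows that honestly rather than manufacturing
certainty.

Mononucleated cells are the intended stratum for fitting (binucleated
cells mix late-mitotic physiology into the counts), and nascent
transcripts must be excluded from the nuclear counts first, because the
model's $M_N$ is mature nuclear mRNA — the analysis scripts demonstrate
the full path.

## Numerical choices and problem sizes

* Linear solves: base-R `solve()` on systems of dimension ≤ ~10 (means)
  and ≤ ~100 (vectorized Lyapunov); no tolerance knobs needed.
* Crossover bisection: relative tolerance $10^{-6}$ on $k_C$; default
  grid $10^{-2}$–$10^3$, 41 log-spaced points.
* Optimizer: 24 random log-space starts, L-BFGS-B, `factr = 1e4`.
* Bootstrap: percentile, 10,000 resamples by default, computed in
  1,000-replicate chunks to bound memory.
* Simulated problem sizes in the shipped analyses: 20,000-cell SSA
  ensembles for validation, 2,000-cell synthetic datasets for estimator
  calibration, $10^4$–$2 \times 10^4$ ABC proposals — sizes at which the
  pipeline's answers are stable to reseeding while the full analysis
  chain runs in minutes on one core.
* All stochastic entry points require an explicit integer seed; the C++
  SSA uses R's RNG stream, so a single `set.seed()` reproduces everything
  downstream.

## Known limitations

Nascent-transcript dynamics at the TS are outside the model (the TS spot
is rendered and classified, but no elongation model is fitted), as are
full CME distributions (moments only), extrinsic-noise convolution, ABC
beyond plain rejection (no SMC), and any claim about specific genes —
fitting real gene-level data requires the corresponding cell-level spot
tables, which are not part of this package.
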