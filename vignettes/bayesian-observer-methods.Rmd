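---
title: "A Bayesian observer for joint color-constancy and color-memory experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian observer for joint color-constancy and color-memory experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huememory)
```

## The scientific problem

Judging surface color places two demands on the visual system at once:
the surface reflectance must be disentangled from the illumination
(color constancy), and a percept formed at one moment must be retained
while another stimulus is inspected (short-term color memory). These
two processes are usually studied separately, under the implicit
assumption that they compose independently. `huememory` provides a
complete simulation-and-analysis pipeline for testing that assumption
in a 2 × 2 factorial 2AFC hue-judgment design:

| condition  | backgrounds  | presentation |
|------------|--------------|--------------|
| baseline   | symmetric    | simultaneous |
| constancy  | asymmetric   | simultaneous |
| memory     | symmetric    | 2 s delay    |
| joint      | asymmetric   | 2 s delay    |

On every trial the observer reports which of two center patches — a
fixed reference and an adjustable test — appears *bluer*. Hue is
parameterized as an angle on an equiluminant circle (radians, larger =
bluer) and treated as an unwrapped real line: the stimulus range spans
a small arc (three greenish references at 2.8, 3.2 and 3.6 rad by
default), so circular statistics are unnecessary. Symmetric blocks use
one uniform background, gray or blue; asymmetric blocks split the
display into a gray field on the left and a blue field on the right,
the standard CRT proxy for an illumination difference.

## The generative model

The synthetic observer is a quantitative instantiation of a
Bayesian-estimation account of the task. For each stimulus interval it

1. draws a noisy hue signal $s \sim \mathcal{N}(h, (\kappa\sigma_s)^2)$,
   where $\sigma_s$ is the sensory likelihood width and $\kappa \ge 1$
   multiplies the width for the *remembered* stimulus (the first
   interval of a delay trial) and its background — memory retention is
   modeled purely as likelihood broadening;
2. infers the illuminant from the background. Backgrounds carry nominal
   illuminant values on a one-dimensional axis — gray at $0$, blue at
   $\delta$ (`illuminant_shift_blue`; only the difference is
   identifiable) — and the estimate is the conjugate-Gaussian posterior
   mean of the nominal value under the illuminant prior
   $\mathcal{N}(\mu_I, \sigma_I^2)$, with the likelihood width again
   scaled by $\kappa$ when the background is remembered;
3. infers reflectance as the posterior mean of $s - \hat I$ under the
   reflectance prior $\mathcal{N}(\mu_R, \sigma_R^2)$;
4. answers "test bluer" iff
   $\hat R_\text{test} - \hat R_\text{ref} + \varepsilon + c > 0$,
   with decision noise $\varepsilon \sim \mathcal{N}(0, \sigma_d^2)$
   and a constant response criterion $c$ that models task-wording
   bias and is identical in all conditions (so baseline subtraction
   removes it). With probability $\lambda$ the response is replaced by
   a coin flip.

All posterior means use the conjugate form
$w\,x + (1-w)\,\mu$ with $w = \sigma_\text{prior}^2 /
(\sigma_\text{prior}^2 + \sigma_\text{lik}^2)$; infinite prior widths
give uniform priors ($w = 1$). This is the minimal quantitative model
that realizes every qualitative prediction of the Bayesian account:
broader likelihoods give the priors more weight, so remembered stimuli
are drawn toward the prior means.

### Why the priors are block-level

A single fixed illuminant prior makes this observer *exactly additive*:
the shrinkage of the remembered illuminant appears identically in the
pure-memory and joint conditions and cancels out of the independence
prediction (this is easy to verify from the posterior algebra, and the
package's tests do). The interaction between memory and context arises
only if the priors track block statistics, which is also what the
estimation account of central tendency requires. With
`block_priors = TRUE` (the default in `experiment_design()`), once per
block:

* the reflectance prior centers on the block's mean reference hue;
* the illuminant prior centers on the mean nominal illuminant of the
  block's backgrounds: $0$ in uniform-gray blocks, $\delta$ in
  uniform-blue blocks, $\delta/2$ in asymmetric blocks.

In symmetric memory blocks the illuminant prior then sits exactly on
the single background, so pure memory shows only the reflectance
central tendency. In the asymmetric joint block, the remembered
reference background's illuminant estimate shrinks toward the
*midpoint* between gray and blue — the two backgrounds become
functionally more similar, compensation falls short of the sum of the
pure effects, and the joint bias is subadditive. Priors are constant
within a block (no trial-by-trial updating). In distractor blocks the
reflectance prior is additionally pulled toward the distractor
distribution mean (reference mean − 0.2 rad) with weight
`distractor_prior_weight` (default 0.5, a deliberately moderate pull:
the distractors are two of the roughly four stimuli an observer sees
per delay trial).

### Default parameters

Defaults were fixed once from the closed-form behavior of the model so
that the simulated effect sizes sit in the empirically typical range
for this kind of display:

| parameter | default | consequence |
|---|---|---|
| `sigma_sensory` | 0.10 rad | baseline threshold ≈ 0.10 rad |
| `kappa_memory` | 2 | memory/no-memory threshold ratio $\sqrt{5/2} \approx 1.58$ |
| `prior_reflectance_sigma` | 0.6 rad | central-tendency slope ≈ −0.075 (memory bias well below constancy bias) |
| `illuminant_shift_blue` | 0.15 rad | with `prior_illuminant_sigma` 0.15: constancy bias ≈ ±0.10 rad, uniform across references |
| `sigma_decision` | 0.05 rad | adds comparison noise beyond the two sensory draws |
| `lapse_rate` | 0.02 | flattens PMF asymptotes; bounded at 0.05 in fitting |
| `response_criterion` | 0 | set nonzero to verify baseline subtraction |

Under these defaults the closed-form per-cell non-additivity indices
range from about −0.09 to −0.28 (mean ≈ −0.16) and the measured joint
bias is about 75% of the independence prediction.

## The two-phase procedure

`generate_dataset()` reproduces the data-collection protocol:

* **Staircase phase.** Four interleaved weighted up-down staircases per
  reference × reference-background cell (20%/80% targets crossed with
  starting points ±0.25 rad), 20 trials each, interleaved in seeded
  random order: 240 trials per uniform block, 480 per asymmetric
  block. The decision rule is Kaernbach's weighted up-down with a 4:1
  step ratio, which has its equilibrium exactly at the target
  percentile; steps start at 3× the final 0.05 rad step and halve at
  each of the first two reversals (floored at the final size).
* **MOCS phase.** Each cell's staircase data are fitted and five test
  levels are spaced evenly between the fitted 1st and 99th percentiles
  ("roughly 0 and 100%" endpoints), then presented 10 times per level
  in seeded random order, references and backgrounds interleaved. If
  an extreme level's observed proportion lands strictly inside
  (0.25, 0.75) the range is re-derived from the pooled fit and a
  second round of repetitions is collected — a conservative,
  automatable version of manual range adjustment.

Presentation times (500 ms) and the 2 s delay are metadata only: the
trial tables record condition structure, not real-time behavior.
Left/right position is randomized per trial, except that asymmetric
blocks pin gray to the left and blue to the right, so the reference
side there is determined by its background.

## Fitting and analysis

`fit_pmf()` fits
$p(x) = \lambda/2 + (1-\lambda)\,\Phi\!\big((x - \alpha)/\beta\big)$
by maximum likelihood (deterministic 9-start L-BFGS-B over
$(\alpha, \log\beta, \lambda)$, $\lambda \in [0, 0.05]$), pooling
staircase and MOCS trials per cell. The PSE is the 50th percentile of
the *underlying* normal ($\alpha$; the lapse scales asymptotes without
moving the underlying percentiles) and the discrimination threshold is
the 75th–50th percentile distance $\beta\,\Phi^{-1}(0.75)$, so
threshold and spread stay exactly proportional. Whether thresholds
should instead be read off the lapse-scaled curve is a convention
choice; the underlying-normal convention is declared, not inferred.
Perceptual bias is the PSE difference from the baseline condition of
the same reference and reference background, which cancels any
constant response bias.

The independence analysis takes the per-background match sets
$r_i \mapsto m(r_i), c(r_i), j(r_i)$ (memory, constancy, joint
matches, each $r_i + \text{bias}$). Under independence the joint match
should be the constancy match *to the memory-biased reference*:
$p(r_i) = C(m(r_i))$, where $C$ is the piecewise-linear interpolant
through $(r_i, c(r_i))$ — exact whenever constancy is affine in
reference hue, which is also what the generative model predicts.
Extrapolation beyond the reference range is allowed to 10% of the
range width (warning past 4%, the scale of departure regarded as
benign) and refused beyond that: a hard cap prevents silent nonsense
on noisy synthetic data. Departures from additivity are summarized by

$$\mathrm{NI} = \frac{|j - r| - |p - r|}{|j - r| + |p - r|} \in [-1, 1],$$

zero at equal magnitudes, negative for subadditivity, positive for
superadditivity — the simplest bounded index with those semantics
(the index is undefined when both biases are zero, and the code says
so rather than returning 0/0). Supporting statistics use standard
machinery: OLS for the central-tendency slope of memory bias on
reference hue, exact binomial tails for one-tailed sign tests (ties
dropped), and Pearson correlations with *t* p-values for
bias–threshold relationships, with logged (never silent) outlier
exclusion.

## What the generator does and does not emulate

The synthetic observer reproduces: binary "bluer" judgments with
monotone psychometric functions; context-induced hue shifts of
opposite sign for the two reference backgrounds; memory-induced
precision loss and central tendency; their subadditive interaction;
and distractor-induced shifts toward yellower hues. It does **not**
render checkerboard stimuli or model luminance/chromatic perturbation
of individual checks, does not touch calibrated color spaces (the hue
axis is abstract), has no trial-by-trial prior updating, no sequential
dependencies or attentional lapses beyond a constant lapse rate, and
no illuminant-estimation noise (the illuminant estimate is the
deterministic shrunk nominal value, so simulated constancy leaves
thresholds unchanged, whereas human constancy thresholds rise
modestly). Passing tests therefore validate the pipeline's inferential
machinery and the qualitative behavior of the estimation account — not
any claim about human data, which the package does not contain.

## Numerical choices and degenerate inputs

* Fits are deterministic given the data (fixed multi-start grid); the
  convergence flag is honest and unconverged cells are *listed*, never
  silently dropped.
* Cells whose responses never straddle the PSE are non-identifiable
  and rejected with a diagnostic; `select_mocs_levels()` refuses
  degenerate (zero-spread) fits; staircases refuse updates past their
  trial budget.
* All randomness flows through per-stage child seeds derived from one
  master seed; the seed of each block is recorded in its trial rows,
  and identical seeds give byte-identical tables.
* Simulation sizes in the test-suite and acceptance runs were chosen
  from the closed-form effect sizes so Monte-Carlo noise sits well
  below the weakest expected effect (e.g. ~5,000 trials per cell for
  the subadditivity check, ~10,000 for the additivity null).

## Known limitations

The hue line is unwrapped, so the model is inappropriate for stimulus
sets spanning a large arc of the hue circle. The block-prior update is
an idealization (instantaneous, exact); a learning-rate version would
interpolate between the fixed-prior (additive) and block-prior
(subadditive) regimes. Constancy in the model costs no precision. And
the NI convention, while satisfying all stated semantics, is one of
several bounded indices that do; comparisons across studies should
compare conventions first.
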