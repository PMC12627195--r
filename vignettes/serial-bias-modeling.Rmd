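---
title: "Modeling serial biases in continuous reports and mouse trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling serial biases in continuous reports and mouse trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In continuous-report psychophysics a participant reproduces a feature of a
stimulus — here a hue on a 360° color wheel — by clicking on a response
wheel. Reports are systematically biased by the *previous* trial's
stimulus: attracted toward it under some task regimes, repelled from it
under others ("serial dependence"). The standard description of this bias
is the first derivative of a Gaussian (DoG) of the relative feature value
of the previous trial,

$$y(x) \;=\; \alpha \, w \, x \, c \, e^{-(wx)^2} \;+\; \beta,
\qquad c = \sqrt{2}\,/\,e^{-1/2},$$

where $x \in (-180°, 180°]$ is the previous target expressed relative to
the current one (positive = clockwise), $y$ is the mean signed report
error, $w$ (1/deg) scales the curve width, $\beta$ (deg) absorbs any
x-independent bias, and the constant $c$ normalizes the curve so that its
extremum equals $\alpha$ exactly: $\alpha$ (deg) is read directly as the
signed peak bias — positive for attraction, negative for repulsion. The
peak sits at $x = 1/(w\sqrt 2)$.

The package estimates $\alpha$ (and $w$, $\beta$) for three report types —
an immediate *perceptual* match of a visible target, a *consolidation*
report given right after stimulus offset, and a delayed *retrieval*
report — and, from mouse-cursor trajectories recorded during each
response, resolves how the bias evolves *within* a single response
movement.

## Data reduction

Trial errors are signed circular differences between response and target.
Per participant × report type, errors are grouped by the relative color
$x$ of the previous trial, which the design steps through
$-144°, -108°, \dots, +144°$ (nine conditions), and summarized by the
circular mean (direction of the mean resultant vector). Random-condition
trials (an off-grid color roughly every tenth trial that decouples hue
repetition from the relative-color manipulation) are excluded, as is the
first trial of a session. A tenth condition at $\pm180°$ is synthesized as
the plain average of the $-144°$ and $+144°$ means, for continuity of the
circular feature space; a sign-flipped variant
$(\bar y_{+144} - \bar y_{-144})/2$ is available behind
`synthesize_edge(edge = "flip")` because plain averaging and antisymmetric
averaging are both defensible readings of "averaging the two edges" (the
default yields ≈ 0 under odd symmetry, consistent with the DoG's
near-zero prediction at 180°).

Two sign conventions circulate for $x$; this package defines
$x = \mathrm{wrap}(\text{previous target} - \text{current target})$
(previous relative to current, positive = clockwise), and
`convention = "current_minus_prev"` flips it for sensitivity analyses.

## The hierarchical model

Condition means are modeled as Gaussian around the DoG:

$$y_{ijb} \sim \mathcal N\!\big(\mathrm{DoG}(x_b;\,
\alpha_{ij}, w_{ij}, \beta_{ij}),\ \sigma^2\big),$$

with cell-level amplitudes decomposed into participant and report-type
effects, $\alpha_{ij} \sim \mathcal N(\alpha_i + \alpha_j,\ \delta^2)$:
participants ($\alpha_i$) are random effects with a sum-to-zero
constraint and a half-normal scale hyperprior; report types ($\alpha_j$)
are fixed effects. Log widths and intercepts get analogous report-level
hierarchies. The four-level variant adds a time-point layer
($\alpha_{ijt}$, with report × time fixed effects and a width shared
across time within participant × report) for horizontal cursor deviations
at twenty 5%-steps of normalized movement time. Its residual scale is
estimated *per time node*: deviation noise in pixels grows roughly with
the cursor's radial progress (about tenfold from onset to click), and a
single pooled residual would leave the small early-movement amplitudes
essentially unidentified — in calibration runs it produced slowly mixing,
even sign-inverted early-node estimates, while per-node scales agree
with per-node least-squares fits.

The *headline* amplitude reported per report type (and time point) is the
participant-marginal mean of the cell-level draws,
$\tfrac1P\sum_i \alpha_{ij}$, summarized by its posterior mean and 95%
highest-density interval (shortest sorted-window interval), with a
three-way sign verdict by whether the HDI crosses zero.

### Sampling

Inference is MCMC via JAGS (rjags). Two parameterization choices matter
and were fixed by simulation-based calibration on the synthetic generator:

* **Non-centered cell effects.** The interaction scale $\delta$ is
  typically near zero, which funnels a centered sampler; writing
  $\alpha_{ij} = \alpha_i + \alpha_j + \delta z_{ij}$,
  $z_{ij}\sim\mathcal N(0,1)$ removes the pathology (split-$\hat R$ = 1.00
  at default sizes versus 1.2–1.9 centered).
* **Sum-to-zero participant effects.** Without it, the additive trade-off
  between $\alpha_i$ and $\alpha_j$ is identified only through the
  priors, which mixes poorly and inflates posterior SDs about threefold.

Defaults run 4 chains and retain 12,000 total draws after 12,000 total
warm-up iterations for the three-level model (2,000/2,000 four-level),
pooled across chains — so the default three-level posterior is exactly a
12,000 × participants × 3 array. Convergence is monitored by split-$\hat R$
on all population-level parameters; values above 1.05 raise a warning but
still return results, keeping failed runs inspectable. Draws are
bit-for-bit reproducible given a seed.

### Priors and width identifiability

Priors are weakly informative on the scale of reported serial biases:
$\alpha_j \sim \mathcal N(0, 10°)$, $\beta$-effects
$\mathcal N(0, 5°)$, half-normal(5°) scales for the participant and
interaction SDs and the residual. The log-width prior is deliberately
tight: $\log w \sim \mathcal N(\log 0.02,\ 0.10)$ with cell deviations of
scale 0.08. The 36°-step design simply cannot resolve widths far outside
this range: if $w$ drifts upward the DoG peak moves inside the innermost
±36° conditions where no data exist, the regressor collapses at every
measured condition, and the amplitude becomes unidentified (in
calibration runs with a loose prior, weak-amplitude conditions showed
3–4× inflated $|\alpha|$ with HDIs spanning tens of degrees). Treating
the width as known to about ±20% restores unbiased amplitude recovery;
all prior scales are exposed in `dog_priors()`.

A deterministic least-squares fit (`fit_dog_ls()`, profiling $w$ on a
grid with closed-form $\alpha, \beta$, then refining) serves as an
independent oracle: on a single participant the hierarchical posterior
means must agree with it within posterior uncertainty, and the test suite
asserts this.

## Trajectory statistics

Each response's cursor path (screen-centered pixels, y up) is cut at
*movement onset* — the first sample strictly more than 10 px from the
center, where the cursor is reset before each response — linearly
interpolated onto a 101-point normalized-time grid over [onset, click],
and rotated so the target's wheel direction is vertical; the rotated
horizontal coordinate $h(t)$ (positive = clockwise of target, matching
the error sign) carries all bias. Trajectories that never leave the
threshold circle are excluded from trajectory analyses only; their trials
remain in the error analyses.

Two area-under-curve statistics summarize a path:
$\mathrm{AUC}_{\text{with}} = \int_0^1 h(t)\,dt$ (trapezoid rule), and an
endpoint-excluded variant integrating $h(t) - t\,h(1)$ — subtracting the
straight ramp to the final click is the unique linear detrending that
zeroes the endpoint while preserving $h(0)$, and under the trapezoid rule
the two variants differ by exactly $h(1)/2$, an identity asserted for
every trajectory. AUCs are averaged arithmetically per condition cell
(they live on a line, not a circle), edge-synthesized like errors, and
fed to the same three-level model; units are px·(unit normalized time),
with a `scale` factor (e.g. 100 for percent-time) for comparability with
other conventions. The time-resolved analysis instead fits $h$ at each
5%-node with the four-level model, separately for early- and late-onset
response sets from a within-cell median split of onset latencies (ties
and the median-valued response go to the early set; cells with fewer than
two usable responses are flagged).

## What the synthetic generator emulates

`simulate_experiment()` generates the full design: 20 participants, 150
perceptual trials and 400 working-memory trials each (one consolidation
plus one retrieval report per WM trial), targets stepping ±36°…±144° in
shuffled balanced blocks with one uniform random-condition trial per block
of ten. Report errors are von Mises with mean
$\mathrm{DoG}(x; \alpha_{\text{true}}, w=0.02, \beta=0)$ and
report-specific concentrations. Design choices a user should know:

* **Amplitudes** default to −0.8° (perceptual), +1.6° (consolidation),
  +6.2° (retrieval), i.e. repulsion during perception turning into
  growing attraction across memory stages. A participant-level offset
  (SD 1°) added to all three report types creates correlated individual
  biases and leaves a minority of participants with attractive perceptual
  biases (about 15–16 of 20).
* **Noise** is von Mises with κ = 100 / 30 / 20 for
  perceptual / consolidation / retrieval (circular SDs ≈ 6° / 11° / 13°):
  matching a continuously visible target is far more precise than
  reporting from memory, and precision degrades over the retention
  interval. A single shared κ would either drown the small perceptual
  effect or understate memory noise.
* **Trajectories** move radially outward (radius $R s^{0.8}$ over
  normalized time $s$, i.e. fast early progress) at wheel angle
  target + $\mathrm{DoG}(x; \alpha_{\text{eff}}(s))$ + a ramp
  $s \cdot \varepsilon$ carrying the trial's drawn response residual, so
  the click lands exactly on the simulated response. The amplitude
  profile $\alpha_{\text{eff}}(s)$ is a decaying repulsive logistic plus
  a rising attractive logistic whose amplitude is solved so
  $\alpha_{\text{eff}}(1)$ equals the trial's generating amplitude. For
  consolidation reports with early movement onset the defaults
  (repulsion −5°, midpoint 0.3; attraction midpoint 0.5) cross from
  repulsion to attraction near 40% of movement time; late-onset
  consolidation movements drop the repulsive component entirely —
  relying on the consolidated memory trace only — because an
  attraction-midpoint shift alone cannot remove the early repulsive
  phase of the profile. Perceptual profiles are constant (the bias is
  available throughout), retrieval profiles are pure early-rising
  attraction. Motor noise is 2 px per sample. Onset latencies are
  log-normal (median 300 ms) and movement durations log-normal
  (median 700 ms).

These defaults reproduce, by construction, the qualitative phenomena the
analysis is meant to detect: the perceptual-to-memory sign flip, the
endpoint/path dissociation for consolidation (endpoint-included AUC
positive, endpoint-excluded negative), and a repulsion-to-attraction
crossover confined to early-onset movements. What passing tests on this
generator show is therefore that the *pipeline* recovers such structure
when present at realistic noise levels — not that real data contain it.
Real data differ in ways the generator deliberately omits: no
guessing/swap mixtures in the error distribution, no categorical color
biases or inhomogeneity of the hue circle, no velocity profiles or
submovement corrections in the cursor paths, and no dependence of noise
on the relative-color condition. The exclusion rules are also idealized:
the generator steps from the random trial's color on the 36° grid, so
post-random trials are on-grid and includable
(`summarize_conditions(exclude_post_random = TRUE)` implements the
stricter exclusion for data where that is not true).

## Numerical and degenerate-input conventions

* Signed offsets live in (−180°, +180°]; exactly opposite colors map to
  +180° so binning is deterministic.
* A circular mean with (near-)zero resultant length is an error, never a
  silent arbitrary angle.
* Off-grid relative colors on non-random trials (beyond 1° tolerance) are
  a data-integrity error rather than a nearest-bin guess.
* Empty condition cells are reported by a warning, not dropped silently.
* Onset latency ties in the median split go to the early set; the
  split-half $\hat R$ of a zero-variance chain is `NA` with a warning.
* `w > 0` is enforced by bounds in the least-squares fit and a log
  transform in the Bayesian model, so the bias sign is carried by
  $\alpha$ alone.

## Problem sizes used by the shipped checks

The test suite exercises MCMC at reduced sizes chosen to keep the full
suite fast while preserving the assertions' meaning: recovery runs use 8
participants at the full trial counts with 1,600 retained draws over 2
chains and check HDI coverage of the realized (participant-marginal)
truth across 20 simulate–fit repetitions; the trajectory dissociation
check uses 8 participants × 150 WM trials; the acceptance script runs the
full 20-participant design with the default 12,000-draw sampler for the
error and AUC models and the default 2,000-draw four-level sampler for
consolidation-only early/late time courses. These sizes are the package's
own choices and are stated here so results can be regenerated exactly.

## Known limitations

* The bias is aligned to the previous *stimulus*; previous-response
  alignment is not implemented.
* The model fits condition-level means with a shared Gaussian residual,
  not trial-level circular likelihoods; very low trial counts per cell
  therefore understate cell uncertainty.
* The wheel is treated as a continuous 360° circle; analyses in a
  180°-folded hue space would need a different wrapping.
* JAGS's samplers are not gradient-based; the non-centered
  parameterization makes this model mix well, but substantially larger
  hierarchies may need longer chains.
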