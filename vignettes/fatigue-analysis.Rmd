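---
title: "Methods: driver fatigue analysis from physiological signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: driver fatigue analysis from physiological signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivefatigue)
```

## The problem

During a long, monotonous drive a driver moves through three mental states:
alert (level 1), able to concentrate but no longer fully alert (level 2),
and losing interest in remaining awake (level 3).  Choice reaction time —
the latency to press the button matching an announced stimulus, sampled
every few minutes — lengthens as fatigue accumulates, and physiological
signals shift with it: EEG alpha activity (8–13 Hz) rises while beta
activity (13–30 Hz) falls, so the α/β band-power ratio grows; heart-rate
variability, summarised by the standard deviation of RR intervals (RRSD),
changes with autonomic balance.

This package implements the full analysis chain on that premise:

1. **`synthdata`** — generate sessions with exactly this statistical
   structure (no recordings are publicly deposited, so everything
   downstream must be testable on synthetic data);
2. **`features`** — reduce raw signals to nine physiological factors per
   reaction-time sample;
3. **`grey`** — rank the factors against the reaction-time sequence by
   grey relational analysis (GRA);
4. **`gasvm`** — classify the three levels with a hierarchical pair of
   RBF soft-margin SVMs whose `(C, g)` are tuned by a genetic algorithm
   with K-fold cross-validation accuracy as fitness;
5. **`evaluate`** — confusion-matrix metrics, reaction-time growth rates,
   rolling volatility;
6. **`run_all`** — one seeded, persisted end-to-end run.

## The feature set

Per 60-s EEG epoch, the one-sided Welch PSD is estimated (4-s Hann
segments, 50% overlap; 0.25 Hz resolution resolves the 1-Hz band edges)
and integrated (trapezoid) over δ (1–4 Hz), θ (4–8 Hz), α (8–13 Hz),
β (13–30 Hz) and the broadband 1–30 Hz range.  From these come the ratio
indices α/β, (α+θ)/β and α-PSD/β-PSD.  From the RR series in a 60-s window
ending at each reaction-time sample come heart rate (60/mean RR) and RRSD,
the *population* standard deviation

$$\mathrm{RRSD} = \sqrt{\tfrac{1}{N}\sum_{i=1}^{N} (RR_i - \overline{RR})^2}.$$

Hardware studies distinguish device-exported "average power spectrum"
values of α, β, θ from PSD integrals computed offline.  One signal path
exists here, so `alpha_over_beta` and `alpha_over_beta_psd` are numerically
identical; both columns are kept so the table retains the canonical
nine-factor layout, and the duplication is resolved explicitly at ranking
time (see *Ties* below).

Alignment choices that the data dictate rather than any formula: epochs are
treated as half-open intervals `(start, end]`, so a reaction-time sample
falling exactly on a 60-s boundary is paired with the epoch just
*completed*.  (The alternative pairs boundary samples with a window that
has not been recorded yet; on synthetic data it biased per-level α/β means
by up to 20% because the paired epoch belonged to the next mental-state
block.)  Samples earlier than one full epoch are dropped with a warning.

A Haar wavelet denoiser (multilevel DWT, soft thresholding, universal
threshold $\hat\sigma\sqrt{2\log n}$ with $\hat\sigma$ from the
finest-level details) is provided for raw-signal cleaning; the synthetic
generator produces noise-controlled signals, so the pipeline does not apply
it by default.

## Grey relational analysis

With reference sequence $x_0$ (reaction time) and factors $x_i$, all run
through the initialization transform $x'(k) = x(k)/x(1)$ (default; min-max
normalization and a combination are selectable), GRA forms
$\Delta_i(k) = |x_0'(k) - x_i'(k)|$ and the coefficient

$$\xi_i(k) = \frac{\min_i\min_k \Delta_i(k) + \varphi\,\max_i\max_k \Delta_i(k)}
                  {\Delta_i(k) + \varphi\,\max_i\max_k \Delta_i(k)},
  \qquad \varphi = 0.5,$$

with the extrema taken jointly over all factors and points.  The relational
degree is the mean coefficient, $\gamma_i = \frac1n \sum_k \xi_i(k)$.  Some
presentations divide by $n-1$ while summing $n$ terms, which makes a
perfect match exceed 1; that convention is selectable
(`degree_denominator = "n_minus_1"`) but the bounded mean is the default.
When several recordings are analysed, degrees are computed per session and
averaged (`grey_rank_cohort()`).

**Preprocessing matters.** The initialization transform compares *relative
growth*: a factor whose trajectory rises 150% while reaction time rises 16%
scores poorly even if both track the same latent state.  Min-max
normalization is scale-free and favours any factor that tracks the
reference's *shape* relative to its own range.  Both are legitimate; the
default follows the transform that feeds the difference sequence in the
standard formulation, and the pipeline exposes the choice.

**Ties.** Exactly tied degrees occur structurally (the duplicated α/β
columns).  `select_top_factor()` warns and resolves ties by a fixed,
documented preference order in which composite ratio indices precede raw
band powers and the plain `alpha_over_beta` label precedes its PSD-labelled
duplicate — when the two columns are one computation, either choice is
scientifically equivalent and the field's conventional label is preferred.

## The classifier

Levels 1–2 form Category I, level 3 Category II.  Stage 1 is a binary
RBF-SVM separating Category II from Category I; stage 2, trained on
Category-I rows only, separates level 1 from level 2.  Inputs default to
reaction time plus the GRA-selected top factor; columns are standardized
with training-set statistics before kernel evaluation because seconds and
ratio units differ by an order of magnitude.

The dual problem
$\max_\alpha \sum_i \alpha_i - \frac12 \sum_{ij} \alpha_i\alpha_j y_i y_j K(x_i,x_j)$
subject to $0 \le \alpha_i \le C$, $\sum_i \alpha_i y_i = 0$, with
$K(x,x') = \exp(-g\|x-x'\|^2)$, is solved by sequential minimal
optimization in compiled code.  Partner selection uses the maximal
$|E_i - E_j|$ heuristic with Platt's deterministic fallback scan; without
the fallback the solver can stall at large $C$ (verified against an
independent libsvm run on a fixture, which the fixed solver matches
exactly).  Dual feasibility ($\alpha_i \in [0, C]$,
$\sum \alpha_i y_i = 0$ to $10^{-6}$) is asserted in the tests.

### Genetic algorithm

Real-coded individuals $(C, g)$; the binary encoding sometimes described
alongside these operators is inconsistent with them, and the arithmetic
crossover $a_k' = a_k(1-b) + a_l b$ ($b \sim U(0,1)$ per gene) and the
boundary-decaying mutation with $f(g) = r_2 (1 - g/G_{max})^2$ only make
sense on the real line.  Mutation moves toward the upper bound when
$r > 0.5$ and toward the lower bound otherwise, staying inside
$[a_{min}, a_{max}]$ by construction; the literal printed sign of the
upper branch would move *away* from the upper bound and can escape the
box, so the standard non-uniform form is used.  Fitness is the stratified
K-fold CV accuracy (K = 10 by default), maximized directly in the roulette
weights — an inverted "$k/F_i$" transform suits minimization problems and
is not applied.  One elite individual survives each generation, making the
best-fitness trace non-decreasing, which the tests assert.

Search bounds default to $C, g \in [0.01, 100]$.  The initial population is
seeded **log-uniformly**: both hyperparameters span four decades and a
linear-uniform draw essentially never proposes $g < 1$, which cripples the
search on smooth problems; the operators themselves act on the linear scale
as specified.  Each stage runs its own GA (a `share_params` flag reuses
stage 1's optimum), and CV folds are fixed across individuals within a run
so fitness differences reflect the hyperparameters, not fold noise.

## Evaluation conventions

`stage_metrics()` reproduces the reporting conventions of two-stage
classification exactly, which are *not* the textbook one-vs-rest rates:

- stage-1 specificity counts a Category-I row as correct only when its
  final level is exact, so stage-1 accuracy equals overall three-class
  accuracy, and specificity $\ne 1 -$ FP rate (FP counts Category-I rows
  predicted level 3);
- stage-2 sensitivity/specificity use whole-row denominators (all actual
  level-2 / level-1 rows), its FN rate counts only level-2 rows predicted
  level 1 (so sensitivity + FN $< 1$ when a level-2 row leaks to level 3),
  and its precision is computed on the Category-I submatrix.

These definitions are pinned by a worked-example matrix whose twelve
derived rates are asserted to the printed decimal in the acceptance tests,
and cross-checked against a from-scratch counting oracle on random
matrices.  Zero denominators yield `NA`, never a silent 0.

`growth_rates()` returns per-group level-to-level growth in percent,
unrounded; its cross-group `average` follows the convention of summary
rows in printed tables — the two-decimal rounded group rates are averaged
with half-up rounding (averaging unrounded rates differs in the second
decimal, e.g. 8.15 vs the tabled 8.16).  Per-level between-group gaps are
computed from the means supplied; note that published summary rows of this
kind are sometimes computed from unrounded source data and then do not
reproduce from the printed means — such values are reported as computed,
not coerced.

"Volatility" of a reaction-time series has no standard definition; it is
implemented as a rolling variance (SD selectable).

## The synthetic world — and what green tests do not establish

`simulate_session()` states one concrete world:

- a 4-h session, three periods (boundaries at 44 and 188 min): level 1,
  then level 2 with occasional stochastic returns to level 1 (transitions
  between adjacent states are not strictly ordered), then level 3;
- reaction times every 3 min: profile level-mean + Gaussian noise
  (SD 0.08 s, doubled before 44 min where behaviour is unstable, floored
  at 0.2 s).  Level means come from the published gender table
  (male 1.21/1.30/1.40 s, female 1.24/1.35/1.46 s), with +0.033 s for the
  over-30 age band (the mean gap between the published age-band rows);
- EEG at 256 Hz as a per-epoch sum of brick-wall band-limited Gaussian
  components, each rescaled to an exact sample SD.  β variance declines
  with level (1.0/0.85/0.7); the α variance is set as *ratio × β*, so the
  realized α/β tracks its per-level target (0.7/1.1/1.8 by default)
  regardless of the β jitter — the ratio is the controlled quantity, as it
  is the index of interest.  Per-epoch log-normal jitter: SD 0.15 on band
  variances, 0.05 on the ratio;
- RR intervals: mean 0.8 s, per-level SD 0.040/0.055/0.070 s (dispersion
  rising as vigilance falls, the parasympathetic-dominance direction),
  floored at 0.3 s.

Gaussian noise, piecewise-constant levels and stationary per-epoch spectra
are stand-ins — no distributional forms are published for any of these.
The generator does not emulate electrode artefacts, eye blinks, overtaking
events (beyond what the RT noise floor absorbs), circadian drift, or
device-specific spectral smoothing.  Consequently a green pipeline
demonstrates that the *methods* are implemented correctly and interact as
designed, not that the published accuracies would be reproduced on real
recordings; the published optimum $(C, g)$ and K-CV accuracy are tied to
undeposited data and are deliberately not asserted anywhere.

Two test-time worlds are derived from the stated one rather than from its
defaults, as their criteria prescribe: the GRA rank-recovery cohorts set
the α/β per-level targets proportional to the reaction-time level means
with small ratio/RT jitter (a cohort in which α/β *by construction* tracks
reaction time most tightly — under the initialization transform the default
world's ranking is dominated by the scale mismatch between a 157% α/β swing
and a 16% RT swing), and the classifier-sanity table draws (RT, α/β) pairs
directly from level-separated Gaussians (SDs 0.04 s and 0.12, counts
112/72/58) so that class separation is controlled exactly.

## Numerical choices

- Welch: 4-s Hann segments, 50% overlap, segment-mean detrend; one-sided
  doubling except DC/Nyquist; band integral by trapezoid on the 0.25-Hz
  grid.  A 10-Hz pure tone of amplitude $A$ integrates to $A^2/2$ within
  5%; adjacent-band leakage is below 2% of a unit-variance component.
- Adjacent bands share edge bins, so the four named bands over-count the
  1–30 Hz broadband integral slightly; the partition property is asserted
  with a 5% allowance.
- SMO: KKT tolerance $10^{-3}$, sweep cap 5000; `converged` is exposed.
- GRA: if all differences are zero (every factor identical to the
  reference) all coefficients are defined as 1.
- Per-stage, per-subject and per-run RNG streams derive from one master
  seed by a string-hash scheme (`derive_seed`), so no two stages share a
  stream and every artefact is reproducible from the run seed; all derived
  seeds stay below $2^{31}$.
- Half-up rounding (`round_half_up`) carries a $10^{-9}$ guard so exact
  .5 boundaries are not lost to binary representation.

## Known limitations

- The SMO solver is plain (full kernel matrix, no shrinking/caching); fine
  for the hundreds-of-rows regime it serves, wrong tool past ~5k rows.
- GRA tie-breaking is only meaningful for the built-in factor layout;
  custom factor sets fall back to input order.
- The device-vs-PSD distinction among the ratio columns cannot be
  reproduced with a single signal path; the columns are documented
  duplicates.
- `read_session()` restores signals from CSV at full double precision but
  does not validate physiological plausibility beyond positivity.
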