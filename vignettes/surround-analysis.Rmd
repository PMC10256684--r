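---
title: "Quantifying classical and competitive surrounds in midbrain spike data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying classical and competitive surrounds in midbrain spike data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(surroundr)
library(dplyr)
```

## The two surrounds and why they are measured differently

Visual neurons of the avian midbrain selection network — the optic tectum
(OT) and the GABAergic nucleus isthmi pars magnocellularis (Imc) — carry two
distinct kinds of inhibitory surround:

* the **classical surround** shapes the response to a *single* stimulus that
  grows within and around the receptive field (RF). It is probed with
  horizontal bars of increasing length centred in the RF: firing rises with
  bar length while the bar mostly recruits the narrow excitatory centre, dips
  as longer bars recruit the broader inhibitory surround, and settles at an
  asymptote once both saturate.
* the **extraclassical (competitive) surround** suppresses the response to an
  in-RF stimulus (S1) when a *second*, distant stimulus (S2, > 30° away and
  stronger) is present — the divisive signature of stimulus competition.

Each surround gets its own statistic:

* **Suppression index (SI)** of the bar-length response profile:
  `SI = (peak − asymptote) / peak`, with the asymptote estimated as the mean
  response to the **three widest bars** presented. The SI is invariant to
  multiplicative rescaling of the whole profile, which makes it robust to the
  slow multiplicative run-down of evoked rates over the hours-long
  baseline → drug → recovery sequence (the peak rate itself is not).
* **Competition slope**: an ordinary least-squares line through per-azimuth
  mean-rate pairs (x = response to S1 alone, y = response to S1 with S2),
  fitted only over azimuths inside the RF. Slope 1 means no competition;
  smaller slopes mean stronger competitive suppression.

A pharmacological manipulation (e.g. GABA-A blockade at the recorded site)
is assessed per site with a repetition-shuffling permutation test on each
statistic, and across sites with nonparametric paired tests on the per-site
differences.

## From spike times to rates

Rates are spike counts in a fixed post-onset window, converted to sp/s, with
the baseline rate subtracted. Count windows are region- and protocol-
specific (`default_window_policy()`): 125–275 ms for Imc tuning curves,
100–250 ms for OT layer-10 tuning curves, 65–175 ms for bar profiles at both.
An alternative bar window of 75–175 ms circulates in example-site displays;
both are supported through the policy table and neither is treated as the
uniquely correct one — the 65 ms onset is the package default.

Two choices the window arithmetic makes explicit:

* the **baseline window** is the 200 ms immediately preceding stimulus onset
  of the same trial. How the baseline rate was estimated is not standardised
  in this literature; a per-trial pre-stimulus window is the common reading,
  and the simulator generates a ≥ 200 ms pre-onset epoch accordingly.
* window membership is `start ≤ t < end`, and baseline-subtracted rates are
  **not rectified at zero** — negative rates are legitimate and downstream
  code tolerates them (an SI can exceed 1 if the asymptote goes negative;
  such values are reported, not clipped).

## The synthetic-data generator

Because per-site values from real recordings depend on a deposited dataset,
every stage is validated instead against a generator whose ground truth is
known (`sim_config()`, `simulate_session()`):

* **Spatial RF**: a one-dimensional difference of Gaussians. A centred bar of
  length $L$ covers a fraction $\mathrm{erf}\!\left(L / (2\sqrt{2}\sigma)\right)$
  of each component's mass, so the expected bar response is
  $r(L) = \text{rundown} \cdot [a_e\,\Phi(L;\sigma_e) - a_i\,\Phi(L;\sigma_i)]$,
  clipped at 0. Loom tuning curves are Gaussian in azimuth with amplitude
  $a_e$.
* **Competition**: S2 is not simulated as a second drive; its entire effect
  is a multiplicative gain $g \in [0, 1.05]$ on in-RF responses
  (the divisive-suppression phenomenology). With zero noise the fitted
  competition slope equals $g$ exactly, which is the parameter-recovery
  anchor of the test suite.
* **Drug switches** are hard per-condition switches, not dose–response
  curves: GABA-A blockade at the recorded Imc site raises $g$
  (release from competition) and leaves the bar DoG untouched; blockade at
  the OT input layer scales the surround amplitude (`surround_scale_drug`),
  flattening the bar profile at both the OT site and the aligned Imc site
  whose surround is inherited from it; silencing a distant Imc site sets
  $g = 1$ at the recorded site and thins the silenced site's evoked spikes.
* **Run-down**: rates are multiplied by `rundown_per_condition` (default
  0.9) at each condition step, emulating the progressive decline over long
  sessions. The SI's invariance to this factor is tested exactly.
* **Noise**: spike counts are Poisson — the evoked count is
  Poisson(rate × duration) placed uniformly in the 250 ms response window
  (latency 50 ms), spontaneous spikes are Poisson throughout the epoch. Only
  window counts matter to the analysis, so no further temporal structure
  (latency jitter, adaptation, bursting) is modelled; spike placement within
  the window is deliberately uninformative.
* **Protocol structure**: 15 repetitions per stimulus value per condition,
  randomly interleaved trial types within a condition, conditions serial.
  Default grids: 11 azimuths spaced 5°, 12 bar lengths from 0.5° to 40°.

Default rates (centre amplitude 100 sp/s, spontaneous 8 sp/s) sit in the
range typical of strongly driven midbrain sites. Two DoG scales are used by
the experiment templates: bar-length designs use σe = 2°, σi = 8° (giving a
pronounced rise–dip–asymptote profile with noise-free SI ≈ 0.40); tuning
designs use a 6° tuning width so that a 5° azimuth grid yields ≥ 5 in-RF
locations, as needed for a stable slope. The tuning width of a site need not
equal the bar-profile centre scale — measured loom tuning reflects stimulus
size and RF scatter as well as the excitatory centre — so the templates set
them independently through the same `sigma_exc` field.

What the generator does **not** emulate: elevation tuning (azimuth-only, as
in the protocol), spike waveforms and sorting quality, habituation, genuine
dose–response pharmacology, and any anatomical circuit structure. Passing
tests therefore demonstrate that the estimators and tests recover the
statistical structure they assume — not that real Imc data satisfy those
assumptions.

```{r}
cfg <- sim_config()
ground_truth(cfg, c("baseline", "drug"))
```

## Permutation tests

Per-site condition comparisons use the repetition-shuffling null: at each
stimulus value *independently*, the pooled per-repetition rates
(15 + 15 by default) are reassigned at random to two pseudo-conditions of
the original sizes; pseudo-condition means are recomputed, the statistic
(SI or slope) derived from them, and the difference stored. 500 permutations
by default. For the slope test the unit of reassignment is the per-repetition
**rate pair** (S1 alone, S1 & S2) — pairs are never split.

Numerical conventions, all of which matter for exactness:

* the p-value is the **literal proportion** of null differences greater than
  or equal to the observed difference. The observed value is *not* added to
  the null set, so p = 0 is attainable and p ≥ 1/n_perm is not guaranteed.
  The degenerate all-equal case yields p = 1, with "≥" counting ties exactly
  as written.
* the ≥ comparison uses a relative guard of 1e-9 so that exact
  mathematical ties are not broken by floating-point noise.
* one-sided orientation: the SI test is oriented baseline − drug (surround
  weakening → positive) and the slope test drug − baseline (release from
  competition → positive); both orientations are available via `direction`
  since the original convention is not fully specified.
* `exhaustive = TRUE` replaces sampling by complete enumeration of all
  balanced reassignments (feasible for ≲ 250,000 combinations); the test
  suite verifies exact agreement with an independently coded enumeration.

```{r}
rt <- simulate_rate_table(default_design_config("imc_gaba_barlength"),
                          protocols = "bar",
                          conditions = c("baseline", "drug"), seed = 8)
tidy(perm_test_si(rt, n_perm = 500, seed = 1))
```

## Population statistics

Across sites the per-site differences (drug − baseline) are screened once —
no iteration — by the median ± 1.5·IQR rule with linearly interpolated
quartiles (R type 7) and a closed inclusion interval; the rule is
quartile-method-sensitive, hence the explicit choice. Which variable the
original screening targeted is not stated; this package applies it to the
difference values, matching how outlier counts are attached to
difference analyses. Surviving differences enter a two-sided Wilcoxon
signed-rank test (`paired_signrank()`: zero differences dropped, exact
distribution for n ≤ 25 without ties, otherwise a tie- and
continuity-corrected normal approximation). Three-condition recovery
analyses run all three pairwise comparisons and Holm-adjust them; both raw
and adjusted p-values are reported because published recovery p-values are
ambiguous about which is printed. A Kolmogorov–Smirnov gate with estimated
parameters (conservative, and documented as such) routes any
normally-distributed metric to parametric alternatives, and
`kruskal_dunnsidak()` covers multi-group comparisons.

The RF needed by the slope analysis is estimated nonparametrically: an
azimuth is in-RF iff its per-repetition evoked rates exceed zero by a
one-sided signed-rank test at α = 0.05 *and* it belongs to the contiguous
run of significant azimuths containing the peak (contiguity suppresses
spurious islands). The published criterion — locations with firing above
baseline — names no test or threshold; a per-location nonparametric test at
the conventional α is the package's reading, and the Gaussian fit to tuning
curves stays purely descriptive (non-convergence flags the fit, it never
aborts an analysis).

## End-to-end designs and the dissociation they test

`run_experiment()` wires the stages together for five designs. The two
headline ones reproduce, in simulation, the dissociation that motivates the
package: GABA-A blockade at an Imc site that only releases the competition
gain (0.6 → 0.95) raises the population median slope by ≈ 0.35 with a
sign-rank p far below 0.01 (40 sites), while leaving the median SI
difference within ±0.03 of zero (28 sites, p > 0.05) — competitive
surrounds are constructed locally, classical surrounds are not.

```{r, eval = FALSE}
res <- run_experiment("imc_gaba_competition", n_sites = 40, seed = 1)
glance(res)
```

Site-to-site heterogeneity in these population simulations: one log-normal
amplitude scale (SD 0.15) shared by centre and surround so the noise-free SI
is constant across sites, log-normal spontaneous rate (SD 0.2), RF centres
scattered on the stimulus grid, and small Gaussian jitter (SD 0.03) on the
competition gains. Paired Imc–Imc analyses include a site only when the
silencing drug significantly reduced responses at the distant site
(one-sided rank-sum at α = 0.05, `site_pair_gate()`), and sites failing a
metric's preconditions (no detectable RF, non-positive peak) are excluded
with logged reasons rather than aborting the run.

## Problem sizes and tolerances used by the test suite

The suite validates: exact equality of the permutation tests with exhaustive
enumeration (instances of 2–3 repetitions per condition); type-I error of
0.05 ± 0.02 over 1000 null simulations per statistic; slope = gain to 1e-10
noise-free and mean slope within ±0.05 of the gain over 1000 noisy
15-repetition sites; SI against numerical quadrature of the DoG to 1e-6 and
run-down invariance to 1e-12; the end-to-end dissociation above at fixed
seed; and the small-sample statistics against sign-flip enumeration and hand
computations. `scripts/acceptance.R` re-derives the headline quantities from
scratch at the study's site counts (40, 28, 14 and 9).

## Known limitations

* The generator's divisive-gain competition is a modelling choice consistent
  with, but not dictated by, the measured tuning curves; alternative
  competitor-drive models would change per-azimuth noise structure but not
  the estimators.
* The slope is fitted with a free intercept (the conservative reading of
  "best linear fit"); a through-origin variant would change per-site values.
* Reading the original deposit's native layout is out of scope; a converter
  to the `trials.csv`/`spikes.csv`/`sites.csv` interchange format is left to
  the user, after which `analyze_experiment()` applies unchanged.
* Elevation is carried as metadata only; all tuning analyses are azimuthal.
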