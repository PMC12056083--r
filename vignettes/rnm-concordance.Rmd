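---
title: "Semi-quantitative network simulation and model-experiment concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-quantitative network simulation and model-experiment concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnmconcord)
```

## The modelling problem

Cartilaginous cells (articular chondrocytes, cartilaginous endplate cells)
integrate mechanical cues — sensed through integrins such as α5β1 and αvβ3
and the osmo-mechanical ion channel TRPV4 — with inflammatory signals such
as TNF. Regulatory network models (RNMs) summarise this signalling as a
signed, weighted directed graph whose node activations lie in [0, 1].
Experimental conditions are encoded as *sustained clamps*: a node held at 0
is fully knocked down, at 1 fully activated, and at 0.5 at a basal level,
for the entire simulation. From random initial conditions the network is
iterated to steady state many times; each steady state is classified
**pro-anabolic** when the matrix-readout node (by convention `ACAN`,
aggrecan) is at or above 0.5, **pro-catabolic** below. The fraction of
pro-anabolic steady states across an ensemble summarises the phenotype a
condition favours.

The second arm is experimental: a bead-based multiplex immunoassay
(Luminex-type) secretome, calibrated from raw median fluorescence
intensities (MFI) to concentrations and then normalized to each analyte's
quantification window. The two arms meet in semi-quantitative concordance
statistics (NMAD and per-protein NRSE) computed over proteins present in
both the model and the panel.

## The dynamics and its parameters

The published chondrocyte network's internal equations are not restated
here; the engine implements a standard continuous-logic formalism, fully
specified so that every test can be checked against closed forms:

* **Aggregated input.** For node $i$ with activators $a$ (weights $w_a$)
  and inhibitors $b$ (weights $w_b$):
  $\omega_i = A_i (1 - I_i)$ with $A_i = \sum w_a x_a / \sum w_a$
  (taken as 1 when the node has inhibitors but no activators) and
  $I_i = \sum w_b x_b / \sum w_b$ (0 when no inhibitors). A node with no
  regulators keeps $\omega_i = x_i$ (self-sustaining), except *pure
  inputs* — nodes tagged `cytokine` or `mechanoreceptor` — which get
  $\omega_i = 0$ and therefore decay unless clamped. This matches the
  biology of the clamped inputs: an unclamped cytokine is simply absent.

* **Update rule.** Explicit Euler on
  $\dot x_i = f(\omega_i) - \gamma x_i$, where $f$ is a logistic of gain
  $h$ rescaled so $f(0) = 0$, $f(1/2) = 1/2$, $f(1) = 1$. The calibration
  is what gives the 0 / 0.5 / 1 clamp values of the condition presets
  their intended meaning: a basal input (0.5) reproduces a basal target.

* **Defaults** (`dynamics_params()`): gain $h = 10$ (steep enough for
  bistability in single-node and toggle motifs), decay $\gamma = 1$ (the
  steady state of a regulated node is then $f(\omega)$ itself), Euler step
  $0.1$, convergence tolerance $10^{-6}$, at most $10^4$ iterations.

* **Convergence** is declared when the maximum node-wise *rate of change*
  $|\Delta x| / \Delta t$ drops below the tolerance. Using the rate rather
  than the raw per-step change makes the criterion invariant to the Euler
  step size and leaves the state within about one tolerance of the true
  fixed point. Non-convergence (e.g. oscillatory attractors) is a flagged
  outcome excluded from steady-state summaries, never an error.

* **Attractor deduplication.** Two converged states are the same attractor
  when their max node-wise difference is below $10^{-3}$ — coarse enough to
  merge numerical twins, fine enough to separate genuinely distinct states
  of a steep-sigmoid network.

Ensembles (`run_ensemble()`) draw unclamped nodes i.i.d. uniform on [0, 1];
the seed fully determines the ensemble. 100 runs per condition is the
default, matching the scale at which such attractor surveys are normally
reported.

## Condition presets

`builtin_presets()` returns ten clamp sets: for each of two derivations
(literature-derived and experiment-derived mechanoreceptor activation), a
day-0 baseline plus control/TNF × unloaded/dynamic. The literature-derived
presets clamp α5β1, αvβ3 and TRPV4 at 0.5 (free swelling) or 1 (dynamic
compression); experiment-derived presets encode observed *absence* of
mechanotransduction — actin clamped to 0, IL-4 at its critical level
0.2585, TRPV4 reduced to 0.25 under TNF — and clamp the dynamic condition
identically to unloaded. TNF stimulation is `TNF = 1` throughout. Values
are carried verbatim and survive JSON round-trips exactly (0.2585 stays
0.2585).

`find_critical_clamp()` locates switch points such as the IL-4 critical
level: bisection on the clamp value of one node, each probe decided by the
majority label of a 25-run ensemble. 25 runs per probe keeps the scan fast
while remaining robust in multistable networks; the probe seed is reused so
repeated scans agree to the bisection tolerance.

## Secretome calibration

`calibrate_panel()` chains the standard immunoassay reduction:

1. **Blank subtraction** per analyte, floored at zero (flagged).
2. **5PL standard curves**: $y = D + (A - D)/(1 + (x/C)^B)^G$, fitted by
   Levenberg–Marquardt with $1/y^2$ weights — the constant-relative-error
   noise structure typical of fluorescence assays. With fewer than five
   distinct standard concentrations the asymmetry $G$ is fixed at 1 (4PL)
   and the curve flagged. Curves that cannot be fitted exclude their
   analyte with a warning.
3. **Inversion** in closed form between the asymptotes; MFI at or below
   the lower asymptote is censored at the lower LOQ, at or above the upper
   asymptote at the upper LOQ.
4. **LOQ normalization**: linear rescaling of concentration to [0, 1]
   between the lower and upper limits of quantification (a log-scale
   option exists but linear is the default — it is the minimal reading of
   "normalized between the limits of quantification").

`aggregate_and_reference()` takes medians across donors (medians are the
robust summary used throughout this kind of small-n donor data), pools the
two sampling days by median — the network model has no notion of time, so
one value per condition is compared against one steady state — and
subtracts the reference condition (`control_unloaded`), placing values on
[-1, 1] with the reference exactly at 0. Per-day concordance remains
available via `pool_days = FALSE`. Analytes undetected in a condition are
lower-LOQ-censored, i.e. normalized to 0.

## Concordance statistics

With $x_n$ the referenced experimental value and $y_n$ the referenced
model activation of aligned protein $n$:

$$\mathrm{NMAD} = \frac{\sum_n^N |x_n - y_n|}{N} \times 100\%$$

$$\mathrm{NRSE}_n = \frac{\mathrm{RSE}_n}{\mathrm{MAX.RSE}}, \qquad
\mathrm{MAX.RSE} = \max_n \mathrm{RSE}_n$$

Two RSE conventions are implemented. The summed form
$\sqrt{(x_n + y_n)^2} = |x_n + y_n|$ is available as mode `"as_printed"`;
it is zero when model and experiment agree in magnitude but differ in
sign, which is inconsistent with its role as an error, so the default mode
is `"difference"`, $|x_n - y_n|$. MAX.RSE is scoped per condition by
default (each condition's worst protein scores 1), with a global option.
Proteins present on only one side are excluded from $N$, never imputed;
name alignment goes through an explicit alias table
(`default_alias_map()`) because assay panels and network models spell
protein names differently.

## What the synthetic generators emulate — and what they do not

The published chondrocyte network and the donor secretome are external to
this package, so every test runs on generated stand-ins:

* `make_benchmark_network()` is a 19-node synthetic network wired so that
  all built-in presets are runnable and key behaviours are planted *by
  construction*: TNF = 1 forces a pro-catabolic steady state; a bistable
  basal-matrix node makes control ensembles split between basins; and the
  readout's activator set is arranged so that, under the recorded scan
  clamps, the majority label flips exactly at a chosen IL-4 clamp level
  (any value in (0, 1) can be planted; the default is 0.2585). The truth
  record carries everything needed to predict downstream statistics.
* `make_synthetic_secretome()` emulates a 73-analyte, 4–5-donor panel
  with TNF-up, TNF-down, time-decaying, null and TNF-induced-absent
  analyte classes, per-analyte 5PL response curves, LOQ censoring and
  log-normal donor/residual noise (defaults 0.2 / 0.1 on the log scale —
  a typical magnitude for immunoassay concentrations; the design has no
  stated error model to inherit, and log-normal is the standard choice).
* `make_paired_fixture()` ties the two together: the secretome's planted
  normalized values for ten shared analytes equal the network's
  ensemble-mean activations, so zero planted deviation implies NMAD = 0%
  in every condition, a single planted deviation $\delta$ on one of $N$
  shared analytes moves one condition's NMAD by exactly
  $100\,\delta/N$, and planted incongruence (experiment flat where the
  model responds) is recovered by the error ranking.

Passing these tests shows the machinery is exact and self-consistent; it
does **not** show that the dynamics formalism reproduces the published
chondrocyte model's numbers (its equations are not restated anywhere
reachable), nor that the noise model captures real donor variability.
Concordance magnitudes on real data therefore remain a user-supplied
question: with the published network file loaded via `read_network()` and
a real calibrated panel, the same functions compute them directly.

## Numerical choices and degenerate inputs

* Clamped nodes are overwritten after every Euler step, so they are exact
  at every iterate, not just in the limit.
* States are clipped to [0, 1] after each step; with the default
  parameters the update cannot leave the box, so the clip only guards
  extreme user-supplied parameters.
* A fully clamped network converges in one iteration to its clamp vector.
* `nmad`/`nrse` on a MAX.RSE of zero define all NRSE as 0.
* Relative condition deltas divide by the baseline mean; a zero baseline
  reports the absolute delta with an `NA` relative change.
* Ties in the error ranking break alphabetically so reports are
  deterministic.
* The 5PL inversion is undefined outside the asymptotes; censoring is a
  flag, never an error, and increasing MFI never decreases the reported
  concentration.

## Problem sizes used in the shipped checks

The test-suite and acceptance script run at desk scale, chosen to keep the
whole suite comfortably fast while leaving each statistic's sampling error
far below its assertion tolerance: ensembles of 100 runs (2 000 and 10 000
for the basin-fraction comparison), a 0.05 grid of initial conditions
against an exhaustive root scan for networks of up to three nodes, 50
replicate noisy standard-curve fits, 50 random networks for the
conservation property, and a 73-analyte noiseless pipeline round-trip.

## A worked example

```{r example, eval = FALSE}
library(rnmconcord)

fx <- make_paired_fixture(seed = 1)
print(fx$ensembles$TNF_unloaded)

report <- concordance_report(fx$ensembles, fx$calibrated_truth,
                             fx$alias_map)
print(report)

bm <- make_benchmark_network(0.2585)
find_critical_clamp(bm$network, "IL4", base_clamps = bm$truth$scan_clamps,
                    seed = 1)
```

## Known limitations

* Boolean (synchronous/asynchronous) update semantics and stochastic
  differential dynamics are out of scope; so is reconstructing the
  published chondrocyte topology.
* The RNM has no time axis: day-to-day contrasts in the data are pooled
  away before concordance by design.
* Oscillatory attractors are only detected as non-convergence; no cycle
  analysis is attempted.
* The alias table ships with common spellings only; panel-specific maps
  should be supplied for real data.
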