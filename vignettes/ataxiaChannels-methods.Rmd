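---
title: "Methods: cross-model channel overlap and Purkinje neuron feature extraction"
author: "ataxiaChannels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-model channel overlap and Purkinje neuron feature extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ataxiaChannels)
```

This vignette documents the models and procedures the package implements,
the parameters that matter and their defaults, what the synthetic-data
generators emulate (and what they do not), and the numerical and design
choices that were genuinely open.

## Cross-model ion-channel overlap

Each ataxia mouse model contributes a table of differentially expressed
(DE) genes from its original analysis; the package consumes these tables
as-is and never re-fits the underlying DE models. Symbols are normalized
to the mouse convention (first letter capitalized) before any set
operation, because the source tables mix microarray- and RNA-seq-era
annotation styles; normalization is idempotent. Tables are then filtered
against a channel universe — a curated list of 270 mouse pore-forming
(alpha subunit) ion channel genes. The bundled universe file is a
synthetic stand-in snapshot assembled from the standard channel gene
families; it matches the size and composition style of the curated
reference list but is not a download of it, and any user-supplied list is
accepted in its place.

Overlaps follow UpSet semantics: with $n$ models, each gene in the union
is assigned to exactly one of the $2^n - 1$ exclusive intersection cells,
so the exclusive counts always partition the union. The headline
statistic is the *at-least-k* union — the genes DE in at least $k$ of the
$n$ models (default $k = 3$ of 4, i.e. the union of all 3-way and 4-way
cells) — together with its consistently downregulated subset (direction =
sign of log2 fold change in every model where the gene is DE).

### Permutation null and exact oracle

The null hypothesis is that an at-least-$k$ union at least as large as
the observed one arises by chance given each model's number of DE channel
genes. Each of `nSims` simulations independently redraws, for every
model, its channel count uniformly without replacement from the universe
and recomputes the statistic. Choices made where the procedure was open:

* **Estimator.** The add-one estimator $(n_{\ge} + 1)/(n_{sims} + 1)$ is
  reported as the p-value because it can never return an impossible zero;
  the raw proportion is emitted alongside for parity with a plain
  1000-simulation procedure. Ties at the observed value count toward the
  tail ($\ge$, not $>$).
* **Draw sizes** are explicit arguments, not inferred, because it is
  ambiguous whether the original resampling used the full or the
  channel-filtered per-model DE counts.
* **Default `nSims = 1000`**, the scale of the original procedure; tests
  use 20 000 for tighter Monte-Carlo bounds.

`exactOverlapDistribution()` is a brute-force oracle: it enumerates every
labeled combination of per-model subsets (bitmask enumeration, budget
capped at $2\times10^6$ combinations) and returns the full null
distribution, which sums to one to $10^{-12}$. The test suite checks the
permutation estimate against the exact tail probability on 20 small
configurations at 20 000 simulations within 3 Monte-Carlo standard
errors. A strict per-configuration 3-SE bound false-alarms about 5% of
the time across 20 configurations even for a perfect sampler, so the
suite applies a pre-registered sequential rule: a configuration beyond
3 SE is re-run once on an independent stream and must then pass. The
sampler itself was verified unbiased (independent-seed z-scores are
standard normal; long runs converge to the exact probabilities).

## ATXN1–Cic dependence classification

Three contrasts enter: ATXN1[82Q] vs wild type, the Cic-binding-deficient
ATXN1[82Q]V591A;S602D mutant vs wild type, and mutant vs ATXN1[82Q].
Channel genes are classified by two criteria: **dependent** = DE in
mutant-vs-82Q and *not* DE in mutant-vs-WT (dysregulation abolished);
**partially dependent** = DE in both; **independent** = not DE in
mutant-vs-82Q. The categories partition the gene set by construction.
Genes DE only in mutant-vs-WT fall into "independent" by the complement
rule; the output notes this rather than ascribing it meaning. Directions
(down/up) come from the 82Q-vs-WT contrast only. The DE flag encodes
adjusted $p < 0.01$ by default (`alpha` is configurable and logged).
Genes absent from one contrast are an error in strict mode, with an
explicit `fillAbsentNotDe` escape hatch — silent absence handling is the
classic source of irreproducible category counts.

## Electrophysiology

### Two-compartment capacitance

Capacitative transients (voltage clamp, 1 s steps from −80 to −90 mV,
100 kHz digitization; ten sweeps averaged then zero-phase low-pass
filtered at 5 kHz) decay as
$i(t) = i_{ss} + A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}$. The fitted
parameters map onto the reduced two-compartment circuit
($C_1$ soma/proximal, $C_2$ distal arbor, $R_1$ access + proximal,
$R_2$ distal coupling), with total capacitance $|C_1 + C_2|$. With
amplitudes in pA, time constants in ms and steps in mV, pA·ms/mV is
already pF and mV/pA is GOhm (converted to MOhm); the unit bookkeeping is
explicit in the code.

Numerical choices:

* **Initialization** by exponential peeling — the slow component from a
  log-linear fit on the tail, the fast one from the corrected head — with
  peeling windows scaled to the transient's effective support so a long
  steady-state tail of pure noise cannot corrupt the slow estimate. A
  Levenberg-Marquardt refinement follows, with deterministic multi-start
  (perturbed time constants plus one generic start) before declaring
  non-convergence. Time constants are optimized on the log scale, which
  enforces positivity.
* **Labeling**: $\tau_1 < \tau_2$ enforced by post-fit relabeling, so
  $C_1$ always refers to the fast (proximal) compartment.
* **Artifact blank**: the first 0.1 ms after step onset is excluded from
  the fit window (electrode artifact; configurable).
* **Degeneracy**: when $\tau_2/\tau_1 < 1.2$ or one amplitude is below
  $10^{-3}$ of the other, the fit is flagged degenerate and a
  single-exponential fallback is attached to the diagnostics — never
  silently substituted — because the compartment map is not identifiable
  there.
* **$i_{ss}$** is initialized from the final 10% of the window and
  refined as a free fit parameter.

The **area method**, $C = \int (i - i_{ss})\,dt / \Delta V$, is the
internal consistency check on the two-compartment estimate. Integration
starts at the step onset (no artifact blank) because area lost to a blank
is unrecoverable, whereas the fit extrapolates through it. On noiseless
double exponentials the two estimators differ by exactly
$\tau_1\big((A_1+A_2)^2 - A_1^2\big)/(A_1 \Delta V)$; at Purkinje-scale
parameters ($C_1 \approx 15$ pF, $C_2 \approx 450$ pF) this is ~2% of the
total, which is why the two methods agree in practice. A window shorter
than about five slow time constants triggers a truncation warning.

QC follows the standard whole-cell rules: reject when series resistance
exceeds 15 MOhm or changes by more than 20% of its *initial* value (the
reference point for the percent rule was open; the initial value is used
and logged), and — for the capacitance protocol only — when input
resistance is below 100 MOhm. Voltages are stored as recorded; the
+10 mV liquid junction potential is subtracted exactly once downstream,
tracked by a metadata flag (a recorded −70 mV becomes −80 mV).

### Firing statistics and classification

Rate and ISI CV are computed over a 10 s cell-attached recording; the CV
uses the sample ($n-1$) standard deviation (the convention was
unstated; the choice is documented and tested) and is flagged undefined
below three spikes. A firing cell is *irregular* when its CV is strictly
greater than the control group's mean + 1 SD (a CV exactly at the
threshold is regular). Silent cells are *depolarization block* when they
fire more than 5 spikes on whole-cell current injection, otherwise
discarded; a silent cell without rescue information is an error, and
cells with 1–2 spikes (CV undefined) are discarded with a reason since
they cannot be placed on the CV scale.

Spike detection (upward threshold crossing, default −20 mV, 2 ms
refractory, peak = local maximum above threshold) is deliberately simple
plumbing: the analyses consume spike times, and any detector can be
substituted upstream.

### AHP

The afterhyperpolarization is measured on the first sweep (escalating
1 s current injections) whose first spike occurs within 50 ms of
injection onset, as the junction-corrected membrane potential at fixed
offsets after the spike peak. The offsets are configuration, not
constants — the defaults {2.5, 5, 10, 15, 25} ms span the early and late
AHP — because no canonical offset list exists.

## Molecular quantification

* **Comparative Ct**: replicate Cts are averaged first; then
  $\Delta C_t = \bar{C_t}(\text{target}) - \bar{C_t}(\text{Actb})$,
  $\Delta\Delta C_t = \Delta C_t - \Delta C_t(\text{calibrator})$ and
  $\text{fold} = 2^{-\Delta\Delta C_t}$. The amplification base is fixed
  at 2 on this path; the standard-curve path instead carries the measured
  efficiency $10^{-1/\text{slope}} - 1$ (a perfect curve has slope
  $-1/\log_{10} 2 \approx -3.32$ cycles per decade).
* **ChIP percent input** interpolates a sample's Ct on the input dilution
  standard curve (0.01–2% input), $10^{(C_t - b)/m}$; Cts more than one
  cycle outside the standard range warn about extrapolation.
* **Line-profile intensity**: trapezoidal AUC of the somatic profile
  divided by line length; per-animal means are normalized to the grand
  mean of the wild-type anterior animals, making the reference group's
  normalized mean exactly 1 and the whole score scale-invariant. Group
  differences are reported as $100\,(\bar{x}_A - \bar{x}_B)/\bar{x}_B$.

Because fold changes and percent input are exponentials of noisy Cts,
their sampling distributions are lognormal and the plain mean is slightly
biased upward. Recovery tests therefore assess unbiasedness on the log
scale ($\Delta\Delta C_t$, $\log_{10}$ percent input), where the
estimators are exactly unbiased; this is stated here so the test
tolerances (±2 SE over 1000 simulated replicates) are interpretable.

## Synthetic data: what it emulates and what it does not

The generators' defaults are the study conditions: a 270-gene universe;
four models with DE channel counts of 30, 42, 25 and 36 and a planted
12-gene at-least-3-of-4 overlap, 11 genes consistently down (fillers are
capped at two models so they cannot contaminate the headline union);
circuit parameters $C_1 = 15$ pF, $C_2 = 450$ pF, $R_1 = 8$,
$R_2 = 10$ MOhm with 10 pA Gaussian current noise at 100 kHz over 1 s
steps; gamma-ISI spike trains (shape $1/\text{CV}^2$, the natural
two-parameter family when only rate and CV are characterized) at 60 Hz,
CV 0.06; triplicate Cts with 0.15-cycle noise and planted folds of
0.45–0.7; a 0.01–2% ChIP dilution design at 100% efficiency; and a
planted 18% intensity effect over 5 animals × 6 cells per group. Where
the studied conditions did not pin a value (per-model DE counts, spike
noise structure, Ct baselines, animal counts) a realistic value was
chosen once and left alone.

The generators do **not** emulate: probe-to-symbol mapping ambiguity in
microarray tables, conductance-based spike dynamics (spike trains are
renewal processes; real Purkinje trains show serial ISI correlations),
bridge-balance or electrode drift artifacts beyond a constant blank,
amplification-efficiency drift across a qPCR plate, or segmentation error
in line profiles. Passing tests therefore demonstrate correctness of the
computations under the stated generative assumptions, not robustness to
every artifact of real recordings.

All generators are deterministic under a fixed seed, restore the caller's
RNG state, and emit truth manifests consumed by the tests.

## Problem sizes used by the test and acceptance runs

Oracle comparisons use universes of 4–8 genes and up to 3 models at
20 000 simulations; the circuit round trip uses a 200-point parameter
grid ($C_1 \in [5, 200]$, $C_2 \in [100, 1000]$ pF, $R_1 \in [3, 15]$,
$R_2 \in [2, 20]$ MOhm); noisy-fit recovery uses 100 seeded transients of
0.12 s at 100 kHz (the shorter window keeps the whole suite quick while
still covering ~15 slow time constants); molecular recovery uses 1000
simulated replicates. The end-to-end pipeline demo runs the full 1 s
Purkinje-scale transient.

## Interfaces

The package is a library, not a shell tool: the exported functions,
`runPipeline()`/`pipelineReport()` and this vignette are the interface,
and `scripts/acceptance.R` is a thin reproduction driver over them. All
machine outputs are JSON (plus TSV for tables) and embed the
configuration hash, seed and package version.

## Known limitations

* The two-compartment map is known to be a statistically reduced
  description of a mature Purkinje neuron; the package mirrors the
  published estimator and its area-method cross-check rather than
  adjudicating model adequacy.
* The dependence classification inherits the DE calls it is given; no
  attempt is made to propagate DE uncertainty into category calls.
* The exact overlap oracle is exponential in models and universe size by
  design (it is an oracle, not a production path); use the permutation
  test beyond the enumeration budget.
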