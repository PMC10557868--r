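---
title: "Methods: SPR screening analysis from sensorgram to confirmed hit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SPR screening analysis from sensorgram to confirmed hit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprscreen)
```

## The problem

Surface plasmon resonance (SPR) screens measure, label-free and in real
time, the mass of small molecules accumulating on a protein-coated sensor
spot. A primary screen injects thousands of compounds one by one over
target and control surfaces and must separate genuine 1:1 binders from
bulk-refractive-index artifacts, promiscuous aggregators that stack far
beyond 1:1 stoichiometry, and surface-density artifacts. sprscreen
implements that analysis end to end — sensorgram simulation, referencing,
kinetic and equilibrium affinity fitting, stoichiometry-based triage, a
reporter-assay secondary criterion, and confirmation-tier analytics — with
seeded generators for every input, so the full screen is testable without
any instrument data.

## The interaction model

All binding signal is modeled as a 1:1 (Langmuir) interaction. During an
injection at analyte concentration $C$:

$$R(t) = \frac{k_a C R_{max}}{k_a C + k_d}\left(1 - e^{-(k_a C + k_d)t}\right),$$

and after the injection ends, $R(t) = R_0 e^{-k_d t}$. At equilibrium the
isotherm is $R_{eq} = C R_{max} / (C + K_D)$ with $K_D = k_d / k_a$. $K_D$
is always the quotient of the fitted rates, never an independent
parameter. Internally the package fixes one unit system — seconds, molar,
RU, Da — and all I/O column names carry unit suffixes, because screening
concentrations (tens of µM) and validation concentrations (low nM) differ
by four orders of magnitude and silent unit mixing is the classic failure
mode. Mass-transport limitation and multi-state models are deliberately
out of scope: the analysis layer assumes a plain 1:1 fit, and data that
violate it should fail the stoichiometry gates rather than be rescued by a
more elaborate model.

The stoichiometric capacity of a spot for a given analyte is

$$R_{max} = R_L \cdot \frac{MW_{analyte}}{MW_{ligand}},$$

where $R_L$ is the immobilization level of the protein (the "ligand" in
SPR convention). This single formula powers the triage normalization: an
observed level far above it means super-stoichiometric stacking, far below
it a weak or partial binder.

## What the generator emulates — and what it does not

`generate_library()` draws compounds with hidden truth: molecular weight
log-uniform in 150–800 Da, and for binders $K_D$ log-uniform in 0.1–20 µM
with $k_a$ log-uniform in $10^3$–$10^6\,\mathrm{M^{-1}s^{-1}}$ — the range
a primary screen at 50 µM injection can actually see. Five classes are
planted: non-binders, ideal specific binders (control-inert),
super-stoichiometric binders (3× capacity by default, so they violate the
200 % gate), weak sub-stoichiometric binders (0.3× capacity, violating the
50 % gate), and density artifacts, which carry an extra nonspecific
square-pulse signal on the low-density target spot at 1.5× their
high-density level. The literature observes such density-dependent
compounds without offering a mechanism; the square pulse is the simplest
construction that makes the low-vs-high-density rule testable in both
directions.

The default injection schedule is 60 s baseline, 60 s association, 120 s
dissociation at 1 Hz — typical for a Biacore-class primary screen; no
instrument timings were available to copy, so these are declared choices.

Artifacts are modeled as: per-cycle linear baseline drift (SD 0.005
RU/s) shared by all spots of a cycle; a constant bulk refractive-index
response of the injection plug (default 10 RU) present in every injection
including buffer blanks; a per-cycle DMSO mismatch (uniform within ±2.5 ×
2 RU); and Gaussian point noise (SD 0.2 RU). Protein-coated spots respond
to the plug at 0.85× the empty reference spot — the excluded-volume effect
that solvent correction exists to remove. The solvent-standard ladder
spans ±4× the mismatch scale because the calibration must bracket every
sample query; the package refuses to extrapolate outside it.

What the generator does **not** emulate: air spikes, regeneration
carry-over, surface decay over a run, mass-transport-limited kinetics,
non-linear solvent responses, and compound insolubility. Passing tests
therefore demonstrate correctness of the analysis chain, not robustness to
every instrument pathology.

## Preprocessing

`double_reference()` computes
$(\mathrm{sample} - \mathrm{reference}) - \overline{(\mathrm{blank}_s - \mathrm{blank}_r)}$
pointwise on a shared time grid (grids must match exactly; resampling is
the caller's explicit step). Blanks are averaged rather than
nearest-in-time matched — the simplest defensible reading of "buffer
injected over all surfaces".

The scalar report point is the mean of the last 5 s of association minus
the mean of the 10 s pre-injection baseline. Published screens rarely say
where on the sensorgram the "binding value" was read; late-association
averaging is the conventional choice and both windows are configurable.

Solvent correction is calibrated per spot as a monotone piecewise-linear
interpolant through (reference-spot excess, observed correction) pairs
from the DMSO ladder — exact on a linear mismatch response, and free of
the quadratic-model assumption some vendors use. One numerical subtlety
matters: the reference-spot excess (the x-axis of the calibration) is read
against a **linear baseline fit over the whole pre-injection baseline,
extrapolated under the injection**. Plain mean-baseline subtraction leaves
the cycle's drift (rate × ≈60 s window separation) in the axis, which both
corrupts the calibration and, in the noiseless limit, breaks the exact
invertibility of the artifact model. The long baseline keeps the
extrapolation's noise amplification negligible (≈0.1 RU at default noise).

On noiseless synthetic data the full chain inverts the planted artifacts
to below $10^{-6}$ RU — a property the test suite asserts, spot by spot.

## Kinetic and equilibrium fitting

`fit_kinetics()` fits one $(k_a, k_d, R_{max})$ set to all cycles of a
multi-concentration series simultaneously, minimizing summed squared
residuals over association and dissociation with Levenberg–Marquardt
(minpack.lm) on $\log_{10}$-scaled parameters, from five log-spaced starts
(the best SSR wins; ties cannot occur in practice and the multi-start
trace is kept in the object). Box bounds keep the search physical:
$k_a \in [10^2, 10^9]\,\mathrm{M^{-1}s^{-1}}$,
$k_d \in [10^{-6}, 1]\,\mathrm{s^{-1}}$. A free per-cycle bulk offset
during the injection is floated by default, standard practice for small
residual refractive-index steps. The reported $\chi^2$ is SSR divided by
(points − free parameters). Noiseless round trips recover the rates to
$10^{-4}$ relative; at 1 RU noise on a six-point, two-decade
concentration ladder the median $|\log(K_{D,fit}/K_{D,true})|$ stays
within $\log 1.2$.

`fit_steady_state()` fits the two-parameter isotherm to equilibrium report
points (≥3 distinct concentrations) the same way, and warns when the
highest concentration is below the fitted $K_D$ — the plateau is then
extrapolated, not measured. Replicates are aggregated as arithmetic mean
and standard error of the mean, matching how screening affinities are
conventionally reported.

## The triage cascade

Per compound, observed report points on the target high-density (HD) and
low-density (LD) spots and the control HD spot are normalized to
% $R_{max}$ and passed through three elimination rules: (i) LD raw signal
strictly above HD raw signal; (ii) HD binding strictly above 200 % of
expected $R_{max}$; (iii) HD binding strictly below 50 %. Rule (i)
compares raw RU because the underlying observation is about *signal* on
two densities of the same protein; (ii) and (iii) are percentage gates by
definition. Surviving compounds are ranked by the specificity fold ratio
(target %$R_{max}$ / control %$R_{max}$, HD surfaces), and a ratio of 5 or
more — inclusive — makes a primary hit.

Two policies needed deciding. Negative corrected report points are floored
at zero before normalization: negative binding is referencing noise, and
propagating it produces meaningless negative percentages. A control
%$R_{max}$ at or below zero yields a ratio of $+\infty$ with a flag: a
non-binding control is the *strongest* specificity evidence, so such
compounds rank first rather than being dropped, and the flag preserves
auditability. Every eliminated compound carries machine-readable reason
codes.

## Secondary screen and confirmation assays

Reporter wells are normalized to the DMSO vehicle mean per reporter
(optionally after total-protein normalization); inhibition is
1 − activity. The pass criterion is target-reporter inhibition strictly
above 70 % **and** control-reporter inhibition strictly below 20 %. The
70 % bound is the published criterion; "without inhibiting" the control
carries no published number, so 20 % — a conventional counter-screen
tolerance — is the declared, configurable default. Compounds activating
the target reporter ≥5-fold without activating the control are exported as
a candidate-activator list, ratio only, no statistics. Group comparisons
use the pooled-variance Student t test by default (Welch available),
matching the labeling convention of the screens this mirrors.

CETSA melt curves are fitted with a descending four-parameter logistic;
$T_{agg}$ is the midpoint. The thermal shift is
$\Delta T_{agg} = T_{agg}^{treated} - T_{agg}^{vehicle}$. Published
thermal-shift figures typically plot means ± SE without fitting;
`melt_curve_summary()` reproduces that display, while the logistic fit is
the quantification layer that yields a number to test. The
$\Delta T_{agg}$ confidence interval is a stratified bootstrap (replicate
bands resampled within each temperature, fixed seed) combined with a
Student-t quantile at replicate-level degrees of freedom. This choice was
measured, not assumed: at 3 replicates per arm and 10 % noise, plain
percentile intervals covered a true +3 °C shift only ~76–84 % of the time
at nominal 95 %, while the bootstrap-SE t-interval covered ~97 %; small
replicate counts make percentile intervals anti-conservative.

Dose–response curves use the standard 4PL,
$y = b + (t - b) / (1 + (d/\mathrm{IC}_{50})^h)$, with IC50 defined as the
inflection dose (relative IC50), fitted by the same bounded
Levenberg–Marquardt multi-start. The generator's default dose ladder spans
0.2–1000 µM precisely so that both the reporter and the viability
transitions are bracketed; an unbracketed lower plateau leaves the 4PL's
bottom and IC50 confounded and is an assay-design error, not a fitting
problem. The selectivity index is IC50(viability) / IC50(reporter); > 1
means transcription is inhibited below cytotoxic doses. The group-IC50
comparison reports $100 (\bar{x}_b - \bar{x}_a)/\bar{x}_b$ with the
higher-mean group as baseline, plus a Student t test; whether the test ran
on IC50s or log-IC50s is recorded in the output because conventions vary.

## Reproducibility machinery

Every generator takes an integer seed and restores the caller's RNG state;
`run_screen()` fans one run seed into fixed per-stage substreams, so any
stage can be re-run in isolation. Outputs are plain UTF-8 CSV with unit
suffixes, plus a manifest JSON holding the config hash, funnel counts and
per-file MD5 checksums; two runs with the same configuration are
byte-identical, and the test suite asserts it at the full 1,000-compound
scale.

## Problem sizes used by the test suite

The suite exercises: 100 random parameter draws against a numerical ODE
oracle; 20 replicate noisy kinetic fits on the six-point ladder; 50 random
500-compound libraries against a brute-force re-evaluation of the triage
rules; one noiseless 1,000-compound screen with 10/20/20/950 planted
classes; 100 noiseless 4PL and melt-curve round trips; 60 repetitions of
the thermal-shift coverage experiment (59 bootstrap resamples each); and
two full 1,000-compound pipeline runs for byte-identity. These sizes give
stable pass/fail behavior for every stochastic check while keeping a
default test run in the low tens of seconds.

## Known limitations

- The 1:1 model is both simulator and fitter; model-mismatch behavior
  (e.g. biphasic dissociation) is untested by construction.
- The solvent correction is linear-in-mismatch by design; strongly
  non-linear excluded-volume responses would need the vendor's quadratic.
- The vendor's proprietary fit-uniqueness statistic is not reproduced;
  multi-start SSR agreement is the convergence diagnostic instead.
- Plate-effect corrections (row/column trends, Z′ panels) are out of
  scope for the secondary screen.
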