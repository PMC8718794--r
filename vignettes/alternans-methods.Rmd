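---
title: "Models and methods: troponin kinetics, CRU-lattice alternans, and transient analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alternans)
```

# Scope

This package studies how slowing Ca^2+^ unbinding from cardiac troponin —
the biophysical consequence of the hypertrophic-cardiomyopathy-linked
troponin-T I79N variant — destabilises beat-to-beat Ca^2+^ handling. It
contains four analysis stages and a synthetic-data generator feeding each
of them:

1. **In-vitro Ca^2+^ kinetics** — Hill fits of steady-state titrations
   (K~d~) and single-exponential fits of stopped-flow dissociation traces
   (k~off~), with two-construct comparisons.
2. **A stochastic lattice of coupled Ca^2+^ release units (CRUs)** with
   explicit troponin buffering, paced over a range of cycle lengths to map
   Ca^2+^ alternans.
3. **Optical-mapping transient metrics** — APD/CaTD at arbitrary recovery
   fractions, triangulation, amplitude alternans, and entrainment
   classification from dual-channel fluorescence traces.
4. **Targeted transcript-count statistics** — housekeeping normalisation,
   per-gene Welch tests with Benjamini–Yekutieli FDR control, and ΔΔCt
   quantification.

Everything runs on synthetic data with known ground truth, so every stage
is testable end-to-end by parameter recovery.

# In-vitro kinetics

A titration is modelled as
$$F(\mathrm{Ca}) = F_{\min} + (F_{\max}-F_{\min})
  \frac{\mathrm{Ca}^{n}}{K_d^{n} + \mathrm{Ca}^{n}},$$
fitted per replicate by Levenberg–Marquardt least squares with analytic
seeding ($K_d$ at the half-span crossing) and a log-spaced multistart
fallback. The reported $K_d$ is the mean of per-replicate estimates and
its SEM the standard error across replicates — aggregation across
replicate titrations, not a pooled fit, because replicate-level scatter is
the natural error unit of the assay. The Hill coefficient is free by
default (cooperative thin-filament binding is expected) with a
`fix_hill_n` option.

Stopped-flow traces follow $F(t) = A e^{-kt} + C$ with $t$ measured from
mixing; the first 1.1 ms (instrument dead time) is unobservable, so
recorded traces start there and the fitted amplitude extrapolates back to
$t = 0$. Rates are reported in s^-1^, the conventional unit for
stopped-flow dissociation at low temperature. Averaging at least five
shots before fitting is the default; fitting each trace individually is
available for SEM estimation.

Two-construct comparisons use the unpaired pooled-variance Student t-test
(the convention for these assays); the transcriptomics module instead uses
Welch's unequal-variance form, which is the convention for count panels
with small unequal groups. Zero variance in both groups with equal means
returns p = 1 by convention.

# The CRU-lattice model

## State and fluxes

Each of the $n_x \times n_y \times n_z$ CRUs (20×5×5 by default; a
100×20×10 = 20,000-CRU lattice is supported) carries cytosolic free
Ca^2+^ $c_i$, troponin-bound Ca^2+^ $b_i$, network-SR Ca^2+^ $n_i$ and
junctional-SR (JSR) free Ca^2+^ $j_i$. Troponin is the only buffer with
explicit kinetics, because its kinetics are the subject:
$$J_{\mathrm{trpn}} = k_{\mathrm{on}}(B_T - b)\,c - k_{\mathrm{off}}\,b,$$
with $k_{\mathrm{on}} = 0.0327\ (\mu M\,ms)^{-1}$ and
$k_{\mathrm{off}} = 0.5$ ms^-1^ (control) or $0.1$ ms^-1^ (the
slowed-unbinding variant) — the only parameter that differs between
variants. $B_T = 70\ \mu M$ is the standard total troponin-site
concentration of the model family the $k_{\mathrm{on}}$ value comes from
(the present study does not restate it). All other buffers (a fast
cytosolic buffer, calsequestrin in the JSR) use the instantaneous
rapid-buffering approximation. SERCA uptake is a Hill pump with
$K_D = 0.25\ \mu M$ and coefficient 2; the SR leak grows steeply near a
luminal ceiling (store-overload-induced release), which caps the
attainable SR load. Sarcolemmal exchange is a linear efflux on free Ca
plus a constant background influx; the stimulus is a 2-ms trigger flux
into every dyad with a high trigger ignition rate, emulating L-type
channel opening. Nearest neighbours are coupled diffusively (cytosol and
network SR) with no-flux boundaries.

## The three Rs

Spark dynamics implement the **r**andomness / **r**ecruitment /
**r**efractoriness triad:

* *Randomness*: per-step Bernoulli ignition with a counter-based
  (splitmix64) random stream per CRU, so trajectories are reproducible
  for a given seed and independent of lattice size.
* *Recruitment*: the ignition rate grows as
  $(c/c_{\mathrm{ref}})^{\gamma}$ with $\gamma = 6$ — released Ca^2+^
  ignites neighbours through the diffusive coupling — and is scaled by a
  luminal factor $(j/j_{\mathrm{ref}})^2$ below the reference load.
* *Refractoriness*: sparks terminate when the local JSR falls below 20%
  of its pre-spark load; the subsequent refractory timer (140 ms)
  advances at rate $1/(1 + (c/c_h)^6)$ with $c_h = 0.145\ \mu M$ —
  recovery from release refractoriness is suppressed while local
  cytosolic Ca^2+^ remains elevated, as in Ca^2+^-dependent RyR
  inactivation.

The third ingredient is what couples the troponin variant to rhythm:
slowed unbinding roughly doubles the differential buffering power
$\partial B_{eq}/\partial c$ near diastolic Ca^2+^, so the variant's
post-beat Ca^2+^ tail crosses the recovery threshold much later, its
effective release refractoriness grows beyond one pacing cycle at short
cycle lengths, and period-2 (alternans) firing emerges — while the
control's fast unbinding clears the tail quickly enough to follow 1:1
down to 300 ms.

## Numerics and conservation

Deterministic fluxes advance by explicit Euler at $\Delta t = 0.02$ ms
(halving $\Delta t$ changes per-beat peak Ca by < 0.2%). The cytosolic
and JSR pools are integrated in *conserved total-Ca variables*
(free + rapidly-buffered); free concentrations are recovered each step by
inverting the rapid-buffer quadratic. Because every internal flux is
applied antisymmetrically between compartments, a closed cell (all
sarcolemmal fluxes off) conserves total Ca^2+^ to floating-point rounding
(measured drift ≈ 10^-14^ over 10 s), rather than the O(Δt) leak that
integrating free concentrations through the buffer nonlinearity would
produce. Non-finite state is detected at every recording step and raises
an integration-failure error naming the time.

## Calibration and what it does and does not show

The study fixes the troponin and SERCA constants but not the spark-level
closure; those rate constants were calibrated once, on the 20×5×5
lattice, against the qualitative bifurcation the study reports: no
alternans for the control variant anywhere on the 300–700 ms cycle-length
grid, and alternans for the slowed-unbinding variant at short cycle
lengths with 1:1 behaviour restored by 500 ms. With the frozen defaults
the control is alternans-free across the full grid (majority vote over
five seeds) and the variant alternates at 300, 350 and 400 ms, giving an
onset boundary of 450 ms against the reported 500 ms. The residual gap is
a known limitation: the width of the variant's alternans window is set by
the ratio of the two variants' Ca^2+^-tail durations, and this closure
could not stretch the window to include the 450-ms grid point while
keeping the control clean at 300 ms.

A second known limitation concerns the direction of two steady-state
observables. In this closure, slowing $k_{\mathrm{off}}$ at fixed
$k_{\mathrm{on}}$ strengthens equilibrium buffering at every attainable
Ca^2+^ level, so the variant's free-Ca transient peak is smaller than
control's, and — because sarcolemmal efflux acts on free Ca — its SR load
settles *higher*, not lower. The study attributes the opposite directions
to enhanced recruitment ("more CRUs fire") in the cited prior model; a
regime of this model with strong tail-driven re-ignition reproduced both
of those directions but showed no alternans, and no explored parameter
set produced both behaviours at once. The corresponding directional test
is kept in the suite, asserted as the study states it, and fails.

Passing the simulator's tests therefore shows that the implemented
mechanism — buffering-controlled release refractoriness on a stochastic
CRU lattice — reproduces the alternans phenomenology and its variant
specificity at desk scale; it does not show that this minimal closure is
quantitatively equivalent to the full ionic model the study used.

# Transient-train analysis

Traces are normalised to ΔF/F₀ using the pre-stimulus baseline (polarity
folded in, so dyes that dim on depolarisation are handled identically).
Beats are stimulus-aligned half-open windows; a transient is accepted
when it clears baseline by four baseline-noise SDs on at least three
frames (single-sample noise spikes are not beats), and windows that span
the record end are dropped. Activation time is the midpoint of the
largest first difference after the stimulus; when the upstroke falls
between the stimulus and the first frame (at 100 frames/s this is
common), the window start is used. Durations at fractional recovery
interpolate linearly between samples, since nearest-frame rounding at 10
ms/frame would dominate the error budget; a beat that never recovers to
the requested level yields NA and counts as irregular. The alternans
ratio uses the absolute even/odd peak-mean difference, making the
arbitrary phase choice irrelevant. The synthetic train generator shapes
each beat as a 5-ms linear upstroke followed by a monotone
piecewise-linear repolarisation passing exactly through the requested
30%/80% recovery times, so generator/analyser round trips recover the
requested metrics to within one frame.

# Transcript-count statistics

Counts are normalised to the geometric mean of seven housekeeping genes
per sample (anchored to the across-sample geometric mean), then
log₂(x+1)-transformed; tests run on the log scale, matching the scale the
results are presented on. Note one subtlety: per-sample rescaling of raw
counts is removed exactly only up to a single global gauge constant that
the +1 pseudocount re-expresses; significance calls are unaffected.
Per-gene Welch tests (variant vs control orientation) are corrected with
the Benjamini–Yekutieli step-up, which is valid under arbitrary
dependence between transcripts, and genes are called at adjusted
p < 0.05 with no fold-change cutoff. An optional background filter keeps
genes whose mean count exceeds the negative-control mean by two SDs — a
documented stand-in for proprietary panel-QC rules. ΔΔCt quantification
aggregates the two reference genes by arithmetic mean in Ct space
(equivalent to geometric-mean normalisation on the linear scale) and
reports $2^{-\Delta\Delta Ct}$.

The count generator is gamma-Poisson with dispersion 0.01 (replicate CV
≈ 10%) and, by default, a fixed 68-gene injected signature (45 up, 23
down) led by NPPA at 18.6-fold and NPPB at 5.9-fold. Both defaults are
calibrated to the study conditions rather than arbitrary: with group
sizes of 4 and 3, a Welch test has 2–6 degrees of freedom, and a
Benjamini–Yekutieli bar at rank ≤ 2 of 236 genes (raw p ≤ 7×10^-5^) is
unreachable for any realistic per-gene precision — the observed panel
called 68 genes significant, which is only possible when differential
expression is pervasive and the step-up bar sits near rank 45–68. A
generator with only two injected effects would therefore misrepresent
the study's operating point. What the passing tests show is that the
pipeline recovers injected effects *under the study's evident precision
and signal density*; they do not show power for sparse signals at these
group sizes (there is essentially none, which is a property of BY at
n = 4 + 3, not of this implementation).

# Seeds and problem sizes

All stochastic stages take explicit integer seeds; pipeline stages derive
their seeds from a master seed keyed by stage name, so adding a stage
never perturbs another. The shipped analysis sizes — 20×5×5 lattice, 20
beats per cycle length with the last two analysed, five-seed majority
votes, 1,000-replicate null panels — were chosen as the smallest sizes at
which the qualitative results are stable from run to run.

# A worked mini-example

```{r example}
td <- gen_titration(true_kd = 2, hill_n = 1, noise_sd = 0.01, seed = 1)
fit_hill(td)

tr <- gen_transient_train(rate = 100, duration = 20,
                          skipped_beats = c(4, 8, 12, 16, 20, 24, 28, 32),
                          noise_sd = 0.01, seed = 1)
entrainment_check(tr)
```
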