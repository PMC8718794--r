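# alternans

Tools for studying how slowed Ca²⁺ unbinding from cardiac troponin — the
biophysical effect of the hypertrophic-cardiomyopathy-linked troponin-T
I79N variant — promotes Ca²⁺ alternans, the beat-to-beat alternation of
the Ca²⁺ transient that precedes arrhythmia. The package is aimed at
cardiac electrophysiology and myofilament labs who want a tested,
reproducible version of the full analysis chain: in-vitro Ca²⁺-binding
kinetics, a stochastic release-unit simulator, optical-mapping transient
metrics, and targeted transcript-count statistics — each fed by seeded
synthetic-data generators, so nothing requires a download and every
stage is verifiable by parameter recovery.

## What is inside

**Troponin Ca²⁺ kinetics** (`fit_hill`, `fit_exp_decay`,
`compare_parameters`). Steady-state titrations are fitted per replicate
with the Hill equation

F(Ca) = F_min + (F_max − F_min) · Ca<sup>n</sup> / (K_d<sup>n</sup> + Ca<sup>n</sup>),

reporting K_d (the Ca²⁺ concentration at half-maximal fluorescence
change) ± SEM across replicates. Stopped-flow dissociation traces
(instrument dead time 1.1 ms) are fitted with F(t) = A·e^(−k·t) + C,
reporting k_off in s⁻¹. Constructs are compared with unpaired Student
t-tests.

**CRU-network simulator** (`make_default_params`, `run_paced`,
`scan_pcl`). A 3-D lattice of coupled Ca²⁺ release units (20×5×5 by
default; 100×20×10 = 20,000 supported) with explicit troponin buffering

J_trpn = k_on (B_t − [CaT]ᵢ) [Ca²⁺]ᵢ − k_off [CaT]ᵢ,

k_on = 0.0327 (μM·ms)⁻¹ and k_off = 0.5 ms⁻¹ (control) or 0.1 ms⁻¹
(slowed-unbinding variant), SERCA K_D = 0.25 μM, stochastic spark
ignition with steep Ca-dependent recruitment, JSR-depletion spark
termination, and Ca-gated recovery from release refractoriness. Pacing
protocols scan cycle lengths from 300 to 700 ms and flag alternans from
the last two per-beat Ca peaks (bifurcation diagram). The integrator
conserves closed-cell total Ca to floating-point rounding and is exactly
reproducible for a given seed.

**Transient-train analysis** (`analyze_trace`, `entrainment_check`,
`triangulation_index`, `pcl_to_bpm`). Dual-channel (voltage- and
Ca-sensitive) fluorescence traces at 100 frames/s are ΔF/F₀-normalised,
segmented into stimulus-aligned beats, and reduced to APD₃₀/APD₈₀,
CaTD₃₀/CaTD₈₀ (linear sub-frame interpolation), triangulation
[(APD₈₀ − APD₃₀)/APD₈₀], amplitude-alternans ratio, and an entrainment
classification counting irregular transients.

**Transcript-count statistics** (`normalize_counts`, `call_degs`,
`ddct_fold`). Counts are normalised to seven housekeeping genes, tested
per gene with Welch's t-test (variant vs control), corrected with the
Benjamini–Yekutieli FDR procedure (valid under arbitrary dependence),
and called at adjusted p < 0.05 with no fold-change cutoff. ΔΔCt
quantification with geometric-mean reference normalisation is included.

**Synthetic data** (`gen_titration`, `gen_stopped_flow`,
`gen_transient_train`, `gen_counts`) emulate each assay with known
ground truth; `run_pipeline` orchestrates all stages end-to-end with a
master seed and a checksum manifest.

## Worked example

```r
library(alternans)

# Hill fit of a synthetic titration (true Kd = 2 uM)
fit_hill(gen_titration(true_kd = 2, hill_n = 1, noise_sd = 0.01, seed = 1))
#> Hill fit [construct]: Kd = 1.975 +/- 0.037 uM (n = 6), n_H = 1.03

# stopped-flow dissociation rate (true koff = 120 s^-1, 9 shots)
fit_exp_decay(gen_stopped_flow(true_koff = 120, n_traces = 9,
                               noise_sd = 0.01, seed = 2),
              average_first = FALSE)
#> Exponential decay fit [construct]: koff = 120.1 +/- 0.24 s^-1 (n = 9 fits)

# a 100-bpm train with 8 skipped transients over 20 s
tr <- gen_transient_train(rate = 100, duration = 20,
                          skipped_beats = c(4, 8, 12, 16, 20, 24, 28, 32),
                          noise_sd = 0.01, seed = 1)
entrainment_check(tr)
#> Rhythm: 33 stimuli, 25 transients, 8 irregular; entrained: FALSE; ...

# differential expression on the default synthetic panel
deg <- call_degs(gen_counts(seed = 1))
head(deg[order(deg$p_adj), c("gene", "log2fc", "p_adj", "significant")], 3)
#>      gene   log2fc        p_adj significant
#> 9    NPPB 2.470647 0.0008328702        TRUE
#> 8    NPPA 4.284742 0.0021371679        TRUE
#> 15 COL1A1 2.515659 0.0021371679        TRUE
```

The fitted Kd and k_off agree with the generating truth to a few
percent; the rhythm report counts exactly the eight injected irregular
transients; and the injected 18.6-fold (NPPA, log₂FC ≈ 4.2) and 5.9-fold
(NPPB, log₂FC ≈ 2.5) markers are recovered as significantly upregulated.

The two-variant bifurcation scan (this is the expensive step, a few
minutes per variant):

```r
bif <- scan_pcl(make_default_params("reduced_koff"), seq(300, 700, 50),
                seeds = 1:5)
bif$table   # alternans flags per pacing cycle length
```

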