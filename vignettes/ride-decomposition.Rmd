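---
title: "Separating latency-variable ERP components: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating latency-variable ERP components: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Event-related potentials are conventionally estimated by averaging EEG
epochs time-locked to a stimulus. Averaging assumes that every neural
component occurs at a fixed delay after the locking event. For late,
decision-related components — the parietal P3 in particular — that
assumption is false: the component's single-trial latency varies by
hundreds of milliseconds and co-varies with the reaction time. Averaging
then smears the component, attenuating its apparent amplitude, and a
fixed measurement window samples an essentially arbitrary part of the
smear. Two groups of subjects that differ in the amplitude *and* typical
latency of such a component can look identical in the conventional
average while differing strongly once single-trial latency variability is
accounted for. `jride` implements both sides of this story: a generative
simulator in which the masking arises by construction, and a
residue-iteration decomposition that undoes it.

## The decomposition model

Each retained single trial $d_i(c, t)$ (channel $c$, time $t$) is modeled
as the superposition of three component clusters that differ only in what
they are time-locked to:

$$d_i(c,t) = S(c, t) + C(c, t - \ell_i) + R(c, t - r_i) + \varepsilon_i(c,t)$$

* the **S cluster** is locked to the stimulus (latency fixed at 0),
* the **R cluster** is locked to the response (latency $r_i$ = the trial's
  reaction time, an observed marker),
* the **C cluster** sits in between at a latent per-trial latency
  $\ell_i$ that must be estimated.

Each cluster is confined to a time-window function: $-200..600$ ms around
the target for S, $200..900$ ms for C, and $\pm 300$ ms around the
response for R, with a cosine (Tukey) taper of fraction 0.1 so that
subtracting shifted components cannot introduce edge discontinuities.

Estimation alternates conditional steps. Given two clusters, the third is
the *median* waveform of the residual after aligning every trial to that
cluster's latency — the median (rather than the mean) makes the estimate
robust to outlier trials and is the defining choice of residue iteration.
Given the waveforms, each trial's $\ell_i$ is re-estimated as the lag
maximizing the channel-summed cross-correlation between the trial
residual (S and R removed) and the current C template, searched within
$\pm 300$ ms of the current estimate, after smoothing the lag curve with
a 20 ms moving average. Iteration stops when the maximum absolute change
of the concatenated waveforms, normalized by their RMS, falls below
`tol = 1e-3`, or at `max_iter`.

Three choices deserve comment:

* **Initialization.** $\ell_i$ starts at the trial's
  reaction-time-proportional lag (window center plus the trial's RT
  deviation). The C template is initialized from the average aligned to
  these latencies, and one cross-correlation pass — computed on
  mean-removed data so that stimulus-locked activity cannot attract the
  alignment — refines the latencies *before* the first S extraction.
  Without this, the S-cluster median absorbs part of the smeared C
  component and the iteration converges to a poor split.
* **Latency prior.** The per-trial lag search is a
  maximum-a-posteriori variant: the SD-standardized correlation curve is
  penalized by `latency_prior_weight` (default 4) times the squared
  deviation from the RT-proportional prediction. When the trial contains
  a clear component the correlation peak dominates; when it contains
  essentially none (small-amplitude subjects exist by design, see below)
  the estimate degrades gracefully toward the behaviorally informed
  prediction instead of a noise-driven argmax. Setting the weight to 0
  recovers the plain Woody-style estimator, which
  `estimate_c_latency()` also exposes directly.
* **Anchoring.** The model is invariant under shifting all $\ell_i$ by a
  constant while shifting $C$ the opposite way. The package anchors the C
  waveform at the grid-aligned median of the latency estimates after the
  initial cross-correlation pass and freezes that reference, so the
  waveform sits on the epoch axis where the trials actually place it,
  group-level measurement windows remain meaningful, and single-sample
  jumps of the median cannot translate the waveform between iterations.

With all latencies constant (the zero-jitter degenerate case) the split
of overlapping windows is not identifiable; the initialization above
deliberately assigns the overlap to the C cluster, so that the C waveform
reproduces the conventional average inside its window — the behavior the
degenerate-case checks assert.

## The generative model

`simulate_epochs()` builds each trial as a sum of smooth unimodal kernels
(half-sine times a Gaussian taper; peak latency, half-width, amplitude)
with fixed per-channel topographies on an idealized unit-sphere montage
of 9 electrodes (Fz, FCz, Cz, C3, C4, Pz, P9, P10, Oz — every electrode
the analysis quantifies):

* flanker- and target-locked visual components at P9/P10 (P1/N1 pairs,
  small 5–6 ms jitter),
* a fronto-central conflict N2 (more negative on incompatible trials),
* an early stimulus-locked parietal positivity at ~310 ms — the classic
  P3 that the fixed 300–320 ms window quantifies — identical across
  groups and with large (CV = 0.5) inter-individual amplitude
  variability,
* the latency-variable central component (P3-like, parietal), whose
  per-subject amplitude, latency and jitter come from the cohort preset,
* a response-locked motor component at C3/C4.

The central component's trial latency is the subject's latency plus an
RT-coupled term (slope 0.6 on the trial's within-condition RT deviation)
plus *right-skewed* jitter: a median-zero shifted lognormal
(log-SD 0.75). Decision endpoints straggle late but cannot precede the
evidence; the skew also means the smear leaks almost nothing into early
fixed windows, which is the masking mechanism in its sharpest form.

Behavior is a shifted lognormal per condition (shift 150 ms), with the
lognormal moments set from the subject's condition mean and the preset's
within-subject SD; correctness is Bernoulli with per-subject accuracy.
Responses slower than the 450 ms deadline stay valid (the task only
signals them), which is how below-chance incompatible accuracy and RT
SDs above 100 ms coexist.

Background noise is a sum of 8 spatially smooth sources
(spherical-Gaussian topographies at random orientations) carrying mixed
1/f-plus-white traces (3:1 power), plus a 5% independent sensor floor,
with total per-channel RMS 8 uV. The spatial smoothness is not cosmetic:
a surface Laplacian amplifies channel-independent noise several-fold
while leaving volume-conducted activity comparatively intact, so
channel-independent noise would make the post-CSD single-trial SNR
unrealistically poor.

What the simulator does *not* contain: ocular or muscle artifacts, a
volume-conduction forward model, overlapping activity from adjacent
trials, non-stationary noise, or latency variability in the visual
components beyond a few milliseconds. Passing tests therefore demonstrate
the pipeline's behavior under the stated model, not robustness to every
property of recorded EEG.

## Cohort presets and calibration

The built-in presets describe two clinical cohorts matched on behavior
(RT 339/402 ms, accuracy 66.2/39.7%, within-subject RT SD 124/134 ms)
that differ only in the central component: per-condition amplitude means
of 12.2/42.0 (inattentive cohort, n = 25) versus 40.7/54.3 (combined
cohort, n = 34) on the post-CSD scale, and latency means of 530 versus
600 ms. Between-subject SDs are reconstructed from the reported standard
errors (SD = SE * sqrt(n)); cross-condition amplitude correlations (0.50
and 0.78) follow from the standard errors of the conflict-effect
contrasts. A consequence worth stating: the inattentive cohort's
compatible cell (12.2 +/- 35.5) necessarily contains subjects with
near-zero or negative component amplitude, for whom single-trial latency
estimation is information-theoretically hopeless — the MAP prior exists
for exactly these subjects.

Two quantities are calibrated end to end, once, and fixed:

* `c_pipeline_gain()` (2.92) converts a
  preset's post-CSD amplitude target into the scalp microvolts the
  simulator emits, absorbing the combined attenuation of filtering, the
  Laplacian's scale, window means, and residual latency-estimation error.
  It was measured by regressing recovered on generative amplitudes over
  calibration cohorts of 25–50 subjects per group until the per-cell
  recovery ratios were within a few percent of 1.
* the generative within-subject RT SDs (126/146 ms) are set so that the
  *observed* per-subject sample SDs — computed on ~106 and ~32 correct
  trials of a right-skewed distribution, and therefore biased low — land
  on the target 124/134 ms.

## Quantification and statistics

Components are measured as arithmetic means over half-open [lo, hi)
electrode/time windows: the visual components at P9/P10, the N2 at
FCz/Cz (conventional) or FCz/Fz (C cluster), the conventional P3 at Pz
in 300–320 ms, the C-cluster P3 at Pz in group-specific windows
(520–540 / 590–610 ms, matching the cohorts' latency means; re-centered
on the observed peak for non-built-in cohorts), and the motor cluster at
C3/C4 in the subject's mean RT +/- 10 ms. Electrode choices can be
validated by testing each electrode's window mean against the mean of
all others across subjects at the Bonferroni-style threshold p < 0.0007
with polarity matching.

The mixed-design ANOVA is computed from sums of squares over orthonormal
within-cell contrast scores (the split-plot partition), with unweighted
marginal means for within effects under unequal group sizes
(Type-III-style), Box/Greenhouse–Geisser epsilon from the pooled
contrast-score covariance (identically 1 for 2-level factors, so the
correction is formally applied but inert in this design), and partial
eta squared as SS_effect/(SS_effect + SS_error). `car::Anova` serves as
an independent cross-check in the test suite, never as the
implementation. Post-hoc tests are pooled-variance or paired t with
Bonferroni multiplication capped at 1; normality checks are
Lilliefors-style Kolmogorov–Smirnov with the Dallal–Wilkinson p
approximation and z = D * sqrt(n).

## The masking experiment

`run_masking_experiment()` replicates the two-cohort design end to end
and records, per replicate, the group-effect p value of (i) the
conventional fixed-window P3 and (ii) the C-cluster P3, plus the
C-cluster group-by-compatibility interaction. Because the groups differ
in a component whose latency is both late and variable, the conventional
window contains an (essentially group-blind) stimulus-locked positivity
plus the faint front edge of the smear, while realignment restores the
full group contrast: the C-cluster path detects the group effect in a
several-fold larger fraction of replicates, and under a true null
(relabeled identical cohorts) both paths sit at the nominal 5%.

Replicated experiments run at a reduced, documented scale — 12 subjects
per cohort, 2 blocks of 60 trials, 128 Hz, -400..1400 ms epochs, 4
decomposition iterations, and epochs simulated for correct trials only
(the only trials any downstream stage consumes; correctness is
independent of the EEG in the generative model). Single-cohort analyses
default to the full study scale (25/34 subjects, 2 x 120 trials, 256 Hz,
-2000..2000 ms epochs, 12 decomposition iterations). The decomposition's own default
iteration cap remains 100 at tolerance 1e-3; the pipeline caps are a
runtime choice, made after observing that waveform changes plateau near
(but above) the tolerance under realistic noise without further quality
gains, driven by the sample-to-sample jitter of re-estimated latencies.

## Numerical notes and limitations

* Filtering is an order-4 Butterworth band-pass applied forward-backward
  (zero phase, magnitude squared, ~48 dB/octave per edge), with the DC
  offset removed first; edge transients of the 0.5 Hz corner are handled
  by the zero-padded two-pass scheme. A compact positive component
  passed through this filter acquires shallow negative side lobes — a
  real pipeline property that the simulator's early-window measures
  inherit.
* The surface Laplacian is a Perrin-style spherical spline (stiffness
  m = 4, 50 Legendre terms, regularization 1e-5) on the unit sphere;
  outputs are proportional to uV/m^2 and all amplitude targets live on
  this post-CSD scale.
* Sub-sample shifts use linear interpolation; latencies are reported on
  the sample grid. Cross-correlation ties break toward the smallest
  absolute lag.
* The flat-line artifact criterion is a peak-to-peak range below 0.5 uV
  in any sliding 200 ms window on any channel; the amplitude criterion
  is +/-100 uV anywhere. Whether the low-activity rule should apply
  per channel or on any channel is ambiguous in the field; any-channel
  is implemented.
* The decomposition never sees the simulator's ground-truth latency
  table; it is carried separately and consumed only by tests.
* With two overlapping window functions and zero latency variability the
  component split is non-identifiable; the package's initialization
  resolves it in favor of the C cluster by construction, and the
  degenerate case converges slowly (geometric rate set by the taper) —
  hence `max_iter = 100` defaults and a `converged` flag rather than an
  error.
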