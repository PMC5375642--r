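---
title: "Quantifying multisensory integration and inverse effectiveness in the tadpole tectum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multisensory integration and inverse effectiveness in the tadpole tectum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tectomsi)
```

## The measurement problem

Multisensory integration (MSI) is the combining of input from distinct
senses into a unified response, and *inverse effectiveness* is its
signature regularity: enhancement is largest where the unisensory responses
are smallest. In the *Xenopus* tadpole optic tectum this can be measured at
three levels with one common index,

$$\mathrm{MSIn} = \frac{\text{multisensory} - \text{unisensory}}{\text{unisensory}},$$

applied to swim-speed changes (behavior), per-cell calcium-transient peaks
(network imaging), and synaptic response areas or spike counts (single-cell
electrophysiology). `tectomsi` implements the full measurement chain for
all three levels plus a synthetic-data generator that produces each data
modality with known ground truth, so every stage of the chain is testable
end to end without any recordings.

## The imaging chain

A recording is a stack of fluorescence frames covering repeated 7 s trials
(5 s prestimulus, 22.8 frames/s; four interleaved conditions: visual,
mechanosensory, multisensory, blank) with 30 s start-to-start spacing.
The stages, in fixed order:

1. **Registration** (`register`). Each frame is translated by the integer
   XY shift maximizing its circular cross-correlation with a template
   average, searched within a configurable bound (default ±5 px). Frames
   whose normalized correlation stays below a floor (default 0.2) are left
   in place and flagged. Shifts are integer only; subpixel refinement is
   out of scope. Note that registration is only defined relative to the
   template: a template averaged over frames that are themselves displaced
   recovers shifts relative to that average, so templates should be taken
   from a stable epoch.
2. **Trace extraction** (`extract_traces`). Arithmetic mean over the ROI
   mask pixels per frame, and likewise over each ROI's neuropil annulus
   (which excludes all ROI pixels).
3. **Bleach flattening, then neuropil subtraction** (`correct_trace`) —
   exactly this order. A slowly varying baseline is estimated per trace by
   fitting $A e^{-t/\tau} + C$ to a rolling 20th-percentile envelope and
   then refitting to the samples the provisional baseline identifies as
   non-transient, which removes the envelope's quantile and edge bias;
   when the fits fail the envelope itself is used. The trace is divided by
   this baseline and rescaled to the initial baseline level, so an
   unbleached trace passes through unchanged. The baseline fit runs in
   wall-clock time, not frame index, because only trial epochs are
   recorded while bleaching continues between them. Then
   `corrected = raw_flat - r * np_flat + mean(r * np_flat)`, keeping the
   corrected trace positive in expectation. The mixing coefficient `r`
   defaults to 0.7, the conventional value for bulk-loaded tissue; the
   underlying study cites a subtraction method but no coefficient, so the
   parameter is exposed.
4. **ΔF/F₀** (`compute_dff`). F₀ is the mean over the trial's prestimulus
   window; ΔF/F₀ is invariant to rescaling the trace by any positive
   factor. A non-positive F₀ is an error, not a silent NaN.
5. **Peak** (`peak_response`). The mean of the three samples around the
   absolute maximum of the post-stimulus portion of the trial; at a window
   edge the two available samples are averaged. The search is restricted
   to the post-stimulus portion — the source protocol does not state this
   restriction explicitly, but a prestimulus "peak" would be noise by
   construction.
6. **Cell summary** (`summarize_cell`). Trial peaks are averaged per
   condition. A cell is *included* when any of the three stimulus
   conditions reaches a mean peak of 0.1; the primary modality is the
   argmax (exact ties resolve toward the larger unisensory response, then
   visual). The inclusion threshold is applied on the ΔF/F₀ scale — the
   protocol text is ambiguous between ΔF and ΔF/F₀, the Methods wording
   supports ΔF/F₀, and the threshold is a parameter in any case.
7. **Inverse-effectiveness fit** (`fit_ie_curve`). MSIn against the
   largest unisensory mean peak, fitted as $y = a e^{bx}$ by nonlinear
   least squares; $b < 0$ is the quantitative signature of inverse
   effectiveness. The published figure annotates its fit as `a^(b*x)`,
   which is numerically implausible for the printed coefficients
   (a ≈ 27, b ≈ −41 would be ≈ 0 everywhere); the exponential-decay form
   is the one consistent with a least-squares decay fit, and the fitted
   object records the form used.

**MSIn denominator.** The index formula names "unisensory" without saying
which one when two are measured. Because the inverse-effectiveness plot
uses the *largest* single-modality response on its x-axis, the default
denominator is the larger of the two unisensory mean peaks, consistently
in imaging and electrophysiology; `denominator = "min"` and `"sum"` are
available for sensitivity analyses.

## The behavioral batteries

**Swim speed.** Per trial, the response is either the mean stimulus-window
speed in cm/s (default, the scale the group comparisons are reported on)
or the absolute percent change from the 1 s pre-trial window; the mode is
a required, recorded parameter since the two scales are not
interchangeable. Animals that show no movement across a contiguous
≥ 3 minute span of stimuli are excluded (movement floor 0.1 cm/s,
configurable; the floor itself is not specified by the protocol).
Per-animal MSIn is computed per contrast from condition means, then the
battery runs:

- visual vs multisensory at each contrast, Sidak-adjusted over the four
  contrasts. The default error formulation is *paired*: the per-animal
  condition difference at each contrast, with the difference variance
  pooled across contrasts, giving $nK - K$ error degrees of freedom
  (144 at n = 37, K = 4 — matching the degrees of freedom reported for
  this design, which a between-cells formulation cannot produce);
  `method = "pooled"` gives the between-cells alternative.
- one-way ANOVA of MSIn across contrasts with Dunnett comparisons against
  the 0% reference, in the textbook between-subjects formulation
  (`multcomp`).

**Startle rate.** Sessions deliver cyclic stimulus sequences (no
randomization, as in the source protocol; no order-effect correction is
applied because none was); outcomes are binary startles. Response rate is
responses/presentations per stimulus type; MSI is the rate-based MSIn at
each contrast. Animals with zero responses across all their 25–30 stimuli
are excluded. A zero visual rate with multisensory responses leaves MSI
undefined and flagged — the protocol does not say how to handle it and
imputation would manufacture data. The group analysis is a one-way ANCOVA
of MSI (groups control-low, control-high, MK801-low) with each animal's
acoustic response rate as covariate (Type II partial F tests), Tukey HSD
on the covariate-adjusted means, and one-sample t-tests of each group
against zero. The published report of this experiment gives the
low-contrast MSI as 0.12 ± 0.13 in one place and 94 ± 109% in another
without stating the normalization that relates them; the package computes
the rate-scale index and reports it both raw and ×100, reconciling
nothing silently.

## The single-cell chain

Responses are quantified as the trapezoidal area between trace and
pre-stimulus baseline (mean of the 100 ms before onset, configurable) over
the 1.5 s following the first stimulus onset for whole-cell recordings, or
as threshold-crossing spike counts within 1.2 s for loose-patch
recordings (upward crossings, 2 ms refractory default — the manual
procedure being emulated had none). Trials are *subthreshold* when both
unisensory areas are below 12 area units and *suprathreshold* when either
reaches the bound; exactly 12 classifies as suprathreshold (the source
wording covers "less than" and "greater than" but not equality, so the
boundary needed a documented rule). The bound's published unit ("pA/ms"
for an area over time) is dimensionally opaque; areas are treated as
amplitude × time in whatever units the traces carry, and the bound applies
on that scale. The linearity analysis compares the arithmetic sum V + H
against the measured crossmodal response VH: `ratio = VH / (V + H)`, with
ratio > 1 supralinear. Group MSIn contrasts use the exact Mann-Whitney
test.

## Shared statistics

- `mann_whitney_u` counts pairs with $x_i < y_j$ (½ per tie) and reports
  $\min(U, n_1 n_2 - U)$, so complete separation gives U = 0. For
  tie-free samples with $\min(n_1, n_2) \le 20$ the two-sided p-value is
  exact: twice the smaller tail of the full null distribution of U
  (computed by dynamic programming over rank placements), capped at 1 — a
  documented convention; with ties the tie-corrected normal approximation
  with continuity correction is used and the method switch is reported.
- `fit_exp_decay` fits $y = a e^{bx}$ with `minpack.lm`, initialized from
  a log-linear regression on the positive-y subset with bounded restarts;
  adjusted $R^2 = 1 - (1 - R^2)(n-1)/(n-3)$; 95% Wald intervals from the
  parameter covariance with $n - 2$ degrees of freedom. Simulated
  calibration at n = 100, σ = 0.01 puts per-parameter coverage near 94%.
- Sidak adjustment is exactly $1 - (1-p)^m$; Dunnett and Tukey come from
  `multcomp`/`emmeans`; the ANCOVA is an `lm` with Type II tests (`car`).

## The synthetic-data generator

The generator exists so that every pipeline stage has a ground truth. Its
defaults are the acquisition constants of the protocols being emulated:
22.8 frames/s, 7 s trials, 5 s prestimulus, 30 s start-to-start, blocks of
3 repetitions × 4 conditions (imaging); 37 animals × 40 presentations,
20 s ISI, contrasts 0/25/50/100%, visual-condition speeds
3.22/3.29/3.7/4.76 cm/s with multisensory enhancement 1.9 and 0.2 cm/s at
the low contrasts (behavior); group sizes 15/23/15 with 25- or 30-stimulus
cyclic sessions (startle); 50 ms crossmodal offset (electrophysiology).

Quantities the protocols do not state were chosen once as plausible for
this preparation and are parameters, not constants: calcium-transient
kernel rise/decay 0.1/1.5 s (indicator kinetics are not described);
additive Gaussian pixel noise SD 2 on a baseline of 100 (Poisson behind a
flag); bleach time constant 600 s; static spatial texture with 15%
relative SD (bulk-loaded tissue is heterogeneous — this is also what
registration correlates on); neuropil contamination fraction 0.7 with a
shared neuropil transient of peak ΔF/F 0.05; swim-trial speed SD
1.2 cm/s with a 0.6 cm/s per-animal offset; logistic startle model with a
per-animal latent acoustic responsiveness (slope 0.8), which is what makes
the ANCOVA covariate meaningful.

**The crossmodal rule is a stand-in, not a mechanism.** The multisensory
amplitude is `v + h + g * min(v, h)` when both unisensory amplitudes lie
below a threshold, and exactly `v + h` otherwise (or whenever `g = 0` or
the blockade flag is set). This reproduces the *phenomenon* — NMDAR-like
supralinear summation confined to small coincident inputs, hence inverse
effectiveness by construction — without claiming any biophysical form,
since the source work proposes none. The hard threshold makes the rule
discontinuous: as an input crosses the gate the bonus vanishes, so the
rule is monotone non-decreasing within each gate regime but steps down at
the boundary. That is intentional (the gate is the point), and the form
used is recorded in the configuration output.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: indicator saturation and nonlinearity,
dye loading gradients, subpixel and z-axis motion, spatially varying
neuropil contamination, correlated (shared-trial) noise across cells,
swimming kinematics beyond trial-mean speeds, and any real synaptic
dynamics beyond a fixed kernel. Results on synthetic data validate the
*arithmetic and inference chain*, not the biology.

## Numerical choices and degenerate inputs

- Baseline fits use the Levenberg–Marquardt optimizer on raw residuals
  (`nls.lm`), which tolerates the exactly-zero-residual case that breaks
  `nls`-object construction on noiseless input.
- `fit_exp_decay` on constant data returns b = 0, a = mean(y); adjusted
  R² is defined as 1 when residuals vanish.
- Empty ROI masks, non-positive F₀, r outside [0, 1], windows outside the
  trace, empty design cells, and groups under three animals are all
  errors with named diagnostics, never silent NA propagation.
- Exclusion operations are pure filters: retained records are bit-for-bit
  unaltered.
- All generators are deterministic given seed and configuration.

## Scales used by the test suite

The packaged tests exercise the full chain at reduced scale, chosen so the
suite runs on a single CPU at desk pace while keeping every statistical
check meaningful: simulated movies of 80 × 80 px with 15–25 cells and 2
trial blocks (the population-level checks aggregate 20 seeded runs);
behavioral simulations at the design size of 37 animals; 500 null
replicates for the ANCOVA size check; 1,000 random instances per oracle
comparison. The acceptance script (`scripts/acceptance.R`) re-runs the
same chain from scratch at these scales and writes its headline numbers as
JSON.

## Known limitations

Integer-pixel registration only; no automated segmentation (ROIs are
inputs); no spike inference from calcium; the behavioral module consumes
scored trial tables, not video; recording-quality exclusions
(holding-current, seal-resistance criteria) are acquisition-time concerns
consumed, if at all, as pre-filtered metadata. The two-way battery's
paired formulation assumes homogeneous difference variance across
contrasts; the Dunnett step is between-subjects even though the design is
repeated-measures, which is conservative in the usual positive-correlation
case.
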