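---
title: "Voltage-clamp fluorometry analysis: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voltage-clamp fluorometry analysis: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorovolt)
```

## The measurement and the signal model

Voltage-clamp fluorometry (VCF) records two things at once from a clamped
cell: the membrane current through a channel population and the emission of a
fluorophore attached at a specific residue. When the fluorophore is
*electrochromic* — its emission responds directly to the local electric
field — a voltage step produces an essentially instantaneous fluorescence
deflection that is linear in the voltage excursion. When the labelled residue
additionally senses a conformational rearrangement coupled to gating, a
second, slower component appears that tracks the open probability. The
analysis problem is to separate these two components, quantify each as a
fractional fluorescence change (ΔF/F, in percent of the baseline), and relate
the slow component to the conductance–voltage (G–V) relationship obtained
from tail currents.

`fluorovolt` implements that analysis chain and, because per-cell raw sweeps
of this kind are rarely deposited, pairs it with a generative simulator so
that every stage can be validated against known ground truth.

### The generative model

One sweep concatenates episodes, one per test potential. Each episode is
`pre` (holding) → `step` → `tail` (fixed tail potential, for G–V work) →
`post` (holding). Within an episode the open probability relaxes
mono-exponentially towards its voltage- and agonist-dependent steady state

$$P_\infty(V, A) = h(A)\left[P_{min} + \frac{P_{max}-P_{min}}
  {1 + e^{zF(V - V_{1/2}(A))/RT}}\right],$$

with Hill occupancy $h(A) = A^n/(EC_{50}^n + A^n)$ and a log-linear agonist
shift $V_{1/2}(A) = V_{1/2,ref} + s\,\log_{10}(A/A_{ref})$. The relaxation
time constant is

$$\tau(V, A) = \tau_{ref}\; e^{(V - V_{1/2}(A))/s_\tau}\;
  (A_{ref}/A)^{q},$$

so kinetics slow down at lower agonist when $q > 0$. The agonist model is a
phenomenological closure: the literature for this receptor establishes the
direction of the concentration dependence (voltage-dependent activation is
facilitated, and its kinetics accelerated, at higher agonist) without
publishing a fitted surface, so the defaults (EC$_{50}$ = 30 µM, $n$ = 1.5,
shift = −30 mV/decade, $q$ = 0.5, reference 300 µM) reproduce the reported
phenomenology without claiming mechanism.

The recorded fluorescence of sample $k$ (0-based) is

$$F_k = F_0\,(1 - R_b k)\left[1 + \frac{s_{ec}}{100}(V_k - V_{hold})
 + \frac{c_{slow}}{100}(Po_k - Po_{hold})\right] + \varepsilon_k,$$

a linear photobleaching envelope multiplying the electrochromic and
gating-coupled terms, plus iid Gaussian noise
($\sigma = \texttt{noise\_sd\_pct}\cdot F_0/100$). Linear (not exponential)
bleaching is deliberate: it is the model the standard compensation arithmetic
assumes, and over the few-percent bleach of a single recording the two are
indistinguishable. Current is ohmic through the open population,
$I = N\gamma\,Po\,(V - E_{rev})$, with $E_{rev} = 0$ mV for a non-selective
cation conductance in a sodium bath.

Two conventions are worth stating explicitly:

* **Episode independence.** Open probability resets to its holding-state
  value at each episode onset: the un-sampled rest between episodes is taken
  to be much longer than any gating τ, and the excitation shutter is treated
  as closed between episodes, so the bleach index advances only with recorded
  samples. This mirrors common practice (seconds between episodes, shuttered
  illumination) and keeps each episode's baseline at the rested state.
* **Signs.** `s_ec > 0` makes fluorescence fall on hyperpolarisation
  (the downward fast deflection); ΔF/F values are reported signed, and
  summaries that quote magnitudes say so.

## Analysis stages

### Photobleaching estimation and compensation

The bleach rate $R$ is the negated least-squares slope of fluorescence
against sample index, expressed as a fraction of the fitted intercept per
sample. The fit windows default to the *pre-step holding segments only*:
these are at the rested state by construction, whereas post-step holding
segments can still carry un-relaxed gating-coupled fluorescence that would
bias the slope. Because a pre segment opens every episode, the windows span
the whole sweep and the slope stays well conditioned.

Three compensation modes are provided:

* `additive` — adds back $R_{abs} k$; exact for a gap-free trace whose
  underlying signal is constant (the agonist-application use case).
* `first_order` — multiplies by $(1 - s k)$ with $s$ the *signed*
  fractional slope, i.e. $(1 + R k)$ for a decaying trace. A literal reading
  of the multiplicative compensation formula with a positive rate would
  deepen the decay rather than undo it, so the signed-slope interpretation
  is used and tested; the residual of this first-order inverse is bounded by
  $(R k_{max})^2$ relative.
* `exact_division` — divides by $(1 - R k)$, the exact inverse of the linear
  model; it errors if the envelope reaches zero.

Step-protocol analyses default to `first_order` (with
`exact_division` one argument away); gap-free agonist recordings are the
additive mode's domain.

### Normalisation and decomposition

Each episode's compensated trace is divided by the mean over its own pre
segment, so the baseline is 1 and ΔF/F is read directly. The fast component
is the mean ΔF/F over the **first 5 ms** of the step (referenced to the
command transition; the simulator has no capacitance artefact, and a
configurable window accommodates real data that needs blanking). The steady
component is the mean over the **last 50 ms** (100 ms for agonist-free
recordings, where the longer window is the convention). The slow component
is their difference — the decomposition identity
$\Delta F_{steady} = \Delta F_{fast} + \Delta F_{slow}$ holds exactly by
construction, so `dF_slow_pct` is always composed, never configured.

Window arithmetic is half-open, $[t_0, t_1)$: at 20 kHz the 5 ms window is
exactly 100 samples starting at the transition sample.

### F–V curves and linearity

F–V curves are plotted against the excursion from holding
($\Delta V = V_{step} - V_{hold}$), with optional normalisation to the most
hyperpolarised point (the convention for slow-component curves). Linearity
classification combines two criteria: $R^2 \ge 0.98$ (just below the 0.99 of
published electrochromic fits) *and* no same-sign residual run reaching
$\lceil n/2 \rceil$ points. The run criterion exists because a small slow
component riding on a dominant linear term can leave $R^2$ near 1 while the
residuals bulge systematically; for an 11-point curve the structural middle
run of a line-plus-sigmoid is exactly 6 = ⌈11/2⌉, which is why a run
*reaching* the threshold counts as curvature. Residuals below $10^{-3}$ of
the curve's standard deviation carry no sign — on noiseless synthetic data
the second-order residue of the first-order bleach compensation (~$10^{-5}$
of the span) is perfectly systematic and would otherwise drive the run count.

### Tail currents, G–V and the Boltzmann fit

Tail amplitudes are short-window means (1 ms settle, 3 ms window by default;
the source analyses do not state a window, and an exponential extrapolation
mode was judged unnecessary for leak-free simulated data). Amplitudes are
normalised by the largest-magnitude amplitude — or by an externally supplied
reference, so several agonist concentrations can share the highest-agonist
maximum. The two-state Boltzmann

$$I(V) = I_{min} + \frac{I_{max} - I_{min}}{1 + e^{ZF(V - V_{1/2})/RT}}$$

is fitted by Levenberg–Marquardt with a deterministic initialisation
(limits from the data extrema, $V_{1/2}$ from the half-range crossing, $Z$
from the local slope there). Since $(I_{min}, I_{max}, Z)$ and
$(I_{max}, I_{min}, -Z)$ describe the same curve, results are canonicalised
to $I_{max} \ge I_{min}$; standard errors come from the Gauss–Newton
covariance with the residual variance. $F = 96485$ C·mol⁻¹,
$R = 8.314$ J·mol⁻¹·K⁻¹ and $T = 297.15$ K (room temperature) throughout.
A fitted $V_{1/2}$ outside the data span is a warning, not an error.

The slow-F–V/G–V correspondence is scored as the RMS pointwise difference of
the two normalised curves on the intersection of their voltage ranges
(linear interpolation on the union grid), both on the absolute step-voltage
axis.

### Kinetics and statistics

Mono-exponential fits use a log-linearised initialisation refined by
Levenberg–Marquardt; a flat segment is a degenerate-input error, while
non-convergence returns `converged = FALSE` with diagnostics rather than
failing silently — on real recordings the slow component is often too small
to fit except at the most extreme potential, and the flag is how that is
surfaced. The slow-component fit window starts after the fast window (5 ms)
to exclude the instantaneous component. Group comparisons are the field's
standard set: paired and two-sample *t* tests (equal variances, matching the
conventional unpaired test) and one-way ANOVA with Tukey's HSD; p-values are
descriptive, with no correction beyond Tukey.

## Preset design

The registry encodes recording conditions whose generative values are
published numbers; everything downstream must *recover* them.

| Preset | Key values | Provenance of the numbers |
|---|---|---|
| `P2X2_A337_EC_FIT` | hold +20, steps +40…−140; $s_{ec}$ = 0.011 %/mV; fast-only | printed F–V fit slope |
| `P2X2_I341_EC_FIT` | hold −40, steps +40…−160; $s_{ec}$ = 0.007 %/mV; fast-only | printed F–V fit slope |
| `K308R_A337_300ATP` | $s_{ec}$ = 3.9/180 %/mV; slow = 0.5 % at −160 mV | printed fast magnitude; slow from the decomposition identity |
| `K308R_A337_0ATP` | $s_{ec}$ = 4.4/180 %/mV; occupancy 0 | printed magnitude; agonist-free |
| `K308R_A337_300ATP_FIG6` | $s_{ec}$ = 1.7/180 %/mV; slow = 0.25 % | printed pair from the same-cell comparison |
| `CiVSP_F401` | hold −60, steps −80…+160; slow-only, 10.6 % at +160 mV (500 nm) | printed voltage-sensor control |

Design decisions a reader should know about:

* **Slow gain is solved, not stored.** `c_slow` is computed from the
  preset's own gating as `target_slow / (P∞(extreme) − P∞(hold))`, so the
  steady value emerges from fast + slow.
* **Gating surface.** $V_{1/2}$(300 µM) = −100 mV and $z$ = 1 are
  unpublished for the hyperpolarised branch and were chosen once, by
  closed-form analysis, together with the τ parameters: with
  τ(−160 mV, 300 µM) ≈ 151 ms and an 800 ms step, the slow contamination of
  the 5 ms fast window is bounded by $w/2\tau \approx 1.7\%$ of the slow
  amplitude and the last-50 ms equilibration shortfall by ~0.6 %, keeping
  fast/steady recovery within a 0.5 % relative band while the slow component
  still saturates. The τ voltage dependence is deliberately mild
  (e-fold per 400 mV): a steep dependence would leave the slow component
  un-equilibrated at intermediate voltages, contradicting the preset's
  design premise that the steady window reads the steady state at every
  activating potential.
* **Step durations** are not published; figures show sub-second steps, so
  the default is 500 ms (800 ms for the mixed-component presets, where the
  window analysis above wants τ ≪ step). Sampling is 20 kHz for the step
  protocols and 10 kHz for the voltage-sensor control, as stated for the
  respective recordings; repeats are 20 (agonist), 5 (agonist-free) and 3
  (sensor control).
* **Bleach and noise.** Each preset bleaches 1 % of $F_0$ over one sweep
  (a realistic per-recording loss that keeps the first-order compensation
  residual, $(R k_{max})^2 = 10^{-4}$, negligible relative to the signals)
  and carries 0.4 % Gaussian noise, the level at which 20-sweep averaging
  yields the signal-to-noise of the published traces.

## What the simulator does and does not emulate

It reproduces the statistical structure the analysis assumes: step-family
episodes, an instantaneous voltage-linear fluorescence term, a slow term
proportional to open probability, linear bleaching, iid Gaussian noise, and
repeat averaging. It deliberately omits: multi-state/Markov gating and
desensitisation, spectral (wavelength-resolved) electrochromism, shot and
1/f noise, membrane capacitance and series-resistance artefacts, leak
currents, and focus or motion drift. Passing tests therefore demonstrate
that the *analysis* is correct under its stated model — not that the model
captures every feature of real oocyte recordings; in particular the absence
of capacitive transients means the 5 ms fast window needs no blanking here,
whereas real data may need the `blank`-style offset via the window
arguments.

## Numerical choices and degenerate inputs

* Segment sample counts are `round(duration × rate)` with the first sample
  at segment onset; time windows are half-open.
* Baseline normalisation requires a positive baseline mean; zero-length
  windows, windows outside the trace, and empty extraction windows are
  errors.
* Bleach estimation needs ≥ 2 distinct sample indices (otherwise the design
  is singular); `exact_division` refuses an envelope that reaches zero.
* The Boltzmann and exponential fits are deterministic given the documented
  initialisations; identical configuration and seed reproduce reports
  bit-for-bit (`withr::with_seed` scopes all randomness, and repeat noise
  substreams are drawn deterministically from the experiment seed).
* Problem sizes were chosen for validation work on a single CPU: one preset
  sweep is 91k–242k samples, the default pipeline run completes in seconds,
  and the Monte-Carlo suites (noise-recovery of the Boltzmann parameters,
  estimator power and null calibration) use 100–1500 replicates.

## Known limitations

* The agonist dependence ($V_{1/2}$ shift, occupancy, τ scaling) is a
  phenomenological stand-in; fitted parameter values for it should not be
  interpreted mechanistically.
* The linear-bleach model is first-order by design; recordings with strong
  exponential bleaching should be compensated externally before analysis.
* Tail-current analysis assumes leak-free, single-population currents; no
  P/N leak subtraction is provided.
* The linearity classifier is tuned for ~10–15 point curves; for much longer
  curves the run criterion becomes conservative.

## A worked run

```{r example}
report <- run_vcf(vcf_config("K308R_A337_300ATP", seed = 1, noise = FALSE))
report
```
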