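---
title: "Methods: the cumulative-dose IFFL model and its quantification pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cumulative-dose IFFL model and its quantification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripedyn)
```

## The circuit model

The posterior *byn* stripe is controlled by an incoherent feedforward loop:
ERK activates both *tailless* (fast, low threshold) and *huckebein* (slow,
high threshold), and *byn* responds to Tll activation unless Hkb protein has
accumulated. The live-imaging observations this package models are that (i)
*tll* transcription begins within minutes of an optogenetic ERK step at any
amplitude, (ii) *hkb* onset is delayed in inverse proportion to stimulus
amplitude, ranging from ~20 min at the top of the amplitude range to ~60 min
at the bottom, with no expression at all below a floor, and (iii) the
transient-vs-sustained character of *byn* follows from the relative timing of
the two branches rather than their steady-state presence.

The model is the minimal structure consistent with those observations. No
system of published equations exists for this circuit; every functional form
below is a package-level choice, and all parameters are calibrated against
the printed timing anchors (see "Calibration").

**Light to ERK.** `E = (sI)^h / ((sI)^h + K_sat^h)`, with relative intensity
`I` (high = 1, low = 1/8), embryo-specific multiplier `s` (log-normal,
median 1, CV 0.3, modelling Gal4/UAS expression variability), `K_sat = 0.2`
and `h = 3`. The map saturates: the 8-fold intensity difference becomes a
~5-fold ERK difference. ERK follows light with a first-order time constant
`tau_cic = 0.3 min`, reflecting fast Cic-mediated relief and the restoration
of repression within minutes of light-off.

**Cumulative-dose thresholds.** The circuit senses the time-integral
`W(t) = ∫ E dt`. Transcription of each branch initiates (after a latency of
`tau_latency = 0.8 min`) when `W` crosses `theta_tll = 2.2` or
`theta_hkb = 19` ERK·min. Because `W` grows at rate `E`, the repressor onset
is `~theta_hkb / E`: amplitude is transduced into delay, the observation at
the core of the study. The integrator is *not* reset by mitosis (signalling
is not assumed mitotically silenced; only transcription is), and the state
persists across cycles. Raw onsets falling in a mitotic gap snap forward to
the next interphase start.

**Transcription indicators.** Binary bursting states, not stochastic burst
kinetics: `x_gene(t) = 1` when `t` is past the gene's onset, in interphase,
before the sensitivity window closes (`window_close = 15` min into NC14, for
both *tll* and *hkb* but not *byn*), and while instantaneous ERK stays above
a small maintenance level (`e_maint = 0.02`). The maintenance condition
implements the rapid restoration of Cic repression at light-off; without it
the repressor branch would keep transcribing after an NC10–13 pulse (whose
45 min at high amplitude deliver far more than `theta_hkb`) and the pulse
experiment could not convert a high input into sustained output.

**Proteins and the output gate.** `dP/dt = k_prod·x − k_dec·P`, integrated
exactly per step. Tll: `k_prod = 1 a.u./min`, `k_dec = 0.02/min`. Hkb:
`k_prod = 1`, `k_dec = 0` — repressor protein is treated as stable over the
~90-min window. This is deliberate: with appreciable Hkb turnover, protein
would fall back below the repression level once the NC14 window closes and
the output would re-activate late in NC14, which is not observed. The gate is
pointwise: `x_byn = 1` iff `P_T > theta_T_on (5)`, `P_H < theta_H_off
(33.5)`, interphase, and before gastrulation.

**Nuclear-cycle schedule.** Interphases NC10 0–2.5, NC11 7–16, NC12 18–30,
NC13 32–45, NC14 48–93 min; gastrulation at 93 min. The anchors are the
~45-min NC10–13 epoch and the ~90-min total. The short NC10 interphase
encodes that surface nuclei are scored only briefly in cycle 10 and plays a
mechanistic role: under a continuous high stimulus from NC10 the raw
activator onset (~3.4 min) falls in the NC10→11 mitotic gap and snaps to
7 min (NC11), whereas the same stimulus applied at the start of NC14 gives
detectable transcription within ~3.4 min — both printed observations. With a
long NC10 interphase these two timings cannot coexist in one parameter set.

**Classification.** NC14 output duration 0 → absent; ≤ 15 min → transient;
≥ 25 min → sustained; otherwise intermediate. These cutoffs mirror the
reported 10–15 min transient pulse and ≥ 25 min sustained transcription.

## The spatial model

A single activated species `C` (the data cannot distinguish which component
diffuses, nor diffusion from transport; we model generic diffusion) obeys
`∂C/∂t = D ∂²C/∂x² + alpha·I·mask(x)·lit(t) − beta·C` on a 1-D axis
perpendicular to the illumination boundary, with no-flux ends. ERK is the
same saturating map applied to the light-equivalent dose `C·beta/alpha`, so
deep inside the mask the spatial model reproduces the zero-dimensional model
exactly at steady state, and the half-plane steady state has the closed form
`C(x>0) = (plateau/2)·exp(−x/λ)`, `λ = sqrt(D/beta)`.

Defaults `D = 125 µm²/min` (≈ 2 µm²/s, ordinary cytoplasmic protein
mobility), `beta = 0.2/min` give `λ = 25 µm`: graded responses detectable to
~2λ ≈ 50 µm, a sustained output band at ~25–50 µm beyond the boundary, and a
~5 min response rise time. The photoconversion control is pure diffusion of a
step (`D` forced to 0 when cellularized) and matches `½·erfc(x/√(4Dt))` to
10⁻³.

Membrane OptoSOS recruitment is modelled as the mask convolved with a
σ = 3 µm Gaussian (the light boundary itself is sharp) and is used only by
the renderer.

## Synthetic imaging

The renderer emulates the two-channel acquisition: 0.5-min frames, 0.5 µm
pixels; channel 1 nuclei (packed disks, radii 6/5/4.5/4/3.5 µm for NC10–14,
counts doubling each cycle, Poisson-disk placement re-seeded per cycle,
absent during mitosis) with MS2 foci (2-D Gaussian spots, σ = 0.6 µm,
log-normal frame-to-frame amplitude with CV 0.2, dropout probability 0.15
per frame inside a burst); channel 2 membrane recruitment following the
blurred mask. Smooth background (constant + ramp) and Gaussian noise
(sd 0.04, focus SNR ≈ 12) degrade both channels after all ground truth is
recorded. Per-nucleus onset jitter (normal, sd 1.5 min, seeded) is applied
to burst starts at render time only.

Focus intensities are arbitrary units; nothing downstream uses absolute
photometry except the enrichment measurement, which is validated against the
configured recruitment amplitude.

What the generator does *not* emulate: stochastic burst kinetics (ground
truth is the binary bursting state), photobleaching, stage drift, z-stacks
(the projection stage is a pass-through), chromatic effects, mitotic-wave
staggering (supported in the annotation API via explicit appearance times,
but rendered waves are synchronous). Passing pipeline tests therefore
demonstrate recovery of a known binary bursting process under noise, dropout
and jitter — not performance on real movies.

## The quantification pipeline

Implements the study's measurement procedures: rolling-ball-style background
subtraction (grayscale opening, radius 50 px by default) and max projection;
focus detection as strict local maxima inside nucleus masks with prominence
above the nucleus fill exceeding `k = 5` times the MAD of the non-nuclear
background (the automated stand-in for a manual "visible focus" call — the
study's threshold is unstated, so `k` is exposed and the acceptance surface
is ground-truth recovery, not agreement with an annotator); per-cycle
bursting intervals from first to last call, with the bursting state filled
across dropouts; durations measured last-minus-first (a single-frame focus
counts one frame interval); proportions out of all nuclei in the quantified
region; the two-step time-to-50% rule with "at least 50%" read as the
⌈n/2⌉-th entrant; fixed-size quantification boxes (50 × 45 µm anterior
extent, 30 × 75 µm boundary shift, half-open trailing edges, the boundary
box abutting the boundary when the extent is within 30 µm of it); and
membrane enrichment/profiles over non-nuclear pixels only.

With the default dropout of 0.15/frame, interval ends are trimmed with
geometric tails; each endpoint is recovered to within one frame for ~97.8%
of bursts, so ~95.5% of bursts have both endpoints within a frame while the
fraction of *durations* within one frame is ~94%. The end-to-end check used
for acceptance is the mean absolute NC14 duration error, which stays well
under 1.5 min.

## Numerical choices

Circuit integration: fixed 0.1-min steps; ERK updated by the exact
first-order decay per step; proteins by the exact exponential update
(`k_dec = 0` handled as pure accumulation); dose by trapezoid; threshold
crossings located by linear interpolation within a step. Constant-input
onset oracles agree to 10⁻⁶ relative. Steps above 0.25 min are refused.

Diffusion: explicit finite differences, dx = 1 µm, dt = 0.4·dx²/(2D), no-flux
via mirrored ghost cells; source cells at the mask edge are weighted by the
lit fraction of the cell so the effective boundary is second-order accurate
(without this the half-cell offset shows up as a 2% error in the steady-state
tail). Steady-state and erfc comparisons hold to 10⁻³.

Tie-breaks and edges: interphases and boxes are half-open; onset exactly at
a mitosis boundary snaps forward; the time-to-50% qualification requires the
proportion condition in the candidate cycle *and every later cycle*.

## Calibration

The study prints timing anchors, not parameters. `calibrate_circuit()`
evaluates a deterministic grid against `calibration_constraints()` — NC14
output durations (10–15 min transient high, ≥ 25 min sustained low and
pulse), the 20–60 min repressor onset range over the six-dose sweep, the
≤ 4 min NC14-start activator latency, the ~10 min (±4) repressor–activator
onset gap, and the NC13-start/NC14-start repressor dichotomy — and returns
the first satisfying parameter set with per-anchor residuals. The shipped
defaults are that output and are stored with the spatial parameters and the
sweep in `inst/extdata/calibration.json`. The lowest sweep amplitude (0.3525)
is the smallest at which the repressor can fire inside the sensitivity
window, matching the observation that the weakest embryos never express it.

## Problem sizes

Default runs use 931 time steps per trajectory (93 min at 0.1 min), 301
spatial positions (±150 µm at 1 µm), and movies of 96–192 px frames at
186 frames; the full test suite and the acceptance script each run in a few
minutes on one CPU with these sizes.

## Limitations

The model is deliberately phenomenological: Boolean transcription, no
enhancer-occupancy mechanism for the dose thresholds (the candidate
mechanisms — slower Cic clearance from *hkb* enhancers, chromatin state —
are not modelled), no intermediate node between Tll and *byn* even though
Tll is characterised as a repressor, 1-D geometry, diffusion rather than
active transport, and stable repressor protein as an effective description
of persistent repression. Embryo-to-embryo variability enters only through
the OptoSOS scale factor. These choices suffice for every anchor the package
reproduces but are not evidence about mechanism beyond the dose-to-delay
computation itself.
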