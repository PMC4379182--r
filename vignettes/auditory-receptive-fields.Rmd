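---
title: "Auditory receptive fields from temporal scale-space theory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditory receptive fields from temporal scale-space theory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auriscale)
```

## The model

`auriscale` implements a linear, feed-forward, two-layer model of early
auditory processing built entirely from scale-space smoothing kernels —
kernels constrained so that coarser scales never create structure that was
not present at finer scales (non-creation of local extrema). Over a purely
temporal domain exactly two kernel classes satisfy this constraint: the
Gaussian (if causality is not required) and, for time-causal processing,
cascades of truncated exponentials \(h(t;\mu_k) = e^{-t/\mu_k}/\mu_k\)
(first-order integrators). Every smoothing operation in the package is one
of these two, which is what gives the model its provable invariance and
covariance properties.

### First layer: multi-scale spectrogram

Each channel at angular frequency \(\omega\) multiplies the input by
\(\cos\omega t\) and \(\sin\omega t\) and smooths both products with the
temporal kernel at window scale \(\tau(\omega)\); the two outputs form the
complex channel response. This is mathematically a Gabor filter bank for
the Gaussian window, a Gammatone filter bank for the equal-time-constant
cascade (\(a = 1/(\mu^K\Gamma(K))\), \(b = 1/(2\pi\mu)\)), and a
generalized Gammatone bank for the logarithmic cascade. Because the
smoothing is done channel-wise in the time domain there are no
block-windowing artifacts, and a spectrogram at any coarser window scale
is an exact smoothing of one at a finer scale (cascade property).

The window scale follows the wavelength,
\(\tau(\omega) = \tau_0 + (2\pi n/\omega)^2\): spectral selectivity
measured in semitones is then the same at every frequency, so a frequency
shift of the input translates the log-frequency spectrogram. A steady
unit-amplitude tone at a channel center yields magnitude \(1/2\) (the
other heterodyne sideband at \(2\omega\) is attenuated by the low-pass
window; for \(n \ge 8\) the residual is below 1%).

### Second layer: spectro-temporal receptive fields

On the dB-magnitude, MIDI-frequency spectrogram \(S_{dB}(t,\nu)\), the
second layer applies
\[
A(t,\nu) \;=\; \partial_t^{\alpha}\,\partial_\nu^{\beta}\,
  \bigl[\,g(\nu - v t;\, s)\; T(t;\,\tau_a)\,\bigr],
\]
with \(T\) again Gaussian or a time-causal cascade and \(g\) Gaussian over
log-frequency. Because a sound-pressure change adds a constant to
\(S_{dB}\), any response with \(\alpha + \beta \ge 1\) is invariant to
level; the glissando shear \(v\) adapts the field to sounds whose
log-frequencies drift linearly in time. Features are the standard
combinations: the positive/negative parts of the \(\alpha = 1\) response
(onsets/offsets), the positive part of \(-\mathcal{D}_{\nu\nu}\)
(\(\beta = 2\); partials at fine \(s\), formants at coarse \(s\)), ridge
curves from sub-grid zero crossings of
\(\partial_\nu(-\mathcal{D}_{\nu\nu})\), and glissando estimates either
as the argmax over a filter bank in \(v\) or as
\(v = -\Upsilon_{t\nu}/\Upsilon_{\nu\nu}\) from the smoothed second-moment
matrix of the first derivatives.

## Parameters that matter

| parameter | meaning | units | default | why |
|---|---|---|---|---|
| `n` | window length / wavelength | — | 8 | sets selectivity: relative bandwidth ≈ 2θ/n; n = 8 gives ≈ 0.57 st at −3 dB (Gaussian) |
| `sigma0` | soft lower bound on window σ | s | 1 ms | keeps high-frequency windows from vanishing; deviation from covariance starts near n/(σ₀√(β²−1)) ≈ 4.6 kHz |
| `tau_inf`, `p` | soft upper bound on τ | s², — | off | caps delay at low frequencies when needed |
| `K` | cascade stages | — | 7 (layer 1), 4 (layer 2) | more stages: sharper selectivity, longer delay |
| `c` | scale ratio, log distribution | — | √2 | smaller c approaches the uniform cascade; delay shrinks as c grows |
| `channels_per_octave` | ν resolution | — | 48 | quarter-semitone channels over 80 Hz–16 kHz |
| `hop` | output decimation | samples | 1 ms | features live at ≥ ms scales |
| `tau_a`, `s` | second-layer scales | s², st² | — | per feature: σ_ν ≈ 0.5 st for partials, ≈ 4 st for formants |
| `C` | ridge strength threshold | dB-units | 3 | suppresses noise ridges |

The choice between families is a selectivity/latency trade-off that the
characterization module quantifies: at −3 dB the bandwidth parameter θ is
0.132 (Gaussian), 0.138 (uniform K = 4) and 0.146 (logarithmic K = 4,
c = 2), while the kernel-peak delay in units of √τ is 0 (after delay
removal), 1.500, and 1.014 respectively.

```{r tables}
characterization_tables()$t_max
```

## Discretization

*Temporal smoothing of sampled signals* uses first-order recursive filters
\(f_{out}(t) - f_{out}(t-1) = (f_{in}(t) - f_{out}(t-1))/(1+\mu)\), whose
discrete variance is \(\mu^2 + \mu\); solving
\(\mu = (\sqrt{1+4\Delta\tau}-1)/2\) per stage makes the variance
bookkeeping exact at any sample rate. The filter state is seeded with the
first input sample, so constants pass through without onset transients
(the initialization is a free choice of the discretization). Temporal
derivatives can be computed from differences between the cascade's stage
outputs, \(L^{(r)}_k = (L^{(r-1)}_{k-1} - L^{(r-1)}_k)/\mu_k\) — the
scale channels double as the temporal derivative buffer.

*Non-causal and spectral smoothing* uses the discrete analogue of the
Gaussian, \(T(n;s) = e^{-s} I_n(s)\), truncated where the retained mass
exceeds \(1-\varepsilon\) (\(\varepsilon = 10^{-6}\)) and renormalized so
a constant maps exactly to itself; boundaries are mirrored (adiabatic
conditions). For \(s > 10^4\) a sampled continuous Gaussian is used:
at such scales the two kernels agree far below the truncation tolerance
while the Bessel recursion becomes needlessly slow. Derivatives use the
stencils \((-1,+1)\) (time; causal, aligned to the later sample — the
half-sample shift is documented, not compensated), \((1,-2,1)\), and
\((-1/2, 0, +1/2)\)/\((1,-2,1)\) over frequency, scaled to per-second /
per-semitone units, then scale-normalized by \(\tau_a^{\alpha/2} s^{\beta/2}\)
(variance-power normalization, the \(\alpha{=}1\)/\(\beta{=}2\) special
cases generalized to all orders).

One deliberate ordering choice: the difference operators are applied
*before* the smoothing stages they commute with. For linear
shift-invariant operators the result is the same; numerically the
difference removes any constant dB baseline exactly (bit for bit) before
it can seep through the smoothing as rounding noise, which makes the
sound-pressure invariance of derivative features exact rather than
approximate. Glissando-adapted fields warp the spectrogram by
\(\nu' = \nu - vt\) (cubic spline per frame, edge replication), smooth
separably in the warped frame, and unwarp; with the default "plain"
derivative convention the temporal differences are taken in the original
frame, with the "adapted" convention (\(\partial_t + v\partial_\nu\))
inside the warped frame. The warp uses the global time origin — a pure
shear — since whole-spectrogram filtering has no distinguished frame
center.

*Kernels without closed form* (distinct time constants) are sampled by
sequential numeric convolution of the analytically sampled primitives on
a grid of step \(\sqrt{\tau_{max}}/1000\) over
\([0, m + 10\sqrt{\tau_{max}}]\), with trapezoid (half) weighting of the
endpoint samples; this reproduces the kernel-peak delays to the third
decimal against closed-form spot checks (e.g. the two-exponential cascade
K = 2, c = 2 peaks at \(\ln(\mu_2/\mu_1)/(1/\mu_1 - 1/\mu_2) = 0.650\)).
Derivatives of these kernels use central differences on the same grid —
no closed form exists to differentiate. Cascades reject derivative orders
\(\alpha \ge K\), since the composed kernel is only \(K-1\) times
continuously differentiable.

*Root finding*: the logarithmic-family bandwidth parameter θ solves a
strictly decreasing dB equation and is bracketed on \((0, 4]\) and
bisected to 1e-9 — bisection because the guaranteed monotonicity makes it
the simplest certifiable scheme at this precision.

*Delay compensation* of time-causal spectrograms shifts each channel
earlier by the first inflection point of its window, rounded to whole
samples (the sub-sample residue is far below the hop used for features;
fractional shifts would buy nothing at ms hops).

## The synthetic stimulus suite

All tests run on synthesized stimuli that mirror the model's reference
material: harmonic complexes with 20 partials and a 6 dB/octave spectral
slope at stated fundamentals (rendered at 44.1 kHz in the defaults;
down-sampled rates of 4–16 kHz and sub-second durations in the tests,
which probe steady-state and ratio properties that do not depend on the
absolute rate), pure tones, gated tones for onset/offset timing, and
exponential-glissando chirps whose phase is integrated in closed form.
The generator is deterministic.

What the generator does *not* emulate — and hence what passing tests do
not show about real audio: additive and reverberant noise, amplitude
modulation and vibrato, inharmonicity, multiple simultaneous sources, and
phase structure across partials. The invariance properties are exact
linear-algebraic facts and transfer to any input; detection-style results
(ridge tracking accuracy, glissando recovery within 10%) are validated
only on clean synthetic signals.

## Sizes, tolerances and degenerate inputs

Test problem sizes were chosen as the smallest that exercise each
property cleanly: spectrograms with 12–96 channels/octave over one to
three octaves, 0.3–0.9 s of signal at 4–16 kHz; the extrema-non-creation
property runs 200 random piecewise-smooth signals; the numeric kernel
grids use 1e5 points. Numeric tolerances follow the quantity: moment
additivity to 0.5% (trapezoid error on finite grids), semigroup to twice
the truncation mass, analytical table entries to the printed three
decimals, parameter recovery to 5–10%.

Degenerate inputs are defined rather than rejected where a natural limit
exists: `s = 0` or `tau_a = 0` skip the corresponding smoothing
(`discrete_gaussian(0)` is the unit impulse), `v = 0` makes the warp the
identity, K = 1 cascades are pure exponentials whose peak sits at the
origin and which have no interior inflection (flagged `NA`). Hard errors
are reserved for genuine contract violations: non-positive scales,
channels above Nyquist, derivative orders reaching K, empty signals.

## Known limitations

The model is linear and feed-forward: no cochlear nonlinearity, half-wave
rectification, adaptation, or binaural processing, and no fitting of the
idealized fields to measured neural data. Magnitude (not phase) is the
only downstream quantity supported from the complex spectrogram. The
two-tap temporal difference carries an uncompensated half-sample delay.
Ridge linking is greedy nearest-frequency within a 1-semitone gate —
adequate for separated partials, not a tracker for crossing trajectories.
The spectrogram engine is O(channels x stages x samples); it favors
exact scale bookkeeping and freedom from blockwise artifacts over raw
speed.
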