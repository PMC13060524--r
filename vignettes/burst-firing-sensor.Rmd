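---
title: "Modelling a burst-firing microcavity single-molecule sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a burst-firing microcavity single-molecule sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffpcsim)
```

## The sensing problem

A fiber Fabry-Pérot microcavity (FFPC) is a micrometre-scale optical
resonator formed by two mirror-coated fiber tips, filled with water and held
on resonance with a pump laser by Pound-Drever-Hall (PDH) feedback. A single
amino acid diffusing through the optical mode changes the local refractive
index through its excess polarizability $\alpha'$ (its polarizability beyond
the water it displaces). The resulting resonance shift is minuscule — below
$10^{-5}$ of the cavity linewidth — yet the locked cavity can respond with
trains of deep, saturating transmission drops ("bursts", reminiscent of
burst-firing neurons) because a photothermal cascade inside the lock loop
amplifies perturbations nonlinearly. This package simulates that detection
chain end to end and implements the associated calibration and
species-differentiation analyses.

## Cavity optics

The closed-form layer is standard resonator physics. The resonance
condition $m\lambda = 2nL$ gives the longitudinal mode number; the free
spectral range is $c/(2nL)$, the finesse $F = \mathrm{FSR}/\kappa$ and
quality factor $Q = \nu/\kappa$ with $\kappa$ the linewidth (FWHM). For the
typical geometry ($L = 10\,\mu$m, ROC $= 33\,\mu$m, $n = 1.33$,
$\lambda = 640$ nm, $\kappa = 190$–$250$ MHz) this gives $F \approx
45{,}000$–$59{,}000$ and $Q \approx 1.9$–$2.5\times 10^6$:

```{r}
geom <- cavity_geometry(linewidth = 250e6)
cavity_figures(geom)
gaussian_mode(geom)
```

The waist of the symmetric-cavity Gaussian mode is
$w_0^2 = \frac{L\lambda}{2\pi}\sqrt{\frac{2\,\mathrm{ROC}-L}{L}}$
and the mode volume is taken as the top-hat-equivalent
$V = \tfrac{\pi}{4} w_0^2 L$, averaging out the standing-wave axial
structure (the photon lifetime, $\sim$0.6 ns, is far below every other
timescale). We use the vacuum wavelength in the waist formula; this
convention reproduces the quoted $\approx 19\,\mu\mathrm{m}^3$ mode volume
for this geometry, whereas the in-medium wavelength gives
$\approx 15\,\mu\mathrm{m}^3$. Neither formula nor convention is uniquely
dictated by the physics at this level of idealization; the vacuum-$\lambda$
convention is adopted package-wide.

The PDH error signal is modelled by the canonical
high-modulation-frequency dispersive shape
$e(\delta) = x/(1+x^2)^2$, $x = 2\delta/\kappa$, normalized to unit slope in
$x$ at resonance. The simulator only relies on its odd symmetry, linear
core and decaying wings; its extremum sits at $\delta = \kappa/(2\sqrt 3)$.

## The molecular drive

A molecule at the mode center shifts the resonance by
$$|\Delta\nu_{\max}| = \frac{2\pi \alpha' \nu}{n^2 V},$$
with $\alpha'$ the excess polarizability volume (stored in Å$^3$, converted
to m$^3$). For $\alpha' = 5$ Å$^3$ this is $\sim$440 Hz — a few parts in
$10^6$ of the linewidth, which is the whole point: the raw shift is
undetectable without amplification. Off-center molecules are weighted by
the normalized mode intensity $I(\rho, z)$ of the fundamental Gaussian
mode.

Molecules arrive at a sensing sphere of radius $R_s = 1.5\,w_0$ centered on
the waist as a homogeneous Poisson process with the Smoluchowski diffusive
flux rate $\lambda = 4\pi D R_s C N_A$ (concentration converted to
molecules/m$^3$), start uniformly on its surface, perform free Brownian
motion (per-axis increments of variance $2D\,\Delta t$, with $D$ from
Stokes-Einstein unless supplied), and are dropped once they pass a kill
radius of $2 R_s$. The Smoluchowski form makes the delivered molecule count
exactly linear in concentration, which the tests exploit.

**The photothermal pre-amplification factor.** The effective drive seen by
the lock is $\delta_{\mathrm{ext}}(t) = G \cdot \Delta\nu_{\max} \cdot
I(r(t))$ with a dimensionless response gain $G$ (default $10^4$, pinned in
the preset). $G$ stands for the fast thermal amplification stage that
converts the raw perturbative shift into the effective detuning excursion
the servo has to fight: experimentally, sub-kHz molecular shifts trigger
the same bursts as multi-MHz piezo test pulses, so some four orders of
magnitude of pre-amplification precede the dynamics this model resolves. A
single-stage model cannot produce both scales from first principles; $G$
is therefore an explicit, documented knob, chosen once so that a
tryptophan-scale molecule ($\alpha' = 25$ Å$^3$) sits just below the pulse
threshold (detection is noise-assisted), while alanine-scale molecules
($\alpha' \le 3$ Å$^3$) stay silent. Consequently the simulator's absolute
event rates are not quantitative predictions — only their orderings,
concentration scaling and statistical behaviour are.

The shipped analyte table (`default_analytes()`) carries **placeholder**
$\alpha'$ values spanning 1–50 Å$^3$ in the expected order glycine <
alanine < threonine < histidine < tryptophan < phospho-threonine <
Myc-tag; replace them with computed values when available. Glycine is
listed at 75.07 Da.

## Lock dynamics and the burst mechanism

The simulator integrates five slow variables with explicit Euler-Maruyama
stepping (default $\Delta t = 10\,\mu$s, decimated to 20 kHz output); the
optical field is adiabatic, so the intracavity power follows the
instantaneous Lorentzian $T(\delta) = 1/(1+(2\delta/\kappa)^2)$:

* servo low-pass $u$: $\dot u = 2\pi f_{LP}\,(e - e_{set} - u)$,
* servo integrator $\iota$: $\dot \iota = u$, with actuator detuning
  $\delta_{\mathrm{lock}} = -k_{\mathrm{act}}(g_p u + g_i \iota)$,
* thermal offset $\Theta$: $\dot\Theta = -\Theta/\tau_{th} + c_{abs}
  P_{in} T$, with thermo-optic detuning $\delta_{th} = k_T (\Theta -
  \Theta_{op})$,
* Ornstein-Uhlenbeck detuning noise $\xi$ (stationary sd
  $\sigma_\delta$, correlation time $\tau_c$), plus white detector noise
  on the sampled transmission.

The total detuning is $\delta = \delta_{\mathrm{lock}} + \delta_{th} + \xi
+ \delta_{\mathrm{ext}}$. The thermal operating point $\Theta_{op}$ is
captured at the end of a 0.5-s settling window (excluded from all
analyses), so the thermal loop engages with zero offset.

The burst regime works as follows. The servo holds the cavity slightly off
the fringe top (small positive set point). A perturbation that pushes the
detuning outward reduces the coupled power; with $k_T < 0$ the resulting
cooling ($\sim$0.5 mK scale) pushes the resonance *further* away — a
regenerative photothermal cascade that runs until the thermal swing
saturates (pinned at $\approx 2.7$ half-linewidths, so transmission drops
to a consistent floor). The integrator then winds up, yanks the detuning
back through resonance, overshoots, and the cascade re-fires: a damped
relaxation oscillation that appears as a burst of several saturating
transmission drops before the baseline returns. Two qualitative
constraints shaped the pinned preset:

* the set point must stay small: beyond the error-signal extremum the
  servo pushes the wrong way and the lock latches off-resonance (the
  simulator flags this as a lock break when $|\delta| > 5\kappa$ for more
  than 50 ms), mirroring the experimental lock-breaking when the set point
  is pushed too far;
* the cascade must outrun the servo within the 1-ms pulse, which requires
  a sub-ms thermal time constant and a low locking bandwidth
  ($f_{LP} = 200$ Hz in the preset; the helper
  `lowpass_cutoff_from_resistance()` maps the experimental 10–32 kΩ
  low-pass resistances to cutoffs given a nominal 10 nF capacitance,
  which is not itself specified).

Sensitivity is tuned by the same knobs the experiment uses: more input
power strengthens the cascade, a lower low-pass cutoff delays the servo,
and a higher set point parks the lock closer to the unstable region. In
the pinned preset the pulse-detection midpoint sits near 28 MHz and moves
to ~24 and ~22 MHz for the two higher-sensitivity presets used in the
ordering tests. Driving the power to 100 µW at low bandwidth breaks the
lock — the regime boundary is part of the model's behaviour, not an
error.

```{r}
s <- burst_regime()
tr <- simulate_trace(s, pulse_program(45e6, t0 = 1, rate = 0.5),
                     duration = 3, seed = 1201)
detect_events(tr)
```

## Event detection

Detection thresholds at `level - max(drop_fraction * (level - floor),
noise_guard * sigma)` where `level` and `sigma` come from a robust
baseline estimate and `floor` is the trace minimum. Because burst drops
saturate, detection is insensitive to `drop_fraction` over a wide range
(default 0.5); the noise guard (default 10 sigma) only matters on blank
traces, where it suppresses chatter. Two numerical choices deserve
mention:

* the baseline sigma is 1.4826 × MAD of the samples above the 60th
  percentile, rescaled by the Gaussian truncation factor 0.533 so that it
  estimates the true baseline noise sd (the raw truncated-sample MAD
  underestimates it by ~2×, which would silently distort every
  sigma-denominated rule downstream);
* "return to baseline" for the 0.5-s independence rule is judged on a
  10-ms moving average staying above `level - 3 sigma`: a sample-wise
  contiguity requirement would essentially never be met under white
  detector noise at 20 kHz.

Spikes separated by less than 0.5 s of contiguous baseline merge into one
detection event; each event records its spike count and per-spike minima
(the saturation diagnostic `spike_depth_cv()` pools the latter). Pulse
*response scoring* (`score_pulse_responses()`) instead clusters with a
0.2-s gap, because calibration pulses arrive every 0.5 s and the
independence rule is meant for free-running molecular data; a pulse is
excluded from the denominator if an event overlaps the 100-ms look-back
window before its onset (the cavity was still oscillating), and events
not matched to a pulse are spurious and ignored. The 100-ms look-back and
250-ms response windows are defaults, not reported values.

## Calibration and sensitivity threshold

The internal calibration injects 1-ms square detuning pulses, 13
amplitudes from 5 to 65 MHz at 2 Hz, 48 pulses per amplitude (four 6.5-s
traces), and fits the fraction detected with a sigmoid
$f(A) = 1/(1+\exp(-(A - A_{50})/s))$ by binomial maximum likelihood
(logistic regression — points carry unequal pulse counts after
exclusions, which unweighted least squares would ignore). $A_{50}$ is the
sensitivity threshold compared across operating points.
`piezo_conversion()` recovers the Hz-per-volt factor of the length
actuator from a triangle-ramp scan across the phase-modulation sidebands
(1 GHz markers): conversion = sideband frequency / (peak separation ×
ramp slope), invariant to scan speed and direction.

## Differentiation statistics

`run_protocol()` simulates the standard experiment — water blanks, analyte
A, analyte B, water blanks again, all at one pinned sensitivity and 33-s
traces by default — and compares per-trace event counts with a two-sided
exact permutation test on the difference of mean rates
(`rate_test()`; full enumeration up to 10 traces, $10^5$ seeded
resamples beyond). Traces are the exchangeable replicates. The test is
assumption-free at $n = 3$–10, at the cost of discreteness: with 5 + 5
traces only 252 label assignments exist, so the attainable type-I error
at the nominal 0.05 level is ~4% at realistic count magnitudes, and
noticeably lower when counts are tiny (ties). Significance categories use
the conventional inclusive thresholds ns / * / ** / *** / ****.

## What the generator does and does not emulate

The synthetic traces reproduce: off-fringe locking with settling,
saturating multi-spike bursts with tightly clustered spike minima,
sigmoidal pulse-detection curves whose midpoints shift with the
experimental sensitivity knobs, near-zero water blank rates with
occasional sporadic events, noise-assisted single-molecule detection with
event rates linear in concentration, and lock breaking when the regime is
overdriven. They do **not** reproduce: absolute event rates or absolute
thermal constants (the photothermal pre-amplification is an effective
parameter), acoustic line spectra (only OU + white noise are modelled),
piezo hysteresis, multi-mode or vectorial optics, or hydrodynamic peak
shapes — in this regime spike widths are set by system parameters, not
molecular motion, so the model makes no claims about transit-time
profiling. Passing tests therefore validate the mechanism and the
analysis pipeline, not instrument-level quantitative agreement.

## Problem sizes and reproducibility

Every simulation takes a mandatory seed and is bit-reproducible; traces
store their resolved settings and seed in metadata, and the CSV container
round-trips both. The shipped test and acceptance runs use scaled-down
protocols — 3–6.5-s traces for pulse work, 5-s traces and 5 traces per
condition for differentiation, 10 traces per concentration for the
linearity check, and a 1000-replicate Poisson calibration at the 33-s
count scale for the type-I error — sizes chosen to keep the full suite
around a minute while leaving every statistical margin comfortable.
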