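# ffpcsim

Simulation and analysis toolkit for label-free single-amino-acid detection
with a locked fiber Fabry-Pérot microcavity (FFPC).

A water-filled micrometre-scale cavity between two mirror-coated fiber tips
is held on resonance by Pound-Drever-Hall (PDH) feedback. A single molecule
diffusing through the optical mode perturbs the intracavity refractive
index in proportion to its excess polarizability α′; although the raw
resonance shift is below 10⁻⁵ of the cavity linewidth, a photothermal
cascade inside the lock loop amplifies the perturbation into trains of
deep, saturating transmission drops — neuron-like signal bursts — which are
counted as detection events. Tuning the lock's sensitivity turns the sensor
into a molecular filter: at a given operating point one species fires
events while a smaller one does not, enabling single-molecule
differentiation of amino acids (and of an amino acid from its
phosphorylated form) at picomolar concentrations. The package is aimed at
people modelling or analysing such instruments: it provides the cavity
optics, the stochastic lock-dynamics simulator, the event detector, the
pulse-response calibration, and the differentiation statistics as one
pipeline.

## The model in brief

* Optics: resonance condition `m λ = 2 n L`; finesse `F = FSR/κ`,
  `Q = ν/κ`; symmetric-cavity Gaussian waist
  `w0² = (Lλ/2π)·√((2·ROC−L)/L)`, mode volume `V = (π/4)·w0²·L`
  (≈ 19 µm³ for the typical L = 10 µm, ROC = 33 µm geometry); Lorentzian
  transmission `T = 1/(1+(2δ/κ)²)` and dispersive PDH error signal
  `e = x/(1+x²)², x = 2δ/κ`.
* Molecule: mode-center shift `|Δν_max| = 2π α′ ν / (n² V)`; Brownian
  transits through a sensing sphere with Smoluchowski arrival rate
  `4π D R_s C N_A`; Stokes-Einstein diffusion.
* Lock dynamics: explicit Euler-Maruyama integration of a PI servo
  (low-passed PDH error), a single-pole thermal stage with thermo-optic
  feedback, Ornstein-Uhlenbeck detuning noise and white detector noise.
  At the pinned off-fringe-top operating point the thermal path is
  regenerative for transmission-reducing excursions, producing all-or-none
  burst firing; see the methods vignette
  (`vignettes/burst-firing-sensor.Rmd`) for the equations and the design
  rationale.
* Analysis: robust-baseline event detection with the 0.5-s
  cluster-independence rule; pulse-response scoring with
  oscillating-before-pulse exclusion; binomial-likelihood sigmoid fits of
  fraction-detected vs. pulse amplitude (the midpoint A50 is the
  sensitivity threshold); exact permutation tests on per-trace event
  counts with ns/*/**/***/**** categories.

## Worked example

```r
library(ffpcsim)

# figures of merit for the typical cavity
geom <- cavity_geometry(linewidth = 250e6)
cavity_figures(geom)
#> FSR 11.27 THz | finesse 45082 | Q 1.87e+06 | m 41.56 | tau_ph 0.637 ns
gaussian_mode(geom)
#> Gaussian mode: w0 = 1.55 um, V = 18.9 um^3, zR = 11.8 um

# a super-threshold 1-ms test pulse fires a saturating multi-spike burst
s <- burst_regime()
tr <- simulate_trace(s, pulse_program(45e6, t0 = 1, rate = 0.5),
                     duration = 3, seed = 1201)
ev <- detect_events(tr)
ev
#>   start_time end_time minimum_transmission spike_count
#> 1          1  1.00205            0.6681807           3

# differentiation at one pinned sensitivity, 10 pM, 5-s traces
an <- default_analytes()
run_protocol(s, an$alanine, an$tryptophan, concentration = 10e-12,
             n_traces = 5, n_water = 3, trace_length = 5, seed = 11)
#> differentiation protocol:
#>   water-before   counts [0, 0, 0]  rate 0.000 /s
#>   alanine        counts [0, 0, 0, 0, 0]  rate 0.000 /s
#>   tryptophan     counts [4, 3, 3, 5, 4]  rate 0.844 /s
#>   water-after    counts [0, 0, 0]  rate 0.000 /s
#>   a_vs_water             p = 1  ns
#>   b_vs_water             p = 0.00211  **
#>   a_vs_b                 p = 0.007937  **
#>   water_before_vs_after  p = 1  ns
```

Reading the output: the burst event starts at the pulse onset, drops to a
transmission floor of ~0.67 three times in quick succession (the
saturating spike train), and water/alanine produce no events while
tryptophan at the same concentration fires ~0.8 events per second — the
below-threshold species is statistically indistinguishable from water
("ns"), the above-threshold one is not ("**").

Note the shipped per-analyte excess polarizabilities are order-of-magnitude
placeholders (see `?default_analytes`), and the simulator's absolute event
rates are not quantitative predictions — orderings, concentration scaling
and the statistics are what the model supports.

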