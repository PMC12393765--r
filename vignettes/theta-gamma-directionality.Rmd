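---
title: "Theta-gamma cross-frequency directionality in feedforward and feedback inhibitory motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theta-gamma cross-frequency directionality in feedforward and feedback inhibitory motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Hippocampal and cortical recordings show gamma (30–150 Hz) amplitude locked
to the phase of theta (4–12 Hz) oscillations. Cross-frequency coupling (CFC)
by itself says nothing about which rhythm leads. Cross-frequency
directionality (CFD) — the phase slope index between a signal and its own
gamma-band amplitude envelope — is signed: positive when the slow phase leads
the fast amplitude, negative when gamma systematically precedes theta.

This package implements a conductance-based spiking-network account of both
signs. Gamma is generated locally by fast-spiking basket cells (BCs) that
inhibit pyramidal cells (PCs) and each other, while theta arrives as an
external spike-packet drive. Two wiring motifs differ only in how the BCs are
recruited:

* **theta-ING** (feedforward): the theta drive excites the BCs directly;
  their mutual inhibition paces gamma, which reaches the PC somata before
  the (slower, dendritically filtered) theta excitation builds up —
  gamma-to-theta directionality, negative CFD.
* **theta-PING** (feedback): the BCs are recruited only by PC firing; gamma
  is carried by the excitatory–inhibitory loop and necessarily follows the
  theta-driven PC depolarisation — theta-to-gamma directionality, positive
  CFD.

Mixed motifs carry both connections; the feedforward weight dominates the
directionality, and more negative CFD co-occurs with faster gamma.

## Model

### Cells

PCs are five-compartment cylinders (basal dendrite, soma, and a
proximal/middle/distal apical chain), each compartment subdivided into three
segments. All compartments carry transient Na and delayed-rectifier K
currents in the Traub–Miles form (somatic densities 100/80 mS/cm², dendritic
10/8 mS/cm²), leak 0.1 mS/cm², and the apical dendrites additionally a slow
hyperpolarization-activated current whose density rises towards the tuft
(0.05/0.1/0.2 mS/cm², reversal −30 mV, 100 ms time constant). Geometry and
axial resistivity (300 Ω·cm) were calibrated so a distal synaptic input
depolarises the soma with a 2–5 ms latency (larger inputs that recruit the
dendritic Na conductance take longer, as expected for dendritic spikes)
while a somatic input arrives in well under 0.5 ms.

BCs are single-compartment Wang–Buzsáki fast-spiking neurons
(35/9/0.1 mS/cm²). Their dendrites are not modelled; instead every external
input to a BC incurs a fixed 1 ms delay. At the calibrated resting potential
(−62 mV) the BC model is an intrinsically tonic pacemaker (~10–15 Hz without
any input). This is a deliberate operating point: it keeps the BCs
responsive enough for sparse PC spikes to recruit them in the feedback motif
without depolarisation block, and tonic baseline firing of PV interneurons
is common in vivo. A practical consequence is that a fully disconnected
network is silent in the PC population but shows metronome-regular BC
spiking — intrinsic dynamics, not hidden input.

### Synapses

AMPA (τ 0.5/3 ms, E = 0 mV), NMDA (τ 2/100 ms, E = 0 mV, voltage-dependent
magnesium block 1/(1 + 0.28·[Mg]·e^(−0.062V)) at [Mg] = 1 mM) and GABA_A
(τ 0.5/5 ms, E = −75 mV), all double-exponential conductances normalised so
the peak equals the weight. Every excitatory projection is an AMPA/NMDA pair
with the NMDA weight fixed at one tenth of the AMPA weight. Transmission
delays are Gaussian per synapse (sd 0.2 ms) around: θ→PC 20 ms, θ→BC
20 + 1 ms, BC→PC, PC→BC and BC→BC 1.5 ms. The long θ delays exist so the
relative delay Δt = t(θ→BC) − t(θ→PC) can be swept ±10 ms without going
negative.

### Theta drive, noise, parallel pathway

The theta drive is a population of 500 driver units emitting spike packets:
packet-peak intervals are Gaussian N(125, 16²) ms and each cycle contains
10,000 spikes spread N(peak, 25²) ms, assigned uniformly to units. Both
jitters are essential — a strictly periodic drive has a line spectrum and no
measurable phase slope. Each PC (distal apical segment) and, in feedforward
motifs, each BC receives a random fan-in of 20 driver units. The small
fan-in with correspondingly larger unitary weights makes the theta pathway
itself the dominant source of membrane fluctuations (shot noise), which
decorrelates the PCs and smooths the population threshold crossing.

Independent 1 ms-mean-interval Poisson noise targets the PC soma, the PC
proximal dendrite, and the BCs. The optional parallel pathway is a second
Poisson input onto the proximal dendrite with tenfold the noise weight and a
1–5 ms mean interval, used by the information protocols.

### Calibration

The free weights were calibrated against the observable contracts of the
study: matched sparse PC firing (0.48 Hz feedforward / 0.49 Hz feedback at
200 PC / 40 BC), theta-nested gamma in the 30–100 Hz band with a higher
gamma frequency in the feedforward motif, BC spiking faster than PC spiking,
and robust CFD signs. The frozen values are in `motif_defaults()`. Weights
behave non-linearly near the operating point (the feedback loop fails by BC
depolarisation block if the PC→BC weight is pushed a few-fold higher), which
is why the defaults should be changed together, not individually.

## Numerics

The cable equation is integrated with a Crank–Nicolson step: gating
variables advance by Rush–Larsen using voltage lookup tables, and the
voltage system of each cell — a chain of consecutively numbered segments —
is solved implicitly with the Thomas algorithm. This is unconditionally
stable against the very stiff axial coupling inside the fat somatic
compartment. The default step is 0.025 ms; halving it changes spike counts
of a fixed run by well under 2%, while doubling it degrades the
(timing-sensitive) feedback-motif CFD and is not used. Delayed spikes are
delivered through a ring-buffer event queue rounded to the step. Poisson
streams are generated in the engine from per-source counter-based RNGs, so
any input stream can be held bit-identical across realizations by fixing its
seed (`run_plan(fixed_inputs = ...)`); all seeds derive deterministically
from one global seed.

Recorded series (1 ms resolution, boxcar-decimated): mean PC somatic
potential `v_pc`, mean somatic transmembrane current `i_transm` (outward
positive, computed as net axial inflow; theta troughs are its minima), the
theta-input synaptic current in the PC dendrites `i_theta`, the
transmembrane current of the theta-receiving dendritic compartment
`i_dend`, and the mean BC potential.

## Analysis stack

* **Filtering**: zero-phase frequency-sampled band-pass (unit passband,
  raised-cosine transitions, 2 Hz transition for amplitude bands), applied
  via a cached FFT of the padded signal; one filter margin is discarded at
  each edge before any metric.
* **CFC**: Canolty-style mean vector length |mean A(t)·e^(iφ(t))| on a grid.
  Default grids: phase 2–20 Hz (half-width 2 Hz), amplitude 20–150 Hz with a
  **fixed** 10 Hz half-width. A phase-frequency-dependent amplitude
  bandwidth was tried and rejected: the unnormalised statistic grows with
  bandwidth, making rows incomparable and letting broad-band rows hijack the
  comodulogram maximum. For simulated population signals the phase axis is
  restricted to 4–12 Hz (`model_phase_freqs()`): the lowest rows of the full
  grid are dominated by slow finite-size drift of the averaged currents
  rather than by theta.
* **Surrogates**: splitting the phase series at a random point and swapping
  the halves is a circular rotation, so the whole surrogate ensemble is read
  off one FFT cross-correlation per cell. Cluster correction: pooled
  99th-percentile threshold, 4-connected clusters scored by summed value,
  accepted when the score exceeds the 99th percentile of surrogate cluster
  scores (surrogates without clusters contribute zero scores). The measured
  false-positive rate on coupling-free 1/f noise is compatible with the
  nominal 1%.
* **CFD**: Welch complex coherence (Hann, 1 s segments, 50% overlap) between
  the raw signal (or an external reference series) and the amplitude
  envelope at each amplitude frequency; the phase slope index integrates
  over a β = 5 Hz band. With the conjugation written on the second series,
  a pure delay of y yields a positive slope — "if the phase difference
  grows with frequency, x leads y" — which a delayed-pair fixture pins as a
  unit test. The raw slope map is multiplied by the CFC normalised to its
  maximum; `cfd_avg` averages the masked map over cells above the 0.95 CFC
  quantile (sign-stable down to 0.85). Two-tailed significance uses
  envelope-shift surrogates whose segment spectra at all shifts come from
  sliding windowed DFTs computed with full-length FFTs.
* **Mutual information**: Kraskov k-nearest-neighbour estimator (k = 3,
  Chebyshev joint metric, tie-breaking jitter 1e-9), validated against the
  Gaussian closed form −½ln(1−ρ²) and used on 5 ms-subsampled rate series
  (spike trains convolved with a causal 5 ms exponential kernel).

## Synthetic benchmark

`coupled_signal()` builds the validation signal: sinusoidal cycles with
Gaussian periods (mean 125 ms, sd 16 ms — matching the model's σ_T, which
the original description leaves open) concatenated **trough-to-trough**, an
80 Hz burst under a raised-cosine window (half-width 25 ms, amplitude 0.3 of
the slow amplitude, both open choices) centred on each trough with a
configurable lag, plus Gaussian noise (sd 0.1 of the slow amplitude). The
trough-to-trough segmentation matters: cycles started at an ascending zero
crossing put the trough at 3/4 of each segment, make the period jitter
asymmetric around the coupling event (0.75 T deterministic backwards vs
0.25 T forwards), and generate a spurious negative phase slope (~−0.15 at
zero lag). With trough-centred segments CFD ≈ 0 at lag 0 and follows the
sign of the imposed lag cleanly. This generator validates the metric stack:
it does not emulate multichannel geometry, non-sinusoidal theta waveforms,
or harmonic artifacts, so passing it shows metric correctness, not
real-data robustness.

## Design decisions in the in-silico experiments

* **Delay sweep signal.** The Δt sweep measures CFD on the dendritic
  compartment current `i_dend`. In this calibration the somatic current's
  theta band is dominated by the theta-gated IPSC envelope, which co-moves
  with the gamma bursts, so somatic CFD barely responds to Δt; the
  theta-receiving compartment mixes the theta EPSC (which shifts with the
  θ→PC delay) with the somatic inhibitory return currents (which do not),
  and reproduces the −, −, + sign pattern. Dendritic-compartment CFD is
  part of the study's repertoire in its own right.
* **Reduced sizes.** Sign-based checks run at 50 PC / 10 BC
  (`desk_scale_motif()`): fan-ins are clamped at the population sizes and
  the affected convergent weights rescaled to preserve each neuron's total
  input, then the two motif-defining weights re-matched so both motifs fire
  at ~0.5 Hz. The strict scaling rule (projection counts ×k, weights /k) is
  kept as the `scale_factor` semantics and holds its 20% rate contract for
  scaling *up*; scaling *down* by 4 changes the operating point drastically,
  which is why the desk configuration exists.
* **Protocol configuration.** The information protocols add the parallel
  pathway, a large extra drive, so `protocol_motif()` re-balances the
  reduced motifs (weaker background noise — the parallel weight is tied to
  it tenfold — and re-matched motif weights). Fidelity and consistency are
  estimated from 5 realizations of 15 s (theta comparisons) or 25–30 s
  (parallel comparisons; the smaller MI values need the longer series). The
  perturbation protocol's "encoding" of one proximal volley is the
  normalised post-pulse output difference (≈ displaced spikes), an
  operational choice since no formula is fixed by the study; gamma-phase
  concentration is computed over trials in the depolarised theta half-cycle.
* **Problem sizes and steps.** The default test suite uses two 10 s
  (post burn-in) full-size runs per motif for the firing-rate checks,
  25–30 s reduced runs for sign checks (averaging two realizations per
  delay condition), one realization per mixed-grid cell at 40 s, and 200
  null runs at 200 surrogates for the false-positive calibration; the
  acceptance script uses three 15 s full-size runs per motif and 30 s
  reduced runs. Rates exclude a 1 s burn-in (the settling transient from
  the common initial condition inflates short-run estimates). Reduced-size
  sweep, delay-sweep and protocol simulations integrate at dt = 0.05 ms —
  the sign properties they test were verified to be step-robust — while
  the default dt = 0.025 ms is used for the full-size runs and the
  analysis drivers.

## Known limitations

* Only one interneuron class; no interneuron diversity, gap junctions, or
  short-term plasticity; no spatial geometry or distance-dependent
  connectivity; no volume-conductor forward model — the somatic
  transmembrane current stands in for a field-potential-like signal.
* Channel kinetics are canonical forms, not fits to the hippocampal
  literature; conclusions should be read at the level of circuit motifs,
  not quantitative biophysics.
* The feedback motif's positive CFD is smaller and noisier than the
  feedforward motif's negative CFD, especially at full size; single short
  realizations can fluctuate near zero.
* The single-pulse perturbation protocol's gamma-phase concentration
  contrast (feedback motif responsive only near a gamma phase, feedforward
  motif throughout the cycle) is not statistically reliable at the reduced
  sizes the package runs by default: responses in the feedback motif are
  rare, so the encoding-weighted concentration rests on a handful of
  trials. The corresponding check is expected to need far larger trial
  ensembles than the defaults.
* Experimental recordings are outside the package's scope; the
  model-side analogues (CFD sign vs. gamma frequency association) are what
  the tests and scripts compute.
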