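---
title: "Biophysical retinal neuron models, simulation-based inference, and electrical stimulus design: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinasim)
```

# Scope

`retinasim` implements an end-to-end analysis pipeline for mouse retinal
cone photoreceptors and cone bipolar cells (BCs): multicompartment cable
models with Hodgkin–Huxley (HH) and Markov channel kinetics and
ribbon-synapse glutamate release; a forward model of iGluSnFR
fluorescence with a seven-component discrepancy against target traces;
a multi-round sequential neural posterior estimation (SNPE) engine; a
quasi-static extracellular field model of a retina/bath cylinder with
disk micro-electrodes, used both to infer tissue electrical properties
from sinusoidal stimulation currents and to design charge-neutral
stimulus waveforms that drive OFF- versus ON-bipolar cells selectively.
Everything runs on synthetic inputs produced by the package's own
generators, so all results below are reproducible without external data.

# The compartmental membrane model

Each neuron is a tree of compartments (spheres, cylinders, or a cone for
the photoreceptor outer segment). A compartment `n` obeys

```
cm_n dVm_n/dt = sum_neighbors (Vm_j - Vm_n)/(ri_j + ri_n)
              + (Vr_n + Vex_n - Vm_n)/rm_n
              + sum_channels ge (Ve + Vex_n - Vm_n)
              + i_inj + cm_n dVex_n/dt
```

with `rm = Rm/Am`, `cm = Cm*Am`, `ri = Ri*lc/Am` derived from the
specific membrane resistance (Ω·cm²), capacitance (µF/cm²) and axial
resistivity (`Ri` = 132 Ω·cm for all cell classes). The axial resistance
convention uses the *membrane surface area* `Am` and compartment length
`lc`; this follows the source simulator's compartment description
literally rather than the cross-sectional convention of most cable
solvers, and the condensation algorithm conserves exactly the two
quantities this convention makes meaningful: total membrane area and the
series sum of `lc/Am` along any path. `Vm` is the intracellular
potential; the transmembrane potential is `Vm − Vex`, which makes the
model exactly invariant under spatially uniform extracellular offsets (a
property the test suite asserts to 10⁻⁹).

Spherical compartments have zero cable length; their axial coupling uses
the sphere radius as a coupling length (configurable), since the source
material is silent on sphere coupling.

## Integration scheme

The linear cable part (axial coupling, leak, frozen channel and synaptic
conductances) is advanced by Crank–Nicolson; gating states are advanced
once per step with rates frozen at the step-start transmembrane
potential — the scalar exponential-Euler update for HH gates (exact for
frozen rates) and a matrix exponential for Markov occupancy vectors
(also exact for frozen rates). Because both updates are exact flows of
the same frozen generator, an HH gate of power `p` and its mechanical
`p+1`-state chain expansion produce identical conductance trajectories
to machine precision, which the suite checks at 10⁻⁶. Calcium stores and
vesicle pools use semi-implicit scalar updates. Rate functions are
tabulated on a 0.05 mV grid and linearly interpolated, so arbitrary
user-supplied rate functions run at full speed in the compiled core.

Default steps: 50 µs for light-driven simulations, 10–20 µs for
electrical pulses; the passive step response converges at second order
(halving `dt` changes the response by < 10⁻⁴). Before any stimulus the
model is settled under constant background drive (2 s by default; the
shorter settles used by the bundled toys are stated with each
experiment); the settled somatic potential and mean release rate define
the "resting" values entering the discrepancy.

Numerical validity is screened rather than raised: non-finite or
runaway states return `status = "unstable"`, and a somatic voltage clamp
(30 mV for 100 ms, recovery to ≤ −30 mV within 300 ms) flags cells with
a biologically implausible depolarized second equilibrium. Both classes
of sample are zero-weighted during inference.

# Channels, calcium, and the ribbon synapse

The L-type calcium channel is the only channel whose kinetics the source
prints in full (`ge = c³·gmax`, with `α(V) = −0.04(V+15)/
(exp(−0.04(V+15))−1)` and `β(V) = 5·exp(−(V+38)/18)` ms⁻¹); it is
implemented exactly, including the removable singularity at −15 mV.
Rates carry a `Q10` temperature factor `exp(log(Q10)(Tsim−Teq)/10)`
(default `Q10 = 2`, since exact sensitivities are unknown) and the
kinetic modifiers ΔV (voltage offsets) and τ (relative time constants)
that inference can estimate. The other families — KV, HCN, Kir, CaT,
NaV, ClCa — ship as HH-style surrogates with matching activation ranges
and signs, flagged `surrogate = TRUE`, because their reference Markov
state tables are not published; the generic Markov machinery accepts
user-supplied transition tables.

Calcium is a single first-shell concentration per release site:
`d[Ca]0/dt = κ|i_Ca| − vmax·[Ca]0/([Ca]0+CaPK) + s0`, with the constant
source `s0` fixing the resting level as an equilibrium. Release follows
the ribbon model: `r = [Ca]0² · (vRRP/vRRPmax) · gl` vesicles/s with the
concentration in µM (the release-rate normalization constant is absorbed
into this unit convention; the `gl` prior absorbs any residual scale),
and the readily releasable pool is replenished at the maximum
sustainable release rate (`rmsr` = 8 ves/s for BCs, 100 ves/s for
cones): `vRRP ← vRRP − r·dt + rmsr·dt·(1 − vRRP/vRRPmax)`, clipped to
`[0, vRRPmax]`. The long-run mean release therefore approaches `rmsr`
under saturating calcium, which the suite verifies within 2%.

Postsynaptic transduction is a declared surrogate: kainate receptors
(OFF) are sign-preserving with first-order desensitization governed by
τγ; mGluR6 (ON) inverts the sign through a low-pass cascade; the
transmitter scale STC multiplies the presynaptic release signal.
Connectivity defaults follow the modelled circuits: OFF-BC ← 5 cones,
ON-BC ← 3 cones, two contacts each at 0.25 nS per contact.
Phototransduction is a bounded two-stage low-pass cascade with divisive
adaptation whose steady current is monotone (hyperpolarizing) in photon
rate, mapped from normalized intensity to 10–31 × 10³ P*/s per cone.

# The discrepancy function

Simulated release is convolved with a causal exponential iGluSnFR kernel
(`τ` = 60 ms, unnormalized and truncated at five time constants —
normalization is irrelevant because the comparison optimizes an affine
map). The trace component is

```
delta_trace = min_{a, b >= 0} ||target − (a + b·sim)||² / ||target − mean||²
```

solved in closed form with the slope clipped at zero, so anticorrelated
traces score exactly 1 and affine transforms score exactly 0. Six signed
bounded penalties (resting release rate and potential, release and
voltage response amplitudes, voltage extremes) use the piecewise
Gaussian-tail form with per-class bounds shipped as defaults (cone
resting release free in [50, 80] ves/s; OFF/ON BCs up to 4/3 ves/s;
voltage excursions at least 5 mV, at most 25/15 mV; and so on). The
total is the L1 norm of the signed vector, read as the sum of component
magnitudes. Peak-timing analysis detects local extrema with a prominence
threshold (10% of range) and 50 ms minimum separation, matches each
simulated peak to the nearest same-polarity target peak, and reports
signed differences with exclusion windows for noisy target segments.

# The inference engine

Priors are independent truncated normals; inference runs in the
normalized space where every truncation box is [0, 1] and the prior
standard deviation is 0.3 of the box. Sampling is by rejection from the
untruncated normal. Each round simulates all draws, computes the
discrepancy summary, updates the adaptive kernel (dimension 1 centered
at the round's minimum trace discrepancy with bandwidth equal to the
20th-percentile distance, floored at 10⁻³; all other dimensions
zero-centered Gaussians with bandwidth 0.25), weights samples by
`(p/p̃)·K(x)` with invalid simulations hard-zeroed, fits the conditional
density, evaluates it at the boundary target and truncates to the prior
box by rejection, with the truncated mass estimated by seeded Monte
Carlo so later-round importance weights use proper densities.

Three design choices in this engine are the package's own, made where
the source delegates to a particular software stack:

* **Density head.** The default conditional density is a single Gaussian
  whose mean is affine in the (standardized) summaries and whose
  covariance is the full weighted residual covariance — a closed-form
  weighted ridge regression. A two-hidden-layer MDN trained by Adam with
  manual backpropagation is implemented and remains available (and is
  the default for the two-component stimulus-search posterior), but at
  hundreds of samples per round its conditional variances collapse
  during likelihood training, which the reference stack prevented with
  variational weight priors. The ridge term (5% of the total weight)
  guards against the near-singular designs produced by concentrated
  kernel weights. The closed-form head cannot collapse and keeps
  credible intervals calibrated, which the bundled recovery experiments
  measure.
* **Boundary evaluation.** The ideal evaluation point is the zero
  summary; since a discrepancy of zero is unattainable under noise, the
  network is evaluated at the boundary of what was observed: the sampled
  summary vector with the smallest total discrepancy, with the trace
  dimension set to the round minimum. When sampled penalties reach zero
  this is exactly the rule of evaluating at
  `[min delta_trace, 0, …, 0]`; when they do not, it avoids conditioning
  outside the training support.
* **Defensive proposals.** Rounds after the first draw 80% of samples
  from the truncated intermediate posterior and 20% from the prior, with
  the exact mixture density in the importance weights — the weighting
  keeps the estimate exact while preventing a biased intermediate
  posterior from starving later rounds of exploration.

# Extracellular fields and tissue inference

The degenerated retina is a cylinder (radius 2 mm, height 105 µm) under
a bath cylinder (height 2 mm); disk electrodes (diameter 30 µm, pitch
70 µm) sit on the bottom face, the grounded return is the bath top, and
all other boundaries insulate. The quasi-static potential solves
`∇·((σ + i2πf ε ε₀)∇V) = 0` with uniform normal current density on the
disk. The solver is a cell-centered finite-volume discretization on a
graded axisymmetric (r, z) grid — the layer interface and the disk edge
are always cell faces, so each cell holds one material and fluxes use
exact series conductances; complex systems are solved as a 2N real
block system. Finite-volume telescoping makes the current through every
horizontal plane equal the injected current to solver precision. Grid
presets: `coarse` (~0.6 k cells, for sampling-heavy inference),
`default` (~1.4 k), `fine` (~5 k, ≤0.6% on-axis error against the
half-space closed form `V(z) = (j/σ)(√(a²+z²)−z)`).

Multi-electrode fields superpose laterally shifted single-disk
solutions, each carrying an equal current share; this is exact for
fixed-current sources in a homogeneous half space and neglects only the
interaction with the distant outer wall (quantified against an analytic
half-space superposition oracle at ≤5%). Broadband pulses are
synthesized from the DC solve plus harmonics of the stimulation window
(default 10–16 harmonics), giving each compartment a complex
transfer value per harmonic; the time-domain extracellular voltage per
compartment then feeds the cable model's `Vex` terms.

Electrode characterization models the electrode (double layer plus
parasitics) as a parallel RC: sinusoid fits by quadrature projection
give the impedance phase and magnitude, and
`Re = |Z|√(1+tan²φ)`, `Ce = −tanφ/(2πf·Re)` invert the parallel-RC
impedance exactly. Tissue inference minimizes the summed squared error
between simulated and target currents through the series
electrode-RC/cylinder circuit in two stages: first over exponents
(`σ = 2^p·0.1` S/m, `ε = 2^p·10⁶`, Gaussian priors mean 1, sd 2, three
50-sample rounds), then over a linear box spanned by the best 10% of
stage-1 samples with truncated-normal priors in normalized space. The
lowest-discrepancy sample is reported.

# Stimulus design

Stimulation currents are natural cubic splines through seven
equidistant knots over 40 ms, `(0, p1…p4, p*, 0)`: the spline is linear
in its knots, so the balancing knot `p*` solves the charge-neutrality
constraint exactly on the sample grid (the suite checks |∫i| below
10⁻¹² of the absolute charge over a thousand random draws), and the
waveform is normalized to a 0.5 µA peak. Natural end conditions are the
default and are recorded with the stimulus. The response metric is the
relative release `Rn = (µ(r) − µ(r_base))Δt / (vRRPmax +
(rmsr − µ(r_base))Δt)` over a 60 ms window from stimulus onset, with
the base rate measured from an unstimulated 60 ms run of the settled
cell; selectivity is the ratio of the non-target to target cell's
relative release (non-responding targets are assigned a declared 10⁶
worst case). Optimization draws 400 knot vectors from zero-mean
Gaussian priors (sd 0.3), reuses them for both target assignments,
trains a two-component untruncated mixture per target and evaluates 100
posterior draws, ranking all stimuli by their selectivity ratio. The
threshold sweep tabulates mean vesicles released per synapse (relative
to pool capacity) across electrode layouts, lateral positions and pulse
amplitudes at 33.5 °C with photoreceptor input removed.

# The synthetic-data generators

The generators define the study conditions: a 30 s chirp (3 s baseline,
3 s bright step, 8 s frequency sweep 0.5→8 Hz, 8 s contrast ramp at
2 Hz, rests between; 500 Hz sampling to match upsampled imaging traces;
optional weak rectification below 20% intensity for the BC stimulus
variant); calibration of intensity to 10–31 × 10³ P*/s with optional
sigmoid-plus-delay correction against a recorded copy; targets built by
simulating a seeded ground truth, convolving with the fluorescence
kernel, applying an arbitrary positive affine map and adding white
Gaussian noise at 10% of trace range (placing the trace-discrepancy
noise floor near 0.1–0.2, the order of good fits); and sinusoidal
electrode recordings (25 Hz at 100–600 mV, 40 Hz at half amplitude)
through a known RC electrode and the cylinder admittance, with optional
noise and second-harmonic skew. A deterministic branched SWC generator
(≥ 100 nodes) stands in for electron-microscopy reconstructions in the
morphology tests.

What the generators deliberately do not emulate: imaging photophysics
beyond the exponential kernel, scan artifacts, amacrine network
feedback, channel noise and stochastic vesicle fusion, and the exact
published chirp timing (configurable, not claimed). Passing the bundled
tests therefore demonstrates that the pipeline recovers what it models
under its own stated conditions — not that the surrogate channel
kinetics reproduce any particular published cell.

# Bundled experiments and problem sizes

The recovery experiments draw the ground truth from the prior per seed,
so repeated seeds probe calibration. The passive experiment (Rm, Cm of
a four-compartment chain; somatic voltage observable; 1-D summary) runs
2 rounds × 200 samples on a 6 s compressed chirp at 0.2 ms steps. The
bipolar-like experiment (CaL and KV densities, release gain, pool
capacity; full seven-component summary) runs 2 rounds × 250 samples on
a 4 s compressed chirp at 0.1 ms steps; a third round was measured to
over-contract the posterior at these sample counts without improving the
best-sample fit, and the bundled default stops at two (the best sampled
discrepancy already sits at the analytic noise floor). Measured over
ten seeds, the passive experiment covered 20/20 parameters and the
bipolar-like toy 34/40 (85%) with 90% marginal credible intervals, with
posterior variance below prior variance in every dimension. Tissue
inference and the selectivity optimizer run on the `coarse` field grid;
analytic field comparisons use `fine`.

# Known limitations

* Surrogate channel kinetics match activation ranges and signs, not any
  specific published state table; inferences about individual channel
  densities are internally consistent but not transferable to real
  cells without replacing the surrogates.
* The single-Gaussian default posterior cannot represent multimodality;
  the mixture head exists but is reserved for low-dimensional searches.
* Superposed array fields ignore electrode-wall interactions, and the
  lumped circuit treats the electrode RC as frequency- and
  amplitude-specific table entries.
* The area-based axial-resistance convention is kept for fidelity to
  the source's compartment description; absolute axial resistances are
  therefore not comparable to cross-section-based cable solvers.
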