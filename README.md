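# retinasim

Biophysical multicompartment models of mouse retinal cone photoreceptors
and cone bipolar cells, Bayesian simulation-based inference of their
parameters from glutamate-imaging-style traces, and a quasi-static
extracellular field model for designing selective electrical stimuli for
retinal prosthetics.

## Who this is for

Computational neuroscientists who want to (i) simulate cable models of
retinal neurons with ribbon-synapse release and Hodgkin–Huxley or Markov
channel kinetics, (ii) fit such models to fluorescence glutamate
reporter (iGluSnFR) traces with likelihood-free sequential neural
posterior estimation (SNPE), and (iii) simulate and optimize subretinal
micro-electrode stimulation of bipolar cells.

## The models in brief

**Cable model.** Compartment `n` follows

    cm_n dVm/dt = sum_j (Vm_j - Vm_n)/(ri_j + ri_n)
                + (Vr + Vex_n - Vm_n)/rm_n
                + sum_e ge (Ve + Vex_n - Vm_n) + i_inj + cm_n dVex_n/dt

with `rm = Rm/Am`, `cm = Cm·Am`, `ri = Ri·lc/Am`. Channels are HH gates
(`ge = c^p·gmax`, rates with Q10 temperature correction and estimable
ΔV/τ modifiers) or Markov occupancy vectors. Release at ribbon synapses
is `r = [Ca]0² (vRRP/vRRPmax) gl` vesicles/s with the readily releasable
pool replenished at the maximum sustainable rate.

**Inference.** Truncated-normal priors over a normalized unit box;
per-round adaptive Gaussian summary kernels; a conditional-Gaussian
density head trained on kernel- and importance-weighted samples;
boundary evaluation and truncation to the prior box. The summary is the
seven-component discrepancy vector: an affine-invariant trace distance
(release convolved with a 60 ms exponential iGluSnFR kernel) plus six
signed bounded penalties on resting and evoked release and membrane
potential.

**Electrical stimulation.** An axisymmetric finite-volume solver for
`∇·((σ + i2πf εε₀)∇V) = 0` in a layered retina/bath cylinder with disk
electrodes; electrode RC characterization from sinusoid fits
(`Re = |Z|√(1+tan²φ)`, `Ce = −tanφ/(2πf Re)`); two-stage inference of
retinal conductivity and permittivity; charge-neutral 40 ms cubic-spline
stimuli optimized for OFF- versus ON-bipolar-cell selectivity via the
same inference engine.

## Worked example

Simulate the bundled cone under a chirp light stimulus and score it
against a synthetic fluorescence target:

```r
library(retinasim)

ch   <- make_chirp(chirp_spec())                 # 30 s chirp, 500 Hz
rate <- calibrate_stimulus(ch$y, dt = ch$dt)$rate # 10-31 x 10^3 P*/s

cone  <- build_cone_cell()
dt    <- 5e-5
drive <- list(i_inj = list(list(
  comp = 2, trace = photocurrent(
    approx(ch$t, rate, xout = seq(0, max(ch$t), by = dt), rule = 2)$y,
    cone$photo, dt))))

st  <- settle_cell(cone$cell, drive = list(i_inj = list(list(
        comp = 2, trace = drive$i_inj[[1]]$trace[1]))), dt = dt)
sim <- simulate_cell(cone$cell, drive, dt = dt,
                     t_end = (length(drive$i_inj[[1]]$trace) - 1) * dt,
                     record_dt = ch$dt, init = st$init)

target <- generate_target(colMeans(sim$rate), ch$dt, seed = 1)$target
dv <- discrepancy_vector(colMeans(sim$rate), sim$Vm[cone$cell$soma, ],
                         target, list(rate_rest = st$rate_rest,
                                      v_rest = st$v_rest),
                         default_penalty_bounds("cone"), ch$dt)
print(dv)
#> <discrepancy_vector> total: 0.314
#> delta_iglusnfr      rate_rest         v_rest     rate_delta        v_delta
#>      0.3139529      0.0000000      0.0000000      0.0000000      0.0000000
#>          v_min          v_max
#>      0.0000000      0.0000000
```

The only nonzero component is the trace distance, which sits at the
target's analytic noise floor (0.311 for this target, generated with 10%
additive noise); the cone's resting release (52 ves/s), resting
potential (-54.8 mV), response amplitudes and voltage extremes all fall
inside their plausible-physiology bounds, so the six penalties are
exactly zero.

A complete parameter-recovery experiment — generate a seeded ground
truth, fit it with two rounds of inference, and report credible-interval
coverage:

```r
rep <- recovery_experiment("passive", seed = 1)
print(rep)
#> <recovery_report> passive cell, 2 x 200 samples (seed 1)
#>   coverage: 2/2 params in 90% CIs; best delta 0.154 (noise floor 0.157)
```

Both membrane parameters lie inside their 90% marginal credible
intervals and the best sampled trace discrepancy (0.154) reaches the
analytic noise floor of the synthetic target (0.157).

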