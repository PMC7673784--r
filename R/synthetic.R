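# ---------------------------------------------------------------------------
# Chirp light stimuli
# ---------------------------------------------------------------------------

#' Chirp stimulus specification
#'
#' A full-field chirp: baseline, a bright step, a frequency sweep
#' (accelerating sinusoid) and a contrast sweep (amplitude-ramped
#' sinusoid at fixed frequency), with rest periods in between. Intensities
#' are normalized to `[0, 1]`. The exact published waveform parameters
#' are not fixed by the recordings themselves, so every segment is
#' configurable; the defaults give a 30 s stimulus of the published
#' class.
#'
#' @param baseline_s,step_s,rest1_s,fsweep_s,rest2_s,csweep_s,rest3_s
#'   segment durations, s.
#' @param f0,f1 frequency sweep range, Hz.
#' @param c_freq contrast-sweep carrier frequency, Hz.
#' @param base_level,amp baseline intensity and modulation amplitude.
#' @param dt sample interval, s (1/500 s, matching upsampled imaging
#'   traces).
#' @param rectify weakly rectify intensities below 0.2 (the
#'   non-linearized bipolar-cell stimulus variant)?
#' @return a `chirp_spec`.
#' @export
chirp_spec <- function(baseline_s = 3, step_s = 3, rest1_s = 2,
                       fsweep_s = 8, f0 = 0.5, f1 = 8, rest2_s = 2,
                       csweep_s = 8, c_freq = 2, rest3_s = 4,
                       base_level = 0.5, amp = 0.4, dt = 1 / 500,
                       rectify = FALSE) {
  structure(as.list(environment()), class = "chirp_spec")
}

#' Generate a chirp light stimulus
#'
#' @param spec a [chirp_spec()].
#' @return list with `t` (s), `y` (intensity in `[0, 1]`), `dt` and the
#'   spec.
#' @export
make_chirp <- function(spec = chirp_spec()) {
  dt <- spec$dt
  seg <- function(dur, f) {
    n <- round(dur / dt)
    tt <- (seq_len(n) - 1) * dt
    f(tt)
  }
  b <- spec$base_level; a <- spec$amp
  y <- c(
    seg(spec$baseline_s, function(tt) rep(b, length(tt))),
    seg(spec$step_s, function(tt) rep(1, length(tt))),
    seg(spec$rest1_s, function(tt) rep(b, length(tt))),
    seg(spec$fsweep_s, function(tt) {
      # linearly increasing instantaneous frequency f0 -> f1
      phase <- 2 * pi * (spec$f0 * tt +
                           (spec$f1 - spec$f0) * tt^2 / (2 * spec$fsweep_s))
      b + a * sin(phase)
    }),
    seg(spec$rest2_s, function(tt) rep(b, length(tt))),
    seg(spec$csweep_s, function(tt) {
      ramp <- tt / spec$csweep_s
      b + a * ramp * sin(2 * pi * spec$c_freq * tt)
    }),
    seg(spec$rest3_s, function(tt) rep(b, length(tt))))
  y <- pmin(pmax(y, 0), 1)
  if (spec$rectify) {
    lo <- y < 0.2
    y[lo] <- 0.2 - (0.2 - y[lo]) * 0.5   # weak rectification below 20%
  }
  list(t = (seq_along(y) - 1) * dt, y = y, dt = dt, spec = spec)
}

#' Calibrate a digital stimulus to photon absorption rates
#'
#' Optionally corrects timing and amplitude of the digital stimulus
#' against a recorded copy (delay by grid search, amplitude by a fitted
#' sigmoid), then maps normalized intensity linearly to photon absorption
#' rates: 10 x 10^3 P*/s per cone at intensity 0 and 31 x 10^3 at
#' intensity 1 (background included).
#'
#' @param digital normalized digital stimulus trace in `[0, 1]`.
#' @param recorded optional recorded stimulus trace (same grid) to
#'   calibrate against.
#' @param dt sample interval, s.
#' @param rate_range photon-rate range `c(low, high)`, P*/s per cone.
#' @param max_shift_s maximum timing correction, s.
#' @return list with `rate` (P*/s trace), `shift_s`, `sigmoid`
#'   (`NULL` without a recording) and `corrected` (the corrected
#'   normalized stimulus).
#' @export
calibrate_stimulus <- function(digital, recorded = NULL, dt,
                               rate_range = c(10e3, 31e3),
                               max_shift_s = 0.1) {
  corrected <- digital
  shift <- 0L
  sig <- NULL
  if (!is.null(recorded)) {
    max_k <- round(max_shift_s / dt)
    shifts <- -max_k:max_k
    sse_at <- function(k, par) {
      d <- .shift_trace(digital, k)
      s <- 1 / (1 + exp(-par[1] * (d - par[2])))
      sum((recorded - s)^2)
    }
    best <- Inf; best_k <- 0L; best_par <- c(8, 0.5)
    for (k in shifts) {
      opt <- stats::optim(best_par, function(p) sse_at(k, p),
                          method = "Nelder-Mead")
      if (opt$value < best) { best <- opt$value; best_k <- k; best_par <- opt$par }
    }
    if (!is.finite(best)) stop("stimulus calibration failed to converge")
    shift <- best_k
    sig <- list(k = best_par[1], x0 = best_par[2], sse = best)
    corrected <- 1 / (1 + exp(-sig$k * (.shift_trace(digital, shift) - sig$x0)))
  }
  rate <- rate_range[1] + (rate_range[2] - rate_range[1]) * corrected
  list(rate = rate, shift_s = shift * dt, sigmoid = sig,
       corrected = corrected)
}

.shift_trace <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  if (k > 0) c(rep(x[1], k), x[seq_len(n - k)])
  else c(x[(-k + 1):n], rep(x[n], -k))
}

#' Align traces by shift and average
#'
#' Each trace is aligned to the first by the integer-sample shift that
#' minimizes the mean squared error (grid search within a window); the
#' mean of the aligned traces is returned.
#'
#' @param traces list of numeric traces on a common grid (>= 2).
#' @param max_shift maximum shift in samples.
#' @return list with `mean` (aligned mean trace), `shifts` (samples,
#'   per trace).
#' @export
align_mean_traces <- function(traces, max_shift = 50) {
  if (length(traces) < 2) stop("need at least 2 traces")
  ref <- traces[[1]]
  n <- length(ref)
  shifts <- integer(length(traces))
  aligned <- list(ref)
  for (i in 2:length(traces)) {
    x <- traces[[i]]
    if (length(x) != n) stop("traces must share a common grid")
    sse <- vapply(-max_shift:max_shift, function(k) {
      idx <- max(1, 1 + k):min(n, n + k)
      mean((ref[idx] - x[idx - k])^2)
    }, numeric(1))
    k <- (-max_shift:max_shift)[which.min(sse)]
    shifts[i] <- k
    aligned[[i]] <- .shift_trace(x, k)
  }
  keep <- (max_shift + 1):(n - max_shift)
  if (!length(keep)) stop("empty overlap after shifting")
  m <- rowMeans(do.call(cbind, lapply(aligned, function(x) x[keep])))
  full <- rowMeans(do.call(cbind, aligned))
  list(mean = full, mean_overlap = m, shifts = shifts)
}

# ---------------------------------------------------------------------------
# Built-in ground-truth cells
# ---------------------------------------------------------------------------

# small linear chain morphology used by the passive recovery toy
.passive_chain_morphology <- function(n_seg = 3) {
  nodes <- data.frame(
    id = seq_len(n_seg + 1), parent = c(-1, seq_len(n_seg)),
    x = c(0, cumsum(rep(20, n_seg))), y = 0, z = 0,
    radius = c(4, rep(0.75, n_seg)), type = c(1, rep(3, n_seg)))
  m <- morphology(nodes, source = "synthetic passive chain")
  m$nodes$region <- c("S", rep("PD", n_seg))
  m
}

#' Passive toy cell for parameter recovery
#'
#' A four-compartment passive chain (spherical soma plus three dendritic
#' segments) whose free parameters are the specific membrane resistance
#' and capacitance. Current is injected at the distal tip; the somatic
#' voltage is the observable.
#'
#' @param Rm specific membrane resistance, Ohm cm^2.
#' @param Cm specific membrane capacitance, uF/cm^2.
#' @return list with the `cell_model` and its `compartments`.
#' @export
toy_passive_cell <- function(Rm = 1e4, Cm = 1) {
  m <- .passive_chain_morphology()
  cp <- compartmentalize(m, membrane_spec(Rm = Rm, Cm = Cm, Ri = 132,
                                          Vr = -60))
  list(cell = cell_model(cp, soma = 1, tsim = 37), comps = cp)
}

# four-compartment bipolar-like morphology (dendrite - soma - axon - terminal)
.bc_toy_morphology <- function() {
  nodes <- data.frame(
    id = 1:4, parent = c(2, -1, 2, 3),
    x = 0, y = 0,
    z = c(-12, 0, 18, 30),
    radius = c(0.75, 3, 0.6, 1.5), type = c(3, 1, 2, 2))
  m <- morphology(nodes, source = "synthetic BC toy")
  m$nodes$region <- c("PD", "S", "PA", "AT")
  m
}

#' Bipolar-like toy cell with calcium-driven ribbon release
#'
#' A four-compartment cell (dendrite, soma, axon, terminal) with an
#' L-type calcium channel plus calcium store and ribbon synapse at the
#' terminal and a delayed-rectifier potassium channel at the soma. Driven
#' through a kainate-type synaptic conductance on the dendrite. The four
#' free parameters of the bundled recovery experiment are the two channel
#' densities, the release gain and the pool capacity.
#'
#' @param g_cal CaL conductance density at the terminal, mS/cm^2.
#' @param g_kv KV conductance density at the soma, mS/cm^2.
#' @param gl ribbon release gain.
#' @param vmax_pool readily-releasable-pool capacity, vesicles.
#' @param Rm,Cm,Vr passive membrane parameters.
#' @param tsim temperature, degrees C.
#' @return list with the `cell_model` and its `compartments`.
#' @export
toy_bc_cell <- function(g_cal = 3, g_kv = 1, gl = 30, vmax_pool = 12,
                        Rm = 2e4, Cm = 1, Vr = -55, tsim = 37) {
  m <- .bc_toy_morphology()
  cp <- compartmentalize(m, membrane_spec(Rm = Rm, Cm = Cm, Ri = 132,
                                          Vr = Vr))
  cell <- cell_model(cp, soma = 2, tsim = tsim)
  cell <- add_channel(cell, cal_channel(), "AT", g_cal)
  cell <- add_channel(cell, kv_channel(), "S", g_kv)
  cell <- add_calcium_store(cell, "AT",
                            calcium_store(ca_rest = 0.08, capk = 2,
                                          vmax = 60, kappa = 2.5e14))
  cell <- add_ribbon(cell, "AT",
                     ribbon_synapse(vmax_pool = vmax_pool, gl = gl,
                                    rmsr = 8))
  list(cell = cell, comps = cp)
}

#' Default biophysical cone cell
#'
#' The four-compartment cone (see [cone_morphology()]) with an L-type
#' calcium channel, calcium store and ribbon synapse (replenishment 100
#' vesicles/s) at the axon terminal, HCN current in inner segment and
#' axon, and a delayed rectifier at the inner segment. Driven by the
#' phototransduction surrogate current into the inner segment.
#'
#' @param g_cal,g_hcn,g_kv conductance densities, mS/cm^2.
#' @param gl,vmax_pool ribbon parameters.
#' @param Rm,Cm,Vr passive membrane parameters.
#' @param tsim temperature, degrees C.
#' @return list with the `cell_model`, its `compartments` and the
#'   [phototransduction()] spec.
#' @export
build_cone_cell <- function(g_cal = 4, g_hcn = 0.3, g_kv = 0.3, gl = 1250,
                            vmax_pool = 8, Rm = 1e4, Cm = 1, Vr = -34.5,
                            tsim = 37) {
  m <- cone_morphology()
  cp <- compartmentalize(m, membrane_spec(Rm = Rm, Cm = Cm, Ri = 132,
                                          Vr = Vr))
  cell <- cell_model(cp, soma = 2, tsim = tsim)
  cell <- add_channel(cell, cal_channel(), "AT", g_cal)
  cell <- add_channel(cell, hcn_channel(), c("IS/S", "A"), g_hcn)
  cell <- add_channel(cell, kv_channel(), "IS/S", g_kv)
  cell <- add_calcium_store(cell, "AT",
                            calcium_store(ca_rest = 0.1, capk = 2,
                                          vmax = 60, kappa = 3.6e14))
  cell <- add_ribbon(cell, "AT",
                     ribbon_synapse(vmax_pool = vmax_pool, gl = gl,
                                    rmsr = 100))
  list(cell = cell, comps = cp,
       photo = phototransduction(i_max = 30e-12, r50 = 60e3,
                                 adapt_strength = 1))
}

# ---------------------------------------------------------------------------
# Target generation
# ---------------------------------------------------------------------------

#' Generate a noisy fluorescence target from a ground-truth simulation
#'
#' Simulates the observable trace at the ground-truth parameters,
#' convolves release-type observables with the iGluSnFR kernel, applies
#' an arbitrary affine map (`b > 0`) and adds white Gaussian noise — the
#' three properties of relative-fluorescence imaging targets.
#'
#' @param trace the noise-free observable (release-rate or voltage
#'   trace) at the ground truth.
#' @param dt sample interval, s.
#' @param seed integer seed for the noise.
#' @param noise_sd noise standard deviation as a fraction of the trace
#'   range.
#' @param affine `c(a, b)` offset and positive scale.
#' @param convolve convolve with the iGluSnFR kernel first?
#' @return list with `target`, `noise_sd_abs`, `meta`.
#' @export
generate_target <- function(trace, dt, seed = 1L, noise_sd = 0.1,
                            affine = c(0, 1), convolve = TRUE) {
  if (affine[2] <= 0) stop("affine scale b must be > 0")
  nu <- if (convolve) iglusnfr_from_release(trace, dt) else trace
  rng <- diff(range(nu))
  if (rng == 0) stop("degenerate (constant) ground-truth trace")
  sd_abs <- noise_sd * rng
  set.seed(seed)
  target <- affine[1] + affine[2] * nu +
    stats::rnorm(length(nu), 0, affine[2] * sd_abs)
  list(target = target, noise_sd_abs = sd_abs,
       meta = list(seed = seed, noise_sd = noise_sd, affine = affine,
                   convolved = convolve))
}

#' Analytic noise floor of the trace discrepancy
#'
#' For a target generated as `b * (nu + noise)` the expected
#' affine-invariant discrepancy at the generating parameters is
#' `var(noise) / (var(nu) + var(noise))`.
#'
#' @param trace noise-free trace.
#' @param noise_sd_abs absolute noise standard deviation (on the trace
#'   scale).
#' @return expected discrepancy in `[0, 1]`.
#' @export
delta_noise_floor <- function(trace, noise_sd_abs) {
  v <- stats::var(trace)
  noise_sd_abs^2 / (v + noise_sd_abs^2)
}

# ---------------------------------------------------------------------------
# Synthetic electrode recordings
# ---------------------------------------------------------------------------

#' Synthetic sinusoidal electrode recordings
#'
#' Emulates the tissue-characterization protocol: sinusoidal stimulation
#' voltages at 25 Hz (amplitudes 100-600 mV) and 40 Hz (amplitudes
#' halved), driven through a known electrode RC into (i) the electrolyte
#' bath alone and (ii) the bath plus a retina with known conductivity and
#' permittivity. Currents come from the same layered-cylinder admittance
#' model used for inference; optional noise and a weak second harmonic
#' emulate recording imperfections. All outputs are labelled synthetic;
#' the generating circuit values are returned as ground truth.
#'
#' @param Re_el,Ce_el electrode resistance (Ohm) and capacitance (F).
#' @param sigma_star,eps_star ground-truth retina conductivity (S/m) and
#'   relative permittivity.
#' @param model_template a [retina_field_model()] (geometry and bath).
#' @param freqs stimulation frequencies, Hz.
#' @param amps_25 stimulus amplitudes at 25 Hz, V (halved at 40 Hz).
#' @param dt sample interval, s.
#' @param n_periods duration per trace in stimulus periods.
#' @param noise_sd current noise, as a fraction of each trace's
#'   amplitude.
#' @param skew relative amplitude of the second-harmonic distortion.
#' @param seed integer seed.
#' @return list with `recordings` (entries: `f`, `amp`, `vstim`,
#'   `i_ames`, `i_retina`, `dt`) and `truth`.
#' @export
make_synthetic_electrode_recordings <- function(Re_el = 1e6, Ce_el = 4e-9,
                                                sigma_star = 0.076,
                                                eps_star = 1.1e7,
                                                model_template = retina_field_model(),
                                                freqs = c(25, 40),
                                                amps_25 = seq(0.1, 0.6, by = 0.1),
                                                dt = 1e-4, n_periods = 5,
                                                noise_sd = 0, skew = 0,
                                                seed = 1L) {
  set.seed(seed)
  ames_model <- model_template
  ames_model$sigma_retina <- model_template$sigma_bath
  ames_model$eps_retina <- model_template$eps_bath
  ret_model <- model_template
  ret_model$sigma_retina <- sigma_star
  ret_model$eps_retina <- eps_star
  rec <- list()
  for (f in freqs) {
    Y_ames <- solve_field(ames_model, istim = 1e-6, frequency = f)$Y
    Y_ret <- solve_field(ret_model, istim = 1e-6, frequency = f)$Y
    Zel <- parallel_rc_impedance(Re_el, Ce_el, f)
    amps <- if (f == freqs[1]) amps_25 else amps_25 / 2
    for (A in amps) {
      t <- seq(0, n_periods / f, by = dt)
      vstim <- A * sin(2 * pi * f * t)
      mk_current <- function(Y) {
        Iph <- A / (Zel + 1 / Y)
        i <- Im(Iph * exp(1i * 2 * pi * f * t))
        if (skew > 0) i <- i + skew * Mod(Iph) * sin(4 * pi * f * t)
        if (noise_sd > 0) i <- i + stats::rnorm(length(i), 0,
                                                noise_sd * Mod(Iph))
        i
      }
      rec[[length(rec) + 1]] <- list(
        f = f, amp = A, vstim = vstim,
        i_ames = mk_current(Y_ames), i_retina = mk_current(Y_ret), dt = dt)
    }
  }
  list(recordings = rec,
       truth = list(Re = Re_el, Ce = Ce_el, sigma_retina = sigma_star,
                    eps_retina = eps_star))
}

# ---------------------------------------------------------------------------
# Synthetic branched bipolar-cell morphology (SWC fixture)
# ---------------------------------------------------------------------------

#' Synthetic branched bipolar-cell-like morphology
#'
#' A deterministic (seeded) skeleton with a soma, a branched dendritic
#' tree below and a branched axon with terminal boutons above, with
#' >= 100 nodes — a stand-in for electron-microscopy reconstructions,
#' used as an SWC I/O and condensation fixture.
#'
#' @param seed integer seed for the positional jitter.
#' @param step_um skeleton sampling step, um.
#' @return a [morphology()].
#' @export
synthetic_bc_morphology <- function(seed = 1L, step_um = 0.8) {
  set.seed(seed)
  nodes <- data.frame(id = 1, parent = -1, x = 0, y = 0, z = 0,
                      radius = 3.5, type = 1)
  nid <- 1L
  grow <- function(nodes, from, dir, len, radius, type, n_branch = 0,
                   branch_len = 0) {
    n_step <- max(2L, round(len / step_um))
    parent <- from
    for (s in seq_len(n_step)) {
      nid <<- nid + 1L
      p <- nodes[nodes$id == parent, ]
      jit <- stats::rnorm(3, 0, 0.15)
      nodes <- rbind(nodes, data.frame(
        id = nid, parent = parent,
        x = p$x + dir[1] * step_um + jit[1],
        y = p$y + dir[2] * step_um + jit[2],
        z = p$z + dir[3] * step_um + jit[3],
        radius = radius, type = type))
      parent <- nid
    }
    attr(nodes, "tip") <- parent
    nodes
  }
  # two primary dendrites going down, each bifurcating once
  for (ang in c(0.5, 2.6)) {
    dir <- c(cos(ang) * 0.5, sin(ang) * 0.5, -0.85)
    nodes <- grow(nodes, 1L, dir, 10, 0.7, 3)
    tip <- attr(nodes, "tip")
    for (da in c(-0.8, 0.8)) {
      dir2 <- c(cos(ang + da) * 0.6, sin(ang + da) * 0.6, -0.7)
      nodes <- grow(nodes, tip, dir2, 8, 0.5, 3)
    }
  }
  # axon going up with two terminal branches carrying boutons
  nodes <- grow(nodes, 1L, c(0.05, -0.05, 1), 30, 0.6, 2)
  axon_tip <- attr(nodes, "tip")
  for (da in c(-1, 1)) {
    nodes <- grow(nodes, axon_tip, c(0.7 * da, 0.2, 0.5), 10, 0.9, 2)
  }
  morphology(nodes, source = sprintf("synthetic BC (seed %d)", seed))
}

# ---------------------------------------------------------------------------
# Recovery experiments
# ---------------------------------------------------------------------------

#' Seeded parameter-recovery experiment
#'
#' Builds a reduced ground-truth cell, generates a noisy synthetic
#' target, runs multi-round posterior estimation and reports
#' credible-interval coverage of the ground truth, posterior contraction
#' and the best sampled discrepancies. The ground truth is drawn from the
#' prior (seeded), so repeated runs probe calibration.
#'
#' @param cell_class `"passive"` (2 parameters: Rm, Cm; somatic voltage
#'   observable, 1-D summary) or `"bc_toy"` (4 parameters: CaL and KV
#'   densities, release gain, pool capacity; release observable with the
#'   full seven-component discrepancy summary).
#' @param rounds,n_per_round inference schedule (defaults: 2 x 200 for
#'   the passive cell, 2 x 250 for the bipolar-like toy).
#' @param seed integer seed controlling ground truth, noise and
#'   inference.
#' @param noise_sd target noise as a fraction of trace range.
#' @param stim_duration_s chirp duration used for the recovery stimulus
#'   (a compressed chirp keeps the experiment desk-scale; defaults: 6 s
#'   for the passive cell, 4 s for the bipolar-like toy).
#' @param ci_level credible level for coverage.
#' @param hidden,epochs network settings.
#' @return a `recovery_report` list.
#' @export
recovery_experiment <- function(cell_class = c("passive", "bc_toy"),
                                rounds = NULL, n_per_round = NULL,
                                seed = 1L, noise_sd = 0.1,
                                stim_duration_s = NULL, ci_level = 0.9,
                                hidden = c(30, 30), epochs = 500) {
  cell_class <- match.arg(cell_class)
  if (is.null(rounds)) rounds <- 2
  if (is.null(n_per_round)) {
    n_per_round <- if (cell_class == "passive") 200 else 250
  }
  if (is.null(stim_duration_s)) {
    stim_duration_s <- if (cell_class == "passive") 6 else 4
  }
  sc <- stim_duration_s / 30
  cs <- chirp_spec(baseline_s = 3 * sc, step_s = 3 * sc, rest1_s = 2 * sc,
                   fsweep_s = 8 * sc, rest2_s = 2 * sc, csweep_s = 8 * sc,
                   rest3_s = 4 * sc, f1 = 8)
  chirp <- make_chirp(cs)

  if (cell_class == "passive") {
    prior <- tn_prior(mean = c(1.2e4, 1.1), lower = c(3e3, 0.5),
                      upper = c(3e4, 2.0), names = c("Rm", "Cm"))
    dt_sim <- 2e-4
    drive_tr <- stats::approx(chirp$t, (chirp$y - 0.5) * 40e-12,
                              xout = seq(0, max(chirp$t), by = dt_sim),
                              rule = 2)$y
    observe <- function(theta) {
      tc <- toy_passive_cell(Rm = theta[1], Cm = theta[2])
      tip <- nrow(tc$comps)
      drive <- list(i_inj = list(list(comp = tc$comps$id[tip],
                                      trace = drive_tr)))
      st <- settle_cell(tc$cell, drive = list(
        i_inj = list(list(comp = tc$comps$id[tip], trace = drive_tr[1]))),
        t_settle = 0.5, dt = dt_sim)
      sim <- simulate_cell(tc$cell, drive, dt = dt_sim,
                           t_end = (length(drive_tr) - 1) * dt_sim,
                           record_dt = chirp$dt, init = st$init)
      list(trace = sim$Vm[tc$cell$soma, ], status = sim$status)
    }
    set.seed(seed)
    theta_star <- as.numeric(sample_truncated(prior, 1, seed = seed + 17L))
    obs <- observe(theta_star)
    tg <- generate_target(obs$trace, chirp$dt, seed = seed + 31L,
                          noise_sd = noise_sd, convolve = FALSE)
    simulator <- function(u) {
      theta <- as.numeric(denormalize_params(u, prior))
      o <- observe(theta)
      if (o$status != "ok") return(list(summary = NA_real_, valid = FALSE))
      list(summary = delta_iglusnfr(tg$target, o$trace), valid = TRUE)
    }
  } else {
    prior <- tn_prior(mean = c(3, 1, 30, 12), lower = c(0.5, 0, 5, 4),
                      upper = c(8, 4, 80, 25),
                      names = c("g_cal", "g_kv", "gl", "vmax_pool"))
    dt_sim <- 1e-4
    # presynaptic (cone-like) release falls with light: OFF pathway drive
    glu <- 60 * pmax(0, 1 - 2.2 * (chirp$y - 0.5))
    rec <- postsynaptic_receptor("kainate", stc = 1)
    open <- receptor_drive(glu, rec, chirp$dt)
    # drive scaled to the toy's gigaohm-range input resistance so light
    # modulates the soma by ~5-15 mV around rest
    g_tr <- stats::approx(chirp$t, open * 0.3e-9,
                          xout = seq(0, max(chirp$t), by = dt_sim),
                          rule = 2)$y
    bounds <- default_penalty_bounds("off_bc")
    observe <- function(theta) {
      tc <- toy_bc_cell(g_cal = theta[1], g_kv = theta[2], gl = theta[3],
                        vmax_pool = theta[4])
      drive <- list(g_syn = list(list(comp = 1, erev = 0, trace = g_tr)))
      st <- settle_cell(tc$cell, drive = list(
        g_syn = list(list(comp = 1, erev = 0, trace = g_tr[1]))),
        t_settle = 1, dt = dt_sim)
      if (st$status != "ok") return(list(status = st$status))
      sim <- simulate_cell(tc$cell, drive, dt = dt_sim,
                           t_end = (length(g_tr) - 1) * dt_sim,
                           record_dt = chirp$dt, init = st$init)
      list(release = colMeans(sim$rate), v = sim$Vm[tc$cell$soma, ],
           rest = list(rate_rest = st$rate_rest, v_rest = st$v_rest),
           status = sim$status)
    }
    set.seed(seed)
    theta_star <- as.numeric(sample_truncated(prior, 1, seed = seed + 17L))
    obs <- observe(theta_star)
    if (obs$status != "ok") stop("ground-truth simulation invalid")
    tg <- generate_target(obs$release, chirp$dt, seed = seed + 31L,
                          noise_sd = noise_sd, convolve = TRUE)
    simulator <- function(u) {
      theta <- as.numeric(denormalize_params(u, prior))
      o <- observe(theta)
      if (o$status != "ok") return(list(summary = rep(NA_real_, 7),
                                        valid = FALSE))
      dv <- discrepancy_vector(o$release, o$v, tg$target, o$rest, bounds,
                               chirp$dt)
      list(summary = as.numeric(dv), valid = TRUE)
    }
  }

  np <- normalized_prior(prior)
  inf <- run_inference(simulator, np, rounds = rounds,
                       n_per_round = n_per_round, seed = seed,
                       x_target = "adaptive", kernel = "adaptive",
                       hidden = hidden, epochs = epochs)
  u_star <- as.numeric(normalize_params(theta_star, prior))
  ci <- posterior_ci(inf$posterior, level = ci_level, seed = seed + 5L)
  covered <- u_star >= ci[, 1] & u_star <= ci[, 2]
  pvar <- posterior_var(inf$posterior, seed = seed + 6L)
  prior_var <- apply(sample_truncated(np, 4000, seed = seed + 7L), 2,
                     stats::var)
  best <- min(unlist(lapply(inf$records,
                            function(r) min(r$summaries[r$valid, 1]))))
  structure(list(
    cell_class = cell_class, seed = seed,
    theta_star = theta_star, u_star = u_star,
    ci = ci, covered = covered,
    posterior_var = pvar, prior_var = prior_var,
    contraction = pvar / prior_var,
    best_delta = best,
    noise_floor = delta_noise_floor(
      if (cell_class == "passive") obs$trace
      else iglusnfr_from_release(obs$release, chirp$dt),
      tg$noise_sd_abs),
    posterior = inf$posterior,
    n_rounds = rounds, n_per_round = n_per_round),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %s cell, %d x %d samples (seed %d)\n",
              x$cell_class, x$n_rounds, x$n_per_round, x$seed))
  cat(sprintf("  coverage: %d/%d params in %s CIs; best delta %.3g (noise floor %.3g)\n",
              sum(x$covered), length(x$covered), "90%",
              x$best_delta, x$noise_floor))
  invisible(x)
}
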