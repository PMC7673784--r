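# ---------------------------------------------------------------------------
# Temperature correction and Hodgkin-Huxley rate machinery
# ---------------------------------------------------------------------------

#' Temperature correction factor for kinetic rates
#'
#' Rates defined at a reference temperature `Teq` are scaled by
#' `exp(log(Q10) * (Tsim - Teq) / 10)` to the simulation temperature.
#'
#' @param q10 temperature sensitivity (factor per 10 K), > 0.
#' @param tsim simulation temperature, degrees C.
#' @param teq reference temperature of the rate equations, degrees C.
#' @return dimensionless scaling factor.
#' @export
eta_t <- function(q10, tsim, teq) {
  if (any(q10 <= 0)) stop("q10 must be > 0")
  exp(log(q10) * (tsim - teq) / 10)
}

#' Hodgkin-Huxley gate specification
#'
#' A gate is described by voltage-dependent opening/closing rates
#' `alpha(V)`, `beta(V)` (1/ms, V in mV) raised to an integer power in the
#' conductance. Kinetics can be modified by voltage offsets `dVa`, `dVb`
#' (mV) and relative time constants `tau_a`, `tau_b`, giving
#' `dc/dt = (1-c) * alpha(V - dVa)/tau_a - c * beta(V - dVb)/tau_b`,
#' everything scaled by the temperature factor [eta_t()].
#'
#' @param power integer exponent of the gate in the conductance.
#' @param alpha,beta functions of voltage (mV) returning rates in 1/ms.
#' @param dVa,dVb voltage offsets (mV) applied to the rate arguments.
#' @param tau_a,tau_b dimensionless relative time constants (> 0).
#' @param ca_input if `TRUE` the gate is driven by the local first-shell
#'   calcium concentration (uM) instead of voltage.
#' @return an `hh_gate` object.
#' @export
hh_gate <- function(power, alpha, beta, dVa = 0, dVb = 0,
                    tau_a = 1, tau_b = 1, ca_input = FALSE) {
  if (tau_a <= 0 || tau_b <= 0) stop("tau_a and tau_b must be > 0")
  structure(list(power = as.integer(power), alpha = alpha, beta = beta,
                 dVa = dVa, dVb = dVb, tau_a = tau_a, tau_b = tau_b,
                 ca_input = ca_input),
            class = "hh_gate")
}

#' Evaluate modified gate rates
#'
#' Applies the voltage offsets, relative time constants and temperature
#' scaling of a gate at one or more voltages.
#'
#' @param v voltage(s), mV (or calcium, uM, for calcium-driven gates).
#' @param gate an [hh_gate()].
#' @param tsim simulation temperature, degrees C.
#' @param q10 temperature sensitivity.
#' @param teq reference temperature, degrees C.
#' @return list with components `alpha` and `beta` in 1/ms.
#' @export
cal_rates <- function(v, gate, tsim = 37, q10 = 2, teq = 22) {
  eta <- eta_t(q10, tsim, teq)
  list(alpha = eta * gate$alpha(v - gate$dVa) / gate$tau_a,
       beta  = eta * gate$beta(v - gate$dVb) / gate$tau_b)
}

# x / (exp(x) - 1) with its removable singularity at x = 0
.expm1_ratio <- function(x) {
  out <- ifelse(abs(x) < 1e-6, 1 - x / 2 + x^2 / 12, x / expm1(x))
  out
}

#' L-type calcium channel activation rates
#'
#' The base rate functions of the L-type calcium channel gate:
#' `alpha(V) = -0.04 (V + 15) / (exp(-0.04 (V + 15)) - 1)` and
#' `beta(V) = 5 exp(-(V + 38) / 18)`, both in 1/ms with V in mV. The
#' removable singularity of `alpha` at V = -15 mV takes its analytic
#' limit of 1/ms.
#'
#' @param v voltage(s), mV.
#' @return rate in 1/ms.
#' @name cal_channel_rates
NULL

#' @rdname cal_channel_rates
#' @export
cal_alpha <- function(v) {
  u <- -0.04 * (v + 15)
  .expm1_ratio(u)
}

#' @rdname cal_channel_rates
#' @export
cal_beta <- function(v) 5 * exp(-(v + 38) / 18)

# ---------------------------------------------------------------------------
# Channel specifications
# ---------------------------------------------------------------------------

#' Hodgkin-Huxley channel specification
#'
#' @param name channel family name (e.g. "CaL", "KV").
#' @param gates list of [hh_gate()] objects.
#' @param erev reversal potential, mV.
#' @param is_ca does the channel carry calcium (couples into the local
#'   calcium store)?
#' @param q10 temperature sensitivity of all rates.
#' @param teq reference temperature, degrees C.
#' @param surrogate `TRUE` for kinetics that stand in for unpublished state
#'   tables and therefore only match the activation range, not the exact
#'   reference kinetics.
#' @return an `hh_channel_spec`.
#' @export
hh_channel_spec <- function(name, gates, erev, is_ca = FALSE,
                            q10 = 2, teq = 22, surrogate = FALSE) {
  structure(list(name = name, type = "hh", gates = gates, erev = erev,
                 is_ca = is_ca, q10 = q10, teq = teq, surrogate = surrogate),
            class = "channel_spec")
}

#' Markov channel specification
#'
#' @param name channel family name.
#' @param rate_fn function of voltage (mV) returning the `n x n` generator
#'   matrix in 1/ms (`Q[i, j]` = transition rate from state i to j,
#'   diagonal = minus the row sum).
#' @param nstate number of states.
#' @param open integer indices of conducting states.
#' @param erev reversal potential, mV.
#' @param is_ca does the channel carry calcium?
#' @param q10,teq temperature correction parameters.
#' @param surrogate `TRUE` when the transition table is a stand-in.
#' @return a `markov_channel_spec`.
#' @export
markov_channel_spec <- function(name, rate_fn, nstate, open, erev,
                                is_ca = FALSE, q10 = 2, teq = 22,
                                surrogate = TRUE) {
  structure(list(name = name, type = "markov", rate_fn = rate_fn,
                 nstate = as.integer(nstate), open = as.integer(open),
                 erev = erev, is_ca = is_ca, q10 = q10, teq = teq,
                 surrogate = surrogate),
            class = "channel_spec")
}

#' The L-type calcium channel (three-gate HH model)
#'
#' Conductance `ge = c^3 * gmax` with the rates of [cal_alpha()] and
#' [cal_beta()]; carries calcium into the axon-terminal store.
#'
#' @param dVa,tau_a kinetic modifiers of the activation rate (the
#'   parameters exposed to inference).
#' @param erev reversal potential, mV.
#' @param q10,teq temperature correction parameters.
#' @return an `hh_channel_spec`.
#' @export
cal_channel <- function(dVa = 0, tau_a = 1, erev = 45, q10 = 2, teq = 22) {
  g <- hh_gate(3, cal_alpha, cal_beta, dVa = dVa, tau_a = tau_a)
  hh_channel_spec("CaL", list(g), erev = erev, is_ca = TRUE,
                  q10 = q10, teq = teq, surrogate = FALSE)
}

# helper: build alpha/beta from steady-state and time-constant curves
.inf_tau_gate <- function(power, inf_fn, tau_fn, ca_input = FALSE) {
  hh_gate(power,
          alpha = function(v) inf_fn(v) / tau_fn(v),
          beta = function(v) (1 - inf_fn(v)) / tau_fn(v),
          ca_input = ca_input)
}

#' Surrogate channel library
#'
#' Hodgkin-Huxley-style stand-ins for the channel families whose reference
#' Markov state tables are not published: delayed-rectifier potassium (KV,
#' classic n^4 kinetics), hyperpolarization-activated cation (HCN),
#' inward-rectifier potassium (Kir), low-threshold transient calcium (CaT,
#' m^2 h), voltage-gated sodium (NaV, m^3 h) and calcium-activated chloride
#' (ClCa, calcium-driven gate). All carry `surrogate = TRUE`: they match
#' the qualitative activation range and sign of their families, not any
#' specific published state table.
#'
#' @param dVa,tau_a activation-rate modifiers (voltage offset in mV and
#'   relative time constant), where the family exposes them.
#' @param q10,teq temperature correction parameters.
#' @return an `hh_channel_spec` with `surrogate = TRUE`.
#' @name surrogate_channels
NULL

#' @rdname surrogate_channels
#' @export
kv_channel <- function(dVa = 0, tau_a = 1, q10 = 2, teq = 22) {
  # classic delayed-rectifier n^4 kinetics:
  # alpha = 0.01 (v+55) / (1 - exp(-(v+55)/10)) = -0.1 u/(exp(u)-1), u = -(v+55)/10
  alpha <- function(v) {
    u <- -(v + 55) / 10
    0.1 * .expm1_ratio(u)
  }
  beta <- function(v) 0.125 * exp(-(v + 65) / 80)
  g <- hh_gate(4, alpha, beta, dVa = dVa, tau_a = tau_a)
  hh_channel_spec("KV", list(g), erev = -80, q10 = q10, teq = teq,
                  surrogate = TRUE)
}

#' @rdname surrogate_channels
#' @export
hcn_channel <- function(q10 = 2, teq = 22) {
  inf_fn <- function(v) 1 / (1 + exp((v + 75) / 5.5))
  tau_fn <- function(v) 50 + 400 / (1 + exp(-(v + 70) / 10)) # ms
  g <- .inf_tau_gate(1, inf_fn, tau_fn)
  hh_channel_spec("HCN", list(g), erev = -30, q10 = q10, teq = teq,
                  surrogate = TRUE)
}

#' @rdname surrogate_channels
#' @export
kir_channel <- function(dVa = 0, q10 = 2, teq = 22) {
  inf_fn <- function(v) 1 / (1 + exp((v + 60) / 10))
  tau_fn <- function(v) rep(5, length(v))
  g <- .inf_tau_gate(1, inf_fn, tau_fn)
  g$dVa <- dVa; g$dVb <- dVa
  hh_channel_spec("Kir", list(g), erev = -80, q10 = q10, teq = teq,
                  surrogate = TRUE)
}

#' @rdname surrogate_channels
#' @export
cat_channel <- function(dVa = 0, tau_a = 1, q10 = 2, teq = 22) {
  m <- .inf_tau_gate(2, function(v) 1 / (1 + exp(-(v + 50) / 6)),
                     function(v) 2 + 8 / (1 + exp((v + 25) / 10)))
  m$dVa <- dVa; m$tau_a <- tau_a
  h <- .inf_tau_gate(1, function(v) 1 / (1 + exp((v + 70) / 6)),
                     function(v) 10 + 40 / (1 + exp((v + 35) / 10)))
  hh_channel_spec("CaT", list(m, h), erev = 45, is_ca = TRUE,
                  q10 = q10, teq = teq, surrogate = TRUE)
}

#' @rdname surrogate_channels
#' @export
nav_channel <- function(dVa = 0, tau_all = 1, q10 = 2, teq = 22) {
  m <- hh_gate(3,
               alpha = function(v) { u <- -(v + 35) / 10; 1.0 * .expm1_ratio(u) },
               beta = function(v) 4 * exp(-(v + 60) / 18),
               dVa = dVa, tau_a = tau_all, tau_b = tau_all)
  h <- hh_gate(1,
               alpha = function(v) 0.07 * exp(-(v + 60) / 20),
               beta = function(v) 1 / (1 + exp(-(v + 30) / 10)),
               tau_a = tau_all, tau_b = tau_all)
  hh_channel_spec("NaV", list(m, h), erev = 60, q10 = q10, teq = teq,
                  surrogate = TRUE)
}

#' @rdname surrogate_channels
#' @export
clca_channel <- function(q10 = 2, teq = 22) {
  # gate driven by [Ca]0 in uM, half-activation 1.5 uM
  inf_fn <- function(ca) ca^2 / (ca^2 + 1.5^2)
  tau_fn <- function(ca) rep(20, length(ca))  # ms
  g <- .inf_tau_gate(1, inf_fn, tau_fn, ca_input = TRUE)
  hh_channel_spec("ClCa", list(g), erev = -45, q10 = q10, teq = teq,
                  surrogate = TRUE)
}

#' Expand an HH gate into its equivalent Markov chain
#'
#' A gate with power `p` is mechanically equivalent to a `p + 1`-state
#' chain in which state `k` has `k` open subunits, forward rate
#' `(p - k) alpha` and backward rate `k beta`; only the fully open state
#' conducts. Used to cross-check the two channel integration paths.
#'
#' @param spec an `hh_channel_spec` with a single gate.
#' @return a `markov_channel_spec` with `p + 1` states.
#' @export
hh_equivalent_markov <- function(spec) {
  stopifnot(spec$type == "hh", length(spec$gates) == 1L)
  g <- spec$gates[[1]]
  p <- g$power
  rate_fn <- function(v) {
    a <- g$alpha(v - g$dVa) / g$tau_a
    b <- g$beta(v - g$dVb) / g$tau_b
    Q <- matrix(0, p + 1, p + 1)
    for (k in 0:(p - 1)) Q[k + 1, k + 2] <- (p - k) * a
    for (k in 1:p) Q[k + 1, k] <- k * b
    diag(Q) <- -rowSums(Q)
    Q
  }
  markov_channel_spec(paste0(spec$name, "-MS"), rate_fn, p + 1,
                      open = p + 1, erev = spec$erev, is_ca = spec$is_ca,
                      q10 = spec$q10, teq = spec$teq, surrogate = spec$surrogate)
}

#' Conductance from a gating state
#'
#' HH channels: `ge = c^power * gmax` (product over gates); Markov
#' channels: `ge = sum(open occupancies) * gmax`.
#'
#' @param state for HH, a numeric vector of gate states in `[0, 1]`
#'   matched with `powers`; for Markov, the occupancy vector with
#'   attribute-free `open` indices given in `open`.
#' @param gmax maximum conductance, S.
#' @param powers integer powers per gate (HH).
#' @param open indices of open states (Markov); if supplied, `state` is
#'   interpreted as an occupancy vector.
#' @return conductance in S.
#' @export
channel_conductance <- function(state, gmax, powers = rep(1L, length(state)),
                                open = NULL) {
  if (!is.null(open)) {
    if (abs(sum(state) - 1) > 1e-9) stop("Markov occupancies must sum to 1")
    return(sum(state[open]) * gmax)
  }
  if (any(state < 0 | state > 1)) stop("HH gate states must lie in [0, 1]")
  gmax * prod(state^powers)
}

# ---------------------------------------------------------------------------
# Calcium store and ribbon synapse
# ---------------------------------------------------------------------------

#' First-shell calcium store
#'
#' Single-shell surrogate for radial-shell calcium diffusion: only the
#' first-shell (membrane) concentration feeds vesicle release. Dynamics
#' are `d[Ca]0/dt = kappa * |i_ca| - vmax * [Ca]0/([Ca]0 + CaPK) + s0`
#' with the constant source `s0` chosen so the resting level is an
#' equilibrium in the absence of calcium current.
#'
#' @param ca_rest resting concentration, uM.
#' @param capk pump half-saturation concentration, uM.
#' @param vmax maximum pump (extrusion) rate, uM/s.
#' @param kappa influx scaling, uM per coulomb of calcium-channel charge.
#' @param ca initial concentration, uM.
#' @return a `calcium_store`.
#' @export
calcium_store <- function(ca_rest = 0.05, capk = 5, vmax = 50,
                          kappa = 5e9, ca = ca_rest) {
  structure(list(ca_rest = ca_rest, capk = capk, vmax = vmax,
                 kappa = kappa, ca = ca),
            class = "calcium_store")
}

#' Advance a calcium store by one time step
#'
#' @param store a [calcium_store()].
#' @param i_ca calcium-channel current, A (sign ignored; magnitude drives
#'   influx).
#' @param dt time step, s.
#' @return the updated store.
#' @export
calcium_update <- function(store, i_ca, dt) {
  if (dt <= 0) stop("dt must be > 0")
  influx <- store$kappa * abs(i_ca)
  pump <- store$vmax * store$ca / (store$ca + store$capk)
  s0 <- store$vmax * store$ca_rest / (store$ca_rest + store$capk)
  store$ca <- max(0, store$ca + dt * (influx - pump + s0))
  store
}

#' Ribbon synapse with a readily releasable pool
#'
#' @param vmax_pool maximum number of vesicles in the readily releasable
#'   pool (RRP).
#' @param gl linear release gain (dimensionless).
#' @param rmsr maximum sustainable release rate: the constant pool
#'   replenishment rate, vesicles/s (8 ves/s for bipolar cells, 100 ves/s
#'   for cones).
#' @param pool current pool occupancy (defaults to full).
#' @return a `ribbon_synapse`.
#' @export
ribbon_synapse <- function(vmax_pool = 12, gl = 1, rmsr = 8,
                           pool = vmax_pool) {
  if (pool < 0 || pool > vmax_pool) stop("pool must lie in [0, vmax_pool]")
  structure(list(vmax_pool = vmax_pool, gl = gl, rmsr = rmsr, pool = pool),
            class = "ribbon_synapse")
}

#' Instantaneous ribbon release rate
#'
#' `r = ca^2 * (vRRP / vRRPmax) * gl` vesicles/s with `ca` the first-shell
#' calcium concentration expressed in uM (the squared-concentration
#' normalization is absorbed into this unit convention; any residual scale
#' is carried by the `gl` prior).
#'
#' @param ca first-shell calcium concentration, uM.
#' @param syn a [ribbon_synapse()].
#' @return release rate in vesicles/s.
#' @export
ribbon_release_rate <- function(ca, syn) {
  if (any(ca < 0)) stop("ca must be >= 0")
  ca^2 * (syn$pool / syn$vmax_pool) * syn$gl
}

#' Advance the readily releasable pool by one time step
#'
#' `vRRP <- vRRP - r dt + rmsr dt (1 - vRRP / vRRPmax)`, clipped to
#' `[0, vRRPmax]`.
#'
#' @param syn a [ribbon_synapse()].
#' @param r release rate, vesicles/s.
#' @param dt time step, s.
#' @return the updated synapse.
#' @export
rrp_update <- function(syn, r, dt) {
  if (dt <= 0) stop("dt must be > 0")
  v <- syn$pool - r * dt + syn$rmsr * dt * (1 - syn$pool / syn$vmax_pool)
  syn$pool <- min(max(v, 0), syn$vmax_pool)
  syn
}

# ---------------------------------------------------------------------------
# Postsynaptic receptors and phototransduction surrogate
# ---------------------------------------------------------------------------

#' Postsynaptic receptor model
#'
#' Kainate receptors (OFF bipolar cells) are sign-preserving with
#' first-order desensitization governed by the inactivation time constant
#' `tau_gamma`; mGluR6 (ON bipolar cells) is sign-inverting, with the open
#' fraction decreasing as transmitter increases. The presynaptic release
#' signal is scaled by the transmitter concentration factor `STC` before
#' receptor activation.
#'
#' @param kind `"kainate"` or `"mGluR6"`.
#' @param stc synaptic transmitter concentration scale factor.
#' @param tau_gamma inactivation (desensitization) time constant, ms
#'   (kainate only).
#' @param k50 release rate (ves/s) producing half-maximal receptor drive.
#' @param tau_m activation low-pass time constant, ms (mGluR6 cascade).
#' @param desens desensitization depth in `[0, 1]` (kainate).
#' @param g_contact conductance per synaptic contact, nS.
#' @return a `postsynaptic_receptor`.
#' @export
postsynaptic_receptor <- function(kind = c("kainate", "mGluR6"), stc = 1,
                                  tau_gamma = 30, k50 = 60, tau_m = 15,
                                  desens = 0.7, g_contact = 0.25) {
  kind <- match.arg(kind)
  structure(list(kind = kind, stc = stc, tau_gamma = tau_gamma, k50 = k50,
                 tau_m = tau_m, desens = desens, g_contact = g_contact),
            class = "postsynaptic_receptor")
}

#' Receptor open fraction from a presynaptic release trace
#'
#' @param glu presynaptic glutamate release-rate trace, vesicles/s (>= 0).
#' @param rec a [postsynaptic_receptor()].
#' @param dt trace sampling interval, s.
#' @param state optional initial filter state (steady state of the first
#'   sample by default).
#' @return numeric trace of open fractions in `[0, 1]`.
#' @export
receptor_drive <- function(glu, rec, dt, state = NULL) {
  if (any(glu < 0)) stop("glu must be >= 0")
  transmitter <- rec$stc * glu
  u <- transmitter / (transmitter + rec$k50)  # instantaneous drive in [0, 1)
  n <- length(u)
  if (rec$kind == "kainate") {
    # open = drive * desensitization state; state relaxes to 1 - desens*u
    tau <- rec$tau_gamma * 1e-3
    a <- exp(-dt / tau)
    h <- numeric(n)
    h[1] <- if (is.null(state)) 1 - rec$desens * u[1] else state
    if (n > 1) for (i in 2:n) {
      hinf <- 1 - rec$desens * u[i]
      h[i] <- hinf + (h[i - 1] - hinf) * a
    }
    out <- u * h
  } else {
    # mGluR6 cascade: low-pass the drive, then invert the sign
    tau <- rec$tau_m * 1e-3
    a <- exp(-dt / tau)
    f <- numeric(n)
    f[1] <- if (is.null(state)) u[1] else state
    if (n > 1) for (i in 2:n) f[i] <- u[i] + (f[i - 1] - u[i]) * a
    out <- 1 - f
  }
  pmin(pmax(out, 0), 1)
}

#' Phototransduction cascade surrogate
#'
#' Two first-order low-pass stages followed by divisive adaptation,
#' producing the hyperpolarizing current entering the cone inner segment.
#' The steady-state current is monotone (more hyperpolarizing) in the
#' steady photon rate and saturates.
#'
#' @param i_max maximal light-evoked current magnitude, A.
#' @param r50 photon rate producing half-maximal steady drive, P*/s.
#' @param tau1,tau2 cascade time constants, ms.
#' @param adapt_tau adaptation time constant, ms.
#' @param adapt_strength divisive adaptation strength (0 disables).
#' @return a `phototransduction` spec.
#' @export
phototransduction <- function(i_max = 25e-12, r50 = 15e3, tau1 = 15,
                              tau2 = 25, adapt_tau = 400,
                              adapt_strength = 0.4) {
  structure(list(i_max = i_max, r50 = r50, tau1 = tau1, tau2 = tau2,
                 adapt_tau = adapt_tau, adapt_strength = adapt_strength),
            class = "phototransduction")
}

#' Photocurrent from a photon absorption rate trace
#'
#' @param photon_rate photon absorption rate trace, P*/s per cone (>= 0).
#' @param spec a [phototransduction()].
#' @param dt sampling interval, s.
#' @param init optional initial state list (from a previous call's
#'   `attr(, "state")`) to continue a simulation.
#' @return current trace in A (negative = hyperpolarizing), with the final
#'   filter state attached as attribute `state`.
#' @export
photocurrent <- function(photon_rate, spec, dt, init = NULL) {
  if (any(photon_rate < 0)) stop("photon_rate must be >= 0")
  u <- photon_rate / (photon_rate + spec$r50)    # bounded drive
  n <- length(u)
  a1 <- exp(-dt / (spec$tau1 * 1e-3))
  a2 <- exp(-dt / (spec$tau2 * 1e-3))
  aa <- exp(-dt / (spec$adapt_tau * 1e-3))
  x1 <- if (is.null(init)) u[1] else init$x1
  x2 <- if (is.null(init)) u[1] else init$x2
  ad <- if (is.null(init)) u[1] else init$ad
  out <- numeric(n)
  for (i in seq_len(n)) {
    x1 <- u[i] + (x1 - u[i]) * a1
    x2 <- x1 + (x2 - x1) * a2
    ad <- x2 + (ad - x2) * aa
    out[i] <- -spec$i_max * x2 / (1 + spec$adapt_strength * ad)
  }
  attr(out, "state") <- list(x1 = x1, x2 = x2, ad = ad)
  out
}
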