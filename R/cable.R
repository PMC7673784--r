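# ---------------------------------------------------------------------------
# Cell model assembly
# ---------------------------------------------------------------------------

#' Assemble a multicompartment cell model
#'
#' Takes the compartments produced by [compartmentalize()] and wires them
#' into the simulator's state owner: axial coupling between each
#' compartment and its parent uses the series resistance `ri_n + ri_parent`
#' of the two compartments. Channels, calcium stores and ribbon synapses
#' are added with [add_channel()], [add_calcium_store()] and
#' [add_ribbon()].
#'
#' @param comps a `compartments` data frame from [compartmentalize()].
#' @param soma id of the soma compartment (defaults to the root).
#' @param tsim simulation temperature, degrees C (in `[20, 40]`).
#' @return a `cell_model`.
#' @export
cell_model <- function(comps, soma = NULL, tsim = 37) {
  stopifnot(inherits(comps, "compartments"))
  if (tsim < 20 || tsim > 40) stop("tsim must lie in [20, 40] degrees C")
  n <- nrow(comps)
  pidx <- match(comps$parent, comps$id)
  edges <- NULL
  for (i in seq_len(n)) {
    if (!is.na(pidx[i])) {
      rser <- comps$ri[i] + comps$ri[pidx[i]]
      if (rser <= 0) stop("non-positive series axial resistance at id ", comps$id[i])
      edges <- rbind(edges, c(i - 1, pidx[i] - 1, 1 / rser))
    }
  }
  if (is.null(soma)) soma <- comps$id[which(is.na(pidx))[1]]
  structure(list(comps = comps, edges = edges,
                 soma = match(soma, comps$id), tsim = tsim,
                 vr = rep(attr(comps, "Vr"), n),
                 channels = list(), stores = list(), ribbons = list(),
                 vex = NULL),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model> %d compartments, %d channels, %d ribbons, Tsim %.1f C\n",
              nrow(x$comps), length(x$channels), length(x$ribbons), x$tsim))
  invisible(x)
}

#' Add a channel population to a cell model
#'
#' @param cell a [cell_model()].
#' @param spec a channel spec ([hh_channel_spec()], [markov_channel_spec()]
#'   or one of the bundled constructors).
#' @param where compartment ids, or a region name present in
#'   `cell$comps$region`.
#' @param gmax_density maximum conductance density, mS/cm^2 (converted with
#'   each compartment's surface area).
#' @return the updated cell model.
#' @export
add_channel <- function(cell, spec, where, gmax_density) {
  ids <- .resolve_where(cell, where)
  for (i in ids) {
    gmax <- gmax_density * 1e-3 * cell$comps$area_um2[i] * 1e-8  # S
    cell$channels[[length(cell$channels) + 1]] <-
      list(spec = spec, comp = i, gmax = gmax)
  }
  cell
}

#' Add a first-shell calcium store to compartments
#'
#' @param cell a [cell_model()].
#' @param where compartment ids or a region name.
#' @param store a [calcium_store()] template.
#' @return the updated cell model.
#' @export
add_calcium_store <- function(cell, where, store = calcium_store()) {
  ids <- .resolve_where(cell, where)
  for (i in ids) cell$stores[[length(cell$stores) + 1]] <- c(list(comp = i), unclass(store))
  cell
}

#' Add ribbon synapses to compartments
#'
#' Each ribbon reads the calcium store of its compartment (which must
#' exist).
#'
#' @param cell a [cell_model()].
#' @param where compartment ids or a region name.
#' @param syn a [ribbon_synapse()] template.
#' @return the updated cell model.
#' @export
add_ribbon <- function(cell, where, syn = ribbon_synapse()) {
  ids <- .resolve_where(cell, where)
  store_comp <- vapply(cell$stores, function(s) s$comp, numeric(1))
  for (i in ids) {
    k <- match(i, store_comp)
    if (is.na(k)) stop("no calcium store at compartment ", cell$comps$id[i])
    cell$ribbons[[length(cell$ribbons) + 1]] <- c(list(store = k), unclass(syn))
  }
  cell
}

.resolve_where <- function(cell, where) {
  if (is.character(where)) {
    ids <- which(cell$comps$region %in% where)
    if (!length(ids)) stop("no compartments in region(s): ",
                           paste(where, collapse = ", "))
    ids
  } else {
    idx <- match(where, cell$comps$id)
    if (anyNA(idx)) stop("unknown compartment id(s): ",
                         paste(where[is.na(idx)], collapse = ", "))
    idx
  }
}

#' Attach extracellular voltage forcing to a cell model
#'
#' @param cell a [cell_model()].
#' @param vex matrix of extracellular voltages, mV, one row per
#'   compartment; columns are time samples on the simulation grid
#'   (`nsteps + 1` values). Without attachment the extracellular potential
#'   is identically zero.
#' @return the updated cell model.
#' @export
apply_vex <- function(cell, vex) {
  vex <- as.matrix(vex)
  if (nrow(vex) != nrow(cell$comps)) {
    stop("vex must have one row per compartment (", nrow(cell$comps), ")")
  }
  cell$vex <- vex
  cell
}

# ---------------------------------------------------------------------------
# Simulation
# ---------------------------------------------------------------------------

# tabulate one HH gate on a fixed grid, SI units for the core (1/s; grid in
# volts for voltage gates, uM for calcium gates)
.gate_table <- function(gate, tsim, q10, teq, state = -1) {
  if (gate$ca_input) {
    grid <- seq(0, 50, by = 0.01)            # uM
    r <- cal_rates(grid, gate, tsim, q10, teq)
    list(power = gate$power, v0 = grid[1], dv = grid[2] - grid[1],
         alpha = r$alpha * 1e3, beta = r$beta * 1e3,
         ca_input = TRUE, state = state)
  } else {
    grid_mv <- seq(-150, 80, by = 0.05)
    r <- cal_rates(grid_mv, gate, tsim, q10, teq)
    list(power = gate$power, v0 = grid_mv[1] * 1e-3, dv = 0.05e-3,
         alpha = r$alpha * 1e3, beta = r$beta * 1e3,
         ca_input = FALSE, state = state)
  }
}

.markov_table <- function(spec, tsim) {
  grid_mv <- seq(-150, 80, by = 0.05)
  eta <- eta_t(spec$q10, tsim, spec$teq)
  Q <- array(0, c(spec$nstate, spec$nstate, length(grid_mv)))
  for (k in seq_along(grid_mv)) {
    Q[, , k] <- spec$rate_fn(grid_mv[k]) * eta * 1e3   # 1/s
  }
  list(v0 = grid_mv[1] * 1e-3, dv = 0.05e-3, Q = Q)
}

# stationary distribution of a generator (rows sum to zero)
.markov_stationary <- function(Q) {
  n <- nrow(Q)
  M <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  p <- qr.solve(M, b)
  p <- pmax(p, 0)
  p / sum(p)
}

.build_core_spec <- function(cell, v0, init = NULL) {
  comps <- cell$comps
  n <- nrow(comps)
  g_leak <- ifelse(is.finite(comps$rm), 1 / comps$rm, 0)
  channels <- list()
  hh_i <- 0; mk_i <- 0
  for (ch in cell$channels) {
    sp <- ch$spec
    if (sp$type == "hh") {
      hh_i <- hh_i + 1
      st <- if (!is.null(init)) init$gates$hh[[hh_i]] else NULL
      gates <- lapply(seq_along(sp$gates), function(g) {
        .gate_table(sp$gates[[g]], cell$tsim, sp$q10, sp$teq,
                    state = if (is.null(st)) -1 else st[g])
      })
      channels[[length(channels) + 1]] <- list(
        type = "hh", comp = ch$comp, gmax = ch$gmax, erev = sp$erev * 1e-3,
        is_ca = sp$is_ca, gates = gates)
    } else {
      mk_i <- mk_i + 1
      tb <- .markov_table(sp, cell$tsim)
      p0 <- if (!is.null(init)) init$gates$markov[[mk_i]]
            else .markov_stationary(sp$rate_fn(v0[ch$comp] * 1e3))
      channels[[length(channels) + 1]] <- list(
        type = "markov", comp = ch$comp, gmax = ch$gmax, erev = sp$erev * 1e-3,
        is_ca = sp$is_ca, v0 = tb$v0, dv = tb$dv, Q = tb$Q, open = sp$open,
        p = p0)
    }
  }
  stores <- lapply(seq_along(cell$stores), function(i) {
    s <- cell$stores[[i]]
    list(comp = s$comp, kappa = s$kappa, vmax = s$vmax, capk = s$capk,
         ca_rest = s$ca_rest,
         ca = if (!is.null(init)) init$ca[i] else s$ca)
  })
  ribbons <- lapply(seq_along(cell$ribbons), function(i) {
    r <- cell$ribbons[[i]]
    list(store = r$store, vmax_pool = r$vmax_pool, gl = r$gl, rmsr = r$rmsr,
         pool = if (!is.null(init)) init$pool[i] else r$pool)
  })
  list(cm = comps$cm, g_leak = g_leak, vr = cell$vr * 1e-3,
       edges = cell$edges, channels = channels, stores = stores,
       ribbons = ribbons, v0 = v0)
}

#' Simulate a cell model
#'
#' Integrates the compartmental membrane equation with Crank-Nicolson
#' coupling of the linear cable terms and exact exponential updates of the
#' gating states, including optional extracellular-voltage forcing
#' (attached with [apply_vex()]), current injections and synaptic
#' conductance drives. The integration is fully deterministic: the seed is
#' recorded for provenance but no randomness enters the solver.
#'
#' @param cell a [cell_model()].
#' @param drive list with optional elements `i_inj` (list of
#'   `list(comp = id, trace = <A, length nsteps + 1>)`), `g_syn` (list of
#'   `list(comp = id, erev = mV, trace = <S, length nsteps + 1>)`) and
#'   `clamp` (`list(comp = id, v = mV, t = s)`, a somatic voltage clamp for
#'   the first `t` seconds).
#' @param dt time step, s.
#' @param t_end total simulated time, s.
#' @param seed integer seed recorded with the result.
#' @param record_dt sampling interval of the returned traces, s (a
#'   multiple of `dt`).
#' @param init optional final-state list of a previous simulation (for
#'   settle-then-stimulate protocols).
#' @param v0 initial membrane potential(s), mV (defaults to the resting
#'   potential, or the initial state's voltages).
#' @return a `simulation_result` with elements `time` (s), `Vm` (mV,
#'   compartments x samples), `rate` (vesicles/s per ribbon), `ca` (uM per
#'   store), `pool` (vesicles per ribbon), `status` (`"ok"` or
#'   `"unstable"`) and `final` (state for chaining).
#' @export
simulate_cell <- function(cell, drive = list(), dt, t_end, seed = 1L,
                          record_dt = dt, init = NULL, v0 = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  nsteps <- round(t_end / dt)
  re <- round(record_dt / dt)
  if (re < 1 || abs(re * dt - record_dt) > 1e-12) {
    stop("record_dt must be a positive multiple of dt")
  }
  if (nsteps %% re != 0) stop("t_end must be a multiple of record_dt")
  n <- nrow(cell$comps)
  if (is.null(v0)) {
    v0 <- if (!is.null(init)) init$v else cell$vr * 1e-3
  } else {
    v0 <- rep(v0, length.out = n) * 1e-3
  }

  dcore <- list()
  if (!is.null(drive$i_inj)) {
    dcore$i_inj <- lapply(drive$i_inj, function(e) {
      tr <- .conform_trace(e$trace, nsteps)
      list(comp = match(e$comp, cell$comps$id), trace = tr)
    })
  }
  if (!is.null(drive$g_syn)) {
    dcore$g_syn <- lapply(drive$g_syn, function(e) {
      tr <- .conform_trace(e$trace, nsteps)
      list(comp = match(e$comp, cell$comps$id), erev = e$erev * 1e-3,
           trace = tr)
    })
  }
  if (!is.null(cell$vex)) {
    if (ncol(cell$vex) != nsteps + 1) {
      stop("vex has ", ncol(cell$vex), " columns; needs nsteps + 1 = ", nsteps + 1)
    }
    dcore$vex <- cell$vex * 1e-3
  }
  if (!is.null(drive$clamp)) {
    dcore$clamp <- list(comp = match(drive$clamp$comp, cell$comps$id),
                        v = drive$clamp$v * 1e-3,
                        steps = round(drive$clamp$t / dt))
  }

  spec <- .build_core_spec(cell, v0, init)
  out <- .sim_core_cpp(spec, dcore, dt, nsteps, re)
  res <- list(time = seq(0, nsteps * dt, by = re * dt),
              Vm = out$V * 1e3, rate = out$rate, ca = out$ca,
              pool = out$pool, status = out$status,
              soma = cell$soma, seed = seed,
              final = list(v = out$final$v,
                           gates = out$final$gates,
                           ca = out$final$ca, pool = out$final$pool))
  class(res) <- "simulation_result"
  res
}

.conform_trace <- function(tr, nsteps) {
  if (length(tr) == 1L) return(rep(tr, nsteps + 1))
  if (length(tr) != nsteps + 1) {
    stop("drive trace has length ", length(tr), "; needs nsteps + 1 = ",
         nsteps + 1)
  }
  tr
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d compartments x %d samples, status: %s\n",
              nrow(x$Vm), ncol(x$Vm), x$status))
  invisible(x)
}

#' Relax a cell model to its background steady state
#'
#' Runs the model under constant background drive and returns the final
#' state; the settled somatic potential and release rates define the
#' "resting" values used by the discrepancy components.
#'
#' @param cell a [cell_model()].
#' @param drive constant background drive (same structure as in
#'   [simulate_cell()]; traces may be scalars).
#' @param t_settle settling duration, s.
#' @param dt time step, s.
#' @return list with `init` (state for [simulate_cell()]), `v_rest` (mV,
#'   somatic), `rate_rest` (mean resting release over ribbons, ves/s).
#' @export
settle_cell <- function(cell, drive = list(), t_settle = 2, dt = 1e-4) {
  res <- simulate_cell(cell, drive, dt = dt, t_end = t_settle,
                       record_dt = t_settle)
  if (res$status != "ok") {
    return(list(init = res$final, v_rest = NA_real_, rate_rest = NA_real_,
                status = res$status))
  }
  rate_rest <- if (length(cell$ribbons)) mean(res$rate[, ncol(res$rate)]) else NA_real_
  list(init = res$final, v_rest = res$Vm[cell$soma, ncol(res$Vm)],
       rate_rest = rate_rest, status = "ok")
}

#' Screen a cell model for a depolarized second equilibrium
#'
#' Simulates a somatic voltage clamp (default 30 mV for 100 ms) and checks
#' whether the somatic membrane potential recovers to -30 mV or lower
#' within a further 300 ms. Models that fail are biologically implausible
#' and are excluded from posterior training.
#'
#' @param cell a [cell_model()].
#' @param drive background drive held during the screen.
#' @param clamp_mv clamp potential, mV.
#' @param t_clamp clamp duration, s.
#' @param t_post post-clamp observation window, s.
#' @param recover_mv recovery criterion, mV.
#' @param dt time step, s.
#' @param init optional settled state.
#' @return `"ok"`, `"depolarized_equilibrium"` or `"unstable"`.
#' @export
voltage_clamp_screen <- function(cell, drive = list(), clamp_mv = 30,
                                 t_clamp = 0.1, t_post = 0.3,
                                 recover_mv = -30, dt = 5e-5, init = NULL) {
  drive$clamp <- list(comp = cell$comps$id[cell$soma], v = clamp_mv,
                      t = t_clamp)
  t_end <- t_clamp + t_post
  res <- simulate_cell(cell, drive, dt = dt, t_end = t_end,
                       record_dt = t_end, init = init)
  if (res$status != "ok") return("unstable")
  v_end <- res$Vm[cell$soma, ncol(res$Vm)]
  if (v_end > recover_mv) "depolarized_equilibrium" else "ok"
}
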