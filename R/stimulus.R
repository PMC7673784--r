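# ---------------------------------------------------------------------------
# Charge-neutral spline stimuli
# ---------------------------------------------------------------------------

#' Build a charge-neutral cubic-spline stimulation current
#'
#' A 40 ms current waveform defined by a natural cubic spline through the
#' knot vector `(0, p1, p2, p3, p4, p*, 0)` placed equidistantly in time.
#' The balancing knot `p*` is solved from the (linear) charge-balance
#' condition so the integral of the current over the window is zero, and
#' the waveform is scaled so its maximum absolute amplitude is `amp`.
#'
#' @param p numeric vector of the four free knots.
#' @param duration window length, s.
#' @param dt sample interval, s.
#' @param amp amplitude cap after normalization, A (0.5 uA).
#' @return a `spline_stimulus`: list with `t` (s), `i` (A), `knots` (the
#'   full 7-knot vector), `p_star`, `dt`.
#' @export
build_stimulus <- function(p, duration = 0.040, dt = 1e-5, amp = 0.5e-6) {
  stopifnot(length(p) == 4, all(is.finite(p)))
  kt <- seq(0, duration, length.out = 7)
  tg <- seq(0, duration, by = dt)
  basis_integral <- function(k) {
    v <- numeric(7); v[k] <- 1
    sum(stats::spline(kt, v, xout = tg, method = "natural")$y) * dt
  }
  w <- vapply(2:6, basis_integral, numeric(1))  # knots p1..p4, p*
  if (w[5] == 0) stop("degenerate spline basis for the balancing knot")
  p_star <- -sum(w[1:4] * p) / w[5]
  knots <- c(0, p, p_star, 0)
  i <- stats::spline(kt, knots, xout = tg, method = "natural")$y
  m <- max(abs(i))
  if (m == 0) stop("all-zero stimulus: normalization undefined")
  i <- i * amp / m
  structure(list(t = tg, i = i, knots = knots, p_star = p_star, dt = dt,
                 amp = amp),
            class = "spline_stimulus")
}

#' @export
print.spline_stimulus <- function(x, ...) {
  cat(sprintf("<spline_stimulus> %d samples, %.1f ms, peak %.3g uA, charge %.2e of |charge|\n",
              length(x$i), max(x$t) * 1e3, max(abs(x$i)) * 1e6,
              abs(sum(x$i)) / max(sum(abs(x$i)), .Machine$double.xmin)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Release-based selectivity metrics
# ---------------------------------------------------------------------------

#' Relative release evoked by a stimulus
#'
#' `Rn = (mu(r_n) - mu(r_base)) * dt_w / (vRRPmax + (rmsr - mu(r_base)) *
#' dt_w)`: the number of vesicles released by the stimulation (mean over
#' synapses) over the response window, relative to the theoretical
#' maximum of releasable vesicles (pool plus replenishment).
#'
#' @param rates release-rate traces over the response window, vesicles/s
#'   (matrix synapses x time, or vector).
#' @param vmax_pool readily-releasable-pool capacity, vesicles.
#' @param rmsr maximum sustainable release rate, vesicles/s.
#' @param base_rate baseline mean release rate without stimulation,
#'   vesicles/s.
#' @param window response window length, s (60 ms).
#' @return relative release `Rn` (dimensionless).
#' @export
relative_release <- function(rates, vmax_pool, rmsr, base_rate,
                             window = 0.060) {
  mu_n <- mean(rates)
  denom <- vmax_pool + (rmsr - base_rate) * window
  if (denom <= 0) stop("non-positive denominator in relative release")
  (mu_n - base_rate) * window / denom
}

#' Stimulus selectivity discrepancy
#'
#' The ratio of the non-target cell's relative release to the target
#' cell's; smaller values mean more selective stimulation of the target.
#' A non-positive target response yields a declared worst-case constant.
#'
#' @param r_target relative release of the targeted cell.
#' @param r_other relative release of the other cell.
#' @param worst value assigned when `r_target <= 0`.
#' @return selectivity discrepancy (>= 0).
#' @export
selectivity_discrepancy <- function(r_target, r_other, worst = 1e6) {
  if (r_target <= 0) {
    out <- worst
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  r_other / r_target
}

# ---------------------------------------------------------------------------
# Selectivity optimization
# ---------------------------------------------------------------------------

#' Optimize a charge-neutral stimulus for cell-type selectivity
#'
#' Single-round posterior estimation over the four free spline knots:
#' `n_prior` knot vectors are drawn from zero-mean Gaussian priors
#' (sd 0.3) and evaluated on both cells; the same prior draws are reused
#' for both target assignments. Per target, a two-component Gaussian
#' mixture posterior (untruncated) is trained on the selectivity
#' discrepancy and `n_post` additional stimuli are drawn from it and
#' evaluated. Stimuli are ranked by their discrepancy.
#'
#' @param response_fns named list of two functions (`target` first), each
#'   mapping a `spline_stimulus` to the cell's relative release `Rn`.
#' @param n_prior prior draws shared between the two runs.
#' @param n_post posterior draws per target.
#' @param seed integer seed.
#' @param prior_sd prior standard deviation of the knots.
#' @param worst worst-case discrepancy for non-responding targets.
#' @param stimulus_args extra arguments to [build_stimulus()].
#' @return list per target name: `ranked` (data frame of knots, releases
#'   and discrepancy, best first), `posterior`, and the shared
#'   `prior_draws`.
#' @export
optimize_selective_stimulus <- function(response_fns, n_prior = 400,
                                        n_post = 100, seed = 1L,
                                        prior_sd = 0.3, worst = 1e6,
                                        stimulus_args = list()) {
  stopifnot(length(response_fns) == 2, !is.null(names(response_fns)))
  cells <- names(response_fns)
  prior <- tn_prior(mean = rep(0, 4), lower = rep(-Inf, 4),
                    upper = rep(Inf, 4), sd = rep(prior_sd, 4),
                    names = paste0("p", 1:4))
  P <- sample_truncated(prior, n_prior, seed = seed)
  eval_R <- function(pvec) {
    stim <- do.call(build_stimulus, c(list(p = pvec), stimulus_args))
    vapply(cells, function(cl) response_fns[[cl]](stim), numeric(1))
  }
  Rprior <- t(apply(P, 1, eval_R))   # n_prior x 2, cols = cells
  out <- list(prior_draws = list(p = P, R = Rprior))
  for (ti in seq_along(cells)) {
    target <- cells[ti]; other <- cells[-ti]
    dvals <- vapply(seq_len(n_prior), function(i) {
      as.numeric(selectivity_discrepancy(Rprior[i, ti], Rprior[i, -ti],
                                         worst = worst))
    }, numeric(1))
    X <- matrix(dvals, ncol = 1)
    ksp <- kernel_update(X)
    w <- kernel_weights(X, ksp)
    if (any(Rprior[, ti] <= 0)) w[Rprior[, ti] <= 0] <- 0
    if (sum(w > 0) < 50) stop("too few responding samples for target ", target)
    net <- train_mdn(P, X, w, n_components = 2, hidden = c(20, 20),
                     head = "mlp", epochs = 500, seed = seed + ti)
    post <- evaluate_posterior(net, x_target = min(dvals), box = NULL)
    if (n_post > 0) {
      Ppost <- posterior_sample(post, n_post, seed = seed + 100L + ti)
      Rpost <- t(apply(Ppost, 1, eval_R))
    } else {
      Ppost <- matrix(numeric(0), 0, 4)
      Rpost <- matrix(numeric(0), 0, 2)
    }
    dpost <- vapply(seq_len(n_post), function(i) {
      as.numeric(selectivity_discrepancy(Rpost[i, ti], Rpost[i, -ti],
                                         worst = worst))
    }, numeric(1))
    tab <- data.frame(rbind(P, Ppost))
    names(tab) <- paste0("p", 1:4)
    tab$R_target <- c(Rprior[, ti], Rpost[, ti])
    tab$R_other <- c(Rprior[, -ti], Rpost[, -ti])
    tab$discrepancy <- c(dvals, dpost)
    tab$phase <- rep(c("prior", "posterior"), c(n_prior, n_post))
    out[[target]] <- list(ranked = tab[order(tab$discrepancy), ],
                          posterior = post)
  }
  out
}

# ---------------------------------------------------------------------------
# Threshold sweep across layouts, positions and pulse amplitudes
# ---------------------------------------------------------------------------

#' Release-versus-charge-density sweep under array stimulation
#'
#' Simulates each cell's response to each pulse waveform, electrode
#' layout and lateral position, and tabulates the mean number of vesicles
#' released per synapse over the simulation window, relative to the pool
#' capacity. Cells must be supplied without photoreceptor input (the
#' degenerated-retina condition); each cell entry provides the cell model
#' plus its compartment geometry.
#'
#' @param cells named list, each `list(cell = <cell_model>,
#'   comps = <compartments>)` (no cone drive attached).
#' @param model a [retina_field_model()].
#' @param pulses named list of current waveforms, A, on a uniform grid of
#'   `dt_pulse` covering the simulation window.
#' @param layouts integer vector of electrodes per side.
#' @param positions_um lateral offsets of the cell from the array center,
#'   um.
#' @param dt_pulse waveform sample interval, s.
#' @param dt_sim simulation time step, s (10 us for electrical pulses).
#' @param z_soma_um soma height above the electrode plane, um.
#' @param n_harmonics harmonics retained in the field synthesis.
#' @param settle_s settling time before the pulse, s.
#' @return data frame with columns `cell`, `pulse`, `layout`, `position_um`,
#'   `charge_density_C_cm2` (anodic charge per electrode area),
#'   `vesicles_per_synapse`, `relative_release` (per pool capacity) and
#'   `status`.
#' @export
threshold_sweep <- function(cells, model, pulses, layouts = c(1, 2),
                            positions_um = c(0, 100, 500),
                            dt_pulse = 1e-5, dt_sim = 1e-5,
                            z_soma_um = 30, n_harmonics = 12,
                            settle_s = 0.2) {
  res <- NULL
  a_cm2 <- pi * (model$a * 1e2)^2      # electrode area in cm^2
  settled_cache <- list()
  for (ly in layouts) {
    bank <- NULL
    for (pn in names(pulses)) {
      wave <- pulses[[pn]]
      nt <- length(wave)
      t_end <- (nt - 1) * dt_sim
      if (is.null(bank)) {
        bank <- harmonic_fields(model, n_side = ly, window_s = nt * dt_pulse,
                                n_harmonics = n_harmonics)
      }
      q_anodic <- sum(pmax(wave, 0)) * dt_pulse / ly^2   # per electrode
      qdens <- q_anodic / a_cm2
      for (cn in names(cells)) {
        ce <- cells[[cn]]
        if (is.null(settled_cache[[cn]])) {
          settled_cache[[cn]] <- settle_cell(ce$cell, t_settle = settle_s,
                                             dt = dt_sim * 5)
        }
        settled <- settled_cache[[cn]]
        base <- simulate_cell(ce$cell, dt = dt_sim, t_end = t_end,
                              record_dt = dt_sim, init = settled$init)
        base_rate <- mean(base$rate)
        for (pos in positions_um) {
          positions <- place_cell(ce$comps, xy_um = c(pos, 0),
                                  z_soma_um = z_soma_um)
          vex <- vex_from_waveform(bank, positions, wave, dt_pulse)
          cellv <- apply_vex(ce$cell, vex)
          sim <- simulate_cell(cellv, dt = dt_sim, t_end = t_end,
                               record_dt = dt_sim, init = settled$init)
          vmax_pool <- ce$cell$ribbons[[1]]$vmax_pool
          ves <- mean(rowSums(sim$rate) * dt_sim)   # per synapse
          res <- rbind(res, data.frame(
            cell = cn, pulse = pn, layout = ly, position_um = pos,
            charge_density_C_cm2 = qdens,
            vesicles_per_synapse = ves,
            relative_release = ves / vmax_pool,
            base_rate = base_rate,
            status = sim$status))
        }
      }
    }
  }
  res
}
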