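# Shared electrical-stimulation toy cells: an OFF-like cell with low-
# threshold transient calcium channels at the terminal and an ON-like
# cell with L-type channels only.
.stim_cell <- function(kind) {
  tc <- toy_bc_cell(g_cal = if (kind == "on") 4 else 0.5,
                    g_kv = 1, gl = 40, vmax_pool = 12, tsim = 33.5)
  if (kind == "off") tc$cell <- add_channel(tc$cell, cat_channel(), "AT", 4)
  tc
}

.stim_response_fn <- function(kind, bank, dt_sim = 2e-5) {
  tc <- .stim_cell(kind)
  pos <- place_cell(tc$comps, c(0, 0), 30)
  st <- settle_cell(tc$cell, t_settle = 0.3, dt = 1e-4)
  base <- simulate_cell(tc$cell, dt = dt_sim, t_end = 0.06 - dt_sim,
                        record_dt = dt_sim, init = st$init)
  base_rate <- mean(base$rate)
  function(stim) {
    wave <- c(stim$i, rep(0, round(0.02 / stim$dt)))
    wave <- stats::approx(seq_along(wave), wave,
                          n = round(0.06 / dt_sim))$y
    vex <- vex_from_waveform(bank, pos, wave, dt_sim)
    sim <- simulate_cell(apply_vex(tc$cell, vex), dt = dt_sim,
                         t_end = 0.06 - dt_sim, record_dt = dt_sim,
                         init = st$init)
    if (sim$status != "ok") return(0)
    relative_release(sim$rate, 12, 8, base_rate)
  }
}

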