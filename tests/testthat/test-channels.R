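test_that("temperature correction follows the Q10 law", {
  expect_equal(eta_t(1, 37, 22), 1)
  expect_equal(eta_t(2, 25, 25), 1)
  expect_equal(eta_t(2, 32, 22), 2)
  expect_equal(eta_t(3, 17, 37), 1 / 9)
  expect_error(eta_t(-1, 30, 22), "q10")
})

test_that("the CaL rates hit their analytic anchor points", {
  # removable singularity: alpha(-15) -> 1/ms by the analytic limit
  expect_equal(cal_alpha(-15), 1)
  # continuity around the singularity
  expect_lt(abs(cal_alpha(-15 + 1e-7) - cal_alpha(-15 - 1e-7)), 1e-6)
  # exponent zero: beta(-38) = 5/ms
  expect_equal(cal_beta(-38), 5)

  g <- hh_gate(3, cal_alpha, cal_beta)
  r <- cal_rates(c(-15, -38), g, tsim = 22, q10 = 2, teq = 22)
  expect_equal(r$alpha[1], 1)
  expect_equal(r$beta[2], 5)
})

test_that("rate modifiers shift and scale exactly and are neutral at defaults", {
  v <- seq(-80, 0, by = 2.5)
  g0 <- hh_gate(3, cal_alpha, cal_beta)
  g5 <- hh_gate(3, cal_alpha, cal_beta, dVa = 5)
  r0 <- cal_rates(v - 5, g0, tsim = 30)
  r5 <- cal_rates(v, g5, tsim = 30)
  expect_identical(r5$alpha, r0$alpha)       # alpha(V; dVa=5) = alpha(V-5)
  gt <- hh_gate(3, cal_alpha, cal_beta, tau_a = 2, tau_b = 4)
  rt <- cal_rates(v, gt, tsim = 22, q10 = 2, teq = 22)
  rb <- cal_rates(v, g0, tsim = 22, q10 = 2, teq = 22)
  expect_identical(rt$alpha, rb$alpha / 2)
  expect_identical(rt$beta, rb$beta / 4)
  # neutral modifiers reproduce the base rates bitwise
  gn <- hh_gate(3, cal_alpha, cal_beta, dVa = 0, dVb = 0, tau_a = 1, tau_b = 1)
  rn <- cal_rates(v, gn, tsim = 31.7)
  expect_identical(rn$alpha, eta_t(2, 31.7, 22) * cal_alpha(v))
})

test_that("channel conductance composes gates and Markov occupancies", {
  expect_equal(channel_conductance(1, 2e-9, powers = 3L), 2e-9)
  expect_equal(channel_conductance(0.5, 8e-9, powers = 3L), 1e-9)
  expect_equal(channel_conductance(c(1, 0, 0, 0), 5e-9, open = 4), 0)
  expect_equal(channel_conductance(c(0, 0, 0.25, 0.75), 4e-9, open = 3:4),
               4e-9)
  expect_error(channel_conductance(c(0.5, 0.2), 1, open = 1), "sum to 1")
})

test_that("ribbon release follows the squared-calcium pool law", {
  syn <- ribbon_synapse(vmax_pool = 10, gl = 1, rmsr = 8, pool = 0)
  expect_equal(ribbon_release_rate(5, syn), 0)
  syn$pool <- 10
  expect_equal(ribbon_release_rate(1, syn), 1)
  expect_equal(ribbon_release_rate(2, syn), 4 * ribbon_release_rate(1, syn))
})

test_that("the pool replenishes at rmsr and is always within bounds", {
  syn <- ribbon_synapse(vmax_pool = 10, gl = 1, rmsr = 8, pool = 10)
  expect_equal(rrp_update(syn, 0, 1)$pool, 10)       # full pool: no change
  syn$pool <- 0
  expect_equal(rrp_update(syn, 0, 1)$pool, 8)        # empty pool: + rmsr*dt

  # long run at saturating calcium: mean release -> rmsr within 2%
  syn <- ribbon_synapse(vmax_pool = 10, gl = 1, rmsr = 8, pool = 10)
  dt <- 1e-3
  rates <- numeric(20000)
  for (i in seq_along(rates)) {
    r <- ribbon_release_rate(100, syn)
    rates[i] <- r
    syn <- rrp_update(syn, r, dt)
  }
  expect_equal(mean(rates[2001:20000]), 8, tolerance = 0.02)

  # pool bounds under randomized calcium drive
  set.seed(11)
  syn <- ribbon_synapse(vmax_pool = 12, gl = 40, rmsr = 8, pool = 12)
  ca <- abs(stats::rnorm(5000, 0.5, 1))
  for (i in seq_along(ca)) {
    r <- ribbon_release_rate(ca[i], syn)
    syn <- rrp_update(syn, r, 5e-3)
    expect_true(syn$pool >= 0 && syn$pool <= 12)
  }
})

test_that("the calcium store has the stated equilibrium and pump behavior", {
  st <- calcium_store(ca_rest = 0.1, capk = 2, vmax = 50, kappa = 1e14,
                      ca = 0.1)
  expect_equal(calcium_update(st, 0, 1e-3)$ca, 0.1)   # equilibrium at rest
  # at ca = capk the pump runs at half its maximum
  st$ca <- 2
  st2 <- calcium_update(st, 0, 1e-4)
  drift <- (st2$ca - 2) / 1e-4
  s0 <- 50 * 0.1 / 2.1
  expect_equal(drift, -(50 / 2 - s0), tolerance = 1e-9)
  # step influx then off: monotone relaxation to rest, matching a
  # fine-step scalar reference
  st$ca <- 0.1
  for (i in 1:2000) st <- calcium_update(st, 2e-14, 1e-4)
  ca_hi <- st$ca
  expect_gt(ca_hi, 0.1)
  trace <- numeric(3000)
  for (i in seq_along(trace)) { st <- calcium_update(st, 0, 1e-4); trace[i] <- st$ca }
  expect_true(all(diff(trace) <= 1e-12))
  ref <- ca_hi
  for (i in 1:30000) {
    ref <- max(0, ref + 1e-5 * (-50 * ref / (ref + 2) + 50 * 0.1 / 2.1))
  }
  expect_equal(trace[3000], ref, tolerance = 1e-3)
})

test_that("postsynaptic receptors have the stated sign conventions", {
  dt <- 1e-3
  kai <- postsynaptic_receptor("kainate", tau_gamma = 30)
  mg <- postsynaptic_receptor("mGluR6")
  z <- rep(0, 100)
  expect_equal(max(receptor_drive(z, kai, dt)), 0)
  expect_equal(min(receptor_drive(z, mg, dt)), 1)    # maximal when silent

  # kainate desensitization half-life doubles with tau_gamma
  step <- c(rep(0, 10), rep(200, 990))
  half_life <- function(tau) {
    o <- receptor_drive(step, postsynaptic_receptor("kainate",
                                                    tau_gamma = tau), dt)
    pk <- max(o); fin <- o[length(o)]
    which(o[-(1:which.max(o))] <= fin + (pk - fin) / 2)[1] * dt
  }
  h1 <- half_life(25); h2 <- half_life(50)
  expect_equal(h2 / h1, 2, tolerance = 0.05)

  # STC = 2 is equivalent to doubling the transmitter input
  g <- abs(stats::rnorm(200, 50, 30))
  o1 <- receptor_drive(g, postsynaptic_receptor("kainate", stc = 2), dt)
  o2 <- receptor_drive(2 * g, postsynaptic_receptor("kainate", stc = 1), dt)
  expect_identical(o1, o2)
})

test_that("the phototransduction surrogate is monotone and tracks its ODE", {
  ph <- phototransduction()
  dt <- 1e-3
  i10 <- photocurrent(rep(10e3, 3000), ph, dt)
  i31 <- photocurrent(rep(31e3, 3000), ph, dt)
  expect_lt(max(abs(diff(tail(i10, 100)))), 1e-18)   # settles to constant
  expect_lt(i31[3000], i10[3000])                    # more hyperpolarizing
  expect_true(all(i10 <= 0))

  # published stimulus range: step from 10e3 to 31e3 P*/s, compared to a
  # 40x finer integration of the same cascade (truncation-error check)
  step <- c(rep(10e3, 500), rep(31e3, 1500))
  coarse <- photocurrent(step, ph, dt)
  fine <- photo_reference(step, ph, dt)
  expect_lt(max(abs(coarse - fine)) / max(abs(fine)), 2e-2)
  # transient then adapted plateau: peak exceeds the adapted level
  seg <- coarse[501:2000]
  expect_lt(min(seg), seg[length(seg)] - 1e-14)
})

test_that("an HH gate and its Markov chain expansion are equivalent", {
  mk_cell <- function(markov) {
    r_um <- sqrt(1000 / (4 * pi))
    m <- morphology(data.frame(id = 1, parent = -1, x = 0, y = 0, z = 0,
                               radius = r_um, type = 1))
    cp <- compartmentalize(m, membrane_spec(Vr = -60))
    cell <- cell_model(cp, tsim = 32)
    spec <- cal_channel()
    if (markov) spec <- hh_equivalent_markov(spec)
    add_channel(cell, spec, 1, 3)
  }
  drv <- list(i_inj = list(list(comp = 1, trace = 8e-12)))
  r_hh <- simulate_cell(mk_cell(FALSE), drv, dt = 5e-5, t_end = 0.2,
                        record_dt = 1e-3)
  r_ms <- simulate_cell(mk_cell(TRUE), drv, dt = 5e-5, t_end = 0.2,
                        record_dt = 1e-3)
  expect_lt(max(abs(r_hh$Vm - r_ms$Vm)) / diff(range(r_hh$Vm)), 1e-6)
  # occupancy conservation after a nontrivial trajectory
  p <- r_ms$final$gates$markov[[1]]
  expect_lt(abs(sum(p) - 1), 1e-9)
  expect_true(all(p >= -1e-12))
})
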