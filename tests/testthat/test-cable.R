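# single passive compartment used throughout (tau = rm * cm = 10 ms)
single_comp_cell <- function(Rm = 1e4, Cm = 1, Vr = -60) {
  r_um <- sqrt(1000 / (4 * pi))   # 1000 um^2 sphere
  m <- morphology(data.frame(id = 1, parent = -1, x = 0, y = 0, z = 0,
                             radius = r_um, type = 1))
  cp <- compartmentalize(m, membrane_spec(Rm = Rm, Cm = Cm, Vr = Vr))
  list(cell = cell_model(cp), comps = cp)
}

test_that("a passive compartment at rest stays at rest", {
  sc <- single_comp_cell()
  r <- simulate_cell(sc$cell, dt = 1e-5, t_end = 0.05, record_dt = 1e-3)
  expect_equal(r$status, "ok")
  expect_lt(max(abs(r$Vm - (-60))), 1e-12)
})

test_that("passive relaxation matches the RC closed form to 1e-6", {
  sc <- single_comp_cell()
  tau <- sc$comps$rm * sc$comps$cm
  r <- simulate_cell(sc$cell, dt = 1e-5, t_end = 0.05, record_dt = 1e-3,
                     v0 = -50)
  vref <- -60 + 10 * exp(-r$time / tau)
  expect_lt(max(abs(r$Vm[1, ] - vref)) / 10, 1e-6)
})

test_that("two coupled compartments track the matrix-exponential oracle", {
  nodes <- data.frame(id = 1:2, parent = c(-1, 1), x = c(0, 15), y = 0,
                      z = 0, radius = c(3, 1), type = c(1, 3))
  cp <- compartmentalize(morphology(nodes), membrane_spec(Vr = -60))
  cell <- cell_model(cp)
  istep <- 5e-12
  r <- simulate_cell(cell,
                     drive = list(i_inj = list(list(comp = 2, trace = istep))),
                     dt = 5e-6, t_end = 0.03, record_dt = 1e-3)
  sys <- passive_system(cp, -60)
  s <- sys$s; s[2] <- s[2] + istep
  vref <- linear_cable_oracle(sys$cm, sys$B, s, rep(-0.060, 2), r$time) * 1e3
  expect_lt(max(abs(r$Vm - vref)) / diff(range(vref)), 1e-6)
})

test_that("extracellular forcing obeys the shift and linear-gradient laws", {
  sc <- single_comp_cell()
  n_steps <- round(0.05 / 1e-5)
  r0 <- simulate_cell(sc$cell, dt = 1e-5, t_end = 0.05, record_dt = 1e-3,
                      v0 = -50)
  # vex identically zero changes nothing
  cz <- apply_vex(sc$cell, matrix(0, 1, n_steps + 1))
  rz <- simulate_cell(cz, dt = 1e-5, t_end = 0.05, record_dt = 1e-3,
                      v0 = -50)
  expect_identical(rz$Vm, r0$Vm)
  # spatially uniform constant vex shifts the transmembrane potential
  cu <- apply_vex(sc$cell, matrix(25, 1, n_steps + 1))
  ru <- simulate_cell(cu, dt = 1e-5, t_end = 0.05, record_dt = 1e-3,
                      v0 = -50 + 25)
  expect_lt(max(abs((ru$Vm - 25) - r0$Vm)), 1e-9)

  # linear-in-space vex across a 3-compartment cable: net membrane charge
  # evolution matches the dense linear-system oracle
  nodes <- data.frame(id = 1:3, parent = c(-1, 1, 2), x = c(0, 15, 30),
                      y = 0, z = 0, radius = c(3, 1, 1), type = c(1, 3, 3))
  cp <- compartmentalize(morphology(nodes), membrane_spec(Vr = -60))
  vex_mv <- c(0, 5, 10)
  cell <- cell_model(cp)
  cell <- apply_vex(cell, matrix(vex_mv, 3, round(0.03 / 5e-6) + 1))
  r <- simulate_cell(cell, dt = 5e-6, t_end = 0.03, record_dt = 1e-3)
  sys <- passive_system(cp, -60)
  gl <- ifelse(is.finite(cp$rm), 1 / cp$rm, 0)
  s <- sys$s + gl * vex_mv * 1e-3
  vref <- linear_cable_oracle(sys$cm, sys$B, s, rep(-0.060, 3), r$time) * 1e3
  expect_lt(max(abs(r$Vm - vref)), 1e-6 * max(abs(vref)))
  q_sim <- colSums(r$Vm * cp$cm)
  q_ref <- colSums(vref * cp$cm)
  expect_equal(q_sim, q_ref, tolerance = 1e-6)
})

test_that("a leakless isolated cable conserves total membrane charge", {
  nodes <- data.frame(id = 1:4, parent = c(-1, 1, 2, 3),
                      x = seq(0, 45, by = 15), y = 0, z = 0,
                      radius = c(3, 1, 1, 1), type = c(1, 3, 3, 3))
  cp <- compartmentalize(morphology(nodes), membrane_spec(Rm = Inf))
  cell <- cell_model(cp)
  r <- simulate_cell(cell, dt = 1e-5, t_end = 0.02, record_dt = 1e-3,
                     v0 = c(-40, -80, -60, -55))
  q <- colSums(r$Vm * cp$cm)
  expect_lt(max(abs(q - q[1])) / abs(q[1]), 1e-9)
})

test_that("halving the step changes the passive step response by < 1e-4", {
  sc <- single_comp_cell()
  drv <- list(i_inj = list(list(comp = 1, trace = 10e-12)))
  r1 <- simulate_cell(sc$cell, drv, dt = 2e-5, t_end = 0.04, record_dt = 0.04)
  r2 <- simulate_cell(sc$cell, drv, dt = 1e-5, t_end = 0.04, record_dt = 0.04)
  v1 <- r1$Vm[1, ncol(r1$Vm)]; v2 <- r2$Vm[1, ncol(r2$Vm)]
  expect_lt(abs(v1 - v2) / abs(v2 + 60), 1e-4)
})

test_that("seeded runs are bitwise identical", {
  tc <- toy_bc_cell()
  drv <- list(g_syn = list(list(comp = 1, erev = 0, trace = 3e-11)))
  r1 <- simulate_cell(tc$cell, drv, dt = 1e-4, t_end = 0.2, record_dt = 1e-3,
                      seed = 42)
  r2 <- simulate_cell(tc$cell, drv, dt = 1e-4, t_end = 0.2, record_dt = 1e-3,
                      seed = 42)
  expect_identical(r1$Vm, r2$Vm)
  expect_identical(r1$rate, r2$rate)
})

test_that("non-finite blowups are reported as unstable, not raised", {
  sc <- single_comp_cell()
  # absurd current injection drives the voltage past the stability guard
  r <- simulate_cell(sc$cell,
                     drive = list(i_inj = list(list(comp = 1, trace = 1))),
                     dt = 1e-4, t_end = 0.05, record_dt = 1e-3)
  expect_equal(r$status, "unstable")
})

test_that("the voltage-clamp screen separates passive from bistable cells", {
  sc <- single_comp_cell()
  expect_equal(voltage_clamp_screen(sc$cell), "ok")

  # regenerative inward conductance with a stable depolarized equilibrium
  bi <- single_comp_cell()
  nap <- hh_channel_spec(
    "NaP-like",
    list(hh_gate(1,
                 alpha = function(v) 5 / (1 + exp(-(v + 40) / 3)),
                 beta = function(v) 5 - 5 / (1 + exp(-(v + 40) / 3)))),
    erev = 30, q10 = 1, teq = 37, surrogate = TRUE)
  cell <- add_channel(bi$cell, nap, 1, 0.5)   # 5x the leak conductance
  expect_equal(voltage_clamp_screen(cell), "depolarized_equilibrium")
})
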