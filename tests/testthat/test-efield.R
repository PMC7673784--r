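# homogeneous big-domain model approximating a half space (for closed-form
# comparisons); material equal in both layers
halfspace_model <- function(grid = "fine") {
  retina_field_model(sigma_retina = 1.54, eps_retina = 78, grid = grid,
                     radius_um = 10000, h_bath_um = 10000)
}

test_that("the single-disk field matches the half-space kernel integration", {
  f <- solve_field(halfspace_model(), istim = 0.5e-6, frequency = 0)
  zq <- c(2, 5, 10, 20, 50) * 1e-6
  v_num <- Re(field_at(f, 0, 0, zq))
  v_ref <- halfspace_disk_onaxis(0.5e-6, 15e-6, 1.54, zq)
  expect_lt(max(abs(v_num / v_ref - 1)), 0.02)
  # off-axis point against direct quadrature of the kernel
  v_off <- Re(field_at(f, 40e-6, 0, 25e-6))
  v_off_ref <- halfspace_disk_offaxis(0.5e-6, 15e-6, 1.54, 40e-6, 25e-6)
  expect_lt(abs(v_off / v_off_ref - 1), 0.02)
})

test_that("current is conserved through every horizontal plane", {
  f <- solve_field(retina_field_model(grid = "default"), istim = 0.5e-6,
                   frequency = 0)
  for (z in c(20, 50, 100, 500, 1500) * 1e-6) {
    expect_lt(abs(Re(plane_current(f, z)) - 0.5e-6) / 0.5e-6, 0.005)
  }
  # complex (capacitive) case conserves the complex current
  f25 <- solve_field(retina_field_model(grid = "coarse"), istim = 0.5e-6,
                     frequency = 25)
  for (z in c(50, 500) * 1e-6) {
    expect_lt(Mod(plane_current(f25, z) - 0.5e-6) / 0.5e-6, 0.005)
  }
})

test_that("the field is linear in the stimulation current", {
  m <- retina_field_model(grid = "coarse")
  f1 <- solve_field(m, istim = 0.5e-6, frequency = 0)
  f2 <- solve_field(m, istim = 1.0e-6, frequency = 0)
  expect_equal(f2$V, 2 * f1$V, tolerance = 1e-10)
})

test_that("solver error shrinks by at least 1.8x per grid refinement", {
  zq <- c(5, 10, 20) * 1e-6
  err <- vapply(c("coarse", "default", "fine"), function(g) {
    f <- solve_field(halfspace_model(g), istim = 0.5e-6, frequency = 0)
    v <- Re(field_at(f, 0, 0, zq))
    max(abs(v / halfspace_disk_onaxis(0.5e-6, 15e-6, 1.54, zq) - 1))
  }, numeric(1))
  expect_gt(err["coarse"] / err["default"], 1.8)
  expect_gt(err["default"] / err["fine"], 1.8)
})

test_that("array superposition reduces to the single disk and is symmetric", {
  m <- retina_field_model(grid = "coarse")
  single <- solve_field(m, istim = 0.5e-6, frequency = 0)
  arr1 <- superpose_electrodes(m, 1, istim_total = 0.5e-6)
  pts <- cbind(c(0, 30e-6, 100e-6), 0, c(20e-6, 40e-6, 60e-6))
  expect_equal(array_field_at(arr1, pts[, 1], pts[, 2], pts[, 3]),
               field_at(single, pts[, 1], pts[, 2], pts[, 3]))

  # 2x2 layout: invariant under 90-degree rotation about the array center
  arr2 <- superpose_electrodes(m, 2, istim_total = 0.5e-6)
  v_a <- array_field_at(arr2, 55e-6, 10e-6, 30e-6)
  v_b <- array_field_at(arr2, -10e-6, 55e-6, 30e-6)
  expect_lt(Mod(v_a - v_b), 1e-9 * Mod(v_a))
  expect_error(superpose_electrodes(m, 2, centers = rbind(c(0, 0), c(1e-5, 0))),
               "overlapping")
})

test_that("a 10x10 array agrees with the analytic half-space superposition", {
  m <- halfspace_model("default")
  arr <- superpose_electrodes(m, 10, istim_total = 1e-6)
  # brute-force oracle: quadrature of the half-space kernel per disk
  pts <- rbind(c(0, 0, 30e-6), c(100e-6, 50e-6, 50e-6), c(400e-6, 0, 80e-6))
  for (k in seq_len(nrow(pts))) {
    v_num <- Re(array_field_at(arr, pts[k, 1], pts[k, 2], pts[k, 3]))
    v_ref <- 0
    for (e in seq_len(nrow(arr$centers))) {
      r <- sqrt((pts[k, 1] - arr$centers[e, 1])^2 +
                  (pts[k, 2] - arr$centers[e, 2])^2)
      v_ref <- v_ref + halfspace_disk_offaxis(1e-6 / 100, 15e-6, 1.54,
                                              r, pts[k, 3], n = 60)
    }
    expect_lt(abs(v_num / v_ref - 1), 0.05)
  }
})

test_that("compartment extracellular voltages follow placement and decay", {
  m <- retina_field_model(grid = "default")
  f <- solve_field(m, istim = 0.5e-6, frequency = 0)
  # deeper on-axis compartments see monotonically smaller voltages
  z <- seq(5, 100, by = 5) * 1e-6
  v <- Re(field_at(f, 0, 0, z))
  expect_true(all(diff(v) < 0))
  # at the return electrode plane the potential vanishes
  v_top <- Re(field_at(f, 0, 0, max(f$zf)))
  expect_lt(abs(v_top), 1e-3 * max(v))
  # symmetric compartments see equal voltages
  expect_equal(field_at(f, 20e-6, 0, 30e-6), field_at(f, -20e-6, 0, 30e-6))
  # out-of-domain query errors
  expect_error(field_at(f, 0, 0, 1), "outside")

  # vex scaling by waveform, and placement via place_cell
  tc <- toy_bc_cell()
  pos <- place_cell(tc$comps, xy_um = c(0, 0), z_soma_um = 30)
  expect_equal(unname(pos[2, 3]), 30e-6)  # soma at 30 um
  wave <- c(0, 0.5e-6, -0.5e-6, 0)
  vex <- vex_at_compartments(f, pos, wave)
  expect_equal(dim(vex), c(4, 4))
  expect_equal(vex[, 1], rep(0, 4))
  expect_equal(vex[, 3], -vex[, 2])
})

test_that("sinusoid fitting is exact on clean data and unbiased in noise", {
  dt <- 1e-4
  t <- seq(0, 0.4, by = dt)
  x <- 2.5 * sin(2 * pi * 25 * t + 0.7) + 1.2
  ft <- fit_sinusoid(x, 25, dt)
  expect_equal(ft$A, 2.5, tolerance = 1e-10)
  expect_equal(ft$phi, 0.7, tolerance = 1e-10)
  expect_equal(ft$offset, 1.2, tolerance = 1e-10)
  # phase convention: a pure sine has phi = 0
  f0 <- fit_sinusoid(sin(2 * pi * 25 * t), 25, dt)
  expect_equal(f0$phi, 0, tolerance = 1e-10)
  expect_error(fit_sinusoid(x[1:100], 25, dt), "3 periods")

  # amplitude unbiased within 1% at SNR 20
  set.seed(8)
  amps <- replicate(60, {
    fit_sinusoid(2.5 * sin(2 * pi * 25 * t) + rnorm(length(t), 0, 2.5 / 20),
                 25, dt)$A
  })
  expect_equal(mean(amps), 2.5, tolerance = 0.01)
})

test_that("the RC relations invert the parallel-circuit impedance exactly", {
  dt <- 1e-4
  t <- seq(0, 0.4, by = dt)
  run_case <- function(R, C, f) {
    Z <- parallel_rc_impedance(R, C, f)
    iph <- 1e-6
    i <- Im(iph * exp(1i * 2 * pi * f * t))
    v <- Im(iph * Z * exp(1i * 2 * pi * f * t))
    rc <- electrode_rc(fit_sinusoid(v, f, dt), fit_sinusoid(i, f, dt), f)
    expect_equal(rc$Re, R, tolerance = 1e-9)
    expect_equal(rc$Ce, C, tolerance = 1e-9)
  }
  run_case(1e6, 1e-9, 25)
  run_case(1e6, 1e-9, 40)   # same circuit at another frequency
  set.seed(3)
  for (i in 1:20) {
    run_case(10^runif(1, 4, 7), 10^runif(1, -10, -8), runif(1, 10, 100))
  }
  # purely resistive: zero phase, Ce = 0
  i <- sin(2 * pi * 25 * t)
  v <- 5e5 * i
  rc0 <- electrode_rc(fit_sinusoid(v, 25, dt), fit_sinusoid(i, 25, dt), 25)
  expect_equal(rc0$Ce, 0, tolerance = 1e-12)
  expect_equal(rc0$Re, 5e5, tolerance = 1e-9)
})

test_that("the circuit current matches a layered-admittance hand calculation", {
  dt <- 2e-4
  t <- seq(0, 0.2, by = dt)
  m <- retina_field_model(sigma_retina = 0.076, eps_retina = 1.1e7,
                          grid = "fine")
  rc <- list(Re = 1e6, Ce = 4e-9)
  f <- 25
  vstim <- 0.3 * sin(2 * pi * f * t)
  i_sim <- simulate_circuit_current(vstim, rc, m, f, dt)
  # independent route: Hankel-mode layered admittance, phasor division
  om <- 2 * pi * f
  k1 <- complex(real = 0.076, imaginary = om * 1.1e7 * 8.8541878128e-12)
  k2 <- complex(real = 1.54, imaginary = om * 78 * 8.8541878128e-12)
  Y <- layered_admittance_oracle(1e-6, 15e-6, k1, k2, 105e-6, 2.105e-3)
  Iph <- 0.3 / (parallel_rc_impedance(1e6, 4e-9, f) + 1 / Y)
  i_ref <- Im(Iph * exp(1i * om * t))
  expect_lt(max(abs(i_sim - i_ref)) / max(abs(i_ref)), 0.02)

  # homogeneity limit: retina material equal to the bath reproduces the
  # no-retina circuit current
  m_ames <- m; m_ames$sigma_retina <- m$sigma_bath
  m_ames$eps_retina <- m$eps_bath
  i_h <- simulate_circuit_current(vstim, rc, m_ames, f, dt)
  m_none <- retina_field_model(sigma_retina = 1.54, eps_retina = 78,
                               grid = "fine")
  i_n <- simulate_circuit_current(vstim, rc, m_none, f, dt)
  expect_equal(i_h, i_n, tolerance = 1e-10)
  # linearity in the stimulus
  i_2 <- simulate_circuit_current(2 * vstim, rc, m, f, dt)
  expect_equal(i_2, 2 * i_sim, tolerance = 1e-9)
})

test_that("tissue parameters are recovered from synthetic currents", {
  dt <- 2e-4
  m <- retina_field_model(grid = "coarse")
  syn <- make_synthetic_electrode_recordings(
    Re_el = 1e6, Ce_el = 4e-9, sigma_star = 0.09, eps_star = 8e6,
    model_template = m, amps_25 = c(0.2, 0.4), dt = dt, seed = 5)
  stimuli <- lapply(syn$recordings, function(r) {
    list(vstim = r$vstim, target = r$i_retina, f = r$f,
         rc = list(Re = 1e6, Ce = 4e-9))
  })
  fit <- infer_tissue_params(stimuli, m, dt, seed = 2)
  expect_equal(fit$sigma_retina, 0.09, tolerance = 0.05)
  expect_equal(fit$eps_retina, 8e6, tolerance = 0.05)
  # discrepancy at the generating parameters is minimal; a 10x wrong
  # conductivity is strictly worse
  d_true <- retinasim:::.tissue_discrepancy(0.09, 8e6, stimuli, m, dt)
  d_off <- retinasim:::.tissue_discrepancy(0.9, 8e6, stimuli, m, dt)
  expect_lt(d_true, d_off)
  expect_error(infer_tissue_params(stimuli[1], m, dt), "2 frequencies")
})
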