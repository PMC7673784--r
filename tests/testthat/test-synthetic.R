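test_that("the chirp stimulus has the specified segment structure", {
  spec <- chirp_spec()
  ch <- make_chirp(spec)
  expect_true(all(ch$y >= 0 & ch$y <= 1))
  total <- spec$baseline_s + spec$step_s + spec$rest1_s + spec$fsweep_s +
    spec$rest2_s + spec$csweep_s + spec$rest3_s
  expect_equal(length(ch$y) * ch$dt, total, tolerance = 1e-6)
  # baseline-only spec gives a constant trace
  flat <- make_chirp(chirp_spec(baseline_s = 2, step_s = 0, rest1_s = 0,
                                fsweep_s = 0, rest2_s = 0, csweep_s = 0,
                                rest3_s = 0))
  expect_equal(stats::sd(flat$y), 0)

  # frequency sweep: zero-crossing spacing decreases monotonically
  t0 <- spec$baseline_s + spec$step_s + spec$rest1_s
  idx <- which(ch$t >= t0 + 0.3 & ch$t < t0 + spec$fsweep_s)
  seg <- ch$y[idx] - spec$base_level
  zc <- which(diff(sign(seg)) != 0)
  gaps <- diff(zc)
  # instantaneous frequency rises: early half-periods are much longer
  expect_gt(mean(utils::head(gaps, 5)), 2 * mean(utils::tail(gaps, 5)))
  expect_lt(stats::cor(seq_along(gaps), gaps), -0.6)

  # rectified variant differs only below the 20% level
  chr <- make_chirp(chirp_spec(rectify = TRUE))
  hi <- ch$y >= 0.2
  expect_equal(chr$y[hi], ch$y[hi])
  expect_true(all(chr$y[!hi] > ch$y[!hi]))
})

test_that("stimulus calibration maps intensity to photon rates", {
  ch <- make_chirp(chirp_spec(baseline_s = 1, step_s = 1, rest1_s = 0.5,
                              fsweep_s = 2, rest2_s = 0.5, csweep_s = 2,
                              rest3_s = 0.5))
  cal <- calibrate_stimulus(ch$y, dt = ch$dt)
  expect_equal(cal$rate, 10e3 + (31e3 - 10e3) * ch$y, tolerance = 1e-12)
  expect_equal(unname(calibrate_stimulus(0, dt = ch$dt)$rate), 10e3)
  expect_equal(unname(calibrate_stimulus(1, dt = ch$dt)$rate), 31e3)
  expect_equal(cal$shift_s, 0)

  # identity recording: timing correction is zero
  cal0 <- calibrate_stimulus(ch$y, 1 / (1 + exp(-8 * (ch$y - 0.5))),
                             dt = ch$dt)
  expect_equal(cal0$shift_s, 0, tolerance = 1e-9)

  # sigmoid distortion plus 20 ms delay is recovered
  k_true <- 6; x0_true <- 0.45
  delayed <- retinasim:::.shift_trace(ch$y, round(0.02 / ch$dt))
  recorded <- 1 / (1 + exp(-k_true * (delayed - x0_true)))
  cal2 <- calibrate_stimulus(ch$y, recorded, dt = ch$dt)
  expect_equal(cal2$shift_s, 0.02, tolerance = ch$dt)
  expect_equal(cal2$sigmoid$k, k_true, tolerance = 0.02)
  expect_equal(cal2$sigmoid$x0, x0_true, tolerance = 0.02)
})

test_that("trace alignment recovers constructed shifts and reduces error", {
  set.seed(3)
  base <- as.numeric(stats::filter(rnorm(800), rep(1 / 20, 20),
                                   method = "convolution", sides = 2))
  base[is.na(base)] <- 0
  shifted <- retinasim:::.shift_trace(base, 5)
  al <- align_mean_traces(list(base, shifted), max_shift = 20)
  expect_equal(al$shifts[2], -5)
  expect_equal(align_mean_traces(list(base, base))$shifts, c(0, 0))
  expect_equal(align_mean_traces(list(base, base))$mean, base)
  # aligned trace is no farther from the reference than the raw one
  aligned2 <- retinasim:::.shift_trace(shifted, al$shifts[2])
  expect_lte(mean((base - aligned2)^2), mean((base - shifted)^2))
  expect_error(align_mean_traces(list(base)), "at least 2")
})

test_that("target generation is affine-invariant and noise-floor calibrated", {
  dt <- 2e-3
  r <- 40 + 30 * abs(sin(seq(0, 10, by = dt)))
  # zero noise, identity affine: a perfect round trip
  tg0 <- generate_target(r, dt, seed = 1, noise_sd = 0)
  nu <- iglusnfr_from_release(r, dt)
  expect_lt(delta_iglusnfr(tg0$target, nu), 1e-10)
  # affine map leaves the discrepancy unchanged
  tg2 <- generate_target(r, dt, seed = 1, noise_sd = 0, affine = c(5, 2))
  expect_lt(delta_iglusnfr(tg2$target, nu), 1e-10)
  expect_error(generate_target(r, dt, affine = c(0, -1)), "b must be > 0")
  expect_error(generate_target(rep(1, 100), dt, convolve = FALSE),
               "constant")

  # at 10% noise the discrepancy at the truth sits near the analytic floor
  tgn <- generate_target(r, dt, seed = 7, noise_sd = 0.1)
  floor_an <- delta_noise_floor(nu, tgn$noise_sd_abs)
  expect_equal(delta_iglusnfr(tgn$target, nu), floor_an, tolerance = 0.2)
})

test_that("synthetic electrode recordings support exact RC recovery", {
  m <- retina_field_model(grid = "coarse")
  syn <- make_synthetic_electrode_recordings(
    Re_el = 8e5, Ce_el = 2e-9, sigma_star = 0.08, eps_star = 9e6,
    model_template = m, amps_25 = c(0.2, 0.4), dt = 1e-4, seed = 3)
  expect_equal(length(syn$recordings), 4)
  # 40 Hz amplitudes are halved
  f25 <- vapply(syn$recordings, function(r) r$f, numeric(1))
  a25 <- vapply(syn$recordings, function(r) r$amp, numeric(1))
  expect_equal(a25[f25 == 40], a25[f25 == 25] / 2)

  # noise-free chain: v_electrode = vstim - i * Z_tissue, then the RC
  # relations recover the generating electrode values
  ames <- m; ames$sigma_retina <- m$sigma_bath; ames$eps_retina <- m$eps_bath
  for (rec in syn$recordings[1:2]) {
    Y <- solve_field(ames, 1e-6, rec$f)$Y
    i_fit <- fit_sinusoid(rec$i_ames, rec$f, rec$dt)
    iph <- i_fit$A * exp(1i * i_fit$phi)
    vph_el <- rec$amp - iph / Y
    t <- (seq_along(rec$vstim) - 1) * rec$dt
    v_el <- Im(vph_el * exp(1i * 2 * pi * rec$f * t))
    rc <- electrode_rc(fit_sinusoid(v_el, rec$f, rec$dt), i_fit, rec$f)
    expect_equal(rc$Re, 8e5, tolerance = 1e-6)
    expect_equal(rc$Ce, 2e-9, tolerance = 1e-6)
  }
})

test_that("every discrepancy component can be activated by a fixture", {
  dt <- 2e-3
  bounds <- default_penalty_bounds("off_bc")
  base_r <- 2 + 1.5 * sin(seq(0, 30, by = dt))
  base_v <- -55 + 6 * sin(seq(0, 30, by = dt))
  target <- generate_target(2 + abs(sin(seq(0, 30, by = dt))), dt,
                            seed = 2, noise_sd = 0.05)$target
  mk <- function(release = base_r, v = base_v, rest_r = 2, rest_v = -55) {
    discrepancy_vector(release, v, target, list(rate_rest = rest_r,
                                                v_rest = rest_v), bounds, dt)
  }
  expect_gt(mk()[["delta_iglusnfr"]], 0)
  expect_gt(mk(rest_r = 6.5)[["rate_rest"]], 0)
  expect_lt(mk(rest_v = -75)[["v_rest"]], 0)
  expect_lt(mk(release = rep(2, length(base_r)) + 1e-3 * base_r)[["rate_delta"]], 0)
  expect_lt(mk(v = -55 + 0.02 * (base_v + 55))[["v_delta"]], 0)
  expect_lt(mk(v = base_v - 40)[["v_min"]], 0)
  expect_gt(mk(v = base_v + 50)[["v_max"]], 0)
})

test_that("recovery experiments are reproducible and calibrated", {
  r1 <- recovery_experiment("passive", seed = 3, rounds = 1,
                            n_per_round = 120, stim_duration_s = 3)
  r2 <- recovery_experiment("passive", seed = 3, rounds = 1,
                            n_per_round = 120, stim_duration_s = 3)
  expect_identical(r1$theta_star, r2$theta_star)
  expect_identical(r1$ci, r2$ci)
  expect_identical(r1$best_delta, r2$best_delta)
  expect_s3_class(r1, "recovery_report")
  # the best sampled discrepancy cannot beat the noise floor by much, and
  # should approach it in a healthy run
  expect_gt(r1$best_delta, 0.5 * r1$noise_floor)
  expect_lt(r1$best_delta, 5 * r1$noise_floor)
})
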