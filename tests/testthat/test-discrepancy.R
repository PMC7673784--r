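test_that("the fluorescence kernel behaves as a causal exponential", {
  dt <- 2e-3
  n <- 500
  r <- numeric(n); r[100] <- 1
  nu <- iglusnfr_from_release(r, dt)
  # impulse response: kappa(t - t0) sampled on the grid
  k_ref <- exp(-(0:30) * dt / 0.060)
  expect_equal(nu[100 + 0:30], k_ref, tolerance = 1e-12)
  expect_equal(nu[99], 0)   # causal

  # constant input: steady value equals the truncated geometric sum
  nu_c <- iglusnfr_from_release(rep(3, n), dt)
  nk <- ceiling(5 * 0.060 / dt) + 1
  steady <- 3 * sum(exp(-(0:(nk - 1)) * dt / 0.060))
  expect_equal(nu_c[n], steady, tolerance = 1e-12)

  # linearity
  set.seed(4)
  a <- runif(n); b <- runif(n)
  expect_equal(iglusnfr_from_release(a + b, dt),
               iglusnfr_from_release(a, dt) + iglusnfr_from_release(b, dt),
               tolerance = 1e-12)
})

test_that("the trace discrepancy is affine-invariant and bounded", {
  x <- sin(seq(0, 20, by = 0.01)) + 0.3 * cos(seq(0, 60, by = 0.03))
  expect_equal(delta_iglusnfr(x, x), 0, tolerance = 1e-12)
  expect_equal(delta_iglusnfr(x, 3 + 2 * x), 0, tolerance = 1e-12)
  # anticorrelated: slope clipped at zero, value exactly 1
  expect_equal(delta_iglusnfr(x, -x), 1, tolerance = 1e-12)
  expect_error(delta_iglusnfr(rep(1, 10), x[1:10]), "constant")

  # never exceeds 1 for random traces (b >= 0 binds at the constant fit)
  set.seed(7)
  for (i in 1:200) {
    tg <- rnorm(100); sm <- rnorm(100)
    d <- delta_iglusnfr(tg, sm)
    expect_true(d >= 0 && d <= 1 + 1e-12)
  }
})

test_that("bounded penalties match their closed forms", {
  b <- penalty_bounds(-80, -55, -40, -20)
  expect_equal(bounded_penalty(-47, b), 0)
  expect_equal(bounded_penalty(-55, b), 0)
  expect_equal(bounded_penalty(-40, b), 0)
  expect_equal(bounded_penalty(-80, b), -(1 - exp(-2)))
  expect_equal(bounded_penalty(-1e6, b), -1, tolerance = 1e-12)
  expect_equal(bounded_penalty(1e6, b), 1, tolerance = 1e-12)
  # continuity at the free-interval edges
  expect_lt(abs(bounded_penalty(-55 - 1e-9, b)), 1e-12)
  expect_lt(abs(bounded_penalty(-40 + 1e-9, b)), 1e-12)
  # infinite bound disables the branch
  b2 <- penalty_bounds(-100, -80, Inf, Inf)
  expect_equal(bounded_penalty(1e9, b2), 0)
  expect_error(penalty_bounds(0, -1, 2, 3), "pl <= tl")
})

test_that("shipped bounds reproduce the per-class reference values", {
  cone <- default_penalty_bounds("cone")
  expect_equal(bounded_penalty(65, cone$rate_rest), 0)     # 65 in [50, 80]
  bc <- default_penalty_bounds("off_bc")
  # resting Vm of -70 mV: -1 + exp(-2 * 25 / 225)
  expect_equal(bounded_penalty(-70, bc$v_rest), -1 + exp(-2 * 25 / 225))
  on <- default_penalty_bounds("on_bc")
  expect_equal(on$rate_rest$tu, 3)
  expect_equal(bc$rate_rest$tu, 4)
  expect_equal(on$v_delta$tu, 15)
  expect_equal(bc$v_delta$tu, 25)
})

test_that("response deltas take the largest absolute excursions", {
  rest <- list(rate_rest = 10, v_rest = -50)
  r <- c(10, 10, 30, 10)
  v <- c(-50, -62, -43, -50)
  d <- response_deltas(r, v, rest)
  expect_equal(d$rate_delta, 20)
  expect_equal(d$v_delta, 12)
  d0 <- response_deltas(rep(10, 5), rep(-50, 5), rest)
  expect_equal(d0$rate_delta, 0)
  expect_equal(d0$v_delta, 0)
})

test_that("the seven-component vector assembles and totals correctly", {
  dt <- 2e-3
  set.seed(12)
  release <- 60 + 5 * sin(seq(0, 12 * pi, length.out = 2000)) +
    55 * pmax(0, sin(seq(0, 3 * pi, length.out = 2000)))
  v <- -50 + 8 * sin(seq(0, 12 * pi, length.out = 2000))
  target <- 2 + 0.5 * iglusnfr_from_release(release, dt)   # affine map
  rest <- list(rate_rest = 60, v_rest = -50)
  dv <- discrepancy_vector(release, v, target, rest,
                           default_penalty_bounds("cone"), dt)
  expect_equal(length(dv), 7)
  expect_equal(as.numeric(dv), rep(0, 7), tolerance = 1e-9)
  expect_equal(delta_total(dv), 0, tolerance = 1e-9)

  # magnitudes bounded by 1 and the total is the L1 norm, over random cases
  for (i in 1:50) {
    rr <- abs(rnorm(400, 50, 40))
    vv <- rnorm(400, -50, 20)
    tg <- rnorm(400)
    di <- discrepancy_vector(rr, vv, tg,
                             list(rate_rest = abs(rnorm(1, 50, 30)),
                                  v_rest = rnorm(1, -50, 15)),
                             default_penalty_bounds("cone"), dt)
    expect_true(all(abs(as.numeric(di)) <= 1 + 1e-12))
    expect_equal(delta_total(di), sum(abs(as.numeric(di))))
    expect_true(delta_total(di) == 0 || any(as.numeric(di) != 0))
  }
  expect_error(discrepancy_vector(release, v, target,
                                  list(rate_rest = NA, v_rest = -50),
                                  default_penalty_bounds("cone"), dt),
               "resting")
})

test_that("peak matching recovers constructed shifts and honors exclusions", {
  dt <- 2e-3
  t <- seq(0, 20, by = dt)
  x <- sin(2 * pi * 0.8 * t) * (1 + 0.2 * sin(2 * pi * 0.05 * t))
  p0 <- peak_time_differences(x, x, dt)
  expect_false(p0$empty)
  expect_equal(p0$median, 0)
  expect_true(all(p0$differences == 0))

  shift <- round(0.015 / dt)   # 16 ms on this grid
  xs <- c(rep(x[1], shift), x[seq_len(length(x) - shift)])
  ps <- peak_time_differences(x, xs, dt)
  expect_equal(ps$median, shift * dt, tolerance = 1e-9)

  # all peaks inside the exclusion window: empty result
  pe <- peak_time_differences(x, x, dt, exclude = list(c(0, 20)))
  expect_true(pe$empty)
  expect_true(is.na(pe$median))
})

test_that("peak detection respects prominence and separation settings", {
  dt <- 1e-3
  t <- seq(0, 2, by = dt)
  x <- sin(2 * pi * 2 * t) + 0.02 * sin(2 * pi * 40 * t)   # ripple < 10%
  pk <- find_peaks(x, dt, prominence = 0.1, min_sep = 0.05)
  expect_equal(nrow(pk), 4)   # four 2 Hz crests in 2 s
  pk2 <- find_peaks(x, dt, prominence = 0.005, min_sep = 0.001)
  expect_gt(nrow(pk2), 4)     # ripple peaks appear when thresholds drop
})
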