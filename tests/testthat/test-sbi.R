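test_that("the truncated-normal rejection sampler matches closed forms", {
  pr <- tn_prior(mean = 0.5, lower = 0, upper = 1)
  s <- sample_truncated(pr, 1e4, seed = 1)
  expect_true(all(s >= 0 & s <= 1))

  # half-normal: mean sqrt(2/pi) within 1% at n = 1e5
  hp <- tn_prior(mean = 0, lower = 0, upper = Inf, sd = 1)
  sh <- sample_truncated(hp, 1e5, seed = 2)
  expect_equal(mean(sh), sqrt(2 / pi), tolerance = 0.01)

  # a +-10 sigma box leaves the moments untruncated
  wp <- tn_prior(mean = 2, lower = 2 - 10, upper = 2 + 10, sd = 1)
  sw <- sample_truncated(wp, 5e4, seed = 3)
  expect_equal(mean(sw), 2, tolerance = 0.02)
  expect_equal(stats::sd(sw), 1, tolerance = 0.02)

  # a vanishingly thin box drives the acceptance rate below the guard
  bad <- tn_prior(mean = 0.5, lower = 0.5 - 1e-5, upper = 0.5 + 1e-5, sd = 1)
  expect_error(sample_truncated(bad, 1e4, seed = 4), "acceptance rate")
})

test_that("parameter normalization is an exact affine round trip", {
  pr <- tn_prior(mean = c(5, 50), lower = c(1, 20), upper = c(9, 100),
                 names = c("a", "b"))
  expect_equal(as.numeric(normalize_params(c(1, 20), pr)), c(0, 0))
  expect_equal(as.numeric(normalize_params(c(9, 100), pr)), c(1, 1))
  expect_equal(as.numeric(normalize_params(c(5, 60), pr)), c(0.5, 0.5))
  th <- sample_truncated(pr, 50, seed = 5)
  back <- denormalize_params(normalize_params(th, pr), pr)
  expect_equal(back, th, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(normalize_params(c(0, 50), pr), "outside")
})

test_that("the adaptive kernel follows the min/percentile update", {
  # crafted so the 20th percentile is exactly 0.3 (type-7 quantile)
  d1 <- c(0.1, 0.3, 0.5, 0.6, 0.7, 0.8)
  X <- cbind(d1, 0)
  ks <- kernel_update(X)
  expect_equal(ks$mu1, 0.1)
  expect_equal(ks$sigma1, 0.2)
  # degenerate round: bandwidth floored
  ks2 <- kernel_update(cbind(rep(0.4, 6), 0))
  expect_equal(ks2$sigma1, 1e-3)
  expect_error(kernel_update(cbind(1:3 / 10, 0)), "at least 5")

  # product kernel: the sample at the minimum gets the largest dim-1 factor
  X3 <- cbind(c(0.1, 0.2, 0.5), c(0, 0, 0), c(0.1, 0.1, 0.1))
  w <- kernel_weights(X3, kernel_update(rbind(X3, X3)))
  expect_equal(which.max(w), 1)
  # manual product check
  ks3 <- kernel_update(rbind(X3, X3))
  w_manual <- exp(-0.5 * ((X3[, 1] - ks3$mu1) / ks3$sigma1)^2) *
    exp(-0.5 * (X3[, 2] / 0.25)^2) * exp(-0.5 * (X3[, 3] / 0.25)^2)
  expect_equal(w, w_manual)
})

test_that("round-1 constant-head training equals the weighted Gaussian ML", {
  set.seed(10)
  th <- cbind(rnorm(400, 0.5, 0.12), rnorm(400, 0.4, 0.07))
  th[, 2] <- th[, 2] + 0.5 * th[, 1]          # correlated
  w <- runif(400)
  net <- train_mdn(th, matrix(0, 400, 1), w, head = "constant")
  wm <- colSums(th * w) / sum(w)
  ct <- sweep(th, 2, wm)
  wc <- crossprod(ct * w, ct) / sum(w)
  expect_equal(as.numeric(net$mu), wm, tolerance = 1e-12)
  expect_equal(net$Sigma[[1]], wc, tolerance = 1e-12)

  # zero-weight samples have no influence
  th2 <- rbind(th, matrix(5, 50, 2))
  w2 <- c(w, rep(0, 50))
  net2 <- train_mdn(th2, matrix(0, 450, 1), w2, head = "constant")
  expect_equal(net2$mu, net$mu)
  expect_equal(net2$Sigma[[1]], net$Sigma[[1]])

  # duplicating the data leaves the optimum unchanged
  net3 <- train_mdn(rbind(th, th), matrix(0, 800, 1), c(w, w),
                    head = "constant")
  expect_equal(net3$mu, net$mu, tolerance = 1e-12)
})

test_that("conditioning recovers the conjugate linear-Gaussian posterior", {
  prior <- tn_prior(mean = 0.5, lower = 0, upper = 1, sd = 0.2)
  sim <- function(u) list(summary = u + rnorm(1, 0, 0.1), valid = TRUE)
  x_o <- 0.62
  set.seed(99)
  inf <- run_inference(sim, prior, rounds = 1, n_per_round = 800, seed = 3,
                       x_target = x_o, kernel = "none", head = "linear")
  s <- posterior_sample(inf$posterior, 5000, seed = 4)
  prec <- 1 / 0.2^2 + 1 / 0.1^2
  mu_an <- (0.5 / 0.2^2 + x_o / 0.1^2) / prec
  expect_equal(mean(s), mu_an, tolerance = 0.05 * mu_an)
  expect_equal(stats::sd(s), sqrt(1 / prec), tolerance = 0.2)
  # contraction: posterior variance below prior variance
  expect_lt(stats::var(as.numeric(s)), 0.2^2)
})

test_that("importance weighting corrects for a non-prior proposal", {
  prior <- tn_prior(mean = 0.5, lower = 0, upper = 1, sd = 0.2)
  sim <- function(u) list(summary = u + rnorm(1, 0, 0.1), valid = TRUE)
  x_o <- 0.58
  set.seed(5)
  direct <- run_inference(sim, prior, rounds = 1, n_per_round = 1500,
                          seed = 11, x_target = x_o, kernel = "none")
  # an off-center truncated-Gaussian proposal with its exact box mass
  mass <- stats::pnorm(1, 0.35, 0.3) - stats::pnorm(0, 0.35, 0.3)
  proposal <- structure(list(pi = 1, mu = matrix(0.35, 1),
                             Sigma = list(diag(0.09, 1)), d = 1,
                             box = list(lower = 0, upper = 1),
                             box_mass = mass),
                        class = "mdn_posterior")
  set.seed(7)
  weighted <- run_inference(sim, prior, rounds = 1, n_per_round = 1500,
                            seed = 12, x_target = x_o, kernel = "none",
                            proposal = proposal)
  m1 <- mean(posterior_sample(direct$posterior, 4000, seed = 8))
  m2 <- mean(posterior_sample(weighted$posterior, 4000, seed = 9))
  expect_equal(m1, m2, tolerance = 0.04)
})

test_that("posteriors respect truncation and contract on repeated rounds", {
  prior <- tn_prior(mean = c(0.5, 0.5), lower = c(0, 0), upper = c(1, 1),
                    sd = c(0.3, 0.3))
  truth <- c(0.62, 0.35)
  sim <- function(u) list(summary = u + rnorm(2, 0, 0.08), valid = TRUE)
  set.seed(21)
  inf <- run_inference(sim, prior, rounds = 2, n_per_round = 500, seed = 31,
                       x_target = truth, kernel = "none")
  s <- posterior_sample(inf$posterior, 3000, seed = 32)
  expect_true(all(s >= 0 & s <= 1))
  pv <- apply(s, 2, stats::var)
  prior_v <- apply(sample_truncated(prior, 5000, seed = 33), 2, stats::var)
  expect_true(all(pv < prior_v))
  expect_equal(colMeans(s), truth, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("invalid simulations are zero-weighted, never fatal", {
  prior <- tn_prior(mean = 0.5, lower = 0, upper = 1, sd = 0.25)
  sim <- function(u) {
    if (u > 0.9) return(list(summary = NA_real_, valid = FALSE))
    list(summary = u + rnorm(1, 0, 0.05), valid = TRUE)
  }
  set.seed(41)
  inf <- run_inference(sim, prior, rounds = 1, n_per_round = 400, seed = 51,
                       x_target = 0.5, kernel = "none")
  rec <- inf$records[[1]]
  expect_true(any(!rec$valid))
  expect_true(all(rec$weights[!rec$valid] == 0))
})

test_that("seeded inference runs are exactly reproducible", {
  prior <- tn_prior(mean = 0.5, lower = 0, upper = 1, sd = 0.25)
  sim <- function(u) list(summary = u + stats::rnorm(1, 0, 0.05),
                          valid = TRUE)
  run <- function() {
    set.seed(77)
    run_inference(sim, prior, rounds = 2, n_per_round = 120, seed = 13,
                  x_target = 0.5, kernel = "adaptive")
  }
  a <- run(); b <- run()
  expect_identical(a$records[[1]]$theta, b$records[[1]]$theta)
  expect_identical(a$records[[2]]$theta, b$records[[2]]$theta)
  expect_identical(a$records[[2]]$weights, b$records[[2]]$weights)
  expect_identical(a$posterior$mu, b$posterior$mu)
})
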