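# ---------------------------------------------------------------------------
# Truncated-normal priors and parameter normalization
# ---------------------------------------------------------------------------

#' Truncated normal prior over a parameter box
#'
#' Independent truncated normal distributions per dimension: a normal
#' density restricted to `[lower, upper]` and renormalized. By default the
#' standard deviation is 0.3 of the box width, matching the normalized
#' parameter space in which inference is run.
#'
#' @param mean prior means (physical units).
#' @param lower,upper truncation bounds per dimension.
#' @param sd prior standard deviations; defaults to `0.3 * (upper - lower)`
#'   where the box is finite.
#' @param names optional parameter names.
#' @return a `tn_prior` object.
#' @export
tn_prior <- function(mean, lower, upper, sd = NULL, names = NULL) {
  d <- length(mean)
  stopifnot(length(lower) == d, length(upper) == d)
  if (is.null(sd)) {
    if (any(!is.finite(lower) | !is.finite(upper))) {
      stop("sd must be given explicitly when bounds are infinite")
    }
    sd <- 0.3 * (upper - lower)
  }
  if (any(sd <= 0)) stop("sd must be > 0")
  if (any(mean < lower | mean > upper)) stop("mean must lie inside the box")
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 names = names, d = d),
            class = "tn_prior")
}

#' Rejection sampler for a truncated normal prior
#'
#' Draws from the untruncated normal and resamples anything outside the
#' box, exactly reproducing the generating process the truncated density
#' normalizes.
#'
#' @param prior a [tn_prior()].
#' @param n number of samples.
#' @param seed integer seed.
#' @return `n x d` matrix of samples, all inside the box.
#' @export
sample_truncated <- function(prior, n, seed = 1L) {
  set.seed(seed)
  d <- prior$d
  out <- matrix(NA_real_, n, d)
  need <- n
  filled <- 0L
  tries <- 0L
  while (need > 0) {
    m <- max(need * 2L, 100L)
    cand <- matrix(stats::rnorm(m * d, mean = rep(prior$mean, each = m),
                                sd = rep(prior$sd, each = m)), m, d)
    ok <- rep(TRUE, m)
    for (j in seq_len(d)) {
      ok <- ok & cand[, j] >= prior$lower[j] & cand[, j] <= prior$upper[j]
    }
    k <- which(ok)
    tries <- tries + m
    if (length(k)) {
      take <- k[seq_len(min(length(k), need))]
      out[filled + seq_along(take), ] <- cand[take, , drop = FALSE]
      filled <- filled + length(take)
      need <- need - length(take)
    }
    if (tries > 1e4 && filled / tries < 1e-4) {
      stop("truncated-normal acceptance rate below 1e-4; ",
           "check that the prior mean and bounds are consistent")
    }
  }
  colnames(out) <- prior$names
  out
}

#' Truncated normal prior density
#'
#' @param prior a [tn_prior()].
#' @param theta matrix of parameter vectors (rows) or a single vector.
#' @param log return log density?
#' @return density values (0 outside the box).
#' @export
tn_density <- function(prior, theta, log = FALSE) {
  theta <- rbind(theta)
  n <- nrow(theta)
  lp <- numeric(n)
  for (j in seq_len(prior$d)) {
    z <- stats::pnorm(prior$upper[j], prior$mean[j], prior$sd[j]) -
      stats::pnorm(prior$lower[j], prior$mean[j], prior$sd[j])
    lp <- lp + stats::dnorm(theta[, j], prior$mean[j], prior$sd[j], log = TRUE) -
      base::log(z)
    out_of_box <- theta[, j] < prior$lower[j] | theta[, j] > prior$upper[j]
    lp[out_of_box] <- -Inf
  }
  if (log) lp else exp(lp)
}

#' Map parameters between physical space and the unit box
#'
#' Inference runs in a normalized space in which the truncation bounds are
#' `[0, 1]` in every dimension.
#'
#' @param theta matrix (rows = samples) or vector of physical parameters.
#' @param prior a [tn_prior()] with finite bounds.
#' @return matrix of normalized (resp. physical) parameters.
#' @export
normalize_params <- function(theta, prior) {
  if (any(!is.finite(prior$lower) | !is.finite(prior$upper))) {
    stop("normalization requires finite bounds")
  }
  theta <- rbind(theta)
  if (any(t(theta) < prior$lower - 1e-12) || any(t(theta) > prior$upper + 1e-12)) {
    stop("value outside the prior bounds")
  }
  out <- sweep(sweep(theta, 2, prior$lower, "-"), 2,
               prior$upper - prior$lower, "/")
  colnames(out) <- prior$names
  out
}

#' @rdname normalize_params
#' @param u matrix or vector of normalized parameters in `[0, 1]^d`.
#' @export
denormalize_params <- function(u, prior) {
  u <- rbind(u)
  out <- sweep(sweep(u, 2, prior$upper - prior$lower, "*"), 2,
               prior$lower, "+")
  colnames(out) <- prior$names
  out
}

#' Normalized-space version of a prior
#'
#' @param prior a [tn_prior()] with finite bounds.
#' @return a [tn_prior()] over `[0, 1]^d` with sd 0.3 scaled accordingly.
#' @export
normalized_prior <- function(prior) {
  w <- prior$upper - prior$lower
  tn_prior(mean = (prior$mean - prior$lower) / w,
           lower = rep(0, prior$d), upper = rep(1, prior$d),
           sd = prior$sd / w, names = prior$names)
}

# ---------------------------------------------------------------------------
# Adaptive kernel weights
# ---------------------------------------------------------------------------

#' Kernel specification for sample weighting
#'
#' Zero-centered Gaussian kernels with bandwidth `sigma` on all summary
#' dimensions except the first; the first (trace-discrepancy) dimension
#' uses an adaptive center `mu1` and bandwidth `sigma1`.
#'
#' @param sigma bandwidth of dimensions 2..d.
#' @param mu1 kernel center of dimension 1.
#' @param sigma1 bandwidth of dimension 1 (floored at `floor1`).
#' @param floor1 lower floor for `sigma1`.
#' @return a `kernel_spec`.
#' @export
kernel_spec <- function(sigma = 0.25, mu1 = 0, sigma1 = 0.25,
                        floor1 = 1e-3) {
  structure(list(sigma = sigma, mu1 = mu1, sigma1 = max(sigma1, floor1),
                 floor1 = floor1),
            class = "kernel_spec")
}

#' Update the adaptive kernel from a round's summaries
#'
#' The first-dimension kernel is recentered at the smallest sampled trace
#' discrepancy, with bandwidth equal to the distance from that minimum to
#' the 20th percentile of the round's sampled values (floored).
#'
#' @param summaries matrix of summary vectors (rows), first column the
#'   trace discrepancy; or a list of `discrepancy_vector`s.
#' @param sigma bandwidth of the non-adaptive dimensions.
#' @param floor1 bandwidth floor for dimension 1.
#' @return a [kernel_spec()].
#' @export
kernel_update <- function(summaries, sigma = 0.25, floor1 = 1e-3) {
  X <- .as_summary_matrix(summaries)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 5) stop("kernel update needs at least 5 valid summaries")
  d1 <- X[, 1]
  mu1 <- min(d1)
  sigma1 <- stats::quantile(d1, 0.20, names = FALSE, type = 7) - mu1
  kernel_spec(sigma = sigma, mu1 = mu1, sigma1 = sigma1, floor1 = floor1)
}

.as_summary_matrix <- function(summaries) {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    do.call(rbind, lapply(summaries, as.numeric))
  } else {
    as.matrix(summaries)
  }
}

#' Kernel weights of summary vectors
#'
#' Product of the per-dimension Gaussian kernels; values in `(0, 1]`.
#' Rows with any non-finite entry receive weight 0.
#'
#' @param summaries matrix of summary vectors (rows).
#' @param kspec a [kernel_spec()].
#' @return numeric vector of weights.
#' @export
kernel_weights <- function(summaries, kspec) {
  X <- .as_summary_matrix(summaries)
  w <- exp(-0.5 * ((X[, 1] - kspec$mu1) / kspec$sigma1)^2)
  if (ncol(X) > 1) {
    for (j in 2:ncol(X)) w <- w * exp(-0.5 * (X[, j] / kspec$sigma)^2)
  }
  w[!is.finite(w)] <- 0
  w[!stats::complete.cases(X)] <- 0
  w
}

# ---------------------------------------------------------------------------
# Mixture-density network
# ---------------------------------------------------------------------------

# forward pass through the MLP; returns activations for backprop
.mdn_forward <- function(net, X) {
  H <- list(X)
  A <- X
  L <- length(net$W)
  for (l in seq_len(L - 1)) {
    A <- tanh(sweep(A %*% net$W[[l]], 2, net$b[[l]], "+"))
    H[[l + 1]] <- A
  }
  O <- sweep(A %*% net$W[[L]], 2, net$b[[L]], "+")
  list(H = H, O = O)
}

# split raw outputs into mixture parameters
.mdn_split <- function(O, K, d) {
  N <- nrow(O)
  logits <- O[, seq_len(K), drop = FALSE]
  mu <- array(O[, K + seq_len(K * d)], c(N, K, d))
  logsd <- array(O[, K + K * d + seq_len(K * d)], c(N, K, d))
  logsd <- pmin(pmax(logsd, -7), 4)
  list(logits = logits, mu = mu, logsd = logsd)
}

# weighted negative log likelihood and gradient wrt raw outputs
.mdn_loss_grad <- function(par, theta, w) {
  K <- dim(par$mu)[2]; d <- dim(par$mu)[3]; N <- nrow(theta)
  logpi <- par$logits - apply(par$logits, 1, function(z) {
    m <- max(z); m + base::log(sum(exp(z - m)))
  })
  # component log densities
  logN <- matrix(0, N, K)
  for (k in seq_len(K)) {
    z2 <- 0; lds <- 0
    for (j in seq_len(d)) {
      sj <- exp(par$logsd[, k, j])
      z2 <- z2 + ((theta[, j] - par$mu[, k, j]) / sj)^2
      lds <- lds + par$logsd[, k, j]
    }
    logN[, k] <- -0.5 * z2 - lds - 0.5 * d * base::log(2 * pi)
  }
  s <- logpi + logN
  smax <- apply(s, 1, max)
  lse <- smax + base::log(rowSums(exp(s - smax)))
  loss <- -sum(w * lse) / sum(w)
  r <- exp(s - lse)                      # responsibilities, N x K
  # gradients wrt raw outputs
  gl <- (exp(logpi) - r) * (w / sum(w))  # logits
  gmu <- array(0, dim(par$mu)); gls <- array(0, dim(par$logsd))
  for (k in seq_len(K)) {
    for (j in seq_len(d)) {
      sj <- exp(par$logsd[, k, j])
      zz <- (par$mu[, k, j] - theta[, j]) / sj^2
      gmu[, k, j] <- r[, k] * zz * (w / sum(w))
      gls[, k, j] <- r[, k] * (1 - ((theta[, j] - par$mu[, k, j]) / sj)^2) *
        (w / sum(w))
    }
  }
  N <- nrow(theta)
  dO <- cbind(gl, matrix(gmu, N, K * d), matrix(gls, N, K * d))
  list(loss = loss, dO = dO)
}

#' Train a mixture-density network on weighted samples
#'
#' Minimizes the importance- and kernel-weighted negative log likelihood
#' `-(1/N) sum_n w_n log q_phi(theta_n | x_n)` of a conditional Gaussian
#' mixture whose parameters are produced by a small multilayer perceptron
#' from the summary statistics. Samples with weight zero have no gradient
#' influence. With `head = "constant"` the network has no summary
#' dependence and the (single-component) optimum is computed in closed
#' form as the weighted mean and full weighted covariance.
#'
#' @param theta `N x d` matrix of parameter samples (normalized space).
#' @param x `N x dx` matrix of summary statistics.
#' @param weights sample weights `(p/p~) * K(x)`, length N.
#' @param n_components number of mixture components.
#' @param hidden integer vector of hidden-layer widths.
#' @param head `"mlp"` (summary-conditioned, diagonal covariances) or
#'   `"constant"` (summary-independent; full covariance for one
#'   component, diagonal EM for more).
#' @param epochs,lr Adam training schedule.
#' @param seed integer seed for weight initialization.
#' @return an `mdn` object.
#' @export
train_mdn <- function(theta, x, weights, n_components = 1,
                      hidden = c(50, 50), head = c("linear", "mlp", "constant"),
                      epochs = 600, lr = 0.02, seed = 1L) {
  head <- match.arg(head)
  theta <- as.matrix(theta); x <- as.matrix(x)
  keep <- weights > 0 & stats::complete.cases(x) & stats::complete.cases(theta)
  theta <- theta[keep, , drop = FALSE]
  x <- x[keep, , drop = FALSE]
  w <- weights[keep]
  if (nrow(theta) < 50) stop("need at least 50 weighted-valid samples")
  d <- ncol(theta); dx <- ncol(x); K <- n_components

  if (head == "constant") {
    if (K == 1) {
      mu <- colSums(theta * w) / sum(w)
      ct <- sweep(theta, 2, mu)
      Sigma <- crossprod(ct * w, ct) / sum(w)
      return(structure(list(head = "constant", K = 1, d = d,
                            pi = 1, mu = matrix(mu, 1), Sigma = list(Sigma)),
                       class = "mdn"))
    }
    return(.mdn_const_em(theta, w, K, seed))
  }

  if (head == "linear") {
    # single Gaussian with affine conditional mean and full (constant)
    # residual covariance; the weighted maximum-likelihood fit is a
    # closed-form weighted ridge regression and cannot collapse. The
    # ridge (on standardized summaries) guards against the near-singular
    # designs that arise when the kernel concentrates the weights.
    if (K != 1) stop("linear head supports a single component")
    x_mean <- colMeans(x)
    x_sd <- apply(x, 2, stats::sd); x_sd[x_sd < 1e-8] <- 1
    xs <- sweep(sweep(x, 2, x_mean), 2, x_sd, "/")
    Xd <- cbind(1, xs)
    XtW <- t(Xd * w)
    ridge <- diag(c(1e-8, rep(0.05 * sum(w), ncol(x))))
    B <- solve(XtW %*% Xd + ridge, XtW %*% theta)
    resid <- theta - Xd %*% B
    Sigma <- crossprod(resid * w, resid) / sum(w)
    return(structure(list(head = "linear", K = 1, d = d, dx = dx,
                          B = B, Sigma = Sigma,
                          x_mean = x_mean, x_sd = x_sd),
                     class = "mdn"))
  }

  # standardize summary inputs (stored with the network)
  x_mean <- colMeans(x)
  x_sd <- apply(x, 2, stats::sd)
  x_sd[x_sd < 1e-8] <- 1
  x <- sweep(sweep(x, 2, x_mean), 2, x_sd, "/")

  set.seed(seed)
  widths <- c(dx, hidden, K + 2 * K * d)
  L <- length(widths) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    sc <- sqrt(2 / (widths[l] + widths[l + 1]))
    W[[l]] <- matrix(stats::rnorm(widths[l] * widths[l + 1], 0, sc),
                     widths[l], widths[l + 1])
    b[[l]] <- rep(0, widths[l + 1])
  }
  # data-informed output bias: component means around the weighted mean,
  # spreads at the weighted sd
  wm <- colSums(theta * w) / sum(w)
  wsd <- sqrt(pmax(colSums(sweep(theta, 2, wm)^2 * w) / sum(w), 1e-8))
  mu0 <- matrix(rep(wm, each = K), K, d)
  if (K > 1) mu0 <- mu0 + stats::rnorm(K * d, 0, 0.3) * rep(wsd, each = K)
  b[[L]] <- c(rep(0, K), as.numeric(matrix(mu0, K, d)),
              rep(base::log(wsd), each = K))
  net <- list(W = W, b = b, K = K, d = d, dx = dx)

  # Adam state
  mW <- lapply(W, function(m) m * 0); vW <- mW
  mB <- lapply(b, function(m) m * 0); vB <- mB
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fw <- .mdn_forward(net, x)
    par <- .mdn_split(fw$O, K, d)
    lg <- .mdn_loss_grad(par, theta, w)
    loss_trace[ep] <- lg$loss
    if (!is.finite(lg$loss)) stop("divergent MDN loss at epoch ", ep)
    # clamp gradient where logsd saturated (split clamps values)
    dO <- lg$dO
    # backprop
    gW <- vector("list", L); gB <- vector("list", L)
    dA <- dO
    for (l in rev(seq_len(L))) {
      gW[[l]] <- crossprod(fw$H[[l]], dA)
      gB[[l]] <- colSums(dA)
      if (l > 1) {
        dA <- (dA %*% t(net$W[[l]])) * (1 - fw$H[[l]]^2)
      }
    }
    for (l in seq_len(L)) {
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
      mB[[l]] <- b1 * mB[[l]] + (1 - b1) * gB[[l]]
      vB[[l]] <- b2 * vB[[l]] + (1 - b2) * gB[[l]]^2
      mhW <- mW[[l]] / (1 - b1^ep); vhW <- vW[[l]] / (1 - b2^ep)
      mhB <- mB[[l]] / (1 - b1^ep); vhB <- vB[[l]] / (1 - b2^ep)
      net$W[[l]] <- net$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
      net$b[[l]] <- net$b[[l]] - lr * mhB / (sqrt(vhB) + eps)
    }
  }
  structure(list(head = "mlp", net = net, K = K, d = d, dx = dx,
                 x_mean = x_mean, x_sd = x_sd,
                 loss_trace = loss_trace),
            class = "mdn")
}

# weighted EM for a summary-independent diagonal Gaussian mixture
.mdn_const_em <- function(theta, w, K, seed, iters = 200) {
  set.seed(seed)
  d <- ncol(theta)
  wm <- colSums(theta * w) / sum(w)
  wsd <- sqrt(pmax(colSums(sweep(theta, 2, wm)^2 * w) / sum(w), 1e-10))
  mu <- matrix(rep(wm, each = K), K, d) +
    matrix(stats::rnorm(K * d, 0, 0.5), K, d) * rep(wsd, each = K)
  sd2 <- matrix(rep(wsd^2, each = K), K, d)
  pk <- rep(1 / K, K)
  for (it in seq_len(iters)) {
    logr <- matrix(0, nrow(theta), K)
    for (k in seq_len(K)) {
      logr[, k] <- base::log(pk[k]) +
        rowSums(stats::dnorm(theta, rep(mu[k, ], each = nrow(theta)),
                             rep(sqrt(sd2[k, ]), each = nrow(theta)),
                             log = TRUE))
    }
    m <- apply(logr, 1, max)
    r <- exp(logr - m - base::log(rowSums(exp(logr - m))))
    rw <- r * w
    nk <- colSums(rw)
    pk <- nk / sum(nk)
    for (k in seq_len(K)) {
      mu[k, ] <- colSums(theta * rw[, k]) / nk[k]
      sd2[k, ] <- pmax(colSums(sweep(theta, 2, mu[k, ])^2 * rw[, k]) / nk[k],
                       1e-10)
    }
  }
  structure(list(head = "constant", K = K, d = d, pi = pk, mu = mu,
                 Sigma = lapply(seq_len(K), function(k) diag(sd2[k, ], d))),
            class = "mdn")
}

#' Evaluate a mixture-density network at a target summary
#'
#' Conditions the trained network on a summary vector (for the adaptive
#' boundary rule, `[min sampled trace discrepancy, 0, ..., 0]`), yielding
#' a concrete Gaussian mixture, and optionally truncates it to a box (the
#' prior bounds); truncation is by rejection at sampling time.
#'
#' @param net an `mdn` from [train_mdn()].
#' @param x_target summary vector to condition on (ignored by
#'   constant-head networks).
#' @param box optional truncation box `list(lower, upper)`.
#' @param seed seed for the Monte Carlo estimate of the truncated mass.
#' @return an `mdn_posterior` with mixture parameters, the box and the
#'   estimated box mass.
#' @export
evaluate_posterior <- function(net, x_target = NULL, box = NULL, seed = 1L) {
  if (net$head == "constant") {
    mix <- list(pi = net$pi, mu = net$mu, Sigma = net$Sigma)
  } else if (net$head == "linear") {
    if (is.null(x_target)) stop("x_target required for summary-conditioned networks")
    xs <- (x_target - net$x_mean) / net$x_sd
    mu <- as.numeric(c(1, xs) %*% net$B)
    mix <- list(pi = 1, mu = matrix(mu, 1), Sigma = list(net$Sigma))
  } else {
    if (is.null(x_target)) stop("x_target required for summary-conditioned networks")
    x_target <- (x_target - net$x_mean) / net$x_sd
    fw <- .mdn_forward(net$net, matrix(x_target, 1))
    par <- .mdn_split(fw$O, net$K, net$d)
    logits <- par$logits[1, ]
    pi_k <- exp(logits - max(logits)); pi_k <- pi_k / sum(pi_k)
    mu <- matrix(par$mu[1, , ], net$K, net$d)
    Sigma <- lapply(seq_len(net$K), function(k) {
      diag(exp(2 * par$logsd[1, k, ]), net$d)
    })
    mix <- list(pi = pi_k, mu = mu, Sigma = Sigma)
  }
  post <- structure(c(mix, list(d = net$d, box = box, box_mass = 1)),
                    class = "mdn_posterior")
  if (!is.null(box)) {
    s <- .mix_sample(post, 4000L, seed = seed)
    inb <- rep(TRUE, nrow(s))
    for (j in seq_len(post$d)) {
      inb <- inb & s[, j] >= box$lower[j] & s[, j] <= box$upper[j]
    }
    post$box_mass <- max(mean(inb), 2.5e-4)
    if (mean(inb) < 1e-6) stop("truncated posterior mass below 1e-6")
  }
  post
}

# raw mixture sampling without truncation
.mix_sample <- function(post, n, seed = 1L) {
  set.seed(seed)
  comp <- sample.int(length(post$pi), n, replace = TRUE, prob = post$pi)
  out <- matrix(0, n, post$d)
  for (k in seq_along(post$pi)) {
    idx <- which(comp == k)
    if (!length(idx)) next
    R <- chol(post$Sigma[[k]] + diag(1e-12, post$d))
    Z <- matrix(stats::rnorm(length(idx) * post$d), length(idx), post$d)
    out[idx, ] <- sweep(Z %*% R, 2, post$mu[k, ], "+")
  }
  out
}

#' Sample from a (possibly truncated) posterior
#'
#' @param post an `mdn_posterior`.
#' @param n number of samples.
#' @param seed integer seed.
#' @return `n x d` matrix; all rows inside the truncation box if one is
#'   set.
#' @export
posterior_sample <- function(post, n, seed = 1L) {
  if (is.null(post$box)) return(.mix_sample(post, n, seed))
  out <- matrix(NA_real_, n, post$d)
  filled <- 0L; round_i <- 0L
  while (filled < n) {
    round_i <- round_i + 1L
    m <- max(2L * (n - filled), 200L)
    s <- .mix_sample(post, m, seed = seed + 7919L * round_i)
    inb <- rep(TRUE, m)
    for (j in seq_len(post$d)) {
      inb <- inb & s[, j] >= post$box$lower[j] & s[, j] <= post$box$upper[j]
    }
    k <- which(inb)
    if (length(k)) {
      take <- k[seq_len(min(length(k), n - filled))]
      out[filled + seq_along(take), ] <- s[take, , drop = FALSE]
      filled <- filled + length(take)
    }
    if (round_i > 2000L) stop("truncated posterior mass too small to sample")
  }
  out
}

#' Posterior (mixture) density
#'
#' Truncated posteriors are renormalized by the Monte Carlo box-mass
#' estimate stored when the posterior was created, so the returned values
#' are proper densities (as required for importance weighting).
#'
#' @param post an `mdn_posterior`.
#' @param theta matrix (rows) or vector of parameter values.
#' @param log return log density?
#' @return density values.
#' @export
posterior_density <- function(post, theta, log = FALSE) {
  theta <- rbind(theta)
  n <- nrow(theta)
  dens <- numeric(n)
  for (k in seq_along(post$pi)) {
    S <- post$Sigma[[k]]
    R <- chol(S + diag(1e-12, post$d))
    z <- forwardsolve(t(R), t(sweep(theta, 2, post$mu[k, ])))
    q <- colSums(z^2)
    logdet <- 2 * sum(base::log(diag(R)))
    dens <- dens + post$pi[k] *
      exp(-0.5 * q - 0.5 * logdet - 0.5 * post$d * base::log(2 * pi))
  }
  if (!is.null(post$box)) {
    inb <- rep(TRUE, n)
    for (j in seq_len(post$d)) {
      inb <- inb & theta[, j] >= post$box$lower[j] &
        theta[, j] <= post$box$upper[j]
    }
    dens <- ifelse(inb, dens / post$box_mass, 0)
  }
  if (log) base::log(dens) else dens
}

#' Marginal credible intervals of a posterior
#'
#' @param post an `mdn_posterior`.
#' @param level credible level (0.9 for 90% intervals).
#' @param n Monte Carlo sample size.
#' @param seed integer seed.
#' @return `d x 2` matrix of interval bounds.
#' @export
posterior_ci <- function(post, level = 0.9, n = 4000L, seed = 1L) {
  s <- posterior_sample(post, n, seed)
  a <- (1 - level) / 2
  t(apply(s, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE))
}

#' Marginal posterior variances (Monte Carlo)
#'
#' @param post an `mdn_posterior`.
#' @param n Monte Carlo sample size.
#' @param seed integer seed.
#' @return vector of variances per dimension.
#' @export
posterior_var <- function(post, n = 4000L, seed = 1L) {
  apply(posterior_sample(post, n, seed), 2, stats::var)
}

# ---------------------------------------------------------------------------
# Multi-round inference
# ---------------------------------------------------------------------------

#' Multi-round sequential neural posterior estimation
#'
#' Round 1 draws parameters from the prior; later rounds draw from the
#' truncated intermediate posterior. Each round simulates all samples,
#' computes summary vectors, updates the adaptive kernel, weights samples
#' by `(p(theta)/p~(theta)) * K(x)` (invalid simulations get weight 0),
#' trains the mixture-density network and evaluates it at the boundary
#' target `[min sampled trace discrepancy, 0, ..., 0]` (or a fixed
#' user-supplied target), truncating the result to the prior box.
#'
#' @param simulator function of a normalized parameter vector returning
#'   `list(summary = <numeric>, valid = <logical>)`. It must never raise
#'   on parameter values inside the box; invalid simulations are flagged,
#'   not thrown.
#' @param prior a [tn_prior()] over the normalized box `[0, 1]^d` (use
#'   [normalized_prior()] for physical priors).
#' @param rounds number of rounds.
#' @param n_per_round samples per round.
#' @param seed master seed; per-round sampling, training and evaluation
#'   streams are derived from it.
#' @param x_target `"adaptive"` (the boundary rule) or a fixed summary
#'   vector.
#' @param kernel `"adaptive"` (per-round [kernel_update()]) or `"none"`
#'   (all weights 1).
#' @param n_components,hidden,head,epochs,lr network settings passed to
#'   [train_mdn()].
#' @param truncate truncate intermediate/final posteriors to the prior
#'   box?
#' @param proposal optional `mdn_posterior` to use as the round-1
#'   proposal instead of the prior (its density then enters the
#'   importance weights).
#' @param defensive fraction of later-round samples drawn from the prior
#'   instead of the intermediate posterior (defensive mixture sampling;
#'   the importance weights use the mixture density, so the estimate
#'   stays exact while exploration never collapses). 0 disables.
#' @return list with `posterior` (an `mdn_posterior`) and `records` (one
#'   per round: sampled parameters, summaries, weights, validity,
#'   proposal identifier, kernel).
#' @export
run_inference <- function(simulator, prior, rounds = 2, n_per_round = 200,
                          seed = 1L, x_target = "adaptive",
                          kernel = c("adaptive", "none"),
                          n_components = 1, hidden = c(50, 50),
                          head = "linear", epochs = 600, lr = 0.02,
                          truncate = TRUE, proposal = NULL,
                          defensive = 0.2) {
  if (!is.function(simulator)) stop("simulator must be a function")
  kernel_mode <- match.arg(kernel)
  box <- list(lower = prior$lower, upper = prior$upper)
  records <- vector("list", rounds)
  post <- NULL
  for (j in seq_len(rounds)) {
    seed_j <- seed + 1000L * j
    if (j == 1 && is.null(proposal)) {
      theta <- sample_truncated(prior, n_per_round, seed = seed_j)
      prop_id <- "prior"
    } else {
      prop <- if (j == 1) proposal else post
      theta <- posterior_sample(prop, n_per_round, seed = seed_j)
      if (defensive > 0 && j > 1) {
        set.seed(seed_j + 3L)
        from_prior <- stats::runif(n_per_round) < defensive
        if (any(from_prior)) {
          theta[from_prior, ] <- sample_truncated(prior, sum(from_prior),
                                                  seed = seed_j + 4L)
        }
      }
      prop_id <- if (j == 1) "user_proposal" else sprintf("posterior_round_%d", j - 1)
    }
    sims <- lapply(seq_len(n_per_round), function(i) simulator(theta[i, ]))
    valid <- vapply(sims, function(s) isTRUE(s$valid), logical(1))
    if (!any(valid)) {
      stop("all samples invalid in round ", j)
    }
    dsum <- length(sims[[which(valid)[1]]]$summary)
    X <- matrix(NA_real_, n_per_round, dsum)
    for (i in which(valid)) X[i, ] <- sims[[i]]$summary
    ksp <- NULL
    if (kernel_mode == "adaptive") {
      ksp <- kernel_update(X[valid, , drop = FALSE])
      kw <- kernel_weights(X, ksp)
    } else {
      kw <- rep(1, n_per_round)
    }
    kw[!valid] <- 0
    # importance weights p / p~
    if (prop_id == "prior") {
      iw <- rep(1, n_per_round)
    } else {
      prop <- if (j == 1) proposal else post
      p <- tn_density(prior, theta)
      ptilde <- posterior_density(prop, theta)
      if (defensive > 0 && j > 1) {
        ptilde <- (1 - defensive) * ptilde + defensive * p
      }
      iw <- ifelse(ptilde > 0, p / ptilde, 0)
    }
    w <- iw * kw
    net <- train_mdn(theta, X, w, n_components = n_components,
                     hidden = hidden, head = head, epochs = epochs, lr = lr,
                     seed = seed_j + 1L)
    xt <- if (identical(x_target, "adaptive")) {
      # boundary evaluation without extrapolation: the ideal target is the
      # zero vector, but the network is only trained on the observed
      # summary cloud, so we condition at the observed summary closest to
      # it (smallest total discrepancy), with the trace-discrepancy
      # dimension set to the round's sampled minimum. When sampled
      # penalties reach zero this reduces to evaluating at
      # [min delta_trace, 0, ..., 0].
      Xv <- X[valid, , drop = FALSE]
      xt0 <- Xv[which.min(rowSums(abs(Xv))), ]
      xt0[1] <- min(Xv[, 1])
      xt0
    } else {
      x_target
    }
    post <- evaluate_posterior(net, x_target = xt,
                               box = if (truncate) box else NULL,
                               seed = seed_j + 2L)
    records[[j]] <- list(round = j, theta = theta, summaries = X,
                         kernel_weights = kw, importance_weights = iw,
                         weights = w, valid = valid, proposal = prop_id,
                         kernel = ksp, x_target = xt, seed = seed_j)
  }
  list(posterior = post, records = records)
}
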