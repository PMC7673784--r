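# ---------------------------------------------------------------------------
# iGluSnFR forward model
# ---------------------------------------------------------------------------

#' Fluorescence proxy from a release-rate trace
#'
#' Convolves a glutamate release-rate trace with a causal exponential
#' iGluSnFR kernel `kappa(t) = exp(-t / tau)`. The kernel is unnormalized
#' and truncated at five time constants; its scale is irrelevant because
#' the trace comparison optimizes an affine transformation.
#'
#' @param r release-rate trace on a uniform grid, vesicles/s.
#' @param dt sampling interval, s.
#' @param tau kernel decay time constant, s (60 ms).
#' @return fluorescence-proxy trace, same length as `r`.
#' @export
iglusnfr_from_release <- function(r, dt, tau = 0.060) {
  nk <- max(1L, ceiling(5 * tau / dt) + 1L)
  k <- exp(-(seq_len(nk) - 1) * dt / tau)
  out <- stats::filter(c(rep(0, nk - 1), r), k, method = "convolution",
                       sides = 1)
  as.numeric(out[nk:(nk - 1 + length(r))])
}

#' Normalized affine-invariant trace discrepancy
#'
#' The squared distance between a target trace and the best affine map
#' `a + b * sim` of a simulated trace with `b >= 0`, normalized by the
#' target's centered sum of squares:
#' `min_{a, b >= 0} ||target - (a + b sim)||^2 / ||target - mean(target)||^2`.
#' Solved in closed form (ordinary least squares; the slope is clipped at
#' zero, where the optimum degenerates to the constant predictor and the
#' value is exactly 1).
#'
#' @param target target trace (must be non-constant).
#' @param sim simulated trace, same length.
#' @return discrepancy in `[0, 1]`.
#' @export
delta_iglusnfr <- function(target, sim) {
  if (length(target) != length(sim)) stop("traces must have equal length")
  tc <- target - mean(target)
  ss_t <- sum(tc^2)
  if (ss_t == 0) stop("target trace is constant (zero variance)")
  sc <- sim - mean(sim)
  ss_s <- sum(sc^2)
  b <- if (ss_s > 0) sum(tc * sc) / ss_s else 0
  if (b < 0) b <- 0
  resid <- tc - b * sc
  sum(resid^2) / ss_t
}

# ---------------------------------------------------------------------------
# Bounded penalties
# ---------------------------------------------------------------------------

#' Penalty bounds for a scalar discrepancy component
#'
#' @param pl,tl,tu,pu bounds with `pl <= tl <= tu <= pu`; `tl = -Inf` or
#'   `tu = Inf` disable the corresponding branch.
#' @return a `penalty_bounds` object.
#' @export
penalty_bounds <- function(pl, tl, tu, pu) {
  if (!(pl <= tl && tl <= tu && tu <= pu)) {
    stop("bounds must satisfy pl <= tl <= tu <= pu")
  }
  structure(list(pl = pl, tl = tl, tu = tu, pu = pu),
            class = "penalty_bounds")
}

#' Signed bounded penalty
#'
#' Values inside `[tl, tu]` incur no penalty. Below `tl` the penalty is
#' `-1 + exp(-2 (y - tl)^2 / (tl - pl)^2)` (approaching -1), above `tu` it
#' is `1 - exp(-2 (y - tu)^2 / (tu - pu)^2)` (approaching +1). An infinite
#' `tl` or `tu` makes its branch identically zero; a zero-width penalty
#' scale (`tl == pl`) makes the branch a hard step to the saturated value.
#'
#' @param y value(s) of the penalized quantity.
#' @param b a [penalty_bounds()].
#' @return signed penalty in `[-1, 1]`, vectorized over `y`.
#' @export
bounded_penalty <- function(y, b) {
  out <- numeric(length(y))
  if (is.finite(b$tl)) {
    lo <- y < b$tl
    if (any(lo)) {
      w <- (b$tl - b$pl)^2
      out[lo] <- if (w > 0) -1 + exp(-2 * (y[lo] - b$tl)^2 / w) else -1
    }
  }
  if (is.finite(b$tu)) {
    hi <- y > b$tu
    if (any(hi)) {
      w <- (b$tu - b$pu)^2
      out[hi] <- if (w > 0) 1 - exp(-2 * (y[hi] - b$tu)^2 / w) else 1
    }
  }
  out
}

#' Default penalty-bound sets per cell class
#'
#' The shipped bounds for the resting release rate (vesicles/s), resting
#' membrane potential (mV), response amplitudes and extreme membrane
#' potentials of the three modelled cell classes. OFF bipolar cells allow
#' a resting release up to 4 ves/s and voltage excursions up to 25 mV; ON
#' bipolar cells 3 ves/s and 15 mV; cones rest between 50 and 80 ves/s.
#'
#' @param cell_class one of `"cone"`, `"off_bc"`, `"on_bc"`.
#' @return named list of [penalty_bounds()] with elements `rate_rest`,
#'   `v_rest`, `rate_delta`, `v_delta`, `v_min`, `v_max`.
#' @export
default_penalty_bounds <- function(cell_class = c("cone", "off_bc", "on_bc")) {
  cell_class <- match.arg(cell_class)
  switch(cell_class,
    cone = list(
      rate_rest = penalty_bounds(0, 50, 80, 100),
      v_rest = penalty_bounds(-80, -55, -40, -20),
      rate_delta = penalty_bounds(0, 50, 65, 100),
      v_delta = penalty_bounds(0, 5, 10, 20),
      v_min = penalty_bounds(-75, -60, Inf, Inf),
      v_max = penalty_bounds(-Inf, -Inf, -35, -20)),
    off_bc = list(
      rate_rest = penalty_bounds(0, 0, 4, 7),
      v_rest = penalty_bounds(-80, -65, -45, -30),
      rate_delta = penalty_bounds(0, 5, Inf, Inf),
      v_delta = penalty_bounds(0, 5, 25, 40),
      v_min = penalty_bounds(-100, -80, Inf, Inf),
      v_max = penalty_bounds(-Inf, -Inf, -10, 0)),
    on_bc = list(
      rate_rest = penalty_bounds(0, 0, 3, 7),
      v_rest = penalty_bounds(-80, -65, -45, -30),
      rate_delta = penalty_bounds(0, 5, Inf, Inf),
      v_delta = penalty_bounds(0, 5, 15, 40),
      v_min = penalty_bounds(-100, -80, Inf, Inf),
      v_max = penalty_bounds(-Inf, -Inf, -10, 0)))
}

#' Largest response excursions from rest
#'
#' @param r release-rate trace after stimulus onset, vesicles/s.
#' @param v somatic voltage trace after stimulus onset, mV.
#' @param rest list with resting values `rate_rest` and `v_rest`.
#' @return list with `rate_delta = max|r - r0|` and
#'   `v_delta = max|v - v0|`.
#' @export
response_deltas <- function(r, v, rest) {
  list(rate_delta = max(abs(r - rest$rate_rest)),
       v_delta = max(abs(v - rest$v_rest)))
}

#' Seven-component discrepancy vector
#'
#' Assembles the full discrepancy between a simulation and a target
#' fluorescence trace: the affine-invariant trace distance plus six signed
#' bounded penalties on resting release rate, resting potential, release
#' and voltage response amplitudes, and voltage extremes. For bipolar
#' cells the release quantities are the mean over all synapses. The total
#' is the L1 norm of the component vector.
#'
#' @param release mean release-rate trace after stimulus onset (ves/s).
#' @param v_soma somatic voltage trace after stimulus onset (mV).
#' @param target target fluorescence trace on the same grid as `release`.
#' @param rest list with `rate_rest` (ves/s) and `v_rest` (mV) from the
#'   settled pre-stimulus state.
#' @param bounds penalty-bound set from [default_penalty_bounds()].
#' @param dt sampling interval, s.
#' @param tau_kernel iGluSnFR kernel time constant, s.
#' @return a `discrepancy_vector`: named numeric of the seven components
#'   with attribute `total` (and `total` entry accessible via
#'   [delta_total()]).
#' @export
discrepancy_vector <- function(release, v_soma, target, rest, bounds,
                               dt, tau_kernel = 0.060) {
  if (is.null(rest$rate_rest) || is.null(rest$v_rest) ||
      is.na(rest$rate_rest) || is.na(rest$v_rest)) {
    stop("missing resting state (rate_rest, v_rest)")
  }
  stopifnot(all(c("rate_rest", "v_rest", "rate_delta", "v_delta",
                  "v_min", "v_max") %in% names(bounds)))
  nu_m <- iglusnfr_from_release(release, dt, tau_kernel)
  d_trace <- delta_iglusnfr(target, nu_m)
  deltas <- response_deltas(release, v_soma, rest)
  x <- c(
    delta_iglusnfr = d_trace,
    rate_rest = bounded_penalty(rest$rate_rest, bounds$rate_rest),
    v_rest = bounded_penalty(rest$v_rest, bounds$v_rest),
    rate_delta = bounded_penalty(deltas$rate_delta, bounds$rate_delta),
    v_delta = bounded_penalty(deltas$v_delta, bounds$v_delta),
    v_min = bounded_penalty(min(v_soma), bounds$v_min),
    v_max = bounded_penalty(max(v_soma), bounds$v_max))
  structure(x, total = sum(abs(x)), class = "discrepancy_vector")
}

#' Total (L1) discrepancy
#'
#' @param x a `discrepancy_vector` (or plain numeric of components).
#' @return sum of absolute component values.
#' @export
delta_total <- function(x) {
  tot <- attr(x, "total")
  if (is.null(tot)) sum(abs(x)) else tot
}

#' @export
print.discrepancy_vector <- function(x, ...) {
  cat("<discrepancy_vector> total:", format(delta_total(x), digits = 4), "\n")
  print(unclass(structure(as.numeric(x), names = names(x))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Peak timing analysis
# ---------------------------------------------------------------------------

#' Detect peaks in a trace
#'
#' Local extrema with a minimum topographic prominence (as a fraction of
#' the trace range) and a minimum separation; higher peaks win ties.
#'
#' @param x numeric trace.
#' @param dt sampling interval, s.
#' @param prominence minimum prominence as a fraction of `diff(range(x))`.
#' @param min_sep minimum separation between kept peaks, s.
#' @param polarity `+1` for maxima, `-1` for minima.
#' @return data frame with `index`, `time` (s), `height`.
#' @export
find_peaks <- function(x, dt, prominence = 0.1, min_sep = 0.05,
                       polarity = 1) {
  y <- polarity * x
  n <- length(y)
  if (n < 3) return(data.frame(index = integer(), time = numeric(),
                               height = numeric()))
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(cand)) return(data.frame(index = integer(), time = numeric(),
                                       height = numeric()))
  rng <- diff(range(x))
  prom_min <- prominence * rng
  keepable <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    h <- y[i]
    # walk left and right to the nearest higher point; prominence is the
    # height above the higher of the two intervening minima
    li <- i; lmin <- h
    while (li > 1 && y[li] <= h) { li <- li - 1; lmin <- min(lmin, y[li]) }
    left_base <- if (y[li] > h) lmin else min(y[1:i])
    ri <- i; rmin <- h
    while (ri < n && y[ri] <= h) { ri <- ri + 1; rmin <- min(rmin, y[ri]) }
    right_base <- if (y[ri] > h) rmin else min(y[i:n])
    prom <- h - max(left_base, right_base)
    keepable[k] <- prom >= prom_min
  }
  cand <- cand[keepable]
  if (!length(cand)) return(data.frame(index = integer(), time = numeric(),
                                       height = numeric()))
  # enforce minimum separation, keeping higher peaks first
  ord <- cand[order(y[cand], decreasing = TRUE)]
  kept <- integer()
  for (i in ord) {
    if (!length(kept) || all(abs(i - kept) * dt >= min_sep)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  data.frame(index = kept, time = (kept - 1) * dt, height = x[kept])
}

#' Peak time differences between simulated and target traces
#'
#' For every peak in the simulated trace, the signed time difference to
#' the closest target peak of the same polarity (positive = simulated peak
#' delayed). Peaks falling inside exclusion windows (where the target is
#' too noisy for reliable detection) are dropped.
#'
#' @param target,sim traces on a common uniform grid.
#' @param dt sampling interval, s.
#' @param exclude list of `c(start, end)` time windows (s) to exclude.
#' @param prominence,min_sep peak-detection settings (see [find_peaks()]).
#' @return list with `differences` (s, signed, both polarities pooled),
#'   `median` (s; `NA` with `empty = TRUE` if no peaks matched).
#' @export
peak_time_differences <- function(target, sim, dt, exclude = list(),
                                  prominence = 0.1, min_sep = 0.05) {
  in_excl <- function(tm) {
    if (!length(exclude)) return(rep(FALSE, length(tm)))
    Reduce(`|`, lapply(exclude, function(w) tm >= w[1] & tm <= w[2]))
  }
  diffs <- numeric()
  for (pol in c(1, -1)) {
    pt <- find_peaks(target, dt, prominence, min_sep, pol)
    ps <- find_peaks(sim, dt, prominence, min_sep, pol)
    pt <- pt[!in_excl(pt$time), , drop = FALSE]
    ps <- ps[!in_excl(ps$time), , drop = FALSE]
    if (!nrow(pt) || !nrow(ps)) next
    for (i in seq_len(nrow(ps))) {
      j <- which.min(abs(pt$time - ps$time[i]))
      diffs <- c(diffs, ps$time[i] - pt$time[j])
    }
  }
  if (!length(diffs)) {
    list(differences = numeric(), median = NA_real_, empty = TRUE)
  } else {
    list(differences = diffs, median = stats::median(diffs), empty = FALSE)
  }
}
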