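# Independent oracles used across the test suite. These deliberately use
# different numerical routes than the package implementation.

# exact solution of the linear compartment system C dV/dt = -B V + s with
# constant B, s via eigendecomposition: V(t) = M(t) (V0 - Vinf) + Vinf
linear_cable_oracle <- function(cm, B, s, v0, times) {
  A <- -diag(1 / cm) %*% B
  b <- s / cm
  vinf <- solve(-A, b)
  eg <- eigen(A)
  Vi <- solve(eg$vectors)
  sapply(times, function(t) {
    M <- eg$vectors %*% diag(exp(eg$values * t), length(cm)) %*% Vi
    Re(M %*% (v0 - vinf) + vinf)
  })
}

# assemble the passive system matrices of a cell model (independent of the
# C++ core): B[i,i] = sum axial + leak, B[i,j] = -g_axial; s = g_leak * Vr
passive_system <- function(comps, vr_mv) {
  n <- nrow(comps)
  pidx <- match(comps$parent, comps$id)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (!is.na(pidx[i])) {
      g <- 1 / (comps$ri[i] + comps$ri[pidx[i]])
      B[i, i] <- B[i, i] + g; B[pidx[i], pidx[i]] <- B[pidx[i], pidx[i]] + g
      B[i, pidx[i]] <- B[i, pidx[i]] - g; B[pidx[i], i] <- B[pidx[i], i] - g
    }
  }
  gl <- ifelse(is.finite(comps$rm), 1 / comps$rm, 0)
  diag(B) <- diag(B) + gl
  list(B = B, s = gl * vr_mv * 1e-3, cm = comps$cm)
}

# on-axis potential of a uniform-flux disk (radius a) on the insulating
# boundary of a conductive half space: integrate the half-space point
# source kernel I/(2 pi sigma R) over the disk (closed form on axis)
halfspace_disk_onaxis <- function(istim, a, sigma, z) {
  j <- istim / (pi * a^2)
  j / sigma * (sqrt(a^2 + z^2) - z)
}

# off-axis potential by numerical integration of the half-space kernel
# over the disk (polar quadrature)
halfspace_disk_offaxis <- function(istim, a, sigma, r, z, n = 400) {
  j <- istim / (pi * a^2)
  rr <- seq(a / (2 * n), a - a / (2 * n), length.out = n)
  th <- seq(0, 2 * pi, length.out = 2 * n + 1)[-1]
  dA <- (a / n) * (2 * pi / (2 * n))
  v <- 0
  for (ri in rr) {
    d <- sqrt((r - ri * cos(th))^2 + (ri * sin(th))^2 + z^2)
    v <- v + sum(ri * dA / d)
  }
  # half-space point-source kernel I/(2 pi sigma R) (source on boundary)
  j * v / (2 * pi * sigma)
}

# two-layer half-space admittance oracle via Hankel modes: layer 1
# (0..h, k1) under layer 2 (h..H, k2) grounded at z = H, uniform flux
# j = istim / (pi a^2) through the disk at z = 0, insulating elsewhere.
# For each radial wavenumber L the 1-D BVP gives phi(L, z); the disk-mean
# potential is assembled from the J1 spectrum of the disk.
layered_admittance_oracle <- function(istim, a, k1, k2, h, H,
                                      nL = 4000, Lmax = NULL) {
  if (is.null(Lmax)) Lmax <- 60 / a
  L <- seq(Lmax / nL / 2, Lmax, length.out = nL)
  dL <- L[2] - L[1]
  j <- istim / (pi * a^2)
  # phi1(z) = A cosh(Lz) + B sinh(Lz); phi2 = C sinh(L (H - z))
  # flux at 0: -k1 L B = -j S(L)  => B = j S(L) / (k1 L), S from Hankel
  # transform of the disk source: S(L) = a J1(L a) / L
  # continuity at h: phi1(h) = phi2(h); k1 phi1'(h) = k2 phi2'(h)
  # layer 1: phi = A cosh(Lz) + B sinh(Lz); layer 2: phi = C sinh(L(H-z)).
  # Injected flux at z = 0: phi'(0) = -j S / k1 with S = a J1(La)/L.
  # Continuity of phi and of k phi' at z = h eliminates C and gives (in
  # overflow-safe tanh form) A = -B (k1 tHh + k2 th)/(k1 th tHh + k2).
  S <- a * besselJ(L * a, 1) / L
  B <- -j * S / (k1 * L)
  th <- tanh(L * h); tHh <- tanh(L * (H - h))
  A <- -B * (k1 * tHh + k2 * th) / (k1 * th * tHh + k2)
  phi0 <- A   # phi1(z=0) spectral coefficient
  # disk-mean potential: mean over disk of inverse Hankel transform
  # <J0(L r)>_disk = 2 J1(L a) / (L a)
  vmean <- sum(phi0 * L * (2 * besselJ(L * a, 1) / (L * a)) * dL)
  istim / vmean
}

# reference solution of the phototransduction cascade: same piecewise-
# constant input integrated at a much finer step, converging to the true
# coupled ODE solution (measures the splitting/truncation error)
photo_reference <- function(photon_rate, spec, dt, refine = 40) {
  fine <- rep(photon_rate, each = refine)
  out <- photocurrent(fine, spec, dt / refine)
  out[seq(refine, length(fine), by = refine)]
}
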