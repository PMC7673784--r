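# ---------------------------------------------------------------------------
# Layered-cylinder retina/bath field model
# ---------------------------------------------------------------------------

.EPS0 <- 8.8541878128e-12  # F/m

#' Retina/bath field model
#'
#' Geometry and material model for quasi-static extracellular fields: a
#' retina cylinder (radius 2 mm, height 105 um) with a bath (electrolyte)
#' cylinder of the same radius above it (height 2 mm). Disk stimulation
#' electrodes (diameter 30 um, grid pitch 70 um) sit on the bottom face;
#' the grounded return electrode is the bath top. All other boundaries
#' are insulating.
#'
#' @param sigma_retina retina conductivity, S/m.
#' @param eps_retina retina relative permittivity.
#' @param sigma_bath bath conductivity, S/m (1.54 for Ames' medium).
#' @param eps_bath bath relative permittivity (78, water).
#' @param h_retina_um,h_bath_um,radius_um cylinder dimensions, um.
#' @param electrode_diam_um electrode disk diameter, um.
#' @param pitch_um electrode center-to-center spacing, um.
#' @param grid resolution preset: `"default"`, `"fine"` or `"coarse"`.
#' @return a `retina_field_model`.
#' @export
retina_field_model <- function(sigma_retina = 0.076, eps_retina = 1.1e7,
                               sigma_bath = 1.54, eps_bath = 78,
                               h_retina_um = 105, h_bath_um = 2000,
                               radius_um = 2000, electrode_diam_um = 30,
                               pitch_um = 70,
                               grid = c("default", "fine", "coarse")) {
  grid <- match.arg(grid)
  if (sigma_retina <= 0 || sigma_bath <= 0) stop("conductivities must be > 0")
  if (eps_retina <= 0 || eps_bath <= 0) stop("permittivities must be > 0")
  structure(list(sigma_retina = sigma_retina, eps_retina = eps_retina,
                 sigma_bath = sigma_bath, eps_bath = eps_bath,
                 h_retina = h_retina_um * 1e-6, h_bath = h_bath_um * 1e-6,
                 radius = radius_um * 1e-6,
                 a = electrode_diam_um * 1e-6 / 2,
                 pitch = pitch_um * 1e-6, grid = grid),
            class = "retina_field_model")
}

# geometric sequence of face positions from x0 to x1, first step h0,
# growth factor g; the last step is stretched to land exactly on x1
.graded_seq <- function(x0, x1, h0, g = 1.3) {
  xs <- x0
  h <- h0
  while (xs[length(xs)] + h < x1 - 1e-15) {
    xs <- c(xs, xs[length(xs)] + h)
    h <- h * g
  }
  if (x1 - xs[length(xs)] < 0.25 * h && length(xs) > 2) {
    xs <- xs[-length(xs)]
  }
  c(xs, x1)
}

.field_grid <- function(model) {
  p <- switch(model$grid,
              fine = list(n_disk = 30, h0z = 0.3e-6, g = 1.12),
              default = list(n_disk = 12, h0z = 1e-6, g = 1.25),
              coarse = list(n_disk = 6, h0z = 2.5e-6, g = 1.4))
  a <- model$a
  # radial faces: uniform across the disk (a is always a face), graded out
  rf_in <- seq(0, a, length.out = p$n_disk + 1)
  rf_out <- .graded_seq(a, model$radius, h0 = (rf_in[2] - rf_in[1]),
                        g = p$g)
  rf <- unique(c(rf_in, rf_out))
  # axial faces: fine near the electrode plane, interface is always a face
  zf_ret <- .graded_seq(0, model$h_retina, h0 = p$h0z, g = p$g)
  zf_bath <- .graded_seq(model$h_retina, model$h_retina + model$h_bath,
                         h0 = (zf_ret[length(zf_ret)] - zf_ret[length(zf_ret) - 1]),
                         g = min(p$g + 0.15, 1.5))
  zf <- unique(c(zf_ret, zf_bath))
  list(rf = rf, zf = zf,
       r = (rf[-1] + rf[-length(rf)]) / 2,
       z = (zf[-1] + zf[-length(zf)]) / 2)
}

#' Solve the axisymmetric quasi-static field of one disk electrode
#'
#' Finite-volume discretization of `div((sigma + i 2 pi f eps eps0)
#' grad V) = 0` on a graded cell-centered (r, z) grid, with a spatially
#' uniform normal current density `istim / A_electrode` on the disk,
#' `V = 0` at the bath top and zero normal current on all other
#' boundaries. The layer interface coincides with a cell face, so each
#' cell has a single material; inter-cell conductances use the exact
#' series (harmonic) combination.
#'
#' @param model a [retina_field_model()].
#' @param istim total stimulation current, A.
#' @param frequency stimulus frequency, Hz (0 = DC, purely conductive).
#' @return a `retina_field` with the complex potential on the grid, an
#'   interpolating sampler (see [field_at()]) and the electrode-terminal
#'   admittance `Y = istim / mean(V over the disk)`.
#' @export
solve_field <- function(model, istim = 0.5e-6, frequency = 0) {
  g <- .field_grid(model)
  r <- g$r; z <- g$z; rf <- g$rf; zf <- g$zf
  nr <- length(r); nz <- length(z)
  omega <- 2 * pi * frequency
  k_of <- function(zc) {
    ifelse(zc < model$h_retina,
           complex(real = model$sigma_retina,
                   imaginary = omega * model$eps_retina * .EPS0),
           complex(real = model$sigma_bath,
                   imaginary = omega * model$eps_bath * .EPS0))
  }
  kz <- k_of(z)                      # per z-row material
  id <- function(i, j) (j - 1L) * nr + i
  N <- nr * nz

  ii <- integer(0); jj <- integer(0); vv <- complex(0)
  diagv <- complex(length.out = N)
  b <- complex(length.out = N)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, v)
  }

  dz <- zf[-1] - zf[-length(zf)]
  # radial face conductances (both cells share the material of row j)
  for (j in seq_len(nz)) {
    for (i in seq_len(nr - 1)) {
      Af <- 2 * pi * rf[i + 1] * dz[j]
      gr <- Af / ((rf[i + 1] - r[i]) / kz[j] + (r[i + 1] - rf[i + 1]) / kz[j])
      a_ <- id(i, j); b_ <- id(i + 1, j)
      add(a_, b_, -gr); add(b_, a_, -gr)
      diagv[a_] <- diagv[a_] + gr; diagv[b_] <- diagv[b_] + gr
    }
  }
  # axial face conductances
  Az <- pi * (rf[-1]^2 - rf[-length(rf)]^2)  # annulus area per column
  for (j in seq_len(nz - 1)) {
    gzc <- Az / ((zf[j + 1] - z[j]) / kz[j] + (z[j + 1] - zf[j + 1]) / kz[j + 1])
    for (i in seq_len(nr)) {
      a_ <- id(i, j); b_ <- id(i, j + 1)
      add(a_, b_, -gzc[i]); add(b_, a_, -gzc[i])
      diagv[a_] <- diagv[a_] + gzc[i]; diagv[b_] <- diagv[b_] + gzc[i]
    }
  }
  # top Dirichlet V = 0 through the last axial half-cell
  gtop <- kz[nz] * Az / (zf[length(zf)] - z[nz])
  for (i in seq_len(nr)) diagv[id(i, nz)] <- diagv[id(i, nz)] + gtop[i]
  # electrode source on bottom cells covered by the disk
  jperp <- istim / (pi * model$a^2)
  cover <- pmin(rf[-1], model$a)^2 - pmin(rf[-length(rf)], model$a)^2
  src <- jperp * pi * pmax(cover, 0)
  for (i in seq_len(nr)) b[id(i, 1)] <- b[id(i, 1)] + src[i]

  ii <- c(ii, seq_len(N)); jj <- c(jj, seq_len(N)); vv <- c(vv, diagv)

  if (frequency == 0) {
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = Re(vv), dims = c(N, N))
    V <- as.numeric(Matrix::solve(A, Re(b)))
    V <- complex(real = V, imaginary = 0)
  } else {
    Ar <- Matrix::sparseMatrix(i = ii, j = jj, x = Re(vv), dims = c(N, N))
    Ai <- Matrix::sparseMatrix(i = ii, j = jj, x = Im(vv), dims = c(N, N))
    BigA <- rbind(cbind(Ar, -Ai), cbind(Ai, Ar))
    rhs <- c(Re(b), Im(b))
    sol <- as.numeric(Matrix::solve(BigA, rhs))
    V <- complex(real = sol[seq_len(N)], imaginary = sol[N + seq_len(N)])
  }
  Vm <- matrix(V, nr, nz)
  # electrode-terminal voltage: area-weighted mean over the disk
  w <- pmax(cover, 0)
  v_el <- sum(Vm[, 1] * w) / sum(w)
  structure(list(model = model, r = r, z = z, rf = rf, zf = zf,
                 V = Vm, istim = istim, frequency = frequency,
                 v_electrode = v_el, Y = istim / v_el),
            class = "retina_field")
}

#' Sample a solved field
#'
#' Bilinear interpolation of the complex potential at arbitrary points;
#' the field of a disk at `center` is the centered solution shifted
#' laterally.
#'
#' @param field a `retina_field` from [solve_field()].
#' @param x,y,z coordinates in meters (vectors recycle).
#' @param center electrode center `c(x, y)` in meters.
#' @return complex potential, V.
#' @export
field_at <- function(field, x, y, z, center = c(0, 0)) {
  rq <- sqrt((x - center[1])^2 + (y - center[2])^2)
  n <- max(length(rq), length(z))
  rq <- rep_len(rq, n); zq <- rep_len(z, n)
  if (any(zq < 0 | zq > max(field$zf) + 1e-12)) {
    stop("query point outside the cylinder (z out of range)")
  }
  if (any(rq > max(field$rf) + 1e-12)) {
    stop("query point outside the cylinder (r out of range)")
  }
  ri <- findInterval(rq, field$r, all.inside = TRUE)
  zi <- findInterval(zq, field$z, all.inside = TRUE)
  fr <- pmin(pmax((rq - field$r[ri]) / (field$r[ri + 1] - field$r[ri]), 0), 1)
  fz <- pmin(pmax((zq - field$z[zi]) / (field$z[zi + 1] - field$z[zi]), 0), 1)
  idx <- cbind(ri, zi)
  v00 <- field$V[idx]
  v10 <- field$V[cbind(ri + 1, zi)]
  v01 <- field$V[cbind(ri, zi + 1)]
  v11 <- field$V[cbind(ri + 1, zi + 1)]
  (1 - fr) * (1 - fz) * v00 + fr * (1 - fz) * v10 +
    (1 - fr) * fz * v01 + fr * fz * v11
}

#' Total current crossing a horizontal plane
#'
#' Sums the axial finite-volume face fluxes across the plane nearest to
#' `z`; by construction of the discretization this equals the injected
#' current for every plane between electrode and return.
#'
#' @param field a `retina_field`.
#' @param z plane height, m.
#' @return complex current, A.
#' @export
plane_current <- function(field, z) {
  j <- which.min(abs((field$z[-1] + field$z[-length(field$z)]) / 2 - z))
  model <- field$model
  omega <- 2 * pi * field$frequency
  k_of <- function(zc) {
    ifelse(zc < model$h_retina,
           complex(real = model$sigma_retina,
                   imaginary = omega * model$eps_retina * .EPS0),
           complex(real = model$sigma_bath,
                   imaginary = omega * model$eps_bath * .EPS0))
  }
  rf <- field$rf
  Az <- pi * (rf[-1]^2 - rf[-length(rf)]^2)
  zf_face <- field$zf[j + 1]
  gz <- Az / ((zf_face - field$z[j]) / k_of(field$z[j]) +
                (field$z[j + 1] - zf_face) / k_of(field$z[j + 1]))
  sum(gz * (field$V[, j] - field$V[, j + 1]))
}

# ---------------------------------------------------------------------------
# Multi-electrode superposition
# ---------------------------------------------------------------------------

#' Field of a regular electrode array by superposition
#'
#' The joint boundary-value problem of an N x N active-electrode array is
#' approximated by summing laterally shifted single-disk solutions, each
#' carrying an equal share of the total current (uniform normal current
#' density across all electrodes). The superposition neglects the
#' interaction of each shifted disk with the distant outer wall; the
#' approximation is quantified against a joint coarse solve in the test
#' suite.
#'
#' @param model a [retina_field_model()].
#' @param n_side electrodes per side (1, 2, 4, 10, ...), centered layout;
#'   or pass explicit `centers`.
#' @param istim_total total stimulation current, A.
#' @param frequency Hz.
#' @param centers optional explicit electrode centers (`m x 2`, meters).
#' @return an `electrode_array_field`.
#' @export
superpose_electrodes <- function(model, n_side = 1, istim_total = 0.5e-6,
                                 frequency = 0, centers = NULL) {
  if (is.null(centers)) {
    off <- (seq_len(n_side) - (n_side + 1) / 2) * model$pitch
    centers <- as.matrix(expand.grid(x = off, y = off))
  }
  centers <- rbind(centers)
  m <- nrow(centers)
  if (m > 1) {
    dmin <- min(stats::dist(centers))
    if (dmin < 2 * model$a) stop("overlapping electrode disks in layout")
  }
  base <- solve_field(model, istim = istim_total / m, frequency = frequency)
  structure(list(base = base, centers = centers, istim_total = istim_total,
                 frequency = frequency, model = model),
            class = "electrode_array_field")
}

#' @rdname field_at
#' @export
array_field_at <- function(field, x, y, z) {
  stopifnot(inherits(field, "electrode_array_field"))
  out <- 0
  for (k in seq_len(nrow(field$centers))) {
    out <- out + field_at(field$base, x, y, z,
                          center = field$centers[k, ])
  }
  out
}

# ---------------------------------------------------------------------------
# Extracellular voltages at compartments
# ---------------------------------------------------------------------------

#' Place a cell's compartments inside the retina cylinder
#'
#' Translates compartment coordinates (um) so the soma sits at lateral
#' offset `xy_um` and height `z_soma_um` above the electrode plane, with
#' the dendrites facing the electrodes (the morphology's lower-z side
#' down).
#'
#' @param comps a `compartments` data frame.
#' @param xy_um lateral offset `c(x, y)`, um.
#' @param z_soma_um height of the soma above the bottom face, um (30 um
#'   for subretinal placement).
#' @param soma soma compartment id (defaults to the root).
#' @return `n x 3` matrix of positions in meters.
#' @export
place_cell <- function(comps, xy_um = c(0, 0), z_soma_um = 30, soma = NULL) {
  if (is.null(soma)) soma <- comps$id[which(comps$parent < 0)[1]]
  k <- match(soma, comps$id)
  px <- (comps$x - comps$x[k] + xy_um[1]) * 1e-6
  py <- (comps$y - comps$y[k] + xy_um[2]) * 1e-6
  pz <- (comps$z - comps$z[k] + z_soma_um) * 1e-6
  cbind(x = px, y = py, z = pz)
}

#' Extracellular voltage traces at compartment centers
#'
#' Uses field linearity: the solved field for a reference current is
#' scaled by the stimulus waveform, `Vex(n, t) = Re V(center_n) *
#' i(t) / i_ref`. Appropriate for DC/resistive solves; for capacitive
#' broadband stimuli use [vex_from_waveform()].
#'
#' @param field a `retina_field` or `electrode_array_field`.
#' @param positions `n x 3` matrix of compartment centers, meters (from
#'   [place_cell()]).
#' @param waveform stimulation current trace, A.
#' @return matrix of extracellular voltages, mV, compartments x time.
#' @export
vex_at_compartments <- function(field, positions, waveform) {
  if (inherits(field, "electrode_array_field")) {
    v <- array_field_at(field, positions[, 1], positions[, 2], positions[, 3])
    iref <- field$istim_total
  } else {
    v <- field_at(field, positions[, 1], positions[, 2], positions[, 3])
    iref <- field$istim
  }
  outer(Re(v) / iref, waveform) * 1e3   # mV
}

#' Harmonic field bank for broadband stimuli
#'
#' Solves the (complex, capacitive) array field at DC and at the first
#' `n_harmonics` harmonics of a periodic stimulation window, for reuse
#' across waveforms and cell positions.
#'
#' @param model a [retina_field_model()].
#' @param n_side electrodes per side.
#' @param window_s stimulation window length, s.
#' @param n_harmonics number of harmonics retained.
#' @return a `harmonic_fields` list of `electrode_array_field`s (unit
#'   total current each).
#' @export
harmonic_fields <- function(model, n_side = 1, window_s = 0.040,
                            n_harmonics = 16) {
  fields <- lapply(0:n_harmonics, function(h) {
    superpose_electrodes(model, n_side, istim_total = 1,
                         frequency = h / window_s)
  })
  structure(list(fields = fields, window_s = window_s,
                 n_harmonics = n_harmonics, n_side = n_side, model = model),
            class = "harmonic_fields")
}

#' Broadband extracellular voltages via Fourier synthesis
#'
#' Decomposes a periodic stimulus waveform into its DC component and
#' harmonics, multiplies each by the corresponding complex field at the
#' compartment positions, and synthesizes the per-compartment
#' extracellular voltage traces in the time domain.
#'
#' @param bank a [harmonic_fields()] bank (or a [retina_field_model()],
#'   in which case the bank is built on the fly).
#' @param positions `n x 3` matrix of compartment centers, meters.
#' @param waveform stimulation current over one window, A (uniform grid
#'   spanning `window_s`).
#' @param dt waveform sampling interval, s.
#' @param n_harmonics number of harmonics (only used when `bank` is a
#'   model).
#' @param n_side electrodes per side (only used when `bank` is a model).
#' @return matrix of extracellular voltages, mV, compartments x time
#'   (same length as `waveform`).
#' @export
vex_from_waveform <- function(bank, positions, waveform, dt,
                              n_harmonics = 16, n_side = 1) {
  nt <- length(waveform)
  Tw <- nt * dt
  if (inherits(bank, "retina_field_model")) {
    bank <- harmonic_fields(bank, n_side = n_side, window_s = Tw,
                            n_harmonics = n_harmonics)
  }
  if (abs(bank$window_s - Tw) > dt / 2) {
    stop("waveform window does not match the harmonic field bank")
  }
  co <- stats::fft(waveform) / nt
  nh <- min(bank$n_harmonics, floor((nt - 1) / 2))
  out <- matrix(0, nrow(positions), nt)
  tgrid <- (seq_len(nt) - 1) * dt
  for (h in 0:nh) {
    fld <- bank$fields[[h + 1]]
    vh <- array_field_at(fld, positions[, 1], positions[, 2],
                         positions[, 3])
    if (h == 0) {
      out <- out + outer(Re(vh), rep(Re(co[1]), nt))
    } else {
      f <- h / Tw
      phas <- outer(vh * 2 * co[h + 1], exp(2i * pi * f * tgrid))
      out <- out + Re(phas)
    }
  }
  out * 1e3   # mV
}

# ---------------------------------------------------------------------------
# Sinusoid fitting and electrode RC characterization
# ---------------------------------------------------------------------------

#' Least-squares sinusoid fit at a fixed frequency
#'
#' Fits `A sin(2 pi f t + phi)` (plus an offset) to a trace by quadrature
#' projection (closed form).
#'
#' @param trace numeric trace.
#' @param f frequency, Hz.
#' @param dt sampling interval, s.
#' @return a `sinusoid_fit`: list with `f`, `A` (>= 0), `phi` in
#'   `(-pi, pi]` and `offset`.
#' @export
fit_sinusoid <- function(trace, f, dt) {
  n <- length(trace)
  if (f * n * dt < 3) stop("trace must span at least 3 periods of f")
  t <- (seq_len(n) - 1) * dt
  S <- sin(2 * pi * f * t); C <- cos(2 * pi * f * t)
  fit <- stats::lm.fit(cbind(1, S, C), trace)
  a <- unname(fit$coefficients[2]); b <- unname(fit$coefficients[3])
  structure(list(f = f, A = sqrt(a^2 + b^2), phi = atan2(b, a),
                 offset = unname(fit$coefficients[1])),
            class = "sinusoid_fit")
}

#' Electrode RC parameters from voltage/current sinusoid fits
#'
#' The electrode (double layer plus parasitics) is modeled as a parallel
#' RC circuit. From the fitted phase difference `phiZ = phi(v) - phi(i)`
#' and amplitude ratio `|Z| = A(v)/A(i)`:
#' `Re = |Z| sqrt(1 + tan(phiZ)^2)` and
#' `Ce = -tan(phiZ) / (2 pi f Re)`.
#'
#' @param v_fit [fit_sinusoid()] of the electrode voltage.
#' @param i_fit [fit_sinusoid()] of the current through the electrode.
#' @param f frequency, Hz (must match both fits).
#' @return list with `f`, `Re` (Ohm), `Ce` (F), `phiZ`, `absZ`.
#' @export
electrode_rc <- function(v_fit, i_fit, f) {
  if (abs(v_fit$f - f) > 1e-9 || abs(i_fit$f - f) > 1e-9) {
    stop("fits must be at the same frequency f")
  }
  if (i_fit$A == 0) stop("zero current amplitude")
  phiZ <- v_fit$phi - i_fit$phi
  phiZ <- atan2(sin(phiZ), cos(phiZ))   # wrap to (-pi, pi]
  absZ <- v_fit$A / i_fit$A
  Re_ <- absZ * sqrt(1 + tan(phiZ)^2)
  Ce <- -tan(phiZ) / (2 * pi * f * Re_)
  list(f = f, Re = Re_, Ce = Ce, phiZ = phiZ, absZ = absZ)
}

#' Parallel-RC impedance
#'
#' @param R resistance, Ohm.
#' @param C capacitance, F.
#' @param f frequency, Hz.
#' @return complex impedance, Ohm.
#' @export
parallel_rc_impedance <- function(R, C, f) {
  R / (1 + 2i * pi * f * R * C)
}

#' Simulate the current through the electrode/tissue circuit
#'
#' The stimulation voltage drives the series combination of the electrode
#' RC (parallel R and C) and the layered cylinder's terminal admittance at
#' the stimulus frequency (from [solve_field()]). Returns the simulated
#' sinusoidal current trace on the same grid as the stimulus.
#'
#' @param vstim stimulation voltage trace, V.
#' @param rc electrode RC entry from [electrode_rc()] (or
#'   `list(Re=, Ce=)`).
#' @param model a [retina_field_model()]; set the retina material equal to
#'   the bath to simulate the no-retina (electrolyte only) circuit.
#' @param f stimulus frequency, Hz.
#' @param dt sampling interval, s.
#' @param field optional pre-solved `retina_field` at `f` (saves the
#'   solve).
#' @return current trace, A.
#' @export
simulate_circuit_current <- function(vstim, rc, model, f, dt, field = NULL) {
  vf <- fit_sinusoid(vstim, f, dt)
  Vph <- vf$A * exp(1i * vf$phi)
  Zel <- parallel_rc_impedance(rc$Re, rc$Ce, f)
  if (is.null(field)) field <- solve_field(model, istim = 1e-6, frequency = f)
  Zt <- 1 / field$Y
  Iph <- Vph / (Zel + Zt)
  t <- (seq_len(length(vstim)) - 1) * dt
  Im(Iph * exp(1i * 2 * pi * f * t))
}

# ---------------------------------------------------------------------------
# Two-stage tissue parameter inference
# ---------------------------------------------------------------------------

# total squared-error discrepancy between simulated and target currents
.tissue_discrepancy <- function(sigma, eps, stimuli, model_template, dt) {
  fields <- list()
  total <- 0
  for (s in stimuli) {
    key <- as.character(s$f)
    if (is.null(fields[[key]])) {
      m <- model_template
      m$sigma_retina <- sigma; m$eps_retina <- eps
      fields[[key]] <- solve_field(m, istim = 1e-6, frequency = s$f)
    }
    isim <- simulate_circuit_current(s$vstim, s$rc, NULL, s$f, dt,
                                     field = fields[[key]])
    total <- total + sum((s$target - isim)^2) * dt
  }
  total
}

#' Infer retina conductivity and permittivity from recorded currents
#'
#' Two-stage sampling optimization of the mean squared error between
#' simulated and target currents. Stage 1 samples the exponents of
#' `sigma = 2^p_sigma * 0.1 S/m` and `eps = 2^p_eps * 1e6` from Gaussian
#' priors (mean 1, sd 2) for three 50-sample rounds using the sequential
#' posterior engine. Stage 2 re-runs the inference in a linear parameter
#' space over the box spanned by the best 10% of stage-1 samples
#' (truncated normal priors, normalized space, sd 0.3). The parameters
#' with the lowest sampled discrepancy are returned.
#'
#' @param stimuli list of stimulus entries, each
#'   `list(vstim = <V trace>, target = <A trace>, f = <Hz>,
#'   rc = <electrode RC entry>)`; at least two frequencies.
#' @param model_template a [retina_field_model()] providing geometry and
#'   bath properties.
#' @param dt trace sampling interval, s.
#' @param seed integer seed.
#' @param rounds,n_per_round sampling schedule per stage.
#' @return list with `sigma_retina`, `eps_retina`, `discrepancy`, and an
#'   `audit` of all sampled parameters and discrepancies.
#' @export
infer_tissue_params <- function(stimuli, model_template, dt, seed = 1L,
                                rounds = 3, n_per_round = 50) {
  if (length(unique(vapply(stimuli, function(s) s$f, numeric(1)))) < 2) {
    stop("need stimuli at >= 2 frequencies")
  }
  for (s in stimuli) {
    if (sum(abs(s$target)) == 0) stop("degenerate target current (all zero)")
  }
  simfun <- function(p) {
    sigma <- 2^p[1] * 0.1
    eps <- 2^p[2] * 1e6
    d <- .tissue_discrepancy(sigma, eps, stimuli, model_template, dt)
    list(summary = base::log(d), valid = is.finite(d))
  }
  prior1 <- tn_prior(mean = c(1, 1), lower = c(-Inf, -Inf),
                     upper = c(Inf, Inf), sd = c(2, 2),
                     names = c("p_sigma", "p_eps"))
  st1 <- run_inference(simfun, prior1, rounds = rounds,
                       n_per_round = n_per_round, seed = seed,
                       x_target = "adaptive", kernel = "adaptive",
                       hidden = c(20, 20), epochs = 400,
                       truncate = FALSE)
  th1 <- do.call(rbind, lapply(st1$records, function(r) r$theta))
  d1 <- unlist(lapply(st1$records, function(r) exp(r$summaries[, 1])))
  sig1 <- 2^th1[, 1] * 0.1
  eps1 <- 2^th1[, 2] * 1e6
  best <- order(d1)[seq_len(max(2, floor(0.1 * length(d1))))]
  lo <- c(min(sig1[best]), min(eps1[best]))
  hi <- c(max(sig1[best]), max(eps1[best]))
  mu <- c(mean(sig1[best]), mean(eps1[best]))
  wiggle <- pmax(hi - lo, c(1e-4, 1e3))
  lo <- pmin(lo, mu - 1e-3 * wiggle); hi <- pmax(hi, mu + 1e-3 * wiggle)
  prior2 <- tn_prior(mean = mu, lower = lo, upper = hi,
                     names = c("sigma_retina", "eps_retina"))
  np <- normalized_prior(prior2)
  simfun2 <- function(u) {
    th <- denormalize_params(u, prior2)
    d <- .tissue_discrepancy(th[1], th[2], stimuli, model_template, dt)
    list(summary = base::log(d), valid = is.finite(d))
  }
  st2 <- run_inference(simfun2, np, rounds = rounds,
                       n_per_round = n_per_round, seed = seed + 1L,
                       x_target = "adaptive", kernel = "adaptive",
                       hidden = c(20, 20), epochs = 400, truncate = TRUE)
  th2 <- do.call(rbind, lapply(st2$records, function(r) r$theta))
  d2 <- unlist(lapply(st2$records, function(r) exp(r$summaries[, 1])))
  phys2 <- denormalize_params(th2, prior2)
  k <- which.min(d2)
  list(sigma_retina = unname(phys2[k, 1]), eps_retina = unname(phys2[k, 2]),
       discrepancy = d2[k],
       audit = list(stage1 = data.frame(sigma = sig1, eps = eps1,
                                        discrepancy = d1),
                    stage2 = data.frame(sigma = phys2[, 1],
                                        eps = phys2[, 2],
                                        discrepancy = d2),
                    stage2_box = list(lower = lo, upper = hi)))
}
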