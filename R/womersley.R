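# Pulsatile pipe-flow generator with closed-form ground truth.
#
# Each flow harmonic Q_n e^{i n w t} drives the classical Bessel-function
# velocity profile; the generator returns the nodal field together with the
# closed-form flow waveform Q(t) and wall shear waveform tau(t) used as
# oracles by the downstream metric tests.

# Complex J0/J1 by power series; accurate for |z| up to ~30, which covers
# Womersley numbers well beyond the physiological range.
besselJ0_c <- function(z) {
  out <- rep(1 + 0i, length(z))
  term <- rep(1 + 0i, length(z))
  zz <- -(z / 2)^2
  for (m in 1:60) {
    term <- term * zz / m^2
    out <- out + term
  }
  out
}

besselJ1_c <- function(z) {
  out <- rep(1 + 0i, length(z))
  term <- rep(1 + 0i, length(z))
  zz <- -(z / 2)^2
  for (m in 1:60) {
    term <- term * zz / (m * (m + 1))
    out <- out + term
  }
  out * z / 2
}

#' Specification of a Womersley pulsatile tube flow
#'
#' @param radius tube radius (m).
#' @param length tube length (m).
#' @param period cycle period T (s).
#' @param harmonics data.frame with columns `n` (integer harmonic index,
#'   0 = steady), `amplitude` (ml/s) and `phase` (rad): the flow waveform is
#'   \eqn{Q(t) = \sum_n A_n \cos(n \omega t + \phi_n)}.
#' @param density fluid density (kg/m^3).
#' @param mu dynamic viscosity (Pa s).
#' @param radii_frac,ntheta,nz mesh resolution passed to [cylinder_mesh()].
#' @return object of class `hd_womersley_spec`; element `alpha` is the
#'   Womersley number \eqn{R\sqrt{\rho\omega/\mu}} of the fundamental.
#' @export
womersley_spec <- function(radius = 0.01, length = 0.04, period = 60 / 94,
                           harmonics = data.frame(n = c(0L, 1L),
                                                  amplitude = c(60, 40),
                                                  phase = c(0, 0)),
                           density = 1056, mu = 3.5e-3,
                           radii_frac = NULL, ntheta = 24L, nz = 8L) {
  stopifnot(radius > 0, period > 0, mu > 0, density > 0)
  omega <- 2 * pi / period
  alpha <- radius * sqrt(density * omega / mu)
  structure(list(radius = radius, length = length, period = period,
                 harmonics = harmonics, density = density, mu = mu,
                 omega = omega, alpha = alpha,
                 radii_frac = radii_frac, ntheta = ntheta, nz = nz),
            class = "hd_womersley_spec")
}

# Complex amplitude per harmonic in SI (m^3/s): Q_n(t) = Re{ Qc e^{i n w t} }.
womersley_qc <- function(spec) {
  h <- spec$harmonics
  complex(modulus = h$amplitude * 1e-6, argument = h$phase)
}

#' Closed-form Womersley flow waveform
#'
#' @param spec an `hd_womersley_spec`.
#' @param t times (s).
#' @return flow (ml/s).
#' @export
womersley_flow <- function(spec, t) {
  h <- spec$harmonics
  qc <- womersley_qc(spec)
  out <- numeric(length(t))
  for (k in seq_len(nrow(h)))
    out <- out + Re(qc[k] * exp(1i * h$n[k] * spec$omega * t)) * 1e6
  out
}

# Axial velocity profile u(r, t) in m/s; r may be a vector.
womersley_profile <- function(spec, r, t) {
  h <- spec$harmonics
  qc <- womersley_qc(spec)
  R <- spec$radius
  u <- matrix(0, length(r), length(t))
  for (k in seq_len(nrow(h))) {
    n <- h$n[k]
    if (n == 0L) {
      u <- u + outer(2 * Re(qc[k]) / (pi * R^2) * (1 - (r / R)^2), rep(1, length(t)))
    } else {
      alpha_n <- R * sqrt(spec$density * n * spec$omega / spec$mu)
      zeta <- complex(modulus = alpha_n, argument = 3 * pi / 4)
      J0z <- besselJ0_c(zeta)
      Dn <- 1 - 2 * besselJ1_c(zeta) / (zeta * J0z)
      prof <- (1 - besselJ0_c(zeta * r / R) / J0z) / Dn * qc[k] / (pi * R^2)
      u <- u + Re(outer(prof, exp(1i * n * spec$omega * t)))
    }
  }
  u
}

#' Closed-form Womersley wall shear waveform
#'
#' Axial component of the wall shear vector \eqn{\mu \partial u/\partial r}
#' at the wall (negative for forward flow, matching the sign convention of
#' [wall_shear_from_field()]).
#'
#' @param spec an `hd_womersley_spec`.
#' @param t times (s).
#' @return wall shear (Pa).
#' @export
womersley_wall_shear <- function(spec, t) {
  h <- spec$harmonics
  qc <- womersley_qc(spec)
  R <- spec$radius
  out <- numeric(length(t))
  for (k in seq_len(nrow(h))) {
    n <- h$n[k]
    if (n == 0L) {
      out <- out - 4 * spec$mu * Re(qc[k]) / (pi * R^3)
    } else {
      alpha_n <- R * sqrt(spec$density * n * spec$omega / spec$mu)
      zeta <- complex(modulus = alpha_n, argument = 3 * pi / 4)
      J0z <- besselJ0_c(zeta)
      Dn <- 1 - 2 * besselJ1_c(zeta) / (zeta * J0z)
      amp <- spec$mu * qc[k] / (pi * R^2) * zeta * besselJ1_c(zeta) / (R * J0z) / Dn
      out <- out + Re(amp * exp(1i * n * spec$omega * t))
    }
  }
  out
}

#' Generate a Womersley velocity field with its analytic oracles
#'
#' Samples the closed-form pulsatile profile at the nodes of a graded
#' cylinder mesh over one cycle.
#'
#' @param spec an `hd_womersley_spec`.
#' @param n_snapshots number of snapshots over the cycle (>= 8).
#' @return list with `field` (`hd_velocity_field`), `flow` and `wall_shear`
#'   (closed-form functions of time), `alpha`, and `spec`.
#' @export
womersley_field <- function(spec, n_snapshots = 16L) {
  if (n_snapshots < 8L)
    stop_hp("need at least 8 snapshots (got %d)", n_snapshots,
            class = "time_grid_error")
  if (spec$alpha > 50)
    warning(sprintf(paste("Womersley number %.1f: Stokes layer may be",
                          "under-resolved on the default mesh"), spec$alpha))
  args <- list(radius = spec$radius, length = spec$length,
               ntheta = spec$ntheta, nz = spec$nz)
  if (!is.null(spec$radii_frac)) args$radii_frac <- spec$radii_frac
  mesh <- do.call(cylinder_mesh, args)
  grid <- time_grid(spec$period, n_snapshots)
  r <- sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2)
  u <- womersley_profile(spec, r, grid$times)   # n_nodes x n_snapshots
  values <- lapply(seq_len(n_snapshots), function(k)
    cbind(0, 0, u[, k]))
  list(field = velocity_field(mesh, grid, values),
       flow = function(t) womersley_flow(spec, t),
       wall_shear = function(t) womersley_wall_shear(spec, t),
       alpha = spec$alpha, spec = spec)
}
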