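#' Uniform cyclic time grid
#'
#' One cardiac cycle `[0, T)` sampled at `n` uniformly spaced instants. All
#' cycle-periodic series in the package store one cycle under the convention
#' `value(T) = value(0)`, so each snapshot carries equal quadrature weight
#' `T/n` in cyclic time integrals.
#'
#' @param period cycle period T (s).
#' @param n number of snapshots (>= 2).
#' @param t0 time of the first snapshot (s), default 0.
#' @return object of class `hd_time_grid` with `period`, `times`, `dt`.
#' @export
time_grid <- function(period, n, t0 = 0) {
  if (n < 2L)
    stop_hp("a time grid needs at least 2 snapshots (got %d)", n,
            class = "time_grid_error")
  if (period <= 0) stop_hp("period must be positive", class = "time_grid_error")
  structure(list(period = period,
                 times = t0 + period * (seq_len(n) - 1L) / n,
                 dt = period / n),
            class = "hd_time_grid")
}

check_uniform_times <- function(times, period) {
  d <- diff(times)
  if (any(abs(d - d[1]) > 1e-9))
    stop_hp("snapshot times are not uniformly spaced", class = "time_grid_error")
  time_grid(period, length(times), t0 = times[1])
}

#' Time-resolved velocity field on a tetrahedral mesh
#'
#' @param mesh an `hd_mesh`.
#' @param grid an `hd_time_grid`; snapshot count must equal `length(values)`.
#' @param values list (one per snapshot) of n x 3 matrices of nodal
#'   velocities (m/s).
#' @return object of class `hd_velocity_field`.
#' @export
velocity_field <- function(mesh, grid, values) {
  stopifnot(inherits(mesh, "hd_mesh"), inherits(grid, "hd_time_grid"))
  if (length(values) != length(grid$times))
    stop_hp("snapshot count (%d) does not match time grid (%d)",
            length(values), length(grid$times), class = "field_error")
  for (v in values) {
    if (!is.matrix(v) || nrow(v) != nrow(mesh$nodes) || ncol(v) != 3L)
      stop_hp("each snapshot must be an n x 3 matrix", class = "field_error")
    if (!all(is.finite(v)))
      stop_hp("velocity values must be finite", class = "field_error")
  }
  structure(list(mesh = mesh, grid = grid, values = values),
            class = "hd_velocity_field")
}

#' @export
print.hd_velocity_field <- function(x, ...) {
  cat(sprintf("<hd_velocity_field> %d snapshots, %d nodes, T = %.4g s\n",
              length(x$values), nrow(x$mesh$nodes), x$grid$period))
  invisible(x)
}

#' Wall shear stress vector time series
#'
#' @param wall_node_ids node ids (into the parent mesh) of the wall nodes.
#' @param grid an `hd_time_grid`.
#' @param tau list (one per snapshot) of w x 3 matrices of shear vectors (Pa).
#' @param mesh optional parent `hd_mesh`, kept for plotting/profiles.
#' @return object of class `hd_wall_shear_field`.
#' @export
wall_shear_field <- function(wall_node_ids, grid, tau, mesh = NULL) {
  stopifnot(inherits(grid, "hd_time_grid"))
  if (length(tau) != length(grid$times))
    stop_hp("snapshot count does not match time grid", class = "field_error")
  for (m in tau) if (!all(is.finite(m)))
    stop_hp("shear values must be finite", class = "field_error")
  structure(list(wall_node_ids = as.integer(wall_node_ids), grid = grid,
                 tau = tau, mesh = mesh),
            class = "hd_wall_shear_field")
}

#' Subdomain labels for helicity regions
#'
#' Per-cell labels naming the five aortic analysis regions: ascending aorta
#' (AA), thoracic and abdominal true lumen (TLt, TLa) and false lumen
#' (FLt, FLa). `none` marks cells outside every region.
#'
#' @param labels character vector, one entry per cell.
#' @param mesh the `hd_mesh` the labels refer to.
#' @return object of class `hd_subdomain_mask`.
#' @export
subdomain_mask <- function(labels, mesh) {
  valid <- c("AA", "TLt", "FLt", "TLa", "FLa", "none")
  labels <- as.character(labels)
  if (length(labels) != nrow(mesh$tets))
    stop_hp("one label per cell required", class = "mask_error")
  if (!all(labels %in% valid))
    stop_hp("invalid labels: %s",
            paste(unique(setdiff(labels, valid)), collapse = ", "),
            class = "mask_error")
  used <- setdiff(unique(labels), "none")
  structure(list(labels = labels, regions = used), class = "hd_subdomain_mask")
}

#' Blood properties and viscosity model
#'
#' Newtonian by default (mu = 3.5 mPa s, density 1056 kg/m^3). A
#' Carreau-Yasuda model can be selected by supplying its coefficients
#' (`mu0`, `mu_inf` in Pa s, relaxation time `lambda` in s, exponents
#' `a`, `n`), in which case the viscosity is evaluated from the local shear
#' rate when wall shear is extracted.
#'
#' @param density fluid density (kg/m^3).
#' @param mu Newtonian dynamic viscosity (Pa s).
#' @param carreau_yasuda optional named list with `mu0`, `mu_inf`, `lambda`,
#'   `a`, `n`.
#' @return object of class `hd_fluid`.
#' @export
fluid_properties <- function(density = 1056, mu = 3.5e-3, carreau_yasuda = NULL) {
  if (density <= 0) stop_hp("density must be positive", class = "fluid_error")
  if (is.null(carreau_yasuda)) {
    if (mu <= 0) stop_hp("viscosity must be positive", class = "fluid_error")
  } else {
    need <- c("mu0", "mu_inf", "lambda", "a", "n")
    if (!all(need %in% names(carreau_yasuda)))
      stop_hp("carreau_yasuda needs fields %s", paste(need, collapse = ", "),
              class = "fluid_error")
    if (carreau_yasuda$mu0 <= 0 || carreau_yasuda$mu_inf <= 0)
      stop_hp("Carreau-Yasuda viscosities must be positive", class = "fluid_error")
  }
  structure(list(density = density, mu = mu, carreau_yasuda = carreau_yasuda),
            class = "hd_fluid")
}

#' Dynamic viscosity at given shear rates
#'
#' @param fluid an `hd_fluid`.
#' @param gamma_dot shear rate(s) (1/s), >= 0.
#' @return viscosity (Pa s), vectorised over `gamma_dot`.
#' @export
viscosity <- function(fluid, gamma_dot = 0) {
  if (is.null(fluid$carreau_yasuda)) return(rep(fluid$mu, length(gamma_dot)))
  cy <- fluid$carreau_yasuda
  cy$mu_inf + (cy$mu0 - cy$mu_inf) *
    (1 + (cy$lambda * gamma_dot)^cy$a)^((cy$n - 1) / cy$a)
}

#' Pressure unit conversion
#'
#' Exact factor 133.322 Pa per mmHg; `to_SI` and `to_mmHg` compose to the
#' identity at double precision.
#'
#' @param value pressure value(s).
#' @param direction `"to_SI"` (mmHg -> Pa) or `"to_mmHg"` (Pa -> mmHg).
#' @return converted pressure.
#' @export
mmhg_convert <- function(value, direction = c("to_SI", "to_mmHg")) {
  direction <- match.arg(direction)
  if (!all(is.finite(value))) stop_hp("pressure must be finite", class = "unit_error")
  if (direction == "to_SI") value * 133.322 else value / 133.322
}
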