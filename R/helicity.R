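# Vorticity, helicity time series, local normalized helicity, and the bulk
# indices h1-h3 by subdomain and cycle phase.

#' Vorticity of a velocity field
#'
#' Curl from cell-wise linear shape-function gradients (exact for linear
#' velocity fields), with volume-weighted node averages for visualisation.
#'
#' @param field an `hd_velocity_field`.
#' @return list with `cell` and `node`: lists (one per snapshot) of
#'   per-cell / per-node vorticity vectors (1/s).
#' @export
vorticity_field <- function(field) {
  op <- gradient_operator(field$mesh)
  cell <- lapply(field$values, function(v) {
    gu <- cell_gradients(op, v[, 1])
    gv <- cell_gradients(op, v[, 2])
    gw <- cell_gradients(op, v[, 3])
    cbind(gw[, 2] - gv[, 3], gu[, 3] - gw[, 1], gv[, 1] - gu[, 2])
  })
  node <- lapply(cell, function(w) cells_to_nodes(field$mesh, w))
  list(cell = cell, node = node)
}

# Cell-centred helicity density per snapshot: v_cell . omega_cell, with
# v_cell the nodal mean. Integration weight is the cell volume.
helicity_density_cells <- function(field, vort = NULL) {
  if (is.null(vort)) vort <- vorticity_field(field)
  tets <- field$mesh$tets
  lapply(seq_along(field$values), function(k) {
    v <- field$values[[k]]
    vc <- (v[tets[, 1], , drop = FALSE] + v[tets[, 2], , drop = FALSE] +
             v[tets[, 3], , drop = FALSE] + v[tets[, 4], , drop = FALSE]) / 4
    rowSums(vc * vort$cell[[k]])
  })
}

region_cells <- function(mask, region, mesh) {
  if (region == "whole") return(seq_len(nrow(mesh$tets)))
  w <- which(mask$labels == region)
  if (length(w) == 0L)
    stop_hp("region %s contains no cells", region, class = "empty_region_error")
  w
}

#' Helicity and helicity-magnitude time series by region
#'
#' `H(t)` integrates the helicity density over the region volume;
#' `|H|(t)` integrates its absolute value (distinguishing symmetric
#' counter-rotation from absent swirl).
#'
#' @param field an `hd_velocity_field`.
#' @param mask an `hd_subdomain_mask` (or `NULL` for the whole domain).
#' @param regions regions to report (default: all in the mask).
#' @return data.frame `region`, `time_s`, `H` (m^4/s^2), `absH`.
#' @export
helicity_timeseries <- function(field, mask = NULL, regions = NULL) {
  hk <- helicity_density_cells(field)
  vol <- field$mesh$cell_volumes
  if (is.null(regions))
    regions <- if (is.null(mask)) "whole" else mask$regions
  out <- lapply(regions, function(rg) {
    cells <- region_cells(mask, rg, field$mesh)
    data.frame(region = rg, time_s = field$grid$times,
               H = vapply(hk, function(h) sum(h[cells] * vol[cells]), numeric(1)),
               absH = vapply(hk, function(h) sum(abs(h[cells]) * vol[cells]),
                             numeric(1)))
  })
  do.call(rbind, out)
}

#' Plane-integrated helicity time series
#'
#' @param field an `hd_velocity_field`.
#' @param plane an `hd_plane`.
#' @return data.frame `time_s`, `H` (m^3/s^2), `absH`.
#' @export
plane_helicity <- function(field, plane) {
  vort <- vorticity_field(field)
  M <- plane_interp(plane, field$mesh)
  rows <- lapply(seq_along(field$values), function(k) {
    v <- sample_on_plane(field, plane, k)
    w <- if (is.null(M)) vort$node[[k]][plane$node_ids, , drop = FALSE]
         else as.matrix(M %*% vort$node[[k]])
    hk <- rowSums(v * w)
    data.frame(time_s = field$grid$times[k],
               H = sum(hk * plane$weights), absH = sum(abs(hk) * plane$weights))
  })
  do.call(rbind, rows)
}

#' Local normalized helicity field
#'
#' `LNH = v . omega / (|v| |omega|)`, clamped to `[-1, 1]`; set to zero by
#' convention where `|v||omega|` falls below `guard` (avoids spurious +-1 in
#' stagnant regions).
#'
#' @param field an `hd_velocity_field`.
#' @param guard zero-guard on `|v||omega|` (SI).
#' @return list (one per snapshot) of per-node LNH values.
#' @export
lnh_field <- function(field, guard = 1e-12) {
  vort <- vorticity_field(field)
  lapply(seq_along(field$values), function(k) {
    v <- field$values[[k]]
    w <- vort$node[[k]]
    denom <- row_norms(v) * row_norms(w)
    lnh <- ifelse(denom < guard, 0, rowSums(v * w) / pmax(denom, guard))
    pmin(pmax(lnh, -1), 1)
  })
}

#' End of systole from a flow waveform
#'
#' First down-crossing of the inlet flow through 5% of its peak after peak
#' systole; falls back to `0.35 T` when the waveform never decays below the
#' threshold.
#'
#' @param q_in flow samples at the grid times (ml/s).
#' @param grid `hd_time_grid`.
#' @return end-of-systole time (s).
#' @export
systole_end <- function(q_in, grid) {
  pk <- which.max(q_in)
  thr <- 0.05 * q_in[pk]
  after <- which(seq_along(q_in) > pk & q_in < thr)
  if (length(after)) grid$times[after[1]] else 0.35 * grid$period
}

#' Bulk helicity indices h1-h3 by region and cycle window
#'
#' `h1` is the time-volume average of the helicity density over the region
#' and window, `h2` the same for its magnitude, and `h3 = h1/h2` the signed
#' balance between right- and left-handed rotation (`+` clockwise). Windows
#' default to systole/diastole/full cycle with the systole end from
#' `q_in` (see [systole_end()]) or `0.35 T`.
#'
#' @param field an `hd_velocity_field`.
#' @param mask an `hd_subdomain_mask` (or `NULL` for the whole domain).
#' @param windows named list of `c(t0, t1)` intervals (s); snapshots with
#'   `t0 <= t < t1` are included.
#' @param q_in optional inlet flow samples used for the default
#'   systole/diastole split.
#' @return object of class `hd_helicity_report`: data.frame `region`,
#'   `window`, `h1` (m/s^2), `h2`, `h3`.
#' @export
bulk_helicity_indices <- function(field, mask = NULL, windows = NULL,
                                  q_in = NULL) {
  Tcyc <- field$grid$period
  if (is.null(windows)) {
    t_sys <- if (is.null(q_in)) 0.35 * Tcyc else systole_end(q_in, field$grid)
    windows <- list(systole = c(0, t_sys), diastole = c(t_sys, Tcyc),
                    full = c(0, Tcyc))
  }
  for (w in windows) if (diff(w) <= 0)
    stop_hp("window of zero length", class = "window_error")
  hk <- helicity_density_cells(field)
  vol <- field$mesh$cell_volumes
  t_rel <- (field$grid$times - field$grid$times[1]) %% Tcyc
  regions <- if (is.null(mask)) "whole" else mask$regions
  rows <- list()
  for (rg in regions) {
    cells <- region_cells(mask, rg, field$mesh)
    vr <- sum(vol[cells])
    for (wn in names(windows)) {
      w <- windows[[wn]]
      in_w <- t_rel >= w[1] - 1e-12 & t_rel < w[2] - 1e-12
      if (!any(in_w))
        stop_hp("window %s contains no snapshots", wn, class = "window_error")
      h1 <- mean(vapply(hk[in_w], function(h) sum(h[cells] * vol[cells]),
                        numeric(1))) / vr
      h2 <- mean(vapply(hk[in_w], function(h) sum(abs(h[cells]) * vol[cells]),
                        numeric(1))) / vr
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, window = wn, h1 = h1, h2 = h2,
        h3 = if (h2 > 0) h1 / h2 else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hd_helicity_report", "data.frame")
  out
}
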