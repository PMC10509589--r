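# Cross-case and clinical-correlate summaries: plane-wise Pearson
# correlation of velocity magnitude, transmural pressure, false-lumen
# ejection fraction, and luminal growth profiles.

#' Plane-wise Pearson correlation of velocity magnitude between cases
#'
#' Samples both fields at the same plane quadrature points and correlates
#' the velocity magnitudes per plane and time instant. Planes carry a lumen
#' tag so true- and false-lumen correlations are reported separately.
#'
#' @param case_a,case_b `hd_velocity_field`s on the same mesh.
#' @param planes list of `hd_plane`s (optionally named).
#' @param times snapshot indices to compare.
#' @return data.frame `plane`, `lumen`, `time_index`, `time_s`, `r`,
#'   `undefined` (zero-variance flag).
#' @export
pearson_planes <- function(case_a, case_b, planes,
                           times = seq_along(case_a$values)) {
  if (!isTRUE(all.equal(case_a$mesh$nodes, case_b$mesh$nodes)))
    stop_hp("cases live on different meshes", class = "mesh_mismatch_error")
  nm <- names(planes) %||% paste0("plane", seq_along(planes))
  rows <- list()
  for (p in seq_along(planes)) {
    for (ti in times) {
      ma <- row_norms(sample_on_plane(case_a, planes[[p]], ti))
      mb <- row_norms(sample_on_plane(case_b, planes[[p]], ti))
      undef <- stats::sd(ma) == 0 || stats::sd(mb) == 0
      rows[[length(rows) + 1L]] <- data.frame(
        plane = nm[p], lumen = planes[[p]]$lumen_tag, time_index = ti,
        time_s = case_a$grid$times[ti],
        r = if (undef) NA_real_ else stats::cor(ma, mb), undefined = undef)
    }
  }
  do.call(rbind, rows)
}

#' Transmural pressure per station
#'
#' TMP is the plane-mean true-lumen pressure minus the plane-mean
#' false-lumen pressure at paired stations. Accepts the paired plane
#' pressure series produced by the phantom (or any data.frame with columns
#' `station`, `time_s`, `p_tl`, `p_fl` in mmHg).
#'
#' @param plane_pressures data.frame `station`, `time_s`, `p_tl`, `p_fl`.
#' @return data.frame per station: `tmp_mean`, `tmp_min`, `tmp_max` (mmHg).
#' @export
transmural_pressure <- function(plane_pressures) {
  need <- c("station", "time_s", "p_tl", "p_fl")
  if (!all(need %in% names(plane_pressures)))
    stop_hp("plane pressures need columns %s", paste(need, collapse = ","),
            class = "pairing_error")
  if (any(!is.finite(plane_pressures$p_tl)) || any(!is.finite(plane_pressures$p_fl)))
    stop_hp("unpaired station: missing TL or FL pressure", class = "pairing_error")
  tmp <- plane_pressures$p_tl - plane_pressures$p_fl
  agg <- function(f) tapply(tmp, plane_pressures$station, f)
  data.frame(station = as.numeric(names(agg(mean))),
             tmp_mean = as.numeric(agg(mean)),
             tmp_min = as.numeric(agg(min)),
             tmp_max = as.numeric(agg(max)))
}

#' Plane-mean of a nodal scalar (e.g. static pressure)
#'
#' @param mesh an `hd_mesh`.
#' @param values nodal scalar values.
#' @param plane an `hd_plane`.
#' @return area-weighted plane mean.
#' @export
plane_mean_scalar <- function(mesh, values, plane) {
  if (!is.null(plane$node_ids)) {
    v <- values[plane$node_ids]
  } else {
    M <- plane_interp(plane, mesh)
    v <- as.vector(M %*% values)
  }
  sum(v * plane$weights) / sum(plane$weights)
}

#' False-lumen ejection fraction
#'
#' Net retrograde flow volume through the primary entry tear per cycle, as
#' a percentage of the stroke volume. The tear plane normal is oriented
#' from true to false lumen, so negative instantaneous flux accumulates
#' into the retrograde volume.
#'
#' @param tear_flow data.frame `time_s`, `q_mls` (one cycle, uniformly
#'   sampled under the cyclic convention).
#' @param stroke_volume_ml stroke volume (ml), positive.
#' @return list: `flef_pct`, `retrograde_volume_ml`, `forward_volume_ml`.
#' @export
false_lumen_ejection_fraction <- function(tear_flow, stroke_volume_ml) {
  if (stroke_volume_ml <= 0)
    stop_hp("stroke volume must be positive", class = "flow_error")
  t <- tear_flow$time_s; q <- tear_flow$q_mls
  d <- diff(t)
  if (length(d) < 1L || any(abs(d - d[1]) > 1e-9 * max(abs(d))))
    stop_hp("tear flow series is not a uniformly sampled cycle",
            class = "periodicity_error")
  dt <- d[1]
  vr <- -sum(pmin(q, 0)) * dt
  vf <- sum(pmax(q, 0)) * dt
  list(flef_pct = 100 * vr / stroke_volume_ml,
       retrograde_volume_ml = vr, forward_volume_ml = vf)
}

#' Luminal growth profile between two acquisitions
#'
#' @param stations strictly increasing arc-length stations (m) from the
#'   primary entry tear.
#' @param areas_t1,areas_t2 luminal areas (mm^2) per station at the two
#'   acquisitions.
#' @return object of class `hd_growth_profile`: data.frame `station`,
#'   `area_t1`, `area_t2`, `growth_pct`.
#' @export
growth_profile <- function(stations, areas_t1, areas_t2) {
  if (length(stations) != length(areas_t1) || length(stations) != length(areas_t2))
    stop_hp("station/area lengths differ", class = "station_mismatch_error")
  if (any(diff(stations) <= 0))
    stop_hp("stations must be strictly increasing", class = "station_mismatch_error")
  out <- data.frame(station = stations, area_t1 = areas_t1, area_t2 = areas_t2,
                    growth_pct = 100 * (areas_t2 - areas_t1) / areas_t1)
  class(out) <- c("hd_growth_profile", "data.frame")
  out
}

#' Join a growth profile with metric station profiles
#'
#' Stations are matched by arc length with a tolerance of half the station
#' spacing; station ids are preserved end-to-end (one row per growth
#' station, no silent reindexing).
#'
#' @param growth an `hd_growth_profile`.
#' @param metric_profiles named list of data.frames each with a `station`
#'   column and one or more metric columns.
#' @param spacing station spacing (m), default 5 mm.
#' @return data.frame: growth columns plus each metric's columns (prefixed
#'   by the profile name), `NA` where a metric has no station within
#'   tolerance.
#' @export
align_growth <- function(growth, metric_profiles, spacing = 0.005) {
  out <- as.data.frame(growth)
  for (nm in names(metric_profiles)) {
    mp <- metric_profiles[[nm]]
    cols <- setdiff(names(mp), "station")
    matched <- lapply(out$station, function(s) {
      d <- abs(mp$station - s)
      j <- which.min(d)
      if (length(j) && d[j] <= spacing / 2) mp[j, cols, drop = FALSE]
      else stats::setNames(as.data.frame(as.list(rep(NA_real_, length(cols)))), cols)
    })
    block <- do.call(rbind, matched)
    names(block) <- paste(nm, cols, sep = "_")
    out <- cbind(out, block)
  }
  out
}
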