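# Synthetic generators beyond Womersley flow: a helical cylinder flow with
# uniform analytic helicity density, an MRI-like corrupted inlet sampler,
# and a two-lumen dissection phantom with prescribed clinical metrics.

#' Helical cylinder flow with uniform helicity density
#'
#' Rigid rotation plus axial translation, \eqn{v = \Omega r \hat\theta +
#' W \hat z}. The vorticity is exactly \eqn{2\Omega \hat z} and the helicity
#' density \eqn{H_k = 2 \Omega W} everywhere, making this the analytic
#' oracle for all helicity metrics.
#'
#' @param Omega rotation rate (rad/s).
#' @param W axial speed (m/s).
#' @param mesh a z-aligned cylinder mesh from [cylinder_mesh()].
#' @param n_snapshots snapshots over the cycle (the field is steady).
#' @param period cycle period (s).
#' @return list with `field` and the analytic `helicity_density`.
#' @export
helical_cylinder_field <- function(Omega, W, mesh, n_snapshots = 4L,
                                   period = 1) {
  grid <- time_grid(period, n_snapshots)
  v <- cbind(-Omega * mesh$nodes[, 2], Omega * mesh$nodes[, 1],
             rep(W, nrow(mesh$nodes)))
  list(field = velocity_field(mesh, grid, rep(list(v), n_snapshots)),
       helicity_density = 2 * Omega * W)
}

#' MRI-like inlet frame sampler
#'
#' Emulates a 4D-flow MRI export of the inlet plane: the velocity field is
#' sampled on a coarse voxel grid at a small number of timeframes, the
#' vessel contour translates and dilates sinusoidally over the cycle, and
#' per-component Gaussian noise is added. All randomness derives from
#' `seed`; the caller's RNG stream is untouched.
#'
#' @param wom result of [womersley_field()] (or any cylinder-mesh velocity
#'   field list with elements `field` and `spec`-like radius info).
#' @param n_frames number of timeframes (>= 4; the acquisition this emulates
#'   used 16).
#' @param voxel in-plane voxel edge (m).
#' @param noise_sd Gaussian noise s.d. per velocity component (m/s).
#' @param motion_amplitude contour translation/dilation amplitude (m).
#' @param seed integer seed fixing the noise stream.
#' @return object of class `hd_inlet_frames`: list of `frames` (each with
#'   `time`, `contour` (k x 3), `points` (q x 3), `vel` (q x 3), `ij` voxel
#'   indices), plus `period`, `radius`, `truth` (uncorrupted velocities).
#' @export
mri_like_inlet <- function(wom, n_frames = 16L, voxel = NULL, noise_sd = 0,
                           motion_amplitude = 0, seed = 1L) {
  if (n_frames < 4L)
    stop_hp("need at least 4 frames", class = "frame_error")
  field <- wom$field
  geo <- field$mesh$geometry
  R <- geo$radius
  if (is.null(voxel)) voxel <- R / 5
  if (voxel > R)
    stop_hp("voxel (%g m) larger than inlet radius (%g m)", voxel, R,
            class = "degenerate_sampling_error")
  Tcyc <- field$grid$period
  frame_times <- Tcyc * (seq_len(n_frames) - 1L) / n_frames

  # reference voxel grid on the undeformed disk
  half <- ceiling(R / voxel)
  gx <- voxel * (-half:half)
  g <- expand.grid(x = gx, y = gx)
  ij <- expand.grid(i = seq_along(gx), j = seq_along(gx))
  keep <- sqrt(g$x^2 + g$y^2) <= R * 0.999
  g <- g[keep, ]; ij <- ij[keep, ]
  ref_pts <- cbind(g$x, g$y, 0)
  M <- interp_matrix(field$mesh, ref_pts)

  ang <- 2 * pi * (0:63) / 64
  snaps <- field$values
  n_snap <- length(snaps)

  frames <- with_seed(seed, lapply(seq_len(n_frames), function(f) {
    t <- frame_times[f]
    # periodic linear interpolation between stored snapshots
    s <- (t / Tcyc) * n_snap
    k0 <- floor(s) %% n_snap; w1 <- s - floor(s)
    v_nodes <- (1 - w1) * snaps[[k0 + 1L]] + w1 * snaps[[(k0 + 1L) %% n_snap + 1L]]
    v_true <- as.matrix(M %*% v_nodes)

    phase <- sin(2 * pi * t / Tcyc)
    centre <- c(motion_amplitude * phase, 0, 0)
    dil <- 1 + 0.5 * (motion_amplitude / R) * phase
    pts <- sweep(ref_pts * dil, 2L, centre, `+`)
    contour <- cbind(centre[1] + R * dil * cos(ang),
                     centre[2] + R * dil * sin(ang), 0)
    vel <- v_true
    if (noise_sd > 0)
      vel <- vel + matrix(stats::rnorm(length(vel), sd = noise_sd),
                          nrow(vel), 3L)
    list(time = t, contour = contour, points = pts, vel = vel,
         truth = v_true, ij = as.matrix(ij))
  }))
  structure(list(frames = frames, period = Tcyc, radius = R, voxel = voxel,
                 seed = seed, n_grid = length(gx)),
            class = "hd_inlet_frames")
}

#' Write / read inlet frames as a CSV directory
#'
#' Per-frame CSV of voxel samples (`x,y,z,vx,vy,vz`) plus a contour polygon
#' CSV, with a JSON index carrying the frame times and cycle period.
#'
#' @param frames an `hd_inlet_frames`.
#' @param dir target directory.
#' @return `dir` (write) / `hd_inlet_frames` (read).
#' @export
write_inlet_frames <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(frames$frames)) {
    fr <- frames$frames[[k]]
    utils::write.csv(data.frame(
      x = fmt_num(fr$points[, 1]), y = fmt_num(fr$points[, 2]),
      z = fmt_num(fr$points[, 3]), vx = fmt_num(fr$vel[, 1]),
      vy = fmt_num(fr$vel[, 2]), vz = fmt_num(fr$vel[, 3])),
      file.path(dir, sprintf("frame_%03d.csv", k)),
      row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(
      x = fmt_num(fr$contour[, 1]), y = fmt_num(fr$contour[, 2]),
      z = fmt_num(fr$contour[, 3])),
      file.path(dir, sprintf("contour_%03d.csv", k)),
      row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(list(times = vapply(frames$frames, `[[`, numeric(1), "time"),
                            period = frames$period, radius = frames$radius),
                       file.path(dir, "frames.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_inlet_frames
#' @export
read_inlet_frames <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "frames.json"), simplifyVector = TRUE)
  frames <- lapply(seq_along(idx$times), function(k) {
    df <- utils::read.csv(file.path(dir, sprintf("frame_%03d.csv", k)))
    ct <- utils::read.csv(file.path(dir, sprintf("contour_%03d.csv", k)))
    list(time = idx$times[k], contour = as.matrix(ct),
         points = cbind(df$x, df$y, df$z), vel = cbind(df$vx, df$vy, df$vz),
         ij = NULL)
  })
  structure(list(frames = frames, period = idx$period, radius = idx$radius),
            class = "hd_inlet_frames")
}

#' Two-lumen dissection phantom with prescribed clinical metrics
#'
#' Two parallel duct lumens (true and false) with a tear plane connecting
#' them: the proximal section of the true lumen stands in for the ascending
#' aorta, and both lumens split into thoracic and abdominal subdomains.
#' Plane pressures, the tear flow waveform and the resulting transmural
#' pressure (TMP) and false-lumen ejection fraction (FLEF) are prescribed,
#' so every downstream clinical metric has an exact oracle.
#'
#' @param period cycle period (s); default matches a 94 bpm heart rate.
#' @param stroke_volume inlet stroke volume (ml).
#' @param retrograde_volume net retrograde tear-flow volume per cycle (ml).
#' @param tmp_offset prescribed TL-FL pressure offset (mmHg).
#' @param n_stations number of 5 mm analysis stations along the lumens.
#' @param n_time time samples for the prescribed waveforms.
#' @param n_cells cells per direction for each lumen's box mesh.
#' @return object of class `hd_phantom`: `mesh`, `mask`
#'   (`hd_subdomain_mask`), `field` (`hd_velocity_field`), `plane_pressures`
#'   (data.frame `station,time_s,p_tl,p_fl` in mmHg), `tear_flow`
#'   (data.frame `time_s,q_mls`, positive TL to FL), `oracles` (list with
#'   `tmp_mmHg`, `flef_pct`, `stroke_volume_ml`).
#' @export
two_lumen_phantom <- function(period = 60 / 94, stroke_volume = 70,
                              retrograde_volume = 1.5, tmp_offset = 2,
                              n_stations = 8L, n_time = 128L,
                              n_cells = c(2L, 2L, 6L)) {
  L <- (n_stations + 1L) * 0.005
  w <- 0.02
  tl <- box_mesh(c(0, 0, 0), c(w, w, L), n_cells)
  fl <- box_mesh(c(2 * w, 0, 0), c(w, w, L), n_cells)
  z_tear <- 0.25 * L
  if (z_tear <= 0 || z_tear >= L)
    stop_hp("tear plane does not intersect both lumens", class = "geometry_error")

  nodes <- rbind(tl$nodes, fl$nodes)
  tets <- rbind(tl$tets, fl$tets + nrow(tl$nodes))
  mesh <- hd_mesh(nodes, tets)

  cen <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] +
            nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  in_tl <- cen[, 1] < 1.5 * w
  lab <- ifelse(in_tl,
                ifelse(cen[, 3] < L / 3, "AA",
                       ifelse(cen[, 3] < 2 * L / 3, "TLt", "TLa")),
                ifelse(cen[, 3] < L / 2, "FLt", "FLa"))
  mask <- subdomain_mask(lab, mesh)

  grid <- time_grid(period, n_time)
  t <- grid$times
  area_tl <- w * w
  q_mean <- stroke_volume / period                      # ml/s
  q_in <- q_mean * (1 + 0.8 * sin(2 * pi * t / period)) # ml/s, always > 0
  values <- lapply(seq_len(n_time), function(k) {
    wz_tl <- q_in[k] * 1e-6 / area_tl
    wz_fl <- 0.1 * wz_tl
    node_tl <- nodes[, 1] < 1.5 * w
    cbind(0, 0, ifelse(node_tl, wz_tl, wz_fl))
  })
  field <- velocity_field(mesh, grid, values)

  stations <- 0.005 * seq_len(n_stations)
  p_tl <- outer(rep(1, n_stations), 100 + 10 * sin(2 * pi * t / period))
  p_fl <- p_tl - tmp_offset
  plane_pressures <- data.frame(
    station = rep(stations, each = n_time),
    time_s = rep(t, n_stations),
    p_tl = as.vector(t(p_tl)), p_fl = as.vector(t(p_fl)))

  # tear flow: forward half-sine over [0, Ts), retrograde half-sine after,
  # with prescribed forward and retrograde volumes (ml)
  Ts <- 0.4 * period
  v_fwd <- retrograde_volume + 0.05 * stroke_volume
  qf <- v_fwd * pi / (2 * Ts)
  qr <- retrograde_volume * pi / (2 * (period - Ts))
  q_tear <- ifelse(t < Ts, qf * sin(pi * t / Ts),
                   -qr * sin(pi * (t - Ts) / (period - Ts)))
  tear_flow <- data.frame(time_s = t, q_mls = q_tear)

  structure(list(mesh = mesh, mask = mask, field = field,
                 plane_pressures = plane_pressures, tear_flow = tear_flow,
                 stations = stations, period = period,
                 oracles = list(tmp_mmHg = tmp_offset,
                                flef_pct = 100 * retrograde_volume / stroke_volume,
                                stroke_volume_ml = stroke_volume)),
            class = "hd_phantom")
}
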