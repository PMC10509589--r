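# Construction of the four inlet velocity profile (IVP) variants from
# per-timeframe inlet data: full three-component (4D), flat, through-plane
# (TP), and velocity-scaled. All variants derive from one reference profile
# so their flow waveforms match by construction.

#' Inlet patch plane of a cylinder mesh
#'
#' @param mesh a [cylinder_mesh()] result.
#' @return an `hd_plane` over the inlet patch, normal oriented into the
#'   domain.
#' @export
inlet_patch_plane <- function(mesh) {
  plane_from_patch(mesh, mesh$inlet_tris, direction = mesh$geometry$axis)
}

# Boundary (perimeter) node ids of a triangulated patch.
patch_perimeter <- function(tris) {
  e <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  once <- key %in% names(which(table(key) == 1L))
  sort(unique(as.vector(e[once, ])))
}

# Periodic piecewise-linear radius function r(theta) from 2D polygon points
# about a given centre, evaluated at angles `at`.
radius_function <- function(p2, centre, at) {
  d <- sweep(p2, 2L, centre)
  th <- atan2(d[, 2], d[, 1])
  r <- sqrt(rowSums(d^2))
  o <- order(th)
  th <- th[o]; r <- r[o]
  th_ext <- c(th - 2 * pi, th, th + 2 * pi)
  r_ext <- c(r, r, r)
  stats::approx(th_ext, r_ext, xout = at)$y
}

#' Register inlet frames onto a fixed inlet patch
#'
#' Maps each frame's sample points onto the inlet: a similarity alignment
#' (translation, uniform scale, in-plane rotation of the frame contour onto
#' the inlet perimeter) followed by a regularised non-rigid radial
#' refinement whose stiffness is set by `rigidity` (large values suppress
#' the non-rigid part; `Inf` disables it). In-plane velocity components are
#' rotated with the alignment.
#'
#' @param frames an `hd_inlet_frames`.
#' @param inlet_plane patch plane from [inlet_patch_plane()].
#' @param rigidity non-negative stiffness weight of the non-rigid step.
#' @return object of class `hd_mapped_frames`: per frame `time`, `points`
#'   (mapped, 3D), `vel`, `map` (function mapping raw 3D points), and
#'   `transform` (`translation`, `scale`, `rotation`, `residual_rms`).
#' @export
register_frames <- function(frames, inlet_plane, rigidity = 10) {
  normal <- inlet_plane$normal
  basis <- plane_basis(normal)
  origin <- inlet_plane$origin
  to2d <- function(p) cbind((sweep(p, 2L, origin)) %*% basis$e1,
                            (sweep(p, 2L, origin)) %*% basis$e2)
  to3d <- function(p2) sweep(p2[, 1, drop = FALSE] %*% t(basis$e1) +
                             p2[, 2, drop = FALSE] %*% t(basis$e2), 2L, origin, `+`)

  perim <- patch_perimeter(inlet_plane$tris)
  target2d <- to2d(inlet_plane$points[match(perim, inlet_plane$node_ids), , drop = FALSE])
  ct <- colMeans(target2d)
  nang <- 128L
  ang <- 2 * pi * (0:(nang - 1L)) / nang
  r_t <- radius_function(target2d, ct, ang)

  mapped <- lapply(frames$frames, function(fr) {
    c2 <- to2d(fr$contour)
    cf <- colMeans(c2)
    r_f <- radius_function(c2, cf, ang)
    scale <- mean(r_t) / mean(r_f)

    # rotation: circular shift of the radius function minimising the misfit;
    # ties resolve to the smallest rotation angle
    costs <- vapply(0:(nang - 1L), function(k) {
      rs <- r_f[((seq_len(nang) - 1L + k) %% nang) + 1L]
      sum((r_t - scale * rs)^2)
    }, numeric(1))
    phis <- ifelse(ang > pi, ang - 2 * pi, ang)
    best <- which(costs <= min(costs) + 1e-9 * sum(r_t^2))
    phi <- phis[best[which.min(abs(phis[best]))]]
    rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L, 2L)

    # non-rigid radial refinement: Fourier-damped angular scale profile
    c2rot <- sweep(sweep(c2, 2L, cf) %*% t(rot), 2L, cf, `+`)
    r_f_rot <- radius_function(c2rot, cf, ang)
    s_ang <- r_t / (scale * r_f_rot)
    if (is.finite(rigidity)) {
      sh <- stats::fft(s_ang)
      k_idx <- c(0:(nang / 2), -((nang / 2 - 1):1))
      sh <- sh / (1 + rigidity * k_idx^2)
      sh[1] <- stats::fft(s_ang)[1]          # keep the mean exactly
      s_sm <- Re(stats::fft(sh, inverse = TRUE)) / nang
    } else s_sm <- rep(mean(s_ang), nang)
    s_fun <- stats::approxfun(c(ang, 2 * pi), c(s_sm, s_sm[1]))

    map2d <- function(p2) {
      q <- sweep(p2, 2L, cf) %*% t(rot) * scale
      th <- atan2(q[, 2], q[, 1]) %% (2 * pi)
      q * s_fun(th) + matrix(ct, nrow(q), 2L, byrow = TRUE)
    }
    map3d <- function(p3) to3d(map2d(to2d(p3)))

    # rotate in-plane velocity components with the alignment
    a <- fr$vel %*% basis$e1
    b <- fr$vel %*% basis$e2
    a2 <- cos(phi) * a - sin(phi) * b
    b2 <- sin(phi) * a + cos(phi) * b
    vel <- fr$vel + (a2 - a) %*% t(basis$e1) + (b2 - b) %*% t(basis$e2)

    mc <- map2d(c2)
    res <- sqrt(mean((sqrt(rowSums(sweep(mc, 2L, ct)^2)) -
                        radius_function(target2d, ct,
                                        atan2(mc[, 2] - ct[2], mc[, 1] - ct[1])))^2))
    if (res > 0.2 * mean(r_t))
      stop_hp(paste("registration residual %.3g m exceeds 20%% of inlet",
                    "radius %.3g m at frame t = %.3f s"), res, mean(r_t),
              fr$time, class = "registration_error")
    list(time = fr$time, points = map3d(fr$points), vel = vel, map = map3d,
         transform = list(translation = c(ct - cf, 0), scale = scale,
                          rotation = phi, residual_rms = res))
  })
  structure(list(frames = mapped, plane = inlet_plane, basis = basis,
                 centre2d = ct, radius = mean(r_t)),
            class = "hd_mapped_frames")
}

# Moving-least-squares (quadratic, Gaussian-weighted) interpolation of
# scattered 2D samples onto query points.
mls_interp <- function(xy, values, query, h) {
  n <- nrow(xy)
  k <- min(12L, n)
  out <- matrix(0, nrow(query), ncol(values))
  for (q in seq_len(nrow(query))) {
    d2 <- (xy[, 1] - query[q, 1])^2 + (xy[, 2] - query[q, 2])^2
    nb <- order(d2)[seq_len(k)]
    w <- exp(-d2[nb] / h^2)
    dx <- xy[nb, 1] - query[q, 1]
    dy <- xy[nb, 2] - query[q, 2]
    A <- cbind(1, dx, dy, dx * dx, dx * dy, dy * dy)
    fit <- tryCatch({
      Aw <- A * w
      coef <- solve(crossprod(Aw, A) + diag(1e-12, 6L), crossprod(Aw, values[nb, , drop = FALSE]))
      coef[1, ]
    }, error = function(e) {
      A1 <- cbind(1, dx, dy)
      Aw <- A1 * w
      coef <- solve(crossprod(Aw, A1) + diag(1e-12, 3L), crossprod(Aw, values[nb, , drop = FALSE]))
      coef[1, ]
    })
    out[q, ] <- fit
  }
  out
}

#' Build the reference (4D) inlet velocity profile
#'
#' Spatially interpolates each mapped frame onto a fixed uniform grid,
#' performs periodic temporal spline interpolation (the frame cycle is
#' repeated three times and the central cycle extracted) to the target time
#' grid, interpolates to the inlet nodes, and zeroes the perimeter nodes so
#' the no-slip condition is met. The flow waveform `Q_in(t)` is computed
#' from the stored profile by patch quadrature.
#'
#' @param mapped an `hd_mapped_frames`.
#' @param target_grid `hd_time_grid` for the output profile.
#' @param grid_frac intermediate uniform grid spacing as a fraction of the
#'   inlet diameter.
#' @return object of class `hd_inlet_profile`: `plane`, `grid`, `values`
#'   (list of q x 3 nodal velocity matrices), `q_in` (ml/s).
#' @export
build_4d_ivp <- function(mapped, target_grid, grid_frac = 1 / 40) {
  plane <- mapped$plane
  basis <- plane_basis(plane$normal)
  origin <- plane$origin
  R <- mapped$radius
  for (fr in mapped$frames) if (!all(is.finite(fr$vel)))
    stop_hp("non-finite frame velocities", class = "data_error")

  hgrid <- 2 * R * grid_frac
  gx <- seq(-R, R, by = hgrid)
  gq <- as.matrix(expand.grid(x = gx, y = gx))
  inside <- sqrt(rowSums(gq^2)) <= R + 1e-12
  gq <- gq[inside, , drop = FALSE]

  frame_times <- vapply(mapped$frames, `[[`, numeric(1), "time")
  nf <- length(frame_times)
  Tcyc <- target_grid$period

  # spatial interpolation of each frame onto the fixed grid
  grid_vals <- lapply(mapped$frames, function(fr) {
    p2 <- cbind(sweep(fr$points, 2L, origin) %*% basis$e1,
                sweep(fr$points, 2L, origin) %*% basis$e2)
    p2c <- sweep(p2, 2L, mapped$centre2d)
    spacing <- stats::median(sqrt(rowSums((p2c - p2c[c(2:nrow(p2c), 1L), ])^2)))
    mls_interp(p2c, fr$vel, gq, h = max(1.5 * spacing, 1.5 * hgrid))
  })

  # periodic temporal spline: tile three cycles, evaluate the central one
  tt <- c(frame_times - Tcyc, frame_times, frame_times + Tcyc)
  interp_t <- function(y) {
    f <- stats::splinefun(tt, rep(y, 3L), method = "natural")
    f(target_grid$times)
  }
  nq <- nrow(gq)
  series <- array(0, c(nq, 3L, length(target_grid$times)))
  for (comp in 1:3) {
    ymat <- vapply(grid_vals, function(gv) gv[, comp], numeric(nq)) # nq x nf
    for (p in seq_len(nq)) series[p, comp, ] <- interp_t(ymat[p, ])
  }

  # bilinear interpolation from the grid to the inlet nodes
  node2d <- cbind(sweep(plane$points, 2L, origin) %*% basis$e1,
                  sweep(plane$points, 2L, origin) %*% basis$e2)
  node2d <- sweep(node2d, 2L, colMeans(node2d))
  values <- bilinear_from_grid(gx, gq, series, node2d)

  perim <- patch_perimeter(plane$tris)
  perim_rows <- match(perim, plane$node_ids)
  for (k in seq_along(values)) values[[k]][perim_rows, ] <- 0

  profile_from_values(plane, target_grid, values)
}

bilinear_from_grid <- function(gx, gq, series, node2d) {
  ng <- length(gx)
  idx <- matrix(NA_integer_, ng, ng)
  gi <- round((gq[, 1] - gx[1]) / (gx[2] - gx[1])) + 1L
  gj <- round((gq[, 2] - gx[1]) / (gx[2] - gx[1])) + 1L
  idx[cbind(gi, gj)] <- seq_len(nrow(gq))
  nt <- dim(series)[3]
  h <- gx[2] - gx[1]
  lapply(seq_len(nt), function(k) {
    out <- matrix(0, nrow(node2d), 3L)
    fi <- (node2d[, 1] - gx[1]) / h
    fj <- (node2d[, 2] - gx[1]) / h
    i0 <- pmin(pmax(floor(fi) + 1L, 1L), ng - 1L)
    j0 <- pmin(pmax(floor(fj) + 1L, 1L), ng - 1L)
    wx <- fi - (i0 - 1L); wy <- fj - (j0 - 1L)
    for (di in 0:1) for (dj in 0:1) {
      cell <- idx[cbind(i0 + di, j0 + dj)]
      wgt <- (if (di) wx else 1 - wx) * (if (dj) wy else 1 - wy)
      ok <- !is.na(cell)
      if (any(ok))
        out[ok, ] <- out[ok, ] + wgt[ok] * series[cell[ok], , k]
    }
    out
  })
}

profile_from_values <- function(plane, grid, values) {
  q_in <- vapply(values, function(v)
    sum((v %*% plane$normal) * plane$weights) * 1e6, numeric(1))
  structure(list(plane = plane, grid = grid, values = values, q_in = q_in),
            class = "hd_inlet_profile")
}

#' @export
print.hd_inlet_profile <- function(x, ...) {
  cat(sprintf("<hd_inlet_profile> %d nodes, %d snapshots, SV = %.2f ml\n",
              nrow(x$values[[1]]), length(x$values), stroke_volume(x)))
  invisible(x)
}

#' Flow waveform and stroke volume of an inlet profile
#'
#' @param profile an `hd_inlet_profile`.
#' @return `q_in_waveform()`: data.frame `time_s`, `q_mls`;
#'   `stroke_volume()`: net inlet volume per cycle (ml).
#' @export
q_in_waveform <- function(profile) {
  data.frame(time_s = profile$grid$times, q_mls = profile$q_in)
}

#' @rdname q_in_waveform
#' @export
stroke_volume <- function(profile) {
  periodic_integral(profile$q_in, profile$grid)
}

#' Flat inlet profile
#'
#' Spatially uniform plane-normal velocity carrying the reference flow
#' waveform: `Q_in(t)/area` at every inlet node, boundary included (the
#' profile is deliberately discontinuous at the wall).
#'
#' @param reference an `hd_inlet_profile`.
#' @return an `hd_inlet_profile` with matching `Q_in(t)`.
#' @export
make_flat_ivp <- function(reference) {
  area <- reference$plane$area
  if (area <= 0) stop_hp("zero inlet area", class = "geometry_error")
  n <- nrow(reference$values[[1]])
  nrm <- reference$plane$normal
  values <- lapply(reference$q_in, function(q)
    matrix(rep(q * 1e-6 / area * nrm, each = n), n, 3L))
  profile_from_values(reference$plane, reference$grid, values)
}

#' Through-plane inlet profile
#'
#' Keeps only the plane-normal component of the reference profile pointwise;
#' the flow waveform is unchanged since in-plane components carry no flux.
#'
#' @param reference an `hd_inlet_profile`.
#' @return an `hd_inlet_profile`.
#' @export
make_tp_ivp <- function(reference) {
  nrm <- reference$plane$normal
  values <- lapply(reference$values, function(v) (v %*% nrm) %*% t(nrm))
  profile_from_values(reference$plane, reference$grid, values)
}

#' Velocity-scaled inlet profile
#'
#' Multiplies all three velocity components by `factor`; the stroke volume
#' scales by exactly the same factor.
#'
#' @param reference an `hd_inlet_profile`.
#' @param factor positive scale factor (1.25 emulates the reported 20-30%
#'   underestimation of velocity by 4D-flow MRI).
#' @return an `hd_inlet_profile`.
#' @export
scale_ivp <- function(reference, factor = 1.25) {
  if (factor <= 0) stop_hp("factor must be positive", class = "ivp_error")
  values <- lapply(reference$values, function(v) v * factor)
  profile_from_values(reference$plane, reference$grid, values)
}
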