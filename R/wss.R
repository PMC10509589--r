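# Wall shear extraction and the four WSS indices (TAWSS, OSI, RRT, ECAP),
# with circumferential station profiles and pointwise case differences.

# Owning tet per wall triangle (a tet containing all three nodes).
wall_owner_tets <- function(mesh) {
  inc <- split(rep(seq_len(nrow(mesh$tets)), 4L), as.vector(mesh$tets))
  vapply(seq_len(nrow(mesh$wall_tris)), function(i) {
    tri <- mesh$wall_tris[i, ]
    cand <- inc[[as.character(tri[1])]]
    cand[vapply(cand, function(tc) all(tri %in% mesh$tets[tc, ]), logical(1))][1]
  }, integer(1))
}

# Outward unit normal per wall node (area-weighted over adjacent triangles).
wall_node_normals <- function(mesh) {
  a <- mesh$nodes[mesh$wall_tris[, 1], , drop = FALSE]
  b <- mesh$nodes[mesh$wall_tris[, 2], , drop = FALSE]
  c_ <- mesh$nodes[mesh$wall_tris[, 3], , drop = FALSE]
  nrm <- row_cross(b - a, c_ - a) / 2   # area-weighted
  n_nodes <- nrow(mesh$nodes)
  acc <- matrix(0, n_nodes, 3L)
  for (j in 1:3)
    for (k in 1:3)
      acc[, k] <- acc[, k] + scatter_add(mesh$wall_tris[, j], nrm[, k], n_nodes)
  nn <- acc[mesh$wall_nodes, , drop = FALSE]
  nn / row_norms(nn)
}

#' Wall shear stress vectors from a velocity field
#'
#' Computes the velocity gradient in wall-adjacent tetrahedra by linear
#' shape functions, volume-averages it to the wall nodes, and evaluates the
#' tangential viscous traction `mu (G + G^T) n` with the normal component
#' removed. For a Carreau-Yasuda fluid the viscosity is evaluated at the
#' local shear rate.
#'
#' @param field an `hd_velocity_field`.
#' @param fluid an `hd_fluid`.
#' @return an `hd_wall_shear_field` over `field$mesh$wall_nodes`.
#' @export
wall_shear_from_field <- function(field, fluid = fluid_properties()) {
  mesh <- field$mesh
  op <- gradient_operator(mesh)
  owners <- wall_owner_tets(mesh)
  normals <- wall_node_normals(mesh)
  wall_ids <- mesh$wall_nodes
  nwall <- length(wall_ids)
  n_nodes <- nrow(mesh$nodes)

  # accumulation of owner-cell gradients to wall nodes, volume weighted
  tri_nodes <- as.vector(mesh$wall_tris)            # 3w node ids
  tri_owner <- rep(owners, 3L)
  wvol <- mesh$cell_volumes[tri_owner]
  wsum_all <- scatter_add(tri_nodes, wvol, n_nodes)
  wsum <- wsum_all[wall_ids]

  tau <- lapply(field$values, function(v) {
    G <- vector("list", 3L)                          # G[[i]][cell, j] = dv_i/dx_j
    for (i in 1:3) G[[i]] <- cell_gradients(op, v[, i])
    Gw <- array(0, c(nwall, 3L, 3L))
    for (i in 1:3) for (j in 1:3) {
      acc <- scatter_add(tri_nodes, G[[i]][tri_owner, j] * wvol, n_nodes)
      Gw[, i, j] <- acc[wall_ids] / wsum
    }
    S <- Gw + aperm(Gw, c(1, 3, 2))                  # G + G^T
    tvec <- matrix(0, nwall, 3L)
    for (i in 1:3)
      tvec[, i] <- rowSums(S[, i, ] * normals)
    gdot <- sqrt(pmax(0.5 * apply(S^2, 1L, sum), 0))
    mu <- viscosity(fluid, gdot)
    tvec <- tvec * mu
    tn <- rowSums(tvec * normals)
    tvec - tn * normals
  })
  wall_shear_field(wall_ids, field$grid, tau, mesh = mesh)
}

#' Wall shear stress indices
#'
#' Cyclic time integrals use the periodic trapezoidal rule (equal snapshot
#' weights). The indices are
#' TAWSS (time-averaged shear magnitude, Pa), OSI (oscillatory shear index,
#' 0 to 0.5), RRT = 1 / ((1 - 2 OSI) TAWSS) = 1 / |time-mean shear vector|
#' (1/Pa), ECAP = OSI / TAWSS (1/Pa). Nodes with identically zero shear are
#' flagged undefined; purely oscillatory nodes have infinite RRT.
#'
#' @param tau an `hd_wall_shear_field`.
#' @return object of class `hd_wall_index_maps`: data.frame with columns
#'   `node_id`, `tawss`, `osi`, `rrt`, `ecap`, `undefined`.
#' @export
compute_wss_indices <- function(tau) {
  if (length(tau$tau) < 2L)
    stop_hp("need at least 2 snapshots", class = "time_grid_error")
  nw <- nrow(tau$tau[[1]])
  mean_vec <- Reduce(`+`, tau$tau) / length(tau$tau)
  mean_mag <- Reduce(`+`, lapply(tau$tau, row_norms)) / length(tau$tau)
  mvn <- row_norms(mean_vec)
  undef <- mean_mag <= 0
  osi <- ifelse(undef, NA_real_,
                pmin(pmax(0.5 * (1 - mvn / mean_mag), 0), 0.5))
  rrt <- ifelse(undef, NA_real_, ifelse(mvn > 0, 1 / mvn, Inf))
  ecap <- ifelse(undef, NA_real_, osi / mean_mag)
  out <- data.frame(node_id = tau$wall_node_ids, tawss = mean_mag, osi = osi,
                    rrt = rrt, ecap = ecap, undefined = undef)
  attr(out, "mesh") <- tau$mesh
  class(out) <- c("hd_wall_index_maps", "data.frame")
  out
}

#' Circumferentially averaged station profiles of the WSS indices
#'
#' Wall nodes are assigned to stations by their arc-length coordinate along
#' a centreline; each station band spans half the station spacing on either
#' side. Empty bands are reported as missing, never as zero.
#'
#' @param maps an `hd_wall_index_maps`.
#' @param arc arc-length coordinate (m) of each wall node (same order as
#'   `maps$node_id`); see [arc_length_along()].
#' @param stations station centres (m), ordered.
#' @param spacing station spacing (m), default 5 mm.
#' @param subset optional logical/index vector restricting the wall nodes
#'   (e.g. to one lumen).
#' @return data.frame `station`, `n_nodes`, `tawss`, `osi`, `rrt`, `ecap`,
#'   `missing`.
#' @export
circumferential_profile <- function(maps, arc, stations, spacing = 0.005,
                                    subset = NULL) {
  stopifnot(length(arc) == nrow(maps))
  keep <- rep(TRUE, nrow(maps))
  if (!is.null(subset)) {
    keep <- rep(FALSE, nrow(maps))
    keep[subset] <- TRUE
  }
  rows <- lapply(stations, function(s) {
    band <- keep & abs(arc - s) <= spacing / 2 & !maps$undefined
    if (!any(band))
      return(data.frame(station = s, n_nodes = 0L, tawss = NA_real_,
                        osi = NA_real_, rrt = NA_real_, ecap = NA_real_,
                        missing = TRUE))
    data.frame(station = s, n_nodes = sum(band),
               tawss = mean(maps$tawss[band]), osi = mean(maps$osi[band]),
               rrt = mean(maps$rrt[band][is.finite(maps$rrt[band])]),
               ecap = mean(maps$ecap[band]), missing = FALSE)
  })
  do.call(rbind, rows)
}

#' Arc-length coordinate of points along a polyline centreline
#'
#' @param centreline k x 3 matrix of centreline points (ordered).
#' @param points n x 3 matrix.
#' @return arc-length (m) of the nearest centreline projection per point.
#' @export
arc_length_along <- function(centreline, points) {
  seg <- diff(centreline)
  seg_len <- row_norms(seg)
  cum <- c(0, cumsum(seg_len))
  best_arc <- rep(Inf, nrow(points))
  best_d <- rep(Inf, nrow(points))
  for (s in seq_len(nrow(seg))) {
    a <- centreline[s, ]
    d <- sweep(points, 2L, a)
    t_ <- pmin(pmax((d %*% seg[s, ]) / seg_len[s]^2, 0), 1)
    proj <- outer(as.vector(t_), seg[s, ])
    dist <- row_norms(d - proj)
    better <- dist < best_d
    best_d[better] <- dist[better]
    best_arc[better] <- cum[s] + t_[better] * seg_len[s]
  }
  best_arc
}

#' Pointwise difference statistics between two index maps
#'
#' Differences are `candidate - baseline` over the masked wall nodes. The
#' percentage statistic is reported two ways: the mean of pointwise
#' relative differences (default, with small-baseline nodes excluded by an
#' epsilon guard) and the ratio of means.
#'
#' @param candidate,baseline `hd_wall_index_maps` on the same wall nodes.
#' @param subset optional logical/index mask of wall nodes (e.g. the false
#'   lumen).
#' @return data.frame per index: `min`, `max`, `mean`, `mean_rel_pct`,
#'   `ratio_of_means_pct`.
#' @export
difference_stats <- function(candidate, baseline, subset = NULL) {
  if (!identical(candidate$node_id, baseline$node_id))
    stop_hp("index maps live on different wall nodes", class = "mesh_mismatch_error")
  idx <- seq_len(nrow(candidate))
  if (!is.null(subset)) idx <- idx[subset]
  rows <- lapply(c("tawss", "osi", "rrt", "ecap"), function(nm) {
    cv <- candidate[[nm]][idx]; bv <- baseline[[nm]][idx]
    ok <- is.finite(cv) & is.finite(bv)
    d <- cv[ok] - bv[ok]
    guard <- max(1e-12, 1e-6 * max(bv[ok], na.rm = TRUE))
    rel_ok <- ok & is.finite(cv) & is.finite(bv) & bv > guard
    rel <- 100 * (cv[rel_ok] - bv[rel_ok]) / bv[rel_ok]
    data.frame(index = nm, min = min(d), max = max(d), mean = mean(d),
               mean_rel_pct = mean(rel),
               ratio_of_means_pct = 100 * mean(d) / mean(bv))
  })
  do.call(rbind, rows)
}
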