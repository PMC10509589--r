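#' Tetrahedral mesh with labelled wall surface
#'
#' Constructs the computational-domain container used by every stage of the
#' pipeline: node positions in metres, tetrahedral connectivity, and the
#' triangulated wall surface with outward normals. Cell volumes are computed
#' on construction; tetrahedra with negative signed volume are reoriented.
#' Node volumes are the usual lumped quarter-volumes.
#'
#' @param nodes numeric n x 3 matrix of node positions (m).
#' @param tets integer m x 4 matrix of tetrahedral connectivity (1-based).
#' @param wall_tris optional integer w x 3 matrix of wall surface triangles;
#'   if `NULL`, the full boundary of the mesh is used as the wall.
#' @return An object of class `hd_mesh` with elements `nodes`, `tets`,
#'   `wall_tris`, `wall_normals` (outward unit normals per wall triangle),
#'   `wall_nodes`, `cell_volumes`, `node_volumes`.
#' @export
hd_mesh <- function(nodes, tets, wall_tris = NULL) {
  nodes <- as.matrix(nodes)
  tets <- as.matrix(tets)
  dimnames(nodes) <- NULL
  dimnames(tets) <- NULL
  storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3L) stop_hp("nodes must be n x 3", class = "mesh_error")
  if (ncol(tets) != 4L)
    stop_hp("only tetrahedral cells are supported", class = "unsupported_mesh_error")
  if (max(tets) > nrow(nodes) || min(tets) < 1L)
    stop_hp("tet connectivity references missing nodes", class = "mesh_error")

  vol <- tet_signed_volumes(nodes, tets)
  flip <- vol < 0
  if (any(flip)) {
    tmp <- tets[flip, 3L]
    tets[flip, 3L] <- tets[flip, 4L]
    tets[flip, 4L] <- tmp
    vol <- abs(vol)
  }
  if (any(vol <= 0))
    stop_hp("mesh contains %d degenerate cells", sum(vol <= 0), class = "mesh_error")

  if (is.null(wall_tris)) {
    wall_tris <- boundary_faces(tets)
  } else {
    wall_tris <- as.matrix(wall_tris)
    storage.mode(wall_tris) <- "integer"
    if (max(wall_tris) > nrow(nodes))
      stop_hp("wall triangles reference missing nodes", class = "mesh_error")
  }
  wn <- orient_outward(nodes, tets, wall_tris)

  node_vol <- scatter_add(as.vector(tets), rep(vol / 4, 4L), nrow(nodes))

  structure(list(
    nodes = nodes, tets = tets,
    wall_tris = wn$tris, wall_normals = wn$normals,
    wall_nodes = sort(unique(as.vector(wn$tris))),
    cell_volumes = vol, node_volumes = node_vol
  ), class = "hd_mesh")
}

#' @export
print.hd_mesh <- function(x, ...) {
  cat(sprintf("<hd_mesh> %d nodes, %d tets, %d wall triangles, volume %.4g m^3\n",
              nrow(x$nodes), nrow(x$tets), nrow(x$wall_tris), sum(x$cell_volumes)))
  invisible(x)
}

tet_signed_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  rowSums(row_cross(b, c_) * d) / 6
}

# Faces of the tet mesh that belong to exactly one cell, in original winding.
boundary_faces <- function(tets) {
  f <- rbind(tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
             tets[, c(2, 3, 4)], tets[, c(1, 4, 3)])
  key <- apply(f, 1L, function(r) paste(sort.int(r), collapse = "_"))
  tab <- table(key)
  f[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

# Orient surface triangles so their normals point out of the mesh volume,
# using the owning tet's remaining node as the inside reference.
orient_outward <- function(nodes, tets, tris) {
  a <- nodes[tris[, 1], , drop = FALSE]
  b <- nodes[tris[, 2], , drop = FALSE]
  c_ <- nodes[tris[, 3], , drop = FALSE]
  nrm <- row_cross(b - a, c_ - a)
  centroid <- (a + b + c_) / 3

  # locate an owning tet per triangle via a node-to-tet incidence list
  n_nodes <- max(tets)
  inc <- split(rep(seq_len(nrow(tets)), 4L), as.vector(tets))
  inside <- matrix(0, nrow(tris), 3L)
  for (i in seq_len(nrow(tris))) {
    tri <- tris[i, ]
    cand <- inc[[as.character(tri[1])]]
    owner <- cand[vapply(cand, function(tc) all(tri %in% tets[tc, ]), logical(1))][1]
    opp <- setdiff(tets[owner, ], tri)
    inside[i, ] <- nodes[opp[1], ]
  }
  flip <- rowSums(nrm * (centroid - inside)) < 0
  if (any(flip)) {
    tmp <- tris[flip, 2L]
    tris[flip, 2L] <- tris[flip, 3L]
    tris[flip, 3L] <- tmp
    nrm[flip, ] <- -nrm[flip, ]
  }
  list(tris = tris, normals = nrm / row_norms(nrm))
}

scatter_add <- function(idx, w, n) {
  out <- numeric(n)
  r <- rowsum(w, idx)
  out[as.integer(rownames(r))] <- r
  out
}

#' Structured tetrahedral cylinder mesh
#'
#' Builds a cylinder of radius `radius` and length `length` aligned with the
#' z axis (inlet at z = 0), from concentric node rings extruded in z and
#' split into tetrahedra with a consistent prism subdivision. The default
#' radial grading clusters nodes towards the wall so that near-wall velocity
#' gradients (and hence wall shear) are resolved.
#'
#' @param radius tube radius (m).
#' @param length tube length (m).
#' @param radii_frac increasing vector of ring radii as fractions of
#'   `radius`, ending at 1.
#' @param ntheta number of circumferential nodes per ring.
#' @param nz number of axial element layers.
#' @return An `hd_mesh` with extra elements `inlet_nodes`, `outlet_nodes`
#'   (node ids on z = 0 and z = length), `inlet_tris`, and `geometry`
#'   (radius, length, axis).
#' @export
cylinder_mesh <- function(radius, length,
                          radii_frac = c(0.2, 0.4, 0.55, 0.68, 0.78, 0.86,
                                         0.92, 0.96, 0.985, 1),
                          ntheta = 24L, nz = 8L) {
  stopifnot(radius > 0, length > 0, all(diff(radii_frac) > 0),
            abs(radii_frac[length(radii_frac)] - 1) < 1e-12)
  nr <- base::length(radii_frac)
  theta <- 2 * pi * (seq_len(ntheta) - 1L) / ntheta

  # disk nodes: centre + rings
  disk <- rbind(c(0, 0),
                do.call(rbind, lapply(radii_frac, function(f)
                  cbind(radius * f * cos(theta), radius * f * sin(theta)))))
  ring_id <- function(j, i) 1L + (j - 1L) * ntheta + ((i - 1L) %% ntheta) + 1L

  # disk triangulation: centre fan + quad-split annuli
  tris <- matrix(0L, 0L, 3L)
  fan <- cbind(1L, ring_id(1L, seq_len(ntheta)), ring_id(1L, seq_len(ntheta) + 1L))
  tris <- rbind(tris, fan)
  if (nr > 1L) for (j in 2L:nr) {
    a <- ring_id(j - 1L, seq_len(ntheta)); b <- ring_id(j - 1L, seq_len(ntheta) + 1L)
    a2 <- ring_id(j, seq_len(ntheta)); b2 <- ring_id(j, seq_len(ntheta) + 1L)
    tris <- rbind(tris, cbind(a, b, b2), cbind(a, b2, a2))
  }

  nd <- nrow(disk)
  zs <- length * (0:nz) / nz
  nodes <- do.call(rbind, lapply(zs, function(z) cbind(disk, z)))

  lower <- tris
  tets <- vector("list", nz)
  for (k in seq_len(nz)) {
    off0 <- (k - 1L) * nd
    off1 <- k * nd
    prisms <- cbind(lower + off0, lower + off1)
    tets[[k]] <- split_prisms(prisms)
  }
  tets <- do.call(rbind, tets)

  m <- hd_mesh(nodes, tets, wall_tris = NULL)
  r2 <- sqrt(nodes[, 1]^2 + nodes[, 2]^2)
  on_wall <- r2 > radius * (1 - 1e-9)
  # restrict wall to the lateral surface; inlet/outlet caps are open boundaries
  lateral <- apply(m$wall_tris, 1L, function(tr) all(on_wall[tr]))
  keep <- which(lateral)
  inlet_keep <- which(apply(m$wall_tris, 1L, function(tr)
    all(abs(nodes[tr, 3]) < 1e-12)))
  m$inlet_tris <- m$wall_tris[inlet_keep, , drop = FALSE]
  m$wall_tris <- m$wall_tris[keep, , drop = FALSE]
  m$wall_normals <- m$wall_normals[keep, , drop = FALSE]
  m$wall_nodes <- sort(unique(as.vector(m$wall_tris)))
  m$inlet_nodes <- which(abs(nodes[, 3]) < 1e-12)
  m$outlet_nodes <- which(abs(nodes[, 3] - length) < 1e-12)
  m$geometry <- list(kind = "cylinder", radius = radius, length = length,
                     axis = c(0, 0, 1))
  m
}

# Consistent prism -> 3 tets subdivision (quad diagonals through the global
# minimum vertex), so adjacent prisms share matching diagonals.
split_prisms <- function(prisms) {
  perms <- rbind(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4), c(3, 1, 2, 6, 4, 5),
                 c(4, 6, 5, 1, 3, 2), c(5, 4, 6, 2, 1, 3), c(6, 5, 4, 3, 2, 1))
  out <- matrix(0L, 3L * nrow(prisms), 4L)
  for (p in seq_len(nrow(prisms))) {
    v0 <- prisms[p, ]
    pos <- which.min(v0)
    v <- v0[perms[pos, ]]
    if (min(v[2], v[6]) < min(v[3], v[5])) {
      t3 <- rbind(v[c(1, 2, 3, 6)], v[c(1, 2, 6, 5)], v[c(1, 5, 6, 4)])
    } else {
      t3 <- rbind(v[c(1, 2, 3, 5)], v[c(1, 5, 3, 6)], v[c(1, 5, 6, 4)])
    }
    out[(3L * p - 2L):(3L * p), ] <- t3
  }
  out
}

#' Structured tetrahedral box mesh
#'
#' Axis-aligned box subdivided into cubes, each split into six tetrahedra
#' along a common main diagonal (Kuhn subdivision, conforming across cubes).
#'
#' @param origin length-3 lower corner (m).
#' @param dims length-3 box edge lengths (m).
#' @param n length-3 integer cell counts per direction.
#' @return An `hd_mesh`; the wall is the full box boundary.
#' @export
box_mesh <- function(origin, dims, n) {
  n <- as.integer(n)
  xs <- origin[1] + dims[1] * (0:n[1]) / n[1]
  ys <- origin[2] + dims[2] * (0:n[2]) / n[2]
  zs <- origin[3] + dims[3] * (0:n[3]) / n[3]
  nx <- n[1] + 1L; ny <- n[2] + 1L
  idx <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  g <- expand.grid(x = xs, y = ys, z = zs)
  nodes <- as.matrix(g)

  cubes <- expand.grid(i = seq_len(n[1]), j = seq_len(n[2]), k = seq_len(n[3]))
  tets <- matrix(0L, 0L, 4L)
  tet_list <- vector("list", nrow(cubes))
  for (q in seq_len(nrow(cubes))) {
    i <- cubes$i[q]; j <- cubes$j[q]; k <- cubes$k[q]
    c000 <- idx(i, j, k);     c100 <- idx(i + 1L, j, k)
    c010 <- idx(i, j + 1L, k); c110 <- idx(i + 1L, j + 1L, k)
    c001 <- idx(i, j, k + 1L); c101 <- idx(i + 1L, j, k + 1L)
    c011 <- idx(i, j + 1L, k + 1L); c111 <- idx(i + 1L, j + 1L, k + 1L)
    tet_list[[q]] <- rbind(
      c(c000, c100, c110, c111), c(c000, c110, c010, c111),
      c(c000, c010, c011, c111), c(c000, c011, c001, c111),
      c(c000, c001, c101, c111), c(c000, c101, c100, c111))
  }
  hd_mesh(nodes, do.call(rbind, tet_list))
}

#' Linear-shape-function gradient operator
#'
#' Precomputes, per tetrahedron, the dual-basis vectors that turn nodal
#' differences into the (constant) cell gradient of a P1 field. Reused by
#' wall shear extraction and vorticity.
#'
#' @param mesh an `hd_mesh`.
#' @return opaque list used by [cell_gradients()].
#' @export
gradient_operator <- function(mesh) {
  t1 <- mesh$tets[, 1]
  r1 <- mesh$nodes[mesh$tets[, 2], , drop = FALSE] - mesh$nodes[t1, , drop = FALSE]
  r2 <- mesh$nodes[mesh$tets[, 3], , drop = FALSE] - mesh$nodes[t1, , drop = FALSE]
  r3 <- mesh$nodes[mesh$tets[, 4], , drop = FALSE] - mesh$nodes[t1, , drop = FALSE]
  det <- rowSums(row_cross(r1, r2) * r3)
  if (any(abs(det) < 1e-30))
    stop_hp("degenerate cells: %s",
            paste(utils::head(which(abs(det) < 1e-30), 10L), collapse = ", "),
            class = "mesh_error")
  list(tets = mesh$tets,
       g1 = row_cross(r2, r3) / det,
       g2 = row_cross(r3, r1) / det,
       g3 = row_cross(r1, r2) / det)
}

#' Cell gradients of a nodal scalar field
#'
#' @param op operator from [gradient_operator()].
#' @param u numeric vector of nodal values.
#' @return m x 3 matrix of per-cell gradients.
#' @export
cell_gradients <- function(op, u) {
  d1 <- u[op$tets[, 2]] - u[op$tets[, 1]]
  d2 <- u[op$tets[, 3]] - u[op$tets[, 1]]
  d3 <- u[op$tets[, 4]] - u[op$tets[, 1]]
  op$g1 * d1 + op$g2 * d2 + op$g3 * d3
}

# Volume-weighted average of per-cell values (vector or n x k matrix) to nodes.
cells_to_nodes <- function(mesh, cell_values) {
  cv <- as.matrix(cell_values)
  n <- nrow(mesh$nodes)
  wsum <- scatter_add(as.vector(mesh$tets), rep(mesh$cell_volumes, 4L), n)
  out <- matrix(0, n, ncol(cv))
  for (j in seq_len(ncol(cv))) {
    out[, j] <- scatter_add(as.vector(mesh$tets),
                            rep(cv[, j] * mesh$cell_volumes, 4L), n) / wsum
  }
  out
}
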