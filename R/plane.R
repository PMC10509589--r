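#' Analysis plane with its own quadrature
#'
#' A `PlaneSection` carries its own triangulated quadrature points and areal
#' weights (generated once from a disk of given radius), so plane integrals
#' do not depend on intersecting the volume mesh. The stored `area` is the
#' sum of the weights.
#'
#' @param origin length-3 plane origin (m).
#' @param normal length-3 plane normal (normalised internally).
#' @param radius disk radius (m).
#' @param nr,ntheta radial / circumferential quadrature resolution.
#' @param lumen_tag one of `"TL"`, `"FL"`, `"whole"`.
#' @return object of class `hd_plane` with `points` (q x 3), `weights` (m^2),
#'   `normal`, `origin`, `area`, `lumen_tag`.
#' @export
disk_plane <- function(origin, normal, radius, nr = 24L, ntheta = 48L,
                       lumen_tag = c("whole", "TL", "FL")) {
  lumen_tag <- match.arg(lumen_tag)
  normal <- normal / sqrt(sum(normal^2))
  basis <- plane_basis(normal)
  theta <- 2 * pi * (seq_len(ntheta) - 1L) / ntheta
  fr <- seq_len(nr) / nr
  p2 <- rbind(c(0, 0), do.call(rbind, lapply(fr, function(f)
    cbind(radius * f * cos(theta), radius * f * sin(theta)))))
  ring_id <- function(j, i) 1L + (j - 1L) * ntheta + ((i - 1L) %% ntheta) + 1L
  tris <- cbind(1L, ring_id(1L, seq_len(ntheta)), ring_id(1L, seq_len(ntheta) + 1L))
  if (nr > 1L) for (j in 2L:nr) {
    a <- ring_id(j - 1L, seq_len(ntheta)); b <- ring_id(j - 1L, seq_len(ntheta) + 1L)
    a2 <- ring_id(j, seq_len(ntheta)); b2 <- ring_id(j, seq_len(ntheta) + 1L)
    tris <- rbind(tris, cbind(a, b, b2), cbind(a, b2, a2))
  }
  tri_area <- abs((p2[tris[, 2], 1] - p2[tris[, 1], 1]) *
                    (p2[tris[, 3], 2] - p2[tris[, 1], 2]) -
                  (p2[tris[, 3], 1] - p2[tris[, 1], 1]) *
                    (p2[tris[, 2], 2] - p2[tris[, 1], 2])) / 2
  w <- scatter_add(as.vector(tris), rep(tri_area / 3, 3L), nrow(p2))
  pts <- sweep(p2[, 1, drop = FALSE] %*% t(basis$e1) +
               p2[, 2, drop = FALSE] %*% t(basis$e2), 2L, origin, `+`)
  structure(list(points = pts, weights = w, normal = normal, origin = origin,
                 area = sum(w), lumen_tag = lumen_tag, radius = radius,
                 basis = basis, cache = new.env(parent = emptyenv())),
            class = "hd_plane")
}

plane_basis <- function(normal) {
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Plane built on a boundary patch of a mesh
#'
#' Uses the patch nodes themselves as quadrature points with lumped triangle
#' areas as weights, so inlet-profile fluxes are exact nodal quadratures.
#'
#' @param mesh an `hd_mesh`.
#' @param tris triangle connectivity of the patch (e.g. `mesh$inlet_tris`).
#' @param direction optional length-3 vector; the patch normal is flipped to
#'   have a positive dot product with it (e.g. into the domain).
#' @param lumen_tag lumen label, as in [disk_plane()].
#' @return an `hd_plane` with extra element `node_ids` (patch node ids).
#' @export
plane_from_patch <- function(mesh, tris, direction = NULL,
                             lumen_tag = c("whole", "TL", "FL")) {
  lumen_tag <- match.arg(lumen_tag)
  if (nrow(tris) == 0L) stop_hp("empty patch", class = "geometry_error")
  a <- mesh$nodes[tris[, 1], , drop = FALSE]
  b <- mesh$nodes[tris[, 2], , drop = FALSE]
  c_ <- mesh$nodes[tris[, 3], , drop = FALSE]
  nrm <- row_cross(b - a, c_ - a) / 2     # area-weighted triangle normals
  mean_n <- colSums(nrm)
  mean_n <- mean_n / sqrt(sum(mean_n^2))
  if (!is.null(direction) && sum(mean_n * direction) < 0) mean_n <- -mean_n
  tri_area <- row_norms(row_cross(b - a, c_ - a)) / 2
  node_ids <- sort(unique(as.vector(tris)))
  w_all <- scatter_add(as.vector(tris), rep(tri_area / 3, 3L), nrow(mesh$nodes))
  pts <- mesh$nodes[node_ids, , drop = FALSE]
  structure(list(points = pts, weights = w_all[node_ids], normal = mean_n,
                 origin = colMeans(pts), area = sum(tri_area),
                 lumen_tag = lumen_tag, node_ids = node_ids, tris = tris),
            class = "hd_plane")
}

#' Interpolation weights from a mesh onto arbitrary points
#'
#' Locates each point in a tetrahedron (with boundary tolerance) and returns
#' the sparse barycentric interpolation matrix. Points outside the mesh get
#' zero rows when `outside = "zero"` (the velocity vanishes at no-slip walls,
#' so quadrature slivers outside a faceted wall contribute nothing).
#'
#' @param mesh an `hd_mesh`.
#' @param pts q x 3 matrix of sample points.
#' @param outside `"zero"` or `"error"`.
#' @return sparse `Matrix` of dimension q x n_nodes; attribute `"inside"`
#'   flags points located inside the mesh.
#' @export
interp_matrix <- function(mesh, pts, outside = c("zero", "error")) {
  outside <- match.arg(outside)
  op <- gradient_operator(mesh)
  tets <- mesh$tets
  x1 <- mesh$nodes[tets[, 1], , drop = FALSE]
  lo <- pmin(x1, mesh$nodes[tets[, 2], , drop = FALSE],
             mesh$nodes[tets[, 3], , drop = FALSE],
             mesh$nodes[tets[, 4], , drop = FALSE])
  hi <- pmax(x1, mesh$nodes[tets[, 2], , drop = FALSE],
             mesh$nodes[tets[, 3], , drop = FALSE],
             mesh$nodes[tets[, 4], , drop = FALSE])
  tol_geo <- 1e-9 * max(hi - lo)

  q <- nrow(pts)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  inside <- logical(q)
  for (p in seq_len(q)) {
    pt <- pts[p, ]
    cand <- which(pt[1] >= lo[, 1] - tol_geo & pt[1] <= hi[, 1] + tol_geo &
                  pt[2] >= lo[, 2] - tol_geo & pt[2] <= hi[, 2] + tol_geo &
                  pt[3] >= lo[, 3] - tol_geo & pt[3] <= hi[, 3] + tol_geo)
    if (length(cand) == 0L) next
    d <- sweep(x1[cand, , drop = FALSE], 2L, pt, function(a, b) b - a)
    l2 <- rowSums(op$g1[cand, , drop = FALSE] * d)
    l3 <- rowSums(op$g2[cand, , drop = FALSE] * d)
    l4 <- rowSums(op$g3[cand, , drop = FALSE] * d)
    l1 <- 1 - l2 - l3 - l4
    minl <- pmin(l1, l2, l3, l4)
    best <- which.max(minl)
    if (minl[best] >= -1e-7) {
      cell <- cand[best]
      lam <- c(l1[best], l2[best], l3[best], l4[best])
      lam <- pmax(lam, 0); lam <- lam / sum(lam)
      ii <- c(ii, rep(p, 4L)); jj <- c(jj, tets[cell, ]); xx <- c(xx, lam)
      inside[p] <- TRUE
    }
  }
  if (!any(inside))
    stop_hp("no sample points lie inside the mesh", class = "empty_sample_error")
  if (outside == "error" && !all(inside))
    stop_hp("%d sample points lie outside the mesh", sum(!inside),
            class = "empty_sample_error")
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(q, nrow(mesh$nodes)))
  attr(M, "inside") <- inside
  M
}

# Retrieve (and cache inside the plane's environment slot) the
# interpolation matrix of a plane against a mesh.
plane_interp <- function(plane, mesh) {
  if (!is.null(plane$node_ids)) return(NULL)  # patch planes sample nodes directly
  if (is.null(plane$cache)) return(interp_matrix(mesh, plane$points))
  key <- paste0("m", nrow(mesh$nodes), "_", nrow(mesh$tets))
  if (is.null(plane$cache[[key]]))
    plane$cache[[key]] <- interp_matrix(mesh, plane$points)
  plane$cache[[key]]
}

#' Sample a velocity field on a plane
#'
#' @param field an `hd_velocity_field`.
#' @param plane an `hd_plane`.
#' @param time_index snapshot index (1-based).
#' @return q x 3 matrix of velocities at the plane quadrature points.
#' @export
sample_on_plane <- function(field, plane, time_index) {
  v <- field$values[[time_index]]
  if (!is.null(plane$node_ids)) return(v[plane$node_ids, , drop = FALSE])
  M <- plane_interp(plane, field$mesh)
  as.matrix(M %*% v)
}

#' Volumetric flow through a plane
#'
#' Quadrature \eqn{\sum_q (v_q \cdot n) w_q}, converted to ml/s. The sign
#' follows the plane normal.
#'
#' @param field an `hd_velocity_field`.
#' @param plane an `hd_plane`.
#' @param time_index snapshot index, or vector of indices.
#' @return flow in ml/s (vectorised over `time_index`).
#' @export
plane_flux <- function(field, plane, time_index = seq_along(field$values)) {
  vapply(time_index, function(ti) {
    v <- sample_on_plane(field, plane, ti)
    sum((v %*% plane$normal) * plane$weights) * 1e6
  }, numeric(1))
}
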