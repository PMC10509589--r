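# Snapshot proper orthogonal decomposition of fluctuating velocity or wall
# shear fields, with normalized energy spectra, truncated reconstruction,
# and reconstruction-based WSS indices.

pod_weights <- function(x, weighting) {
  if (inherits(x, "hd_velocity_field")) {
    if (weighting == "volume") x$mesh$node_volumes else
      rep(1, nrow(x$mesh$nodes))
  } else {
    if (weighting == "volume" && !is.null(x$mesh)) {
      tris <- x$mesh$wall_tris
      a <- x$mesh$nodes[tris[, 1], , drop = FALSE]
      b <- x$mesh$nodes[tris[, 2], , drop = FALSE]
      c_ <- x$mesh$nodes[tris[, 3], , drop = FALSE]
      ar <- row_norms(row_cross(b - a, c_ - a)) / 2
      w <- scatter_add(as.vector(tris), rep(ar / 3, 3L), nrow(x$mesh$nodes))
      w[x$wall_node_ids]
    } else rep(1, length(x$wall_node_ids))
  }
}

pod_snapshots <- function(x) {
  snaps <- if (inherits(x, "hd_velocity_field")) x$values else x$tau
  do.call(cbind, lapply(snaps, as.vector))   # (3n) x N, components stacked
}

#' Snapshot proper orthogonal decomposition
#'
#' Mean-subtracts the snapshot set, forms the temporal Gram matrix under a
#' weighted inner product (cell/surface measure by default, so the energy is
#' mesh-independent), and eigen-decomposes it. Modes are orthonormal under
#' the chosen inner product, eigenvalues are sorted non-increasing, and each
#' mode's sign is fixed by making its largest-magnitude component positive.
#'
#' @param x an `hd_velocity_field` or `hd_wall_shear_field`.
#' @param weighting `"volume"` (node volumes / lumped wall areas) or
#'   `"uniform"`.
#' @return object of class `hd_pod`: `mean` (vector, stacked components),
#'   `modes` ((3n) x K matrix), `a` (N x K temporal coefficients),
#'   `lambda`, `fractions`, `n_effective` (modes above the rank tolerance),
#'   `weights`, `kind`, `grid`, `template` (the input object, values
#'   dropped).
#' @export
snapshot_pod <- function(x, weighting = c("volume", "uniform")) {
  weighting <- match.arg(weighting)
  X <- pod_snapshots(x)
  if (ncol(X) < 2L) stop_hp("need at least 2 snapshots", class = "pod_error")
  if (!all(is.finite(X))) stop_hp("non-finite snapshot values", class = "pod_error")
  w_node <- pod_weights(x, weighting)
  w <- rep(w_node, 3L)
  xbar <- rowMeans(X)
  Xc <- X - xbar
  K <- crossprod(Xc, w * Xc)
  K <- (K + t(K)) / 2
  eg <- eigen(K, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  N <- ncol(X)
  tol <- max(lambda) * 1e-12
  n_eff <- sum(lambda > tol)
  modes <- matrix(0, nrow(X), N)
  a <- matrix(0, N, N)
  for (k in seq_len(n_eff)) {
    phi <- Xc %*% eg$vectors[, k] / sqrt(lambda[k])
    ak <- eg$vectors[, k] * sqrt(lambda[k])
    imax <- which.max(abs(phi))
    if (phi[imax] < 0) { phi <- -phi; ak <- -ak }
    modes[, k] <- phi
    a[, k] <- ak
  }
  template <- x
  if (inherits(x, "hd_velocity_field")) template$values <- NULL else template$tau <- NULL
  structure(list(mean = xbar, modes = modes, a = a, lambda = lambda,
                 fractions = if (sum(lambda) > 0) lambda / sum(lambda)
                             else rep(0, N),
                 n_effective = n_eff, weights = w, kind = class(x)[1],
                 grid = x$grid, template = template),
            class = "hd_pod")
}

#' @export
print.hd_pod <- function(x, ...) {
  cat(sprintf("<hd_pod> %d snapshots, %d effective modes; mode 1 carries %.1f%% of KE\n",
              length(x$lambda), x$n_effective, 100 * x$fractions[1]))
  invisible(x)
}

#' Normalized modal energy spectrum
#'
#' Energy fractions are normalized by the total fluctuating energy across
#' all modes of the case; the threshold crossing reports how many modes
#' capture the requested fraction (98% by default).
#'
#' @param pod an `hd_pod`.
#' @param k_list mode counts to tabulate (default all).
#' @param threshold cumulative-energy threshold to report.
#' @return list: `table` (data.frame `k`, `fraction`, `cumulative`),
#'   `k_at_threshold`.
#' @export
energy_spectrum <- function(pod, k_list = NULL, threshold = 0.98) {
  fr <- pod$fractions
  if (is.null(k_list)) k_list <- seq_along(fr)
  if (any(k_list < 1L | k_list > length(fr)))
    stop_hp("k_list outside mode count", class = "pod_error")
  cum <- cumsum(fr)
  list(table = data.frame(k = k_list, fraction = fr[k_list],
                          cumulative = cum[k_list]),
       k_at_threshold = if (any(cum >= threshold)) which(cum >= threshold)[1]
                        else NA_integer_)
}

#' Truncated reconstruction from POD modes
#'
#' Returns the mean field plus the first `k` modes; `k = 0` gives the
#' time-constant mean field.
#'
#' @param pod an `hd_pod`.
#' @param k number of modes retained.
#' @return a field of the input kind.
#' @export
reconstruct <- function(pod, k) {
  N <- length(pod$lambda)
  if (k < 0 || k > N) stop_hp("k must be in [0, %d]", N, class = "pod_error")
  X <- matrix(pod$mean, length(pod$mean), N)
  if (k > 0)
    X <- X + pod$modes[, seq_len(k), drop = FALSE] %*%
      t(pod$a[, seq_len(k), drop = FALSE])
  n <- length(pod$mean) / 3L
  snaps <- lapply(seq_len(N), function(j) matrix(X[, j], n, 3L))
  tpl <- pod$template
  if (pod$kind == "hd_velocity_field") {
    velocity_field(tpl$mesh, pod$grid, snaps)
  } else {
    wall_shear_field(tpl$wall_node_ids, pod$grid, snaps, mesh = tpl$mesh)
  }
}

#' WSS indices from a truncated wall-shear reconstruction
#'
#' Reconstructs the wall shear field with `k` modes and recomputes the WSS
#' indices, reporting each index's relative L2 error against the full-field
#' indices.
#'
#' @param tau_pod an `hd_pod` built from an `hd_wall_shear_field`.
#' @param k number of modes retained.
#' @return an `hd_wall_index_maps` with attribute `"rel_error"` (named
#'   vector over indices).
#' @export
wss_indices_from_modes <- function(tau_pod, k) {
  if (tau_pod$kind != "hd_wall_shear_field")
    stop_hp("POD was not built from a wall shear field", class = "pod_error")
  full <- compute_wss_indices(reconstruct(tau_pod, length(tau_pod$lambda)))
  trunc <- compute_wss_indices(reconstruct(tau_pod, k))
  rel <- vapply(c("tawss", "osi", "rrt", "ecap"), function(nm) {
    fv <- full[[nm]]; tv <- trunc[[nm]]
    ok <- is.finite(fv) & is.finite(tv)
    if (!any(ok) || sum(fv[ok]^2) == 0) return(NA_real_)
    sqrt(sum((tv[ok] - fv[ok])^2) / sum(fv[ok]^2))
  }, numeric(1))
  attr(trunc, "rel_error") <- rel
  trunc
}
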