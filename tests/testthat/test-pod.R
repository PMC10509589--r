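pod_random_field <- function(n_snap = 10L, seed = 7L) {
  m <- fx_small_cyl()
  set.seed(seed)
  grid <- time_grid(1, n_snap)
  vals <- lapply(seq_len(n_snap), function(k)
    matrix(rnorm(3 * nrow(m$nodes)), nrow(m$nodes), 3))
  velocity_field(m, grid, vals)
}

test_that("a separable rank-1 field yields a single mode with full energy", {
  m <- fx_small_cyl()
  set.seed(3)
  n <- nrow(m$nodes)
  phi <- matrix(rnorm(3 * n), n, 3)
  at <- sin(2 * pi * (1:12) / 12)
  f <- velocity_field(m, time_grid(1, 12),
                      lapply(at, function(a) a * phi))
  pod <- snapshot_pod(f)
  expect_equal(pod$n_effective, 1L)
  expect_equal(pod$fractions[1], 1, tolerance = 1e-12)
  es <- energy_spectrum(pod)
  expect_equal(es$table$cumulative[1], 1, tolerance = 1e-12)
  expect_equal(es$k_at_threshold, 1L)
})

test_that("modes and eigenvalues match a direct weighted factorization oracle", {
  f <- pod_random_field()
  pod <- snapshot_pod(f)
  X <- sapply(f$values, as.vector)
  w <- rep(f$mesh$node_volumes, 3)
  Xc <- X - rowMeans(X)
  sv <- svd(sqrt(w) * Xc)
  k_eff <- pod$n_effective
  expect_equal(pod$lambda[1:k_eff], sv$d[1:k_eff]^2, tolerance = 1e-8)
  phi_o <- (1 / sqrt(w)) * sv$u
  for (k in 1:k_eff) {
    dev <- min(sqrt(sum((pod$modes[, k] - phi_o[, k])^2)),
               sqrt(sum((pod$modes[, k] + phi_o[, k])^2)))
    expect_lt(dev, 1e-8)
  }
  # energy conservation: sum of eigenvalues equals total weighted energy
  expect_equal(sum(pod$lambda), sum(w * Xc^2), tolerance = 1e-10)
})

test_that("modes are orthonormal and coefficients uncorrelated", {
  pod <- snapshot_pod(pod_random_field())
  k <- pod$n_effective
  G <- t(pod$modes[, 1:k]) %*% (pod$weights * pod$modes[, 1:k])
  expect_lt(max(abs(G - diag(k))), 1e-8)
  A <- crossprod(pod$a[, 1:k])
  expect_lt(max(abs(A - diag(diag(A)))), 1e-8 * max(diag(A)))
})

test_that("the eigenvalue spectrum is invariant to snapshot order and rigid rotation", {
  f <- pod_random_field()
  pod <- snapshot_pod(f)
  f_shift <- velocity_field(f$mesh, f$grid, f$values[c(4:10, 1:3)])
  expect_equal(snapshot_pod(f_shift)$lambda, pod$lambda, tolerance = 1e-10)
  th <- 1.1
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  f_rot <- velocity_field(f$mesh, f$grid, lapply(f$values, function(v) v %*% t(Q)))
  expect_equal(snapshot_pod(f_rot)$lambda, pod$lambda, tolerance = 1e-8)
})

test_that("energy fractions sum to one and cumulative curves are monotone", {
  pod <- snapshot_pod(pod_random_field())
  expect_equal(sum(pod$fractions), 1, tolerance = 1e-10)
  es <- energy_spectrum(pod)
  expect_true(all(diff(es$table$cumulative) >= -1e-14))
  expect_equal(es$table$cumulative, cumsum(pod$lambda) / sum(pod$lambda))
  # equal eigenvalues give equal fractions
  m <- fx_small_cyl(); n <- nrow(m$nodes)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  vals <- lapply(1:3, function(k) cbind(q[1, k], q[2, k], q[3, k])[rep(1, n), ])
  f_eq <- velocity_field(m, time_grid(1, 3), lapply(vals, function(v) v))
  pe <- snapshot_pod(f_eq, weighting = "uniform")
  fr <- pe$fractions[1:pe$n_effective]
  expect_equal(fr, rep(1 / pe$n_effective, pe$n_effective), tolerance = 1e-8)
})

test_that("truncated reconstruction obeys the Parseval tail identity", {
  f <- pod_random_field()
  pod <- snapshot_pod(f)
  X <- sapply(f$values, as.vector)
  w <- pod$weights
  tot <- sum(pod$lambda)
  for (k in c(0L, 3L, 7L, length(pod$lambda))) {
    rec <- reconstruct(pod, k)
    e2 <- sum(vapply(seq_along(f$values), function(j)
      sum(w * (as.vector(rec$values[[j]]) - X[, j])^2), numeric(1)))
    tail <- sum(pod$lambda[seq_along(pod$lambda) > k])
    expect_equal(e2, tail, tolerance = 1e-8 * tot)
  }
  # k = 0 is the time-constant mean field
  rec0 <- reconstruct(pod, 0L)
  for (j in seq_along(rec0$values))
    expect_equal(rec0$values[[j]], rec0$values[[1]])
  # full reconstruction reproduces the input
  rec_all <- reconstruct(pod, length(pod$lambda))
  dev <- max(abs(unlist(rec_all$values) - unlist(f$values)))
  expect_lt(dev, 1e-8 * max(abs(X)))
})

test_that("reconstruction-based WSS indices converge to the full-field indices", {
  # two-harmonic synthetic shear history over 40 wall nodes
  set.seed(21)
  nw <- 40L; nt <- 16L
  grid <- time_grid(1, nt)
  base <- matrix(rnorm(nw * 3), nw, 3)
  m1 <- matrix(rnorm(nw * 3), nw, 3)
  m2 <- matrix(rnorm(nw * 3), nw, 3)
  tau_vals <- lapply(grid$times, function(t)
    base + sin(2 * pi * t) * m1 + 0.4 * cos(4 * pi * t) * m2)
  tau <- wall_shear_field(1:nw, grid, tau_vals)
  pod <- snapshot_pod(tau, weighting = "uniform")

  full <- compute_wss_indices(tau)
  rec_all <- wss_indices_from_modes(pod, length(pod$lambda))
  expect_lt(max(attr(rec_all, "rel_error")[c("tawss", "osi")], na.rm = TRUE), 1e-8)

  r1 <- attr(wss_indices_from_modes(pod, 1L), "rel_error")
  r2 <- attr(wss_indices_from_modes(pod, 2L), "rel_error")
  # OSI needs more modes than TAWSS and both improve with k
  expect_gte(r1["osi"], r1["tawss"])
  expect_lte(r2["tawss"], r1["tawss"] + 1e-12)
  expect_lte(r2["osi"], r1["osi"] + 1e-12)

  # mean-only reconstruction is steady: OSI = 0 everywhere
  rec0 <- wss_indices_from_modes(pod, 0L)
  expect_lt(max(rec0$osi[!rec0$undefined]), 1e-12)
})
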