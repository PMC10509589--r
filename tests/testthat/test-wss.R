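test_that("steady Poiseuille wall shear matches the closed form within 5%", {
  wom <- fx_poiseuille()
  tau <- wall_shear_from_field(wom$field)
  target <- 4 * wom$spec$mu * 60e-6 / (pi * wom$spec$radius^3)
  mags <- row_norms(tau$tau[[1]])
  expect_lt(max(abs(mags - target)), 0.05 * target)
  # the steady field gives steady indices: OSI = 0, RRT = 1/|tau|, ECAP = 0
  ix <- compute_wss_indices(tau)
  expect_equal(ix$osi, rep(0, nrow(ix)), tolerance = 1e-12)
  expect_equal(ix$rrt * ix$tawss, rep(1, nrow(ix)), tolerance = 1e-12)
  expect_equal(ix$ecap, rep(0, nrow(ix)), tolerance = 1e-12)
})

test_that("pulsatile wall shear matches the Bessel-form waveform within 5% L2", {
  wom <- fx_womersley_a5()
  tau <- wall_shear_from_field(wom$field)
  tz <- vapply(tau$tau, function(m) mean(m[, 3]), numeric(1))
  te <- wom$wall_shear(wom$field$grid$times)
  expect_lt(sqrt(sum((tz - te)^2) / sum(te^2)), 0.05)
  # extracted shear is tangential to the wall
  normals <- haemopost:::wall_node_normals(wom$field$mesh)
  for (k in c(1L, 12L)) {
    tn <- rowSums(tau$tau[[k]] * normals)
    expect_lt(max(abs(tn)), 1e-6 * max(row_norms(tau$tau[[k]])))
  }
})

test_that("a zero field yields zero wall shear and undefined indices", {
  m <- fx_small_cyl()
  f <- velocity_field(m, time_grid(1, 2),
                      rep(list(matrix(0, nrow(m$nodes), 3)), 2))
  tau <- wall_shear_from_field(f)
  expect_true(all(unlist(tau$tau) == 0))
  ix <- compute_wss_indices(tau)
  expect_true(all(ix$undefined))
  expect_true(all(is.na(ix$osi)))
})

test_that("index closed forms hold for constant, alternating and two-phase shear", {
  # constant shear
  ix <- compute_wss_indices(tau_series(rep(list(c(2, 0, 0)), 8)))
  expect_equal(ix$tawss, 2)
  expect_equal(ix$osi, 0)
  expect_equal(ix$rrt, 0.5)
  expect_equal(ix$ecap, 0)
  # purely oscillatory shear: zero mean vector
  alt <- tau_series(c(rep(list(c(1, 0, 0)), 4), rep(list(c(-1, 0, 0)), 4)))
  ix2 <- compute_wss_indices(alt)
  expect_equal(ix2$osi, 0.5)
  expect_true(is.infinite(ix2$rrt))
  # orthogonal half-cycles
  two <- tau_series(c(rep(list(c(1, 0, 0)), 4), rep(list(c(0, 1, 0)), 4)))
  ix3 <- compute_wss_indices(two)
  expect_equal(ix3$osi, (1 - sqrt(2) / 2) / 2, tolerance = 1e-12)
})

test_that("OSI stays in [0, 0.5] and the RRT identity holds on random histories", {
  set.seed(42)
  for (rep_i in 1:5) {
    n <- 12L
    tau <- wall_shear_field(1:20, time_grid(1, n),
                            lapply(1:n, function(k) matrix(rnorm(60), 20, 3)))
    ix <- compute_wss_indices(tau)
    expect_true(all(ix$osi >= 0 & ix$osi <= 0.5))
    fin <- is.finite(ix$rrt)
    expect_equal((1 - 2 * ix$osi[fin]) * ix$tawss[fin] * ix$rrt[fin],
                 rep(1, sum(fin)), tolerance = 1e-10)
    expect_equal(ix$ecap, ix$osi / ix$tawss, tolerance = 1e-12)
  }
})

test_that("indices are invariant under rigid rotation and cyclic snapshot shift", {
  set.seed(7)
  n <- 10L
  base <- lapply(1:n, function(k) matrix(rnorm(45), 15, 3))
  grid <- time_grid(1, n)
  ix <- compute_wss_indices(wall_shear_field(1:15, grid, base))
  th <- 0.7
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- lapply(base, function(m) m %*% t(Q))
  ix_rot <- compute_wss_indices(wall_shear_field(1:15, grid, rot))
  expect_equal(ix_rot$tawss, ix$tawss, tolerance = 1e-12)
  expect_equal(ix_rot$osi, ix$osi, tolerance = 1e-12)
  expect_equal(ix_rot$rrt, ix$rrt, tolerance = 1e-10)
  shift <- base[c(4:n, 1:3)]
  ix_sh <- compute_wss_indices(wall_shear_field(1:15, grid, shift))
  expect_equal(ix_sh$tawss, ix$tawss)
  expect_equal(ix_sh$osi, ix$osi)
})

test_that("Carreau-Yasuda viscosity is positive, shear-thinning, and bounded", {
  cy <- list(mu0 = 0.056, mu_inf = 0.0035, lambda = 3.3, a = 2, n = 0.36)
  fl <- fluid_properties(carreau_yasuda = cy)
  g <- c(0, 0.1, 1, 10, 100, 1e4)
  mu <- viscosity(fl, g)
  expect_equal(mu[1], cy$mu0)
  expect_true(all(diff(mu) < 0))
  expect_true(all(mu > cy$mu_inf))
})

test_that("circumferential station profiles average correctly and flag empty bands", {
  m <- fx_small_cyl()
  grid <- time_grid(1, 4)
  wall <- m$wall_nodes
  arc <- m$nodes[wall, 3]                       # axial coordinate as arc length
  # uniform index map: profile constant
  tau_u <- wall_shear_field(wall, grid,
                            rep(list(matrix(c(1.5, 0, 0), length(wall), 3,
                                            byrow = TRUE)), 4), mesh = m)
  maps_u <- compute_wss_indices(tau_u)
  st <- c(0.005, 0.015, 0.025, 0.035)
  pr <- circumferential_profile(maps_u, arc, st, spacing = 0.01)
  expect_equal(pr$tawss, rep(1.5, 4))
  expect_false(any(pr$missing))
  # ramp index map: station means sit at the band centres
  tau_r <- wall_shear_field(wall, grid,
                            rep(list(cbind(arc, 0, 0)), 4), mesh = m)
  maps_r <- compute_wss_indices(tau_r)
  pr_r <- circumferential_profile(maps_r, arc, st, spacing = 0.01)
  expect_true(all(abs(pr_r$tawss - st) <= 0.005 + 1e-12))
  # a station beyond the domain is flagged missing, not zero
  pr_m <- circumferential_profile(maps_u, arc, c(0.02, 0.2), spacing = 0.01)
  expect_true(pr_m$missing[2])
  expect_true(is.na(pr_m$tawss[2]))
})

test_that("difference statistics match a brute-force recomputation", {
  set.seed(11)
  grid <- time_grid(1, 6)
  mk <- function(vals) {
    tau <- wall_shear_field(1:100, grid, vals)
    compute_wss_indices(tau)
  }
  base_vals <- lapply(1:6, function(k) matrix(rnorm(300, sd = 2), 100, 3))
  base <- mk(base_vals)
  # identical maps: all stats zero
  d0 <- difference_stats(base, base)
  expect_true(all(abs(d0$min) < 1e-14 & abs(d0$max) < 1e-14 &
                    abs(d0$mean) < 1e-14))
  # uniform offset on one index
  cand <- base
  cand$tawss <- base$tawss + 0.1
  d1 <- difference_stats(cand, base)
  r1 <- d1[d1$index == "tawss", ]
  expect_equal(c(r1$min, r1$max, r1$mean), c(0.1, 0.1, 0.1), tolerance = 1e-12)
  # random maps against an independent loop oracle
  cand_vals <- lapply(1:6, function(k) matrix(rnorm(300, sd = 2), 100, 3))
  cand2 <- mk(cand_vals)
  d2 <- difference_stats(cand2, base)
  for (nm in c("tawss", "osi", "ecap")) {
    cv <- cand2[[nm]]; bv <- base[[nm]]
    ok <- is.finite(cv) & is.finite(bv)
    dd <- cv[ok] - bv[ok]
    row <- d2[d2$index == nm, ]
    expect_equal(row$min, min(dd))
    expect_equal(row$max, max(dd))
    expect_equal(row$mean, mean(dd))
    guard <- max(1e-12, 1e-6 * max(bv[ok]))
    sel <- ok & bv > guard
    expect_equal(row$mean_rel_pct, mean(100 * (cv[sel] - bv[sel]) / bv[sel]))
  }
  expect_error(difference_stats(mk(base_vals[1:6]),
                                compute_wss_indices(
                                  wall_shear_field(2:101, grid, base_vals))),
               class = "mesh_mismatch_error")
})
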