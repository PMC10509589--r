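test_that("cell curls reproduce analytic vorticity for canonical flows", {
  m <- fx_small_cyl()
  grid <- time_grid(1, 2)
  n <- nrow(m$nodes)
  # rigid rotation: curl = 2 Omega z, exact for a linear field
  Om <- 10
  f_rot <- velocity_field(m, grid,
                          rep(list(cbind(-Om * m$nodes[, 2],
                                         Om * m$nodes[, 1], 0)), 2))
  w <- vorticity_field(f_rot)
  expect_equal(w$cell[[1]],
               matrix(rep(c(0, 0, 2 * Om), each = nrow(m$tets)), ncol = 3),
               tolerance = 1e-9)
  # uniform translation: curl = 0
  f_tr <- velocity_field(m, grid, rep(list(matrix(0.3, n, 3)), 2))
  expect_lt(max(abs(vorticity_field(f_tr)$cell[[1]])), 1e-12)
  # planar shear u = (gamma y, 0, 0): curl = (0, 0, -gamma)
  f_sh <- velocity_field(m, grid, rep(list(cbind(2.5 * m$nodes[, 2], 0, 0)), 2))
  expect_equal(vorticity_field(f_sh)$cell[[1]],
               matrix(rep(c(0, 0, -2.5), each = nrow(m$tets)), ncol = 3),
               tolerance = 1e-9)
})

test_that("helicity time series integrate the analytic density over regions", {
  m <- fx_small_cyl()
  hel <- helical_cylinder_field(10, 0.5, m)
  hts <- helicity_timeseries(hel$field)
  expect_equal(hts$H, rep(10 * sum(m$cell_volumes), 4), tolerance = 1e-12)
  expect_equal(hts$absH, hts$H, tolerance = 1e-12)
  # swirl-free planar flow carries no helicity at all
  f_planar <- velocity_field(m, time_grid(1, 2),
                             rep(list(cbind(0.1, -0.2, 0) %x% rep(1, nrow(m$nodes))), 2))
  hp <- helicity_timeseries(f_planar)
  expect_lt(max(abs(hp$H)), 1e-15)
  expect_lt(max(abs(hp$absH)), 1e-12)
})

test_that("volume integration is additive over disjoint regions", {
  ph <- fx_phantom()
  hts <- helicity_timeseries(ph$field, ph$mask)
  parts <- split(hts, hts$region)
  total <- Reduce(`+`, lapply(parts, function(p) p$H))
  whole <- helicity_timeseries(ph$field, NULL)
  expect_equal(total, whole$H, tolerance = 1e-10)
})

test_that("LNH attains +-1 on the axis and its closed form off-axis", {
  m <- fx_small_cyl()
  hel <- helical_cylinder_field(10, 0.5, m)
  lnh <- lnh_field(hel$field)[[1]]
  expect_true(all(abs(lnh) <= 1))
  axis <- which(m$nodes[, 1] == 0 & m$nodes[, 2] == 0)
  expect_equal(lnh[axis], rep(1, length(axis)))
  r <- sqrt(m$nodes[, 1]^2 + m$nodes[, 2]^2)
  expect_equal(lnh, 0.5 / sqrt(100 * r^2 + 0.25), tolerance = 0.02)
  # reversed axial flow anti-aligns velocity and vorticity on the axis
  neg <- helical_cylinder_field(10, -0.5, m)
  expect_equal(lnh_field(neg$field)[[1]][axis], rep(-1, length(axis)))
  # stagnant regions are zero by convention, not +-1
  f0 <- velocity_field(m, time_grid(1, 2),
                       rep(list(matrix(0, nrow(m$nodes), 3)), 2))
  expect_true(all(lnh_field(f0)[[1]] == 0))
})

test_that("bulk indices satisfy their algebraic structure and closed forms", {
  m <- fx_small_cyl()
  hel <- helical_cylinder_field(10, 0.5, m)
  rep1 <- bulk_helicity_indices(hel$field, windows = list(full = c(0, 1)))
  expect_equal(rep1$h1, 10, tolerance = 1e-12)
  expect_equal(rep1$h2, 10, tolerance = 1e-12)
  expect_equal(rep1$h3, 1)
  neg <- helical_cylinder_field(-10, 0.5, m)
  repn <- bulk_helicity_indices(neg$field, windows = list(full = c(0, 1)))
  expect_equal(repn$h3, -1)
})

test_that("a mirror-antisymmetric flow has h1 = h3 = 0 with positive h2", {
  m <- cylinder_mesh(0.01, 0.04, ntheta = 32L)
  Om <- 10; cc <- 50
  # helicity density c*Omega*x: odd across the mirror plane x = 0
  v <- cbind(-Om * m$nodes[, 2], Om * m$nodes[, 1], cc * m$nodes[, 1])
  f <- velocity_field(m, time_grid(1, 2), rep(list(v), 2))
  rep_ <- bulk_helicity_indices(f, windows = list(full = c(0, 1)))
  expect_gt(rep_$h2, 0)
  expect_lt(abs(rep_$h1), 1e-10 * rep_$h2)
  expect_lt(abs(rep_$h3), 1e-10)
  # h2 matches the closed-form mean of |x| over the disk, 4R/(3 pi)
  expect_equal(rep_$h2, cc * Om * 4 * 0.01 / (3 * pi), tolerance = 0.01)
  hts <- helicity_timeseries(f)
  expect_lt(abs(hts$H[1]), 1e-10 * hts$absH[1])
  expect_gt(hts$absH[1], 0)
})

test_that("mirror reflection flips signed helicity and preserves magnitudes", {
  m <- fx_small_cyl()
  hel <- helical_cylinder_field(7, 0.4, m)
  r1 <- bulk_helicity_indices(hel$field, windows = list(full = c(0, 1)))
  # reflect through x -> -x (mesh is symmetric in x): v_x flips
  vref <- hel$field$values[[1]]
  nodes_ref <- m$nodes; nodes_ref[, 1] <- -nodes_ref[, 1]
  idx <- vapply(seq_len(nrow(m$nodes)), function(i)
    which.min(colSums((t(m$nodes) - nodes_ref[i, ])^2)), integer(1))
  expect_lt(max(rowSums((m$nodes[idx, ] - nodes_ref)^2)), 1e-24)
  v2 <- vref[idx, ]; v2[, 1] <- -v2[, 1]
  f2 <- velocity_field(m, hel$field$grid, rep(list(v2), 4))
  r2 <- bulk_helicity_indices(f2, windows = list(full = c(0, 1)))
  expect_equal(r2$h1, -r1$h1, tolerance = 1e-9)
  expect_equal(r2$h2, r1$h2, tolerance = 1e-9)
})

test_that("h2 matches a brute-force cell loop and |h3| <= 1 on random smooth fields", {
  m <- fx_small_cyl()
  set.seed(13)
  grid <- time_grid(1, 4)
  vals <- lapply(1:4, function(k) {
    a <- rnorm(3, sd = 5); b <- rnorm(3, sd = 5)
    cbind(a[1] + b[1] * m$nodes[, 2], a[2] + b[2] * m$nodes[, 3],
          a[3] + b[3] * m$nodes[, 1])
  })
  f <- velocity_field(m, grid, vals)
  rep_ <- bulk_helicity_indices(f, windows = list(full = c(0, 1)))
  expect_true(all(abs(rep_$h3) <= 1 + 1e-12))
  # independent loop oracle for h2
  hk <- haemopost:::helicity_density_cells(f)
  acc <- 0
  for (k in 1:4) {
    s <- 0
    for (c_ in seq_len(nrow(m$tets)))
      s <- s + abs(hk[[k]][c_]) * m$cell_volumes[c_]
    acc <- acc + s
  }
  h2_brute <- acc / 4 / sum(m$cell_volumes)
  expect_equal(rep_$h2, h2_brute, tolerance = 1e-12)
})

test_that("window handling rejects degenerate windows and empty regions", {
  m <- fx_small_cyl()
  hel <- helical_cylinder_field(10, 0.5, m)
  expect_error(bulk_helicity_indices(hel$field, windows = list(bad = c(0.5, 0.5))),
               class = "window_error")
  lab <- rep("TLt", nrow(m$tets))
  mask <- subdomain_mask(lab, m)
  expect_error(helicity_timeseries(hel$field, mask, regions = "FLa"),
               class = "empty_region_error")
})

test_that("the systole end is detected from the waveform down-crossing", {
  grid <- time_grid(1, 100)
  q <- pmax(sin(2 * pi * grid$times / 1), 0) * 400
  te <- systole_end(q, grid)
  expect_gt(te, 0.25); expect_lt(te, 0.55)
  # waveform that never decays below threshold: fallback at 0.35 T
  expect_equal(systole_end(rep(10, 100), grid), 0.35)
})
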