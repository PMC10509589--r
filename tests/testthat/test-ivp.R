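test_that("registration recovers a rigid translation exactly", {
  ch <- fx_ivp_chain()
  fr <- ch$frames
  fr$frames <- lapply(fr$frames, function(f) {
    f$contour[, 1] <- f$contour[, 1] + 0.002
    f$contour[, 2] <- f$contour[, 2] + 0.001
    f$points[, 1] <- f$points[, 1] + 0.002
    f$points[, 2] <- f$points[, 2] + 0.001
    f
  })
  mp <- register_frames(fr, ch$inlet)
  tr <- mp$frames[[1]]$transform
  expect_equal(tr$translation[1:2], c(-0.002, -0.001), tolerance = 1e-6)
  expect_equal(tr$scale, 1, tolerance = 1e-9)
  expect_lt(tr$residual_rms, 1e-9)
  expect_equal(mp$frames[[1]]$points, ch$mapped$frames[[1]]$points,
               tolerance = 1e-6)
})

test_that("registration recovers a uniform dilation within 1%", {
  ch <- fx_ivp_chain()
  fr <- ch$frames
  fr$frames <- lapply(fr$frames, function(f) {
    f$contour[, 1:2] <- f$contour[, 1:2] * 1.1
    f$points[, 1:2] <- f$points[, 1:2] * 1.1
    f
  })
  mp <- register_frames(fr, ch$inlet)
  expect_equal(mp$frames[[1]]$transform$scale, 1 / 1.1, tolerance = 0.01)
})

test_that("mapping a noisy ellipse onto the circular inlet is fold-over free", {
  ch <- fx_ivp_chain()
  fr <- ch$frames
  set.seed(4)
  fr$frames <- lapply(fr$frames, function(f) {
    f$contour[, 1] <- f$contour[, 1] * 1.15
    f$contour[, 1:2] <- f$contour[, 1:2] +
      matrix(stats::rnorm(2 * nrow(f$contour), sd = 1e-4), ncol = 2)
    f$points[, 1] <- f$points[, 1] * 1.15
    f
  })
  mp <- register_frames(fr, ch$inlet, rigidity = 1)
  # triangulate the voxel grid and check that every mapped triangle keeps
  # its orientation
  f1 <- fr$frames[[1]]; m1 <- mp$frames[[1]]
  ij <- f1$ij
  key <- paste(ij[, 1], ij[, 2])
  id_at <- function(i, j) match(paste(i, j), key)
  tris <- list()
  for (r in seq_len(nrow(ij))) {
    i <- ij[r, 1]; j <- ij[r, 2]
    a <- r; b <- id_at(i + 1L, j); c_ <- id_at(i, j + 1L); d <- id_at(i + 1L, j + 1L)
    if (!is.na(b) && !is.na(d)) tris[[length(tris) + 1L]] <- c(a, b, d)
    if (!is.na(d) && !is.na(c_)) tris[[length(tris) + 1L]] <- c(a, d, c_)
  }
  tris <- do.call(rbind, tris)
  signed_area <- function(p, t)
    (p[t[, 2], 1] - p[t[, 1], 1]) * (p[t[, 3], 2] - p[t[, 1], 2]) -
    (p[t[, 3], 1] - p[t[, 1], 1]) * (p[t[, 2], 2] - p[t[, 1], 2])
  before <- signed_area(f1$points, tris)
  after <- signed_area(m1$points, tris)
  expect_true(all(sign(before) == sign(after)))
})

test_that("the rebuilt 4D profile matches the generating flow within 3% per frame", {
  ch <- fx_ivp_chain()
  ref <- ch$ref
  spec <- ch$wom$spec
  rr <- sqrt(ref$plane$points[, 1]^2 + ref$plane$points[, 2]^2)
  ft <- vapply(ch$frames$frames, `[[`, numeric(1), "time")
  u_exact <- haemopost:::womersley_profile(spec, rr, ft)
  for (k in seq_along(ft)) {
    j <- which.min(abs(ch$grid$times - ft[k]))
    err <- sqrt(sum((ref$values[[j]][, 3] - u_exact[, k])^2) /
                  sum(u_exact[, k]^2))
    expect_lt(err, 0.03)
  }
})

test_that("the 4D profile honours no-slip at the perimeter and constant input stays constant", {
  ch <- fx_ivp_chain()
  perim <- haemopost:::patch_perimeter(ch$inlet$tris)
  rows <- match(perim, ch$inlet$node_ids)
  for (v in ch$ref$values) expect_true(all(v[rows, ] == 0))

  # time-constant frames build a time-constant profile
  fr <- ch$frames
  for (k in seq_along(fr$frames)) fr$frames[[k]]$vel <- fr$frames[[1]]$vel
  mp <- register_frames(fr, ch$inlet)
  prof <- build_4d_ivp(mp, ch$grid)
  for (k in seq_along(prof$values))
    expect_equal(prof$values[[k]], prof$values[[1]], tolerance = 1e-9)
})

test_that("non-finite frame velocities are rejected", {
  ch <- fx_ivp_chain()
  mp <- ch$mapped
  mp$frames[[2]]$vel[1, 1] <- NaN
  expect_error(build_4d_ivp(mp, ch$grid), class = "data_error")
})

test_that("flat, TP and scaled variants preserve the designed flow relations", {
  ch <- fx_ivp_chain()
  ref <- ch$ref
  flat <- make_flat_ivp(ref)
  tp <- make_tp_ivp(ref)
  sc <- scale_ivp(ref, 1.25)

  qmax <- max(abs(ref$q_in))
  expect_lt(max(abs(flat$q_in - ref$q_in)), 1e-10 * qmax)
  expect_lt(max(abs(tp$q_in - ref$q_in)), 1e-12 * qmax)

  # flat: uniform normal speed Q/A, zero in-plane
  k <- which.max(abs(ref$q_in))
  vn <- flat$values[[k]] %*% flat$plane$normal
  expect_equal(as.vector(vn),
               rep(ref$q_in[k] * 1e-6 / flat$plane$area, length(vn)),
               tolerance = 1e-12)
  ip <- flat$values[[k]] - vn %*% t(flat$plane$normal)
  expect_lt(max(abs(ip)), 1e-15)

  # TP: normal component preserved pointwise, in-plane removed
  expect_equal(tp$values[[k]] %*% tp$plane$normal,
               ref$values[[k]] %*% ref$plane$normal, tolerance = 1e-14)
  ip_tp <- tp$values[[k]] - (tp$values[[k]] %*% tp$plane$normal) %*% t(tp$plane$normal)
  expect_lt(max(abs(ip_tp)), 1e-15)
  # projection is idempotent
  expect_equal(make_tp_ivp(tp)$values[[k]], tp$values[[k]], tolerance = 1e-15)

  # scaling: identity at 1, linear waveform scaling, exact stroke-volume ratio
  expect_equal(scale_ivp(ref, 1)$values[[k]], ref$values[[k]])
  expect_equal(scale_ivp(ref, 0.5)$q_in, 0.5 * ref$q_in, tolerance = 1e-14)
  expect_equal(stroke_volume(sc) / stroke_volume(ref), 1.25,
               tolerance = 1e-10)
})

test_that("a reference with only in-plane flow has a zero TP variant and zero flux", {
  ch <- fx_ivp_chain()
  ref <- ch$ref
  nrm <- ref$plane$normal
  vals <- lapply(ref$values, function(v) v - (v %*% nrm) %*% t(nrm))
  ip_ref <- haemopost:::profile_from_values(ref$plane, ref$grid, vals)
  expect_lt(max(abs(ip_ref$q_in)), 1e-9)
  tp <- make_tp_ivp(ip_ref)
  expect_lt(max(abs(unlist(tp$values))), 1e-15)
  # zero waveform gives a zero flat field
  flat0 <- make_flat_ivp(tp)
  expect_true(all(unlist(flat0$values) == 0))
})
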