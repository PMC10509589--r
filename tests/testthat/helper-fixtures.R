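# Shared fixtures, computed lazily and cached for the whole test run.

row_norms <- haemopost:::row_norms

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- expr
  .fixture_cache[[name]]
}

# coarse cylinder for topology / property tests
fx_small_cyl <- function() fixture("small_cyl",
  cylinder_mesh(0.01, 0.04, radii_frac = c(0.35, 0.7, 1), ntheta = 12L, nz = 4L))

# steady Poiseuille flow (Q = 60 ml/s) on the default graded mesh
fx_poiseuille <- function() fixture("poiseuille", {
  spec <- womersley_spec(harmonics = data.frame(n = 0L, amplitude = 60, phase = 0))
  womersley_field(spec, 8L)
})

# two-harmonic pulsatile flow at Womersley number 5, resolution suited to
# flux and wall-shear oracle comparisons
fx_womersley_a5 <- function() fixture("womersley_a5", {
  R <- 0.01; mu <- 3.5e-3; rho <- 1056
  Tc <- 2 * pi * rho * R^2 / (25 * mu)          # alpha = 5 exactly
  spec <- womersley_spec(
    radius = R, period = Tc, mu = mu, density = rho,
    harmonics = data.frame(n = c(0L, 1L), amplitude = c(60, 40),
                           phase = c(0, 0.5)),
    ntheta = 36L,
    radii_frac = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.78, 0.85, 0.9,
                   0.94, 0.97, 0.985, 1))
  womersley_field(spec, 24L)
})

# moderate-Womersley pulsatile flow whose boundary layer is resolvable by
# the MRI-like voxel sampling (used by the inlet-profile chain)
fx_wom_mid <- function() fixture("wom_mid", {
  spec <- womersley_spec(mu = 0.07,
                         harmonics = data.frame(n = c(0L, 1L),
                                                amplitude = c(60, 30),
                                                phase = c(0, 0.8)))
  womersley_field(spec, 32L)
})

fx_ivp_chain <- function() fixture("ivp_chain", {
  wom <- fx_wom_mid()
  frames <- mri_like_inlet(wom, n_frames = 16L, voxel = 0.001,
                           noise_sd = 0, motion_amplitude = 0, seed = 3L)
  inlet <- inlet_patch_plane(wom$field$mesh)
  mapped <- register_frames(frames, inlet)
  grid <- time_grid(wom$field$grid$period, 32L)
  list(wom = wom, frames = frames, inlet = inlet, mapped = mapped,
       ref = build_4d_ivp(mapped, grid), grid = grid)
})

fx_phantom <- function() fixture("phantom", two_lumen_phantom())

# constant-in-time wall shear series on a single node
tau_series <- function(vectors, period = 1) {
  n <- length(vectors)
  wall_shear_field(1L, time_grid(period, n),
                   lapply(vectors, function(v) matrix(v, 1L, 3L)))
}
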