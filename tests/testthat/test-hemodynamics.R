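test_that("Quemada viscosity honours its closed-form limits", {
  # no red cells: plasma viscosity at every shear rate
  r0 <- rheology_params(hematocrit = 0)
  expect_equal(quemada_viscosity(c(0, 1, 1e4), r0), rep(1.2e-3, 3))
  # k0 = k_inf: Newtonian at mu_p / (1 - 0.5 k Hct)^2
  rn <- rheology_params(k0 = 2, k_inf = 2, hematocrit = 0.4)
  expect_equal(quemada_viscosity(c(0.01, 10, 1e5), rn),
               rep(1.2e-3 / (1 - 0.4)^2, 3), tolerance = 1e-12)
  # high-shear limit
  rheo <- rheology_params()
  mu_inf <- rheo$plasma_viscosity *
    (1 - 0.5 * rheo$k_inf * rheo$hematocrit)^-2
  expect_rel(quemada_viscosity(1e6 * rheo$gamma_c, rheo), mu_inf, 0.005)
  # shear-thinning: strictly decreasing in shear rate
  mus <- quemada_viscosity(10^seq(-2, 4, by = 0.5), rheo)
  expect_true(all(diff(mus) < 0))
  expect_error(rheology_params(hematocrit = 1.2), "hematocrit")
  expect_error(rheology_params(k0 = 1, k_inf = 2), "k0")
})

test_that("Rabinowitsch-Mooney solver matches Poiseuille and power-law forms", {
  mu_eff <- 3.45e-3
  rnewt <- rheology_params(plasma_viscosity = mu_eff * (1 - 0.4)^2,
                           k0 = 2, k_inf = 2, hematocrit = 0.4)
  tw <- wall_shear_stress_tube(1e-5, 0.01, rnewt)
  expect_rel(tw, 4 * mu_eff * 1e-5 / (pi * 0.01^3), 0.005)
  # power-law fluid through the same machinery
  K <- 0.01; n <- 0.7; Q <- 1e-5; R <- 0.01
  tw_pl <- wall_shear_stress_tube(Q, R, tau_fun = function(g) K * g^n)
  expect_rel(tw_pl, K * ((3 * n + 1) / (4 * n) * 4 * Q / (pi * R^3))^n, 0.01)
  # no flow, no shear
  expect_identical(wall_shear_stress_tube(0, 0.01), 0)
})

test_that("wall shear stress is monotone and sublinear under shear-thinning", {
  rheo <- rheology_params()
  qs <- c(2e-6, 5e-6, 1e-5, 3e-5, 1e-4)
  tws <- vapply(qs, wall_shear_stress_tube, numeric(1), radius = 0.01,
                rheo = rheo)
  expect_true(all(diff(tws) > 0))
  # tau(cQ) <= c tau(Q) for c >= 1
  for (c_ in c(2, 5)) {
    expect_lte(wall_shear_stress_tube(c_ * 1e-5, 0.01, rheo),
               c_ * wall_shear_stress_tube(1e-5, 0.01, rheo) * (1 + 1e-9))
  }
})

test_that("waveform templates integrate as specified", {
  flat <- make_waveform("flat", 0.4)
  expect_equal(mean(flat$velocities), 0.4)
  sharp <- make_waveform("sharp", 0.4, n_samples = 512)
  expect_equal(max(sharp$velocities), 0.4, tolerance = 1e-6)
  expect_lt(mean(sharp$velocities), 0.4 * 0.5)
  real <- make_waveform("real", 0.4, n_samples = 256)
  # exactly one contiguous reverse-flow interval
  neg <- real$velocities < 0
  runs <- rle(neg)
  expect_equal(sum(runs$values), 1L)
  expect_error(make_waveform("bogus"), "arg")
  expect_error(velocity_waveform(c(0, 0.1), c(1, 1)), "samples")
})

test_that("quasi-1D tube reduction recovers generator radii", {
  cyl <- make_cylinder_mesh(10, 100, 96, 32)
  tube <- tube_from_mesh(cyl, 15)
  expect_true(all(abs(tube$radii - 10) / 10 < 0.01))
  p <- anatomy_params()
  aaa_tube <- tube_from_mesh(make_aaa_mesh(p), 33)
  # station nearest the sac centre reads the sac radius
  i_sac <- which.min(abs(aaa_tube$stations - p$sac_center_frac * p$height))
  expect_rel(aaa_tube$radii[i_sac], p$sac_radius, 0.02)
  # below the bifurcation, two limbs pool into an equivalent tube
  p2 <- anatomy_params(limb_radius = 7)
  sl_tube <- tube_from_mesh(make_stentgraft_mesh(p2, "long"), 33)
  expect_rel(min(sl_tube$radii), sqrt(2) * 7, 0.02)
})

test_that("WSS series obeys homogeneity, monotonicity and linearity", {
  rheo <- rheology_params()
  cyl_tube <- tube_from_mesh(make_cylinder_mesh(10, 100, 64, 16), 15)
  flat <- make_waveform("flat", 0.4, n_samples = 16)
  s <- wss_series(cyl_tube, flat, rheo)
  expect_lt(diff(range(s$wss)) / mean(s$wss), 1e-12)
  expect_rel(s$wss[1],
             wall_shear_stress_tube(0.4 * pi * 0.01^2, 0.01, rheo), 0.01)
  # an aneurysmal tube carries lower WSS than its neck cylinder
  p <- anatomy_params()
  aaa_tube <- tube_from_mesh(make_aaa_mesh(p), 15)
  neck_tube <- tube_from_mesh(make_cylinder_mesh(p$neck_radius, p$height,
                                                 64, 16), 15)
  expect_lt(wss_total(wss_series(aaa_tube, flat, rheo)),
            wss_total(wss_series(neck_tube, flat, rheo)))
  # Newtonian chain is linear in the flow rate
  rnewt <- rheology_params(k0 = 2, k_inf = 2)
  sharp1 <- make_waveform("sharp", 0.2, n_samples = 64)
  sharp2 <- make_waveform("sharp", 0.4, n_samples = 64)
  s1 <- wss_series(cyl_tube, sharp1, rnewt)
  s2 <- wss_series(cyl_tube, sharp2, rnewt)
  expect_equal(s2$wss, 2 * s1$wss, tolerance = 1e-8)
})

test_that("cycle aggregation is the exact mean and matches quadrature", {
  const <- structure(list(times = (0:7) / 8, wss = rep(5, 8), dt = 1 / 8,
                          kind = "flat"), class = "wss_series")
  expect_equal(wss_total(const), 5)
  two <- structure(list(times = c(0, 0.5), wss = c(2, 4), dt = 0.5,
                        kind = "flat"), class = "wss_series")
  expect_equal(wss_total(two), 3)
  # raised-cosine series vs trapezoid time integral / period at n = 512
  n <- 512
  t <- (seq_len(n) - 1) / n
  w <- 3 + 2 * cos(2 * pi * t)
  series <- structure(list(times = t, wss = w, dt = 1 / n, kind = "real"),
                      class = "wss_series")
  trap <- sum((w + c(w[-1], w[1])) / 2) / n  # periodic trapezoid over [0, 1]
  expect_rel(wss_total(series), trap, 0.001)
})

test_that("drag force converts shear and area to newtons", {
  mk <- function(wss) structure(list(times = (0:7) / 8, wss = rep(wss, 8),
                                     dt = 1 / 8, kind = "flat"),
                                class = "wss_series")
  expect_equal(drag_force(mk(1), 1e6), 1)        # 1 Pa on 1 m^2
  expect_equal(drag_force(mk(300), 0.01e6), 3)   # 300 Pa on 0.01 m^2
  expect_equal(drag_force(mk(0), 123), 0)
  expect_error(drag_force(mk(1), 0), "side_surface")
})

test_that("waveform CSV round-trips", {
  wf <- make_waveform("real", 0.35, n_samples = 32)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform(wf, path)
  back <- read_waveform(path, kind = "real")
  expect_equal(back$velocities, wf$velocities)
  expect_equal(back$times, wf$times)
})
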