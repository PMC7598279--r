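test_that("cylinder generator matches its analytic lateral surface", {
  cyl <- make_cylinder_mesh(1, 1, 256, 64)
  expect_rel(side_surface_area(cyl), 2 * pi, 5e-4)
  expect_equal(axial_height(make_cylinder_mesh(10, 100, 32, 8)), 100)
  expect_error(make_cylinder_mesh(1, 1, 2, 8), "segments")
})

test_that("AAA generator hits its construction parameters", {
  p <- anatomy_params(neck_radius = 10, sac_radius = 27.5, height = 130)
  aaa <- make_aaa_mesh(p)
  # max cross-section diameter = 2 * sac_radius (55 mm scale)
  r_max <- max(sqrt(rowSums(aaa$vertices[, 1:2]^2)))
  expect_rel(2 * r_max, 55, 0.01)
  expect_equal(axial_height(aaa), 130, tolerance = 1e-9)
  # degenerate bump: plain cylinder, shape factor 1
  p0 <- anatomy_params(neck_radius = 10, sac_radius = 10)
  expect_lt(abs(shape_factor_vs_cylinder(make_aaa_mesh(p0)) - 1), 0.01)
  # determinism
  expect_identical(make_aaa_mesh(p)$vertices, make_aaa_mesh(p)$vertices)
  expect_error(anatomy_params(sac_radius = 5), "neck_radius")
})

test_that("stent-graft bodies share height and differ in limb split", {
  p <- anatomy_params()
  sl <- make_stentgraft_mesh(p, "long")
  ss <- make_stentgraft_mesh(p, "short")
  expect_equal(axial_height(sl), axial_height(ss), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(side_surface_area(sl), side_surface_area(ss))))
  # the short body leaves a longer limb region below the bifurcation
  limb_extent <- function(m, p) {
    r <- sqrt(rowSums(m$vertices[, 1:2]^2))
    max(m$vertices[r < p$neck_radius * 0.95, 3])
  }
  expect_gt(limb_extent(ss, p), limb_extent(sl, p) - 1e-9)
  expect_error(make_stentgraft_mesh(anatomy_params(bifurcation_angle = 60), "long"),
               "angle")
})

test_that("cross-section area is conserved through a straight bifurcation", {
  p <- anatomy_params(neck_radius = 10, limb_radius = 10 / sqrt(2),
                      bifurcation_angle = 0)
  sl <- make_stentgraft_mesh(p, "long")
  tube <- tube_from_mesh(sl, n_stations = 33)
  # equivalent radius below the bifurcation = sqrt(2) * limb = neck radius
  expect_rel(min(tube$radii), p$neck_radius, 0.01)
  expect_rel(max(tube$radii), p$neck_radius, 0.01)
})

test_that("cohorts are reproducible and jitter behaves as specified", {
  spec <- cohort_spec(n_patients = 3, seed = 1, param_jitter = 0.08)
  base <- anatomy_params(circumferential_segments = 24, axial_segments = 24)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(make_cohort(spec, base), d1)
  write_cohort(make_cohort(spec, base), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6),
                     info = f)
  }
  # different seeds give different anatomies
  c1 <- make_cohort(spec, base)
  c2 <- make_cohort(cohort_spec(3, seed = 2, param_jitter = 0.08), base)
  expect_false(isTRUE(all.equal(side_surface_area(c1[[1]]$aaa),
                                side_surface_area(c2[[1]]$aaa))))
  # zero jitter reproduces the base parameters
  c0 <- make_cohort(cohort_spec(1, seed = 9, param_jitter = 0), base)
  expect_identical(c0[[1]]$params, base)
})

test_that("per-patient heights satisfy the common-height convention", {
  cohort <- make_cohort(cohort_spec(4, seed = 3),
                        anatomy_params(circumferential_segments = 24,
                                       axial_segments = 24))
  for (rec in cohort) {
    h <- c(axial_height(rec$aaa), axial_height(rec$sl), axial_height(rec$ss))
    expect_lt(max(h) - min(h), 1e-6)
  }
})

test_that("a wider sac increases side surface and shape factor", {
  mk <- function(rs) make_aaa_mesh(anatomy_params(sac_radius = rs,
                                                  circumferential_segments = 32,
                                                  axial_segments = 48))
  radii <- c(20, 25, 30, 35)
  areas <- vapply(radii, function(r) side_surface_area(mk(r)), numeric(1))
  phis <- vapply(radii, function(r) shape_factor_vs_cylinder(mk(r)), numeric(1))
  expect_true(all(diff(areas) > 0))
  expect_true(all(diff(phis) > 0))
})
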