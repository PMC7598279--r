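test_that("areas and volumes agree with brute-force oracles on random meshes", {
  set.seed(42)
  for (i in 1:50) {
    soup <- random_soup(n_tri = sample(2:8, 1))
    expect_rel(side_surface_area(soup), brute_area(soup), 1e-9)
  }
  for (i in 1:50) {
    tet <- random_tetra()
    expect_rel(enclosed_volume(tet$mesh), brute_tetra_volume(tet$pts), 1e-9)
    expect_rel(side_surface_area(tet$mesh), brute_area(tet$mesh), 1e-9)
  }
})

test_that("single-triangle and unit-cube closed forms hold exactly", {
  tri <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  expect_equal(side_surface_area(tri), 0.5)
  # unit cube as 12 outward-oriented triangles
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = 0 (down)
             c(5, 6, 7), c(6, 8, 7),   # z = 1 (up)
             c(1, 2, 5), c(2, 6, 5),   # y = 0
             c(3, 7, 4), c(4, 7, 8),   # y = 1
             c(1, 5, 3), c(3, 5, 7),   # x = 0
             c(2, 4, 6), c(4, 8, 6))   # x = 1
  cube <- tri_mesh(v, f, clean = FALSE)
  expect_equal(enclosed_volume(cube), 1.0)
})

test_that("axial height is the axis-aligned extent, sign-invariant", {
  cyl <- make_cylinder_mesh(1, 1, 32, 8)
  expect_equal(axial_height(cyl), 1.0)
  flipped <- tri_mesh(cyl$vertices, cyl$faces, axis = c(0, 0, -1))
  expect_equal(axial_height(flipped), 1.0)
  aaa <- make_aaa_mesh(anatomy_params(height = 130))
  expect_equal(axial_height(aaa), 130, tolerance = 1e-9)
})

test_that("strip_caps recovers the open lateral surface", {
  capped <- make_cylinder_mesh(1, 1, 128, 32, capped = TRUE)
  open_ <- strip_caps(capped)
  expect_rel(side_surface_area(open_), 2 * pi, 0.002)
  # already-open mesh is untouched
  plain <- make_cylinder_mesh(1, 1, 64, 16)
  expect_equal(nrow(strip_caps(plain)$faces), nrow(plain$faces))
  # a flat disc is all caps
  nc <- 32
  th <- 2 * pi * (seq_len(nc) - 1) / nc
  disc <- tri_mesh(rbind(cbind(cos(th), sin(th), 0), c(0, 0, 0)),
                   cbind(seq_len(nc), c(seq_len(nc)[-1], 1), nc + 1))
  expect_error(strip_caps(disc), "all caps")
})

test_that("open tubes are virtually capped before the volume sum", {
  cyl <- make_cylinder_mesh(1, 1, 192, 48)
  expect_rel(enclosed_volume(cyl), pi, 0.002)
  # bifurcated graft: three open tube components, each capped independently
  p <- anatomy_params()
  sl <- make_stentgraft_mesh(p, "long")
  frac <- p$graft_body_frac_long
  expect_rel(enclosed_volume(sl),
             pi * p$neck_radius^2 * frac * p$height +
               2 * pi * p$limb_radius^2 * (1 - frac) * p$height,
             0.01)
})

test_that("reference cylinder satisfies its defining identities", {
  # object with side surface 2*pi and height 1 has reference diameter 2
  cyl <- make_cylinder_mesh(1, 1, 256, 64)
  rc <- build_reference_cylinder(cyl)
  expect_rel(rc$diameter, 2, 0.002)
  for (mesh in list(cyl, make_aaa_mesh(anatomy_params()))) {
    rc <- build_reference_cylinder(mesh)
    expect_rel(pi * rc$diameter * rc$height, side_surface_area(mesh), 1e-9)
    expect_rel(rc$volume, pi * rc$diameter^2 / 4 * rc$height, 1e-9)
  }
  # a bulged AAA carries more lateral area than its neck cylinder
  rc_aaa <- build_reference_cylinder(make_aaa_mesh(anatomy_params()))
  expect_gt(rc_aaa$diameter, 20)
  expect_error(build_reference_cylinder(cyl, height_override = 0), "positive")
})

test_that("shape factor is 1 for a cylinder and converges under refinement", {
  coarse <- make_cylinder_mesh(1, 1, 160, 64)   # ~20k faces
  fine <- make_cylinder_mesh(1, 1, 320, 128)    # ~80k faces
  phi_c <- shape_factor_vs_cylinder(coarse)
  phi_f <- shape_factor_vs_cylinder(fine)
  expect_lt(abs(phi_c - 1), 0.01)
  expect_lt(abs(phi_f - 1), abs(phi_c - 1))
})

test_that("shape factors are scale invariant", {
  p <- anatomy_params(circumferential_segments = 32, axial_segments = 32)
  aaa <- make_aaa_mesh(p)
  sl <- make_stentgraft_mesh(p, "long")
  for (s in c(0.37, 2.5)) {
    aaa_s <- tri_mesh(aaa$vertices * s, aaa$faces)
    sl_s <- tri_mesh(sl$vertices * s, sl$faces)
    expect_rel(shape_factor_vs_cylinder(aaa_s),
               shape_factor_vs_cylinder(aaa), 1e-9)
    expect_rel(shape_factor_pair(aaa_s, sl_s)$phi_AS,
               shape_factor_pair(aaa, sl)$phi_AS, 1e-9)
  }
})

test_that("paired shape factor honours identity, ratio and reciprocity", {
  cyl <- make_cylinder_mesh(1, 1, 64, 16)
  expect_equal(shape_factor_pair(cyl, cyl)$phi_AS, 1.0)
  big <- make_cylinder_mesh(2, 1, 128, 32)
  small <- make_cylinder_mesh(1, 1, 128, 32)
  fwd <- shape_factor_pair(big, small, "aneurysm_over_graft")$phi_AS
  rev_ <- shape_factor_pair(big, small, "graft_over_aneurysm")$phi_AS
  expect_rel(fwd, 2.0, 0.005)
  expect_rel(rev_, 0.5, 0.005)
  expect_equal(fwd * rev_, 1.0, tolerance = 1e-12)
  # taller graft triggers a warning, aneurysm height is used
  tall <- make_cylinder_mesh(1, 1.2, 64, 16)
  expect_warning(shape_factor_pair(small, tall), "height")
})
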