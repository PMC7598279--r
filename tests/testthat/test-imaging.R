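test_that("phantom generation is deterministic with controlled levels", {
  ph0 <- make_phantom(noise_sigma = 0, shape = c(40, 40, 40))
  expect_equal(sort(unique(as.vector(ph0$volume$intensities))), c(205.2, 249))
  a <- make_phantom(seed = 11, shape = c(40, 40, 40))
  b <- make_phantom(seed = 11, shape = c(40, 40, 40))
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_error(make_phantom(object_radius = 100, shape = c(40, 40, 40)),
               "fit")
})

test_that("region growing floods uniform volumes and exact phantoms", {
  u <- voxel_volume(array(7, dim = c(12, 12, 12)))
  m <- region_grow(u, c(6, 6, 6), tolerance = 1)
  expect_true(all(m))
  ph <- make_phantom(noise_sigma = 0, shape = c(40, 40, 40), object_radius = 10)
  m2 <- region_grow(ph$volume, c(20, 20, 20), tolerance = 20)
  expect_identical(m2, ph$truth)
  expect_error(region_grow(ph$volume, c(99, 1, 1), 10), "outside")
})

test_that("region growing contains its seed and is tolerance-monotone", {
  ph <- make_phantom(noise_sigma = 0, shape = c(40, 40, 40), object_radius = 10)
  seed <- c(20, 20, 20)
  m_small <- region_grow(ph$volume, seed, tolerance = 5)
  m_large <- region_grow(ph$volume, seed, tolerance = 60)
  expect_true(m_small[20, 20, 20])
  expect_true(all(m_large[m_small]))   # superset at larger tolerance
  expect_gt(sum(m_large), sum(m_small))
})

test_that("hole filling closes cavities, is idempotent and non-destructive", {
  ph <- make_phantom(noise_sigma = 0, shape = c(40, 40, 40), object_radius = 12)
  shell <- ph$truth
  core <- make_phantom(noise_sigma = 0, shape = c(40, 40, 40),
                       object_radius = 7)$truth
  shell[core] <- FALSE
  filled <- fill_holes(shell)
  expect_identical(filled, ph$truth)        # hollow shell -> solid ball
  expect_identical(fill_holes(filled), filled)
  expect_true(all(filled[shell]))
  solid <- fill_holes(ph$truth)
  expect_identical(solid, ph$truth)         # nothing to fill
})

test_that("BI and CNR follow their definitions and shift behaviour", {
  d <- c(64, 64, 32)
  ph <- make_phantom(object_radius = 12, object_intensity = 249,
                     background_intensity = 205.2, noise_sigma = 10,
                     shape = d, seed = 3)
  ctr <- as.integer((d + 1) / 2)
  obj <- lapply((ctr[3] - 3):(ctr[3] + 3), function(s) {
    roi_spec(c(ctr[1], ctr[2], s), 80)
  })
  noise <- list(roi_spec(c(8, 8, ctr[3]), 100),
                roi_spec(c(d[1] - 7, d[2] - 7, ctr[3]), 100))
  bg <- list(roi_spec(c(10, ctr[2], ctr[3]), 80),
             roi_spec(c(d[1] - 9, ctr[2], ctr[3]), 80))
  bi <- brightness_to_noise(ph$volume, obj, noise)
  cnr <- contrast_to_noise(ph$volume, obj, bg, noise)
  expect_rel(bi, 24.9, 0.1)
  expect_rel(cnr, 4.38, 0.15)
  # intensity shift: CNR invariant, BI shifts by offset / noise
  shifted <- voxel_volume(ph$volume$intensities + 100, ph$volume$spacing)
  expect_equal(contrast_to_noise(shifted, obj, bg, noise), cnr,
               tolerance = 1e-9)
  bi_shift <- brightness_to_noise(shifted, obj, noise)
  expect_gt(bi_shift, bi + 5)
  # zero-noise volumes make the quotients undefined
  flat <- voxel_volume(array(1, dim = c(12, 12, 12)))
  fr <- list(roi_spec(c(6, 6, 6), 20))
  expect_error(brightness_to_noise(flat, fr, fr), "noise")
  # alternate noise reading (mean over SD) stays positive and finite
  bi2 <- brightness_to_noise(ph$volume, obj, noise,
                             noise_definition = "mean_over_sd")
  expect_true(is.finite(bi2) && bi2 > 0)
})
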