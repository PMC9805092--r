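test_that("background estimation matches the generator and handles degenerate frames", {
  img <- matrix(100, 200, 200)
  labels <- matrix(0L, 200, 200); labels[90:110, 90:110] <- 1L
  expect_equal(estimate_background(img, labels), 100)
  # noisy scene: median of many background pixels is tight around truth
  sc <- generate_micrograph(scene_spec(n_cells = 5, image_shape = c(400, 400),
                                       noise_sd = 5, seed = 21))
  cm <- segment_cells(sc$wall)
  expect_equal(estimate_background(sc$gfp, cm), 100, tolerance = 0.01)
  # noiseless: exact
  sc0 <- generate_micrograph(scene_spec(n_cells = 3, image_shape = c(300, 300),
                                        noise_sd = 0, seed = 22))
  cm0 <- segment_cells(sc0$wall)
  expect_lt(abs(estimate_background(sc0$gfp, cm0) - 100), 0.05)
  full <- matrix(1L, 20, 20)
  expect_error(estimate_background(matrix(0, 20, 20), full), "no background")
  expect_error(estimate_background(matrix(0, 10, 10), labels), "shape")
})

test_that("normalized profiles are flat for flat cells and flag degenerate denominators", {
  side <- 61
  d <- sqrt(outer((1:side - 31)^2, (1:side - 31)^2, "+"))
  mask <- matrix(as.integer(d <= 20), side, side)
  rg <- peel_rings(as_cell_label_map(mask))
  flat <- matrix(50, side, side); flat[mask == 1L] <- 300
  pr <- ring_profile(flat, rg, background = 50)
  inward <- pr$rings[pr$rings$ring <= 0 & pr$rings$npix > 0, ]
  expect_true(all(abs(inward$normalized - 1) < 1e-12))
  # cell at background level -> invalid, not an error
  pr2 <- ring_profile(matrix(50, side, side), rg, background = 50)
  expect_false(pr2$cells$valid)
})

test_that("profiles are invariant to adding a constant to the whole image", {
  sc <- generate_micrograph(scene_spec(n_cells = 4, image_shape = c(360, 360),
                                       seed = 23))
  cm <- segment_cells(sc$wall)
  rg <- peel_rings(cm)
  p1 <- ring_profile(sc$gfp, rg, estimate_background(sc$gfp, cm))
  shifted <- sc$gfp + 37
  p2 <- ring_profile(shifted, rg, estimate_background(shifted, cm))
  expect_equal(p1$rings$normalized, p2$rings$normalized, tolerance = 1e-9)
})

test_that("peak localization distinguishes wall, membrane and intracellular patterns", {
  # synthetic membrane-like shell one pixel deeper than the wall stain
  for (depth in c(4, 5)) {
    sc <- generate_micrograph(scene_spec(n_cells = 4, image_shape = c(360, 360),
                                         wall_peak_depth = depth,
                                         surface_fraction_true = 1,
                                         noise_sd = 0, seed = 24))
    rg <- peel_rings(as_cell_label_map(sc$truth$labels))
    pr <- ring_profile(sc$truth$noiseless_gfp, rg, background = 0)
    expect_true(all(locate_peak(pr) == -depth))
  }
  # intracellular pattern peaks at the innermost ring
  sci <- generate_micrograph(scene_spec(n_cells = 4, image_shape = c(360, 360),
                                        surface_fraction_true = 0,
                                        noise_sd = 0, seed = 25))
  rgi <- peel_rings(as_cell_label_map(sci$truth$labels))
  pri <- ring_profile(sci$truth$noiseless_gfp, rgi, background = 0)
  expect_true(all(locate_peak(pri) <= -8))
  # tie rule: equal maxima resolve to the outermost ring
  fake <- pri
  one <- fake$rings$cell_id == 1 & fake$rings$ring %in% c(-3, -4)
  fake$rings$normalized[one] <- 2
  expect_equal(unname(locate_peak(fake, cell_id = 1)), -3)
})

test_that("uniform fill with no blur gives FB = 1 on every populated ring", {
  sc <- generate_micrograph(scene_spec(n_cells = 3, image_shape = c(300, 300),
                                       surface_fraction_true = 0, psf_sigma = 0,
                                       noise_sd = 0, seed = 26))
  rg <- peel_rings(as_cell_label_map(sc$truth$labels))
  pr <- ring_profile(sc$gfp, rg, background = 100)
  fb <- estimate_bleedthrough(pr, min_cells = 3)
  expect_true(all(abs(fb$fb$fb - 1) < 1e-9))
})

test_that("FB from synthetic controls matches fb_true and is monotone inward", {
  scenes <- make_scenes(2, f_true = 0, seed0 = 260, n_cells = 25)
  fb <- pooled_fb(scenes, min_cells = 40)
  fb_true <- scenes[[1]]$truth$fb_true
  for (rg in fb$fb$ring) {
    expect_lt(abs(fb$fb$fb[fb$fb$ring == rg] -
                  fb_true$fb[fb_true$ring == rg]), 0.05)
  }
  ordered <- fb$fb[order(-fb$fb$ring), "fb"]  # ring 0 -> -9
  expect_true(all(diff(ordered) > -0.01))
  expect_error(estimate_bleedthrough(list(), min_cells = 40), "deficit")
})

test_that("the tuned bleed-geometry preset reproduces ~90% bleed at ring -4", {
  scenes <- lapply(1:2, function(i)
    generate_micrograph(bleed_geometry_preset(n_cells = 25,
                                              image_shape = c(512, 512),
                                              seed = 270 + i)))
  fb <- pooled_fb(scenes, min_cells = 40)
  expect_equal(fb$fb$fb[fb$fb$ring == -4], 0.9, tolerance = 0.05)
  # deeper rings carry at least as much intracellular signal
  expect_gte(fb$fb$fb[fb$fb$ring == -5] + 0.01,
             fb$fb$fb[fb$fb$ring == -4])
})

test_that("FB estimates agree between one strain and pooled strains", {
  one <- make_scenes(2, f_true = 0, seed0 = 280, n_cells = 25)
  three <- make_scenes(6, f_true = 0, seed0 = 290, n_cells = 25)
  fb1 <- pooled_fb(one); fb3 <- pooled_fb(three)
  for (rg in fb1$fb$ring) {
    a <- fb1$fb[fb1$fb$ring == rg, ]; b <- fb3$fb[fb3$fb$ring == rg, ]
    sem <- sqrt(a$sd^2 / a$n + b$sd^2 / b$n)
    expect_lt(abs(a$fb - b$fb), 2 * sem + 0.01)
  }
})
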