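test_that("scene generation is deterministic and validates its spec", {
  sp <- scene_spec(n_cells = 6, image_shape = c(300, 300), seed = 1,
                   surface_fraction_true = 0.3)
  a <- generate_micrograph(sp)
  b <- generate_micrograph(sp)
  expect_identical(a$gfp, b$gfp)
  expect_identical(a$wall, b$wall)
  expect_identical(a$truth$labels, b$truth$labels)

  expect_error(scene_spec(surface_fraction_true = 1.2), "\\[0, 1\\]")
  expect_error(scene_spec(inner_intensity = -1), ">= 0")
  # overlap-placement failure is an explicit error
  expect_error(generate_micrograph(
    scene_spec(n_cells = 50, image_shape = c(120, 120), seed = 1)),
    "could not place|too small")
})

test_that("an empty scene is pure background plus noise", {
  sc <- generate_micrograph(scene_spec(n_cells = 0, image_shape = c(80, 80),
                                       noise_sd = 0, seed = 1))
  expect_true(all(sc$gfp == 100))
  expect_true(all(sc$truth$labels == 0L))
  sc2 <- generate_micrograph(scene_spec(n_cells = 0, image_shape = c(80, 80),
                                        noise_sd = 3, seed = 1))
  expect_equal(mean(sc2$gfp), 100, tolerance = 0.01)
})

test_that("with no blur and pure surface display the core is exactly background", {
  # narrow shell: its compact support cannot reach any CORE pixel, so the
  # core is background exactly, not just approximately
  sc <- generate_micrograph(scene_spec(n_cells = 3, image_shape = c(260, 260),
                                       surface_fraction_true = 1,
                                       wall_shell_sigma = 1,
                                       psf_sigma = 0, noise_sd = 0, seed = 2))
  rg <- peel_rings(as_cell_label_map(sc$truth$labels))
  core <- ring_mask(rg, 1, core_code(rg))
  expect_true(all(abs(sc$gfp[core] - sc$spec$background_level) < 1e-9))
  # all cell GFP is in the wall band: total inside rings ~ total truth
  expect_gt(sum(sc$gfp - 100), 0.999 * sum(sc$truth$cells$total_gfp_true))
  # at the default shell width the core still carries < 0.5% of the fill level
  sc2 <- generate_micrograph(scene_spec(n_cells = 3, image_shape = c(260, 260),
                                        surface_fraction_true = 1,
                                        psf_sigma = 0, noise_sd = 0, seed = 2))
  rg2 <- peel_rings(as_cell_label_map(sc2$truth$labels))
  core2 <- ring_mask(rg2, 1, core_code(rg2))
  expect_lt(stats::median(sc2$gfp[core2]) - 100, 0.005 * sc2$spec$inner_intensity)
})

test_that("rendered GFP is conserved against ground truth (noise off)", {
  sc <- generate_micrograph(scene_spec(n_cells = 8, image_shape = c(400, 400),
                                       surface_fraction_true = 0.4,
                                       noise_sd = 0, seed = 3))
  total_rendered <- sum(sc$truth$noiseless_gfp)
  total_true <- sum(sc$truth$cells$total_gfp_true)
  expect_equal(total_rendered, total_true, tolerance = 1e-3)
})

test_that("the wall-stain radial profile peaks at -wall_peak_depth for radii >= 12", {
  for (depth in c(4, 5)) {
    sc <- generate_micrograph(scene_spec(n_cells = 6, image_shape = c(400, 400),
                                         wall_peak_depth = depth,
                                         radius_range = c(14, 24),
                                         noise_sd = 0, seed = 4))
    rg <- peel_rings(as_cell_label_map(sc$truth$labels))
    pr <- ring_profile(sc$truth$noiseless_wall, rg, background = 0)
    peaks <- locate_peak(pr)
    expect_true(all(peaks == -depth),
                info = sprintf("wall depth %d gave peaks %s", depth,
                               paste(peaks, collapse = ",")))
  }
})

test_that("scene IO round-trips through 16-bit TIFF and a JSON sidecar", {
  dir <- withr::local_tempdir()
  sc <- generate_micrograph(scene_spec(n_cells = 3, image_shape = c(220, 220),
                                       seed = 5))
  paths <- write_scene(sc, dir, "t")
  expect_true(all(file.exists(paths)))
  gfp <- read_tiff16(paths["gfp"])
  expect_equal(dim(gfp), dim(sc$gfp))
  expect_lt(max(abs(gfp - pmax(round(sc$gfp), 0))), 0.5)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$seed, 5)
  expect_equal(nrow(truth$cells), 3)
  # saturation warning on clipping
  hot <- sc; hot$gfp[1, 1] <- 1e6
  expect_warning(write_scene(hot, dir, "hot"), "clipped")
})

test_that("calibration table generator matches its stated power law", {
  tab <- generate_calibration_table(noise_sd = 0, seed = 1)
  dat <- calibration_gfp_norm(tab)
  fit <- fit_calibration(dat$gfp_norm, dat$molecules_per_cell_true)
  expect_equal(fit$r2, 1.0, tolerance = 1e-12)
  expect_equal(fit$slope, 1.0, tolerance = 1e-9)
  expect_equal(fit$intercept, -3.5, tolerance = 1e-9)
  expect_error(generate_calibration_table(abundances = c(-1, 10, 100)),
               "positive")
})

test_that("kinetics generator obeys saturation and half-saturation identities", {
  sp <- assay_spec(vmax_true = 2, km_true = 5,
                   substrate_concentrations = c(2.5, 5, 10, 100, 5000),
                   n_replicates = 1, autohydrolysis_rate = 0,
                   read_noise_sd = 0, seed = 1)
  tab <- generate_kinetics_dataset(sp)
  v <- initial_rate(pnp_concentration(tab$a405, tab$a405_control,
                                      sp$epsilon, sp$pathlength),
                    tab$duration_min)
  expect_equal(v[tab$s_uM == 5000], 2, tolerance = 1e-3)   # S = 1000 Km
  expect_equal(v[tab$s_uM == 5], 1, tolerance = 1e-9)      # S = Km
  expect_error(assay_spec(km_true = -1), "> 0")
  expect_error(assay_spec(substrate_concentrations = c(3, 2, 1)), "sorted")
})

test_that("growth-curve generator recovers its generating rate structure", {
  # early exponential segment, noise off
  g <- generate_growth_curves(0.4, od0 = 0.01, duration_h = 6,
                              noise_sd = 0, seed = 1)
  mu <- growth_rate(g$time_min, g$od600)
  expect_equal(mu, 0.4, tolerance = 0.02)
  expect_error(generate_growth_curves(0.4, od0 = 0), "> 0")
  expect_error(generate_growth_curves(-0.1), "> 0")
})
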